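#' @importFrom methods as
NULL

# Read primary alignments from SAM or BAM, excluding secondary,
# supplementary, duplicate and unmapped records (one vote per fragment).
.read_alignments <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such alignment file: ", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    first <- readLines(path, n = 1)
    if (length(first) == 0 || !startsWith(first, "@")) {
      rlang::abort(paste0("SAM file lacks a header: ", path))
    }
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, indexDestination = FALSE),
      error = function(e) rlang::abort(paste0("failed to parse ", path, ": ",
                                              conditionMessage(e))))
  }
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE,
                                 isUnmappedQuery = FALSE)
  GenomicAlignments::readGAlignments(bam, use.names = TRUE,
                                     param = Rsamtools::ScanBamParam(flag = flag))
}

# annotation-derived index reused across samples
.counting_index <- function(ann) {
  geom <- .gene_geometry(ann)
  gene_gr <- .gene_ranges(ann)
  ex <- ann$exons
  exon_gr <- GenomicRanges::GRanges(ex$chrom,
                                    IRanges::IRanges(ex$start + 1L, ex$end))
  S4Vectors::mcols(exon_gr)$transcript_id <- ex$transcript_id
  introns <- geom$introns
  intron_gr <- GenomicRanges::GRanges(introns$chrom,
                                      IRanges::IRanges(introns$start + 1L,
                                                       introns$end))
  S4Vectors::mcols(intron_gr)$transcript_id <- introns$transcript_id
  rule2_gr <- GenomicRanges::GRanges()
  if (length(geom$rule2) > 0) {
    w <- vapply(geom$rule2, length, 1L)
    genes_w <- names(geom$rule2)[w > 0]
    if (length(genes_w) > 0) {
      ir <- unlist(IRanges::IRangesList(geom$rule2[genes_w]), use.names = FALSE)
      chroms <- rep(setNames(ann$genes$chrom, ann$genes$gene_id)[genes_w],
                    w[genes_w])
      rule2_gr <- GenomicRanges::GRanges(chroms, ir)
      S4Vectors::mcols(rule2_gr)$gene_id <- rep(genes_w, w[genes_w])
    }
  }
  n_exons_tx <- table(ex$transcript_id)
  n_introns_tx <- if (nrow(introns) > 0) table(introns$transcript_id) else table(character(0))
  tx_gene <- setNames(ann$transcripts$gene_id, ann$transcripts$transcript_id)
  list(gene_gr = gene_gr, exon_gr = exon_gr, intron_gr = intron_gr,
       rule2_gr = rule2_gr, has_introns = geom$has_introns, tx_gene = tx_gene)
}

#' Classify aligned read pairs into splice layers
#'
#' Applies the layer rules per read pair: the pair is assigned to the
#' single gene whose span contains all aligned blocks of its mapped mates
#' (overlap with several genes, or none, is `unassigned`); it is `spliced`
#' if some mate's alignment gap(s) exactly match annotated intron(s) of a
#' transcript with all that mate's blocks exonic in the same transcript
#' and no mate touches constitutively intronic sequence; `unspliced` if
#' any aligned base overlaps a region intronic in every transcript of the
#' gene; reads in intronless genes are `spliced` by definition; everything
#' else is `ambiguous`. Secondary/supplementary/duplicate alignments are
#' ignored; a pair with an unmapped mate is classified by the mapped mate.
#'
#' @param path SAM or BAM file of one sample.
#' @param ann A [genome_annotation()].
#' @param index Optional prebuilt index (internal use across samples).
#' @return Tibble `qname`, `gene_id` (`NA` if unassigned), `class` in
#'   `spliced`/`unspliced`/`ambiguous`/`unassigned`.
#' @export
classify_reads <- function(path, ann, index = NULL) {
  stopifnot(inherits(ann, "genome_annotation"))
  if (is.null(index)) index <- .counting_index(ann)
  gal <- .read_alignments(path)
  if (length(gal) == 0) {
    return(tibble(qname = character(0), gene_id = character(0),
                  class = character(0)))
  }
  qname <- names(gal)
  aln_chrom <- as.character(GenomicAlignments::seqnames(gal))

  # pair-level gene assignment: enclosing range over both mates' blocks
  aln_tbl <- tibble(aln = seq_along(gal), qname = qname, chrom = aln_chrom,
                    start = GenomicAlignments::start(gal),
                    end = GenomicAlignments::end(gal))
  pair_span <- aln_tbl |>
    group_by(.data$qname) |>
    summarise(chrom = dplyr::first(.data$chrom),
              nchrom = n_distinct(.data$chrom),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  span_gr <- GenomicRanges::GRanges(pair_span$chrom,
                                    IRanges::IRanges(pair_span$start,
                                                     pair_span$end))
  hits <- GenomicRanges::findOverlaps(span_gr, index$gene_gr, type = "within",
                                      ignore.strand = TRUE)
  nhit <- tabulate(S4Vectors::queryHits(hits), nbins = nrow(pair_span))
  gene_of <- rep(NA_character_, nrow(pair_span))
  uniq <- which(nhit == 1)
  first_hit <- S4Vectors::queryHits(hits)
  gene_of[uniq] <- names(index$gene_gr)[S4Vectors::subjectHits(hits)[match(uniq, first_hit)]]
  gene_of[pair_span$nchrom > 1] <- NA_character_
  pair_gene <- setNames(gene_of, pair_span$qname)
  assigned <- pair_gene[qname]

  # per-alignment blocks and junction gaps
  blocks <- GenomicAlignments::grglist(gal)
  bl_flat <- unlist(blocks, use.names = FALSE)
  bl_aln <- rep(seq_along(gal), S4Vectors::elementNROWS(blocks))
  n_blocks <- S4Vectors::elementNROWS(blocks)
  gaps <- GenomicAlignments::junctions(gal)
  gp_flat <- unlist(gaps, use.names = FALSE)
  gp_aln <- rep(seq_along(gal), S4Vectors::elementNROWS(gaps))
  n_gaps <- S4Vectors::elementNROWS(gaps)

  # rule 2: any block overlapping the assigned gene's constitutive introns
  rule2_aln <- rep(FALSE, length(gal))
  if (length(index$rule2_gr) > 0 && length(bl_flat) > 0) {
    h2 <- GenomicRanges::findOverlaps(bl_flat, index$rule2_gr,
                                      ignore.strand = TRUE)
    if (length(h2) > 0) {
      a <- bl_aln[S4Vectors::queryHits(h2)]
      g <- S4Vectors::mcols(index$rule2_gr)$gene_id[S4Vectors::subjectHits(h2)]
      ok <- !is.na(assigned[a]) & assigned[a] == g
      rule2_aln[unique(a[ok])] <- TRUE
    }
  }

  # rule 1: per alignment, a transcript of the assigned gene whose introns
  # match every gap exactly and whose exons contain every block
  rule1_aln <- rep(FALSE, length(gal))
  with_gaps <- which(n_gaps > 0 & !is.na(assigned[qname]))
  if (length(with_gaps) > 0 && length(gp_flat) > 0) {
    hg <- GenomicRanges::findOverlaps(gp_flat, index$intron_gr, type = "equal",
                                      ignore.strand = TRUE)
    gap_match <- tibble(
      aln = gp_aln[S4Vectors::queryHits(hg)],
      gap = S4Vectors::queryHits(hg),
      tx = S4Vectors::mcols(index$intron_gr)$transcript_id[S4Vectors::subjectHits(hg)])
    hb <- GenomicRanges::findOverlaps(bl_flat, index$exon_gr, type = "within",
                                      ignore.strand = TRUE)
    blk_match <- tibble(
      aln = bl_aln[S4Vectors::queryHits(hb)],
      blk = S4Vectors::queryHits(hb),
      tx = S4Vectors::mcols(index$exon_gr)$transcript_id[S4Vectors::subjectHits(hb)])
    if (nrow(gap_match) > 0) {
      cand <- gap_match |>
        distinct(.data$aln, .data$gap, .data$tx) |>
        count(.data$aln, .data$tx, name = "gaps_ok") |>
        filter(.data$gaps_ok == n_gaps[.data$aln],
               index$tx_gene[.data$tx] == assigned[qname[.data$aln]])
      if (nrow(cand) > 0) {
        blk_ok <- blk_match |>
          distinct(.data$aln, .data$blk, .data$tx) |>
          count(.data$aln, .data$tx, name = "blocks_ok") |>
          dplyr::semi_join(cand, by = c("aln", "tx")) |>
          filter(.data$blocks_ok == n_blocks[.data$aln])
        rule1_aln[unique(blk_ok$aln)] <- TRUE
      }
    }
  }

  per_pair <- tibble(qname = qname, rule1 = rule1_aln, rule2 = rule2_aln) |>
    group_by(.data$qname) |>
    summarise(rule1 = any(.data$rule1), rule2 = any(.data$rule2),
              .groups = "drop")
  per_pair$gene_id <- unname(pair_gene[per_pair$qname])
  intronless <- !index$has_introns
  per_pair |>
    mutate(class = dplyr::case_when(
      is.na(.data$gene_id) ~ "unassigned",
      .data$rule2 ~ "unspliced",
      .data$rule1 ~ "spliced",
      intronless[.data$gene_id] ~ "spliced",
      TRUE ~ "ambiguous")) |>
    select("qname", "gene_id", "class") |>
    arrange(.data$qname)
}

#' Count reads into spliced/unspliced/ambiguous layers
#'
#' Runs [classify_reads()] on one alignment file per sample and tallies
#' read pairs per gene and layer. Each pair is counted once, in exactly
#' one layer of one gene; the result is independent of record order in
#' the input files.
#'
#' @param paths Character vector of SAM/BAM files, one per sample.
#' @param ann A [genome_annotation()].
#' @param sample_names Sample labels; default the file base names.
#' @return A [layered_counts()] with one column per file and a summary
#'   tibble (assigned/unassigned tallies per sample) in attribute
#'   `"summary"`.
#' @export
count_layers <- function(paths, ann, sample_names = NULL) {
  stopifnot(inherits(ann, "genome_annotation"))
  if (is.null(sample_names)) {
    sample_names <- sub("\\.(sam|bam)$", "", basename(paths), ignore.case = TRUE)
  }
  index <- .counting_index(ann)
  genes <- ann$genes$gene_id
  empty <- function() matrix(0L, nrow = length(genes), ncol = length(paths),
                             dimnames = list(genes, sample_names))
  mats <- list(spliced = empty(), unspliced = empty(), ambiguous = empty())
  summaries <- vector("list", length(paths))
  for (j in seq_along(paths)) {
    cls <- classify_reads(paths[j], ann, index = index)
    tallied <- cls |>
      filter(.data$class != "unassigned") |>
      count(.data$gene_id, .data$class)
    for (l in names(mats)) {
      sub <- filter(tallied, .data$class == l)
      mats[[l]][match(sub$gene_id, genes), j] <- sub$n
    }
    summaries[[j]] <- tibble(sample = sample_names[j],
                             n_pairs = nrow(cls),
                             assigned = sum(cls$class != "unassigned"),
                             unassigned = sum(cls$class == "unassigned"),
                             ambiguous = sum(cls$class == "ambiguous"))
  }
  lc <- layered_counts(mats$spliced, mats$unspliced, mats$ambiguous,
                       samples = tibble(sample = sample_names,
                                        condition = NA_character_))
  attr(lc, "summary") <- bind_rows(summaries)
  lc
}

#' Assign a read (pair) to a gene by span containment
#'
#' @param ann A [genome_annotation()].
#' @param chrom Chromosome of the aligned blocks.
#' @param blocks Tibble of aligned blocks `start`, `end` (0-based
#'   half-open), pooled over both mates.
#' @return The containing gene id, or `NA` if the blocks overlap zero or
#'   several genes (or lie on an unannotated chromosome).
#' @export
assign_gene <- function(ann, chrom, blocks) {
  g <- ann$genes
  enc_start <- min(blocks$start)
  enc_end <- max(blocks$end)
  hit <- g$chrom == chrom & g$start <= enc_start & g$end >= enc_end
  # also reject if blocks overlap an additional gene
  touch <- g$chrom == chrom & g$start < enc_end & g$end > enc_start
  if (sum(hit) == 1 && sum(touch) == 1) g$gene_id[hit] else NA_character_
}

#' Classify one read pair against a gene's transcript models
#'
#' Pure-R single-pair version of the layer rules, convenient for
#' rule-level inspection. Mates are lists with `blocks` (tibble `start`,
#' `end`, 0-based half-open) and optional `gaps` (same format).
#'
#' @param ann A [genome_annotation()].
#' @param gene_id Assigned gene.
#' @param mates List of 1-2 mate descriptions.
#' @return `"spliced"`, `"unspliced"` or `"ambiguous"`.
#' @export
classify_read <- function(ann, gene_id, mates) {
  geom <- .gene_geometry(ann)
  txs <- ann$transcripts$transcript_id[ann$transcripts$gene_id == gene_id]
  introns <- geom$introns
  rule2_ir <- geom$rule2[[gene_id]]
  as_ir <- function(df) {
    if (is.null(df) || nrow(df) == 0) IRanges::IRanges()
    else IRanges::IRanges(df$start + 1L, df$end)
  }
  rule2 <- FALSE
  rule1 <- FALSE
  for (m in mates) {
    bl <- as_ir(m$blocks)
    gp <- as_ir(m$gaps)
    if (length(rule2_ir) > 0 &&
        any(IRanges::countOverlaps(bl, rule2_ir) > 0)) rule2 <- TRUE
    if (length(gp) > 0) {
      for (tx in txs) {
        tx_in <- filter(introns, .data$transcript_id == tx)
        tx_ex <- filter(ann$exons, .data$transcript_id == tx)
        in_ir <- as_ir(tx_in)
        ex_ir <- as_ir(tx_ex)
        gaps_ok <- all(IRanges::countOverlaps(gp, in_ir, type = "equal") > 0)
        blocks_ok <- all(IRanges::countOverlaps(bl, ex_ir, type = "within") > 0)
        if (gaps_ok && blocks_ok) { rule1 <- TRUE; break }
      }
    }
  }
  if (rule2) return("unspliced")
  if (rule1) return("spliced")
  if (!geom$has_introns[[gene_id]]) return("spliced")
  "ambiguous"
}
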