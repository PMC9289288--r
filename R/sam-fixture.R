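# Per-gene interval geometry used by both the fixture generator and the
# read classifier: per-transcript introns, the region intronic in ALL
# transcripts of a gene (rule-2 region), the exon union, and whether the
# gene has any intron at all.
.gene_geometry <- function(ann) {
  introns <- intron_intervals(ann)
  tx_by_gene <- split(ann$transcripts$transcript_id, ann$transcripts$gene_id)
  intr_by_tx <- split(IRanges::IRanges(introns$start + 1L, introns$end),
                      factor(introns$transcript_id,
                             levels = ann$transcripts$transcript_id))
  rule2 <- lapply(tx_by_gene, function(txs) {
    Reduce(IRanges::intersect, unname(intr_by_tx[txs]))
  })
  ex_by_gene <- split(IRanges::IRanges(ann$exons$start + 1L, ann$exons$end),
                      factor(ann$exons$gene_id, levels = names(tx_by_gene)))
  exon_union <- lapply(ex_by_gene, IRanges::reduce)
  has_introns <- vapply(tx_by_gene, function(txs) {
    any(vapply(intr_by_tx[txs], length, 1L) > 0)
  }, logical(1))
  list(rule2 = rule2, exon_union = exon_union, has_introns = has_introns,
       introns = introns)
}

.sam_header <- function(ann) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(ann$chrom_lengths),
            as.integer(ann$chrom_lengths)))
}

.sam_record <- function(qname, flag, chrom, pos1, cigar, mchrom = "=",
                        mpos1 = 0L, tlen = 0L, mlen = NULL) {
  if (is.null(mlen)) {
    # aligned query length from CIGAR M operations
    ops <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")[[1]]
    mlen <- sum(as.integer(ops[ops[, 3] %in% c("M", "I", "S", "=", "X"), 2]))
  }
  paste(qname, flag, chrom, pos1, 60L, cigar, mchrom, mpos1, tlen,
        strrep("A", max(mlen, 1L)), strrep("I", max(mlen, 1L)), sep = "\t")
}

#' Generate a SAM fixture with known splice-status labels
#'
#' Writes a headered, unsorted paired-end SAM file whose read pairs are
#' constructed to have unambiguous truth: junction pairs whose aligned gap
#' matches an annotated intron exactly (`spliced`), pairs lying wholly
#' inside regions intronic in every isoform (`unspliced`), exonic
#' non-junction pairs in intron-bearing genes (`ambiguous`), reads in
#' intronless genes (`spliced` by definition), and junction reads with an
#' unmapped mate to exercise single-mate classification.
#'
#' @param ann A [genome_annotation()]; needs multi-exon and single-exon genes.
#' @param n_pairs Number of read pairs.
#' @param path Output SAM path.
#' @param seed Integer seed.
#' @param proportions Named mix over categories `spliced_junction`,
#'   `unspliced_intronic`, `ambiguous_exonic`, `single_exon`,
#'   `junction_halfpair`; renormalised over categories with candidates.
#' @return Tibble `qname`, `gene_id`, `category`, `truth` (one row per
#'   pair), with the SAM path in attribute `"path"`.
#' @export
generate_sam_fixture <- function(ann, n_pairs = 1000, path, seed = 1,
                                 proportions = c(spliced_junction = 0.35,
                                                 unspliced_intronic = 0.25,
                                                 ambiguous_exonic = 0.25,
                                                 single_exon = 0.10,
                                                 junction_halfpair = 0.05)) {
  stopifnot(inherits(ann, "genome_annotation"))
  geom <- .gene_geometry(ann)
  gene_chrom <- setNames(ann$genes$chrom, ann$genes$gene_id)

  # candidate tables per category (1-based closed intervals)
  ex <- ann$exons
  junc <- geom$introns |>
    group_by(.data$transcript_id) |>
    mutate(idx = dplyr::row_number()) |>
    ungroup()
  if (nrow(junc) > 0) {
    flank <- ex |>
      group_by(.data$transcript_id) |>
      arrange(.data$start, .by_group = TRUE) |>
      mutate(idx = dplyr::row_number()) |>
      ungroup()
    junc <- junc |>
      left_join(flank |> select("transcript_id", "idx",
                                left_start = "start", left_end = "end"),
                by = c("transcript_id", "idx")) |>
      left_join(flank |> mutate(idx = .data$idx - 1L) |>
                  select("transcript_id", "idx",
                         right_start = "start", right_end = "end"),
                by = c("transcript_id", "idx")) |>
      filter(.data$left_end - .data$left_start >= 31,
             .data$right_end - .data$right_start >= 15)
  }
  rule2_tbl <- purrr::imap_dfr(geom$rule2, function(ir, g) {
    if (length(ir) == 0) return(tibble())
    tibble(gene_id = g, start1 = IRanges::start(ir), end1 = IRanges::end(ir))
  })
  if (nrow(rule2_tbl) > 0) {
    rule2_tbl <- filter(rule2_tbl, .data$end1 - .data$start1 + 1 >= 60)
  }
  amb_tbl <- ex |>
    filter(.data$gene_id %in% names(which(geom$has_introns)),
           .data$end - .data$start >= 40) |>
    distinct(.data$gene_id, .data$start, .data$end)
  single_tbl <- ex |>
    filter(.data$gene_id %in% names(which(!geom$has_introns)),
           .data$end - .data$start >= 40) |>
    distinct(.data$gene_id, .data$start, .data$end)

  avail <- c(spliced_junction = nrow(junc) > 0,
             unspliced_intronic = nrow(rule2_tbl) > 0,
             ambiguous_exonic = nrow(amb_tbl) > 0,
             single_exon = nrow(single_tbl) > 0,
             junction_halfpair = nrow(junc) > 0)
  pr <- proportions[names(avail)][avail]
  if (length(pr) == 0) rlang::abort("annotation offers no fixture candidates")
  pr <- pr / sum(pr)

  .with_seed(seed, {
    cats <- sample(names(pr), n_pairs, replace = TRUE, prob = pr)
    lines <- character(0)
    truth <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      qn <- sprintf("r%06d", i)
      cat_i <- cats[i]
      if (cat_i %in% c("spliced_junction", "junction_halfpair")) {
        row <- junc[sample.int(nrow(junc), 1), ]
        ilen <- row$end - row$start
        pos1 <- row$start + 1L - 15L           # 0-based intron start -> anchor
        cigar1 <- sprintf("15M%dN15M", ilen)
        ch <- gene_chrom[[row$gene_id]]
        # mate 2 inside the left flanking exon
        m2_start <- row$left_start + 1L +
          sample.int(max(row$left_end - row$left_start - 30L, 1L), 1) - 1L
        if (cat_i == "spliced_junction") {
          rec1 <- .sam_record(qn, 99L, ch, pos1, cigar1, "=", m2_start)
          rec2 <- .sam_record(qn, 147L, ch, m2_start, "30M", "=", pos1)
          lines <- c(lines, rec1, rec2)
        } else {
          rec1 <- .sam_record(qn, 73L, ch, pos1, cigar1, "=", pos1)
          rec2 <- .sam_record(qn, 133L, ch, pos1, "*", "=", pos1, mlen = 30L)
          lines <- c(lines, rec1, rec2)
        }
        truth[[i]] <- tibble(qname = qn, gene_id = row$gene_id,
                             category = cat_i, truth = "spliced")
      } else if (cat_i == "unspliced_intronic") {
        row <- rule2_tbl[sample.int(nrow(rule2_tbl), 1), ]
        ch <- gene_chrom[[row$gene_id]]
        p1 <- row$start1 + sample.int(max(row$end1 - row$start1 - 39L, 1L), 1) - 1L
        p2 <- min(p1 + 10L, row$end1 - 29L)
        rec1 <- .sam_record(qn, 99L, ch, p1, "30M", "=", p2)
        rec2 <- .sam_record(qn, 147L, ch, p2, "30M", "=", p1)
        lines <- c(lines, rec1, rec2)
        truth[[i]] <- tibble(qname = qn, gene_id = row$gene_id,
                             category = cat_i, truth = "unspliced")
      } else {
        tbl <- if (cat_i == "ambiguous_exonic") amb_tbl else single_tbl
        row <- tbl[sample.int(nrow(tbl), 1), ]
        ch <- gene_chrom[[row$gene_id]]
        lo <- row$start + 1L
        hi <- row$end - 30L
        p1 <- lo + sample.int(max(hi - lo, 1L), 1) - 1L
        p2 <- min(p1 + 5L, hi)
        rec1 <- .sam_record(qn, 99L, ch, p1, "30M", "=", p2)
        rec2 <- .sam_record(qn, 147L, ch, p2, "30M", "=", p1)
        lines <- c(lines, rec1, rec2)
        lab <- if (cat_i == "ambiguous_exonic") "ambiguous" else "spliced"
        truth[[i]] <- tibble(qname = qn, gene_id = row$gene_id,
                             category = cat_i, truth = lab)
      }
    }
    writeLines(c(.sam_header(ann), lines), path)
    out <- bind_rows(truth)
    attr(out, "path") <- path
    out
  })
}
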