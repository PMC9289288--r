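#' @import dplyr
#' @import tibble
#' @importFrom rlang .data abort warn
#' @importFrom purrr map map2 map_dbl map_chr map_int map_lgl pmap imap walk
#' @importFrom stats setNames
NULL

# Ensembl biotype strings -> internal biotype vocabulary
.BIOTYPE_MAP <- c(
  protein_coding          = "protein_coding",
  retained_intron         = "retained_intron",
  processed_transcript    = "orf_lacking",
  nonsense_mediated_decay = "nmd",
  lncRNA                  = "lncRNA",
  lincRNA                 = "lncRNA"
)

# internal vocabulary -> Ensembl string used when writing GTF
.BIOTYPE_UNMAP <- c(
  protein_coding  = "protein_coding",
  retained_intron = "retained_intron",
  orf_lacking     = "processed_transcript",
  nmd             = "nonsense_mediated_decay",
  lncRNA          = "lncRNA",
  other           = "misc_RNA"
)

#' Transcript biotype vocabulary
#'
#' Internal biotype categories used throughout the package, following the
#' Ensembl transcript classes relevant to coding/noncoding pool analysis:
#' `protein_coding`, `retained_intron`, `orf_lacking` (Ensembl
#' "processed_transcript"), `nmd` (nonsense-mediated decay), `lncRNA`,
#' and `other` for everything else.
#'
#' @return Character vector of the six biotype levels.
#' @export
biotype_levels <- function() {
  c("protein_coding", "retained_intron", "orf_lacking", "nmd", "lncRNA", "other")
}

#' Map Ensembl biotype strings to the internal vocabulary
#'
#' @param x Character vector of Ensembl biotype strings (e.g.
#'   `"processed_transcript"`, `"nonsense_mediated_decay"`).
#' @return Character vector over [biotype_levels()]; unknown strings map to
#'   `"other"`.
#' @export
map_biotype <- function(x) {
  out <- unname(.BIOTYPE_MAP[x])
  out[is.na(out)] <- "other"
  out
}

#' Construct a genome annotation
#'
#' The central gene-model container. All coordinates are 0-based half-open;
#' GTF input/output converts at the boundary. Genes, transcripts and their
#' exon structure are stored as tibbles so they compose directly with dplyr
#' verbs.
#'
#' @param exons Tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `start`, `end` (0-based half-open).
#' @param biotypes Optional tibble `transcript_id`, `biotype` (internal
#'   vocabulary, see [biotype_levels()]); transcripts without an entry get
#'   `"other"`.
#' @param chrom_lengths Optional named numeric vector of chromosome lengths
#'   in bp; defaults to the maximum annotated end per chromosome.
#' @param cytobands Optional tibble `chrom`, `start`, `end`, `name`
#'   (0-based half-open) of first-level chromosome bands.
#' @return An object of class `genome_annotation` with elements `genes`,
#'   `transcripts`, `exons`, `chrom_lengths`, `cytobands`. Gene records
#'   carry a `cytoband` column (`NA` until [assign_cytobands()] is applied,
#'   which happens automatically when `cytobands` is supplied).
#' @export
genome_annotation <- function(exons, biotypes = NULL, chrom_lengths = NULL,
                              cytobands = NULL) {
  req <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(req, names(exons))
  if (length(missing_cols) > 0) {
    abort(paste0("exons is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  exons <- as_tibble(exons)[req]
  if (any(is.na(exons$transcript_id)) || any(exons$transcript_id == "")) {
    abort("exon record without transcript_id")
  }
  if (any(exons$end <= exons$start)) abort("exon with end <= start")
  if (!all(exons$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  exons <- arrange(exons, .data$chrom, .data$transcript_id, .data$start)

  # exons within a transcript must be non-overlapping
  ov <- exons |>
    group_by(.data$transcript_id) |>
    summarise(bad = any(.data$start[-1] < .data$end[-length(.data$end)]),
              nchrom = n_distinct(.data$chrom),
              nstrand = n_distinct(.data$strand), .groups = "drop")
  if (any(ov$bad, na.rm = TRUE)) {
    abort(paste0("overlapping exons within transcript(s): ",
                 paste(ov$transcript_id[which(ov$bad)], collapse = ", ")))
  }
  if (any(ov$nchrom > 1) || any(ov$nstrand > 1)) {
    abort("transcript spans multiple chromosomes or strands")
  }

  transcripts <- exons |>
    group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_exons = n(), .groups = "drop")
  tx_gene <- transcripts |> count(.data$transcript_id) |> filter(.data$n > 1)
  if (nrow(tx_gene) > 0) {
    abort(paste0("transcript assigned to multiple genes: ",
                 paste(tx_gene$transcript_id, collapse = ", ")))
  }
  if (!is.null(biotypes)) {
    biotypes <- as_tibble(biotypes)
    bad <- setdiff(biotypes$biotype, biotype_levels())
    if (length(bad) > 0) {
      abort(paste0("unknown biotype(s): ", paste(unique(bad), collapse = ", ")))
    }
    transcripts <- left_join(transcripts, biotypes[c("transcript_id", "biotype")],
                             by = "transcript_id")
    transcripts$biotype[is.na(transcripts$biotype)] <- "other"
  } else {
    transcripts$biotype <- "other"
  }

  genes <- transcripts |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_transcripts = n(), .groups = "drop") |>
    mutate(cytoband = NA_character_) |>
    arrange(.data$chrom, .data$start, .data$gene_id)
  transcripts <- arrange(transcripts, .data$gene_id, .data$transcript_id)
  exons <- arrange(exons, .data$transcript_id, .data$start)

  if (is.null(chrom_lengths)) {
    chrom_lengths <- exons |>
      group_by(.data$chrom) |>
      summarise(len = max(.data$end), .groups = "drop")
    chrom_lengths <- setNames(chrom_lengths$len, chrom_lengths$chrom)
  } else {
    bad <- genes |> filter(.data$end > chrom_lengths[.data$chrom])
    if (nrow(bad) > 0) abort("gene coordinates exceed chromosome length")
  }

  ann <- structure(
    list(genes = genes, transcripts = transcripts, exons = exons,
         chrom_lengths = chrom_lengths, cytobands = cytobands),
    class = "genome_annotation")
  if (!is.null(cytobands)) {
    ann$cytobands <- .check_cytobands(as_tibble(cytobands))
    ann <- assign_cytobands(ann)
  }
  ann
}

.check_cytobands <- function(cb) {
  req <- c("chrom", "start", "end", "name")
  if (!all(req %in% names(cb))) abort("cytobands need chrom, start, end, name")
  cb <- arrange(as_tibble(cb[req]), .data$chrom, .data$start)
  ov <- cb |>
    group_by(.data$chrom) |>
    summarise(bad = any(.data$start[-1] < .data$end[-length(.data$end)]),
              .groups = "drop")
  if (any(ov$bad, na.rm = TRUE)) abort("overlapping cytobands on a chromosome")
  cb
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ",
      nrow(x$genes), " genes, ", nrow(x$transcripts), " transcripts, ",
      nrow(x$exons), " exons on ", length(x$chrom_lengths), " chromosome(s)",
      if (!is.null(x$cytobands)) paste0(", ", nrow(x$cytobands), " cytobands"),
      "\n", sep = "")
  invisible(x)
}

#' Read a GTF gene model
#'
#' Parses an Ensembl-dialect GTF into a [genome_annotation()]. The model is
#' built from `exon` records (gene and transcript rows are permitted and
#' ignored), GTF 1-based closed coordinates are converted to the internal
#' 0-based half-open convention, and `transcript_biotype` attributes are
#' mapped through [map_biotype()] (absent biotype becomes `"other"`).
#'
#' @param path GTF file path.
#' @param cytobands Optional cytoband tibble or path to a 4-column TSV
#'   (`chrom`, `start`, `end`, `name`), see [read_cytobands()].
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return A `genome_annotation`.
#' @export
read_gtf <- function(path, cytobands = NULL, chrom_lengths = NULL) {
  if (!file.exists(path)) abort(paste0("no such GTF file: ", path))
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- stringr::str_count(lines[body], stringr::fixed("\t")) + 1L
  if (any(nfield != 9L)) {
    bad_line <- which(body)[which(nfield != 9L)[1]]
    abort(paste0("malformed GTF line ", bad_line, ": expected 9 tab-separated fields"))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(gr)
  is_exon <- md$type == "exon"
  if (!any(is_exon)) abort("GTF contains no exon records")
  md <- md[is_exon, , drop = FALSE]
  if (!"transcript_id" %in% names(md) || anyNA(md$transcript_id)) {
    abort("exon record without transcript_id attribute")
  }
  if (!"gene_id" %in% names(md) || anyNA(md$gene_id)) {
    abort("exon record without gene_id attribute")
  }
  exons <- tibble(
    transcript_id = as.character(md$transcript_id),
    gene_id = as.character(md$gene_id),
    chrom = as.character(md$seqnames),
    strand = as.character(md$strand),
    start = md$start - 1L,   # GTF 1-based closed -> 0-based half-open
    end = md$end
  )
  if (any(exons$strand == "*")) abort("exon with undefined strand")
  bt <- NULL
  if ("transcript_biotype" %in% names(md)) {
    bt <- tibble(transcript_id = as.character(md$transcript_id),
                 biotype = map_biotype(as.character(md$transcript_biotype))) |>
      distinct(.data$transcript_id, .keep_all = TRUE)
  }
  if (is.character(cytobands)) cytobands <- read_cytobands(cytobands)
  genome_annotation(exons, biotypes = bt, chrom_lengths = chrom_lengths,
                    cytobands = cytobands)
}

#' Write a genome annotation back to GTF
#'
#' Emits one `exon` record per exon with `gene_id`, `transcript_id` and
#' `transcript_biotype` attributes, converting back to 1-based closed
#' coordinates. Re-reading the file with [read_gtf()] reproduces the model.
#'
#' @param ann A `genome_annotation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "genome_annotation"))
  ex <- left_join(ann$exons,
                  ann$transcripts[c("transcript_id", "biotype")],
                  by = "transcript_id")
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand)
  S4Vectors::mcols(gr)$source <- "gravirebound"
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$gene_id <- ex$gene_id
  S4Vectors::mcols(gr)$transcript_id <- ex$transcript_id
  S4Vectors::mcols(gr)$transcript_biotype <- unname(.BIOTYPE_UNMAP[ex$biotype])
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a cytoband table
#'
#' @param path 4-column TSV (`chrom`, `start`, `end`, `name`), 0-based
#'   half-open, no header.
#' @return Tibble of cytobands.
#' @export
read_cytobands <- function(path) {
  cb <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                        col_types = "ciic", progress = FALSE)
  .check_cytobands(cb)
}

#' Intron intervals of transcripts
#'
#' Gaps between consecutive exons of each transcript, in internal 0-based
#' half-open coordinates. Zero-length gaps (abutting exons) are dropped;
#' single-exon transcripts contribute no rows.
#'
#' @param ann A `genome_annotation`.
#' @param transcript_id Optional transcript id(s) to restrict to.
#' @return Tibble `transcript_id`, `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @export
intron_intervals <- function(ann, transcript_id = NULL) {
  stopifnot(inherits(ann, "genome_annotation"))
  ex <- ann$exons
  if (!is.null(transcript_id)) ex <- filter(ex, .data$transcript_id %in% !!transcript_id)
  ex |>
    group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) |>
    reframe(istart = .data$end[-n()], iend = .data$start[-1]) |>
    rename(start = "istart", end = "iend") |>
    filter(.data$end > .data$start)
}

#' Assign genes to cytobands
#'
#' Each gene is mapped to the band containing its strand-aware 5' end
#' (plus-strand genes: `start`; minus-strand genes: `end - 1`). Genes
#' falling outside every band, or on chromosomes missing from the band
#' table, are left unassigned (`NA`), with a warning for chromosome
#' mismatches.
#'
#' @param ann A `genome_annotation` whose `cytobands` element is set.
#' @return The annotation with the `cytoband` column of `genes` filled in.
#' @export
assign_cytobands <- function(ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  if (is.null(ann$cytobands)) abort("annotation has no cytoband table")
  cb <- ann$cytobands
  g <- ann$genes
  tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  band_gr <- GenomicRanges::GRanges(cb$chrom,
                                    IRanges::IRanges(cb$start + 1L, cb$end))
  tss_gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(tss + 1L, tss + 1L))
  hit <- GenomicRanges::findOverlaps(tss_gr, band_gr, select = "first")
  g$cytoband <- ifelse(is.na(hit), NA_character_, cb$name[hit])
  off_chrom <- !(g$chrom %in% unique(cb$chrom))
  if (any(off_chrom)) {
    warn(paste0(sum(off_chrom), " gene(s) on chromosome(s) absent from the ",
                "cytoband table left unassigned"))
  }
  ann$genes <- g
  ann
}

#' Tidy views of an annotation
#'
#' @param x A `genome_annotation`.
#' @param ... Unused.
#' @return `tidy()` returns the gene table; `glance()` a one-row summary.
#' @method tidy genome_annotation
#' @export
tidy.genome_annotation <- function(x, ...) x$genes

#' @rdname tidy.genome_annotation
#' @method glance genome_annotation
#' @export
glance.genome_annotation <- function(x, ...) {
  tibble(n_genes = nrow(x$genes),
         n_transcripts = nrow(x$transcripts),
         n_exons = nrow(x$exons),
         n_chromosomes = length(x$chrom_lengths),
         n_cytobands = if (is.null(x$cytobands)) 0L else nrow(x$cytobands))
}

# GRanges of gene spans (1-based closed, as GenomicRanges expects)
.gene_ranges <- function(ann) {
  g <- ann$genes
  gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1L, g$end),
                               strand = g$strand)
  names(gr) <- g$gene_id
  gr
}
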