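#' Flatten transcript exons into disjoint counting bins
#'
#' Overlapping exons of a gene's transcripts are split at every exon
#' boundary into disjoint bins; each bin records the set of transcripts
#' containing it. Within a gene, bins are disjoint and their union equals
#' the union of the gene's exons.
#'
#' @param ann A [genome_annotation()].
#' @return Tibble `bin_id` (`gene:E###`, ordered by start), `gene_id`,
#'   `chrom`, `strand`, `start`, `end` (0-based half-open),
#'   `transcripts` (list of parent transcript ids).
#' @export
flatten_exons <- function(ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  ex_split <- split(ann$exons, ann$exons$gene_id)
  purrr::imap_dfr(ex_split, function(ex, g) {
    ir <- IRanges::IRanges(ex$start + 1L, ex$end)
    bins <- IRanges::disjoin(ir)
    hit <- IRanges::findOverlaps(bins, ir, type = "within")
    parents <- split(ex$transcript_id[S4Vectors::subjectHits(hit)],
                     factor(S4Vectors::queryHits(hit), levels = seq_along(bins)))
    parents <- lapply(parents, function(x) sort(unique(x)))
    tibble(bin_id = sprintf("%s:E%03d", g, seq_along(bins)),
           gene_id = g,
           chrom = ex$chrom[1], strand = ex$strand[1],
           start = IRanges::start(bins) - 1L, end = IRanges::end(bins),
           transcripts = unname(parents))
  })
}

#' Count read pairs into exon bins
#'
#' Pairs are assigned to genes by span containment exactly as in
#' [count_layers()]; each assigned pair is then counted toward every bin
#' of its gene that any of its aligned blocks overlaps (junction reads
#' therefore count toward each flanking bin). Deterministic in read order.
#'
#' @param paths SAM/BAM files, one per sample.
#' @param ann A [genome_annotation()].
#' @param bins Output of [flatten_exons()].
#' @param sample_names Optional labels; default file base names.
#' @return Integer matrix bins x samples with `bin_id` rownames.
#' @export
count_exon_bins <- function(paths, ann, bins, sample_names = NULL) {
  if (is.null(sample_names)) {
    sample_names <- sub("\\.(sam|bam)$", "", basename(paths), ignore.case = TRUE)
  }
  index <- .counting_index(ann)
  bins_gr <- GenomicRanges::GRanges(bins$chrom,
                                    IRanges::IRanges(bins$start + 1L, bins$end))
  out <- matrix(0L, nrow = nrow(bins), ncol = length(paths),
                dimnames = list(bins$bin_id, sample_names))
  for (j in seq_along(paths)) {
    gal <- .read_alignments(paths[j])
    if (length(gal) == 0) next
    qname <- names(gal)
    aln_tbl <- tibble(qname = qname,
                      chrom = as.character(GenomicAlignments::seqnames(gal)),
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
    hits <- GenomicRanges::findOverlaps(span_gr, index$gene_gr,
                                        type = "within", ignore.strand = TRUE)
    nhit <- tabulate(S4Vectors::queryHits(hits), nbins = nrow(pair_span))
    gene_of <- rep(NA_character_, nrow(pair_span))
    uniq <- which(nhit == 1)
    gene_of[uniq] <- names(index$gene_gr)[
      S4Vectors::subjectHits(hits)[match(uniq, S4Vectors::queryHits(hits))]]
    gene_of[pair_span$nchrom > 1] <- NA_character_
    pair_gene <- setNames(gene_of, pair_span$qname)

    blocks <- GenomicAlignments::grglist(gal)
    bl_flat <- unlist(blocks, use.names = FALSE)
    bl_aln <- rep(seq_along(gal), S4Vectors::elementNROWS(blocks))
    hb <- GenomicRanges::findOverlaps(bl_flat, bins_gr, ignore.strand = TRUE)
    if (length(hb) == 0) next
    hits_tbl <- tibble(qname = qname[bl_aln[S4Vectors::queryHits(hb)]],
                       bin = S4Vectors::subjectHits(hb)) |>
      mutate(gene = pair_gene[.data$qname],
             bin_gene = bins$gene_id[.data$bin]) |>
      filter(!is.na(.data$gene), .data$gene == .data$bin_gene) |>
      distinct(.data$qname, .data$bin) |>
      count(.data$bin)
    out[hits_tbl$bin, j] <- hits_tbl$n
  }
  out
}

# method-of-moments dispersion with a per-cell offset matrix (exposure =
# per-sample gene total for usage proportions), trend-shrunk as in
# estimate_dispersion()
.mom_dispersion_offsets <- function(y, off, group) {
  group <- as.factor(group)
  z <- y / off
  z[off == 0] <- NA
  inv <- 1 / off
  inv[off == 0] <- NA
  a_num <- rep(0, nrow(y)); a_den <- rep(0, nrow(y))
  for (g in levels(group)) {
    jj <- which(group == g)
    if (length(jj) < 2) next
    zg <- z[, jj, drop = FALSE]
    mu_g <- rowMeans(zg, na.rm = TRUE)
    v_g <- apply(zg, 1, stats::var, na.rm = TRUE)
    c_g <- rowMeans(inv[, jj, drop = FALSE], na.rm = TRUE)
    a_g <- ifelse(mu_g > 0, (v_g - mu_g * c_g) / mu_g^2, NA_real_)
    w <- length(jj) - 1
    ok <- !is.na(a_g)
    a_num[ok] <- a_num[ok] + w * a_g[ok]
    a_den[ok] <- a_den[ok] + w
  }
  floor_d <- 1e-8
  a_raw <- ifelse(a_den > 0, a_num / a_den, NA_real_)
  xmean <- rowMeans(y)
  fit_ok <- which(!is.na(a_raw) & xmean > 0)
  trend <- rep(NA_real_, nrow(y))
  if (length(fit_ok) >= 20) {
    lo <- stats::loess(a_raw[fit_ok] ~ log(xmean[fit_ok]), span = 1, degree = 1)
    at <- pmin(pmax(log(pmax(xmean, min(xmean[fit_ok]))), min(lo$x)), max(lo$x))
    trend <- pmax(stats::predict(lo, newdata = at), floor_d)
  } else if (length(fit_ok) >= 2) {
    trend <- rep(pmax(mean(a_raw[fit_ok]), floor_d), nrow(y))
  }
  disp <- ifelse(is.na(trend), pmax(a_raw, floor_d),
                 0.5 * trend + 0.5 * pmax(a_raw, 0, na.rm = TRUE))
  disp[is.na(disp)] <- floor_d
  out <- pmax(disp, floor_d)
  attr(out, "resid_df") <- sum(pmax(table(group) - 1, 0))
  out
}

#' Differential exon usage test
#'
#' Tests, per bin, whether the bin's share of its gene's counts (usage,
#' a proportion) differs between two conditions. The bin counts are
#' modelled as NB with the per-sample gene total as exposure, so the test
#' is independent of gene-level expression changes by construction:
#' doubling all counts of one condition leaves usage unchanged.
#' `usage_lfc` is the log2 ratio of fitted usage proportions
#' (numerator over denominator); positive values mean increased usage.
#' Per-bin p-values are BH-adjusted across observable bins; per gene, the
#' minimum bin p is Sidak-aggregated (1 - (1 - p_min)^k over k observable
#' bins) and BH-adjusted across genes. Genes with a single bin carry no
#' test (usage is undefined).
#'
#' @param bin_counts Integer matrix bins x samples (rownames = bin ids).
#' @param bins Bin table from [flatten_exons()] (needs `bin_id`,
#'   `gene_id`).
#' @param group Condition label per sample.
#' @param numerator,denominator Conditions contrasted.
#' @param min_count Observability threshold on the mean bin count across
#'   the contrast's samples (default 5).
#' @param alpha Significance threshold stored for downstream calls.
#' @return A `deu_result`: list with `bins` (per-bin results) and `genes`
#'   (per-gene aggregation), plus the contrast label.
#' @export
deu_test <- function(bin_counts, bins, group, numerator, denominator,
                     min_count = 5, alpha = 0.05) {
  stopifnot(all(rownames(bin_counts) %in% bins$bin_id))
  bins <- bins[match(rownames(bin_counts), bins$bin_id), ]
  gene_tot <- rowsum(bin_counts, bins$gene_id)
  offsets <- gene_tot[bins$gene_id, , drop = FALSE]
  remainder <- offsets - bin_counts
  dimnames(offsets) <- dimnames(bin_counts)
  n_bins_gene <- table(bins$gene_id)
  multi <- as.integer(n_bins_gene[bins$gene_id]) > 1L

  group <- as.character(group)
  jj <- which(group %in% c(numerator, denominator))
  disp <- .mom_dispersion_offsets(bin_counts[, jj, drop = FALSE],
                                  offsets[, jj, drop = FALSE], group[jj])
  res <- nb_wald_contrast(bin_counts, sf = rep(1, ncol(bin_counts)),
                          dispersions = disp, group = group,
                          numerator = numerator, denominator = denominator,
                          min_mean = 0, offsets = offsets)
  mean_count <- rowMeans(bin_counts[, jj, drop = FALSE])
  observable <- multi & mean_count >= min_count & !is.na(res$p)
  fdr <- rep(NA_real_, nrow(res))
  fdr[observable] <- bh_adjust(res$p[observable])

  bin_res <- tibble(bin_id = rownames(bin_counts), gene_id = bins$gene_id,
                    mean_count = mean_count, usage_lfc = res$lfc,
                    se = res$se, p = ifelse(multi, res$p, NA_real_),
                    fdr = fdr, observable = observable)
  obs_bins <- filter(bin_res, .data$observable)
  if (nrow(obs_bins) == 0) {
    gene_res <- tibble(gene_id = character(0), n_bins = integer(0),
                       p_min = numeric(0), p_sidak = numeric(0),
                       gene_q = numeric(0), significant = logical(0))
  } else {
    gene_res <- obs_bins |>
      group_by(.data$gene_id) |>
      summarise(n_bins = n(), p_min = min(.data$p), .groups = "drop") |>
      mutate(p_sidak = 1 - (1 - .data$p_min)^.data$n_bins,
             gene_q = bh_adjust(.data$p_sidak),
             significant = .data$gene_q < alpha)
  }
  structure(list(bins = bin_res, genes = gene_res,
                 contrast = paste0(numerator, "-", denominator),
                 alpha = alpha),
            class = "deu_result")
}

#' @export
print.deu_result <- function(x, ...) {
  cat("<deu_result> ", x$contrast, ": ", sum(x$bins$observable),
      " observable bins, ",
      sum(x$bins$fdr < x$alpha, na.rm = TRUE), " DU bins, ",
      sum(x$genes$significant), " DEU genes\n", sep = "")
  invisible(x)
}

#' @method tidy deu_result
#' @export
tidy.deu_result <- function(x, ...) x$bins

#' @method glance deu_result
#' @export
glance.deu_result <- function(x, ...) {
  tibble(contrast = x$contrast,
         n_bins = nrow(x$bins),
         n_observable = sum(x$bins$observable),
         n_du_bins = sum(x$bins$fdr < x$alpha, na.rm = TRUE),
         n_deu_genes = sum(x$genes$significant))
}

#' Usage calls per bin
#'
#' @param deu A `deu_result`.
#' @param alpha FDR threshold (default the result's).
#' @return Tibble `bin_id`, `gene_id`, `call` in
#'   `increased`/`decreased`/`ns`/`unobserved`.
#' @export
du_usage_calls <- function(deu, alpha = NULL) {
  alpha <- alpha %||% deu$alpha
  b <- deu$bins
  tibble(bin_id = b$bin_id, gene_id = b$gene_id,
         call = dplyr::case_when(
           is.na(b$fdr) ~ "unobserved",
           b$fdr < alpha & b$usage_lfc > 0 ~ "increased",
           b$fdr < alpha & b$usage_lfc < 0 ~ "decreased",
           TRUE ~ "ns"))
}

#' Transition table of usage calls between two contrasts
#'
#' The same transition machinery as for expression calls, applied to
#' increased/ns/decreased usage over bins observable in both contrasts.
#'
#' @param deuA,deuB `deu_result` objects.
#' @param alpha FDR threshold.
#' @return Tibble `from`, `to`, `n`, `ids`.
#' @export
du_temporal_coherence <- function(deuA, deuB, alpha = 0.05) {
  transition_table(du_usage_calls(deuA, alpha), du_usage_calls(deuB, alpha),
                   id = "bin_id")
}

#' Map significant DU exons to affected transcripts
#'
#' Every parent transcript of a significant bin is included; duplicated
#' transcripts are collapsed to a single instance per direction, so a
#' transcript hit by bins of both signs appears once in each direction.
#'
#' @param deu A `deu_result`.
#' @param bins Bin table from [flatten_exons()] (supplies parentage).
#' @param alpha FDR threshold (default the result's).
#' @return Tibble `transcript_id`, `direction`
#'   (`"increased"`/`"decreased"`).
#' @export
map_du_to_transcripts <- function(deu, bins, alpha = NULL) {
  alpha <- alpha %||% deu$alpha
  sig <- deu$bins |>
    filter(!is.na(.data$fdr), .data$fdr < alpha, .data$usage_lfc != 0) |>
    mutate(direction = ifelse(.data$usage_lfc > 0, "increased", "decreased"))
  if (nrow(sig) == 0) {
    return(tibble(transcript_id = character(0), direction = character(0)))
  }
  sig |>
    left_join(bins[c("bin_id", "transcripts")], by = "bin_id") |>
    select("direction", "transcripts") |>
    tidyr::unnest("transcripts") |>
    distinct(transcript_id = .data$transcripts, .data$direction) |>
    arrange(.data$transcript_id, .data$direction)
}
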