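#' Tally regulation calls per genomic region
#'
#' Counts detected (observable) genes, DEGs and their directions per
#' chromosome or cytoband. Regions with no detected gene are dropped
#' (they are untestable and would dilute the FDR family).
#'
#' @param calls Tibble `gene_id`, `call` from [call_regulation()].
#' @param ann A [genome_annotation()].
#' @param level `"chromosome"` or `"cytoband"` (cytobands are identified
#'   as `chrom:band`).
#' @return Tibble `region`, `n_detected`, `n_deg`, `n_up`, `n_down`.
#' @export
region_tally <- function(calls, ann, level = c("chromosome", "cytoband")) {
  level <- match.arg(level)
  g <- ann$genes
  region <- if (level == "chromosome") g$chrom else
    ifelse(is.na(g$cytoband), NA_character_, paste0(g$chrom, ":", g$cytoband))
  placed <- tibble(gene_id = g$gene_id, region = region)
  calls |>
    filter(.data$call != "unobserved") |>
    inner_join(placed, by = "gene_id") |>
    filter(!is.na(.data$region)) |>
    group_by(.data$region) |>
    summarise(n_detected = n(),
              n_deg = sum(.data$call %in% c("up", "down")),
              n_up = sum(.data$call == "up"),
              n_down = sum(.data$call == "down"),
              .groups = "drop")
}

#' Expected DEG counts per region under uniform placement
#'
#' Adds the expectation model of the chromosome-distribution analysis:
#' assuming a uniform probability of differential expression, the
#' expected number of DEGs in a region is its number of detected genes
#' times the global DEG fraction; the expected number of upregulated
#' genes among a region's DEGs is the region's DEG count times the
#' global up fraction among DEGs. Expectations sum exactly to the global
#' totals.
#'
#' @param tally Output of [region_tally()].
#' @return The tally with `expected_deg` and `expected_up` columns.
#' @export
expected_counts <- function(tally) {
  total_detected <- sum(tally$n_detected)
  if (total_detected == 0) rlang::abort("no detected genes")
  total_deg <- sum(tally$n_deg)
  total_up <- sum(tally$n_up)
  total_down <- sum(tally$n_down)
  up_frac <- if (total_up + total_down > 0) total_up / (total_up + total_down) else 0
  tally |>
    mutate(expected_deg = .data$n_detected * total_deg / total_detected,
           expected_up = .data$n_deg * up_frac)
}

.fisher_p <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m)$p.value
}

#' Fisher tests of regional DEG enrichment and up/down skew
#'
#' Per region, two two-sided Fisher exact tests: (a) DEG enrichment,
#' contrasting DEG/non-DEG counts inside the region against the rest of
#' the genome; (b) direction skew, contrasting up/down counts inside
#' against outside. Degenerate margins give p = 1. BH adjustment is
#' applied within each test family, and each test carries the direction
#' of the deviation from expectation.
#'
#' @param tally Output of [region_tally()] (expectations are added if
#'   absent).
#' @return Tally with `fisher_p_total`, `fdr_total`, `direction_total`,
#'   `fisher_p_updown`, `fdr_updown`, `direction_updown`.
#' @export
fisher_region_tests <- function(tally) {
  if (!"expected_deg" %in% names(tally)) tally <- expected_counts(tally)
  tot_det <- sum(tally$n_detected)
  tot_deg <- sum(tally$n_deg)
  tot_up <- sum(tally$n_up)
  tot_down <- sum(tally$n_down)
  p_tot <- purrr::pmap_dbl(tally, function(n_detected, n_deg, ...) {
    .fisher_p(n_deg, n_detected - n_deg,
              tot_deg - n_deg, (tot_det - n_detected) - (tot_deg - n_deg))
  })
  p_ud <- purrr::pmap_dbl(tally, function(n_up, n_down, ...) {
    .fisher_p(n_up, n_down, tot_up - n_up, tot_down - n_down)
  })
  tally |>
    mutate(fisher_p_total = p_tot,
           fdr_total = bh_adjust(p_tot),
           direction_total = sign(.data$n_deg - .data$expected_deg),
           fisher_p_updown = p_ud,
           fdr_updown = bh_adjust(p_ud),
           direction_updown = sign(.data$n_up - .data$expected_up))
}

#' Spearman correlation of expected versus actual regional counts
#'
#' @param tally Output of [fisher_region_tests()] or [expected_counts()].
#' @return One-row tibble `rho_total` (expected vs actual DEG counts),
#'   `rho_updown` (expected vs actual up counts), `n_regions`, and
#'   degeneracy flags for constant vectors.
#' @export
expected_actual_correlation <- function(tally) {
  if (!"expected_deg" %in% names(tally)) tally <- expected_counts(tally)
  if (nrow(tally) < 3) rlang::abort("need at least 3 regions")
  sp <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
    else stats::cor(x, y, method = "spearman")
  }
  tibble(rho_total = sp(tally$expected_deg, tally$n_deg),
         rho_updown = sp(tally$expected_up, tally$n_up),
         n_regions = nrow(tally),
         degenerate_total = stats::sd(tally$expected_deg) == 0 ||
           stats::sd(tally$n_deg) == 0,
         degenerate_updown = stats::sd(tally$expected_up) == 0 ||
           stats::sd(tally$n_up) == 0)
}

#' Chromosomal distribution of differentially used exons
#'
#' Observed-versus-expected analysis of DU exons per chromosome: the
#' expected number of increased-usage exons in a region is its DU-exon
#' count times the global increased:decreased ratio; a two-sided Fisher
#' test contrasts the region's increased/decreased split against the rest,
#' with BH across regions. Regions with no DU exon are reported with
#' expectation 0 and no test.
#'
#' @param du_calls Tibble with one row per DU exon: `gene_id` (or a
#'   `region` column directly) and `direction` (`"increased"` /
#'   `"decreased"`).
#' @param ann A [genome_annotation()] used to map genes to chromosomes
#'   (ignored when `du_calls` already has `region`).
#' @return Tibble `region`, `n_du`, `n_increased`, `n_decreased`,
#'   `expected_increased`, `fisher_p`, `fdr`, `direction`.
#' @export
du_exon_distribution <- function(du_calls, ann = NULL) {
  if (!"region" %in% names(du_calls)) {
    stopifnot(!is.null(ann))
    placed <- tibble(gene_id = ann$genes$gene_id, region = ann$genes$chrom)
    du_calls <- inner_join(du_calls, placed, by = "gene_id")
  }
  tal <- du_calls |>
    group_by(.data$region) |>
    summarise(n_du = n(),
              n_increased = sum(.data$direction == "increased"),
              n_decreased = sum(.data$direction == "decreased"),
              .groups = "drop")
  tot_inc <- sum(tal$n_increased)
  tot_dec <- sum(tal$n_decreased)
  inc_frac <- if (tot_inc + tot_dec > 0) tot_inc / (tot_inc + tot_dec) else 0
  tal <- mutate(tal, expected_increased = .data$n_du * inc_frac)
  testable <- tal$n_du > 0
  p <- rep(NA_real_, nrow(tal))
  p[testable] <- purrr::pmap_dbl(tal[testable, ], function(n_increased, n_decreased, ...) {
    .fisher_p(n_increased, n_decreased,
              tot_inc - n_increased, tot_dec - n_decreased)
  })
  fdr <- rep(NA_real_, nrow(tal))
  fdr[testable] <- bh_adjust(p[testable])
  mutate(tal, fisher_p = p, fdr = fdr,
         direction = sign(.data$n_increased - .data$expected_increased))
}
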