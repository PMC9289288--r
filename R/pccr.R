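#' Protein coding counts ratio per gene and condition
#'
#' For each gene and condition, transcript counts are summed into a
#' coding pool (protein-coding isoforms) and a noncoding pool (retained
#' intron + ORF-lacking + NMD isoforms; lncRNA is excluded from both
#' pools by default, matching the ratio's defining formula — set
#' `include_lncrna = TRUE` to count lncRNA as noncoding). PCCR =
#' coding / (coding + noncoding). A gene whose ratio changes between the
#' two compared conditions by strictly more than `threshold` (one percent
#' point by default) is classed `increased`/`decreased` by sign,
#' otherwise `constant`; genes with an empty pool in either compared
#' condition are `undefined`.
#'
#' @param tx_counts Long tibble `transcript_id`, `gene_id`, `biotype`,
#'   `condition`, `count` (counts already summed per condition).
#' @param conditions Length-2 character vector: reference and comparison
#'   condition (default `c("Ctrl", "hypg3")`).
#' @param threshold Classification threshold in ratio units (default
#'   0.01 = one percent point; strict inequality).
#' @param include_lncrna Count lncRNA transcripts as noncoding.
#' @return A `pccr_result` tibble: `gene_id`, one `pccr_<condition>`
#'   column per condition present in the data, `delta`, `class`, and the
#'   per-condition coding/noncoding sums for the compared conditions.
#' @export
compute_pccr <- function(tx_counts, conditions = c("Ctrl", "hypg3"),
                         threshold = 0.01, include_lncrna = FALSE) {
  stopifnot(length(conditions) == 2)
  noncoding <- c("retained_intron", "orf_lacking", "nmd",
                 if (include_lncrna) "lncRNA")
  pools <- tx_counts |>
    mutate(pool = dplyr::case_when(
      .data$biotype == "protein_coding" ~ "coding",
      .data$biotype %in% noncoding ~ "noncoding",
      TRUE ~ NA_character_)) |>
    filter(!is.na(.data$pool)) |>
    group_by(.data$gene_id, .data$condition, .data$pool) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "pool", values_from = "count",
                       values_fill = 0)
  if (!"coding" %in% names(pools)) pools$coding <- 0
  if (!"noncoding" %in% names(pools)) pools$noncoding <- 0
  pools <- mutate(pools,
                  total = .data$coding + .data$noncoding,
                  pccr = ifelse(.data$total > 0,
                                .data$coding / .data$total, NA_real_))
  wide <- pools |>
    select("gene_id", "condition", "pccr") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "pccr",
                       names_prefix = "pccr_")
  ref <- paste0("pccr_", conditions[1])
  cmp <- paste0("pccr_", conditions[2])
  if (!all(c(ref, cmp) %in% names(wide))) {
    rlang::abort(paste0("conditions not found in tx_counts: ",
                        paste(conditions, collapse = ", ")))
  }
  detail <- pools |>
    filter(.data$condition %in% conditions) |>
    select("gene_id", "condition", "coding", "noncoding") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("coding", "noncoding"))
  res <- wide |>
    mutate(delta = .data[[cmp]] - .data[[ref]],
           class = dplyr::case_when(
             is.na(.data$delta) ~ "undefined",
             .data$delta > threshold ~ "increased",
             .data$delta < -threshold ~ "decreased",
             TRUE ~ "constant")) |>
    left_join(detail, by = "gene_id") |>
    arrange(.data$gene_id)
  class(res) <- c("pccr_result", class(res))
  attr(res, "conditions") <- conditions
  attr(res, "threshold") <- threshold
  res
}

#' @method glance pccr_result
#' @export
glance.pccr_result <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_increased = sum(x$class == "increased"),
         n_decreased = sum(x$class == "decreased"),
         n_constant = sum(x$class == "constant"),
         n_undefined = sum(x$class == "undefined"))
}

#' Overlap of PCCR classes with differential expression
#'
#' For each PCCR class and count layer, tallies the up/downregulated
#' genes in the class, the DEG fraction, and a two-sided Fisher test of
#' the class's up/down split against all other genes' up/down split in
#' the same layer (the overall DEG background). Stars mark FDR < 0.05
#' (`*`) and < 0.01 (`**`).
#'
#' @param pccr A `pccr_result`.
#' @param calls_by_layer Tibble `layer`, `gene_id`, `call` (regulation
#'   calls per layer for one contrast, e.g. from [de_layers()] piped
#'   through [call_regulation()] per layer).
#' @return Tibble per class x layer: `class`, `layer`, `n_genes`,
#'   `n_deg`, `deg_fraction`, `n_up`, `n_down`, `fisher_p`, `fdr`,
#'   `stars`.
#' @export
pccr_deg_overlap <- function(pccr, calls_by_layer) {
  classes <- filter(as_tibble(pccr), .data$class != "undefined")[
    c("gene_id", "class")]
  joined <- inner_join(calls_by_layer, classes, by = "gene_id")
  out <- joined |>
    group_by(.data$class, .data$layer) |>
    summarise(n_genes = n(),
              n_deg = sum(.data$call %in% c("up", "down")),
              n_up = sum(.data$call == "up"),
              n_down = sum(.data$call == "down"),
              .groups = "drop") |>
    mutate(deg_fraction = ifelse(.data$n_genes > 0,
                                 .data$n_deg / .data$n_genes, NA_real_))
  totals <- calls_by_layer |>
    group_by(.data$layer) |>
    summarise(tot_up = sum(.data$call == "up"),
              tot_down = sum(.data$call == "down"), .groups = "drop")
  out <- left_join(out, totals, by = "layer")
  p <- purrr::pmap_dbl(out, function(n_up, n_down, tot_up, tot_down, n_deg, ...) {
    if (n_deg == 0) return(NA_real_)
    .fisher_p(n_up, n_down, tot_up - n_up, tot_down - n_down)
  })
  tested <- !is.na(p)
  fdr <- rep(NA_real_, length(p))
  fdr[tested] <- bh_adjust(p[tested])
  out |>
    mutate(fisher_p = p, fdr = fdr,
           stars = dplyr::case_when(
             is.na(fdr) ~ "",
             fdr < 0.01 ~ "**",
             fdr < 0.05 ~ "*",
             TRUE ~ "")) |>
    select("class", "layer", "n_genes", "n_deg", "deg_fraction",
           "n_up", "n_down", "fisher_p", "fdr", "stars")
}

#' Read a transcript-by-condition count table
#'
#' Wide TSV with columns `transcript_id`, `gene_id`, `biotype`, then one
#' column per condition; returned in the long format [compute_pccr()]
#' expects.
#'
#' @param path TSV path.
#' @return Long tibble `transcript_id`, `gene_id`, `biotype`,
#'   `condition`, `count`.
#' @export
read_transcript_counts <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  req <- c("transcript_id", "gene_id", "biotype")
  if (!all(req %in% names(df))) {
    rlang::abort("transcript counts need transcript_id, gene_id, biotype columns")
  }
  tidyr::pivot_longer(df, cols = -dplyr::all_of(req),
                      names_to = "condition", values_to = "count")
}
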