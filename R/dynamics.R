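#' Regulation calls from a contrast result
#'
#' Deterministic mapping of per-gene statistics to qualitative calls:
#' `up` (fdr < alpha and lfc > 0), `down` (fdr < alpha and lfc < 0),
#' `ns` otherwise, `unobserved` when no fdr is defined. An lfc of exactly
#' 0 with significant fdr is `ns` (direction undefined).
#'
#' @param res A `contrast_result` tibble (or any tibble with `gene_id`,
#'   `lfc`, `fdr`).
#' @param alpha FDR threshold (default 0.05).
#' @return Tibble `gene_id`, `call`.
#' @export
call_regulation <- function(res, alpha = 0.05) {
  tibble(gene_id = res$gene_id,
         call = dplyr::case_when(
           is.na(res$fdr) ~ "unobserved",
           res$fdr < alpha & res$lfc > 0 ~ "up",
           res$fdr < alpha & res$lfc < 0 ~ "down",
           TRUE ~ "ns"))
}

#' Transition table between two call sets
#'
#' Cross-tabulates calls at contrast A against calls at contrast B over
#' the genes observable in both (the shared universe). The cells
#' partition that universe: every shared gene appears in exactly one cell.
#'
#' @param callsA,callsB Tibbles `gene_id`, `call` from [call_regulation()]
#'   (or increased/ns/decreased usage calls; any call vocabulary works).
#' @param id Name of the id column (default `"gene_id"`).
#' @return Tibble `from`, `to`, `n`, `ids` (list-column of ids per cell).
#' @export
transition_table <- function(callsA, callsB, id = "gene_id") {
  a <- callsA[callsA$call != "unobserved", c(id, "call")]
  b <- callsB[callsB$call != "unobserved", c(id, "call")]
  names(a) <- c("id", "from")
  names(b) <- c("id", "to")
  shared <- inner_join(a, b, by = "id")
  if (nrow(shared) == 0) rlang::abort("no gene observable in both call sets")
  shared |>
    group_by(.data$from, .data$to) |>
    summarise(n = n(), ids = list(.data$id), .groups = "drop") |>
    arrange(.data$from, .data$to)
}

#' Refined 15-min categories for genes regulated at 3 min
#'
#' For a gene regulated at the first time point, its behaviour at the
#' second one is refined using all three contrasts (3 min vs control,
#' 15 vs 3 min, 15 min vs control):
#' \describe{
#'   \item{overshoot}{regulated in the opposite direction relative to
#'     control at 15 min (crossed past baseline).}
#'   \item{continued}{still moving in the initial direction between 3 and
#'     15 min.}
#'   \item{inner_grey}{constant between 3 and 15 min but still
#'     lower/higher than control.}
#'   \item{outer_grey}{moving back (opposite direction between 3 and
#'     15 min) but still lower/higher than control.}
#'   \item{recovered}{no longer different from control at 15 min.}
#' }
#'
#' @param calls3 Calls for the 3 min vs control contrast.
#' @param calls15v3 Calls for the 15 vs 3 min contrast.
#' @param calls15vCtrl Calls for the 15 min vs control contrast.
#' @return Tibble `gene_id`, `direction_3min` (`up`/`down`), `category`;
#'   only genes regulated at 3 min and observable in all three contrasts
#'   are returned.
#' @export
refine_grey_categories <- function(calls3, calls15v3, calls15vCtrl) {
  j <- calls3 |>
    rename(c3 = "call") |>
    inner_join(rename(calls15v3, cB = "call"), by = "gene_id") |>
    inner_join(rename(calls15vCtrl, cC = "call"), by = "gene_id") |>
    filter(.data$c3 %in% c("up", "down"),
           .data$cB != "unobserved", .data$cC != "unobserved")
  opp <- c(up = "down", down = "up")
  j |>
    mutate(category = dplyr::case_when(
      .data$cC == opp[.data$c3] ~ "overshoot",
      .data$cB == .data$c3 ~ "continued",
      .data$cB == "ns" & .data$cC == .data$c3 ~ "inner_grey",
      .data$cB == opp[.data$c3] & .data$cC == .data$c3 ~ "outer_grey",
      .data$cC == "ns" ~ "recovered",
      TRUE ~ "other")) |>
    select("gene_id", direction_3min = "c3", "category")
}

#' Fold-change anticorrelation between adjacent contrasts
#'
#' Spearman correlation (average ranks for ties) between the log2 fold
#' changes of two contrasts over a shared gene universe, plus the
#' directional-coherence fraction: among genes called in a non-ns
#' direction in both contrasts, the fraction keeping the same direction.
#' A strongly negative rho is the rebound signature.
#'
#' @param resA,resB Contrast results (tibbles with `gene_id`, `lfc`,
#'   `fdr`, `observable`).
#' @param universe `"observable"` (default: genes observable in both) or
#'   `"deg"` (genes significant in at least one contrast at `alpha`).
#' @param alpha FDR threshold used for `"deg"` mode and the coherence
#'   fraction.
#' @return One-row tibble `rho`, `n_genes`, `frac_same_direction`,
#'   `degenerate` (TRUE when a vector was constant and rho undefined).
#' @export
rebound_correlation <- function(resA, resB, universe = c("observable", "deg"),
                                alpha = 0.05) {
  universe <- match.arg(universe)
  j <- inner_join(
    tibble(gene_id = resA$gene_id, lfcA = resA$lfc, fdrA = resA$fdr,
           obsA = resA$observable),
    tibble(gene_id = resB$gene_id, lfcB = resB$lfc, fdrB = resB$fdr,
           obsB = resB$observable),
    by = "gene_id") |>
    filter(.data$obsA, .data$obsB, !is.na(.data$lfcA), !is.na(.data$lfcB))
  if (universe == "deg") {
    j <- filter(j, (!is.na(.data$fdrA) & .data$fdrA < alpha) |
                  (!is.na(.data$fdrB) & .data$fdrB < alpha))
  }
  if (nrow(j) < 3) rlang::abort("need at least 3 shared genes")
  degenerate <- stats::sd(j$lfcA) == 0 || stats::sd(j$lfcB) == 0
  rho <- if (degenerate) NA_real_ else
    stats::cor(j$lfcA, j$lfcB, method = "spearman")
  dirA <- j$fdrA < alpha & j$lfcA != 0
  dirB <- j$fdrB < alpha & j$lfcB != 0
  both <- which(!is.na(dirA) & dirA & !is.na(dirB) & dirB)
  frac <- if (length(both) == 0) NA_real_ else
    mean(sign(j$lfcA[both]) == sign(j$lfcB[both]))
  tibble(rho = rho, n_genes = nrow(j), frac_same_direction = frac,
         degenerate = degenerate)
}

#' Coherence flow across a series of datasets
#'
#' Given regulation-call tables from several datasets ordered by exposure
#' time, restricts to genes observable in all of them, builds
#' Sankey-style per-step flows over up/ns/down, and per step computes the
#' coherence fraction: the probability that a gene called in a non-ns
#' direction at step k keeps the same direction at step k+1, given it is
#' non-ns at both. Also reports the recurrently regulated subset (non-ns
#' in at least `min_datasets` datasets).
#'
#' @param call_list Named list (>= 2) of tibbles `gene_id`, `call`,
#'   ordered by exposure time.
#' @param min_datasets Minimum datasets a gene must be regulated in to
#'   count as recurrent; default 3/5 of the series (rounded up).
#' @return List with `links` (tibble `step`, `from`, `to`, `n`),
#'   `coherence` (tibble `step`, `frac_same_direction`, `n_directional`),
#'   and `recurrent_genes` (tibble `gene_id`, `n_regulated`).
#' @export
cross_dataset_coherence <- function(call_list,
                                    min_datasets = ceiling(length(call_list) * 3 / 5)) {
  if (length(call_list) < 2) rlang::abort("need at least 2 datasets")
  if (is.null(names(call_list)) || any(names(call_list) == "")) {
    names(call_list) <- paste0("t", seq_along(call_list))
  }
  obs <- purrr::imap(call_list, function(x, nm) {
    x <- filter(x, .data$call != "unobserved")
    setNames(x[c("gene_id", "call")], c("gene_id", nm))
  })
  wide <- purrr::reduce(obs, inner_join, by = "gene_id")
  if (nrow(wide) < 2) rlang::abort("fewer than 2 genes shared by all datasets")
  nms <- names(call_list)
  links <- purrr::map_dfr(seq_len(length(nms) - 1), function(k) {
    tibble(step = paste0(nms[k], "->", nms[k + 1]),
           from = wide[[nms[k]]], to = wide[[nms[k + 1]]]) |>
      count(.data$step, .data$from, .data$to)
  })
  coherence <- purrr::map_dfr(seq_len(length(nms) - 1), function(k) {
    f <- wide[[nms[k]]]; t <- wide[[nms[k + 1]]]
    dir_k <- f %in% c("up", "down")
    tibble(step = paste0(nms[k], "->", nms[k + 1]),
           frac_same_direction = if (any(dir_k)) mean(t[dir_k] == f[dir_k]) else NA_real_,
           n_directional = sum(dir_k))
  })
  n_reg <- rowSums(sapply(nms, function(nm) wide[[nm]] %in% c("up", "down")))
  recurrent <- tibble(gene_id = wide$gene_id, n_regulated = n_reg) |>
    filter(.data$n_regulated >= min_datasets) |>
    arrange(dplyr::desc(.data$n_regulated), .data$gene_id)
  list(links = links, coherence = coherence, recurrent_genes = recurrent)
}
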