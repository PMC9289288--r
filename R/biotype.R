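#' Tally DU-affected transcripts by biotype and direction
#'
#' @param du_tx Tibble `transcript_id`, `direction` from
#'   [map_du_to_transcripts()] (already deduplicated per direction).
#' @param ann A [genome_annotation()] supplying transcript biotypes;
#'   transcripts with unknown biotype fall into `"other"` with a warning.
#' @return Tibble `direction`, `biotype`, `n`, `fraction` (of the
#'   direction's column total).
#' @export
biotype_tally <- function(du_tx, ann) {
  if (nrow(du_tx) == 0) {
    return(tibble(direction = character(0), biotype = character(0),
                  n = integer(0), fraction = numeric(0)))
  }
  bt <- ann$transcripts[c("transcript_id", "biotype")]
  j <- left_join(du_tx, bt, by = "transcript_id")
  if (anyNA(j$biotype)) {
    rlang::warn(paste0(sum(is.na(j$biotype)),
                       " transcript(s) without annotated biotype -> 'other'"))
    j$biotype[is.na(j$biotype)] <- "other"
  }
  j |>
    count(.data$direction, .data$biotype) |>
    group_by(.data$direction) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
}

#' Association between DU-transcript biotypes and DEG direction
#'
#' For each biotype, the DEGs hosting at least one DU transcript of that
#' biotype are compared against the DEGs hosting DU transcripts of other
#' biotypes: a two-sided Fisher test on the 2x2 table (up/down x
#' this-biotype/other-biotypes). Because a gene can host DU transcripts
#' of several biotypes, the table counts gene-biotype pairs by default
#' (`mode = "pair"`); `mode = "exclusive"` removes a biotype's genes from
#' its background instead. Biotype groups with fewer than `min_genes`
#' DEGs are excluded before FDR adjustment. The expected number of
#' downregulated DEGs per group is the group size times the global
#' downregulated fraction among all DEGs of the contrast.
#'
#' @param du_tx Tibble `transcript_id`, `direction`.
#' @param gene_calls Tibble `gene_id`, `call` for the chosen layer
#'   (the spliced layer is the informative default).
#' @param ann A [genome_annotation()] (maps transcripts to host genes and
#'   biotypes).
#' @param min_genes Minimum DEGs per biotype group (default 20).
#' @param mode Background construction, `"pair"` or `"exclusive"`.
#' @return Tibble per biotype: `biotype`, `n_deg`, `n_up`, `n_down`,
#'   `expected_down`, `included`, `fisher_p`, `fdr`.
#' @export
biotype_deg_association <- function(du_tx, gene_calls, ann, min_genes = 20,
                                    mode = c("pair", "exclusive")) {
  mode <- match.arg(mode)
  degs <- filter(gene_calls, .data$call %in% c("up", "down"))
  if (nrow(degs) == 0 || nrow(du_tx) == 0) {
    return(tibble(biotype = character(0), n_deg = integer(0),
                  n_up = integer(0), n_down = integer(0),
                  expected_down = numeric(0), included = logical(0),
                  fisher_p = numeric(0), fdr = numeric(0)))
  }
  down_frac <- mean(degs$call == "down")
  tx2gene <- ann$transcripts[c("transcript_id", "gene_id", "biotype")]
  pairs <- du_tx |>
    inner_join(tx2gene, by = "transcript_id") |>
    distinct(.data$gene_id, .data$biotype) |>
    inner_join(degs, by = "gene_id")
  groups <- pairs |>
    group_by(.data$biotype) |>
    summarise(n_deg = n(), n_up = sum(.data$call == "up"),
              n_down = sum(.data$call == "down"), .groups = "drop") |>
    mutate(expected_down = .data$n_deg * down_frac,
           included = .data$n_deg >= min_genes)
  p <- purrr::map_dbl(seq_len(nrow(groups)), function(i) {
    if (!groups$included[i]) return(NA_real_)
    this_bt <- groups$biotype[i]
    if (mode == "pair") {
      other <- filter(pairs, .data$biotype != this_bt)
    } else {
      this_genes <- pairs$gene_id[pairs$biotype == this_bt]
      other <- filter(pairs, !(.data$gene_id %in% this_genes))
    }
    other <- distinct(other, .data$gene_id, .keep_all = TRUE)
    .fisher_p(groups$n_up[i], groups$n_down[i],
              sum(other$call == "up"), sum(other$call == "down"))
  })
  fdr <- rep(NA_real_, nrow(groups))
  fdr[groups$included] <- bh_adjust(p[groups$included])
  mutate(groups, fisher_p = p, fdr = fdr)
}
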