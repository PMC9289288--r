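#' Simulation design for a hypergravity-style time course
#'
#' Describes the sampling layout the generator emulates: three conditions
#' (control at 1xg, 3 min and 15 min of stimulus) with four replicates
#' each, per-sample library-depth jitter, NB dispersion with per-gene
#' log-normal jitter, polyA capture efficiency for unspliced molecules and
#' the ambiguous-read fraction.
#'
#' @param replicates Replicates per condition (>= 2; default 4).
#' @param conditions Tibble `condition`, `time_min` mapping condition
#'   labels to minutes of exposure; default `Ctrl` = 0, `hypg3` = 3,
#'   `hypg15` = 15.
#' @param lib_size_sd SD of log-normal per-sample depth factors.
#' @param dispersion Baseline NB dispersion (> 0; default 0.05).
#' @param dispersion_jitter_sd SD of per-gene log-normal dispersion jitter.
#' @param polya_capture Multiplicative capture efficiency of unspliced
#'   molecules in a polyA-enriched library (default 0.15).
#' @param ambiguous_fraction Expected ambiguous-layer counts as a fraction
#'   of spliced counts (default 0.1).
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(replicates = 4,
                              conditions = tibble(
                                condition = c("Ctrl", "hypg3", "hypg15"),
                                time_min = c(0, 3, 15)),
                              lib_size_sd = 0.1,
                              dispersion = 0.05,
                              dispersion_jitter_sd = 0.3,
                              polya_capture = 0.15,
                              ambiguous_fraction = 0.1) {
  stopifnot(replicates >= 2, dispersion > 0, polya_capture > 0,
            ambiguous_fraction >= 0)
  structure(list(replicates = as.integer(replicates),
                 conditions = as_tibble(conditions),
                 lib_size_sd = lib_size_sd, dispersion = dispersion,
                 dispersion_jitter_sd = dispersion_jitter_sd,
                 polya_capture = polya_capture,
                 ambiguous_fraction = ambiguous_fraction),
            class = "simulation_design")
}

#' Generate a synthetic genome annotation
#'
#' Builds a compact genome with genes laid end-to-end along chromosomes,
#' 1-3 transcripts per gene sharing exon boundaries (alternative
#' transcripts skip internal exons, so flattened bins differ in parentage),
#' a mixture of single- and multi-exon genes, Ensembl-style biotypes and
#' first-level cytobands.
#'
#' @param n_genes Number of genes.
#' @param n_chroms Number of chromosomes.
#' @param seed Integer seed.
#' @param p_single_exon Fraction of single-exon (hence intronless) genes.
#' @param max_transcripts Maximum transcripts per gene.
#' @param bands_per_chrom Cytobands per chromosome.
#' @return A [genome_annotation()].
#' @export
synthetic_annotation <- function(n_genes = 60, n_chroms = 4, seed = 1,
                                 p_single_exon = 0.15, max_transcripts = 3,
                                 bands_per_chrom = 5) {
  .with_seed(seed, {
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    chrom <- paste0("chr", 1 + (seq_len(n_genes) - 1) %% n_chroms)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    single <- runif(n_genes) < p_single_exon
    n_ex <- ifelse(single, 1L, sample(2:6, n_genes, replace = TRUE))
    n_tx <- ifelse(n_ex >= 3, sample(seq_len(max_transcripts), n_genes, replace = TRUE), 1L)

    rows <- vector("list", n_genes)
    offset <- setNames(rep(1000L, n_chroms), paste0("chr", seq_len(n_chroms)))
    for (i in seq_len(n_genes)) {
      ex_len <- sample(100:300, n_ex[i], replace = TRUE)
      in_len <- if (n_ex[i] > 1) sample(200:500, n_ex[i] - 1, replace = TRUE) else integer(0)
      starts <- offset[[chrom[i]]] + cumsum(c(0L, ex_len[-n_ex[i]] + in_len))
      ends <- starts + ex_len
      offset[[chrom[i]]] <- max(ends) + sample(2000:5000, 1)
      tx_rows <- vector("list", n_tx[i])
      for (k in seq_len(n_tx[i])) {
        keep <- seq_len(n_ex[i])
        if (k > 1 && n_ex[i] >= 3) {
          # alternative isoform: drop one internal exon
          keep <- setdiff(keep, sample(2:(n_ex[i] - 1), 1))
        }
        tx_rows[[k]] <- tibble(
          transcript_id = sprintf("%s_T%d", gene_ids[i], k),
          gene_id = gene_ids[i], chrom = chrom[i], strand = strand[i],
          start = starts[keep], end = ends[keep])
      }
      rows[[i]] <- bind_rows(tx_rows)
    }
    exons <- bind_rows(rows)

    tx <- distinct(exons, .data$transcript_id, .data$gene_id)
    first_tx <- !duplicated(tx$gene_id)
    biotype <- ifelse(first_tx, "protein_coding",
                      sample(c("retained_intron", "orf_lacking", "nmd",
                               "lncRNA", "other"),
                             nrow(tx), replace = TRUE,
                             prob = c(0.4, 0.2, 0.2, 0.1, 0.1)))
    biotypes <- tibble(transcript_id = tx$transcript_id, biotype = biotype)

    chrom_len <- setNames(as.numeric(offset) + 10000, names(offset))
    bands <- purrr::map_dfr(names(chrom_len), function(ch) {
      edges <- round(seq(0, chrom_len[[ch]], length.out = bands_per_chrom + 1))
      tibble(chrom = ch, start = edges[-length(edges)], end = edges[-1],
             name = c(paste0("p", rev(seq_len(floor(bands_per_chrom / 2)))),
                      paste0("q", seq_len(ceiling(bands_per_chrom / 2)))))
    })
    genome_annotation(exons, biotypes = biotypes, chrom_lengths = chrom_len,
                      cytobands = bands)
  })
}

#' Simulate per-gene ground truth
#'
#' Assigns each annotated gene a response class, kinetic parameters, an NB
#' dispersion and a PCCR shift. Classes are realised mechanistically:
#' `transcriptional_up` steps transcription up at stimulus onset
#' (sustained); `post_transcriptional_down` steps the degradation rate of
#' spliced transcripts up (sustained), leaving unspliced expectations
#' untouched; the two `rebound_*` classes step transcription and revert it
#' past baseline at `rebound_time`, producing a genuine temporal inversion
#' for the downstream rebound analysis to recover.
#'
#' @param ann A [genome_annotation()] supplying gene placement.
#' @param seed Integer seed.
#' @param class_probs Named probabilities over the five classes.
#' @param fold_alpha Transcription step fold for up classes (default 3).
#' @param fold_gamma Degradation step fold for `post_transcriptional_down`
#'   (default 2).
#' @param rebound_time Minute at which rebound classes revert (default 5).
#' @param rebound_fold Post-rebound transcription as a multiple of baseline
#'   (default 0.5: undershoot, the inverted regulation seen at 15 min).
#' @param alpha_meanlog,alpha_sdlog Log-normal baseline transcription rate.
#' @param beta Baseline splicing rate, 1/min (default 1.5).
#' @param gamma Baseline spliced degradation rate, 1/min (default 0.5).
#' @param design A [simulation_design()] supplying dispersion defaults.
#' @param pccr_probs Named probabilities for `pccr_shift` in
#'   `none`/`up`/`down`.
#' @return Tibble with one row per gene: placement (`chrom`, `cytoband`),
#'   `class`, kinetic parameters, `dispersion` and `pccr_shift`.
#' @export
simulate_ground_truth <- function(ann, seed = 1,
                                  class_probs = c(null = 0.75,
                                                  transcriptional_up = 0.05,
                                                  post_transcriptional_down = 0.05,
                                                  rebound_up_then_down = 0.10,
                                                  rebound_down_then_up = 0.05),
                                  fold_alpha = 3, fold_gamma = 2,
                                  rebound_time = 5, rebound_fold = 0.5,
                                  alpha_meanlog = log(150), alpha_sdlog = 0.7,
                                  beta = 1.5, gamma = 0.5,
                                  design = simulation_design(),
                                  pccr_probs = c(none = 0.8, up = 0.1, down = 0.1)) {
  stopifnot(inherits(ann, "genome_annotation"))
  stopifnot(abs(sum(class_probs) - 1) < 1e-8)
  g <- ann$genes
  .with_seed(seed, {
    cls <- sample(names(class_probs), nrow(g), replace = TRUE, prob = class_probs)
    alpha <- stats::rlnorm(nrow(g), alpha_meanlog, alpha_sdlog)
    disp <- design$dispersion *
      stats::rlnorm(nrow(g), 0, design$dispersion_jitter_sd)
    tibble(gene_id = g$gene_id, chrom = g$chrom, cytoband = g$cytoband,
           class = cls,
           perturbation = dplyr::case_when(
             cls == "null" ~ "none",
             cls == "post_transcriptional_down" ~ "gamma",
             TRUE ~ "alpha"),
           fold = dplyr::case_when(
             cls == "null" ~ 1,
             cls == "transcriptional_up" ~ fold_alpha,
             cls == "post_transcriptional_down" ~ fold_gamma,
             cls == "rebound_up_then_down" ~ fold_alpha,
             cls == "rebound_down_then_up" ~ 1 / fold_alpha),
           rebound_time = ifelse(startsWith(cls, "rebound"), rebound_time, NA_real_),
           rebound_fold = dplyr::case_when(
             cls == "rebound_up_then_down" ~ rebound_fold,
             cls == "rebound_down_then_up" ~ 1 / rebound_fold,
             TRUE ~ 1),
           alpha = alpha, beta = beta, gamma = gamma,
           dispersion = disp,
           pccr_shift = sample(names(pccr_probs), nrow(g), replace = TRUE,
                               prob = pccr_probs))
  })
}

# expected (u, s) abundance for one truth row at time t
.truth_abundance <- function(row, t) {
  p <- kinetic_params(row$alpha, row$beta, row$gamma,
                      perturbation = row$perturbation,
                      fold = row$fold,
                      rebound_time = if (is.na(row$rebound_time)) NULL else row$rebound_time,
                      rebound_fold = row$rebound_fold)
  solve_kinetics(p, t)
}

#' Simulate layered counts for a design and ground truth
#'
#' For every gene and sample, expected spliced counts are the kinetic
#' spliced abundance at the condition's exposure time scaled by the
#' sample's depth factor; expected unspliced counts are the unspliced
#' abundance additionally scaled by the polyA capture factor (the
#' unspliced fraction of a polyA library is depleted); the ambiguous layer
#' is a configurable fraction of spliced. Counts are NB-sampled with the
#' gene's dispersion. Identical seeds give identical matrices.
#'
#' @param design A [simulation_design()].
#' @param truth Output of [simulate_ground_truth()].
#' @param seed Integer seed.
#' @return A [layered_counts()] object with the truth table attached as
#'   attribute `"truth"` and per-sample depth factors in the sample table.
#' @export
simulate_layered_counts <- function(design, truth, seed = 1) {
  stopifnot(inherits(design, "simulation_design"))
  conds <- design$conditions
  n_samp <- nrow(conds) * design$replicates
  samples <- tibble(
    sample = paste0(rep(conds$condition, each = design$replicates), "_",
                    rep(seq_len(design$replicates), nrow(conds))),
    condition = rep(conds$condition, each = design$replicates),
    time_min = rep(conds$time_min, each = design$replicates))

  # expected abundance per gene x condition
  ab <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    st <- .truth_abundance(truth[i, ], conds$time_min)
    tibble(gene_id = truth$gene_id[i], condition = conds$condition,
           u = st$u, s = st$s)
  })
  u_mat <- matrix(ab$u, nrow = nrow(truth), byrow = TRUE,
                  dimnames = list(truth$gene_id, conds$condition))
  s_mat <- matrix(ab$s, nrow = nrow(truth), byrow = TRUE,
                  dimnames = list(truth$gene_id, conds$condition))

  .with_seed(seed, {
    depth <- exp(stats::rnorm(n_samp, 0, design$lib_size_sd))
    if (any(depth <= 0)) rlang::abort("non-positive library depth")
    samples$depth_factor <- depth
    idx <- match(samples$condition, conds$condition)
    mu_s <- s_mat[, idx, drop = FALSE] %*% diag(depth)
    mu_u <- u_mat[, idx, drop = FALSE] %*% diag(depth) * design$polya_capture
    mu_a <- mu_s * design$ambiguous_fraction
    dimnames(mu_s) <- dimnames(mu_u) <- dimnames(mu_a) <-
      list(truth$gene_id, samples$sample)
    draw <- function(mu) {
      m <- matrix(stats::rnbinom(length(mu), mu = as.numeric(mu),
                                 size = rep(1 / truth$dispersion, ncol(mu))),
                  nrow = nrow(mu), dimnames = dimnames(mu))
      storage.mode(m) <- "integer"
      m
    }
    lc <- layered_counts(draw(mu_s), draw(mu_u), draw(mu_a), samples = samples)
    attr(lc, "truth") <- truth
    lc
  })
}

#' Simulate transcript-level counts per condition with PCCR shifts
#'
#' Emulates condition-pooled transcript quantification: per gene, total
#' counts per condition are drawn around `mean_total` and split between
#' protein-coding and noncoding (retained-intron / ORF-lacking / NMD)
#' isoforms. Genes with `pccr_shift = "down"` lose `shift_pp` of their
#' coding fraction between `Ctrl` and `hypg3` (recovering halfway by
#' `hypg15`); `"up"` gains it; `"none"` keeps the coding fraction constant
#' in expectation.
#'
#' @param truth Ground-truth tibble from [simulate_ground_truth()].
#' @param seed Integer seed.
#' @param ann Optional [genome_annotation()]; when supplied, counts are
#'   distributed over its annotated transcripts (genes lacking both a
#'   coding and a noncoding isoform cannot shift and are treated as
#'   `none`). Otherwise each gene gets one synthetic coding and one
#'   noncoding transcript.
#' @param conditions Condition labels, first is the reference.
#' @param mean_total Log-normal mean of per-gene per-condition total
#'   counts; PCCR classification is intended for well-quantified genes, so
#'   the default is deep (20000, i.e. pooled over four replicates).
#' @param coding_base Baseline coding fraction (default 0.9).
#' @param shift_pp Coding-fraction shift in ratio units (default 0.05 = 5
#'   percentage points).
#' @return Long tibble `transcript_id`, `gene_id`, `biotype`, `condition`,
#'   `count`, carrying the per-gene true coding fractions as attribute
#'   `"coding_fraction"`.
#' @export
simulate_transcript_counts <- function(truth, seed = 1, ann = NULL,
                                       conditions = c("Ctrl", "hypg3", "hypg15"),
                                       mean_total = 20000,
                                       coding_base = 0.9, shift_pp = 0.05) {
  noncoding <- c("retained_intron", "orf_lacking", "nmd")
  if (is.null(ann)) {
    tx <- bind_rows(
      tibble(transcript_id = paste0(truth$gene_id, "_Tc"),
             gene_id = truth$gene_id, biotype = "protein_coding"),
      tibble(transcript_id = paste0(truth$gene_id, "_Tn"),
             gene_id = truth$gene_id,
             biotype = rep_len(noncoding, nrow(truth))))
  } else {
    tx <- ann$transcripts[c("transcript_id", "gene_id", "biotype")]
  }
  tx <- tx |>
    mutate(pool = dplyr::case_when(
      .data$biotype == "protein_coding" ~ "coding",
      .data$biotype %in% noncoding ~ "noncoding",
      TRUE ~ "other")) |>
    filter(.data$gene_id %in% truth$gene_id)
  eligible <- tx |>
    group_by(.data$gene_id) |>
    summarise(ok = any(.data$pool == "coding") & any(.data$pool == "noncoding"),
              .groups = "drop")

  shift <- truth |>
    left_join(eligible, by = "gene_id") |>
    mutate(eff = ifelse(.data$ok & .data$pccr_shift == "down", -shift_pp,
                 ifelse(.data$ok & .data$pccr_shift == "up", shift_pp, 0)))
  # coding fraction per condition: full shift at 3 min, half-recovered at 15
  frac <- purrr::map_dfr(seq_along(conditions), function(k) {
    w <- c(0, 1, 0.5)[min(k, 3)]
    tibble(gene_id = shift$gene_id, condition = conditions[k],
           coding_fraction = pmin(pmax(coding_base + w * shift$eff, 0), 1))
  })

  .with_seed(seed, {
    totals <- tibble(
      gene_id = rep(truth$gene_id, times = length(conditions)),
      condition = rep(conditions, each = nrow(truth)),
      total = stats::rpois(nrow(truth) * length(conditions),
                           stats::rlnorm(nrow(truth) * length(conditions),
                                         log(mean_total), 0.3)))
    out <- totals |>
      left_join(frac, by = c("gene_id", "condition")) |>
      left_join(tidyr::nest(tx, tx = -"gene_id"), by = "gene_id")
    counts <- purrr::pmap(out, function(gene_id, condition, total,
                                        coding_fraction, tx, ...) {
      # lncRNA/other isoforms get a fixed 5% side pool so they carry counts
      # without entering the coding/(coding+noncoding) ratio
      has_other <- any(tx$pool == "other")
      main <- if (has_other) 0.95 else 1
      pool_w <- c(coding = main * coding_fraction,
                  noncoding = main * (1 - coding_fraction),
                  other = if (has_other) 0.05 else 0)
      w <- as.numeric(pool_w[tx$pool])
      n_per_pool <- as.numeric(table(tx$pool)[tx$pool])
      w <- w / n_per_pool
      if (sum(w) <= 0) w <- rep(1, length(w))
      drawn <- as.integer(stats::rmultinom(1, total, prob = w / sum(w)))
      tibble(transcript_id = tx$transcript_id, biotype = tx$biotype,
             count = drawn)
    })
    res <- out |>
      select("gene_id", "condition") |>
      mutate(data = counts) |>
      tidyr::unnest("data") |>
      select("transcript_id", "gene_id", "biotype", "condition", "count")
    attr(res, "coding_fraction") <- frac
    res
  })
}
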