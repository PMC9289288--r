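#' Pipeline configuration
#'
#' Assembles (or loads from YAML) the configuration driving
#' [run_pipeline()]: input paths, the contrast list, thresholds and
#' seeds. All analysis thresholds are surfaced here with their standard
#' defaults (call FDR 0.05, PCCR one percent point, biotype group
#' minimum 20 DEGs, enrichment set-size cap 400).
#'
#' @param path Optional YAML file to load; fields below override it.
#' @param out_dir Output directory.
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param n_genes Number of genes for the synthetic stages.
#' @param sam Optional character vector of SAM/BAM files (one per
#'   sample) for the counting stage; when `NULL` a labelled fixture is
#'   generated.
#' @param gtf,cytobands Optional annotation inputs; when `NULL` a
#'   synthetic annotation is generated.
#' @param counts_prefix Optional prefix of TSV layered counts (see
#'   [read_layered_counts()]); when `NULL` counts are simulated.
#' @param tx_counts Optional transcript-count TSV for the PCCR stage.
#' @param gmt Optional GMT file of gene sets for the enrichment stage.
#' @param contrasts Contrast strings (numerator-denominator).
#' @param alpha Call FDR threshold.
#' @param pccr_threshold PCCR classification threshold (ratio units).
#' @param min_mean DE observability threshold.
#' @param n_perm Permutations for preranked enrichment.
#' @param fixture_pairs Read pairs per generated per-sample SAM fixture
#'   (used only when `sam` is `NULL`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, out_dir = "gravirebound_run",
                            seed = 1, n_genes = 120, sam = NULL, gtf = NULL,
                            cytobands = NULL, counts_prefix = NULL,
                            tx_counts = NULL, gmt = NULL,
                            contrasts = c("hypg3-Ctrl", "hypg15-hypg3",
                                          "hypg15-Ctrl"),
                            alpha = 0.05, pccr_threshold = 0.01,
                            min_mean = 5, n_perm = 500, fixture_pairs = 2000) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), n_genes = n_genes,
              sam = sam, gtf = gtf, cytobands = cytobands,
              counts_prefix = counts_prefix, tx_counts = tx_counts,
              gmt = gmt, contrasts = contrasts, alpha = alpha,
              pccr_threshold = pccr_threshold, min_mean = min_mean,
              n_perm = n_perm, fixture_pairs = fixture_pairs)
  if (!is.null(path)) {
    loaded <- yaml::read_yaml(path)
    for (nm in names(loaded)) cfg[[nm]] <- loaded[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config A `pipeline_config`.
#' @return Character vector of problems; empty means runnable.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  chk_file <- function(p, what) {
    if (!is.null(p) && !all(file.exists(p))) {
      paste0(what, " not found: ", paste(p[!file.exists(p)], collapse = ", "))
    }
  }
  problems <- c(problems,
                chk_file(config$sam, "alignment file"),
                chk_file(config$gtf, "GTF"),
                chk_file(config$cytobands, "cytoband table"),
                chk_file(config$tx_counts, "transcript counts"),
                chk_file(config$gmt, "GMT"))
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1) {
    problems <- c(problems, "alpha must be in (0, 1)")
  }
  if (!is.numeric(config$pccr_threshold) || config$pccr_threshold < 0) {
    problems <- c(problems, "pccr_threshold must be >= 0")
  }
  conds <- c("Ctrl", "hypg3", "hypg15")
  for (ct in config$contrasts) {
    parts <- strsplit(ct, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !all(parts %in% conds)) {
      problems <- c(problems, paste0("unknown contrast: ", ct))
    }
  }
  problems[!is.na(problems)]
}

.stage_write <- function(df, out_dir, stage, name, manifest) {
  p <- file.path(out_dir, paste0(name, ".tsv"))
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.list),
                                        ~ purrr::map_chr(.x, paste, collapse = ",")))
  readr::write_tsv(df, p, progress = FALSE)
  bind_rows(manifest, tibble(file = basename(p), stage = stage,
                             md5 = unname(tools::md5sum(p))))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: annotation, (synthetic or
#' provided) layered counts, splice counting on alignment files,
#' per-layer differential expression, temporal dynamics (transitions,
#' grey-ball refinement, rebound correlation), genomic distribution over
#' chromosomes and cytobands, differential exon usage with biotype
#' association, PCCR, and enrichment. Every output table is written
#' under `config$out_dir` and listed in `manifest.tsv` with its stage
#' and MD5 checksum; given identical seeds the run is byte-identical.
#'
#' @param config A `pipeline_config`.
#' @return The manifest tibble, invisibly.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems) > 0) {
    rlang::abort(paste0("invalid config:\n", paste("-", problems, collapse = "\n")))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- tibble(file = character(0), stage = character(0),
                     md5 = character(0))
  seed <- config$seed
  message("[annotation] building gene model")
  ann <- if (!is.null(config$gtf)) {
    read_gtf(config$gtf, cytobands = config$cytobands)
  } else {
    synthetic_annotation(n_genes = config$n_genes, seed = seed)
  }
  manifest <- .stage_write(glance(ann), config$out_dir, "annotation",
                           "annotation_summary", manifest)

  design <- simulation_design()
  truth <- simulate_ground_truth(ann, seed = seed + 1, design = design)
  message("[counts] layered counts")
  if (!is.null(config$counts_prefix)) {
    lc <- read_layered_counts(config$counts_prefix)
  } else {
    lc <- simulate_layered_counts(design, truth, seed = seed + 2)
    manifest <- .stage_write(truth, config$out_dir, "synthetic", "ground_truth",
                             manifest)
  }
  write_layered_counts(lc, file.path(config$out_dir, "counts"))
  for (l in c("spliced", "unspliced", "ambiguous", "samples")) {
    p <- file.path(config$out_dir, paste0("counts_", l, ".tsv"))
    manifest <- bind_rows(manifest, tibble(file = basename(p), stage = "counts",
                                           md5 = unname(tools::md5sum(p))))
  }

  message("[splice_counting] classifying alignments")
  sams <- config$sam
  sam_group <- NULL
  if (is.null(sams)) {
    # one labelled fixture per sample of the first two conditions, so the
    # counting and exon-usage stages run on a realistic per-sample layout
    fix_samples <- lc$samples$sample[lc$samples$condition %in% c("Ctrl", "hypg3")]
    if (length(fix_samples) == 0) fix_samples <- lc$samples$sample
    sams <- file.path(config$out_dir, paste0("fixture_", fix_samples, ".sam"))
    for (i in seq_along(sams)) {
      tr <- generate_sam_fixture(ann, n_pairs = config$fixture_pairs,
                                 path = sams[i], seed = seed + 30 + i)
      if (i == 1) {
        manifest <- .stage_write(tr, config$out_dir, "splice_counting",
                                 "sam_truth", manifest)
      }
    }
    sam_group <- lc$samples$condition[match(fix_samples, lc$samples$sample)]
  }
  counted <- count_layers(sams, ann)
  manifest <- .stage_write(attr(counted, "summary"), config$out_dir,
                           "splice_counting", "counting_summary", manifest)

  message("[diffexpr] per-layer differential expression")
  de <- de_layers(lc, contrasts = config$contrasts, min_mean = config$min_mean)
  manifest <- .stage_write(de, config$out_dir, "diffexpr", "de_results", manifest)

  message("[dynamics] rebound analysis")
  calls <- de |>
    group_by(.data$layer, .data$contrast) |>
    group_modify(~ call_regulation(.x, alpha = config$alpha)) |>
    ungroup()
  manifest <- .stage_write(calls, config$out_dir, "dynamics", "calls", manifest)
  get_calls <- function(l, ct) filter(calls, .data$layer == l, .data$contrast == ct)
  cts <- config$contrasts
  dyn_out <- list()
  if (all(c("hypg3-Ctrl", "hypg15-hypg3") %in% cts)) {
    tt <- transition_table(get_calls("total", "hypg3-Ctrl"),
                           get_calls("total", "hypg15-hypg3"))
    manifest <- .stage_write(tt, config$out_dir, "dynamics", "transitions",
                             manifest)
    deA <- filter(de, .data$layer == "total", .data$contrast == "hypg3-Ctrl")
    deB <- filter(de, .data$layer == "total", .data$contrast == "hypg15-hypg3")
    rc <- rebound_correlation(deA, deB)
    manifest <- .stage_write(rc, config$out_dir, "dynamics",
                             "rebound_correlation", manifest)
  }
  if (all(c("hypg3-Ctrl", "hypg15-hypg3", "hypg15-Ctrl") %in% cts)) {
    grey <- refine_grey_categories(get_calls("total", "hypg3-Ctrl"),
                                   get_calls("total", "hypg15-hypg3"),
                                   get_calls("total", "hypg15-Ctrl"))
    manifest <- .stage_write(grey, config$out_dir, "dynamics",
                             "grey_categories", manifest)
  }

  message("[distribution] regional expectation tests")
  for (lvl in c("chromosome", "cytoband")) {
    tal <- region_tally(get_calls("total", cts[1]), ann, level = lvl) |>
      expected_counts() |>
      fisher_region_tests()
    manifest <- .stage_write(tal, config$out_dir, "distribution",
                             paste0("region_", lvl), manifest)
    manifest <- .stage_write(expected_actual_correlation(tal), config$out_dir,
                             "distribution", paste0("region_", lvl, "_cor"),
                             manifest)
  }

  message("[deu] differential exon usage")
  bins <- flatten_exons(ann)
  bin_counts <- count_exon_bins(sams, ann, bins)
  deu <- NULL
  if (ncol(bin_counts) >= 4) {
    grp <- if (!is.null(sam_group)) sam_group else
      lc$samples$condition[match(colnames(bin_counts), lc$samples$sample)]
    parts <- strsplit(cts[1], "-", fixed = TRUE)[[1]]
    if (sum(grp == parts[1], na.rm = TRUE) >= 2 &&
        sum(grp == parts[2], na.rm = TRUE) >= 2) {
      deu <- deu_test(bin_counts, bins, grp, parts[1], parts[2],
                      alpha = config$alpha)
      manifest <- .stage_write(deu$bins, config$out_dir, "deu", "deu_bins",
                               manifest)
      du_tx <- map_du_to_transcripts(deu, bins)
      manifest <- .stage_write(biotype_tally(du_tx, ann), config$out_dir,
                               "biotype", "biotype_tally", manifest)
      spliced_calls <- get_calls("spliced", cts[1])
      manifest <- .stage_write(
        biotype_deg_association(du_tx, spliced_calls, ann),
        config$out_dir, "biotype", "biotype_deg_association", manifest)
    }
  }

  message("[pccr] protein coding counts ratio")
  tx_counts <- if (!is.null(config$tx_counts)) {
    read_transcript_counts(config$tx_counts)
  } else {
    simulate_transcript_counts(truth, seed = seed + 4, ann = ann)
  }
  pccr <- compute_pccr(tx_counts, threshold = config$pccr_threshold)
  manifest <- .stage_write(as_tibble(pccr), config$out_dir, "pccr", "pccr",
                           manifest)
  calls_by_layer <- calls |>
    filter(.data$contrast == cts[1]) |>
    select("layer", "gene_id", "call")
  manifest <- .stage_write(pccr_deg_overlap(pccr, calls_by_layer),
                           config$out_dir, "pccr", "pccr_deg_overlap", manifest)

  message("[enrichment] gene-set tests")
  sets <- if (!is.null(config$gmt)) read_gmt(config$gmt) else {
    .with_seed(seed + 5, {
      universe0 <- ann$genes$gene_id
      c(list(RESPONSIVE_TRUTH = truth$gene_id[truth$class != "null"]),
        setNames(lapply(1:4, function(i) sample(universe0, 25)),
                 paste0("RANDOM_", 1:4)))
    })
  }
  de_first <- filter(de, .data$layer == "total", .data$contrast == cts[1],
                     .data$observable)
  universe <- de_first$gene_id
  query <- de_first$gene_id[!is.na(de_first$fdr) &
                              de_first$fdr < config$alpha]
  if (length(query) > 0) {
    ora <- suppressWarnings(ora_fisher(query, universe, sets))
    manifest <- .stage_write(ora, config$out_dir, "enrichment", "ora", manifest)
  }
  ranked <- setNames(de_first$stat, de_first$gene_id)
  ranked <- ranked[!is.na(ranked)]
  pre <- suppressWarnings(preranked_enrichment(ranked, sets,
                                               n_perm = config$n_perm,
                                               seed = seed + 6))
  manifest <- .stage_write(pre, config$out_dir, "enrichment", "preranked",
                           manifest)

  manifest <- arrange(manifest, .data$file)
  readr::write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"),
                   progress = FALSE)
  invisible(manifest)
}

#' One-command synthetic demonstration run
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @return Manifest tibble, invisibly.
#' @export
run_demo <- function(out_dir = "gravirebound_demo", seed = 1) {
  run_pipeline(pipeline_config(out_dir = out_dir, seed = seed))
}
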