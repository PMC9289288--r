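#' Median-of-ratios size factors
#'
#' Per-sample normalization scalars computed against the geometric-mean
#' reference sample, using only genes with positive counts in every
#' sample. For layered analyses the factors are computed once from the
#' total layer (spliced + unspliced + ambiguous) and reused for every
#' layer, so all layers share identical normalization.
#'
#' @param counts Integer matrix, genes x samples (>= 2 samples).
#' @return Named positive numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  if (ncol(counts) < 2) rlang::abort("need at least 2 samples")
  logg <- rowMeans(log(counts))
  use <- is.finite(logg)
  if (!any(use)) {
    rlang::abort(paste0("no gene has positive counts in all samples; ",
                        "normalization needs a pseudo-reference"))
  }
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - logg[use]))
  })
  setNames(sf, colnames(counts))
}

#' Counts normalized by size factors
#'
#' @param counts Integer matrix genes x samples.
#' @param sf Size factors from [size_factors()].
#' @return Numeric matrix `counts[, j] / sf[j]`.
#' @export
normalized_counts <- function(counts, sf) {
  sweep(counts, 2, sf, "/")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement (delegates to
#' [stats::p.adjust()]); `NA`/`NaN` p-values propagate.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in \[0, 1\].
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Per-gene NB dispersion by moments with trend shrinkage
#'
#' Method-of-moments dispersion per gene from normalized counts: the
#' pooled within-group variance is compared with the NB mean-variance
#' relation, giving a raw (possibly negative) genewise value. A
#' mean-dispersion trend is fitted across genes by loess on the raw
#' values against log mean — fitting on the raw scale keeps the trend
#' unbiased despite the large sampling noise of genewise moments at
#' small replicate numbers — and the final estimate blends the trend and
#' the (non-negative part of the) genewise value equally, floored at
#' `1e-8`. With too few genes for a trend the raw method-of-moments
#' value is used directly.
#'
#' @param counts Integer matrix genes x samples.
#' @param sf Size factors.
#' @param group Factor/character vector of sample conditions (>= 2
#'   replicates per level).
#' @return Tibble `gene_id`, `base_mean`, `dispersion_mom` (raw),
#'   `dispersion_trend`, `dispersion`.
#' @export
estimate_dispersion <- function(counts, sf, group) {
  group <- as.factor(group)
  z <- normalized_counts(counts, sf)
  a_num <- rep(0, nrow(counts))
  a_den <- rep(0, nrow(counts))
  for (g in levels(group)) {
    jj <- which(group == g)
    if (length(jj) < 2) next
    zg <- z[, jj, drop = FALSE]
    mu_g <- rowMeans(zg)
    v_g <- apply(zg, 1, stats::var)
    cg <- mean(1 / sf[jj])
    a_g <- ifelse(mu_g > 0, (v_g - mu_g * cg) / mu_g^2, NA_real_)
    w <- length(jj) - 1
    ok <- !is.na(a_g)
    a_num[ok] <- a_num[ok] + w * a_g[ok]
    a_den[ok] <- a_den[ok] + w
  }
  base_mean <- rowMeans(z)
  floor_d <- 1e-8
  a_raw <- ifelse(a_den > 0, a_num / pmax(a_den, 1), NA_real_)

  fit_ok <- which(!is.na(a_raw) & base_mean > 0)
  trend <- rep(NA_real_, nrow(counts))
  if (length(fit_ok) >= 20) {
    lo <- stats::loess(a_raw[fit_ok] ~ log(base_mean[fit_ok]), span = 1,
                       degree = 1)
    pred_at <- pmin(pmax(log(pmax(base_mean, min(base_mean[fit_ok]))),
                         min(lo$x)), max(lo$x))
    trend <- pmax(stats::predict(lo, newdata = pred_at), floor_d)
  } else if (length(fit_ok) >= 2) {
    trend <- rep(pmax(mean(a_raw[fit_ok]), floor_d), nrow(counts))
  }
  disp <- ifelse(is.na(trend), pmax(a_raw, floor_d),
                 0.5 * trend + 0.5 * pmax(a_raw, 0, na.rm = TRUE))
  disp[is.na(disp)] <- floor_d
  out <- tibble(gene_id = rownames(counts), base_mean = base_mean,
                dispersion_mom = a_raw, dispersion_trend = trend,
                dispersion = pmax(disp, floor_d))
  attr(out, "resid_df") <- sum(pmax(table(group) - 1, 0))
  out
}

# Fisher scoring for the log-mean of an NB group with known dispersion:
# y_ij ~ NB(mean = q_i * s_ij, size = 1/a_i). Vectorized over genes.
# Returns the MLE q and the observed Fisher information of log(q).
.nb_group_fit <- function(y, s, a, iter = 50, tol = 1e-12) {
  ysum <- rowSums(y)
  q <- ysum / rowSums(s)
  pos <- which(ysum > 0)
  if (length(pos) > 0) {
    eta <- log(q[pos])
    yp <- y[pos, , drop = FALSE]
    sp <- s[pos, , drop = FALSE]
    ap <- a[pos]
    for (k in seq_len(iter)) {
      mu <- exp(eta) * sp
      denom <- 1 + ap * mu
      U <- rowSums((yp - mu) / denom)
      I <- rowSums(mu / denom)
      step <- U / pmax(I, 1e-12)
      step <- pmin(pmax(step, -5), 5)
      eta <- eta + step
      if (max(abs(step)) < tol) break
    }
    q[pos] <- exp(eta)
  }
  mu <- q * s
  info <- rowSums(mu / (1 + a * mu))
  list(q = q, info = info)
}

#' Two-group negative-binomial Wald contrast
#'
#' Per-gene NB log-link mean fit in each group (dispersion held at the
#' supplied per-gene estimate), with a Wald test of the log2 fold change
#' numerator/denominator. The construction is symmetric in the two groups:
#' swapping them negates `lfc` and leaves `p` unchanged. Genes whose mean
#' normalized count across the contrast's samples falls below
#' `min_mean` are flagged non-observable and excluded from the BH family
#' (`fdr = NA`).
#'
#' @param counts Integer matrix genes x samples.
#' @param sf Size factors (shared across layers).
#' @param dispersions Per-gene dispersion vector (e.g. the `dispersion`
#'   column of [estimate_dispersion()]).
#' @param group Condition label per sample.
#' @param numerator,denominator Condition labels contrasted as
#'   log2(numerator / denominator).
#' @param min_mean Observability threshold on the mean normalized count
#'   (default 5).
#' @param offsets Optional gene x sample offset matrix overriding
#'   `sf` (used by the exon-usage test, where the exposure is the
#'   per-sample gene total).
#' @param df Reference degrees of freedom for the Wald p-value; the
#'   default `Inf` is the standard normal reference. A finite value gives
#'   a t reference for small designs where dispersion-estimation noise
#'   should be charged to the test.
#' @return A `contrast_result` tibble: `gene_id`, `base_mean`, `lfc`,
#'   `se`, `stat`, `p`, `fdr`, `observable`, with the contrast label in
#'   attribute `"contrast"`.
#' @export
nb_wald_contrast <- function(counts, sf, dispersions, group, numerator,
                             denominator, min_mean = 5, offsets = NULL,
                             df = Inf) {
  group <- as.character(group)
  jn <- which(group == numerator)
  jd <- which(group == denominator)
  if (length(jn) < 2 || length(jd) < 2) {
    rlang::abort("both groups need at least 2 samples")
  }
  if (is.null(offsets)) {
    # fit on normalized counts with unit exposures: every statistic is then
    # an exact function of counts/sf, so rescaling a sample's counts
    # together with its size factor changes nothing (the NB score equations
    # accept continuous observations)
    counts <- sweep(counts, 2, sf, "/")
    offsets <- matrix(1, nrow = nrow(counts), ncol = ncol(counts),
                      dimnames = dimnames(counts))
  }
  a <- pmax(dispersions, 1e-8)
  yn <- counts[, jn, drop = FALSE]; sn <- offsets[, jn, drop = FALSE]
  yd <- counts[, jd, drop = FALSE]; sd_ <- offsets[, jd, drop = FALSE]
  fn <- .nb_group_fit(yn, sn, a)
  fd <- .nb_group_fit(yd, sd_, a)
  qn <- pmax(fn$q, 1e-8)
  qd <- pmax(fd$q, 1e-8)
  lfc <- (log(qn) - log(qd)) / log(2)
  var_log <- 1 / pmax(fn$info, 1e-12) + 1 / pmax(fd$info, 1e-12)
  se <- sqrt(var_log) / log(2)
  stat <- (log(qn) - log(qd)) / sqrt(var_log)
  p <- if (is.finite(df)) 2 * stats::pt(-abs(stat), df = df)
       else 2 * stats::pnorm(-abs(stat))

  z <- counts[, c(jn, jd), drop = FALSE] / offsets[, c(jn, jd), drop = FALSE]
  z[!is.finite(z)] <- NA
  base_mean <- rowMeans(z, na.rm = TRUE)
  base_mean[is.nan(base_mean)] <- 0
  all_zero <- rowSums(counts[, c(jn, jd), drop = FALSE]) == 0
  observable <- !all_zero & base_mean >= min_mean
  lfc[all_zero] <- NA_real_
  se[all_zero] <- NA_real_
  stat[all_zero] <- NA_real_
  p[all_zero] <- NA_real_
  fdr <- rep(NA_real_, length(p))
  fdr[observable] <- bh_adjust(p[observable])
  res <- tibble(gene_id = rownames(counts), base_mean = unname(base_mean),
                lfc = unname(lfc), se = unname(se), stat = unname(stat),
                p = unname(p), fdr = unname(fdr),
                observable = unname(observable))
  class(res) <- c("contrast_result", class(res))
  attr(res, "contrast") <- paste0(numerator, "-", denominator)
  res
}

#' Differential expression across layers and contrasts
#'
#' The layered DE workflow: size factors are computed once from the total
#' layer and shared by every layer; per layer, dispersions are estimated
#' and each requested contrast is tested with [nb_wald_contrast()].
#'
#' @param lc A [layered_counts()] whose sample table has a `condition`
#'   column.
#' @param contrasts Character vector like `"hypg3-Ctrl"` (numerator minus
#'   denominator).
#' @param layers Layers to analyse (default spliced, unspliced, total).
#' @param min_mean Observability threshold passed through.
#' @return Tibble with `layer` and `contrast` columns ahead of the
#'   `contrast_result` schema.
#' @export
de_layers <- function(lc, contrasts = c("hypg3-Ctrl", "hypg15-hypg3", "hypg15-Ctrl"),
                      layers = c("spliced", "unspliced", "total"),
                      min_mean = 5) {
  stopifnot(inherits(lc, "layered_counts"))
  group <- lc$samples$condition
  sf <- size_factors(total_counts(lc))
  purrr::map_dfr(layers, function(l) {
    m <- layer_counts(lc, l)
    disp <- estimate_dispersion(m, sf, group)$dispersion
    purrr::map_dfr(contrasts, function(ct) {
      parts <- strsplit(ct, "-", fixed = TRUE)[[1]]
      if (length(parts) != 2 || !all(parts %in% group)) {
        rlang::abort(paste0("contrast '", ct, "' does not match conditions"))
      }
      res <- nb_wald_contrast(m, sf, disp, group, parts[1], parts[2],
                              min_mean = min_mean)
      mutate(as_tibble(res), layer = l, contrast = ct, .before = 1)
    })
  })
}

#' @method tidy contrast_result
#' @export
tidy.contrast_result <- function(x, ...) as_tibble(x)

#' @method glance contrast_result
#' @export
glance.contrast_result <- function(x, ...) {
  tibble(contrast = attr(x, "contrast") %||% NA_character_,
         n_genes = nrow(x),
         n_observable = sum(x$observable),
         n_significant = sum(x$fdr < 0.05, na.rm = TRUE))
}

#' @importFrom rlang %||%
NULL
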