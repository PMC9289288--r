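#' Read gene sets from a GMT file
#'
#' @param path GMT path (set name, description, then gene ids, tab
#'   separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- purrr::imap_chr(sets, function(g, nm) {
    paste(c(nm, description, g), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' The curated cytoskeletal-nuclear mechanical axis gene set
#'
#' 55 genes covering the lamins, cytoskeletal actins and tubulins, the
#' LINC complex (nesprins, SUN proteins, emerin) and the nuclear pore
#' complex with its associated transport factors, shipped with the
#' package as a GMT file.
#'
#' @return Named list with one element, `MECHANICAL_AXIS`.
#' @export
mechanical_axis_set <- function() {
  read_gmt(system.file("extdata", "mechanical_axis.gmt",
                       package = "gravirebound", mustWork = TRUE))
}

#' Fisher overrepresentation analysis
#'
#' Two-sided Fisher exact test per gene set on the 2x2 membership table
#' (in set / out of set x in query / out of query), after intersecting
#' every set with the detected universe. The p-value depends only on the
#' four margins. BH adjustment across tested sets.
#'
#' @param query Character vector of genes of interest (subset of
#'   `universe`).
#' @param universe Character vector of all detected genes.
#' @param sets Named list of gene sets.
#' @param min_size Drop sets smaller than this after intersection
#'   (default 1; empty sets are always dropped with a warning).
#' @param max_size Drop sets larger than this after intersection.
#' @return Tibble `set`, `k` (overlap), `K` (set size in universe),
#'   `n` (query size), `N` (universe size), `odds_ratio`, `p`, `fdr`.
#' @export
ora_fisher <- function(query, universe, sets, min_size = 1, max_size = Inf) {
  universe <- unique(universe)
  if (length(universe) == 0) rlang::abort("empty universe")
  query <- unique(query)
  if (!all(query %in% universe)) rlang::abort("query must be within universe")
  isects <- lapply(sets, intersect, universe)
  sizes <- lengths(isects)
  if (any(sizes == 0)) {
    rlang::warn(paste0(sum(sizes == 0), " set(s) disjoint from the universe dropped"))
  }
  keep <- sizes >= max(min_size, 1) & sizes <= max_size
  isects <- isects[keep]
  if (length(isects) == 0) {
    return(tibble(set = character(0), k = integer(0), K = integer(0),
                  n = integer(0), N = integer(0), odds_ratio = numeric(0),
                  p = numeric(0), fdr = numeric(0)))
  }
  N <- length(universe)
  n <- length(query)
  res <- purrr::imap_dfr(isects, function(s, nm) {
    K <- length(s)
    k <- length(intersect(s, query))
    ft <- stats::fisher.test(matrix(c(k, K - k, n - k, N - K - (n - k)), 2))
    tibble(set = nm, k = k, K = K, n = n, N = N,
           odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  mutate(res, fdr = bh_adjust(.data$p))
}

# weighted running-sum enrichment score for set positions `idx` (sorted,
# 1-based) in a ranking with weights w (|stat|), total N
.running_es <- function(idx, w_abs, N) {
  K <- length(idx)
  wr <- w_abs[idx]
  NR <- sum(wr)
  hit_inc <- if (NR > 0) wr / NR else rep(1 / K, K)
  miss_dec <- 1 / (N - K)
  cum_hit <- cumsum(hit_inc)
  miss_before <- (idx - seq_len(K)) * miss_dec      # misses up to just before hit
  right <- cum_hit - miss_before                    # value after each hit
  left <- c(0, cum_hit[-K]) - miss_before           # value just before each hit
  cand <- c(right, left)
  unname(cand[which.max(abs(cand))])
}

#' Preranked running-sum enrichment with a permutation null
#'
#' Genes are ranked by decreasing statistic (ties broken by gene id for
#' determinism) and a weighted Kolmogorov-Smirnov-style running sum is
#' computed per set (weight = |stat|, exponent 1). The null is built by
#' gene-label permutation: random same-size gene subsets. When the number
#' of distinct subsets does not exceed `n_perm`, all subsets are
#' enumerated, making the p-value exact; otherwise `n_perm` subsets are
#' sampled under `seed`. The p-value is one-sided among null scores with
#' the sign of the observed score; `nes` normalizes by the mean absolute
#' null score of that sign. Sets with more than `max_size` genes (in the
#' universe) are excluded before testing; BH across tested sets. The
#' smallest achievable sampled p is 1/(n_perm+1).
#'
#' @param stats Named numeric vector of per-gene ranking statistics (no
#'   duplicate names), or a tibble `gene_id`, `stat`.
#' @param sets Named list of gene sets.
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param seed Integer seed for the permutation draw.
#' @param max_size Maximum set size (default 400).
#' @param min_size Minimum set size after intersection (default 2).
#' @return Tibble `set`, `K`, `es`, `nes`, `p_perm`, `fdr`, `exhaustive`.
#' @export
preranked_enrichment <- function(stats, sets, n_perm = 1000, seed = 1,
                                 max_size = 400, min_size = 2) {
  if (is.data.frame(stats)) stats <- setNames(stats$stat, stats$gene_id)
  if (anyDuplicated(names(stats))) rlang::abort("duplicate gene ids in stats")
  if (n_perm < 100) rlang::warn("fewer than 100 permutations: p-values are coarse")
  ord <- order(-stats, names(stats))
  ranked <- stats[ord]
  genes <- names(ranked)
  w_abs <- abs(ranked)
  N <- length(genes)
  isects <- lapply(sets, intersect, genes)
  if (any(lengths(isects) > N - 1)) {
    rlang::abort("a gene set covers the whole universe; enrichment undefined")
  }
  keep <- lengths(isects) >= min_size & lengths(isects) <= max_size
  if (any(lengths(isects) == 0)) {
    rlang::warn(paste0(sum(lengths(isects) == 0),
                       " set(s) disjoint from the ranking dropped"))
  }
  isects <- isects[keep]
  if (length(isects) == 0) {
    return(tibble(set = character(0), K = integer(0), es = numeric(0),
                  nes = numeric(0), p_perm = numeric(0), fdr = numeric(0),
                  exhaustive = logical(0)))
  }
  res <- purrr::imap_dfr(isects, function(s, nm) {
    K <- length(s)
    idx <- sort(match(s, genes))
    es <- .running_es(idx, w_abs, N)
    n_subsets <- suppressWarnings(choose(N, K))
    exhaustive <- is.finite(n_subsets) && n_subsets <= n_perm
    if (exhaustive) {
      combs <- utils::combn(N, K)
      null_es <- apply(combs, 2, function(ii) .running_es(sort(ii), w_abs, N))
    } else {
      null_es <- .with_seed(seed + match(nm, names(isects)), {
        vapply(seq_len(n_perm), function(b) {
          .running_es(sort(sample.int(N, K)), w_abs, N)
        }, numeric(1))
      })
    }
    same <- if (es >= 0) null_es >= 0 else null_es < 0
    n_same <- sum(same)
    if (exhaustive) {
      p <- if (n_same > 0) sum(abs(null_es[same]) >= abs(es)) / n_same else NA_real_
    } else {
      p <- (1 + sum(same & abs(null_es) >= abs(es))) / (1 + n_same)
    }
    nes <- if (n_same > 0) es / mean(abs(null_es[same])) else NA_real_
    tibble(set = nm, K = K, es = es, nes = nes, p_perm = p,
           exhaustive = exhaustive)
  })
  mutate(res, fdr = bh_adjust(.data$p_perm))
}
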