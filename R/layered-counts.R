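#' Layered count container
#'
#' Holds gene-by-sample integer count matrices for the three read layers
#' (`spliced`, `unspliced`, `ambiguous`) produced by splice-aware counting,
#' plus a sample table. The `total` layer is defined as the elementwise sum
#' and is computed on demand with [total_counts()]; size factors for
#' differential expression are always computed from this sum so all layers
#' share identical normalization.
#'
#' @param spliced,unspliced,ambiguous Integer matrices with identical
#'   dimnames (genes x samples); non-negative.
#' @param samples Tibble with at least `sample` and `condition`; defaults
#'   to the column names with condition `NA`.
#' @return An object of class `layered_counts`.
#' @export
layered_counts <- function(spliced, unspliced, ambiguous, samples = NULL) {
  mats <- list(spliced = spliced, unspliced = unspliced, ambiguous = ambiguous)
  dn <- dimnames(spliced)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!is.matrix(m)) rlang::abort(paste0(nm, " must be a matrix"))
    if (!identical(dimnames(m), dn)) {
      rlang::abort("layer matrices must share identical dimnames")
    }
    if (any(m < 0)) rlang::abort(paste0("negative counts in layer ", nm))
    storage.mode(mats[[nm]]) <- "integer"
  }
  if (is.null(samples)) {
    samples <- tibble(sample = colnames(spliced), condition = NA_character_)
  }
  if (!all(colnames(spliced) == samples$sample)) {
    rlang::abort("samples$sample must match column names")
  }
  structure(list(spliced = mats$spliced, unspliced = mats$unspliced,
                 ambiguous = mats$ambiguous, samples = as_tibble(samples)),
            class = "layered_counts")
}

#' Total counts across layers
#'
#' @param x A `layered_counts` object.
#' @return Integer matrix `spliced + unspliced + ambiguous`.
#' @export
total_counts <- function(x) {
  stopifnot(inherits(x, "layered_counts"))
  x$spliced + x$unspliced + x$ambiguous
}

#' Extract one layer
#'
#' @param x A `layered_counts` object.
#' @param layer One of `"spliced"`, `"unspliced"`, `"ambiguous"`, `"total"`.
#' @return Integer matrix.
#' @export
layer_counts <- function(x, layer = c("spliced", "unspliced", "ambiguous", "total")) {
  layer <- match.arg(layer)
  if (layer == "total") total_counts(x) else x[[layer]]
}

#' @export
print.layered_counts <- function(x, ...) {
  cat("<layered_counts> ", nrow(x$spliced), " genes x ", ncol(x$spliced),
      " samples; layers: spliced, unspliced, ambiguous\n", sep = "")
  invisible(x)
}

#' @export
dim.layered_counts <- function(x) dim(x$spliced)

#' Tidy a layered_counts object into long form
#'
#' @param x A `layered_counts` object.
#' @param ... Unused.
#' @return Tibble `gene_id`, `sample`, `layer`, `count`.
#' @method tidy layered_counts
#' @export
tidy.layered_counts <- function(x, ...) {
  purrr::map_dfr(c("spliced", "unspliced", "ambiguous"), function(l) {
    m <- x[[l]]
    tibble(gene_id = rep(rownames(m), ncol(m)),
           sample = rep(colnames(m), each = nrow(m)),
           layer = l,
           count = as.integer(m))
  })
}

#' @method glance layered_counts
#' @export
glance.layered_counts <- function(x, ...) {
  tibble(n_genes = nrow(x$spliced), n_samples = ncol(x$spliced),
         total_spliced = sum(x$spliced),
         total_unspliced = sum(x$unspliced),
         total_ambiguous = sum(x$ambiguous))
}

#' Write layered counts as one TSV per layer
#'
#' Files `<prefix>_spliced.tsv` etc., genes in rows, a leading `gene_id`
#' column, one column per sample; plus `<prefix>_samples.tsv`.
#'
#' @param x A `layered_counts` object.
#' @param prefix Output path prefix.
#' @return The file paths, invisibly.
#' @export
write_layered_counts <- function(x, prefix) {
  stopifnot(inherits(x, "layered_counts"))
  paths <- character(0)
  for (l in c("spliced", "unspliced", "ambiguous")) {
    p <- paste0(prefix, "_", l, ".tsv")
    df <- bind_cols(tibble(gene_id = rownames(x[[l]])), as_tibble(x[[l]]))
    readr::write_tsv(df, p, progress = FALSE)
    paths <- c(paths, p)
  }
  p <- paste0(prefix, "_samples.tsv")
  readr::write_tsv(x$samples, p, progress = FALSE)
  invisible(c(paths, p))
}

#' Read layered counts written by [write_layered_counts()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `layered_counts` object.
#' @export
read_layered_counts <- function(prefix) {
  mats <- lapply(c("spliced", "unspliced", "ambiguous"), function(l) {
    df <- readr::read_tsv(paste0(prefix, "_", l, ".tsv"), col_types = readr::cols(),
                          progress = FALSE)
    m <- as.matrix(df[-1])
    rownames(m) <- df$gene_id
    storage.mode(m) <- "integer"
    m
  })
  samples <- readr::read_tsv(paste0(prefix, "_samples.tsv"),
                             col_types = readr::cols(), progress = FALSE)
  layered_counts(mats[[1]], mats[[2]], mats[[3]], samples = samples)
}
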