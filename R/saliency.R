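#' Normalize a segment's variables by their own SD
#'
#' Within a repetition segment each of the 30 time series is scaled by its
#' within-segment standard deviation so that variables measured in meters,
#' radians, m/s and rad/s become comparable before the covariance analysis.
#' Columns with zero SD (a variable frozen throughout the segment) are
#' passed through unscaled and flagged.
#'
#' @param slice data frame or matrix of variable-table rows (>= 2).
#' @return numeric matrix of the same shape with attribute
#'   \code{zero_sd} naming any untouched columns.
#' @export
normalize_segment <- function(slice) {
  x <- as.matrix(slice)
  if (nrow(x) < 2) stop("segment must have at least two rows", call. = FALSE)
  s <- apply(x, 2, stats::sd)
  zero <- s == 0
  s[zero] <- 1
  out <- sweep(x, 2, s, "/")
  attr(out, "zero_sd") <- colnames(x)[zero]
  out
}

#' Covariance spectrum of a normalized segment
#'
#' Population covariance of the normalized columns,
#' \eqn{K[i,j] = \frac{1}{T}\sum_t (s_i(t)-\bar s_i)(s_j(t)-\bar s_j)}
#' (the mean-of-products form), with its eigendecomposition attached,
#' eigenvalues sorted in descending order and eigenvectors aligned.
#'
#' @param normalized matrix from [normalize_segment()].
#' @return list of class \code{covariance_spectrum} with \code{K} (p x p),
#'   \code{values} (descending eigenvalues) and \code{vectors} (columns
#'   aligned with \code{values}).
#' @export
segment_covariance <- function(normalized) {
  x <- as.matrix(normalized)
  if (nrow(x) < 2) stop("need at least two rows", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite values in segment", call. = FALSE)
  xc <- sweep(x, 2, colMeans(x))
  K <- crossprod(xc) / nrow(x)
  eig <- eigen(K, symmetric = TRUE)   # eigen() already sorts descending
  structure(list(K = K, values = eig$values, vectors = eig$vectors,
                 names = colnames(x)),
            class = "covariance_spectrum")
}

#' Number of dominant eigenvalues by the spectral-gap rule
#'
#' The spectral gap is the largest difference between consecutive
#' eigenvalues sorted in descending order; the eigenvalues preceding the gap
#' are dominant. Ties in the maximal gap are broken toward the earliest
#' position, i.e. fewer retained components.
#'
#' @param values eigenvalues in descending order (length >= 2).
#' @return integer count of dominant eigenvalues.
#' @export
spectral_gap_count <- function(values) {
  if (length(values) < 2) stop("need at least two eigenvalues", call. = FALSE)
  gaps <- -diff(values)
  which.max(gaps)   # first maximum on ties
}

#' Salient variables by the loading-gap rule
#'
#' The absolute principal-component loadings are sorted in descending order
#' and the largest consecutive drop marks the cut: variables loading before
#' the gap are retained as salient, in descending-loading order. Eigenvector
#' sign is irrelevant.
#'
#' @param vector one eigenvector (principal-component loadings).
#' @param names variable names aligned with \code{vector}.
#' @return character vector of salient variable names.
#' @export
loading_gap_select <- function(vector, names) {
  stopifnot(length(vector) == length(names), length(vector) >= 2)
  a <- abs(vector)
  ord <- order(a, decreasing = TRUE)
  k <- spectral_gap_count(a[ord])
  names[ord][seq_len(k)]
}

#' Per-segment saliency analysis
#'
#' Runs normalization, covariance eigendecomposition, spectral-gap component
#' selection and loading-gap variable selection on every labelled segment of
#' a variable table.
#'
#' @param table variable table from [assemble_variable_table()].
#' @param segments labelled segments from [build_segments()].
#' @return data-frame-free list, one element per segment, each with
#'   \code{class}, \code{repetition}, \code{n_components} and
#'   \code{salient} (variables of the first principal component).
#' @export
segment_saliency <- function(table, segments) {
  lapply(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    rows <- seq.int(seg$start + 1L, seg$end)
    spec <- segment_covariance(normalize_segment(table[rows, , drop = FALSE]))
    list(class = seg$class, repetition = seg$repetition,
         n_components = spectral_gap_count(spec$values),
         salient = loading_gap_select(spec$vectors[, 1], spec$names),
         values = spec$values)
  })
}

#' Aggregate per-segment salient variables by movement class
#'
#' The per-repetition salient lists of each gesture are combined by union,
#' with occurrence counts recording in how many repetitions each variable
#' was selected.
#'
#' @param saliency list from [segment_saliency()] (or any list of elements
#'   with \code{class} and \code{salient}).
#' @return named list (one element per movement class) of data frames with
#'   columns \code{variable} and \code{count}, ordered by decreasing count.
#' @export
aggregate_saliency <- function(saliency) {
  classes <- unique(vapply(saliency, `[[`, character(1), "class"))
  out <- lapply(classes, function(cl) {
    lists <- lapply(Filter(function(s) s$class == cl, saliency), `[[`,
                    "salient")
    tab <- sort(table(unlist(lists)), decreasing = TRUE)
    data.frame(variable = names(tab), count = as.integer(tab))
  })
  stats::setNames(out, classes)
}

#' Write per-class salient sets as JSON
#'
#' @param salient_sets result of [aggregate_saliency()].
#' @param path JSON file path.
#' @export
write_salient_sets <- function(salient_sets, path) {
  jsonlite::write_json(salient_sets, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
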