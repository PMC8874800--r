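#' Specification of the 21 window features
#'
#' Each 13-step window (0.15 s at 89 Hz) is summarised by: the means of the
#' 12 controller pose variables relative to the head frame (position and
#' orientation of both controllers), the sample SDs of the 6 controller
#' orientation angles, and the Pearson correlations of the 3 homologous
#' angle pairs across hands — 12 + 6 + 3 = 21 features. The SD variable set
#' is configurable; an alternative reading of the feature table uses the
#' right controller's position + orientation instead, which is available by
#' passing those columns in \code{sd_vars}.
#'
#' @param window_length window size in time steps.
#' @param mean_vars,sd_vars character vectors of variable-table columns.
#' @param cor_pairs list of length-2 character vectors.
#' @return object of class \code{feature_spec}.
#' @export
feature_spec <- function(window_length = 13,
                         mean_vars = c("X_H_R", "Y_H_R", "Z_H_R",
                                       "gamma_H_R", "beta_H_R", "alpha_H_R",
                                       "X_H_L", "Y_H_L", "Z_H_L",
                                       "gamma_H_L", "beta_H_L", "alpha_H_L"),
                         sd_vars = c("gamma_H_R", "beta_H_R", "alpha_H_R",
                                     "gamma_H_L", "beta_H_L", "alpha_H_L"),
                         cor_pairs = list(c("gamma_H_R", "gamma_H_L"),
                                          c("beta_H_R", "beta_H_L"),
                                          c("alpha_H_R", "alpha_H_L"))) {
  stopifnot(window_length >= 2)
  spec <- structure(list(window_length = as.integer(window_length),
                         mean_vars = mean_vars, sd_vars = sd_vars,
                         cor_pairs = cor_pairs),
                    class = "feature_spec")
  spec
}

#' Names of the features produced by a spec
#' @param spec a [feature_spec()].
#' @return character vector of feature names, in output order.
#' @export
feature_names <- function(spec = feature_spec()) {
  c(paste0("mean_", spec$mean_vars),
    paste0("sd_", spec$sd_vars),
    vapply(spec$cor_pairs, function(p)
      paste0("cor_", p[1], "__", p[2]), character(1)))
}

#' Majority-vote label of a window
#'
#' The true class of a window is the mode of its per-step labels (7 or more
#' of 13 steps under the defaults). A tie between classes is resolved
#' deterministically in favour of the class occurring earliest in the
#' window.
#'
#' @param classes character vector of per-step labels (one window).
#' @return single class label.
#' @export
window_label <- function(classes) {
  if (length(classes) == 0) stop("empty window", call. = FALSE)
  counts <- table(classes)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) return(top)
  top[which.min(match(top, classes))]
}

#' Feature vector of one window
#'
#' Means, sample (N-1) SDs and Pearson correlations as listed in the spec,
#' in fixed output order. A correlation whose pair includes a zero-variance
#' column within the window is reported as 0 (flagged via the
#' \code{degenerate_cor} attribute).
#'
#' @param slice \code{window_length} rows of a variable table.
#' @param spec a [feature_spec()].
#' @return named numeric vector of length 21 under the default spec.
#' @export
window_features <- function(slice, spec = feature_spec()) {
  x <- as.matrix(slice)
  if (nrow(x) != spec$window_length)
    stop("window must have exactly ", spec$window_length, " rows",
         call. = FALSE)
  if (!all(is.finite(x))) stop("missing values in window", call. = FALSE)
  mu <- colMeans(x[, spec$mean_vars, drop = FALSE])
  sds <- apply(x[, spec$sd_vars, drop = FALSE], 2, stats::sd)
  degenerate <- character(0)
  cors <- vapply(spec$cor_pairs, function(p) {
    a <- x[, p[1]]; b <- x[, p[2]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      degenerate <<- c(degenerate, paste(p, collapse = "__"))
      0
    } else stats::cor(a, b)
  }, numeric(1))
  out <- stats::setNames(c(mu, sds, cors), feature_names(spec))
  if (length(degenerate)) attr(out, "degenerate_cor") <- degenerate
  out
}

# rolling sums over windows of length w, aligned to the window start:
# result[i] = sum(x[i:(i+w-1)])
rolling_sum <- function(x, w) {
  cs <- cumsum(x)
  cs[w:length(x)] - c(0, cs)[1:(length(x) - w + 1)]
}

#' Sliding-window dataset from a labelled variable table
#'
#' Slides a stride-1 window of \code{window_length} steps over the table,
#' computing the feature vector and majority-vote true class of every
#' window: an N-row table yields N - window_length + 1 windows (N - 12
#' under the defaults). Feature columns are computed with vectorised
#' rolling sums and agree with [window_features()] to numerical tolerance.
#'
#' @param table variable table carrying a \code{labels} attribute (as
#'   produced by [assemble_variable_table()] on a labelled session), or
#'   supply \code{labels} explicitly.
#' @param spec a [feature_spec()].
#' @param labels optional per-row class labels overriding the attribute.
#' @return data frame with the feature columns of [feature_names()], a
#'   \code{class} factor column, and \code{window_start} (1-based row index
#'   of each window's first step).
#' @export
build_window_dataset <- function(table, spec = feature_spec(),
                                 labels = attr(table, "labels")) {
  if (is.null(labels))
    stop("per-step labels are required to build a window dataset",
         call. = FALSE)
  x <- as.matrix(table[, unique(c(spec$mean_vars, spec$sd_vars,
                                  unlist(spec$cor_pairs))), drop = FALSE])
  n <- nrow(x)
  w <- spec$window_length
  if (n < w) stop("table shorter than one window", call. = FALSE)
  if (length(labels) != n)
    stop("labels length does not match the table", call. = FALSE)
  nw <- n - w + 1L

  as_mat <- function(m, nms) matrix(m, nrow = nw,
                                    dimnames = list(NULL, nms))
  rs <- function(col) rolling_sum(x[, col], w)
  mu_all <- as_mat(vapply(colnames(x), rs, numeric(nw)), colnames(x))
  feat <- mu_all[, spec$mean_vars, drop = FALSE] / w
  colnames(feat) <- paste0("mean_", spec$mean_vars)

  sq <- function(col) rolling_sum(x[, col]^2, w)
  var_of <- function(col) {
    v <- (sq(col) - mu_all[, col]^2 / w) / (w - 1)
    pmax(v, 0)
  }
  sds <- as_mat(vapply(spec$sd_vars, function(col) sqrt(var_of(col)),
                       numeric(nw)),
                paste0("sd_", spec$sd_vars))

  cors <- vapply(spec$cor_pairs, function(p) {
    sxy <- rolling_sum(x[, p[1]] * x[, p[2]], w)
    cov <- (sxy - mu_all[, p[1]] * mu_all[, p[2]] / w) / (w - 1)
    den <- sqrt(var_of(p[1]) * var_of(p[2]))
    r <- ifelse(den > 0, cov / den, 0)
    pmin(pmax(r, -1), 1)
  }, numeric(nw))
  cors <- as_mat(cors, vapply(spec$cor_pairs, function(p)
    paste0("cor_", p[1], "__", p[2]), character(1)))

  lab_codes <- factor(labels)
  cls <- character(nw)
  # per-class rolling counts; ties resolved by earliest occurrence in window
  counts <- as_mat(vapply(levels(lab_codes), function(lv)
    rolling_sum(as.numeric(lab_codes == lv), w), numeric(nw)),
    levels(lab_codes))
  max_count <- apply(counts, 1, max)
  for (i in seq_len(nw)) {
    top <- levels(lab_codes)[counts[i, ] == max_count[i]]
    cls[i] <- if (length(top) == 1) top
              else window_label(labels[i:(i + w - 1)])
  }
  out <- data.frame(feat, sds, cors, check.names = FALSE)
  out$class <- factor(cls)
  out$window_start <- seq_len(nw)
  out
}

#' Write a window dataset to CSV
#' @param dataset result of [build_window_dataset()].
#' @param path CSV file path.
#' @export
write_window_dataset <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE)
  invisible(path)
}
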