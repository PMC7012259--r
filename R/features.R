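#' Feature matrix with subject labels
#'
#' Column-per-subject matrix of voxel features: `X` has M feature rows and N
#' subject columns, `labels` holds one class index in `0..C-1` per column.
#' An optional `feature_index_map` (n x 3 voxel coordinates, as produced by
#' [vectorize()]) records where each feature row sits in a reference volume.
#'
#' @param X numeric matrix, features in rows, subjects in columns.
#' @param labels integer class labels, one per column.
#' @param feature_index_map optional n x 3 voxel-coordinate matrix with one
#'   row per feature row of `X`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(X, labels, feature_index_map = NULL) {
  X <- as.matrix(X)
  if (ncol(X) != length(labels))
    stop("feature_matrix: one label per subject column required (",
         ncol(X), " columns, ", length(labels), " labels)", call. = FALSE)
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 0))
    stop("feature_matrix: labels must be nonnegative integers", call. = FALSE)
  if (!is.null(feature_index_map)) {
    feature_index_map <- as.matrix(feature_index_map)
    if (nrow(feature_index_map) != nrow(X))
      stop("feature_matrix: `feature_index_map` must have one row per feature",
           call. = FALSE)
  }
  structure(list(X = X, labels = labels, feature_index_map = feature_index_map),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$X), "features x", ncol(x$X), "subjects; classes:",
      paste(names(table(x$labels)), "=", table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Two-sample t-test feature screening
#'
#' Row-wise two-sample t-test between the two classes of a training feature
#' matrix; rows with two-sided p-value below `threshold` are retained. Used
#' only on training columns so that feature selection never sees test data.
#'
#' Degenerate rows: when the pooled variance is zero the t statistic is
#' undefined; a row with equal class means carries no signal and gets p = 1
#' (dropped), while a row with unequal means and zero variance separates the
#' classes perfectly and gets p = 0 (retained).
#'
#' @param train a [feature_matrix()] with exactly 2 classes, each with >= 2
#'   subjects.
#' @param threshold p-value cutoff (default 0.05).
#' @param welch if `TRUE` use the Welch (unequal-variance) statistic instead
#'   of the pooled-variance Student statistic.
#' @return An object of class `screen_result`: `selected` (sorted retained row
#'   indices), `pvalues`, `statistic`, `threshold`.
#' @export
ttest_screen <- function(train, threshold = 0.05, welch = FALSE) {
  stopifnot(inherits(train, "feature_matrix"))
  if (length(threshold) != 1L || !is.finite(threshold) || threshold < 0 ||
      threshold > 1)
    stop("ttest_screen: `threshold` must lie in [0, 1]", call. = FALSE)
  cls <- sort(unique(train$labels))
  if (length(cls) != 2L)
    stop("ttest_screen: exactly 2 classes required, got ", length(cls),
         call. = FALSE)
  i1 <- train$labels == cls[1]
  i2 <- train$labels == cls[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L)
    stop("ttest_screen: each class needs >= 2 training subjects (have ",
         n1, " and ", n2, ")", call. = FALSE)
  X1 <- train$X[, i1, drop = FALSE]
  X2 <- train$X[, i2, drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep.int(n1 + n2 - 2, length(se2))
  }
  tstat <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  zero_var <- se2 == 0
  p[zero_var & m1 == m2] <- 1
  p[zero_var & m1 != m2] <- 0
  structure(list(selected = which(p < threshold), pvalues = p,
                 statistic = tstat, threshold = threshold),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result:", length(x$selected), "of", length(x$pvalues),
      "features retained at p <", x$threshold, "\n")
  invisible(x)
}

#' Map screening p-values back into a volume
#'
#' Builds a biomarker map: a volume whose value at each selected feature's
#' voxel is `-log10(p)` and 0 elsewhere, for visualizing which voxels carry
#' class-related signal before vs after feature decomposition.
#'
#' @param screen a [ttest_screen()] result.
#' @param index_map n x 3 voxel-coordinate matrix mapping each screened
#'   feature row to its voxel (the `feature_index_map` of the screened
#'   [feature_matrix()]).
#' @param dim length-3 shape of the reference volume.
#' @param cap upper bound on `-log10(p)` (p = 0 maps to `cap`; default 16).
#' @return A [volume3d()].
#' @export
biomarker_map <- function(screen, index_map, dim, cap = 16) {
  stopifnot(inherits(screen, "screen_result"))
  if (is.null(index_map))
    stop("biomarker_map: a feature index map is required to place features in a volume",
         call. = FALSE)
  index_map <- as.matrix(index_map)
  if (nrow(index_map) != length(screen$pvalues))
    stop("biomarker_map: `index_map` must have one row per screened feature",
         call. = FALSE)
  a <- array(0, dim)
  if (length(screen$selected) > 0) {
    p <- screen$pvalues[screen$selected]
    a[index_map[screen$selected, , drop = FALSE]] <- pmin(-log10(p), cap)
  }
  volume3d(a)
}

#' Prepare a feature matrix from density volumes
#'
#' Smooth, downsample and vectorize a set of registered density volumes into
#' one column-per-subject feature matrix.
#'
#' @param volumes list of [volume3d()] of identical shape.
#' @param labels class label per volume.
#' @param smooth_sigma Gaussian smoothing sigma in voxels (`NULL` to skip).
#' @param downsample_factor integer block-mean downsampling factor (`NULL` or
#'   1 to skip).
#' @param mask optional logical array (at the post-downsampling shape).
#' @return A [feature_matrix()] carrying the voxel `feature_index_map`.
#' @export
prepare_features <- function(volumes, labels, smooth_sigma = 1,
                             downsample_factor = 4, mask = NULL) {
  if (length(volumes) == 0L)
    stop("prepare_features: no volumes given", call. = FALSE)
  cols <- vector("list", length(volumes))
  imap <- NULL
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    if (!is.null(smooth_sigma)) v <- smooth_volume(v, smooth_sigma)
    if (!is.null(downsample_factor) && downsample_factor > 1L)
      v <- downsample(v, downsample_factor)
    vec <- vectorize(v, mask)
    cols[[i]] <- vec$values
    if (is.null(imap)) imap <- vec$index_map
  }
  feature_matrix(do.call(cbind, cols), labels, feature_index_map = imap)
}
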