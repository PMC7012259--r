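#' Pipeline configuration
#'
#' Settings for the full screen -> decompose -> KDA -> nearest-neighbor
#' pipeline and its cross-validation harness.
#'
#' @param screen_threshold t-test p-value cutoff for training-only feature
#'   screening (1 keeps every testable feature).
#' @param decomp a [decomp_params()].
#' @param kernel a [kernel_spec()].
#' @param delta KDA ridge regularization (`NULL` = scale-aware default).
#' @param n_folds number of cross-validation folds (default 10).
#' @param cv_seed seed for the stratified fold assignment.
#' @param positive_class which label counts as "positive" (the disease /
#'   progressor group) for sensitivity, specificity and the AUC score.
#' @param decompose if `FALSE`, skip the dictionary decomposition and run KDA
#'   directly on the screened features (the ablation the decomposition is
#'   compared against).
#' @param test_tol,test_max_iter settings passed to [test_decompose()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(screen_threshold = 0.05,
                            decomp = decomp_params(),
                            kernel = kernel_spec(),
                            delta = NULL,
                            n_folds = 10L,
                            cv_seed = 1L,
                            positive_class = 1L,
                            decompose = TRUE,
                            test_tol = 1e-7,
                            test_max_iter = 2000L) {
  if (!is.finite(n_folds) || n_folds != round(n_folds) || n_folds < 2)
    stop("pipeline_config: `n_folds` must be an integer >= 2", call. = FALSE)
  stopifnot(inherits(decomp, "decomp_params"), inherits(kernel, "kernel_spec"))
  structure(list(screen_threshold = screen_threshold, decomp = decomp,
                 kernel = kernel, delta = delta, n_folds = as.integer(n_folds),
                 cv_seed = as.integer(cv_seed),
                 positive_class = as.integer(positive_class),
                 decompose = isTRUE(decompose),
                 test_tol = test_tol, test_max_iter = as.integer(test_max_iter)),
            class = "pipeline_config")
}

#' Fit the full classification pipeline
#'
#' Runs, in order and on the training subjects only: t-test feature
#' screening, dictionary decomposition of the screened features (unless
#' disabled), and spectral-regression KDA on the training class-specific
#' components (the columns of the learned dictionary A).
#'
#' @param train a [feature_matrix()] with 2 classes, each with >= 2 subjects.
#' @param config a [pipeline_config()].
#' @return An object of class `bd_pipeline` holding the screening result, the
#'   decomposition model (or `NULL` for the ablation) and the KDA model.
#' @export
pipeline_fit <- function(train, config = pipeline_config()) {
  stopifnot(inherits(train, "feature_matrix"), inherits(config, "pipeline_config"))
  cls <- sort(unique(train$labels))
  if (length(cls) != 2L)
    stop("pipeline_fit: exactly 2 training classes required, got ",
         length(cls), call. = FALSE)
  if (any(table(train$labels) < 2L))
    stop("pipeline_fit: every class needs >= 2 training subjects", call. = FALSE)

  screen <- tryCatch(ttest_screen(train, config$screen_threshold),
                     error = function(e) stop("pipeline_fit [screen]: ",
                                              conditionMessage(e), call. = FALSE))
  if (length(screen$selected) < 2L)
    stop("pipeline_fit [screen]: fewer than 2 features survive screening; ",
         "raise `screen_threshold`", call. = FALSE)
  Xs <- train$X[screen$selected, , drop = FALSE]

  dmodel <- NULL
  if (config$decompose) {
    dmodel <- tryCatch(train_decompose(Xs, config$decomp, labels = train$labels),
                       error = function(e) stop("pipeline_fit [decompose]: ",
                                                conditionMessage(e), call. = FALSE))
    comps <- dmodel$A
  } else {
    comps <- Xs
  }
  kda <- tryCatch(srkda_fit(comps, train$labels, config$kernel, config$delta),
                  error = function(e) stop("pipeline_fit [kda]: ",
                                           conditionMessage(e), call. = FALSE))
  structure(list(screen = screen, dmodel = dmodel, kda = kda,
                 config = config, n_features = nrow(train$X),
                 classes = cls), class = "bd_pipeline")
}

#' @export
print.bd_pipeline <- function(x, ...) {
  cat("bd_pipeline:", length(x$screen$selected), "of", x$n_features,
      "features after screening;",
      if (is.null(x$dmodel)) "no decomposition (ablation);"
      else "decomposition + ", "SRKDA + 1-NN\n")
  invisible(x)
}

#' Predict with a fitted pipeline
#'
#' Applies the training-fold screening mask, decomposes each test sample
#' against the fold's dictionaries, projects the class-specific component
#' into the discriminant space and classifies by nearest neighbor. The
#' continuous score is the nearest-negative-class distance minus the
#' nearest-positive-class distance in the embedding, so larger scores mean
#' more positive-like.
#'
#' @param fit a [pipeline_fit()] result.
#' @param newdata numeric matrix of test feature vectors (columns), in the
#'   training feature space, or a [feature_matrix()].
#' @return A list with `labels`, `scores`, `margin` and per-sample
#'   decomposition `converged` flags (all `TRUE` for the ablation).
#' @export
pipeline_predict <- function(fit, newdata) {
  stopifnot(inherits(fit, "bd_pipeline"))
  Y <- if (inherits(newdata, "feature_matrix")) newdata$X else as.matrix(newdata)
  if (ncol(Y) == 0L)
    return(list(labels = integer(0), scores = numeric(0), margin = numeric(0),
                converged = logical(0)))
  if (nrow(Y) != fit$n_features)
    stop("pipeline_predict: test vectors have ", nrow(Y),
         " features, training had ", fit$n_features, call. = FALSE)
  Ys <- Y[fit$screen$selected, , drop = FALSE]

  converged <- rep(TRUE, ncol(Ys))
  if (!is.null(fit$dmodel)) {
    comps <- matrix(0, nrow(Ys), ncol(Ys))
    for (i in seq_len(ncol(Ys))) {
      code <- test_decompose(Ys[, i], fit$dmodel, tol = fit$config$test_tol,
                             max_iter = fit$config$test_max_iter)
      converged[i] <- code$converged
      comps[, i] <- class_component(code, fit$dmodel)
    }
  } else {
    comps <- Ys
  }
  emb <- kda_project(fit$kda, comps)
  nn <- nn_classify(fit$kda, emb)
  pos <- fit$config$positive_class
  neg <- setdiff(fit$classes, pos)
  if (length(neg) != 1L || !(pos %in% fit$classes))
    stop("pipeline_predict: `positive_class` must be one of the 2 training classes",
         call. = FALSE)
  scores <- nn$class_dist[, as.character(neg)] -
    nn$class_dist[, as.character(pos)]
  list(labels = nn$labels, scores = unname(scores), margin = nn$margin,
       converged = converged)
}

# stratified fold assignment: per class, shuffle then deal round-robin
stratified_folds <- function(labels, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (l in unique(labels)) {
    idx <- which(labels == l)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Classification metrics
#'
#' Accuracy, sensitivity, specificity and AUC. `SEN = TP / (TP + FN)` over
#' the positive class, `SPE = TN / (TN + FP)` over the rest. AUC is the
#' rank-based (Mann-Whitney) statistic on `scores`, ties counting 1/2.
#' When only one class is present in `truth`, accuracy is still computed and
#' the other metrics are `NA`.
#'
#' @param truth true labels.
#' @param pred predicted labels.
#' @param scores continuous scores oriented so larger = more positive-like.
#' @param positive_class label counted as positive.
#' @return Named numeric vector `c(ACC, SEN, SPE, AUC)`, all in [0, 1].
#' @export
compute_metrics <- function(truth, pred, scores, positive_class = 1L) {
  if (length(truth) != length(pred) || length(truth) != length(scores))
    stop("compute_metrics: `truth`, `pred`, `scores` must have equal length",
         call. = FALSE)
  acc <- mean(truth == pred)
  is_pos <- truth == positive_class
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L)
    return(c(ACC = acc, SEN = NA_real_, SPE = NA_real_, AUC = NA_real_))
  sen <- sum(is_pos & pred == positive_class) / n_pos
  spe <- sum(!is_pos & pred != positive_class) / n_neg
  r <- rank(scores)                              # midranks: ties count 1/2
  auc <- (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  c(ACC = acc, SEN = sen, SPE = spe, AUC = auc)
}

#' Stratified k-fold cross-validation of the pipeline
#'
#' Splits the cohort into stratified folds (seeded shuffle, round-robin
#' assignment within each class), fits the entire pipeline from scratch on
#' each training fold - screening, decomposition and KDA all see training
#' subjects only - and evaluates on the held-out fold. Reports per-fold
#' metrics and pooled metrics over the concatenated held-out predictions.
#'
#' @param data a [feature_matrix()] with 2 classes.
#' @param config a [pipeline_config()]; `n_folds` must not exceed the
#'   smallest class size.
#' @return An object of class `cv_report`: `fold_assignments`, `per_fold`
#'   (data frame of ACC/SEN/SPE/AUC per fold), `pooled`, `predictions`
#'   (subject, fold, truth, predicted, score) and the `config` snapshot.
#' @export
run_cv <- function(data, config = pipeline_config()) {
  stopifnot(inherits(data, "feature_matrix"), inherits(config, "pipeline_config"))
  tab <- table(data$labels)
  if (length(tab) != 2L)
    stop("run_cv: exactly 2 classes required", call. = FALSE)
  if (config$n_folds > min(tab))
    stop("run_cv: n_folds (", config$n_folds,
         ") exceeds the smallest class size (", min(tab), ")", call. = FALSE)
  fold <- stratified_folds(data$labels, config$n_folds, config$cv_seed)

  N <- ncol(data$X)
  pred <- integer(N); score <- numeric(N)
  per_fold <- matrix(NA_real_, config$n_folds, 4,
                     dimnames = list(NULL, c("ACC", "SEN", "SPE", "AUC")))
  for (f in seq_len(config$n_folds)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    fit <- pipeline_fit(feature_matrix(data$X[, tr, drop = FALSE],
                                       data$labels[tr]), config)
    out <- pipeline_predict(fit, data$X[, te, drop = FALSE])
    pred[te] <- out$labels
    score[te] <- out$scores
    per_fold[f, ] <- compute_metrics(data$labels[te], out$labels, out$scores,
                                     config$positive_class)
  }
  pooled <- compute_metrics(data$labels, pred, score, config$positive_class)
  structure(list(
    fold_assignments = fold,
    per_fold = data.frame(fold = seq_len(config$n_folds), per_fold),
    pooled = pooled,
    predictions = data.frame(subject = seq_len(N), fold = fold,
                             truth = data$labels, predicted = pred,
                             score = score),
    config = config), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(x$config$n_folds, "-fold stratified cross-validation (",
      length(x$fold_assignments), " subjects)\n", sep = "")
  cat(sprintf("  pooled: ACC %.1f%%  SEN %.1f%%  SPE %.1f%%  AUC %.1f%%\n",
              100 * x$pooled["ACC"], 100 * x$pooled["SEN"],
              100 * x$pooled["SPE"], 100 * x$pooled["AUC"]))
  invisible(x)
}
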