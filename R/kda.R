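#' Kernel specification
#'
#' @param sigma Gaussian bandwidth (> 0), or `"median"` for the
#'   median-pairwise-distance heuristic resolved on the training points.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(sigma = "median") {
  if (is.character(sigma)) {
    if (!identical(sigma, "median"))
      stop("kernel_spec: `sigma` must be a positive number or \"median\"",
           call. = FALSE)
  } else if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("kernel_spec: `sigma` must be > 0", call. = FALSE)
  }
  structure(list(kind = "gaussian", sigma = sigma), class = "kernel_spec")
}

#' Resolve the kernel bandwidth
#'
#' A numeric `sigma` is returned as is; `"median"` returns the median of the
#' pairwise Euclidean distances over all distinct point pairs.
#'
#' @param P points matrix, one point per column.
#' @param spec a [kernel_spec()].
#' @return The bandwidth, a positive number.
#' @export
resolve_sigma <- function(P, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (is.numeric(spec$sigma)) return(spec$sigma)
  P <- as.matrix(P)
  if (ncol(P) < 2L)
    stop("resolve_sigma: median heuristic needs >= 2 points", call. = FALSE)
  m <- stats::median(stats::dist(t(P)))
  if (!is.finite(m) || m <= 0)
    stop("resolve_sigma: median pairwise distance is 0 (all points identical); ",
         "supply a numeric sigma", call. = FALSE)
  m
}

#' Gaussian kernel matrix
#'
#' Entry (i, j) is `exp(-||p_i - q_j||^2 / (2 sigma^2))` for column points
#' `p_i` of `P` and `q_j` of `Q`. With `Q` omitted the matrix is symmetric
#' with unit diagonal.
#'
#' @param P,Q points matrices (one point per column, shared row dimension).
#' @param sigma bandwidth > 0.
#' @return The `ncol(P) x ncol(Q)` kernel matrix.
#' @export
gaussian_kernel <- function(P, Q = NULL, sigma) {
  P <- as.matrix(P)
  same <- is.null(Q)
  Q <- if (same) P else as.matrix(Q)
  if (nrow(P) != nrow(Q))
    stop("gaussian_kernel: `P` and `Q` must share the feature dimension",
         call. = FALSE)
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("gaussian_kernel: `sigma` must be > 0", call. = FALSE)
  d2 <- outer(colSums(P^2), colSums(Q^2), "+") - 2 * crossprod(P, Q)
  d2 <- pmax(d2, 0)
  K <- exp(-d2 / (2 * sigma^2))
  if (same) {
    K <- (K + t(K)) / 2
    diag(K) <- 1
  }
  K
}

# class-graph matrix: W_ij = 1/N_l iff i and j share class l
class_graph <- function(labels) {
  N <- length(labels)
  W <- matrix(0, N, N)
  for (l in unique(labels)) {
    idx <- which(labels == l)
    W[idx, idx] <- 1 / length(idx)
  }
  W
}

#' Fit kernel discriminant analysis in spectral-regression form
#'
#' Maximizes the regularized kernel discriminant Rayleigh quotient
#' `(a' KWK a) / (a' (KK + delta K) a)`, where `K` is the training Gaussian
#' kernel matrix and `W` the class-graph matrix (`W_ij = 1/N_l` iff subjects
#' i, j share class l). The solver exploits the spectral-regression
#' structure of the pencil: every eigenvector's response `c = (K + delta I) a`
#' lies in the span of the class indicators, so the C candidate responses are
#' obtained exactly from a C x C reduced eigenproblem and each coefficient
#' vector by one ridge solve `(K + delta I) a = c`. The direction whose
#' response is most aligned with the all-ones vector is the non-discriminant
#' (constant) solution and is dropped; the remaining C - 1 directions embed
#' the training set via `f_i = sum_j a_j K(x_j, x_i)`.
#'
#' @param components training class-specific components, one subject per
#'   column.
#' @param labels training class labels (>= 2 classes, each nonempty).
#' @param kernel a [kernel_spec()].
#' @param delta ridge regularization (>= 0); default `0.01 * trace(K) / N`.
#' @return An object of class `kda_model`: resolved `sigma`, `delta`,
#'   `train_points`, `K`, `W`, `labels`, `coeffs` (N x (C-1)),
#'   `embedded_train` (N x (C-1)), `quotients` (achieved Rayleigh quotient of
#'   each kept direction), and `quotient_max` (the optimum over all C
#'   computed directions, equal to the pencil's top generalized eigenvalue).
#' @export
srkda_fit <- function(components, labels, kernel = kernel_spec(), delta = NULL) {
  P <- as.matrix(components)
  labels <- as.integer(labels)
  N <- ncol(P)
  if (length(labels) != N)
    stop("srkda_fit: one label per component column required", call. = FALSE)
  cls <- sort(unique(labels))
  C <- length(cls)
  if (C < 2L)
    stop("srkda_fit: at least 2 classes required", call. = FALSE)
  sigma <- resolve_sigma(P, kernel)
  K <- gaussian_kernel(P, sigma = sigma)
  if (is.null(delta)) delta <- 0.01 * sum(diag(K)) / N
  if (!is.finite(delta) || delta < 0)
    stop("srkda_fit: `delta` must be >= 0", call. = FALSE)
  W <- class_graph(labels)

  Kreg <- K + delta * diag(N)
  ind <- sapply(cls, function(l) as.numeric(labels == l))   # N x C indicators
  MI <- tryCatch(solve(Kreg, ind), error = function(e)
    stop("srkda_fit: (K + delta I) is singular; increase `delta`",
         call. = FALSE))
  KMI <- K %*% MI                                           # M %*% 1_l columns
  # reduced problem T a = lambda a on the indicator span:
  # T[j, l] = class-j mean of K (K + delta I)^{-1} 1_l
  Tm <- matrix(0, C, C)
  for (j in seq_len(C))
    Tm[j, ] <- colMeans(KMI[labels == cls[j], , drop = FALSE])
  ev <- eigen(Tm)
  a_red <- Re(ev$vectors)
  # fix eigenvector sign so embeddings are reproducible across equivalent fits
  for (k in seq_len(C)) {
    i <- which.max(abs(a_red[, k]))
    if (a_red[i, k] < 0) a_red[, k] <- -a_red[, k]
  }

  A_num <- K %*% W %*% K
  B_den <- K %*% K + delta * K
  quot <- numeric(C)
  coeffs <- matrix(0, N, C)
  ones_align <- numeric(C)
  for (k in seq_len(C)) {
    cvec <- ind %*% a_red[, k]
    alpha <- solve(Kreg, cvec)
    coeffs[, k] <- alpha
    den <- drop(crossprod(alpha, B_den %*% alpha))
    quot[k] <- if (den > 0) drop(crossprod(alpha, A_num %*% alpha)) / den else 0
    ones_align[k] <- abs(sum(cvec)) / (sqrt(sum(cvec^2)) * sqrt(N))
  }
  trivial <- which.max(ones_align)
  keep <- setdiff(seq_len(C), trivial)
  keep <- keep[order(quot[keep], decreasing = TRUE)]

  structure(list(
    kernel = kernel, sigma = sigma, delta = delta,
    train_points = P, K = K, W = W, labels = labels, classes = cls,
    coeffs = coeffs[, keep, drop = FALSE],
    embedded_train = K %*% coeffs[, keep, drop = FALSE],
    quotients = quot[keep], quotient_max = max(quot),
    quotients_all = quot), class = "kda_model")
}

#' @export
print.kda_model <- function(x, ...) {
  cat("kda_model:", ncol(x$train_points), "training subjects,",
      length(x$classes), "classes; sigma =", signif(x$sigma, 4),
      ", delta =", signif(x$delta, 4), "\n")
  cat("  discriminant Rayleigh quotient(s):",
      paste(signif(x$quotients, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Project class-specific components into the discriminant space
#'
#' Applies the kernel projective function `f(x) = sum_i a_i K(x_i, x)` of the
#' fitted model to new points. Projecting the training points reproduces the
#' stored training embedding.
#'
#' @param model a [srkda_fit()] model.
#' @param components points to project, one per column (same feature
#'   dimension as the training components).
#' @return Matrix of embedded points, one row per test point, one column per
#'   discriminant direction.
#' @export
kda_project <- function(model, components) {
  stopifnot(inherits(model, "kda_model"))
  P <- as.matrix(components)
  if (nrow(P) != nrow(model$train_points))
    stop("kda_project: components have ", nrow(P), " features, model expects ",
         nrow(model$train_points), call. = FALSE)
  if (ncol(P) == 0L)
    return(matrix(0, 0, ncol(model$coeffs)))
  Kx <- gaussian_kernel(model$train_points, P, sigma = model$sigma)
  t(Kx) %*% model$coeffs
}

# max generalized eigenvalue (and eigenvector) of (A_S, B_S) on a support
support_eig <- function(A, B, S) {
  As <- A[S, S, drop = FALSE]
  Bs <- B[S, S, drop = FALSE]
  out <- tryCatch({
    ev <- eigen(solve(Bs, As))
    i <- which.max(Re(ev$values))
    list(lambda = Re(ev$values[i]), vec = Re(ev$vectors[, i]))
  }, error = function(e) NULL)
  out
}

#' Cardinality-constrained sparse kernel discriminant direction
#'
#' Maximizes the Rayleigh quotient `(a' KWK a) / (a' KK a)` over coefficient
#' vectors with exactly `k` nonzeros. The optimum over a fixed support equals
#' the top generalized eigenvalue of the corresponding principal submatrices,
#' so the search is over supports: `"greedy"` runs forward selection (adding
#' the index that maximizes the support's top generalized eigenvalue) followed
#' by one backward-elimination/replacement sweep; `"exact"` enumerates all
#' size-`k` supports (only for N <= 20). Supports with a computationally
#' singular denominator submatrix are skipped.
#'
#' @param K training kernel matrix (N x N).
#' @param W class-graph matrix (N x N).
#' @param k cardinality, 1 <= k <= N.
#' @param mode `"greedy"` or `"exact"`.
#' @return An object of class `sparse_kda_result`: `support` (sorted index
#'   set of size `k`), `coeffs_on_support`, `quotient`.
#' @export
sparse_kda <- function(K, W, k, mode = c("greedy", "exact")) {
  mode <- match.arg(mode)
  N <- nrow(K)
  if (length(k) != 1L || !is.finite(k) || k != round(k) || k < 1 || k > N)
    stop("sparse_kda: `k` must lie in 1..N = ", N, call. = FALSE)
  k <- as.integer(k)
  A <- K %*% W %*% K
  B <- K %*% K
  skipped <- 0L

  eval_support <- function(S) {
    e <- support_eig(A, B, S)
    if (is.null(e)) { skipped <<- skipped + 1L; return(-Inf) }
    e$lambda
  }

  if (mode == "exact") {
    if (N > 20L)
      stop("sparse_kda: exact mode only for N <= 20", call. = FALSE)
    supports <- utils::combn(N, k, simplify = FALSE)
    vals <- vapply(supports, eval_support, numeric(1))
    best <- supports[[which.max(vals)]]
  } else {
    S <- integer(0)
    for (step in seq_len(k)) {
      cand <- setdiff(seq_len(N), S)
      vals <- vapply(cand, function(j) eval_support(c(S, j)), numeric(1))
      S <- c(S, cand[which.max(vals)])
    }
    # one backward sweep: try replacing each member with the best outsider
    if (k < N) {
      for (i in seq_len(k)) {
        cur <- eval_support(S)
        cand <- setdiff(seq_len(N), S)
        for (j in cand) {
          Snew <- c(S[-i], j)
          if (eval_support(Snew) > cur) {
            S <- Snew
            cur <- eval_support(S)
          }
        }
      }
    }
    best <- S
  }
  best <- sort(best)
  e <- support_eig(A, B, best)
  if (is.null(e))
    stop("sparse_kda: denominator submatrix singular on the chosen support",
         call. = FALSE)
  structure(list(support = best, coeffs_on_support = e$vec,
                 quotient = e$lambda, skipped_supports = skipped),
            class = "sparse_kda_result")
}

#' Nearest-neighbor classification in the discriminant space
#'
#' 1-nearest-neighbor by Euclidean distance between embedded test points and
#' the embedded training set. Exact distance ties are broken toward the
#' lowest training index. The margin score for each test point is the
#' distance to the nearest training point of any other class minus the
#' distance to the nearest point of the predicted class; per-class nearest
#' distances are also returned so a caller can orient a continuous score by
#' its positive class.
#'
#' @param model a [srkda_fit()] model.
#' @param embedded_test matrix of embedded test points (rows), as returned by
#'   [kda_project()].
#' @return A list with `labels` (predicted), `margin`, and `class_dist`
#'   (n_test x C matrix of nearest-neighbor distance per class, columns named
#'   by class).
#' @export
nn_classify <- function(model, embedded_test) {
  stopifnot(inherits(model, "kda_model"))
  Et <- as.matrix(embedded_test)
  Tr <- as.matrix(model$embedded_train)
  if (nrow(Et) == 0L) {
    cd <- matrix(0, 0, length(model$classes),
                 dimnames = list(NULL, model$classes))
    return(list(labels = integer(0), margin = numeric(0), class_dist = cd))
  }
  if (ncol(Et) != ncol(Tr))
    stop("nn_classify: embedding dimension mismatch", call. = FALSE)
  d2 <- outer(rowSums(Et^2), rowSums(Tr^2), "+") - 2 * Et %*% t(Tr)
  D <- sqrt(pmax(d2, 0))
  nn_idx <- apply(D, 1L, which.min)            # first minimum = lowest index
  pred <- model$labels[nn_idx]
  class_dist <- sapply(model$classes, function(l)
    apply(D[, model$labels == l, drop = FALSE], 1L, min))
  class_dist <- matrix(class_dist, nrow = nrow(Et),
                       dimnames = list(NULL, model$classes))
  dist_same <- class_dist[cbind(seq_len(nrow(Et)),
                                match(pred, model$classes))]
  dist_other <- vapply(seq_len(nrow(Et)), function(i)
    min(class_dist[i, model$classes != pred[i]]), numeric(1))
  list(labels = pred, margin = dist_other - dist_same, class_dist = class_dist)
}
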