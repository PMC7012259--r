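#' Elementwise soft thresholding
#'
#' Proximal operator of the L1 norm: `sign(x) * pmax(abs(x) - t, 0)`.
#'
#' @param x numeric scalar, vector or matrix.
#' @param t threshold, a single value >= 0.
#' @return Object of the same shape as `x`.
#' @export
soft_threshold <- function(x, t) {
  if (length(t) != 1L || !is.finite(t) || t < 0)
    stop("soft_threshold: `t` must be a single value >= 0", call. = FALSE)
  sign(x) * pmax(abs(x) - t, 0)
}

#' Singular value thresholding
#'
#' Proximal operator of the nuclear norm: given any SVD `U S V'` of `M`,
#' returns `U max(S - t, 0) V'`.
#'
#' @param M numeric matrix with finite entries.
#' @param t threshold, a single value >= 0.
#' @return Matrix of the same shape with singular values shrunk by `t`.
#' @export
svt <- function(M, t) {
  if (length(t) != 1L || !is.finite(t) || t < 0)
    stop("svt: `t` must be a single value >= 0", call. = FALSE)
  if (any(!is.finite(M)))
    stop("svt: `M` must have finite entries", call. = FALSE)
  s <- svd(M)
  keep <- pmax(s$d - t, 0)
  s$u %*% (keep * t(s$v))
}

#' Decomposition solver parameters
#'
#' Balance and solver settings for the regularized dictionary decomposition
#' `min ||A||* + mu ||B||* + gamma ||beta||_F^2 + tau ||E||_1` subject to
#' `X = A + B beta + E`, solved by inexact augmented Lagrange multipliers.
#'
#' `tau = NULL` resolves to `1/sqrt(max(M, N))` at fit time (the usual L1
#' weight for nuclear + L1 programs); `n_atoms = NULL` resolves to
#' `min(M, N)`; `rho_init = NULL` resolves to `1/||X||_2`.
#'
#' @param mu weight on the nuclear norm of the confound dictionary B.
#' @param gamma weight on the squared Frobenius norm of the codes beta.
#' @param tau weight on the L1 norm of the sparse error E.
#' @param n_atoms number of columns d of B.
#' @param rho_init initial ALM penalty.
#' @param rho_scale penalty growth factor (> 1).
#' @param rho_max penalty cap.
#' @param tol relative constraint-residual stopping tolerance.
#' @param max_iter outer iteration cap.
#' @param seed seed for the (optional) random initialization.
#' @param init `"svd"` (deterministic warm start) or `"random"`.
#' @return An object of class `decomp_params`.
#' @export
decomp_params <- function(mu = 1, gamma = 1, tau = NULL, n_atoms = NULL,
                          rho_init = NULL, rho_scale = 1.2, rho_max = 1e7,
                          tol = 1e-7, max_iter = 500L, seed = 1L,
                          init = c("svd", "random")) {
  init <- match.arg(init)
  for (nm in c("mu", "gamma")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0)
      stop("decomp_params: `", nm, "` must be > 0", call. = FALSE)
  }
  if (!is.null(tau) && (!is.finite(tau) || tau <= 0))
    stop("decomp_params: `tau` must be > 0", call. = FALSE)
  if (!is.finite(rho_scale) || rho_scale <= 1)
    stop("decomp_params: `rho_scale` must be > 1", call. = FALSE)
  if (!is.finite(tol) || tol <= 0)
    stop("decomp_params: `tol` must be > 0", call. = FALSE)
  structure(list(mu = mu, gamma = gamma, tau = tau, n_atoms = n_atoms,
                 rho_init = rho_init, rho_scale = rho_scale, rho_max = rho_max,
                 tol = tol, max_iter = as.integer(max_iter),
                 seed = as.integer(seed), init = init),
            class = "decomp_params")
}

#' Objective of the training decomposition
#'
#' Evaluates `||A||* + mu ||B||* + gamma ||beta||_F^2 + tau ||E||_1` for any
#' candidate decomposition, e.g. the planted ground truth of a synthetic
#' cohort.
#'
#' @param A,B,beta,E candidate components.
#' @param mu,gamma,tau balance parameters.
#' @return The objective value.
#' @export
decomp_objective <- function(A, B, beta, E, mu = 1, gamma = 1, tau = 1) {
  sum(svd(A, nu = 0, nv = 0)$d) + mu * sum(svd(B, nu = 0, nv = 0)$d) +
    gamma * sum(beta^2) + tau * sum(abs(E))
}

#' Learn class-specific and confound dictionaries from training features
#'
#' Decomposes the training matrix `X` (features x subjects) as
#' `X = A + B beta + E`, where `A` is the class-specific dictionary (one
#' column per training subject, inheriting that subject's label, since the
#' training codes over A are fixed to the identity), `B beta` is the
#' non-class-specific low-rank confound term and `E` is a sparse error.
#' Solves `min ||A||* + mu ||B||* + gamma ||beta||_F^2 + tau ||E||_1`
#' subject to the exact decomposition constraint by inexact ALM: one proximal
#' pass per variable per outer iteration (SVT for A; a linearized SVT step
#' for B with beta fixed; a closed-form ridge solve for beta; soft
#' thresholding for E), then a multiplier update `Y <- Y + rho R` and penalty
#' growth `rho <- min(rho * rho_scale, rho_max)`.
#'
#' `B` starts from the leading `n_atoms` left singular vectors of `X` scaled
#' by their singular values and `beta` from the corresponding least-squares
#' codes, so the solve is deterministic; `init = "random"` uses the seed
#' instead.
#'
#' @param X a [feature_matrix()] or a plain numeric matrix (features x
#'   subjects).
#' @param params a [decomp_params()].
#' @param labels training labels, required when `X` is a plain matrix.
#' @return An object of class `decomp_model` with elements `A`, `B`,
#'   `beta_train`, `E`, `labels`, resolved `params`, per-iteration `history`
#'   (objective and relative constraint residual), `residual` and `converged`.
#'   Non-convergence within `max_iter` is flagged, not an error.
#' @export
train_decompose <- function(X, params = decomp_params(), labels = NULL) {
  if (inherits(X, "feature_matrix")) {
    labels <- X$labels
    X <- X$X
  }
  X <- as.matrix(X)
  if (any(is.na(X)) || any(!is.finite(X)))
    stop("train_decompose: `X` contains NA or non-finite entries", call. = FALSE)
  if (ncol(X) < 2L)
    stop("train_decompose: need at least 2 training subjects", call. = FALSE)
  stopifnot(inherits(params, "decomp_params"))
  M <- nrow(X); N <- ncol(X)
  d <- if (is.null(params$n_atoms)) min(M, N) else as.integer(params$n_atoms)
  if (d < 1L || d > M)
    stop("train_decompose: `n_atoms` must lie in 1..M", call. = FALSE)
  tau <- if (is.null(params$tau)) 1 / sqrt(max(M, N)) else params$tau
  mu <- params$mu; gamma <- params$gamma
  nX <- norm(X, "F")

  if (nX == 0) {                               # trivially feasible minimum
    params$tau <- tau; params$n_atoms <- d
    return(structure(list(
      A = matrix(0, M, N), B = matrix(0, M, d), beta_train = matrix(0, d, N),
      E = matrix(0, M, N), labels = labels, params = params,
      history = data.frame(iter = 0L, objective = 0, residual = 0),
      residual = 0, converged = TRUE), class = "decomp_model"))
  }

  if (params$init == "random") {
    set.seed(params$seed)
    B <- matrix(stats::rnorm(M * d), M) / sqrt(M)
  } else {
    s0 <- svd(X, nu = d, nv = 0)
    B <- s0$u %*% diag(s0$d[seq_len(d)], d)
  }
  beta <- tryCatch(qr.solve(B, X), error = function(e) matrix(0, d, N))
  A <- matrix(0, M, N)
  E <- matrix(0, M, N)
  Y <- matrix(0, M, N)
  sig1 <- svd(X, nu = 0, nv = 0)$d[1]
  rho <- if (is.null(params$rho_init)) 1 / sig1 else params$rho_init
  hist_obj <- numeric(params$max_iter)
  hist_res <- numeric(params$max_iter)
  res <- Inf
  it <- 0L
  while (it < params$max_iter) {
    it <- it + 1L
    Bb <- B %*% beta
    A <- svt(X - Bb - E + Y / rho, 1 / rho)
    E <- soft_threshold(X - A - Bb + Y / rho, tau / rho)
    G <- X - A - E + Y / rho
    beta <- solve(rho * crossprod(B) + 2 * gamma * diag(d),
                  rho * crossprod(B, G))
    Lb <- max(svd(beta, nu = 0, nv = 0)$d)^2
    Lb <- max(Lb, 1e-12)
    B <- svt(B + (G - B %*% beta) %*% t(beta) / Lb, mu / (rho * Lb))
    R <- X - A - B %*% beta - E
    res <- norm(R, "F") / nX
    hist_res[it] <- res
    hist_obj[it] <- decomp_objective(A, B, beta, E, mu, gamma, tau)
    if (res <= params$tol) break
    Y <- Y + rho * R
    rho <- min(rho * params$rho_scale, params$rho_max)
  }
  params$tau <- tau; params$n_atoms <- d
  structure(list(
    A = A, B = B, beta_train = beta, E = E, labels = labels, params = params,
    history = data.frame(iter = seq_len(it), objective = hist_obj[seq_len(it)],
                         residual = hist_res[seq_len(it)]),
    residual = res, converged = res <= params$tol),
    class = "decomp_model")
}

#' @export
print.decomp_model <- function(x, ...) {
  cat("decomp_model:", nrow(x$A), "features,", ncol(x$A), "training subjects,",
      ncol(x$B), "confound atoms\n")
  cat(sprintf("  relative residual %.3g after %d iterations (%s)\n",
              x$residual, nrow(x$history),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Decompose a test sample against learned dictionaries
#'
#' Solves `min ||alpha||_1 + gamma ||beta||_2^2 + tau ||eps||_1` subject to
#' `y = A alpha + B beta + eps` by ALM with alternating proximal steps:
#' linearized soft-thresholding sweeps for the sparse code `alpha`, a
#' closed-form ridge solve for the confound code `beta`, soft thresholding
#' for the sparse residual `eps`, then multiplier and penalty updates.
#' `gamma` and `tau` are taken from the fitted model.
#'
#' @param y numeric feature vector of length `nrow(model$A)`.
#' @param model a fitted [train_decompose()] model.
#' @param tol relative residual stopping tolerance.
#' @param max_iter outer iteration cap.
#' @param rho_scale penalty growth factor per outer iteration.
#' @param inner number of linearized proximal sweeps on `alpha` per outer
#'   iteration.
#' @return An object of class `test_code` with `alpha`, `beta`, `eps`, the
#'   achieved `objective`, per-iteration objective `history`, the final
#'   relative `residual` and a `converged` flag.
#' @export
test_decompose <- function(y, model, tol = 1e-9, max_iter = 4000L,
                           rho_scale = 1.05, inner = 10L) {
  stopifnot(inherits(model, "decomp_model"))
  y <- as.numeric(y)
  M <- nrow(model$A)
  if (length(y) != M)
    stop("test_decompose: `y` has length ", length(y), ", expected ", M,
         call. = FALSE)
  A <- model$A; B <- model$B
  gamma <- model$params$gamma; tau <- model$params$tau
  N <- ncol(A); d <- ncol(B)
  ny <- max(sqrt(sum(y^2)), 1)

  if (all(y == 0)) {
    return(structure(list(alpha = numeric(N), beta = numeric(d),
                          eps = numeric(M), objective = 0,
                          history = numeric(0), residual = 0,
                          converged = TRUE), class = "test_code"))
  }

  al <- numeric(N); be <- numeric(d); ep <- numeric(M); lam <- numeric(M)
  LA <- max(svd(A, nu = 0, nv = 0)$d)^2
  LA <- max(LA, 1e-12)
  BtB <- crossprod(B)
  rho <- 1 / ny
  rho_max <- 1e8
  hist_obj <- numeric(max_iter)
  res <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    r <- y - B %*% be - ep + lam / rho
    for (k in seq_len(inner))
      al <- soft_threshold(al + crossprod(A, r - A %*% al) / LA, 1 / (rho * LA))
    be <- solve(rho * BtB + 2 * gamma * diag(d),
                rho * crossprod(B, y - A %*% al - ep + lam / rho))
    ep <- soft_threshold(y - A %*% al - B %*% be + lam / rho, tau / rho)
    R <- y - A %*% al - drop(B %*% be) - ep
    res <- sqrt(sum(R^2)) / ny
    hist_obj[it] <- sum(abs(al)) + gamma * sum(be^2) + tau * sum(abs(ep))
    if (res <= tol && it > 20L) break
    lam <- lam + rho * drop(R)
    rho <- min(rho * rho_scale, rho_max)
  }
  structure(list(alpha = drop(al), beta = drop(be), eps = drop(ep),
                 objective = hist_obj[it], history = hist_obj[seq_len(it)],
                 residual = res, converged = res <= tol),
            class = "test_code")
}

#' Class-specific component of a sample
#'
#' Reconstruction `A alpha` of a test sample from the class-specific
#' dictionary only, i.e. the part of the sample carrying label-related
#' structure that the classifier consumes. For training subjects the
#' class-specific component is the corresponding column of `A`.
#'
#' @param code a [test_decompose()] result.
#' @param model the fitted [train_decompose()] model.
#' @return Numeric feature vector of length `nrow(model$A)`.
#' @export
class_component <- function(code, model) {
  stopifnot(inherits(code, "test_code"), inherits(model, "decomp_model"))
  drop(model$A %*% code$alpha)
}

#' Save / load a fitted model archive
#'
#' Serializes a fitted decomposition model, KDA model or full pipeline to a
#' single archive with a versioned schema.
#'
#' @param model object to save.
#' @param path archive path.
#' @return `path` invisibly for `save_model`; the restored object for
#'   `load_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(list(schema_version = 1L, package = "braindecomp",
               class = class(model)[1], model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  arch <- readRDS(path)
  if (!is.list(arch) || is.null(arch$schema_version))
    stop("load_model: not a braindecomp model archive", call. = FALSE)
  if (arch$schema_version != 1L)
    stop("load_model: unsupported schema version ", arch$schema_version,
         call. = FALSE)
  arch$model
}
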