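test_that("proximal operators match their definitional oracles", {
  expect_equal(soft_threshold(1.5, 1), 0.5)
  expect_equal(soft_threshold(-0.3, 1), 0)
  expect_equal(soft_threshold(-2.0, 0.5), -1.5)
  expect_error(soft_threshold(1, -0.1), ">= 0")

  expect_equal(svt(diag(c(3, 1)), 2), diag(c(1, 0)))
  expect_equal(svt(matrix(0, 3, 4), 5), matrix(0, 3, 4))
  expect_error(svt(matrix(c(1, NA, 1, 1), 2), 1), "finite")

  set.seed(30)
  for (i in 1:50) {
    x <- matrix(rnorm(20), 5)
    t <- runif(1, 0, 2)
    expect_lt(max(abs(soft_threshold(x, t) - sign(x) * pmax(abs(x) - t, 0))), 1e-12)
    Mx <- matrix(rnorm(20), 5, 4)
    s <- svd(Mx)
    want <- s$u %*% diag(pmax(s$d - t, 0)) %*% t(s$v)
    expect_lt(max(abs(svt(Mx, t) - want)), 1e-8)
    # singular values of the result are the shrunken spectrum
    expect_equal(svd(svt(Mx, t))$d, pmax(s$d - t, 0), tolerance = 1e-8)
  }
})

test_that("the zero matrix decomposes to the trivial feasible minimum", {
  m <- train_decompose(matrix(0, 6, 4), decomp_params(), labels = c(0, 0, 1, 1))
  expect_true(m$converged)
  expect_equal(m$A, matrix(0, 6, 4))
  expect_equal(m$B %*% m$beta_train, matrix(0, 6, 4))
  expect_equal(m$E, matrix(0, 6, 4))
  expect_equal(decomp_objective(m$A, m$B, m$beta_train, m$E), 0)
})

test_that("training ALM reaches feasibility and beats the planted objective", {
  for (seed in 1:4) {
    coh <- tiny_cohort(seed, dim = 60, n = c(10, 10))
    X <- coh$features$X
    m <- train_decompose(X, decomp_params())
    expect_true(m$converged)
    expect_lte(norm(X - m$A - m$B %*% m$beta_train - m$E, "F") / norm(X, "F"),
               m$params$tol)
    o_fit <- decomp_objective(m$A, m$B, m$beta_train, m$E,
                              tau = m$params$tau)
    o_planted <- planted_objective(coh, tau = m$params$tau)
    expect_lte(o_fit, o_planted)
    # class dictionary never exceeds the numerical rank of the input
    nrank <- function(Z) { d <- svd(Z, nu = 0, nv = 0)$d; sum(d > 1e-6 * d[1]) }
    expect_lte(nrank(m$A), nrank(X))
  }
})

test_that("label metadata rides along on the class dictionary columns", {
  coh <- tiny_cohort(3, dim = 30, n = c(5, 5))
  m <- train_decompose(coh$features, decomp_params())
  expect_identical(m$labels, coh$features$labels)
  expect_identical(ncol(m$A), length(m$labels))
})

test_that("decomposition is scale-equivariant when gamma is scaled with the data", {
  coh <- tiny_cohort(6, dim = 40, n = c(6, 6))
  X <- coh$features$X
  c_scale <- 3.7
  m1 <- train_decompose(X, decomp_params(gamma = 1))
  m2 <- train_decompose(c_scale * X, decomp_params(gamma = c_scale,
                                                   tau = m1$params$tau))
  expect_equal(m2$A, c_scale * m1$A, tolerance = 1e-7)
  expect_equal(m2$E, c_scale * m1$E, tolerance = 1e-7)
  expect_equal(m2$B %*% m2$beta_train, c_scale * m1$B %*% m1$beta_train,
               tolerance = 1e-7)
})

test_that("sparse corruption lands in E on its planted support", {
  coh <- tiny_cohort(8, dim = 60, n = c(10, 10), sparsity = 0.05,
                     sparse_scale = 5)
  m <- train_decompose(coh$features$X, decomp_params())
  planted <- which(coh$truth_sparse != 0)
  top <- order(abs(m$E), decreasing = TRUE)[seq_along(planted)]
  expect_gte(mean(top %in% planted), 0.9)
})

test_that("malformed decomposition inputs are rejected", {
  expect_error(train_decompose(matrix(c(1, NA, 2, 3), 2), decomp_params()), "NA")
  expect_error(train_decompose(matrix(1, 5, 1), decomp_params()), "2 training")
  expect_error(decomp_params(mu = -1), "mu")
  expect_error(decomp_params(rho_scale = 0.9), "rho_scale")
  expect_error(decomp_params(tol = 0), "tol")
})

test_that("the zero test vector yields the zero code", {
  m <- train_decompose(tiny_cohort(2, dim = 20, n = c(4, 4))$features$X,
                       decomp_params())
  code <- test_decompose(rep(0, 20), m)
  expect_true(code$converged)
  expect_equal(code$alpha, rep(0, 8))
  expect_equal(code$objective, 0)
  expect_equal(class_component(code, m), rep(0, 20))
})

test_that("a dictionary column is explained for at most unit cost", {
  # with gamma and tau large, alpha = e_j is the cheap feasible explanation
  m <- train_decompose(tiny_cohort(4, dim = 25, n = c(5, 5))$features$X,
                       decomp_params())
  m$params$gamma <- 1e4
  m$params$tau <- 1e4
  for (j in c(1L, 6L)) {
    code <- test_decompose(m$A[, j], m)
    expect_true(code$converged)
    expect_lte(code$objective, 1 + 1e-6)
  }
})

test_that("the test code objective is non-increasing after multiplier warm-up", {
  m <- train_decompose(tiny_cohort(5, dim = 30, n = c(5, 5))$features$X,
                       decomp_params())
  code <- test_decompose(m$A[, 2] + 0.1 * rnorm(30), m)
  h <- code$history
  # warm-up ends once the multipliers enforce near-feasibility; by the second
  # half of the run the objective must only decrease
  warm <- seq(ceiling(length(h) / 2), length(h))
  expect_true(all(diff(h[warm]) <= 1e-8 * max(1, h[warm[1]])))
})

test_that("test decomposition reaches the convex optimum on small instances", {
  skip_if_not_installed("pracma")
  qp_oracle <- function(y, A, B, gamma, tau) {
    M <- length(y); N <- ncol(A); d <- ncol(B)
    n <- 2 * N + d + 2 * M
    H <- diag(1e-9, n)
    H[2 * N + (1:d), 2 * N + (1:d)] <- diag(2 * gamma, d)
    f <- c(rep(1, 2 * N), rep(0, d), rep(tau, 2 * M))
    Aeq <- cbind(A, -A, B, diag(M), -diag(M))
    lb <- c(rep(0, 2 * N), rep(-1e4, d), rep(0, 2 * M))
    pracma::quadprog(H, f, Aeq = Aeq, beq = y, lb = lb, ub = rep(1e4, n))$fval
  }
  set.seed(31)
  for (rep in 1:3) {
    M <- 15; N <- 6; d <- 4
    A <- matrix(rnorm(M * N), M); B <- matrix(rnorm(M * d), M)
    y <- drop(A %*% rnorm(N) * 0.5 + B %*% rnorm(d) * 0.5 +
                soft_threshold(rnorm(M), 1.2))
    model <- structure(list(A = A, B = B,
                            params = list(gamma = 1, tau = 0.5)),
                       class = "decomp_model")
    code <- test_decompose(y, model)
    opt <- qp_oracle(y, A, B, 1, 0.5)
    expect_lte((code$objective - opt) / max(abs(opt), 1e-12), 1e-3)
  }
})

test_that("class components track the planted class signal, not the confound", {
  coh <- tiny_cohort(12, dim = 60, n = c(10, 10), effect = 4, noise_sd = 0.1)
  m <- train_decompose(coh$features$X, decomp_params())
  cors_cls <- cors_cf <- numeric(0)
  for (j in c(1L, 5L, 15L)) {
    code <- test_decompose(coh$features$X[, j], m, tol = 1e-7, max_iter = 2000)
    comp <- class_component(code, m)
    cors_cls <- c(cors_cls, cor(comp, coh$truth_class_component[, j]))
    cors_cf <- c(cors_cf, cor(comp, coh$truth_confound_component[, j]))
  }
  expect_gt(mean(cors_cls), mean(cors_cf))
})

test_that("dimension mismatches and model archives are handled", {
  m <- train_decompose(tiny_cohort(1, dim = 20, n = c(4, 4))$features$X,
                       decomp_params())
  expect_error(test_decompose(rep(0, 19), m), "length 19")

  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$A, m$A)
  saveRDS(1:3, f)
  expect_error(load_model(f), "archive")
})
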