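test_that("the Gaussian kernel matches its formula and limits", {
  expect_equal(gaussian_kernel(matrix(0), matrix(1), sigma = 1)[1, 1],
               exp(-0.5))
  p <- matrix(rnorm(3))
  expect_equal(gaussian_kernel(p, p, sigma = 2)[1, 1], 1)
  set.seed(40)
  P <- matrix(rnorm(12), 3)
  expect_true(all(abs(gaussian_kernel(P, sigma = 1e9) - 1) < 1e-6))
  expect_error(gaussian_kernel(matrix(1, 2, 2), matrix(1, 3, 2), sigma = 1),
               "feature dimension")
  expect_error(gaussian_kernel(P, sigma = 0), "sigma")
})

test_that("training kernels are valid (symmetric, unit diagonal, PSD)", {
  set.seed(41)
  for (i in 1:50) {
    P <- matrix(rnorm(4 * sample(3:10, 1)), 4)
    K <- gaussian_kernel(P, sigma = runif(1, 0.3, 3))
    expect_identical(K, t(K))
    expect_equal(unname(diag(K)), rep(1, ncol(P)))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("bandwidth resolution honors fixed values and the median heuristic", {
  expect_equal(resolve_sigma(matrix(rnorm(6), 2), kernel_spec(2.5)), 2.5)
  P <- matrix(c(0, 1, 3), 1)    # pairwise distances 1, 2, 3
  expect_equal(resolve_sigma(P, kernel_spec("median")), 2)
  set.seed(42)
  P <- matrix(rnorm(100), 2)
  want <- median(as.vector(dist(t(P))))
  expect_equal(resolve_sigma(P, kernel_spec("median")), want)
  expect_error(resolve_sigma(matrix(1, 2, 3), kernel_spec("median")),
               "identical")
  expect_error(kernel_spec(-1), "sigma")
})

test_that("SRKDA separates well-separated classes in the embedding", {
  P <- matrix(c(0, 0.1, -0.1, 10, 10.1, 9.9), 1)
  lab <- rep(0:1, each = 3)
  m <- srkda_fit(P, lab, kernel_spec("median"), delta = 1e-6)
  f <- drop(m$embedded_train)
  expect_true(max(f[lab == 0]) < min(f[lab == 1]) ||
              min(f[lab == 0]) > max(f[lab == 1]))
})

test_that("the achieved Rayleigh quotient equals the dense pencil optimum", {
  set.seed(43)
  for (delta in c(1e-6, 1e-3)) {
    for (rep in 1:10) {
      n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
      P <- cbind(matrix(rnorm(3 * n1), 3), matrix(rnorm(3 * n2), 3) + 1.5)
      lab <- rep(0:1, c(n1, n2))
      m <- srkda_fit(P, lab, kernel_spec("median"), delta = delta)
      A <- m$K %*% m$W %*% m$K
      B <- m$K %*% m$K + delta * m$K
      lam <- max(Re(eigen(solve(B, A), only.values = TRUE)$values))
      expect_equal(m$quotient_max, lam, tolerance = 1e-6)
      # the kept discriminant direction achieves its reported quotient
      a <- m$coeffs[, 1]
      q <- drop(crossprod(a, A %*% a) / crossprod(a, B %*% a))
      expect_equal(q, m$quotients[1], tolerance = 1e-10)
    }
  }
})

test_that("duplicating every training point leaves the embedding values fixed", {
  set.seed(44)
  P <- cbind(matrix(rnorm(8), 2), matrix(rnorm(8), 2) + 2)
  lab <- rep(0:1, each = 4)
  m1 <- srkda_fit(P, lab, kernel_spec(1), delta = 1e-6)
  idx <- rep(seq_len(8), each = 2)
  m2 <- srkda_fit(P[, idx], lab[idx], kernel_spec(1), delta = 1e-6)
  e1 <- sort(drop(m1$embedded_train))
  e2all <- sort(drop(m2$embedded_train))       # 16 values in 8 near-equal pairs
  odd <- seq(1, 15, by = 2)
  expect_lt(max(abs(e2all[odd] - e2all[odd + 1])), 1e-6)  # duplicates coincide
  # the regularized embedding shifts by O(delta * cond(K)) under duplication
  expect_lt(max(abs(e1 - (e2all[odd] + e2all[odd + 1]) / 2)), 1e-5)
})

test_that("SRKDA preconditions produce informative errors", {
  P <- matrix(rnorm(10), 2)
  expect_error(srkda_fit(P, rep(0, 5)), "2 classes")
  expect_error(srkda_fit(P, rep(0:1, c(2, 3)), delta = -1), "delta")
  expect_error(srkda_fit(P, rep(0:1, c(2, 2))), "one label per")
})

test_that("projection applies the kernel projective function exactly", {
  set.seed(45)
  P <- cbind(matrix(rnorm(6), 2), matrix(rnorm(4), 2) + 3)
  lab <- c(0, 0, 0, 1, 1)
  m <- srkda_fit(P, lab, kernel_spec(1.3), delta = 1e-4)
  # projecting the training points reproduces the stored embedding
  expect_lt(max(abs(kda_project(m, P) - m$embedded_train)), 1e-8)
  # direct summation oracle on a 5-training-point model
  Q <- matrix(rnorm(6), 2)
  got <- kda_project(m, Q)
  for (t in 1:3) {
    want <- sum(sapply(1:5, function(i)
      m$coeffs[i, 1] * exp(-sum((P[, i] - Q[, t])^2) / (2 * 1.3^2))))
    expect_equal(got[t, 1], want, tolerance = 1e-10)
  }
  expect_error(kda_project(m, matrix(1, 3, 2)), "features")
})

test_that("subject order does not change predictions", {
  set.seed(46)
  P <- cbind(matrix(rnorm(20), 2), matrix(rnorm(20), 2) + 2)
  lab <- rep(0:1, each = 10)
  Q <- matrix(rnorm(10), 2) + 1
  m <- srkda_fit(P, lab, kernel_spec(1), delta = 1e-3)
  pred <- nn_classify(m, kda_project(m, Q))$labels
  perm <- sample(20)
  m2 <- srkda_fit(P[, perm], lab[perm], kernel_spec(1), delta = 1e-3)
  pred2 <- nn_classify(m2, kda_project(m2, Q))$labels
  expect_identical(pred, pred2)
})

test_that("sparse KDA honors its cardinality and bound properties", {
  set.seed(47)
  P <- cbind(matrix(rnorm(8), 2), matrix(rnorm(8), 2) + 1)
  lab <- rep(0:1, each = 4)
  m <- srkda_fit(P, lab, kernel_spec(1), delta = 1e-3)
  K <- m$K; W <- m$W
  N <- 8

  # k = 1: both modes return the best single index
  diag_quot <- diag(K %*% W %*% K) / diag(K %*% K)
  for (mode in c("greedy", "exact")) {
    r1 <- sparse_kda(K, W, 1, mode)
    expect_identical(r1$support, which.max(diag_quot))
    expect_equal(r1$quotient, max(diag_quot), tolerance = 1e-10)
  }

  # k = N: constraint vacuous, equals the unconstrained pencil optimum
  rN <- sparse_kda(K, W, N, "greedy")
  lam <- max(Re(eigen(solve(K %*% K, K %*% W %*% K),
                      only.values = TRUE)$values))
  expect_equal(rN$quotient, lam, tolerance = 1e-8)
  expect_length(rN$support, N)

  # greedy never beats exhaustive enumeration, and the support has size k
  for (k in 2:3) {
    rg <- sparse_kda(K, W, k, "greedy")
    re <- sparse_kda(K, W, k, "exact")
    expect_length(rg$support, k)
    expect_lte(rg$quotient, re$quotient + 1e-9)
    # reported quotient is the top generalized eigenvalue on the support
    As <- (K %*% W %*% K)[re$support, re$support]
    Bs <- (K %*% K)[re$support, re$support]
    expect_equal(re$quotient,
                 max(Re(eigen(solve(Bs, As), only.values = TRUE)$values)),
                 tolerance = 1e-8)
  }
  expect_error(sparse_kda(K, W, 0), "1..N")
  expect_error(sparse_kda(K, W, 9), "1..N")
})

test_that("nearest-neighbor classification, ties and margins behave", {
  # 1D embedding built by hand through a trivial model object
  m <- structure(list(
    embedded_train = matrix(c(-1, 1), 2, 1), labels = c(0L, 1L),
    classes = c(0L, 1L), train_points = matrix(c(-1, 1), 1)),
    class = "kda_model")
  # exact tie: lowest training index (label 0) wins
  out <- nn_classify(m, matrix(0, 1, 1))
  expect_identical(out$labels, 0L)
  expect_equal(out$margin, 0)
  # empty test set
  out0 <- nn_classify(m, matrix(0, 0, 1))
  expect_length(out0$labels, 0L)

  # well-separated blobs classify perfectly
  set.seed(48)
  P <- cbind(matrix(rnorm(40, sd = 0.5), 2), matrix(rnorm(40, sd = 0.5), 2) + 10)
  lab <- rep(0:1, each = 20)
  mod <- srkda_fit(P, lab, kernel_spec("median"))
  Q <- cbind(matrix(rnorm(50, sd = 0.5), 2), matrix(rnorm(50, sd = 0.5), 2) + 10)
  truth <- rep(0:1, each = 25)
  pred <- nn_classify(mod, kda_project(mod, Q))
  expect_identical(pred$labels, truth)
  expect_true(all(pred$margin > 0))
})
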