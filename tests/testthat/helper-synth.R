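# shared fixtures, built in code

# small noiseless cohort whose planted triple is exactly feasible
tiny_cohort <- function(seed = 1, dim = 60, n = c(10, 10), effect = 3,
                        sparsity = 0.05, noise_sd = 0, ...) {
  generate_cohort(synth_spec(n_per_class = n, dim = dim, rank_class = 2,
                             rank_confound = 3, sparsity = sparsity,
                             effect = effect, noise_sd = noise_sd,
                             seed = seed, ...))
}

# objective of the planted ground-truth triple, using the SVD factorization
# of the confound as the feasible (B, beta) pair
planted_objective <- function(cohort, mu = 1, gamma = 1, tau = 1) {
  cf <- cohort$truth_confound_component
  sv <- svd(cf)
  r <- sum(sv$d > 1e-9 * max(sv$d, 1e-300))
  Bt <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
  bt <- t(sv$v[, seq_len(r), drop = FALSE])
  decomp_objective(cohort$truth_class_component, Bt, bt, cohort$truth_sparse,
                   mu = mu, gamma = gamma, tau = tau)
}

# random labeled feature matrix (no structure)
random_fm <- function(seed, M = 20, n = c(5, 5)) {
  set.seed(seed)
  feature_matrix(matrix(rnorm(M * sum(n)), M), rep(seq_along(n) - 1L, n))
}
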