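#' Specification of a synthetic cohort
#'
#' Describes a cohort of synthetic subjects whose feature matrix follows the
#' additive model the decomposition stage assumes: a low-rank class-specific
#' component (shared within-class loadings plus class-mean offsets), a
#' low-rank class-independent confound shared by all subjects, sparse
#' large-amplitude corruption, and optional dense Gaussian noise.
#'
#' Default group sizes are the four diagnostic groups of a typical
#' AD / pMCI / sMCI / NC morphometry cohort (198/167/236/229, 830 subjects
#' total); tests and examples use far smaller cohorts.
#'
#' @param n_per_class integer vector, subjects per class (length C >= 2).
#' @param dim feature dimension M (number of voxel features per subject).
#' @param rank_class rank of the planted within-class low-rank structure.
#' @param rank_confound rank of the planted shared confound.
#' @param sparsity fraction of entries corrupted by the sparse error, in [0, 1).
#' @param effect between-class mean separation on signal features, in units of
#'   the within-class standard deviation.
#' @param noise_sd standard deviation of dense Gaussian noise (0 allowed).
#' @param seed integer RNG seed; identical specs generate bitwise-identical
#'   cohorts.
#' @param confound_sd per-entry standard deviation of the confound component.
#' @param sparse_scale multiplier on the sparse-corruption amplitude (base
#'   amplitude is +/- U(1,2) times the within-class feature scale).
#' @param signal_frac fraction of features carrying the class-mean offset
#'   (the "signal voxels"); the remaining features are confound/noise only.
#' @return An object of class `synth_spec`.
#' @seealso [generate_cohort()]
#' @export
synth_spec <- function(n_per_class = c(AD = 198L, pMCI = 167L, sMCI = 236L, NC = 229L),
                       dim = 1000L,
                       rank_class = 2L,
                       rank_confound = 3L,
                       sparsity = 0.05,
                       effect = 3,
                       noise_sd = 0.1,
                       seed = 1L,
                       confound_sd = 1,
                       sparse_scale = 1,
                       signal_frac = 0.25) {
  check_count <- function(x, name) {
    if (length(x) == 0L || any(!is.finite(x)) || any(x != round(x)) || any(x <= 0))
      stop("synth_spec: `", name, "` must be positive integer(s), got ",
           paste(x, collapse = ","), call. = FALSE)
  }
  check_count(n_per_class, "n_per_class")
  if (length(n_per_class) < 2L)
    stop("synth_spec: `n_per_class` must list at least 2 classes", call. = FALSE)
  check_count(dim, "dim")
  check_count(rank_class, "rank_class")
  check_count(rank_confound, "rank_confound")
  if (rank_class + rank_confound > min(dim, sum(n_per_class)))
    stop("synth_spec: rank_class + rank_confound must be <= min(dim, total n) = ",
         min(dim, sum(n_per_class)), call. = FALSE)
  if (!is.finite(sparsity) || sparsity < 0 || sparsity >= 1)
    stop("synth_spec: `sparsity` must lie in [0, 1)", call. = FALSE)
  if (!is.finite(effect) || effect < 0)
    stop("synth_spec: `effect` must be >= 0", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("synth_spec: `noise_sd` must be >= 0", call. = FALSE)
  if (!is.finite(confound_sd) || confound_sd < 0)
    stop("synth_spec: `confound_sd` must be >= 0", call. = FALSE)
  if (!is.finite(signal_frac) || signal_frac <= 0 || signal_frac > 1)
    stop("synth_spec: `signal_frac` must lie in (0, 1]", call. = FALSE)
  structure(list(
    n_per_class = as.integer(n_per_class), dim = as.integer(dim),
    rank_class = as.integer(rank_class), rank_confound = as.integer(rank_confound),
    sparsity = sparsity, effect = effect, noise_sd = noise_sd,
    seed = as.integer(seed), confound_sd = confound_sd,
    sparse_scale = sparse_scale, signal_frac = signal_frac
  ), class = "synth_spec")
}

#' Generate a synthetic cohort
#'
#' Draws a feature matrix `X = class + confound + sparse + noise` realizing
#' the additive representation the decomposition model assumes, together with
#' the planted ground-truth components.
#'
#' The class component uses `rank_class` loading directions shared across
#' classes (subject scores are i.i.d. standard normal) plus class-mean offsets
#' confined to the first `ceiling(signal_frac * dim)` features, scaled so that
#' adjacent classes are separated by `effect` within-class standard deviations
#' on those features; its rank is therefore at most `rank_class + C - 1`.
#' The confound loads on all features with per-entry standard deviation
#' `confound_sd`. Sparse corruption has uniformly random support and
#' amplitudes `+/- U(1,2) * sparse_scale` times the within-class scale.
#'
#' @param spec a [synth_spec()].
#' @return An object of class `synth_cohort`: a list with `features` (a
#'   [feature_matrix()] with labels `0..C-1` in class blocks),
#'   `truth_class_component`, `truth_confound_component`, `truth_sparse`
#'   (matrices of the planted components), `signal_rows` (indices of features
#'   carrying the class-mean offset) and `spec`.
#' @examples
#' coh <- generate_cohort(synth_spec(n_per_class = c(5, 5), dim = 50,
#'                                   rank_class = 2, rank_confound = 3,
#'                                   sparsity = 0.05, effect = 3, seed = 1))
#' dim(coh$features$X)   # 50 x 10
#' table(coh$features$labels)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "synth_spec"))
    stop("generate_cohort: `spec` must be a synth_spec object", call. = FALSE)
  set.seed(spec$seed)
  M <- spec$dim
  n <- spec$n_per_class
  C <- length(n)
  N <- sum(n)
  labels <- rep.int(seq_len(C) - 1L, n)

  # within-class feature scale: shared loadings (unit variance) + confound + noise
  s_w <- sqrt(1 + spec$confound_sd^2 + spec$noise_sd^2)

  U <- matrix(stats::rnorm(M * spec$rank_class), M)
  Z <- matrix(stats::rnorm(spec$rank_class * N), spec$rank_class)
  cls <- U %*% Z / sqrt(spec$rank_class)
  n_sig <- ceiling(spec$signal_frac * M)
  signal_rows <- seq_len(n_sig)
  offset_dir <- numeric(M)
  offset_dir[signal_rows] <- 1
  class_codes <- (seq_len(C) - 1L) - (C - 1) / 2   # centered, adjacent gap 1
  cls <- cls + outer(offset_dir * spec$effect * s_w, class_codes[labels + 1L])

  V <- matrix(stats::rnorm(M * spec$rank_confound), M)
  Zc <- matrix(stats::rnorm(spec$rank_confound * N), spec$rank_confound)
  cf <- V %*% Zc * spec$confound_sd / sqrt(spec$rank_confound)

  S <- matrix(0, M, N)
  if (spec$sparsity > 0) {
    supp <- which(matrix(stats::runif(M * N), M) < spec$sparsity)
    if (length(supp) > 0)
      S[supp] <- sample(c(-1, 1), length(supp), replace = TRUE) *
        stats::runif(length(supp), 1, 2) * spec$sparse_scale * s_w
  }

  X <- cls + cf + S
  if (spec$noise_sd > 0)
    X <- X + matrix(stats::rnorm(M * N, sd = spec$noise_sd), M)

  structure(list(
    features = feature_matrix(X, labels),
    truth_class_component = cls,
    truth_confound_component = cf,
    truth_sparse = S,
    signal_rows = signal_rows,
    spec = spec
  ), class = "synth_cohort")
}

#' Generate a synthetic 3D density volume
#'
#' Test fixtures for the volume-preparation stage: a constant volume, a unit
#' impulse at the central voxel, or a random block pattern (constant values on
#' 4x4x4 blocks, so that factor-4 downsampling has a closed-form result).
#' Voxel values are nonnegative, as densities are.
#'
#' @param side voxels per axis (>= 4 and divisible by 4 for `"blocks"`).
#' @param pattern one of `"constant"`, `"impulse"`, `"blocks"`.
#' @param value the constant value for `"constant"` (default 1).
#' @param seed RNG seed used by `"blocks"`.
#' @return A [volume3d()] with unit voxel size.
#' @export
generate_volume <- function(side, pattern = c("blocks", "constant", "impulse"),
                            value = 1, seed = 1L) {
  pattern <- match.arg(pattern)
  if (length(side) != 1L || !is.finite(side) || side != round(side) || side <= 0)
    stop("generate_volume: `side` must be a positive integer", call. = FALSE)
  side <- as.integer(side)
  vals <- switch(pattern,
    constant = array(value, c(side, side, side)),
    impulse = {
      a <- array(0, c(side, side, side))
      ctr <- side %/% 2L + 1L
      a[ctr, ctr, ctr] <- 1
      a
    },
    blocks = {
      if (side < 4L || side %% 4L != 0L)
        stop("generate_volume: `side` must be >= 4 and divisible by 4 for blocks",
             call. = FALSE)
      set.seed(seed)
      nb <- side %/% 4L
      b <- array(stats::runif(nb^3), c(nb, nb, nb))
      b[rep(seq_len(nb), each = 4L), rep(seq_len(nb), each = 4L),
        rep(seq_len(nb), each = 4L)]
    })
  volume3d(vals)
}

#' Write a synthetic cohort to a directory
#'
#' Writes the feature matrix and planted truth components as tab-delimited
#' matrix files and the labels as a CSV (`subject_id,label`).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "synth_cohort"))
    stop("write_cohort: `cohort` must be a synth_cohort", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wm <- function(m, f)
    utils::write.table(m, file.path(dir, f), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  wm(cohort$features$X, "features.tsv")
  wm(cohort$truth_class_component, "truth_class.tsv")
  wm(cohort$truth_confound_component, "truth_confound.tsv")
  wm(cohort$truth_sparse, "truth_sparse.tsv")
  utils::write.csv(
    data.frame(subject_id = seq_along(cohort$features$labels),
               label = cohort$features$labels),
    file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$features$X), "features x",
      ncol(x$features$X), "subjects in", length(x$spec$n_per_class),
      "classes\n")
  cat("  planted ranks: class <=", x$spec$rank_class + length(x$spec$n_per_class) - 1L,
      ", confound <=", x$spec$rank_confound,
      "; sparsity", x$spec$sparsity, "\n")
  invisible(x)
}
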