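#' Generate a synthetic cross-over trial dataset under the null
#'
#' Seeded generator of trial-like data emulating a small randomized
#' placebo-controlled 2x2 cross-over study with four visits per period:
#' overdispersed, serially correlated count outcomes (blister counts) and
#' ordinal 0-10 scores on a half-point grid (VAS for pain/pruritus).  The
#' generator builds a *null* dataset -- no treatment, period or carry-over
#' effect -- so that rejection rates of any test applied to its output (or to
#' block permutations of it) estimate type-I error; treatment effects are
#' added afterwards with [inject_effect()].
#'
#' Mechanism: each subject carries a mean-one log-normal frailty
#' (`exp(u - sigma_u^2/2)`, `u ~ N(0, sigma_u^2)`) for between-subject
#' heterogeneity; within each subject-period a latent standard-normal AR(1)
#' path over the four visits (lag-1 correlation `rho`) is pushed through a
#' Gaussian copula onto negative-binomial count margins with mean
#' `lambda0 * frailty` and size `nb_size`; a second AR(1) path is mapped
#' affinely to the VAS scale and rounded to the half-point grid (clamped to
#' [0, 10]), so ties arise naturally.  With `sigma_u = 0`, `rho = 0` and
#' `nb_size = Inf` the counts are i.i.d. Poisson(`lambda0`).
#'
#' @param n_subjects Number of subjects (default 15, the motivating trial).
#' @param sequence_split Integer pair: subjects on the placebo-first ("PV")
#'   and verum-first ("VP") sequence; must sum to `n_subjects` (default 8/7).
#' @param lambda0 Baseline count mean (> 0, default 7).
#' @param sigma_u Between-subject heterogeneity SD on the log scale
#'   (default 0.5).
#' @param rho Lag-1 serial correlation of the latent paths, in [0, 1)
#'   (default 0.6).
#' @param nb_size Negative-binomial size (dispersion) parameter; `Inf` gives
#'   Poisson margins (default 4).
#' @param vas_mean,vas_sd Mean and SD of the latent Gaussian mapped to the
#'   VAS grid (defaults 5 and 2).
#' @param seed Integer seed; the same seed reproduces the dataset
#'   bit-for-bit.  `NULL` uses (and advances) the current RNG state.
#' @return A validated [as_trial_data()] tibble with `count` and `vas`
#'   outcomes.
#' @export
#' @examples
#' d <- generate_trial(seed = 42)
#' dplyr::count(d, sequence, treatment)
generate_trial <- function(n_subjects = 15, sequence_split = c(8, 7),
                           lambda0 = 7, sigma_u = 0.5, rho = 0.6,
                           nb_size = 4, vas_mean = 5, vas_sd = 2,
                           seed = NULL) {
  stopifnot(length(sequence_split) == 2, all(sequence_split >= 0))
  if (sum(sequence_split) != n_subjects) {
    stop("n_subjects must equal sum(sequence_split)", call. = FALSE)
  }
  stopifnot(lambda0 > 0, sigma_u >= 0, rho >= 0, rho < 1,
            nb_size > 0, vas_sd >= 0)

  with_seed(seed, {
    ids <- sprintf("S%03d", seq_len(n_subjects))
    seqs <- rep(c("PV", "VP"), times = sequence_split)
    n_blocks <- 2L * n_subjects

    frailty <- exp(stats::rnorm(n_subjects, 0, sigma_u) - sigma_u^2 / 2)
    z_count <- .ar1_paths(n_blocks, 4L, rho)  # one row per (subject, period)
    z_vas <- .ar1_paths(n_blocks, 4L, rho)

    mu <- lambda0 * rep(frailty, each = 2L)   # block order: subject x period
    u <- stats::pnorm(z_count)
    counts <- if (is.finite(nb_size)) {
      stats::qnbinom(u, size = nb_size, mu = rep(mu, each = 4L))
    } else {
      stats::qpois(u, lambda = rep(mu, each = 4L))
    }
    vas <- pmin(10, pmax(0, round(2 * (vas_mean + vas_sd * z_vas)) / 2))

    sequence <- rep(seqs, each = 8L)
    period <- rep(rep(1:2, each = 4L), times = n_subjects)
    out <- tibble::tibble(
      subject_id = rep(ids, each = 8L),
      sequence = sequence,
      period = period,
      treatment = ifelse((sequence == "PV") == (period == 1),
                         "placebo", "verum"),
      time = rep(1:4, times = n_blocks),
      count = as.integer(counts),
      vas = as.double(vas)
    )
    as_trial_data(out)
  })
}

# latent AR(1) paths with standard-normal margins, flattened row-major
# (values of one path are consecutive)
.ar1_paths <- function(n_paths, len, rho) {
  eps <- matrix(stats::rnorm(n_paths * len), n_paths, len)
  z <- eps
  for (t in seq_len(len - 1)) {
    z[, t + 1] <- rho * z[, t] + sqrt(1 - rho^2) * eps[, t + 1]
  }
  as.vector(t(z))
}

#' Pooled lag-1 correlation within subject-period blocks
#'
#' Diagnostic for the serial dependence the generator (and the real data it
#' emulates) carries within each block of four repeated measurements: the
#' Pearson correlation of all within-block lag-1 pairs, pooled over blocks.
#'
#' @param data A trial data frame.
#' @param outcome Outcome column to assess.
#' @return A scalar correlation estimate.
#' @export
lag1_block_correlation <- function(data, outcome = c("count", "vas", "binary")) {
  outcome <- match.arg(outcome)
  blocks <- period_blocks(data, outcome)
  if (nrow(blocks) < 2) stop("need at least 2 blocks", call. = FALSE)
  m <- as.matrix(blocks[c("t1", "t2", "t3", "t4")])
  x <- as.vector(m[, 1:3])
  y <- as.vector(m[, 2:4])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("lag-1 correlation undefined for a constant outcome", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so seeded helpers do not perturb an enclosing simulation stream.
#' With `seed = NULL` the code simply uses (and advances) the current state.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# derive a stream of replicate seeds from one master seed, all < 2^31
.spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}
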