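#' Specification for a synthetic clinical-table simulation
#'
#' Describes a class-conditional Gaussian dataset shaped like the
#' breast-cancer tables: `n` records, `d` continuous features, a binary
#' label, block-diagonal feature correlation (so the field-ordering
#' optimizer has recoverable structure) and optional missing cells.
#'
#' Informative features have class means separated by `separation`
#' standard deviations; the remaining features are pure noise.
#'
#' @param n number of records (at least 4).
#' @param d number of features (at least 2).
#' @param separation standardized mean difference between classes on each
#'   informative feature.
#' @param informative_fraction proportion of features carrying class
#'   signal (first `ceiling(informative_fraction * d)` features).
#' @param block_correlation within-block feature correlation in `[0, 1)`.
#' @param n_blocks number of equal-size correlation blocks (at most `d`).
#' @param class_ratio expected proportion of benign (label 1) records.
#' @param missing_rate proportion of cells replaced by missing markers.
#' @param seed integer seed; the draw is fully deterministic given it.
#' @export
sim_spec <- function(n = 400L, d = 10L, separation = 1,
                     informative_fraction = 0.5, block_correlation = 0,
                     n_blocks = 1L, class_ratio = 0.5, missing_rate = 0,
                     seed = 1L) {
  n <- as.integer(n); d <- as.integer(d); n_blocks <- as.integer(n_blocks)
  stopifnot(n >= 4L, d >= 2L, separation >= 0,
            informative_fraction >= 0, informative_fraction <= 1,
            block_correlation >= 0, block_correlation < 1,
            class_ratio > 0, class_ratio < 1,
            missing_rate >= 0, missing_rate < 1)
  if (n_blocks > d) stop("n_blocks may not exceed d")
  structure(list(n = n, d = d, separation = separation,
                 informative_fraction = informative_fraction,
                 block_correlation = block_correlation, n_blocks = n_blocks,
                 class_ratio = class_ratio, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# Equal-size block assignment; any remainder goes to the last block.
block_assignment <- function(d, n_blocks) {
  size <- d %/% n_blocks
  blocks <- rep(seq_len(n_blocks), each = size)
  c(blocks, rep(n_blocks, d - length(blocks)))
}

#' Simulate a tabular binary-class dataset
#'
#' Features are drawn class-conditionally from multivariate normal
#' distributions with unit variances and block-diagonal correlation;
#' informative features carry class means of `+/- separation / 2`.
#' Labels are Bernoulli with the configured benign proportion.  Missing
#' cells (if any) are inserted uniformly at random and flagged in the
#' mask, mirroring the `"?"` marker semantics of the clinical files.
#'
#' @param spec a [sim_spec()].
#' @return a [tabular_dataset()].
#' @examples
#' ds <- simulate_tabular(sim_spec(n = 50, d = 6, separation = 2, seed = 7))
#' ds
#' @export
simulate_tabular <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(spec$seed)
  d <- spec$d; n <- spec$n
  blocks <- block_assignment(d, spec$n_blocks)
  sigma <- outer(blocks, blocks, function(a, b)
    ifelse(a == b, spec$block_correlation, 0))
  diag(sigma) <- 1
  cl <- chol(sigma)
  z <- matrix(stats::rnorm(n * d), n, d) %*% cl
  labels <- as.integer(stats::runif(n) < spec$class_ratio)
  n_inf <- ceiling(spec$informative_fraction * d)
  if (n_inf > 0L && spec$separation > 0) {
    shift <- ifelse(labels == 1L, spec$separation / 2, -spec$separation / 2)
    z[, seq_len(n_inf)] <- z[, seq_len(n_inf)] + shift
  }
  mask <- matrix(FALSE, n, d)
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(n * d) < spec$missing_rate, n, d)
    z[mask] <- NA_real_
  }
  tabular_dataset(z, labels,
                  field_names = paste0("feat", sprintf("%02d", seq_len(d))),
                  missing_mask = mask)
}

#' Random rank instance with a recorded exhaustive optimum
#'
#' Generates a random symmetric closeness-score matrix, ranks it exactly
#' as [covariance_rank_matrix()] would, and records the brute-force
#' optimal ordering — a self-verifying fixture for regression-testing the
#' genetic-algorithm search.
#'
#' @param d number of fields, between 3 and 8.
#' @param seed integer seed.
#' @return list with `rank_matrix`, `optimum` (a [field_ordering()]) and
#'   `identity_cost`.
#' @export
known_rank_instance <- function(d, seed = 1L) {
  d <- as.integer(d)
  if (d < 3L || d > 8L) stop("d must be between 3 and 8")
  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(as.integer(seed))
  s <- matrix(stats::runif(d * d), d, d)
  s <- (s + t(s)) / 2
  rm <- rank_matrix_from_scores(abs(s), derivation = s)
  opt <- brute_force_order(rm)
  list(rank_matrix = rm, optimum = opt,
       identity_cost = path_cost(seq_len(d), rm))
}
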