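# Synthetic grouped splicing counts with known ground truth.
#
# The generator states a two-condition single-cell experiment: per-event
# mean logit-PSI profiles, per-cell logit-PSI drawn Gaussian around them
# with unit variance, an equal random split of cells into two conditions,
# a random subset of events made truly differential by shifting
# condition-2 cells by +/- eta on the logit scale (one sign per event),
# and grouped counts drawn from the multinomial observation model at
# given per-(cell, event) total depths. Counts are sampled directly from
# the model's observation layer rather than via a read-level simulator,
# since alignment is out of scope here.

#' Simulation configuration
#'
#' Defaults state the benchmark design: 130 cells, 2248 skipped-exon
#' events, 400 true differential (DAS) events, unit logit-PSI variance,
#' and an effect size of eta (levels of interest: 2, 3, 5) added to or
#' subtracted from condition-2 cells at DAS events.
#'
#' @param n_cells Number of cells M (default 130).
#' @param n_events Number of events N (default 2248).
#' @param n_das Number of true DAS events (default 400; must be
#'   `<= n_events`).
#' @param eta Non-negative logit-scale effect size (default 5).
#' @param z_sd Cell-to-cell standard deviation of logit-PSI around the
#'   event mean (default 1).
#' @param mean_profile Optional length-`n_events` vector of per-event mean
#'   logit-PSI (a seed profile); when absent, means are drawn
#'   `N(0, mean_sd^2)`.
#' @param mean_sd Standard deviation of drawn event means (default 1.5,
#'   giving a long-tailed PSI spread typical of real events).
#' @param totals Optional M x N matrix of per-(cell, event) total read
#'   counts; when absent, totals are drawn negative binomial with mean
#'   `depth_mean` and size `depth_size`.
#' @param depth_mean,depth_size Negative-binomial depth parameters
#'   (defaults 20 and 0.5: sparse, overdispersed SMART-seq-like coverage).
#' @param exons Integer 3-vector of exon lengths for the shared
#'   skipped-exon geometry (default `c(500, 100, 500)`).
#' @param read_len Read length (default 100).
#' @param overhang Minimum junction overhang (default 1).
#' @param seed Integer seed (default 1).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 130L, n_events = 2248L, n_das = 400L,
                       eta = 5, z_sd = 1, mean_profile = NULL, mean_sd = 1.5,
                       totals = NULL, depth_mean = 20, depth_size = 0.5,
                       exons = c(500L, 100L, 500L), read_len = 100L,
                       overhang = 1L, seed = 1L) {
  stopifnot(n_cells >= 1, n_events >= 1, n_das >= 0, eta >= 0, z_sd > 0,
            mean_sd > 0, depth_mean > 0, depth_size > 0,
            length(exons) == 3L, read_len >= 1)
  if (n_das > n_events) stop("'n_das' cannot exceed 'n_events'")
  if (!is.null(mean_profile) && length(mean_profile) != n_events)
    stop("'mean_profile' must have one entry per event")
  if (!is.null(totals) && !all(dim(totals) == c(n_cells, n_events)))
    stop("'totals' must be an n_cells x n_events matrix")
  structure(list(n_cells = as.integer(n_cells), n_events = as.integer(n_events),
                 n_das = as.integer(n_das), eta = eta, z_sd = z_sd,
                 mean_profile = mean_profile, mean_sd = mean_sd,
                 totals = totals, depth_mean = depth_mean,
                 depth_size = depth_size, exons = as.integer(exons),
                 read_len = as.integer(read_len), overhang = as.integer(overhang),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate the ground-truth logit-PSI matrix and condition labels
#'
#' Cells are split randomly but equally into two conditions (condition 2
#' receives `floor(n_cells / 2)` cells). `n_das` events are drawn as true
#' DAS events; each gets one random sign, and condition-2 cells at that
#' event have their logit-PSI shifted by `sign * eta`.
#'
#' @param config A [sim_config()].
#' @return A `sim_truth` list: `condition` (per-cell, in `{1, 2}`),
#'   `das_flag` (per-event logical), `das_sign` (per-event, `+/-1` at DAS
#'   events, 0 elsewhere), `mean_z` (per-event), `Z_true` and `psi_true`
#'   (M x N matrices).
#' @export
simulate_truth <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  restore <- .restore_rng(); on.exit(restore())
  set.seed(config$seed)
  M <- config$n_cells; N <- config$n_events
  mean_z <- if (is.null(config$mean_profile))
    stats::rnorm(N, 0, config$mean_sd) else config$mean_profile
  condition <- rep(1L, M)
  condition[sample.int(M, M %/% 2L)] <- 2L
  das_flag <- rep(FALSE, N)
  das_flag[sample.int(N, config$n_das)] <- TRUE
  das_sign <- integer(N)
  das_sign[das_flag] <- sample(c(-1L, 1L), config$n_das, replace = TRUE)
  Z <- matrix(stats::rnorm(M * N, 0, config$z_sd), M, N) +
    matrix(mean_z, M, N, byrow = TRUE)
  shift <- outer(condition == 2L, das_sign * config$eta)
  Z <- Z + shift
  structure(list(condition = condition, das_flag = das_flag,
                 das_sign = das_sign, mean_z = mean_z,
                 Z_true = Z, psi_true = stats::plogis(Z)),
            class = "sim_truth")
}

#' Simulate grouped counts from a ground truth
#'
#' Per (cell, event), the three group counts are multinomial with total
#' `n_{c,g}` and proportions `rho(psi_true, L)` from the shared
#' skipped-exon effective-length matrix; totals are preserved exactly.
#'
#' @param truth A [simulate_truth()] result.
#' @param config The matching [sim_config()].
#' @return A validated `SplicingCountData` with cells `cell1..cellM` and
#'   events `event1..eventN`.
#' @export
simulate_counts <- function(truth, config = sim_config()) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  restore <- .restore_rng(); on.exit(restore())
  set.seed(config$seed + 1L)
  M <- config$n_cells; N <- config$n_events
  L <- effective_lengths_se(config$exons[1], config$exons[2], config$exons[3],
                            read_len = config$read_len,
                            overhang = config$overhang)
  ntot <- config$totals
  if (is.null(ntot))
    ntot <- matrix(stats::rnbinom(M * N, mu = config$depth_mean,
                                  size = config$depth_size), M, N)
  psi <- truth$psi_true
  # rho columns, vectorised over all (cell, event) pairs
  den <- psi * sum(L[1, ]) + (1 - psi) * sum(L[2, ])
  r1 <- (psi * L[1, 1] + (1 - psi) * L[2, 1]) / den
  r2 <- (psi * L[1, 2] + (1 - psi) * L[2, 2]) / den
  r3 <- 1 - r1 - r2
  # sequential binomial decomposition of the multinomial
  s1 <- matrix(stats::rbinom(M * N, size = ntot, prob = r1), M, N)
  p2 <- ifelse(r1 < 1, r2 / (1 - r1), 0)
  s2 <- matrix(stats::rbinom(M * N, size = ntot - s1,
                             prob = pmin(pmax(p2, 0), 1)), M, N)
  s3 <- ntot - s1 - s2
  lengths <- matrix(rep(c(L[1, ], L[2, ]), each = N), N, 6)
  colnames(lengths) <- c("l11", "l12", "l13", "l21", "l22", "l23")
  splicing_count_data(s1, s2, s3, lengths,
                      cell_ids = paste0("cell", seq_len(M)),
                      event_ids = paste0("event", seq_len(N)))
}

#' Simulate a full dataset: truth, counts and the covariate matrix
#'
#' Convenience wrapper combining [simulate_truth()] and
#' [simulate_counts()], and building the cell covariate matrix used for
#' differential testing (an intercept plus a 0/1 condition-2 indicator).
#'
#' @param config A [sim_config()].
#' @return List with `data` (`SplicingCountData`), `truth` (`sim_truth`)
#'   and `cell_features` (M x 2 matrix, columns `intercept`, `condition`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  truth <- simulate_truth(config)
  data <- simulate_counts(truth, config)
  Y <- cbind(intercept = 1, condition = as.numeric(truth$condition == 2L))
  list(data = data, truth = truth, cell_features = Y)
}
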