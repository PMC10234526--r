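#' Exact stochastic simulation of a reaction network
#'
#' Gillespie's direct method, statistically exact for the network's chemical
#' master equation. The initial state is the network's `x0` (all enhancers
#' unbound, zero TFs and mRNA). The state is recorded on a regular time grid;
#' the same seed and network give a bit-identical trajectory. If the total
#' propensity reaches zero with no constant-rate reactions the system is
#' absorbed and the remaining grid repeats the final state (documented
#' behavior, not an error).
#'
#' @param network A `reaction_network`.
#' @param t_end End time (> 0).
#' @param seed Integer RNG seed.
#' @param grid_dt Sampling interval (default 0.5 time units).
#' @return A `trajectory`: list with `times`, integer `counts` matrix
#'   (time x species), `seed` and `network`.
#' @export
gillespie_simulate <- function(network, t_end, seed = 1L, grid_dt = 0.5) {
  stopifnot(inherits(network, "reaction_network"), t_end > 0, grid_dt > 0)
  times <- seq(0, t_end, by = grid_dt)
  p <- network$propensity
  counts <- withr::with_seed(seed, .ssa_core(
    network$stoich, p$order, p$rate,
    ifelse(is.na(p$s1), -1L, p$s1 - 1L), ifelse(is.na(p$s2), -1L, p$s2 - 1L),
    as.integer(network$x0), times))
  colnames(counts) <- network$species$name
  structure(list(times = times, counts = counts, seed = seed,
                 network = network),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("SSA trajectory: ", nrow(x$counts), " samples over [0, ",
      max(x$times), "], seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write a trajectory as tidy CSV
#' @param trajectory A `trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- data.frame(time = trajectory$times, trajectory$counts,
                   seed = trajectory$seed, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Stationary moments from an SSA ensemble
#'
#' Estimates stationary means, variances and covariances by combined ensemble
#' and time averaging: each of `n_traj` trajectories (seeds derived
#' deterministically from `base_seed`) is averaged over the window
#' `[burn_in, t_end]`, and the per-trajectory (batch) estimates are averaged
#' across the ensemble. Monte Carlo standard errors are the batch-means
#' standard errors over trajectories.
#'
#' @param network A `reaction_network`.
#' @param n_traj Number of trajectories (>= 2).
#' @param t_end Trajectory length.
#' @param burn_in Discarded initial window (default 100 time units, large
#'   relative to the slowest fixture relaxation time).
#' @param base_seed Base seed; trajectory i uses `base_seed + i - 1`.
#' @param grid_dt Sampling interval.
#' @return A `moment_state` with `se` (standard errors for means and
#'   covariances) and `method = "ssa"`.
#' @export
ensemble_stats <- function(network, n_traj = 200L, t_end = 500,
                           burn_in = 100, base_seed = 1L, grid_dt = 0.5) {
  stopifnot(n_traj >= 2L, burn_in < t_end)
  ns <- nrow(network$species)
  nm <- network$species$name
  mean_b <- matrix(NA_real_, n_traj, ns)
  m2_b <- array(NA_real_, c(n_traj, ns, ns))
  for (i in seq_len(n_traj)) {
    tr <- gillespie_simulate(network, t_end, seed = base_seed + i - 1L,
                             grid_dt = grid_dt)
    w <- tr$times >= burn_in
    X <- tr$counts[w, , drop = FALSE]
    mean_b[i, ] <- colMeans(X)
    m2_b[i, , ] <- crossprod(X) / nrow(X)
  }
  means <- colMeans(mean_b)
  M2 <- apply(m2_b, c(2, 3), mean)
  covm <- M2 - tcrossprod(means)
  # batch covariance estimates relative to the pooled mean
  cov_b <- array(NA_real_, c(n_traj, ns, ns))
  for (i in seq_len(n_traj))
    cov_b[i, , ] <- m2_b[i, , ] - outer(means, mean_b[i, ]) -
      outer(mean_b[i, ], means) + tcrossprod(means)
  se_mean <- apply(mean_b, 2, stats::sd) / sqrt(n_traj)
  se_cov <- apply(cov_b, c(2, 3), stats::sd) / sqrt(n_traj)
  names(means) <- nm
  dimnames(covm) <- list(nm, nm)
  dimnames(se_cov) <- list(nm, nm)
  moment_state(means, covm,
               se = list(means = stats::setNames(se_mean, nm), cov = se_cov),
               method = "ssa",
               extra = list(n_traj = n_traj, t_end = t_end,
                            burn_in = burn_in, base_seed = base_seed))
}
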