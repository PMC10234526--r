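## Comparative studies: configuration sweeps, duplication-vs-splitting series,
## logarithmic parameter randomization and monotone-trend verdicts.

with_regime <- function(config, regime) {
  if (is.null(regime) || identical(regime, config$regime)) return(config)
  system_config(config$enhancers, params = config$params, regime = regime,
                d1 = config$d1, d2 = config$d2, sat_rate = config$sat_rate)
}

evaluate_config <- function(config, method = "mc2", tol = 1e-8,
                            n_traj = 200L, t_end = 500, burn_in = 100,
                            seed = 1L) {
  tau <- total_sites(config)
  rec <- data.frame(
    config_id = config_signature(config),
    n_enhancers = length(config$enhancers),
    tau1 = tau[1], tau2 = if (length(tau) >= 2L) tau[2] else 0L,
    sites_signature = config_signature(config),
    regime = config$regime, method = method,
    mean_R = NA_real_, var_R = NA_real_, cv = NA_real_,
    fidelity_T1 = NA_real_, fidelity_T2 = NA_real_, fano = NA_real_,
    converged = FALSE, pathological = FALSE, flag = "",
    seed = if (method == "ssa") seed else NA_integer_,
    stringsAsFactors = FALSE)
  state <- tryCatch({
    net <- build_network(config)
    if (method == "ssa")
      ensemble_stats(net, n_traj = n_traj, t_end = t_end, burn_in = burn_in,
                     base_seed = seed)
    else
      solve_stationary(derive_moment_odes(net,
                                          order = if (method == "mc3") 3L
                                                  else 2L),
                       tol = tol)
  }, error = function(e) e)
  if (inherits(state, "error")) {
    rec$flag <- conditionMessage(state)
    return(rec)
  }
  rec$converged <- state$converged
  rec$pathological <- state$pathological
  rec$mean_R <- state$means[["R"]]
  rec$var_R <- state$cov["R", "R"]
  safely <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  if (!state$pathological) {
    rec$cv <- safely(coefficient_of_variation(state))
    rec$fano <- safely(fano_factor(state))
    rec$fidelity_T1 <- safely(fidelity(state, "T1"))
    if ("T2" %in% names(state$means))
      rec$fidelity_T2 <- safely(fidelity(state, "T2"))
  } else rec$flag <- "pathological moment state"
  rec
}

#' Sweep noise and fidelity over a list of configurations
#'
#' Evaluates every configuration under one method and collects the stationary
#' mRNA mean, noise (CV), fidelity with respect to each TF and Fano factor in
#' one tidy table. Configurations that fail (e.g. negative modulated rates)
#' are recorded with a flag, never dropped.
#'
#' @param configs List of `system_config`s (e.g. from
#'   [enumerate_configurations()]).
#' @param regime Optional regime override applied to every config.
#' @param method `"mc2"` (second-order zero-cumulant closure, default),
#'   `"mc3"`, or `"ssa"`.
#' @param tol Stationarity tolerance for the closure methods.
#' @param n_traj,t_end,burn_in SSA ensemble settings.
#' @param base_seed Base seed; config i uses `base_seed + i - 1` (ssa only).
#' @return A `data.frame` of one record per configuration, in input order.
#' @export
run_sweep <- function(configs, regime = NULL, method = "mc2", tol = 1e-8,
                      n_traj = 200L, t_end = 500, burn_in = 100,
                      base_seed = 1L) {
  method <- match.arg(method, c("mc2", "mc3", "ssa"))
  if (length(configs) == 0L) stop("empty configuration list", call. = FALSE)
  rows <- lapply(seq_along(configs), function(i)
    evaluate_config(with_regime(configs[[i]], regime), method = method,
                    tol = tol, n_traj = n_traj, t_end = t_end,
                    burn_in = burn_in, seed = base_seed + i - 1L))
  do.call(rbind, rows)
}

#' Duplication vs splitting series for a single enhancer
#'
#' Builds the two shadow-enhancer origin scenarios side by side. Duplication:
#' 1..`max_copies` exact copies of the base enhancer (enhancer count and total
#' sites both grow). Splitting: the matched series with the same enhancer
#' counts but a fixed total site pool (the duplication end point,
#' `max_copies` times the base sites) dealt as evenly as possible. A copy
#' count at which modulated rates turn negative truncates that series with a
#' flagged record.
#'
#' @param base_config Single-enhancer `system_config`.
#' @param max_copies Largest enhancer count.
#' @param regime Optional regime override.
#' @param method,tol,base_seed As in [run_sweep()].
#' @return A `data.frame` with extra columns `series` ("duplication" or
#'   "splitting") and `copies`.
#' @export
duplication_series <- function(base_config, max_copies, regime = NULL,
                               method = "mc2", tol = 1e-8, base_seed = 1L) {
  stopifnot(max_copies >= 1)
  base_config <- with_regime(base_config, regime)
  if (length(base_config$enhancers) != 1L)
    stop("base config must have a single enhancer", call. = FALSE)
  tau_total <- total_sites(base_config) * max_copies
  rows <- list()
  for (cc in seq_len(max_copies)) {
    dup <- evaluate_config(duplicate_system(base_config, cc),
                           method = method, tol = tol,
                           seed = base_seed + cc - 1L)
    dup$series <- "duplication"; dup$copies <- cc
    spl_cfg <- tryCatch(
      split_system(tau_total, cc, params = base_config$params,
                   regime = base_config$regime, d1 = base_config$d1,
                   d2 = base_config$d2, sat_rate = base_config$sat_rate),
      error = function(e) e)
    spl <- if (inherits(spl_cfg, "error")) {
      r <- dup; r[1, ] <- NA; r$flag <- conditionMessage(spl_cfg); r
    } else evaluate_config(spl_cfg, method = method, tol = tol,
                           seed = base_seed + max_copies + cc - 1L)
    spl$series <- "splitting"; spl$copies <- cc
    rows <- c(rows, list(dup, spl))
  }
  do.call(rbind, rows)
}

#' Randomize rate parameters over logarithmic ranges
#'
#' Draws a fresh parameter set, log-uniformly, for robustness checks: all
#' rates except the transcription rates and kon from \[0.1, 100\];
#' transcription rates r from \[10, 1000\]; kon from \[0.1, 10\]. Burst sizes
#' are rounded to integers (at least 1). Deterministic under `seed`.
#'
#' @param base_params `rate_parameters` defining the number of TF types.
#' @param seed Integer seed.
#' @return A new `rate_parameters`.
#' @export
randomize_parameters <- function(base_params, seed) {
  nt <- n_tf_types(base_params)
  withr::with_seed(seed, {
    logu <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))
    rate_parameters(
      kon = logu(nt, 0.1, 10), koff = logu(nt, 0.1, 100),
      burst_rate = logu(nt, 0.1, 100),
      burst_size = pmax(1L, as.integer(round(logu(nt, 0.1, 100)))),
      tf_deg = logu(nt, 0.1, 100), r = logu(nt, 10, 1000),
      alpha = logu(1, 0.1, 100))
  })
}

#' Monotone-trend verdicts over a sweep table
#'
#' Checks the direction of each metric across groups: groups the usable rows
#' (unflagged, converged, non-pathological, finite metric) by `grouping`,
#' takes group means, and classifies the trend as flat (`"0"`, relative spread
#' below `flat_tol`), increasing (`"+"`) or decreasing (`"-"`) by the sign of
#' the Spearman correlation between group value and group mean. Magnitudes are
#' never asserted. Claims with fewer than two usable groups are marked
#' untestable, not failed.
#'
#' @param result_table Output of [run_sweep()] or [duplication_series()].
#' @param grouping Column name to group by (e.g. `"n_enhancers"`).
#' @param expected_directions Named character vector, metric -> expected
#'   direction (`"+"`, `"-"`, `"0"`), e.g. `c(cv = "+", fidelity_T1 = "0")`.
#' @param flat_tol Relative spread below which a trend counts as flat
#'   (default 1e-3, suited to deterministic closure output).
#' @return A `data.frame`: metric, expected, observed, n_groups, verdict
#'   (`"pass"`, `"fail"`, `"untestable"`).
#' @export
trend_report <- function(result_table, grouping, expected_directions,
                         flat_tol = 1e-3) {
  stopifnot(grouping %in% names(result_table))
  out <- lapply(names(expected_directions), function(metric) {
    expd <- expected_directions[[metric]]
    ok <- result_table$flag == "" & result_table$converged &
      !result_table$pathological & is.finite(result_table[[metric]])
    d <- result_table[ok, , drop = FALSE]
    gm <- tapply(d[[metric]], d[[grouping]], mean)
    res <- data.frame(metric = metric, expected = expd,
                      observed = NA_character_, n_groups = length(gm),
                      verdict = "untestable", stringsAsFactors = FALSE)
    if (length(gm) < 2L) return(res)
    spread <- (max(gm) - min(gm)) / max(abs(mean(gm)), .Machine$double.eps)
    obs <- if (spread < flat_tol) "0" else {
      rho <- stats::cor(as.numeric(names(gm)), as.numeric(gm),
                        method = "spearman")
      if (rho > 0) "+" else if (rho < 0) "-" else "0"
    }
    res$observed <- obs
    res$verdict <- if (obs == expd) "pass" else "fail"
    res
  })
  do.call(rbind, out)
}

## single-TF parameter subset (TF 1 kinetics), used by saturation/synergy runs
params_tf1 <- function(params) {
  rate_parameters(kon = params$kon[1], koff = params$koff[1],
                  burst_rate = params$burst_rate[1],
                  burst_size = params$burst_size[1],
                  tf_deg = params$tf_deg[1], r = params$r[1],
                  alpha = params$alpha)
}

#' Run the standard battery of enhancer-number trend claims
#'
#' Reproduces, for one parameter set, the qualitative claims of the
#' comparative studies as monotone-trend verdicts versus enhancer count:
#' subadditive noise rises; superadditive noise and fidelity fall; additive
#' noise and fidelity are flat; saturation noise falls and fidelity rises;
#' synergy noise rises and fidelity falls; duplication of a subadditive
#' enhancer raises fidelity and mean mRNA while noise falls. Sub-, super- and
#' additive claims use a fixed pool of 2 + 2 binding sites split across 1 to
#' `max_enhancers` enhancers; saturation/synergy use 1 to `max_enhancers`
#' single-site enhancers with the TF 1 kinetics; duplication copies a
#' single-site TF 1 enhancer 1 to `max_copies` times.
#'
#' @param params Two-TF `rate_parameters` (the single-TF runs take its TF 1
#'   components).
#' @param max_enhancers,max_copies Series lengths.
#' @param method,tol,flat_tol As in [run_sweep()] / [trend_report()].
#' @return A `data.frame` of verdicts with a `claim` label column.
#' @export
standard_trend_suite <- function(params = default_parameters(2L),
                                 max_enhancers = 4L, max_copies = 4L,
                                 method = "mc2", tol = 1e-8,
                                 flat_tol = 1e-3) {
  p1 <- params_tf1(params)
  out <- list()
  add <- function(label, verdicts) {
    verdicts$claim <- label
    out[[length(out) + 1L]] <<- verdicts
  }
  split_cfgs <- function(regime) lapply(seq_len(max_enhancers), function(n)
    split_system(c(2L, 2L), n, params = params, regime = regime))
  single_cfgs <- function(regime) lapply(seq_len(max_enhancers), function(n)
    system_config(rep(list(1L), n), params = p1, regime = regime))
  expected <- list(
    subadditive = c(cv = "+"),
    superadditive = c(cv = "-", fidelity_T1 = "-"),
    additive = c(cv = "0", fidelity_T1 = "0"),
    saturation = c(cv = "-", fidelity_T1 = "+"),
    synergy = c(cv = "+", fidelity_T1 = "-"))
  for (reg in c("subadditive", "superadditive", "additive")) {
    tb <- run_sweep(split_cfgs(reg), method = method, tol = tol)
    add(reg, trend_report(tb, "n_enhancers", expected[[reg]],
                          flat_tol = flat_tol))
  }
  for (reg in c("saturation", "synergy")) {
    tb <- run_sweep(single_cfgs(reg), method = method, tol = tol)
    add(reg, trend_report(tb, "n_enhancers", expected[[reg]],
                          flat_tol = flat_tol))
  }
  base <- system_config(list(c(1L, 0L)), params = params,
                        regime = "subadditive")
  ds <- duplication_series(base, max_copies, method = method, tol = tol)
  dup <- ds[ds$series == "duplication", , drop = FALSE]
  add("duplication", trend_report(dup, "copies",
                                  c(fidelity_T1 = "+", cv = "-",
                                    mean_R = "+"), flat_tol = flat_tol))
  res <- do.call(rbind, out)
  res[, c("claim", setdiff(names(res), "claim"))]
}

#' Write a sweep table as tidy CSV
#' @param result_table A sweep `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(result_table, path) {
  utils::write.csv(result_table, path, row.names = FALSE)
  invisible(path)
}
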