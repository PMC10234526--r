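#' Kinetic rate parameters for enhancer systems
#'
#' Container for all rate constants of the stochastic enhancer model. Rates are
#' stored per transcription-factor (TF) type as parallel vectors; time units are
#' a single consistent arbitrary unit throughout the package.
#'
#' @param kon Per-molecule TF binding rate to an empty site, one value per TF
#'   type (1/time/molecule).
#' @param koff Unbinding rate of a bound TF, per TF type (1/time).
#' @param burst_rate Rate at which TF synthesis bursts fire, per TF type
#'   (bursts/time).
#' @param burst_size Number of TF molecules produced per burst, per TF type
#'   (positive integer).
#' @param tf_deg First-order TF degradation rate, per TF type (1/time).
#' @param r Transcription rate contributed by one bound TF of each type
#'   (mRNA/time per bound site).
#' @param alpha First-order mRNA degradation rate (1/time).
#'
#' @return An object of class `rate_parameters`.
#' @seealso [default_parameters()] for the fitted Kruppel values,
#'   [apply_rate_modulation()] for the sub/superadditive rate shifts.
#' @export
rate_parameters <- function(kon, koff, burst_rate, burst_size, tf_deg, r,
                            alpha) {
  n_tf <- length(kon)
  stopifnot(length(koff) == n_tf, length(burst_rate) == n_tf,
            length(burst_size) == n_tf, length(tf_deg) == n_tf,
            length(r) == n_tf, length(alpha) == 1L)
  p <- list(kon = as.numeric(kon), koff = as.numeric(koff),
            burst_rate = as.numeric(burst_rate),
            burst_size = as.integer(round(burst_size)),
            tf_deg = as.numeric(tf_deg), r = as.numeric(r),
            alpha = as.numeric(alpha))
  if (any(unlist(p[c("kon", "koff", "burst_rate", "tf_deg", "r", "alpha")]) < 0))
    stop("all rates must be >= 0", call. = FALSE)
  if (any(p$burst_size < 1L))
    stop("burst sizes must be positive integers", call. = FALSE)
  structure(p, class = "rate_parameters", n_tf = n_tf, modulated = FALSE)
}

#' Default rate parameters fitted to Kruppel expression data
#'
#' The two-TF parameter set used throughout: TF 1 binds with
#' kon = 0.36, koff = 1.8, bursts of size 4 at rate 0.33, degradation 2.7,
#' transcription 120 per bound site; TF 2 binds with kon = 0.19, koff = 1.5,
#' bursts of size 12 at rate 0.29, degradation 3.9, transcription 140; mRNA
#' degrades at 1.96. All in one arbitrary time unit.
#'
#' @param n_tf Number of TF types to keep (1 or 2). `n_tf = 1` retains only the
#'   first TF's kinetics, as used for saturation/synergy systems.
#' @return A `rate_parameters` object.
#' @export
default_parameters <- function(n_tf = 2L) {
  stopifnot(n_tf %in% c(1L, 2L))
  idx <- seq_len(n_tf)
  rate_parameters(kon = c(0.36, 0.19)[idx], koff = c(1.8, 1.5)[idx],
                  burst_rate = c(0.33, 0.29)[idx],
                  burst_size = c(4L, 12L)[idx],
                  tf_deg = c(2.7, 3.9)[idx], r = c(120, 140)[idx],
                  alpha = 1.96)
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat("Rate parameters (", attr(x, "n_tf"), " TF type(s)",
      if (isTRUE(attr(x, "modulated"))) ", modulated", "):\n", sep = "")
  for (f in c("kon", "koff", "burst_rate", "burst_size", "tf_deg", "r"))
    cat(sprintf("  %-11s %s\n", f, paste(signif(x[[f]], 4), collapse = "  ")))
  cat(sprintf("  %-11s %s\n", "alpha", signif(x$alpha, 4)))
  invisible(x)
}

n_tf_types <- function(params) attr(params, "n_tf")

#' Default modulation coefficients for a regime
#'
#' Linear per-enhancer shifts of the binding kinetics. For subadditive systems
#' kon decreases by d1 and koff increases by d2 per enhancer; for superadditive
#' systems the signs flip. Defaults: subadditive d1 = (0.04, 0.02),
#' d2 = (0.75, 0.75); superadditive d1 = (0.01, 0.01), d2 = (0.4, 0.3)
#' (per TF type 1, 2).
#'
#' @param regime Interaction regime name.
#' @param n_tf Number of TF types.
#' @return List with numeric vectors `d1` and `d2` (zeros for regimes without
#'   modulation).
#' @export
default_modulation <- function(regime, n_tf = 2L) {
  idx <- seq_len(n_tf)
  switch(regime,
    subadditive   = list(d1 = c(0.04, 0.02)[idx], d2 = c(0.75, 0.75)[idx]),
    superadditive = list(d1 = c(0.01, 0.01)[idx], d2 = c(0.40, 0.30)[idx]),
    list(d1 = rep(0, n_tf), d2 = rep(0, n_tf)))
}

REGIMES <- c("additive", "subadditive", "superadditive", "saturation",
             "synergy")

#' Apply sub/superadditive modulation to binding rates
#'
#' Shifts kon and koff linearly with the total enhancer count n:
#' subadditive kon -> kon - n*d1, koff -> koff + n*d2; superadditive
#' kon -> kon + n*d1, koff -> koff - n*d2. Additive, saturation and synergy
#' regimes return the parameters unchanged. Modulation must be applied exactly
#' once: the result carries a guard flag and re-modulating is an error.
#'
#' @param params A `rate_parameters` object (unmodulated).
#' @param regime Interaction regime.
#' @param n_enhancers Total number of enhancers in the system.
#' @param d1,d2 Per-TF modulation coefficients (>= 0); default per
#'   [default_modulation()].
#' @return Modulated `rate_parameters`. Any resulting negative rate is a hard
#'   error (the linear scheme's known failure mode), never clamped.
#' @export
apply_rate_modulation <- function(params, regime, n_enhancers,
                                  d1 = NULL, d2 = NULL) {
  regime <- match.arg(regime, REGIMES)
  stopifnot(n_enhancers >= 1)
  if (isTRUE(attr(params, "modulated")))
    stop("rate modulation has already been applied to these parameters",
         call. = FALSE)
  if (!regime %in% c("subadditive", "superadditive")) return(params)
  nt <- n_tf_types(params)
  mod <- default_modulation(regime, nt)
  if (!is.null(d1)) mod$d1 <- rep_len(d1, nt)
  if (!is.null(d2)) mod$d2 <- rep_len(d2, nt)
  if (any(mod$d1 < 0) || any(mod$d2 < 0))
    stop("modulation coefficients must be >= 0", call. = FALSE)
  sgn <- if (regime == "subadditive") 1 else -1
  out <- params
  out$kon <- params$kon - sgn * n_enhancers * mod$d1
  out$koff <- params$koff + sgn * n_enhancers * mod$d2
  if (any(out$kon < 0) || any(out$koff < 0))
    stop(sprintf(
      "negative effective binding rate after %s modulation with %d enhancers",
      regime, n_enhancers), call. = FALSE)
  attr(out, "modulated") <- TRUE
  out
}
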