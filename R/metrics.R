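#' Transcriptional noise: coefficient of variation
#'
#' CV = sigma / mean of the stationary copy number of a species (mRNA by
#' default). Pathological states (negative closure variances) are refused.
#'
#' @param state A `moment_state`.
#' @param species Species name, default `"R"`.
#' @return The dimensionless CV.
#' @export
coefficient_of_variation <- function(state, species = "R") {
  check_state(state, species)
  m <- state$means[[species]]
  v <- state$cov[species, species]
  if (m <= 0) stop("CV undefined: mean of ", species, " is not positive",
                   call. = FALSE)
  if (v < 0) stop("CV undefined: negative variance for ", species,
                  call. = FALSE)
  sqrt(v) / m
}

#' Transcriptional fidelity: TF-mRNA correlation
#'
#' Pearson correlation between the stationary free TF copy number and the mRNA
#' copy number, `cov(T, R) / (sigma_T sigma_R)`. The free TF species is used
#' (not free + bound); switch `tf` to `"T2"` for the second TF.
#'
#' @param state A `moment_state`.
#' @param tf Free TF species name, default `"T1"`.
#' @param mrna mRNA species name, default `"R"`.
#' @return Correlation in \[-1, 1\].
#' @export
fidelity <- function(state, tf = "T1", mrna = "R") {
  check_state(state, tf, mrna)
  vt <- state$cov[tf, tf]; vr <- state$cov[mrna, mrna]
  if (vt <= 0 || vr <= 0)
    stop("fidelity undefined: zero or negative variance", call. = FALSE)
  rho <- state$cov[tf, mrna] / sqrt(vt * vr)
  min(1, max(-1, rho))
}

#' Fano factor
#'
#' Stationary variance over mean of a species' copy number; 1 for a Poisson
#' process, (n + 1)/2 for production in bursts of size n with linear decay.
#'
#' @param state A `moment_state`.
#' @param species Species name, default `"R"`.
#' @return The dimensionless Fano factor.
#' @export
fano_factor <- function(state, species = "R") {
  check_state(state, species)
  m <- state$means[[species]]
  if (m <= 0) stop("Fano factor undefined: mean of ", species,
                   " is not positive", call. = FALSE)
  state$cov[species, species] / m
}

check_state <- function(state, ...) {
  stopifnot(inherits(state, "moment_state"))
  if (state$pathological)
    stop("refusing metrics on a pathological moment state ",
         "(negative closure variance)", call. = FALSE)
  for (sp in c(...))
    if (!sp %in% names(state$means))
      stop("species '", sp, "' not in state", call. = FALSE)
  invisible(TRUE)
}
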