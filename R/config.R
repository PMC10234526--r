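#' Declare one enhancer by its binding-site counts
#'
#' @param site_counts Integer vector over TF types: number of binding sites for
#'   TF 1, TF 2, ... At least one entry must be positive.
#' @return Integer vector of class `enhancer_spec`.
#' @export
enhancer_spec <- function(site_counts) {
  s <- as.integer(site_counts)
  if (length(s) < 1L || any(is.na(s)) || any(s < 0L))
    stop("site counts must be non-negative integers", call. = FALSE)
  if (sum(s) == 0L)
    stop("an enhancer must have at least one binding site", call. = FALSE)
  structure(s, class = "enhancer_spec")
}

#' Declare a complete enhancer system
#'
#' A declarative description of an enhancer system: the enhancers (each a
#' vector of per-TF binding-site counts), the kinetic parameters, the
#' interaction regime, and optional modulation coefficients. Enhancers are
#' stored in canonical order (lexicographically sorted site-count vectors) so
#' that configurations differing only in enhancer order compare equal.
#'
#' @param enhancers List of site-count vectors (or `enhancer_spec`s), one per
#'   enhancer; all the same length (= number of TF types).
#' @param params `rate_parameters`; default [default_parameters()] sized to the
#'   number of TF types.
#' @param regime One of `"additive"`, `"subadditive"`, `"superadditive"`,
#'   `"saturation"`, `"synergy"`.
#' @param d1,d2 Optional per-TF modulation coefficients overriding
#'   [default_modulation()].
#' @param sat_rate Transcription rate used by the saturation/synergy regimes;
#'   `NULL` means the TF 1 rate `params$r[1]`.
#' @return A `system_config` object.
#' @export
system_config <- function(enhancers, params = NULL, regime = "additive",
                          d1 = NULL, d2 = NULL, sat_rate = NULL) {
  regime <- match.arg(regime, REGIMES)
  if (length(enhancers) < 1L) stop("need at least one enhancer", call. = FALSE)
  enhancers <- lapply(enhancers, enhancer_spec)
  nt <- unique(vapply(enhancers, length, 1L))
  if (length(nt) != 1L)
    stop("all enhancers must list the same number of TF types", call. = FALSE)
  if (is.null(params)) params <- default_parameters(min(nt, 2L))
  if (n_tf_types(params) != nt)
    stop("parameter set has ", n_tf_types(params),
         " TF type(s) but enhancers list ", nt, call. = FALSE)
  ord <- order(vapply(enhancers, function(e)
    paste(sprintf("%03d", e), collapse = ","), ""), decreasing = TRUE)
  structure(list(enhancers = enhancers[ord], params = params, regime = regime,
                 d1 = d1, d2 = d2, sat_rate = sat_rate),
            class = "system_config")
}

#' @export
print.system_config <- function(x, ...) {
  cat("Enhancer system (", x$regime, " regime): ",
      length(x$enhancers), " enhancer(s)\n", sep = "")
  for (i in seq_along(x$enhancers))
    cat("  ", LETTERS[i], ": sites per TF [",
        paste(x$enhancers[[i]], collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Total binding sites per TF type
#' @param config A `system_config`.
#' @return Integer vector tau over TF types.
#' @export
total_sites <- function(config) {
  Reduce(`+`, lapply(config$enhancers, as.integer))
}

config_signature <- function(config) {
  paste0(length(config$enhancers), ":",
         paste(vapply(config$enhancers,
                      function(e) paste0("[", paste(e, collapse = ","), "]"),
                      ""), collapse = "+"))
}

#' The two-enhancer Kruppel reference configuration
#'
#' Enhancer A with one TF 1 site and enhancer B with one TF 2 site, additive
#' regime, default (fitted) rate parameters — the minimal shadow-enhancer
#' system for the Kruppel gene.
#'
#' @return A `system_config` with two single-site enhancers.
#' @export
make_kruppel_config <- function() {
  system_config(list(c(1L, 0L), c(0L, 1L)))
}

#' Enumerate all enhancer configurations within size bounds
#'
#' Generates every configuration with at most `max_enhancers` enhancers and at
#' most `max_total_sites` binding sites in total, deduplicated as unordered
#' multisets of per-enhancer site-count vectors, in a deterministic canonical
#' order (by total sites, then enhancer count, then lexicographic signature).
#'
#' @param max_enhancers,max_total_sites Upper bounds (>= 1).
#' @param n_tf Number of TF types.
#' @param params,regime,d1,d2 Passed to every generated [system_config()];
#'   `params` defaults to [default_parameters()] of the right size.
#' @return List of `system_config` objects.
#' @export
enumerate_configurations <- function(max_enhancers, max_total_sites,
                                     n_tf = 2L, params = NULL,
                                     regime = "additive",
                                     d1 = NULL, d2 = NULL) {
  stopifnot(max_enhancers >= 1, max_total_sites >= 1, n_tf >= 1)
  # all nonzero site-count vectors with total <= max_total_sites
  grids <- do.call(expand.grid, rep(list(0:max_total_sites), n_tf))
  keep <- rowSums(grids) >= 1 & rowSums(grids) <= max_total_sites
  vecs <- lapply(which(keep), function(i) as.integer(grids[i, ]))
  # multisets: combinations with repetition, non-decreasing index sequences
  res <- list()
  recurse <- function(start, chosen, total) {
    if (length(chosen) > 0L) res[[length(res) + 1L]] <<- chosen
    if (length(chosen) == max_enhancers) return()
    for (j in start:length(vecs)) {
      w <- sum(vecs[[j]])
      if (total + w <= max_total_sites)
        recurse(j, c(chosen, list(vecs[[j]])), total + w)
    }
  }
  recurse(1L, list(), 0L)
  configs <- lapply(res, system_config, params = params, regime = regime,
                    d1 = d1, d2 = d2)
  sig <- vapply(configs, config_signature, "")
  tot <- vapply(configs, function(cf) sum(total_sites(cf)), 1L)
  nen <- vapply(configs, function(cf) length(cf$enhancers), 1L)
  configs <- configs[order(tot, nen, sig)]
  configs[!duplicated(vapply(configs, config_signature, ""))]
}

#' Duplicate every enhancer of a single-enhancer system
#'
#' Models shadow-enhancer creation by tandem duplication: the result carries
#' `copies` exact copies of the original enhancer, so both the enhancer count
#' and the total binding sites grow with `copies`. The regime and modulation
#' coefficients carry over; modulation is re-evaluated at the new enhancer
#' count when the network is built.
#'
#' @param config A single-enhancer `system_config`.
#' @param copies Number of copies (>= 1); 1 returns an identical system.
#' @return A `system_config` with `copies` identical enhancers.
#' @export
duplicate_system <- function(config, copies) {
  stopifnot(inherits(config, "system_config"))
  if (copies < 1) stop("copies must be >= 1", call. = FALSE)
  if (length(config$enhancers) != 1L)
    stop("duplication is defined for single-enhancer systems", call. = FALSE)
  system_config(rep(config$enhancers, copies), params = config$params,
                regime = config$regime, d1 = config$d1, d2 = config$d2,
                sat_rate = config$sat_rate)
}

#' Split a fixed pool of binding sites across enhancers
#'
#' Models shadow-enhancer creation by fission of one large enhancer: the total
#' number of binding sites per TF is preserved exactly while the enhancer count
#' grows. Sites are dealt deterministically, one at a time (TF types in order),
#' always to the enhancer with the fewest sites so far (ties to the lowest
#' index), giving the canonical most-even distribution.
#'
#' @param total_sites_per_tf Integer vector tau: total sites per TF type.
#' @param n_enhancers Number of enhancers to split into; must not exceed the
#'   total site count (every enhancer receives at least one site).
#' @param params,regime,d1,d2,sat_rate Passed to [system_config()].
#' @return A `system_config` with `n_enhancers` enhancers.
#' @export
split_system <- function(total_sites_per_tf, n_enhancers, params = NULL,
                         regime = "additive", d1 = NULL, d2 = NULL,
                         sat_rate = NULL) {
  tau <- as.integer(total_sites_per_tf)
  stopifnot(all(tau >= 0L), n_enhancers >= 1)
  if (sum(tau) < n_enhancers)
    stop("cannot split ", sum(tau), " sites across ", n_enhancers,
         " enhancers (each needs at least one site)", call. = FALSE)
  counts <- matrix(0L, nrow = n_enhancers, ncol = length(tau))
  for (m in seq_along(tau)) {
    for (k in seq_len(tau[m])) {
      target <- which.min(rowSums(counts))
      counts[target, m] <- counts[target, m] + 1L
    }
  }
  system_config(lapply(seq_len(n_enhancers), function(i) counts[i, ]),
                params = params, regime = regime, d1 = d1, d2 = d2,
                sat_rate = sat_rate)
}

#' Read a system configuration from a YAML or JSON file
#'
#' Expected keys: `enhancers` (list of per-TF site-count lists), optional
#' `params` (named: beta1, beta_m1, gamma1, gamma_m1, kon1, koff1, kon2,
#' koff2, alpha, r1, r2, n1, n2), optional `regime`, `d1`, `d2`, `sat_rate`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `system_config`.
#' @export
read_system_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw$enhancers)) stop("config file lacks 'enhancers'",
                                   call. = FALSE)
  enh <- raw$enhancers
  if (is.matrix(enh)) enh <- lapply(seq_len(nrow(enh)), function(i) enh[i, ])
  params <- if (!is.null(raw$params)) {
    p <- raw$params
    need1 <- c("beta1", "beta_m1", "kon1", "koff1", "alpha", "r1", "n1")
    if (!all(need1 %in% names(p)))
      stop("config params must name at least ", paste(need1, collapse = ", "),
           call. = FALSE)
    two <- all(c("gamma1", "gamma_m1", "kon2", "koff2", "r2", "n2") %in%
                 names(p))
    if (two)
      rate_parameters(kon = c(p$kon1, p$kon2), koff = c(p$koff1, p$koff2),
                      burst_rate = c(p$beta1, p$gamma1),
                      burst_size = c(p$n1, p$n2),
                      tf_deg = c(p$beta_m1, p$gamma_m1), r = c(p$r1, p$r2),
                      alpha = p$alpha)
    else
      rate_parameters(kon = p$kon1, koff = p$koff1, burst_rate = p$beta1,
                      burst_size = p$n1, tf_deg = p$beta_m1, r = p$r1,
                      alpha = p$alpha)
  } else NULL
  system_config(enh, params = params,
                regime = if (is.null(raw$regime)) "additive" else raw$regime,
                d1 = raw$d1, d2 = raw$d2, sat_rate = raw$sat_rate)
}
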