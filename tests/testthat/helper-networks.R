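# shared helpers for the test suite

# delta-method standard error for CV = sqrt(var)/mean from ensemble SEs
cv_se <- function(state, species = "R") {
  m <- state$means[[species]]
  v <- state$cov[species, species]
  sqrt((state$se$cov[species, species] / (2 * sqrt(v) * m))^2 +
         (sqrt(v) / m^2 * state$se$means[[species]])^2)
}

# count binding reactions that start from the all-empty occupancy state;
# equals the total number of distinct binding sites in the system
n_root_binding_sites <- function(network) {
  empty_states <- vapply(network$groups, `[`, 1L, 1L)
  sum(network$propensity$order == 2L &
        network$propensity$s2 %in% empty_states)
}
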