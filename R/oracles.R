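## Synthetic benchmark fixtures and brute-force solvers. These make every
## other module testable without external data: small networks with known
## closed-form stationary moments, plus an exact stationary solve of the
## truncated chemical master equation.

new_raw_network <- function(species, stoich, propensity, groups, x0,
                            reactions) {
  rownames(stoich) <- species$name
  names(x0) <- species$name
  structure(list(species = species, stoich = stoich, propensity = propensity,
                 reactions = reactions, groups = groups, x0 = x0,
                 params = NULL, config = NULL),
            class = "reaction_network")
}

#' Build a named benchmark network
#'
#' Available fixtures:
#' \describe{
#'   \item{birth_death}{`0 -> R` at rate `k` (default 10), `R -> 0` at `alpha`
#'     (default 2); Poisson stationary law.}
#'   \item{bursty_birth_death}{`0 -> n T1` at rate `beta` (defaults 0.33, n=4),
#'     `T1 -> 0` at `delta` (default 2.7); mean n*beta/delta, Fano (n+1)/2.}
#'   \item{telegraph}{two-state promoter `G0 <-> G1` (rates `kon`, `koff`),
#'     transcription `G1 -> G1 + R` at `r`, decay at `alpha`.}
#'   \item{single_enhancer_T1}{one enhancer with one TF 1 binding site,
#'     default fitted kinetics (single-TF parameter set).}
#'   \item{kruppel}{the two-enhancer reference system,
#'     `build_network(make_kruppel_config())`.}
#' }
#'
#' @param fixture Fixture name.
#' @param ... Parameter overrides (see defaults above).
#' @return A `reaction_network`.
#' @export
make_fixture <- function(fixture, ...) {
  ov <- list(...)
  g <- function(key, default) if (!is.null(ov[[key]])) ov[[key]] else default
  switch(fixture,
    birth_death = {
      k <- g("k", 10); alpha <- g("alpha", 2)
      new_raw_network(
        data.frame(name = "R", role = "mrna", group = NA_integer_),
        matrix(c(1L, -1L), nrow = 1),
        data.frame(order = c(0L, 1L), rate = c(k, alpha),
                   s1 = c(NA_integer_, 1L), s2 = NA_integer_),
        groups = list(), x0 = 0L,
        reactions = c("0 -> R", "R -> 0"))
    },
    bursty_birth_death = {
      beta <- g("beta", 0.33); n <- g("n", 4L); delta <- g("delta", 2.7)
      new_raw_network(
        data.frame(name = "T1", role = "free_tf", group = NA_integer_),
        matrix(c(as.integer(n), -1L), nrow = 1),
        data.frame(order = c(0L, 1L), rate = c(beta, delta),
                   s1 = c(NA_integer_, 1L), s2 = NA_integer_),
        groups = list(), x0 = 0L,
        reactions = c(sprintf("0 -> %d T1", n), "T1 -> 0"))
    },
    telegraph = {
      kon <- g("kon", 1); koff <- g("koff", 1)
      r <- g("r", 10); alpha <- g("alpha", 1)
      new_raw_network(
        data.frame(name = c("G0", "G1", "R"),
                   role = c("enhancer_state", "enhancer_state", "mrna"),
                   group = c(1L, 1L, NA_integer_)),
        matrix(c(-1L, 1L, 0L,  1L, -1L, 0L,  0L, 0L, 1L,  0L, 0L, -1L),
               nrow = 3),
        data.frame(order = c(1L, 1L, 1L, 1L), rate = c(kon, koff, r, alpha),
                   s1 = c(1L, 2L, 2L, 3L), s2 = NA_integer_),
        groups = list(1:2), x0 = c(1L, 0L, 0L),
        reactions = c("G0 -> G1", "G1 -> G0", "G1 -> G1 + R", "R -> 0"))
    },
    single_enhancer_T1 =
      build_network(system_config(list(1L),
                                  params = default_parameters(1L))),
    kruppel = build_network(make_kruppel_config()),
    stop("unknown fixture '", fixture, "'", call. = FALSE))
}

#' Exact stationary moments of analytic fixtures
#'
#' Closed-form stationary means/variances: birth-death is Poisson(k/alpha);
#' bursty production in clusters of n gives mean n*beta/delta and variance
#' mean*(n+1)/2; the telegraph promoter follows the standard two-state result
#' (mean r*p_on/alpha, Fano 1 + r*koff/((kon+koff)(kon+koff+alpha))).
#'
#' @param fixture One of `"birth_death"`, `"bursty_birth_death"`, `"telegraph"`.
#' @param ... Parameter overrides as in [make_fixture()].
#' @return A `moment_state` with `method = "exact"`.
#' @export
closed_form_moments <- function(fixture, ...) {
  ov <- list(...)
  g <- function(key, default) if (!is.null(ov[[key]])) ov[[key]] else default
  switch(fixture,
    birth_death = {
      k <- g("k", 10); alpha <- g("alpha", 2)
      m <- k / alpha
      moment_state(c(R = m), matrix(m, 1, 1, dimnames = list("R", "R")),
                   method = "exact")
    },
    bursty_birth_death = {
      beta <- g("beta", 0.33); n <- g("n", 4L); delta <- g("delta", 2.7)
      m <- n * beta / delta
      v <- m * (n + 1) / 2
      moment_state(c(T1 = m), matrix(v, 1, 1, dimnames = list("T1", "T1")),
                   method = "exact")
    },
    telegraph = {
      kon <- g("kon", 1); koff <- g("koff", 1)
      r <- g("r", 10); alpha <- g("alpha", 1)
      p <- kon / (kon + koff)
      mr <- r * p / alpha
      s <- kon + koff + alpha
      covg1r <- r * p * koff / ((kon + koff) * s)
      vr <- mr * (1 + r * koff / ((kon + koff) * s))
      vg <- p * (1 - p)
      nm <- c("G0", "G1", "R")
      covm <- matrix(c(vg, -vg, -covg1r,
                       -vg, vg, covg1r,
                       -covg1r, covg1r, vr), 3, 3,
                     dimnames = list(nm, nm))
      moment_state(c(G0 = 1 - p, G1 = p, R = mr), covm, method = "exact")
    },
    stop("no closed form for fixture '", fixture, "'", call. = FALSE))
}

#' Exact stationary moments of the truncated master equation
#'
#' Enumerates the state space exactly over the conserved occupancy groups and
#' a finite copy-number box for the unconserved species, builds the sparse
#' truncated generator (transitions leaving the box are dropped, i.e. a
#' reflecting truncation) and solves the stationary linear system. The
#' probability mass sitting on the box boundary is reported as a truncation
#' quality proxy in `$extra$boundary_mass`.
#'
#' @param network A `reaction_network`.
#' @param copy_bounds Named integer vector of per-species caps for the
#'   unconserved species; `NULL` estimates mean + 10 SD from a pilot SSA run.
#' @param max_states Refuse state spaces larger than this (default 5e4).
#' @param pilot_seed Seed for the pilot run when bounds are estimated.
#' @return A `moment_state` with `method = "cme"` (exact for the truncated
#'   chain).
#' @export
solve_cme_truncated <- function(network, copy_bounds = NULL,
                                max_states = 5e4, pilot_seed = 1L) {
  sp <- network$species
  grouped <- !is.na(sp$group)
  free_sp <- which(!grouped)
  if (is.null(copy_bounds)) {
    tr <- gillespie_simulate(network, t_end = 300, seed = pilot_seed)
    w <- tr$times >= 100
    X <- tr$counts[w, free_sp, drop = FALSE]
    copy_bounds <- stats::setNames(
      pmax(5L, as.integer(ceiling(colMeans(X) + 10 * apply(X, 2, stats::sd)))),
      sp$name[free_sp])
  }
  caps <- as.integer(copy_bounds[sp$name[free_sp]])
  if (any(is.na(caps)))
    stop("copy_bounds must name every unconserved species", call. = FALSE)
  # dimensions: one per conservation group (member index), one per free species
  dim_sizes <- c(vapply(network$groups, length, 1L), caps + 1L)
  n_grp <- length(network$groups)
  N <- prod(dim_sizes)
  if (N > max_states)
    stop("truncated state space has ", N, " states (> ", max_states,
         "); use the SSA ensemble instead", call. = FALSE)
  strides <- cumprod(c(1L, dim_sizes[-length(dim_sizes)]))
  dim_val <- lapply(seq_along(dim_sizes), function(d)
    rep(rep(0:(dim_sizes[d] - 1L), each = strides[d]),
        length.out = N))
  # species value vector over all states
  sp_dim <- integer(nrow(sp)); sp_member <- integer(nrow(sp))
  for (gi in seq_len(n_grp)) {
    mem <- network$groups[[gi]]
    sp_dim[mem] <- gi
    sp_member[mem] <- seq_along(mem) - 1L
  }
  sp_dim[free_sp] <- n_grp + seq_along(free_sp)
  spval <- function(s) {
    d <- sp_dim[s]
    if (d <= n_grp) as.numeric(dim_val[[d]] == sp_member[s])
    else as.numeric(dim_val[[d]])
  }
  ii <- list(); jj <- list(); xx <- list()
  P <- network$propensity
  for (r in seq_len(ncol(network$stoich))) {
    a <- rep(P$rate[r], N)
    if (P$order[r] >= 1L) a <- a * spval(P$s1[r])
    if (P$order[r] == 2L) a <- a * spval(P$s2[r])
    ok <- a > 0
    didx <- 0L
    nz <- which(network$stoich[, r] != 0L)
    for (s in nz) {
      d <- sp_dim[s]; delta <- network$stoich[s, r]
      if (d <= n_grp) {
        # group move: applicable only where this member is occupied/free
        if (delta < 0L) ok <- ok & (dim_val[[d]] == sp_member[s])
        didx <- didx + delta * sp_member[s] * strides[d]
      } else {
        newv <- dim_val[[d]] + delta
        ok <- ok & newv >= 0L & newv <= (dim_sizes[d] - 1L)
        didx <- didx + delta * strides[d]
      }
    }
    src <- which(ok)
    if (length(src)) {
      ii[[length(ii) + 1L]] <- src + didx
      jj[[length(jj) + 1L]] <- src
      xx[[length(xx) + 1L]] <- a[src]
    }
  }
  ii <- unlist(ii); jj <- unlist(jj); xx <- unlist(xx)
  Q <- if (length(ii))
    Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
  else Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(N, N))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::colSums(Q)
  # Q[i, j] = rate from state j to state i, diagonal = -outflow, so the
  # stationary distribution solves Q pi = 0. Pin the reference state (all
  # empty, index 1) to probability 1, solve the reduced nonsingular system,
  # then renormalize; this keeps the LU sparse (no dense constraint row).
  pi_vec <- numeric(N)
  pi_vec[1L] <- 1
  if (N > 1L)
    pi_vec[-1L] <- as.numeric(Matrix::solve(Q[-1L, -1L, drop = FALSE],
                                            -Q[-1L, 1L, drop = FALSE]))
  pi_vec <- pmax(pi_vec, 0); pi_vec <- pi_vec / sum(pi_vec)
  nm <- sp$name
  ns <- nrow(sp)
  vals <- lapply(seq_len(ns), spval)
  means <- vapply(vals, function(v) sum(pi_vec * v), 0)
  covm <- matrix(0, ns, ns, dimnames = list(nm, nm))
  for (i in seq_len(ns)) for (j in i:ns) {
    cij <- sum(pi_vec * vals[[i]] * vals[[j]]) - means[i] * means[j]
    covm[i, j] <- cij; covm[j, i] <- cij
  }
  on_boundary <- rep(FALSE, N)
  for (d in n_grp + seq_along(free_sp))
    on_boundary <- on_boundary | (dim_val[[d]] == dim_sizes[d] - 1L)
  moment_state(stats::setNames(means, nm), covm, method = "cme",
               extra = list(boundary_mass = sum(pi_vec[on_boundary]),
                            n_states = N,
                            copy_bounds = stats::setNames(caps,
                                                          sp$name[free_sp]),
                            degenerate = any(caps == 0L)))
}
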