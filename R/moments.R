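## Raw-moment ODEs with zero-cumulant (Gaussian) closure.
##
## For a mass-action network with stoichiometry s_r and propensity a_r(x) =
## c_r * prod(x over the monomial nu_r) (|nu_r| <= 2), the exact moment
## dynamics are d E[x^mu]/dt = sum_r E[a_r(x) * (prod_{i in mu}(x_i + s_ri) -
## x^mu)]. Expanding the product over subsets of mu gives a polynomial whose
## raw moments extend at most one order above |mu| + 1; at truncation order q
## the moments of order q+1 are eliminated by setting all cumulants above q to
## zero. Everything is assembled index-based (no symbolic math): the RHS is a
## single sparse matrix product over a vector of dynamic and closed moments.

key_str <- function(v) paste(v, collapse = ".")

## all multisets of {1..n} of size 1..q, as sorted integer vectors
moment_keys <- function(n, q) {
  keys <- lapply(seq_len(n), function(i) i)
  if (q >= 2)
    for (i in seq_len(n)) for (j in i:n)
      keys[[length(keys) + 1L]] <- c(i, j)
  if (q >= 3)
    for (i in seq_len(n)) for (j in i:n) for (k in j:n)
      keys[[length(keys) + 1L]] <- c(i, j, k)
  keys
}

## all set partitions of 1..n (n <= 4), each a list of integer blocks
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  smaller <- set_partitions(n - 1L)
  out <- list()
  for (p in smaller) {
    for (b in seq_along(p)) {
      q <- p; q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

#' Zero-cumulant closure of a third raw moment
#'
#' Setting the third cumulant of (x_i, x_j, x_k) to zero expresses the third
#' raw moment through first and second raw moments:
#' `E[xyz] = E[x]E[yz] + E[y]E[xz] + E[z]E[xy] - 2E[x]E[y]E[z]`.
#' Symmetric under any permutation of the indices.
#'
#' @param means Numeric vector of first moments E\[x\].
#' @param second_raw_moments Symmetric matrix of raw second moments E\[x_i x_j\].
#' @param ijk Integer vector of three species indices (repeats allowed).
#' @return The closed third raw moment (a number).
#' @export
close_third_moment <- function(means, second_raw_moments, ijk) {
  stopifnot(length(ijk) == 3)
  i <- ijk[1]; j <- ijk[2]; k <- ijk[3]
  means[i] * second_raw_moments[j, k] +
    means[j] * second_raw_moments[i, k] +
    means[k] * second_raw_moments[i, j] -
    2 * means[i] * means[j] * means[k]
}

#' Derive closed moment ODEs from a reaction network
#'
#' Builds the coupled ODE system for all raw moments up to `order` (2 or 3)
#' under zero-cumulant closure: moments one order above the truncation, which
#' enter through bimolecular propensities, are replaced by their Gaussian
#' (zero-cumulant) expressions in the retained moments. Networks with only
#' constant and first-order propensities close exactly (the closure is never
#' invoked).
#'
#' @param network A `reaction_network` with propensity order <= 2.
#' @param order Truncation order, 2 (default) or 3.
#' @return A `moment_system`: dynamic moment index, sparse RHS matrix, closure
#'   evaluation tables and the initial (deterministic) moment vector.
#' @export
derive_moment_odes <- function(network, order = 2L) {
  if (!order %in% c(2L, 3L)) stop("closure order must be 2 or 3",
                                  call. = FALSE)
  if (any(network$propensity$order > 2L))
    stop("unsupported network: propensity order > 2", call. = FALSE)
  n <- nrow(network$species)
  q <- as.integer(order)
  keys <- moment_keys(n, q)
  kstr <- vapply(keys, key_str, "")
  dyn_id <- stats::setNames(seq_along(keys), kstr)
  S <- network$stoich
  P <- network$propensity
  monomials <- lapply(seq_len(nrow(P)), function(r)
    as.integer(stats::na.omit(c(P$s1[r], P$s2[r]))))

  nzs <- lapply(seq_len(ncol(S)), function(r) which(S[, r] != 0L))
  chunks <- vector("list", length(keys))
  for (mu_i in seq_along(keys)) {
    mu <- keys[[mu_i]]
    cf_loc <- numeric(0); key_loc <- character(0)
    for (r in seq_len(ncol(S))) {
      if (!any(mu %in% nzs[[r]])) next
      sv <- S[mu, r]
      npos <- length(mu)
      for (mask in 0:(2^npos - 2L)) {     # proper subsets kept as x-factors
        inS <- as.logical(bitwAnd(mask, 2L^(seq_len(npos) - 1L)))
        cf <- P$rate[r] * prod(sv[!inS])
        if (cf == 0) next
        kk <- sort(c(mu[inS], monomials[[r]]))
        cf_loc <- c(cf_loc, cf)
        key_loc <- c(key_loc, if (length(kk)) key_str(kk) else "const")
      }
    }
    chunks[[mu_i]] <- list(coef = cf_loc, key = key_loc)
  }
  coef <- unlist(lapply(chunks, `[[`, "coef"))
  tkey <- unlist(lapply(chunks, `[[`, "key"))
  tgt <- rep(seq_along(keys),
             vapply(chunks, function(ch) length(ch$coef), 1L))
  ukeys <- unique(tkey)
  uk_id <- stats::setNames(seq_along(ukeys), ukeys)
  Tmat <- Matrix::sparseMatrix(i = tgt, j = uk_id[tkey], x = coef,
                               dims = c(length(keys), length(ukeys)))
  is_const <- ukeys == "const"
  uorder <- lengths(strsplit(ukeys, ".", fixed = TRUE))
  is_dyn <- !is_const & uorder <= q
  dyn_map <- ifelse(is_dyn, dyn_id[ukeys], NA_integer_)
  closed_keys <- lapply(strsplit(ukeys[!is_dyn & !is_const], ".",
                                 fixed = TRUE), as.integer)
  closure <- if (q == 2L) build_closure3(closed_keys, dyn_id)
             else build_closure4(closed_keys, dyn_id, n)
  x0 <- as.numeric(network$x0)
  y0 <- vapply(keys, function(kv) prod(x0[kv]), 0)
  structure(list(network = network, order = q, keys = keys,
                 dyn_id = dyn_id, Tmat = Tmat, n_valkeys = length(ukeys),
                 const_slot = which(is_const),
                 dyn_slot = which(is_dyn), dyn_map = dyn_map[is_dyn],
                 closed_slot = which(!is_dyn & !is_const), closure = closure,
                 y0 = y0, n_species = n),
            class = "moment_system")
}

## order-2 closure tables: each closed key is a triple (a,b,c)
build_closure3 <- function(triples, dyn_id) {
  if (length(triples) == 0L)
    return(list(kind = 3L, n = 0L))
  g <- function(v) dyn_id[[key_str(sort(v))]]
  list(kind = 3L, n = length(triples),
       ma = vapply(triples, function(t) g(t[1]), 1L),
       mb = vapply(triples, function(t) g(t[2]), 1L),
       mc = vapply(triples, function(t) g(t[3]), 1L),
       mbc = vapply(triples, function(t) g(t[2:3]), 1L),
       mac = vapply(triples, function(t) g(t[c(1, 3)]), 1L),
       mab = vapply(triples, function(t) g(t[1:2]), 1L))
}

eval_closure3 <- function(cl, y) {
  if (cl$n == 0L) return(numeric(0))
  y[cl$ma] * y[cl$mbc] + y[cl$mb] * y[cl$mac] + y[cl$mc] * y[cl$mab] -
    2 * y[cl$ma] * y[cl$mb] * y[cl$mc]
}

## order-3 closure tables: each closed key is a quadruple; zero fourth cumulant
## gives E[x^quad] = sum over the 14 proper set partitions of the positions of
## products of block cumulants (sizes 1-3). Cumulants are computed on the fly
## from the dynamic raw moments for exactly the pairs/triples needed.
build_closure4 <- function(quads, dyn_id, n) {
  if (length(quads) == 0L) return(list(kind = 4L, n = 0L))
  g <- function(v) dyn_id[[key_str(sort(v))]]
  parts <- Filter(function(p) length(p) > 1L, set_partitions(4L))
  pair_keys <- character(0); trip_keys <- character(0)
  for (qd in quads) {
    cmb2 <- utils::combn(4, 2)
    pair_keys <- c(pair_keys, apply(cmb2, 2, function(ix)
      key_str(sort(qd[ix]))))
    cmb3 <- utils::combn(4, 3)
    trip_keys <- c(trip_keys, apply(cmb3, 2, function(ix)
      key_str(sort(qd[ix]))))
  }
  pair_keys <- unique(pair_keys); trip_keys <- unique(trip_keys)
  pair_id <- stats::setNames(seq_along(pair_keys), pair_keys)
  trip_id <- stats::setNames(seq_along(trip_keys), trip_keys)
  pairs <- lapply(strsplit(pair_keys, ".", fixed = TRUE), as.integer)
  trips <- lapply(strsplit(trip_keys, ".", fixed = TRUE), as.integer)
  # kappa slot layout: 1 = const 1.0; 2..(n+1) = kappa1; then kappa2; kappa3
  k1 <- function(i) 1L + i
  k2 <- function(ij) 1L + n + pair_id[[key_str(sort(ij))]]
  k3 <- function(ijk) 1L + n + length(pairs) + trip_id[[key_str(sort(ijk))]]
  # tables to build kappa2 from raw moments: kappa2 = m2 - mu_i mu_j
  p_m2 <- vapply(pairs, function(p) g(p), 1L)
  p_i <- vapply(pairs, function(p) g(p[1]), 1L)
  p_j <- vapply(pairs, function(p) g(p[2]), 1L)
  # kappa3 = m3 - mu_a k2_bc - mu_b k2_ac - mu_c k2_ab - mu_a mu_b mu_c
  t_m3 <- vapply(trips, function(t) g(t), 1L)
  t_a <- vapply(trips, function(t) g(t[1]), 1L)
  t_b <- vapply(trips, function(t) g(t[2]), 1L)
  t_c <- vapply(trips, function(t) g(t[3]), 1L)
  t_bc <- vapply(trips, function(t) k2(t[2:3]) - 1L - n, 1L)
  t_ac <- vapply(trips, function(t) k2(t[c(1, 3)]) - 1L - n, 1L)
  t_ab <- vapply(trips, function(t) k2(t[1:2]) - 1L - n, 1L)
  # partition products: up to 4 kappa-slot factors each, padded with slot 1
  f <- matrix(1L, nrow = 0L, ncol = 4L); out <- integer(0)
  for (ci in seq_along(quads)) {
    qd <- quads[[ci]]
    for (p in parts) {
      slots <- vapply(p, function(blk) {
        v <- qd[blk]
        switch(length(blk), k1(v), k2(v), k3(v))
      }, 1L)
      f <- rbind(f, c(slots, rep(1L, 4L - length(slots))))
      out <- c(out, ci)
    }
  }
  Pm <- Matrix::sparseMatrix(i = out, j = seq_along(out), x = 1,
                             dims = c(length(quads), length(out)))
  list(kind = 4L, n = length(quads), n_sp = n,
       p_m2 = p_m2, p_i = p_i, p_j = p_j,
       t_m3 = t_m3, t_a = t_a, t_b = t_b, t_c = t_c,
       t_bc = t_bc, t_ac = t_ac, t_ab = t_ab,
       f1 = f[, 1], f2 = f[, 2], f3 = f[, 3], f4 = f[, 4], Pm = Pm)
}

eval_closure4 <- function(cl, y) {
  if (cl$n == 0L) return(numeric(0))
  n <- cl$n_sp
  kap2 <- y[cl$p_m2] - y[cl$p_i] * y[cl$p_j]
  kap3 <- y[cl$t_m3] - y[cl$t_a] * kap2[cl$t_bc] -
    y[cl$t_b] * kap2[cl$t_ac] - y[cl$t_c] * kap2[cl$t_ab] -
    y[cl$t_a] * y[cl$t_b] * y[cl$t_c]
  kv <- c(1, y[seq_len(n)], kap2, kap3)
  prods <- kv[cl$f1] * kv[cl$f2] * kv[cl$f3] * kv[cl$f4]
  as.numeric(cl$Pm %*% prods)
}

moment_rhs <- function(ms, y) {
  val <- numeric(ms$n_valkeys)
  val[ms$const_slot] <- 1
  val[ms$dyn_slot] <- y[ms$dyn_map]
  if (length(ms$closed_slot))
    val[ms$closed_slot] <- if (ms$closure$kind == 3L)
      eval_closure3(ms$closure, y) else eval_closure4(ms$closure, y)
  as.numeric(ms$Tmat %*% val)
}

#' Solve closed moment ODEs to stationarity
#'
#' Integrates the moment system from the deterministic zero-copy initial state
#' (enhancers all-empty) with a stiff-capable integrator until the relative
#' RHS norm `max(|dy/dt| / max(|y|, 1))` falls below `tol`, in geometrically
#' growing time chunks up to `t_max`.
#'
#' @param moment_system From [derive_moment_odes()].
#' @param tol Stationarity tolerance on the relative RHS norm (default 1e-8).
#' @param t_max Integration horizon; exceeding it without convergence is an
#'   error carrying the last state in `$state`.
#' @param rtol,atol Integrator tolerances.
#' @return A `moment_state`: stationary means, covariance matrix, convergence
#'   and pathology (negative closure variance) flags.
#' @export
solve_stationary <- function(moment_system, tol = 1e-8, t_max = 1e4,
                             rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(moment_system, "moment_system"), tol > 0)
  ms <- moment_system
  rhs <- function(t, y, parms) list(moment_rhs(ms, y))
  y <- ms$y0
  t_now <- 0; t_chunk <- 50
  converged <- FALSE
  while (t_now < t_max) {
    t_next <- min(t_now + t_chunk, t_max)
    sol <- deSolve::ode(y, times = c(t_now, t_next), func = rhs, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 50000)
    y <- as.numeric(sol[nrow(sol), -1])
    t_now <- t_next; t_chunk <- t_chunk * 4
    f <- moment_rhs(ms, y)
    if (max(abs(f) / pmax(abs(y), 1)) < tol) { converged <- TRUE; break }
  }
  state <- moments_to_state(ms, y, converged)
  if (!converged) {
    err <- simpleError(sprintf(
      "moment ODEs did not reach stationarity by t_max = %g", t_max))
    err$state <- state
    stop(err)
  }
  state
}

moments_to_state <- function(ms, y, converged) {
  n <- ms$n_species
  nm <- ms$network$species$name
  means <- stats::setNames(y[seq_len(n)], nm)
  M2 <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) for (j in i:n) {
    v <- y[ms$dyn_id[[key_str(c(i, j))]]]
    M2[i, j] <- v; M2[j, i] <- v
  }
  covm <- M2 - tcrossprod(means)
  moment_state(means, covm,
               method = paste0("mc", ms$order), converged = converged)
}

#' Construct a stationary moment state
#'
#' Shared container for stationary first and second moments, produced by the
#' moment-closure solver, the SSA ensemble estimator, the truncated-CME oracle
#' and the closed-form oracles.
#'
#' @param means Named numeric vector of stationary means.
#' @param cov Covariance matrix (symmetric, dimnames matching `means`).
#' @param se Optional list of Monte Carlo standard errors (`means`, `cov`).
#' @param method Label: "mc2", "mc3", "ssa", "cme", "exact".
#' @param converged Logical convergence flag.
#' @param extra Optional named list of extra diagnostics.
#' @return A `moment_state` object; `pathological` is set when any variance is
#'   negative beyond numerical round-off (a known Gaussian-closure failure at
#'   low copy numbers).
#' @export
moment_state <- function(means, cov, se = NULL, method = "mc2",
                         converged = TRUE, extra = list()) {
  cov <- (cov + t(cov)) / 2
  vars <- diag(cov)
  pathological <- any(vars < -1e-8 * pmax(1, means^2))
  structure(list(means = means, cov = cov, se = se, method = method,
                 converged = converged, pathological = pathological,
                 extra = extra),
            class = "moment_state")
}

#' @export
print.moment_state <- function(x, ...) {
  cat("Stationary moments (", x$method,
      if (!x$converged) ", NOT converged",
      if (x$pathological) ", PATHOLOGICAL (negative variance)", "):\n",
      sep = "")
  df <- data.frame(mean = signif(x$means, 5),
                   variance = signif(diag(x$cov), 5))
  print(df)
  invisible(x)
}
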