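test_that("moment ODEs are exact on linear networks", {
  # birth-death: Poisson stationary law, mean = var = k/alpha
  st <- solve_stationary(derive_moment_odes(make_fixture("birth_death",
                                                         k = 10, alpha = 2)))
  expect_equal(st$means[["R"]], 5, tolerance = 1e-8)
  expect_equal(st$cov["R", "R"], 5, tolerance = 1e-8)
  expect_false(st$pathological)
  # bursty production: mean n*beta/delta, Fano (n+1)/2
  st2 <- solve_stationary(derive_moment_odes(make_fixture(
    "bursty_birth_death")))
  expect_equal(st2$means[["T1"]], 4 * 0.33 / 2.7, tolerance = 1e-8)
  expect_equal(fano_factor(st2, "T1"), 2.5, tolerance = 1e-8)
  # telegraph promoter: linear network, closure exact including covariances
  st3 <- solve_stationary(derive_moment_odes(make_fixture("telegraph")))
  ex <- closed_form_moments("telegraph")
  expect_equal(st3$means[["R"]], ex$means[["R"]], tolerance = 1e-7)
  expect_equal(st3$cov["R", "R"], ex$cov["R", "R"], tolerance = 1e-7)
  expect_equal(st3$cov["G1", "R"], ex$cov["G1", "R"], tolerance = 1e-7)
})

test_that("order-2 and order-3 closures agree on linear networks", {
  net <- make_fixture("bursty_birth_death")
  s2 <- solve_stationary(derive_moment_odes(net, order = 2))
  s3 <- solve_stationary(derive_moment_odes(net, order = 3))
  expect_equal(s3$means[["T1"]], s2$means[["T1"]], tolerance = 1e-7)
  expect_equal(s3$cov["T1", "T1"], s2$cov["T1", "T1"], tolerance = 1e-7)
})

test_that("the zero-cumulant third-moment identity holds", {
  # all means zero: every odd Gaussian moment vanishes
  M <- matrix(c(2, 1, 1, 3), 2, 2)
  expect_equal(close_third_moment(c(0, 0), M, c(1, 2, 2)), 0)
  # single species: E[x^3] = 3 mu m2 - 2 mu^3
  mu <- 1.7; m2 <- 4.1
  expect_equal(close_third_moment(mu, matrix(m2, 1, 1), c(1, 1, 1)),
               3 * mu * m2 - 2 * mu^3)
  # independent species factorize
  mus <- c(2, 3, 5)
  M3 <- diag(c(6, 10, 26))
  M3[1, 2] <- M3[2, 1] <- mus[1] * mus[2]
  M3[1, 3] <- M3[3, 1] <- mus[1] * mus[3]
  M3[2, 3] <- M3[3, 2] <- mus[2] * mus[3]
  expect_equal(close_third_moment(mus, M3, c(1, 2, 3)), prod(mus))
  # permutation symmetry
  Mg <- matrix(c(4, 1, 0.5, 1, 5, 2, 0.5, 2, 6), 3, 3)
  mug <- c(1, 2, 3)
  vals <- apply(rbind(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1)), 1,
                function(p) close_third_moment(mug, Mg, p))
  expect_equal(max(vals) - min(vals), 0)
})

test_that("closure error on the one-site enhancer stays within 15% of exact", {
  net <- make_fixture("single_enhancer_T1")
  exact <- solve_cme_truncated(net, c(T1 = 30, R = 400))
  mc2 <- solve_stationary(derive_moment_odes(net))
  expect_lt(abs(coefficient_of_variation(mc2) /
                  coefficient_of_variation(exact) - 1), 0.15)
  expect_lt(abs(fidelity(mc2) / fidelity(exact) - 1), 0.15)
})

test_that("order-3 closure tracks order-2 trends on small enhancer systems", {
  cv_of <- function(cfg, ord) coefficient_of_variation(
    solve_stationary(derive_moment_odes(build_network(cfg), order = ord)))
  cfgs <- list(system_config(list(c(1L, 0L))),
               system_config(list(c(1L, 1L))),
               system_config(list(c(2L, 2L))))
  cv2 <- vapply(cfgs, cv_of, 0, ord = 2)
  cv3 <- vapply(cfgs, cv_of, 0, ord = 3)
  # same direction: noise falls with added binding sites under both closures
  expect_true(all(diff(cv2) < 0))
  expect_true(all(diff(cv3) < 0))
})

test_that("unsupported and non-convergent systems fail loudly", {
  net <- make_fixture("birth_death")
  bad <- net
  bad$propensity$order[1] <- 3L
  expect_error(derive_moment_odes(bad), "order > 2")
  expect_error(derive_moment_odes(net, order = 4), "order must be 2 or 3")
  # no degradation: first moment grows without bound, never stationary
  diverging <- make_fixture("birth_death", k = 10, alpha = 0)
  err <- tryCatch(solve_stationary(derive_moment_odes(diverging),
                                   t_max = 100),
                  error = function(e) e)
  expect_match(conditionMessage(err), "did not reach stationarity")
  expect_s3_class(err$state, "moment_state")
  expect_false(err$state$converged)
})
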