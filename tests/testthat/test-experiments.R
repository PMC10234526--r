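test_that("sweeps are deterministic, complete and flag failures", {
  expect_error(run_sweep(list()), "empty")
  cfgs <- enumerate_configurations(2, 2, 2)
  t1 <- run_sweep(cfgs, method = "mc2")
  t2 <- run_sweep(cfgs, method = "mc2")
  expect_identical(t1, t2)
  expect_equal(nrow(t1), length(cfgs))
  expect_true(all(c("config_id", "n_enhancers", "tau1", "tau2", "regime",
                    "method", "mean_R", "var_R", "cv", "fidelity_T1",
                    "fidelity_T2", "fano", "converged", "pathological",
                    "flag") %in% names(t1)))
  expect_true(all(t1$flag == ""))
  # six superadditive enhancers push koff2 negative: flagged, not dropped
  bad <- run_sweep(lapply(1:6, function(n)
    system_config(rep(list(c(0L, 1L)), n))), regime = "superadditive")
  expect_equal(nrow(bad), 6L)
  expect_match(bad$flag[6], "negative effective")
  expect_true(is.na(bad$cv[6]))
})

test_that("ssa sweeps agree with the closure sweeps within tolerance", {
  cfgs <- list(system_config(list(1L), params = default_parameters(1L)))
  mc <- run_sweep(cfgs, method = "mc2")
  ss <- run_sweep(cfgs, method = "ssa", n_traj = 100, t_end = 300,
                  base_seed = 23)
  expect_false(is.na(ss$seed[1]))
  # closure bias on this system is certified < 15% against the exact CME;
  # the sampled values must sit within the same band around the closure
  expect_lt(abs(ss$cv[1] / mc$cv[1] - 1), 0.15)
  expect_lt(abs(ss$fidelity_T1[1] / mc$fidelity_T1[1] - 1), 0.15)
})

test_that("duplication and splitting series share structure and endpoints", {
  base <- system_config(list(c(1L, 0L)), regime = "subadditive")
  ds <- duplication_series(base, 3)
  expect_equal(nrow(ds), 6L)
  expect_setequal(unique(ds$series), c("duplication", "splitting"))
  dup <- ds[ds$series == "duplication", ]
  spl <- ds[ds$series == "splitting", ]
  # duplication grows total sites; splitting holds them at the endpoint pool
  expect_equal(dup$tau1, 1:3)
  expect_equal(unique(spl$tau1), 3L)
  # at the last step both series are the same system
  expect_equal(dup$cv[3], spl$cv[3], tolerance = 1e-12)
  # a single copy reproduces the plain sweep record
  one <- duplication_series(base, 1)
  sw <- run_sweep(list(base))
  expect_equal(one$cv[one$series == "duplication"], sw$cv, tolerance = 1e-12)
  expect_error(duplication_series(system_config(list(1L, 1L),
                                                params =
                                                  default_parameters(1L)),
                                  2), "single enhancer")
})

test_that("parameter randomization honors its logarithmic ranges", {
  base <- default_parameters(2L)
  draws <- lapply(1:20, function(s) randomize_parameters(base, seed = s))
  for (p in draws) {
    expect_true(all(p$kon >= 0.1 & p$kon <= 10))
    expect_true(all(p$r >= 10 & p$r <= 1000))
    expect_true(all(p$koff >= 0.1 & p$koff <= 100))
    expect_true(all(p$tf_deg >= 0.1 & p$tf_deg <= 100))
    expect_gte(p$alpha, 0.1); expect_lte(p$alpha, 100)
    expect_true(all(p$burst_size >= 1L))
    expect_true(all(p$burst_size == round(p$burst_size)))
  }
  expect_identical(randomize_parameters(base, 7),
                   randomize_parameters(base, 7))
  expect_false(identical(draws[[1]], draws[[2]]))
})

test_that("trend verdicts classify directions and untestable claims", {
  tab <- data.frame(n_enhancers = rep(1:4, each = 2),
                    cv = c(1, 1, 2, 2, 3, 3, 4, 4) + 0.001,
                    fidelity_T1 = rep(0.5, 8),
                    down = seq(8, 1),
                    flag = "", converged = TRUE, pathological = FALSE)
  rep1 <- trend_report(tab, "n_enhancers",
                       c(cv = "+", fidelity_T1 = "0", down = "-"))
  expect_equal(rep1$verdict, rep("pass", 3))
  rep2 <- trend_report(tab, "n_enhancers", c(cv = "-"))
  expect_equal(rep2$verdict, "fail")
  # one usable group -> untestable, not failed
  tab$flag[tab$n_enhancers > 1] <- "negative effective rate"
  rep3 <- trend_report(tab, "n_enhancers", c(cv = "+"))
  expect_equal(rep3$verdict, "untestable")
})

test_that("result tables serialize to CSV byte-identically", {
  tb <- run_sweep(enumerate_configurations(1, 2, 1,
                                           params = default_parameters(1L)))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_results_csv(tb, f1)
  write_results_csv(run_sweep(enumerate_configurations(
    1, 2, 1, params = default_parameters(1L))), f2)
  expect_identical(readLines(f1), readLines(f2))
})
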