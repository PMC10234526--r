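test_that("the Kruppel reference system has the published structure", {
  cfg <- make_kruppel_config()
  expect_length(cfg$enhancers, 2L)
  expect_equal(as.integer(cfg$enhancers[[1]]), c(1L, 0L))
  expect_equal(as.integer(cfg$enhancers[[2]]), c(0L, 1L))
  expect_equal(cfg$regime, "additive")
  p <- cfg$params
  expect_equal(p$r, c(120, 140))
  expect_equal(p$burst_size, c(4L, 12L))
  expect_equal(p$kon, c(0.36, 0.19))
  expect_equal(p$koff, c(1.8, 1.5))
  expect_equal(p$burst_rate, c(0.33, 0.29))
  expect_equal(p$tf_deg, c(2.7, 3.9))
  expect_equal(p$alpha, 1.96)

  net <- build_network(cfg)
  expect_equal(nrow(net$species), 7L)
  expect_setequal(net$species$name, c("T1", "T2", "R", "A0", "A1", "B0", "B1"))
  # 2 bind + 2 unbind + 2 transcribe + 2 burst + 2 TF-degrade + 1 mRNA-degrade
  expect_equal(ncol(net$stoich), 11L)
  expect_true(all(net$propensity$order <= 2L))
})

test_that("multi-site enhancers enumerate occupancy states and additive rates", {
  cfg <- system_config(list(c(2L, 0L)))
  net <- build_network(cfg)
  states <- net$species$name[net$species$role == "enhancer_state"]
  expect_length(states, 4L)   # 2^2 occupancy states
  # the doubly-bound state transcribes at 2 * r1
  full <- which(net$species$name == "A11")
  tx <- which(net$propensity$order == 1L & net$propensity$s1 == full &
                net$stoich[net$species$name == "R", ] == 1L)
  expect_length(tx, 1L)
  expect_equal(net$propensity$rate[tx], 2 * 120)
})

test_that("degenerate configurations are rejected", {
  expect_error(enhancer_spec(c(0L, 0L)), "at least one binding site")
  expect_error(system_config(list()), "at least one enhancer")
  expect_error(build_network(system_config(list(13L),
                                           params = default_parameters(1L))),
               "state space")
})

test_that("transcription_rate implements all five regimes", {
  p <- default_parameters(2L)
  # one enhancer, one T1 and one T2 site, both bound
  expect_equal(transcription_rate(list(c(1L, 1L)), list(c(1L, 1L)), p,
                                  "additive"), 260)
  # sub/superadditivity never act through the rate formula
  expect_equal(transcription_rate(list(c(1L, 1L)), list(c(1L, 1L)), p,
                                  "subadditive"), 260)
  p1 <- default_parameters(1L)
  occ4 <- function(k) lapply(seq_len(4), function(i)
    if (i <= k) 1L else 0L)
  sc4 <- rep(list(1L), 4)
  expect_equal(transcription_rate(occ4(0), sc4, p1, "saturation"), 0)
  expect_equal(transcription_rate(occ4(1), sc4, p1, "saturation"), 120)
  expect_equal(transcription_rate(occ4(3), sc4, p1, "synergy"), 0)
  expect_equal(transcription_rate(occ4(4), sc4, p1, "synergy"), 120)
  expect_equal(transcription_rate(occ4(4), sc4, p1, "synergy",
                                  sat_rate = 55), 55)
  expect_error(transcription_rate(list(c(1L)), list(c(1L, 1L)), p,
                                  "additive"), "occupancy")
})

test_that("rate modulation shifts kon/koff linearly and guards reuse", {
  p <- default_parameters(2L)
  sub <- apply_rate_modulation(p, "subadditive", 2)
  expect_equal(sub$kon[1], 0.36 - 2 * 0.04)   # 0.28
  expect_equal(sub$koff[1], 1.8 + 2 * 0.75)   # 3.3
  sup <- apply_rate_modulation(p, "superadditive", 2)
  expect_equal(sup$koff[1], 1.8 - 2 * 0.4)    # 1.0
  expect_equal(sup$kon[1], 0.36 + 2 * 0.01)
  # additive regime is the identity
  expect_identical(apply_rate_modulation(p, "additive", 3), p)
  # applying modulation twice is an error (guard flag)
  expect_error(apply_rate_modulation(sub, "subadditive", 2),
               "already been applied")
  # negative effective rates are a hard error, never clamped
  expect_error(apply_rate_modulation(p, "subadditive", 10),
               "negative effective")
  expect_error(apply_rate_modulation(p, "superadditive", 6),
               "negative effective")
})

test_that("configuration enumeration is complete and deduplicated", {
  expect_length(enumerate_configurations(1, 1, 2), 2L)
  cfgs <- enumerate_configurations(2, 2, 2)
  expect_length(cfgs, 8L)
  sigs <- vapply(cfgs, enhancerNoise:::config_signature, "")
  expect_equal(anyDuplicated(sigs), 0L)
  # no two configs equal up to enhancer reordering (constructor canonicalizes)
  big <- enumerate_configurations(4, 4, 2)
  expect_equal(anyDuplicated(vapply(big, enhancerNoise:::config_signature,
                                    "")), 0L)
  expect_true(all(vapply(big, function(cf) sum(total_sites(cf)) <= 4, TRUE)))
})

test_that("duplication scales enhancers and sites together", {
  base <- system_config(list(c(2L, 0L)))
  dup <- duplicate_system(base, 3)
  expect_length(dup$enhancers, 3L)
  expect_equal(total_sites(dup), c(6L, 0L))
  expect_equal(enhancerNoise:::config_signature(duplicate_system(base, 1)),
               enhancerNoise:::config_signature(base))
  expect_error(duplicate_system(base, 0), ">= 1")
  # subadditive duplication: effective kon strictly decreases with copies
  kon_at <- function(cc) {
    cfg <- duplicate_system(system_config(list(c(1L, 0L)),
                                          regime = "subadditive"), cc)
    build_network(cfg)$params$kon[1]
  }
  kons <- vapply(1:4, kon_at, 0)
  expect_true(all(diff(kons) < 0))
})

test_that("splitting preserves site totals and distributes evenly", {
  s4 <- split_system(c(4L, 0L), 4)
  expect_length(s4$enhancers, 4L)
  expect_true(all(vapply(s4$enhancers, function(e)
    identical(as.integer(e), c(1L, 0L)), TRUE)))
  s2 <- split_system(c(2L, 2L), 2)
  expect_true(all(vapply(s2$enhancers, function(e)
    identical(as.integer(e), c(1L, 1L)), TRUE)))
  expect_error(split_system(c(1L, 0L), 2), "cannot split")
  # totals always preserved
  for (n in 1:3) expect_equal(total_sites(split_system(c(3L, 1L), n)),
                              c(3L, 1L))
})

test_that("site bookkeeping and canonical forms are relabeling-invariant", {
  for (enh in list(list(c(2L, 1L)), list(c(1L, 0L), c(0L, 1L)),
                   list(c(1L, 1L), c(2L, 0L)))) {
    cfg <- system_config(enh)
    net <- build_network(cfg)
    expect_equal(n_root_binding_sites(net), sum(total_sites(cfg)))
  }
  # enhancer order is not meaningful
  a <- build_network(system_config(list(c(2L, 0L), c(0L, 1L))))
  b <- build_network(system_config(list(c(0L, 1L), c(2L, 0L))))
  expect_identical(canonical_form(a), canonical_form(b))
  # different partitions of the same sites are different networks
  c1 <- build_network(system_config(list(c(1L, 1L))))
  expect_false(identical(canonical_form(a), canonical_form(c1)))
})

test_that("config files round-trip through YAML and JSON", {
  cfg <- system_config(list(c(1L, 0L), c(0L, 2L)), regime = "subadditive",
                       d1 = c(0.03, 0.01))
  yml <- tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(list(
    enhancers = lapply(cfg$enhancers, as.integer),
    params = list(beta1 = 0.33, beta_m1 = 2.7, gamma1 = 0.29,
                  gamma_m1 = 3.9, kon1 = 0.36, koff1 = 1.8, kon2 = 0.19,
                  koff2 = 1.5, alpha = 1.96, r1 = 120, r2 = 140,
                  n1 = 4, n2 = 12),
    regime = "subadditive", d1 = c(0.03, 0.01))), yml)
  rt <- read_system_config(yml)
  expect_equal(enhancerNoise:::config_signature(rt),
               enhancerNoise:::config_signature(cfg))
  expect_equal(rt$regime, "subadditive")
  expect_equal(rt$params$r, c(120, 140))
  expect_equal(rt$d1, c(0.03, 0.01))
  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(list(enhancers = lapply(cfg$enhancers, as.integer),
                            regime = "additive"),
                       jsn, auto_unbox = TRUE)
  rt2 <- read_system_config(jsn)
  expect_equal(total_sites(rt2), c(1L, 2L))
})

test_that("SBML export writes a well-formed model", {
  net <- build_network(make_kruppel_config())
  f <- tempfile(fileext = ".xml")
  write_sbml(net, f)
  doc <- xml2::read_xml(f)
  ns <- xml2::xml_ns(doc)
  sp <- xml2::xml_find_all(doc, ".//d1:species", ns)
  rx <- xml2::xml_find_all(doc, ".//d1:reaction", ns)
  expect_length(sp, nrow(net$species))
  expect_length(rx, ncol(net$stoich))
  amounts <- as.numeric(xml2::xml_attr(sp, "initialAmount"))
  expect_equal(sum(amounts), length(net$groups))
})
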