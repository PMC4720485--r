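kc <- kinetic_constants()

test_that("Eyring step rates reproduce the textbook reference points", {
  # flat profile: zero activation -> kB*T/h
  pr <- fe_profile("well", 0, 1)
  r <- step_rates_from_profile(pr, kc)
  expect_equal(r$backward, kc$eyring_prefactor)
  expect_equal(r$forward, kc$eyring_prefactor)  # terminal well: barrierless
  expect_equal(kc$eyring_prefactor, 6.25e12, tolerance = 1e-3)

  # a barrier of RT*ln2 halves the rate
  pr2 <- fe_profile(c("well", "barrier"), c(0, kc$RT * log(2)), 1:2)
  r2 <- step_rates_from_profile(pr2, kc)
  expect_equal(r2$forward, kc$eyring_prefactor / 2, tolerance = 1e-12)

  # barrier +3 from well -2: activation 5 kcal/mol
  pr3 <- fe_profile(c("well", "barrier"), c(-2, 3), 1:2)
  r3 <- step_rates_from_profile(pr3, kc)
  expect_equal(r3$forward, kc$eyring_prefactor * exp(-5 / kc$RT))
  expect_equal(r3$backward, kc$eyring_prefactor * exp(-2 / kc$RT))
})

test_that("migration probability: symmetry, limits, single-barrier formula", {
  # symmetric well: kf == kb -> 1/2
  pr <- fe_profile(c("barrier", "well", "barrier"), c(2, -1, 2), 1:3)
  expect_equal(migration_probability(pr, kc), 0.5, tolerance = 1e-12)

  # free descent forward, 10 kcal/mol wall backward -> ~1
  pr2 <- fe_profile(c("barrier", "well"), c(10, 0), 1:2)
  expect_equal(migration_probability(pr2, kc), 1, tolerance = 1e-7)

  # one interior well reduces to kf/(kf+kb) exactly
  pr3 <- fe_profile(c("well", "barrier"), c(-2, 1.4), 1:2)
  r <- step_rates_from_profile(pr3, kc)
  expect_equal(migration_probability(pr3, kc),
               r$forward / (r$forward + r$backward), tolerance = 1e-12)
})

test_that("multi-well splitting probability matches the master-equation solve", {
  # hop-rate ratios up to 10^3 (barrier asymmetries to ~4 kcal/mol): the
  # band where the double-precision linear solve itself resolves 1e-10;
  # the closed-form product expression is exact at any ratio
  set.seed(31)
  worst <- 0
  for (i in 1:300) {
    n <- sample(1:6, 1)
    f <- 10^runif(n, -1.5, 1.5)
    b <- 10^runif(n, -1.5, 1.5)
    mine <- splitting_probability(f, b)
    orac <- oracle_absorption(f, b)
    worst <- max(worst, abs(mine - orac[["to_heme"]]))
  }
  expect_lt(worst, 1e-10)
  # conservation: independently solved exit probabilities sum to one
  set.seed(32)
  for (i in 1:50) {
    n <- sample(1:6, 1)
    orac <- oracle_absorption(10^runif(n, -1, 1), 10^runif(n, -1, 1))
    expect_equal(unname(sum(orac)), 1, tolerance = 1e-12)
  }
})

test_that("well enhancement reproduces the ~150x concentration effect", {
  expect_equal(well_enhancement(0, kc), 1)
  expect_gt(well_enhancement(3, kc), 150)
  expect_equal(well_enhancement(3, kc), exp(3 / kc$RT))
  expect_equal(well_enhancement(1, kc), 5.35, tolerance = 0.01)
  expect_error(well_enhancement(-1, kc), class = "trhbkin_data_error")
})

test_that("tunnel combination is an arithmetic sum bounded per tunnel", {
  expect_equal(combine_tunnels(0.4, 0, 0), 0.4)
  expect_equal(combine_tunnels(0, 0, 0), 0)
  expect_equal(combine_tunnels(0.9, 0.9, 0), 1.8)
  # a second open tunnel at most doubles one open tunnel's contribution
  expect_lte(combine_tunnels(0.9, 0.9, 0), 2 * 0.9)
  expect_error(combine_tunnels(1.2, 0, 0), class = "trhbkin_data_error")
})

test_that("water equilibrium follows the per-hydrogen-bond penalty", {
  expect_equal(water_equilibrium(0, kc), 1)
  expect_equal(water_equilibrium(1, kc), 7.10e-3, tolerance = 1e-3)
  expect_equal(water_equilibrium(2, kc), 5.03e-5, tolerance = 1e-3)
  # each added bond divides kon by exp(2.95/RT) ~ 141, for every m
  ratio <- exp(kc$dG_per_hbond / kc$RT)
  expect_equal(ratio, 141, tolerance = 0.005)
  for (m in 0:4) {
    kon_m <- association_rate(0.5, water_equilibrium(m, kc), kc)
    kon_m1 <- association_rate(0.5, water_equilibrium(m + 1, kc), kc)
    expect_equal(kon_m / kon_m1, ratio, tolerance = 1e-12)
  }
})

test_that("association rate is proportional to its drivers", {
  k1 <- association_rate(0.2, 1e-3, kc)
  expect_equal(association_rate(0.4, 1e-3, kc), 2 * k1)
  expect_equal(association_rate(0, 0.5, kc), 0)
})

test_that("dissociation rate reproduces the free-heme reference and closed form", {
  expect_identical(dissociation_rate(0, kc), 1e4)
  expect_equal(dissociation_rate(kc$RT * log(1e8), kc), 1e-4, tolerance = 1e-12)
  expect_equal(dissociation_rate(-kc$RT * log(10), kc), 1e5, tolerance = 1e-12)
  # adapter: raw binding energies are negative-favourable
  expect_equal(ddE_from_binding_energy(-28, kc), 6)
  expect_equal(dissociation_rate(ddE_from_binding_energy(-22, kc), kc), 1e4)
})

test_that("p50 arithmetic and the half-saturation definition agree", {
  p <- oxygen_affinity_p50(1e7, 1, kc)
  expect_equal(p, 1 / (1e7 * 1.82e-6), tolerance = 1e-12)
  expect_equal(p, 0.0549, tolerance = 1e-3)
  expect_equal(oxygen_affinity_p50(1e7, 2, kc), 2 * p)
  # saturation at [O2] corresponding to p50 is exactly 1/2
  o2 <- p * kc$o2_solubility
  expect_equal(1e7 * o2 / (1e7 * o2 + 1), 0.5, tolerance = 1e-12)
  expect_error(oxygen_affinity_p50(0, 1, kc), class = "trhbkin_data_error")
})

test_that("affinity and koff classes follow their bands", {
  expect_equal(classify_affinity(c(0.5, 3, 50), kc),
               c("low_p50", "moderate_p50", "high_p50"))
  expect_equal(classify_koff(c(200, 5, 1e-3), kc),
               c("fast", "moderate", "low"))
})

test_that("kon decreases with barrier heights and hydrogen bonds; koff with ddE", {
  kons <- vapply(seq(0, 8, by = 1), function(b) {
    pr <- fe_profile(c("well", "barrier"), c(-2, b), 1:2)
    association_rate(migration_probability(pr, kc), 1, kc)
  }, numeric(1))
  expect_true(all(diff(kons) < 0))
  kon_h <- association_rate(0.5, water_equilibrium(0:5, kc), kc)
  expect_true(all(diff(kon_h) < 0))
  koffs <- dissociation_rate(seq(-2, 12, by = 0.5), kc)
  expect_true(all(diff(koffs) < 0))
})

test_that("predict_rates assembles a consistent per-protein table", {
  tbl <- tibble::tibble(id = c("a", "b"),
                        k_LT = c(0.5, 0), k_STG8 = c(0.1, 0), k_E7G = c(0, 0.2),
                        n_hbonds = c(2, 0), ddE_O2 = c(8, 1),
                        hexacoordinated = c(FALSE, TRUE))
  out <- predict_rates(tbl, kc)
  expect_equal(out$k_tunnels, c(0.6, 0.2))
  expect_equal(out$p50, out$koff / (out$kon * kc$o2_solubility))
  expect_equal(out$kon_is_upper_bound, c(FALSE, TRUE))
  expect_error(predict_rates(tbl[, -3], kc), "missing required",
               class = "trhbkin_data_error")
})

test_that("a profile with no wells is treated as a single transition state", {
  pr <- fe_profile("barrier", 2.5, 1)
  k <- migration_probability(pr, kc)
  expect_equal(k, exp(-2.5 / kc$RT) / (exp(-2.5 / kc$RT) + 1), tolerance = 1e-12)
  # flat pass: 50/50 split
  expect_equal(migration_probability(
    fe_profile(character(), numeric(), numeric()), kc), 0.5)
})
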