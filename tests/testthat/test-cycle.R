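test_that("Gompertz density inhibition is the log-distance to capacity", {
  expect_equal(density_inhibition(2e5, 7.43, 2e5), log(7.43),
               tolerance = 1e-12)
  expect_equal(density_inhibition(7.43 * 2e5, 7.43, 2e5), 0,
               tolerance = 1e-12)
  expect_equal(density_inhibition(7.43 * 2e5 / exp(1), 7.43, 2e5), 1,
               tolerance = 1e-12)
  expect_error(density_inhibition(0, 7.43, 2e5), "positive")
})

test_that("mitotic arrest is gated on ELYS exceeding baseline", {
  expect_identical(mitotic_arrest_rate(1.0, 2.39e-2, 3), 0)
  expect_identical(mitotic_arrest_rate(0.8, 2.39e-2, 3), 0)
  expect_equal(mitotic_arrest_rate(1.5, 2.39e-2, 3),
               2.39e-2 * 1.5^3, tolerance = 1e-12)
  ## the smooth gate is essentially closed (< 0.3%) at baseline
  expect_lt(mitotic_arrest_rate(1.0, 2.39e-2, 3, gate = "smooth"),
            3e-3 * 2.39e-2)
  expect_equal(mitotic_arrest_rate(1.1, 2.39e-2, 3, gate = "smooth"),
               mitotic_arrest_rate(1.1, 2.39e-2, 3, gate = "exact"),
               tolerance = 1e-8)
})

test_that("arrested-cell apoptosis rate composes the four protein
           signals", {
  expect_equal(arrested_apoptosis_rate(1, 1, 1, 1), 0.111,
               tolerance = 1e-12)
  expect_equal(arrested_apoptosis_rate(1, 1, 1, 0.5), 0.222,
               tolerance = 1e-12)
  expect_equal(arrested_apoptosis_rate(1, 0.033, 1, 1),
               0.111 * 0.033^(-0.0772), tolerance = 1e-12)
  expect_error(arrested_apoptosis_rate(1, 0, 1, 1), "positive")
})

test_that("cell bookkeeping: division is the only source and apoptotic
           clearance the only sink", {
  cp <- cycle_params()
  st <- c(G1 = 8e4, S = 5e4, M = 6e4, MA = 1e4, PL = 5e3, Apo = 2e4,
          D1 = 1.1, D2 = 1.05, D3 = 1)
  for (prot in list(NULL,
                    c(cIAP1 = 0.033, BAX = 1.2, Bcl2 = 0.4,
                      ELYS = 1.18, ASPP2 = 1.18))) {
    r <- cycle_rhs(st, cp, proteins = prot)
    d_total <- sum(r$deriv[c("G1", "S", "M", "MA", "PL", "Apo")])
    expect_equal(d_total,
                 cp$k31 * st[["M"]] - cp$k_ap * st[["Apo"]],
                 tolerance = 1e-12)
  }
})

test_that("the doubling-time approximation matches its printed anchors", {
  cp <- cycle_params()
  expect_equal(doubling_time_cycle(2e5, cp), 25.1, tolerance = 0.1 / 25.1)
  expect_equal(doubling_time_cycle(7.43 * 2e5 / exp(1), cp),
               1 / 4.48e-2 + 1 / 0.129 + 1 / (2 * 8.07e-2),
               tolerance = 1e-12)
  ## the S + G2/M residence floor as density inhibition vanishes
  expect_equal(1 / 0.129 + 1 / (2 * 8.07e-2), 13.95, tolerance = 1e-3)
  expect_error(doubling_time_cycle(7.43 * 2e5, cp), "capacity")
})

test_that("the unperturbed culture saturates at its capacity", {
  expect_equal(1.486e6, 7.43 * 2e5, tolerance = 1e-6)
  ## live cells plateau near N_max * live0; spontaneous apoptosis holds
  ## the realized plateau a few percent below the Gompertz ceiling
  cp <- cycle_params()
  sim <- simulate_cycle(cp, times = seq(0, 1200, by = 50))
  expect_equal(max(sim$live), 7.43 * 2e5, tolerance = 0.05)
  expect_lt(max(sim$live), 7.43 * 2e5)
  ## the plateau is genuinely stationary at the end of the horizon
  tail_live <- sim$live[sim$time_h >= 1000]
  expect_lt(max(abs(diff(tail_live))) / max(tail_live), 1e-3)
  ## all compartments stay non-negative throughout
  expect_true(all(sim$G1 >= 0 & sim$S >= 0 & sim$M >= 0 &
                    sim$MA >= 0 & sim$PL >= 0 & sim$Apo >= 0))
})

test_that("with proteins pinned at baseline the drug machinery is
           inert", {
  cp <- cycle_params()
  tt <- c(0, 17, 48, 72)
  ctrl <- simulate_cycle(cp, trt = treatment(FALSE, FALSE),
                         times = tt)
  ## drug effects all zeroed: identical to the control simulation
  np0 <- network_params(sti_IRAK4 = 0, inh_cIAP1_B = 0, sti_ELYS_P = 0,
                        inh_pJNK_deg_BP = 0)
  off <- simulate_cycle(cp, np0, treatment(TRUE, TRUE), times = tt)
  expect_equal(off$live, ctrl$live, tolerance = 1e-8)
  expect_equal(off$pct_apoptotic, ctrl$pct_apoptotic, tolerance = 1e-6)
})

test_that("polyploid pool is absorbing and non-decreasing under PTX", {
  cp <- cycle_params()
  sim <- simulate_cycle(cp, trt = treatment(FALSE, TRUE),
                        times = seq(0, 72, by = 1))
  expect_true(all(diff(sim$PL) >= -1e-9))
  expect_gt(sim$pct_polyploid[sim$time_h == 72], 0)
  ## arrested cells appear before polyploids accumulate
  expect_gt(sim$MA[sim$time_h == 17], sim$PL[sim$time_h == 17])
})

test_that("Michaelis-Menten conversion reproduces the reference
           exposure", {
  expect_equal(mm_ic50(0.967, 100), 3.41, tolerance = 1e-3)
  ic50 <- mm_ic50(0.967, 100)
  expect_equal(mm_extrapolate(0.967, 100, ic50), 0.5, tolerance = 1e-12)
  expect_identical(mm_extrapolate(0.967, 100, 0), 0)
  expect_identical(mm_extrapolate(2.22, 10, 0, mode = "stimulation"), 0)
  ## the stimulation law returns the fitted magnitude at the reference
  expect_equal(mm_extrapolate(2.22, 10, 10, mode = "stimulation"), 2.22,
               tolerance = 1e-12)
  expect_error(mm_extrapolate(1.2, 100, 10), "must lie in")
})

test_that("plate-context conversion rescales capacity and arrest", {
  cp <- cycle_params()
  cp96 <- plate_context(cp, "well96")
  expect_equal(cp96$k_ma0, 1.673e-2, tolerance = 1e-3)
  expect_equal(cp96$N_max, 30)
  expect_identical(plate_context(cp, "well6"), cp)
  expect_identical(plate_context(cp96, "well96"), cp96)  # idempotent
  expect_error(plate_context(cp, "flask"))
})

test_that("control-stage fitting recovers the generating cycle
           parameters from noise-free data", {
  spec <- synthetic_spec(seed = 31L, delta_pct = 0, delta_n = 0,
                         sigma_n = 0)
  cd <- generate_cycle_data(spec, arms = "control")
  fit <- fit_cycle(cd, NULL, free_control = c("k12", "k23", "k31"),
                   seed = 32L, n_starts = 2L)
  expect_equal(fit$control$estimates$k12, 4.48e-2, tolerance = 5e-3)
  expect_equal(fit$control$estimates$k23, 0.129, tolerance = 5e-3)
  expect_equal(fit$control$estimates$k31, 8.07e-2, tolerance = 5e-3)
  expect_error(fit_cycle(cd[0, ], NULL), "control")
})

test_that("drug-stage fitting recovers the cIAP1 apoptosis coupling", {
  spec <- synthetic_spec(seed = 33L, delta_pct = 0, delta_n = 0,
                         sigma_n = 0)
  cd <- generate_cycle_data(spec, arms = c("control", "B"))
  fit <- fit_cycle(cd[cd$arm == "control", ], cd[cd$arm == "B", ],
                   free_control = c("k12", "k23", "k31"),
                   free_drug = "gamma_cIAP_ap", seed = 34L,
                   n_starts = 2L)
  expect_equal(fit$drug$estimates$gamma_cIAP_ap, -0.532,
               tolerance = 0.15)
})
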