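test_that("the Hill killing signal behaves as specified", {
  expect_equal(killing_signal(18.3, 0.0233, 18.3, 1), 0.0233 / 2)
  expect_identical(killing_signal(0, 0.02, 100), 0)
  expect_equal(killing_signal(18.3, 0.0233, 18.3, 0.69),
               0.0233 * 18.3 / (0.69 * 18.3 + 18.3), tolerance = 1e-12)
  expect_equal(killing_signal(18.3, 0.0233, 18.3, 0.69), 0.01379,
               tolerance = 1e-3)
  expect_error(killing_signal(-1, 0.02, 100), "negative")

  ## monotone in C, decreasing in psi, saturating at K_max
  C <- seq(0, 5000, by = 50)
  s <- killing_signal(C, 0.0233, 18.3, 1)
  expect_true(all(diff(s) > 0))
  expect_true(all(s < 0.0233))
  expect_true(all(killing_signal(C[-1], 0.0233, 18.3, 0.69) >
                    killing_signal(C[-1], 0.0233, 18.3, 1)))
})

test_that("growth simulation reduces to exponential growth without drug", {
  gp <- growth_params()
  des <- exposure_design(times = c(24, 30.8, 48, 72, 96, 120))
  sim <- simulate_growth(gp, des)
  expect_equal(sim$N, exp(0.0225 * sim$time_h), tolerance = 1e-12)
  expect_equal(sim$N[sim$time_h == 30.8], 2, tolerance = 1e-2)
})

test_that("undelayed kill balancing growth holds the population level", {
  gp <- growth_params(n_transit = 0L, psi = 1)
  ## concentration at which the PTX kill rate equals k_G
  C_bal <- 0.0225 * 18.3 / (0.0233 - 0.0225)
  des <- exposure_design(C_P = C_bal, times = c(10, 50, 100))
  sim <- simulate_growth(gp, des)
  expect_equal(sim$N, rep(1, 3), tolerance = 1e-10)
})

test_that("closed-form growth solution matches a reference integration", {
  gp <- growth_params(n_transit = 3L)
  for (des in list(exposure_design(C_P = 20, times = c(12, 36, 72, 120)),
                   exposure_design(C_B = 250, C_P = 10,
                                   times = c(6, 24, 96)))) {
    expect_equal(simulate_growth(gp, des)$N,
                 growth_ode_oracle(gp, des), tolerance = 1e-6)
  }
})

test_that("the transit chain relaxes to its stationary input", {
  gp <- growth_params(n_transit = 3L, tau_P = 24)
  des <- exposure_design(C_P = 40, times = c(1, 12, 24, 240))
  sim <- simulate_growth(gp, des, signals = TRUE)
  S0 <- killing_signal(40, gp$K_maxP, gp$KC50_P, 1)
  expect_lt(sim$S_P[1], 0.05 * S0)           # barely transmitted early
  expect_equal(sim$S_P[4], S0, tolerance = 1e-6)  # fully transmitted late
  expect_true(all(diff(sim$S_P) > 0))
})

test_that("doubling time and half-life formulas are ln(2)/k", {
  expect_equal(doubling_time(0.0225), 30.8, tolerance = 0.1 / 30.8)
  expect_equal(doubling_time(log(2)), 1)
  expect_equal(doubling_time(0.649), 1.07, tolerance = 0.005)
  expect_error(doubling_time(0), "positive")
})

test_that("saturating PTX eradicates while saturating BRP only retards", {
  gp <- growth_params()
  ## long-run log-slope at saturating concentration: k_G - K_max
  expect_lt(gp$k_G - gp$K_maxP, 0)
  expect_gt(gp$k_G - gp$K_maxB, 0)
  des_P <- exposure_design(C_P = 1e6, times = c(400, 500))
  des_B <- exposure_design(C_B = 1e6, times = c(400, 500))
  slope <- function(sim) diff(log(sim$N)) / diff(sim$time_h)
  expect_lt(slope(simulate_growth(gp, des_P)), 0)
  expect_gt(slope(simulate_growth(gp, des_B)), 0)
})

test_that("polyploidy correction factor spans (1/weight, 1]", {
  expect_identical(correction_factor(100, 0), 1)
  expect_identical(correction_factor(0, 50), 0.5)
  expect_equal(correction_factor(50, 50), 100 / 150, tolerance = 1e-12)
  expect_error(correction_factor(0, 0), "both zero")
  set.seed(2)
  cf <- correction_factor(runif(50, 0, 1e5), runif(50, 0, 1e5))
  expect_true(all(cf > 0.5 & cf <= 1))
})

test_that("additivity ratios flag the direction of the interaction", {
  gp <- growth_params(psi = 1)
  des <- exposure_design(C_B = 250, C_P = 10,
                         times = c(24, 48, 72, 96, 120))
  obs_add <- simulate_growth(gp, des)$N
  expect_equal(additivity_ratio(obs_add, gp, des), rep(1, 5),
               tolerance = 1e-12)

  gp_syn <- growth_params(psi = 0.69)
  obs_syn <- simulate_growth(gp_syn, des)$N
  r_syn <- additivity_ratio(obs_syn, gp, des)
  expect_true(all(r_syn[des$times >= 72] < 1))

  gp_ant <- growth_params(psi = 1.5)
  obs_ant <- simulate_growth(gp_ant, des)$N
  expect_true(all(additivity_ratio(obs_ant, gp, des)[des$times >= 72] > 1))
})

test_that("noise-free single-agent data returns the generating Hill
           parameters", {
  truth <- growth_params()
  tab <- make_growth_table(truth, conc_B = numeric(0),
                           combos = data.frame(C_B = numeric(0),
                                               C_P = numeric(0)))
  fit <- fit_growth(tab, vspec = variance_spec("constant", delta = 0.02),
                    seed = 3, joint = FALSE)
  expect_equal(fit$params$K_maxP, truth$K_maxP, tolerance = 0.01)
  expect_equal(fit$params$KC50_P, truth$KC50_P, tolerance = 0.01)
  expect_equal(fit$params$k_G, truth$k_G, tolerance = 0.01)
})

test_that("a control-only table identifies growth but flags kill
           parameters", {
  truth <- growth_params()
  des <- exposure_design(times = c(24, 48, 72, 96, 120))
  tab <- data.frame(time_h = des$times, conc_PTX_nM = 0, conc_BRP_nM = 0,
                    replicate = 1L,
                    density_norm = simulate_growth(truth, des)$N)
  fit <- fit_growth(tab, vspec = variance_spec("constant", delta = 0.02),
                    seed = 4)
  expect_equal(fit$params$k_G, truth$k_G, tolerance = 1e-3)
  expect_true(all(c("K_maxP", "KC50_P") %in% fit$unidentifiable))
  expect_error(fit_growth(tab[tab$conc_PTX_nM > 0, ]), "control")
})

test_that("transit depth can be selected by AIC from growth data", {
  truth <- growth_params(n_transit = 3L)
  set.seed(11)
  tab <- make_growth_table(truth, conc_P = c(20, 60), conc_B = 1000,
                           combos = data.frame(C_B = numeric(0),
                                               C_P = numeric(0)))
  tab$density_norm <- tab$density_norm *
    (1 + rnorm(nrow(tab), 0, 0.01))
  fits <- lapply(0:5, function(nt) {
    fit_growth(tab, vspec = variance_spec("constant", delta = 0.02),
               n_transit = nt, seed = 5, joint = FALSE, psi_free = FALSE,
               n_starts = 2L)
  })
  depth <- select_transit_depth(fits, depths = 0:5)
  expect_equal(depth, 3L, tolerance = 1L)  # strong delay signal, low noise
})
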