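test_that("negative log-likelihood matches Gaussian density arithmetic", {
  vs1 <- variance_spec("constant", delta = 1)
  expect_equal(neg_log_likelihood(1.0, 1.0, vs1), 0.5 * log(2 * pi),
               tolerance = 1e-12)
  expect_equal(neg_log_likelihood(2.0, 0.0, vs1), 0.5 * log(2 * pi) + 2,
               tolerance = 1e-12)

  vs2 <- variance_spec("affine_proportional", delta = 0.5, sigma = 0.1)
  expect_equal(neg_log_likelihood(10, 11, vs2),
               -dnorm(11, mean = 10, sd = 0.5 + 0.1 * 10, log = TRUE),
               tolerance = 1e-12)

  ## random vectors against a direct density oracle
  set.seed(4)
  for (i in 1:5) {
    pred <- runif(7, 1, 5)
    obs <- pred + rnorm(7)
    expect_equal(neg_log_likelihood(pred, obs, vs2),
                 -sum(dnorm(obs, pred, 0.5 + 0.1 * pred, log = TRUE)),
                 tolerance = 1e-10)
  }

  expect_error(neg_log_likelihood(1:3, 1:2, vs1), "equal length")
  vs0 <- variance_spec("affine_proportional", delta = 0, sigma = 1)
  expect_error(neg_log_likelihood(c(1, 0), c(1, 1), vs0),
               "non-positive variance at observation index 2")
})

test_that("grouped variance models evaluate per observation block", {
  vs <- list(variance_spec("constant", delta = 2),
             variance_spec("affine_proportional", delta = 1, sigma = 0.5))
  pred <- c(1, 2, 10, 20)
  obs <- c(1.5, 2, 11, 18)
  grp <- c(1L, 1L, 2L, 2L)
  manual <- -sum(dnorm(obs[1:2], pred[1:2], 2, log = TRUE)) -
    sum(dnorm(obs[3:4], pred[3:4], 1 + 0.5 * pred[3:4], log = TRUE))
  expect_equal(neg_log_likelihood(pred, obs, vs, groups = grp), manual,
               tolerance = 1e-10)
})

test_that("AIC is -2 loglik + 2 n_free and linear in n_free", {
  expect_identical(aic(-10, 3), 26)
  expect_identical(aic(0, 0), 0)
  expect_identical(aic(-5.5, 9), 29)
  ll <- -3.7
  diffs <- diff(vapply(0:6, function(k) aic(ll, k), numeric(1)))
  expect_equal(diffs, rep(2, 6), tolerance = 1e-12)
})

test_that("fit_ml recovers a one-parameter exponential from clean data", {
  tt <- seq(0, 120, by = 12)
  truth <- 0.0225
  obs <- exp(truth * tt)
  fit <- fit_ml(function(p) exp(p$k * tt), obs,
                free = list(k = list(start = 0.01, lower = 0)),
                vspec = variance_spec("constant", delta = 0.05),
                seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$estimates$k, truth, tolerance = 1e-4 / truth)
  expect_equal(fit$n_obs, length(tt))
  expect_length(fit$residuals, length(tt))
  expect_equal(fit$aic, -2 * fit$loglik + 2, tolerance = 1e-12)
})

test_that("fit_ml agrees with an exhaustive grid search", {
  tt <- seq(0, 96, by = 8)
  set.seed(9)
  obs <- exp(0.02 * tt) * (1 + rnorm(length(tt), 0, 0.05))
  vs <- variance_spec("constant", delta = 0.1)
  nll <- function(k) neg_log_likelihood(exp(k * tt), obs, vs)
  grid <- seq(0.005, 0.05, length.out = 1000)
  k_grid <- grid[which.min(vapply(grid, nll, numeric(1)))]
  fit <- fit_ml(function(p) exp(p$k * tt), obs,
                free = list(k = list(start = 0.03, lower = 0)),
                vspec = vs, seed = 2)
  expect_lt(abs(fit$estimates$k - k_grid), diff(grid[1:2]))
})

test_that("transit depth selection minimizes AIC with ties to simpler", {
  mk <- function(a) structure(list(aic = a), class = "fit_result")
  expect_identical(select_transit_depth(lapply(c(100, 90, 85, 86, 88, 91),
                                               mk)), 2L)
  expect_identical(select_transit_depth(lapply(c(50, 50), mk)), 0L)
  ## permutation invariance apart from index bookkeeping
  aics <- c(44, 41, 40.5, 42, 47, 50)
  perm <- c(3, 1, 5, 2, 6, 4)
  expect_identical(
    select_transit_depth(lapply(aics[perm], mk), depths = (0:5)[perm]),
    select_transit_depth(lapply(aics, mk), depths = 0:5))
  expect_error(select_transit_depth(list()), "empty")
})

test_that("sequential fitting freezes upstream estimates downstream", {
  tt <- seq(0, 48, by = 4)
  k1 <- 0.649; amp <- 2.5
  y1 <- exp(-k1 * tt)
  y2 <- amp * exp(-k1 * tt)
  vs <- variance_spec("constant", delta = 0.05)
  stages <- list(
    list(name = "turnover", model_fn = function(p) exp(-p$k1 * tt),
         observations = y1,
         free = list(k1 = list(start = 0.3, lower = 0)), vspec = vs),
    list(name = "driven", model_fn = function(p) p$a * exp(-p$k1 * tt),
         observations = y2,
         free = list(a = list(start = 1, lower = 0)), vspec = vs,
         needs = "k1"))
  res <- sequential_fit(stages, seed = 5)
  expect_named(res, c("turnover", "driven"))
  expect_equal(res$turnover$estimates$k1, k1, tolerance = 1e-4)
  expect_equal(res$driven$estimates$a, amp, tolerance = 1e-4)
  expect_equal(res$driven$fixed$k1, res$turnover$estimates$k1)

  ## a single stage is an ordinary ML fit
  solo <- sequential_fit(stages[1], seed = 5)
  direct <- fit_ml(stages[[1]]$model_fn, y1, stages[[1]]$free,
                   vspec = vs, seed = 6)
  expect_equal(solo[[1]]$estimates$k1, direct$estimates$k1,
               tolerance = 1e-6)

  ## running the downstream stage first violates its dependency
  expect_error(sequential_fit(rev(stages), seed = 5),
               "requires upstream estimates: k1")
})

test_that("fit reports are written with parameter table and run log", {
  tt <- 0:10
  fit <- fit_ml(function(p) p$a * tt, 2 * tt + rnorm(11, 0, 1e-6),
                free = list(a = list(start = 1, lower = 0)),
                vspec = variance_spec("constant", delta = 1), seed = 1)
  base <- file.path(tempdir(), "fit_report_test")
  paths <- write_fit_report(fit, base, seed = 1)
  expect_true(all(file.exists(paths)))
  txt <- readLines(paths[1])
  expect_true(any(grepl("^a ", txt)))
  log <- read.csv(paths[2])
  expect_true(all(c("start", "objective", "convergence") %in% names(log)))
  unlink(paths)
})
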