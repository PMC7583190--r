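#' Growth-model parameter set
#'
#' Parameters of the cell-growth kinetic model: exponential proliferation
#' at net rate `k_G`, concentration-dependent killing for each drug
#' described by a Hill function with capacity `K_max` and potency `KC50`,
#' a transit-compartment delay chain (mean transit time `tau`,
#' `n_transit` compartments) between drug exposure and cell kill, and a
#' dimensionless interaction term `psi` that multiplies both drugs'
#' `KC50` in combination exposures (`psi < 1`: synergy; `psi = 1`:
#' additivity; `psi > 1`: antagonism).
#'
#' Defaults are the reference estimates for paclitaxel (PTX, drug "P")
#' plus birinapant (BRP, drug "B") acting on PANC-1 cells:
#' `k_G = 0.0225` h^-1, `K_maxP = 0.0233` h^-1, `KC50_P = 18.3` nM,
#' `K_maxB = 0.0153` h^-1, `KC50_B = 277` nM, `psi = 0.69`. The transit
#' times are design choices (`tau = 24` h, three compartments).
#'
#' @param k_G Net first-order growth rate constant (h^-1).
#' @param K_maxB,K_maxP Maximum kill rate constants (h^-1).
#' @param KC50_B,KC50_P Half-maximal kill concentrations (nM).
#' @param tau_B,tau_P Mean transit times of the delay chains (h).
#' @param n_transit Number of transit compartments per drug (>= 0).
#' @param psi Interaction term (> 0); fixed to 1 for single-drug arms.
#' @return Object of class `growth_params`.
#' @export
growth_params <- function(k_G = 0.0225,
                          K_maxB = 0.0153, K_maxP = 0.0233,
                          KC50_B = 277, KC50_P = 18.3,
                          tau_B = 24, tau_P = 24,
                          n_transit = 3L, psi = 0.69) {
  stopifnot(k_G > 0, K_maxB > 0, K_maxP > 0, KC50_B > 0, KC50_P > 0,
            tau_B > 0, tau_P > 0, n_transit >= 0,
            n_transit == round(n_transit), psi > 0)
  structure(list(k_G = k_G, K_maxB = K_maxB, K_maxP = K_maxP,
                 KC50_B = KC50_B, KC50_P = KC50_P,
                 tau_B = tau_B, tau_P = tau_P,
                 n_transit = as.integer(n_transit), psi = psi),
            class = "growth_params")
}

#' Exposure design for a growth experiment
#'
#' Constant drug concentrations applied at time zero and maintained for
#' the experiment duration (media are not refreshed), with cell density
#' normalized to the mean density at treatment initiation (T0).
#'
#' @param C_B,C_P Constant concentrations of the two drugs (nM, >= 0).
#' @param times Observation times (h).
#' @param N0 Initial normalized cell density (dimensionless).
#' @return Object of class `exposure_design`.
#' @export
exposure_design <- function(C_B = 0, C_P = 0,
                            times = c(24, 48, 72, 96, 120), N0 = 1) {
  stopifnot(C_B >= 0, C_P >= 0, all(times >= 0), N0 > 0)
  structure(list(C_B = C_B, C_P = C_P, times = sort(times), N0 = N0),
            class = "exposure_design")
}

#' Hill killing signal
#'
#' Stationary kill-rate signal generated by a drug at concentration `C`:
#' `K_max * C / (psi * KC50 + C)`. The interaction term scales the
#' half-maximal concentration, so `psi = 0.69` is equivalent to a 31\%
#' reduction in `KC50` relative to single-agent exposure.
#'
#' @param C Drug concentration (nM, >= 0).
#' @param K_max Maximum kill rate constant (h^-1).
#' @param KC50 Half-maximal kill concentration (nM).
#' @param psi Interaction term applied to `KC50`.
#' @return Kill rate (h^-1); 0 at `C = 0`.
#' @export
killing_signal <- function(C, K_max, KC50, psi = 1) {
  if (any(C < 0)) stop("negative drug concentration")
  stopifnot(K_max > 0, KC50 > 0, psi > 0)
  K_max * C / (psi * KC50 + C)
}

## Time-average fraction of the stationary kill signal transmitted by an
## n-compartment transit chain by time t. The chain
## dS_j/dt = (S_{j-1} - S_j) * (n/tau) driven by a constant input S_0 has
## the Erlang(n, n/tau) distribution function as its unit response, so the
## integral of the delayed signal has the closed form
##   A(t) = t * F_n(t) - (n/rate) * F_{n+1}(t),  rate = n/tau,
## with F_k the Gamma(k, rate) CDF. For n = 0 the signal is undelayed and
## A(t) = t.
.transit_integral <- function(t, n_transit, tau) {
  if (n_transit == 0L) return(t)
  rate <- n_transit / tau
  t * stats::pgamma(t, shape = n_transit, rate = rate) -
    (n_transit / rate) * stats::pgamma(t, shape = n_transit + 1, rate = rate)
}

## Instantaneous delayed signal fraction (chain output / stationary input).
.transit_output <- function(t, n_transit, tau) {
  if (n_transit == 0L) return(rep(1, length(t)))
  stats::pgamma(t, shape = n_transit, rate = n_transit / tau)
}

#' Simulate the growth model
#'
#' Integrates `dN/dt = k_G * N - (S_B + S_P) * N`, where each kill
#' signal is the Hill function of the constant drug concentration passed
#' through its transit-compartment chain (initialized at zero). Because
#' the chain is linear with constant input, the solution is evaluated in
#' closed form through the Erlang distribution function rather than by
#' numerical integration; the result is exact for constant exposures.
#' The interaction term is applied only when both drugs are present.
#'
#' @param params A [growth_params()].
#' @param design An [exposure_design()].
#' @param signals If `TRUE`, also return the instantaneous delayed kill
#'   signals for each drug.
#' @return `data.frame` with columns `time_h`, `N` (and `S_B`, `S_P`
#'   when `signals = TRUE`).
#' @export
simulate_growth <- function(params, design, signals = FALSE) {
  stopifnot(inherits(params, "growth_params"),
            inherits(design, "exposure_design"))
  t <- design$times
  combo <- design$C_B > 0 && design$C_P > 0
  psi <- if (combo) params$psi else 1
  S0B <- if (design$C_B > 0) {
    killing_signal(design$C_B, params$K_maxB, params$KC50_B, psi)
  } else 0
  S0P <- if (design$C_P > 0) {
    killing_signal(design$C_P, params$K_maxP, params$KC50_P, psi)
  } else 0
  logN <- log(design$N0) + params$k_G * t -
    S0B * .transit_integral(t, params$n_transit, params$tau_B) -
    S0P * .transit_integral(t, params$n_transit, params$tau_P)
  out <- data.frame(time_h = t, N = exp(logN))
  if (signals) {
    out$S_B <- S0B * .transit_output(t, params$n_transit, params$tau_B)
    out$S_P <- S0P * .transit_output(t, params$n_transit, params$tau_P)
  }
  out
}

#' Interaction-term recovery experiment
#'
#' Simulates replicate synthetic proliferation studies over the full
#' single-agent plus combination concentration grid from the reference
#' growth parameters (interaction term included as ground truth), adds
#' affine-proportional measurement noise, and refits the growth model
#' with the interaction term free. Averaging the recovered estimates
#' over independent replicate studies reduces the Monte-Carlo scatter
#' of the recovery summary.
#'
#' @param seed Base integer seed; replicate r uses `seed + 1000 * r`.
#' @param n_replicates Number of independent replicate studies.
#' @param truth Ground-truth [growth_params()].
#' @param ... Further arguments passed to [synthetic_spec()] (noise
#'   levels, design).
#' @return List with `psi_hat` (per-replicate estimates), `psi_mean`,
#'   `ci95` (asymptotic 95\% CI of the first replicate's estimate) and
#'   `fits` (the per-replicate `fit_result`s).
#' @export
psi_recovery_experiment <- function(seed = 1L, n_replicates = 4L,
                                    truth = growth_params(), ...) {
  fits <- vector("list", n_replicates)
  psi_hat <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    spec <- synthetic_spec(seed = seed + 1000L * r,
                           growth_params = truth, ...)
    gd <- generate_growth_data(spec)
    fits[[r]] <- fit_growth(gd, seed = seed + r)
    psi_hat[r] <- fits[[r]]$estimates$psi
  }
  list(psi_hat = psi_hat, psi_mean = mean(psi_hat),
       ci95 = fits[[1L]]$psi_ci95, fits = fits)
}

#' Doubling time (or half-life) of a first-order rate constant
#'
#' @param k Positive first-order rate constant (h^-1).
#' @return `log(2) / k` in hours.
#' @examples
#' doubling_time(0.0225)  # 30.8 h
#' @export
doubling_time <- function(k) {
  if (any(k <= 0)) stop("rate constant must be positive")
  log(2) / k
}

#' Polyploidy correction factor for total-protein cell-mass assays
#'
#' Total-protein stains (e.g. SRB) overestimate cell number when part of
#' the population is polyploid, because a polyploid cell carries roughly
#' twice the protein of a diploid cell. The correction factor
#' `CF = (N_diploid + N_polyploid) / (N_diploid + 2 * N_polyploid)`
#' multiplies the measured optical density to recover true cell number;
#' it lies in (0.5, 1].
#'
#' @param n_diploid,n_polyploid Non-negative cell counts (not both zero).
#' @param weight Protein content of a polyploid cell relative to a
#'   diploid cell (default 2).
#' @return Correction factor in (1/weight, 1].
#' @export
correction_factor <- function(n_diploid, n_polyploid, weight = 2) {
  if (any(n_diploid < 0) || any(n_polyploid < 0)) {
    stop("cell counts must be non-negative")
  }
  tot <- n_diploid + n_polyploid
  if (any(tot == 0)) stop("diploid and polyploid counts are both zero")
  tot / (n_diploid + weight * n_polyploid)
}

#' Observed/predicted growth ratios under an additivity null
#'
#' Compares observed combination-arm densities against the growth model
#' prediction with the interaction term forced to 1 (additive null built
#' from single-agent parameters). Ratios below 1 indicate supra-additive
#' (synergistic) killing; above 1, sub-additive.
#'
#' @param observed Numeric vector of observed densities at
#'   `design$times`.
#' @param params A [growth_params()] describing the single-agent fits.
#' @param design An [exposure_design()] for the combination arm.
#' @return Numeric vector `observed / predicted` per time point.
#' @export
additivity_ratio <- function(observed, params, design) {
  p1 <- params
  p1$psi <- 1
  pred <- simulate_growth(p1, design)$N
  if (any(pred == 0)) stop("additive prediction is zero")
  if (length(observed) != length(pred)) {
    stop("observed length does not match design times")
  }
  observed / pred
}

## predictions for a proliferation table (one row per observation)
.growth_predict_table <- function(pars, data) {
  gp <- growth_params(
    k_G = pars$k_G, K_maxB = pars$K_maxB, K_maxP = pars$K_maxP,
    KC50_B = pars$KC50_B, KC50_P = pars$KC50_P,
    tau_B = pars$tau_B, tau_P = pars$tau_P,
    n_transit = pars$n_transit, psi = pars$psi)
  key <- interaction(data$conc_BRP_nM, data$conc_PTX_nM, drop = TRUE)
  pred <- numeric(nrow(data))
  for (k in levels(key)) {
    idx <- key == k
    des <- exposure_design(C_B = data$conc_BRP_nM[idx][1],
                           C_P = data$conc_PTX_nM[idx][1],
                           times = data$time_h[idx], N0 = 1)
    ## exposure_design sorts times; map back to row order
    sim <- simulate_growth(gp, des)
    pred[idx] <- sim$N[match(data$time_h[idx], sim$time_h)]
  }
  pred
}

#' Fit the growth model to a proliferation table
#'
#' Fits the cell-growth kinetic model to a table of normalized cell
#' densities over a concentration grid by maximum likelihood under an
#' affine-proportional variance model. Estimation is sequential, mirroring
#' the model's causal structure: the control arm determines `k_G`, each
#' single-agent series determines that drug's `K_max` and `KC50` (with
#' `psi` fixed at 1), and the combination arms determine `psi`; a final
#' joint refinement then frees all parameters simultaneously. The transit
#' depth is either fixed or chosen by AIC over candidate depths.
#'
#' @param data `data.frame` with columns `time_h`, `conc_PTX_nM`,
#'   `conc_BRP_nM`, `replicate`, `density_norm`. A vehicle control arm
#'   (both concentrations zero) is required.
#' @param vspec Variance model for the densities (default
#'   affine-proportional, `delta = 0.05`, `sigma = 0.1`).
#' @param n_transit Integer transit depth, or `"auto"` to select 0-5 by
#'   AIC.
#' @param tau Mean transit time used for both drugs' chains (h).
#' @param psi_free If `FALSE`, `psi` is held at 1 (additivity).
#' @param joint If `TRUE` (default) a joint refinement over all free
#'   parameters follows the sequential stages.
#' @param seed Seed for the optimizer multi-starts.
#' @param n_starts Optimizer starts per stage.
#' @return A `fit_result` for the final (joint or psi) stage, with extra
#'   fields: `params` (a [growth_params()] with all estimates),
#'   `n_transit` (depth used), `psi_ci95` (asymptotic 95\% confidence
#'   interval for `psi`, when free) and `stage_fits`.
#' @export
fit_growth <- function(data,
                       vspec = variance_spec("affine_proportional",
                                             delta = 0.05, sigma = 0.1),
                       n_transit = 3L, tau = 24, psi_free = TRUE,
                       joint = TRUE, seed = 1L, n_starts = 3L) {
  req <- c("time_h", "conc_PTX_nM", "conc_BRP_nM", "density_norm")
  stopifnot(all(req %in% names(data)))
  is_ctrl <- data$conc_PTX_nM == 0 & data$conc_BRP_nM == 0
  if (!any(is_ctrl)) stop("proliferation table lacks a vehicle control arm")
  is_P <- data$conc_PTX_nM > 0 & data$conc_BRP_nM == 0
  is_B <- data$conc_BRP_nM > 0 & data$conc_PTX_nM == 0
  is_BP <- data$conc_PTX_nM > 0 & data$conc_BRP_nM > 0

  if (identical(n_transit, "auto")) {
    fits <- lapply(0:5, function(nt) {
      fit_growth(data, vspec = vspec, n_transit = nt, tau = tau,
                 psi_free = psi_free, joint = joint, seed = seed,
                 n_starts = n_starts)
    })
    depth <- select_transit_depth(fits, depths = 0:5)
    out <- fits[[depth + 1L]]
    out$depth_aics <- vapply(fits, function(f) f$aic, numeric(1))
    return(out)
  }
  n_transit <- as.integer(n_transit)

  base_fixed <- list(tau_B = tau, tau_P = tau, n_transit = n_transit)
  dummy <- list(K_maxB = 0.02, K_maxP = 0.02, KC50_B = 100, KC50_P = 10,
                psi = 1)

  ## stage 1: control arm -> k_G
  ctrl <- data[is_ctrl, ]
  fit_kG <- fit_ml(
    function(p) .growth_predict_table(p, ctrl),
    ctrl$density_norm,
    free = list(k_G = list(start = 0.02, lower = 0)),
    fixed = c(base_fixed, dummy),
    vspec = vspec, seed = seed, n_starts = n_starts)
  kG_hat <- fit_kG$estimates$k_G
  stage_fits <- list(control = fit_kG)
  est <- list(k_G = kG_hat, K_maxB = NA, K_maxP = NA,
              KC50_B = NA, KC50_P = NA, psi = if (psi_free) NA else 1)

  ## stage 2: single-agent arms -> per-drug Hill parameters
  have_P <- any(is_P)
  have_B <- any(is_B)
  if (have_P) {
    dP <- data[is_P, ]
    fit_P <- fit_ml(
      function(p) .growth_predict_table(p, dP),
      dP$density_norm,
      free = list(K_maxP = list(start = 0.02, lower = 0),
                  KC50_P = list(start = stats::median(dP$conc_PTX_nM),
                                lower = 0)),
      fixed = c(base_fixed, list(k_G = kG_hat, K_maxB = 0.02,
                                 KC50_B = 100, psi = 1)),
      vspec = vspec, seed = seed + 1L, n_starts = n_starts)
    est$K_maxP <- fit_P$estimates$K_maxP
    est$KC50_P <- fit_P$estimates$KC50_P
    stage_fits$PTX <- fit_P
  }
  if (have_B) {
    dB <- data[is_B, ]
    fit_B <- fit_ml(
      function(p) .growth_predict_table(p, dB),
      dB$density_norm,
      free = list(K_maxB = list(start = 0.02, lower = 0),
                  KC50_B = list(start = stats::median(dB$conc_BRP_nM),
                                lower = 0)),
      fixed = c(base_fixed, list(k_G = kG_hat, K_maxP = 0.02,
                                 KC50_P = 10, psi = 1)),
      vspec = vspec, seed = seed + 2L, n_starts = n_starts)
    est$K_maxB <- fit_B$estimates$K_maxB
    est$KC50_B <- fit_B$estimates$KC50_B
    stage_fits$BRP <- fit_B
  }
  if (!have_P || !have_B) {
    if (!any(is_BP) && !have_P && !have_B) {
      ## control-only table: growth rate is identifiable, kill is not
      fit_kG$params <- growth_params(k_G = kG_hat, tau_B = tau,
                                     tau_P = tau, n_transit = n_transit,
                                     psi = 1)
      fit_kG$n_transit <- n_transit
      fit_kG$unidentifiable <- c("K_maxB", "K_maxP", "KC50_B", "KC50_P",
                                 "psi")
      fit_kG$stage_fits <- stage_fits
      return(fit_kG)
    }
  }

  ## stage 3: combination arms -> psi
  final_fit <- NULL
  if (psi_free && any(is_BP)) {
    dBP <- data[is_BP, ]
    fit_psi <- fit_ml(
      function(p) .growth_predict_table(p, dBP),
      dBP$density_norm,
      free = list(psi = list(start = 1, lower = 0)),
      fixed = c(base_fixed, est[c("k_G", "K_maxB", "K_maxP",
                                  "KC50_B", "KC50_P")]),
      vspec = vspec, seed = seed + 3L, n_starts = n_starts)
    est$psi <- fit_psi$estimates$psi
    stage_fits$psi <- fit_psi
    final_fit <- fit_psi
  } else {
    est$psi <- 1
    final_fit <- stage_fits[[length(stage_fits)]]
  }

  ## joint refinement over all arms
  if (joint) {
    all_free <- list(k_G = list(start = est$k_G, lower = 0))
    dflt <- function(x, d) if (is.null(x) || is.na(x)) d else x
    if (have_B || any(is_BP)) {
      all_free$K_maxB <- list(start = dflt(est$K_maxB, 0.02), lower = 0)
      all_free$KC50_B <- list(start = dflt(est$KC50_B, 100), lower = 0)
    }
    if (have_P || any(is_BP)) {
      all_free$K_maxP <- list(start = dflt(est$K_maxP, 0.02), lower = 0)
      all_free$KC50_P <- list(start = dflt(est$KC50_P, 10), lower = 0)
    }
    if (psi_free && any(is_BP)) {
      all_free$psi <- list(start = est$psi, lower = 0)
    }
    fixed_joint <- base_fixed
    if (!have_B && !any(is_BP)) {
      fixed_joint$K_maxB <- 0.02; fixed_joint$KC50_B <- 100
    }
    if (!have_P && !any(is_BP)) {
      fixed_joint$K_maxP <- 0.02; fixed_joint$KC50_P <- 10
    }
    if (!(psi_free && any(is_BP))) fixed_joint$psi <- 1
    final_fit <- fit_ml(
      function(p) .growth_predict_table(p, data),
      data$density_norm,
      free = all_free, fixed = fixed_joint,
      vspec = vspec, seed = seed + 4L, n_starts = 1L)
    est[names(all_free)] <- final_fit$estimates[names(all_free)]
  }

  dflt <- function(x, d) if (is.null(x) || is.na(x)) d else x
  final_fit$params <- growth_params(
    k_G = est$k_G,
    K_maxB = dflt(est$K_maxB, 0.02), K_maxP = dflt(est$K_maxP, 0.02),
    KC50_B = dflt(est$KC50_B, 100), KC50_P = dflt(est$KC50_P, 10),
    tau_B = tau, tau_P = tau, n_transit = n_transit, psi = est$psi)
  unident <- c("K_maxB", "KC50_B")[rep(!have_B && !any(is_BP), 2)]
  unident <- c(unident, c("K_maxP", "KC50_P")[rep(!have_P && !any(is_BP), 2)])
  if (length(unident) > 0L) final_fit$unidentifiable <- unident
  final_fit$n_transit <- n_transit
  final_fit$stage_fits <- stage_fits
  if (psi_free && any(is_BP)) {
    se <- NA_real_
    cv <- final_fit$cv_percent$psi
    if (!is.null(cv) && is.finite(cv)) se <- abs(est$psi) * cv / 100
    final_fit$psi_ci95 <- est$psi + c(-1, 1) * 1.96 * se
  }
  final_fit
}
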