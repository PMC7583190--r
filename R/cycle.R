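#' Cell-cycle/apoptosis model parameter set
#'
#' Parameters of the compartment model for cycling (G0/G1 -> S -> G2/M ->
#' division), mitotically arrested (MA), polyploid (PL) and apoptotic
#' (Apo) cells, and of its coupling to the protein network. Defaults are
#' the reference estimates for PANC-1 cells in 6-well plates.
#'
#' Division returns `2 * k31 * M` cells to G0/G1; the G0/G1 -> S
#' transition is slowed by Gompertz density inhibition
#' ([density_inhibition()]) with capacity `N_max` fold of the seeding
#' count `live0`. Cycling cells undergo spontaneous apoptosis at
#' `k_ap * cIAP1^gamma_cIAP_ap`; G2/M cells arrest at the ELYS-gated
#' rate ([mitotic_arrest_rate()]); arrested cells either die at the
#' protein-modulated rate ([arrested_apoptosis_rate()]) fed by a delayed
#' ASPP2 signal, or slip into the apoptosis-resistant polyploid pool at
#' `k_pl`. The apoptotic pool clears at the unmodified `k_ap`.
#'
#' The initial phase split of the seeded cells (`init_frac`) is a fitted
#' quantity in applications; the default reflects the partial
#' synchronization observed at treatment start — an elevated G2/M
#' fraction that relaxes over the first hours of culture — and was
#' calibrated once so the unperturbed model reproduces the reported
#' 72-h doubling-time trajectory (25.1 h at seeding rising to 53.6 h),
#' with G0/G1 and S at their balanced-growth proportions.
#'
#' @param k12,k23,k31 Phase transition rate constants (h^-1).
#' @param k_ap Spontaneous apoptosis rate constant (h^-1).
#' @param k_pl Mitotic-slippage (arrest -> polyploid) rate (h^-1).
#' @param k_ma0 Base mitotic-arrest rate constant (h^-1).
#' @param k_apm0 Base arrested-cell apoptosis rate constant (h^-1).
#' @param N_max Live-cell capacity as fold of seeding.
#' @param live0 Seeding count (cells/well).
#' @param gamma_cIAP_ap,gamma_cIAP_apm,gamma_BAX Power coefficients
#'   coupling protein fold-changes to apoptosis rates.
#' @param gamma_ELYS Power coefficient of ELYS on mitotic arrest (fixed
#'   at 3 in the reference model).
#' @param n_delay_ASPP2,tau_ASPP2 Transit-chain depth and mean transit
#'   time (h) of the delayed ASPP2 apoptosis signal.
#' @param init_frac Length-3 vector of initial G0/G1, S, G2/M fractions
#'   (must sum to 1).
#' @param apo0 Initial apoptotic count (cells).
#' @param elys_gate `"smooth"` (logistic gate of width `gate_width`, the
#'   default, for integrator stability) or `"exact"` (hard indicator
#'   `ELYS > 1`).
#' @param gate_width Width of the smooth ELYS gate.
#' @param pl_weight Relative protein content of a polyploid cell (used
#'   by the SRB correction; default 2).
#' @return Object of class `cycle_params`.
#' @export
cycle_params <- function(k12 = 4.48e-2, k23 = 0.129, k31 = 8.07e-2,
                         k_ap = 2.18e-3, k_pl = 1.97e-2,
                         k_ma0 = 2.39e-2, k_apm0 = 0.111,
                         N_max = 7.43, live0 = 2.0e5,
                         gamma_cIAP_ap = -0.532,
                         gamma_cIAP_apm = -7.72e-2,
                         gamma_BAX = 0.208, gamma_ELYS = 3,
                         n_delay_ASPP2 = 3L, tau_ASPP2 = 24,
                         init_frac = c(G1 = 0.283, S = 0.167, M = 0.550),
                         apo0 = 0,
                         elys_gate = c("smooth", "exact"),
                         gate_width = 1e-3, pl_weight = 2) {
  elys_gate <- match.arg(elys_gate)
  stopifnot(k12 > 0, k23 > 0, k31 > 0, k_ap > 0, k_pl > 0, k_ma0 > 0,
            k_apm0 > 0, N_max > 1, live0 > 0, gamma_ELYS > 0,
            gamma_cIAP_ap < 0, gamma_cIAP_apm < 0,
            n_delay_ASPP2 >= 1, tau_ASPP2 > 0,
            length(init_frac) == 3L,
            abs(sum(init_frac) - 1) < 1e-8, all(init_frac >= 0),
            apo0 >= 0, pl_weight > 0)
  structure(list(k12 = k12, k23 = k23, k31 = k31, k_ap = k_ap,
                 k_pl = k_pl, k_ma0 = k_ma0, k_apm0 = k_apm0,
                 N_max = N_max, live0 = live0,
                 gamma_cIAP_ap = gamma_cIAP_ap,
                 gamma_cIAP_apm = gamma_cIAP_apm,
                 gamma_BAX = gamma_BAX, gamma_ELYS = gamma_ELYS,
                 n_delay_ASPP2 = as.integer(n_delay_ASPP2),
                 tau_ASPP2 = tau_ASPP2,
                 init_frac = stats::setNames(init_frac,
                                             c("G1", "S", "M")),
                 apo0 = apo0, elys_gate = elys_gate,
                 gate_width = gate_width, pl_weight = pl_weight),
            class = "cycle_params")
}

#' Gompertz density inhibition
#'
#' `I0 = ln(N_max * live0) - ln(live)`: the log-distance of the current
#' live-cell count from the culture's capacity. It multiplies the
#' G0/G1 -> S transition rate, so proliferation slows smoothly to zero
#' as the culture approaches confluency.
#'
#' @param live Current live-cell count (> 0).
#' @param N_max Capacity as fold of seeding.
#' @param live0 Seeding count.
#' @return Dimensionless inhibition factor (0 at capacity).
#' @export
density_inhibition <- function(live, N_max, live0) {
  if (any(live <= 0)) stop("live-cell count must be positive")
  log(N_max * live0) - log(live)
}

#' ELYS-gated mitotic arrest rate
#'
#' `k_ma = k_ma0 * ELYS^gamma_ELYS` when the ELYS fold-change exceeds
#' baseline, and 0 otherwise: mitotic arrest only engages when the
#' spindle/kinetochore response is above its unperturbed level. The hard
#' indicator can optionally be smoothed with a narrow logistic gate for
#' use inside ODE integration.
#'
#' @param ELYS ELYS fold-change (> 0).
#' @param k_ma0 Base arrest rate constant (h^-1).
#' @param gamma_ELYS Power coefficient (> 0).
#' @param gate `"exact"` indicator or `"smooth"` logistic gate.
#' @param gate_width Logistic width for the smooth gate.
#' @return Arrest rate (h^-1).
#' @export
mitotic_arrest_rate <- function(ELYS, k_ma0, gamma_ELYS = 3,
                                gate = c("exact", "smooth"),
                                gate_width = 1e-3) {
  if (any(ELYS <= 0)) stop("ELYS fold-change must be positive")
  gate <- match.arg(gate)
  g <- if (gate == "exact") {
    as.numeric(ELYS > 1)
  } else {
    ## logistic ramp displaced by 6 widths so the gate is effectively
    ## closed (< 0.3% open) at the ELYS = 1 baseline
    stats::plogis((ELYS - 1) / gate_width - 6)
  }
  k_ma0 * ELYS^gamma_ELYS * g
}

#' Protein-modulated apoptosis rate of mitotically arrested cells
#'
#' `k_apm = k_apm0 * ASPP2_delayed * cIAP1^gamma_cIAP_apm *
#' BAX^gamma_BAX / Bcl2`. Pro-apoptotic inputs (delayed ASPP2, BAX)
#' raise the rate; anti-apoptotic inputs (cIAP1, Bcl2) suppress it, so
#' drug-induced loss of cIAP1 or Bcl2 accelerates death of arrested
#' cells.
#'
#' @param ASPP2_delayed Output of the ASPP2 transit chain (> 0).
#' @param cIAP,BAX,Bcl2 Protein fold-changes (> 0).
#' @param k_apm0 Base rate constant (h^-1).
#' @param gamma_cIAP_apm,gamma_BAX Power coefficients.
#' @return Apoptosis rate of arrested cells (h^-1).
#' @export
arrested_apoptosis_rate <- function(ASPP2_delayed, cIAP, BAX, Bcl2,
                                    k_apm0 = 0.111,
                                    gamma_cIAP_apm = -7.72e-2,
                                    gamma_BAX = 0.208) {
  if (any(c(ASPP2_delayed, cIAP, BAX, Bcl2) <= 0)) {
    stop("protein inputs must be positive")
  }
  k_apm0 * ASPP2_delayed * cIAP^gamma_cIAP_apm * BAX^gamma_BAX / Bcl2
}

#' Right-hand side of the cell-cycle/apoptosis ODEs
#'
#' @param state Named vector with `G1`, `S`, `M`, `MA`, `PL`, `Apo` and
#'   delay states `D1..Dn`.
#' @param params A [cycle_params()].
#' @param proteins Named vector of protein fold-changes (at least
#'   `cIAP1`, `BAX`, `Bcl2`, `ELYS`, `ASPP2`); defaults to all-baseline.
#' @return List with the derivative vector and the instantaneous rates
#'   `k_ma`, `k_apm` (as attributes of the first element's names, see
#'   [simulate_cycle()] for tabulated output).
#' @export
cycle_rhs <- function(state, params, proteins = NULL) {
  if (is.null(proteins)) {
    proteins <- c(cIAP1 = 1, BAX = 1, Bcl2 = 1, ELYS = 1, ASPP2 = 1)
  }
  if (any(proteins <= 0)) stop("non-positive protein input")
  G1 <- state[["G1"]]; S <- state[["S"]]; M <- state[["M"]]
  MA <- state[["MA"]]; PL <- state[["PL"]]; Apo <- state[["Apo"]]
  n <- params$n_delay_ASPP2
  D <- state[paste0("D", seq_len(n))]
  live <- G1 + S + M + MA + PL
  I0 <- density_inhibition(live, params$N_max, params$live0)
  k_ap_mod <- params$k_ap * proteins[["cIAP1"]]^params$gamma_cIAP_ap
  k_ma <- mitotic_arrest_rate(proteins[["ELYS"]], params$k_ma0,
                              params$gamma_ELYS,
                              gate = params$elys_gate,
                              gate_width = params$gate_width)
  k_apm <- arrested_apoptosis_rate(D[[n]], proteins[["cIAP1"]],
                                   proteins[["BAX"]], proteins[["Bcl2"]],
                                   params$k_apm0, params$gamma_cIAP_apm,
                                   params$gamma_BAX)
  dG1 <- 2 * params$k31 * M - params$k12 * I0 * G1 - k_ap_mod * G1
  dS <- params$k12 * I0 * G1 - params$k23 * S - k_ap_mod * S
  dM <- params$k23 * S - params$k31 * M - k_ma * M - k_ap_mod * M
  dMA <- k_ma * M - (k_apm + params$k_pl) * MA
  dPL <- params$k_pl * MA
  dApo <- k_ap_mod * (G1 + S + M) + k_apm * MA - params$k_ap * Apo
  krate <- n / params$tau_ASPP2
  Dprev <- c(proteins[["ASPP2"]], D[-n])
  dD <- (Dprev - D) * krate
  list(deriv = stats::setNames(c(dG1, dS, dM, dMA, dPL, dApo, dD),
                               names(state)),
       k_ma = k_ma, k_apm = k_apm, I0 = I0)
}

#' Doubling-time approximation for the cycle model
#'
#' `1/(k12 * I0) + 1/k23 + 1/(2 * k31)`: the sum of the mean residence
#' times in G0/G1 (slowed by density inhibition evaluated at the current
#' live count), S, and half of G2/M (division doubles the cohort).
#'
#' @param live Live-cell count, strictly between 0 and capacity.
#' @param params A [cycle_params()].
#' @return Doubling time (h).
#' @examples
#' doubling_time_cycle(2e5, cycle_params())  # ~25.1 h at seeding density
#' @export
doubling_time_cycle <- function(live, params) {
  I0 <- density_inhibition(live, params$N_max, params$live0)
  if (any(I0 <= 0)) stop("live count at or above capacity")
  1 / (params$k12 * I0) + 1 / params$k23 + 1 / (2 * params$k31)
}

#' Simulate the linked cell-cycle/apoptosis and protein network model
#'
#' Co-integrates the ten-protein network and the six-compartment cycle
#' model (plus the ASPP2 delay chain) under a constant treatment, and
#' tabulates the observables quantified by flow cytometry: phase
#' percentages among live cells (with G2/M and arrested cells pooled as
#' 4N), the polyploid and apoptotic percentages, and total cell count.
#'
#' @param params A [cycle_params()].
#' @param network A [network_params()].
#' @param trt A [treatment()].
#' @param times Output times (h).
#' @param context Plate context passed to [plate_context()] (`"well6"`
#'   leaves parameters unchanged).
#' @param rtol,atol Integrator tolerances.
#' @return `data.frame` with columns `time_h`, compartment counts,
#'   `live`, `total_cells`, percentage observables, the protein-coupled
#'   rates `k_ma` and `k_apm`, and the SRB correction factor `CF`.
#' @export
simulate_cycle <- function(params, network = network_params(),
                           trt = treatment(), times = seq(0, 72, by = 1),
                           context = c("well6", "well96"),
                           rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(params, "cycle_params"),
            inherits(network, "network_params"))
  params <- plate_context(params, match.arg(context))
  times <- sort(unique(c(0, times)))
  n <- params$n_delay_ASPP2
  effects <- effective_drug_effects(network, trt)

  y0 <- c(rep(1, 10),
          params$init_frac * params$live0,
          0, 0, params$apo0, rep(1, n))
  names(y0) <- c(.network_proteins, "G1", "S", "M", "MA", "PL", "Apo",
                 paste0("D", seq_len(n)))
  rhs <- function(t, y, parms) {
    prot <- y[.network_proteins]
    dprot <- network_rhs(prot, network, trt, effects = effects)
    cyc <- cycle_rhs(y[-(1:10)], params, proteins = prot)
    list(c(dprot, cyc$deriv), k_ma = cyc$k_ma, k_apm = cyc$k_apm)
  }
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 20000)
  if (attr(sol, "istate")[1L] < 0) stop("cycle ODE integration failed")
  out <- as.data.frame(sol)
  names(out)[1L] <- "time_h"
  live <- out$G1 + out$S + out$M + out$MA + out$PL
  out$live <- live
  out$total_cells <- live + out$Apo
  out$pct_G0G1 <- 100 * out$G1 / live
  out$pct_S <- 100 * out$S / live
  out$pct_4N <- 100 * (out$M + out$MA) / live
  out$pct_polyploid <- 100 * out$PL / live
  out$pct_apoptotic <- 100 * out$Apo / (live + out$Apo)
  out$CF <- correction_factor(live - out$PL, out$PL,
                              weight = params$pl_weight)
  out
}

#' Michaelis-Menten occupancy relative to a reference exposure
#'
#' Back-calculates the half-maximal concentration implied by a
#' fractional effect `E_ref` observed at `C_ref`
#' (`XC50 = C_ref * (1 - E_ref) / E_ref`) and returns the occupancy
#' `C / (C + XC50)` at concentration `C`.
#'
#' @param C Concentration(s) at which to evaluate occupancy (nM, >= 0).
#' @param C_ref Reference concentration (> 0).
#' @param E_ref Fractional effect at the reference, in (0, 1).
#' @return Occupancy in [0, 1).
#' @export
mm_occupancy <- function(C, C_ref, E_ref) {
  if (E_ref <= 0 || E_ref >= 1) stop("E_ref must lie in (0, 1)")
  stopifnot(C_ref > 0, all(C >= 0))
  XC50 <- C_ref * (1 - E_ref) / E_ref
  C / (C + XC50)
}

#' Michaelis-Menten extrapolation of a fitted drug effect
#'
#' Converts a drug-effect magnitude fitted at one reference
#' concentration into a concentration-dependent Michaelis-Menten law so
#' the model can be extrapolated across a concentration grid.
#'
#' For a fractional inhibition (`mode = "inhibition_unit_max"`, effect
#' in (0, 1) with implicit maximum 1) the implied `IC50` is
#' `C_ref * (1 - E_ref) / E_ref` and the extrapolated effect is
#' `C / (C + IC50)`. For an unbounded stimulation
#' (`mode = "stimulation"`) the reference exposure is treated as
#' 96.7\%-saturating — mirroring the fractional saturation of the
#' reference inhibition case — so `EC50 = C_ref * (1 - 0.967) / 0.967`
#' and `E_max = E_ref / 0.967`; the extrapolated effect
#' `E_max * C / (C + EC50)` then reproduces `E_ref` exactly at `C_ref`.
#'
#' @param E_ref Fitted effect magnitude at the reference concentration.
#' @param C_ref Reference concentration (nM, > 0).
#' @param C Concentration(s) at which to evaluate the effect (>= 0).
#' @param mode `"inhibition_unit_max"` or `"stimulation"`.
#' @param saturation Fractional saturation assumed at the reference for
#'   stimulation mode (default 0.967).
#' @return Extrapolated effect magnitude(s); 0 at `C = 0`.
#' @examples
#' mm_extrapolate(0.967, 100, 3.41)  # 0.5: half-maximal at the IC50
#' @export
mm_extrapolate <- function(E_ref, C_ref, C,
                           mode = c("inhibition_unit_max", "stimulation"),
                           saturation = 0.967) {
  mode <- match.arg(mode)
  stopifnot(C_ref > 0, all(C >= 0))
  if (mode == "inhibition_unit_max") {
    if (E_ref <= 0 || E_ref >= 1) {
      stop("inhibition effect must lie in (0, 1)")
    }
    IC50 <- C_ref * (1 - E_ref) / E_ref
    C / (C + IC50)
  } else {
    stopifnot(E_ref >= 0, saturation > 0, saturation < 1)
    EC50 <- C_ref * (1 - saturation) / saturation
    E_max <- E_ref / saturation
    E_max * C / (C + EC50)
  }
}

#' Implied half-maximal concentration of a fitted fractional effect
#'
#' @param E_ref Fractional effect in (0, 1) at `C_ref`.
#' @param C_ref Reference concentration (nM).
#' @return The implied IC50/EC50 (nM).
#' @examples
#' mm_ic50(0.967, 100)  # 3.41 nM
#' @export
mm_ic50 <- function(E_ref, C_ref) {
  if (E_ref <= 0 || E_ref >= 1) stop("E_ref must lie in (0, 1)")
  C_ref * (1 - E_ref) / E_ref
}

#' Plate-context adjustment of cycle parameters
#'
#' Cell-growth experiments in 96-well plates start much further from
#' confluency than the 6-well cytometry experiments the model was fitted
#' in, so the capacity is raised to `N_max = 30` and the base mitotic
#' arrest rate is reduced by 0.3-fold (`k_ma0 * 0.7`). Values are set
#' absolutely from the reference estimates, so the adjustment is
#' idempotent.
#'
#' @param params A [cycle_params()].
#' @param context `"well6"` (identity) or `"well96"`.
#' @return Adjusted [cycle_params()].
#' @export
plate_context <- function(params, context = c("well6", "well96")) {
  context <- match.arg(context)
  if (context == "well6") return(params)
  params$N_max <- 30
  params$k_ma0 <- 2.39e-2 * 0.7
  params
}

#' Balanced-growth phase distribution
#'
#' Dominant-eigenvector phase split of the linear cycle system
#' (G0/G1 -> S -> G2/M -> division) evaluated at a given live count:
#' the distribution an unsynchronized exponentially growing culture
#' relaxes to. Useful as a principled initial condition when no
#' synchronization information is available.
#'
#' @param params A [cycle_params()].
#' @param live Live count at which to evaluate density inhibition
#'   (default: seeding).
#' @return Named fractions `G1`, `S`, `M` summing to 1.
#' @export
balanced_phase_distribution <- function(params, live = params$live0) {
  a <- params$k12 * density_inhibition(live, params$N_max, params$live0)
  b <- params$k23
  c_ <- params$k31
  A <- matrix(c(-a, 0, 2 * c_,
                a, -b, 0,
                0, b, -c_), nrow = 3, byrow = TRUE)
  eg <- eigen(A)
  i <- which.max(Re(eg$values))
  v <- abs(Re(eg$vectors[, i]))
  stats::setNames(v / sum(v), c("G1", "S", "M"))
}

## predictions for a flow-cytometry summary table; returns the stacked
## vector (percentages then counts) matching .cycle_obs_vector()
.cycle_predict <- function(pars, data, base_cycle, base_network, arms) {
  cp <- base_cycle
  for (nm in intersect(names(pars),
                       c("k12", "k23", "k31", "k_ap", "k_pl", "k_ma0",
                         "k_apm0", "N_max", "gamma_cIAP_ap",
                         "gamma_cIAP_apm", "gamma_BAX", "tau_ASPP2"))) {
    cp[[nm]] <- pars[[nm]]
  }
  if (!is.null(pars$f_G1)) {
    f1 <- pars$f_G1
    f2 <- (1 - f1) * pars$f_S_rel
    cp$init_frac <- stats::setNames(c(f1, f2, 1 - f1 - f2),
                                    c("G1", "S", "M"))
  }
  pred <- NULL
  for (a in arms) {
    sub <- data[data$arm == a, ]
    sub <- sub[order(sub$time_h), ]
    tt <- sort(unique(sub$time_h))
    sim <- simulate_cycle(cp, base_network, .arm_treatment(a), times = tt)
    m <- match(sub$time_h, sim$time_h)
    pred_pct <- c(sim$pct_G0G1[m], sim$pct_S[m], sim$pct_4N[m],
                  sim$pct_polyploid[m], sim$pct_apoptotic[m])
    pred_cnt <- sim$total_cells[m]
    pred <- c(pred, pred_pct, pred_cnt)
  }
  pred
}

.cycle_obs_vector <- function(data, arms) {
  obs <- NULL
  grp <- NULL
  for (a in arms) {
    sub <- data[data$arm == a, ]
    sub <- sub[order(sub$time_h), ]
    obs <- c(obs, sub$pct_G0G1, sub$pct_S, sub$pct_4N,
             sub$pct_polyploid, sub$pct_apoptotic, sub$total_cells)
    grp <- c(grp, rep(1L, 5 * nrow(sub)), rep(2L, nrow(sub)))
  }
  list(obs = obs, groups = grp)
}

#' Fit the cell-cycle/apoptosis model
#'
#' Two-stage sequential fit. Stage 1 uses the unperturbed vehicle
#' control to estimate the system parameters (phase transition rates,
#' spontaneous apoptosis, capacity, and the initial phase split); stage
#' 2 freezes those and the protein network, and estimates the
#' drug-linked parameters (arrest, arrested-apoptosis, slippage and the
#' protein power coefficients) from the treated arms. Percentages use a
#' constant error model; total counts use an affine-proportional model.
#'
#' @param control_data `data.frame` for the vehicle arm with columns
#'   `time_h`, `arm` (== "control"), `pct_G0G1`, `pct_S`, `pct_4N`,
#'   `pct_polyploid`, `pct_apoptotic`, `total_cells`.
#' @param drug_data Same layout for treated arms (`B`, `P`, `BP`), or
#'   `NULL` to fit the control stage only.
#' @param params Starting [cycle_params()]; fixed values are taken from
#'   here.
#' @param network Fixed [network_params()] (estimated upstream).
#' @param free_control Names of stage-1 free parameters.
#' @param free_drug Names of stage-2 free parameters.
#' @param delta_pct Constant error SD for percentages (points).
#' @param delta_n,sigma_n Affine-proportional error terms for counts.
#' @param seed,n_starts Optimizer controls.
#' @return List with `control` and (if fitted) `drug` `fit_result`s and
#'   `params`, the updated [cycle_params()].
#' @export
fit_cycle <- function(control_data, drug_data = NULL,
                      params = cycle_params(),
                      network = network_params(),
                      free_control = c("k12", "k23", "k31", "k_ap",
                                       "N_max", "f_G1", "f_S_rel"),
                      free_drug = c("k_ma0", "k_apm0", "k_pl",
                                    "gamma_cIAP_ap"),
                      delta_pct = 2, delta_n = 5e3, sigma_n = 0.05,
                      seed = 1L, n_starts = 3L) {
  if (is.null(control_data) || nrow(control_data) == 0L) {
    stop("control arm data is required")
  }
  vs <- list(variance_spec("constant", delta = delta_pct),
             variance_spec("affine_proportional", delta = delta_n,
                           sigma = sigma_n))
  start_of <- list(
    k12 = list(start = params$k12, lower = 0),
    k23 = list(start = params$k23, lower = 0),
    k31 = list(start = params$k31, lower = 0),
    k_ap = list(start = params$k_ap, lower = 0),
    k_pl = list(start = params$k_pl, lower = 0),
    k_ma0 = list(start = params$k_ma0, lower = 0),
    k_apm0 = list(start = params$k_apm0, lower = 0),
    N_max = list(start = params$N_max, lower = 1),
    f_G1 = list(start = unname(params$init_frac["G1"]), lower = 0.01,
                upper = 0.95),
    f_S_rel = list(start = unname(params$init_frac["S"] /
                                    (1 - params$init_frac["G1"])),
                   lower = 0.01, upper = 0.99),
    gamma_cIAP_ap = list(start = params$gamma_cIAP_ap, upper = 0),
    gamma_cIAP_apm = list(start = params$gamma_cIAP_apm, upper = 0),
    gamma_BAX = list(start = params$gamma_BAX),
    tau_ASPP2 = list(start = params$tau_ASPP2, lower = 1))

  ov <- .cycle_obs_vector(control_data, "control")
  fit_ctrl <- fit_ml(
    function(p) .cycle_predict(p, control_data, params, network,
                               "control"),
    ov$obs, free = start_of[free_control], fixed = list(),
    vspec = vs, groups = ov$groups, seed = seed, n_starts = n_starts)

  cp <- params
  for (nm in intersect(names(fit_ctrl$estimates),
                       c("k12", "k23", "k31", "k_ap", "N_max"))) {
    cp[[nm]] <- fit_ctrl$estimates[[nm]]
  }
  if (!is.null(fit_ctrl$estimates$f_G1)) {
    f1 <- fit_ctrl$estimates$f_G1
    f2 <- (1 - f1) * fit_ctrl$estimates$f_S_rel
    cp$init_frac <- stats::setNames(c(f1, f2, 1 - f1 - f2),
                                    c("G1", "S", "M"))
  }
  out <- list(control = fit_ctrl, params = cp)

  if (!is.null(drug_data) && nrow(drug_data) > 0L) {
    arms <- unique(as.character(drug_data$arm))
    ovd <- .cycle_obs_vector(drug_data, arms)
    fit_drug <- fit_ml(
      function(p) .cycle_predict(p, drug_data, cp, network, arms),
      ovd$obs, free = start_of[free_drug], fixed = list(),
      vspec = vs, groups = ovd$groups, seed = seed + 1L,
      n_starts = n_starts)
    for (nm in intersect(names(fit_drug$estimates),
                         c("k_pl", "k_ma0", "k_apm0", "gamma_cIAP_ap",
                           "gamma_cIAP_apm", "gamma_BAX",
                           "tau_ASPP2"))) {
      cp[[nm]] <- fit_drug$estimates[[nm]]
    }
    out$drug <- fit_drug
    out$params <- cp
  }
  out
}
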