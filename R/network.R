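## The ten modeled proteins, in state-vector order.
.network_proteins <- c("cIAP1", "pNFkB", "BAX", "Bcl2", "IRAK4",
                       "pJNK", "pSTAT3", "VDAC1", "ELYS", "ASPP2")

#' Protein-network parameter set
#'
#' Parameters of the indirect-response network for the ten modeled
#' proteins. Each protein's fold-change `P_i` (1 = vehicle-matched
#' baseline) turns over as
#' `dP_i/dt = k_syn_i * (drug factors) * prod_j P_j^gamma_ij - k_deg_i *
#' (1 - Inh_deg_i) * P_i`, with `k_syn_i = k_deg_i` so the drug-free
#' baseline is exactly 1. Regulatory edges act multiplicatively on the
#' synthesis term as power laws `P_j^gamma`; drug effects enter as
#' `(1 + Sti)` or `(1 - Inh)` synthesis factors, except the combination
#' effect on pJNK which fully inhibits its degradation.
#'
#' Default values are the reference maximum-likelihood estimates for
#' PANC-1 cells exposed to 100 nM birinapant (B) and/or 10 nM paclitaxel
#' (P): turnover constants `k_deg` (h^-1), edge power coefficients
#' `gamma`, and drug-effect magnitudes `sti_IRAK4 = 0.960` (any
#' treatment), `inh_cIAP1_B = 0.967` (B), `sti_ELYS_P = 2.22` (P) and
#' `inh_pJNK_deg_BP = 1` (combination only).
#'
#' @param k_deg Named numeric vector of degradation rate constants
#'   (h^-1) for all ten proteins.
#' @param gamma `data.frame` with columns `target`, `regulator`,
#'   `gamma` describing the synthesis-side power-law edges.
#' @param sti_IRAK4,inh_cIAP1_B,sti_ELYS_P,inh_pJNK_deg_BP Drug-effect
#'   magnitudes (see Details).
#' @return Object of class `network_params`.
#' @export
network_params <- function(
    k_deg = c(cIAP1 = 0.649, pNFkB = 0.649, BAX = 2.91e-2, Bcl2 = 0.649,
              IRAK4 = 0.127, pJNK = 8.26e-3, pSTAT3 = 3.16e-2,
              VDAC1 = 0.696, ELYS = 2.80e-2, ASPP2 = 0.861),
    gamma = default_network_edges(),
    sti_IRAK4 = 0.960, inh_cIAP1_B = 0.967, sti_ELYS_P = 2.22,
    inh_pJNK_deg_BP = 1.0) {
  stopifnot(all(.network_proteins %in% names(k_deg)),
            all(k_deg[.network_proteins] > 0),
            all(c("target", "regulator", "gamma") %in% names(gamma)),
            all(gamma$target %in% .network_proteins),
            all(gamma$regulator %in% .network_proteins),
            sti_IRAK4 >= 0, sti_ELYS_P >= 0,
            inh_cIAP1_B >= 0, inh_cIAP1_B <= 1,
            inh_pJNK_deg_BP >= 0, inh_pJNK_deg_BP <= 1)
  structure(list(k_deg = k_deg[.network_proteins], gamma = gamma,
                 sti_IRAK4 = sti_IRAK4, inh_cIAP1_B = inh_cIAP1_B,
                 sti_ELYS_P = sti_ELYS_P,
                 inh_pJNK_deg_BP = inh_pJNK_deg_BP),
            class = "network_params")
}

#' Default regulatory edge table
#'
#' The eleven synthesis-side power-law edges of the ten-protein network
#' with their reference power coefficients. Negative coefficients invert
#' the regulator's effect (an inhibitor falling below baseline raises the
#' target's synthesis); self-edges with large negative coefficients
#' implement bounded auto-feedback for BAX and ELYS.
#'
#' @return `data.frame` with columns `target`, `regulator`, `gamma`.
#' @export
default_network_edges <- function() {
  data.frame(
    target    = c("pNFkB", "BAX",   "Bcl2",  "pSTAT3", "VDAC1", "ASPP2",
                  "Bcl2",  "Bcl2",  "pSTAT3", "BAX",  "ELYS"),
    regulator = c("cIAP1", "pNFkB", "pNFkB", "IRAK4",  "pJNK",  "ELYS",
                  "pSTAT3", "VDAC1", "pJNK",  "BAX",  "ELYS"),
    gamma     = c(-0.298,  1.85,    0.768,   1.0,      1.0,     1.0,
                  1.33,    -4.16,   -2.30,   -9.55,  -6.10),
    stringsAsFactors = FALSE)
}

#' Treatment description
#'
#' Which drugs are present, and at what constant concentrations. The
#' reference fits correspond to 100 nM birinapant and 10 nM paclitaxel;
#' concentrations only matter when the Michaelis-Menten extrapolation
#' layer is enabled (see [effective_drug_effects()]). Combination-only
#' effects are active iff both drugs are present.
#'
#' @param has_B,has_P Logical flags for birinapant / paclitaxel.
#' @param C_B,C_P Concentrations (nM); defaults are the reference
#'   exposures.
#' @param extrapolate If `TRUE`, drug-effect magnitudes are scaled from
#'   their reference values to `C_B`/`C_P` via Michaelis-Menten
#'   occupancy (see [mm_extrapolate()]).
#' @return Object of class `pd_treatment`.
#' @export
treatment <- function(has_B = FALSE, has_P = FALSE,
                      C_B = if (has_B) 100 else 0,
                      C_P = if (has_P) 10 else 0,
                      extrapolate = FALSE) {
  stopifnot(is.logical(has_B), is.logical(has_P), C_B >= 0, C_P >= 0)
  structure(list(has_B = has_B, has_P = has_P, C_B = C_B, C_P = C_P,
                 extrapolate = extrapolate),
            class = "pd_treatment")
}

#' Drug-effect magnitudes for a treatment
#'
#' Returns the active stimulation/inhibition magnitudes for a treatment.
#' At the reference exposures (100 nM B, 10 nM P) these equal the fitted
#' constants. When `treatment$extrapolate` is `TRUE` the concentration-
#' dependent effects are rescaled by Michaelis-Menten occupancy relative
#' to the reference concentration ([mm_extrapolate()]); the IRAK4
#' stimulation is dose-independent, and the combination effect on pJNK
#' degradation scales as the product of the two drugs' occupancies.
#'
#' @param params A [network_params()].
#' @param trt A [treatment()].
#' @return Named list `sti_IRAK4`, `inh_cIAP1`, `sti_ELYS`,
#'   `inh_pJNK_deg`.
#' @export
effective_drug_effects <- function(params, trt) {
  any_drug <- trt$has_B || trt$has_P
  eff <- list(
    sti_IRAK4 = if (any_drug) params$sti_IRAK4 else 0,
    inh_cIAP1 = if (trt$has_B) params$inh_cIAP1_B else 0,
    sti_ELYS = if (trt$has_P) params$sti_ELYS_P else 0,
    inh_pJNK_deg = if (trt$has_B && trt$has_P) params$inh_pJNK_deg_BP
                   else 0)
  if (isTRUE(trt$extrapolate)) {
    occ_B <- if (trt$has_B) {
      mm_occupancy(trt$C_B, C_ref = 100, E_ref = params$inh_cIAP1_B)
    } else 0
    occ_P <- if (trt$has_P) {
      mm_occupancy(trt$C_P, C_ref = 10, E_ref = 0.967)
    } else 0
    eff$inh_cIAP1 <- if (trt$has_B) occ_B else 0
    eff$sti_ELYS <- if (trt$has_P) {
      params$sti_ELYS_P / 0.967 * occ_P
    } else 0
    eff$inh_pJNK_deg <- if (trt$has_B && trt$has_P) {
      params$inh_pJNK_deg_BP * occ_B * occ_P
    } else 0
    ## sti_IRAK4 deliberately left dose-independent
  }
  eff
}

#' Right-hand side of the protein network ODEs
#'
#' @param state Named numeric vector of strictly positive fold-changes
#'   for the ten proteins.
#' @param params A [network_params()].
#' @param trt A [treatment()] (or precomputed effect list via
#'   `effects`).
#' @param effects Optional precomputed [effective_drug_effects()] list.
#' @return Named derivative vector (h^-1).
#' @export
network_rhs <- function(state, params, trt, effects = NULL) {
  if (any(state <= 0)) {
    stop("non-positive protein fold-change; power-law terms undefined")
  }
  if (is.null(effects)) effects <- effective_drug_effects(params, trt)
  p <- state[.network_proteins]
  kd <- params$k_deg
  ## synthesis-side regulation: log-domain accumulation of power laws
  reg <- rep(0, length(p))
  names(reg) <- .network_proteins
  g <- params$gamma
  logp <- log(p)
  for (i in seq_len(nrow(g))) {
    reg[g$target[i]] <- reg[g$target[i]] + g$gamma[i] * logp[g$regulator[i]]
  }
  syn_fac <- rep(1, length(p))
  names(syn_fac) <- .network_proteins
  syn_fac["IRAK4"] <- 1 + effects$sti_IRAK4
  syn_fac["cIAP1"] <- 1 - effects$inh_cIAP1
  syn_fac["ELYS"] <- syn_fac["ELYS"] * (1 + effects$sti_ELYS)
  deg_fac <- rep(1, length(p))
  names(deg_fac) <- .network_proteins
  deg_fac["pJNK"] <- 1 - effects$inh_pJNK_deg
  kd * syn_fac * exp(reg) - kd * deg_fac * p
}

#' Simulate the protein network
#'
#' Integrates the ten-protein indirect-response network from the
#' all-baseline state (every fold-change 1) under a constant treatment.
#'
#' @param params A [network_params()].
#' @param trt A [treatment()].
#' @param times Output times (h); 0 is prepended if absent.
#' @param log2 If `TRUE`, return log2 fold-changes.
#' @param rtol,atol Integrator tolerances.
#' @return `data.frame` with `time_h` and one column per protein.
#' @export
simulate_network <- function(params, trt, times = seq(0, 72, by = 0.5),
                             log2 = FALSE, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "network_params"))
  times <- sort(unique(c(0, times)))
  effects <- effective_drug_effects(params, trt)
  y0 <- rep(1, length(.network_proteins))
  names(y0) <- .network_proteins
  rhs <- function(t, y, parms) {
    list(network_rhs(y, params, trt, effects = effects))
  }
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0) stop("network ODE integration failed")
  out <- as.data.frame(sol)
  names(out)[1L] <- "time_h"
  if (log2) out[.network_proteins] <- log2(out[.network_proteins])
  out
}

#' Protein half-life from a turnover constant
#'
#' @param k_deg Positive first-order degradation rate constant (h^-1).
#' @return `log(2) / k_deg` in hours.
#' @examples
#' half_life(0.649)    # ~1.07 h (fast turnover)
#' half_life(2.80e-2)  # ~24.8 h (slow turnover)
#' @export
half_life <- function(k_deg) {
  if (any(k_deg <= 0)) stop("degradation rate constant must be positive")
  log(2) / k_deg
}

## simulate one protein across arms and return log2 predictions aligned
## with a (protein, arm, time) data subset
.network_predict <- function(pars, data_sub, base_params) {
  prm <- .apply_network_estimates(base_params, pars)
  arms <- unique(data_sub$arm)
  pred <- numeric(nrow(data_sub))
  for (a in arms) {
    trt <- .arm_treatment(a)
    idx <- data_sub$arm == a
    tt <- sort(unique(data_sub$time_h[idx]))
    sim <- simulate_network(prm, trt, times = tt, log2 = TRUE)
    for (pn in unique(data_sub$protein[idx])) {
      sel <- idx & data_sub$protein == pn
      pred[sel] <- sim[[pn]][match(data_sub$time_h[sel], sim$time_h)]
    }
  }
  pred
}

.arm_treatment <- function(arm) {
  switch(as.character(arm),
         control = treatment(FALSE, FALSE),
         B = treatment(TRUE, FALSE),
         P = treatment(FALSE, TRUE),
         BP = treatment(TRUE, TRUE),
         stop("unknown treatment arm: ", arm))
}

#' Fit the protein network to expression profiles
#'
#' Fits the indirect-response network to log2 fold-change time series by
#' sequential maximum likelihood under a constant error model. Stages
#' follow the network's causal order: drug-proximal proteins first
#' (cIAP1, IRAK4, ELYS, pJNK), then their direct targets (pNF-kB, ASPP2,
#' VDAC1, pSTAT3), then the convergent mitochondrial branch (BAX, Bcl2).
#' Parameters estimated in one stage are frozen downstream. The three
#' reference-fixed unit power coefficients (pSTAT3<-IRAK4, VDAC1<-pJNK,
#' ASPP2<-ELYS) and the complete combination block of pJNK degradation
#' are held fixed throughout.
#'
#' @param profiles `data.frame` with columns `protein`, `arm` (one of
#'   `"B"`, `"P"`, `"BP"`; a `"control"` arm is allowed and ignored by
#'   the staged fits), `time_h`, `replicate`, `value` (log2
#'   fold-change).
#' @param delta_p Constant error SD on the log2 scale (default 0.2).
#' @param params Starting/structural [network_params()]; fixed values
#'   are taken from here.
#' @param stages Character vector choosing which stages to run (default
#'   all, in causal order). Running a subset is useful for targeted
#'   recovery checks; stages always receive upstream estimates from the
#'   stages run before them.
#' @param seed,n_starts Optimizer controls.
#' @return Named list of `fit_result` objects (one per stage) with an
#'   attribute `params` holding the updated [network_params()].
#' @export
fit_network <- function(profiles, delta_p = 0.2,
                        params = network_params(),
                        stages = c("cIAP1", "IRAK4", "ELYS", "pJNK",
                                   "pNFkB", "ASPP2", "VDAC1", "pSTAT3",
                                   "BAX", "Bcl2"),
                        seed = 1L, n_starts = 3L) {
  req <- c("protein", "arm", "time_h", "value")
  stopifnot(all(req %in% names(profiles)))
  vs <- variance_spec("constant", delta = delta_p)
  need_arms <- c("B", "P", "BP")
  have <- unique(as.character(profiles$arm))
  missing_arms <- setdiff(need_arms, have)
  if (length(missing_arms) > 0L) {
    stop("profiles lack required arms: ",
         paste(missing_arms, collapse = ", "))
  }

  ## current working parameter set; updated as stages complete
  cur <- params

  stage_def <- list(
    cIAP1 = list(arms = c("B", "BP"),
                 free = list(kdeg_fast = list(start = 0.5, lower = 0),
                             inh_cIAP1_B = list(start = 0.9, lower = 0,
                                                upper = 1))),
    IRAK4 = list(arms = c("B", "P", "BP"),
                 free = list(kdeg_IRAK4 = list(start = 0.1, lower = 0),
                             sti_IRAK4 = list(start = 1, lower = 0))),
    ELYS = list(arms = c("P", "BP"),
                free = list(kdeg_ELYS = list(start = 0.03, lower = 0),
                            sti_ELYS_P = list(start = 2, lower = 0),
                            gamma_ELYS_ELYS = list(start = -5))),
    pJNK = list(arms = "BP",
                free = list(kdeg_pJNK = list(start = 0.01, lower = 0))),
    pNFkB = list(arms = c("B", "BP"),
                 free = list(gamma_pNFkB_cIAP1 = list(start = -0.3))),
    ASPP2 = list(arms = c("P", "BP"),
                 free = list(kdeg_ASPP2 = list(start = 0.5, lower = 0))),
    VDAC1 = list(arms = "BP",
                 free = list(kdeg_VDAC1 = list(start = 0.5, lower = 0))),
    pSTAT3 = list(arms = c("B", "P", "BP"),
                  free = list(kdeg_pSTAT3 = list(start = 0.03, lower = 0),
                              gamma_pSTAT3_pJNK = list(start = -2))),
    BAX = list(arms = c("B", "BP"),
               free = list(kdeg_BAX = list(start = 0.03, lower = 0),
                           gamma_BAX_pNFkB = list(start = 2),
                           gamma_BAX_BAX = list(start = -8))),
    Bcl2 = list(arms = c("B", "P", "BP"),
                free = list(gamma_Bcl2_pNFkB = list(start = 0.8),
                            gamma_Bcl2_pSTAT3 = list(start = 1),
                            gamma_Bcl2_VDAC1 = list(start = -4)))
  )
  stages <- match.arg(stages, names(stage_def), several.ok = TRUE)

  results <- list()
  for (snm in stages) {
    sd_ <- stage_def[[snm]]
    sub <- profiles[profiles$protein == snm &
                      profiles$arm %in% sd_$arms, , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop("no data for stage ", snm, " in arms ",
           paste(sd_$arms, collapse = "/"))
    }
    base <- cur  # freeze upstream estimates
    fit <- fit_ml(
      function(p) .network_predict(p, sub, base),
      sub$value, free = sd_$free, fixed = list(),
      vspec = vs, seed = seed + length(results), n_starts = n_starts)
    results[[snm]] <- fit
    ## fold estimates into the working parameter set
    cur <- .apply_network_estimates(cur, fit$estimates)
  }
  attr(results, "params") <- cur
  results
}

.apply_network_estimates <- function(prm, est) {
  for (nm in names(est)) {
    val <- est[[nm]]
    if (nm == "kdeg_fast") {
      prm$k_deg[c("cIAP1", "pNFkB", "Bcl2")] <- val
    } else if (startsWith(nm, "kdeg_")) {
      prm$k_deg[sub("^kdeg_", "", nm)] <- val
    } else if (startsWith(nm, "gamma_")) {
      bits <- strsplit(sub("^gamma_", "", nm), "_")[[1]]
      hit <- prm$gamma$target == bits[1] & prm$gamma$regulator == bits[2]
      prm$gamma$gamma[hit] <- val
    } else if (nm %in% c("sti_IRAK4", "inh_cIAP1_B", "sti_ELYS_P",
                         "inh_pJNK_deg_BP")) {
      prm[[nm]] <- val
    }
  }
  prm
}
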