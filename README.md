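# synergypd

Multi-scale pharmacodynamic modeling of cytotoxic drug synergy in
cultured cancer cells.

## The problem

When two cytotoxic drugs are combined — here the SMAC-mimetic
birinapant (BRP), which promotes apoptosis by degrading cIAP1, and
paclitaxel (PTX), which arrests mitosis — cell-growth assays can show
that the combination kills more than additivity predicts, but not
*why*. `synergypd` implements a three-scale modeling chain that first
quantifies the interaction empirically and then explains it
mechanistically:

1. **Cell-growth kill model.** Exponential growth (rate `k_G`) with
   additive, transit-delayed Hill killing per drug:

   `dN/dt = k_G·N − (S_B + S_P)·N`,  `S_x = K_max,x·C_x/(Ψ·KC50,x + C_x)`

   passed through an `n`-stage transit chain (mean delay τ). The
   interaction term Ψ scales both drugs' `KC50` in combination arms:
   Ψ < 1 is synergy (the reference estimate Ψ = 0.69 is a 31% potency
   gain for each drug), Ψ = 1 additivity, Ψ > 1 antagonism.
2. **Ten-protein indirect-response network.** Fold-changes of cIAP1,
   pNF-κB, BAX, Bcl2, IRAK4, pJNK, pSTAT3, VDAC1, ELYS and ASPP2 obey
   turnover equations `dP/dt = k_syn·(drug factors)·Π P_j^γ − k_deg·P`
   with `k_syn = k_deg` (baseline ≡ 1) and power-law regulatory edges.
3. **Cell-cycle/apoptosis compartments.** G0/G1 → S → G2/M → division
   with Gompertz density inhibition, protein-modulated spontaneous
   apoptosis (`k_ap·cIAP1^γ`), ELYS-gated mitotic arrest, mitotic
   slippage to an apoptosis-resistant polyploid pool, and
   arrested-cell death at
   `k_apm0·ASPP2_delayed·cIAP1^γ·BAX^γ/Bcl2`.

Estimation is maximum likelihood with the study's heteroscedastic
variance models (`Var = (δ + σ·Y)²` for counts/densities, constant
error for log2 fold-changes and percentages), AIC selection of the
transit depth, and sequential fix-upstream/fit-downstream staging.
A proteomics module provides quantile normalization, control-matched
log2 fold-changes and seeded temporal k-means clustering; a
synthetic-data module regenerates every input from the models and
their noise structure, so the full pipeline runs without any external
data.

## Worked example

```r
library(synergypd)

gp <- growth_params()          # reference PANC-1 estimates
doubling_time(gp$k_G)
#> [1] 30.80654

## Observed/predicted ratios under an additivity null: simulate a
## combination arm with the fitted interaction (psi = 0.69) and compare
## with the psi = 1 prediction - ratios sink below 1 as synergy emerges
des <- exposure_design(C_B = 250, C_P = 10, times = c(24, 48, 72, 96, 120))
obs <- simulate_growth(gp, des)$N
round(additivity_ratio(obs, growth_params(psi = 1), des), 3)
#> [1] 0.981 0.918 0.846 0.779 0.716

## Protein network under the combination: cIAP1 collapses to 1 - Inh_B,
## pNF-kB rises ~2.8-fold, pJNK creeps up linearly (degradation fully
## blocked), and Bcl2 falls below baseline only after 24 h
net <- simulate_network(network_params(), treatment(has_B = TRUE, has_P = TRUE),
                        times = c(6, 24, 48, 72))
round(subset(net, time_h > 0)[, c("time_h", "cIAP1", "pNFkB", "Bcl2", "pJNK")], 3)
#>   time_h cIAP1 pNFkB  Bcl2  pJNK
#> 2      6 0.053 2.065 1.405 1.050
#> 3     24 0.033 2.764 1.385 1.198
#> 4     48 0.033 2.764 0.683 1.396
#> 5     72 0.033 2.764 0.308 1.595

## Unperturbed cell-cycle model over 72 h: the doubling-time
## approximation 1/(k12*I0) + 1/k23 + 1/(2*k31) lengthens from 25.1 h
## to 53.6 h as the culture densifies, with ~8% apoptotic cells
cyc <- simulate_cycle(cycle_params(), times = c(0, 72))
round(doubling_time_cycle(cyc$live[cyc$time_h == 72], cycle_params()), 1)
#> [1] 53.6
round(cyc$pct_apoptotic[cyc$time_h == 72], 2)
#> [1] 7.89

## Michaelis-Menten conversion of a fitted effect for extrapolation:
## 96.7% cIAP1 inhibition at 100 nM implies IC50 = 3.41 nM
mm_ic50(0.967, 100)
#> [1] 3.412616
```

The numbers mean: untreated cells double every ~31 h; under the
250/10 nM combination, measured growth falls to 72% of the additive
prediction by day 5; birinapant erases cIAP1 within hours
(de-repressing NF-κB) while only the combination drives the
pro-survival protein Bcl2 below baseline — the mechanistic signature
of the synergy; and the fitted constant drug effects convert to
concentration-dependent laws for predicting untested dose pairs
(`predict_grid()`).

An end-to-end synthetic run (generate → cluster → fit → predict →
report) is available via
`run_pipeline(run_config("out_dir", seed = 1))`.

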