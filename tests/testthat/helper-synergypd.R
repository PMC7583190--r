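## Reference ODE integration of the growth model (independent oracle for
## the closed-form solution): integrates the transit chain and cell
## number with deSolve at tight tolerance.
growth_ode_oracle <- function(params, design, rtol = 1e-10,
                              atol = 1e-12) {
  n <- params$n_transit
  combo <- design$C_B > 0 && design$C_P > 0
  psi <- if (combo) params$psi else 1
  S0B <- if (design$C_B > 0) {
    killing_signal(design$C_B, params$K_maxB, params$KC50_B, psi)
  } else 0
  S0P <- if (design$C_P > 0) {
    killing_signal(design$C_P, params$K_maxP, params$KC50_P, psi)
  } else 0
  y0 <- c(N = design$N0, SB = rep(0, n), SP = rep(0, n))
  rhs <- function(t, y, p) {
    N <- y[1]
    SB <- if (n > 0) y[2:(n + 1)] else S0B
    SP <- if (n > 0) y[(n + 2):(2 * n + 1)] else S0P
    outB <- if (n > 0) SB[n] else S0B
    outP <- if (n > 0) SP[n] else S0P
    dN <- params$k_G * N - (outB + outP) * N
    dSB <- if (n > 0) (c(S0B, SB[-n]) - SB) * (n / params$tau_B) else NULL
    dSP <- if (n > 0) (c(S0P, SP[-n]) - SP) * (n / params$tau_P) else NULL
    list(c(dN, dSB, dSP))
  }
  tt <- sort(unique(c(0, design$times)))
  sol <- deSolve::lsoda(y0, tt, rhs, parms = NULL, rtol = rtol,
                        atol = atol)
  sol[match(design$times, sol[, "time"]), "N"]
}

## small noise-free proliferation table over a reduced grid
make_growth_table <- function(params = growth_params(),
                              conc_P = c(5, 20, 60),
                              conc_B = c(60, 1000),
                              combos = data.frame(C_B = c(60, 1000),
                                                  C_P = c(10, 20)),
                              times = c(24, 48, 72, 96, 120)) {
  arms <- data.frame(C_B = 0, C_P = 0)
  if (length(conc_P) > 0) {
    arms <- rbind(arms, data.frame(C_B = 0, C_P = conc_P))
  }
  if (length(conc_B) > 0) {
    arms <- rbind(arms, data.frame(C_B = conc_B, C_P = 0))
  }
  if (nrow(combos) > 0) arms <- rbind(arms, combos)
  do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
    des <- exposure_design(C_B = arms$C_B[i], C_P = arms$C_P[i],
                           times = times)
    data.frame(time_h = times, conc_PTX_nM = arms$C_P[i],
               conc_BRP_nM = arms$C_B[i], replicate = 1L,
               density_norm = simulate_growth(params, des)$N)
  }))
}
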