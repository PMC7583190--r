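#' Synthetic-study specification
#'
#' Bundles the ground-truth parameter sets, experimental design and
#' noise models used to generate every input the analysis pipeline
#' consumes. Defaults reproduce the reference study conditions: a 6 x 4
#' single-agent concentration grid of paclitaxel (2.5-60 nM) and
#' birinapant (15-1000 nM) plus their 24 pairwise combinations sampled
#' at 24-120 h in triplicate for growth; vehicle and reference-exposure
#' arms at 0/17/48/72 h for cytometry; and 6/24/48/72 h protein
#' profiles. Noise magnitudes follow the fitted variance models
#' (affine-proportional for densities and counts; constant on the log2
#' scale for fold-changes; constant in percentage points for cytometry
#' fractions).
#'
#' @param seed Integer seed; a fixed seed makes every generator
#'   deterministic.
#' @param growth_params Ground-truth [growth_params()].
#' @param network Ground-truth [network_params()].
#' @param cycle Ground-truth [cycle_params()].
#' @param conc_PTX,conc_BRP Single-agent concentration levels (nM).
#' @param combo_grid `data.frame` with `C_B`, `C_P` for the combination
#'   arms; default all 24 pairs of the 6 PTX x 4 BRP sub-grids.
#' @param growth_times,cycle_times,protein_times Sampling times (h).
#' @param n_replicates Replicates per arm/time.
#' @param delta,sigma Affine-proportional noise on normalized density.
#' @param delta_p Constant log2-scale SD for protein fold-changes.
#' @param delta_pct Constant SD (percentage points) for cytometry
#'   fractions.
#' @param delta_n,sigma_n Affine-proportional noise for cell counts.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           growth_params = synergypd::growth_params(),
                           network = network_params(),
                           cycle = cycle_params(),
                           conc_PTX = c(2.5, 5, 10, 20, 40, 60),
                           conc_BRP = c(15, 60, 250, 1000),
                           combo_grid = NULL,
                           growth_times = c(24, 48, 72, 96, 120),
                           cycle_times = c(0, 17, 48, 72),
                           protein_times = c(6, 24, 48, 72),
                           n_replicates = 3L,
                           delta = 0.05, sigma = 0.1,
                           delta_p = 0.2, delta_pct = 2,
                           delta_n = 5e3, sigma_n = 0.05) {
  if (is.null(combo_grid)) {
    combo_grid <- expand.grid(C_B = c(15, 60, 250, 1000),
                              C_P = c(2.5, 5, 10, 20, 40, 60))
  }
  stopifnot(n_replicates >= 1L, delta >= 0, sigma >= 0, delta_p >= 0,
            delta_pct >= 0, delta_n >= 0, sigma_n >= 0)
  structure(list(seed = as.integer(seed), growth_params = growth_params,
                 network = network, cycle = cycle,
                 conc_PTX = conc_PTX, conc_BRP = conc_BRP,
                 combo_grid = combo_grid, growth_times = growth_times,
                 cycle_times = cycle_times,
                 protein_times = protein_times,
                 n_replicates = as.integer(n_replicates),
                 delta = delta, sigma = sigma, delta_p = delta_p,
                 delta_pct = delta_pct, delta_n = delta_n,
                 sigma_n = sigma_n),
            class = "synthetic_spec")
}

## positive Gaussian draw: redraw (not clip) to avoid a point mass at 0
.rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0 & sd > 0)
  tries <- 0L
  while (length(bad) > 0L && tries < 100L) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] <= 0]
    tries <- tries + 1L
  }
  if (length(bad) > 0L) x[bad] <- abs(x[bad])  # pathological sd >> mean
  x
}

#' Generate a synthetic proliferation table
#'
#' Simulates the growth model over the full single-agent plus
#' combination concentration grid (including the vehicle control arm)
#' and perturbs the normalized densities with affine-proportional
#' Gaussian noise, truncated at zero by redraw.
#'
#' @param spec A [synthetic_spec()].
#' @return `data.frame` with columns `time_h`, `conc_PTX_nM`,
#'   `conc_BRP_nM`, `replicate`, `density_norm`.
#' @export
generate_growth_data <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rng_state <- .save_seed()
  on.exit(.restore_seed(rng_state), add = TRUE)
  set.seed(spec$seed)
  arms <- rbind(data.frame(C_B = 0, C_P = 0),
                data.frame(C_B = 0, C_P = spec$conc_PTX),
                data.frame(C_B = spec$conc_BRP, C_P = 0),
                spec$combo_grid[, c("C_B", "C_P")])
  rows <- list()
  for (i in seq_len(nrow(arms))) {
    des <- exposure_design(C_B = arms$C_B[i], C_P = arms$C_P[i],
                           times = spec$growth_times)
    mu <- simulate_growth(spec$growth_params, des)$N
    for (r in seq_len(spec$n_replicates)) {
      sd <- spec$delta + spec$sigma * mu
      y <- if (all(sd == 0)) mu else .rnorm_pos(length(mu), mu, sd)
      rows[[length(rows) + 1L]] <- data.frame(
        time_h = des$times, conc_PTX_nM = arms$C_P[i],
        conc_BRP_nM = arms$C_B[i], replicate = r, density_norm = y)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic flow-cytometry summary table
#'
#' Simulates the linked cycle/apoptosis model for the requested arms,
#' perturbs the cycle-phase percentages with constant-error noise and
#' renormalizes them to sum to 100, perturbs the apoptotic percentage
#' with constant error, and the total counts with affine-proportional
#' error.
#'
#' @param spec A [synthetic_spec()].
#' @param arms Character vector of arms (default control, B, P, BP at
#'   the reference exposures).
#' @return `data.frame` with columns `time_h`, `arm`, `conc_PTX_nM`,
#'   `conc_BRP_nM`, `pct_G0G1`, `pct_S`, `pct_4N`, `pct_polyploid`,
#'   `pct_apoptotic`, `total_cells`, `replicate`.
#' @export
generate_cycle_data <- function(spec, arms = c("control", "B", "P",
                                               "BP")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rng_state <- .save_seed()
  on.exit(.restore_seed(rng_state), add = TRUE)
  set.seed(spec$seed + 1L)
  rows <- list()
  for (a in arms) {
    trt <- .arm_treatment(a)
    sim <- simulate_cycle(spec$cycle, spec$network, trt,
                          times = spec$cycle_times)
    m <- match(spec$cycle_times, sim$time_h)
    for (r in seq_len(spec$n_replicates)) {
      pcts <- cbind(sim$pct_G0G1[m], sim$pct_S[m], sim$pct_4N[m],
                    sim$pct_polyploid[m])
      if (spec$delta_pct > 0) {
        noisy <- pcts + stats::rnorm(length(pcts), 0, spec$delta_pct)
        noisy[noisy < 0] <- 0
        noisy <- noisy / rowSums(noisy) * 100
      } else {
        noisy <- pcts
      }
      apo <- sim$pct_apoptotic[m] +
        stats::rnorm(length(m), 0, spec$delta_pct)
      apo <- pmin(pmax(apo, 0), 100)
      mu_n <- sim$total_cells[m]
      cnt <- if (spec$delta_n + spec$sigma_n == 0) mu_n else {
        .rnorm_pos(length(mu_n), mu_n,
                   spec$delta_n + spec$sigma_n * mu_n)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        time_h = spec$cycle_times, arm = a,
        conc_PTX_nM = trt$C_P, conc_BRP_nM = trt$C_B,
        pct_G0G1 = noisy[, 1], pct_S = noisy[, 2], pct_4N = noisy[, 3],
        pct_polyploid = noisy[, 4], pct_apoptotic = apo,
        total_cells = cnt, replicate = r, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate synthetic protein fold-change profiles
#'
#' Simulates the protein network for the B, P and BP reference arms,
#' samples the log2 fold-changes at the proteomics timepoints and adds
#' constant-error Gaussian noise on the log2 scale.
#'
#' @param spec A [synthetic_spec()].
#' @param arms Arms to generate (default B, P, BP).
#' @return `data.frame` with columns `protein`, `arm`, `time_h`,
#'   `replicate`, `value`.
#' @export
generate_protein_profiles <- function(spec, arms = c("B", "P", "BP")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rng_state <- .save_seed()
  on.exit(.restore_seed(rng_state), add = TRUE)
  set.seed(spec$seed + 2L)
  rows <- list()
  for (a in arms) {
    sim <- simulate_network(spec$network, .arm_treatment(a),
                            times = spec$protein_times, log2 = TRUE)
    m <- match(spec$protein_times, sim$time_h)
    for (pn in .network_proteins) {
      mu <- sim[[pn]][m]
      for (r in seq_len(spec$n_replicates)) {
        y <- mu + stats::rnorm(length(mu), 0, spec$delta_p)
        rows[[length(rows) + 1L]] <- data.frame(
          protein = pn, arm = a, time_h = spec$protein_times,
          replicate = r, value = y, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

## nine archetype responses: a temporal shape (on a unit time grid)
## paired with an arm-response pattern (relative response in the B, P
## and BP arms), emulating drug-selective protein groups: birinapant-
## driven, paclitaxel-driven, combination-only, any-treatment, and
## divergent responses, rising or falling, sustained or transient
.archetypes <- function(times) {
  u <- (times - min(times)) / diff(range(times))
  lin <- u
  fast <- 1 - exp(-5 * u)
  trans <- 6 * u * exp(-3 * u)
  sinb <- sin(pi * u)
  list(
    list(shape = lin,    arms = c(B = 1.0, P = 0,    BP = 1.1)),
    list(shape = lin,    arms = c(B = -1.0, P = 0,   BP = -1.1)),
    list(shape = trans,  arms = c(B = 0,   P = 1.0,  BP = 1.1)),
    list(shape = -lin,   arms = c(B = 0,   P = 1.0,  BP = 1.1)),
    list(shape = fast,   arms = c(B = 0,   P = 0,    BP = 1.2)),
    list(shape = -fast,  arms = c(B = 0,   P = 0,    BP = 1.2)),
    list(shape = sinb,   arms = c(B = 1.0, P = 1.0,  BP = 1.0)),
    list(shape = fast,   arms = c(B = 1.0, P = 1.0,  BP = 1.0)),
    list(shape = lin,    arms = c(B = 1.0, P = -1.0, BP = 0.3))
  )
}

#' Generate a synthetic full-size proteomics matrix
#'
#' Builds a protein-by-sample intensity matrix with planted temporal
#' cluster structure: `n_archetypes` archetype log2 fold-change shapes
#' are assigned to proteins in cluster sizes drawn from
#' `size_range`, applied to the drug arms on top of lognormal baseline
#' intensities with multiplicative lognormal measurement noise. Samples
#' are split into two acquisition batches with distinct monotone
#' intensity distortions, so the value of quantile normalization can be
#' demonstrated by ablation. Ground-truth labels are returned for
#' recovery scoring.
#'
#' @param spec A [synthetic_spec()].
#' @param n_proteins Number of proteins (default 3325).
#' @param n_archetypes Number of planted temporal clusters (default 9).
#' @param size_range Admissible cluster sizes (default `c(30, 508)`).
#' @param noise_sd Lognormal (log2-scale) measurement noise SD.
#' @param batch_distort If `TRUE` (default) batch 2 intensities are
#'   passed through a monotone power distortion.
#' @return List with `matrix` (a [proteomics_matrix()]) and `labels`
#'   (named integer vector of planted cluster ids).
#' @export
generate_cluster_matrix <- function(spec, n_proteins = 3325L,
                                    n_archetypes = 9L,
                                    size_range = c(30L, 508L),
                                    noise_sd = 0.25,
                                    batch_distort = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"),
            n_archetypes <= n_proteins,
            n_archetypes * size_range[2] >= n_proteins,
            n_archetypes * size_range[1] <= n_proteins)
  rng_state <- .save_seed()
  on.exit(.restore_seed(rng_state), add = TRUE)
  set.seed(spec$seed + 3L)

  ## cluster sizes within the admissible range, summing to n_proteins
  sizes <- rep(floor(n_proteins / n_archetypes), n_archetypes)
  sizes[seq_len(n_proteins - sum(sizes))] <-
    sizes[seq_len(n_proteins - sum(sizes))] + 1L
  jit <- stats::runif(n_archetypes, -0.35, 0.35) *
    (size_range[2] - size_range[1]) / 2
  sizes <- round(sizes + jit - mean(jit))
  sizes <- pmin(pmax(sizes, size_range[1]), size_range[2])
  while (sum(sizes) != n_proteins) {
    i <- sample.int(n_archetypes, 1L)
    step <- sign(n_proteins - sum(sizes))
    cand <- sizes[i] + step
    if (cand >= size_range[1] && cand <= size_range[2]) sizes[i] <- cand
  }
  labels <- rep(seq_len(n_archetypes), sizes)
  labels <- labels[sample.int(n_proteins)]

  times <- spec$protein_times
  arms <- c("control", "B", "P", "BP")
  n_rep <- 2L
  arch <- .archetypes(times)
  if (n_archetypes > length(arch)) {
    stop("at most ", length(arch), " archetypes are defined")
  }
  shape_mat <- t(vapply(arch, `[[`, numeric(length(times)), "shape"))
  arm_mat <- t(vapply(arch, `[[`, numeric(3L), "arms"))
  colnames(arm_mat) <- c("B", "P", "BP")

  ## two acquisition batches mirroring the source design: the drug arms
  ## form one experiment and the unperturbed control time course a
  ## separate one, so every control-matched fold-change crosses batches
  meta <- expand.grid(replicate = seq_len(n_rep), time_h = times,
                      arm = arms, stringsAsFactors = FALSE)
  meta$batch <- ifelse(meta$arm == "control", 2L, 1L)
  prot_ids <- sprintf("prot%04d", seq_len(n_proteins))
  base <- 2^stats::rnorm(n_proteins, 10, 2)  # lognormal baselines
  ## per-protein response amplitude jitter within a cluster
  amp <- stats::runif(n_proteins, 0.7, 1.3)

  vals <- matrix(NA_real_, n_proteins, nrow(meta),
                 dimnames = list(prot_ids, NULL))
  for (j in seq_len(nrow(meta))) {
    a <- meta$arm[j]
    arm_fac <- if (a == "control") 0 else arm_mat[labels, a]
    sh <- shape_mat[labels, match(meta$time_h[j], times)] * amp * arm_fac
    noise <- stats::rnorm(n_proteins, 0, noise_sd)
    x <- base * 2^(sh + noise)
    if (batch_distort && meta$batch[j] == 2L) {
      ## monotone, non-log-linear inter-batch distortion (detector-like
      ## response curvature): removable by quantile normalization but
      ## biases fold-changes in an intensity-dependent way if ignored
      l <- log2(x)
      x <- 2^(l + 0.08 * (l - 10)^2)
    }
    vals[, j] <- x
  }
  list(matrix = proteomics_matrix(vals, meta),
       labels = stats::setNames(labels, prot_ids))
}
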