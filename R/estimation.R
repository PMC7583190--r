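#' Variance model specification
#'
#' Observation-level variance models used by the maximum-likelihood
#' machinery. Two forms are supported: a constant error model with
#' `Var = delta^2` for every observation, and an affine-proportional model
#' with `Var = (delta + sigma * Y)^2` evaluated at the model prediction
#' `Y`. The constant model is appropriate for quantities already on a
#' stabilized scale (log2 fold-changes, cell-cycle percentages); the
#' affine-proportional model for cell counts and normalized densities
#' whose dispersion grows with the signal.
#'
#' @param kind One of `"constant"` or `"affine_proportional"`.
#' @param delta Non-negative additive error term.
#' @param sigma Non-negative proportional error term (only used by the
#'   affine-proportional model).
#' @return An object of class `variance_spec`.
#' @examples
#' vs <- variance_spec("affine_proportional", delta = 0.05, sigma = 0.1)
#' variance_at(vs, c(1, 10))
#' @export
variance_spec <- function(kind = c("constant", "affine_proportional"),
                          delta, sigma = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(delta), length(delta) == 1L, delta >= 0,
            is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  structure(list(kind = kind, delta = delta, sigma = sigma),
            class = "variance_spec")
}

#' Evaluate a variance model at model predictions
#'
#' @param vspec A [variance_spec()].
#' @param predictions Numeric vector of model-predicted values.
#' @return Vector of variances, one per prediction.
#' @export
variance_at <- function(vspec, predictions) {
  stopifnot(inherits(vspec, "variance_spec"))
  if (vspec$kind == "constant") {
    rep(vspec$delta^2, length(predictions))
  } else {
    (vspec$delta + vspec$sigma * predictions)^2
  }
}

#' Negative log-likelihood under independent Gaussian errors
#'
#' Computes `-sum(dnorm(obs, pred, sd_i, log = TRUE))` where the
#' per-observation standard deviation comes from the variance model
#' evaluated at the prediction. When several observation blocks carry
#' different error structures (e.g. percentages with constant error and
#' counts with affine-proportional error), supply a list of variance
#' specs and a `groups` index mapping each observation to its spec.
#'
#' @param predictions,observations Numeric vectors of equal length.
#' @param vspec A [variance_spec()], or a list of them.
#' @param groups Integer vector indexing into `vspec` when `vspec` is a
#'   list; ignored otherwise.
#' @return Scalar negative log-likelihood.
#' @export
neg_log_likelihood <- function(predictions, observations, vspec,
                               groups = NULL) {
  if (length(predictions) != length(observations)) {
    stop("predictions and observations must have equal length (",
         length(predictions), " vs ", length(observations), ")")
  }
  if (inherits(vspec, "variance_spec")) {
    v <- variance_at(vspec, predictions)
  } else {
    stopifnot(is.list(vspec), !is.null(groups),
              length(groups) == length(predictions))
    v <- numeric(length(predictions))
    for (g in unique(groups)) {
      idx <- groups == g
      v[idx] <- variance_at(vspec[[g]], predictions[idx])
    }
  }
  bad <- which(v <= 0)
  if (length(bad) > 0L) {
    stop("non-positive variance at observation index ", bad[1L])
  }
  sum(0.5 * log(2 * pi * v) + (observations - predictions)^2 / (2 * v))
}

#' Akaike information criterion
#'
#' @param loglik Maximized log-likelihood.
#' @param n_free Number of free parameters (non-negative).
#' @return `-2 * loglik + 2 * n_free`.
#' @export
aic <- function(loglik, n_free) {
  stopifnot(is.numeric(loglik), length(loglik) == 1L,
            n_free >= 0, n_free == round(n_free))
  -2 * loglik + 2 * n_free
}

## ---- parameter transforms ------------------------------------------------
## Rate constants and variance parameters are kept positive by optimizing
## on the log scale; doubly bounded parameters use a logit map; sign-free
## power coefficients are left untransformed.

.par_transform <- function(x, lower, upper) {
  if (is.finite(lower) && is.finite(upper)) {
    p <- (x - lower) / (upper - lower)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    log(p / (1 - p))
  } else if (is.finite(lower)) {
    log(pmax(x - lower, 1e-300))
  } else if (is.finite(upper)) {
    log(pmax(upper - x, 1e-300))
  } else {
    x
  }
}

.par_untransform <- function(z, lower, upper) {
  if (is.finite(lower) && is.finite(upper)) {
    lower + (upper - lower) / (1 + exp(-z))
  } else if (is.finite(lower)) {
    lower + exp(z)
  } else if (is.finite(upper)) {
    upper - exp(z)
  } else {
    z
  }
}

.free_table <- function(free) {
  ## normalize the `free` argument into a data.frame with
  ## name/start/lower/upper
  if (is.data.frame(free)) {
    stopifnot(all(c("name", "start") %in% names(free)))
    if (is.null(free$lower)) free$lower <- -Inf
    if (is.null(free$upper)) free$upper <- Inf
    return(free[, c("name", "start", "lower", "upper")])
  }
  stopifnot(is.list(free), !is.null(names(free)))
  out <- data.frame(name = names(free), start = NA_real_,
                    lower = -Inf, upper = Inf,
                    stringsAsFactors = FALSE)
  for (i in seq_along(free)) {
    fi <- free[[i]]
    if (is.numeric(fi) && length(fi) == 1L) {
      out$start[i] <- fi
    } else {
      out$start[i] <- fi$start
      if (!is.null(fi$lower)) out$lower[i] <- fi$lower
      if (!is.null(fi$upper)) out$upper[i] <- fi$upper
    }
  }
  out
}

#' Maximum-likelihood fit of a prediction function
#'
#' Minimizes [neg_log_likelihood()] over the free parameters of an
#' arbitrary deterministic prediction function using a multi-start
#' Nelder-Mead simplex with bound-enforcing transformations (log for
#' singly bounded, logit for doubly bounded parameters). Parameter
#' uncertainty (CV%) is obtained from the inverse of a finite-difference
#' observed-information matrix; this is the standard asymptotic
#' maximum-likelihood approximation.
#'
#' @param model_fn Function taking a named list/vector of parameters
#'   (free and fixed merged) and returning a numeric vector of
#'   predictions aligned with `observations`.
#' @param observations Numeric vector of observed values.
#' @param free Named list describing free parameters; each element is
#'   either a numeric start value or a list with `start`, `lower`,
#'   `upper`. Alternatively a data.frame with those columns plus `name`.
#' @param fixed Named list of parameters held fixed.
#' @param vspec A [variance_spec()] or list of them (see
#'   [neg_log_likelihood()]).
#' @param groups Observation-to-variance-spec index when `vspec` is a list.
#' @param seed Integer seed controlling the multi-start jitter.
#' @param n_starts Number of optimizer starts (first start is unjittered).
#' @param reltol Relative convergence tolerance on the objective.
#' @param maxit Maximum iterations per start.
#' @param jitter_sd Standard deviation of the start jitter on the
#'   transformed scale.
#' @return An object of class `fit_result` with elements `estimates`,
#'   `cv_percent`, `loglik`, `aic`, `n_obs`, `converged`, `residuals`
#'   (weighted), `fixed`, `n_free`, `vcov` and `run_log`.
#' @export
fit_ml <- function(model_fn, observations, free, fixed = list(),
                   vspec, groups = NULL, seed = 1L, n_starts = 5L,
                   reltol = 1e-8, maxit = 5000L, jitter_sd = 0.3) {
  ft <- .free_table(free)
  n_free <- nrow(ft)
  stopifnot(n_free >= 1L,
            all(ft$start >= ft$lower & ft$start <= ft$upper))
  obs <- as.numeric(observations)

  build_params <- function(z) {
    x <- vapply(seq_len(n_free), function(i) {
      .par_untransform(z[i], ft$lower[i], ft$upper[i])
    }, numeric(1))
    names(x) <- ft$name
    c(as.list(x), fixed)
  }
  objective <- function(z) {
    pars <- build_params(z)
    ## warnings are routine when the optimizer probes extreme parameter
    ## regions (e.g. stiff ODE excursions); only errors matter here
    pred <- tryCatch(suppressWarnings(model_fn(pars)),
                     error = function(e) NULL)
    if (is.null(pred) || anyNA(pred) || any(!is.finite(pred))) {
      return(1e10)
    }
    val <- tryCatch(neg_log_likelihood(pred, obs, vspec, groups),
                    error = function(e) 1e10)
    if (!is.finite(val)) 1e10 else val
  }

  z0 <- vapply(seq_len(n_free), function(i) {
    .par_transform(ft$start[i], ft$lower[i], ft$upper[i])
  }, numeric(1))

  rng_state <- .save_seed()
  on.exit(.restore_seed(rng_state), add = TRUE)
  set.seed(seed)
  best <- NULL
  run_log <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    zs <- if (s == 1L) z0 else z0 + stats::rnorm(n_free, 0, jitter_sd)
    opt <- if (n_free == 1L) {
      ## 1-D: coarse grid presearch (the likelihood can be flat far from
      ## the optimum, defeating golden-section search on a wide bracket),
      ## then golden-section/parabolic refinement inside the bracketing
      ## triple
      zg <- seq(zs - 15, zs + 15, length.out = 121L)
      fg <- vapply(zg, objective, numeric(1))
      i <- which.min(fg)
      lo <- zg[max(1L, i - 1L)]
      hi <- zg[min(length(zg), i + 1L)]
      o <- stats::optimize(objective, interval = c(lo, hi),
                           tol = 1e-12)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      stats::optim(zs, objective, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = maxit))
    }
    run_log[[s]] <- data.frame(start = s, objective = opt$value,
                               convergence = opt$convergence)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  ## polish the best solution with fresh simplexes until no improvement
  if (n_free > 1L) {
    for (rep in 1:3) {
      polish <- stats::optim(best$par, objective, method = "Nelder-Mead",
                             control = list(reltol = reltol,
                                            maxit = maxit))
      improved <- polish$value < best$value - 1e-10
      if (polish$value <= best$value) best <- polish
      if (!improved) break
    }
  }

  z_hat <- best$par
  pars_hat <- build_params(z_hat)
  est <- unlist(pars_hat[ft$name])
  pred <- model_fn(pars_hat)
  v <- if (inherits(vspec, "variance_spec")) {
    variance_at(vspec, pred)
  } else {
    vv <- numeric(length(pred))
    for (g in unique(groups)) {
      vv[groups == g] <- variance_at(vspec[[g]], pred[groups == g])
    }
    vv
  }
  wres <- (obs - pred) / sqrt(v)
  loglik <- -best$value
  converged <- best$convergence == 0L && best$value < 1e10

  ## observed information on the natural (untransformed) scale
  nll_nat <- function(x) {
    pars <- c(as.list(x), fixed)
    pred <- tryCatch(model_fn(pars), error = function(e) NULL)
    if (is.null(pred) || anyNA(pred)) return(NA_real_)
    tryCatch(neg_log_likelihood(pred, obs, vspec, groups),
             error = function(e) NA_real_)
  }
  hess <- .fd_hessian(nll_nat, est)
  cv <- rep(NA_real_, n_free)
  names(cv) <- ft$name
  vcov <- NULL
  if (!anyNA(hess)) {
    vcov <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vcov)) {
      dg <- diag(vcov)
      ok <- dg > 0
      cv[ok] <- 100 * sqrt(dg[ok]) / abs(est[ok])
    }
  }

  structure(list(
    estimates = as.list(est),
    cv_percent = as.list(cv),
    loglik = loglik,
    aic = aic(loglik, n_free),
    n_obs = length(obs),
    converged = converged,
    residuals = wres,
    fixed = fixed,
    n_free = n_free,
    vcov = vcov,
    run_log = do.call(rbind, run_log)
  ), class = "fit_result")
}

.fd_hessian <- function(fn, x, rel_step = 1e-4) {
  n <- length(x)
  h <- pmax(abs(x) * rel_step, 1e-7)
  H <- matrix(NA_real_, n, n)
  f0 <- fn(x)
  if (is.na(f0)) return(H)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
        H[i, j] <- H[j, i] <-
          (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_seed <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Maximum-likelihood fit (", x$n_free, " free parameter",
      if (x$n_free != 1L) "s", ", ", x$n_obs, " observations)\n", sep = "")
  cat("  -2LL = ", format(-2 * x$loglik, digits = 6),
      "   AIC = ", format(x$aic, digits = 6),
      "   converged: ", x$converged, "\n", sep = "")
  est <- unlist(x$estimates)
  cv <- unlist(x$cv_percent)
  tab <- data.frame(estimate = signif(est, 4),
                    `CV%` = signif(cv, 3), check.names = FALSE)
  print(tab)
  invisible(x)
}

#' Select transit-chain depth by AIC
#'
#' Given fits of the same model with increasing numbers of transit
#' compartments, returns the depth with the lowest AIC; ties are broken
#' toward the shallower (simpler) chain.
#'
#' @param fit_results List of `fit_result` objects ordered by depth, the
#'   first element corresponding to `depths[1]`.
#' @param depths Integer vector of candidate depths (default
#'   `0:(length(fit_results) - 1)`).
#' @return The selected depth (integer).
#' @export
select_transit_depth <- function(fit_results,
                                 depths = seq_along(fit_results) - 1L) {
  if (length(fit_results) == 0L) stop("empty fit_results list")
  stopifnot(length(depths) == length(fit_results))
  aics <- vapply(fit_results, function(f) f$aic, numeric(1))
  ord <- order(depths)
  aics <- aics[ord]
  depths <- depths[ord]
  depths[which.min(aics)]   # which.min takes the first (smallest depth) tie
}

#' Sequential (fix-upstream, fit-downstream) model fitting
#'
#' Fits an ordered chain of estimation stages. Parameters estimated in
#' earlier stages are frozen (added to `fixed`) for all later stages, so
#' upstream relationships constrain downstream ones without being
#' re-estimated. A stage may declare `needs`, a character vector of
#' parameter names that must already have been estimated (or supplied as
#' fixed); violation aborts before fitting, which catches mis-ordered
#' chains.
#'
#' @param stages List of stage descriptions. Each stage is a list with
#'   elements `model_fn`, `observations`, `free`, `vspec` and optionally
#'   `fixed`, `groups`, `needs`, `name`, `n_starts`.
#' @param seed Integer seed passed to each stage (offset by stage index).
#' @return List of `fit_result` objects, one per stage, named after the
#'   stages.
#' @export
sequential_fit <- function(stages, seed = 1L) {
  stopifnot(length(stages) >= 1L)
  carried <- list()
  results <- vector("list", length(stages))
  names(results) <- vapply(seq_along(stages), function(i) {
    nm <- stages[[i]]$name
    if (is.null(nm)) paste0("stage", i) else nm
  }, character(1))
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    fixed <- c(st$fixed %||% list(), carried)
    needs <- st$needs %||% character(0)
    missing_deps <- setdiff(needs, names(fixed))
    if (length(missing_deps) > 0L) {
      stop("stage ", names(results)[i], " requires upstream estimates: ",
           paste(missing_deps, collapse = ", "))
    }
    fit <- fit_ml(st$model_fn, st$observations, st$free, fixed = fixed,
                  vspec = st$vspec, groups = st$groups %||% NULL,
                  seed = seed + i, n_starts = st$n_starts %||% 5L)
    results[[i]] <- fit
    carried <- c(fit$estimates, carried)
    carried <- carried[!duplicated(names(carried))]
  }
  results
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a fit report to disk
#'
#' Writes a human-readable parameter table (name, estimate, CV%,
#' free/fixed) and a machine-readable run log (start index, objective,
#' convergence code) as CSV.
#'
#' @param fit A `fit_result`.
#' @param path Base path; `<path>.txt` and `<path>_runlog.csv` are written.
#' @param seed Seed recorded in the report header (optional).
#' @return Invisibly, the paths written.
#' @export
write_fit_report <- function(fit, path, seed = NA) {
  stopifnot(inherits(fit, "fit_result"))
  txt <- paste0(path, ".txt")
  csv <- paste0(path, "_runlog.csv")
  est <- unlist(fit$estimates)
  cv <- unlist(fit$cv_percent)
  fixed <- unlist(Filter(function(x) is.numeric(x) && length(x) == 1L,
                         fit$fixed))
  lines <- c(
    "Maximum-likelihood fit report",
    paste0("seed: ", seed),
    paste0("n_obs: ", fit$n_obs),
    paste0("loglik: ", format(fit$loglik, digits = 10)),
    paste0("AIC: ", format(fit$aic, digits = 10)),
    paste0("converged: ", fit$converged),
    "",
    sprintf("%-22s %14s %10s %7s", "parameter", "estimate", "CV%", "status"),
    sprintf("%-22s %14.6g %10.3g %7s", names(est), est, cv, "free")
  )
  if (length(fixed) > 0L) {
    lines <- c(lines,
               sprintf("%-22s %14.6g %10s %7s", names(fixed), fixed,
                       "-", "fixed"))
  }
  writeLines(lines, txt)
  utils::write.csv(fit$run_log, csv, row.names = FALSE)
  invisible(c(txt, csv))
}
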