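#' Protein expression matrix container
#'
#' Bundles a positive protein-by-sample intensity matrix with its sample
#' metadata (treatment arm, timepoint, replicate, acquisition batch).
#' Proteins with non-finite or non-positive intensities are dropped at
#' ingestion with a logged manifest; identification-level filters
#' (peptide counts, FDR) are assumed to have been applied upstream.
#'
#' @param values Numeric matrix, proteins in rows (rownames = protein
#'   ids), samples in columns.
#' @param sample_meta `data.frame` with one row per column of `values`
#'   and columns `arm` (one of control/B/P/BP), `time_h`, `replicate`,
#'   `batch`.
#' @return Object of class `proteomics_matrix` with elements `values`,
#'   `sample_meta`, `dropped` (character vector of excluded proteins).
#' @export
proteomics_matrix <- function(values, sample_meta) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            nrow(sample_meta) == ncol(values),
            all(c("arm", "time_h", "replicate", "batch") %in%
                  names(sample_meta)))
  ok <- apply(values, 1L, function(r) all(is.finite(r)) && all(r > 0))
  dropped <- rownames(values)[!ok]
  structure(list(values = values[ok, , drop = FALSE],
                 sample_meta = sample_meta,
                 dropped = dropped),
            class = "proteomics_matrix")
}

#' Quantile normalization across samples
#'
#' Forces every sample's intensity distribution onto the mean-quantile
#' reference of the pooled sample set (ranks preserved within sample,
#' ties averaged), removing monotone between-batch distortions. All
#' batches must carry the same protein set. Applying the normalization
#' twice equals applying it once.
#'
#' @param pmx A [proteomics_matrix()].
#' @return A [proteomics_matrix()] with normalized intensities.
#' @export
quantile_normalize <- function(pmx) {
  stopifnot(inherits(pmx, "proteomics_matrix"))
  if (length(unique(pmx$sample_meta$batch)) < 2L) {
    warning("single batch; quantile normalization applied anyway")
  }
  norm <- limma::normalizeQuantiles(pmx$values, ties = TRUE)
  dimnames(norm) <- dimnames(pmx$values)
  pmx$values <- norm
  pmx
}

#' Control-matched log2 fold-change profiles
#'
#' For every protein, treated arm and timepoint, computes
#' `log2(mean_treated / mean_control)` against the vehicle control at
#' the same timepoint (replicates averaged first). Alternatively each
#' arm can be normalized to its own pretreatment baseline
#' (`mode = "t0"`), which isolates within-arm kinetics at the cost of
#' retaining shared culture-age trends.
#'
#' @param pmx A [proteomics_matrix()].
#' @param mode `"control"` (vehicle-matched, the default) or `"t0"`.
#' @param arms Treated arms to profile (default all non-control arms
#'   present).
#' @return `data.frame` with columns `protein`, `arm`, `time_h`,
#'   `value` (log2 fold-change), of class `temporal_profiles`.
#' @export
log2_fold_change <- function(pmx, mode = c("control", "t0"),
                             arms = NULL) {
  stopifnot(inherits(pmx, "proteomics_matrix"))
  mode <- match.arg(mode)
  meta <- pmx$sample_meta
  vals <- pmx$values
  if (is.null(arms)) arms <- setdiff(unique(meta$arm), "control")
  times <- sort(unique(meta$time_h))
  if (mode == "control" && !any(meta$arm == "control")) {
    stop("control arm absent; cannot form vehicle-matched fold-changes")
  }
  out <- list()
  for (a in arms) {
    for (tp in times) {
      trt_idx <- meta$arm == a & meta$time_h == tp
      if (!any(trt_idx)) next
      ref_idx <- if (mode == "control") {
        meta$arm == "control" & meta$time_h == tp
      } else {
        meta$arm == a & meta$time_h == min(times)
      }
      if (!any(ref_idx)) {
        stop("no reference samples for arm ", a, " at time ", tp)
      }
      mt <- rowMeans(vals[, trt_idx, drop = FALSE])
      mr <- rowMeans(vals[, ref_idx, drop = FALSE])
      if (any(mr <= 0)) {
        stop("non-positive reference mean for protein(s): ",
             paste(utils::head(rownames(vals)[mr <= 0], 5),
                   collapse = ", "))
      }
      out[[length(out) + 1L]] <- data.frame(
        protein = rownames(vals), arm = a, time_h = tp,
        value = log2(mt / mr), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("temporal_profiles", class(res))
  res
}

## reshape long profiles to a protein x (arm:time) matrix
.profile_matrix <- function(profiles) {
  key <- paste(profiles$arm, profiles$time_h, sep = "@")
  cols <- unique(key[order(profiles$arm, profiles$time_h)])
  prots <- unique(profiles$protein)
  m <- matrix(NA_real_, length(prots), length(cols),
              dimnames = list(prots, cols))
  m[cbind(match(profiles$protein, prots), match(key, cols))] <-
    profiles$value
  if (anyNA(m)) stop("profiles do not share a common time grid")
  m
}

#' Temporal k-means clustering of expression profiles
#'
#' Clusters log2 fold-change temporal profiles with seeded multi-restart
#' k-means (Euclidean distance on the stacked profile vectors). The
#' cluster count is chosen over `k_range` by the maximum member-centroid
#' deviation: because that criterion can only improve as k grows, the
#' selected k is the smallest one whose maximum deviation is within
#' `rel_tol` of the best achieved over the range (an elbow rule on the
#' stated criterion); `rel_tol = 0` reduces to the literal minimizer
#' with ties broken toward smaller k.
#'
#' Profiles are grouped by temporal shape: by default each profile
#' vector is scaled to unit Euclidean norm before clustering
#' (`scale_profiles = "unit"`), so proteins sharing a response pattern
#' cluster together regardless of response amplitude; `"none"` clusters
#' the raw log2 profiles. Centroids and deviations are reported on the
#' clustered (scaled) space.
#'
#' @param profiles A `temporal_profiles` data.frame (see
#'   [log2_fold_change()]) or a numeric profile matrix (rows =
#'   proteins).
#' @param k_range Candidate cluster counts (default `2:15`), or a single
#'   fixed k.
#' @param seed Integer seed; identical seeds give identical assignments.
#' @param nstart Random restarts per k.
#' @param rel_tol Relative tolerance of the elbow rule.
#' @param iter_max Maximum k-means iterations.
#' @param scale_profiles `"unit"` (default) or `"none"`.
#' @return Object of class `cluster_result`: `k`, `assignments` (named
#'   integer vector), `centroids` (k x timepoints matrix),
#'   `max_deviation` (per cluster), `criterion` (per candidate k),
#'   `sizes`.
#' @export
cluster_temporal <- function(profiles, k_range = 2:15, seed = 1L,
                             nstart = 10L, rel_tol = 0.05,
                             iter_max = 200L,
                             scale_profiles = c("unit", "none")) {
  scale_profiles <- match.arg(scale_profiles)
  m <- if (is.matrix(profiles)) profiles else .profile_matrix(profiles)
  if (max(k_range) > nrow(m)) {
    stop("k exceeds the number of profiles (", nrow(m), ")")
  }
  if (scale_profiles == "unit") {
    nrm <- sqrt(rowSums(m^2))
    m <- m / ifelse(nrm > 0, nrm, 1)
  }
  rng_state <- .save_seed()
  on.exit(.restore_seed(rng_state), add = TRUE)

  ## distance-weighted (k-means++) seeding: robust when many profiles
  ## are near-duplicates, where uniform random initialization routinely
  ## drops whole archetypes
  kpp_centers <- function(k) {
    n <- nrow(m)
    ctr <- m[sample.int(n, 1L), , drop = FALSE]
    d2 <- rowSums((m - ctr[rep(1L, n), , drop = FALSE])^2)
    while (nrow(ctr) < k) {
      pick <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2)
              else sample.int(n, 1L)
      ctr <- rbind(ctr, m[pick, , drop = FALSE])
      d2 <- pmin(d2, rowSums((m - m[rep(pick, n), , drop = FALSE])^2))
    }
    ctr + stats::rnorm(length(ctr), 0, 1e-9)  # break exact ties
  }

  run_k <- function(k) {
    set.seed(seed + k)   # per-k seeding keeps runs independent of k_range
    ## Lloyd iterations warn when a cluster empties, which is expected
    ## when k exceeds the number of distinct profile shapes
    km <- suppressWarnings(
      stats::kmeans(m, centers = kpp_centers(k),
                    iter.max = iter_max, algorithm = "Lloyd"))
    for (s in seq_len(max(0L, nstart - 1L))) {
      cand <- suppressWarnings(
        stats::kmeans(m, centers = kpp_centers(k),
                      iter.max = iter_max, algorithm = "Lloyd"))
      if (cand$tot.withinss < km$tot.withinss) km <- cand
    }
    dev <- sqrt(rowSums((m - km$centers[km$cluster, , drop = FALSE])^2))
    list(km = km, max_dev = max(dev),
         per_cluster = vapply(seq_len(k), function(j) {
           if (any(km$cluster == j)) max(dev[km$cluster == j]) else 0
         }, numeric(1)))
  }

  k_range <- sort(unique(as.integer(k_range)))
  runs <- lapply(k_range, run_k)
  crit <- vapply(runs, function(r) r$max_dev, numeric(1))
  best <- min(crit)
  k_idx <- which(crit <= best * (1 + rel_tol))[1L]
  sel <- runs[[k_idx]]
  structure(list(k = k_range[k_idx],
                 assignments = stats::setNames(sel$km$cluster,
                                               rownames(m)),
                 centroids = sel$km$centers,
                 max_deviation = sel$per_cluster,
                 criterion = stats::setNames(crit, k_range),
                 sizes = as.integer(table(sel$km$cluster))),
            class = "cluster_result")
}

#' Representative profile of a cluster
#'
#' Returns the cluster centroid (the mean profile over time) or, when a
#' named member is requested, that member's own profile — e.g. a single
#' well-characterized protein chosen to stand for its functional group.
#'
#' @param cluster A `cluster_result`.
#' @param cluster_id Cluster number.
#' @param profiles The profile matrix (or `temporal_profiles`) the
#'   clustering was run on; required when `named_member` is given.
#' @param named_member Optional protein id; must belong to the cluster.
#' @return Numeric profile vector.
#' @export
representative_profile <- function(cluster, cluster_id, profiles = NULL,
                                   named_member = NULL) {
  stopifnot(inherits(cluster, "cluster_result"))
  if (!cluster_id %in% seq_len(cluster$k)) {
    stop("unknown cluster id: ", cluster_id)
  }
  if (is.null(named_member)) {
    return(cluster$centroids[cluster_id, ])
  }
  if (!named_member %in% names(cluster$assignments)) {
    stop("unknown member: ", named_member)
  }
  if (cluster$assignments[[named_member]] != cluster_id) {
    stop("member ", named_member, " belongs to cluster ",
         cluster$assignments[[named_member]], ", not ", cluster_id)
  }
  m <- if (is.matrix(profiles)) profiles else .profile_matrix(profiles)
  m[named_member, ]
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two cluster assignments of the
#' same items; 1 for identical partitions, ~0 for independent ones.
#' Used to score recovery of planted cluster structure.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Scalar adjusted Rand index.
#' @export
cluster_agreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
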