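# Mahalanobis-distance activity scoring: PCA truncation at >= 90% explained
# variance, sample-weighted pooled covariance, vehicle-derived null
# distribution and the mean + 3 SD activity cutoff.

#' Number of principal components explaining a variance target
#'
#' Returns the smallest prefix of components whose cumulative explained
#' variance fraction reaches the target (default 0.90). If even all
#' components fall short of the target, all are used with a warning.
#'
#' @param explained ordered vector of per-component explained-variance
#'   fractions
#' @param target cumulative variance target (default 0.90)
#' @return integer `q`
#' @export
select_pcs <- function(explained, target = 0.90) {
  stopifnot(length(explained) >= 1, all(explained >= 0))
  if (sum(explained) > 1 + 1e-8) {
    stop("explained-variance fractions sum to more than 1", call. = FALSE)
  }
  cum <- cumsum(explained)
  if (cum[length(cum)] < target) {
    warning("total explained variance ", round(cum[length(cum)], 4),
            " below target ", target, "; using all components")
    return(length(explained))
  }
  which(cum >= target)[1]
}

#' Sample-weighted pooled covariance of two groups
#'
#' `Sigma = (n_t * Sigma_t + n_c * Sigma_c) / (n_t + n_c)`, each term the
#' ordinary sample covariance of its group. If the result is numerically
#' singular a ridge `eps * mean(diag(Sigma)) * I` is added and flagged via
#' the `"ridge_used"` attribute.
#'
#' @param treat,control numeric matrices (rows = wells, columns = PC scores),
#'   each with at least 2 rows
#' @param ridge_eps relative ridge magnitude used on singular matrices
#' @return the pooled covariance matrix, with attribute `ridge_used`
#' @export
pooled_covariance <- function(treat, control, ridge_eps = 1e-6) {
  treat <- as.matrix(treat); control <- as.matrix(control)
  if (nrow(treat) < 2L || nrow(control) < 2L) {
    stop("each group needs at least 2 rows for a covariance", call. = FALSE)
  }
  n_t <- nrow(treat); n_c <- nrow(control)
  sigma <- (n_t * cov(treat) + n_c * cov(control)) / (n_t + n_c)
  ridge_used <- FALSE
  ok <- is.finite(rcond(sigma)) && rcond(sigma) > 1e-12
  if (!ok) {
    sigma <- sigma + diag(ridge_eps * mean(diag(sigma)), nrow(sigma))
    ridge_used <- TRUE
  }
  attr(sigma, "ridge_used") <- ridge_used
  sigma
}

# Mahalanobis distance between group centroids given PC scores for each group.
.maha_from_scores <- function(score_t, score_c, ridge_eps = 1e-6) {
  sigma <- pooled_covariance(score_t, score_c, ridge_eps = ridge_eps)
  d <- colMeans(score_t) - colMeans(score_c)
  sol <- try(solve(sigma, d), silent = TRUE)
  if (inherits(sol, "try-error")) {
    stop("pooled covariance singular even after ridge regularization",
         call. = FALSE)
  }
  list(score = sqrt(max(0, sum(d * sol))),
       ridge_used = attr(sigma, "ridge_used"))
}

# PCA of the stacked matrix with the activity-step convention (scaled,
# uncentered by default), truncated at the variance target.
.pc_scores <- function(stacked, variance_target, center = FALSE, scale = TRUE) {
  if (scale) {
    denom <- if (center) apply(stacked, 2, sd)
             else sqrt(colSums(stacked^2) / (nrow(stacked) - 1))
    zero <- which(denom == 0)
    if (length(zero)) {
      stop("cannot scale zero-variance feature(s): ",
           paste(colnames(stacked)[zero], collapse = ", "), call. = FALSE)
    }
  }
  pc <- prcomp(stacked, center = center, scale. = scale)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  q <- select_pcs(explained, target = variance_target)
  list(scores = pc$x[, seq_len(q), drop = FALSE], q = q)
}

#' Mahalanobis activity score of a treatment against vehicle wells
#'
#' Replicate treatment wells are stacked with the vehicle wells and PCA is
#' run on the combined matrix (scaled and uncentered by default, the
#' convention for profiles that are already vehicle-centered by robust
#' z-scoring). The first `q` components reaching the variance target are
#' kept; the two groups' covariances in PC space are pooled with sample-size
#' weights, and the activity score is the Mahalanobis distance between the
#' group centroids: `sqrt((mu_t - mu_c)' Sigma^-1 (mu_t - mu_c))`.
#'
#' @param treat numeric matrix of treatment well profiles (>= 2 rows)
#' @param vehicle numeric matrix of vehicle well profiles (>= 8 rows),
#'   same features
#' @param variance_target cumulative explained-variance target (default 0.90)
#' @param center,scale PCA convention (defaults: uncentered, scaled)
#' @param ridge_eps ridge used on singular pooled covariances
#' @return list with `score`, `q` and `ridge_used`
#' @export
mahalanobis_activity <- function(treat, vehicle, variance_target = 0.90,
                                 center = FALSE, scale = TRUE,
                                 ridge_eps = 1e-6) {
  treat <- as.matrix(treat); vehicle <- as.matrix(vehicle)
  if (nrow(treat) < 2L) stop("need >= 2 treatment wells", call. = FALSE)
  if (nrow(vehicle) < 8L) stop("need >= 8 vehicle wells", call. = FALSE)
  if (ncol(treat) != ncol(vehicle)) {
    stop("treatment and vehicle wells must share a feature set", call. = FALSE)
  }
  pcs <- .pc_scores(rbind(treat, vehicle), variance_target, center, scale)
  idx_t <- seq_len(nrow(treat))
  m <- .maha_from_scores(pcs$scores[idx_t, , drop = FALSE],
                         pcs$scores[-idx_t, , drop = FALSE],
                         ridge_eps = ridge_eps)
  list(score = m$score, q = pcs$q, ridge_used = m$ridge_used)
}

#' Null activity distances from vehicle pseudo-treatments
#'
#' Vehicle wells are partitioned (by a seeded shuffle) into pseudo-treatment
#' groups of `group_size` wells; each group is scored with
#' [mahalanobis_activity()] against the remaining vehicle wells. Because a
#' group plus the remaining vehicles is always the full vehicle set, the PCA
#' is computed once and shared across groups (numerically identical to
#' scoring each group independently).
#'
#' @param vehicle numeric matrix of vehicle well profiles
#' @param group_size wells per pseudo-treatment (default 4, the replicate
#'   plate count)
#' @param seed seed for the shuffle
#' @param variance_target,center,scale,ridge_eps as in
#'   [mahalanobis_activity()]
#' @return numeric vector of null distances, one per pseudo-group
#' @export
vehicle_null_distances <- function(vehicle, group_size = 4, seed = 1,
                                   variance_target = 0.90, center = FALSE,
                                   scale = TRUE, ridge_eps = 1e-6) {
  vehicle <- as.matrix(vehicle)
  n <- nrow(vehicle)
  if (group_size < 2L) stop("group_size must be >= 2", call. = FALSE)
  if (n < 2L * group_size) {
    stop("need at least 2 * group_size vehicle wells (", 2 * group_size,
         "), got ", n, call. = FALSE)
  }
  if (n - group_size < 8L) {
    stop("remaining vehicle wells after forming a pseudo-group must be >= 8",
         call. = FALSE)
  }
  perm <- with_seed(seed, sample.int(n))
  n_groups <- floor(n / group_size)
  pcs <- .pc_scores(vehicle, variance_target, center, scale)
  vapply(seq_len(n_groups), function(g) {
    rows <- perm[seq.int((g - 1L) * group_size + 1L, g * group_size)]
    .maha_from_scores(pcs$scores[rows, , drop = FALSE],
                      pcs$scores[-rows, , drop = FALSE],
                      ridge_eps = ridge_eps)$score
  }, numeric(1))
}

#' Call active treatments against the vehicle null
#'
#' The activity cutoff is `mean(null) + sd_multiplier * SD(null)` (3 SD by
#' default, matching the DMSO-well convention); a treatment is active iff its
#' score strictly exceeds the cutoff.
#'
#' @param results data.frame with an `activity_score` column
#' @param null vector of >= 8 vehicle null distances
#' @param sd_multiplier cutoff multiplier (default 3)
#' @return list with `results` (input plus `cutoff` and `active` columns) and
#'   `threshold` (`null`, `mean`, `sd`, `cutoff`)
#' @export
call_actives <- function(results, null, sd_multiplier = 3) {
  if (length(null) < 8L) stop("need >= 8 null distances", call. = FALSE)
  if (sd(null) == 0) stop("null distances have zero variance", call. = FALSE)
  cutoff <- mean(null) + sd_multiplier * sd(null)
  results$cutoff <- cutoff
  results$active <- results$activity_score > cutoff     # strict inequality
  list(results = results,
       threshold = list(null = null, mean = mean(null), sd = sd(null),
                        sd_multiplier = sd_multiplier, cutoff = cutoff))
}

#' Relative cell number of a treatment
#'
#' Per plate, the treatment's mean cell count as a fraction of the same
#' plate's vehicle mean cell count, averaged across plates and expressed in
#' percent.
#'
#' @param treat_meta metadata rows (with `plate_id` and `cell_count`) of the
#'   treatment wells
#' @param vehicle_meta metadata rows of the vehicle wells
#' @return percentage of vehicle cell count
#' @export
relative_cell_number <- function(treat_meta, vehicle_meta) {
  if (anyNA(treat_meta$cell_count) || anyNA(vehicle_meta$cell_count)) {
    stop("missing cell counts", call. = FALSE)
  }
  ratios <- vapply(unique(treat_meta$plate_id), function(pl) {
    v <- vehicle_meta$cell_count[vehicle_meta$plate_id == pl]
    if (length(v) == 0L || mean(v) <= 0) {
      stop("plate ", pl, " lacks vehicle wells with positive cell counts",
           call. = FALSE)
    }
    mean(treat_meta$cell_count[treat_meta$plate_id == pl]) / mean(v)
  }, numeric(1))
  100 * mean(ratios)
}

#' Score a whole screen
#'
#' Driver over a normalized profile matrix: computes one Mahalanobis activity
#' score per compound x concentration (pooling replicate wells across
#' plates, each scored against all vehicle wells), builds the vehicle null
#' from seeded pseudo-groups, applies the mean + `sd_multiplier` SD cutoff
#' and attaches relative cell numbers.
#'
#' @param x a normalized `well_profiles` object
#' @param group_size pseudo-group size for the null (default: the number of
#'   replicate plates)
#' @param seed seed for the null partition
#' @param variance_target,center,scale,ridge_eps PCA/covariance settings, see
#'   [mahalanobis_activity()]
#' @param sd_multiplier cutoff multiplier (default 3)
#' @param granularity `"concentration"` (default; one score per compound x
#'   concentration, the per-dose reading behind trajectory plots) or
#'   `"compound"` (all of a compound's wells pooled across doses, the
#'   screen-summary reading; `concentration_um` is reported as `NA`)
#' @return list with `results` (data.frame: `compound_id, concentration_um,
#'   activity_score, q, cutoff, active, relative_cell_number,
#'   n_treatment_wells, n_vehicle_wells`) and `threshold`
#' @export
score_screen <- function(x, group_size = NULL, seed = 1,
                         variance_target = 0.90, center = FALSE, scale = TRUE,
                         ridge_eps = 1e-6, sd_multiplier = 3,
                         granularity = c("concentration", "compound")) {
  stopifnot(inherits(x, "well_profiles"))
  granularity <- match.arg(granularity)
  veh <- x$meta$role == "vehicle"
  if (!any(veh)) stop("no vehicle wells in screen", call. = FALSE)
  if (is.null(group_size)) {
    group_size <- max(2L, length(unique(x$meta$plate_id[!veh])))
  }
  trt <- x$meta$role %in% c("treatment", "positive_control")
  groups <- unique(x$meta[trt, c("compound_id", "concentration_um")])
  if (granularity == "compound") {
    groups <- data.frame(compound_id = unique(groups$compound_id),
                         concentration_um = NA_real_,
                         stringsAsFactors = FALSE)
  }
  groups <- groups[order(groups$compound_id, groups$concentration_um), ]

  veh_vals <- x$values[veh, , drop = FALSE]
  veh_meta <- x$meta[veh, , drop = FALSE]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- trt & x$meta$compound_id == groups$compound_id[i]
    if (granularity == "concentration") {
      sel <- sel & x$meta$concentration_um == groups$concentration_um[i]
    }
    ma <- mahalanobis_activity(x$values[sel, , drop = FALSE], veh_vals,
                               variance_target = variance_target,
                               center = center, scale = scale,
                               ridge_eps = ridge_eps)
    data.frame(compound_id = groups$compound_id[i],
               concentration_um = groups$concentration_um[i],
               activity_score = ma$score, q = ma$q,
               ridge_used = ma$ridge_used,
               relative_cell_number =
                 relative_cell_number(x$meta[sel, , drop = FALSE], veh_meta),
               n_treatment_wells = sum(sel), n_vehicle_wells = sum(veh),
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  null <- vehicle_null_distances(veh_vals, group_size = group_size, seed = seed,
                                 variance_target = variance_target,
                                 center = center, scale = scale,
                                 ridge_eps = ridge_eps)
  call_actives(results, null, sd_multiplier = sd_multiplier)
}
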