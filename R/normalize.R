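# Per-plate robust normalization against vehicle wells, field-to-well
# aggregation, and correlation-based redundant-feature removal.

#' Aggregate field-level profiles to well level
#'
#' Imaging acquires several fields (sites) per well; profile features are the
#' arithmetic mean over a well's fields and the cell count is the sum.
#'
#' @param x a `well_profiles` object whose metadata contains a `field` column
#' @return a well-level `well_profiles` (no `field` column)
#' @export
aggregate_fields_to_wells <- function(x) {
  stopifnot(inherits(x, "well_profiles"))
  if (!"field" %in% names(x$meta)) {
    stop("no 'field' column present; input is already well-level", call. = FALSE)
  }
  key <- paste(x$meta$plate_id, x$meta$well, sep = "\r")
  idx <- split(seq_along(key), key)
  if (any(lengths(idx) == 0L)) stop("well with zero fields", call. = FALSE)
  first <- vapply(idx, `[`, integer(1), 1L)
  ord <- order(first)  # keep first-appearance order
  idx <- idx[ord]
  vals <- do.call(rbind, lapply(idx, function(i) {
    colMeans(x$values[i, , drop = FALSE])
  }))
  meta <- x$meta[vapply(idx, `[`, integer(1), 1L), , drop = FALSE]
  meta$cell_count <- vapply(idx, function(i) sum(x$meta$cell_count[i]),
                            numeric(1))
  meta$field <- NULL
  colnames(vals) <- feature_names(x)
  well_profiles(meta, vals, provenance = x$provenance)
}

#' Robust z-score normalization against vehicle wells
#'
#' For every plate and feature, values are centered on the median and scaled
#' by 1.4826 x MAD of that plate's vehicle (DMSO) wells:
#' `z = (x - median_vehicle) / (1.4826 * MAD_vehicle)`. Features whose
#' vehicle MAD is zero on any plate carry no usable scale and are dropped
#' (and reported). Requires at least `min_vehicle_wells` vehicle wells per
#' plate.
#'
#' @param x a well-level `well_profiles` object (raw provenance)
#' @param min_vehicle_wells minimum vehicle wells per plate (default 8)
#' @return list with `profiles` (normalized `well_profiles`) and `params`
#'   (per plate x feature medians/MADs as a data.frame, plus
#'   `dropped_features`)
#' @export
robust_z_normalize <- function(x, min_vehicle_wells = 8) {
  stopifnot(inherits(x, "well_profiles"))
  plates <- unique(x$meta$plate_id)
  feats <- feature_names(x)
  med <- mad_s <- matrix(NA_real_, length(plates), length(feats),
                         dimnames = list(plates, feats))
  for (pl in plates) {
    veh <- x$meta$plate_id == pl & x$meta$role == "vehicle"
    if (!any(veh)) {
      stop("plate ", pl, " has no vehicle wells; cannot normalize", call. = FALSE)
    }
    if (sum(veh) < min_vehicle_wells) {
      stop("plate ", pl, " has only ", sum(veh), " vehicle wells (minimum ",
           min_vehicle_wells, ")", call. = FALSE)
    }
    v <- x$values[veh, , drop = FALSE]
    med[pl, ] <- apply(v, 2, median)
    mad_s[pl, ] <- apply(v, 2, mad, constant = 1.4826)
  }
  dropped <- feats[apply(mad_s == 0, 2, any)]
  keep <- setdiff(feats, dropped)
  if (length(keep) == 0L) stop("all features have zero vehicle spread", call. = FALSE)

  z <- x$values[, keep, drop = FALSE]
  pl_idx <- match(x$meta$plate_id, plates)
  z <- (z - med[pl_idx, keep, drop = FALSE]) / mad_s[pl_idx, keep, drop = FALSE]

  params <- data.frame(
    plate_id = rep(plates, each = length(feats)),
    feature = rep(feats, times = length(plates)),
    vehicle_median = as.vector(t(med)),
    vehicle_mad_scaled = as.vector(t(mad_s)),
    dropped = rep(feats %in% dropped, times = length(plates)),
    stringsAsFactors = FALSE)
  list(profiles = well_profiles(x$meta, z, provenance = "normalized"),
       params = list(table = params, dropped_features = dropped,
                     min_vehicle_wells = min_vehicle_wells))
}

#' Remove redundant (highly correlated) features
#'
#' Greedy elimination: while any feature pair has `|Pearson r| > threshold`,
#' the pair with the largest `|r|` is located and the member with the larger
#' mean absolute correlation to all remaining features is dropped; ties are
#' broken by dropping the lexicographically later feature name. The retained
#' set satisfies pairwise `|r| <= threshold`, and the operation is a fixed
#' point on its own output.
#'
#' @param x a normalized `well_profiles` object with at least 2 wells
#' @param threshold correlation threshold in (0, 1]; default 0.9
#' @return list with `profiles` (reduced `well_profiles`), and `reduction`:
#'   `retained`, `dropped` (data.frame of dropped features with the pair that
#'   triggered each drop) and `threshold`
#' @export
reduce_redundant_features <- function(x, threshold = 0.9) {
  stopifnot(inherits(x, "well_profiles"))
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  if (nrow(x$values) < 2L) stop("need at least 2 wells", call. = FALSE)
  feats <- feature_names(x)
  r <- abs(cor(x$values))
  diag(r) <- 0
  alive <- setNames(rep(TRUE, length(feats)), feats)
  drops <- list()
  repeat {
    sub <- r[alive, alive, drop = FALSE]
    if (max(sub) <= threshold) break
    hit <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- c(rownames(sub)[hit[1]], colnames(sub)[hit[2]])
    mean_r <- rowMeans(sub[pair, , drop = FALSE]) * ncol(sub) / (ncol(sub) - 1)
    victim <- if (mean_r[1] > mean_r[2]) pair[1]
              else if (mean_r[2] > mean_r[1]) pair[2]
              else sort(pair)[2]                    # tie: later name
    drops[[length(drops) + 1L]] <- data.frame(
      dropped = victim, partner = setdiff(pair, victim),
      abs_r = unname(sub[pair[1], pair[2]]), stringsAsFactors = FALSE)
    alive[victim] <- FALSE
    if (sum(alive) < 2L) break
  }
  retained <- feats[alive[feats]]
  dropped_df <- if (length(drops)) do.call(rbind, drops) else
    data.frame(dropped = character(0), partner = character(0),
               abs_r = numeric(0), stringsAsFactors = FALSE)
  out <- x[, retained]
  out$provenance <- "reduced"
  list(profiles = out,
       reduction = list(retained = retained, dropped = dropped_df,
                        threshold = threshold))
}
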