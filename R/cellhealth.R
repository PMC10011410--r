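# Live-cell time-course summarization (background correction, trapezoid AUC)
# and glutathione quantification with standard curves and outlier flags.

#' Background-correct time courses with reagent-free wells
#'
#' Subtracts, per plate / metric / time point, the mean value of that
#' plate's reagent-free wells (which measure cellular autofluorescence).
#' Negative corrected values are clipped to zero; the number of clips is
#' recorded in the `"n_clipped"` attribute. Confluence (a label-free
#' phase-contrast metric) is not corrected.
#'
#' @param tc long-format time-course data.frame (`plate_id, well,
#'   compound_id, concentration_um, replicate, role, metric, time_h, value`)
#' @param metrics metrics to correct (default: all except `"confluence"`)
#' @return the corrected data.frame, reagent-free rows removed, with
#'   attribute `n_clipped`
#' @export
background_correct <- function(tc, metrics = NULL) {
  stopifnot(all(c("plate_id", "role", "metric", "time_h", "value") %in% names(tc)))
  if (is.null(metrics)) metrics <- setdiff(unique(tc$metric), "confluence")
  n_clipped <- 0L
  for (pl in unique(tc$plate_id)) {
    rf <- tc$plate_id == pl & tc$role == "reagent_free"
    if (!any(rf)) {
      stop("plate ", pl, " has no reagent-free wells for background correction",
           call. = FALSE)
    }
    for (mm in intersect(metrics, unique(tc$metric[tc$plate_id == pl]))) {
      bg <- tapply(tc$value[rf & tc$metric == mm], tc$time_h[rf & tc$metric == mm],
                   mean)
      sel <- tc$plate_id == pl & tc$metric == mm & !rf
      corr <- tc$value[sel] - as.numeric(bg[as.character(tc$time_h[sel])])
      n_clipped <- n_clipped + sum(corr < 0)
      tc$value[sel] <- pmax(0, corr)
    }
  }
  out <- tc[tc$role != "reagent_free", ]
  rownames(out) <- NULL
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Trapezoid area under a time course
#'
#' Composite trapezoid rule over the recorded grid; units are
#' metric-units x hours.
#'
#' @param times strictly increasing time points (hours), length >= 2
#' @param values metric values at `times`
#' @return the AUC
#' @export
trapezoid_auc <- function(times, values) {
  if (length(times) < 2L || length(times) != length(values)) {
    stop("need >= 2 matched time/value points", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  sum(diff(times) * (head(values, -1) + tail(values, -1)) / 2)
}

#' Summarize cell-health time courses into AUCs
#'
#' Per compound x concentration x metric: the trapezoid AUC of each well's
#' trace, averaged over replicate wells. Compounds on the exclusion list
#' (e.g. autofluorescent interferers) are kept in the table with
#' `excluded = TRUE` and a reason, so they can be omitted from aggregate
#' statistics downstream.
#'
#' @param tc background-corrected long-format time courses
#' @param exclusions character vector of compound ids to flag, or a named
#'   character vector (names = compound ids, values = reason)
#' @return data.frame `compound_id, concentration_um, metric, auc,
#'   n_replicates, excluded, exclude_reason`
#' @export
summarize_health <- function(tc, exclusions = character(0)) {
  reasons <- if (is.null(names(exclusions))) {
    setNames(rep("excluded", length(exclusions)), exclusions)
  } else exclusions
  sel <- tc$role %in% c("treatment", "vehicle", "positive_control")
  tc <- tc[sel, ]
  key <- paste(tc$compound_id, tc$concentration_um, tc$metric, tc$plate_id,
               tc$well, sep = "\r")
  per_well <- lapply(split(tc, key), function(d) {
    d <- d[order(d$time_h), ]
    data.frame(compound_id = d$compound_id[1],
               concentration_um = d$concentration_um[1], metric = d$metric[1],
               auc = trapezoid_auc(d$time_h, d$value), stringsAsFactors = FALSE)
  })
  per_well <- do.call(rbind, per_well)
  agg <- aggregate(auc ~ compound_id + concentration_um + metric, per_well,
                   function(v) c(mean(v), length(v)))
  out <- data.frame(agg[c("compound_id", "concentration_um", "metric")],
                    auc = agg$auc[, 1], n_replicates = as.integer(agg$auc[, 2]),
                    stringsAsFactors = FALSE)
  out$excluded <- out$compound_id %in% names(reasons)
  out$exclude_reason <- ifelse(out$excluded, reasons[out$compound_id], NA_character_)
  out <- out[order(out$compound_id, out$concentration_um, out$metric), ]
  rownames(out) <- NULL
  out
}

#' Per-compound aggregation of health AUCs
#'
#' Mean AUC per compound x metric across concentrations (the
#' concentration-collapsed summary). Compounds flagged as excluded are
#' omitted from the aggregate entirely.
#'
#' @param health the table from [summarize_health()]
#' @return data.frame `compound_id, metric, mean_auc, n_concentrations`
#' @export
aggregate_health_by_compound <- function(health) {
  keep <- health[!health$excluded, , drop = FALSE]
  agg <- aggregate(auc ~ compound_id + metric, keep,
                   function(v) c(mean(v), length(v)))
  out <- data.frame(agg[c("compound_id", "metric")],
                    mean_auc = agg$auc[, 1],
                    n_concentrations = as.integer(agg$auc[, 2]),
                    stringsAsFactors = FALSE)
  out[order(out$compound_id, out$metric), ]
}

#' Correct luminescence wells for row/column effects
#'
#' Estimates multiplicative per-row and per-column gain factors from a
#' uniformity plate (all wells nominally identical) and divides them out of
#' the measured wells: `corrected = lum / (row_factor * col_factor)`, where
#' each factor is the uniformity plate's row (column) mean over its grand
#' mean.
#'
#' @param wells data.frame with `well` (384-well labels) and `lum` columns
#' @param uniformity data.frame with `well` and `lum` for the uniformity
#'   plate
#' @return `wells` with corrected `lum`
#' @export
uniformity_correct <- function(wells, uniformity) {
  stopifnot(all(c("well", "lum") %in% names(wells)),
            all(c("well", "lum") %in% names(uniformity)))
  u_row <- substr(uniformity$well, 1, 1)
  u_col <- substr(uniformity$well, 2, 3)
  grand <- mean(uniformity$lum)
  row_f <- tapply(uniformity$lum, u_row, mean) / grand
  col_f <- tapply(uniformity$lum, u_col, mean) / grand
  w_row <- substr(wells$well, 1, 1)
  w_col <- substr(wells$well, 2, 3)
  if (anyNA(row_f[w_row]) || anyNA(col_f[w_col])) {
    stop("uniformity plate does not cover all rows/columns of the data",
         call. = FALSE)
  }
  wells$lum <- wells$lum / (as.numeric(row_f[w_row]) * as.numeric(col_f[w_col]))
  wells
}

#' Fit a glutathione standard curve
#'
#' Ordinary least-squares line `lum = slope * conc + intercept` on
#' background-corrected standards (>= 5 levels; the assay uses triplicate
#' 10-point standards, 2-fold from 6.4 uM). A recovery check (back-predicted
#' concentration of each standard) is reported.
#'
#' @param conc known standard concentrations (uM)
#' @param lum measured luminescence (background-corrected)
#' @return a `standard_curve` list: `slope`, `intercept`, `residual_sd`,
#'   `recovery` (data.frame of known vs recovered concentration)
#' @export
fit_standard_curve <- function(conc, lum) {
  stopifnot(length(conc) == length(lum))
  if (length(unique(conc)) < 5L) {
    stop("need at least 5 standard concentration levels", call. = FALSE)
  }
  fit <- lm(lum ~ conc)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope <= 0) {
    stop("standard curve slope is not positive; curve unusable", call. = FALSE)
  }
  recovered <- (lum - intercept) / slope
  structure(list(slope = slope, intercept = intercept,
                 residual_sd = sd(fit$residuals),
                 recovery = data.frame(conc = conc, recovered = recovered)),
            class = "standard_curve")
}

#' Invert a standard curve
#'
#' @param curve a [fit_standard_curve()] object
#' @param lum luminescence values
#' @return concentrations in uM
#' @export
invert_standard_curve <- function(curve, lum) {
  (lum - curve$intercept) / curve$slope
}

#' Quantify glutathione and flag outliers
#'
#' Converts total-glutathione and GSSG luminescence to uM through the
#' standard curve, computes reduced glutathione by the kit stoichiometry
#' `GSH = total - 2 * GSSG` (each GSSG carries two GSH equivalents) and the
#' `GSH:GSSG` ratio, plus percent-of-vehicle values for total and GSSG.
#' Flags: `outlier_gssg` when GSSG exceeds 200% of vehicle; `gsh_negative`
#' (ratio withheld) when computed GSH < 0; `undefined_high` when GSSG is
#' ~0 with GSH > 0 (ratio unbounded); otherwise `ok`.
#'
#' @param total_lum named-by-nothing numeric vector of total-glutathione
#'   luminescence per sample (replicate-averaged or raw; averaged internally
#'   if `group` is given)
#' @param gssg_lum GSSG luminescence, aligned with `total_lum`
#' @param curve_total,curve_gssg standard curves for the two assays (a single
#'   curve may be passed for both)
#' @param vehicle_total_lum,vehicle_gssg_lum vehicle-well luminescence used
#'   as the 100% reference
#' @param meta optional data.frame (e.g. compound/concentration) cbound onto
#'   the result
#' @return data.frame with `total_um, gssg_um, gsh_um, ratio,
#'   total_pct_vehicle, gssg_pct_vehicle, flag`
#' @export
quantify_glutathione <- function(total_lum, gssg_lum, curve_total,
                                 curve_gssg = curve_total,
                                 vehicle_total_lum, vehicle_gssg_lum,
                                 meta = NULL) {
  stopifnot(length(total_lum) == length(gssg_lum))
  total_um <- invert_standard_curve(curve_total, total_lum)
  gssg_um <- invert_standard_curve(curve_gssg, gssg_lum)
  veh_total <- mean(invert_standard_curve(curve_total, vehicle_total_lum))
  veh_gssg <- mean(invert_standard_curve(curve_gssg, vehicle_gssg_lum))
  if (veh_total <= 0 || veh_gssg <= 0) {
    stop("vehicle reference concentrations must be positive", call. = FALSE)
  }
  gsh_um <- total_um - 2 * gssg_um
  total_pct <- 100 * total_um / veh_total
  gssg_pct <- 100 * gssg_um / veh_gssg

  flag <- rep("ok", length(total_um))
  ratio <- gsh_um / gssg_um
  # GSSG indistinguishable from zero (to curve-fit precision) with GSH > 0:
  # the ratio is unbounded, not a division
  undef <- gssg_um <= 1e-9 * veh_gssg & gsh_um > 0
  flag[undef] <- "undefined_high"; ratio[undef] <- NA_real_
  neg <- gsh_um < 0
  flag[neg] <- "gsh_negative"; ratio[neg] <- NA_real_
  out_gssg <- gssg_pct > 200
  flag[out_gssg] <- "outlier_gssg"; ratio[out_gssg] <- NA_real_

  out <- data.frame(total_um = total_um, gssg_um = gssg_um, gsh_um = gsh_um,
                    ratio = ratio, total_pct_vehicle = total_pct,
                    gssg_pct_vehicle = gssg_pct, flag = flag,
                    stringsAsFactors = FALSE)
  if (!is.null(meta)) out <- cbind(as.data.frame(meta), out)
  out
}

#' Quantify glutathione from a generated plate
#'
#' Convenience driver over the long-format plate emitted by
#' [generate_glutathione_plate()] (or equivalent real data): corrects
#' standards and samples for cell-free background luminescence, fits one
#' standard curve per assay, averages replicate wells per compound x
#' concentration and applies [quantify_glutathione()].
#'
#' @param plate long-format data.frame (`assay` in `total`/`gssg`, roles
#'   `standard`, `cell_free`, `vehicle`, `treatment`)
#' @param uniformity optional data.frame (`well`, `lum`) from uniformity
#'   plates; when supplied, row/column gain factors are divided out via
#'   [uniformity_correct()] before any quantification, otherwise the
#'   correction is skipped with a message
#' @return list with `results` (per compound x concentration) and `curves`
#' @export
glutathione_from_plate <- function(plate, uniformity = NULL) {
  if (is.null(uniformity)) {
    message("no uniformity plates supplied; row/column correction skipped")
  } else {
    plate <- uniformity_correct(plate, uniformity)
  }
  by_assay <- split(plate, plate$assay)
  stopifnot(all(c("total", "gssg") %in% names(by_assay)))

  prep <- function(d) {
    bg <- mean(d$lum[d$role == "cell_free"])
    std <- d[d$role == "standard", ]
    curve <- fit_standard_curve(std$known_conc_um, std$lum - bg)
    trt <- d[d$role == "treatment", ]
    key <- paste(trt$compound_id, trt$concentration_um, sep = "@")
    lum <- tapply(trt$lum - bg, key, mean)
    veh <- d$lum[d$role == "vehicle"] - bg
    list(curve = curve, lum = lum, veh = veh)
  }
  tot <- prep(by_assay$total)
  gss <- prep(by_assay$gssg)
  shared <- intersect(names(tot$lum), names(gss$lum))
  meta <- do.call(rbind, strsplit(shared, "@", fixed = TRUE))
  meta <- data.frame(compound_id = meta[, 1],
                     concentration_um = as.numeric(meta[, 2]),
                     stringsAsFactors = FALSE)
  res <- quantify_glutathione(as.numeric(tot$lum[shared]),
                              as.numeric(gss$lum[shared]),
                              curve_total = tot$curve, curve_gssg = gss$curve,
                              vehicle_total_lum = tot$veh,
                              vehicle_gssg_lum = gss$veh, meta = meta)
  res <- res[order(res$compound_id, res$concentration_um), ]
  rownames(res) <- NULL
  list(results = res, curves = list(total = tot$curve, gssg = gss$curve))
}
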