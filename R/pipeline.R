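# End-to-end orchestration: seeded, manifest-logged pipeline stages writing
# delimited-text artifacts (simulate -> normalize -> score -> cluster ->
# match -> health -> report).

#' Default pipeline run configuration
#'
#' Nested parameter blocks with the screen-anchored defaults: PCA variance
#' target 0.90, activity cutoff at mean + 3 SD of the vehicle null, k = 9
#' phenotype clusters, redundancy threshold 0.9, HC/NC correlation
#' thresholds 0.5/0.2. Every block can be overridden through the `config`
#' argument of [run_pipeline()]; unknown keys are rejected.
#'
#' @return nested list of defaults
#' @export
default_run_config <- function() {
  sim <- formals(synth_config)
  sim <- lapply(sim[setdiff(names(sim), "seed")], eval)
  list(
    simulate = sim,
    normalize = list(redundancy_threshold = 0.9, min_vehicle_wells = 8),
    activity = list(variance_target = 0.90, sd_multiplier = 3,
                    null_group_size = NULL, pca_center = FALSE,
                    pca_scale = TRUE, ridge_eps = 1e-6),
    cluster = list(k = 9, method = "ward.D2"),
    match = list(hc_threshold = 0.5, nc_threshold = 0.2, target_cluster = NULL),
    health = list(exclusions = character(0)),
    seed = 1
  )
}

.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      .merge_config(defaults[[k]], user[[k]], paste0(path, k, "$"))
    } else user[[k]]
  }
  defaults
}

.artifact <- function(outdir, name) file.path(outdir, name)

.require_artifact <- function(outdir, name, produced_by) {
  p <- .artifact(outdir, name)
  if (!file.exists(p)) {
    stop("missing artifact '", name, "'; run stage '", produced_by, "' first",
         call. = FALSE)
  }
  p
}

.write_manifest <- function(outdir, stage, params, seed, inputs) {
  hashes <- if (length(inputs)) {
    setNames(as.list(unname(tools::md5sum(inputs))), basename(inputs))
  } else list()
  manifest <- list(stage = stage, seed = seed, parameters = params,
                   input_md5 = hashes,
                   package_version = as.character(utils::packageVersion("cptriage")))
  jsonlite::write_json(manifest, .artifact(outdir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the triage pipeline
#'
#' Executes one stage (or `"all"`) of the profiling pipeline, reading and
#' writing delimited-text artifacts under `outdir`. Each stage writes a JSON
#' manifest with its parameters, seed and input-file hashes; reruns with
#' identical config and inputs reproduce identical tables.
#'
#' Stages and their artifacts:
#' \describe{
#'   \item{simulate}{`profiles.csv`, `ground_truth.csv`,
#'     `planted_signatures.csv`, `timecourses.csv`, `glutathione.csv`,
#'     `glutathione_truth.csv`}
#'   \item{normalize}{`normalized.csv`, `reduced.csv`,
#'     `normalization_params.csv`, `reduction_dropped.csv`}
#'   \item{score}{`activity.csv`, `threshold.json`}
#'   \item{cluster}{`cluster_labels.csv`, `cluster_signatures.csv`,
#'     `cluster_tree.nwk`}
#'   \item{match}{`matches.csv`}
#'   \item{health}{`health_auc.csv`, `glutathione_results.csv`}
#'   \item{report}{`report.txt`}
#' }
#'
#' @param stage one of `simulate`, `normalize`, `score`, `cluster`, `match`,
#'   `health`, `report`, `all`
#' @param config named list of overrides over [default_run_config()], or a
#'   path to a JSON file of such overrides
#' @param outdir output directory (created if absent)
#' @param seed master seed; overrides `config$seed` when non-NULL
#' @return the merged configuration, invisibly
#' @export
run_pipeline <- function(stage = c("all", "simulate", "normalize", "score",
                                   "cluster", "match", "health", "report"),
                         config = list(), outdir = "cptriage_run",
                         seed = NULL) {
  stage <- match.arg(stage)
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- .merge_config(default_run_config(), config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  stages <- if (stage == "all") {
    c("simulate", "normalize", "score", "cluster", "match", "health", "report")
  } else stage
  for (s in stages) {
    switch(s,
           simulate = .stage_simulate(cfg, outdir),
           normalize = .stage_normalize(cfg, outdir),
           score = .stage_score(cfg, outdir),
           cluster = .stage_cluster(cfg, outdir),
           match = .stage_match(cfg, outdir),
           health = .stage_health(cfg, outdir),
           report = .stage_report(cfg, outdir))
  }
  invisible(cfg)
}

.stage_simulate <- function(cfg, outdir) {
  sc <- do.call(synth_config, c(cfg$simulate, list(seed = cfg$seed)))
  screen <- generate_screen(sc)
  write_profiles(screen$profiles, .artifact(outdir, "profiles.csv"))
  data.table::fwrite(screen$truth, .artifact(outdir, "ground_truth.csv"))
  sig <- data.frame(cluster = seq_len(nrow(screen$signatures)),
                    screen$signatures, check.names = FALSE)
  data.table::fwrite(sig, .artifact(outdir, "planted_signatures.csv"))
  tc <- generate_timecourses(sc, screen$truth)
  data.table::fwrite(tc, .artifact(outdir, "timecourses.csv"))
  gsh <- generate_glutathione_plate(sc, screen$truth)
  data.table::fwrite(gsh$plate, .artifact(outdir, "glutathione.csv"))
  data.table::fwrite(gsh$truth_gsh, .artifact(outdir, "glutathione_truth.csv"))
  .write_manifest(outdir, "simulate", cfg$simulate, cfg$seed, character(0))
  .log_stage("simulate", nrow(screen$profiles$meta), " wells x ",
             ncol(screen$profiles$values), " features, seed ", cfg$seed)
}

.stage_normalize <- function(cfg, outdir) {
  src <- .require_artifact(outdir, "profiles.csv", "simulate")
  raw <- read_profiles(src)
  nz <- robust_z_normalize(raw, min_vehicle_wells = cfg$normalize$min_vehicle_wells)
  write_profiles(nz$profiles, .artifact(outdir, "normalized.csv"))
  data.table::fwrite(nz$params$table, .artifact(outdir, "normalization_params.csv"))
  red <- reduce_redundant_features(nz$profiles,
                                   threshold = cfg$normalize$redundancy_threshold)
  write_profiles(red$profiles, .artifact(outdir, "reduced.csv"))
  data.table::fwrite(red$reduction$dropped, .artifact(outdir, "reduction_dropped.csv"))
  .write_manifest(outdir, "normalize", cfg$normalize, cfg$seed, src)
  .log_stage("normalize", length(red$reduction$retained), " of ",
             ncol(raw$values), " features retained at |r| <= ",
             cfg$normalize$redundancy_threshold)
}

.stage_score <- function(cfg, outdir) {
  src <- .require_artifact(outdir, "normalized.csv", "normalize")
  x <- read_profiles(src, provenance = "normalized")
  ab <- cfg$activity
  sc <- score_screen(x, group_size = ab$null_group_size, seed = cfg$seed,
                     variance_target = ab$variance_target,
                     center = ab$pca_center, scale = ab$pca_scale,
                     ridge_eps = ab$ridge_eps, sd_multiplier = ab$sd_multiplier)
  data.table::fwrite(sc$results, .artifact(outdir, "activity.csv"))
  jsonlite::write_json(sc$threshold, .artifact(outdir, "threshold.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_manifest(outdir, "score", ab, cfg$seed, src)
  .log_stage("score", sum(sc$results$active), " of ", nrow(sc$results),
             " treatments active at cutoff ", round(sc$threshold$cutoff, 3))
}

.stage_cluster <- function(cfg, outdir) {
  act_p <- .require_artifact(outdir, "activity.csv", "score")
  red_p <- .require_artifact(outdir, "reduced.csv", "normalize")
  activity <- data.table::fread(act_p, data.table = FALSE)
  x <- read_profiles(red_p, provenance = "reduced")
  prof <- treatment_profiles(x)
  active_keys <- paste(activity$compound_id, activity$concentration_um,
                       sep = "@")[activity$active]
  prof <- prof[rownames(prof) %in% active_keys, , drop = FALSE]
  if (nrow(prof) < max(2L, cfg$cluster$k)) {
    stop("only ", nrow(prof), " active treatment profiles; cannot cut ",
         cfg$cluster$k, " clusters", call. = FALSE)
  }
  d <- correlation_distance_matrix(prof, ids = rownames(prof))
  model <- ward_cluster(d, k = cfg$cluster$k, method = cfg$cluster$method)
  sig <- cluster_signatures(model, prof)
  data.table::fwrite(data.frame(id = names(model$labels),
                                cluster = unname(model$labels)),
                     .artifact(outdir, "cluster_labels.csv"))
  data.table::fwrite(data.frame(cluster = rownames(sig), sig,
                                check.names = FALSE),
                     .artifact(outdir, "cluster_signatures.csv"))
  write_cluster_tree(model, .artifact(outdir, "cluster_tree.nwk"))
  .write_manifest(outdir, "cluster", cfg$cluster, cfg$seed, c(act_p, red_p))
  .log_stage("cluster", nrow(prof), " active treatments into k = ",
             cfg$cluster$k, " clusters")
}

.stage_match <- function(cfg, outdir) {
  sig_p <- .require_artifact(outdir, "cluster_signatures.csv", "cluster")
  red_p <- .require_artifact(outdir, "reduced.csv", "normalize")
  act_p <- .require_artifact(outdir, "activity.csv", "score")
  sig_tab <- data.table::fread(sig_p, data.table = FALSE)
  sig <- as.matrix(sig_tab[, -1, drop = FALSE])
  rownames(sig) <- sig_tab[[1]]
  x <- read_profiles(red_p, provenance = "reduced")
  activity <- data.table::fread(act_p, data.table = FALSE)
  prof <- treatment_profiles(x)
  active_keys <- paste(activity$compound_id, activity$concentration_um,
                       sep = "@")[activity$active]
  prof <- prof[rownames(prof) %in% active_keys, , drop = FALSE]
  target <- cfg$match$target_cluster
  if (is.null(target)) target <- nrow(sig)
  rows <- lapply(rownames(prof), function(id) {
    m <- match_to_signatures(prof[id, ], sig,
                             hc_threshold = cfg$match$hc_threshold,
                             nc_threshold = cfg$match$nc_threshold,
                             target_cluster = target)
    data.frame(id = id, best_cluster = m$best_cluster, best_r = m$best_r,
               target_r = m$target_r, call = m$call, stringsAsFactors = FALSE)
  })
  matches <- do.call(rbind, rows)
  data.table::fwrite(matches, .artifact(outdir, "matches.csv"))
  .write_manifest(outdir, "match",
                  list(hc_threshold = cfg$match$hc_threshold,
                       nc_threshold = cfg$match$nc_threshold,
                       target_cluster = target),
                  cfg$seed, c(sig_p, red_p, act_p))
  .log_stage("match", nrow(matches), " profiles matched; ",
             sum(matches$call == "HC"), " HC / ",
             sum(matches$call == "NC"), " NC")
}

.stage_health <- function(cfg, outdir) {
  tc_p <- .require_artifact(outdir, "timecourses.csv", "simulate")
  gsh_p <- .require_artifact(outdir, "glutathione.csv", "simulate")
  tc <- data.table::fread(tc_p, data.table = FALSE)
  corrected <- background_correct(tc)
  health <- summarize_health(corrected, exclusions = cfg$health$exclusions)
  data.table::fwrite(health, .artifact(outdir, "health_auc.csv"))
  gsh <- data.table::fread(gsh_p, data.table = FALSE)
  gres <- glutathione_from_plate(gsh)
  data.table::fwrite(gres$results, .artifact(outdir, "glutathione_results.csv"))
  .write_manifest(outdir, "health", cfg$health, cfg$seed, c(tc_p, gsh_p))
  .log_stage("health", nrow(health), " AUC rows; ",
             sum(gres$results$flag != "ok"), " flagged glutathione rows")
}

.stage_report <- function(cfg, outdir) {
  act_p <- .require_artifact(outdir, "activity.csv", "score")
  activity <- data.table::fread(act_p, data.table = FALSE)
  lines <- c("cptriage pipeline report",
             sprintf("seed: %s", cfg$seed),
             sprintf("treatments scored: %d", nrow(activity)),
             sprintf("active treatments: %d (%.1f%%)", sum(activity$active),
                     100 * mean(activity$active)),
             sprintf("activity cutoff: %.4f", activity$cutoff[1]))
  lab_p <- .artifact(outdir, "cluster_labels.csv")
  if (file.exists(lab_p)) {
    labels <- data.table::fread(lab_p, data.table = FALSE)
    occ <- table(labels$cluster)
    lines <- c(lines, sprintf("cluster occupancy: %s",
                              paste(names(occ), occ, sep = "=", collapse = " ")))
  }
  gsh_p <- .artifact(outdir, "glutathione_results.csv")
  if (file.exists(gsh_p)) {
    g <- data.table::fread(gsh_p, data.table = FALSE)
    lines <- c(lines, sprintf("glutathione rows: %d (flags: %s)", nrow(g),
                              paste(names(table(g$flag)), table(g$flag),
                                    sep = "=", collapse = " ")))
  }
  writeLines(lines, .artifact(outdir, "report.txt"))
  .write_manifest(outdir, "report", list(), cfg$seed, act_p)
  .log_stage("report", "written to report.txt")
}
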