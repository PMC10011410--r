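# Seeded synthetic screen generator. Emulates the statistical structure the
# analysis assumes: 384-well qHTS plates with vehicle wells and four positive
# controls, correlated morphological features, planted phenotype signatures
# with Hill-shaped concentration response, a negative coupling between effect
# magnitude and cell count, 60-h live-cell time courses and glutathione
# luminescence plates with 10-point standards. Ground truth is emitted for
# recovery tests.

# Evaluate `expr` with the global RNG seeded to `seed`, restoring the
# caller's RNG state afterwards. All generator sub-streams derive from one
# master seed through this helper, so identical configs give identical data.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive independent sub-seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

hill_effect <- function(conc, effect_max, ec50, hill_slope) {
  ifelse(conc <= 0, 0,
         effect_max * conc^hill_slope / (conc^hill_slope + ec50^hill_slope))
}

#' Configuration for the synthetic screen generator
#'
#' Defaults reproduce the stated screening layout: 384-well plates (16 x 24)
#' with 116 vehicle control wells and four positive-control compounds at six
#' concentrations per plate, compounds in qHTS format at six 2-fold doses
#' (0.625-20 uM) on four replicate plates, and a few hundred correlated
#' morphological features carrying planted phenotype signatures.
#'
#' `effect_max` is the maximal planted effect magnitude expressed as the
#' per-feature RMS displacement in units of `noise_sd` (so `effect_max = 3`
#' means a top-dose effect three times the feature noise; see the methods
#' vignette for why the effect is parameterized per feature rather than as a
#' total profile norm). `cellcount_coupling` is the log-linear slope linking
#' effect magnitude to expected cell count (negative: stronger phenotype,
#' fewer cells).
#'
#' @param n_features number of morphological features
#' @param n_clusters number of planted phenotype signatures (default 9)
#' @param n_compounds_per_cluster compounds planted per cluster
#' @param n_inert_compounds compounds with no planted effect
#' @param concentrations dose series in uM, strictly increasing
#' @param n_replicate_plates replicate plates (default 4)
#' @param n_vehicle_wells_per_plate vehicle (DMSO) wells per plate (default 116)
#' @param plate_rows,plate_cols plate geometry (default 16 x 24 = 384 wells)
#' @param effect_ec50 typical EC50 in uM; per-compound EC50s are jittered
#'   2-fold around this value
#' @param effect_max maximal effect magnitude (per-feature RMS, noise-SD units)
#' @param hill_slope Hill coefficient of the concentration response
#' @param noise_sd feature-wise Gaussian noise SD
#' @param cellcount_coupling log-linear slope of cell count on effect magnitude
#' @param baseline_cells_per_well expected vehicle-well cell count
#' @param block_size size of correlated feature blocks
#' @param block_cor within-block feature correlation
#' @param plate_offset_sd SD of the per-plate, per-feature additive offset
#' @param timecourse_concentrations doses (uM) used for time courses and
#'   glutathione plates
#' @param tc_noise_sd additive noise SD on time-course metrics
#' @param gsh_noise relative (fractional) luminescence noise
#' @param seed master seed; all sub-streams derive from it
#' @return a validated `synth_config` list
#' @export
synth_config <- function(n_features = 300,
                         n_clusters = 9,
                         n_compounds_per_cluster = 3,
                         n_inert_compounds = 6,
                         concentrations = c(0.625, 1.25, 2.5, 5, 10, 20),
                         n_replicate_plates = 4,
                         n_vehicle_wells_per_plate = 116,
                         plate_rows = 16, plate_cols = 24,
                         effect_ec50 = 2.5,
                         effect_max = 3,
                         hill_slope = 2,
                         noise_sd = 1,
                         cellcount_coupling = -0.3,
                         baseline_cells_per_well = 1500,
                         block_size = 5,
                         block_cor = 0.95,
                         plate_offset_sd = 0.25,
                         timecourse_concentrations = c(5, 10, 20),
                         tc_noise_sd = 1,
                         gsh_noise = 0.01,
                         seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_features >= 1, n_clusters >= 1, n_compounds_per_cluster >= 1,
            n_inert_compounds >= 0, n_replicate_plates >= 1,
            plate_rows >= 1, plate_rows <= 16, plate_cols >= 1, plate_cols <= 24)
  if (any(concentrations <= 0) || any(diff(concentrations) <= 0)) {
    stop("concentrations must be strictly increasing and positive", call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (effect_max < 0) stop("effect_max must be >= 0", call. = FALSE)
  n_compounds <- n_clusters * n_compounds_per_cluster + n_inert_compounds
  n_conc <- length(concentrations)
  # per plate: treatments + 4 positive controls at every dose + vehicles
  n_needed <- n_compounds * n_conc + 4L * n_conc + n_vehicle_wells_per_plate
  capacity <- plate_rows * plate_cols
  if (n_needed > capacity) {
    stop(sprintf("plate capacity exceeded: %d wells needed, %d available",
                 n_needed, capacity), call. = FALSE)
  }
  cfg$n_compounds <- n_compounds
  class(cfg) <- "synth_config"
  cfg
}

#' Generate planted phenotype signatures
#'
#' Draws `k` unit vectors in feature space with low mutual overlap (maximum
#' absolute pairwise cosine similarity 0.3, matrices redrawn until the bound
#' holds). These play the role of the distinct phenotype cluster directions
#' (tubulin poisons, genotoxins, gross injury, ...) that the clustering stage
#' is expected to recover.
#'
#' @param k number of signatures (>= 1)
#' @param n_features dimensionality (>= k)
#' @param seed RNG seed
#' @param max_cosine pairwise |cosine| bound (default 0.3)
#' @param max_tries redraw attempts before declaring the geometry impossible
#' @return a `k x n_features` matrix with unit-norm rows
#' @export
generate_signatures <- function(k, n_features, seed = 1, max_cosine = 0.3,
                                max_tries = 200) {
  stopifnot(k >= 1, n_features >= k)
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      s <- matrix(rnorm(k * n_features), nrow = k)
      s <- s / sqrt(rowSums(s^2))
      if (k == 1L) return(s)
      g <- abs(tcrossprod(s))
      diag(g) <- 0
      if (max(g) <= max_cosine) return(s)
    }
    stop(sprintf(paste0("could not draw %d signatures in %d dimensions with ",
                        "pairwise |cosine| <= %.2f after %d attempts; ",
                        "the geometry is too tight"),
                 k, n_features, max_cosine, max_tries), call. = FALSE)
  })
}

# category assigned from the planted cluster: gross-injury-like clusters map
# to nonspecific electrophiles, others to prototypical injury classes
.category_for_cluster <- function(cluster, k) {
  ifelse(is.na(cluster), "inactive_analog",
  ifelse(cluster == k, "NSE",
  ifelse(cluster == max(1L, k - 1L), "tubulin_poison",
  ifelse(cluster == max(1L, k - 3L), "genotoxin", "misc_injury"))))
}

.well_labels <- function(rows, cols) {
  as.vector(outer(LETTERS[seq_len(rows)], sprintf("%02d", seq_len(cols)),
                  paste0))
}

#' Generate a synthetic cell-painting screen
#'
#' Emits raw (unnormalized) well profiles for `n_replicate_plates` plates plus
#' a ground-truth table. Vehicle wells are feature-wise noise around a
#' plate-specific baseline; a treatment well for a compound planted in cluster
#' `j` at dose `c` is `baseline + m(c) * sqrt(n_features) * signature_j +
#' noise`, where `m(c)` follows a Hill curve (so `m` is the per-feature RMS
#' effect in noise-SD units). Features come in correlated blocks; cell counts
#' are Poisson with log-mean `log(baseline_cells) + cellcount_coupling * m(c)`.
#'
#' @param config a [synth_config()]
#' @return list with `profiles` (a raw `well_profiles`), `truth` (data.frame
#'   keyed by compound and concentration: planted cluster, category, EC50,
#'   effect magnitude `m`, `true_active` flag), `signatures` (the planted
#'   `k x n_features` matrix) and `config`
#' @export
generate_screen <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  seeds <- derive_seeds(config$seed, 6)
  k <- config$n_clusters
  p <- config$n_features
  feat_blocks <- ceiling(seq_len(p) / config$block_size)
  n_sig_blocks <- max(feat_blocks)
  feat_names <- sprintf("ft%04d_b%03d", seq_len(p), feat_blocks)
  # Signatures are drawn at the correlated-block level and expanded so that
  # block-mates respond identically (redundant features move together, which
  # is what makes them redundant); the expansion preserves unit norm and
  # pairwise cosines. Block-level directions are random orthonormal (QR of a
  # Gaussian matrix, i.e. Haar-distributed), which meets the <= 0.3 pairwise
  # cosine bound for any k <= number of blocks; when there are fewer blocks
  # than clusters, feature-level signatures from generate_signatures() are
  # used instead.
  if (n_sig_blocks >= k) {
    sig_b <- with_seed(seeds[1], {
      g <- matrix(rnorm(n_sig_blocks * n_sig_blocks), n_sig_blocks)
      q <- qr.Q(qr(g))
      t(q[, seq_len(k), drop = FALSE])
    })
    counts <- tabulate(feat_blocks)
    sig <- sig_b[, feat_blocks, drop = FALSE] /
      rep(sqrt(counts[feat_blocks]), each = k)
  } else {
    sig <- generate_signatures(k, p, seed = seeds[1])
  }
  colnames(sig) <- feat_names

  # compound table (treatments + four positive controls)
  n_cpd <- config$n_compounds
  cluster_of <- c(rep(seq_len(k), each = config$n_compounds_per_cluster),
                  rep(NA_integer_, config$n_inert_compounds))
  compounds <- data.frame(
    compound_id = sprintf("CPD%03d", seq_len(n_cpd)),
    planted_cluster = cluster_of,
    role = "treatment",
    stringsAsFactors = FALSE)
  controls <- data.frame(
    compound_id = c("colchicine", "nocodazole", "radicicol", "wortmannin"),
    planted_cluster = pmin(k, c(max(1L, k - 1L), max(1L, k - 1L),
                                max(1L, k - 3L), max(1L, k - 5L))),
    role = "positive_control",
    stringsAsFactors = FALSE)
  compounds <- rbind(compounds, controls)
  compounds$category <- .category_for_cluster(compounds$planted_cluster, k)
  compounds$category[compounds$role == "positive_control"] <- "positive_control"
  compounds$ec50_um <- with_seed(seeds[2], {
    config$effect_ec50 * 2^runif(nrow(compounds), -1, 1)
  })
  compounds$effect_max <- ifelse(is.na(compounds$planted_cluster), 0,
                                 config$effect_max)

  # ground truth, one record per compound x concentration
  truth <- merge(compounds,
                 data.frame(concentration_um = config$concentrations),
                 by = NULL)
  truth$effect <- hill_effect(truth$concentration_um, truth$effect_max,
                              truth$ec50_um, config$hill_slope)
  # detectable-by-design: at least half the reference effect magnitude of
  # 3 noise-SD per feature (the Hill curve only approaches effect_max)
  truth$true_active <- truth$effect >= 1.5 * config$noise_sd
  truth <- truth[order(truth$compound_id, truth$concentration_um), ]
  rownames(truth) <- NULL

  n_conc <- length(config$concentrations)
  labels <- .well_labels(config$plate_rows, config$plate_cols)
  rho <- config$block_cor
  blocks <- ceiling(seq_len(p) / config$block_size)
  n_blocks <- max(blocks)
  baseline <- with_seed(seeds[3], rnorm(p))  # global feature means

  meta_list <- list(); val_list <- list()
  plate_seeds <- derive_seeds(seeds[4], config$n_replicate_plates)
  for (pl in seq_len(config$n_replicate_plates)) {
    plate_id <- sprintf("PLATE%02d", pl)
    res <- with_seed(plate_seeds[pl], {
      plate_offset <- rnorm(p, 0, config$plate_offset_sd)
      # treatment layout: every compound at every dose, once per plate
      trt <- truth[c("compound_id", "planted_cluster", "role",
                     "concentration_um", "effect")]
      veh <- data.frame(compound_id = "VEHICLE", planted_cluster = NA_integer_,
                        role = "vehicle", concentration_um = 0, effect = 0,
                        stringsAsFactors = FALSE)
      veh <- veh[rep(1L, config$n_vehicle_wells_per_plate), ]
      wells <- rbind(trt, veh)
      wells$well <- sample(labels, nrow(wells))  # randomized plate layout
      n <- nrow(wells)
      z_block <- matrix(rnorm(n * n_blocks), n, n_blocks)
      eps <- matrix(rnorm(n * p), n, p)
      noise <- config$noise_sd *
        (sqrt(rho) * z_block[, blocks, drop = FALSE] + sqrt(1 - rho) * eps)
      effect_dir <- matrix(0, n, p)
      planted <- !is.na(wells$planted_cluster) & wells$effect > 0
      if (any(planted)) {
        effect_dir[planted, ] <- (wells$effect[planted] * sqrt(p)) *
          sig[wells$planted_cluster[planted], , drop = FALSE]
      }
      vals <- matrix(baseline + plate_offset, n, p, byrow = TRUE) +
        effect_dir + noise
      colnames(vals) <- feat_names
      lambda <- config$baseline_cells_per_well *
        exp(config$cellcount_coupling * wells$effect)
      wells$cell_count <- rpois(n, lambda)
      list(wells = wells, vals = vals)
    })
    w <- res$wells
    meta_list[[pl]] <- data.frame(
      plate_id = plate_id, well = w$well, compound_id = w$compound_id,
      concentration_um = w$concentration_um, replicate = pl, role = w$role,
      cell_count = w$cell_count, stringsAsFactors = FALSE)
    val_list[[pl]] <- res$vals
  }
  profiles <- well_profiles(do.call(rbind, meta_list), do.call(rbind, val_list))
  list(profiles = profiles,
       truth = truth[c("compound_id", "planted_cluster", "category", "role",
                       "ec50_um", "effect_max", "concentration_um", "effect",
                       "true_active")],
       signatures = sig, config = config)
}

#' Generate synthetic live-cell imaging time courses
#'
#' Emulates a 60-h live-cell cytotoxicity experiment sampled every 4 h
#' (16 time points): confluence follows logistic growth whose rate is damped
#' by the planted effect magnitude, while caspase-3/7 and membrane-integrity
#' object counts (and their overlap) rise with effect and dose. Fluorescence
#' metrics carry an additive autofluorescence background that reagent-free
#' wells measure directly. Three replicate plates; vehicle wells included.
#'
#' @param config a [synth_config()]
#' @param truth the ground-truth table from [generate_screen()]
#' @return long-format data.frame: `plate_id, well, compound_id,
#'   concentration_um, replicate, role, metric, time_h, value`
#' @export
generate_timecourses <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"))
  times <- seq(0, 60, by = 4)
  concs <- config$timecourse_concentrations
  cpds <- unique(truth[c("compound_id", "effect_max", "ec50_um", "role")])
  bg <- 20                      # autofluorescence background (object counts)
  conf0 <- 10; K <- 100; g0 <- 0.08

  traj <- function(m, noise_sd) {
    g <- g0 / (1 + m)
    conf <- K * conf0 * exp(g * times) / (K + conf0 * (exp(g * times) - 1))
    list(confluence = conf + rnorm(length(times), 0, noise_sd * 0.5),
         caspase_count = bg + 200 * m * (times / 60)^2 +
           rnorm(length(times), 0, noise_sd),
         membrane_count = bg + 150 * m * (pmax(0, times - 8) / 52)^2 +
           rnorm(length(times), 0, noise_sd),
         overlap_count = bg + 100 * m * (times / 60)^3 +
           rnorm(length(times), 0, noise_sd))
  }

  seeds <- derive_seeds(derive_seeds(config$seed, 6)[5], 3)
  out <- list()
  for (pl in 1:3) {
    out[[pl]] <- with_seed(seeds[pl], {
      wells <- rbind(
        merge(cpds, data.frame(concentration_um = concs), by = NULL),
        data.frame(compound_id = "VEHICLE", effect_max = 0, ec50_um = 1,
                   role = "vehicle", concentration_um = 0)[rep(1, 8), ],
        data.frame(compound_id = "VEHICLE", effect_max = 0, ec50_um = 1,
                   role = "reagent_free", concentration_um = 0)[rep(1, 8), ])
      labels <- .well_labels(16, 24)
      if (nrow(wells) > length(labels)) {
        stop("too many time-course wells for one 384-well plate", call. = FALSE)
      }
      wells$well <- labels[seq_len(nrow(wells))]
      rows <- lapply(seq_len(nrow(wells)), function(i) {
        m <- hill_effect(wells$concentration_um[i], wells$effect_max[i],
                         wells$ec50_um[i], config$hill_slope)
        tr <- traj(m, config$tc_noise_sd)
        if (wells$role[i] == "reagent_free") {
          # no caspase/membrane reagent: fluorescence channels read background only
          for (mm in c("caspase_count", "membrane_count", "overlap_count")) {
            tr[[mm]] <- bg + rnorm(length(times), 0, config$tc_noise_sd)
          }
        }
        do.call(rbind, lapply(names(tr), function(mm) {
          data.frame(plate_id = sprintf("TCPLATE%02d", pl),
                     well = wells$well[i], compound_id = wells$compound_id[i],
                     concentration_um = wells$concentration_um[i],
                     replicate = pl, role = wells$role[i], metric = mm,
                     time_h = times, value = tr[[mm]],
                     stringsAsFactors = FALSE)
        }))
      })
      do.call(rbind, rows)
    })
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Generate synthetic glutathione luminescence plates
#'
#' Forward-simulates the GSH/GSSG luminescence assay: two assays (total
#' glutathione and GSSG) measured in parallel, each with triplicate 10-point
#' GSH standards (2-fold serial dilutions from 6.4 uM down to ~13 nM),
#' cell-free background wells, vehicle wells and compound wells at the
#' time-course doses in five replicates. Luminescence is linear in
#' concentration (`lum = gain * conc + background`) with relative noise
#' `gsh_noise`. Electrophile-like compounds (NSE/tubulin-class categories
#' flagged as electrophile in the truth table) deplete total glutathione and
#' accumulate GSSG with dose.
#'
#' @param config a [synth_config()]
#' @param truth the ground-truth table from [generate_screen()]
#' @param gain luminescence counts per uM glutathione
#' @param background additive background luminescence (cell-free level)
#' @return list with `plate` (long data.frame of wells:
#'   `plate_id, well, assay, role, compound_id, concentration_um, replicate,
#'   known_conc_um, lum`) and `truth_gsh` (planted total/GSSG uM per
#'   compound x concentration)
#' @export
generate_glutathione_plate <- function(config, truth, gain = 1e5,
                                       background = 500) {
  stopifnot(inherits(config, "synth_config"))
  concs <- config$timecourse_concentrations
  cpds <- unique(truth[c("compound_id", "category", "effect_max", "ec50_um")])
  total0 <- 4; gssg0 <- 0.25    # vehicle-well totals, uM

  grid <- merge(cpds, data.frame(concentration_um = concs), by = NULL)
  m <- hill_effect(grid$concentration_um, grid$effect_max, grid$ec50_um,
                   config$hill_slope)
  dep <- m / (1 + m)
  is_el <- grid$category %in% c("NSE")
  grid$true_total_um <- total0 * (1 - ifelse(is_el, 0.85, 0.2) * dep)
  grid$true_gssg_um <- gssg0 * (1 + ifelse(is_el, 2.5, 0.3) * dep)

  std_conc <- 6.4 / 2^(0:9)
  seeds <- derive_seeds(derive_seeds(config$seed, 6)[6], 2)
  noisy <- function(x) x * (1 + rnorm(length(x), 0, config$gsh_noise))

  make_assay <- function(assay, seed) {
    with_seed(seed, {
      std <- data.frame(role = "standard", compound_id = NA_character_,
                        concentration_um = 0,
                        replicate = rep(1:3, each = length(std_conc)),
                        known_conc_um = rep(std_conc, 3))
      cf <- data.frame(role = "cell_free", compound_id = NA_character_,
                       concentration_um = 0, replicate = 1:6,
                       known_conc_um = NA_real_)
      veh <- data.frame(role = "vehicle", compound_id = "VEHICLE",
                        concentration_um = 0, replicate = 1:5,
                        known_conc_um = NA_real_)
      trt <- merge(grid[c("compound_id", "concentration_um", "true_total_um",
                          "true_gssg_um")],
                   data.frame(replicate = 1:5), by = NULL)
      trt_conc <- if (assay == "total") trt$true_total_um else trt$true_gssg_um
      trt <- data.frame(role = "treatment", compound_id = trt$compound_id,
                        concentration_um = trt$concentration_um,
                        replicate = trt$replicate, known_conc_um = NA_real_,
                        true_conc = trt_conc)
      std$true_conc <- std$known_conc_um
      cf$true_conc <- 0
      veh$true_conc <- if (assay == "total") total0 else gssg0
      w <- rbind(std, cf, veh, trt)
      n <- nrow(w)
      labels <- .well_labels(16, 24)
      n_plates <- ceiling(n / length(labels))
      w$plate_id <- sprintf("GSH_%s_%02d", assay,
                            rep(seq_len(n_plates), each = length(labels))[seq_len(n)])
      w$well <- rep(labels, n_plates)[seq_len(n)]
      w$assay <- assay
      w$lum <- noisy(gain * w$true_conc + background)
      w$true_conc <- NULL
      w[c("plate_id", "well", "assay", "role", "compound_id",
          "concentration_um", "replicate", "known_conc_um", "lum")]
    })
  }
  plate <- rbind(make_assay("total", seed = seeds[1]),
                 make_assay("gssg", seed = seeds[2]))
  rownames(plate) <- NULL
  list(plate = plate,
       truth_gsh = grid[c("compound_id", "category", "concentration_um",
                          "true_total_um", "true_gssg_um")])
}
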