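# Shared fixtures and independent oracles for the test suite.

# Independent brute-force Mahalanobis activity oracle: explicit
# eigendecomposition of the (scaled, uncentered) cross-product, hand-rolled
# group covariances, explicit matrix inverse. Deliberately avoids prcomp()
# and the package's covariance/scoring code paths.
oracle_mahalanobis <- function(treat, veh, variance_target = 0.9) {
  x <- rbind(treat, veh)
  n <- nrow(x)
  denom <- sqrt(colSums(x^2) / (n - 1))
  xs <- sweep(x, 2, denom, "/")
  g <- crossprod(xs) / (n - 1)
  eg <- eigen(g, symmetric = TRUE)
  explained <- eg$values / sum(eg$values)
  q <- which(cumsum(explained) >= variance_target)[1]
  v <- eg$vectors[, seq_len(q), drop = FALSE]
  scores <- xs %*% v
  st <- scores[seq_len(nrow(treat)), , drop = FALSE]
  sc <- scores[-seq_len(nrow(treat)), , drop = FALSE]
  covm <- function(m) {
    mu <- colMeans(m)
    cent <- sweep(m, 2, mu)
    crossprod(cent) / (nrow(m) - 1)
  }
  sigma <- (nrow(st) * covm(st) + nrow(sc) * covm(sc)) / (nrow(st) + nrow(sc))
  d <- colMeans(st) - colMeans(sc)
  list(score = sqrt(drop(t(d) %*% solve(sigma) %*% d)), q = q)
}

# Adjusted Rand index between two label vectors (closed-form contingency
# version; independent of any clustering internals).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Small screen configuration used across tests: 384-well semantics but
# scaled down (fewer features / vehicle wells / compounds) for CPU budget.
# Effect sizes, noise and thresholds are the defaults of the stated world.
small_config <- function(seed = 1, ...) {
  args <- list(n_features = 80, n_compounds_per_cluster = 2,
               n_inert_compounds = 3, n_vehicle_wells_per_plate = 24,
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_config, args)
}

# Tiny hand-built well_profiles object.
toy_profiles <- function(values, roles = NULL, plate = "P1",
                         cell_count = 100) {
  n <- nrow(values)
  if (is.null(roles)) roles <- rep("treatment", n)
  wells <- sprintf("%s%02d", rep(LETTERS[1:16], each = 24)[seq_len(n)],
                   rep(1:24, 16)[seq_len(n)])
  meta <- data.frame(
    plate_id = plate, well = wells,
    compound_id = ifelse(roles == "vehicle", "VEHICLE",
                         sprintf("C%02d", seq_len(n))),
    concentration_um = ifelse(roles == "vehicle", 0, 10),
    replicate = 1L, role = roles, cell_count = cell_count,
    stringsAsFactors = FALSE)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("f%02d", seq_len(ncol(values)))
  }
  well_profiles(meta, values)
}

# Run generate -> normalize (all features) on a small config.
normalized_screen <- function(cfg) {
  scr <- generate_screen(cfg)
  nz <- robust_z_normalize(scr$profiles)
  list(screen = scr, normalized = nz$profiles, params = nz$params)
}

# Truth lookup keyed like treatment_profiles() rownames.
truth_key <- function(truth, col) {
  setNames(truth[[col]], paste(truth$compound_id, truth$concentration_um,
                               sep = "@"))
}
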