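test_that("select_pcs returns the minimal prefix reaching the target", {
  expect_equal(select_pcs(c(0.8, 0.15, 0.05)), 2)
  expect_equal(select_pcs(c(0.95, 0.05)), 1)
  expect_equal(select_pcs(c(0.5, 0.2, 0.15, 0.1, 0.05)), 4)
  expect_warning(q <- select_pcs(c(0.4, 0.3), target = 0.9), "all components")
  expect_equal(q, 2)
  expect_error(select_pcs(c(0.9, 0.4)), "more than 1")
})

test_that("pooled covariance is sample-weighted with a logged ridge", {
  set.seed(11)
  a <- matrix(rnorm(20), 10, 2)
  # identical groups: pooled equals either group covariance
  expect_equal(pooled_covariance(a, a), cov(a), ignore_attr = TRUE)

  # equal sizes: unweighted average
  b <- matrix(rnorm(20), 10, 2)
  expect_equal(pooled_covariance(a, b), (cov(a) + cov(b)) / 2,
               ignore_attr = TRUE)

  # hand-computed 2-D case with unequal sizes
  t2 <- rbind(c(0, 0), c(2, 0), c(0, 2))                 # n_t = 3
  c2 <- rbind(c(1, 1), c(3, 1), c(1, 3), c(3, 3), c(2, 2))  # n_c = 5
  expect_equal(pooled_covariance(t2, c2),
               (3 * cov(t2) + 5 * cov(c2)) / 8, ignore_attr = TRUE)

  # numerically singular input triggers the ridge and reports it
  s <- cbind(1:4, 1:4)  # perfectly collinear
  ps <- pooled_covariance(s, s)
  expect_true(attr(ps, "ridge_used"))
  expect_error(pooled_covariance(a[1, , drop = FALSE], b), "at least 2 rows")
})

test_that("mahalanobis_activity reduces to the expected closed forms", {
  set.seed(21)
  veh <- matrix(rnorm(40, 10), 10, 4)
  # identical point sets: centroids coincide, score 0
  out <- mahalanobis_activity(veh, veh)
  expect_equal(out$score, 0, tolerance = 1e-8)

  # the fixed 4 + 4 two-feature instance against the brute-force oracle
  veh2 <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  veh2 <- rbind(veh2, veh2 + 0.01)    # 8 vehicle wells (precondition)
  trt2 <- rbind(c(3, 3), c(4, 3), c(3, 4), c(4, 4))
  got <- mahalanobis_activity(trt2, veh2, variance_target = 1)
  want <- oracle_mahalanobis(trt2, veh2, variance_target = 1)
  expect_equal(got$q, want$q)
  expect_equal(got$score, want$score, tolerance = 1e-8)

  # q = 1: score is |mean difference| / sqrt(pooled variance)
  t1 <- matrix(c(5, 6, 7), 3, 1)
  c1 <- matrix(c(0.5, 1, 1.5, 2, 2.5, 3, 3.5, 1), 8, 1)
  o <- mahalanobis_activity(t1, c1, center = FALSE, scale = FALSE)
  pooled <- (3 * var(as.numeric(t1)) + 8 * var(as.numeric(c1))) / 11
  expect_equal(o$q, 1)
  expect_equal(o$score, abs(mean(t1) - mean(c1)) / sqrt(pooled),
               tolerance = 1e-10)
})

test_that("mahalanobis_activity matches the brute-force oracle on random instances", {
  # small-instance oracle equivalence (the full >= 100-instance sweep lives
  # in the acceptance suite; here a fast sample across shapes)
  set.seed(33)
  for (i in 1:25) {
    p <- sample(2:6, 1)
    n_t <- sample(4:16, 1)
    n_c <- sample(8:16, 1)
    trt <- matrix(rnorm(n_t * p, mean = 2), n_t, p)
    veh <- matrix(rnorm(n_c * p, mean = 0), n_c, p)
    got <- mahalanobis_activity(trt, veh)
    want <- oracle_mahalanobis(trt, veh)
    expect_equal(got$q, want$q)
    expect_equal(got$score, want$score, tolerance = 1e-8)
  }
})

test_that("activity score is invariant to well and feature permutation", {
  set.seed(41)
  trt <- matrix(rnorm(20, 1), 5, 4)
  veh <- matrix(rnorm(40), 10, 4)
  ref <- mahalanobis_activity(trt, veh)
  p_w <- sample(5); p_v <- sample(10); p_f <- sample(4)
  expect_equal(mahalanobis_activity(trt[p_w, ], veh[p_v, ])$score, ref$score,
               tolerance = 1e-10)
  expect_equal(mahalanobis_activity(trt[, p_f], veh[, p_f])$score, ref$score,
               tolerance = 1e-10)
})

test_that("vehicle null distances are seeded, positive and match the direct route", {
  set.seed(55)
  veh <- matrix(rnorm(30 * 6), 30, 6)
  d1 <- vehicle_null_distances(veh, group_size = 4, seed = 9)
  d2 <- vehicle_null_distances(veh, group_size = 4, seed = 9)
  expect_identical(d1, d2)                      # determinism
  expect_length(d1, 7)                          # floor(30 / 4)
  expect_true(all(d1 > 0))

  # shared-PCA fast path equals scoring each pseudo-group directly
  perm <- with_seed(9, sample.int(30))
  for (g in 1:3) {
    rows <- perm[((g - 1) * 4 + 1):(g * 4)]
    direct <- mahalanobis_activity(veh[rows, ], veh[-rows, ])
    expect_equal(d1[g], direct$score, tolerance = 1e-10)
  }

  expect_error(vehicle_null_distances(veh[1:7, ], group_size = 4), "2 \\* group_size")
  expect_error(vehicle_null_distances(veh[1:10, ], group_size = 5), "8")
})

test_that("actives are called at mean + 3 SD with a strict boundary", {
  null <- c(1, 2, 3, rep(2, 5))                 # mean 2, keeps sd > 0
  res <- data.frame(compound_id = c("a", "b"), activity_score = c(6, 4))
  out <- call_actives(res, c(1, 2, 3, 1, 2, 3, 1, 2, 3))
  m <- mean(c(1, 2, 3, 1, 2, 3, 1, 2, 3)); s <- sd(c(1, 2, 3, 1, 2, 3, 1, 2, 3))
  expect_equal(out$threshold$cutoff, m + 3 * s)
  expect_identical(out$results$active, c(6, 4) > m + 3 * s)

  # boundary: score exactly at the cutoff is inactive
  res2 <- data.frame(activity_score = m + 3 * s)
  expect_false(call_actives(res2, c(1, 2, 3, 1, 2, 3, 1, 2, 3))$results$active)

  expect_error(call_actives(res, c(1, 2, 3)), ">= 8")
  expect_error(call_actives(res, rep(2, 10)), "zero variance")
})

test_that("score_screen exposes both scoring granularities", {
  cfg <- small_config(seed = 47, n_features = 30,
                      n_compounds_per_cluster = 1, n_inert_compounds = 1)
  nx <- normalized_screen(cfg)$normalized
  per_conc <- score_screen(nx, seed = 2)
  per_cpd <- score_screen(nx, seed = 2, granularity = "compound")
  n_cpd <- length(unique(per_conc$results$compound_id))
  expect_equal(nrow(per_cpd$results), n_cpd)
  expect_true(all(is.na(per_cpd$results$concentration_um)))
  expect_equal(nrow(per_conc$results), n_cpd * length(cfg$concentrations))
  # pooled wells per compound = doses x replicate plates
  expect_true(all(per_cpd$results$n_treatment_wells ==
                    length(cfg$concentrations) * cfg$n_replicate_plates))
  # same null partition, same cutoff
  expect_equal(per_cpd$threshold$cutoff, per_conc$threshold$cutoff)
})

test_that("relative cell number averages per-plate vehicle-normalized counts", {
  tm <- data.frame(plate_id = c("P1", "P2", "P3", "P4"),
                   cell_count = c(100, 80, 60, 40))
  vm <- data.frame(plate_id = rep(c("P1", "P2", "P3", "P4"), each = 2),
                   cell_count = rep(100, 8))
  expect_equal(relative_cell_number(tm, vm), 70)     # mean of 100,80,60,40 %
  expect_equal(relative_cell_number(tm[1, ], vm), 100)
  tm$cell_count <- vm$cell_count[seq_len(4)] / 2
  expect_equal(relative_cell_number(tm, vm), 50)
  tm$cell_count[1] <- NA
  expect_error(relative_cell_number(tm, vm), "missing")
})
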