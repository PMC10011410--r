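test_that("correlation distances follow 1 - Pearson r", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  d <- as.matrix(correlation_distance_matrix(x))
  expect_equal(unname(d["a", "b"]), 0, tolerance = 1e-12)   # identical shape
  expect_equal(unname(d["a", "c"]), 2, tolerance = 1e-12)   # r = -1
  expect_equal(unname(diag(d)), rep(0, 3))

  # hand-made 4-feature profiles vs direct cor() arithmetic
  set.seed(61)
  y <- matrix(rnorm(12), 3, 4, dimnames = list(c("p1", "p2", "p3"), NULL))
  dy <- as.matrix(correlation_distance_matrix(y))
  expect_equal(unname(dy["p1", "p2"]), 1 - cor(y["p1", ], y["p2", ]),
               tolerance = 1e-12)
  expect_equal(unname(dy["p2", "p3"]), 1 - cor(y["p2", ], y["p3", ]),
               tolerance = 1e-12)

  flat <- rbind(p1 = c(1, 1, 1, 1), p2 = c(1, 2, 3, 4))
  expect_error(correlation_distance_matrix(flat), "zero-variance.*p1")
})

test_that("ward_cluster recovers planted blobs and handles edge cuts", {
  set.seed(67)
  blob1 <- matrix(rnorm(50, 0), 10, 5) + matrix(rep(c(5, 0, 0, 0, 0), each = 10), 10)
  blob2 <- matrix(rnorm(50, 0), 10, 5) + matrix(rep(c(0, 5, 0, 0, 0), each = 10), 10)
  x <- rbind(blob1, blob2)
  rownames(x) <- sprintf("w%02d", 1:20)
  d <- correlation_distance_matrix(x)
  model <- ward_cluster(d, k = 2)
  planted <- rep(1:2, each = 10)
  expect_equal(adjusted_rand(model$labels, planted), 1)

  # k = n: singletons
  mk <- ward_cluster(d, k = 20)
  expect_equal(length(unique(mk$labels)), 20)

  # duplicate profiles merge first at height 0
  dup <- rbind(x[1:6, ], dupe = x[1, ])
  d2 <- correlation_distance_matrix(dup)
  m2 <- ward_cluster(d2, k = 2)
  expect_equal(min(m2$hclust$height), 0, tolerance = 1e-10)
  first_merge <- m2$hclust$merge[1, ]
  expect_setequal(m2$hclust$labels[-first_merge], c("w01", "dupe"))

  expect_error(ward_cluster(d, k = 21), "between 1")
})

test_that("cluster signatures are member means with label equivariance", {
  x <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(10, 10, 10))
  colnames(x) <- c("f1", "f2", "f3")
  labels <- setNames(c(1L, 1L, 2L), rownames(x))
  sig <- cluster_signatures(labels, x)
  expect_equal(unname(sig["cluster_1", ]), c(2, 2, 2))
  expect_equal(unname(sig["cluster_2", ]), c(10, 10, 10))  # singleton

  # permuting members leaves signatures unchanged
  perm <- c(3, 1, 2)
  sig_p <- cluster_signatures(labels[perm], x[perm, ])
  expect_equal(sig_p, sig)

  expect_error(cluster_signatures(labels[1:2], x), "cover")
})

test_that("signature matching calls HC/NC and is affine-invariant", {
  set.seed(71)
  sig <- matrix(rnorm(9 * 20), 9, 20,
                dimnames = list(paste0("cluster_", 1:9), sprintf("f%02d", 1:20)))
  prof <- setNames(sig[9, ], colnames(sig))
  m <- match_to_signatures(prof, sig)
  expect_equal(m$best_cluster, 9)
  expect_equal(m$best_r, 1, tolerance = 1e-12)
  expect_identical(m$call, "HC")

  # affine rescaling leaves Pearson matching unchanged
  m2 <- match_to_signatures(3 * prof + 7, sig)
  expect_equal(m2$correlations, m$correlations, tolerance = 1e-12)

  # profile orthogonal (r = 0) to the target signature: NC
  set.seed(72)
  target <- sig[9, ]
  noise <- rnorm(20)
  ortho <- noise - target * sum(noise * (target - mean(target))) /
    sum(target * (target - mean(target)))
  expect_equal(cor(ortho, target), 0, tolerance = 1e-10)
  m3 <- match_to_signatures(setNames(ortho, colnames(sig)), sig,
                            nc_threshold = 0.05)
  expect_identical(m3$call, "NC")

  # matching happens over shared features only
  shuffled <- prof[sample(20)]
  m4 <- match_to_signatures(shuffled, sig)
  expect_equal(m4$best_r, 1, tolerance = 1e-12)

  expect_error(match_to_signatures(prof[1:2], sig), "shared features")
})

test_that("uncentered scaled PCA embedding matches an eigendecomposition oracle", {
  set.seed(73)
  x <- matrix(rnorm(15, mean = 3), 3, 5)
  colnames(x) <- sprintf("f%d", 1:5)
  emb <- pca_embedding(x)

  # oracle: eigenvectors of the uncentered scaled cross-product
  xs <- sweep(x, 2, sqrt(colSums(x^2) / (nrow(x) - 1)), "/")
  eg <- eigen(crossprod(xs) / (nrow(x) - 1), symmetric = TRUE)
  want <- xs %*% eg$vectors
  got <- emb$coordinates
  for (j in seq_len(ncol(got))) {
    if (eg$values[j] < 1e-12) next
    expect_equal(abs(got[, j]), abs(want[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }

  # projecting the fitting data reproduces its own coordinates
  expect_equal(project_embedding(emb, x), emb$coordinates,
               ignore_attr = TRUE, tolerance = 1e-10)

  # equal profiles get equal coordinates
  y <- rbind(x, x[1, ])
  emb2 <- pca_embedding(y)
  expect_equal(emb2$coordinates[4, ], emb2$coordinates[1, ], tolerance = 1e-10)

  xz <- cbind(x, fz = 0)
  expect_error(pca_embedding(xz), "zero-variance.*fz")
})

test_that("entanglement is 0 for identical, 1 for reversed, and enumerable", {
  set.seed(79)
  x <- matrix(rnorm(40), 8, 5)
  rownames(x) <- letters[1:8]
  d <- correlation_distance_matrix(x)
  t1 <- hclust(d, method = "ward.D2")
  expect_equal(entanglement(t1, t1), 0)

  # reversed leaf order attains the worst-case normalizer
  t2 <- t1
  t2$order <- rev(t1$order)
  expect_equal(entanglement(t1, t2), 1)
  expect_equal(entanglement(t1, t2, L = 1), 1)

  # n = 4, two adjacent labels swapped, L = 1: 2 / 8 = 0.25
  ta <- list(order = 1:4, labels = c("a", "b", "c", "d"))
  tb <- list(order = 1:4, labels = c("a", "b", "c", "d"))
  class(ta) <- class(tb) <- "hclust"
  tb$order <- c(2, 1, 3, 4)
  expect_equal(entanglement(ta, tb, L = 1), 0.25)

  # symmetry and invariance to consistent relabeling
  expect_equal(entanglement(ta, tb), entanglement(tb, ta))
  tc1 <- ta; tc2 <- tb
  tc1$labels <- tc2$labels <- c("w", "x", "y", "z")
  expect_equal(entanglement(tc1, tc2, L = 1), entanglement(ta, tb, L = 1))

  t3 <- t1; t3$labels <- LETTERS[1:8]
  expect_error(entanglement(t1, t3), "label set")
})

test_that("category summaries and trajectories aggregate correctly", {
  results <- data.frame(
    compound_id = c("c1", "c1", "c2", "c3", "c4"),
    concentration_um = c(10, 20, 20, 20, 20),
    activity_score = c(2, 4, 6, 8, 10),
    active = c(FALSE, TRUE, TRUE, TRUE, TRUE))
  labels <- setNames(c(1L, 1L, 2L, 2L),
                     c("c1@20", "c2@20", "c3@20", "c4@20"))
  categories <- c(c1 = "NSE", c2 = "NSE", c3 = "KATI", c4 = "KATI")
  summ <- category_cluster_summary(results, labels, categories)

  # fractions per category sum to 1
  agg <- tapply(summ$fraction_of_category, summ$category, sum)
  expect_equal(as.numeric(agg), c(1, 1))
  # one category entirely in one cluster
  expect_equal(summ$fraction_of_category[summ$category == "KATI" &
                                           summ$cluster == 2], 1)
  # hand-computed mean activity: NSE in cluster 1 = mean(4, 6) = 5
  expect_equal(summ$mean_activity[summ$category == "NSE" & summ$cluster == 1], 5)
  expect_equal(summ$n[summ$category == "KATI" & summ$cluster == 1], 0)

  traj <- cluster_trajectory(results, labels, "c1")
  expect_equal(traj$concentration_um, c(10, 20))      # ascending dose
  expect_true(is.na(traj$cluster[1]))                 # inactive: no label
  expect_equal(traj$cluster[2], 1L)

  single <- cluster_trajectory(results[3, ], labels, "c2")
  expect_equal(nrow(single), 1)
  expect_error(cluster_trajectory(results, labels, "nope"), "not in results")
})
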