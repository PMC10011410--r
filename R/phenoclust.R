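# Phenotype clustering of treatment profiles: (1 - Pearson) distances, Ward
# linkage, cluster phenotype signatures, signature-correlation matching of
# external profiles, uncentered scaled PCA embedding, dendrogram entanglement
# and category/cluster summaries.

#' Correlation distance matrix between profiles
#'
#' Pairwise distances `d(i, j) = 1 - Pearson r(profile_i, profile_j)`
#' across features; values lie in `[0, 2]`.
#'
#' @param x a `well_profiles` object or numeric matrix (rows = profiles),
#'   with >= 2 profiles and >= 3 features
#' @param ids optional row identifiers (default: compound x concentration
#'   labels for `well_profiles`, rownames otherwise)
#' @return a `dist` object
#' @export
correlation_distance_matrix <- function(x, ids = NULL) {
  vals <- if (inherits(x, "well_profiles")) x$values else as.matrix(x)
  if (is.null(ids)) {
    ids <- if (inherits(x, "well_profiles")) {
      paste(x$meta$compound_id, x$meta$concentration_um, sep = "@")
    } else rownames(vals)
  }
  if (nrow(vals) < 2L || ncol(vals) < 3L) {
    stop("need >= 2 profiles and >= 3 features", call. = FALSE)
  }
  sds <- apply(vals, 1, sd)
  if (any(sds == 0)) {
    stop("zero-variance profile(s): ",
         paste(ids[sds == 0], collapse = ", "), call. = FALSE)
  }
  d <- 1 - cor(t(vals))
  rownames(d) <- colnames(d) <- ids
  as.dist(d)
}

#' Ward clustering of profiles from correlation distances
#'
#' Agglomerative clustering with Ward's minimum-increase-of-sum-of-squares
#' criterion on the (1 - Pearson) distances; by default the Lance-Williams
#' update is applied to squared input distances (`"ward.D2"`), switchable to
#' the unsquared variant (`"ward.D"`). The tree is cut to exactly `k`
#' clusters.
#'
#' @param d a `dist` of pairwise (1 - Pearson) distances with labels
#' @param k number of clusters, `1 <= k <= n` (default 9)
#' @param method `"ward.D2"` (default) or `"ward.D"`
#' @return a `cluster_model` list: `hclust` (the linkage tree), `k`,
#'   `labels` (named integer vector id -> cluster), `ids`
#' @export
ward_cluster <- function(d, k = 9, method = c("ward.D2", "ward.D")) {
  stopifnot(inherits(d, "dist"))
  method <- match.arg(method)
  n <- attr(d, "Size")
  if (k < 1 || k > n) stop("k must be between 1 and the number of profiles (",
                           n, ")", call. = FALSE)
  hc <- hclust(d, method = method)
  labels <- cutree(hc, k = k)
  structure(list(hclust = hc, k = as.integer(k), labels = labels,
                 ids = hc$labels, method = method),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %d profiles, k = %d (%s linkage)\n",
              length(x$labels), x$k, x$method))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Cluster phenotype signatures
#'
#' The phenotype of a cluster is the feature-wise arithmetic mean profile of
#' its members.
#'
#' @param model a `cluster_model` (or a named integer label vector)
#' @param x a `well_profiles` object or matrix whose rows correspond, in
#'   order, to the clustered profiles
#' @return `k x features` matrix of cluster mean signatures, rownames
#'   `"cluster_<j>"`
#' @export
cluster_signatures <- function(model, x) {
  labels <- if (inherits(model, "cluster_model")) model$labels else model
  vals <- if (inherits(x, "well_profiles")) x$values else as.matrix(x)
  if (length(labels) != nrow(vals)) {
    stop("labels do not cover the profile matrix (", length(labels), " vs ",
         nrow(vals), " rows)", call. = FALSE)
  }
  lev <- sort(unique(labels))
  if (inherits(model, "cluster_model") &&
      length(lev) < model$k) {
    stop("empty cluster(s): ",
         paste(setdiff(seq_len(model$k), lev), collapse = ", "), call. = FALSE)
  }
  sig <- do.call(rbind, lapply(lev, function(j) {
    colMeans(vals[labels == j, , drop = FALSE])
  }))
  rownames(sig) <- paste0("cluster_", lev)
  sig
}

#' Match a profile to cluster signatures
#'
#' Correlates one profile against each cluster phenotype over the shared
#' features (profiles from external datasets are first restricted to the
#' feature intersection). The call against the target cluster (the gross
#' injury cluster, by default the last) follows the high-correlation /
#' no-correlation convention: `HC` if `r >= hc_threshold`, `NC` if
#' `|r| <= nc_threshold`, otherwise `intermediate`.
#'
#' @param profile named numeric vector (or 1-row matrix) of feature values
#' @param signatures `k x features` signature matrix (named columns)
#' @param hc_threshold high-correlation call threshold (default 0.5)
#' @param nc_threshold no-correlation call threshold (default 0.2)
#' @param target_cluster row index of the signature the HC/NC call refers to
#'   (default: the last cluster)
#' @return list: `correlations` (named vector over clusters), `best_cluster`,
#'   `best_r`, `call`, `shared_features`, thresholds
#' @export
match_to_signatures <- function(profile, signatures, hc_threshold = 0.5,
                                nc_threshold = 0.2,
                                target_cluster = nrow(signatures)) {
  if (is.matrix(profile)) profile <- profile[1, ]
  prof_m <- matrix(profile, nrow = 1,
                   dimnames = list(NULL, names(profile)))
  al <- align_shared_features(prof_m, signatures)
  if (length(al$shared) < 3L) {
    stop("fewer than 3 shared features between profile and signatures",
         call. = FALSE)
  }
  pv <- as.numeric(al$a)
  if (sd(pv) == 0) {
    stop("profile has zero variance over the shared features", call. = FALSE)
  }
  r <- apply(al$b, 1, function(s) cor(pv, s))
  best <- which.max(r)
  rt <- r[target_cluster]
  call <- if (rt >= hc_threshold) "HC"
          else if (abs(rt) <= nc_threshold) "NC"
          else "intermediate"
  list(correlations = r, best_cluster = unname(best), best_r = unname(r[best]),
       target_cluster = target_cluster, target_r = unname(rt), call = call,
       hc_threshold = hc_threshold, nc_threshold = nc_threshold,
       shared_features = al$shared)
}

#' Uncentered, scaled PCA embedding
#'
#' Fits PCA once on a full set of non-aggregated profiles with columns scaled
#' to unit (uncentered) variance and no mean-centering; any subset or
#' aggregate can then be projected through the stored loadings so that all
#' plots share one coordinate system.
#'
#' @param x a `well_profiles` object or numeric matrix with >= 3 rows
#' @return a `pca_embedding` object: `rotation` (loadings), `scale_factors`,
#'   `coordinates` of the fitting data, `explained` variance fractions
#' @export
pca_embedding <- function(x) {
  vals <- if (inherits(x, "well_profiles")) x$values else as.matrix(x)
  if (nrow(vals) < 3L) stop("need >= 3 profiles", call. = FALSE)
  scale_factors <- sqrt(colSums(vals^2) / (nrow(vals) - 1))
  zero <- which(scale_factors == 0)
  if (length(zero)) {
    stop("zero-variance feature(s) must be filtered before embedding: ",
         paste(colnames(vals)[zero], collapse = ", "), call. = FALSE)
  }
  pc <- prcomp(vals, center = FALSE, scale. = TRUE)
  structure(list(rotation = pc$rotation, scale_factors = scale_factors,
                 coordinates = pc$x,
                 explained = pc$sdev^2 / sum(pc$sdev^2)),
            class = "pca_embedding")
}

#' Project profiles into an existing PCA embedding
#'
#' @param embedding a [pca_embedding()] object
#' @param x profiles (matrix or `well_profiles`) over the same features
#' @return coordinate matrix (rows x components)
#' @export
project_embedding <- function(embedding, x) {
  vals <- if (inherits(x, "well_profiles")) x$values else as.matrix(x)
  stopifnot(ncol(vals) == nrow(embedding$rotation))
  sweep(vals, 2, embedding$scale_factors, "/") %*% embedding$rotation
}

.leaf_order_labels <- function(tree) {
  if (inherits(tree, "hclust")) return(tree$labels[tree$order])
  if (inherits(tree, "dendrogram")) return(labels(tree))
  stop("trees must be hclust or dendrogram objects", call. = FALSE)
}

#' Entanglement between two dendrograms
#'
#' Quantifies leaf-order disagreement between two trees over the same label
#' set. With `r1`, `r2` the ranks of each label in the two leaf orders,
#' entanglement is `sum(|r1 - r2|^L)` normalized by the worst case (one
#' order exactly reversed), giving a value in `[0, 1]`: 0 for identical leaf
#' orders, 1 for a full reversal. Leaf orders are the trees' natural merge
#' orders; no untangling search is applied.
#'
#' @param t1,t2 `hclust` or `dendrogram` objects over identical label sets
#' @param L rank-difference exponent (default 1.5)
#' @return entanglement value in `[0, 1]`
#' @export
entanglement <- function(t1, t2, L = 1.5) {
  l1 <- .leaf_order_labels(t1)
  l2 <- .leaf_order_labels(t2)
  if (!setequal(l1, l2) || length(l1) != length(l2)) {
    stop("trees must share an identical label set", call. = FALSE)
  }
  n <- length(l1)
  if (n < 2L) stop("need at least 2 leaves", call. = FALSE)
  r1 <- seq_len(n)
  r2 <- match(l1, l2)
  worst <- sum(abs(seq_len(n) - rev(seq_len(n)))^L)
  sum(abs(r1 - r2)^L) / worst
}

#' Category-by-cluster summary ("dot plot" table)
#'
#' For every compound category and phenotype cluster: the number of scored
#' treatments, the fraction of the category's treatments they represent, and
#' their mean activity score. Empty cells are emitted with zero counts.
#'
#' @param results activity results data.frame (`compound_id`,
#'   `concentration_um`, `activity_score`)
#' @param labels named integer vector of cluster labels, names formatted
#'   `"<compound_id>@<concentration_um>"` as produced by
#'   [correlation_distance_matrix()]
#' @param categories named character vector compound_id -> category
#' @return data.frame `category, cluster, n, fraction_of_category,
#'   mean_activity`
#' @export
category_cluster_summary <- function(results, labels, categories) {
  key <- paste(results$compound_id, results$concentration_um, sep = "@")
  idx <- match(names(labels), key)
  if (anyNA(idx)) {
    stop("cluster labels present for unscored treatments: ",
         paste(names(labels)[is.na(idx)][1], "..."), call. = FALSE)
  }
  tab <- data.frame(category = unname(categories[results$compound_id[idx]]),
                    cluster = unname(labels),
                    activity = results$activity_score[idx],
                    stringsAsFactors = FALSE)
  if (anyNA(tab$category)) {
    stop("compound(s) without a category", call. = FALSE)
  }
  cats <- sort(unique(tab$category))
  clus <- sort(unique(tab$cluster))
  grid <- expand.grid(category = cats, cluster = clus,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$n <- mapply(function(ca, cl) sum(tab$category == ca & tab$cluster == cl),
                   grid$category, grid$cluster)
  cat_n <- table(tab$category)
  grid$fraction_of_category <- grid$n / as.numeric(cat_n[grid$category])
  grid$mean_activity <- mapply(function(ca, cl) {
    v <- tab$activity[tab$category == ca & tab$cluster == cl]
    if (length(v)) mean(v) else 0
  }, grid$category, grid$cluster)
  grid[order(grid$category, grid$cluster), ]
}

#' Concentration-response cluster trajectory of a compound
#'
#' The "rainbow plot" data: for one compound, the assigned phenotype cluster
#' and activity at each concentration in ascending dose order. Inactive
#' treatments (below the activity cutoff) carry no cluster label
#' (`NA`) since clustering noise profiles would be meaningless; trajectories
#' need not pass through intermediate clusters.
#'
#' @param results activity results data.frame with `active` flags
#' @param labels named cluster label vector (`"<compound>@<conc>"` names);
#'   labels are only consulted for active treatments
#' @param compound_id the compound
#' @return data.frame `concentration_um, activity_score, active, cluster`
#'   in ascending concentration order
#' @export
cluster_trajectory <- function(results, labels, compound_id) {
  sel <- results$compound_id == compound_id
  if (!any(sel)) stop("compound '", compound_id, "' not in results", call. = FALSE)
  out <- results[sel, c("concentration_um", "activity_score", "active")]
  out <- out[order(out$concentration_um), ]
  key <- paste(compound_id, out$concentration_um, sep = "@")
  out$cluster <- ifelse(out$active, unname(labels[key]), NA_integer_)
  rownames(out) <- NULL
  out
}

#' Average replicate wells into treatment profiles
#'
#' Clustering operates on per-treatment profiles: for every compound x
#' concentration, the feature-wise mean over its replicate wells. Vehicle
#' wells are excluded.
#'
#' @param x a `well_profiles` object (normalized/reduced)
#' @param roles metadata roles to include (default treatment and positive
#'   control wells)
#' @return matrix of treatment profiles with `"<compound>@<conc>"` rownames
#' @export
treatment_profiles <- function(x, roles = c("treatment", "positive_control")) {
  stopifnot(inherits(x, "well_profiles"))
  sel <- x$meta$role %in% roles
  key <- paste(x$meta$compound_id[sel], x$meta$concentration_um[sel], sep = "@")
  idx <- split(which(sel), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    colMeans(x$values[i, , drop = FALSE])
  }))
  colnames(out) <- feature_names(x)
  out
}

#' Serialize a cluster tree to Newick
#'
#' Writes the linkage tree with merge heights as branch lengths.
#'
#' @param model a `cluster_model`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_cluster_tree <- function(model, path) {
  stopifnot(inherits(model, "cluster_model"))
  ape::write.tree(ape::as.phylo(model$hclust), file = path)
  invisible(path)
}
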