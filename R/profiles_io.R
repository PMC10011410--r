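#' @importFrom stats cor cov mad median prcomp sd cutree hclust as.dist
#'   rnorm rpois runif setNames aggregate lm coef quantile
#' @importFrom utils head tail
"_PACKAGE"

# Reserved metadata columns, in canonical serialization order. "field" is an
# optional extra column for pre-aggregation (field-level) tables.
.meta_cols <- c("plate_id", "well", "compound_id", "concentration_um",
                "replicate", "role", "cell_count")

.roles <- c("treatment", "vehicle", "positive_control", "reagent_free",
            "cell_free", "standard")

#' Well-profile feature matrix
#'
#' The central container of the pipeline: a rectangular wells x features
#' matrix of morphological profile values together with per-well metadata
#' (plate, well position, compound, concentration, replicate, role, cell
#' count). Rows are wells (or well fields, when a `field` column is present
#' in `meta`); columns are named features.
#'
#' @param meta data.frame with columns `plate_id`, `well`, `compound_id`,
#'   `concentration_um`, `replicate`, `role`, `cell_count` and optionally
#'   `field`. Well labels use the 384-well convention: row letter A-P plus
#'   zero-padded column 01-24 (e.g. "A01", "P24"). Vehicle wells must have
#'   concentration 0.
#' @param values numeric matrix, `nrow(meta)` rows, uniquely named columns.
#' @param provenance one of `"raw"`, `"normalized"`, `"reduced"`.
#' @return an object of class `well_profiles` with elements `meta`,
#'   `values` and `provenance`.
#' @export
well_profiles <- function(meta, values, provenance = "raw") {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  provenance <- match.arg(provenance, c("raw", "normalized", "reduced"))

  missing_cols <- setdiff(.meta_cols, names(meta))
  if (length(missing_cols) > 0L) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(meta) != nrow(values)) {
    stop("metadata has ", nrow(meta), " rows but values has ", nrow(values),
         call. = FALSE)
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("feature columns must have unique names", call. = FALSE)
  }

  bad_well <- !grepl("^[A-P](0[1-9]|1[0-9]|2[0-4])$", meta$well)
  if (any(bad_well)) {
    stop("invalid 384-well position label(s): ",
         paste(unique(meta$well[bad_well]), collapse = ", "), call. = FALSE)
  }
  bad_role <- !meta$role %in% .roles
  if (any(bad_role)) {
    stop("invalid role(s): ", paste(unique(meta$role[bad_role]), collapse = ", "),
         call. = FALSE)
  }
  if (any(meta$concentration_um < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (any(meta$role == "vehicle" & meta$concentration_um != 0)) {
    stop("vehicle wells must have concentration 0", call. = FALSE)
  }
  key_cols <- c("plate_id", "well", if ("field" %in% names(meta)) "field")
  key <- do.call(paste, c(meta[key_cols], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- meta[duplicated(key), key_cols, drop = FALSE]
    stop("duplicate well record(s): ",
         paste(do.call(paste, c(dup, sep = "/")), collapse = ", "),
         call. = FALSE)
  }
  rownames(values) <- NULL
  rownames(meta) <- NULL
  structure(list(meta = meta, values = values, provenance = provenance),
            class = "well_profiles")
}

#' @export
print.well_profiles <- function(x, ...) {
  cat(sprintf("<well_profiles> %d wells x %d features [%s]\n",
              nrow(x$values), ncol(x$values), x$provenance))
  cat("  plates:", length(unique(x$meta$plate_id)),
      " roles:", paste(names(table(x$meta$role)), table(x$meta$role),
                       sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.well_profiles <- function(x) dim(x$values)

#' Subset a well_profiles object
#'
#' `i` selects wells (rows), `j` selects features (columns, by index or name).
#'
#' @param x a `well_profiles` object
#' @param i,j row / column index
#' @param ... ignored
#' @export
`[.well_profiles` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  structure(list(meta = x$meta[i, , drop = FALSE],
                 values = x$values[i, j, drop = FALSE],
                 provenance = x$provenance),
            class = "well_profiles")
}

#' Feature names of a profile matrix
#' @param x a `well_profiles` object
#' @return character vector of feature names
#' @export
feature_names <- function(x) colnames(x$values)

#' Write well profiles to delimited text
#'
#' Serializes metadata columns (in the documented reserved order) followed by
#' feature columns as CSV. Numeric values round-trip within 1e-12 relative.
#'
#' @param x a `well_profiles` object
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_profiles <- function(x, path) {
  stopifnot(inherits(x, "well_profiles"))
  extra <- intersect("field", names(x$meta))
  tab <- cbind(x$meta[c(.meta_cols, extra)], as.data.frame(x$values))
  data.table::fwrite(tab, path)
  invisible(path)
}

#' Read well profiles from delimited text
#'
#' Expects the reserved metadata columns written by [write_profiles()]
#' followed by numeric feature columns. Fails fast on duplicate wells,
#' unparseable numbers and all-missing feature columns, naming the offender.
#'
#' @param path CSV file path
#' @param provenance provenance flag to attach (`"raw"`, `"normalized"`,
#'   `"reduced"`)
#' @return a `well_profiles` object
#' @export
read_profiles <- function(path, provenance = "raw") {
  tab <- data.table::fread(path, data.table = FALSE)
  missing_cols <- setdiff(.meta_cols, names(tab))
  if (length(missing_cols) > 0L) {
    stop("profile file lacks reserved column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  meta_cols <- c(.meta_cols, intersect("field", names(tab)))
  feat_cols <- setdiff(names(tab), meta_cols)
  if (length(feat_cols) == 0L) stop("no feature columns found", call. = FALSE)
  for (fc in feat_cols) {
    col <- tab[[fc]]
    if (all(is.na(col))) {
      stop("feature column '", fc, "' is entirely missing", call. = FALSE)
    }
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
      stop("feature column '", fc, "' is not numeric",
           if (length(bad)) paste0(" (first offending row: ", bad[1], ")"),
           call. = FALSE)
    }
    if (anyNA(col)) {
      stop("feature column '", fc, "' contains missing values (row ",
           which(is.na(col))[1], "); imputation is not supported",
           call. = FALSE)
    }
  }
  well_profiles(tab[meta_cols], as.matrix(tab[feat_cols]),
                provenance = provenance)
}

#' Restrict two profile matrices to their shared features
#'
#' Matching a profile against signatures derived from another dataset is only
#' meaningful over the feature intersection; both matrices are restricted to
#' the shared feature names, in the same order.
#'
#' @param a,b `well_profiles` objects, or plain numeric matrices with named
#'   columns
#' @return list with elements `a`, `b` (restricted inputs) and `shared`
#'   (the common feature names, in `a`'s order)
#' @export
align_shared_features <- function(a, b) {
  fa <- if (inherits(a, "well_profiles")) feature_names(a) else colnames(a)
  fb <- if (inherits(b, "well_profiles")) feature_names(b) else colnames(b)
  shared <- intersect(fa, fb)
  if (length(shared) == 0L) {
    stop("no shared features between the two matrices", call. = FALSE)
  }
  take <- function(x, keep) {
    if (inherits(x, "well_profiles")) x[, keep] else x[, keep, drop = FALSE]
  }
  list(a = take(a, shared), b = take(b, shared), shared = shared)
}

#' Validate a plate map
#'
#' Report-only check of a plate layout table: counts wells per role on each
#' plate, flags invalid well position labels and plates without vehicle wells
#' (fatal for per-plate normalization).
#'
#' @param map data.frame with at least `plate_id`, `well`, `role`
#' @return list with `per_plate` (a plate x role count table as data.frame,
#'   plus an `n_vehicle` column and `vehicle_ok` flag) and `issues`
#'   (character vector of problems found; empty when clean)
#' @export
validate_platemap <- function(map) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  stopifnot(all(c("plate_id", "well", "role") %in% names(map)))
  issues <- character(0)

  bad_well <- !grepl("^[A-P](0[1-9]|1[0-9]|2[0-4])$", map$well)
  if (any(bad_well)) {
    issues <- c(issues, paste0("invalid well position: plate ",
                               map$plate_id[bad_well], " well '",
                               map$well[bad_well], "'"))
  }
  bad_role <- !map$role %in% .roles
  if (any(bad_role)) {
    issues <- c(issues, paste0("unknown role '", unique(map$role[bad_role]), "'"))
  }

  counts <- as.data.frame.matrix(table(map$plate_id, map$role))
  counts <- cbind(plate_id = rownames(counts), counts,
                  stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  counts$n_vehicle <- if ("vehicle" %in% names(counts)) counts$vehicle else 0L
  counts$vehicle_ok <- counts$n_vehicle > 0L
  if (any(!counts$vehicle_ok)) {
    issues <- c(issues,
                paste0("plate ", counts$plate_id[!counts$vehicle_ok],
                       " has no vehicle wells: per-plate normalization impossible"))
  }
  list(per_plate = counts, issues = issues)
}
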