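#' Areal dataset container
#'
#' Bundles the areal unit table (populations, K outcome counts, C raw
#' covariates) with its adjacency structure and per-covariate orientation
#' flags. Constructed by [load_dataset()] or [simulate_dataset()].
#'
#' @param ids unit identifiers (length n).
#' @param populations positive integer vector (length n).
#' @param counts n-by-K nonnegative integer matrix of outcome counts.
#' @param covariates n-by-C numeric matrix of raw sociodemographic variables.
#' @param adjacency an `svc_adjacency` over the same units, in the same order.
#' @param orientation character vector of length C, each `"direct"` or
#'   `"inverse"`; inverse-oriented variables (e.g. per capita income) are
#'   flipped with `max(x) - x` before decile scoring so that larger oriented
#'   values always mean greater disadvantage.
#' @return an object of class `areal_dataset`.
#' @export
areal_dataset <- function(ids, populations, counts, covariates, adjacency,
                          orientation = rep("direct", ncol(covariates))) {
  counts <- as.matrix(counts); covariates <- as.matrix(covariates)
  n <- length(ids)
  if (n < 10L) stop("dataset must have at least 10 units")
  stopifnot(length(populations) == n, nrow(counts) == n, nrow(covariates) == n)
  if (anyNA(populations) || anyNA(counts) || anyNA(covariates)) {
    stop("areal_dataset does not admit missing values; filter before construction")
  }
  if (any(populations <= 0)) stop("all retained units must have positive population")
  if (any(counts < 0) || any(counts != round(counts))) stop("counts must be nonnegative integers")
  if (length(orientation) != ncol(covariates) ||
      !all(orientation %in% c("direct", "inverse"))) {
    stop("orientation must be one 'direct'/'inverse' flag per covariate")
  }
  stopifnot(inherits(adjacency, "svc_adjacency"), adjacency$n == n)
  if (!identical(as.character(ids), adjacency$ids)) {
    stop("unit ids must match the adjacency ids in order")
  }
  validate_adjacency(adjacency)
  structure(list(ids = as.character(ids),
                 populations = as.numeric(populations),
                 counts = counts, covariates = covariates,
                 adjacency = adjacency, orientation = orientation,
                 n = n, K = ncol(counts), C = ncol(covariates)),
            class = "areal_dataset")
}

#' @export
print.areal_dataset <- function(x, ...) {
  cat(sprintf("areal_dataset: n=%d units, K=%d outcomes, C=%d covariates\n",
              x$n, x$K, x$C))
  invisible(x)
}

#' Load an areal dataset from a unit table and adjacency file
#'
#' Reads `units.csv` (columns `id`, `population`, `y_1..y_K`, `x_1..x_C`) and
#' a GAL or edge-list adjacency file. Units with zero (or missing) population
#' or any missing covariate are dropped, mirroring the usual exclusion of
#' unpopulated and incompletely observed block groups; the drop counts are
#' reported via `message()` and attached as the `"exclusions"` attribute.
#' Decile cutpoints are computed later, on the analysis set only.
#'
#' @param units_path CSV of the unit table.
#' @param adjacency_path `.gal` file, or an edge CSV with `from`/`to` columns.
#' @param orientation named character vector (or path to a YAML mapping)
#'   assigning `"direct"`/`"inverse"` per covariate column name; unnamed
#'   covariates default to `"direct"`.
#' @return an `areal_dataset` (attribute `"exclusions"` holds the counts).
#' @export
load_dataset <- function(units_path, adjacency_path, orientation = NULL) {
  df <- utils::read.csv(units_path)
  if (!all(c("id", "population") %in% names(df))) {
    stop("units file must have 'id' and 'population' columns")
  }
  ycols <- grep("^y_", names(df), value = TRUE)
  xcols <- grep("^x_", names(df), value = TRUE)
  if (length(ycols) < 1L || length(xcols) < 1L) {
    stop("units file must have outcome columns y_1.. and covariate columns x_1..")
  }
  df$id <- as.character(df$id)

  adj_all <- if (grepl("\\.gal$", adjacency_path, ignore.case = TRUE)) {
    read_gal(adjacency_path)
  } else {
    read_edge_csv(adjacency_path, df$id)
  }
  if (!setequal(adj_all$ids, df$id)) {
    stop("unit ids in the adjacency file do not match the units file")
  }
  # align the unit table to adjacency order
  df <- df[match(adj_all$ids, df$id), , drop = FALSE]

  zero_pop <- is.na(df$population) | df$population <= 0
  miss_cov <- apply(df[, xcols, drop = FALSE], 1L, anyNA) & !zero_pop
  keep <- !zero_pop & !miss_cov
  n_zero <- sum(zero_pop); n_miss <- sum(miss_cov)
  if (n_zero + n_miss > 0L) {
    message(sprintf("load_dataset: dropped %d zero-population and %d missing-covariate units (%d -> %d)",
                    n_zero, n_miss, nrow(df), sum(keep)))
  }
  df <- df[keep, , drop = FALSE]
  adj <- subset_adjacency(adj_all, keep)
  if (!is_connected(adj)) {
    stop("adjacency graph is disconnected after exclusions; cannot proceed")
  }
  if (anyNA(df[, ycols])) stop("missing outcome counts are not supported")

  ori <- rep("direct", length(xcols))
  names(ori) <- xcols
  if (!is.null(orientation)) {
    if (is.character(orientation) && length(orientation) == 1L &&
        file.exists(orientation)) {
      orientation <- unlist(yaml::read_yaml(orientation))
    }
    bad <- setdiff(names(orientation), xcols)
    if (length(bad)) stop("orientation refers to unknown covariates: ",
                          paste(bad, collapse = ", "))
    ori[names(orientation)] <- unname(orientation)
  }

  ds <- areal_dataset(ids = df$id, populations = df$population,
                      counts = as.matrix(df[, ycols, drop = FALSE]),
                      covariates = as.matrix(df[, xcols, drop = FALSE]),
                      adjacency = adj, orientation = unname(ori))
  attr(ds, "exclusions") <- c(zero_population = n_zero, missing_covariates = n_miss)
  ds
}

#' Orient a covariate so larger values mean greater disadvantage
#'
#' Direct orientation is the identity; inverse orientation applies
#' `max(x) - x`, the standard flip used for variables such as per capita
#' income whose raw direction opposes the disadvantage construct.
#'
#' @param x numeric vector (finite).
#' @param flag `"direct"` or `"inverse"`.
#' @return the oriented vector.
#' @examples
#' orient_variable(c(1, 4, 10), "inverse")  # 9 6 0
#' @export
orient_variable <- function(x, flag = c("direct", "inverse")) {
  flag <- match.arg(flag)
  if (any(!is.finite(x))) stop("orient_variable requires finite values")
  if (flag == "direct") x else max(x) - x
}

#' Decile-score a variable
#'
#' Assigns each unit the smallest decile d in 1..10 whose empirical cutpoint
#' (quantiles at probabilities 0.1, ..., 0.9, median-unbiased definition,
#' `type = 8`) is >= the unit's value; tied values share a decile, assigned to
#' the lowest admissible one. Decile coding puts heterogeneous covariates on
#' a common 1-10 scale, damping outliers and measurement noise, which is what
#' the weighted index consumes.
#'
#' @param x oriented numeric vector, length >= 10.
#' @return list with integer vector `q` (values in 1..10) and the 9-vector
#'   `cutpoints`.
#' @export
compute_deciles <- function(x) {
  if (length(x) < 10L) stop("decile scoring needs at least 10 units")
  if (any(!is.finite(x))) stop("compute_deciles requires finite values")
  cut <- stats::quantile(x, probs = seq(0.1, 0.9, by = 0.1), type = 8, names = FALSE)
  if (max(x) == min(x)) {
    warning("constant column: all units assigned decile 1")
    return(list(q = rep(1L, length(x)), cutpoints = cut))
  }
  q <- findInterval(x, cut, left.open = TRUE) + 1L
  list(q = as.integer(q), cutpoints = cut)
}

#' Build the decile design matrix for a dataset
#'
#' Orients every covariate per the dataset's orientation flags, then
#' decile-scores each column on the analysis set.
#'
#' @param dataset an `areal_dataset`.
#' @return object of class `decile_design`: `q` (n-by-C integer matrix),
#'   `cutpoints` (9-by-C), `orientation`.
#' @export
decile_design <- function(dataset) {
  stopifnot(inherits(dataset, "areal_dataset"))
  C <- dataset$C
  q <- matrix(NA_integer_, dataset$n, C)
  cuts <- matrix(NA_real_, 9L, C)
  for (j in seq_len(C)) {
    xo <- orient_variable(dataset$covariates[, j], dataset$orientation[j])
    d <- compute_deciles(xo)
    q[, j] <- d$q
    cuts[, j] <- d$cutpoints
  }
  colnames(q) <- colnames(dataset$covariates)
  structure(list(q = q, cutpoints = cuts, orientation = dataset$orientation),
            class = "decile_design")
}

#' Expected counts under internal standardization
#'
#' For each outcome k the overall rate is `r_k = sum_i y_ik / sum_i p_i` and
#' the expected count is `E_ik = r_k * p_i`, so that by construction
#' `sum_i E_ik = sum_i y_ik` — the usual internally standardized baseline for
#' Poisson relative-risk models.
#'
#' @param y n-by-K nonnegative count matrix.
#' @param p positive population vector, length n.
#' @return list with `rates` (K-vector) and `E` (n-by-K matrix).
#' @export
compute_expected_counts <- function(y, p) {
  y <- as.matrix(y)
  if (any(p <= 0)) stop("populations must be positive")
  if (any(y < 0)) stop("counts must be nonnegative")
  tot <- colSums(y)
  if (any(tot == 0)) {
    stop("outcome column with zero total count: overall rate undefined")
  }
  r <- tot / sum(p)
  E <- outer(p, r)
  dimnames(E) <- dimnames(y)
  list(rates = r, E = E)
}
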