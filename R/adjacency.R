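#' Areal adjacency structures
#'
#' An adjacency object represents the symmetric, binary, zero-diagonal
#' neighbor structure of a set of areal units. Internally it is stored as an
#' edge list plus a neighbor index list (CSR-like), which scales to thousands
#' of units without a dense n-by-n matrix.
#'
#' @param ids character or integer vector of unit identifiers (length n).
#' @param edges two-column integer matrix of unit indices (1-based), one row
#'   per unordered neighbor pair.
#' @return An object of class `svc_adjacency` with elements `ids`, `n`,
#'   `edges` (i < j per row), and `nbr` (list of neighbor index vectors).
#' @keywords internal
new_adjacency <- function(ids, edges) {
  n <- length(ids)
  if (anyDuplicated(ids)) stop("duplicate unit ids in adjacency")
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L | edges > n)) stop("edge index out of range")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-neighbor (nonzero diagonal) not allowed")
    swap <- edges[, 1L] > edges[, 2L]
    edges[swap, ] <- edges[swap, c(2L, 1L)]
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  nbr <- vector("list", n)
  for (i in seq_len(n)) nbr[[i]] <- integer(0)
  if (nrow(edges) > 0L) {
    half <- split(c(edges[, 2L], edges[, 1L]), c(edges[, 1L], edges[, 2L]))
    for (nm in names(half)) nbr[[as.integer(nm)]] <- sort(half[[nm]])
  }
  structure(list(ids = as.character(ids), n = n, edges = edges, nbr = nbr),
            class = "svc_adjacency")
}

#' @export
print.svc_adjacency <- function(x, ...) {
  cat(sprintf("svc_adjacency: %d units, %d edges, %s\n", x$n, nrow(x$edges),
              if (is_connected(x)) "connected" else "DISCONNECTED"))
  invisible(x)
}

degrees <- function(adj) lengths(adj$nbr)

#' Test whether an adjacency structure is connected
#'
#' Breadth-first search from the first unit; the structure is connected when
#' every unit is reached.
#'
#' @param adj an `svc_adjacency` object.
#' @return logical scalar.
#' @export
is_connected <- function(adj) {
  n <- adj$n
  if (n == 0L) return(FALSE)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0L) {
    frontier <- unique(unlist(adj$nbr[queue], use.names = FALSE))
    frontier <- frontier[!seen[frontier]]
    seen[frontier] <- TRUE
    queue <- frontier
  }
  all(seen)
}

validate_adjacency <- function(adj) {
  stopifnot(inherits(adj, "svc_adjacency"))
  # symmetry and zero diagonal are guaranteed by construction; check connectivity
  if (!is_connected(adj)) stop("adjacency graph is disconnected (single component required)")
  invisible(adj)
}

#' Build a regular lattice adjacency
#'
#' Constructs the neighbor structure of an `nrows` x `ncols` grid under rook
#' (shared edge) or queen (shared edge or corner) contiguity. Units are
#' labelled `"u1"`, ..., `"u(nrows*ncols)"` in row-major order. This stands in
#' for real areal geographies (e.g. census block groups) in synthetic studies.
#'
#' @param nrows,ncols grid dimensions, each at least 2.
#' @param connectivity `"rook"` (default) or `"queen"`.
#' @return an `svc_adjacency` object; always connected.
#' @examples
#' adj <- make_lattice(3, 3)
#' table(lengths(adj$nbr))
#' @export
make_lattice <- function(nrows, ncols, connectivity = c("rook", "queen")) {
  connectivity <- match.arg(connectivity)
  nrows <- as.integer(nrows); ncols <- as.integer(ncols)
  if (nrows < 2L || ncols < 2L) stop("nrows and ncols must each be >= 2")
  idx <- function(r, c) (r - 1L) * ncols + c
  rr <- rep(seq_len(nrows), each = ncols)
  cc <- rep(seq_len(ncols), times = nrows)
  e_right <- cbind(idx(rr, cc), idx(rr, cc + 1L))[cc < ncols, , drop = FALSE]
  e_down  <- cbind(idx(rr, cc), idx(rr + 1L, cc))[rr < nrows, , drop = FALSE]
  edges <- rbind(e_right, e_down)
  if (connectivity == "queen") {
    e_dr <- cbind(idx(rr, cc), idx(rr + 1L, cc + 1L))[rr < nrows & cc < ncols, , drop = FALSE]
    e_dl <- cbind(idx(rr, cc), idx(rr + 1L, cc - 1L))[rr < nrows & cc > 1L, , drop = FALSE]
    edges <- rbind(edges, e_dr, e_dl)
  }
  adj <- new_adjacency(paste0("u", seq_len(nrows * ncols)), edges)
  if (!is_connected(adj)) stop("internal error: lattice adjacency disconnected")
  adj
}

#' Read a GAL spatial-weights file
#'
#' The GAL format has a header line whose last-but-one or only numeric field
#' is the unit count, followed by one `"id degree"` line and one line of
#' neighbor ids per unit. Both the plain (`"n"`) and the four-field
#' (`"0 n file area"`) header variants are accepted.
#'
#' @param path path to a `.gal` file.
#' @return an `svc_adjacency` object.
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- as.integer(if (length(header) >= 2L) header[2L] else header[1L])
  if (is.na(n) || n < 1L) stop("malformed GAL header: ", lines[1L])
  ids <- character(n)
  nbr_ids <- vector("list", n)
  pos <- 2L
  for (i in seq_len(n)) {
    rec <- strsplit(trimws(lines[pos]), "\\s+")[[1L]]
    ids[i] <- rec[1L]
    deg <- as.integer(rec[2L])
    nbr_ids[[i]] <- if (deg > 0L) strsplit(trimws(lines[pos + 1L]), "\\s+")[[1L]] else character(0)
    if (length(nbr_ids[[i]]) != deg) {
      stop(sprintf("GAL record for unit %s declares %d neighbors but lists %d",
                   ids[i], deg, length(nbr_ids[[i]])))
    }
    pos <- pos + ifelse(deg > 0L, 2L, 2L)
  }
  lookup <- stats::setNames(seq_len(n), ids)
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    j <- lookup[nbr_ids[[i]]]
    if (anyNA(j)) stop("GAL neighbor id not among unit ids: ",
                       paste(nbr_ids[[i]][is.na(j)], collapse = ", "))
    if (length(j)) cbind(i, as.integer(j)) else NULL
  }))
  # require the listing to be symmetric before deduplication
  if (!is.null(edges)) {
    key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    cnt <- table(key)
    if (any(cnt != 2L)) {
      bad <- names(cnt)[cnt != 2L][1L]
      stop("asymmetric adjacency: pair (", gsub(" ", ",", bad),
           ") listed in one direction only")
    }
  }
  new_adjacency(ids, if (is.null(edges)) matrix(integer(0), ncol = 2L) else edges)
}

#' Write a GAL spatial-weights file
#'
#' @param adj an `svc_adjacency` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gal <- function(adj, path) {
  stopifnot(inherits(adj, "svc_adjacency"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(adj$n), con)
  for (i in seq_len(adj$n)) {
    nb <- adj$nbr[[i]]
    writeLines(paste(adj$ids[i], length(nb)), con)
    writeLines(paste(adj$ids[nb], collapse = " "), con)
  }
  invisible(path)
}

#' Read adjacency from an edge-list CSV
#'
#' Expects columns `from` and `to` holding unit ids; each unordered pair may
#' appear once or twice (both directions).
#'
#' @param path CSV path.
#' @param ids full vector of unit ids (isolated units are impossible in a
#'   connected graph, but the id universe must come from the caller).
#' @return an `svc_adjacency` object.
#' @export
read_edge_csv <- function(path, ids) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("from", "to") %in% names(df))) stop("edge CSV needs 'from' and 'to' columns")
  lookup <- stats::setNames(seq_along(ids), as.character(ids))
  i <- lookup[df$from]; j <- lookup[df$to]
  if (anyNA(i) || anyNA(j)) stop("edge CSV references unknown unit ids")
  new_adjacency(ids, cbind(as.integer(i), as.integer(j)))
}

#' Build an adjacency structure from an explicit edge list
#'
#' @param ids unit identifiers.
#' @param edges two-column matrix of 1-based unit indices, one row per
#'   unordered neighbor pair.
#' @return an `svc_adjacency` object.
#' @export
adjacency_from_edges <- function(ids, edges) new_adjacency(ids, edges)

#' Restrict an adjacency structure to a subset of units
#'
#' @param adj an `svc_adjacency` object.
#' @param keep logical or integer index of units to retain.
#' @return an `svc_adjacency` on the retained units (edges within the subset).
#' @keywords internal
subset_adjacency <- function(adj, keep) {
  idx <- seq_len(adj$n)[keep]
  remap <- integer(adj$n)
  remap[idx] <- seq_along(idx)
  e <- adj$edges
  e <- e[e[, 1L] %in% idx & e[, 2L] %in% idx, , drop = FALSE]
  new_adjacency(adj$ids[idx], cbind(remap[e[, 1L]], remap[e[, 2L]]))
}

#' Graph Laplacian of an adjacency structure
#'
#' @param adj an `svc_adjacency` object.
#' @return dense n-by-n Laplacian matrix D - A.
#' @keywords internal
graph_laplacian <- function(adj) {
  n <- adj$n
  L <- matrix(0, n, n)
  e <- adj$edges
  L[cbind(e[, 1L], e[, 2L])] <- -1
  L[cbind(e[, 2L], e[, 1L])] <- -1
  diag(L) <- degrees(adj)
  L
}
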