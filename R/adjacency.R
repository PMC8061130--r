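#' Adjacency structure over small areas
#'
#' A `bymsir_adjacency` object stores, for each area, the indices of the
#' areas it shares a boundary with.  Weights are binary and symmetric
#' (`w_ij = w_ji`, `w_ii = 0`).  Areas with no neighbours are retained and
#' flagged as islands.
#'
#' @param ids character vector of unique area identifiers.
#' @param nb list of integer vectors, one per area, giving 1-based indices of
#'   that area's neighbours.
#' @return an object of class `bymsir_adjacency` with elements `ids`, `nb`
#'   (neighbour index lists), `n` (number of areas) and `islands` (indices of
#'   areas with no neighbours).
#' @export
adjacency_structure <- function(ids, nb) {
  ids <- as.character(ids)
  stop_if(anyDuplicated(ids) > 0L, "area ids must be unique")
  stop_if(length(nb) != length(ids), "one neighbour list per area required")
  nb <- lapply(nb, function(x) sort(unique(as.integer(x))))
  n <- length(ids)
  for (i in seq_len(n)) {
    stop_if(any(nb[[i]] < 1L | nb[[i]] > n), "neighbour index out of range")
    stop_if(any(nb[[i]] == i), "self-neighbour not allowed")
    for (j in nb[[i]])
      stop_if(!(i %in% nb[[j]]), sprintf("adjacency not symmetric: %s -> %s", ids[i], ids[j]))
  }
  islands <- which(lengths(nb) == 0L)
  if (length(islands))
    warning(sprintf("%d island area(s) with no neighbours: %s",
                    length(islands), paste(ids[islands], collapse = ", ")))
  structure(list(ids = ids, nb = nb, n = n, islands = islands),
            class = "bymsir_adjacency")
}

#' @export
print.bymsir_adjacency <- function(x, ...) {
  cat(sprintf("Adjacency over %d areas: %d edges, %d island(s)\n",
              x$n, nrow(adjacency_edges(x)), length(x$islands)))
  invisible(x)
}

#' Unique undirected edges of an adjacency structure
#'
#' @param adj a `bymsir_adjacency`.
#' @return two-column integer matrix, one row per unordered neighbour pair
#'   with `i < j`.
#' @export
adjacency_edges <- function(adj) {
  stopifnot(inherits(adj, "bymsir_adjacency"))
  ii <- rep.int(seq_len(adj$n), lengths(adj$nb))
  jj <- unlist(adj$nb, use.names = FALSE)
  if (!length(ii)) return(matrix(integer(), 0L, 2L))
  keep <- ii < jj
  cbind(i = ii[keep], j = jj[keep])
}

#' Binary (or row-standardised) spatial weight matrix
#'
#' @param adj a `bymsir_adjacency`.
#' @param row_standardise divide each row by its neighbour count so rows sum
#'   to one (islands keep an all-zero row).
#' @return an `n x n` numeric matrix.
#' @export
adjacency_matrix <- function(adj, row_standardise = FALSE) {
  stopifnot(inherits(adj, "bymsir_adjacency"))
  W <- matrix(0, adj$n, adj$n, dimnames = list(adj$ids, adj$ids))
  for (i in seq_len(adj$n)) W[i, adj$nb[[i]]] <- 1
  if (row_standardise) {
    m <- lengths(adj$nb)
    W[m > 0L, ] <- W[m > 0L, , drop = FALSE] / m[m > 0L]
  }
  W
}

## ---- contiguity from polygon geometry -------------------------------------

## Collinear-overlap length of two segments; 0 unless they lie on the same
## line and overlap over a stretch of positive length. Shared endpoints alone
## (corner touches) contribute 0.
segment_overlap_length <- function(p1, p2, q1, q2, tol) {
  d <- p2 - p1
  len <- sqrt(sum(d^2))
  if (len < tol) return(0)
  u <- d / len
  ## both endpoints of q must lie on the infinite line through p1-p2
  off1 <- (q1 - p1) - sum((q1 - p1) * u) * u
  off2 <- (q2 - p1) - sum((q2 - p1) * u) * u
  if (sqrt(sum(off1^2)) > tol || sqrt(sum(off2^2)) > tol) return(0)
  t1 <- sum((q1 - p1) * u)
  t2 <- sum((q2 - p1) * u)
  lo <- max(0, min(t1, t2))
  hi <- min(len, max(t1, t2))
  max(0, hi - lo)
}

poly_edges <- function(ring) {
  ## ring: closed coordinate matrix (first row == last row)
  k <- nrow(ring) - 1L
  list(a = ring[seq_len(k), , drop = FALSE], b = ring[seq_len(k) + 1L, , drop = FALSE])
}

#' Build contiguity adjacency from polygon features
#'
#' Two areas are neighbours if and only if their boundaries share a segment
#' of positive length; polygons touching only at a single point (a shared
#' corner) are not neighbours.  This is rook contiguity on a regular lattice
#' and matches the convention of defining neighbouring areas as those sharing
#' a common boundary.
#'
#' @param features list of features, each a list with `area_id` (character)
#'   and `ring` (closed two-column coordinate matrix).  The output of
#'   [read_geojson()] or the `$features` element of [make_lattice()] has this
#'   shape.
#' @param tol length tolerance for the shared-boundary predicate; coordinates
#'   closer than `tol` are treated as coincident.  The default suits exact
#'   synthetic lattices; loosen for real-world polygons.
#' @return a [adjacency_structure()] object.
#' @export
adjacency_from_polygons <- function(features, tol = 1e-9) {
  ids <- vapply(features, function(f) as.character(f$area_id), character(1))
  stop_if(anyDuplicated(ids) > 0L, "duplicate area_id in features")
  rings <- lapply(features, function(f) {
    r <- as.matrix(f$ring)
    stop_if(!is.numeric(r) || ncol(r) != 2L || nrow(r) < 4L || anyNA(r),
            sprintf("invalid geometry for feature '%s'", f$area_id))
    stop_if(any(abs(r[1L, ] - r[nrow(r), ]) > tol),
            sprintf("ring not closed for feature '%s'", f$area_id))
    r
  })
  n <- length(rings)
  bbox <- t(vapply(rings, function(r) c(min(r[, 1]), max(r[, 1]), min(r[, 2]), max(r[, 2])),
                   numeric(4)))
  edges <- lapply(rings, poly_edges)
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ## bounding-box prefilter
      if (bbox[i, 2] < bbox[j, 1] - tol || bbox[j, 2] < bbox[i, 1] - tol ||
          bbox[i, 4] < bbox[j, 3] - tol || bbox[j, 4] < bbox[i, 3] - tol) next
      shared <- 0
      ei <- edges[[i]]; ej <- edges[[j]]
      for (a in seq_len(nrow(ei$a))) {
        for (b in seq_len(nrow(ej$a))) {
          shared <- shared + segment_overlap_length(ei$a[a, ], ei$b[a, ],
                                                    ej$a[b, ], ej$b[b, ], tol)
        }
        if (shared > tol) break
      }
      if (shared > tol) {
        nb[[i]] <- c(nb[[i]], j)
        nb[[j]] <- c(nb[[j]], i)
      }
    }
  }
  adjacency_structure(ids, nb)
}
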