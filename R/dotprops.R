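#' Construct a dotprops object
#'
#' A dotprops object represents a neuron as N points in registered template
#' space (micrometers), each carrying a unit tangent vector giving the local
#' heading of the neurite. It is the representation scored by [raw_score()].
#' Tangent sign is arbitrary and never canonicalized; all scoring uses the
#' absolute dot product.
#'
#' @param points N x 3 numeric matrix of positions (micrometers).
#' @param vect N x 3 numeric matrix of unit tangent vectors.
#' @param k Neighborhood size used to estimate the tangents (or `NA` when
#'   unknown, e.g. for externally supplied vectors).
#' @param label Identifier string.
#' @return An object of class `dotprops`.
#' @export
dotprops <- function(points, vect, k = NA_integer_, label = "") {
  points <- as.matrix(points)
  vect <- as.matrix(vect)
  if (ncol(points) != 3L || ncol(vect) != 3L)
    stop("points and vect must have 3 columns")
  if (nrow(points) != nrow(vect))
    stop("points and vect must have the same number of rows")
  if (nrow(points) > 0L) {
    nrm <- sqrt(rowSums(vect^2))
    if (any(abs(nrm - 1) > 1e-9))
      stop("tangent vectors must be unit length (tolerance 1e-9)")
  }
  storage.mode(points) <- "double"
  storage.mode(vect) <- "double"
  dimnames(points) <- NULL
  dimnames(vect) <- NULL
  structure(list(points = points, vect = vect, k = k,
                 label = as.character(label)),
            class = "dotprops")
}

#' Number of segments in a dotprops object
#' @param dp A [dotprops()] object.
#' @return Integer segment (point) count.
#' @export
n_segments <- function(dp) nrow(dp$points)

#' @export
print.dotprops <- function(x, ...) {
  cat(sprintf("dotprops '%s': %d segments (k = %s)\n",
              x$label, n_segments(x),
              if (is.na(x$k)) "?" else x$k))
  invisible(x)
}

unit_rows <- function(m) m / sqrt(rowSums(m^2))

#' Build dotprops from a raw point cloud
#'
#' For each point, the tangent is the principal direction of the point
#' together with its `k` nearest neighbours: the first right-singular vector
#' of the SVD of the centered (k+1) x 3 coordinate block. Neighbour ties are
#' broken towards the lowest row index. When fewer than `k + 1` points are
#' available, `k` is reduced to N - 1 with a warning so that short fragments
#' can still be represented.
#'
#' @param points N x 3 matrix of positions (micrometers), N >= 2.
#' @param k Number of nearest neighbours used per point (default 5).
#' @param label Identifier string.
#' @return A [dotprops()] object with one unit tangent per input point.
#' @export
make_dotprops <- function(points, k = 5L, label = "") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points to estimate tangents")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (n <= k) {
    warning(sprintf("only %d points; reducing k from %d to %d", n, k, n - 1L))
    k <- n - 1L
  }
  nbr <- kd_knn(points, k + 1L)  # includes the point itself, nearest first
  vect <- matrix(0, n, 3L)
  degenerate <- FALSE
  for (i in seq_len(n)) {
    block <- points[nbr[i, ], , drop = FALSE]
    block <- sweep(block, 2L, colMeans(block))
    sv <- svd(block, nu = 0L, nv = 3L)
    if (sv$d[1L] - sv$d[2L] <= 1e-12) degenerate <- TRUE
    vect[i, ] <- sv$v[, 1L]
  }
  if (degenerate)
    warning("degenerate neighbourhood: top two singular values equal; ",
            "tangent direction arbitrary there")
  dotprops(points, unit_rows(vect), k = k, label = label)
}

#' Resample a skeleton to evenly spaced points
#'
#' Decomposes the skeleton into unbranched paths (root or branch point to
#' the next branch point or leaf) and walks each by arc length, emitting a
#' point every `step` micrometers starting at the path head. Every path
#' contributes at least one point, so a step larger than the total cable
#' still yields a valid sample. Exact duplicate positions (shared branch
#' points) are removed.
#'
#' @param skel A valid `neuron_skeleton`.
#' @param step Target spacing in micrometers (default 1).
#' @return M x 3 matrix of resampled positions.
#' @export
resample_skeleton <- function(skel, step = 1) {
  validate_skeleton(skel)
  if (step <= 0) stop("step must be positive")
  idx_of <- seq_len(nrow(skel))
  names(idx_of) <- as.character(skel$node_id)
  parent <- ifelse(skel$parent_id == -1L, NA_integer_,
                   idx_of[as.character(skel$parent_id)])
  nkids <- tabulate(parent[!is.na(parent)], nbins = nrow(skel))
  xyz <- as.matrix(skel[, c("x", "y", "z")])
  # path heads: children of roots/branch points, and isolated roots
  is_root <- is.na(parent)
  head_child <- which(!is_root & (is_root[parent] | nkids[parent] >= 2L))
  out <- list()
  # isolated root nodes (no children) must still appear
  lone <- which(is_root & nkids == 0L)
  if (length(lone)) out[[length(out) + 1L]] <- xyz[lone, , drop = FALSE]
  for (h in head_child) {
    # walk back is trivial (head's parent), walk forward while unbranched
    chain <- c(parent[h], h)
    cur <- h
    while (nkids[cur] == 1L) {
      cur <- which(parent == cur)[1L]
      chain <- c(chain, cur)
    }
    pts <- xyz[chain, , drop = FALSE]
    seg <- sqrt(rowSums(diff(pts)^2))
    cum <- c(0, cumsum(seg))
    total <- cum[length(cum)]
    at <- unique(c(seq(0, total, by = step), total))  # keep the path end
    out[[length(out) + 1L]] <- cbind(
      stats::approx(cum, pts[, 1L], xout = at, ties = "ordered")$y,
      stats::approx(cum, pts[, 2L], xout = at, ties = "ordered")$y,
      stats::approx(cum, pts[, 3L], xout = at, ties = "ordered")$y)
  }
  pts <- do.call(rbind, out)
  pts[!duplicated(pts), , drop = FALSE]
}

#' Convert a skeleton to dotprops
#'
#' Resamples the skeleton's cable at `step` micrometer intervals with
#' [resample_skeleton()], then estimates tangents with [make_dotprops()].
#'
#' @inheritParams resample_skeleton
#' @inheritParams make_dotprops
#' @return A [dotprops()] object.
#' @export
skeleton_to_dotprops <- function(skel, step = 1, k = 5L, label = "") {
  make_dotprops(resample_skeleton(skel, step = step), k = k, label = label)
}

#' Apply a rigid (or improper rigid) transform to dotprops
#'
#' Points are mapped affinely (`p R^T + t`); tangent vectors are mapped by
#' the rotation only, preserving unit length.
#'
#' @param dp A [dotprops()] object.
#' @param rotation 3 x 3 orthonormal matrix.
#' @param translation Length-3 numeric vector (micrometers).
#' @return The transformed [dotprops()] object.
#' @export
rigid_transform <- function(dp, rotation, translation = c(0, 0, 0)) {
  stopifnot(inherits(dp, "dotprops"))
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be a 3x3 orthonormal matrix (tolerance 1e-9)")
  pts <- dp$points %*% t(rotation)
  pts <- sweep(pts, 2L, as.numeric(translation), "+")
  dotprops(pts, unit_rows(dp$vect %*% t(rotation)), k = dp$k,
           label = dp$label)
}

#' Reflect dotprops about the midplane of a bounding span
#'
#' Maps coordinate `c` to `lo + hi - c` on the chosen axis and negates the
#' corresponding tangent component. The operation is an involution; because
#' scoring uses the absolute dot product, the tangent sign flip has no
#' effect on scores. This is a plain planar mirror: it does not attempt any
#' non-rigid refinement across hemispheres.
#'
#' @param dp A [dotprops()] object.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param bounding_span Numeric `c(lo, hi)` with `lo < hi` (micrometers).
#' @return The mirrored [dotprops()] object.
#' @export
mirror_flip <- function(dp, axis = c("x", "y", "z"),
                        bounding_span) {
  stopifnot(inherits(dp, "dotprops"))
  axis <- match.arg(axis)
  a <- match(axis, c("x", "y", "z"))
  lo <- bounding_span[1L]; hi <- bounding_span[2L]
  if (!(lo < hi)) stop("bounding_span must satisfy lo < hi")
  pts <- dp$points
  pts[, a] <- lo + hi - pts[, a]
  vect <- dp$vect
  vect[, a] <- -vect[, a]
  dotprops(pts, vect, k = dp$k, label = dp$label)
}

#' Subset dotprops to a spatial region
#'
#' Keeps exactly the segments whose points lie inside an axis-aligned box
#' (closed bounds) or satisfy a caller-supplied predicate. Tangent vectors
#' are kept as computed on the full neuron. An empty result is returned as a
#' zero-row dotprops; scoring operations reject such objects.
#'
#' @param dp A [dotprops()] object.
#' @param box Numeric length-6 vector `c(xmin, xmax, ymin, ymax, zmin,
#'   zmax)` (micrometers); ignored if `predicate` is given.
#' @param predicate Optional function taking an N x 3 point matrix and
#'   returning a logical vector of rows to keep.
#' @return The subsetted [dotprops()] object.
#' @export
spatial_subset <- function(dp, box = NULL, predicate = NULL) {
  stopifnot(inherits(dp, "dotprops"))
  if (is.null(predicate)) {
    if (is.null(box) || length(box) != 6L)
      stop("supply box = c(xmin, xmax, ymin, ymax, zmin, zmax) or a predicate")
    if (any(box[c(1, 3, 5)] >= box[c(2, 4, 6)]))
      stop("degenerate box: each min must be < its max")
    p <- dp$points
    keep <- p[, 1L] >= box[1L] & p[, 1L] <= box[2L] &
      p[, 2L] >= box[3L] & p[, 2L] <= box[4L] &
      p[, 3L] >= box[5L] & p[, 3L] <= box[6L]
  } else {
    keep <- predicate(dp$points)
  }
  dotprops(dp$points[keep, , drop = FALSE], dp$vect[keep, , drop = FALSE],
           k = dp$k, label = dp$label)
}
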