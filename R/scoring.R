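#' Default histogram bin boundaries
#'
#' The scoring matrix is binned on 21 distance bins and 10 absolute
#' dot-product bins. The dot-product bins are uniform on \[0, 1\]. The
#' distance edge table (micrometers) is fixed in code: sub-micrometer bins
#' near zero where the score is most sensitive, roughly 1 um bins out to 10
#' um, then geometric widening to a 500 um cap. Distances beyond the cap
#' clamp into the outermost bin at lookup and binning time.
#'
#' @return A list with components `dist_breaks` (length 22) and
#'   `dot_breaks` (length 11).
#' @export
default_breaks <- function() {
  list(dist_breaks = c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6, 7, 8, 9,
                       10, 15, 20, 30, 50, 100, 250, 500),
       dot_breaks = seq(0, 1, by = 0.1))
}

check_breaks <- function(dist_breaks, dot_breaks) {
  if (length(dist_breaks) < 2L || any(diff(dist_breaks) <= 0))
    stop("dist_breaks must be strictly increasing with >= 2 edges")
  if (length(dot_breaks) < 2L || any(diff(dot_breaks) <= 0))
    stop("dot_breaks must be strictly increasing with >= 2 edges")
  if (abs(dot_breaks[1L]) > 1e-12 ||
      abs(dot_breaks[length(dot_breaks)] - 1) > 1e-12)
    stop("dot_breaks must span exactly [0, 1]")
  invisible(TRUE)
}

#' Match every query segment to its nearest target segment
#'
#' The matching rule shared by scoring-matrix training and search: each
#' query segment is paired with the Euclidean-nearest target segment (point
#' position only; ties broken towards the lowest target row index), giving
#' the matched distance `d` (micrometers) and the absolute dot product of
#' the two unit tangents.
#'
#' @param query,target [dotprops()] objects; both must be non-empty.
#' @return A data frame with columns `d`, `absdot` and `target_index`, one
#'   row per query segment.
#' @export
segment_matches <- function(query, target) {
  stopifnot(inherits(query, "dotprops"), inherits(target, "dotprops"))
  if (n_segments(query) == 0L || n_segments(target) == 0L)
    stop("cannot match empty dotprops")
  nn <- kd_nn1(target$points, query$points)
  absdot <- abs(rowSums(query$vect * target$vect[nn$index, , drop = FALSE]))
  data.frame(d = nn$distance, absdot = pmin(absdot, 1),
             target_index = nn$index)
}

#' Collect segment-match statistics over neuron pairs
#'
#' For every ordered (query, target) pair in `pairs`, every query segment
#' contributes one match against its nearest target segment, under the same
#' matching rule as [raw_score()].
#'
#' @param pairs A list of length-2 lists of [dotprops()] objects
#'   (query first, target second).
#' @return A data frame of matches with columns `d` and `absdot`.
#' @export
collect_match_statistics <- function(pairs) {
  if (length(pairs) == 0L) stop("no pairs supplied")
  out <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    m <- segment_matches(p[[1L]], p[[2L]])
    out[[i]] <- m[, c("d", "absdot")]
  }
  do.call(rbind, out)
}

bin_index <- function(x, breaks) {
  # clamp out-of-range values into the edge bins; last bin right-closed
  findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Bin segment matches into a joint probability histogram
#'
#' Counts matches on the 2D (distance, |dot|) grid and divides by the total
#' count, giving a joint probability density over bins (cells sum to 1).
#' Distances beyond the last break clamp into the final distance bin so
#' that every match is counted.
#'
#' @param matches Data frame with columns `d` and `absdot` (>= 1 row).
#' @param dist_breaks,dot_breaks Bin edges; default [default_breaks()].
#' @return A `probability_histogram`: list with `dist_breaks`,
#'   `dot_breaks` and a `density` matrix of dimension
#'   `(length(dist_breaks)-1) x (length(dot_breaks)-1)`.
#' @export
histogram_from_matches <- function(matches,
                                   dist_breaks = default_breaks()$dist_breaks,
                                   dot_breaks = default_breaks()$dot_breaks) {
  if (nrow(matches) == 0L) stop("no matches to bin")
  check_breaks(dist_breaks, dot_breaks)
  di <- bin_index(matches$d, dist_breaks)
  ai <- bin_index(matches$absdot, dot_breaks)
  nd <- length(dist_breaks) - 1L
  na <- length(dot_breaks) - 1L
  counts <- matrix(tabulate((ai - 1L) * nd + di, nbins = nd * na), nd, na)
  structure(list(dist_breaks = dist_breaks, dot_breaks = dot_breaks,
                 density = counts / sum(counts)),
            class = "probability_histogram")
}

#' Construct a scoring matrix object
#'
#' @param values Numeric matrix of log2-odds cell values, dimension
#'   `(length(dist_breaks)-1) x (length(dot_breaks)-1)`.
#' @param dist_breaks,dot_breaks Bin edges (micrometers; \[0,1\]).
#' @param epsilon Pseudocount used during training.
#' @param provenance Free-text description of how the matrix was trained.
#' @return An object of class `scoring_matrix`.
#' @export
scoring_matrix <- function(values, dist_breaks, dot_breaks,
                           epsilon = 1e-6, provenance = "") {
  check_breaks(dist_breaks, dot_breaks)
  values <- as.matrix(values)
  if (!all(dim(values) == c(length(dist_breaks) - 1L,
                            length(dot_breaks) - 1L)))
    stop("scoring-matrix values have dimension ",
         paste(dim(values), collapse = "x"), " but breaks imply ",
         length(dist_breaks) - 1L, "x", length(dot_breaks) - 1L)
  if (any(is.nan(values)))
    stop("scoring-matrix values must not be NaN")
  dimnames(values) <- NULL
  structure(list(values = values, dist_breaks = dist_breaks,
                 dot_breaks = dot_breaks, epsilon = epsilon,
                 provenance = as.character(provenance)),
            class = "scoring_matrix")
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat(sprintf("scoring_matrix: %d distance x %d |dot| bins, range [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  if (nzchar(x$provenance)) cat(" provenance:", x$provenance, "\n")
  invisible(x)
}

#' Train a log2-odds scoring matrix from matching and random neuron pairs
#'
#' Segment-match statistics are collected for the same-type pairs and the
#' random pairs, binned into joint probability densities p_match and
#' p_rand, and combined cell-wise as `log2((p_match + eps) / (p_rand +
#' eps))`. The pseudocount keeps every cell finite even when a histogram
#' cell is empty. With `epsilon = 0`, cells empty in both histograms take
#' the continuous-limit value 0 and one-sided empty cells become infinite.
#'
#' @param match_pairs List of ordered same-type (query, target) dotprops
#'   pairs.
#' @param rand_pairs List of ordered random (query, target) dotprops pairs.
#' @param dist_breaks,dot_breaks Bin edges; default [default_breaks()].
#' @param epsilon Pseudocount (default 1e-6).
#' @param provenance Free-text training description.
#' @return A [scoring_matrix()].
#' @export
build_scoring_matrix <- function(match_pairs, rand_pairs,
                                 dist_breaks = default_breaks()$dist_breaks,
                                 dot_breaks = default_breaks()$dot_breaks,
                                 epsilon = 1e-6,
                                 provenance = "") {
  if (length(match_pairs) == 0L || length(rand_pairs) == 0L)
    stop("both match_pairs and rand_pairs must be non-empty")
  p_match <- histogram_from_matches(collect_match_statistics(match_pairs),
                                    dist_breaks, dot_breaks)$density
  p_rand <- histogram_from_matches(collect_match_statistics(rand_pairs),
                                   dist_breaks, dot_breaks)$density
  ratio <- (p_match + epsilon) / (p_rand + epsilon)
  ratio[p_match == 0 & p_rand == 0] <- 1  # continuous limit at epsilon = 0
  values <- log2(ratio)
  scoring_matrix(values, dist_breaks, dot_breaks, epsilon = epsilon,
                 provenance = provenance)
}

#' Look up scoring-matrix values for segment matches
#'
#' Returns the cell value for the bin containing each (d, |dot|) pair.
#' Out-of-range distances clamp into the outermost distance bin; |dot| = 1
#' falls in the top dot bin. Total function: every match scores.
#'
#' @param smat A [scoring_matrix()].
#' @param d Numeric vector of matched distances (micrometers).
#' @param absdot Numeric vector of absolute dot products, same length.
#' @return Numeric vector of log2-odds values.
#' @export
smat_lookup <- function(smat, d, absdot) {
  stopifnot(inherits(smat, "scoring_matrix"))
  di <- bin_index(d, smat$dist_breaks)
  ai <- bin_index(absdot, smat$dot_breaks)
  smat$values[cbind(di, ai)]
}

#' Does a scoring matrix attain its maximum at the best-match cell?
#'
#' The best-match cell is the smallest-distance, highest-|dot| bin — the
#' bin every self-match falls in. Well-populated trained matrices attain
#' their maximum there, which guarantees that normalized scores never
#' exceed 1. Sparsely trained matrices can violate it: cells where the
#' random histogram is empty reduce to `log2(p_match / epsilon)` and
#' sampling noise decides among them.
#'
#' @param smat A [scoring_matrix()].
#' @return `TRUE` if the (first distance bin, last dot bin) cell is a
#'   global maximum of the matrix.
#' @export
smat_max_at_origin <- function(smat) {
  stopifnot(inherits(smat, "scoring_matrix"))
  smat$values[1L, ncol(smat$values)] >= max(smat$values)
}

#' Enumerate ordered same-type pairs from a labelled neuron set
#'
#' @param neurons Named list of [dotprops()] objects.
#' @param labels Vector of type labels, one per neuron.
#' @param type The type whose ordered pairs (i != j, both directions) are
#'   wanted.
#' @return List of length-2 lists of dotprops.
#' @export
same_type_pairs <- function(neurons, labels, type) {
  idx <- which(labels == type)
  if (length(idx) < 2L) stop("type ", type, " has fewer than 2 members")
  grid <- expand.grid(q = idx, t = idx)
  grid <- grid[grid$q != grid$t, ]
  lapply(seq_len(nrow(grid)), function(r)
    list(neurons[[grid$q[r]]], neurons[[grid$t[r]]]))
}

#' Sample random ordered neuron pairs without replacement
#'
#' Draws up to `n` distinct ordered (query, target) pairs with `query !=
#' target`; when `labels` are supplied only cross-type pairs are eligible,
#' so the sample approximates unrelated-neuron statistics.
#'
#' @param neurons Named list of [dotprops()] objects.
#' @param n Number of pairs to draw (default 5000; capped at the number of
#'   eligible pairs).
#' @param labels Optional type labels; when given, pairs are cross-type.
#' @param seed Optional integer seed for reproducible sampling.
#' @return List of length-2 lists of dotprops.
#' @export
sample_random_pairs <- function(neurons, n = 5000L, labels = NULL,
                                seed = NULL) {
  m <- length(neurons)
  if (m < 2L) stop("need at least 2 neurons")
  grid <- expand.grid(q = seq_len(m), t = seq_len(m))
  keep <- grid$q != grid$t
  if (!is.null(labels)) keep <- keep & labels[grid$q] != labels[grid$t]
  grid <- grid[keep, ]
  if (nrow(grid) == 0L) stop("no eligible pairs")
  n <- min(n, nrow(grid))
  pick <- with_seed(seed, sample.int(nrow(grid), n))
  lapply(pick, function(r) list(neurons[[grid$q[r]]], neurons[[grid$t[r]]]))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# NULL seed leaves the global RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
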