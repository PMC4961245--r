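#' Convert a mean-normalized score table to a distance matrix
#'
#' Distance is defined as `1 - mean score`, a fixed convention of this
#' package: a self comparison has distance 0 and the score-0 natural cutoff
#' corresponds to distance 1. The table must be square over the same id set
#' and symmetric to within 1e-9.
#'
#' @param table A square, mean-normalized [score_table()].
#' @return A symmetric numeric matrix with zero diagonal and class
#'   `nb_distance`, dimnames = neuron ids.
#' @export
scores_to_distance <- function(table) {
  stopifnot(inherits(table, "score_table"))
  v <- table$values
  if (nrow(v) != ncol(v) || !identical(rownames(v), colnames(v)))
    stop("score table must be square over the same query/target ids")
  if (table$normalization != "mean")
    stop("distances are defined on mean-normalized scores, got ",
         table$normalization)
  if (max(abs(v - t(v))) > 1e-9)
    stop("score table is asymmetric beyond 1e-9")
  d <- 1 - (v + t(v)) / 2
  diag(d) <- 0
  structure(d, class = c("nb_distance", "matrix"))
}

#' Ward hierarchical clustering of a neuron distance matrix
#'
#' Runs Ward's minimum-variance agglomeration on the unsquared distances
#' (`stats::hclust`, method `"ward.D"`), so reported merge heights are on
#' the same 1 - mean-score scale as the input.
#'
#' @param dist An `nb_distance` matrix from [scores_to_distance()], or any
#'   symmetric zero-diagonal matrix with dimnames.
#' @param linkage Only `"ward"` is supported.
#' @return A `cluster_result` list with elements `method`, `hclust`
#'   (the merge tree) and `ids`.
#' @export
hierarchical_cluster <- function(dist, linkage = "ward") {
  if (!identical(linkage, "ward")) stop("only ward linkage is supported")
  v <- unclass(dist)
  if (nrow(v) < 2L) stop("need at least 2 neurons to cluster")
  hc <- stats::hclust(stats::as.dist(v), method = "ward.D")
  structure(list(method = "ward", hclust = hc, ids = rownames(v),
                 parameters = list(linkage = "ward")),
            class = "cluster_result")
}

#' Cut a dendrogram into flat cluster labels
#'
#' Exactly one of `h` (cut height, on the unsquared-distance scale) or `k`
#' (number of groups) must be given. Cutting above the root yields one
#' cluster; at height 0, every neuron is its own cluster.
#'
#' @param result A hierarchical `cluster_result`.
#' @param h Cut height.
#' @param k Number of groups.
#' @return A `cluster_result` with an added `labels` component: a named
#'   integer vector mapping each id to a cluster.
#' @export
cut_dendrogram <- function(result, h = NULL, k = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  if (is.null(result$hclust)) stop("result carries no dendrogram")
  if (is.null(h) == is.null(k))
    stop("give exactly one of h (height) or k (groups)")
  labels <- if (is.null(k)) stats::cutree(result$hclust, h = h)
            else stats::cutree(result$hclust, k = k)
  result$labels <- labels
  result$parameters <- c(result$parameters, list(h = h, k = k))
  result
}

#' Export a dendrogram in Newick format
#'
#' @param result A hierarchical `cluster_result`.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(result, path = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  if (is.null(result$hclust)) stop("result carries no dendrogram")
  phy <- ape::as.phylo(result$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Affinity-propagation clustering of a score table
#'
#' Frey-Dueck message passing on the mean-normalized scores used directly
#' as similarities, with every self-similarity (preference) set to `p`. At
#' the default `p = 0`, a neuron prefers joining an exemplar whenever their
#' similarity beats the score level at which segment matches are equally
#' likely from matching and non-matching neurons. A seed-controlled jitter
#' of order 1e-12 breaks symmetry degeneracies; results are deterministic
#' given the seed and damping.
#'
#' @param table A square, symmetric (to 1e-9) mean-normalized
#'   [score_table()].
#' @param preference Self-similarity `p` (default 0).
#' @param seed Integer seed for the degeneracy-breaking jitter.
#' @param damping Message damping factor in (0.5, 1) (default 0.9).
#' @param maxit Iteration cap (default 1000).
#' @param conv_window Stop once the exemplar set is unchanged for this many
#'   iterations (default 100).
#' @return A `cluster_result` with `exemplars` (ids), `labels` (named
#'   integer vector; clusters numbered in exemplar order) and `parameters`.
#' @export
affinity_propagation <- function(table, preference = 0, seed = 1L,
                                 damping = 0.9, maxit = 1000L,
                                 conv_window = 100L) {
  stopifnot(inherits(table, "score_table"))
  v <- table$values
  if (nrow(v) != ncol(v) || !identical(rownames(v), colnames(v)))
    stop("similarity table must be square over the same ids")
  if (max(abs(v - t(v))) > 1e-9) stop("similarity table is asymmetric")
  if (damping <= 0.5 || damping >= 1) stop("damping must be in (0.5, 1)")
  n <- nrow(v)
  ids <- rownames(v)
  S <- (v + t(v)) / 2
  diag(S) <- preference
  S <- S + with_seed(seed, matrix(stats::runif(n * n), n, n)) * 1e-12
  R <- A <- matrix(0, n, n)
  ex_prev <- NULL
  stable <- 0L
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    # responsibilities
    AS <- A + S
    m1_idx <- max.col(AS, ties.method = "first")
    m1 <- AS[cbind(seq_len(n), m1_idx)]
    AS[cbind(seq_len(n), m1_idx)] <- -Inf
    m2 <- AS[cbind(seq_len(n), max.col(AS, ties.method = "first"))]
    Rnew <- S - m1
    Rnew[cbind(seq_len(n), m1_idx)] <- S[cbind(seq_len(n), m1_idx)] - m2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- pmin(matrix(cs, n, n, byrow = TRUE) - Rp, 0)
    diag(Anew) <- cs - diag(R)  # sum over others of max(0, r)
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, ex_prev)) stable <- stable + 1L else stable <- 0L
    ex_prev <- ex
    if (stable >= conv_window && length(ex) > 0L) break
  }
  ex <- ex_prev
  if (length(ex) == 0L || stable < conv_window) {
    cond <- structure(class = c("ap_no_convergence", "error", "condition"),
                      list(message = sprintf(
                        "affinity propagation did not converge in %d iterations",
                        maxit),
                        call = sys.call(),
                        iterations = it, exemplars = ids[ex]))
    stop(cond)
  }
  # assign each point to the most similar exemplar; exemplars to themselves
  assign_idx <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  assign_idx[ex] <- ex
  labels <- match(assign_idx, ex)
  names(labels) <- ids
  structure(list(method = "affinity_propagation",
                 exemplars = ids[ex], labels = labels,
                 parameters = list(preference = preference, seed = seed,
                                   damping = damping, iterations = it)),
            class = "cluster_result")
}

#' Exemplar clustering plus a dendrogram over the exemplars
#'
#' Runs [affinity_propagation()] on the full table, then Ward hierarchical
#' clustering restricted to the exemplar neurons, so very large sets can be
#' navigated through a small exemplar tree. Each neuron is cross-referenced
#' to its exemplar's dendrogram leaf.
#'
#' @inheritParams affinity_propagation
#' @return A list with `ap` (the exemplar `cluster_result`), `dendrogram`
#'   (a hierarchical `cluster_result` over the exemplars) and
#'   `neuron_exemplar` (named character vector: id -> exemplar id).
#' @export
cluster_exemplar_hierarchy <- function(table, preference = 0, seed = 1L) {
  ap <- affinity_propagation(table, preference = preference, seed = seed)
  ex <- ap$exemplars
  if (length(ex) < 2L)
    stop("fewer than 2 exemplars; no exemplar dendrogram possible")
  sub <- score_table(table$values[ex, ex, drop = FALSE],
                     normalization = table$normalization)
  hc <- hierarchical_cluster(scores_to_distance(sub))
  neuron_exemplar <- ex[ap$labels]
  names(neuron_exemplar) <- names(ap$labels)
  list(ap = ap, dendrogram = hc, neuron_exemplar = neuron_exemplar)
}
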