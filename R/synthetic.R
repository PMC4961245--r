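#' Specify a synthetic neuron population
#'
#' The generator emulates a registered set of neuron types: each type is a
#' template tree drawn as a momentum random walk with Bernoulli branching
#' inside a common bounding span, and each instance of a type is the
#' template with i.i.d. Gaussian positional jitter plus a contiguous
#' dropout of segments (truncated arbors). Tangents are re-estimated per
#' instance, so jitter propagates into both position and direction
#' statistics, mimicking sister neurons of the same type.
#'
#' Defaults are sized to the scale of registered fly-brain neurons while
#' keeping desk-scale runs fast: 200 segments of 1 um inside a 100 um span,
#' momentum 0.9, branch probability 0.02, 1 um jitter and 5% contiguous
#' dropout.
#'
#' @param n_types Number of neuron types.
#' @param instances_per_type Instances generated per type.
#' @param n_segments Points per template.
#' @param step Walk step length (micrometers).
#' @param momentum Direction persistence in \[0, 1).
#' @param branch_prob Per-step probability of starting a new branch.
#' @param span Side of the cubic region template roots are drawn in
#'   (micrometers).
#' @param jitter_sigma Per-coordinate s.d. of instance positional noise
#'   (micrometers).
#' @param dropout_fraction Fraction of contiguous segments removed per
#'   instance, in \[0, 1).
#' @param k Neighbourhood size for tangent estimation.
#' @param seed Integer seed; the whole population is reproducible from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_types = 10L, instances_per_type = 10L,
                           n_segments = 200L, step = 1, momentum = 0.9,
                           branch_prob = 0.02, span = 100,
                           jitter_sigma = 1, dropout_fraction = 0.05,
                           k = 5L, seed = 1L) {
  spec <- list(n_types = as.integer(n_types),
               instances_per_type = as.integer(instances_per_type),
               n_segments = as.integer(n_segments), step = step,
               momentum = momentum, branch_prob = branch_prob, span = span,
               jitter_sigma = jitter_sigma,
               dropout_fraction = dropout_fraction,
               k = as.integer(k), seed = as.integer(seed))
  with(spec, {
    if (n_types < 1L || instances_per_type < 1L || n_segments < 2L)
      stop("counts must be >= 1 (and n_segments >= 2)")
    if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)")
    if (branch_prob < 0 || branch_prob >= 1)
      stop("branch_prob must be in [0, 1)")
    if (dropout_fraction < 0 || dropout_fraction >= 1)
      stop("dropout_fraction must be in [0, 1)")
    if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
    if (step <= 0 || span <= 0) stop("step and span must be positive")
  })
  structure(spec, class = "synthetic_spec")
}

random_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

# Draw one template tree: momentum random walk with Bernoulli branching.
# Returns points (n x 3) and a parent index vector (root = NA).
generate_template <- function(spec) {
  n <- spec$n_segments
  pts <- matrix(NA_real_, n, 3L)
  parent <- rep(NA_integer_, n)
  pts[1L, ] <- stats::runif(3, 0, spec$span)
  dir <- random_unit()
  cur <- 1L
  for (i in 2:n) {
    if (i > 2L && stats::runif(1) < spec$branch_prob) {
      cur <- sample.int(i - 1L, 1L)  # branch from a random earlier node
      dir <- random_unit()
    }
    dir <- dir * spec$momentum + random_unit() * (1 - spec$momentum)
    dir <- dir / sqrt(sum(dir^2))
    pts[i, ] <- pts[cur, ] + spec$step * dir
    parent[i] <- cur
    cur <- i
  }
  list(points = pts, parent = parent)
}

template_to_skeleton <- function(tmpl, structure = 0L) {
  n <- nrow(tmpl$points)
  skel <- data.frame(node_id = seq_len(n),
                     structure = rep(as.integer(structure), n),
                     x = tmpl$points[, 1L], y = tmpl$points[, 2L],
                     z = tmpl$points[, 3L], radius = rep(1, n),
                     parent_id = ifelse(is.na(tmpl$parent), -1L,
                                        tmpl$parent))
  class(skel) <- c("neuron_skeleton", "data.frame")
  skel
}

# One instance: jitter + contiguous dropout, tangents re-estimated.
instantiate <- function(tmpl, spec, label) {
  n <- nrow(tmpl$points)
  for (attempt in 1:10) {
    pts <- tmpl$points +
      matrix(stats::rnorm(n * 3L, sd = spec$jitter_sigma), n, 3L)
    if (spec$dropout_fraction > 0) {
      len <- round(spec$dropout_fraction * n)
      if (len > 0L) {
        start <- sample.int(n - len + 1L, 1L)
        pts <- pts[-(start:(start + len - 1L)), , drop = FALSE]
      }
    }
    if (nrow(pts) > spec$k + 1L)
      return(make_dotprops(pts, k = spec$k, label = label))
    warning("degenerate instance (too few points after dropout); ",
            "regenerating")
  }
  stop("failed to generate a non-degenerate instance for ", label)
}

#' Generate a seeded synthetic neuron population
#'
#' Draws one template per type and `instances_per_type` jittered instances
#' of each; fully reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `neurons` (named list of [dotprops()]), `labels`
#'   (named integer vector of type per neuron), `templates` (list of
#'   template trees) and `spec`.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    neurons <- list()
    labels <- integer(0)
    templates <- vector("list", spec$n_types)
    for (t in seq_len(spec$n_types)) {
      templates[[t]] <- generate_template(spec)
      for (j in seq_len(spec$instances_per_type)) {
        id <- sprintf("type%02d_inst%02d", t, j)
        neurons[[id]] <- instantiate(templates[[t]], spec, id)
        labels[id] <- t
      }
    }
    list(neurons = neurons, labels = labels, templates = templates,
         spec = spec)
  })
}

#' Train a scoring matrix from a synthetic population
#'
#' Mirrors the empirical training design: all ordered same-type pairs of
#' one designated type serve as the matching set, and seeded random
#' cross-type pairs as the random set.
#'
#' @param spec A [synthetic_spec()] with at least 2 types.
#' @param match_type Type whose ordered pairs define the matching
#'   statistics (default 1).
#' @param n_rand Number of random cross-type pairs (default 5000, capped at
#'   availability).
#' @param epsilon Pseudocount (default 1e-6).
#' @return A [scoring_matrix()].
#' @export
train_test_matrix <- function(spec, match_type = 1L, n_rand = 5000L,
                              epsilon = 1e-6) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_types < 2L)
    stop("need >= 2 types: matching pairs from one, random pairs across")
  if (spec$instances_per_type < 2L)
    stop("need >= 2 instances per type for matching pairs")
  pop <- generate_population(spec)
  mp <- same_type_pairs(pop$neurons, pop$labels, match_type)
  rp <- sample_random_pairs(pop$neurons, n = n_rand, labels = pop$labels,
                            seed = spec$seed + 1L)
  build_scoring_matrix(mp, rp, epsilon = epsilon,
                       provenance = sprintf(
                         "synthetic: %d types x %d instances, sigma %g um, seed %d",
                         spec$n_types, spec$instances_per_type,
                         spec$jitter_sigma, spec$seed))
}

#' Leave-one-out 1-nearest-neighbour type assignment benchmark
#'
#' For each neuron, the top mean-score hit among all other neurons is
#' found; the error rate is the fraction whose hit carries a different type
#' label. Types with a single instance cannot be recovered and are excluded
#' with a warning.
#'
#' @param neurons Named list of [dotprops()] objects.
#' @param labels Named type labels (same names as `neurons`).
#' @param smat A [scoring_matrix()].
#' @return A list with `error_rate`, `n_evaluated`, and `hits` (data frame
#'   of query id, top-hit id, both labels, and whether they agree).
#' @export
benchmark_1nn_type_assignment <- function(neurons, labels, smat) {
  labels <- labels[names(neurons)]
  sizes <- table(labels)
  singleton <- names(sizes)[sizes < 2L]
  if (length(singleton)) {
    warning("excluding singleton types: ", paste(singleton, collapse = ", "))
    keep <- !(labels %in% singleton)
    neurons <- neurons[keep]
    labels <- labels[keep]
  }
  if (length(neurons) < 2L) stop("fewer than 2 usable neurons")
  tab <- all_by_all(neurons, smat, normalization = "mean")$values
  ids <- rownames(tab)
  hit <- character(length(ids))
  for (i in seq_along(ids)) {
    s <- tab[i, -i]
    o <- order(-s, names(s), method = "radix")[1L]
    hit[i] <- names(s)[o]
  }
  agree <- labels[ids] == labels[hit]
  list(error_rate = mean(!agree), n_evaluated = length(ids),
       hits = data.frame(query = ids, hit = hit,
                         query_type = unname(labels[ids]),
                         hit_type = unname(labels[hit]),
                         correct = unname(agree),
                         stringsAsFactors = FALSE))
}
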