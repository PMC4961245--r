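block_table <- function(sizes, within = 0.9, between = -0.5,
                        jitter = 0, seed = NULL) {
  # mean-normalized score table with block structure: one block per type
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  v <- matrix(between, n, n)
  for (g in seq_along(sizes)) v[lab == g, lab == g] <- within
  if (jitter > 0) {
    if (!is.null(seed)) set.seed(seed)
    noise <- matrix(rnorm(n * n, sd = jitter), n, n)
    v <- v + (noise + t(noise)) / 2
  }
  diag(v) <- 1
  ids <- sprintf("n%02d", seq_len(n))
  dimnames(v) <- list(ids, ids)
  list(tab = score_table(v, "mean"), labels = stats::setNames(lab, ids))
}

test_that("scores_to_distance is 1 - mean score with a zero diagonal", {
  bt <- block_table(c(2, 2), within = 0.4, between = -0.2)
  d <- scores_to_distance(bt$tab)
  expect_equal(d[1, 2], 0.6)
  expect_equal(d[1, 3], 1.2)
  expect_equal(unname(diag(d)), rep(0, 4))

  set.seed(51)
  v <- matrix(rnorm(400), 20, 20)
  v <- (v + t(v)) / 2
  diag(v) <- 1
  dimnames(v) <- list(sprintf("a%d", 1:20), sprintf("a%d", 1:20))
  tab <- score_table(v, "mean")
  d <- scores_to_distance(tab)
  # independent elementwise sweep
  for (i in 1:20) for (j in 1:20)
    expect_equal(d[i, j], if (i == j) 0 else 1 - v[i, j])

  raw_tab <- score_table(v, "raw")
  expect_error(scores_to_distance(raw_tab), "mean")
  v2 <- v; v2[1, 2] <- v2[1, 2] + 1e-6
  dimnames(v2) <- dimnames(v)
  expect_error(scores_to_distance(score_table(v2, "mean")), "asymmetric")
  expect_error(scores_to_distance(score_table(v[, 1:10], "mean")), "square")
})

test_that("ward merges follow the distance structure", {
  # two neurons: single merge at their distance
  bt <- block_table(c(1, 1), between = 0.25)
  hc <- hierarchical_cluster(scores_to_distance(bt$tab))
  expect_equal(hc$hclust$height, 0.75)

  # three points, distances {0.1, 0.9, 0.9}: first merge joins the 0.1 pair
  v <- matrix(c(1, 0.9, 0.1, 0.9, 1, 0.1, 0.1, 0.1, 1), 3, 3,
              dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  hc <- hierarchical_cluster(scores_to_distance(score_table(v, "mean")))
  expect_equal(sort(hc$hclust$merge[1, ]), c(-2, -1))
  expect_equal(hc$hclust$height[1], 0.1)

  expect_error(hierarchical_cluster(matrix(0, 1, 1,
                                           dimnames = list("a", "a"))),
               "at least 2")
})

test_that("the k = 3 cut equals the exhaustive ward-optimal 3-partition", {
  bt <- block_table(c(3, 3, 3), within = 0.8, between = -0.4,
                    jitter = 0.05, seed = 52)
  d <- scores_to_distance(bt$tab)
  hc <- hierarchical_cluster(d)
  got <- cut_dendrogram(hc, k = 3)$labels

  # brute force: minimize the Ward objective sum_c (1/(2 n_c)) sum_{ij} d^2
  ward_obj <- function(assign) {
    tot <- 0
    for (g in unique(assign)) {
      idx <- which(assign == g)
      tot <- tot + sum(d[idx, idx]^2) / (2 * length(idx))
    }
    tot
  }
  n <- 9
  best <- NULL; best_obj <- Inf
  for (code in 0:(3^n - 1)) {
    assign <- (code %/% 3^(0:(n - 1))) %% 3
    if (length(unique(assign)) != 3L) next
    o <- ward_obj(assign)
    if (o < best_obj) { best_obj <- o; best <- assign }
  }
  expect_same_partition(got, best)
  expect_same_partition(got, bt$labels)
})

test_that("dendrogram cuts behave at the extremes and nest monotonically", {
  bt <- block_table(c(4, 4, 4), jitter = 0.05, seed = 53)
  hc <- hierarchical_cluster(scores_to_distance(bt$tab))
  root <- max(hc$hclust$height)
  expect_equal(unname(unique(cut_dendrogram(hc, h = root + 1)$labels)), 1L)
  expect_length(unique(cut_dendrogram(hc, k = 12)$labels), 12L)
  expect_length(unique(cut_dendrogram(hc, h = 0)$labels), 12L)
  # increasing h => non-increasing cluster counts
  counts <- vapply(seq(0, root + 0.5, length.out = 25), function(h)
    length(unique(cut_dendrogram(hc, h = h)$labels)), 1L)
  expect_true(all(diff(counts) <= 0))
  expect_error(cut_dendrogram(hc, h = 1, k = 2), "exactly one")
  expect_error(cut_dendrogram(hc), "exactly one")
})

test_that("affinity propagation finds block exemplars", {
  bt <- block_table(c(3, 3), within = 0.9, between = -0.5)
  ap <- affinity_propagation(bt$tab, preference = 0, seed = 1)
  expect_length(ap$exemplars, 2L)
  expect_same_partition(ap$labels, bt$labels)
  # one exemplar from each block
  expect_equal(sum(ap$exemplars %in% c("n01", "n02", "n03")), 1L)
  expect_equal(sum(ap$exemplars %in% c("n04", "n05", "n06")), 1L)

  # preference far above every similarity: every neuron its own exemplar
  ap_all <- affinity_propagation(bt$tab, preference = 10, seed = 1)
  expect_length(ap_all$exemplars, 6L)
})

test_that("affinity propagation cluster count shrinks as preference drops", {
  bt <- block_table(c(4, 4, 4), within = 0.7, between = -0.3,
                    jitter = 0.1, seed = 54)
  prefs <- c(2, 0.5, 0, -2, -10)
  counts <- vapply(prefs, function(p)
    length(affinity_propagation(bt$tab, preference = p,
                                seed = 7)$exemplars), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("affinity propagation is deterministic given the seed", {
  bt <- block_table(c(3, 3, 3), jitter = 0.05, seed = 55)
  a <- affinity_propagation(bt$tab, preference = 0, seed = 42)
  b <- affinity_propagation(bt$tab, preference = 0, seed = 42)
  expect_identical(a$exemplars, b$exemplars)
  expect_identical(a$labels, b$labels)
})

test_that("exemplar hierarchies cover every neuron", {
  bt <- block_table(c(3, 3), within = 0.9, between = -0.5)
  eh <- cluster_exemplar_hierarchy(bt$tab, preference = 0, seed = 1)
  expect_length(eh$ap$exemplars, 2L)
  expect_equal(length(eh$dendrogram$hclust$height), 1L)
  # every neuron maps to exactly one exemplar leaf
  expect_setequal(names(eh$neuron_exemplar), rownames(bt$tab$values))
  expect_true(all(eh$neuron_exemplar %in% eh$ap$exemplars))

  bt10 <- block_table(c(3, 3, 3, 3), within = 0.8, between = -0.4,
                      jitter = 0.05, seed = 56)
  eh <- cluster_exemplar_hierarchy(bt10$tab, preference = 0, seed = 1)
  cut <- cut_dendrogram(eh$dendrogram, k = length(eh$ap$exemplars))
  expect_length(unique(cut$labels), length(eh$ap$exemplars))
})

test_that("dendrograms export as valid newick trees", {
  bt <- block_table(c(3, 3), jitter = 0.02, seed = 57)
  hc <- hierarchical_cluster(scores_to_distance(bt$tab))
  nwk <- write_newick(hc)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, rownames(bt$tab$values))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hc, path)
  expect_identical(readLines(path), nwk)
})
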