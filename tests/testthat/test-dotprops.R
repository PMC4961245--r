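test_that("tangents of collinear points recover the line direction", {
  pts <- cbind(0:5, 0, 0)
  dp <- make_dotprops(pts, k = 5)
  expect_equal(abs(dp$vect[, 1]), rep(1, 6), tolerance = 1e-12)
  expect_equal(dp$vect[, 2:3], matrix(0, 6, 2), tolerance = 1e-9)
})

test_that("tangents on a circle are perpendicular to the radius", {
  # 40 points on a 10 um circle (1.6 um spacing, comparable to 1 um
  # resampling); with sparser sampling the asymmetric 6-point
  # neighbourhood tilts the principal axis by more than this bound
  n <- 40
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  pts <- cbind(10 * cos(theta), 10 * sin(theta), 0)
  dp <- make_dotprops(pts, k = 5)
  radial <- cbind(cos(theta), sin(theta), 0)
  cosang <- abs(rowSums(dp$vect * radial))
  # within 5 degrees of the analytic tangent (perpendicular to radius)
  expect_true(all(cosang < sin(5 * pi / 180)))
})

test_that("tangents equal the leading eigenvector of the neighbourhood", {
  set.seed(9)
  pts <- matrix(rnorm(21), 7, 3)
  dp <- make_dotprops(pts, k = 5)
  for (i in 1:7) {
    d2 <- colSums((t(pts) - pts[i, ])^2)
    nbr <- order(d2)[1:6]
    block <- scale(pts[nbr, ], center = TRUE, scale = FALSE)
    ev <- eigen(crossprod(block), symmetric = TRUE)$vectors[, 1]
    # equal up to sign
    expect_equal(abs(sum(dp$vect[i, ] * ev)), 1, tolerance = 1e-9)
  }
})

test_that("k is reduced with a warning for tiny fragments", {
  pts <- cbind(0:3, 0, 0)
  expect_warning(dp <- make_dotprops(pts, k = 5), "reducing k")
  expect_equal(dp$k, 3L)
  expect_equal(abs(dp$vect[, 1]), rep(1, 4))
  expect_error(make_dotprops(pts[1, , drop = FALSE], k = 5), "at least 2")
})

straight_skel <- function(len = 10) {
  skel <- data.frame(node_id = 1:2, structure = 0L,
                     x = c(0, len), y = 0, z = 0, radius = 1,
                     parent_id = c(-1L, 1L))
  class(skel) <- c("neuron_skeleton", "data.frame")
  skel
}

y_skel <- function(branch_len = 20, n_per = 41) {
  # root -> branch point along +x, two arms at +-45 degrees in xy
  t1 <- seq(0, branch_len, length.out = n_per)
  stem <- cbind(t1, 0, 0)
  s <- branch_len / sqrt(2)
  t2 <- seq(0, 1, length.out = n_per)[-1]
  arm1 <- cbind(branch_len + s * t2, s * t2, 0)
  arm2 <- cbind(branch_len + s * t2, -s * t2, 0)
  pts <- rbind(stem, arm1, arm2)
  n <- nrow(pts)
  parent <- c(-1L, 1:(n_per - 1L),                      # stem chain
              n_per, n_per + 1:(n_per - 2L),            # arm 1
              n_per, 2L * n_per - 1L + 1:(n_per - 2L))  # arm 2
  skel <- data.frame(node_id = 1:n, structure = 0L, x = pts[, 1],
                     y = pts[, 2], z = pts[, 3], radius = 1,
                     parent_id = parent)
  class(skel) <- c("neuron_skeleton", "data.frame")
  skel
}

test_that("skeleton resampling spaces points by arc length", {
  pts <- resample_skeleton(straight_skel(10), step = 1)
  expect_equal(nrow(pts), 11L)
  expect_equal(pts[, 1], 0:10)

  dp <- skeleton_to_dotprops(straight_skel(10), step = 1, k = 5)
  expect_equal(abs(dp$vect[, 1]), rep(1, 11), tolerance = 1e-9)

  # arc-length oracle: total cable of the Y tree is 3 x 20 um
  skel <- y_skel()
  cable <- 0
  pid <- match(skel$parent_id, skel$node_id)
  for (i in seq_len(nrow(skel))) if (!is.na(pid[i]))
    cable <- cable + sqrt(sum((skel[i, c("x", "y", "z")] -
                               skel[pid[i], c("x", "y", "z")])^2))
  expect_equal(cable, 60, tolerance = 1e-9)
  pts <- resample_skeleton(skel, step = 1)
  expect_true(abs(nrow(pts) - 60) <= 2)

  # step larger than the total cable: at least one point per branch
  pts <- resample_skeleton(skel, step = 1000)
  expect_true(nrow(pts) >= 3L)
})

test_that("rigid transforms act on points and vectors correctly", {
  set.seed(11)
  dp <- rand_dp(40)
  expect_equal(rigid_transform(dp, diag(3), c(0, 0, 0)), dp)

  # 90 degree rotation about z maps x-axis tangents to y-axis tangents
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  line <- dotprops(cbind(0:4, 0, 0), matrix(rep(c(1, 0, 0), 5), 5, 3,
                                            byrow = TRUE))
  rot <- rigid_transform(line, Rz)
  expect_equal(rot$vect, matrix(rep(c(0, 1, 0), 5), 5, 3, byrow = TRUE),
               tolerance = 1e-12)
  expect_equal(rot$points[, 2], 0:4, tolerance = 1e-12)

  # distance-matrix oracle: rigid motion preserves all pairwise distances
  R <- rand_rotation()
  moved <- rigid_transform(dp, R, c(5, -3, 12))
  expect_equal(as.matrix(dist(moved$points)), as.matrix(dist(dp$points)),
               tolerance = 1e-9)
  expect_equal(sqrt(rowSums(moved$vect^2)), rep(1, 40), tolerance = 1e-9)

  expect_error(rigid_transform(dp, diag(3) * 2), "orthonormal")
})

test_that("make_dotprops is rigid-invariant up to tangent sign", {
  set.seed(13)
  pts <- matrix(rnorm(90), 30, 3)
  R <- rand_rotation()
  tr <- c(2, -1, 4)
  dp1 <- make_dotprops(pts, k = 5)
  dp2 <- make_dotprops(sweep(pts %*% t(R), 2, tr, "+"), k = 5)
  back <- dp2$vect %*% R  # rotate tangents back
  expect_equal(abs(rowSums(back * dp1$vect)), rep(1, 30), tolerance = 1e-6)
})

test_that("mirror_flip is an involution that reflects about the midplane", {
  set.seed(17)
  dp <- rand_dp(30)
  flipped <- mirror_flip(dp, "x", c(0, 50))
  twice <- mirror_flip(flipped, "x", c(0, 50))
  expect_equal(twice$points, dp$points, tolerance = 1e-12)
  expect_equal(twice$vect, dp$vect, tolerance = 1e-12)

  edge <- dotprops(matrix(c(0, 5, 5), 1, 3), matrix(c(1, 0, 0), 1, 3))
  m <- mirror_flip(edge, "x", c(0, 50))
  expect_equal(m$points[1, 1], 50)
  expect_equal(m$vect[1, ], c(-1, 0, 0))

  # sign flip is invisible to scoring (|dot| is used)
  smat <- toy_smat()
  a <- rand_dp(20, label = "a")
  b <- rand_dp(25, label = "b")
  expect_identical(raw_score(mirror_flip(a, "x", c(0, 50)),
                             mirror_flip(b, "x", c(0, 50)), smat),
                   raw_score(a, b, smat))
  expect_error(mirror_flip(dp, "x", c(10, 10)), "lo < hi")
})

test_that("spatial_subset keeps exactly the rows inside the region", {
  set.seed(19)
  dp <- rand_dp(200, span = 100)
  all_box <- c(-1, 101, -1, 101, -1, 101)
  expect_equal(spatial_subset(dp, all_box), dp)

  none <- spatial_subset(dp, c(200, 300, 200, 300, 200, 300))
  expect_equal(n_segments(none), 0L)
  expect_error(segment_matches(none, dp), "empty")

  # membership oracle on a half space
  half <- spatial_subset(dp, c(-1, 50, -1, 101, -1, 101))
  oracle <- sum(dp$points[, 1] <= 50)
  expect_equal(n_segments(half), oracle)
  keep <- dp$points[, 1] <= 50
  expect_equal(half$vect, dp$vect[keep, , drop = FALSE])

  expect_error(spatial_subset(dp, c(5, 5, 0, 1, 0, 1)), "degenerate")
})

test_that("all tangent vectors stay unit length through every operation", {
  set.seed(23)
  dp <- make_dotprops(matrix(rnorm(150), 50, 3), k = 5)
  ops <- list(function(d) rigid_transform(d, rand_rotation(), rnorm(3)),
              function(d) mirror_flip(d, "y", c(-10, 10)),
              function(d) spatial_subset(d, c(-10, 10, -10, 10, -10, 10)))
  for (op in ops) {
    out <- op(dp)
    if (n_segments(out) > 0)
      expect_equal(sqrt(rowSums(out$vect^2)), rep(1, n_segments(out)),
                   tolerance = 1e-9)
  }
})
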