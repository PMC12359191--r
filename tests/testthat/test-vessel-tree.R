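test_that("Murray split radii", {
  expect_equal(murray_split_radii(1, c(0.5, 0.5)), rep(2^(-1 / 3), 2),
               tolerance = 1e-12)
  r <- murray_split_radii(1, c(0.75, 0.25))
  expect_equal(r, c(0.908560, 0.629961), tolerance = 1e-6)
  expect_equal(sum(r^3), 1, tolerance = 1e-12)
  expect_equal(murray_split_radii(2.5, 1), 2.5)
  # alternative exponent
  r2 <- murray_split_radii(1, c(0.3, 0.7), exponent = 2.2)
  expect_equal(sum(r2^2.2), 1, tolerance = 1e-12)
  expect_error(murray_split_radii(-1, c(0.5, 0.5)), "> 0")
  expect_error(murray_split_radii(1, c(0.5, 0.6)), "sum to 1")
})

test_that("candidate point sampling respects boundaries and seeds", {
  b <- unit_sphere_boundary()
  P <- sample_candidate_points(b, 1000L, seed = 7)
  expect_true(all(sqrt(rowSums(P^2)) < 1))
  expect_identical(P, sample_candidate_points(b, 1000L, seed = 7))
  expect_false(identical(P, sample_candidate_points(b, 1000L, seed = 8)))
  # single-voxel mask: all points within that voxel
  mask <- array(FALSE, c(3, 3, 3))
  mask[2, 2, 2] <- TRUE
  bm <- list(type = "mask", mask = mask, origin = c(0, 0, 0), spacing = 0.3)
  Pm <- sample_candidate_points(bm, 200L, seed = 1)
  expect_true(all(Pm > 0.3 & Pm < 0.6))
  # empty boundary errors
  expect_error(sample_candidate_points(
    list(type = "mask", mask = array(FALSE, c(2, 2, 2)),
         origin = c(0, 0, 0), spacing = 0.3), 5L), "zero interior")
})

test_that("terminal allocation is proportional within 1", {
  vols <- c(3.2, 1.1, 7.7, 0.4)
  n <- 57L
  counts <- allocate_terminals(vols, n)
  expect_equal(sum(counts), n)
  expect_true(all(abs(counts - n * vols / sum(vols)) < 1))
})

test_that("optimize_bifurcation finds the volume-minimizing junction", {
  # symmetric anchors, equal radii: junction on the symmetry axis (x = 0)
  X <- optimize_bifurcation(c(0, 0, 1), rbind(c(-1, 0, -1), c(1, 0, -1)),
                            c(0.5, 0.4, 0.4))
  expect_lt(abs(X[1]), 1e-5)
  expect_lt(abs(X[2]), 1e-5)
  # one child radius -> 0: junction on the parent/other-child segment
  X2 <- optimize_bifurcation(c(0, 0, 0), rbind(c(2, 0, 0), c(1, 5, 0)),
                             c(0.5, 0.5, 1e-9))
  expect_lt(abs(X2[2]), 1e-4) # segment is the x-axis
  expect_lt(abs(X2[3]), 1e-4)
  # collinear anchors: weighted midpoint, message logged
  expect_message(
    optimize_bifurcation(c(0, 0, 0), rbind(c(1, 0, 0), c(2, 0, 0)),
                         c(1, 1, 1)), "collinear")
  # random instances: never worse than a grid-search oracle
  set.seed(5)
  for (i in 1:5) {
    par <- runif(3); c1 <- runif(3); c2 <- runif(3); rr <- runif(3, 0.1, 1)
    X <- optimize_bifurcation(par, rbind(c1, c2), rr)
    cost <- attr(X, "cost")
    g <- seq(0, 1, length.out = 12)
    grid <- as.matrix(expand.grid(g, g, g))
    gc_cost <- min(apply(grid, 1, function(x) {
      pi * sum(rr^2 * c(vnorm(x - par), vnorm(x - c1), vnorm(x - c2)))
    }))
    expect_lte(cost, gc_cost + 1e-9)
  }
})

test_that("curvature interpolation honors knots and boundaries", {
  # 2 points: straight segment
  P <- rbind(c(0, 0, 0), c(1, 1, 1))
  out <- interpolate_curvature(P, degree = 3, samples = 11)
  expect_equal(out[1, ], P[1, ], tolerance = 1e-12)
  expect_equal(out[11, ], P[2, ], tolerance = 1e-12)
  expect_equal(out[6, ], c(0.5, 0.5, 0.5), tolerance = 1e-9)
  # 3 collinear points stay collinear
  P3 <- rbind(c(0, 0, 0), c(1, 2, 0), c(2, 4, 0))
  out3 <- interpolate_curvature(P3, degree = 2, samples = 21)
  expect_true(all(abs(out3[, 2] - 2 * out3[, 1]) < 1e-9))
  # quadratic through 3 noncollinear control points
  Pq <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0))
  outq <- interpolate_curvature(Pq, degree = 2, samples = 101)
  for (r in 1:3) {
    d <- min(sqrt(rowSums(sweep(outq, 2, Pq[r, ], `-`)^2)))
    expect_lt(d, 1e-9)
  }
  # boundary projection logs and keeps samples inside
  b <- unit_sphere_boundary(1.05)
  Pw <- rbind(c(-0.9, 0, 0), c(0, 1.0, 0), c(0.9, 0, 0))
  suppressMessages({
    outb <- interpolate_curvature(Pw, degree = 2, samples = 51, boundary = b)
  })
  expect_true(all(boundary_contains(b, outb)))
})

test_that("intersection check agrees with an independent sampled oracle", {
  # two parallel segments with gap greater than radii sum: empty
  g1 <- centerline_graph(
    data.frame(id = 1:4, x = c(0, 1, 0, 1), y = c(0, 0, 1, 1),
               z = c(0, 0, 0, 0)),
    data.frame(id = 1:2, a = c(1, 3), b = c(2, 4), radius = 0.2,
               tree = c("a", "b")),
    roots = c(a = 1L, b = 3L))
  expect_equal(nrow(check_intersections(g1)), 0L)
  # two crossing segments: one pair
  g2 <- centerline_graph(
    data.frame(id = 1:4, x = c(-1, 1, 0, 0), y = c(0, 0, -1, 1),
               z = c(0, 0, 0.1, 0.1)),
    data.frame(id = 1:2, a = c(1, 3), b = c(2, 4), radius = 0.2,
               tree = c("a", "b")),
    roots = c(a = 1L, b = 3L))
  hits <- check_intersections(g2)
  expect_equal(nrow(hits), 1L)
  # randomized set versus a dense-sampling distance oracle
  set.seed(21)
  n <- 12L
  nodes <- data.frame(id = 1:(2 * n), x = runif(2 * n), y = runif(2 * n),
                      z = runif(2 * n))
  edges <- data.frame(id = 1:n, a = seq(1, 2 * n, 2), b = seq(2, 2 * n, 2),
                      radius = runif(n, 0.01, 0.05), tree = "t")
  # every edge is its own tree so none are adjacent
  g <- centerline_graph(nodes, edges, roots = c(t = 1L))
  got <- check_intersections(g, clearance = 0.01)
  key_got <- sort(paste(got$edge1, got$edge2))
  # oracle: densely sampled point-point distances
  ts <- seq(0, 1, length.out = 400)
  pts <- lapply(seq_len(n), function(e) {
    a <- unlist(nodes[edges$a[e], c("x", "y", "z")])
    b <- unlist(nodes[edges$b[e], c("x", "y", "z")])
    outer(ts, a - a) + cbind(a[1] + ts * (b[1] - a[1]),
                             a[2] + ts * (b[2] - a[2]),
                             a[3] + ts * (b[3] - a[3]))
  })
  expected <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d2 <- outer(rowSums(pts[[i]]^2), rep(1, 400)) +
        outer(rep(1, 400), rowSums(pts[[j]]^2)) -
        2 * pts[[i]] %*% t(pts[[j]])
      dmin <- sqrt(max(0, min(d2)))
      if (dmin < edges$radius[i] + edges$radius[j] + 0.01) {
        expected <- c(expected, paste(i, j))
      }
    }
  }
  expect_setequal(key_got, sort(expected))
})

test_that("grow_tree: single terminal, Murray residuals, determinism", {
  b <- unit_sphere_boundary()
  cfg1 <- growth_config(b, root_position = c(0, 0, 0.999), root_radius = 0.3,
                        n_terminals = 1L, seed = 2)
  g1 <- grow_tree(cfg1)
  expect_equal(nrow(g1$edges), 1L)
  expect_equal(g1$edges$radius, 0.3)

  cfg <- growth_config(b, root_position = c(0, 0, 0.999), root_radius = 0.1,
                       n_terminals = 30L, seed = 11, min_radius = 0.01)
  g <- grow_tree(cfg)
  # all nodes inside (root may sit on the boundary)
  pos <- as.matrix(g$nodes[, c("x", "y", "z")])
  expect_true(all(sqrt(rowSums(pos[-1, ]^2)) < 1))
  # Murray residual at every bifurcation
  for (nid in g$nodes$id) {
    kids <- g$edges$radius[g$edges$a == nid]
    par <- g$edges$radius[g$edges$b == nid]
    if (length(kids) >= 2L && length(par) == 1L) {
      expect_lt(abs(par^3 - sum(kids^3)), 1e-9 * par^3)
    }
  }
  # radii non-increasing from root to terminals
  for (e in seq_len(nrow(g$edges))) {
    down <- g$edges$radius[g$edges$a == g$edges$b[e]]
    if (length(down)) expect_true(all(down <= g$edges$radius[e] + 1e-12))
  }
  # no radius below the configured minimum
  expect_true(all(g$edges$radius >= cfg$min_radius - 1e-12))
  # freshly grown tree is intersection-free at zero clearance
  expect_equal(nrow(check_intersections(g, clearance = 0)), 0L)
  # determinism
  g2 <- grow_tree(cfg)
  expect_equal(g$nodes, g2$nodes)
  expect_equal(g$edges, g2$edges)
  # min-radius violation is rejected up front
  expect_error(grow_tree(growth_config(b, c(0, 0, 0.999), root_radius = 0.1,
                                       n_terminals = 50L, min_radius = 0.1)),
               "minimum radius")
})

test_that("grow_tree avoids an existing tree and subregions get shares", {
  b <- unit_sphere_boundary()
  cfg_a <- growth_config(b, c(0, 0, 0.99), 0.1, 12L, seed = 3,
                         min_radius = 0.01, tree_label = "arterial")
  ga <- grow_tree(cfg_a)
  cfg_v <- growth_config(b, c(0, 0, -0.99), 0.1, 12L, seed = 4,
                         min_radius = 0.01, tree_label = "venous")
  gboth <- grow_tree(cfg_v, existing = ga)
  expect_setequal(unique(gboth$edges$tree), c("arterial", "venous"))
  expect_equal(nrow(check_intersections(gboth, clearance = 0)), 0L)
  # subregion allocation: two half-ball masks with 2:1 volume
  cfg_s <- growth_config(b, c(0, 0, 0.99), 0.1, 9L, seed = 5,
                         min_radius = 0.01,
                         subregions = list(
                           big = list(type = "box", lo = c(-0.5, -0.5, -0.5),
                                      hi = c(0.5, 0.5, 0.3)),
                           small = list(type = "box", lo = c(-0.5, -0.5, 0.3),
                                        hi = c(0.5, 0.5, 0.7))))
  vols <- c(1 * 1 * 0.8, 1 * 1 * 0.4)
  counts <- allocate_terminals(vols, 9L)
  expect_equal(sum(counts), 9L)
  expect_true(all(abs(counts - 9 * vols / sum(vols)) < 1))
  g <- grow_tree(cfg_s)
  expect_equal(sum(g$edges$b %in% attr(g, "terminal_nodes")), 9L)
})

test_that("Hungarian assignment matches brute force and triplets close", {
  set.seed(33)
  for (n in c(3L, 4L, 5L)) {
    cost <- matrix(runif(n * n), n, n)
    perm <- hungarian_assignment(cost)
    best <- Inf
    for (p in asplit(gtools_perms(n), 1)) {
      best <- min(best, sum(cost[cbind(seq_len(n), p)]))
    }
    expect_equal(attr(perm, "cost"), best, tolerance = 1e-12)
    expect_setequal(as.integer(perm), seq_len(n))
  }
  # identical point sets: identity matching, zero cost
  P <- matrix(runif(15), 5, 3)
  tri <- match_endpoint_triplets(P, P, P)
  expect_equal(attr(tri, "cost"), 0, tolerance = 1e-12)
  expect_equal(tri[, "arterial"], tri[, "venous"])
  expect_equal(tri[, "portal"], tri[, "venous"])
  # single point per set
  one <- match_endpoint_triplets(matrix(1:3, 1), matrix(4:6, 1),
                                 matrix(7:9, 1))
  expect_equal(dim(one), c(1L, 3L))
  # unequal sizes error
  expect_error(match_endpoint_triplets(P, P[1:4, ], P), "equal sizes")
  # each endpoint used exactly once on a random instance
  A <- matrix(runif(12), 4); V <- matrix(runif(12), 4)
  Q <- matrix(runif(12), 4)
  tri2 <- match_endpoint_triplets(A, V, Q)
  expect_setequal(tri2[, "arterial"], 1:4)
  expect_setequal(tri2[, "portal"], 1:4)
})

test_that("centerline graph JSON round trip", {
  g <- y_graph()
  tmp <- tempfile(fileext = ".json")
  write_centerline_graph(g, tmp)
  g2 <- read_centerline_graph(tmp)
  expect_equal(g2$nodes, g$nodes)
  expect_equal(g2$edges$radius, g$edges$radius)
  expect_equal(unname(unlist(g2$roots)), unname(g$roots))
})
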