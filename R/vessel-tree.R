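#' Vascular centerline graph
#'
#' A collection of nodes (positions in mm) and radius-carrying edges forming
#' one or more rooted vessel trees. Each tree is connected and acyclic from
#' its root, radii are positive and non-increasing from root to terminals,
#' and all nodes lie inside the organ boundary (roots may lie on it).
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z`.
#' @param edges data.frame with columns `id`, `a` (tail node), `b` (head
#'   node), `radius` (mm), `tree` (label).
#' @param roots named integer vector: entry node id per tree label.
#' @return an object of class `centerline_graph`.
#' @export
centerline_graph <- function(nodes, edges, roots) {
  stopifnot(all(c("id", "x", "y", "z") %in% names(nodes)),
            all(c("id", "a", "b", "radius", "tree") %in% names(edges)))
  if (nrow(edges) > 0L) {
    if (any(edges$radius <= 0)) stop("edge radii must be > 0")
    if (!all(c(edges$a, edges$b) %in% nodes$id)) {
      stop("edge references unknown node id")
    }
  }
  structure(list(nodes = nodes, edges = edges, roots = roots),
            class = "centerline_graph")
}

#' @export
print.centerline_graph <- function(x, ...) {
  cat(sprintf("centerline_graph: %d nodes, %d edges, %d tree(s)\n",
              nrow(x$nodes), nrow(x$edges), length(x$roots)))
  invisible(x)
}

#' Growth configuration for synthetic vessel trees
#'
#' @param boundary organ boundary: `list(type = "sphere", center, radius)`,
#'   `list(type = "box", lo, hi)`, or `list(type = "mask", mask, origin,
#'   spacing)` with a logical 3D array (isotropic spacing in mm, default
#'   0.3 mm voxels).
#' @param root_position entry point of the major input vessel (on or inside
#'   the boundary).
#' @param root_radius prescribed radius of the input vessel (mm).
#' @param n_terminals number of terminal endpoints to reach (>= 1).
#' @param murray_exponent Murray's-law exponent (default 3).
#' @param min_radius smallest admissible vessel radius in mm (default 0.1,
#'   i.e. 100 um); growth errors out rather than violate it.
#' @param seed integer seed driving all stochastic steps.
#' @param tree_label label for the grown tree.
#' @param curvature_degree polynomial degree for optional post-hoc centerline
#'   smoothing with [interpolate_curvature()].
#' @param candidate_neighbors number of nearest edges considered as
#'   attachment sites per terminal.
#' @param clearance minimum surface-to-surface clearance enforced against
#'   existing vessels during growth (mm).
#' @param retry_limit resampling attempts for an unattachable terminal.
#' @param subregions optional named list of sub-boundaries; terminal counts
#'   are allocated proportionally to their volumes (largest remainder).
#' @return an object of class `growth_config`.
#' @export
growth_config <- function(boundary, root_position, root_radius,
                          n_terminals, murray_exponent = 3,
                          min_radius = 0.1, seed = 1L, tree_label = "tree1",
                          curvature_degree = 3L, candidate_neighbors = 10L,
                          clearance = 0, retry_limit = 20L,
                          subregions = NULL) {
  if (n_terminals < 1L) stop("terminal count must be >= 1")
  if (murray_exponent <= 0) stop("murray exponent must be > 0")
  stopifnot_scalar_num(root_radius, "root_radius", positive = TRUE)
  structure(list(boundary = boundary, root_position = as.numeric(root_position),
                 root_radius = root_radius, n_terminals = as.integer(n_terminals),
                 murray_exponent = murray_exponent, min_radius = min_radius,
                 seed = seed, tree_label = tree_label,
                 curvature_degree = curvature_degree,
                 candidate_neighbors = as.integer(candidate_neighbors),
                 clearance = clearance, retry_limit = as.integer(retry_limit),
                 subregions = subregions),
            class = "growth_config")
}

# ---- boundaries -------------------------------------------------------------

boundary_bbox <- function(boundary) {
  switch(boundary$type,
    sphere = rbind(lo = boundary$center - boundary$radius,
                   hi = boundary$center + boundary$radius),
    box = rbind(lo = as.numeric(boundary$lo), hi = as.numeric(boundary$hi)),
    mask = {
      d <- dim(boundary$mask)
      rbind(lo = boundary$origin,
            hi = boundary$origin + boundary$spacing * d)
    },
    stop("unknown boundary type: ", boundary$type))
}

boundary_contains <- function(boundary, P) {
  P <- matrix(as.numeric(P), ncol = 3L)
  switch(boundary$type,
    sphere = sqrt(rowSums(sweep(P, 2L, boundary$center, `-`)^2)) <
      boundary$radius,
    box = P[, 1] > boundary$lo[1] & P[, 1] < boundary$hi[1] &
          P[, 2] > boundary$lo[2] & P[, 2] < boundary$hi[2] &
          P[, 3] > boundary$lo[3] & P[, 3] < boundary$hi[3],
    mask = {
      d <- dim(boundary$mask)
      ijk <- sweep(P, 2L, boundary$origin, `-`) / boundary$spacing
      i <- floor(ijk[, 1]) + 1L; j <- floor(ijk[, 2]) + 1L
      k <- floor(ijk[, 3]) + 1L
      ok <- i >= 1L & j >= 1L & k >= 1L & i <= d[1] & j <= d[2] & k <= d[3]
      res <- logical(nrow(P))
      if (any(ok)) {
        res[ok] <- boundary$mask[cbind(i[ok], j[ok], k[ok])]
      }
      res
    },
    stop("unknown boundary type: ", boundary$type))
}

boundary_volume <- function(boundary) {
  switch(boundary$type,
    sphere = 4 / 3 * pi * boundary$radius^3,
    box = prod(boundary$hi - boundary$lo),
    mask = sum(boundary$mask) * boundary$spacing^3,
    stop("unknown boundary type: ", boundary$type))
}

#' Sample candidate points inside an organ boundary
#'
#' Uniform rejection sampling of points strictly inside the boundary;
#' deterministic for a fixed seed.
#'
#' @param boundary boundary description (see [growth_config()]).
#' @param n number of points (>= 1).
#' @param seed integer seed.
#' @return `n x 3` matrix of positions (mm).
#' @export
sample_candidate_points <- function(boundary, n, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  if (boundary_volume(boundary) <= 0) {
    stop("boundary has zero interior volume")
  }
  bb <- boundary_bbox(boundary)
  with_seed(seed, {
    out <- matrix(NA_real_, 0L, 3L)
    guard <- 0L
    while (nrow(out) < n && guard < 10000L) {
      guard <- guard + 1L
      m <- max(64L, 2L * (n - nrow(out)))
      P <- cbind(runif(m, bb["lo", 1], bb["hi", 1]),
                 runif(m, bb["lo", 2], bb["hi", 2]),
                 runif(m, bb["lo", 3], bb["hi", 3]))
      keep <- boundary_contains(boundary, P)
      out <- rbind(out, P[keep, , drop = FALSE])
    }
    if (nrow(out) < n) stop("rejection sampling failed; boundary too thin?")
    out[seq_len(n), , drop = FALSE]
  })
}

#' Murray's-law bifurcation radii
#'
#' Splits a parent vessel radius into child radii carrying the given flow
#' fractions: `r_child = r_parent * fraction^(1/exponent)`, so the
#' exponent-th powers of the child radii sum exactly to the parent's.
#'
#' @param parent_radius parent radius (> 0).
#' @param flow_fractions positive fractions summing to 1.
#' @param exponent Murray exponent (default 3).
#' @return child radii, one per fraction.
#' @export
murray_split_radii <- function(parent_radius, flow_fractions, exponent = 3) {
  stopifnot_scalar_num(parent_radius, "parent_radius", positive = TRUE)
  if (any(flow_fractions <= 0)) stop("flow fractions must be positive")
  if (abs(sum(flow_fractions) - 1) > 1e-9) {
    stop("flow fractions must sum to 1")
  }
  parent_radius * flow_fractions^(1 / exponent)
}

#' Proportional allocation of terminal endpoints to subregions
#'
#' Largest-remainder apportionment of `total` endpoints proportional to
#' subregion volumes; every count is within 1 of the exact proportional
#' share.
#'
#' @param volumes positive subregion volumes.
#' @param total total endpoint count.
#' @return integer vector of counts summing to `total`.
#' @export
allocate_terminals <- function(volumes, total) {
  if (any(volumes <= 0)) stop("subregion volumes must be positive")
  share <- total * volumes / sum(volumes)
  counts <- floor(share)
  rem <- total - sum(counts)
  if (rem > 0L) {
    ord <- order(share - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
  }
  as.integer(counts)
}

#' Optimal bifurcation junction position
#'
#' Positions the junction of a parent segment and two child segments to
#' minimize the local tube volume `sum_i pi r_i^2 l_i` over the three
#' incident segments, by derivative-free (Nelder-Mead) iteration to 1e-6 mm.
#' Degenerate (collinear) anchors fall back to the radius-squared-weighted
#' midpoint.
#'
#' @param parent parent anchor point (length-3).
#' @param children 2 x 3 matrix of child anchor points.
#' @param radii radii of (parent, child1, child2) segments.
#' @return junction position (length-3); attribute `cost` holds the achieved
#'   volume.
#' @export
optimize_bifurcation <- function(parent, children, radii) {
  parent <- as.numeric(parent)
  children <- matrix(as.numeric(children), 2L, 3L)
  w <- radii^2
  anchors <- rbind(parent, children)
  cost <- function(x) {
    d1 <- sqrt(sum((x - anchors[1L, ])^2))
    d2 <- sqrt(sum((x - anchors[2L, ])^2))
    d3 <- sqrt(sum((x - anchors[3L, ])^2))
    pi * (w[1L] * d1 + w[2L] * d2 + w[3L] * d3)
  }
  v1 <- children[1L, ] - parent
  v2 <- children[2L, ] - parent
  cr <- vcross(v1, v2)
  scale2 <- max(sum(v1^2), sum(v2^2))
  if (scale2 == 0 || sum(cr^2) < (1e-12 * scale2)^2) {
    x <- colSums(anchors * w) / sum(w)
    message("optimize_bifurcation: collinear anchors, using weighted midpoint")
    return(structure(x, cost = cost(x)))
  }
  x0 <- colSums(anchors * w) / sum(w)
  fit <- stats::optim(x0, cost, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000L))
  structure(as.numeric(fit$par), cost = fit$value)
}

#' Polynomial smoothing of a vessel centerline
#'
#' Interpolates each coordinate of the polyline with a polynomial in the
#' chord-length parameter. With `degree >= n - 1` the curve passes through
#' every control point; lower degrees least-squares fit the interior while
#' endpoints are always reproduced exactly. Samples falling outside a
#' supplied boundary are projected inward toward the nearest control point.
#'
#' @param polyline `n x 3` matrix of control points (n >= 2).
#' @param degree polynomial degree.
#' @param samples number of output samples along the curve.
#' @param boundary optional boundary for containment projection.
#' @return `samples x 3` matrix; attribute `n_projected` counts boundary
#'   projections.
#' @export
interpolate_curvature <- function(polyline, degree = 3L, samples = 50L,
                                  boundary = NULL) {
  P <- as.matrix(polyline)
  n <- nrow(P)
  if (n < 2L) stop("polyline needs at least 2 control points")
  seglen <- sqrt(rowSums((P[-1L, , drop = FALSE] -
                          P[-n, , drop = FALSE])^2))
  t <- c(0, cumsum(seglen))
  if (t[n] == 0) stop("degenerate polyline (zero total length)")
  t <- t / t[n]
  deg <- min(degree, n - 1L)
  ts <- seq(0, 1, length.out = samples)
  Vand <- outer(t, 0:deg, `^`)
  Vs <- outer(ts, 0:deg, `^`)
  out <- matrix(0, samples, 3L)
  for (c in 1:3) {
    coef <- qr.solve(Vand, P[, c])
    out[, c] <- Vs %*% coef
  }
  # exact endpoints (least-squares fits can miss them slightly)
  corr0 <- P[1L, ] - out[1L, ]
  corr1 <- P[n, ] - out[samples, ]
  out <- out + outer(1 - ts, corr0) + outer(ts, corr1)
  n_proj <- 0L
  if (!is.null(boundary)) {
    inside <- boundary_contains(boundary, out)
    for (i in which(!inside)) {
      target <- P[which.min(sqrt(rowSums(sweep(P, 2L, out[i, ], `-`)^2))), ]
      for (step in seq(0.05, 1, by = 0.05)) {
        cand <- (1 - step) * out[i, ] + step * target
        if (boundary_contains(boundary, cand)) {
          out[i, ] <- cand
          n_proj <- n_proj + 1L
          break
        }
      }
    }
    if (n_proj > 0L) {
      message(sprintf("interpolate_curvature: projected %d sample(s) inward",
                      n_proj))
    }
  }
  structure(out, n_projected = n_proj)
}

# minimum distance between segments [p1,p2] and [q1,q2]
segment_segment_distance <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1
  d2 <- q2 - q1
  r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 1e-300 && e <= 1e-300) return(vnorm(r))
  if (a <= 1e-300) {
    t <- min(max(f / e, 0), 1)
    return(vnorm(p1 - (q1 + t * d2)))
  }
  cc <- sum(d1 * r)
  if (e <= 1e-300) {
    s <- min(max(-cc / a, 0), 1)
    return(vnorm((p1 + s * d1) - q1))
  }
  b <- sum(d1 * d2)
  denom <- a * e - b * b
  s <- if (denom > 1e-300) min(max((b * f - cc * e) / denom, 0), 1) else 0
  t <- (b * s + f) / e
  if (t < 0) {
    t <- 0; s <- min(max(-cc / a, 0), 1)
  } else if (t > 1) {
    t <- 1; s <- min(max((b - cc) / a, 0), 1)
  }
  vnorm((p1 + s * d1) - (q1 + t * d2))
}

graph_segment_table <- function(graph) {
  pos <- graph$nodes
  idx <- match(graph$edges$a, pos$id)
  jdx <- match(graph$edges$b, pos$id)
  data.frame(edge = graph$edges$id,
             a = graph$edges$a, b = graph$edges$b,
             ax = pos$x[idx], ay = pos$y[idx], az = pos$z[idx],
             bx = pos$x[jdx], by = pos$y[jdx], bz = pos$z[jdx],
             radius = graph$edges$radius, tree = graph$edges$tree)
}

#' Find vessel segment pairs violating a clearance
#'
#' Reports all nonadjacent segment pairs (segments sharing a node are
#' adjacent) whose capsule-to-capsule distance is below the sum of radii
#' plus `clearance`.
#'
#' @param graphs a [centerline_graph()] or list of them.
#' @param clearance required surface clearance (mm, default 0).
#' @return data.frame of violating pairs with their distances (0 rows if
#'   none).
#' @export
check_intersections <- function(graphs, clearance = 0) {
  if (inherits(graphs, "centerline_graph")) graphs <- list(graphs)
  tabs <- Map(function(g, gi) transform(graph_segment_table(g), graph = gi),
              graphs, seq_along(graphs))
  st <- do.call(rbind, tabs)
  n <- nrow(st)
  out <- list()
  if (n >= 2L) {
    A <- as.matrix(st[, c("ax", "ay", "az")])
    B <- as.matrix(st[, c("bx", "by", "bz")])
    lo <- pmin(A, B) - st$radius
    hi <- pmax(A, B) + st$radius
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        adjacent <- st$graph[i] == st$graph[j] &&
          length(intersect(c(st$a[i], st$b[i]), c(st$a[j], st$b[j]))) > 0L
        if (adjacent) next
        thr <- st$radius[i] + st$radius[j] + clearance
        if (any(lo[i, ] > hi[j, ] + clearance) ||
            any(lo[j, ] > hi[i, ] + clearance)) next
        d <- segment_segment_distance(A[i, ], B[i, ], A[j, ], B[j, ])
        if (d < thr) {
          out[[length(out) + 1L]] <- data.frame(
            edge1 = st$edge[i], graph1 = st$graph[i],
            edge2 = st$edge[j], graph2 = st$graph[j],
            distance = d, threshold = thr)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(edge1 = integer(0), graph1 = integer(0),
                      edge2 = integer(0), graph2 = integer(0),
                      distance = numeric(0), threshold = numeric(0)))
  }
  do.call(rbind, out)
}

# ---- tree growth ------------------------------------------------------------

#' Grow a synthetic vessel tree inside an organ boundary
#'
#' Sequential constrained-constructive growth: terminal endpoints are
#' sampled uniformly inside the boundary and attached one at a time, each to
#' the existing edge whose splitting minimizes the locally added tube volume
#' `sum pi r^2 l` (junction placed by [optimize_bifurcation()]). All radii
#' derive from Murray's law with equal flow per terminal, so the Murray
#' identity holds to rounding at every bifurcation. New segments must stay
#' inside the boundary and keep `clearance` from all existing vessels
#' (including `existing` graphs); an unattachable terminal is resampled up
#' to `retry_limit` times, then growth errors out.
#'
#' @param config a [growth_config()].
#' @param existing optional [centerline_graph()] to avoid (and include in
#'   the returned graph).
#' @return a [centerline_graph()] containing the new tree (appended to
#'   `existing` when given).
#' @export
grow_tree <- function(config, existing = NULL) {
  stopifnot(inherits(config, "growth_config"))
  bnd <- config$boundary
  root <- config$root_position
  K <- config$n_terminals
  expo <- config$murray_exponent
  # terminal radius check up front: r_term = r_root * (1/K)^(1/expo)
  if (config$root_radius * (1 / K)^(1 / expo) < config$min_radius - 1e-12) {
    stop(sprintf(paste0("terminal radius %.4g mm would fall below the ",
                        "minimum radius %.4g mm; reduce terminal count or ",
                        "increase the root radius"),
                 config$root_radius * (1 / K)^(1 / expo), config$min_radius))
  }
  if (!is.null(config$subregions)) {
    vols <- vapply(config$subregions, boundary_volume, numeric(1))
    counts <- allocate_terminals(vols, K)
    terminals <- do.call(rbind, Map(function(b, m, i) {
      if (m == 0L) return(matrix(numeric(0), 0L, 3L))
      sample_candidate_points(b, m, seed = config$seed + i)
    }, config$subregions, counts, seq_along(counts)))
  } else {
    terminals <- sample_candidate_points(bnd, K, seed = config$seed)
  }
  ext_st <- if (!is.null(existing)) graph_segment_table(existing) else NULL

  # growth state: positions, parent pointers, per-node subtree terminal count
  pos <- matrix(root, 1L, 3L)
  parent <- c(NA_integer_)
  nterm <- c(0L)          # terminals below each node (via its parent edge)
  is_terminal <- c(FALSE)

  add_node <- function(p, par, nt, term) {
    pos <<- rbind(pos, p)
    parent <<- c(parent, par)
    nterm <<- c(nterm, nt)
    is_terminal <<- c(is_terminal, term)
    nrow(pos)
  }
  bump_ancestors <- function(v) {
    while (!is.na(parent[v])) {
      nterm[v] <<- nterm[v] + 1L
      v <- parent[v]
    }
    nterm[v] <<- nterm[v] + 1L
  }
  edge_radius <- function(v, total) {
    config$root_radius * (nterm[v] / total)^(1 / expo)
  }
  # Full clearance audit of the current tree state (all nonadjacent edge
  # pairs, plus all pairs against `existing`). Radii of ancestor edges grow
  # as terminals accumulate, so every tentative insertion re-audits the
  # whole tree with updated radii and is rolled back on any violation: the
  # finished tree is intersection-free at the configured clearance.
  state_clean <- function() {
    kids <- which(!is.na(parent))
    E <- length(kids)
    total <- max(1L, nterm[1L])
    A <- pos[parent[kids], , drop = FALSE]
    B <- pos[kids, , drop = FALSE]
    R <- config$root_radius * (nterm[kids] / total)^(1 / expo)
    lo <- pmin(A, B) - R
    hi <- pmax(A, B) + R
    if (E >= 2L) {
      for (i in seq_len(E - 1L)) {
        for (j in seq((i + 1L), E)) {
          if (length(intersect(c(parent[kids[i]], kids[i]),
                               c(parent[kids[j]], kids[j]))) > 0L) next
          thr <- R[i] + R[j] + config$clearance
          if (any(lo[i, ] > hi[j, ] + config$clearance) ||
              any(lo[j, ] > hi[i, ] + config$clearance)) next
          if (segment_segment_distance(A[i, ], B[i, ], A[j, ], B[j, ]) <
              thr) {
            return(FALSE)
          }
        }
      }
    }
    if (!is.null(ext_st)) {
      for (i in seq_len(E)) {
        for (r in seq_len(nrow(ext_st))) {
          d <- segment_segment_distance(
            A[i, ], B[i, ],
            c(ext_st$ax[r], ext_st$ay[r], ext_st$az[r]),
            c(ext_st$bx[r], ext_st$by[r], ext_st$bz[r]))
          if (d < R[i] + ext_st$radius[r] + config$clearance) return(FALSE)
        }
      }
    }
    TRUE
  }

  # first terminal: single root-to-terminal edge (validated against any
  # existing vasculature)
  first_ok <- FALSE
  ti <- 1L
  retries <- 0L
  while (!first_ok) {
    if (ti > nrow(terminals)) {
      retries <- retries + 1L
      if (retries > config$retry_limit) {
        stop("grow_tree: retry limit exceeded while placing the root edge")
      }
      terminals <- rbind(terminals,
                         sample_candidate_points(bnd, K, seed = config$seed +
                                                   2000L + retries))
    }
    t1 <- terminals[ti, ]
    ti <- ti + 1L
    v <- add_node(t1, 1L, 1L, TRUE)
    nterm[1L] <- 1L
    if (state_clean()) {
      first_ok <- TRUE
    } else {
      pos <- pos[1L, , drop = FALSE]
      parent <- parent[1L]
      nterm <- c(0L)
      is_terminal <- c(FALSE)
    }
  }
  placed <- 1L
  while (placed < K) {
    if (ti > nrow(terminals)) {
      terminals <- rbind(terminals,
                         sample_candidate_points(bnd, K, seed = config$seed +
                                                   1000L + retries))
    }
    t <- terminals[ti, ]
    ti <- ti + 1L
    total_new <- placed + 1L
    # candidate edges ranked by distance from t
    cand <- which(!is.na(parent))
    dist_t <- vapply(cand, function(v) {
      points_segment_distance(matrix(t, 1L, 3L), pos[parent[v], ], pos[v, ])
    }, numeric(1))
    ord <- cand[order(dist_t)]
    ord <- head(ord, config$candidate_neighbors)
    # rank candidates by locally added tube volume, then attempt in order
    ranked <- list()
    for (v in ord) {
      p_node <- parent[v]
      A <- pos[p_node, ]
      B <- pos[v, ]
      kB <- nterm[v]
      r_AX <- config$root_radius * ((kB + 1L) / total_new)^(1 / expo)
      r_XB <- config$root_radius * (kB / total_new)^(1 / expo)
      r_XT <- config$root_radius * (1 / total_new)^(1 / expo)
      X <- suppressMessages(
        optimize_bifurcation(A, rbind(B, t), c(r_AX, r_XB, r_XT)))
      added <- attr(X, "cost") -
        pi * config$root_radius^2 * (kB / placed)^(2 / expo) * vnorm(B - A)
      Xn <- as.numeric(X)
      # keep the junction off the anchors (zero-length edges break meshing)
      if (min(vnorm(Xn - A), vnorm(Xn - B), vnorm(Xn - t)) <
          1e-4 * vnorm(B - A)) {
        Xn <- 0.9 * Xn + 0.1 * (A + B + t) / 3
      }
      pts <- rbind(Xn, t, (A + Xn) / 2, (Xn + B) / 2, (Xn + t) / 2)
      if (!all(boundary_contains(bnd, pts))) next
      ranked[[length(ranked) + 1L]] <- list(v = v, X = Xn, added = added)
    }
    if (length(ranked)) {
      ranked <- ranked[order(vapply(ranked, `[[`, numeric(1), "added"))]
    }
    accepted <- FALSE
    for (candi in ranked) {
      v <- candi$v
      p_node <- parent[v]
      # tentative insertion
      xid <- add_node(candi$X, p_node, nterm[v], FALSE)
      parent[v] <- xid
      tid <- add_node(t, xid, 1L, TRUE)
      bump_ancestors(xid)
      if (state_clean()) {
        accepted <- TRUE
        break
      }
      # rollback
      nn <- length(parent)
      w <- xid
      while (!is.na(parent[w])) {
        nterm[w] <- nterm[w] - 1L
        w <- parent[w]
      }
      nterm[w] <- nterm[w] - 1L
      parent[v] <- p_node
      pos <- pos[seq_len(nn - 2L), , drop = FALSE]
      parent <- parent[seq_len(nn - 2L)]
      nterm <- nterm[seq_len(nn - 2L)]
      is_terminal <- is_terminal[seq_len(nn - 2L)]
    }
    if (!accepted) {
      retries <- retries + 1L
      message(sprintf("grow_tree: terminal unattachable, resampling (%d/%d)",
                      retries, config$retry_limit))
      if (retries > config$retry_limit) {
        stop("grow_tree: retry limit exceeded while attaching terminals")
      }
      next
    }
    placed <- placed + 1L
  }

  # assemble the final graph with exact Murray radii
  total <- nterm[1L]
  nn <- nrow(pos)
  node_df <- data.frame(id = seq_len(nn), x = pos[, 1L], y = pos[, 2L],
                        z = pos[, 3L])
  kids <- which(!is.na(parent))
  edge_df <- data.frame(
    id = seq_along(kids), a = parent[kids], b = kids,
    radius = config$root_radius * (nterm[kids] / total)^(1 / expo),
    tree = config$tree_label)
  if (any(edge_df$radius < config$min_radius - 1e-12)) {
    stop("grow_tree: produced a radius below min_radius (internal error)")
  }
  g <- centerline_graph(node_df, edge_df,
                        roots = stats::setNames(1L, config$tree_label))
  attr(g, "terminal_nodes") <- which(is_terminal)
  if (!is.null(existing)) {
    g <- merge_graphs(existing, g)
  }
  g
}

#' Merge two centerline graphs
#'
#' Re-indexes node and edge ids of `g2` and appends it to `g1` (trees remain
#' distinct via their labels/roots).
#'
#' @param g1,g2 [centerline_graph()] objects.
#' @return combined [centerline_graph()].
#' @export
merge_graphs <- function(g1, g2) {
  off_n <- max(g1$nodes$id)
  off_e <- if (nrow(g1$edges)) max(g1$edges$id) else 0L
  n2 <- transform(g2$nodes, id = id + off_n)
  e2 <- transform(g2$edges, id = id + off_e, a = a + off_n, b = b + off_n)
  t2 <- attr(g2, "terminal_nodes")
  g <- centerline_graph(rbind(g1$nodes, n2), rbind(g1$edges, e2),
                        c(g1$roots, g2$roots + off_n))
  attr(g, "terminal_nodes") <- c(attr(g1, "terminal_nodes"),
                                 if (!is.null(t2)) t2 + off_n)
  g
}

#' Terminal endpoint positions of a tree
#'
#' Nodes of degree 1 other than the roots.
#'
#' @param graph a [centerline_graph()].
#' @param tree optional tree label filter.
#' @return matrix of positions with node ids as rownames.
#' @export
terminal_positions <- function(graph, tree = NULL) {
  ed <- graph$edges
  if (!is.null(tree)) ed <- ed[ed$tree == tree, , drop = FALSE]
  deg <- table(c(ed$a, ed$b))
  ids <- as.integer(names(deg)[deg == 1L])
  ids <- setdiff(ids, unname(graph$roots))
  idx <- match(ids, graph$nodes$id)
  out <- as.matrix(graph$nodes[idx, c("x", "y", "z")])
  rownames(out) <- ids
  out
}

# ---- assignment / triplet matching -----------------------------------------

#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Solves the linear assignment problem for a square cost matrix by the
#' shortest-augmenting-path variant of the Hungarian algorithm (O(n^3)).
#'
#' @param cost square numeric cost matrix.
#' @return integer vector `perm` with `perm[i]` the column assigned to row
#'   `i`; attribute `cost` holds the total.
#' @export
hungarian_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (ncol(cost) != n) stop("cost matrix must be square")
  INF <- sum(abs(cost)) + 1
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)          # p[j+1]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) {
          minv[j + 1L] <- cur
          way[j + 1L] <- j0
        }
        if (minv[j + 1L] < delta) {
          delta <- minv[j + 1L]
          j1 <- j
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  perm <- integer(n)
  total <- 0
  for (j in seq_len(n)) {
    if (p[j + 1L] > 0L) {
      perm[p[j + 1L]] <- j
      total <- total + cost[p[j + 1L], j]
    }
  }
  structure(perm, cost = total)
}

#' Match terminal endpoints of three trees into circulation triplets
#'
#' One-to-one minimum-total-distance mappings arterial -> venous and
#' portal -> venous (each stage a Hungarian assignment), producing one
#' closed-circulation triplet per venous endpoint.
#'
#' @param arterial,venous,portal equally sized point matrices (n x 3).
#' @return `n x 3` integer matrix with columns `arterial`, `venous`,
#'   `portal`; attribute `cost` holds the summed Euclidean cost of both
#'   stages.
#' @export
match_endpoint_triplets <- function(arterial, venous, portal) {
  arterial <- as.matrix(arterial); venous <- as.matrix(venous)
  portal <- as.matrix(portal)
  n <- nrow(venous)
  if (nrow(arterial) != n || nrow(portal) != n) {
    stop("the three endpoint sets must have equal sizes")
  }
  dmat <- function(P, Q) {
    sqrt(outer(rowSums(P^2), rep(1, nrow(Q))) +
         outer(rep(1, nrow(P)), rowSums(Q^2)) - 2 * P %*% t(Q))
  }
  av <- hungarian_assignment(dmat(arterial, venous))
  pv <- hungarian_assignment(dmat(portal, venous))
  a_of_v <- integer(n); a_of_v[av] <- seq_len(n)
  p_of_v <- integer(n); p_of_v[pv] <- seq_len(n)
  out <- cbind(arterial = a_of_v, venous = seq_len(n), portal = p_of_v)
  structure(out, cost = attr(av, "cost") + attr(pv, "cost"))
}

# ---- graph JSON I/O ---------------------------------------------------------

#' Read and write centerline graphs as JSON
#'
#' Schema: `nodes: [{id, x, y, z}]`, `edges: [{id, a, b, radius, tree}]`,
#' `roots: {tree: node id}`; units mm.
#'
#' @param graph a [centerline_graph()].
#' @param path file path.
#' @return reader returns the graph; writer returns `path` invisibly.
#' @export
write_centerline_graph <- function(graph, path) {
  jsonlite::write_json(
    list(nodes = graph$nodes, edges = graph$edges,
         roots = as.list(graph$roots)),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_centerline_graph
#' @export
read_centerline_graph <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  centerline_graph(d$nodes, d$edges, unlist(d$roots))
}
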