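#' Rodrigues rotation matrix
#'
#' The 3x3 matrix rotating by angle `theta` about the unit axis `u`:
#' `R = cos(theta) I + sin(theta) [u]_x + (1 - cos(theta)) u u^T`, written
#' out entrywise.
#'
#' @param u unit axis (length-3 numeric, |u| = 1 within 1e-9).
#' @param theta rotation angle in radians.
#' @return orthogonal 3x3 matrix with determinant +1.
#' @export
rodrigues_matrix <- function(u, theta) {
  if (abs(vnorm(u) - 1) > 1e-9) stop("rotation axis must be a unit vector")
  ct <- cos(theta)
  st <- sin(theta)
  vt <- 1 - ct
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  matrix(c(
    ct + ux^2 * vt,        ux * uy * vt - uz * st, ux * uz * vt + uy * st,
    uy * ux * vt + uz * st, ct + uy^2 * vt,        uy * uz * vt - ux * st,
    uz * ux * vt - uy * st, uz * uy * vt + ux * st, ct + uz^2 * vt),
    nrow = 3L, byrow = TRUE)
}

#' Place a unit cylinder along a vessel segment
#'
#' Scales the template unit cylinder radially to the target radius and
#' axially to the segment length, rotates its +z axis onto the segment
#' direction by the Rodrigues rotation about the axis orthogonal to both
#' (for an antiparallel segment any fixed perpendicular axis with angle pi
#' is used), and translates the base to the segment start.
#'
#' @param cyl template mesh from [unit_cylinder()].
#' @param a,b segment start / end points (mm).
#' @param radius target radius (mm).
#' @return a [triangle_mesh()] whose axis coincides with the segment.
#' @export
transform_segment <- function(cyl, a, b, radius) {
  a <- as.numeric(a); b <- as.numeric(b)
  len <- vnorm(b - a)
  if (len <= 0) stop("zero-length segment")
  stopifnot_scalar_num(radius, "radius", positive = TRUE)
  v <- (b - a) / len
  R <- rotation_between(c(0, 0, 1), v)
  transform_mesh(cyl, rotation = R, translation = a,
                 scale = c(radius, radius, len))
}

#' Instance undersized cylinders along every graph edge
#'
#' Builds one capped cylinder per centerline edge with its radius reduced by
#' `offset`: the subsequent offset-compensated wrapping ([wrap_union()])
#' restores the full radius, so the final surface carries accurate vessel
#' radii. The result is a disjoint collection (one connected component per
#' edge); segment provenance is kept in the `segments` attribute so the
#' wrapper can work from the exact geometry.
#'
#' @param graph a [centerline_graph()].
#' @param offset undersizing thickness in mm; must be smaller than the
#'   smallest edge radius.
#' @param radial cylinder tessellation (radial vertex count).
#' @return a [triangle_mesh()] with attribute `segments` (data.frame of
#'   endpoints, undersized and full radii).
#' @export
assemble_segments <- function(graph, offset, radial = 32L) {
  stopifnot(inherits(graph, "centerline_graph"))
  ed <- graph$edges
  if (nrow(ed) == 0L) stop("graph has no edges")
  if (offset < 0) stop("offset must be >= 0")
  if (offset >= min(ed$radius)) {
    stop(sprintf("offset (%.4g) must be smaller than the minimum radius (%.4g)",
                 offset, min(ed$radius)))
  }
  pos <- graph$nodes
  tmpl <- unit_cylinder(radial)
  segs <- vector("list", nrow(ed))
  meshes <- vector("list", nrow(ed))
  for (r in seq_len(nrow(ed))) {
    a <- unlist(pos[pos$id == ed$a[r], c("x", "y", "z")])
    b <- unlist(pos[pos$id == ed$b[r], c("x", "y", "z")])
    meshes[[r]] <- transform_segment(tmpl, a, b, ed$radius[r] - offset)
    segs[[r]] <- data.frame(ax = a[1], ay = a[2], az = a[3],
                            bx = b[1], by = b[2], bz = b[3],
                            radius = ed$radius[r] - offset,
                            radius_full = ed$radius[r])
  }
  out <- concat_meshes(meshes)
  attr(out, "segments") <- do.call(rbind, segs)
  attr(out, "offset") <- offset
  out
}

# distance from points (n x 3) to a segment [a, b]
points_segment_distance <- function(P, a, b) {
  ab <- b - a
  L2 <- sum(ab * ab)
  if (L2 == 0) {
    d <- sweep(P, 2L, a, `-`)
    return(sqrt(rowSums(d * d)))
  }
  t <- (sweep(P, 2L, a, `-`) %*% ab) / L2
  t <- pmin(pmax(as.vector(t), 0), 1)
  Q <- cbind(a[1] + t * ab[1], a[2] + t * ab[2], a[3] + t * ab[3])
  sqrt(rowSums((P - Q)^2))
}

# signed distance of points to a union of capsules; negative inside
capsule_union_sdf <- function(P, segments, radii) {
  d <- rep(Inf, nrow(P))
  for (r in seq_len(nrow(segments))) {
    a <- as.numeric(segments[r, c("ax", "ay", "az")])
    b <- as.numeric(segments[r, c("bx", "by", "bz")])
    d <- pmin(d, points_segment_distance(P, a, b) - radii[r])
  }
  d
}

# Extract a triangle mesh from a scalar field callback evaluated on a
# regular grid (inside = field < iso). `field_fun` maps an n x 3 point
# matrix to n field values; evaluation is chunked by z-slab.
isosurface_from_function <- function(field_fun, lo, hi, spacing, iso = 0) {
  n <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  sp <- (hi - lo) / (n - 1L)
  xs <- lo[1] + sp[1] * (seq_len(n[1]) - 1L)
  ys <- lo[2] + sp[2] * (seq_len(n[2]) - 1L)
  zs <- lo[3] + sp[3] * (seq_len(n[3]) - 1L)
  field <- numeric(prod(n))
  slab <- as.matrix(expand.grid(x = xs, y = ys))
  np <- nrow(slab)
  for (k in seq_len(n[3])) {
    P <- cbind(slab, zs[k])
    field[(k - 1L) * np + seq_len(np)] <- field_fun(P)
  }
  res <- .mt_isosurface(field, n, lo, sp, iso)
  triangle_mesh(res$vertices, res$faces)
}

#' Offset-compensated wrap of a cylinder collection
#'
#' Produces a single watertight surface enclosing all input cylinders, with
#' the outer surface approximating the union of full-radius capsules: the
#' `offset` added back by the wrap compensates the deliberate undersizing
#' applied by [assemble_segments()]. Implemented as an implicit capsule-union
#' isosurface extracted by marching tetrahedra (the watertight,
#' offset-compensated contract of alpha wrapping, with a different
#' algorithm).
#'
#' @param cylinders output of [assemble_segments()] (its `segments`
#'   attribute supplies exact centerline geometry).
#' @param offset the same offset passed to [assemble_segments()] (mm).
#' @param resolution target number of grid cells across the largest bounding
#'   box extent (default 96); at least 6 cells span the smallest radius.
#' @return a watertight [triangle_mesh()].
#' @export
wrap_union <- function(cylinders, offset, resolution = 96L) {
  if (is.null(cylinders) || nrow(cylinders$faces) == 0L) {
    stop("empty input: nothing to wrap")
  }
  segs <- attr(cylinders, "segments")
  if (is.null(segs)) {
    stop("wrap_union requires the 'segments' attribute written by ",
         "assemble_segments()")
  }
  radii <- segs$radius + offset
  A <- as.matrix(segs[, c("ax", "ay", "az")])
  B <- as.matrix(segs[, c("bx", "by", "bz")])
  lo <- pmin(apply(A, 2L, min), apply(B, 2L, min)) - max(radii) * 1.5
  hi <- pmax(apply(A, 2L, max), apply(B, 2L, max)) + max(radii) * 1.5
  h <- min(max(hi - lo) / resolution, min(radii) / 6)
  mesh <- isosurface_from_function(
    function(P) capsule_union_sdf(P, segs, radii), lo, hi, rep(h, 3L))
  wt <- is_watertight(mesh)
  if (!isTRUE(wt)) {
    stop("wrap produced a non-watertight mesh: ", attr(wt, "reason"))
  }
  attr(mesh, "segments") <- transform(segs, radius = radii)
  mesh
}

#' Boolean union of watertight meshes
#'
#' Unions several watertight surfaces. Exact duplicates collapse to a single
#' copy and mutually disjoint inputs are concatenated unchanged (volume adds
#' exactly); genuinely overlapping groups are unioned implicitly (minimum of
#' per-mesh signed distance fields sampled on a grid, isosurfaced by marching
#' tetrahedra), which re-meshes those groups with small (grid-limited)
#' volume error.
#'
#' @param meshes list of watertight [triangle_mesh()] objects.
#' @param resolution grid cells across the largest extent of an overlapping
#'   group (default 96).
#' @return a watertight [triangle_mesh()].
#' @export
boolean_union_trees <- function(meshes, resolution = 96L) {
  if (length(meshes) == 0L) stop("no meshes supplied")
  for (i in seq_along(meshes)) {
    wt <- is_watertight(meshes[[i]])
    if (!isTRUE(wt)) {
      stop(sprintf("input mesh %d is not watertight: %s", i,
                   attr(wt, "reason")))
    }
  }
  # collapse exact duplicates
  sig <- vapply(meshes, function(m) {
    paste(nrow(m$vertices), nrow(m$faces),
          sprintf("%.12g", sum(m$vertices) + sum(m$faces * 1.0)),
          sprintf("%.12g", mesh_volume(m)))
  }, character(1))
  meshes <- meshes[!duplicated(sig)]
  if (length(meshes) == 1L) return(meshes[[1L]])
  # group meshes whose bounding boxes overlap
  bb <- lapply(meshes, mesh_bbox)
  n <- length(meshes)
  grp <- seq_len(n)
  overlap <- function(b1, b2) all(b1["lo", ] <= b2["hi", ] &
                                  b2["lo", ] <= b1["hi", ])
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (overlap(bb[[i]], bb[[j]])) grp[grp == grp[j]] <- grp[i]
    }
  }
  parts <- lapply(unique(grp), function(g) {
    members <- meshes[grp == g]
    if (length(members) == 1L) return(members[[1L]])
    lo <- Reduce(pmin, lapply(members, function(m) mesh_bbox(m)["lo", ]))
    hi <- Reduce(pmax, lapply(members, function(m) mesh_bbox(m)["hi", ]))
    pad <- 0.05 * max(hi - lo)
    lo <- lo - pad
    hi <- hi + pad
    ncell <- pmax(2L, as.integer(ceiling((hi - lo) / (max(hi - lo) /
                                                      resolution))) + 1L)
    sp <- (hi - lo) / (ncell - 1L)
    field <- Reduce(pmin, lapply(members, function(m) {
      .grid_signed_distance(m$vertices, m$faces, ncell, lo, sp)
    }))
    res <- .mt_isosurface(field, ncell, lo, sp, 0)
    triangle_mesh(res$vertices, res$faces)
  })
  out <- concat_meshes(parts)
  wt <- is_watertight(out)
  if (!isTRUE(wt)) {
    stop("union produced a non-watertight mesh: ", attr(wt, "reason"))
  }
  out
}
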