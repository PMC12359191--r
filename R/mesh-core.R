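#' Triangle surface mesh
#'
#' Minimal indexed triangle mesh: an `n x 3` numeric vertex matrix (mm) and
#' an `m x 3` integer face matrix of 1-based vertex indices. Meshes flagged
#' watertight must be closed, 2-manifold and consistently outward-oriented
#' (see [is_watertight()]).
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z in mm).
#' @param faces integer matrix, one row per triangle (1-based vertex ids).
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

empty_mesh <- function() {
  triangle_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
}

#' Enclosed volume of a triangle mesh
#'
#' Signed volume via the divergence theorem (sum of signed tetrahedron
#' volumes against the origin). Positive for closed, outward-oriented
#' meshes; multiple disjoint closed components add up.
#'
#' @param mesh a [triangle_mesh()].
#' @return volume in mm^3 (units of the vertex coordinates cubed).
#' @export
mesh_volume <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(0)
  V <- mesh$vertices
  a <- V[mesh$faces[, 1L], , drop = FALSE]
  b <- V[mesh$faces[, 2L], , drop = FALSE]
  c <- V[mesh$faces[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * c[, 3L] - b[, 3L] * c[, 2L]) +
      a[, 2L] * (b[, 3L] * c[, 1L] - b[, 1L] * c[, 3L]) +
      a[, 3L] * (b[, 1L] * c[, 2L] - b[, 2L] * c[, 1L])) / 6
}

#' Watertightness / manifoldness check
#'
#' A mesh passes when every directed edge appears exactly once and every
#' undirected edge is shared by exactly two faces with opposite directions
#' (closed, edge-manifold, consistently oriented), and no face is
#' degenerate. Self-intersection is not tested here.
#'
#' @param mesh a [triangle_mesh()].
#' @return logical; attribute `reason` explains a failure.
#' @export
is_watertight <- function(mesh) {
  F <- mesh$faces
  if (nrow(F) == 0L) {
    return(structure(FALSE, reason = "empty mesh"))
  }
  if (any(F[, 1L] == F[, 2L] | F[, 2L] == F[, 3L] | F[, 1L] == F[, 3L])) {
    return(structure(FALSE, reason = "degenerate face"))
  }
  he_from <- c(F[, 1L], F[, 2L], F[, 3L])
  he_to <- c(F[, 2L], F[, 3L], F[, 1L])
  nv <- nrow(mesh$vertices)
  key <- (he_from - 1) * as.double(nv) + (he_to - 1)
  if (anyDuplicated(key)) {
    return(structure(FALSE, reason = "duplicated directed edge"))
  }
  rkey <- (he_to - 1) * as.double(nv) + (he_from - 1)
  if (!all(key %in% rkey)) {
    return(structure(FALSE, reason = "boundary edge (mesh not closed)"))
  }
  TRUE
}

#' Connected components of a mesh
#'
#' Counts face-connectivity components (faces sharing a vertex are
#' connected). Isolated vertices are ignored.
#'
#' @param mesh a [triangle_mesh()].
#' @return number of connected components.
#' @export
mesh_components <- function(mesh) {
  F <- mesh$faces
  if (nrow(F) == 0L) return(0L)
  nv <- nrow(mesh$vertices)
  parent <- seq_len(nv)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in seq_len(nrow(F))) {
    a <- find(F[r, 1L]); b <- find(F[r, 2L]); c <- find(F[r, 3L])
    parent[b] <- a
    parent[find(c)] <- find(a)
  }
  roots <- vapply(unique(as.vector(F)), find, integer(1))
  length(unique(roots))
}

#' Concatenate meshes
#'
#' Stacks vertex and face tables (face indices re-offset). No vertex
#' merging: components remain disjoint.
#'
#' @param meshes list of [triangle_mesh()] objects.
#' @return a single [triangle_mesh()].
#' @export
concat_meshes <- function(meshes) {
  meshes <- Filter(function(m) nrow(m$faces) > 0L, meshes)
  if (length(meshes) == 0L) return(empty_mesh())
  offs <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$vertices),
                              integer(1))))
  V <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  F <- do.call(rbind, Map(function(m, o) m$faces + o, meshes,
                          offs[seq_along(meshes)]))
  triangle_mesh(V, F)
}

transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                           scale = c(1, 1, 1)) {
  V <- mesh$vertices
  V <- sweep(V, 2L, scale, `*`)
  V <- V %*% t(rotation)
  V <- sweep(V, 2L, translation, `+`)
  triangle_mesh(V, mesh$faces)
}

mesh_bbox <- function(mesh) {
  rbind(lo = apply(mesh$vertices, 2L, min), hi = apply(mesh$vertices, 2L, max))
}

# ---- primitive generators ---------------------------------------------------

#' Primitive meshes
#'
#' Watertight parametric primitives: the unit cylinder (radius 1, height 1,
#' base disc centered at the origin in the x-y plane, axis +z), an arbitrary
#' capped cylinder between two points, a hollow tube (annular cylinder), a
#' regular icosahedron, an icosphere, a hexagonal prism and an axis-aligned
#' box.
#'
#' @param radial number of radial subdivisions (default 32).
#' @return a [triangle_mesh()].
#' @export
unit_cylinder <- function(radial = 32L) {
  th <- 2 * pi * (seq_len(radial) - 1L) / radial
  ring <- cbind(cos(th), sin(th))
  V <- rbind(cbind(ring, 0), cbind(ring, 1), c(0, 0, 0), c(0, 0, 1))
  bot <- seq_len(radial)
  top <- radial + seq_len(radial)
  cb <- 2L * radial + 1L
  ct <- 2L * radial + 2L
  nxt <- c(seq_len(radial)[-1L], 1L)
  F <- rbind(
    cbind(bot, bot[nxt], top[nxt]),         # side, outward
    cbind(bot, top[nxt], top),
    cbind(cb, bot[nxt], bot),               # bottom cap (normal -z)
    cbind(ct, top, top[nxt]))               # top cap (normal +z)
  triangle_mesh(V, F)
}

#' @rdname unit_cylinder
#' @param a,b segment endpoints (length-3 numeric, mm).
#' @param radius cylinder radius (mm).
#' @export
cylinder_mesh <- function(a, b, radius, radial = 32L) {
  transform_segment(unit_cylinder(radial), a, b, radius)
}

#' @rdname unit_cylinder
#' @param r_inner,r_outer inner and outer radii of the tube wall.
#' @export
tube_mesh <- function(a, b, r_inner, r_outer, radial = 32L) {
  stopifnot(r_outer > r_inner, r_inner > 0)
  th <- 2 * pi * (seq_len(radial) - 1L) / radial
  ring <- cbind(cos(th), sin(th))
  # rings: outer bottom, outer top, inner bottom, inner top
  V <- rbind(cbind(r_outer * ring, 0), cbind(r_outer * ring, 1),
             cbind(r_inner * ring, 0), cbind(r_inner * ring, 1))
  ob <- seq_len(radial); ot <- radial + ob
  ib <- 2L * radial + seq_len(radial); it <- 3L * radial + seq_len(radial)
  nxt <- c(seq_len(radial)[-1L], 1L)
  F <- rbind(
    cbind(ob, ob[nxt], ot[nxt]), cbind(ob, ot[nxt], ot),   # outer wall
    cbind(ib, it, it[nxt]), cbind(ib, it[nxt], ib[nxt]),   # inner wall
    cbind(ob, ib, ib[nxt]), cbind(ob, ib[nxt], ob[nxt]),   # bottom annulus
    cbind(ot, ot[nxt], it[nxt]), cbind(ot, it[nxt], it))   # top annulus
  m <- triangle_mesh(V, F)
  len <- vnorm(b - a)
  if (len <= 0) stop("zero-length tube")
  z <- c(0, 0, 1)
  v <- (b - a) / len
  R <- rotation_between(z, v)
  transform_mesh(m, rotation = R, translation = a, scale = c(1, 1, len))
}

#' @rdname unit_cylinder
#' @param center icosahedron center.
#' @param circumradius circumscribed sphere radius.
#' @export
icosahedron_mesh <- function(center = c(0, 0, 0), circumradius = 1) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(1 + phi^2) * circumradius
  V <- sweep(V, 2L, center, `+`)
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  triangle_mesh(V, F)
}

#' @rdname unit_cylinder
#' @param subdiv icosphere subdivision level.
#' @export
icosphere_mesh <- function(center = c(0, 0, 0), radius = 1, subdiv = 2L) {
  m <- icosahedron_mesh()
  for (s in seq_len(subdiv)) {
    V <- m$vertices
    F <- m$faces
    edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    mid_env <- new.env(parent = emptyenv())
    newV <- list()
    midpoint <- function(i, j) {
      k <- edge_key(i, j)
      idx <- mid_env[[k]]
      if (!is.null(idx)) return(idx)
      p <- unitize((V[i, ] + V[j, ]) / 2)
      newV[[length(newV) + 1L]] <<- p
      idx <- nrow(V) + length(newV)
      mid_env[[k]] <- idx
      idx
    }
    newF <- matrix(0L, 4L * nrow(F), 3L)
    for (r in seq_len(nrow(F))) {
      i <- F[r, 1L]; j <- F[r, 2L]; k <- F[r, 3L]
      a <- midpoint(i, j); b <- midpoint(j, k); c <- midpoint(k, i)
      newF[4L * r - 3L, ] <- c(i, a, c)
      newF[4L * r - 2L, ] <- c(j, b, a)
      newF[4L * r - 1L, ] <- c(k, c, b)
      newF[4L * r, ] <- c(a, b, c)
    }
    m <- triangle_mesh(rbind(V, do.call(rbind, newV)), newF)
    m$vertices <- t(apply(m$vertices, 1L, unitize))
  }
  m$vertices <- sweep(m$vertices * radius, 2L, center, `+`)
  m
}

#' @rdname unit_cylinder
#' @param apothem hexagon apothem (center to edge midpoint).
#' @param height prism height; base at z = 0, axis +z; flats face the
#'   x/rotated-by-60-degree directions (vertices at azimuths 30 + 60k deg).
#' @export
hexagonal_prism_mesh <- function(apothem, height, center = c(0, 0, 0)) {
  s <- 2 * apothem / sqrt(3)
  th <- pi / 6 + (0:5) * pi / 3
  ring <- cbind(s * cos(th), s * sin(th))
  V <- rbind(cbind(ring, 0), cbind(ring, height),
             c(0, 0, 0), c(0, 0, height))
  bot <- 1:6; top <- 7:12; cb <- 13L; ct <- 14L
  nxt <- c(2:6, 1L)
  F <- rbind(
    cbind(bot, bot[nxt], top[nxt]), cbind(bot, top[nxt], top),
    cbind(cb, bot[nxt], bot), cbind(ct, top, top[nxt]))
  transform_mesh(triangle_mesh(V, F), translation = center)
}

#' @rdname unit_cylinder
#' @param lo,hi opposite box corners.
#' @export
box_mesh <- function(lo, hi) {
  V <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  dimnames(V) <- NULL
  # corners indexed 1..8 with x fastest; 12 outward triangles
  F <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = lo
    c(5, 6, 7), c(6, 8, 7),   # z = hi
    c(1, 2, 5), c(2, 6, 5),   # y = lo
    c(3, 7, 4), c(4, 7, 8),   # y = hi
    c(1, 5, 3), c(3, 5, 7),   # x = lo
    c(2, 4, 6), c(4, 8, 6))   # x = hi
  triangle_mesh(V, F)
}

# rotation carrying unit vector `from` onto unit vector `to`
rotation_between <- function(from, to) {
  from <- unitize(from)
  to <- unitize(to)
  d <- sum(from * to)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) {
    u <- any_perpendicular(from)
    return(rodrigues_matrix(u, pi))
  }
  u <- unitize(vcross(from, to))
  rodrigues_matrix(u, acos(max(-1, min(1, d))))
}

# ---- mesh file I/O ----------------------------------------------------------

#' Read and write triangle meshes (OBJ, PLY, STL)
#'
#' Plain-text mesh exchange: Wavefront OBJ (`v`/`f` records), ASCII PLY and
#' ASCII STL. STL stores no connectivity, so vertices are merged by exact
#' coordinate match on read. Format chosen by file extension.
#'
#' @param mesh a [triangle_mesh()].
#' @param path file path ending in `.obj`, `.ply` or `.stl`.
#' @return `read_mesh()` returns a [triangle_mesh()]; `write_mesh()` returns
#'   `path` invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  V <- mesh$vertices
  F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  if (ext == "obj") {
    writeLines(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3]), con)
  } else if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(V)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(F)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L),
               con)
  } else if (ext == "stl") {
    writeLines("solid vasodose", con)
    for (r in seq_len(nrow(F))) {
      a <- V[F[r, 1L], ]; b <- V[F[r, 2L], ]; c <- V[F[r, 3L], ]
      n <- vcross(b - a, c - a)
      nn <- vnorm(n)
      if (nn > 0) n <- n / nn
      writeLines(c(sprintf("facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                   "  outer loop",
                   sprintf("    vertex %.9g %.9g %.9g", a[1], a[2], a[3]),
                   sprintf("    vertex %.9g %.9g %.9g", b[1], b[2], b[3]),
                   sprintf("    vertex %.9g %.9g %.9g", c[1], c[2], c[3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid vasodose", con)
  } else {
    stop("unsupported mesh format: ", ext)
  }
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "obj") {
    vl <- lines[startsWith(lines, "v ")]
    fl <- lines[startsWith(lines, "f ")]
    V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                               function(x) as.numeric(x[1:3])))
    F <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                               function(x) as.integer(sub("/.*", "", x[1:3]))))
    triangle_mesh(V, F)
  } else if (ext == "ply") {
    hdr_end <- which(lines == "end_header")[1L]
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)[1L]))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)[1L]))
    vl <- lines[hdr_end + seq_len(nv)]
    fl <- lines[hdr_end + nv + seq_len(nf)]
    V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                               function(x) as.numeric(x[1:3])))
    F <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"),
                               function(x) as.integer(x[2:4]) + 1L))
    triangle_mesh(V, F)
  } else if (ext == "stl") {
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                    function(x) as.numeric(x[2:4])))
    key <- apply(coords, 1L, paste, collapse = ",")
    uk <- !duplicated(key)
    V <- coords[uk, , drop = FALSE]
    idx <- match(key, key[uk])
    F <- matrix(idx, ncol = 3L, byrow = TRUE)
    triangle_mesh(V, F)
  } else {
    stop("unsupported mesh format: ", ext)
  }
}
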