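# Analytic solid primitives backing the lobule builder and the mesh-set
# voxelizer: each primitive knows its exact volume, an inside test / signed
# distance (exact zero set; the outside field uses a max-metric, which is all
# isosurfacing needs), a parametric watertight mesh, and its bounding box.
# A primitive may carry a `clip` box (axis-aligned), in which case its mesh
# is extracted implicitly.

prim_cylinder <- function(a, b, r) {
  list(type = "cylinder", a = as.numeric(a), b = as.numeric(b), r = r)
}

prim_tube <- function(a, b, r_inner, r_outer) {
  list(type = "tube", a = as.numeric(a), b = as.numeric(b),
       r_inner = r_inner, r_outer = r_outer)
}

prim_icosahedron <- function(center, circumradius, rot = diag(3)) {
  list(type = "icosahedron", center = as.numeric(center),
       r = circumradius, rot = rot)
}

prim_hexprism <- function(apothem, height, base = c(0, 0, 0)) {
  list(type = "hexprism", apothem = apothem, height = height,
       base = as.numeric(base))
}

prim_box <- function(lo, hi) {
  list(type = "box", lo = as.numeric(lo), hi = as.numeric(hi))
}

prim_translate <- function(prim, v) {
  v <- as.numeric(v)
  p <- prim
  if (!is.null(p$a)) p$a <- p$a + v
  if (!is.null(p$b)) p$b <- p$b + v
  if (!is.null(p$center)) p$center <- p$center + v
  if (!is.null(p$base)) p$base <- p$base + v
  if (!is.null(p$lo)) { p$lo <- p$lo + v; p$hi <- p$hi + v }
  if (!is.null(p$clip)) {
    p$clip$lo <- p$clip$lo + v
    p$clip$hi <- p$clip$hi + v
  }
  p
}

prim_volume <- function(prim) {
  if (!is.null(prim$clip)) {
    return(mesh_volume(prim_mesh(prim)))
  }
  switch(prim$type,
    cylinder = pi * prim$r^2 * vnorm(prim$b - prim$a),
    tube = pi * (prim$r_outer^2 - prim$r_inner^2) * vnorm(prim$b - prim$a),
    icosahedron = {
      edge <- 4 * prim$r / sqrt(10 + 2 * sqrt(5))
      5 / 12 * (3 + sqrt(5)) * edge^3
    },
    hexprism = 2 * sqrt(3) * prim$apothem^2 * prim$height,
    box = prod(prim$hi - prim$lo),
    stop("unknown primitive type: ", prim$type))
}

# face planes of the unit icosahedron (outward normals + common offset),
# computed lazily and cached
.ico_cache <- new.env(parent = emptyenv())
ico_planes <- function() {
  if (is.null(.ico_cache$normals)) {
    m <- icosahedron_mesh()
    normals <- t(vapply(seq_len(nrow(m$faces)), function(r) {
      a <- m$vertices[m$faces[r, 1L], ]
      b <- m$vertices[m$faces[r, 2L], ]
      c <- m$vertices[m$faces[r, 3L], ]
      unitize(vcross(b - a, c - a))
    }, numeric(3)))
    a <- m$vertices[m$faces[1L, 1L], ]
    .ico_cache$normals <- normals
    .ico_cache$offset <- sum(a * normals[1L, ])
  }
  list(normals = .ico_cache$normals, offset = .ico_cache$offset)
}

prim_sdf <- function(prim, P) {
  P <- matrix(as.numeric(P), ncol = 3L)
  d <- switch(prim$type,
    cylinder = {
      u <- prim$b - prim$a
      L <- vnorm(u)
      u <- u / L
      rel <- sweep(P, 2L, prim$a, `-`)
      s <- as.vector(rel %*% u)
      radial <- sqrt(pmax(rowSums(rel^2) - s^2, 0))
      pmax(radial - prim$r, -s, s - L)
    },
    tube = {
      u <- prim$b - prim$a
      L <- vnorm(u)
      u <- u / L
      rel <- sweep(P, 2L, prim$a, `-`)
      s <- as.vector(rel %*% u)
      radial <- sqrt(pmax(rowSums(rel^2) - s^2, 0))
      pmax(radial - prim$r_outer, prim$r_inner - radial, -s, s - L)
    },
    icosahedron = {
      ip <- ico_planes()
      rel <- sweep(P, 2L, prim$center, `-`) %*% prim$rot # world -> body
      dists <- rel %*% t(ip$normals) - ip$offset * prim$r
      apply(dists, 1L, max)
    },
    hexprism = {
      az <- (0:5) * pi / 3
      n <- cbind(cos(az), sin(az))
      rel2 <- sweep(P[, 1:2, drop = FALSE], 2L, prim$base[1:2], `-`)
      dh <- apply(rel2 %*% t(n) - prim$apothem, 1L, max)
      z <- P[, 3L] - prim$base[3L]
      pmax(dh, -z, z - prim$height)
    },
    box = {
      pmax(prim$lo[1] - P[, 1], P[, 1] - prim$hi[1],
           prim$lo[2] - P[, 2], P[, 2] - prim$hi[2],
           prim$lo[3] - P[, 3], P[, 3] - prim$hi[3])
    },
    stop("unknown primitive type: ", prim$type))
  if (!is.null(prim$clip)) {
    dbox <- pmax(prim$clip$lo[1] - P[, 1], P[, 1] - prim$clip$hi[1],
                 prim$clip$lo[2] - P[, 2], P[, 2] - prim$clip$hi[2],
                 prim$clip$lo[3] - P[, 3], P[, 3] - prim$clip$hi[3])
    d <- pmax(d, dbox)
  }
  d
}

prim_inside <- function(prim, P) prim_sdf(prim, P) < 0

prim_bbox <- function(prim) {
  bb <- switch(prim$type,
    cylinder = rbind(lo = pmin(prim$a, prim$b) - prim$r,
                     hi = pmax(prim$a, prim$b) + prim$r),
    tube = rbind(lo = pmin(prim$a, prim$b) - prim$r_outer,
                 hi = pmax(prim$a, prim$b) + prim$r_outer),
    icosahedron = rbind(lo = prim$center - prim$r, hi = prim$center + prim$r),
    hexprism = {
      s <- 2 * prim$apothem / sqrt(3)
      rbind(lo = prim$base - c(s, s, 0),
            hi = prim$base + c(s, s, prim$height))
    },
    box = rbind(lo = prim$lo, hi = prim$hi),
    stop("unknown primitive type: ", prim$type))
  if (!is.null(prim$clip)) {
    bb["lo", ] <- pmax(bb["lo", ], prim$clip$lo)
    bb["hi", ] <- pmin(bb["hi", ], prim$clip$hi)
  }
  bb
}

# watertight mesh of a primitive; clipped primitives are isosurfaced on a
# feature-sized local grid (cells capped to keep memory bounded)
prim_mesh <- function(prim, radial = 24L, clip_cells = 6L,
                      max_cells = 4e5) {
  if (is.null(prim$clip)) {
    return(switch(prim$type,
      cylinder = cylinder_mesh(prim$a, prim$b, prim$r, radial),
      tube = tube_mesh(prim$a, prim$b, prim$r_inner, prim$r_outer, radial),
      icosahedron = {
        m <- icosahedron_mesh(circumradius = prim$r)
        transform_mesh(m, rotation = prim$rot, translation = prim$center)
      },
      hexprism = hexagonal_prism_mesh(prim$apothem, prim$height, prim$base),
      box = box_mesh(prim$lo, prim$hi),
      stop("unknown primitive type: ", prim$type)))
  }
  if (prim$type == "tube") {
    # clipped tube = clipped outer cylinder with a clipped inner cylinder
    # cavity (faces flipped): signed volumes subtract, parity tests nest
    outer <- prim_cylinder(prim$a, prim$b, prim$r_outer)
    inner <- prim_cylinder(prim$a, prim$b, prim$r_inner)
    outer$clip <- prim$clip
    inner$clip <- prim$clip
    mo <- prim_mesh(outer, radial, clip_cells, max_cells)
    mi <- prim_mesh(inner, radial, clip_cells, max_cells)
    if (nrow(mi$faces)) mi$faces <- mi$faces[, c(1L, 3L, 2L)]
    return(concat_meshes(list(mo, mi)))
  }
  if (prim$type == "cylinder" &&
      abs(prim$a[1] - prim$b[1]) < 1e-12 &&
      abs(prim$a[2] - prim$b[2]) < 1e-12) {
    # z-aligned cylinder clipped by a box: exact convex extrusion
    z0 <- max(min(prim$a[3], prim$b[3]), prim$clip$lo[3])
    z1 <- min(max(prim$a[3], prim$b[3]), prim$clip$hi[3])
    if (z1 <= z0) return(empty_mesh())
    th <- 2 * pi * (seq_len(96L) - 1L) / 96L
    poly <- cbind(prim$a[1] + prim$r * cos(th), prim$a[2] + prim$r * sin(th))
    poly <- clip_polygon_rect(poly, prim$clip$lo[1:2], prim$clip$hi[1:2])
    if (is.null(poly) || nrow(poly) < 3L) return(empty_mesh())
    return(extrude_polygon(poly, z0, z1))
  }
  bb <- prim_bbox(prim)
  if (any(bb["hi", ] <= bb["lo", ])) return(empty_mesh())
  feature <- switch(prim$type,
    cylinder = prim$r,
    icosahedron = prim$r,
    hexprism = prim$apothem / 2,
    box = min(prim$hi - prim$lo) / 2,
    min(bb["hi", ] - bb["lo", ]) / 2)
  h <- feature / clip_cells
  pad <- 2 * h
  span <- bb["hi", ] - bb["lo", ] + 2 * pad
  ncell <- prod(pmax(2, ceiling(span / h)))
  if (ncell > max_cells) h <- h * (ncell / max_cells)^(1 / 3)
  isosurface_from_function(function(P) prim_sdf(prim, P),
                           bb["lo", ] - pad, bb["hi", ] + pad, rep(h, 3L))
}

# Sutherland-Hodgman clip of a convex CCW polygon against a rectangle
clip_polygon_rect <- function(poly, lo, hi) {
  clip_half <- function(P, keep, cross_t) {
    n <- nrow(P)
    if (n == 0L) return(P)
    out <- list()
    for (i in seq_len(n)) {
      cur <- P[i, ]
      prv <- P[if (i == 1L) n else i - 1L, ]
      cin <- keep(cur)
      pin <- keep(prv)
      if (cin) {
        if (!pin) out[[length(out) + 1L]] <- cross_t(prv, cur)
        out[[length(out) + 1L]] <- cur
      } else if (pin) {
        out[[length(out) + 1L]] <- cross_t(prv, cur)
      }
    }
    if (length(out) == 0L) return(poly[0, , drop = FALSE])
    do.call(rbind, out)
  }
  edges <- list(
    list(function(p) p[1] >= lo[1], 1L, lo[1]),
    list(function(p) p[1] <= hi[1], 1L, hi[1]),
    list(function(p) p[2] >= lo[2], 2L, lo[2]),
    list(function(p) p[2] <= hi[2], 2L, hi[2]))
  P <- poly
  for (e in edges) {
    ax <- e[[2]]
    val <- e[[3]]
    P <- clip_half(P, e[[1]], function(p1, p2) {
      t <- (val - p1[ax]) / (p2[ax] - p1[ax])
      p1 + t * (p2 - p1)
    })
    if (nrow(P) < 3L) return(NULL)
  }
  P
}

# watertight extrusion of a convex CCW polygon between two z planes
extrude_polygon <- function(poly, z0, z1) {
  n <- nrow(poly)
  ctr <- colMeans(poly)
  V <- rbind(cbind(poly, z0), cbind(poly, z1),
             c(ctr, z0), c(ctr, z1))
  bot <- seq_len(n)
  top <- n + bot
  cb <- 2L * n + 1L
  ct <- 2L * n + 2L
  nxt <- c(bot[-1L], 1L)
  F <- rbind(cbind(bot, bot[nxt], top[nxt]), cbind(bot, top[nxt], top),
             cbind(cb, bot[nxt], bot), cbind(ct, top, top[nxt]))
  triangle_mesh(V, F)
}
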