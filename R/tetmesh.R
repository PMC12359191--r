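#' Labeled tetrahedral mesh
#'
#' Node table (positions, mm), element table (four node ids plus an integer
#' region label) and a region catalogue mapping labels to names. The
#' transport and sampling substrate of the package.
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z`.
#' @param elements data.frame with columns `n1`..`n4` (node ids) and
#'   `region` (integer label).
#' @param regions named integer vector or named list: region label -> name
#'   (optional; labels default to their own names).
#' @return an object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, elements, regions = NULL) {
  stopifnot(all(c("id", "x", "y", "z") %in% names(nodes)),
            all(c("n1", "n2", "n3", "n4", "region") %in% names(elements)))
  ids <- nodes$id
  for (cc in c("n1", "n2", "n3", "n4")) {
    if (!all(elements[[cc]] %in% ids)) {
      stop("element references unknown node id in column ", cc)
    }
  }
  if (is.null(regions)) {
    labs <- sort(unique(elements$region))
    regions <- stats::setNames(as.list(paste0("region", labs)),
                               as.character(labs))
  }
  structure(list(nodes = nodes, elements = elements, regions = regions),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tetrahedra, %d region(s)\n",
              nrow(x$nodes), nrow(x$elements), length(x$regions)))
  invisible(x)
}

#' Tetrahedron volume
#'
#' Absolute (orientation-free) volume from the 4x4 homogeneous-coordinate
#' determinant, `V = |det| / 6`.
#'
#' @param A,B,C,D vertex positions (length-3 numeric).
#' @return volume (>= 0; 0 for coplanar points).
#' @export
tet_volume <- function(A, B, C, D) {
  M <- rbind(c(A, 1), c(B, 1), c(C, 1), c(D, 1))
  abs(det(M)) / 6
}

# vectorized volumes of all elements
element_volumes <- function(mesh) {
  P <- as.matrix(mesh$nodes[, c("x", "y", "z")])
  idx <- function(cc) match(mesh$elements[[cc]], mesh$nodes$id)
  a <- P[idx("n1"), , drop = FALSE]
  b <- P[idx("n2"), , drop = FALSE] - a
  c <- P[idx("n3"), , drop = FALSE] - a
  d <- P[idx("n4"), , drop = FALSE] - a
  abs(b[, 1] * (c[, 2] * d[, 3] - c[, 3] * d[, 2]) -
      b[, 2] * (c[, 1] * d[, 3] - c[, 3] * d[, 1]) +
      b[, 3] * (c[, 1] * d[, 2] - c[, 2] * d[, 1])) / 6
}

#' Per-region volumes of a tetrahedral mesh
#'
#' @param mesh a [tet_mesh()].
#' @return named numeric vector: region label -> summed element volume.
#' @export
region_volumes <- function(mesh) {
  v <- element_volumes(mesh)
  tapply(v, mesh$elements$region, sum)
}

#' Sample points uniformly from a mesh region
#'
#' Volume-proportional tetrahedron selection by acceptance/rejection
#' (element volumes normalized by the maximum volume in the region are the
#' acceptance thresholds against uniform deviates), then a uniform point
#' within the accepted tetrahedron from normalized barycentric weights
#' `delta_i = u_i / sum(u)` applied to the vertices. Deterministic per seed.
#'
#' A Walker alias-table fast path (`method = "alias"`) draws the tetrahedron
#' index in O(1); it is distribution-equivalent and kept behind the flag.
#'
#' @param mesh a [tet_mesh()].
#' @param region integer region label (or vector of labels).
#' @param n number of points.
#' @param seed integer seed.
#' @param method `"rejection"` (default, the reference procedure) or
#'   `"alias"`.
#' @return `n x 3` matrix of positions; attribute `tet_index` gives the row
#'   of the element table each point came from.
#' @export
sample_points <- function(mesh, region, n, seed = 1L,
                          method = c("rejection", "alias")) {
  method <- match.arg(method)
  sel <- which(mesh$elements$region %in% region)
  if (length(sel) == 0L) stop("region has no elements: ",
                              paste(region, collapse = ", "))
  vols <- element_volumes(mesh)[sel]
  if (sum(vols) <= 0) stop("region has zero total volume")
  with_seed(seed, {
    if (method == "rejection") {
      thresh <- vols / max(vols)
      picks <- integer(n)
      got <- 0L
      while (got < n) {
        m <- max(256L, 2L * (n - got))
        cand <- sample.int(length(sel), m, replace = TRUE)
        acc <- runif(m) <= thresh[cand]
        cand <- cand[acc]
        take <- min(length(cand), n - got)
        if (take > 0L) {
          picks[got + seq_len(take)] <- cand[seq_len(take)]
          got <- got + take
        }
      }
    } else {
      picks <- alias_sample(vols / sum(vols), n)
    }
    tet_rows <- sel[picks]
    P <- as.matrix(mesh$nodes[, c("x", "y", "z")])
    idx <- function(cc) match(mesh$elements[[cc]][tet_rows], mesh$nodes$id)
    A <- P[idx("n1"), , drop = FALSE]
    B <- P[idx("n2"), , drop = FALSE]
    C <- P[idx("n3"), , drop = FALSE]
    D <- P[idx("n4"), , drop = FALSE]
    # open-interval uniforms: sum(u) is never zero
    U <- matrix(runif(4L * n, min = .Machine$double.eps, max = 1), n, 4L)
    U <- U / rowSums(U)
    out <- U[, 1L] * A + U[, 2L] * B + U[, 3L] * C + U[, 4L] * D
    structure(out, tet_index = tet_rows, barycentric = U)
  })
}

# Walker alias method for categorical sampling
alias_sample <- function(prob, n) {
  k <- length(prob)
  prob <- prob / sum(prob)
  q <- prob * k
  alias <- integer(k)
  small <- which(q < 1)
  large <- which(q >= 1)
  qq <- q
  while (length(small) > 0L && length(large) > 0L) {
    s <- small[length(small)]; small <- small[-length(small)]
    l <- large[length(large)]
    alias[s] <- l
    qq[l] <- qq[l] - (1 - qq[s])
    if (qq[l] < 1) {
      large <- large[-length(large)]
      small <- c(small, l)
    }
  }
  cols <- sample.int(k, n, replace = TRUE)
  flips <- runif(n) >= qq[cols]
  ifelse(flips, alias[cols], cols)
}

# ---- TetGen-dialect I/O -----------------------------------------------------

#' Read and write TetGen node/ele file pairs
#'
#' TetGen text dialect: the `.node` file holds `<#points> <dim> <#attrs>
#' <#markers>` then one `id x y z` row per node; the `.ele` file holds
#' `<#tets> <nodes-per-tet> <#attrs>` then `id n1 n2 n3 n4 [region]` rows.
#' Both 1-based (default) and 0-based index dialects are handled via the
#' first listed node id. The element attribute column carries the region
#' label (absent = region 1).
#'
#' @param node_path,ele_path file paths.
#' @param mesh a [tet_mesh()] (writer).
#' @return reader: a [tet_mesh()]; writer: invisible paths.
#' @export
read_node_ele <- function(node_path, ele_path) {
  strip <- function(lines) {
    lines <- sub("#.*$", "", lines)
    which_keep <- nzchar(trimws(lines))
    list(lines = trimws(lines[which_keep]), lineno = which(which_keep))
  }
  nf <- strip(readLines(node_path))
  hdr <- as.numeric(strsplit(nf$lines[1L], "\\s+")[[1L]])
  n_nodes <- as.integer(hdr[1L])
  if (length(nf$lines) - 1L < n_nodes) {
    stop(sprintf("%s: header announces %d nodes but only %d rows present",
                 node_path, n_nodes, length(nf$lines) - 1L))
  }
  node_rows <- lapply(seq_len(n_nodes) + 1L, function(i) {
    v <- as.numeric(strsplit(nf$lines[i], "\\s+")[[1L]])
    if (length(v) < 4L || anyNA(v[1:4])) {
      stop(sprintf("%s line %d: malformed node row", node_path, nf$lineno[i]))
    }
    v[1:4]
  })
  nd <- do.call(rbind, node_rows)
  zero_based <- nd[1L, 1L] == 0
  nodes <- data.frame(id = as.integer(nd[, 1L]) + if (zero_based) 1L else 0L,
                      x = nd[, 2L], y = nd[, 3L], z = nd[, 4L])

  ef <- strip(readLines(ele_path))
  ehdr <- as.numeric(strsplit(ef$lines[1L], "\\s+")[[1L]])
  n_ele <- as.integer(ehdr[1L])
  n_attr <- if (length(ehdr) >= 3L) as.integer(ehdr[3L]) else 0L
  if (length(ef$lines) - 1L < n_ele) {
    stop(sprintf("%s: header announces %d elements but only %d rows present",
                 ele_path, n_ele, length(ef$lines) - 1L))
  }
  ele_rows <- lapply(seq_len(n_ele) + 1L, function(i) {
    v <- as.numeric(strsplit(ef$lines[i], "\\s+")[[1L]])
    if (length(v) < 5L || anyNA(v[1:5])) {
      stop(sprintf("%s line %d: malformed element row", ele_path,
                   ef$lineno[i]))
    }
    v
  })
  el <- do.call(rbind, lapply(ele_rows, function(v) {
    c(v[2:5], if (n_attr >= 1L && length(v) >= 6L) v[6L] else 1)
  }))
  off <- if (zero_based) 1L else 0L
  elements <- data.frame(n1 = as.integer(el[, 1L]) + off,
                         n2 = as.integer(el[, 2L]) + off,
                         n3 = as.integer(el[, 3L]) + off,
                         n4 = as.integer(el[, 4L]) + off,
                         region = as.integer(el[, 5L]))
  bad <- !(c(elements$n1, elements$n2, elements$n3, elements$n4) %in%
           nodes$id)
  if (any(bad)) {
    row <- ((which(bad)[1L] - 1L) %% nrow(elements)) + 1L
    stop(sprintf("%s line %d: element references a missing node", ele_path,
                 ef$lineno[row + 1L]))
  }
  tet_mesh(nodes, elements)
}

#' @rdname read_node_ele
#' @export
write_node_ele <- function(mesh, node_path, ele_path) {
  nd <- mesh$nodes
  con <- file(node_path, "w")
  writeLines(sprintf("%d 3 0 0", nrow(nd)), con)
  writeLines(sprintf("%d %.12g %.12g %.12g", nd$id, nd$x, nd$y, nd$z), con)
  close(con)
  el <- mesh$elements
  con <- file(ele_path, "w")
  writeLines(sprintf("%d 4 1", nrow(el)), con)
  writeLines(sprintf("%d %d %d %d %d %d", seq_len(nrow(el)), el$n1, el$n2,
                     el$n3, el$n4, el$region), con)
  close(con)
  invisible(c(node_path, ele_path))
}

#' Write sampled points as whitespace-separated text
#'
#' Dump-file analogue: one `x y z` row per sampled point.
#'
#' @param points `n x 3` matrix.
#' @param path output path.
#' @export
write_point_dump <- function(points, path) {
  writeLines(sprintf("%.12g %.12g %.12g", points[, 1], points[, 2],
                     points[, 3]), path)
  invisible(path)
}

# ---- helper geometry: tetrahedralized box -----------------------------------

#' Tetrahedralize an axis-aligned box
#'
#' Splits a box on a regular grid into 6 tetrahedra per cell (the same
#' decomposition the isosurfacer uses). Used to build exactly-known test and
#' demonstration geometries; region labels can be assigned afterwards from
#' element centroids.
#'
#' @param lo,hi box corners.
#' @param n integer cells per axis (scalar or length 3).
#' @return a [tet_mesh()] (all elements region 1).
#' @export
box_tet_mesh <- function(lo, hi, n = 1L) {
  n <- rep(as.integer(n), length.out = 3L)
  xs <- seq(lo[1], hi[1], length.out = n[1] + 1L)
  ys <- seq(lo[2], hi[2], length.out = n[2] + 1L)
  zs <- seq(lo[3], hi[3], length.out = n[3] + 1L)
  gid <- function(i, j, k) i + (n[1] + 1L) * ((j - 1L) + (n[2] + 1L) *
                                                (k - 1L))
  nodes <- expand.grid(x = xs, y = ys, z = zs)
  nodes <- data.frame(id = seq_len(nrow(nodes)), x = nodes$x, y = nodes$y,
                      z = nodes$z)
  paths <- rbind(c(0L, 1L, 3L, 7L), c(0L, 1L, 5L, 7L), c(0L, 2L, 3L, 7L),
                 c(0L, 2L, 6L, 7L), c(0L, 4L, 5L, 7L), c(0L, 4L, 6L, 7L))
  els <- list()
  for (k in seq_len(n[3])) {
    for (j in seq_len(n[2])) {
      for (i in seq_len(n[1])) {
        corner <- vapply(0:7, function(cc) {
          gid(i + bitwAnd(cc, 1L),
              j + bitwAnd(bitwShiftR(cc, 1L), 1L),
              k + bitwAnd(bitwShiftR(cc, 2L), 1L))
        }, integer(1))
        for (t in seq_len(6L)) {
          els[[length(els) + 1L]] <- corner[paths[t, ] + 1L]
        }
      }
    }
  }
  em <- do.call(rbind, els)
  tet_mesh(nodes, data.frame(n1 = em[, 1L], n2 = em[, 2L], n3 = em[, 3L],
                             n4 = em[, 4L], region = 1L))
}

#' Centroids of all elements
#'
#' @param mesh a [tet_mesh()].
#' @return `n_elements x 3` matrix.
#' @export
element_centroids <- function(mesh) {
  P <- as.matrix(mesh$nodes[, c("x", "y", "z")])
  idx <- function(cc) match(mesh$elements[[cc]], mesh$nodes$id)
  (P[idx("n1"), , drop = FALSE] + P[idx("n2"), , drop = FALSE] +
   P[idx("n3"), , drop = FALSE] + P[idx("n4"), , drop = FALSE]) / 4
}
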