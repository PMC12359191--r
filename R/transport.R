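#' Particle specification for the toy transport
#'
#' Describes a monoenergetic source particle. Charged kinds (`alpha`,
#' `electron`) carry a CSDA range-energy table for tissue; photons carry a
#' mass attenuation table. Bundled reference tables are used by default (see
#' [build_range_table()] and [build_attenuation_table()]).
#'
#' @param kind `"alpha"`, `"electron"` or `"photon"`.
#' @param energy_MeV particle energy in MeV.
#' @param range_table optional range table from [build_range_table()].
#' @param attenuation optional attenuation table from
#'   [build_attenuation_table()].
#' @return an object of class `particle_spec`.
#' @export
particle_spec <- function(kind = c("alpha", "electron", "photon"),
                          energy_MeV, range_table = NULL,
                          attenuation = NULL) {
  kind <- match.arg(kind)
  stopifnot_scalar_num(energy_MeV, "energy_MeV", positive = TRUE)
  if (kind %in% c("alpha", "electron") && is.null(range_table)) {
    range_table <- build_range_table(kind)
  }
  if (kind == "photon" && is.null(attenuation)) {
    attenuation <- build_attenuation_table()
  }
  structure(list(kind = kind, energy_MeV = energy_MeV,
                 range_table = range_table, attenuation = attenuation),
            class = "particle_spec")
}

#' CSDA range-energy table for tissue
#'
#' Builds a monotone range(energy) lookup from the bundled transcription of
#' published CSDA ranges (printed values are rounded to two significant
#' figures, so isotonic regression enforces monotonicity before the log-log
#' monotone-cubic interpolation). Queries outside the knot span extrapolate
#' log-log linearly with the boundary slope.
#'
#' @param particle `"alpha"` or `"electron"`.
#' @param path optional CSV (`particle,energy_MeV,range_mm`) overriding the
#'   bundled table.
#' @return list with knots and a `range_mm(energy_MeV)` function.
#' @export
build_range_table <- function(particle = c("alpha", "electron"),
                              path = NULL) {
  particle <- match.arg(particle)
  path <- path %||% vasodose_extdata("csda_ranges_tissue.csv")
  d <- utils::read.csv(path, comment.char = "#")
  d <- d[d$particle == particle, ]
  if (nrow(d) < 2L) stop("range table needs at least 2 knots")
  d <- d[order(d$energy_MeV), ]
  d <- stats::aggregate(range_mm ~ energy_MeV, data = d, FUN = mean)
  iso <- stats::isoreg(d$energy_MeV, d$range_mm)
  r <- iso$yf
  # strictly increasing for the interpolator
  for (i in seq_along(r)[-1L]) {
    if (r[i] <= r[i - 1L]) r[i] <- r[i - 1L] * (1 + 1e-9)
  }
  le <- log10(d$energy_MeV)
  lr <- log10(r)
  f <- stats::splinefun(le, lr, method = "monoH.FC")
  slope_lo <- (lr[2L] - lr[1L]) / (le[2L] - le[1L])
  k <- length(le)
  slope_hi <- (lr[k] - lr[k - 1L]) / (le[k] - le[k - 1L])
  range_fun <- function(energy_MeV) {
    x <- log10(energy_MeV)
    y <- ifelse(x < le[1L], lr[1L] + slope_lo * (x - le[1L]),
         ifelse(x > le[k], lr[k] + slope_hi * (x - le[k]), f(x)))
    10^y
  }
  list(particle = particle, energy_MeV = d$energy_MeV, range_mm = r,
       range_mm_of = range_fun)
}

#' Photon attenuation table
#'
#' Linear attenuation lookup (per mm) from the bundled water mass
#' attenuation coefficients scaled by material density, interpolated
#' monotone-cubically on log-log axes.
#'
#' @param density material density in g/cm^3 (default 1.0).
#' @param path optional CSV (`energy_MeV,mu_over_rho_cm2_g`).
#' @return list with knots and a `mu_mm(energy_MeV)` function.
#' @export
build_attenuation_table <- function(density = 1.0, path = NULL) {
  path <- path %||% vasodose_extdata("photon_attenuation_water.csv")
  d <- utils::read.csv(path, comment.char = "#")
  le <- log10(d$energy_MeV)
  lm <- log10(d$mu_over_rho_cm2_g)
  f <- stats::splinefun(le, lm, method = "monoH.FC")
  k <- length(le)
  mu_fun <- function(energy_MeV, dens = density) {
    x <- pmin(pmax(log10(energy_MeV), le[1L]), le[k])
    10^f(x) * dens / 10 # cm^2/g * g/cm^3 = 1/cm -> 1/mm
  }
  list(energy_MeV = d$energy_MeV, mu_over_rho = d$mu_over_rho_cm2_g,
       mu_mm_of = mu_fun)
}

#' Transport configuration
#'
#' @param n number of primary histories (>= 1).
#' @param seed integer seed.
#' @param boundary_mode `"escape"` (energy leaving the grid bounding box is
#'   lost) or `"reflective"` (position and direction mirrored at the box,
#'   representing an infinitely tiled geometry).
#' @param resolution voxel count along the largest extent when a tetrahedral
#'   mesh is voxelized for region lookup (default 64).
#' @param source_region region name(s) or label(s) the source is uniformly
#'   distributed in.
#' @return an object of class `transport_config`.
#' @export
transport_config <- function(n = 10000L, seed = 1L,
                             boundary_mode = c("escape", "reflective"),
                             resolution = 64L, source_region) {
  boundary_mode <- match.arg(boundary_mode)
  if (n < 1L) stop("n must be >= 1")
  structure(list(n = as.integer(n), seed = seed,
                 boundary_mode = boundary_mode,
                 resolution = as.integer(resolution),
                 source_region = source_region),
            class = "transport_config")
}

#' Labeled voxel grid
#'
#' Region-lookup substrate of the toy transport: an integer 3D array of
#' region labels (0 = void/outside), grid origin and isotropic-or-not voxel
#' spacing, region names for labels `1..K`, and per-region densities
#' (g/cm^3, used to scale photon attenuation).
#'
#' @param labels integer 3D array.
#' @param origin grid corner (position of the lowest voxel corner), mm.
#' @param spacing voxel edge lengths (scalar or length 3), mm.
#' @param region_names character vector naming labels `1..K`.
#' @param densities per-region densities (default 1.0).
#' @return an object of class `label_grid`.
#' @export
label_grid <- function(labels, origin, spacing, region_names,
                       densities = NULL) {
  stopifnot(length(dim(labels)) == 3L)
  storage.mode(labels) <- "integer"
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  k <- length(region_names)
  if (max(labels) > k) stop("labels exceed the number of region names")
  densities <- densities %||% rep(1.0, k)
  structure(list(labels = labels, origin = as.numeric(origin),
                 spacing = spacing, region_names = region_names,
                 densities = rep(densities, length.out = k)),
            class = "label_grid")
}

#' @export
print.label_grid <- function(x, ...) {
  cat(sprintf("label_grid: %s voxels, spacing %s mm, regions: %s\n",
              paste(dim(x$labels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "/"),
              paste(x$region_names, collapse = ", ")))
  invisible(x)
}

#' Region volumes of a label grid
#'
#' @param grid a [label_grid()].
#' @return named numeric vector of voxel-counted volumes (mm^3) per region.
#' @export
label_grid_volumes <- function(grid) {
  vox <- prod(grid$spacing)
  counts <- tabulate(grid$labels, nbins = length(grid$region_names))
  stats::setNames(counts * vox, grid$region_names)
}

#' Voxelize a labeled tetrahedral mesh
#'
#' Rasterizes each element onto voxel centers (region attribute wins by
#' element order). Region labels are renumbered densely; their names come
#' from the mesh's region catalogue.
#'
#' @param mesh a [tet_mesh()].
#' @param resolution voxels along the largest bounding-box extent.
#' @return a [label_grid()].
#' @export
voxelize_tetmesh <- function(mesh, resolution = 64L) {
  P <- as.matrix(mesh$nodes[, c("x", "y", "z")])
  lo <- apply(P, 2L, min)
  hi <- apply(P, 2L, max)
  h <- max(hi - lo) / resolution
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / h)))
  sp <- (hi - lo) / dims
  labs <- sort(unique(mesh$elements$region))
  dense <- match(mesh$elements$region, labs)
  idx <- function(cc) match(mesh$elements[[cc]], mesh$nodes$id)
  elems <- cbind(idx("n1"), idx("n2"), idx("n3"), idx("n4"))
  centers0 <- lo + sp / 2
  arr <- .rasterize_tets(P, elems, as.integer(dense), dims, centers0, sp)
  dim(arr) <- dims
  names_out <- vapply(as.character(labs), function(l) {
    nm <- mesh$regions[[l]]
    if (is.null(nm)) paste0("region", l) else nm
  }, character(1))
  label_grid(arr, origin = lo, spacing = sp, region_names = unname(names_out))
}

#' Build a label grid from a labeling function
#'
#' Evaluates `label_fun` (mapping an `n x 3` point matrix to integer labels)
#' at voxel centers, chunked by z-slab.
#'
#' @param label_fun vectorized labeling function.
#' @param lo,hi grid bounding box corners.
#' @param spacing voxel edge (scalar).
#' @param region_names names of labels `1..K`.
#' @param densities optional per-region densities.
#' @return a [label_grid()].
#' @export
label_grid_from_function <- function(label_fun, lo, hi, spacing,
                                     region_names, densities = NULL) {
  dims <- pmax(1L, as.integer(round((hi - lo) / spacing)))
  sp <- (hi - lo) / dims
  xs <- lo[1] + sp[1] * (seq_len(dims[1]) - 0.5)
  ys <- lo[2] + sp[2] * (seq_len(dims[2]) - 0.5)
  zs <- lo[3] + sp[3] * (seq_len(dims[3]) - 0.5)
  arr <- integer(prod(dims))
  slab <- as.matrix(expand.grid(x = xs, y = ys))
  np <- nrow(slab)
  for (k in seq_len(dims[3])) {
    P <- cbind(slab, zs[k])
    arr[(k - 1L) * np + seq_len(np)] <- as.integer(label_fun(P))
  }
  dim(arr) <- dims
  label_grid(arr, origin = lo, spacing = sp, region_names = region_names,
             densities = densities)
}

# uniform source points within voxels carrying the given labels
sample_grid_points <- function(grid, labels, n, seed) {
  sel <- which(grid$labels %in% labels)
  if (length(sel) == 0L) stop("no voxels carry the source label(s)")
  d <- dim(grid$labels)
  with_seed(seed, {
    pick <- sel[sample.int(length(sel), n, replace = TRUE)]
    k <- (pick - 1L) %/% (d[1] * d[2])
    j <- ((pick - 1L) %/% d[1]) %% d[2]
    i <- (pick - 1L) %% d[1]
    cbind(grid$origin[1] + (i + runif(n)) * grid$spacing[1],
          grid$origin[2] + (j + runif(n)) * grid$spacing[2],
          grid$origin[3] + (k + runif(n)) * grid$spacing[3])
  })
}

resolve_region_labels <- function(grid, region) {
  if (is.character(region)) {
    lab <- match(region, grid$region_names)
    if (anyNA(lab)) {
      stop("unknown region(s): ",
           paste(region[is.na(lab)], collapse = ", "))
    }
    lab
  } else {
    as.integer(region)
  }
}

#' Run the toy particle transport
#'
#' Simplified desk-scale transport producing absorbed-fraction estimates:
#' charged particles (alpha, electron) deposit energy uniformly along a
#' single straight track of length equal to their CSDA range, apportioned to
#' regions by exact ray/voxel traversal; photons fly exponential free paths
#' (Woodcock tracking against per-region attenuation) and deposit their full
#' energy at the first interaction point. The grid bounding box either
#' reflects particles (micro mode: the geometry tiles all space) or lets
#' energy escape (macro mode). Deterministic per seed.
#'
#' This is a surrogate for production Monte Carlo codes: it validates the
#' multiscale coupling arithmetic, not transport physics. Externally
#' computed absorbed-fraction tables can be imported with [read_af_table()]
#' instead.
#'
#' @param geometry a [label_grid()], [tet_mesh()] (voxelized at
#'   `cfg$resolution`) or [labeled_mesh_set()] (voxelized from its
#'   primitives).
#' @param source a [particle_spec()].
#' @param cfg a [transport_config()] (its `source_region` names the source).
#' @param source_points optional `n x 3` matrix of source positions
#'   overriding the uniform-in-region sampling (e.g. a point source repeated
#'   n times).
#' @return an `energy_deposit_tally`: data.frame of per-region deposits
#'   (MeV) and relative statistical errors, with attributes `emitted_MeV`,
#'   `histories`, `boundary_mode`, `source_region`, `particle`,
#'   `energy_MeV`.
#' @export
run_transport <- function(geometry, source, cfg, source_points = NULL) {
  stopifnot(inherits(source, "particle_spec"),
            inherits(cfg, "transport_config"))
  grid <- if (inherits(geometry, "label_grid")) {
    geometry
  } else if (inherits(geometry, "tet_mesh")) {
    voxelize_tetmesh(geometry, cfg$resolution)
  } else if (inherits(geometry, "labeled_mesh_set")) {
    voxelize_mesh_set(geometry, cfg$resolution)
  } else {
    stop("geometry must be a label_grid, tet_mesh or labeled_mesh_set")
  }
  src_lab <- resolve_region_labels(grid, cfg$source_region)
  if (!is.null(source_points)) {
    starts <- matrix(as.numeric(source_points), ncol = 3L)
    if (nrow(starts) != cfg$n) {
      starts <- starts[rep_len(seq_len(nrow(starts)), cfg$n), , drop = FALSE]
    }
  } else if (inherits(geometry, "tet_mesh")) {
    # barycentric sampling on the exact tetrahedra
    labs <- sort(unique(geometry$elements$region))
    region_raw <- labs[src_lab]
    starts <- sample_points(geometry, region_raw, cfg$n, seed = cfg$seed)
  } else {
    starts <- sample_grid_points(grid, src_lab, cfg$n, seed = cfg$seed)
  }
  reflective <- cfg$boundary_mode == "reflective"
  nreg <- length(grid$region_names)
  if (source$kind %in% c("alpha", "electron")) {
    range_mm <- source$range_table$range_mm_of(source$energy_MeV)
    res <- .charged_transport(as.integer(grid$labels), dim(grid$labels),
                              grid$origin, grid$spacing, starts,
                              source$energy_MeV, range_mm, reflective, nreg,
                              as.double(cfg$seed %% 2^31 + 17))
  } else {
    mu <- source$attenuation$mu_mm_of(source$energy_MeV) *
      grid$densities / 1.0
    res <- .photon_transport(as.integer(grid$labels), dim(grid$labels),
                             grid$origin, grid$spacing, starts,
                             source$energy_MeV, c(0, mu), reflective,
                             as.double(cfg$seed %% 2^31 + 17))
  }
  tally <- data.frame(region = c("void", grid$region_names),
                      deposit_MeV = res$deposit_MeV,
                      rel_err = res$rel_err)
  structure(tally, class = c("energy_deposit_tally", "data.frame"),
            emitted_MeV = res$emitted_MeV, histories = res$histories,
            boundary_mode = cfg$boundary_mode,
            source_region = if (is.character(cfg$source_region))
              paste(cfg$source_region, collapse = "+") else
              paste(grid$region_names[src_lab], collapse = "+"),
            particle = source$kind, energy_MeV = source$energy_MeV)
}

#' Group a tally into absorbed fractions
#'
#' Maps tallied regions onto source-class groups (e.g. blood / parenchyma)
#' and returns absorbed-fraction rows `AF(group <- source) = grouped deposit
#' / emitted energy`, with relative errors combined in quadrature.
#'
#' @param tally an `energy_deposit_tally` from [run_transport()].
#' @param grouping named character vector: region name -> group name; must
#'   cover every tallied region with nonzero deposit (besides `void`).
#' @param scale scale tag for the rows (`"macro"` or `"micro"`).
#' @return data.frame with the absorbed-fraction schema (`scale`, `source`,
#'   `target`, `particle`, `energy_MeV`, `af`, `rel_err`).
#' @export
estimate_absorbed_fractions <- function(tally, grouping, scale = "macro") {
  emitted <- attr(tally, "emitted_MeV")
  if (is.null(emitted) || emitted <= 0) stop("tally has no emitted energy")
  regs <- setdiff(tally$region, "void")
  uncovered <- setdiff(regs, names(grouping))
  if (length(uncovered)) {
    stop("grouping does not cover region(s): ",
         paste(uncovered, collapse = ", "))
  }
  rows <- lapply(unique(grouping), function(g) {
    members <- names(grouping)[grouping == g]
    sub <- tally[tally$region %in% members, , drop = FALSE]
    dep <- sum(sub$deposit_MeV)
    re <- if (dep > 0) {
      sqrt(sum((sub$deposit_MeV * sub$rel_err)^2)) / dep
    } else 0
    data.frame(scale = scale, source = attr(tally, "source_region"),
               target = g, particle = attr(tally, "particle"),
               energy_MeV = attr(tally, "energy_MeV"),
               af = dep / emitted, rel_err = re)
  })
  do.call(rbind, rows)
}

#' Absorbed-fraction table I/O
#'
#' The CSV interchange schema consumed by the coupling module (and the
#' import path for externally computed Monte Carlo results): columns
#' `scale, source, target, particle, energy_MeV, af, rel_err`.
#'
#' @param af data.frame in the schema.
#' @param path file path.
#' @return reader returns the validated data.frame; writer returns `path`
#'   invisibly.
#' @export
write_af_table <- function(af, path) {
  utils::write.csv(validate_af_table(af), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_af_table
#' @export
read_af_table <- function(path) {
  validate_af_table(utils::read.csv(path))
}

validate_af_table <- function(af) {
  need <- c("scale", "source", "target", "particle", "energy_MeV", "af",
            "rel_err")
  miss <- setdiff(need, names(af))
  if (length(miss)) {
    stop("absorbed-fraction table lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  if (any(af$af < -1e-12 | af$af > 1 + 1e-9)) {
    stop("absorbed fractions must lie in [0, 1]")
  }
  af[need]
}
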