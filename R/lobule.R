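#' Labeled mesh set
#'
#' A named collection of watertight component meshes (one per lobule tissue
#' component), their densities, the analytic primitives they were built from
#' (used for exact volumes, voxelization and cropping), the enclosing prism
#' and an optional fill component whose volume is the prism minus all other
#' components.
#'
#' @param meshes named list of [triangle_mesh()] objects.
#' @param densities named numeric vector (g/cm^3) per component.
#' @param primitives named list of primitive lists (internal representation).
#' @param prism primitive describing the enclosing prism/box.
#' @param fill_component name of the fill component (mesh = the prism; its
#'   volume is computed by subtraction), or `NULL`.
#' @return an object of class `labeled_mesh_set`.
#' @export
labeled_mesh_set <- function(meshes, densities, primitives = NULL,
                             prism = NULL, fill_component = NULL) {
  stopifnot(is.list(meshes), !is.null(names(meshes)))
  structure(list(meshes = meshes,
                 densities = densities[names(meshes)],
                 primitives = primitives, prism = prism,
                 fill_component = fill_component),
            class = "labeled_mesh_set")
}

#' @export
print.labeled_mesh_set <- function(x, ...) {
  cat(sprintf("labeled_mesh_set: %d component(s): %s\n", length(x$meshes),
              paste(names(x$meshes), collapse = ", ")))
  invisible(x)
}

#' Component volumes of a labeled mesh set
#'
#' Exact primitive volumes where available (falling back to mesh volumes);
#' the fill component's volume is the prism volume minus all others.
#'
#' @param set a [labeled_mesh_set()].
#' @return named numeric vector of volumes.
#' @export
mesh_set_volumes <- function(set) {
  out <- vapply(names(set$meshes), function(nm) {
    if (!is.null(set$fill_component) && nm == set$fill_component)

      return(NA_real_)
    prims <- set$primitives[[nm]]
    if (!is.null(prims)) {
      sum(vapply(prims, prim_volume, numeric(1)))
    } else {
      mesh_volume(set$meshes[[nm]])
    }
  }, numeric(1))
  # Kupffer cells sit inside the sinusoid lumina: the blood volume is the
  # lumen minus the cells
  if (all(c("sinusoids", "kupffer_cells") %in% names(out))) {
    out["sinusoids"] <- out["sinusoids"] - out["kupffer_cells"]
  }
  if (!is.null(set$fill_component)) {
    total <- prim_volume(set$prism)
    out[set$fill_component] <- total - sum(out, na.rm = TRUE)
  }
  out
}

#' Default densities of the lobule tissue components
#'
#' Whole-blood compartments and sinusoids at 1.060, bile/interstitial fluids
#' at 1.000, cellular components at 1.068 g/cm^3 (the published material
#' table).
#'
#' @return named numeric vector over the nine components.
#' @export
lobule_component_densities <- function() {
  c(central_vein = 1.060, portal_arteries = 1.060, portal_veins = 1.060,
    bile_ducts = 1.000, bile_canaliculi = 1.000, sinusoids = 1.060,
    space_of_disse = 1.000, kupffer_cells = 1.068, hepatocytes = 1.068)
}

#' Material assignment of the lobule components
#'
#' Maps each component to a bundled material name. Under the default
#' `"text"` rule the blood-containing compartments (central vein, portal
#' arteries, portal veins, sinusoids) carry whole blood and the bile- and
#' interstitial-fluid compartments carry the plasma/lymph material. The
#' `"table"` rule reproduces the published material table verbatim, where
#' the sinusoid row carries the plasma/lymph composition and bile canaliculi
#' carry blood; both assignments are supported because the two sources
#' disagree.
#'
#' @param rule `"text"` (default) or `"table"`.
#' @return named character vector: component -> material name for
#'   [reference_composition()].
#' @export
lobule_component_materials <- function(rule = c("text", "table")) {
  rule <- match.arg(rule)
  base <- c(central_vein = "icrp_blood", portal_arteries = "icrp_blood",
            portal_veins = "icrp_blood", bile_ducts = "plasma_lymph",
            bile_canaliculi = "plasma_lymph", sinusoids = "icrp_blood",
            space_of_disse = "plasma_lymph", kupffer_cells = "cell_material",
            hepatocytes = "cell_material")
  if (rule == "table") {
    base[["sinusoids"]] <- "plasma_lymph"
    base[["bile_canaliculi"]] <- "icrp_blood"
  }
  base
}

#' Lobule build specification
#'
#' Geometry of the stylized hexagonal-prism lobule. The sinusoid diameter
#' defaults to 16 um; the remaining dimensions default to values on the
#' scale of the classical stylized lobule lineage (center-to-vertex about
#' 0.5 mm) and are exposed here rather than fixed, since no single
#' authoritative value exists. Component radii (central vein, portal vessels,
#' Disse thickness) are not free: they are solved from the target mass
#' fractions.
#'
#' @param apothem_um hexagon apothem (center to edge midpoint), um.
#' @param height_um prism height, um.
#' @param sinusoid_diameter_um sinusoid lumen diameter (default 16).
#' @param target_fractions a [lobule_mass_fractions()] (defaults to the
#'   bundled reference values).
#' @param densities named densities per component (g/cm^3).
#' @param kupffer_circumradius_um icosahedral Kupffer cell circumradius;
#'   must be smaller than the sinusoid radius so cells fit in the lumen.
#' @param canaliculus_radius_um bile canaliculus radius (oversized relative
#'   to anatomy for meshability; the mass fraction, not the caliber, is the
#'   constrained quantity).
#' @param radial_segments cylinder tessellation.
#' @param seed integer seed (drives Kupffer cell placement).
#' @return an object of class `lobule_spec`.
#' @export
lobule_spec <- function(apothem_um = 433, height_um = 800,
                        sinusoid_diameter_um = 16,
                        target_fractions = reference_lobule_fractions(),
                        densities = lobule_component_densities(),
                        kupffer_circumradius_um = 7,
                        canaliculus_radius_um = 4,
                        radial_segments = 16L, seed = 1L) {
  if (sinusoid_diameter_um <= 0) stop("sinusoid diameter must be > 0")
  stopifnot(inherits(target_fractions, "lobule_mass_fractions"))
  if (kupffer_circumradius_um >= sinusoid_diameter_um / 2) {
    stop("Kupffer circumradius must be smaller than the sinusoid radius")
  }
  structure(list(apothem_um = apothem_um, height_um = height_um,
                 sinusoid_diameter_um = sinusoid_diameter_um,
                 target_fractions = target_fractions, densities = densities,
                 kupffer_circumradius_um = kupffer_circumradius_um,
                 canaliculus_radius_um = canaliculus_radius_um,
                 radial_segments = as.integer(radial_segments), seed = seed),
            class = "lobule_spec")
}

# hexagon boundary radius at azimuth phi (flats face azimuths 0, 60, ...)
hex_boundary_radius <- function(apothem, phi) {
  # angular distance to the nearest flat normal (flats face 0, 60, ... deg)
  f <- 30 - abs(((phi * 180 / pi) %% 60) - 30)
  apothem / cos(f * pi / 180)
}

# Radial fan slot plan: mirror-symmetric azimuth tiers (counts are multiples
# of 6, aligned with azimuth 0) with start radii chosen so that neighboring
# slots at the same z keep a positive gap. Returns angle/start pairs.
fan_slots <- function(half_width, r_start, apothem, gap = 1.5,
                      tier_cutoff = 0.7) {
  w <- half_width + gap / 2
  n0 <- 6L * max(1L, floor(pi / asin(min(0.999, w / r_start)) / 6))
  slots <- data.frame(angle = 2 * pi * (seq_len(n0) - 1L) / n0,
                      r_start = r_start)
  delta <- 2 * pi / n0
  repeat {
    delta <- delta / 2
    rk <- w / sin(delta / 2)
    if (rk > tier_cutoff * apothem) break
    n_prev <- nrow(slots)
    new_angles <- sort(unique(slots$angle))
    mid <- new_angles + diff(c(new_angles, 2 * pi + new_angles[1L]))[
      seq_along(new_angles)] / 2
    slots <- rbind(slots, data.frame(angle = mid, r_start = rk))
    if (nrow(slots) > 4096L || n_prev == nrow(slots)) break
  }
  slots
}

# shorten a radial 2D ray against circular obstacles (triad vessels)
limit_by_obstacles <- function(angle, r_end, obstacles, clearance) {
  u <- c(cos(angle), sin(angle))
  for (ob in obstacles) {
    thr <- ob$r + clearance
    along <- sum(ob$c * u)
    perp <- abs(ob$c[1] * u[2] - ob$c[2] * u[1])
    if (along > 0 && perp < thr) {
      r_end <- min(r_end, along - sqrt(thr^2 - perp^2) - 0.5)
    }
  }
  r_end
}

# symmetric z positions: n rows centered on h/2
symmetric_rows <- function(n, zmin, zmax) {
  if (n < 1L) return(numeric(0))
  mid <- (zmin + zmax) / 2
  pitch <- (zmax - zmin) / n
  mid + (seq_len(n) - (n + 1) / 2) * pitch
}

#' Build the stylized hexagonal-prism lobule
#'
#' Constructs the nine-component lobule as analytic primitives meshed
#' parametrically: a central vein on the prism axis sized to its target mass
#' fraction; portal triads (portal vein, portal artery, bile duct cylinders)
#' at the six vertices; straight sinusoids of the prescribed diameter
#' radiating outward from the central vein toward the hexagon edges in
#' mirror-symmetric azimuth fans stacked over symmetric z rows, their total
#' length scaled so the sinusoid mass fraction matches its target exactly;
#' a space-of-Disse shell around every sinusoid whose thickness is solved
#' from the Disse/sinusoid target ratio; bile canaliculi as thin radial
#' cylinders on the interleaved z rows; icosahedral Kupffer cells placed
#' inside the sinusoid lumina ([place_kupffer_cells()]); and hepatocytes as
#' the fill region (prism minus everything else). Components with zero
#' target fraction are omitted. Achieved mass fractions land within 5%
#' relative of the targets by construction; infeasible targets (blood
#' volume exceeding the packable volume) raise an error.
#'
#' @param spec a [lobule_spec()].
#' @return a [labeled_mesh_set()]; attribute `achieved_fractions` holds the
#'   realized mass fractions.
#' @export
build_hexagonal_lobule <- function(spec) {
  stopifnot(inherits(spec, "lobule_spec"))
  a <- spec$apothem_um
  h <- spec$height_um
  fr <- spec$target_fractions$fractions
  rho <- spec$densities
  V <- 2 * sqrt(3) * a^2 * h
  M <- V / sum(fr / rho[names(fr)])
  vol_target <- fr * M / rho[names(fr)]

  prims <- list()
  # --- central vein ---------------------------------------------------------
  r_cv <- sqrt(vol_target[["central_vein"]] / (pi * h))
  prims$central_vein <- list(prim_cylinder(c(0, 0, 0), c(0, 0, h), r_cv))
  # --- portal triads at the six vertices ------------------------------------
  r_pv <- sqrt(vol_target[["portal_veins"]] / (6 * pi * h))
  r_pa <- sqrt(vol_target[["portal_arteries"]] / (6 * pi * h))
  r_bd <- sqrt(vol_target[["bile_ducts"]] / (6 * pi * h))
  gap <- 1.5
  Rv <- 2 * a / sqrt(3)
  ext <- r_pv + 2 * max(r_pa, r_bd) + 2 * gap
  R_cl <- (a - ext - 2) / cos(pi / 6)
  if (R_cl <= r_cv + ext) stop("lobule too small to host the portal triads")
  pv <- pa <- bd <- list()
  obstacles <- list()
  for (k in 0:5) {
    az <- pi / 6 + k * pi / 3
    u <- c(cos(az), sin(az))
    ctr <- R_cl * u
    p_pv <- ctr
    p_bd <- ctr + u * (r_pv + r_bd + gap)
    p_pa <- ctr - u * (r_pv + r_pa + gap)
    pv[[k + 1L]] <- prim_cylinder(c(p_pv, 0), c(p_pv, h), r_pv)
    pa[[k + 1L]] <- prim_cylinder(c(p_pa, 0), c(p_pa, h), r_pa)
    bd[[k + 1L]] <- prim_cylinder(c(p_bd, 0), c(p_bd, h), r_bd)
    obstacles <- c(obstacles, list(list(c = p_pv, r = r_pv),
                                   list(c = p_pa, r = r_pa),
                                   list(c = p_bd, r = r_bd)))
  }
  prims$portal_veins <- pv
  prims$portal_arteries <- pa
  prims$bile_ducts <- bd

  # --- sinusoids + space of Disse -------------------------------------------
  rs <- spec$sinusoid_diameter_um / 2
  t_disse <- if (vol_target[["sinusoids"]] > 0) {
    rs * (sqrt(1 + vol_target[["space_of_disse"]] /
                 vol_target[["sinusoids"]]) - 1)
  } else 0
  ws <- rs + t_disse
  wc <- spec$canaliculus_radius_um
  # z-independent row template of radial slots, with triad avoidance
  row_template <- function(half_width, min_len) {
    slots <- fan_slots(half_width, r_cv + half_width + 2, a, gap = gap)
    slots$r_end <- vapply(seq_len(nrow(slots)), function(s) {
      # shrink the hexagon by the tube half-width (margin along the face
      # normals, not along the ray) so the full tube stays inside
      r1 <- hex_boundary_radius(a - half_width - 2, slots$angle[s])
      limit_by_obstacles(slots$angle[s], r1, obstacles,
                         half_width + gap / 2)
    }, numeric(1))
    slots[slots$r_end - slots$r_start >= min_len, , drop = FALSE]
  }
  make_radial <- function(target_vol, tube_r, tmpl, zrows) {
    cap <- pi * tube_r^2 * sum(tmpl$r_end - tmpl$r_start) * length(zrows)
    if (cap < target_vol) {
      stop(sprintf(paste0("infeasible lobule targets: component needs ",
                          "%.3g um^3 but only %.3g um^3 is packable"),
                   target_vol, cap))
    }
    lambda <- target_vol / cap
    out <- list()
    for (z in zrows) {
      for (s in seq_len(nrow(tmpl))) {
        len <- (tmpl$r_end[s] - tmpl$r_start[s]) * lambda
        u <- c(cos(tmpl$angle[s]), sin(tmpl$angle[s]))
        out[[length(out) + 1L]] <- prim_cylinder(
          c(tmpl$r_start[s] * u, z),
          c((tmpl$r_start[s] + len) * u, z), tube_r)
      }
    }
    out
  }
  # pack extra lumen for the Kupffer cells that will be carved out of it
  sin_target <- vol_target[["sinusoids"]] + vol_target[["kupffer_cells"]]
  can_target <- vol_target[["bile_canaliculi"]]
  if (sin_target > 0) {
    tmpl_s <- row_template(ws, 6 * rs)
    if (nrow(tmpl_s) == 0L) stop("infeasible lobule: no sinusoid slots fit")
    row_cap <- pi * rs^2 * sum(tmpl_s$r_end - tmpl_s$r_start)
    n_rows <- max(1L, ceiling(sin_target / (0.95 * row_cap)))
    zmin <- ws + 2
    zmax <- h - ws - 2
    pitch_need <- 2 * ws + 2 * wc + 3 * gap
    if ((zmax - zmin) / n_rows < pitch_need) {
      stop("infeasible lobule targets: sinusoid rows do not fit the height")
    }
    z_s <- symmetric_rows(n_rows, zmin, zmax)
    prims$sinusoids <- make_radial(sin_target, rs, tmpl_s, z_s)
    if (t_disse > 0) {
      prims$space_of_disse <- lapply(prims$sinusoids, function(p) {
        prim_tube(p$a, p$b, rs, rs + t_disse)
      })
    }
    if (can_target > 0) {
      # canaliculi rows midway between sinusoid rows (symmetric about h/2)
      half_pitch <- if (n_rows > 1L) diff(z_s)[1L] / 2 else (zmax - zmin) / 4
      z_c_all <- sort(c(z_s - half_pitch, z_s[length(z_s)] + half_pitch))
      z_c_all <- z_c_all[z_c_all > wc + 1 & z_c_all < h - wc - 1]
      tmpl_c <- row_template(wc, 10 * wc)
      if (nrow(tmpl_c) == 0L) {
        stop("infeasible lobule: no canaliculus slots fit")
      }
      row_cap_c <- pi * wc^2 * sum(tmpl_c$r_end - tmpl_c$r_start)
      n_c <- ceiling(can_target / (0.95 * row_cap_c))
      # a centered subset keeps the stack mirror-symmetric about h/2
      if ((length(z_c_all) - n_c) %% 2L == 1L) n_c <- n_c + 1L
      if (n_c > length(z_c_all)) {
        stop("infeasible lobule targets: bile canaliculi rows do not fit")
      }
      first <- (length(z_c_all) - n_c) %/% 2L
      keep <- first + seq_len(n_c)
      prims$bile_canaliculi <- make_radial(can_target, wc, tmpl_c,
                                           z_c_all[keep])
    }
  } else if (can_target > 0) {
    tmpl_c <- row_template(wc, 10 * wc)
    z_c <- symmetric_rows(max(1L, ceiling(can_target /
      (0.95 * pi * wc^2 * sum(tmpl_c$r_end - tmpl_c$r_start)))),
      wc + 2, h - wc - 2)
    prims$bile_canaliculi <- make_radial(can_target, wc, tmpl_c, z_c)
  }

  # --- meshes ---------------------------------------------------------------
  prims <- Filter(function(p) length(p) > 0L, prims)
  meshes <- lapply(prims, function(pl) {
    concat_meshes(lapply(pl, prim_mesh, radial = spec$radial_segments))
  })

  # --- Kupffer cells inside the sinusoid lumina -----------------------------
  kup_target <- vol_target[["kupffer_cells"]]
  if (kup_target > 0) {
    if (is.null(prims$sinusoids)) {
      stop("Kupffer cells require sinusoids to live in")
    }
    sin_mesh <- meshes$sinusoids
    attr(sin_mesh, "primitives") <- prims$sinusoids
    kup <- place_kupffer_cells(sin_mesh, kup_target,
                               spec$kupffer_circumradius_um, spec$seed)
    prims$kupffer_cells <- attr(kup, "primitives")
    meshes$kupffer_cells <- kup
  }

  prism <- prim_hexprism(a, h, c(0, 0, 0))
  meshes$hepatocytes <- prim_mesh(prism)
  prims$hepatocytes <- list(prism)
  set <- labeled_mesh_set(meshes, spec$densities, primitives = prims,
                          prism = prism, fill_component = "hepatocytes")
  vols <- mesh_set_volumes(set)
  masses <- vols * spec$densities[names(vols)]
  achieved <- masses / sum(masses)
  targets <- fr[names(achieved)]
  relerr <- abs(achieved - targets) / pmax(targets, 1e-12)
  if (any(relerr > 0.05 & targets > 0)) {
    stop("achieved mass fractions deviate more than 5% from targets: ",
         paste(names(achieved)[relerr > 0.05], collapse = ", "))
  }
  attr(set, "achieved_fractions") <- achieved
  attr(set, "spec") <- spec
  set
}

#' Place icosahedral Kupffer cells inside the sinusoids
#'
#' Randomly generates icosahedra and keeps those entirely contained in the
#' sinusoid lumina (center on-axis within the clearance the circumradius
#' allows, so the full cell lies inside), with centers kept at least one
#' cell diameter apart, until the target total volume is reached. When the
#' sinusoid mesh carries its source primitives the containment test is
#' analytic; otherwise vertices are tested against the mesh directly.
#' Deterministic per seed.
#'
#' @param sinusoids sinusoid [triangle_mesh()] (ideally with the
#'   `primitives` attribute written by [build_hexagonal_lobule()]).
#' @param target_volume total cell volume to place (um^3); 0 returns an
#'   empty mesh.
#' @param cell_size icosahedron circumradius (um).
#' @param seed integer seed.
#' @param max_attempts placement attempts before giving up.
#' @return [triangle_mesh()] of all cells, with attribute `primitives`.
#' @export
place_kupffer_cells <- function(sinusoids, target_volume, cell_size, seed,
                                max_attempts = NULL) {
  if (target_volume == 0) {
    return(structure(empty_mesh(), primitives = list()))
  }
  edge <- 4 * cell_size / sqrt(10 + 2 * sqrt(5))
  v_ico <- 5 / 12 * (3 + sqrt(5)) * edge^3
  n_cells <- max(1L, round(target_volume / v_ico))
  if (abs(n_cells * v_ico - target_volume) / target_volume > 0.02) {
    stop(sprintf(paste0("target volume %.4g is not reachable within 2%% ",
                        "with whole cells of volume %.4g"), target_volume,
                 v_ico))
  }
  prims <- attr(sinusoids, "primitives")
  max_attempts <- max_attempts %||% (500L * n_cells)
  with_seed(seed, {
    centers <- matrix(numeric(0), 0L, 3L)
    cells <- list()
    attempts <- 0L
    if (!is.null(prims)) {
      lens <- vapply(prims, function(p) vnorm(p$b - p$a), numeric(1))
      radii <- vapply(prims, function(p) p$r, numeric(1))
      ok_prims <- which(radii > cell_size & lens > 2 * cell_size)
      if (length(ok_prims) == 0L) {
        stop("no sinusoid is wide enough for the requested cell size")
      }
      wts <- lens[ok_prims] * radii[ok_prims]^2
      while (length(cells) < n_cells && attempts < max_attempts) {
        attempts <- attempts + 1L
        p <- prims[[ok_prims[alias_sample(wts / sum(wts), 1L)]]]
        u <- (p$b - p$a) / vnorm(p$b - p$a)
        s <- runif(1L, cell_size, vnorm(p$b - p$a) - cell_size)
        slack <- p$r - cell_size
        perp <- any_perpendicular(u)
        off <- runif(1L, 0, slack) *
          (rodrigues_matrix(u, runif(1L, 0, 2 * pi)) %*% perp)
        ctr <- p$a + s * u + as.numeric(off)
        if (nrow(centers) > 0L &&
            min(sqrt(rowSums(sweep(centers, 2L, ctr, `-`)^2))) <
            2 * cell_size) next
        rot <- rodrigues_matrix(unitize(rnorm(3L)), runif(1L, 0, 2 * pi))
        cells[[length(cells) + 1L]] <- prim_icosahedron(ctr, cell_size, rot)
        centers <- rbind(centers, ctr)
      }
    } else {
      bb <- mesh_bbox(sinusoids)
      while (length(cells) < n_cells && attempts < max_attempts) {
        attempts <- attempts + 1L
        ctr <- runif(3L, bb["lo", ], bb["hi", ])
        rot <- rodrigues_matrix(unitize(rnorm(3L)), runif(1L, 0, 2 * pi))
        cand <- prim_icosahedron(ctr, cell_size, rot)
        m <- prim_mesh(cand)
        pts <- rbind(m$vertices, ctr)
        if (!all(.pts_in_mesh(pts, sinusoids$vertices, sinusoids$faces))) {
          next
        }
        if (nrow(centers) > 0L &&
            min(sqrt(rowSums(sweep(centers, 2L, ctr, `-`)^2))) <
            2 * cell_size) next
        cells[[length(cells) + 1L]] <- cand
        centers <- rbind(centers, ctr)
      }
    }
    if (length(cells) < n_cells) {
      stop(sprintf(paste0("Kupffer placement exhausted %d attempts at %d of ",
                          "%d cells (achieved volume %.4g of %.4g)"),
                   attempts, length(cells), n_cells,
                   length(cells) * v_ico, target_volume))
    }
    mesh <- concat_meshes(lapply(cells, prim_mesh))
    structure(mesh, primitives = cells, achieved_volume = n_cells * v_ico)
  })
}

#' Tile the lobule and crop to a rectangular prism
#'
#' Duplicates the hexagonal lobule six times onto the neighboring lattice
#' sites (translations of two apothems toward each flat), then crops the
#' seven-lobule patch to the rectangular unit cell of the hexagonal tiling
#' (2a wide, 2*sqrt(3)*a deep, full height; exactly two lobule areas), whose
#' faces are mirror planes of the tiling, so reflective transport boundaries
#' see mirrored geometry. Primitives wholly inside the cell keep their exact
#' parametric meshes; boundary-crossing primitives are clipped implicitly.
#' Relative mass fractions are preserved by the periodicity of the tiling up
#' to the (small) clipping discretization error.
#'
#' @param lobule a [labeled_mesh_set()] from [build_hexagonal_lobule()].
#' @return a [labeled_mesh_set()] over the rectangular cell; attribute
#'   `achieved_fractions` holds the post-crop mass fractions.
#' @export
tile_and_crop_prism <- function(lobule) {
  stopifnot(inherits(lobule, "labeled_mesh_set"))
  if (is.null(lobule$prism) || lobule$prism$type != "hexprism") {
    stop("tile_and_crop_prism needs the hexagonal prism metadata")
  }
  a <- lobule$prism$apothem
  h <- lobule$prism$height
  box <- prim_box(c(-a, -sqrt(3) * a, 0), c(a, sqrt(3) * a, h))
  shifts <- rbind(c(0, 0, 0),
                  t(vapply(0:5, function(k) {
                    2 * a * c(cos(k * pi / 3), sin(k * pi / 3), 0)
                  }, numeric(3))))
  comp_names <- setdiff(names(lobule$meshes), lobule$fill_component)
  new_prims <- list()
  new_meshes <- list()
  for (nm in comp_names) {
    pl <- lobule$primitives[[nm]]
    if (is.null(pl)) stop("component lacks primitive metadata: ", nm)
    out <- list()
    for (s in seq_len(nrow(shifts))) {
      for (p in pl) {
        q <- prim_translate(p, shifts[s, ])
        bb <- prim_bbox(q)
        if (any(bb["lo", ] >= box$hi) || any(bb["hi", ] <= box$lo)) next
        if (all(bb["lo", ] >= box$lo - 1e-9) &&
            all(bb["hi", ] <= box$hi + 1e-9)) {
          out[[length(out) + 1L]] <- q
        } else {
          q$clip <- list(lo = box$lo, hi = box$hi)
          out[[length(out) + 1L]] <- q
        }
      }
    }
    if (length(out) == 0L) next
    new_prims[[nm]] <- out
    new_meshes[[nm]] <- concat_meshes(lapply(out, prim_mesh))
  }
  fill <- lobule$fill_component
  if (!is.null(fill)) {
    new_meshes[[fill]] <- prim_mesh(box)
    new_prims[[fill]] <- list(box)
  }
  set <- labeled_mesh_set(new_meshes, lobule$densities,
                          primitives = new_prims, prism = box,
                          fill_component = fill)
  vols <- mesh_set_volumes(set)
  masses <- vols * lobule$densities[names(vols)]
  attr(set, "achieved_fractions") <- masses / sum(masses)
  set
}

#' Mass report of a labeled mesh set
#'
#' Per-component mass from enclosed mesh volume times density (the fill
#' component, when present, gets the prism volume minus all the others);
#' fractions are normalized to the total. Open meshes raise an error.
#'
#' @param set a [labeled_mesh_set()], or a named list of meshes.
#' @param densities named densities (taken from the set when omitted).
#' @return data.frame with `component`, `volume`, `density`, `mass`,
#'   `fraction`.
#' @export
region_mass_report <- function(set, densities = NULL) {
  if (!inherits(set, "labeled_mesh_set")) {
    set <- labeled_mesh_set(set, densities)
  }
  densities <- densities %||% set$densities
  for (nm in names(set$meshes)) {
    if (!is.null(set$fill_component) && nm == set$fill_component) next
    wt <- is_watertight(set$meshes[[nm]])
    if (!isTRUE(wt)) {
      stop(sprintf("component '%s' mesh is open: %s", nm, attr(wt, "reason")))
    }
  }
  vols <- vapply(names(set$meshes), function(nm) {
    if (!is.null(set$fill_component) && nm == set$fill_component) {
      return(NA_real_)
    }
    mesh_volume(set$meshes[[nm]])
  }, numeric(1))
  if (all(c("sinusoids", "kupffer_cells") %in% names(vols))) {
    vols["sinusoids"] <- vols["sinusoids"] - vols["kupffer_cells"]
  }
  if (!is.null(set$fill_component)) {
    vols[set$fill_component] <- prim_volume(set$prism) -
      sum(vols, na.rm = TRUE)
  }
  mass <- vols * densities[names(vols)]
  data.frame(component = names(vols), volume = unname(vols),
             density = unname(densities[names(vols)]),
             mass = unname(mass), fraction = unname(mass / sum(mass)),
             row.names = NULL)
}

#' Classify points by lobule component
#'
#' Assigns each point the name of the component containing it (components
#' queried in order, fill component last as background inside the prism) or
#' `NA` for points outside the model. Uses the analytic primitives.
#'
#' @param set a [labeled_mesh_set()] with primitive metadata.
#' @param P `n x 3` point matrix.
#' @return character vector of component names.
#' @export
classify_points <- function(set, P) {
  if (is.null(set$primitives)) stop("mesh set lacks primitive metadata")
  P <- matrix(as.numeric(P), ncol = 3L)
  out <- rep(NA_character_, nrow(P))
  fill <- set$fill_component
  # reverse order: later components take precedence (Kupffer cells sit
  # inside sinusoids), matching the voxelizer
  for (nm in rev(setdiff(names(set$meshes), fill))) {
    todo <- which(is.na(out))
    if (!length(todo)) break
    for (p in set$primitives[[nm]]) {
      if (!length(todo)) break
      inside <- prim_inside(p, P[todo, , drop = FALSE])
      out[todo[inside]] <- nm
      todo <- todo[!inside]
    }
  }
  if (!is.null(fill)) {
    todo <- which(is.na(out))
    if (length(todo)) {
      inside <- prim_inside(set$prism, P[todo, , drop = FALSE])
      out[todo[inside]] <- fill
    }
  }
  out
}

#' Voxelize a labeled mesh set
#'
#' Builds a transport label grid from the analytic primitives: the fill
#' component labels the prism background, then every other component stamps
#' its voxels (later components win inside overlapping tolerance bands).
#'
#' @param set a [labeled_mesh_set()] with primitive metadata.
#' @param resolution voxels along the largest extent.
#' @return a [label_grid()] whose region names are the component names.
#' @export
voxelize_mesh_set <- function(set, resolution = 64L) {
  if (is.null(set$primitives)) stop("mesh set lacks primitive metadata")
  bb <- prim_bbox(set$prism)
  lo <- bb["lo", ]
  hi <- bb["hi", ]
  hvox <- max(hi - lo) / resolution
  dims <- pmax(1L, as.integer(round((hi - lo) / hvox)))
  sp <- (hi - lo) / dims
  comp <- names(set$meshes)
  labels <- array(0L, dims)
  xs <- lo[1] + sp[1] * (seq_len(dims[1]) - 0.5)
  ys <- lo[2] + sp[2] * (seq_len(dims[2]) - 0.5)
  zs <- lo[3] + sp[3] * (seq_len(dims[3]) - 0.5)
  fill_lab <- match(set$fill_component, comp)
  if (!is.na(fill_lab)) {
    # background: inside the prism
    slab <- as.matrix(expand.grid(x = xs, y = ys))
    for (k in seq_len(dims[3])) {
      P <- cbind(slab, zs[k])
      inside <- prim_inside(set$prism, P)
      lk <- labels[, , k]
      lk[matrix(inside, dims[1], dims[2])] <- fill_lab
      labels[, , k] <- lk
    }
  }
  for (ci in seq_along(comp)) {
    nm <- comp[ci]
    if (!is.na(fill_lab) && ci == fill_lab) next
    for (p in set$primitives[[nm]]) {
      pb <- prim_bbox(p)
      i <- which(xs >= pb["lo", 1] - sp[1] & xs <= pb["hi", 1] + sp[1])
      j <- which(ys >= pb["lo", 2] - sp[2] & ys <= pb["hi", 2] + sp[2])
      k <- which(zs >= pb["lo", 3] - sp[3] & zs <= pb["hi", 3] + sp[3])
      if (!length(i) || !length(j) || !length(k)) next
      G <- as.matrix(expand.grid(x = xs[i], y = ys[j], z = zs[k]))
      inside <- prim_inside(p, G)
      if (any(inside)) {
        idx <- as.matrix(expand.grid(i = i, j = j, k = k))[inside, ,
                                                           drop = FALSE]
        labels[idx] <- ci
      }
    }
  }
  label_grid(labels, origin = lo, spacing = sp, region_names = comp,
             densities = unname(set$densities[comp]))
}
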