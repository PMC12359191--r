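#' Liver region mass table
#'
#' Container for the six region masses of the coupled liver vasculature
#' models: whole liver (`mL`), total liver blood (`mLB`), bloodless
#' parenchyma (`mLP`), blood in macroscale vessels (`mLBM`), macroscale
#' composite tissue (`mLCTM`, parenchyma plus microscale blood), and
#' microscale blood (`mLBmu`). All masses in grams. The regions obey the
#' closure identities `mLB = mLBM + mLBmu`, `mL = mLB + mLP` and
#' `mLCTM = mL - mLBM` up to the rounding carried by published tables.
#'
#' @param mL,mLB,mLP,mLBM,mLCTM,mLBmu region masses in g, all > 0
#'   (`mLBM`/`mLBmu` may be 0).
#' @param sex_label free-text label of the modeled individual.
#' @param closure_tol closure tolerance in g used by validation (default
#'   0.05 g; published tables carry 0.01 g rounding residues).
#' @return an object of class `mass_table`.
#' @seealso [validate_closure()], [reference_mass_table()]
#' @export
mass_table <- function(mL, mLB, mLP, mLBM, mLCTM, mLBmu,
                       sex_label = "", closure_tol = 0.05) {
  for (nm in c("mL", "mLB", "mLP", "mLBM", "mLCTM", "mLBmu")) {
    stopifnot_scalar_num(get(nm), nm)
  }
  if (mL <= 0 || mLB <= 0 || mLP <= 0 || mLCTM <= 0 || mLBM < 0 || mLBmu < 0) {
    stop("mass_table: masses must be positive (macro/micro blood may be zero)")
  }
  mt <- structure(
    list(mL = mL, mLB = mLB, mLP = mLP, mLBM = mLBM, mLCTM = mLCTM,
         mLBmu = mLBmu, sex_label = sex_label),
    class = "mass_table")
  rep <- validate_closure(mt, tol = closure_tol)
  if (any(!rep$pass)) {
    stop("mass_table closure violated: ",
         paste(rep$identity[!rep$pass], collapse = "; "),
         sprintf(" (tol %.3g g)", closure_tol))
  }
  mt
}

#' @export
print.mass_table <- function(x, ...) {
  cat(sprintf("mass_table [%s]\n", x$sex_label))
  for (nm in c("mL", "mLB", "mLP", "mLBM", "mLCTM", "mLBmu")) {
    cat(sprintf("  %-6s %10.2f g\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Check the closure identities of a mass table
#'
#' Reports the residual of each closure identity of the region masses and
#' flags residuals exceeding `tol`. Reference tables rounded to 0.01 g
#' typically carry residuals of 0.01-0.02 g.
#'
#' @param mt a [mass_table()] (or a plain named list with the same fields).
#' @param tol tolerance in g.
#' @return data.frame with columns `identity`, `residual_g`, `pass`.
#' @export
validate_closure <- function(mt, tol = 0.05) {
  res <- c(
    "mLB = mLBM + mLBmu" = mt$mLB - (mt$mLBM + mt$mLBmu),
    "mL = mLB + mLP"     = mt$mL - (mt$mLB + mt$mLP),
    "mLCTM = mL - mLBM"  = mt$mLCTM - (mt$mL - mt$mLBM))
  data.frame(identity = names(res), residual_g = abs(unname(res)),
             pass = abs(unname(res)) <= tol, row.names = NULL)
}

#' Elemental composition of a tissue material
#'
#' Mass fractions (dimensionless, summing to 1) over the ten elements used by
#' the liver tissue models (H, C, N, O, Na, P, S, Cl, K, Fe), plus a mass
#' density.
#'
#' @param fractions named numeric vector of elemental mass fractions; if
#'   `percent = TRUE`, given in percent and divided by 100 on input.
#' @param density mass density in g/cm^3.
#' @param percent logical flag: fractions supplied in percent.
#' @param sum_tol allowed deviation of the fraction sum from 1 (default 1e-3,
#'   matching tables printed in percent to two decimals).
#' @return an object of class `elemental_composition`.
#' @export
elemental_composition <- function(fractions, density, percent = FALSE,
                                  sum_tol = 1e-3) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop("fractions must be a named numeric vector")
  }
  f <- as.numeric(fractions)
  names(f) <- names(fractions)
  if (percent) f <- f / 100
  if (any(f < 0)) {
    stop("negative elemental fraction for: ",
         paste(names(f)[f < 0], collapse = ", "))
  }
  if (abs(sum(f) - 1) > sum_tol) {
    stop(sprintf("elemental fractions sum to %.6f, expected 1 within %g",
                 sum(f), sum_tol))
  }
  stopifnot_scalar_num(density, "density", positive = TRUE)
  structure(list(fractions = f, density = density),
            class = "elemental_composition")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("elemental_composition (percent):\n")
  print(round(100 * x$fractions, 4))
  cat(sprintf("density: %.3f g/cm^3\n", x$density))
  invisible(x)
}

#' Lobule component mass fractions
#'
#' The nine tissue components of the microscale hexagonal lobule model and
#' their mass fractions (summing to 1).
#'
#' @param fractions named numeric vector over the nine lobule components
#'   (`central_vein`, `portal_arteries`, `portal_veins`, `bile_ducts`,
#'   `bile_canaliculi`, `sinusoids`, `space_of_disse`, `kupffer_cells`,
#'   `hepatocytes`); percent if `percent = TRUE`.
#' @param total_mass total lobule mass in g.
#' @param percent logical flag: fractions supplied in percent.
#' @return an object of class `lobule_mass_fractions`.
#' @export
lobule_mass_fractions <- function(fractions, total_mass, percent = FALSE) {
  expected <- c("central_vein", "portal_arteries", "portal_veins",
                "bile_ducts", "bile_canaliculi", "sinusoids",
                "space_of_disse", "kupffer_cells", "hepatocytes")
  if (!setequal(names(fractions), expected)) {
    stop("lobule components must be exactly: ",
         paste(expected, collapse = ", "))
  }
  f <- as.numeric(fractions)[match(expected, names(fractions))]
  names(f) <- expected
  if (percent) f <- f / 100
  if (any(f < 0)) stop("lobule mass fractions must be >= 0")
  if (abs(sum(f) - 1) > 1e-3) {
    stop(sprintf("lobule mass fractions sum to %.6f, expected 1 within 1e-3",
                 sum(f)))
  }
  stopifnot_scalar_num(total_mass, "total_mass", positive = TRUE)
  structure(list(fractions = f, total_mass = total_mass),
            class = "lobule_mass_fractions")
}

# Names of the lobule components that carry whole blood.
lobule_blood_components <- function() {
  c("central_vein", "portal_arteries", "portal_veins", "sinusoids")
}

#' Derive the parenchyma composition by elemental subtraction
#'
#' Computes the composition of the macroscale parenchyma region (composite
#' tissue outside the explicitly modeled vessels) by subtracting the
#' elemental masses of macroscale vessel blood from those of the homogenized
#' liver and renormalizing over the composite tissue mass. This guarantees
#' that re-homogenizing parenchyma and vessel blood at the model's mass
#' ratio recovers the homogenized liver material.
#'
#' Trace elements may come out marginally negative because the published
#' input fractions are rounded (e.g. Fe, present in blood but printed as
#' 0.00 for liver). Deficits of magnitude at most `neg_tol` (as a fraction of
#' composite mass) are clamped to zero before renormalization, mirroring the
#' published derived row; larger deficits signal inconsistent inputs and
#' raise an error naming the element.
#'
#' @param liver,blood [elemental_composition()] of homogenized liver and
#'   blood.
#' @param mL,mLBM,mLCTM masses in g of liver, macroscale vessel blood and
#'   macroscale composite tissue.
#' @param neg_tol clamping tolerance for rounding-induced negative fractions.
#' @return an [elemental_composition()] with density carried from `liver`;
#'   attribute `clamped_elements` lists any elements clamped to zero.
#' @export
derive_parenchyma_composition <- function(liver, blood, mL, mLBM, mLCTM,
                                          neg_tol = 1e-3) {
  stopifnot(inherits(liver, "elemental_composition"),
            inherits(blood, "elemental_composition"))
  if (!(mL > mLBM)) stop("mL must exceed mLBM")
  stopifnot_scalar_num(mLCTM, "mLCTM", positive = TRUE)
  elems <- names(liver$fractions)
  if (!setequal(elems, names(blood$fractions))) {
    stop("liver and blood compositions must cover the same elements")
  }
  b <- blood$fractions[elems]
  f <- (mL * liver$fractions - mLBM * b) / mLCTM
  neg <- f < 0
  if (any(f < -neg_tol)) {
    stop("negative elemental mass after subtraction for: ",
         paste(elems[f < -neg_tol], collapse = ", "),
         " (inconsistent liver/blood inputs)")
  }
  clamped <- elems[neg]
  f[neg] <- 0
  f <- f / sum(f)
  out <- elemental_composition(f, density = liver$density)
  attr(out, "clamped_elements") <- clamped
  out
}

#' Macroscale/microscale blood partition
#'
#' Percent of total liver blood residing in macroscale vessels versus
#' microscale structures. The two shares sum to 100 exactly (the microscale
#' share is computed as the complement).
#'
#' @param mt a [mass_table()].
#' @return named numeric vector `c(macro = ..., micro = ...)` in percent.
#' @export
blood_partition_summary <- function(mt) {
  if (mt$mLB == 0) stop("mLB is zero; blood partition undefined")
  macro <- 100 * mt$mLBM / mt$mLB
  c(macro = macro, micro = 100 - macro)
}

#' Share of liver blood contained in the sinusoids
#'
#' Combines the macro/micro blood split of the mass table with the relative
#' blood-compartment fractions of the lobule model: the sinusoid share of
#' total liver blood is `100 * mLBmu * (f_sinusoids / sum of blood-compartment
#' fractions) / mLB`.
#'
#' @param mt a [mass_table()].
#' @param lf a [lobule_mass_fractions()].
#' @return percentage of total liver blood in the sinusoids.
#' @export
sinusoid_blood_share <- function(mt, lf) {
  stopifnot(inherits(lf, "lobule_mass_fractions"))
  bc <- lobule_blood_components()
  missing <- setdiff(bc, names(lf$fractions))
  if (length(missing)) {
    stop("missing lobule blood compartment(s): ",
         paste(missing, collapse = ", "))
  }
  if (mt$mLB == 0) stop("mLB is zero")
  fb <- lf$fractions[bc]
  100 * mt$mLBmu * (fb[["sinusoids"]] / sum(fb)) / mt$mLB
}

#' Solve the free cell-material composition of a mixture
#'
#' Given a target mixture composition and a set of components with known mass
#' fractions, of which the `free_components` share one unknown elemental
#' composition, solves element-by-element for the unknown composition such
#' that the fraction-weighted sum of component compositions matches the
#' target, then renormalizes the solution to sum to 1.
#'
#' With a single shared unknown the per-element least-squares solution is
#' exact division by the total free fraction; residuals are reported from
#' re-mixing the solved composition forward against the target.
#'
#' @param targets [elemental_composition()] the mixture should match.
#' @param components named list; each entry is `list(fraction =, composition =)`
#'   where `composition` is an [elemental_composition()] (may be `NULL` for
#'   free components).
#' @param free_components character names of entries sharing the unknown
#'   composition.
#' @return the solved [elemental_composition()]; attribute `residuals` holds
#'   per-element (target minus re-mixed) fractions, attribute `raw_fractions`
#'   the pre-renormalization solution.
#' @export
solve_cell_composition <- function(targets, components, free_components) {
  stopifnot(inherits(targets, "elemental_composition"))
  if (!all(free_components %in% names(components))) {
    stop("free_components must name entries of components")
  }
  fr <- vapply(components, function(cc) cc$fraction, numeric(1))
  f_free <- sum(fr[free_components])
  if (f_free <= 0) stop("total free fraction is zero; nothing to solve")
  if (abs(sum(fr) - 1) > 1e-3) {
    stop(sprintf("component fractions sum to %.6f, expected 1", sum(fr)))
  }
  elems <- names(targets$fractions)
  known <- setdiff(names(components), free_components)
  mixed_known <- rep(0, length(elems))
  names(mixed_known) <- elems
  inv_rho_known <- 0
  for (nm in known) {
    cc <- components[[nm]]
    if (is.null(cc$composition)) stop("known component lacks composition: ", nm)
    mixed_known <- mixed_known + cc$fraction * cc$composition$fractions[elems]
    inv_rho_known <- inv_rho_known + cc$fraction / cc$composition$density
  }
  x <- (targets$fractions - mixed_known) / f_free
  raw <- x
  x[x < 0] <- 0
  if (sum(x) <= 0) stop("solved composition is entirely non-positive")
  x <- x / sum(x)
  # free density from the harmonic (mass-fraction) density mixing rule
  inv_rho_free <- (1 / targets$density - inv_rho_known) / f_free
  dens <- if (inv_rho_free > 0) 1 / inv_rho_free else targets$density
  out <- elemental_composition(x, density = dens)
  remixed <- mixed_known + f_free * x
  attr(out, "residuals") <- targets$fractions - remixed
  attr(out, "raw_fractions") <- raw
  out
}

# ---- bundled reference fixtures -------------------------------------------

#' Bundled reference mass tables, compositions and lobule fractions
#'
#' Loaders for the transcribed reference values shipped with the package:
#' region masses of the adult male/female coupled liver models, elemental
#' compositions of the tissue materials, and lobule component mass fractions.
#'
#' @param sex `"male"` or `"female"`.
#' @return `reference_mass_table()`: a [mass_table()];
#'   `reference_composition()`: an [elemental_composition()];
#'   `reference_lobule_fractions()`: a [lobule_mass_fractions()].
#' @export
reference_mass_table <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  d <- jsonlite::read_json(vasodose_extdata("liver_region_masses.json"),
                           simplifyVector = TRUE)[[sex]]
  mass_table(mL = d$mL, mLB = d$mLB, mLP = d$mLP, mLBM = d$mLBM,
             mLCTM = d$mLCTM, mLBmu = d$mLBmu, sex_label = d$sex_label)
}

#' @rdname reference_mass_table
#' @param material one of the bundled material names (`"icrp_liver"`,
#'   `"icrp_blood"`, `"plasma_lymph"`, `"parenchyma_derived"`,
#'   `"cell_material"`).
#' @export
reference_composition <- function(material) {
  d <- jsonlite::read_json(vasodose_extdata("tissue_compositions.json"),
                           simplifyVector = TRUE)
  if (!material %in% names(d$materials)) {
    stop("unknown bundled material: ", material, "; available: ",
         paste(names(d$materials), collapse = ", "))
  }
  m <- d$materials[[material]]
  elemental_composition(unlist(m$fractions), density = m$density,
                        percent = isTRUE(d$percent))
}

#' @rdname reference_mass_table
#' @export
reference_lobule_fractions <- function() {
  d <- jsonlite::read_json(vasodose_extdata("lobule_mass_fractions.json"),
                           simplifyVector = TRUE)
  fr <- vapply(d$components, function(x) x$fraction, numeric(1))
  lobule_mass_fractions(fr, total_mass = d$total_mass_g,
                        percent = isTRUE(d$percent))
}

# ---- JSON I/O --------------------------------------------------------------

#' Read and write mass tables and compositions as JSON
#'
#' Key-value text interchange for [mass_table()] and
#' [elemental_composition()] objects. Compositions written by the package
#' carry fractions (0-1); files with `"percent": true` are converted on read.
#'
#' @param path file path.
#' @param x object to write.
#' @return readers return the parsed object; writers return `path`
#'   invisibly.
#' @export
read_mass_table <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  mass_table(mL = d$mL, mLB = d$mLB, mLP = d$mLP, mLBM = d$mLBM,
             mLCTM = d$mLCTM, mLBmu = d$mLBmu,
             sex_label = d$sex_label %||% "")
}

#' @rdname read_mass_table
#' @export
write_mass_table <- function(x, path) {
  stopifnot(inherits(x, "mass_table"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_mass_table
#' @export
read_composition <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  elemental_composition(unlist(d$fractions), density = d$density,
                        percent = isTRUE(d$percent))
}

#' @rdname read_mass_table
#' @export
write_composition <- function(x, path) {
  stopifnot(inherits(x, "elemental_composition"))
  jsonlite::write_json(list(fractions = as.list(x$fractions),
                            density = x$density, percent = FALSE),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
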