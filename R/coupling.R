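# Multiscale absorbed-fraction coupling.
#
# Domains: LBM (blood in macroscale vessels), LCTM (macroscale composite
# tissue = parenchyma + microscale blood), LBmu (microscale blood), LP
# (bloodless parenchyma), LB = LBM + LBmu (all blood), L = whole liver.
# Macroscale transport gives phi_M(target <- source) with escape through the
# organ surface; microscale transport gives phi_mu under reflective
# (infinitely tiled) boundaries. The coupling scales microscale results by
# the macroscale self-retention phi_M(LCTM <- LCTM) to restore the energy
# escape the infinite tiling cannot see, and by mass ratios where one domain
# is a proper subdomain of another (equal-density assumption).

check_af_unit <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals) | vals < 0 | vals > 1)) {
    stop("absorbed-fraction inputs must lie in [0, 1]; got: ",
         paste(signif(vals, 6), collapse = ", "))
  }
  invisible(vals)
}

mass_kg <- function(mt, field) mt[[field]] / 1000

# source-mass weights of the blood compartments; they sum to 1 exactly
blood_weights <- function(mt) {
  wM <- mt$mLBM / mt$mLB
  c(macro = wM, micro = 1 - wM)
}

#' Blood-to-parenchyma crossfire coupling
#'
#' Couples the macroscale and microscale absorbed fractions into the overall
#' `phi(LP <- LB)`: the macroscale-blood contribution is
#' `phi_M(LCTM <- LBM) * mLP / mLCTM` (LP is a proper subdomain of LCTM, of
#' approximately equal density), the microscale-blood contribution is
#' `phi_mu(LP <- LBmu) * phi_M(LCTM <- LCTM)` (scaled by the macroscale
#' self-retention, which the infinitely tiled microscale run cannot see).
#' The two are source-mass-weighted by `mLBM/mLB` and `mLBmu/mLB`, and the
#' specific absorbed fraction is `phi / mLP` (per kg).
#'
#' @param phiM_LCTM_LBM macroscale AF, composite tissue from macro blood.
#' @param phimu_LP_LBmu microscale AF, parenchyma from micro blood.
#' @param phiM_LCTM_LCTM macroscale composite-tissue self-AF.
#' @param mt a [mass_table()].
#' @param rel_err optional relative errors of the three AF inputs (in the
#'   argument order), propagated in quadrature assuming independence.
#' @return list with `phi`, `Phi_per_kg` and `rel_err`.
#' @export
crossfire_P_from_B <- function(phiM_LCTM_LBM, phimu_LP_LBmu,
                               phiM_LCTM_LCTM, mt, rel_err = c(0, 0, 0)) {
  check_af_unit(phiM_LCTM_LBM, phimu_LP_LBmu, phiM_LCTM_LCTM)
  w <- blood_weights(mt)
  t1 <- phiM_LCTM_LBM * (mt$mLP / mt$mLCTM) * w[["macro"]]
  t2 <- phimu_LP_LBmu * phiM_LCTM_LCTM * w[["micro"]]
  phi <- t1 + t2
  var <- (t1 * rel_err[1L])^2 +
    t2^2 * (rel_err[2L]^2 + rel_err[3L]^2)
  list(phi = phi, Phi_per_kg = phi / mass_kg(mt, "mLP"),
       rel_err = if (phi > 0) sqrt(var) / phi else 0)
}

#' Parenchyma-to-blood crossfire coupling
#'
#' `phi(LB <- LP) = phi_mu(LBmu <- LP) * phi_M(LCTM <- LCTM) +
#' phi_M(LBM <- LCTM)`: the microscale target is scaled by macroscale
#' self-retention while the macroscale-vessel target comes directly from the
#' macroscale run (the two targets are disjoint, the source is the same).
#' `Phi = phi / mLB`.
#'
#' @param phimu_LBmu_LP microscale AF, micro blood from parenchyma.
#' @param phiM_LCTM_LCTM macroscale composite-tissue self-AF.
#' @param phiM_LBM_LCTM macroscale AF, macro blood from composite tissue.
#' @inheritParams crossfire_P_from_B
#' @return list with `phi`, `Phi_per_kg` and `rel_err`.
#' @export
crossfire_B_from_P <- function(phimu_LBmu_LP, phiM_LCTM_LCTM,
                               phiM_LBM_LCTM, mt, rel_err = c(0, 0, 0)) {
  check_af_unit(phimu_LBmu_LP, phiM_LCTM_LCTM, phiM_LBM_LCTM)
  t1 <- phimu_LBmu_LP * phiM_LCTM_LCTM
  phi <- t1 + phiM_LBM_LCTM
  if (phi > 1 + 1e-9) {
    stop(sprintf("phi(LB <- LP) = %.6f exceeds 1: inconsistent AF inputs",
                 phi))
  }
  var <- t1^2 * (rel_err[1L]^2 + rel_err[2L]^2) +
    (phiM_LBM_LCTM * rel_err[3L])^2
  list(phi = phi, Phi_per_kg = phi / mass_kg(mt, "mLB"),
       rel_err = if (phi > 0) sqrt(var) / phi else 0)
}

#' Parenchyma self-dose coupling
#'
#' `phi(LP <- LP) = phi_mu(LP <- LP) * phi_M(LCTM <- LCTM)`: the microscale
#' self-AF adjusted by the fraction of energy retained in the composite
#' tissue at the macroscale. `Phi = phi / mLP`.
#'
#' @param phimu_LP_LP microscale parenchyma self-AF.
#' @param phiM_LCTM_LCTM macroscale composite-tissue self-AF.
#' @inheritParams crossfire_P_from_B
#' @return list with `phi`, `Phi_per_kg` and `rel_err`.
#' @export
parenchyma_self <- function(phimu_LP_LP, phiM_LCTM_LCTM, mt,
                            rel_err = c(0, 0)) {
  check_af_unit(phimu_LP_LP, phiM_LCTM_LCTM)
  phi <- phimu_LP_LP * phiM_LCTM_LCTM
  list(phi = phi, Phi_per_kg = phi / mass_kg(mt, "mLP"),
       rel_err = sqrt(rel_err[1L]^2 + rel_err[2L]^2))
}

#' Blood self-dose coupling
#'
#' Blood self-dose collects macroscale and microscale source contributions:
#' `phi(LB <- LBM) = phi_M(LBM <- LBM) + phi_M(LCTM <- LBM) * mLBmu/mLCTM`
#' (the second term is the share of composite-tissue deposition landing in
#' the microscale blood it contains) and
#' `phi(LB <- LBmu) = phi_M(LBM <- LCTM) * mLBmu/mLCTM +
#' phi_mu(LBmu <- LBmu) * phi_M(LCTM <- LCTM)`. The two are
#' source-mass-weighted by `mLBM/mLB` and `mLBmu/mLB`; `Phi = phi / mLB`.
#'
#' The published form of the micro-source-to-macro-vessel term scales
#' `phi_M(LBM <- LCTM)` by `mLBmu/mLCTM`. Because the microscale blood is
#' uniformly dispersed through the composite tissue, a source confined to it
#' has the same macroscale emission density as a source uniform in the whole
#' composite, so reciprocity and energy conservation actually require that
#' term unscaled (the parenchyma-source counterpart is used unscaled).
#' `micro_to_macro = "published"` (default) keeps the printed formula;
#' `"conservative"` drops the mass ratio, restoring exact whole-liver energy
#' conservation for no-escape inputs. The difference is bounded by
#' `phi_M(LBM <- LCTM)`, which is small whenever particle range is small
#' against inter-vessel spacing.
#'
#' @param phiM_LBM_LBM macroscale vessel-blood self-AF.
#' @param phiM_LCTM_LBM macroscale AF, composite tissue from macro blood.
#' @param phiM_LBM_LCTM macroscale AF, macro blood from composite tissue.
#' @param phimu_LBmu_LBmu microscale blood self-AF.
#' @param phiM_LCTM_LCTM macroscale composite-tissue self-AF.
#' @inheritParams crossfire_P_from_B
#' @return list with `phi`, `Phi_per_kg` and `rel_err`.
#' @export
blood_self <- function(phiM_LBM_LBM, phiM_LCTM_LBM, phiM_LBM_LCTM,
                       phimu_LBmu_LBmu, phiM_LCTM_LCTM, mt,
                       rel_err = c(0, 0, 0, 0, 0),
                       micro_to_macro = c("published", "conservative")) {
  micro_to_macro <- match.arg(micro_to_macro)
  check_af_unit(phiM_LBM_LBM, phiM_LCTM_LBM, phiM_LBM_LCTM,
                phimu_LBmu_LBmu, phiM_LCTM_LCTM)
  w <- blood_weights(mt)
  fmu <- mt$mLBmu / mt$mLCTM
  a1 <- phiM_LBM_LBM
  a2 <- phiM_LCTM_LBM * fmu
  phi_from_macro <- a1 + a2
  b1 <- phiM_LBM_LCTM * (if (micro_to_macro == "published") fmu else 1)
  b2 <- phimu_LBmu_LBmu * phiM_LCTM_LCTM
  phi_from_micro <- b1 + b2
  phi <- phi_from_macro * w[["macro"]] + phi_from_micro * w[["micro"]]
  if (phi > 1 + 1e-9) {
    stop(sprintf("phi(LB <- LB) = %.6f exceeds 1: inconsistent AF inputs",
                 phi))
  }
  var <- (w[["macro"]] * a1 * rel_err[1L])^2 +
    (w[["macro"]] * a2 * rel_err[2L])^2 +
    (w[["micro"]] * b1 * rel_err[3L])^2 +
    (w[["micro"]] * b2)^2 * (rel_err[4L]^2 + rel_err[5L]^2)
  list(phi = phi, Phi_per_kg = phi / mass_kg(mt, "mLB"),
       rel_err = if (phi > 0) sqrt(var) / phi else 0)
}

#' Whole-liver absorbed fractions
#'
#' Sums the coupled absorbed fractions over the whole organ:
#' `phi(L <- LB) = phi(LB <- LB) + phi(LP <- LB)` and
#' `phi(L <- LP) = phi(LB <- LP) + phi(LP <- LP)`. Both are bounded by 1;
#' a larger sum signals unphysical inputs and raises an error. Homogeneous
#' vessel distribution makes the two approximately equal at low energy; the
#' approximation degrades with particle escape, so both sides are reported
#' rather than asserted equal.
#'
#' @param phi_LBLB,phi_LPLB,phi_LBLP,phi_LPLP coupled absorbed fractions.
#' @return named vector `c(L_from_LB = ..., L_from_LP = ...)`.
#' @export
whole_liver_af <- function(phi_LBLB, phi_LPLB, phi_LBLP, phi_LPLP) {
  check_af_unit(phi_LBLB, phi_LPLB, phi_LBLP, phi_LPLP)
  out <- c(L_from_LB = phi_LBLB + phi_LPLB,
           L_from_LP = phi_LBLP + phi_LPLP)
  if (any(out > 1 + 1e-9)) {
    stop("whole-liver absorbed fraction exceeds 1: unphysical inputs")
  }
  out
}

#' Macroscale-only comparator SAFs
#'
#' The single-scale approximations used by macroscale-only liver vasculature
#' models: `Phi(LP <- LP) ~ phi(LCTM <- LCTM) / mLCTM` and
#' `Phi(LP <- LB) ~ [fBV phi(LCTM <- LBM) + (1 - fBV) phi(LCTM <- LCTM)] /
#' mLCTM`, with `fBV = mLBM / mLB` the mass fraction of liver blood captured
#' in macroscale vessels.
#'
#' @param phiM_LCTM_LBM,phiM_LCTM_LCTM macroscale absorbed fractions.
#' @param mt a [mass_table()].
#' @return named vector `c(Phi_LPLP_per_kg, Phi_LPLB_per_kg)`.
#' @export
macro_only_saf <- function(phiM_LCTM_LBM, phiM_LCTM_LCTM, mt) {
  check_af_unit(phiM_LCTM_LBM, phiM_LCTM_LCTM)
  fBV <- mt$mLBM / mt$mLB
  m <- mass_kg(mt, "mLCTM")
  c(Phi_LPLP_per_kg = phiM_LCTM_LCTM / m,
    Phi_LPLB_per_kg = (fBV * phiM_LCTM_LBM +
                       (1 - fBV) * phiM_LCTM_LCTM) / m)
}

# exact-match AF lookup; errors name the missing row
af_lookup <- function(afs, scale, source, target, particle, energy) {
  hit <- afs$scale == scale & afs$source == source & afs$target == target &
    afs$particle == particle & afs$energy_MeV == energy
  if (sum(hit) == 0L) {
    stop(sprintf("missing absorbed-fraction row: (%s, %s <- %s, %s, %g MeV)",
                 scale, target, source, particle, energy))
  }
  row <- afs[which(hit)[1L], ]
  c(af = row$af, rel_err = row$rel_err)
}

#' Couple macro and micro absorbed-fraction tables over an energy grid
#'
#' For each (particle, energy) present in the table, fetches the four
#' macroscale rows (sources `LBM`, `LCTM`; targets `LBM`, `LCTM`) and four
#' microscale rows (sources `LBmu`, `LP`; targets `LBmu`, `LP`), runs the
#' four coupling operations and returns the coupled absorbed fractions and
#' specific absorbed fractions. Macro and micro rows must share the exact
#' energy grid: no interpolation happens here (that is the dosimetry
#' module's job).
#'
#' For photons above `photon_vf_threshold` (default 0.150 MeV) the
#' microscale AFs are replaced by the target's volume fraction before
#' coupling: at such energies the reflective micro-model AF to any component
#' approximately equals its fractional volume, so micro simulations need only
#' cover energies up to the threshold.
#'
#' @param afs absorbed-fraction table (schema of [write_af_table()]).
#' @param mt a [mass_table()].
#' @param photon_vf_threshold photon energy threshold in MeV.
#' @param region_volume_fractions named vector with micro-model volume
#'   fractions `c(LP = ..., LBmu = ...)`; required when the table contains
#'   photon rows above the threshold.
#' @param micro_to_macro passed to [blood_self()].
#' @param densities optional named vector of component densities (g/cm^3);
#'   the coupling's mass-ratio scalings assume near-equal densities, so a
#'   spread above 2% triggers a warning.
#' @return data.frame (class `coupled_safs`) with one row per (particle,
#'   energy): `phi_*` and `Phi_*_kg` for the four source-target combinations
#'   plus propagated `relerr_*` columns.
#' @export
assemble_coupled_curves <- function(afs, mt, photon_vf_threshold = 0.150,
                                    region_volume_fractions = NULL,
                                    micro_to_macro = "published",
                                    densities = NULL) {
  if (!is.null(densities) && max(densities) / min(densities) > 1.02) {
    warning("component densities differ by more than 2%; the equal-density ",
            "mass-ratio scalings of the coupling become approximate")
  }
  afs <- validate_af_table(afs)
  keys <- unique(afs[, c("particle", "energy_MeV")])
  keys <- keys[order(keys$particle, keys$energy_MeV), ]
  rows <- lapply(seq_len(nrow(keys)), function(r) {
    pt <- keys$particle[r]
    en <- keys$energy_MeV[r]
    gM <- function(tgt, src) af_lookup(afs, "macro", src, tgt, pt, en)
    M_LCTM_LBM <- gM("LCTM", "LBM")
    M_LBM_LBM <- gM("LBM", "LBM")
    M_LCTM_LCTM <- gM("LCTM", "LCTM")
    M_LBM_LCTM <- gM("LBM", "LCTM")
    if (pt == "photon" && en > photon_vf_threshold) {
      if (is.null(region_volume_fractions)) {
        stop("photon rows above the volume-fraction threshold require ",
             "region_volume_fractions")
      }
      vf <- region_volume_fractions
      u_LP_LBmu <- c(af = unname(vf["LP"]), rel_err = 0)
      u_LBmu_LP <- c(af = unname(vf["LBmu"]), rel_err = 0)
      u_LP_LP <- c(af = unname(vf["LP"]), rel_err = 0)
      u_LBmu_LBmu <- c(af = unname(vf["LBmu"]), rel_err = 0)
    } else {
      gU <- function(tgt, src) af_lookup(afs, "micro", src, tgt, pt, en)
      u_LP_LBmu <- gU("LP", "LBmu")
      u_LBmu_LP <- gU("LBmu", "LP")
      u_LP_LP <- gU("LP", "LP")
      u_LBmu_LBmu <- gU("LBmu", "LBmu")
    }
    pb <- crossfire_P_from_B(M_LCTM_LBM["af"], u_LP_LBmu["af"],
                             M_LCTM_LCTM["af"], mt,
                             rel_err = c(M_LCTM_LBM["rel_err"],
                                         u_LP_LBmu["rel_err"],
                                         M_LCTM_LCTM["rel_err"]))
    bp <- crossfire_B_from_P(u_LBmu_LP["af"], M_LCTM_LCTM["af"],
                             M_LBM_LCTM["af"], mt,
                             rel_err = c(u_LBmu_LP["rel_err"],
                                         M_LCTM_LCTM["rel_err"],
                                         M_LBM_LCTM["rel_err"]))
    pp <- parenchyma_self(u_LP_LP["af"], M_LCTM_LCTM["af"], mt,
                          rel_err = c(u_LP_LP["rel_err"],
                                      M_LCTM_LCTM["rel_err"]))
    bb <- blood_self(M_LBM_LBM["af"], M_LCTM_LBM["af"], M_LBM_LCTM["af"],
                     u_LBmu_LBmu["af"], M_LCTM_LCTM["af"], mt,
                     rel_err = c(M_LBM_LBM["rel_err"], M_LCTM_LBM["rel_err"],
                                 M_LBM_LCTM["rel_err"],
                                 u_LBmu_LBmu["rel_err"],
                                 M_LCTM_LCTM["rel_err"]),
                     micro_to_macro = micro_to_macro)
    data.frame(particle = pt, energy_MeV = en,
               phi_LBLB = bb$phi, phi_LBLP = bp$phi,
               phi_LPLB = pb$phi, phi_LPLP = pp$phi,
               Phi_LBLB_kg = bb$Phi_per_kg, Phi_LBLP_kg = bp$Phi_per_kg,
               Phi_LPLB_kg = pb$Phi_per_kg, Phi_LPLP_kg = pp$Phi_per_kg,
               relerr_LBLB = bb$rel_err, relerr_LBLP = bp$rel_err,
               relerr_LPLB = pb$rel_err, relerr_LPLP = pp$rel_err)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("coupled_safs", "data.frame")
  out
}

#' Coupled SAF table I/O
#'
#' CSV round trip of the [assemble_coupled_curves()] output.
#'
#' @param x a `coupled_safs` data.frame.
#' @param path file path.
#' @export
write_coupled_safs <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coupled_safs
#' @export
read_coupled_safs <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("coupled_safs", "data.frame")
  out
}
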