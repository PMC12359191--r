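# Toy multiscale organ used by the acceptance suite: a sphere of composite
# tissue holding three orthogonal macroscale vessels, with the composite
# filled by a periodic micro unit cell (one blood cylinder per cell). Every
# structure is fully resolvable on a desk-scale grid, so absorbed fractions
# can be computed both directly and through the two-scale coupling.

build_toy_organ <- function(spacing = 0.004, cell = 0.2, r_micro = 0.05,
                            r_macro = 0.05, R_organ = 0.7) {
  box <- c(1.5, 1.5, 1.5)
  ctr <- box / 2
  label_fun <- function(P) {
    rel <- sweep(P, 2, ctr, `-`)
    in_organ <- rowSums(rel^2) < R_organ^2
    in_macro <- (rel[, 1]^2 + rel[, 2]^2 < r_macro^2) |
      (rel[, 1]^2 + rel[, 3]^2 < r_macro^2) |
      (rel[, 2]^2 + rel[, 3]^2 < r_macro^2)
    mx <- P[, 1] %% cell - cell / 2
    my <- P[, 2] %% cell - cell / 2
    in_micro <- (mx^2 + my^2) < r_micro^2
    ifelse(!in_organ, 0L, ifelse(in_macro, 1L, ifelse(in_micro, 2L, 3L)))
  }
  resolved <- label_grid_from_function(label_fun, c(0, 0, 0), box, spacing,
                                       c("LBM", "LBmu", "LP"))
  macro <- label_grid(
    array(ifelse(resolved$labels == 0L, 0L,
                 ifelse(resolved$labels == 1L, 1L, 2L)),
          dim(resolved$labels)),
    resolved$origin, resolved$spacing, c("LBM", "LCTM"))
  micro <- label_grid_from_function(function(P) {
    ifelse((P[, 1] - cell / 2)^2 + (P[, 2] - cell / 2)^2 < r_micro^2,
           1L, 2L)
  }, c(0, 0, 0), rep(cell, 3), spacing / 2, c("LBmu", "LP"))
  vols <- label_grid_volumes(resolved)
  mt <- mass_table(mL = sum(vols) * 1e-3,
                   mLB = (vols[["LBM"]] + vols[["LBmu"]]) * 1e-3,
                   mLP = vols[["LP"]] * 1e-3,
                   mLBM = vols[["LBM"]] * 1e-3,
                   mLCTM = (vols[["LBmu"]] + vols[["LP"]]) * 1e-3,
                   mLBmu = vols[["LBmu"]] * 1e-3,
                   closure_tol = 1e-9, sex_label = "toy organ")
  list(resolved = resolved, macro = macro, micro = micro, mt = mt)
}

toy_af <- function(tal, regions) {
  sum(tal$deposit_MeV[tal$region %in% regions]) / attr(tal, "emitted_MeV")
}
toy_re <- function(tal, region) tal$rel_err[tal$region == region]

# one transport run on a toy grid
toy_run <- function(grid, source_region, kind, energy, mode, n, seed) {
  cfg <- transport_config(n = n, seed = seed, boundary_mode = mode,
                          source_region = source_region)
  run_transport(grid, particle_spec(kind, energy), cfg)
}

# the four macroscale + four microscale AF rows at one (kind, energy),
# already coupled into the four overall absorbed fractions (with errors)
toy_coupled <- function(org, kind, energy, n, seed,
                        macro_mode = "escape") {
  ma_B <- toy_run(org$macro, "LBM", kind, energy, macro_mode, n, seed + 1)
  ma_C <- toy_run(org$macro, "LCTM", kind, energy, macro_mode, n, seed + 2)
  mi_B <- toy_run(org$micro, "LBmu", kind, energy, "reflective", n, seed + 3)
  mi_P <- toy_run(org$micro, "LP", kind, energy, "reflective", n, seed + 4)
  mt <- org$mt
  pb <- crossfire_P_from_B(toy_af(ma_B, "LCTM"), toy_af(mi_B, "LP"),
                           toy_af(ma_C, "LCTM"), mt,
                           rel_err = c(toy_re(ma_B, "LCTM"),
                                       toy_re(mi_B, "LP"),
                                       toy_re(ma_C, "LCTM")))
  bp <- crossfire_B_from_P(toy_af(mi_P, "LBmu"), toy_af(ma_C, "LCTM"),
                           toy_af(ma_C, "LBM"), mt,
                           rel_err = c(toy_re(mi_P, "LBmu"),
                                       toy_re(ma_C, "LCTM"),
                                       toy_re(ma_C, "LBM")))
  pp <- parenchyma_self(toy_af(mi_P, "LP"), toy_af(ma_C, "LCTM"), mt,
                        rel_err = c(toy_re(mi_P, "LP"),
                                    toy_re(ma_C, "LCTM")))
  bb <- blood_self(toy_af(ma_B, "LBM"), toy_af(ma_B, "LCTM"),
                   toy_af(ma_C, "LBM"), toy_af(mi_B, "LBmu"),
                   toy_af(ma_C, "LCTM"), mt,
                   rel_err = c(toy_re(ma_B, "LBM"), toy_re(ma_B, "LCTM"),
                               toy_re(ma_C, "LBM"), toy_re(mi_B, "LBmu"),
                               toy_re(ma_C, "LCTM")))
  list(phi = c(LBLB = bb$phi, LPLB = pb$phi, LBLP = bp$phi, LPLP = pp$phi),
       Phi = c(LBLB = bb$Phi_per_kg, LPLB = pb$Phi_per_kg,
               LBLP = bp$Phi_per_kg, LPLP = pp$Phi_per_kg),
       rel_err = c(LBLB = bb$rel_err, LPLB = pb$rel_err,
                   LBLP = bp$rel_err, LPLP = pp$rel_err))
}
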