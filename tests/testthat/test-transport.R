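# Toy transport tests use 1e4-2e4 histories (scaled down from production
# runs) -- plenty for the 3-sigma checks here since the Rcpp engine reports
# per-region statistical errors.

test_that("range and attenuation tables are monotone and hit known knots", {
  rt <- build_range_table("alpha")
  expect_true(all(diff(rt$range_mm) >= 0))
  # the 5.87 MeV alpha has a 48 um CSDA range in tissue
  expect_equal(rt$range_mm_of(5.87), 0.048, tolerance = 0.02)
  re <- build_range_table("electron")
  expect_true(all(diff(re$range_mm) >= 0))
  expect_equal(re$range_mm_of(0.934), 4.0, tolerance = 0.03)
  dense <- 10^seq(log10(0.01), log10(2), length.out = 200)
  expect_true(all(diff(re$range_mm_of(dense)) > 0))
  at <- build_attenuation_table()
  expect_true(all(diff(at$mu_mm_of(10^seq(-2, 0.5, length.out = 100))) < 0))
  # water at 1 MeV: mu/rho = 0.0707 cm^2/g -> 0.00707 /mm at unit density
  expect_equal(at$mu_mm_of(1.0), 0.00707, tolerance = 1e-3)
})

test_that("reflective single-region box conserves energy exactly", {
  labs <- array(1L, c(8, 8, 8))
  g <- label_grid(labs, c(0, 0, 0), 0.125, "tissue")
  for (src in list(particle_spec("alpha", 5.87),
                   particle_spec("electron", 0.5),
                   particle_spec("photon", 0.3))) {
    cfg <- transport_config(n = 2000L, seed = 5, boundary_mode = "reflective",
                            source_region = "tissue")
    tal <- run_transport(g, src, cfg)
    expect_equal(sum(tal$deposit_MeV), attr(tal, "emitted_MeV"),
                 tolerance = 1e-9)
    # self-AF exactly 1
    af <- estimate_absorbed_fractions(tal, c(tissue = "tissue"),
                                      scale = "micro")
    expect_equal(af$af, 1, tolerance = 1e-9)
  }
})

test_that("alpha point source in a sphere: constant-LET closed form", {
  # sphere radius R centered in a box, homogeneous; point-isotropic source
  # at the center deposits R/range of its energy inside the sphere
  R <- 0.03 # mm
  range_mm <- 0.048 # 5.87 MeV alpha
  g <- label_grid_from_function(function(P) {
    ifelse(rowSums(sweep(P, 2, c(0.1, 0.1, 0.1))^2) < R^2, 1L, 2L)
  }, c(0, 0, 0), c(0.2, 0.2, 0.2), 0.002, c("sphere", "rest"))
  n <- 20000L
  cfg <- transport_config(n = n, seed = 7, boundary_mode = "reflective",
                          source_region = "sphere")
  tal <- run_transport(g, particle_spec("alpha", 5.87), cfg,
                       source_points = matrix(rep(0.1, 3), 1))
  af_sphere <- tal$deposit_MeV[tal$region == "sphere"] /
    attr(tal, "emitted_MeV")
  sigma <- tal$rel_err[tal$region == "sphere"] * af_sphere
  expect_lt(abs(af_sphere - R / range_mm), 3 * sigma + 0.01)
})

test_that("high-energy photons in a reflective box deposit by volume", {
  g <- two_region_box_grid(n = 20L, split = 0.3)
  vf <- label_grid_volumes(g)
  vf <- vf / sum(vf)
  cfg <- transport_config(n = 20000L, seed = 3,
                          boundary_mode = "reflective",
                          source_region = "LBM")
  tal <- run_transport(g, particle_spec("photon", 1.0), cfg)
  for (r in c("LBM", "LCTM")) {
    af <- tal$deposit_MeV[tal$region == r] / attr(tal, "emitted_MeV")
    sigma <- tal$rel_err[tal$region == r] * af
    expect_lt(abs(af - vf[[r]]), 3 * sigma)
  }
})

test_that("escape-mode AF decreases with particle energy", {
  # small sphere of tissue in void; alphas of increasing energy escape more
  g <- label_grid_from_function(function(P) {
    ifelse(rowSums(sweep(P, 2, c(0.05, 0.05, 0.05))^2) < 0.04^2, 1L, 0L)
  }, c(0, 0, 0), c(0.1, 0.1, 0.1), 0.002, "sphere")
  afs <- vapply(c(5.8, 7.4, 8.78), function(E) {
    cfg <- transport_config(n = 5000L, seed = 11, boundary_mode = "escape",
                            source_region = "sphere")
    tal <- run_transport(g, particle_spec("alpha", E), cfg)
    sum(tal$deposit_MeV[tal$region == "sphere"]) / attr(tal, "emitted_MeV")
  }, numeric(1))
  expect_true(all(diff(afs) < 0))
  expect_true(all(afs > 0 & afs < 1))
})

test_that("reciprocity holds in a uniform reflective geometry", {
  g <- two_region_box_grid(n = 16L, split = 0.35)
  masses <- label_grid_volumes(g) # unit density
  for (src in list(particle_spec("electron", 0.134),
                   particle_spec("photon", 0.08))) {
    af <- list()
    for (reg in c("LBM", "LCTM")) {
      cfg <- transport_config(n = 20000L, seed = 17,
                              boundary_mode = "reflective",
                              source_region = reg)
      tal <- run_transport(g, src, cfg)
      af[[reg]] <- tal
    }
    # Phi(LCTM <- LBM) vs Phi(LBM <- LCTM)
    p1 <- af$LBM$deposit_MeV[af$LBM$region == "LCTM"] /
      attr(af$LBM, "emitted_MeV") / masses[["LCTM"]]
    p2 <- af$LCTM$deposit_MeV[af$LCTM$region == "LBM"] /
      attr(af$LCTM, "emitted_MeV") / masses[["LBM"]]
    s1 <- p1 * af$LBM$rel_err[af$LBM$region == "LCTM"]
    s2 <- p2 * af$LCTM$rel_err[af$LCTM$region == "LBM"]
    expect_lt(abs(p1 - p2), 3 * sqrt(s1^2 + s2^2))
  }
})

test_that("tally grouping arithmetic and additivity", {
  tal <- structure(
    data.frame(region = c("void", "A", "B", "C"),
               deposit_MeV = c(0, 3, 1, 2), rel_err = c(0, 0.01, 0.02, 0.01)),
    class = c("energy_deposit_tally", "data.frame"),
    emitted_MeV = 10, histories = 100L, boundary_mode = "escape",
    source_region = "A", particle = "alpha", energy_MeV = 5)
  af <- estimate_absorbed_fractions(tal, c(A = "G", B = "G", C = "H"))
  expect_equal(af$af[af$target == "G"], 0.4)
  expect_equal(af$af[af$target == "H"], 0.2)
  # additivity against a merged group
  af2 <- estimate_absorbed_fractions(tal, c(A = "all", B = "all", C = "all"))
  expect_equal(af2$af, sum(af$af), tolerance = 1e-12)
  # uncovered region errors
  expect_error(estimate_absorbed_fractions(tal, c(A = "G", B = "G")), "C")
})

test_that("transport is deterministic per seed and AF tables round trip", {
  g <- two_region_box_grid(n = 10L)
  cfg <- transport_config(n = 500L, seed = 23, boundary_mode = "escape",
                          source_region = "LBM")
  t1 <- run_transport(g, particle_spec("alpha", 6.0), cfg)
  t2 <- run_transport(g, particle_spec("alpha", 6.0), cfg)
  expect_equal(t1$deposit_MeV, t2$deposit_MeV, tolerance = 1e-15)
  af <- estimate_absorbed_fractions(t1, c(LBM = "LBM", LCTM = "LCTM"))
  tmp <- tempfile(fileext = ".csv")
  write_af_table(af, tmp)
  expect_equal(read_af_table(tmp)$af, af$af, tolerance = 1e-12)
  expect_error(read_af_table({
    f <- tempfile()
    writeLines("scale,source\nmacro,LBM", f)
    f
  }), "lacks column")
})

test_that("transport runs on tetrahedral meshes with barycentric sources", {
  m <- box_tet_mesh(c(0, 0, 0), c(1, 1, 1), n = 4L)
  cen <- element_centroids(m)
  m$elements$region <- ifelse(cen[, 1] < 0.25, 1L, 2L)
  m$regions <- list(`1` = "slab", `2` = "bulk")
  cfg <- transport_config(n = 5000L, seed = 2, boundary_mode = "reflective",
                          resolution = 32L, source_region = "slab")
  tal <- run_transport(m, particle_spec("photon", 1.0), cfg)
  expect_equal(sum(tal$deposit_MeV), attr(tal, "emitted_MeV"),
               tolerance = 1e-9)
  # high-energy photon: deposition by volume fraction
  af_slab <- tal$deposit_MeV[tal$region == "slab"] / attr(tal, "emitted_MeV")
  expect_equal(af_slab, 0.25,
               tolerance = 3 * tal$rel_err[tal$region == "slab"] + 0.01)
})
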