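test_that("parenchyma derivation reproduces the published derived row", {
  liver <- reference_composition("icrp_liver")
  blood <- reference_composition("icrp_blood")
  mt <- male_masses()
  par <- derive_parenchyma_composition(liver, blood, mt$mL, mt$mLBM, mt$mLCTM)
  pct <- 100 * par$fractions
  expect_equal(round(pct[["C"]], 2), 13.38)
  expect_equal(round(pct[["O"]], 2), 72.12)
  expect_equal(round(pct[["H"]], 2), 10.20)
  expect_equal(round(pct[["N"]], 2), 3.08)
  # the Fe deficit from rounded inputs is clamped, mirroring the table
  expect_true("Fe" %in% attr(par, "clamped_elements"))
  expect_equal(sum(par$fractions), 1, tolerance = 1e-12)
  expect_equal(par$density, liver$density)
})

test_that("parenchyma derivation edge cases", {
  liver <- reference_composition("icrp_liver")
  # identical blood: output equals input composition
  out <- derive_parenchyma_composition(liver, liver, 2000, 300, 1700)
  expect_equal(out$fractions, liver$fractions, tolerance = 1e-12)
  # strongly inconsistent inputs error, naming the element
  hot <- elemental_composition(c(H = 0.10, C = 0.50, O = 0.40), 1.06)
  base <- elemental_composition(c(H = 0.10, C = 0.05, O = 0.85), 1.06)
  expect_error(
    derive_parenchyma_composition(base, hot, 1000, 500, 500),
    "C")
})

test_that("round trip: derived parenchyma remixed with blood gives liver", {
  # construct a consistent liver from known parenchyma + blood (no clamping)
  blood <- reference_composition("icrp_blood")
  par0 <- reference_composition("parenchyma_derived")
  mt <- male_masses()
  mL <- mt$mLBM + mt$mLCTM # exactly closed total for this synthetic liver
  liver_fr <- (mt$mLBM * blood$fractions + mt$mLCTM * par0$fractions) / mL
  liver <- elemental_composition(liver_fr / sum(liver_fr), 1.060)
  out <- derive_parenchyma_composition(liver, blood, mL, mt$mLBM, mt$mLCTM)
  # printed reference row sums to 100.01%; compare on normalized fractions
  expect_equal(out$fractions, par0$fractions / sum(par0$fractions),
               tolerance = 1e-6)
})

test_that("blood partition shares match the published split and sum to 100", {
  m <- blood_partition_summary(male_masses())
  expect_equal(round(m[["macro"]], 1), 31.5)
  f <- blood_partition_summary(reference_mass_table("female"))
  expect_equal(round(f[["macro"]], 1), 30.6)
  expect_identical(m[["macro"]] + m[["micro"]], 100)
  # all-micro degenerate case
  mt0 <- mass_table(mL = 100, mLB = 20, mLP = 80, mLBM = 0, mLCTM = 100,
                    mLBmu = 20)
  expect_equal(blood_partition_summary(mt0)[["macro"]], 0)
  expect_equal(blood_partition_summary(mt0)[["micro"]], 100)
})

test_that("sinusoid blood share reproduces the ~60% statement", {
  share <- sinusoid_blood_share(male_masses(), reference_lobule_fractions())
  expect_equal(round(share), 60)
  expect_equal(round(share, 1), 60.2) # frozen: 100*383.77*(15.38/17.49)/560.48
  # degenerate: all microscale blood in sinusoids, all blood microscale
  lf <- lobule_mass_fractions(
    c(central_vein = 0, portal_arteries = 0, portal_veins = 0,
      bile_ducts = 0, bile_canaliculi = 0, sinusoids = 0.2,
      space_of_disse = 0, kupffer_cells = 0, hepatocytes = 0.8), 1e-4)
  mt <- mass_table(mL = 100, mLB = 20, mLP = 80, mLBM = 0, mLCTM = 100,
                   mLBmu = 20)
  expect_equal(sinusoid_blood_share(mt, lf), 100)
  # missing compartment errors
  lf2 <- lf
  names(lf2$fractions)[6] <- "sinusoid" # corrupt the key
  expect_error(sinusoid_blood_share(mt, lf2), "sinusoids")
})

test_that("closure validation flags residuals beyond tolerance", {
  rep <- validate_closure(male_masses(), tol = 0.05)
  expect_true(all(rep$pass))
  expect_equal(rep$residual_g[rep$identity == "mLB = mLBM + mLBmu"], 0.01,
               tolerance = 1e-9)
  # exact table: zero residuals
  mt <- mass_table(mL = 100, mLB = 20, mLP = 80, mLBM = 5, mLCTM = 95,
                   mLBmu = 15)
  expect_true(all(validate_closure(mt)$residual_g < 1e-12))
  # perturbation flagged (construct the broken list directly: the
  # constructor itself rejects it)
  broken <- list(mL = 100, mLB = 20, mLP = 80, mLBM = 5, mLCTM = 95,
                 mLBmu = 16)
  expect_false(all(validate_closure(broken, tol = 0.05)$pass))
  expect_error(mass_table(mL = 100, mLB = 20, mLP = 80, mLBM = 5,
                          mLCTM = 95, mLBmu = 16), "closure")
})

test_that("solve_cell_composition recovers a constructed unknown", {
  target_known <- elemental_composition(c(H = 0.1, C = 0.2, O = 0.7), 1.05)
  # 50/50 with one known component equal to the target -> unknown = target
  out <- solve_cell_composition(
    target_known,
    list(a = list(fraction = 0.5, composition = target_known),
         b = list(fraction = 0.5, composition = NULL)),
    free_components = "b")
  expect_equal(out$fractions, target_known$fractions, tolerance = 1e-12)
  expect_true(all(abs(attr(out, "residuals")) < 1e-12))

  # three components, target built by forward mixing a known answer
  known1 <- elemental_composition(c(H = 0.11, C = 0.05, O = 0.84), 1.00)
  answer <- elemental_composition(c(H = 0.10, C = 0.15, O = 0.75), 1.07)
  fr <- c(0.2, 0.3, 0.5)
  mix <- fr[1] * known1$fractions + (fr[2] + fr[3]) * answer$fractions
  dens <- 1 / (fr[1] / known1$density + (fr[2] + fr[3]) / answer$density)
  target <- elemental_composition(mix, dens)
  out <- solve_cell_composition(
    target,
    list(k = list(fraction = fr[1], composition = known1),
         f1 = list(fraction = fr[2], composition = NULL),
         f2 = list(fraction = fr[3], composition = NULL)),
    free_components = c("f1", "f2"))
  expect_equal(out$fractions, answer$fractions, tolerance = 1e-10)
  expect_equal(out$density, answer$density, tolerance = 1e-10)
  # zero free fraction errors
  expect_error(solve_cell_composition(
    target, list(k = list(fraction = 1, composition = known1),
                 f = list(fraction = 0, composition = NULL)),
    free_components = "f"), "free fraction")
})

test_that("cell-material fit against the published tables is reported", {
  # The published hepatocyte/Kupffer row is NOT asserted: the reference's
  # fit procedure is unstated and simple mass balance does not reproduce it.
  # We only require the solver to run and report residuals.
  mats <- lobule_component_materials("text")
  lf <- reference_lobule_fractions()
  target <- reference_composition("parenchyma_derived")
  free <- c("kupffer_cells", "hepatocytes")
  comps <- lapply(names(lf$fractions), function(nm) {
    list(fraction = lf$fractions[[nm]],
         composition = if (nm %in% free) NULL else
           reference_composition(mats[[nm]]))
  })
  names(comps) <- names(lf$fractions)
  out <- solve_cell_composition(target, comps, free)
  expect_true(all(is.finite(out$fractions)))
  expect_equal(sum(out$fractions), 1, tolerance = 1e-9)
  printed <- reference_composition("cell_material")
  # report-style check: solved carbon is in the right ballpark (not equality)
  expect_lt(abs(out$fractions[["C"]] - printed$fractions[["C"]]), 0.05)
})

test_that("mass table and composition JSON I/O round trips", {
  tmp <- tempfile(fileext = ".json")
  mt <- male_masses()
  write_mass_table(mt, tmp)
  expect_equal(read_mass_table(tmp)$mLCTM, mt$mLCTM)
  tmp2 <- tempfile(fileext = ".json")
  comp <- reference_composition("icrp_blood")
  write_composition(comp, tmp2)
  expect_equal(read_composition(tmp2)$fractions, comp$fractions)
  # percent flag accepted on read
  writeLines(jsonlite::toJSON(list(
    fractions = list(H = 10, C = 20, O = 70), density = 1.0,
    percent = TRUE), auto_unbox = TRUE), tmp2)
  expect_equal(sum(read_composition(tmp2)$fractions), 1)
})
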