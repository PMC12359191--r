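#' Radionuclide decay scheme
#'
#' Per-radiation rows of a nuclide's decay data: radiation class, energy
#' `E_i` (MeV) and yield `Y_i` (per nuclear transformation). Beta spectra may
#' be represented by a single mean-energy row or a multi-row discretized
#' spectrum.
#'
#' @param nuclide nuclide name.
#' @param rows data.frame with columns `class` (one of `photon`, `beta`,
#'   `electron`, `alpha`, `alpha_recoil`), `energy_MeV` (> 0) and `yield`
#'   (> 0).
#' @return an object of class `decay_scheme`.
#' @export
decay_scheme <- function(nuclide, rows) {
  valid <- c("photon", "beta", "electron", "alpha", "alpha_recoil")
  stopifnot(all(c("class", "energy_MeV", "yield") %in% names(rows)))
  bad <- !rows$class %in% valid
  if (any(bad)) {
    stop("unknown radiation class(es): ",
         paste(unique(rows$class[bad]), collapse = ", "))
  }
  if (any(rows$energy_MeV <= 0)) stop("energies must be > 0")
  if (any(rows$yield <= 0)) stop("yields must be > 0")
  structure(list(nuclide = nuclide,
                 rows = rows[, c("class", "energy_MeV", "yield")]),
            class = "decay_scheme")
}

#' @export
print.decay_scheme <- function(x, ...) {
  cat(sprintf("decay_scheme %s: %d radiation row(s)\n", x$nuclide,
              nrow(x$rows)))
  invisible(x)
}

#' Read and write decay scheme CSV files
#'
#' CSV with header `nuclide,class,energy_MeV,yield`; one file holds one
#' nuclide.
#'
#' @param path file path.
#' @param scheme a [decay_scheme()] (writer).
#' @return reader: a [decay_scheme()]; writer: `path` invisibly.
#' @export
read_decay_scheme <- function(path) {
  d <- tryCatch(utils::read.csv(path), error = function(e) {
    stop("cannot parse decay scheme file: ", conditionMessage(e))
  })
  if (nrow(d) == 0L) stop("decay scheme file is empty: ", path)
  need <- c("nuclide", "class", "energy_MeV", "yield")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("decay scheme lacks column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(d$energy_MeV) | !is.finite(d$yield))
  if (length(bad)) {
    stop(sprintf("decay scheme %s: malformed row at data line %d", path,
                 bad[1L]))
  }
  decay_scheme(d$nuclide[1L], d)
}

#' @rdname read_decay_scheme
#' @export
write_decay_scheme <- function(scheme, path) {
  d <- cbind(nuclide = scheme$nuclide, scheme$rows)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Monotone cubic interpolation of an SAF energy curve
#'
#' Piecewise cubic Hermite interpolation (Fritsch-Carlson monotone tangents)
#' of specific absorbed fractions versus source particle energy, carried out
#' on a log10 energy axis because SAF curves span decades of energy (set
#' `log_energy = FALSE` for a linear axis). The interpolant passes through
#' every knot, preserves monotone runs without overshoot, and refuses to
#' extrapolate.
#'
#' @param energies strictly increasing knot energies (MeV, >= 2 knots).
#' @param values SAF values at the knots.
#' @param query energies to evaluate (must lie within the knot range).
#' @param log_energy interpolate on log10(energy) (default TRUE).
#' @return interpolated values at `query`.
#' @export
interpolate_saf <- function(energies, values, query, log_energy = TRUE) {
  if (length(energies) < 2L) stop("need at least 2 knots")
  if (any(diff(energies) <= 0)) {
    stop("knot energies must be strictly increasing")
  }
  if (any(query < energies[1L] - 1e-12) ||
      any(query > energies[length(energies)] + 1e-12)) {
    stop(sprintf("query energy outside the knot range [%g, %g] MeV",
                 energies[1L], energies[length(energies)]))
  }
  x <- if (log_energy) log10(energies) else energies
  xq <- if (log_energy) log10(query) else query
  f <- stats::splinefun(x, values, method = "monoH.FC")
  out <- f(pmin(pmax(xq, x[1L]), x[length(x)]))
  # exact knot reproduction despite log/float round trips
  hit <- match(round(query, 12), round(energies, 12))
  out[!is.na(hit)] <- values[hit[!is.na(hit)]]
  out
}

# map radiation classes onto the particle vocabulary of the SAF curves
class_to_particle <- function(class) {
  switch(class,
         photon = "photon",
         beta = "electron",
         electron = "electron",
         alpha = "alpha",
         alpha_recoil = "alpha",
         stop("unknown radiation class: ", class))
}

# conversion: MeV/kg per decay -> mGy per MBq-second
# 1 MeV = 1.60218e-13 J; 1 MBq = 1e6 decays/s; 1 Gy = 1e3 mGy
MEV_PER_KG_TO_MGY_PER_MBQ_S <- 1.60218e-13 * 1e6 * 1e3

#' S-value of a radionuclide for one source-target pair
#'
#' MIRD-schema S-value: `S(rT <- rS) = sum_i E_i Y_i Phi(rT <- rS, E_i)`,
#' with the SAF evaluated at each radiation energy by [interpolate_saf()]
#' and the result converted to mGy/(MBq s). Beta and electron rows use the
#' electron SAF curves; alpha-recoil rows use the alpha curves at their own
#' energy.
#'
#' @param scheme a [decay_scheme()].
#' @param saf_curves named list (by particle: `photon`, `electron`, `alpha`)
#'   of lists `list(energy_MeV =, Phi_per_kg =)` giving the SAF knots of the
#'   source-target pair.
#' @return list with `S_mGy_per_MBq_s` and the per-radiation-class
#'   subtotals.
#' @export
s_value <- function(scheme, saf_curves) {
  stopifnot(inherits(scheme, "decay_scheme"))
  per_class <- vapply(split(seq_len(nrow(scheme$rows)), scheme$rows$class),
                      function(idx) {
    total <- 0
    for (i in idx) {
      cls <- scheme$rows$class[i]
      e <- scheme$rows$energy_MeV[i]
      y <- scheme$rows$yield[i]
      part <- class_to_particle(cls)
      curve <- saf_curves[[part]]
      if (is.null(curve)) {
        stop(sprintf("no SAF curve for particle '%s' (decay row: %s %g MeV)",
                     part, cls, e))
      }
      Phi <- tryCatch(
        interpolate_saf(curve$energy_MeV, curve$Phi_per_kg, e),
        error = function(err) {
          stop(sprintf("decay row (%s, %g MeV) not covered by the %s curve: %s",
                       cls, e, part, conditionMessage(err)))
        })
      total <- total + e * y * Phi
    }
    total * MEV_PER_KG_TO_MGY_PER_MBQ_S
  }, numeric(1))
  list(S_mGy_per_MBq_s = sum(per_class), per_class = per_class)
}

#' S-value table for the four blood/parenchyma combinations
#'
#' Computes `S(LB <- LB)`, `S(LB <- LP)`, `S(LP <- LB)` and `S(LP <- LP)`
#' for a nuclide from a coupled SAF table.
#'
#' @param scheme a [decay_scheme()].
#' @param coupled a `coupled_safs` table from [assemble_coupled_curves()].
#' @return one-row data.frame with the four S-values (mGy/(MBq s)); the
#'   `per_class` attribute holds radiation-class subtotals per combination.
#' @export
s_value_table <- function(scheme, coupled) {
  combos <- c(LBLB = "Phi_LBLB_kg", LBLP = "Phi_LBLP_kg",
              LPLB = "Phi_LPLB_kg", LPLP = "Phi_LPLP_kg")
  curves_for <- function(col) {
    parts <- unique(coupled$particle)
    out <- list()
    for (p in parts) {
      sub <- coupled[coupled$particle == p, ]
      sub <- sub[order(sub$energy_MeV), ]
      out[[p]] <- list(energy_MeV = sub$energy_MeV, Phi_per_kg = sub[[col]])
    }
    out
  }
  vals <- lapply(combos, function(col) s_value(scheme, curves_for(col)))
  out <- data.frame(nuclide = scheme$nuclide,
                    S_LBLB = vals$LBLB$S_mGy_per_MBq_s,
                    S_LBLP = vals$LBLP$S_mGy_per_MBq_s,
                    S_LPLB = vals$LPLB$S_mGy_per_MBq_s,
                    S_LPLP = vals$LPLP$S_mGy_per_MBq_s)
  attr(out, "per_class") <- lapply(vals, `[[`, "per_class")
  out
}

#' Partition imaged organ activity into blood and parenchyma
#'
#' From the measured blood activity concentration, blood-inclusive organ
#' concentration and organ volume, with a reference volume-fractional blood
#' content: `A(LB) = C_blood * V * f_blood` and `A(LP) = C_organ * V -
#' A(LB)`. A negative parenchyma activity signals inconsistent
#' concentrations and raises an error.
#'
#' @param C_blood blood activity concentration (MBq/mL).
#' @param C_organ blood-inclusive organ activity concentration (MBq/mL).
#' @param V_organ organ volume (mL).
#' @param f_blood volume-fractional blood content (0-1).
#' @return named vector `c(A_LB = ..., A_LP = ...)` in MBq.
#' @export
activity_partition <- function(C_blood, C_organ, V_organ, f_blood) {
  for (nm in c("C_blood", "C_organ", "V_organ", "f_blood")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("'%s' must be a nonnegative numeric scalar", nm))
    }
  }
  if (f_blood > 1) stop("f_blood must be <= 1")
  A_LB <- C_blood * V_organ * f_blood
  A_LP <- C_organ * V_organ - A_LB
  if (A_LP < 0) {
    stop(sprintf(paste0("negative parenchyma activity (%.4g MBq): blood and ",
                        "organ concentrations are inconsistent"), A_LP))
  }
  c(A_LB = A_LB, A_LP = A_LP)
}

#' Parenchyma absorbed dose rate
#'
#' The organ self-dose term of the MIRD sum replaced by the separate blood
#' and parenchyma source contributions:
#' `Ddot(LP) = sum(external) + A(LP) S(LP <- LP) + A(LB) S(LP <- LB)`.
#'
#' @param A_LB,A_LP activities in MBq.
#' @param S_LPLP,S_LPLB S-values in mGy/(MBq s).
#' @param external_terms optional numeric vector of cross-dose rate terms
#'   from sources outside the liver (mGy/s), summed in.
#' @return dose rate in mGy/s.
#' @export
dose_rate_parenchyma <- function(A_LB, A_LP, S_LPLP, S_LPLB,
                                 external_terms = numeric(0)) {
  for (nm in c("A_LB", "A_LP", "S_LPLP", "S_LPLB")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("'%s' must be a nonnegative numeric scalar", nm))
    }
  }
  sum(external_terms) + A_LP * S_LPLP + A_LB * S_LPLB
}
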