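# Shared fixtures. Everything is generated in code; geometry used in tests
# is scaled down from the package defaults to keep the suite fast (noted
# where it happens).

male_masses <- function() reference_mass_table("male")

# Small lobule specification for geometry tests: same target mass fractions
# and 16 um sinusoids as the default, but a much smaller prism so builds
# take fractions of a second.
small_lobule_spec <- function(seed = 1L, radial_segments = 10L, ...) {
  lobule_spec(apothem_um = 150, height_um = 280,
              radial_segments = radial_segments,
              canaliculus_radius_um = 3, seed = seed, ...)
}

# Tiny two-region reflective box grid: region 1 = slab, region 2 = rest.
# Same material in both -> uniform medium.
two_region_box_grid <- function(n = 24L, split = 0.3, side_mm = 1) {
  labs <- array(2L, dim = c(n, n, n))
  labs[seq_len(max(1L, round(split * n))), , ] <- 1L
  label_grid(labs, origin = c(0, 0, 0), spacing = side_mm / n,
             region_names = c("LBM", "LCTM"))
}

# Uniform-composition micro cell: central cylinder = blood, rest parenchyma
micro_cell_grid <- function(n = 32L, cell_mm = 0.2, r_mm = 0.05) {
  label_grid_from_function(function(P) {
    ifelse((P[, 1] - cell_mm / 2)^2 + (P[, 2] - cell_mm / 2)^2 < r_mm^2,
           1L, 2L)
  }, lo = c(0, 0, 0), hi = rep(cell_mm, 3), spacing = cell_mm / n,
  region_names = c("LBmu", "LP"))
}

# Deterministic small centerline graph: a Y with prescribed radii satisfying
# Murray's law (exponent 3).
y_graph <- function(r_root = 0.4) {
  rc <- r_root * 0.5^(1 / 3)
  centerline_graph(
    nodes = data.frame(id = 1:4,
                       x = c(0, 0, -1, 1), y = c(0, 0, -0.6, 0.6),
                       z = c(0, 1.5, 3, 3)),
    edges = data.frame(id = 1:3, a = c(1, 2, 2), b = c(2, 3, 4),
                       radius = c(r_root, rc, rc), tree = "t"),
    roots = c(t = 1L))
}

unit_sphere_boundary <- function(r = 1) {
  list(type = "sphere", center = c(0, 0, 0), radius = r)
}

# all permutations of 1..n as a matrix (brute-force assignment oracle)
gtools_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- gtools_perms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
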