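#' @useDynLib vasodose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim runif rnorm splinefun isoreg chisq.test
#' @importFrom utils read.csv write.csv head tail
#' @importFrom tools file_ext
NULL

# Run `code` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic operations in the package
# funnel through this so one seed argument pins the whole result.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

unitize <- function(a) {
  n <- vnorm(a)
  if (n == 0) stop("cannot normalize a zero vector")
  a / n
}

# A deterministic vector orthogonal to `a` (used for degenerate rotation axes).
any_perpendicular <- function(a) {
  a <- unitize(a)
  ref <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitize(vcross(a, ref))
}

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  }
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vasodose_extdata <- function(file) {
  path <- system.file("extdata", file, package = "vasodose")
  if (path == "") stop("bundled data file not found: ", file)
  path
}
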