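## Small numerical helpers shared across modules. All coordinates are DICOM
## patient coordinates in millimetres.

#' Cross product of two 3-vectors
#' @param a,b numeric length-3 vectors.
#' @return numeric length-3 vector a x b.
#' @keywords internal
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(x) sqrt(sum(x * x))

unit3 <- function(x) {
  n <- vnorm(x)
  if (n < .Machine$double.eps^0.75)
    stop("cannot normalize a (near-)zero vector")
  x / n
}

#' Scalar triple product det[a, b, c]
#' @keywords internal
det3 <- function(a, b, c) sum(a * cross3(b, c))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Row-wise norms of an n x 3 matrix.
rowNorms <- function(m) sqrt(rowSums(m * m))

## Cumulative trapezoid integral of y over x, starting at 0.
cumTrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  dx <- diff(x)
  c(0, cumsum(dx * (y[-n] + y[-1L]) / 2))
}

## 4th-order finite differences of a vector-valued function f on [0,1]:
## central in the interior, one-sided 5-point stencils at the ends. f(t)
## must return a length-k vector.
fdDeriv <- function(f, t, h = 1e-4) {
  t <- as.numeric(t)
  ev <- function(tt) f(tt)
  vapply(t, function(ti) {
    if (ti - 2 * h >= 0 && ti + 2 * h <= 1) {
      (ev(ti - 2 * h) - 8 * ev(ti - h) + 8 * ev(ti + h) - ev(ti + 2 * h)) /
        (12 * h)
    } else if (ti + 4 * h <= 1) {
      (-25 * ev(ti) + 48 * ev(ti + h) - 36 * ev(ti + 2 * h) +
         16 * ev(ti + 3 * h) - 3 * ev(ti + 4 * h)) / (12 * h)
    } else {
      (25 * ev(ti) - 48 * ev(ti - h) + 36 * ev(ti - 2 * h) -
         16 * ev(ti - 3 * h) + 3 * ev(ti - 4 * h)) / (12 * h)
    }
  }, ev(t[1L]))
}

## Deterministic orthonormal completion: two unit vectors spanning the plane
## orthogonal to unit vector e. Picks the coordinate axis least aligned with e.
orthoFrame <- function(e) {
  k <- diag(3)[, which.min(abs(e))]
  f1 <- unit3(cross3(k, e))
  f2 <- cross3(e, f1)
  list(f1 = f1, f2 = f2)
}

## Condition constructors: texturization distinguishes "outside the volume"
## and "geometry not supported" from programming errors.
outOfVolumeError <- function(msg) {
  structure(class = c("outOfVolumeError", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

nonRegularError <- function(msg) {
  structure(class = c("nonRegularError", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

## Run code with a temporarily seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
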