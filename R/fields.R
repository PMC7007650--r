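## Analytic gray-level fields for phantom volumes. Each field has a known
## closed form so texturization output can be checked against ground truth.

#' Trilinear ramp field
#'
#' \code{f(x,y,z) = c0 + cx x + cy y + cz z + cxy xy + cxz xz + cyz yz +
#' cxyz xyz}: exactly trilinear, so trilinear interpolation of its samples
#' must reproduce it up to rounding.
#'
#' @param coef named numeric vector with any of \code{c0, cx, cy, cz, cxy,
#'   cxz, cyz, cxyz}; missing terms are 0.
#' @param valueRange integer gray bounds \code{c(lo, hi)} values clamp into.
#' @return an \linkS4class{AnalyticField}.
#' @examples
#' f <- trilinearRampField(c(cx = 1, cy = 2, cz = 3))
#' groundTruthGray(f, c(1, 1, 1))   # 6
#' @export
trilinearRampField <- function(coef = c(cx = 1, cy = 2, cz = 3),
                               valueRange = c(0L, 4095L)) {
  full <- c(c0 = 0, cx = 0, cy = 0, cz = 0, cxy = 0, cxz = 0, cyz = 0,
            cxyz = 0)
  stopifnot(!is.null(names(coef)), all(names(coef) %in% names(full)))
  full[names(coef)] <- coef
  new("AnalyticField", kind = "trilinear_ramp",
      params = list(coef = full), valueRange = as.numeric(valueRange))
}

#' Bright ellipsoidal shell with localized defects
#'
#' A shell of revolution (semi-axes \code{a} along \code{axis}, \code{b}
#' equatorial) of given relative thickness is bright; spherical-cap defect
#' patches (center directions + angular radii) punch background-valued
#' holes, emulating tears in the tissue sheath around a bright structure.
#'
#' @param center,axis shell center (mm) and unit axis.
#' @param a,b semi-axes (mm).
#' @param thickness shell thickness in normalized radius units (the shell is
#'   \code{|rho(q) - 1| <= thickness / 2} with
#'   \code{rho^2 = (h/a)^2 + (r/b)^2}).
#' @param defects list of \code{list(dir = unit 3-vector, angle = radians)}.
#' @param background,bright gray levels.
#' @inheritParams trilinearRampField
#' @export
brightShellField <- function(center = c(0, 0, 0), axis = c(0, 0, 1),
                             a = 20, b = 20, thickness = 0.12,
                             defects = list(), background = 100,
                             bright = 3000, valueRange = c(0L, 4095L)) {
  new("AnalyticField", kind = "bright_shell_with_defects",
      params = list(center = center, axis = unit3(axis), a = a, b = b,
                    thickness = thickness, defects = defects,
                    background = background, bright = bright),
      valueRange = as.numeric(valueRange))
}

#' Curved bright tube with a bulge
#'
#' A tube around a Bezier centerline whose radius swells by a Gaussian bump
#' (an aneurysm-like dilation). Intensity peaks on the centerline and decays
#' quadratically to background at the local tube radius.
#'
#' @param controlPoints centerline Bezier control points (mm).
#' @param radius base tube radius (mm).
#' @param bulgeAmp relative radius amplification at the bulge peak.
#' @param bulgeCenter,bulgeWidth bump location/width in curve parameter.
#' @param background,peak gray levels.
#' @inheritParams trilinearRampField
#' @export
brightTubeField <- function(controlPoints, radius = 6, bulgeAmp = 0.8,
                            bulgeCenter = 0.5, bulgeWidth = 0.12,
                            background = 100, peak = 3000,
                            valueRange = c(0L, 4095L)) {
  curve <- bezierCurve(controlPoints)
  tDense <- seq(0, 1, length.out = 512L)
  new("AnalyticField", kind = "bright_tube_with_bulge",
      params = list(curve = curve, samples = curveEval(curve, tDense, 0L),
                    tDense = tDense, radius = radius, bulgeAmp = bulgeAmp,
                    bulgeCenter = bulgeCenter, bulgeWidth = bulgeWidth,
                    background = background, peak = peak),
      valueRange = as.numeric(valueRange))
}

#' Dental-arch phantom field
#'
#' Vertical bright cylinders (tooth stand-ins) placed along the parabola
#' \code{y = arch * x^2}, following the observation that the jaw line is
#' well approximated by a parabola.
#'
#' @param arch parabola coefficient (1/mm).
#' @param xPositions cylinder centers' x coordinates (mm).
#' @param cylRadius cylinder radius (mm).
#' @param zRange vertical extent \code{c(zLo, zHi)} of the cylinders (mm).
#' @param background,bright gray levels.
#' @inheritParams trilinearRampField
#' @export
dentalArchField <- function(arch = 0.02, xPositions = seq(-25, 25, by = 5),
                            cylRadius = 2.2, zRange = c(-8, 8),
                            background = 100, bright = 3000,
                            valueRange = c(0L, 4095L)) {
  centers <- cbind(xPositions, arch * xPositions^2)
  new("AnalyticField", kind = "dental_arch",
      params = list(arch = arch, centers = centers, cylRadius = cylRadius,
                    zRange = zRange, background = background,
                    bright = bright),
      valueRange = as.numeric(valueRange))
}

#' Exact analytic gray value of a field at 3D points
#'
#' The pre-rounding ground truth used as oracle by the texturization tests.
#' Values are clamped into the field's \code{valueRange} but not rounded.
#'
#' @param field an \linkS4class{AnalyticField}.
#' @param p a 3-vector or an \code{n x 3} matrix of positions (mm).
#' @return numeric vector of exact gray values.
#' @export
groundTruthGray <- function(field, p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  stopifnot(ncol(p) == 3L, all(is.finite(p)))
  pr <- field@params
  val <- switch(field@kind,
    trilinear_ramp = {
      cf <- pr$coef
      cf["c0"] + cf["cx"] * p[, 1L] + cf["cy"] * p[, 2L] +
        cf["cz"] * p[, 3L] + cf["cxy"] * p[, 1L] * p[, 2L] +
        cf["cxz"] * p[, 1L] * p[, 3L] + cf["cyz"] * p[, 2L] * p[, 3L] +
        cf["cxyz"] * p[, 1L] * p[, 2L] * p[, 3L]
    },
    bright_shell_with_defects = {
      q <- sweep(p, 2L, pr$center)
      h <- q %*% pr$axis
      rad2 <- rowSums(q^2) - h^2
      rho <- sqrt((h / pr$a)^2 + rad2 / pr$b^2)
      inShell <- abs(rho - 1) <= pr$thickness / 2
      if (length(pr$defects) && any(inShell)) {
        qn <- q / pmax(rowNorms(q), .Machine$double.eps)
        for (d in pr$defects) {
          ang <- acos(clamp(qn %*% unit3(d$dir), -1, 1))
          inShell <- inShell & (ang > d$angle)
        }
      }
      ifelse(inShell, pr$bright, pr$background)
    },
    bright_tube_with_bulge = {
      ## distance to the densely sampled centerline polyline: nearest
      ## vertex, then projection onto its adjacent segments
      ns <- nrow(pr$samples)
      d2 <- vapply(seq_len(nrow(p)), function(k) {
        dd <- sweep(pr$samples, 2L, p[k, ])
        i <- which.min(rowSums(dd * dd))
        best <- c(sqrt(sum(dd[i, ]^2)), pr$tDense[i])
        for (j in c(i - 1L, i)) {
          if (j < 1L || j >= ns) next
          seg <- pr$samples[j + 1L, ] - pr$samples[j, ]
          len2 <- sum(seg^2)
          if (len2 == 0) next
          s <- clamp(sum((p[k, ] - pr$samples[j, ]) * seg) / len2, 0, 1)
          q <- pr$samples[j, ] + s * seg
          dq <- sqrt(sum((p[k, ] - q)^2))
          if (dq < best[1L])
            best <- c(dq, pr$tDense[j] + s * (pr$tDense[j + 1L] -
                                                pr$tDense[j]))
        }
        best
      }, numeric(2L))
      R <- pr$radius * (1 + pr$bulgeAmp *
                          exp(-((d2[2L, ] - pr$bulgeCenter) /
                                  pr$bulgeWidth)^2))
      w <- pmax(0, 1 - (d2[1L, ] / R)^2)
      pr$background + (pr$peak - pr$background) * w
    },
    dental_arch = {
      inside <- rep(FALSE, nrow(p))
      zOK <- p[, 3L] >= pr$zRange[1L] & p[, 3L] <= pr$zRange[2L]
      for (k in seq_len(nrow(pr$centers))) {
        dx <- p[, 1L] - pr$centers[k, 1L]
        dy <- p[, 2L] - pr$centers[k, 2L]
        inside <- inside | (zOK & dx * dx + dy * dy <= pr$cylRadius^2)
      }
      ifelse(inside, pr$bright, pr$background)
    },
    stop("unknown field kind: ", field@kind))
  clamp(as.numeric(val), field@valueRange[1L], field@valueRange[2L])
}
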