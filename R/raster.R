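## Raster export: window/level mapping of gray levels to 8-bit and PNG
## output; uninformed samples render as pure blue. Lossless companions are
## plain CSV matrices plus a JSON sidecar.

#' Window/level mapping of gray levels to [0, 1]
#'
#' @param gray numeric vector/matrix of gray levels.
#' @param window \code{c(center, width)}; levels below
#'   \code{center - width/2} map to 0, above \code{center + width/2} to 1.
#' @return same shape as \code{gray}, clamped into \code{[0, 1]}.
#' @export
windowGray <- function(gray, window) {
  stopifnot(length(window) == 2L, window[2L] > 0)
  clamp((gray - (window[1L] - window[2L] / 2)) / window[2L], 0, 1)
}

#' Default display window of a volume
#'
#' Maps the 1st--99th percentiles of the volume's gray levels to the
#' display range.
#'
#' @param volume a \linkS4class{DicomVolume}.
#' @return \code{c(center, width)}.
#' @export
defaultWindow <- function(volume) {
  g <- unlist(lapply(volume@slices, slicePixelGrays), use.names = FALSE)
  qs <- stats::quantile(g, c(0.01, 0.99), names = FALSE)
  if (qs[2L] <= qs[1L]) qs[2L] <- qs[1L] + 1
  c(mean(qs), diff(qs))
}

## RGB array (h x w x 3) for a gray matrix + informed mask: uninformed
## samples are pure blue (the reserved display class).
grayToRGB <- function(gray, informed, window) {
  lum <- windowGray(gray, window)
  h <- nrow(gray); w <- ncol(gray)
  img <- array(0, dim = c(h, w, 3L))
  img[, , 1L] <- lum * informed
  img[, , 2L] <- lum * informed
  img[, , 3L] <- lum * informed + !informed
  img
}

#' Export a textured surface as PNG plus lossless companions
#'
#' Writes \code{<base>.png} (windowed 8-bit, uninformed samples in blue),
#' \code{<base>_gray.csv} and \code{<base>_informed.csv} (lossless), and
#' \code{<base>.json} with the run metadata.
#'
#' @param textured a \linkS4class{TexturedSurface}.
#' @param base output path without extension.
#' @param window \code{c(center, width)} display window.
#' @return named character vector of written paths, invisibly.
#' @export
exportTexture <- function(textured, base, window) {
  paths <- c(png = paste0(base, ".png"), gray = paste0(base, "_gray.csv"),
             informed = paste0(base, "_informed.csv"),
             meta = paste0(base, ".json"))
  ## image rows = v samples (top to bottom), columns = u samples
  png::writePNG(grayToRGB(t(textured@gray), t(textured@informed), window),
                paths[["png"]])
  utils::write.table(textured@gray, paths[["gray"]], sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(textured@informed * 1L, paths[["informed"]], sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(type = "TexturedSurface", method = textured@method,
         resolution = c(length(textured@u), length(textured@v)),
         window = window, uninformed = uninformedCount(textured)),
    paths[["meta"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Rasterize and export a flattened sheet
#'
#' The planar grid is resampled onto a square-pixel raster by
#' inverse-distance weighting of the grid samples inside each pixel's
#' neighborhood; pixels beyond the sheet are transparent-black, uninformed
#' samples blue. Lossless companions carry the exact planar coordinates and
#' grays.
#'
#' @param sheet a \linkS4class{FlattenedSheet}.
#' @param base output path without extension.
#' @param window \code{c(center, width)} display window.
#' @param pixelsPerMM raster resolution.
#' @return named character vector of written paths, invisibly.
#' @export
exportSheet <- function(sheet, base, window, pixelsPerMM = 2) {
  paths <- c(png = paste0(base, ".png"), x = paste0(base, "_x.csv"),
             y = paste0(base, "_y.csv"), gray = paste0(base, "_gray.csv"),
             informed = paste0(base, "_informed.csv"),
             meta = paste0(base, ".json"))
  xs <- sheet@planeGrid[, , 1L]
  ys <- sheet@planeGrid[, , 2L]
  step <- 1 / pixelsPerMM
  gx <- seq(min(xs) - step, max(xs) + step, by = step)
  gy <- seq(min(ys) - step, max(ys) + step, by = step)
  ## bin samples into pixels, then inverse-distance blend per pixel from a
  ## 3x3 pixel neighborhood
  px <- findInterval(as.numeric(xs), gx)
  py <- findInterval(as.numeric(ys), gy)
  samp <- data.frame(px = px, py = py, x = as.numeric(xs),
                     y = as.numeric(ys), gray = as.numeric(sheet@gray),
                     informed = as.numeric(sheet@informed))
  key <- paste(samp$px, samp$py)
  byCell <- split(seq_len(nrow(samp)), key)
  lum <- matrix(NA_real_, length(gy), length(gx))
  inf <- matrix(TRUE, length(gy), length(gx))
  medStep <- stats::median(sqrt(diff(xs[, 1L])^2 + diff(ys[, 1L])^2))
  rmax <- max(2 * medStep, step)
  for (cy in seq_along(gy)) {
    for (cx in seq_along(gx)) {
      keys <- paste(rep(cx + (-1:1), 3L), rep(cy + (-1:1), each = 3L))
      idx <- unlist(byCell[keys], use.names = FALSE)
      if (!length(idx)) next
      ctr <- c(gx[cx] + step / 2, gy[cy] + step / 2)
      d <- sqrt((samp$x[idx] - ctr[1L])^2 + (samp$y[idx] - ctr[2L])^2)
      keep <- d <= rmax
      if (!any(keep)) next
      idx <- idx[keep]; d <- d[keep]
      w <- 1 / pmax(d, 1e-9)
      if (any(samp$informed[idx] < 0.5)) {
        ## an uninformed sample dominates if it is the nearest
        if (samp$informed[idx][which.min(d)] < 0.5) {
          lum[cy, cx] <- -1
          inf[cy, cx] <- FALSE
          next
        }
        keepI <- samp$informed[idx] > 0.5
        idx <- idx[keepI]; w <- w[keepI]
      }
      lum[cy, cx] <- sum(w * samp$gray[idx]) / sum(w)
    }
  }
  inf[is.na(lum)] <- TRUE                    # outside: plain black
  lum[is.na(lum)] <- window[1L] - window[2L] # maps to 0
  png::writePNG(grayToRGB(lum[rev(seq_along(gy)), ], # y up in the plane
                          inf[rev(seq_along(gy)), ], window),
                paths[["png"]])
  utils::write.table(xs, paths[["x"]], sep = ",", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(ys, paths[["y"]], sep = ",", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(sheet@gray, paths[["gray"]], sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sheet@informed * 1L, paths[["informed"]], sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(type = "FlattenedSheet",
         resolution = c(length(sheet@u), length(sheet@v)),
         window = window, pixelsPerMM = pixelsPerMM,
         uninformed = uninformedCount(sheet)),
    paths[["meta"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
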