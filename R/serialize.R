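## JSON (de)serialization of curves and surfaces so command-line runs are
## reproducible from a surface-spec file.

#' Serialize a curve or surface to a JSON-ready list
#' @param x a \linkS4class{BezierCurve}, \linkS4class{EllipsoidPatch} or
#'   \linkS4class{RuledSurface} built by \code{\link{buildDevelopable}}.
#' @return a plain list (see \code{\link{writeSurfaceSpec}}).
#' @export
surfaceToList <- function(x) {
  if (is(x, "BezierCurve"))
    return(list(kind = "bezier", controlPoints = x@controlPoints))
  if (is(x, "EllipsoidPatch"))
    return(list(kind = "ellipsoid", center = x@center, axis = x@axis,
                a = x@a, b = x@b, hemisphere = x@hemisphere,
                delta = x@delta))
  if (is(x, "RuledSurface")) {
    if (x@construction == "custom")
      stop("custom ruled surfaces (closure rulings) cannot be serialized")
    dtx <- x@directrix
    if (!is(dtx, "BezierCurve"))
      stop("only Bezier directrices can be serialized")
    d <- attr(x, "referenceDirection")
    return(list(kind = "developable", construction = x@construction,
                controlPoints = dtx@controlPoints, extent = x@extent,
                d = if (is.null(d)) NULL else d))
  }
  stop("unsupported object of class ", class(x))
}

#' Write / read a surface spec JSON document
#' @param x object accepted by \code{\link{surfaceToList}}.
#' @param path JSON file path.
#' @export
writeSurfaceSpec <- function(x, path) {
  jsonlite::write_json(surfaceToList(x), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeSurfaceSpec
#' @return \code{readSurfaceSpec}: the reconstructed curve/surface object.
#' @export
readSurfaceSpec <- function(path) {
  sp <- jsonlite::read_json(path, simplifyVector = TRUE)
  listToSurface(sp)
}

#' @rdname writeSurfaceSpec
#' @param sp a list as produced by \code{\link{surfaceToList}}.
#' @export
listToSurface <- function(sp) {
  switch(sp$kind,
    bezier = bezierCurve(matrix(unlist(sp$controlPoints), ncol = 3L)),
    ellipsoid = ellipsoidPatch(sp$center, sp$axis, sp$a, sp$b,
                               hemisphere = sp$hemisphere %||% 1,
                               delta = sp$delta %||% 0),
    developable = {
      curve <- bezierCurve(matrix(unlist(sp$controlPoints), ncol = 3L))
      surf <- buildDevelopable(curve, sp$construction,
                               extent = as.numeric(sp$extent),
                               d = if (is.null(sp$d)) c(0, 0, 1)
                                   else as.numeric(sp$d))
      attr(surf, "referenceDirection") <-
        if (is.null(sp$d)) NULL else as.numeric(sp$d)
      surf
    },
    stop("unknown surface spec kind: ", sp$kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
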