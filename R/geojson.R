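#' Read region annotations from GeoJSON
#'
#' Annotations (region of analysis, analyst seed regions for tumor and
#' stroma) travel as GeoJSON FeatureCollections of polygons. Each feature
#' carries a `"class"` property, one of `"tumor"`, `"stroma"` or `"roa"`.
#' Coordinates are in pixel units, `(x, y) = (col, row)`, 0-based.
#'
#' @param x Path to a GeoJSON file, or an already-parsed list with the same
#'   structure.
#' @return An object of class `"annotation_set"`: a list of regions, each a
#'   list with elements `class` (character) and `coords` (two-column matrix
#'   of x, y vertices).
#' @export
read_annotations <- function(x) {
  if (is.character(x)) x <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  if (!is.list(x) || is.null(x$features))
    stop("expected a GeoJSON FeatureCollection with a 'features' array",
         call. = FALSE)
  regions <- lapply(x$features, function(f) {
    geom <- f$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon"))
      stop("only Polygon geometries are supported", call. = FALSE)
    ring <- geom$coordinates[[1]]
    coords <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    cls <- f$properties$class %||% "roa"
    list(class = cls, coords = coords)
  })
  structure(regions, class = "annotation_set")
}

#' Write region annotations to GeoJSON
#'
#' @param regions An `"annotation_set"` (see [read_annotations()]) or a bare
#'   list of `list(class=, coords=)` regions.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(regions, path) {
  feats <- lapply(regions, function(r) {
    coords <- r$coords
    # close the ring
    if (any(coords[1, ] != coords[nrow(coords), ]))
      coords <- rbind(coords, coords[1, ])
    list(
      type = "Feature",
      properties = list(class = r$class),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(coords)),
                                  function(i) as.numeric(coords[i, ])))
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build a rectangular annotation region
#'
#' @param x0,y0,x1,y1 Corner pixel coordinates (x = col, y = row, 0-based).
#' @param class Region class, one of `"tumor"`, `"stroma"`, `"roa"`.
#' @return A single region list usable inside an annotation set.
#' @export
rect_region <- function(x0, y0, x1, y1, class = "roa") {
  list(class = class,
       coords = cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)))
}

# Which of the points (row, col) fall inside any region of the given class?
# Containment follows the even-odd rule; the centroid rule used by callers
# makes edge cases immaterial in practice.
points_in_regions <- function(row, col, regions, class = NULL) {
  if (length(row) == 0L) return(logical(0))
  inside <- rep(FALSE, length(row))
  for (r in regions) {
    if (!is.null(class) && !identical(r$class, class)) next
    inside <- inside | pracma::inpolygon(col, row,
                                         r$coords[, 1], r$coords[, 2],
                                         boundary = TRUE)
  }
  inside
}
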