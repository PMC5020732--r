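#' Typed vector layer
#'
#' A lightweight container for planar vector features. Each feature is a
#' list with a `geometry` (type `"point"`, `"polyline"` or `"polygon"` plus
#' coordinates in metres) and an `attributes` named list. Polygon
#' coordinates are a list of rings (first outer, any others holes), each an
#' unclosed two-column matrix; polylines and points use a two-column matrix.
#'
#' @param features list of features as described above.
#' @return an object of class `vector_layer`.
#' @export
vector_layer <- function(features = list()) {
  for (f in features) {
    if (!is.list(f) || is.null(f$geometry) ||
        !f$geometry$type %in% c("point", "polyline", "polygon"))
      stop("each feature needs a geometry of type point/polyline/polygon")
  }
  structure(list(features = features), class = "vector_layer")
}

#' @export
print.vector_layer <- function(x, ...) {
  types <- vapply(x$features, function(f) f$geometry$type, "")
  cat(sprintf("<vector_layer> %d features (%s)\n", length(x$features),
              paste(sprintf("%s: %d", names(table(types)), table(types)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
length.vector_layer <- function(x) length(x$features)

vl_feature <- function(type, coords, attributes = list()) {
  list(geometry = list(type = type, coords = coords),
       attributes = attributes)
}

#' Construct point / polyline / polygon features
#'
#' `vl_points` takes a two-column coordinate matrix and builds one point
#' feature per row (attributes recycled); `vl_line` one polyline from its
#' vertex matrix; `vl_polygon` one polygon from a ring matrix or a list of
#' ring matrices.
#'
#' @param coords two-column numeric matrix of (x, y) in metres.
#' @param ... named attributes attached to each feature.
#' @return a list of features, ready for [vector_layer()].
#' @export
vl_points <- function(coords, ...) {
  coords <- rbind(coords)
  attrs <- list(...)
  lapply(seq_len(nrow(coords)), function(i) {
    a <- lapply(attrs, function(v) if (length(v) > 1) v[[i]] else v[[1]])
    vl_feature("point", coords[i, , drop = TRUE], a)
  })
}

#' @rdname vl_points
#' @export
vl_line <- function(coords, ...) {
  list(vl_feature("polyline", rbind(coords), list(...)))
}

#' @rdname vl_points
#' @export
vl_polygon <- function(coords, ...) {
  if (!is.list(coords)) coords <- list(rbind(coords))
  list(vl_feature("polygon", lapply(coords, rbind), list(...)))
}

#' Axis-aligned rectangle polygon feature
#' @param xmin,xmax,ymin,ymax rectangle bounds in metres.
#' @param ... named attributes.
#' @export
vl_rect <- function(xmin, xmax, ymin, ymax, ...) {
  vl_polygon(cbind(c(xmin, xmax, xmax, xmin),
                   c(ymin, ymin, ymax, ymax)), ...)
}

#' Extract a feature attribute as a vector
#' @param layer a `vector_layer`.
#' @param name attribute name.
#' @export
vl_attr <- function(layer, name) {
  vals <- lapply(layer$features, function(f) f$attributes[[name]])
  vals[vapply(vals, is.null, logical(1))] <- NA
  unlist(vals, use.names = FALSE)
}

#' Subset a layer by an attribute value
#' @param layer a `vector_layer`.
#' @param name attribute name.
#' @param value values to keep.
#' @export
vl_subset <- function(layer, name, value) {
  keep <- vapply(layer$features, function(f) {
    v <- f$attributes[[name]]
    !is.null(v) && v %in% value
  }, logical(1))
  vector_layer(layer$features[keep])
}

#' Stack feature coordinates of point features
#' @param layer a `vector_layer` of points.
#' @return two-column matrix of coordinates.
#' @export
vl_coords <- function(layer) {
  do.call(rbind, lapply(layer$features, function(f) {
    if (f$geometry$type != "point") stop("vl_coords expects point features")
    rbind(f$geometry$coords)
  }))
}

close_ring <- function(m) {
  if (!isTRUE(all.equal(m[1, ], m[nrow(m), ]))) rbind(m, m[1, ]) else m
}

#' Write a vector layer as GeoJSON
#' @param layer a `vector_layer`.
#' @param path output file path.
#' @export
write_geojson <- function(layer, path) {
  feats <- lapply(layer$features, function(f) {
    g <- f$geometry
    geom <- switch(g$type,
      point = list(type = "Point", coordinates = as.numeric(g$coords)),
      polyline = list(type = "LineString",
                      coordinates = unname(apply(g$coords, 1, as.numeric,
                                                 simplify = FALSE))),
      polygon = list(type = "Polygon",
                     coordinates = lapply(g$coords, function(r) {
                       r <- close_ring(r)
                       unname(apply(r, 1, as.numeric, simplify = FALSE))
                     })))
    props <- f$attributes
    if (length(props) == 0) props <- structure(list(), names = character())
    list(type = "Feature", geometry = geom, properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection into a vector layer
#' @param path file path.
#' @export
read_geojson <- function(path) {
  js <- jsonlite::read_json(path)
  if (!identical(js$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  feats <- lapply(js$features, function(f) {
    g <- f$geometry
    coords <- g$coordinates
    mat <- function(cc) do.call(rbind, lapply(cc, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    geom <- switch(g$type,
      Point = list(type = "point",
                   coords = c(as.numeric(coords[[1]]),
                              as.numeric(coords[[2]]))),
      LineString = list(type = "polyline", coords = mat(coords)),
      Polygon = list(type = "polygon", coords = lapply(coords, function(r) {
        m <- mat(r)
        if (isTRUE(all.equal(m[1, ], m[nrow(m), ]))) m[-nrow(m), , drop = FALSE]
        else m
      })),
      stop("unsupported GeoJSON geometry: ", g$type))
    list(geometry = geom, attributes = lapply(f$properties, identity))
  })
  vector_layer(feats)
}
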