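# Synthetic landscapes: linear features (roads, streams) and habitat patches
# (dense forest, deciduous dipterocarp forest) in projected meter coordinates.

#' Landscape generator configuration
#'
#' @param extent numeric length-4 vector `c(xmin, ymin, xmax, ymax)` in meters.
#' @param n_roads,n_streams number of random polylines per feature type.
#' @param n_forest_patches number of dense-forest polygons.
#' @param n_ddf_patches number of open deciduous dipterocarp forest polygons.
#' @param seed integer seed; identical seeds give identical landscapes.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(extent = c(0, 0, 20000, 20000),
                             n_roads = 3, n_streams = 3,
                             n_forest_patches = 5, n_ddf_patches = 5,
                             seed = 1L) {
  stopifnot(length(extent) == 4, is.numeric(extent))
  if (!(extent[3] > extent[1] && extent[4] > extent[2])) {
    stop("degenerate extent: xmax must exceed xmin and ymax must exceed ymin",
         call. = FALSE)
  }
  counts <- c(n_roads, n_streams, n_forest_patches, n_ddf_patches)
  if (any(counts < 0)) stop("feature counts must be >= 0", call. = FALSE)
  structure(list(extent = as.numeric(extent),
                 n_roads = as.integer(n_roads),
                 n_streams = as.integer(n_streams),
                 n_forest_patches = as.integer(n_forest_patches),
                 n_ddf_patches = as.integer(n_ddf_patches),
                 seed = as.integer(seed)),
            class = "landscape_config")
}

#' Generate a synthetic landscape
#'
#' Roads and streams are random-walk polylines; dense-forest and DDF patches
#' are buffered random points (regular polygons). All vertices are clamped to
#' the extent. Any geometry supporting distance queries is acceptable for the
#' downstream covariates; this one is deliberately simple.
#'
#' @param config a [landscape_config()].
#' @return a `canid_landscape` object: list with `extent` and `features`,
#'   each feature a list with `type` (road/stream/dense_forest/ddf), `kind`
#'   (line/polygon) and a two-column coordinate matrix.
#' @export
gen_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  ext <- config$extent
  w <- ext[3] - ext[1]; hgt <- ext[4] - ext[2]
  step <- sqrt(w * hgt) / 40
  clamp <- function(xy) {
    xy[, 1] <- pmin(ext[3], pmax(ext[1], xy[, 1]))
    xy[, 2] <- pmin(ext[4], pmax(ext[2], xy[, 2]))
    xy
  }
  walk <- function(wiggle) {
    n_steps <- 40L
    x0 <- stats::runif(1, ext[1], ext[3]); y0 <- stats::runif(1, ext[2], ext[4])
    heading <- stats::runif(1, 0, 2 * pi) +
      cumsum(stats::rnorm(n_steps, 0, wiggle))
    clamp(cbind(x0 + cumsum(c(0, step * cos(heading))),
                y0 + cumsum(c(0, step * sin(heading)))))
  }
  patch <- function(frac) {
    r <- stats::runif(1, 0.5, 1.5) * frac * min(w, hgt)
    cx <- stats::runif(1, ext[1], ext[3]); cy <- stats::runif(1, ext[2], ext[4])
    ang <- seq(0, 2 * pi, length.out = 25L)[-25L]
    clamp(cbind(cx + r * cos(ang), cy + r * sin(ang)))
  }
  feats <- with_seed(config$seed, {
    out <- list()
    for (i in seq_len(config$n_roads)) {
      out[[length(out) + 1L]] <- list(type = "road", kind = "line", coords = walk(0.25))
    }
    for (i in seq_len(config$n_streams)) {
      out[[length(out) + 1L]] <- list(type = "stream", kind = "line", coords = walk(0.45))
    }
    for (i in seq_len(config$n_forest_patches)) {
      out[[length(out) + 1L]] <- list(type = "dense_forest", kind = "polygon",
                                      coords = patch(0.04))
    }
    for (i in seq_len(config$n_ddf_patches)) {
      out[[length(out) + 1L]] <- list(type = "ddf", kind = "polygon",
                                      coords = patch(0.08))
    }
    out
  })
  structure(list(extent = ext, features = feats, config = config),
            class = "canid_landscape")
}

#' Feature types present in a landscape
#' @param landscape a `canid_landscape`.
#' @return character vector of types with at least one feature.
#' @export
feature_types <- function(landscape) {
  unique(vapply(landscape$features, `[[`, "", "type"))
}

#' Distance from points to the nearest feature of each type
#'
#' Euclidean distance in meters; points inside a polygon feature get 0.
#'
#' @param points two-column matrix or data frame of x/y coordinates (m).
#' @param landscape a `canid_landscape`.
#' @param types feature types to compute; default all types requested.
#' @return matrix (n points x length(types)), columns named `dist_<type>`.
#' @export
landscape_distances <- function(points, landscape,
                                types = feature_types(landscape)) {
  pts <- as.matrix(if (is.data.frame(points)) points[, c(1, 2)]
                   else points[, c(1, 2), drop = FALSE])
  storage.mode(pts) <- "double"
  out <- matrix(NA_real_, nrow(pts), length(types),
                dimnames = list(NULL, paste0("dist_", types)))
  for (j in seq_along(types)) {
    feats <- Filter(function(f) f$type == types[j], landscape$features)
    if (length(feats) == 0) {
      stop("landscape has no features of type '", types[j], "'", call. = FALSE)
    }
    d <- rep(Inf, nrow(pts))
    for (f in feats) {
      if (f$kind == "line") {
        segs <- polyline_segments(f$coords)
      } else {
        ring <- rbind(f$coords, f$coords[1, ])
        segs <- polyline_segments(ring)
      }
      df <- dist_point_segments(pts, segs)
      if (f$kind == "polygon") df[points_in_polygon(pts, f$coords)] <- 0
      d <- pmin(d, df)
    }
    out[, j] <- d
  }
  out
}

#' Write a landscape as GeoJSON
#'
#' One FeatureCollection; each feature carries a `feature_type` property in
#' {road, stream, dense_forest, ddf}. Lines become LineStrings, patches
#' Polygons (closed rings).
#'
#' @param landscape a `canid_landscape`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_landscape_geojson <- function(landscape, path) {
  feat_list <- lapply(landscape$features, function(f) {
    if (f$kind == "line") {
      geom <- list(type = "LineString",
                   coordinates = unname(apply(f$coords, 1, as.list, simplify = FALSE)))
    } else {
      ring <- rbind(f$coords, f$coords[1, , drop = FALSE])
      geom <- list(type = "Polygon",
                   coordinates = list(unname(apply(ring, 1, as.list, simplify = FALSE))))
    }
    list(type = "Feature", properties = list(feature_type = f$type), geometry = geom)
  })
  fc <- list(type = "FeatureCollection", features = feat_list)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a landscape from GeoJSON written by [write_landscape_geojson()]
#' @param path GeoJSON file path.
#' @return a `canid_landscape` (extent recomputed from coordinates).
#' @export
read_landscape_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- lapply(fc$features, function(f) {
    g <- f$geometry
    if (g$type == "LineString") {
      coords <- do.call(rbind, lapply(g$coordinates, function(p) c(p[[1]], p[[2]])))
      list(type = f$properties$feature_type, kind = "line", coords = coords)
    } else {
      ring <- do.call(rbind, lapply(g$coordinates[[1]], function(p) c(p[[1]], p[[2]])))
      list(type = f$properties$feature_type, kind = "polygon",
           coords = ring[-nrow(ring), , drop = FALSE])
    }
  })
  all_xy <- do.call(rbind, lapply(feats, `[[`, "coords"))
  structure(list(extent = c(min(all_xy[, 1]), min(all_xy[, 2]),
                            max(all_xy[, 1]), max(all_xy[, 2])),
                 features = feats, config = NULL),
            class = "canid_landscape")
}
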