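# Kernel and minimum-convex-polygon home ranges, bandwidth selection,
# utilization-distribution overlap, monthly ranges, and group-count density.

.points_matrix <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("x", "y") %in% names(points))) points <- points[, c("x", "y")]
    points <- as.matrix(points)
  }
  storage.mode(points) <- "double"
  if (ncol(points) != 2 || any(!is.finite(points))) {
    stop("points must be a two-column matrix of finite coordinates", call. = FALSE)
  }
  points
}

#' Reference bandwidth for a bivariate Gaussian kernel
#'
#' h_ref = sigma_hat * n^(-1/6) with sigma_hat = sqrt((s_x^2 + s_y^2)/2),
#' the reference rule for bivariate normal data.
#'
#' @param points two-column matrix/data frame of projected coordinates (m).
#' @return bandwidth in meters.
#' @export
href <- function(points) {
  xy <- .points_matrix(points)
  n <- nrow(xy)
  if (n < 5) stop("need at least 5 points", call. = FALSE)
  s2 <- (stats::var(xy[, 1]) + stats::var(xy[, 2])) / 2
  if (s2 == 0) stop("all points identical; bandwidth undefined", call. = FALSE)
  sqrt(s2) * n^(-1 / 6)
}

#' Build a kernel grid around points
#'
#' Square cells covering the data bounding box expanded by `margin * h` on
#' all sides.
#'
#' @param points coordinate matrix.
#' @param h bandwidth (m) used for the margin.
#' @param n nominal cells along the longer axis (default 256).
#' @param margin margin in bandwidths (default 3).
#' @return list (x, y, cell): cell-center coordinate vectors and cell size.
#' @export
make_grid <- function(points, h, n = 256L, margin = 3) {
  xy <- .points_matrix(points)
  xr <- range(xy[, 1]) + c(-1, 1) * margin * h
  yr <- range(xy[, 2]) + c(-1, 1) * margin * h
  cell <- max(diff(xr), diff(yr)) / n
  nx <- ceiling(diff(xr) / cell)
  ny <- ceiling(diff(yr) / cell)
  list(x = xr[1] + (seq_len(nx) - 0.5) * cell,
       y = yr[1] + (seq_len(ny) - 0.5) * cell,
       cell = cell)
}

#' Gaussian-kernel utilization distribution
#'
#' Cell mass is proportional to sum_i exp(-((x - x_i)^2 + (y - y_i)^2) /
#' (2 h^2)) evaluated at cell centers, normalized to sum to 1.
#'
#' @param points coordinate matrix (m).
#' @param h bandwidth (m), > 0.
#' @param grid optional grid from [make_grid()]; must cover the points with
#'   at least a 3h margin. Built automatically when `NULL`.
#' @param grid_n grid resolution when building automatically.
#' @return a `canid_ud`: list (x, y, cell, h, z) with `z` the nx x ny matrix
#'   of cell probability masses.
#' @export
kde_ud <- function(points, h, grid = NULL, grid_n = 256L) {
  xy <- .points_matrix(points)
  if (h <= 0) stop("h must be > 0", call. = FALSE)
  if (is.null(grid)) grid <- make_grid(xy, h, n = grid_n)
  tol <- 1e-6
  covers <- min(xy[, 1]) - 3 * h >= grid$x[1] - grid$cell / 2 - tol &&
    max(xy[, 1]) + 3 * h <= grid$x[length(grid$x)] + grid$cell / 2 + tol &&
    min(xy[, 2]) - 3 * h >= grid$y[1] - grid$cell / 2 - tol &&
    max(xy[, 2]) + 3 * h <= grid$y[length(grid$y)] + grid$cell / 2 + tol
  if (!covers) stop("grid does not cover the points with a 3h margin", call. = FALSE)
  kx <- exp(-outer(grid$x, xy[, 1], "-")^2 / (2 * h^2))
  ky <- exp(-outer(grid$y, xy[, 2], "-")^2 / (2 * h^2))
  z <- kx %*% t(ky)
  structure(list(x = grid$x, y = grid$y, cell = grid$cell, h = h,
                 z = z / sum(z)),
            class = "canid_ud")
}

#' Isopleth cell set of a utilization distribution
#'
#' The smallest set of highest-mass cells whose cumulative mass reaches the
#' level. Ties at the crossing are resolved deterministically by cell index
#' (mass descending, index ascending; stop at first crossing). Area is
#' counted cell area.
#'
#' @param ud a `canid_ud`.
#' @param level isopleth level in (0, 1].
#' @return a `canid_isopleth`: list (level, mask, x, y, cell, n_cells,
#'   area_km2).
#' @export
isopleth <- function(ud, level) {
  stopifnot(inherits(ud, "canid_ud"))
  if (level <= 0 || level > 1) stop("level must be in (0, 1]", call. = FALSE)
  zv <- as.vector(ud$z)
  ord <- order(-zv, seq_along(zv))
  cum <- cumsum(zv[ord])
  k <- which(cum >= level - 1e-12)[1]
  if (is.na(k)) k <- length(zv)
  sel <- ord[seq_len(k)]
  sel <- sel[zv[sel] > 0]
  mask <- matrix(FALSE, nrow(ud$z), ncol(ud$z))
  mask[sel] <- TRUE
  structure(list(level = level, mask = mask, x = ud$x, y = ud$y,
                 cell = ud$cell, n_cells = sum(mask),
                 area_km2 = sum(mask) * ud$cell^2 / 1e6),
            class = "canid_isopleth")
}

# Vectorized flood fill by dilation. Returns logical matrix of cells of
# `mask` reachable from `seed` (logical matrix), using 8- or 4-connectivity.
.flood <- function(mask, seed, conn = 8) {
  reached <- seed & mask
  if (!any(reached)) return(reached)
  nr <- nrow(mask); nc <- ncol(mask)
  shift <- function(m, di, dj) {
    out <- matrix(FALSE, nr, nc)
    ri <- seq_len(nr); rj <- seq_len(nc)
    si <- ri - di; sj <- rj - dj
    ok_i <- si >= 1 & si <= nr; ok_j <- sj >= 1 & sj <= nc
    out[ri[ok_i], rj[ok_j]] <- m[si[ok_i], sj[ok_j]]
    out
  }
  offs <- if (conn == 8) {
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
         c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  } else {
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  }
  repeat {
    grown <- reached
    for (o in offs) grown <- grown | shift(reached, o[1], o[2])
    grown <- grown & mask
    if (identical(grown, reached)) break
    reached <- grown
  }
  reached
}

# TRUE if the cell set is a single 8-connected component with no interior
# holes (complement 4-connected to the grid border).
.contiguous_no_holes <- function(mask) {
  if (!any(mask)) return(FALSE)
  seed <- matrix(FALSE, nrow(mask), ncol(mask))
  seed[which(mask)[1]] <- TRUE
  if (!identical(.flood(mask, seed, conn = 8), mask)) return(FALSE)
  comp <- !mask
  border <- matrix(FALSE, nrow(mask), ncol(mask))
  border[1, ] <- TRUE; border[nrow(mask), ] <- TRUE
  border[, 1] <- TRUE; border[, ncol(mask)] <- TRUE
  outside <- .flood(comp, border & comp, conn = 4)
  identical(outside, comp)
}

#' Ad hoc bandwidth (contiguity scan)
#'
#' Scans multipliers m = 1.00, 0.95, ..., 0.05 of the reference bandwidth
#' and returns the smallest m * h_ref whose 95% isopleth is still one
#' 8-connected cell set without interior holes. If the isopleth is already
#' fragmented at m = 1.00, h_ref is returned with a warning.
#'
#' @param points coordinate matrix (m).
#' @param level isopleth level (default 0.95).
#' @param step scan step on the multiplier (default 0.05).
#' @param grid_n grid resolution for the scan (default 128).
#' @return bandwidth in meters with attribute `multiplier`.
#' @export
adhoc_bandwidth <- function(points, level = 0.95, step = 0.05, grid_n = 128L) {
  xy <- .points_matrix(points)
  h_ref <- href(xy)
  grid <- make_grid(xy, h_ref, n = grid_n)
  multipliers <- seq(1, step, by = -step)
  last_good <- NA_real_
  for (m in multipliers) {
    ud <- kde_ud(xy, m * h_ref, grid = grid)
    ok <- .contiguous_no_holes(isopleth(ud, level)$mask)
    if (!ok) {
      if (is.na(last_good)) {
        warning("isopleth fragmented even at h_ref; returning h_ref",
                call. = FALSE)
        return(structure(h_ref, multiplier = 1))
      }
      break
    }
    last_good <- m
  }
  structure(last_good * h_ref, multiplier = last_good)
}

#' Bandwidth selection rule
#'
#' h_used = max(factor * h_ref, h_adhoc): the reference bandwidth shrunk by
#' `factor` (default 0.8) to limit over-smoothing, unless the ad hoc
#' contiguity bandwidth is greater, in which case the greater one is used.
#'
#' @inheritParams adhoc_bandwidth
#' @param factor shrinkage factor on h_ref (default 0.8).
#' @return a `bandwidth_spec`: list (h_ref, factor, h_adhoc, h_used), m.
#' @export
select_bandwidth <- function(points, factor = 0.8, level = 0.95,
                             step = 0.05, grid_n = 128L) {
  h_ref <- href(points)
  h_adhoc <- as.numeric(adhoc_bandwidth(points, level = level, step = step,
                                        grid_n = grid_n))
  structure(list(h_ref = h_ref, factor = factor, h_adhoc = h_adhoc,
                 h_used = max(factor * h_ref, h_adhoc)),
            class = "bandwidth_spec")
}

#' Minimum convex polygon home range
#'
#' Removes the floor((1 - percent) * n) points farthest (Euclidean) from the
#' arithmetic mean of all points, then takes the convex hull of the rest.
#'
#' @param points coordinate matrix (m).
#' @param percent fraction of points retained (default 0.95).
#' @return a `canid_mcp`: list (vertices open-ring matrix, area_km2,
#'   percent, n_used).
#' @export
mcp <- function(points, percent = 0.95) {
  xy <- .points_matrix(points)
  n <- nrow(xy)
  if (n < 5) stop("need at least 5 points", call. = FALSE)
  n_remove <- floor((1 - percent) * n)
  ctr <- colMeans(xy)
  d <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
  keep <- xy[order(d)[seq_len(n - n_remove)], , drop = FALSE]
  if (nrow(keep) < 3) stop("fewer than 3 points survive removal", call. = FALSE)
  hull <- keep[grDevices::chull(keep), , drop = FALSE]
  structure(list(vertices = hull,
                 area_km2 = shoelace_area(hull) / 1e6,
                 percent = percent, n_used = nrow(keep)),
            class = "canid_mcp")
}

.polygon_matrix <- function(poly) {
  if (inherits(poly, "canid_mcp")) return(poly$vertices)
  .points_matrix(poly)
}

#' Utilization distribution overlap index (UDOI)
#'
#' Discrete form: UDOI = A_overlap * sum(UD_a(c) * UD_b(c)) / cell_area,
#' where A_overlap is the area of intersection of the two level-isopleth
#' cell sets. 0 = no overlap; 1 for identical uniform distributions whose
#' isopleths cover the full support; > 1 indicates concentrated shared use.
#'
#' @param ud_a,ud_b `canid_ud` objects on the identical grid.
#' @param level isopleth level for the overlap area (default 0.95).
#' @return numeric UDOI >= 0.
#' @export
udoi <- function(ud_a, ud_b, level = 0.95) {
  stopifnot(inherits(ud_a, "canid_ud"), inherits(ud_b, "canid_ud"))
  same <- isTRUE(all.equal(ud_a$x, ud_b$x)) && isTRUE(all.equal(ud_a$y, ud_b$y)) &&
    isTRUE(all.equal(ud_a$cell, ud_b$cell))
  if (!same) stop("the two UDs must share an identical grid", call. = FALSE)
  mask_a <- isopleth(ud_a, level)$mask
  mask_b <- isopleth(ud_b, level)$mask
  cell_area <- ud_a$cell^2
  a_overlap <- sum(mask_a & mask_b) * cell_area
  a_overlap * sum(ud_a$z * ud_b$z) / cell_area
}

#' Directed percent area overlap of two polygons
#'
#' 100 * area(A intersect B) / area(A), the reverse, and their mean. Both
#' polygons must be convex (minimum convex polygons are).
#'
#' @param poly_a,poly_b `canid_mcp` objects or open-ring coordinate matrices.
#' @return named numeric (a_on_b, b_on_a, mean), in percent.
#' @export
percent_area_overlap <- function(poly_a, poly_b) {
  a <- .polygon_matrix(poly_a)
  b <- .polygon_matrix(poly_b)
  area_a <- shoelace_area(a); area_b <- shoelace_area(b)
  if (area_a == 0 || area_b == 0) stop("zero-area polygon", call. = FALSE)
  inter <- clip_polygon_convex(a, b)
  ai <- if (nrow(inter) >= 3) shoelace_area(inter) else 0
  out <- c(a_on_b = 100 * ai / area_a, b_on_a = 100 * ai / area_b)
  c(out, mean = mean(out))
}

#' Monthly 95% kernel home ranges
#'
#' A calendar month qualifies only if it has at least `min_locations`
#' relocations spanning at least `min_span_days` days; each qualifying month
#' gets its own bandwidth (selection rule) and utilization distribution.
#'
#' @param relocations data frame (animal_id, timestamp, x, y).
#' @param min_locations minimum fixes per month (default 28).
#' @param min_span_days minimum within-month span in days (default 14).
#' @param factor,grid_n passed to [select_bandwidth()] / [kde_ud()].
#' @return data frame (animal_id, month, n_locations, span_days, h_used,
#'   kde95_km2); empty with a warning if no month qualifies.
#' @export
monthly_ranges <- function(relocations, min_locations = 28L,
                           min_span_days = 14, factor = 0.8, grid_n = 128L) {
  stopifnot(all(c("animal_id", "timestamp", "x", "y") %in% names(relocations)))
  key <- paste(relocations$animal_id, format(relocations$timestamp, "%Y-%m"))
  rows <- list()
  for (k in unique(key)) {
    sub <- relocations[key == k, , drop = FALSE]
    span <- as.numeric(difftime(max(sub$timestamp), min(sub$timestamp),
                                units = "days"))
    if (nrow(sub) < min_locations || span < min_span_days) next
    bw <- select_bandwidth(sub[, c("x", "y")], factor = factor, grid_n = grid_n)
    ud <- kde_ud(sub[, c("x", "y")], bw$h_used, grid_n = grid_n)
    rows[[k]] <- data.frame(
      animal_id = sub$animal_id[1],
      month = format(sub$timestamp[1], "%Y-%m"),
      n_locations = nrow(sub), span_days = span, h_used = bw$h_used,
      kde95_km2 = isopleth(ud, 0.95)$area_km2,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    warning("no month satisfies the inclusion filters", call. = FALSE)
    return(data.frame(animal_id = character(0), month = character(0),
                      n_locations = integer(0), span_days = numeric(0),
                      h_used = numeric(0), kde95_km2 = numeric(0)))
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Mean and standard error of home-range areas
#' @param areas numeric vector of areas (n >= 2).
#' @return list (mean, se) with SE = sample SD / sqrt(n).
#' @export
summarize_ranges <- function(areas) {
  if (length(areas) < 2) stop("need at least 2 areas for a standard error",
                              call. = FALSE)
  list(mean = mean(areas), se = stats::sd(areas) / sqrt(length(areas)))
}

#' Group-count density
#'
#' density = n_groups * mean_group_size / area_km2 (animals per km^2), the
#' pre-whelping density construction for territorial canids.
#'
#' @param n_groups number of resident groups (> 0).
#' @param mean_group_size mean adults per group (> 0).
#' @param area_km2 total area, km^2 (> 0).
#' @return numeric density.
#' @export
density_estimate <- function(n_groups, mean_group_size, area_km2) {
  if (area_km2 <= 0) stop("area_km2 must be > 0", call. = FALSE)
  if (n_groups <= 0 || mean_group_size <= 0) {
    stop("n_groups and mean_group_size must be > 0", call. = FALSE)
  }
  n_groups * mean_group_size / area_km2
}

#' Exclude or flag extraterritorial forays
#'
#' Manual mode removes fixes inside id + time-window exclusions. Auto mode
#' only flags fixes farther than `auto_threshold_km` from the animal's
#' median location (column `foray_flag`) for review; it never removes.
#'
#' @param relocations data frame (animal_id, timestamp, x, y).
#' @param exclusions optional data frame (animal_id, start, end) of windows
#'   to remove (POSIXct or coercible).
#' @param auto_threshold_km optional flagging distance in km (e.g. 12).
#' @return the relocations, filtered and/or with a `foray_flag` column.
#' @export
exclude_forays <- function(relocations, exclusions = NULL,
                           auto_threshold_km = NULL) {
  out <- relocations
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    drop <- rep(FALSE, nrow(out))
    for (i in seq_len(nrow(exclusions))) {
      drop <- drop | (out$animal_id == exclusions$animal_id[i] &
                        out$timestamp >= as.POSIXct(exclusions$start[i], tz = "UTC") &
                        out$timestamp <= as.POSIXct(exclusions$end[i], tz = "UTC"))
    }
    out <- out[!drop, , drop = FALSE]
  }
  if (!is.null(auto_threshold_km)) {
    flag <- rep(FALSE, nrow(out))
    for (id in unique(out$animal_id)) {
      sel <- out$animal_id == id
      mx <- stats::median(out$x[sel]); my <- stats::median(out$y[sel])
      d_km <- sqrt((out$x[sel] - mx)^2 + (out$y[sel] - my)^2) / 1000
      flag[sel] <- d_km >= auto_threshold_km
    }
    out$foray_flag <- flag
  }
  out
}

#' Trace isopleth cell-set boundaries as polygon rings
#'
#' Chains the exterior edges of the isopleth cell set into closed rings
#' (one per boundary loop), for GeoJSON export.
#'
#' @param iso a `canid_isopleth`.
#' @return list of closed-ring coordinate matrices.
#' @export
isopleth_polygons <- function(iso) {
  stopifnot(inherits(iso, "canid_isopleth"))
  mask <- iso$mask
  nx <- nrow(mask); ny <- ncol(mask)
  half <- iso$cell / 2
  xmin <- iso$x - half; xmax <- iso$x + half
  ymin <- iso$y - half; ymax <- iso$y + half
  pad <- function(m, di, dj) {
    out <- matrix(FALSE, nx, ny)
    ri <- seq_len(nx); rj <- seq_len(ny)
    si <- ri - di; sj <- rj - dj
    ok_i <- si >= 1 & si <= nx; ok_j <- sj >= 1 & sj <= ny
    out[ri[ok_i], rj[ok_j]] <- m[si[ok_i], sj[ok_j]]
    out
  }
  # Directed boundary edges (interior on the left), on the corner lattice.
  starts <- character(0); ends <- character(0)
  sx <- numeric(0); sy <- numeric(0); ex <- numeric(0); ey <- numeric(0)
  add_edges <- function(cells, x1, y1, x2, y2, k1i, k1j, k2i, k2j) {
    idx <- which(cells, arr.ind = TRUE)
    if (nrow(idx) == 0) return()
    i <- idx[, 1]; j <- idx[, 2]
    starts <<- c(starts, paste(i + k1i, j + k1j))
    ends <<- c(ends, paste(i + k2i, j + k2j))
    sx <<- c(sx, x1[i]); sy <<- c(sy, y1[j])
    ex <<- c(ex, x2[i]); ey <<- c(ey, y2[j])
  }
  add_edges(mask & !pad(mask, 0, 1), xmin, ymin, xmax, ymin, -1, -1, 0, -1)   # bottom
  add_edges(mask & !pad(mask, -1, 0), xmax, ymin, xmax, ymax, 0, -1, 0, 0)    # right
  add_edges(mask & !pad(mask, 0, -1), xmax, ymax, xmin, ymax, 0, 0, -1, 0)    # top
  add_edges(mask & !pad(mask, 1, 0), xmin, ymax, xmin, ymin, -1, 0, -1, -1)   # left
  used <- rep(FALSE, length(starts))
  by_start <- split(seq_along(starts), starts)
  rings <- list()
  for (e0 in seq_along(starts)) {
    if (used[e0]) next
    ring_x <- sx[e0]; ring_y <- sy[e0]
    cur <- e0
    repeat {
      used[cur] <- TRUE
      ring_x <- c(ring_x, ex[cur]); ring_y <- c(ring_y, ey[cur])
      if (ends[cur] == starts[e0]) break
      nxt <- by_start[[ends[cur]]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0) break
      cur <- nxt[1]
    }
    rings[[length(rings) + 1L]] <- cbind(ring_x, ring_y)
  }
  rings
}

#' Write a utilization distribution as an ESRI ASCII grid
#' @param ud a `canid_ud`.
#' @param path output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_ud_asc <- function(ud, path) {
  stopifnot(inherits(ud, "canid_ud"))
  nx <- length(ud$x); ny <- length(ud$y)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", nx), paste("nrows", ny),
               paste("xllcorner", format(ud$x[1] - ud$cell / 2)),
               paste("yllcorner", format(ud$y[1] - ud$cell / 2)),
               paste("cellsize", format(ud$cell)),
               "NODATA_value -9999"), con)
  for (j in rev(seq_len(ny))) {
    writeLines(paste(signif(ud$z[, j], 6), collapse = " "), con)
  }
  invisible(path)
}
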