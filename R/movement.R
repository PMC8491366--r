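# Habitat-biased movement simulation: independent fixes from a bivariate
# normal availability kernel thinned by an exponential selection function.

#' Movement generator configuration
#'
#' @param center length-2 numeric, home-range center (x, y) in meters.
#' @param sigma availability spread (m) of the bivariate normal kernel; > 0.
#' @param beta named numeric vector of true selection coefficients on the
#'   standardized log-distance covariates; names are landscape feature types
#'   (e.g. `c(road = -0.4, stream = 0.15, dense_forest = 0.5)`). Positive
#'   coefficients on a distance mean avoidance of the feature.
#' @param n_fixes number of relocations to generate (>= 1).
#' @param fix_interval_h fix spacing in hours (default 6, the GPS schedule).
#' @param start first timestamp (POSIXct, UTC).
#' @param seed integer seed.
#' @return a `movement_config` list.
#' @export
movement_config <- function(center, sigma, beta, n_fixes,
                            fix_interval_h = 6,
                            start = as.POSIXct("2015-03-13 00:00:00", tz = "UTC"),
                            seed = 1L) {
  stopifnot(length(center) == 2, is.numeric(sigma), is.numeric(beta))
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (n_fixes < 1) stop("n_fixes must be >= 1", call. = FALSE)
  if (length(beta) > 0 && is.null(names(beta))) {
    stop("beta must be named by landscape feature type", call. = FALSE)
  }
  structure(list(center = as.numeric(center), sigma = sigma, beta = beta,
                 n_fixes = as.integer(n_fixes), fix_interval_h = fix_interval_h,
                 start = start, seed = as.integer(seed)),
            class = "movement_config")
}

# Standardized log-distance covariates for proposal points, given a frozen
# scaler (list with center, scale, types).
.movement_covariates <- function(points, landscape, scaler) {
  d <- landscape_distances(points, landscape, types = scaler$types)
  v <- log(d + 1)
  sweep(sweep(v, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

#' Simulate relocations for one animal
#'
#' Positions are independent draws obtained by rejection sampling: proposals
#' come from a bivariate normal centered on the configured home-range center
#' with spread `sigma`; a proposal at location s with standardized covariate
#' vector x(s) is accepted with probability proportional to `exp(x(s) %*%
#' beta)`. Covariates are log(distance + 1), centered and scaled against a
#' calibration sample from the availability kernel, so `beta` is expressed on
#' the same standardized scale a resource-selection fit estimates.
#' Timestamps are evenly spaced at the configured fix interval.
#'
#' @param landscape a `canid_landscape` with nonempty layers for every
#'   coefficient named in `config$beta`.
#' @param config a [movement_config()].
#' @param animal_id identifier recorded in the output.
#' @return data frame (animal_id, timestamp, x, y, source) with attributes
#'   `scaler` (the frozen covariate scaler) and `acceptance_rate`.
#' @export
gen_movement <- function(landscape, config, animal_id = "A1") {
  stopifnot(inherits(landscape, "canid_landscape"),
            inherits(config, "movement_config"))
  types <- names(config$beta)
  missing <- setdiff(types, feature_types(landscape))
  if (length(missing) > 0) {
    stop("landscape has no features of type: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  res <- with_seed(config$seed, {
    propose <- function(n) {
      cbind(stats::rnorm(n, config$center[1], config$sigma),
            stats::rnorm(n, config$center[2], config$sigma))
    }
    if (length(types) == 0) {
      xy <- propose(config$n_fixes)
      list(xy = xy, scaler = NULL, rate = 1)
    } else {
      cal <- propose(2000L)
      dcal <- log(landscape_distances(cal, landscape, types = types) + 1)
      scaler <- list(types = types,
                     center = colMeans(dcal),
                     scale = apply(dcal, 2, stats::sd))
      if (any(scaler$scale == 0)) {
        stop("zero-variance covariate in availability sample", call. = FALSE)
      }
      eta_max <- max(sweep(sweep(dcal, 2, scaler$center, "-"),
                           2, scaler$scale, "/") %*% config$beta)
      kept <- matrix(numeric(0), 0, 2)
      n_prop <- 0L
      while (nrow(kept) < config$n_fixes) {
        batch <- max(2000L, 4L * (config$n_fixes - nrow(kept)))
        cand <- propose(batch)
        eta <- .movement_covariates(cand, landscape, scaler) %*% config$beta
        acc <- stats::runif(batch) < exp(eta - eta_max)
        kept <- rbind(kept, cand[acc, , drop = FALSE])
        n_prop <- n_prop + batch
        rate <- nrow(kept) / n_prop
        if (n_prop >= 2e5 && rate < 1e-4) {
          stop("acceptance rate below 1e-4: beta too extreme for this landscape",
               call. = FALSE)
        }
      }
      list(xy = kept[seq_len(config$n_fixes), , drop = FALSE],
           scaler = scaler, rate = nrow(kept) / n_prop)
    }
  })
  out <- data.frame(
    animal_id = animal_id,
    timestamp = config$start + (seq_len(config$n_fixes) - 1L) * config$fix_interval_h * 3600,
    x = res$xy[, 1], y = res$xy[, 2],
    source = "gps",
    stringsAsFactors = FALSE
  )
  attr(out, "scaler") <- res$scaler
  attr(out, "acceptance_rate") <- res$rate
  out
}

#' Draw an availability sample from a movement configuration
#'
#' Raw proposals from the bivariate normal availability kernel, without
#' habitat thinning. This is the correct "available" contrast when the aim is
#' to recover `beta` from simulated tracks.
#'
#' @param config a [movement_config()].
#' @param n number of points.
#' @param seed seed (defaults to `config$seed + 1` so it does not reuse the
#'   track's stream).
#' @return data frame (x, y).
#' @export
gen_availability <- function(config, n, seed = config$seed + 1L) {
  stopifnot(inherits(config, "movement_config"), n >= 1)
  xy <- with_seed(seed, cbind(stats::rnorm(n, config$center[1], config$sigma),
                              stats::rnorm(n, config$center[2], config$sigma)))
  data.frame(x = xy[, 1], y = xy[, 2])
}

#' Ground-truth density scenario
#'
#' A territory layout with known density: `n_groups` social groups of
#' `group_size` adults in `area_km2` square kilometers, the group-count
#' density construction used for territorial canids.
#'
#' @param n_groups number of resident groups (> 0).
#' @param group_size mean adults per group (> 0).
#' @param area_km2 total occupied area, km^2 (> 0).
#' @return a `canid_density_scenario` with element `true_density`
#'   (adults/km^2).
#' @export
gen_territories <- function(n_groups, group_size, area_km2) {
  if (area_km2 <= 0) stop("area_km2 must be > 0", call. = FALSE)
  if (n_groups <= 0 || group_size <= 0) {
    stop("n_groups and group_size must be > 0", call. = FALSE)
  }
  structure(list(n_groups = n_groups, group_size = group_size,
                 area_km2 = area_km2,
                 true_density = n_groups * group_size / area_km2),
            class = "canid_density_scenario")
}

#' Write relocations to CSV (animal_id, timestamp ISO-8601, x, y, source)
#' @param relocations data frame from [gen_movement()] or compatible.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_relocations_csv <- function(relocations, path) {
  df <- relocations
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read relocations from CSV
#' @param path CSV with columns animal_id, timestamp, x, y and optional source.
#' @return data frame with POSIXct timestamps.
#' @export
read_relocations_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("animal_id", "timestamp", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("relocations file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%SZ",
                                            "%Y-%m-%d %H:%M:%S", "%Y-%m-%d"))
  if (is.null(df$source)) df$source <- "gps"
  df
}
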