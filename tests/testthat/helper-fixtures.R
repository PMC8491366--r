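# Shared fixtures, built in code. The landscape is cached per test run.

toy_landscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- gen_landscape(landscape_config(extent = c(0, 0, 20000, 20000),
                                               seed = 7L))
    }
    cache
  }
})

# A minimal hand-built landscape with exactly one feature per type, at known
# geometry, for distance assertions.
unit_landscape <- function() {
  structure(list(
    extent = c(-1000, -1000, 1000, 1000),
    features = list(
      list(type = "road", kind = "line",
           coords = cbind(c(3, 3), c(4, 100))),
      list(type = "stream", kind = "line",
           coords = cbind(c(-500, -500), c(-500, 500))),
      list(type = "dense_forest", kind = "polygon",
           coords = cbind(c(200, 400, 400, 200), c(200, 200, 400, 400)))),
    config = NULL), class = "canid_landscape")
}

# Long-format scats from a compact spec: list of named volume vectors, one
# per scat; equal dry weights unless given.
make_scats <- function(items, dry_weight = 10, dates = NULL) {
  n <- length(items)
  if (length(dry_weight) == 1) dry_weight <- rep(dry_weight, n)
  if (is.null(dates)) dates <- rep(as.Date("2014-01-15"), n)
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    v <- items[[i]]
    data.frame(scat_id = sprintf("S%03d", i), date = dates[i],
               dry_weight_g = dry_weight[i], taxon = names(v),
               volume_percent = as.numeric(v), stringsAsFactors = FALSE)
  }))
  rows
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "wildcanid")
  if (path == "") path <- file.path("../../inst/extdata", file)
  path
}

published_diet <- function() {
  utils::read.csv(extdata("jackal_diet_biomass.csv"), stringsAsFactors = FALSE)
}

published_availability <- function() {
  av <- utils::read.csv(extdata("ungulate_availability.csv"),
                        stringsAsFactors = FALSE)
  available_biomass(stats::setNames(av$density_per_km2, av$species),
                    stats::setNames(av$adult_female_mass_kg, av$species))
}

# Build a canid_ud directly from a bivariate density function on a square
# grid (for oracle comparisons that bypass the KDE path).
ud_from_density <- function(f, xlim, ylim, n = 200L) {
  cell <- max(diff(xlim), diff(ylim)) / n
  gx <- xlim[1] + (seq_len(ceiling(diff(xlim) / cell)) - 0.5) * cell
  gy <- ylim[1] + (seq_len(ceiling(diff(ylim) / cell)) - 0.5) * cell
  z <- outer(gx, gy, f)
  structure(list(x = gx, y = gy, cell = cell, h = NA_real_, z = z / sum(z)),
            class = "canid_ud")
}

# Independent convex hull via Andrew's monotone chain (oracle for MCP).
monotone_chain_hull <- function(xy) {
  xy <- unique(xy[order(xy[, 1], xy[, 2]), , drop = FALSE])
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(pts) {
    h <- list()
    for (i in seq_len(nrow(pts))) {
      p <- pts[i, ]
      while (length(h) >= 2 &&
             cross(h[[length(h) - 1]], h[[length(h)]], p) <= 0) {
        h[[length(h)]] <- NULL
      }
      h[[length(h) + 1]] <- p
    }
    h
  }
  lower <- build(xy)
  upper <- build(xy[rev(seq_len(nrow(xy))), , drop = FALSE])
  do.call(rbind, c(lower[-length(lower)], upper[-length(upper)]))
}
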