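# Kernel home ranges, bandwidths, MCP, overlap indices, summaries.

std_points <- function(n, seed, sd = 1) {
  set.seed(seed)
  cbind(stats::rnorm(n, 0, sd), stats::rnorm(n, 0, sd))
}

# Exact-unit-sample-variance cloud (so h_ref is forced by the formula).
unit_var_points <- function(n, seed) {
  xy <- std_points(n, seed)
  cbind((xy[, 1] - mean(xy[, 1])) / stats::sd(xy[, 1]),
        (xy[, 2] - mean(xy[, 2])) / stats::sd(xy[, 2]))
}

test_that("the reference bandwidth follows the bivariate normal plug-in rule", {
  xy <- unit_var_points(64, 1)
  expect_equal(href(xy), 64^(-1 / 6), tolerance = 1e-12)
  expect_equal(href(xy), 0.5, tolerance = 1e-12)
  expect_equal(href(xy * 250), 250 * href(xy), tolerance = 1e-9)
  expect_error(href(xy[1:4, ]), "at least 5")
  expect_error(href(matrix(1, 10, 2)), "identical")
  # Monte-Carlo: mean h_ref near sigma * n^(-1/6) for normal data
  set.seed(2)
  hs <- replicate(100, href(cbind(stats::rnorm(100, 0, 1000),
                                  stats::rnorm(100, 0, 1000))))
  expect_lt(abs(mean(hs) - 1000 * 100^(-1 / 6)) / (1000 * 100^(-1 / 6)), 0.05)
})

test_that("the kernel UD normalizes, peaks at the data, and matches kde2d", {
  one <- matrix(c(120, 340), 1, 2)
  ud <- kde_ud(one, h = 50, grid_n = 64)
  expect_equal(sum(ud$z), 1, tolerance = 1e-12)
  peak <- which(ud$z == max(ud$z), arr.ind = TRUE)
  expect_lt(abs(ud$x[peak[1]] - 120), ud$cell)
  expect_lt(abs(ud$y[peak[2]] - 340), ud$cell)

  xy <- std_points(200, 3, sd = 100)
  h <- 40
  ud2 <- kde_ud(xy, h, grid_n = 128)
  ref <- MASS::kde2d(xy[, 1], xy[, 2], h = 4 * h,
                     n = c(length(ud2$x), length(ud2$y)),
                     lims = c(range(ud2$x), range(ud2$y)))
  refz <- ref$z / sum(ref$z)
  expect_lt(max(abs(ud2$z - refz)), 1e-10)

  expect_error(kde_ud(xy, h, grid = list(x = 0:10, y = 0:10, cell = 1)),
               "3h margin")
})

test_that("95% KDE area approaches the analytic Gaussian ellipse", {
  xy <- std_points(1000, 4)
  h <- 0.8 * href(xy)
  ud <- kde_ud(xy, h, grid_n = 192)
  area_m2 <- isopleth(ud, 0.95)$area_km2 * 1e6
  analytic <- pi * stats::qchisq(0.95, 2) * (1 + h^2)
  expect_lt(abs(area_m2 - analytic) / analytic, 0.15)
})

test_that("isopleths count highest-mass cells with deterministic tie-breaking", {
  z <- matrix(1 / 100, 10, 10)
  ud <- structure(list(x = seq(0.5, 9.5), y = seq(0.5, 9.5), cell = 1,
                       h = 1, z = z), class = "canid_ud")
  expect_equal(isopleth(ud, 0.95)$n_cells, 95L)
  expect_equal(isopleth(ud, 1.0)$n_cells, 100L)
  # zero-mass cells are never included at level 1
  z2 <- z; z2[1:5] <- 0; z2 <- z2 / sum(z2)
  ud2 <- structure(list(x = ud$x, y = ud$y, cell = 1, h = 1, z = z2),
                   class = "canid_ud")
  expect_equal(isopleth(ud2, 1.0)$n_cells, 95L)
  # nesting
  xy <- std_points(300, 5, sd = 500)
  ud3 <- kde_ud(xy, 200, grid_n = 96)
  m50 <- isopleth(ud3, 0.5)$mask
  m95 <- isopleth(ud3, 0.95)$mask
  expect_true(all(m95[m50]))
  expect_lte(isopleth(ud3, 0.5)$area_km2, isopleth(ud3, 0.95)$area_km2)
})

test_that("KDE area shrinks with the bandwidth and is grid-stable", {
  xy <- std_points(300, 6, sd = 1000)
  h_ref <- href(xy)
  grid <- make_grid(xy, h_ref, n = 128)
  areas <- vapply(seq(1, 0.2, by = -0.2), function(m) {
    isopleth(kde_ud(xy, m * h_ref, grid = grid), 0.95)$area_km2
  }, 0)
  expect_true(all(diff(areas) < 0))
  a128 <- isopleth(kde_ud(xy, h_ref, grid_n = 128), 0.95)$area_km2
  a256 <- isopleth(kde_ud(xy, h_ref, grid_n = 256), 0.95)$area_km2
  expect_lt(abs(a256 - a128) / a128, 0.05)
})

test_that("the ad hoc bandwidth scan finds the contiguity threshold", {
  # single tight cluster: small multiplier, contiguous at h, fragmented below
  xy <- std_points(1000, 7)
  h <- adhoc_bandwidth(xy, grid_n = 128)
  m <- attr(h, "multiplier")
  expect_lte(m, 0.7)  # well below h_ref for one tight cluster
  grid <- make_grid(xy, href(xy), n = 128)
  ok_at <- function(mult) {
    wildcanid:::.contiguous_no_holes(
      isopleth(kde_ud(xy, mult * href(xy), grid = grid), 0.95)$mask)
  }
  expect_true(ok_at(m))
  expect_false(ok_at(m - 0.05))
  expect_lte(as.numeric(h), href(xy))

  # two clusters: the returned multiplier is the smallest that keeps the
  # bridge closed; one step below, the isopleth splits
  two <- rbind(std_points(400, 8), sweep(std_points(400, 9), 2, c(7, 0), "+"))
  h2 <- adhoc_bandwidth(two, grid_n = 96)
  m2 <- attr(h2, "multiplier")
  expect_gt(m2, 0.05)
  grid2 <- make_grid(two, href(two), n = 96)
  ok2 <- function(mult) {
    wildcanid:::.contiguous_no_holes(
      isopleth(kde_ud(two, mult * href(two), grid = grid2), 0.95)$mask)
  }
  expect_true(ok2(m2))
  expect_false(ok2(m2 - 0.05))

  # far-apart clusters are fragmented even at h_ref: warning and h_ref back
  far <- rbind(std_points(300, 10), sweep(std_points(300, 11), 2, c(20, 0), "+"))
  expect_warning(h3 <- adhoc_bandwidth(far, grid_n = 96), "fragmented")
  expect_equal(as.numeric(h3), href(far))
})

test_that("the bandwidth rule takes the larger of 0.8 h_ref and the ad hoc value", {
  xy <- std_points(500, 12, sd = 800)
  bw <- select_bandwidth(xy, grid_n = 96)
  expect_equal(bw$h_used, max(0.8 * bw$h_ref, bw$h_adhoc))
  expect_gt(bw$h_used, 0)
})

test_that("MCP removes the farthest points and matches an independent hull", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  m <- mcp(square, percent = 1.0)
  expect_equal(m$area_km2 * 1e6, 1, tolerance = 1e-12)

  # boundary ring plus a distant outlier: outlier is removed at 95%
  t <- seq(0, 1, length.out = 26)[-26]
  ring <- 10000 * rbind(cbind(t, 0), cbind(1, t), cbind(1 - t, 1), cbind(0, 1 - t))
  pts <- rbind(ring, c(50000, 50000))
  m95 <- mcp(pts, percent = 0.95)
  expect_true(all(m95$vertices[, 1] <= 10000 + 1e-9))
  expect_equal(m95$area_km2, 100, tolerance = 0.1)

  # monotone in percent
  xy <- std_points(200, 13, sd = 1000)
  areas <- vapply(c(0.5, 0.75, 0.95, 1), function(p) mcp(xy, p)$area_km2, 0)
  expect_true(all(diff(areas) >= 0))

  # shoelace hull area agrees with a monotone-chain oracle
  set.seed(14)
  for (i in 1:20) {
    xy <- cbind(stats::runif(50), stats::runif(50))
    expect_equal(mcp(xy, 1)$area_km2 * 1e6,
                 shoelace_area(monotone_chain_hull(xy)), tolerance = 1e-9)
  }
  expect_error(mcp(xy[1:4, ], 1), "at least 5")
})

test_that("UDOI hits its identities and agrees with closed-form quadrature", {
  # identical uniform UDs over the full support
  z <- matrix(0, 20, 20); z[6:15, 6:15] <- 1 / 100
  udu <- structure(list(x = seq(0.5, 19.5), y = seq(0.5, 19.5), cell = 1,
                        h = 1, z = z), class = "canid_ud")
  expect_equal(udoi(udu, udu, level = 1.0), 1, tolerance = 1e-12)

  # disjoint supports
  z2 <- matrix(0, 20, 20); z2[1:3, 1:3] <- 1 / 9
  udv <- structure(list(x = udu$x, y = udu$y, cell = 1, h = 1, z = z2),
                   class = "canid_ud")
  expect_equal(udoi(udu, udv), 0)

  # grid mismatch is an error
  udw <- structure(list(x = udu$x + 1, y = udu$y, cell = 1, h = 1, z = z),
                   class = "canid_ud")
  expect_error(udoi(udu, udw), "identical grid")

  # two unit Gaussians 1 sigma apart vs the analytic double integral
  f1 <- function(x, y) exp(-(x^2 + y^2) / 2)
  f2 <- function(x, y) exp(-((x - 1)^2 + y^2) / 2)
  lim <- c(-6, 7)
  ua <- ud_from_density(f1, lim, lim, n = 400)
  ub <- ud_from_density(f2, lim, lim, n = 400)
  got <- udoi(ua, ub, level = 0.95)
  # analytic: integral of the two unit normal densities = exp(-d^2/4)/(4 pi);
  # overlap area = lens of two radius-r circles, r^2 = chi2_2(0.95), d = 1
  r <- sqrt(stats::qchisq(0.95, 2)); d <- 1
  lens <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  expected <- lens * exp(-d^2 / 4) / (4 * pi)
  expect_lt(abs(got - expected) / expected, 0.02)
  expect_equal(udoi(ua, ub), udoi(ub, ua), tolerance = 1e-12)
})

test_that("percent area overlap is exact on constructed geometries", {
  A <- rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1))
  expect_equal(unname(percent_area_overlap(A, A)), c(100, 100, 100))
  B <- rbind(c(10, 10), c(11, 10), c(11, 11), c(10, 11))
  expect_equal(unname(percent_area_overlap(A, B)), c(0, 0, 0))
  half <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(unname(percent_area_overlap(half, A)), c(100, 50, 75))
  expect_error(percent_area_overlap(A, rbind(c(0, 0), c(1, 1), c(2, 2))),
               "zero-area")
})

test_that("monthly ranges enforce the location-count and span filters", {
  mk <- function(id, n, days, month0 = "2015-05-01") {
    data.frame(animal_id = id,
               timestamp = as.POSIXct(month0, tz = "UTC") +
                 seq(0, days * 86400, length.out = n),
               x = stats::rnorm(n, 0, 800), y = stats::rnorm(n, 0, 800),
               stringsAsFactors = FALSE)
  }
  set.seed(15)
  too_few <- mk("a", 27, 20)
  too_short <- mk("b", 30, 10)
  ok <- mk("c", 28, 15)
  expect_warning(r1 <- monthly_ranges(rbind(too_few, too_short), grid_n = 64),
                 "no month")
  expect_equal(nrow(r1), 0)
  r2 <- monthly_ranges(rbind(too_few, too_short, ok), grid_n = 64)
  expect_equal(r2$animal_id, "c")
  expect_equal(r2$n_locations, 28L)
})

test_that("range summaries reproduce the published mean and SE arithmetic", {
  s <- summarize_ranges(c(50.7, 46.7, 40.1, 50.8))
  expect_equal(round(s$mean, 1), 47.1)
  expect_equal(round(s$se, 1), 2.5)
  expect_equal(summarize_ranges(c(4, 4, 4))$se, 0)
  expect_equal(summarize_ranges(c(1, 3)), list(mean = 2, se = 1))
  expect_error(summarize_ranges(5), "at least 2")
})

test_that("group-count density is exact arithmetic with guarded inputs", {
  expect_equal(density_estimate(4, 2, 800), 0.01)
  expect_equal(density_estimate(1, 1, 1), 1)
  expect_equal(density_estimate(5, 3.2, 400), 0.04)
  expect_error(density_estimate(4, 2, 0), "area")
})

test_that("foray handling removes only listed windows and flags by distance", {
  base <- as.POSIXct("2015-06-01 00:00:00", tz = "UTC")
  rel <- data.frame(animal_id = "a",
                    timestamp = base + (0:9) * 21600,
                    x = c(rep(0, 9), 12000), y = 0,
                    stringsAsFactors = FALSE)
  expect_equal(exclude_forays(rel), rel)
  # manual exclusion removes the window
  excl <- data.frame(animal_id = "a", start = base + 9 * 21600 - 1,
                     end = base + 9 * 21600 + 1)
  expect_equal(nrow(exclude_forays(rel, exclusions = excl)), 9)
  # auto mode flags the 12-km fix at threshold 12 but removes nothing
  fl <- exclude_forays(rel, auto_threshold_km = 12)
  expect_equal(nrow(fl), 10)
  expect_equal(sum(fl$foray_flag), 1)
  expect_true(fl$foray_flag[10])
  # flag count nonincreasing in threshold
  counts <- vapply(c(1, 5, 12, 13),
                   function(th) sum(exclude_forays(rel, auto_threshold_km = th)$foray_flag),
                   0)
  expect_true(all(diff(counts) <= 0))
})

test_that("isopleth polygons trace closed rings with the right total area", {
  xy <- std_points(400, 16, sd = 500)
  iso <- isopleth(kde_ud(xy, 300, grid_n = 64), 0.95)
  rings <- isopleth_polygons(iso)
  expect_gt(length(rings), 0)
  for (r in rings) {
    expect_equal(r[1, ], r[nrow(r), ], ignore_attr = TRUE)
  }
  outer_area <- sum(vapply(rings, shoelace_area, 0))
  # ring areas (outer minus holes, all positive here) match counted cells
  expect_equal(outer_area / 1e6, iso$area_km2, tolerance = 0.25)
})

test_that("the ASCII grid writer emits a parseable normalized surface", {
  xy <- std_points(100, 17, sd = 300)
  ud <- kde_ud(xy, 200, grid_n = 32)
  f <- withr::local_tempfile(fileext = ".asc")
  write_ud_asc(ud, f)
  hdr <- readLines(f, n = 6)
  expect_match(hdr[1], "^ncols")
  vals <- scan(f, skip = 6, quiet = TRUE)
  expect_equal(sum(vals), 1, tolerance = 1e-4)
})
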