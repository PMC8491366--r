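# Internal geometry and RNG helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are reproducible without clobbering the session.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Shoelace signed area of a polygon given as a 2-column matrix (open ring).
shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Minimum Euclidean distance from each point to a set of segments.
# points: n x 2 matrix; segs: m x 4 matrix (x1, y1, x2, y2).
dist_point_segments <- function(points, segs) {
  px <- points[, 1]; py <- points[, 2]
  best <- rep(Inf, length(px))
  for (i in seq_len(nrow(segs))) {
    x1 <- segs[i, 1]; y1 <- segs[i, 2]; x2 <- segs[i, 3]; y2 <- segs[i, 4]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d2 <- (px - x1)^2 + (py - y1)^2
    } else {
      t <- ((px - x1) * dx + (py - y1) * dy) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# Convert a polyline (k x 2) to a segment matrix (k-1 x 4).
polyline_segments <- function(xy) {
  k <- nrow(xy)
  cbind(xy[-k, 1], xy[-k, 2], xy[-1, 1], xy[-1, 2])
}

# Even-odd point-in-polygon test; poly is an open ring (k x 2).
points_in_polygon <- function(points, poly) {
  px <- points[, 1]; py <- points[, 2]
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Sutherland-Hodgman clipping of polygon `subject` by convex polygon `clip`.
# Both open rings; returns an open ring matrix (possibly with 0 rows).
clip_polygon_convex <- function(subject, clip) {
  # orient clip counter-clockwise so "inside" is a consistent half-plane test
  if (polygon_signed_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]; b <- clip[if (i == nc) 1L else i + 1L, ]
    input <- out
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(input)
    side <- (b[1] - a[1]) * (input[, 2] - a[2]) - (b[2] - a[2]) * (input[, 1] - a[1])
    for (k in seq_len(n)) {
      kn <- if (k == n) 1L else k + 1L
      cur_in <- side[k] >= -1e-12
      nxt_in <- side[kn] >= -1e-12
      if (cur_in) out <- rbind(out, input[k, ])
      if (cur_in != nxt_in) {
        t <- side[k] / (side[k] - side[kn])
        out <- rbind(out, input[k, ] + t * (input[kn, ] - input[k, ]))
      }
    }
  }
  out
}

polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# Dirichlet sampler (one draw).
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1  # degenerate guard
  g / sum(g)
}

# Short config hash for output headers (polynomial rolling hash, mod 2^31-1).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
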