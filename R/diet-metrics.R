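# Dietary niche and prey-selection metrics: Levins niche breadth, Horn's
# overlap, density x mass biomass availability, and Jacobs' electivity.

# Validate a proportion vector: nonnegative, sums to 1 within 1e-6
# (renormalized), else rejected.
.check_proportions <- function(p, arg = "p") {
  if (any(p < 0)) stop(arg, " has negative entries", call. = FALSE)
  s <- sum(p)
  if (abs(s - 1) > 1e-6) {
    stop(arg, " must sum to 1 (got ", format(s), "); use as_proportions()",
         call. = FALSE)
  }
  p / s
}

#' Normalize a nonnegative vector to proportions
#' @param x nonnegative numeric vector (e.g. percentages).
#' @return `x / sum(x)`, names preserved.
#' @export
as_proportions <- function(x) {
  if (any(x < 0) || sum(x) <= 0) {
    stop("x must be nonnegative with positive sum", call. = FALSE)
  }
  x / sum(x)
}

#' Levins measure of niche breadth
#'
#' B = 1 / sum(p_i^2), the effective number of equally used diet categories;
#' 1 <= B <= number of taxa.
#'
#' @param p proportion vector (sums to 1 within 1e-6).
#' @return numeric B.
#' @export
levins_B <- function(p) {
  p <- .check_proportions(p)
  1 / sum(p^2)
}

#' Horn's index of dietary overlap
#'
#' R0 = \[sum((p+q) ln(p+q)) - sum(p ln p) - sum(q ln q)\] / (2 ln 2) with
#' 0 ln 0 := 0, computed over the union of the two taxon sets (zero-filled);
#' 0 = disjoint diets, 1 = identical.
#'
#' @param p,q proportion vectors; if named, aligned by name over the union.
#' @return numeric R0 in \[0, 1\].
#' @export
horns_R0 <- function(p, q) {
  if (!is.null(names(p)) || !is.null(names(q))) {
    if (is.null(names(p)) || is.null(names(q))) {
      stop("either both or neither of p and q must be named", call. = FALSE)
    }
    taxa <- union(names(p), names(q))
    p <- stats::setNames(p[taxa], taxa); p[is.na(p)] <- 0
    q <- stats::setNames(q[taxa], taxa); q[is.na(q)] <- 0
  } else if (length(p) != length(q)) {
    stop("unnamed p and q must have equal length", call. = FALSE)
  }
  p <- .check_proportions(p, "p")
  q <- .check_proportions(q, "q")
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  r0 <- (sum(xlx(p + q)) - sum(xlx(p)) - sum(xlx(q))) / (2 * log(2))
  min(1, max(0, r0))
}

#' Ungulate biomass availability from densities and body masses
#'
#' biomass_share_i = density_i * mass_i / sum_j density_j * mass_j. Shares
#' are invariant to common rescaling of densities or masses.
#'
#' @param densities named numeric, individuals per km^2 (> 0).
#' @param masses named numeric, adult female body mass in kg (> 0); same
#'   species set as `densities`.
#' @return data frame (species, density, mass, biomass_share), shares
#'   summing to 1.
#' @export
available_biomass <- function(densities, masses) {
  if (is.null(names(densities)) || is.null(names(masses))) {
    stop("densities and masses must be named by species", call. = FALSE)
  }
  if (!setequal(names(densities), names(masses))) {
    stop("densities and masses must cover the same species", call. = FALSE)
  }
  if (any(densities <= 0) || any(masses <= 0)) {
    stop("densities and masses must be > 0", call. = FALSE)
  }
  masses <- masses[names(densities)]
  b <- densities * masses
  data.frame(species = names(densities),
             density = as.numeric(densities),
             mass = as.numeric(masses),
             biomass_share = as.numeric(b / sum(b)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Jacobs' electivity index
#'
#' D = (r - p) / (r + p - 2 r p) for consumed share r and available share p;
#' -1 is complete avoidance, +1 complete selection, 0 use in proportion to
#' availability. Vectorized.
#'
#' @param r consumed (used) share in \[0, 1\].
#' @param p available share in \[0, 1\]; r and p must not both be 0.
#' @return numeric D in \[-1, 1\].
#' @export
jacobs_D <- function(r, p) {
  if (any(r < 0 | r > 1) || any(p < 0 | p > 1)) {
    stop("r and p must lie in [0, 1]", call. = FALSE)
  }
  if (any(r == 0 & p == 0)) {
    stop("D is undefined when r and p are both 0", call. = FALSE)
  }
  (r - p) / (r + p - 2 * r * p)
}

# Extract item-level biomass percents for given species from a composition
# table or a named numeric vector; absent species get 0. Also returns the
# category total used as the electivity denominator: the category roll-up
# row when present (it can differ from the item sum by printed rounding),
# otherwise the sum over category items, otherwise the sum over species.
.consumed_percent <- function(composition, species, category) {
  if (is.data.frame(composition)) {
    tab <- composition
    if (!is.null(tab$season) && "total" %in% tab$season) {
      tab <- tab[tab$season == "total", , drop = FALSE]
    }
    items <- if (!is.null(tab$level)) tab[tab$level == "item", , drop = FALSE] else tab
    v <- stats::setNames(items$biomass_percent, items$taxon)
    total <- NA_real_
    if (!is.null(tab$level) && !is.null(tab$category)) {
      cr <- tab[tab$level == "category" & tab$taxon == category, , drop = FALSE]
      if (nrow(cr) == 1) total <- cr$biomass_percent
      if (is.na(total)) {
        total <- sum(items$biomass_percent[items$category == category])
      }
    }
  } else {
    v <- composition
    if (is.null(names(v))) stop("composition vector must be named", call. = FALSE)
    total <- sum(v)
  }
  out <- stats::setNames(as.numeric(v[species]), species)
  out[is.na(out)] <- 0
  if (is.na(total) || total <= 0) total <- sum(out)
  list(consumed = out, total = total)
}

#' Prey electivity of ungulates from a diet composition
#'
#' Consumed shares r are each species' biomass percent divided by the total
#' biomass percent of the ungulate category (so species absent from the diet
#' get r = 0), availability shares p come from [available_biomass()], and
#' Jacobs' D is computed per species.
#'
#' @param composition a [composition_table()] result (the pooled "total"
#'   season is used; the category roll-up row supplies the denominator), or
#'   a named numeric vector of biomass percents of the category members.
#' @param avail an [available_biomass()] result.
#' @param category category label whose total is the denominator (default
#'   "ungulate").
#' @return data frame (species, r, p, D).
#' @export
ungulate_selection <- function(composition, avail, category = "ungulate") {
  stopifnot(is.data.frame(avail), all(c("species", "biomass_share") %in% names(avail)))
  cp <- .consumed_percent(composition, avail$species, category)
  if (sum(cp$consumed) <= 0) {
    stop("no ungulate biomass consumed; electivity undefined", call. = FALSE)
  }
  r <- pmin(1, as.numeric(cp$consumed / cp$total))
  p <- avail$biomass_share
  data.frame(species = avail$species, r = r, p = p,
             D = jacobs_D(r, p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dietary overlap between two compositions
#'
#' Horn's R0 on the two biomass proportion vectors, aligned on the union of
#' their category schemes (zero-filled; disjoint schemes give 0).
#'
#' @param comp_a,comp_b composition tables (item level, total season used)
#'   or named biomass-percent vectors.
#' @return numeric R0 in \[0, 1\].
#' @export
diet_overlap <- function(comp_a, comp_b) {
  va <- .composition_vector(comp_a)
  vb <- .composition_vector(comp_b)
  horns_R0(as_proportions(va), as_proportions(vb))
}

.composition_vector <- function(composition) {
  if (is.data.frame(composition)) {
    items <- composition
    if (!is.null(items$level)) items <- items[items$level == "item", , drop = FALSE]
    if (!is.null(items$season) && "total" %in% items$season) {
      items <- items[items$season == "total", , drop = FALSE]
    }
    stats::setNames(items$biomass_percent, items$taxon)
  } else {
    if (is.null(names(composition))) {
      stop("composition vector must be named", call. = FALSE)
    }
    composition
  }
}
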