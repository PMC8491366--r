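# Synthetic scat generator with known ground-truth biomass proportions.
#
# The design goal is exact invertibility: the correction-factor (CF) biomass
# pipeline applied to generated scats must recover the configured true
# biomass shares in expectation. Dry-residue "weight" of taxon t per unit
# biomass is 1/CF_t, so residue shares are w_t = p_t / CF_t (normalized).
# Items are selected by systematic PPS sampling with closed-form inclusion
# probabilities pi_t, volume means within a scat are proportional to
# w_t / pi_t, and the scat dry weight is scaled by the scat's total residue
# weight, which makes E[CF-reconstructed share] equal p_t exactly.

#' Diet generator configuration
#'
#' @param p_true named numeric vector of true biomass proportions (sums to 1).
#' @param cf named numeric vector of correction factors (grams consumed per
#'   gram dry residue), same names as `p_true`; all > 0.
#' @param items_per_scat probability vector over 1..5 items per scat
#'   (default the observed field mix 14.4/38.4/27.4/17.1/2.7 percent);
#'   truncated and renormalized if there are fewer taxa than 5.
#' @param dry_weight_logmean,dry_weight_logsd lognormal parameters of the
#'   baseline scat dry weight in grams (defaults log(10) and 0.5; biomass
#'   shares are invariant to this scale).
#' @param volume_concentration Dirichlet concentration for within-scat
#'   volume shares (default 6; larger = less variable volumes).
#' @param n_scats number of scats.
#' @param date_range length-2 character/date vector; collection dates are
#'   drawn uniformly in this window (default one dry season, Nov-May).
#' @param seed integer seed.
#' @return a `diet_config` list.
#' @export
diet_config <- function(p_true, cf,
                        items_per_scat = c(0.144, 0.384, 0.274, 0.171, 0.027),
                        dry_weight_logmean = log(10), dry_weight_logsd = 0.5,
                        volume_concentration = 6,
                        n_scats = 1000L,
                        date_range = c("2013-11-01", "2014-05-31"),
                        seed = 1L) {
  if (is.null(names(p_true)) || is.null(names(cf))) {
    stop("p_true and cf must be named", call. = FALSE)
  }
  if (!setequal(names(p_true), names(cf))) {
    stop("p_true and cf must cover the same taxa", call. = FALSE)
  }
  if (abs(sum(p_true) - 1) > 1e-9) {
    stop("p_true must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  if (any(cf <= 0)) stop("all correction factors must be > 0", call. = FALSE)
  if (any(items_per_scat < 0) || sum(items_per_scat) <= 0) {
    stop("items_per_scat must be a nonnegative probability vector", call. = FALSE)
  }
  structure(list(p_true = p_true, cf = cf[names(p_true)],
                 items_per_scat = items_per_scat / sum(items_per_scat),
                 dry_weight_logmean = dry_weight_logmean,
                 dry_weight_logsd = dry_weight_logsd,
                 volume_concentration = volume_concentration,
                 n_scats = as.integer(n_scats),
                 date_range = as.Date(date_range),
                 seed = as.integer(seed)),
            class = "diet_config")
}

# Exact inclusion probabilities for size-proportional sampling of k items
# with capping: pi = k*w/sum(w), units at/above 1 are included surely and the
# remainder re-solved.
pps_inclusion <- function(w, k) {
  n <- length(w)
  pi <- rep(NA_real_, n)
  idx <- seq_len(n)
  kk <- k
  repeat {
    p <- kk * w[idx] / sum(w[idx])
    if (all(p <= 1 + 1e-12)) {
      pi[idx] <- pmin(p, 1)
      break
    }
    capped <- idx[p >= 1]
    pi[capped] <- 1
    idx <- setdiff(idx, capped)
    kk <- kk - length(capped)
    if (length(idx) == 0L || kk <= 0L) {
      if (length(idx) > 0L) pi[idx] <- 0
      break
    }
  }
  pi
}

# Systematic PPS draw honouring the inclusion probabilities from
# pps_inclusion (sure units always in; randomized order for the rest).
pps_draw <- function(pi) {
  sure <- which(pi >= 1 - 1e-12)
  rest <- which(pi > 0 & pi < 1 - 1e-12)
  if (length(rest) == 0L) return(sure)
  ord <- sample(rest)
  cum <- cumsum(pi[ord])
  k <- round(cum[length(cum)])
  if (k == 0L) return(sure)
  u <- stats::runif(1)
  sel <- ord[findInterval(u + 0:(k - 1L), c(0, cum), rightmost.closed = TRUE)]
  c(sure, sel)
}

#' Generate synthetic scats
#'
#' Per scat: the item count is drawn from the configured distribution, items
#' are chosen by inclusion-probability-proportional-to-size sampling with
#' size w = p_true/CF (inverse-CF weighting), visual volume percents are
#' Dirichlet with mean compensated by the inclusion probabilities, and the
#' dry weight is lognormal scaled by the scat's total residue weight. The
#' construction makes the CF biomass pipeline unbiased for `p_true`.
#'
#' @param config a [diet_config()].
#' @return long-format data frame (scat_id, date, dry_weight_g, taxon,
#'   volume_percent), one row per item.
#' @export
gen_scats <- function(config) {
  stopifnot(inherits(config, "diet_config"))
  taxa <- names(config$p_true)
  ntax <- length(taxa)
  w <- config$p_true / config$cf
  wbar <- w / sum(w)
  kp <- config$items_per_scat[seq_len(min(length(config$items_per_scat), ntax))]
  kp <- kp / sum(kp)
  pi_by_k <- lapply(seq_along(kp), function(k) pps_inclusion(wbar, k))
  with_seed(config$seed, {
    n <- config$n_scats
    ks <- sample(seq_along(kp), n, replace = TRUE, prob = kp)
    dates <- config$date_range[1] +
      sample.int(as.integer(diff(config$date_range)) + 1L, n, replace = TRUE) - 1L
    rows_id <- integer(0); rows_tax <- integer(0)
    rows_vol <- numeric(0); rows_dw <- numeric(0)
    for (s in seq_len(n)) {
      pi <- pi_by_k[[ks[s]]]
      sel <- pps_draw(pi)
      a <- wbar[sel] / pi[sel]
      A <- sum(a)
      v <- if (length(sel) == 1L) 1 else rdirichlet1(config$volume_concentration * a / A)
      dw <- stats::rlnorm(1, config$dry_weight_logmean, config$dry_weight_logsd) * A
      rows_id <- c(rows_id, rep.int(s, length(sel)))
      rows_tax <- c(rows_tax, sel)
      rows_vol <- c(rows_vol, 100 * v)
      rows_dw <- c(rows_dw, rep.int(dw, length(sel)))
    }
    data.frame(scat_id = sprintf("S%05d", rows_id),
               date = dates[rows_id],
               dry_weight_g = rows_dw,
               taxon = taxa[rows_tax],
               volume_percent = rows_vol,
               stringsAsFactors = FALSE)
  })
}

#' Write/read scats in the long CSV format
#' @param scats long-format scat data frame.
#' @param path file path.
#' @return `path` (write) or the data frame (read).
#' @export
write_scats_csv <- function(scats, path) {
  utils::write.csv(scats, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scats_csv
#' @export
read_scats_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("scat_id", "date", "dry_weight_g", "taxon", "volume_percent")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("scats file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$date <- as.Date(df$date)
  df
}
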