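# Scat-based diet composition: trace exclusion, correction-factor biomass,
# percent volume, frequency of occurrence, seasonal tables, and the seasonal
# contingency chi-square.
#
# Scats are handled in long format: one row per identified item with columns
# scat_id, date, dry_weight_g, taxon, volume_percent. Identified volumes may
# sum to less than 100 within a scat (the unidentified remainder contributes
# nothing to biomass).

#' Season definition by collection month
#'
#' Default mapping: November-February cool_dry, March-May hot_dry,
#' June-October rainy. Every month must map to exactly one season.
#'
#' @param map named character vector of length 12, names "1".."12".
#' @return a `season_definition` (named character vector).
#' @export
season_definition <- function(map = NULL) {
  if (is.null(map)) {
    map <- c("1" = "cool_dry", "2" = "cool_dry", "3" = "hot_dry",
             "4" = "hot_dry", "5" = "hot_dry", "6" = "rainy", "7" = "rainy",
             "8" = "rainy", "9" = "rainy", "10" = "rainy",
             "11" = "cool_dry", "12" = "cool_dry")
  }
  if (!setequal(names(map), as.character(1:12))) {
    stop("season map must assign every month 1..12 exactly once", call. = FALSE)
  }
  structure(map[as.character(1:12)], class = "season_definition")
}

.season_of <- function(dates, seasons) {
  unclass(seasons)[as.character(as.integer(format(as.Date(dates), "%m")))]
}

.check_scats <- function(scats) {
  need <- c("scat_id", "dry_weight_g", "taxon", "volume_percent")
  miss <- setdiff(need, names(scats))
  if (length(miss) > 0) {
    stop("scat data missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  vol_sums <- tapply(scats$volume_percent, scats$scat_id, sum)
  if (any(vol_sums > 100 + 1e-6)) {
    bad <- names(vol_sums)[which(vol_sums > 100 + 1e-6)][1]
    stop("item volumes exceed 100% in scat ", bad, call. = FALSE)
  }
  dup <- duplicated(scats[, c("scat_id", "taxon")])
  if (any(dup)) {
    stop("duplicated taxon within scat ", scats$scat_id[which(dup)[1]],
         call. = FALSE)
  }
  invisible(scats)
}

#' Remove trace items from scats
#'
#' Items at or below the threshold volume percent are dropped; remaining
#' volumes are left untouched (no renormalization). A scat may end up with
#' no items.
#'
#' @param scats long-format scat data frame.
#' @param threshold_percent inclusive trace threshold (default 2, i.e. items
#'   making up 1-2% of a scat are considered trace).
#' @return the filtered data frame.
#' @export
exclude_trace <- function(scats, threshold_percent = 2) {
  if (threshold_percent < 0) stop("threshold must be >= 0", call. = FALSE)
  scats[scats$volume_percent > threshold_percent, , drop = FALSE]
}

# Normalize a CF table argument to a data.frame(taxon, cf, category).
.cf_table <- function(cf) {
  if (is.data.frame(cf)) {
    if (!all(c("taxon", "cf") %in% names(cf))) {
      stop("CF table needs columns taxon and cf", call. = FALSE)
    }
    if (is.null(cf$category)) cf$category <- cf$taxon
    tab <- cf[, c("taxon", "cf", "category")]
  } else {
    if (is.null(names(cf))) stop("cf vector must be named by taxon", call. = FALSE)
    tab <- data.frame(taxon = names(cf), cf = as.numeric(cf),
                      category = names(cf), stringsAsFactors = FALSE)
  }
  if (any(tab$cf <= 0)) stop("all correction factors must be > 0", call. = FALSE)
  tab
}

#' Biomass consumed per taxon via correction factors
#'
#' Scat dry weight is allocated to items by volume share; the dry remains of
#' each item are converted to ingested biomass with the taxon's correction
#' factor (grams consumed per gram dry residue). Unidentified volume
#' (identified volumes summing below 100) contributes nothing.
#'
#' @param scats long-format scat data frame (after any trace exclusion).
#' @param cf named numeric vector or data frame (taxon, cf, category).
#' @return data frame (taxon, dry_mass_g, biomass_g, biomass_percent),
#'   biomass_percent summing to 100.
#' @export
biomass_consumed <- function(scats, cf) {
  .check_scats(scats)
  tab <- .cf_table(cf)
  unknown <- !(scats$taxon %in% tab$taxon)
  if (any(unknown)) {
    i <- which(unknown)[1]
    stop("no correction factor for taxon '", scats$taxon[i],
         "' (scat ", scats$scat_id[i], ")", call. = FALSE)
  }
  dry <- scats$dry_weight_g * scats$volume_percent / 100
  dry_by_taxon <- tapply(dry, scats$taxon, sum)
  cfv <- stats::setNames(tab$cf, tab$taxon)
  bio <- dry_by_taxon * cfv[names(dry_by_taxon)]
  data.frame(taxon = names(dry_by_taxon),
             dry_mass_g = as.numeric(dry_by_taxon),
             biomass_g = as.numeric(bio),
             biomass_percent = 100 * as.numeric(bio) / sum(bio),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean percent volume per taxon
#'
#' Arithmetic mean over all scats of the taxon's per-scat volume percent,
#' counting 0 where the taxon is absent.
#'
#' @param scats long-format scat data frame.
#' @return data frame (taxon, volume_percent).
#' @export
percent_volume <- function(scats) {
  if (nrow(scats) == 0) stop("no scats", call. = FALSE)
  n_scats <- length(unique(scats$scat_id))
  tot <- tapply(scats$volume_percent, scats$taxon, sum)
  data.frame(taxon = names(tot),
             volume_percent = as.numeric(tot) / n_scats,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Frequency of occurrence per taxon
#'
#' Percentage of scats containing the taxon. When a category map is given,
#' category-level occurrence counts a scat once if it contains any member
#' taxon (set union).
#'
#' @param scats long-format scat data frame.
#' @param categories optional named character vector taxon -> category.
#' @return data frame (level, taxon, occurrence_percent) where level is
#'   "item" or "category".
#' @export
frequency_occurrence <- function(scats, categories = NULL) {
  if (nrow(scats) == 0) stop("no scats", call. = FALSE)
  n_scats <- length(unique(scats$scat_id))
  cnt <- tapply(scats$scat_id, scats$taxon, function(s) length(unique(s)))
  out <- data.frame(level = "item", taxon = names(cnt),
                    occurrence_percent = 100 * as.numeric(cnt) / n_scats,
                    stringsAsFactors = FALSE)
  if (!is.null(categories)) {
    cat_of <- categories[scats$taxon]
    ccnt <- tapply(scats$scat_id, cat_of, function(s) length(unique(s)))
    out <- rbind(out,
                 data.frame(level = "category", taxon = names(ccnt),
                            occurrence_percent = 100 * as.numeric(ccnt) / n_scats,
                            stringsAsFactors = FALSE))
  }
  row.names(out) <- NULL
  out
}

#' Seasonal and pooled diet composition
#'
#' Applies trace exclusion, then builds one composition per represented
#' season plus a pooled "total": percent biomass (correction factors),
#' percent volume (per-scat mean), and frequency of occurrence, at item
#' level and rolled up to the CF table's category labels. Scats left without
#' items after trace exclusion drop out entirely.
#'
#' @param scats long-format scat data frame with a `date` column.
#' @param cf named numeric vector or data frame (taxon, cf, category).
#' @param seasons a [season_definition()].
#' @param trace_threshold passed to [exclude_trace()] (default 2; 0 disables).
#' @return data frame (season, level, taxon, category, biomass_percent,
#'   volume_percent, occurrence_percent, n_scats).
#' @export
composition_table <- function(scats, cf, seasons = season_definition(),
                              trace_threshold = 2) {
  if (is.null(scats$date)) stop("scats need a date column", call. = FALSE)
  tab <- .cf_table(cf)
  scats <- exclude_trace(scats, trace_threshold)
  if (nrow(scats) == 0) stop("no scats left after trace exclusion", call. = FALSE)
  .check_scats(scats)
  cat_map <- stats::setNames(tab$category, tab$taxon)
  season <- .season_of(scats$date, seasons)
  one <- function(sub, label) {
    n_scats <- length(unique(sub$scat_id))
    bio <- biomass_consumed(sub, tab)
    vol <- percent_volume(sub)
    occ <- frequency_occurrence(sub, categories = cat_map)
    items <- merge(bio[, c("taxon", "biomass_percent")], vol, by = "taxon")
    items <- merge(items, occ[occ$level == "item", c("taxon", "occurrence_percent")],
                   by = "taxon")
    items$level <- "item"
    items$category <- unname(cat_map[items$taxon])
    roll <- stats::aggregate(items[, c("biomass_percent", "volume_percent")],
                             by = list(taxon = items$category), FUN = sum)
    occ_cat <- occ[occ$level == "category", c("taxon", "occurrence_percent")]
    roll <- merge(roll, occ_cat, by = "taxon")
    roll$level <- "category"
    roll$category <- roll$taxon
    out <- rbind(items[, c("level", "taxon", "category", "biomass_percent",
                           "volume_percent", "occurrence_percent")],
                 roll[, c("level", "taxon", "category", "biomass_percent",
                          "volume_percent", "occurrence_percent")])
    out$season <- label
    out$n_scats <- n_scats
    out
  }
  res <- list()
  for (s in sort(unique(season))) {
    res[[s]] <- one(scats[season == s, , drop = FALSE], s)
  }
  res$total <- one(scats, "total")
  out <- do.call(rbind, res)
  row.names(out) <- NULL
  out[, c("season", "level", "taxon", "category", "biomass_percent",
          "volume_percent", "occurrence_percent", "n_scats")]
}

#' Seasonal diet contingency chi-square
#'
#' Pearson chi-square on a seasons x categories table of occurrence counts.
#'
#' @param counts matrix of nonnegative counts (>= 2 columns), rows = seasons.
#' @return list (statistic, df, p_value).
#' @export
seasonal_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2 || nrow(counts) < 2) {
    stop("need at least a 2 x 2 table", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) {
    stop("zero expected cell count; drop empty rows/columns first", call. = FALSE)
  }
  if (any(expected < 5)) {
    warning("expected cell count below 5; chi-square approximation may be poor",
            call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Read a correction-factor table from CSV
#' @param path CSV with columns taxon, cf and optional category.
#' @return data frame (taxon, cf, category).
#' @export
read_cf_csv <- function(path) {
  .cf_table(utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE))
}
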