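# Used-available resource selection function: design construction,
# covariate preprocessing, weighted logistic fitting (mixed or fixed
# effects), prediction, and individual-blocked k-fold cross-validation.
#
# Covariates are distances to features, so a negative coefficient means
# selection for the feature and a positive one avoidance.

#' Sample available points uniformly within a polygon
#'
#' @param polygon a `canid_mcp` (typically the animal's 100% MCP) or an
#'   open-ring coordinate matrix.
#' @param n_presence number of presence points for this animal.
#' @param ratio available : presence ratio (default 10).
#' @param seed integer seed.
#' @return data frame (x, y) with `ratio * n_presence` rows inside the
#'   polygon.
#' @export
sample_available <- function(polygon, n_presence, ratio = 10, seed = 1L) {
  poly <- .polygon_matrix(polygon)
  if (nrow(poly) < 3 || shoelace_area(poly) == 0) {
    stop("degenerate availability polygon", call. = FALSE)
  }
  if (ratio < 1) stop("ratio must be >= 1", call. = FALSE)
  n <- as.integer(round(ratio * n_presence))
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  with_seed(seed, {
    kept <- matrix(numeric(0), 0, 2)
    while (nrow(kept) < n) {
      m <- max(1000L, 2L * (n - nrow(kept)))
      cand <- cbind(stats::runif(m, xr[1], xr[2]), stats::runif(m, yr[1], yr[2]))
      kept <- rbind(kept, cand[points_in_polygon(cand, poly), , drop = FALSE])
    }
    data.frame(x = kept[seq_len(n), 1], y = kept[seq_len(n), 2])
  })
}

#' Raw distance covariates for points
#'
#' Euclidean distance in meters from each point to the nearest feature of
#' each requested type (0 inside polygon features).
#'
#' @param points data frame or matrix of x/y coordinates.
#' @param landscape a `canid_landscape`.
#' @param types feature types (default all present).
#' @return data frame of `dist_<type>` columns.
#' @export
distance_covariates <- function(points, landscape,
                                types = feature_types(landscape)) {
  missing <- setdiff(types, feature_types(landscape))
  if (length(missing) > 0) {
    stop("missing landscape layer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  as.data.frame(landscape_distances(.points_matrix(points), landscape, types))
}

#' Build a used-available design
#'
#' One presence row (case = 1, weight 1) per relocation and `ratio`
#' available rows (case = 0, weight `weight_available`) per presence, per
#' animal. Available points are sampled uniformly within the animal's 100%
#' MCP unless supplied explicitly.
#'
#' @param relocations data frame (animal_id, timestamp, x, y).
#' @param landscape a `canid_landscape`.
#' @param types covariate feature types.
#' @param ratio available : presence ratio (default 10).
#' @param weight_available likelihood weight on available rows (default
#'   1000).
#' @param available optional named list of data frames (x, y) of available
#'   points per animal, overriding MCP sampling.
#' @param seed integer seed for availability sampling.
#' @return a `rsf_design` data frame (animal_id, case, weight, x, y,
#'   dist_* columns) with attribute `covariates`.
#' @export
rsf_design <- function(relocations, landscape, types = feature_types(landscape),
                       ratio = 10, weight_available = 1000,
                       available = NULL, seed = 1L) {
  stopifnot(all(c("animal_id", "x", "y") %in% names(relocations)))
  ids <- unique(relocations$animal_id)
  parts <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    used <- relocations[relocations$animal_id == id, c("x", "y")]
    if (is.null(available)) {
      hr <- mcp(used, percent = 1.0)
      avail <- sample_available(hr, nrow(used), ratio = ratio,
                                seed = seed + i)
    } else {
      avail <- available[[id]]
      if (is.null(avail)) stop("no available points for animal ", id, call. = FALSE)
    }
    pts <- rbind(as.data.frame(used), avail[, c("x", "y")])
    d <- distance_covariates(pts, landscape, types)
    parts[[i]] <- cbind(
      data.frame(animal_id = id,
                 case = rep(c(1L, 0L), c(nrow(used), nrow(avail))),
                 weight = rep(c(1, weight_available), c(nrow(used), nrow(avail)))),
      pts, d)
  }
  out <- do.call(rbind, parts)
  row.names(out) <- NULL
  structure(out, covariates = paste0("dist_", types), class = c("rsf_design", "data.frame"))
}

#' Transform design covariates: log, center, scale, collinearity screen
#'
#' Each raw distance d becomes log(d + 1), then is centered and scaled to
#' mean 0, SD 1 using the pooled (presence + available) sample. Covariate
#' pairs with |Pearson r| at or above the threshold are reported and the
#' lower-priority member dropped.
#'
#' @param design a [rsf_design()].
#' @param collin_threshold |r| threshold for dropping (default 0.7).
#' @param drop_priority character vector of covariate columns to drop first
#'   when correlated (default: the later column of the pair).
#' @return the design with transformed covariate columns and attributes
#'   `covariates`, `scaler` (center/scale), `dropped`, `correlations`.
#' @export
preprocess <- function(design, collin_threshold = 0.7, drop_priority = NULL) {
  covs <- attr(design, "covariates")
  if (is.null(covs)) covs <- grep("^dist_", names(design), value = TRUE)
  v <- log(as.matrix(design[, covs, drop = FALSE]) + 1)
  ctr <- colMeans(v)
  scl <- apply(v, 2, stats::sd)
  if (any(scl == 0)) {
    stop("zero-variance covariate: ", paste(covs[scl == 0], collapse = ", "),
         call. = FALSE)
  }
  v <- sweep(sweep(v, 2, ctr, "-"), 2, scl, "/")
  cm <- stats::cor(v)
  dropped <- character(0)
  if (length(covs) > 1) {
    pairs <- which(abs(cm) >= collin_threshold & upper.tri(cm), arr.ind = TRUE)
    for (k in seq_len(nrow(pairs))) {
      a <- covs[pairs[k, 1]]; b <- covs[pairs[k, 2]]
      if (a %in% dropped || b %in% dropped) next
      pick <- if (!is.null(drop_priority) && a %in% drop_priority) a
      else if (!is.null(drop_priority) && b %in% drop_priority) b
      else b
      dropped <- c(dropped, pick)
      message("dropping '", pick, "' (|r| = ", round(abs(cm[a, b]), 3),
              " with '", if (pick == a) b else a, "')")
    }
  }
  keep <- setdiff(covs, dropped)
  design[covs] <- as.data.frame(v)
  design <- design[, setdiff(names(design), dropped), drop = FALSE]
  structure(design, covariates = keep,
            scaler = list(center = ctr[keep], scale = scl[keep]),
            dropped = dropped, correlations = cm,
            preprocessed = TRUE, class = c("rsf_design", "data.frame"))
}

#' Fit the weighted logistic resource selection function
#'
#' Maximizes the weighted Bernoulli log-likelihood sum(w_i * (y_i log pi_i +
#' (1 - y_i) log(1 - pi_i))) with pi = logistic(b0 + a_id + x (beta + b_id)).
#' In mixed mode the per-animal random intercept has its variance fixed at
#' `intercept_variance` (not estimated) and random slopes have estimated
#' variances, via a Laplace-approximated marginal likelihood. Fixed mode is
#' plain weighted iteratively reweighted least squares with no random terms,
#' appropriate when variance components are near zero.
#'
#' @param design a preprocessed [rsf_design()].
#' @param method "mixed" (random intercept + slopes) or "fixed".
#' @param intercept_variance fixed random-intercept variance (default 1e6).
#' @return an `rsf_model`: list with `coefficients` (variable, beta, se,
#'   lcl, ucl, z, p; Wald 95% CI), `ranef_variance`, `method`, `scaler`,
#'   `covariates`, `fit`.
#' @export
fit_rsf <- function(design, method = c("mixed", "fixed"),
                    intercept_variance = 1e6) {
  method <- match.arg(method)
  if (!isTRUE(attr(design, "preprocessed"))) {
    stop("design must be preprocessed first (see preprocess())", call. = FALSE)
  }
  covs <- attr(design, "covariates")
  dat <- as.data.frame(design)
  dat$animal_id <- factor(dat$animal_id)
  if (method == "mixed" && nlevels(dat$animal_id) < 2) {
    stop("random effects need at least 2 animals", call. = FALSE)
  }
  if (method == "mixed") {
    re_terms <- paste(c("(1 | animal_id)",
                        paste0("(0 + ", covs, " | animal_id)")), collapse = " + ")
    form <- stats::as.formula(paste("case ~", paste(covs, collapse = " + "),
                                    "+", re_terms))
    n_theta <- 1L + length(covs)
    fit <- glmmTMB::glmmTMB(
      form, data = dat, family = stats::binomial(), weights = weight,
      start = list(theta = c(log(sqrt(intercept_variance)),
                             rep(log(0.1), length(covs)))),
      map = list(theta = factor(c(NA, seq_along(covs)))))
    if (!isTRUE(fit$sdr$pdHess)) {
      stop("mixed RSF did not converge to a positive-definite Hessian",
           call. = FALSE)
    }
    est <- glmmTMB::fixef(fit)$cond
    se <- summary(fit)$coefficients$cond[, "Std. Error"]
    theta <- glmmTMB::getME(fit, "theta")
    ranef_var <- stats::setNames(exp(2 * theta[-1]), covs)
  } else {
    form <- stats::as.formula(paste("case ~", paste(covs, collapse = " + ")))
    fit <- stats::glm(form, data = dat, family = stats::binomial(),
                      weights = weight)
    if (!fit$converged) stop("fixed-effects RSF did not converge", call. = FALSE)
    est <- stats::coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
    ranef_var <- NULL
  }
  if (any(abs(est[-1]) > 25)) {
    stop("separation suspected: |beta| > 25 on a standardized covariate",
         call. = FALSE)
  }
  z <- est / se
  coefs <- data.frame(variable = names(est), beta = as.numeric(est),
                      se = as.numeric(se),
                      lcl = as.numeric(est - 1.96 * se),
                      ucl = as.numeric(est + 1.96 * se),
                      z = as.numeric(z),
                      p = as.numeric(2 * stats::pnorm(-abs(z))),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(coefficients = coefs, ranef_variance = ranef_var,
                 method = method, intercept_variance = intercept_variance,
                 scaler = attr(design, "scaler"), covariates = covs,
                 fit = fit),
            class = "rsf_model")
}

#' Relative selection score
#'
#' score = exp(x beta_hat) using fixed-effect slopes only (no intercept):
#' a relative, unitless probability of use.
#'
#' @param model an `rsf_model`.
#' @param newdata data frame with either the model's transformed covariate
#'   columns or raw `dist_*` distances (transformed with the training
#'   scaler when `raw = TRUE`).
#' @param raw whether `newdata` holds raw distances (default TRUE).
#' @return numeric score vector.
#' @export
predict_rsf <- function(model, newdata, raw = TRUE) {
  covs <- model$covariates
  miss <- setdiff(covs, names(newdata))
  if (length(miss) > 0) {
    stop("newdata missing covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(newdata[, covs, drop = FALSE])
  if (raw) {
    x <- sweep(sweep(log(x + 1), 2, model$scaler$center, "-"),
               2, model$scaler$scale, "/")
  }
  beta <- model$coefficients$beta[match(covs, model$coefficients$variable)]
  as.numeric(exp(x %*% beta))
}

#' Individual-blocked k-fold cross-validation
#'
#' Each fold withholds one animal, trains on the rest, scores the withheld
#' animal's available points, forms 10 equal-available-area bins (score
#' deciles of the withheld available points), computes the area-adjusted
#' frequency per bin = (withheld presence share in bin) / 0.1, and
#' Spearman-correlates the frequencies against bin rank. Folds whose
#' withheld animal has fewer than 10 presence points are skipped with a
#' warning.
#'
#' @param design a preprocessed [rsf_design()].
#' @param method model for the training folds ("fixed" is the default: with
#'   a single shared selection surface the variance components are near 0).
#' @param n_bins number of equal-area bins (default 10).
#' @return a `rsf_cv`: list with `folds` (animal_id, rho, p), `mean_rho`,
#'   `pooled_rho`, `pooled_p`, and the pooled `bin_table`.
#' @export
blocked_kfold_cv <- function(design, method = c("fixed", "mixed"),
                             n_bins = 10L) {
  method <- match.arg(method)
  covs <- attr(design, "covariates")
  ids <- unique(design$animal_id)
  if (length(ids) < 2) stop("need at least 2 animals", call. = FALSE)
  fold_rows <- list()
  freq_mat <- NULL
  for (id in ids) {
    test <- design[design$animal_id == id, , drop = FALSE]
    if (sum(test$case == 1) < 10) {
      warning("skipping fold for animal ", id, ": fewer than 10 presence points",
              call. = FALSE)
      next
    }
    train <- design[design$animal_id != id, , drop = FALSE]
    for (a in c("covariates", "scaler", "preprocessed")) {
      attr(train, a) <- attr(design, a)
    }
    model <- fit_rsf(train, method = method)
    avail <- test[test$case == 0, , drop = FALSE]
    pres <- test[test$case == 1, , drop = FALSE]
    s_avail <- predict_rsf(model, avail, raw = FALSE)
    s_pres <- predict_rsf(model, pres, raw = FALSE)
    breaks <- stats::quantile(s_avail, probs = seq(0, 1, length.out = n_bins + 1))
    breaks[1] <- -Inf; breaks[n_bins + 1] <- Inf
    bin_pres <- cut(s_pres, breaks = unique(breaks), labels = FALSE)
    counts <- tabulate(bin_pres, nbins = n_bins)
    freq <- (counts / sum(counts)) / (1 / n_bins)
    ct <- suppressWarnings(
      stats::cor.test(freq, seq_len(n_bins), method = "spearman", exact = FALSE))
    fold_rows[[id]] <- data.frame(animal_id = id,
                                  rho = unname(ct$estimate),
                                  p = ct$p.value, stringsAsFactors = FALSE)
    freq_mat <- rbind(freq_mat, freq)
  }
  if (length(fold_rows) == 0) stop("no usable folds", call. = FALSE)
  folds <- do.call(rbind, fold_rows)
  row.names(folds) <- NULL
  pooled <- colMeans(freq_mat)
  pt <- suppressWarnings(
    stats::cor.test(pooled, seq_len(n_bins), method = "spearman", exact = FALSE))
  structure(list(folds = folds, mean_rho = mean(folds$rho),
                 pooled_rho = unname(pt$estimate), pooled_p = pt$p.value,
                 bin_table = data.frame(bin = seq_len(n_bins),
                                        available_share = 1 / n_bins,
                                        area_adjusted_frequency = pooled)),
            class = "rsf_cv")
}
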