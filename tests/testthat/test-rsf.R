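# Used-available design, preprocessing, weighted logistic fits, CV.

square_poly <- function(side = 1000) {
  rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
}

# Small shared simulation for fitting tests: 3 animals, common true betas.
sim_design <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ls1 <- toy_landscape()
    beta_true <- c(dense_forest = 0.5, road = -0.4, stream = 0.15)
    relocs <- list(); avail <- list()
    for (i in 1:3) {
      cfg <- movement_config(center = c(7000 + 1500 * i, 8000 + 1000 * i),
                             sigma = 2500, beta = beta_true, n_fixes = 300,
                             seed = 40L + i)
      id <- paste0("A", i)
      relocs[[i]] <- gen_movement(ls1, cfg, animal_id = id)
      avail[[id]] <- gen_availability(cfg, 3000)
    }
    design <- rsf_design(do.call(rbind, relocs), ls1,
                         types = names(beta_true), available = avail)
    cache <<- preprocess(design)
    cache
  }
})

test_that("available points are uniform in the polygon and seed-stable", {
  poly <- square_poly()
  pts <- sample_available(poly, n_presence = 100, ratio = 10, seed = 3L)
  expect_equal(nrow(pts), 1000L)
  expect_true(all(pts$x >= 0 & pts$x <= 1000 & pts$y >= 0 & pts$y <= 1000))
  expect_identical(pts, sample_available(poly, 100, 10, seed = 3L))
  # uniformity: chi-square over a 4 x 4 partition, alpha = 0.01
  big <- sample_available(poly, 1000, 10, seed = 4L)
  bx <- cut(big$x, seq(0, 1000, length.out = 5), labels = FALSE)
  by <- cut(big$y, seq(0, 1000, length.out = 5), labels = FALSE)
  ct <- stats::chisq.test(table(bx, by))
  expect_gt(ct$p.value, 0.01)
  expect_error(sample_available(rbind(c(0, 0), c(1, 1), c(2, 2)), 10),
               "degenerate")
})

test_that("distance covariates use exact point-segment geometry", {
  ls1 <- unit_landscape()
  d <- distance_covariates(rbind(c(0, 0)), ls1)
  expect_equal(d$dist_road, 5)          # (0,0) to segment (3,4)-(3,100)
  expect_equal(d$dist_stream, 500)
  on_road <- distance_covariates(rbind(c(3, 50)), ls1)
  expect_equal(on_road$dist_road, 0)
  inside <- distance_covariates(rbind(c(300, 300)), ls1)
  expect_equal(inside$dist_dense_forest, 0)
  # rigid translation of points and layers together leaves distances unchanged
  ls2 <- ls1
  ls2$features <- lapply(ls1$features, function(f) {
    f$coords <- sweep(f$coords, 2, c(111, -222), "+"); f
  })
  d2 <- distance_covariates(rbind(c(111, -222)), ls2)
  expect_equal(as.numeric(d2), as.numeric(d), tolerance = 1e-9)
  expect_error(distance_covariates(rbind(c(0, 0)), ls1, types = "ddf"), "ddf")
})

test_that("preprocessing standardizes, screens collinearity, and keeps a scaler", {
  design <- sim_design()
  covs <- attr(design, "covariates")
  for (v in covs) {
    expect_lt(abs(mean(design[[v]])), 1e-9)
    expect_equal(stats::sd(design[[v]]), 1, tolerance = 1e-9)
  }
  expect_named(attr(design, "scaler"), c("center", "scale"))

  # constructed near-duplicate covariate is flagged and dropped
  raw <- data.frame(animal_id = rep(c("a", "b"), each = 200),
                    case = rep(c(1L, 0L), 200),
                    weight = rep(c(1, 1000), 200))
  set.seed(30)
  raw$dist_road <- stats::rlnorm(400, 5, 1)
  raw$dist_copy <- exp(0.9 * log(raw$dist_road + 1) + stats::rnorm(400, 0, 0.1)) - 1
  raw$dist_other <- stats::rlnorm(400, 5, 1)
  d <- structure(raw, covariates = c("dist_road", "dist_copy", "dist_other"),
                 class = c("rsf_design", "data.frame"))
  expect_message(p <- preprocess(d), "dropping")
  expect_equal(attr(p, "dropped"), "dist_copy")
  expect_false("dist_copy" %in% names(p))
  # priority list can protect a covariate by sacrificing the other
  expect_message(p2 <- preprocess(d, drop_priority = "dist_road"), "dist_road")
  expect_equal(attr(p2, "dropped"), "dist_road")
})

test_that("weighted logistic fits are invariant to weight rescaling and stable in W", {
  design <- sim_design()
  m1 <- fit_rsf(design, method = "fixed")
  d5 <- design
  d5$weight <- d5$weight * 5
  for (a in c("covariates", "scaler", "preprocessed")) attr(d5, a) <- attr(design, a)
  m5 <- fit_rsf(d5, method = "fixed")
  expect_equal(m5$coefficients$beta, m1$coefficients$beta, tolerance = 1e-6)

  ls1 <- toy_landscape()
  betas <- sapply(c(100, 1000, 10000), function(W) {
    dW <- design
    dW$weight[dW$case == 0] <- W
    for (a in c("covariates", "scaler", "preprocessed")) attr(dW, a) <- attr(design, a)
    fit_rsf(dW, method = "fixed")$coefficients$beta[-1]
  })
  expect_lt(max(abs(betas[, 3] - betas[, 2]) / abs(betas[, 2])), 0.01)
})

test_that("mixed and fixed fits agree when between-animal variance is zero", {
  design <- sim_design()
  mf <- fit_rsf(design, method = "fixed")
  mm <- fit_rsf(design, method = "mixed")
  # animals share one true beta, so slope variances collapse and estimates agree
  expect_lt(max(mm$ranef_variance), 0.05)
  for (v in attr(design, "covariates")) {
    bf <- mf$coefficients[mf$coefficients$variable == v, ]
    bm <- mm$coefficients[mm$coefficients$variable == v, ]
    expect_lt(abs(bf$beta - bm$beta), bf$se + bm$se)
  }
  # recovered signs match the simulated selection pattern:
  # avoid forest and streams (positive on distance), select roads (negative)
  b <- stats::setNames(mf$coefficients$beta, mf$coefficients$variable)
  expect_gt(b[["dist_dense_forest"]], 0)
  expect_lt(b[["dist_road"]], 0)
  expect_gt(b[["dist_stream"]], 0)
  # Wald interval construction
  expect_equal(mf$coefficients$ucl, mf$coefficients$beta + 1.96 * mf$coefficients$se)
  d0 <- design
  attr(d0, "preprocessed") <- NULL
  expect_error(fit_rsf(d0), "preprocess")
})

test_that("prediction is exp(x beta) with training-scaler transforms", {
  design <- sim_design()
  m <- fit_rsf(design, method = "fixed")
  covs <- m$covariates
  zero <- as.data.frame(stats::setNames(as.list(rep(0, length(covs))), covs))
  expect_equal(predict_rsf(m, zero, raw = FALSE), 1)
  x3 <- as.data.frame(matrix(stats::rnorm(9), 3, 3,
                             dimnames = list(NULL, covs)))
  beta <- m$coefficients$beta[match(covs, m$coefficients$variable)]
  eta <- as.matrix(x3) %*% beta
  expect_equal(order(predict_rsf(m, x3, raw = FALSE)), order(eta))
  expect_equal(predict_rsf(m, x3, raw = FALSE), as.numeric(exp(eta)))
  expect_error(predict_rsf(m, x3[, 1:2]), "missing covariate")
})

test_that("blocked cross-validation scores folds and skips tiny animals", {
  design <- sim_design()
  cv <- blocked_kfold_cv(design)
  expect_equal(nrow(cv$folds), 3)
  expect_true(all(abs(cv$folds$rho) <= 1))
  expect_gt(cv$mean_rho, 0.5)  # simulated selection is strong
  expect_equal(sum(cv$bin_table$available_share), 1)

  # an animal with < 10 presence points is skipped with a warning
  small <- design[design$case == 0 | design$animal_id != "A1", ]
  extra <- design[design$animal_id == "A1" & design$case == 1, ][1:5, ]
  dd <- rbind(small[small$animal_id != "A1", ],
              rbind(extra, small[small$animal_id == "A1", ]))
  for (a in c("covariates", "scaler", "preprocessed")) attr(dd, a) <- attr(design, a)
  expect_warning(cv2 <- blocked_kfold_cv(dd), "fewer than 10")
  expect_equal(nrow(cv2$folds), 2)
})
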