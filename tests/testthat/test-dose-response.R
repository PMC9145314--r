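# Nested exponential/Hill dose-response modelling: evaluation, ML fitting,
# LRT selection, goodness of fit, BMD and profile-likelihood intervals.

test_that("model evaluation matches hand-derived values and returns a at dose 0", {
  expect_equal(eval_model(dr_model("exponential", 2, a = 100, b = 0), 10), 100)
  expect_equal(eval_model(dr_model("hill", 2, a = 100, b = 5), 5), 50)
  expect_equal(eval_model(dr_model("exponential", 3, a = 2, b = log(2), d = 1), 1), 4)
  # asymptote of the canonical four-parameter exponential is a * c
  e4 <- dr_model("exponential", 4, a = 100, b = 0.1, c = 0.2)
  expect_equal(eval_model(e4, 1e6), 20, tolerance = 1e-10)
  # every family member returns the background at dose zero
  for (fam in c("exponential", "hill")) {
    for (lv in 1:5) {
      spec <- dr_model(fam, lv, a = 42, b = if (fam == "hill") 7 else 0.3,
                       c = 0.5, d = 2)
      expect_equal(eval_model(spec, 0), 42, info = paste(fam, lv))
    }
  }
  expect_error(dr_model("exponential", 3, a = 1, b = 1), "requires parameter 'd'")
  expect_error(eval_model(dr_model("hill", 2, a = 1, b = 1), -1), ">= 0")
})

test_that("closed-form BMDs match the analytic expressions", {
  e2 <- dr_model("exponential", 2, a = 100, b = -0.05)
  expect_equal(compute_bmd(e2, 0.10, direction = "decreasing"),
               log(0.9) / -0.05, tolerance = 1e-10)
  h2 <- dr_model("hill", 2, a = 100, b = 27)
  expect_equal(compute_bmd(h2, 0.10, direction = "decreasing"), 27 / 9,
               tolerance = 1e-10)
  # relative error of the closed forms is tiny: invert by evaluating back
  for (spec in list(dr_model("exponential", 3, a = 50, b = -0.01, d = 2),
                    dr_model("exponential", 4, a = 50, b = 0.05, c = 0.3),
                    dr_model("hill", 3, a = 50, b = 30, d = 1.7),
                    dr_model("hill", 4, a = 50, b = 30, c = 2.5))) {
    dir <- if (!is.null(spec$c) && spec$c > 1) "increasing" else "decreasing"
    bmd <- compute_bmd(spec, 0.25, direction = dir)
    target <- spec$a * (if (dir == "increasing") 1.25 else 0.75)
    expect_equal(eval_model(spec, bmd), target, tolerance = 1e-8)
  }
  # continuity at the background: bmr -> 0 gives BMD -> 0
  bmds <- vapply(c(0.1, 0.01, 0.001, 1e-5), function(bmr) {
    compute_bmd(e2, bmr, direction = "decreasing")
  }, 0)
  expect_true(all(diff(bmds) < 0) && bmds[4] < 1e-3)
  # a curve that never reaches the benchmark response errors
  shallow <- dr_model("exponential", 4, a = 100, b = 1, c = 0.95)
  expect_error(compute_bmd(shallow, 0.10, direction = "decreasing", xmax = 10),
               "beyond observed range")
})

test_that("maximum-likelihood fit recovers noiseless curves and constant data", {
  doses <- c(0, 3.125, 6.25, 12.5, 25, 50)
  x <- rep(doses, each = 3)
  y <- eval_model(dr_model("exponential", 2, a = 100, b = -0.05), x)
  fit <- fit_mle(dr_dataset(x, y), "exponential", 2)
  expect_true(fit$converged)
  expect_equal(fit$spec$a, 100, tolerance = 0.01)
  expect_equal(fit$spec$b, -0.05, tolerance = 0.01)
  # constant data: the level-1 MLE of a is the geometric mean
  set.seed(7)
  yc <- exp(rnorm(length(x), log(80), 0.3))
  fit1 <- fit_mle(dr_dataset(x, yc), "exponential", 1)
  expect_equal(fit1$spec$a, exp(mean(log(yc))), tolerance = 1e-12)
  expect_error(dr_dataset(x, y - 100), "positive")
})

test_that("log-likelihood is non-decreasing along both nesting chains", {
  doses <- c(0, 3.125, 6.25, 12.5, 25, 50, 100)
  gens <- list(dr_model("exponential", 3, a = 100, b = -0.002, d = 1.5),
               dr_model("exponential", 2, a = 60, b = 0.01),
               dr_model("hill", 4, a = 30, b = 20, c = 3))
  for (seed in 1:3) {
    gen <- gens[[seed]]
    d <- gen_dose_response(gen, doses = doses, sd = 0.08, seed = seed)
    for (fam in c("exponential", "hill")) {
      sel <- select_model(d, fam)
      ll <- vapply(attr(sel, "fits"), `[[`, 0, "log_likelihood")
      expect_true(all(diff(ll[c(1, 2, 3, 5)]) >= -1e-6),
                  info = sprintf("%s 1-2-3-5 seed %d", fam, seed))
      expect_true(all(diff(ll[c(1, 2, 4, 5)]) >= -1e-6),
                  info = sprintf("%s 1-2-4-5 seed %d", fam, seed))
    }
  }
})

test_that("LRT selection keeps the simple model on flat data and finds shape on sigmoids", {
  # zero log-likelihood gain => extension rejected (p = 1)
  doses <- c(0, 5, 10, 20, 40, 80)
  x <- rep(doses, each = 3)
  set.seed(11)
  y <- exp(rnorm(length(x), log(100), 0.05))
  sel <- select_model(dr_dataset(x, y), "exponential")
  lrt <- attr(sel, "lrt")
  expect_true(all(lrt$p >= 0.05))
  expect_lte(sel$spec$level, 2)

  # flat truth: over 200 simulations, level <= 2 selected in >= 95%
  n_sims <- 200
  flat <- dr_model("exponential", 1, a = 100)
  levels <- vapply(seq_len(n_sims), function(s) {
    d <- gen_dose_response(flat, doses = doses, sd = 0.05, seed = 1000 + s)
    select_model(d, "exponential")$spec$level
  }, 0L)
  expect_gte(mean(levels <= 2), 0.95)

  # steep sigmoid truth: the selected model carries the shape exponent d
  steep <- dr_model("exponential", 5, a = 100, b = 6.4e-5, c = 0.1, d = 3)
  d <- gen_dose_response(steep, doses = c(0, 3.125, 6.25, 12.5, 25, 50, 100),
                         sd = 0.05, seed = 99)
  sel <- select_model(d, "exponential")
  expect_true(sel$spec$level %in% c(3, 5))
})

test_that("full-model goodness of fit accepts its own curve and rejects a bump", {
  doses <- c(0, 5, 10, 20, 40, 80)
  x <- rep(doses, each = 3)
  # data exactly on the fitted curve: p = 1
  y <- eval_model(dr_model("exponential", 2, a = 100, b = -0.02), x)
  d <- dr_dataset(x, y)
  fit <- fit_mle(d, "exponential", 2)
  expect_equal(goodness_of_fit(fit, d), 1, tolerance = 1e-6)
  # one replicate per dose, saturated fit: p = 1
  xs <- c(0, 5, 10, 20)
  ys <- eval_model(dr_model("exponential", 4, a = 100, b = 0.1, c = 0.4), xs)
  ds <- dr_dataset(xs, ys)
  fs <- fit_mle(ds, "exponential", 4)
  expect_equal(goodness_of_fit(fs, ds), 1, tolerance = 1e-6)
  # a strong non-monotone bump is rejected against a monotone E2 fit
  bump_mean <- c(100, 100, 160, 160, 100, 90)
  rejected <- vapply(seq_len(200), function(s) {
    set.seed(2000 + s)
    yb <- rep(bump_mean, each = 3) * exp(rnorm(length(x), 0, 0.05))
    db <- dr_dataset(x, yb)
    goodness_of_fit(fit_mle(db, "exponential", 2), db) < 0.05
  }, NA)
  expect_gte(mean(rejected), 0.90)
})

test_that("profile interval brackets the MLE, widens with noise, matches the oracle", {
  gen <- dr_model("exponential", 3, a = 100, b = -0.002, d = 1.5)
  d1 <- gen_dose_response(gen, sd = 0.05, seed = 3)
  fit <- select_model(d1, "exponential")
  bmd <- compute_bmd(fit, 0.10)
  ci <- profile_ci(fit, d1, 0.10)
  expect_lte(ci["bmdl"], bmd)
  expect_gte(ci["bmdu"], bmd)
  # doubling the noise (same seed => same standardized residuals) widens it
  d2 <- gen_dose_response(gen, sd = 0.10, seed = 3)
  fit2 <- select_model(d2, "exponential")
  ci2 <- profile_ci(fit2, d2, 0.10)
  expect_gt(ci2["bmdu"] - ci2["bmdl"], ci["bmdu"] - ci["bmdl"])
  # brute-force grid-refit oracle agreement on one fixture (more in the
  # acceptance suite)
  oracle <- oracle_profile_bounds(d1, "exponential", fit$spec$level, 0.10,
                                  fit$direction, fit$log_likelihood, bmd)
  expect_equal(unname(ci["bmdl"]), unname(oracle["bmdl"]), tolerance = 0.02)
  expect_equal(unname(ci["bmdu"]), unname(oracle["bmdu"]), tolerance = 0.02)
})

test_that("BMD, BMDL and BMDU are equivariant under dose rescaling", {
  gen <- dr_model("exponential", 3, a = 100, b = -0.002, d = 1.5)
  d <- gen_dose_response(gen, sd = 0.05, seed = 5)
  k <- 1000
  dk <- dr_dataset(d$dose * k, d$response)
  f1 <- select_model(d, "exponential")
  f2 <- select_model(dk, "exponential")
  expect_equal(compute_bmd(f2, 0.10), k * compute_bmd(f1, 0.10),
               tolerance = 1e-3)
  c1 <- profile_ci(f1, d, 0.10)
  c2 <- profile_ci(f2, dk, 0.10)
  expect_equal(unname(c2), unname(k * c1), tolerance = 0.01)
})

test_that("model averaging follows the geometric-mean and min/max rules", {
  tab <- data.frame(model = c("E3", "H3"), bmd = c(2, 8),
                    bmdl = c(1, 2), bmdu = c(3, 5))
  avg <- model_average(tab)
  expect_equal(avg$averaged_bmd, 4)
  expect_equal(unname(avg$ci90), c(1, 5))
  one <- model_average(tab[1, ])
  expect_equal(one$averaged_bmd, 2)
  expect_equal(unname(one$ci90), c(1, 3))
  expect_error(model_average(tab[0, ]), "no accepted models")
  # averaged BMD always sits inside the pooled interval
  expect_true(avg$ci90[1] <= avg$averaged_bmd && avg$averaged_bmd <= avg$ci90[2])
})

test_that("dose-response CSV round trip preserves the dataset", {
  d <- gen_dose_response(dr_model("exponential", 2, a = 100, b = -0.02),
                         sd = 0.05, seed = 8)
  path <- tempfile(fileext = ".csv")
  write_dr_csv(d, path)
  d2 <- read_dr_csv(path)
  expect_equal(d2$dose, d$dose)
  expect_equal(d2$response, d$response, tolerance = 1e-12)
  expect_true(file.exists(sub("\\.csv$", "_truth.json", path)))
})
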