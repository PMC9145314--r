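# Maximum-likelihood fitting of the nested dose-response families ---------
#
# Likelihood: log-normal residuals with a homoscedastic log-scale standard
# deviation, i.e. log y_ij ~ N(log f(x_i), sigma^2). Maximizing this
# likelihood is nonlinear least squares on the log responses; sigma is
# profiled analytically (sigma^2 = RSS/n), giving
#   loglik = -n/2 * (log(2 pi sigma^2) + 1).
# The background parameter a enters multiplicatively, so for fixed shape
# parameters the MLE of a is exp(mean(log y - log h(x))) with f = a h(x);
# this is exploited throughout (fits and profiles optimize shape only).

#' Construct a dose-response dataset
#'
#' @param dose Numeric doses (>= 0); must contain a zero-dose control and at
#'   least three distinct doses.
#' @param response Positive continuous endpoint values, one per
#'   (dose, replicate) observation.
#' @param replicate Optional replicate index per observation.
#' @param experiment Optional experiment identifier; replicate experiments
#'   are pooled for fitting, the identifier is retained.
#' @param endpoint Endpoint label, e.g. `"viability"` or `"IL-1b"`.
#' @param unit Dose unit, e.g. `"ug/mL"` or `"nM"`.
#' @return A data frame of class `dr_dataset` with attributes `endpoint`
#'   and `unit`.
#' @export
dr_dataset <- function(dose, response, replicate = NULL, experiment = NULL,
                       endpoint = "response", unit = "ug/mL") {
  if (length(dose) != length(response)) {
    stop("dose and response must have equal length")
  }
  if (any(!is.finite(dose)) || any(dose < 0)) stop("doses must be finite and >= 0")
  if (any(!is.finite(response)) || any(response <= 0)) {
    stop("all responses must be positive (log-scale likelihood)")
  }
  if (length(unique(dose)) < 3) stop("need >= 3 distinct doses")
  if (!any(dose == 0)) stop("a zero-dose control group is required")
  d <- data.frame(
    dose = dose, response = response,
    replicate = if (is.null(replicate)) ave(dose, dose, FUN = seq_along) else replicate,
    experiment = if (is.null(experiment)) 1L else experiment
  )
  attr(d, "endpoint") <- endpoint
  attr(d, "unit") <- unit
  class(d) <- c("dr_dataset", "data.frame")
  d
}

#' Read a dose-response CSV (columns dose, response[, replicate, experiment, endpoint])
#'
#' @param path CSV path.
#' @param endpoint Optional endpoint filter when the file carries several.
#' @param unit Dose unit to record.
#' @return A [dr_dataset()].
#' @export
read_dr_csv <- function(path, endpoint = NULL, unit = "ug/mL") {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("dose", "response") %in% names(x))) {
    stop("CSV must contain columns 'dose' and 'response'")
  }
  if (!is.null(endpoint) && "endpoint" %in% names(x)) {
    x <- x[x$endpoint == endpoint, , drop = FALSE]
  }
  dr_dataset(x$dose, x$response,
             replicate = x$replicate, experiment = x$experiment,
             endpoint = if (is.null(endpoint)) "response" else endpoint,
             unit = unit)
}

# log f(x) = log a + log h(x); h depends only on shape parameters.
.dr_log_h <- function(family, level, x, b, cc, d) {
  h <- switch(paste0(substr(family, 1, 1), level),
    e1 = rep_len(1, length(x)),
    e2 = exp(b * x),
    e3 = exp(b * x^d),
    e4 = cc - (cc - 1) * exp(-b * x),
    e5 = cc - (cc - 1) * exp(-b * x^d),
    h1 = rep_len(1, length(x)),
    h2 = 1 - x / (b + x),
    h3 = 1 - x^d / (b^d + x^d),
    h4 = 1 + (cc - 1) * x / (b + x),
    h5 = 1 + (cc - 1) * x^d / (b^d + x^d)
  )
  log(pmax(h, 1e-12))
}

# Profile out a and sigma: given shape params, return the maximized
# log-likelihood, the analytic a-hat, and the RSS.
.dr_profile_a <- function(logy, logh) {
  loga <- mean(logy - logh)
  rss <- sum((logy - logh - loga)^2)
  n <- length(logy)
  s2 <- max(rss / n, 1e-12)
  list(loglik = -n / 2 * (log(2 * pi * s2) + 1), loga = loga, rss = rss)
}

# Deterministic multi-start list for a family member, derived from data
# quantiles (geometric control mean, top/control ratio, dose range).
.dr_starts <- function(data, family, level, parent = NULL) {
  x <- data$dose; logy <- log(data$response)
  y0 <- exp(mean(logy[x == 0]))
  xmax <- max(x)
  ytop <- exp(mean(logy[x == xmax]))
  ratio <- max(ytop / y0, 1e-6)
  bexp <- log(ratio) / xmax
  if (abs(bexp) < 1e-8) bexp <- 1e-3 / xmax
  starts <- list()
  add <- function(b = NULL, cc = NULL, d = NULL) {
    starts[[length(starts) + 1L]] <<- list(b = b, cc = cc, d = d)
  }
  if (family == "exponential") {
    switch(as.character(level),
      "2" = { for (k in c(0.5, 1, 2)) add(b = k * bexp) },
      "3" = { for (d0 in c(1, 2, 3.5)) add(b = log(ratio) / xmax^d0, d = d0)
              add(b = bexp, d = 1.2) },
      "4" = { add(b = -bexp, cc = 1e-4)
              add(b = 2 / xmax, cc = ratio)
              add(b = 0.5 / xmax, cc = ratio) },
      "5" = { add(b = -bexp, cc = 1e-4, d = 1)
              add(b = 2 / xmax, cc = ratio, d = 1)
              add(b = 2 / xmax^2, cc = ratio, d = 2)
              add(b = 4 / xmax^3, cc = ratio, d = 3) }
    )
  } else {
    switch(as.character(level),
      "2" = { for (k in c(0.25, 1, 4)) add(b = k * xmax) },
      "3" = { for (d0 in c(1, 2, 3.5)) add(b = xmax / 2, d = d0)
              add(b = xmax / 4, d = 1.5) },
      "4" = { add(b = xmax / 4, cc = ratio)
              add(b = xmax, cc = ratio)
              add(b = xmax / 4, cc = 1e-4) },
      "5" = { add(b = xmax / 4, cc = ratio, d = 1)
              add(b = xmax / 2, cc = ratio, d = 2)
              add(b = xmax / 4, cc = 1e-4, d = 1)
              add(b = xmax / 2, cc = ratio, d = 3.5) }
    )
  }
  # warm start from the parent (nested) fit: reproduces its curve exactly
  if (!is.null(parent)) {
    ps <- parent$spec
    if (family == "exponential") {
      if (level == 3 && ps$level == 2) add(b = ps$b, d = 1)
      if (level == 4 && ps$level == 2) add(b = -ps$b, cc = 1e-8)
      if (level == 5 && ps$level == 3) add(b = -ps$b, cc = 1e-8, d = ps$d)
      if (level == 5 && ps$level == 4) add(b = ps$b, cc = ps$c, d = 1)
    } else {
      if (level == 3 && ps$level == 2) add(b = ps$b, d = 1)
      if (level == 4 && ps$level == 2) add(b = ps$b, cc = 1e-8)
      if (level == 5 && ps$level == 3) add(b = ps$b, cc = 1e-8, d = ps$d)
      if (level == 5 && ps$level == 4) add(b = ps$b, cc = ps$c, d = 1)
    }
  }
  starts
}

# Level-2 members have one shape parameter. The objective is multiscale in b
# (its natural scale depends on the dose range), so minimize over a signed
# log-spaced grid first, then refine between the best point's neighbours.
.dr_fit_1d <- function(data, family, obj) {
  xpos <- data$dose[data$dose > 0]
  if (family == "exponential") {
    mags <- 10^seq(log10(1e-4 / max(xpos)), log10(30 / min(xpos)), length.out = 19)
    grid <- sort(c(-mags, 0, mags))
  } else {
    # upper end reaches the near-flat limit so H1 stays nested in H2
    grid <- seq(log(min(xpos) / 100), log(max(xpos) * 1e8), length.out = 49)
  }
  vals <- vapply(grid, obj$fn, 0)
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  o <- stats::optimize(obj$fn, lower = lo, upper = hi, tol = 1e-10)
  if (o$objective <= vals[i]) list(par = o$minimum, value = o$objective)
  else list(par = grid[i], value = vals[i])
}

# Pack/unpack shape parameters for the optimizer. Exponential-family b is
# raw (sign-free); hill b on log scale (> 0); c raw clamped at >= 0;
# d raw clamped to [1, 4].
.dr_shape_obj <- function(data, family, level) {
  x <- data$dose; logy <- log(data$response)
  has_b <- level >= 2
  has_c <- level >= 4
  has_d <- level %in% c(3, 5)
  unpack <- function(par) {
    i <- 0L
    b <- cc <- d <- NULL
    if (has_b) { i <- i + 1L; b <- if (family == "hill") exp(par[i]) else par[i] }
    if (has_c) { i <- i + 1L; cc <- max(par[i], 0) }
    if (has_d) { i <- i + 1L; d <- min(max(par[i], 1), 4) }
    list(b = b, cc = cc, d = d)
  }
  pack <- function(s) {
    c(if (has_b) { if (family == "hill") log(s$b) else s$b },
      if (has_c) s$cc,
      if (has_d) s$d)
  }
  fn <- function(par) {
    s <- unpack(par)
    lh <- .dr_log_h(family, level, x, s$b, s$cc, s$d)
    if (any(!is.finite(lh))) return(1e10)
    pr <- .dr_profile_a(logy, lh)
    pr$rss
  }
  list(fn = fn, pack = pack, unpack = unpack,
       has_b = has_b, has_c = has_c, has_d = has_d)
}

#' Fit one family member by maximum likelihood
#'
#' Multi-start local optimization of the log-normal likelihood (deterministic
#' starts derived from data quantiles, plus an optional warm start from a
#' nested parent fit), with a Nelder-Mead polish of the best start.
#'
#' @param data A [dr_dataset()].
#' @param family `"exponential"` or `"hill"`.
#' @param level Integer 1-5.
#' @param parent Optional `dr_fit` of a nested submodel used as a warm start.
#' @return A list of class `dr_fit`: `spec` ([dr_model()] with estimates and
#'   `sigma`), `log_likelihood`, `converged`, `n_parameters` (free mean
#'   parameters + 1 for sigma), `direction`, `xmax`, `n`.
#' @export
fit_mle <- function(data, family, level, parent = NULL) {
  stopifnot(inherits(data, "dr_dataset"))
  family <- match.arg(family, DR_FAMILIES)
  level <- as.integer(level)
  x <- data$dose; logy <- log(data$response)
  n <- length(logy)
  if (level == 1) {
    pr <- .dr_profile_a(logy, rep(0, n))
    spec <- dr_model(family, 1, a = exp(pr$loga), sigma = sqrt(pr$rss / n))
    return(.dr_fit_obj(spec, pr$loglik, TRUE, data))
  }
  obj <- .dr_shape_obj(data, family, level)
  if (level == 2L) {
    best <- .dr_fit_1d(data, family, obj)
    converged <- TRUE
  } else {
    best <- NULL
    for (s in .dr_starts(data, family, level, parent)) {
      p0 <- obj$pack(s)
      res <- tryCatch(
        stats::optim(p0, obj$fn, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-10)),
        error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
    }
    if (is.null(best)) stop(sprintf("all starts failed for %s level %d", family, level))
    # polish: re-run from the best point; convergence requires no further gain
    pol <- stats::optim(best$par, obj$fn, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-12))
    converged <- pol$value >= best$value - 1e-6 || pol$convergence == 0
    if (pol$value < best$value) best <- pol
  }
  s <- obj$unpack(best$par)
  lh <- .dr_log_h(family, level, x, s$b, s$cc, s$d)
  pr <- .dr_profile_a(logy, lh)
  spec <- dr_model(family, level, a = exp(pr$loga), b = s$b, c = s$cc, d = s$d,
                   sigma = sqrt(max(pr$rss, 1e-12 * n) / n))
  .dr_fit_obj(spec, pr$loglik, converged, data)
}

.dr_fit_obj <- function(spec, loglik, converged, data) {
  xmax <- max(data$dose)
  f_top <- eval_model(spec, xmax)
  rel <- f_top / spec$a - 1
  direction <- if (abs(rel) < 1e-8) "constant" else
    if (rel > 0) "increasing" else "decreasing"
  structure(
    list(spec = spec, log_likelihood = loglik, converged = converged,
         n_parameters = length(dr_free_params(spec$family, spec$level)) + 1L,
         direction = direction, xmax = xmax, n = nrow(data)),
    class = "dr_fit"
  )
}

#' @export
print.dr_fit <- function(x, ...) {
  cat(sprintf("<dr_fit %s%d loglik=%.4f%s>\n",
              toupper(substr(x$spec$family, 1, 1)), x$spec$level,
              x$log_likelihood, if (x$converged) "" else " (NOT converged)"))
  print(x$spec)
  invisible(x)
}

#' Select a family member by likelihood-ratio testing
#'
#' Walks the nesting chain 1 -> 2 -> {3, 4} -> 5. An extension is accepted
#' only when the likelihood-ratio statistic 2*(loglik gain) exceeds the
#' chi-square critical value with degrees of freedom equal to the difference
#' in free parameter count; the returned member is the one that cannot be
#' significantly improved.
#'
#' @param data A [dr_dataset()].
#' @param family `"exponential"` or `"hill"`.
#' @param alpha LRT significance level (default 0.05).
#' @return The selected `dr_fit`, with an `lrt` attribute (data frame of the
#'   tests performed) and a `fits` attribute (all five fitted members).
#' @export
select_model <- function(data, family, alpha = 0.05) {
  family <- match.arg(family, DR_FAMILIES)
  fits <- vector("list", 5)
  fits[[1]] <- fit_mle(data, family, 1)
  fits[[2]] <- fit_mle(data, family, 2, parent = fits[[1]])
  fits[[3]] <- fit_mle(data, family, 3, parent = fits[[2]])
  fits[[4]] <- fit_mle(data, family, 4, parent = fits[[2]])
  fits[[5]] <- fit_mle(data, family, 5,
                       parent = fits[[which.max(c(NA, NA,
                         fits[[3]]$log_likelihood, fits[[4]]$log_likelihood))]])
  lrt <- function(small, big) {
    stat <- max(2 * (big$log_likelihood - small$log_likelihood), 0)
    df <- big$n_parameters - small$n_parameters
    stats::pchisq(stat, df, lower.tail = FALSE)
  }
  tests <- data.frame(comparison = character(), p = numeric())
  note <- function(lab, p) tests[nrow(tests) + 1L, ] <<- list(lab, p)

  sel <- fits[[1]]
  p12 <- lrt(fits[[1]], fits[[2]]); note("2 vs 1", p12)
  if (p12 < alpha) {
    sel <- fits[[2]]
    p23 <- lrt(fits[[2]], fits[[3]]); note("3 vs 2", p23)
    p24 <- lrt(fits[[2]], fits[[4]]); note("4 vs 2", p24)
    cand <- list()
    if (p23 < alpha) cand <- c(cand, list(fits[[3]]))
    if (p24 < alpha) cand <- c(cand, list(fits[[4]]))
    if (length(cand)) {
      ll <- vapply(cand, `[[`, 0, "log_likelihood")
      sel <- cand[[which.max(ll)]]
      p5 <- lrt(sel, fits[[5]]); note(sprintf("5 vs %d", sel$spec$level), p5)
      if (p5 < alpha) sel <- fits[[5]]
    }
  }
  attr(sel, "lrt") <- tests
  attr(sel, "fits") <- fits
  sel
}

#' Goodness of fit against the saturated ("full") model
#'
#' The full model consists of the observed per-dose-group means on the log
#' scale. The fitted model is compared to it by a likelihood-ratio test; the
#' fit is conventionally accepted when p > 0.05.
#'
#' @param fit A `dr_fit`.
#' @param data The [dr_dataset()] it was fitted to.
#' @return The LRT p-value.
#' @export
goodness_of_fit <- function(fit, data) {
  stopifnot(inherits(fit, "dr_fit"), inherits(data, "dr_dataset"))
  if (!fit$converged) stop("goodness of fit requires a converged fit")
  x <- data$dose; logy <- log(data$response)
  n <- length(logy)
  groups <- split(logy, x)
  g <- length(groups)
  n_mean_fit <- fit$n_parameters - 1L
  if (g < n_mean_fit) {
    stop("fewer dose groups than fitted parameters: full-model test undefined")
  }
  rss_full <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  ll_full <- -n / 2 * (log(2 * pi * max(rss_full / n, 1e-12)) + 1)
  stat <- max(2 * (ll_full - fit$log_likelihood), 0)
  df <- g - n_mean_fit
  if (df == 0L) return(if (stat <= 1e-6) 1 else stats::pchisq(stat, 1, lower.tail = FALSE))
  stats::pchisq(stat, df, lower.tail = FALSE)
}

#' Profile-likelihood confidence interval for the BMD
#'
#' Reparameterizes the fitted model so the BMD is explicit (the potency
#' parameter b is expressed in terms of the BMD), maximizes the remaining
#' parameters at fixed BMD, and finds where the profile log-likelihood falls
#' `qchisq(level, 1) / 2` below its maximum (1.353 for the default 90%
#' interval).
#'
#' @param fit A converged `dr_fit` of level >= 2.
#' @param data The [dr_dataset()] it was fitted to.
#' @param bmr Benchmark response fraction in (0, 1).
#' @param level Confidence level (default 0.90).
#' @return Named numeric `c(bmdl, bmdu)`; an unbounded side is reported as
#'   0 (lower) or `Inf` (upper).
#' @export
profile_ci <- function(fit, data, bmr, level = 0.90) {
  stopifnot(inherits(fit, "dr_fit"))
  if (!fit$converged) stop("profile CI requires a converged fit")
  spec <- fit$spec
  bmd_hat <- compute_bmd(fit, bmr)
  t <- if (fit$direction == "increasing") 1 + bmr else 1 - bmr
  drop <- stats::qchisq(level, 1) / 2
  target <- fit$log_likelihood - drop

  pll <- .dr_profile_fn(data, spec, t, fit)
  # lower bound
  bmdl <- .dr_profile_root(pll, target, bmd_hat, direction = -1,
                           limit = bmd_hat * 1e-6)
  if (is.na(bmdl)) bmdl <- 0
  # upper bound
  bmdu <- .dr_profile_root(pll, target, bmd_hat, direction = +1,
                           limit = max(data$dose) * 1e4)
  if (is.na(bmdu)) bmdu <- Inf
  c(bmdl = min(bmdl, bmd_hat), bmdu = max(bmdu, bmd_hat))
}

# profile log-likelihood at fixed BMD: optimize remaining shape params
# (c and/or d); a and sigma are profiled analytically, b is implied by BMD.
.dr_profile_fn <- function(data, spec, t, fit) {
  x <- data$dose; logy <- log(data$response)
  family <- spec$family; level <- spec$level
  has_c <- level >= 4
  has_d <- level %in% c(3, 5)
  ll_at <- function(bmd, cc, d) {
    b <- .dr_b_from_bmd(family, level, bmd, t, cc = cc, d = d)
    if (!is.finite(b)) return(-Inf)
    if (family == "hill" && b <= 0) return(-Inf)
    lh <- .dr_log_h(family, level, x, b, cc, d)
    if (any(!is.finite(lh))) return(-Inf)
    .dr_profile_a(logy, lh)$loglik
  }
  function(bmd) {
    if (!has_c && !has_d) return(ll_at(bmd, NULL, NULL))
    if (has_d && !has_c) {
      o <- stats::optimize(function(d) -ll_at(bmd, NULL, d),
                           lower = 1, upper = 4, tol = 1e-7)
      return(-o$objective)
    }
    if (has_c && !has_d) {
      o <- stats::optimize(function(lc) -ll_at(bmd, exp(lc), NULL),
                           lower = log(1e-8), upper = log(1e6), tol = 1e-7)
      return(-o$objective)
    }
    # level 5: optimize (log c, d) by Nelder-Mead from the MLE and one alternate
    f2 <- function(p) {
      v <- ll_at(bmd, exp(p[1]), min(max(p[2], 1), 4))
      if (!is.finite(v)) 1e10 else -v
    }
    p0s <- list(c(log(max(spec$c, 1e-8)), spec$d), c(log(0.5), 1.5))
    best <- Inf
    for (p0 in p0s) {
      r <- tryCatch(stats::optim(p0, f2, method = "Nelder-Mead",
                                 control = list(maxit = 400, reltol = 1e-10)),
                    error = function(e) NULL)
      if (!is.null(r) && r$value < best) best <- r$value
    }
    -best
  }
}

# March from the MLE BMD in one direction until the profile drops below
# `target`, then root-find the crossing. NA when the profile never drops
# before `limit` (unbounded side).
.dr_profile_root <- function(pll, target, bmd_hat, direction, limit) {
  g <- function(x) pll(x) - target
  x_prev <- bmd_hat
  g_prev <- g(bmd_hat)
  if (!is.finite(g_prev) || g_prev < -1e-6) {
    # profile at the MLE should sit at the maximum; tolerate tiny noise
    g_prev <- max(g_prev, 0)
  }
  step <- if (direction < 0) 0.5 else 2
  repeat {
    x_new <- x_prev * step
    done <- if (direction < 0) x_new < limit else x_new > limit
    if (done) return(NA_real_)
    g_new <- g(x_new)
    if (is.finite(g_new) && g_new < 0) {
      lo <- min(x_prev, x_new); hi <- max(x_prev, x_new)
      r <- stats::uniroot(g, lower = lo, upper = hi, tol = min(lo, 1) * 1e-5)
      return(r$root)
    }
    if (!is.finite(g_new)) return(x_prev)  # constrained model infeasible beyond here
    x_prev <- x_new
    g_prev <- g_new
  }
}

#' Full benchmark-dose analysis of one endpoint
#'
#' Runs model selection in the requested families, applies the full-model
#' goodness-of-fit filter, computes the BMD and its profile-likelihood
#' interval for each accepted member, and averages.
#'
#' @param data A [dr_dataset()].
#' @param bmr Benchmark response fraction (default 0.10, the "ED10" flavour).
#' @param families Families to consider.
#' @param alpha LRT significance level.
#' @param gof_alpha Full-model acceptance level (fit accepted when p > this).
#' @param ci Confidence level for the profile interval.
#' @return A list of class `bmd_analysis`: `result` ([model_average()]
#'   output or NULL when no model is accepted), `selected` (per-family fits),
#'   `gof` (per-family p-values), `bmr`, `notes` (character log).
#' @export
bmd_analysis <- function(data, bmr = 0.10,
                         families = c("exponential", "hill"),
                         alpha = 0.05, gof_alpha = 0.05, ci = 0.90) {
  selected <- list(); gof <- c(); rows <- list(); notes <- character()
  for (fam in families) {
    sel <- select_model(data, fam, alpha = alpha)
    selected[[fam]] <- sel
    if (sel$spec$level == 1 || sel$direction == "constant") {
      notes <- c(notes, sprintf(
        "%s family: no dose-response relationship (constant model selected)", fam))
      next
    }
    p_gof <- goodness_of_fit(sel, data)
    gof[fam] <- p_gof
    if (p_gof <= gof_alpha) {
      notes <- c(notes, sprintf(
        "%s family: selected model rejected by full-model GOF (p = %.3g)",
        fam, p_gof))
      next
    }
    bmd <- tryCatch(compute_bmd(sel, bmr), error = function(e) {
      notes <<- c(notes, sprintf("%s family: %s", fam, conditionMessage(e)))
      NULL
    })
    if (is.null(bmd)) next
    bounds <- profile_ci(sel, data, bmr, level = ci)
    rows[[fam]] <- data.frame(
      model = sprintf("%s%d", toupper(substr(fam, 1, 1)), sel$spec$level),
      bmd = bmd, bmdl = unname(bounds[1]), bmdu = unname(bounds[2]))
  }
  result <- if (length(rows)) model_average(do.call(rbind, rows)) else NULL
  structure(list(result = result, selected = selected, gof = gof,
                 bmr = bmr, notes = notes),
            class = "bmd_analysis")
}

#' @export
print.bmd_analysis <- function(x, ...) {
  cat(sprintf("<bmd_analysis bmr=%.2g>\n", x$bmr))
  if (is.null(x$result)) cat("  no accepted models\n") else print(x$result)
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Write a benchmark-dose report (JSON + TSV summary)
#'
#' @param analysis A [bmd_analysis()] result.
#' @param json_path,tsv_path Output paths; either may be NULL to skip.
#' @return Invisibly, the report list written to JSON.
#' @export
write_bmd_report <- function(analysis, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(analysis, "bmd_analysis"))
  rep <- list(
    bmr = analysis$bmr,
    accepted_models = if (is.null(analysis$result)) character() else
      analysis$result$accepted_models,
    averaged_bmd = if (is.null(analysis$result)) NA else
      analysis$result$averaged_bmd,
    ci90 = if (is.null(analysis$result)) c(NA, NA) else
      unname(analysis$result$ci90),
    per_model = if (is.null(analysis$result)) NULL else analysis$result$per_model,
    selected = lapply(analysis$selected, function(f) list(
      model = sprintf("%s%d", toupper(substr(f$spec$family, 1, 1)), f$spec$level),
      log_likelihood = f$log_likelihood,
      parameters = f$spec[c("a", "b", "c", "d", "sigma")],
      lrt = attr(f, "lrt"))),
    gof_p = as.list(analysis$gof),
    notes = analysis$notes)
  if (!is.null(json_path)) {
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  if (!is.null(tsv_path) && !is.null(analysis$result)) {
    tab <- analysis$result$per_model
    tab$averaged_bmd <- analysis$result$averaged_bmd
    tab$ci90_lower <- analysis$result$ci90[1]
    tab$ci90_upper <- analysis$result$ci90[2]
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(rep)
}
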