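#' @keywords internal
"_PACKAGE"

# Nested dose-response families ------------------------------------------
#
# Two families of five nested models for a continuous endpoint y at dose x,
# the standard benchmark-dose families used in regulatory toxicology
# (PROAST/EFSA style):
#
#   exponential                      hill
#   E1: y = a                        H1: y = a
#   E2: y = a exp(b x)               H2: y = a (1 - x/(b + x))
#   E3: y = a exp(b x^d)             H3: y = a (1 - x^d/(b^d + x^d))
#   E4: y = a [c - (c-1) exp(-b x)]  H4: y = a (1 + (c-1) x/(b + x))
#   E5: y = a [c - (c-1) exp(-b x^d)]H5: y = a (1 + (c-1) x^d/(b^d + x^d))
#
# a > 0 is the background response (every member returns a at x = 0),
# b the potency/sensitivity parameter (sign-free in the exponential family,
# a positive half-max-type dose in the hill family), c >= 0 the asymptote
# factor (asymptote a*c for E4/E5/H4/H5), and d in [1, 4] a shape exponent.
# Nesting: 1 -> 2 -> {3, 4} -> 5 within each family (E2 sits inside E4 at
# c = 0 with the sign of b flipped; H2 inside H4 at c = 0).

DR_FAMILIES <- c("exponential", "hill")

#' Free mean-function parameters of a family member
#'
#' @param family `"exponential"` or `"hill"`.
#' @param level Integer 1-5.
#' @return Character vector of parameter names among `a`, `b`, `c`, `d`.
#' @export
dr_free_params <- function(family, level) {
  family <- match.arg(family, DR_FAMILIES)
  if (!level %in% 1:5) stop("model level must be an integer in 1..5")
  switch(as.character(level),
    "1" = "a",
    "2" = c("a", "b"),
    "3" = c("a", "b", "d"),
    "4" = c("a", "b", "c"),
    "5" = c("a", "b", "c", "d")
  )
}

#' Construct a dose-response model specification
#'
#' @param family `"exponential"` or `"hill"`.
#' @param level Integer 1-5 selecting the nested family member.
#' @param a Background response (> 0, response units).
#' @param b Potency parameter (per dose unit; sign-free for the exponential
#'   family, strictly positive for the hill family).
#' @param c Asymptote factor (>= 0, dimensionless); levels 4-5 only.
#' @param d Shape exponent in `[1, 4]`; levels 3 and 5 only.
#' @param sigma Optional residual standard deviation on the log scale.
#' @return An object of class `dr_model`.
#' @export
dr_model <- function(family, level, a, b = NULL, c = NULL, d = NULL,
                     sigma = NULL) {
  family <- match.arg(family, DR_FAMILIES)
  level <- as.integer(level)
  need <- dr_free_params(family, level)
  pars <- list(a = a, b = b, c = c, d = d)
  for (p in need) {
    if (is.null(pars[[p]]) || !is.finite(pars[[p]])) {
      stop(sprintf("model %s%d requires parameter '%s'",
                   toupper(substr(family, 1, 1)), level, p))
    }
  }
  if (a <= 0) stop("background response 'a' must be > 0")
  if ("d" %in% need && (d < 1 || d > 4)) {
    stop("shape exponent 'd' must lie in [1, 4]")
  }
  if ("c" %in% need && c < 0) stop("asymptote factor 'c' must be >= 0")
  if (family == "hill" && "b" %in% need && b <= 0) {
    stop("hill-family 'b' must be > 0")
  }
  structure(
    list(family = family, level = level,
         a = a, b = if ("b" %in% need) b else NULL,
         c = if ("c" %in% need) c else NULL,
         d = if ("d" %in% need) d else NULL,
         sigma = sigma),
    class = "dr_model"
  )
}

#' @export
print.dr_model <- function(x, ...) {
  tag <- paste0(toupper(substr(x$family, 1, 1)), x$level)
  pars <- vapply(dr_free_params(x$family, x$level),
                 function(p) sprintf("%s=%.4g", p, x[[p]]), "")
  cat(sprintf("<dr_model %s: %s%s>\n", tag, paste(pars, collapse = ", "),
              if (!is.null(x$sigma)) sprintf(", sigma=%.4g", x$sigma) else ""))
  invisible(x)
}

#' Evaluate the mean response of a dose-response model
#'
#' @param spec A [dr_model()].
#' @param x Vector of doses (>= 0).
#' @return Mean responses at `x`; equals `a` at `x = 0` for every member.
#' @export
eval_model <- function(spec, x) {
  stopifnot(inherits(spec, "dr_model"))
  if (any(x < 0)) stop("doses must be >= 0")
  a <- spec$a; b <- spec$b; cc <- spec$c; d <- spec$d
  if (spec$family == "exponential") {
    switch(as.character(spec$level),
      "1" = rep_len(a, length(x)),
      "2" = a * exp(b * x),
      "3" = a * exp(b * x^d),
      "4" = a * (cc - (cc - 1) * exp(-b * x)),
      "5" = a * (cc - (cc - 1) * exp(-b * x^d))
    )
  } else {
    switch(as.character(spec$level),
      "1" = rep_len(a, length(x)),
      "2" = a * (1 - x / (b + x)),
      "3" = a * (1 - x^d / (b^d + x^d)),
      "4" = a * (1 + (cc - 1) * x / (b + x)),
      "5" = a * (1 + (cc - 1) * x^d / (b^d + x^d))
    )
  }
}

#' Benchmark dose of a fitted or specified model (closed form)
#'
#' The benchmark dose (BMD) is the dose at which the mean response differs
#' from the background `a` by the fraction `bmr` (the benchmark response),
#' in the direction of the fitted curve: the BMD solves
#' `f(x) = a * (1 - bmr)` for a decreasing curve and `f(x) = a * (1 + bmr)`
#' for an increasing one.
#'
#' @param fit A `dr_fit` from [fit_mle()] (or a bare [dr_model()], in which
#'   case `direction` and `xmax` must be supplied).
#' @param bmr Benchmark response as a fraction in (0, 1).
#' @param direction `"increasing"` or `"decreasing"`; taken from the fit
#'   when available.
#' @param xmax Largest observed dose; the BMD must not exceed `10 * xmax`.
#' @return The benchmark dose (same units as the doses).
#' @export
compute_bmd <- function(fit, bmr, direction = NULL, xmax = NULL) {
  spec <- if (inherits(fit, "dr_fit")) fit$spec else fit
  stopifnot(inherits(spec, "dr_model"))
  if (!(bmr > 0 && bmr < 1)) stop("bmr must lie in (0, 1)")
  if (is.null(direction) && inherits(fit, "dr_fit")) direction <- fit$direction
  if (is.null(xmax) && inherits(fit, "dr_fit")) xmax <- fit$xmax
  if (is.null(xmax)) xmax <- Inf
  if (spec$level == 1) stop("BMD undefined for a constant model")
  if (is.null(direction) || direction == "constant") {
    stop("BMD undefined: fitted curve is constant over the observed range")
  }
  t <- if (direction == "increasing") 1 + bmr else 1 - bmr
  b <- spec$b; cc <- spec$c; d <- spec$d
  x <- suppressWarnings(if (spec$family == "exponential") {
    switch(as.character(spec$level),
      "2" = log(t) / b,
      "3" = (log(t) / b)^(1 / d),
      "4" = { u <- (cc - t) / (cc - 1); -log(u) / b },
      "5" = { u <- (cc - t) / (cc - 1); (-log(u) / b)^(1 / d) }
    )
  } else {
    switch(as.character(spec$level),
      "2" = b * bmr / (1 - bmr),
      "3" = b * (bmr / (1 - bmr))^(1 / d),
      "4" = { s <- (t - 1) / (cc - 1); b * s / (1 - s) },
      "5" = { s <- (t - 1) / (cc - 1); b * (s / (1 - s))^(1 / d) }
    )
  })
  if (!is.finite(x) || is.complex(x) || x <= 0) {
    stop("BMD beyond observed range: curve never reaches the benchmark response")
  }
  if (x > 10 * xmax) {
    stop(sprintf(
      "BMD beyond observed range: %.4g exceeds 10 x max dose (%.4g)", x, xmax))
  }
  x
}

# b implied by a fixed BMD, used for BMD-explicit reparameterization in
# profile likelihood. t is the target response factor (1 +/- bmr); returns
# NA when the constrained model cannot reach the target at that BMD.
.dr_b_from_bmd <- function(family, level, bmd, t, cc = NULL, d = NULL) {
  if (family == "exponential") {
    switch(as.character(level),
      "2" = log(t) / bmd,
      "3" = log(t) / bmd^d,
      "4" = { u <- (cc - t) / (cc - 1)
              if (!is.finite(u) || u <= 0) return(NA_real_)
              -log(u) / bmd },
      "5" = { u <- (cc - t) / (cc - 1)
              if (!is.finite(u) || u <= 0) return(NA_real_)
              -log(u) / bmd^d }
    )
  } else {
    switch(as.character(level),
      "2" = if (t >= 1) NA_real_ else bmd * t / (1 - t),
      "3" = if (t >= 1) NA_real_ else bmd * (t / (1 - t))^(1 / d),
      "4" = { s <- (t - 1) / (cc - 1)
              if (!is.finite(s) || s <= 0 || s >= 1) return(NA_real_)
              bmd * (1 - s) / s },
      "5" = { s <- (t - 1) / (cc - 1)
              if (!is.finite(s) || s <= 0 || s >= 1) return(NA_real_)
              bmd * ((1 - s) / s)^(1 / d) }
    )
  }
}

#' Geometric model averaging of benchmark doses
#'
#' Summarizes the accepted family members: the pooled BMD is the geometric
#' mean of the per-model BMDs, and the pooled 90% interval spans the
#' smallest per-model BMDL to the largest per-model BMDU.
#'
#' @param results A data frame (or list coercible to one) with columns
#'   `model`, `bmd`, `bmdl`, `bmdu`, one row per accepted model.
#' @return A list of class `bmd_result` with elements `averaged_bmd`,
#'   `ci90` (length-2), `per_model` (the input table), `accepted_models`.
#' @export
model_average <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, as.data.frame))
  }
  if (is.null(results) || nrow(results) == 0) stop("no accepted models")
  stopifnot(all(c("model", "bmd", "bmdl", "bmdu") %in% names(results)))
  structure(
    list(
      averaged_bmd = exp(mean(log(results$bmd))),
      ci90 = c(lower = min(results$bmdl), upper = max(results$bmdu)),
      per_model = results,
      accepted_models = as.character(results$model)
    ),
    class = "bmd_result"
  )
}

#' @export
print.bmd_result <- function(x, ...) {
  cat(sprintf("<bmd_result: BMD %.4g, 90%% CI [%.4g, %.4g], models: %s>\n",
              x$averaged_bmd, x$ci90[1], x$ci90[2],
              paste(x$accepted_models, collapse = ", ")))
  invisible(x)
}
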