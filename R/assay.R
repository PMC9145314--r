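# Plate-assay arithmetic: WST-1 viability, 5PL ELISA calibration,
# endotoxin classification, dose-metric conversion, particle geometry.

#' WST-1 viability as percentage of control
#'
#' Corrected signal is A440 - A620. Replicate wells for each role are
#' averaged first; viability is
#' `(A(cells, X) - A(medium, X)) / (A(cells, C) - A(medium, C)) * 100`.
#'
#' @param plate Data frame with columns `role` (one of `cells_treated`,
#'   `medium_treated`, `cells_control`, `medium_control`), `A440`, `A620`,
#'   and optionally `treatment`.
#' @param treatment When the plate holds several treatments, the one to
#'   evaluate (matched against the `treatment` column for the treated roles).
#' @return Viability percent of control.
#' @export
viability_percent <- function(plate, treatment = NULL) {
  need <- c("cells_treated", "medium_treated", "cells_control", "medium_control")
  if (!all(c("role", "A440", "A620") %in% names(plate))) {
    stop("plate needs columns role, A440, A620")
  }
  p <- plate
  if (!is.null(treatment) && "treatment" %in% names(p)) {
    keep <- p$role %in% c("cells_control", "medium_control") |
      p$treatment == treatment
    p <- p[keep, , drop = FALSE]
  }
  sig <- p$A440 - p$A620
  m <- vapply(need, function(r) {
    v <- sig[p$role == r]
    if (!length(v)) stop(sprintf("plate is missing wells with role '%s'", r))
    mean(v)
  }, 0)
  denom <- m["cells_control"] - m["medium_control"]
  if (denom <= 0) stop("assay failure: control signal (denominator) is <= 0")
  unname((m["cells_treated"] - m["medium_treated"]) / denom * 100)
}

# 5PL: y = lower + (upper - lower) / (1 + (x/c)^-b)^g
# lower/upper asymptotes, c inflection-type concentration, b slope (> 0 for
# an increasing curve), g asymmetry (> 0; g = 1 is the 4PL).

#' Evaluate a five-parameter logistic calibration curve
#'
#' @param curve A `curve_5pl` (see [fit_5pl()]) or a list/vector with
#'   elements `lower`, `upper`, `c`, `b`, `g`.
#' @param x Concentrations (>= 0); `x = 0` returns the lower asymptote.
#' @return Predicted optical densities.
#' @export
eval_5pl <- function(curve, x) {
  p <- as.list(curve)[c("lower", "upper", "c", "b", "g")]
  y <- rep_len(p$lower, length(x))
  pos <- x > 0
  y[pos] <- p$lower + (p$upper - p$lower) / (1 + (x[pos] / p$c)^(-p$b))^p$g
  y
}

#' Fit a 5PL calibration curve to ELISA standards
#'
#' Least-squares fit of the asymmetric logistic to a standard dilution
#' series; blank wells (concentration 0) anchor the lower asymptote.
#'
#' @param concentration Standard concentrations (>= 0; 0 = blank).
#' @param od Measured optical densities.
#' @return A list of class `curve_5pl` with elements `lower`, `upper`, `c`,
#'   `b`, `g`, `rss`, `monotone` (were the mean standards monotone?).
#' @export
fit_5pl <- function(concentration, od) {
  stopifnot(length(concentration) == length(od))
  if (any(concentration < 0)) stop("standard concentrations must be >= 0")
  if (length(unique(concentration[concentration > 0])) < 5) {
    stop("need >= 5 distinct non-zero standard concentrations")
  }
  means <- tapply(od, concentration, mean)
  xs <- as.numeric(names(means))
  ord <- order(xs)
  mono <- !is.unsorted(means[ord]) || !is.unsorted(rev(means[ord]))
  if (!mono) warning("standards are not monotone; best-effort fit flagged")
  lo0 <- if (any(concentration == 0)) means[["0"]] else min(means)
  hi0 <- max(means)
  cmid <- stats::median(concentration[concentration > 0])
  obj <- function(p) {
    cv <- list(lower = p[1], upper = p[2], c = exp(p[3]),
               b = exp(p[4]), g = exp(p[5]))
    if (cv$upper <= cv$lower) return(1e10)
    r <- od - eval_5pl(cv, concentration)
    sum(r^2)
  }
  best <- NULL
  for (g0 in c(0, log(0.5), log(2))) {
    p0 <- c(lo0, hi0 * 1.05, log(cmid), log(1), g0)
    r <- tryCatch(stats::optim(p0, obj, method = "Nelder-Mead",
                               control = list(maxit = 2000, reltol = 1e-12)),
                  error = function(e) NULL)
    if (!is.null(r) && (is.null(best) || r$value < best$value)) best <- r
  }
  if (is.null(best)) stop("5PL fit failed")
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 4000, reltol = 1e-14))
  p <- best$par
  structure(list(lower = p[1], upper = p[2], c = exp(p[3]),
                 b = exp(p[4]), g = exp(p[5]),
                 rss = best$value, monotone = mono),
            class = "curve_5pl")
}

#' @export
print.curve_5pl <- function(x, ...) {
  cat(sprintf(
    "<curve_5pl lower=%.4g upper=%.4g c=%.4g b=%.4g g=%.4g rss=%.3g>\n",
    x$lower, x$upper, x$c, x$b, x$g, x$rss))
  invisible(x)
}

#' Invert a 5PL curve (OD to concentration)
#'
#' Analytic inversion of the asymmetric logistic, multiplied by the sample
#' pre-dilution factor. ODs outside the open asymptote interval are flagged,
#' not clipped.
#'
#' @param curve A `curve_5pl`.
#' @param od Optical densities.
#' @param dilution_factor Pre-dilution applied to the samples (default 1).
#' @return Data frame with columns `od`, `concentration` (NA when out of
#'   range) and `flag` (`"ok"`, `"below_range"`, `"above_range"`).
#' @export
invert_5pl <- function(curve, od, dilution_factor = 1) {
  stopifnot(inherits(curve, "curve_5pl"), dilution_factor > 0)
  lo <- curve$lower; hi <- curve$upper
  flag <- ifelse(od <= lo, "below_range", ifelse(od >= hi, "above_range", "ok"))
  conc <- rep(NA_real_, length(od))
  ok <- flag == "ok"
  ratio <- (hi - lo) / (od[ok] - lo)
  conc[ok] <- curve$c * (ratio^(1 / curve$g) - 1)^(-1 / curve$b) * dilution_factor
  data.frame(od = od, concentration = conc, flag = flag,
             stringsAsFactors = FALSE)
}

#' Classify endotoxin content of a nanoparticle dispersion
#'
#' The contamination threshold in EU/mL is `limit` (EU/mg) times the product
#' concentration in mg/mL. Outcomes: `"A"` below threshold, `"B"` above,
#' `"C"` when particle interference precludes an accurate measurement.
#'
#' @param measured Measured endotoxin (EU/mL).
#' @param product_conc Product concentration in ug/mL.
#' @param limit Endotoxin limit in EU/mg (default 0.5).
#' @param interference Logical; does the particle interfere with the assay?
#' @return `"A"`, `"B"` or `"C"`.
#' @export
endotoxin_classify <- function(measured, product_conc, limit = 0.5,
                               interference = FALSE) {
  if (any(c(measured, product_conc, limit) < 0)) stop("inputs must be >= 0")
  if (product_conc <= 0) stop("product concentration must be > 0")
  if (isTRUE(interference)) return("C")
  threshold <- limit * product_conc / 1000  # ug/mL -> mg/mL
  if (measured < threshold) "A" else "B"
}

#' Spike-recovery interference helper
#'
#' Flags interference when recovery of a known endotoxin spike falls outside
#' the conventional LAL acceptance window.
#'
#' @param measured_spiked Measured endotoxin of the spiked dispersion (EU/mL).
#' @param measured_unspiked Measured endotoxin of the unspiked dispersion.
#' @param spike Spiked amount (EU/mL), default 0.5.
#' @param window Acceptable recovery window as a fraction (default 50-200%).
#' @return List with `recovery` (fraction) and `interference` (logical).
#' @export
spike_recovery <- function(measured_spiked, measured_unspiked, spike = 0.5,
                           window = c(0.5, 2)) {
  stopifnot(spike > 0)
  rec <- (measured_spiked - measured_unspiked) / spike
  list(recovery = rec, interference = rec < window[1] || rec > window[2])
}

#' Particle geometry
#'
#' @param shape `"rod"` or `"sphere"`.
#' @param radius Radius in nm (> 0); for rods, the cylinder radius.
#' @param length Rod length in nm (rods only).
#' @param mass_per_nM Mass-concentration equivalent of 1 nM particle number
#'   concentration, in ug/mL per nM (e.g. 1.324 for a 60 x 14 nm gold rod).
#' @return A list of class `particle_geometry`.
#' @export
particle_geometry <- function(shape = c("rod", "sphere"), radius,
                              length = NULL, mass_per_nM = NA_real_) {
  shape <- match.arg(shape)
  if (radius <= 0) stop("radius must be > 0")
  if (shape == "rod") {
    if (is.null(length) || length <= 0) stop("rods need a positive length")
  }
  structure(list(shape = shape, radius = radius, length = length,
                 mass_per_nM = mass_per_nM),
            class = "particle_geometry")
}

#' Surface-area-to-volume ratio of a particle
#'
#' Rods are treated as flat-capped cylinders: `2 (r + h) / (r h)`;
#' spheres give `3 / r`.
#'
#' @param geom A [particle_geometry()].
#' @return Ratio in 1/nm.
#' @export
surface_to_volume <- function(geom) {
  stopifnot(inherits(geom, "particle_geometry"))
  r <- geom$radius
  if (geom$shape == "rod") {
    h <- geom$length
    2 * (r + h) / (r * h)
  } else {
    3 / r
  }
}

#' Convert particle number concentration to mass concentration
#'
#' @param number_conc Particle number concentration in nM (>= 0).
#' @param geom A [particle_geometry()] carrying `mass_per_nM`.
#' @return Mass concentration in ug/mL.
#' @export
dose_convert <- function(number_conc, geom) {
  stopifnot(inherits(geom, "particle_geometry"))
  if (any(number_conc < 0)) stop("number concentration must be >= 0")
  if (!is.finite(geom$mass_per_nM) || geom$mass_per_nM <= 0) {
    stop("geometry must carry a positive mass_per_nM factor")
  }
  number_conc * geom$mass_per_nM
}

#' Log2 dose axis
#'
#' @param dose Mass concentration in ug/mL (> 0).
#' @return log2(dose).
#' @export
log2_dose <- function(dose) {
  if (any(dose <= 0)) stop("log2 dose is defined for positive doses only")
  log2(dose)
}

#' Process an ELISA plate CSV into calibrated concentrations
#'
#' Expects columns `well`, `role` (`standard`, `blank`, `sample`),
#' `concentration` (standards; ignored for samples), `od`, and optionally
#' `condition`. Blank wells enter the calibration at concentration 0.
#' Replicate sample wells are averaged after calibration.
#'
#' @param plate Data frame or CSV path.
#' @param dilution_factor Sample pre-dilution (default 20).
#' @return List with `curve` (the [fit_5pl()] fit) and `samples` (data frame
#'   of per-condition mean concentrations in pg/mL).
#' @export
elisa_plate_analysis <- function(plate, dilution_factor = 20) {
  if (is.character(plate)) plate <- utils::read.csv(plate, stringsAsFactors = FALSE)
  std <- plate[plate$role %in% c("standard", "blank"), ]
  conc <- ifelse(std$role == "blank", 0, std$concentration)
  curve <- fit_5pl(conc, std$od)
  smp <- plate[plate$role == "sample", ]
  inv <- invert_5pl(curve, smp$od, dilution_factor = dilution_factor)
  inv$condition <- if ("condition" %in% names(smp)) smp$condition else "sample"
  agg <- stats::aggregate(concentration ~ condition, data = inv, FUN = mean,
                          na.action = stats::na.pass)
  flags <- stats::aggregate(flag ~ condition, data = inv,
                            FUN = function(f) paste(unique(f), collapse = ","))
  list(curve = curve, samples = merge(agg, flags, by = "condition"),
       wells = inv)
}
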