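# Clinical cardiovascular outcome module.
#
# Outcome rates for non-fatal/fatal myocardial infarction and stroke
# are degree-10 polynomials in the Total:HDL cholesterol biomarker,
# stratified by gender x age group x rural/urban location.  The
# polynomial coefficient tensor stands in for unpublished
# survey-calibrated lookup tables: it is generated by fitting the
# polynomials to a logistic relative-risk model on the admissible
# biomarker range.

POLY_DEGREE <- 10L

#' Default synthetic risk parameters
#'
#' Baseline outcome rates (evaluated at the low end of the biomarker
#' range) rise exponentially with age, are lower for women and in rural
#' areas, and differ by illness; the log relative risk per unit of the
#' Total:HDL ratio is higher for myocardial infarction than for stroke.
#'
#' @return list with `base_rate` array `[gender, age, location, illness]`
#'   and `log_rr` per illness.
#' @export
default_risk_params <- function() {
  age_mid <- c(seq(2.5, 67.5, by = 5), 75)
  base60 <- c("MI-nf" = 1.5e-3, "S-nf" = 1.2e-3,
              "MI-f" = 8e-4, "S-f" = 5e-4)
  br <- array(0, dim = c(2, length(AGE_GROUPS), 2, length(ILLNESSES)),
              dimnames = list(GENDERS, AGE_GROUPS, c("rural", "urban"),
                              ILLNESSES))
  for (i in ILLNESSES) {
    curve <- base60[i] * exp(0.085 * (age_mid - 62))
    br["male", , "urban", i] <- curve
    br["female", , "urban", i] <- curve * 0.6
    br["male", , "rural", i] <- curve * 0.9
    br["female", , "rural", i] <- curve * 0.54
  }
  list(base_rate = br,
       log_rr = c("MI-nf" = 0.45, "S-nf" = 0.25,
                  "MI-f" = 0.45, "S-f" = 0.25))
}

# Evaluate a logistic hazard-rate curve in the biomarker.
logistic_rate <- function(chol, base, log_rr) {
  stats::plogis(stats::qlogis(base) + log_rr * (chol - CHOL_RANGE[1]))
}

# Fit a degree-10 polynomial in the raw biomarker to f on [2, 7].  The
# fit runs in the scaled variable u = (x - 4.5)/2.5 for conditioning
# and the coefficients are expanded back to raw monomials.
fit_poly10 <- function(f) {
  k <- 200
  u <- cos(pi * (2 * seq_len(k) - 1) / (2 * k))    # Chebyshev nodes
  x <- 4.5 + 2.5 * u
  V <- outer(u, 0:POLY_DEGREE, `^`)
  a <- qr.solve(V, f(x))
  # expand sum a_k ((x-4.5)/2.5)^k into raw powers of x
  coefs <- numeric(POLY_DEGREE + 1)
  base_poly <- c(-4.5 / 2.5, 1 / 2.5)              # u as a poly in x
  pow <- 1                                          # u^0
  for (kk in 0:POLY_DEGREE) {
    coefs[seq_along(pow)] <- coefs[seq_along(pow)] + a[kk + 1] * pow
    if (kk < POLY_DEGREE) {
      # multiply pow by base_poly (convolution)
      newp <- numeric(length(pow) + 1)
      newp[seq_along(pow)] <- newp[seq_along(pow)] + pow * base_poly[1]
      newp[seq_along(pow) + 1] <- newp[seq_along(pow) + 1] + pow * base_poly[2]
      pow <- newp
    }
  }
  coefs
}

#' Horner evaluation of a polynomial
#'
#' @param coefs coefficients in ascending degree order (r = 0..10).
#' @param x evaluation points.
#' @return polynomial values.
#' @export
horner <- function(coefs, x) {
  coefs <- unname(coefs)
  out <- rep(coefs[length(coefs)], length(x))
  for (k in seq(length(coefs) - 1, 1)) out <- out * x + coefs[k]
  out
}

#' Generate the clinical outcome lookup tensor
#'
#' For every gender x age group x location x illness cell, evaluates a
#' logistic hazard-rate model over the biomarker range and fits a
#' degree-10 polynomial.  The fit is verified on a 1,001-point grid:
#' maximum absolute error at most 1e-6, rates within \[0, 1\], and
#' non-decreasing in the biomarker (to numerical tolerance).
#'
#' @param seed unused (the generator is deterministic given
#'   `risk_params`); kept for interface stability.
#' @param risk_params see [default_risk_params()].
#' @return object of class `clinical_lookup`: coefficient array
#'   `[gender, age, location, illness, degree0..10]`.
#' @export
generate_lookup <- function(seed = NULL, risk_params = default_risk_params()) {
  bp <- risk_params$base_rate
  lrr <- risk_params$log_rr
  dn <- dimnames(bp)
  coefs <- array(0, dim = c(dim(bp), POLY_DEGREE + 1),
                 dimnames = c(dn, list(paste0("r", 0:POLY_DEGREE))))
  grid <- seq(CHOL_RANGE[1], CHOL_RANGE[2], length.out = 1001)
  for (g in dn[[1]]) for (a in dn[[2]]) for (l in dn[[3]]) for (i in dn[[4]]) {
    f <- function(x) logistic_rate(x, bp[g, a, l, i], lrr[i])
    cf <- fit_poly10(f)
    vals <- horner(cf, grid)
    err <- max(abs(vals - f(grid)))
    stop_if(err > 1e-6, "lookup fit error %.2e exceeds 1e-6", err)
    stop_if(any(vals < -1e-9 | vals > 1 + 1e-9),
            "lookup rates outside [0, 1]")
    stop_if(any(diff(vals) < -1e-9),
            "lookup rates not non-decreasing in biomarker")
    coefs[g, a, l, i, ] <- cf
  }
  structure(list(coefs = coefs), class = "clinical_lookup")
}

#' Stratified clinical outcome rates for one household
#'
#' Horner-evaluates the lookup polynomials at each stratum's
#' representative biomarker value; the rural/urban location is resolved
#' from the household's class.
#'
#' @param lookup a `clinical_lookup`.
#' @param dist the household's `biomarker_distribution`.
#' @param location `"rural"` or `"urban"`.
#' @return array `[stratum, gender, age, illness]` of annual rates.
#' @export
clin_rates <- function(lookup, dist, location = c("urban", "rural")) {
  location <- match.arg(location)
  v <- dist$values
  stop_if(any(v < CHOL_RANGE[1] - 1e-9 | v > CHOL_RANGE[2] + 1e-9),
          "biomarker value outside admissible range (upstream bug)")
  dn <- dimnames(lookup$coefs)
  out <- array(0, dim = c(length(v), length(dn[[1]]), length(dn[[2]]),
                          length(dn[[4]])),
               dimnames = list(NULL, dn[[1]], dn[[2]], dn[[4]]))
  for (g in dn[[1]]) for (a in dn[[2]]) for (i in dn[[4]]) {
    out[, g, a, i] <- horner(lookup$coefs[g, a, location, i, ], v)
  }
  out
}

#' Clinical outcome levels
#'
#' Converts stratified rates into incident-person levels by mixing over
#' the biomarker strata and multiplying by population counts.
#'
#' @param rates array `[stratum, gender, age, illness]` from
#'   [clin_rates()].
#' @param freq stratum frequencies (sum to 1).
#' @param pop matrix `[gender, age]` of population counts.
#' @return array `[gender, age, illness]` of persons per year.
#' @export
clin_levels <- function(rates, freq, pop) {
  stop_if(any(pop < 0), "negative population")
  stop_if(abs(sum(freq) - 1) > 1e-8, "frequencies must sum to 1")
  mixed <- apply(rates * freq, c(2, 3, 4), sum)   # [g, a, i]
  sweep(mixed, c(1, 2), pop, `*`)
}
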