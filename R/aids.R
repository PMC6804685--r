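# Household demand and nutrition transmission.
#
# Expenditure shares follow an Almost Ideal Demand System whose share
# equations are linear in log prices and in log real expenditure,
# deflated by the economy's GDP deflator:
#
#   w_c = alpha_c + beta_c log(e/P) + sum_c' gamma_{cc'} log p_c'
#   x_c = w_c e / p_c
#
# Calibration reproduces supplied income and uncompensated price
# elasticities at the base point via the share-elasticity relations
# (eta_c = 1 + beta_c/w_c, eps_{cc'} = -delta_{cc'} + gamma_{cc'}/w_c),
# then projects the parameters onto the adding-up / homogeneity /
# symmetry constraint set by least squares.

#' Calibrate an AIDS demand system from base shares and elasticities
#'
#' @param base_shares base expenditure shares (named, summing to 1).
#' @param income_elasticities income elasticities per commodity.
#' @param price_elasticities matrix of uncompensated price elasticities
#'   (`[c, c']`: response of quantity c to price c').
#' @param e0,P0,p0 base expenditure, deflator and prices (defaults 1).
#' @return an object of class `demand_system` with the calibrated
#'   parameters; attribute `projection` records the least-squares
#'   adjustment distances for beta and gamma.
#' @export
aids_calibrate <- function(base_shares, income_elasticities,
                           price_elasticities, e0 = 1, P0 = 1,
                           p0 = rep(1, length(base_shares))) {
  w0 <- base_shares
  n <- length(w0)
  stop_if(abs(sum(w0) - 1) > 1e-8, "base shares must sum to 1")
  stop_if(any(w0 <= 0 &
                (abs(income_elasticities) > 0 |
                   apply(abs(price_elasticities), 1, max) > 0)),
          "zero base share with nonzero elasticity")
  # target parameters from the share-elasticity relations
  beta_t <- w0 * (income_elasticities - 1)
  gamma_t <- w0 * (price_elasticities + diag(n))
  # adding-up for beta: sum(beta) = 0
  beta <- beta_t - sum(beta_t) / n
  # gamma: symmetric with zero row sums (hence zero column sums).
  # Parameterise by the upper triangle (incl. diagonal) and project the
  # symmetrised target onto {row sums = 0} by least squares.
  s_sym <- (gamma_t + t(gamma_t)) / 2
  ut <- which(upper.tri(s_sym, diag = TRUE), arr.ind = TRUE)
  svec <- s_sym[ut]
  C <- matrix(0, n, nrow(ut))
  for (k in seq_len(nrow(ut))) {
    i <- ut[k, 1]; j <- ut[k, 2]
    C[i, k] <- C[i, k] + 1
    if (i != j) C[j, k] <- C[j, k] + 1
  }
  gvec <- project_affine(svec, C)
  gamma <- matrix(0, n, n)
  gamma[ut] <- gvec
  gamma <- gamma + t(gamma) - diag(diag(gamma))
  alpha <- w0 - beta * log(e0 / P0) - as.numeric(gamma %*% log(p0))
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 w0 = w0, p0 = p0, e0 = e0, P0 = P0,
                 commodities = names(w0)),
            projection = c(beta = sqrt(sum((beta - beta_t)^2)),
                           gamma = sqrt(sum((gamma - gamma_t)^2))),
            class = "demand_system")
}

#' Expenditure shares of an AIDS system
#'
#' Shares always sum to one analytically; negative predicted shares
#' (possible under large shocks, AIDS not being globally regular) are
#' clipped at zero and the vector renormalised, with a warning when the
#' violation exceeds 0.01.
#'
#' @param ds a `demand_system`.
#' @param p price vector.
#' @param e total expenditure.
#' @param P deflator price index.
#' @return share vector.
#' @export
aids_shares <- function(ds, p, e, P) {
  stop_if(any(p <= 0) || e <= 0 || P <= 0,
          "prices, expenditure and deflator must be positive")
  w <- ds$alpha + ds$beta * log(e / P) + as.numeric(ds$gamma %*% log(p))
  if (any(w < 0)) {
    if (min(w) < -0.01)
      warning(sprintf(
        "AIDS share %.4f outside regular region; clipped and renormalised",
        min(w)))
    w <- pmax(w, 0)
    w <- w / sum(w)
  }
  stats::setNames(w, ds$commodities)
}

#' Commodity demands of an AIDS system
#'
#' @inheritParams aids_shares
#' @return quantity vector `x = w e / p`.
#' @export
aids_demand <- function(ds, p, e, P) {
  w <- aids_shares(ds, p, e, P)
  w * e / p
}

# Finite-difference elasticities at an evaluation point (test oracle
# support and calibration diagnostics).
aids_elasticities <- function(ds, p, e, P, h = 1e-6) {
  x0 <- aids_demand(ds, p, e, P)
  n <- length(p)
  eps <- matrix(0, n, n)
  for (j in seq_len(n)) {
    pj <- p; pj[j] <- p[j] * (1 + h)
    eps[, j] <- (aids_demand(ds, pj, e, P) / x0 - 1) / h
  }
  eta <- (aids_demand(ds, p, e * (1 + h), P) / x0 - 1) / h
  list(income = eta, price = eps)
}

# ---------------------------------------------------------------------------
# Nutrition transmission

#' Fatty-acid energy intake shares
#'
#' Energy intake shares from saturated, mono-unsaturated and
#' poly-unsaturated fatty acids: each share is the fatty-acid energy
#' delivered by the consumption bundle divided by its total energy.
#'
#' @param x consumption vector (named by commodity).
#' @param nutrients matrix `[commodity, c("total","SFA","MUFA","PUFA")]`
#'   of energy contents per unit of consumption.
#' @return named vector `c(SFA=, MUFA=, PUFA=, total_energy=)`.
#' @export
intake_shares <- function(x, nutrients) {
  stop_if(any(x < 0), "negative consumption")
  nm <- rownames(nutrients)
  x <- x[nm]
  tot <- sum(nutrients[, "total"] * x)
  stop_if(tot <= 0, "zero total energy intake")
  out <- c(SFA = sum(nutrients[, "SFA"] * x) / tot,
           MUFA = sum(nutrients[, "MUFA"] * x) / tot,
           PUFA = sum(nutrients[, "PUFA"] * x) / tot)
  c(out, total_energy = tot)
}

#' Cholesterol biomarker build-up from intake-share changes
#'
#' Total:HDL ratio change from changes in fatty-acid energy intake
#' shares.  The MUFA pathway is weighted by the ratio of the MUFA share
#' to the total fatty-acid share (`mufa_term = "ratio"`, the default) or
#' enters linearly (`"linear"`).
#'
#' @param d_shares named vector of intake-share changes
#'   (`SFA`, `MUFA`, `PUFA`).
#' @param levels current intake-share levels (same names), used by the
#'   ratio weighting.
#' @param response named build-up coefficients per unit share change.
#' @param mufa_term weighting convention for the MUFA term.
#' @return scalar biomarker change.
#' @export
cholesterol_delta <- function(d_shares, levels, response,
                              mufa_term = c("ratio", "linear")) {
  mufa_term <- match.arg(mufa_term)
  stop_if(any(!is.finite(d_shares)) || any(!is.finite(levels)),
          "non-finite inputs to cholesterol_delta")
  etot <- levels[["SFA"]] + levels[["MUFA"]] + levels[["PUFA"]]
  mw <- if (mufa_term == "ratio" && etot > 0) levels[["MUFA"]] / etot else 1
  response[["SFA"]] * d_shares[["SFA"]] +
    response[["MUFA"]] * mw * d_shares[["MUFA"]] +
    response[["PUFA"]] * d_shares[["PUFA"]]
}

# ---------------------------------------------------------------------------
# Biomarker distributions

#' Construct a stratified biomarker distribution
#'
#' Ten equidistant strata over the admissible Total:HDL ratio range
#' \[2.0, 7.0\]; each stratum carries a frequency and a representative
#' value (initially the bin midpoint).
#'
#' @param mean mean biomarker level.
#' @param freq stratum frequencies (length 10, non-negative, sum 1).
#' @param values representative stratum values (default bin midpoints).
#' @return object of class `biomarker_distribution`.
#' @export
biomarker_distribution <- function(mean, freq,
                                   values = seq(2.25, 6.75, by = 0.5)) {
  stop_if(length(freq) != N_STRATA, "expected %d strata", N_STRATA)
  stop_if(any(freq < 0) || abs(sum(freq) - 1) > 1e-8,
          "frequencies must be non-negative and sum to 1")
  stop_if(any(values < CHOL_RANGE[1] - 1e-12 |
                values > CHOL_RANGE[2] + 1e-12),
          "stratum values outside biomarker range")
  structure(list(mean = mean, freq = freq, values = values),
            class = "biomarker_distribution")
}

#' Shift a biomarker distribution by a mean change
#'
#' Every stratum's representative value (and the mean) moves by
#' `d_chol`, clamped to the admissible range; frequencies are unchanged
#' so probability mass is conserved.
#'
#' @param dist a `biomarker_distribution`.
#' @param d_chol biomarker change.
#' @return shifted `biomarker_distribution`.
#' @export
shift_distribution <- function(dist, d_chol) {
  clamp <- function(v) pmin(pmax(v, CHOL_RANGE[1]), CHOL_RANGE[2])
  biomarker_distribution(clamp(dist$mean + d_chol), dist$freq,
                         clamp(dist$values + d_chol))
}
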