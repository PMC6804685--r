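# Constant-elasticity aggregator primitives.
#
# A single parametrisation covers both CES cost minimisation (sigma > 0)
# and CET revenue maximisation (pass sigma = -sigma_t < 0): the dual
# unit-value function and the Shephard/Hotelling input (output) demands
# have the same algebraic form with the sign of the exponent flipped.
# sigma == 1 is handled as the Cobb-Douglas limit.

#' Calibrate a CES/CET nest from base-point data
#'
#' Given base prices and base quantities that are assumed to satisfy the
#' first-order conditions of the nest, recovers share parameters `delta`
#' (normalised to sum to one over active inputs) and the shift `alpha`
#' such that the aggregate quantity at the base point equals `sum(p0*x0)`
#' valued at a unit aggregate price (i.e. base unit cost/revenue is 1
#' when all base prices are 1).
#'
#' @param p0 base prices (positive for active inputs).
#' @param x0 base quantities (zero entries mark permanently inactive inputs).
#' @param sigma substitution elasticity; negative values denote a CET
#'   transformation nest with elasticity `-sigma`; `sigma = 1` is
#'   Cobb-Douglas.
#' @return an object of class `ces_nest`.
#' @keywords internal
ces_calibrate <- function(p0, x0, sigma) {
  stop_if(length(p0) != length(x0), "ces_calibrate: length mismatch")
  stop_if(any(x0 < 0), "ces_calibrate: negative base quantity")
  active <- x0 > 0
  stop_if(!any(active), "ces_calibrate: no active inputs")
  delta <- numeric(length(x0))
  if (abs(sigma - 1) < 1e-12) {
    delta[active] <- p0[active] * x0[active]
    delta <- delta / sum(delta)
    q0 <- sum(p0 * x0)                       # unit price aggregate
    alpha <- q0 / prod((x0[active])^delta[active])
  } else {
    delta[active] <- p0[active] * x0[active]^(1 / sigma)
    delta <- delta / sum(delta)
    rho <- 1 / sigma - 1
    q0 <- sum(p0 * x0)
    agg <- sum(delta[active] * x0[active]^(-rho))^(-1 / rho)
    alpha <- q0 / agg
  }
  structure(list(delta = delta, alpha = alpha, sigma = sigma,
                 active = active),
            class = "ces_nest")
}

#' Dual unit value of a CES/CET nest
#'
#' Unit cost for a CES nest, unit revenue for a CET nest (sigma < 0).
#'
#' @param nest a `ces_nest`.
#' @param p price vector (entries for inactive inputs are ignored).
#' @return scalar unit value.
#' @keywords internal
ces_unit_value <- function(nest, p) {
  a <- nest$active
  d <- nest$delta[a]
  pp <- p[a]
  stop_if(any(pp <= 0), "ces_unit_value: nonpositive price")
  s <- nest$sigma
  if (abs(s - 1) < 1e-12) {
    exp(sum(d * log(pp / d))) / nest$alpha
  } else {
    (sum(d^s * pp^(1 - s)))^(1 / (1 - s)) / nest$alpha
  }
}

#' Optimal inputs (or outputs) per the nest FOCs
#'
#' Returns the cost-minimising input vector (CES) or revenue-maximising
#' output split (CET) that delivers aggregate quantity `q` at prices `p`.
#'
#' @param nest a `ces_nest`.
#' @param p price vector.
#' @param q aggregate quantity.
#' @return quantity vector (zeros for inactive inputs).
#' @keywords internal
ces_inputs <- function(nest, p, q) {
  a <- nest$active
  d <- nest$delta[a]
  pp <- p[a]
  s <- nest$sigma
  uv <- ces_unit_value(nest, p)
  x <- numeric(length(nest$delta))
  if (abs(s - 1) < 1e-12) {
    x[a] <- d * uv * q / pp
  } else {
    # Shephard/Hotelling: x_i = q * d_i^s * (alpha*uv / p_i)^s / alpha ...
    x[a] <- q * d^s * pp^(-s) * (nest$alpha * uv)^s / nest$alpha
  }
  x
}
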