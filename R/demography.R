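# Cohort-component demographic projection with annual steps over
# five-year age groups.  Within a year the order of events is: survive
# (1 - mortality), remain (1 - net emigration), then transition to the
# next age group with the (dynamically calibrated) transition
# probability; the terminal 70+ group accumulates.  Births apply the
# sex ratio to fertility-weighted previous-year female populations.

#' Extract the vital rates of a single year
#'
#' @param rates fixture vital-rate bundle (arrays keyed by year).
#' @param year calendar year.
#' @return list with `sexratio`, `asfr`, `mu`, `migr`, `ptrans` for the
#'   requested year.
#' @export
vital_slice <- function(rates, year) {
  t <- match(as.character(year), dimnames(rates$mu)[[4]])
  stop_if(is.na(t), "no vital rates for year %s", year)
  slice3 <- function(a) {
    s <- a[, , , t, drop = FALSE]
    array(s, dim = dim(a)[1:3], dimnames = dimnames(a)[1:3])
  }
  list(sexratio = rates$sexratio,
       asfr = rates$asfr[, t],
       mu = slice3(rates$mu),
       migr = slice3(rates$migr),
       ptrans = slice3(rates$ptrans))
}

#' Project the population one year forward
#'
#' @param pop array `[household, gender, age]` of persons.
#' @param v vital rates for the projection year, see [vital_slice()];
#'   `mu`, `migr`, `ptrans` are `[household, gender, age]` arrays,
#'   `asfr` a per-age vector, `sexratio` a per-gender vector summing
#'   to 1.
#' @return projected population array of the same shape.
#' @export
project_year <- function(pop, v) {
  stop_if(any(pop < 0), "negative population")
  for (r in c("mu", "migr", "ptrans")) {
    stop_if(any(v[[r]] < 0 | v[[r]] > 1), "%s outside [0, 1]", r)
  }
  dn <- dimnames(pop)
  H <- dn[[1]]; G <- dn[[2]]; A <- dn[[3]]
  nA <- length(A)
  surv <- (1 - v$mu) * (1 - v$migr)       # [h, g, a]
  out <- array(0, dim = dim(pop), dimnames = dn)
  stay <- (1 - v$ptrans) * surv * pop
  move <- v$ptrans * surv * pop
  out[, , 1] <- stay[, , 1]
  for (a in 2:(nA - 1)) out[, , a] <- move[, , a - 1] + stay[, , a]
  out[, , nA] <- move[, , nA - 1] + surv[, , nA] * pop[, , nA]
  births_tot <- as.numeric(pop[, "female", ] %*% v$asfr)   # per household
  for (g in G) out[, g, 1] <- out[, g, 1] + v$sexratio[g] * births_tot
  out
}

# Deaths and net emigration implied by one projection step (accounting
# identity support).
project_flows <- function(pop, v) {
  deaths <- v$mu * pop
  migr <- v$migr * (1 - v$mu) * pop
  births <- as.numeric(pop[, "female", ] %*% v$asfr)
  list(deaths = deaths, migr = migr, births = births)
}

#' Dynamically calibrate age-group transition probabilities
#'
#' Solves, year by year and cohort by cohort, for the transition
#' probabilities that reproduce a target population path given the
#' other vital rates.  The equations are sequential in age: the
#' youngest group pins its own exit probability, each middle group then
#' pins the next, and the terminal group provides a feasibility check
#' (its equation involves no new unknown).
#'
#' @param pop0 base-year population `[household, gender, age]`.
#' @param target_path target array `[household, gender, age, year]`
#'   whose first slice is `pop0`.
#' @param rates vital-rate bundle (the `ptrans` entries are ignored).
#' @return list with the calibrated `ptrans` array, the maximum
#'   relative residual on the terminal group, and a count of
#'   \[0, 1\]-clamped probabilities.
#' @export
calibrate_transitions <- function(pop0, target_path, rates) {
  dn <- dimnames(target_path)
  years <- as.integer(dn[[4]])
  nA <- length(dn[[3]])
  ptr <- array(0, dim = dim(rates$mu), dimnames = dimnames(rates$mu))
  clamped <- 0L
  max_resid <- 0
  pop <- pop0
  for (t in 2:length(years)) {
    v <- vital_slice(rates, years[t])
    tgt <- array(target_path[, , , t, drop = FALSE],
                 dim = dim(target_path)[1:3],
                 dimnames = dimnames(target_path)[1:3])
    surv <- (1 - v$mu) * (1 - v$migr) * pop      # [h,g,a] survivors in place
    births <- as.numeric(pop[, "female", ] %*% v$asfr)
    p <- array(0, dim = dim(pop), dimnames = dimnames(pop))
    for (h in seq_len(dim(pop)[1])) for (g in 1:2) {
      b <- v$sexratio[g] * births[h]
      # age 1: tgt = (1 - p1) surv1 + births
      inflow <- b
      for (a in 1:(nA - 1)) {
        s <- surv[h, g, a]
        pa <- if (s > 0) 1 - (tgt[h, g, a] - inflow) / s else 0
        if (pa < 0 || pa > 1) {
          clamped <- clamped + 1L
          pa <- min(max(pa, 0), 1)
        }
        p[h, g, a] <- pa
        inflow <- pa * s
      }
      # terminal group: no unknown; record feasibility residual
      pred <- inflow + surv[h, g, nA]
      max_resid <- max(max_resid,
                       abs(pred - tgt[h, g, nA]) /
                         max(tgt[h, g, nA], 1e-8))
    }
    ti <- match(as.character(years[t]), dimnames(ptr)[[4]])
    ptr[, , , ti] <- p
    vv <- v; vv$ptrans <- p
    pop <- project_year(pop, vv)
  }
  if (clamped > 0)
    warning(sprintf("%d transition probabilities clamped to [0, 1]", clamped))
  list(ptrans = ptr, terminal_residual = max_resid, clamped = clamped)
}

#' Illness-specific cholesterol-related excess mortality rates
#'
#' Frequency-weighted average of the stratified fatal outcome rates.
#'
#' @param rates array `[stratum, gender, age, illness]` from
#'   [clin_rates()].
#' @param freq stratum frequencies.
#' @return array `[gender, age, illness]` restricted to the fatal
#'   illnesses.
#' @export
excess_mortality <- function(rates, freq) {
  fatal <- c("MI-f", "S-f")
  apply(rates[, , , fatal, drop = FALSE] * freq, c(2, 3, 4), sum)
}

#' Apply the excess-mortality feedback to all-cause mortality
#'
#' Policy all-cause mortality equals counterfactual all-cause mortality
#' plus the policy-minus-counterfactual difference in fatal-illness
#' excess mortality, clamped to \[0, 1\] with a warning.
#'
#' @param mu_count counterfactual all-cause mortality `[.., age ..]`.
#' @param excess_policy,excess_count fatal-illness excess mortality
#'   arrays of a common shape whose sum over illnesses conforms to
#'   `mu_count`.
#' @return adjusted mortality array.
#' @export
apply_excess_feedback <- function(mu_count, excess_policy, excess_count) {
  stop_if(!identical(dim(excess_policy), dim(excess_count)),
          "excess mortality shape mismatch")
  nd <- length(dim(excess_policy))
  delta <- apply(excess_policy - excess_count, seq_len(nd - 1), sum)
  out <- mu_count + as.numeric(delta)
  if (any(out < 0 | out > 1)) {
    warning("adjusted all-cause mortality clamped to [0, 1]")
    out <- pmin(pmax(out, 0), 1)
  }
  out
}
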