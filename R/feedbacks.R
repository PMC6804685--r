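# Economic feedback effects: caregiver/patient time losses, YLD
# morbidity, effective labour supplies and lagged formal health costs.

#' Caregiver and patient time losses from non-fatal outcomes
#'
#' Caregiver worktime and leisure losses are rate x illness duration x
#' summed non-fatal incident levels; YLD morbidity applies disability
#' weights; patient worktime losses are participation-weighted YLD.
#' Patient losses are computed over the non-fatal illnesses (the YLD
#' approximation); set `patient_over_fatal = TRUE` for the literal
#' fatal-illness indexing.
#'
#' @param levels array `[household, gender, age, illness]` of incident
#'   levels (persons/year).
#' @param params health-economic parameter list, see
#'   [fixture_healthecon()].
#' @param patient_over_fatal index patient worktime losses by the fatal
#'   illnesses instead of the non-fatal ones.
#' @return list with `tu_care_ls`, `tu_care_nonls` (`[household,
#'   illness]`), `yld` (`[household, gender, illness]`) and
#'   `tu_patient` (`[household, illness]`), all in person-years.
#' @export
time_losses <- function(levels, params, patient_over_fatal = FALSE) {
  stop_if(any(levels < 0), "negative incident levels")
  H <- dimnames(levels)[[1]]
  nf <- c("MI-nf", "S-nf")
  tot_hi <- apply(levels[, , , nf, drop = FALSE], c(1, 4), sum)
  dur <- params$illdur[nf]
  tu_ls <- sweep(tot_hi, 2, params$tu_care_ls[nf] * dur, `*`)
  tu_nonls <- sweep(tot_hi, 2, params$tu_care_nonls[nf] * dur, `*`)
  tot_hgi <- apply(levels[, , , nf, drop = FALSE], c(1, 2, 4), sum)
  yld <- sweep(tot_hgi, 3, params$yld_weight[nf] * dur, `*`)
  pw <- apply(sweep(yld, 2, params$partrate[dimnames(yld)[[2]]], `*`),
              c(1, 3), sum)
  if (patient_over_fatal) dimnames(pw)[[2]] <- c("MI-f", "S-f")
  list(tu_care_ls = tu_ls, tu_care_nonls = tu_nonls, yld = yld,
       tu_patient = pw)
}

#' Effective labour supplies
#'
#' Skill-share split of the participation-weighted working-age (15-64)
#' population of the previous year, net of the policy-minus-
#' counterfactual patient and caregiver worktime loss differences.
#'
#' @param pop_prev previous-year population `[household, gender, age]`.
#' @param d_tu_patient,d_tu_care policy-minus-counterfactual worktime
#'   loss deltas `[household, illness]` (person-years); zero matrices
#'   for a counterfactual run.
#' @param params health-economic parameter list.
#' @param sklshr matrix `[household, c("uskl","skl")]` of labour skill
#'   composition shares (rows sum to 1).
#' @return matrix `[household, skill]` of effective labour supplies in
#'   persons.
#' @export
labour_supply <- function(pop_prev, d_tu_patient, d_tu_care, params,
                          sklshr) {
  wa <- WORKING_AGES
  base_h <- vapply(dimnames(pop_prev)[[1]], function(h) {
    sum(vapply(GENDERS, function(g)
      params$partrate[g] * sum(pop_prev[h, g, wa]), numeric(1)))
  }, numeric(1))
  adj <- base_h - rowSums(d_tu_patient) - rowSums(d_tu_care)
  ls <- sklshr * adj
  if (any(ls < 0)) warning("negative effective labour supply")
  ls
}

#' Lagged formal health costs
#'
#' Health unit costs grow with the GDP deflator; household excess
#' health costs accumulate unit cost x lagged non-fatal incident
#' levels over lags 0-3 (lags 1-3 are only non-zero for non-fatal
#' stroke), and split into publicly and privately funded parts by a
#' configured share.
#'
#' @param level_history list of `[household, illness]` summed non-fatal
#'   incident levels, most recent year first (index 1 = lag 0); missing
#'   lags are treated as zero incremental cost (pad with counterfactual
#'   levels upstream for delta accounting).
#' @param params health-economic parameter list (`huc` is
#'   `[illness, lag0..3]` base unit costs, `public_share` the publicly
#'   funded fraction).
#' @param gdpdef,gdpdef0 current and base-year GDP deflator.
#' @return list with `huc` (unit costs at `gdpdef`), `hc`, `hcp`,
#'   `hcg` (`[household, illness]`).
#' @export
health_costs <- function(level_history, params, gdpdef, gdpdef0) {
  huc <- params$huc * (gdpdef / gdpdef0)
  nf <- rownames(huc)
  h1 <- level_history[[1]]
  hc <- matrix(0, nrow(h1), length(nf),
               dimnames = list(rownames(h1), nf))
  for (lag in 0:3) {
    lev <- if (lag + 1 <= length(level_history)) level_history[[lag + 1]]
           else NULL
    if (is.null(lev)) next
    hc <- hc + sweep(lev[, nf, drop = FALSE], 2, huc[, lag + 1], `*`)
  }
  list(huc = huc, hc = hc,
       hcg = hc * params$public_share,
       hcp = hc * (1 - params$public_share))
}
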