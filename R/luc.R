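# Land-use-change satellite module: converts year-on-year land
# reallocations across agricultural activities into bilateral crop
# transition flows (proportional mixing between losing and gaining
# crops within each region) and greenhouse-gas emission changes.

#' Crop transition flows between two land allocations
#'
#' Within each region the total positive land-use change is pooled;
#' gain and loss shares (activities with exactly zero change count as
#' losses of zero magnitude) allocate it to bilateral loser-to-gainer
#' flows.
#'
#' @param prev,curr matrices `[activity, region]` of land areas
#'   (hectares) in consecutive years; regional totals must be equal
#'   (fixed land supplies).
#' @param tol tolerance for the regional conservation check, relative
#'   to the regional total.
#' @return array `[activity1, activity2, region]` of hectares moving
#'   from activity1 to activity2.
#' @export
land_transitions <- function(prev, curr, tol = 1e-6) {
  stop_if(!identical(dimnames(prev), dimnames(curr)),
          "land allocations must share accounts")
  tot_prev <- colSums(prev); tot_curr <- colSums(curr)
  stop_if(any(abs(tot_prev - tot_curr) > tol * pmax(tot_prev, 1)),
          "regional land total not conserved")
  acts <- rownames(prev); regs <- colnames(prev)
  flows <- array(0, dim = c(length(acts), length(acts), length(regs)),
                 dimnames = list(acts, acts, regs))
  for (r in regs) {
    d <- curr[, r] - prev[, r]
    pos <- sum(d[d > 0])
    if (pos <= 0) next
    gain_shr <- ifelse(d > 0, d, 0) / pos
    loss_shr <- ifelse(d <= 0, -d, 0) / pos
    flows[, , r] <- (loss_shr %o% gain_shr) * pos
  }
  flows
}

#' Greenhouse-gas emission change from crop transitions
#'
#' @param flows transition array from [land_transitions()].
#' @param coef antisymmetric emission coefficient matrix
#'   `[activity1, activity2]` in Mt CO2-eq per hectare (positive when
#'   the transition releases carbon).
#' @return scalar emission change (Mt CO2-eq).
#' @export
ghg_delta <- function(flows, coef) {
  stop_if(max(abs(coef + t(coef))) > 1e-12 * max(abs(coef), 1),
          "emission coefficient matrix must be antisymmetric")
  sum(vapply(seq_len(dim(flows)[3]),
             function(r) sum(coef * flows[, , r]), numeric(1)))
}
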