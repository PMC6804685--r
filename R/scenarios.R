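# Scenario orchestration: assembles the full model from a fixture
# bundle, runs counterfactual/policy pairs through the annual
# economy -> diet -> cholesterol -> clinical -> demography -> feedback
# loop, performs efficiency and health-pathway decompositions, and
# produces the indicator set and cost-effectiveness report.
#
# Within-year coupling: the economy of year t is solved with labour
# supplies built from the previous year's population and with health
# time-loss and cost feedbacks entering with a one-year lag (the
# recursive-dynamic convention that breaks the within-period
# simultaneity between the economy and the clinical outcomes it
# causes).

hh_location <- function(h) if (grepl("_ru$", h)) "rural" else "urban"

#' Assemble the simulation model from a fixture bundle
#'
#' Calibrates the CGE, links person-based labour supplies to the
#' value-based factor supplies of the SAM, and precomputes the
#' baseline labour-supply path from the demographic fixture.
#'
#' @param fx a `fixture_bundle`.
#' @return object of class `med_model`.
#' @export
build_model <- function(fx) {
  params <- cge_calibrate(fx$sam_model, fx$demand$elasticities)
  he <- fx$healthecon
  sklshr <- params$LS0 / rowSums(params$LS0)
  colnames(sklshr) <- params$labfacs
  pop0 <- fx$demog$pop0
  ls_person0 <- labour_supply(pop0,
                              zero_tu(params$households),
                              zero_tu(params$households), he, sklshr)
  labscale <- params$LS0 / ls_person0
  years <- fx$demog$years
  ls_value_path <- list()
  ls_person_path <- list()
  for (t in 2:length(years)) {
    lp <- labour_supply(fx$demog$target_path[, , , t - 1],
                        zero_tu(params$households),
                        zero_tu(params$households), he, sklshr)
    ls_person_path[[as.character(years[t])]] <- lp
    ls_value_path[[as.character(years[t])]] <- lp * labscale
  }
  structure(list(params = params, fixtures = fx, sklshr = sklshr,
                 labscale = labscale, pop0 = pop0,
                 ls_value_path = ls_value_path,
                 ls_person_path = ls_person_path,
                 state0 = initial_state(params),
                 locations = vapply(params$households, hh_location,
                                    character(1))),
            class = "med_model")
}

zero_tu <- function(hhs) {
  matrix(0, length(hhs), 2, dimnames = list(hhs, c("MI-nf", "S-nf")))
}

#' Calibrate business-as-usual growth trends for a model
#'
#' Convenience wrapper around [dynamic_calibrate()] using the model's
#' baseline labour-supply path.
#'
#' @param model a `med_model`.
#' @param years simulation years.
#' @param ... passed to [dynamic_calibrate()].
#' @return a `growth_trends`.
#' @export
calibrate_trends <- function(model, years = 2016:2035, ...) {
  dynamic_calibrate(model$params, model$state0,
                    ls_path = model$ls_value_path, years = years, ...)
}

# ---------------------------------------------------------------------------
# Tariff instruments

food_model_sectors <- function() {
  names(MODEL_TO_COARSE)[MODEL_TO_COARSE %in% FOOD_COARSE]
}

#' Build a per-commodity tariff vector from an intervention spec
#'
#' @param params a `cge_params`.
#' @param base tariff vector the edit applies to.
#' @param edit list with `type` in `none`, `eliminate_food`,
#'   `eliminate_nonfood`, `eliminate_all`, `set_food`, `set_all`,
#'   `set_sector`; `rate` for the `set_*` types; `sector` (coarse food
#'   sector name) for `set_sector`.
#' @return named tariff vector.
#' @export
tariff_edit <- function(params, base, edit) {
  tm <- base
  food <- intersect(food_model_sectors(), params$sectors)
  nonfood <- setdiff(params$sectors, food)
  switch(edit$type,
         none = tm,
         eliminate_food = { tm[food] <- 0; tm },
         eliminate_nonfood = { tm[nonfood] <- 0; tm },
         eliminate_all = { tm[] <- 0; tm },
         set_food = { tm[food] <- edit$rate; tm },
         set_all = { tm[] <- edit$rate; tm },
         set_sector = {
           mods <- names(MODEL_TO_COARSE)[MODEL_TO_COARSE == edit$sector]
           stop_if(length(mods) == 0, "unknown sector %s", edit$sector)
           tm[intersect(mods, params$sectors)] <- edit$rate
           tm
         },
         stop_if(TRUE, "unknown tariff edit type %s", edit$type))
}

# ---------------------------------------------------------------------------
# Annual pipeline

# Run the coupled annual loop.  `mode`:
#   counterfactual - ratio fiscal rule, no health feedback deltas
#   policy         - real government path and health deltas vs `ref`
#   efficiency     - efficiency closure vs `ref`, economy only
#   pathway        - counterfactual tariffs plus exogenous health
#                    shocks from `exo` (a completed policy run)
run_pipeline <- function(model, trends, tm, years = 2016:2035,
                         mode = c("counterfactual", "policy",
                                  "efficiency", "pathway"),
                         ref = NULL, exo = NULL, g_path = NULL) {
  mode <- match.arg(mode)
  fx <- model$fixtures
  p <- model$params
  he <- fx$healthecon
  econ_only <- mode %in% c("efficiency", "pathway")
  needs_ref <- mode != "counterfactual"
  stop_if(needs_ref && is.null(ref), "%s run requires a reference run", mode)
  stop_if(mode == "pathway" && is.null(exo),
          "pathway run requires a completed policy run")

  hhs <- p$households
  crops <- intersect(CROP_SECTORS, p$sectors)
  land_ha <- function(FD) {
    m <- t(FD[p$landfacs, crops, drop = FALSE])
    sweep(m, 2, fx$luc$ha_per_value[sub("^land\\.", "", p$landfacs)], `*`)
  }

  state <- model$state0
  eq <- trends$base_eq
  dist <- fx$biomarkers
  shares_prev <- lapply(hhs, function(h)
    intake_shares(p$cons0[, h], fx$nutrition$table[[h]]))
  names(shares_prev) <- hhs
  pop <- model$pop0
  prev_ha <- land_ha(p$FD0)
  lev_hist <- list()        # [h, i] non-fatal level sums, newest first
  losses_prev <- NULL

  out <- list(years = years, mode = mode, econ = list(), shares = list(),
              chol = list(), levels = list(), losses = list(),
              pop = list(), ls_person = list(), hc = list(),
              ghg = numeric(0), ghg_cum = numeric(0))
  ghg_cum <- 0

  for (yr in years) {
    ys <- as.character(yr)
    # --- labour supply and health-cost shocks (one-year lag) ---
    if (mode %in% c("counterfactual", "efficiency")) {
      ls_person <- model$ls_person_path[[ys]]
      ls_value <- model$ls_value_path[[ys]]
      shocks <- list()
    } else if (mode == "policy") {
      d_pat <- d_care <- zero_tu(hhs)
      if (!is.null(losses_prev)) {
        rl <- ref$losses[[as.character(yr - 1)]]
        d_pat <- losses_prev$tu_patient - rl$tu_patient
        d_care <- losses_prev$tu_care_ls - rl$tu_care_ls
      }
      ls_person <- labour_supply(pop, d_pat, d_care, he, model$sklshr)
      ls_value <- ls_person * model$labscale
      shocks <- policy_hc_shocks(lev_hist, ref, yr, he, trends)
    } else {                      # pathway: exogenous deltas from `exo`
      d_ls <- exo$ls_person[[ys]] - ref$ls_person[[ys]]
      ls_person <- model$ls_person_path[[ys]] + d_ls
      ls_value <- ls_person * model$labscale
      shocks <- delta_shocks(exo$hc[[ys]], ref$hc[[ys]])
    }

    # --- economy ---
    closure <- pipeline_closure(mode, ref, ys)
    if (!is.null(g_path) && mode == "counterfactual")
      closure <- list(mode = "policy", g_rule = "real",
                      g_real = g_path[[ys]], c_real = NA_real_,
                      tb_real = NA_real_)
    state <- advance(state, eq, LS_next = ls_value,
                     A_next = trends$A[ys], cpi_next = trends$cpi[ys])
    start <- if (needs_ref) ref$econ[[ys]] else trends$starts[[ys]]
    eq <- solve_period(p, state, tm = tm, closure = closure,
                       shocks = shocks, start = start)
    out$econ[[ys]] <- eq
    out$ls_person[[ys]] <- ls_person

    # --- land use ---
    cur_ha <- land_ha(eq$FD)
    fl <- land_transitions(prev_ha, cur_ha)        # [act, region]
    dghg <- ghg_delta(fl, fx$luc$emiss_coef[crops, crops])
    ghg_cum <- ghg_cum + dghg
    out$ghg[ys] <- dghg
    out$ghg_cum[ys] <- ghg_cum
    prev_ha <- cur_ha

    if (econ_only) next

    # --- nutrition and cholesterol ---
    shares <- lapply(hhs, function(h)
      intake_shares(stats::setNames(eq$x[, match(h, hhs)], p$sectors),
                    fx$nutrition$table[[h]]))
    names(shares) <- hhs
    dist <- lapply(stats::setNames(nm = hhs), function(h) {
      d_sh <- shares[[h]][c("SFA", "MUFA", "PUFA")] -
        shares_prev[[h]][c("SFA", "MUFA", "PUFA")]
      dchol <- cholesterol_delta(d_sh, shares_prev[[h]],
                                 fx$nutrition$response)
      shift_distribution(dist[[h]], dchol)
    })
    shares_prev <- shares
    out$shares[[ys]] <- shares
    out$chol[[ys]] <- dist

    # --- clinical rates, demographic projection, outcome levels ---
    rates <- lapply(stats::setNames(nm = hhs), function(h)
      clin_rates(fx$lookups, dist[[h]], model$locations[h]))
    v <- vital_slice(fx$demog$rates, yr)
    if (mode == "policy") {
      exc_ref <- ref$excess[[ys]]
      for (h in hhs) {
        hi <- match(h, hhs)
        v$mu[hi, , ] <- apply_excess_feedback(
          v$mu[hi, , ],
          excess_mortality(rates[[h]], dist[[h]]$freq),
          exc_ref[[h]])
      }
    }
    pop <- project_year(pop, v)
    out$pop[[ys]] <- pop
    out$excess[[ys]] <- lapply(stats::setNames(nm = hhs), function(h)
      excess_mortality(rates[[h]], dist[[h]]$freq))

    levels <- array(0, dim = c(length(hhs), 2, length(AGE_GROUPS),
                               length(ILLNESSES)),
                    dimnames = list(hhs, GENDERS, AGE_GROUPS, ILLNESSES))
    for (h in hhs) {
      levels[h, , , ] <- clin_levels(rates[[h]], dist[[h]]$freq,
                                     pop[h, , ])
    }
    out$levels[[ys]] <- levels
    losses <- time_losses(levels, he)
    out$losses[[ys]] <- losses
    losses_prev <- losses

    lev_hi <- apply(levels[, , , c("MI-nf", "S-nf"), drop = FALSE],
                    c(1, 4), sum)
    lev_hist <- c(list(lev_hi), lev_hist)
    if (length(lev_hist) > 4) lev_hist <- lev_hist[1:4]
    out$hc[[ys]] <- health_costs(lev_hist, he, eq$GDPDEF, 1)
  }
  out
}

pipeline_closure <- function(mode, ref, ys) {
  if (mode == "counterfactual") return(default_closure())
  req <- ref$econ[[ys]]
  if (mode == "efficiency") {
    list(mode = "efficiency", g_rule = "real", g_real = req$GSCALE,
         c_real = sum(req$QC), tb_real = req$real_tb)
  } else {
    list(mode = "policy", g_rule = "real", g_real = req$GSCALE,
         c_real = NA_real_, tb_real = NA_real_)
  }
}

# Health-cost shocks for a policy run: policy-minus-counterfactual
# formal cost deltas from lagged level histories.
policy_hc_shocks <- function(lev_hist, ref, yr, he, trends) {
  if (length(lev_hist) == 0) return(list())
  gd <- ref$econ[[as.character(yr - 1)]]$GDPDEF
  pol <- health_costs(lev_hist, he, gd, 1)
  ref_hist <- lapply(seq_along(lev_hist), function(k)
    ref_level_sum(ref, yr - k))
  cnt <- health_costs(ref_hist, he, gd, 1)
  delta_shocks(pol, cnt)
}

ref_level_sum <- function(ref, yr) {
  lv <- ref$levels[[as.character(yr)]]
  apply(lv[, , , c("MI-nf", "S-nf"), drop = FALSE], c(1, 4), sum)
}

delta_shocks <- function(pol_hc, ref_hc) {
  if (is.null(pol_hc) || is.null(ref_hc)) return(list())
  list(hcp = rowSums(pol_hc$hcp) - rowSums(ref_hc$hcp),
       hcg = sum(pol_hc$hcg) - sum(ref_hc$hcg))
}

# ---------------------------------------------------------------------------
# Scenario runs and indicators

#' Run a policy scenario against its counterfactual
#'
#' Executes the full annual loop for the counterfactual and the policy
#' run, optionally adds the efficiency and health-pathway
#' decompositions, and assembles the indicator set of policy-minus-
#' counterfactual deltas.
#'
#' @param spec list with `counterfactual` (`"BaU"` or `"NITD"`),
#'   `edit` (see [tariff_edit()]), `years`, and `modes` (subset of
#'   `c("policy", "efficiency", "pathway")`).
#' @param model a `med_model`.
#' @param trends a `growth_trends` (from [calibrate_trends()]).
#' @return object of class `scenario_result`.
#' @export
run_scenario <- function(spec, model, trends) {
  p <- model$params
  years <- spec$years %||% 2016:2035
  modes <- spec$modes %||% "policy"
  nitd <- (spec$counterfactual %||% "BaU") == "NITD"
  tm_base <- if (nitd)
    stats::setNames(rep(0, length(p$sectors)), p$sectors) else p$tm0
  tm_pol <- tariff_edit(p, tm_base, spec$edit %||% list(type = "none"))

  # real government consumption follows the historically calibrated
  # (business-as-usual) growth path in every simulation, including the
  # no-tariff-distortion counterfactual
  g_path <- NULL
  if (nitd) {
    bau <- run_pipeline(model, trends, p$tm0, years, "counterfactual")
    g_path <- lapply(bau$econ, function(e) e$GSCALE)
  }
  count <- run_pipeline(model, trends, tm_base, years, "counterfactual",
                        g_path = g_path)
  policy <- run_pipeline(model, trends, tm_pol, years, "policy",
                         ref = count)
  eff <- path <- NULL
  if ("efficiency" %in% modes)
    eff <- efficiency_run(model, trends, tm_pol, years, count)
  if ("pathway" %in% modes)
    path <- health_pathway_valuation(model, trends, tm_base, years,
                                     count, policy)
  structure(list(spec = spec, years = years, count = count,
                 policy = policy, efficiency = eff, pathway = path,
                 indicators = scenario_indicators(model, count, policy,
                                                  eff, path)),
            class = "scenario_result")
}

#' Efficiency decomposition run
#'
#' Solves the policy tariffs under the efficiency closure: aggregate
#' real private consumption, real government consumption and the real
#' trade balance follow the counterfactual path, isolating the
#' production/investment-side efficiency effect in real GDP.
#'
#' @param model a `med_model`.
#' @param trends a `growth_trends`.
#' @param tm_pol policy tariff vector.
#' @param years simulation years.
#' @param count completed counterfactual run.
#' @return pipeline result (economy only).
#' @export
efficiency_run <- function(model, trends, tm_pol, years, count) {
  run_pipeline(model, trends, tm_pol, years, "efficiency", ref = count)
}

#' Health-pathway valuation run
#'
#' Values the health impacts of a policy by imposing only its labour
#' supply and formal health-cost deltas on the counterfactual economy,
#' without the underlying tariff instrument.
#'
#' @param model a `med_model`.
#' @param trends a `growth_trends`.
#' @param tm_base counterfactual tariff vector.
#' @param years simulation years.
#' @param count completed counterfactual run.
#' @param policy completed policy run supplying the health deltas.
#' @return pipeline result (economy only).
#' @export
health_pathway_valuation <- function(model, trends, tm_base, years,
                                     count, policy) {
  run_pipeline(model, trends, tm_base, years, "pathway", ref = count,
               exo = policy)
}

path_stat <- function(run, years, f) {
  vapply(as.character(years), function(ys) f(run, ys), numeric(1))
}

scenario_indicators <- function(model, count, policy, eff = NULL,
                                path = NULL) {
  fx <- model$fixtures
  usd <- fx$healthecon$usd_per_unit
  years <- count$years
  ys <- as.character(years)
  rg <- function(run) vapply(ys, function(y) run$econ[[y]]$RGDP,
                             numeric(1))
  d_rgdp <- sum(rg(policy) - rg(count))
  T_ <- ys[length(ys)]
  mean_share <- function(run, nm)
    mean(vapply(run$shares[[T_]], function(s) s[[nm]], numeric(1)))
  mean_chol <- function(run)
    mean(vapply(run$chol[[T_]], function(d) d$mean, numeric(1)))
  cum_lev <- function(run, ill)
    sum(vapply(ys, function(y) sum(run$levels[[y]][, , , ill]),
               numeric(1)))
  cum_pop <- function(run)
    sum(vapply(ys, function(y) sum(run$pop[[y]]), numeric(1)))
  cum_ls <- function(run)
    sum(vapply(ys, function(y) sum(run$ls_person[[y]]), numeric(1)))

  nf <- c("MI-nf", "S-nf"); fat <- c("MI-f", "S-f")
  base_pop <- cum_pop(count)
  base_ls <- cum_ls(count)
  ind <- list(
    cum_real_gdp = d_rgdp,
    cum_real_gdp_usd = d_rgdp * usd,
    sfa_share_pct = 100 * (mean_share(policy, "SFA") /
                             mean_share(count, "SFA") - 1),
    mufa_share_pct = 100 * (mean_share(policy, "MUFA") /
                              mean_share(count, "MUFA") - 1),
    pufa_share_pct = 100 * (mean_share(policy, "PUFA") /
                              mean_share(count, "PUFA") - 1),
    chol_pct = 100 * (mean_chol(policy) / mean_chol(count) - 1),
    incident_cases = cum_lev(policy, nf) - cum_lev(count, nf),
    premature_deaths = cum_lev(policy, fat) - cum_lev(count, fat),
    person_years = cum_pop(policy) - cum_pop(count),
    workforce_years = cum_ls(policy) - cum_ls(count),
    person_years_per_100k = (cum_pop(policy) - cum_pop(count)) /
      base_pop * 1e5,
    workforce_per_100k = (cum_ls(policy) - cum_ls(count)) /
      base_ls * 1e5,
    ghg_mt = policy$ghg_cum[[T_]] - count$ghg_cum[[T_]])
  if (!is.null(eff)) {
    d <- sum(vapply(ys, function(y) eff$econ[[y]]$RGDP, numeric(1)) -
               rg(count))
    ind$efficiency_real_gdp <- d
    ind$efficiency_real_gdp_usd <- d * usd
  }
  if (!is.null(path)) {
    d <- sum(vapply(ys, function(y) path$econ[[y]]$RGDP, numeric(1)) -
               rg(count))
    ind$pathway_real_gdp <- d
    ind$pathway_real_gdp_usd <- d * usd
  }
  ind
}

# ---------------------------------------------------------------------------
# Cost-effectiveness

#' Round a cost per person-year to reporting granularity
#'
#' Nearest 100,000 when the cost is at least 500,000; nearest 10,000
#' below that.
#'
#' @param x cost per person-year (currency units).
#' @return rounded value.
#' @export
round_cost <- function(x) {
  ifelse(abs(x) >= 5e5, round(x / 1e5) * 1e5, round(x / 1e4) * 1e4)
}

#' Cost-effectiveness of an intervention
#'
#' Cost per person-year saved, with an optional adjustment valuing
#' greenhouse-gas emission reductions at a carbon price.
#'
#' @param efficiency_loss economic efficiency loss (positive = loss),
#'   in currency units (USD).
#' @param person_years person-years saved (> 0).
#' @param ghg_mt greenhouse-gas emission reduction (Mt CO2-eq,
#'   positive = reduction).
#' @param carbon_price carbon valuation in currency units per tonne.
#' @param rounding rounding rule applied to reported costs.
#' @return object of class `ce_report`: raw and rounded cost per
#'   person-year, the GHG valuation, and the GHG-adjusted cost.
#' @export
cost_effectiveness <- function(efficiency_loss, person_years,
                               ghg_mt = 0, carbon_price = 100,
                               rounding = round_cost) {
  stop_if(person_years <= 0, "person-years saved must be positive")
  cost <- efficiency_loss / person_years
  ghg_value <- carbon_price * ghg_mt * 1e6
  adj <- (efficiency_loss - ghg_value) / person_years
  structure(list(efficiency_loss = efficiency_loss,
                 person_years = person_years,
                 cost_per_person_year = cost,
                 cost_per_person_year_rounded = rounding(cost),
                 ghg_mt = ghg_mt, carbon_price = carbon_price,
                 ghg_value = ghg_value,
                 adjusted_cost_per_person_year = adj,
                 adjusted_cost_per_person_year_rounded = rounding(adj)),
            class = "ce_report")
}

#' Write scenario results to disk
#'
#' Tidy indicator CSV, a JSON summary, and a run log.
#'
#' @param results named list of `scenario_result` objects.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
report <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(names(results), function(nm) {
    ind <- results[[nm]]$indicators
    if (length(ind) == 0) return(NULL)
    data.frame(scenario = nm, indicator = names(ind),
               value = as.numeric(unlist(ind)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(scenario = character(), indicator = character(),
                       value = numeric())
  utils::write.csv(rows, file.path(out_dir, "indicators.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(results, function(r) r$indicators),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  writeLines(c(sprintf("scenarios: %s", paste(names(results),
                                              collapse = ", ")),
               sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d"))),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
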