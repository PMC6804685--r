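# Scenario orchestration, closures, decompositions and reporting.

test_that("null scenario yields exactly zero deltas", {
  sc <- run_scenario(list(counterfactual = "BaU",
                          edit = list(type = "none"),
                          years = SHORT_YEARS,
                          modes = c("policy", "efficiency", "pathway")),
                     model_cached(), trends_cached())
  expect_true(all(unlist(sc$indicators) == 0))
})

test_that("scenario runs are deterministic", {
  spec <- list(counterfactual = "BaU",
               edit = list(type = "eliminate_food"), years = SHORT_YEARS)
  a <- run_scenario(spec, model_cached(), trends_cached())
  b <- run_scenario(spec, model_cached(), trends_cached())
  expect_identical(a$indicators, b$indicators)
})

test_that("tariff edits build the intended instrument vectors", {
  params <- model_cached()$params
  food <- tariffmed:::food_model_sectors()
  tm <- tariff_edit(params, params$tm0, list(type = "set_food", rate = 0.3))
  expect_true(all(tm[food] == 0.3))
  expect_equal(tm[setdiff(params$sectors, food)],
               params$tm0[setdiff(params$sectors, food)])
  tm2 <- tariff_edit(params, params$tm0, list(type = "eliminate_nonfood"))
  expect_true(all(tm2[setdiff(params$sectors, food)] == 0))
  tm3 <- tariff_edit(params, params$tm0,
                     list(type = "set_sector", sector = "beverages",
                          rate = 0.3))
  expect_equal(unname(tm3["beverages"]), 0.3)
  expect_equal(tm3[setdiff(params$sectors, "beverages")],
               params$tm0[setdiff(params$sectors, "beverages")])
  expect_error(tariff_edit(params, params$tm0,
                           list(type = "set_sector", sector = "nope")),
               "unknown sector")
})

test_that("30% food tariffs cut food imports against the NITD baseline", {
  sc <- run_scenario(list(counterfactual = "NITD",
                          edit = list(type = "set_food", rate = 0.3),
                          years = SHORT_YEARS), model_cached(),
                     trends_cached())
  params <- model_cached()$params
  food <- intersect(tariffmed:::food_model_sectors(), params$sectors)
  fi <- match(food, params$sectors)
  ys <- as.character(SHORT_YEARS[1])
  imp_pol <- sum((params$pwm * sc$policy$econ[[ys]]$QM)[fi])
  imp_cnt <- sum((params$pwm * sc$count$econ[[ys]]$QM)[fi])
  expect_lt(imp_pol, imp_cnt)
  # NITD counterfactual really has zero tariffs
  expect_true(all(sc$count$econ[[ys]]$tm == 0))
})

test_that("eliminate-all equals the NITD-vs-BaU twin-run difference", {
  model <- model_cached(); tr <- trends_cached()
  sc <- run_scenario(list(counterfactual = "BaU",
                          edit = list(type = "eliminate_all"),
                          years = SHORT_YEARS), model, tr)
  # independent assembly: the free-trade path simulated as a
  # counterfactual (same fiscal rule, but by construction without the
  # policy run's health-feedback channel)
  bau <- count_run_cached()
  nitd <- tariffmed:::run_pipeline(
    model, tr, setNames(rep(0, length(model$params$sectors)),
                        model$params$sectors),
    SHORT_YEARS, "counterfactual",
    g_path = lapply(bau$econ, function(e) e$GSCALE))
  for (ys in as.character(SHORT_YEARS)) {
    a <- sc$policy$econ[[ys]]$RGDP - sc$count$econ[[ys]]$RGDP
    b <- nitd$econ[[ys]]$RGDP - bau$econ[[ys]]$RGDP
    # the two assemblies differ only through the health feedback, a
    # second-order channel: agreement to 1% of the delta (and far
    # tighter relative to the GDP level)
    expect_lt(abs(a - b), max(0.01 * abs(b), 1e-4 * bau$econ[[ys]]$RGDP))
  }
})

test_that("efficiency closure pins real consumption, G and trade balance", {
  model <- model_cached(); tr <- trends_cached()
  count <- count_run_cached()
  tm <- tariff_edit(model$params, model$params$tm0,
                    list(type = "set_food", rate = 0.3))
  eff <- efficiency_run(model, tr, tm, SHORT_YEARS, count)
  for (ys in as.character(SHORT_YEARS)) {
    expect_lt(abs(sum(eff$econ[[ys]]$QC) - sum(count$econ[[ys]]$QC)) /
                sum(count$econ[[ys]]$QC), 1e-8)
    expect_equal(eff$econ[[ys]]$GSCALE, count$econ[[ys]]$GSCALE)
    expect_lt(abs(eff$econ[[ys]]$real_tb - count$econ[[ys]]$real_tb) /
                abs(count$econ[[ys]]$real_tb), 1e-8)
    expect_lt(abs(eff$econ[[ys]]$walras), 1e-8)
  }
  # a uniform distortionary tariff cannot raise efficiency real GDP
  d_eff <- sum(vapply(as.character(SHORT_YEARS),
                      function(y) eff$econ[[y]]$RGDP -
                        count$econ[[y]]$RGDP, numeric(1)))
  expect_lte(d_eff, 0)
})

test_that("health-pathway valuation is null without health deltas and
           locally linear in labour shocks", {
  model <- model_cached(); tr <- trends_cached()
  count <- count_run_cached()
  # null policy -> zero pathway effect
  pathway0 <- health_pathway_valuation(model, tr, model$params$tm0,
                                       SHORT_YEARS, count, count)
  for (ys in as.character(SHORT_YEARS))
    expect_equal(pathway0$econ[[ys]]$RGDP, count$econ[[ys]]$RGDP,
                 tolerance = 1e-12)
  # linearity and sign of a small planted labour-supply delta
  perturbed <- count
  ys1 <- as.character(SHORT_YEARS[1])
  rgdp_of <- function(scale) {
    pert <- count
    pert$ls_person <- lapply(count$ls_person, function(m) m * (1 + scale))
    run <- health_pathway_valuation(model, tr, model$params$tm0,
                                    SHORT_YEARS[1], count, pert)
    run$econ[[ys1]]$RGDP - count$econ[[ys1]]$RGDP
  }
  d1 <- rgdp_of(1e-3)
  d2 <- rgdp_of(2e-3)
  expect_gt(d1, 0)                      # more workers, more output
  expect_equal(d2 / d1, 2, tolerance = 0.02)
})

test_that("cost-effectiveness arithmetic and reporting round-trip", {
  ce <- cost_effectiveness(28.6e9, 55210)
  expect_equal(ce$cost_per_person_year_rounded, 5e5)
  ce2 <- cost_effectiveness(45.1e9, 128400, ghg_mt = 31.9,
                            carbon_price = 100)
  expect_equal(ce2$cost_per_person_year_rounded, 3.5e5)
  expect_equal(ce2$ghg_value, 3.19e9)
  expect_error(cost_effectiveness(1e9, 0), "positive")
  expect_equal(cost_effectiveness(0, 100)$cost_per_person_year, 0)

  # report: JSON summary re-reads to the in-memory indicators
  sc <- run_scenario(list(counterfactual = "BaU",
                          edit = list(type = "none"),
                          years = SHORT_YEARS), model_cached(),
                     trends_cached())
  dir <- file.path(tempdir(), "report-test")
  report(list(null = sc), dir)
  back <- jsonlite::read_json(file.path(dir, "summary.json"),
                              simplifyVector = TRUE)
  expect_equal(back$null$cum_real_gdp, sc$indicators$cum_real_gdp)
  csv <- read.csv(file.path(dir, "indicators.csv"))
  expect_true(all(c("scenario", "indicator", "value") %in% names(csv)))
  # empty result set -> header-only CSV
  report(list(), file.path(tempdir(), "report-empty"))
  empty <- read.csv(file.path(tempdir(), "report-empty",
                              "indicators.csv"))
  expect_equal(nrow(empty), 0)
})

test_that("food + non-food elimination deltas approximately compose to
           all-tariff elimination, with a reported residual", {
  model <- model_cached(); tr <- trends_cached()
  yrs <- SHORT_YEARS
  cum_delta <- function(edit) {
    sc <- run_scenario(list(counterfactual = "BaU", edit = edit,
                            years = yrs), model, tr)
    sc$indicators$cum_real_gdp
  }
  d_food <- cum_delta(list(type = "eliminate_food"))
  d_nonfood <- cum_delta(list(type = "eliminate_nonfood"))
  d_all <- cum_delta(list(type = "eliminate_all"))
  residual <- d_all - (d_food + d_nonfood)
  # interaction terms exist but must be second-order
  expect_lt(abs(residual), 0.2 * abs(d_all))
})

test_that("per-100k normalisation matches its definition", {
  sc <- run_scenario(list(counterfactual = "BaU",
                          edit = list(type = "eliminate_food"),
                          years = SHORT_YEARS), model_cached(),
                     trends_cached())
  cum_base <- sum(vapply(as.character(SHORT_YEARS),
                         function(y) sum(sc$count$pop[[y]]), numeric(1)))
  expect_equal(sc$indicators$person_years_per_100k,
               sc$indicators$person_years / cum_base * 1e5)
})
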