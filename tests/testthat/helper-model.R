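# Shared lazily-built fixtures: the default bundle, the calibrated
# model and a short-horizon trend calibration are expensive enough to
# build once per test run.

.cache <- new.env(parent = emptyenv())

fx_cached <- function() {
  if (is.null(.cache$fx)) .cache$fx <- make_fixtures()
  .cache$fx
}

model_cached <- function() {
  if (is.null(.cache$model)) .cache$model <- build_model(fx_cached())
  .cache$model
}

SHORT_YEARS <- 2016:2018

trends_cached <- function() {
  if (is.null(.cache$trends))
    .cache$trends <- calibrate_trends(model_cached(), years = SHORT_YEARS)
  .cache$trends
}

count_run_cached <- function() {
  if (is.null(.cache$count))
    .cache$count <- tariffmed:::run_pipeline(
      model_cached(), trends_cached(), model_cached()$params$tm0,
      SHORT_YEARS, "counterfactual")
  .cache$count
}

# A tiny self-contained demographic world for hand-computable cases.
toy_demog <- function(nA = 3, hh = "hh1", years = 2015:2017) {
  dn <- list(hh, c("male", "female"), paste0("a", seq_len(nA)),
             as.character(years))
  zero4 <- array(0, dim = c(1, 2, nA, length(years)), dimnames = dn)
  asfr <- matrix(0, nA, length(years),
                 dimnames = list(dn[[3]], dn[[4]]))
  list(sexratio = c(male = 0.5, female = 0.5), asfr = asfr,
       mu = zero4, migr = zero4, ptrans = zero4, years = years)
}

toy_pop <- function(nA = 3, vals = c(100, 80, 60)) {
  array(rep(vals, each = 2), dim = c(1, 2, nA),
        dimnames = list("hh1", c("male", "female"),
                        paste0("a", seq_len(nA))))
}
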