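# Cohort-component projection and dynamic transition calibration.

test_that("all-zero rates freeze the population; conveyor advances it", {
  pop <- toy_pop()
  v <- tariffmed::vital_slice(toy_demog(), 2016)
  expect_equal(project_year(pop, v), pop)
  # closed population, certain transition: whole cohorts advance
  v$ptrans[, , 1:2] <- 1
  out <- project_year(pop, v)
  expect_equal(sum(out), sum(pop))
  expect_equal(as.numeric(out[1, "male", ]), c(0, 100, 140))
})

test_that("two-year projection matches independent hand arithmetic", {
  pop <- toy_pop(vals = c(100, 80, 60))
  d <- toy_demog()
  d$mu[, , , ] <- 0.01
  d$migr[, , , ] <- 0.005
  d$ptrans[, , 1:2, ] <- 0.2
  d$asfr["a2", ] <- 0.08
  v <- tariffmed::vital_slice(d, 2016)
  # independent spreadsheet-style recursion, female column
  s <- (1 - 0.01) * (1 - 0.005)
  f <- c(100, 80, 60)
  births <- 0.08 * 80
  hand1 <- c((1 - 0.2) * s * f[1] + 0.5 * births,
             0.2 * s * f[1] + (1 - 0.2) * s * f[2],
             0.2 * s * f[2] + s * f[3])
  out1 <- project_year(pop, v)
  expect_equal(as.numeric(out1[1, "female", ]), hand1, tolerance = 1e-12)
  births2 <- 0.08 * hand1[2]
  hand2 <- c((1 - 0.2) * s * hand1[1] + 0.5 * births2,
             0.2 * s * hand1[1] + (1 - 0.2) * s * hand1[2],
             0.2 * s * hand1[2] + s * hand1[3])
  out2 <- project_year(out1, v)
  expect_equal(as.numeric(out2[1, "female", ]), hand2, tolerance = 1e-12)
})

test_that("population accounting identity holds on the fixture", {
  fx <- fx_cached()
  pop <- fx$demog$pop0
  v <- tariffmed::vital_slice(fx$demog$rates, 2016)
  out <- project_year(pop, v)
  fl <- tariffmed:::project_flows(pop, v)
  expect_equal(sum(out),
               sum(pop) - sum(fl$deaths) - sum(fl$migr) + sum(fl$births),
               tolerance = 1e-9)
})

test_that("transition calibration recovers planted probabilities", {
  fx <- fx_cached()
  res <- calibrate_transitions(fx$demog$pop0, fx$demog$target_path,
                               fx$demog$rates)
  planted <- fx$demog$rates$ptrans
  yrs <- as.character(2016:2035)
  nA <- length(AGE_GROUPS)
  expect_lt(max(abs(res$ptrans[, , -nA, yrs] - planted[, , -nA, yrs])),
            1e-8)
  expect_lt(res$terminal_residual, 1e-8)
  expect_equal(res$clamped, 0L)
})

test_that("stationary targets with zero rates imply zero transitions", {
  d <- toy_demog()
  pop <- toy_pop()
  tgt <- array(rep(pop, 3), dim = c(dim(pop), 3),
               dimnames = c(dimnames(pop), list(as.character(2015:2017))))
  res <- calibrate_transitions(pop, tgt, d)
  expect_true(all(res$ptrans[, , 1:2, c("2016", "2017")] == 0))
})

test_that("infeasible targets are clamped with a warning", {
  d <- toy_demog()
  pop <- toy_pop()
  tgt <- array(rep(pop, 3), dim = c(dim(pop), 3),
               dimnames = c(dimnames(pop), list(as.character(2015:2017))))
  tgt[1, 1, 1, 2] <- 500    # unreachable without negative exit
  expect_warning(res <- calibrate_transitions(pop, tgt, d), "clamped")
  expect_gt(res$clamped, 0)
})

test_that("excess-mortality feedback: null, additive, twin-run", {
  mu <- matrix(0.01, 2, 3)
  exc <- array(0.001, dim = c(2, 3, 2))
  expect_equal(apply_excess_feedback(mu, exc, exc), mu,
               ignore_attr = TRUE)
  exc2 <- exc
  exc2[1, 1, 1] <- exc2[1, 1, 1] + 0.001
  out <- apply_excess_feedback(mu, exc2, exc)
  expect_equal(out[1, 1], 0.011)
  expect_equal(out[2, 2], 0.01)
  # twin-run: person-years lost from a planted excess equals the
  # difference of two independent projections
  fx <- fx_cached()
  pop <- fx$demog$pop0
  v <- tariffmed::vital_slice(fx$demog$rates, 2016)
  v2 <- v
  v2$mu <- v$mu + 0.0005
  base <- project_year(pop, v)
  shocked <- project_year(pop, v2)
  # equivalent via apply_excess_feedback on each household slice
  v3 <- v
  for (h in seq_len(dim(pop)[1])) {
    excess_c <- array(0, dim = c(2, 15, 2))
    excess_p <- excess_c + 0.00025
    v3$mu[h, , ] <- apply_excess_feedback(v$mu[h, , ], excess_p,
                                          excess_c)
  }
  expect_equal(project_year(pop, v3), shocked, tolerance = 1e-12)
})
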