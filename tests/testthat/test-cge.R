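# CGE core: benchmark replication, analytic oracle, comparative
# statics, homogeneity, dynamics.

toy_cd_sam <- function(theta = c(0.3, 0.6), alpha = c(0.4, 0.6),
                       E = 100) {
  v <- alpha * E
  labv <- theta * v; capv <- (1 - theta) * v
  lab <- c("act.x1", "act.x2", "com.x1", "com.x2",
           "fac.uskl", "fac.cap", "hh.h")
  m <- matrix(0, 7, 7, dimnames = list(lab, lab))
  m["act.x1", "com.x1"] <- v[1]; m["act.x2", "com.x2"] <- v[2]
  m["fac.uskl", c("act.x1", "act.x2")] <- labv
  m["fac.cap", c("act.x1", "act.x2")] <- capv
  m["com.x1", "hh.h"] <- v[1]; m["com.x2", "hh.h"] <- v[2]
  m["hh.h", "fac.uskl"] <- sum(labv); m["hh.h", "fac.cap"] <- sum(capv)
  sam(m)
}

cd_elasticities <- function(n = 2, hh = "h") {
  secs <- paste0("x", seq_len(n))
  list(income = matrix(1, n, 1, dimnames = list(secs, hh)),
       price = array(-diag(n), dim = c(n, n, 1),
                     dimnames = list(secs, secs, hh)))
}

test_that("2x2 Cobb-Douglas economy matches its closed form to 1e-8", {
  theta <- c(0.3, 0.6); alpha <- c(0.4, 0.6)
  s <- toy_cd_sam(theta, alpha)
  params <- cge_calibrate(s, cd_elasticities(),
                          elasticities = list(top = 1, va = 1,
                                              armington = 1, cet = 1))
  st <- initial_state(params)
  # benchmark
  eq0 <- solve_period(params, st)
  expect_lt(max(abs(eq0$QA / params$QA0 - 1)), 1e-8)
  # shock: double the capital endowment
  st2 <- st; st2$K <- 2 * st$K
  eq <- solve_period(params, st2, start = eq0)
  # closed form: CD production, fixed expenditure shares
  L <- sum(params$LS0); K <- st2$K
  lsh <- sum(theta * alpha)                    # labour share of income
  L_a <- L * theta * alpha / lsh
  K_a <- K * (1 - theta) * alpha / (1 - lsh)
  L0 <- L * theta * alpha / lsh; K0 <- params$K0 * (1 - theta) * alpha /
    (1 - lsh)
  A_a <- (alpha * 100) / (L0^theta * K0^(1 - theta))
  X_a <- A_a * L_a^theta * K_a^(1 - theta)
  # price level pinned by the consumption-weighted numeraire
  E_star <- 1 / sum(alpha * alpha / X_a)       # cwts = alpha here
  p_a <- alpha * E_star / X_a
  expect_equal(as.numeric(eq$QA), X_a, tolerance = 1e-8)
  expect_equal(as.numeric(eq$PDS), p_a, tolerance = 1e-8)
  w_star <- lsh * E_star / L
  r_star <- (1 - lsh) * E_star / K
  expect_equal(unname(eq$WF[c("uskl", "cap")]), c(w_star, r_star),
               tolerance = 1e-8)
})

test_that("benchmark replication and Walras residual on the fixture", {
  params <- model_cached()$params
  eq <- solve_period(params, initial_state(params))
  expect_lt(max(abs(eq$QA / params$QA0 - 1)), 1e-8)
  expect_lt(max(abs(eq$PDS - 1)), 1e-8)
  expect_lt(abs(eq$walras), 1e-8)
  expect_equal(eq$RGDP, eq$NGDP, tolerance = 1e-10)
  expect_equal(eq$GDPDEF, 1, tolerance = 1e-10)
})

test_that("numeraire homogeneity: nominal scales, real invariant", {
  params <- model_cached()$params
  st <- initial_state(params)
  eq1 <- solve_period(params, st)
  st2 <- st; st2$cpi <- 1.7
  eq2 <- solve_period(params, st2, start = eq1)
  expect_equal(eq2$NGDP, 1.7 * eq1$NGDP, tolerance = 1e-9)
  expect_equal(eq2$RGDP, eq1$RGDP, tolerance = 1e-10)
  expect_equal(eq2$QA, eq1$QA, tolerance = 1e-10)
  expect_equal(eq2$PDS, 1.7 * eq1$PDS, tolerance = 1e-9)
  expect_equal(eq2$GDPDEF, 1.7 * eq1$GDPDEF, tolerance = 1e-9)
})

test_that("doubling all SAM flows doubles the nominal scale only", {
  fx <- fx_cached()
  s2 <- sam(2 * fx$sam_model$flows)
  p2 <- cge_calibrate(s2, fx$demand$elasticities)
  p1 <- model_cached()$params
  expect_equal(p2$tm0, p1$tm0, tolerance = 1e-12)
  eq2 <- solve_period(p2, initial_state(p2))
  eq1 <- solve_period(p1, initial_state(p1))
  expect_equal(eq2$PDS, eq1$PDS, tolerance = 1e-8)
  expect_equal(eq2$RGDP, 2 * eq1$RGDP, tolerance = 1e-8)
})

test_that("raising one tariff weakly reduces that import", {
  params <- model_cached()$params
  st <- initial_state(params)
  eq0 <- solve_period(params, st)
  for (j in c("beverages", "procfood")) {
    tm <- params$tm0
    tm[j] <- tm[j] + 0.10
    eq <- solve_period(params, st, tm = tm, start = eq0)
    expect_lt(eq$QM[match(j, params$sectors)],
              eq0$QM[match(j, params$sectors)] + 1e-10)
    expect_lt(abs(eq$walras), 1e-8)
  }
})

test_that("tariff elimination raises impact-year aggregate imports", {
  params <- model_cached()$params
  st <- initial_state(params)
  eq0 <- solve_period(params, st)
  tm <- params$tm0; tm[] <- 0
  eq <- solve_period(params, st, tm = tm, start = eq0)
  expect_gt(sum(params$pwm * eq$QM), sum(params$pwm * eq0$QM))
})

test_that("capital accumulation: conservation and boundary cases", {
  params <- model_cached()$params
  st <- initial_state(params)
  eq <- solve_period(params, st)
  eq_no_inv <- eq; eq_no_inv$QINV <- 0 * eq$QINV
  expect_equal(advance(st, eq_no_inv, depreciation = 0)$K, st$K)
  expect_equal(advance(st, eq_no_inv, depreciation = 1)$K, 0)
  expect_equal(advance(st, eq, depreciation = 0.05)$K,
               0.95 * st$K + sum(eq$QINV))
})

test_that("null growth targets give a flat path; planted trend recovered", {
  model <- model_cached()
  tr0 <- dynamic_calibrate(model$params, model$state0,
                           ls_path = NULL, years = 2016,
                           real_growth = 0, nominal_growth = 0)
  expect_equal(tr0$rgdp[["2016"]], tr0$rgdp[["2015"]], tolerance = 1e-7)
  expect_equal(tr0$ngdp[["2016"]], tr0$ngdp[["2015"]], tolerance = 1e-9)
  # plant a productivity factor, measure its growth, recover it
  st <- model$state0
  eq0 <- solve_period(model$params, st)
  st1 <- advance(st, eq0)
  st1$A <- 1.03
  eq1 <- solve_period(model$params, st1, start = eq0)
  g_true <- eq1$RGDP / eq0$RGDP - 1
  tr <- dynamic_calibrate(model$params, model$state0, ls_path = NULL,
                          years = 2016, real_growth = g_true,
                          nominal_growth = g_true)
  expect_equal(tr$A[["2016"]], 1.03, tolerance = 1e-5)
})
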