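# AIDS demand systems and nutrition transmission.

# A 3-commodity system whose elasticities already satisfy the AIDS
# restrictions, so calibration is projection-free and must reproduce
# them exactly.
consistent_system <- function() {
  w0 <- c(a = 0.5, b = 0.3, c = 0.2)
  gamma <- matrix(c(0.10, -0.06, -0.04,
                    -0.06, 0.09, -0.03,
                    -0.04, -0.03, 0.07), 3, 3, byrow = TRUE)
  beta <- c(0.05, -0.02, -0.03)
  eta <- 1 + beta / w0
  eps <- sweep(gamma, 1, w0, "/") - diag(3)
  list(w0 = w0, beta = beta, gamma = gamma, eta = eta, eps = eps)
}

test_that("calibration reproduces supplied elasticities (FD oracle)", {
  s <- consistent_system()
  ds <- aids_calibrate(s$w0, s$eta, s$eps)
  expect_equal(ds$beta, s$beta, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ds$gamma, s$gamma, tolerance = 1e-10, ignore_attr = TRUE)
  el <- tariffmed:::aids_elasticities(ds, rep(1, 3), 1, 1)
  expect_equal(el$income, s$eta, tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(el$price, s$eps, tolerance = 1e-5, ignore_attr = TRUE)
  # base point returns base shares exactly
  expect_equal(aids_shares(ds, rep(1, 3), 1, 1), s$w0,
               tolerance = 1e-14)
})

test_that("homothetic calibration yields zero expenditure coefficients", {
  w0 <- c(a = 0.4, b = 0.6)
  ds <- aids_calibrate(w0, c(1, 1), matrix(c(-1, 0, 0, -1), 2))
  expect_equal(ds$beta, c(0, 0), ignore_attr = TRUE)
})

test_that("adding-up, homogeneity and Engel aggregation hold everywhere", {
  fx <- fx_cached()
  params <- model_cached()$params
  set.seed(42)
  for (k in 1:20) {
    h <- sample(length(params$households), 1)
    ds <- params$demand[[h]]
    p <- exp(runif(length(ds$alpha), -0.3, 0.3))
    e <- params$e0[h] * exp(runif(1, -0.3, 0.3))
    P <- exp(runif(1, -0.2, 0.2))
    w <- aids_shares(ds, p, e, P)
    x <- aids_demand(ds, p, e, P)
    expect_lt(abs(sum(w) - 1), 1e-10)
    expect_lt(abs(sum(p * x) - e) / e, 1e-10)
    lam <- 1.7
    expect_equal(aids_demand(ds, lam * p, lam * e, lam * P), x,
                 tolerance = 1e-12)
  }
})

test_that("homothetic demands match the translog dual (duality oracle)", {
  skip_if_not_installed("numDeriv")
  s <- consistent_system()
  ds <- aids_calibrate(s$w0, rep(1, 3), s$eps)   # beta = 0
  p <- c(1.10, 0.95, 1.00)                        # 10% price rise in good 1
  u <- 2.3
  logP <- function(p) sum(ds$alpha * log(p)) +
    0.5 * as.numeric(log(p) %*% ds$gamma %*% log(p))
  cost <- function(p) u * exp(logP(p))
  x_shephard <- numDeriv::grad(cost, p)
  x_pkg <- aids_demand(ds, p, cost(p), 1)
  expect_equal(x_pkg, x_shephard, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("out-of-region shares are clipped with a warning", {
  w0 <- c(a = 0.05, b = 0.95)
  eps <- matrix(c(-8, 0, 0.4, -1), 2, 2, byrow = TRUE)
  ds <- aids_calibrate(w0, c(1, 1), eps)
  expect_warning(w <- aids_shares(ds, c(3, 1), 1, 1), "regular region")
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1)
})

test_that("zero base share with nonzero elasticity is rejected", {
  expect_error(
    aids_calibrate(c(a = 0, b = 1), c(1, 1), matrix(c(-1, 0, 0, -1), 2)),
    "zero base share")
})

# --- nutrition -------------------------------------------------------------

nut3 <- rbind(x = c(10, 2, 1, 1), y = c(5, 0, 2, 0.5),
              z = c(8, 0, 0, 0))
colnames(nut3) <- c("total", "SFA", "MUFA", "PUFA")

test_that("intake shares: saturation, scale invariance, hand example", {
  one <- rbind(x = c(4, 4, 0, 0))
  colnames(one) <- colnames(nut3)
  expect_equal(intake_shares(c(x = 2), one)[["SFA"]], 1)
  x <- c(x = 1, y = 2, z = 0.5)
  sh <- intake_shares(x, nut3)
  expect_equal(intake_shares(2 * x, nut3)[1:3], sh[1:3])
  # hand arithmetic
  tot <- 10 * 1 + 5 * 2 + 8 * 0.5
  expect_equal(sh[["SFA"]], 2 / tot)
  expect_equal(sh[["MUFA"]], (1 + 4) / tot)
  expect_equal(sh[["PUFA"]], (1 + 1) / tot)
  expect_error(intake_shares(c(x = 0, y = 0, z = 0), nut3), "zero total")
})

test_that("cholesterol build-up arithmetic and sign structure", {
  resp <- c(SFA = 0.3, MUFA = -2.6, PUFA = -3.2)
  lv <- c(SFA = 0.10, MUFA = 0.12, PUFA = 0.05)
  expect_equal(cholesterol_delta(c(SFA = 0, MUFA = 0, PUFA = 0), lv, resp),
               0)
  d <- c(SFA = 0, MUFA = 0, PUFA = 0.01)
  expect_lt(cholesterol_delta(d, lv, resp), 0)
  d2 <- c(SFA = 0.004, MUFA = -0.002, PUFA = 0.001)
  hand <- 0.3 * 0.004 + (-2.6) * (0.12 / 0.27) * (-0.002) +
    (-3.2) * 0.001
  expect_equal(cholesterol_delta(d2, lv, resp), hand, tolerance = 1e-12)
  lin <- 0.3 * 0.004 + (-2.6) * (-0.002) + (-3.2) * 0.001
  expect_equal(cholesterol_delta(d2, lv, resp, mufa_term = "linear"),
               lin, tolerance = 1e-12)
})

test_that("distribution shifting conserves mass, clamps and reverses", {
  b <- biomarker_distribution(4, rep(0.1, 10))
  expect_equal(shift_distribution(b, 0), b)
  s <- shift_distribution(b, 0.2)
  expect_equal(s$freq, b$freq)
  expect_equal(shift_distribution(s, -0.2)$values, b$values)
  big <- shift_distribution(b, 10)
  expect_true(all(big$values == 7))
  expect_equal(sum(big$freq), 1)
})
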