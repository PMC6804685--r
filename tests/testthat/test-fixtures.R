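# Synthetic fixture generator: share-target fidelity, determinism,
# internal consistency of every component.

test_that("generated SAM hits every sectoral share target within 0.05pp", {
  fx <- fx_cached()
  coarse <- sam_aggregate(fx$sam, fx$maps$fine_coarse)
  sh <- sam_structure_shares(coarse)
  tg <- table1_targets()
  m <- match(tg$sector, sh$sector)
  tol <- 5e-4 + 1e-12
  expect_true(all(abs(sh$impshr[m] - tg$impshr) <= tol))
  expect_true(all(abs(sh$expshr[m] - tg$expshr) <= tol))
  expect_true(all(abs(sh$tariff[m] - tg$tariff) <= tol))
  expect_true(all(abs(sh$salesshr[m] - tg$salesshr) <= tol))
  expect_true(all(abs(sh$hhshr[m] - tg$hhshr) <= tol))
  # tariff revenue cells equal rate x import value, per fine sector
  f <- fx$sam$flows
  com <- sam_accounts(fx$sam, "com")
  mims <- f["row", com]; trs <- f["gov", com]
  crs <- fx$maps$fine_coarse$coarse[match(sub("^com\\.", "", com),
                                          fx$maps$fine_coarse$fine)]
  expect_equal(trs, mims * tg$tariff[match(crs, tg$sector)],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("fixture generation is a pure function of the seed", {
  a <- make_fixtures(seed = 123)
  b <- make_fixtures(seed = 123)
  expect_identical(a, b)
  c_ <- make_fixtures(seed = 124)
  expect_false(identical(a$sam$flows, c_$sam$flows))
})

test_that("generated SAMs are balanced and non-negative", {
  fx <- fx_cached()
  expect_lt(sam_imbalance(fx$sam), 1e-9)
  expect_lt(sam_imbalance(fx$sam_model), 1e-9)
  expect_true(all(fx$sam$flows >= 0))
})

test_that("infeasible share targets are rejected", {
  tg <- table1_targets()
  tg$salesshr[1] <- tg$salesshr[1] + 0.05      # sums to 105%
  expect_error(make_fixtures(targets = tg), "infeasible")
  tg2 <- table1_targets()
  tg2$impshr[2] <- 1.2
  expect_error(make_fixtures(targets = tg2), "out of range")
})

test_that("fixture components satisfy their invariants", {
  fx <- fx_cached()
  for (h in names(fx$nutrition$table)) {
    m <- fx$nutrition$table[[h]]
    expect_true(all(m >= 0))
    expect_true(all(m[, "SFA"] + m[, "MUFA"] + m[, "PUFA"] <=
                      m[, "total"] + 1e-12))
  }
  for (h in names(fx$biomarkers)) {
    b <- fx$biomarkers[[h]]
    expect_equal(sum(b$freq), 1, tolerance = 1e-12)
    expect_true(all(b$freq >= 0))
    expect_equal(b$values, seq(2.25, 6.75, by = 0.5))
  }
  expect_true(all(fx$demog$pop0 >= 0))
  r <- fx$demog$rates
  for (nm in c("mu", "migr", "ptrans"))
    expect_true(all(r[[nm]] >= 0 & r[[nm]] <= 1))
  expect_equal(sum(r$sexratio), 1)
  # emission coefficients antisymmetric with zero diagonal
  ec <- fx$luc$emiss_coef
  expect_equal(ec, -t(ec))
  expect_true(all(diag(ec) == 0))
})

test_that("fixture bundle round-trips through its CSV directory", {
  fx <- fx_cached()
  dir <- file.path(tempdir(), "fx-roundtrip")
  unlink(dir, recursive = TRUE)
  write_fixtures(fx, dir)
  back <- read_fixtures(dir)
  expect_identical(back$sam$flows, fx$sam$flows)
  expect_equal(back$demand$elasticities$income,
               fx$demand$elasticities$income, ignore_attr = TRUE)
  expect_equal(back$lookups$coefs, fx$lookups$coefs,
               ignore_attr = TRUE)
  expect_equal(back$demog$target_path, fx$demog$target_path,
               ignore_attr = TRUE)
  expect_equal(back$healthecon$huc, fx$healthecon$huc,
               ignore_attr = TRUE)
  # tampering is caught by the manifest checksums
  p <- file.path(dir, "biomarkers.csv")
  writeLines(c(readLines(p), "tamper"), p)
  expect_error(read_fixtures(dir), "checksum")
})
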