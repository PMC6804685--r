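# Synthetic-economy fixture generator.
#
# Builds a complete, internally consistent stand-in for the data a
# middle-income-country diet/health CGE study needs: a balanced
# multi-sector SAM hitting published sectoral trade/tariff share
# targets, household demand elasticities, nutrient and cholesterol
# response coefficients, biomarker distributions, clinical outcome
# lookups, a demographic baseline with vital rates, health-economic
# parameters and land-use-change emission coefficients.  Everything is
# a pure function of (seed, targets).

MODEL_SECTORS <- c("rice", "maize", "cassava", "sugarcane", "oilpalm",
                   "fruitveg", "rubber", "opother", "palmoil", "othoils",
                   "procfood", "beverages", "manuf", "services")
CROP_SECTORS <- c("rice", "maize", "cassava", "sugarcane", "oilpalm",
                  "fruitveg", "rubber")
COARSE_SECTORS <- c("primfood", "othprim", "palmoil", "othoils",
                    "procfood", "beverages", "manuf", "services")
FOOD_COARSE <- c("primfood", "palmoil", "othoils", "procfood", "beverages")
MODEL_TO_COARSE <- c(rice = "primfood", maize = "primfood",
                     cassava = "primfood", sugarcane = "primfood",
                     oilpalm = "primfood", fruitveg = "primfood",
                     rubber = "othprim", opother = "othprim",
                     palmoil = "palmoil", othoils = "othoils",
                     procfood = "procfood", beverages = "beverages",
                     manuf = "manuf", services = "services")
HOUSEHOLDS <- c("bkk", "c_ur", "c_ru", "n_ur", "n_ru",
                "ne_ur", "ne_ru", "s_ur", "s_ru")
RURAL_HH <- c("c_ru", "n_ru", "ne_ru", "s_ru")
LAND_REGIONS <- c("ce", "n", "ne", "s")
AGE_GROUPS <- c("0-4", "5-9", "10-14", "15-19", "20-24", "25-29",
                "30-34", "35-39", "40-44", "45-49", "50-54", "55-59",
                "60-64", "65-69", "70+")
GENDERS <- c("male", "female")
ILLNESSES <- c("MI-nf", "S-nf", "MI-f", "S-f")
WORKING_AGES <- AGE_GROUPS[4:13]         # 15-64
FERTILE_AGES <- AGE_GROUPS[4:10]         # 15-49
CHOL_RANGE <- c(2.0, 7.0)
N_STRATA <- 10L

# Fine (49-sector) detail: invented labels under each model sector.
FINE_UNDER_MODEL <- list(
  rice = "rice", maize = "maize", cassava = "cassava",
  sugarcane = "sugarcane", oilpalm = "oilpalm", fruitveg = "fruitveg",
  rubber = "rubber",
  opother = c("op.livestock", "op.fisheries", "op.forestry",
              "op.mining", "op.othercrops"),
  palmoil = "palmoil",
  othoils = c("oil.soybean", "oil.coconut"),
  procfood = c("pf.milling", "pf.fishprep", "pf.fruitprep", "pf.meatprep",
               "pf.sugar", "pf.bakery", "pf.noodles", "pf.dairy",
               "pf.confection", "pf.othfood"),
  beverages = c("bev.alcoholic", "bev.soft"),
  manuf = c("mf.textiles", "mf.garments", "mf.leather", "mf.wood",
            "mf.paper", "mf.chemicals", "mf.plastics", "mf.petroleum",
            "mf.cement", "mf.metals", "mf.machinery", "mf.electronics",
            "mf.vehicles", "mf.othmanuf"),
  services = c("sv.utilities", "sv.construction", "sv.trade",
               "sv.transport", "sv.finance", "sv.realestate",
               "sv.public", "sv.othservices"))

#' Sectoral share targets for the synthetic economy
#'
#' Published structure of the eight aggregate sectors: import share of
#' domestic sales, export share of production, import tariff rate,
#' share in domestic sales, and share in household consumption (all as
#' fractions), plus a food flag.
#'
#' @return data.frame with one row per coarse sector.
#' @export
table1_targets <- function() {
  data.frame(
    sector = COARSE_SECTORS,
    impshr  = c(0.053, 0.045, 0.031, 0.289, 0.104, 0.145, 0.391, 0.112),
    expshr  = c(0.034, 0.061, 0.118, 0.209, 0.431, 0.098, 0.679, 0.138),
    tariff  = c(0.014, 0.003, 0.000, 0.002, 0.028, 0.227, 0.016, 0.000),
    salesshr = c(0.035, 0.022, 0.002, 0.001, 0.059, 0.018, 0.471, 0.393),
    hhshr   = c(0.049, 0.012, 0.004, 0.001, 0.080, 0.058, 0.281, 0.516),
    food    = COARSE_SECTORS %in% FOOD_COARSE,
    stringsAsFactors = FALSE)
}

# Make a share vector sum exactly to 1 while moving no single share by
# more than `cap` (default 0.05 percentage points): the printed targets
# carry rounding error of that order.  The excess is taken from (or
# added to) the largest shares in steps of at most `cap`.
normalize_shares <- function(x, cap = 5e-4, what = "share") {
  excess <- sum(x) - 1
  stop_if(abs(excess) > length(x) * cap,
          "infeasible %s targets: sum %.4f not within rounding of 1",
          what, sum(x))
  ord <- order(x, decreasing = TRUE)
  for (i in ord) {
    if (abs(excess) < 1e-15) break
    step <- sign(excess) * min(cap, abs(excess))
    x[i] <- x[i] - step
    excess <- excess - step
  }
  x
}

#' Sector maps of the synthetic economy
#'
#' @return list with `fine_coarse` (49 to 8), `fine_model` (49 to 14)
#'   and `model_coarse` (14 to 8) [sector_map()]s; food sectors are
#'   flagged on the coarse maps.
#' @export
fixture_sector_maps <- function() {
  fine <- unlist(FINE_UNDER_MODEL, use.names = FALSE)
  parent <- rep(names(FINE_UNDER_MODEL),
                lengths(FINE_UNDER_MODEL))
  list(
    fine_model = sector_map(fine, parent),
    fine_coarse = sector_map(fine, unname(MODEL_TO_COARSE[parent]),
                             food = FOOD_COARSE),
    model_coarse = sector_map(MODEL_SECTORS,
                              unname(MODEL_TO_COARSE[MODEL_SECTORS]),
                              food = FOOD_COARSE))
}

# ---------------------------------------------------------------------------
# SAM construction

build_model_sam <- function(targets, rng_draws) {
  tg <- targets
  tg$salesshr <- normalize_shares(tg$salesshr, what = "sales share")
  tg$hhshr <- normalize_shares(tg$hhshr, what = "household share")
  stop_if(any(tg$impshr < 0 | tg$impshr >= 1 | tg$expshr < 0 |
                tg$expshr >= 1 | tg$tariff < 0),
          "infeasible share targets: rates out of range")
  rownames(tg) <- tg$sector

  TS <- 10000                           # total domestic sales, currency units
  d <- rng_draws

  # Model-level sectoral table: split primfood over the six crops and
  # othprim over rubber / rest; rates are inherited from the coarse sector.
  salesw_pf <- d$salesw_pf
  salesw_op <- d$salesw_op
  msec <- data.frame(sector = MODEL_SECTORS, stringsAsFactors = FALSE)
  rownames(msec) <- MODEL_SECTORS
  coarse_of <- MODEL_TO_COARSE[MODEL_SECTORS]
  for (cl in c("impshr", "expshr", "tariff")) {
    msec[[cl]] <- tg[coarse_of, cl]
  }
  msec$salesshr <- tg[coarse_of, "salesshr"] *
    ifelse(coarse_of == "primfood", salesw_pf[MODEL_SECTORS],
    ifelse(coarse_of == "othprim", salesw_op[MODEL_SECTORS], 1))
  msec$hhshr <- tg[coarse_of, "hhshr"] *
    ifelse(coarse_of == "primfood", d$hhw_pf[MODEL_SECTORS],
    ifelse(coarse_of == "othprim", d$hhw_op[MODEL_SECTORS], 1))

  msec$sales <- msec$salesshr * TS
  msec$M <- msec$impshr * msec$sales
  msec$TR <- msec$tariff * msec$M
  msec$QD <- msec$sales - msec$M
  stop_if(any(msec$QD <= 0), "infeasible targets: import share >= sales")
  msec$X <- msec$QD / (1 - msec$expshr)
  msec$E <- msec$expshr * msec$X

  va_share <- c(rice = 0.55, maize = 0.55, cassava = 0.55,
                sugarcane = 0.50, oilpalm = 0.55, fruitveg = 0.60,
                rubber = 0.55, opother = 0.60, palmoil = 0.35,
                othoils = 0.30, procfood = 0.35, beverages = 0.40,
                manuf = 0.35, services = 0.60)
  msec$VA <- va_share[MODEL_SECTORS] * msec$X
  msec$INT <- msec$X - msec$VA

  absorption <- msec$sales + msec$TR
  F_tot <- sum(absorption) - sum(msec$INT)
  stop_if(F_tot <= 0, "infeasible targets: no room for final demand")
  C_tot <- 0.70 * F_tot
  G_tot <- 0.18 * F_tot
  I_tot <- 0.12 * F_tot

  Cc <- msec$hhshr * C_tot
  Gc <- stats::setNames(numeric(14), MODEL_SECTORS)
  Gc[c("services", "manuf", "procfood")] <- G_tot * c(0.85, 0.10, 0.05)
  Ic <- stats::setNames(numeric(14), MODEL_SECTORS)
  Ic[c("manuf", "services")] <- I_tot * c(0.55, 0.45)

  int_row <- absorption - Cc - Gc - Ic   # intermediate demand per commodity
  stop_if(any(int_row < 0),
          "infeasible targets: negative residual intermediate demand")
  io <- ras(d$io_prior * (int_row %o% msec$INT) / sum(int_row),
            int_row, msec$INT, tol = 1e-11, max_iter = 20000)$m
  dimnames(io) <- list(MODEL_SECTORS, MODEL_SECTORS)

  # Factor payments per activity.
  fac <- c("fac.uskl", "fac.skl", "fac.cap",
           paste0("fac.land.", LAND_REGIONS))
  FD <- matrix(0, length(fac), 14, dimnames = list(fac, MODEL_SECTORS))
  for (s in MODEL_SECTORS) {
    va <- msec[s, "VA"]
    if (s %in% CROP_SECTORS) {
      land <- 0.30 * va
      FD[paste0("fac.land.", LAND_REGIONS), s] <- land * d$landw[[s]]
      FD["fac.uskl", s] <- 0.40 * va
      FD["fac.skl", s] <- 0.05 * va
      FD["fac.cap", s] <- 0.25 * va
    } else {
      sp <- switch(s,
                   opother = c(0.40, 0.10, 0.50),
                   services = c(0.25, 0.35, 0.40),
                   c(0.30, 0.15, 0.55))
      FD[c("fac.uskl", "fac.skl", "fac.cap"), s] <- sp * va
    }
  }

  # Institutions.
  VA_tot <- sum(msec$VA)
  capinc <- sum(FD["fac.cap", ])
  tau <- 0.10
  sbar <- 0.30
  repat_need <- VA_tot - C_tot / ((1 - sbar) * (1 - tau))
  repat <- min(0.85 * capinc, max(0, repat_need))

  hhinc <- matrix(0, length(HOUSEHOLDS), length(fac),
                  dimnames = list(paste0("hh.", HOUSEHOLDS), fac))
  hhinc[, "fac.uskl"] <- d$usklw * sum(FD["fac.uskl", ])
  hhinc[, "fac.skl"] <- d$sklw * sum(FD["fac.skl", ])
  hhinc[, "fac.cap"] <- d$capw * (capinc - repat)
  for (r in LAND_REGIONS) {
    f <- paste0("fac.land.", r)
    hh_r <- switch(r, ce = c("c_ru", "c_ur"), n = c("n_ru", "n_ur"),
                   ne = c("ne_ru", "ne_ur"), s = c("s_ru", "s_ur"))
    hhinc[paste0("hh.", hh_r), f] <- sum(FD[f, ]) * c(0.8, 0.2)
  }
  Y <- rowSums(hhinc)
  tax <- tau * Y
  sav_need <- (1 - tau) * (VA_tot - repat) - C_tot
  stop_if(sav_need < 0, "infeasible targets: negative aggregate saving")
  s0 <- stats::setNames(
    c(0.35, 0.30, 0.25, 0.30, 0.25, 0.30, 0.25, 0.30, 0.25),
    paste0("hh.", HOUSEHOLDS))
  kappa <- sav_need / sum(s0 * (1 - tau) * Y)
  stop_if(any(kappa * s0 >= 0.95), "implied household savings rate >= 95%")
  sav <- kappa * s0 * (1 - tau) * Y
  Ch <- (1 - tau) * Y - sav

  # Household consumption matrix (commodities x households) via RAS on a
  # taste-shifted proportional prior.
  prior <- (Cc %o% Ch) / sum(Cc) * d$taste
  cons <- ras(prior, Cc, Ch, tol = 1e-11, max_iter = 20000)$m
  dimnames(cons) <- list(MODEL_SECTORS, paste0("hh.", HOUSEHOLDS))

  rev <- sum(tax) + sum(msec$TR)
  gsav <- rev - G_tot
  nl <- sum(msec$E) - sum(msec$M) - repat   # net lending abroad via s-i

  acc <- c(paste0("act.", MODEL_SECTORS), paste0("com.", MODEL_SECTORS),
           fac, paste0("hh.", HOUSEHOLDS), "gov", "s-i", "row")
  fl <- matrix(0, length(acc), length(acc), dimnames = list(acc, acc))
  act <- paste0("act.", MODEL_SECTORS)
  com <- paste0("com.", MODEL_SECTORS)
  fl[cbind(act, com)] <- msec$QD
  fl[act, "row"] <- msec$E
  fl[com, act] <- io
  fl[fac, act] <- FD
  fl[com, paste0("hh.", HOUSEHOLDS)] <- cons
  fl[com, "gov"] <- Gc
  fl[com, "s-i"] <- Ic
  fl["row", com] <- msec$M
  fl["gov", com] <- msec$TR
  fl[paste0("hh.", HOUSEHOLDS), fac] <- hhinc
  fl["row", "fac.cap"] <- repat
  fl["gov", paste0("hh.", HOUSEHOLDS)] <- tax
  fl["s-i", paste0("hh.", HOUSEHOLDS)] <- sav
  if (gsav >= 0) fl["s-i", "gov"] <- gsav else fl["gov", "s-i"] <- -gsav
  if (nl >= 0) fl["row", "s-i"] <- nl else fl["s-i", "row"] <- -nl

  list(sam = sam(fl, tol = 1e-9), msec = msec, tg = tg,
       tau = tau, repat = repat)
}

# Expand the 14-sector model SAM to the 49-sector fine SAM: each
# compound sector's activity and commodity account is split with one
# weight vector applied to both, so every within-group share (tariff
# rate, import share, ...) is inherited exactly.
expand_to_fine <- function(model_sam, finew) {
  f <- model_sam$flows
  lab <- rownames(f)
  parent <- lab
  w <- rep(1, length(lab))
  out_lab <- character(0); out_par <- integer(0); out_w <- numeric(0)
  for (i in seq_along(lab)) {
    cls <- account_class(lab[i])
    if (cls %in% c("act", "com")) {
      bare <- sub("^(act|com)\\.", "", lab[i])
      kids <- FINE_UNDER_MODEL[[bare]]
      ww <- if (length(kids) == 1) 1 else finew[[bare]]
      out_lab <- c(out_lab, paste0(substr(lab[i], 1, 4), kids))
      out_par <- c(out_par, rep(i, length(kids)))
      out_w <- c(out_w, ww)
    } else {
      out_lab <- c(out_lab, lab[i])
      out_par <- c(out_par, i)
      out_w <- c(out_w, 1)
    }
  }
  ff <- f[out_par, out_par] * (out_w %o% out_w)
  dimnames(ff) <- list(out_lab, out_lab)
  sam(ff, tol = 1e-9)
}

# ---------------------------------------------------------------------------
# Non-SAM fixture components

fixture_demography <- function(d) {
  H <- HOUSEHOLDS; G <- GENDERS; A <- AGE_GROUPS
  years <- 2015:2035
  hh_tot <- c(bkk = 11, c_ur = 4.5, c_ru = 7, n_ur = 3, n_ru = 7.5,
              ne_ur = 4.5, ne_ru = 15, s_ur = 3.5, s_ru = 8) * 1e6
  age_w <- c(5.5, 5.8, 6.2, 6.6, 7.2, 7.6, 7.8, 7.9, 7.7, 7.3,
             6.6, 5.6, 4.6, 3.5, 5.1)
  age_w <- age_w / sum(age_w)
  pop0 <- array(0, dim = c(length(H), length(G), length(A)),
                dimnames = list(H, G, A))
  for (h in seq_along(H)) {
    shape <- age_w * d$age_noise[h, ]
    shape <- shape / sum(shape)
    pop0[h, "male", ] <- hh_tot[h] * 0.49 * shape
    pop0[h, "female", ] <- hh_tot[h] * 0.51 * shape
  }

  mu_base <- c(0.0020, 0.0003, 0.0003, 0.0008, 0.0010, 0.0012, 0.0015,
               0.0020, 0.0030, 0.0045, 0.0070, 0.0110, 0.0170, 0.0270,
               0.0700)
  mu <- array(0, dim = c(length(H), length(G), length(A), length(years)),
              dimnames = list(H, G, A, years))
  migr <- array(0, dim = dim(mu), dimnames = dimnames(mu))
  for (t in seq_along(years)) {
    tr <- 0.995^(t - 1)
    for (h in seq_along(H)) {
      mu[h, "male", , t] <- mu_base * tr
      mu[h, "female", , t] <- mu_base * 0.65 * tr
      if (H[h] %in% RURAL_HH) migr[h, , 4:8, t] <- 0.0005
    }
  }

  asfr <- matrix(0, length(A), length(years), dimnames = list(A, years))
  asfr[FERTILE_AGES, ] <- outer(c(0.035, 0.080, 0.090, 0.060, 0.025,
                                  0.006, 0.0005),
                                0.997^(seq_along(years) - 1))
  sexratio <- c(male = 0.513, female = 0.487)

  ptrans <- array(0.2, dim = dim(mu), dimnames = dimnames(mu))
  wiggle <- 0.2 + d$ptrans_noise        # planted, time-constant
  for (t in seq_along(years)) ptrans[, , , t] <- wiggle
  ptrans[, , length(A), ] <- 0           # terminal group has no exit

  rates <- list(sexratio = sexratio, asfr = asfr, mu = mu, migr = migr,
                ptrans = ptrans, years = years)
  # Baseline population path: forward run with the planted transition
  # probabilities; dynamic calibration can recover them exactly.
  path <- array(0, dim = c(length(H), length(G), length(A), length(years)),
                dimnames = list(H, G, A, years))
  path[, , , 1] <- pop0
  for (t in 2:length(years)) {
    path[, , , t] <- project_year(path[, , , t - 1],
                                  vital_slice(rates, years[t]))
  }
  list(pop0 = pop0, rates = rates, target_path = path, years = years)
}

fixture_nutrition <- function(d) {
  # Energy per unit of consumption value and fatty-acid energy contents
  # (same units); literature-informed synthetic magnitudes.
  base <- rbind(
    #             total   SFA   MUFA  PUFA
    rice      = c(10.0,  0.20, 0.30, 0.30),
    maize     = c( 8.0,  0.30, 0.50, 0.80),
    cassava   = c( 8.0,  0.10, 0.10, 0.20),
    sugarcane = c( 9.0,  0.00, 0.00, 0.00),
    oilpalm   = c( 2.0,  0.90, 0.70, 0.20),
    fruitveg  = c( 3.0,  0.10, 0.20, 0.30),
    rubber    = c( 0.0,  0.00, 0.00, 0.00),
    opother   = c( 4.0,  1.20, 1.00, 0.60),
    palmoil   = c(35.0, 17.00, 13.00, 3.20),
    othoils   = c(35.0,  5.40, 8.00, 20.30),
    procfood  = c(12.0,  2.50, 2.00, 1.50),
    beverages = c( 6.0,  0.30, 0.20, 0.10),
    manuf     = c( 0.0,  0.00, 0.00, 0.00),
    services  = c( 0.0,  0.00, 0.00, 0.00))
  colnames(base) <- c("total", "SFA", "MUFA", "PUFA")
  tab <- list()
  for (h in seq_along(HOUSEHOLDS)) {
    m <- base * d$nutr_noise[h]
    tab[[HOUSEHOLDS[h]]] <- m
  }
  # Cholesterol (Total:HDL) change per unit change in fatty-acid energy
  # intake share; magnitudes follow the controlled-trial literature
  # (per 1% of energy: SFA +0.003, MUFA -0.026, PUFA -0.032).
  resp <- c(SFA = 0.3, MUFA = -2.6, PUFA = -3.2)
  list(table = tab, response = resp)
}

fixture_biomarkers <- function(d) {
  edges <- seq(CHOL_RANGE[1], CHOL_RANGE[2], length.out = N_STRATA + 1)
  mids <- (edges[-1] + edges[-(N_STRATA + 1)]) / 2
  out <- list()
  for (h in seq_along(HOUSEHOLDS)) {
    mean_h <- d$chol_mean[h]
    p <- diff(stats::pnorm(edges, mean = mean_h, sd = 0.85))
    p <- p / sum(p)
    out[[HOUSEHOLDS[h]]] <- biomarker_distribution(mean_h, p, mids)
  }
  out
}

fixture_elasticities <- function(d) {
  inc_base <- c(rice = 0.45, maize = 0.55, cassava = 0.50,
                sugarcane = 0.60, oilpalm = 0.60, fruitveg = 0.80,
                rubber = 0.90, opother = 0.70, palmoil = 0.55,
                othoils = 0.60, procfood = 0.90, beverages = 1.10,
                manuf = 1.25, services = 1.35)
  own_base <- c(rice = -0.40, maize = -0.45, cassava = -0.45,
                sugarcane = -0.50, oilpalm = -0.50, fruitveg = -0.60,
                rubber = -0.70, opother = -0.60, palmoil = -0.55,
                othoils = -0.65, procfood = -0.75, beverages = -0.80,
                manuf = -0.90, services = -0.80)
  n <- length(MODEL_SECTORS)
  income <- matrix(0, n, length(HOUSEHOLDS),
                   dimnames = list(MODEL_SECTORS, HOUSEHOLDS))
  price <- array(0, dim = c(n, n, length(HOUSEHOLDS)),
                 dimnames = list(MODEL_SECTORS, MODEL_SECTORS, HOUSEHOLDS))
  for (h in seq_along(HOUSEHOLDS)) {
    income[, h] <- pmax(0.1, inc_base * d$inc_noise[, h])
    eps <- matrix(0, n, n, dimnames = list(MODEL_SECTORS, MODEL_SECTORS))
    diag(eps) <- own_base * d$own_noise[, h]
    # weak substitutability off the diagonal; the two edible oils are
    # close substitutes for one another
    off <- 0.02 + 0.03 * d$cross_noise[, , h]
    diag(off) <- 0
    eps <- eps + off
    eps["palmoil", "othoils"] <- 0.45
    eps["othoils", "palmoil"] <- 0.45
    price[, , h] <- eps
  }
  list(income = income, price = price)
}

fixture_healthecon <- function() {
  list(
    tu_care_ls = c("MI-nf" = 0.10, "S-nf" = 0.10),
    tu_care_nonls = c("MI-nf" = 0.15, "S-nf" = 0.15),
    illdur = c("MI-nf" = 28 / 365, "S-nf" = 1.0),
    yld_weight = c("MI-nf" = 0.12, "S-nf" = 0.27),
    partrate = c(male = 0.80, female = 0.65),
    # base health unit costs per incident case, SAM currency units
    # (1 unit = 1e9 THB); lags 1-3 non-zero only for non-fatal stroke
    huc = rbind("MI-nf" = c(1.2e-4, 0, 0, 0),
                "S-nf" = c(1.5e-4, 0.6e-4, 0.3e-4, 0.15e-4)),
    public_share = 0.80,
    usd_per_unit = 1e9 / 34.5)
}

fixture_luc <- function(sam_model) {
  ha <- c(ce = 5.5e6, n = 4.5e6, ne = 7.5e6, s = 2.5e6)
  stocks <- c(rice = 15, maize = 18, cassava = 20, sugarcane = 30,
              oilpalm = 100, fruitveg = 60, rubber = 120) * 1e-6
  coef <- outer(stocks, stocks, "-")    # Mt CO2-eq per hectare
  land_val <- vapply(LAND_REGIONS, function(r)
    sum(sam_model$flows[paste0("fac.land.", r),
                        paste0("act.", CROP_SECTORS)]), numeric(1))
  list(hectares = ha, carbon_stocks = stocks, emiss_coef = coef,
       ha_per_value = ha / land_val)
}

# ---------------------------------------------------------------------------

#' Generate the complete synthetic fixture bundle
#'
#' Deterministically generates every model input: the balanced
#' 49-sector SAM hitting the sectoral share targets, sector maps,
#' demand-system elasticities, nutrient and cholesterol-response
#' coefficients, biomarker distributions, clinical outcome lookups,
#' demographic baseline and vital rates, health-economic parameters and
#' land-use-change coefficients.  The result is a pure function of
#' `(seed, targets)`: the same seed reproduces the bundle bit for bit.
#'
#' @param seed integer seed for all stochastic draws.
#' @param targets sectoral share targets, see [table1_targets()].
#' @return an object of class `fixture_bundle`.
#' @export
make_fixtures <- function(seed = 20160101, targets = table1_targets()) {
  with_seed(seed, {
    nH <- length(HOUSEHOLDS); nC <- length(MODEL_SECTORS)
    draws <- list(
      salesw_pf = stats::setNames(numeric(nC), MODEL_SECTORS),
      salesw_op = stats::setNames(numeric(nC), MODEL_SECTORS),
      hhw_pf = stats::setNames(numeric(nC), MODEL_SECTORS),
      hhw_op = stats::setNames(numeric(nC), MODEL_SECTORS))
    pf <- names(which(MODEL_TO_COARSE == "primfood"))
    op <- names(which(MODEL_TO_COARSE == "othprim"))
    draws$salesw_pf[pf] <- rdirichlet1(c(30, 6, 6, 6, 6, 16) * 4)
    draws$salesw_op[op] <- rdirichlet1(c(35, 65) * 2)
    draws$hhw_pf[pf] <- rdirichlet1(c(55, 4, 3, 8, 1, 29) * 4)
    draws$hhw_op[op] <- c(0.02, 0.98)
    draws$landw <- lapply(stats::setNames(nm = CROP_SECTORS), function(s) {
      prior <- switch(s,
        rice = c(0.25, 0.20, 0.45, 0.10), maize = c(0.20, 0.50, 0.25, 0.05),
        cassava = c(0.30, 0.10, 0.55, 0.05),
        sugarcane = c(0.35, 0.25, 0.35, 0.05),
        oilpalm = c(0.10, 0.02, 0.03, 0.85),
        fruitveg = c(0.30, 0.30, 0.20, 0.20),
        rubber = c(0.10, 0.05, 0.15, 0.70))
      stats::setNames(rdirichlet1(prior * 60), LAND_REGIONS)
    })
    io_prior <- matrix(0.5, nC, nC, dimnames = list(MODEL_SECTORS,
                                                    MODEL_SECTORS))
    io_prior["services", ] <- 3; io_prior["manuf", ] <- 3
    diag(io_prior) <- diag(io_prior) + 1.5
    io_prior[c("rice", "maize", "cassava", "sugarcane", "fruitveg"),
             "procfood"] <- c(4, 1, 1, 2, 2)
    io_prior["opother", "procfood"] <- 3
    io_prior["oilpalm", "palmoil"] <- 6
    io_prior["opother", "othoils"] <- 2
    io_prior["procfood", "beverages"] <- 2
    io_prior[c("rice", "sugarcane"), "beverages"] <- 1.5
    io_prior["manuf", CROP_SECTORS] <- 2
    io_prior <- io_prior * matrix(stats::runif(nC * nC, 0.8, 1.2), nC, nC)
    draws$io_prior <- io_prior
    draws$usklw <- rdirichlet1(c(18, 8, 14, 5, 12, 6, 20, 6, 11) * 10)
    draws$sklw <- rdirichlet1(c(45, 10, 6, 7, 5, 7, 8, 7, 5) * 10)
    draws$capw <- rdirichlet1(c(35, 10, 6, 10, 6, 10, 7, 10, 6) * 10)
    taste <- matrix(1, nC, nH, dimnames = list(MODEL_SECTORS, HOUSEHOLDS))
    taste["rice", RURAL_HH] <- 1.6
    taste["services", RURAL_HH] <- 0.75
    taste["rice", "bkk"] <- 0.6
    taste[c("services", "beverages"), "bkk"] <- c(1.25, 1.2)
    taste <- taste * matrix(stats::runif(nC * nH, 0.9, 1.1), nC, nH)
    draws$taste <- taste

    built <- build_model_sam(targets, draws)
    finew <- lapply(FINE_UNDER_MODEL[lengths(FINE_UNDER_MODEL) > 1],
                    function(k) rdirichlet1(rep(3, length(k))))
    sam_fine <- expand_to_fine(built$sam, finew)

    demog_draws <- list(
      age_noise = matrix(stats::runif(nH * length(AGE_GROUPS), 0.95, 1.05),
                         nH, length(AGE_GROUPS)),
      ptrans_noise = array(stats::runif(nH * 2 * length(AGE_GROUPS),
                                        -0.02, 0.02),
                           dim = c(nH, 2, length(AGE_GROUPS))))
    demog <- fixture_demography(demog_draws)

    nutr <- fixture_nutrition(list(nutr_noise = stats::runif(nH, 0.95, 1.05)))
    biom <- fixture_biomarkers(list(chol_mean = stats::rnorm(nH, 3.9, 0.15)))
    elas <- fixture_elasticities(list(
      inc_noise = matrix(stats::runif(nC * nH, 0.9, 1.1), nC, nH),
      own_noise = matrix(stats::runif(nC * nH, 0.9, 1.1), nC, nH),
      cross_noise = array(stats::runif(nC * nC * nH), c(nC, nC, nH))))

    lookups <- generate_lookup(risk_params = default_risk_params())

    bundle <- structure(list(
      seed = seed,
      targets = targets,
      sam = sam_fine,
      sam_model = built$sam,
      maps = fixture_sector_maps(),
      msec = built$msec,
      demand = list(elasticities = elas),
      nutrition = nutr,
      biomarkers = biom,
      lookups = lookups,
      demog = demog,
      healthecon = fixture_healthecon(),
      luc = fixture_luc(built$sam)),
      class = "fixture_bundle")
    bundle
  })
}

#' Sectoral structure shares computed from a SAM
#'
#' Recomputes, for each coarse sector of an aggregated SAM, the import
#' share of domestic sales, export share of production, tariff rate,
#' sales share and household consumption share.
#'
#' @param x a coarse (aggregated) `sam`.
#' @return data.frame keyed by sector, shares as fractions.
#' @export
sam_structure_shares <- function(x) {
  f <- x$flows
  secs <- sub("^com\\.", "", sam_accounts(x, "com"))
  hh <- sam_accounts(x, "hh")
  out <- data.frame(sector = secs, stringsAsFactors = FALSE)
  com <- paste0("com.", secs); act <- paste0("act.", secs)
  M <- f["row", com]
  TR <- f["gov", com]
  QD <- f[cbind(act, com)]
  E <- f[act, "row"]
  X <- QD + E
  sales <- QD + M
  C <- rowSums(f[com, hh, drop = FALSE])
  out$impshr <- as.numeric(M / sales)
  out$expshr <- as.numeric(E / X)
  out$tariff <- as.numeric(ifelse(M > 0, TR / M, 0))
  out$salesshr <- as.numeric(sales / sum(sales))
  out$hhshr <- as.numeric(C / sum(C))
  out$avg_tariff <- sum(TR) / sum(M)
  out$avg_impshr <- sum(M) / sum(sales)
  out
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle> seed %d: %d-sector SAM (model %d), %d households\n",
              x$seed, length(sam_accounts(x$sam, "com")),
              length(sam_accounts(x$sam_model, "com")), length(HOUSEHOLDS)))
  invisible(x)
}
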