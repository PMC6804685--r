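# Static CGE core and recursive dynamics.
#
# Structure: one activity per commodity; CES production over value
# added and an aggregate Leontief intermediate bundle; a CES factor
# nest over two labour types, mobile capital and four region-specific
# land factors; Armington CES import aggregation and CET export
# transformation against fixed world prices with a flexible real
# exchange rate clearing a fixed balance of payments; household-
# specific AIDS consumption; savings-driven investment; government
# with income taxes and import tariffs.  The consumer price index is
# the numeraire and is steered by an exogenous price-trend factor;
# real variables are numeraire-invariant.
#
# The within-period equilibrium is solved by a damped Newton iteration
# on the logarithms of (domestic prices, activity levels, factor
# prices, exchange rate, government and investment scales, GDP
# deflator), with one commodity-clearing equation dropped and checked
# afterwards as the Walras residual.

DEFAULT_ELASTICITIES <- list(top = 0.8, va = 0.6, armington = 0.8,
                             cet = 1.6)

#' Calibrate the CGE from a balanced SAM
#'
#' Recovers all share/shift parameters, tax and tariff rates, and
#' household demand systems such that solving the model at base policy
#' replicates the SAM exactly (benchmark replication).
#'
#' @param sam_model a balanced `sam` at model resolution with
#'   one-to-one activity/commodity accounts.
#' @param demand_elasticities list with `income` (`[commodity,
#'   household]`) and `price` (`[c, c', household]`) elasticity arrays
#'   used to parameterise the household AIDS systems.
#' @param elasticities substitution elasticities for the production,
#'   Armington and CET nests.
#' @return object of class `cge_params`.
#' @export
cge_calibrate <- function(sam_model, demand_elasticities,
                          elasticities = DEFAULT_ELASTICITIES) {
  f <- sam_model$flows
  secs <- sub("^com\\.", "", sam_accounts(sam_model, "com"))
  stop_if(!setequal(paste0("act.", secs), sam_accounts(sam_model, "act")),
          "activities and commodities must map one-to-one")
  facs <- sub("^fac\\.", "", sam_accounts(sam_model, "fac"))
  hhs <- sub("^hh\\.", "", sam_accounts(sam_model, "hh"))
  act <- paste0("act.", secs); com <- paste0("com.", secs)
  fac <- paste0("fac.", facs); hh <- paste0("hh.", hhs)
  n <- length(secs)
  lab <- rownames(f)
  # singleton accounts may be absent in closed test economies
  g <- function(r, c) {
    if (all(r %in% lab) && all(c %in% lab)) f[r, c]
    else rep(0, max(length(r), length(c)))
  }

  QD0 <- stats::setNames(f[cbind(act, com)], secs)
  E0 <- stats::setNames(g(act, "row"), secs)
  Mcif0 <- stats::setNames(g("row", com), secs)
  TR0 <- stats::setNames(g("gov", com), secs)
  QM0 <- Mcif0 + TR0                      # tariff-inclusive base value
  tm0 <- ifelse(Mcif0 > 0, TR0 / Mcif0, 0)
  pwm <- ifelse(QM0 > 0, Mcif0 / QM0, 1)  # PM0 = pwm (1 + tm0) = 1
  pwe <- rep(1, n)
  QX0 <- QD0 + E0
  QQ0 <- QD0 + QM0
  QA0 <- QX0

  io <- f[com, act, drop = FALSE]; dimnames(io) <- list(secs, secs)
  FD0 <- f[fac, act, drop = FALSE]; dimnames(FD0) <- list(facs, secs)
  VA0 <- colSums(FD0)
  INT0 <- colSums(io)
  stop_if(any(abs(VA0 + INT0 - QA0) > 1e-6 * max(QA0)),
          "activity accounts do not balance production")
  stop_if(any(VA0 <= 0), "zero value added in an activity")
  ica <- sweep(io, 2, ifelse(INT0 > 0, INT0, 1), "/")

  arm <- lapply(seq_len(n), function(c)
    ces_calibrate(c(1, 1), c(QD0[c], QM0[c]), elasticities$armington))
  cet <- lapply(seq_len(n), function(c)
    ces_calibrate(c(1, 1), c(QD0[c], E0[c]), -elasticities$cet))
  top <- lapply(seq_len(n), function(a)
    ces_calibrate(c(1, 1), c(VA0[a], INT0[a]), elasticities$top))
  va <- lapply(seq_len(n), function(a)
    ces_calibrate(rep(1, length(facs)), FD0[, a], elasticities$va))
  names(arm) <- names(cet) <- names(top) <- names(va) <- secs

  hhinc0 <- f[hh, fac, drop = FALSE]; dimnames(hhinc0) <- list(hhs, facs)
  Y0 <- rowSums(hhinc0)
  tau <- stats::setNames(g("gov", hh) / Y0, hhs)
  srate <- stats::setNames(g("s-i", hh) / Y0, hhs)
  cons0 <- f[com, hh, drop = FALSE]; dimnames(cons0) <- list(secs, hhs)
  e0 <- colSums(cons0)
  stop_if(any(abs((1 - tau - srate) * Y0 - e0) > 1e-6 * max(Y0)),
          "household accounts do not balance")
  # savings rate re-expressed out of after-tax income
  s_dis <- srate / (1 - tau)

  labfacs <- intersect(c("uskl", "skl"), facs)
  landfacs <- grep("^land\\.", facs, value = TRUE)
  capfac <- intersect("cap", facs)
  LS0 <- hhinc0[, labfacs, drop = FALSE]
  repat0 <- if (length(capfac)) g("row", "fac.cap") else 0
  K0 <- if (length(capfac)) sum(FD0["cap", ]) else 0
  repshare <- if (K0 > 0) repat0 / K0 else 0
  capshr <- if (length(capfac) && (K0 - repat0) > 0)
    hhinc0[, "cap"] / (K0 - repat0) else stats::setNames(rep(0, length(hhs)), hhs)
  landshr <- sapply(landfacs, function(lf) {
    tot <- sum(FD0[lf, ])
    if (tot > 0) hhinc0[, lf] / tot else rep(0, length(hhs))
  })
  if (length(landfacs))
    landshr <- matrix(landshr, ncol = length(landfacs),
                      dimnames = list(hhs, landfacs))
  LAND0 <- vapply(landfacs, function(lf) sum(FD0[lf, ]), numeric(1))

  G0 <- stats::setNames(g(com, "gov"), secs)
  I0 <- stats::setNames(g(com, "s-i"), secs)
  GSAV0 <- sum(g("s-i", "gov")) - sum(g("gov", "s-i"))
  NL0 <- sum(g("row", "s-i")) - sum(g("s-i", "row"))
  absorption0 <- sum(e0) + sum(G0) + sum(I0)
  gov_ratio <- sum(G0) / absorption0

  w0 <- sweep(cons0, 2, e0, "/")
  ds <- lapply(seq_along(hhs), function(h) {
    aids_calibrate(stats::setNames(w0[, h], secs),
                   demand_elasticities$income[secs, hhs[h]],
                   demand_elasticities$price[secs, secs, hhs[h]],
                   e0 = e0[h])
  })
  names(ds) <- hhs
  cwts <- rowSums(cons0) / sum(cons0)

  NGDP0 <- sum(e0) + sum(G0) + sum(I0) + sum(E0) - sum(pwm * QM0)

  structure(list(
    sectors = secs, factors = facs, households = hhs,
    labfacs = labfacs, landfacs = landfacs,
    QD0 = QD0, QM0 = QM0, QE0 = E0, QX0 = QX0, QQ0 = QQ0, QA0 = QA0,
    tm0 = tm0, pwm = pwm, pwe = pwe, ica = ica, FD0 = FD0,
    arm = arm, cet = cet, top = top, va = va,
    LS0 = LS0, K0 = K0, LAND0 = LAND0, repshare = repshare,
    capshr = capshr, landshr = landshr, tau = tau, s_dis = s_dis,
    cons0 = cons0, e0 = e0, G0 = G0, I0 = I0, GSAV0 = GSAV0, NL0 = NL0,
    gov_ratio = gov_ratio, demand = ds, cwts = cwts, NGDP0 = NGDP0,
    elasticities = elasticities),
    class = "cge_params")
}

#' Import-value-weighted tariff rates recovered from calibration
#'
#' @param params a `cge_params`.
#' @return list with per-commodity `rates` and the import-value-
#'   weighted `average` (both as fractions).
#' @export
tariff_rates <- function(params) {
  mcif <- params$pwm * params$QM0
  list(rates = params$tm0,
       average = sum(params$tm0 * mcif) / sum(mcif))
}

#' Initial economy state implied by the calibration
#'
#' @param params a `cge_params`.
#' @param year base year.
#' @return object of class `economy_state`: capital stock, effective
#'   labour supplies (value units), fixed land endowments, productivity
#'   and price-trend factors.
#' @export
initial_state <- function(params, year = 2015) {
  structure(list(year = year, K = params$K0, LS = params$LS0,
                 LAND = params$LAND0, A = 1, cpi = 1),
            class = "economy_state")
}

default_closure <- function() {
  list(mode = "policy", g_rule = "ratio", g_real = 1,
       c_real = NA_real_, tb_real = NA_real_)
}

# ---------------------------------------------------------------------------
# Within-period equilibrium

# Evaluate the full economy at a candidate point; returns residuals and
# (optionally) all derived quantities.
cge_active <- function(params, closure) {
  list(eff = closure$mode == "efficiency",
       gov = sum(params$G0) > 0 && closure$g_rule == "ratio",
       inv = sum(params$I0) > 0,
       trade = sum(params$QM0) + sum(params$QE0) > 0)
}

cge_eval <- function(z, params, state, tm, closure, shocks, detail = FALSE) {
  p <- params
  n <- length(p$sectors)
  act <- cge_active(p, closure)
  eff <- act$eff
  i <- 0
  take <- function(k) { v <- z[(i + 1):(i + k)]; i <<- i + k; v }
  PDS <- exp(take(n)); QA <- p$QA0 * exp(take(n))
  WF <- stats::setNames(exp(take(length(p$factors))), p$factors)
  EXR <- if (act$trade) exp(take(1)) else 1
  GSCALE <- if (act$gov) exp(take(1)) else closure$g_real
  ISCALE <- if (act$inv) exp(take(1)) else 1
  GDPDEF <- exp(take(1))
  ssc <- if (eff) exp(take(1)) else 1

  PM <- p$pwm * (1 + tm) * EXR
  PE <- p$pwe * EXR
  PQ <- vapply(seq_len(n), function(c)
    ces_unit_value(p$arm[[c]], c(PDS[c], PM[c])), numeric(1))
  PINTA <- as.numeric(crossprod(p$ica, PQ))
  pva <- vapply(seq_len(n), function(a)
    ces_unit_value(p$va[[a]], WF), numeric(1)) / state$A
  cost <- vapply(seq_len(n), function(a) {
    pr2 <- c(pva[a], if (PINTA[a] > 0) PINTA[a] else 1)
    ces_unit_value(p$top[[a]], pr2)
  }, numeric(1))
  prev <- vapply(seq_len(n), function(a)
    ces_unit_value(p$cet[[a]], c(PDS[a], PE[a])), numeric(1))

  # supply side quantities
  QDs <- numeric(n); QE <- numeric(n)
  QVA <- numeric(n); QINTA <- numeric(n)
  for (a in seq_len(n)) {
    sp <- ces_inputs(p$cet[[a]], c(PDS[a], PE[a]), QA[a])
    QDs[a] <- sp[1]; QE[a] <- sp[2]
    ti <- ces_inputs(p$top[[a]], c(pva[a], if (PINTA[a] > 0) PINTA[a] else 1),
                     QA[a])
    QVA[a] <- ti[1]; QINTA[a] <- ti[2]
  }
  FD <- vapply(seq_len(n), function(a)
    ces_inputs(p$va[[a]], WF, QVA[a] / state$A), numeric(length(p$factors)))
  dimnames(FD) <- list(p$factors, p$sectors)
  QINT <- sweep(p$ica, 2, QINTA, "*")

  # incomes
  labinc <- sweep(state$LS, 2, WF[p$labfacs], "*")
  capinc <- if ("cap" %in% p$factors) WF["cap"] * state$K else 0
  repat <- p$repshare * capinc
  Y <- rowSums(labinc) + p$capshr * (capinc - repat)
  if (length(p$landfacs))
    Y <- Y + as.numeric(p$landshr %*% (WF[p$landfacs] * state$LAND))
  hcp <- shocks$hcp %||% stats::setNames(rep(0, length(p$households)),
                                         p$households)
  disp <- (1 - p$tau) * Y - hcp
  e_h <- (1 - p$s_dis * ssc) * disp
  sav <- p$s_dis * ssc * disp

  x <- vapply(seq_along(p$households), function(h)
    aids_demand(p$demand[[h]], PQ, e_h[h], GDPDEF), numeric(n))
  QC <- rowSums(x)
  QG <- p$G0 * GSCALE
  QINV <- p$I0 * ISCALE
  QQd <- QC + rowSums(QINT) + QG + QINV
  # exogenous health costs are spent on the health-service commodity
  hcg <- shocks$hcg %||% 0
  hc_tot <- hcg + sum(hcp)
  hs <- match(shocks$health_sector %||% "services", p$sectors)
  Qhealth <- 0
  if (hc_tot != 0) {
    stop_if(is.na(hs), "no health-service sector for health-cost shocks")
    Qhealth <- hc_tot / PQ[hs]
    QQd[hs] <- QQd[hs] + Qhealth
  }
  QDd <- numeric(n); QM <- numeric(n)
  for (c in seq_len(n)) {
    ai <- ces_inputs(p$arm[[c]], c(PDS[c], PM[c]), QQd[c])
    QDd[c] <- ai[1]; QM[c] <- ai[2]
  }

  tariffrev <- sum(tm * p$pwm * QM * EXR)
  govrev <- sum(p$tau * Y) + tariffrev
  Gnom <- sum(PQ * QG) + hcg
  GSAV <- govrev - Gnom
  NL <- if (eff) sum(p$pwe * QE) - sum(p$pwm * QM) - repat / EXR else p$NL0
  Inom <- sum(PQ * QINV)
  Cnom <- sum(e_h) + sum(hcp)
  NGDP <- Cnom + Gnom + Inom + sum(PE * QE) - sum(p$pwm * QM) * EXR
  RGDP <- sum(QC) + Qhealth + sum(QG) + sum(QINV) + sum(QE) -
    sum(p$pwm * QM)
  CPI <- sum(p$cwts * PQ)

  sc_q <- pmax(p$QD0, 1e-3 * max(p$QD0))
  sc_f <- pmax(rowSums(p$FD0), 1e-6 * sum(p$FD0))
  sc_m <- p$NGDP0

  res <- c(
    zp = log(cost) - log(prev),
    dom = ((QDs - QDd) / sc_q)[-n],
    fac = (rowSums(FD) - c(
      vapply(p$factors, function(fct) {
        if (fct %in% p$labfacs) sum(state$LS[, fct])
        else if (fct == "cap") state$K
        else state$LAND[fct]
      }, numeric(1)))) / sc_f,
    ext = if (!act$trade) NULL
          else if (eff) (sum(QE) - sum(p$pwm * QM) - closure$tb_real) / sc_m
          else (sum(p$pwm * QM) + repat / EXR + p$NL0 -
                  sum(p$pwe * QE)) / sc_m,
    gov = if (act$gov) (Gnom - p$gov_ratio * (Cnom + Gnom + Inom)) / sc_m
          else NULL,
    si = if (act$inv) (sum(sav) + GSAV - Inom - NL * EXR) / sc_m else NULL,
    cpi = CPI / state$cpi - 1,
    def = (NGDP - GDPDEF * RGDP) / sc_m,
    cons = if (eff) (sum(QC) - closure$c_real) / sum(p$QD0) else NULL)

  if (!detail) return(res)
  walras <- (QDs[n] - QDd[n]) / sc_q[n]
  land_fd <- FD[p$landfacs, , drop = FALSE]
  list(residuals = res, walras = walras,
       PDS = stats::setNames(PDS, p$sectors),
       PQ = stats::setNames(PQ, p$sectors), PM = PM, PE = PE,
       WF = WF, EXR = EXR, GDPDEF = GDPDEF, CPI = CPI,
       QA = stats::setNames(QA, p$sectors), QDs = QDs, QE = QE,
       QM = QM, QC = QC, QG = QG, QINV = QINV, QVA = QVA,
       FD = FD, FLAND = land_fd, x = x, e_h = e_h, Y = Y, sav = sav,
       GSCALE = GSCALE, ISCALE = ISCALE, ssc = ssc,
       govrev = govrev, tariffrev = tariffrev, GSAV = GSAV, NL = NL,
       NGDP = NGDP, RGDP = RGDP,
       Cnom = Cnom, Gnom = Gnom, Inom = Inom,
       real_tb = sum(QE) - sum(p$pwm * QM))
}

n_unknowns <- function(params, closure) {
  act <- cge_active(params, closure)
  2 * length(params$sectors) + length(params$factors) + 1 +
    act$trade + act$gov + act$inv + act$eff
}

base_start <- function(params, closure) {
  rep(0, n_unknowns(params, closure))
}

# Build a start vector for `closure` from a solved equilibrium
# (possibly obtained under a different closure).
make_start <- function(params, closure, eq) {
  act <- cge_active(params, closure)
  unname(c(log(eq$PDS), log(eq$QA / params$QA0), log(eq$WF),
           if (act$trade) log(eq$EXR),
           if (act$gov) log(eq$GSCALE),
           if (act$inv) log(eq$ISCALE),
           log(eq$GDPDEF),
           if (act$eff) log(eq$ssc %||% 1)))
}

#' Solve the within-period equilibrium
#'
#' Damped Newton iteration with a finite-difference Jacobian on the
#' log-transformed unknowns; if the iteration fails from the supplied
#' start, a homotopy path in the tariff vector is attempted.
#'
#' @param params a `cge_params`.
#' @param state an `economy_state`.
#' @param tm named per-commodity tariff vector (default: calibrated
#'   base rates).
#' @param closure closure specification, see [default_closure()].
#' @param shocks optional exogenous health shocks: `hcp` per-household
#'   private health costs, `hcg` total public health costs (nominal).
#' @param start optional start vector (a previous solution's `z`).
#' @param tol convergence tolerance on the scaled residual norm.
#' @param max_iter Newton iteration cap.
#' @return object of class `cge_equilibrium` with all prices,
#'   quantities, incomes, the GDP aggregates and solver diagnostics.
#' @export
solve_period <- function(params, state, tm = params$tm0,
                         closure = default_closure(),
                         shocks = list(), start = NULL,
                         tol = 1e-11, max_iter = 60) {
  z <- if (is.null(start)) base_start(params, closure)
       else if (inherits(start, "cge_equilibrium"))
         make_start(params, closure, start)
       else start
  stop_if(length(z) != n_unknowns(params, closure),
          "start vector has wrong length for this closure")
  fn <- function(z) cge_eval(z, params, state, tm, closure, shocks)
  sol <- newton_solve(fn, z, tol = tol, max_iter = max_iter)
  if (!sol$converged) {
    # homotopy in the tariff vector from the calibrated base
    z <- base_start(params, closure)
    ok <- TRUE
    for (lam in seq(0.25, 1, by = 0.25)) {
      tml <- params$tm0 + lam * (tm - params$tm0)
      s2 <- newton_solve(function(zz)
        cge_eval(zz, params, state, tml, closure, shocks),
        z, tol = tol, max_iter = max_iter)
      if (!s2$converged) { ok <- FALSE; break }
      z <- s2$z
    }
    stop_if(!ok || !s2$converged,
            "CGE solver failed to converge (last residual %.3g)",
            if (ok) max(abs(s2$res)) else max(abs(sol$res)))
    sol <- s2
  }
  out <- cge_eval(sol$z, params, state, tm, closure, shocks, detail = TRUE)
  out$z <- sol$z
  out$iterations <- sol$iterations
  out$tm <- tm
  out$year <- state$year
  class(out) <- "cge_equilibrium"
  out
}

# Damped Newton with forward-difference Jacobian.
newton_solve <- function(fn, z, tol = 1e-11, max_iter = 60,
                         fd_step = 1e-7) {
  res <- fn(z)
  m <- length(res)
  for (it in seq_len(max_iter)) {
    nrm <- max(abs(res))
    if (nrm < tol) {
      return(list(z = z, res = res, converged = TRUE, iterations = it - 1))
    }
    J <- matrix(0, m, length(z))
    for (j in seq_along(z)) {
      zj <- z; zj[j] <- zj[j] + fd_step
      J[, j] <- (fn(zj) - res) / fd_step
    }
    dz <- tryCatch(solve(J, -res), error = function(e) {
      qr.solve(J, -res, tol = 1e-14)
    })
    # line search
    step <- 1
    repeat {
      z2 <- z + step * dz
      res2 <- tryCatch(fn(z2), error = function(e) NULL)
      if (!is.null(res2) && all(is.finite(res2)) &&
          max(abs(res2)) < nrm * (1 - 1e-4 * step) + 1e-15) break
      step <- step / 2
      if (step < 1e-6) break
    }
    if (step < 1e-6) {
      return(list(z = z, res = res, converged = FALSE, iterations = it))
    }
    z <- z2; res <- res2
  }
  list(z = z, res = res, converged = max(abs(res)) < tol,
       iterations = max_iter)
}

# ---------------------------------------------------------------------------
# Recursive dynamics

#' Advance the economy state one year
#'
#' Capital accumulates by depreciation plus real investment; effective
#' labour supplies, the productivity factor and the price-trend factor
#' are supplied by their respective modules.
#'
#' @param state current `economy_state`.
#' @param eq solved `cge_equilibrium` of the current year.
#' @param LS_next next-year effective labour supplies (value units).
#' @param A_next,cpi_next next-year productivity and price-trend
#'   factors.
#' @param depreciation annual capital depreciation rate.
#' @return next-year `economy_state`.
#' @export
advance <- function(state, eq, LS_next = state$LS, A_next = state$A,
                    cpi_next = state$cpi, depreciation = 0.05) {
  K <- (1 - depreciation) * state$K + sum(eq$QINV)
  stop_if(K < 0, "negative capital stock")
  structure(list(year = state$year + 1, K = K, LS = LS_next,
                 LAND = state$LAND, A = A_next, cpi = cpi_next),
            class = "economy_state")
}

#' Calibrate productivity and price trends to GDP growth targets
#'
#' Finds, year by year, the Hicks-neutral productivity factor that puts
#' counterfactual real GDP on the target compound growth path, and the
#' price-trend (numeraire) factor that puts nominal GDP on its target
#' path; the latter is exact by homogeneity.
#'
#' @param params a `cge_params`.
#' @param state0 base-year `economy_state`.
#' @param ls_path list (by year) of effective labour supplies in value
#'   units; `NULL` entries keep the base supplies.
#' @param years simulation years.
#' @param real_growth,nominal_growth target growth rates per annum.
#' @param tol relative tolerance on the yearly real-GDP target.
#' @return object of class `growth_trends`: named vectors `A` and
#'   `cpi` by year (including the base year), the solved base-year
#'   equilibrium and per-year solver starts for reuse.
#' @export
dynamic_calibrate <- function(params, state0, ls_path = NULL,
                              years = 2016:2035, real_growth = 0.039,
                              nominal_growth = 0.062, tol = 1e-8) {
  closure <- default_closure()
  eq0 <- solve_period(params, state0, closure = closure)
  A <- stats::setNames(numeric(length(years) + 1),
                       c(state0$year, years))
  cpi <- A
  A[1] <- state0$A; cpi[1] <- state0$cpi
  rgdp <- A; ngdp <- A
  rgdp[1] <- eq0$RGDP; ngdp[1] <- eq0$NGDP
  starts <- list()
  state <- state0
  eq <- eq0
  rgdp_prev <- eq0$RGDP
  ngdp_prev <- eq0$NGDP
  z <- eq0$z
  for (k in seq_along(years)) {
    yr <- years[k]
    LS <- if (!is.null(ls_path)) ls_path[[as.character(yr)]] %||% state$LS
          else state$LS
    state <- advance(state, eq, LS_next = LS)
    rtarget <- rgdp_prev * (1 + real_growth)
    ntarget <- ngdp_prev * (1 + nominal_growth)
    # secant iteration on log productivity
    a1 <- log(state$A); state$A <- exp(a1)
    e1 <- solve_period(params, state, closure = closure, start = z)
    f1 <- e1$RGDP / rtarget - 1
    a2 <- a1 + 0.02
    for (s in 1:40) {
      if (abs(f1) < tol) break
      state$A <- exp(a2)
      e2 <- solve_period(params, state, closure = closure, start = e1$z)
      f2 <- e2$RGDP / rtarget - 1
      if (abs(f2 - f1) < 1e-15) break
      a_new <- a2 - f2 * (a2 - a1) / (f2 - f1)
      a1 <- a2; f1 <- f2; e1 <- e2
      a2 <- a_new
    }
    state$A <- exp(if (abs(f1) < tol) a1 else a2)
    eq <- solve_period(params, state, closure = closure, start = e1$z)
    stop_if(abs(eq$RGDP / rtarget - 1) > 10 * tol,
            "real growth calibration failed in %d", yr)
    # nominal target via the price-trend factor (exact by homogeneity)
    state$cpi <- state$cpi * ntarget / eq$NGDP
    zsc <- eq$z
    eq <- solve_period(params, state, closure = closure, start = zsc)
    A[k + 1] <- state$A
    cpi[k + 1] <- state$cpi
    rgdp[k + 1] <- eq$RGDP
    ngdp[k + 1] <- eq$NGDP
    starts[[as.character(yr)]] <- eq
    z <- eq$z
    rgdp_prev <- eq$RGDP
    ngdp_prev <- eq$NGDP
  }
  structure(list(A = A, cpi = cpi, years = years, base_eq = eq0,
                 rgdp = rgdp, ngdp = ngdp,
                 real_growth = real_growth,
                 nominal_growth = nominal_growth, starts = starts),
            class = "growth_trends")
}
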