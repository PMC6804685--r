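# Fixture bundle serialisation: a directory of plain-text CSVs plus a
# JSON manifest carrying the seed, the share targets and per-file
# checksums.  Arrays are written in long (tidy) format with one key
# column per dimension.

array_to_long <- function(a, value = "value") {
  dn <- dimnames(a)
  stop_if(is.null(dn), "array must be fully named for serialisation")
  g <- expand.grid(dn, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[[value]] <- as.vector(a)
  g
}

long_to_array <- function(df, dims, value = "value") {
  a <- array(NA_real_, dim = lengths(dims), dimnames = dims)
  idx <- mapply(function(col, dn) match(df[[col]], dn),
                names(dims), dims, SIMPLIFY = FALSE)
  a[as.matrix(as.data.frame(idx))] <- df[[value]]
  a
}

fx_write_csv <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(format(df, digits = 17, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  path
}

#' Write a fixture bundle to a directory of CSV files
#'
#' Serialises every component as plain-text CSV and writes a
#' `manifest.json` with the seed, the share targets and md5 checksums
#' of each file.
#'
#' @param bundle a `fixture_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  files["sam"] <- write_sam(bundle$sam, file.path(dir, "sam.csv"))
  files["sam_model"] <- write_sam(bundle$sam_model,
                                  file.path(dir, "sam_model.csv"))
  files["targets"] <- fx_write_csv(bundle$targets, dir, "targets")

  el <- bundle$demand$elasticities
  files["income_elast"] <- fx_write_csv(
    array_to_long(el$income), dir, "income_elast")
  names(dimnames(el$price)) <- c("commodity", "cross", "household")
  files["price_elast"] <- fx_write_csv(
    array_to_long(el$price), dir, "price_elast")

  nut <- do.call(rbind, lapply(names(bundle$nutrition$table), function(h) {
    m <- bundle$nutrition$table[[h]]
    data.frame(household = h, commodity = rownames(m),
               total = m[, "total"], SFA = m[, "SFA"],
               MUFA = m[, "MUFA"], PUFA = m[, "PUFA"],
               row.names = NULL)
  }))
  files["nutrients"] <- fx_write_csv(nut, dir, "nutrients")
  files["chol_response"] <- fx_write_csv(
    data.frame(pathway = names(bundle$nutrition$response),
               coef = as.numeric(bundle$nutrition$response)),
    dir, "chol_response")

  bio <- do.call(rbind, lapply(names(bundle$biomarkers), function(h) {
    b <- bundle$biomarkers[[h]]
    data.frame(household = h, stratum = seq_along(b$freq),
               mean = b$mean, freq = b$freq, value = b$values)
  }))
  files["biomarkers"] <- fx_write_csv(bio, dir, "biomarkers")

  cf <- bundle$lookups$coefs
  names(dimnames(cf)) <- c("gender", "age", "location", "illness",
                           "degree")
  files["lookups"] <- fx_write_csv(array_to_long(cf), dir, "lookups")

  dg <- bundle$demog
  names(dimnames(dg$pop0)) <- c("household", "gender", "age")
  files["pop0"] <- fx_write_csv(array_to_long(dg$pop0), dir, "pop0")
  tp <- dg$target_path
  names(dimnames(tp)) <- c("household", "gender", "age", "year")
  files["pop_target"] <- fx_write_csv(array_to_long(tp), dir,
                                      "pop_target")
  for (nm in c("mu", "migr", "ptrans")) {
    a <- dg$rates[[nm]]
    names(dimnames(a)) <- c("household", "gender", "age", "year")
    files[nm] <- fx_write_csv(array_to_long(a), dir, nm)
  }
  files["asfr"] <- fx_write_csv(
    cbind(data.frame(age = rownames(dg$rates$asfr)),
          as.data.frame(dg$rates$asfr)), dir, "asfr")
  files["sexratio"] <- fx_write_csv(
    data.frame(gender = names(dg$rates$sexratio),
               share = as.numeric(dg$rates$sexratio)), dir, "sexratio")

  he <- bundle$healthecon
  files["healthecon"] <- fx_write_csv(
    data.frame(parameter = c(
      paste0("tu_care_ls.", names(he$tu_care_ls)),
      paste0("tu_care_nonls.", names(he$tu_care_nonls)),
      paste0("illdur.", names(he$illdur)),
      paste0("yld_weight.", names(he$yld_weight)),
      paste0("partrate.", names(he$partrate)),
      paste0("huc.", rep(rownames(he$huc), 4), ".lag",
             rep(0:3, each = 2)),
      "public_share", "usd_per_unit"),
      value = c(he$tu_care_ls, he$tu_care_nonls, he$illdur,
                he$yld_weight, he$partrate, as.numeric(he$huc),
                he$public_share, he$usd_per_unit)),
    dir, "healthecon")

  luc <- bundle$luc
  files["luc_land"] <- fx_write_csv(
    data.frame(region = names(luc$hectares),
               hectares = as.numeric(luc$hectares),
               ha_per_value = as.numeric(
                 luc$ha_per_value[names(luc$hectares)])),
    dir, "luc_land")
  files["luc_stocks"] <- fx_write_csv(
    data.frame(activity = names(luc$carbon_stocks),
               stock = as.numeric(luc$carbon_stocks)), dir, "luc_stocks")

  manifest <- list(seed = bundle$seed,
                   targets = bundle$targets,
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(unlist(files))),
                     basename(unlist(files)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a fixture bundle back from a directory
#'
#' Reconstructs the components written by [write_fixtures()]; file
#' checksums are verified against the manifest.
#'
#' @param dir directory written by [write_fixtures()].
#' @return a `fixture_bundle` (the derived `maps`/`msec` members are
#'   regenerated, `lookups` are re-read from CSV).
#' @export
read_fixtures <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  for (f in names(manifest$files)) {
    sum_now <- unname(tools::md5sum(file.path(dir, f)))
    stop_if(!identical(sum_now, manifest$files[[f]]),
            "checksum mismatch for %s", f)
  }
  rd <- function(name) utils::read.csv(file.path(dir, paste0(name, ".csv")),
                                       stringsAsFactors = FALSE,
                                       check.names = FALSE)
  sam_fine <- read_sam(file.path(dir, "sam.csv"))
  sam_model <- read_sam(file.path(dir, "sam_model.csv"))

  ie <- rd("income_elast")
  names(ie)[1:2] <- c("commodity", "household")
  income <- long_to_array(ie, list(commodity = MODEL_SECTORS,
                                   household = HOUSEHOLDS))
  pe <- rd("price_elast")
  price <- long_to_array(pe, list(commodity = MODEL_SECTORS,
                                  cross = MODEL_SECTORS,
                                  household = HOUSEHOLDS))
  dimnames(price) <- list(MODEL_SECTORS, MODEL_SECTORS, HOUSEHOLDS)
  dimnames(income) <- list(MODEL_SECTORS, HOUSEHOLDS)

  nut <- rd("nutrients")
  tab <- lapply(stats::setNames(nm = HOUSEHOLDS), function(h) {
    m <- as.matrix(nut[nut$household == h, c("total", "SFA", "MUFA",
                                             "PUFA")])
    rownames(m) <- nut$commodity[nut$household == h]
    m[MODEL_SECTORS, ]
  })
  cr <- rd("chol_response")
  response <- stats::setNames(cr$coef, cr$pathway)

  bio <- rd("biomarkers")
  biomarkers <- lapply(stats::setNames(nm = HOUSEHOLDS), function(h) {
    b <- bio[bio$household == h, ]
    b <- b[order(b$stratum), ]
    biomarker_distribution(b$mean[1], b$freq, b$value)
  })

  lk <- rd("lookups")
  cf <- long_to_array(lk, list(gender = GENDERS, age = AGE_GROUPS,
                               location = c("rural", "urban"),
                               illness = ILLNESSES,
                               degree = paste0("r", 0:POLY_DEGREE)))
  lookups <- structure(list(coefs = cf), class = "clinical_lookup")

  years <- 2015:2035
  dims4 <- list(household = HOUSEHOLDS, gender = GENDERS,
                age = AGE_GROUPS, year = as.character(years))
  pop0 <- long_to_array(rd("pop0"), dims4[1:3])
  target_path <- long_to_array(rd("pop_target"), dims4)
  rates <- list(mu = long_to_array(rd("mu"), dims4),
                migr = long_to_array(rd("migr"), dims4),
                ptrans = long_to_array(rd("ptrans"), dims4))
  asfr_df <- rd("asfr")
  asfr <- as.matrix(asfr_df[, -1])
  rownames(asfr) <- asfr_df$age
  colnames(asfr) <- as.character(years)
  sx <- rd("sexratio")
  rates$asfr <- asfr
  rates$sexratio <- stats::setNames(sx$share, sx$gender)
  rates$years <- years

  hed <- rd("healthecon")
  hev <- stats::setNames(hed$value, hed$parameter)
  pick <- function(prefix, nms)
    stats::setNames(hev[paste0(prefix, ".", nms)], nms)
  huc <- matrix(0, 2, 4, dimnames = list(c("MI-nf", "S-nf"), NULL))
  for (lag in 0:3)
    huc[, lag + 1] <- hev[paste0("huc.", rownames(huc), ".lag", lag)]
  healthecon <- list(
    tu_care_ls = pick("tu_care_ls", c("MI-nf", "S-nf")),
    tu_care_nonls = pick("tu_care_nonls", c("MI-nf", "S-nf")),
    illdur = pick("illdur", c("MI-nf", "S-nf")),
    yld_weight = pick("yld_weight", c("MI-nf", "S-nf")),
    partrate = pick("partrate", c("male", "female")),
    huc = huc,
    public_share = unname(hev["public_share"]),
    usd_per_unit = unname(hev["usd_per_unit"]))

  ll <- rd("luc_land")
  ls <- rd("luc_stocks")
  stocks <- stats::setNames(ls$stock, ls$activity)
  luc <- list(hectares = stats::setNames(ll$hectares, ll$region),
              carbon_stocks = stocks,
              emiss_coef = outer(stocks, stocks, "-"),
              ha_per_value = stats::setNames(ll$ha_per_value, ll$region))

  structure(list(seed = manifest$seed,
                 targets = as.data.frame(manifest$targets),
                 sam = sam_fine, sam_model = sam_model,
                 maps = fixture_sector_maps(),
                 demand = list(elasticities = list(income = income,
                                                   price = price)),
                 nutrition = list(table = tab, response = response),
                 biomarkers = biomarkers, lookups = lookups,
                 demog = list(pop0 = pop0, rates = rates,
                              target_path = target_path, years = years),
                 healthecon = healthecon, luc = luc),
            class = "fixture_bundle")
}
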