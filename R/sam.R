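# Social Accounting Matrix: data model, CSV serialisation, balance
# checking, RAS repair and sector aggregation.
#
# Account labels carry their class as a prefix: "act." (activities),
# "com." (commodities), "fac." (factors), "hh." (households), and the
# singleton accounts "gov", "s-i" and "row".  Flows are non-negative and
# read column-pays-row: flows[i, j] is the payment from account j to
# account i.

SAM_CLASSES <- c("act", "com", "fac", "hh", "gov", "s-i", "row")

#' Classify SAM account labels
#'
#' @param x character vector of account labels.
#' @return character vector of account classes.
#' @keywords internal
account_class <- function(x) {
  cls <- ifelse(grepl("^act\\.", x), "act",
         ifelse(grepl("^com\\.", x), "com",
         ifelse(grepl("^fac\\.", x), "fac",
         ifelse(grepl("^hh\\.",  x), "hh",
         ifelse(x %in% c("gov", "s-i", "row"), x, NA_character_)))))
  bad <- is.na(cls)
  stop_if(any(bad), "unknown account class for label(s): %s",
          paste(x[bad], collapse = ", "))
  cls
}

#' Construct a Social Accounting Matrix
#'
#' @param flows square numeric matrix with identical row and column
#'   labels (column account pays row account), all entries >= 0.
#' @param tol balance tolerance as a fraction of the grand total.
#' @param check if `FALSE`, skip the balance check (used internally
#'   before repair).
#' @return an object of class `sam`.
#' @export
sam <- function(flows, tol = 1e-6, check = TRUE) {
  flows <- as.matrix(flows)
  stop_if(nrow(flows) != ncol(flows), "SAM matrix must be square")
  rn <- rownames(flows); cn <- colnames(flows)
  stop_if(is.null(rn) || is.null(cn), "SAM matrix must be fully labelled")
  stop_if(!identical(rn, cn), "SAM row order must equal column order")
  stop_if(any(flows < 0), "negative flow in SAM")
  cls <- account_class(rn)
  obj <- structure(list(flows = flows,
                        accounts = data.frame(name = rn, class = cls,
                                              stringsAsFactors = FALSE)),
                   class = "sam")
  if (check) {
    imb <- sam_imbalance(obj)
    stop_if(imb > tol,
            "SAM unbalanced: max |rowsum-colsum| = %.3g x grand total (tol %.3g)",
            imb, tol)
  }
  obj
}

#' Maximum account imbalance of a SAM
#'
#' @param x a `sam`.
#' @return max over accounts of |row sum - column sum| divided by the
#'   grand total of all flows.
#' @export
sam_imbalance <- function(x) {
  f <- x$flows
  gt <- sum(f)
  stop_if(gt <= 0, "SAM grand total must be positive")
  max(abs(rowSums(f) - colSums(f))) / gt
}

#' Account names of a given class
#' @param x a `sam`.
#' @param class one of `"act"`, `"com"`, `"fac"`, `"hh"`, `"gov"`,
#'   `"s-i"`, `"row"`.
#' @return character vector of labels.
#' @export
sam_accounts <- function(x, class = NULL) {
  if (is.null(class)) return(x$accounts$name)
  x$accounts$name[x$accounts$class %in% class]
}

#' @export
print.sam <- function(x, ...) {
  tab <- table(x$accounts$class)
  cat(sprintf("<sam> %d accounts (%s), grand total %.6g, imbalance %.2e\n",
              nrow(x$flows),
              paste(sprintf("%s:%d", names(tab), tab), collapse = ", "),
              sum(x$flows), sam_imbalance(x)))
  invisible(x)
}

#' Read a SAM from a labelled CSV matrix
#'
#' The first row and first column hold account labels with class
#' prefixes (`act.`, `com.`, `fac.`, `hh.`) or the singleton names
#' `gov`, `s-i`, `row`; the body holds non-negative payments, column
#' account pays row account.
#'
#' @param path path to the CSV file.
#' @param tol balance tolerance as a fraction of the grand total.
#' @param repair if `TRUE`, an unbalanced matrix is repaired by
#'   [ras_balance()] instead of raising an error.
#' @return a `sam`.
#' @export
read_sam <- function(path, tol = 1e-6, repair = FALSE) {
  raw <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  if (repair) {
    s <- sam(m, check = FALSE)
    if (sam_imbalance(s) > tol) s <- ras_balance(s) else s
  } else {
    sam(m, tol = tol)
  }
}

#' Write a SAM as a labelled CSV matrix
#'
#' Values are serialised with 17 significant digits so that a
#' write/read cycle is bit-identical.
#'
#' @param x a `sam`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(x, path) {
  f <- x$flows
  lab <- colnames(f)
  lines <- c(paste(c("account", lab), collapse = ","),
             vapply(seq_len(nrow(f)), function(i) {
               paste(c(lab[i], formatC(f[i, ], digits = 17, format = "g")),
                     collapse = ",")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Biproportional (RAS) scaling of a non-negative matrix
#'
#' Iteratively scales rows and columns of `m` towards the target
#' margins.  Zero cells remain zero.
#'
#' @param m non-negative matrix.
#' @param row_targets,col_targets target margins; must have equal sums.
#' @param tol convergence tolerance on the maximum relative margin error.
#' @param max_iter iteration cap.
#' @return list with elements `m` (scaled matrix), `iterations`, and
#'   `max_err`.
#' @export
ras <- function(m, row_targets, col_targets, tol = 1e-9, max_iter = 10000) {
  stop_if(any(m < 0), "RAS requires a non-negative matrix")
  stop_if(abs(sum(row_targets) - sum(col_targets)) >
            1e-8 * max(sum(row_targets), 1),
          "RAS margins must have equal sums")
  stop_if(any(row_targets > 0 & rowSums(m) == 0),
          "RAS infeasible: zero row with positive target margin")
  stop_if(any(col_targets > 0 & colSums(m) == 0),
          "RAS infeasible: zero column with positive target margin")
  scale_err <- function(m) {
    re <- abs(rowSums(m) - row_targets) / pmax(row_targets, 1e-300)
    ce <- abs(colSums(m) - col_targets) / pmax(col_targets, 1e-300)
    max(re[row_targets > 0], ce[col_targets > 0], 0)
  }
  it <- 0
  repeat {
    rs <- rowSums(m)
    r <- ifelse(rs > 0, row_targets / rs, 1)
    m <- m * r
    cs <- colSums(m)
    s <- ifelse(cs > 0, col_targets / cs, 1)
    m <- sweep(m, 2, s, "*")
    it <- it + 1
    err <- scale_err(m)
    if (err <= tol) break
    stop_if(it >= max_iter,
            "RAS did not converge in %d iterations (err %.3g): structurally unbalanceable",
            max_iter, err)
  }
  list(m = m, iterations = it, max_err = err)
}

#' Balance a SAM by RAS towards its average margins
#'
#' Target margins are the averages of current row and column sums, so
#' the repair is the minimal symmetric adjustment consistent with the
#' biproportional family.  Zero cells stay zero.
#'
#' @param x a `sam` (possibly unbalanced; construct with `check = FALSE`).
#' @param tol RAS convergence tolerance.
#' @param max_iter iteration cap.
#' @return a balanced `sam` with attribute `"ras_log"` holding the
#'   iteration record.
#' @export
ras_balance <- function(x, tol = 1e-9, max_iter = 10000) {
  f <- x$flows
  stop_if(sum(f) <= 0, "RAS balancing requires a positive grand total")
  tgt <- (rowSums(f) + colSums(f)) / 2
  res <- ras(f, tgt, tgt, tol = tol, max_iter = max_iter)
  out <- sam(res$m, tol = 1e-6)
  attr(out, "ras_log") <- list(iterations = res$iterations,
                               max_err = res$max_err)
  out
}

#' Define a fine-to-coarse sector mapping
#'
#' @param fine character vector of fine sector names (bare, without the
#'   `act.`/`com.` prefix).
#' @param coarse character vector (same length): coarse sector of each
#'   fine sector.
#' @param food character vector of coarse sectors flagged as food.
#' @return object of class `sector_map`.
#' @export
sector_map <- function(fine, coarse, food = character()) {
  stop_if(length(fine) != length(coarse), "fine/coarse length mismatch")
  stop_if(anyDuplicated(fine) > 0, "duplicate fine sector in map")
  stop_if(!all(food %in% coarse), "food flag for unknown coarse sector")
  structure(data.frame(fine = fine, coarse = coarse,
                       stringsAsFactors = FALSE),
            food = food, class = c("sector_map", "data.frame"))
}

#' Aggregate the activity and commodity accounts of a SAM
#'
#' Sums flows within coarse groups defined by `map`; all non-sector
#' accounts are unchanged.  Balance is preserved exactly.
#'
#' @param x a `sam`.
#' @param map a [sector_map()] covering every fine sector in `x`.
#' @return the aggregated `sam`.
#' @export
sam_aggregate <- function(x, map) {
  f <- x$flows
  lab <- rownames(f)
  cls <- x$accounts$class
  bare <- sub("^(act|com)\\.", "", lab)
  sec <- cls %in% c("act", "com")
  stop_if(!all(bare[sec] %in% map$fine),
          "sector map does not cover all fine sectors")
  to <- lab
  idx <- match(bare[sec], map$fine)
  to[sec] <- paste0(ifelse(cls[sec] == "act", "act.", "com."),
                    map$coarse[idx])
  keep <- unique(to)
  agg <- rowsum(f, group = to, reorder = FALSE)
  agg <- t(rowsum(t(agg), group = to, reorder = FALSE))
  agg <- agg[keep, keep]
  sam(agg)
}
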