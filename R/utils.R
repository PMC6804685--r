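# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(sprintf(...), call. = FALSE)
  invisible(NULL)
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so that fixture generation never perturbs user-level
#' reproducibility.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Least-squares projection of s onto {x : C x = d}.
# Solves the KKT system directly; C must have full row rank.
project_affine <- function(s, C, d = rep(0, nrow(C))) {
  C <- as.matrix(C)
  CtC <- C %*% t(C)
  lam <- solve(CtC, C %*% s - d)
  as.numeric(s - t(C) %*% lam)
}

# Dirichlet draw (via gamma normalisation); alpha a positive vector.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Relative difference with a floor on the denominator.
rel_diff <- function(a, b, floor = 1e-8) {
  abs(a - b) / pmax(abs(b), floor)
}
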