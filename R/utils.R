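#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("phagestate_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("phagestate_data_error", "error")))
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards, so seeded operations do not disturb the caller's
#' random stream. `seed = NULL` evaluates the code unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      stop_config("seed must be a single finite number")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

## lower-triangle vector of a symmetric matrix, column-major (matches dist())
lower_tri <- function(m) m[lower.tri(m)]

#' Pearson correlation with t-based p-values
#'
#' Vectorised Pearson correlation over the rows of a matrix, with two-sided
#' p-values from the t reference distribution on n - 2 degrees of freedom.
#' Rows with zero variance yield `NA` correlations (flagged by the caller).
#'
#' @param x numeric matrix, variables in rows, observations in columns.
#' @return list with elements `rho`, `p` (square matrices) and `n`.
#' @export
cor_with_pvalues <- function(x) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (n < 3L) stop_data("at least 3 observations are required for correlation p-values")
  rho <- suppressWarnings(stats::cor(t(x)))
  df <- n - 2L
  r2 <- pmin(rho^2, 1)
  tstat <- rho * sqrt(df / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[r2 >= 1] <- 0
  diag(p) <- 0
  list(rho = rho, p = p, n = n)
}

#' Two-sided Pearson test for a single pair of vectors
#'
#' Pearson correlation with a two-sided p-value, either from the classical t
#' reference distribution on n - 2 degrees of freedom or from a seeded
#' permutation null. Constant inputs are reported as undefined rather than
#' given a coefficient.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @param method `"t"` or `"permutation"`.
#' @param n_perm,seed permutation-null settings.
#' @return list with `rho`, `p`, `n`, `undefined`.
#' @export
pearson_pair_test <- function(x, y, method = c("t", "permutation"),
                              n_perm = 9999, seed = 1) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 3L) stop_data("at least 3 samples are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, undefined = TRUE))
  rho <- stats::cor(x, y)
  if (method == "t") {
    p <- stats::cor.test(x, y)$p.value
  } else {
    p <- with_seed(seed, {
      null <- replicate(n_perm, abs(stats::cor(x, sample(y))))
      (1 + sum(null >= abs(rho))) / (n_perm + 1)
    })
  }
  list(rho = rho, p = p, n = n, undefined = FALSE)
}
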