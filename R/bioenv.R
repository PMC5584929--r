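## BEST / BIOENV: exhaustive search for the environmental-variable subset
## whose Euclidean inter-sample distances maximally rank-correlate
## (Spearman, average ranks) with a biological resemblance matrix, plus a
## global permutation test that re-runs the full search on sample-permuted
## environmental tables.

## per-variable squared-difference columns over the lower triangle
env_sq_diff <- function(z) {
  apply(z, 2L, function(v) as.vector(stats::dist(v))^2)
}

## search all subsets up to max_size; returns max rho, argmax, per-size bests
bioenv_search <- function(sq, bio_rank, max_size) {
  p <- ncol(sq)
  vars <- colnames(sq)
  best_rho <- -Inf
  best_subset <- character(0)
  per_size <- vector("list", max_size)
  for (k in seq_len(max_size)) {
    combs <- utils::combn(p, k)
    rho_k <- apply(combs, 2L, function(idx) {
      e <- sqrt(rowSums(sq[, idx, drop = FALSE]))
      stats::cor(rank(e), bio_rank)
    })
    i <- which.max(rho_k)
    per_size[[k]] <- list(size = k, subset = vars[combs[, i]],
                          rho = rho_k[i])
    if (rho_k[i] > best_rho) {
      best_rho <- rho_k[i]
      best_subset <- vars[combs[, i]]
    }
  }
  list(rho = best_rho, subset = best_subset, per_size = per_size)
}

#' BEST / BIOENV environmental subset selection
#'
#' Exhaustively searches every non-empty subset of environmental variables
#' up to `max_subset_size`; each subset is scored by the Spearman rank
#' correlation (average ranks for ties) between the lower triangle of the
#' Euclidean distance matrix on the z-scored subset and that of the
#' biological resemblance matrix. The global permutation p re-runs the full
#' search on row-permuted environmental tables and compares maximal rho
#' values, accounting for the selection over subsets.
#'
#' @param d a `distance_matrix` (biological resemblance).
#' @param env data frame of numeric environmental variables, rows aligned
#'   with the samples of `d`; missing values are refused (impute or drop
#'   upstream). At most 20 variables (exhaustive search bound).
#' @param max_subset_size largest subset size searched (>= 1).
#' @param n_perm global-test permutations (0 skips the test).
#' @param seed RNG seed for the permutation test.
#' @return a `best_result`: `best_subset`, `rho`, `p_global`, `per_size`
#'   (data frame of the best subset at each size), `n_subsets_searched`.
#' @export
best_bioenv <- function(d, env, max_subset_size = 5, n_perm = 99, seed = 1) {
  if (max_subset_size < 1) stop_config("max_subset_size must be >= 1")
  env <- as.data.frame(env)
  if (anyNA(env))
    stop_data("missing environmental values are refused; impute or drop upstream")
  if (ncol(env) > 20L)
    stop_config("more than 20 candidate variables; exhaustive search refused")
  dm <- as.matrix(d)
  if (nrow(env) != nrow(dm)) stop_data("env rows must match the samples of d")
  if (!is.null(rownames(env)) && !is.null(rownames(dm)) &&
      all(rownames(dm) %in% rownames(env)))
    env <- env[rownames(dm), , drop = FALSE]
  max_subset_size <- min(max_subset_size, ncol(env))
  z <- scale(as.matrix(env))
  sq <- env_sq_diff(z)
  bio_rank <- rank(as.vector(stats::as.dist(dm)))
  obs <- bioenv_search(sq, bio_rank, max_subset_size)
  p_global <- NA_real_
  if (n_perm > 0) {
    p_global <- with_seed(seed, {
      null_max <- replicate(n_perm, {
        zp <- z[sample.int(nrow(z)), , drop = FALSE]
        bioenv_search(env_sq_diff(zp), bio_rank, max_subset_size)$rho
      })
      (1 + sum(null_max >= obs$rho)) / (n_perm + 1)
    })
  }
  per_size <- do.call(rbind, lapply(obs$per_size, function(x)
    data.frame(size = x$size, subset = paste(x$subset, collapse = ","),
               rho = x$rho, stringsAsFactors = FALSE)))
  structure(list(best_subset = obs$subset, rho = obs$rho,
                 p_global = p_global, per_size = per_size,
                 n_subsets_searched = sum(choose(ncol(env),
                                                 seq_len(max_subset_size)))),
            class = "best_result")
}

#' @export
print.best_result <- function(x, ...) {
  cat("BEST/BIOENV: rho =", signif(x$rho, 4), "for {",
      paste(x$best_subset, collapse = ", "), "}",
      if (!is.na(x$p_global)) paste("; global p =", signif(x$p_global, 3)),
      "\n")
  print(x$per_size)
  invisible(x)
}
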