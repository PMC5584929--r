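## Ordination: Bray-Curtis resemblance over transformed whole-genome
## expression, Kruskal non-metric MDS (stress-1, isotonic regression,
## multiple restarts), environmental vector fitting, and similarity-level
## group membership.

#' Bray-Curtis dissimilarity between samples
#'
#' `d(i, j) = sum|x_gi - x_gj| / sum(x_gi + x_gj)` over genes. A pair of
#' all-zero samples is defined as distance 0, with a warning.
#'
#' @param expr an [expression_matrix()] or non-negative matrix, genes in
#'   rows, samples in columns.
#' @return symmetric `distance_matrix` (zero diagonal, entries in `[0, 1]`)
#'   with sample labels as dimnames.
#' @export
bray_curtis <- function(expr) {
  vals <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  if (any(vals < 0)) stop_data("Bray-Curtis requires non-negative values")
  if (ncol(vals) < 2L) stop_data("at least 2 samples are required")
  ## vegdist warns about all-zero samples; the NaN case is handled below
  d <- suppressWarnings(as.matrix(vegan::vegdist(t(vals), method = "bray")))
  if (any(is.nan(d))) {
    warning("all-zero sample pair(s): Bray-Curtis defined as 0", call. = FALSE)
    d[is.nan(d)] <- 0
  }
  structure(d, class = c("distance_matrix", "matrix"))
}

## stress-1 with Kruskal's primary treatment of ties: monotone regression of
## configuration distances on dissimilarity order (ties ordered by distance)
stress1 <- function(delta, dvec, ord = order(dvec, delta)) {
  dhat <- numeric(length(delta))
  dhat[ord] <- stats::isoreg(delta[ord])$yf
  list(stress = sqrt(sum((delta - dhat)^2) / sum(delta^2)), dhat = dhat)
}

## Guttman transform step with step-halving fallback so the recorded
## stress-1 trace is non-increasing
nmds_single <- function(dvec, n, n_dim, init, max_iter, tol) {
  pair <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)  # (row > col)
  x <- init
  delta <- as.vector(stats::dist(x))
  if (all(delta == 0)) {
    x <- x + matrix(stats::rnorm(length(x), sd = 1e-6), n, n_dim)
    delta <- as.vector(stats::dist(x))
  }
  s <- stress1(delta, dvec)
  trace <- s$stress
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ratio <- ifelse(delta > 0, s$dhat / delta, 0)
    b <- matrix(0, n, n)
    b[pair] <- -ratio
    b <- b + t(b)
    diag(b) <- -rowSums(b)
    x_new <- (b %*% x) / n
    delta_new <- as.vector(stats::dist(x_new))
    s_new <- stress1(delta_new, dvec)
    tries <- 0L
    while (s_new$stress > s$stress && tries < 20L) {   # backtrack
      x_new <- (x + x_new) / 2
      delta_new <- as.vector(stats::dist(x_new))
      s_new <- stress1(delta_new, dvec)
      tries <- tries + 1L
    }
    if (s_new$stress > s$stress) { converged <- TRUE; break }
    improvement <- s$stress - s_new$stress
    x <- x_new; delta <- delta_new; s <- s_new
    trace <- c(trace, s$stress)
    if (improvement < tol) { converged <- TRUE; break }
  }
  list(points = x, stress = s$stress, trace = trace, converged = converged)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Iterative stress-1 minimisation with monotone (isotonic) regression of
#' configuration distances on dissimilarity ranks, a Guttman-transform
#' update with step-halving (so stress never increases within a restart),
#' and multiple restarts: the first from classical metric scaling, the rest
#' random (seeded). The best configuration is centred, rotated to its
#' principal axes and sign-fixed for reproducibility.
#'
#' @param d a `distance_matrix` (or symmetric matrix / `dist`).
#' @param n_dim embedding dimension, default 2.
#' @param n_restarts number of restarts, default 50.
#' @param max_iter,tol per-restart iteration cap and stress-improvement
#'   tolerance.
#' @param seed RNG seed for the random restarts.
#' @return an `ordination`: `points` (samples x n_dim), `stress` (the
#'   minimum across restarts), `stress_trace` of the best restart,
#'   `restarts_used`, `per_restart_stress`, `converged`.
#' @export
nmds <- function(d, n_dim = 2, n_restarts = 50, max_iter = 300,
                 tol = 1e-7, seed = 1) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 3L) stop_data("at least 3 samples are required for an nMDS")
  labels <- rownames(dm) %||% paste0("s", seq_len(n))
  dvec <- as.vector(stats::as.dist(dm))
  best <- NULL
  per_restart <- numeric(0)
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init <- if (r == 1L) {
        cm <- suppressWarnings(stats::cmdscale(dm, k = n_dim))
        if (ncol(cm) < n_dim)
          cm <- cbind(cm, matrix(stats::rnorm(n * (n_dim - ncol(cm)),
                                              sd = 1e-4), n))
        cm
      } else {
        matrix(stats::rnorm(n * n_dim), n, n_dim)
      }
      fit <- nmds_single(dvec, n, n_dim, init, max_iter, tol)
      per_restart[r] <- fit$stress
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
  })
  pts <- scale(best$points, scale = FALSE)
  rms <- sqrt(mean(rowSums(pts^2)))
  if (rms > 0) pts <- pts / rms            # stress-1 is scale-free
  rot <- stats::prcomp(pts, center = FALSE)$rotation
  pts <- pts %*% rot
  for (k in seq_len(ncol(pts)))                       # fix reflections
    if (pts[which.max(abs(pts[, k])), k] < 0) pts[, k] <- -pts[, k]
  dimnames(pts) <- list(labels, paste0("MDS", seq_len(n_dim)))
  if (!best$converged)
    warning("best nMDS restart stopped at the iteration cap before reaching ",
            "the stress tolerance", call. = FALSE)
  structure(list(points = pts, stress = best$stress,
                 stress_trace = best$trace, restarts_used = n_restarts,
                 per_restart_stress = per_restart,
                 converged = best$converged),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("ordination:", nrow(x$points), "samples in", ncol(x$points),
      "dimensions; stress-1 =", signif(x$stress, 4), "\n")
  invisible(x)
}

#' Fit environmental vectors onto an ordination
#'
#' For each environmental variable, the least-squares direction of the
#' (standardised) variable on the ordination plane, its multiple correlation
#' R, and a permutation p-value (variable shuffled across samples). Backed
#' by `vegan::vectorfit`; constant variables are skipped with a warning.
#'
#' @param ord an `ordination` from [nmds()].
#' @param env data frame of environmental variables, rows aligned with the
#'   ordination samples.
#' @param n_perm permutations, default 999.
#' @param seed RNG seed.
#' @return data frame `variable`, `dx`, `dy` (unit direction scaled by R),
#'   `R`, `p_value`.
#' @export
env_fit <- function(ord, env, n_perm = 999, seed = 1) {
  env <- as.data.frame(env)
  if (nrow(env) != nrow(ord$points))
    stop_data("env table does not cover the ordination samples")
  if (all(rownames(ord$points) %in% rownames(env)))
    env <- env[rownames(ord$points), , drop = FALSE]
  constant <- vapply(env, function(v) stats::sd(v) == 0, logical(1))
  if (any(constant)) {
    warning("skipping constant variable(s): ",
            paste(names(env)[constant], collapse = ", "), call. = FALSE)
    env <- env[, !constant, drop = FALSE]
  }
  ## degenerate (near-zero-variance) axes carry no geometry: excluding them
  ## keeps the least-squares direction from blowing up on numerical noise
  pts <- ord$points
  ax_sd <- apply(pts, 2L, stats::sd)
  keep_ax <- ax_sd > 1e-4 * max(ax_sd)
  fit <- with_seed(seed,
    vegan::vectorfit(pts[, keep_ax, drop = FALSE], scale(env),
                     permutations = n_perm))
  arrows <- matrix(0, nrow(fit$arrows), ncol(pts),
                   dimnames = list(rownames(fit$arrows), colnames(pts)))
  arrows[, keep_ax] <- fit$arrows           # unit direction cosines
  R <- sqrt(fit$r)
  data.frame(variable = rownames(arrows),
             dx = arrows[, 1] * R, dy = arrows[, 2] * R,
             R = R, p_value = fit$pvals, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Group membership at fixed similarity levels
#'
#' Average-linkage clustering of the resemblance matrix cut at the given
#' Bray-Curtis similarity thresholds (similarity = 1 - dissimilarity); the
#' tabular stand-in for similarity contours drawn on an nMDS plot.
#'
#' @param d a `distance_matrix`.
#' @param thresholds similarity levels in (0, 1), default 40/60/80%.
#' @return data frame: `sample` plus one membership column per threshold.
#' @export
similarity_groups <- function(d, thresholds = c(0.4, 0.6, 0.8)) {
  hc <- stats::hclust(stats::as.dist(as.matrix(d)), method = "average")
  out <- data.frame(sample = hc$labels, stringsAsFactors = FALSE)
  for (th in thresholds)
    out[[sprintf("sim_%d", round(th * 100))]] <-
      stats::cutree(hc, h = 1 - th)[hc$labels]
  out
}
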