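#' Build spatial weights from point coordinates
#'
#' Constructs an n-by-n spatial weight matrix from lon/lat points (WGS84
#' decimal degrees) using great-circle (haversine) distances.  `"knn"` links
#' each point to its `k` nearest neighbours (ties broken by record order);
#' `"inverse_distance"` weights every pair by `1/d`.  Row standardization
#' (the default) scales each row to sum to 1.
#'
#' @param coords Two-column matrix or data.frame of `lon`, `lat`.
#' @param scheme `"knn"` (default) or `"inverse_distance"`.
#' @param k Number of neighbours for `"knn"`; capped at `n - 1`.  Default 8.
#' @param row_standardize Scale rows to sum to 1 (default `TRUE`).
#' @return An object of class `"spatial_weights"`: the matrix `w`, the
#'   `scheme`, `k`, `row_standardized` flag and a one-line `spec`
#'   description.
#' @export
build_weights <- function(coords, scheme = c("knn", "inverse_distance"),
                          k = 8L, row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  coords <- as.matrix(coords[, 1:2])
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  d <- geosphere::distm(coords, fun = geosphere::distHaversine)
  if (all(d[upper.tri(d)] == 0)) {
    stop("all points are coincident; weights are undefined", call. = FALSE)
  }
  w <- matrix(0, n, n)
  if (scheme == "knn") {
    k <- min(as.integer(k), n - 1L)
    if (k < 1L) stop("k must be at least 1", call. = FALSE)
    for (i in seq_len(n)) {
      nn <- order(d[i, ])          # stable: ties broken by record order
      nn <- nn[nn != i][seq_len(k)]
      w[i, nn] <- 1
    }
  } else {
    w <- 1 / d
    diag(w) <- 0
    w[!is.finite(w)] <- 0          # coincident pairs get zero weight
  }
  if (row_standardize) {
    rs <- rowSums(w)
    rs[rs == 0] <- 1
    w <- w / rs
  }
  structure(list(w = w, scheme = scheme,
                 k = if (scheme == "knn") k else NA_integer_,
                 row_standardized = row_standardize,
                 spec = paste0(scheme,
                               if (scheme == "knn") paste0("(k=", k, ")"),
                               if (row_standardize) ", row-standardized",
                               ", haversine")),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("Spatial weights: ", nrow(x$w), " x ", ncol(x$w), ", ", x$spec, "\n",
      sep = "")
  invisible(x)
}

#' Global Moran's I with randomization inference
#'
#' Computes the textbook global Moran's I,
#' `I = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z = y - mean(y)`,
#' its expectation `-1/(n-1)` and its variance under the randomization
#' (permutation) assumption, giving a z-score and two-sided p-value.  An
#' optional Monte-Carlo permutation p-value is available via `n_perm`.
#'
#' @param values Numeric vector (non-constant).
#' @param weights A [build_weights()] object or an n-by-n weight matrix.
#' @param n_perm If non-`NULL`, also compute a two-sided permutation p-value
#'   from this many random relabelings.
#' @param seed Optional seed for the permutation p-value.
#' @return An object of class `"moran_result"`: `i_statistic`, `expected_i`,
#'   `variance_i`, `z_score`, `p_value` (analytic), `p_perm` (or `NA`),
#'   `n`, `weights_spec`.
#' @export
moran_i <- function(values, weights, n_perm = NULL, seed = NULL) {
  w <- if (inherits(weights, "spatial_weights")) weights$w else
    as.matrix(weights)
  spec <- if (inherits(weights, "spatial_weights")) weights$spec else
    "user-supplied matrix"
  y <- as.numeric(values)
  n <- length(y)
  if (n != nrow(w) || n != ncol(w)) {
    stop("length(values) must match the weight matrix dimension",
         call. = FALSE)
  }
  if (stats::var(y) == 0) stop("values are constant; Moran's I undefined",
                               call. = FALSE)
  z <- y - mean(y)
  s0 <- sum(w)
  obs_i <- function(zz) n / s0 * sum(w * tcrossprod(zz)) / sum(zz^2)
  i_stat <- obs_i(z)
  e_i <- -1 / (n - 1)
  s1 <- 0.5 * sum((w + t(w))^2)
  s2 <- sum((rowSums(w) + colSums(w))^2)
  b2 <- n * sum(z^4) / sum(z^2)^2
  var_i <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
            b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
           ((n - 1) * (n - 2) * (n - 3) * s0^2) - e_i^2
  z_score <- (i_stat - e_i) / sqrt(var_i)
  p <- 2 * stats::pnorm(-abs(z_score))
  p_perm <- NA_real_
  if (!is.null(n_perm)) {
    if (!is.null(seed)) {
      old <- get0(".Random.seed", globalenv(), inherits = FALSE)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    dev <- abs(i_stat - e_i)
    hits <- sum(vapply(seq_len(n_perm), function(b) {
      abs(obs_i(z[sample.int(n)]) - e_i) >= dev
    }, logical(1)))
    p_perm <- (1 + hits) / (1 + n_perm)
  }
  structure(list(i_statistic = i_stat, expected_i = e_i, variance_i = var_i,
                 z_score = z_score, p_value = p, p_perm = p_perm, n = n,
                 weights_spec = spec), class = "moran_result")
}

#' @export
print.moran_result <- function(x, digits = 4, ...) {
  cat("Global Moran's I: I = ", signif(x$i_statistic, digits),
      " (E[I] = ", signif(x$expected_i, digits), "), z = ",
      signif(x$z_score, digits), ", p = ", format.pval(x$p_value), "\n",
      "  n = ", x$n, ", weights: ", x$weights_spec,
      if (!is.na(x$p_perm)) paste0(", permutation p = ", x$p_perm),
      "\n", sep = "")
  invisible(x)
}

#' Moran's I spatial-dependence check on an accident table
#'
#' Convenience wrapper: builds k-nearest-neighbour row-standardized weights
#' from the record coordinates and tests the chosen outcome for global
#' spatial autocorrelation.  Positive I with `z > 2.58` indicates spatial
#' dependence at the 1% level, the usual basis for preferring spatially
#' aware models.
#'
#' @param table An [accident_table()].
#' @param outcome `"fatalities"` or `"injuries"`.
#' @param k Neighbours for the kNN weights (default 8).
#' @param scheme Passed to [build_weights()].
#' @param ... Passed to [moran_i()].
#' @return A `"moran_result"`.
#' @export
moran_test <- function(table, outcome = c("fatalities", "injuries"), k = 8L,
                       scheme = "knn", ...) {
  validate_accident_table(table)
  outcome <- match.arg(outcome)
  w <- build_weights(table$records[, c("lon", "lat")], scheme = scheme, k = k)
  moran_i(table$records[[outcome]], w, ...)
}
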