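#' The factor detector: q statistic of a stratification
#'
#' Decomposes the total sum of squared deviations of an outcome into within-
#' and between-strata parts and returns `q = 1 - SSW/SST`, the share of the
#' outcome's spatial stratified heterogeneity explained by the stratification.
#' Variances are population variances (divisor `N_h`, `N`), so
#' `SST = N * sigma^2` and `SSW = sum(N_h * sigma_h^2)` agree exactly with the
#' sum-of-squares form.  `q = 0` means the stratification explains nothing;
#' `q = 1` means it determines the outcome completely.  Records with a missing
#' value or a missing stratum assignment are dropped.
#'
#' @param values Numeric outcome, one value per record.
#' @param strat A [stratify()] result, or any vector of stratum labels of the
#'   same length.
#' @return An object of class `"q_result"`: `q`, `sst`, `ssw`, `per_stratum`
#'   (label, n, mean, population variance), `n_used`, `degenerate` (`TRUE`
#'   when `SST = 0`, in which case `q = 0` by convention) and `p_value`
#'   (`NA` until filled by [q_significance()] or [qdetect()]).
#' @examples
#' compute_q(c(1, 2, 3, 4), c("A", "A", "B", "B"))  # q = 0.8
#' @export
compute_q <- function(values, strat) {
  strat <- as_stratification(strat)
  values <- as.numeric(values)
  if (length(values) != length(strat$assignment)) {
    stop("'values' and stratification cover different numbers of records",
         call. = FALSE)
  }
  if (any(is.infinite(values)) || any(is.nan(values))) {
    stop("non-finite outcome values", call. = FALSE)
  }
  keep <- !is.na(values) & !is.na(strat$assignment)
  y <- values[keep]
  g <- strat$assignment[keep]
  n <- length(y)
  if (n < 2L) stop("need at least 2 usable records", call. = FALSE)
  sums <- rowsum(y, g)
  sq <- rowsum(y^2, g)
  n_h <- as.integer(rowsum(rep(1L, n), g))
  labels <- rownames(sums)
  means <- sums[, 1L] / n_h
  ss_h <- sq[, 1L] - sums[, 1L]^2 / n_h     # within-stratum sum of squares
  ssw <- sum(ss_h)
  sst <- sum(y^2) - sum(y)^2 / n
  degenerate <- sst <= 0
  q <- if (degenerate) 0 else min(max(1 - ssw / sst, 0), 1)
  structure(list(
    q = q, sst = sst, ssw = ssw,
    per_stratum = data.frame(label = labels, n = n_h, mean = unname(means),
                             var = unname(ss_h / n_h),
                             stringsAsFactors = FALSE, row.names = NULL),
    n_used = n, degenerate = degenerate, p_value = NA_real_,
    source = strat$source), class = "q_result")
}

#' @export
print.q_result <- function(x, digits = 4, ...) {
  cat("q-statistic (", paste(x$source, collapse = " ∩ "), "): q = ",
      signif(x$q, digits), "  [explains ", signif(100 * x$q, digits),
      "% of heterogeneity]\n", sep = "")
  cat("  strata: ", nrow(x$per_stratum), ", records: ", x$n_used,
      ", SSW/SST = ", signif(x$ssw, digits), "/", signif(x$sst, digits),
      if (!is.na(x$p_value)) paste0(", p = ", format.pval(x$p_value)),
      if (x$degenerate) "  (degenerate: SST = 0)", "\n", sep = "")
  invisible(x)
}

#' Significance of an observed q value
#'
#' Default method is a permutation test: stratum assignments are randomly
#' relabelled `n_perm` times and `p = (1 + #\{q_perm >= q_obs\}) /
#' (1 + n_perm)`.  The alternative `"noncentral_f"` method is the analytic
#' test in which `F = (N-H)/(H-1) * q/(1-q)` is referred to a noncentral F
#' distribution with `H-1` and `N-H` degrees of freedom; it is offered as a
#' cross-check.  A degenerate outcome (`SST = 0`) returns `p = 1`.
#'
#' @param values,strat As in [compute_q()].
#' @param method `"permutation"` (default) or `"noncentral_f"`.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional integer seed giving a reproducible permutation p;
#'   the caller's RNG state is restored afterwards.
#' @return A single p-value in (0, 1].
#' @export
q_significance <- function(values, strat,
                           method = c("permutation", "noncentral_f"),
                           n_perm = 999L, seed = NULL) {
  method <- match.arg(method)
  strat <- as_stratification(strat)
  qr <- compute_q(values, strat)
  if (qr$degenerate) return(1)
  if (method == "noncentral_f") return(q_noncentral_f_p(qr))
  if (n_perm < 99L) stop("n_perm must be at least 99", call. = FALSE)
  keep <- !is.na(values) & !is.na(strat$assignment)
  y <- as.numeric(values)[keep]
  g <- factor(strat$assignment[keep])
  n <- length(y)
  idx <- as.integer(g)
  n_h <- tabulate(idx)
  # q_perm >= q_obs  <=>  sum_h S_h^2 / N_h >= observed between-group mass,
  # because sum(y^2) and SST are permutation-invariant.
  stat <- function(yy) sum(rowsum(yy, idx)[, 1L]^2 / n_h)
  obs <- stat(y)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  hits <- 0L
  tol <- 1e-12 * max(1, abs(obs))
  for (b in seq_len(n_perm)) {
    if (stat(y[sample.int(n)]) >= obs - tol) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

# Analytic q-significance: noncentral-F transform of q.
q_noncentral_f_p <- function(qr) {
  H <- nrow(qr$per_stratum)
  n <- qr$n_used
  if (H < 2L || n <= H) return(1)
  q <- min(qr$q, 1 - 1e-12)
  f_val <- (n - H) / (H - 1) * q / (1 - q)
  sigma2 <- qr$sst / n
  m <- qr$per_stratum$mean
  n_h <- qr$per_stratum$n
  lambda <- (sum(n_h * m^2) - sum(sqrt(n_h) * m)^2 / n) / sigma2
  stats::pf(f_val, H - 1, n - H, ncp = lambda, lower.tail = FALSE)
}

#' The influence (risk) detector: pairwise stratum-mean comparisons
#'
#' For every unordered pair of strata with at least two members each, tests
#' whether the stratum means of the outcome differ, using the Welch t
#' statistic `t = (m_a - m_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Satterthwaite degrees of freedom.  High-risk strata are those whose mean
#' outcome is significantly higher than others'.
#'
#' @param values,strat As in [compute_q()].
#' @param confidence Confidence level for the `significant` flag
#'   (default 0.95).
#' @param p_adjust Multiple-testing adjustment passed to [stats::p.adjust()];
#'   default `"none"` (per-pair comparisons), `"BH"` available.
#' @return An object of class `"risk_comparison"`: data.frame `pairs` with
#'   one row per comparison (`stratum_a`, `stratum_b`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `t_statistic`, `df`, `p_value`, `significant`), plus
#'   `confidence` and `stratum_means`.
#' @export
risk_detector <- function(values, strat, confidence = 0.95,
                          p_adjust = "none") {
  stopifnot(confidence > 0, confidence < 1)
  strat <- as_stratification(strat)
  keep <- !is.na(values) & !is.na(strat$assignment)
  y <- as.numeric(values)[keep]
  g <- strat$assignment[keep]
  labs <- sort(unique(g))
  n_h <- vapply(labs, function(l) sum(g == l), integer(1))
  m_h <- vapply(labs, function(l) mean(y[g == l]), numeric(1))
  v_h <- vapply(labs, function(l) stats::var(y[g == l]), numeric(1))
  eligible <- labs[n_h >= 2L]
  if (length(eligible) < 2L) {
    warning("fewer than 2 strata with >= 2 members; no comparisons",
            call. = FALSE)
    pairs <- data.frame(stratum_a = character(), stratum_b = character(),
                        n_a = integer(), n_b = integer(),
                        mean_a = numeric(), mean_b = numeric(),
                        t_statistic = numeric(), df = numeric(),
                        p_value = numeric(), significant = logical(),
                        stringsAsFactors = FALSE)
  } else {
    cmb <- utils::combn(eligible, 2L)
    one <- function(a, b) {
      ia <- match(a, labs); ib <- match(b, labs)
      se2a <- v_h[ia] / n_h[ia]; se2b <- v_h[ib] / n_h[ib]
      denom <- se2a + se2b
      t_stat <- if (denom > 0) (m_h[ia] - m_h[ib]) / sqrt(denom) else 0
      df <- if (denom > 0) {
        denom^2 / (se2a^2 / (n_h[ia] - 1) + se2b^2 / (n_h[ib] - 1))
      } else {
        n_h[ia] + n_h[ib] - 2
      }
      p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
      c(t_stat, df, p)
    }
    res <- t(apply(cmb, 2L, function(ab) one(ab[1L], ab[2L])))
    p_adj <- stats::p.adjust(res[, 3L], method = p_adjust)
    ia <- match(cmb[1L, ], labs); ib <- match(cmb[2L, ], labs)
    pairs <- data.frame(stratum_a = cmb[1L, ], stratum_b = cmb[2L, ],
                        n_a = n_h[ia], n_b = n_h[ib],
                        mean_a = unname(m_h[ia]), mean_b = unname(m_h[ib]),
                        t_statistic = res[, 1L], df = res[, 2L],
                        p_value = p_adj,
                        significant = p_adj < (1 - confidence),
                        stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(pairs = pairs, confidence = confidence,
                 stratum_means = data.frame(label = labs, n = unname(n_h),
                                            mean = unname(m_h),
                                            stringsAsFactors = FALSE),
                 source = strat$source), class = "risk_comparison")
}

#' @export
print.risk_comparison <- function(x, digits = 4, ...) {
  cat("Risk detector (", paste(x$source, collapse = " ∩ "), "), ",
      nrow(x$pairs), " stratum pairs at ", 100 * x$confidence,
      "% confidence; ", sum(x$pairs$significant), " significant\n", sep = "")
  if (nrow(x$pairs)) {
    print(cbind(x$pairs[, c("stratum_a", "stratum_b")],
                round(x$pairs[, c("mean_a", "mean_b", "t_statistic", "df",
                                  "p_value")], digits),
                significant = x$pairs$significant), row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.risk_comparison <- function(x, ...) x$pairs

#' The ecological detector: which of two factors explains more?
#'
#' Compares the within-strata variance sums of two stratifications of the
#' same outcome via `F = N_a (N_b - 1) SSW_a / (N_b (N_a - 1) SSW_b)`,
#' referred (two-sided) to an F distribution with `(N_a - 1, N_b - 1)`
#' degrees of freedom.  When the difference is significant, the factor with
#' the smaller within-strata variance sum is reported as dominant.
#'
#' @param values Numeric outcome.
#' @param strat_a,strat_b Two stratifications over the same records.
#' @param confidence Confidence level (default 0.95).
#' @return An object of class `"eco_result"`: `f_statistic`, `df_num`,
#'   `df_den`, `p_value`, `dominant` (a factor name or `"tie"`), `ssw_a`,
#'   `ssw_b`, `infinite` flag.
#' @export
ecological_detector <- function(values, strat_a, strat_b, confidence = 0.95) {
  strat_a <- as_stratification(strat_a)
  strat_b <- as_stratification(strat_b)
  qa <- compute_q(values, strat_a)
  qb <- compute_q(values, strat_b)
  n_a <- qa$n_used; n_b <- qb$n_used
  name_a <- paste(strat_a$source, collapse = " ∩ ")
  name_b <- paste(strat_b$source, collapse = " ∩ ")
  infinite <- qb$ssw <= 0
  f_stat <- if (infinite) Inf else
    (n_a * (n_b - 1) * qa$ssw) / (n_b * (n_a - 1) * qb$ssw)
  p <- if (infinite) 0 else {
    lo <- stats::pf(f_stat, n_a - 1, n_b - 1)
    min(1, 2 * min(lo, 1 - lo))
  }
  dominant <- if (p < (1 - confidence)) {
    if (qa$ssw < qb$ssw) name_a else name_b
  } else "tie"
  structure(list(f_statistic = f_stat, df_num = n_a - 1, df_den = n_b - 1,
                 p_value = p, dominant = dominant,
                 ssw_a = qa$ssw, ssw_b = qb$ssw,
                 factor_a = name_a, factor_b = name_b, infinite = infinite),
            class = "eco_result")
}

#' @export
print.eco_result <- function(x, digits = 4, ...) {
  cat("Ecological detector: ", x$factor_a, " vs ", x$factor_b, "\n",
      "  F = ", signif(x$f_statistic, digits), " (df ", x$df_num, ", ",
      x$df_den, "), p = ", format.pval(x$p_value), ", dominant: ",
      x$dominant, if (x$infinite) "  (denominator SSW = 0)", "\n", sep = "")
  invisible(x)
}

#' Overlay (superposition) of two stratifications
#'
#' The common refinement whose strata are the observed joint categories of
#' two stratifications; cells with no records simply do not appear.  Records
#' missing in either input stratification are missing in the overlay.
#'
#' @param strat_a,strat_b Stratifications over the same record set.
#' @return A `"stratification"` whose `source` is the union of the inputs'
#'   sources.
#' @export
overlay <- function(strat_a, strat_b) {
  strat_a <- as_stratification(strat_a)
  strat_b <- as_stratification(strat_b)
  if (length(strat_a$assignment) != length(strat_b$assignment)) {
    stop("stratifications cover different numbers of records", call. = FALSE)
  }
  joint <- ifelse(is.na(strat_a$assignment) | is.na(strat_b$assignment),
                  NA_character_,
                  paste(strat_a$assignment, strat_b$assignment, sep = " & "))
  new_stratification(source = union(strat_a$source, strat_b$source),
                     assignment = joint)
}

interaction_types <- c("Weaken, nonlinear", "Weaken, single", "Enhance, bi",
                       "Independent", "Enhance, nonlinear")

#' Classify the interaction of two factors from their q values
#'
#' Given `q_a = q(X1)`, `q_b = q(X2)` and `q_ab = q(X1 ∩ X2)` (the overlay),
#' assigns the interaction type:
#' \describe{
#'   \item{Independent}{`q_ab = q_a + q_b` within `tolerance`.}
#'   \item{Enhance, nonlinear}{`q_ab > q_a + q_b`.}
#'   \item{Weaken, nonlinear}{`q_ab < min(q_a, q_b)`.}
#'   \item{Enhance, bi}{`q_ab >= max(q_a, q_b)` (and below the sum).}
#'   \item{Weaken, single}{`min(q_a, q_b) <= q_ab < max(q_a, q_b)`.}
#' }
#' The rules are checked in that order, so the classification is total and
#' deterministic on all of `[0,1]^3`; exact ties with the min or max resolve
#' to the adjacent category nearer Independence.
#'
#' @param q_a,q_b,q_ab q values in `[0, 1]`.
#' @param tolerance Half-width of the Independence band (default `1e-9`).
#' @return An object of class `"interaction_result"`: `q_a`, `q_b`, `q_ab`,
#'   `q_sum`, `type`.
#' @examples
#' classify_interaction(0.094, 0.042, 0.178)$type  # "Enhance, nonlinear"
#' @export
classify_interaction <- function(q_a, q_b, q_ab, tolerance = 1e-9) {
  for (q in c(q_a, q_b, q_ab)) {
    if (!is.finite(q) || q < 0 || q > 1) {
      stop("q values must lie in [0, 1]", call. = FALSE)
    }
  }
  q_sum <- q_a + q_b
  type <- if (abs(q_ab - q_sum) <= tolerance) {
    "Independent"
  } else if (q_ab > q_sum) {
    "Enhance, nonlinear"
  } else if (q_ab < min(q_a, q_b)) {
    "Weaken, nonlinear"
  } else if (q_ab >= max(q_a, q_b)) {
    "Enhance, bi"
  } else {
    "Weaken, single"
  }
  structure(list(q_a = q_a, q_b = q_b, q_ab = q_ab, q_sum = q_sum,
                 type = type, tolerance = tolerance,
                 factors = c("X1", "X2")),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, digits = 4, ...) {
  cat("Interaction ", x$factors[1L], " ∩ ", x$factors[2L], ": ",
      x$type, "\n  q(X1) = ", signif(x$q_a, digits), ", q(X2) = ",
      signif(x$q_b, digits), ", q(X1∩X2) = ", signif(x$q_ab, digits),
      ", q(X1)+q(X2) = ", signif(x$q_sum, digits), "\n", sep = "")
  invisible(x)
}

#' The interaction detector
#'
#' Computes `q` for each of two stratifications and for their overlay, then
#' classifies the interaction with [classify_interaction()].  Because the
#' overlay is a common refinement of both inputs, `q_ab >= max(q_a, q_b)` up
#' to numerical tolerance, so Weaken types cannot arise from a true overlay.
#'
#' @param values Numeric outcome.
#' @param strat_a,strat_b Stratifications over the same records.
#' @param tolerance Passed to [classify_interaction()].
#' @return An `"interaction_result"` whose `factors` element names the two
#'   sources.
#' @export
interaction_detector <- function(values, strat_a, strat_b, tolerance = 1e-9) {
  strat_a <- as_stratification(strat_a)
  strat_b <- as_stratification(strat_b)
  both <- overlay(strat_a, strat_b)
  # evaluate all three q's over the records usable in the overlay, so the
  # refinement inequality holds even under factor-specific missingness
  mask <- ifelse(is.na(both$assignment), NA_character_, "")
  q_a <- compute_q(values, sub_strat(strat_a, mask))
  q_b <- compute_q(values, sub_strat(strat_b, mask))
  q_ab <- compute_q(values, both)
  out <- classify_interaction(q_a$q, q_b$q, q_ab$q, tolerance)
  out$factors <- c(paste(strat_a$source, collapse = " ∩ "),
                   paste(strat_b$source, collapse = " ∩ "))
  out
}

# Restrict a stratification to records where 'mask' is non-NA.
sub_strat <- function(strat, mask) {
  a <- strat$assignment
  a[is.na(mask)] <- NA_character_
  new_stratification(strat$source, a)
}
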