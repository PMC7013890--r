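#' Full stratified-heterogeneity analysis of an accident table
#'
#' Reproduces the shape of the published analysis: the records are split
#' into the fatality group (analysed on fatalities) and the injuries-only
#' group (analysed on injuries); per group the pipeline runs a Moran's I
#' spatial-dependence check, factor detection over every coded factor with
#' significance masking at `alpha`, risk detection (pairwise stratum-mean
#' comparisons) for each significant factor, the interaction detector over
#' all unordered factor pairs — including masked factors, since combinations
#' of individually non-significant factors can be significant — with
#' type-share summaries, and (optionally) a secondary combined-factor
#' detection with top-k ranking.
#'
#' @param table An [accident_table()].
#' @param alpha Masking significance level (default 0.05).
#' @param n_perm Permutations for q significance (default 999).
#' @param seed Seed for all randomness in the report (default 1).
#' @param combine Optional character pair of factor names for the secondary
#'   combined-factor detection (e.g. `c("primary_cause",
#'   "responsible_party")`).
#' @param top_k Rows in the combined ranking (default 10).
#' @param moran_k Neighbours for the Moran weights (default 8).
#' @param run_interactions Compute the all-pairs interaction matrix
#'   (default `TRUE`).
#' @return An object of class `"accident_report"`: per-outcome lists with
#'   `moran`, `factor_table`, `risk_tables`, `interaction_matrix`,
#'   `interaction_shares` and `combined`, plus `settings` and `diagnostics`.
#' @export
run_analysis <- function(table, alpha = 0.05, n_perm = 999L, seed = 1L,
                         combine = NULL, top_k = 10L, moran_k = 8L,
                         run_interactions = TRUE) {
  validate_accident_table(table)
  split <- split_groups(table)
  groups <- list(fatalities = split$group1, injuries = split$group2)
  out <- list()
  for (oc in names(groups)) {
    g <- groups[[oc]]
    if (is.null(g)) {
      warning("empty group for outcome '", oc, "'; section omitted",
              call. = FALSE)
      next
    }
    fit <- qdetect(stats::as.formula(paste(oc, "~ .")), g, n_perm = n_perm,
                   seed = seed, alpha = alpha)
    ft <- fit$factor_table
    y <- g$records[[oc]]
    risk <- list()
    for (fn in ft$factor[!ft$masked]) {
      risk[[fn]] <- risk_detector(y, stratify(g, fn),
                                  confidence = 1 - alpha)
    }
    imat <- NULL
    shares <- NULL
    if (run_interactions && nrow(ft) >= 2L) {
      pairs <- utils::combn(ft$factor, 2L)
      rows <- lapply(seq_len(ncol(pairs)), function(j) {
        a <- pairs[1L, j]; b <- pairs[2L, j]
        ir <- interaction_detector(y, stratify(g, a), stratify(g, b))
        data.frame(factor_a = a, factor_b = b, q_a = ir$q_a, q_b = ir$q_b,
                   q_ab = ir$q_ab, q_sum = ir$q_sum, type = ir$type,
                   stringsAsFactors = FALSE)
      })
      imat <- do.call(rbind, rows)
      imat <- imat[order(-imat$q_ab), ]
      rownames(imat) <- NULL
      shares <- interaction_type_shares(imat)
    }
    combined <- NULL
    if (!is.null(combine)) {
      combined <- combined_detection(g, combine[1L], combine[2L],
                                     outcome = oc, top_k = top_k,
                                     confidence = 1 - alpha)
    }
    out[[oc]] <- list(moran = moran_test(g, oc, k = moran_k),
                      factor_table = ft, risk_tables = risk,
                      interaction_matrix = imat,
                      interaction_shares = shares, combined = combined)
  }
  structure(list(outcomes = out,
                 settings = list(alpha = alpha, n_perm = n_perm, seed = seed,
                                 combine = combine, top_k = top_k,
                                 moran_k = moran_k),
                 diagnostics = list(n = split$n, excluded = split$excluded,
                                    n_group1 = if (is.null(split$group1)) 0L
                                               else nrow(split$group1$records),
                                    n_group2 = if (is.null(split$group2)) 0L
                                               else nrow(split$group2$records))),
            class = "accident_report")
}

#' @export
print.accident_report <- function(x, digits = 3, ...) {
  d <- x$diagnostics
  cat("Accident severity report: ", d$n, " records (group 1: ", d$n_group1,
      ", group 2: ", d$n_group2, ", excluded: ", d$excluded, ")\n", sep = "")
  for (oc in names(x$outcomes)) {
    sec <- x$outcomes[[oc]]
    cat("\n== Outcome: ", oc, " ==\n", sep = "")
    cat("Moran's I = ", signif(sec$moran$i_statistic, digits), " (z = ",
        signif(sec$moran$z_score, digits), ", p = ",
        format.pval(sec$moran$p_value), ")\n", sep = "")
    ft <- sec$factor_table[order(-sec$factor_table$q), ]
    cat("Factor table (q masked when p > alpha):\n")
    print(data.frame(factor = ft$factor,
                     q = ifelse(ft$masked, "-",
                                format(round(ft$q, digits))),
                     p_value = format(round(ft$p_value, digits))),
          row.names = FALSE)
    if (!is.null(sec$interaction_shares)) {
      sh <- sec$interaction_shares[sec$interaction_shares > 0]
      cat("Interaction type shares: ",
          paste0(names(sh), " ", round(100 * sh, 1), "%", collapse = "; "),
          "\n", sep = "")
    }
    if (!is.null(sec$combined)) {
      cat("Top combined-factor strata:\n")
      print(utils::head(sec$combined$ranking, 5), row.names = FALSE,
            digits = digits)
    }
  }
  invisible(x)
}

#' Secondary detection of a combined factor with top-k ranking
#'
#' Overlays two factors and ranks the resulting joint strata by mean
#' outcome; each stratum is annotated with whether its mean is significantly
#' higher than that of all remaining records (one-sided Welch comparison).
#' This mirrors the "top 10 high-risk behaviours" analysis of combined
#' primary cause and responsible party.
#'
#' @param table An [accident_table()].
#' @param factor_a,factor_b Factor names to combine.
#' @param outcome `"fatalities"` or `"injuries"`.
#' @param top_k Strata to return (all if fewer; default 10).
#' @param confidence Confidence level for the one-sided flag (default 0.95).
#' @param min_n Smallest stratum size considered (default 2).
#' @return An object of class `"combined_ranking"`: `ranking` data.frame
#'   (rank, stratum, n, mean, t_statistic, df, p_value,
#'   significantly_higher) and the inputs.
#' @export
combined_detection <- function(table, factor_a, factor_b,
                               outcome = c("fatalities", "injuries"),
                               top_k = 10L, confidence = 0.95, min_n = 2L) {
  validate_accident_table(table)
  outcome <- match.arg(outcome)
  y <- table$records[[outcome]]
  strat <- overlay(stratify(table, factor_a), stratify(table, factor_b))
  keep <- !is.na(strat$assignment)
  yk <- y[keep]; gk <- strat$assignment[keep]
  cells <- strat$strata[strat$strata$n >= min_n, , drop = FALSE]
  if (nrow(cells) == 0L) {
    stop("no overlay stratum reaches the minimum size of ", min_n,
         call. = FALSE)
  }
  rows <- lapply(cells$label, function(lab) {
    in_cell <- gk == lab
    a <- yk[in_cell]; b <- yk[!in_cell]
    if (length(a) >= 2L && length(b) >= 2L &&
        isTRUE(stats::var(a) + stats::var(b) > 0)) {
      se2a <- stats::var(a) / length(a); se2b <- stats::var(b) / length(b)
      t_stat <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
      df <- (se2a + se2b)^2 /
        (se2a^2 / (length(a) - 1) + se2b^2 / (length(b) - 1))
      p <- stats::pt(t_stat, df, lower.tail = FALSE)   # one-sided: higher?
    } else {
      t_stat <- 0; df <- NA_real_; p <- 1
    }
    data.frame(stratum = lab, n = length(a), mean = mean(a),
               t_statistic = t_stat, df = df, p_value = p,
               significantly_higher = p < (1 - confidence),
               stringsAsFactors = FALSE)
  })
  rk <- do.call(rbind, rows)
  rk <- rk[order(-rk$mean, rk$stratum), ]
  rk <- utils::head(rk, top_k)
  rk$rank <- seq_len(nrow(rk))
  rk <- rk[, c("rank", setdiff(names(rk), "rank"))]
  rownames(rk) <- NULL
  structure(list(ranking = rk, factors = c(factor_a, factor_b),
                 outcome = outcome, confidence = confidence),
            class = "combined_ranking")
}

#' @export
print.combined_ranking <- function(x, digits = 4, ...) {
  cat("Combined-factor detection: ", x$factors[1L], " ∩ ", x$factors[2L],
      " on ", x$outcome, " (top ", nrow(x$ranking), ")\n", sep = "")
  print(x$ranking, row.names = FALSE, digits = digits)
  invisible(x)
}

#' Shares of interaction types in an interaction matrix
#'
#' @param matrix The `interaction_matrix` data.frame of [run_analysis()] (or
#'   any data.frame with a `type` column).
#' @return Named numeric vector over the five interaction types, summing
#'   to 1.
#' @export
interaction_type_shares <- function(matrix) {
  if (is.null(matrix) || nrow(matrix) == 0L) {
    stop("empty interaction matrix", call. = FALSE)
  }
  counts <- table(factor(matrix$type, levels = interaction_types))
  stats::setNames(as.numeric(counts) / sum(counts), interaction_types)
}

#' Write a report to CSV tables and a JSON bundle
#'
#' One CSV per report table (factor tables, risk-comparison pairs,
#' interaction matrices, combined rankings) plus a single JSON bundle with
#' everything including the settings and seed for provenance.
#'
#' @param report An [run_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "accident_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(settings = report$settings, diagnostics = report$diagnostics)
  for (oc in names(report$outcomes)) {
    sec <- report$outcomes[[oc]]
    utils::write.csv(sec$factor_table,
                     file.path(dir, paste0("factor_table_", oc, ".csv")),
                     row.names = FALSE)
    if (!is.null(sec$interaction_matrix)) {
      utils::write.csv(sec$interaction_matrix,
                       file.path(dir, paste0("interactions_", oc, ".csv")),
                       row.names = FALSE)
    }
    for (fn in names(sec$risk_tables)) {
      utils::write.csv(sec$risk_tables[[fn]]$pairs,
                       file.path(dir, paste0("risk_", oc, "_", fn, ".csv")),
                       row.names = FALSE)
    }
    if (!is.null(sec$combined)) {
      utils::write.csv(sec$combined$ranking,
                       file.path(dir, paste0("combined_", oc, ".csv")),
                       row.names = FALSE)
    }
    bundle[[oc]] <- list(
      moran = unclass(sec$moran),
      factor_table = sec$factor_table,
      interaction_matrix = sec$interaction_matrix,
      interaction_shares = as.list(sec$interaction_shares),
      risk = lapply(sec$risk_tables, function(r) r$pairs),
      combined = if (!is.null(sec$combined)) sec$combined$ranking)
  }
  jsonlite::write_json(bundle, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null", na = "null")
  invisible(dir)
}
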