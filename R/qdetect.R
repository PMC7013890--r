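#' Fit the factor detector across candidate factors
#'
#' The headline fitting interface: given a formula such as
#' `fatalities ~ primary_cause + zones` (or `fatalities ~ .` for every coded
#' factor) and an [accident_table()] (or plain data.frame), computes the q
#' statistic of each candidate factor's stratification of the outcome
#' together with its significance, and returns a classed model object with
#' the usual accessor methods.  A factor "explains" `100 * q` percent of the
#' outcome's stratified heterogeneity; factors whose q fails the
#' significance test at `alpha` are flagged as masked.
#'
#' @param formula Outcome on the left; candidate factors (or `.`) on the
#'   right.
#' @param data An [accident_table()] or a data.frame whose candidate columns
#'   are category codes.
#' @param n_perm Permutations for the significance test (default 999).
#' @param seed Optional seed making the permutation p-values reproducible;
#'   the caller's RNG state is restored.
#' @param alpha Masking level for `summary()` and downstream reports
#'   (default 0.05).
#' @param method Significance method, `"permutation"` or `"noncentral_f"`.
#' @return An object of class `"qdetect"` with methods [print.qdetect()],
#'   [summary.qdetect()], [coef.qdetect()], [plot.qdetect()],
#'   [predict.qdetect()], [fitted.qdetect()] and [residuals.qdetect()].
#' @examples
#' tab <- generate(make_preset("interaction_demo"))
#' fit <- qdetect(injuries ~ factor_a + factor_b, tab, n_perm = 199,
#'                seed = 1)
#' coef(fit)
#' @export
qdetect <- function(formula, data, n_perm = 999L, seed = NULL, alpha = 0.05,
                    method = c("permutation", "noncentral_f")) {
  method <- match.arg(method)
  cl <- match.call()
  is_table <- inherits(data, "accident_table")
  df <- if (is_table) data$records else as.data.frame(data)
  outcome <- all.vars(formula[[2]])
  if (length(outcome) != 1L || !outcome %in% names(df)) {
    stop("formula must have a single outcome present in the data",
         call. = FALSE)
  }
  rhs <- attr(stats::terms(formula,
                           data = if (is_table) {
                             df[, c(outcome, names(data$coding)),
                                drop = FALSE]
                           } else df[, setdiff(names(df), outcome),
                                     drop = FALSE]),
              "term.labels")
  rhs <- rhs[!grepl(":", rhs, fixed = TRUE)]
  if (!length(rhs)) stop("no candidate factors on the right-hand side",
                         call. = FALSE)
  y <- df[[outcome]]
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  results <- list()
  for (fn in rhs) {
    strat <- if (is_table && (fn %in% names(data$coding) || fn == "year")) {
      stratify(data, fn)
    } else {
      new_stratification(fn, ifelse(is.na(df[[fn]]), NA_character_,
                                    paste0(fn, "=", df[[fn]])))
    }
    qr <- compute_q(y, strat)
    qr$p_value <- q_significance(y, strat, method = method, n_perm = n_perm)
    results[[fn]] <- qr
  }
  tab <- data.frame(
    factor = rhs,
    q = vapply(results, `[[`, numeric(1), "q"),
    p_value = vapply(results, `[[`, numeric(1), "p_value"),
    n_strata = vapply(results, function(r) nrow(r$per_stratum), integer(1)),
    n_used = vapply(results, `[[`, integer(1), "n_used"),
    stringsAsFactors = FALSE, row.names = NULL)
  tab$masked <- tab$p_value > alpha
  structure(list(call = cl, outcome = outcome, results = results,
                 factor_table = tab, alpha = alpha, n_perm = n_perm,
                 method = method, data = data, y = y),
            class = "qdetect")
}

#' @export
print.qdetect <- function(x, digits = 4, ...) {
  cat("Factor detection of '", x$outcome, "' (", x$method, " test, alpha = ",
      x$alpha, ")\n", sep = "")
  tab <- x$factor_table[order(-x$factor_table$q), ]
  shown <- data.frame(factor = tab$factor,
                      q = ifelse(tab$masked, "-",
                                 format(round(tab$q, digits))),
                      p_value = format(round(tab$p_value, digits)),
                      stringsAsFactors = FALSE)
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Summarise a factor-detection fit
#'
#' @param object A [qdetect()] fit.
#' @param ... Unused.
#' @return The factor table (factor, q, p_value, n_strata, n_used, masked),
#'   sorted by decreasing q, with an `explained_pct` column (`100 * q`).
#' @export
summary.qdetect <- function(object, ...) {
  tab <- object$factor_table[order(-object$factor_table$q), ]
  tab$explained_pct <- 100 * tab$q
  rownames(tab) <- NULL
  class(tab) <- c("summary.qdetect", "data.frame")
  tab
}

#' @export
print.summary.qdetect <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.qdetect <- function(object, ...) {
  stats::setNames(object$factor_table$q, object$factor_table$factor)
}

#' Barplot of explanatory power per factor
#'
#' @param x A [qdetect()] fit.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.qdetect <- function(x, ...) {
  tab <- x$factor_table[order(x$factor_table$q), ]
  graphics::barplot(tab$q, names.arg = tab$factor, horiz = TRUE, las = 1,
                    col = ifelse(tab$masked, "grey80", "steelblue"),
                    xlab = "q (share of heterogeneity explained)", ...)
  invisible(x)
}

best_factor <- function(object) {
  tab <- object$factor_table
  tab$factor[which.max(ifelse(tab$masked, -Inf, tab$q))]
}

#' Fitted stratum means of a detection fit
#'
#' The q model's prediction for a record is the mean outcome of its stratum
#' under the chosen factor (default: the highest unmasked q).
#'
#' @param object A [qdetect()] fit.
#' @param factor Factor name; default the best unmasked factor.
#' @param ... Unused.
#' @return Numeric vector of per-record stratum means (`NA` for records
#'   missing the factor).
#' @export
fitted.qdetect <- function(object, factor = NULL, ...) {
  if (is.null(factor)) factor <- best_factor(object)
  qr <- object$results[[factor]]
  if (is.null(qr)) stop("factor '", factor, "' not in the fit", call. = FALSE)
  assign_means(object, factor, qr)
}

assign_means <- function(object, factor, qr,
                         df = NULL) {
  if (is.null(df)) {
    df <- if (inherits(object$data, "accident_table")) object$data$records
          else object$data
  }
  labels <- paste0(factor, "=", df[[factor]])
  labels[is.na(df[[factor]])] <- NA_character_
  qr$per_stratum$mean[match(labels, qr$per_stratum$label)]
}

#' @export
residuals.qdetect <- function(object, factor = NULL, ...) {
  object$y - fitted.qdetect(object, factor = factor)
}

#' Predict stratum-mean outcomes for new records
#'
#' @param object A [qdetect()] fit.
#' @param newdata Data.frame (or accident table) containing the factor
#'   column; default the training data.
#' @param factor Factor to predict from; default the best unmasked factor.
#' @param ... Unused.
#' @return Per-record predicted means; `NA` (with a warning) for category
#'   codes unseen during fitting.
#' @export
predict.qdetect <- function(object, newdata = NULL, factor = NULL, ...) {
  if (is.null(factor)) factor <- best_factor(object)
  qr <- object$results[[factor]]
  if (is.null(qr)) stop("factor '", factor, "' not in the fit", call. = FALSE)
  df <- if (is.null(newdata)) NULL else {
    if (inherits(newdata, "accident_table")) newdata$records else
      as.data.frame(newdata)
  }
  out <- assign_means(object, factor, qr, df = df)
  if (!is.null(df) && anyNA(out) && !all(is.na(df[[factor]]))) {
    warning("some category codes were unseen during fitting; NA returned",
            call. = FALSE)
  }
  out
}
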