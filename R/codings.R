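#' Declare the category coding of a single factor
#'
#' A factor coding names an explanatory factor and enumerates its admissible
#' integer category codes with human-readable labels.  Every factor column of
#' an [accident_table()] is validated against its coding.
#'
#' @param name Factor identifier, e.g. `"primary_cause"`.
#' @param codes Integer vector of admissible category codes (unique, at least
#'   two).
#' @param labels Character vector of category labels, same length as `codes`.
#' @return An object of class `"factor_coding"`.
#' @examples
#' factor_coding("topography", 1:3, c("Plain", "Hill", "Mountain"))
#' @export
factor_coding <- function(name, codes, labels = as.character(codes)) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  codes <- as.integer(codes)
  if (anyNA(codes)) stop("category codes must be integers", call. = FALSE)
  if (anyDuplicated(codes)) {
    stop("category codes for '", name, "' must be unique", call. = FALSE)
  }
  if (length(codes) < 2L) {
    stop("factor '", name, "' needs at least 2 categories", call. = FALSE)
  }
  if (length(labels) != length(codes)) {
    stop("labels and codes must have equal length", call. = FALSE)
  }
  structure(list(name = name, codes = codes, labels = as.character(labels)),
            class = "factor_coding")
}

#' @export
print.factor_coding <- function(x, ...) {
  cat("Factor coding '", x$name, "' (", length(x$codes), " categories)\n",
      sep = "")
  cat(paste0("  ", x$codes, " = ", x$labels), sep = "\n")
  invisible(x)
}

#' Read a set of factor codings from JSON
#'
#' The JSON layout is `{"factors": [{"name": ..., "categories":
#' [{"code": ..., "label": ...}, ...]}, ...]}`; [shenzhen_codings()] reads the
#' coding file shipped with the package.
#'
#' @param path Path to a codings JSON file.
#' @return A named list of [factor_coding()] objects.
#' @export
read_codings_json <- function(path) {
  spec <- jsonlite::read_json(path)
  if (is.null(spec$factors)) stop("no 'factors' entry in ", path, call. = FALSE)
  out <- lapply(spec$factors, function(f) {
    codes <- vapply(f$categories, function(cc) as.integer(cc$code), integer(1))
    labels <- vapply(f$categories, function(cc) as.character(cc$label),
                     character(1))
    factor_coding(f$name, codes, labels)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Category codings of the 17 Shenzhen accident factors
#'
#' Returns the codings of the 17 categorical factors used in the Shenzhen
#' traffic-accident severity analysis (geographical zones, time of occurrence,
#' road factors, management status, environment condition and traffic
#' violations), as shipped in `extdata/shenzhen_factor_codings.json`.
#'
#' @return A named list of 17 [factor_coding()] objects.
#' @examples
#' names(shenzhen_codings())
#' @export
shenzhen_codings <- function() {
  read_codings_json(system.file("extdata", "shenzhen_factor_codings.json",
                                package = "qdetect", mustWork = TRUE))
}
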