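#' 2x2 exposure-by-outcome table
#'
#' The substrate of every association statistic in the package. Cells follow
#' the epidemiological convention: `a` = exposed cases, `b` = exposed
#' controls, `c` = unexposed cases, `d` = unexposed controls. For the
#' homozygosity analysis "exposed" means homozygous at the focal locus and
#' "case" means disease-positive.
#'
#' @param a,b,c,d Non-negative integer cell counts; their sum must be
#'   positive.
#' @return An object of class `table2x2`, a named list with elements
#'   `a`, `b`, `c`, `d` and `n` (the total).
#' @examples
#' table2x2(1, 0, 6, 26)
#' @export
table2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop("table2x2 cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) <= 0) {
    stop("table2x2 must contain at least one observation", call. = FALSE)
  }
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c), d = as.numeric(d),
                 n = as.numeric(a + b + c + d)),
            class = "table2x2")
}

#' @export
print.table2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(exposure = c("exposed", "unexposed"),
                              outcome = c("case", "control")))
  print(m)
  invisible(x)
}

#' @export
as.matrix.table2x2 <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), 2, 2,
         dimnames = list(exposure = c("exposed", "unexposed"),
                         outcome = c("case", "control")))
}

#' Stratified collection of 2x2 tables
#'
#' An ordered set of [table2x2] objects, one per stratum (for the per-allele
#' analysis, one stratum per allele carried). Strata need not be independent:
#' when strata are defined by allele carriage, a heterozygote appears in two
#' strata.
#'
#' @param tables A list of [table2x2] objects.
#' @param labels Optional character vector of stratum labels.
#' @return An object of class `stratified_tables`.
#' @export
stratified_tables <- function(tables, labels = NULL) {
  if (length(tables) < 1L) stop("need at least one stratum", call. = FALSE)
  ok <- vapply(tables, inherits, logical(1), what = "table2x2")
  if (!all(ok)) stop("all strata must be table2x2 objects", call. = FALSE)
  if (is.null(labels)) labels <- as.character(seq_along(tables))
  if (length(labels) != length(tables)) {
    stop("labels must match the number of strata", call. = FALSE)
  }
  structure(list(tables = tables, labels = as.character(labels)),
            class = "stratified_tables")
}

#' @export
print.stratified_tables <- function(x, ...) {
  cat(sprintf("stratified_tables: %d strata (%s)\n",
              length(x$tables), paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' @export
length.stratified_tables <- function(x) length(x$tables)

# Internal: stratum cell counts as a K x 4 matrix (a, b, c, d columns).
strata_matrix <- function(strata) {
  stopifnot(inherits(strata, "stratified_tables"))
  t(vapply(strata$tables, function(s) c(s$a, s$b, s$c, s$d), numeric(4)))
}

#' Association test result
#'
#' Container for the output of the association statistics. Not usually
#' constructed by hand.
#'
#' @param odds_ratio Point estimate of the odds ratio (may be `NA` for pure
#'   test procedures such as the homogeneity test).
#' @param ci_low,ci_high 95\% confidence limits.
#' @param p_value Two-sided p-value in \[0, 1\].
#' @param method One of `"glm_lrt"`, `"fisher"`, `"cmh"`, `"tarone"`.
#' @param statistic Test statistic (chi-squared where applicable).
#' @param df Degrees of freedom of the reference distribution, if any.
#' @param corrected `TRUE` when the Haldane-Anscombe zero-cell correction
#'   was applied to the estimate and its interval.
#' @return An object of class `assoc_result`.
#' @export
assoc_result <- function(odds_ratio = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, p_value = NA_real_,
                         method, statistic = NA_real_, df = NA_real_,
                         corrected = FALSE) {
  method <- match.arg(method, c("glm_lrt", "fisher", "cmh", "tarone"))
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    stop("p-value outside [0, 1]", call. = FALSE)
  }
  structure(list(odds_ratio = odds_ratio, ci_low = ci_low, ci_high = ci_high,
                 p_value = p_value, method = method, statistic = statistic,
                 df = df, corrected = corrected),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("assoc_result [%s]%s\n", x$method,
              if (isTRUE(x$corrected)) " (zero-cell corrected)" else ""))
  if (!is.na(x$odds_ratio)) {
    cat(sprintf("  OR = %.4g (95%% CI %.4g, %.4g)\n",
                x$odds_ratio, x$ci_low, x$ci_high))
  }
  if (!is.na(x$statistic)) {
    cat(sprintf("  statistic = %.4g%s\n", x$statistic,
                if (!is.na(x$df)) sprintf(" on %g df", x$df) else ""))
  }
  cat(sprintf("  p = %.4g\n", x$p_value))
  invisible(x)
}
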