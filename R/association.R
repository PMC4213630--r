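#' Homozygosity-by-disease 2x2 table
#'
#' Cross-tabulates homozygosity at the focal locus against case/control
#' status: `a` = homozygous cases, `b` = homozygous controls,
#' `c` = heterozygous cases, `d` = heterozygous controls.
#'
#' @param records A genotype table as returned by [read_genotype_table()] or
#'   [sample_genotypes()] (with status assigned).
#' @return A [table2x2].
#' @export
build_homozygosity_table <- function(records) {
  records <- validate_genotypes(records)
  hom <- records$allele_a == records$allele_b
  case <- records$status == "case"
  table2x2(sum(hom & case), sum(hom & !case),
           sum(!hom & case), sum(!hom & !case))
}

#' Per-allele carriage strata
#'
#' One stratum per allele observed in the data. Stratum *i* contains every
#' animal carrying at least one copy of allele *i*; within the stratum the
#' exposure is homozygosity for allele *i*. A heterozygote *i*,*j* therefore
#' contributes (as unexposed) to both stratum *i* and stratum *j*, so strata
#' share animals and are not independent — the Mantel-Haenszel machinery is
#' applied to them as a descriptive pooling device, mirroring how per-allele
#' homozygosity is conventionally summarised.
#'
#' @inheritParams build_homozygosity_table
#' @return A [stratified_tables] with one stratum per observed allele, in
#'   sorted allele order.
#' @export
build_allele_strata <- function(records) {
  records <- validate_genotypes(records)
  alleles <- sort(unique(c(records$allele_a, records$allele_b)))
  tabs <- list(); labs <- character(0)
  for (al in alleles) {
    carrier <- records$allele_a == al | records$allele_b == al
    if (!any(carrier)) next
    sub <- records[carrier, , drop = FALSE]
    hom <- sub$allele_a == al & sub$allele_b == al
    case <- sub$status == "case"
    tabs[[length(tabs) + 1L]] <- table2x2(
      sum(hom & case), sum(hom & !case),
      sum(!hom & case), sum(!hom & !case))
    labs <- c(labs, al)
  }
  stratified_tables(tabs, labs)
}

#' Odds ratio from a logit-link binomial model
#'
#' Fits the two-parameter logistic model (intercept plus a binary exposure
#' indicator) to a 2x2 table by iteratively reweighted least squares and
#' reports the exposure odds ratio `exp(beta)`, a 95\% Wald interval, and a
#' likelihood-ratio p-value against chi-squared on 1 df. With all cells
#' positive the fitted OR equals the sample cross-product ratio `ad/bc`.
#'
#' When any cell is zero the maximum-likelihood estimate is on the boundary;
#' the Haldane-Anscombe correction (add 0.5 to all four cells) is then used
#' for the point estimate and interval, the LRT p-value is still computed
#' from the uncorrected fit, and the result is flagged `corrected = TRUE`.
#'
#' @param table A [table2x2].
#' @return An [assoc_result] with `method = "glm_lrt"`.
#' @examples
#' fit_logit_or(table2x2(20, 10, 10, 20))  # OR = 4
#' @export
fit_logit_or <- function(table) {
  stopifnot(inherits(table, "table2x2"))
  dat <- data.frame(exposed = c(1, 0),
                    cases = c(table$a, table$c),
                    ctrls = c(table$b, table$d))
  fit <- suppressWarnings(stats::glm(
    cbind(cases, ctrls) ~ exposed, family = stats::binomial(),
    data = dat, control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  null <- suppressWarnings(stats::glm(
    cbind(cases, ctrls) ~ 1, family = stats::binomial(),
    data = dat, control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  lrt <- max(0, null$deviance - fit$deviance)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  zero_cell <- any(c(table$a, table$b, table$c, table$d) == 0)
  if (zero_cell) {
    a <- table$a + 0.5; b <- table$b + 0.5
    c_ <- table$c + 0.5; d <- table$d + 0.5
    log_or <- log(a * d / (b * c_))
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  } else {
    log_or <- unname(stats::coef(fit)["exposed"])
    se <- unname(sqrt(diag(stats::vcov(fit))["exposed"]))
  }
  assoc_result(odds_ratio = exp(log_or),
               ci_low = exp(log_or - 1.96 * se),
               ci_high = exp(log_or + 1.96 * se),
               p_value = p, method = "glm_lrt", statistic = lrt, df = 1,
               corrected = zero_cell)
}

#' Two-sided Fisher exact test
#'
#' Exact test of association in a 2x2 table by the probability method: the
#' p-value is the sum, over all tables with the observed margins, of the
#' hypergeometric probabilities no larger than that of the observed table
#' (up to a relative tolerance of 1e-7 to absorb floating-point ties).
#'
#' @param table A [table2x2].
#' @return An [assoc_result] with `method = "fisher"` and the conditional
#'   maximum-likelihood odds ratio and exact interval from
#'   [stats::fisher.test()] attached when the margins allow them.
#' @examples
#' fisher_exact_two_sided(table2x2(1, 0, 6, 26))  # p = 0.212
#' @export
fisher_exact_two_sided <- function(table) {
  stopifnot(inherits(table, "table2x2"))
  m <- table$a + table$c        # case column total
  nn <- table$b + table$d       # control column total
  k <- table$a + table$b        # exposed row total
  if (m == 0 || nn == 0 || k == 0 || k == table$n) {
    # degenerate margins: only one table is possible
    return(assoc_result(odds_ratio = NA_real_, p_value = 1,
                        method = "fisher"))
  }
  support <- max(0, k - nn):min(k, m)
  probs <- stats::dhyper(support, m, nn, k)
  p_obs <- stats::dhyper(table$a, m, nn, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  ft <- stats::fisher.test(as.matrix(table))
  assoc_result(odds_ratio = unname(ft$estimate),
               ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
               p_value = p, method = "fisher")
}

#' Mantel-Haenszel common odds ratio
#'
#' Pooled odds ratio over strata, `sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`,
#' with a 95\% interval from the Robins-Breslow-Greenland variance of the
#' log common OR.
#'
#' @param strata A [stratified_tables].
#' @return An [assoc_result] with `method = "cmh"` (no test statistic; see
#'   [cmh_chi2()] for the test).
#' @export
mh_common_or <- function(strata) {
  m <- strata_matrix(strata)
  a <- m[, 1]; b <- m[, 2]; cc <- m[, 3]; d <- m[, 4]
  n <- a + b + cc + d
  R_i <- a * d / n; S_i <- b * cc / n
  R <- sum(R_i); S <- sum(S_i)
  if (R == 0 || S == 0) {
    stop("Mantel-Haenszel odds ratio undefined: a zero numerator or ",
         "denominator across all strata", call. = FALSE)
  }
  or <- R / S
  P_i <- (a + d) / n; Q_i <- (b + cc) / n
  var_log <- sum(P_i * R_i) / (2 * R^2) +
    sum(P_i * S_i + Q_i * R_i) / (2 * R * S) +
    sum(Q_i * S_i) / (2 * S^2)
  se <- sqrt(var_log)
  assoc_result(odds_ratio = or,
               ci_low = exp(log(or) - 1.96 * se),
               ci_high = exp(log(or) + 1.96 * se),
               p_value = NA_real_, method = "cmh")
}

#' Cochran-Mantel-Haenszel chi-squared test
#'
#' Stratified test of conditional independence:
#' `(|sum(a_i - E_i)| - 0.5 * continuity)^2 / sum(V_i)` with `E_i` and `V_i`
#' the hypergeometric mean and variance of the exposed-case cell given the
#' stratum margins, referred to chi-squared on 1 df. The continuity
#' correction is on by default.
#'
#' @param strata A [stratified_tables].
#' @param continuity Apply the 0.5 continuity correction (default `TRUE`).
#' @return An [assoc_result] with `method = "cmh"`, carrying the statistic,
#'   p-value, and the Mantel-Haenszel common OR and its interval.
#' @export
cmh_chi2 <- function(strata, continuity = TRUE) {
  m <- strata_matrix(strata)
  a <- m[, 1]; b <- m[, 2]; cc <- m[, 3]; d <- m[, 4]
  n <- a + b + cc + d
  E <- (a + b) * (a + cc) / n
  keep <- n > 1
  V <- ifelse(keep,
              (a + b) * (cc + d) * (a + cc) * (b + d) / (n^2 * (n - 1)),
              0)
  sumV <- sum(V)
  if (sumV <= 0) {
    stop("degenerate strata: zero total hypergeometric variance",
         call. = FALSE)
  }
  dev <- abs(sum(a - E)) - if (continuity) 0.5 else 0
  stat <- max(0, dev)^2 / sumV
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  est <- tryCatch(mh_common_or(strata), error = function(e) NULL)
  assoc_result(odds_ratio = if (is.null(est)) NA_real_ else est$odds_ratio,
               ci_low = if (is.null(est)) NA_real_ else est$ci_low,
               ci_high = if (is.null(est)) NA_real_ else est$ci_high,
               p_value = p, method = "cmh", statistic = stat, df = 1)
}

# Internal: expected exposed-case cell under a common odds ratio psi, with
# the stratum margins fixed. Root of
#   (1 - psi) x^2 + (n - r1 - c1 + psi (r1 + c1)) x - psi r1 c1 = 0
# inside [max(0, r1 + c1 - n), min(r1, c1)].
expected_cell_common_or <- function(a, b, cc, d, psi) {
  r1 <- a + b; c1 <- a + cc; n <- a + b + cc + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  if (abs(psi - 1) < 1e-12) {
    return(r1 * c1 / n)
  }
  A <- 1 - psi
  B <- n - r1 - c1 + psi * (r1 + c1)
  C <- -psi * r1 * c1
  disc <- sqrt(max(0, B^2 - 4 * A * C))
  roots <- c((-B + disc) / (2 * A), (-B - disc) / (2 * A))
  ok <- roots >= lo - 1e-8 & roots <= hi + 1e-8
  if (!any(ok)) stop("no admissible root for expected cell", call. = FALSE)
  min(max(roots[ok][1], lo), hi)
}

#' Breslow-Day-Tarone test of odds-ratio homogeneity
#'
#' Tests whether the stratum-specific odds ratios share a common value. The
#' Breslow-Day statistic is evaluated at the Mantel-Haenszel common OR: for
#' each stratum the expected exposed-case cell under the common OR solves a
#' quadratic in the fixed margins, and the squared standardised residuals
#' are summed. Tarone's correction term
#' `(sum(a_i - atilde_i))^2 / sum(Var(atilde_i))` is subtracted, and the
#' statistic is referred to chi-squared on K - 1 df over the K estimable
#' strata.
#'
#' Strata whose margins make the odds ratio inestimable (an empty row or
#' column) carry no information about homogeneity and are dropped; at least
#' two estimable strata are required.
#'
#' @param strata A [stratified_tables].
#' @return An [assoc_result] with `method = "tarone"`.
#' @export
tarone_homogeneity <- function(strata) {
  m <- strata_matrix(strata)
  a <- m[, 1]; b <- m[, 2]; cc <- m[, 3]; d <- m[, 4]
  n <- a + b + cc + d
  estimable <- (a + b) > 0 & (cc + d) > 0 & (a + cc) > 0 & (b + d) > 0
  if (sum(estimable) < 2) {
    stop("fewer than 2 strata with estimable odds ratios", call. = FALSE)
  }
  keep <- which(estimable)
  psi <- mh_common_or(stratified_tables(strata$tables[keep],
                                        strata$labels[keep]))$odds_ratio
  atil <- vtil <- numeric(length(keep))
  for (i in seq_along(keep)) {
    j <- keep[i]
    atil[i] <- expected_cell_common_or(a[j], b[j], cc[j], d[j], psi)
    r1 <- a[j] + b[j]; c1 <- a[j] + cc[j]; nj <- n[j]
    cells <- c(atil[i], r1 - atil[i], c1 - atil[i], nj - r1 - c1 + atil[i])
    cells <- pmax(cells, 1e-12)
    vtil[i] <- 1 / sum(1 / cells)
  }
  resid <- a[keep] - atil
  bd <- sum(resid^2 / vtil)
  stat <- max(0, bd - sum(resid)^2 / sum(vtil))
  df <- length(keep) - 1
  assoc_result(odds_ratio = psi, p_value =
                 stats::pchisq(stat, df = df, lower.tail = FALSE),
               method = "tarone", statistic = stat, df = df)
}

#' Run the full association stage on a genotype table
#'
#' Convenience wrapper producing a tidy data frame of every association
#' statistic: the pooled homozygosity OR (logistic LRT and Fisher exact),
#' and the per-allele stratified analysis (Mantel-Haenszel common OR,
#' continuity-corrected CMH chi-squared, Tarone homogeneity, and each
#' stratum's own OR).
#'
#' @inheritParams build_homozygosity_table
#' @param continuity Continuity correction for the CMH test.
#' @return A data frame with columns `analysis`, `stratum`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `statistic`, `df`, `p_value`, `corrected`.
#' @export
associate_homozygosity <- function(records, continuity = TRUE) {
  tab <- build_homozygosity_table(records)
  strata <- build_allele_strata(records)
  rows <- list()
  push <- function(analysis, stratum, r) {
    rows[[length(rows) + 1L]] <<- data.frame(
      analysis = analysis, stratum = stratum,
      odds_ratio = r$odds_ratio, ci_low = r$ci_low, ci_high = r$ci_high,
      statistic = r$statistic, df = r$df, p_value = r$p_value,
      corrected = isTRUE(r$corrected), stringsAsFactors = FALSE)
  }
  push("homozygosity_glm_lrt", "pooled", fit_logit_or(tab))
  push("homozygosity_fisher", "pooled", fisher_exact_two_sided(tab))
  push("mh_common_or", "all_alleles", mh_common_or(strata))
  push("cmh_chi2", "all_alleles", cmh_chi2(strata, continuity = continuity))
  tar <- tryCatch(tarone_homogeneity(strata), error = function(e) NULL)
  if (!is.null(tar)) push("tarone_homogeneity", "all_alleles", tar)
  for (i in seq_along(strata$tables)) {
    push("allele_glm_lrt", strata$labels[i], fit_logit_or(strata$tables[[i]]))
  }
  do.call(rbind, rows)
}
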