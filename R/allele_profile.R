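#' Case counts per genotype
#'
#' Tallies, for each observed unordered genotype, the number of cases `k`
#' and the total number of animals `n` carrying that genotype.
#'
#' @inheritParams build_homozygosity_table
#' @return A data frame with columns `genotype` (label "a/b" with alleles
#'   sorted), `allele_a`, `allele_b`, `k`, `n`; `sum(n)` equals the number
#'   of records and `sum(k)` the number of cases.
#' @export
genotype_counts <- function(records) {
  records <- validate_genotypes(records)
  lo <- pmin(records$allele_a, records$allele_b)
  hi <- pmax(records$allele_a, records$allele_b)
  g <- paste(lo, hi, sep = "/")
  ord <- order(lo, hi)
  keys <- unique(g[ord])
  out <- data.frame(genotype = keys,
                    allele_a = sub("/.*", "", keys),
                    allele_b = sub(".*/", "", keys),
                    k = as.integer(tapply(records$status == "case", g,
                                          sum)[keys]),
                    n = as.integer(table(g)[keys]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Grid-based binomial risk profile for one genotype
#'
#' Builds the distribution of the case probability for a genotype observed
#' in `k` cases out of `n` animals, on a fixed probability grid (default
#' 0.00 to 0.99 in steps of 0.01, never extrapolating to 1). In the default
#' `"likelihood"` mode the binomial point probability `Binom(k; n, p)` is
#' evaluated at each grid point and normalised — equivalently, a posterior
#' under a uniform prior on the grid. Mode `"cdf"` instead spreads mass
#' proportional to the cumulative `P(X <= k; n, p)`. The median and the
#' 2.5th/97.5th percentile limits are read off the discrete cumulative
#' weight function at its first crossing of 0.5, 0.025 and 0.975
#' (a deterministic, conservative tie-break).
#'
#' @param k Number of cases with the genotype.
#' @param n Total number of animals with the genotype (`n >= 1`).
#' @param grid Probability grid (ordered, within \[0, 1)).
#' @param mode `"likelihood"` (default) or `"cdf"`.
#' @param genotype Optional genotype label carried into the result.
#' @return An object of class `risk_profile`: list with `genotype`, `k`,
#'   `n`, `grid`, `weights` (summing to 1), `median_p`, `lcl`, `ucl`.
#' @examples
#' binomial_profile(0, 50)$median_p  # 0.01
#' @export
binomial_profile <- function(k, n, grid = seq(0, 0.99, by = 0.01),
                             mode = c("likelihood", "cdf"),
                             genotype = NA_character_) {
  mode <- match.arg(mode)
  if (n < 1) stop("undefined profile: n must be >= 1", call. = FALSE)
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE) || any(grid < 0) || any(grid >= 1)) {
    stop("grid must be strictly increasing within [0, 1)", call. = FALSE)
  }
  w <- switch(mode,
              likelihood = stats::dbinom(k, n, grid),
              cdf = stats::pbinom(k, n, grid))
  if (sum(w) <= 0) stop("all grid weights are zero", call. = FALSE)
  w <- w / sum(w)
  cw <- cumsum(w)
  first_cross <- function(q) grid[which(cw >= q - 1e-12)[1]]
  structure(list(genotype = genotype, k = as.integer(k), n = as.integer(n),
                 grid = grid, weights = w,
                 median_p = first_cross(0.5),
                 lcl = first_cross(0.025),
                 ucl = first_cross(0.975),
                 mode = mode),
            class = "risk_profile")
}

#' @export
print.risk_profile <- function(x, ...) {
  cat(sprintf("risk_profile %s: k = %d / n = %d, median = %.2f (%.2f, %.2f)\n",
              if (is.na(x$genotype)) "" else x$genotype,
              x$k, x$n, x$median_p, x$lcl, x$ucl))
  invisible(x)
}

#' Risk profiles for every observed genotype
#'
#' @inheritParams build_homozygosity_table
#' @inheritParams binomial_profile
#' @return A list of `risk_profile` objects, one per observed genotype.
#' @export
genotype_profiles <- function(records, grid = seq(0, 0.99, by = 0.01),
                              mode = c("likelihood", "cdf")) {
  mode <- match.arg(mode)
  counts <- genotype_counts(records)
  lapply(seq_len(nrow(counts)), function(i) {
    binomial_profile(counts$k[i], counts$n[i], grid = grid, mode = mode,
                     genotype = counts$genotype[i])
  })
}

#' Rank genotype risk profiles and call overlaps with the top profile
#'
#' Sorts profiles by median probability (descending) and, for the
#' top-ranked profile, lists every other genotype whose median lies at or
#' above the top profile's lower confidence limit — the interval-overlap
#' criterion used to judge whether the apparently riskiest genotype is
#' distinguishable from the rest.
#'
#' @param profiles A list of at least two `risk_profile` objects.
#' @return A list with `ranking` (data frame: genotype, k, n, median_p,
#'   lcl, ucl, sorted by median descending, ties broken by genotype label)
#'   and `overlaps_top` (character vector of genotypes overlapping the top
#'   profile).
#' @export
compare_profiles <- function(profiles) {
  if (length(profiles) < 2) stop("need at least two profiles", call. = FALSE)
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(genotype = p$genotype, k = p$k, n = p$n,
               median_p = p$median_p, lcl = p$lcl, ucl = p$ucl,
               stringsAsFactors = FALSE)
  }))
  df <- df[order(-df$median_p, df$genotype), , drop = FALSE]
  rownames(df) <- NULL
  top <- df[1, ]
  rest <- df[-1, , drop = FALSE]
  list(ranking = df,
       overlaps_top = rest$genotype[rest$median_p >= top$lcl])
}

#' Plot genotype risk profiles
#'
#' Point-and-interval plot of the per-genotype median case probabilities
#' with their 2.5th/97.5th percentile limits.
#'
#' @param profiles A list of `risk_profile` objects.
#' @param ... Passed to [graphics::plot()].
#' @return The ranking data frame, invisibly.
#' @export
plot_profiles <- function(profiles, ...) {
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(genotype = p$genotype, median_p = p$median_p,
               lcl = p$lcl, ucl = p$ucl, stringsAsFactors = FALSE)
  }))
  x <- seq_len(nrow(df))
  graphics::plot(x, df$median_p, ylim = c(0, 1), xaxt = "n", pch = 19,
                 xlab = "genotype", ylab = "case probability", ...)
  graphics::axis(1, at = x, labels = df$genotype)
  graphics::segments(x, df$lcl, x, df$ucl)
  invisible(df)
}
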