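# Independent oracles and fixture builders shared across the suite.

# Random 2x2 table with total at most n_max (at least one observation).
random_table <- function(n_max = 30, min_cell = 0) {
  repeat {
    cells <- as.integer(rmultinom(1, sample(4:n_max, 1), rep(0.25, 4)))
    if (min_cell > 0 && any(cells < min_cell)) next
    if (sum(cells) > 0) {
      return(table2x2(cells[1], cells[2], cells[3], cells[4]))
    }
  }
}

random_strata <- function(K = 3, n_max = 60) {
  stratified_tables(replicate(K, random_table(n_max, min_cell = 1),
                              simplify = FALSE))
}

# Two-sided Fisher p by explicit enumeration of the hypergeometric support,
# written independently of the package's implementation.
fisher_enum_p <- function(tab) {
  m <- as.matrix(tab)
  row1 <- sum(m[1, ]); col1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, row1 + col1 - n):min(row1, col1)
  probs <- vapply(support, function(x) {
    choose(col1, x) * choose(n - col1, row1 - x) / choose(n, row1)
  }, numeric(1))
  obs <- probs[match(m[1, 1], support)]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Direct-formula Mantel-Haenszel common OR by independent summation.
mh_or_direct <- function(strata) {
  num <- den <- 0
  for (t in strata$tables) {
    num <- num + t$a * t$d / t$n
    den <- den + t$b * t$c / t$n
  }
  num / den
}

# Direct-formula CMH chi-squared statistic.
cmh_stat_direct <- function(strata, continuity = TRUE) {
  dev <- sumV <- 0
  for (t in strata$tables) {
    dev <- dev + t$a - (t$a + t$b) * (t$a + t$c) / t$n
    sumV <- sumV + (t$a + t$b) * (t$c + t$d) * (t$a + t$c) * (t$b + t$d) /
      (t$n^2 * (t$n - 1))
  }
  max(0, abs(dev) - if (continuity) 0.5 else 0)^2 / sumV
}

# Exhaustive global-alignment score by plain recursion (tiny inputs only).
brute_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(a) && j > length(b)) return(0)
    if (i > length(a)) return(gap * (length(b) - j + 1))
    if (j > length(b)) return(gap * (length(a) - i + 1))
    max((if (a[i] == b[j]) match else mismatch) + rec(i + 1, j + 1),
        gap + rec(i + 1, j),
        gap + rec(i, j + 1))
  }
  rec(1, 1)
}

# Minimal genotype data frame from compact genotype strings like "1/2".
make_records <- function(genotypes, statuses, studies = "A",
                         ids = sprintf("a%02d", seq_along(genotypes))) {
  parts <- strsplit(genotypes, "/")
  data.frame(animal_id = ids, status = statuses,
             study = rep_len(studies, length(genotypes)),
             allele_a = vapply(parts, `[`, "", 1),
             allele_b = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
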