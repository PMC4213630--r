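test_that("repeat parsing anchors on the leftmost AC run", {
  s <- paste0("GG", strrep("AC", 7), strrep("CA", 15), strrep("C", 5), "TT")
  rs <- parse_repeat_structure(s)
  expect_equal(rs$lead_ac, 7L)
  expect_equal(rs$ca_n, 15L)
  expect_equal(rs$poly_c, 5L)
  expect_equal(rs$anchor_offset, 2L)
  # degenerate pure-AC input under the greedy rule
  rs2 <- parse_repeat_structure("ACACAC")
  expect_equal(unlist(rs2[c("lead_ac", "ca_n", "poly_c")]),
               c(lead_ac = 3L, ca_n = 0L, poly_c = 0L))
  expect_error(parse_repeat_structure("GGGTTT"), "no \\(AC\\)")
  # motif reconstruction round-trips through the parser
  motif <- repeat_motif(rs)
  expect_equal(nchar(motif), 2 * 7 + 2 * 15 + 5)
  rs3 <- parse_repeat_structure(motif)
  expect_equal(rs3[c("lead_ac", "ca_n", "poly_c")],
               rs[c("lead_ac", "ca_n", "poly_c")])
})

test_that("generated repeat sequences invert exactly for random constructs", {
  set.seed(111)
  for (i in 1:100) {
    ca <- sample(0:30, 1)
    pc <- sample(0:8, 1)
    s <- make_repeat_sequence("x", ca, flank_lengths = sample(5:40, 2),
                              poly_c = pc, seed = i)
    rs <- parse_repeat_structure(s)
    expect_equal(rs$lead_ac, 7L)
    expect_equal(rs$ca_n, ca)
    expect_equal(rs$poly_c, pc)
  }
})

test_that("sliding-window identity equals brute-force column counts", {
  ident <- strrep("ACGT", 75)
  tr <- sliding_identity(c(ident, ident), window = 100)
  expect_true(all(tr$values == 100))
  expect_equal(tr$coordinates, 1:201)
  # exactly half the columns matching -> 50%
  a <- paste0(strrep("A", 50), strrep("C", 50))
  b <- paste0(strrep("A", 50), strrep("G", 50))
  expect_equal(sliding_identity(c(a, b), window = 100)$values, 50)
  # random pair vs direct recomputation, including gaps and N
  set.seed(222)
  av <- sample(c("A", "C", "G", "T", "-", "N"), 300, replace = TRUE,
               prob = c(0.23, 0.23, 0.23, 0.23, 0.05, 0.03))
  bv <- sample(c("A", "C", "G", "T", "-", "N"), 300, replace = TRUE,
               prob = c(0.23, 0.23, 0.23, 0.23, 0.05, 0.03))
  pair <- c(paste(av, collapse = ""), paste(bv, collapse = ""))
  tr2 <- sliding_identity(pair, window = 40, step = 7)
  match_col <- av == bv & av != "-" & av != "N" & bv != "N"
  for (j in seq_along(tr2$coordinates)) {
    s <- tr2$coordinates[j]
    expect_equal(tr2$values[j], mean(match_col[s:(s + 39)]) * 100)
  }
  # symmetric in the two sequences
  expect_equal(sliding_identity(rev(pair), window = 40, step = 7)$values,
               tr2$values)
  expect_error(sliding_identity(pair, window = 400), "window")
})

test_that("the low-identity mask flags scrambled inserts and nothing else", {
  ident <- strrep("ACGT", 100)
  expect_false(any(low_identity_mask(c(ident, ident))))
  # fully mismatched alignment: everything masked
  all_bad <- c(strrep("A", 120), strrep("C", 120))
  expect_true(all(low_identity_mask(all_bad)))
  # a fully mismatched insert inside identical flanks: the coverage rule
  # masks exactly the columns all of whose covering windows stay below
  # threshold, i.e. those at least 37 columns from both insert edges
  a <- paste0(strrep("ACGT", 50), strrep("A", 150), strrep("ACGT", 50))
  b <- paste0(strrep("ACGT", 50), strrep("C", 150), strrep("ACGT", 50))
  mask <- low_identity_mask(c(a, b), min_identity = 25, span = 50)
  iv <- mask_intervals(mask)
  expect_equal(nrow(iv), 1)
  expect_equal(c(iv$start, iv$end), c(201 + 37, 350 - 37))
  # the same insert at 60 columns is too narrow for any column to lose
  # all of its high-identity context
  a60 <- paste0(strrep("ACGT", 50), strrep("A", 60), strrep("ACGT", 50))
  b60 <- paste0(strrep("ACGT", 50), strrep("C", 60), strrep("ACGT", 50))
  expect_false(any(low_identity_mask(c(a60, b60))))
  # brute-force per-column coverage rule on a random pair
  set.seed(333)
  av <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  bv <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  pair <- c(paste(av, collapse = ""), paste(bv, collapse = ""))
  span <- 30; thr <- 40
  mask2 <- low_identity_mask(pair, min_identity = thr, span = span)
  match_col <- av == bv
  win_id <- vapply(1:(200 - span + 1),
                   function(s) mean(match_col[s:(s + span - 1)]) * 100,
                   numeric(1))
  brute <- vapply(1:200, function(col) {
    starts <- max(1, col - span + 1):min(col, length(win_id))
    all(win_id[starts] < thr)
  }, logical(1))
  expect_equal(mask2, brute)
  # relaxing the threshold never grows the mask
  mask_lo <- low_identity_mask(pair, min_identity = 25, span = span)
  expect_true(all(mask2[mask_lo]))
})

test_that("global alignment reproduces exhaustive scores on tiny inputs", {
  aln <- global_align("ACGTACGT", "ACGTACGT")
  expect_equal(aln$score, 8)
  expect_equal(unname(aln$pair[1]), unname(aln$pair[2]))
  expect_equal(global_align("A", "G")$score, -1)
  set.seed(444)
  for (i in 1:25) {
    a <- random_dna(sample(1:8, 1))
    b <- random_dna(sample(1:8, 1))
    expect_equal(global_align(a, b)$score, brute_align_score(a, b),
                 info = paste(a, b))
  }
  # aligned output has equal gapped lengths and recovers the inputs
  aln2 <- global_align("ACGTTGCA", "ACGGCA")
  expect_equal(unname(nchar(aln2$pair[1])), unname(nchar(aln2$pair[2])))
  expect_equal(unname(gsub("-", "", aln2$pair[1])), "ACGTTGCA")
})
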