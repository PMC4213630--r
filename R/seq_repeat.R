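#' Parse the repeat architecture of a dinucleotide microsatellite allele
#'
#' The locus modelled here is an (AC)-anchored CA microsatellite: a fixed
#' lead of AC dinucleotide units, a variable tract of CA units, and a
#' trailing mononucleotide C run. The parser is greedy and left-to-right:
#' it anchors on the leftmost maximal `(AC)+` run, then takes the longest
#' `(CA)+` run starting exactly where the lead ends, then the longest `C+`
#' run where the CA tract ends. Any intervening non-repeat base terminates
#' a block.
#'
#' @param seq A DNA string (A/C/G/T/N, uppercased internally).
#' @return An object of class `repeat_structure`: list with `lead_ac`,
#'   `ca_n`, `poly_c` (unit counts, all >= 0) and `anchor_offset` (0-based
#'   position of the lead in `seq`). The reconstructed motif length is
#'   `2*lead_ac + 2*ca_n + poly_c`.
#' @examples
#' parse_repeat_structure(paste0("GG", strrep("AC", 7), strrep("CA", 15),
#'                               strrep("C", 5), "TT"))
#' @export
parse_repeat_structure <- function(seq) {
  seq <- toupper(as.character(seq)[1])
  m <- regexpr("(AC)+", seq)
  if (m[1] == -1) stop("no (AC) run found in sequence", call. = FALSE)
  offset <- m[1] - 1L
  lead_len <- attr(m, "match.length")
  lead_ac <- lead_len %/% 2L
  rest <- substring(seq, m[1] + lead_len)
  ca <- regexpr("^(CA)+", rest)
  ca_len <- if (ca[1] == 1) attr(ca, "match.length") else 0L
  ca_n <- ca_len %/% 2L
  rest2 <- substring(rest, ca_len + 1L)
  pc <- regexpr("^C+", rest2)
  poly_c <- if (pc[1] == 1) attr(pc, "match.length") else 0L
  structure(list(lead_ac = as.integer(lead_ac), ca_n = as.integer(ca_n),
                 poly_c = as.integer(poly_c),
                 anchor_offset = as.integer(offset)),
            class = "repeat_structure")
}

#' @export
print.repeat_structure <- function(x, ...) {
  cat(sprintf("repeat_structure: (AC)%d (CA)%d C%d at offset %d\n",
              x$lead_ac, x$ca_n, x$poly_c, x$anchor_offset))
  invisible(x)
}

#' Reconstruct the repeat motif from a parsed structure
#'
#' @param structure A `repeat_structure`.
#' @return The motif string `(AC)^lead (CA)^ca C^poly`; parsing it again
#'   recovers the same counts.
#' @export
repeat_motif <- function(structure) {
  stopifnot(inherits(structure, "repeat_structure"))
  paste0(strrep("AC", structure$lead_ac), strrep("CA", structure$ca_n),
         strrep("C", structure$poly_c))
}

# Internal: per-column match indicator for an aligned pair. Gap-vs-base,
# gap-vs-gap and anything involving N all count as non-matching.
alignment_matches <- function(pair) {
  if (length(pair) != 2) stop("need exactly two sequences", call. = FALSE)
  a <- strsplit(toupper(pair[[1]]), "")[[1]]
  b <- strsplit(toupper(pair[[2]]), "")[[1]]
  if (length(a) != length(b)) {
    stop("aligned sequences have unequal lengths", call. = FALSE)
  }
  a == b & a != "-" & a != "N" & b != "N"
}

#' Sliding-window percent identity over an aligned pair
#'
#' Computes, for every window of alignment columns, the percentage of
#' matching columns. Windows are defined on alignment columns (not on
#' ungapped sequence positions) and coordinates are 1-based inclusive
#' window starts. A column matches only when both sequences carry the same
#' unambiguous base: gaps and N never match anything.
#'
#' @param pair Character vector of two equal-length gapped sequences, as
#'   from [read_aligned_pair()] or [global_align()].
#' @param window Window length in alignment columns (default 100).
#' @param step Step between window starts in columns (default 1).
#' @return An object of class `identity_track`: list with `window`, `step`,
#'   `coordinates` (window starts), `values` (percent identities in
#'   \[0, 100\]).
#' @export
sliding_identity <- function(pair, window = 100, step = 1) {
  eq <- alignment_matches(pair)
  L <- length(eq)
  if (window < 1 || window > L) {
    stop(sprintf("window (%d) must lie in [1, alignment length %d]",
                 window, L), call. = FALSE)
  }
  if (step < 1) stop("step must be >= 1", call. = FALSE)
  starts <- seq.int(1L, L - window + 1L, by = step)
  cs <- c(0, cumsum(eq))
  values <- (cs[starts + window] - cs[starts]) / window * 100
  structure(list(window = as.integer(window), step = as.integer(step),
                 coordinates = as.integer(starts), values = values),
            class = "identity_track")
}

#' @export
print.identity_track <- function(x, ...) {
  cat(sprintf("identity_track: %d windows of %d columns (step %d), identity %.1f-%.1f%%\n",
              length(x$values), x$window, x$step,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Low-identity column mask
#'
#' Flags alignment columns that sit in a region of persistently low
#' identity: a column is masked when *every* window of `span` columns
#' covering it has percent identity below `min_identity`. This per-column
#' coverage rule means a masked run marks columns with no supporting
#' high-identity context on either side.
#'
#' @inheritParams sliding_identity
#' @param min_identity Identity threshold in percent (default 25).
#' @param span Window length used for the coverage rule, in columns
#'   (default 50).
#' @return A logical vector, one element per alignment column; `TRUE`
#'   marks low-identity columns.
#' @seealso [mask_intervals()] to export the mask as 1-based intervals.
#' @export
low_identity_mask <- function(pair, min_identity = 25, span = 50) {
  track <- sliding_identity(pair, window = span, step = 1)
  L <- length(alignment_matches(pair))
  low <- track$values < min_identity
  n_win <- length(low)
  # column c is covered by window starts max(1, c-span+1) .. min(c, n_win)
  mask <- logical(L)
  for (col in seq_len(L)) {
    s1 <- max(1L, col - span + 1L)
    s2 <- min(col, n_win)
    mask[col] <- all(low[s1:s2])
  }
  mask
}

#' Masked regions as 1-based inclusive intervals
#'
#' @param mask Logical column mask from [low_identity_mask()].
#' @return A data frame with columns `start`, `end` (1-based, inclusive),
#'   one row per maximal masked run; zero rows when nothing is masked.
#' @export
mask_intervals <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

#' Needleman-Wunsch global alignment
#'
#' Optimal global alignment under a simple linear scheme (match +1,
#' mismatch -1, gap -2 per column by default), delegated to
#' [Biostrings::pairwiseAlignment()] with a zero gap-opening cost so the
#' gap penalty is purely per-column.
#'
#' @param a,b DNA strings to align (A/C/G/T).
#' @param match,mismatch Substitution scores.
#' @param gap Per-column gap score (negative).
#' @return A list with `pair` (named character vector of the two gapped
#'   sequences, equal length) and `score`.
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- toupper(as.character(a)[1]); b <- toupper(as.character(b)[1])
  if (nchar(a) == 0 || nchar(b) == 0) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = sub,
                                       gapOpening = 0, gapExtension = -gap)
  pair <- c(a = as.character(Biostrings::alignedPattern(aln)),
            b = as.character(Biostrings::alignedSubject(aln)))
  list(pair = pair, score = Biostrings::score(aln))
}

#' Plot a sliding-window identity track
#'
#' Line plot of percent identity per window start, with low-identity masked
#' intervals shaded.
#'
#' @param track An `identity_track` from [sliding_identity()].
#' @param mask Optional logical column mask from [low_identity_mask()].
#' @param ... Passed to [graphics::plot()].
#' @return `track`, invisibly.
#' @export
plot_identity_track <- function(track, mask = NULL, ...) {
  graphics::plot(track$coordinates, track$values, type = "l",
                 ylim = c(0, 100), xlab = "alignment column (window start)",
                 ylab = "% identity", ...)
  if (!is.null(mask)) {
    iv <- mask_intervals(mask)
    if (nrow(iv) > 0) {
      graphics::rect(iv$start, 0, iv$end, 100,
                     col = grDevices::adjustcolor("red", 0.25), border = NA)
    }
  }
  invisible(track)
}
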