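#' Loss-of-heterozygosity peak-height ratio
#'
#' For a heterozygous animal with matched normal (skin) and lesion tissue,
#' the LOH ratio is `(N2/N1) / (T2/T1)`: the relative height of the two
#' allele peaks in normal tissue divided by the same quantity in lesion
#' tissue. A balanced lesion gives a ratio near 1; preferential loss of one
#' allele pushes it away from 1 in either direction. The ratio is invariant
#' to rescaling all four heights and its reciprocal corresponds to swapping
#' the tissue roles.
#'
#' Replicate runs of the same animal are averaged per allele per tissue
#' before the ratio is formed.
#'
#' @param N1,N2 Peak heights of alleles 1 and 2 in normal tissue. Vectors
#'   are treated as replicate runs and averaged.
#' @param T1,T2 Peak heights of the same alleles, same order, in lesion
#'   tissue.
#' @return The LOH ratio, a positive scalar.
#' @examples
#' loh_ratio(100, 100, 100, 44)  # 2.27: loss suggested
#' @export
loh_ratio <- function(N1, N2, T1, T2) {
  h <- c(N1, N2, T1, T2)
  if (any(!is.finite(h)) || any(h <= 0)) {
    stop("peak heights must be strictly positive", call. = FALSE)
  }
  (mean(N2) / mean(N1)) / (mean(T2) / mean(T1))
}

#' Classify an LOH ratio
#'
#' Allele loss is strongly suggested when the ratio falls below 0.5 or
#' above 2.0; the thresholds are strict, so ratios of exactly 0.5 or 2.0
#' are called retained. A `partial` flag marks animals whose ratio suggests
#' loss but whose lesion genotype call is unchanged (both lesion peaks
#' still above a detection floor, by default 10\% of the taller lesion
#' peak) — partial rather than complete loss of the allele.
#'
#' @param ratio A positive LOH ratio, as from [loh_ratio()].
#' @param T1,T2 Optional lesion peak heights used for the `partial` flag.
#' @param floor_frac Detection floor as a fraction of the taller lesion
#'   peak (default 0.10).
#' @param animal_id Optional identifier carried into the result.
#' @return A one-row data frame with `animal_id`, `ratio`, `call`
#'   (`"retained"` or `"loss_suggested"`) and logical `partial`.
#' @export
classify_loh <- function(ratio, T1 = NULL, T2 = NULL, floor_frac = 0.10,
                         animal_id = NA_character_) {
  if (!is.finite(ratio) || ratio <= 0) {
    stop("LOH ratio must be a positive finite number", call. = FALSE)
  }
  loss <- ratio < 0.5 || ratio > 2.0
  partial <- FALSE
  if (loss && !is.null(T1) && !is.null(T2)) {
    floor_h <- floor_frac * max(mean(T1), mean(T2))
    partial <- mean(T1) >= floor_h && mean(T2) >= floor_h
  }
  data.frame(animal_id = animal_id, ratio = ratio,
             call = if (loss) "loss_suggested" else "retained",
             partial = partial, stringsAsFactors = FALSE)
}

#' Per-animal LOH calls for a peak-height table
#'
#' Averages replicate runs per animal, computes the LOH ratio and the
#' loss/retained call with the partial-loss flag.
#'
#' @param peaks A peak table from [read_peak_table()] or
#'   [simulate_peaks()].
#' @param floor_frac Detection floor passed to [classify_loh()].
#' @return A data frame with one row per animal: `animal_id`, `status`,
#'   `n_replicates`, `ratio`, `call`, `partial`.
#' @export
call_loh <- function(peaks, floor_frac = 0.10) {
  peaks <- validate_peaks(peaks)
  ids <- unique(peaks$animal_id)
  rows <- lapply(ids, function(id) {
    sub <- peaks[peaks$animal_id == id, , drop = FALSE]
    r <- loh_ratio(sub$N1, sub$N2, sub$T1, sub$T2)
    cl <- classify_loh(r, T1 = sub$T1, T2 = sub$T2,
                       floor_frac = floor_frac, animal_id = id)
    cbind(cl[, "animal_id", drop = FALSE],
          data.frame(status = sub$status[1], n_replicates = nrow(sub)),
          cl[, c("ratio", "call", "partial")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort LOH summary and loss-by-status table
#'
#' Summarises per-group LOH ratios (min, median, max for cases and
#' controls) and cross-tabulates loss calls against case/control status in
#' a [table2x2] (`a` = cases with loss, `b` = controls with loss, `c` =
#' cases retained, `d` = controls retained) suitable for
#' [fisher_exact_two_sided()]; the Fisher p-value is included.
#'
#' @inheritParams call_loh
#' @return A list with `calls` (the per-animal data frame), `summary`
#'   (per-group ratio range data frame; groups with no animals are marked
#'   absent with `NA` ranges), `table` (the [table2x2]) and `fisher`
#'   (an [assoc_result]).
#' @export
loh_cohort_summary <- function(peaks, floor_frac = 0.10) {
  calls <- call_loh(peaks, floor_frac = floor_frac)
  grp <- function(st) {
    r <- calls$ratio[calls$status == st]
    data.frame(status = st, n = length(r),
               min = if (length(r)) min(r) else NA_real_,
               median = if (length(r)) stats::median(r) else NA_real_,
               max = if (length(r)) max(r) else NA_real_)
  }
  summary <- rbind(grp("case"), grp("control"))
  loss <- calls$call == "loss_suggested"
  case <- calls$status == "case"
  tab <- table2x2(sum(loss & case), sum(loss & !case),
                  sum(!loss & case), sum(!loss & !case))
  list(calls = calls, summary = summary, table = tab,
       fisher = fisher_exact_two_sided(tab))
}

#' Detect somatic repeat-length imbalance between tissues
#'
#' Compares the parsed repeat structure of the same allele in normal (skin)
#' and lesion tissue and calls a somatic change in the CA tract:
#' `contraction` when the lesion carries fewer CA units, `expansion` when
#' more, `stable` otherwise. Differences in the trailing poly-C run are
#' reported but do not enter the call (mononucleotide runs are prone to
#' amplification slippage).
#'
#' @param skin A `repeat_structure` from [parse_repeat_structure()] for the
#'   normal tissue.
#' @param lesion The structure of the same allele of the same animal in
#'   lesion tissue.
#' @param animal_id,allele_label Optional identifiers carried through.
#' @return A one-row data frame: `animal_id`, `allele_label`, `delta_ca`
#'   (lesion minus skin CA count), `delta_poly_c`, `call`.
#' @export
detect_imbalance <- function(skin, lesion, animal_id = NA_character_,
                             allele_label = NA_character_) {
  stopifnot(inherits(skin, "repeat_structure"),
            inherits(lesion, "repeat_structure"))
  delta <- lesion$ca_n - skin$ca_n
  call <- if (delta < 0) "contraction" else if (delta > 0) "expansion" else "stable"
  data.frame(animal_id = animal_id, allele_label = allele_label,
             delta_ca = as.integer(delta),
             delta_poly_c = as.integer(lesion$poly_c - skin$poly_c),
             call = call, stringsAsFactors = FALSE)
}
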