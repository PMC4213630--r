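#' Simulation configuration for a synthetic case-control cohort
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' emulate the study design the analysis pipeline targets: a single
#' 5-allele dinucleotide locus with one dominant allele, an inbreeding
#' coefficient inflating homozygosity above Hardy-Weinberg, a disease model
#' in which homozygosity multiplies the odds of disease (default odds ratio
#' 1.8), paired-tissue peak heights with multiplicative log-normal noise
#' and rare injected allele loss, and alleles of the form
#' `(AC)7 (CA)n ... Cm`.
#'
#' @param n_animals Cohort size (default 371).
#' @param allele_freqs Named or unnamed probability vector of allele
#'   frequencies, summing to 1. Default `c(0.55, 0.20, 0.12, 0.08, 0.05)`
#'   for alleles "1".."5".
#' @param inbreeding_f Inbreeding coefficient F in \[0, 1):
#'   `P(ii) = p_i^2 + F p_i (1 - p_i)`, `P(ij) = 2 p_i p_j (1 - F)`.
#'   Default 0.10.
#' @param baseline_logit Intercept of the disease model (log-odds of
#'   disease in heterozygotes). Default `qlogis(0.30)`.
#' @param hom_log_or Log odds ratio for homozygosity. Default `log(1.8)`.
#' @param study_labels Named vector of study split proportions (default
#'   `c(A = 0.5, B = 0.5)`).
#' @param loh_fraction Proportion of heterozygous cases receiving injected
#'   allele loss in lesion tissue (default 1/7).
#' @param loss_factor Multiplicative reduction of one lesion-tissue peak in
#'   affected animals, in (0, 1). Default 0.44, giving an LOH ratio of
#'   1/0.44 = 2.27 in the noise-free case.
#' @param peak_cv Coefficient of variation of the multiplicative log-normal
#'   peak noise (default 0.10).
#' @param replicate_fraction Fraction of animals whose peaks are run twice
#'   (default 0.5).
#' @param contraction_count Number of animals given a somatic CA-tract
#'   contraction in lesion tissue (default 3).
#' @param ca_range Integer range (min, max) of CA unit counts across
#'   alleles (default `c(11, 19)`).
#' @param seed Integer seed; one global seed fans out to independent
#'   per-stage substreams so stages can be regenerated independently.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_animals = 371,
                       allele_freqs = c("1" = 0.55, "2" = 0.20, "3" = 0.12,
                                        "4" = 0.08, "5" = 0.05),
                       inbreeding_f = 0.10,
                       baseline_logit = stats::qlogis(0.30),
                       hom_log_or = log(1.8),
                       study_labels = c(A = 0.5, B = 0.5),
                       loh_fraction = 1 / 7,
                       loss_factor = 0.44,
                       peak_cv = 0.10,
                       replicate_fraction = 0.5,
                       contraction_count = 3,
                       ca_range = c(11, 19),
                       seed = 1L) {
  if (is.null(names(allele_freqs))) {
    names(allele_freqs) <- as.character(seq_along(allele_freqs))
  }
  stopifnot(n_animals >= 1,
            abs(sum(allele_freqs) - 1) <= 1e-12,
            all(allele_freqs > 0),
            inbreeding_f >= 0, inbreeding_f < 1,
            loh_fraction >= 0, loh_fraction <= 1,
            loss_factor > 0, loss_factor < 1,
            peak_cv >= 0,
            replicate_fraction >= 0, replicate_fraction <= 1,
            contraction_count >= 0,
            length(ca_range) == 2, ca_range[1] <= ca_range[2])
  if (is.null(names(study_labels))) {
    names(study_labels) <- LETTERS[seq_along(study_labels)]
  }
  study_labels <- study_labels / sum(study_labels)
  structure(list(n_animals = as.integer(n_animals),
                 allele_freqs = allele_freqs,
                 inbreeding_f = inbreeding_f,
                 baseline_logit = baseline_logit,
                 hom_log_or = hom_log_or,
                 study_labels = study_labels,
                 loh_fraction = loh_fraction,
                 loss_factor = loss_factor,
                 peak_cv = peak_cv,
                 replicate_fraction = replicate_fraction,
                 contraction_count = as.integer(contraction_count),
                 ca_range = as.integer(ca_range),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Internal: deterministic per-stage substream seed below 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(genotypes = 11L, disease = 23L, peaks = 37L,
               sequences = 53L, contractions = 71L, tables = 89L)
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

#' Sample diploid genotypes from an inbred population
#'
#' Draws unordered genotypes from the inbreeding-adjusted genotype
#' distribution `P(ii) = p_i^2 + F p_i (1 - p_i)`,
#' `P(ij) = 2 p_i p_j (1 - F)`, and assigns study labels by the configured
#' split. Status is left unset (`NA`) until [assign_disease()].
#'
#' @param cfg A [sim_config()].
#' @return A genotype data frame (columns `animal_id`, `status`, `study`,
#'   `allele_a`, `allele_b`, `is_homozygous`) with `status = NA`.
#' @export
sample_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "genotypes"))
  p <- cfg$allele_freqs
  al <- names(p)
  K <- length(p)
  combos <- list(); probs <- numeric(0)
  for (i in seq_len(K)) {
    for (j in i:K) {
      combos[[length(combos) + 1L]] <- c(al[i], al[j])
      probs <- c(probs,
                 if (i == j) p[i]^2 + cfg$inbreeding_f * p[i] * (1 - p[i])
                 else 2 * p[i] * p[j] * (1 - cfg$inbreeding_f))
    }
  }
  idx <- sample.int(length(combos), cfg$n_animals, replace = TRUE,
                    prob = probs)
  g <- do.call(rbind, combos[idx])
  study <- sample(names(cfg$study_labels), cfg$n_animals, replace = TRUE,
                  prob = cfg$study_labels)
  data.frame(animal_id = sprintf("a%04d", seq_len(cfg$n_animals)),
             status = NA_character_, study = study,
             allele_a = g[, 1], allele_b = g[, 2],
             is_homozygous = g[, 1] == g[, 2],
             stringsAsFactors = FALSE)
}

#' Assign disease status under a homozygosity-risk model
#'
#' Case status is Bernoulli with
#' `P(case) = plogis(baseline_logit + hom_log_or * I(homozygous))`.
#'
#' @param records Genotypes from [sample_genotypes()].
#' @param cfg The same [sim_config()].
#' @return The records with `status` filled in ("case"/"control").
#' @export
assign_disease <- function(records, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "disease"))
  hom <- records$allele_a == records$allele_b
  pr <- stats::plogis(cfg$baseline_logit + cfg$hom_log_or * hom)
  records$status <- ifelse(stats::runif(nrow(records)) < pr,
                           "case", "control")
  records
}

#' Simulate one synthetic case-control cohort
#'
#' [sample_genotypes()] followed by [assign_disease()].
#'
#' @param cfg A [sim_config()].
#' @return A validated genotype data frame with status assigned.
#' @export
simulate_cohort <- function(cfg) {
  validate_genotypes(assign_disease(sample_genotypes(cfg), cfg))
}

#' Simulate paired-tissue electropherogram peak heights
#'
#' For every heterozygous animal, baseline peak heights of 1000
#' fluorescence units per allele per tissue are perturbed by multiplicative
#' log-normal noise with the configured coefficient of variation. A
#' designated fraction of heterozygous *case* animals
#' (`round(loh_fraction * n)` of them) receives injected allele loss: the
#' lesion-tissue height of one randomly chosen allele is multiplied by
#' `loss_factor`. A configured fraction of animals is run twice
#' (two replicate rows).
#'
#' @param records Genotypes with status, as from [simulate_cohort()].
#' @param cfg The same [sim_config()].
#' @return A peak table (one row per replicate) with attribute
#'   `"loss_truth"`: a data frame of `animal_id`, `lost_allele` (1 or 2)
#'   for the injected-loss animals.
#' @export
simulate_peaks <- function(records, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "peaks"))
  het <- records[records$allele_a != records$allele_b, , drop = FALSE]
  if (nrow(het) == 0) stop("no heterozygous animals to simulate",
                           call. = FALSE)
  sdlog <- sqrt(log(1 + cfg$peak_cv^2))
  het_cases <- het$animal_id[het$status == "case"]
  n_loss <- round(cfg$loh_fraction * length(het_cases))
  loss_ids <- if (n_loss > 0) {
    sample(het_cases, min(n_loss, length(het_cases)))
  } else character(0)
  lost_allele <- if (length(loss_ids)) {
    stats::setNames(sample(1:2, length(loss_ids), replace = TRUE), loss_ids)
  } else integer(0)
  dup <- stats::runif(nrow(het)) < cfg$replicate_fraction
  rows <- list()
  for (i in seq_len(nrow(het))) {
    id <- het$animal_id[i]
    for (rep_id in seq_len(if (dup[i]) 2L else 1L)) {
      h <- 1000 * stats::rlnorm(4, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      names(h) <- c("N1", "N2", "T1", "T2")
      if (id %in% loss_ids) {
        tcol <- if (lost_allele[[id]] == 1L) "T1" else "T2"
        h[tcol] <- h[tcol] * cfg$loss_factor
      }
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = id, status = het$status[i],
        N1 = h[["N1"]], N2 = h[["N2"]], T1 = h[["T1"]], T2 = h[["T2"]],
        replicate_id = rep_id, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  truth <- data.frame(animal_id = names(lost_allele),
                      lost_allele = as.integer(lost_allele),
                      stringsAsFactors = FALSE)
  attr(out, "loss_truth") <- truth
  out
}

#' Construct a microsatellite allele sequence
#'
#' Builds `5'flank + (AC)7 + (CA)ca_count + C^poly_c + 3'flank` with random
#' flanks constrained so that [parse_repeat_structure()] inverts the
#' construction exactly: the 5' flank contains no "AC" dinucleotide (so the
#' lead anchor is the leftmost AC run) and the 3' flank does not start with
#' "C" (so the poly-C run is not extended).
#'
#' @param allele_label Label used to name the sequence.
#' @param ca_count Number of CA units in the variable tract.
#' @param flank_lengths Lengths of the 5' and 3' flanks (default 30, 30).
#' @param poly_c Trailing C count (default 5).
#' @param seed Integer seed.
#' @return A named character vector of length 1 (an allele sequence).
#' @export
make_repeat_sequence <- function(allele_label, ca_count,
                                 flank_lengths = c(30, 30), poly_c = 5,
                                 seed = 1L) {
  stopifnot(ca_count >= 0, poly_c >= 0, all(flank_lengths >= 0))
  set.seed(as.integer(seed))
  rand_flank <- function(len, ok) {
    if (len == 0) return("")
    repeat {
      f <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
      if (ok(f)) return(f)
    }
  }
  # 5' flank: no AC dinucleotide, so the lead is the leftmost AC run.
  # 3' flank: must not extend the poly-C run (leading C), must not turn a
  # single trailing C into an extra CA unit (leading A when poly_c == 1),
  # and must not extend the AC lead when both tracts are empty.
  ok3 <- function(f) {
    !startsWith(f, "C") &&
      !(poly_c == 1 && startsWith(f, "A")) &&
      !(ca_count == 0 && poly_c == 0 && startsWith(f, "AC"))
  }
  seq <- paste0(rand_flank(flank_lengths[1],
                           function(f) !grepl("AC", f, fixed = TRUE)),
                strrep("AC", 7), strrep("CA", ca_count),
                strrep("C", poly_c),
                rand_flank(flank_lengths[2], ok3))
  stats::setNames(seq, as.character(allele_label))
}

#' Simulate paired skin/lesion repeat sequences with injected contractions
#'
#' Gives every allele label a CA count spaced across `ca_range`, builds one
#' skin and one lesion sequence per animal for the animal's first allele,
#' and injects a CA-tract contraction (1-3 fewer units) into the lesion
#' sequence of `contraction_count` randomly chosen animals.
#'
#' @param records Genotypes with status.
#' @param cfg A [sim_config()].
#' @return A list with `sequences` (named character vector; names are
#'   `<animal_id>|skin` and `<animal_id>|lesion`), `ca_map` (allele label
#'   to CA count), and `truth` (data frame of `animal_id`, `allele_label`,
#'   `skin_ca`, `lesion_ca` for every animal).
#' @export
simulate_tissue_sequences <- function(records, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "contractions"))
  alleles <- sort(unique(c(records$allele_a, records$allele_b)))
  ca_map <- stats::setNames(
    as.integer(round(seq(cfg$ca_range[1], cfg$ca_range[2],
                         length.out = max(2, length(alleles)))))[
                           seq_along(alleles)],
    alleles)
  n <- nrow(records)
  n_contr <- min(cfg$contraction_count, n)
  contr_idx <- if (n_contr > 0) sample.int(n, n_contr) else integer(0)
  seqs <- character(0)
  truth <- data.frame(animal_id = records$animal_id,
                      allele_label = records$allele_a,
                      skin_ca = unname(ca_map[records$allele_a]),
                      lesion_ca = unname(ca_map[records$allele_a]),
                      stringsAsFactors = FALSE)
  truth$lesion_ca[contr_idx] <- truth$skin_ca[contr_idx] -
    sample(1:3, n_contr, replace = TRUE)
  for (i in seq_len(n)) {
    sd <- stage_seed(cfg$seed, "sequences") %% 100000L + i
    skin <- make_repeat_sequence(records$allele_a[i], truth$skin_ca[i],
                                 seed = sd)
    lesion <- make_repeat_sequence(records$allele_a[i], truth$lesion_ca[i],
                                   seed = sd)
    seqs[paste0(records$animal_id[i], "|skin")] <- unname(skin)
    seqs[paste0(records$animal_id[i], "|lesion")] <- unname(lesion)
  }
  list(sequences = seqs, ca_map = ca_map, truth = truth)
}

#' Simulate independent stratified 2x2 tables under a common odds ratio
#'
#' Generates K independent strata: within stratum k, each of
#' `n_per_stratum` subjects is exposed with probability `p_exposed` and
#' diseased with probability
#' `plogis(baseline_logit_k + log(common_or) * exposed)`, with per-stratum
#' baselines drawn uniformly in `baseline_range`. The common odds ratio
#' holds in every stratum, making this the null configuration for
#' [tarone_homogeneity()] and, with `common_or = 1`, for [cmh_chi2()].
#'
#' @param K Number of strata.
#' @param n_per_stratum Subjects per stratum.
#' @param common_or Common odds ratio across strata.
#' @param p_exposed Exposure probability.
#' @param baseline_range Range of per-stratum baseline logits.
#' @return A [stratified_tables] with K strata.
#' @export
sample_stratified_tables <- function(K = 4, n_per_stratum = 100,
                                     common_or = 1.8, p_exposed = 0.3,
                                     baseline_range = c(-1.2, -0.4)) {
  tabs <- vector("list", K)
  for (k in seq_len(K)) {
    b0 <- stats::runif(1, baseline_range[1], baseline_range[2])
    exposed <- stats::runif(n_per_stratum) < p_exposed
    pr <- stats::plogis(b0 + log(common_or) * exposed)
    case <- stats::runif(n_per_stratum) < pr
    tabs[[k]] <- table2x2(sum(exposed & case), sum(exposed & !case),
                          sum(!exposed & case), sum(!exposed & !case))
  }
  stratified_tables(tabs)
}

#' Write a full synthetic dataset to disk
#'
#' Emits the genotype CSV, the peak-height CSV, a FASTA of per-allele
#' reference sequences, a FASTA of paired skin/lesion sequences, and a
#' ground-truth JSON (true model coefficients, injected-loss animals, true
#' CA counts and contraction animals) for downstream assertions. Output is
#' byte-identical under a fixed config.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_dataset <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- simulate_cohort(cfg)
  peaks <- simulate_peaks(records, cfg)
  tissues <- simulate_tissue_sequences(
    records[records$is_homozygous, , drop = FALSE], cfg)
  allele_seqs <- vapply(names(tissues$ca_map), function(al) {
    unname(make_repeat_sequence(al, tissues$ca_map[[al]],
                                seed = stage_seed(cfg$seed, "sequences")))
  }, character(1))
  files <- c(genotypes = file.path(out_dir, "genotypes.csv"),
             peaks = file.path(out_dir, "peaks.csv"),
             alleles = file.path(out_dir, "alleles.fasta"),
             tissues = file.path(out_dir, "tissue_sequences.fasta"),
             truth = file.path(out_dir, "truth.json"))
  write_genotype_table(records, files[["genotypes"]])
  write_peak_table(peaks, files[["peaks"]])
  write_fasta(allele_seqs, files[["alleles"]])
  write_fasta(tissues$sequences, files[["tissues"]])
  truth <- list(baseline_logit = cfg$baseline_logit,
                hom_log_or = cfg$hom_log_or,
                inbreeding_f = cfg$inbreeding_f,
                allele_freqs = as.list(cfg$allele_freqs),
                loss_animals = attr(peaks, "loss_truth"),
                ca_map = as.list(tissues$ca_map),
                tissue_truth = tissues$truth,
                seed = cfg$seed)
  jsonlite::write_json(truth, files[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(files)
}
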