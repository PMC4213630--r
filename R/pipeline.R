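#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [run_all()]: a
#' `simulate` block (the [sim_config()] parameters), an `assoc` block
#' (`continuity`), a `profile` block (`mode`), a `loh` block
#' (`floor_frac`), and a `seqscan` block (`window`, `step`,
#' `min_identity`, `span`). Any subset can be overridden via a YAML file
#' (see [read_pipeline_config()]) or by list merge.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(seed = 1L,
       simulate = list(),
       assoc = list(continuity = TRUE),
       profile = list(mode = "likelihood"),
       loh = list(floor_frac = 0.10),
       seqscan = list(window = 100L, step = 1L,
                      min_identity = 25, span = 50L))
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its default.
#'
#' @param path Path to a YAML file.
#' @return A configuration list as from [default_config()].
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Run the whole pipeline end to end
#'
#' Simulates a dataset (unless `data_dir` points at an existing one),
#' then runs every analysis stage — association statistics, genotype risk
#' profiles, LOH calling with the cohort Fisher test, repeat-imbalance
#' detection, and a sliding-window identity scan of a skin/lesion pair —
#' writing one CSV per stage plus a reproducibility manifest with MD5
#' digests of every input and output file.
#'
#' @param config A configuration list ([default_config()] structure) or a
#'   path to a YAML file.
#' @param out_dir Run directory for all outputs.
#' @param seed Optional integer overriding `config$seed`.
#' @param data_dir Optional directory holding an existing dataset
#'   (`genotypes.csv`, `peaks.csv`, `tissue_sequences.fasta`); when `NULL`
#'   the dataset is simulated into `out_dir/data`.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_all <- function(config = default_config(), out_dir, seed = NULL,
                    data_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(data_dir)) {
    data_dir <- file.path(out_dir, "data")
    cfg <- do.call(sim_config, c(config$simulate, list(seed = config$seed)))
    in_files <- write_dataset(cfg, data_dir)
  } else {
    in_files <- c(genotypes = file.path(data_dir, "genotypes.csv"),
                  peaks = file.path(data_dir, "peaks.csv"),
                  tissues = file.path(data_dir, "tissue_sequences.fasta"))
    missing <- in_files[!file.exists(in_files)]
    if (length(missing) > 0) {
      stop("stage input missing: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }

  # assoc stage
  records <- read_genotype_table(in_files[["genotypes"]])
  assoc <- associate_homozygosity(records,
                                  continuity = isTRUE(config$assoc$continuity))
  out_assoc <- file.path(out_dir, "assoc_results.csv")
  utils::write.csv(assoc, out_assoc, row.names = FALSE)

  # profile stage
  profiles <- genotype_profiles(records, mode = config$profile$mode)
  prof_df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(genotype = p$genotype, k = p$k, n = p$n,
               median_p = p$median_p, lcl = p$lcl, ucl = p$ucl)
  }))
  out_prof <- file.path(out_dir, "profiles.csv")
  utils::write.csv(prof_df, out_prof, row.names = FALSE)

  # loh stage
  peaks <- read_peak_table(in_files[["peaks"]])
  loh <- loh_cohort_summary(peaks, floor_frac = config$loh$floor_frac)
  out_loh <- file.path(out_dir, "loh_results.csv")
  utils::write.csv(loh$calls, out_loh, row.names = FALSE)
  out_loh_sum <- file.path(out_dir, "loh_summary.csv")
  loh_sum <- loh$summary
  loh_sum$fisher_p <- loh$fisher$p_value
  utils::write.csv(loh_sum, out_loh_sum, row.names = FALSE)

  # seqscan stage: per-animal imbalance calls from paired tissue sequences,
  # plus an identity scan of the first skin/lesion pair after re-alignment.
  tissue_seqs <- read_fasta(in_files[["tissues"]])
  ids <- unique(sub("\\|(skin|lesion)$", "", names(tissue_seqs)))
  imb <- do.call(rbind, lapply(ids, function(id) {
    skin <- parse_repeat_structure(tissue_seqs[[paste0(id, "|skin")]])
    lesion <- parse_repeat_structure(tissue_seqs[[paste0(id, "|lesion")]])
    detect_imbalance(skin, lesion, animal_id = id)
  }))
  out_imb <- file.path(out_dir, "imbalance.csv")
  utils::write.csv(imb, out_imb, row.names = FALSE)

  aln <- global_align(tissue_seqs[[paste0(ids[1], "|skin")]],
                      tissue_seqs[[paste0(ids[1], "|lesion")]])
  L <- nchar(aln$pair[[1]])
  win <- min(config$seqscan$window, L)
  span <- min(config$seqscan$span, L)
  track <- sliding_identity(aln$pair, window = win,
                            step = config$seqscan$step)
  mask <- low_identity_mask(aln$pair,
                            min_identity = config$seqscan$min_identity,
                            span = span)
  out_track <- file.path(out_dir, "identity_track.csv")
  utils::write.csv(data.frame(start = track$coordinates,
                              identity = track$values),
                   out_track, row.names = FALSE)
  out_mask <- file.path(out_dir, "low_identity_intervals.csv")
  utils::write.csv(mask_intervals(mask), out_mask, row.names = FALSE)

  outputs <- c(assoc = out_assoc, profiles = out_prof, loh = out_loh,
               loh_summary = out_loh_sum, imbalance = out_imb,
               identity = out_track, mask = out_mask)
  manifest <- list(
    package_version = as.character(utils::packageVersion("msatcc")),
    seed = config$seed,
    config = config,
    inputs = as.list(tools::md5sum(unname(in_files))),
    outputs = as.list(tools::md5sum(unname(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
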