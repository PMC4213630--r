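#' Read a case-control genotype table
#'
#' Reads a delimited text file of diploid genotypes at the focal
#' microsatellite locus, one row per animal, with columns `animal_id`,
#' `status`, `study`, `allele_a`, `allele_b` (additional columns, e.g.
#' control-locus genotypes, are carried through untouched). Allele labels are
#' opaque strings compared by equality; the reader never bins fragment
#' sizes. Status tokens `case`/`control` are canonical; `UGC` and `CTRL`
#' are accepted as synonyms (case-insensitively).
#'
#' @param path Path to the file.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return A data frame with the canonical columns plus a logical
#'   `is_homozygous`, validated so that every record has both allele calls
#'   and a unique `animal_id`.
#' @seealso [write_genotype_table()], [split_by_study()]
#' @export
read_genotype_table <- function(path, delim = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          colClasses = "character", check.names = TRUE,
                          stringsAsFactors = FALSE)
  validate_genotypes(df)
}

# Canonicalise and validate a genotype data frame (also the entry point for
# programmatically built tables).
validate_genotypes <- function(df) {
  required <- c("animal_id", "status", "study", "allele_a", "allele_b")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("genotype table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop("genotype table has no rows", call. = FALSE)
  df$animal_id <- as.character(df$animal_id)
  dup <- duplicated(df$animal_id)
  if (any(dup)) {
    stop("duplicate animal_id(s): ",
         paste(unique(df$animal_id[dup]), collapse = ", "), call. = FALSE)
  }
  df$status <- canonical_status(df$status)
  for (col in c("allele_a", "allele_b")) {
    v <- trimws(as.character(df[[col]]))
    bad <- is.na(v) | v == "" | toupper(v) == "NA"
    if (any(bad)) {
      stop(sprintf("missing %s in row(s) %s (half-calls are rejected)",
                   col, paste(which(bad), collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- v
  }
  df$study <- as.character(df$study)
  df$is_homozygous <- df$allele_a == df$allele_b
  df
}

canonical_status <- function(status) {
  s <- tolower(trimws(as.character(status)))
  out <- ifelse(s %in% c("case", "ugc"), "case",
                ifelse(s %in% c("control", "ctrl"), "control", NA))
  if (anyNA(out)) {
    bad <- which(is.na(out))
    stop(sprintf("unknown status token '%s' in row %d (expected case/control or UGC/CTRL)",
                 status[bad[1]], bad[1]), call. = FALSE)
  }
  out
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]; `write` then `read` is the identity
#' on the canonical columns.
#'
#' @param records A validated genotype data frame.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(records, path, delim = ",") {
  records <- validate_genotypes(records)
  records$is_homozygous <- NULL
  utils::write.table(records, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Split a genotype table by study
#'
#' @param records A validated genotype data frame.
#' @return A named list with one data frame per study label plus `pooled`.
#' @export
split_by_study <- function(records) {
  records <- validate_genotypes(records)
  out <- split(records, records$study)
  out$pooled <- records
  out
}

#' Read paired-tissue electropherogram peak heights
#'
#' One row per replicate run per animal, columns `animal_id`, `status`,
#' `N1`, `N2` (peak heights of alleles 1 and 2 in normal tissue, in
#' fluorescence units), `T1`, `T2` (same alleles, same order, in lesion
#' tissue) and optionally `replicate_id`. Allele ordering must be identical
#' between tissues — pairing is by allele label, never by height rank.
#'
#' @param path Path to the file.
#' @param delim Field delimiter.
#' @return A data frame with numeric, strictly positive heights and an
#'   integer `replicate_id` (1 for rows that did not carry one).
#' @export
read_peak_table <- function(path, delim = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE)
  validate_peaks(df)
}

validate_peaks <- function(df) {
  required <- c("animal_id", "status", "N1", "N2", "T1", "T2")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("peak table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop("peak table has no rows", call. = FALSE)
  df$animal_id <- as.character(df$animal_id)
  df$status <- canonical_status(df$status)
  for (col in c("N1", "N2", "T1", "T2")) {
    v <- as.numeric(df[[col]])
    bad <- is.na(v) | v <= 0
    if (any(bad)) {
      stop(sprintf("non-positive or missing peak height %s in row(s) %s",
                   col, paste(which(bad), collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- v
  }
  if (is.null(df$replicate_id)) {
    df$replicate_id <- stats::ave(seq_len(nrow(df)), df$animal_id,
                                  FUN = seq_along)
  }
  df$replicate_id <- as.integer(df$replicate_id)
  df
}

#' Write a peak-height table
#'
#' @param peaks A validated peak data frame.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path, delim = ",") {
  peaks <- validate_peaks(peaks)
  utils::write.table(peaks, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read allele sequences from FASTA
#'
#' Sequences are uppercased and validated over the alphabet A, C, G, T, N;
#' alignment gaps are not allowed here (use [read_aligned_pair()] for gapped
#' input).
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0)) stop("empty sequence in FASTA", call. = FALSE)
  if (any(grepl("[^ACGTN]", seqs))) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  names(seqs) <- names(ss)
  seqs
}

#' Read a pairwise alignment from FASTA
#'
#' Expects exactly two records of equal gapped length; the gap character
#' `-` is preserved.
#'
#' @param path Path to a FASTA file holding the two aligned sequences.
#' @return A named character vector of length 2 over A, C, G, T, N, `-`.
#' @export
read_aligned_pair <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 2) {
    stop(sprintf("aligned pair must have exactly 2 records, found %d",
                 length(ss)), call. = FALSE)
  }
  seqs <- toupper(as.character(ss))
  if (nchar(seqs[1]) != nchar(seqs[2])) {
    stop("aligned sequences have unequal gapped lengths", call. = FALSE)
  }
  if (any(grepl("[^ACGTN-]", seqs))) {
    stop("alignment contains characters outside {A,C,G,T,N,-}", call. = FALSE)
  }
  names(seqs) <- names(ss)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences (gaps allowed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named", call. = FALSE)
  }
  lines <- character(2 * length(seqs))
  lines[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  lines[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(lines, path)
  invisible(path)
}
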