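# Domain containers and TSV readers/writers.
#
# Three on-disk artifacts flow through the pipeline:
#   * a contig x sample count matrix (integer TSV, first column contig_id),
#   * a sample sheet assigning samples to groups {A, P, F1},
#   * a site-level pileup table carrying strand-resolved allele depths
#     ("dp4": ref-forward, ref-reverse, alt-forward, alt-reverse) per sample.
# All readers validate and fail with messages naming the offending record;
# every writer/reader pair is inverse on valid data.

GROUPS <- c("A", "P", "F1")
BASES <- c("A", "C", "G", "T")

#' Construct a sample sheet
#'
#' A sample sheet assigns each sequenced library to a group: `"A"` (parent
#' accession A, e.g. the *H. annuus* line), `"P"` (parent accession P, e.g.
#' the *H. petiolaris* accession) or `"F1"` (interspecific hybrid offspring).
#' The `excluded_in_reduced` flag marks samples dropped in the reduced
#' (outlier-free) re-analysis; reduced-set membership is an explicit design
#' decision recorded here, never inferred automatically.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param group character vector, one of `"A"`, `"P"`, `"F1"` per sample.
#' @param excluded_in_reduced logical vector; `TRUE` for samples dropped in
#'   the reduced analysis. Defaults to all `FALSE`.
#' @return A `data.frame` of class `"sample_sheet"`.
#' @examples
#' sample_sheet(c("HA89.5", "HA89.9", "PET.2", "PET.3", paste0("F1.", 1:8)),
#'              c("A", "A", "P", "P", rep("F1", 8)))
#' @export
sample_sheet <- function(sample_id, group,
                         excluded_in_reduced = rep(FALSE, length(sample_id))) {
  ss <- data.frame(sample_id = as.character(sample_id),
                   group = as.character(group),
                   excluded_in_reduced = as.logical(excluded_in_reduced),
                   stringsAsFactors = FALSE)
  class(ss) <- c("sample_sheet", "data.frame")
  validate_sample_sheet(ss)
  ss
}

validate_sample_sheet <- function(ss) {
  if (anyDuplicated(ss$sample_id))
    stop("sample sheet: duplicated sample_id '",
         ss$sample_id[duplicated(ss$sample_id)][1], "'")
  bad <- setdiff(unique(ss$group), GROUPS)
  if (length(bad))
    stop("sample sheet: unknown group '", bad[1],
         "' (expected A, P or F1)")
  if (anyNA(ss$excluded_in_reduced))
    stop("sample sheet: excluded_in_reduced must be TRUE/FALSE")
  n <- table(factor(ss$group, levels = GROUPS))
  if (n[["A"]] < 2 || n[["P"]] < 2)
    stop("sample sheet: need >= 2 samples in each parental group ",
         "(got A=", n[["A"]], ", P=", n[["P"]], ")")
  if (n[["F1"]] < 2)
    stop("sample sheet: need >= 2 F1 samples (got ", n[["F1"]], ")")
  kept <- ss[!ss$excluded_in_reduced, ]
  nk <- table(factor(kept$group, levels = GROUPS))
  if (any(nk == 0))
    stop("sample sheet: reduced design leaves group ",
         names(nk)[which(nk == 0)[1]], " empty")
  invisible(ss)
}

#' Samples belonging to one group
#' @param ss a [sample_sheet()].
#' @param group one of `"A"`, `"P"`, `"F1"`.
#' @param reduced if `TRUE`, drop samples flagged `excluded_in_reduced`.
#' @return character vector of sample ids.
#' @export
group_samples <- function(ss, group, reduced = FALSE) {
  keep <- ss$group == group
  if (reduced) keep <- keep & !ss$excluded_in_reduced
  ss$sample_id[keep]
}

#' Construct a validated count matrix
#'
#' @param counts integer matrix (contigs x samples) of mapped-read counts,
#'   with contig ids as rownames and sample ids as colnames.
#' @param contig_lengths optional named vector of contig lengths in bases
#'   (only used for RPKM-style reporting, never required).
#' @return An integer matrix of class `"count_matrix"`.
#' @export
count_matrix <- function(counts, contig_lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix: contig ids (rownames) and sample ids (colnames) required")
  if (anyDuplicated(rownames(counts)))
    stop("count matrix: duplicated contig_id '",
         rownames(counts)[duplicated(rownames(counts))][1], "'")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)[1, ]
    stop("count matrix: cell [", rownames(counts)[bad[1]], ", ",
         colnames(counts)[bad[2]], "] = ", counts[bad[1], bad[2]],
         " is not a non-negative integer")
  }
  storage.mode(counts) <- "integer"
  if (!is.null(contig_lengths)) {
    if (is.null(names(contig_lengths)) ||
        !all(rownames(counts) %in% names(contig_lengths)))
      stop("count matrix: contig_lengths must be named by contig_id")
    if (any(contig_lengths <= 0))
      stop("count matrix: contig lengths must be positive")
    attr(counts, "contig_lengths") <- contig_lengths[rownames(counts)]
  }
  class(counts) <- c("count_matrix", class(counts))
  counts
}

#' Read a count matrix from TSV
#'
#' Expects a header row `contig_id<TAB>sample1<TAB>...` followed by one row
#' per contig with integer cells.
#'
#' @param path path to a tab-separated file.
#' @param sample_sheet optional [sample_sheet()]; when given, the file's
#'   sample columns are checked by name and order against it.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, sample_sheet = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("count matrix file ", path, ": no sample columns")
  ids <- df[[1]]
  m <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
              dimnames = list(ids, colnames(df)[-1]))
  for (j in seq_len(ncol(df) - 1L)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop("count matrix file ", path, ": cell [row '", ids[bad[1]],
           "', column '", colnames(df)[j + 1L], "'] = '",
           df[[j + 1L]][bad[1]], "' is not a non-negative integer")
    m[, j] <- v
  }
  cm <- count_matrix(m)
  if (!is.null(sample_sheet)) {
    if (!identical(colnames(cm), sample_sheet$sample_id))
      stop("count matrix file ", path, ": sample columns (",
           paste(colnames(cm), collapse = ","),
           ") do not match the sample sheet (",
           paste(sample_sheet$sample_id, collapse = ","), ")")
  }
  message("read_count_matrix: ", nrow(cm), " contigs x ", ncol(cm),
          " samples from ", path)
  cm
}

#' Write a count matrix to TSV
#' @param cm a [count_matrix()].
#' @param path output path.
#' @export
write_count_matrix <- function(cm, path) {
  df <- data.frame(contig_id = rownames(cm), as.data.frame(unclass(cm)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("contig_id", colnames(cm))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet from TSV
#' @param path TSV with columns `sample_id`, `group`, `excluded_in_reduced`.
#' @return A [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  need <- c("sample_id", "group", "excluded_in_reduced")
  if (!all(need %in% colnames(df)))
    stop("sample sheet file ", path, ": missing column(s) ",
         paste(setdiff(need, colnames(df)), collapse = ","))
  sample_sheet(df$sample_id, df$group,
               toupper(df$excluded_in_reduced) %in% c("TRUE", "YES", "1"))
}

#' Write a sample sheet to TSV
#' @param ss a [sample_sheet()].
#' @param path output path.
#' @export
write_sample_sheet <- function(ss, path) {
  utils::write.table(as.data.frame(ss), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- pileup tables ---------------------------------------------------------

pileup_depth_cols <- function(sample_ids)
  as.vector(t(outer(sample_ids, c("rf", "rr", "af", "ar"), paste, sep = "_")))

#' Construct a pileup table
#'
#' One row per variant site. Positions are 1-based (pileup convention).
#' Each sample contributes a strand-resolved depth quadruple
#' (`<sample>_rf`, `_rr`, `_af`, `_ar`): reference-allele forward/reverse
#' then alternate-allele forward/reverse read depths.
#'
#' @param sites data.frame with columns `contig`, `pos`, `ref`, `alt`,
#'   `qual` followed by the four depth columns per sample.
#' @param sample_ids character vector of sample ids in column order.
#' @return A `data.frame` of class `"pileup_table"`.
#' @export
pileup_table <- function(sites, sample_ids) {
  need <- c("contig", "pos", "ref", "alt", "qual",
            pileup_depth_cols(sample_ids))
  miss <- setdiff(need, colnames(sites))
  if (length(miss))
    stop("pileup table: missing column(s) ", paste(miss, collapse = ","))
  sites <- sites[, need, drop = FALSE]
  if (nrow(sites)) {
    if (any(sites$pos < 1 | sites$pos != round(sites$pos)))
      stop("pileup table: positions must be 1-based integers")
    badb <- which(!(sites$ref %in% BASES) | !(sites$alt %in% BASES))
    if (length(badb))
      stop("pileup table: record ", sites$contig[badb[1]], ":",
           sites$pos[badb[1]], " has non-ACGT allele")
    same <- which(sites$ref == sites$alt)
    if (length(same))
      stop("pileup table: record ", sites$contig[same[1]], ":",
           sites$pos[same[1]], " has ref == alt ('", sites$ref[same[1]], "')")
    if (any(sites$qual < 0))
      stop("pileup table: negative site quality")
    dp <- as.matrix(sites[, pileup_depth_cols(sample_ids), drop = FALSE])
    badd <- which(is.na(dp) | dp < 0 | dp != round(dp), arr.ind = TRUE)
    if (nrow(badd))
      stop("pileup table: record ", sites$contig[badd[1, 1]], ":",
           sites$pos[badd[1, 1]], " column '", colnames(dp)[badd[1, 2]],
           "' has invalid depth '", dp[badd[1, 1], badd[1, 2]], "'")
  }
  rownames(sites) <- NULL
  attr(sites, "sample_ids") <- sample_ids
  class(sites) <- c("pileup_table", "data.frame")
  sites
}

#' Read a pileup table from TSV
#'
#' Expects header `contig  pos  ref  alt  qual` followed by four columns
#' (`<sample>_rf`, `_rr`, `_af`, `_ar`) per sample, in sample-sheet order.
#'
#' @param path TSV path.
#' @param sample_sheet optional [sample_sheet()] to check sample identity
#'   and order against.
#' @return A [pileup_table()].
#' @export
read_pileup_table <- function(path, sample_sheet = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  dcols <- setdiff(colnames(df), c("contig", "pos", "ref", "alt", "qual"))
  if (length(dcols) %% 4L != 0L)
    stop("pileup file ", path, ": depth columns not a multiple of 4")
  ids <- unique(sub("_(rf|rr|af|ar)$", "", dcols))
  pt <- pileup_table(df, ids)
  if (!is.null(sample_sheet) &&
      !identical(ids, sample_sheet$sample_id))
    stop("pileup file ", path,
         ": sample columns do not match the sample sheet")
  message("read_pileup_table: ", nrow(pt), " sites x ", length(ids),
          " samples from ", path)
  pt
}

#' Write a pileup table to TSV
#' @param pt a [pileup_table()].
#' @param path output path.
#' @export
write_pileup_table <- function(pt, path) {
  utils::write.table(as.data.frame(pt), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-sample, per-allele depths for one pileup row
#'
#' Sums forward and reverse strands for each allele.
#'
#' @param pt a [pileup_table()].
#' @param samples sample ids to extract (default all).
#' @return list with matrices `ref` and `alt` (sites x samples) of
#'   strand-summed depths, plus `ref_fwd`, `ref_rev`, `alt_fwd`, `alt_rev`.
#' @export
pileup_allele_depths <- function(pt, samples = attr(pt, "sample_ids")) {
  get <- function(sfx) {
    m <- as.matrix(as.data.frame(pt)[, paste(samples, sfx, sep = "_"),
                                     drop = FALSE])
    colnames(m) <- samples
    m
  }
  rf <- get("rf"); rr <- get("rr"); af <- get("af"); ar <- get("ar")
  list(ref = rf + rr, alt = af + ar,
       ref_fwd = rf, ref_rev = rr, alt_fwd = af, alt_rev = ar)
}

# ---- combined classification table ----------------------------------------

CLASS_LEVELS <- list(
  species_difference = c("A", "P", "NONE"),
  non_additive = c("UP", "DOWN", "MID"),
  transgressive = c("UP", "DOWN", "NONE"),
  allelic_bias = c("A", "P", "INCONSISTENT", "NONE"))
PROV_LEVELS <- c("BOTH", "FULL", "REDUCED", "NONE")

#' Construct a per-contig classification table
#'
#' Combines the five inheritance flags with per-flag provenance. Symbols
#' follow ASCII conventions: direction `UP`/`DOWN`/`MID`, accession/allele
#' `A`/`P`, provenance `BOTH`/`FULL`/`REDUCED` (significant in both the
#' complete and the outlier-reduced analyses, or in one only).
#'
#' @param df data.frame with columns `contig_id`, `species_difference`,
#'   `species_provenance`, `non_additive`, `non_additive_provenance`,
#'   `transgressive`, `transgressive_provenance`, `high_cv` (logical),
#'   `high_cv_provenance`, `allelic_bias`, `allelic_bias_provenance`.
#' @return data.frame of class `"classification_table"`.
#' @export
classification_table <- function(df) {
  cols <- classification_columns()
  miss <- setdiff(cols, colnames(df))
  if (length(miss))
    stop("classification table: missing column(s) ",
         paste(miss, collapse = ","))
  df <- df[, cols, drop = FALSE]
  df$high_cv <- as.logical(df$high_cv)
  for (fl in names(CLASS_LEVELS)) {
    bad <- which(!(df[[fl]] %in% CLASS_LEVELS[[fl]]))
    if (length(bad))
      stop("classification table: contig ", df$contig_id[bad[1]],
           " has invalid ", fl, " '", df[[fl]][bad[1]], "'")
  }
  for (pv in grep("_provenance$", cols, value = TRUE)) {
    bad <- which(!(df[[pv]] %in% PROV_LEVELS))
    if (length(bad))
      stop("classification table: contig ", df$contig_id[bad[1]],
           " has invalid ", pv, " '", df[[pv]][bad[1]], "'")
  }
  none_of <- list(species_difference = "NONE", non_additive = "MID",
                  transgressive = "NONE", allelic_bias = "NONE")
  for (fl in names(none_of)) {
    pv <- paste0(switch(fl, species_difference = "species", fl),
                 "_provenance")
    flagged <- df[[fl]] != none_of[[fl]]
    bad <- which(flagged & df[[pv]] == "NONE")
    if (length(bad))
      stop("classification table: contig ", df$contig_id[bad[1]],
           " has flag ", fl, " without provenance")
  }
  rownames(df) <- NULL
  class(df) <- c("classification_table", "data.frame")
  df
}

classification_columns <- function()
  c("contig_id",
    "species_difference", "species_provenance",
    "non_additive", "non_additive_provenance",
    "transgressive", "transgressive_provenance",
    "high_cv", "high_cv_provenance",
    "allelic_bias", "allelic_bias_provenance")

#' Write the classification table to TSV
#'
#' The column order is fixed and documented in `#`-prefixed header lines.
#'
#' @param ct a [classification_table()].
#' @param path output path.
#' @export
write_classification_table <- function(ct, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# per-contig inheritance classification",
    "# columns: contig_id, species_difference (A|P|NONE), species_provenance,",
    "#   non_additive (UP|DOWN|MID), non_additive_provenance,",
    "#   transgressive (UP|DOWN|NONE), transgressive_provenance,",
    "#   high_cv (TRUE|FALSE), high_cv_provenance,",
    "#   allelic_bias (A|P|INCONSISTENT|NONE), allelic_bias_provenance",
    "# provenance codes: BOTH|FULL|REDUCED|NONE"), con)
  utils::write.table(as.data.frame(ct), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a classification table written by [write_classification_table()]
#' @param path TSV path.
#' @return a [classification_table()].
#' @export
read_classification_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  classification_table(df)
}
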