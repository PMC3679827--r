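# End-to-end orchestration: run the full and reduced analyses, intersect
# their flags into per-contig provenance, merge everything into the
# combined classification table, and expose a small CLI.

#' Run configuration
#'
#' Collects every pipeline threshold in one validated object so a run is
#' fully reconstructible from its log.
#'
#' @param q_threshold BH q-value significance threshold (default 0.01).
#' @param ci_level prediction-band coverage for non-additivity (0.99).
#' @param cv_threshold high-variance CV threshold (2).
#' @param cv_formula CV formula, see [cv_f1()].
#' @param min_qual,min_depth fixed-SNP filters, see [call_fixed_snps()].
#' @param run_reduced also run the reduced (outlier-excluded) analysis.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(q_threshold = 0.01, ci_level = 0.99,
                       cv_threshold = 2,
                       cv_formula = c("lognormal_standard", "literal"),
                       min_qual = 80, min_depth = 5, run_reduced = TRUE) {
  stopifnot(q_threshold > 0, q_threshold < 1,
            ci_level > 0, ci_level < 1, cv_threshold > 0,
            min_qual >= 0, min_depth >= 0)
  cfg <- list(q_threshold = q_threshold, ci_level = ci_level,
              cv_threshold = cv_threshold,
              cv_formula = match.arg(cv_formula),
              min_qual = min_qual, min_depth = min_depth,
              run_reduced = isTRUE(run_reduced))
  class(cfg) <- "run_config"
  cfg
}

run_one_analysis <- function(counts, ss, cfg, snps, pileup, reduced) {
  sm <- if (reduced) ss$sample_id[!ss$excluded_in_reduced] else ss$sample_id
  cm <- unclass(counts)[, sm, drop = FALSE]
  cm <- count_matrix(cm)
  grp <- ss$group[match(sm, ss$sample_id)]
  sf <- estimate_size_factors(cm)
  disp <- estimate_dispersions(cm, sf, grp)
  gs <- function(g) sm[grp == g]
  da_AP <- pairwise_da(cm, sf, disp, gs("A"), gs("P"), cfg$q_threshold)
  da_AF <- pairwise_da(cm, sf, disp, gs("A"), gs("F1"), cfg$q_threshold)
  da_PF <- pairwise_da(cm, sf, disp, gs("P"), gs("F1"), cfg$q_threshold)
  ss_sub <- ss[match(sm, ss$sample_id), , drop = FALSE]
  pairs <- midparent_means(cm, sf, ss_sub)
  mfit <- fit_midparent_model(pairs)
  nonadd <- classify_nonadditive(mfit, pairs, cfg$ci_level)
  transg <- classify_transgressive(da_AF, da_PF)
  cv <- cv_f1(cm, sf, gs("F1"), cfg$cv_threshold, cfg$cv_formula)
  bias_snp <- bias_contig <- NULL
  if (!is.null(snps) && nrow(snps)) {
    ac <- extract_allele_counts(snps, pileup, gs("F1"))
    bias_snp <- test_allelic_bias(ac, sf, cfg$q_threshold)
    bias_contig <- aggregate_to_contig(bias_snp)
  }
  list(samples = sm, size_factors = sf, dispersions = disp,
       da_AP = da_AP, da_AF = da_AF, da_PF = da_PF,
       midparent_fit = mfit, nonadditive = nonadd, transgressive = transg,
       cv = cv, bias_snp = bias_snp, bias_contig = bias_contig)
}

#' Run the full and reduced analyses end-to-end
#'
#' Executes the three pairwise comparisons, the midparent/non-additive,
#' transgressive and CV classifications, and the allelic-bias chain on the
#' complete sample set and (when `cfg$run_reduced`) on the reduced set
#' excluding the sample-sheet-flagged outliers. Fixed SNPs are called once
#' from the complete parental pileups (accession-level discovery needs
#' both samples of each parent); only the F1 allele testing is repeated
#' per analysis.
#'
#' @param counts a [count_matrix()].
#' @param ss a [sample_sheet()].
#' @param pileup a [pileup_table()] or `NULL` to skip allelic bias.
#' @param cfg a [run_config()].
#' @return list of class `"hybrid_bundle"` with elements `full`,
#'   `reduced` (or `NULL`), `snps`, `config`, `samples`.
#' @export
run_full_and_reduced <- function(counts, ss, pileup = NULL,
                                 cfg = run_config()) {
  validate_sample_sheet(ss)
  if (cfg$run_reduced) {
    kept <- ss[!ss$excluded_in_reduced, ]
    if (!all(GROUPS %in% kept$group))
      stop("run_full_and_reduced: reduced set leaves a group empty")
  }
  snps <- NULL
  if (!is.null(pileup) && nrow(pileup))
    snps <- call_fixed_snps(pileup, ss, cfg$min_qual, cfg$min_depth)
  message("run_full_and_reduced: q<", cfg$q_threshold, ", ci=",
          cfg$ci_level, ", cv>", cfg$cv_threshold, " (", cfg$cv_formula,
          "), snp filters qual>=", cfg$min_qual, " depth>=", cfg$min_depth,
          if (!is.null(snps)) paste0("; ", nrow(snps), " fixed SNPs") else
            "; no pileup")
  full <- run_one_analysis(counts, ss, cfg, snps, pileup, reduced = FALSE)
  reduced <- if (cfg$run_reduced)
    run_one_analysis(counts, ss, cfg, snps, pileup, reduced = TRUE)
  out <- list(full = full, reduced = reduced, snps = snps, config = cfg,
              samples = ss)
  class(out) <- "hybrid_bundle"
  out
}

# Combine a flag observed in the full and reduced analyses into
# (value, provenance); disagreeing non-none values demote to none.
merge_flag <- function(vf, vr, none, run_reduced) {
  n <- length(vf)
  if (!run_reduced)
    return(list(value = vf,
                provenance = ifelse(vf != none, "FULL", "NONE")))
  value <- rep(none, n); prov <- rep("NONE", n)
  fset <- vf != none; rset <- vr != none
  agree <- fset & rset & vf == vr
  value[agree] <- vf[agree]; prov[agree] <- "BOTH"
  fonly <- fset & !rset
  value[fonly] <- vf[fonly]; prov[fonly] <- "FULL"
  ronly <- rset & !fset
  value[ronly] <- vr[ronly]; prov[ronly] <- "REDUCED"
  # fset & rset & vf != vr stays none/NONE (direction conflict)
  list(value = value, provenance = prov)
}

#' Merge all flags into the combined classification table
#'
#' One row per contig combining the species difference (A vs P), the
#' non-additive, transgressive and high-CV flags and the allelic-bias
#' direction, each with full/reduced provenance. Per-category totals are
#' reported via `message()` and returned in `attr(, "summary")`.
#'
#' @param bundle a [run_full_and_reduced()] result.
#' @return a [classification_table()].
#' @export
classify_all <- function(bundle) {
  fu <- bundle$full; re <- bundle$reduced
  rr <- !is.null(re)
  ids <- fu$da_AP$contig_id
  sig_dir <- function(da) {
    s <- !is.na(da$significant) & da$significant
    ifelse(s, ifelse(da$log2fc < 0, "A", "P"), "NONE")   # log2fc is P over A
  }
  spec <- merge_flag(sig_dir(fu$da_AP),
                     if (rr) sig_dir(re$da_AP) else NULL, "NONE", rr)
  na_lab <- function(an) {
    x <- an$nonadditive$non_additive
    ifelse(x == "above", "UP", ifelse(x == "below", "DOWN", "MID"))
  }
  nonadd <- merge_flag(na_lab(fu), if (rr) na_lab(re) else NULL, "MID", rr)
  tg_lab <- function(an)
    ifelse(an$transgressive$transgressive == "HIGH", "UP",
           ifelse(an$transgressive$transgressive == "LOW", "DOWN", "NONE"))
  transg <- merge_flag(tg_lab(fu), if (rr) tg_lab(re) else NULL, "NONE", rr)
  cv_lab <- function(an) ifelse(an$cv$high_cv, "YES", "NO")
  hcv <- merge_flag(cv_lab(fu), if (rr) cv_lab(re) else NULL, "NO", rr)
  ab_lab <- function(an) {
    if (is.null(an$bias_contig)) return(rep("NONE", length(ids)))
    m <- match(ids, an$bias_contig$contig_id)
    d <- an$bias_contig$direction[m]
    out <- rep("NONE", length(ids))
    out[!is.na(d) & d == "A_allele"] <- "A"
    out[!is.na(d) & d == "P_allele"] <- "P"
    out[!is.na(d) & d == "inconsistent"] <- "INCONSISTENT"
    out
  }
  bias <- merge_flag(ab_lab(fu), if (rr) ab_lab(re) else NULL, "NONE", rr)
  ct <- classification_table(data.frame(
    contig_id = ids,
    species_difference = spec$value, species_provenance = spec$provenance,
    non_additive = nonadd$value, non_additive_provenance = nonadd$provenance,
    transgressive = transg$value,
    transgressive_provenance = transg$provenance,
    high_cv = hcv$value == "YES", high_cv_provenance = hcv$provenance,
    allelic_bias = bias$value, allelic_bias_provenance = bias$provenance,
    stringsAsFactors = FALSE))
  summ <- c(species_difference = sum(ct$species_difference != "NONE"),
            non_additive = sum(ct$non_additive != "MID"),
            transgressive = sum(ct$transgressive != "NONE"),
            high_cv = sum(ct$high_cv),
            allelic_bias = sum(ct$allelic_bias != "NONE"))
  message("classify_all: ", paste(names(summ), summ, sep = "=",
                                  collapse = ", "))
  attr(ct, "summary") <- summ
  ct
}

#' Run the whole pipeline from files
#'
#' Reads the count matrix, sample sheet and (optionally) pileup table,
#' runs [run_full_and_reduced()] and [classify_all()], and writes the
#' classification table plus a plain-text summary under `out_dir`.
#'
#' @param counts_path,samples_path,pileup_path input TSV paths
#'   (`pileup_path = NULL` skips allelic bias).
#' @param out_dir output directory.
#' @param cfg a [run_config()].
#' @return invisibly, the bundle with the classification attached.
#' @export
run_pipeline <- function(counts_path, samples_path, pileup_path = NULL,
                         out_dir = ".", cfg = run_config()) {
  ss <- read_sample_sheet(samples_path)
  counts <- read_count_matrix(counts_path, ss)
  pileup <- if (!is.null(pileup_path)) read_pileup_table(pileup_path, ss)
  bundle <- run_full_and_reduced(counts, ss, pileup, cfg)
  ct <- classify_all(bundle)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_classification_table(ct, file.path(out_dir, "classification.tsv"))
  writeLines(report_text(bundle, ct), file.path(out_dir, "summary.txt"))
  bundle$classification <- ct
  invisible(bundle)
}

#' Plain-text run report
#' @param bundle a [run_full_and_reduced()] result.
#' @param ct the matching [classify_all()] table.
#' @return character vector of report lines.
#' @export
report_text <- function(bundle, ct) {
  s <- attr(ct, "summary")
  an <- bundle$full
  nsig <- function(da) sum(da$significant, na.rm = TRUE)
  c("hybridexpress run summary",
    sprintf("samples: %d (%s reduced analysis)", nrow(bundle$samples),
            if (is.null(bundle$reduced)) "without" else "with"),
    sprintf("significant A vs P: %d; A vs F1: %d; P vs F1: %d (full)",
            nsig(an$da_AP), nsig(an$da_AF), nsig(an$da_PF)),
    sprintf("midparent model (full): slope %.4f, intercept %.4g, R^2 %.4f, %d influential contig(s) removed",
            an$midparent_fit$slope, an$midparent_fit$intercept,
            an$midparent_fit$r_squared,
            length(an$midparent_fit$removed_contigs)),
    if (!is.null(bundle$snps))
      sprintf("fixed SNPs: %d in %d contigs", nrow(bundle$snps),
              length(unique(bundle$snps$contig))),
    paste0("classification: ",
           paste(names(s), s, sep = "=", collapse = ", ")))
}

#' Command-line interface
#'
#' `hybridexpress_cli(c("simulate", "--out-dir", DIR, ...))` writes a
#' synthetic dataset; `hybridexpress_cli(c("run", "--counts", F,
#' "--samples", F, "--pileup", F, "--out-dir", DIR))` runs the pipeline;
#' `report` prints the summary of an existing run directory.
#'
#' @param args character vector of arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly.
#' @export
hybridexpress_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: hybridexpress simulate|run|report [options]\n")
    return(invisible(1L))
  }
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (!length(i)) return(default)
    args[i + 1L]
  }
  cmd <- args[1]
  if (cmd == "simulate") {
    cfg <- sim_config(
      n_contigs = as.integer(opt("n-contigs", 16312L)),
      seed = as.integer(opt("seed", 1L)))
    simulate_dataset(cfg, opt("out-dir", "."))
  } else if (cmd == "run") {
    cfg <- run_config(
      q_threshold = as.numeric(opt("q", 0.01)),
      ci_level = as.numeric(opt("ci", 0.99)),
      cv_threshold = as.numeric(opt("cv-threshold", 2)),
      cv_formula = opt("cv-formula", "lognormal_standard"),
      min_qual = as.numeric(opt("min-qual", 80)),
      min_depth = as.numeric(opt("min-depth", 5)),
      run_reduced = is.null(opt("no-reduced")))
    run_pipeline(opt("counts"), opt("samples"), opt("pileup"),
                 opt("out-dir", "."), cfg)
  } else if (cmd == "report") {
    cat(readLines(file.path(opt("out-dir", "."), "summary.txt")), sep = "\n")
  } else {
    cat("unknown command: ", cmd, "\n")
    return(invisible(1L))
  }
  invisible(0L)
}
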