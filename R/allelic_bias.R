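# Allele-specific expression: fixed-SNP discovery from parental pileups,
# per-allele counting in F1s with one-strand artifact removal, SNP-level
# bias testing with the NB exact test, contig-level aggregation, and the
# cis/trans overlap analyses against parental accession differences.

#' Call fixed inter-parental SNPs from parental pileup records
#'
#' A site is retained when all of the following hold: (i) within each
#' parental accession exactly one allele is observed across its samples
#' (any read of a second base fails, up to `minor_allele_tol`); (ii) the
#' two accessions' alleles differ — which also excludes sites where every
#' parental sample carries the alternate base, i.e. divergence from the
#' reference but not between accessions; (iii) site quality is at least
#' `min_qual` (phred); (iv) every parental sample covers the site with at
#' least `min_depth` reads. Such sites allow parent-of-origin assignment
#' of hybrid reads.
#'
#' @param pileups a [pileup_table()] containing the parental samples.
#' @param ss a [sample_sheet()] naming the parental samples (groups A, P).
#' @param min_qual minimum phred site quality (default 80).
#' @param min_depth minimum per-parental-sample depth (default 5).
#' @param minor_allele_tol tolerated within-accession minor-allele read
#'   fraction (default 0: strict).
#' @return data.frame of class `"fixed_snps"`: `contig`, `pos`, `ref`,
#'   `alt`, `qual`, `allele_A`, `allele_P` (bases) and `A_is_ref`.
#' @export
call_fixed_snps <- function(pileups, ss, min_qual = 80, min_depth = 5,
                            minor_allele_tol = 0) {
  a_samples <- group_samples(ss, "A")
  p_samples <- group_samples(ss, "P")
  if (length(a_samples) < 2 || length(p_samples) < 2)
    stop("call_fixed_snps: need >= 2 pileup samples per parental accession")
  pt <- as.data.frame(pileups)
  dA <- pileup_allele_depths(pileups, a_samples)
  dP <- pileup_allele_depths(pileups, p_samples)
  par_ref <- cbind(dA$ref, dP$ref); par_alt <- cbind(dA$alt, dP$alt)
  depth_ok <- rowSums((par_ref + par_alt) < min_depth) == 0
  qual_ok <- pt$qual >= min_qual
  acc_allele <- function(refm, altm) {
    r <- rowSums(refm); a <- rowSums(altm)
    tot <- r + a
    minor <- pmin(r, a)
    mono <- tot > 0 & (minor == 0 | minor / tot <= minor_allele_tol)
    ifelse(mono, ifelse(r >= a, "ref", "alt"), NA_character_)
  }
  aA <- acc_allele(dA$ref, dA$alt)
  aP <- acc_allele(dP$ref, dP$alt)
  keep <- depth_ok & qual_ok & !is.na(aA) & !is.na(aP) & aA != aP
  out <- data.frame(contig = pt$contig[keep], pos = pt$pos[keep],
                    ref = pt$ref[keep], alt = pt$alt[keep],
                    qual = pt$qual[keep],
                    allele_A = ifelse(aA[keep] == "ref", pt$ref[keep],
                                      pt$alt[keep]),
                    allele_P = ifelse(aP[keep] == "ref", pt$ref[keep],
                                      pt$alt[keep]),
                    A_is_ref = aA[keep] == "ref",
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("fixed_snps", "data.frame")
  out
}

#' Per-allele read counts in F1 samples with strand screening
#'
#' For each fixed SNP, per-F1-sample counts of the A-genome and P-genome
#' alleles are formed by summing forward and reverse depths of the
#' corresponding base. A SNP gets `strand_ok = FALSE` — and is excluded
#' from testing — when either allele's reads, pooled over all F1 samples,
#' are nonzero yet occur on exactly one strand (a sequencing-artifact
#' signature). SNPs absent from the pileup are dropped with a message.
#'
#' @param snps a [call_fixed_snps()] result.
#' @param pileups a [pileup_table()] containing the F1 samples.
#' @param f1_samples character vector of F1 sample ids.
#' @return list of class `"allele_counts"`: `snps` (the matched SNP table),
#'   matrices `count_A` and `count_P` (SNPs x F1 samples), and `strand_ok`.
#' @export
extract_allele_counts <- function(snps, pileups, f1_samples) {
  pt <- as.data.frame(pileups)
  key <- paste(pt$contig, pt$pos)
  hit <- match(paste(snps$contig, snps$pos), key)
  if (anyNA(hit)) {
    message("extract_allele_counts: ", sum(is.na(hit)),
            " SNP(s) absent from the F1 pileup; excluded")
    snps <- snps[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
  }
  d <- pileup_allele_depths(pileups, f1_samples)
  pick <- function(mat_ref, mat_alt)
    ifelse(matrix(snps$A_is_ref, nrow(snps), length(f1_samples)),
           mat_ref[hit, , drop = FALSE], mat_alt[hit, , drop = FALSE])
  count_A <- pick(d$ref, d$alt)
  count_P <- pick(d$alt, d$ref)
  fa <- pick(d$ref_fwd, d$alt_fwd); ra <- pick(d$ref_rev, d$alt_rev)
  fp <- pick(d$alt_fwd, d$ref_fwd); rp <- pick(d$alt_rev, d$ref_rev)
  one_strand <- function(f, r) {
    tf <- rowSums(f); tr <- rowSums(r)
    (tf + tr) > 0 & (tf == 0 | tr == 0)
  }
  strand_ok <- !(one_strand(fa, ra) | one_strand(fp, rp))
  dimnames(count_A) <- dimnames(count_P) <-
    list(paste(snps$contig, snps$pos, sep = ":"), f1_samples)
  out <- list(snps = snps, count_A = count_A, count_P = count_P,
              strand_ok = strand_ok, f1_samples = f1_samples)
  class(out) <- "allele_counts"
  out
}

#' SNP-level allelic-bias test
#'
#' Treats the two alleles of each SNP as the two groups of the NB exact
#' test, summing per-allele counts over F1 samples. Both alleles originate
#' from the same libraries, so identical per-sample size factors (from the
#' contig-level count matrix) apply to both groups. Dispersions are
#' estimated from the allele-count table with [estimate_dispersions()];
#' BH adjustment forms a single family across all tested SNPs. A SNP is
#' tested when it passed the strand screen and at least `min_informative`
#' F1 samples have nonzero total depth.
#'
#' @param allele_counts an [extract_allele_counts()] result.
#' @param sf named size factors for the F1 samples.
#' @param q_threshold BH significance threshold.
#' @param min_informative minimum F1 samples with reads (default 2).
#' @return data.frame of class `"snp_bias_result"`: per SNP `contig`,
#'   `pos`, `k_A`, `k_P`, `log2_bias` (A over P, pooled normalized),
#'   `pvalue`, `qvalue`, `significant`, `tested`.
#' @export
test_allelic_bias <- function(allele_counts, sf, q_threshold = 0.01,
                              min_informative = 2) {
  ac <- allele_counts
  f1 <- ac$f1_samples
  sfv <- sf[f1]
  informative <- rowSums(ac$count_A + ac$count_P > 0) >= min_informative
  tested <- ac$strand_ok & informative
  n <- nrow(ac$snps)
  p <- rep(NA_real_, n)
  alpha <- rep(NA_real_, n)
  if (any(tested)) {
    tab <- cbind(ac$count_A[tested, , drop = FALSE],
                 ac$count_P[tested, , drop = FALSE])
    rownames(tab) <- rownames(ac$count_A)[tested]
    alpha[tested] <- estimate_dispersions(
      tab, c(sfv, sfv), rep(c("alleleA", "alleleP"), each = length(f1)))
    s <- sum(sfv); ssq <- sum(sfv^2)
    kA <- rowSums(ac$count_A); kP <- rowSums(ac$count_P)
    for (i in which(tested))
      p[i] <- nb_exact_test(kA[i], kP[i], s, s, alpha[i], ssq, ssq)
  }
  q <- rep(NA_real_, n)
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  nA <- rowSums(sweep(ac$count_A, 2, sfv, "/"))
  nP <- rowSums(sweep(ac$count_P, 2, sfv, "/"))
  res <- data.frame(contig = ac$snps$contig, pos = ac$snps$pos,
                    k_A = rowSums(ac$count_A), k_P = rowSums(ac$count_P),
                    log2_bias = log2(nA / nP),
                    pvalue = p, qvalue = q,
                    significant = ifelse(tested, q < q_threshold, NA),
                    tested = tested, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "q_threshold") <- q_threshold
  class(res) <- c("snp_bias_result", "data.frame")
  res
}

#' Aggregate SNP-level bias results to contigs
#'
#' A contig is flagged when at least one of its SNPs is significant;
#' `mean_log2_bias` averages the (finite) log2 biases of significant SNPs,
#' and `mean_log2_bias_all` those of all tested SNPs (the quantity used by
#' [fit_bias_vs_parental()], which must not condition on significance).
#' Significant SNPs disagreeing in sign make the contig `inconsistent`.
#'
#' @param snp_results a [test_allelic_bias()] result.
#' @return data.frame of class `"contig_bias_result"`: `contig_id`,
#'   `n_snps_tested`, `n_snps_significant`, `mean_log2_bias`,
#'   `mean_log2_bias_all`, `direction` in
#'   `{A_allele, P_allele, inconsistent, none}`.
#' @export
aggregate_to_contig <- function(snp_results) {
  sp <- split(seq_len(nrow(snp_results)), snp_results$contig)
  rows <- lapply(names(sp), function(cid) {
    i <- sp[[cid]]
    ti <- i[snp_results$tested[i]]
    si <- ti[!is.na(snp_results$significant[ti]) &
               snp_results$significant[ti]]
    b <- snp_results$log2_bias[si]
    ball <- snp_results$log2_bias[ti]
    dir <- if (!length(si)) "none"
           else if (all(b > 0)) "A_allele"
           else if (all(b < 0)) "P_allele"
           else "inconsistent"
    data.frame(contig_id = cid,
               n_snps_tested = length(ti), n_snps_significant = length(si),
               mean_log2_bias = if (length(si)) mean(b[is.finite(b)])
                                else NA_real_,
               mean_log2_bias_all = if (length(ti))
                 mean(ball[is.finite(ball)]) else NA_real_,
               direction = dir, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contig_bias_result", "data.frame")
  out
}

#' Overlap between allelic bias and parental accession differences
#'
#' Restricted to contigs with at least one tested SNP and a tested parental
#' comparison: counts of bias-significant, parent-significant and doubly
#' significant contigs, and — within the overlap — the fraction whose
#' directions agree (accession A higher matching the A allele higher in
#' F1s, and likewise for P; `inconsistent` contigs count as disagreement).
#' Strong agreement indicates cis regulatory divergence; bias at the
#' type-I level only indicates trans.
#'
#' @param bias_results an [aggregate_to_contig()] result.
#' @param parental_results a [pairwise_da()] result with X = parent A,
#'   Y = parent P (log2fc is P over A).
#' @return list with `n_tested`, `n_bias_significant`,
#'   `n_parent_significant`, `n_both`, `n_direction_agree`,
#'   `fraction_agree`.
#' @export
overlap_with_parental <- function(bias_results, parental_results) {
  hit <- match(bias_results$contig_id, parental_results$contig_id)
  ok <- !is.na(hit) & bias_results$n_snps_tested > 0
  br <- bias_results[ok, , drop = FALSE]
  pr <- parental_results[hit[ok], , drop = FALSE]
  keep <- pr$tested
  br <- br[keep, , drop = FALSE]; pr <- pr[keep, , drop = FALSE]
  bias_sig <- br$n_snps_significant > 0
  par_sig <- !is.na(pr$significant) & pr$significant
  both <- bias_sig & par_sig
  # accession A higher <=> log2fc (P over A) < 0
  par_dir <- ifelse(pr$log2fc < 0, "A", "P")
  bias_dir <- ifelse(br$direction == "A_allele", "A",
                     ifelse(br$direction == "P_allele", "P", NA))
  agree <- both & !is.na(bias_dir) & bias_dir == par_dir
  list(n_tested = nrow(br),
       n_bias_significant = sum(bias_sig),
       n_parent_significant = sum(par_sig),
       n_both = sum(both),
       n_direction_agree = sum(agree),
       fraction_agree = if (sum(both)) sum(agree) / sum(both) else NA_real_)
}

#' Linear model of allelic bias on the parental accession difference
#'
#' OLS of the contig's mean log2 allelic bias (A allele over P allele,
#' averaged over tested SNPs) on the parental log2 fold change oriented
#' the same way (accession A over accession P). Under pure cis divergence
#' the slope is 1; under pure trans it is 0. Contigs with infinite values
#' are excluded.
#'
#' @param bias_results an [aggregate_to_contig()] result.
#' @param parental_results a [pairwise_da()] result with X = parent A,
#'   Y = parent P.
#' @return list with `slope`, `intercept`, `r_squared`, `slope_se`,
#'   `slope_ci99` (99% confidence interval), `n`.
#' @export
fit_bias_vs_parental <- function(bias_results, parental_results) {
  hit <- match(bias_results$contig_id, parental_results$contig_id)
  ok <- !is.na(hit) & bias_results$n_snps_tested > 0
  x <- -parental_results$log2fc[hit[ok]]   # A over P orientation
  y <- bias_results$mean_log2_bias_all[ok]
  use <- is.finite(x) & is.finite(y)
  if (sum(use) < 10)
    stop("fit_bias_vs_parental: fewer than 10 usable contigs")
  fit <- stats::lm(y[use] ~ x[use])
  s <- summary(fit)
  ci <- stats::confint(fit, level = 0.99)[2, ]
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       slope_se = s$coefficients[2, 2],
       slope_ci99 = unname(ci), n = sum(use))
}
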