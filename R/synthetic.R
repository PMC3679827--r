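# Synthetic-data generator with known ground truth.
#
# Emulates the study design this pipeline targets: 2 + 2 parental samples and
# 8 F1 hybrids over a ~16k-contig transcriptome reference, negative-binomially
# distributed read counts, and pileup records carrying fixed inter-parental
# SNPs. Effects are planted per contig (parental/trans differences, cis
# allelic bias, transgressive, high-variance) and recorded in a truth table
# so downstream recovery can be quantified.

#' Default study-design sample sheet
#'
#' Two samples per parental accession and eight F1 individuals; one parental
#' and one F1 sample are pre-flagged for exclusion in the reduced analysis,
#' mirroring the outlier screen of the motivating design.
#' @return a [sample_sheet()].
#' @export
default_samples <- function() {
  sample_sheet(
    sample_id = c("HA89.5", "HA89.9", "PET.2", "PET.3",
                  "F1.01", "F1.03", "F1.04", "F1.07",
                  "F1.14", "F1.17", "F1.TA", "F1.TB"),
    group = c("A", "A", "P", "P", rep("F1", 8)),
    excluded_in_reduced = c(FALSE, TRUE, FALSE, FALSE,
                            FALSE, FALSE, FALSE, FALSE,
                            FALSE, FALSE, TRUE, FALSE))
}

#' Simulation configuration
#'
#' Defaults state the emulated world once: a 16,312-contig reference with
#' base means spread log-uniformly over three decades, NB dispersion
#' alpha = 0.05 (variance m + alpha m^2), roughly 10% of contigs carrying a
#' parental accession difference (split between cis- and trans-driven),
#' transgressive contigs at the per-mille scale with an 8-fold effect (the
#' magnitude printed for the study's ten transgressive contigs), 1% of
#' contigs with high inter-F1 variance (sigma = 1.5 on the log scale, CV
#' about 2.9), and on average 0.85 fixed SNPs per contig (about 14k sites
#' total, about half of contigs carrying none).
#'
#' @param n_contigs number of contigs.
#' @param samples a [sample_sheet()]; default 2 A + 2 P + 8 F1.
#' @param base_mean_log10_range range of log10 base mean counts.
#' @param dispersion NB dispersion alpha (variance = m + alpha m^2).
#' @param fraction_parent_diff fraction of contigs with a parental
#'   difference equalized in F1 alleles (a trans effect; added to
#'   `fraction_trans`).
#' @param fraction_cis fraction with a cis-driven parental difference: the
#'   F1 allele ratio equals the parental mean ratio.
#' @param fraction_trans fraction with a trans-driven parental difference:
#'   F1 at the midparent with balanced alleles.
#' @param fraction_transgressive fraction with F1 mean outside the parental
#'   range (split evenly between high and low).
#' @param fraction_high_variance fraction with lognormal per-F1-individual
#'   expression multipliers.
#' @param parent_log2fc_magnitude |log2 fold change| planted between parents.
#' @param transgressive_multiplier fold change of the F1 mean beyond the
#'   parental range for transgressive contigs (> 1).
#' @param high_variance_sigma sd of the lognormal inter-F1 multiplier.
#' @param snps_per_contig_mean Poisson mean of fixed SNPs per contig.
#' @param mean_allele_depth target per-sample total read depth at a SNP.
#' @param strand_artifact_rate fraction of sites emitted as one-strand
#'   artifacts (alternate-allele reads on the forward strand only in F1s).
#' @param snp_violation_rate fraction of sites planted to violate each of
#'   the four fixed-SNP filter criteria (low quality, low depth,
#'   within-accession polymorphism, all-samples-alternate).
#' @param size_factor_range true library size factors are drawn log-uniform
#'   in this interval.
#' @param seed integer seed; all three generator operations are
#'   deterministic given the seed.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_contigs = 16312,
                       samples = default_samples(),
                       base_mean_log10_range = c(0.5, 3.5),
                       dispersion = 0.05,
                       fraction_parent_diff = 0.04,
                       fraction_cis = 0.03,
                       fraction_trans = 0.03,
                       fraction_transgressive = 0.001,
                       fraction_high_variance = 0.01,
                       parent_log2fc_magnitude = 1.5,
                       transgressive_multiplier = 8,
                       high_variance_sigma = 1.5,
                       snps_per_contig_mean = 0.85,
                       mean_allele_depth = 20,
                       strand_artifact_rate = 0.02,
                       snp_violation_rate = 0.05,
                       size_factor_range = c(0.7, 1.4),
                       seed = 1L) {
  fr <- c(fraction_parent_diff, fraction_cis, fraction_trans,
          fraction_transgressive, fraction_high_variance)
  if (any(fr < 0 | fr > 1))
    stop("sim_config: effect fractions must lie in [0, 1]")
  if (sum(fr) > 1)
    stop("sim_config: effect-class fractions sum to ", sum(fr), " > 1")
  if (dispersion < 0) stop("sim_config: dispersion must be >= 0")
  if (transgressive_multiplier <= 1)
    stop("sim_config: transgressive_multiplier must exceed 1")
  if (strand_artifact_rate < 0 || strand_artifact_rate > 1 ||
      snp_violation_rate < 0 || 4 * snp_violation_rate +
        strand_artifact_rate > 1)
    stop("sim_config: site class rates invalid")
  if (abs(seed) > 2^31 - 10) stop("sim_config: seed out of integer range")
  cfg <- list(n_contigs = as.integer(n_contigs), samples = samples,
              base_mean_log10_range = base_mean_log10_range,
              dispersion = dispersion,
              fraction_parent_diff = fraction_parent_diff,
              fraction_cis = fraction_cis, fraction_trans = fraction_trans,
              fraction_transgressive = fraction_transgressive,
              fraction_high_variance = fraction_high_variance,
              parent_log2fc_magnitude = parent_log2fc_magnitude,
              transgressive_multiplier = transgressive_multiplier,
              high_variance_sigma = high_variance_sigma,
              snps_per_contig_mean = snps_per_contig_mean,
              mean_allele_depth = mean_allele_depth,
              strand_artifact_rate = strand_artifact_rate,
              snp_violation_rate = snp_violation_rate,
              size_factor_range = size_factor_range,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Evaluate expr under a fixed seed without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

SIM_MODES <- c("null", "trans_diff", "cis_diff", "transgressive_high",
               "transgressive_low", "high_variance")

#' Draw per-contig ground truth
#'
#' Contig modes are drawn with the configured fractions; expected group
#' means and the F1 allele ratio obey the mode invariants: `null` and
#' `high_variance` contigs have equal means everywhere; `trans_diff` and
#' `cis_diff` contigs split the planted fold change symmetrically around
#' the base mean with the F1 at the midparent; only `cis_diff` contigs
#' carry an allele ratio != 1 (equal to mu_A / mu_P); transgressive contigs
#' put the F1 mean a multiplier beyond the parental range.
#'
#' @param config a [sim_config()].
#' @return data.frame of class `"truth_table"` with columns `contig_id`,
#'   `mode`, `mu_A`, `mu_P`, `mu_F1`, `allele_ratio`, `n_snps`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_contigs
    ids <- sprintf("contig%06d", seq_len(n))
    pr <- c(null = 1 - config$fraction_parent_diff - config$fraction_cis -
              config$fraction_trans - config$fraction_transgressive -
              config$fraction_high_variance,
            trans_diff = config$fraction_parent_diff + config$fraction_trans,
            cis_diff = config$fraction_cis,
            transgressive_high = config$fraction_transgressive / 2,
            transgressive_low = config$fraction_transgressive / 2,
            high_variance = config$fraction_high_variance)
    mode <- sample(names(pr), n, replace = TRUE, prob = pr)
    mu0 <- 10^stats::runif(n, config$base_mean_log10_range[1],
                           config$base_mean_log10_range[2])
    mu_A <- mu_P <- mu_F1 <- mu0
    diffm <- mode %in% c("trans_diff", "cis_diff")
    sgn <- ifelse(stats::runif(n) < 0.5, 1, -1)
    half <- 2^(config$parent_log2fc_magnitude / 2)
    mu_A[diffm] <- mu0[diffm] * half^sgn[diffm]
    mu_P[diffm] <- mu0[diffm] * half^(-sgn[diffm])
    mu_F1[diffm] <- (mu_A[diffm] + mu_P[diffm]) / 2
    hi <- mode == "transgressive_high"
    lo <- mode == "transgressive_low"
    mu_F1[hi] <- mu0[hi] * config$transgressive_multiplier
    mu_F1[lo] <- mu0[lo] / config$transgressive_multiplier
    allele_ratio <- ifelse(mode == "cis_diff", mu_A / mu_P, 1)
    n_snps <- stats::rpois(n, config$snps_per_contig_mean)
    tt <- data.frame(contig_id = ids, mode = mode, mu_A = mu_A, mu_P = mu_P,
                     mu_F1 = mu_F1, allele_ratio = allele_ratio,
                     n_snps = n_snps, stringsAsFactors = FALSE)
    class(tt) <- c("truth_table", "data.frame")
    tt
  })
}

#' Simulate the count matrix from a truth table
#'
#' Counts are drawn NB(mean = s_j * mu_group, dispersion alpha) with true
#' per-sample size factors drawn log-uniform in `size_factor_range`.
#' High-variance contigs additionally multiply each F1 sample's mean by an
#' independent lognormal(0, `high_variance_sigma`) factor.
#'
#' @param truth a [generate_truth()] table.
#' @param config the matching [sim_config()].
#' @return a [count_matrix()] with the true size factors stored in
#'   `attr(, "true_size_factors")`.
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(truth, "truth_table"))
  with_seed(config$seed + 1L, {
    ss <- config$samples
    m <- nrow(ss); n <- nrow(truth)
    sfr <- config$size_factor_range
    sf <- exp(stats::runif(m, log(sfr[1]), log(sfr[2])))
    names(sf) <- ss$sample_id
    mu_by_group <- cbind(A = truth$mu_A, P = truth$mu_P, F1 = truth$mu_F1)
    mu <- mu_by_group[, ss$group, drop = FALSE] %*% diag(sf)
    colnames(mu) <- ss$sample_id
    hv <- truth$mode == "high_variance"
    if (any(hv)) {
      f1c <- which(ss$group == "F1")
      mult <- matrix(exp(stats::rnorm(sum(hv) * length(f1c), 0,
                                      config$high_variance_sigma)),
                     nrow = sum(hv))
      mu[hv, f1c] <- mu[hv, f1c] * mult
    }
    a <- config$dispersion
    k <- if (a < 1e-12) stats::rpois(n * m, lambda = as.vector(mu))
         else stats::rnbinom(n * m, mu = as.vector(mu), size = 1 / a)
    cm <- matrix(k, nrow = n, dimnames = list(truth$contig_id, ss$sample_id))
    cm <- count_matrix(cm)
    attr(cm, "true_size_factors") <- sf
    cm
  })
}

SITE_CLASSES <- c("clean", "low_qual", "low_depth", "within_poly",
                  "all_alt", "strand_artifact")

#' Simulate a pileup table coherent with the simulated counts
#'
#' For every contig with `n_snps > 0`, sites are planted at which parental
#' samples carry accession-uniform alleles (A samples the reference/A-genome
#' allele, P samples the alternate) and F1 per-sample depths are the contig's
#' simulated counts thinned by a per-site capture fraction, then split
#' between the two parental alleles at the contig's true allele ratio. Reads
#' land on forward/reverse strands Bernoulli(1/2). A configurable fraction
#' of sites deliberately violates each fixed-SNP filter criterion, and
#' one-strand artifacts are emitted at `strand_artifact_rate`; the planted
#' class of every site is recorded in the attached site truth, together with
#' a record-level reapplication of the filter criteria
#' (`passes_filters`), usable as an exact expected set for SNP calling.
#'
#' @param truth a [generate_truth()] table.
#' @param counts the matching [simulate_counts()] matrix.
#' @param config the matching [sim_config()].
#' @return a [pileup_table()] with `attr(, "site_truth")`.
#' @export
simulate_pileups <- function(truth, counts, config) {
  stopifnot(inherits(truth, "truth_table"))
  ss <- config$samples
  with_seed(config$seed + 2L, {
    idx <- which(truth$n_snps > 0)
    nspc <- pmin(truth$n_snps[idx], 500L)
    ns <- sum(nspc)
    if (ns == 0L) {
      empty <- as.data.frame(matrix(numeric(0), 0,
                                    5 + 4 * nrow(ss),
                                    dimnames = list(NULL,
                                      c("contig", "pos", "ref", "alt", "qual",
                                        pileup_depth_cols(ss$sample_id)))))
      empty$contig <- character(0); empty$ref <- character(0)
      empty$alt <- character(0)
      pt <- pileup_table(empty, ss$sample_id)
      attr(pt, "site_truth") <- data.frame(contig = character(0),
                                           pos = integer(0),
                                           class = character(0),
                                           passes_filters = logical(0))
      return(pt)
    }
    row_of <- rep(idx, nspc)                     # truth row per site
    contig <- truth$contig_id[row_of]
    pos <- unlist(lapply(nspc, function(k) sort(sample.int(1000L, k))))
    v <- config$snp_violation_rate
    cls <- sample(SITE_CLASSES, ns, replace = TRUE,
                  prob = c(1 - 4 * v - config$strand_artifact_rate,
                           v, v, v, v, config$strand_artifact_rate))
    ref <- sample(BASES, ns, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), "")
    qual <- stats::runif(ns, 80, 200)
    qual[cls == "low_qual"] <- stats::runif(sum(cls == "low_qual"), 5, 79.5)

    m <- nrow(ss)
    a_cols <- which(ss$group == "A"); p_cols <- which(ss$group == "P")
    f_cols <- which(ss$group == "F1")
    cap <- pmin(1, config$mean_allele_depth / pmax(truth$mu_F1[row_of], 1))
    cnt <- unclass(counts)[contig, ss$sample_id, drop = FALSE]
    d <- matrix(stats::rbinom(ns * m, size = as.vector(cnt),
                              prob = rep(cap, m)), nrow = ns)

    ld <- which(cls == "low_depth")
    if (length(ld)) {                     # force one parental sample under 5
      tgt <- sample(c(a_cols, p_cols), length(ld), replace = TRUE)
      d[cbind(ld, tgt)] <- pmin(d[cbind(ld, tgt)],
                                sample(0:4, length(ld), replace = TRUE))
    }

    # per-sample allele counts: h = A-genome allele, p = P-genome allele
    h <- p <- matrix(0L, ns, m)
    h[, a_cols] <- d[, a_cols]
    p[, p_cols] <- d[, p_cols]
    wp <- which(cls == "within_poly")
    if (length(wp)) {                     # second A sample shows both alleles
      mixed <- a_cols[length(a_cols)]
      h[wp, mixed] <- stats::rbinom(length(wp), d[wp, mixed], 0.5)
      p[wp, mixed] <- d[wp, mixed] - h[wp, mixed]
    }
    ratio <- truth$allele_ratio[row_of]
    pHA <- ratio / (1 + ratio)
    for (j in f_cols) {
      h[, j] <- stats::rbinom(ns, d[, j], pHA)
      p[, j] <- d[, j] - h[, j]
    }
    aa <- which(cls == "all_alt")         # every sample carries the alt base
    if (length(aa)) { h[aa, ] <- 0L; p[aa, ] <- d[aa, ] }

    # A-genome allele is the reference base except at all_alt sites
    r_cnt <- h; a_cnt <- p
    rf <- matrix(stats::rbinom(ns * m, as.vector(r_cnt), 0.5), ns, m)
    rr <- r_cnt - rf
    af <- matrix(stats::rbinom(ns * m, as.vector(a_cnt), 0.5), ns, m)
    ar <- a_cnt - af
    sa <- which(cls == "strand_artifact") # F1 alt reads forward-only
    if (length(sa)) {
      af[sa, f_cols] <- a_cnt[sa, f_cols]
      ar[sa, f_cols] <- 0L
    }

    dp <- matrix(0L, ns, 4 * m)
    dp[, seq(1, 4 * m, 4)] <- rf; dp[, seq(2, 4 * m, 4)] <- rr
    dp[, seq(3, 4 * m, 4)] <- af; dp[, seq(4, 4 * m, 4)] <- ar
    colnames(dp) <- pileup_depth_cols(ss$sample_id)
    sites <- data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
                        qual = qual, dp, check.names = FALSE,
                        stringsAsFactors = FALSE)
    pt <- pileup_table(sites, ss$sample_id)
    attr(pt, "site_truth") <- data.frame(
      contig = contig, pos = pos, class = cls,
      passes_filters = site_passes_filters(rf, rr, af, ar, qual,
                                           a_cols, p_cols),
      stringsAsFactors = FALSE)
    pt
  })
}

# Record-level reapplication of the fixed-SNP criteria (brute-force oracle,
# independent of call_fixed_snps): per parental sample depth >= 5, site
# quality >= 80, a single allele within each accession, accession alleles
# differ (which also excludes sites where all samples carry the alternate).
site_passes_filters <- function(rf, rr, af, ar, qual, a_cols, p_cols,
                                min_qual = 80, min_depth = 5) {
  ns <- nrow(rf)
  ok <- logical(ns)
  for (i in seq_len(ns)) {
    dref <- rf[i, ] + rr[i, ]; dalt <- af[i, ] + ar[i, ]
    if (any(dref[c(a_cols, p_cols)] + dalt[c(a_cols, p_cols)] < min_depth))
      next
    if (qual[i] < min_qual) next
    allele_of <- function(cols) {
      r <- sum(dref[cols]); a <- sum(dalt[cols])
      if (r > 0 && a > 0) return(NA_character_)
      if (r > 0) "ref" else if (a > 0) "alt" else NA_character_
    }
    aA <- allele_of(a_cols); aP <- allele_of(p_cols)
    if (is.na(aA) || is.na(aP) || aA == aP) next
    ok[i] <- TRUE
  }
  ok
}

#' Write a full synthetic dataset to disk
#'
#' Writes `counts.tsv`, `pileup.tsv`, `samples.tsv`, `truth.tsv` and
#' `site_truth.tsv` under `out_dir`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects.
#' @export
simulate_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_truth(config)
  counts <- simulate_counts(truth, config)
  pileup <- simulate_pileups(truth, counts, config)
  write_count_matrix(counts, file.path(out_dir, "counts.tsv"))
  write_pileup_table(pileup, file.path(out_dir, "pileup.tsv"))
  write_sample_sheet(config$samples, file.path(out_dir, "samples.tsv"))
  utils::write.table(as.data.frame(truth), file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(attr(pileup, "site_truth"),
                     file.path(out_dir, "site_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(truth = truth, counts = counts, pileup = pileup,
                 samples = config$samples))
}
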