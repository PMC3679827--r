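# Minimal hand-built pileup worlds keep every rule visible; the generator
# based oracle check lives at the end and in test-acceptance.R.

mk_pileup <- function(rows, ids) {
  dpc <- hybridexpress:::pileup_depth_cols(ids)
  df <- do.call(rbind, lapply(rows, function(r) {
    dp <- setNames(as.list(r$dp), dpc)
    cbind(data.frame(contig = r$contig, pos = r$pos, ref = r$ref,
                     alt = r$alt, qual = r$qual, stringsAsFactors = FALSE),
          as.data.frame(dp, check.names = FALSE))
  }))
  pileup_table(df, ids)
}

ss6 <- sample_sheet(c("a1", "a2", "p1", "p2", "f1", "f2"),
                    c("A", "A", "P", "P", "F1", "F1"))
ids6 <- ss6$sample_id
# dp4 helper: ref split 50/50-ish, alt likewise
q4 <- function(ref, alt) c(ceiling(ref / 2), floor(ref / 2),
                           ceiling(alt / 2), floor(alt / 2))

test_that("call_fixed_snps applies all five conditions", {
  rows <- list(
    # clean fixed site: A = ref, P = alt, deep, high qual
    list(contig = "c1", pos = 1, ref = "A", alt = "G", qual = 120,
         dp = c(q4(10, 0), q4(12, 0), q4(0, 9), q4(0, 11),
                q4(5, 5), q4(6, 4))),
    # one A sample at depth 4 -> rejected (depth criterion)
    list(contig = "c1", pos = 2, ref = "A", alt = "G", qual = 120,
         dp = c(q4(4, 0), q4(12, 0), q4(0, 9), q4(0, 11),
                q4(5, 5), q4(6, 4))),
    # all four parental samples 100% alt -> rejected (reference-only divergence)
    list(contig = "c1", pos = 3, ref = "A", alt = "G", qual = 120,
         dp = c(q4(0, 10), q4(0, 12), q4(0, 9), q4(0, 11),
                q4(0, 10), q4(0, 10))),
    # low quality -> rejected
    list(contig = "c1", pos = 4, ref = "A", alt = "G", qual = 79.9,
         dp = c(q4(10, 0), q4(12, 0), q4(0, 9), q4(0, 11),
                q4(5, 5), q4(6, 4))),
    # within-accession polymorphism (a2 carries both) -> rejected
    list(contig = "c1", pos = 5, ref = "A", alt = "G", qual = 120,
         dp = c(q4(10, 0), q4(6, 6), q4(0, 9), q4(0, 11),
                q4(5, 5), q4(6, 4))),
    # reversed orientation: A accession carries the alt allele
    list(contig = "c2", pos = 7, ref = "T", alt = "C", qual = 95,
         dp = c(q4(0, 10), q4(0, 12), q4(9, 0), q4(11, 0),
                q4(5, 5), q4(6, 4))))
  pt <- mk_pileup(rows, ids6)
  snps <- call_fixed_snps(pt, ss6)
  expect_identical(paste(snps$contig, snps$pos), c("c1 1", "c2 7"))
  expect_identical(snps$A_is_ref, c(TRUE, FALSE))
  expect_identical(snps$allele_A, c("A", "C"))
  expect_identical(snps$allele_P, c("G", "T"))
  # minor-allele tolerance admits the polymorphic site when relaxed
  snps_tol <- call_fixed_snps(pt, ss6, minor_allele_tol = 0.5)
  expect_true("c1 5" %in% paste(snps_tol$contig, snps_tol$pos))
})

test_that("extract_allele_counts sums dp4 per allele and screens strands", {
  rows <- list(
    # ref = A allele; f1 dp4 (3,4,2,1): A-allele 7, P-allele 3
    list(contig = "c1", pos = 1, ref = "A", alt = "G", qual = 120,
         dp = c(q4(10, 0), q4(12, 0), q4(0, 9), q4(0, 11),
                c(3, 4, 2, 1), c(2, 2, 3, 3))),
    # alt reads all-forward across every F1 -> strand_ok FALSE
    list(contig = "c1", pos = 2, ref = "A", alt = "G", qual = 120,
         dp = c(q4(10, 0), q4(12, 0), q4(0, 9), q4(0, 11),
                c(3, 4, 5, 0), c(2, 2, 4, 0))))
  pt <- mk_pileup(rows, ids6)
  snps <- call_fixed_snps(pt, ss6)
  ac <- extract_allele_counts(snps, pt, c("f1", "f2"))
  expect_equal(unname(ac$count_A[1, ]), c(7, 4))
  expect_equal(unname(ac$count_P[1, ]), c(3, 6))
  expect_identical(unname(ac$strand_ok), c(TRUE, FALSE))
  # random pileups: counts equal an independent summation oracle
  set.seed(50)
  rr <- lapply(1:20, function(i)
    list(contig = "cx", pos = i, ref = "A", alt = "G", qual = 120,
         dp = c(q4(10, 0), q4(10, 0), q4(0, 10), q4(0, 10),
                rpois(4, 4) + 1, rpois(4, 4) + 1)))
  ptr <- mk_pileup(rr, ids6)
  snr <- call_fixed_snps(ptr, ss6)
  acr <- extract_allele_counts(snr, ptr, c("f1", "f2"))
  df <- as.data.frame(ptr)
  m <- match(paste(acr$snps$contig, acr$snps$pos), paste(df$contig, df$pos))
  expect_equal(unname(acr$count_A[, "f1"]), df$f1_rf[m] + df$f1_rr[m])
  expect_equal(unname(acr$count_P[, "f2"]), df$f2_af[m] + df$f2_ar[m])
})

test_that("allelic-bias testing, aggregation and overlap behave", {
  # balanced alleles -> p = 1
  ac <- list(snps = data.frame(contig = "c1", pos = 1, A_is_ref = TRUE),
             count_A = matrix(c(5L, 7L), 1, 2,
                              dimnames = list("c1:1", c("f1", "f2"))),
             count_P = matrix(c(5L, 7L), 1, 2,
                              dimnames = list("c1:1", c("f1", "f2"))),
             strand_ok = TRUE, f1_samples = c("f1", "f2"))
  class(ac) <- "allele_counts"
  sf <- setNames(c(1, 1), c("f1", "f2"))
  br <- test_allelic_bias(ac, sf)
  expect_equal(br$pvalue, 1)
  expect_equal(br$log2_bias, 0)

  # aggregation arithmetic and the inconsistency rule
  snp_res <- data.frame(
    contig = c("g1", "g1", "g2", "g2", "g3"),
    pos = 1:5, k_A = 10, k_P = 10,
    log2_bias = c(1, 0.5, 1, -1, 0.3),
    pvalue = 1e-5, qvalue = c(1e-4, 1e-4, 1e-4, 1e-4, 0.5),
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    tested = TRUE, stringsAsFactors = FALSE)
  agg <- aggregate_to_contig(snp_res)
  g1 <- agg[agg$contig_id == "g1", ]
  expect_equal(g1$mean_log2_bias, 0.75)
  expect_identical(g1$direction, "A_allele")
  expect_identical(agg$direction[agg$contig_id == "g2"], "inconsistent")
  expect_identical(agg$direction[agg$contig_id == "g3"], "none")
  expect_identical(agg$n_snps_significant[agg$contig_id == "g3"], 0L)

  # overlap with disjoint significant sets -> zero doubly significant
  par <- data.frame(contig_id = c("g1", "g2", "g3"),
                    log2fc = c(1, -1, 1), significant = c(FALSE, FALSE, TRUE),
                    tested = TRUE, stringsAsFactors = FALSE)
  ov <- overlap_with_parental(agg, par)
  expect_identical(ov$n_both, 0L)
  expect_identical(ov$n_bias_significant, 2L)
  # bias == parental difference exactly -> slope 1, R^2 1
  par2 <- data.frame(contig_id = sprintf("g%d", 1:30),
                     log2fc = -seq(-1.5, 1.4, 0.1), significant = TRUE,
                     tested = TRUE, stringsAsFactors = FALSE)
  bias2 <- data.frame(contig_id = sprintf("g%d", 1:30),
                      n_snps_tested = 2, n_snps_significant = 2,
                      mean_log2_bias = seq(-1.5, 1.4, 0.1),
                      mean_log2_bias_all = seq(-1.5, 1.4, 0.1),
                      direction = "A_allele", stringsAsFactors = FALSE)
  fit <- suppressWarnings(fit_bias_vs_parental(bias2, par2))  # exact fit
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_bias_vs_parental(bias2[1:5, ], par2), "fewer than 10")
})

test_that("bias testing is invariant to allele relabelling up to sign", {
  set.seed(51)
  f1 <- sprintf("f%d", 1:8)
  cA <- matrix(rpois(40 * 8, 12), 40, 8, dimnames = list(NULL, f1))
  cP <- matrix(rpois(40 * 8, 6), 40, 8, dimnames = list(NULL, f1))
  snps <- data.frame(contig = sprintf("c%02d", 1:40), pos = 1, A_is_ref = TRUE)
  mk <- function(a, p) {
    x <- list(snps = snps, count_A = a, count_P = p,
              strand_ok = rep(TRUE, 40), f1_samples = f1)
    class(x) <- "allele_counts"
    x
  }
  sf <- setNames(runif(8, 0.8, 1.2), f1)
  b1 <- test_allelic_bias(mk(cA, cP), sf)
  b2 <- test_allelic_bias(mk(cP, cA), sf)
  expect_equal(b1$pvalue, b2$pvalue, tolerance = 1e-10)
  expect_equal(b1$log2_bias, -b2$log2_bias, tolerance = 1e-12)
})

test_that("generator-labelled pileups: calling equals the brute-force filter", {
  cfg <- sim_config(n_contigs = 400, snps_per_contig_mean = 2,
                    snp_violation_rate = 0.08, strand_artifact_rate = 0.05,
                    seed = 52)
  tt <- generate_truth(cfg)
  cm <- simulate_counts(tt, cfg)
  pt <- simulate_pileups(tt, cm, cfg)
  st <- attr(pt, "site_truth")
  snps <- call_fixed_snps(pt, cfg$samples)
  expect_identical(sort(paste(snps$contig, snps$pos)),
                   sort(paste(st$contig, st$pos)[st$passes_filters]))
})
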