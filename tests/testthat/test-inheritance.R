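test_that("midparent means match direct arithmetic", {
  ss <- default_samples()
  cm <- random_counts(50, 12, seed = 40)
  colnames(cm) <- ss$sample_id
  sf <- setNames(runif(12, 0.8, 1.2), ss$sample_id)
  mm <- midparent_means(cm, sf, ss)
  # independent arithmetic oracle, loops only
  norm <- sweep(unclass(cm), 2, sf, "/")
  for (i in c(1, 17, 50)) {
    mA <- mean(norm[i, sam(ss, "A")]); mP <- mean(norm[i, sam(ss, "P")])
    expect_equal(mm$mean_parent[i], (mA + mP) / 2, tolerance = 1e-12)
    expect_equal(mm$mean_F1[i], mean(norm[i, sam(ss, "F1")]),
                 tolerance = 1e-12)
  }
  # A means 10, P means 30 -> midparent 20
  cm2 <- unclass(cm)
  cm2[1, ] <- c(10L, 10L, 30L, 30L, rep(15L, 8))
  mm2 <- midparent_means(count_matrix(cm2), setNames(rep(1, 12),
                                                     ss$sample_id), ss)
  expect_equal(mm2$mean_parent[1], 20)
  # all-zero contig -> (0, 0)
  cm2[2, ] <- 0L
  mm3 <- midparent_means(count_matrix(cm2), setNames(rep(1, 12),
                                                     ss$sample_id), ss)
  expect_equal(unlist(mm3[2, c("mean_parent", "mean_F1")]),
               c(mean_parent = 0, mean_F1 = 0))
})

test_that("midparent fit: exact line, influence pruning, CI coverage", {
  n <- 200
  mp <- seq(1, 400, length.out = n)
  pairs <- data.frame(contig_id = sprintf("c%03d", 1:n), mean_A = mp,
                      mean_P = mp, mean_parent = mp, mean_F1 = mp)
  fit <- fit_midparent_model(pairs)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_length(fit$removed_contigs, 0)
  cl <- classify_nonadditive(fit, pairs)
  expect_true(all(cl$non_additive == "intermediate"))
  expect_equal(cl$percent_of_predicted, rep(100, n), tolerance = 1e-9)

  # planted leverage outlier: removed, refit much closer to truth
  set.seed(41)
  pairs2 <- pairs
  pairs2$mean_F1 <- 2 * mp + rnorm(n, 0, 2)
  pairs2$mean_parent[n] <- 5000; pairs2$mean_F1[n] <- 500
  fit2 <- fit_midparent_model(pairs2)
  expect_true("c200" %in% fit2$removed_contigs)
  err_refit <- abs(fit2$slope - 2)
  err_keep <- abs(fit2$initial$slope - 2)
  expect_lt(err_refit, err_keep / 5)
  # direct Cook's D oracle for the planted point
  f0 <- lm(mean_F1 ~ mean_parent, pairs2)
  expect_gt(unname(cooks.distance(f0)[n]), 1)
  # single-pass rule: refit excludes exactly the flagged contigs
  expect_identical(sort(fit2$removed_contigs),
                   sort(pairs2$contig_id[cooks.distance(f0) > 1]))

  # slope inside its own 99% CI in >= 95% of additive replicates
  cover <- 0
  for (r in 1:150) {
    set.seed(100 + r)
    p3 <- data.frame(contig_id = sprintf("c%03d", 1:n), mean_A = mp,
                     mean_P = mp, mean_parent = mp,
                     mean_F1 = mp + rnorm(n, 0, 15))
    f3 <- fit_midparent_model(p3)
    ci <- f3$slope + c(-1, 1) * qt(0.995, n - 2 -
                                     length(f3$removed_contigs)) * f3$slope_se
    cover <- cover + (ci[1] <= 1 && 1 <= ci[2])
  }
  expect_gte(cover / 150, 0.95)

  expect_error(fit_midparent_model(pairs[1:5, ]), ">= 10")
  pairs$mean_parent <- 7
  expect_error(fit_midparent_model(pairs), "zero variance")
})

test_that("prediction bands flag planted deviations and only those", {
  set.seed(42)
  n <- 2000
  mp <- 10^runif(n, 0.5, 3)
  f1 <- mp + rnorm(n, 0, 20)
  f1[1:10] <- 5 * mp[1:10] + 2000          # well above the band
  pairs <- data.frame(contig_id = sprintf("c%04d", 1:n), mean_A = mp,
                      mean_P = mp, mean_parent = mp, mean_F1 = f1)
  fit <- fit_midparent_model(pairs)
  cl <- classify_nonadditive(fit, pairs, level = 0.99)
  expect_true(all(cl$non_additive[1:10] == "above"))
  expect_lt(mean(cl$non_additive[-(1:10)] != "intermediate"), 0.05)
})

test_that("transgressive calls follow significance + direction", {
  # printed worked example: means A=1, F1=47, P=1, significant vs both -> HIGH
  mk <- function(meanX, meanF, sig) {
    data.frame(contig_id = c("BigSet010982", "mid1"),
               mean_norm_X = meanX, mean_norm_Y = meanF,
               log2fc = log2(meanF / meanX), significant = sig,
               tested = TRUE, stringsAsFactors = FALSE)
  }
  resA <- mk(c(1, 10), c(47, 20), c(TRUE, TRUE))
  resP <- mk(c(1, 30), c(47, 20), c(TRUE, TRUE))
  tg <- classify_transgressive(resA, resP)
  expect_identical(tg$transgressive, c("HIGH", "none"))  # mid1 is between
  # not significant vs one parent -> none even if outside the range
  resA2 <- mk(c(1, 10), c(47, 20), c(FALSE, TRUE))
  expect_identical(classify_transgressive(resA2, resP)$transgressive[1],
                   "none")
  # direction-only mode fires on the range rule alone
  expect_identical(
    classify_transgressive(resA2, resP, significance = FALSE)$transgressive,
    c("HIGH", "none"))
  # containment: transgressive subset of doubly-significant contigs
  set.seed(43)
  sigA <- runif(30) < 0.5; sigP <- runif(30) < 0.5
  rA <- data.frame(contig_id = sprintf("c%02d", 1:30),
                   mean_norm_X = runif(30, 1, 10),
                   mean_norm_Y = runif(30, 1, 60),
                   log2fc = 1, significant = sigA, tested = TRUE)
  rP <- data.frame(contig_id = sprintf("c%02d", 1:30),
                   mean_norm_X = runif(30, 1, 10),
                   mean_norm_Y = rA$mean_norm_Y,
                   log2fc = 1, significant = sigP, tested = TRUE)
  tg2 <- classify_transgressive(rA, rP)
  expect_true(all(tg2$transgressive == "none" | (sigA & sigP)))
})

test_that("CV screen: zero variance, closed form, monotonicity", {
  ss <- default_samples()
  f1 <- sam(ss, "F1")
  cm <- random_counts(20, 12, seed = 44)
  colnames(cm) <- ss$sample_id
  cm_u <- unclass(cm); cm_u[1, ss$group == "F1"] <- 77L
  cv <- cv_f1(count_matrix(cm_u), setNames(rep(1, 12), ss$sample_id), f1)
  expect_equal(cv$sigma_ln[1], 0)
  expect_equal(cv$cv[1], 0)
  expect_false(cv$high_cv[1])

  # closed form: many pseudo-F1 columns so sigma_ln is tight; deep counts
  nrep <- 50
  set.seed(45)
  mu <- 1e5
  lmult <- matrix(rnorm(400 * nrep, 0, 1.5), 400, nrep)
  cmat <- matrix(rpois(400 * nrep, mu * exp(lmult)), 400, nrep,
                 dimnames = list(sprintf("c%03d", 1:400),
                                 sprintf("h%02d", 1:nrep)))
  cvr <- cv_f1(count_matrix(cmat), setNames(rep(1, nrep), colnames(cmat)),
               colnames(cmat))
  target <- sqrt(exp(1.5^2) - 1)
  expect_lt(abs(median(cvr$cv) / target - 1), 0.10)
  # literal variant and monotonicity in sigma under both formulas
  sig_grid <- seq(0.1, 2, 0.1)
  std <- sqrt(exp(sig_grid^2) - 1)
  lit <- sqrt(exp(2 * sig_grid) - 1)
  expect_true(all(diff(std) > 0) && all(diff(lit) > 0))
  cvl <- cv_f1(count_matrix(cmat), setNames(rep(1, nrep), colnames(cmat)),
               colnames(cmat), formula = "literal")
  expect_equal(cvl$cv, sqrt(exp(2 * cvl$sigma_ln) - 1), tolerance = 1e-12)
})

test_that("sample outlier screen flags a permuted sample only", {
  ss <- default_samples()
  set.seed(46)
  base <- rpois(800, 200) * (1 + rexp(800))        # strong common signal
  cm <- vapply(1:12, function(j) rpois(800, base), numeric(800))
  dimnames(cm) <- list(sprintf("c%04d", 1:800), ss$sample_id)
  cm <- count_matrix(matrix(as.integer(cm), 800, 12,
                            dimnames = dimnames(cm)))
  sc0 <- sample_outlier_screen(cm, ss)
  expect_false(any(sc0$flagged))
  rho <- attr(sc0, "rho")
  expect_equal(rho, t(rho))
  expect_equal(unname(diag(rho)), rep(1, 12))
  # permute one F1 column
  cm_u <- unclass(cm)
  cm_u[, "F1.07"] <- sample(cm_u[, "F1.07"])
  sc1 <- sample_outlier_screen(count_matrix(cm_u), ss)
  expect_true(sc1$flagged[sc1$sample_id == "F1.07"])
  expect_identical(sum(sc1$flagged), 1L)   # median keeps peers unflagged
})
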