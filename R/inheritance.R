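# Inheritance-mode classification: additivity (midparent) modelling with
# influence pruning and prediction bands, significance-based transgressive
# calls, the inter-F1 coefficient-of-variation screen, and a correlation
# based sample-outlier advisory.

#' Per-contig midparent and F1 means
#'
#' On normalized counts, the midparent value is the average of the two
#' parental accession means — the F1 expectation under purely additive
#' inheritance — and is paired with the observed mean across F1 samples.
#'
#' @param counts a [count_matrix()].
#' @param sf size factors.
#' @param ss a [sample_sheet()].
#' @param reduced use the reduced sample set.
#' @return data.frame with `contig_id`, `mean_A`, `mean_P`, `mean_parent`,
#'   `mean_F1`.
#' @export
midparent_means <- function(counts, sf, ss, reduced = FALSE) {
  cm <- unclass(counts)
  gm <- function(g) {
    s <- group_samples(ss, g, reduced)
    rowMeans(sweep(cm[, s, drop = FALSE], 2, sf[s], "/"))
  }
  mA <- gm("A"); mP <- gm("P"); mF <- gm("F1")
  data.frame(contig_id = rownames(cm), mean_A = mA, mean_P = mP,
             mean_parent = (mA + mP) / 2, mean_F1 = mF,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the midparent additivity model
#'
#' Ordinary least squares of the F1 mean on the midparent value, on the raw
#' normalized-count scale. Contigs with Cook's distance above
#' `cooks_cutoff` in the initial fit are removed and the model refitted
#' once (single pass); both fits' parameters are reported.
#'
#' @param pairs output of [midparent_means()].
#' @param cooks_cutoff influence threshold (default 1).
#' @return list of class `"additivity_fit"`: `slope`, `intercept`,
#'   `residual_sd`, `r_squared`, `removed_contigs`, `initial` (the same
#'   summaries for the pre-pruning fit) and the refit `lm` object.
#' @export
fit_midparent_model <- function(pairs, cooks_cutoff = 1) {
  if (nrow(pairs) < 10)
    stop("fit_midparent_model: need >= 10 contigs")
  if (stats::var(pairs$mean_parent) == 0)
    stop("fit_midparent_model: zero variance in midparent values")
  fit0 <- stats::lm(mean_F1 ~ mean_parent, data = pairs)
  cd <- stats::cooks.distance(fit0)
  cd[!is.finite(cd)] <- 0
  # an (essentially) exact fit has no meaningful influence measure
  if (suppressWarnings(summary(fit0)$sigma) <=
      1e-8 * (1 + mean(abs(pairs$mean_F1))))
    cd[] <- 0
  removed <- pairs$contig_id[!is.na(cd) & cd > cooks_cutoff]
  keep <- !(pairs$contig_id %in% removed)
  fit1 <- stats::lm(mean_F1 ~ mean_parent, data = pairs[keep, , drop = FALSE])
  summ <- function(f) {
    s <- suppressWarnings(summary(f))   # quiet on an exactly additive fit
    list(slope = unname(stats::coef(f)[2]),
         intercept = unname(stats::coef(f)[1]),
         slope_se = s$coefficients[2, 2],
         intercept_se = s$coefficients[1, 2],
         residual_sd = s$sigma, r_squared = s$r.squared)
  }
  out <- c(summ(fit1),
           list(removed_contigs = removed, cooks_cutoff = cooks_cutoff,
                initial = summ(fit0), fit = fit1))
  class(out) <- "additivity_fit"
  out
}

#' @export
print.additivity_fit <- function(x, ...) {
  cat(sprintf("midparent additivity fit: slope %.4f (+/-%.4g), intercept %.4g (+/-%.4g)\n",
              x$slope, x$slope_se, x$intercept, x$intercept_se))
  cat(sprintf("  R^2 = %.4f, residual sd = %.4g, %d influential contig(s) removed\n",
              x$r_squared, x$residual_sd, length(x$removed_contigs)))
  invisible(x)
}

#' Classify non-additive contigs by prediction band
#'
#' For each contig, the pruned model's prediction interval for a new
#' observation at the contig's midparent value is computed at `level`
#' (default 99%); contigs whose F1 mean falls outside are labelled
#' `"above"` or `"below"`, all others `"intermediate"`.
#'
#' @param fit an [fit_midparent_model()] result.
#' @param pairs output of [midparent_means()].
#' @param level prediction-interval coverage.
#' @return data.frame with `contig_id`, `predicted`, `lower`, `upper`,
#'   `non_additive` in `{above, below, intermediate}` and
#'   `percent_of_predicted` (100 * mean_F1 / predicted; `NA` when the
#'   prediction is non-positive).
#' @export
classify_nonadditive <- function(fit, pairs, level = 0.99) {
  pr <- stats::predict(fit$fit, newdata = pairs, interval = "prediction",
                       level = level)
  eps <- 1e-8 * (1 + abs(pr[, "fit"]))     # guard exact-boundary round-off
  lab <- ifelse(pairs$mean_F1 > pr[, "upr"] + eps, "above",
                ifelse(pairs$mean_F1 < pr[, "lwr"] - eps, "below",
                       "intermediate"))
  pct <- ifelse(pr[, "fit"] > 0, 100 * pairs$mean_F1 / pr[, "fit"], NA_real_)
  data.frame(contig_id = pairs$contig_id, predicted = pr[, "fit"],
             lower = pr[, "lwr"], upper = pr[, "upr"],
             non_additive = lab, percent_of_predicted = pct,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Transgressive classification from the two parent-vs-F1 comparisons
#'
#' A contig is `HIGH` when the F1 differs significantly from both parents
#' and its mean exceeds both parental means, `LOW` when significant against
#' both and below both; otherwise `none`. Pass `significance = FALSE` to
#' apply the direction rule alone (F1 mean outside the parental range).
#'
#' @param results_A_vs_F1 [pairwise_da()] result with X = parent A,
#'   Y = F1.
#' @param results_P_vs_F1 [pairwise_da()] result with X = parent P,
#'   Y = F1.
#' @param significance require q-significance against both parents.
#' @return data.frame with `contig_id`, `mean_A`, `mean_P`, `mean_F1`,
#'   `transgressive` in `{HIGH, LOW, none}`.
#' @export
classify_transgressive <- function(results_A_vs_F1, results_P_vs_F1,
                                   significance = TRUE) {
  stopifnot(identical(results_A_vs_F1$contig_id, results_P_vs_F1$contig_id))
  mean_A <- results_A_vs_F1$mean_norm_X
  mean_P <- results_P_vs_F1$mean_norm_X
  mean_F1 <- results_A_vs_F1$mean_norm_Y
  sigA <- !is.na(results_A_vs_F1$significant) & results_A_vs_F1$significant
  sigP <- !is.na(results_P_vs_F1$significant) & results_P_vs_F1$significant
  sig <- if (significance) sigA & sigP else TRUE
  lab <- ifelse(sig & mean_F1 > pmax(mean_A, mean_P), "HIGH",
                ifelse(sig & mean_F1 < pmin(mean_A, mean_P), "LOW", "none"))
  data.frame(contig_id = results_A_vs_F1$contig_id, mean_A = mean_A,
             mean_P = mean_P, mean_F1 = mean_F1, transgressive = lab,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Coefficient of variation across F1 individuals
#'
#' `sigma_ln` is the sample standard deviation of `ln(normalized count + 1)`
#' across F1 samples (the pseudocount keeps zero counts defined). Under the
#' default `lognormal_standard` formula the CV uses the lognormal identity
#' `sqrt(exp(sigma^2) - 1)`; `literal` applies `sqrt(exp(2*sigma) - 1)`
#' instead. Contigs with CV above `threshold` (default 2) are flagged
#' high-variance.
#'
#' @param counts a [count_matrix()].
#' @param sf size factors.
#' @param f1_samples character vector of F1 sample ids (>= 2).
#' @param threshold CV flag threshold.
#' @param formula `"lognormal_standard"` or `"literal"`.
#' @return data.frame with `contig_id`, `sigma_ln`, `cv`, `high_cv`.
#' @export
cv_f1 <- function(counts, sf, f1_samples, threshold = 2,
                  formula = c("lognormal_standard", "literal")) {
  formula <- match.arg(formula)
  stopifnot(length(f1_samples) >= 2)
  cm <- unclass(counts)
  ln <- log(sweep(cm[, f1_samples, drop = FALSE], 2, sf[f1_samples], "/") + 1)
  mu <- rowMeans(ln)
  sigma <- sqrt(rowSums((ln - mu)^2) / (length(f1_samples) - 1L))
  cv <- if (formula == "lognormal_standard") sqrt(exp(sigma^2) - 1)
        else sqrt(exp(2 * sigma) - 1)
  data.frame(contig_id = rownames(cm), sigma_ln = sigma, cv = cv,
             high_cv = cv > threshold, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Correlation-based sample outlier advisory
#'
#' Computes the Spearman correlation matrix of per-contig counts over the
#' whole reference and flags any sample whose median correlation with the
#' other members of its own group falls below `min_within_group_rho`. The
#' median (rather than the mean) keeps one grossly aberrant sample from
#' dragging its innocent group-mates below the threshold. Advisory only:
#' reduced-set membership remains a sample-sheet decision.
#'
#' @param counts a [count_matrix()].
#' @param ss a [sample_sheet()].
#' @param min_within_group_rho flag threshold (default 0.95).
#' @param sf optional size factors (Spearman is invariant to per-sample
#'   scaling, so this only affects tie patterns).
#' @return data.frame with `sample_id`, `group`, `within_group_rho`
#'   (median within-group correlation), `flagged`; the full correlation
#'   matrix is in `attr(, "rho")`.
#' @export
sample_outlier_screen <- function(counts, ss, min_within_group_rho = 0.95,
                                  sf = NULL) {
  cm <- unclass(counts)[, ss$sample_id, drop = FALSE]
  stopifnot(ncol(cm) >= 3)
  if (!is.null(sf)) cm <- sweep(cm, 2, sf[colnames(cm)], "/")
  rho <- stats::cor(cm, method = "spearman")
  mwr <- vapply(seq_len(ncol(cm)), function(j) {
    peers <- which(ss$group == ss$group[j])
    peers <- setdiff(peers, j)
    if (!length(peers)) return(NA_real_)
    stats::median(rho[j, peers])
  }, numeric(1))
  out <- data.frame(sample_id = ss$sample_id, group = ss$group,
                    within_group_rho = mwr,
                    flagged = !is.na(mwr) & mwr < min_within_group_rho,
                    stringsAsFactors = FALSE)
  attr(out, "rho") <- rho
  out
}
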