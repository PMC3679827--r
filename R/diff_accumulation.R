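# Negative-binomial differential accumulation between sample groups.
#
# Median-of-ratios size factors, method-of-moments dispersion estimation
# with a 1/m + const trend and conservative (elementwise max) sharing, and
# an exact conditional test on group count sums under the NB model — the
# count-based testing core that the classification stages build on.

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over contigs (restricted
#' to contigs with nonzero counts in every sample) of the ratio of the
#' sample's count to the contig's geometric mean across samples. Doubling a
#' sample's library doubles its size factor; the estimate is robust to a
#' minority of differentially accumulated contigs.
#'
#' @param counts a [count_matrix()] (or integer matrix).
#' @return named numeric vector of positive per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  counts <- unclass(counts)
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use))
    stop("estimate_size_factors: no contig has nonzero counts in all samples")
  sf <- apply(counts[use, , drop = FALSE], 2,
              function(cj) stats::median(exp(log(cj) - loggeo[use])))
  if (any(!is.finite(sf) | sf <= 0))
    stop("estimate_size_factors: non-positive size factor")
  sf
}

#' Per-contig NB dispersion with trend sharing
#'
#' Method-of-moments gene-wise estimates on normalized counts, pooled across
#' within-group replicates: `alpha_hat = max(0, (v - m) / m^2)` with `v` the
#' pooled within-group variance and `m` the mean over the samples of groups
#' with replication. A mean-dispersion trend `a1/m + a0` is fitted by least
#' squares, and the final per-contig dispersion is the elementwise maximum
#' of the gene-wise estimate, the trend value and `alpha_floor` — the
#' conservative sharing appropriate for two-replicate parental groups.
#'
#' @param counts a [count_matrix()].
#' @param sf size factors from [estimate_size_factors()].
#' @param groups character vector assigning each column to a group.
#' @param alpha_floor lower bound on the returned dispersion.
#' @return named numeric vector of final dispersions, with the gene-wise
#'   estimates, trend coefficients and base means in attributes.
#' @export
estimate_dispersions <- function(counts, sf, groups, alpha_floor = 1e-8) {
  counts <- unclass(counts)
  stopifnot(length(sf) == ncol(counts), length(groups) == ncol(counts))
  tab <- table(groups)
  rep_groups <- names(tab)[tab >= 2]
  if (!length(rep_groups))
    stop("estimate_dispersions: no group has replicates")
  norm <- sweep(counts, 2, sf, "/")
  cols <- which(groups %in% rep_groups)
  m <- rowMeans(norm[, cols, drop = FALSE])
  ssq <- 0; df <- 0
  for (g in rep_groups) {
    gc <- which(groups == g)
    mg <- rowMeans(norm[, gc, drop = FALSE])
    ssq <- ssq + rowSums((norm[, gc, drop = FALSE] - mg)^2)
    df <- df + length(gc) - 1L
  }
  v <- ssq / df
  alpha_gene <- ifelse(m > 0, pmax(0, (v - m) / m^2), 0)
  ok <- m > 0
  if (sum(ok) >= 2) {
    x <- 1 / m[ok]
    fit <- stats::lm.fit(cbind(a0 = 1, a1 = x), alpha_gene[ok])
    a <- fit$coefficients
    if (anyNA(a))                       # collinear (constant means): flat trend
      a <- c(a0 = mean(alpha_gene[ok]), a1 = 0)
  } else {
    a <- c(a0 = if (any(ok)) mean(alpha_gene[ok]) else 0, a1 = 0)
  }
  alpha_trend <- rep(0, length(m))
  alpha_trend[ok] <- pmax(0, a[["a0"]] + a[["a1"]] / m[ok])
  alpha <- pmax(alpha_gene, alpha_trend, alpha_floor)
  names(alpha) <- rownames(counts)
  attr(alpha, "alpha_gene") <- alpha_gene
  attr(alpha, "trend") <- a
  attr(alpha, "base_mean") <- m
  alpha
}

# NB pmf on the group-sum scale. mu = s * qhat; the full variance of the sum
# is mu + alpha * qhat^2 * ssq (ssq = sum of squared per-sample size factors,
# the replicate-sum variance of the NB model). The default ssq = s^2 gives
# the single-unit form variance = mu + alpha * mu^2.
.nb_sum_logpmf <- function(x, qhat, s, alpha, ssq) {
  mu <- s * qhat
  extra <- alpha * qhat^2 * ssq
  if (extra <= mu * 1e-12)
    return(stats::dpois(x, lambda = mu, log = TRUE))
  stats::dnbinom(x, mu = mu, size = mu^2 / extra, log = TRUE)
}

.nb_sum_quantile <- function(pq, qhat, s, alpha, ssq) {
  mu <- s * qhat
  extra <- alpha * qhat^2 * ssq
  if (extra <= mu * 1e-12) return(stats::qpois(pq, lambda = mu))
  stats::qnbinom(pq, mu = mu, size = mu^2 / extra)
}

#' Exact conditional NB test for two group sums
#'
#' Conditions on the total `K = k_A + k_B`. Under the null of a common
#' per-size-unit mean `qhat = K / (sA + sB)`, the probability of every split
#' `(a, K - a)` is the product of two NB pmfs with means `sA*qhat` and
#' `sB*qhat`; the two-sided p-value sums the probabilities of all splits no
#' more likely than the observed one, normalized by the total. For totals
#' above `max_enum` the enumeration is truncated to the central region
#' carrying at least 1 - 1e-12 of the null mass.
#'
#' By default the NB variance is `mean + alpha * mean^2` on the sum scale.
#' When the group sum aggregates replicate libraries, pass `ssqA`/`ssqB`
#' (sums of squared size factors) so the overdispersion term is
#' `alpha * qhat^2 * ssq`, the variance of a sum of independent NB
#' replicates sharing dispersion `alpha`.
#'
#' @param k_A,k_B observed count sums in groups A and B.
#' @param sA,sB summed size factors of the two groups.
#' @param alpha NB dispersion.
#' @param ssqA,ssqB sums of squared size factors (default `sA^2`, `sB^2`).
#' @param max_enum largest total enumerated exhaustively.
#' @return two-sided p-value in \[0, 1\]; `K = 0` returns 1 by convention.
#' @export
nb_exact_test <- function(k_A, k_B, sA, sB, alpha,
                          ssqA = sA^2, ssqB = sB^2, max_enum = 10000L) {
  stopifnot(k_A >= 0, k_B >= 0, sA > 0, sB > 0, alpha >= 0)
  K <- k_A + k_B
  if (K == 0) return(1)
  qhat <- K / (sA + sB)
  if (K <= max_enum) {
    a <- 0:K
  } else {
    lo <- min(.nb_sum_quantile(1e-13, qhat, sA, alpha, ssqA),
              K - .nb_sum_quantile(1 - 1e-13, qhat, sB, alpha, ssqB), k_A)
    hi <- max(.nb_sum_quantile(1 - 1e-13, qhat, sA, alpha, ssqA),
              K - .nb_sum_quantile(1e-13, qhat, sB, alpha, ssqB), k_A)
    a <- max(0, lo):min(K, hi)
  }
  logp <- .nb_sum_logpmf(a, qhat, sA, alpha, ssqA) +
    .nb_sum_logpmf(K - a, qhat, sB, alpha, ssqB)
  mx <- max(logp)
  pr <- exp(logp - mx)
  obs <- exp(.nb_sum_logpmf(k_A, qhat, sA, alpha, ssqA) +
               .nb_sum_logpmf(k_B, qhat, sB, alpha, ssqB) - mx)
  p <- sum(pr[pr <= obs * (1 + 1e-7)]) / sum(pr)
  min(max(p, 0), 1)
}

#' Pairwise differential accumulation between two sample groups
#'
#' Applies [nb_exact_test()] to per-contig count sums of the two groups,
#' using the replicate-sum variance (sums of squared size factors), then
#' adjusts p-values by Benjamini-Hochberg across all tested contigs.
#' Contigs with zero counts in every sample of both groups are untested
#' (`NA` p/q) and excluded from the BH family.
#'
#' @param counts a [count_matrix()].
#' @param sf named size factors covering both groups.
#' @param dispersions named per-contig dispersions
#'   (from [estimate_dispersions()]); a single value is recycled.
#' @param samples_X,samples_Y character vectors of sample ids.
#' @param q_threshold significance threshold on the BH-adjusted q-value.
#' @return data.frame of class `"pairwise_result"` with per-contig group
#'   means (normalized), `log2fc` (Y over X; infinite when one mean is zero,
#'   with `log2fc_finite` flagging usable values), `pvalue`, `qvalue`,
#'   `significant` and `tested`.
#' @export
pairwise_da <- function(counts, sf, dispersions, samples_X, samples_Y,
                        q_threshold = 0.01) {
  cm <- unclass(counts)
  stopifnot(all(c(samples_X, samples_Y) %in% colnames(cm)),
            length(samples_X) >= 1, length(samples_Y) >= 1)
  if (length(dispersions) == 1L)
    dispersions <- stats::setNames(rep(dispersions, nrow(cm)), rownames(cm))
  dispersions <- dispersions[rownames(cm)]
  kX <- rowSums(cm[, samples_X, drop = FALSE])
  kY <- rowSums(cm[, samples_Y, drop = FALSE])
  sX <- sum(sf[samples_X]); sY <- sum(sf[samples_Y])
  ssqX <- sum(sf[samples_X]^2); ssqY <- sum(sf[samples_Y]^2)
  tested <- (kX + kY) > 0
  p <- rep(NA_real_, nrow(cm))
  ti <- which(tested)
  p[ti] <- vapply(ti, function(i)
    nb_exact_test(kX[i], kY[i], sX, sY, dispersions[i], ssqX, ssqY),
    numeric(1))
  q <- rep(NA_real_, nrow(cm))
  q[ti] <- stats::p.adjust(p[ti], method = "BH")
  normX <- rowMeans(sweep(cm[, samples_X, drop = FALSE], 2,
                          sf[samples_X], "/"))
  normY <- rowMeans(sweep(cm[, samples_Y, drop = FALSE], 2,
                          sf[samples_Y], "/"))
  lfc <- log2(normY / normX)            # Y over X; +-Inf when a mean is 0
  lfc[!tested] <- NA_real_
  res <- data.frame(contig_id = rownames(cm),
                    mean_norm_X = normX, mean_norm_Y = normY,
                    log2fc = lfc, log2fc_finite = is.finite(lfc),
                    pvalue = p, qvalue = q,
                    significant = ifelse(tested, q < q_threshold, NA),
                    tested = tested, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "q_threshold") <- q_threshold
  attr(res, "samples_X") <- samples_X
  attr(res, "samples_Y") <- samples_Y
  class(res) <- c("pairwise_result", "data.frame")
  res
}

#' Intersect full and reduced pairwise analyses
#'
#' Per-contig provenance of a significant call: `BOTH` when significant with
#' the same direction in the full and reduced analyses, `FULL`/`REDUCED`
#' when significant in one only, `NONE` otherwise. Contigs significant in
#' both but with disagreeing directions are demoted to `NONE` and counted
#' in `attr(, "direction_conflicts")`.
#'
#' @param results_full,results_reduced [pairwise_da()] results on the same
#'   contig universe.
#' @return data.frame with `contig_id`, `provenance`, `direction`
#'   (sign of the agreed log2 fold change: `"up"`, `"down"` or `NA`).
#' @export
intersect_full_reduced <- function(results_full, results_reduced) {
  if (!identical(results_full$contig_id, results_reduced$contig_id))
    stop("intersect_full_reduced: contig universes differ")
  sf_ <- !is.na(results_full$significant) & results_full$significant
  sr_ <- !is.na(results_reduced$significant) & results_reduced$significant
  dirf <- ifelse(results_full$log2fc > 0, "up", "down")
  dirr <- ifelse(results_reduced$log2fc > 0, "up", "down")
  prov <- rep("NONE", nrow(results_full))
  agree <- sf_ & sr_ & dirf == dirr
  conflict <- sf_ & sr_ & dirf != dirr
  prov[agree] <- "BOTH"
  prov[sf_ & !sr_] <- "FULL"
  prov[!sf_ & sr_] <- "REDUCED"
  direction <- rep(NA_character_, nrow(results_full))
  direction[agree] <- dirf[agree]
  direction[sf_ & !sr_] <- dirf[sf_ & !sr_]
  direction[!sf_ & sr_] <- dirr[!sf_ & sr_]
  if (any(conflict))
    message("intersect_full_reduced: ", sum(conflict),
            " contig(s) significant in both analyses with opposite ",
            "directions; demoted to NONE")
  out <- data.frame(contig_id = results_full$contig_id, provenance = prov,
                    direction = direction, stringsAsFactors = FALSE)
  attr(out, "direction_conflicts") <-
    results_full$contig_id[conflict]
  out
}
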