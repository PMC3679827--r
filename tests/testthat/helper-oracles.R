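# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: the NB pmf is written out via lgamma, enumeration is
# always full-range on the linear scale.

# log NB pmf with mean mu and size r, from first principles
.oracle_lognb <- function(x, mu, r) {
  lgamma(x + r) - lgamma(r) - lfactorial(x) +
    r * log(r / (r + mu)) + x * log(mu / (r + mu))
}

.oracle_pmf <- function(x, s, qhat, alpha, ssq) {
  mu <- s * qhat
  extra <- alpha * qhat^2 * ssq
  if (extra <= mu * 1e-12) return(exp(-mu + x * log(mu) - lfactorial(x)))
  exp(.oracle_lognb(x, mu, mu^2 / extra))
}

# brute-force exact conditional NB test: full enumeration, linear scale
brute_nb_exact <- function(kA, kB, sA, sB, alpha,
                           ssqA = sA^2, ssqB = sB^2) {
  K <- kA + kB
  if (K == 0) return(1)
  qhat <- K / (sA + sB)
  pa <- .oracle_pmf(0:K, sA, qhat, alpha, ssqA)
  pb <- .oracle_pmf(K:0, sB, qhat, alpha, ssqB)
  pr <- pa * pb
  pobs <- .oracle_pmf(kA, sA, qhat, alpha, ssqA) *
    .oracle_pmf(kB, sB, qhat, alpha, ssqB)
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]) / sum(pr))
}

# brute-force median-of-ratios size factors (loops, no apply tricks)
brute_size_factors <- function(counts) {
  counts <- unclass(counts)
  keep <- which(apply(counts, 1, function(r) all(r > 0)))
  out <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    ratios <- numeric(length(keep))
    for (i in seq_along(keep)) {
      g <- prod(counts[keep[i], ])^(1 / ncol(counts))
      ratios[i] <- counts[keep[i], j] / g
    }
    out[j] <- median(ratios)
  }
  names(out) <- colnames(counts)
  out
}

# random valid count matrix
random_counts <- function(n, m, seed, lambda = 50) {
  set.seed(seed)
  cm <- matrix(rpois(n * m, lambda), n,
               dimnames = list(sprintf("c%04d", seq_len(n)),
                               sprintf("s%02d", seq_len(m))))
  count_matrix(cm)
}

# study-design sample sheet shortcut
ss12 <- function() default_samples()

sam <- function(ss, g) ss$sample_id[ss$group == g]
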