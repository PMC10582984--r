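#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on observed genotype counts: conditioning on the
#' allele totals, the probability of every attainable heterozygote count
#' (same parity as the minor-allele count) is computed by the standard
#' recurrence, and the two-sided p-value is the sum of the probabilities of
#' all configurations no more probable than the observed one. A monomorphic
#' variant has a single attainable configuration and p = 1.
#'
#' All three arguments are vectorized; tables sharing allele totals reuse the
#' same conditional distribution, so exhaustive sweeps over genotype tables
#' are cheap.
#'
#' @param n_AA,n_AB,n_BB Non-negative genotype counts (equal-length vectors).
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' hweExactTest(50, 0, 0)        # 1
#' hweExactTest(25, 50, 25)
#' @export
hweExactTest <- function(n_AA, n_AB, n_BB) {
    k <- max(length(n_AA), length(n_AB), length(n_BB))
    n_AA <- rep_len(as.integer(n_AA), k)
    n_AB <- rep_len(as.integer(n_AB), k)
    n_BB <- rep_len(as.integer(n_BB), k)
    if (anyNA(n_AA) || anyNA(n_AB) || anyNA(n_BB) ||
        any(n_AA < 0 | n_AB < 0 | n_BB < 0))
        stop("genotype counts must be non-negative integers")
    n <- n_AA + n_AB + n_BB
    if (any(n == 0L))
        stop("all genotype counts are zero")
    nA <- 2L * n_AA + n_AB
    r <- pmin(nA, 2L * n - nA)          # rare-allele count
    p <- numeric(k)
    for (key in split(seq_len(k), paste(n, r))) {
        ni <- n[key[1]]; ri <- r[key[1]]
        dist <- .hweHetDist(ni, ri)
        ## p(h) = sum of probabilities <= prob(h), with a relative guard
        ## against ties decided by floating-point noise
        srt <- sort(dist$prob)
        cum <- cumsum(srt)
        idx <- findInterval(dist$prob[match(n_AB[key], dist$het)] *
                            (1 + 1e-9), srt)
        p[key] <- pmin(cum[idx], 1)
    }
    p
}

## conditional distribution of the heterozygote count given n genotypes and
## rare-allele count r (Wigginton-style recurrence in log space)
.hweHetDist <- function(n, r) {
    hets <- seq.int(r %% 2L, r, by = 2L)
    m <- length(hets)
    lp <- numeric(m)
    if (m > 1L) {
        for (i in seq_len(m - 1L)) {
            h <- hets[i]
            hom_r <- (r - h) / 2
            hom_c <- n - h - hom_r
            lp[i + 1L] <- lp[i] + log(4 * hom_r * hom_c) -
                log((h + 1) * (h + 2))
        }
    }
    pr <- exp(lp - max(lp))
    list(het = hets, prob = pr / sum(pr))
}
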