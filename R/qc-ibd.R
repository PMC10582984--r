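#' Pairwise identity-by-descent estimates (method of moments)
#'
#' Re-implements the PLINK-style moments estimator: per pair, identity-by-
#' state (IBS) sharing counts over overlapping non-missing autosomal markers
#' are combined with allele frequencies to solve for the IBD state
#' probabilities P(IBD=0/1/2), which are truncated to `[0, 1]` and
#' renormalized; `pi_hat = P(IBD=2) + P(IBD=1)/2`.
#'
#' With counted-allele frequency `p` (and `q = 1 - p`) the per-marker IBS
#' expectations are `P(IBS0|IBD0) = 2 p^2 q^2`,
#' `P(IBS1|IBD0) = 4 p^3 q + 4 p q^3`, `P(IBS1|IBD1) = 2 p^2 q + 2 p q^2`,
#' `P(IBS2|IBD0) = p^4 + q^4 + 4 p^2 q^2`,
#' `P(IBS2|IBD1) = p^3 + q^3 + p^2 q + p q^2` and `P(IBS2|IBD2) = 1`.
#'
#' @param g A [GenotypeMatrix-class].
#' @param samples Optional sample subset (default: all samples).
#' @param freqs Optional named allele-b frequencies; estimated from all
#'   samples of `g` when `NULL`.
#' @param min_overlap Minimum overlapping informative markers per pair
#'   (default 50); pairs below it raise an error.
#' @return `data.frame` with one row per unordered pair: `id1`, `id2`,
#'   `n_ibs0`, `n_ibs1`, `n_ibs2`, `z0`, `z1`, `z2`, `pi_hat`.
#' @export
ibdEstimateAll <- function(g, samples = NULL, freqs = NULL,
                           min_overlap = 50) {
    stopifnot(is(g, "GenotypeMatrix"))
    d <- dosages(g)[!rowData(g)$is_x, , drop = FALSE]
    if (is.null(freqs)) freqs <- rowMeans(d, na.rm = TRUE) / 2
    else freqs <- freqs[rownames(d)]
    if (!is.null(samples)) d <- d[, samples, drop = FALSE]
    if (ncol(d) < 2L) stop("need at least 2 samples")
    poly <- !is.na(freqs) & freqs > 0 & freqs < 1
    d <- d[poly, , drop = FALSE]
    p <- freqs[poly]; q <- 1 - p
    e00 <- 2 * p^2 * q^2
    e10 <- 4 * p^3 * q + 4 * p * q^3
    e11 <- 2 * p^2 * q + 2 * p * q^2
    e20 <- p^4 + q^4 + 4 * p^2 * q^2
    e21 <- p^3 + q^3 + p^2 * q + p * q^2

    nonmiss <- !is.na(d)
    a0 <- (!is.na(d) & d == 0L) + 0
    a1 <- (!is.na(d) & d == 1L) + 0
    a2 <- (!is.na(d) & d == 2L) + 0
    N  <- nonmiss + 0
    n_ibs0 <- crossprod(a0, a2); n_ibs0 <- n_ibs0 + t(n_ibs0)
    n_ibs2 <- crossprod(a0) + crossprod(a1) + crossprod(a2)
    overlap <- crossprod(N)
    n_ibs1 <- overlap - n_ibs0 - n_ibs2
    E00 <- crossprod(N, e00 * N)
    E10 <- crossprod(N, e10 * N)
    E11 <- crossprod(N, e11 * N)
    E20 <- crossprod(N, e20 * N)
    E21 <- crossprod(N, e21 * N)

    ids <- colnames(d)
    ut <- which(upper.tri(overlap), arr.ind = TRUE)
    m <- overlap[ut]
    if (any(m < min_overlap))
        stop("insufficient markers: ", sum(m < min_overlap),
             " pair(s) below the overlap floor of ", min_overlap)
    z0 <- n_ibs0[ut] / E00[ut]
    z1 <- (n_ibs1[ut] - z0 * E10[ut]) / E11[ut]
    z2 <- (n_ibs2[ut] - z0 * E20[ut] - z1 * E21[ut]) / m
    z0 <- pmin(pmax(z0, 0), 1)
    z1 <- pmin(pmax(z1, 0), 1)
    z2 <- pmin(pmax(z2, 0), 1)
    tot <- z0 + z1 + z2
    z0 <- z0 / tot; z1 <- z1 / tot; z2 <- z2 / tot
    data.frame(id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
               n_ibs0 = n_ibs0[ut], n_ibs1 = n_ibs1[ut],
               n_ibs2 = n_ibs2[ut],
               z0 = z0, z1 = z1, z2 = z2, pi_hat = z2 + z1 / 2,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname ibdEstimateAll
#' @param pair Character vector of two sample IDs.
#' @export
ibdEstimate <- function(g, pair, freqs = NULL, min_overlap = 50) {
    stopifnot(length(pair) == 2L)
    ibdEstimateAll(g, samples = pair, freqs = freqs,
                   min_overlap = min_overlap)
}

#' Greedy relatedness removal
#'
#' For every pair with `pi_hat` above the threshold (default 0.1875, halfway
#' between second- and third-degree expected sharing), the member with the
#' lower call rate is removed (ties: the later `sample_id`). Pairs are
#' processed in decreasing `pi_hat` order and already-removed samples settle
#' their remaining pairs, so the result is deterministic and no surviving
#' pair exceeds the threshold.
#'
#' @param estimates Output of [ibdEstimateAll()].
#' @param call_rates Named numeric vector of per-sample call rates (e.g.
#'   from [sampleCallRateFilter()]); missing names count as call rate 1.
#' @param threshold `pi_hat` cutoff (default 0.1875).
#' @return Character vector of removed sample IDs (possibly empty).
#' @export
relatednessFilter <- function(estimates, call_rates = NULL,
                              threshold = 0.1875) {
    off <- estimates[estimates$pi_hat > threshold, , drop = FALSE]
    if (!nrow(off)) return(character())
    off <- off[order(-off$pi_hat, off$id1, off$id2), , drop = FALSE]
    cr <- function(id) {
        if (!is.null(call_rates) && id %in% names(call_rates))
            call_rates[[id]] else 1
    }
    removed <- character()
    for (i in seq_len(nrow(off))) {
        a <- off$id1[i]; b <- off$id2[i]
        if (a %in% removed || b %in% removed) next
        drop <- if (cr(a) < cr(b)) a
                else if (cr(b) < cr(a)) b
                else max(a, b)        # tie: later sample_id
        removed <- c(removed, drop)
    }
    removed
}
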