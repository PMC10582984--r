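#' Per-sample call-rate filter
#'
#' A sample is excluded when its genotype call rate falls strictly below the
#' threshold (default 95%); a sample exactly at the threshold is kept.
#'
#' @param g A [GenotypeMatrix-class].
#' @param threshold Minimum fraction of non-missing calls (default 0.95).
#' @return `data.frame` with `sample_id`, `call_rate`, `excluded`, `reasons`.
#' @export
sampleCallRateFilter <- function(g, threshold = 0.95) {
    stopifnot(is(g, "GenotypeMatrix"), nrow(g) >= 1)
    d <- dosages(g)
    cr <- colMeans(!is.na(d))
    excl <- cr < threshold
    data.frame(sample_id = sampleIds(g), call_rate = as.numeric(cr),
               excluded = excl,
               reasons = ifelse(excl, "low_call_rate", ""),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample heterozygosity outlier filter
#'
#' The heterozygous fraction among non-missing autosomal calls is computed
#' per sample; samples more than `sd_threshold` standard deviations from the
#' cohort mean are excluded. With zero SD (all rates equal) nobody is
#' excluded.
#'
#' @param g A [GenotypeMatrix-class].
#' @param sd_threshold Exclusion threshold in SD units (default 5).
#' @param samples Optional subset of sample IDs over which the mean/SD and
#'   the filter are computed (e.g. samples surviving earlier filters).
#' @return `data.frame` with `sample_id`, `het_rate`, `excluded`, `reasons`.
#' @export
heterozygosityFilter <- function(g, sd_threshold = 5, samples = NULL) {
    stopifnot(is(g, "GenotypeMatrix"))
    d <- dosages(g)[!rowData(g)$is_x, , drop = FALSE]
    if (!is.null(samples)) d <- d[, samples, drop = FALSE]
    if (ncol(d) < 3L) stop("need at least 3 samples")
    het <- colSums(d == 1L, na.rm = TRUE) / colSums(!is.na(d))
    m <- mean(het); s <- stats::sd(het)
    excl <- if (is.na(s) || s == 0) rep(FALSE, length(het))
            else abs(het - m) > sd_threshold * s
    data.frame(sample_id = colnames(d), het_rate = as.numeric(het),
               excluded = excl, reasons = ifelse(excl, "het_outlier", ""),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Inbreeding coefficient F of one sample
#'
#' Method-of-moments excess homozygosity,
#' `F = (O_hom - E_hom) / (n - E_hom)`, where `E_hom` sums
#' `1 - 2 p q n_i / (n_i - 1)` over the markers used (the small-sample
#' correction standard in PLINK's `--het`). On X-linked markers F separates
#' males (F near 1) from females (F near 0) and drives [sexCheckFilter()].
#'
#' @param g A [GenotypeMatrix-class].
#' @param sample Sample ID.
#' @param use_x If `TRUE`, restrict to X-flagged variants (sex check);
#'   otherwise autosomal variants.
#' @param freqs Optional named allele-b frequencies; estimated from `g`
#'   across all samples when `NULL`.
#' @return Scalar F (dimensionless; may be negative).
#' @export
inbreedingF <- function(g, sample, use_x = FALSE, freqs = NULL) {
    stopifnot(is(g, "GenotypeMatrix"))
    keep <- if (use_x) rowData(g)$is_x else !rowData(g)$is_x
    d <- dosages(g)[keep, , drop = FALSE]
    if (is.null(freqs)) {
        freqs <- rowMeans(d, na.rm = TRUE) / 2
    } else freqs <- freqs[rownames(d)]
    nonmiss_per_marker <- rowSums(!is.na(d))
    x <- d[, sample]
    use <- !is.na(x) & freqs > 0 & freqs < 1 & nonmiss_per_marker > 1
    if (!any(use)) stop("no polymorphic markers available for sample ",
                        sample)
    p <- freqs[use]; ni <- nonmiss_per_marker[use]
    o_hom <- sum(x[use] != 1L)
    e_hom <- sum(1 - 2 * p * (1 - p) * ni / (ni - 1))
    n <- sum(use)
    if (n == e_hom) return(1)
    (o_hom - e_hom) / (n - e_hom)
}

#' Sex-discordance filter from X-chromosome inbreeding
#'
#' Exclusion rule: a sample annotated male with F below 0.8, or annotated
#' female with F above 0.2, is excluded. Samples of unknown sex are never
#' excluded by this rule (a message reports how many were skipped).
#'
#' @param g A [GenotypeMatrix-class] with X-flagged variants.
#' @param samples Optional sample subset (default: all).
#' @return `data.frame` with `sample_id`, `F`, `annotated_sex`, `excluded`,
#'   `reasons`.
#' @export
sexCheckFilter <- function(g, samples = NULL) {
    stopifnot(is(g, "GenotypeMatrix"))
    if (!any(rowData(g)$is_x))
        stop("no X-flagged variants available for the sex check")
    if (is.null(samples)) samples <- sampleIds(g)
    sex <- annotatedSex(g)[samples]
    f <- vapply(samples, function(s) inbreedingF(g, s, use_x = TRUE),
                numeric(1))
    excl <- (sex == "male" & f < 0.8) | (sex == "female" & f > 0.2)
    if (any(sex == "unknown"))
        message(sum(sex == "unknown"), " sample(s) of unknown sex skipped ",
                "by the sex check")
    data.frame(sample_id = samples, F = as.numeric(f),
               annotated_sex = as.character(sex), excluded = excl,
               reasons = ifelse(excl, "sex_discordant", ""),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' PCA-based population outlier filter
#'
#' Variants are standardized (mean imputation of missing dosages, unit
#' variance), samples are projected onto the top principal components, and a
#' sample is flagged when any of the top components places it more than
#' `sd_threshold` SDs from that component's mean. By default outliers are
#' flagged relative to the cohort itself; pre-computed reference coordinates
#' (e.g. from an external reference panel projection) can be supplied
#' instead.
#'
#' @param g A [GenotypeMatrix-class].
#' @param n_components Number of leading components examined (default 10).
#' @param sd_threshold Flagging threshold in SD units (default 5; `Inf`
#'   disables flagging).
#' @param coords Optional pre-computed samples x components score matrix; when
#'   supplied the PCA step is skipped.
#' @return `data.frame` with `sample_id`, `excluded`, `reasons`, plus the
#'   component scores as attribute `"scores"`.
#' @export
pcaOutlierFilter <- function(g, n_components = 10, sd_threshold = 5,
                             coords = NULL) {
    stopifnot(is(g, "GenotypeMatrix"))
    if (is.null(coords)) {
        d <- dosages(g)[!rowData(g)$is_x, , drop = FALSE]
        if (ncol(d) < n_components + 1)
            stop("need more than n_components samples")
        x <- t(d)                              # samples x variants
        mu <- colMeans(x, na.rm = TRUE)
        for (j in seq_len(ncol(x))) {
            na <- is.na(x[, j]); if (any(na)) x[na, j] <- mu[j]
        }
        v <- apply(x, 2, stats::var)
        x <- x[, v > 0, drop = FALSE]
        if (ncol(x) == 0) stop("constant genotype matrix: PCA undefined")
        pc <- stats::prcomp(x, center = TRUE, scale. = TRUE, rank. =
                            min(n_components, ncol(x), nrow(x) - 1))
        coords <- pc$x
    }
    k <- min(n_components, ncol(coords))
    z <- scale(coords[, seq_len(k), drop = FALSE])
    flag <- apply(abs(z) > sd_threshold, 1, any)
    flag[is.na(flag)] <- FALSE
    out <- data.frame(sample_id = rownames(coords), excluded = as.logical(flag),
                      reasons = ifelse(flag, "pca_outlier", ""),
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "scores") <- coords
    out
}
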