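#' Per-variant QC filters
#'
#' Applies the three variant-level rules in one pass: call rate below
#' `call_thr` (default 98%), minor allele frequency below `maf_thr` (default
#' 0.01), and failure of the Hardy-Weinberg exact test at `hwe_thr` (default
#' 1e-4). MAF is computed on non-missing calls; the HWE test uses the
#' non-missing autosomal genotype counts (X-flagged variants are exempt from
#' the HWE rule). A variant with zero non-missing calls is excluded for call
#' rate only, with MAF and HWE left undefined (`NA`).
#'
#' @param g A [GenotypeMatrix-class].
#' @param call_thr,maf_thr,hwe_thr Filter thresholds.
#' @param samples Optional sample subset on which rates are computed.
#' @return `data.frame` with `snp_id`, `call_rate`, `maf`, `hwe_p`,
#'   `excluded`, `reasons` (comma-joined).
#' @export
variantFilters <- function(g, call_thr = 0.98, maf_thr = 0.01,
                           hwe_thr = 1e-4, samples = NULL) {
    stopifnot(is(g, "GenotypeMatrix"), ncol(g) >= 1)
    d <- dosages(g)
    if (!is.null(samples)) d <- d[, samples, drop = FALSE]
    nonmiss <- rowSums(!is.na(d))
    cr <- nonmiss / ncol(d)
    n_bb <- rowSums(d == 2L, na.rm = TRUE)
    n_ab <- rowSums(d == 1L, na.rm = TRUE)
    n_aa <- nonmiss - n_ab - n_bb
    pb <- (2 * n_bb + n_ab) / (2 * nonmiss)
    maf <- pmin(pb, 1 - pb)
    maf[nonmiss == 0] <- NA_real_
    hwe_p <- rep(NA_real_, nrow(d))
    auto <- !rowData(g)$is_x & nonmiss > 0
    if (any(auto))
        hwe_p[auto] <- hweExactTest(n_aa[auto], n_ab[auto], n_bb[auto])
    reasons <- mapply(function(c_ok, m, h) {
        r <- character()
        if (!c_ok) r <- c(r, "low_call_rate")
        if (!is.na(m) && m < maf_thr) r <- c(r, "low_maf")
        if (!is.na(h) && h < hwe_thr) r <- c(r, "hwe_fail")
        paste(r, collapse = ",")
    }, cr >= call_thr, maf, hwe_p)
    data.frame(snp_id = rownames(d), call_rate = as.numeric(cr),
               maf = as.numeric(maf), hwe_p = as.numeric(hwe_p),
               excluded = nzchar(reasons), reasons = unname(reasons),
               row.names = NULL, stringsAsFactors = FALSE)
}
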