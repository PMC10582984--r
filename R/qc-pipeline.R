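#' Run the full genotype QC chain
#'
#' Applies the QC stages in the study's order — sample call rate, PCA
#' population outliers, IBD relatedness, heterozygosity outliers, X-linked
#' inbreeding sex check — then the variant-level filters (call rate, MAF,
#' HWE) on the surviving samples. Each exclusion records the stage at which
#' it occurred; later stages are computed on the samples surviving earlier
#' ones. Stages that cannot run on the given data (no X-flagged variants for
#' the sex check; fewer overlapping markers than the IBD floor) are skipped
#' with a note rather than failing the chain.
#'
#' @param g A [GenotypeMatrix-class].
#' @param sample_call_thr,variant_call_thr,maf_thr,hwe_thr,ibd_thr,het_sd,
#'   pca_sd,pca_components QC thresholds (defaults: 0.95, 0.98, 0.01, 1e-4,
#'   0.1875, 5, 5, 10).
#' @param min_ibd_overlap Minimum overlapping markers for the IBD stage.
#' @return List with `samples` (per-sample report: `sample_id`, `call_rate`,
#'   `het_rate`, `F`, `excluded`, `reasons`, `stage`), `variants` (per-variant
#'   report), `pairs` (IBD estimates or `NULL`), `filtered` (the pruned
#'   [GenotypeMatrix-class]), `funnel` (per-stage surviving sample counts)
#'   and `notes`.
#' @export
runQC <- function(g, sample_call_thr = 0.95, variant_call_thr = 0.98,
                  maf_thr = 0.01, hwe_thr = 1e-4, ibd_thr = 0.1875,
                  het_sd = 5, pca_sd = 5, pca_components = 10,
                  min_ibd_overlap = 50) {
    stopifnot(is(g, "GenotypeMatrix"))
    notes <- character()
    rep_s <- data.frame(sample_id = sampleIds(g),
                        call_rate = NA_real_, het_rate = NA_real_,
                        F = NA_real_, excluded = FALSE, reasons = "",
                        stage = "", stringsAsFactors = FALSE)
    rownames(rep_s) <- rep_s$sample_id
    funnel <- c(input = ncol(g))
    mark <- function(rep_s, ids, reason, stage) {
        rep_s[ids, "excluded"] <- TRUE
        rep_s[ids, "reasons"] <- ifelse(
            nzchar(rep_s[ids, "reasons"]),
            paste(rep_s[ids, "reasons"], reason, sep = ","), reason)
        rep_s[ids, "stage"] <- ifelse(nzchar(rep_s[ids, "stage"]),
                                      rep_s[ids, "stage"], stage)
        rep_s
    }
    alive <- function(rep_s) rep_s$sample_id[!rep_s$excluded]

    ## 1. sample call rate
    crr <- sampleCallRateFilter(g, sample_call_thr)
    rep_s$call_rate <- crr$call_rate[match(rep_s$sample_id, crr$sample_id)]
    rep_s <- mark(rep_s, crr$sample_id[crr$excluded], "low_call_rate",
                  "call_rate")
    funnel <- c(funnel, call_rate = length(alive(rep_s)))

    ## 2. PCA outliers
    keep <- alive(rep_s)
    if (length(keep) > pca_components + 1) {
        pcar <- tryCatch(
            pcaOutlierFilter(g[, keep], pca_components, pca_sd),
            error = function(e) e)
        if (inherits(pcar, "error")) {
            notes <- c(notes, paste("PCA stage skipped:",
                                    conditionMessage(pcar)))
        } else {
            rep_s <- mark(rep_s, pcar$sample_id[pcar$excluded],
                          "pca_outlier", "pca")
        }
    } else notes <- c(notes, "PCA stage skipped: too few samples")
    funnel <- c(funnel, pca = length(alive(rep_s)))

    ## 3. IBD relatedness
    keep <- alive(rep_s)
    pairs <- NULL
    n_auto <- sum(!rowData(g)$is_x)
    if (length(keep) >= 2 && n_auto >= min_ibd_overlap) {
        pairs <- tryCatch(
            ibdEstimateAll(g, samples = keep, min_overlap = min_ibd_overlap),
            error = function(e) e)
        if (inherits(pairs, "error")) {
            notes <- c(notes, paste("IBD stage skipped:",
                                    conditionMessage(pairs)))
            pairs <- NULL
        } else {
            cr <- stats::setNames(rep_s$call_rate, rep_s$sample_id)
            rel <- relatednessFilter(pairs, cr, ibd_thr)
            rep_s <- mark(rep_s, rel, "related", "ibd")
        }
    } else if (n_auto < min_ibd_overlap)
        notes <- c(notes, paste0("IBD stage skipped: only ", n_auto,
                                 " autosomal markers (< ", min_ibd_overlap,
                                 ")"))
    funnel <- c(funnel, ibd = length(alive(rep_s)))

    ## 4. heterozygosity outliers (mean/SD over surviving samples)
    keep <- alive(rep_s)
    if (length(keep) >= 3) {
        hr <- heterozygosityFilter(g, het_sd, samples = keep)
        rep_s$het_rate[match(hr$sample_id, rep_s$sample_id)] <- hr$het_rate
        rep_s <- mark(rep_s, hr$sample_id[hr$excluded], "het_outlier", "het")
    } else notes <- c(notes, "heterozygosity stage skipped: too few samples")
    funnel <- c(funnel, het = length(alive(rep_s)))

    ## 5. sex check (X-linked inbreeding F)
    keep <- alive(rep_s)
    if (any(rowData(g)$is_x) && length(keep)) {
        sx <- suppressMessages(sexCheckFilter(g, samples = keep))
        rep_s$F[match(sx$sample_id, rep_s$sample_id)] <- sx$F
        rep_s <- mark(rep_s, sx$sample_id[sx$excluded], "sex_discordant",
                      "sex_check")
    } else notes <- c(notes, "sex check skipped: no X-flagged variants")
    funnel <- c(funnel, sex_check = length(alive(rep_s)))

    ## 6. variant filters on surviving samples
    keep <- alive(rep_s)
    rep_v <- variantFilters(g, variant_call_thr, maf_thr, hwe_thr,
                            samples = keep)
    keep_v <- rep_v$snp_id[!rep_v$excluded]
    filtered <- g[keep_v, keep]
    list(samples = rep_s[, c("sample_id", "call_rate", "het_rate", "F",
                             "excluded", "reasons", "stage")],
         variants = rep_v, pairs = pairs, filtered = filtered,
         funnel = funnel, notes = notes)
}
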