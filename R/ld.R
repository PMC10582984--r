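#' Greedy LD pruning keeping the highest-OR variant per correlated set
#'
#' Pairwise linkage disequilibrium is measured as the squared Pearson
#' correlation of dosage vectors over complete pairs (composite genotype
#' r-squared, phase-free). While any kept pair exceeds the threshold
#' (default r-squared > 0.2), the member with the lower SLE odds ratio is
#' dropped (ties: lower risk-allele frequency, then lexicographically larger
#' snp_id), so the variant with the highest published OR represents each
#' risk locus. A zero-variance dosage vector has r-squared defined as 0 with
#' a warning.
#'
#' @param g A [GenotypeMatrix-class] containing all variants of `table`.
#' @param table A [WeightTable-class] supplying the ORs and RAFs used for
#'   the tie-breaks.
#' @param r2_threshold Pruning threshold (default 0.2).
#' @return List with `kept` (character vector of snp_ids, in table order)
#'   and `removed` (`data.frame` of `snp_id`, `partner_snp_id`, `r2`).
#' @export
ldPrune <- function(g, table, r2_threshold = 0.2) {
    stopifnot(is(g, "GenotypeMatrix"), is(table, "WeightTable"))
    v <- as.data.frame(variantTable(table))
    miss <- setdiff(v$snp_id, snpIds(g))
    if (length(miss))
        stop("weight-table variants absent from genotypes: ",
             paste(miss, collapse = ", "))
    d <- dosages(g)[v$snp_id, , drop = FALSE]
    vr <- apply(d, 1, stats::var, na.rm = TRUE)
    if (any(is.na(vr) | vr == 0))
        warning("zero-variance dosage vector(s): ",
                paste(v$snp_id[is.na(vr) | vr == 0], collapse = ", "),
                "; their r2 is taken as 0")
    r2 <- suppressWarnings(
        stats::cor(t(d), use = "pairwise.complete.obs")^2)
    r2[!is.finite(r2)] <- 0
    diag(r2) <- 0

    kept <- v$snp_id
    removed <- data.frame(snp_id = character(), partner_snp_id = character(),
                          r2 = numeric(), stringsAsFactors = FALSE)
    repeat {
        sub <- r2[kept, kept, drop = FALSE]
        w <- which(sub > r2_threshold, arr.ind = TRUE)
        w <- w[w[, 1] < w[, 2], , drop = FALSE]
        if (!nrow(w)) break
        ## worst offending pair first, deterministically
        vals <- sub[w]
        w <- w[order(-vals, kept[w[, 1]], kept[w[, 2]]), , drop = FALSE]
        a <- kept[w[1, 1]]; b <- kept[w[1, 2]]
        ia <- match(a, v$snp_id); ib <- match(b, v$snp_id)
        drop_a <-
            if (v$or_sle[ia] != v$or_sle[ib]) v$or_sle[ia] < v$or_sle[ib]
            else if (v$raf[ia] != v$raf[ib]) v$raf[ia] < v$raf[ib]
            else a > b
        loser <- if (drop_a) a else b
        winner <- if (drop_a) b else a
        removed <- rbind(removed, data.frame(
            snp_id = loser, partner_snp_id = winner,
            r2 = r2[loser, winner], stringsAsFactors = FALSE))
        kept <- setdiff(kept, loser)
    }
    list(kept = kept, removed = removed)
}
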