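## Shared fixtures and independent oracles, built in code at test time.

## write a minimal weight-table TSV and return its path
writeWeightTSV <- function(rows, path = tempfile(fileext = ".tsv")) {
    hdr <- paste("snp_id", "risk_allele", "other_allele", "raf", "or_sle",
                 "gene", "in_bcell_prs", "in_bcell_activation_prs",
                 "source", sep = "\t")
    writeLines(c(hdr, rows), path)
    path
}

## one-variant table: rs2230926 G/T raf 0.06 OR 2.03, both pathways
oneSnpTable <- function() {
    loadWeightTable(writeWeightTSV(
        "rs2230926\tG\tT\t0.06\t2.03\tTNFAIP3\t1\t1\tMorris et al"))
}

## genotype matrix from an explicit variants x samples dosage matrix,
## default alleles matching the packaged risk/other orientation
gmFromDosage <- function(dos, snp_ids = rownames(dos),
                         allele_a = "T", allele_b = "G",
                         is_x = FALSE, sex = "female") {
    if (is.null(snp_ids)) snp_ids <- paste0("rs", seq_len(nrow(dos)))
    GenotypeMatrix(dos,
        variants = data.frame(snp_id = snp_ids, chrom = "1",
            pos = seq_len(nrow(dos)), allele_a = allele_a,
            allele_b = allele_b, is_x = is_x),
        sample_ids = colnames(dos), sex = sex)
}

## independent HWE oracle: closed-form conditional probabilities via lgamma
## (direct formula, no recurrence), same tie-inclusion rule
hweOracle <- function(n, r) {
    hets <- seq.int(r %% 2L, r, by = 2L)
    ha <- (r - hets) / 2
    hc <- n - hets - ha
    lp <- lgamma(n + 1) - lgamma(ha + 1) - lgamma(hc + 1) -
        lgamma(hets + 1) + hets * log(2) +
        lgamma(r + 1) + lgamma(2 * n - r + 1) - lgamma(2 * n + 1)
    probs <- exp(lp)
    p <- vapply(probs, function(po) sum(probs[probs <= po * (1 + 1e-9)]),
                numeric(1))
    list(het = hets, p = pmin(p, 1))
}

## gene-dropping full sibs at given allele freqs: returns 2 x m dosages
simulateSibPair <- function(freqs) {
    m <- length(freqs)
    pat <- matrix(rbinom(2 * m, 1, rep(freqs, 2)), 2, m, byrow = TRUE)
    mat <- matrix(rbinom(2 * m, 1, rep(freqs, 2)), 2, m, byrow = TRUE)
    child <- function() pat[cbind(sample(1:2, m, TRUE), 1:m)] +
                        mat[cbind(sample(1:2, m, TRUE), 1:m)]
    rbind(child(), child())
}
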