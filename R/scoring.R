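#' Compute per-sample polygenic risk scores for one pathway
#'
#' The PRS of a sample is the sum over the pathway's variants of the
#' risk-allele dosage multiplied by the variant weight (the natural log of the
#' published per-allele odds ratio). Risk-allele dosage is resolved from the
#' genotype matrix allele labels: if the risk allele is the counted allele the
#' dosage is used as-is, if it is the other allele the dosage is reflected
#' (`2 - d`), and if the labels disagree a strand flip (reverse complement)
#' is attempted for non-ambiguous pairs with a warning. Mismatches at
#' strand-ambiguous variants (A/T or C/G) are fatal because a silent strand
#' error would invert the score. A missing dosage is imputed by its
#' Hardy-Weinberg expectation `2 * raf` and counted in `n_missing_used`.
#'
#' @param genotypes A [GenotypeMatrix-class].
#' @param table A [WeightTable-class]; orientation is applied first via
#'   [orientWeights()] so all weights are non-negative.
#' @param pathway Pathway name (one of `pathwayNames(table)`).
#' @return `data.frame` with columns `sample_id`, `score`, `n_missing_used`.
#' @examples
#' wt <- loadWeightTable()
#' gm <- simulateGenotypes(setNames(variantTable(wt)$raf, snpIds(wt)),
#'                         n = 5, seed = 1, table = wt)
#' computePRS(gm, wt, "bcell")
#' @export
computePRS <- function(genotypes, table, pathway = "bcell") {
    stopifnot(is(genotypes, "GenotypeMatrix"), is(table, "WeightTable"))
    table <- orientWeights(table)
    v <- as.data.frame(variantTable(table))
    if (!paste0("in_", pathway) %in% colnames(v))
        stop("unknown pathway '", pathway, "'; available: ",
             paste(pathwayNames(table), collapse = ", "))
    v <- v[v[[paste0("in_", pathway)]], , drop = FALSE]
    missing_snps <- setdiff(v$snp_id, snpIds(genotypes))
    if (length(missing_snps))
        stop("pathway variants absent from genotypes: ",
             paste(missing_snps, collapse = ", "))
    d <- dosages(genotypes)[v$snp_id, , drop = FALSE]
    rd <- as.data.frame(rowData(genotypes))[v$snp_id, , drop = FALSE]

    risk_dosage <- matrix(NA_real_, nrow(v), ncol(d), dimnames = dimnames(d))
    for (i in seq_len(nrow(v))) {
        ori <- .resolveAlleles(v$risk_allele[i], v$other_allele[i],
                               rd$allele_a[i], rd$allele_b[i], v$snp_id[i])
        risk_dosage[i, ] <- if (ori == "b") d[i, ] else 2 - d[i, ]
    }
    n_missing_used <- colSums(is.na(risk_dosage))
    if (any(n_missing_used > 0)) {
        imp <- 2 * v$raf
        for (i in seq_len(nrow(v))) {
            na <- is.na(risk_dosage[i, ])
            if (any(na)) risk_dosage[i, na] <- imp[i]
        }
    }
    score <- as.numeric(crossprod(risk_dosage, v$weight))
    data.frame(sample_id = colnames(d), score = score,
               n_missing_used = as.integer(n_missing_used),
               row.names = NULL, stringsAsFactors = FALSE)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

## decide whether the risk allele maps to the counted allele ("b") or the
## reference allele ("a"), allowing a strand flip for non-ambiguous pairs
.resolveAlleles <- function(risk, other, allele_a, allele_b, snp_id) {
    if (risk == allele_b && other == allele_a) return("b")
    if (risk == allele_a && other == allele_b) return("a")
    ambiguous <- identical(.COMPLEMENT[[risk]], other)
    if (ambiguous)
        stop("allele mismatch at strand-ambiguous variant ", snp_id,
             " (", risk, "/", other, " vs ", allele_a, "/", allele_b, ")")
    rc_risk <- .COMPLEMENT[[risk]]
    rc_other <- .COMPLEMENT[[other]]
    if (rc_risk == allele_b && rc_other == allele_a) {
        warning("strand flip applied at ", snp_id)
        return("b")
    }
    if (rc_risk == allele_a && rc_other == allele_b) {
        warning("strand flip applied at ", snp_id)
        return("a")
    }
    stop("unresolvable allele mismatch at ", snp_id,
         " (", risk, "/", other, " vs ", allele_a, "/", allele_b, ")")
}

#' Compute PRS profiles for all pathways
#'
#' Wide per-sample table of scores, one column per pathway, plus the total
#' count of imputed (missing) locus dosages used.
#'
#' @inheritParams computePRS
#' @param pathways Character vector of pathway names; defaults to all
#'   pathways of `table`.
#' @return `data.frame` with `sample_id`, one `prs_<pathway>` column per
#'   pathway, and `n_missing_used`.
#' @export
computeProfiles <- function(genotypes, table,
                            pathways = pathwayNames(table)) {
    out <- NULL
    nmiss <- 0L
    for (p in pathways) {
        one <- computePRS(genotypes, table, p)
        nmiss <- pmax(nmiss, one$n_missing_used)
        col <- stats::setNames(one["score"], paste0("prs_", p))
        out <- if (is.null(out))
            cbind(one["sample_id"], col) else cbind(out, col)
    }
    out$n_missing_used <- as.integer(nmiss)
    out
}

#' Assign high/low quartile groups
#'
#' Scores are binarized at the third quartile: `high` means strictly above
#' the 75th percentile (type-7 linear-interpolation quantile), `low` means
#' quartiles 1-3. With n distinct scores the high group holds floor(n/4) or
#' ceil(n/4) samples.
#'
#' @param scores Either the `data.frame` returned by [computePRS()] or a
#'   numeric vector of scores (optionally named by sample).
#' @param pathway Label recorded in the output (no computational role).
#' @return `data.frame` with columns `sample_id`, `pathway`, `score`,
#'   `group` (`"high"`/`"low"`) and `q3_threshold`.
#' @examples
#' classifyQuartiles(c(a = 1, b = 2, c = 3, d = 10))$group
#' @export
classifyQuartiles <- function(scores, pathway = "bcell") {
    if (is.data.frame(scores)) {
        s <- scores$score
        ids <- scores$sample_id
    } else {
        s <- as.numeric(scores)
        ids <- if (!is.null(names(scores))) names(scores)
               else paste0("S", seq_along(s))
    }
    if (length(s) < 4L)
        stop("need at least 4 profiles to form quartiles")
    if (anyNA(s))
        stop("scores contain NA")
    if (diff(range(s)) == 0)
        stop("degenerate score distribution: all scores identical")
    q3 <- as.numeric(stats::quantile(s, 0.75, type = 7))
    data.frame(sample_id = ids, pathway = pathway, score = s,
               group = ifelse(s > q3, "high", "low"),
               q3_threshold = q3, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Summarize a score distribution
#'
#' Mean with its t-based 95% confidence interval, SD and n:
#' `CI = mean +/- t(0.975, n-1) * SD / sqrt(n)`.
#'
#' @param scores Numeric vector or the output of [computePRS()].
#' @return One-row `data.frame` with `mean`, `ci_lo`, `ci_hi`, `sd`, `n`.
#' @export
summarizeScores <- function(scores) {
    s <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
    n <- length(s)
    if (n < 2L) stop("need at least 2 scores")
    m <- mean(s)
    sdev <- stats::sd(s)
    half <- stats::qt(0.975, n - 1) * sdev / sqrt(n)
    data.frame(mean = m, ci_lo = m - half, ci_hi = m + half, sd = sdev, n = n)
}

#' Write a scores table to TSV
#'
#' One row per sample: `sample_id`, `prs_<pathway>` and `group_<pathway>` for
#' each pathway, and `n_missing_used`.
#'
#' @param genotypes A [GenotypeMatrix-class].
#' @param table A [WeightTable-class].
#' @param path Output TSV path.
#' @param pathways Pathways to score (default: all in `table`).
#' @return Invisibly, the written `data.frame`.
#' @export
writeScores <- function(genotypes, table, path,
                        pathways = pathwayNames(table)) {
    prof <- computeProfiles(genotypes, table, pathways)
    for (p in pathways) {
        qa <- classifyQuartiles(
            data.frame(sample_id = prof$sample_id,
                       score = prof[[paste0("prs_", p)]]), p)
        prof[[paste0("group_", p)]] <- qa$group
    }
    prof <- prof[, c("sample_id", paste0("prs_", pathways),
                     paste0("group_", pathways), "n_missing_used")]
    utils::write.table(prof, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(prof)
}
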