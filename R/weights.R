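#' Load a PRS weight table from TSV
#'
#' Reads a tab-separated weight table with columns `snp_id`, `risk_allele`,
#' `other_allele`, `raf`, `or_sle`, `gene`, one or more pathway flag columns
#' named `in_<pathway>` (0/1), and `source`. The per-variant weight is
#' computed as the natural logarithm of the per-allele odds ratio,
#' `weight = log(or_sle)`, at full double precision.
#'
#' The packaged table (`path = NULL`) holds the 20 SLE risk variants mapped to
#' B cell function genes that define the SLE B cell PRS; 12 of them, in genes
#' restricted to B cell activation, additionally define the SLE B cell
#' activation PRS. Risk alleles, risk-allele frequencies (in the patient
#' cohort) and literature odds ratios are as published; the non-risk allele is
#' supplied for allele bookkeeping (it is not part of the published table).
#'
#' @param path Path to a TSV file, or `NULL` for the packaged 20-variant
#'   B cell table.
#' @return A validated [WeightTable-class].
#' @examples
#' wt <- loadWeightTable()
#' nVariants(wt)                         # 20
#' length(pathwaySnps(wt, "bcell_activation"))  # 12
#' @export
loadWeightTable <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "table2_weights.tsv",
                            package = "BcellPRS", mustWork = TRUE)
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    need <- c("snp_id", "risk_allele", "other_allele", "raf", "or_sle",
              "gene", "source")
    miss <- setdiff(need, colnames(raw))
    if (length(miss))
        stop("weight table missing columns: ", paste(miss, collapse = ", "))
    if (nrow(raw) == 0L)
        stop("empty weight table: ", path)
    flagcols <- grep("^in_", colnames(raw), value = TRUE)
    if (!length(flagcols))
        stop("weight table has no pathway flag (in_*) columns")
    dup <- unique(raw$snp_id[duplicated(raw$snp_id)])
    if (length(dup))
        stop("duplicate snp_id in weight table: ", paste(dup, collapse = ", "))
    raf <- as.numeric(raw$raf)
    or_sle <- as.numeric(raw$or_sle)
    bad <- which(is.na(raf) | raf <= 0 | raf >= 1)
    if (length(bad))
        stop("raf outside (0,1) at data row ", bad[1],
             " (", raw$snp_id[bad[1]], ")")
    bad <- which(is.na(or_sle) | or_sle <= 0)
    if (length(bad))
        stop("or_sle <= 0 at data row ", bad[1],
             " (", raw$snp_id[bad[1]], ")")
    v <- DataFrame(
        snp_id = raw$snp_id,
        risk_allele = toupper(raw$risk_allele),
        other_allele = toupper(raw$other_allele),
        raf = raf,
        or_sle = or_sle,
        weight = log(or_sle),
        gene = raw$gene,
        source = raw$source,
        row.names = raw$snp_id)
    ## pathway names drop the "in_" prefix and any "_prs" suffix, so the
    ## spec'd file columns in_bcell_prs / in_bcell_activation_prs map to
    ## pathways "bcell" and "bcell_activation"
    pathways <- sub("_prs$", "", sub("^in_", "", flagcols))
    for (i in seq_along(flagcols))
        v[[paste0("in_", pathways[i])]] <- as.integer(raw[[flagcols[i]]]) == 1L
    new("WeightTable", variants = v, pathways = pathways)
}

#' Orient weights so every odds ratio is risk-increasing
#'
#' A variant whose listed allele is protective (OR < 1) is flipped so that the
#' major/other allele becomes the risk allele: alleles are swapped, the odds
#' ratio is inverted (`1/OR`) and the risk-allele frequency complemented
#' (`1 - raf`). Variants with OR >= 1 are returned unchanged; a variant with
#' OR exactly 1 contributes zero weight and is reported via a message.
#' The operation is idempotent and leaves all output odds ratios >= 1, so the
#' directionality of the score is consistently towards disease risk.
#'
#' @param table A [WeightTable-class].
#' @return A [WeightTable-class] with all `or_sle >= 1`.
#' @examples
#' wt <- loadWeightTable()
#' identical(variantTable(orientWeights(wt))$or_sle, variantTable(wt)$or_sle)
#' @export
orientWeights <- function(table) {
    stopifnot(is(table, "WeightTable"))
    v <- table@variants
    if (any(v$or_sle == 0))
        stop("or_sle of 0 cannot be oriented")
    flip <- which(v$or_sle < 1)
    if (length(flip)) {
        ra <- v$risk_allele[flip]
        v$risk_allele[flip] <- v$other_allele[flip]
        v$other_allele[flip] <- ra
        v$or_sle[flip] <- 1 / v$or_sle[flip]
        v$raf[flip] <- 1 - v$raf[flip]
        v$weight[flip] <- log(v$or_sle[flip])
    }
    zero <- which(v$or_sle == 1)
    if (length(zero))
        message("zero-weight variants (OR = 1): ",
                paste(v$snp_id[zero], collapse = ", "))
    initialize(table, variants = v)
}
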