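#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @import SummarizedExperiment
NULL

#' WeightTable: per-variant PRS weights
#'
#' An ordered table of risk variants, one per locus, carrying the parameters
#' of a polygenic risk score: the risk and non-risk allele, the risk-allele
#' frequency (RAF) in the reference cohort, the published per-allele odds
#' ratio for SLE, the derived weight `log(or_sle)`, the mapped gene and one
#' logical membership column per pathway score (columns named `in_<pathway>`).
#'
#' @slot variants A [S4Vectors::DataFrame] with columns `snp_id`,
#'   `risk_allele`, `other_allele`, `raf`, `or_sle`, `weight`, `gene`,
#'   `source`, and one logical `in_<pathway>` column per pathway.
#' @slot pathways Character vector of pathway names (e.g. `"bcell"`,
#'   `"bcell_activation"`).
#'
#' @seealso [loadWeightTable()], [orientWeights()], [computePRS()]
#' @export
setClass("WeightTable",
    representation(variants = "DataFrame", pathways = "character"))

setValidity("WeightTable", function(object) {
    v <- object@variants
    msgs <- character()
    need <- c("snp_id", "risk_allele", "other_allele", "raf", "or_sle",
              "weight", "gene", "source")
    miss <- setdiff(need, colnames(v))
    if (length(miss))
        msgs <- c(msgs, paste("missing columns:", paste(miss, collapse = ", ")))
    else {
        if (anyDuplicated(v$snp_id))
            msgs <- c(msgs, paste("duplicate snp_id:",
                paste(unique(v$snp_id[duplicated(v$snp_id)]), collapse = ", ")))
        bad <- which(!(v$raf > 0 & v$raf < 1))
        if (length(bad))
            msgs <- c(msgs, paste0("raf outside (0,1) at row ", bad[1]))
        bad <- which(!(v$or_sle > 0))
        if (length(bad))
            msgs <- c(msgs, paste0("or_sle <= 0 at row ", bad[1]))
        if (any(abs(v$weight - log(v$or_sle)) > 1e-12 * pmax(1, abs(v$weight))))
            msgs <- c(msgs, "weight != log(or_sle)")
    }
    for (p in object@pathways) {
        col <- paste0("in_", p)
        if (!col %in% colnames(v))
            msgs <- c(msgs, paste("missing pathway column", col))
    }
    if (length(msgs)) msgs else TRUE
})

#' GenotypeMatrix: dosage matrix with variant and sample annotation
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a single `"dosage"`
#' assay of risk-of-allele-b counts in \{0, 1, 2, NA\}, with variants as rows
#' (rowData: `snp_id`, `chrom`, `pos` 1-based, `allele_a`, `allele_b`, `is_x`)
#' and samples as columns (colData: `sample_id`, `sex` in
#' \{"male","female","unknown"\}).
#'
#' @seealso [GenotypeMatrix()], [readGenotypes()], [dosages()]
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
    msgs <- character()
    if (!"dosage" %in% assayNames(object))
        return("assay 'dosage' is required")
    d <- assay(object, "dosage")
    ok <- is.na(d) | d == 0 | d == 1 | d == 2
    if (!all(ok))
        msgs <- c(msgs, "dosages must be 0, 1, 2 or NA")
    rd <- rowData(object)
    need <- c("snp_id", "chrom", "pos", "allele_a", "allele_b", "is_x")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msgs <- c(msgs, paste("rowData missing:", paste(miss, collapse = ", ")))
    else if (anyDuplicated(rd$snp_id))
        msgs <- c(msgs, "duplicate snp_id in rowData")
    cd <- colData(object)
    if (!"sex" %in% colnames(cd))
        msgs <- c(msgs, "colData missing 'sex'")
    else if (!all(cd$sex %in% c("male", "female", "unknown")))
        msgs <- c(msgs, "sex must be male/female/unknown")
    if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage Integer/numeric matrix of allele-b dosages, variants in rows
#'   and samples in columns (values 0/1/2/NA). A samples-in-rows matrix whose
#'   column names are the variant IDs is transposed automatically when
#'   `variants` is supplied and matches the column names.
#' @param variants `data.frame` (or DataFrame) with columns `snp_id`, `chrom`,
#'   `pos`, `allele_a`, `allele_b` and optionally `is_x` (default `FALSE`).
#' @param sample_ids Character vector of sample identifiers.
#' @param sex Optional character vector (`"male"`, `"female"`, `"unknown"`),
#'   recycled to the number of samples; default `"unknown"`.
#'
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' gm <- GenotypeMatrix(
#'     dosage = matrix(c(0, 1, 2, 1), 2, 2,
#'         dimnames = list(c("rs1", "rs2"), c("s1", "s2"))),
#'     variants = data.frame(snp_id = c("rs1", "rs2"), chrom = "1",
#'         pos = c(100L, 200L), allele_a = "A", allele_b = "G"),
#'     sample_ids = c("s1", "s2"))
#' dosages(gm)
#' @export
GenotypeMatrix <- function(dosage, variants, sample_ids = colnames(dosage),
                           sex = "unknown") {
    variants <- as.data.frame(variants)
    if (!"is_x" %in% colnames(variants)) variants$is_x <- FALSE
    if (!is.null(colnames(dosage)) &&
        all(colnames(dosage) %in% variants$snp_id) &&
        !all(rownames(dosage) %in% variants$snp_id)) {
        dosage <- t(dosage)        # samples-in-rows input
        if (missing(sample_ids) || is.null(sample_ids))
            sample_ids <- colnames(dosage)
    }
    if (is.null(sample_ids))
        sample_ids <- paste0("S", seq_len(ncol(dosage)))
    if (nrow(dosage) != nrow(variants))
        stop("dosage rows (", nrow(dosage), ") != variant records (",
             nrow(variants), ")")
    if (ncol(dosage) != length(sample_ids))
        stop("dosage columns != number of sample_ids")
    storage.mode(dosage) <- "integer"
    dimnames(dosage) <- list(variants$snp_id, sample_ids)
    sex <- rep_len(as.character(sex), length(sample_ids))
    se <- SummarizedExperiment(
        assays = list(dosage = dosage),
        rowData = DataFrame(variants, row.names = variants$snp_id),
        colData = DataFrame(sample_id = sample_ids, sex = sex,
                            row.names = sample_ids))
    new("GenotypeMatrix", se)
}

setMethod("show", "WeightTable", function(object) {
    v <- object@variants
    cat("WeightTable with", nrow(v), "variants\n")
    for (p in object@pathways)
        cat("  pathway ", p, ": ", sum(v[[paste0("in_", p)]]),
            " variants\n", sep = "")
    cat("  OR range: [", format(min(v$or_sle)), ", ",
        format(max(v$or_sle)), "]\n", sep = "")
})

setMethod("show", "GenotypeMatrix", function(object) {
    cat("GenotypeMatrix:", nrow(object), "variants x", ncol(object),
        "samples\n")
    d <- assay(object, "dosage")
    cat("  missingness:", format(round(mean(is.na(d)), 4)), "\n")
    cat("  X-linked variants:", sum(rowData(object)$is_x), "\n")
})
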