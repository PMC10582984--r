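#' Accessors for WeightTable and GenotypeMatrix
#'
#' `variantTable()` returns the per-variant DataFrame of a [WeightTable-class];
#' `pathwayNames()` its pathway flag names; `snpIds()` the variant identifiers
#' of either class; `nVariants()` the variant count; `pathwaySnps()` the IDs
#' flagged for one pathway; `dosages()` the dosage matrix of a
#' [GenotypeMatrix-class] (variants x samples); `sampleIds()` its sample
#' identifiers; `annotatedSex()` the per-sample sex annotation.
#'
#' @param x A [WeightTable-class] or [GenotypeMatrix-class] object.
#' @param pathway Pathway name, e.g. `"bcell"`.
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))
#' @rdname accessors
#' @export
setGeneric("pathwayNames", function(x) standardGeneric("pathwayNames"))
#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))
#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setGeneric("pathwaySnps", function(x, pathway) standardGeneric("pathwaySnps"))
#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("annotatedSex", function(x) standardGeneric("annotatedSex"))

#' @rdname accessors
setMethod("variantTable", "WeightTable", function(x) x@variants)
#' @rdname accessors
setMethod("pathwayNames", "WeightTable", function(x) x@pathways)
#' @rdname accessors
setMethod("snpIds", "WeightTable", function(x) x@variants$snp_id)
#' @rdname accessors
setMethod("nVariants", "WeightTable", function(x) nrow(x@variants))
#' @rdname accessors
setMethod("pathwaySnps", "WeightTable", function(x, pathway) {
    col <- paste0("in_", pathway)
    if (!col %in% colnames(x@variants))
        stop("unknown pathway '", pathway, "'; available: ",
             paste(x@pathways, collapse = ", "))
    x@variants$snp_id[x@variants[[col]]]
})
#' @rdname accessors
setMethod("snpIds", "GenotypeMatrix",
    function(x) rowData(x)$snp_id)
#' @rdname accessors
setMethod("nVariants", "GenotypeMatrix", function(x) nrow(x))
#' @rdname accessors
setMethod("dosages", "GenotypeMatrix",
    function(x) assay(x, "dosage"))
#' @rdname accessors
setMethod("sampleIds", "GenotypeMatrix",
    function(x) colData(x)$sample_id)
#' @rdname accessors
setMethod("annotatedSex", "GenotypeMatrix", function(x) {
    s <- colData(x)$sex
    names(s) <- colData(x)$sample_id
    s
})
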