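#' Read genotypes from VCF or a TSV dosage matrix
#'
#' VCF input (biallelic SNVs) is parsed with \pkg{vcfR}; dosages count the
#' ALT allele from the GT field (`NA` for missing). TSV input is a dosage
#' matrix whose first column is `sample_id` and whose remaining headers are
#' rsIDs, accompanied by a sidecar variant TSV with columns `snp_id`,
#' `chrom`, `pos`, `allele_a`, `allele_b` and optionally `is_x` (0/1).
#'
#' @param path Genotype file (`.vcf`/`.vcf.gz` or `.tsv`).
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param variants Sidecar variant TSV path (TSV input only).
#' @param sex Optional named character vector of sample sexes, or a 2-column
#'   TSV path (`sample_id`, `sex`).
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "tsv"),
                          variants = NULL, sex = NULL) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
    if (!file.exists(path)) stop("genotype file not found: ", path)
    if (format == "vcf") {
        vcf <- vcfR::read.vcfR(path, verbose = FALSE)
        fix <- vcfR::getFIX(vcf)
        gt <- vcfR::extract.gt(vcf, element = "GT")
        alt_count <- function(x) {
            x <- sub("\\|", "/", x)
            ifelse(is.na(x) | x %in% c(".", "./."), NA_integer_,
                   (substr(x, 1, 1) == "1") + (substr(x, 3, 3) == "1"))
        }
        dos <- apply(gt, 2, alt_count)
        dim(dos) <- dim(gt); dimnames(dos) <- dimnames(gt)
        vtab <- data.frame(
            snp_id = fix[, "ID"], chrom = fix[, "CHROM"],
            pos = as.integer(fix[, "POS"]),
            allele_a = fix[, "REF"], allele_b = fix[, "ALT"],
            is_x = fix[, "CHROM"] %in% c("X", "chrX", "23"),
            stringsAsFactors = FALSE)
        bad <- nchar(vtab$allele_a) != 1 | nchar(vtab$allele_b) != 1
        if (any(bad)) {
            warning(sum(bad), " non-biallelic-SNV record(s) dropped")
            vtab <- vtab[!bad, , drop = FALSE]
            dos <- dos[!bad, , drop = FALSE]
        }
        gm <- GenotypeMatrix(dos, vtab, sample_ids = colnames(dos))
    } else {
        if (is.null(variants))
            stop("TSV input requires a sidecar variant table (variants=)")
        dm <- utils::read.delim(path, check.names = FALSE,
                                stringsAsFactors = FALSE)
        if (colnames(dm)[1] != "sample_id")
            stop("malformed dosage TSV ", path,
                 ": first column must be sample_id")
        ids <- dm$sample_id
        dos <- t(as.matrix(dm[, -1, drop = FALSE]))
        colnames(dos) <- ids
        vtab <- utils::read.delim(variants, stringsAsFactors = FALSE)
        if (!all(rownames(dos) %in% vtab$snp_id))
            stop("dosage columns missing from the variant sidecar: ",
                 paste(setdiff(rownames(dos), vtab$snp_id), collapse = ", "))
        vtab <- vtab[match(rownames(dos), vtab$snp_id), , drop = FALSE]
        if ("is_x" %in% colnames(vtab))
            vtab$is_x <- as.logical(as.integer(vtab$is_x))
        gm <- GenotypeMatrix(dos, vtab, sample_ids = ids)
    }
    if (!is.null(sex)) {
        if (is.character(sex) && length(sex) == 1 && file.exists(sex)) {
            st <- utils::read.delim(sex, stringsAsFactors = FALSE)
            sex <- stats::setNames(st$sex, st$sample_id)
        }
        s <- sex[sampleIds(gm)]
        s[is.na(s)] <- "unknown"
        colData(gm)$sex <- unname(s)
    }
    gm
}

#' Write a GenotypeMatrix as VCF
#'
#' Minimal VCFv4.2 writer with GT-only genotype fields: dosage 0/1/2 maps to
#' `0/0`, `0/1`, `1/1` and missing to `./.`. `allele_a` is written as REF and
#' `allele_b` (the counted allele) as ALT.
#'
#' @param g A [GenotypeMatrix-class].
#' @param path Output `.vcf` path.
#' @return Invisibly, `path`.
#' @export
writeVCF <- function(g, path) {
    stopifnot(is(g, "GenotypeMatrix"))
    rd <- as.data.frame(rowData(g))
    d <- dosages(g)
    gtmap <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow(d), ncol(d))
    ok <- !is.na(d)
    gt[ok] <- gtmap[d[ok] + 1L]
    hdr <- c("##fileformat=VCFv4.2",
             "##source=BcellPRS",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(d)), collapse = "\t"))
    body <- paste(rd$chrom, rd$pos, rd$snp_id, rd$allele_a, rd$allele_b,
                  ".", "PASS", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read / write a phenotype table
#'
#' The phenotype TSV has one row per sample: `sample_id`, `is_case` (0/1),
#' `disease_duration`, `age_at_onset`, binary outcome columns (e.g. `dsdna`,
#' `renal`, `immunological`, `low_complement`, the remaining ACR items;
#' 0/1/NA), `time_to_ln` + `ln_event`, and tag-SNP dosage columns
#' `tag_rs1269852`, `tag_rs3135388`. Controls carry `NA` in the clinical
#' columns.
#'
#' @param path TSV path.
#' @return `data.frame`.
#' @export
readPhenotypes <- function(path) {
    ph <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"sample_id" %in% colnames(ph))
        stop("phenotype table ", path, " lacks a sample_id column")
    if (any(ph$disease_duration < 0, na.rm = TRUE))
        stop("negative disease_duration in ", path)
    if (any(ph$time_to_ln < 0, na.rm = TRUE))
        stop("negative time_to_ln in ", path)
    ph
}

#' @rdname readPhenotypes
#' @param pheno Phenotype `data.frame`.
#' @export
writePhenotypes <- function(pheno, path) {
    utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
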