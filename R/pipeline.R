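#' Pipeline stage commands
#'
#' Thin orchestration layer over the package: each command reads its inputs
#' from files, runs the corresponding module, writes TSV/JSON artifacts into
#' `out_dir` and updates `manifest.json` there (tool version, settings,
#' per-stage sample/variant counts, timestamp). These functions back the
#' `bprs` command-line script shipped under `inst/cli/`.
#'
#' `cmdSimulate` writes `genotypes.vcf`, `phenotypes.tsv` and `truth.json`.
#' `cmdQC` writes `qc_samples.tsv`, `qc_variants.tsv`, `qc_pairs.tsv`, an
#' exclusion log and the filtered matrix `genotypes_qc.vcf`.
#' `cmdScore` writes `scores.tsv` and `score_summary.tsv`.
#' `cmdAssociate` writes `results.tsv` in the reported-table layout
#' (outcome, pathway, stratum, n, estimate, CI, p).
#' `cmdReport` renders `report.md` from whatever artifacts exist.
#'
#' @param out_dir Run directory (created if needed).
#' @param config A [cohortConfig()] (simulate only).
#' @param seed Integer seed (simulate only).
#' @param genotypes Genotype file (VCF or dosage TSV).
#' @param variants Sidecar variant TSV for TSV input.
#' @param weights Weight-table TSV (`NULL` = packaged table).
#' @param phenotypes Phenotype TSV.
#' @param scores Scores TSV from `cmdScore`.
#' @param thresholds Named list overriding QC thresholds (names as in
#'   [runQC()] arguments).
#' @return Each command invisibly returns its main artifact path.
#' @name pipeline
NULL

.manifestUpdate <- function(out_dir, stage, entries) {
    path <- file.path(out_dir, "manifest.json")
    man <- if (file.exists(path))
        jsonlite::read_json(path, simplifyVector = TRUE) else
        list(tool = "BcellPRS",
             version = as.character(utils::packageVersion("BcellPRS")),
             stages = list())
    man$stages[[stage]] <- c(entries,
                             list(timestamp = format(Sys.time(), "%FT%T")))
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(path)
}

#' @rdname pipeline
#' @export
cmdSimulate <- function(out_dir, config = cohortConfig(), seed = 1) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    coh <- generateCohort(config, seed)
    writeVCF(coh$genotypes, file.path(out_dir, "genotypes.vcf"))
    writePhenotypes(coh$phenotypes, file.path(out_dir, "phenotypes.tsv"))
    truth <- coh$truth
    truth$prevalences <- as.list(truth$prevalences)
    truth$hla_weights <- as.list(truth$hla_weights)
    truth$control_freqs <- as.list(truth$control_freqs)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    .manifestUpdate(out_dir, "simulate",
                    list(seed = seed, n_samples = ncol(coh$genotypes),
                         n_variants = nrow(coh$genotypes)))
    invisible(file.path(out_dir, "genotypes.vcf"))
}

#' @rdname pipeline
#' @export
cmdQC <- function(genotypes, out_dir, variants = NULL, thresholds = list()) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    g <- readGenotypes(genotypes, variants = variants)
    qc <- do.call(runQC, c(list(g = g), thresholds))
    wtsv <- function(x, f) utils::write.table(
        x, file.path(out_dir, f), sep = "\t", quote = FALSE,
        row.names = FALSE)
    wtsv(qc$samples, "qc_samples.tsv")
    wtsv(qc$variants, "qc_variants.tsv")
    if (!is.null(qc$pairs)) wtsv(qc$pairs, "qc_pairs.tsv")
    excl <- qc$samples[qc$samples$excluded, ]
    log_lines <- c(sprintf("sample\t%s\t%s\t%s", excl$sample_id,
                           excl$stage, excl$reasons),
                   sprintf("variant\t%s\t-\t%s",
                           qc$variants$snp_id[qc$variants$excluded],
                           qc$variants$reasons[qc$variants$excluded]),
                   paste("note", qc$notes, sep = "\t"))
    writeLines(c("type\tid\tstage\treasons", log_lines),
               file.path(out_dir, "exclusions.log"))
    writeVCF(qc$filtered, file.path(out_dir, "genotypes_qc.vcf"))
    .manifestUpdate(out_dir, "qc",
                    list(funnel = as.list(qc$funnel),
                         variants_kept = nrow(qc$filtered),
                         thresholds = thresholds))
    invisible(file.path(out_dir, "genotypes_qc.vcf"))
}

#' @rdname pipeline
#' @export
cmdScore <- function(genotypes, out_dir, variants = NULL, weights = NULL) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    g <- readGenotypes(genotypes, variants = variants)
    wt <- loadWeightTable(weights)
    sc <- writeScores(g, wt, file.path(out_dir, "scores.tsv"))
    summ <- do.call(rbind, lapply(pathwayNames(wt), function(p)
        cbind(pathway = p, summarizeScores(sc[[paste0("prs_", p)]]))))
    utils::write.table(summ, file.path(out_dir, "score_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .manifestUpdate(out_dir, "score",
                    list(n_samples = nrow(sc),
                         pathways = pathwayNames(wt)))
    invisible(file.path(out_dir, "scores.tsv"))
}

#' @rdname pipeline
#' @export
cmdAssociate <- function(scores, phenotypes, out_dir) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sc <- utils::read.delim(scores, stringsAsFactors = FALSE)
    ph <- readPhenotypes(phenotypes)
    battery <- defaultBattery()
    known <- c(colnames(ph), "ln")
    battery <- battery[battery$outcome %in% known, , drop = FALSE]
    res <- runAnalysisBattery(ph, sc, battery)
    out <- res[, c("outcome", "pathway", "stratum", "model", "n",
                   "estimate", "ci_lo", "ci_hi", "p", "estimable", "note")]
    utils::write.table(out, file.path(out_dir, "results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    nbad <- sum(!out$estimable)
    if (nbad) warning(nbad, " battery row(s) not estimable")
    .manifestUpdate(out_dir, "associate",
                    list(n_tests = nrow(out), n_not_estimable = nbad))
    invisible(file.path(out_dir, "results.tsv"))
}

#' @rdname pipeline
#' @export
cmdReport <- function(out_dir) {
    fmt1 <- function(x) formatC(x, digits = 2, format = "f")
    lines <- c("# BcellPRS run report", "")
    manp <- file.path(out_dir, "manifest.json")
    if (!file.exists(manp))
        stop("incomplete run directory: missing manifest.json")
    man <- jsonlite::read_json(manp, simplifyVector = TRUE)
    lines <- c(lines, paste0("Tool version: ", man$version), "")
    if (!is.null(man$stages$qc)) {
        lines <- c(lines, "## QC funnel", "",
                   paste0("- ", names(man$stages$qc$funnel), ": ",
                          unlist(man$stages$qc$funnel), " samples"),
                   paste0("- variants kept: ", man$stages$qc$variants_kept),
                   "")
    }
    sump <- file.path(out_dir, "score_summary.tsv")
    if (file.exists(sump)) {
        s <- utils::read.delim(sump)
        lines <- c(lines, "## Score distributions", "",
                   sprintf("- %s: mean %s (%s to %s), SD %s, n=%d",
                           s$pathway, fmt1(s$mean), fmt1(s$ci_lo),
                           fmt1(s$ci_hi), fmt1(s$sd), s$n), "")
    }
    resp <- file.path(out_dir, "results.tsv")
    if (file.exists(resp)) {
        r <- utils::read.delim(resp)
        lines <- c(lines, "## Associations", "",
                   "| outcome | pathway | stratum | model | n | estimate (95% CI) | p |",
                   "|---|---|---|---|---|---|---|",
                   sprintf("| %s | %s | %s | %s | %d | %s |  %s |",
                           r$outcome, r$pathway, r$stratum, r$model, r$n,
                           ifelse(r$estimable,
                                  sprintf("%s (%s to %s)", fmt1(r$estimate),
                                          fmt1(r$ci_lo), fmt1(r$ci_hi)),
                                  "not estimable"),
                           ifelse(r$estimable, format(r$p, digits = 2), "-")),
                   "")
    } else {
        lines <- c(lines, "_Association stage not run._", "")
    }
    writeLines(lines, file.path(out_dir, "report.md"))
    invisible(file.path(out_dir, "report.md"))
}
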