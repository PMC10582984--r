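#' Assign HLA-DRB1*03/15 tag-SNP strata
#'
#' Patients are stratified by carriage of the HLA-DRB1*03:01 and
#' HLA-DRB1*15:01 risk haplotypes, proxied by tag SNPs rs1269852 and
#' rs3135388 under dominant coding (positive = tag dosage >= 1):
#' `neg_neg` carries neither tag, `double_pos` carries both, `single_pos`
#' carries exactly one. Samples with a missing tag dosage are left
#' unassigned (`NA`) and counted in a message.
#'
#' @param pheno Phenotype `data.frame` with `tag_rs1269852` and
#'   `tag_rs3135388` dosage columns.
#' @return `data.frame` with `sample_id` and `group`.
#' @examples
#' hlaGroupAssign(data.frame(sample_id = c("a", "b", "c"),
#'     tag_rs1269852 = c(0, 2, 1), tag_rs3135388 = c(0, 1, 0)))
#' @export
hlaGroupAssign <- function(pheno) {
    need <- c("tag_rs1269852", "tag_rs3135388")
    miss <- setdiff(need, colnames(pheno))
    if (length(miss))
        stop("phenotype table lacks tag-SNP columns: ",
             paste(miss, collapse = ", "))
    t1 <- pheno$tag_rs1269852 >= 1
    t2 <- pheno$tag_rs3135388 >= 1
    grp <- ifelse(t1 & t2, "double_pos",
           ifelse(!t1 & !t2, "neg_neg", "single_pos"))
    if (anyNA(grp))
        message(sum(is.na(grp)), " sample(s) with missing tag dosage left ",
                "unassigned")
    data.frame(sample_id = pheno$sample_id, group = grp,
               row.names = NULL, stringsAsFactors = FALSE)
}

.assocRow <- function(effect_type, estimate, ci_lo, ci_hi, p, n,
                      covariates = "", estimable = TRUE, note = "") {
    data.frame(effect_type = effect_type, estimate = estimate,
               ci_lo = ci_lo, ci_hi = ci_hi, p = p, n = n,
               covariates = covariates, estimable = estimable, note = note,
               stringsAsFactors = FALSE)
}

#' Two-sample Student's t-test on score distributions
#'
#' Pooled-variance (classical Student) two-sided t-test comparing mean
#' scores of two groups; the estimate is the mean difference `a - b` with
#' its 95% CI. Two identical constant groups return `p = 1` by convention.
#'
#' @param scores_a,scores_b Numeric vectors (each of length >= 2).
#' @return One-row `data.frame` (`effect_type = "mean_diff"`).
#' @export
compareMeansTTest <- function(scores_a, scores_b) {
    if (length(scores_a) < 2 || length(scores_b) < 2)
        stop("each group needs at least 2 observations")
    na <- length(scores_a); nb <- length(scores_b)
    diff <- mean(scores_a) - mean(scores_b)
    sp2 <- ((na - 1) * stats::var(scores_a) +
            (nb - 1) * stats::var(scores_b)) / (na + nb - 2)
    if (sp2 == 0)
        return(.assocRow("mean_diff", diff, diff, diff,
                         if (diff == 0) 1 else 0, na + nb))
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    tt <- diff / se
    df <- na + nb - 2
    p <- 2 * stats::pt(-abs(tt), df)
    half <- stats::qt(0.975, df) * se
    .assocRow("mean_diff", diff, diff - half, diff + half, p, na + nb)
}

## shared guts: binomial GLM with Wald inference on the exposure term
.logisticFit <- function(outcome, exposure, covariate = NULL) {
    dat <- data.frame(y = outcome, x = exposure)
    form <- y ~ x
    covs <- ""
    if (!is.null(covariate)) {
        dat$z <- covariate
        form <- y ~ x + z
        covs <- "disease_duration"
    }
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    if (length(unique(dat$y)) < 2)
        stop("outcome has a single level after complete-case filtering")
    if (length(unique(dat$x)) < 2)
        stop("exposure has a single level after complete-case filtering")
    fit <- suppressWarnings(
        stats::glm(form, data = dat, family = stats::binomial()))
    sm <- summary(fit)$coefficients
    b <- sm["x", "Estimate"]; se <- sm["x", "Std. Error"]
    if (!is.finite(b) || !is.finite(se) || abs(b) > 15 || se > 100)
        stop("perfect separation: the logistic fit did not converge to a ",
             "finite exposure effect; consider an exact or penalized model")
    p <- 2 * stats::pnorm(-abs(b / se))
    .assocRow("OR", exp(b), exp(b - 1.96 * se), exp(b + 1.96 * se), p,
              nrow(dat), covs)
}

#' Duration-adjusted logistic association
#'
#' Maximum-likelihood logistic regression of a binary outcome on a binary
#' exposure (e.g. the high-PRS quartile indicator), optionally adjusted for
#' years of disease duration. The reported estimate is the exposure odds
#' ratio with Wald 95% CI and p-value, on complete cases. Perfect separation
#' is an error rather than a silently absurd estimate.
#'
#' @param outcome Binary (0/1) vector.
#' @param exposure Binary (0/1 or logical) vector, or a `"high"`/`"low"`
#'   character vector.
#' @param covariate Optional numeric covariate (disease duration, years).
#' @return One-row `data.frame` (`effect_type = "OR"`).
#' @export
logisticAssoc <- function(outcome, exposure, covariate = NULL) {
    if (is.character(exposure)) exposure <- as.integer(exposure == "high")
    .logisticFit(as.integer(outcome), as.numeric(exposure), covariate)
}

#' Stratified logistic associations
#'
#' Runs [logisticAssoc()] separately inside each stratum (no pooling, no
#' interaction term). A stratum whose fit is impossible (single outcome or
#' exposure level, perfect separation) is reported as not estimable instead
#' of aborting the other strata.
#'
#' @inheritParams logisticAssoc
#' @param strata Character vector of stratum labels (e.g. from
#'   [hlaGroupAssign()]); `NA` strata are dropped.
#' @return `data.frame` with one row per stratum (column `stratum` first).
#' @export
stratifiedAssoc <- function(outcome, exposure, covariate = NULL, strata) {
    if (is.character(exposure)) exposure <- as.integer(exposure == "high")
    lev <- sort(unique(strata[!is.na(strata)]))
    out <- lapply(lev, function(s) {
        idx <- !is.na(strata) & strata == s
        row <- tryCatch(
            logisticAssoc(outcome[idx], exposure[idx],
                          if (is.null(covariate)) NULL else covariate[idx]),
            error = function(e) .assocRow(
                "OR", NA_real_, NA_real_, NA_real_, NA_real_,
                sum(idx), estimable = FALSE, note = conditionMessage(e)))
        cbind(stratum = s, row, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Age-adjusted Cox proportional-hazards association
#'
#' Partial-likelihood Cox fit (Breslow tie handling) of time-to-event on a
#' binary exposure, optionally adjusted for age at disease onset; reports
#' the exposure hazard ratio with Wald 95% CI and p-value.
#'
#' @param time Follow-up times (years, non-negative).
#' @param event Event indicator (1 = event, 0 = censored).
#' @param exposure Binary exposure vector.
#' @param covariate Optional numeric covariate (age at onset, years).
#' @return One-row `data.frame` (`effect_type = "HR"`).
#' @export
coxAssoc <- function(time, event, exposure, covariate = NULL) {
    if (is.character(exposure)) exposure <- as.integer(exposure == "high")
    dat <- data.frame(time = time, event = as.integer(event),
                      x = as.numeric(exposure))
    form <- survival::Surv(time, event) ~ x
    covs <- ""
    if (!is.null(covariate)) {
        dat$z <- covariate
        form <- survival::Surv(time, event) ~ x + z
        covs <- "age_at_onset"
    }
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    if (sum(dat$event) == 0) stop("no events observed")
    if (any(tapply(dat$event, dat$x, sum) == 0))
        stop("an exposure group has no events")
    fit <- survival::coxph(form, data = dat, ties = "breslow")
    sm <- summary(fit)$coefficients
    b <- sm["x", "coef"]; se <- sm["x", "se(coef)"]
    if (!is.finite(b) || !is.finite(se) || abs(b) > 15)
        stop("degenerate Cox fit for the exposure effect")
    p <- 2 * stats::pnorm(-abs(b / se))
    .assocRow("HR", exp(b), exp(b - 1.96 * se), exp(b + 1.96 * se), p,
              nrow(dat), covs)
}

#' Default association battery
#'
#' The packaged configuration mirrors the study's reported comparisons: each
#' ACR criterion, the autoantibodies and low complement against the high
#' B cell PRS indicator (duration-adjusted logistic, whole cohort); renal
#' disorder against the high B cell activation PRS; HLA-stratified analyses
#' of immunological disorder, anti-dsDNA and low complement; and the
#' nephritis-vs-dsDNA logistic and Cox models.
#'
#' @return `data.frame` with columns `outcome`, `pathway`, `exposure`,
#'   `stratum`, `model`.
#' @export
defaultBattery <- function() {
    acr <- c("malar_rash", "discoid_rash", "photosensitivity", "oral_ulcer",
             "arthritis", "serositis", "renal", "neurological",
             "haematological", "immunological", "ana")
    extra <- c("dsdna", "sm", "cardiolipin", "lupus_anticoagulant",
               "b2gp1", "ssa", "ssb", "low_complement")
    rows <- rbind(
        data.frame(outcome = c(acr, extra), pathway = "bcell",
                   exposure = "prs_high", stratum = "overall",
                   model = "logistic", stringsAsFactors = FALSE),
        data.frame(outcome = "renal", pathway = "bcell_activation",
                   exposure = "prs_high", stratum = "overall",
                   model = "logistic", stringsAsFactors = FALSE),
        expand.grid(outcome = c("immunological", "dsdna", "low_complement"),
                    pathway = "bcell", exposure = "prs_high",
                    stratum = c("neg_neg", "single_pos", "double_pos"),
                    model = "logistic", stringsAsFactors = FALSE),
        data.frame(outcome = "ln", pathway = "none", exposure = "dsdna",
                   stratum = "overall", model = c("logistic", "cox"),
                   stringsAsFactors = FALSE))
    rownames(rows) <- NULL
    rows
}

#' Run an association battery
#'
#' Executes one association per configured row: logistic models are adjusted
#' for disease duration, Cox models for age at onset; HLA-stratified rows
#' restrict to the requested stratum; `ln` rows use anti-dsDNA status as the
#' exposure. Analyses run on patients only (`is_case == 1`); nominal
#' p-values are reported without multiplicity adjustment, and the number of
#' tests run is attached as attribute `"n_tests"`.
#'
#' @param pheno Phenotype `data.frame` (see [readPhenotypes()]).
#' @param assignments Quartile assignments: `data.frame` with `sample_id`
#'   and one `group_<pathway>` column per pathway (see [writeScores()] /
#'   [classifyQuartiles()]).
#' @param battery Configuration `data.frame` as from [defaultBattery()].
#' @return `data.frame`: one row per battery row with `outcome`, `pathway`,
#'   `stratum`, `model`, `n`, `estimate`, `ci_lo`, `ci_hi`, `p`,
#'   `estimable`, `note`.
#' @export
runAnalysisBattery <- function(pheno, assignments,
                               battery = defaultBattery()) {
    pat <- pheno[pheno$is_case == 1, , drop = FALSE]
    pat <- merge(pat, assignments, by = "sample_id", sort = FALSE)
    hla <- suppressMessages(hlaGroupAssign(pat))
    strata <- hla$group[match(pat$sample_id, hla$sample_id)]
    out <- vector("list", nrow(battery))
    for (i in seq_len(nrow(battery))) {
        b <- battery[i, ]
        if (!b$outcome %in% c(colnames(pat), "ln"))
            stop("unknown outcome '", b$outcome, "'")
        row <- tryCatch({
            if (b$model == "cox") {
                coxAssoc(pat$time_to_ln, pat$ln_event, pat[[b$exposure]],
                         pat$age_at_onset)
            } else {
                y <- if (b$outcome == "ln") pat$renal else pat[[b$outcome]]
                x <- if (b$exposure == "prs_high")
                    as.integer(pat[[paste0("group_", b$pathway)]] == "high")
                else pat[[b$exposure]]
                keep <- if (b$stratum == "overall") rep(TRUE, nrow(pat))
                        else !is.na(strata) & strata == b$stratum
                logisticAssoc(y[keep], x[keep], pat$disease_duration[keep])
            }
        }, error = function(e) .assocRow(
            if (b$model == "cox") "HR" else "OR",
            NA_real_, NA_real_, NA_real_, NA_real_, 0L,
            estimable = FALSE, note = conditionMessage(e)))
        out[[i]] <- cbind(b[, c("outcome", "pathway", "stratum", "model")],
                          row, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "n_tests") <- nrow(res)
    res
}
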