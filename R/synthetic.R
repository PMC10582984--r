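#' Control-population risk-allele frequency implied by a per-allele OR
#'
#' The packaged weight table reports risk-allele frequencies in the patient
#' cohort; the corresponding control frequency is implied by the per-allele
#' odds ratio through `odds(case) / odds(control) = OR`, i.e.
#' `p_control = raf / (raf + (1 - raf) * OR)`.
#'
#' @param raf_case Risk-allele frequency among cases, in (0, 1).
#' @param or_allele Per-allele odds ratio (> 0).
#' @return Control-population frequency in (0, 1).
#' @examples
#' deriveControlFreq(0.06, 2.03)   # 0.0305
#' @export
deriveControlFreq <- function(raf_case, or_allele) {
    stopifnot(all(raf_case > 0 & raf_case < 1), all(or_allele > 0))
    raf_case / (raf_case + (1 - raf_case) * or_allele)
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Independent loci with dosage ~ Binomial(2, p). When a [WeightTable-class]
#' is supplied the counted allele b is the (oriented) risk allele, so
#' dosages feed directly into [computePRS()]; variant coordinates are
#' synthetic placeholders.
#'
#' @param freqs Named vector of counted-allele frequencies in (0, 1).
#' @param n Number of samples.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param table Optional [WeightTable-class] supplying allele labels.
#' @param prefix Sample-ID prefix.
#' @param sex Per-sample sex annotation (default `"female"`, the study
#'   population).
#' @return A [GenotypeMatrix-class].
#' @export
simulateGenotypes <- function(freqs, n, seed = NULL, table = NULL,
                              prefix = "S", sex = "female") {
    stopifnot(all(freqs > 0 & freqs < 1), n >= 1)
    if (!is.null(seed)) set.seed(seed)
    m <- length(freqs)
    if (is.null(names(freqs)))
        names(freqs) <- paste0("snp", seq_len(m))
    dos <- matrix(stats::rbinom(m * n, 2L, rep(freqs, times = n)), m, n)
    if (!is.null(table)) {
        v <- as.data.frame(variantTable(orientWeights(table)))
        v <- v[match(names(freqs), v$snp_id), ]
        variants <- data.frame(snp_id = names(freqs), chrom = "1",
                               pos = seq_len(m) * 1000L,
                               allele_a = v$other_allele,
                               allele_b = v$risk_allele, is_x = FALSE,
                               stringsAsFactors = FALSE)
    } else {
        variants <- data.frame(snp_id = names(freqs), chrom = "1",
                               pos = seq_len(m) * 1000L,
                               allele_a = "A", allele_b = "G", is_x = FALSE,
                               stringsAsFactors = FALSE)
    }
    GenotypeMatrix(dos, variants,
                   sample_ids = sprintf("%s%04d", prefix, seq_len(n)),
                   sex = sex)
}

#' Calibrate a logistic intercept to a target marginal prevalence
#'
#' Bisection solve of `mean(plogis(alpha + eta)) = target` to an absolute
#' prevalence tolerance of 1e-6 (at most 200 iterations).
#'
#' @param linear_predictors Numeric vector of per-individual linear
#'   predictors (without intercept).
#' @param target_prevalence Target marginal prevalence in (0, 1).
#' @return The intercept `alpha`.
#' @examples
#' calibrateIntercept(rep(0, 10), 0.5)   # 0
#' @export
calibrateIntercept <- function(linear_predictors, target_prevalence) {
    stopifnot(target_prevalence > 0, target_prevalence < 1)
    f <- function(a) mean(stats::plogis(a + linear_predictors)) -
        target_prevalence
    lo <- -40; hi <- 40
    if (f(lo) > 0 || f(hi) < 0) stop("target prevalence unreachable")
    for (i in seq_len(200)) {
        mid <- (lo + hi) / 2
        if (abs(f(mid)) < 1e-6) return(mid)
        if (f(mid) < 0) lo <- mid else hi <- mid
    }
    stop("intercept calibration did not converge in 200 iterations")
}

#' Packaged phenotype prevalences
#'
#' Marginal prevalences of the clinical outcomes among patients, as observed
#' in the study cohort (fractions of n = 1248).
#'
#' @return Named numeric vector.
#' @export
defaultPrevalences <- function() {
    c(malar_rash = 0.567, discoid_rash = 0.220, photosensitivity = 0.692,
      oral_ulcer = 0.280, arthritis = 0.774, serositis = 0.375,
      renal = 0.297, neurological = 0.093, haematological = 0.642,
      immunological = 0.695, ana = 0.983,
      dsdna = 0.626, sm = 0.115, cardiolipin = 0.325,
      lupus_anticoagulant = 0.278, b2gp1 = 0.251, ssa = 0.346, ssb = 0.213,
      low_complement = 0.554)
}

#' Packaged effect specification
#'
#' True effect sizes used by the generator, taken from the study's reported
#' associations: quartile (high vs low PRS) odds ratios per outcome, the
#' HLA-stratum-specific odds ratios, and the nephritis-vs-dsDNA odds and
#' hazard ratios. `exposure` names the generating indicator
#' (`bcell_high`, `activation_high` or `dsdna`).
#'
#' @return `data.frame` with columns `outcome`, `exposure`, `stratum`,
#'   `effect_type`, `effect`.
#' @export
defaultEffectSpec <- function() {
    E <- function(outcome, exposure, stratum, effect_type, effect)
        data.frame(outcome = outcome, exposure = exposure,
                   stratum = stratum, effect_type = effect_type,
                   effect = effect, stringsAsFactors = FALSE)
    rbind(
        E("sle", "bcell_high", "overall", "OR", 1.64),
        E("sle", "activation_high", "overall", "OR", 1.58),
        E(c("malar_rash", "discoid_rash", "photosensitivity", "oral_ulcer",
            "arthritis", "serositis", "renal", "neurological",
            "haematological", "immunological", "ana", "dsdna", "sm",
            "cardiolipin", "lupus_anticoagulant", "b2gp1", "ssa", "ssb",
            "low_complement"),
          "bcell_high", "overall", "OR",
          c(0.97, 0.77, 0.93, 0.94, 0.99, 1.19, 1.20, 1.16, 1.05, 1.44,
            1.04, 1.47, 0.91, 1.01, 1.08, 1.20, 1.17, 1.09, 1.21)),
        E("renal", "activation_high", "overall", "OR", 1.32),
        E("dsdna", "bcell_high", c("neg_neg", "single_pos", "double_pos"),
          "OR", c(0.99, 1.64, 4.47)),
        E("immunological", "bcell_high", "single_pos", "OR", 1.54),
        E("low_complement", "bcell_high", "double_pos", "OR", 3.92),
        E("ln", "dsdna", "overall", "OR", 2.80),
        E("ln", "dsdna", "overall", "HR", 2.89))
}

#' Look up one packaged effect
#'
#' @param outcome,exposure,stratum,effect_type Selector; see
#'   [defaultEffectSpec()].
#' @param spec Effect table (default the packaged one).
#' @return Scalar effect (OR or HR).
#' @export
lookupEffect <- function(outcome, exposure, stratum = "overall",
                         effect_type = "OR", spec = defaultEffectSpec()) {
    hit <- spec$outcome == outcome & spec$exposure == exposure &
        spec$stratum == stratum & spec$effect_type == effect_type
    if (sum(hit) != 1)
        stop("effect lookup (", outcome, ", ", exposure, ", ", stratum,
             ", ", effect_type, ") matched ", sum(hit), " rows")
    spec$effect[hit]
}

#' Cohort generator configuration
#'
#' Defaults encode the study conditions: 1248 female patients and 400
#' controls; the packaged 20-variant weight table; outcome prevalences and
#' effect sizes from the published tables; HLA-DRB1*03/15 stratum weights
#' proportional to the reported 354 : 656 : 143 split. Disease duration and
#' age at onset are log-normal (medians 18 and 35 years, wide spread) —
#' arbitrary but realistic shapes, since only medians and ranges were
#' published. `dur_beta` and `age_beta` are the small generating covariate
#' effects per year; the survival block is an exponential nephritis-onset
#' model with independent exponential censoring capped at `max_followup`.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param weight_table A [WeightTable-class].
#' @param prevalences Named outcome prevalences.
#' @param effect_spec Effect table (see [defaultEffectSpec()]).
#' @param hla_weights Stratum weights, normalized internally.
#' @param dur_meanlog,dur_sdlog,onset_meanlog,onset_sdlog Log-normal
#'   parameters for disease duration and age at onset (years).
#' @param dur_beta,age_beta Generating log-odds / log-hazard per year.
#' @param baseline_hazard Baseline nephritis onset rate (events/year).
#' @param censor_rate Independent censoring rate (events/year).
#' @param max_followup Administrative censoring horizon (years).
#' @return A list of class `"cohort_config"`.
#' @export
cohortConfig <- function(n_cases = 1248, n_controls = 400,
                         weight_table = loadWeightTable(),
                         prevalences = defaultPrevalences(),
                         effect_spec = defaultEffectSpec(),
                         hla_weights = c(neg_neg = 354, single_pos = 656,
                                         double_pos = 143),
                         dur_meanlog = log(18), dur_sdlog = 0.7,
                         onset_meanlog = log(35), onset_sdlog = 0.45,
                         dur_beta = 0.02, age_beta = 0.01,
                         baseline_hazard = 0.02, censor_rate = 0.04,
                         max_followup = 40) {
    stopifnot(n_cases >= 4, n_controls >= 0,
              all(prevalences > 0 & prevalences < 1),
              all(effect_spec$effect > 0), all(hla_weights >= 0))
    structure(list(
        n_cases = n_cases, n_controls = n_controls,
        weight_table = weight_table, prevalences = prevalences,
        effect_spec = effect_spec,
        hla_weights = hla_weights / sum(hla_weights),
        dur_meanlog = dur_meanlog, dur_sdlog = dur_sdlog,
        onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
        dur_beta = dur_beta, age_beta = age_beta,
        baseline_hazard = baseline_hazard, censor_rate = censor_rate,
        max_followup = max_followup), class = "cohort_config")
}

## generating exposure per outcome in the default cohort: renal is driven by
## the activation-pathway indicator, everything else by the B cell indicator
.generatingExposure <- function(outcome) {
    if (outcome == "renal") "activation_high" else "bcell_high"
}

#' Simulate patient phenotypes
#'
#' Given quartile assignments for the scored pathways, draws: the HLA
#' stratum (with consistent tag-SNP dosages), disease duration and age at
#' onset (log-normal), each binary outcome from a logistic model
#' `alpha + log(OR) * exposure + dur_beta * (duration - mean)` with the
#' intercept calibrated to the configured marginal prevalence, and the time
#' to nephritis onset from an exponential model whose log-hazard carries the
#' packaged coefficient on dsDNA status plus an age-at-onset term, with
#' independent censoring.
#'
#' @param assignments `data.frame` with `sample_id`, `group_bcell` and
#'   `group_bcell_activation` columns (`"high"`/`"low"`).
#' @param config A [cohortConfig()].
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param effect_overrides Optional named numeric vector replacing the
#'   generating odds ratio of specific outcomes (names = outcomes).
#' @return Phenotype `data.frame` (see [readPhenotypes()]).
#' @export
simulatePhenotypes <- function(assignments, config = cohortConfig(),
                               seed = NULL, effect_overrides = NULL) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(assignments)
    strat <- sample(names(config$hla_weights), n, replace = TRUE,
                    prob = config$hla_weights)
    tag1 <- ifelse(strat == "neg_neg", 0L,
            ifelse(strat == "double_pos", 1L,
                   stats::rbinom(n, 1L, 0.5)))
    tag2 <- ifelse(strat == "double_pos", 1L,
            ifelse(strat == "neg_neg", 0L, 1L - tag1))
    duration <- stats::rlnorm(n, config$dur_meanlog, config$dur_sdlog)
    onset <- stats::rlnorm(n, config$onset_meanlog, config$onset_sdlog)
    dur_c <- duration - mean(duration)
    x_bcell <- as.integer(assignments$group_bcell == "high")
    x_act <- as.integer(assignments$group_bcell_activation == "high")

    ph <- data.frame(sample_id = assignments$sample_id, is_case = 1L,
                     disease_duration = duration, age_at_onset = onset,
                     stringsAsFactors = FALSE)
    ## renal is generated last: its model adds the nephritis-vs-dsDNA
    ## log-odds on top of the activation-PRS indicator effect
    outcomes <- names(config$prevalences)
    outcomes <- c(setdiff(outcomes, "renal"),
                  intersect("renal", outcomes))
    for (outc in outcomes) {
        expo <- .generatingExposure(outc)
        or <- if (!is.null(effect_overrides) &&
                  outc %in% names(effect_overrides))
            effect_overrides[[outc]]
        else lookupEffect(outc, expo, "overall", "OR", config$effect_spec)
        x <- if (expo == "activation_high") x_act else x_bcell
        eta <- log(or) * x + config$dur_beta * dur_c
        if (outc == "renal" && !is.null(ph$dsdna))
            eta <- eta + log(lookupEffect("ln", "dsdna", "overall", "OR",
                                          config$effect_spec)) * ph$dsdna
        alpha <- calibrateIntercept(eta, config$prevalences[[outc]])
        ph[[outc]] <- stats::rbinom(n, 1L, stats::plogis(alpha + eta))
    }
    ## nephritis onset: exponential PH on dsDNA status, age-adjusted
    hr <- lookupEffect("ln", "dsdna", "overall", "HR", config$effect_spec)
    rate <- config$baseline_hazard *
        exp(log(hr) * ph$dsdna + config$age_beta * (onset - mean(onset)))
    t_event <- stats::rexp(n, rate)
    t_cens <- pmin(stats::rexp(n, config$censor_rate), config$max_followup)
    ph$time_to_ln <- pmin(t_event, t_cens)
    ph$ln_event <- as.integer(t_event <= t_cens)
    ph$tag_rs1269852 <- tag1
    ph$tag_rs3135388 <- tag2
    ph$hla_stratum <- strat
    ph
}

#' Generate a full synthetic case-control cohort
#'
#' Patients receive Hardy-Weinberg genotypes at the oriented patient-cohort
#' risk-allele frequencies; controls at the control frequencies implied by
#' the per-allele odds ratios ([deriveControlFreq()]), so the case mean PRS
#' exceeds the control mean whenever any OR is above 1. Pathway scores and
#' within-patient quartile groups drive the phenotype generator; controls
#' (blood donors) carry genotypes only, with clinical columns `NA`. The
#' complete generating parameter set is attached as the `truth` element.
#'
#' @param config A [cohortConfig()].
#' @param seed Integer seed; generation is reproducible given the seed.
#' @return List of class `"synthetic_cohort"`: `genotypes`
#'   ([GenotypeMatrix-class]), `phenotypes` (`data.frame`), `profiles`,
#'   `assignments`, `truth`.
#' @export
generateCohort <- function(config = cohortConfig(), seed = 1) {
    set.seed(seed)
    wt <- orientWeights(config$weight_table)
    v <- as.data.frame(variantTable(wt))
    raf <- stats::setNames(v$raf, v$snp_id)
    ctl <- deriveControlFreq(raf, v$or_sle)
    g_case <- simulateGenotypes(raf, config$n_cases, seed = NULL,
                                table = wt, prefix = "CASE")
    geno <- g_case
    if (config$n_controls > 0) {
        g_ctl <- simulateGenotypes(ctl, config$n_controls, seed = NULL,
                                   table = wt, prefix = "CTRL")
        geno <- cbind(g_case, g_ctl)
    }
    profiles <- computeProfiles(geno, wt)
    is_case <- grepl("^CASE", profiles$sample_id)

    assignments <- profiles["sample_id"]
    for (p in pathwayNames(wt)) {
        qa <- classifyQuartiles(
            data.frame(sample_id = profiles$sample_id[is_case],
                       score = profiles[[paste0("prs_", p)]][is_case]), p)
        assignments[[paste0("group_", p)]] <-
            qa$group[match(assignments$sample_id, qa$sample_id)]
    }
    ph_case <- simulatePhenotypes(assignments[is_case, , drop = FALSE],
                                  config, seed = NULL)
    if (config$n_controls > 0) {
        ph_ctl <- ph_case[0, ][seq_len(config$n_controls), ]
        ph_ctl$sample_id <- profiles$sample_id[!is_case]
        ph_ctl$is_case <- 0L
        rownames(ph_ctl) <- NULL
        pheno <- rbind(ph_case, ph_ctl)
    } else pheno <- ph_case
    truth <- c(config[setdiff(names(config), "weight_table")],
               list(seed = seed, control_freqs = ctl))
    structure(list(genotypes = geno, phenotypes = pheno,
                   profiles = profiles, assignments = assignments,
                   truth = truth),
              class = "synthetic_cohort")
}

#' Indicator-mode case-status generator
#'
#' Generates a pool of `n_cases + n_controls` genotyped individuals at the
#' patient-cohort allele frequencies, scores them, forms the pool-wide
#' quartile indicator for the requested pathway, and draws SLE case status
#' from a logistic model on that indicator using the packaged odds ratio,
#' with the intercept calibrated so the expected case fraction matches the
#' configured cohort composition. This is the generating model under which
#' the case-prevalence quartile association is exactly recoverable.
#'
#' @param config A [cohortConfig()].
#' @param seed Integer seed.
#' @param pathway `"bcell"` or `"bcell_activation"`.
#' @return `data.frame` with `sample_id`, `score`, `high` (0/1), `is_case`.
#' @export
simulateCaseStatus <- function(config = cohortConfig(), seed = 1,
                               pathway = "bcell") {
    set.seed(seed)
    wt <- orientWeights(config$weight_table)
    v <- as.data.frame(variantTable(wt))
    n <- config$n_cases + config$n_controls
    geno <- simulateGenotypes(stats::setNames(v$raf, v$snp_id), n,
                              seed = NULL, table = wt)
    prs <- computePRS(geno, wt, pathway)
    qa <- classifyQuartiles(prs, pathway)
    high <- as.integer(qa$group == "high")
    expo <- if (pathway == "bcell") "bcell_high" else "activation_high"
    or <- lookupEffect("sle", expo, "overall", "OR", config$effect_spec)
    eta <- log(or) * high
    alpha <- calibrateIntercept(eta, config$n_cases / n)
    data.frame(sample_id = prs$sample_id, score = prs$score, high = high,
               is_case = stats::rbinom(n, 1L, stats::plogis(alpha + eta)),
               stringsAsFactors = FALSE)
}

#' Parameter-recovery harness for the packaged effects
#'
#' Regenerates data under one packaged generating model and re-estimates the
#' effect with the corresponding association routine, once per replicate
#' seed. Designs:
#' \describe{
#'   \item{`sle`}{[simulateCaseStatus()] pool; unadjusted logistic of case
#'     status on the high-B cell-PRS indicator.}
#'   \item{`dsdna`, `renal_activation`, `low_complement`}{patient cohort of
#'     `config$n_cases`; duration-adjusted logistic on the generating
#'     indicator.}
#'   \item{`dsdna_double_pos`, `low_complement_double_pos`}{single HLA
#'     stratum of the published size (n = 143), fitted through
#'     [stratifiedAssoc()]; non-estimable replicates are dropped.}
#'   \item{`ln_dsdna`}{patient cohort; duration-adjusted logistic of
#'     nephritis on dsDNA status.}
#'   \item{`ln_hr`}{patient cohort; age-adjusted Cox model of nephritis
#'     onset time on dsDNA status.}
#' }
#'
#' @param target One of the designs above.
#' @param seeds Integer vector of replicate seeds.
#' @param config A [cohortConfig()].
#' @param stratum_n Stratum size for the stratum designs (default 143).
#' @return `data.frame` with one row per estimable replicate: `seed`,
#'   `log_effect`, `se`; the generating log-effect is attached as attribute
#'   `"truth"`.
#' @export
recoverEffect <- function(target = c("sle", "dsdna", "renal_activation",
                                     "low_complement", "dsdna_double_pos",
                                     "low_complement_double_pos",
                                     "ln_dsdna", "ln_hr"),
                          seeds = 1:200, config = cohortConfig(),
                          stratum_n = 143) {
    target <- match.arg(target)
    wt <- orientWeights(config$weight_table)
    v <- as.data.frame(variantTable(wt))
    raf <- stats::setNames(v$raf, v$snp_id)
    spec <- config$effect_spec

    patientRep <- function(seed, n, outcome, expo, or) {
        set.seed(seed)
        geno <- simulateGenotypes(raf, n, seed = NULL, table = wt)
        pathway <- if (expo == "activation_high") "bcell_activation"
                   else "bcell"
        prs <- computePRS(geno, wt, pathway)
        x <- as.integer(classifyQuartiles(prs, pathway)$group == "high")
        duration <- stats::rlnorm(n, config$dur_meanlog, config$dur_sdlog)
        eta <- log(or) * x + config$dur_beta * (duration - mean(duration))
        alpha <- calibrateIntercept(eta, config$prevalences[[outcome]])
        y <- stats::rbinom(n, 1L, stats::plogis(alpha + eta))
        list(y = y, x = x, duration = duration)
    }
    one <- function(seed) {
        switch(target,
        sle = {
            d <- simulateCaseStatus(config, seed)
            logisticAssoc(d$is_case, d$high)
        },
        dsdna = {
            or <- lookupEffect("dsdna", "bcell_high", spec = spec)
            d <- patientRep(seed, config$n_cases, "dsdna", "bcell_high", or)
            logisticAssoc(d$y, d$x, d$duration)
        },
        renal_activation = {
            or <- lookupEffect("renal", "activation_high", spec = spec)
            d <- patientRep(seed, config$n_cases, "renal",
                            "activation_high", or)
            logisticAssoc(d$y, d$x, d$duration)
        },
        low_complement = {
            or <- lookupEffect("low_complement", "bcell_high", spec = spec)
            d <- patientRep(seed, config$n_cases, "low_complement",
                            "bcell_high", or)
            logisticAssoc(d$y, d$x, d$duration)
        },
        dsdna_double_pos = {
            or <- lookupEffect("dsdna", "bcell_high", "double_pos",
                               spec = spec)
            d <- patientRep(seed, stratum_n, "dsdna", "bcell_high", or)
            r <- stratifiedAssoc(d$y, d$x, d$duration,
                                 rep("double_pos", stratum_n))
            if (!r$estimable[1]) stop(r$note[1])
            r[1, -1]
        },
        low_complement_double_pos = {
            or <- lookupEffect("low_complement", "bcell_high", "double_pos",
                               spec = spec)
            d <- patientRep(seed, stratum_n, "low_complement", "bcell_high",
                            or)
            r <- stratifiedAssoc(d$y, d$x, d$duration,
                                 rep("double_pos", stratum_n))
            if (!r$estimable[1]) stop(r$note[1])
            r[1, -1]
        },
        ln_dsdna = {
            set.seed(seed)
            n <- config$n_cases
            or <- lookupEffect("ln", "dsdna", spec = spec)
            dsdna <- stats::rbinom(n, 1L, config$prevalences[["dsdna"]])
            duration <- stats::rlnorm(n, config$dur_meanlog,
                                      config$dur_sdlog)
            eta <- log(or) * dsdna +
                config$dur_beta * (duration - mean(duration))
            alpha <- calibrateIntercept(eta, config$prevalences[["renal"]])
            y <- stats::rbinom(n, 1L, stats::plogis(alpha + eta))
            logisticAssoc(y, dsdna, duration)
        },
        ln_hr = {
            set.seed(seed)
            n <- config$n_cases
            hr <- lookupEffect("ln", "dsdna", effect_type = "HR",
                               spec = spec)
            dsdna <- stats::rbinom(n, 1L, config$prevalences[["dsdna"]])
            onset <- stats::rlnorm(n, config$onset_meanlog,
                                   config$onset_sdlog)
            rate <- config$baseline_hazard *
                exp(log(hr) * dsdna + config$age_beta * (onset - mean(onset)))
            t_event <- stats::rexp(n, rate)
            t_cens <- pmin(stats::rexp(n, config$censor_rate),
                           config$max_followup)
            coxAssoc(pmin(t_event, t_cens),
                     as.integer(t_event <= t_cens), dsdna, onset)
        })
    }
    rows <- lapply(seeds, function(s) {
        r <- tryCatch(one(s), error = function(e) NULL)
        if (is.null(r)) return(NULL)
        se <- (log(r$ci_hi) - log(r$ci_lo)) / (2 * 1.96)
        data.frame(seed = s, log_effect = log(r$estimate), se = se)
    })
    out <- do.call(rbind, rows)
    truth <- switch(target,
        sle = log(lookupEffect("sle", "bcell_high", spec = spec)),
        dsdna = log(lookupEffect("dsdna", "bcell_high", spec = spec)),
        renal_activation = log(lookupEffect("renal", "activation_high",
                                            spec = spec)),
        low_complement = log(lookupEffect("low_complement", "bcell_high",
                                          spec = spec)),
        dsdna_double_pos = log(lookupEffect("dsdna", "bcell_high",
                                            "double_pos", spec = spec)),
        low_complement_double_pos = log(lookupEffect(
            "low_complement", "bcell_high", "double_pos", spec = spec)),
        ln_dsdna = log(lookupEffect("ln", "dsdna", spec = spec)),
        ln_hr = log(lookupEffect("ln", "dsdna", effect_type = "HR",
                                 spec = spec)))
    attr(out, "truth") <- truth
    out
}

#' Add LD-correlated partner variants (test helper for pruning)
#'
#' For each requested variant, appends a partner whose dosage copies the
#' original allele-wise with probability `r` per allele (so the expected
#' genotype correlation is about `r`), giving a controlled way to create
#' linkage for [ldPrune()] exercises.
#'
#' @param g A [GenotypeMatrix-class].
#' @param snp_ids Variants to mirror.
#' @param r Per-allele copy fidelity in (0, 1].
#' @param seed Integer seed.
#' @return A [GenotypeMatrix-class] with the partner variants appended
#'   (IDs suffixed `"_ld"`).
#' @export
addCorrelatedVariants <- function(g, snp_ids, r = 0.95, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    d <- dosages(g)
    rd <- as.data.frame(rowData(g))
    newd <- list(); newv <- list()
    for (s in snp_ids) {
        x <- d[s, ]
        p <- mean(x, na.rm = TRUE) / 2
        flip <- function(a) ifelse(stats::runif(length(a)) < r, a,
                                   stats::rbinom(length(a), 1L, p))
        a1 <- flip(as.integer(x >= 1))
        a2 <- flip(as.integer(x == 2))
        newd[[s]] <- a1 + a2
        nv <- rd[s, ]; nv$snp_id <- paste0(s, "_ld")
        nv$pos <- nv$pos + 1L
        newv[[s]] <- nv
    }
    GenotypeMatrix(rbind(d, do.call(rbind, newd)),
                   rbind(rd, do.call(rbind, newv)),
                   sample_ids = colnames(d),
                   sex = unname(annotatedSex(g)))
}
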