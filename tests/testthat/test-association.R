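test_that("HLA tag-SNP strata follow dominant coding", {
    ph <- data.frame(sample_id = c("a", "b", "c", "d", "e"),
                     tag_rs1269852 = c(0, 2, 1, 0, NA),
                     tag_rs3135388 = c(0, 1, 0, 1, 1))
    expect_message(grp <- hlaGroupAssign(ph), "unassigned")
    expect_identical(grp$group[1:4],
                     c("neg_neg", "double_pos", "single_pos", "single_pos"))
    expect_true(is.na(grp$group[5]))
    expect_error(hlaGroupAssign(data.frame(sample_id = "a")), "tag-SNP")
})

test_that("pooled-variance t-test matches closed-form computation", {
    r <- compareMeansTTest(c(1, 2, 3), c(4, 5, 6))
    expect_equal(r$estimate, -3)
    ## t = -3/sqrt((2/3)) = -3.6742, df = 4
    expect_equal(r$p, 0.021311641128757, tolerance = 1e-9)
    expect_identical(r$n, 6L)
    ## identical constant groups: p = 1 by convention
    r0 <- compareMeansTTest(c(2, 2), c(2, 2))
    expect_identical(r0$p, 1)
    expect_identical(r0$estimate, 0)
    expect_error(compareMeansTTest(1, c(1, 2)), "at least 2")
    ## under the null, p is approximately uniform (KS over replicates)
    set.seed(31)
    ps <- replicate(400, compareMeansTTest(rnorm(40), rnorm(40))$p)
    expect_gt(ks.test(ps, "punif")$p.value, 0.001)
})

test_that("logistic association equals the crude 2x2 odds ratio", {
    y <- rep(c(1, 0, 1, 0), c(30, 70, 10, 90))
    x <- rep(c(1, 0), c(100, 100))
    r <- logisticAssoc(y, x)
    expect_equal(r$estimate, 30 * 90 / (70 * 10), tolerance = 1e-6)
    expect_identical(r$effect_type, "OR")
    expect_identical(r$n, 200L)
    expect_true(r$ci_lo <= r$estimate && r$estimate <= r$ci_hi)
})

test_that("logistic association is null-calibrated and guards separation", {
    set.seed(32)
    n <- 1e4
    y <- rbinom(n, 1, 0.5)
    x <- rbinom(n, 1, 0.25)
    r <- logisticAssoc(y, x, covariate = runif(n, 0, 30))
    expect_lt(abs(log(r$estimate)), 0.1)
    ## perfect separation errors instead of reporting nonsense
    expect_error(logisticAssoc(c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 1, 1, 1)),
                 "separation")
    expect_error(logisticAssoc(rep(1, 10), rbinom(10, 1, .5)),
                 "single level")
})

test_that("stratified fits match per-stratum fits and tolerate failures", {
    set.seed(33)
    n <- 900
    strata <- sample(c("neg_neg", "single_pos", "double_pos"), n, TRUE)
    x <- rbinom(n, 1, 0.25)
    dur <- rlnorm(n, log(15), 0.5)
    eta <- log(1.6) * x * (strata == "single_pos") +
           log(4) * x * (strata == "double_pos")
    y <- rbinom(n, 1, plogis(-0.3 + eta))
    r <- stratifiedAssoc(y, x, dur, strata)
    expect_identical(nrow(r), 3L)
    for (s in unique(strata)) {
        idx <- strata == s
        direct <- logisticAssoc(y[idx], x[idx], dur[idx])
        expect_equal(r$estimate[r$stratum == s], direct$estimate,
                     tolerance = 1e-10)
    }
    ## invariance to stratum ordering
    ord <- sample(n)
    r2 <- stratifiedAssoc(y[ord], x[ord], dur[ord], strata[ord])
    expect_equal(r2$estimate, r$estimate, tolerance = 1e-10)
    ## a single stratum equals the plain fit
    r1 <- stratifiedAssoc(y, x, dur, rep("all", n))
    expect_equal(r1$estimate, logisticAssoc(y, x, dur)$estimate)
    ## zero-event stratum flagged, others unaffected
    y2 <- y; y2[strata == "neg_neg"] <- 0
    r3 <- stratifiedAssoc(y2, x, dur, strata)
    expect_false(r3$estimable[r3$stratum == "neg_neg"])
    expect_true(all(r3$estimable[r3$stratum != "neg_neg"]))
})

test_that("Cox association is null-calibrated and directional", {
    set.seed(34)
    n <- 5000
    x <- rbinom(n, 1, 0.5)
    t_ev <- rexp(n, 0.1)
    cens <- rexp(n, 0.05)
    r <- coxAssoc(pmin(t_ev, cens), as.integer(t_ev <= cens), x)
    expect_lt(abs(log(r$estimate)), 0.1)
    expect_identical(r$effect_type, "HR")
    ## exposed hazard twice the unexposed: HR > 1, finite
    set.seed(35)
    x2 <- rep(c(1, 0), each = 150)
    t2 <- rexp(300, 0.05 * 2^x2)
    r2 <- coxAssoc(t2, rep(1L, 300), x2)
    expect_gt(r2$estimate, 1)
    expect_true(is.finite(r2$estimate))
    ## complete separation of event times degenerates loudly, not silently
    expect_error(suppressWarnings(
        coxAssoc(c(1, 1.1, 1.2, 2, 2.1, 2.2), rep(1L, 6),
                 c(1, 1, 1, 0, 0, 0))), "degenerate")
    expect_error(coxAssoc(c(1, 2), c(0, 0), c(0, 1)), "no events")
})

test_that("the analysis battery mirrors the configured comparisons", {
    cfg <- cohortConfig(n_cases = 400, n_controls = 0)
    coh <- generateCohort(cfg, seed = 41)
    res <- runAnalysisBattery(coh$phenotypes, coh$assignments)
    bat <- defaultBattery()
    expect_identical(nrow(res), nrow(bat))
    expect_identical(attr(res, "n_tests"), nrow(bat))
    ## Table-3-style rows present
    expect_true(all(c("dsdna", "renal", "low_complement", "immunological")
                    %in% res$outcome))
    ## HLA-stratified rows for the stratified outcomes
    strat <- res[res$stratum != "overall", ]
    expect_setequal(unique(strat$stratum),
                    c("neg_neg", "single_pos", "double_pos"))
    ## nephritis rows: logistic OR + Cox HR on dsDNA exposure
    ln <- res[res$outcome == "ln", ]
    expect_setequal(ln$model, c("logistic", "cox"))
    ## unknown outcome errors
    bad <- rbind(bat, data.frame(outcome = "nonesuch", pathway = "bcell",
                                 exposure = "prs_high", stratum = "overall",
                                 model = "logistic"))
    expect_error(runAnalysisBattery(coh$phenotypes, coh$assignments, bad),
                 "unknown outcome")
})

test_that("tiny cohorts degrade to not-estimable rows, not crashes", {
    cfg <- cohortConfig(n_cases = 12, n_controls = 0)
    coh <- generateCohort(cfg, seed = 42)
    res <- runAnalysisBattery(coh$phenotypes, coh$assignments)
    expect_identical(nrow(res), nrow(defaultBattery()))
    expect_true(any(!res$estimable))
    expect_true(all(nzchar(res$note[!res$estimable])))
})
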