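test_that("sample call-rate filter is strict at the threshold", {
    set.seed(1)
    dos <- matrix(rbinom(100 * 4, 2, 0.3), 100, 4,
                  dimnames = list(paste0("v", 1:100), paste0("s", 1:4)))
    dos[1:6, 1] <- NA            # 94/100
    dos[1:5, 2] <- NA            # 95/100 (boundary, kept)
    dos[, 4] <- NA               # fully missing
    rep <- sampleCallRateFilter(gmFromDosage(dos))
    expect_identical(rep$excluded, c(TRUE, FALSE, FALSE, TRUE))
    expect_equal(rep$call_rate, c(0.94, 0.95, 1, 0))
    expect_identical(rep$reasons[1], "low_call_rate")
})

test_that("variant filters apply call-rate, MAF and HWE rules", {
    ## (AA=90, AB=9, BB=1): maf 0.055, HWE-fine, full call rate
    d1 <- rep(c(0L, 1L, 2L), c(90, 9, 1))
    d2 <- rep(0L, 100)                      # monomorphic
    d3 <- c(rep(NA, 3), rbinom(97, 2, 0.4)) # 97% call rate
    d4 <- rep(1L, 100)                      # all-het: HWE catastrophic
    dos <- rbind(v1 = d1, v2 = d2, v3 = d3, v4 = d4)
    colnames(dos) <- paste0("s", 1:100)
    rep <- variantFilters(gmFromDosage(dos))
    expect_equal(rep$maf[1], 0.055)
    expect_false(grepl("low_maf", rep$reasons[1]))
    expect_false(rep$excluded[1])
    expect_true(rep$excluded[2])
    expect_identical(rep$reasons[2], "low_maf")
    expect_true(grepl("low_call_rate", rep$reasons[3]))
    expect_true(grepl("hwe_fail", rep$reasons[4]))
    ## zero non-missing calls: excluded for call rate only, NA-safe
    dos0 <- rbind(dos, v5 = rep(NA_integer_, 100))
    rep0 <- variantFilters(gmFromDosage(dos0))
    expect_identical(rep0$reasons[5], "low_call_rate")
    expect_true(is.na(rep0$maf[5]))
})

test_that("heterozygosity outliers are flagged relative to cohort SD", {
    set.seed(2)
    n <- 400
    dos <- matrix(rbinom(200 * n, 2, 0.5), 200, n,
                  dimnames = list(NULL, paste0("s", seq_len(n))))
    rownames(dos) <- paste0("v", 1:200)
    dos[, 1] <- 1L                      # het rate 1: gross outlier
    rep <- heterozygosityFilter(gmFromDosage(dos))
    expect_true(rep$excluded[1])
    expect_identical(sum(rep$excluded), 1L)
    ## identical rates: SD 0, nobody excluded
    cons <- matrix(rep(c(0L, 1L), each = 4), 2, 4, byrow = TRUE,
                   dimnames = list(c("v1", "v2"), paste0("s", 1:4)))
    expect_false(any(heterozygosityFilter(gmFromDosage(cons),
                                          sd_threshold = 5)$excluded))
})

test_that("inbreeding F hits its closed-form anchors", {
    ## fully homozygous sample: F = 1 regardless of frequencies
    set.seed(3)
    dos <- matrix(rbinom(500 * 10, 2, 0.5), 500, 10,
                  dimnames = list(paste0("v", 1:500), paste0("s", 1:10)))
    dos[, 1] <- ifelse(dos[, 1] == 1L, 2L, dos[, 1])
    expect_equal(inbreedingF(gmFromDosage(dos), "s1"), 1)
    ## all-heterozygous sample at 0.5-frequency markers: F near -1
    dos[, 2] <- 1L
    f2 <- inbreedingF(gmFromDosage(dos), "s2")
    expect_lt(f2, -0.8)
    ## an ordinary HWE sample: F near 0 (3 SE over replicates; frequencies
    ## estimated from a cohort large enough that the shared-sample bias
    ## is negligible)
    fs <- replicate(30, {
        d <- matrix(rbinom(2000 * 150, 2, 0.3), 2000, 150)
        rownames(d) <- paste0("v", 1:2000)
        colnames(d) <- paste0("s", 1:150)
        inbreedingF(gmFromDosage(d), "s1")
    })
    expect_lt(abs(mean(fs)), 3 * sd(fs) / sqrt(length(fs)))
    expect_error(inbreedingF(gmFromDosage(
        matrix(0L, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))),
        "x"), "polymorphic")
})

test_that("sex check applies the F thresholds per annotated sex", {
    ## construct X genotypes with target F via het fraction
    set.seed(4)
    n <- 40
    xdos <- matrix(rbinom(400 * n, 2, 0.5), 400, n)
    rownames(xdos) <- paste0("x", 1:400)
    colnames(xdos) <- paste0("s", seq_len(n))
    make_f <- function(col, het_frac) {
        g <- rbinom(400, 2, 0.5)
        het <- rbinom(400, 1, het_frac) == 1
        g[!het & g == 1L] <- ifelse(rbinom(sum(!het & g == 1L), 1, .5), 0L, 2L)
        g[het] <- 1L
        g
    }
    xdos[, 1] <- make_f(1, 0.25)   # F ~ 0.5: discordant for a male
    xdos[, 2] <- make_f(2, 0.50)   # F ~ 0: fine for a female
    xdos[, 3] <- make_f(3, 0.30)   # F ~ 0.4: discordant for a female
    sex <- c("male", "female", "female", rep("female", n - 3))
    gm <- gmFromDosage(xdos, is_x = TRUE, sex = sex)
    rep <- sexCheckFilter(gm)
    expect_true(rep$excluded[rep$sample_id == "s1"])
    expect_false(rep$excluded[rep$sample_id == "s2"])
    expect_true(rep$excluded[rep$sample_id == "s3"])
    ## unknown sex is never excluded by this rule
    sex[4] <- "unknown"
    gm2 <- gmFromDosage(xdos, is_x = TRUE, sex = sex)
    expect_message(rep2 <- sexCheckFilter(gm2), "unknown")
    expect_false(rep2$excluded[rep2$sample_id == "s4"])
})

test_that("IBD estimates separate duplicates, sibs and unrelateds", {
    set.seed(5)
    freqs <- runif(1000, 0.1, 0.9)
    ## duplicate: a sample against itself
    base <- matrix(rbinom(1000 * 30, 2, freqs), 1000, 30)
    rownames(base) <- paste0("v", 1:1000)
    colnames(base) <- paste0("s", 1:30)
    dup <- cbind(base, dup = base[, 1])
    colnames(dup) <- c(paste0("s", 1:30), "dup")
    est <- ibdEstimate(gmFromDosage(dup), c("s1", "dup"))
    expect_gte(est$pi_hat, 0.95)
    ## unrelated pairs: mean pi_hat < 0.05 over 100 replicates
    ## full sibs via gene dropping: mean pi_hat ~ 0.5 +/- 0.05
    pi_unrel <- pi_sib <- numeric(100)
    for (i in 1:100) {
        sib <- simulateSibPair(freqs)                 # 2 x 1000
        unrel <- t(matrix(rbinom(1000 * 20, 2, freqs), 1000, 20))
        d <- t(rbind(sib, unrel))                     # variants x samples
        rownames(d) <- paste0("v", 1:1000)
        colnames(d) <- c("sib1", "sib2", paste0("u", 1:20))
        gm <- gmFromDosage(d)
        pi_sib[i] <- ibdEstimate(gm, c("sib1", "sib2"))$pi_hat
        pi_unrel[i] <- ibdEstimate(gm, c("u1", "u2"))$pi_hat
    }
    expect_lt(mean(pi_unrel), 0.05)
    expect_lt(abs(mean(pi_sib) - 0.5), 0.05)
    ## self-sharing dominates unrelated sharing
    expect_gt(est$pi_hat, max(pi_unrel))
    ## overlap floor
    small <- gmFromDosage(base[1:10, ], snp_ids = paste0("v", 1:10))
    expect_error(ibdEstimate(small, c("s1", "s2")), "insufficient markers")
})

test_that("relatedness removal is greedy, minimal and deterministic", {
    expect_identical(relatednessFilter(
        data.frame(id1 = "a", id2 = "b", pi_hat = 0.1)), character())
    ## one duplicate pair: remove the lower-call-rate member
    est <- data.frame(id1 = "a", id2 = "b", pi_hat = 0.9)
    expect_identical(relatednessFilter(est, c(a = 0.99, b = 0.97)), "b")
    expect_identical(relatednessFilter(est, c(a = 0.97, b = 0.99)), "a")
    ## tie on call rate: drop the later sample_id
    expect_identical(relatednessFilter(est, c(a = 0.99, b = 0.99)), "b")
    ## 3-clique: exactly 2 removed (brute-force minimum for a triangle)
    tri <- data.frame(id1 = c("a", "a", "b"), id2 = c("b", "c", "c"),
                      pi_hat = c(0.6, 0.5, 0.4))
    expect_length(relatednessFilter(tri), 2)
})

test_that("PCA outlier filter flags a diverged subpopulation only", {
    set.seed(6)
    p <- runif(150, 0.2, 0.8)
    main <- matrix(rbinom(150 * 395, 2, p), 150, 395)
    ## strongly diverged frequencies for 5 samples
    p2 <- plogis(qlogis(p) + rnorm(150, 0, 3))
    div <- matrix(rbinom(150 * 5, 2, p2), 150, 5)
    dos <- cbind(main, div)
    rownames(dos) <- paste0("v", 1:150)
    colnames(dos) <- c(paste0("m", 1:395), paste0("o", 1:5))
    rep <- pcaOutlierFilter(gmFromDosage(dos), n_components = 10,
                            sd_threshold = 5)
    flagged <- rep$sample_id[rep$excluded]
    expect_true(all(paste0("o", 1:5) %in% flagged))
    expect_lt(length(setdiff(flagged, paste0("o", 1:5))), 3)
    ## homogeneous cohort: nobody past 5 SD
    rep0 <- pcaOutlierFilter(gmFromDosage(main[, 1:200,
        drop = FALSE]), n_components = 10, sd_threshold = 5)
    expect_identical(sum(rep0$excluded), 0L)
    ## infinite threshold disables flagging
    rep_inf <- pcaOutlierFilter(gmFromDosage(dos), sd_threshold = Inf)
    expect_false(any(rep_inf$excluded))
})

test_that("LD pruning keeps the highest-OR variant per correlated set", {
    rows <- c("rsA\tG\tT\t0.30\t1.5\tg1\t1\t0\tsrc",
              "rsB\tG\tT\t0.30\t1.4\tg2\t1\t0\tsrc",
              "rsC\tG\tT\t0.30\t1.3\tg3\t1\t0\tsrc")
    wt <- loadWeightTable(writeWeightTSV(rows))
    set.seed(7)
    a <- rbinom(400, 2, 0.3)
    c_ind <- rbinom(400, 2, 0.3)
    ## A and B perfectly correlated, C independent
    dos <- rbind(rsA = a, rsB = a, rsC = c_ind)
    colnames(dos) <- paste0("s", 1:400)
    pr <- ldPrune(gmFromDosage(dos), wt)
    expect_identical(sort(pr$kept), c("rsA", "rsC"))
    expect_identical(pr$removed$snp_id, "rsB")
    expect_identical(pr$removed$partner_snp_id, "rsA")
    expect_gt(pr$removed$r2, 0.99)
    ## all three mutually correlated: only the top-OR survives
    dos2 <- rbind(rsA = a, rsB = a, rsC = a)
    colnames(dos2) <- paste0("s", 1:400)
    pr2 <- ldPrune(gmFromDosage(dos2), wt)
    expect_identical(pr2$kept, "rsA")
    ## independent variants: nothing pruned, and kept pairs satisfy r2 <= 0.2
    dos3 <- rbind(rsA = rbinom(400, 2, .3), rsB = rbinom(400, 2, .3),
                  rsC = rbinom(400, 2, .3))
    colnames(dos3) <- paste0("s", 1:400)
    pr3 <- ldPrune(gmFromDosage(dos3), wt)
    expect_length(pr3$kept, 3)
    ## zero-variance vector: warned, treated as uncorrelated
    dos4 <- rbind(rsA = a, rsB = rep(0L, 400), rsC = c_ind)
    colnames(dos4) <- paste0("s", 1:400)
    expect_warning(pr4 <- ldPrune(gmFromDosage(dos4), wt),
                   "zero-variance")
    expect_length(pr4$kept, 3)
})

test_that("the QC chain runs stages in order and records them", {
    set.seed(8)
    n <- 80
    m <- 4000
    freqs <- runif(m, 0.2, 0.8)
    dos <- matrix(rbinom(m * n, 2, freqs), m, n)
    rownames(dos) <- paste0("v", 1:m)
    colnames(dos) <- sprintf("s%02d", 1:n)
    mx <- 800                        # enough X markers that F noise
    xdos <- matrix(rbinom(mx * n, 2, 0.5), mx, n)  # stays well under 0.2
    rownames(xdos) <- paste0("x", 1:mx)
    ## planted defects
    dos[1:280, 1] <- NA                 # 94.2% call rate (of 4800)
    dos[, 2] <- dos[, 3]                                # duplicate pair
    xdos[, 4] <- ifelse(xdos[, 4] == 1L, 2L, xdos[, 4]) # female with F ~ 1
    hom5 <- which(dos[, 5] != 1L)                       # het outlier:
    dos[sample(hom5, round(0.13 * length(hom5))), 5] <- 1L  # rate ~ +6 SD
    full <- rbind(dos, xdos)
    gm <- GenotypeMatrix(full,
        variants = data.frame(snp_id = rownames(full),
            chrom = c(rep("1", m), rep("X", mx)),
            pos = seq_len(m + mx), allele_a = "T", allele_b = "G",
            is_x = c(rep(FALSE, m), rep(TRUE, mx))),
        sample_ids = colnames(full), sex = "female")
    qc <- runQC(gm, min_ibd_overlap = 50, pca_sd = Inf)
    smp <- qc$samples
    expect_identical(smp$stage[smp$sample_id == "s01"], "call_rate")
    expect_true(any(smp$excluded & smp$stage == "ibd" &
                    smp$sample_id %in% c("s02", "s03")))
    expect_identical(sum(smp$stage == "ibd"), 1L)
    expect_identical(smp$stage[smp$sample_id == "s05"], "het")
    expect_identical(smp$stage[smp$sample_id == "s04"], "sex_check")
    ## funnel counts reconcile with exclusions and are non-increasing
    expect_true(all(diff(qc$funnel) <= 0))
    expect_identical(unname(qc$funnel["sex_check"]),
                     sum(!smp$excluded))
    expect_s4_class(qc$filtered, "GenotypeMatrix")
    expect_identical(ncol(qc$filtered), sum(!smp$excluded))
})
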