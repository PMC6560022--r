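test_that("noise-free planted multiplicative effect back-transforms exactly", {
    fit <- fitMMRM(cloneTrial(eff = 0.75), "M")
    ct <- estimateContrast(fit, "A", "B")
    avg <- ct[ct$visit == "average", ]
    expect_equal(avg$delta, log(0.75), tolerance = 1e-6)
    expect_equal(avg$estimate, -25, tolerance = 1e-4)
    expect_equal(ct$estimate[ct$visit == "52"], -25, tolerance = 1e-4)

    fit0 <- fitMMRM(cloneTrial(eff = 1), "M")
    ct0 <- estimateContrast(fit0, "A", "B")
    expect_equal(ct0$estimate[ct0$visit == "average"], 0, tolerance = 1e-6)
})

test_that("relabelling arms flips the contrast as 100*(1/(1+p/100)-1)", {
    fit <- fitMMRM(cloneTrial(eff = 0.8, seed = 4), "M")
    ab <- estimateContrast(fit, "A", "B")
    ba <- estimateContrast(fit, "B", "A")
    expect_equal(ba$delta, -ab$delta, tolerance = 1e-10)
    p <- ab$estimate
    expect_equal(ba$estimate, 100 * (1 / (1 + p / 100) - 1),
                 tolerance = 1e-8)
    expect_equal(ab$pValue, ba$pValue, tolerance = 1e-10)
})

test_that("MMRM preconditions are enforced", {
    tr <- cloneTrial()
    rec <- trialRecords(tr)
    one <- makeTrial(rec[rec$visitWeek %in% c(0, 52), ])
    expect_error(fitMMRM(one, "M"), "two post-baseline")
    expect_error(fitMMRM(tr, "nope"), "not in the trial")
    fit <- fitMMRM(tr, "M")
    expect_error(estimateContrast(fit, "A", "Z"), "unknown arm")

    # a visit with fewer than 2 subjects in an arm is rejected
    drop <- rec[!(rec$arm == "A" & rec$visitWeek == 104 &
                  rec$subject != "a1"), ]
    expect_error(fitMMRM(makeTrial(drop), "M"), "at least 2 subjects")
})

test_that("unstructured covariance recovers the baseline-conditional correlation", {
    # with a subject random intercept of share rho of the total variance,
    # conditioning on the baseline leaves correlation rho / (1 + rho)
    # between post-baseline visits
    rho <- 0.5
    cfg <- simulationConfig(nSubjectsPerArm = 500, withinSubjectCorr = rho,
                            seed = 61)
    sim <- simulateTrial(cfg)
    fit <- fitMMRM(sim$trial, "TNFR1")
    cc <- cov2cor(residualCovariance(fit))
    expect_equal(cc[1, 2], rho / (1 + rho), tolerance = 0.1)
})

test_that("change correlations hit the trivial anchors and report NA for constants", {
    subj <- paste0("s", 1:4)
    x <- c(1, 2, 3, 4)
    rec <- function(marker, changes) {
        rbind(data.frame(subject = subj, arm = "A", visitWeek = 0,
                         biomarker = marker, value = 1),
              data.frame(subject = subj, arm = "A", visitWeek = 52,
                         biomarker = marker, value = 1 + changes / 100))
    }
    tr <- makeTrial(rbind(rec("X", x), rec("Y", 2 * x), rec("Z", rev(x)),
                          rec("W", c(5, 5, 5, 5))))
    out <- correlateChanges(tr, c("X", "Y", "Z", "W"), atWeek = 52)
    expect_equal(out$r["X", "X"], 1)
    expect_equal(out$r["X", "Y"], 1, tolerance = 1e-12)
    expect_equal(out$r["X", "Z"], -1, tolerance = 1e-12)
    expect_true(is.na(out$r["X", "W"]))
    expect_true(out$significant["X", "Y"])
    expect_false(out$significant["X", "W"])
    expect_equal(out$r, t(out$r))
})

test_that("tertile stratification splits ranks with remainder to lower tertiles", {
    t9 <- stratifyTertiles(setNames(9:1, paste0("s", 9:1)))
    expect_equal(as.vector(table(t9)), c(3, 3, 3))
    expect_equal(unname(t9[paste0("s", 1:3)]),
                 factor(c("T1", "T1", "T1"), levels = c("T1", "T2", "T3")))

    set.seed(2)
    v294 <- setNames(sample(seq_len(1000), 294), sprintf("p%03d", 1:294))
    expect_equal(as.vector(table(stratifyTertiles(v294))), c(98, 98, 98))

    v10 <- setNames(runif(10), letters[1:10])
    expect_equal(as.vector(table(stratifyTertiles(v10))), c(4, 3, 3))

    # invariant to input order, ties broken by subject id
    vTie <- setNames(c(1, 1, 1, 1, 2), c("e", "c", "a", "b", "d"))
    t1 <- stratifyTertiles(vTie)
    t2 <- stratifyTertiles(vTie[c(5, 3, 1, 2, 4)])
    expect_equal(t1[sort(names(t1))], t2[sort(names(t2))])
    expect_error(stratifyTertiles(c(a = 1, b = 2)), "at least 3")
})

test_that("eGFR association recovers a planted dependence and orders tertile means", {
    cfg <- simulationConfig(nSubjectsPerArm = 150, seed = 5)
    sim <- simulateTrial(cfg, markers = "TNFR1",
                         egfrAssociation = list(marker = "TNFR1",
                                                slope = -8))
    chg <- biomarkerChange(sim$trial, "TNFR1", 52)
    res <- associateEgfrDecline(sim$trial, chg, grouping = "tertiles")
    expect_lt(res$continuousP, 0.05)
    expect_lt(res$slope, 0)
    # monotone planted dependence -> monotone least-squares means
    expect_true(all(diff(res$groups$lsmean) < 0))
    expect_equal(sum(res$groups$n), length(unique(names(chg))))
    expect_true(all(res$groups$ciLow <= res$groups$lsmean &
                    res$groups$lsmean <= res$groups$ciHigh))

    bands <- associateEgfrDecline(sim$trial, chg, grouping = "named_bands")
    expect_true(all(bands$groups$group %in%
        c("reduction_ge30", "reduction_30_0", "increase")))
})

test_that("eGFR association is well calibrated under the null", {
    set.seed(77)
    est <- replicate(60, {
        seed <- sample.int(1e6, 1)
        cfg <- simulationConfig(nSubjectsPerArm = 50, seed = seed)
        sim <- simulateTrial(cfg, markers = "TNFR1")
        chg <- biomarkerChange(sim$trial, "TNFR1", 52)
        associateEgfrDecline(sim$trial, chg)$slope
    })
    mcse <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est)), 3 * mcse)
})
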