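test_that("preferential-attachment interactome has the forced size and is connected", {
    g <- simulateInteractome(2, 1)
    expect_equal(igraph::ecount(g), 1)

    g <- simulateInteractome(50, 2, seed = 7)
    expect_equal(igraph::vcount(g), 50)
    expect_equal(igraph::ecount(g), 2 * (50 - 2))
    expect_false(any(igraph::which_loop(g)))
    expect_false(any(igraph::which_multiple(g)))
    # connectivity via the BFS oracle, not igraph's own check
    el <- igraph::as_edgelist(g)
    dist <- oracleDistToSet(data.frame(from = el[, 1], to = el[, 2]),
                            igraph::V(g)$name, igraph::V(g)$name[1])
    expect_true(all(is.finite(dist)))
})

test_that("interactome generation is deterministic under a seed and validates inputs", {
    g1 <- simulateInteractome(40, 3, seed = 7)
    g2 <- simulateInteractome(40, 3, seed = 7)
    expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
    g3 <- simulateInteractome(40, 3, seed = 8)
    expect_false(identical(igraph::as_edgelist(g1),
                           igraph::as_edgelist(g3)))

    expect_error(simulateInteractome(1, 1), "at least 2")
    expect_error(simulateInteractome(10, 10), "attachment")
    expect_error(simulateInteractome(10, 0), "attachment")
})

test_that("planted gene sets have the requested sizes and overlap", {
    net <- simulateInteractome(200, 2, seed = 1)

    cfg <- simulationConfig(interactomeSize = 200, diseaseSetSize = 60,
                            drugSetSize = 30, plantedOverlap = 10, seed = 3)
    sets <- simulateGeneSets(net, cfg)
    expect_length(sets$diseaseGenes, 60)
    expect_length(sets$drugLiteratureGenes, 30)
    expect_length(intersect(sets$diseaseGenes, sets$drugLiteratureGenes), 10)

    cfg0 <- simulationConfig(interactomeSize = 200, diseaseSetSize = 20,
                             drugSetSize = 20, plantedOverlap = 0, seed = 3)
    s0 <- simulateGeneSets(net, cfg0)
    expect_length(intersect(s0$diseaseGenes, s0$drugLiteratureGenes), 0)

    cfgEmpty <- simulationConfig(interactomeSize = 200, diseaseSetSize = 20,
                                 drugSetSize = 0, plantedOverlap = 0)
    expect_length(simulateGeneSets(net, cfgEmpty)$drugLiteratureGenes, 0)

    expect_error(simulationConfig(interactomeSize = 30, diseaseSetSize = 25,
                                  drugSetSize = 25, plantedOverlap = 5),
                 "do not fit")
    expect_error(simulationConfig(plantedOverlap = 50, drugSetSize = 30),
                 "exceeds")
})

test_that("expression generator plants exact fold changes and dimensions", {
    cfg <- simulationConfig(interactomeSize = 100, nDeGenes = 8,
                            noiseSd = 0, probesPerGene = 2,
                            nReplicates = 4, seed = 11)
    net <- simulateInteractome(cfg$interactomeSize, cfg$attachment, cfg$seed)
    ex <- simulateExpression(net, cfg)
    expect_equal(dim(SummarizedExperiment::assay(ex$se)), c(200, 8))
    expect_true(all(SummarizedExperiment::assay(ex$se) > 0))
    expect_true(all(abs(ex$deGenes) >= cfg$fcLow &
                    abs(ex$deGenes) <= cfg$fcHigh))

    # noise-free: treated/control gene mean ratio equals the planted ratio
    fc <- computeFoldChanges(summarizeProbes(ex$se))
    planted <- ex$deGenes
    got <- setNames(fc$signedFC, fc$gene)[names(planted)]
    expect_equal(unname(got), unname(planted), tolerance = 1e-12)

    expect_error(simulationConfig(noiseSd = -0.1), "non-negative")
})

test_that("explicitly planted deregulated genes are honoured", {
    net <- simulateInteractome(50, 2, seed = 2)
    cfg <- simulationConfig(interactomeSize = 50, diseaseSetSize = 20,
                            drugSetSize = 10, plantedOverlap = 5,
                            noiseSd = 0, seed = 2)
    plant <- setNames(c(1.5, -2), igraph::V(net)$name[c(3, 10)])
    ex <- simulateExpression(net, cfg, deGenes = plant)
    expect_identical(ex$deGenes, plant)
    expect_error(simulateExpression(net, cfg,
                                    deGenes = c(zzz = 1.5)), "nodes")
    expect_error(simulateExpression(net, cfg,
        deGenes = setNames(0.9, igraph::V(net)$name[1])), "magnitude")
})

test_that("trial generator: dimensions, planted effects and determinism", {
    cfg <- simulationConfig(nSubjectsPerArm = 100, seed = 21)
    sim <- simulateTrial(cfg)
    rec <- trialRecords(sim$trial)
    bio <- rec[rec$biomarker == "TNFR1", ]
    expect_equal(nrow(bio), 100 * 2 * 3)
    expect_equal(sort(unique(bio$visitWeek)), c(0, 52, 104))
    expect_setequal(unique(bio$arm), c("control", "treated"))
    expect_equal(nrow(trialCovariates(sim$trial)), 200)
    expect_equal(sim$truth$trialEffects$effect[
        sim$truth$trialEffects$arm == "treated"], c(0.75, 0.75))

    sim2 <- simulateTrial(cfg)
    expect_identical(trialRecords(sim$trial), trialRecords(sim2$trial))

    expect_error(simulationConfig(withinSubjectCorr = 1), "\\[0, 1\\)")
    expect_error(simulationConfig(withinSubjectCorr = -0.2), "\\[0, 1\\)")
    expect_error(simulationConfig(visitWeeks = c(0)), "visitWeeks")
})

test_that("zero within-subject correlation yields near-zero residual correlation", {
    cfg <- simulationConfig(nSubjectsPerArm = 300, withinSubjectCorr = 0,
                            plantedEffects = list(
                                control = c("52" = 1, "104" = 1),
                                treated = c("52" = 1, "104" = 1)),
                            seed = 33)
    sim <- simulateTrial(cfg)
    rec <- trialRecords(sim$trial)
    rec <- rec[rec$biomarker == "TNFR1", ]
    w <- reshape(rec[, c("subject", "visitWeek", "value")],
                 idvar = "subject", timevar = "visitWeek",
                 direction = "wide")
    r <- cor(log(w$value.52), log(w$value.104))
    expect_lt(abs(r), 0.1)
})

test_that("monotone dropout removes later visits only", {
    cfg <- simulationConfig(nSubjectsPerArm = 200, dropout = 0.2, seed = 9)
    sim <- simulateTrial(cfg)
    rec <- trialRecords(sim$trial)
    rec <- rec[rec$biomarker == "TNFR1", ]
    perSubj <- tapply(rec$visitWeek, rec$subject, function(v) sort(v))
    # every observed visit pattern is a prefix of the full schedule
    ok <- vapply(perSubj, function(v)
        identical(v, c(0, 52, 104)[seq_along(v)]), logical(1))
    expect_true(all(ok))
    expect_lt(sum(rec$visitWeek == 104), sum(rec$visitWeek == 0))
})
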