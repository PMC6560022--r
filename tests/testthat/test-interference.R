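mkModel <- function(net, genes) extractConnectedSubmodel(net, genes)

test_that("interference signature is the node and edge intersection", {
    net <- igraph::graph_from_edgelist(rbind(
        c("a", "b"), c("b", "c"), c("c", "d")), directed = FALSE)
    A <- mkModel(net, c("a", "b", "c"))
    B <- mkModel(net, c("b", "c", "d"))
    sig <- computeInterference(A, B)
    expect_equal(sharedNodes(sig), c("b", "c"))
    expect_equal(unname(sharedEdges(sig)), cbind("b", "c"))

    self <- computeInterference(A, A)
    expect_equal(sharedNodes(self), modelNodes(A))
    expect_equal(sharedEdges(self)[order(sharedEdges(self)[, 1]), ],
                 modelEdges(A)[order(modelEdges(A)[, 1]), ])

    # node-disjoint models give an empty but valid signature
    net2 <- igraph::graph_from_edgelist(rbind(c("x", "y"), c("p", "q")),
                                        directed = FALSE)
    sig0 <- computeInterference(mkModel(net2, c("x", "y")),
                                mkModel(net2, c("p", "q")))
    expect_length(sharedNodes(sig0), 0)
    expect_equal(nrow(sharedEdges(sig0)), 0)
})

test_that("interference is symmetric and contained in both models", {
    set.seed(15)
    for (i in 1:20) {
        edges <- randomEdges(sample(10:28, 1))
        net <- edgesToGraph(edges)
        nodes <- igraph::V(net)$name
        A <- tryCatch(mkModel(net, sample(nodes, length(nodes) %/% 2)),
                      error = function(e) NULL)
        B <- tryCatch(mkModel(net, sample(nodes, length(nodes) %/% 2)),
                      error = function(e) NULL)
        if (is.null(A) || is.null(B)) next
        s1 <- computeInterference(A, B)
        s2 <- computeInterference(B, A)
        expect_identical(sharedNodes(s1), sharedNodes(s2))
        expect_identical(sharedEdges(s1), sharedEdges(s2))
        expect_true(all(sharedNodes(s1) %in% modelNodes(A)))
        expect_true(all(sharedNodes(s1) %in% modelNodes(B)))
        keys <- if (nrow(sharedEdges(s1))) {
            edgeKeyOracle(sharedEdges(s1)[, 1], sharedEdges(s1)[, 2])
        } else {
            character(0)
        }
        expect_true(all(keys %in% modelEdgeKeys(A)))
        expect_true(all(keys %in% modelEdgeKeys(B)))
    }
})

test_that("prognostic evidence filter applies all four publication rules", {
    expect_length(filterPrognosticEvidence(
        data.frame(gene = character(0), publication_id = character(0),
                   terms = character(0), major_terms = character(0),
                   study_flags = character(0))), 0)

    ann <- data.frame(
        gene = c("G", "G", "H", "I", "J", "K"),
        publication_id = paste0("P", 1:6),
        terms = c("biological markers;prognosis",
                  "biological markers;prognosis",
                  "biological markers;prognosis",
                  "biological markers",
                  "biological markers;prognosis",
                  "Biological Markers ; Prognosis"),
        major_terms = c("diabetic nephropathies",
                        "diabetic nephropathies",
                        "diabetic nephropathies",
                        "diabetic nephropathies",
                        "something else",
                        "Diabetic Nephropathies"),
        study_flags = c("human",
                        "human;omics_profiling",  # excluded study type
                        "",                        # no allowed context
                        "human",                   # missing prognosis term
                        "human",                   # wrong major topic
                        "clinical_trial"))
    ev <- filterPrognosticEvidence(ann)
    # G: P1 counts, P2 is an omics study; K shows case/space-insensitivity
    expect_equal(ev, c(G = 1L, K = 1L))
})

test_that("candidate ranking tiers by distance with deterministic ordering", {
    net <- igraph::graph_from_edgelist(rbind(
        c("a", "b"), c("b", "c"), c("c", "e"), c("e", "f")),
        directed = FALSE)
    A <- mkModel(net, c("a", "b", "c"))
    B <- mkModel(net, c("b", "c", "e"))
    sig <- computeInterference(A, B)   # nodes {b, c}
    cand <- rankCandidates(sig, net, c("c", "e", "f"), proximityMax = 1)
    expect_equal(cand$gene, c("c", "e"))
    expect_equal(cand$tier, c("in_signature", "proximal"))
    expect_equal(cand$distance, c(0L, 1L))

    # proximityMax = 0 keeps exactly the in-signature prognostic genes
    cand0 <- rankCandidates(sig, net, c("c", "e", "f"), proximityMax = 0)
    expect_equal(cand0$gene, "c")

    # growing the radius never removes candidates
    cand2 <- rankCandidates(sig, net, c("c", "e", "f"), proximityMax = 2)
    expect_true(all(cand$gene %in% cand2$gene))
    expect_true("f" %in% cand2$gene)

    expect_equal(nrow(rankCandidates(sig, net, character(0))), 0)
    expect_error(rankCandidates(sig, net, "c", proximityMax = -1), ">= 0")
    expect_warning(rankCandidates(sig, net, c("c", "nope")), "dropped")

    # ties order by descending evidence then gene id
    ev <- c(b = 1L, c = 5L)
    candEv <- rankCandidates(sig, net, ev, proximityMax = 0)
    expect_equal(candEv$gene, c("c", "b"))
})

test_that("benchmark fixture yields the expected signature and candidates", {
    b <- syntheticBenchmark()
    core <- extractConnectedSubmodel(b$network, b$drugLiteratureGenes)
    moa <- extendMoaModel(core, b$network, b$foldChanges)
    dkd <- extractConnectedSubmodel(b$network, b$diseaseGenes)
    sig <- computeInterference(dkd, moa)
    expect_length(sharedNodes(sig), 44)
    ev <- filterPrognosticEvidence(b$annotation)
    cand <- rankCandidates(sig, b$network, ev, proximityMax = 1)
    expect_equal(sum(cand$tier == "in_signature"), 10)
    expect_equal(cand$gene[cand$tier == "proximal"], "prx1")
    # the distance-2 prognostic gene appears only at a wider radius
    cand2 <- rankCandidates(sig, b$network, ev, proximityMax = 2)
    expect_true("prx2" %in% cand2$gene)
})
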