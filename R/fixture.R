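# A small fully synthetic benchmark with known structure, used in examples
# and tests to exercise the whole network pipeline with hand-checkable
# counts at every stage.

#' Synthetic benchmark dataset for the network pipeline
#'
#' Constructs, deterministically, a small synthetic interactome together
#' with literature gene sets, a signed fold-change vector and a literature
#' annotation table, engineered so that every pipeline stage has a known
#' expected outcome: 78 drug literature genes of which 74 are mutually
#' linked (the MoA core); 11 core genes past the 1.2-fold deregulation
#' threshold; 31 deregulated non-core genes linked to deregulated core
#' genes (plus decoys failing each rule), so the extended MoA model has
#' 105 nodes; a disease gene set whose model shares exactly 44 nodes with
#' the extended MoA model; and prognostic literature evidence for 10
#' signature genes plus one direct neighbour of the signature.
#'
#' @return list with elements \code{network} (igraph),
#'   \code{drugLiteratureGenes}, \code{diseaseGenes},
#'   \code{foldChanges} (named signed fold-change vector),
#'   \code{annotation} (literature annotation \code{data.frame}) and
#'   \code{prognosticGenes} (the genes carrying qualifying evidence).
#' @examples
#' bench <- syntheticBenchmark()
#' core <- extractConnectedSubmodel(bench$network, bench$drugLiteratureGenes)
#' length(modelNodes(core))  # 74
#' @export
syntheticBenchmark <- function() {
    moa <- sprintf("moa%02d", 1:78)
    ext <- sprintf("ext%02d", 1:31)
    dis <- sprintf("dis%02d", 1:50)
    fill <- sprintf("fil%02d", 1:4)

    edges <- rbind(
        # MoA core: a path linking moa01..moa74; moa75..78 touch only fillers
        cbind(moa[1:73], moa[2:74]),
        cbind(moa[75:78], fill),
        # each extension gene interacts with one deregulated core gene
        cbind(ext, moa[(seq_along(ext) - 1L) %% 11L + 1L]),
        # decoys: right fold change but wrong neighbourhood, and vice versa
        cbind("dcy1", moa[50]),   # |fc| passes, neighbour not deregulated
        cbind("dcy2", moa[1]),    # neighbour deregulated, |fc| below 1.2
        cbind("dcy3", ext[1]),    # linked only to an extension gene
        # disease-only genes: a path, attached to the shared region
        cbind(dis[1:49], dis[2:50]),
        cbind(dis[1], moa[1]),
        # prognostic genes outside both models at distance 1 and 2
        cbind("prx1", moa[2]),
        cbind("prx2", "prx1"))
    network <- igraph::graph_from_edgelist(edges, directed = FALSE)

    fc <- c(setNames(c(1.5, -1.8, 1.3, 2.0, -1.4, 1.6, -2.2, 1.25, 1.9,
                       -1.5, 1.7), moa[1:11]),
            setNames(1.1, "moa12"),           # core, below threshold
            setNames(ifelse(seq_along(ext) %% 2 == 0, -1, 1) *
                     (1.2 + 0.04 * seq_along(ext)), ext),
            dcy1 = 1.5, dcy2 = 1.1, dcy3 = -1.6)

    inSig <- c(moa[c(1, 3, 7, 15, 20, 25)], ext[c(1, 5, 9, 13)])
    prognostic <- c(inSig, "prx1", "prx2")
    qual <- do.call(rbind, lapply(seq_along(prognostic), function(i) {
        g <- prognostic[i]
        nPub <- 1L + (i %% 3L)
        data.frame(gene = g,
                   publication_id = paste0("PMID", i * 100L + seq_len(nPub)),
                   terms = "biological markers;prognosis",
                   major_terms = "diabetic nephropathies",
                   study_flags = c("human", "clinical_trial",
                                   "animal_model")[1L + (i %% 3L)])
    }))
    noise <- data.frame(
        gene = c(inSig[1], "moa40", "moa40", dis[5]),
        publication_id = c("PMIDX1", "PMIDX2", "PMIDX3", "PMIDX4"),
        terms = c("biological markers;prognosis",
                  "biological markers;prognosis",
                  "biological markers",            # missing prognosis term
                  "biological markers;prognosis"),
        major_terms = c("diabetic nephropathies",
                        "diabetic nephropathies",
                        "diabetic nephropathies",
                        "kidney failure, chronic"), # wrong major topic
        study_flags = c("human;omics_profiling",   # excluded study type
                        "",                        # no allowed context
                        "human",
                        "human"))
    list(network = network,
         drugLiteratureGenes = moa,
         diseaseGenes = c(moa[1:30], ext[1:14], dis),
         foldChanges = fc,
         annotation = rbind(qual, noise),
         prognosticGenes = prognostic)
}
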