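# Brute-force reference implementations of the graph-stage operations,
# written with plain loops and set operations (no igraph) so they are
# independent of the package's implementation path.

edgeKeyOracle <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "|")
}

# induced-subgraph extraction keeping only non-isolated members
oracleExtract <- function(edges, genes) {
    keep <- edges$from %in% genes & edges$to %in% genes
    e <- edges[keep & edges$from != edges$to, , drop = FALSE]
    keys <- sort(unique(edgeKeyOracle(e$from, e$to)))
    nodes <- sort(intersect(genes, unique(c(e$from, e$to))))
    list(nodes = nodes, edgeKeys = keys)
}

# one-pass MoA extension: non-core genes past the threshold and adjacent
# to a deregulated core gene
oracleExtend <- function(coreNodes, edges, fc, thr) {
    passing <- names(fc)[abs(fc) >= thr]
    derCore <- intersect(coreNodes, passing)
    ext <- character(0)
    for (g in setdiff(passing, coreNodes)) {
        adj <- any((edges$from == g & edges$to %in% derCore) |
                   (edges$to == g & edges$from %in% derCore))
        if (adj) ext <- c(ext, g)
    }
    nodes <- sort(union(coreNodes, ext))
    keep <- edges$from %in% nodes & edges$to %in% nodes &
        edges$from != edges$to
    e <- edges[keep, , drop = FALSE]
    list(nodes = nodes,
         edgeKeys = sort(unique(edgeKeyOracle(e$from, e$to))),
         extension = sort(ext), deregulatedCore = sort(derCore))
}

oracleInterference <- function(nodesA, keysA, nodesB, keysB) {
    list(nodes = sort(intersect(nodesA, nodesB)),
         edgeKeys = sort(intersect(keysA, keysB)))
}

# breadth-first search distance from every node to a target set
oracleDistToSet <- function(edges, allNodes, targets) {
    adj <- lapply(setNames(allNodes, allNodes), function(n) {
        unique(c(edges$to[edges$from == n], edges$from[edges$to == n]))
    })
    dist <- setNames(rep(Inf, length(allNodes)), allNodes)
    frontier <- intersect(targets, allNodes)
    dist[frontier] <- 0
    d <- 0
    while (length(frontier) > 0) {
        nxt <- setdiff(unique(unlist(adj[frontier])),
                       names(dist)[is.finite(dist)])
        d <- d + 1
        dist[nxt] <- d
        frontier <- nxt
    }
    dist
}

oracleRank <- function(sigNodes, edges, allNodes, prognostic, pmax) {
    dist <- oracleDistToSet(edges, allNodes, sigNodes)
    rows <- lapply(sort(prognostic), function(g) {
        if (!g %in% allNodes) return(NULL)
        if (!is.finite(dist[g]) || dist[g] > pmax) return(NULL)
        data.frame(gene = g,
                   tier = if (dist[g] == 0) "in_signature" else "proximal",
                   distance = as.integer(dist[g]))
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(gene = character(0), tier = character(0),
                          distance = integer(0))
    out[order(match(out$tier, c("in_signature", "proximal")),
              out$distance, out$gene), , drop = FALSE]
}

# random simple connected-ish test network as a plain edge data.frame
randomEdges <- function(n, p = 0.15) {
    nodes <- sprintf("n%02d", seq_len(n))
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < p
    if (!any(keep)) keep[sample.int(nrow(pairs), 1)] <- TRUE
    data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
               stringsAsFactors = FALSE)
}

edgesToGraph <- function(edges, allNodes = NULL) {
    g <- igraph::graph_from_edgelist(as.matrix(edges[, c("from", "to")]),
                                     directed = FALSE)
    if (!is.null(allNodes)) {
        miss <- setdiff(allNodes, igraph::V(g)$name)
        if (length(miss)) g <- igraph::add_vertices(g, length(miss),
                                                    name = miss)
    }
    g
}

modelEdgeKeys <- function(model) {
    e <- modelEdges(model)
    if (nrow(e) == 0) return(character(0))
    sort(edgeKeyOracle(e[, 1], e[, 2]))
}

# small probe-level SummarizedExperiment built from a matrix
makeSE <- function(values, gene, groups) {
    SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = values),
        rowData = S4Vectors::DataFrame(gene = gene,
                                       row.names = rownames(values)),
        colData = S4Vectors::DataFrame(group = groups,
                                       row.names = colnames(values)))
}

# trial with arm A an exact scaled clone of arm B (same baselines, every
# post-baseline value multiplied by `eff`): the fitted contrast must be
# exactly log(eff)
cloneTrial <- function(n = 30, eff = 0.75, seed = 1) {
    set.seed(seed)
    base <- exp(rnorm(n, 7, 0.3))
    v52 <- base * exp(rnorm(n, 0, 0.2))
    v104 <- base * exp(rnorm(n, 0, 0.25))
    long <- function(pref, arm, b, x52, x104) {
        data.frame(subject = rep(paste0(pref, seq_len(n)), 3),
                   arm = arm,
                   visitWeek = rep(c(0, 52, 104), each = n),
                   biomarker = "M", value = c(b, x52, x104))
    }
    makeTrial(rbind(long("a", "A", base, eff * v52, eff * v104),
                    long("b", "B", base, v52, v104)))
}

# minimal TrialData from a long data.frame (covariates optional)
makeTrial <- function(records, covariates = NULL) {
    if (is.null(covariates)) {
        subj <- unique(records$subject)
        covariates <- data.frame(age = rep(55, length(subj)),
                                 row.names = subj)
    }
    methods::new("TrialData", records = records, covariates = covariates)
}
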