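# Molecular model construction on an interactome: induced-subgraph
# extraction of a literature gene set (non-isolated members only) and
# extension of a drug MoA core by deregulated genes linked to deregulated
# core members.

.induceEdges <- function(network, nodes) {
    sub <- igraph::induced_subgraph(network, nodes)
    el <- igraph::as_edgelist(sub)
    if (nrow(el) == 0L) {
        return(matrix(character(0), ncol = 2L,
                      dimnames = list(NULL, c("from", "to"))))
    }
    swap <- el[, 1L] > el[, 2L]
    el[swap, ] <- el[swap, c(2L, 1L)]
    el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
    dimnames(el) <- list(NULL, c("from", "to"))
    el
}

.newModel <- function(nodes, edges, source, deregulated, signedFC) {
    nodes <- sort(nodes)
    nd <- data.frame(source = source[nodes],
                     deregulated = deregulated[nodes],
                     signedFC = signedFC[nodes],
                     row.names = nodes)
    methods::new("MolecularModel", nodes = nodes, edges = edges,
                 nodeData = nd)
}

#' Extract a molecular model from a gene set on an interactome
#'
#' Builds the induced subgraph of the interactome on a gene set and drops
#' genes that share no interaction with another member of the set
#' (degree 0 in the induced subgraph). The model may consist of several
#' connected components; only isolation disqualifies a gene. Genes absent
#' from the interactome are dropped with a warning.
#'
#' @param network interactome as an \code{igraph} graph with named vertices.
#' @param genes character vector of gene identifiers (must be non-empty).
#' @param source provenance label recorded for every retained node.
#' @return a [MolecularModel-class].
#' @examples
#' net <- simulateInteractome(100, 2, seed = 3)
#' mod <- extractConnectedSubmodel(net, igraph::V(net)$name[1:20])
#' @export
extractConnectedSubmodel <- function(network, genes,
                                     source = "literature") {
    genes <- unique(as.character(genes))
    if (length(genes) == 0L)
        stop("empty input gene set")
    known <- genes %in% igraph::V(network)$name
    if (!all(known)) {
        warning(sum(!known), " gene(s) not in the interactome, dropped: ",
                paste(head(genes[!known], 5L), collapse = ", "),
                if (sum(!known) > 5L) ", ...")
        genes <- genes[known]
    }
    if (length(genes) == 0L)
        stop("no input gene is present in the interactome")
    edges <- .induceEdges(network, genes)
    keep <- genes[genes %in% c(edges[, 1L], edges[, 2L])]
    src <- setNames(rep(source, length(keep)), keep)
    der <- setNames(rep(FALSE, length(keep)), keep)
    sfc <- setNames(rep(NA_real_, length(keep)), keep)
    .newModel(keep, edges, src, der, sfc)
}

#' Extend a drug MoA core model with deregulated genes
#'
#' Marks core-model genes found in the deregulated set with their signed
#' fold change (provenance becomes \code{"both"}), then adds every non-core
#' gene whose fold-change magnitude meets the threshold \emph{and} that is
#' linked in the interactome to at least one deregulated core gene. Added
#' genes get provenance \code{"expression"}; adjacency to other extension
#' genes does not qualify (a single pass, no transitive closure). Edges are
#' recomputed as the interactome-induced edge set on the final nodes.
#'
#' @param core a [MolecularModel-class] built by
#'   [extractConnectedSubmodel()].
#' @param network the interactome the core was built on.
#' @param deregulated named numeric vector of signed fold changes, or the
#'   \code{data.frame} returned by [selectDeregulated()].
#' @param threshold fold-change magnitude required of extension genes
#'   (default 1.2, inclusive).
#' @return the extended [MolecularModel-class].
#' @export
extendMoaModel <- function(core, network, deregulated, threshold = 1.2) {
    if (is.data.frame(deregulated))
        deregulated <- setNames(deregulated$signedFC, deregulated$gene)
    deregulated <- deregulated[names(deregulated) %in%
                               igraph::V(network)$name]
    coreNodes <- modelNodes(core)
    passing <- deregulated[abs(deregulated) >= threshold]
    derCore <- intersect(coreNodes, names(passing))

    ext <- character(0)
    if (length(derCore) > 0L) {
        candidates <- setdiff(names(passing), coreNodes)
        if (length(candidates) > 0L) {
            nbr <- igraph::adjacent_vertices(network, derCore)
            nbrNames <- unique(unlist(lapply(nbr, function(v) v$name)))
            ext <- sort(intersect(candidates, nbrNames))
        }
    }

    nodes <- c(coreNodes, ext)
    src <- setNames(rep("expression", length(nodes)), nodes)
    src[coreNodes] <- nodeData(core)[coreNodes, "source"]
    src[derCore] <- "both"
    der <- setNames(rep(FALSE, length(nodes)), nodes)
    der[c(derCore, ext)] <- TRUE
    sfc <- setNames(rep(NA_real_, length(nodes)), nodes)
    sfc[names(passing)[names(passing) %in% nodes]] <-
        passing[names(passing) %in% nodes]
    edges <- .induceEdges(network, nodes)
    .newModel(nodes, edges, src, der, sfc)
}
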