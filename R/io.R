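# Readers and writers for the plain-text interchange formats: edge-list
# TSV / SIF interactomes, gene-set text files, expression matrix +
# probe-annotation TSVs, model / signature JSON, and trial CSVs.

#' Read an interactome from an edge-list TSV or SIF file
#'
#' Two-column TSV files are read as (gene_a, gene_b) undirected edges;
#' three-column files are treated as SIF (gene_a, interaction_type,
#' gene_b). Self-loops and duplicate edges are dropped.
#'
#' @param path file path.
#' @return an undirected simple \code{igraph} graph with named vertices.
#' @export
readInteractome <- function(path) {
    d <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
    el <- if (ncol(d) >= 3) cbind(d[[1]], d[[3]]) else cbind(d[[1]], d[[2]])
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    igraph::simplify(g)
}

#' Write an interactome as a two-column edge-list TSV
#'
#' One undirected edge per line, endpoints lexicographically ordered within
#' each line and lines sorted, no duplicates.
#'
#' @param network igraph graph with named vertices.
#' @param path output file path.
#' @export
writeInteractome <- function(network, path) {
    el <- igraph::as_edgelist(network)
    swap <- el[, 1] > el[, 2]
    el[swap, ] <- el[swap, c(2, 1)]
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
    write.table(el, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read / write a one-column gene-set text file
#' @param path file path.
#' @return character vector of gene identifiers.
#' @export
readGeneSet <- function(path) {
    x <- readLines(path)
    x <- trimws(x)
    unique(x[nzchar(x)])
}

#' @rdname readGeneSet
#' @param genes character vector of gene identifiers.
#' @export
writeGeneSet <- function(genes, path) {
    writeLines(as.character(genes), path)
    invisible(path)
}

#' Read an expression matrix TSV plus its probe-annotation TSV
#'
#' The matrix file has probe identifiers in the first column and sample
#' identifiers as header; the annotation file has columns (probe, gene).
#' Group labels are taken from the \code{groups} argument or, when absent,
#' inferred from the sample-name prefix before the last underscore
#' (\code{treated_1}, \code{control_2}, ...).
#'
#' @param matrixPath path of the intensity matrix TSV.
#' @param annotationPath path of the probe-to-gene annotation TSV.
#' @param groups optional named character vector sample -> group.
#' @return a probe-level \code{SummarizedExperiment}.
#' @export
readExpression <- function(matrixPath, annotationPath, groups = NULL) {
    m <- read.table(matrixPath, sep = "\t", header = TRUE,
                    row.names = 1, check.names = FALSE)
    ann <- read.table(annotationPath, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
    gene <- setNames(ann[[2]], ann[[1]])[rownames(m)]
    if (is.null(groups))
        groups <- setNames(sub("_[^_]*$", "", colnames(m)), colnames(m))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = as.matrix(m)),
        rowData = S4Vectors::DataFrame(gene = unname(gene),
                                       row.names = rownames(m)),
        colData = S4Vectors::DataFrame(group = unname(groups[colnames(m)]),
                                       row.names = colnames(m)))
}

#' @rdname readExpression
#' @param se a probe-level \code{SummarizedExperiment}.
#' @export
writeExpression <- function(se, matrixPath, annotationPath) {
    m <- SummarizedExperiment::assay(se, 1)
    out <- data.frame(probe = rownames(m), m, check.names = FALSE)
    write.table(out, matrixPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    ann <- data.frame(probe = rownames(m),
                      gene = SummarizedExperiment::rowData(se)$gene)
    write.table(ann, annotationPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(matrixPath)
}

#' Write / read a molecular model as JSON
#'
#' Nodes are stored with their attributes (source, deregulated, signed
#' fold change) together with the induced edge list.
#'
#' @param model a [MolecularModel-class].
#' @param path JSON file path.
#' @export
writeModelJSON <- function(model, path) {
    nd <- nodeData(model)
    obj <- list(nodes = data.frame(gene = rownames(nd), nd,
                                   row.names = NULL),
                edges = as.data.frame(modelEdges(model)))
    jsonlite::write_json(obj, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- obj$nodes
    edges <- if (length(obj$edges)) {
        as.matrix(obj$edges)
    } else {
        matrix(character(0), ncol = 2)
    }
    dimnames(edges) <- list(NULL, c("from", "to"))
    sfc <- if ("signedFC" %in% names(nodes)) nodes$signedFC
           else rep(NA_real_, nrow(nodes))
    methods::new("MolecularModel", nodes = nodes$gene, edges = edges,
                 nodeData = data.frame(source = nodes$source,
                                       deregulated = nodes$deregulated,
                                       signedFC = as.numeric(sfc),
                                       row.names = nodes$gene))
}

#' Write an interference signature as JSON
#' @param signature an [InterferenceSignature-class].
#' @param path JSON file path.
#' @export
writeSignatureJSON <- function(signature, path) {
    jsonlite::write_json(
        list(sharedNodes = sharedNodes(signature),
             sharedEdges = as.data.frame(sharedEdges(signature))),
        path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read / write a longitudinal trial dataset
#'
#' The records file is a long CSV with header
#' \code{subject,arm,visit_week,biomarker,value}; the covariates file is a
#' CSV keyed by its \code{subject} column.
#'
#' @param recordsPath path of the long-format records CSV.
#' @param covariatesPath path of the per-subject covariates CSV.
#' @return a [TrialData-class].
#' @export
readTrial <- function(recordsPath, covariatesPath) {
    r <- utils::read.csv(recordsPath, stringsAsFactors = FALSE)
    names(r)[names(r) == "visit_week"] <- "visitWeek"
    cov <- utils::read.csv(covariatesPath, stringsAsFactors = FALSE)
    rownames(cov) <- cov$subject
    cov$subject <- NULL
    methods::new("TrialData", records = r, covariates = cov)
}

#' @rdname readTrial
#' @param trial a [TrialData-class].
#' @export
writeTrial <- function(trial, recordsPath, covariatesPath) {
    r <- trialRecords(trial)
    names(r)[names(r) == "visitWeek"] <- "visit_week"
    utils::write.csv(r, recordsPath, row.names = FALSE, quote = FALSE)
    cov <- trialCovariates(trial)
    utils::write.csv(data.frame(subject = rownames(cov), cov,
                                row.names = NULL),
                     covariatesPath, row.names = FALSE, quote = FALSE)
    invisible(recordsPath)
}
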