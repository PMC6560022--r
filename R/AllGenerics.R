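#' @rdname MolecularModel-class
#' @param object,x a \code{MolecularModel}, \code{InterferenceSignature} or
#'   \code{TrialData} object.
#' @export
setGeneric("modelNodes", function(x) standardGeneric("modelNodes"))

#' @rdname MolecularModel-class
#' @export
setGeneric("modelEdges", function(x) standardGeneric("modelEdges"))

#' @rdname MolecularModel-class
#' @export
setGeneric("nodeData", function(x) standardGeneric("nodeData"))

#' @rdname InterferenceSignature-class
#' @export
setGeneric("sharedNodes", function(x) standardGeneric("sharedNodes"))

#' @rdname InterferenceSignature-class
#' @export
setGeneric("sharedEdges", function(x) standardGeneric("sharedEdges"))

#' @rdname TrialData-class
#' @export
setGeneric("trialRecords", function(x) standardGeneric("trialRecords"))

#' @rdname TrialData-class
#' @export
setGeneric("trialCovariates", function(x) standardGeneric("trialCovariates"))

#' @rdname MolecularModel-class
#' @export
setMethod("modelNodes", "MolecularModel", function(x) x@nodes)

#' @rdname MolecularModel-class
#' @export
setMethod("modelEdges", "MolecularModel", function(x) x@edges)

#' @rdname MolecularModel-class
#' @export
setMethod("nodeData", "MolecularModel", function(x) x@nodeData)

#' @rdname InterferenceSignature-class
#' @export
setMethod("sharedNodes", "InterferenceSignature", function(x) x@sharedNodes)

#' @rdname InterferenceSignature-class
#' @export
setMethod("sharedEdges", "InterferenceSignature", function(x) x@sharedEdges)

#' @rdname TrialData-class
#' @export
setMethod("trialRecords", "TrialData", function(x) x@records)

#' @rdname TrialData-class
#' @export
setMethod("trialCovariates", "TrialData", function(x) x@covariates)

#' @rdname MolecularModel-class
#' @export
setMethod("show", "MolecularModel", function(object) {
    nd <- object@nodeData
    cat("MolecularModel with", length(object@nodes), "nodes and",
        nrow(object@edges), "edges\n")
    if (nrow(nd)) {
        cat("  sources:",
            paste(sprintf("%s=%d", names(table(nd$source)), table(nd$source)),
                  collapse = ", "), "\n")
        cat("  deregulated nodes:", sum(nd$deregulated), "\n")
    }
    invisible(NULL)
})

#' @rdname InterferenceSignature-class
#' @export
setMethod("show", "InterferenceSignature", function(object) {
    cat("InterferenceSignature:", length(object@sharedNodes),
        "shared nodes,", nrow(object@sharedEdges), "shared edges\n")
    invisible(NULL)
})

#' @rdname TrialData-class
#' @export
setMethod("show", "TrialData", function(object) {
    r <- object@records
    cat("TrialData:", length(unique(r$subject)), "subjects,",
        length(unique(r$arm)), "arms,",
        length(unique(r$visitWeek)), "visits,",
        length(unique(r$biomarker)), "biomarkers,",
        nrow(r), "records\n")
    invisible(NULL)
})

#' @rdname MMRMFit-class
#' @param object an \code{MMRMFit}.
#' @export
setMethod("show", "MMRMFit", function(object) {
    cat("MMRM fit for biomarker", sQuote(object@biomarker),
        if (object@logTransform) "(log scale)" else "(percentage change)",
        "\n  arms:", paste(object@arms, collapse = ", "),
        "\n  post-baseline visits:", paste(object@visits, collapse = ", "),
        "\n  converged:", object@converged, "\n")
    invisible(NULL)
})
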