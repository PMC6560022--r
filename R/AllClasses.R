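#' @import methods
#' @importFrom stats pnorm qnorm rnorm rbinom rlnorm runif cor.test coef vcov
#'   model.matrix complete.cases setNames sd quantile
#' @importFrom utils read.table write.table head
NULL

# canonical undirected edge key: endpoints sorted lexicographically, "|"-joined
.edgeKey <- function(a, b) {
    swap <- a > b
    key1 <- ifelse(swap, b, a)
    key2 <- ifelse(swap, a, b)
    paste(key1, key2, sep = "|")
}

.keyToEdges <- function(keys) {
    if (length(keys) == 0L) {
        return(matrix(character(0), ncol = 2L,
                      dimnames = list(NULL, c("from", "to"))))
    }
    parts <- strsplit(keys, "|", fixed = TRUE)
    matrix(c(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L)),
           ncol = 2L, dimnames = list(NULL, c("from", "to")))
}

#' Molecular network model
#'
#' A molecular model is a gene set mapped onto an interactome together with
#' its induced protein-protein interactions. Nodes carry provenance
#' (\code{"literature"}, \code{"expression"}, or \code{"both"}), a
#' deregulation flag and, where known, a signed fold change. By construction
#' a model contains no isolated nodes: literature genes enter only if they
#' interact with at least one other member, and expression-derived extension
#' genes are attached through an interaction with a deregulated core gene.
#'
#' @slot nodes character vector of gene identifiers.
#' @slot edges two-column character matrix of undirected interactions
#'   (endpoints lexicographically ordered within each row, rows sorted,
#'   no duplicates, no self-loops).
#' @slot nodeData \code{data.frame} with one row per node (rownames = gene):
#'   columns \code{source}, \code{deregulated}, \code{signedFC}.
#'
#' @seealso [extractConnectedSubmodel()], [extendMoaModel()]
#' @export
setClass("MolecularModel",
    representation(nodes = "character",
                   edges = "matrix",
                   nodeData = "data.frame"))

setValidity("MolecularModel", function(object) {
    msg <- character(0)
    e <- object@edges
    if (ncol(e) != 2L)
        msg <- c(msg, "edges must be a two-column matrix")
    if (nrow(e) > 0L) {
        if (!all(c(e[, 1L], e[, 2L]) %in% object@nodes))
            msg <- c(msg, "edge endpoints must be model nodes")
        if (any(e[, 1L] == e[, 2L]))
            msg <- c(msg, "self-loops are not allowed")
        if (anyDuplicated(.edgeKey(e[, 1L], e[, 2L])))
            msg <- c(msg, "duplicate edges are not allowed")
    }
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "duplicate nodes")
    if (!identical(sort(rownames(object@nodeData)), sort(object@nodes)))
        msg <- c(msg, "nodeData rownames must match nodes")
    if (length(msg)) msg else TRUE
})

#' Interference signature of two molecular models
#'
#' The shared nodes and shared interactions of two molecular models built on
#' the same interactome: the region of the disease model affected by the
#' drug, used as the pool of candidate response biomarkers.
#'
#' @slot sharedNodes character vector of genes present in both models.
#' @slot sharedEdges two-column character matrix of interactions present in
#'   both models.
#'
#' @seealso [computeInterference()], [rankCandidates()]
#' @export
setClass("InterferenceSignature",
    representation(sharedNodes = "character", sharedEdges = "matrix"))

setValidity("InterferenceSignature", function(object) {
    e <- object@sharedEdges
    if (ncol(e) != 2L)
        return("sharedEdges must be a two-column matrix")
    if (nrow(e) > 0L && !all(c(e[, 1L], e[, 2L]) %in% object@sharedNodes))
        return("sharedEdges endpoints must be shared nodes")
    TRUE
})

#' Longitudinal trial dataset
#'
#' Long-format biomarker measurements from a randomised trial, one record
#' per (subject, biomarker, visit), plus a baseline covariate table keyed by
#' subject. Week 0 is the baseline visit.
#'
#' @slot records \code{data.frame} with columns \code{subject}, \code{arm},
#'   \code{visitWeek}, \code{biomarker}, \code{value}.
#' @slot covariates \code{data.frame} keyed by rowname = subject; typical
#'   columns: \code{age}, \code{sex}, \code{sbp}, \code{dbp}, \code{bmi},
#'   \code{hba1c}, \code{egfr}, \code{uacr}.
#'
#' @seealso [simulateTrial()], [fitMMRM()]
#' @export
setClass("TrialData",
    representation(records = "data.frame", covariates = "data.frame"))

setValidity("TrialData", function(object) {
    r <- object@records
    need <- c("subject", "arm", "visitWeek", "biomarker", "value")
    if (!all(need %in% names(r)))
        return(paste("records must have columns:",
                     paste(need, collapse = ", ")))
    if (anyDuplicated(r[, c("subject", "biomarker", "visitWeek")]))
        return("each (subject, biomarker, visit) may appear at most once")
    if (any(!is.na(r$value) & r$value <= 0) &&
        !all(r$biomarker[!is.na(r$value) & r$value <= 0] == "eGFR"))
        return("biomarker values must be positive")
    TRUE
})

#' Fitted mixed-model repeated measures (MMRM) analysis
#'
#' A marginal linear model for one biomarker with fixed effects for
#' treatment, visit, their interaction and the baseline level, and an
#' unstructured within-subject covariance over post-baseline visits,
#' estimated by REML.
#'
#' @slot fit the underlying \code{\link[nlme]{gls}} fit.
#' @slot data the analysis \code{data.frame} the model was fitted to.
#' @slot biomarker name of the modelled biomarker.
#' @slot logTransform whether the response is the natural log of the value
#'   (otherwise: percentage change from baseline).
#' @slot visits post-baseline visit weeks in the fit.
#' @slot arms arm labels (first level is the reference).
#' @slot converged logical convergence flag.
#'
#' @seealso [fitMMRM()], [estimateContrast()]
#' @export
setClass("MMRMFit",
    representation(fit = "ANY", data = "data.frame", biomarker = "character",
                   logTransform = "logical", visits = "numeric",
                   arms = "character", converged = "logical"))
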