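# Network interference analysis: the shared nodes and shared interactions
# of two molecular models, plus literature-evidence filtering and
# proximity-based candidate-biomarker ranking.

#' Compute the interference signature of two molecular models
#'
#' The signature is the set of genes present in both models together with
#' the interactions present in both models. Since both models carry the
#' interactome-induced edge set on their nodes, the shared edges equal the
#' induced edge set on the shared nodes. The operation is symmetric in its
#' arguments; an empty intersection is a valid result.
#'
#' @param modelA,modelB [MolecularModel-class] objects built on the same
#'   interactome namespace.
#' @return an [InterferenceSignature-class].
#' @export
computeInterference <- function(modelA, modelB) {
    nodes <- sort(intersect(modelNodes(modelA), modelNodes(modelB)))
    ea <- modelEdges(modelA)
    eb <- modelEdges(modelB)
    keysA <- .edgeKey(ea[, 1L], ea[, 2L])
    keysB <- .edgeKey(eb[, 1L], eb[, 2L])
    shared <- sort(intersect(keysA, keysB))
    methods::new("InterferenceSignature", sharedNodes = nodes,
                 sharedEdges = .keyToEdges(shared))
}

.normTerm <- function(x) {
    tolower(gsub("\\s+", " ", trimws(x)))
}

.splitMulti <- function(x) {
    lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
           function(v) unique(.normTerm(v[nzchar(trimws(v))])))
}

#' Count prognostic literature evidence per gene
#'
#' Applies the publication-level evidence rule to a literature annotation
#' table: a publication counts for a gene when it carries the required
#' major-topic term, carries all additionally required terms, is annotated
#' with at least one allowed study context, and carries none of the
#' excluded flags (by default, high-throughput omics profiling studies are
#' excluded). Term matching is case-insensitive after whitespace
#' normalisation. Genes with at least one qualifying publication are
#' considered prognostic.
#'
#' @param annotation \code{data.frame} with columns \code{gene},
#'   \code{publication_id}, \code{terms}, \code{major_terms},
#'   \code{study_flags}; multi-valued columns are \code{";"}-separated.
#' @param requiredMajor term that must appear among the major-topic terms.
#' @param requiredTerms terms that must all appear among the annotation
#'   terms (major or minor).
#' @param allowedContexts study flags of which at least one must be
#'   present.
#' @param excludeFlags study flags of which none may be present.
#' @return named integer vector: qualifying publication count per gene
#'   (genes with zero evidence are absent).
#' @export
filterPrognosticEvidence <- function(annotation,
        requiredMajor = "diabetic nephropathies",
        requiredTerms = c("biological markers", "prognosis"),
        allowedContexts = c("human", "animal_model", "clinical_trial"),
        excludeFlags = "omics_profiling") {
    need <- c("gene", "publication_id", "terms", "major_terms",
              "study_flags")
    if (!all(need %in% names(annotation)))
        stop("annotation must have columns: ", paste(need, collapse = ", "))
    if (nrow(annotation) == 0L)
        return(setNames(integer(0), character(0)))
    if (any(is.na(annotation$publication_id) |
            !nzchar(trimws(annotation$publication_id))))
        stop("publication_id must be non-empty")
    terms <- .splitMulti(annotation$terms)
    major <- .splitMulti(annotation$major_terms)
    flags <- .splitMulti(annotation$study_flags)
    requiredMajor <- .normTerm(requiredMajor)
    requiredTerms <- .normTerm(requiredTerms)
    allowedContexts <- .normTerm(allowedContexts)
    excludeFlags <- .normTerm(excludeFlags)
    ok <- vapply(seq_len(nrow(annotation)), function(i) {
        allTerms <- union(terms[[i]], major[[i]])
        requiredMajor %in% major[[i]] &&
            all(requiredTerms %in% allTerms) &&
            any(allowedContexts %in% flags[[i]]) &&
            !any(excludeFlags %in% flags[[i]])
    }, logical(1))
    hit <- unique(annotation[ok, c("gene", "publication_id")])
    counts <- table(hit$gene)
    setNames(as.integer(counts), names(counts))
}

#' Rank candidate biomarkers by interference-signature proximity
#'
#' Prognostic genes inside the interference signature form the
#' \code{"in_signature"} tier (distance 0); prognostic genes within
#' \code{proximityMax} interaction steps of any signature gene, measured on
#' the full interactome, form the \code{"proximal"} tier. Candidates are
#' ordered by tier, then distance, then descending evidence count, then
#' gene identifier, making the output deterministic.
#'
#' @param signature an [InterferenceSignature-class].
#' @param network the interactome graph (distances are measured here, not
#'   within either model, so proximity can recruit genes outside the
#'   signature).
#' @param prognostic character vector of prognostic genes, or the named
#'   evidence-count vector from [filterPrognosticEvidence()].
#' @param proximityMax largest shortest-path distance that still counts as
#'   "close proximity" (default 1 = direct interaction partner); 0
#'   restricts to signature members.
#' @return \code{data.frame} with columns \code{gene}, \code{tier},
#'   \code{distance}, \code{evidenceCount}.
#' @export
rankCandidates <- function(signature, network, prognostic,
                           proximityMax = 1) {
    if (proximityMax < 0)
        stop("proximityMax must be >= 0")
    evidence <- if (is.null(names(prognostic))) {
        setNames(rep(1L, length(prognostic)), as.character(prognostic))
    } else {
        prognostic
    }
    genes <- names(evidence)
    known <- genes %in% igraph::V(network)$name
    if (!all(known)) {
        warning(sum(!known), " prognostic gene(s) not in the interactome, ",
                "dropped")
        evidence <- evidence[known]
        genes <- genes[known]
    }
    sig <- sharedNodes(signature)
    empty <- data.frame(gene = character(0), tier = character(0),
                        distance = integer(0), evidenceCount = integer(0))
    if (length(genes) == 0L || length(sig) == 0L)
        return(empty)
    d <- igraph::distances(network, v = genes, to = sig)
    dmin <- apply(d, 1L, min)
    keep <- is.finite(dmin) & dmin <= proximityMax
    if (!any(keep))
        return(empty)
    out <- data.frame(gene = genes[keep],
                      tier = ifelse(dmin[keep] == 0,
                                    "in_signature", "proximal"),
                      distance = as.integer(dmin[keep]),
                      evidenceCount = as.integer(evidence[keep]),
                      row.names = NULL)
    out[order(match(out$tier, c("in_signature", "proximal")), out$distance,
              -out$evidenceCount, out$gene), , drop = FALSE] |>
        (\(x) {rownames(x) <- NULL; x})()
}
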