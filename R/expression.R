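# Fold-change filtering of two-arm expression data. The deregulation rule
# is a signed-ratio threshold (default 1.2-fold, inclusive) on the ratio of
# arithmetic group means; an optional Welch test can be layered on top but
# the rule itself is fold-change-only.

.checkExpression <- function(se) {
    if (!methods::is(se, "SummarizedExperiment"))
        stop("expected a SummarizedExperiment")
    if (!"group" %in% names(SummarizedExperiment::colData(se)))
        stop("colData(se) must have a 'group' column")
    grp <- SummarizedExperiment::colData(se)$group
    if (!all(grp %in% c("treated", "control")))
        stop("groups must be 'treated' or 'control'")
    if (!all(c("treated", "control") %in% grp))
        stop("both groups must be non-empty")
    vals <- SummarizedExperiment::assay(se, 1L)
    if (any(vals <= 0))
        stop("intensities must be positive")
    invisible(vals)
}

#' Summarize probe-level intensities to gene level
#'
#' Collapses probes mapping to the same gene to their arithmetic mean per
#' sample. Probes without a gene annotation (\code{NA} or empty) are
#' dropped. Group labels are preserved. The result is invariant to probe
#' row order.
#'
#' @param se probe-level \code{SummarizedExperiment} with assay of positive
#'   intensities, \code{rowData(se)$gene} annotation and
#'   \code{colData(se)$group} in \code{{"treated", "control"}}.
#' @return a gene-level \code{SummarizedExperiment}, one row per distinct
#'   annotated gene (rows sorted by gene).
#' @export
summarizeProbes <- function(se) {
    vals <- .checkExpression(se)
    gene <- SummarizedExperiment::rowData(se)$gene
    if (is.null(gene))
        stop("rowData(se) must have a 'gene' column")
    gene <- as.character(gene)
    keep <- !is.na(gene) & nzchar(gene)
    if (!any(keep))
        stop("no probe carries a gene annotation")
    vals <- vals[keep, , drop = FALSE]
    gene <- gene[keep]
    sums <- rowsum(vals, group = gene, reorder = TRUE)
    counts <- as.vector(table(gene)[rownames(sums)])
    means <- sums / counts
    SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = means),
        rowData = S4Vectors::DataFrame(gene = rownames(means),
                                       row.names = rownames(means)),
        colData = SummarizedExperiment::colData(se))
}

#' Compute signed fold changes between treated and control arms
#'
#' For each gene the ratio \eqn{r} of arithmetic group means
#' (treated / control) is encoded as a signed fold change: \eqn{r} when
#' \eqn{r \ge 1}, \eqn{-1/r} otherwise, so the magnitude is symmetric in
#' direction and never below 1. A Welch two-sample t-test on log
#' intensities is attached when each group has at least two samples.
#'
#' @param geneSE gene-level \code{SummarizedExperiment} (from
#'   [summarizeProbes()], or probe-level data with one probe per gene).
#' @return \code{data.frame} with columns \code{gene}, \code{treatedMean},
#'   \code{controlMean}, \code{signedFC} and, when computable,
#'   \code{pValue}.
#' @export
computeFoldChanges <- function(geneSE) {
    vals <- .checkExpression(geneSE)
    grp <- SummarizedExperiment::colData(geneSE)$group
    tIdx <- grp == "treated"
    cIdx <- grp == "control"
    tm <- rowMeans(vals[, tIdx, drop = FALSE])
    cm <- rowMeans(vals[, cIdx, drop = FALSE])
    if (any(tm <= 0) || any(cm <= 0))
        stop("group means must be positive")
    r <- tm / cm
    signedFC <- ifelse(r >= 1, r, -1 / r)
    gene <- SummarizedExperiment::rowData(geneSE)$gene
    if (is.null(gene)) gene <- rownames(vals)
    out <- data.frame(gene = as.character(gene), treatedMean = tm,
                      controlMean = cm, signedFC = signedFC,
                      row.names = NULL)
    if (sum(tIdx) >= 2 && sum(cIdx) >= 2) {
        lv <- log(vals)
        out$pValue <- vapply(seq_len(nrow(lv)), function(i) {
            x <- lv[i, tIdx]; y <- lv[i, cIdx]
            if (sd(x) == 0 && sd(y) == 0)
                return(if (mean(x) == mean(y)) 1 else 0)
            stats::t.test(x, y)$p.value
        }, numeric(1))
    }
    out
}

#' Select deregulated genes by the fold-change criterion
#'
#' Keeps genes whose signed fold-change magnitude meets the threshold
#' (default 1.2-fold, inclusive comparison) and labels each as
#' \code{"up"} or \code{"down"}. Setting \code{strict = TRUE} switches to a
#' strict \code{>} comparison. An optional p-value cutoff additionally
#' requires the Welch test attached by [computeFoldChanges()] to pass; it
#' is off by default, so selection is fold-change-only.
#'
#' @param fcTable a fold-change table from [computeFoldChanges()].
#' @param threshold fold-change magnitude threshold, at least 1.
#' @param strict use strict inequality instead of the default inclusive one.
#' @param maxP optional p-value cutoff (requires a \code{pValue} column).
#' @return \code{data.frame} with columns \code{gene}, \code{direction},
#'   \code{signedFC}, ordered by decreasing magnitude.
#' @export
selectDeregulated <- function(fcTable, threshold = 1.2, strict = FALSE,
                              maxP = NULL) {
    if (threshold < 1)
        stop("threshold must be >= 1")
    mag <- abs(fcTable$signedFC)
    keep <- if (strict) mag > threshold else mag >= threshold
    if (!is.null(maxP)) {
        if (is.null(fcTable$pValue))
            stop("maxP given but fcTable has no pValue column")
        keep <- keep & fcTable$pValue <= maxP
    }
    sel <- fcTable[keep, , drop = FALSE]
    out <- data.frame(gene = sel$gene,
                      direction = ifelse(sel$signedFC > 0, "up", "down"),
                      signedFC = sel$signedFC, row.names = NULL)
    out[order(-abs(out$signedFC), out$gene), , drop = FALSE]
}
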