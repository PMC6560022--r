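# Synthetic-data generators: interactome, planted gene sets, two-arm
# expression data, and longitudinal trial data with known planted truth.
# Every generator is a pure function of (config, seed); sub-generators use
# independent streams derived from the single config seed.

.deriveSeed <- function(seed, tag) {
    h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    as.integer((as.numeric(seed) * 2654435 + h * 97) %% 2147483647)
}

#' Simulation configuration
#'
#' Bundles all parameters of the synthetic-data generators and checks their
#' joint feasibility. Defaults describe the study conditions the pipeline is
#' exercised under: a scale-free interactome of 1000 genes, literature gene
#' sets of 60 (disease) and 30 (drug) genes sharing 10, 20 planted
#' deregulated genes with fold-change magnitudes in [1.5, 2.5], four
#' replicates per expression arm with 5\% multiplicative noise, and a
#' two-arm, three-visit trial (weeks 0/52/104, 100 subjects per arm) in
#' which the treated arm's post-baseline biomarker levels are multiplied
#' by 0.75.
#'
#' @param interactomeSize number of genes in the simulated interactome.
#' @param attachment edges added per new node during preferential attachment.
#' @param diseaseSetSize,drugSetSize sizes of the planted literature gene
#'   sets.
#' @param plantedOverlap number of genes in both sets.
#' @param nDeGenes number of planted deregulated genes.
#' @param fcLow,fcHigh bounds of the planted fold-change magnitude
#'   (\code{fcLow >= 1}).
#' @param noiseSd standard deviation of expression noise on the natural-log
#'   scale.
#' @param nReplicates biological replicates per expression arm.
#' @param probesPerGene array probes per gene.
#' @param nSubjectsPerArm trial subjects per arm.
#' @param visitWeeks trial visit weeks; must include 0 (baseline).
#' @param plantedEffects named list, one element per arm, each a numeric
#'   vector named by post-baseline visit week giving the multiplicative
#'   effect on the biomarker level at that visit.
#' @param withinSubjectCorr within-subject correlation of log biomarker
#'   values across visits, in [0, 1).
#' @param trialSd total standard deviation of the log biomarker value
#'   (subject intercept + residual).
#' @param dropout per-visit probability that a subject's follow-up stops
#'   (monotone missing-at-random); 0 disables dropout.
#' @param seed integer seed; all generators derive independent streams
#'   from it.
#'
#' @return a list of class \code{"SimulationConfig"}.
#' @examples
#' cfg <- simulationConfig(interactomeSize = 200, seed = 1)
#' net <- simulateInteractome(cfg$interactomeSize, cfg$attachment, cfg$seed)
#' @export
simulationConfig <- function(interactomeSize = 1000,
                             attachment = 2,
                             diseaseSetSize = 60,
                             drugSetSize = 30,
                             plantedOverlap = 10,
                             nDeGenes = 20,
                             fcLow = 1.5,
                             fcHigh = 2.5,
                             noiseSd = 0.05,
                             nReplicates = 4,
                             probesPerGene = 1,
                             nSubjectsPerArm = 100,
                             visitWeeks = c(0, 52, 104),
                             plantedEffects = list(
                                 control = c("52" = 1, "104" = 1),
                                 treated = c("52" = 0.75, "104" = 0.75)),
                             withinSubjectCorr = 0.5,
                             trialSd = 0.4,
                             dropout = 0,
                             seed = 1L) {
    stopifnot(interactomeSize >= 2, attachment >= 1,
              attachment < interactomeSize,
              diseaseSetSize >= 0, drugSetSize >= 0, plantedOverlap >= 0,
              nDeGenes >= 0, nReplicates >= 1, probesPerGene >= 1,
              nSubjectsPerArm >= 1, dropout >= 0, dropout < 1)
    if (fcLow < 1)
        stop("fcLow must be >= 1 (fold-change magnitudes)")
    if (fcHigh < fcLow)
        stop("fcHigh must be >= fcLow")
    if (noiseSd < 0)
        stop("noiseSd must be non-negative")
    if (plantedOverlap > min(diseaseSetSize, drugSetSize))
        stop("plantedOverlap exceeds a set size")
    if (diseaseSetSize + drugSetSize - plantedOverlap > interactomeSize)
        stop("gene sets do not fit in the interactome")
    if (!0 %in% visitWeeks || length(visitWeeks) < 2)
        stop("visitWeeks must include 0 and at least one later visit")
    if (withinSubjectCorr < 0 || withinSubjectCorr >= 1)
        stop("withinSubjectCorr must be in [0, 1)")
    post <- sort(setdiff(visitWeeks, 0))
    for (arm in names(plantedEffects)) {
        eff <- plantedEffects[[arm]]
        if (!all(as.character(post) %in% names(eff)))
            stop("plantedEffects for arm ", arm,
                 " must name every post-baseline visit")
        if (any(eff <= 0))
            stop("planted effects must be positive")
    }
    structure(list(interactomeSize = as.integer(interactomeSize),
                   attachment = as.integer(attachment),
                   diseaseSetSize = as.integer(diseaseSetSize),
                   drugSetSize = as.integer(drugSetSize),
                   plantedOverlap = as.integer(plantedOverlap),
                   nDeGenes = as.integer(nDeGenes),
                   fcLow = fcLow, fcHigh = fcHigh, noiseSd = noiseSd,
                   nReplicates = as.integer(nReplicates),
                   probesPerGene = as.integer(probesPerGene),
                   nSubjectsPerArm = as.integer(nSubjectsPerArm),
                   visitWeeks = sort(unique(visitWeeks)),
                   plantedEffects = plantedEffects,
                   withinSubjectCorr = withinSubjectCorr,
                   trialSd = trialSd, dropout = dropout,
                   seed = as.integer(seed)),
              class = "SimulationConfig")
}

#' Simulate a scale-free interactome
#'
#' Grows an undirected simple connected graph by preferential attachment:
#' \code{attachment} seed nodes, then each new node attaches
#' \code{attachment} edges to distinct existing nodes chosen with
#' probability proportional to degree. The result has
#' \code{attachment * (n - attachment)} edges and a heavy-tailed degree
#' distribution, the shape of curated protein-interaction networks.
#'
#' @param n number of genes (nodes), at least 2.
#' @param attachment edges per new node, in \code{[1, n)}.
#' @param seed optional integer seed for reproducibility.
#' @return an undirected \code{\link[igraph]{igraph}} graph with named
#'   vertices.
#' @examples
#' net <- simulateInteractome(50, 2, seed = 7)
#' igraph::ecount(net)  # 96
#' @export
simulateInteractome <- function(n, attachment, seed = NULL) {
    if (n < 2)
        stop("n must be at least 2")
    if (attachment < 1 || attachment >= n)
        stop("attachment must be in [1, n)")
    n <- as.integer(n); m <- as.integer(attachment)
    if (!is.null(seed))
        set.seed(as.integer(seed))
    fmt <- paste0("g%0", max(4L, nchar(n)), "d")
    from <- integer((n - m) * m)
    to <- integer((n - m) * m)
    # `repeated` lists each node once per unit of degree, so uniform picks
    # from it are degree-proportional
    repeated <- integer(0)
    targets <- seq_len(m)
    k <- 0L
    for (v in seq.int(m + 1L, n)) {
        idx <- k + seq_len(m)
        from[idx] <- v
        to[idx] <- targets
        k <- k + m
        repeated <- c(repeated, targets, rep.int(v, m))
        if (v < n) {
            targets <- integer(0)
            while (length(targets) < m) {
                cand <- repeated[sample.int(length(repeated), 1L)]
                if (!cand %in% targets)
                    targets <- c(targets, cand)
            }
        }
    }
    el <- cbind(sprintf(fmt, from), sprintf(fmt, to))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    igraph::permute(g, match(igraph::V(g)$name,
                             sort(igraph::V(g)$name)))
}

#' Plant disease and drug literature gene sets
#'
#' Samples a disease gene set and a drug literature gene set of the
#' configured sizes from the interactome nodes, without replacement, with
#' exactly \code{plantedOverlap} genes in common.
#'
#' @param network an interactome as returned by [simulateInteractome()].
#' @param config a [simulationConfig()].
#' @return a list with elements \code{diseaseGenes} and
#'   \code{drugLiteratureGenes} (character vectors).
#' @export
simulateGeneSets <- function(network, config) {
    nodes <- igraph::V(network)$name
    if (config$diseaseSetSize + config$drugSetSize - config$plantedOverlap >
        length(nodes))
        stop("gene sets do not fit in this interactome")
    set.seed(.deriveSeed(config$seed, "genesets"))
    both <- sample(nodes, config$plantedOverlap)
    rest <- setdiff(nodes, both)
    disOnly <- sample(rest, config$diseaseSetSize - config$plantedOverlap)
    rest <- setdiff(rest, disOnly)
    drugOnly <- sample(rest, config$drugSetSize - config$plantedOverlap)
    list(diseaseGenes = sort(c(both, disOnly)),
         drugLiteratureGenes = sort(c(both, drugOnly)))
}

#' Simulate two-arm probe-level expression data with planted fold changes
#'
#' Draws per-gene baseline intensities from a log-normal distribution,
#' multiplies treated-arm means of the planted deregulated genes by their
#' planted fold change (signed convention: magnitude \code{r} up, or
#' \code{1/r} down), applies multiplicative log-normal noise of standard
#' deviation \code{noiseSd}, and expands each gene into
#' \code{probesPerGene} probes with probe-specific affinities.
#'
#' @param network interactome graph; its nodes are the gene universe.
#' @param config a [simulationConfig()].
#' @param deGenes optional named numeric vector of signed fold changes to
#'   plant; when \code{NULL}, \code{nDeGenes} genes are sampled with
#'   magnitudes uniform in \code{[fcLow, fcHigh]} and random direction.
#' @return a list: \code{se}, a
#'   \code{\link[SummarizedExperiment]{SummarizedExperiment}} with assay
#'   \code{intensity}, \code{rowData(se)$gene} probe annotation and
#'   \code{colData(se)$group} labels; and \code{deGenes}, the planted
#'   truth as a named signed fold-change vector.
#' @export
simulateExpression <- function(network, config, deGenes = NULL) {
    if (config$noiseSd < 0)
        stop("noiseSd must be non-negative")
    genes <- sort(igraph::V(network)$name)
    set.seed(.deriveSeed(config$seed, "expression"))
    if (is.null(deGenes)) {
        if (config$nDeGenes > length(genes))
            stop("more planted deregulated genes than interactome genes")
        de <- sample(genes, config$nDeGenes)
        mag <- runif(length(de), config$fcLow, config$fcHigh)
        sgn <- sample(c(1, -1), length(de), replace = TRUE)
        deGenes <- setNames(sgn * mag, de)
    } else {
        if (!all(names(deGenes) %in% genes))
            stop("planted deregulated genes must be interactome nodes")
        if (any(abs(deGenes) < 1))
            stop("signed fold changes must have magnitude >= 1")
    }
    ratio <- setNames(rep(1, length(genes)), genes)
    ratio[names(deGenes)] <- ifelse(deGenes > 0, deGenes, -1 / deGenes)

    nrep <- config$nReplicates
    ppg <- config$probesPerGene
    baseline <- setNames(rlnorm(length(genes), meanlog = 5, sdlog = 1), genes)
    probeGene <- rep(genes, each = ppg)
    probeId <- paste0("pr_", probeGene, "_", rep(seq_len(ppg), length(genes)))
    affinity <- rlnorm(length(probeId), meanlog = 0, sdlog = 0.3)

    samples <- c(paste0("treated_", seq_len(nrep)),
                 paste0("control_", seq_len(nrep)))
    group <- rep(c("treated", "control"), each = nrep)
    mean0 <- baseline[probeGene] * affinity
    vals <- vapply(seq_along(samples), function(j) {
        mu <- if (group[j] == "treated") mean0 * ratio[probeGene] else mean0
        mu * exp(rnorm(length(mu), 0, config$noiseSd))
    }, numeric(length(probeId)))
    dimnames(vals) <- list(probeId, samples)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = vals),
        rowData = S4Vectors::DataFrame(gene = probeGene, row.names = probeId),
        colData = S4Vectors::DataFrame(group = group, row.names = samples))
    list(se = se, deGenes = deGenes)
}

.simCovariates <- function(subjects) {
    n <- length(subjects)
    data.frame(
        age = round(pmin(80, pmax(18, rnorm(n, 56, 9)))),
        sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.43, 0.57)),
        sbp = rnorm(n, 134, 13),
        dbp = rnorm(n, 81, 8),
        bmi = pmax(18, rnorm(n, 30.7, 5)),
        hba1c = rnorm(n, 63, 9),
        egfr = pmax(20, rnorm(n, 90, 18)),
        uacr = exp(rnorm(n, log(3.7), 0.8)),
        row.names = subjects)
}

#' Simulate a longitudinal two-(or more-)arm biomarker trial
#'
#' Generates long-format biomarker records at the configured visit weeks.
#' Log biomarker values decompose into a subject random intercept plus
#' independent visit residuals, with variances chosen so the total log-scale
#' standard deviation is \code{trialSd} and the correlation between any two
#' visits of the same subject is \code{withinSubjectCorr}. Post-baseline arm
#' means are multiplied by the planted per-visit effects. Baseline
#' covariates (age, sex, blood pressures, BMI, HbA1c, eGFR, UACR) are drawn
#' from fixed plausible distributions. Longitudinal eGFR records (additive
#' change scale) are included alongside the biomarkers, with an optional
#' planted linear dependence of eGFR change on a biomarker's log-change.
#'
#' @param config a [simulationConfig()].
#' @param markers character vector of biomarker names to simulate.
#' @param egfrAssociation optional \code{list(marker =, slope =)}: each
#'   subject's post-baseline eGFR change gains \code{slope} times the
#'   subject's log-change of \code{marker} from baseline to the first
#'   post-baseline visit.
#' @return a list: \code{trial}, a [TrialData-class] object; and
#'   \code{truth} with elements \code{trialEffects} (the planted
#'   multiplicative effects) and \code{egfrAssociation}.
#' @export
simulateTrial <- function(config, markers = "TNFR1",
                          egfrAssociation = NULL) {
    if (config$withinSubjectCorr < 0 || config$withinSubjectCorr >= 1)
        stop("withinSubjectCorr must be in [0, 1)")
    arms <- names(config$plantedEffects)
    if (length(arms) < 2)
        stop("at least two arms are required")
    visits <- config$visitWeeks
    post <- sort(setdiff(visits, 0))
    if (length(post) < 1)
        stop("at least one post-baseline visit is required")
    set.seed(.deriveSeed(config$seed, "trial"))
    nsub <- config$nSubjectsPerArm
    subjects <- sprintf("s%04d", seq_len(nsub * length(arms)))
    subjArm <- rep(arms, each = nsub)
    covars <- .simCovariates(subjects)

    sdB <- sqrt(config$withinSubjectCorr) * config$trialSd
    sdE <- sqrt(1 - config$withinSubjectCorr) * config$trialSd

    # monotone MAR dropout: once a visit is missed all later ones are too
    lastVisit <- rep(max(visits), length(subjects))
    if (config$dropout > 0) {
        for (i in seq_along(subjects)) {
            for (k in seq_along(post)) {
                if (runif(1) < config$dropout) {
                    lastVisit[i] <- if (k == 1) 0 else post[k - 1]
                    break
                }
            }
        }
    }

    recs <- list()
    logChangeFirstPost <- list()
    for (m in markers) {
        mu <- log(1000)
        b <- rnorm(length(subjects), 0, sdB)
        valMat <- matrix(NA_real_, length(subjects), length(visits),
                         dimnames = list(subjects, visits))
        for (vi in seq_along(visits)) {
            v <- visits[vi]
            eff <- vapply(subjArm, function(a) {
                if (v == 0) 1 else config$plantedEffects[[a]][as.character(v)]
            }, numeric(1))
            valMat[, vi] <- exp(mu + b + log(eff) +
                                rnorm(length(subjects), 0, sdE))
        }
        logChangeFirstPost[[m]] <-
            log(valMat[, as.character(post[1])] / valMat[, "0"])
        for (vi in seq_along(visits)) {
            keep <- visits[vi] <= lastVisit
            recs[[length(recs) + 1L]] <- data.frame(
                subject = subjects[keep], arm = subjArm[keep],
                visitWeek = visits[vi], biomarker = m,
                value = valMat[keep, vi])
        }
    }

    # longitudinal eGFR on the additive scale with a mild background decline
    drift <- setNames(-2 * seq_along(post), as.character(post))
    assocSlope <- 0
    assocMarker <- NULL
    if (!is.null(egfrAssociation)) {
        assocMarker <- egfrAssociation$marker
        assocSlope <- egfrAssociation$slope
        if (!assocMarker %in% markers)
            stop("egfrAssociation marker not among simulated markers")
    }
    for (v in visits) {
        keep <- v <= lastVisit
        val <- covars$egfr
        if (v != 0) {
            val <- val + drift[as.character(v)] +
                rnorm(length(subjects), 0, 6)
            if (assocSlope != 0)
                val <- val + assocSlope * logChangeFirstPost[[assocMarker]]
        }
        recs[[length(recs) + 1L]] <- data.frame(
            subject = subjects[keep], arm = subjArm[keep],
            visitWeek = v, biomarker = "eGFR", value = val[keep])
    }

    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    trial <- methods::new("TrialData", records = records,
                          covariates = covars)
    effects <- do.call(rbind, lapply(arms, function(a) {
        data.frame(arm = a, visitWeek = post,
                   effect = unname(config$plantedEffects[[a]][
                       as.character(post)]))
    }))
    list(trial = trial,
         truth = list(trialEffects = effects,
                      egfrAssociation = egfrAssociation))
}
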