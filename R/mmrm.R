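# Longitudinal biomarker statistics: mixed-model repeated measures (MMRM)
# with unstructured within-subject covariance over post-baseline visits,
# percentage-difference contrasts between arms, change/achieved-level
# correlation matrices, tertile stratification, and the association of a
# biomarker's change with kidney-function (eGFR) decline.

.trialWide <- function(trial, biomarker) {
    r <- trialRecords(trial)
    r <- r[r$biomarker == biomarker, , drop = FALSE]
    if (nrow(r) == 0L)
        stop("biomarker ", sQuote(biomarker), " not in the trial data")
    r
}

.baselineValues <- function(rec) {
    b <- rec[rec$visitWeek == 0, , drop = FALSE]
    setNames(b$value, b$subject)
}

.mmrmFrame <- function(trial, biomarker, logTransform) {
    rec <- .trialWide(trial, biomarker)
    base <- .baselineValues(rec)
    post <- rec[rec$visitWeek != 0, , drop = FALSE]
    post <- post[post$subject %in% names(base), , drop = FALSE]
    visits <- sort(unique(post$visitWeek))
    if (length(visits) < 2)
        stop("at least two post-baseline visits are required")
    b0 <- base[post$subject]
    d <- data.frame(subject = post$subject,
                    arm = factor(post$arm),
                    visitF = factor(post$visitWeek, levels = visits),
                    visitIdx = match(post$visitWeek, visits),
                    stringsAsFactors = FALSE)
    if (logTransform) {
        d$y <- log(post$value)
        d$base0 <- log(b0)
    } else {
        d$y <- 100 * (post$value / b0 - 1)
        d$base0 <- b0
    }
    tab <- table(d$arm, d$visitF)
    if (any(tab < 2))
        stop("every visit must have at least 2 subjects per arm")
    d
}

.glsUnstructured <- function(formula, data) {
    nlme::gls(formula, data = data,
              correlation = nlme::corSymm(form = ~ visitIdx | subject),
              weights = nlme::varIdent(form = ~ 1 | visitF),
              method = "REML", na.action = stats::na.omit)
}

#' Fit an MMRM to one biomarker of a longitudinal trial
#'
#' Fits, by REML, a marginal linear model with fixed effects for treatment
#' arm, visit, their interaction and the baseline biomarker level, and an
#' unstructured variance-covariance matrix over the post-baseline visits of
#' each subject. All available records contribute: subjects with missing
#' visits are retained (valid under missing-at-random). The response is the
#' natural log of the value when \code{logTransform = TRUE} (the default,
#' appropriate for right-skewed biomarkers), otherwise the percentage
#' change from baseline.
#'
#' @param trial a [TrialData-class] object.
#' @param biomarker name of the biomarker to model.
#' @param logTransform model log values (default) or raw percentage change.
#' @return an [MMRMFit-class].
#' @seealso [estimateContrast()] for between-arm percentage differences.
#' @export
fitMMRM <- function(trial, biomarker, logTransform = TRUE) {
    d <- .mmrmFrame(trial, biomarker, logTransform)
    fit <- tryCatch(
        .glsUnstructured(y ~ arm * visitF + base0, d),
        error = function(e) e)
    converged <- !inherits(fit, "error")
    if (!converged)
        stop("MMRM did not converge for ", sQuote(biomarker), ": ",
             conditionMessage(fit))
    methods::new("MMRMFit", fit = fit, data = d, biomarker = biomarker,
                 logTransform = logTransform,
                 visits = as.numeric(levels(d$visitF)),
                 arms = levels(d$arm), converged = converged)
}

#' Estimated within-subject residual covariance of an MMRM fit
#'
#' @param object an [MMRMFit-class].
#' @return the estimated (unstructured) covariance matrix across
#'   post-baseline visits.
#' @export
residualCovariance <- function(object) {
    stopifnot(methods::is(object, "MMRMFit"))
    m <- nlme::getVarCov(object@fit)
    dimnames(m) <- list(object@visits, object@visits)
    m
}

.contrastL <- function(object, armA, armB, visit = NULL) {
    d <- object@data
    grid <- expand.grid(arm = factor(c(armA, armB), levels = levels(d$arm)),
                        visitF = factor(levels(d$visitF),
                                        levels = levels(d$visitF)),
                        base0 = mean(d$base0))
    X <- model.matrix(~ arm * visitF + base0, grid)
    if (!is.null(visit)) {
        keep <- grid$visitF == as.character(visit)
        grid <- grid[keep, , drop = FALSE]
        X <- X[keep, , drop = FALSE]
    }
    colMeans(X[grid$arm == armA, , drop = FALSE]) -
        colMeans(X[grid$arm == armB, , drop = FALSE])
}

#' Between-arm contrast as a percentage difference
#'
#' Estimates the arm-A-minus-arm-B fixed-effect contrast at each
#' post-baseline visit and averaged over visits. For a log-transformed
#' response, a contrast \eqn{\delta} on the log scale is reported as the
#' percentage difference \eqn{100(e^{\delta}-1)} with the 95\% confidence
#' bounds transformed the same way; for a percentage-change response the
#' contrast is a difference in percentage points and is reported directly.
#' Inference is by two-sided Wald tests with a normal reference.
#'
#' @param object an [MMRMFit-class].
#' @param armA,armB arm labels; the estimate is A minus B.
#' @param level confidence level (default 0.95).
#' @return \code{data.frame} with one row per visit plus a row
#'   \code{"average"}: columns \code{biomarker}, \code{armA}, \code{armB},
#'   \code{visit}, \code{delta} (model scale), \code{estimate},
#'   \code{ciLow}, \code{ciHigh} (percentage scale), \code{pValue}.
#' @export
estimateContrast <- function(object, armA, armB, level = 0.95) {
    stopifnot(methods::is(object, "MMRMFit"))
    if (!all(c(armA, armB) %in% object@arms))
        stop("unknown arm label(s): ",
             paste(setdiff(c(armA, armB), object@arms), collapse = ", "))
    beta <- coef(object@fit)
    V <- vcov(object@fit)
    z <- qnorm(1 - (1 - level) / 2)
    one <- function(visit) {
        L <- .contrastL(object, armA, armB, visit)
        delta <- sum(L * beta)
        se <- sqrt(drop(t(L) %*% V %*% L))
        lo <- delta - z * se
        hi <- delta + z * se
        p <- 2 * pnorm(-abs(delta / se))
        if (object@logTransform) {
            est <- 100 * (exp(c(delta, lo, hi)) - 1)
        } else {
            est <- c(delta, lo, hi)
        }
        data.frame(biomarker = object@biomarker, armA = armA, armB = armB,
                   visit = if (is.null(visit)) "average"
                           else as.character(visit),
                   delta = delta, estimate = est[1], ciLow = est[2],
                   ciHigh = est[3], pValue = p)
    }
    out <- rbind(one(NULL),
                 do.call(rbind, lapply(object@visits, one)))
    rownames(out) <- NULL
    out
}

#' Per-subject biomarker change or achieved level
#'
#' @param trial a [TrialData-class].
#' @param biomarker biomarker name.
#' @param atWeek the visit week.
#' @param mode \code{"change"}: percentage change from baseline;
#'   \code{"achieved"}: the value at \code{atWeek}.
#' @return named numeric vector keyed by subject (subjects missing either
#'   visit are absent).
#' @export
biomarkerChange <- function(trial, biomarker, atWeek = 52,
                            mode = c("change", "achieved")) {
    mode <- match.arg(mode)
    rec <- .trialWide(trial, biomarker)
    at <- rec[rec$visitWeek == atWeek, , drop = FALSE]
    if (nrow(at) == 0L)
        stop("no records at week ", atWeek)
    v <- setNames(at$value, at$subject)
    if (mode == "achieved")
        return(v)
    base <- .baselineValues(rec)
    common <- intersect(names(v), names(base))
    100 * (v[common] / base[common] - 1)
}

#' Pairwise Pearson correlations of biomarker changes or achieved levels
#'
#' Computes the Pearson correlation between every pair of biomarkers over
#' subjects with complete pairs, flagging correlations with p below the
#' significance cutoff (default 0.001). A constant vector makes the
#' correlation undefined; it is reported as \code{NA}, never as a number.
#'
#' @param trial a [TrialData-class].
#' @param markers biomarker names to correlate.
#' @param atWeek visit week at which changes/levels are taken.
#' @param mode \code{"change"} (percentage change from baseline) or
#'   \code{"achieved"} (level at \code{atWeek}).
#' @param alpha significance cutoff for the flag matrix.
#' @return list of three matrices: \code{r}, \code{p},
#'   \code{significant}; \code{r} is symmetric with unit diagonal.
#' @export
correlateChanges <- function(trial, markers, atWeek = 52,
                             mode = c("change", "achieved"),
                             alpha = 0.001) {
    mode <- match.arg(mode)
    vals <- lapply(markers, function(m)
        biomarkerChange(trial, m, atWeek, mode))
    names(vals) <- markers
    k <- length(markers)
    r <- matrix(NA_real_, k, k, dimnames = list(markers, markers))
    p <- matrix(NA_real_, k, k, dimnames = list(markers, markers))
    diag(r) <- 1
    for (i in seq_len(k)) for (j in seq_len(k)) {
        if (j <= i) next
        common <- intersect(names(vals[[i]]), names(vals[[j]]))
        x <- vals[[i]][common]; y <- vals[[j]][common]
        ok <- is.finite(x) & is.finite(y)
        x <- x[ok]; y <- y[ok]
        if (length(x) >= 3 && sd(x) > 0 && sd(y) > 0) {
            ct <- cor.test(x, y, method = "pearson")
            r[i, j] <- r[j, i] <- unname(ct$estimate)
            p[i, j] <- p[j, i] <- ct$p.value
        }
    }
    list(r = r, p = p, significant = !is.na(p) & p < alpha)
}

#' Stratify per-subject changes into tertiles
#'
#' Rank-based split into three groups whose sizes differ by at most one;
#' when the count is not divisible by three, the extra subjects go to the
#' lower tertiles first. Ties are broken by subject identifier, making the
#' labelling deterministic and invariant to input order.
#'
#' @param changes named numeric vector of per-subject changes (names =
#'   subject identifiers); missing values are dropped.
#' @return factor with levels \code{"T1" < "T2" < "T3"} (ascending change),
#'   named by subject, in the input's (non-missing) order.
#' @export
stratifyTertiles <- function(changes) {
    if (is.null(names(changes)))
        names(changes) <- as.character(seq_along(changes))
    changes <- changes[!is.na(changes)]
    n <- length(changes)
    if (n < 3)
        stop("at least 3 non-missing values are required")
    sizes <- n %/% 3 + (seq_len(3) <= n %% 3)
    ord <- order(changes, names(changes))
    lab <- rep(c("T1", "T2", "T3"), times = sizes)
    out <- factor(character(n), levels = c("T1", "T2", "T3"))
    out[ord] <- lab
    names(out) <- names(changes)
    out
}

.egfrFrame <- function(trial, change, uacrChange = NULL) {
    rec <- .trialWide(trial, "eGFR")
    base <- .baselineValues(rec)
    post <- rec[rec$visitWeek != 0, , drop = FALSE]
    visits <- sort(unique(post$visitWeek))
    if (length(visits) < 2)
        stop("eGFR must be measured at >= 2 post-baseline visits")
    cov <- trialCovariates(trial)
    d <- data.frame(subject = post$subject,
                    arm = factor(post$arm),
                    visitF = factor(post$visitWeek, levels = visits),
                    visitIdx = match(post$visitWeek, visits),
                    dE = post$value - base[post$subject],
                    chg = unname(change[post$subject]))
    adj <- cov[post$subject, c("age", "sex", "sbp", "dbp", "bmi", "hba1c",
                               "egfr", "uacr"), drop = FALSE]
    names(adj)[names(adj) == "egfr"] <- "egfr0"
    adj$sex <- factor(adj$sex)
    adj$luacr <- log(adj$uacr)
    adj$uacr <- NULL
    d <- cbind(d, adj)
    if (!is.null(uacrChange))
        d$uacrChg <- unname(uacrChange[post$subject])
    d[stats::complete.cases(d), , drop = FALSE]
}

.adjTerms <- function(d) {
    base <- c("age", "sex", "sbp", "dbp", "bmi", "hba1c", "egfr0", "luacr")
    if ("uacrChg" %in% names(d)) base <- c(base, "uacrChg")
    paste(base, collapse = " + ")
}

.lsmeans <- function(fit, d, formula, groupVar, level = 0.95) {
    beta <- coef(fit)
    V <- vcov(fit)
    z <- qnorm(1 - (1 - level) / 2)
    numeric_means <- vapply(d[vapply(d, is.numeric, logical(1))], mean,
                            numeric(1))
    do.call(rbind, lapply(levels(d[[groupVar]]), function(g) {
        grid <- expand.grid(arm = levels(d$arm),
                            visitF = factor(levels(d$visitF),
                                            levels = levels(d$visitF)),
                            sex = levels(d$sex))
        grid[[groupVar]] <- factor(g, levels = levels(d[[groupVar]]))
        for (nm in names(numeric_means))
            if (!nm %in% names(grid)) grid[[nm]] <- numeric_means[[nm]]
        grid$arm <- factor(grid$arm, levels = levels(d$arm))
        X <- model.matrix(formula, grid)
        L <- colMeans(X)
        est <- sum(L * beta)
        se <- sqrt(drop(t(L) %*% V %*% L))
        data.frame(group = g,
                   n = length(unique(d$subject[d[[groupVar]] == g])),
                   lsmean = est, ciLow = est - z * se, ciHigh = est + z * se)
    }))
}

#' Association between a biomarker's change and eGFR decline
#'
#' Fits an MMRM to the change in eGFR from baseline over post-baseline
#' visits, with treatment and visit as factors, the biomarker change and
#' its interaction with visit as covariates, and adjustment for baseline
#' age, sex, systolic and diastolic blood pressure, BMI, HbA1c, eGFR,
#' log UACR and (when supplied) the change in UACR. The continuous analysis
#' reports the Wald p value of the biomarker-change slope averaged over
#' visits. The grouped analyses replace the continuous covariate by tertile
#' labels or by named change bands (reduction of at least 30\%; reduction
#' between 30\% and 0\%; any increase) and report least-squares-mean eGFR
#' change with 95\% confidence intervals per group (factor levels weighted
#' equally, numeric covariates at their means).
#'
#' @param trial a [TrialData-class] containing \code{"eGFR"} records.
#' @param change named per-subject biomarker change (percentage), e.g. from
#'   [biomarkerChange()].
#' @param grouping \code{"continuous"}, \code{"tertiles"} or
#'   \code{"named_bands"}.
#' @param uacrChange optional named per-subject change in UACR.
#' @return list: \code{continuousP} (p value of the continuous slope),
#'   \code{slope} (averaged slope estimate), \code{groups}
#'   (\code{data.frame} of least-squares means, \code{NULL} for continuous
#'   grouping), \code{fit} (the underlying \code{gls} fit of the requested
#'   analysis).
#' @export
associateEgfrDecline <- function(trial, change,
                                 grouping = c("continuous", "tertiles",
                                              "named_bands"),
                                 uacrChange = NULL) {
    grouping <- match.arg(grouping)
    d <- .egfrFrame(trial, change, uacrChange)
    tab <- table(d$arm, d$visitF)
    if (any(tab < 2))
        stop("every visit must have at least 2 subjects per arm")
    adj <- .adjTerms(d)
    fmlCont <- stats::as.formula(
        paste("dE ~ arm + visitF + chg + chg:visitF +", adj))
    fitCont <- .glsUnstructured(fmlCont, d)
    beta <- coef(fitCont)
    V <- vcov(fitCont)
    # averaged-over-visit slope of the continuous change covariate
    L <- setNames(numeric(length(beta)), names(beta))
    L["chg"] <- 1
    inter <- grep("^chg:visitF", names(beta), value = TRUE)
    L[inter] <- 1 / nlevels(d$visitF)
    slope <- sum(L * beta)
    se <- sqrt(drop(t(L) %*% V %*% L))
    continuousP <- 2 * pnorm(-abs(slope / se))

    groups <- NULL
    fit <- fitCont
    if (grouping != "continuous") {
        subjChg <- change[!duplicated(names(change))]
        if (grouping == "tertiles") {
            g <- stratifyTertiles(subjChg)
        } else {
            g <- cut(subjChg, breaks = c(-Inf, -30, 0, Inf),
                     labels = c("reduction_ge30", "reduction_30_0",
                                "increase"))
            names(g) <- names(subjChg)
        }
        d$grp <- g[d$subject]
        d <- d[!is.na(d$grp), , drop = FALSE]
        d$grp <- droplevels(d$grp)
        fmlGrp <- stats::as.formula(
            paste("dE ~ arm + visitF + grp + grp:visitF +", adj))
        fit <- .glsUnstructured(fmlGrp, d)
        groups <- .lsmeans(fit, d, stats::as.formula(
            paste("~ arm + visitF + grp + grp:visitF +", adj)), "grp")
        rownames(groups) <- NULL
    }
    list(continuousP = continuousP, slope = slope, groups = groups,
         fit = fit)
}
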