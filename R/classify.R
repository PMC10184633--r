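#' Signed trapezoidal area under a deflection time course
#'
#' Integrates `median - baseline` over the course's time span by the
#' trapezoid rule (log2 units times hours, signed). The baseline is either
#' the value at t = 0 (`"t0"`) or a matched control course on the same grid
#' (`"ctrl_course"`).
#'
#' @param tc a [TimeCourse-class] with complete medians (interpolate first).
#' @param baseline `"ctrl_course"` or `"t0"`.
#' @param ctrl control [TimeCourse-class], required for `"ctrl_course"`.
#' @return numeric(1) signed area.
#' @export
timecourseAUC <- function(tc, baseline = c("ctrl_course", "t0"),
                          ctrl = NULL) {
    baseline <- match.arg(baseline)
    if (length(tc@timesH) < 2L) stop("AUC needs at least 2 timepoints")
    y <- deflectionMedians(tc, baseline, ctrl)
    pracma::trapz(tc@timesH, y)
}

#' Median deflection of a course from its baseline
#' @inheritParams timecourseAUC
#' @return numeric vector of deflections per timepoint.
#' @export
deflectionMedians <- function(tc, baseline = c("ctrl_course", "t0"),
                              ctrl = NULL) {
    baseline <- match.arg(baseline)
    if (anyNA(tc@medians))
        stop("medians incomplete; run interpolateTimecourse() first")
    if (baseline == "ctrl_course") {
        if (is.null(ctrl)) stop("ctrl course required for baseline = ctrl_course")
        if (!isTRUE(all.equal(tc@timesH, ctrl@timesH)))
            stop("time-grid mismatch between course and control")
        if (anyNA(ctrl@medians))
            stop("control medians incomplete; run interpolateTimecourse() first")
        tc@medians - ctrl@medians
    } else {
        tc@medians - tc@medians[1L]
    }
}

#' Pearson correlation between two time courses
#'
#' Computed on replicate-median values over matched time grids. When either
#' course has zero variance the correlation is undefined and `NA` is
#' returned (the shape classification then falls through to `NONE`).
#'
#' @param tcComb,tcSingle [TimeCourse-class] objects on identical grids with
#'   at least 3 timepoints, or plain numeric median vectors of equal length.
#' @return numeric(1) Pearson r, or `NA`.
#' @export
timecourseCorrelation <- function(tcComb, tcSingle) {
    a <- if (is(tcComb, "TimeCourse")) tcComb@medians else as.numeric(tcComb)
    b <- if (is(tcSingle, "TimeCourse")) tcSingle@medians else as.numeric(tcSingle)
    if (is(tcComb, "TimeCourse") && is(tcSingle, "TimeCourse") &&
        !isTRUE(all.equal(tcComb@timesH, tcSingle@timesH)))
        stop("time-grid mismatch between courses")
    if (length(a) != length(b)) stop("time-grid mismatch between courses")
    if (length(a) < 3L) stop("correlation needs at least 3 timepoints")
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
}

#' S1-S4 shape classification from correlations
#'
#' Combined-course dynamics are classed by Pearson correlation with the two
#' single-stimulus courses: `S1` (TNF-like shape) if r(TNF) > rHigh and
#' r(IFN) < rHigh; `S2` mirrored; `S3` (common shape) if both exceed rHigh;
#' `S4` (combined-specific shape) if both fall below rLow. Cutoffs are
#' strict; boundary values and missing correlations give `NONE`.
#'
#' @param rTnf,rIfn correlations with the single-stimulus courses (may be
#'   vectors).
#' @param cfg a [ThresholdConfig-class] (rHigh = 0.7, rLow = 0.3 by default).
#' @return character vector over `S1`, `S2`, `S3`, `S4`, `NONE`.
#' @export
classifyShape <- function(rTnf, rIfn, cfg = thresholdConfig()) {
    hi <- cfg@rHigh; lo <- cfg@rLow
    out <- rep("NONE", length(rTnf))
    ok <- !is.na(rTnf) & !is.na(rIfn)
    out[ok & rTnf > hi & rIfn > hi] <- "S3"
    out[ok & rTnf > hi & rIfn < hi] <- "S1"
    out[ok & rTnf < hi & rIfn > hi] <- "S2"
    out[ok & rTnf < lo & rIfn < lo] <- "S4"
    out
}

.aucRatioTo <- function(aucComb, aucSingle) {
    ## sign disagreement: the single stimulus cannot explain the combined
    ## direction, so its ratio is +Inf
    ifelse(sign(aucSingle) != sign(aucComb), Inf,
           abs(aucComb) / pmax(abs(aucSingle), 1e-6 * abs(aucComb)))
}

#' E1-E3 effect classification from AUC ratios
#'
#' Effect sizes are compared through combined/single AUC ratios:
#' `E1` (TNF effect) if ratio-to-TNF < 2 and ratio-to-IFN > 2; `E2`
#' mirrored; `E3` (combined effect, i.e. super-additivity against both
#' singles) if both ratios exceed 2. Ratios use magnitudes; a single course
#' whose AUC sign disagrees with the combined course gets ratio +Inf. A zero
#' combined AUC gives `NONE`.
#'
#' @param aucComb,aucTnf,aucIfn signed AUCs on a common baseline convention.
#' @param cfg a [ThresholdConfig-class] (`aucRatio = 2` by default, strict).
#' @return character vector over `E1`, `E2`, `E3`, `NONE`.
#' @export
classifyEffect <- function(aucComb, aucTnf, aucIfn, cfg = thresholdConfig()) {
    k <- cfg@aucRatio
    out <- rep("NONE", length(aucComb))
    ok <- !is.na(aucComb) & aucComb != 0 & !is.na(aucTnf) & !is.na(aucIfn)
    rT <- .aucRatioTo(aucComb, aucTnf)
    rI <- .aucRatioTo(aucComb, aucIfn)
    out[ok & rT < k & rI > k] <- "E1"
    out[ok & rT > k & rI < k] <- "E2"
    out[ok & rT > k & rI > k] <- "E3"
    out
}

#' Final response class from shape and effect
#'
#' Default rule table, in precedence order: `SYNERGY` if S4 or E3; `TNF` if
#' S1, or S3 with E1; `IFN` if S2, or S3 with E2; `COMMON` if S3 (and not
#' E3, by precedence); otherwise `NOT_CLASSIFIED`. The alternative
#' `"s3-or-e3"` rule evaluates the synergy clause as literally S3-or-E3
#' after the single-stimulus and common clauses.
#'
#' @param shape,effect character vectors from [classifyShape()] and
#'   [classifyEffect()].
#' @param rule `"s4-or-e3"` (default) or `"s3-or-e3"`.
#' @return character vector over `responseClassLevels()`.
#' @export
assignResponseClass <- function(shape, effect,
                                rule = c("s4-or-e3", "s3-or-e3")) {
    rule <- match.arg(rule)
    n <- max(length(shape), length(effect))
    shape <- rep_len(shape, n); effect <- rep_len(effect, n)
    out <- rep("NOT_CLASSIFIED", n)
    if (rule == "s4-or-e3") {
        out[shape == "S3"] <- "COMMON"
        out[shape == "S2" | (shape == "S3" & effect == "E2")] <- "IFN"
        out[shape == "S1" | (shape == "S3" & effect == "E1")] <- "TNF"
        out[shape == "S4" | effect == "E3"] <- "SYNERGY"
    } else {
        out[shape == "S3" | effect == "E3"] <- "SYNERGY"
        out[shape == "S3" & effect != "E3"] <- "COMMON"
        out[shape == "S2" | (shape == "S3" & effect == "E2")] <- "IFN"
        out[shape == "S1" | (shape == "S3" & effect == "E1")] <- "TNF"
    }
    out
}

#' Additive expectation of the combined response
#'
#' Pointwise sum of the two single-stimulus median deflection courses — the
#' gray reference against which synergistic excess is judged.
#'
#' @param tcTnf,tcIfn [TimeCourse-class] deflection courses on one grid.
#' @return A [TimeCourse-class] whose medians are the pointwise sums.
#' @export
additiveExpectation <- function(tcTnf, tcIfn) {
    if (!isTRUE(all.equal(tcTnf@timesH, tcIfn@timesH)))
        stop("time-grid mismatch between courses")
    sums <- tcTnf@medians + tcIfn@medians
    TimeCourse(paste0(tcTnf@feature, "+additive"), "TNF_IFN",
               tcTnf@timesH, matrix(sums, nrow = 1L))
}

#' Decompose the combined AUC into single-stimulus and excess fractions
#'
#' `frac_tnf = auc_tnf/auc_comb`, `frac_ifn = auc_ifn/auc_comb`,
#' `frac_excess = 1 - frac_tnf - frac_ifn` (the part of the combined
#' response not explained by the sum of singles). Fractions sum to 1 and may
#' be negative under antagonism; they are reported as-is.
#'
#' @param aucTnf,aucIfn,aucComb signed AUCs; `aucComb` must be non-zero.
#' @return `data.frame` with `frac_tnf`, `frac_ifn`, `frac_excess`.
#' @export
synergyDecomposition <- function(aucTnf, aucIfn, aucComb) {
    if (any(aucComb == 0)) stop("combined AUC is zero")
    fT <- aucTnf / aucComb; fI <- aucIfn / aucComb
    data.frame(frac_tnf = fT, frac_ifn = fI, frac_excess = 1 - fT - fI)
}

#' Classify responses of all combined-significant features
#'
#' The paper-style driver: features significant under combined stimulation
#' (any timepoint) are extracted as median time courses per condition,
#' interpolated, expressed as deflections from the matched control course
#' (or from t = 0), correlated with the single-stimulus courses, integrated
#' (trapezoidal AUC), and assigned S/E/final classes plus the synergy
#' decomposition.
#'
#' @param m an [OmicsMatrix-class].
#' @param diffResults `DifferentialResult` table for `m` from
#'   [runDifferential()]; used as the significance gate.
#' @param cfg a [ThresholdConfig-class].
#' @param baseline `"ctrl_course"` (default) or `"t0"`.
#' @param rule synergy rule-table reading, see [assignResponseClass()].
#' @return `data.frame`, one row per gated feature, with `r_tnf`, `r_ifn`,
#'   the three AUCs, `shape`, `effect`, `final` and the synergy fractions.
#' @export
classifyResponses <- function(m, diffResults, cfg = thresholdConfig(),
                              baseline = c("ctrl_course", "t0"),
                              rule = c("s4-or-e3", "s3-or-e3")) {
    baseline <- match.arg(baseline); rule <- match.arg(rule)
    sig <- unique(diffResults$feature[diffResults$condition == "TNF_IFN" &
                                      diffResults$significant])
    rows <- lapply(sig, function(f) {
        tcs <- lapply(c(CTRL = "CTRL", TNF = "TNF", IFN = "IFN",
                        TNF_IFN = "TNF_IFN"), function(cond)
            tryCatch(interpolateTimecourse(extractTimecourse(m, f, cond)),
                     error = function(e) NULL))
        if (any(vapply(tcs, is.null, TRUE))) return(NULL)
        ctrl <- if (baseline == "ctrl_course") tcs$CTRL else NULL
        d <- lapply(tcs[c("TNF", "IFN", "TNF_IFN")], deflectionMedians,
                    baseline = baseline, ctrl = ctrl)
        rT <- timecourseCorrelation(d$TNF_IFN, d$TNF)
        rI <- timecourseCorrelation(d$TNF_IFN, d$IFN)
        times <- tcs$TNF_IFN@timesH
        auc <- vapply(d, function(y) pracma::trapz(times, y), 0)
        shape <- classifyShape(rT, rI, cfg)
        effect <- classifyEffect(auc[["TNF_IFN"]], auc[["TNF"]],
                                 auc[["IFN"]], cfg)
        fr <- if (auc[["TNF_IFN"]] != 0)
            synergyDecomposition(auc[["TNF"]], auc[["IFN"]], auc[["TNF_IFN"]])
        else data.frame(frac_tnf = NA_real_, frac_ifn = NA_real_,
                        frac_excess = NA_real_)
        data.frame(feature = f, layer = omicsLayer(m),
                   gene = rowData(m)[f, "gene"],
                   r_tnf = rT, r_ifn = rI,
                   auc_tnf = auc[["TNF"]], auc_ifn = auc[["IFN"]],
                   auc_comb = auc[["TNF_IFN"]],
                   shape = shape, effect = effect,
                   final = assignResponseClass(shape, effect, rule),
                   fr, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(feature = character(), layer = character(),
                          gene = character(), r_tnf = numeric(),
                          r_ifn = numeric(), auc_tnf = numeric(),
                          auc_ifn = numeric(), auc_comb = numeric(),
                          shape = character(), effect = character(),
                          final = character(), frac_tnf = numeric(),
                          frac_ifn = numeric(), frac_excess = numeric(),
                          stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}
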