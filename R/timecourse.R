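#' Extract one feature's time course under one condition
#'
#' Collects the replicate values of `feature` across the ordered timepoints
#' of `condition` and summarizes each timepoint by the median across
#' replicates (missing entries ignored; a time with all replicates missing
#' yields a missing median).
#'
#' @param m an [OmicsMatrix-class].
#' @param feature feature id present in `m`.
#' @param condition one of `conditionLevels()`.
#' @return A [TimeCourse-class].
#' @export
extractTimecourse <- function(m, feature, condition) {
    if (!feature %in% rownames(m)) stop("unknown feature: ", feature)
    cd <- colData(m)
    sel <- cd$condition == condition
    if (!any(sel)) stop("condition not present: ", condition)
    times <- sort(unique(cd$time_h[sel]))
    reps <- sort(unique(cd$replicate[sel]))
    vals <- omicsValues(m)[feature, , drop = TRUE]
    rv <- matrix(NA_real_, length(reps), length(times),
                 dimnames = list(paste0("R", reps), format(times)))
    idx <- which(sel)
    rv[cbind(match(cd$replicate[idx], reps), match(cd$time_h[idx], times))] <-
        vals[idx]
    TimeCourse(feature, condition, times, rv)
}

#' Fill missing medians of a time course by linear approximation
#'
#' Interior gaps are linearly interpolated against time in hours; leading and
#' trailing gaps take the nearest observed value. Observed medians are never
#' altered. Used only for time-course extraction (correlation and AUC), never
#' for the differential tests.
#'
#' @param tc a [TimeCourse-class] with at least two observed medians.
#' @return A [TimeCourse-class] with complete medians.
#' @export
interpolateTimecourse <- function(tc) {
    med <- tc@medians
    obs <- !is.na(med)
    if (sum(obs) < 2L)
        stop("interpolation needs at least two observed medians (feature ",
             tc@feature, ")")
    if (all(obs)) return(tc)
    filled <- approx(tc@timesH[obs], med[obs], xout = tc@timesH,
                     method = "linear", rule = 2)$y
    filled[obs] <- med[obs]
    out <- tc
    out@medians <- filled
    out
}
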