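#' Earliest significant timepoint of a feature
#'
#' Onset is the first attainment of significance; later loss of significance
#' (transient events) is ignored.
#'
#' @param results `DifferentialResult` table (one layer/condition or mixed).
#' @param feature feature id.
#' @return numeric(1) onset time in hours, or `NA` if never significant.
#' @export
firstOnset <- function(results, feature) {
    t <- results$time_h[results$feature == feature & results$significant]
    if (!length(t)) NA_real_ else min(t)
}

#' Per-feature onset table
#' @param results `DifferentialResult` table with a `layer` column.
#' @return `data.frame` with `layer`, `feature`, `onset_h` (`NA` when never
#'   significant).
#' @export
firstOnsetTable <- function(results) {
    sig <- results[results$significant, , drop = FALSE]
    if (nrow(sig)) {
        on <- stats::aggregate(time_h ~ layer + feature, data = sig, FUN = min)
        names(on)[names(on) == "time_h"] <- "onset_h"
    } else {
        on <- data.frame(layer = character(), feature = character(),
                         onset_h = numeric())
    }
    all <- unique(results[, c("layer", "feature")])
    out <- merge(all, on, all.x = TRUE, sort = FALSE)
    out[order(out$layer, out$feature), , drop = FALSE]
}

#' Cumulative temporal event curve
#'
#' At each grid time t, counts the features whose first significant event
#' occurred at or before t; monotone non-decreasing by construction, ending
#' at the number of ever-significant features. `mode = "per_timepoint"`
#' instead counts features significant at each individual timepoint
#' (not cumulative).
#'
#' @param results `DifferentialResult` table.
#' @param layer,condition subset to summarize.
#' @param mode `"onset"` (cumulative, default) or `"per_timepoint"`.
#' @return `data.frame` with `layer`, `condition`, `time_h`, `count`.
#' @export
cumulativeEventCurve <- function(results, layer, condition,
                                 mode = c("onset", "per_timepoint")) {
    mode <- match.arg(mode)
    sub <- results[results$layer == layer & results$condition == condition, ,
                   drop = FALSE]
    times <- sort(unique(results$time_h[results$layer == layer]))
    if (!length(times))
        return(data.frame(layer = character(), condition = character(),
                          time_h = numeric(), count = integer(),
                          stringsAsFactors = FALSE))
    if (mode == "onset") {
        onsets <- vapply(unique(sub$feature), function(f) firstOnset(sub, f), 0)
        onsets <- onsets[!is.na(onsets)]
        count <- vapply(times, function(t) sum(onsets <= t), 0L)
    } else {
        count <- vapply(times, function(t)
            sum(sub$significant[sub$time_h == t]), 0L)
    }
    data.frame(layer = layer, condition = condition, time_h = times,
               count = as.integer(count), stringsAsFactors = FALSE)
}

#' Rank omics layers by median event onset
#'
#' Layers are ordered by the median of their per-feature onset times (the
#' cascade view: phosphoregulation first, then transcripts, then proteins on
#' study-like data). Ties are broken by mean onset, then layer name. Layers
#' without any significant event are excluded with a warning.
#'
#' @param results `DifferentialResult` table with a `layer` column (pool of
#'   conditions to summarize over, typically one condition).
#' @return `data.frame` ordered by onset with `layer`, `median_onset_h`,
#'   `mean_onset_h`, `n_events`.
#' @export
onsetOrdering <- function(results) {
    on <- firstOnsetTable(results)
    empty <- setdiff(unique(results$layer), on$layer[!is.na(on$onset_h)])
    if (length(empty))
        warning("layer(s) with zero events excluded: ",
                paste(empty, collapse = ", "))
    on <- on[!is.na(on$onset_h), , drop = FALSE]
    if (!nrow(on))
        return(data.frame(layer = character(), median_onset_h = numeric(),
                          mean_onset_h = numeric(), n_events = integer()))
    agg <- do.call(rbind, lapply(split(on, on$layer), function(d)
        data.frame(layer = d$layer[1L], median_onset_h = median(d$onset_h),
                   mean_onset_h = mean(d$onset_h), n_events = nrow(d),
                   stringsAsFactors = FALSE)))
    agg <- agg[order(agg$median_onset_h, agg$mean_onset_h, agg$layer), ,
               drop = FALSE]
    rownames(agg) <- NULL
    agg
}
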