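#' Per-feature effect estimates for one stimulus/timepoint contrast
#'
#' For every feature, contrasts the stimulated arm against matched-time
#' control: `log2fc = mean(stim) - mean(ctrl)` on the log scale, with the
#' pooled within-arm variance and its residual degrees of freedom. Features
#' with fewer than two observed replicates in either arm are flagged
#' untestable and carry `NA` estimates.
#'
#' @param m an [OmicsMatrix-class].
#' @param condition stimulated condition (`TNF`, `IFN` or `TNF_IFN`).
#' @param time_h timepoint in hours, present in `m`.
#' @return `data.frame` with columns `feature`, `condition`, `time_h`,
#'   `log2fc`, `s2`, `df`, `n_stim`, `n_ctrl`, `testable`.
#' @export
estimateEffects <- function(m, condition, time_h) {
    cd <- colData(m)
    iStim <- which(cd$condition == condition & cd$time_h == time_h)
    iCtrl <- which(cd$condition == "CTRL" & cd$time_h == time_h)
    if (!length(iStim) || !length(iCtrl))
        stop("contrast arms absent for ", condition, " at t = ", time_h, " h")
    vals <- omicsValues(m)
    one <- function(f) {
        x <- vals[f, iStim]; y <- vals[f, iCtrl]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        n1 <- length(x); n2 <- length(y)
        if (n1 < 2L || n2 < 2L)
            return(c(NA_real_, NA_real_, NA_real_, n1, n2, 0))
        df <- n1 + n2 - 2L
        s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
        c(mean(x) - mean(y), s2, df, n1, n2, 1)
    }
    est <- t(vapply(seq_len(nrow(vals)), one, numeric(6L)))
    data.frame(feature = rownames(vals), condition = condition,
               time_h = time_h, log2fc = est[, 1L], s2 = est[, 2L],
               df = est[, 3L], n_stim = est[, 4L], n_ctrl = est[, 5L],
               testable = est[, 6L] == 1, stringsAsFactors = FALSE)
}

## invert the trigamma function by bisection; trigamma is strictly decreasing
.trigammaInverse <- function(y, tol = 1e-8, cap = 1e7) {
    if (y <= trigamma(cap)) return(Inf)
    lo <- 1e-8; hi <- cap
    while (hi - lo > tol * max(1, lo)) {
        mid <- (lo + hi) / 2
        if (trigamma(mid) > y) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
}

#' Fit the empirical-Bayes variance prior
#'
#' Moment-matches a scaled inverse-chi-square prior (`d0`, `s0^2`) to the
#' observed per-feature sample variances on the log scale: with
#' `e = log(s2) - digamma(df/2) + log(df/2)`, the excess spread of `e` over
#' the theoretical `trigamma(df/2)` determines `trigamma(d0/2)`, solved by
#' bisection to 1e-8; no excess spread gives `d0 = Inf` (complete shrinkage).
#' `d0` above 1e6 is reported as infinite.
#'
#' @param s2 per-feature residual variances (zeros/NAs dropped from the fit).
#' @param df residual degrees of freedom (recycled to `length(s2)`).
#' @return list with `d0` (prior degrees of freedom, possibly `Inf`) and
#'   `s0Sq` (prior variance).
#' @export
fitModeration <- function(s2, df) {
    df <- rep_len(df, length(s2))
    ok <- is.finite(s2) & s2 > 0 & df > 0
    if (sum(ok) < 10L)
        stop("fewer than 10 usable variances; use an ordinary t-test")
    s2 <- s2[ok]; df <- df[ok]
    e <- log(s2) - digamma(df / 2) + log(df / 2)
    n <- length(e)
    evar <- sum((e - mean(e))^2) / (n - 1L) - mean(trigamma(df / 2))
    if (evar > 0) {
        d0 <- 2 * .trigammaInverse(evar)
        if (d0 > 1e6) d0 <- Inf
    } else d0 <- Inf
    ## with no excess spread the prior is a point mass; its first moment is
    ## the plain mean of the sample variances
    s0Sq <- if (is.finite(d0))
        exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    else mean(s2)
    list(d0 = d0, s0Sq = s0Sq)
}

#' Moderated t-statistics and two-sided p-values
#'
#' Shrinks each feature's variance toward the prior,
#' `s2_post = (d0 * s0^2 + df * s2) / (d0 + df)`, and tests
#' `t = log2fc / sqrt(s2_post * (1/n1 + 1/n2))` against a t distribution
#' with `d0 + df` degrees of freedom (standard normal when `d0 = Inf`).
#' With `d0 = 0` this reduces to the ordinary two-sample t-test.
#'
#' @param log2fc,s2,df per-feature effect estimates (see [estimateEffects()]).
#' @param fit a moderation fit from [fitModeration()].
#' @param n1,n2 per-arm replicate counts.
#' @return `data.frame` with `t_mod`, `p`, `df_total`, `s2_post`.
#' @export
moderatedT <- function(log2fc, s2, df, fit, n1, n2) {
    d0 <- fit$d0
    s2post <- if (is.finite(d0)) {
        if (d0 == 0) s2 else (d0 * fit$s0Sq + df * s2) / (d0 + df)
    } else rep_len(fit$s0Sq, length(s2))
    se <- sqrt(s2post * (1 / n1 + 1 / n2))
    t <- log2fc / se
    t[se == 0 & log2fc == 0] <- 0
    dfTotal <- d0 + df
    p <- if (is.finite(d0)) 2 * pt(-abs(t), dfTotal) else 2 * pnorm(-abs(t))
    data.frame(t_mod = t, p = p, df_total = dfTotal, s2_post = s2post)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values (monotone in rank, capped at 1).
#' @export
bhAdjust <- function(p) {
    pp <- p[!is.na(p)]
    if (any(pp < 0 | pp > 1)) stop("p-values outside [0,1]")
    stats::p.adjust(p, method = "BH")
}

#' Flag significant differential events
#'
#' Applies BH adjustment within each `(condition, time_h)` family and flags
#' `significant = (p_adj < alpha) & (|log2fc| > lfcMin)`, with the
#' layer-appropriate alpha (0.01 for the secretome layer, 0.05 otherwise by
#' default).
#'
#' @param results effect table carrying `condition`, `time_h`, `log2fc`, `p`
#'   (e.g. the joined output of [estimateEffects()] and [moderatedT()]).
#' @param cfg a [ThresholdConfig-class].
#' @param layer omics layer the results belong to.
#' @return the input with `p_adj`, `significant` and a `layer` column;
#'   attribute `family` records the adjustment family.
#' @export
callEvents <- function(results, cfg = thresholdConfig(), layer) {
    alpha <- layerAlpha(cfg, layer)
    results$p_adj <- NA_real_
    for (key in unique(paste(results$condition, results$time_h))) {
        i <- paste(results$condition, results$time_h) == key
        results$p_adj[i] <- bhAdjust(results$p[i])
    }
    results$significant <- !is.na(results$p_adj) &
        results$p_adj < alpha & abs(results$log2fc) > cfg@lfcMin
    results$layer <- layer
    attr(results, "family") <- "per (layer, condition, timepoint)"
    attr(results, "alpha") <- alpha
    results
}

#' Run the full differential stage on one layer
#'
#' For every stimulated condition and post-baseline timepoint, estimates
#' effects against matched-time control, fits the empirical-Bayes variance
#' prior across features within the contrast, computes moderated t p-values
#' and calls events via [callEvents()].
#'
#' @param m an [OmicsMatrix-class].
#' @param cfg a [ThresholdConfig-class].
#' @param conditions stimulated conditions to test.
#' @return a `DifferentialResult` table: one row per testable
#'   feature/condition/timepoint with `log2fc`, `s2`, `df`, `t_mod`, `p`,
#'   `p_adj`, `significant`.
#' @export
runDifferential <- function(m, cfg = thresholdConfig(),
                            conditions = c("TNF", "IFN", "TNF_IFN")) {
    cd <- colData(m)
    times <- setdiff(sort(unique(cd$time_h)), 0)
    out <- list()
    for (cond in intersect(conditions, unique(cd$condition))) {
        for (t in times) {
            eff <- estimateEffects(m, cond, t)
            eff <- eff[eff$testable, , drop = FALSE]
            if (!nrow(eff)) next
            fit <- fitModeration(eff$s2, eff$df)
            mt <- moderatedT(eff$log2fc, eff$s2, eff$df, fit,
                             eff$n_stim, eff$n_ctrl)
            out[[paste(cond, t)]] <- cbind(eff, mt)
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    callEvents(res, cfg, omicsLayer(m))
}

#' No-intercept linear model for SILAC ratios
#'
#' SILAC log2 ratios already encode stimulus versus control within a sample,
#' so the per-condition effect is tested directly against zero with a linear
#' model without intercept on non-imputed (observed) entries only. The
#' per-condition effect equals the mean of that condition's observed ratios;
#' the residual degrees of freedom are `n_observed - n_conditions`.
#'
#' @param ratios numeric matrix of log2 ratios, replicates x conditions
#'   (column names label conditions); `NA` marks missing, never imputed.
#' @return `data.frame` with `condition`, `effect`, `n`, `t`, `p`, `df`,
#'   `testable`; conditions with fewer than two observed ratios are flagged
#'   untestable.
#' @export
fitSilacNoIntercept <- function(ratios) {
    ratios <- as.matrix(ratios)
    if (is.null(colnames(ratios)))
        colnames(ratios) <- paste0("C", seq_len(ncol(ratios)))
    nObs <- colSums(!is.na(ratios))
    eff <- colMeans(ratios, na.rm = TRUE)
    eff[nObs == 0L] <- NA_real_
    k <- sum(nObs >= 1L)
    rss <- sum(sweep(ratios, 2L, eff)^2, na.rm = TRUE)
    df <- sum(nObs) - k
    s2 <- if (df > 0) rss / df else NA_real_
    se <- sqrt(s2 / nObs)
    t <- eff / se
    t[!is.na(eff) & eff == 0] <- 0
    p <- 2 * pt(-abs(t), df)
    testable <- nObs >= 2L
    t[!testable] <- NA_real_; p[!testable] <- NA_real_
    data.frame(condition = colnames(ratios), effect = eff, n = nObs,
               t = t, p = p, df = df, testable = testable,
               row.names = NULL, stringsAsFactors = FALSE)
}
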