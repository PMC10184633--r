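#' Downshifted-normal imputation of intensity-dependent missing values
#'
#' Missing entries in each sample column are drawn from a normal distribution
#' compressed and shifted below that column's observed distribution,
#' `Normal(mean_j - shift * sd_j, (width * sd_j)^2)`, reflecting the
#' assumption that undetected proteins sit close to the detection limit
#' (missing not at random). Observed cells are never altered. This is the
#' Perseus-style convention with the downshift statistics computed per
#' sample column.
#'
#' @param m an [OmicsMatrix-class] on a log2 scale.
#' @param width imputation width as a fraction of the column SD (default 0.3).
#' @param shift downshift in column SD units (default 1.8).
#' @param seed RNG seed; identical seed reproduces the draws.
#' @return An [OmicsMatrix-class] with no missing cells.
#' @export
imputeDownshiftedNormal <- function(m, width = 0.3, shift = 1.8, seed = 1L) {
    vals <- omicsValues(m)
    nObs <- colSums(!is.na(vals))
    if (any(nObs < 3L))
        stop("sample has fewer than 3 observed values: ",
             colnames(vals)[which(nObs < 3L)[1L]])
    set.seed(as.integer(seed))
    for (j in seq_len(ncol(vals))) {
        miss <- is.na(vals[, j])
        if (!any(miss)) next
        obs <- vals[!miss, j]
        mu <- mean(obs); s <- sd(obs)
        vals[miss, j] <- rnorm(sum(miss), mu - shift * s, width * s)
    }
    out <- m
    SummarizedExperiment::assay(out, "values") <- vals
    out
}
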