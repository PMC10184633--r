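# small in-code fixtures shared across tests

# 2-feature matrix with the full condition/time/replicate grid
smallOmics <- function(times = c(0, 4, 24), reps = 2, layer = "transcript",
                       scale = "VST", conditions = conditionLevels(),
                       seed = 1) {
    set.seed(seed)
    grid <- expand.grid(replicate = seq_len(reps), time_h = times,
                        condition = conditions, stringsAsFactors = FALSE)
    hdr <- mapply(formatSampleKey, grid$condition, grid$time_h,
                  grid$replicate, USE.NAMES = FALSE)
    v <- matrix(rnorm(2 * nrow(grid), 10), 2,
                dimnames = list(c("ICAM1", "SELE"), hdr))
    OmicsMatrix(v, layer = layer, scale = scale)
}

# noise-free single-layer dataset from an explicit plan row
planRow <- function(cls, tnf, ifn, mult, gene = "GENE0001",
                    layer = "transcript") {
    data.frame(feature = gene, layer = layer, gene = gene, site = NA,
               true_class = cls,
               tnf_kind = tnf@kind, tnf_amplitude = tnf@amplitude,
               tnf_tpeak = tnf@tPeakH, tnf_rate = tnf@rate,
               ifn_kind = ifn@kind, ifn_amplitude = ifn@amplitude,
               ifn_tpeak = ifn@tPeakH, ifn_rate = ifn@rate,
               synergy_multiplier = mult, stringsAsFactors = FALSE)
}

# brute-force BH step-up: reject the k smallest p where
# k = max{ i : p_(i) <= i * alpha / m }
bhOracleReject <- function(p, alpha) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    ok <- which(ps <= seq_len(m) * alpha / m)
    rej <- logical(m)
    if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
    rej
}

# minimal differential-result table builder
diffRow <- function(feature, condition, time_h, significant,
                    layer = "transcript", log2fc = 2) {
    data.frame(feature = feature, condition = condition, time_h = time_h,
               log2fc = log2fc, significant = significant, layer = layer,
               stringsAsFactors = FALSE)
}
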