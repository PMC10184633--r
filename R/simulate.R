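#' Evaluate a shape archetype at given times
#'
#' Returns the log2 deflection from baseline at time `t` (hours). All shapes
#' are exactly zero at t = 0. Functional forms:
#' \itemize{
#'   \item `TRANSIENT_PEAK`: a gamma-style bump
#'     `A * ((t/tp) * exp(1 - t/tp))^k` with peak value `A` attained exactly
#'     at `tPeakH`; `rate` acts as the dimensionless sharpness exponent `k`.
#'   \item `SUSTAINED_RISE`: saturating exponential `A * (1 - exp(-t/rate))`.
#'   \item `LAGGED_RISE`: the same saturating rise delayed by an onset lag,
#'     `A * (1 - exp(-max(t - tPeakH, 0)/rate))` (`tPeakH` is the lag).
#'   \item `FAST_DECAY`: exponential relaxation to `A` with a short time
#'     constant, `A * (1 - exp(-t/rate))`; reaches 95 percent of `|A|` by
#'     `3 * rate`.
#'   \item `FLAT`: zero everywhere.
#' }
#'
#' @param s a [ShapeSpec-class].
#' @param t_h numeric vector of non-negative times in hours.
#' @return numeric vector of log2 deflections.
#' @export
shapeValue <- function(s, t_h) {
    stopifnot(is(s, "ShapeSpec"))
    if (any(t_h < 0)) stop("negative time in shapeValue")
    A <- s@amplitude
    switch(s@kind,
           FLAT = rep(0, length(t_h)),
           TRANSIENT_PEAK = {
               x <- t_h / s@tPeakH
               A * (x * exp(1 - x))^s@rate
           },
           SUSTAINED_RISE = A * (1 - exp(-t_h / s@rate)),
           LAGGED_RISE = A * (1 - exp(-pmax(t_h - s@tPeakH, 0) / s@rate)),
           FAST_DECAY = A * (1 - exp(-t_h / s@rate)),
           stop("unknown shape kind: ", s@kind))
}

## default archetype per layer: fast phospho transients, transient/sustained
## transcript responses, lagged protein accumulation
.defaultShapeFor <- function(layer, amplitude, pick) {
    switch(layer,
           phospho = shapeSpec("FAST_DECAY", amplitude, rate = 0.01),
           transcript = if (pick < 0.5)
               shapeSpec("TRANSIENT_PEAK", amplitude, tPeakH = 4, rate = 2)
           else shapeSpec("SUSTAINED_RISE", amplitude, rate = 6),
           protein = shapeSpec("LAGGED_RISE", amplitude, tPeakH = 8, rate = 4),
           secretome = shapeSpec("LAGGED_RISE", amplitude, tPeakH = 8, rate = 4))
}

#' Build a ground-truth plan for one omics layer
#'
#' Draws per-feature response archetypes with known class labels. Single
#' stimulus classes activate one cytokine's shape and leave the other flat
#' (multiplier 1, so the combined course equals the active single course).
#' `COMMON` features share one identical shape across both stimuli with a
#' combined multiplier of 0.5, modelling shared-pathway saturation: the
#' combined course equals each single course, so combined/single AUC ratios
#' sit near 1 as the common class requires. `SYNERGY` features share one
#' shape with multiplier `synergyMultiplier` (default 3), putting both AUC
#' ratios at twice the multiplier. `NULL` features are flat everywhere.
#'
#' @param nPerClass named integer vector over
#'   `TNF`, `IFN`, `COMMON`, `SYNERGY`, `NULL` (missing names mean 0).
#' @param layer omics layer the features belong to.
#' @param seed RNG seed for amplitude/archetype draws.
#' @param amplitudeRange absolute amplitude range, log2 units (default 2-4).
#' @param synergyMultiplier combined-course multiplier for `SYNERGY` features.
#' @param signs allowed deflection signs (default both).
#' @return `data.frame` with one row per feature: feature id, layer, gene,
#'   site, `true_class`, TNF/IFN shape parameters and `synergy_multiplier`.
#' @export
makeTruthPlan <- function(nPerClass, layer = "transcript", seed = 1L,
                          amplitudeRange = c(2, 4), synergyMultiplier = 3,
                          signs = c(-1, 1)) {
    stopifnot(layer %in% .LAYERS)
    classes <- intersect(.TRUE_CLASSES, names(nPerClass))
    set.seed(as.integer(seed))
    rows <- list()
    i <- 0L
    flat <- shapeSpec("FLAT")
    for (cls in classes) {
        for (k in seq_len(nPerClass[[cls]])) {
            i <- i + 1L
            amp <- sample(signs, 1L) *
                runif(1L, amplitudeRange[1L], amplitudeRange[2L])
            pick <- runif(2L)
            sh <- .defaultShapeFor(layer, amp, pick[1L])
            tnf <- flat; ifn <- flat; mult <- 1
            if (cls == "TNF") tnf <- sh
            else if (cls == "IFN") ifn <- sh
            else if (cls == "COMMON") { tnf <- sh; ifn <- sh; mult <- 0.5 }
            else if (cls == "SYNERGY") { tnf <- sh; ifn <- sh
                                         mult <- synergyMultiplier }
            gene <- sprintf("GENE%04d", i)
            site <- if (layer == "phospho") sprintf("S%d", 100L + i) else NA
            rows[[i]] <- data.frame(
                feature = if (layer == "phospho") paste0(gene, "|", site) else gene,
                layer = layer, gene = gene, site = site, true_class = cls,
                tnf_kind = tnf@kind, tnf_amplitude = tnf@amplitude,
                tnf_tpeak = tnf@tPeakH, tnf_rate = tnf@rate,
                ifn_kind = ifn@kind, ifn_amplitude = ifn@amplitude,
                ifn_tpeak = ifn@tPeakH, ifn_rate = ifn@rate,
                synergy_multiplier = mult, stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}

.planShape <- function(row, which) {
    shapeSpec(kind = row[[paste0(which, "_kind")]],
              amplitude = row[[paste0(which, "_amplitude")]],
              tPeakH = row[[paste0(which, "_tpeak")]],
              rate = row[[paste0(which, "_rate")]])
}

#' Generate a synthetic multi-layer stimulation dataset
#'
#' For every plan feature, the control course is a constant baseline; the
#' single-stimulus courses add the respective shape deflection; the combined
#' course adds `synergy_multiplier * (tnf + ifn)` deflection. Replicate noise
#' is i.i.d. Gaussian on the log scale. Proteomic layers (phospho, protein,
#' secretome) then lose values through a logistic intensity-dependent
#' dropout. One RNG stream seeded from `cfg@seed` drives baselines, noise and
#' missingness in feature-major order, so identical config and plan reproduce
#' the dataset bit-identically.
#'
#' @param cfg a [SimConfig-class].
#' @param truthPlan plan `data.frame` from [makeTruthPlan()] (layers may be
#'   mixed; one matrix is emitted per layer present).
#' @return list with `matrices` (named list of [OmicsMatrix-class] per layer)
#'   and `truth` (the plan with a `true_class` column).
#' @export
generateDataset <- function(cfg, truthPlan) {
    stopifnot(is(cfg, "SimConfig"), nrow(truthPlan) > 0L)
    set.seed(cfg@seed)
    times <- cfg@timesH
    reps <- seq_len(cfg@nReplicates)
    samples <- expand.grid(replicate = reps, time_h = times,
                           condition = .CONDITIONS,
                           stringsAsFactors = FALSE)[, 3:1]
    headers <- mapply(formatSampleKey, samples$condition, samples$time_h,
                      samples$replicate, USE.NAMES = FALSE)
    matrices <- list()
    for (layer in intersect(.LAYERS, unique(truthPlan$layer))) {
        plan <- truthPlan[truthPlan$layer == layer, , drop = FALSE]
        vals <- matrix(NA_real_, nrow(plan), nrow(samples),
                       dimnames = list(plan$feature, headers))
        baseRange <- if (layer == "transcript") c(6, 12) else c(18, 24)
        for (f in seq_len(nrow(plan))) {
            row <- plan[f, ]
            tnf <- shapeValue(.planShape(row, "tnf"), times)
            ifn <- shapeValue(.planShape(row, "ifn"), times)
            defl <- rbind(CTRL = 0, TNF = tnf, IFN = ifn,
                          TNF_IFN = row$synergy_multiplier * (tnf + ifn))
            baseline <- runif(1L, baseRange[1L], baseRange[2L])
            mu <- baseline + defl[cbind(match(samples$condition, rownames(defl)),
                                        match(samples$time_h, times))]
            x <- mu + rnorm(nrow(samples), 0, cfg@noiseSd)
            if (layer %in% .PROTEOMIC_LAYERS) {
                pMiss <- stats::plogis(-(x - cfg@missingMidpoint) *
                                       cfg@missingSlope)
                x[runif(nrow(samples)) < pMiss] <- NA_real_
            }
            vals[f, ] <- x
        }
        scale <- if (layer == "transcript") "VST" else "LOG2_LFQ"
        matrices[[layer]] <- OmicsMatrix(vals, layer = layer, scale = scale)
    }
    list(matrices = matrices, truth = truthPlan)
}

#' Write a synthetic dataset as a plain-text fixture
#'
#' Emits one matrix TSV per layer (`<layer>.tsv`), the ground-truth plan
#' (`ground_truth.tsv`) and a `layers.tsv` manifest mapping layer to scale
#' and file. Round-trips through [readOmicsMatrix()].
#'
#' @param dataset result of [generateDataset()].
#' @param outDir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return `outDir`, invisibly.
#' @export
writeFixture <- function(dataset, outDir, overwrite = FALSE) {
    if (dir.exists(outDir) && length(dir(outDir)) > 0L && !overwrite)
        stop("output directory ", outDir,
             " is not empty; use overwrite = TRUE")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    man <- data.frame(layer = character(), scale = character(),
                      file = character())
    for (layer in names(dataset$matrices)) {
        f <- paste0(layer, ".tsv")
        writeOmicsMatrix(dataset$matrices[[layer]], file.path(outDir, f))
        man <- rbind(man, data.frame(layer = layer,
                                     scale = valueScale(dataset$matrices[[layer]]),
                                     file = f))
    }
    write.table(dataset$truth, file.path(outDir, "ground_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(man, file.path(outDir, "layers.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(outDir)
}

#' Read back a fixture written by [writeFixture()]
#' @param dir fixture directory.
#' @return list with `matrices` and `truth`, as from [generateDataset()].
#' @export
readFixture <- function(dir) {
    man <- read.delim(file.path(dir, "layers.tsv"), stringsAsFactors = FALSE)
    matrices <- list()
    for (i in seq_len(nrow(man)))
        matrices[[man$layer[i]]] <- readOmicsMatrix(
            file.path(dir, man$file[i]), man$layer[i], man$scale[i])
    truth <- read.delim(file.path(dir, "ground_truth.tsv"),
                        stringsAsFactors = FALSE)
    list(matrices = matrices, truth = truth)
}
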