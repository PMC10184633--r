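#' @import methods
#' @importFrom stats approx cor median pnorm pt qnorm rnorm runif sd setNames var
#' @importFrom utils read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## controlled vocabularies shared across the pipeline
.CONDITIONS <- c("CTRL", "TNF", "IFN", "TNF_IFN")
.LAYERS <- c("phospho", "transcript", "protein", "secretome")
.SCALES <- c("LOG2_LFQ", "LOG2_SILAC_RATIO", "VST")
.SHAPE_KINDS <- c("TRANSIENT_PEAK", "SUSTAINED_RISE", "LAGGED_RISE",
                  "FAST_DECAY", "FLAT")
.TRUE_CLASSES <- c("TNF", "IFN", "COMMON", "SYNERGY", "NULL")
.FINAL_CLASSES <- c("TNF", "IFN", "COMMON", "SYNERGY", "NOT_CLASSIFIED")
## MS-based layers are subject to intensity-dependent (MNAR) missingness
.PROTEOMIC_LAYERS <- c("phospho", "protein", "secretome")

#' Condition, layer and class vocabularies
#'
#' Constant character vectors naming the stimulation conditions
#' (`CTRL`, `TNF`, `IFN`, `TNF_IFN`), the omics layers
#' (`phospho`, `transcript`, `protein`, `secretome`) and the final
#' response classes (`TNF`, `IFN`, `COMMON`, `SYNERGY`, `NOT_CLASSIFIED`).
#'
#' @return A character vector.
#' @export
conditionLevels <- function() .CONDITIONS

#' @rdname conditionLevels
#' @export
layerLevels <- function() .LAYERS

#' @rdname conditionLevels
#' @export
responseClassLevels <- function() .FINAL_CLASSES

## ---------------------------------------------------------------------------
## OmicsMatrix
## ---------------------------------------------------------------------------

#' OmicsMatrix: one omics layer's feature-by-sample value table
#'
#' An `OmicsMatrix` extends [SummarizedExperiment::SummarizedExperiment] with
#' a `layer` tag (phospho, transcript, protein or secretome) and a value
#' `scale` tag (`LOG2_LFQ`, `LOG2_SILAC_RATIO` or `VST`). Rows are features
#' identified as `"GENE"` or `"GENE|SITE"` (phospho layer only); columns are
#' samples keyed by stimulation condition, timepoint in hours and replicate.
#' Missing values are `NA` (never zero).
#'
#' @slot layer character(1), one of `layerLevels()`.
#' @slot scale character(1), the value scale tag.
#' @export
setClass("OmicsMatrix",
         contains = "SummarizedExperiment",
         slots = c(layer = "character", scale = "character"))

setValidity("OmicsMatrix", function(object) {
    msg <- character()
    if (length(object@layer) != 1L || !object@layer %in% .LAYERS)
        msg <- c(msg, sprintf("layer must be one of: %s",
                              paste(.LAYERS, collapse = ", ")))
    if (length(object@scale) != 1L || !object@scale %in% .SCALES)
        msg <- c(msg, sprintf("scale must be one of: %s",
                              paste(.SCALES, collapse = ", ")))
    cd <- colData(object)
    need <- c("condition", "time_h", "replicate")
    if (!all(need %in% colnames(cd))) {
        msg <- c(msg, "colData must contain condition, time_h, replicate")
        return(if (length(msg)) msg else TRUE)
    }
    if (!all(cd$condition %in% .CONDITIONS))
        msg <- c(msg, "unknown condition in colData")
    if (any(cd$time_h < 0)) msg <- c(msg, "time_h must be non-negative")
    if (any(cd$replicate < 1)) msg <- c(msg, "replicate must be >= 1")
    rd <- rowData(object)
    if (!all(c("gene", "site") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain gene and site")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, sprintf("duplicate feature id: %s",
                              rownames(object)[duplicated(rownames(object))][1L]))
    if ("gene" %in% colnames(rd)) {
        if (any(!nzchar(rd$gene))) msg <- c(msg, "empty gene symbol")
        has_site <- !is.na(rd$site)
        if (object@layer == "phospho" && any(!has_site))
            msg <- c(msg, "phospho features must carry a site")
        if (object@layer != "phospho" && any(has_site))
            msg <- c(msg, "site is only allowed on the phospho layer")
    }
    ## every condition must carry the full time x replicate grid
    if (nrow(cd) > 0L && !length(msg)) {
        grid <- expand.grid(time_h = sort(unique(cd$time_h)),
                            replicate = sort(unique(cd$replicate)))
        for (cond in unique(cd$condition)) {
            sub <- cd[cd$condition == cond, , drop = FALSE]
            key <- paste(sub$time_h, sub$replicate)
            full <- paste(grid$time_h, grid$replicate)
            if (anyDuplicated(key) || !setequal(key, full) ||
                length(key) != length(full))
                msg <- c(msg, sprintf(
                    "inconsistent replicate grid for condition %s", cond))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix (features x samples); `NA` marks missing.
#'   Row names are feature ids (`"GENE"` or `"GENE|SITE"`); column names, if
#'   `colData` is not given, must follow the sample-header grammar
#'   `CONDITION_T<hours>h_R<rep>` (e.g. `"TNF_T24h_R1"`).
#' @param layer one of `layerLevels()`.
#' @param scale one of `"LOG2_LFQ"`, `"LOG2_SILAC_RATIO"`, `"VST"`.
#' @param colData optional `DataFrame` with columns `condition`, `time_h`,
#'   `replicate`; parsed from `colnames(values)` when omitted.
#' @return A validated [OmicsMatrix-class] object.
#' @examples
#' v <- matrix(rnorm(4), 2, 2,
#'             dimnames = list(c("ICAM1", "SELE"),
#'                             c("TNF_T24h_R1", "TNF_T24h_R2")))
#' om <- OmicsMatrix(v, layer = "transcript", scale = "VST")
#' omicsLayer(om)
#' @export
OmicsMatrix <- function(values, layer, scale, colData = NULL) {
    if (is.null(rownames(values)))
        stop("values must have feature ids as row names")
    if (is.null(colData)) {
        if (is.null(colnames(values)))
            stop("values must have sample-key column names when colData is absent")
        colData <- do.call(rbind, lapply(colnames(values), parseSampleKey))
        colData <- DataFrame(colData, row.names = colnames(values))
    }
    rd <- .parseFeatureIds(rownames(values), layer)
    se <- SummarizedExperiment(assays = list(values = as.matrix(values)),
                               rowData = rd, colData = colData)
    new("OmicsMatrix", se, layer = layer, scale = scale)
}

.parseFeatureIds <- function(ids, layer) {
    parts <- strsplit(ids, "|", fixed = TRUE)
    gene <- toupper(vapply(parts, `[`, "", 1L))
    site <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, "")
    if (layer == "phospho" && any(is.na(site)))
        stop("phospho feature ids must be of the form GENE|SITE; offending id: ",
             ids[is.na(site)][1L])
    DataFrame(gene = gene, site = site, row.names = ids)
}

#' Parse a sample-header token
#'
#' Decodes the `CONDITION_T<hours>h_R<rep>` grammar used in the delimited
#' matrix format, e.g. `"TNF_IFN_T0.0333h_R2"`.
#'
#' @param token character(1) sample header.
#' @return A one-row `data.frame` with `condition`, `time_h`, `replicate`.
#' @export
parseSampleKey <- function(token) {
    pat <- "^(TNF_IFN|CTRL|TNF|IFN)_T([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)h_R([0-9]+)$"
    m <- regmatches(token, regexec(pat, token))[[1L]]
    if (length(m) != 4L)
        stop("malformed sample header token: '", token, "'")
    data.frame(condition = m[2L], time_h = as.numeric(m[3L]),
               replicate = as.integer(m[4L]), stringsAsFactors = FALSE)
}

#' Encode a sample key as a header token
#' @param condition,time_h,replicate components of the key.
#' @return character(1) header token.
#' @export
formatSampleKey <- function(condition, time_h, replicate) {
    sprintf("%s_T%sh_R%d", condition, format(time_h, digits = 15,
                                             scientific = FALSE),
            as.integer(replicate))
}

#' @describeIn OmicsMatrix omics layer tag
#' @param object,x an `OmicsMatrix`.
#' @export
omicsLayer <- function(object) object@layer

#' @describeIn OmicsMatrix value scale tag
#' @export
valueScale <- function(object) object@scale

#' @describeIn OmicsMatrix feature ids (row names)
#' @export
featureIds <- function(object) rownames(object)

#' @describeIn OmicsMatrix the numeric value matrix
#' @export
omicsValues <- function(object) assay(object, "values")

setMethod("show", "OmicsMatrix", function(object) {
    cat(sprintf("OmicsMatrix [%s, %s]: %d features x %d samples\n",
                object@layer, object@scale, nrow(object), ncol(object)))
    cd <- colData(object)
    cat("  conditions:", paste(unique(cd$condition), collapse = ", "), "\n")
    cat("  times (h):", paste(sort(unique(cd$time_h)), collapse = ", "), "\n")
    cat(sprintf("  replicates: %d; missing values: %d (%.1f%%)\n",
                length(unique(cd$replicate)),
                sum(is.na(assay(object))),
                100 * mean(is.na(assay(object)))))
})

## ---------------------------------------------------------------------------
## TimeCourse
## ---------------------------------------------------------------------------

#' TimeCourse: one feature under one condition
#'
#' Ordered timepoints with per-replicate values and per-time medians
#' (missing replicate entries are ignored; a time with all replicates
#' missing yields a missing median).
#'
#' @slot feature character(1) feature id.
#' @slot condition character(1) condition.
#' @slot timesH numeric, strictly increasing timepoints in hours.
#' @slot replicateValues numeric matrix (replicates x times).
#' @slot medians numeric, one median per timepoint.
#' @export
setClass("TimeCourse",
         slots = c(feature = "character", condition = "character",
                   timesH = "numeric", replicateValues = "matrix",
                   medians = "numeric"))

setValidity("TimeCourse", function(object) {
    msg <- character()
    if (is.unsorted(object@timesH, strictly = TRUE))
        msg <- c(msg, "timesH must be strictly increasing")
    if (length(object@medians) != length(object@timesH))
        msg <- c(msg, "medians and timesH lengths differ")
    if (ncol(object@replicateValues) != length(object@timesH))
        msg <- c(msg, "replicateValues must have one column per timepoint")
    if (length(msg)) msg else TRUE
})

#' Construct a TimeCourse
#' @param feature,condition identifiers.
#' @param timesH timepoints in hours, strictly increasing.
#' @param replicateValues numeric matrix, replicates x times; `NA` allowed.
#' @return A [TimeCourse-class] object with medians computed across replicates.
#' @export
TimeCourse <- function(feature, condition, timesH, replicateValues) {
    replicateValues <- as.matrix(replicateValues)
    med <- apply(replicateValues, 2L, function(v)
        if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE))
    new("TimeCourse", feature = feature, condition = condition,
        timesH = as.numeric(timesH), replicateValues = replicateValues,
        medians = as.numeric(med))
}

#' @describeIn TimeCourse per-time medians across replicates
#' @param object a `TimeCourse`.
#' @export
tcMedians <- function(object) object@medians

#' @describeIn TimeCourse timepoints in hours
#' @export
tcTimes <- function(object) object@timesH

setMethod("show", "TimeCourse", function(object) {
    cat(sprintf("TimeCourse %s [%s]: %d timepoints, %d replicates\n",
                object@feature, object@condition, length(object@timesH),
                nrow(object@replicateValues)))
    print(setNames(round(object@medians, 3), format(object@timesH)))
})

## ---------------------------------------------------------------------------
## ThresholdConfig
## ---------------------------------------------------------------------------

#' ThresholdConfig: every numeric cutoff the pipeline applies
#'
#' Defaults follow the study conventions: BH-adjusted p < 0.05 with
#' |log2FC| > 1 (secretome p < 0.01); shape-correlation cutoffs 0.7 (high)
#' and 0.3 (low); AUC effect-ratio cutoff 2; interaction edge score > 0.95
#' (high confidence); receptor-ligand interaction score > 0.4; downshifted
#' imputation width 0.3 and shift 1.8 (in units of the per-sample SD).
#'
#' @slot alpha BH significance level for lysate layers.
#' @slot alphaSecretome BH significance level for the secretome layer.
#' @slot lfcMin minimum |log2 fold change|.
#' @slot rHigh,rLow Pearson-correlation cutoffs for the S1-S4 shape classes.
#' @slot aucRatio AUC ratio cutoff for the E1-E3 effect classes.
#' @slot edgeScoreMin minimum combined interaction score (strict).
#' @slot ligandScoreMin minimum score linking a ligand to a receptor.
#' @slot imputeWidth,imputeShift downshifted-normal imputation parameters.
#' @export
setClass("ThresholdConfig",
         slots = c(alpha = "numeric", alphaSecretome = "numeric",
                   lfcMin = "numeric", rHigh = "numeric", rLow = "numeric",
                   aucRatio = "numeric", edgeScoreMin = "numeric",
                   ligandScoreMin = "numeric", imputeWidth = "numeric",
                   imputeShift = "numeric"),
         prototype = prototype(alpha = 0.05, alphaSecretome = 0.01,
                               lfcMin = 1.0, rHigh = 0.7, rLow = 0.3,
                               aucRatio = 2.0, edgeScoreMin = 0.95,
                               ligandScoreMin = 0.4, imputeWidth = 0.3,
                               imputeShift = 1.8))

setValidity("ThresholdConfig", function(object) {
    msg <- character()
    probs <- c(alpha = object@alpha, alphaSecretome = object@alphaSecretome)
    if (any(probs <= 0 | probs >= 1))
        msg <- c(msg, "alpha and alphaSecretome must lie in (0,1)")
    if (object@rLow >= object@rHigh) msg <- c(msg, "rLow must be < rHigh")
    if (object@aucRatio <= 1) msg <- c(msg, "aucRatio must exceed 1")
    if (object@lfcMin < 0) msg <- c(msg, "lfcMin must be non-negative")
    if (object@edgeScoreMin < 0 || object@edgeScoreMin > 1)
        msg <- c(msg, "edgeScoreMin must lie in [0,1]")
    if (length(msg)) msg else TRUE
})

#' Construct a ThresholdConfig
#' @param ... named slot overrides, e.g. `thresholdConfig(alpha = 0.01)`.
#' @return A [ThresholdConfig-class] object.
#' @export
thresholdConfig <- function(...) new("ThresholdConfig", ...)

#' Significance level appropriate for a layer
#' @param cfg a `ThresholdConfig`.
#' @param layer an omics layer.
#' @return numeric(1), `alphaSecretome` for the secretome layer, else `alpha`.
#' @export
layerAlpha <- function(cfg, layer) {
    if (identical(layer, "secretome")) cfg@alphaSecretome else cfg@alpha
}

setMethod("show", "ThresholdConfig", function(object) {
    cat("ThresholdConfig:\n")
    for (s in slotNames(object))
        cat(sprintf("  %-15s %s\n", s, format(slot(object, s))))
})

## ---------------------------------------------------------------------------
## ShapeSpec / SimConfig
## ---------------------------------------------------------------------------

#' ShapeSpec: parametric time-course archetype
#'
#' Smooth stand-ins for the canonical stimulation dynamics: a transient
#' transcript peak (e.g. 30 min-4 h), a sustained rise saturating by 24 h,
#' a lagged protein accumulation (onset 8-24 h), a fast phospho relaxation
#' (complete within minutes), or a flat null course. All shapes are zero at
#' t = 0 and are expressed as log2 deflections from baseline.
#'
#' @slot kind one of `TRANSIENT_PEAK`, `SUSTAINED_RISE`, `LAGGED_RISE`,
#'   `FAST_DECAY`, `FLAT`.
#' @slot amplitude peak log2 deflection; negative for downregulation; 0 for
#'   `FLAT`.
#' @slot tPeakH peak time in hours (`TRANSIENT_PEAK`) or onset lag
#'   (`LAGGED_RISE`).
#' @slot rate time constant in hours (rises/decay); for `TRANSIENT_PEAK` a
#'   dimensionless sharpness exponent.
#' @export
setClass("ShapeSpec",
         slots = c(kind = "character", amplitude = "numeric",
                   tPeakH = "numeric", rate = "numeric"),
         prototype = prototype(kind = "FLAT", amplitude = 0,
                               tPeakH = 4, rate = 2))

setValidity("ShapeSpec", function(object) {
    msg <- character()
    if (!object@kind %in% .SHAPE_KINDS)
        msg <- c(msg, sprintf("kind must be one of: %s",
                              paste(.SHAPE_KINDS, collapse = ", ")))
    if (object@kind == "FLAT" && object@amplitude != 0)
        msg <- c(msg, "FLAT shapes must have amplitude 0")
    if (object@rate <= 0) msg <- c(msg, "rate must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a ShapeSpec
#' @param kind shape kind; see [ShapeSpec-class].
#' @param amplitude peak log2 deflection (0 for `FLAT`).
#' @param tPeakH peak time (`TRANSIENT_PEAK`) or lag (`LAGGED_RISE`), hours.
#' @param rate time constant (h), or sharpness for `TRANSIENT_PEAK`.
#' @return A [ShapeSpec-class] object.
#' @export
shapeSpec <- function(kind = "FLAT", amplitude = 0, tPeakH = 4, rate = 2) {
    new("ShapeSpec", kind = kind, amplitude = amplitude,
        tPeakH = tPeakH, rate = rate)
}

#' SimConfig: synthetic study design
#'
#' Defaults mirror the study layout: four conditions over the grid
#' \{0, 2 min, 30 min, 4 h, 8 h, 12 h, 24 h\} with three biological
#' replicates and Gaussian replicate noise of 0.2 on the log2 scale.
#' Proteomic layers additionally receive intensity-dependent missingness
#' through a logistic dropout curve.
#'
#' @slot nFeaturesPerClass named integer vector over
#'   `TNF`, `IFN`, `COMMON`, `SYNERGY`, `NULL`.
#' @slot timesH timepoint grid in hours; must include 0 and 24.
#' @slot nReplicates replicates per condition/time (>= 2).
#' @slot noiseSd replicate noise SD, log2 units.
#' @slot missingMidpoint,missingSlope logistic dropout parameters: a value x
#'   is deleted with probability `plogis(-(x - midpoint) * slope)` in
#'   proteomic layers (probability falls with intensity).
#' @slot seed RNG seed driving noise then missingness.
#' @export
setClass("SimConfig",
         slots = c(nFeaturesPerClass = "integer", timesH = "numeric",
                   nReplicates = "integer", noiseSd = "numeric",
                   missingMidpoint = "numeric", missingSlope = "numeric",
                   seed = "integer"),
         prototype = prototype(
             nFeaturesPerClass = c(TNF = 25L, IFN = 25L, COMMON = 25L,
                                   SYNERGY = 25L, "NULL" = 25L),
             timesH = c(0, 0.0333, 0.5, 4, 8, 12, 24),
             nReplicates = 3L, noiseSd = 0.2,
             missingMidpoint = 17, missingSlope = 1.5, seed = 1L))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (!all(c(0, 24) %in% object@timesH))
        msg <- c(msg, "timesH must include 0 and 24")
    if (is.unsorted(object@timesH, strictly = TRUE))
        msg <- c(msg, "timesH must be strictly increasing")
    if (object@nReplicates < 2L) msg <- c(msg, "nReplicates must be >= 2")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
    if (!all(names(object@nFeaturesPerClass) %in% .TRUE_CLASSES))
        msg <- c(msg, "nFeaturesPerClass names must be response classes")
    if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#' @param ... named slot overrides; see [SimConfig-class] for defaults.
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(...) {
    args <- list(...)
    if (!is.null(args$nFeaturesPerClass)) {
        n <- args$nFeaturesPerClass
        args$nFeaturesPerClass <- setNames(as.integer(n), names(n))
    }
    if (!is.null(args$nReplicates))
        args$nReplicates <- as.integer(args$nReplicates)
    if (!is.null(args$seed)) args$seed <- as.integer(args$seed)
    do.call(new, c(list("SimConfig"), args))
}

setMethod("show", "SimConfig", function(object) {
    cat(sprintf("SimConfig: %d features, %d timepoints x %d replicates, noise SD %.2g, seed %d\n",
                sum(object@nFeaturesPerClass), length(object@timesH),
                object@nReplicates, object@noiseSd, object@seed))
})
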