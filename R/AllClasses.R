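#' @import methods
#' @importFrom stats coef predict sd var median setNames
NULL

#' MethylExperiment: a multi-sample methylation matrix
#'
#' S4 container for per-site methylation fractions and read coverages across
#' samples, extending \linkS4class{RangedSummarizedExperiment}. Rows are
#' site-by-modification-by-strand observations (a "site" throughout this
#' package), columns are samples. Two assays are mandatory: \code{"fraction"}
#' (methylated fraction in [0,1]) and \code{"coverage"} (valid read count).
#' Row ranges carry the genomic position (width-1 \code{GRanges}, strand kept
#' as called — plus and minus strand observations are distinct sites) with a
#' \code{mod_code} metadata column (\code{"a"} = 6mA, \code{"m"} = 5mC).
#' Column data is the sample manifest: \code{sample_id}, \code{age_days},
#' \code{group}, \code{treatment}.
#'
#' Objects are normally built with \code{\link{buildMethylMatrix}}, which
#' intersects per-sample site sets so the matrix is complete-case by
#' construction (no missing cells, every coverage at or above the filter
#' threshold used upstream).
#'
#' @seealso \code{\link{buildMethylMatrix}}, \code{\link{siteKeys}},
#'   \code{\link{fractions}}, \code{\link{coverages}}
#' @export
setClass("MethylExperiment", contains = "RangedSummarizedExperiment")

.validMethylExperiment <- function(object) {
    msg <- NULL
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("fraction", "coverage") %in% an))
        msg <- c(msg, "assays must include 'fraction' and 'coverage'")
    else {
        fr <- SummarizedExperiment::assay(object, "fraction")
        cv <- SummarizedExperiment::assay(object, "coverage")
        if (anyNA(fr) || anyNA(cv))
            msg <- c(msg, "missing cells are not allowed (complete-case by construction)")
        else {
            if (any(fr < 0 | fr > 1))
                msg <- c(msg, "fractions must lie in [0, 1]")
            if (any(cv < 0))
                msg <- c(msg, "coverages must be non-negative")
        }
    }
    cd <- SummarizedExperiment::colData(object)
    need <- c("sample_id", "age_days", "group", "treatment")
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, sprintf("colData must carry %s", paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(cd$sample_id))
            msg <- c(msg, "sample_id must be unique")
        if (any(cd$age_days <= 0))
            msg <- c(msg, "age_days must be positive")
    }
    rr <- SummarizedExperiment::rowRanges(object)
    if (!"mod_code" %in% colnames(S4Vectors::mcols(rr)))
        msg <- c(msg, "rowRanges must carry a 'mod_code' metadata column")
    else if (!all(S4Vectors::mcols(rr)$mod_code %in% c("a", "m")))
        msg <- c(msg, "mod_code must be 'a' (6mA) or 'm' (5mC)")
    if (is.null(msg)) TRUE else msg
}
setValidity("MethylExperiment", .validMethylExperiment)

#' @describeIn MethylExperiment compact display
#' @param object a \code{MethylExperiment}
#' @export
setMethod("show", "MethylExperiment", function(object) {
    cat("MethylExperiment:", nrow(object), "sites x", ncol(object), "samples\n")
    mods <- table(S4Vectors::mcols(SummarizedExperiment::rowRanges(object))$mod_code)
    cat("  mod channels:",
        paste(sprintf("%s=%d", names(mods), as.integer(mods)), collapse = ", "), "\n")
    cd <- SummarizedExperiment::colData(object)
    cat("  ages (days):", paste(sort(unique(cd$age_days)), collapse = ", "), "\n")
    cat("  groups:", paste(levels(factor(cd$group)), collapse = ", "), "\n")
    trt <- setdiff(unique(as.character(cd$treatment)), "none")
    if (length(trt)) cat("  treatments:", paste(trt, collapse = ", "), "\n")
    invisible(NULL)
})

#' Accessors for MethylExperiment
#'
#' \code{fractions} and \code{coverages} return the two assays;
#' \code{siteKeys} returns the canonical site identifier
#' \code{"contig:start:strand:mod"} (0-based start, bedMethyl convention);
#' \code{sampleAges} and \code{sampleGroups} expose the manifest columns.
#'
#' @param x a \code{MethylExperiment}
#' @return \code{fractions}/\code{coverages}: numeric matrix (sites x
#'   samples); \code{siteKeys}: character vector; \code{sampleAges}: numeric
#'   vector of ages in days; \code{sampleGroups}: character vector.
#' @name methylexperiment-accessors
NULL

#' @rdname methylexperiment-accessors
#' @export
fractions <- function(x) SummarizedExperiment::assay(x, "fraction")

#' @rdname methylexperiment-accessors
#' @export
coverages <- function(x) SummarizedExperiment::assay(x, "coverage")

#' @rdname methylexperiment-accessors
#' @export
siteKeys <- function(x) {
    rr <- SummarizedExperiment::rowRanges(x)
    paste(as.character(GenomicRanges::seqnames(rr)),
          GenomicRanges::start(rr) - 1L,
          as.character(GenomicRanges::strand(rr)),
          S4Vectors::mcols(rr)$mod_code, sep = ":")
}

#' @rdname methylexperiment-accessors
#' @export
sampleAges <- function(x) SummarizedExperiment::colData(x)$age_days

#' @rdname methylexperiment-accessors
#' @export
sampleGroups <- function(x) as.character(SummarizedExperiment::colData(x)$group)

#' ClockModel: a fitted penalized-regression epigenetic clock
#'
#' Holds the final refit model of one clock type together with its
#' cross-validation history. Slots:
#' \describe{
#'   \item{clockType}{\code{"elasticnet_levels"}, \code{"ridge_dms"} or
#'     \code{"elasticnet_entropy"}.}
#'   \item{mixing}{glmnet alpha: 0.5 for elastic net, 0 for ridge.}
#'   \item{sites}{site keys of features with nonzero coefficient in the final
#'     refit (ridge keeps all input sites).}
#'   \item{coefficients}{named numeric vector on the original feature scale.}
#'   \item{intercept}{model intercept (days).}
#'   \item{lambda}{penalty chosen by full-training leave-one-out CV.}
#'   \item{foldFeatureCounts}{nonzero-feature count in each outer LOOCV fold.}
#'   \item{foldLambdas}{penalty chosen in each outer fold's inner CV.}
#'   \item{cvPredictions}{outer-fold (cross-validated) predicted ages of the
#'     training samples, named by sample id.}
#'   \item{trainingMetrics}{list with cross-validated \code{mae_days},
#'     \code{mre_percent}, \code{pearson_r}.}
#'   \item{featureNames}{all feature columns the model was trained on (the
#'     prediction contract: new samples must provide these).}
#' }
#' @export
setClass("ClockModel", representation(
    clockType = "character",
    mixing = "numeric",
    sites = "character",
    coefficients = "numeric",
    intercept = "numeric",
    lambda = "numeric",
    foldFeatureCounts = "integer",
    foldLambdas = "numeric",
    cvPredictions = "numeric",
    trainingMetrics = "list",
    featureNames = "character"
))

setValidity("ClockModel", function(object) {
    msg <- NULL
    if (!object@clockType %in% c("elasticnet_levels", "ridge_dms", "elasticnet_entropy"))
        msg <- c(msg, "unknown clockType")
    if (length(object@mixing) != 1 || object@mixing < 0 || object@mixing > 1)
        msg <- c(msg, "mixing must be a single value in [0, 1]")
    if (length(object@coefficients) != length(object@sites))
        msg <- c(msg, "coefficients must be named by the selected sites")
    if (!is.finite(object@intercept))
        msg <- c(msg, "intercept must be finite")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn ClockModel compact display
#' @param object a \code{ClockModel}
#' @export
setMethod("show", "ClockModel", function(object) {
    cat("ClockModel (", object@clockType, ", alpha = ", object@mixing, ")\n", sep = "")
    cat("  features in:", length(object@featureNames),
        "| nonzero:", length(object@sites), "\n")
    cat("  lambda:", signif(object@lambda, 4), "\n")
    tm <- object@trainingMetrics
    if (length(tm))
        cat(sprintf("  CV training: MAE = %.2f d, MRE = %.1f%%, r = %.3f\n",
                    tm$mae_days, tm$mre_percent, tm$pearson_r))
    invisible(NULL)
})

#' @describeIn ClockModel selected site keys (nonzero coefficients)
#' @param x a \code{ClockModel}
#' @export
selectedSites <- function(x) x@sites

#' @describeIn ClockModel named coefficient vector on the original feature scale
#' @export
clockCoefficients <- function(x) x@coefficients

#' @describeIn ClockModel cross-validated training metrics (MAE, MRE, Pearson r)
#' @export
trainingMetrics <- function(x) x@trainingMetrics
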