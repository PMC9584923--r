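#' @import methods
NULL

#' BackboneProfile: positional intensity arrays for one protein
#'
#' Per-residue aggregates of the peptides observed on a single protein
#' backbone in one tissue: summed intensity of peptides starting / stopping at
#' each position, summed coverage, distinct-peptide boundary counts, and the
#' modified-boundary subsets (amidated stops, acetylated starts).  These
#' arrays encode the peptide-cluster morphology that the PPV features are
#' computed from.
#'
#' Conservation identities tie the arrays to the underlying observations:
#' the start-intensity and stop-intensity arrays each sum to the total peptide
#' abundance, and the coverage array sums to abundance times peptide length.
#'
#' @slot accession protein accession the profile belongs to.
#' @slot length protein length in residues.
#' @slot startIntensity,stopIntensity numeric vectors (length \code{length});
#'   summed abundance of peptides starting / stopping at each position.
#' @slot coverage summed abundance of peptides covering each position.
#' @slot startCount,stopCount distinct-peptide counts per boundary position.
#' @slot amidatedStopIntensity stop intensity restricted to C-terminally
#'   amidated forms; bounded above by \code{stopIntensity}.
#' @slot acetylatedStartIntensity start intensity restricted to N-terminally
#'   acetylated forms.
#' @exportClass BackboneProfile
setClass("BackboneProfile",
    representation(
        accession = "character",
        length = "integer",
        startIntensity = "numeric",
        stopIntensity = "numeric",
        coverage = "numeric",
        startCount = "numeric",
        stopCount = "numeric",
        amidatedStopIntensity = "numeric",
        acetylatedStartIntensity = "numeric"
    )
)

setValidity("BackboneProfile", function(object) {
    L <- object@length
    msgs <- character()
    vecs <- c("startIntensity", "stopIntensity", "coverage", "startCount",
              "stopCount", "amidatedStopIntensity", "acetylatedStartIntensity")
    for (v in vecs) {
        x <- slot(object, v)
        if (length(x) != L)
            msgs <- c(msgs, sprintf("slot '%s' must have length %d", v, L))
        else if (any(x < -1e-9))
            msgs <- c(msgs, sprintf("slot '%s' must be non-negative", v))
    }
    if (length(msgs) == 0L) {
        tol <- 1e-6 * (1 + max(object@stopIntensity, 0))
        if (any(object@amidatedStopIntensity > object@stopIntensity + tol))
            msgs <- c(msgs, "amidated stop intensity exceeds stop intensity")
        if (any(object@acetylatedStartIntensity > object@startIntensity + tol))
            msgs <- c(msgs, "acetylated start intensity exceeds start intensity")
    }
    if (length(msgs)) msgs else TRUE
})

#' TransferFunction: log-linear cross-engine intensity map
#'
#' First-degree polynomial in log10-log10 space, log10(y) = a * log10(x) + b,
#' mapping Mascot intensities (x) onto the MaxQuant intensity scale (y).
#' Fitted by ordinary least squares on peptides quantified by both engines and
#' applied to peptides seen exclusively by Mascot.
#'
#' @slot a slope in log10-log10 space (dimensionless).
#' @slot b intercept (log10 intensity units).
#' @slot nFit number of intensity pairs used in the fit.
#' @slot r2 coefficient of determination of the fit.
#' @exportClass TransferFunction
setClass("TransferFunction",
    representation(a = "numeric", b = "numeric", nFit = "integer",
                   r2 = "numeric")
)

setValidity("TransferFunction", function(object) {
    if (length(object@a) != 1L || length(object@b) != 1L)
        return("'a' and 'b' must be scalars")
    if (!is.finite(object@a) || !is.finite(object@b))
        return("'a' and 'b' must be finite")
    if (object@nFit < 2L)
        return("a transfer function requires at least 2 fitted pairs")
    TRUE
})

#' PPVModel: nested cross-validated logistic PPV model bundle
#'
#' Holds everything produced by \code{\link{trainNestedCV}}: the coefficients
#' of the n_outer x n_inner inner models (20 at the 5x4 default), per-fold
#' standardization and regularization choices, out-of-fold scores for every
#' candidate, and the final model refit on all rows.
#'
#' @slot featureNames the 14 feature column names, in training order.
#' @slot innerCoefs matrix (n_outer*n_inner) x (p+1) of inner-model
#'   coefficients at each outer fold's selected regularization strength;
#'   column 1 is the intercept.
#' @slot innerFolds data.frame mapping innerCoefs rows to (outer, inner) fold.
#' @slot outerFold integer outer-fold assignment per training row.
#' @slot selectedLambda regularization strength selected in each outer fold.
#' @slot lambdaGrid the candidate strengths searched.
#' @slot finalWeights named numeric, intercept first, refit on all rows at the
#'   modal selected strength.
#' @slot center,scale standardization parameters of the final model.
#' @slot outerCenter,outerScale per-outer-fold standardization parameters
#'   (nOuter x p), computed from each fold's training rows only.
#' @slot oofScores out-of-fold PPV score per training row.
#' @slot seed,nOuter,nInner training configuration.
#' @slot upsampleRatio target positive:negative ratio after resampling
#'   positives with replacement in fitting sets (length 0 = no upsampling).
#' @exportClass PPVModel
setClass("PPVModel",
    representation(
        featureNames = "character",
        innerCoefs = "matrix",
        innerFolds = "data.frame",
        outerFold = "integer",
        selectedLambda = "numeric",
        lambdaGrid = "numeric",
        finalWeights = "numeric",
        center = "numeric",
        scale = "numeric",
        outerCenter = "matrix",
        outerScale = "matrix",
        oofScores = "numeric",
        seed = "integer",
        nOuter = "integer",
        nInner = "integer",
        upsampleRatio = "numeric"
    )
)

setValidity("PPVModel", function(object) {
    p <- length(object@featureNames)
    msgs <- character()
    if (nrow(object@innerCoefs) != object@nOuter * object@nInner)
        msgs <- c(msgs, sprintf("expected %d inner models, got %d",
                                object@nOuter * object@nInner,
                                nrow(object@innerCoefs)))
    if (ncol(object@innerCoefs) != p + 1L)
        msgs <- c(msgs, "innerCoefs must have one column per feature plus intercept")
    if (length(object@finalWeights) != p + 1L)
        msgs <- c(msgs, "finalWeights must have one entry per feature plus intercept")
    if (length(object@center) != p || length(object@scale) != p)
        msgs <- c(msgs, "center/scale must have one entry per feature")
    if (!identical(dim(object@outerCenter), c(as.integer(object@nOuter), p)) ||
        !identical(dim(object@outerScale), c(as.integer(object@nOuter), p)))
        msgs <- c(msgs, "outerCenter/outerScale must be nOuter x p matrices")
    if (length(object@oofScores) != length(object@outerFold))
        msgs <- c(msgs, "oofScores and outerFold must align")
    if (!all(object@outerFold %in% seq_len(object@nOuter)))
        msgs <- c(msgs, "outerFold values must lie in 1..nOuter")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "BackboneProfile", function(object) {
    cat("BackboneProfile for", object@accession,
        sprintf("(%d aa)\n", object@length))
    cov <- object@coverage > 0
    cat(sprintf("  covered positions: %d (%.1f%%)\n",
                sum(cov), 100 * mean(cov)))
    cat(sprintf("  total start intensity: %.4g\n", sum(object@startIntensity)))
})

setMethod("show", "TransferFunction", function(object) {
    cat(sprintf("TransferFunction: log10(y) = %.4f * log10(x) + %.4f\n",
                object@a, object@b))
    cat(sprintf("  fitted on %d shared peptides (R2 = %.3f)\n",
                object@nFit, object@r2))
})

setMethod("show", "PPVModel", function(object) {
    cat(sprintf("PPVModel: %dx%d nested CV (%d inner models), seed %d\n",
                object@nOuter, object@nInner, nrow(object@innerCoefs),
                object@seed))
    cat(sprintf("  %d candidates, %d features\n",
                length(object@oofScores), length(object@featureNames)))
    cat("  selected strengths:",
        paste(signif(object@selectedLambda, 3), collapse = ", "), "\n")
})
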