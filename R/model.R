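# The PPV model: L2-regularised logistic regression over the 14 features,
# trained with group-aware nested cross-validation (outer folds for unbiased
# out-of-fold scores, inner folds for regularization selection).  All
# candidates of one protein share an outer fold so that overlapping variants
# of one precursor never straddle a train/test split.

sigmoid <- function(z) 1 / (1 + exp(-z))

# deterministic, positive-balancing assignment of groups to k folds:
# shuffle groups (seeded), order by positive count (stable), then greedily
# place each group in the fold with the fewest positives (ties: fewest rows).
assignGroupFolds <- function(groups, positive, k, seed) {
    ug <- unique(groups)
    ug <- withr::with_seed(seed, sample(ug))
    posPer <- vapply(ug, function(g) sum(positive[groups == g]), numeric(1))
    rowsPer <- vapply(ug, function(g) sum(groups == g), numeric(1))
    ord <- order(-posPer)
    foldPos <- foldRows <- numeric(k)
    foldOf <- setNames(integer(length(ug)), ug)
    for (i in ord) {
        f <- order(foldPos, foldRows)[1]
        foldOf[ug[i]] <- f
        foldPos[f] <- foldPos[f] + posPer[i]
        foldRows[f] <- foldRows[f] + rowsPer[i]
    }
    unname(foldOf[groups])
}

standardizeStats <- function(X) {
    ctr <- colMeans(X)
    sdv <- apply(X, 2L, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    list(center = ctr, scale = sdv)
}

applyStandardize <- function(X, st) {
    sweep(sweep(X, 2L, st$center, "-"), 2L, st$scale, "/")
}

upsampleIndex <- function(y, ratio, seed) {
    idx <- seq_along(y)
    if (is.null(ratio) || length(ratio) == 0L) return(idx)
    nPos <- sum(y); nNeg <- sum(!y)
    target <- ceiling(ratio * nNeg)
    if (target <= nPos) return(idx)
    extra <- withr::with_seed(seed,
        sample(which(y), target - nPos, replace = TRUE))
    c(idx, extra)
}

fitRidge <- function(Xs, y, lambdaGrid) {
    glmnet::glmnet(Xs, factor(y, levels = c(FALSE, TRUE)),
                   family = "binomial", alpha = 0,
                   lambda = sort(lambdaGrid, decreasing = TRUE),
                   standardize = FALSE, thresh = 1e-10, maxit = 1e6)
}

ridgeCoef <- function(fit, lambda) {
    as.numeric(glmnet::coef.glmnet(fit, s = lambda, exact = FALSE))
}

ridgePredict <- function(fit, lambda, Xs) {
    cf <- ridgeCoef(fit, lambda)
    as.numeric(sigmoid(cf[1] + Xs %*% cf[-1]))
}

#' Train the PPV model with nested cross-validation
#'
#' Outer folds give each candidate exactly one out-of-fold score from a model
#' that never saw it (nor any candidate of the same protein) during training
#' or regularization selection.  Within each outer training split, an inner
#' cross-validation over \code{regGrid} selects the L2 strength by pooled
#' inner-test AUC; the default 5x4 layout yields 20 inner models whose
#' coefficients are retained for importance/directionality analysis.  The
#' deployed model is refit on all rows at the modal selected strength.
#' Standardization (per-feature mean/sd) is always computed on the fitting
#' rows of the model at hand, never on its test rows.
#'
#' @param design design matrix from \code{\link{buildDesignMatrix}}.
#' @param nOuter,nInner outer/inner fold counts (defaults 5 and 4).
#' @param regGrid candidate L2 strengths (glmnet lambda values).
#' @param upsampleRatio optional target positive:negative ratio; positives are
#'   resampled with replacement in fitting sets only (the assembly-model
#'   variant; default off).
#' @param seed integer seed; training is bit-reproducible given the seed.
#' @return a \code{\linkS4class{PPVModel}}.
#' @export
trainNestedCV <- function(design, nOuter = 5L, nInner = 4L,
                          regGrid = 10^seq(-4, 0, by = 1),
                          upsampleRatio = NULL, seed = 1L) {
    if (nOuter < 2L) stopf("nOuter must be at least 2")
    if (nInner < 2L) stopf("nInner must be at least 2")
    fn <- ppvFeatureNames()
    if (!all(fn %in% names(design)))
        stopf("design is missing feature column(s): %s",
              paste(setdiff(fn, names(design)), collapse = ", "))
    X <- as.matrix(design[, fn, drop = FALSE])
    y <- design$label == "positive"
    if (all(y) || !any(y))
        stopf("both classes are required to train the PPV model")
    groups <- as.character(design$group_key)
    seed <- as.integer(seed)

    outer <- assignGroupFolds(groups, y, nOuter, seed)
    for (o in seq_len(nOuter))
        if (sum(y[outer != o]) < 2L)
            stopf("outer training split %d has fewer than 2 positives", o)

    lambdaGrid <- sort(regGrid)
    innerCoefs <- NULL
    innerFolds <- data.frame(outer = integer(), inner = integer())
    selected <- numeric(nOuter)
    oof <- rep(NA_real_, nrow(design))
    outerCenter <- outerScale <- matrix(NA_real_, nOuter, length(fn),
                                        dimnames = list(NULL, fn))

    for (o in seq_len(nOuter)) {
        trIdx <- which(outer != o)
        teIdx <- which(outer == o)
        innerAssign <- assignGroupFolds(groups[trIdx], y[trIdx], nInner,
                                        seed + 1000L * o)
        # fit one glmnet path per inner fold, evaluate every lambda on the
        # pooled inner-test predictions
        innerFits <- vector("list", nInner)
        innerStats <- vector("list", nInner)
        predPerLambda <- matrix(NA_real_, length(trIdx), length(lambdaGrid))
        for (i in seq_len(nInner)) {
            fitRows <- trIdx[innerAssign != i]
            prdRows <- which(innerAssign == i)
            if (sum(y[fitRows]) < 1L || all(y[fitRows]))
                stopf(paste("inner training split %d/%d is single-class;",
                            "positives span too few proteins"), o, i)
            st <- standardizeStats(X[fitRows, , drop = FALSE])
            up <- upsampleIndex(y[fitRows], upsampleRatio,
                                seed + 1000L * o + i)
            Xs <- applyStandardize(X[fitRows, , drop = FALSE], st)[up, ,
                                                                   drop = FALSE]
            fit <- fitRidge(Xs, y[fitRows][up], lambdaGrid)
            innerFits[[i]] <- fit
            innerStats[[i]] <- st
            Xp <- applyStandardize(X[trIdx[prdRows], , drop = FALSE], st)
            for (l in seq_along(lambdaGrid))
                predPerLambda[prdRows, l] <- ridgePredict(fit, lambdaGrid[l],
                                                          Xp)
        }
        aucs <- vapply(seq_along(lambdaGrid), function(l) {
            rocAUC(y[trIdx], predPerLambda[, l])
        }, numeric(1))
        # ties resolved toward the stronger regularization
        best <- max(which(aucs == max(aucs)))
        selected[o] <- lambdaGrid[best]
        for (i in seq_len(nInner)) {
            innerCoefs <- rbind(innerCoefs,
                                ridgeCoef(innerFits[[i]], selected[o]))
            innerFolds <- rbind(innerFolds,
                                data.frame(outer = o, inner = i))
        }
        # outer model: refit on the full outer-train at the selected strength
        st <- standardizeStats(X[trIdx, , drop = FALSE])
        outerCenter[o, ] <- st$center
        outerScale[o, ] <- st$scale
        up <- upsampleIndex(y[trIdx], upsampleRatio, seed + 1000L * o)
        Xs <- applyStandardize(X[trIdx, , drop = FALSE], st)[up, ,
                                                             drop = FALSE]
        fit <- fitRidge(Xs, y[trIdx][up], lambdaGrid)
        oof[teIdx] <- ridgePredict(fit, selected[o],
                                   applyStandardize(X[teIdx, , drop = FALSE],
                                                    st))
    }

    tabSel <- table(selected)
    modal <- as.numeric(names(tabSel)[tabSel == max(tabSel)])
    finalLambda <- max(modal)
    stAll <- standardizeStats(X)
    upAll <- upsampleIndex(y, upsampleRatio, seed + 999983L)
    fitAll <- fitRidge(applyStandardize(X, stAll)[upAll, , drop = FALSE],
                       y[upAll], lambdaGrid)
    w <- ridgeCoef(fitAll, finalLambda)
    names(w) <- c("(Intercept)", fn)

    colnames(innerCoefs) <- c("(Intercept)", fn)
    new("PPVModel", featureNames = fn, innerCoefs = innerCoefs,
        innerFolds = innerFolds, outerFold = as.integer(outer),
        selectedLambda = selected, lambdaGrid = lambdaGrid,
        finalWeights = w, center = stAll$center, scale = stAll$scale,
        outerCenter = outerCenter, outerScale = outerScale,
        oofScores = oof, seed = seed, nOuter = as.integer(nOuter),
        nInner = as.integer(nInner),
        upsampleRatio = if (is.null(upsampleRatio)) numeric()
                        else as.numeric(upsampleRatio))
}

#' Score candidates with a trained PPV model
#'
#' Logistic of the standardized feature vector dotted with the final refit
#' weights.  The feature columns must match the training schema exactly.
#'
#' @param bundle a \code{PPVModel}.
#' @param features design matrix (or feature matrix) with the 14 feature
#'   columns.
#' @return PPV score (probability in (0, 1)) per row.
#' @export
scorePeptides <- function(bundle, features) {
    stopifnot(is(bundle, "PPVModel"))
    fn <- bundle@featureNames
    features <- as.data.frame(features)
    if (!all(fn %in% names(features)))
        stopf("feature schema mismatch; missing: %s",
              paste(setdiff(fn, names(features)), collapse = ", "))
    X <- as.matrix(features[, fn, drop = FALSE])
    Xs <- applyStandardize(X, list(center = bundle@center,
                                   scale = bundle@scale))
    w <- bundle@finalWeights
    as.numeric(sigmoid(w[1] + Xs %*% w[-1]))
}

#' Classify a PPV score into its reporting tier
#'
#' `very_high` above 0.05, `high` above 0.01, `low` otherwise; boundary
#' values fall to the lower tier (strict inequalities).
#'
#' @param p PPV score(s) in [0, 1].
#' @param veryHigh,high tier thresholds.
#' @return factor with levels `low`, `high`, `very_high`.
#' @export
classifyScoreTier <- function(p, veryHigh = 0.05, high = 0.01) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stopf("scores must lie in [0, 1]")
    factor(ifelse(p > veryHigh, "very_high", ifelse(p > high, "high", "low")),
           levels = c("low", "high", "very_high"))
}

#' Consolidate per-tissue PPV scores
#'
#' Noisy-OR combiner: 1 - prod(1 - p_t) over tissues, treating each tissue as
#' independent evidence that the peptide is real.  Symmetric in tissue order;
#' a single tissue returns its own score unchanged.
#'
#' @param scores numeric vector (or list) of per-tissue probabilities for one
#'   peptide.
#' @return consolidated probability.
#' @export
combineTissueScores <- function(scores) {
    scores <- as.numeric(unlist(scores))
    if (length(scores) == 0L) stopf("at least one tissue score is required")
    if (any(is.na(scores)) || any(scores < 0 | scores > 1))
        stopf("tissue scores must lie in [0, 1]")
    1 - prod(1 - scores)
}

#' Deterministic ranking of scored candidates
#'
#' Orders by score descending, breaking ties by total abundance descending,
#' then accession and start ascending — stable and reproducible.
#'
#' @param scores PPV scores.
#' @param totalAbundance,protein,start tie-break columns.
#' @return integer permutation placing the top candidate first.
#' @export
rankOrder <- function(scores, totalAbundance = NULL, protein = NULL,
                      start = NULL) {
    n <- length(scores)
    if (is.null(totalAbundance)) totalAbundance <- rep(0, n)
    if (is.null(protein)) protein <- rep("", n)
    if (is.null(start)) start <- rep(0L, n)
    order(-scores, -totalAbundance, protein, start)
}

#' Serialize / restore a PPV model bundle as JSON
#'
#' @param bundle a \code{PPVModel}.
#' @param path JSON file path.
#' @return \code{readModel}: the restored \code{PPVModel}.
#' @export
writeModel <- function(bundle, path) {
    stopifnot(is(bundle, "PPVModel"))
    payload <- list(
        format = "pepvar-model", version = 1L,
        featureNames = bundle@featureNames,
        innerCoefs = bundle@innerCoefs,
        innerFolds = bundle@innerFolds,
        outerFold = bundle@outerFold,
        selectedLambda = bundle@selectedLambda,
        lambdaGrid = bundle@lambdaGrid,
        finalWeights = as.list(bundle@finalWeights),
        center = as.list(bundle@center),
        scale = as.list(bundle@scale),
        outerCenter = bundle@outerCenter,
        outerScale = bundle@outerScale,
        oofScores = bundle@oofScores,
        seed = bundle@seed, nOuter = bundle@nOuter, nInner = bundle@nInner,
        upsampleRatio = bundle@upsampleRatio)
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
    p <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(p$format) || p$format != "pepvar-model")
        stopf("not a pepvar model bundle: %s", path)
    ic <- as.matrix(p$innerCoefs)
    colnames(ic) <- c("(Intercept)", p$featureNames)
    new("PPVModel", featureNames = p$featureNames, innerCoefs = ic,
        innerFolds = as.data.frame(p$innerFolds),
        outerFold = as.integer(p$outerFold),
        selectedLambda = as.numeric(p$selectedLambda),
        lambdaGrid = as.numeric(p$lambdaGrid),
        finalWeights = unlist(p$finalWeights),
        center = unlist(p$center), scale = unlist(p$scale),
        outerCenter = matrix(as.matrix(p$outerCenter),
                             ncol = length(p$featureNames),
                             dimnames = list(NULL, p$featureNames)),
        outerScale = matrix(as.matrix(p$outerScale),
                            ncol = length(p$featureNames),
                            dimnames = list(NULL, p$featureNames)),
        oofScores = as.numeric(p$oofScores), seed = as.integer(p$seed),
        nOuter = as.integer(p$nOuter), nInner = as.integer(p$nInner),
        upsampleRatio = as.numeric(p$upsampleRatio))
}
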