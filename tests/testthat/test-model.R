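# hand-made bundle for closed-form scoring checks
manualBundle <- function(weights, intercept, center = NULL, scale = NULL) {
    fn <- ppvFeatureNames()
    p <- length(fn)
    if (is.null(center)) center <- setNames(rep(0, p), fn)
    if (is.null(scale)) scale <- setNames(rep(1, p), fn)
    nOuter <- 2L; nInner <- 2L
    new("PPVModel", featureNames = fn,
        innerCoefs = matrix(0, nOuter * nInner, p + 1,
                            dimnames = list(NULL, c("(Intercept)", fn))),
        innerFolds = data.frame(outer = rep(1:2, each = 2),
                                inner = rep(1:2, 2)),
        outerFold = c(1L, 2L), selectedLambda = c(0.01, 0.01),
        lambdaGrid = 0.01,
        finalWeights = c("(Intercept)" = intercept, weights),
        center = center, scale = scale,
        outerCenter = matrix(0, nOuter, p, dimnames = list(NULL, fn)),
        outerScale = matrix(1, nOuter, p, dimnames = list(NULL, fn)),
        oofScores = c(0.5, 0.5), seed = 1L, nOuter = nOuter,
        nInner = nInner, upsampleRatio = numeric())
}

zeroFeatureRow <- function(values = NULL) {
    fn <- ppvFeatureNames()
    row <- as.data.frame(as.list(setNames(rep(0, length(fn)), fn)))
    if (!is.null(values)) row[names(values)] <- values
    row
}

test_that("scorePeptides is the logistic of the standardized dot product", {
    fn <- ppvFeatureNames()
    w <- setNames(rep(0, length(fn)), fn)
    b <- manualBundle(w, intercept = -1.3)
    expect_equal(scorePeptides(b, zeroFeatureRow()), plogis(-1.3))
    # weight 1 on f5 only, intercept -3, z-score 3 -> sigmoid(0) = 0.5
    w2 <- w; w2["f5_log_abundance"] <- 1
    b2 <- manualBundle(w2, intercept = -3)
    expect_equal(scorePeptides(b2, zeroFeatureRow(c(f5_log_abundance = 3))),
                 0.5)
    # monotone in a positively weighted feature
    s1 <- scorePeptides(b2, zeroFeatureRow(c(f5_log_abundance = 1)))
    s2 <- scorePeptides(b2, zeroFeatureRow(c(f5_log_abundance = 2)))
    expect_gt(s2, s1)
    # schema mismatch is refused
    bad <- zeroFeatureRow()
    names(bad)[1] <- "not_a_feature"
    expect_error(scorePeptides(b2, bad), "schema")
})

test_that("score tiers use the strict reporting thresholds", {
    expect_equal(as.character(classifyScoreTier(0.273)), "very_high")
    expect_equal(as.character(classifyScoreTier(0.017)), "high")
    expect_equal(as.character(classifyScoreTier(0.01)), "low")
    expect_equal(as.character(classifyScoreTier(0.05)), "high")
    expect_error(classifyScoreTier(1.2), "0, 1")
})

test_that("tissue consolidation is noisy-OR", {
    expect_equal(combineTissueScores(0.3), 0.3)
    expect_equal(combineTissueScores(c(0.5, 0.5)), 0.75)
    expect_equal(combineTissueScores(c(0.2, 1, 0.7)), 1)
    expect_equal(combineTissueScores(c(0.1, 0.9)),
                 combineTissueScores(c(0.9, 0.1)))
    expect_error(combineTissueScores(numeric()), "at least one")
    expect_error(combineTissueScores(c(0.5, 1.2)))
})

test_that("nested CV produces 20 inner models on a separable design", {
    st <- smallStudy()
    b <- trainNestedCV(st$design, seed = 1L)
    expect_equal(nrow(innerCoefficients(b)), 20L)
    expect_equal(nrow(b@innerFolds), 20L)
    # outer folds partition the candidates
    expect_equal(sort(unique(outerFoldAssignment(b))), 1:5)
    expect_length(outerFoldAssignment(b), nrow(st$design))
    # group-aware: all candidates of one protein share a fold
    split_folds <- tapply(outerFoldAssignment(b), st$design$group_key,
                          function(x) length(unique(x)))
    expect_true(all(split_folds == 1L))
    # the simulated signal is separable enough for near-perfect ranking
    expect_gte(rocAUC(st$design$label, oofScores(b)), 0.95)
})

test_that("single-class designs are refused", {
    st <- smallStudy()
    d <- st$design
    d$label <- factor("negative", levels = c("negative", "positive"))
    expect_error(trainNestedCV(d, seed = 1), "both classes")
    expect_error(trainNestedCV(st$design, nOuter = 1L, seed = 1), "nOuter")
})

test_that("training is bit-reproducible under a fixed seed", {
    st <- smallStudy()
    b1 <- trainNestedCV(st$design, seed = 9L)
    b2 <- trainNestedCV(st$design, seed = 9L)
    expect_identical(oofScores(b1), oofScores(b2))
    expect_identical(innerCoefficients(b1), innerCoefficients(b2))
    expect_identical(finalWeights(b1), finalWeights(b2))
    b3 <- trainNestedCV(st$design, seed = 10L)
    expect_false(identical(outerFoldAssignment(b1),
                           outerFoldAssignment(b3)))
})

test_that("standardization statistics never include a fold's test rows", {
    st <- smallStudy()
    b <- trainNestedCV(st$design, seed = 2L)
    X <- as.matrix(st$design[, ppvFeatureNames()])
    stz <- outerStandardization(b)
    for (o in seq_len(b@nOuter)) {
        train <- outerFoldAssignment(b) != o
        expect_equal(unname(stz$center[o, ]), unname(colMeans(X[train, ])),
                     tolerance = 1e-12)
        esd <- apply(X[train, ], 2, sd)
        esd[esd == 0] <- 1  # constant features standardize with unit scale
        expect_equal(unname(stz$scale[o, ]), unname(esd), tolerance = 1e-12)
        # and they differ from the all-rows statistics
        expect_false(isTRUE(all.equal(unname(stz$center[o, ]),
                                      unname(colMeans(X)))))
    }
})

test_that("upsampling changes fitting balance but never test rows", {
    st <- smallStudy()
    b <- trainNestedCV(st$design, seed = 3L, upsampleRatio = 0.1)
    expect_equal(length(oofScores(b)), nrow(st$design))
    expect_equal(b@upsampleRatio, 0.1)
    # out-of-fold scores still cover every candidate exactly once
    expect_false(any(is.na(oofScores(b))))
})

test_that("model bundles survive JSON serialization", {
    st <- smallStudy()
    b <- trainNestedCV(st$design, seed = 4L)
    path <- tempfile(fileext = ".json")
    writeModel(b, path)
    b2 <- readModel(path)
    expect_equal(scorePeptides(b2, st$design), scorePeptides(b, st$design))
    expect_equal(oofScores(b2), oofScores(b))
    expect_equal(innerCoefficients(b2), innerCoefficients(b))
})
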