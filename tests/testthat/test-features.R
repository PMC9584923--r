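test_that("collapseForms pools forms into candidate-level fractions", {
    # a single amidated form
    obs1 <- makeObs("P1", 5, 12, sequence = "AAAAAAAA", abundances = 100,
                    amid = TRUE)
    c1 <- collapseForms(obs1)
    expect_equal(c1$amidation_fraction, 1.0)
    # 990 amidated vs 10 unamidated -> fraction 0.99, reported "Yes"
    obs2 <- makeObs("P1", c(5, 5), c(12, 12), sequence = "AAAAAAAA",
                    abundances = c(990, 10), amid = c(TRUE, FALSE))
    c2 <- collapseForms(obs2)
    expect_equal(nrow(c2), 1L)
    expect_equal(c2$amidation_fraction, 0.99)
    expect_equal(amidationCall(c2$amidation_fraction), "Yes")
    # symmetric 50/50 -> ambiguous
    obs3 <- makeObs("P1", c(5, 5), c(12, 12), sequence = "AAAAAAAA",
                    abundances = c(50, 50), amid = c(TRUE, FALSE))
    expect_equal(amidationCall(collapseForms(obs3)$amidation_fraction),
                 "ambiguous")
    expect_equal(amidationCall(0.01), "No")
})

test_that("a lone peptide has the closed-form feature values", {
    A <- 1000
    obs <- makeObs("P1", 10, 19, sequence = paste(rep("A", 10), collapse = ""),
                   abundances = A)
    cand <- collapseForms(obs)
    prof <- list(P1 = buildProfile("P1", 40L, obs))
    eps <- 0.5 * A
    X <- computeFeatureMatrix(cand, prof, epsilon = eps)
    expect_equal(unname(X[1, "f1_intensity_start"]), log10((A + eps) / eps))
    expect_equal(unname(X[1, "f2_intensity_stop"]), log10((A + eps) / eps))
    expect_equal(unname(X[1, "f5_log_abundance"]), log10(A))
    expect_equal(unname(X[1, "f6_start_share"]), 1)
    expect_equal(unname(X[1, "f7_stop_share"]), 1)
    expect_equal(unname(X[1, "f8_cluster_share"]), 1)
    expect_equal(unname(X[1, "f13_cluster_span_ratio"]), 1)
    expect_equal(unname(X[1, "f14_log_ladder_count"]), 0)
    expect_equal(unname(X[1, "f12_log_length"]), 1)
})

test_that("boundary positions read as zero intensity", {
    A <- 100
    obs <- makeObs("P1", 1, 8, sequence = "AAAAAAAA", abundances = A)
    cand <- collapseForms(obs)
    prof <- list(P1 = buildProfile("P1", 20L, obs))
    X <- computeFeatureMatrix(cand, prof, epsilon = 1)
    # start at position 1: the s-1 term is the off-backbone zero
    expect_equal(unname(X[1, "f1_intensity_start"]), log10((A + 1) / 1))
})

test_that("features match the brute-force oracle on a hand-built cluster", {
    seqs <- c(H1 = randomProtein(60))
    obs <- makeObs(rep("H1", 4), c(10, 10, 13, 30), c(25, 20, 25, 40),
                   proteins = seqs,
                   abundances = matrix(c(1000, NA, 500, 250, 125, 60,
                                         80, NA), 4, 2),
                   amid = c(TRUE, FALSE, FALSE, FALSE),
                   acet = c(FALSE, FALSE, TRUE, FALSE))
    cand <- collapseForms(obs)
    profs <- list(H1 = buildProfile("H1", 60L, obs))
    eps <- 0.5 * attr(cand, "min_form_abundance")
    X <- computeFeatureMatrix(cand, profs)
    O <- oracleFeatures(obs, list(H1 = 60L), eps)
    expect_lt(max(abs(X - O)), 1e-10)
})

test_that("features equal the oracle on 100 random peptidomes", {
    worst <- 0
    for (seed in 1:100) {
        rp <- randomPeptidome(seed)
        cand <- collapseForms(rp$obs)
        profs <- buildProfiles(rp$obs, proteomeFromStrings(rp$proteins))
        eps <- 0.5 * attr(cand, "min_form_abundance")
        X <- computeFeatureMatrix(cand, profs)
        O <- oracleFeatures(rp$obs, as.list(nchar(rp$proteins)), eps)
        worst <- max(worst, max(abs(X - O)))
    }
    expect_lt(worst, 1e-10)
})

test_that("bounded features stay in [0, 1] and raising abundance is monotone", {
    for (seed in c(5, 23)) {
        rp <- randomPeptidome(seed)
        cand <- collapseForms(rp$obs)
        profs <- buildProfiles(rp$obs, proteomeFromStrings(rp$proteins))
        X <- computeFeatureMatrix(cand, profs)
        expect_true(all(is.finite(X)))
        bounded <- c("f6_start_share", "f7_stop_share", "f8_cluster_share",
                     "f9_sample_penetrance", "f10_amidation_fraction",
                     "f11_acetylation_fraction", "f13_cluster_span_ratio")
        expect_true(all(X[, bounded] >= 0 & X[, bounded] <= 1))
        expect_true(all(X[, "f14_log_ladder_count"] >= 0))
    }
    # monotonicity: scale one candidate's own form up, others fixed
    rp <- randomPeptidome(7)
    eps <- 0.5 * min(formAbundance(rp$obs)[formAbundance(rp$obs) > 0])
    featuresOf <- function(obs) {
        cand <- collapseForms(obs)
        profs <- buildProfiles(obs, proteomeFromStrings(rp$proteins))
        list(cand = cand, X = computeFeatureMatrix(cand, profs,
                                                   epsilon = eps))
    }
    base <- featuresOf(rp$obs)
    i <- 1L  # boost all forms of the first candidate
    key <- paste(rp$obs$protein, rp$obs$start, rp$obs$stop)
    ck <- paste(base$cand$protein, base$cand$start, base$cand$stop)
    obs2 <- rp$obs
    sel <- key == ck[i]
    icols <- grep("^intensity_", names(obs2))
    obs2[sel, icols] <- obs2[sel, icols] * 10
    boosted <- featuresOf(obs2)
    for (f in c("f1_intensity_start", "f5_log_abundance", "f6_start_share",
                "f8_cluster_share"))
        expect_gte(boosted$X[i, f], base$X[i, f])
})

test_that("annotation matching distinguishes full, partial and none", {
    cand <- data.frame(protein = c("A", "A", "A", "B"),
                       start = c(58L, 60L, 58L, 5L),
                       stop = c(68L, 65L, 68L, 10L),
                       amidation_fraction = c(0.99, 0, 0.5, 0))
    ann <- data.frame(protein = "A", start = 58L, stop = 68L, name = "SP",
                      amidated = TRUE)
    # exact+consistent, strictly inside, exact-but-ambiguous-PTM, other prot
    expect_equal(matchAnnotations(cand[1, ], ann), "full")
    expect_equal(matchAnnotations(cand[2, ], ann), "partial")
    expect_equal(matchAnnotations(cand[3, ], ann), "none")
    expect_equal(matchAnnotations(cand[4, ], ann), "none")
    # unknown amidation status is always consistent
    annU <- ann; annU$amidated <- NA
    expect_equal(matchAnnotations(cand[3, ], annU), "full")
    # annotated-unamidated requires a low fraction
    annN <- ann; annN$amidated <- FALSE
    expect_equal(matchAnnotations(cand[1, ], annN), "none")
    expect_equal(matchAnnotations(cand[2, ], annN), "partial")
})

test_that("design matrix labels positives from full matches only", {
    seqs <- c(G1 = randomProtein(80))
    obs <- makeObs(rep("G1", 5), c(10, 12, 30, 30, 50), c(25, 20, 45, 40, 60),
                   proteins = seqs, abundances = c(100, 40, 500, 50, 30),
                   amid = FALSE)
    cand <- collapseForms(obs)
    profs <- buildProfiles(obs, proteomeFromStrings(seqs))
    ann <- data.frame(protein = "G1", start = c(10L, 30L),
                      stop = c(25L, 45L), name = c("k1", "k2"),
                      amidated = c(NA, NA))
    d <- buildDesignMatrix(cand, profs, ann)
    expect_equal(sum(d$label == "positive"), 2L)
    # strictly-inside fragments stay negative but are flagged partial
    expect_equal(d$match_status[d$start == 12], "partial")
    expect_equal(d$label[d$start == 12], factor("negative",
                                                levels = c("negative",
                                                           "positive")))
    expect_equal(d$group_key, d$protein)
    # no positives -> actionable error
    annFar <- data.frame(protein = "G1", start = 70L, stop = 75L,
                         name = "x", amidated = NA)
    expect_error(buildDesignMatrix(cand, profs, annFar), "annotation")
    # duplicate candidates -> error
    expect_error(buildDesignMatrix(rbind(cand, cand[1, ]), profs, ann),
                 "duplicate")
})
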