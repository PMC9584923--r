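tinyConfig <- function(...) {
    simulationConfig(n_proteins = 12L, n_precursors = 6L,
                     protein_length_range = c(150L, 250L),
                     n_samples = 4L, ...)
}

test_that("the simulator is deterministic given its seed", {
    s1 <- simulateStudy(tinyConfig(seed = 5L))
    s2 <- simulateStudy(tinyConfig(seed = 5L))
    expect_identical(as.character(s1$proteome), as.character(s2$proteome))
    expect_identical(s1$truth, s2$truth)
    expect_identical(s1$observations, s2$observations)
    s3 <- simulateStudy(tinyConfig(seed = 6L))
    expect_false(identical(as.character(s1$proteome),
                           as.character(s3$proteome)))
})

test_that("planted peptides are flanked by dibasic motifs on demand", {
    gp <- generateProteome(tinyConfig(seed = 2L, dibasic_flank_prob = 1))
    seqs <- as.character(gp$proteome)
    dibasic <- c("KR", "RR", "KK", "RK")
    for (i in seq_len(nrow(gp$truth))) {
        ps <- seqs[[gp$truth$protein[i]]]
        s <- gp$truth$start[i]; e <- gp$truth$stop[i]
        expect_true(substr(ps, s - 2, s - 1) %in% dibasic)
        cOff <- if (gp$truth$plus_one_gly[i]) 1L else 0L
        if (gp$truth$plus_one_gly[i])
            expect_equal(substr(ps, e + 1, e + 1), "G")
        expect_true(substr(ps, e + 1 + cOff, e + 2 + cOff) %in% dibasic)
    }
    # no precursors -> empty truth set
    gp0 <- generateProteome(tinyConfig(seed = 2L, n_precursors = 0L))
    expect_equal(nrow(gp0$truth), 0L)
})

test_that("planted peptides are mutually non-nested within a precursor", {
    gp <- generateProteome(simulationConfig(seed = 8L, n_proteins = 30L,
                                            n_precursors = 20L))
    for (p in unique(gp$truth$protein)) {
        tt <- gp$truth[gp$truth$protein == p, ]
        if (nrow(tt) < 2) next
        for (i in seq_len(nrow(tt) - 1)) for (j in seq(i + 1, nrow(tt)))
            expect_false(tt$start[i] <= tt$start[j] &&
                         tt$stop[i] >= tt$stop[j] ||
                         tt$start[j] <= tt$start[i] &&
                         tt$stop[j] >= tt$stop[i])
    }
})

test_that("the noise-free limit reproduces exactly the planted peptides", {
    cfg <- tinyConfig(seed = 3L, n_ladder_fragments = 0L,
                      background_fragments_per_protein = 0L,
                      sample_log10_sd = 0,
                      detection_midpoint = -Inf)
    sim <- simulateStudy(cfg)
    expect_equal(nrow(sim$observations), nrow(sim$truth))
    expect_equal(
        sort(paste(sim$observations$protein, sim$observations$start,
                   sim$observations$stop)),
        sort(paste(sim$truth$protein, sim$truth$start, sim$truth$stop)))
    # boundary-exact, fully penetrant, f6 = f7 = 1
    cand <- collapseForms(sim$observations)
    profs <- buildProfiles(sim$observations, sim$proteome)
    X <- computeFeatureMatrix(cand, profs)
    expect_true(all(X[, "f6_start_share"] == 1))
    expect_true(all(X[, "f7_stop_share"] == 1))
    expect_true(all(X[, "f9_sample_penetrance"] == 1))
})

test_that("amidation propagates only to fragments keeping the C-terminus", {
    cfg <- tinyConfig(seed = 9L, plus_one_gly_prob = 1,
                      amidation_given_gly_prob = 1,
                      background_fragments_per_protein = 0L,
                      detection_midpoint = -Inf)
    sim <- simulateStudy(cfg)
    expect_true(all(sim$truth$amidated))
    for (i in seq_len(nrow(sim$truth))) {
        tr <- sim$truth[i, ]
        frags <- sim$observations[sim$observations$protein == tr$protein &
                                  sim$observations$start >= tr$start &
                                  sim$observations$stop <= tr$stop, ]
        keepC <- frags$stop == tr$stop
        expect_true(all(frags$c_term_amidated[keepC]))
        expect_false(any(frags$c_term_amidated[!keepC]))
    }
})

test_that("ladder sizes match the geometric-trimming expectation", {
    # long planted peptides so the length cap never binds; detection certain
    cfg <- simulationConfig(seed = 21L, n_proteins = 60L, n_precursors = 60L,
                            peptides_per_precursor = 1L,
                            protein_length_range = c(300L, 400L),
                            planted_length_range = c(40L, 45L),
                            background_fragments_per_protein = 0L,
                            detection_midpoint = -Inf, n_samples = 4L)
    sim <- simulateStudy(cfg)
    lam <- cfg$ladder_decay
    n <- cfg$n_ladder_fragments
    # P(kn = a) = (1-lam) lam^a; the (0,0) draw is remapped to (1,0)
    kmax <- 40L
    pk <- (1 - lam) * lam^(0:kmax)
    q <- outer(pk, pk)              # q[a+1, b+1] = P(a, b)
    q[2, 1] <- q[2, 1] + q[1, 1]    # forced N-terminal trim
    q[1, 1] <- 0
    expectedDistinct <- sum(1 - (1 - q)^n)
    obsKeys <- paste(sim$observations$protein, sim$observations$start,
                     sim$observations$stop)
    perPlanted <- vapply(seq_len(nrow(sim$truth)), function(i) {
        tr <- sim$truth[i, ]
        sum(sim$observations$protein == tr$protein &
            sim$observations$start >= tr$start &
            sim$observations$stop <= tr$stop) - 1L  # minus the parent
    }, integer(1))
    # Monte-Carlo tolerance: 60 planted peptides, sd(distinct) < 2
    expect_lt(abs(mean(perPlanted) - expectedDistinct),
              4 * 2 / sqrt(length(perPlanted)))
})

test_that("the truth set round-trips through the annotation format", {
    gp <- generateProteome(tinyConfig(seed = 4L))
    path <- tempfile(fileext = ".tsv")
    writeAnnotations(gp$truth, path)
    back <- readAnnotations(path)
    for (col in c("protein", "start", "stop", "name", "amidated"))
        expect_equal(back[[col]], gp$truth[[col]])
})

test_that("planted peptides outscore background candidates out of fold", {
    for (seed in c(1L, 2L, 3L)) {
        cfg <- simulationConfig(n_proteins = 40L, n_precursors = 10L,
                                seed = seed)
        sim <- simulateStudy(cfg)
        cand <- collapseForms(sim$observations)
        profs <- buildProfiles(sim$observations, sim$proteome)
        design <- buildDesignMatrix(cand, profs, sim$truth)
        b <- trainNestedCV(design, seed = seed)
        pos <- oofScores(b)[design$label == "positive"]
        neg <- oofScores(b)[design$label == "negative"]
        expect_lt(wilcox.test(pos, neg, alternative = "greater")$p.value,
                  0.01)
    }
})
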