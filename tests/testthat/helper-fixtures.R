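# Fixture builders shared across test files.  Everything is generated in
# code; nothing is read from disk.

# observation table from a compact description: one row per peptide form
makeObs <- function(protein, start, stop, sequence = NULL, proteins = NULL,
                    abundances, amid = FALSE, acet = FALSE,
                    engine = "maxquant", score = 50, tissue = "t1",
                    samples = NULL) {
    n <- length(start)
    if (is.null(sequence)) {
        stopifnot(!is.null(proteins))
        sequence <- substring(proteins[protein], start, stop)
    }
    if (is.matrix(abundances)) {
        ab <- abundances
    } else {
        ab <- matrix(abundances, ncol = 1L)
    }
    if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(ab)))
    obs <- data.frame(protein = protein, start = as.integer(start),
                      stop = as.integer(stop), sequence = sequence,
                      n_term_acetyl = rep_len(acet, n),
                      c_term_amidated = rep_len(amid, n),
                      engine = rep_len(engine, n),
                      engine_score = rep_len(score, n),
                      tissue = rep_len(tissue, n),
                      group = rep_len("WT", n),
                      multi_mapped = rep_len(FALSE, n),
                      stringsAsFactors = FALSE)
    colnames(ab) <- paste0("intensity_", samples)
    cbind(obs, as.data.frame(ab))
}

randomProtein <- function(L) {
    paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                 L, replace = TRUE), collapse = "")
}

# random small peptidome: <= 5 proteins, <= 50 peptide forms, 3 samples with
# missing values, random PTM flags.  Independent of the package simulator.
randomPeptidome <- function(seed) {
    withr::with_seed(seed, {
        nProt <- sample(1:5, 1)
        lens <- sample(30:80, nProt, replace = TRUE)
        accs <- sprintf("RP%02d", seq_len(nProt))
        seqs <- vapply(lens, randomProtein, character(1))
        names(seqs) <- accs
        nPep <- sample(5:50, 1)
        p <- sample(accs, nPep, replace = TRUE)
        s <- e <- integer(nPep)
        for (i in seq_len(nPep)) {
            L <- lens[match(p[i], accs)]
            len <- sample(3:min(20L, L), 1)
            s[i] <- sample(L - len + 1L, 1)
            e[i] <- s[i] + len - 1L
        }
        ab <- matrix(10^runif(nPep * 3, 2, 6), nPep, 3)
        ab[matrix(runif(nPep * 3) < 0.3, nPep, 3)] <- NA
        # every form needs one detected sample
        none <- rowSums(!is.na(ab)) == 0
        ab[none, 1] <- 10^runif(sum(none), 2, 6)
        obs <- makeObs(p, s, e, proteins = seqs, abundances = ab,
                       amid = runif(nPep) < 0.25, acet = runif(nPep) < 0.15)
        list(proteins = seqs, obs = obs)
    })
}

proteomeFromStrings <- function(seqs) {
    ps <- Biostrings::AAStringSet(seqs)
    names(ps) <- names(seqs)
    ps
}

# default-preset study with trained model, reused by the acceptance tests
defaultStudy <- function() {
    if (is.null(.fixtureEnv$default)) {
        sim <- simulateStudy(simulationConfig(seed = 1L))
        cand <- collapseForms(sim$observations)
        profs <- buildProfiles(sim$observations, sim$proteome)
        design <- buildDesignMatrix(cand, profs, sim$truth)
        bundle <- trainNestedCV(design, seed = 1L)
        .fixtureEnv$default <- list(sim = sim, design = design,
                                    bundle = bundle)
    }
    .fixtureEnv$default
}

# small simulated study reused by several model tests (computed once)
.fixtureEnv <- new.env(parent = emptyenv())
smallStudy <- function() {
    if (is.null(.fixtureEnv$small)) {
        cfg <- simulationConfig(n_proteins = 40L, n_precursors = 10L,
                                seed = 11L)
        sim <- simulateStudy(cfg)
        cand <- collapseForms(sim$observations)
        profs <- buildProfiles(sim$observations, sim$proteome)
        design <- buildDesignMatrix(cand, profs, sim$truth)
        .fixtureEnv$small <- list(sim = sim, cand = cand, profs = profs,
                                  design = design)
    }
    .fixtureEnv$small
}
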