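# Synthetic peptidome simulator.  Generates a proteome with planted
# "mature peptide" intervals whose flanks carry prohormone-convertase
# dibasic motifs (KR/RR/KK/RK) and optional +1 Glycines licensing C-terminal
# amidation, then emits a peptide table containing (i) the planted peptides
# at log-normal signal abundance with boundary-exact termini, (ii) geometric
# exopeptidase degradation ladders trimmed from either terminus, and (iii)
# uniform background protein-turnover fragments at lower abundance, all
# observed across replicate samples through multiplicative log-normal noise
# and a logistic detection model.

# approximate vertebrate proteome residue composition (normalised at use)
AA_BACKGROUND_FREQ <- c(
    A = 0.070, C = 0.023, D = 0.048, E = 0.071, F = 0.036, G = 0.066,
    H = 0.026, I = 0.044, K = 0.058, L = 0.100, M = 0.021, N = 0.036,
    P = 0.063, Q = 0.040, R = 0.056, S = 0.083, T = 0.054, V = 0.060,
    W = 0.011, Y = 0.027)

DIBASIC_MOTIFS <- c("KR", "RR", "KK", "RK")

#' Simulation configuration
#'
#' Returns the default simulation preset, optionally overridden.  The default
#' (degradation-ladder dense) preset: 300 proteins of 200-800 aa, 40 precursor
#' proteins carrying 2 planted peptides each (8-45 aa), 12 degradation-ladder
#' fragments per planted peptide, 20 background fragments per protein, and 12
#' replicate samples.  Signal peptides are drawn at log10 abundance
#' 6.5 +/- 1.0 against a background of 5.5 +/- 1.0, so abundance alone
#' separates the classes only weakly — known bioactive peptides are not
#' simply the most abundant species in a tissue.
#'
#' @param ... named overrides of any default field.
#' @return a list of class `ppv_sim_config`.
#' @export
simulationConfig <- function(...) {
    cfg <- list(
        seed = 1L,
        n_proteins = 300L,
        protein_length_range = c(200L, 800L),
        n_precursors = 40L,
        peptides_per_precursor = 2L,
        planted_length_range = c(8L, 45L),
        dibasic_flank_prob = 0.8,
        plus_one_gly_prob = 0.5,
        amidation_given_gly_prob = 0.8,
        ladder_decay = 0.8,
        n_ladder_fragments = 12L,
        background_fragments_per_protein = 20L,
        background_length_shape = 2,
        background_length_scale = 4,
        background_amidation_rate = 0.02,
        acetylation_prob = 0.1,
        signal_log10_mean = 6.5,
        signal_log10_sd = 1.0,
        background_log10_mean = 5.5,
        background_log10_sd = 1.0,
        sample_log10_sd = 0.3,
        n_samples = 12L,
        detection_midpoint = 4.5,
        detection_slope = 1.5,
        nongly_amidation_rate = 0.1,
        nongly_ep_bias = 0.7,
        tissue = "sim",
        group = "WT")
    over <- list(...)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
        stopf("unknown simulation field(s): %s",
              paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    probs <- c("dibasic_flank_prob", "plus_one_gly_prob",
               "amidation_given_gly_prob", "background_amidation_rate",
               "acetylation_prob", "nongly_amidation_rate", "nongly_ep_bias")
    for (p in probs)
        if (cfg[[p]] < 0 || cfg[[p]] > 1)
            stopf("'%s' must lie in [0, 1]", p)
    if (cfg$ladder_decay <= 0 || cfg$ladder_decay >= 1)
        stopf("'ladder_decay' must lie in (0, 1)")
    if (cfg$signal_log10_mean <= cfg$background_log10_mean)
        stopf("signal abundance must exceed background abundance")
    class(cfg) <- "ppv_sim_config"
    cfg
}

#' @export
print.ppv_sim_config <- function(x, ...) {
    cat("ppv_sim_config:",
        sprintf("%d proteins (%d precursors x %d planted), %d samples, seed %d\n",
                x$n_proteins, x$n_precursors, x$peptides_per_precursor,
                x$n_samples, x$seed))
    invisible(x)
}

randomResidues <- function(n) {
    p <- AA_BACKGROUND_FREQ / sum(AA_BACKGROUND_FREQ)
    sample(names(p), n, replace = TRUE, prob = p)
}

#' Generate a synthetic proteome with planted peptides
#'
#' Residues are drawn from a fixed background composition; the first
#' \code{n_precursors} proteins receive planted peptide intervals (mutually
#' non-nested, one per protein block).  Planted flanks are dibasic with
#' probability \code{dibasic_flank_prob}; a +1 Glycine is inserted with
#' \code{plus_one_gly_prob} (shifting the C-terminal dibasic to +2/+3, the
#' canonical G-K-R arrangement) and then licenses amidation with
#' \code{amidation_given_gly_prob}.  Without the Glycine, amidation occurs at
#' \code{nongly_amidation_rate} and biases the -1/+1 residues toward E/P with
#' probability \code{nongly_ep_bias}.  Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with `proteome` (\code{AAStringSet}) and `truth`
#'   (annotation-style data.frame with generative parameters).
#' @export
generateProteome <- function(config) {
    stopifnot(inherits(config, "ppv_sim_config"))
    withr::with_seed(config$seed, generateProteomeImpl(config))
}

generateProteomeImpl <- function(cfg) {
    lens <- sample(seq(cfg$protein_length_range[1],
                       cfg$protein_length_range[2]), cfg$n_proteins,
                   replace = TRUE)
    acc <- sprintf("SIMP%04d", seq_len(cfg$n_proteins))
    seqs <- lapply(lens, randomResidues)
    truth <- list()
    for (i in seq_len(cfg$n_precursors)) {
        L <- lens[i]
        k <- cfg$peptides_per_precursor
        blockSize <- L %/% k
        for (j in seq_len(k)) {
            b0 <- (j - 1L) * blockSize + 1L
            b1 <- j * blockSize
            margin <- 6L
            maxLen <- min(cfg$planted_length_range[2],
                          b1 - b0 + 1L - 2L * margin)
            if (maxLen < cfg$planted_length_range[1])
                stopf("protein %s too short to plant peptide %d", acc[i], j)
            plen <- sample(seq(cfg$planted_length_range[1], maxLen), 1L)
            s <- sample(seq(b0 + margin, b1 - margin - plen + 1L), 1L)
            e <- s + plen - 1L
            if (stats::runif(1) < cfg$dibasic_flank_prob)
                seqs[[i]][(s - 2L):(s - 1L)] <-
                    strsplit(sample(DIBASIC_MOTIFS, 1L), "")[[1]]
            gly <- stats::runif(1) < cfg$plus_one_gly_prob
            if (gly) {
                seqs[[i]][e + 1L] <- "G"
                if (stats::runif(1) < cfg$dibasic_flank_prob)
                    seqs[[i]][(e + 2L):(e + 3L)] <-
                        strsplit(sample(DIBASIC_MOTIFS, 1L), "")[[1]]
                amid <- stats::runif(1) < cfg$amidation_given_gly_prob
            } else {
                if (stats::runif(1) < cfg$dibasic_flank_prob)
                    seqs[[i]][(e + 1L):(e + 2L)] <-
                        strsplit(sample(DIBASIC_MOTIFS, 1L), "")[[1]]
                amid <- stats::runif(1) < cfg$nongly_amidation_rate
                if (amid && stats::runif(1) < cfg$nongly_ep_bias) {
                    seqs[[i]][e] <- sample(c("E", "P"), 1L)
                    seqs[[i]][e + 1L] <- sample(c("E", "P"), 1L)
                }
            }
            truth[[length(truth) + 1L]] <- data.frame(
                protein = acc[i], start = s, stop = e,
                name = sprintf("PLANT_%s_%d", acc[i], j),
                amidated = amid,
                plus_one_gly = gly && seqs[[i]][e + 1L] == "G",
                n_term_acetyl = stats::runif(1) < cfg$acetylation_prob,
                true_abundance = 10^stats::rnorm(1, cfg$signal_log10_mean,
                                                 cfg$signal_log10_sd),
                stringsAsFactors = FALSE)
        }
    }
    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(protein = character(), start = integer(),
                             stop = integer(), name = character(),
                             amidated = logical(), plus_one_gly = logical(),
                             n_term_acetyl = logical(),
                             true_abundance = numeric())
    proteome <- Biostrings::AAStringSet(
        vapply(seqs, paste, character(1), collapse = ""))
    names(proteome) <- acc
    list(proteome = proteome, truth = truth)
}

rgeomSurvival <- function(n, lambda) {
    # number of trimmed residues; P(k) = (1 - lambda) * lambda^k
    stats::rgeom(n, prob = 1 - lambda)
}

#' Simulate the observed peptidome of a synthetic proteome
#'
#' Each planted peptide is emitted with boundary-exact termini at its true
#' (log-normal) abundance, together with \code{n_ladder_fragments}
#' exopeptidase degradation variants trimmed from either terminus by
#' geometric(\code{ladder_decay}) residue counts, the abundance decaying by
#' the same factor per trimmed residue.  Amidation propagates only to
#' fragments retaining the planted C-terminus (acetylation to those retaining
#' the N-terminus).  Background protein-turnover fragments get uniform random
#' starts and gamma-distributed lengths at background abundance.  Per-sample
#' intensities add multiplicative log-normal noise, and a sample records a
#' peptide only when a logistic detection draw at its log10 intensity
#' succeeds; forms detected nowhere are dropped.
#'
#' @param proteome,truth output of \code{\link{generateProteome}}.
#' @param config the same \code{\link{simulationConfig}}.
#' @return observation data.frame in the package's standard layout.
#' @export
simulatePeptidome <- function(proteome, truth, config) {
    stopifnot(inherits(config, "ppv_sim_config"))
    withr::with_seed(config$seed + 1L,
                     simulatePeptidomeImpl(proteome, truth, config))
}

simulatePeptidomeImpl <- function(proteome, truth, cfg) {
    seqs <- as.character(proteome)
    lens <- nchar(seqs)
    frag <- list()
    addFrag <- function(p, s, e, ab, amid, acet) {
        frag[[length(frag) + 1L]] <<- list(p = p, s = s, e = e, ab = ab,
                                           amid = amid, acet = acet)
    }
    for (i in seq_len(nrow(truth))) {
        p <- truth$protein[i]
        s <- truth$start[i]; e <- truth$stop[i]
        A <- truth$true_abundance[i]
        plen <- e - s + 1L
        addFrag(p, s, e, A, truth$amidated[i], truth$n_term_acetyl[i])
        if (cfg$n_ladder_fragments > 0L) {
            kn <- rgeomSurvival(cfg$n_ladder_fragments, cfg$ladder_decay)
            kc <- rgeomSurvival(cfg$n_ladder_fragments, cfg$ladder_decay)
            kn[kn + kc == 0L] <- 1L  # a ladder fragment differs from its parent
            kn <- pmin(kn, plen - 7L)
            kc <- pmin(kc, pmax(plen - 7L - kn, 0L))
            for (j in seq_len(cfg$n_ladder_fragments)) {
                if (kn[j] + kc[j] == 0L) next
                addFrag(p, s + kn[j], e - kc[j],
                        A * cfg$ladder_decay^(kn[j] + kc[j]),
                        truth$amidated[i] && kc[j] == 0L,
                        truth$n_term_acetyl[i] && kn[j] == 0L)
            }
        }
    }
    nBg <- cfg$background_fragments_per_protein
    if (nBg > 0L) {
        for (p in names(seqs)) {
            L <- lens[[p]]
            bl <- 7L + floor(stats::rgamma(nBg, shape = cfg$background_length_shape,
                                           scale = cfg$background_length_scale))
            bl <- pmin(bl, L)
            bs <- vapply(bl, function(l) sample(L - l + 1L, 1L), numeric(1))
            ab <- 10^stats::rnorm(nBg, cfg$background_log10_mean,
                                  cfg$background_log10_sd)
            am <- stats::runif(nBg) < cfg$background_amidation_rate
            for (j in seq_len(nBg))
                addFrag(p, as.integer(bs[j]), as.integer(bs[j] + bl[j] - 1L),
                        ab[j], am[j], FALSE)
        }
    }
    if (length(frag) == 0L)
        return(emptyObservations(paste0(INTENSITY_PREFIX,
                                        sprintf("s%02d", seq_len(cfg$n_samples)))))
    fd <- data.frame(
        protein = vapply(frag, `[[`, character(1), "p"),
        start = vapply(frag, function(x) as.integer(x$s), integer(1)),
        stop = vapply(frag, function(x) as.integer(x$e), integer(1)),
        ab = vapply(frag, `[[`, numeric(1), "ab"),
        amid = vapply(frag, `[[`, logical(1), "amid"),
        acet = vapply(frag, `[[`, logical(1), "acet"),
        stringsAsFactors = FALSE)
    # collapse duplicate forms (same locus and PTM flags) before sampling
    key <- paste(fd$protein, fd$start, fd$stop, fd$amid, fd$acet)
    sums <- rowsum(fd$ab, key)
    fd <- fd[!duplicated(key), , drop = FALSE]
    fd$ab <- as.numeric(sums[key[!duplicated(key)], ])
    rownames(fd) <- NULL
    nS <- cfg$n_samples
    sampleNames <- sprintf("s%02d", seq_len(nS))
    n <- nrow(fd)
    noise <- matrix(10^stats::rnorm(n * nS, 0, cfg$sample_log10_sd), n, nS)
    inten <- fd$ab * noise
    detP <- stats::plogis(cfg$detection_slope *
                          (log10(inten) - cfg$detection_midpoint))
    detP[is.nan(detP)] <- 1  # -Inf midpoint: detection certain
    detected <- matrix(stats::runif(n * nS), n, nS) < detP
    inten[!detected] <- NA_real_
    keep <- rowSums(detected) > 0L
    obs <- data.frame(protein = fd$protein, start = fd$start, stop = fd$stop,
                      sequence = substring(seqs[fd$protein], fd$start,
                                           fd$stop),
                      n_term_acetyl = fd$acet, c_term_amidated = fd$amid,
                      engine = "maxquant",
                      engine_score = stats::runif(n, 20, 100),
                      tissue = cfg$tissue, group = cfg$group,
                      multi_mapped = FALSE, stringsAsFactors = FALSE)
    colnames(inten) <- paste0(INTENSITY_PREFIX, sampleNames)
    obs <- cbind(obs, as.data.frame(inten))
    obs <- obs[keep, , drop = FALSE]
    obs <- obs[order(obs$protein, obs$start, obs$stop, obs$c_term_amidated,
                     obs$n_term_acetyl), , drop = FALSE]
    rownames(obs) <- NULL
    obs
}

#' Run the full simulation preset
#'
#' Convenience wrapper: generates the proteome with its planted truth set and
#' simulates the observed peptidome.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with `proteome`, `truth`, `observations`.
#' @export
simulateStudy <- function(config = simulationConfig()) {
    gp <- generateProteome(config)
    obs <- simulatePeptidome(gp$proteome, gp$truth, config)
    list(proteome = gp$proteome, truth = gp$truth, observations = obs)
}
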