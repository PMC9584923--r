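# Flanking-region motif analysis: flank extraction from the protein backbone,
# Kullback-Leibler divergence logos contrasting high-scoring predictions with
# low-scoring background, and enrichment of residues around non-Glycine
# amidation sites.  These analyses validate predictions; flank sequence is
# deliberately NOT a model input.

#' Extract flanking regions for candidate peptides
#'
#' Reads \code{w} residues upstream of the start and downstream of the stop
#' from the protein backbone, padding with `-` beyond the protein termini.
#' `plus_one` is the residue immediately after the stop (the position a
#' Glycine must occupy for PAM-mediated C-terminal amidation).
#'
#' @param candidates data.frame with `protein`, `start`, `stop`.
#' @param proteome \code{AAStringSet} covering the candidate proteins.
#' @param w flank width in residues (default 4).
#' @return the candidates with `n_flank`, `c_flank`, `plus_one` columns added.
#' @export
extractFlanks <- function(candidates, proteome, w = 4L) {
    missing <- setdiff(unique(candidates$protein), names(proteome))
    if (length(missing))
        stopf("unknown protein(s): %s", paste(missing, collapse = ", "))
    seqs <- as.character(proteome)
    nfl <- cfl <- character(nrow(candidates))
    for (i in seq_len(nrow(candidates))) {
        ps <- seqs[[candidates$protein[i]]]
        L <- nchar(ps)
        s <- candidates$start[i]; e <- candidates$stop[i]
        if (s < 1L || e > L) stopf("candidate outside protein bounds")
        npos <- (s - w):(s - 1L)
        cpos <- (e + 1L):(e + w)
        getres <- function(pos) {
            r <- rep("-", length(pos))
            ok <- which(pos >= 1L & pos <= L)
            if (length(ok))
                r[ok] <- substring(ps, pos[ok], pos[ok])
            paste(r, collapse = "")
        }
        nfl[i] <- getres(npos)
        cfl[i] <- getres(cpos)
    }
    candidates$n_flank <- nfl
    candidates$c_flank <- cfl
    candidates$plus_one <- substr(cfl, 1L, 1L)
    candidates
}

#' Select foreground / background sets for a divergence logo
#'
#' Foreground: predictions scoring above \code{fgThreshold}.  Background: the
#' lowest-scoring \code{bgQuantile} share of predictions.  Full-match known
#' peptides are removed from both sets first (when \code{dropKnown}), so the
#' logo reflects the new predictions rather than the training peptides.
#'
#' @param predictions data.frame with `ppv_score` (and `match_status` when
#'   \code{dropKnown}).
#' @param fgThreshold foreground score cut (default 0.01).
#' @param bgQuantile background share (default 0.80).
#' @param dropKnown drop full annotation matches first (default TRUE).
#' @return list with `foreground` and `background` data.frames.
#' @export
selectLogoSets <- function(predictions, fgThreshold = 0.01,
                           bgQuantile = 0.80, dropKnown = TRUE) {
    preds <- predictions
    if (dropKnown && "match_status" %in% names(preds))
        preds <- preds[preds$match_status != "full", , drop = FALSE]
    fg <- preds[preds$ppv_score > fgThreshold, , drop = FALSE]
    if (nrow(fg) == 0L)
        stopf("empty foreground: no prediction scores above %g", fgThreshold)
    nBg <- floor(bgQuantile * nrow(preds))
    ord <- order(preds$ppv_score)
    bg <- preds[ord[seq_len(nBg)], , drop = FALSE]
    list(foreground = fg, background = bg)
}

flankCounts <- function(flanks, pseudocount) {
    w <- unique(nchar(flanks))
    if (length(w) != 1L) stopf("flank strings must share one width")
    counts <- matrix(0, w, length(AA_ALPHABET),
                     dimnames = list(NULL, AA_ALPHABET))
    for (pos in seq_len(w)) {
        ch <- substring(flanks, pos, pos)
        ch <- ch[ch %in% AA_ALPHABET]  # gap-padded termini excluded
        tb <- table(factor(ch, levels = AA_ALPHABET))
        counts[pos, ] <- as.numeric(tb)
    }
    freq <- (counts + pseudocount) /
        (rowSums(counts) + pseudocount * length(AA_ALPHABET))
    freq
}

#' Positional Kullback-Leibler divergence between flank sets
#'
#' Per flank position, residue frequencies are estimated with an additive
#' pseudocount over the 20-letter alphabet (gap symbols carry no mass) and
#' the divergence KL(fg || bg) is computed in bits.  The per-residue signed
#' contributions p_fg * log2(p_fg / p_bg) are the letter heights of a
#' divergence logo.
#'
#' @param fgFlanks,bgFlanks character vectors of equal-width flank strings.
#' @param pseudocount additive pseudocount per residue per position
#'   (default 0.5).
#' @return list with `kl` (numeric per position, bits) and `contributions`
#'   (positions x residues matrix).
#' @export
klPositionDivergence <- function(fgFlanks, bgFlanks, pseudocount = 0.5) {
    if (length(fgFlanks) == 0L || length(bgFlanks) == 0L)
        stopf("foreground and background flank sets must be non-empty")
    if (pseudocount <= 0) stopf("pseudocount must be positive")
    pf <- flankCounts(fgFlanks, pseudocount)
    pb <- flankCounts(bgFlanks, pseudocount)
    if (nrow(pf) != nrow(pb)) stopf("flank sets differ in window width")
    contrib <- pf * log2(pf / pb)
    list(kl = rowSums(contrib), contributions = contrib)
}

#' Residue enrichment around non-Glycine amidation sites
#'
#' Foreground: amidated candidates (amidation fraction above
#' \code{amidThreshold}) whose +1 residue is not Glycine — peptides whose
#' C-terminal amide cannot come from canonical PAM processing.  Background:
#' all candidates with a non-Glycine +1.  Enrichment is the foreground over
#' background frequency of each residue at the -1 (last peptide residue) and
#' +1 positions, plus the combinatorial (-1, +1) pairs.
#'
#' @param candidates data.frame with `sequence`, `amidation_fraction` and a
#'   `plus_one` column (see \code{\link{extractFlanks}}).
#' @param amidThreshold amidation-call threshold (default 0.98).
#' @return data.frame with `slot` (-1, +1 or pair), `motif`, counts,
#'   frequencies, `enrichment` and a `zero_support` flag (TRUE when the
#'   foreground is empty).
#' @export
amidationMotifEnrichment <- function(candidates, amidThreshold = 0.98) {
    if (!"plus_one" %in% names(candidates))
        stopf("candidates need a 'plus_one' column; run extractFlanks first")
    cand <- candidates[candidates$plus_one != "G" &
                       candidates$plus_one %in% AA_ALPHABET, , drop = FALSE]
    minus1 <- substring(cand$sequence, nchar(cand$sequence),
                        nchar(cand$sequence))
    fgSel <- cand$amidation_fraction > amidThreshold
    zero <- !any(fgSel)
    tabRows <- function(slot, fgv, bgv) {
        motifs <- sort(unique(bgv))
        fgN <- length(fgv); bgN <- length(bgv)
        do.call(rbind, lapply(motifs, function(m) {
            fc <- sum(fgv == m); bc <- sum(bgv == m)
            ff <- if (fgN > 0) fc / fgN else NA_real_
            bf <- bc / bgN
            data.frame(slot = slot, motif = m, fg_count = fc, bg_count = bc,
                       fg_freq = ff, bg_freq = bf,
                       enrichment = if (fgN > 0) ff / bf else NA_real_,
                       zero_support = zero, stringsAsFactors = FALSE)
        }))
    }
    out <- rbind(
        tabRows("-1", minus1[fgSel], minus1),
        tabRows("+1", cand$plus_one[fgSel], cand$plus_one),
        tabRows("pair", paste0(minus1, cand$plus_one)[fgSel],
                paste0(minus1, cand$plus_one)))
    rownames(out) <- NULL
    out
}
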