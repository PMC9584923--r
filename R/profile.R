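# Backbone profiles: per-residue positional aggregates of the peptides
# observed on one protein, and the contiguous coverage clusters they form.
# Positions outside [1, length] read as intensity 0, which keeps boundary
# step features defined at the protein termini.

#' Build a positional backbone profile
#'
#' Aggregates all observations of one protein into per-residue arrays: summed
#' abundance of peptides starting / stopping / covering each position,
#' distinct-peptide boundary counts, and the amidated-stop / acetylated-start
#' intensity subsets.  Peptide abundance is collapsed across samples with
#' \code{abundanceMode} (missing intensities count as "not detected" and
#' contribute 0 in sum mode).
#'
#' @param protein accession of the profiled protein.
#' @param proteinLength protein length in residues.
#' @param observations observation data.frame; all rows must belong to
#'   \code{protein} and lie within its bounds.
#' @param abundanceMode `"sum_samples"` (default) or `"median_samples"`.
#' @return a \code{\linkS4class{BackboneProfile}}.
#' @export
buildProfile <- function(protein, proteinLength, observations,
                         abundanceMode = c("sum_samples", "median_samples")) {
    abundanceMode <- match.arg(abundanceMode)
    L <- as.integer(proteinLength)
    obs <- observations[observations$protein == protein, , drop = FALSE]
    if (nrow(obs) != nrow(observations))
        stopf("observations for foreign protein(s) passed to buildProfile")
    startI <- stopI <- cov <- amStop <- acStart <- numeric(L)
    startC <- stopC <- numeric(L)
    if (nrow(obs)) {
        if (any(obs$start < 1L | obs$stop > L | obs$stop < obs$start))
            stopf("observation out of protein bounds for %s (length %d)",
                  protein, L)
        ab <- formAbundance(obs, abundanceMode)
        for (i in seq_len(nrow(obs))) {
            s <- obs$start[i]; e <- obs$stop[i]
            startI[s] <- startI[s] + ab[i]
            stopI[e] <- stopI[e] + ab[i]
            cov[s:e] <- cov[s:e] + ab[i]
            if (obs$c_term_amidated[i]) amStop[e] <- amStop[e] + ab[i]
            if (obs$n_term_acetyl[i]) acStart[s] <- acStart[s] + ab[i]
        }
        key <- paste(obs$start, obs$stop, sep = "-")
        uk <- !duplicated(key)
        startC <- as.numeric(tabulate(obs$start[uk], nbins = L))
        stopC <- as.numeric(tabulate(obs$stop[uk], nbins = L))
    }
    new("BackboneProfile", accession = protein, length = L,
        startIntensity = startI, stopIntensity = stopI, coverage = cov,
        startCount = startC, stopCount = stopC,
        amidatedStopIntensity = amStop, acetylatedStartIntensity = acStart)
}

#' Build profiles for every protein in a peptidome
#'
#' @param observations observation data.frame (any number of proteins).
#' @param proteome \code{AAStringSet} covering all observed proteins.
#' @inheritParams buildProfile
#' @return named list of \code{BackboneProfile}, one per observed protein.
#' @export
buildProfiles <- function(observations, proteome,
                          abundanceMode = c("sum_samples", "median_samples")) {
    abundanceMode <- match.arg(abundanceMode)
    prots <- unique(observations$protein)
    missing <- setdiff(prots, names(proteome))
    if (length(missing))
        stopf("proteome lacks accession(s): %s",
              paste(missing, collapse = ", "))
    out <- lapply(prots, function(p) {
        buildProfile(p, Biostrings::width(proteome[p]),
                     observations[observations$protein == p, , drop = FALSE],
                     abundanceMode)
    })
    names(out) <- prots
    out
}

#' Find coverage clusters on a backbone profile
#'
#' Maximal runs of residues with coverage > 0, ordered by first position.
#' When \code{observations} is supplied, each observation is assigned to
#' exactly one cluster (the run containing its interval).
#'
#' @param profile a \code{BackboneProfile}.
#' @param observations optional observation data.frame for the same protein;
#'   adds a \code{members} list-column of observation row indices.
#' @return data.frame with columns `protein`, `first`, `last` (and `members`).
#' @export
findClusters <- function(profile, observations = NULL) {
    covered <- profile@coverage > 0
    if (!any(covered)) {
        out <- data.frame(protein = character(), first = integer(),
                          last = integer())
        if (!is.null(observations)) out$members <- list()
        return(out)
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    first <- starts[r$values]
    last <- ends[r$values]
    out <- data.frame(protein = profile@accession, first = first,
                      last = last, stringsAsFactors = FALSE)
    if (!is.null(observations)) {
        out$members <- lapply(seq_len(nrow(out)), function(k) {
            which(observations$start >= out$first[k] &
                  observations$stop <= out$last[k])
        })
    }
    out
}

#' Export a profile as a per-position table
#'
#' One row per residue: position, coverage, start/stop intensity, amidated
#' stop and acetylated start intensity — the layout used for coverage-map
#' plots of peptide clusters along a precursor.
#'
#' @param profile a \code{BackboneProfile}.
#' @return data.frame with one row per position.
#' @export
profileTable <- function(profile) {
    data.frame(pos = seq_len(profile@length),
               cov = profile@coverage,
               start_int = profile@startIntensity,
               stop_int = profile@stopIntensity,
               am_stop = profile@amidatedStopIntensity,
               ac_start = profile@acetylatedStartIntensity)
}
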