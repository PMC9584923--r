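# The 14-dimensional PPV feature vector.  Candidates are collapsed peptide
# loci (protein, start, stop) pooling modified and unmodified forms; features
# are positional log-ratios and shares read off the backbone profile, plus
# abundance, penetrance, modification fractions and cluster geometry.

#' Names of the 14 PPV features, in canonical order
#' @export
ppvFeatureNames <- function() {
    c("f1_intensity_start", "f2_intensity_stop",
      "f3_coverage_step_start", "f4_coverage_step_stop",
      "f5_log_abundance", "f6_start_share", "f7_stop_share",
      "f8_cluster_share", "f9_sample_penetrance",
      "f10_amidation_fraction", "f11_acetylation_fraction",
      "f12_log_length", "f13_cluster_span_ratio", "f14_log_ladder_count")
}

#' Collapse peptide forms into candidate peptides
#'
#' One candidate per (protein, start, stop) locus within a tissue.  The
#' amidation fraction is the summed abundance of C-terminally amidated forms
#' divided by the candidate's total abundance (acetylation analogously), and
#' sample penetrance is the fraction of samples in which any form of the
#' candidate was detected.
#'
#' @param observations observation data.frame for one tissue.
#' @return candidate data.frame with columns `protein`, `start`, `stop`,
#'   `sequence`, `tissue`, `total_abundance`, `amidation_fraction`,
#'   `acetylation_fraction`, `sample_penetrance`, `n_forms`.  The smallest
#'   non-zero form abundance of the input is attached as attribute
#'   `min_form_abundance` (the basis of the default feature pseudo-intensity).
#' @export
collapseForms <- function(observations) {
    if (length(unique(observations$tissue)) > 1L)
        stopf("collapseForms expects observations from a single tissue")
    ab <- formAbundance(observations)
    key <- obsKey(observations)
    m <- intensityMatrix(observations)
    det <- !is.na(m) & m > 0
    idx <- split(seq_along(key), key)
    rows <- lapply(idx, function(ii) {
        i1 <- ii[1]
        tot <- sum(ab[ii])
        data.frame(protein = observations$protein[i1],
                   start = observations$start[i1],
                   stop = observations$stop[i1],
                   sequence = observations$sequence[i1],
                   tissue = observations$tissue[i1],
                   total_abundance = tot,
                   amidation_fraction =
                       sum(ab[ii][observations$c_term_amidated[ii]]) / tot,
                   acetylation_fraction =
                       sum(ab[ii][observations$n_term_acetyl[ii]]) / tot,
                   sample_penetrance =
                       mean(colSums(det[ii, , drop = FALSE]) > 0),
                   n_forms = length(ii),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$protein, out$start, out$stop), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "min_form_abundance") <- if (any(ab > 0)) min(ab[ab > 0]) else NA
    out
}

#' Report an amidation call from a fraction
#'
#' `"Yes"` above 0.98, `"No"` below 0.02, `"ambiguous"` in between — the
#' intensity-fraction reporting rule used for the C-terminal amidation column
#' of prediction tables.
#'
#' @param fraction amidated-intensity fraction(s) in [0, 1].
#' @param yes,no thresholds for the Yes / No calls.
#' @return character vector of calls.
#' @export
amidationCall <- function(fraction, yes = 0.98, no = 0.02) {
    ifelse(fraction > yes, "Yes", ifelse(fraction < no, "No", "ambiguous"))
}

profAt <- function(vec, i) {
    # positions outside [1, length] read as 0
    out <- numeric(length(i))
    ok <- i >= 1L & i <= length(vec)
    out[ok] <- vec[i[ok]]
    out
}

#' Compute the 14 PPV features for a candidate table
#'
#' With s = start, e = stop, eps the pseudo-intensity, and arrays read from
#' the candidate's backbone profile:
#' \itemize{
#'   \item f1/f2: log10 step of start (stop) intensity at s vs s-1 (e vs e+1);
#'   \item f3/f4: the analogous log10 steps of the coverage array;
#'   \item f5: log10 total candidate abundance;
#'   \item f6/f7: start (stop) intensity share of coverage at the boundary;
#'   \item f8: candidate abundance over the summed abundance of all candidates
#'     overlapping [s, e] (itself included);
#'   \item f9: detected-sample fraction;
#'   \item f10/f11: amidation / acetylation intensity fractions;
#'   \item f12: log10 peptide length;
#'   \item f13: peptide length over the span of its coverage cluster;
#'   \item f14: log10(1 + number of distinct observed peptides contained in
#'     [s, e], the candidate itself excluded) — the degradation-ladder count.
#' }
#'
#' @param candidates candidate data.frame from \code{\link{collapseForms}}.
#' @param profiles named list of \code{BackboneProfile} covering all candidate
#'   proteins (built from the same observations).
#' @param epsilon pseudo-intensity added inside the log ratios; default half
#'   the smallest non-zero form abundance (attribute `min_form_abundance`).
#' @return numeric matrix, one row per candidate, columns
#'   \code{\link{ppvFeatureNames}}.
#' @export
computeFeatureMatrix <- function(candidates, profiles, epsilon = NULL) {
    if (is.null(epsilon)) {
        mfa <- attr(candidates, "min_form_abundance")
        if (is.null(mfa) || is.na(mfa))
            mfa <- min(candidates$total_abundance[candidates$total_abundance > 0])
        epsilon <- 0.5 * mfa
    }
    if (!is.finite(epsilon) || epsilon <= 0)
        stopf("epsilon must be a positive pseudo-intensity")
    n <- nrow(candidates)
    X <- matrix(NA_real_, n, 14L, dimnames = list(NULL, ppvFeatureNames()))
    for (p in unique(candidates$protein)) {
        prof <- profiles[[p]]
        if (is.null(prof)) stopf("no profile for protein %s", p)
        ii <- which(candidates$protein == p)
        s <- candidates$start[ii]; e <- candidates$stop[ii]
        if (any(s < 1L | e > prof@length))
            stopf("candidate out of profile bounds on %s", p)
        tot <- candidates$total_abundance[ii]
        X[ii, 1] <- log10((profAt(prof@startIntensity, s) + epsilon) /
                          (profAt(prof@startIntensity, s - 1L) + epsilon))
        X[ii, 2] <- log10((profAt(prof@stopIntensity, e) + epsilon) /
                          (profAt(prof@stopIntensity, e + 1L) + epsilon))
        X[ii, 3] <- log10((profAt(prof@coverage, s) + epsilon) /
                          (profAt(prof@coverage, s - 1L) + epsilon))
        X[ii, 4] <- log10((profAt(prof@coverage, e) + epsilon) /
                          (profAt(prof@coverage, e + 1L) + epsilon))
        X[ii, 5] <- log10(tot)
        X[ii, 6] <- profAt(prof@startIntensity, s) / profAt(prof@coverage, s)
        X[ii, 7] <- profAt(prof@stopIntensity, e) / profAt(prof@coverage, e)
        # overlap / containment over the candidate set of this protein
        ir <- IRanges::IRanges(start = s, end = e)
        ov <- IRanges::findOverlaps(ir, ir)
        ovl <- S4Vectors::queryHits(ov)
        ovs <- S4Vectors::subjectHits(ov)
        denom <- numeric(length(ii))
        denom[sort(unique(ovl))] <- as.numeric(rowsum(tot[ovs], ovl))
        X[ii, 8] <- tot / denom
        contained <- s[ovs] >= s[ovl] & e[ovs] <= e[ovl] &
            !(s[ovs] == s[ovl] & e[ovs] == e[ovl])
        cnt <- tabulate(ovl[contained], nbins = length(ii))
        X[ii, 14] <- log10(1 + cnt)
        X[ii, 9] <- candidates$sample_penetrance[ii]
        X[ii, 10] <- candidates$amidation_fraction[ii]
        X[ii, 11] <- candidates$acetylation_fraction[ii]
        X[ii, 12] <- log10(e - s + 1)
        cl <- findClusters(prof)
        ci <- vapply(seq_along(ii), function(k) {
            which(cl$first <= s[k] & cl$last >= e[k])[1]
        }, integer(1))
        span <- cl$last[ci] - cl$first[ci] + 1L
        X[ii, 13] <- (e - s + 1) / span
    }
    X
}

#' Match candidates against the known-peptide annotation list
#'
#' A candidate is a \code{full} match when its (protein, start, stop) equals
#' an annotated peptide's and its amidation evidence is consistent with the
#' annotation: an annotated-amidated peptide requires amidation fraction above
#' \code{amidYes}, an annotated-unamidated one a fraction below \code{amidNo},
#' and unknown annotation status is always consistent.  A candidate strictly
#' inside an annotated interval of the same protein is a \code{partial} match
#' (a shorter degradation fragment of a known peptide); everything else is
#' \code{none}.
#'
#' @param candidates candidate data.frame.
#' @param annotations annotation data.frame (see \code{\link{readAnnotations}}).
#' @param amidYes,amidNo amidation consistency thresholds (Table-style
#'   `>98\% / <2\%` reporting rule).
#' @return character vector (`"full"`, `"partial"`, `"none"`) per candidate.
#' @export
matchAnnotations <- function(candidates, annotations, amidYes = 0.98,
                             amidNo = 0.02) {
    status <- rep("none", nrow(candidates))
    if (nrow(annotations) == 0L) return(status)
    for (i in seq_len(nrow(candidates))) {
        p <- candidates$protein[i]
        s <- candidates$start[i]; e <- candidates$stop[i]
        aa <- annotations[annotations$protein == p, , drop = FALSE]
        if (nrow(aa) == 0L) next
        exact <- aa$start == s & aa$stop == e
        if (any(exact)) {
            am <- aa$amidated[which(exact)[1]]
            fr <- candidates$amidation_fraction[i]
            consistent <- is.na(am) || (am && fr > amidYes) ||
                (!am && fr < amidNo)
            if (consistent) {
                status[i] <- "full"
                next
            }
        }
        inside <- aa$start <= s & aa$stop >= e & !(aa$start == s & aa$stop == e)
        if (any(inside)) status[i] <- "partial"
    }
    status
}

#' Build the PPV design matrix
#'
#' Joins the candidate table, its 14-feature matrix and the annotation labels
#' into one modelling table.  Candidates with a \code{full} annotation match
#' are the positive class; everything else — including \code{partial} matches,
#' which are retained and flagged — is negative.  The grouping key for
#' fold assignment is the protein accession, so all variants of one precursor
#' share a fold.
#'
#' @param candidates candidate data.frame from \code{\link{collapseForms}}.
#' @param profiles named list of \code{BackboneProfile}.
#' @param annotations annotation data.frame.
#' @param epsilon pseudo-intensity passed to \code{\link{computeFeatureMatrix}}.
#' @return data.frame: candidate key columns, the 14 feature columns, `label`
#'   (factor negative/positive), `match_status`, `group_key`.
#' @export
buildDesignMatrix <- function(candidates, profiles, annotations,
                              epsilon = NULL) {
    key <- paste(candidates$protein, candidates$start, candidates$stop,
                 sep = ":")
    if (anyDuplicated(key))
        stopf("duplicate candidate row(s): %s",
              paste(unique(key[duplicated(key)]), collapse = ", "))
    X <- computeFeatureMatrix(candidates, profiles, epsilon = epsilon)
    status <- matchAnnotations(candidates, annotations)
    if (!any(status == "full"))
        stopf(paste("no positive examples: no candidate fully matches the",
                    "annotation list; supply a larger annotation set"))
    design <- cbind(
        candidates[, c("protein", "start", "stop", "sequence", "tissue",
                       "total_abundance", "amidation_fraction",
                       "sample_penetrance")],
        as.data.frame(X))
    design$label <- factor(ifelse(status == "full", "positive", "negative"),
                           levels = c("negative", "positive"))
    design$match_status <- status
    design$group_key <- candidates$protein
    rownames(design) <- NULL
    design
}
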