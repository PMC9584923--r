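# PPV-assembly: stitch overlapping observed fragments into in-silico
# full-length candidate peptides.  An assembled peptide (s, e) takes an
# observed start s and an observed stop e > s and requires a chain of
# observed fragments, each lying within [s, e], consecutive members
# overlapping by at least `overlapMin` residues, the first starting exactly
# at s and the last stopping exactly at e.  Its abundance is the minimum
# positional coverage across the span — the chain is only as strong as its
# weakest bridge.

# union-find over fragment indices
dsuFind <- function(parent, i) {
    while (parent[i] != i) i <- parent[i]
    i
}

#' Assemble overlapping fragments into candidate peptides
#'
#' Enumerates every (observed start, observed stop) pair connected by an
#' overlap chain, per protein.  Pairs identical to an observed peptide are
#' emitted with \code{synthetic = FALSE}; all output is capped
#' deterministically at \code{maxPerProtein} rows per protein by descending
#' assembled abundance (ties: start, stop ascending).
#'
#' @param observations observation data.frame (one or more proteins; each
#'   protein is assembled independently).
#' @param overlapMin minimum residue overlap between consecutive chain
#'   members (default 1).
#' @param maxSpan maximum assembled length in residues (default 100).
#' @param maxPerProtein output cap per protein (default 500); capping is
#'   logged.
#' @return data.frame with columns `protein`, `start`, `stop`, `synthetic`,
#'   `assembled_abundance`, `chain` (semicolon-joined member keys
#'   `start-stop`).
#' @export
assembleFragments <- function(observations, overlapMin = 1L, maxSpan = 100L,
                              maxPerProtein = 500L) {
    out <- lapply(unique(observations$protein), function(p) {
        assembleOneProtein(
            observations[observations$protein == p, , drop = FALSE],
            overlapMin, maxSpan, maxPerProtein)
    })
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(protein = character(), start = integer(),
                          stop = integer(), synthetic = logical(),
                          assembled_abundance = numeric(),
                          chain = character(), stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
}

assembleOneProtein <- function(obs, overlapMin, maxSpan, maxPerProtein) {
    # collapse to distinct fragment intervals with summed abundance
    ab <- formAbundance(obs)
    key <- paste(obs$start, obs$stop, sep = "-")
    agg <- rowsum(ab, key)
    parts <- do.call(rbind, strsplit(rownames(agg), "-", fixed = TRUE))
    fs <- as.integer(parts[, 1]); fe <- as.integer(parts[, 2])
    fab <- as.numeric(agg)
    n <- length(fs)
    if (n == 0L) return(NULL)
    L <- max(fe)
    cov <- numeric(L)
    for (i in seq_len(n)) cov[fs[i]:fe[i]] <- cov[fs[i]:fe[i]] + fab[i]

    obsKeySet <- paste(fs, fe)
    startsU <- sort(unique(fs))
    hits <- list()
    for (s in startsU) {
        cand <- which(fs >= s)
        if (length(cand) == 0L) next
        ord <- cand[order(fe[cand], fs[cand])]
        stopsHere <- sort(unique(fe[ord]))
        stopsHere <- stopsHere[stopsHere > s & stopsHere - s + 1L <= maxSpan]
        if (length(stopsHere) == 0L) next
        parent <- integer(0)
        added <- integer(0)
        nextAdd <- 1L
        for (e in stopsHere) {
            while (nextAdd <= length(ord) && fe[ord[nextAdd]] <= e) {
                j <- ord[nextAdd]
                added <- c(added, j)
                parent[length(added)] <- length(added)
                jj <- length(added)
                if (jj > 1L) {
                    prev <- seq_len(jj - 1L)
                    ovl <- pmin(fe[added[prev]], fe[j]) -
                        pmax(fs[added[prev]], fs[j]) + 1L
                    for (q in prev[ovl >= overlapMin]) {
                        rq <- dsuFind(parent, q)
                        rj <- dsuFind(parent, jj)
                        if (rq != rj) parent[rq] <- rj
                    }
                }
                nextAdd <- nextAdd + 1L
            }
            srcs <- which(fs[added] == s)
            if (length(srcs) == 0L) next
            tgts <- which(fe[added] == e)
            if (length(tgts) == 0L) next
            roots <- vapply(seq_along(added),
                            function(q) dsuFind(parent, q), integer(1))
            if (any(roots[srcs] %in% roots[tgts]))
                hits[[length(hits) + 1L]] <- c(s, e)
        }
    }
    if (length(hits) == 0L) return(NULL)
    hm <- do.call(rbind, hits)
    res <- data.frame(protein = obs$protein[1], start = hm[, 1],
                      stop = hm[, 2], stringsAsFactors = FALSE)
    res$synthetic <- !(paste(res$start, res$stop) %in% obsKeySet)
    res$assembled_abundance <- vapply(seq_len(nrow(res)), function(i) {
        min(cov[res$start[i]:res$stop[i]])
    }, numeric(1))
    ord <- order(-res$assembled_abundance, res$start, res$stop)
    if (nrow(res) > maxPerProtein) {
        message(sprintf("assembly cap hit on %s: keeping %d of %d candidates",
                        obs$protein[1], maxPerProtein, nrow(res)))
        ord <- ord[seq_len(maxPerProtein)]
    }
    res <- res[ord, , drop = FALSE]
    res$chain <- vapply(seq_len(nrow(res)), function(i) {
        chainFor(res$start[i], res$stop[i], fs, fe, overlapMin)
    }, character(1))
    rownames(res) <- NULL
    res
}

# breadth-first shortest chain from a fragment starting at s to a fragment
# stopping at e, restricted to fragments within [s, e]
chainFor <- function(s, e, fs, fe, overlapMin) {
    inside <- which(fs >= s & fe <= e)
    a <- fs[inside]; b <- fe[inside]
    src <- which(a == s)
    prev <- rep(NA_integer_, length(inside))
    seen <- logical(length(inside))
    queue <- src
    seen[src] <- TRUE
    goal <- NA_integer_
    while (length(queue)) {
        u <- queue[1]; queue <- queue[-1]
        if (b[u] == e) { goal <- u; break }
        ovl <- pmin(b, b[u]) - pmax(a, a[u]) + 1L
        nb <- which(!seen & ovl >= overlapMin)
        seen[nb] <- TRUE
        prev[nb] <- u
        queue <- c(queue, nb)
    }
    if (is.na(goal)) return(NA_character_)
    path <- goal
    while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
    paste(paste(a[path], b[path], sep = "-"), collapse = ";")
}

#' Expansion factor of an assembly
#'
#' Synthetic assembled peptides per distinct observed peptide.
#'
#' @param assembled output of \code{\link{assembleFragments}}.
#' @param observations the observations that were assembled.
#' @return count(synthetic) / count(distinct observed peptides).
#' @export
expansionFactor <- function(assembled, observations) {
    nObs <- length(unique(obsKey(observations)))
    if (nObs == 0L) stopf("no observed peptides")
    sum(assembled$synthetic) / nObs
}
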