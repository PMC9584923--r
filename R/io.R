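# Peptidome I/O: proteome FASTA, search-engine peptide tables (MaxQuant-like
# and Mascot-like dialects), the curated annotation list, and the two-engine
# merge through a log-linear intensity transfer function.
#
# Coordinates are 1-based and inclusive everywhere (UniProt convention: the
# interval 58-68 spans 11 residues).

#' Read a proteome from FASTA
#'
#' Accessions are parsed from UniProt-style headers (`sp|ACC|NAME` or
#' `tr|ACC|NAME`) or taken as the first whitespace-delimited token of a bare
#' header.  Sequences are uppercased.
#'
#' @param path FASTA file.
#' @return an \code{AAStringSet} named by accession.
#' @export
readProteome <- function(path) {
    if (!file.exists(path)) stopf("file not found: %s", path)
    seqs <- Biostrings::readAAStringSet(path)
    if (length(seqs) == 0L) stopf("empty proteome: %s", path)
    headers <- names(seqs)
    acc <- vapply(headers, function(h) {
        tok <- strsplit(h, "[ \t]")[[1]][1]
        parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
        if (length(parts) >= 2L && parts[1] %in% c("sp", "tr"))
            parts[2]
        else
            parts[1]
    }, character(1), USE.NAMES = FALSE)
    if (anyDuplicated(acc))
        stopf("duplicate accession(s) in proteome: %s",
              paste(unique(acc[duplicated(acc)]), collapse = ", "))
    seqs <- Biostrings::AAStringSet(toupper(as.character(seqs)))
    if (any(Biostrings::width(seqs) == 0L))
        stopf("zero-length sequence for accession(s): %s",
              paste(acc[Biostrings::width(seqs) == 0L], collapse = ", "))
    names(seqs) <- acc
    seqs
}

parseFlag <- function(x) {
    if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
    if (is.numeric(x)) return(ifelse(is.na(x), FALSE, x > 0))
    x <- tolower(trimws(as.character(x)))
    x %in% c("yes", "y", "true", "1", "+")
}

maxquantColumns <- list(sequence = "Sequence", protein = "Proteins",
                        start = "Start position", stop = "End position",
                        score = "Score", amidated = "Amidated (C-term)",
                        acetylated = "Acetyl (N-term)",
                        intensity_prefix = "Intensity ")
mascotColumns <- list(sequence = "pep_seq", protein = "prot_acc",
                      start = "pep_start", stop = "pep_end",
                      score = "pep_score", amidated = "pep_amidated",
                      acetylated = "pep_acetylated",
                      intensity_prefix = "intensity_")

#' Load a search-engine peptide table
#'
#' Reads a MaxQuant-like or Mascot-like TSV, applies the row filters (peptides
#' shorter than \code{minLength} residues; Mascot identifications scoring
#' below \code{minMascotScore}), validates every peptide against the proteome,
#' and locates peptides by substring search when start/stop columns are
#' absent.  A sequence occurring at several loci of its protein yields one
#' observation per locus, flagged \code{multi_mapped}.
#'
#' @param path TSV file.
#' @param engine `"maxquant"` or `"mascot"`.
#' @param proteome an \code{AAStringSet} from \code{\link{readProteome}}.
#' @param minLength minimum peptide length in residues (default 7).
#' @param minMascotScore minimum Mascot engine score (default 20); ignored for
#'   MaxQuant tables.
#' @param tissue,group labels attached to every observation.
#' @param columns optional named list overriding the dialect's column names
#'   (elements `sequence`, `protein`, `start`, `stop`, `score`, `amidated`,
#'   `acetylated`, `intensity_prefix`).
#' @return observation data.frame (one row per peptide form per locus).
#' @export
loadObservations <- function(path, engine = c("maxquant", "mascot"), proteome,
                             minLength = 7L, minMascotScore = 20,
                             tissue = "unknown", group = NA_character_,
                             columns = NULL) {
    engine <- match.arg(engine)
    tab <- readTSV(path)
    cols <- if (engine == "maxquant") maxquantColumns else mascotColumns
    if (!is.null(columns)) cols[names(columns)] <- columns
    need <- c(cols$sequence, cols$protein)
    if (!all(need %in% names(tab)))
        stopf("missing required column(s): %s",
              paste(setdiff(need, names(tab)), collapse = ", "))
    icols <- grep(paste0("^", cols$intensity_prefix), names(tab), value = TRUE)
    if (length(icols) == 0L)
        stopf("no intensity columns with prefix '%s'", cols$intensity_prefix)
    imat <- tab[, icols, drop = FALSE]
    bad <- !vapply(imat, function(x) is.numeric(x) || all(is.na(x)),
                   logical(1))
    if (any(bad))
        stopf("malformed abundance column(s): %s",
              paste(icols[bad], collapse = ", "))

    seqs <- toupper(trimws(as.character(tab[[cols$sequence]])))
    prot <- trimws(as.character(tab[[cols$protein]]))

    n0 <- nrow(tab)
    keep <- nchar(seqs) >= minLength
    if (any(!keep))
        message(sprintf("dropped %d row(s) shorter than %d residues",
                        sum(!keep), minLength))
    if (engine == "mascot" && cols$score %in% names(tab)) {
        ok <- is.na(tab[[cols$score]]) | tab[[cols$score]] >= minMascotScore
        if (any(!ok & keep))
            message(sprintf("dropped %d row(s) with Mascot score below %g",
                            sum(!ok & keep), minMascotScore))
        keep <- keep & ok
    }
    tab <- tab[keep, , drop = FALSE]
    imat <- imat[keep, , drop = FALSE]
    seqs <- seqs[keep]
    prot <- prot[keep]
    if (nrow(tab) == 0L) message(sprintf("all %d rows filtered out", n0))

    unknown <- !(prot %in% names(proteome))
    if (any(unknown))
        stopf("unknown protein accession(s) in rows %s: %s",
              paste(utils::head(which(unknown), 10L), collapse = ", "),
              paste(unique(prot[unknown]), collapse = ", "))

    getcol <- function(nm) if (nm %in% names(tab)) tab[[nm]] else NULL
    startCol <- suppressWarnings(as.integer(getcol(cols$start)))
    stopCol <- suppressWarnings(as.integer(getcol(cols$stop)))
    scoreCol <- getcol(cols$score)
    amid <- if (is.null(getcol(cols$amidated))) rep(FALSE, nrow(tab))
            else parseFlag(getcol(cols$amidated))
    acet <- if (is.null(getcol(cols$acetylated))) rep(FALSE, nrow(tab))
            else parseFlag(getcol(cols$acetylated))

    protSeq <- as.character(proteome)
    out <- vector("list", nrow(tab))
    rejected <- integer()
    for (i in seq_len(nrow(tab))) {
        ps <- protSeq[[prot[i]]]
        loci <- NULL
        if (!is.null(startCol) && !is.na(startCol[i])) {
            s <- startCol[i]
            e <- if (!is.null(stopCol) && !is.na(stopCol[i])) stopCol[i]
                 else s + nchar(seqs[i]) - 1L
            if (s >= 1L && e <= nchar(ps) &&
                substr(ps, s, e) == seqs[i] &&
                e - s + 1L == nchar(seqs[i]))
                loci <- matrix(c(s, e), ncol = 2L)
        }
        if (is.null(loci)) {
            hits <- gregexpr(seqs[i], ps, fixed = TRUE)[[1]]
            if (hits[1] == -1L) {
                rejected <- c(rejected, i)
                next
            }
            loci <- cbind(as.integer(hits),
                          as.integer(hits) + nchar(seqs[i]) - 1L)
        } else {
            # the stated locus verified; still detect additional loci so the
            # multi-mapping flag is faithful
            hits <- gregexpr(seqs[i], ps, fixed = TRUE)[[1]]
            if (hits[1] != -1L && length(hits) > 1L)
                loci <- cbind(as.integer(hits),
                              as.integer(hits) + nchar(seqs[i]) - 1L)
        }
        multi <- nrow(loci) > 1L
        rows <- lapply(seq_len(nrow(loci)), function(j) {
            data.frame(protein = prot[i], start = loci[j, 1],
                       stop = loci[j, 2], sequence = seqs[i],
                       n_term_acetyl = acet[i], c_term_amidated = amid[i],
                       engine = engine,
                       engine_score = if (is.null(scoreCol)) NA_real_
                                      else as.numeric(scoreCol[i]),
                       tissue = tissue, group = group, multi_mapped = multi,
                       stringsAsFactors = FALSE)
        })
        block <- do.call(rbind, rows)
        im <- imat[rep(i, nrow(block)), , drop = FALSE]
        names(im) <- paste0(INTENSITY_PREFIX,
                            sub(paste0("^", cols$intensity_prefix), "", icols))
        out[[i]] <- cbind(block, im)
    }
    if (length(rejected))
        message(sprintf(
            "rejected %d row(s) whose sequence is absent from the stated protein (rows %s)",
            length(rejected),
            paste(utils::head(rejected, 10L), collapse = ", ")))
    obs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(obs)) obs <- emptyObservations(
        paste0(INTENSITY_PREFIX, sub(paste0("^", cols$intensity_prefix), "", icols)))
    rownames(obs) <- NULL
    if (nrow(obs)) {
        m <- intensityMatrix(obs)
        detected <- rowSums(!is.na(m) & m > 0) > 0
        if (any(!detected))
            message(sprintf("dropped %d row(s) with no detected abundance",
                            sum(!detected)))
        obs <- obs[detected, , drop = FALSE]
        rownames(obs) <- NULL
    }
    obs
}

emptyObservations <- function(intensity_cols = character()) {
    base <- data.frame(protein = character(), start = integer(),
                       stop = integer(), sequence = character(),
                       n_term_acetyl = logical(), c_term_amidated = logical(),
                       engine = character(), engine_score = numeric(),
                       tissue = character(), group = character(),
                       multi_mapped = logical(), stringsAsFactors = FALSE)
    for (cc in intensity_cols) base[[cc]] <- numeric()
    base
}

#' Fit the cross-engine intensity transfer function
#'
#' Ordinary least squares of log10(y) on log10(x) over peptides quantified by
#' both engines, giving log10(y) = a * log10(x) + b with y on the MaxQuant
#' scale and x on the Mascot scale.
#'
#' @param paired data.frame or matrix with columns `mascot` (x) and
#'   `maxquant` (y), one row per shared peptide/sample intensity pair.
#' @return a \code{\linkS4class{TransferFunction}}.
#' @export
fitTransferFunction <- function(paired) {
    paired <- as.data.frame(paired)
    if (!all(c("mascot", "maxquant") %in% names(paired)))
        stopf("'paired' needs columns 'mascot' and 'maxquant'")
    x <- as.numeric(paired$mascot)
    y <- as.numeric(paired$maxquant)
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2L)
        stopf("at least 2 intensity pairs are required (got %d)", length(x))
    if (any(x <= 0) || any(y <= 0))
        stopf("intensities must be strictly positive for the log-linear fit")
    fit <- stats::lm(log10(y) ~ log10(x))
    cf <- stats::coef(fit)
    # noiseless input fits exactly; the perfect-fit warning is expected
    r2 <- suppressWarnings(summary(fit)$r.squared)
    new("TransferFunction", a = unname(cf[2]), b = unname(cf[1]),
        nFit = length(x), r2 = if (is.na(r2)) 1 else r2)
}

#' Apply a transfer function to Mascot-scale intensities
#'
#' @param tf a \code{TransferFunction}.
#' @param x positive intensities (NA passes through).
#' @return intensities on the MaxQuant scale, 10^(a*log10(x)+b).
#' @export
applyTransfer <- function(tf, x) {
    stopifnot(is(tf, "TransferFunction"))
    if (any(!is.na(x) & x <= 0))
        stopf("transfer function requires strictly positive intensities")
    10^(tf@a * log10(x) + tf@b)
}

#' Merge MaxQuant and Mascot observation tables
#'
#' Peptide forms are keyed by (protein, start, stop, PTM flags).  Keys seen by
#' MaxQuant (exclusively or by both engines) keep the MaxQuant abundances;
#' Mascot-exclusive keys have their per-sample intensities mapped through the
#' transfer function.  Engine provenance is retained per row.
#'
#' @param maxquantObs,mascotObs observation data.frames.
#' @param tf \code{TransferFunction} fitted on the shared peptides of the same
#'   two tables (see \code{\link{sharedIntensityPairs}}).
#' @return merged observation data.frame.
#' @export
mergeEngineTables <- function(maxquantObs, mascotObs, tf) {
    key <- function(o) paste(o$protein, o$start, o$stop,
                             o$n_term_acetyl, o$c_term_amidated, sep = ":")
    kmq <- key(maxquantObs)
    kmc <- key(mascotObs)
    shared <- intersect(kmq, kmc)
    if (length(shared)) {
        sq1 <- maxquantObs$sequence[match(shared, kmq)]
        sq2 <- mascotObs$sequence[match(shared, kmc)]
        if (any(sq1 != sq2))
            stopf("conflicting sequences for key(s): %s",
                  paste(shared[sq1 != sq2], collapse = ", "))
    }
    only <- mascotObs[!(kmc %in% kmq), , drop = FALSE]
    if (nrow(only)) {
        ic <- intensityColumns(only)
        for (cc in ic) only[[cc]] <- applyTransfer(tf, only[[cc]])
    }
    allCols <- union(names(maxquantObs), names(only))
    pad <- function(o) {
        for (cc in setdiff(allCols, names(o))) o[[cc]] <- NA_real_
        o[, allCols, drop = FALSE]
    }
    out <- rbind(pad(maxquantObs), pad(only))
    rownames(out) <- NULL
    out
}

#' Shared per-sample intensity pairs between two engine tables
#'
#' Collects, for every peptide form present in both tables, the per-sample
#' (mascot, maxquant) intensity pairs where both engines report a positive
#' value.  This is the input expected by \code{\link{fitTransferFunction}}.
#'
#' @param maxquantObs,mascotObs observation data.frames.
#' @return data.frame with columns `mascot` and `maxquant`.
#' @export
sharedIntensityPairs <- function(maxquantObs, mascotObs) {
    key <- function(o) paste(o$protein, o$start, o$stop,
                             o$n_term_acetyl, o$c_term_amidated, sep = ":")
    kmq <- key(maxquantObs); kmc <- key(mascotObs)
    shared <- intersect(kmq, kmc)
    samples <- intersect(sampleIDs(maxquantObs), sampleIDs(mascotObs))
    if (length(shared) == 0L || length(samples) == 0L)
        return(data.frame(mascot = numeric(), maxquant = numeric()))
    mq <- maxquantObs[match(shared, kmq), , drop = FALSE]
    mc <- mascotObs[match(shared, kmc), , drop = FALSE]
    xs <- ys <- numeric()
    for (s in samples) {
        cc <- paste0(INTENSITY_PREFIX, s)
        x <- mc[[cc]]; y <- mq[[cc]]
        ok <- !is.na(x) & !is.na(y) & x > 0 & y > 0
        xs <- c(xs, x[ok]); ys <- c(ys, y[ok])
    }
    data.frame(mascot = xs, maxquant = ys)
}

#' Write / read an internal peptidome table
#'
#' The internal TSV round-trips every observation column bit-identically.
#'
#' @param observations observation data.frame.
#' @param path file path.
#' @param seed seed recorded in the provenance header.
#' @return \code{readPeptidome}: the observation data.frame.
#' @export
writePeptidome <- function(observations, path, seed = NA) {
    writeTSV(observations, path, seed = seed)
}

#' @rdname writePeptidome
#' @export
readPeptidome <- function(path) {
    obs <- readTSV(path)
    for (cc in c("n_term_acetyl", "c_term_amidated", "multi_mapped"))
        if (cc %in% names(obs)) obs[[cc]] <- as.logical(obs[[cc]])
    for (cc in c("start", "stop"))
        if (cc %in% names(obs)) obs[[cc]] <- as.integer(obs[[cc]])
    for (cc in intensityColumns(obs)) obs[[cc]] <- as.numeric(obs[[cc]])
    obs
}

#' Read / write the known-peptide annotation list
#'
#' TSV with columns `protein`, `start`, `stop`, `name`, `amidated`
#' (Yes/No/Unknown).  Unknown amidation status is stored as NA and treated as
#' always consistent during matching.
#'
#' @param path file path.
#' @return data.frame with logical-or-NA `amidated`.
#' @export
readAnnotations <- function(path) {
    ann <- readTSV(path)
    need <- c("protein", "start", "stop", "name")
    if (!all(need %in% names(ann)))
        stopf("annotation table must have columns: %s",
              paste(need, collapse = ", "))
    ann$start <- as.integer(ann$start)
    ann$stop <- as.integer(ann$stop)
    if (any(ann$stop < ann$start))
        stopf("annotation interval with stop < start")
    if (!"amidated" %in% names(ann)) ann$amidated <- NA
    if (!is.logical(ann$amidated)) {
        a <- tolower(trimws(as.character(ann$amidated)))
        ann$amidated <- ifelse(a %in% c("yes", "true", "1"), TRUE,
                        ifelse(a %in% c("no", "false", "0"), FALSE, NA))
    }
    ann
}

#' @rdname readAnnotations
#' @param annotations annotation data.frame.
#' @param seed seed recorded in the provenance header.
#' @export
writeAnnotations <- function(annotations, path, seed = NA) {
    out <- annotations
    out$amidated <- ifelse(is.na(out$amidated), "Unknown",
                    ifelse(out$amidated, "Yes", "No"))
    writeTSV(out, path, seed = seed)
}

#' Write a proteome to FASTA
#'
#' @param proteome an \code{AAStringSet} named by accession.
#' @param path output FASTA path.
#' @export
writeProteome <- function(proteome, path) {
    Biostrings::writeXStringSet(proteome, path)
    invisible(path)
}
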