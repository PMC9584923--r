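# Shared helpers.  Observation tables are plain data.frames with one row per
# peptide FORM (a (protein, start, stop, PTM-flag) combination) and one
# `intensity_<sample>` column per sample; NA intensity means "not detected".

INTENSITY_PREFIX <- "intensity_"
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Sample identifiers of an observation table
#'
#' @param observations an observation data.frame.
#' @return character vector of sample ids (the `intensity_` column suffixes).
#' @export
sampleIDs <- function(observations) {
    cols <- grep(paste0("^", INTENSITY_PREFIX), names(observations),
                 value = TRUE)
    sub(paste0("^", INTENSITY_PREFIX), "", cols)
}

intensityColumns <- function(observations) {
    grep(paste0("^", INTENSITY_PREFIX), names(observations), value = TRUE)
}

intensityMatrix <- function(observations) {
    m <- as.matrix(observations[, intensityColumns(observations),
                                drop = FALSE])
    storage.mode(m) <- "double"
    m
}

#' Per-form abundance across samples
#'
#' Aggregates the per-sample intensities of each observation row into one
#' abundance value.  Missing values mean "not detected" and contribute 0 to
#' the sum mode; the median mode takes the median of detected intensities.
#'
#' @param observations an observation data.frame.
#' @param mode `"sum_samples"` (default) or `"median_samples"`.
#' @return numeric vector, one abundance per row.
#' @export
formAbundance <- function(observations,
                          mode = c("sum_samples", "median_samples")) {
    mode <- match.arg(mode)
    m <- intensityMatrix(observations)
    if (mode == "sum_samples") {
        ab <- rowSums(m, na.rm = TRUE)
    } else {
        ab <- apply(m, 1L, function(x) {
            x <- x[!is.na(x)]
            if (length(x) == 0L) 0 else stats::median(x)
        })
    }
    as.numeric(ab)
}

obsKey <- function(observations) {
    paste(observations$protein, observations$start, observations$stop,
          sep = ":")
}

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Provenance-aware TSV I/O: every artifact starts with a '#' comment header
# recording tool version and seed, which readers skip.
provenanceHeader <- function(seed = NA) {
    v <- tryCatch(as.character(utils::packageVersion("pepvar")),
                  error = function(e) "0.0.0")
    sprintf("# pepvar %s; seed=%s", v, ifelse(is.na(seed), "NA", seed))
}

#' Write a table with a provenance header
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param seed seed recorded in the header (NA if the artifact is
#'   deterministic).
#' @export
writeTSV <- function(x, path, seed = NA) {
    out <- x
    for (cc in names(out))  # 17 significant digits: doubles round-trip
        if (is.double(out[[cc]])) out[[cc]] <- sprintf("%.17g", out[[cc]])
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(provenanceHeader(seed), con)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a table written by \code{writeTSV}
#'
#' @param path input path.
#' @return data.frame.
#' @export
readTSV <- function(path) {
    if (!file.exists(path)) stopf("file not found: %s", path)
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      check.names = FALSE)
}
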