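# Independent brute-force oracles.  These re-derive expected values from
# first principles with naive loops and no shared code paths with the
# package implementation.

# per-candidate 14-feature oracle: naive per-position summation
oracleFeatures <- function(obs, protLens, epsilon) {
    ab <- rowSums(as.matrix(obs[, grep("^intensity_", names(obs)),
                                drop = FALSE]), na.rm = TRUE)
    key <- paste(obs$protein, obs$start, obs$stop, sep = ":")
    ord <- order(obs$protein, obs$start, obs$stop)
    ukey <- unique(key[ord])
    det <- !is.na(as.matrix(obs[, grep("^intensity_", names(obs)),
                                drop = FALSE])) &
        as.matrix(obs[, grep("^intensity_", names(obs)), drop = FALSE]) > 0
    nSamples <- ncol(det)
    X <- matrix(NA_real_, length(ukey), 14)
    for (ci in seq_along(ukey)) {
        rows <- which(key == ukey[ci])
        p <- obs$protein[rows[1]]
        s <- obs$start[rows[1]]; e <- obs$stop[rows[1]]
        L <- protLens[[p]]
        prows <- which(obs$protein == p)
        at <- function(vec, i) if (i >= 1 && i <= L) vec[i] else 0
        startI <- stopI <- cov <- numeric(L)
        for (r in prows) {
            startI[obs$start[r]] <- startI[obs$start[r]] + ab[r]
            stopI[obs$stop[r]] <- stopI[obs$stop[r]] + ab[r]
            for (pos in obs$start[r]:obs$stop[r])
                cov[pos] <- cov[pos] + ab[r]
        }
        tot <- sum(ab[rows])
        X[ci, 1] <- log10((at(startI, s) + epsilon) /
                          (at(startI, s - 1) + epsilon))
        X[ci, 2] <- log10((at(stopI, e) + epsilon) /
                          (at(stopI, e + 1) + epsilon))
        X[ci, 3] <- log10((at(cov, s) + epsilon) / (at(cov, s - 1) + epsilon))
        X[ci, 4] <- log10((at(cov, e) + epsilon) / (at(cov, e + 1) + epsilon))
        X[ci, 5] <- log10(tot)
        X[ci, 6] <- at(startI, s) / at(cov, s)
        X[ci, 7] <- at(stopI, e) / at(cov, e)
        # overlap sum over distinct candidates of this protein
        pk <- unique(key[prows])
        ovSum <- 0
        ladder <- 0
        for (k2 in pk) {
            r2 <- which(key == k2)[1]
            s2 <- obs$start[r2]; e2 <- obs$stop[r2]
            tot2 <- sum(ab[key == k2])
            if (s2 <= e && e2 >= s) ovSum <- ovSum + tot2
            if (s2 >= s && e2 <= e && !(s2 == s && e2 == e))
                ladder <- ladder + 1
        }
        X[ci, 8] <- tot / ovSum
        X[ci, 9] <- sum(apply(det[rows, , drop = FALSE], 2, any)) / nSamples
        X[ci, 10] <- sum(ab[rows][obs$c_term_amidated[rows]]) / tot
        X[ci, 11] <- sum(ab[rows][obs$n_term_acetyl[rows]]) / tot
        X[ci, 12] <- log10(e - s + 1)
        # cluster span: expand [s, e] while adjacent positions are covered
        first <- s; last <- e
        while (first > 1 && cov[first - 1] > 0) first <- first - 1
        while (last < L && cov[last + 1] > 0) last <- last + 1
        X[ci, 13] <- (e - s + 1) / (last - first + 1)
        X[ci, 14] <- log10(1 + ladder)
    }
    X
}

# all-pairs AUC with half credit for ties
oracleAUC <- function(labels, scores) {
    pos <- scores[labels]
    neg <- scores[!labels]
    tot <- 0
    for (a in pos) for (b in neg)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
}

# brute-force assembly: enumerate all (observed start, observed stop) pairs
# and search for an overlap chain by transitive closure
oracleAssembly <- function(starts, stops, overlapMin = 1, maxSpan = 100) {
    n <- length(starts)
    res <- NULL
    for (s in sort(unique(starts))) for (e in sort(unique(stops))) {
        if (e <= s || e - s + 1 > maxSpan) next
        inside <- which(starts >= s & stops <= e)
        if (length(inside) == 0) next
        m <- length(inside)
        adj <- matrix(FALSE, m, m)
        for (i in seq_len(m)) for (j in seq_len(m)) {
            ov <- min(stops[inside[i]], stops[inside[j]]) -
                max(starts[inside[i]], starts[inside[j]]) + 1
            adj[i, j] <- ov >= overlapMin
        }
        reach <- adj
        for (k in seq_len(m))
            reach <- reach | (reach %*% reach > 0)
        src <- which(starts[inside] == s)
        tgt <- which(stops[inside] == e)
        if (length(src) && length(tgt) &&
            any(reach[src, tgt, drop = FALSE]))
            res <- rbind(res, c(s, e))
    }
    res
}
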