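# Independent oracles used across tests. Each is a direct, brute-force
# transcription of the defining rule, kept free of the package's own
# implementation choices.

# valley of a median-of-3 smoothed series by direct walk: the first
# strict descent that later turns upward; a plateau valley resolves to
# its first index
oracle_first_valley <- function(counts) {
    n <- length(counts)
    s <- vapply(seq_len(n), function(i)
        stats::median(c(counts[max(1L, i - 1L)], counts[i],
                        counts[min(n, i + 1L)])), 0)
    i <- 2L
    while (i <= n) {
        # descend to a candidate minimum
        if (s[i] < s[i - 1L]) {
            j <- i
            while (j < n && s[j + 1L] == s[j]) j <- j + 1L
            if (j < n && s[j + 1L] > s[j]) return(i)
            i <- j + 1L
        } else i <- i + 1L
    }
    NA_integer_
}

# transitive-closure clustering of intervals: merge any two hits with
# fewer than `dist` bases strictly between them, then take envelopes
oracle_merge <- function(starts, ends, dist) {
    n <- length(starts)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        gap <- max(starts[j] - ends[i] - 1L, starts[i] - ends[j] - 1L, 0L)
        overlap <- starts[j] <= ends[i] && starts[i] <= ends[j]
        adj[i, j] <- overlap || gap < dist
    }
    # transitive closure
    repeat {
        nxt <- adj | (adj %*% adj > 0)
        if (identical(nxt, adj)) break
        adj <- nxt
    }
    comp <- rep(NA_integer_, n)
    k <- 0L
    for (i in seq_len(n)) if (is.na(comp[i])) {
        k <- k + 1L
        comp[adj[i, ]] <- k
    }
    t(vapply(seq_len(k), function(g)
        c(min(starts[comp == g]), max(ends[comp == g])), numeric(2)))
}

# Weir & Cockerham (1984) components transcribed directly from the
# published equations (2)-(4), structured differently from the package
# implementation: inputs are per-population allele frequencies,
# heterozygote frequencies and sample sizes for one site
oracle_wc_site <- function(n_i, p_i, h_i) {
    r <- length(n_i)
    n_bar <- sum(n_i) / r
    C2 <- sum(n_i^2) / (r * n_bar^2) - 1          # squared CV of sizes
    n_c <- n_bar * (1 - C2 / (r - 1))
    p_bar <- sum(n_i * p_i) / (r * n_bar)
    s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / (r * n_bar)
    a <- (n_bar / n_c) *
        (s2 - (1 / (n_bar - 1)) *
             (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
    b <- (n_bar / (n_bar - 1)) *
        (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
             ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
    cc <- h_bar / 2
    c(a = a, b = b, c = cc)
}

# brute-force Nei-Gojobori difference classification for one codon pair:
# enumerate all orders of the differing positions with independent code
oracle_ng_diffs <- function(ca, cb, exclude_stop_paths = TRUE) {
    code <- Biostrings::GENETIC_CODE
    pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    perms <- if (length(pos) <= 1) list(pos) else {
        idx <- seq_along(pos)
        prm <- as.matrix(expand.grid(rep(list(idx), length(pos))))
        prm <- prm[apply(prm, 1, function(x) !any(duplicated(x))), , drop = FALSE]
        lapply(seq_len(nrow(prm)), function(i) pos[prm[i, ]])
    }
    walk <- function(ord, skip_stop) {
        cur <- strsplit(ca, "")[[1]]; tgt <- strsplit(cb, "")[[1]]
        sd <- nd <- 0
        for (p in ord) {
            prev <- paste(cur, collapse = "")
            cur[p] <- tgt[p]
            now <- paste(cur, collapse = "")
            if (skip_stop && code[[now]] == "*") return(NULL)
            if (code[[prev]] == code[[now]]) sd <- sd + 1 else nd <- nd + 1
        }
        c(sd, nd)
    }
    res <- Filter(Negate(is.null),
                  lapply(perms, walk, skip_stop = exclude_stop_paths))
    if (!length(res)) res <- lapply(perms, walk, skip_stop = FALSE)
    Reduce(`+`, res) / length(res)
}

# deterministic hit layout on one scaffold from gap lengths (bases
# strictly between consecutive hits)
layout_hits <- function(gaps, hit_len = 148L, scaffold = "s") {
    starts <- integer(length(gaps) + 1L)
    starts[1L] <- 1L
    for (i in seq_along(gaps))
        starts[i + 1L] <- starts[i] + hit_len + gaps[i]
    GenomicRanges::GRanges(scaffold,
        IRanges::IRanges(starts, width = hit_len), kind = "centromere",
        identity = 1)
}
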