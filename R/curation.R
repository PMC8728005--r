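## Telomere/centromere-guided scaffold curation.
##
## Chromosome ends carry tandem arrays of the 7-bp telomere unit
## CCCT[A/C]AA (C-rich strand); centromeres are dense clusters of a 148-bp
## tandem repeat. Scaffolding can fuse two chromosomes into one scaffold;
## such fusions betray themselves by a second centromeric region and by
## internal telomere arrays whose orientation points outward. The
## functions here locate both repeat classes, merge centromere copies
## into regions, split fused scaffolds, and summarise the assembly.

.TELOMERE_VARIANTS <- c("CCCTAAA", "CCCTCAA")

#' The bundled 148-bp centromeric repeat consensus
#'
#' Returns the tandem-repeat unit used to locate centromeric regions,
#' shipped as a plain-FASTA package fixture.
#'
#' @return a \code{DNAString} of length 148.
#' @export
centromereConsensus <- function() {
    f <- system.file("extdata", "centromere_consensus.fa",
                     package = "PolyploidTools", mustWork = TRUE)
    x <- Biostrings::readDNAStringSet(f)
    Biostrings::DNAString(as.character(x[[1L]]))
}

# identity of an ungapped window against a pattern of equal length
.window_identity <- function(subject_chunk, pattern_chars) {
    mean(strsplit(toupper(subject_chunk), "")[[1L]] == pattern_chars)
}

#' Scan a scaffold for telomere repeat arrays
#'
#' Finds maximal tandem runs of the telomere unit (both degenerate
#' variants, both strands). A run may tolerate mismatching bases between
#' exact unit copies up to \code{max_mismatch_frac} of its span. The
#' reported orientation is the strand carrying the C-rich motif:
#' \code{+} arrays mark 5' chromosome ends, \code{-} arrays 3' ends.
#'
#' @param record a single sequence (\code{BString}/\code{DNAString}/
#'   character) or a named set; sets are scanned per record.
#' @param name scaffold name used when \code{record} is a bare sequence.
#' @param min_array_bp minimal array span to report.
#' @param max_mismatch_frac maximal fraction of non-motif bases in a run.
#' @return a \code{GRanges} of hits with \code{kind = "telomere"},
#'   orientation in \code{strand()}, and an \code{identity} column
#'   (motif bases / span).
#' @export
scanTelomeres <- function(record, name = "scaffold", min_array_bp = 100,
                          max_mismatch_frac = 0.1) {
    if (is(record, "XStringSet") || (is.character(record) && length(record) > 1L)) {
        hits <- lapply(seq_along(record), function(i)
            scanTelomeres(record[[i]], names(record)[i], min_array_bp,
                          max_mismatch_frac))
        return(suppressWarnings(do.call(c, hits)))
    }
    seq <- Biostrings::DNAString(toupper(as.character(record)))
    unit <- nchar(.TELOMERE_VARIANTS[1L])
    # exact unit matches per strand; mismatch tolerance comes from chaining
    starts_for <- function(patterns) {
        sort(unique(unlist(lapply(patterns, function(p)
            Biostrings::start(matchPattern(Biostrings::DNAString(p), seq))))))
    }
    rc <- vapply(.TELOMERE_VARIANTS, function(p)
        as.character(reverseComplement(Biostrings::DNAString(p))), "")
    seq_chr <- as.character(seq)
    # mismatching bases inside a gap between exact copies: when the gap
    # keeps the tandem phase (multiple of the unit), compare each frame
    # to the closer motif variant; a phase-breaking gap counts in full
    gap_mismatches <- function(from, to, variants) {
        gseq <- substr(seq_chr, from, to)
        glen <- nchar(gseq)
        if (glen == 0L) return(0L)
        if (glen %% unit != 0L) return(glen)
        vc <- lapply(variants, function(v) strsplit(v, "")[[1L]])
        sum(vapply(seq_len(glen %/% unit), function(k) {
            chunk <- strsplit(substr(gseq, (k - 1L) * unit + 1L,
                                     k * unit), "")[[1L]]
            min(vapply(vc, function(v) sum(chunk != v), 0L))
        }, 0L))
    }
    runs_from <- function(starts, ori, variants) {
        if (!length(starts)) return(NULL)
        # chain copies separated by short gaps; actual mismatching bases
        # in the gaps are counted against the run budget afterwards
        gap <- c(Inf, starts[-1L] - (starts[-length(starts)] + unit))
        grp <- cumsum(gap > 3L * unit)
        out <- lapply(split(starts, grp), function(ss) {
            span_start <- ss[1L]; span_end <- ss[length(ss)] + unit - 1L
            span <- span_end - span_start + 1L
            mm <- 0L
            if (length(ss) > 1L) {
                g_from <- ss[-length(ss)] + unit
                g_to <- ss[-1L] - 1L
                nz <- which(g_to >= g_from)
                mm <- sum(vapply(nz, function(k)
                    gap_mismatches(g_from[k], g_to[k], variants), 0L))
            }
            frac <- mm / span
            if (span >= min_array_bp && frac <= max_mismatch_frac)
                data.frame(start = span_start, end = span_end,
                           identity = 1 - frac, orientation = ori)
            else NULL
        })
        do.call(rbind, out)
    }
    df <- rbind(runs_from(starts_for(.TELOMERE_VARIANTS), "+",
                          .TELOMERE_VARIANTS),
                runs_from(starts_for(rc), "-", unname(rc)))
    if (is.null(df))
        return(GRanges(character(), IRanges::IRanges(), kind = character(),
                       identity = numeric()))
    gr <- GRanges(name, IRanges::IRanges(df$start, df$end),
                  strand = df$orientation, kind = "telomere",
                  identity = df$identity)
    sort(gr, ignore.strand = TRUE)
}

#' Scan a scaffold for the 148-bp centromeric repeat
#'
#' Ungapped sliding matches of the consensus on both strands with
#' per-window identity at least \code{min_identity}; overlapping windows
#' are merged into maximal hits.
#'
#' @param record a single sequence or a named set (scanned per record).
#' @param name scaffold name for bare sequences.
#' @param consensus the repeat unit (\code{DNAString}); must be 148 bp.
#' @param min_identity minimal window identity.
#' @param min_hit_bp minimal merged hit length.
#' @return a \code{GRanges} of hits with \code{kind = "centromere"} and
#'   \code{identity} (best contributing window).
#' @export
scanCentromeres <- function(record, name = "scaffold",
                            consensus = centromereConsensus(),
                            min_identity = 0.8, min_hit_bp = 100) {
    if (length(consensus) != 148L)
        stop("centromere consensus must be 148 bp, got ", length(consensus))
    if (is(record, "XStringSet") || (is.character(record) && length(record) > 1L)) {
        hits <- lapply(seq_along(record), function(i)
            scanCentromeres(record[[i]], names(record)[i], consensus,
                            min_identity, min_hit_bp))
        return(suppressWarnings(do.call(c, hits)))
    }
    seq <- Biostrings::DNAString(toupper(as.character(record)))
    mm <- floor((1 - min_identity) * length(consensus))
    seq_chr <- as.character(seq)
    one_strand <- function(pat) {
        m <- matchPattern(pat, seq, max.mismatch = mm)
        if (!length(m)) return(NULL)
        pc <- strsplit(as.character(pat), "")[[1L]]
        idy <- vapply(seq_along(m), function(i) .window_identity(
            substr(seq_chr, Biostrings::start(m)[i], Biostrings::end(m)[i]), pc),
            0)
        keep <- idy >= min_identity
        if (!any(keep)) return(NULL)
        data.frame(start = Biostrings::start(m)[keep],
                   end = Biostrings::end(m)[keep], identity = idy[keep])
    }
    fw <- one_strand(consensus)
    rv <- one_strand(reverseComplement(consensus))
    if (!is.null(fw)) fw$orientation <- "+"
    if (!is.null(rv)) rv$orientation <- "-"
    df <- rbind(fw, rv)
    if (is.null(df))
        return(GRanges(character(), IRanges::IRanges(), kind = character(),
                       identity = numeric()))
    raw <- IRanges::IRanges(df$start, df$end)
    merged <- IRanges::reduce(raw)
    ov <- IRanges::findOverlaps(raw, merged)
    best <- vapply(seq_along(merged), function(j)
        max(df$identity[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == j]]), 0)
    ori <- vapply(seq_along(merged), function(j) {
        o <- df$orientation[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == j]]
        names(sort(table(o), decreasing = TRUE))[1L]
    }, "")
    keep <- IRanges::width(merged) >= min_hit_bp
    GRanges(name, merged[keep], strand = ori[keep], kind = "centromere",
            identity = best[keep])
}

#' Merge centromere hits into centromeric regions
#'
#' Single-linkage merge of per-scaffold hits whose gap (next start minus
#' previous end, minus 1 intervening base convention: the count of bases
#' strictly between the hits) is strictly below \code{merge_distance}.
#' The region interval is the envelope of its hits; \code{copy_count}
#' records how many hits merged.
#'
#' @param hits a \code{GRanges} of centromere hits.
#' @param merge_distance merge threshold in bp (strict \code{<}).
#' @return a \code{GRanges} of regions with \code{copy_count}; regions on
#'   one scaffold are pairwise separated by at least
#'   \code{merge_distance}.
#' @export
mergeCentromericHits <- function(hits, merge_distance = 250000) {
    if (!length(hits))
        return(GRanges(character(), IRanges::IRanges(), copy_count = integer()))
    out <- lapply(split(hits, as.character(seqnames(hits))), function(h) {
        h <- sort(h, ignore.strand = TRUE)
        s <- start(h); e <- end(h)
        gap <- s[-1L] - e[-length(e)] - 1L         # bases strictly between
        grp <- cumsum(c(0L, as.integer(!(gap < merge_distance))))
        reg_s <- tapply(s, grp, min); reg_e <- tapply(e, grp, max)
        GRanges(as.character(seqnames(h))[1L],
                IRanges::IRanges(as.integer(reg_s), as.integer(reg_e)),
                copy_count = as.integer(table(grp)))
    })
    unname(suppressWarnings(do.call(c, unname(out))))
}

# N-gap runs (>= min_run Ns) within a sequence, as an IRanges
.n_gaps <- function(seq_chr, min_run = 1L) {
    r <- rle(strsplit(toupper(seq_chr), "")[[1L]] == "N")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_run
    IRanges::IRanges(starts[keep], ends[keep])
}

#' Split scaffolds so no scaffold holds two centromeric regions
#'
#' For every scaffold with two or more centromeric regions, a cut is
#' placed between each consecutive region pair: (a) when internal
#' telomere arrays lie between the two regions, the scaffold is cut at
#' the boundary of each internal array whose orientation faces its
#' nearer centromere (the array end pointing away from that centromere
#' is a chromosome end, and the cut keeps the array with its arm); (b)
#' with no internal telomere, the cut falls at the midpoint of the
#' largest N-gap between the regions; (c) with neither, the pair is
#' flagged unresolved and left uncut.
#'
#' @param scaffolds named \code{BStringSet}/\code{DNAStringSet} (or named
#'   character vector).
#' @param regions centromeric regions from
#'   \code{\link{mergeCentromericHits}}.
#' @param telomere_hits telomere hits from \code{\link{scanTelomeres}}.
#' @return list with \code{sequences} (the curated set; pieces named
#'   \code{<scaffold>.1}, \code{.2}, ... in order) and \code{report}
#'   (data.frame of scaffold, cut_after, reason, including unresolved
#'   flags with \code{cut_after = NA}).
#' @export
splitScaffolds <- function(scaffolds, regions, telomere_hits) {
    if (is.character(scaffolds)) scaffolds <- BStringSet(scaffolds)
    if (length(regions) &&
        !all(as.character(seqnames(regions)) %in% names(scaffolds)))
        stop("region on unknown scaffold: ",
             setdiff(as.character(seqnames(regions)), names(scaffolds))[1L])
    report <- data.frame(scaffold = character(), cut_after = integer(),
                         reason = character())
    out_seqs <- list()
    for (nm in names(scaffolds)) {
        seq_chr <- as.character(scaffolds[[nm]])
        reg <- regions[as.character(seqnames(regions)) == nm]
        reg <- reg[order(start(reg))]
        cuts <- integer()
        if (length(reg) >= 2L) {
            tel <- telomere_hits[as.character(seqnames(telomere_hits)) == nm]
            for (k in seq_len(length(reg) - 1L)) {
                lo <- end(reg)[k]; hi <- start(reg)[k + 1L]
                internal <- tel[start(tel) > lo & end(tel) < hi]
                pair_cuts <- integer(); reasons <- character()
                for (j in seq_along(internal)) {
                    ts <- start(internal)[j]; te <- end(internal)[j]
                    ori <- as.character(strand(internal))[j]
                    mid <- (ts + te) / 2
                    nearer_left <- (mid - lo) <= (hi - mid)
                    if (ori == "-" && nearer_left) {
                        # 3'-end array of the left chromosome: cut after it
                        pair_cuts <- c(pair_cuts, te)
                        reasons <- c(reasons, "telomere")
                    } else if (ori == "+" && !nearer_left) {
                        # 5'-end array of the right chromosome: cut before it
                        pair_cuts <- c(pair_cuts, ts - 1L)
                        reasons <- c(reasons, "telomere")
                    }
                }
                if (!length(pair_cuts)) {
                    gaps <- .n_gaps(substr(seq_chr, lo + 1L, hi - 1L))
                    if (length(gaps)) {
                        g <- gaps[which.max(IRanges::width(gaps))]
                        pair_cuts <- lo + as.integer((IRanges::start(g) +
                            IRanges::end(g)) %/% 2)
                        reasons <- "gap"
                    } else {
                        report <- rbind(report, data.frame(scaffold = nm,
                            cut_after = NA_integer_, reason = "unresolved"))
                    }
                }
                if (length(pair_cuts)) {
                    report <- rbind(report, data.frame(scaffold = nm,
                        cut_after = as.integer(pair_cuts), reason = reasons))
                    cuts <- c(cuts, pair_cuts)
                }
            }
        }
        cuts <- sort(unique(cuts))
        cuts <- cuts[cuts >= 1L & cuts < nchar(seq_chr)]
        if (!length(cuts)) {
            out_seqs[[nm]] <- seq_chr
        } else {
            bounds <- c(0L, cuts, nchar(seq_chr))
            for (p in seq_len(length(bounds) - 1L))
                out_seqs[[paste0(nm, ".", p)]] <-
                    substr(seq_chr, bounds[p] + 1L, bounds[p + 1L])
        }
    }
    list(sequences = BStringSet(unlist(out_seqs)), report = report)
}

#' Classify centromere-bearing scaffolds by terminal telomeres
#'
#' A scaffold with a centromeric region and a telomere array within
#' \code{end_window} of either terminus likely spans a complete
#' chromosome arm.
#'
#' @param scaffolds named sequence set.
#' @param regions centromeric regions.
#' @param telomere_hits telomere hits.
#' @param end_window distance from a terminus within which an array
#'   counts as terminal.
#' @return data.frame of scaffold, class (\code{arm_with_telomere_end} or
#'   \code{centromeric_no_telomere}).
#' @export
classifyArms <- function(scaffolds, regions, telomere_hits,
                         end_window = 1000) {
    nms <- unique(as.character(seqnames(regions)))
    cls <- vapply(nms, function(nm) {
        len <- nchar(as.character(scaffolds[[nm]]))
        tel <- telomere_hits[as.character(seqnames(telomere_hits)) == nm]
        terminal <- length(tel) && any(start(tel) <= end_window |
                                       end(tel) >= len - end_window + 1L)
        if (terminal) "arm_with_telomere_end" else "centromeric_no_telomere"
    }, "")
    data.frame(scaffold = nms, class = unname(cls))
}

# N50-style statistic: largest L among lengths such that lengths >= L sum
# to at least half the target
.nx50 <- function(lengths, target) {
    if (!length(lengths) || target <= 0) return(NA_integer_)
    lengths <- sort(as.numeric(lengths), decreasing = TRUE)
    cum <- cumsum(lengths)
    i <- which(cum >= target / 2)
    if (!length(i)) return(NA_integer_)
    as.integer(lengths[i[1L]])
}

#' Assembly statistics (N50 and NG50 for contigs and scaffolds)
#'
#' Contigs are scaffolds split at runs of at least \code{contig_gap_min}
#' Ns. N50 uses half the assembly total; NG50 uses half of a fixed
#' genome-size estimate, so the statistic stays comparable across
#' assembly versions.
#'
#' @param scaffolds named sequence set.
#' @param fixed_genome_size genome size for NG50 (bp); NA skips NG50.
#' @param contig_gap_min minimal N-run treated as a contig break.
#' @return list of totals, counts, N50 and NG50 values.
#' @export
assemblyStats <- function(scaffolds, fixed_genome_size = NA,
                          contig_gap_min = 10L) {
    if (is.character(scaffolds)) scaffolds <- BStringSet(scaffolds)
    sc_len <- vapply(seq_along(scaffolds), function(i)
        nchar(as.character(scaffolds[[i]])), 0)
    ctg_len <- unlist(lapply(seq_along(scaffolds), function(i) {
        s <- as.character(scaffolds[[i]])
        gaps <- .n_gaps(s, contig_gap_min)
        if (!length(gaps)) return(nchar(s))
        keep <- IRanges::setdiff(IRanges::IRanges(1L, nchar(s)), gaps)
        IRanges::width(keep)
    }))
    ctg_len <- ctg_len[ctg_len > 0]
    total <- sum(sc_len)
    if (!is.na(fixed_genome_size) && fixed_genome_size <= 0)
        stop("fixed_genome_size must be positive for NG50")
    list(total_bp = total, n_scaffolds = length(sc_len),
         n_contigs = length(ctg_len),
         scaffold_n50 = .nx50(sc_len, total),
         contig_n50 = .nx50(ctg_len, sum(ctg_len)),
         scaffold_ng50 = if (is.na(fixed_genome_size)) NA_integer_
             else .nx50(sc_len, fixed_genome_size),
         contig_ng50 = if (is.na(fixed_genome_size)) NA_integer_
             else .nx50(ctg_len, fixed_genome_size))
}

#' Total spans and ratio of two repeat superfamilies
#'
#' Sums interval widths per repeat class and reports the larger:smaller
#' span ratio, the summary used to contrast Copia and Gypsy LTR content.
#'
#' @param repeats a \code{GRanges} with a \code{class} metadata column,
#'   or a named numeric vector of per-class total spans in bp.
#' @param classes the two class labels to compare.
#' @return list with per-class spans (bp) and \code{ratio}
#'   (larger / smaller).
#' @export
repeatSpanRatio <- function(repeats, classes = c("Copia", "Gypsy")) {
    if (is(repeats, "GRanges")) {
        spans <- vapply(classes, function(cl)
            sum(as.numeric(width(repeats[mcols(repeats)$class == cl]))), 0)
    } else spans <- repeats[classes]
    if (any(is.na(spans)) || any(spans <= 0))
        stop("both repeat classes need positive spans")
    list(spans = spans, ratio = max(spans) / min(spans))
}
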