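## Seeded generators for scaffold and k-mer-spectrum inputs.
##
## One integer seed fans out to fixed per-generator substreams, so a run
## of one generator is reproducible independently of the others.

.SIM_OFFSETS <- c(scaffolds = 1L, histogram = 2L, genes = 3L, ortho = 4L,
                  trees = 5L, variants = 6L)

# one telomere array string: tandem copies of the two degenerate variants
.telomere_array <- function(copies) {
    paste(sample(.TELOMERE_VARIANTS, copies, replace = TRUE), collapse = "")
}

#' Simulate scaffolds with planted telomere and centromere arrays
#'
#' Builds chromosome-like scaffolds: a 5' telomere array (tandem
#' CCCT[A/C]AA copies, C-rich strand forward), an arm of random sequence
#' with an internal N-gap, a centromeric array of 148-bp unit copies
#' (optionally fragmented into clusters separated by short gaps that the
#' merge step must rejoin), a second arm, and a 3' telomere array on the
#' reverse strand. Optionally, pairs of chromosomes are concatenated into
#' "fused" scaffolds carrying two centromeric regions and internal,
#' outward-oriented telomere arrays -- the split targets; with
#' \code{fused_telomeres = FALSE} the fusion junction is an N-gap
#' instead.
#'
#' @param n_chromosomes number of unfused chromosome scaffolds.
#' @param n_fused number of fused (two-chromosome) scaffolds.
#' @param arm_length bp of random sequence per chromosome arm.
#' @param telomere_copies tandem telomere unit copies per array.
#' @param centromere_copies 148-bp unit copies per centromeric cluster.
#' @param centromere_clusters clusters per centromere; clusters are
#'   separated by \code{cluster_gap} bp and belong to one planted region.
#' @param cluster_gap bp between clusters (keep below the merge distance).
#' @param n_gap_length bp of Ns inserted mid-arm (contig break).
#' @param fused_telomeres plant internal telomeres at fusion junctions.
#' @param fusion_spacer bp of junk sequence between the two chromosomes
#'   of a fused scaffold (the region the splits excise).
#' @param seed integer seed.
#' @return list with \code{sequences} (named \code{BStringSet}) and
#'   \code{truth}: a \code{GRanges} of every planted feature
#'   (\code{kind} = telomere / centromere_cluster / centromere_region;
#'   telomere orientation in \code{strand()}).
#' @export
simScaffolds <- function(n_chromosomes = 2L, n_fused = 1L,
                         arm_length = 150000L, telomere_copies = 30L,
                         centromere_copies = 10L, centromere_clusters = 2L,
                         cluster_gap = 2000L, n_gap_length = 100L,
                         fused_telomeres = TRUE, fusion_spacer = 5000L,
                         seed = 1L) {
    stopifnot(arm_length > 2L * n_gap_length + 100L)
    unit <- as.character(centromereConsensus())
    with_seed(substream_seed(seed, .SIM_OFFSETS["scaffolds"]), {
        build_chr <- function(tel5 = TRUE, tel3 = TRUE) {
            pieces <- character(); feats <- list(); pos <- 0L
            add <- function(s, kind = NA, ori = "*") {
                pieces[[length(pieces) + 1L]] <<- s
                if (!is.na(kind))
                    feats[[length(feats) + 1L]] <<- data.frame(
                        start = pos + 1L, end = pos + nchar(s),
                        kind = kind, orientation = ori)
                pos <<- pos + nchar(s)
            }
            arm <- function() {
                half <- (arm_length - n_gap_length) %/% 2L
                add(random_dna(half))
                add(strrep("N", n_gap_length))
                add(random_dna(arm_length - n_gap_length - half))
            }
            if (tel5) add(.telomere_array(telomere_copies), "telomere", "+")
            arm()
            cen_start <- pos + 1L
            for (cl in seq_len(centromere_clusters)) {
                add(strrep(unit, centromere_copies), "centromere_cluster")
                if (cl < centromere_clusters) add(random_dna(cluster_gap))
            }
            feats[[length(feats) + 1L]] <- data.frame(start = cen_start,
                end = pos, kind = "centromere_region", orientation = "*")
            arm()
            if (tel3) add(as.character(reverseComplement(Biostrings::DNAString(
                .telomere_array(telomere_copies)))), "telomere", "-")
            list(seq = paste(pieces, collapse = ""),
                 feats = do.call(rbind, feats))
        }
        seqs <- list(); truth <- list()
        emit <- function(nm, chr) {
            seqs[[nm]] <<- chr$seq
            f <- chr$feats
            truth[[nm]] <<- GRanges(nm, IRanges::IRanges(f$start, f$end),
                strand = f$orientation, kind = f$kind)
        }
        for (i in seq_len(n_chromosomes))
            emit(sprintf("chr%02d", i), build_chr())
        for (i in seq_len(n_fused)) {
            a <- build_chr(tel3 = fused_telomeres)
            b <- build_chr(tel5 = fused_telomeres)
            # telomere-free junction: an N run longer than the mid-arm
            # gaps, so the largest-gap rule picks the true junction
            joint <- if (fused_telomeres) random_dna(fusion_spacer)
                     else strrep("N", 3L * n_gap_length)
            fb <- b$feats
            fb$start <- fb$start + nchar(a$seq) + nchar(joint)
            fb$end <- fb$end + nchar(a$seq) + nchar(joint)
            emit(sprintf("fused%02d", i),
                 list(seq = paste0(a$seq, joint, b$seq),
                      feats = rbind(a$feats, fb)))
        }
        list(sequences = BStringSet(unlist(seqs)),
             truth = unname(suppressWarnings(do.call(c, unname(truth)))))
    })
}

#' Simulate a polyploid k-mer spectrum
#'
#' Emits a histogram with (i) an error component whose distinct counts
#' decay geometrically from coverage 1, and (ii) Poisson-shaped signal
#' components centred at \eqn{c, 2c, 3c} whose areas are
#' \eqn{f_1 G, f_2 G / 2, f_3 G / 3} distinct k-mers -- k-mers shared by
#' \eqn{m} subgenomes appear once but at \eqn{m}-fold depth, so instance
#' mass totals \eqn{G \cdot c} regardless of the sharing split.
#'
#' @param genome_size haploid genome size \eqn{G} in bp (k-mer count
#'   approximation: one k-mer per bp).
#' @param peak_coverage main peak depth \eqn{c} (>= 8).
#' @param shares fractions \eqn{(f_1, f_2, f_3)} of the genome unique to
#'   one subgenome, shared by two, shared by three; must sum to 1.
#' @param error_distinct distinct error k-mers at coverage 1.
#' @param error_decay geometric decay of error counts per coverage step.
#' @param overdispersion 0 gives Poisson-shaped peaks; larger values
#'   widen them (negative-binomial shape with size = peak / value).
#' @param noise add Poisson sampling noise to every bin.
#' @param seed integer seed.
#' @return a \linkS4class{KmerHistogram}.
#' @export
simHistogram <- function(genome_size = 1e7, peak_coverage = 57L,
                         shares = c(0.6, 0.25, 0.15),
                         error_distinct = genome_size, error_decay = 0.4,
                         overdispersion = 0, noise = TRUE, seed = 1L) {
    stopifnot(peak_coverage >= 8L, length(shares) == 3L, all(shares >= 0))
    if (abs(sum(shares) - 1) > 1e-8) stop("shares must sum to 1")
    with_seed(substream_seed(seed, .SIM_OFFSETS["histogram"]), {
        xmax <- ceiling(3.6 * peak_coverage)
        x <- seq_len(xmax)
        expected <- error_distinct * error_decay^(x - 1)
        for (m in 1:3) {
            if (shares[m] == 0) next
            lam <- m * peak_coverage
            shape <- if (overdispersion > 0)
                stats::dnbinom(x, size = lam / overdispersion, mu = lam)
            else stats::dpois(x, lam)
            expected <- expected + shares[m] * genome_size / m * shape
        }
        counts <- if (noise) stats::rpois(xmax, expected) else round(expected)
        # downstream stages need a valley between error mass and the c peak
        if (all(diff(expected[seq_len(peak_coverage)]) <= 0))
            warning("error and signal components overlap; no valley exists")
        KmerHistogram(x, counts)
    })
}
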