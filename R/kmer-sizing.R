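## Genome-size estimation from a k-mer spectrum.
##
## The estimator is the classical instance-mass quotient: with error k-mers
## excluded below a valley cutoff, the haploid genome size is
## G = T / c, where T is the total number of k-mer instances (sum of
## coverage x distinct-count) at or above the cutoff and c the coverage of
## the main spectrum peak. For a haploid sample of a hexaploid, k-mers
## identical across two or three subgenomes pile up near 2c and 3c;
## summing T over the whole spectrum and dividing by the 1x peak counts
## such shared sequence once per subgenomic copy.

# Valley/peak detection both work on a median-of-3 smoothed series so a
# single noisy bin cannot fake a turning point.
.smoothed <- function(hist) median3(kmerCounts(hist))

#' Find the error/signal coverage cutoff
#'
#' Scans the median-of-3 smoothed distinct-count series upward from
#' coverage 1 and returns the coverage at the first local minimum (for a
#' valley plateau, its first bin) below the global mode. Sequencing-error
#' k-mers decay from coverage 1, so this valley separates error mass from
#' genuine genomic coverage. If the series never turns upward, 1 is
#' returned with a warning.
#'
#' @param hist a \linkS4class{KmerHistogram} with at least 3 bins.
#' @return integer coverage cutoff.
#' @examples
#' h <- KmerHistogram(1:6, c(1000, 200, 50, 80, 120, 90))
#' findErrorCutoff(h)  # 3
#' @export
findErrorCutoff <- function(hist) {
    if (length(hist) == 0L) stop("empty histogram")
    if (length(hist) < 3L) stop("need at least 3 histogram bins")
    s <- .smoothed(hist)
    cov <- coverageBins(hist)
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    # first run lower than both neighbours = first valley; for a plateau
    # valley the cutoff is its first bin
    if (length(r$values) >= 3L) {
        for (i in 2:(length(r$values) - 1L)) {
            if (r$values[i] < r$values[i - 1L] && r$values[i] < r$values[i + 1L])
                return(cov[starts[i]])
        }
    }
    warning("no valley found in the spectrum; cutoff set to 1")
    cov[1L]
}

#' Find the main spectrum peak
#'
#' Coverage with the maximal smoothed distinct-count among bins at or
#' above the cutoff; ties break toward the smaller coverage.
#'
#' @param hist a \linkS4class{KmerHistogram}.
#' @param cutoff error cutoff, e.g. from \code{\link{findErrorCutoff}}.
#' @return integer peak coverage \eqn{c}.
#' @export
findMainPeak <- function(hist, cutoff) {
    s <- .smoothed(hist)
    cov <- coverageBins(hist)
    keep <- cov >= cutoff
    if (!any(keep) || all(s[keep] == 0)) stop("no signal above cutoff")
    cov[keep][which.max(s[keep])]
}

#' Estimate genome size from the spectrum
#'
#' \eqn{T = \sum_{X \ge cutoff} X \cdot count(X)} and \eqn{G = T / c}.
#' The sum runs over the whole spectrum above the cutoff, including the
#' shared-subgenome peaks, so sequence identical between subgenomes is
#' counted once per copy.
#'
#' @param hist a \linkS4class{KmerHistogram}.
#' @param cutoff error cutoff (must be < \code{peak}).
#' @param peak main peak coverage \eqn{c}; found automatically when NULL.
#' @return list with \code{error_cutoff}, \code{main_peak},
#'   \code{total_instances} (T), \code{genome_size} (bp, exact quotient),
#'   \code{genome_size_gbp} (1-decimal rounding), \code{subgenome_peaks}.
#' @examples
#' h <- KmerHistogram(c(9L, 57L), c(2, 26371235539))
#' estimateGenomeSize(h, cutoff = 5L, peak = 57L)$genome_size
#' @export
estimateGenomeSize <- function(hist, cutoff = NULL, peak = NULL) {
    if (is.null(cutoff)) cutoff <- findErrorCutoff(hist)
    if (is.null(peak)) peak <- refinePeak(hist, cutoff, findMainPeak(hist, cutoff))
    if (cutoff >= peak) stop("cutoff must be below the main peak")
    cov <- as.numeric(coverageBins(hist))
    keep <- cov >= cutoff
    T_inst <- sum(cov[keep] * kmerCounts(hist)[keep])
    if (T_inst == 0) stop("no k-mer mass above cutoff")
    G <- T_inst / peak
    list(error_cutoff = as.integer(cutoff), main_peak = as.integer(peak),
         total_instances = T_inst, genome_size = G,
         genome_size_gbp = round(G / 1e9, 1),
         subgenome_peaks = findSubgenomePeaks(hist, cutoff, peak))
}

#' Refine a peak coverage by local centroid
#'
#' The discrete argmax of a coverage peak is ambiguous when neighbouring
#' bins (near-)tie -- for a Poisson-shaped peak the bins at \eqn{c - 1}
#' and \eqn{c} hold identical mass, so the low-coverage tie-break of
#' \code{\link{findMainPeak}} lands one bin short. The count-weighted
#' centroid over a window of \eqn{\pm 3\sqrt{c}} around the argmax (capped
#' at \eqn{0.4c} so the next fold-coverage peak stays outside) recovers
#' the component centre; windows narrower than 5 bins return the argmax
#' unchanged.
#'
#' @param hist a \linkS4class{KmerHistogram}.
#' @param cutoff error cutoff (window never extends below it).
#' @param peak argmax peak coverage to refine.
#' @return integer refined peak coverage.
#' @export
refinePeak <- function(hist, cutoff, peak) {
    cov <- coverageBins(hist)
    cnt <- kmerCounts(hist)
    half <- max(2L, min(ceiling(3 * sqrt(peak)), floor(0.4 * peak)))
    win <- which(cov >= max(cutoff, peak - half) & cov <= peak + half)
    if (length(win) < 5L) return(as.integer(peak))
    as.integer(round(sum(as.numeric(cov[win]) * cnt[win]) / sum(cnt[win])))
}

#' Locate shared-subgenome peaks
#'
#' Searches the smoothed series for local maxima inside the windows
#' \eqn{mc \pm 0.25c} for multiplicities \eqn{m = 2, 3}; these hold
#' k-mers identical in two or three subgenomes. A window with no genuine
#' local maximum (or only negligible mass, below \code{min_rel_height} of
#' the main peak) contributes nothing: absent peaks are never invented.
#'
#' @param hist a \linkS4class{KmerHistogram}.
#' @param cutoff error cutoff.
#' @param peak main peak coverage \eqn{c}.
#' @param multiplicities integer multiples of \eqn{c} to scan.
#' @param min_rel_height minimum peak height relative to the main peak.
#' @return integer vector of peak coverages (possibly empty).
#' @export
findSubgenomePeaks <- function(hist, cutoff, peak,
                               multiplicities = 2:3, min_rel_height = 0.005) {
    s <- .smoothed(hist)
    cov <- coverageBins(hist)
    main_h <- s[match(peak, cov)]
    if (is.na(main_h)) main_h <- max(s[cov >= cutoff])
    is_locmax <- s >= c(-Inf, s[-length(s)]) & s >= c(s[-1L], -Inf)
    out <- integer()
    for (m in multiplicities) {
        win <- which(cov >= (m - 0.25) * peak & cov <= (m + 0.25) * peak &
                     cov >= cutoff)
        if (!length(win)) next
        cand <- win[is_locmax[win] & s[win] >= min_rel_height * main_h]
        if (!length(cand)) next
        out <- c(out, cov[cand[which.max(s[cand])]])
    }
    out
}

#' Sequencing fold coverage against a fixed genome size
#'
#' \code{read_count * mean_read_length / genome_size}, the arithmetic used
#' to express each library's depth against the k-mer genome-size estimate.
#'
#' @param read_count number of reads.
#' @param mean_read_length mean read length in bp.
#' @param genome_size genome size in bp (> 0).
#' @return fold coverage (numeric, unrounded).
#' @examples
#' foldCoverage(21588293516, 150, 26.5e9)  # ~122
#' @export
foldCoverage <- function(read_count, mean_read_length, genome_size) {
    stopifnot(read_count >= 0, mean_read_length > 0)
    if (genome_size <= 0) stop("genome_size must be positive")
    read_count * mean_read_length / genome_size
}
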