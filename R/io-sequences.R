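#' @importFrom Biostrings readBStringSet writeXStringSet BStringSet
#'   DNAString DNAStringSet reverseComplement matchPattern
#'   letterFrequency pairwiseAlignment nmatch alphabetFrequency
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols
#'   GRangesList
#' @importFrom S4Vectors mcols<- queryHits subjectHits
#' @importFrom IRanges reduce findOverlaps subsetByOverlaps Views
NULL

#' Read a (softmasked) FASTA file
#'
#' Reads nucleotide FASTA preserving case, so that softmasking (lowercase)
#' survives the round trip and per-gene softmask fractions stay computable.
#' Record order is preserved; ids are the first whitespace-delimited token
#' of each header.
#'
#' @param path path to a FASTA file.
#' @return A \code{BStringSet} (case-preserving) named by record id.
#'   Empty files give an empty set.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acGT"), f)
#' x <- readFastaMasked(f)
#' softmaskFraction(x[[1]])
#' @export
readFastaMasked <- function(path) {
    stopifnot(file.exists(path))
    if (file.size(path) == 0L) return(BStringSet())
    x <- readBStringSet(path)
    names(x) <- sub("\\s.*$", "", names(x))
    if (any(names(x) == ""))
        stop("malformed FASTA header: empty record id in ", path)
    if (anyDuplicated(names(x)))
        stop("duplicate record id in ", path, ": ",
             names(x)[duplicated(names(x))][1L])
    ok <- grepl("^[ACGTNacgtn]*$", as.character(x))
    if (!all(ok))
        stop("non-ACGTN characters in FASTA record ", names(x)[!ok][1L])
    x
}

#' Write sequences to FASTA, preserving case
#'
#' @param x a named \code{BStringSet}/\code{DNAStringSet} or named character
#'   vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFastaMasked <- function(x, path) {
    if (is.character(x)) x <- BStringSet(x)
    writeXStringSet(x, path)
    invisible(path)
}

#' Fraction of softmasked (lowercase) bases
#'
#' @param x a single sequence (\code{BString}, \code{DNAString} or
#'   character scalar).
#' @param start,end optional 1-based closed subrange.
#' @return lowercase fraction of the (sub)sequence, NaN for width 0.
#' @export
softmaskFraction <- function(x, start = 1L, end = NA_integer_) {
    s <- as.character(x)
    if (is.na(end)) end <- nchar(s)
    s <- substr(s, start, end)
    if (nchar(s) == 0L) return(NaN)
    ch <- strsplit(s, "")[[1L]]
    mean(ch %in% c("a", "c", "g", "t", "n"))
}

#' Read a k-mer "histo" file
#'
#' Parses the two-column text emitted by k-mer counters: one
#' \code{coverage count} pair per line, whitespace-separated. Out-of-order
#' lines are sorted on load with a message; duplicate coverages and
#' non-integer or negative tokens are errors.
#'
#' @param path path to the histo file.
#' @param k k-mer length to record (the file itself does not carry it).
#' @return A \linkS4class{KmerHistogram}.
#' @export
readHisto <- function(path, k = 31L) {
    stopifnot(file.exists(path))
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty histogram file: ", path)
    parts <- strsplit(trimws(lines), "\\s+")
    if (any(lengths(parts) != 2L))
        stop("histo format error: expected 'coverage count' pairs in ", path)
    m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
    if (!all(grepl("^[0-9]+$", m)))
        stop("histo format error: non-integer token in ", path)
    cov <- as.integer(m[, 1L])
    cnt <- as.numeric(m[, 2L])
    if (anyDuplicated(cov))
        stop("histo format error: duplicate coverage in ", path)
    if (is.unsorted(cov))
        message("readHisto: coverages out of order; sorted on load")
    KmerHistogram(cov, cnt, k = k)
}

#' Write a KmerHistogram in histo form
#'
#' @param hist a \linkS4class{KmerHistogram}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeHisto <- function(hist, path) {
    writeLines(paste(hist@coverage, format(hist@count, scientific = FALSE,
        trim = TRUE)), path)
    invisible(path)
}

#' Read/write BED interval reports
#'
#' Thin wrappers over \pkg{rtracklayer} for the repeat/region BED reports;
#' BED's 0-based half-open coordinates are converted to/from 1-based closed
#' \code{GRanges} at this boundary.
#'
#' @param path BED file path.
#' @return \code{readBed}: a \code{GRanges} with a \code{name} column.
#' @export
readBed <- function(path) {
    rtracklayer::import(path, format = "BED")
}

#' @rdname readBed
#' @param gr a \code{GRanges}; its \code{name} metadata column (if any) is
#'   written as the BED name field.
#' @return \code{writeBed}: \code{path}, invisibly.
#' @export
writeBed <- function(gr, path) {
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}
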