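#' Read and write newick gene trees
#'
#' Wrappers over \pkg{ape} that accept one or many newick strings per file,
#' preserve leaf labels verbatim, keep internal node labels (support
#' values) and allow polytomies. Unbalanced parentheses or an empty file
#' are format errors.
#'
#' @param path newick file (one tree per line or ape multi-tree format).
#' @return \code{readNewick}: a \code{multiPhylo} list of trees (length 1
#'   for single-tree files).
#' @export
readNewick <- function(path) {
    stopifnot(file.exists(path))
    txt <- paste(readLines(path), collapse = "")
    if (!nzchar(trimws(txt))) stop("empty newick file: ", path)
    op <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
    cl <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
    if (op != cl) stop("newick format error: unbalanced parentheses in ", path)
    tr <- ape::read.tree(path)
    if (is.null(tr)) stop("newick format error in ", path)
    if (inherits(tr, "phylo")) tr <- structure(list(tr), class = "multiPhylo")
    tr
}

#' @rdname readNewick
#' @param trees a \code{phylo} or \code{multiPhylo}.
#' @return \code{writeNewick}: \code{path}, invisibly.
#' @export
writeNewick <- function(trees, path) {
    ape::write.tree(trees, file = path)
    invisible(path)
}
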