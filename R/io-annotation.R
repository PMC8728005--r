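#' Read GFF3 gene models
#'
#' Parses gene/mRNA/exon/CDS features (1-based closed coordinates, per the
#' GFF3 standard) into a \linkS4class{GeneModelSet}, one model per mRNA.
#' Exons and CDS are sorted into transcription order (ascending on
#' \code{+}, descending start on \code{-}). An mRNA without a parent gene
#' gets a synthesized gene container with a warning; a model whose CDS
#' falls outside its exon span is flagged invalid (\code{valid = FALSE})
#' rather than dropped. When \code{fasta} is supplied, the softmask
#' fraction of each gene span (lowercase bases / span length) is computed.
#'
#' @param path GFF3 file path.
#' @param fasta optional named \code{BStringSet} (or FASTA path) holding
#'   the softmasked scaffolds.
#' @return A \linkS4class{GeneModelSet}.
#' @export
readGff3 <- function(path, fasta = NULL) {
    stopifnot(file.exists(path))
    if (is.character(fasta)) fasta <- readFastaMasked(fasta)
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (!length(lines))
        return(GeneModelSet(S4Vectors::DataFrame(id = character(),
            scaffold = character(), strand = character()),
            IRanges::IRangesList(), IRanges::IRangesList()))
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) != 9L)) stop("GFF3 format error: expected 9 columns")
    f <- matrix(unlist(f), ncol = 9L, byrow = TRUE)
    attr_field <- function(attrs, key) {
        m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
        vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
    }
    type <- f[, 3L]
    ids <- attr_field(f[, 9L], "ID")
    parents <- attr_field(f[, 9L], "Parent")
    start <- as.integer(f[, 4L]); end <- as.integer(f[, 5L])
    if (any(is.na(start)) || any(is.na(end)) || any(start > end))
        stop("GFF3 format error: bad coordinates")

    mr <- which(type == "mRNA")
    gene_ids <- ids[type == "gene"]
    orphan <- mr[!is.na(parents[mr]) & !(parents[mr] %in% gene_ids) |
                 is.na(parents[mr])]
    if (length(orphan))
        warning("mRNA without parent gene; gene container synthesized for: ",
                paste(ids[orphan], collapse = ", "))

    rows <- lapply(mr, function(i) {
        mid <- ids[i]
        kid <- which(!is.na(parents) & parents == mid)
        ex <- kid[type[kid] == "exon"]
        cd <- kid[type[kid] == "CDS"]
        std <- f[i, 7L]
        ord <- function(j) j[order(start[j], decreasing = (std == "-"))]
        ex <- ord(ex); cd <- ord(cd)
        exr <- IRanges::IRanges(start[ex], end[ex])
        cdr <- IRanges::IRanges(start[cd], end[cd])
        valid <- TRUE
        if (length(cd)) {
            # every CDS base must fall inside some exon
            inside <- IRanges::countOverlaps(cdr,
                IRanges::reduce(exr), type = "within") > 0L
            if (length(ex) && !all(inside)) valid <- FALSE
        }
        sf <- NA_real_
        if (!is.null(fasta) && f[i, 1L] %in% names(fasta))
            sf <- softmaskFraction(fasta[[f[i, 1L]]], start[i], end[i])
        list(id = mid, scaffold = f[i, 1L], strand = std,
             softmask_fraction = sf, valid = valid, exons = exr, cds = cdr)
    })
    genes <- S4Vectors::DataFrame(
        id = vapply(rows, `[[`, "", "id"),
        scaffold = vapply(rows, `[[`, "", "scaffold"),
        strand = vapply(rows, `[[`, "", "strand"),
        softmask_fraction = vapply(rows, `[[`, 0, "softmask_fraction"),
        valid = vapply(rows, `[[`, TRUE, "valid"))
    GeneModelSet(genes,
        IRanges::IRangesList(lapply(rows, `[[`, "exons")),
        IRanges::IRangesList(lapply(rows, `[[`, "cds")))
}

#' Write a GeneModelSet as GFF3
#'
#' Emits one gene + mRNA pair per model with its exon and CDS children,
#' 1-based closed coordinates. Together with \code{\link{readGff3}} this
#' round-trips ids, strands and coordinates exactly.
#'
#' @param models a \linkS4class{GeneModelSet}.
#' @param path output path.
#' @param source value for GFF3 column 2.
#' @return \code{path}, invisibly.
#' @export
writeGff3 <- function(models, path, source = "PolyploidTools") {
    g <- geneInfo(models)
    con <- file(path, "w"); on.exit(close(con))
    writeLines("##gff-version 3", con)
    for (i in seq_len(nrow(g))) {
        ex <- geneExons(models)[[i]]; cd <- geneCds(models)[[i]]
        span <- range(c(IRanges::start(ex), IRanges::start(cd)))
        hi <- max(c(IRanges::end(ex), IRanges::end(cd)))
        lo <- min(span)
        line <- function(type, s, e, id, parent = NULL) {
            attrs <- paste0("ID=", id,
                if (!is.null(parent)) paste0(";Parent=", parent) else "")
            paste(g$scaffold[i], source, type, s, e, ".", g$strand[i], ".",
                  attrs, sep = "\t")
        }
        out <- c(line("gene", lo, hi, paste0(g$id[i], ".g")),
                 line("mRNA", lo, hi, g$id[i], paste0(g$id[i], ".g")))
        for (j in seq_along(ex))
            out <- c(out, line("exon", IRanges::start(ex)[j],
                IRanges::end(ex)[j], paste0(g$id[i], ".exon", j), g$id[i]))
        for (j in seq_along(cd))
            out <- c(out, line("CDS", IRanges::start(cd)[j],
                IRanges::end(cd)[j], paste0(g$id[i], ".cds", j), g$id[i]))
        writeLines(out, con)
    }
    invisible(path)
}

#' Read and write evidence-flag tables
#'
#' Tab-separated functional-evidence flags (similarity hit, domain count,
#' family assignment, retroelement domain) keyed by gene id, as produced
#' by external functional annotation and consumed by the gene filters.
#'
#' @param path TSV path with columns \code{id}, \code{has_similarity_hit},
#'   \code{domain_count}, \code{has_family_assignment},
#'   \code{retro_domain_flag}.
#' @return \code{readEvidence}: a data.frame.
#' @export
readEvidence <- function(path) {
    ev <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("id", "has_similarity_hit", "domain_count",
              "has_family_assignment", "retro_domain_flag")
    if (!all(need %in% colnames(ev)))
        stop("evidence TSV missing columns: ",
             paste(setdiff(need, colnames(ev)), collapse = ", "))
    ev
}

#' @rdname readEvidence
#' @param models a \linkS4class{GeneModelSet} whose evidence columns are
#'   replaced by the table values (matched on gene id).
#' @param evidence a data.frame as returned by \code{readEvidence}.
#' @return \code{attachEvidence}: the updated \code{GeneModelSet}.
#' @export
attachEvidence <- function(models, evidence) {
    g <- geneInfo(models)
    m <- match(g$id, evidence$id)
    if (anyNA(m)) stop("evidence missing for gene(s): ",
        paste(g$id[is.na(m)], collapse = ", "))
    g$has_similarity_hit <- as.logical(evidence$has_similarity_hit[m])
    g$domain_count <- as.integer(evidence$domain_count[m])
    g$has_family_assignment <- as.logical(evidence$has_family_assignment[m])
    g$retro_domain_flag <- as.logical(evidence$retro_domain_flag[m])
    GeneModelSet(g, geneExons(models), geneCds(models))
}
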