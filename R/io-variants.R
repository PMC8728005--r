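#' Read a minimal VCF into a VariantTable
#'
#' Parses the minimal VCF subset this pipeline exchanges: CHROM, POS
#' (1-based), REF, ALT and per-sample GT fields of \code{0/0}, \code{0/1},
#' \code{1/1} or \code{./.} (phased \code{|} separators accepted).
#' Multi-allelic sites (comma in ALT) are skipped with a warning and
#' counted in the \code{skipped_multiallelic} attribute; a record without
#' a GT field is an error.
#'
#' @param path VCF file path.
#' @param populations named character vector mapping sample id to
#'   population id; defaults to one population "pop1" for all samples.
#' @return A \linkS4class{VariantTable}; attribute
#'   \code{skipped_multiallelic} carries the skip count.
#' @export
readVariants <- function(path, populations = NULL) {
    stopifnot(file.exists(path))
    lines <- readLines(path)
    hdr <- grep("^#CHROM", lines)
    if (!length(hdr)) stop("VCF format error: missing #CHROM header line")
    cols <- strsplit(sub("^#", "", lines[hdr[1L]]), "\t")[[1L]]
    if (length(cols) < 10L) stop("VCF format error: no sample columns")
    samples <- cols[10:length(cols)]
    body <- lines[-seq_len(hdr[1L])]
    body <- body[nzchar(body) & !grepl("^#", body)]
    f <- strsplit(body, "\t", fixed = TRUE)
    if (length(f) && any(lengths(f) != length(cols)))
        stop("VCF format error: ragged record")
    f <- matrix(unlist(f), ncol = length(cols), byrow = TRUE)
    multi <- grepl(",", f[, 5L], fixed = TRUE)
    if (any(multi))
        warning(sum(multi), " multi-allelic site(s) skipped")
    keep <- which(!multi)
    gt_idx <- vapply(strsplit(f[keep, 9L], ":", fixed = TRUE),
        function(x) match("GT", x), 0L)
    if (anyNA(gt_idx)) stop("VCF format error: record without GT field")
    geno <- matrix(NA_integer_, nrow = length(keep), ncol = length(samples),
        dimnames = list(NULL, samples))
    for (j in seq_along(samples)) {
        raw <- vapply(seq_along(keep), function(i)
            strsplit(f[keep[i], 9L + j], ":", fixed = TRUE)[[1L]][gt_idx[i]], "")
        al <- strsplit(gsub("|", "/", raw, fixed = TRUE), "/", fixed = TRUE)
        ok <- lengths(al) == 2L
        dose <- rep(NA_integer_, length(raw))
        a1 <- vapply(al, `[`, "", 1L); a2 <- vapply(al, `[`, "", 2L)
        num <- ok & a1 %in% c("0", "1") & a2 %in% c("0", "1")
        dose[num] <- as.integer(a1[num]) + as.integer(a2[num])
        geno[, j] <- dose
    }
    if (is.null(populations))
        populations <- stats::setNames(rep("pop1", length(samples)), samples)
    vt <- VariantTable(
        sites = S4Vectors::DataFrame(scaffold = f[keep, 1L],
            pos = as.integer(f[keep, 2L]), ref = f[keep, 4L],
            alt = f[keep, 5L]),
        genotypes = geno, populations = populations)
    attr(vt, "skipped_multiallelic") <- sum(multi)
    vt
}

#' Write a VariantTable as minimal VCF
#'
#' @param x a \linkS4class{VariantTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeVariants <- function(x, path) {
    s <- variantSites(x); g <- genotypeMatrix(x)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", colnames(g)), collapse = "\t")), con)
    code <- c("0/0", "0/1", "1/1")
    for (i in seq_len(nrow(s))) {
        gt <- ifelse(is.na(g[i, ]), "./.", code[g[i, ] + 1L])
        writeLines(paste(c(as.character(s$scaffold[i]), s$pos[i], ".",
            as.character(s$ref[i]), as.character(s$alt[i]), ".", "PASS",
            ".", "GT", gt), collapse = "\t"), con)
    }
    invisible(path)
}

#' Read a population map
#'
#' Two-column TSV (\code{sample}, \code{population}), as used alongside
#' the VCF input of the diversity/Fst stage.
#'
#' @param path TSV path.
#' @return named character vector sample -> population.
#' @export
readPopulations <- function(path) {
    p <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("sample", "population") %in% colnames(p)))
        stop("population map needs 'sample' and 'population' columns")
    stats::setNames(p$population, p$sample)
}

#' Read and write orthogroup matrices
#'
#' The orthogroup TSV dialect: one row per family, first column
#' \code{family}, remaining columns one per species holding integer copy
#' counts. The optional gene-metadata TSV has columns \code{gene},
#' \code{family}, \code{species}, \code{length_aa}, \code{scaffold},
#' \code{start}.
#'
#' @param path matrix TSV path.
#' @param gene_meta_path optional per-gene metadata TSV path.
#' @return \code{readOrthogroups}: an \linkS4class{OrthogroupSet}.
#' @export
readOrthogroups <- function(path, gene_meta_path = NULL) {
    m <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"family" %in% colnames(m))
        stop("orthogroup TSV needs a 'family' column")
    counts <- as.matrix(m[, setdiff(colnames(m), "family"), drop = FALSE])
    rownames(counts) <- m$family
    gi <- list(); gm <- NULL
    if (!is.null(gene_meta_path)) {
        meta <- utils::read.delim(gene_meta_path, stringsAsFactors = FALSE)
        gm <- S4Vectors::DataFrame(length_aa = as.integer(meta$length_aa),
            scaffold = meta$scaffold, start = as.integer(meta$start),
            row.names = meta$gene)
        for (i in seq_len(nrow(meta)))
            gi[[meta$family[i]]][[meta$species[i]]] <-
                c(gi[[meta$family[i]]][[meta$species[i]]], meta$gene[i])
    }
    OrthogroupSet(counts, geneIndex = gi, geneMeta = gm)
}

#' @rdname readOrthogroups
#' @param x an \linkS4class{OrthogroupSet}.
#' @return \code{writeOrthogroups}: \code{path}, invisibly.
#' @export
writeOrthogroups <- function(x, path) {
    cnt <- familyCounts(x)
    df <- data.frame(family = rownames(cnt), cnt, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
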