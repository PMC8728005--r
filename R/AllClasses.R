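#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IRanges IRangesList
NULL

#' KmerHistogram: distinct k-mer counts by read coverage
#'
#' A k-mer spectrum as emitted by k-mer counters in "histo" form: for each
#' integer coverage depth \eqn{X}, the number of distinct k-mers observed
#' exactly \eqn{X} times in the reads. For a haploid sample of an
#' (auto)polyploid genome the spectrum shows a main peak at the sequencing
#' depth \eqn{c} plus secondary peaks near \eqn{2c} and \eqn{3c} from k-mers
#' shared identically between two or three subgenomes.
#'
#' @slot k k-mer length (integer, typically 31).
#' @slot coverage integer vector of coverage depths, strictly increasing.
#' @slot count numeric vector of distinct k-mer counts (>= 0), parallel to
#'   \code{coverage}. Numeric because genome-scale counts exceed 32-bit range.
#'
#' @aliases KmerHistogram-class
#' @exportClass KmerHistogram
setClass("KmerHistogram",
    representation(k = "integer", coverage = "integer", count = "numeric"))

setValidity("KmerHistogram", function(object) {
    msg <- character()
    if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
        msg <- c(msg, "'k' must be a single positive integer")
    if (length(object@coverage) != length(object@count))
        msg <- c(msg, "'coverage' and 'count' must be parallel")
    if (length(object@coverage) && any(diff(object@coverage) <= 0L))
        msg <- c(msg, "'coverage' must be strictly increasing")
    if (length(object@coverage) && any(object@coverage < 1L))
        msg <- c(msg, "'coverage' must be positive")
    if (any(is.na(object@count)) || any(object@count < 0))
        msg <- c(msg, "'count' must be nonnegative and non-missing")
    if (length(msg)) msg else TRUE
})

#' Construct a KmerHistogram
#'
#' @param coverage integer coverage depths (sorted automatically).
#' @param count distinct k-mer counts parallel to \code{coverage}.
#' @param k k-mer length.
#' @return A \linkS4class{KmerHistogram}.
#' @examples
#' KmerHistogram(1:5, c(1000, 100, 40, 80, 30))
#' @export
KmerHistogram <- function(coverage, count, k = 31L) {
    o <- order(coverage)
    new("KmerHistogram", k = as.integer(k),
        coverage = as.integer(coverage)[o], count = as.numeric(count)[o])
}

#' @describeIn KmerHistogram number of histogram bins.
#' @param x,object a \code{KmerHistogram}.
#' @export
setMethod("length", "KmerHistogram", function(x) length(x@coverage))

#' @rdname KmerHistogram
#' @export
coverageBins <- function(x) x@coverage

#' @rdname KmerHistogram
#' @export
kmerCounts <- function(x) x@count

#' @rdname KmerHistogram
#' @export
kmerLength <- function(x) x@k

setMethod("show", "KmerHistogram", function(object) {
    cat(sprintf("KmerHistogram (k = %d) with %d bins, coverage %d..%d\n",
        object@k, length(object@coverage),
        if (length(object@coverage)) min(object@coverage) else NA_integer_,
        if (length(object@coverage)) max(object@coverage) else NA_integer_))
    cat(sprintf("  total k-mer instances: %.6g\n",
        sum(as.numeric(object@coverage) * object@count)))
})

#' GeneModelSet: predicted gene models with structure and evidence
#'
#' Container for the unit of annotation filtering: one row per gene model,
#' with exon and CDS structure held as \code{IRangesList}s parallel to the
#' table. Coordinates are 1-based closed on the forward strand of the named
#' scaffold (GFF3 convention). The evidence columns carry the outcomes of
#' external functional annotation (sequence similarity, protein domains,
#' gene-family assignment, retroelement domain) consumed as flags.
#'
#' @slot genes a \code{DataFrame} with columns \code{id}, \code{scaffold},
#'   \code{strand}, \code{protein} (amino acids, \code{*} = stop, may be
#'   \code{NA}), \code{softmask_fraction} (lowercase fraction of the gene
#'   span, \code{NA} when no sequence was supplied),
#'   \code{has_similarity_hit}, \code{domain_count},
#'   \code{has_family_assignment}, \code{retro_domain_flag},
#'   \code{source} ("prediction" or "transcriptome"), \code{valid}.
#' @slot exons,cds \code{IRangesList} parallel to \code{genes}, in
#'   transcription order.
#'
#' @aliases GeneModelSet-class
#' @exportClass GeneModelSet
setClass("GeneModelSet",
    representation(genes = "DataFrame", exons = "IRangesList",
                   cds = "IRangesList"))

.gene_cols <- c("id", "scaffold", "strand", "protein", "softmask_fraction",
    "has_similarity_hit", "domain_count", "has_family_assignment",
    "retro_domain_flag", "source", "valid")

setValidity("GeneModelSet", function(object) {
    msg <- character()
    miss <- setdiff(.gene_cols, colnames(object@genes))
    if (length(miss))
        msg <- c(msg, paste("missing gene columns:", paste(miss, collapse = ", ")))
    n <- nrow(object@genes)
    if (length(object@exons) != n || length(object@cds) != n)
        msg <- c(msg, "'exons' and 'cds' must be parallel to 'genes'")
    if (n && anyDuplicated(object@genes$id))
        msg <- c(msg, "gene ids must be unique")
    if (n && !all(object@genes$strand %in% c("+", "-", ".")))
        msg <- c(msg, "strand must be one of +, -, .")
    sf <- object@genes$softmask_fraction
    if (n && any(!is.na(sf) & (sf < 0 | sf > 1)))
        msg <- c(msg, "softmask_fraction must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneModelSet
#'
#' @param genes a data.frame/DataFrame with the columns documented in
#'   \linkS4class{GeneModelSet}; missing evidence columns are filled with
#'   permissive defaults.
#' @param exons,cds \code{IRangesList} (or list of \code{IRanges}) parallel
#'   to \code{genes}.
#' @return A \linkS4class{GeneModelSet}.
#' @export
GeneModelSet <- function(genes, exons, cds) {
    genes <- as(genes, "DataFrame")
    defaults <- list(protein = NA_character_, softmask_fraction = NA_real_,
        has_similarity_hit = FALSE, domain_count = 0L,
        has_family_assignment = FALSE, retro_domain_flag = FALSE,
        source = "prediction", valid = TRUE)
    for (nm in names(defaults))
        if (!nm %in% colnames(genes))
            genes[[nm]] <- rep(defaults[[nm]], nrow(genes))
    if (!is(exons, "IRangesList")) exons <- as(exons, "IRangesList")
    if (!is(cds, "IRangesList")) cds <- as(cds, "IRangesList")
    new("GeneModelSet", genes = genes[, .gene_cols], exons = exons, cds = cds)
}

#' @describeIn GeneModelSet number of gene models.
#' @param x,object a \code{GeneModelSet}.
#' @export
setMethod("length", "GeneModelSet", function(x) nrow(x@genes))

#' @rdname GeneModelSet
#' @export
geneInfo <- function(x) x@genes

#' @rdname GeneModelSet
#' @export
geneExons <- function(x) x@exons

#' @rdname GeneModelSet
#' @export
geneCds <- function(x) x@cds

#' @rdname GeneModelSet
#' @param i index or logical/character vector selecting gene models.
#' @export
setMethod("[", "GeneModelSet", function(x, i) {
    if (is.character(i)) i <- match(i, x@genes$id)
    new("GeneModelSet", genes = x@genes[i, , drop = FALSE],
        exons = x@exons[i], cds = x@cds[i])
})

#' @rdname GeneModelSet
#' @export
isMonoExonic <- function(x) lengths(x@exons) == 1L

setMethod("show", "GeneModelSet", function(object) {
    n <- nrow(object@genes)
    cat(sprintf("GeneModelSet with %d gene models (%d mono-exonic) on %d scaffolds\n",
        n, sum(lengths(object@exons) == 1L),
        length(unique(object@genes$scaffold))))
})

#' OrthogroupSet: gene-family copy counts across species
#'
#' A family-by-species matrix of copy counts, with per-gene metadata
#' (protein length, scaffold, start) for the focal-species members that
#' drive tandem detection and phylogeny candidate selection.
#'
#' @slot counts integer matrix, rows = orthogroup/family ids, columns =
#'   species ids.
#' @slot geneIndex named list (by family) of named lists (by species) of
#'   member gene id vectors; may omit families/species with no recorded
#'   members.
#' @slot geneMeta \code{DataFrame} with rownames = gene id and columns
#'   \code{length_aa}, \code{scaffold}, \code{start}.
#'
#' @aliases OrthogroupSet-class
#' @exportClass OrthogroupSet
setClass("OrthogroupSet",
    representation(counts = "matrix", geneIndex = "list", geneMeta = "DataFrame"))

setValidity("OrthogroupSet", function(object) {
    msg <- character()
    cnt <- object@counts
    if (!is.numeric(cnt)) msg <- c(msg, "'counts' must be numeric")
    else if (any(cnt < 0) || any(cnt != round(cnt)))
        msg <- c(msg, "'counts' must be nonnegative integers")
    if ((nrow(cnt) && is.null(rownames(cnt))) ||
        (ncol(cnt) && is.null(colnames(cnt))))
        msg <- c(msg, "'counts' must have family rownames and species colnames")
    for (fam in names(object@geneIndex)) {
        for (sp in names(object@geneIndex[[fam]])) {
            ids <- object@geneIndex[[fam]][[sp]]
            if (!fam %in% rownames(cnt) || !sp %in% colnames(cnt) ||
                length(ids) != cnt[fam, sp]) {
                msg <- c(msg, "geneIndex sizes must match counts")
                break
            }
        }
    }
    if (nrow(object@geneMeta) &&
        !all(c("length_aa", "scaffold", "start") %in% colnames(object@geneMeta)))
        msg <- c(msg, "geneMeta needs length_aa, scaffold, start")
    if (nrow(object@geneMeta) && any(object@geneMeta$length_aa <= 0,
        na.rm = TRUE))
        msg <- c(msg, "protein lengths must be positive")
    if (length(msg)) unique(msg) else TRUE
})

#' Construct an OrthogroupSet
#'
#' @param counts family-by-species integer matrix with dimnames.
#' @param geneIndex optional nested list of member gene ids (family ->
#'   species -> character vector); sizes must match \code{counts}.
#' @param geneMeta optional per-gene metadata with rownames = gene id and
#'   columns \code{length_aa}, \code{scaffold}, \code{start}.
#' @return An \linkS4class{OrthogroupSet}.
#' @export
OrthogroupSet <- function(counts, geneIndex = list(), geneMeta = NULL) {
    storage.mode(counts) <- "integer"
    if (is.null(geneMeta))
        geneMeta <- DataFrame(length_aa = integer(), scaffold = character(),
            start = integer())
    new("OrthogroupSet", counts = counts, geneIndex = geneIndex,
        geneMeta = as(geneMeta, "DataFrame"))
}

#' @rdname OrthogroupSet
#' @param x,object an \code{OrthogroupSet}.
#' @export
familyCounts <- function(x) x@counts

#' @rdname OrthogroupSet
#' @export
familyGenes <- function(x) x@geneIndex

#' @rdname OrthogroupSet
#' @export
geneMeta <- function(x) x@geneMeta

setMethod("show", "OrthogroupSet", function(object) {
    cat(sprintf("OrthogroupSet: %d families x %d species (%s)\n",
        nrow(object@counts), ncol(object@counts),
        paste(colnames(object@counts), collapse = ", ")))
})

#' VariantTable: biallelic genotypes with population labels
#'
#' Minimal variant container for windowed diversity and Fst: one row per
#' biallelic site, diploid genotypes coded as alternate-allele dosage
#' 0/1/2 with \code{NA} for missing.
#'
#' @slot sites \code{DataFrame} with columns \code{scaffold}, \code{pos}
#'   (1-based), \code{ref}, \code{alt}; positions strictly increasing per
#'   scaffold.
#' @slot genotypes integer matrix, sites x samples, values 0/1/2/NA.
#' @slot populations named character vector: sample id -> population id.
#'
#' @aliases VariantTable-class
#' @exportClass VariantTable
setClass("VariantTable",
    representation(sites = "DataFrame", genotypes = "matrix",
                   populations = "character"))

setValidity("VariantTable", function(object) {
    msg <- character()
    if (!all(c("scaffold", "pos", "ref", "alt") %in% colnames(object@sites)))
        msg <- c(msg, "sites needs scaffold, pos, ref, alt")
    if (nrow(object@sites) != nrow(object@genotypes))
        msg <- c(msg, "genotypes rows must match sites")
    g <- object@genotypes
    if (!all(g[!is.na(g)] %in% 0:2))
        msg <- c(msg, "genotypes must be 0, 1, 2 or NA")
    if (ncol(g) && (is.null(colnames(g)) ||
        !all(colnames(g) %in% names(object@populations))))
        msg <- c(msg, "every sample must have a population label")
    if (nrow(object@sites)) {
        bad <- vapply(split(object@sites$pos, object@sites$scaffold),
            function(p) any(diff(p) <= 0), logical(1))
        if (any(bad))
            msg <- c(msg, "positions must be strictly increasing per scaffold")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a VariantTable
#'
#' @param sites data.frame/DataFrame with \code{scaffold}, \code{pos},
#'   \code{ref}, \code{alt}.
#' @param genotypes sites-by-samples matrix of alternate-allele dosages
#'   (0/1/2/NA) with sample ids as colnames.
#' @param populations named character vector mapping sample id to
#'   population id.
#' @return A \linkS4class{VariantTable}.
#' @export
VariantTable <- function(sites, genotypes, populations) {
    new("VariantTable", sites = as(sites, "DataFrame"),
        genotypes = genotypes, populations = populations)
}

#' @rdname VariantTable
#' @param x,object a \code{VariantTable}.
#' @export
variantSites <- function(x) x@sites

#' @rdname VariantTable
#' @export
genotypeMatrix <- function(x) x@genotypes

#' @rdname VariantTable
#' @export
samplePopulations <- function(x) x@populations

#' @describeIn VariantTable number of sites.
#' @export
setMethod("length", "VariantTable", function(x) nrow(x@sites))

setMethod("show", "VariantTable", function(object) {
    cat(sprintf("VariantTable: %d sites, %d samples, %d populations\n",
        nrow(object@sites), ncol(object@genotypes),
        length(unique(object@populations))))
})
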