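## Copy-number classification of orthogroups.
##
## For a hexaploid whose diploid relatives are represented once per
## gene, family copy counts carry the ploidy signal: 3:1:1 and 2:1:1
## families are the raw material of the polyploid-origin test, while
## presence/absence and fold-change classes describe lineage-specific
## gene-family dynamics.

#' Families present only in the focal species
#'
#' @param og an \linkS4class{OrthogroupSet}.
#' @param focal focal species column name.
#' @return character vector of family ids with focal count > 0 and zero
#'   in every other species.
#' @export
speciesSpecific <- function(og, focal) {
    cnt <- familyCounts(og)
    stopifnot(focal %in% colnames(cnt))
    others <- cnt[, setdiff(colnames(cnt), focal), drop = FALSE]
    rownames(cnt)[cnt[, focal] > 0L & rowSums(others) == 0L]
}

#' Families present in the focal species but absent from a species set
#'
#' Other, non-excluded species are unconstrained -- e.g. "present in the
#' focal species but absent from all other members of its family".
#'
#' @param og an \linkS4class{OrthogroupSet}.
#' @param focal focal species.
#' @param excluded_species species that must have zero copies.
#' @return character vector of family ids.
#' @export
absentInSet <- function(og, focal, excluded_species) {
    cnt <- familyCounts(og)
    stopifnot(all(c(focal, excluded_species) %in% colnames(cnt)))
    ex <- cnt[, excluded_species, drop = FALSE]
    rownames(cnt)[cnt[, focal] > 0L & rowSums(ex) == 0L]
}

#' Fold-change expansion/contraction relative to other species
#'
#' The baseline is the mean copy count over the non-focal species that
#' possess the family (count > 0). A family is expanded iff the focal
#' count is at least \code{fold} times the baseline, contracted iff at
#' most baseline / \code{fold}. Families found only in the focal species
#' have no baseline and are skipped (returned separately).
#'
#' @param og an \linkS4class{OrthogroupSet}.
#' @param focal focal species.
#' @param fold fold-change threshold.
#' @return list of family-id vectors: \code{expanded},
#'   \code{contracted}, \code{skipped_focal_only}.
#' @export
foldDeviation <- function(og, focal, fold = 2) {
    cnt <- familyCounts(og)
    stopifnot(focal %in% colnames(cnt))
    others <- cnt[, setdiff(colnames(cnt), focal), drop = FALSE]
    baseline <- apply(others, 1L, function(x)
        if (any(x > 0L)) mean(x[x > 0L]) else NA_real_)
    fc <- cnt[, focal]
    present <- fc > 0L
    has_base <- !is.na(baseline)
    list(expanded = rownames(cnt)[present & has_base & fc >= fold * baseline],
         contracted = rownames(cnt)[present & has_base & fc <= baseline / fold],
         skipped_focal_only = rownames(cnt)[present & !has_base])
}

#' Exact copy-number classes (e.g. 3:1:1 and 2:1:1)
#'
#' Families whose focal count equals \code{focal_copies} and whose count
#' in every reference species equals \code{ref_copies}.
#'
#' @param og an \linkS4class{OrthogroupSet}.
#' @param focal focal species.
#' @param reference_species reference species vector.
#' @param focal_copies required focal copy count.
#' @param ref_copies required count in each reference species.
#' @return character vector of family ids.
#' @export
copyClass <- function(og, focal, reference_species, focal_copies,
                      ref_copies = 1L) {
    cnt <- familyCounts(og)
    stopifnot(all(c(focal, reference_species) %in% colnames(cnt)))
    refs <- cnt[, reference_species, drop = FALSE]
    rownames(cnt)[cnt[, focal] == focal_copies &
                  rowSums(refs == ref_copies) == length(reference_species)]
}

#' Flag families with tandem-duplicated focal members
#'
#' A family is tandem-flagged iff at least two focal members lie on the
#' same scaffold with start positions within \code{max_separation_bp}.
#'
#' @param og an \linkS4class{OrthogroupSet} with gene metadata.
#' @param focal focal species.
#' @param max_separation_bp maximal separation in bp.
#' @return named logical vector over families that have focal members.
#' @export
flagTandem <- function(og, focal, max_separation_bp = 100000) {
    gi <- familyGenes(og)
    gm <- geneMeta(og)
    vapply(gi, function(fam) {
        ids <- fam[[focal]]
        if (length(ids) < 2L) return(FALSE)
        sc <- gm[ids, "scaffold"]; st <- gm[ids, "start"]
        for (s in unique(sc)) {
            p <- sort(st[sc == s])
            if (length(p) >= 2L && any(diff(p) <= max_separation_bp))
                return(TRUE)
        }
        FALSE
    }, logical(1))
}

#' Select families for the phylogenetic origin test
#'
#' Candidates are families with 2 or 3 focal copies and single-copy
#' reference species, excluding tandem-flagged families, where every
#' member protein is strictly longer than \code{min_len_aa} and at least
#' \code{min_frac_of_max} of the family's maximum length. A
#' deterministic random sample of \code{sample_n} passing families is
#' drawn under \code{seed}.
#'
#' @param og an \linkS4class{OrthogroupSet} with gene metadata.
#' @param focal focal species.
#' @param reference_species single-copy reference species.
#' @param min_len_aa strict minimal member length (aa).
#' @param min_frac_of_max minimal member length as a fraction of the
#'   family maximum.
#' @param sample_n families to sample; NULL returns all passing.
#' @param seed sampling seed.
#' @return list with \code{passing} (all qualifying family ids) and
#'   \code{sampled}.
#' @export
phyloCandidates <- function(og, focal, reference_species,
                            min_len_aa = 300L, min_frac_of_max = 0.75,
                            sample_n = NULL, seed = 1L) {
    pool <- c(copyClass(og, focal, reference_species, 2L),
              copyClass(og, focal, reference_species, 3L))
    tandem <- flagTandem(og, focal)
    pool <- pool[!pool %in% names(tandem)[tandem]]
    gm <- geneMeta(og)
    gi <- familyGenes(og)
    ok <- vapply(pool, function(fam) {
        ids <- unlist(gi[[fam]][c(focal, reference_species)])
        lens <- gm[ids, "length_aa"]
        all(lens > min_len_aa) && all(lens >= min_frac_of_max * max(lens))
    }, logical(1))
    passing <- pool[ok]
    sampled <- passing
    if (!is.null(sample_n)) {
        if (sample_n > length(passing)) {
            warning("sample_n exceeds passing families; returning all")
        } else {
            sampled <- with_seed(seed,
                sample(passing, sample_n))
        }
    }
    list(passing = passing, sampled = sampled)
}

#' Genes with a repeat insertion nearby
#'
#' A gene qualifies iff any interval of the repeat set overlaps the gene
#' span or lies within \code{window} bp of it on the same scaffold
#' (strand-agnostic).
#'
#' @param gene_intervals \code{GRanges} of gene spans (names or
#'   \code{mcols()$id} identify genes).
#' @param repeat_intervals \code{GRanges} of repeat insertions.
#' @param window maximal gap in bp.
#' @return character vector of qualifying gene ids.
#' @export
copiaProximity <- function(gene_intervals, repeat_intervals, window = 3000) {
    hits <- GenomicRanges::findOverlaps(gene_intervals, repeat_intervals,
        maxgap = window, ignore.strand = TRUE)
    idx <- unique(S4Vectors::queryHits(hits))
    ids <- names(gene_intervals)
    if (is.null(ids)) ids <- mcols(gene_intervals)$id
    if (is.null(ids)) ids <- as.character(seq_along(gene_intervals))
    ids[idx]
}

#' Greedy centroid clustering of focal proteins by identity
#'
#' An approximation of identity-threshold clustering for duplication
#' status: proteins are visited longest-first; each joins the first
#' existing cluster whose centroid it matches at \code{min_identity}
#' (matches / shorter sequence length, from a local alignment),
#' otherwise it founds a new cluster.
#'
#' @param proteins named character vector of protein sequences.
#' @param min_identity identity threshold.
#' @return named integer vector of cluster ids.
#' @export
clusterProteinsGreedy <- function(proteins, min_identity = 0.70) {
    ord <- order(nchar(proteins), decreasing = TRUE)
    centroids <- integer()
    assign_id <- stats::setNames(integer(length(proteins)), names(proteins))
    for (i in ord) {
        placed <- FALSE
        q <- Biostrings::AAString(gsub("\\*", "", proteins[[i]]))
        for (ci in seq_along(centroids)) {
            s <- Biostrings::AAString(gsub("\\*", "",
                proteins[[centroids[ci]]]))
            al <- pairwiseAlignment(q, s, type = "local",
                substitutionMatrix = .aa_identity_matrix(),
                gapOpening = 5, gapExtension = 2)
            idy <- nmatch(al) / min(length(q), length(s))
            if (idy >= min_identity) {
                assign_id[i] <- ci
                placed <- TRUE
                break
            }
        }
        if (!placed) {
            centroids <- c(centroids, i)
            assign_id[i] <- length(centroids)
        }
    }
    assign_id
}
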