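## Staged reduction of an inflated predicted gene set.
##
## Ab initio prediction over a huge, repeat-rich polyploid genome emits
## orders of magnitude more models than plausible genes; the surviving
## set is carved out by structural constraints, functional evidence,
## a coupled retroelement/softmask rule, a processed-pseudogene rule for
## mono-exonic models, and overlap resolution against transcriptome-
## derived models. Stage order is fixed: structural -> functional ->
## retroelement -> mono-exonic -> overlap resolution.

.filter_report <- function(models, removed, reason) {
    g <- geneInfo(models)
    data.frame(id = g$id, removed = removed,
               reason = ifelse(removed, reason, ""))
}

#' Structural gene-model filter
#'
#' A model passes iff its CDS totals at least \code{min_cds} bp and is a
#' multiple of 3, the protein is a complete ORF (leading M, trailing
#' stop, no internal stop), and every exon and every intron is at least
#' \code{min_feature} bp. Models without CDS are removed with reason
#' \code{no_cds}.
#'
#' @param models a \linkS4class{GeneModelSet}.
#' @param min_cds minimal total CDS length (bp).
#' @param min_feature minimal exon and intron length (bp).
#' @return list with \code{passing} (a \code{GeneModelSet}) and
#'   \code{report} (per-gene disposition with reason codes).
#' @export
structuralFilter <- function(models, min_cds = 100L, min_feature = 9L) {
    g <- geneInfo(models)
    n <- length(models)
    reason <- character(n)
    for (i in seq_len(n)) {
        cd <- geneCds(models)[[i]]
        ex <- geneExons(models)[[i]]
        p <- g$protein[i]
        reason[i] <- if (!length(cd)) "no_cds"
            else if (sum(IRanges::width(cd)) < min_cds) "cds_lt_100"
            else if (sum(IRanges::width(cd)) %% 3L != 0L) "cds_not_codon"
            else if (is.na(p) || !startsWith(p, "M")) "no_start"
            else if (!endsWith(p, "*")) "no_stop"
            else if (grepl("\\*.", p)) "internal_stop"
            else if (length(ex) && any(IRanges::width(ex) < min_feature))
                "exon_lt_9"
            else if (length(ex) > 1L && {
                exs <- ex[order(IRanges::start(ex))]  # genomic order
                iv <- IRanges::start(exs)[-1L] -
                      IRanges::end(exs)[-length(exs)] - 1L
                any(iv < min_feature)
            }) "intron_lt_9"
            else ""
    }
    removed <- reason != ""
    list(passing = models[!removed],
         report = .filter_report(models, removed, reason))
}

#' Functional-evidence filter
#'
#' A model is retained iff it carries at least one kind of functional
#' evidence: a sequence-similarity hit, at least one protein domain, or
#' a gene-family assignment. Models lacking all three are discarded.
#'
#' @param models a \linkS4class{GeneModelSet}.
#' @return list with \code{passing} and \code{report}.
#' @export
functionalFilter <- function(models) {
    g <- geneInfo(models)
    keep <- g$has_similarity_hit | g$domain_count >= 1L |
            g$has_family_assignment
    list(passing = models[keep],
         report = .filter_report(models, !keep, "no_evidence"))
}

#' Retroelement filter
#'
#' Removes a model iff it is flagged with a retroelement domain AND its
#' gene span is at least \code{mask_threshold} softmasked -- both
#' conditions are required; either alone retains the model.
#'
#' @param models a \linkS4class{GeneModelSet}.
#' @param mask_threshold softmask fraction at or above which a flagged
#'   model is removed (boundary inclusive).
#' @return list with \code{passing} and \code{report}.
#' @export
retroelementFilter <- function(models, mask_threshold = 0.70) {
    g <- geneInfo(models)
    sf <- g$softmask_fraction
    drop <- g$retro_domain_flag & !is.na(sf) & sf >= mask_threshold
    list(passing = models[!drop],
         report = .filter_report(models, drop, "retroelement"))
}

# best local alignment of one protein against a set; identity over
# aligned columns and coverage of the query
.best_protein_hit <- function(query, subjects) {
    q <- Biostrings::AAString(gsub("\\*", "", query))
    best <- list(identity = 0, coverage = 0, subject = NA_character_)
    for (nm in names(subjects)) {
        s <- Biostrings::AAString(gsub("\\*", "", subjects[[nm]]))
        al <- pairwiseAlignment(q, s, type = "local",
            substitutionMatrix = .aa_identity_matrix(),
            gapOpening = 5, gapExtension = 2)
        cols <- Biostrings::nchar(al)
        if (cols == 0L) next
        idy <- nmatch(al) / cols
        cov <- Biostrings::width(Biostrings::pattern(al)) / length(q)
        if (idy * cov > best$identity * best$coverage ||
            (idy > best$identity && cov >= best$coverage)) {
            best <- list(identity = idy, coverage = cov, subject = nm)
        }
    }
    best
}

# +1/-1 identity scoring over the amino-acid alphabet
.aa_identity_matrix <- local({
    m <- NULL
    function() {
        if (is.null(m)) {
            aa <- strsplit("ARNDCQEGHILKMFPSTWYVBZX*", "")[[1L]]
            m <<- matrix(-1, length(aa), length(aa), dimnames = list(aa, aa))
            diag(m) <<- 1
        }
        m
    }
})

#' Mono-exonic processed-pseudogene filter
#'
#' Processed pseudogenes are intronless, high-identity copies of
#' multi-exonic genes. Each mono-exonic protein is locally aligned to
#' every multi-exonic protein; a mono-exonic model whose best hit
#' reaches \code{min_identity} over at least \code{min_coverage} of its
#' own length is removed (or, with \code{remove_matches = FALSE},
#' retained as transcriptionally supported -- the opposite reading of
#' the rule, exposed as a switch).
#'
#' @param models a \linkS4class{GeneModelSet} with proteins available.
#' @param min_identity minimal identity (matches / aligned columns).
#' @param min_coverage minimal fraction of the mono-exonic protein
#'   covered by the alignment.
#' @param remove_matches remove matching mono-exonic models (default) or
#'   keep only them.
#' @return list with \code{passing}, \code{report}, and \code{hits}
#'   (best-hit statistics per mono-exonic model).
#' @export
monoexonicFilter <- function(models, min_identity = 0.75,
                             min_coverage = 0.70, remove_matches = TRUE) {
    mono <- isMonoExonic(models)
    g <- geneInfo(models)
    multi_prot <- stats::setNames(as.list(g$protein[!mono]), g$id[!mono])
    multi_prot <- multi_prot[!is.na(unlist(multi_prot))]
    if (!length(multi_prot)) {
        warning("no multi-exonic proteins; all mono-exonic models retained")
        return(list(passing = models,
                    report = .filter_report(models, rep(FALSE, length(models)),
                                            ""),
                    hits = NULL))
    }
    ids <- g$id[mono]
    hits <- do.call(rbind, lapply(which(mono), function(i) {
        b <- .best_protein_hit(g$protein[i], multi_prot)
        data.frame(id = g$id[i], best_subject = b$subject,
                   identity = b$identity, coverage = b$coverage)
    }))
    matched <- if (is.null(hits)) character() else
        hits$id[hits$identity >= min_identity & hits$coverage >= min_coverage]
    drop <- if (remove_matches) g$id %in% matched
            else mono & !(g$id %in% matched)
    list(passing = models[!drop],
         report = .filter_report(models, drop,
             if (remove_matches) "processed_pseudogene" else "unsupported_monoexonic"),
         hits = hits)
}

#' Transcript-to-genome alignment evidence filter
#'
#' Drops alignment records below the identity or coverage thresholds;
#' survivors are the transcriptome-derived models fed to the structural
#' filter.
#'
#' @param records data.frame with columns \code{identity} and
#'   \code{coverage} (fractions).
#' @param min_identity,min_coverage inclusive thresholds.
#' @return the passing subset of \code{records}.
#' @export
alignmentEvidenceFilter <- function(records, min_identity = 0.95,
                                    min_coverage = 0.95) {
    stopifnot(all(c("identity", "coverage") %in% colnames(records)))
    records[records$identity >= min_identity &
            records$coverage >= min_coverage, , drop = FALSE]
}

#' Resolve overlaps between predicted and transcriptome models
#'
#' Where a prediction and a transcriptome-derived model share at least
#' one CDS bp on the same strand of the same scaffold, the transcriptome
#' model wins and the prediction is dropped; everything else passes
#' through from both sources.
#'
#' @param prediction_models,transcriptome_models
#'   \linkS4class{GeneModelSet}s.
#' @return list with \code{merged} (a \code{GeneModelSet}; transcriptome
#'   models keep \code{source = "transcriptome"}) and \code{n_dropped}.
#' @export
resolveOverlaps <- function(prediction_models, transcriptome_models) {
    cds_ranges <- function(models) {
        g <- geneInfo(models)
        grl <- lapply(seq_len(length(models)), function(i) {
            cd <- geneCds(models)[[i]]
            GRanges(g$scaffold[i], cd, strand = g$strand[i])
        })
        if (!length(grl)) return(GRanges())
        gr <- do.call(c, grl)
        mcols(gr)$model <- rep(seq_len(length(models)),
                               lengths(geneCds(models)))
        gr
    }
    pg <- cds_ranges(prediction_models)
    tg <- cds_ranges(transcriptome_models)
    hit <- GenomicRanges::findOverlaps(pg, tg, ignore.strand = FALSE)
    dropped <- unique(mcols(pg)$model[S4Vectors::queryHits(hit)])
    keep_pred <- setdiff(seq_len(length(prediction_models)), dropped)
    gp <- geneInfo(prediction_models)[keep_pred, , drop = FALSE]
    gt <- geneInfo(transcriptome_models)
    gt$source <- rep("transcriptome", nrow(gt))
    merged <- GeneModelSet(rbind(gp, gt),
        c(geneExons(prediction_models)[keep_pred],
          geneExons(transcriptome_models)),
        c(geneCds(prediction_models)[keep_pred],
          geneCds(transcriptome_models)))
    list(merged = merged, n_dropped = length(dropped))
}

#' Run the full annotation-filter pipeline
#'
#' Applies, in order: structural, functional-evidence, retroelement and
#' mono-exonic filters to the predictions, then resolves overlaps with
#' transcriptome models (themselves structurally filtered). Each stage's
#' removed + retained counts reconcile exactly with its input.
#'
#' @param models predicted \linkS4class{GeneModelSet}.
#' @param transcriptome_models optional transcriptome-derived set.
#' @param mask_threshold,min_identity,min_coverage,remove_matches stage
#'   parameters (see the individual filters).
#' @return list with \code{passing}, per-stage \code{reports}, and
#'   \code{counts} (input/removed/retained per stage).
#' @export
filterAnnotation <- function(models, transcriptome_models = NULL,
                             mask_threshold = 0.70, min_identity = 0.75,
                             min_coverage = 0.70, remove_matches = TRUE) {
    stages <- list()
    s1 <- structuralFilter(models)
    stages$structural <- s1$report
    s2 <- functionalFilter(s1$passing)
    stages$functional <- s2$report
    s3 <- retroelementFilter(s2$passing, mask_threshold)
    stages$retroelement <- s3$report
    s4 <- monoexonicFilter(s3$passing, min_identity, min_coverage,
                           remove_matches)
    stages$monoexonic <- s4$report
    out <- s4$passing
    n_overlap_dropped <- 0L
    if (!is.null(transcriptome_models) && length(transcriptome_models)) {
        ts <- structuralFilter(transcriptome_models)
        stages$transcriptome_structural <- ts$report
        ov <- resolveOverlaps(out, ts$passing)
        out <- ov$merged
        n_overlap_dropped <- ov$n_dropped
    }
    counts <- data.frame(
        stage = names(stages),
        input = vapply(stages, nrow, 0L),
        removed = vapply(stages, function(r) sum(r$removed), 0L))
    counts$retained <- counts$input - counts$removed
    list(passing = out, reports = stages, counts = counts,
         n_overlap_dropped = n_overlap_dropped)
}
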