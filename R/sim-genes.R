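## Seeded generators for annotation-filter and orthogroup inputs.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

.random_protein <- function(len_aa) {
    paste0("M", paste(sample(.AA20, len_aa - 2L, replace = TRUE),
                      collapse = ""), "*")
}

# mutate a protein to a target identity, never touching the leading M or
# trailing stop
.mutate_protein <- function(prot, identity) {
    ch <- strsplit(prot, "")[[1L]]
    core <- 2:(length(ch) - 1L)
    n_mut <- round((1 - identity) * length(ch))
    idx <- sample(core, min(n_mut, length(core)))
    ch[idx] <- vapply(ch[idx], function(a)
        sample(setdiff(.AA20, a), 1L), "")
    paste(ch, collapse = "")
}

#' Simulate a predicted gene set with planted filter targets
#'
#' Plants four truth classes on one synthetic scaffold: (i) valid
#' multi-exonic genes (complete ORF, all exons/introns >= 9 bp,
#' CDS >= 100 bp, functional evidence present); (ii) structurally broken
#' genes (an 8-bp intron, a 99-bp CDS, or a missing stop codon); (iii)
#' retroelement genes (retro-domain evidence flag plus a softmasked gene
#' span); (iv) processed pseudogenes -- mono-exonic copies of planted
#' valid proteins at a configured amino-acid identity and full coverage.
#' Retro gene spans are emitted lowercase in the scaffold so the softmask
#' fraction is recomputable from sequence.
#'
#' @param n_valid,n_broken,n_retro,n_pseudo class sizes.
#' @param pseudo_identity amino-acid identity of pseudogene copies.
#' @param retro_mask softmasked fraction of retro gene spans.
#' @param seed integer seed.
#' @return list with \code{models} (a \linkS4class{GeneModelSet}, all
#'   evidence attached), \code{scaffold} (named \code{BStringSet} of one
#'   scaffold, case-significant) and \code{truth} (data.frame of id,
#'   class).
#' @export
simGeneModels <- function(n_valid = 8L, n_broken = 6L, n_retro = 4L,
                          n_pseudo = 4L, pseudo_identity = 0.8,
                          retro_mask = 0.8, seed = 1L) {
    stopifnot(n_valid >= 1L)
    with_seed(substream_seed(seed, .SIM_OFFSETS["genes"]), {
        spacer <- 300L
        pos <- 0L
        seq_parts <- character()
        rows <- list(); exons <- list(); cds <- list(); truth <- list()
        add_gene <- function(id, class, protein, exon_widths, intron_widths,
                             evidence, masked = FALSE) {
            seq_parts[[length(seq_parts) + 1L]] <<- random_dna(spacer)
            pos <<- pos + spacer
            gstart <- pos + 1L
            ex <- integer(0); cur <- gstart
            body <- character()
            for (k in seq_along(exon_widths)) {
                ex <- c(ex, cur)
                body <- c(body, random_dna(exon_widths[k]))
                cur <- cur + exon_widths[k]
                if (k < length(exon_widths)) {
                    body <- c(body, random_dna(intron_widths[k]))
                    cur <- cur + intron_widths[k]
                }
            }
            gene_seq <- paste(body, collapse = "")
            span <- nchar(gene_seq)
            if (masked) {
                nmask <- round(retro_mask * span)
                gene_seq <- paste0(tolower(substr(gene_seq, 1L, nmask)),
                                   substr(gene_seq, nmask + 1L, span))
            }
            seq_parts[[length(seq_parts) + 1L]] <<- gene_seq
            pos <<- pos + span
            er <- IRanges::IRanges(ex, width = exon_widths)
            rows[[id]] <<- data.frame(id = id, scaffold = "sim_sc1",
                strand = "+", protein = protein,
                softmask_fraction = if (masked) retro_mask else 0,
                has_similarity_hit = evidence[1L],
                domain_count = as.integer(evidence[2L]),
                has_family_assignment = evidence[3L],
                retro_domain_flag = evidence[4L],
                source = "prediction", valid = TRUE)
            exons[[id]] <<- er
            cds[[id]] <<- er
            truth[[id]] <<- data.frame(id = id, class = class)
        }
        multi_structure <- function(len_aa) {
            cds_len <- 3L * len_aa
            n_ex <- sample(2:4, 1L)
            brk <- sort(sample(seq(9L, cds_len - 9L, by = 3L), n_ex - 1L))
            w <- diff(c(0L, brk, cds_len))
            while (any(w < 9L)) {       # rejection keeps every exon >= 9 bp
                brk <- sort(sample(seq(9L, cds_len - 9L, by = 3L), n_ex - 1L))
                w <- diff(c(0L, brk, cds_len))
            }
            list(w = w, introns = sample(20:120, n_ex - 1L, replace = TRUE))
        }
        valid_prot <- character(n_valid)
        for (i in seq_len(n_valid)) {
            len_aa <- sample(120:220, 1L)
            valid_prot[i] <- .random_protein(len_aa)
            st <- multi_structure(len_aa)
            add_gene(sprintf("valid_%02d", i), "valid", valid_prot[i],
                     st$w, st$introns, c(TRUE, 2L, TRUE, FALSE))
        }
        broken_kinds <- rep(c("intron_lt_9", "cds_lt_100", "missing_stop"),
                            length.out = n_broken)
        for (i in seq_len(n_broken)) {
            kind <- broken_kinds[i]
            if (kind == "intron_lt_9") {
                len_aa <- sample(120:200, 1L)
                p <- .random_protein(len_aa)
                st <- multi_structure(len_aa)
                st$introns[1L] <- 8L
                add_gene(sprintf("broken_%02d", i), "broken", p, st$w,
                         st$introns, c(TRUE, 1L, TRUE, FALSE))
            } else if (kind == "cds_lt_100") {
                p <- .random_protein(33L)   # 99-bp CDS, complete ORF
                add_gene(sprintf("broken_%02d", i), "broken", p, 99L,
                         integer(0), c(TRUE, 1L, TRUE, FALSE))
            } else {
                len_aa <- sample(120:200, 1L)
                p <- sub("\\*$", sample(.AA20, 1L), .random_protein(len_aa))
                st <- multi_structure(len_aa)
                add_gene(sprintf("broken_%02d", i), "broken", p, st$w,
                         st$introns, c(TRUE, 1L, TRUE, FALSE))
            }
        }
        for (i in seq_len(n_retro)) {
            len_aa <- sample(150:300, 1L)
            st <- multi_structure(len_aa)
            add_gene(sprintf("retro_%02d", i), "retro",
                     .random_protein(len_aa), st$w, st$introns,
                     c(TRUE, 1L, FALSE, TRUE), masked = TRUE)
        }
        for (i in seq_len(n_pseudo)) {
            src <- sample(n_valid, 1L)
            p <- .mutate_protein(valid_prot[src], pseudo_identity)
            add_gene(sprintf("pseudo_%02d", i), "pseudogene", p,
                     3L * nchar(p), integer(0), c(FALSE, 1L, FALSE, FALSE))
        }
        seq_parts[[length(seq_parts) + 1L]] <- random_dna(spacer)
        models <- GeneModelSet(do.call(rbind, unname(rows)),
            IRanges::IRangesList(exons), IRanges::IRangesList(cds))
        list(models = models,
             scaffold = BStringSet(c(sim_sc1 = paste(seq_parts, collapse = ""))),
             truth = do.call(rbind, unname(truth)))
    })
}

#' Simulate an orthogroup matrix with planted copy-number classes
#'
#' Plants disjoint truth classes over species
#' (focal \code{CR}; references \code{GS}, \code{MG}; outgroups
#' \code{PA}, \code{AT}): species-specific families, families absent in
#' the reference clade but present elsewhere, >= 2-fold expanded and
#' contracted families, 3:1:1 and 2:1:1 classes, tandem-duplicate
#' families (2:1:1 counts with two focal members within
#' \code{tandem_span} on one scaffold) and uninformative background
#' families. Counts are chosen so each classifier recovers exactly its
#' planted set. Focal members of non-tandem families land on distinct
#' scaffolds; protein lengths lie in [0.8 max, max] above 300 aa so
#' multicopy families pass the phylogeny-candidate length rules.
#'
#' @param n_specific,n_absent,n_expanded,n_contracted,n_three,n_two
#'   class sizes.
#' @param n_tandem tandem-duplicate families (counts like 2:1:1).
#' @param n_background uninformative 1:1:1:1 families.
#' @param tandem_span bp separating tandem member starts.
#' @param seed integer seed.
#' @return list with \code{orthogroups} (an \linkS4class{OrthogroupSet})
#'   and \code{truth} (data.frame of family, class, tandem).
#' @export
simOrthogroups <- function(n_specific = 5L, n_absent = 5L, n_expanded = 5L,
                           n_contracted = 3L, n_three = 7L, n_two = 7L,
                           n_tandem = 3L, n_background = 10L,
                           tandem_span = 50000L, seed = 1L) {
    species <- c("CR", "GS", "MG", "PA", "AT")
    with_seed(substream_seed(seed, .SIM_OFFSETS["ortho"]), {
        fam_rows <- list(); truth <- list(); meta <- list(); gi <- list()
        sc_counter <- 0L
        add_family <- function(class, counts, tandem = FALSE) {
            fam <- sprintf("OG%05d", length(fam_rows) + 1L)
            fam_rows[[fam]] <<- counts
            truth[[fam]] <<- data.frame(family = fam, class = class,
                                        tandem = tandem)
            max_len <- sample(400:600, 1L)
            for (sp in species) {
                k <- counts[sp]
                if (k == 0L) next
                lens <- sample(seq(as.integer(0.8 * max_len), max_len), k,
                               replace = TRUE)
                ids <- sprintf("%s_%s_g%d", fam, sp, seq_len(k))
                if (sp == "CR" && tandem && k >= 2L) {
                    sc_counter <<- sc_counter + 1L
                    sc <- rep(sprintf("CRsc_%04d", sc_counter), k)
                    st <- 1000L + (seq_len(k) - 1L) * tandem_span
                } else {
                    sc <- sprintf("CRsc_%04d", sc_counter + seq_len(k))
                    sc_counter <<- sc_counter + k
                    st <- sample.int(1e6, k)
                }
                gi[[fam]][[sp]] <<- ids
                meta[[length(meta) + 1L]] <<- data.frame(gene = ids,
                    family = fam, species = sp, length_aa = lens,
                    scaffold = sc, start = st)
            }
        }
        cnt <- function(cr, gs, mg, pa, at)
            stats::setNames(c(cr, gs, mg, pa, at), species)
        for (i in seq_len(n_specific))
            add_family("species_specific", cnt(sample(1:4, 1L), 0, 0, 0, 0))
        for (i in seq_len(n_absent))
            add_family("absent_in_clade", cnt(sample(2:3, 1L), 0, 0, 2, 2))
        for (i in seq_len(n_expanded))
            add_family("expanded", cnt(8, 2, 2, 2, 0))
        for (i in seq_len(n_contracted))
            add_family("contracted", cnt(1, 4, 4, 4, 0))
        for (i in seq_len(n_three))
            add_family("three_to_one", cnt(3, 1, 1, 3, 0))
        for (i in seq_len(n_two))
            add_family("two_to_one", cnt(2, 1, 1, 2, 0))
        for (i in seq_len(n_tandem))
            add_family("two_to_one", cnt(2, 1, 1, 2, 0), tandem = TRUE)
        for (i in seq_len(n_background))
            add_family("background", cnt(1, 1, 1, 1, 1))
        counts <- do.call(rbind, fam_rows)
        meta <- do.call(rbind, meta)
        gm <- S4Vectors::DataFrame(length_aa = meta$length_aa,
            scaffold = meta$scaffold, start = meta$start,
            row.names = meta$gene)
        og <- OrthogroupSet(counts, geneIndex = gi, geneMeta = gm)
        list(orthogroups = og, truth = do.call(rbind, unname(truth)),
             gene_meta_table = meta)
    })
}
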