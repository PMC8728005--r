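## Pairwise divergence estimators and the polyploid-origin tree test.

.is_acgt <- function(ch) ch %in% c("A", "C", "G", "T")

.PURINES <- c("A", "G")

#' Kimura two-parameter distance
#'
#' From an aligned nucleotide pair, columns holding a gap or ambiguity
#' in either sequence are excluded pairwise; the rest yield the
#' transition proportion \eqn{P}, transversion proportion \eqn{Q} and
#' \deqn{K = -\tfrac12 \ln((1 - 2P - Q)\sqrt{1 - 2Q}).}
#' When \eqn{1 - 2P - Q \le 0} or \eqn{1 - 2Q \le 0} the distance is
#' saturated and reported as \code{NA} with \code{saturated = TRUE}.
#'
#' @param seq_a,seq_b aligned, equal-length nucleotide strings.
#' @return list with \code{P}, \code{Q}, \code{K}, \code{sites_used},
#'   \code{saturated}.
#' @examples
#' kimura2p("ACGT", "ACGA")$K
#' @export
kimura2p <- function(seq_a, seq_b) {
    a <- strsplit(toupper(as.character(seq_a)), "")[[1L]]
    b <- strsplit(toupper(as.character(seq_b)), "")[[1L]]
    if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
    use <- .is_acgt(a) & .is_acgt(b)
    a <- a[use]; b <- b[use]
    n <- length(a)
    if (n == 0L) stop("no comparable sites")
    diff <- a != b
    ts <- diff & ((a %in% .PURINES) == (b %in% .PURINES))
    P <- sum(ts) / n
    Q <- sum(diff & !ts) / n
    w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
    saturated <- w1 <= 0 || w2 <= 0
    K <- if (saturated) NA_real_ else -0.5 * log(w1 * sqrt(w2))
    list(P = P, Q = Q, K = K, sites_used = n, saturated = saturated)
}

# per-codon fraction of the 9 single-base changes that are synonymous,
# position by position; changes to stop codons count as nonsynonymous
.codon_site_table <- local({
    tab <- NULL
    function() {
        if (!is.null(tab)) return(tab)
        gc <- Biostrings::GENETIC_CODE
        bases <- c("A", "C", "G", "T")
        codons <- names(gc)
        syn <- stats::setNames(numeric(length(codons)), codons)
        for (cd in codons) {
            if (gc[[cd]] == "*") { syn[cd] <- NA_real_; next }
            s <- 0
            ch <- strsplit(cd, "")[[1L]]
            for (p in 1:3) for (nb in setdiff(bases, ch[p])) {
                alt <- ch; alt[p] <- nb
                alt <- paste(alt, collapse = "")
                if (gc[[alt]] == gc[[cd]]) s <- s + 1 / 3
            }
            syn[cd] <- s
        }
        tab <<- syn
        tab
    }
})

# classify the single-base steps of all mutational pathways between two
# codons; returns average (syn, nonsyn) differences over valid pathways
.pathway_diffs <- function(ca, cb) {
    gc <- Biostrings::GENETIC_CODE
    pos <- which(strsplit(ca, "")[[1L]] != strsplit(cb, "")[[1L]])
    if (!length(pos)) return(c(0, 0))
    perms <- if (length(pos) == 1L) list(pos)
        else if (length(pos) == 2L) list(pos, rev(pos))
        else {
            p <- pos
            list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)],
                 p[c(2,3,1)], p[c(3,1,2)], p[c(3,2,1)])
        }
    eval_path <- function(order) {
        cur <- strsplit(ca, "")[[1L]]
        tgt <- strsplit(cb, "")[[1L]]
        sd <- 0; nd <- 0
        for (p in order) {
            nxt <- cur; nxt[p] <- tgt[p]
            c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
            if (gc[[c2]] == "*") return(NULL)      # stop-crossing pathway
            if (gc[[c1]] == gc[[c2]]) sd <- sd + 1 else nd <- nd + 1
            cur <- nxt
        }
        c(sd, nd)
    }
    res <- Filter(Negate(is.null), lapply(perms, eval_path))
    if (!length(res)) {
        # all pathways cross a stop codon: fall back to counting steps
        # without the stop exclusion
        res <- lapply(perms, function(order) {
            cur <- strsplit(ca, "")[[1L]]; tgt <- strsplit(cb, "")[[1L]]
            sd <- 0; nd <- 0
            for (p in order) {
                nxt <- cur; nxt[p] <- tgt[p]
                if (gc[[paste(cur, collapse = "")]] ==
                    gc[[paste(nxt, collapse = "")]]) sd <- sd + 1
                else nd <- nd + 1
                cur <- nxt
            }
            c(sd, nd)
        })
    }
    Reduce(`+`, res) / length(res)
}

#' Counting-based pairwise dN/dS (Nei-Gojobori 1986)
#'
#' Synonymous/nonsynonymous site fractions per codon come from the
#' standard genetic code and are averaged over both sequences; observed
#' differences are classified along minimal mutational pathways
#' (multi-hit codons averaged uniformly over pathway orders, pathways
#' through stop codons excluded); the Jukes-Cantor correction
#' \eqn{d = -\tfrac34 \ln(1 - 4p/3)} converts proportions to rates.
#' Codons containing a gap or ambiguity in either sequence, and stop
#' codons, are excluded pairwise.
#'
#' @param cds_a,cds_b aligned coding sequences (lengths equal and, after
#'   exclusions, a multiple of 3).
#' @return list with sites \code{N}, \code{S}, differences \code{Nd},
#'   \code{Sd}, proportions \code{pN}, \code{pS}, corrected rates
#'   \code{dN}, \code{dS}, \code{omega} (\code{NA} when \code{dS} is 0
#'   or saturated), \code{codons_used}.
#' @export
pairwiseDnDs <- function(cds_a, cds_b) {
    a <- toupper(as.character(cds_a)); b <- toupper(as.character(cds_b))
    if (nchar(a) != nchar(b)) stop("sequences must be aligned (equal length)")
    if (nchar(a) %% 3L != 0L) stop("alignment length must be a codon multiple")
    st <- .codon_site_table()
    n_cod <- nchar(a) %/% 3L
    ca <- substring(a, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
    cb <- substring(b, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
    ok <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
    ok <- ok & !is.na(st[ca]) & !is.na(st[cb])   # drop stop codons
    ca <- ca[ok]; cb <- cb[ok]
    if (!length(ca)) stop("no comparable codons")
    S <- (sum(st[ca]) + sum(st[cb])) / 2
    N <- 3 * length(ca) - S
    d <- vapply(which(ca != cb), function(i)
        .pathway_diffs(ca[i], cb[i]), numeric(2))
    Sd <- if (length(d)) sum(d[1L, ]) else 0
    Nd <- if (length(d)) sum(d[2L, ]) else 0
    pS <- if (S > 0) Sd / S else NA_real_
    pN <- if (N > 0) Nd / N else NA_real_
    jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_
                      else -0.75 * log(1 - 4 * p / 3)
    dS <- jc(pS); dN <- jc(pN)
    omega <- if (is.na(dS) || is.na(dN) || dS == 0) NA_real_ else dN / dS
    list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
         dN = dN, dS = dS, omega = omega, codons_used = length(ca))
}

#' Classify one gene tree for the polyploid-origin test
#'
#' The tree is rooted on the outgroup. The focal species' copies are
#' monophyletic iff they form a clade; if so, the sibling subtree of
#' that clade names the sister lineage when exactly one candidate
#' species occurs in it, otherwise the sister is \code{unclear}. An
#' autopolyploid origin predicts focal monophyly in (nearly) every gene
#' tree; an allopolyploid origin places some copies with the donor
#' lineage.
#'
#' @param tree a \code{phylo}.
#' @param focal_species focal species id.
#' @param candidate_sisters candidate sister species ids.
#' @param outgroup outgroup species id.
#' @param species_fun maps a leaf label to its species id (default: text
#'   before the first underscore).
#' @param support_threshold optional: a focal clade with support below
#'   this value is reported with \code{sister = "unclear"}.
#' @return list with \code{focal_monophyletic}, \code{n_focal_copies},
#'   \code{sister} (a candidate, \code{"unclear"}, or \code{NA} when not
#'   monophyletic) and \code{support_at_focal_clade}.
#' @export
classifyTopology <- function(tree, focal_species = "CR",
                             candidate_sisters = c("GS", "MG"),
                             outgroup = "OUT",
                             species_fun = function(x) sub("_.*$", "", x),
                             support_threshold = NULL) {
    sp <- species_fun(tree$tip.label)
    out_tips <- tree$tip.label[sp == outgroup]
    if (!length(out_tips)) stop("outgroup '", outgroup, "' not in tree")
    focal_tips <- tree$tip.label[sp == focal_species]
    if (length(focal_tips) < 2L)
        stop("need at least 2 focal copies, found ", length(focal_tips))
    if (!all(candidate_sisters %in% sp))
        stop("candidate sister(s) missing from tree")
    tree <- ape::root(tree, outgroup = out_tips, resolve.root = TRUE)
    mono <- ape::is.monophyletic(tree, focal_tips)
    sister <- NA_character_
    support <- NA_real_
    if (mono) {
        mrca <- if (length(focal_tips) == 1L)
            match(focal_tips, tree$tip.label)
        else ape::getMRCA(tree, focal_tips)
        if (!is.null(tree$node.label) && mrca > length(tree$tip.label)) {
            lab <- tree$node.label[mrca - length(tree$tip.label)]
            support <- suppressWarnings(as.numeric(lab))
        }
        parent <- tree$edge[tree$edge[, 2L] == mrca, 1L]
        if (length(parent)) {
            sibs <- setdiff(tree$edge[tree$edge[, 1L] == parent, 2L], mrca)
            sib_tips <- unlist(lapply(sibs, function(nd)
                if (nd <= length(tree$tip.label)) tree$tip.label[nd]
                else ape::extract.clade(tree, nd)$tip.label))
            present <- intersect(candidate_sisters, unique(species_fun(sib_tips)))
            sister <- if (length(present) == 1L) present else "unclear"
        } else sister <- "unclear"
        if (!is.null(support_threshold) && !is.na(support) &&
            support < support_threshold)
            sister <- "unclear"
    }
    list(focal_monophyletic = mono, n_focal_copies = length(focal_tips),
         sister = sister, support_at_focal_clade = support)
}

#' Tally topology calls over a set of gene trees
#'
#' @param calls a list of results from \code{\link{classifyTopology}},
#'   or a \code{multiPhylo} (classified with \code{...} passed through).
#' @param ... arguments for \code{\link{classifyTopology}} when
#'   \code{calls} is a tree set.
#' @return list with \code{tally} (counts of monophyletic-by-sister and
#'   non-monophyletic) and \code{by_copy_number} (2- vs 3-copy trees).
#' @export
tallyTopologies <- function(calls, ...) {
    if (inherits(calls, "multiPhylo") || inherits(calls, "phylo")) {
        if (inherits(calls, "phylo")) calls <- list(calls)
        calls <- lapply(calls, classifyTopology, ...)
    }
    sisters <- vapply(calls, function(x)
        if (!x$focal_monophyletic) "non_monophyletic" else x$sister, "")
    copies <- vapply(calls, `[[`, 0L, "n_focal_copies")
    lev <- c("GS", "MG", "unclear", "non_monophyletic")
    lev <- c(setdiff(unique(sisters), c(lev)), lev)  # keep custom sisters
    tally <- table(factor(sisters, levels = lev))
    list(tally = tally,
         by_copy_number = table(copies = copies, call = factor(sisters,
             levels = lev)))
}
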