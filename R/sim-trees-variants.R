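## Seeded generators for gene trees and population genotypes.

#' Simulate gene trees under autopolyploid or allopolyploid scenarios
#'
#' Builds newick gene trees for a focal species with 2 or 3 gene copies,
#' two candidate sister lineages (\code{GS}, \code{MG}) and an outgroup
#' (\code{OUT}). Under \code{auto} the focal copies form an exclusive
#' clade whose sister lineage is drawn from \code{sister_weights}; under
#' \code{allo_GS} / \code{allo_MG} one focal copy branches inside the
#' named donor lineage, so the focal copies are not monophyletic.
#' Topological noise is applied as random nearest-neighbour-interchange
#' moves. Leaf labels are \code{<species>_<copy>}.
#'
#' @param n_trees number of trees.
#' @param scenario one of \code{"auto"}, \code{"allo_GS"},
#'   \code{"allo_MG"}.
#' @param focal_copies 2 or 3 focal gene copies.
#' @param sister_weights sampling weights for the sister lineage under
#'   \code{auto}, named \code{GS} and \code{MG}.
#' @param nni_moves number of random NNI moves applied per tree.
#' @param seed integer seed.
#' @return a \code{multiPhylo} of \code{n_trees} trees.
#' @export
simGeneTrees <- function(n_trees = 50L, scenario = c("auto", "allo_GS",
                         "allo_MG"), focal_copies = 3L,
                         sister_weights = c(GS = 1, MG = 0),
                         nni_moves = 0L, seed = 1L) {
    scenario <- match.arg(scenario)
    stopifnot(focal_copies %in% 2:3)
    with_seed(substream_seed(seed, .SIM_OFFSETS["trees"]), {
        focal_clade <- function(copies) {
            tips <- sprintf("CR_%d", seq_len(copies))
            if (copies == 1L) tips
            else if (copies == 2L) sprintf("(%s,%s)", tips[1L], tips[2L])
            else sprintf("((%s,%s),%s)", tips[1L], tips[2L], tips[3L])
        }
        trees <- lapply(seq_len(n_trees), function(i) {
            if (scenario == "auto") {
                sis <- sample(names(sister_weights), 1L,
                              prob = sister_weights)
                other <- setdiff(c("GS", "MG"), sis)
                nwk <- sprintf("(((%s,%s_1),%s_1),OUT_1);",
                               focal_clade(focal_copies), sis, other)
            } else {
                donor <- sub("allo_", "", scenario)
                other <- setdiff(c("GS", "MG"), donor)
                # one copy joins the donor lineage; remaining copies stay
                # together and get renumbered so labels are unique
                rest <- gsub("CR_1\\b", "CR_x", focal_clade(focal_copies - 1L))
                nwk <- sprintf("(((CR_1,%s_1),(%s,%s_1)),OUT_1);",
                               donor, rest, other)
            }
            tr <- ape::read.tree(text = nwk)
            tr$tip.label <- sub("^CR_x$", sprintf("CR_%d", focal_copies),
                                tr$tip.label)
            tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
            if (nni_moves > 0L) tr <- phangorn::rNNI(tr, moves = nni_moves)
            tr
        })
        class(trees) <- "multiPhylo"
        trees
    })
}

#' Simulate structured population genotypes (Balding-Nichols model)
#'
#' Per locus, an ancestral allele frequency is drawn uniformly on
#' (0.05, 0.95); each population's frequency is drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), giving among-population variance
#' \eqn{F p (1-p)}; diploid genotypes are binomial draws. Positions are
#' uniform over one scaffold. Loci fixed across all samples by the
#' binomial sampling are retained (their per-site diversity is 0).
#'
#' @param n_pops number of populations.
#' @param n_per_pop diploid individuals per population.
#' @param n_loci number of loci.
#' @param fst target differentiation \eqn{F}, 0 < F < 1.
#' @param scaffold_length bp span over which positions are drawn.
#' @param seed integer seed.
#' @return a \linkS4class{VariantTable} with populations
#'   \code{pop1..popr} and samples \code{pop<i>_s<j>}.
#' @export
simVariants <- function(n_pops = 2L, n_per_pop = 30L, n_loci = 20000L,
                        fst = 0.05, scaffold_length = 2e7, seed = 1L) {
    stopifnot(fst > 0, fst < 1, n_loci <= scaffold_length)
    with_seed(substream_seed(seed, .SIM_OFFSETS["variants"]), {
        pos <- sort(sample.int(scaffold_length, n_loci))
        p_anc <- stats::runif(n_loci, 0.05, 0.95)
        a <- p_anc * (1 - fst) / fst
        b <- (1 - p_anc) * (1 - fst) / fst
        geno <- matrix(NA_integer_, n_loci, n_pops * n_per_pop)
        pops <- character()
        for (k in seq_len(n_pops)) {
            pk <- stats::rbeta(n_loci, a, b)
            block <- matrix(stats::rbinom(n_loci * n_per_pop, 2L, pk),
                            nrow = n_loci)   # pk recycles down columns
            cols <- (k - 1L) * n_per_pop + seq_len(n_per_pop)
            geno[, cols] <- block
            pops <- c(pops, rep(sprintf("pop%d", k), n_per_pop))
        }
        samples <- sprintf("%s_s%d", pops,
                           unlist(lapply(seq_len(n_pops),
                                         function(k) seq_len(n_per_pop))))
        colnames(geno) <- samples
        bases <- c("A", "C", "G", "T")
        ref <- sample(bases, n_loci, replace = TRUE)
        alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
        VariantTable(
            sites = S4Vectors::DataFrame(scaffold = "sim_chr1", pos = pos,
                ref = ref, alt = unname(alt)),
            genotypes = geno,
            populations = stats::setNames(pops, samples))
    })
}
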