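mk_og <- function(mat, meta = NULL, gi = list()) {
    OrthogroupSet(mat, geneIndex = gi, geneMeta = meta)
}

cnt_mat <- function(...) {
    rows <- list(...)
    m <- do.call(rbind, rows)
    colnames(m) <- c("CR", "GS", "MG", "PA")
    rownames(m) <- sprintf("OG%03d", seq_len(nrow(m)))
    m
}

test_that("species-specific families need zero copies everywhere else", {
    og <- mk_og(cnt_mat(c(4, 0, 0, 0), c(4, 1, 0, 0), c(0, 2, 2, 2)))
    expect_identical(speciesSpecific(og, "CR"), "OG001")
    empty <- mk_og(matrix(integer(), 0, 2,
        dimnames = list(character(), c("CR", "GS"))))
    expect_length(speciesSpecific(empty, "CR"), 0L)
})

test_that("clade absence constrains only the excluded species", {
    og <- mk_og(cnt_mat(c(2, 0, 0, 2), c(2, 1, 0, 2), c(3, 0, 0, 0)))
    expect_setequal(absentInSet(og, "CR", c("GS", "MG")),
                    c("OG001", "OG003"))
    # empty exclusion degenerates to a presence filter
    expect_setequal(absentInSet(og, "CR", character()),
                    c("OG001", "OG002", "OG003"))
})

test_that("fold deviation uses the mean over possessing species", {
    og <- mk_og(cnt_mat(c(10, 4, 4, 4),   # 10 >= 2*4       -> expanded
                        c(7, 4, 4, 4),    # neither
                        c(1, 4, 4, 4),    # 1 <= 4/2        -> contracted
                        c(8, 2, 6, 0),    # baseline mean 4  -> expanded
                        c(5, 0, 0, 0)))   # focal-only       -> skipped
    fd <- foldDeviation(og, "CR")
    expect_setequal(fd$expanded, c("OG001", "OG004"))
    expect_identical(fd$contracted, "OG003")
    expect_identical(fd$skipped_focal_only, "OG005")
})

test_that("fold deviation is scale-consistent", {
    m1 <- cnt_mat(c(8, 4, 4, 4))
    m2 <- cnt_mat(c(16, 8, 8, 8))
    expect_identical(length(foldDeviation(mk_og(m1), "CR")$expanded),
                     length(foldDeviation(mk_og(m2), "CR")$expanded))
})

test_that("exact copy classes match focal and every reference count", {
    og <- mk_og(cnt_mat(c(3, 1, 1, 9),    # 3:1:1 (PA unconstrained)
                        c(2, 1, 1, 0),    # 2:1:1
                        c(3, 1, 2, 0),    # ref mismatch
                        c(2, 2, 1, 0)))   # ref mismatch
    three <- copyClass(og, "CR", c("GS", "MG"), 3L)
    two <- copyClass(og, "CR", c("GS", "MG"), 2L)
    expect_identical(three, "OG001")
    expect_identical(two, "OG002")
    expect_length(intersect(three, two), 0L)
})

test_that("tandem flag needs two focal members close on one scaffold", {
    meta <- S4Vectors::DataFrame(
        length_aa = rep(400L, 6L),
        scaffold = c("s1", "s1", "s2", "s3", "s4", "s4"),
        start = c(1000L, 51000L, 1000L, 1000L, 1000L, 201000L),
        row.names = paste0("g", 1:6))
    gi <- list(
        near = list(CR = c("g1", "g2")),
        apart_scaffolds = list(CR = c("g3", "g4")),
        far_same_scaffold = list(CR = c("g5", "g6")),
        single = list(CR = "g1"))
    mat <- matrix(c(2L, 2L, 2L, 1L), ncol = 1L,
                  dimnames = list(names(gi), "CR"))
    og <- mk_og(mat, meta, gi)
    fl <- flagTandem(og, "CR", max_separation_bp = 100000)
    expect_true(fl[["near"]])
    expect_false(fl[["apart_scaffolds"]])
    expect_false(fl[["far_same_scaffold"]])
    expect_false(fl[["single"]])
})

test_that("phylogeny candidates enforce both length rules strictly", {
    meta <- S4Vectors::DataFrame(
        length_aa = c(400L, 350L, 320L,  350L, 310L, 200L,
                      400L, 290L, 395L),
        scaffold = paste0("s", 1:9), start = rep(1L, 9L),
        row.names = paste0("g", 1:9))
    gi <- list(
        pass = list(CR = c("g1", "g2"), GS = "g3"),
        fail_short = list(CR = c("g4", "g5"), GS = "g6"),   # 200 < 262.5, < 300
        fail_at_300 = list(CR = c("g7", "g8"), GS = "g9"))  # 290 not > 300
    mat <- matrix(2L, nrow = 3L, ncol = 2L,
                  dimnames = list(names(gi), c("CR", "GS")))
    mat[, "GS"] <- 1L
    og <- mk_og(mat, meta, gi)
    pc <- phyloCandidates(og, "CR", "GS")
    expect_identical(pc$passing, "pass")
})

test_that("candidate sampling is deterministic and warns when short", {
    sim <- simOrthogroups(seed = 9L)
    a <- phyloCandidates(sim$orthogroups, "CR", c("GS", "MG"),
                         sample_n = 5L, seed = 4L)
    b <- phyloCandidates(sim$orthogroups, "CR", c("GS", "MG"),
                         sample_n = 5L, seed = 4L)
    expect_identical(a$sampled, b$sampled)
    expect_length(a$sampled, 5L)
    expect_warning(
        phyloCandidates(sim$orthogroups, "CR", c("GS", "MG"),
                        sample_n = 10000L), "exceeds")
    # tandem-flagged families never qualify
    expect_length(intersect(a$passing,
        sim$truth$family[sim$truth$tandem]), 0L)
})

test_that("repeat proximity uses overlap or gap within the window", {
    genes <- GenomicRanges::GRanges("s", IRanges::IRanges(
        c(10000L, 50000L, 90000L), width = 5000L))
    names(genes) <- c("gA", "gB", "gC")
    copia <- GenomicRanges::GRanges("s", IRanges::IRanges(
        c(10000L - 3000L + 1L,      # 2999 bp upstream of gA
          58002L,                   # 3001 bp beyond gB end (55000 + 3001)
          91000L), width = c(1L, 1L, 100L)))   # inside gC
    hit <- copiaProximity(genes, copia, window = 3000)
    expect_setequal(hit, c("gA", "gC"))
})

test_that("planted orthogroup classes are recovered exactly across seeds", {
    for (seed in seq_len(20L)) {
        sim <- simOrthogroups(seed = seed)
        og <- sim$orthogroups; tr <- sim$truth
        expect_setequal(speciesSpecific(og, "CR"),
                        tr$family[tr$class == "species_specific"])
        expect_setequal(absentInSet(og, "CR", c("GS", "MG")),
            tr$family[tr$class %in% c("species_specific", "absent_in_clade")])
        fd <- foldDeviation(og, "CR")
        expect_setequal(fd$expanded, tr$family[tr$class == "expanded"])
        expect_setequal(fd$contracted, tr$family[tr$class == "contracted"])
        expect_setequal(copyClass(og, "CR", c("GS", "MG"), 3L),
                        tr$family[tr$class == "three_to_one"])
        expect_setequal(copyClass(og, "CR", c("GS", "MG"), 2L),
                        tr$family[tr$class == "two_to_one"])
        fl <- flagTandem(og, "CR")
        expect_setequal(names(fl)[fl], tr$family[tr$tandem])
    }
})

test_that("greedy identity clustering groups near-duplicates only", {
    prots <- c(a1 = paste0("M", strrep("ACDEFGHIKL", 20L)),
               a2 = paste0("M", strrep("ACDEFGHIKL", 20L)),
               b1 = paste0("M", strrep("WYSTPVNQRH", 20L)))
    cl <- clusterProteinsGreedy(prots, min_identity = 0.70)
    expect_identical(cl[["a1"]], cl[["a2"]])
    expect_false(cl[["b1"]] == cl[["a1"]])
})
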