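tel_plus <- function(copies) strrep("CCCTAAA", copies)
tel_minus <- function(copies) strrep("TTTAGGG", copies)
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

test_that("telomere arrays are found with correct span and orientation", {
    set.seed(1)
    seq <- paste0(tel_plus(30L), rand_dna(2000), tel_minus(25L))
    hits <- scanTelomeres(seq, name = "s1")
    expect_length(hits, 2L)
    expect_identical(as.character(GenomicRanges::strand(hits)), c("+", "-"))
    expect_identical(GenomicRanges::width(hits)[1L], 210L)
    expect_identical(GenomicRanges::start(hits)[1L], 1L)
    expect_identical(GenomicRanges::end(hits)[2L], nchar(seq))
})

test_that("short arrays below the minimum span are not reported", {
    set.seed(2)
    seq <- paste0(rand_dna(500), strrep("CCCTAAA", 2L), rand_dna(500))
    expect_length(scanTelomeres(seq, min_array_bp = 100), 0L)
})

test_that("telomere runs tolerate scattered substitutions within budget", {
    set.seed(3)
    arr <- strsplit(strrep("CCCTCAA", 40L), "")[[1L]]
    idx <- seq(15L, 265L, by = 35L)                 # 8 scattered changes
    arr[idx] <- "G"
    seq <- paste0(rand_dna(300), paste(arr, collapse = ""), rand_dna(300))
    hits <- scanTelomeres(seq)
    expect_length(hits, 1L)
    expect_gte(sum(GenomicRanges::width(hits)), 0.9 * 280L)
})

test_that("centromere scan hits exact and degraded copies, both strands", {
    set.seed(4)
    unit <- as.character(centromereConsensus())
    mut <- strsplit(unit, "")[[1L]]
    pos <- sample(148L, 14L)                         # 10% substitutions
    mut[pos] <- vapply(mut[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    rc <- as.character(Biostrings::reverseComplement(centromereConsensus()))
    seq <- paste0(rand_dna(400), unit, rand_dna(400),
                  paste(mut, collapse = ""), rand_dna(400), rc, rand_dna(400))
    hits <- scanCentromeres(seq, min_identity = 0.8)
    expect_length(hits, 3L)
    expect_equal(max(hits$identity), 1.0)
    expect_true(any(as.character(GenomicRanges::strand(hits)) == "-"))
    expect_error(scanCentromeres(seq, consensus = Biostrings::DNAString("ACGT")),
                 "148")
})

test_that("merging respects the strict distance rule", {
    h1 <- layout_hits(c(100000L))
    expect_length(mergeCentromericHits(h1, 250000), 1L)
    h2 <- layout_hits(c(250000L))
    expect_length(mergeCentromericHits(h2, 250000), 2L)
    h3 <- layout_hits(c(249999L))
    expect_length(mergeCentromericHits(h3, 250000), 1L)
})

test_that("merging is idempotent and separates regions correctly", {
    set.seed(5)
    gaps <- sample(c(50000L, 400000L), 30L, TRUE)
    h <- layout_hits(gaps)
    r1 <- mergeCentromericHits(h)
    r2 <- mergeCentromericHits(r1)
    expect_identical(GenomicRanges::start(r2), GenomicRanges::start(r1))
    expect_identical(GenomicRanges::end(r2), GenomicRanges::end(r1))
    gap_between <- GenomicRanges::start(r1)[-1L] -
        GenomicRanges::end(r1)[-length(r1)] - 1L
    expect_true(all(gap_between >= 250000L))
})

test_that("merge equals brute-force transitive closure on random layouts", {
    set.seed(6)
    for (i in 1:20) {
        n <- sample(5:60, 1L)
        gaps <- sample(c(1000L, 100000L, 249999L, 250000L, 500000L),
                       n - 1L, TRUE)
        h <- layout_hits(gaps)
        got <- mergeCentromericHits(h, 250000)
        want <- oracle_merge(GenomicRanges::start(h), GenomicRanges::end(h),
                             250000L)
        expect_identical(GenomicRanges::start(got), as.integer(want[, 1L]))
        expect_identical(GenomicRanges::end(got), as.integer(want[, 2L]))
    }
})

test_that("the 40-copy layout with 7 short gaps merges into 33 regions", {
    gaps <- rep(300000L, 39L)
    gaps[c(2L, 7L, 12L, 17L, 22L, 27L, 32L)] <- 100000L
    regions <- mergeCentromericHits(layout_hits(gaps), 250000)
    expect_length(regions, 33L)
})

test_that("a fused scaffold splits at both internal telomere boundaries", {
    # toy replica of a two-chromosome fusion: centromeres flank a junction
    # carrying the 3' telomere of the left chromosome and the 5' telomere
    # of the right one
    set.seed(7)
    cen <- GenomicRanges::GRanges("sc", IRanges::IRanges(
        c(755000L, 1015000L), width = 3000L), copy_count = 1L)
    tel <- GenomicRanges::GRanges("sc", IRanges::IRanges(
        c(779000L, 980000L), width = 210L), strand = c("-", "+"),
        kind = "telomere", identity = 1)
    scaffold <- c(sc = rand_dna(1100000L))
    sp <- splitScaffolds(scaffold, cen, tel)
    expect_identical(nrow(sp$report), 2L)
    expect_identical(sp$report$reason, c("telomere", "telomere"))
    expect_identical(sort(sp$report$cut_after),
                     c(779000L + 209L, 980000L - 1L))
    expect_length(sp$sequences, 3L)
    expect_identical(paste(as.character(sp$sequences), collapse = ""),
                     unname(scaffold))
})

test_that("single-centromere scaffolds pass through unchanged", {
    set.seed(8)
    scaffold <- c(sc = rand_dna(10000L))
    cen <- GenomicRanges::GRanges("sc", IRanges::IRanges(4000L, 4500L),
                                  copy_count = 1L)
    sp <- splitScaffolds(scaffold, cen,
        GenomicRanges::GRanges(character(), IRanges::IRanges()))
    expect_identical(names(sp$sequences), "sc")
    expect_identical(nrow(sp$report), 0L)
})

test_that("without internal telomeres the cut falls in the largest N gap", {
    set.seed(9)
    scaffold <- c(sc = paste0(rand_dna(4000L), strrep("N", 50L),
                              rand_dna(2000L), strrep("N", 200L),
                              rand_dna(4000L)))
    cen <- GenomicRanges::GRanges("sc", IRanges::IRanges(c(1000L, 9000L),
        width = 500L), copy_count = 1L)
    sp <- splitScaffolds(scaffold, cen,
        GenomicRanges::GRanges(character(), IRanges::IRanges()))
    expect_identical(sp$report$reason, "gap")
    cut <- sp$report$cut_after
    expect_gte(cut, 4000L + 50L + 2000L)          # inside the 200-N run
    expect_lte(cut, 4000L + 50L + 2000L + 200L)
    expect_length(sp$sequences, 2L)
})

test_that("a pair with no telomere and no gap is flagged unresolved", {
    set.seed(10)
    scaffold <- c(sc = rand_dna(20000L))
    cen <- GenomicRanges::GRanges("sc", IRanges::IRanges(c(1000L, 15000L),
        width = 500L), copy_count = 1L)
    sp <- splitScaffolds(scaffold, cen,
        GenomicRanges::GRanges(character(), IRanges::IRanges()))
    expect_identical(sp$report$reason, "unresolved")
    expect_identical(names(sp$sequences), "sc")
    expect_error(splitScaffolds(scaffold,
        GenomicRanges::GRanges("nope", IRanges::IRanges(1, 10)),
        GenomicRanges::GRanges(character(), IRanges::IRanges())), "unknown")
})

test_that("curation on generated scaffolds recovers truth and de-fuses", {
    for (seed in c(21L, 22L)) {
        ss <- simScaffolds(seed = seed)
        tel <- scanTelomeres(ss$sequences)
        cen <- scanCentromeres(ss$sequences)
        reg <- mergeCentromericHits(cen)
        # every planted feature recovered with >= 90% overlap
        truth_tel <- ss$truth[ss$truth$kind == "telomere"]
        ov <- GenomicRanges::findOverlaps(truth_tel, tel)
        expect_identical(length(unique(S4Vectors::queryHits(ov))),
                         length(truth_tel))
        for (i in seq_along(truth_tel)) {
            j <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i][1L]
            inter <- GenomicRanges::pintersect(truth_tel[i], tel[j])
            expect_gte(GenomicRanges::width(inter) /
                       GenomicRanges::width(truth_tel[i]), 0.9)
        }
        truth_reg <- ss$truth[ss$truth$kind == "centromere_region"]
        expect_identical(length(reg), length(truth_reg))
        ovr <- GenomicRanges::findOverlaps(truth_reg, reg)
        expect_identical(length(unique(S4Vectors::queryHits(ovr))),
                         length(truth_reg))
        # splitting conserves sequence and leaves <= 1 region per scaffold
        sp <- splitScaffolds(ss$sequences, reg, tel)
        for (nm in names(ss$sequences)) {
            pieces <- sp$sequences[grep(paste0("^", nm, "($|\\.)"),
                                        names(sp$sequences))]
            expect_identical(paste(as.character(pieces), collapse = ""),
                             as.character(ss$sequences[[nm]]))
        }
        reg2 <- mergeCentromericHits(scanCentromeres(sp$sequences))
        expect_lte(max(table(as.character(GenomicRanges::seqnames(reg2)))), 1L)
    }
})

test_that("merge count equals the planted cluster count across many seeds", {
    # layouts drawn directly at the hit level: clusters of 1-4 copies with
    # intra-cluster gaps far below and inter-cluster gaps far above the
    # merge distance
    set.seed(33)
    for (i in 1:100) {
        k <- sample(1:8, 1L)
        gaps <- integer(0)
        for (cl in seq_len(k)) {
            copies <- sample(1:4, 1L)
            gaps <- c(gaps, sample(1000:200000, copies - 1L, TRUE),
                      if (cl < k) sample(250000:900000, 1L))
        }
        got <- mergeCentromericHits(layout_hits(gaps), 250000)
        expect_length(got, k)
    }
})

test_that("arm classification keys on terminal telomeres within a window", {
    set.seed(12)
    scaffolds <- c(a = rand_dna(10000L), b = rand_dna(10000L))
    reg <- GenomicRanges::GRanges(c("a", "b"),
        IRanges::IRanges(c(5000L, 5000L), width = 300L), copy_count = 1L)
    tel <- GenomicRanges::GRanges(c("a", "b"), IRanges::IRanges(
        c(9800L, 6000L), width = 150L), strand = "-", kind = "telomere",
        identity = 1)
    cls <- classifyArms(scaffolds, reg, tel, end_window = 1000L)
    expect_identical(cls$class[cls$scaffold == "a"], "arm_with_telomere_end")
    expect_identical(cls$class[cls$scaffold == "b"], "centromeric_no_telomere")
})

test_that("N50 and NG50 follow their cumulative definitions", {
    lens <- c(10L, 9L, 8L, 7L, 6L)
    scaffolds <- stats::setNames(strrep("A", lens), paste0("s", 1:5))
    st <- assemblyStats(scaffolds, fixed_genome_size = 60)
    expect_identical(st$scaffold_n50, 8L)
    expect_identical(st$scaffold_ng50, 7L)
    expect_identical(st$total_bp, 40)
    one <- assemblyStats(c(s = strrep("A", 123L)))
    expect_identical(one$scaffold_n50, 123L)
    expect_error(assemblyStats(scaffolds, fixed_genome_size = -1), "positive")
})

test_that("contigs are scaffold pieces between long N runs", {
    sc <- c(s = paste0(strrep("A", 100L), strrep("N", 10L), strrep("C", 50L),
                       strrep("N", 9L), strrep("G", 30L)))
    st <- assemblyStats(sc, contig_gap_min = 10L)
    expect_identical(st$n_contigs, 2L)      # the 9-N run does not break
    expect_identical(st$n_scaffolds, 1L)
    expect_identical(st$contig_n50, 100L)
})

test_that("repeat span ratio reproduces the larger:smaller quotient", {
    r <- repeatSpanRatio(c(Copia = 2.06e9, Gypsy = 5.94e9))
    expect_equal(round(r$ratio, 2), 2.88)
    gr <- GenomicRanges::GRanges("s", IRanges::IRanges(
        c(1, 2001, 5001), width = c(1000, 2000, 1500)),
        class = c("Copia", "Gypsy", "Copia"))
    r2 <- repeatSpanRatio(gr)
    expect_equal(unname(r2$spans), c(2500, 2000))
    expect_equal(r2$ratio, 1.25)
})
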