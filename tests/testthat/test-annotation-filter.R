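# minimal constructor for hand-built models
mk_models <- function(df, exons, cds = exons) {
    GeneModelSet(df, IRanges::IRangesList(exons), IRanges::IRangesList(cds))
}

ok_prot <- function(n = 100L) paste0("M", strrep("A", n - 2L), "*")

test_that("structural filter enforces ORF, CDS and feature-length rules", {
    df <- data.frame(
        id = c("good", "short_intron", "short_cds", "no_stop",
               "internal_stop", "no_cds", "tiny_exon"),
        scaffold = "s", strand = "+",
        protein = c(ok_prot(100), ok_prot(100), ok_prot(33),
                    paste0("M", strrep("A", 99)),
                    paste0("M", strrep("A", 40), "*", strrep("A", 58), "*"),
                    ok_prot(50), ok_prot(100)))
    exons <- list(
        good = IRanges::IRanges(c(1, 200), width = c(150, 150)),
        short_intron = IRanges::IRanges(c(1, 159), width = c(150, 150)),
        short_cds = IRanges::IRanges(1, width = 99),
        no_stop = IRanges::IRanges(1, width = 300),
        internal_stop = IRanges::IRanges(1, width = 300),
        no_cds = IRanges::IRanges(1, width = 300),
        tiny_exon = IRanges::IRanges(c(1, 100), width = c(8, 292)))
    cds <- exons
    cds$no_cds <- IRanges::IRanges()
    out <- structuralFilter(mk_models(df, exons, cds))
    rep <- out$report
    expect_identical(geneInfo(out$passing)$id, "good")
    expect_identical(rep$reason[rep$id == "short_intron"], "intron_lt_9")
    expect_identical(rep$reason[rep$id == "short_cds"], "cds_lt_100")
    expect_identical(rep$reason[rep$id == "no_stop"], "no_stop")
    expect_identical(rep$reason[rep$id == "internal_stop"], "internal_stop")
    expect_identical(rep$reason[rep$id == "no_cds"], "no_cds")
    expect_identical(rep$reason[rep$id == "tiny_exon"], "exon_lt_9")
    expect_identical(sum(rep$removed) + length(out$passing), nrow(rep))
})

test_that("one kind of functional evidence suffices to retain a model", {
    df <- data.frame(id = paste0("g", 1:4), scaffold = "s", strand = "+",
        protein = ok_prot(100),
        has_similarity_hit = c(FALSE, TRUE, FALSE, FALSE),
        domain_count = c(0L, 0L, 1L, 0L),
        has_family_assignment = c(FALSE, FALSE, FALSE, TRUE))
    ex <- lapply(1:4, function(i) IRanges::IRanges(1, 300))
    out <- functionalFilter(mk_models(df, ex))
    expect_identical(geneInfo(out$passing)$id, c("g2", "g3", "g4"))
    expect_identical(out$report$reason[out$report$id == "g1"], "no_evidence")
})

test_that("retroelement removal needs flag AND mask, boundary inclusive", {
    df <- data.frame(id = paste0("g", 1:4), scaffold = "s", strand = "+",
        protein = ok_prot(100),
        softmask_fraction = c(0.70, 0.69, 0.95, 0.70),
        retro_domain_flag = c(TRUE, TRUE, FALSE, FALSE))
    ex <- lapply(1:4, function(i) IRanges::IRanges(1, 300))
    out <- retroelementFilter(mk_models(df, ex))
    expect_identical(geneInfo(out$passing)$id, c("g2", "g3", "g4"))
})

test_that("mono-exonic filter removes near-copies above both thresholds", {
    base <- ok_prot(102)                      # 100 informative residues
    ch <- strsplit(base, "")[[1L]]
    mut <- function(k) {                       # k scattered internal changes
        x <- ch
        x[unique(round(seq(5, 95, length.out = k)))] <-
            rep(c("W", "Y"), length.out = k)
        paste(x, collapse = "")
    }
    df <- data.frame(
        id = c("multi", "copy80", "copy74", "unique"),
        scaffold = "s", strand = "+",
        protein = c(base, mut(15L), mut(30L), paste0("M", strrep("H", 90), "*")),
        has_similarity_hit = TRUE)
    exons <- list(
        multi = IRanges::IRanges(c(1, 400), width = c(150, 156)),
        copy80 = IRanges::IRanges(1, width = 306),
        copy74 = IRanges::IRanges(1, width = 306),
        unique = IRanges::IRanges(1, width = 276))
    out <- monoexonicFilter(mk_models(df, exons))
    expect_setequal(geneInfo(out$passing)$id, c("multi", "copy74", "unique"))
    h <- out$hits
    expect_gte(h$identity[h$id == "copy80"], 0.75)
    expect_lt(h$identity[h$id == "copy74"], 0.75)
})

test_that("with no multi-exonic proteins all mono-exonics are retained", {
    df <- data.frame(id = "m1", scaffold = "s", strand = "+",
                     protein = ok_prot(60))
    ex <- list(m1 = IRanges::IRanges(1, 180))
    expect_warning(out <- monoexonicFilter(mk_models(df, ex)), "retained")
    expect_length(out$passing, 1L)
})

test_that("alignment evidence thresholds are inclusive on both axes", {
    rec <- data.frame(id = paste0("t", 1:4),
        identity = c(0.96, 0.94, 0.95, 0.99),
        coverage = c(0.97, 0.99, 0.95, 0.94))
    out <- alignmentEvidenceFilter(rec)
    expect_identical(out$id, c("t1", "t3"))
})

test_that("overlap resolution keeps transcriptome models on shared strand", {
    mk <- function(ids, starts, strands, src) {
        df <- data.frame(id = ids, scaffold = "s", strand = strands,
                         protein = ok_prot(100), source = src)
        ex <- lapply(starts, function(s) IRanges::IRanges(s, width = 300))
        names(ex) <- ids
        mk_models(df, ex)
    }
    pred <- mk(c("p1", "p2", "p3"), c(1, 1000, 5000), c("+", "-", "+"),
               "prediction")
    tx <- mk(c("t1", "t2"), c(1, 1000), c("+", "+"), "transcriptome")
    out <- resolveOverlaps(pred, tx)
    ids <- geneInfo(out$merged)$id
    expect_setequal(ids, c("p2", "p3", "t1", "t2"))  # p1 lost to t1
    expect_identical(out$n_dropped, 1L)
    src <- geneInfo(out$merged)$source
    expect_identical(src[match("t1", ids)], "transcriptome")
})

test_that("pipeline counts reconcile at every stage on generated data", {
    gm <- simGeneModels(seed = 14L)
    res <- filterAnnotation(gm$models)
    expect_true(all(res$counts$input ==
                    res$counts$removed + res$counts$retained))
    # stage inputs chain: next stage sees the previous stage's survivors
    expect_identical(res$counts$input[-1L],
                     res$counts$retained[-nrow(res$counts)])
})

test_that("filters recover every planted truth class exactly", {
    for (seed in c(1L, 2L)) {
        gm <- simGeneModels(seed = seed)
        res <- filterAnnotation(gm$models)
        surv <- geneInfo(res$passing)$id
        tr <- gm$truth
        expect_setequal(surv, tr$id[tr$class == "valid"])
    }
})

test_that("disjoint-reason filters give the same survivors in any order", {
    gm <- simGeneModels(seed = 3L, n_pseudo = 0L)
    filters <- list(
        s = function(m) structuralFilter(m)$passing,
        f = function(m) functionalFilter(m)$passing,
        r = function(m) retroelementFilter(m)$passing)
    orders <- list(c("s","f","r"), c("s","r","f"), c("f","s","r"),
                   c("f","r","s"), c("r","s","f"), c("r","f","s"))
    results <- lapply(orders, function(o) {
        m <- gm$models
        for (k in o) m <- filters[[k]](m)
        sort(geneInfo(m)$id)
    })
    for (i in 2:6) expect_identical(results[[i]], results[[1L]])
})

test_that("a planted 0.80-identity full-coverage pseudogene is removed, a
           lower-identity copy survives", {
    gm_lo <- simGeneModels(seed = 5L, pseudo_identity = 0.60)
    out <- monoexonicFilter(structuralFilter(gm_lo$models)$passing)
    pseudo <- gm_lo$truth$id[gm_lo$truth$class == "pseudogene"]
    expect_true(all(pseudo %in% geneInfo(out$passing)$id))
    gm_hi <- simGeneModels(seed = 5L, pseudo_identity = 0.90)
    out2 <- monoexonicFilter(structuralFilter(gm_hi$models)$passing)
    pseudo2 <- gm_hi$truth$id[gm_hi$truth$class == "pseudogene"]
    expect_false(any(pseudo2 %in% geneInfo(out2$passing)$id))
})
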