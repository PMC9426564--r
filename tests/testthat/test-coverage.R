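tsv_alignments <- function(df, sample_id = "s1") {
    p <- tempfile(fileext = ".tsv")
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    loadAlignments(p, sampleId = sample_id)
}

test_that("SAM records normalize to 0-based half-open intervals", {
    sam <- withr::local_tempfile(fileext = ".sam")
    write_sam(sam, c(c1 = 2000L),
              c(sam_record("r1", 0, "c1", 1, 60, "100M"),
                sam_record("r2", 256, "c1", 11, 60, "50M"),
                sam_record("r3", 0, "c1", 21, 2, "10M20D10M"),
                sam_record("r4", 4, "c1", 0, 0, "*")))
    al <- loadAlignments(sam, sampleId = "s1")
    expect_equal(al$start[al$query_id == "r1"], 0L)
    expect_equal(al$end[al$query_id == "r1"], 100L)
    ## secondary dropped by default, unmapped always dropped
    expect_false("r2" %in% al$query_id)
    expect_false("r4" %in% al$query_id)
    ## deletions extend the reference span, insertions would not
    expect_equal(al$end[al$query_id == "r3"] - al$start[al$query_id == "r3"],
                 40L)
    al2 <- loadAlignments(sam, sampleId = "s1", primaryOnly = FALSE)
    expect_true("r2" %in% al2$query_id)
    al3 <- loadAlignments(sam, sampleId = "s1", mapqMin = 10)
    expect_false("r3" %in% al3$query_id)
})

test_that("TSV alignments equal the intervals from equivalent SAM", {
    sam <- withr::local_tempfile(fileext = ".sam")
    write_sam(sam, c(c1 = 2000L),
              sam_record("r1", 0, "c1", 101, 60, "75M"))
    from_sam <- loadAlignments(sam, sampleId = "s1")
    from_tsv <- tsv_alignments(data.frame(query_id = "r1", target_id = "c1",
                                          start = 100, end = 175))
    cols <- c("query_id", "target_id", "start", "end", "sample_id")
    expect_equal(from_sam[, cols], from_tsv[, cols])
})

test_that("depth table matches the per-base oracle on a worked case", {
    al <- tsv_alignments(data.frame(query_id = "r1", target_id = "c1",
                                    start = 0, end = 50))
    tab <- contigDepthTable(al, c(c1 = 2000L))
    v <- oracle_coverage_vector(0, 50, 2000)
    expect_equal(meanDepths(tab)["c1", "s1"], 50 / 2000)
    expect_equal(meanDepths(tab)["c1", "s1"], mean(v))
    expect_equal(depthVariances(tab)["c1", "s1"], pop_var(v),
                 tolerance = 1e-12)
})

test_that("contigs below the 1500-nt floor are excluded, empty ones kept", {
    al <- tsv_alignments(data.frame(query_id = c("r1", "r2"),
                                    target_id = c("short", "long"),
                                    start = c(0, 0), end = c(100, 100)))
    tab <- contigDepthTable(al, c(short = 1000L, long = 2000L,
                                  untouched = 1800L))
    expect_setequal(contigInfo(tab)$contig_id, c("long", "untouched"))
    expect_equal(meanDepths(tab)["untouched", "s1"], 0)
    expect_equal(depthVariances(tab)["untouched", "s1"], 0)
})

test_that("alignments beyond the target length are rejected by name", {
    al <- tsv_alignments(data.frame(query_id = "r1", target_id = "c9",
                                    start = 0, end = 3000))
    expect_error(contigDepthTable(al, c(c9 = 2000L)), "c9")
})

test_that("depth and breadth agree with the per-base oracle on random data", {
    withr::with_seed(55, {
        lens <- setNames(sample(1500:4000, 20), sprintf("c%02d", 1:20))
        rows <- do.call(rbind, lapply(1:400, function(i) {
            ct <- sample(names(lens), 1)
            st <- sample(0:(lens[[ct]] - 60), 1)
            data.frame(query_id = sprintf("r%03d", i), target_id = ct,
                       start = st, end = st + sample(30:60, 1))
        }))
        sams <- sample(c("sA", "sB", "sC"), 400, replace = TRUE)
    })
    al <- do.call(rbind, lapply(unique(sams), function(s)
        tsv_alignments(rows[sams == s, ], sample_id = s)))
    tab <- contigDepthTable(al, lens, sampleIds = c("sA", "sB", "sC"),
                            minContigLen = 1500L)
    cov <- genomeCoverage(al, lens,
                          readsPerSample = c(sA = 500, sB = 500, sC = 500))
    for (ct in names(lens)) for (s in c("sA", "sB", "sC")) {
        sub <- al[al$target_id == ct & al$sample_id == s, ]
        v <- oracle_coverage_vector(sub$start, sub$end, lens[[ct]])
        expect_equal(meanDepths(tab)[ct, s], mean(v), tolerance = 1e-9)
        expect_equal(depthVariances(tab)[ct, s], pop_var(v),
                     tolerance = 1e-9)
        i <- cov$genome_id == ct & cov$sample_id == s
        expect_equal(cov$breadth[i], mean(v >= 1), tolerance = 1e-9)
        expect_equal(cov$mean_depth[i], mean(v), tolerance = 1e-9)
        expect_equal(cov$mapped_read_fraction[i],
                     length(unique(sub$query_id)) / 500)
    }
})

test_that("breadth counts overlapping coverage once", {
    al <- tsv_alignments(data.frame(query_id = c("r1", "r2"),
                                    target_id = "g1",
                                    start = c(0, 50), end = c(100, 150)))
    cov <- genomeCoverage(al, c(g1 = 300), readsPerSample = c(s1 = 10))
    expect_equal(cov$breadth, 150 / 300)
    ## full tiling reaches breadth 1; absent genomes report zeros
    al2 <- tsv_alignments(data.frame(query_id = "r1", target_id = "g1",
                                     start = 0, end = 300))
    cov2 <- genomeCoverage(al2, c(g1 = 300, g2 = 500),
                           readsPerSample = c(s1 = 10))
    expect_equal(cov2$breadth[cov2$genome_id == "g1"], 1)
    g2 <- cov2[cov2$genome_id == "g2", ]
    expect_equal(unlist(g2[, c("breadth", "mean_depth",
                               "mapped_read_fraction")]),
                 c(breadth = 0, mean_depth = 0, mapped_read_fraction = 0))
})

test_that("duplicate alignments of one read add depth but not recruitment", {
    al <- tsv_alignments(data.frame(query_id = c("r1", "r1"),
                                    target_id = "g1",
                                    start = c(0, 100), end = c(50, 150)))
    cov <- genomeCoverage(al, c(g1 = 1000), readsPerSample = c(s1 = 100))
    expect_equal(cov$mapped_read_fraction, 1 / 100)
    expect_equal(cov$mean_depth, 100 / 1000)
})

test_that("genomes split over contigs aggregate through contigMap", {
    al <- tsv_alignments(data.frame(query_id = c("r1", "r2"),
                                    target_id = c("ct1", "ct2"),
                                    start = c(0, 0), end = c(100, 200)))
    cov <- genomeCoverage(al, c(gA = 1000),
                          readsPerSample = c(s1 = 50),
                          contigMap = c(ct1 = "gA", ct2 = "gA"),
                          contigLengths = c(ct1 = 400, ct2 = 600))
    expect_equal(cov$breadth, 300 / 1000)
    expect_equal(cov$mapped_read_fraction, 2 / 50)
})

test_that("breadth is monotone as alignments accumulate", {
    withr::with_seed(66, {
        st <- sample(0:900, 30)
        b_prev <- 0
        for (m in c(5, 10, 20, 30)) {
            al <- tsv_alignments(data.frame(
                query_id = sprintf("r%d", 1:m), target_id = "g",
                start = st[1:m], end = st[1:m] + 50))
            b <- genomeCoverage(al, c(g = 1000),
                                readsPerSample = c(s1 = 30))$breadth
            expect_gte(b, b_prev)
            b_prev <- b
        }
    })
})

test_that("splitting a sample's alignments and merging equals one pass", {
    withr::with_seed(67, {
        rows <- data.frame(query_id = sprintf("r%d", 1:50),
                           target_id = "c1",
                           start = sample(0:1900, 50))
        rows$end <- rows$start + 50
    })
    whole <- tsv_alignments(rows)
    halves <- rbind(tsv_alignments(rows[1:25, ]),
                    tsv_alignments(rows[26:50, ]))
    t1 <- contigDepthTable(whole, c(c1 = 2000L))
    t2 <- contigDepthTable(halves, c(c1 = 2000L))
    expect_equal(meanDepths(t1), meanDepths(t2))
    expect_equal(depthVariances(t1), depthVariances(t2))
})

test_that("detection uses an inclusive 0.3 breadth threshold", {
    expect_false(detectGenome(0.29))
    expect_true(detectGenome(0.30))
    expect_true(detectGenome(0.31))
    expect_equal(detectGenome(c(0.1, 0.5), breadthMin = 0.4),
                 c(FALSE, TRUE))
})

test_that("prevalence and cumulative abundance follow their definitions", {
    cov <- data.frame(genome_id = rep("g1", 5),
                      sample_id = paste0("s", 1:5),
                      breadth = c(0.5, 0.31, 0.35, 0.1, 0.0),
                      mean_depth = 1,
                      mapped_read_fraction = c(0.02, 0.01, 0, 0, 0))
    pa <- prevalenceAbundance(cov, c(g1 = 2e6))
    expect_equal(pa$prevalence, 3L)
    expect_equal(pa$cumulative_abundance, (2 + 1) / 2e6)
    none <- cov; none$breadth <- 0; none$mapped_read_fraction <- 0
    pa0 <- prevalenceAbundance(none, c(g1 = 2e6))
    expect_equal(pa0$prevalence, 0L)
    expect_equal(pa0$cumulative_abundance, 0)
})
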