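test_that("genome generation is seeded and hits its GC target", {
    g1 <- generateGenome(2e4, gc = 0.6, seed = 5)
    g2 <- generateGenome(2e4, gc = 0.6, seed = 5)
    expect_identical(as.character(g1), as.character(g2))

    big <- generateGenome(1e5, gc = 0.6, seed = 6)
    f <- Biostrings::letterFrequency(big, c("G", "C"))
    gc <- sum(f) / 1e5
    expect_gt(gc, 0.59); expect_lt(gc, 0.61)   # 4 sigma of binomial
})

test_that("different GC genomes have distinguishable tetranucleotides", {
    a <- generateGenome(5e4, gc = 0.5, seed = 7)
    b <- generateGenome(5e4, gc = 0.3, seed = 8)
    fa <- Biostrings::oligonucleotideFrequency(a, 4)[1, ]
    fb <- Biostrings::oligonucleotideFrequency(b, 4)[1, ]
    p <- suppressWarnings(chisq.test(rbind(fa, fb))$p.value)
    expect_lt(p, 0.01)
})

test_that("mutation bookkeeping is exact", {
    g <- generateGenome(1e5, seed = 9)
    expect_identical(as.character(mutateGenome(g, 0, seed = 10)),
                     as.character(g))
    m <- mutateGenome(g, 0.02, seed = 11)
    nsub <- S4Vectors::metadata(m)$n_substitutions
    expect_gt(nsub, 1800); expect_lt(nsub, 2200)  # 4 sigma of Binomial
    ham <- Biostrings::neditAt(m[[1]], g[[1]])
    expect_equal(ham, nsub)
    expect_equal(S4Vectors::metadata(m)$realized_rate, nsub / 1e5)
})

test_that("abundance draws are normalized log-normals", {
    a <- sampleAbundances(50, seed = 12)
    expect_equal(sum(a), 1, tolerance = 1e-12)
    expect_equal(sampleAbundances(1, seed = 13), 1)
})

test_that("error-free reads are exact genome substrings", {
    g <- generateGenome(2e4, seed = 14)
    sim <- simulateReads(g, 1, nReads = 100, readLength = 80,
                         errorRate = 0, seed = 15)
    gplus <- as.character(g)
    gminus <- as.character(Biostrings::reverseComplement(g))
    for (r in sim$reads[1:50])
        expect_true(grepl(r, gplus, fixed = TRUE) ||
                    grepl(r, gminus, fixed = TRUE))
})

test_that("read origins follow abundance x length weights", {
    gs <- c(as.character(generateGenome(2e4, seed = 16, id = "gA")),
            as.character(generateGenome(2e4, seed = 17, id = "gB")))
    names(gs) <- c("gA", "gB")
    sim <- simulateReads(gs, c(0.9, 0.1), nReads = 10000, readLength = 60,
                         errorRate = 0, seed = 18)
    nA <- sum(sim$truth$genome_id == "gA")
    ## Binomial(1e4, 0.9): 4 sigma = 120
    expect_gt(nA, 8880); expect_lt(nA, 9120)
})

test_that("read simulation is byte-deterministic under a seed", {
    g <- generateGenome(2e4, seed = 19)
    s1 <- simulateReads(g, 1, 500, 70, errorRate = 0.01, seed = 20)
    s2 <- simulateReads(g, 1, 500, 70, errorRate = 0.01, seed = 20)
    expect_identical(s1$reads, s2$reads)
    expect_identical(s1$truth, s2$truth)
    expect_error(simulateReads(g, 1, 10, 30000, seed = 1), "read_length")
})

small_spec <- function(...) {
    args <- utils::modifyList(
        list(nGenomes = 6L, genomeLength = 20000L, nSamples = 6L,
             nGroups = 2L, readsPerSample = 500L, readLength = 100L),
        list(...))
    do.call(communitySpec, args)
}

test_that("clustered datasets are deterministic given spec and seed", {
    d1 <- generateClusteredDataset(small_spec(seed = 21))
    d2 <- generateClusteredDataset(small_spec(seed = 21))
    expect_identical(as.character(d1$genomes), as.character(d2$genomes))
    expect_identical(d1$samples, d2$samples)
    expect_identical(genomeAbundances(d1$truth), genomeAbundances(d2$truth))
    d3 <- generateClusteredDataset(small_spec(seed = 22))
    expect_false(identical(d1$samples, d3$samples))
})

test_that("planted truth is internally consistent", {
    ds <- generateClusteredDataset(small_spec(seed = 23))
    ab <- genomeAbundances(ds$truth)
    expect_equal(unname(rowSums(ab)), rep(1, 6), tolerance = 1e-9)
    grp <- sampleGroups(ds$truth)
    expect_length(grp, 6)
    ## samples only draw genomes from their own group's pool
    for (s in names(grp)) {
        drawn <- colnames(ab)[ab[s, ] > 0]
        expect_true(all(ds$pool[drawn] %in% c(0L, grp[[s]])))
    }
    ## read origins never cross pools either
    for (s in names(grp))
        expect_true(all(ds$pool[readOrigin(ds$truth)[[s]]] %in%
                        c(0L, grp[[s]])))
})

test_that("written datasets round-trip through the manifest", {
    dirp <- withr::local_tempdir()
    ds <- generateClusteredDataset(small_spec(seed = 24), dir = dirp)
    expect_true(all(file.exists(file.path(dirp,
        c("genomes.fasta", "manifest.tsv", "truth_groups.tsv",
          "truth_abundances.tsv", paste0(names(ds$samples), ".fastq.gz"))))))
    man <- readSampleManifest(file.path(dirp, "manifest.tsv"))
    reads <- readSequences(man$path_r1[1])
    expect_identical(unname(as.character(reads)),
                     unname(ds$samples[[man$sample_id[1]]]))
})

test_that("a single planted group leaves no cluster structure", {
    ds <- generateClusteredDataset(small_spec(nGroups = 1L, seed = 25))
    dm <- pairwiseDistances(ds$samples, k = 15)
    off <- as.matrix(dm)[upper.tri(as.matrix(dm))]
    ## distances vary by sampling noise only: narrow spread, no gap
    expect_lt(diff(range(off)), 0.35)
})

test_that("FASTQ written by the generator round-trips", {
    p <- withr::local_tempfile(fileext = ".fastq.gz")
    reads <- c(r1 = "ACGTACGT", r2 = "GGGTTTAA")
    writeFastq(reads, p)
    back <- readSequences(p)
    expect_identical(as.character(back), reads)
})
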