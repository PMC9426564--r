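make_profile <- function(counts, sample_id = "p", k = 2L) {
    new("KmerProfile", sampleId = sample_id, k = k,
        counts = counts, total = sum(counts))
}

test_that("countKmers handles palindromes, homopolymers and N windows", {
    expect_equal(kmerCounts(countKmers("ACGT", k = 4)), c(ACGT = 1))
    expect_equal(kmerCounts(countKmers("AAAA", k = 2)), c(AA = 3))
    ## windows AC and GT; canonical(GT) = min(GT, AC) = AC
    expect_equal(kmerCounts(countKmers("ACNGT", k = 2)), c(AC = 2))
})

test_that("countKmers agrees with the brute-force window oracle", {
    withr::with_seed(11, {
        for (rep in 1:25) {
            n <- sample(20:300, 1)
            s <- paste(sample(c("A", "C", "G", "T", "N"), n, TRUE,
                              prob = c(.24, .24, .24, .24, .04)),
                       collapse = "")
            for (k in c(3, 11)) {
                got <- kmerCounts(countKmers(s, k = k))
                want <- oracle_count_kmers(s, k)
                expect_equal(got, want[order(names(want))])
            }
        }
    })
})

test_that("minAbundance filters before totalling", {
    p <- countKmers(c("AAAAA", "ACGTT"), k = 4, minAbundance = 2)
    expect_equal(kmerCounts(p), c(AAAA = 2))
    expect_equal(profileTotal(p), 2)
})

test_that("k longer than every read warns and yields an empty profile", {
    expect_warning(p <- countKmers("ACG", k = 8), "exceeds every read length")
    expect_length(kmerCounts(p), 0)
})

test_that("AB-Jaccard matches hand computations and conventions", {
    p <- make_profile(c(AA = 2, AC = 1))
    q <- make_profile(c(AA = 1, AG = 1))
    expect_equal(abJaccardDistance(p, q), 0.75)  # 1 - 1/4
    expect_equal(abJaccardDistance(p, p), 0)
    disj <- make_profile(c(CC = 3))
    expect_equal(abJaccardDistance(p, disj), 1)
    empty <- make_profile(setNames(numeric(), character()))
    expect_equal(abJaccardDistance(empty, empty), 0)
})

test_that("Bray-Curtis matches hand computations", {
    p <- make_profile(c(AA = 2, AC = 1))
    q <- make_profile(c(AA = 1, AG = 1))
    expect_equal(brayCurtisDistance(p, q), 1 - 2 * 1 / 5)
    expect_equal(brayCurtisDistance(p, p), 0)
    expect_equal(brayCurtisDistance(p, make_profile(c(CC = 1))), 1)
})

test_that("mismatched k is a usage error", {
    p <- make_profile(c(AA = 1), k = 2L)
    q <- new("KmerProfile", sampleId = "q", k = 3L,
             counts = c(AAA = 1), total = 1)
    expect_error(abJaccardDistance(p, q), "different k")
    expect_error(brayCurtisDistance(p, q), "different k")
})

test_that("AB-Jaccard is a metric on random profiles", {
    profiles <- lapply(1:30, random_profile)
    withr::with_seed(99, {
        for (rep in 1:60) {
            idx <- sample(30, 3)
            x <- profiles[[idx[1]]]; y <- profiles[[idx[2]]]
            z <- profiles[[idx[3]]]
            dxy <- abJaccardDistance(x, y)
            expect_equal(dxy, abJaccardDistance(y, x), tolerance = 1e-15)
            expect_equal(abJaccardDistance(x, x), 0)
            expect_lte(dxy,
                       abJaccardDistance(x, z) + abJaccardDistance(z, y) +
                           1e-12)
            bc <- brayCurtisDistance(x, y)
            expect_true(bc >= 0 && bc <= 1)
            expect_equal(bc, brayCurtisDistance(y, x), tolerance = 1e-15)
        }
    })
})

test_that("the matrix path agrees with scalar distances pair by pair", {
    withr::with_seed(5, {
        reads <- lapply(1:4, function(i)
            vapply(1:30, function(j) random_dna(70), character(1)))
        names(reads) <- paste0("s", 1:4)
    })
    for (metric in c("ab_jaccard", "bray_curtis")) {
        dm <- pairwiseDistances(reads, k = 13, metric = metric)
        profs <- lapply(names(reads), function(s)
            countKmers(reads[[s]], k = 13, sampleId = s))
        scalar_fun <- if (metric == "ab_jaccard") abJaccardDistance else
            brayCurtisDistance
        m <- as.matrix(dm)
        for (i in 1:3) for (j in (i + 1):4)
            expect_equal(m[i, j], scalar_fun(profs[[i]], profs[[j]]),
                         tolerance = 1e-12)
        ## and the KmerProfile-list path gives the same matrix
        dm2 <- pairwiseDistances(profs, metric = metric)
        expect_equal(as.matrix(dm2), m, tolerance = 1e-12)
    }
})

test_that("identical samples sit at distance zero off the diagonal", {
    reads <- vapply(1:20, function(i) random_dna(80), character(1))
    dm <- pairwiseDistances(list(a = reads, b = reads), k = 15)
    expect_equal(as.matrix(dm)["a", "b"], 0)
})

test_that("distances are invariant to read order within a sample", {
    withr::with_seed(21, {
        reads <- vapply(1:50, function(i) random_dna(90), character(1))
        shuf <- sample(reads)
    })
    dm <- pairwiseDistances(list(a = reads, b = shuf, c = reads[1:25]),
                            k = 17)
    expect_equal(as.matrix(dm)["a", "b"], 0)
    expect_equal(as.matrix(dm)["a", "c"], as.matrix(dm)["b", "c"],
                 tolerance = 1e-12)
})

test_that("pairwise distance preconditions are enforced", {
    expect_error(pairwiseDistances(list(a = "ACGT")), "at least 2")
    man <- data.frame(sample_id = c("s1", "s2"),
                      path_r1 = c("missing1.fq", "missing2.fq"),
                      path_r2 = NA_character_)
    expect_error(pairwiseDistances(man, k = 11), "s1")
})

test_that("manifest and in-memory paths agree", {
    dirp <- withr::local_tempdir()
    withr::with_seed(31, {
        reads <- lapply(1:3, function(i)
            setNames(vapply(1:20, function(j) random_dna(60), character(1)),
                     paste0("r", 1:20)))
    })
    names(reads) <- paste0("s", 1:3)
    for (s in names(reads))
        writeFastq(reads[[s]], file.path(dirp, paste0(s, ".fastq")))
    man <- data.frame(sample_id = names(reads),
                      path_r1 = file.path(dirp, paste0(names(reads), ".fastq")),
                      path_r2 = NA_character_)
    expect_equal(as.matrix(pairwiseDistances(man, k = 11)),
                 as.matrix(pairwiseDistances(reads, k = 11)),
                 tolerance = 1e-12)
})
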