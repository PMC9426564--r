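dm_from <- function(m, ids = sprintf("s%d", seq_len(nrow(m)))) {
    new("DistanceMatrix", sampleIds = ids, values = m,
        metric = "ab_jaccard")
}

tri_matrix <- function(dab = 0.1, dac = 0.9, dbc = 0.9) {
    m <- matrix(0, 3, 3)
    m[1, 2] <- m[2, 1] <- dab
    m[1, 3] <- m[3, 1] <- dac
    m[2, 3] <- m[3, 2] <- dbc
    dm_from(m, c("a", "b", "c"))
}

test_that("Ward clustering merges the closest pair first", {
    d2 <- dm_from(matrix(c(0, .4, .4, 0), 2), c("a", "b"))
    dd <- wardCluster(d2)
    expect_equal(nLeaves(dd), 2L)
    expect_equal(nrow(mergeSteps(dd)), 1L)

    dd3 <- wardCluster(tri_matrix())
    ms <- mergeSteps(dd3)
    ## first merge joins leaves 1 and 2 (a, b), the closest pair
    expect_setequal(unlist(ms[1, c("left", "right")]), c(-1, -2))
    expect_equal(ms$size, c(2L, 3L))
})

test_that("the tree is invariant under sample permutation", {
    m <- as.matrix(planted_matrix(c(1, 1, 2, 2, 3, 3), seed = 3))
    perm <- c(4, 2, 6, 1, 3, 5)
    ids <- sprintf("s%02d", 1:6)
    d1 <- dm_from(m, ids)
    d2 <- dm_from(m[perm, perm], ids[perm])
    c1 <- cutDendrogram(wardCluster(d1), 3)
    c2 <- cutDendrogram(wardCluster(d2), 3)
    ## same partition of the same ids, up to label renaming
    expect_equal(mclust::adjustedRandIndex(c1[ids], c2[ids]), 1)
    expect_equal(sort(wardCluster(d1)@hc$height),
                 sort(wardCluster(d2)@hc$height), tolerance = 1e-12)
})

test_that("cutDendrogram spans k = 1 .. n and rejects out-of-range k", {
    dd <- wardCluster(tri_matrix())
    expect_equal(length(unique(cutDendrogram(dd, 1))), 1L)
    expect_equal(length(unique(cutDendrogram(dd, 3))), 3L)
    two <- cutDendrogram(dd, 2)
    expect_equal(two[["a"]], two[["b"]])
    expect_false(two[["a"]] == two[["c"]])
    expect_error(cutDendrogram(dd, 4), "must be in")
    expect_error(cutDendrogram(dd, 0), "must be in")
})

test_that("successive cuts differ by exactly one cluster split", {
    dm <- planted_matrix(rep(1:4, each = 3), seed = 17)
    dd <- wardCluster(dm)
    for (k in 2:11) {
        a <- cutDendrogram(dd, k)
        b <- cutDendrogram(dd, k + 1)
        ## every k+1 cluster lies inside one k cluster, and exactly one
        ## k cluster is split in two
        tab <- table(a, b)
        expect_true(all(colSums(tab > 0) == 1))
        expect_equal(sum(rowSums(tab > 0) == 2), 1)
    }
})

test_that("meanSilhouette evaluates the two-pair worked example exactly", {
    m <- matrix(0.9, 4, 4)
    m[1, 2] <- m[2, 1] <- 0.1
    m[3, 4] <- m[4, 3] <- 0.1
    diag(m) <- 0
    s <- meanSilhouette(dm_from(m), c(1, 1, 2, 2))
    expect_equal(s, (0.9 - 0.1) / 0.9, tolerance = 1e-15)
})

test_that("silhouette conventions: equal distances, singletons, one cluster", {
    m <- matrix(0.5, 4, 4); diag(m) <- 0
    expect_equal(meanSilhouette(dm_from(m), c(1, 1, 2, 2)), 0)

    m2 <- matrix(c(0, .3, .3, 0), 2)
    expect_equal(meanSilhouette(dm_from(m2, c("a", "b")), c(1, 2)), 0)

    expect_error(meanSilhouette(dm_from(m), rep(1, 4)), "single cluster")
})

test_that("meanSilhouette matches independent implementations", {
    withr::with_seed(41, {
        for (n in c(6, 15, 40)) {
            m <- matrix(0, n, n)
            m[upper.tri(m)] <- runif(n * (n - 1) / 2)
            m <- m + t(m)
            dm <- dm_from(m)
            for (k in c(2, 3, min(5, n - 1))) {
                labels <- sample(k, n, replace = TRUE)
                if (length(unique(labels)) < 2) next
                got <- meanSilhouette(dm, labels)
                expect_equal(got, oracle_silhouette(m, labels),
                             tolerance = 1e-12)
                ## cross-check against cluster::silhouette, which uses
                ## the same singleton convention
                sil <- cluster::silhouette(as.integer(factor(labels)),
                                           dmatrix = m)
                expect_equal(got, mean(sil[, "sil_width"]),
                             tolerance = 1e-12)
            }
        }
    })
})

test_that("the silhouette sweep recovers planted partitions", {
    groups <- rep(1:3, each = 4)
    dm <- planted_matrix(groups, seed = 8)
    res <- findOptimalClustering(dm)
    expect_equal(optimalK(res), 3L)
    expect_equal(mclust::adjustedRandIndex(labelsAt(res, 3), groups), 1)
    curve <- silhouetteCurve(res)
    expect_equal(curve$k, 2:11)
    expect_equal(max(curve$mean_silhouette),
                 curve$mean_silhouette[curve$k == 3])
})

test_that("planted partitions beat random partitions of the same size", {
    groups <- rep(1:3, each = 4)
    dm <- planted_matrix(groups, seed = 12)
    s_true <- meanSilhouette(dm, groups)
    withr::with_seed(13, {
        for (i in 1:50) {
            rand <- sample(groups)
            if (identical(rand, groups)) next
            expect_gte(s_true, meanSilhouette(dm, rand))
        }
    })
})

test_that("degenerate sweeps and ties behave as documented", {
    dm <- tri_matrix()
    res <- findOptimalClustering(dm)
    expect_equal(names(res@silhouetteByK), "2")
    expect_equal(optimalK(res), 2L)
    expect_error(findOptimalClustering(dm_from(matrix(0, 2, 2),
                                               c("a", "b"))),
                 "at least 3")
})

test_that("suboptimal-k picks the local maximum nearest the target", {
    mk_res <- function(ks, sil) {
        labelsByK <- lapply(ks, function(k) c(rep(1, 30 - k + 1),
                                              seq_len(k - 1) + 1))
        names(labelsByK) <- as.character(ks)
        names(sil) <- as.character(ks)
        new("ClusteringResult", sampleIds = sprintf("s%02d", 1:30),
            labelsByK = labelsByK, silhouetteByK = sil,
            optimalK = ks[which.max(sil)], suboptimalK = NA_integer_)
    }
    ks <- 2:29
    ## unimodal bumps at k = 11 and k = 24, global max at 24
    sil <- 0.2 - abs(ks - 24) * 0.01
    sil[ks <= 15] <- 0.12 - abs(ks[ks <= 15] - 11) * 0.01
    res <- mk_res(ks, sil)
    expect_equal(optimalK(res), 24L)
    expect_equal(suboptimalK(findSuboptimalClustering(res, 12)), 11L)
    expect_equal(suboptimalK(findSuboptimalClustering(res, 24)), 24L)

    ## monotone decreasing curve: only local maximum is the first point
    res2 <- mk_res(ks, 0.5 - 0.01 * ks)
    expect_equal(suboptimalK(findSuboptimalClustering(res2, 20)), 2L)

    expect_error(findSuboptimalClustering(res, 1), "within the swept range")
})

test_that("plans from labels number groups by first appearance", {
    plan <- planFromLabels(c("s1", "s2", "s3"), c(0, 0, 1), 2)
    expect_equal(sampleGroups(plan),
                 list(`1` = c("s1", "s2"), `2` = "s3"))
    expect_equal(sourceK(plan), 2L)
    one <- planFromLabels(c("a", "b"), c(7, 7), 1)
    expect_equal(lengths(sampleGroups(one)), c(`1` = 2L))
    ## round-trip through the manifest
    p <- withr::local_tempfile(fileext = ".tsv")
    writeCoassemblyManifest(plan, p)
    expect_equal(sampleGroups(readCoassemblyManifest(p)),
                 sampleGroups(plan))
})

test_that("planted distance matrices are recovered across replicates", {
    hits <- 0
    for (seed in 1:20) {
        g <- withr::with_seed(seed, sample(3:8, 1))
        per <- withr::with_seed(seed + 1000, sample(2:5, 1))
        groups <- rep(seq_len(g), each = per)
        dm <- planted_matrix(groups, seed = seed)
        res <- findOptimalClustering(dm)
        ok <- optimalK(res) == g &&
            mclust::adjustedRandIndex(labelsAt(res, optimalK(res)),
                                      groups) == 1
        hits <- hits + ok
    }
    expect_gte(hits, 19)
})
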