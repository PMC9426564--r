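## Ward clustering of the metagenomic distance matrix with a
## silhouette-scored sweep over every cut level, giving the number of
## coassembly sets without prior knowledge.

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering under the Ward criterion applied directly
#' to the given dissimilarities (the "ward.D2" convention: Lance-
#' Williams updates on squared dissimilarities), with no Euclidean
#' embedding. Deterministic given the matrix.
#'
#' @param matrix a \code{\link{DistanceMatrix}}
#' @return a \code{\link{Dendrogram}}
#' @export
wardCluster <- function(matrix) {
    .assert(is(matrix, "DistanceMatrix"), "expected a DistanceMatrix")
    n <- length(matrix@sampleIds)
    .assert(n >= 2, "need at least 2 samples to cluster")
    .assert(!anyNA(matrix@values), "distance matrix contains NA")
    hc <- stats::hclust(stats::as.dist(as.matrix(matrix)), method = "ward.D2")
    new("Dendrogram", hc = hc, nLeaves = n)
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last k-1 merges, yielding exactly k clusters.
#'
#' @param dendro a \code{\link{Dendrogram}}
#' @param k number of clusters, 1..nLeaves
#' @return named integer vector of per-sample labels
#' @export
cutDendrogram <- function(dendro, k) {
    .assert(is(dendro, "Dendrogram"), "expected a Dendrogram")
    k <- as.integer(k)
    .assert(k >= 1 && k <= dendro@nLeaves,
            "k must be in [1, ", dendro@nLeaves, "]")
    stats::cutree(dendro@hc, k = k)
}

#' Mean silhouette score of a partition
#'
#' Per sample i with cluster size > 1, a(i) is the mean distance to its
#' co-members, b(i) the smallest mean distance to any other cluster and
#' s(i) = (b(i) - a(i)) / max(a(i), b(i)); samples in singleton
#' clusters score 0 by convention. Returns the unweighted mean of s(i).
#' Higher is better; the score drives the choice of how many coassembly
#' sets to form.
#'
#' @param matrix a \code{\link{DistanceMatrix}}
#' @param labels per-sample cluster labels (>= 2 distinct values)
#' @return mean silhouette in [-1, 1]
#' @export
meanSilhouette <- function(matrix, labels) {
    .assert(is(matrix, "DistanceMatrix"), "expected a DistanceMatrix")
    d <- matrix@values
    n <- nrow(d)
    .assert(length(labels) == n, "labels must cover all samples")
    labels <- as.integer(factor(labels))
    ncl <- max(labels)
    .assert(ncl >= 2, "silhouette is undefined for a single cluster")
    ## cluster x sample matrix of summed distances
    sums <- rowsum(d, labels)                    # ncl x n
    sizes <- tabulate(labels, nbins = ncl)
    s <- numeric(n)
    for (i in seq_len(n)) {
        ci <- labels[i]
        if (sizes[ci] == 1L) { s[i] <- 0; next }
        a <- sums[ci, i] / (sizes[ci] - 1L)
        b <- min(sums[-ci, i] / sizes[-ci])
        m <- max(a, b)
        s[i] <- if (m > 0) (b - a) / m else 0
    }
    mean(s)
}

#' Silhouette-optimal clustering over all cut levels
#'
#' Builds the Ward dendrogram once, cuts it at every k in
#' [kMin, kMax], scores each cut with \code{\link{meanSilhouette}} and
#' selects the k maximizing the score (smallest k on ties). The whole
#' score curve is retained for reporting and for the suboptimal-k
#' selection.
#'
#' @param matrix a \code{\link{DistanceMatrix}} over n >= 3 samples
#' @param kMin,kMax swept range; defaults 2 and n-1
#' @return a \code{\link{ClusteringResult}}
#' @export
findOptimalClustering <- function(matrix, kMin = 2L, kMax = NULL) {
    .assert(is(matrix, "DistanceMatrix"), "expected a DistanceMatrix")
    n <- length(matrix@sampleIds)
    .assert(n >= 3, "need at least 3 samples (no k in [2, n-1] otherwise)")
    if (is.null(kMax)) kMax <- n - 1L
    kMin <- as.integer(kMin); kMax <- as.integer(kMax)
    .assert(2L <= kMin && kMin <= kMax && kMax <= n - 1L,
            "need 2 <= kMin <= kMax <= n-1")
    dendro <- wardCluster(matrix)
    ks <- kMin:kMax
    labelsByK <- lapply(ks, function(k) unname(cutDendrogram(dendro, k)))
    sil <- vapply(labelsByK, function(lab) meanSilhouette(matrix, lab),
                  numeric(1))
    names(labelsByK) <- names(sil) <- as.character(ks)
    opt <- ks[which.max(sil)]       # which.max returns the first maximum
    new("ClusteringResult", sampleIds = matrix@sampleIds,
        labelsByK = labelsByK, silhouetteByK = sil,
        optimalK = opt, suboptimalK = NA_integer_)
}

#' Pick a suboptimal k near a target cluster count
#'
#' When the silhouette-optimal partition has many more clusters than an
#' external grouping one wants to compare against (e.g. a geography-
#' based partition), a suboptimal solution of comparable size is
#' chosen: among the local maxima of the silhouette curve (score >= its
#' neighbours; endpoints compare one-sided), the k minimizing
#' |k - targetK| is returned, ties broken toward higher silhouette and
#' then smaller k. This selection rule is a documented policy, not a
#' uniquely determined procedure; it can be bypassed by choosing k
#' directly.
#'
#' @param result a \code{\link{ClusteringResult}}
#' @param targetK desired cluster count, within the swept range
#' @return the \code{ClusteringResult} with \code{suboptimalK} set
#' @export
findSuboptimalClustering <- function(result, targetK) {
    .assert(is(result, "ClusteringResult"), "expected a ClusteringResult")
    ks <- as.integer(names(result@silhouetteByK))
    targetK <- as.integer(targetK)
    .assert(targetK >= min(ks) && targetK <= max(ks),
            "targetK must lie within the swept range [", min(ks), ", ",
            max(ks), "]")
    sil <- unname(result@silhouetteByK)
    m <- length(sil)
    left <- c(-Inf, sil[-m])
    right <- c(sil[-1], -Inf)
    local_max <- which(sil >= left & sil >= right)
    cand <- data.frame(k = ks[local_max], sil = sil[local_max])
    cand$dist <- abs(cand$k - targetK)
    cand <- cand[order(cand$dist, -cand$sil, cand$k), ]
    result@suboptimalK <- cand$k[1]
    result
}

#' Build a coassembly plan from cluster labels
#'
#' Groups are numbered 1..k in order of first appearance along the
#' sample list.
#'
#' @param sampleIds ordered sample ids
#' @param labels per-sample cluster labels
#' @param k expected number of groups (checked)
#' @return a \code{\link{CoassemblyPlan}}
#' @export
planFromLabels <- function(sampleIds, labels, k = length(unique(labels))) {
    .assert(length(sampleIds) == length(labels),
            "labels must match sampleIds in length")
    .assert(length(unique(labels)) == k, "labels do not use exactly k groups")
    first_seen <- unique(labels)
    groups <- lapply(first_seen, function(g) sampleIds[labels == g])
    names(groups) <- as.character(seq_along(groups))
    new("CoassemblyPlan", groups = groups, sourceK = as.integer(k))
}

#' Coassembly plan at a chosen cut of a clustering result
#'
#' Convenience wrapper: extracts the labels at \code{k} (default the
#' silhouette-optimal k) and builds the plan.
#'
#' @param result a \code{\link{ClusteringResult}}
#' @param k cut level; defaults to \code{optimalK(result)}
#' @return a \code{\link{CoassemblyPlan}}
#' @export
coassemblyPlan <- function(result, k = optimalK(result)) {
    labs <- labelsAt(result, k)
    planFromLabels(result@sampleIds, unname(labs), as.integer(k))
}
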