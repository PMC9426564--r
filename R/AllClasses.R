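## S4 classes for the coassembly workflow. Validity methods enforce the
## structural invariants each downstream step relies on.

.revcomp_chr <- function(x) {
    chartr("ACGT", "TGCA", vapply(strsplit(x, NULL), function(s)
        paste(rev(s), collapse = ""), character(1)))
}

#' KmerProfile: canonical k-mer abundances of one sample
#'
#' Holds the canonical k-mer counts of one metagenomic sample, the unit
#' of comparison for the coassembly distances. Keys are canonical
#' k-mers (the lexicographic minimum of a k-mer and its reverse
#' complement), so counting is strand-agnostic.
#'
#' @slot sampleId sample label
#' @slot k k-mer length (1-31)
#' @slot counts named numeric vector, canonical k-mer -> abundance
#' @slot total sum of counts
#' @exportClass KmerProfile
setClass("KmerProfile",
    representation(sampleId = "character", k = "integer",
                   counts = "numeric", total = "numeric"))

setValidity("KmerProfile", function(object) {
    msg <- NULL
    if (length(object@sampleId) != 1L) msg <- c(msg, "sampleId must be length 1")
    if (object@k < 1L || object@k > 31L) msg <- c(msg, "k must be in [1, 31]")
    nm <- names(object@counts)
    if (length(object@counts) && is.null(nm))
        msg <- c(msg, "counts must be named by k-mer")
    if (length(object@counts)) {
        if (any(nchar(nm) != object@k))
            msg <- c(msg, "all k-mer keys must have length k")
        if (any(object@counts <= 0))
            msg <- c(msg, "all abundances must be positive")
        ## spot-check canonicality on a bounded subset to keep validation cheap
        idx <- head(seq_along(nm), 100L)
        if (any(.revcomp_chr(nm[idx]) < nm[idx]))
            msg <- c(msg, "k-mer keys must be canonical (min of self and reverse complement)")
    }
    if (!isTRUE(all.equal(object@total, sum(object@counts))))
        msg <- c(msg, "total must equal sum(counts)")
    if (is.null(msg)) TRUE else msg
})

#' @rdname KmerProfile-class
#' @param object,x a \code{KmerProfile}
#' @aliases sampleIds,KmerProfile-method kmerSize,KmerProfile-method
#'   kmerCounts,KmerProfile-method profileTotal,KmerProfile-method
#' @exportMethod sampleIds
setMethod("sampleIds", "KmerProfile", function(x, ...) x@sampleId)

#' @rdname KmerProfile-class
setMethod("kmerSize", "KmerProfile", function(x, ...) x@k)

#' @rdname KmerProfile-class
setMethod("kmerCounts", "KmerProfile", function(x, ...) x@counts)

#' @rdname KmerProfile-class
setMethod("profileTotal", "KmerProfile", function(x, ...) x@total)

setMethod("show", "KmerProfile", function(object) {
    cat("KmerProfile for sample '", object@sampleId, "': ",
        length(object@counts), " canonical ", object@k, "-mers, total count ",
        format(object@total), "\n", sep = "")
})

#' DistanceMatrix: labelled pairwise metagenomic distances
#'
#' Square symmetric matrix of pairwise sample distances with zero
#' diagonal and entries in [0, 1]; the input to
#' \code{\link{wardCluster}}.
#'
#' @slot sampleIds ordered sample labels
#' @slot values square numeric matrix
#' @slot metric "ab_jaccard" or "bray_curtis"
#' @exportClass DistanceMatrix
setClass("DistanceMatrix",
    representation(sampleIds = "character", values = "matrix",
                   metric = "character"))

setValidity("DistanceMatrix", function(object) {
    msg <- NULL
    v <- object@values
    n <- length(object@sampleIds)
    if (!all(dim(v) == c(n, n))) msg <- c(msg, "values must be n x n")
    if (anyNA(v)) msg <- c(msg, "values must not contain NA")
    else {
        if (!isTRUE(all.equal(v, t(v), tolerance = 1e-12)))
            msg <- c(msg, "values must be symmetric")
        if (n > 0 && any(abs(diag(v)) > 1e-12))
            msg <- c(msg, "diagonal must be zero")
        if (any(v < -1e-12) || any(v > 1 + 1e-12))
            msg <- c(msg, "entries must lie in [0, 1]")
    }
    if (!object@metric %in% c("ab_jaccard", "bray_curtis"))
        msg <- c(msg, "metric must be 'ab_jaccard' or 'bray_curtis'")
    if (anyDuplicated(object@sampleIds)) msg <- c(msg, "sampleIds must be unique")
    if (is.null(msg)) TRUE else msg
})

#' @rdname DistanceMatrix-class
#' @param object,x a \code{DistanceMatrix}
#' @param ... unused
setMethod("sampleIds", "DistanceMatrix", function(x, ...) x@sampleIds)

#' @rdname DistanceMatrix-class
setMethod("distMetric", "DistanceMatrix", function(x, ...) x@metric)

#' @rdname DistanceMatrix-class
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) {
    m <- x@values
    dimnames(m) <- list(x@sampleIds, x@sampleIds)
    m
})

setMethod("show", "DistanceMatrix", function(object) {
    cat("DistanceMatrix (", object@metric, ") over ",
        length(object@sampleIds), " samples\n", sep = "")
    if (length(object@sampleIds) > 0) {
        off <- object@values[upper.tri(object@values)]
        if (length(off))
            cat("  off-diagonal range: [", format(min(off), digits = 4), ", ",
                format(max(off), digits = 4), "]\n", sep = "")
    }
})

#' Dendrogram: Ward merge tree over samples
#'
#' Thin wrapper around the agglomerative merge sequence produced by
#' \code{\link{wardCluster}}; retains the sample labels and exposes the
#' merge steps as a data.frame.
#'
#' @slot hc the underlying \code{hclust} object
#' @slot nLeaves number of samples
#' @exportClass Dendrogram
setClass("Dendrogram", representation(hc = "ANY", nLeaves = "integer"))

setValidity("Dendrogram", function(object) {
    msg <- NULL
    if (!inherits(object@hc, "hclust")) msg <- c(msg, "hc must be an hclust object")
    else {
        if (nrow(object@hc$merge) != object@nLeaves - 1L)
            msg <- c(msg, "must contain exactly nLeaves - 1 merge steps")
        if (is.unsorted(object@hc$height))
            msg <- c(msg, "merge heights must be non-decreasing")
    }
    if (is.null(msg)) TRUE else msg
})

#' @rdname Dendrogram-class
#' @param object,x a \code{Dendrogram}
#' @param ... unused
setMethod("nLeaves", "Dendrogram", function(x, ...) x@nLeaves)

#' @rdname Dendrogram-class
setMethod("mergeSteps", "Dendrogram", function(x, ...) {
    data.frame(left = x@hc$merge[, 1], right = x@hc$merge[, 2],
               height = x@hc$height,
               size = .merge_sizes(x@hc$merge))
})

.merge_sizes <- function(merge) {
    sz <- integer(nrow(merge))
    for (i in seq_len(nrow(merge))) {
        l <- merge[i, 1]; r <- merge[i, 2]
        sz[i] <- (if (l < 0) 1L else sz[l]) + (if (r < 0) 1L else sz[r])
    }
    sz
}

setMethod("show", "Dendrogram", function(object) {
    cat("Dendrogram over", object@nLeaves, "samples (Ward linkage,",
        nrow(object@hc$merge), "merges)\n")
})

#' ClusteringResult: silhouette-scored sweep over dendrogram cuts
#'
#' Records, for every tested number of clusters k, the per-sample
#' labels and the mean silhouette score, plus the silhouette-optimal k
#' and (optionally) a suboptimal k chosen near a target cluster count.
#'
#' @slot sampleIds ordered sample labels
#' @slot labelsByK named list, as.character(k) -> integer labels
#' @slot silhouetteByK named numeric, as.character(k) -> mean silhouette
#' @slot optimalK silhouette-maximizing k (smallest on ties)
#' @slot suboptimalK chosen suboptimal k, or NA
#' @exportClass ClusteringResult
setClass("ClusteringResult",
    representation(sampleIds = "character", labelsByK = "list",
                   silhouetteByK = "numeric", optimalK = "integer",
                   suboptimalK = "integer"))

setValidity("ClusteringResult", function(object) {
    msg <- NULL
    ks <- names(object@labelsByK)
    if (!identical(ks, names(object@silhouetteByK)))
        msg <- c(msg, "labelsByK and silhouetteByK must cover the same k values")
    for (k in ks) {
        lab <- object@labelsByK[[k]]
        if (length(lab) != length(object@sampleIds))
            msg <- c(msg, "labels must cover all samples")
        if (length(unique(lab)) != as.integer(k))
            msg <- c(msg, sprintf("labels for k=%s must use exactly %s clusters", k, k))
    }
    if (length(ks)) {
        sil <- object@silhouetteByK
        best <- max(sil)
        kopt <- as.character(object@optimalK)
        if (!kopt %in% ks || sil[[kopt]] < best - 1e-12)
            msg <- c(msg, "optimalK must maximize the silhouette curve")
    }
    if (is.null(msg)) TRUE else msg
})

#' @rdname ClusteringResult-class
#' @param object,x a \code{ClusteringResult}
#' @param k number of clusters to extract labels for
#' @param ... unused
setMethod("sampleIds", "ClusteringResult", function(x, ...) x@sampleIds)

#' @rdname ClusteringResult-class
setMethod("optimalK", "ClusteringResult", function(x, ...) x@optimalK)

#' @rdname ClusteringResult-class
setMethod("suboptimalK", "ClusteringResult", function(x, ...) x@suboptimalK)

#' @rdname ClusteringResult-class
setMethod("labelsAt", "ClusteringResult", function(x, k, ...) {
    kk <- as.character(as.integer(k))
    if (!kk %in% names(x@labelsByK))
        stop("k = ", k, " was not part of the swept range")
    setNames(x@labelsByK[[kk]], x@sampleIds)
})

#' @rdname ClusteringResult-class
setMethod("silhouetteCurve", "ClusteringResult", function(x, ...) {
    data.frame(k = as.integer(names(x@silhouetteByK)),
               mean_silhouette = unname(x@silhouetteByK))
})

setMethod("show", "ClusteringResult", function(object) {
    cat("ClusteringResult over", length(object@sampleIds), "samples\n")
    cat("  swept k:", min(as.integer(names(object@silhouetteByK))), "..",
        max(as.integer(names(object@silhouetteByK))), "\n")
    cat("  optimal k =", object@optimalK, "(mean silhouette",
        format(object@silhouetteByK[[as.character(object@optimalK)]],
               digits = 4), ")\n")
    if (!is.na(object@suboptimalK))
        cat("  suboptimal k =", object@suboptimalK, "\n")
})

#' CoassemblyPlan: partition of samples into coassembly sets
#'
#' @slot groups named list, group id ("1", "2", ...) -> member sample ids
#' @slot sourceK number of clusters the plan was cut at
#' @exportClass CoassemblyPlan
setClass("CoassemblyPlan",
    representation(groups = "list", sourceK = "integer"))

setValidity("CoassemblyPlan", function(object) {
    msg <- NULL
    ids <- unlist(object@groups, use.names = FALSE)
    if (anyDuplicated(ids)) msg <- c(msg, "groups must be disjoint")
    if (any(lengths(object@groups) == 0L)) msg <- c(msg, "groups must be non-empty")
    if (!identical(names(object@groups), as.character(seq_along(object@groups))))
        msg <- c(msg, "group ids must be consecutive integers from 1")
    if (is.null(msg)) TRUE else msg
})

#' @rdname CoassemblyPlan-class
#' @param object,x a \code{CoassemblyPlan}
#' @param ... unused
setMethod("sampleGroups", "CoassemblyPlan", function(x, ...) x@groups)

#' @rdname CoassemblyPlan-class
setMethod("sampleIds", "CoassemblyPlan", function(x, ...)
    unlist(x@groups, use.names = FALSE))

#' @rdname CoassemblyPlan-class
setMethod("sourceK", "CoassemblyPlan", function(x, ...) x@sourceK)

setMethod("show", "CoassemblyPlan", function(object) {
    cat("CoassemblyPlan:", length(object@groups), "groups over",
        length(unlist(object@groups)), "samples (cut at k =",
        object@sourceK, ")\n")
})

#' StrategyPlan: one assembly-binning strategy expanded to jobs
#'
#' Concrete work plan for one of the four strategies: the assembly
#' units (one per sample for single assembly, one per coassembly group
#' otherwise) and the (sample, unit) read-mapping jobs feeding the
#' binning abundance tables. Cobinning maps every sample against every
#' unit, which is what makes its cost quadratic in the number of
#' metagenomes.
#'
#' @slot strategy "SASB", "SACB", "CASB" or "CACB"
#' @slot units named list, unit id -> member sample ids
#' @slot mappingJobs data.frame with columns sample_id, unit_id
#' @exportClass StrategyPlan
setClass("StrategyPlan",
    representation(strategy = "character", units = "list",
                   mappingJobs = "data.frame"))

setValidity("StrategyPlan", function(object) {
    msg <- NULL
    if (!object@strategy %in% c("SASB", "SACB", "CASB", "CACB"))
        msg <- c(msg, "strategy must be one of SASB, SACB, CASB, CACB")
    members <- unlist(object@units, use.names = FALSE)
    if (anyDuplicated(members))
        msg <- c(msg, "every sample must appear in exactly one assembly unit")
    if (!identical(sort(colnames(object@mappingJobs)),
                   c("sample_id", "unit_id")))
        msg <- c(msg, "mappingJobs must have columns sample_id and unit_id")
    else if (anyDuplicated(object@mappingJobs))
        msg <- c(msg, "mappingJobs must be deduplicated")
    if (is.null(msg)) TRUE else msg
})

#' @rdname StrategyPlan-class
#' @param object,x a \code{StrategyPlan}
#' @param ... unused
setMethod("assemblyUnits", "StrategyPlan", function(x, ...) x@units)

#' @rdname StrategyPlan-class
setMethod("mappingJobs", "StrategyPlan", function(x, ...) x@mappingJobs)

#' @rdname StrategyPlan-class
setMethod("strategyName", "StrategyPlan", function(x, ...) x@strategy)

setMethod("show", "StrategyPlan", function(object) {
    cat("StrategyPlan [", object@strategy, "]: ", length(object@units),
        " assembly units, ", nrow(object@mappingJobs),
        " mapping jobs\n", sep = "")
})

#' ContigDepthTable: per-contig mean depths across samples
#'
#' The abundance input to composition+abundance binners: per contig and
#' sample, the mean and population variance of per-base coverage.
#' Serialized by \code{\link{writeDepthTable}} in the column layout of
#' \code{jgi_summarize_bam_contig_depths} so MetaBAT2 consumes it
#' unchanged.
#'
#' @slot contigs data.frame with columns contig_id, length
#' @slot sampleIds ordered sample labels
#' @slot meanDepth contig x sample matrix of mean depths
#' @slot depthVariance contig x sample matrix of population variances
#' @exportClass ContigDepthTable
setClass("ContigDepthTable",
    representation(contigs = "data.frame", sampleIds = "character",
                   meanDepth = "matrix", depthVariance = "matrix"))

setValidity("ContigDepthTable", function(object) {
    msg <- NULL
    nc <- nrow(object@contigs); ns <- length(object@sampleIds)
    if (!all(dim(object@meanDepth) == c(nc, ns)) ||
        !all(dim(object@depthVariance) == c(nc, ns)))
        msg <- c(msg, "depth matrices must be contig x sample")
    if (anyDuplicated(object@contigs$contig_id))
        msg <- c(msg, "duplicate contig names")
    if (length(object@meanDepth) && any(object@meanDepth < 0))
        msg <- c(msg, "mean depths must be non-negative")
    if (length(object@depthVariance) && any(object@depthVariance < -1e-12))
        msg <- c(msg, "depth variances must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' @rdname ContigDepthTable-class
#' @param object,x a \code{ContigDepthTable}
#' @param ... unused
setMethod("sampleIds", "ContigDepthTable", function(x, ...) x@sampleIds)

#' @rdname ContigDepthTable-class
setMethod("contigInfo", "ContigDepthTable", function(x, ...) x@contigs)

#' @rdname ContigDepthTable-class
setMethod("meanDepths", "ContigDepthTable", function(x, ...) {
    m <- x@meanDepth
    dimnames(m) <- list(x@contigs$contig_id, x@sampleIds)
    m
})

#' @rdname ContigDepthTable-class
setMethod("depthVariances", "ContigDepthTable", function(x, ...) {
    m <- x@depthVariance
    dimnames(m) <- list(x@contigs$contig_id, x@sampleIds)
    m
})

setMethod("show", "ContigDepthTable", function(object) {
    cat("ContigDepthTable:", nrow(object@contigs), "contigs x",
        length(object@sampleIds), "samples\n")
})

#' DereplicationResult: ANI-linked clusters of MAGs
#'
#' Connected components of the graph joining two MAGs when their ANI
#' reaches the chosen identity threshold over more than the required
#' aligned fraction of the smaller genome, with one representative per
#' component.
#'
#' @slot threshold ANI identity threshold t (e.g. 0.95 species, 0.99 strain)
#' @slot afMin minimum aligned fraction (strict; default 0.6)
#' @slot clusters named list, cluster id -> member bin ids
#' @slot representatives named character, cluster id -> representative bin id
#' @slot ani data.frame of all pairwise estimates
#'   (genome_a, genome_b, ani, aligned_fraction)
#' @exportClass DereplicationResult
setClass("DereplicationResult",
    representation(threshold = "numeric", afMin = "numeric",
                   clusters = "list", representatives = "character",
                   ani = "data.frame"))

setValidity("DereplicationResult", function(object) {
    msg <- NULL
    ids <- unlist(object@clusters, use.names = FALSE)
    if (anyDuplicated(ids)) msg <- c(msg, "clusters must partition the MAG set")
    if (!identical(names(object@clusters), names(object@representatives)))
        msg <- c(msg, "clusters and representatives must share cluster ids")
    for (cid in names(object@clusters))
        if (!object@representatives[[cid]] %in% object@clusters[[cid]])
            msg <- c(msg, "each representative must belong to its cluster")
    if (object@threshold <= 0 || object@threshold >= 1)
        msg <- c(msg, "threshold must be in (0, 1)")
    if (is.null(msg)) TRUE else msg
})

#' @rdname DereplicationResult-class
#' @param object,x a \code{DereplicationResult}
#' @param ... unused
setMethod("derepClusters", "DereplicationResult", function(x, ...) x@clusters)

#' @rdname DereplicationResult-class
setMethod("representatives", "DereplicationResult", function(x, ...)
    x@representatives)

#' @rdname DereplicationResult-class
setMethod("aniTable", "DereplicationResult", function(x, ...) x@ani)

#' @rdname DereplicationResult-class
setMethod("aniThreshold", "DereplicationResult", function(x, ...) x@threshold)

setMethod("show", "DereplicationResult", function(object) {
    cat("DereplicationResult at t =", object@threshold, ":",
        length(unlist(object@clusters)), "MAGs ->",
        length(object@clusters), "clusters\n")
})

#' CommunitySpec: parameters of a synthetic clustered community
#'
#' Describes a multi-sample community with planted sample-group
#' structure: genomes are split into disjoint per-group pools (plus an
#' optional shared pool) and each sample draws log-normal abundances
#' over its group's pool. Defaults are desk-scale: 12 samples in 3
#' groups, 20,000 150-bp reads per sample from 100-kb genomes, with
#' log-normal abundance parameters mu = 1, sigma = 2 on the natural-log
#' scale.
#'
#' @slot nGenomes,genomeLength community size and genome length (bp)
#' @slot mu,sigma log-normal abundance parameters (natural log scale)
#' @slot sigmaWithin per-sample log-normal perturbation of the group's
#'   base abundances (0 = identical composition within a group)
#' @slot nSamples,nGroups samples and planted groups (nGroups <= nSamples)
#' @slot readsPerSample,readLength read simulation size
#' @slot errorRate per-base substitution probability in [0, 0.25)
#' @slot gc genome GC content in (0, 1)
#' @slot sharedFraction fraction of genomes shared across all groups
#' @slot seed integer seed making every derived artifact reproducible
#' @exportClass CommunitySpec
setClass("CommunitySpec",
    representation(nGenomes = "integer", genomeLength = "integer",
                   mu = "numeric", sigma = "numeric",
                   sigmaWithin = "numeric",
                   nSamples = "integer", nGroups = "integer",
                   readsPerSample = "integer", readLength = "integer",
                   errorRate = "numeric", gc = "numeric",
                   sharedFraction = "numeric", seed = "integer"))

setValidity("CommunitySpec", function(object) {
    msg <- NULL
    if (object@nGroups > object@nSamples)
        msg <- c(msg, "nGroups must not exceed nSamples")
    if (object@nGenomes < object@nGroups)
        msg <- c(msg, "need at least one genome per group")
    if (any(c(object@nGenomes, object@genomeLength, object@nSamples,
              object@nGroups, object@readsPerSample, object@readLength) < 1L))
        msg <- c(msg, "all counts must be positive")
    if (object@errorRate < 0 || object@errorRate >= 0.25)
        msg <- c(msg, "errorRate must be in [0, 0.25)")
    if (object@gc <= 0 || object@gc >= 1) msg <- c(msg, "gc must be in (0, 1)")
    if (object@sharedFraction < 0 || object@sharedFraction >= 1)
        msg <- c(msg, "sharedFraction must be in [0, 1)")
    if (object@sigmaWithin < 0)
        msg <- c(msg, "sigmaWithin must be >= 0")
    if (object@readLength > object@genomeLength)
        msg <- c(msg, "readLength must not exceed genomeLength")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "CommunitySpec", function(object) {
    cat("CommunitySpec:", object@nGenomes, "genomes x",
        object@genomeLength, "bp;", object@nSamples, "samples in",
        object@nGroups, "groups;", object@readsPerSample, "x",
        object@readLength, "bp reads/sample; error rate",
        object@errorRate, "; seed", object@seed, "\n")
})

#' PlantedTruth: ground truth of a synthetic clustered dataset
#'
#' Everything needed to score recovery without re-reading the FASTQ:
#' the planted sample-to-group labels, the per-sample genome abundance
#' matrix, and the source genome of every simulated read.
#'
#' @slot sampleGroup named integer, sample id -> group
#' @slot abundances sample x genome relative-abundance matrix
#'   (rows sum to 1)
#' @slot origin named list, sample id -> per-read source genome ids
#' @exportClass PlantedTruth
setClass("PlantedTruth",
    representation(sampleGroup = "integer", abundances = "matrix",
                   origin = "list"))

setValidity("PlantedTruth", function(object) {
    msg <- NULL
    if (is.null(names(object@sampleGroup)))
        msg <- c(msg, "sampleGroup must be named by sample id")
    rs <- rowSums(object@abundances)
    if (length(rs) && any(abs(rs - 1) > 1e-9))
        msg <- c(msg, "per-sample abundances must sum to 1")
    if (is.null(msg)) TRUE else msg
})

#' @rdname PlantedTruth-class
#' @param object,x a \code{PlantedTruth}
#' @param ... unused
setMethod("sampleGroups", "PlantedTruth", function(x, ...) x@sampleGroup)

#' @rdname PlantedTruth-class
setMethod("genomeAbundances", "PlantedTruth", function(x, ...) x@abundances)

#' @rdname PlantedTruth-class
setMethod("readOrigin", "PlantedTruth", function(x, ...) x@origin)

setMethod("show", "PlantedTruth", function(object) {
    cat("PlantedTruth:", length(object@sampleGroup), "samples in",
        length(unique(object@sampleGroup)), "groups,",
        ncol(object@abundances), "genomes\n")
})
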