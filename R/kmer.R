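## Canonical k-mer counting and Simka-style abundance-weighted
## metagenomic distances.

#' Count canonical k-mers in a set of reads
#'
#' Every length-k window over A/C/G/T contributes one count to its
#' canonical form (the lexicographic minimum of the window and its
#' reverse complement); windows containing N (or any other character)
#' are skipped. k-mers whose final count falls below
#' \code{minAbundance} are removed before totalling, mirroring a
#' solid-k-mer filter; the default keeps singletons.
#'
#' @param records a \code{DNAStringSet} or character vector of reads;
#'   both mates of a paired-end sample should be pooled here
#' @param k k-mer length, 1-31 (default 21, the conventional choice for
#'   comparative metagenomics)
#' @param minAbundance drop k-mers with final count below this (>= 1)
#' @param sampleId label stored in the profile
#' @return a \code{\link{KmerProfile}}
#' @examples
#' countKmers("AAAA", k = 2)            # {AA: 3}
#' countKmers("ACGT", k = 4)            # palindromic: {ACGT: 1}
#' @export
countKmers <- function(records, k = 21L, minAbundance = 1L,
                       sampleId = "sample") {
    .assert(k >= 1 && k <= 31, "k must be in [1, 31]")
    .assert(minAbundance >= 1, "minAbundance must be >= 1")
    seqs <- .as_seq_chr(records)
    res <- .cpp_count_kmers(seqs, as.integer(k), as.integer(minAbundance))
    if (length(res$counts) == 0 && length(seqs) > 0 &&
        all(nchar(seqs) < k))
        warning("k = ", k, " exceeds every read length; profile is empty",
                call. = FALSE)
    new("KmerProfile", sampleId = sampleId, k = as.integer(k),
        counts = res$counts, total = res$total)
}

.check_pair <- function(p, q) {
    .assert(is(p, "KmerProfile") && is(q, "KmerProfile"),
            "expected two KmerProfile objects")
    .assert(p@k == q@k, "profiles were counted at different k (",
            p@k, " vs ", q@k, ")")
}

#' Abundance-weighted Jaccard (AB-Jaccard) distance
#'
#' \code{1 - sum(min(p_w, q_w)) / sum(max(p_w, q_w))} over the union of
#' k-mers, with absent k-mers counting 0. Unlike Bray-Curtis this
#' abundance-weighted Jaccard satisfies the triangle inequality, which
#' is why it is preferred for clustering metagenomes into coassembly
#' sets. Two empty profiles are at distance 0.
#'
#' @param p,q \code{\link{KmerProfile}} objects counted at the same k
#' @return distance in [0, 1]
#' @export
abJaccardDistance <- function(p, q) {
    .check_pair(p, q)
    u <- union(names(p@counts), names(q@counts))
    if (length(u) == 0) return(0)
    pv <- qv <- numeric(length(u))
    pv[match(names(p@counts), u)] <- p@counts
    qv[match(names(q@counts), u)] <- q@counts
    smax <- sum(pmax(pv, qv))
    if (smax == 0) return(0)
    1 - sum(pmin(pv, qv)) / smax
}

#' Bray-Curtis distance between k-mer profiles
#'
#' \code{1 - 2 sum(min(p_w, q_w)) / (total_p + total_q)}. Bounded in
#' [0, 1] and symmetric but not a metric (no triangle inequality);
#' provided for comparison with the default AB-Jaccard.
#'
#' @inheritParams abJaccardDistance
#' @return distance in [0, 1]
#' @export
brayCurtisDistance <- function(p, q) {
    .check_pair(p, q)
    tot <- p@total + q@total
    if (tot == 0) return(0)
    shared <- intersect(names(p@counts), names(q@counts))
    smin <- sum(pmin(p@counts[shared], q@counts[shared]))
    1 - 2 * smin / tot
}

#' Pairwise metagenomic distances across samples
#'
#' Counts canonical k-mers per sample and assembles the full labelled
#' distance matrix. Input is either a sample manifest data.frame
#' (columns \code{sample_id}, \code{path_r1}, optional \code{path_r2};
#' mates are pooled) or a list of \code{\link{KmerProfile}} objects.
#' Sample order is preserved from the input.
#'
#' @param samples manifest data.frame, a named list of read sets
#'   (character vectors / DNAStringSets, one per sample), or a list of
#'   \code{KmerProfile}s
#' @param k,minAbundance passed to the counting step when samples are
#'   given as reads
#' @param metric "ab_jaccard" (default) or "bray_curtis"
#' @return a \code{\link{DistanceMatrix}}
#' @export
pairwiseDistances <- function(samples, k = 21L,
                              metric = c("ab_jaccard", "bray_curtis"),
                              minAbundance = 1L) {
    metric <- match.arg(metric)
    from_profiles <- is.list(samples) && !is.data.frame(samples) &&
        length(samples) > 0 && is(samples[[1]], "KmerProfile")
    if (from_profiles) {
        profiles <- samples
        .assert(length(profiles) >= 2, "need at least 2 samples")
        .assert(all(vapply(profiles, is, logical(1), "KmerProfile")),
                "expected KmerProfile objects")
        ks <- vapply(profiles, function(p) p@k, integer(1))
        .assert(length(unique(ks)) == 1, "profiles counted at different k")
        k <- ks[1]
        ids <- vapply(profiles, function(p) p@sampleId, character(1))
        .assert(!anyDuplicated(ids), "duplicate sample ids")
        vals <- .cpp_distance_matrix(lapply(profiles, function(p) p@counts),
                                     as.integer(k), metric)
        return(.finish_distance_matrix(vals, ids, metric))
    }
    if (is.data.frame(samples)) {
        .assert(nrow(samples) >= 2, "need at least 2 samples")
        ids <- samples$sample_id
        read_sets <- lapply(seq_len(nrow(samples)), function(i) {
            paths <- c(samples$path_r1[i], samples$path_r2[i])
            paths <- paths[!is.na(paths)]
            tryCatch(
                do.call(c, lapply(paths, function(p)
                    as.character(readSequences(p)))),
                error = function(e) stop("failed reading sample '", ids[i],
                                         "': ", conditionMessage(e),
                                         call. = FALSE))
        })
    } else {
        read_sets <- samples
        ids <- names(read_sets)
        .assert(!is.null(ids), "read-set list must be named by sample id")
        .assert(length(read_sets) >= 2, "need at least 2 samples")
    }
    .assert(!anyDuplicated(ids), "duplicate sample ids")
    .assert(k >= 1 && k <= 26,
            "pairwise counting supports k up to 26; count profiles ",
            "explicitly for larger k")
    coded <- lapply(read_sets, function(r)
        .cpp_count_kmer_codes(.as_seq_chr(r), as.integer(k),
                              as.integer(minAbundance)))
    vals <- .cpp_distance_matrix_codes(coded, metric)
    .finish_distance_matrix(vals, ids, metric)
}

## clamp tiny float excursions so the matrix passes its invariants
.finish_distance_matrix <- function(vals, ids, metric) {
    vals[vals < 0] <- 0
    vals[vals > 1] <- 1
    vals <- (vals + t(vals)) / 2
    new("DistanceMatrix", sampleIds = ids, values = vals, metric = metric)
}
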