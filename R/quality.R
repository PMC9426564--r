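## Bin quality classes and ANI-based dereplication of MAGs.

#' Classify bin quality from completeness and contamination
#'
#' High quality (HQ): completeness > 90 and contamination < 5; medium
#' quality (MQ): completeness > 50 and contamination < 10; everything
#' else is low quality (LQ). All inequalities are strict, so a bin at
#' exactly (90, 5) is MQ. Only HQ and MQ bins count as MAGs.
#'
#' @param completeness percent in [0, 100] (vectorized)
#' @param contamination percent >= 0; may exceed 100 (vectorized)
#' @return character vector of "HQ", "MQ", "LQ"
#' @examples
#' classifyQuality(91, 4)    # "HQ"
#' classifyQuality(90, 5)    # "MQ": fails both strict HQ bounds
#' classifyQuality(95, 12)   # "LQ": contamination >= 10
#' @export
classifyQuality <- function(completeness, contamination) {
    .assert(all(completeness >= 0 & completeness <= 100),
            "completeness must lie in [0, 100]")
    .assert(all(contamination >= 0), "contamination must be >= 0")
    ifelse(completeness > 90 & contamination < 5, "HQ",
           ifelse(completeness > 50 & contamination < 10, "MQ", "LQ"))
}

#' Representative-selection score for a genome bin
#'
#' \code{completeness - 5 * contamination}, the conventional weighting
#' used by dereplication tools to rank candidate representatives.
#'
#' @param completeness,contamination percentages (vectorized)
#' @return numeric score
#' @export
scoreGenome <- function(completeness, contamination) {
    completeness - 5 * contamination
}

#' Alignment-free ANI estimate by windowed k-mer containment
#'
#' The smaller genome is tiled into non-overlapping windows (trailing
#' partial windows are dropped). For each window, j is the fraction of
#' its canonical k-mers found anywhere in the other genome; under a
#' uniform substitution model E[j] = (1 - p)^k for divergence p, so
#' each mapped window's identity is estimated as \code{j^(1/k)}.
#' Windows with j = 0 are unmapped. ANI is the mean identity over
#' mapped windows and the aligned fraction is the share of mapped
#' windows, measured on the smaller genome. Unrelated genomes share
#' essentially no 16-mers, so both values collapse to ~0.
#'
#' @param genomeA,genomeB sequences (DNAStringSet or character; a
#'   multi-contig genome is a vector)
#' @param window window size in bp (default 1000; must be >= 2k)
#' @param k k-mer size for containment (default 16)
#' @return one-row data.frame: genome_a, genome_b, ani,
#'   aligned_fraction (ids taken from argument names when available)
#' @export
estimateAni <- function(genomeA, genomeB, window = 1000L, k = 16L) {
    .assert(window >= 2 * k, "window must be at least 2k")
    a <- .as_seq_chr(genomeA)
    b <- .as_seq_chr(genomeB)
    .assert(length(a) > 0 && length(b) > 0 && all(nchar(c(a, b)) > 0),
            "both genomes must be non-empty")
    la <- sum(nchar(a)); lb <- sum(nchar(b))
    if (la <= lb) { query <- a; ref <- b; flipped <- FALSE }
    else          { query <- b; ref <- a; flipped <- TRUE }
    js <- .cpp_window_containment(query, ref, as.integer(window),
                                  as.integer(k))
    if (length(js) == 0) {
        warning("smaller genome shorter than one window; ANI undefined, ",
                "reporting 0", call. = FALSE)
        ani <- 0; af <- 0
    } else {
        mapped <- js > 0
        af <- mean(mapped)
        ani <- if (any(mapped)) mean(js[mapped]^(1 / k)) else 0
    }
    data.frame(genome_a = "genome_a", genome_b = "genome_b",
               ani = ani, aligned_fraction = af)
}

#' Dereplicate MAGs at an ANI threshold
#'
#' Two MAGs are duplicates when their pairwise ANI reaches the identity
#' threshold \code{t} over strictly more than \code{afMin} of the
#' smaller genome's bases. Duplicate links are resolved by single
#' linkage: clusters are the connected components of the threshold
#' graph. Within each cluster the representative maximizes
#' \code{completeness - 5 * contamination}, ties broken by larger total
#' genome length then lexicographic bin id. \code{t = 0.95}
#' corresponds to species-level and \code{t = 0.99} to strain-level
#' dereplication.
#'
#' @param mags named list, bin id -> sequences (DNAStringSet or
#'   character vector of contigs)
#' @param quality data.frame with columns bin_id, completeness,
#'   contamination covering every bin; all bins must be MAGs (HQ or
#'   MQ), LQ input is an error
#' @param t ANI identity threshold in (0, 1)
#' @param afMin aligned-fraction requirement (strict >; default 0.6)
#' @param window,k passed to \code{\link{estimateAni}}
#' @return a \code{\link{DereplicationResult}}
#' @export
dereplicate <- function(mags, quality, t = 0.95, afMin = 0.6,
                        window = 1000L, k = 16L) {
    .assert(t > 0 && t < 1, "t must be in (0, 1)")
    ids <- names(mags)
    .assert(!is.null(ids) && !anyDuplicated(ids),
            "mags must be a named list with unique bin ids")
    .assert(all(ids %in% quality$bin_id),
            "quality table must cover every bin")
    q <- quality[match(ids, quality$bin_id), ]
    cls <- classifyQuality(q$completeness, q$contamination)
    .assert(!any(cls == "LQ"),
            "low-quality bin(s) in input (only MAGs are dereplicated): ",
            paste(ids[cls == "LQ"], collapse = ", "))
    n <- length(ids)
    pairs <- if (n >= 2) utils::combn(n, 2) else matrix(integer(), 2, 0)
    ani <- data.frame(genome_a = character(), genome_b = character(),
                      ani = numeric(), aligned_fraction = numeric())
    edges <- matrix(character(), ncol = 2, nrow = 0)
    for (p in seq_len(ncol(pairs))) {
        i <- pairs[1, p]; j <- pairs[2, p]
        est <- estimateAni(mags[[i]], mags[[j]], window = window, k = k)
        est$genome_a <- ids[i]; est$genome_b <- ids[j]
        ani <- rbind(ani, est)
        if (est$ani >= t && est$aligned_fraction > afMin)
            edges <- rbind(edges, c(ids[i], ids[j]))
    }
    g <- igraph::make_empty_graph(directed = FALSE) +
        igraph::vertices(ids)
    if (nrow(edges))
        g <- igraph::add_edges(g, t(edges))
    comp <- igraph::components(g)$membership
    ## order clusters by their lexicographically smallest member
    members <- split(names(comp), comp)
    members <- members[order(vapply(members, min, character(1)))]
    names(members) <- as.character(seq_along(members))
    lens <- vapply(mags, function(s) sum(nchar(.as_seq_chr(s))), numeric(1))
    score <- setNames(scoreGenome(q$completeness, q$contamination), ids)
    reps <- vapply(members, function(m) {
        m[order(-score[m], -lens[m], m)][1]
    }, character(1))
    new("DereplicationResult", threshold = t, afMin = afMin,
        clusters = members, representatives = reps, ani = ani)
}
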