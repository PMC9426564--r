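# Independent oracles used against the package's optimized paths.
# These deliberately use the most literal formulation available
# (string windows, double loops, per-base arrays).

# Brute-force canonical k-mer counting: explicit window enumeration
# with string reverse complement.
oracle_count_kmers <- function(seqs, k, min_abundance = 1) {
    words <- unlist(lapply(toupper(seqs), function(s) {
        n <- nchar(s)
        if (n < k) return(character())
        w <- substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
        w[!grepl("[^ACGT]", w)]
    }))
    if (length(words) == 0) return(setNames(numeric(), character()))
    rc <- vapply(strsplit(chartr("ACGT", "TGCA", words), NULL),
                 function(x) paste(rev(x), collapse = ""), character(1))
    canon <- pmin(words, rc)
    tab <- table(canon)
    out <- as.numeric(tab)
    names(out) <- names(tab)
    out[out >= min_abundance]
}

# Literal two-loop mean silhouette.
oracle_silhouette <- function(d, labels) {
    n <- nrow(d)
    labels <- as.integer(factor(labels))
    s <- numeric(n)
    for (i in seq_len(n)) {
        own <- which(labels == labels[i])
        if (length(own) == 1) { s[i] <- 0; next }
        a <- mean(d[i, setdiff(own, i)])
        b <- Inf
        for (cl in setdiff(unique(labels), labels[i]))
            b <- min(b, mean(d[i, labels == cl]))
        s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
    }
    mean(s)
}

# Per-base coverage oracle for one target: returns the full coverage
# vector from 0-based half-open intervals.
oracle_coverage_vector <- function(starts, ends, len) {
    v <- integer(len)
    for (i in seq_along(starts)) {
        idx <- (starts[i] + 1):ends[i]
        v[idx] <- v[idx] + 1L
    }
    v
}

pop_var <- function(x) mean((x - mean(x))^2)

# Random KmerProfile built through read simulation (used where the test
# needs realistic profiles, not a counting oracle).
random_profile <- function(seed, n_reads = 40, len = 60, k = 11,
                           sample_id = paste0("s", seed)) {
    withr::with_seed(seed, {
        reads <- vapply(seq_len(n_reads), function(i)
            paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
            character(1))
        countKmers(reads, k = k, sampleId = sample_id)
    })
}

# Random DNA string.
random_dna <- function(n, seed = NULL) {
    gen <- function() paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
    if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Minimal SAM writer for fixtures.
write_sam <- function(path, targets, records) {
    hdr <- c("@HD\tVN:1.6",
             sprintf("@SQ\tSN:%s\tLN:%d", names(targets), targets))
    writeLines(c(hdr, records), path)
}

sam_record <- function(qname, flag, rname, pos, mapq, cigar) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
            qname, flag, rname, pos, mapq, cigar)
}

# Planted block distance matrix: within-group ~U(0.05, 0.15), between
# ~U(0.7, 0.9).
planted_matrix <- function(groups, seed,
                           within = c(0.05, 0.15), between = c(0.7, 0.9)) {
    withr::with_seed(seed, {
        n <- length(groups)
        m <- matrix(0, n, n)
        for (i in seq_len(n - 1)) for (j in (i + 1):n) {
            r <- if (groups[i] == groups[j]) within else between
            m[i, j] <- m[j, i] <- runif(1, r[1], r[2])
        }
        new("DistanceMatrix", sampleIds = sprintf("s%02d", seq_len(n)),
            values = m, metric = "ab_jaccard")
    })
}
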