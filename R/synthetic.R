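## Deterministic synthetic-community generator: genomes, log-normal
## abundances, reads with substitution errors, planted sample-group
## structure and controlled-divergence genome pairs. All randomness
## flows through R's RNG under an explicit seed, so identical seeds
## give byte-identical outputs.

#' Construct a synthetic community specification
#'
#' Defaults describe the desk-scale study community: 12 samples in 3
#' planted groups, 20,000 150-bp reads per sample (~3 Mbp, a scaled-
#' down metagenome) drawn from 100-kb genomes, per-sample abundances
#' log-normal with mu = 1, sigma = 2 on the natural-log scale, and a
#' 0.5\% uniform substitution error rate typical of short reads.
#'
#' @param nGenomes,genomeLength community size and genome length
#' @param mu,sigma log-normal abundance parameters
#' @param sigmaWithin per-sample multiplicative log-normal noise around
#'   the group's base abundance profile (default 0.5): samples of one
#'   group share a community composition up to moderate fluctuation,
#'   as replicate metagenomes from one habitat do
#' @param nSamples,nGroups samples and planted groups
#' @param readsPerSample,readLength read simulation size
#' @param errorRate per-base substitution probability
#' @param gc genome GC content
#' @param sharedFraction fraction of genomes placed in a pool shared by
#'   all groups (default 0: fully disjoint pools)
#' @param seed integer seed
#' @return a \code{\link{CommunitySpec}}
#' @export
communitySpec <- function(nGenomes = 12L, genomeLength = 100000L,
                          mu = 1, sigma = 2, sigmaWithin = 0.5,
                          nSamples = 12L, nGroups = 3L,
                          readsPerSample = 20000L, readLength = 150L,
                          errorRate = 0.005, gc = 0.5,
                          sharedFraction = 0, seed = 1L) {
    new("CommunitySpec", nGenomes = as.integer(nGenomes),
        genomeLength = as.integer(genomeLength), mu = mu, sigma = sigma,
        sigmaWithin = sigmaWithin,
        nSamples = as.integer(nSamples), nGroups = as.integer(nGroups),
        readsPerSample = as.integer(readsPerSample),
        readLength = as.integer(readLength), errorRate = errorRate,
        gc = gc, sharedFraction = sharedFraction, seed = as.integer(seed))
}

#' Generate a random genome
#'
#' Bases are i.i.d. with P(G) + P(C) = \code{gc}; deterministic for a
#' fixed seed.
#'
#' @param length genome length (>= 1000)
#' @param gc GC content in (0, 1)
#' @param seed integer seed, or NULL to use the current RNG stream
#' @param id sequence name
#' @return a named \code{DNAStringSet} of length 1
#' @export
generateGenome <- function(length, gc = 0.5, seed = NULL, id = "genome") {
    .assert(length >= 1000, "genome length must be >= 1000")
    .assert(gc > 0 && gc < 1, "gc must be in (0, 1)")
    seq <- .with_seed(seed, paste(
        sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = ""))
    setNames(Biostrings::DNAStringSet(seq), id)
}

#' Mutate a genome at a controlled substitution rate
#'
#' Each base is substituted with probability \code{divergence} to a
#' uniformly chosen different base; length is unchanged and the
#' realized substitution count is recorded in
#' \code{metadata(x)$n_substitutions}.
#'
#' @param genome DNAStringSet (or character) of one or more sequences
#' @param divergence per-base substitution probability in [0, 0.2]
#' @param seed integer seed, or NULL
#' @return a \code{DNAStringSet} of the same shape
#' @export
mutateGenome <- function(genome, divergence, seed = NULL) {
    .assert(divergence >= 0 && divergence <= 0.2,
            "divergence must be in [0, 0.2]")
    seqs <- .as_seq_chr(genome)
    res <- .with_seed(seed, .cpp_mutate_sequences(seqs, divergence))
    out <- Biostrings::DNAStringSet(res$seq)
    names(out) <- names(genome)
    S4Vectors::metadata(out)$n_substitutions <- sum(res$n_substitutions)
    S4Vectors::metadata(out)$realized_rate <-
        sum(res$n_substitutions) / sum(nchar(seqs))
    out
}

#' Draw normalized log-normal genome abundances
#'
#' x_i ~ LogNormal(mu, sigma) on the natural-log scale, returned
#' normalized to sum 1.
#'
#' @param nGenomes number of genomes (>= 1)
#' @param mu,sigma log-normal parameters (defaults 1 and 2)
#' @param seed integer seed, or NULL
#' @return abundance vector summing to 1
#' @export
sampleAbundances <- function(nGenomes, mu = 1, sigma = 2, seed = NULL) {
    .assert(nGenomes >= 1, "nGenomes must be >= 1")
    x <- .with_seed(seed, rlnorm(nGenomes, meanlog = mu, sdlog = sigma))
    x / sum(x)
}

#' Simulate shotgun reads from a community
#'
#' Each read's source genome is drawn proportionally to abundance times
#' genome length; start position and strand are uniform; substitution
#' errors are applied at \code{errorRate}. The returned truth table
#' records every read's source genome, start and strand.
#'
#' @param genomes named \code{DNAStringSet} (or character vector)
#' @param abundances relative abundances, same length as genomes
#' @param nReads number of reads
#' @param readLength read length (must not exceed any genome length)
#' @param errorRate per-base substitution probability
#' @param seed integer seed, or NULL
#' @param sampleId prefix for read ids
#' @return list with elements \code{reads} (named character vector) and
#'   \code{truth} (data.frame read_id, genome_id, start, forward)
#' @export
simulateReads <- function(genomes, abundances, nReads, readLength,
                          errorRate = 0, seed = NULL, sampleId = "s") {
    seqs <- .as_seq_chr(genomes)
    gids <- names(genomes)
    if (is.null(gids)) gids <- paste0("g", seq_along(seqs))
    .assert(length(abundances) == length(seqs),
            "abundances must match genomes")
    .assert(all(abundances >= 0) && sum(abundances) > 0,
            "abundances must be non-negative and not all zero")
    w <- abundances * nchar(seqs)
    w <- w / sum(w)
    res <- .with_seed(seed,
        .cpp_simulate_reads(seqs, w, as.integer(nReads),
                            as.integer(readLength), errorRate))
    ids <- sprintf("%s_r%06d", sampleId, seq_len(nReads))
    reads <- setNames(as.character(res$reads), ids)
    truth <- data.frame(read_id = ids, genome_id = gids[res$origin],
                        start = res$start, forward = res$forward)
    list(reads = reads, truth = truth)
}

#' Generate a multi-sample dataset with planted group structure
#'
#' Genomes are split into per-group pools (disjoint up to an optional
#' shared fraction). Each group draws one log-normal base abundance
#' vector over its pool; each sample perturbs that base by independent
#' per-genome log-normal noise (\code{sigmaWithin}) and renormalizes,
#' then simulates reads. Samples of the same group therefore share
#' both k-mer content and approximate composition (small distances)
#' while samples of different groups share essentially none, planting
#' a recoverable cluster structure. Ground truth (group labels,
#' abundance matrix, read origins) is returned alongside.
#'
#' @param spec a \code{\link{CommunitySpec}}
#' @param dir optional output directory; when given, per-sample FASTQ
#'   (\code{<sample>.fastq.gz}), \code{genomes.fasta},
#'   \code{manifest.tsv}, \code{truth_groups.tsv} and
#'   \code{truth_abundances.tsv} are written there
#' @return list with elements \code{genomes} (DNAStringSet),
#'   \code{pool} (named integer: genome -> group, 0 = shared),
#'   \code{samples} (named list: sample id -> character vector of
#'   reads) and \code{truth} (a \code{\link{PlantedTruth}})
#' @export
generateClusteredDataset <- function(spec, dir = NULL) {
    .assert(is(spec, "CommunitySpec"), "expected a CommunitySpec")
    .with_seed(spec@seed, {
        ng <- spec@nGenomes
        n_shared <- floor(spec@sharedFraction * ng)
        gids <- sprintf("g%03d", seq_len(ng))
        pool <- integer(ng)
        if (n_shared > 0) pool[seq_len(n_shared)] <- 0L
        own <- setdiff(seq_len(ng), seq_len(n_shared))
        pool[own] <- rep(seq_len(spec@nGroups), length.out = length(own))
        names(pool) <- gids
        genomes <- Biostrings::DNAStringSet(vapply(seq_len(ng), function(i)
            paste(sample(c("A", "C", "G", "T"), spec@genomeLength,
                         replace = TRUE,
                         prob = c((1 - spec@gc) / 2, spec@gc / 2,
                                  spec@gc / 2, (1 - spec@gc) / 2)),
                  collapse = ""), character(1)))
        names(genomes) <- gids
        sample_group <- rep(seq_len(spec@nGroups), length.out = spec@nSamples)
        sample_group <- sort(sample_group)
        sids <- sprintf("s%03d", seq_len(spec@nSamples))
        names(sample_group) <- sids
        ab <- matrix(0, spec@nSamples, ng, dimnames = list(sids, gids))
        samples <- vector("list", spec@nSamples)
        names(samples) <- sids
        origin <- vector("list", spec@nSamples)
        names(origin) <- sids
        gseq <- as.character(genomes)
        base_ab <- lapply(seq_len(spec@nGroups), function(g) {
            in_pool <- which(pool == g | pool == 0L)
            setNames(rlnorm(length(in_pool), meanlog = spec@mu,
                            sdlog = spec@sigma), gids[in_pool])
        })
        for (i in seq_len(spec@nSamples)) {
            in_pool <- which(pool == sample_group[i] | pool == 0L)
            a <- base_ab[[sample_group[i]]] *
                rlnorm(length(in_pool), meanlog = 0, sdlog = spec@sigmaWithin)
            a <- unname(a / sum(a))
            ab[i, in_pool] <- a
            sim <- simulateReads(setNames(gseq[in_pool], gids[in_pool]),
                                 a, spec@readsPerSample, spec@readLength,
                                 errorRate = spec@errorRate, seed = NULL,
                                 sampleId = sids[i])
            samples[[i]] <- sim$reads
            origin[[i]] <- sim$truth$genome_id
        }
        truth <- new("PlantedTruth", sampleGroup = sample_group,
                     abundances = ab, origin = origin)
        if (!is.null(dir)) {
            dir.create(dir, recursive = TRUE, showWarnings = FALSE)
            Biostrings::writeXStringSet(genomes,
                                        file.path(dir, "genomes.fasta"))
            for (i in seq_len(spec@nSamples))
                writeFastq(samples[[i]],
                           file.path(dir, paste0(sids[i], ".fastq.gz")))
            write.table(data.frame(sample_id = sids,
                                   path_r1 = paste0(sids, ".fastq.gz")),
                        file.path(dir, "manifest.tsv"), sep = "\t",
                        quote = FALSE, row.names = FALSE)
            write.table(data.frame(sample_id = sids,
                                   group = unname(sample_group)),
                        file.path(dir, "truth_groups.tsv"), sep = "\t",
                        quote = FALSE, row.names = FALSE)
            abdf <- data.frame(sample_id = rep(sids, each = ng),
                               genome_id = rep(gids, spec@nSamples),
                               abundance = as.vector(t(ab)))
            write.table(abdf, file.path(dir, "truth_abundances.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        }
        list(genomes = genomes, pool = pool, samples = samples,
             truth = truth)
    })
}

#' Synthetic panel of species and strains for dereplication tests
#'
#' Generates \code{nSpecies} unrelated ancestor genomes and, for each,
#' \code{nStrains} strains mutated from the ancestor so that pairwise
#' strain divergence lands in \code{intraRange} while inter-species
#' divergence stays at the random-sequence level (far above any ANI
#' threshold). Each strain is mutated at half its target pairwise
#' rate, because substitutions on two independent branches add.
#'
#' @param nSpecies,nStrains panel dimensions
#' @param genomeLength genome length in bp
#' @param intraRange pairwise intra-species divergence range
#' @param seed integer seed
#' @return list with \code{mags} (named list of character genomes,
#'   \code{spXX_stYY}), \code{species} (named character: bin ->
#'   species) and \code{quality} (data.frame with uniform HQ values)
#' @export
strainPanel <- function(nSpecies = 5L, nStrains = 3L,
                        genomeLength = 100000L,
                        intraRange = c(0.01, 0.03), seed = 1L) {
    .with_seed(seed, {
        mags <- list()
        species <- character()
        for (s in seq_len(nSpecies)) {
            anc <- paste(sample(c("A", "C", "G", "T"), genomeLength,
                                replace = TRUE), collapse = "")
            target <- runif(nStrains, intraRange[1], intraRange[2])
            for (st in seq_len(nStrains)) {
                id <- sprintf("sp%02d_st%02d", s, st)
                res <- .cpp_mutate_sequences(anc, target[st] / 2)
                mags[[id]] <- res$seq
                species[id] <- sprintf("sp%02d", s)
            }
        }
        quality <- data.frame(bin_id = names(mags),
                              completeness = 95, contamination = 1)
        list(mags = mags, species = species, quality = quality)
    })
}
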