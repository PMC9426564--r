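## Per-contig depth tables (the abundance input to binning) and
## per-genome breadth / abundance / prevalence metrics from read
## alignments. All coordinates are normalized to 0-based half-open
## intervals; per-base coverage counts each aligned reference span
## once, which is what depth summarizers measure.

#' Load read alignments as a table of reference intervals
#'
#' Accepts SAM/BAM (via Rsamtools; SAM is converted on the fly) or a
#' plain TSV with columns \code{query_id, target_id, start, end}
#' (0-based half-open; optional \code{mapq} and \code{is_primary}
#' columns are honoured). SAM 1-based POS plus the CIGAR's reference
#' span become \code{start = POS - 1}, \code{end = start + span}.
#' Unmapped records are dropped; with \code{primaryOnly} (default)
#' secondary and supplementary alignments are dropped too.
#'
#' @param path alignment file
#' @param format "auto" (by extension), "sam", "bam" or "tsv"
#' @param sampleId sample label attached to every interval
#' @param mapqMin minimum mapping quality (default 0: no filter)
#' @param primaryOnly keep primary alignments only (default TRUE)
#' @return data.frame with columns query_id, target_id, start, end,
#'   sample_id, is_primary, mapq
#' @export
loadAlignments <- function(path, format = c("auto", "sam", "bam", "tsv"),
                           sampleId = "sample", mapqMin = 0L,
                           primaryOnly = TRUE) {
    format <- match.arg(format)
    .assert(file.exists(path), "alignment file not found: ", path)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, sam = "sam", bam = "bam", "tsv")
    }
    if (format == "tsv") {
        df <- read.delim(path, stringsAsFactors = FALSE)
        .assert(all(c("query_id", "target_id", "start", "end") %in%
                    colnames(df)),
                "alignment TSV needs columns query_id, target_id, start, end")
        if (!"mapq" %in% colnames(df)) df$mapq <- 255L
        if (!"is_primary" %in% colnames(df)) df$is_primary <- TRUE
        out <- data.frame(query_id = as.character(df$query_id),
                          target_id = as.character(df$target_id),
                          start = as.integer(df$start),
                          end = as.integer(df$end),
                          sample_id = sampleId,
                          is_primary = as.logical(df$is_primary),
                          mapq = as.integer(df$mapq))
    } else {
        bam <- path
        if (format == "sam")
            bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                                    indexDestination = FALSE)
        res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
            what = c("qname", "rname", "pos", "mapq", "cigar", "flag")))[[1]]
        keep <- !is.na(res$pos) & bitwAnd(res$flag, 4L) == 0L
        res <- lapply(res, `[`, keep)
        span <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
        secondary <- bitwAnd(res$flag, 256L) != 0L
        supplementary <- bitwAnd(res$flag, 2048L) != 0L
        out <- data.frame(query_id = res$qname,
                          target_id = as.character(res$rname),
                          start = res$pos - 1L,
                          end = res$pos - 1L + span,
                          sample_id = sampleId,
                          is_primary = !(secondary | supplementary),
                          mapq = ifelse(is.na(res$mapq), 255L, res$mapq))
    }
    .assert(all(out$start >= 0 & out$end > out$start, na.rm = TRUE),
            "invalid interval coordinates (need 0 <= start < end)")
    if (primaryOnly) out <- out[out$is_primary, , drop = FALSE]
    out <- out[out$mapq >= mapqMin, , drop = FALSE]
    rownames(out) <- NULL
    out
}

## Mean and population variance of the per-base coverage of one target,
## from its intervals (0-based half-open) and length, via run-length
## coverage vectors.
.cov_stats <- function(starts, ends, len) {
    if (length(starts) == 0) return(c(mean = 0, var = 0, covered = 0))
    cov <- IRanges::coverage(IRanges::IRanges(start = starts + 1L, end = ends),
                             width = len)
    v <- S4Vectors::runValue(cov)
    w <- S4Vectors::runLength(cov)
    m <- sum(as.numeric(v) * w) / len
    va <- sum(w * (as.numeric(v) - m)^2) / len
    c(mean = m, var = va, covered = sum(w[v >= 1]))
}

.check_targets <- function(alignments, lengths) {
    unknown <- setdiff(unique(alignments$target_id), names(lengths))
    .assert(length(unknown) == 0,
            "alignments reference unknown target(s): ",
            paste(head(unknown, 5), collapse = ", "))
    over <- alignments$end > lengths[alignments$target_id]
    .assert(!any(over), "interval exceeds target length on: ",
            paste(head(unique(alignments$target_id[over]), 5), collapse = ", "))
}

#' Per-contig depth table across samples
#'
#' Accumulates per-base coverage per (contig, sample) and reports the
#' mean and population variance of the coverage vector. Contigs
#' shorter than \code{minContigLen} (default 1500 nt, the conventional
#' floor for contigs entering binning) are excluded; retained contigs
#' with no alignments report 0/0.
#'
#' @param alignments data.frame from \code{\link{loadAlignments}}
#'   (possibly several samples concatenated)
#' @param contigLengths named integer vector, contig id -> length
#' @param sampleIds column order of the output; defaults to the sorted
#'   sample ids present in \code{alignments}
#' @param minContigLen minimum contig length retained (default 1500)
#' @return a \code{\link{ContigDepthTable}}
#' @export
contigDepthTable <- function(alignments, contigLengths, sampleIds = NULL,
                             minContigLen = 1500L) {
    .assert(!is.null(names(contigLengths)), "contigLengths must be named")
    .check_targets(alignments, contigLengths)
    keep <- names(contigLengths)[contigLengths >= minContigLen]
    if (is.null(sampleIds))
        sampleIds <- sort(unique(alignments$sample_id))
    md <- matrix(0, length(keep), length(sampleIds))
    dv <- matrix(0, length(keep), length(sampleIds))
    al <- alignments[alignments$target_id %in% keep, , drop = FALSE]
    if (nrow(al)) {
        grp <- split(al, list(al$target_id, al$sample_id), drop = TRUE)
        for (g in grp) {
            i <- match(g$target_id[1], keep)
            j <- match(g$sample_id[1], sampleIds)
            if (is.na(j)) next
            st <- .cov_stats(g$start, g$end, contigLengths[[g$target_id[1]]])
            md[i, j] <- st[["mean"]]
            dv[i, j] <- st[["var"]]
        }
    }
    new("ContigDepthTable",
        contigs = data.frame(contig_id = keep,
                             length = as.integer(contigLengths[keep])),
        sampleIds = sampleIds, meanDepth = md, depthVariance = dv)
}

#' Per-genome breadth, depth and read recruitment per sample
#'
#' Breadth (horizontal coverage) is the fraction of genome positions
#' covered by at least one read; mean depth is total aligned bases over
#' genome length; the mapped read fraction is the number of distinct
#' mapped query ids over the sample's total read count (duplicate
#' alignments of one read add depth but count once for recruitment).
#' When a genome is split over contigs, pass \code{contigMap} (contig
#' id -> genome id) and \code{contigLengths}; the genome's positions
#' are then the union of its member contigs'.
#'
#' @param alignments data.frame from \code{\link{loadAlignments}}
#' @param genomeLengths named vector, genome id -> total length
#' @param readsPerSample named vector, sample id -> total reads (> 0)
#' @param contigMap optional named character, contig id -> genome id
#' @param contigLengths required with \code{contigMap}
#' @return data.frame with one row per (genome, sample):
#'   genome_id, sample_id, breadth, mean_depth, mapped_read_fraction
#' @export
genomeCoverage <- function(alignments, genomeLengths, readsPerSample,
                           contigMap = NULL, contigLengths = NULL) {
    .assert(!is.null(names(genomeLengths)), "genomeLengths must be named")
    .assert(all(genomeLengths > 0), "genome with zero length")
    .assert(!is.null(names(readsPerSample)) && all(readsPerSample > 0),
            "readsPerSample must be named and positive")
    if (!is.null(contigMap)) {
        .assert(!is.null(contigLengths),
                "contigLengths is required with contigMap")
        .check_targets(alignments, contigLengths)
    } else {
        .check_targets(alignments, genomeLengths)
    }
    genomes <- names(genomeLengths)
    samples <- names(readsPerSample)
    out <- expand.grid(genome_id = genomes, sample_id = samples,
                       stringsAsFactors = FALSE)
    out$breadth <- 0; out$mean_depth <- 0; out$mapped_read_fraction <- 0
    if (nrow(alignments)) {
        al <- alignments
        al$genome_id <- if (is.null(contigMap)) al$target_id else
            unname(contigMap[al$target_id])
        al <- al[!is.na(al$genome_id) & al$genome_id %in% genomes &
                 al$sample_id %in% samples, , drop = FALSE]
        grp <- split(al, list(al$genome_id, al$sample_id), drop = TRUE)
        for (g in grp) {
            gid <- g$genome_id[1]; sid <- g$sample_id[1]
            L <- genomeLengths[[gid]]
            if (is.null(contigMap)) {
                st <- .cov_stats(g$start, g$end, L)
                covered <- st[["covered"]]
                bases <- sum(as.numeric(g$end - g$start))
            } else {
                covered <- 0
                for (ct in unique(g$target_id)) {
                    gi <- g[g$target_id == ct, ]
                    st <- .cov_stats(gi$start, gi$end, contigLengths[[ct]])
                    covered <- covered + st[["covered"]]
                }
                bases <- sum(as.numeric(g$end - g$start))
            }
            i <- which(out$genome_id == gid & out$sample_id == sid)
            out$breadth[i] <- covered / L
            out$mean_depth[i] <- bases / L
            out$mapped_read_fraction[i] <-
                length(unique(g$query_id)) / readsPerSample[[sid]]
        }
    }
    out
}

#' Breadth-based genome detection
#'
#' A genome is called present in a sample when its breadth reaches
#' \code{breadthMin}. The boundary is inclusive (breadth of exactly
#' 0.30 counts as detected): a stated "minimum horizontal coverage of
#' 30\%" reads as >=.
#'
#' @param cov a \code{\link{genomeCoverage}} data.frame or a numeric
#'   vector of breadths
#' @param breadthMin detection threshold (default 0.3)
#' @return logical vector
#' @export
detectGenome <- function(cov, breadthMin = 0.3) {
    b <- if (is.data.frame(cov)) cov$breadth else cov
    b >= breadthMin
}

#' Prevalence and cumulative abundance per genome
#'
#' Prevalence is the number of samples in which the genome is detected
#' (breadth >= \code{breadthMin}); cumulative abundance is the sum over
#' samples of the percentage of mapped reads divided by the genome
#' length.
#'
#' @param covs \code{\link{genomeCoverage}} output covering all samples
#' @param genomeLengths named vector, genome id -> length
#' @param breadthMin detection threshold (default 0.3)
#' @return data.frame with columns genome_id, prevalence,
#'   cumulative_abundance
#' @export
prevalenceAbundance <- function(covs, genomeLengths, breadthMin = 0.3) {
    .assert(all(covs$genome_id %in% names(genomeLengths)),
            "genomeLengths must cover all genomes")
    det <- detectGenome(covs, breadthMin)
    prev <- tapply(det, covs$genome_id, sum)
    ab <- tapply(100 * covs$mapped_read_fraction, covs$genome_id, sum)
    gids <- names(prev)
    data.frame(genome_id = gids,
               prevalence = as.integer(prev),
               cumulative_abundance = as.numeric(ab[gids]) /
                   as.numeric(genomeLengths[gids]),
               row.names = NULL)
}
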