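## Expansion of the four assembly-binning strategies into concrete
## work plans. Naming follows the field's shorthand: SA/CA = single/
## coassembly, SB/CB = single-binning/cobinning. Single-binning maps
## only the samples that went into an assembly unit back onto it;
## cobinning maps every sample onto every unit (N^2 mapping jobs for
## SACB with N metagenomes, N x G for CACB with G coassembly groups).

.STRATEGIES <- c("SASB", "SACB", "CASB", "CACB")

#' Expand samples (and optionally a coassembly plan) into a strategy plan
#'
#' @param samples character vector of sample ids, or a manifest
#'   data.frame with a \code{sample_id} column
#' @param strategy one of "SASB", "SACB", "CASB", "CACB"
#' @param coassembly a \code{\link{CoassemblyPlan}}; required for
#'   CASB/CACB and checked to partition exactly the sample set
#' @return a \code{\link{StrategyPlan}}; unit ids are
#'   \code{single_<sample>} / \code{coasm_<group>} and the job list is
#'   deduplicated and sorted
#' @examples
#' planStrategy(c("s1", "s2", "s3", "s4"), "SACB")  # 4 units, 16 jobs
#' @export
planStrategy <- function(samples, strategy = .STRATEGIES, coassembly = NULL) {
    strategy <- match.arg(strategy, .STRATEGIES)
    if (is.data.frame(samples)) samples <- samples$sample_id
    .assert(is.character(samples) && length(samples) >= 1,
            "need at least one sample id")
    .assert(!anyDuplicated(samples), "duplicate sample ids")
    single_assembly <- strategy %in% c("SASB", "SACB")
    if (single_assembly) {
        units <- as.list(samples)
        names(units) <- paste0("single_", samples)
    } else {
        .assert(!is.null(coassembly),
                strategy, " requires a coassembly plan")
        .assert(is(coassembly, "CoassemblyPlan"), "expected a CoassemblyPlan")
        planned <- sort(unlist(coassembly@groups, use.names = FALSE))
        .assert(identical(planned, sort(samples)),
                "coassembly plan does not partition the sample set")
        units <- coassembly@groups
        names(units) <- paste0("coasm_", names(coassembly@groups))
    }
    cobinning <- strategy %in% c("SACB", "CACB")
    if (cobinning) {
        jobs <- expand.grid(sample_id = samples, unit_id = names(units),
                            stringsAsFactors = FALSE)
    } else {
        jobs <- data.frame(
            sample_id = unlist(units, use.names = FALSE),
            unit_id = rep(names(units), lengths(units)))
    }
    jobs <- unique(jobs)
    jobs <- jobs[order(jobs$unit_id, jobs$sample_id), , drop = FALSE]
    jobs <- data.frame(sample_id = jobs$sample_id, unit_id = jobs$unit_id)
    new("StrategyPlan", strategy = strategy, units = units,
        mappingJobs = jobs)
}

#' Write a strategy plan to a directory
#'
#' Emits \code{<strategy>_units.tsv} (strategy, unit_id, member_samples
#' semicolon-joined) and \code{<strategy>_jobs.tsv} (strategy,
#' sample_id, unit_id), both in stable sort order.
#'
#' @param plan a \code{\link{StrategyPlan}}
#' @param dir output directory (created if missing)
#' @return invisibly, the two file paths
#' @export
emitPlan <- function(plan, dir) {
    .assert(is(plan, "StrategyPlan"), "expected a StrategyPlan")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    units <- data.frame(
        strategy = plan@strategy,
        unit_id = names(plan@units),
        member_samples = vapply(plan@units, function(m)
            paste(sort(m), collapse = ";"), character(1)))
    units <- units[order(units$unit_id), , drop = FALSE]
    jobs <- cbind(strategy = plan@strategy, plan@mappingJobs)
    up <- file.path(dir, paste0(plan@strategy, "_units.tsv"))
    jp <- file.path(dir, paste0(plan@strategy, "_jobs.tsv"))
    write.table(units, up, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(jobs, jp, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(units = up, jobs = jp))
}

#' Read back a strategy plan written by \code{\link{emitPlan}}
#'
#' @param dir directory holding the two TSVs
#' @param strategy which strategy to load
#' @return a \code{\link{StrategyPlan}}
#' @export
readPlan <- function(dir, strategy = .STRATEGIES) {
    strategy <- match.arg(strategy, .STRATEGIES)
    up <- file.path(dir, paste0(strategy, "_units.tsv"))
    jp <- file.path(dir, paste0(strategy, "_jobs.tsv"))
    .assert(file.exists(up) && file.exists(jp),
            "plan files for ", strategy, " not found under ", dir)
    ut <- read.delim(up, stringsAsFactors = FALSE)
    jt <- read.delim(jp, stringsAsFactors = FALSE)
    units <- strsplit(ut$member_samples, ";", fixed = TRUE)
    names(units) <- ut$unit_id
    jobs <- jt[, c("sample_id", "unit_id")]
    jobs <- jobs[order(jobs$unit_id, jobs$sample_id), , drop = FALSE]
    rownames(jobs) <- NULL
    new("StrategyPlan", strategy = strategy, units = units,
        mappingJobs = jobs)
}
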