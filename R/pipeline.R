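## Run configuration and the end-to-end pipeline driver
## (distance -> cluster -> plan). Assembly and read mapping themselves
## are external: the pipeline's boundary is the emitted plan files and
## the alignment files it consumes downstream.

.CONFIG_DEFAULTS <- list(
    k = 21L, metric = "ab_jaccard", min_abundance = 1L,
    k_min = 2L, k_max = "auto", suboptimal_target = NULL,
    strategies = c("SASB", "SACB", "CASB", "CACB"),
    min_contig_len = 1500L, breadth_min = 0.3,
    ani_thresholds = c(0.95, 0.99), af_min = 0.6,
    seed = 1L, log_level = "info")

.validate_config <- function(cfg) {
    chk <- function(cond, key, why)
        .assert(cond, "invalid config value for '", key, "': ", why)
    chk(cfg$k >= 11 && cfg$k <= 31, "k", "must be in [11, 31]")
    chk(cfg$metric %in% c("ab_jaccard", "bray_curtis"), "metric",
        "must be ab_jaccard or bray_curtis")
    chk(cfg$min_abundance >= 1, "min_abundance", "must be >= 1")
    chk(cfg$k_min >= 2, "k_min", "must be >= 2")
    chk(identical(cfg$k_max, "auto") || cfg$k_max >= cfg$k_min, "k_max",
        "must be 'auto' or >= k_min")
    chk(cfg$min_contig_len >= 1, "min_contig_len", "must be >= 1")
    chk(cfg$breadth_min >= 0 && cfg$breadth_min <= 1, "breadth_min",
        "must be in [0, 1]")
    chk(all(cfg$ani_thresholds > 0 & cfg$ani_thresholds < 1),
        "ani_thresholds", "must be in (0, 1)")
    chk(cfg$af_min >= 0 && cfg$af_min < 1, "af_min", "must be in [0, 1)")
    chk(all(cfg$strategies %in% .STRATEGIES), "strategies",
        "must be among SASB, SACB, CASB, CACB")
    chk(cfg$log_level %in% c("debug", "info", "warning", "error"),
        "log_level", "unknown level")
    cfg
}

#' Load a run configuration
#'
#' Precedence: explicit overrides (CLI flags) > YAML file > defaults.
#' Unknown keys are an error listing the valid ones; every value is
#' validated against the preconditions of the module that consumes it.
#' Defaults carry the workflow's standard thresholds: k = 21,
#' min_contig_len = 1500, breadth_min = 0.3, ani_thresholds =
#' (0.95, 0.99), af_min = 0.6.
#'
#' @param path YAML file or NULL (all defaults)
#' @param overrides named list taking precedence over the file
#' @return validated config list
#' @export
loadConfig <- function(path = NULL, overrides = list()) {
    cfg <- .CONFIG_DEFAULTS
    apply_layer <- function(cfg, layer, src) {
        unknown <- setdiff(names(layer), names(.CONFIG_DEFAULTS))
        .assert(length(unknown) == 0,
                "unknown config key(s) in ", src, ": ",
                paste(unknown, collapse = ", "), "; valid keys: ",
                paste(names(.CONFIG_DEFAULTS), collapse = ", "))
        for (kk in names(layer)) cfg[[kk]] <- layer[[kk]]
        cfg
    }
    if (!is.null(path)) {
        .assert(file.exists(path), "config file not found: ", path)
        y <- yaml::read_yaml(path)
        if (!is.null(y)) cfg <- apply_layer(cfg, y, path)
    }
    cfg <- apply_layer(cfg, overrides, "overrides")
    for (kk in c("k", "min_abundance", "k_min", "min_contig_len", "seed"))
        cfg[[kk]] <- as.integer(cfg[[kk]])
    if (!identical(cfg$k_max, "auto")) cfg$k_max <- as.integer(cfg$k_max)
    .validate_config(cfg)
}

.stage_fresh <- function(outputs, inputs) {
    all(file.exists(outputs)) &&
        (length(inputs) == 0 ||
         min(file.mtime(outputs)) >= max(file.mtime(inputs)))
}

#' Run the coassembly-planning pipeline
#'
#' Executes distance -> cluster -> plan on the samples of a manifest,
#' writing \code{dist.tsv}, \code{silhouette.tsv}, \code{groups.tsv},
#' per-strategy plans under \code{plans/}, the resolved configuration
#' (\code{config.yaml}) and a machine-readable \code{run_summary.json}.
#' Reruns skip stages whose outputs are newer than their inputs.
#' Output files contain no timestamps, so two fresh runs with the same
#' seed are byte-identical.
#'
#' @param config list from \code{\link{loadConfig}}
#' @param manifest sample manifest path (TSV: sample_id, path_r1,
#'   optional path_r2); relative read paths resolve against the
#'   manifest's directory
#' @param outDir output directory
#' @return invisibly, the run summary list
#' @export
runPipeline <- function(config, manifest, outDir) {
    config <- .validate_config(utils::modifyList(.CONFIG_DEFAULTS, config,
                                                 keep.null = TRUE))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    samples <- readSampleManifest(manifest)
    read_files <- c(samples$path_r1, samples$path_r2)
    read_files <- read_files[!is.na(read_files)]
    .assert(all(file.exists(read_files)), "missing read file(s): ",
            paste(read_files[!file.exists(read_files)], collapse = ", "))

    cfg_path <- file.path(outDir, "config.yaml")
    yaml::write_yaml(config, cfg_path)
    summary <- list(tool = "coamag",
                    version = as.character(utils::packageVersion("coamag")),
                    config_md5 = unname(tools::md5sum(cfg_path)),
                    n_samples = nrow(samples), stages = list())
    stage <- function(name, outputs, inputs, run) {
        if (.stage_fresh(outputs, inputs)) {
            message("[", name, "] up to date, skipped")
            summary$stages[[name]] <<- "skipped"
        } else {
            ok <- tryCatch({ run(); TRUE },
                           error = function(e) {
                               stop("stage '", name, "' failed: ",
                                    conditionMessage(e), call. = FALSE)
                           })
            summary$stages[[name]] <<- "completed"
        }
    }
    dist_path <- file.path(outDir, "dist.tsv")
    stage("distance", dist_path, read_files, function() {
        dm <- pairwiseDistances(samples, k = config$k,
                                metric = config$metric,
                                minAbundance = config$min_abundance)
        writeDistanceMatrix(dm, dist_path)
    })
    sil_path <- file.path(outDir, "silhouette.tsv")
    grp_path <- file.path(outDir, "groups.tsv")
    stage("cluster", c(sil_path, grp_path), dist_path, function() {
        dm <- readDistanceMatrix(dist_path, metric = config$metric)
        n <- length(sampleIds(dm))
        kmax <- if (identical(config$k_max, "auto")) n - 1L else
            min(config$k_max, n - 1L)
        res <- findOptimalClustering(dm, kMin = config$k_min, kMax = kmax)
        if (!is.null(config$suboptimal_target))
            res <- findSuboptimalClustering(res, config$suboptimal_target)
        write.table(silhouetteCurve(res), sil_path, sep = "\t",
                    quote = FALSE, row.names = FALSE)
        writeCoassemblyManifest(coassemblyPlan(res), grp_path)
    })
    plan_dir <- file.path(outDir, "plans")
    plan_files <- file.path(plan_dir, c(
        paste0(config$strategies, "_units.tsv"),
        paste0(config$strategies, "_jobs.tsv")))
    stage("plan", plan_files, grp_path, function() {
        cplan <- readCoassemblyManifest(grp_path)
        for (s in config$strategies) {
            sp <- planStrategy(samples$sample_id, s,
                               coassembly = if (s %in% c("CASB", "CACB"))
                                   cplan else NULL)
            emitPlan(sp, plan_dir)
        }
    })
    jsonlite::write_json(summary, file.path(outDir, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(summary)
}
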