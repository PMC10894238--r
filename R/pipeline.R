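#' End-to-end pipeline: design -> simulate -> call -> stats -> logo
#'
#' A single configuration object drives the whole run; one global seed
#' governs all stochastic stages, every intermediate artifact lands on disk,
#' and the machine-readable report lists each emitted file with its MD5
#' checksum so that identical config + seed yields identical reports.
#'
#' @name pipeline_cli
NULL

#' Build a run configuration
#'
#' @param library Named list of [context_library_spec()] arguments.
#' @param simulation Named list of [read_sim_config()] arguments (seed is
#'   supplied by the run).
#' @param caller Named list: qmin, min_reads, max_umi_mismatch.
#' @param stats Named list: window_threshold, selectivity_positions, lod.
#' @param outdir Output directory.
#' @param seed Global integer seed.
#' @return A `RunConfig` object.
#' @export
run_config <- function(library = list(), simulation = list(),
                       caller = list(), stats = list(),
                       outdir = tempfile("beprofiler_run_"), seed = 1L) {
  defaults <- list(
    caller = list(qmin = 20L, min_reads = 100L, max_umi_mismatch = 1L),
    stats = list(window_threshold = 0.20, selectivity_positions = 4:8,
                 lod = 0.1)
  )
  caller <- utils::modifyList(defaults$caller, caller)
  stats <- utils::modifyList(defaults$stats, stats)
  structure(
    list(library = library, simulation = simulation, caller = caller,
         stats = stats, outdir = outdir, seed = as.integer(seed)),
    class = "RunConfig"
  )
}

#' Validate a run configuration
#'
#' Always returns; every violated invariant is reported with its field path.
#'
#' @param config A `RunConfig` (or bare list).
#' @return Character vector of violations; empty means ok.
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(path, msg) c(v, sprintf("%s: %s", path, msg))
  spec <- try(do.call(context_library_spec, config$library), silent = TRUE)
  if (inherits(spec, "try-error")) {
    v <- add("library", conditionMessage(attr(spec, "condition")))
    spec <- NULL
  }
  sim <- config$simulation
  for (nm in c("p_target", "p_cross", "error_rate", "indel_rate")) {
    if (!is.null(sim[[nm]]) && (any(is.na(sim[[nm]])) || any(sim[[nm]] < 0) ||
                                any(sim[[nm]] > 1))) {
      v <- add(paste0("simulation.", nm), "must lie in [0,1]")
    }
  }
  if (!is.null(sim$depth) && sim$depth < 0) v <- add("simulation.depth", "must be >= 0")
  if (!is.null(sim$replicates) && sim$replicates < 1) {
    v <- add("simulation.replicates", "must be >= 1")
  }
  if (!is.null(config$caller$qmin) && config$caller$qmin < 0) {
    v <- add("caller.qmin", "must be >= 0")
  }
  th <- config$stats$window_threshold
  if (!is.null(th) && (th <= 0 || th > 1)) {
    v <- add("stats.window_threshold", "must lie in (0,1]")
  }
  sp <- config$stats$selectivity_positions
  if (!is.null(sp) && !is.null(spec) &&
      (any(sp < 1) || any(sp > spec$protospacer_length))) {
    v <- add("stats.selectivity_positions", "outside the scored position range")
  }
  if (!is.null(config$stats$lod) && config$stats$lod <= 0) {
    v <- add("stats.lod", "must be > 0")
  }
  if (is.null(config$seed) || is.na(config$seed)) v <- add("seed", "required")
  v
}

#' Run the full pipeline
#'
#' Stages: enumerate the library, simulate reads, call edits per replicate,
#' aggregate, compute profiles / editing window / selectivity / context logo,
#' and write all artifacts plus a JSON report under `config$outdir`.
#'
#' @param config A [run_config()].
#' @return A `RunReport` list (also written as `report.json`): per-stage
#'   counts, parameters, headline statistics, and file checksums.
#' @export
run_pipeline <- function(config) {
  violations <- validate_config(config)
  if (length(violations)) {
    bep_config_error("invalid config:\n  %s", paste(violations, collapse = "\n  "))
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  spec <- do.call(context_library_spec, config$library)
  lib <- enumerate_context_library(spec, seed = config$seed)
  lib_files <- write_library(lib, outdir)

  sim_args <- config$simulation
  sim_args$seed <- config$seed
  sim_cfg <- do.call(read_sim_config, sim_args)
  sim <- simulate_reads(lib, sim_cfg, outdir = outdir)

  mats <- lapply(sim$reads, function(r) {
    call_edits(r, lib,
               qmin = config$caller$qmin,
               min_reads = config$caller$min_reads,
               lod = config$stats$lod,
               max_umi_mismatch = config$caller$max_umi_mismatch)
  })
  agg <- aggregate_replicates(mats)
  edit_files <- write_edit_matrix(agg, outdir)

  headline <- list()
  profiles <- list()
  for (tb in sort(spec$target_bases)) {
    conv <- if (tb == "C") "C>T" else "A>G"
    prof <- position_profile(agg, lib, conv, tb)
    profiles[[conv]] <- prof
    write_tsv(as.data.frame(prof),
              file.path(outdir, sprintf("profile_%s.tsv", sub(">", "2", conv))))
  }
  win <- NULL
  main_conv <- if ("C" %in% spec$target_bases) "C>T" else "A>G"
  if (nrow(profiles[[main_conv]]) && any(profiles[[main_conv]]$mean_pct > 0)) {
    win <- editing_window(profiles[[main_conv]], config$stats$window_threshold)
    jsonlite::write_json(unclass(win), file.path(outdir, "window.json"),
                         auto_unbox = TRUE, digits = NA)
    headline$window <- win
  }
  if (all(c("C>T", "A>G") %in% names(profiles))) {
    sp <- config$stats$selectivity_positions
    covered <- all(sp %in% profiles[["C>T"]]$position) &&
      all(sp %in% profiles[["A>G"]]$position)
    if (covered) {
      selv <- selectivity_ratio(profiles[["C>T"]], profiles[["A>G"]],
                                positions = sp, lod = config$stats$lod)
      jsonlite::write_json(unclass(selv), file.path(outdir, "selectivity.json"),
                           auto_unbox = TRUE, digits = NA)
      headline$selectivity <- selv
    }
  }
  if (!is.null(win)) {
    logo <- context_logo(agg, lib, win, conversion = main_conv)
    write_tsv(as.data.frame(logo), file.path(outdir, "logo.tsv"))
    headline$logo_total_ic <- sum(logo$ic)
  }

  files <- list.files(outdir, full.names = TRUE)
  files <- files[!basename(files) %in% "report.json"]
  checksums <- tools::md5sum(sort(files))
  names(checksums) <- basename(names(checksums))
  report <- list(
    stages = list(
      design = list(n_members = nrow(lib)),
      simulate = list(n_reads = sum(lengths(lapply(sim$reads, `[[`, "seq"))),
                      replicates = sim_cfg$replicates, depth = sim_cfg$depth),
      call = lapply(mats, function(m) attr(m, "summary")[c(
        "n_total", "n_assigned", "n_unassigned", "n_ambiguous")])
    ),
    parameters = list(library = unclass(spec),
                      simulation = unclass(sim_cfg),
                      caller = config$caller,
                      stats = config$stats,
                      seed = config$seed),
    headline = list(
      window = if (!is.null(headline$window)) unclass(headline$window),
      selectivity = if (!is.null(headline$selectivity))
        unclass(headline$selectivity),
      logo_total_ic = headline$logo_total_ic
    ),
    checksums = as.list(checksums)
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  report$edits <- agg
  report$library <- lib
  report$profiles <- profiles
  class(report) <- "RunReport"
  report
}

#' Read a run configuration from YAML (or JSON)
#' @param path Config file path.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(run_config, cfg)
}
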