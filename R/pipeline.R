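# End-to-end pipeline: generate -> titrate -> geometry -> landscape ->
# report, as one reproducible run with explicit seeds, plain-file stage
# outputs and a checksummed manifest. Every stage writes TSV/PDB so any
# stage can be re-run standalone on externally produced inputs.

#' Build and validate a run configuration
#'
#' @param conditions generator presets to run (see [preset_config()]).
#' @param n_replicates trajectories per condition.
#' @param n_frames frames per trajectory.
#' @param dt_ns frame spacing, ns.
#' @param equilibration_cutoff_ns equilibration cutoff for averages.
#' @param bins,range landscape grid parameters.
#' @param pH named list mapping pH labels to pH values for the titration
#'   stage.
#' @param titration list with `n_sites`, `pka_jitter_sd`, `dielectric`.
#' @param seed mandatory master seed; all stage seeds derive from it.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(conditions = c("high_pH_WT", "low_pH_WT"),
                       n_replicates = 2L, n_frames = 150L, dt_ns = 1,
                       equilibration_cutoff_ns = 50,
                       bins = 60L, range = c(2, 14),
                       pH = list(high = 7.4, low = 6.0),
                       titration = list(n_sites = 8L, pka_jitter_sd = 1.5,
                                        dielectric = 80),
                       seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("run_config requires an explicit seed")
  }
  known <- c("high_pH_WT", "low_pH_WT", "high_pH_H122N", "low_pH_H122N")
  bad <- setdiff(conditions, known)
  if (length(bad) > 0L) stop("unknown condition(s): ",
                             paste(bad, collapse = ", "))
  stopifnot(n_replicates >= 1L, n_frames >= 2L,
            equilibration_cutoff_ns >= 0,
            equilibration_cutoff_ns < (n_frames - 1) * dt_ns)
  structure(list(conditions = conditions,
                 n_replicates = as.integer(n_replicates),
                 n_frames = as.integer(n_frames), dt_ns = dt_ns,
                 equilibration_cutoff_ns = equilibration_cutoff_ns,
                 bins = as.integer(bins), range = range, pH = pH,
                 titration = titration, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Read a run configuration from a YAML or JSON file
#'
#' @param path config file; keys as in [run_config()].
#' @return `RunConfig`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$seed)) {
    stop("config validation failed: missing required 'seed'")
  }
  args <- raw[intersect(names(raw), names(formals(run_config)))]
  if (!is.null(args$pH)) args$pH <- as.list(args$pH)
  if (!is.null(args$titration)) args$titration <- as.list(args$titration)
  if (!is.null(args$range)) args$range <- as.numeric(args$range)
  do.call(run_config, args)
}

# per-frame distance metrics used by the pipeline's geometry stage
PAIR_METRICS <- list(
  d_E235_K246 = function(frame, chain)
    sidechain_com_distance(frame, c(chain, 235L), c(chain, 246L)),
  d_res122_E235 = function(frame, chain)
    sidechain_com_distance(frame, c(chain, 122L), c(chain, 235L))
)

stage_msg <- function(stage, t0, ...) {
  message(sprintf("[%s] %s (%.1f s)", stage, paste0(...),
                  as.numeric(proc.time()[3] - t0)))
}

#' Run the full pipeline
#'
#' Executes generate -> titrate -> geometry -> landscape -> report for
#' every configured condition, writing all stage outputs and a manifest
#' (config hash, package version, seeds, per-file checksums) under
#' `outdir`. Re-running with the same config reproduces every numeric
#' output bit for bit.
#'
#' @param config `RunConfig`.
#' @param outdir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "RunConfig"))
  t0 <- proc.time()[3]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  add <- function(path) files <<- c(files, path)
  fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  # -- generate -------------------------------------------------------
  trajs <- list()
  tryCatch({
    for (cond in config$conditions) {
      for (r in seq_len(config$n_replicates)) {
        seed_r <- derive_seed(config$seed, paste0(cond, ".", r))
        cfg <- preset_config(cond, n_frames = config$n_frames,
                             dt_ns = config$dt_ns, seed = seed_r,
                             replicate_id = paste0(cond, ".", r))
        traj <- simulate_conformational_trajectory(cfg)
        trajs[[paste0(cond, ".", r)]] <- traj
        stem <- file.path(outdir, paste0("traj_", cond, "_", r))
        write_trajectory(traj, paste0(stem, ".pdb"))
        write_table(attr(traj, "states"), paste0(stem, "_states.tsv"))
        add(paste0(stem, ".pdb")); add(paste0(stem, "_states.tsv"))
      }
    }
  }, error = function(e) fail("generate", e))
  stage_msg("generate", t0, length(trajs), " trajectories")

  # -- titrate --------------------------------------------------------
  tryCatch({
    tsys <- simulate_titration_system(
      n_sites = config$titration$n_sites,
      seed = derive_seed(config$seed, "titration"),
      pka_jitter_sd = config$titration$pka_jitter_sd,
      dielectric = config$titration$dielectric)
    write_site_table(tsys, file.path(outdir, "titration_sites.tsv"))
    add(file.path(outdir, "titration_sites.tsv"))
    for (lab in names(config$pH)) {
      res <- self_consistent_titration(tsys, pH = config$pH[[lab]])
      rpt <- res$report
      rpt$protonated <- res$protonation
      rpt$converged <- res$converged
      window <- select_pka_window(res$report)
      path <- file.path(outdir, paste0("pka_report_", lab, ".tsv"))
      write_table(as.data.frame(rpt), path); add(path)
      path <- file.path(outdir, paste0("pka_window_", lab, ".tsv"))
      write_table(as.data.frame(window), path); add(path)
    }
    for (variant in unique(sub("^(high|low)_pH_", "",
                               config$conditions))) {
      for (lab in c("high", "low")) {
        preset <- protonation_preset(lab, variant)
        path <- file.path(outdir,
                          paste0("protonation_", lab, "_", variant,
                                 ".tsv"))
        write_table(preset, path); add(path)
      }
    }
  }, error = function(e) fail("titrate", e))
  stage_msg("titrate", t0, "pKa reports at pH ",
            paste(unlist(config$pH), collapse = "/"))

  # -- geometry -------------------------------------------------------
  series <- list()
  tryCatch({
    for (nm in names(trajs)) {
      traj <- trajs[[nm]]
      s <- list(
        angle122 = metric_series(traj, "angle122",
          equilibration_cutoff_ns = config$equilibration_cutoff_ns),
        length = metric_series(traj, "length",
          equilibration_cutoff_ns = config$equilibration_cutoff_ns)
      )
      for (pm in names(PAIR_METRICS)) {
        s[[pm]] <- metric_series(traj, PAIR_METRICS[[pm]],
          equilibration_cutoff_ns = config$equilibration_cutoff_ns)
      }
      series[[nm]] <- s
      per_frame <- do.call(rbind, lapply(names(s), function(mn) {
        data.frame(metric = mn, s[[mn]])
      }))
      path <- file.path(outdir, paste0("metrics_", nm, ".tsv"))
      write_table(per_frame, path); add(path)
    }
    # replicate averages across trajectories
    rep_rows <- do.call(rbind, lapply(names(series), function(nm) {
      traj <- trajs[[nm]]
      do.call(rbind, lapply(names(series[[nm]]), function(mn) {
        pooling <- if (mn == "length") "channel" else "subunit"
        ra <- replicate_averages(series[[nm]][[mn]], pooling)
        data.frame(metric = mn,
                   pH_label = traj$condition$pH_label,
                   variant = traj$condition$variant,
                   ra)
      }))
    }))
    path <- file.path(outdir, "replicate_averages.tsv")
    write_table(rep_rows, path); add(path)
  }, error = function(e) fail("geometry", e))
  stage_msg("geometry", t0, "metric series for ", length(series),
            " trajectories")

  # -- landscape ------------------------------------------------------
  tryCatch({
    for (cond in config$conditions) {
      nms <- grep(paste0("^", cond, "\\."), names(series), value = TRUE)
      sx <- do.call(rbind, lapply(nms, function(nm)
        series[[nm]]$d_E235_K246))
      sy <- do.call(rbind, lapply(nms, function(nm)
        series[[nm]]$d_res122_E235))
      attr(sx, "equilibration_cutoff_ns") <- config$equilibration_cutoff_ns
      attr(sy, "equilibration_cutoff_ns") <- config$equilibration_cutoff_ns
      class(sx) <- class(sy) <- c("MetricSeries", "data.frame")
      grid <- paired_distance_grid(sx, sy, bins = config$bins,
                                   range = config$range)
      grid <- smooth_grid(grid)
      regions <- locate_regions(grid)
      path <- file.path(outdir, paste0("landscape_", cond, ".tsv"))
      write_table(landscape_table(grid), path); add(path)
      path <- file.path(outdir, paste0("landscape_", cond,
                                       "_smoothed.tsv"))
      write_table(landscape_table(grid, smoothed = TRUE), path); add(path)
      path <- file.path(outdir, paste0("regions_", cond, ".tsv"))
      write_table(regions$regions, path); add(path)
    }
  }, error = function(e) fail("landscape", e))
  stage_msg("landscape", t0, "grids for ",
            paste(config$conditions, collapse = ", "))

  # -- report ---------------------------------------------------------
  tryCatch({
    rep_rows <- read_table(file.path(outdir, "replicate_averages.tsv"))
    variants <- unique(rep_rows$variant)
    reps <- list()
    for (mn in unique(rep_rows$metric)) {
      reps[[mn]] <- list()
      for (v in variants) {
        grp <- list()
        for (lab in c("high", "low")) {
          sel <- rep_rows$metric == mn & rep_rows$variant == v &
            rep_rows$pH_label == lab
          if (sum(sel) >= 2L) grp[[lab]] <- rep_rows$mean_value[sel]
        }
        if (length(grp) == 2L) reps[[mn]][[v]] <- grp
      }
      if (length(reps[[mn]]) == 0L) reps[[mn]] <- NULL
    }
    if (length(reps) > 0L) {
      report <- condition_report(reps)
      path <- file.path(outdir, "condition_report.tsv")
      write_table(report, path); add(path)
    }
  }, error = function(e) fail("report", e))
  stage_msg("report", t0, "condition report")

  # -- manifest -------------------------------------------------------
  cfg_plain <- unclass(config)
  manifest <- list(
    package = "titrascape",
    version = as.character(utils::packageVersion("titrascape")),
    config = cfg_plain,
    config_hash = unname(tools::md5sum(
      write_tempfile(jsonlite::toJSON(cfg_plain, auto_unbox = TRUE)))),
    seed = config$seed,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

write_tempfile <- function(text) {
  f <- tempfile(fileext = ".json")
  writeLines(text, f)
  f
}
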