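## Run configuration and command entry points binding the pipeline stages.
## Each stage is re-entrant from on-disk intermediates (TIFF images, per-cell
## CSV tables), so real microscopy data can be inserted at any stage.

config_defaults <- function() {
  list(master_seed = 1L,
       out_dir = "darkbench_run",
       scenarios = c("pGFPamy@OD5", "AF_GFP@OD5"),
       pairs = list(list(ev = "pGFPamy@OD5", af = "AF_GFP@OD5")),
       promoter_pairs = list(list(fusion = "PrapE_Star@OD6",
                                  ev = "pGFP_Star@OD6")),
       n_cells = 3000,
       n_fields = 20,
       k_replicates = 1L,
       use_imaging = FALSE,
       field = list(),
       camera = list(),
       segmentation = list(),
       min_cells = 500,
       n_boot = 2000,
       alpha = 0.05)
}

#' Build or load a run configuration
#'
#' A run configuration is a named list over documented defaults: seed,
#' scenario selections, field/camera/segmentation parameters, benchmark
#' pairs, cell counts and replicate structure. It round-trips losslessly
#' through YAML.
#'
#' @param x `NULL` (defaults), a named list of overrides, or the path to a
#'   YAML file of overrides.
#' @return object of class `"run_config"`.
#' @export
#' @examples
#' cfg <- run_config(list(n_cells = 500, master_seed = 7))
run_config <- function(x = NULL) {
  defaults <- config_defaults()
  over <- if (is.null(x)) list()
          else if (is.character(x) && length(x) == 1) yaml::read_yaml(x)
          else if (is.list(x)) x
          else stop("`x` must be NULL, a list, or a YAML path", call. = FALSE)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; valid keys: ", paste(names(defaults), collapse = ", "),
         call. = FALSE)
  }
  # key-wise replacement (not modifyList: unnamed nested lists such as
  # `pairs` must be replaced wholesale, not merged)
  cfg <- defaults
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#' @param config a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_objects <- function(cfg) {
  list(spec = do.call(field_spec, cfg$field),
       camera = do.call(camera_model, cfg$camera))
}

log_stage <- function(stage, ...) {
  message(sprintf("[darkbench:%s] %s", stage, sprintf(...)))
}

#' Simulate image sets for the configured scenarios
#'
#' Renders `k_replicates` x `n_fields` brightfield/fluorescence/mask TIFF
#' triples plus ground-truth CSVs for every configured scenario, under
#' `out_dir/<condition>/<replicate>/field<N>_{bf,fl,mask}.tif`. Layout and
#' content are deterministic given the master seed.
#'
#' @param config a [run_config()] (or list/path accepted by it).
#' @return manifest data.frame (condition, replicate, field, path prefix),
#'   invisibly.
#' @export
cmd_simulate <- function(config = NULL) {
  cfg <- run_config(if (inherits(config, "run_config")) unclass(config)
                    else config)
  if (!length(cfg$scenarios)) {
    log_stage("simulate", "no scenarios configured; nothing to do")
    return(invisible(data.frame()))
  }
  obj <- config_objects(cfg)
  catalogue <- builtin_scenarios()
  manifest <- list()
  cond_seeds <- derive_seeds(cfg$master_seed, length(cfg$scenarios))
  for (ci in seq_along(cfg$scenarios)) {
    cond <- cfg$scenarios[ci]
    sc <- catalogue[[cond]]
    if (is.null(sc)) stop("unknown scenario '", cond, "'", call. = FALSE)
    rep_seeds <- derive_seeds(cond_seeds[ci], cfg$k_replicates)
    for (r in seq_len(cfg$k_replicates)) {
      run <- image_condition(sc, cfg$n_cells, cfg$n_fields, obj$spec,
                             obj$camera, seed = rep_seeds[r],
                             replicate_id = sprintf("r%d", r),
                             segment_params = cfg$segmentation)
      for (f in seq_along(run$fields)) {
        prefix <- file.path(cfg$out_dir, gsub("[^A-Za-z0-9_.-]", "_", cond),
                            sprintf("r%d", r), sprintf("field%03d", f))
        write_field_image(run$fields[[f]], prefix)
        manifest[[length(manifest) + 1L]] <-
          data.frame(condition = cond, replicate = r, field = f,
                     prefix = prefix)
      }
      log_stage("simulate", "%s r%d: %d cells placed over %d fields",
                cond, r, sum(vapply(run$populations, `[[`, 0L, "n")),
                length(run$fields))
    }
  }
  invisible(do.call(rbind, manifest))
}

# Pooled distributions for the configured conditions, via imaging or
# population-level simulation, or from a user-supplied per-cell CSV.
config_distributions <- function(cfg, conditions, cells_csv = NULL) {
  catalogue <- builtin_scenarios()
  if (!is.null(cells_csv)) {
    records <- utils::read.csv(cells_csv)
    need <- c("condition", "corrected_mean")
    if (!all(need %in% names(records))) {
      stop("per-cell CSV must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (!"replicate_id" %in% names(records)) records$replicate_id <- "r1"
    out <- lapply(conditions, function(cond) {
      sub <- records[records$condition == cond, , drop = FALSE]
      if (!nrow(sub)) stop("condition '", cond, "' missing from ", cells_csv,
                           call. = FALSE)
      pool_condition(sub, min_cells = cfg$min_cells)
    })
    return(stats::setNames(out, conditions))
  }
  obj <- config_objects(cfg)
  seeds <- derive_seeds(cfg$master_seed, length(conditions))
  out <- lapply(seq_along(conditions), function(i) {
    cond <- conditions[i]
    sc <- catalogue[[cond]]
    if (is.null(sc)) stop("unknown scenario '", cond, "'", call. = FALSE)
    if (cfg$use_imaging) {
      run <- image_condition(sc, cfg$n_cells, cfg$n_fields, obj$spec,
                             obj$camera, seed = seeds[i],
                             segment_params = cfg$segmentation)
      d <- pool_condition(run$records, min_cells = cfg$min_cells)
    } else {
      d <- population_distribution(sc, cfg$n_cells, seeds[i])
    }
    log_stage("quantify", "%s: %d cells pooled", cond, d$n)
    d
  })
  stats::setNames(out, conditions)
}

#' Run the configured benchmark comparisons and write the report
#'
#' For every `pairs` entry (empty vector vs autofluorescence reference)
#' computes D and S with bootstrap uncertainty and writes the report CSV.
#' Inputs come from the built-in scenario catalogue (population-level, or
#' through the imaging pipeline when `use_imaging` is set), or from a
#' user-supplied per-cell CSV (columns `condition`, `corrected_mean`, and
#' optionally `replicate_id`), bypassing simulation entirely.
#'
#' @param config a [run_config()] (or list/path accepted by it).
#' @param cells_csv optional path to a per-cell CSV.
#' @param report_path output CSV path; default `out_dir/benchmark_report.csv`.
#' @return the report data.frame, invisibly.
#' @export
cmd_benchmark <- function(config = NULL, cells_csv = NULL,
                          report_path = NULL) {
  cfg <- run_config(if (inherits(config, "run_config")) unclass(config)
                    else config)
  if (!length(cfg$pairs)) stop("no benchmark pairs configured", call. = FALSE)
  conds <- unique(unlist(lapply(cfg$pairs, function(p) c(p$ev, p$af))))
  for (p in cfg$pairs) {
    if (is.null(p$af)) stop("benchmark pair without AF reference condition",
                            call. = FALSE)
  }
  dists <- config_distributions(cfg, conds, cells_csv)
  boot_seeds <- derive_seeds(cfg$master_seed + 1L, length(cfg$pairs))
  rows <- lapply(seq_along(cfg$pairs), function(i) {
    p <- cfg$pairs[[i]]
    ev <- dists[[p$ev]]; af <- dists[[p$af]]
    if (ev$n < cfg$min_cells || af$n < cfg$min_cells) {
      log_stage("benchmark", "WARNING %s vs %s: below min_cells = %d",
                p$ev, p$af, cfg$min_cells)
    }
    ds <- compute_ds(ev, af, n_boot = cfg$n_boot, seed = boot_seeds[i])
    sc <- builtin_scenarios()[[p$ev]]
    list(vector = sub("@.*$", "", p$ev),
         channel = if (!is.null(sc)) sc$channel else NA_character_,
         od600 = if (!is.null(sc)) sc$od600 else NA_real_,
         results = list(ds))
  })
  if (is.null(report_path)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    report_path <- file.path(cfg$out_dir, "benchmark_report.csv")
  }
  rep <- benchmark_report(rows, report_path)
  log_stage("benchmark", "report written to %s (%d rows)", report_path,
            nrow(rep))
  invisible(rep)
}

#' Run the configured promoter assays and write the reports
#'
#' For every `promoter_pairs` entry (promoter fusion vs matched empty-vector
#' control) runs interference detection, moment deconvolution and, when the
#' additive model holds, density deconvolution; writes
#' `promoter_report.csv` (+ one density CSV per additive pair).
#'
#' @param config a [run_config()] (or list/path accepted by it).
#' @param cells_csv optional path to a per-cell CSV (as in
#'   [cmd_benchmark()]).
#' @return list of per-pair results (`interference`, `moments`, `density`),
#'   invisibly.
#' @export
cmd_promoter <- function(config = NULL, cells_csv = NULL) {
  cfg <- run_config(if (inherits(config, "run_config")) unclass(config)
                    else config)
  if (!length(cfg$promoter_pairs)) {
    stop("no promoter pairs configured", call. = FALSE)
  }
  conds <- unique(unlist(lapply(cfg$promoter_pairs,
                                function(p) c(p$fusion, p$ev))))
  dists <- config_distributions(cfg, conds, cells_csv)
  seeds <- derive_seeds(cfg$master_seed + 2L, length(cfg$promoter_pairs))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- lapply(seq_along(cfg$promoter_pairs), function(i) {
    p <- cfg$promoter_pairs[[i]]
    fusion <- dists[[p$fusion]]; ev <- dists[[p$ev]]
    ir <- detect_interference(fusion, ev, n_boot = cfg$n_boot,
                              alpha = cfg$alpha, seed = seeds[i])
    mom <- suppressWarnings(deconvolve_moments(fusion, ev))
    dens <- NULL
    if (mom$valid && fusion$n >= 100 && ev$n >= 100) {
      dens <- deconvolve_density(fusion, ev)
      write_density_csv(dens, file.path(cfg$out_dir,
        sprintf("density_%s.csv", gsub("[^A-Za-z0-9_.-]", "_", p$fusion))))
    }
    log_stage("promoter", "%s vs %s: %s (delta_mu = %.2f AU)",
              p$fusion, p$ev, ir$verdict, ir$delta_mu)
    list(interference = ir, moments = mom, density = dens)
  })
  irs <- lapply(out, `[[`, "interference")
  write_interference_csv(irs, file.path(cfg$out_dir, "promoter_report.csv"))
  invisible(out)
}
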