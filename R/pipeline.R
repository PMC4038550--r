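## End-to-end experiment drivers: population-level (imaging bypassed) and
## full synthetic-imaging benchmarking experiments.

#' Population-level intensity distribution for a scenario
#'
#' Simulates `n` cells and returns their total fluorescence directly as an
#' intensity distribution, bypassing imaging. This is the generative truth
#' that the imaging pipeline should recover.
#'
#' @param scenario a [scenario()].
#' @param n number of cells.
#' @param seed integer seed.
#' @param replicate_id replicate label.
#' @return an [intensity_distribution()].
#' @export
population_distribution <- function(scenario, n, seed = 1L,
                                    replicate_id = "r1") {
  pop <- simulate_population(scenario, n, seed, replicate_id)
  intensity_distribution(pop$total_values, scenario$name, replicate_id)
}

#' Simulate, render and quantify one condition through the imaging pipeline
#'
#' Splits `n_cells` over `n_fields` synthetic fields: simulates the
#' population, places and renders cells with the camera model, segments the
#' brightfield, estimates and subtracts the fluorescence background, and
#' measures per-cell corrected means. Fewer than `n_cells` records may be
#' returned when fields saturate or segmentation drops cells.
#'
#' @param scenario a [scenario()].
#' @param n_cells target number of cells for the condition.
#' @param n_fields number of fields to spread them over.
#' @param spec a [field_spec()] (its `n_cells_target` is overridden).
#' @param camera a [camera_model()].
#' @param seed master seed for this condition; per-field seeds are derived
#'   with [derive_seeds()].
#' @param replicate_id replicate label.
#' @param segment_params list of arguments for [segment_brightfield()].
#' @param use_truth_mask quantify over the ground-truth mask instead of the
#'   segmented mask (for calibration checks).
#' @return list with `records` (per-cell data.frame), `fields` (list of
#'   [render_field()] objects), `populations`.
#' @export
image_condition <- function(scenario, n_cells = 3000, n_fields = 20,
                            spec = field_spec(), camera = camera_model(),
                            seed = 1L, replicate_id = "r1",
                            segment_params = list(),
                            use_truth_mask = FALSE) {
  stopifnot(inherits(scenario, "scenario"))
  per_field <- ceiling(n_cells / n_fields)
  seeds <- matrix(derive_seeds(seed, 3L * n_fields), ncol = 3)
  records <- vector("list", n_fields)
  fields <- vector("list", n_fields)
  pops <- vector("list", n_fields)
  for (f in seq_len(n_fields)) {
    geoms <- place_cells(spec, per_field, seed = seeds[f, 1])
    pop <- simulate_population(scenario, nrow(geoms), seed = seeds[f, 2],
                               replicate_id = replicate_id)
    fi <- render_field(pop$total_values, geoms, spec, camera,
                       seed = seeds[f, 3])
    mask <- if (use_truth_mask) {
      label_mask(fi$truth_mask, list(source = "truth"))
    } else {
      do.call(segment_brightfield, c(list(fi$brightfield), segment_params))
    }
    bg <- estimate_background(fi$fluorescence, mask)
    rec <- measure_cells(mask, fi$fluorescence, bg, gain = camera$gain,
                         field_id = sprintf("f%03d", f),
                         replicate_id = replicate_id,
                         condition = scenario$name)
    records[[f]] <- rec
    fields[[f]] <- fi
    pops[[f]] <- pop
  }
  list(records = do.call(rbind, records), fields = fields, populations = pops)
}

#' Run a full synthetic-image benchmarking experiment
#'
#' Renders and analyzes matched empty-vector and autofluorescence conditions
#' through the complete chain (simulate -> render -> segment -> background
#' subtract -> quantify -> pool -> D/S).
#'
#' @param ev_scenario,af_scenario [scenario()] objects for the empty-vector
#'   strain and the untransformed (autofluorescence) reference.
#' @param n_cells target cells per condition.
#' @param n_fields fields per condition.
#' @param spec,camera imaging model, see [field_spec()], [camera_model()].
#' @param seed master seed; EV and AF conditions get independent derived
#'   seeds.
#' @param n_boot bootstrap resamples for [compute_ds()].
#' @param min_cells low-n warning threshold for [pool_condition()].
#' @param ... passed to [image_condition()] (e.g. `segment_params`).
#' @return list with `ds` ([compute_ds()] result), `ev`, `af`
#'   (intensity distributions), `ev_run`, `af_run` (full
#'   [image_condition()] outputs).
#' @export
run_benchmark_experiment <- function(ev_scenario, af_scenario,
                                     n_cells = 3000, n_fields = 20,
                                     spec = field_spec(),
                                     camera = camera_model(),
                                     seed = 1L, n_boot = 2000,
                                     min_cells = 500, ...) {
  seeds <- derive_seeds(seed, 3)
  ev_run <- image_condition(ev_scenario, n_cells, n_fields, spec, camera,
                            seed = seeds[1], ...)
  af_run <- image_condition(af_scenario, n_cells, n_fields, spec, camera,
                            seed = seeds[2], ...)
  ev <- pool_condition(ev_run$records, min_cells = min_cells)
  af <- pool_condition(af_run$records, min_cells = min_cells)
  list(ds = compute_ds(ev, af, n_boot = n_boot, seed = seeds[3]),
       ev = ev, af = af, ev_run = ev_run, af_run = af_run)
}

#' Population-level D/S benchmark of a catalogued scenario
#'
#' Bypasses imaging: simulates the EV and matched AF populations directly
#' and computes D and S.
#'
#' @param ev_scenario an empty-vector [scenario()].
#' @param af_scenario matched AF [scenario()]; default: the channel baseline
#'   at the same OD.
#' @param n cells per condition.
#' @param seed master seed.
#' @param n_boot bootstrap resamples.
#' @return a [compute_ds()] result.
#' @export
benchmark_population <- function(ev_scenario, af_scenario = NULL,
                                 n = 1e5, seed = 1L, n_boot = 2000) {
  if (is.null(af_scenario)) {
    af_scenario <- af_scenario_for(ev_scenario)
  }
  seeds <- derive_seeds(seed, 3)
  ev <- population_distribution(ev_scenario, n, seeds[1])
  af <- population_distribution(af_scenario, n, seeds[2])
  compute_ds(ev, af, n_boot = n_boot, seed = seeds[3])
}

# Matched AF reference scenario (same channel baseline and OD).
af_scenario_for <- function(sc) {
  scenario(sprintf("AF_%s@OD%g", sc$channel, sc$od600),
           channel = sc$channel, od600 = sc$od600,
           af_mean = sc$af_mean, af_sd = sc$af_sd)
}
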