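## Built-in scenario catalogue, calibrated from the published D/S benchmark
## values of the pXFPamy / pGFPbglS / pUA139 empty vectors and the
## terminator-buffered pXFP_Star family.

#' Published D/S benchmark values used for calibration
#'
#' The printed benchmark rows for the terminator-less empty vectors (backbone
#' panel, stationary phase), the growth series of pGFPamy / pGFP_Star, and
#' the pXFP_Star family. Uncertainties are the printed +/- values (treated as
#' SEM across replicate experiments); `NA` where none was printed.
#'
#' @return data.frame with columns `vector`, `channel`, `host`, `od600`,
#'   `D`, `D_unc`, `S`, `S_unc`, `group`.
#' @export
reference_ds_table <- function() {
  df <- read.csv(text =
"vector,channel,host,od600,D,D_unc,S,S_unc,group
pGFPamy,GFP,B. subtilis,5,2.13,0.20,2.15,0.39,backbone
pYFPamy,YFP,B. subtilis,5,1.87,0.12,2.69,0.18,backbone
pCFPamy,CFP,B. subtilis,5,1.16,0.08,1.21,0.09,backbone
pGFPbglS,GFP,B. subtilis,5,1.47,0.07,1.46,0.13,backbone
pUA139,GFP,E. coli,4,1.22,NA,1.25,NA,backbone
pGFPamy,GFP,B. subtilis,0.3,1.25,0.11,1.31,0.20,growth
pGFPamy,GFP,B. subtilis,3,1.51,0.06,1.37,0.04,growth
pGFP_Star,GFP,B. subtilis,0.3,1.01,0.05,1.05,0.05,growth
pGFP_Star,GFP,B. subtilis,3,1.02,0.03,0.97,0.05,growth
pGFP_Star,GFP,B. subtilis,5,1.07,0.10,0.97,0.14,star
pYFP_Star,YFP,B. subtilis,5,1.05,0.06,1.10,0.07,star
pCFP_Star,CFP,B. subtilis,5,0.87,0.06,0.98,0.07,star
", stringsAsFactors = FALSE)
  df
}

#' Default per-channel autofluorescence baselines
#'
#' Channels differ in cellular autofluorescence (different excitation bands
#' and exposure); GFP is the reference at 100 AU mean / 25 AU SD, YFP and CFP
#' scale it by 0.5 and 1.5. The absolute scale is arbitrary: the D and S
#' ratios are baseline-independent.
#'
#' @return named list (`GFP`, `YFP`, `CFP`), each with `af_mean`, `af_sd`.
#' @export
default_af_baselines <- function() {
  list(GFP = list(af_mean = 100, af_sd = 25),
       YFP = list(af_mean = 50,  af_sd = 12.5),
       CFP = list(af_mean = 150, af_sd = 37.5))
}

#' Autofluorescence scenario for a channel
#'
#' @param channel `"GFP"`, `"YFP"` or `"CFP"`.
#' @param od600 growth-phase tag.
#' @param af_baselines per-channel baselines, see [default_af_baselines()].
#' @return an AF [scenario()] (no spurious, no promoter component).
#' @export
af_scenario <- function(channel = "GFP", od600 = 5,
                        af_baselines = default_af_baselines()) {
  base <- af_baselines[[channel]]
  if (is.null(base)) stop("no AF baseline for channel ", channel, call. = FALSE)
  scenario(sprintf("AF_%s@OD%g", channel, od600), channel = channel,
           od600 = od600, af_mean = base$af_mean, af_sd = base$af_sd)
}

# Calibrate one empty-vector scenario from a printed (D, S) row. Sub-unity
# printed values are clamped to the ideal reporter (suppressWarnings: the
# clamp is intended here, not a user mistake).
calibrated_ev <- function(name, channel, od600, d, s, readthrough,
                          af_baselines) {
  base <- af_baselines[[channel]]
  cal <- suppressWarnings(
    calibrate_from_ds(base$af_mean, base$af_sd, d, s))
  scenario(name, channel = channel, od600 = od600,
           af_mean = base$af_mean, af_sd = base$af_sd,
           spur_mean = cal$spur_mean, spur_sd = cal$spur_sd,
           readthrough = readthrough)
}

#' Built-in scenario catalogue
#'
#' One calibrated scenario per published benchmark row, plus matched
#' autofluorescence references and the rapE promoter-fusion scenarios.
#'
#' Empty-vector scenarios of the terminator-less vectors (`readthrough = 1`)
#' carry a spurious component calibrated so that forward simulation
#' reproduces the printed (D, S). Star-family scenarios share the parent
#' vector's spurious component but have `readthrough = 0`: the terminator
#' blocks spurious transcripts, so their asymptotic D = S = 1 (printed Star
#' values near 1 are treated as sampling fluctuation around this ideal).
#'
#' The rapE fusion scenarios are illustrative (the source histograms carry no
#' printed axis values): at OD 2.5 the promoter is repressed; at OD 6 it is
#' weakly active with promoter mean equal to one AF SD. The terminator-less
#' fusion (`PrapE_amy`) has interference suppression factors < 1, so its mean
#' falls below its empty-vector control; the Star fusion is purely additive.
#'
#' @param af_baselines per-channel AF baselines, see [default_af_baselines()].
#' @return named list of [scenario()] objects.
#' @seealso [builtin_scenario()] for single lookup.
#' @export
#' @examples
#' names(builtin_scenarios())
builtin_scenarios <- function(af_baselines = default_af_baselines()) {
  tab <- reference_ds_table()
  out <- list()

  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    star <- grepl("_Star", row$vector)
    nm <- sprintf("%s@OD%g", row$vector, row$od600)
    if (star) {
      # mechanistic model: parent spurious component, terminator closed
      parent <- sub("_Star", "amy", row$vector)
      pr <- tab[tab$vector == parent & tab$od600 == row$od600, ]
      if (nrow(pr) == 1) {
        out[[nm]] <- calibrated_ev(nm, row$channel, row$od600,
                                   pr$D, pr$S, readthrough = 0, af_baselines)
      } else {
        # no printed parent row at this OD: clamp to ideal via printed values
        out[[nm]] <- calibrated_ev(nm, row$channel, row$od600,
                                   row$D, row$S, readthrough = 0, af_baselines)
      }
    } else {
      out[[nm]] <- calibrated_ev(nm, row$channel, row$od600,
                                 row$D, row$S, readthrough = 1, af_baselines)
    }
  }

  # AF references for every channel x OD present
  for (i in seq_len(nrow(tab))) {
    nm <- sprintf("AF_%s@OD%g", tab$channel[i], tab$od600[i])
    if (is.null(out[[nm]])) {
      out[[nm]] <- af_scenario(tab$channel[i], tab$od600[i], af_baselines)
    }
  }

  # rapE promoter assay (GFP): empty-vector controls at the assay ODs reuse
  # the nearest benchmarked growth-phase calibration (OD3 -> OD2.5,
  # OD5 -> OD6); fusions add a promoter component.
  base <- af_baselines$GFP
  ev_mid <- calibrate_from_ds(base$af_mean, base$af_sd, 1.51, 1.37)
  ev_stat <- calibrate_from_ds(base$af_mean, base$af_sd, 2.13, 2.15)
  prom_on <- list(mean = base$af_sd, sd = 0.6 * base$af_sd)

  mk <- function(name, od, ev, rt, prom_mean, prom_sd,
                 gamma = 1, cv = 0) {
    scenario(name, channel = "GFP", od600 = od,
             af_mean = base$af_mean, af_sd = base$af_sd,
             spur_mean = ev$spur_mean, spur_sd = ev$spur_sd,
             readthrough = rt, prom_mean = prom_mean, prom_sd = prom_sd,
             gamma_s = gamma, gamma_p = gamma,
             interference_extra_cv = cv)
  }
  out[["pGFPamy@OD2.5"]]   <- mk("pGFPamy@OD2.5", 2.5, ev_mid, 1, 0, 0)
  out[["pGFPamy@OD6"]]     <- mk("pGFPamy@OD6", 6, ev_stat, 1, 0, 0)
  out[["pGFP_Star@OD2.5"]] <- mk("pGFP_Star@OD2.5", 2.5, ev_mid, 0, 0, 0)
  out[["pGFP_Star@OD6"]]   <- mk("pGFP_Star@OD6", 6, ev_stat, 0, 0, 0)
  # repressed promoter still collides with spurious transcription (slight
  # suppression); active promoter interferes strongly with it
  out[["PrapE_amy@OD2.5"]] <- mk("PrapE_amy@OD2.5", 2.5, ev_mid, 1,
                                 prom_mean = 2, prom_sd = 2,
                                 gamma = 0.8, cv = 0.15)
  out[["PrapE_amy@OD6"]]   <- mk("PrapE_amy@OD6", 6, ev_stat, 1,
                                 prom_mean = prom_on$mean,
                                 prom_sd = prom_on$sd,
                                 gamma = 0.5, cv = 0.3)
  out[["PrapE_Star@OD2.5"]] <- mk("PrapE_Star@OD2.5", 2.5, ev_mid, 0, 0, 0)
  out[["PrapE_Star@OD6"]]   <- mk("PrapE_Star@OD6", 6, ev_stat, 0,
                                  prom_mean = prom_on$mean,
                                  prom_sd = prom_on$sd)

  out[["AF_GFP@OD2.5"]] <- af_scenario("GFP", 2.5, af_baselines)
  out[["AF_GFP@OD6"]]   <- af_scenario("GFP", 6, af_baselines)
  out
}

#' Look up a built-in scenario by name
#'
#' @param name catalogue name, e.g. `"pGFPamy@OD5"`.
#' @param af_baselines per-channel AF baselines.
#' @return a [scenario()].
#' @export
#' @examples
#' builtin_scenario("pGFP_Star@OD5")$readthrough  # 0: terminator closed
builtin_scenario <- function(name, af_baselines = default_af_baselines()) {
  cat_ <- builtin_scenarios(af_baselines)
  if (is.null(cat_[[name]])) {
    stop(sprintf("unknown scenario '%s'; valid names are:\n  %s",
                 name, paste(names(cat_), collapse = ", ")), call. = FALSE)
  }
  cat_[[name]]
}

## YAML serialization --------------------------------------------------------

#' Write a scenario catalogue to a YAML file
#'
#' The schema is a map of scenario name to parameter map (all [scenario()]
#' fields). Round-trips losslessly through [read_scenarios_yaml()].
#'
#' @param scenarios named list of [scenario()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scenarios_yaml <- function(scenarios, path) {
  if (inherits(scenarios, "scenario")) {
    scenarios <- stats::setNames(list(scenarios), scenarios$name)
  }
  payload <- lapply(scenarios, function(sc) unclass(sc))
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' Read a scenario catalogue from a YAML file
#'
#' @param path YAML file written by [write_scenarios_yaml()] (or hand-edited
#'   with the same schema).
#' @return named list of [scenario()] objects.
#' @export
read_scenarios_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(p) do.call(scenario, p))
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}
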