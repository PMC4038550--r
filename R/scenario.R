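#' Define a reporter-strain fluorescence scenario
#'
#' A scenario parameterizes the generative model of per-cell fluorescence for
#' one strain x channel x growth phase. Total per-cell fluorescence is the
#' dark-noise decomposition
#' \deqn{F_i = A_i + \rho\, g_{s,i} X_{s,i} + g_{p,i} X_{p,i}}
#' where \eqn{A_i} is cellular autofluorescence (general dark noise),
#' \eqn{X_{s,i}} is expression from spurious upstream transcripts at full
#' terminator read-through (specific dark noise), \eqn{\rho} is the
#' terminator read-through fraction, and \eqn{X_{p,i}} is the promoter-driven
#' signal. \eqn{g_{s,i}, g_{p,i}} are realized interference suppression
#' factors (see Details). All components are gamma-distributed with the
#' stated means and standard deviations, in arbitrary fluorescence units
#' (AU).
#'
#' @details
#' When both the spurious pathway is open (`readthrough > 0`,
#' `spur_mean > 0`) and the promoter is active (`prom_mean > 0`) the two
#' transcription processes may interfere rather than add. This is modelled
#' multiplicatively: \eqn{g_{s,i} = \gamma_s L_i} and
#' \eqn{g_{p,i} = \gamma_p L_i} with \eqn{L_i} lognormal with mean 1 and
#' coefficient of variation `interference_extra_cv`. The defaults
#' (`gamma_s = gamma_p = 1`, `interference_extra_cv = 0`) give pure
#' additivity. The suppression factors are a phenomenological stand-in for
#' transcriptional interference, which lowers the fusion mean below the
#' empty-vector mean and broadens its relative spread; no mechanistic claim
#' (roadblock, occlusion, collision) is made.
#'
#' @param name label, e.g. `"pGFPamy@OD5"`.
#' @param channel one of `"GFP"`, `"YFP"`, `"CFP"`.
#' @param od600 growth-phase tag (culture optical density at harvest).
#' @param af_mean,af_sd autofluorescence mean and SD (AU, >= 0).
#' @param spur_mean,spur_sd spurious-transcription component mean and SD at
#'   full read-through (AU, >= 0).
#' @param readthrough terminator read-through fraction in [0, 1]; ~1 for
#'   terminator-less vectors, ~0 for terminator-buffered ("Star") vectors.
#' @param prom_mean,prom_sd promoter-driven component mean and SD (AU, >= 0);
#'   both 0 for empty-vector and autofluorescence scenarios.
#' @param gamma_s,gamma_p interference suppression factors in [0, 1] applied
#'   to the spurious and promoter components when both are active.
#' @param interference_extra_cv extra multiplicative noise (CV >= 0) applied
#'   under interference.
#' @return an object of class `"scenario"`.
#' @seealso [simulate_population()], [calibrate_from_ds()],
#'   [builtin_scenarios()]
#' @export
#' @examples
#' af <- scenario("AF", af_mean = 100, af_sd = 25)
#' ev <- scenario("pGFPamy@OD5", af_mean = 100, af_sd = 25,
#'                spur_mean = 113, spur_sd = 19, readthrough = 1)
scenario <- function(name,
                     channel = c("GFP", "YFP", "CFP"),
                     od600 = 5,
                     af_mean = 100, af_sd = 25,
                     spur_mean = 0, spur_sd = 0,
                     readthrough = 1,
                     prom_mean = 0, prom_sd = 0,
                     gamma_s = 1, gamma_p = 1,
                     interference_extra_cv = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  channel <- match.arg(channel)
  check_pos(od600, "od600")
  check_nonneg(af_mean, "af_mean")
  check_nonneg(af_sd, "af_sd")
  check_nonneg(spur_mean, "spur_mean")
  check_nonneg(spur_sd, "spur_sd")
  check_unit(readthrough, "readthrough")
  check_nonneg(prom_mean, "prom_mean")
  check_nonneg(prom_sd, "prom_sd")
  check_unit(gamma_s, "gamma_s")
  check_unit(gamma_p, "gamma_p")
  check_nonneg(interference_extra_cv, "interference_extra_cv")
  structure(
    list(name = name, channel = channel, od600 = od600,
         af_mean = af_mean, af_sd = af_sd,
         spur_mean = spur_mean, spur_sd = spur_sd,
         readthrough = readthrough,
         prom_mean = prom_mean, prom_sd = prom_sd,
         gamma_s = gamma_s, gamma_p = gamma_p,
         interference_extra_cv = interference_extra_cv),
    class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s  [%s, OD600 = %g]\n", x$name, x$channel, x$od600))
  cat(sprintf("  AF:       mean %.3g, sd %.3g AU\n", x$af_mean, x$af_sd))
  cat(sprintf("  spurious: mean %.3g, sd %.3g AU, read-through %.3g\n",
              x$spur_mean, x$spur_sd, x$readthrough))
  cat(sprintf("  promoter: mean %.3g, sd %.3g AU\n", x$prom_mean, x$prom_sd))
  if (x$gamma_s < 1 || x$gamma_p < 1 || x$interference_extra_cv > 0) {
    cat(sprintf("  interference: gamma_s %.3g, gamma_p %.3g, extra CV %.3g\n",
                x$gamma_s, x$gamma_p, x$interference_extra_cv))
  }
  invisible(x)
}

# Asymptotic (population) moments of the total fluorescence under the
# scenario. Interference factors enter through E[g] = gamma and
# Var contribution of the shared lognormal L.
scenario_moments <- function(sc) {
  interf <- sc$readthrough > 0 && sc$spur_mean > 0 && sc$prom_mean > 0
  gs <- if (interf) sc$gamma_s else 1
  gp <- if (interf) sc$gamma_p else 1
  cv2 <- if (interf) sc$interference_extra_cv^2 else 0
  ms <- sc$readthrough * gs * sc$spur_mean
  mp <- gp * sc$prom_mean
  mu <- sc$af_mean + ms + mp
  # Y = L * (rho*gs*Xs + gp*Xp), L independent of (Xs, Xp), E[L] = 1.
  m_y <- ms + mp
  v_y0 <- (sc$readthrough * gs * sc$spur_sd)^2 + (gp * sc$prom_sd)^2
  v_y <- (1 + cv2) * (v_y0 + m_y^2) - m_y^2
  list(mean = mu, var = sc$af_sd^2 + v_y)
}

#' Calibrate the spurious component from target D and S values
#'
#' Inverts the benchmark statistics D = mu_EV / mu_AF and
#' S = sigma_EV / sigma_AF for the spurious-transcription component of an
#' empty-vector strain, under independence of autofluorescence and spurious
#' expression:
#' \deqn{\mu_{spur} = (D - 1)\,\mu_{AF}, \qquad
#'       \sigma_{spur} = \sigma_{AF}\sqrt{S^2 - 1}.}
#' Printed D or S values below 1 are unphysical as component moments
#' (they would require negative mean or variance) and are clamped to the
#' ideal-reporter value 0 with a warning.
#'
#' @param af_mean,af_sd autofluorescence mean and SD (AU, > 0).
#' @param d_target,s_target target ratios (> 0).
#' @return list with `spur_mean` and `spur_sd` (AU, >= 0).
#' @export
#' @examples
#' calibrate_from_ds(100, 10, 2.13, 2.15)  # spur_mean 113, spur_sd 19.03
#' calibrate_from_ds(100, 10, 1, 1)        # ideal reporter: (0, 0)
calibrate_from_ds <- function(af_mean, af_sd, d_target, s_target) {
  check_pos(af_mean, "af_mean")
  check_pos(af_sd, "af_sd")
  check_pos(d_target, "d_target")
  check_pos(s_target, "s_target")
  if (d_target < 1) {
    warning("d_target < 1: spurious mean clamped to 0 (ideal reporter)",
            call. = FALSE)
    spur_mean <- 0
  } else {
    spur_mean <- (d_target - 1) * af_mean
  }
  if (s_target < 1) {
    warning("s_target < 1: spurious SD clamped to 0 (ideal reporter)",
            call. = FALSE)
    spur_sd <- 0
  } else {
    spur_sd <- af_sd * sqrt(s_target^2 - 1)
  }
  list(spur_mean = spur_mean, spur_sd = spur_sd)
}

#' Simulate a cell population under a scenario
#'
#' Draws `n` cells from the scenario's generative model and returns the
#' component breakdown together with the total per-cell fluorescence. This is
#' the pipeline's hidden ground truth: rendering, segmentation and
#' quantification downstream attempt to recover the distribution of
#' `total_values`.
#'
#' @param scenario a [scenario()].
#' @param n number of cells (>= 0).
#' @param seed integer seed; the draw is fully reproducible given
#'   `(scenario, n, seed)`.
#' @param replicate_id label attached to the population.
#' @return object of class `"cell_population"`: list with `scenario`, `n`,
#'   `af_values`, `spur_values` (pre-suppression, pre-read-through),
#'   `prom_values`, `total_values`, `seed`, `replicate_id`.
#' @export
#' @examples
#' pop <- simulate_population(scenario("AF"), n = 1000, seed = 1)
#' mean(pop$total_values)
simulate_population <- function(scenario, n, seed = 1L, replicate_id = "r1") {
  stopifnot(inherits(scenario, "scenario"))
  if (!is_number(n) || n < 0 || n != round(n)) {
    stop("`n` must be a single nonnegative integer", call. = FALSE)
  }
  n <- as.integer(n)
  sc <- scenario
  draws <- with_seed(seed, {
    af <- rgamma_ms(n, sc$af_mean, sc$af_sd)
    xs <- rgamma_ms(n, sc$spur_mean, sc$spur_sd)
    xp <- rgamma_ms(n, sc$prom_mean, sc$prom_sd)
    interf <- sc$readthrough > 0 && sc$spur_mean > 0 && sc$prom_mean > 0
    if (interf) {
      l <- rlnorm_unit(n, sc$interference_extra_cv)
      gs <- sc$gamma_s * l
      gp <- sc$gamma_p * l
    } else {
      gs <- rep(1, n)
      gp <- rep(1, n)
    }
    list(af = af, xs = xs, xp = xp,
         total = af + sc$readthrough * gs * xs + gp * xp)
  })
  structure(
    list(scenario = sc, n = n,
         af_values = draws$af, spur_values = draws$xs,
         prom_values = draws$xp, total_values = draws$total,
         seed = as.integer(seed), replicate_id = replicate_id),
    class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf("<cell_population> %d cells from scenario '%s' (replicate %s)\n",
              x$n, x$scenario$name, x$replicate_id))
  if (x$n > 0) {
    cat(sprintf("  total fluorescence: mean %.4g, sd %.4g AU\n",
                mean(x$total_values), stats::sd(x$total_values)))
  }
  invisible(x)
}

#' @export
as.data.frame.cell_population <- function(x, ...) {
  if (x$n == 0) {
    return(data.frame(cell_id = integer(0), replicate_id = character(0),
                      scenario = character(0), od600 = numeric(0),
                      af = numeric(0), spur = numeric(0), prom = numeric(0),
                      total = numeric(0)))
  }
  data.frame(cell_id = seq_len(x$n),
             replicate_id = x$replicate_id,
             scenario = x$scenario$name,
             od600 = x$scenario$od600,
             af = x$af_values,
             spur = x$spur_values,
             prom = x$prom_values,
             total = x$total_values)
}

#' Export simulated populations to CSV
#'
#' @param populations a `cell_population` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(populations, path) {
  if (inherits(populations, "cell_population")) populations <- list(populations)
  df <- do.call(rbind, lapply(populations, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
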