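## The D and S benchmarking statistics with bootstrap uncertainty, replicate
## aggregation, and histogram export.

# Vectorized bootstrap of mean and sd. Resamples are drawn in chunks so the
# peak allocation stays below ~2^24 doubles regardless of n * n_boot.
boot_mu_sigma <- function(values, n_boot) {
  n <- length(values)
  chunk <- max(1L, min(n_boot, as.integer(2^24 / n)))
  mu <- sg <- numeric(n_boot)
  done <- 0L
  while (done < n_boot) {
    b <- min(chunk, n_boot - done)
    m <- matrix(values[sample.int(n, n * b, replace = TRUE)], nrow = n)
    cm <- colMeans(m)
    mu[done + seq_len(b)] <- cm
    sg[done + seq_len(b)] <- sqrt((colMeans(m^2) - cm^2) * n / (n - 1))
    done <- done + b
  }
  list(mu = mu, sigma = sg)
}

#' Compute the D and S dark-noise benchmark statistics
#'
#' D is the ratio of the mean intensities and S the ratio of the standard
#' deviations of the empty-vector (EV) and autofluorescence (AF) intensity
#' distributions:
#' \deqn{D = \mu_{EV} / \mu_{AF}, \qquad S = \sigma_{EV} / \sigma_{AF}.}
#' An ideal reporter has D = 1 and S = 1: no specific dark noise, limited
#' only by cellular autofluorescence. Larger D shrinks the accessible
#' dynamic range; larger S reduces sensitivity. Uncertainty is a seeded
#' percentile bootstrap over cells, resampling within each distribution
#' independently (EV and AF come from different strains; no pairing).
#'
#' @param ev empty-vector [intensity_distribution()].
#' @param af autofluorescence [intensity_distribution()].
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed.
#' @param conf confidence level for the percentile intervals.
#' @return object of class `"ds_benchmark"`: list with `D`, `S`, `d_ci`,
#'   `s_ci`, `d_se`, `s_se` (bootstrap SEs), `n_ev`, `n_af`, `ev_condition`,
#'   `af_condition`.
#' @export
#' @examples
#' af <- intensity_distribution(c(90, 100, 110), "AF")
#' ev <- intensity_distribution(c(180, 200, 220), "EV")
#' compute_ds(ev, af, n_boot = 200, seed = 1)  # D = 2, S = 2
compute_ds <- function(ev, af, n_boot = 2000, seed = 1L, conf = 0.95) {
  stopifnot(inherits(ev, "intensity_distribution"),
            inherits(af, "intensity_distribution"))
  if (ev$n < 2 || af$n < 2) {
    stop("both distributions need at least 2 cells", call. = FALSE)
  }
  if (!is.finite(af$mu) || af$mu <= 0 || !is.finite(af$sigma) ||
      af$sigma == 0) {
    stop("degenerate AF reference: mu must be > 0 and sigma > 0",
         call. = FALSE)
  }
  D <- ev$mu / af$mu
  S <- ev$sigma / af$sigma
  alpha <- 1 - conf
  bt <- with_seed(seed, {
    be <- boot_mu_sigma(ev$values, n_boot)
    ba <- boot_mu_sigma(af$values, n_boot)
    list(d = be$mu / ba$mu, s = be$sigma / ba$sigma)
  })
  # tiny samples can yield degenerate (constant) resamples; drop them
  bt$d <- bt$d[is.finite(bt$d)]
  bt$s <- bt$s[is.finite(bt$s)]
  structure(list(D = D, S = S,
                 d_ci = unname(stats::quantile(bt$d, c(alpha / 2, 1 - alpha / 2))),
                 s_ci = unname(stats::quantile(bt$s, c(alpha / 2, 1 - alpha / 2))),
                 d_se = stats::sd(bt$d), s_se = stats::sd(bt$s),
                 conf = conf, n_boot = n_boot,
                 n_ev = ev$n, n_af = af$n,
                 ev_condition = ev$condition, af_condition = af$condition),
            class = "ds_benchmark")
}

#' @export
print.ds_benchmark <- function(x, ...) {
  cat(sprintf("<ds_benchmark> %s vs %s (n = %d / %d cells)\n",
              x$ev_condition, x$af_condition, x$n_ev, x$n_af))
  cat(sprintf("  D = %.3f  [%.3f, %.3f] %.0f%% bootstrap CI\n",
              x$D, x$d_ci[1], x$d_ci[2], 100 * x$conf))
  cat(sprintf("  S = %.3f  [%.3f, %.3f] %.0f%% bootstrap CI\n",
              x$S, x$s_ci[1], x$s_ci[2], 100 * x$conf))
  invisible(x)
}

#' Aggregate D/S results across replicate experiments
#'
#' Across-replicate uncertainty is the standard error of the mean,
#' SEM = SD / sqrt(k); it is `NA` for a single replicate.
#'
#' @param results list of [compute_ds()] results (one per replicate).
#' @return object of class `"replicate_summary"`: `mean_D`, `sem_D`,
#'   `mean_S`, `sem_S`, `k`.
#' @export
aggregate_replicates <- function(results) {
  if (inherits(results, "ds_benchmark")) results <- list(results)
  if (!length(results)) stop("empty result list", call. = FALSE)
  stopifnot(all(vapply(results, inherits, TRUE, "ds_benchmark")))
  d <- vapply(results, `[[`, 0, "D")
  s <- vapply(results, `[[`, 0, "S")
  k <- length(results)
  structure(list(mean_D = mean(d),
                 sem_D = if (k >= 2) stats::sd(d) / sqrt(k) else NA_real_,
                 mean_S = mean(s),
                 sem_S = if (k >= 2) stats::sd(s) / sqrt(k) else NA_real_,
                 k = k),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  fmt <- function(m, se) {
    if (is.na(se)) sprintf("%.3f (single replicate)", m)
    else sprintf("%.3f +/- %.3f SEM", m, se)
  }
  cat(sprintf("<replicate_summary> k = %d replicates\n", x$k))
  cat("  D =", fmt(x$mean_D, x$sem_D), "\n")
  cat("  S =", fmt(x$mean_S, x$sem_S), "\n")
  invisible(x)
}

#' Histogram table of an intensity distribution
#'
#' Half-open bins `[left, right)`; the last bin is extended to include the
#' maximum. Counts sum to `n`, frequencies to 1.
#'
#' @param dist an [intensity_distribution()].
#' @param bin_width bin width in AU (mutually exclusive with `bin_count`).
#' @param bin_count number of bins over the data range.
#' @param origin left edge of the first bin (default: floor of the minimum
#'   in units of the bin width).
#' @return data.frame with `bin_left`, `bin_right`, `count`, `frequency`.
#' @export
export_histogram <- function(dist, bin_width = NULL, bin_count = NULL,
                             origin = NULL) {
  stopifnot(inherits(dist, "intensity_distribution"))
  v <- dist$values
  if (is.null(bin_width) && is.null(bin_count)) bin_count <- 30
  if (!is.null(bin_width)) {
    check_pos(bin_width, "bin_width")
    if (is.null(origin)) origin <- floor(min(v) / bin_width) * bin_width
    k <- max(1, ceiling((max(v) - origin) / bin_width + 1e-9))
    breaks <- origin + bin_width * (0:k)
  } else {
    check_pos(bin_count, "bin_count")
    rng <- range(v)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = bin_count + 1)
  }
  idx <- findInterval(v, breaks, rightmost.closed = TRUE, left.open = FALSE)
  idx[idx < 1] <- 1; idx[idx > length(breaks) - 1] <- length(breaks) - 1
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  data.frame(bin_left = breaks[-length(breaks)],
             bin_right = breaks[-1],
             count = counts,
             frequency = counts / sum(counts))
}

#' Write a benchmark report mirroring the published table shape
#'
#' One row per vector/condition: `vector`, `channel`, `od600`, `D`, `D_unc`,
#' `S`, `S_unc`, `n_ev`, `n_af`, `k_replicates`, `unc_type`. With k >= 2
#' replicates the uncertainty is the across-replicate SEM; with a single
#' replicate it is the bootstrap CI half-width (the type is labelled in the
#' `unc_type` column).
#'
#' @param rows list of lists, each with `vector`, `channel`, `od600`,
#'   `results` (list of [compute_ds()] objects, one per replicate).
#' @param path output CSV path, or `NULL` to return the data.frame only.
#' @return the report data.frame, invisibly if written.
#' @export
benchmark_report <- function(rows, path = NULL) {
  out <- do.call(rbind, lapply(rows, function(r) {
    agg <- aggregate_replicates(r$results)
    k <- agg$k
    if (k >= 2) {
      d_unc <- agg$sem_D; s_unc <- agg$sem_S; type <- "sem"
    } else {
      b <- r$results[[1]]
      d_unc <- diff(b$d_ci) / 2; s_unc <- diff(b$s_ci) / 2
      type <- "bootstrap_ci_halfwidth"
    }
    data.frame(vector = r$vector, channel = r$channel, od600 = r$od600,
               D = agg$mean_D, D_unc = d_unc, S = agg$mean_S, S_unc = s_unc,
               n_ev = sum(vapply(r$results, `[[`, 0L, "n_ev")),
               n_af = sum(vapply(r$results, `[[`, 0L, "n_af")),
               k_replicates = k, unc_type = type)
  }))
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
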