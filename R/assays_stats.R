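# Plate-assay logic and the statistical conventions used throughout:
# MIC calling on 2-fold dilution series (including ">max" and range
# consolidation across replicates), voltage-dye release summaries, net
# inhibition-zone areas, competition abundance, and unpaired two-tailed
# Student's t-tests with significance-star binning.

#' Call a MIC from a concentration series
#'
#' The MIC is the lowest concentration with no growth. If growth occurs at
#' every concentration the result is `">max"`. With several replicates, a
#' disagreement is consolidated to a range string `"a-b"` (en dash style
#' "16-32"). Non-monotone patterns (growth above a no-growth well) are
#' flagged and the MIC placed at the highest transition, i.e. just above the
#' highest growth well.
#'
#' @param concentrations numeric vector, strictly increasing 2-fold series.
#' @param growth logical matrix (replicates x concentrations) or vector; TRUE
#'   = visible growth.
#' @param od optional numeric OD matrix instead of `growth`.
#' @param threshold OD threshold for growth when `od` is given.
#' @return list with `mic` (string), `value` (numeric, NA for ">max" /
#'   ranges), `per_replicate` (numeric, NA where all-growth), `flags`.
#' @export
mic_call <- function(concentrations, growth = NULL, od = NULL,
                     threshold = 0.05) {
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  if (is.null(growth)) {
    if (is.null(od)) stop("provide growth or od")
    growth <- od > threshold
  }
  if (is.vector(growth)) growth <- matrix(growth, nrow = 1)
  if (ncol(growth) != length(concentrations))
    stop("growth columns must match concentrations")
  flags <- character(0)
  per_rep <- apply(growth, 1, function(g) {
    if (all(g)) return(NA_real_)
    if (!any(g)) return(concentrations[1])
    last_growth <- max(which(g))
    first_clear <- min(which(!g))
    if (last_growth > first_clear) {
      flags <<- c(flags, "non-monotone growth pattern")
      if (last_growth == length(g)) return(NA_real_) # growth at the top: no clear well above
      return(concentrations[last_growth + 1L])
    }
    concentrations[first_clear]
  })
  if (all(is.na(per_rep))) {
    mic <- paste0(">", concentrations[length(concentrations)])
    value <- NA_real_
  } else if (any(is.na(per_rep))) {
    flags <- c(flags, "replicates disagree on growth at the top concentration")
    mic <- paste0(">", concentrations[length(concentrations)])
    value <- NA_real_
  } else if (length(unique(per_rep)) == 1L) {
    value <- per_rep[1]
    mic <- format(value, trim = TRUE)
  } else {
    lo <- min(per_rep); hi <- max(per_rep)
    if (hi / lo > 2) flags <- c(flags, "replicates disagree by more than one dilution step")
    mic <- paste0(format(lo, trim = TRUE), "–", format(hi, trim = TRUE))
    value <- NA_real_
  }
  list(mic = mic, value = value, per_replicate = per_rep, flags = unique(flags))
}

#' Summarize a voltage-sensitive dye release trace
#'
#' Baseline is the mean of the last `baseline_window` minutes before compound
#' addition (requiring their range below `tolerance`); the plateau is the
#' first post-addition time whose forward `plateau_window`-minute window has
#' a range below `tolerance`; the release magnitude is plateau level minus
#' baseline. Tolerance defaults to 2% of the trace's dynamic range.
#'
#' @param time numeric minutes.
#' @param signal numeric fluorescence (RFU), same length.
#' @param addition_time minute at which the compound is added.
#' @param tolerance stability tolerance (RFU); default 2% of range.
#' @param baseline_window,plateau_window minutes.
#' @return list: baseline, addition_time, release, plateau_time,
#'   time_to_plateau, flags.
#' @export
disc_summary <- function(time, signal, addition_time, tolerance = NULL,
                         baseline_window = 5, plateau_window = 2) {
  stopifnot(length(time) == length(signal))
  if (is.null(tolerance)) tolerance <- 0.02 * diff(range(signal))
  if (tolerance == 0) tolerance <- .Machine$double.eps
  flags <- character(0)
  pre <- time < addition_time & time >= addition_time - baseline_window
  if (!any(pre)) stop("no pre-addition samples in the baseline window")
  if (diff(range(signal[pre])) >= tolerance)
    flags <- c(flags, "unstable baseline")
  baseline <- mean(signal[pre])
  post_idx <- which(time >= addition_time)
  plateau_time <- NA_real_
  for (i in post_idx) {
    if (time[i] + plateau_window > max(time) + 1e-9) break # window must fit
    win <- signal[time >= time[i] & time <= time[i] + plateau_window]
    if (length(win) >= 2 && diff(range(win)) < tolerance) {
      plateau_time <- time[i]
      break
    }
  }
  if (is.na(plateau_time)) {
    flags <- c(flags, "no plateau")
    release <- NA_real_
  } else {
    release <- mean(signal[time >= plateau_time & time <= plateau_time + plateau_window]) -
      baseline
  }
  list(baseline = baseline, addition_time = addition_time, release = release,
       plateau_time = plateau_time,
       time_to_plateau = plateau_time - addition_time, flags = flags)
}

#' Net inhibition-zone area
#'
#' Total inhibition area minus the producer spot area.
#'
#' @param total_area,spot_area areas in mm^2.
#' @return net area (mm^2).
#' @export
zone_area <- function(total_area, spot_area) {
  if (any(spot_area > total_area)) stop("spot area exceeds total inhibition area")
  total_area - spot_area
}

#' Relative abundance in a two-species competition
#'
#' @param countsA,countsB cell counts of the two species.
#' @return percent of species A, `100 * A / (A + B)`.
#' @export
competition_abundance <- function(countsA, countsB) {
  if (countsA + countsB == 0) stop("no cells counted")
  100 * countsA / (countsA + countsB)
}

#' Classify segmented cells into rods and cocci by aspect ratio
#'
#' @param cells data.frame from [segment_cells()].
#' @param min_aspect rods have length/width above this (default 1.5).
#' @return list with `rods`, `cocci` (counts), `percent_cocci`, and the
#'   per-cell class vector.
#' @export
classify_morphology <- function(cells, min_aspect = 1.5) {
  aspect <- cells$length / cells$width
  cls <- ifelse(aspect >= min_aspect, "rod", "coccus")
  list(rods = sum(cls == "rod"), cocci = sum(cls == "coccus"),
       percent_cocci = 100 * mean(cls == "coccus"), class = cls)
}

#' Unpaired two-tailed Student's t-test with significance stars
#'
#' Pooled-variance Student's t by default (Welch behind a flag), two-sided,
#' with the 95% confidence interval of the mean difference and the star
#' binning used in the figure legends: ns for p > .05, `*` for .05-.01,
#' `**` for .01-.001, `***` for .001-.0001, `****` for p <= .0001. Bin
#' boundaries .01/.001/.0001 belong to the more significant bin; p = .05
#' exactly is "ns".
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param welch use the Welch correction instead of pooled variance.
#' @return list: t, df, p, ci (length 2), mean_diff, stars.
#' @export
ttest_groups <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
    return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                ci = c(0, 0), mean_diff = 0, stars = "ns"))
  }
  tt <- t.test(a, b, var.equal = !welch, conf.level = 0.95)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, ci = unname(tt$conf.int),
       mean_diff = mean(a) - mean(b), stars = star_class(tt$p.value))
}

#' Star bin for a p-value
#'
#' @param p p-value in `[0, 1]`.
#' @return one of "ns", "*", "**", "***", "****".
#' @export
star_class <- function(p) {
  stopifnot(is.finite(p), p >= 0, p <= 1)
  if (p <= 1e-4) "****"
  else if (p <= 1e-3) "***"
  else if (p <= 1e-2) "**"
  else if (p < 0.05) "*"
  else "ns"
}
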