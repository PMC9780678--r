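#' Fluorescence ratio relative to a reference
#'
#' `Ratio (%) = 100 * F / F0`, the percent scale used for probe-based
#' readouts (hydroxyl-radical scavenging with a coumarin-3-carboxylic acid
#' probe, intracellular ROS with DCFH-DA): `F` is the probe intensity in
#' the treated condition and `F0` in the reference condition.
#'
#' @param f Fluorescence intensity (arbitrary units, >= 0).
#' @param f0 Reference intensity (arbitrary units, > 0).
#' @return Ratio in percent. Vectorised over `f` and `f0`.
#' @examples
#' fluorescence_ratio(20, 100)  # 20 percent of reference
#' @export
fluorescence_ratio <- function(f, f0) {
  if (any(f0 <= 0)) stop("reference intensity F0 must be positive",
                         call. = FALSE)
  if (any(f < 0)) stop("fluorescence intensity F must be non-negative",
                       call. = FALSE)
  100 * f / f0
}

#' Mitochondrial membrane potential ratio (JC-1)
#'
#' Ratio of JC-1 monomer (530 nm) to JC-1 aggregate (590 nm) fluorescence
#' intensity; higher values indicate depolarised mitochondria.
#'
#' @param fi530 Monomer intensity (arbitrary units, >= 0).
#' @param fi590 Aggregate intensity (arbitrary units, > 0).
#' @return Unitless ratio. Vectorised.
#' @export
mmp_ratio <- function(fi530, fi590) {
  if (any(fi590 <= 0)) stop("aggregate intensity FI590 must be positive",
                            call. = FALSE)
  if (any(fi530 < 0)) stop("monomer intensity FI530 must be non-negative",
                           call. = FALSE)
  fi530 / fi590
}

#' Normalise measurements to percent of control
#'
#' Scales a group of replicate measurements so that the control group's
#' mean maps to 100%.
#'
#' @param values Numeric vector of measurements.
#' @param control Numeric vector of control-group measurements.
#' @return `values` on the percent-of-control scale.
#' @export
percent_of_control <- function(values, control) {
  if (length(values) == 0L) stop("empty measurement group", call. = FALSE)
  if (length(control) == 0L) stop("empty control group", call. = FALSE)
  cm <- mean(control)
  if (cm <= 0) stop("control mean must be positive", call. = FALSE)
  100 * values / cm
}

#' Single-sample t-test against a reference mean
#'
#' Tests whether the mean of a replicate group differs from a fixed
#' reference value: `t = (mean - reference) / (sd / sqrt(n))` with `n - 1`
#' degrees of freedom, two-sided. This is the group-comparison test used
#' throughout the assay analysis (each treated group against the control
#' mean). Degenerate inputs are handled explicitly: if all values equal
#' the reference, `t = 0, p = 1`; if all values are equal but differ from
#' the reference the test is degenerate and `p = 0` is reported with a
#' warning.
#'
#' @param values Replicate measurements (n >= 2).
#' @param reference_mean Reference value to test against.
#' @return A list with `t`, `df`, `p`, `mean`, `sd`, `n`, and a
#'   `degenerate` flag.
#' @export
one_sample_ttest <- function(values, reference_mean) {
  n <- length(values)
  if (n < 2L) stop("need at least two replicates", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) {
    if (m == reference_mean) {
      return(list(t = 0, df = n - 1L, p = 1, mean = m, sd = s, n = n,
                  degenerate = TRUE))
    }
    warning("zero variance with mean != reference: degenerate test, ",
            "p reported as 0", call. = FALSE)
    return(list(t = sign(m - reference_mean) * Inf, df = n - 1L, p = 0,
                mean = m, sd = s, n = n, degenerate = TRUE))
  }
  ht <- stats::t.test(values, mu = reference_mean)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean = m, sd = s, n = n, degenerate = FALSE)
}

#' Welch two-sample t-test
#'
#' Configurable alternative to the single-sample test: compares a treated
#' group against the control replicates directly, without assuming the
#' control mean is known exactly.
#'
#' @param values Treated-group replicates (n >= 2).
#' @param control Control-group replicates (n >= 2).
#' @return A list with `t`, `df`, `p`.
#' @export
welch_ttest <- function(values, control) {
  if (length(values) < 2L || length(control) < 2L) {
    stop("need at least two replicates per group", call. = FALSE)
  }
  ht <- stats::t.test(values, control)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Lag time of an amyloid-aggregation fluorescence time course
#'
#' Summarises a thioflavin-T (ThT) aggregation curve by the nucleation lag
#' time: the first time (linear interpolation between samples) at which
#' the baseline-corrected intensity crosses `threshold_fraction` of the
#' total rise. Baseline is the first point, plateau the maximum.
#'
#' @param times Time points in hours, strictly increasing (>= 4 points).
#' @param intensities Fluorescence intensities, same length.
#' @param threshold_fraction Fraction of the baseline-to-plateau rise that
#'   defines the end of the lag phase (default 0.1).
#' @return Lag time in hours, or `NA_real_` when the series shows no
#'   transition (plateau equals baseline).
#' @export
tht_lag_time <- function(times, intensities, threshold_fraction = 0.1) {
  stopifnot(length(times) == length(intensities))
  if (length(times) < 4L) {
    stop("need at least 4 time points for lag estimation", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must be in (0, 1)", call. = FALSE)
  }
  baseline <- intensities[1L]
  plateau <- max(intensities)
  if (plateau <= baseline) return(NA_real_)
  target <- baseline + threshold_fraction * (plateau - baseline)
  above <- which(intensities >= target)
  i <- above[above > 1L][1L]
  if (is.na(i)) i <- above[1L]
  if (i == 1L) return(times[1L])
  x0 <- times[i - 1L]; x1 <- times[i]
  y0 <- intensities[i - 1L]; y1 <- intensities[i]
  if (y1 == y0) return(x1)
  x0 + (target - y0) / (y1 - y0) * (x1 - x0)
}

#' Summarise replicate assay groups against a control
#'
#' Takes long-format assay data (`group`, `value`), reports per-group mean,
#' SD, n and percent of control, and tests each non-control group against
#' the control (single-sample t-test against the control mean by default,
#' Welch two-sample optionally). Significance stars mirror the usual
#' convention: `*` for p < 0.05, `**` for p < 0.01.
#'
#' @param data Data frame with columns `group` and `value`.
#' @param control_label Name of the control group.
#' @param method `"one_sample"` (default) or `"welch"`.
#' @param bonferroni Apply Bonferroni correction across the tested groups
#'   (default `FALSE`; no correction).
#' @return Data frame with one row per group: `group`, `mean`, `sd`, `n`,
#'   `percent_of_control`, `t`, `df`, `p`, `signif`.
#' @export
summarize_assay <- function(data, control_label = "control",
                            method = c("one_sample", "welch"),
                            bonferroni = FALSE) {
  method <- match.arg(method)
  stopifnot(all(c("group", "value") %in% names(data)))
  groups <- unique(as.character(data$group))
  if (!control_label %in% groups) {
    stop("control group '", control_label, "' not found", call. = FALSE)
  }
  control <- data$value[data$group == control_label]
  rows <- lapply(groups, function(g) {
    v <- data$value[data$group == g]
    res <- if (g == control_label) {
      list(t = NA_real_, df = NA_real_, p = NA_real_)
    } else if (method == "one_sample") {
      one_sample_ttest(v, mean(control))
    } else {
      welch_ttest(v, control)
    }
    data.frame(group = g, mean = mean(v), sd = stats::sd(v),
               n = length(v),
               percent_of_control = mean(percent_of_control(v, control)),
               t = res$t, df = res$df, p = res$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bonferroni) {
    tested <- !is.na(out$p)
    out$p[tested] <- stats::p.adjust(out$p[tested], method = "bonferroni")
  }
  out$signif <- ifelse(is.na(out$p), "",
                       ifelse(out$p < 0.01, "**",
                              ifelse(out$p < 0.05, "*", "")))
  rownames(out) <- NULL
  out
}
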