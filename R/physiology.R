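# Sodium self-inhibition (SSI) from voltage-clamp traces, group comparisons,
# and RPKM/FPKM expression calls.

#' Voltage-clamp current trace with bath-event annotations
#'
#' @param time Strictly increasing time in seconds.
#' @param current Current in microamperes (inward negative).
#' @param t_switch Time of the 1 -> 110 mM Na+ bath switch.
#' @param t_amiloride Time amiloride enters the bath (> `t_switch`).
#' @param peak_window Seconds after the switch searched for the peak
#'   (default 15, bounded because the decay time constant is ~2-3 s).
#' @param ss_center,ss_halfwidth Steady-state averaging window: centered
#'   `ss_center` seconds after the switch (default 60, i.e. "1 min"),
#'   half-width `ss_halfwidth` (default 5).
#' @param amil_equilibration Seconds allowed for amiloride block to
#'   equilibrate before the baseline window (default 10).
#' @param amil_window Final-seconds window averaged for the amiloride
#'   baseline (default 5).
#' @export
current_trace <- function(time, current, t_switch, t_amiloride,
                          peak_window = 15, ss_center = 60, ss_halfwidth = 5,
                          amil_equilibration = 10, amil_window = 5) {
  stopifnot(length(time) == length(current), length(time) >= 2)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (t_amiloride <= t_switch)
    stop("amiloride window before switch: t_switch must precede t_amiloride")
  if (t_switch < min(time) || t_amiloride > max(time))
    stop("event annotations outside the time range")
  structure(list(time = time, current = current, t_switch = t_switch,
                 t_amiloride = t_amiloride, peak_window = peak_window,
                 ss_center = ss_center, ss_halfwidth = ss_halfwidth,
                 amil_equilibration = amil_equilibration,
                 amil_window = amil_window), class = "current_trace")
}

#' Read a trace CSV (`time_s,current_uA`) plus an events list
#'
#' @param path CSV path.
#' @param events List with `t_switch` and `t_amiloride` (and optionally any
#'   window parameter of [current_trace()]).
#' @export
read_trace_csv <- function(path, events) {
  d <- read.csv(path)
  if (!all(c("time_s", "current_uA") %in% names(d)))
    stop("trace CSV needs columns time_s,current_uA")
  do.call(current_trace,
          c(list(time = d$time_s, current = d$current_uA), events))
}

#' Extract peak, steady-state and amiloride currents from a trace
#'
#' `I_peak` is the inward extremum (minimum, currents signed) in
#' `(t_switch, t_switch + peak_window]`; `I_ss` the mean over the
#' steady-state window clipped to before `t_amiloride`; `I_amil` the mean
#' over the final `amil_window` seconds, which must start after
#' `t_amiloride + amil_equilibration`.
#'
#' @param trace A [current_trace()].
#' @return List `I_peak`, `I_ss`, `I_amil`.
#' @export
detect_events <- function(trace) {
  stopifnot(inherits(trace, "current_trace"))
  tt <- trace$time; cc <- trace$current
  pk <- tt > trace$t_switch & tt <= trace$t_switch + trace$peak_window
  if (!any(pk)) stop("empty peak window")
  I_peak <- min(cc[pk])
  ss_lo <- trace$t_switch + trace$ss_center - trace$ss_halfwidth
  ss_hi <- trace$t_switch + trace$ss_center + trace$ss_halfwidth
  if (ss_hi > trace$t_amiloride)
    stop("steady-state window overlaps the amiloride application")
  ss <- tt >= ss_lo & tt <= ss_hi
  if (!any(ss)) stop("empty steady-state window")
  I_ss <- mean(cc[ss])
  am_lo <- max(tt) - trace$amil_window
  if (am_lo < trace$t_amiloride + trace$amil_equilibration)
    stop("amiloride baseline window starts before equilibration")
  am <- tt >= am_lo
  I_amil <- mean(cc[am])
  list(I_peak = I_peak, I_ss = I_ss, I_amil = I_amil)
}

#' Sodium self-inhibition fraction
#'
#' `SSI = (I_peak - I_ss) / (I_peak - I_amil)`: the reduction of current
#' from the peak to steady state relative to the total amiloride-sensitive
#' current. Currents are signed throughout, so the formula is
#' sign-convention safe; 0 means no decay, 1 means decay all the way to the
#' amiloride baseline. Values outside [0, 1] are clamped and flagged.
#'
#' @param I_peak,I_ss,I_amil Signed currents (same units).
#' @param noise_floor Minimum `|I_peak - I_amil|` for a defined result.
#' @return List `ssi`, `clamped`, `undefined`, and the three inputs.
#' @export
compute_ssi <- function(I_peak, I_ss, I_amil, noise_floor = 0) {
  denom <- I_peak - I_amil
  if (denom == 0 || abs(denom) <= noise_floor)
    return(list(ssi = NA_real_, clamped = FALSE, undefined = TRUE,
                I_peak = I_peak, I_ss = I_ss, I_amil = I_amil))
  raw <- (I_peak - I_ss) / denom
  list(ssi = min(1, max(0, raw)), clamped = raw < 0 || raw > 1,
       undefined = FALSE, I_peak = I_peak, I_ss = I_ss, I_amil = I_amil)
}

#' @rdname compute_ssi
#' @param trace A [current_trace()]; events are detected first.
#' @export
trace_ssi <- function(trace, noise_floor = 0) {
  ev <- detect_events(trace)
  compute_ssi(ev$I_peak, ev$I_ss, ev$I_amil, noise_floor)
}

#' Sidak adjustment of p-values over m comparisons
#' @param p Raw p-value(s).
#' @param m Number of pairwise comparisons.
#' @export
sidak_adjust <- function(p, m) 1 - (1 - p)^m

#' Group comparisons: two-sample / paired t-tests and one-way ANOVA
#'
#' Two-sample and paired designs use Student's t-test (pooled variance for
#' two samples); the one-way design runs an F-test followed by pairwise
#' pooled-variance t-tests with Sidak adjustment over the requested
#' comparisons (all pairs by default).
#'
#' @param values Numeric vector.
#' @param groups Factor/character of group labels (same length).
#' @param design `"two-sample"`, `"paired"` or `"one-way"`.
#' @param comparisons For `"one-way"`: list of length-2 character vectors of
#'   group names to compare (default all pairs).
#' @return List with `statistic`, `p_value`, `degenerate` flag and, for
#'   one-way, a `pairwise` data frame with raw and Sidak-adjusted p-values.
#' @export
compare_groups <- function(values, groups,
                           design = c("two-sample", "paired", "one-way"),
                           comparisons = NULL) {
  design <- match.arg(design)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  if (any(table(groups) < 2)) stop("need >= 2 values per group")
  split_v <- split(values, groups)
  if (design %in% c("two-sample", "paired")) {
    if (length(split_v) != 2) stop(design, " design needs exactly 2 groups")
    x <- split_v[[1]]; y <- split_v[[2]]
    if (design == "paired" && length(x) != length(y))
      stop("paired design needs equal group sizes")
    degen <- if (design == "paired") sd(x - y) == 0
             else sd(c(x - mean(x), y - mean(y))) == 0
    if (degen) {
      equal <- isTRUE(all.equal(mean(x), mean(y)))
      return(list(statistic = if (equal) 0 else Inf,
                  p_value = if (equal) 1 else 0, degenerate = TRUE,
                  design = design))
    }
    tt <- if (design == "paired") t.test(x, y, paired = TRUE)
          else t.test(x, y, var.equal = TRUE)
    return(list(statistic = unname(tt$statistic), p_value = tt$p.value,
                degenerate = FALSE, design = design))
  }
  # one-way ANOVA + Sidak-adjusted pairwise pooled t-tests
  g <- factor(groups)
  fit <- aov(values ~ g)
  atab <- anova(fit)
  if (is.null(comparisons))
    comparisons <- utils::combn(levels(g), 2, simplify = FALSE)
  m <- length(comparisons)
  pw <- do.call(rbind, lapply(comparisons, function(pair) {
    x <- split_v[[pair[1]]]; y <- split_v[[pair[2]]]
    degen <- sd(c(x - mean(x), y - mean(y))) == 0
    p_raw <- if (degen) {
      if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    } else t.test(x, y, var.equal = TRUE)$p.value
    data.frame(group1 = pair[1], group2 = pair[2], p_raw = p_raw,
               p_sidak = sidak_adjust(p_raw, m), degenerate = degen)
  }))
  list(statistic = atab$`F value`[1], p_value = atab$`Pr(>F)`[1],
       degenerate = FALSE, design = design, pairwise = pw)
}

#' RPKM/FPKM expression calls against a background threshold
#'
#' `value = counts / ((length/1e3) * (library_total/1e6))`; a gene is called
#' expressed iff its value strictly exceeds the threshold (a value exactly
#' at the threshold is background).
#'
#' @param counts Non-negative read/fragment counts.
#' @param lengths Feature lengths in bp (> 0).
#' @param library_total Total mapped reads/fragments (> 0).
#' @param metric `"RPKM"` or `"FPKM"` (label only; the formula is shared).
#' @param threshold Expressed/background boundary (default 0.3).
#' @param gene_ids Optional gene identifiers.
#' @return Data frame `gene`, `count`, `length_bp`, `value`, `expressed`.
#' @export
expression_call <- function(counts, lengths, library_total,
                            metric = c("RPKM", "FPKM"), threshold = 0.3,
                            gene_ids = NULL) {
  metric <- match.arg(metric)
  if (any(counts < 0)) stop("negative counts")
  if (any(lengths <= 0)) stop("zero or negative feature length")
  if (library_total <= 0) stop("zero library total")
  value <- counts / ((lengths / 1e3) * (library_total / 1e6))
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_along(counts))
  d <- data.frame(gene = gene_ids, count = counts, length_bp = lengths,
                  value = value, expressed = value > threshold,
                  stringsAsFactors = FALSE)
  attr(d, "metric") <- metric
  attr(d, "threshold") <- threshold
  d
}
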