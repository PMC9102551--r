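# Imaging summary statistics: ROI-based translocation ratios, cell
# migration rates from 2-D tracks, agonist peak amplitudes, and
# baseline-normalised fluorescence (dF/F0) with its post-stimulus slope.

#' Relative cytoplasmic translocation R
#'
#' `R = (Ics - Im) / Im` for a paired cytosolic/membrane ROI; dimensionless,
#' higher R meaning more cytosolic retention of the probe.
#'
#' @param i_cs cytosolic ROI fluorescence intensity.
#' @param i_m membrane ROI fluorescence intensity (> 0).
#' @return R (vectorised).
#' @examples
#' cytoplasmic_translocation(2, 1)  # 1
#' @export
cytoplasmic_translocation <- function(i_cs, i_m) {
  if (any(!is.finite(i_m)) || any(i_m <= 0))
    stop("membrane intensity must be > 0", call. = FALSE)
  (i_cs - i_m) / i_m
}

#' Per-cell translocation time series from paired ROI traces
#'
#' Computes R per ROI pair per time point and aggregates across the pairs of
#' each cell (mean by default, median by flag). ROIs without a matching
#' membrane/cytosol partner at a time point are rejected; cells with no
#' valid pair are excluded with a message; cells with fewer than 4 pairs are
#' computed but flagged with a warning (below the recommended minimum).
#'
#' @param traces long data frame `cell_id`, `roi_pair_id`, `compartment`
#'   (`"membrane"`/`"cytosol"`), `time`, `intensity`.
#' @param aggregate `"mean"` or `"median"` across ROI pairs.
#' @return data frame `cell_id`, `time`, `R`, `n_pairs`.
#' @export
cell_translocation_series <- function(traces, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  need <- c("cell_id", "roi_pair_id", "compartment", "time", "intensity")
  stopifnot(is.data.frame(traces), all(need %in% names(traces)))
  mem <- traces[traces$compartment == "membrane", ]
  cyt <- traces[traces$compartment == "cytosol", ]
  key <- function(d) paste(d$cell_id, d$roi_pair_id, d$time, sep = "\r")
  mk <- key(mem); ck <- key(cyt)
  matched <- match(mk, ck)
  ok <- !is.na(matched)
  n_unpaired <- sum(!ok) + sum(!(ck %in% mk))
  if (n_unpaired > 0)
    message(sprintf("cell_translocation_series: %d unpaired ROI record(s) rejected",
                    n_unpaired))
  if (!any(ok)) {
    message("cell_translocation_series: no valid ROI pairs")
    return(data.frame(cell_id = character(0), time = numeric(0),
                      R = numeric(0), n_pairs = integer(0)))
  }
  mem <- mem[ok, ]
  r <- cytoplasmic_translocation(cyt$intensity[matched[ok]], mem$intensity)
  pairs_per_cell <- tapply(mem$roi_pair_id, mem$cell_id,
                           function(x) length(unique(x)))
  if (any(pairs_per_cell < 4))
    warning(sprintf("%d cell(s) with fewer than 4 ROI pairs",
                    sum(pairs_per_cell < 4)), call. = FALSE)
  agg <- if (aggregate == "mean") mean else stats::median
  grp <- interaction(mem$cell_id, mem$time, drop = TRUE, lex.order = TRUE)
  out <- data.frame(
    cell_id = tapply(mem$cell_id, grp, `[`, 1),
    time = as.numeric(tapply(mem$time, grp, `[`, 1)),
    R = as.numeric(tapply(r, grp, agg)),
    n_pairs = as.integer(tapply(r, grp, length)),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$cell_id, out$time), ]
}

#' Migration rate from 2-D cell tracks
#'
#' Mean frame-to-frame speed per cell: the distance covered between two
#' consecutive time points (micrometres, after pixel conversion) divided by
#' the interval, averaged along the track. Flagged cells (e.g. cells that
#' left the field or divided) are excluded before computation, as are
#' single-point tracks.
#'
#' @param tracks data frame `cell_id`, `time` (minutes, strictly increasing
#'   per cell), `x`, `y` (micrometres).
#' @param exclude character vector of cell ids to drop.
#' @return data frame `cell_id`, `rate` (micrometres per minute), `n_steps`.
#' @examples
#' tr <- data.frame(cell_id = "c1", time = c(0, 10), x = c(0, 12), y = 0)
#' migration_rate(tr)  # 1.2 um/min
#' @export
migration_rate <- function(tracks, exclude = NULL) {
  need <- c("cell_id", "time", "x", "y")
  stopifnot(is.data.frame(tracks), all(need %in% names(tracks)))
  tracks <- tracks[!tracks$cell_id %in% exclude, , drop = FALSE]
  cells <- split(tracks, tracks$cell_id)
  single <- vapply(cells, nrow, 0L) < 2
  if (any(single))
    message(sprintf("migration_rate: %d single-point track(s) excluded",
                    sum(single)))
  cells <- cells[!single]
  out <- do.call(rbind, lapply(cells, function(tr) {
    tr <- tr[order(tr$time), ]
    dt <- diff(tr$time)
    if (any(dt <= 0))
      stop("track times must be strictly increasing for cell ",
           tr$cell_id[1], call. = FALSE)
    step <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    data.frame(cell_id = tr$cell_id[1], rate = mean(step / dt),
               n_steps = length(step), stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(cell_id = character(0), rate = numeric(0),
                      n_steps = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Peak amplitude of a fluorescence trace after a stimulus
#'
#' Difference between the maximum and minimum values recorded in the window
#' (default about 300 s) following the stimulus; pre-stimulus samples are
#' ignored.
#'
#' @param time sample times in seconds.
#' @param value fluorescence values (e.g. a 340/380 ratio).
#' @param stimulus_time agonist administration time (seconds).
#' @param window window length after the stimulus (seconds).
#' @return the amplitude (max - min over the window).
#' @export
peak_amplitude <- function(time, value, stimulus_time, window = 300) {
  stopifnot(length(time) == length(value))
  sel <- time >= stimulus_time & time <= stimulus_time + window
  if (!any(sel)) stop("no samples in the post-stimulus window", call. = FALSE)
  max(value[sel]) - min(value[sel])
}

#' Baseline-normalised fluorescence and post-stimulus slope
#'
#' `F0` is the mean signal over the `baseline` seconds preceding the
#' stimulus; the normalised trace is `(F - F0) / F0`, and the release slope
#' is the least-squares slope of the normalised trace over a post-stimulus
#' window (default 60 s; per second).
#'
#' @param time sample times in seconds.
#' @param value fluorescence values (> 0 around the baseline).
#' @param stimulus_time stimulus time in seconds.
#' @param baseline baseline length before the stimulus (seconds; needs >= 2
#'   samples in it).
#' @param slope_window post-stimulus window for the slope fit (seconds).
#' @return list with `f0`, `trace` (data frame `time`, `dff0`) and `slope`.
#' @export
delta_f_over_f0 <- function(time, value, stimulus_time, baseline = 100,
                            slope_window = 60) {
  stopifnot(length(time) == length(value))
  base <- time >= stimulus_time - baseline & time < stimulus_time
  if (sum(base) < 2)
    stop("need at least 2 pre-stimulus samples in the baseline window",
         call. = FALSE)
  f0 <- mean(value[base])
  if (!is.finite(f0) || f0 <= 0) stop("baseline F0 must be > 0", call. = FALSE)
  dff0 <- (value - f0) / f0
  win <- time >= stimulus_time & time <= stimulus_time + slope_window
  slope <- if (sum(win) >= 2)
    unname(stats::coef(stats::lm(dff0[win] ~ time[win]))[2]) else NA_real_
  list(f0 = f0, trace = data.frame(time = time, dff0 = dff0), slope = slope)
}

#' Control-normalised band ratio for densitometry
#'
#' `(sample_num / sample_den) / (control_num / control_den)`, e.g. a
#' pulled-down active fraction over its total lysate, normalised on the same
#' ratio in the control condition; optionally on a log2 scale.
#'
#' @param sample_num,sample_den,control_num,control_den band intensities;
#'   all denominators must be > 0.
#' @param log2_output return log2 of the ratio.
#' @return the normalised ratio (vectorised).
#' @export
normalized_ratio <- function(sample_num, sample_den, control_num, control_den,
                             log2_output = FALSE) {
  if (any(c(sample_den, control_den) <= 0) || any(control_num <= 0))
    stop("denominators must be > 0", call. = FALSE)
  out <- (sample_num / sample_den) / (control_num / control_den)
  if (log2_output) log2(out) else out
}
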