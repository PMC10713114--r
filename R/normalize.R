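# Landmark-based peak normalization.
#
# Batch effects in cytometry typically show up as per-channel shifts of the
# density peaks (e.g. the negative and positive modes of a marker). Peaks
# are detected per sample and channel by kernel density estimation, matched
# across samples by rank ("low" peaks with "low" peaks, "high" with
# "high"), and each sample is warped by a continuous piecewise-linear map
# sending its peaks to per-rank consensus targets. The warp is monotone by
# construction and degenerates to a pure shift for a single landmark.

local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

# topographic prominence of each peak index on a density curve
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    left <- y[seq_len(p - 1)]
    higher_l <- which(left > h)
    base_l <- if (length(higher_l)) min(y[(max(higher_l)):(p - 1)]) else min(left, h)
    right <- y[(p + 1):length(y)]
    higher_r <- which(right > h)
    base_r <- if (length(higher_r)) {
      min(y[(p + 1):(p + min(higher_r))])
    } else {
      min(right, h)
    }
    h - max(base_l, base_r)
  }, numeric(1))
}

#' Detect density peaks of one channel
#'
#' Evaluates a Gaussian kernel density estimate (Silverman's rule-of-thumb
#' bandwidth) on a 512-point grid over the channel range and keeps local
#' maxima whose topographic prominence is at least `prominence` times the
#' global density maximum. The `L` candidates with the highest density are
#' returned sorted by position; when fewer than `L` are found, the result
#' carries attribute `needs_override = TRUE`.
#'
#' @param sample A `cp_sample` with at least 200 events, transformed so the
#'   peak shapes are roughly symmetric.
#' @param channel Channel label or short name.
#' @param L Number of expected peaks (>= 1).
#' @param prominence Minimum prominence as a fraction of the global density
#'   maximum; default 0.05.
#' @return Sorted numeric positions (length <= L).
#' @export
detect_peaks <- function(sample, channel, L, prominence = 0.05) {
  if (n_events(sample) < 200) {
    cp_stop("cp_estimation_error",
            "peak detection needs >= 200 events (got %d)", n_events(sample))
  }
  i <- resolve_channels(sample$channels, channel)
  x <- sample$events[, i]
  d <- stats::density(x, bw = "nrd0", n = 512, from = min(x), to = max(x))
  idx <- local_maxima(d$y)
  if (length(idx)) {
    prom <- peak_prominence(d$y, idx)
    idx <- idx[prom >= prominence * max(d$y)]
  }
  if (length(idx) > L) {
    idx <- idx[order(d$y[idx], decreasing = TRUE)[seq_len(L)]]
  }
  pos <- sort(d$x[idx])
  if (length(pos) < L) attr(pos, "needs_override") <- TRUE
  pos
}

#' Declare expected landmarks and manual overrides
#'
#' @param expected_peaks Named integer vector `channel -> L` (number of
#'   peaks expected per channel, >= 1).
#' @param overrides Optional named list; names of the form
#'   `"<sample_id>::<channel>"`, values sorted ascending numeric positions
#'   of length `L` for that channel. Overrides replace automatic detection
#'   for that sample and channel.
#' @return A `cp_landmark_spec`.
#' @export
landmark_spec <- function(expected_peaks, overrides = list()) {
  if (any(expected_peaks < 1)) {
    cp_stop("cp_parameter_error", "expected_peaks must be >= 1")
  }
  for (nm in names(overrides)) {
    ch <- strsplit(nm, "::", fixed = TRUE)[[1]][2]
    v <- overrides[[nm]]
    if (is.unsorted(v, strictly = TRUE)) {
      cp_stop("cp_parameter_error", "override '%s' must be sorted ascending", nm)
    }
    if (!is.na(ch) && ch %in% names(expected_peaks) &&
        length(v) != expected_peaks[[ch]]) {
      cp_stop("cp_parameter_error",
              "override '%s' has %d positions but channel '%s' expects %d",
              nm, length(v), ch, expected_peaks[[ch]])
    }
  }
  structure(list(expected_peaks = expected_peaks, overrides = overrides),
            class = "cp_landmark_spec")
}

#' Read a peak-override file
#'
#' TSV with columns `sample_id`, `channel`, `rank`, `position`; converted
#' into the override list consumed by [landmark_spec()].
#'
#' @param path Path to the TSV file.
#' @return Named list of sorted positions keyed by
#'   `"<sample_id>::<channel>"`.
#' @export
read_peak_overrides <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "channel", "rank", "position")
  if (!all(need %in% names(tab))) {
    cp_stop("cp_io_error", "override file must have columns %s",
            paste(need, collapse = ", "))
  }
  out <- list()
  for (key in unique(paste0(tab$sample_id, "::", tab$channel))) {
    sub <- tab[paste0(tab$sample_id, "::", tab$channel) == key, ]
    out[[key]] <- sub$position[order(sub$rank)]
  }
  out
}

#' Detect landmarks dataset-wide and derive per-rank targets
#'
#' Runs [detect_peaks()] for every (sample, channel) pair, applies manual
#' overrides, and sets the per-channel target landmark positions to the
#' across-sample median of each rank. Samples whose detection found fewer
#' peaks than expected (and have no override) are excluded from the medians
#' and listed in `needs_override`.
#'
#' @param dataset A `cp_dataset`.
#' @param spec A [landmark_spec()].
#' @return A `cp_landmark_map` with fields `detected`, `targets`,
#'   `needs_override` and `L`.
#' @export
build_landmark_map <- function(dataset, spec) {
  detected <- list()
  needs <- character(0)
  for (ch in names(spec$expected_peaks)) {
    L <- spec$expected_peaks[[ch]]
    per_sample <- list()
    for (s in dataset$samples) {
      key <- paste0(s$sample_id, "::", ch)
      if (key %in% names(spec$overrides)) {
        per_sample[[s$sample_id]] <- as.numeric(spec$overrides[[key]])
      } else {
        pos <- detect_peaks(s, ch, L)
        if (isTRUE(attr(pos, "needs_override"))) {
          needs <- c(needs, key)
          per_sample[[s$sample_id]] <- NULL
        } else {
          per_sample[[s$sample_id]] <- as.numeric(pos)
        }
        detected[[key]] <- as.numeric(pos)
      }
      if (key %in% names(spec$overrides)) detected[[key]] <- as.numeric(spec$overrides[[key]])
    }
    if (length(per_sample) < length(dataset$samples) / 2) {
      cp_stop("cp_normalization_infeasible_error",
              "channel '%s': %d of %d samples need manual peak overrides",
              ch, length(dataset$samples) - length(per_sample),
              length(dataset$samples))
    }
  }
  targets <- list()
  for (ch in names(spec$expected_peaks)) {
    L <- spec$expected_peaks[[ch]]
    mat <- do.call(rbind, lapply(sample_ids(dataset), function(id) {
      key <- paste0(id, "::", ch)
      if (key %in% needs) return(NULL)
      detected[[key]]
    }))
    targets[[ch]] <- apply(mat, 2, stats::median)
  }
  structure(list(detected = detected, targets = targets,
                 needs_override = unique(needs),
                 L = spec$expected_peaks),
            class = "cp_landmark_map")
}

# continuous piecewise-linear warp through (peaks, targets) with slope-1
# extrapolation beyond the outermost landmarks
warp_values <- function(x, peaks, targets) {
  if (length(peaks) == 1) return(x + (targets - peaks))
  out <- numeric(length(x))
  lo <- x < peaks[1]
  hi <- x > peaks[length(peaks)]
  mid <- !lo & !hi
  out[lo] <- x[lo] + (targets[1] - peaks[1])
  out[hi] <- x[hi] + (targets[length(targets)] - peaks[length(peaks)])
  if (any(mid)) {
    out[mid] <- stats::approx(peaks, targets, xout = x[mid], ties = "ordered")$y
  }
  out
}

#' Warp every sample so same-rank peaks align across samples
#'
#' Applies the continuous piecewise-linear landmark warp per sample and
#' covered channel. With one landmark the warp is a pure shift. Before and
#' after density curves are attached as attribute `"qc"` for plotting.
#'
#' @param dataset A `cp_dataset`.
#' @param map A `cp_landmark_map` from [build_landmark_map()] covering all
#'   channels to normalize; every covered (sample, channel) must have
#'   exactly `L` landmark positions (use overrides for samples flagged
#'   `needs_override`).
#' @return The normalized `cp_dataset`, with attribute `"qc"` holding long
#'   before/after density tables per channel.
#' @export
normalize_dataset <- function(dataset, map) {
  qc <- list()
  for (ch in names(map$targets)) {
    tg <- map$targets[[ch]]
    if (is.unsorted(tg, strictly = TRUE)) {
      cp_stop("cp_warp_error", "targets for channel '%s' are not strictly increasing", ch)
    }
    idx <- resolve_channels(dataset$panel, ch)
    before <- after <- list()
    for (id in sample_ids(dataset)) {
      key <- paste0(id, "::", ch)
      peaks <- map$detected[[key]]
      if (is.null(peaks) || length(peaks) != length(tg)) {
        cp_stop("cp_warp_error",
                "sample '%s' channel '%s' has %d landmarks but %d targets; supply an override",
                id, ch, length(peaks), length(tg))
      }
      if (is.unsorted(peaks, strictly = TRUE)) {
        cp_stop("cp_warp_error",
                "sample '%s' channel '%s': landmark positions out of order", id, ch)
      }
      s <- dataset$samples[[id]]
      x <- s$events[, idx]
      d0 <- stats::density(x, n = 256)
      y <- warp_values(x, peaks, tg)
      d1 <- stats::density(y, n = 256)
      before[[id]] <- data.frame(sample_id = id, x = d0$x, density = d0$y)
      after[[id]] <- data.frame(sample_id = id, x = d1$x, density = d1$y)
      s$events[, idx] <- y
      s <- record_provenance(s, "normalize_dataset",
                             list(channel = ch, peaks = peaks, targets = tg))
      dataset$samples[[id]] <- s
    }
    qc[[ch]] <- list(before = do.call(rbind, before),
                     after = do.call(rbind, after))
  }
  attr(dataset, "qc") <- qc
  dataset
}

#' Export normalization QC density curves
#'
#' Writes per-channel before/after density curves (as produced by
#' [normalize_dataset()]) to delimited files for plotting.
#'
#' @param dataset A normalized `cp_dataset` carrying the `"qc"` attribute.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
export_normalization_qc <- function(dataset, dir) {
  qc <- attr(dataset, "qc")
  if (is.null(qc)) cp_stop("cp_lookup_error", "dataset carries no normalization QC data")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in names(qc)) {
    for (phase in c("before", "after")) {
      p <- file.path(dir, sprintf("density_%s_%s.tsv", gsub("[^A-Za-z0-9_-]", "_", ch), phase))
      utils::write.table(qc[[ch]][[phase]], p, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
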