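# Balanced non-destructive downsampling, percentile rescaling, and
# cell-wise train/validation splitting.

#' Balanced, non-destructive downsampling
#'
#' Tags a subset of events (`downsampled`) such that every group
#' contributes equally to the downsampled dataset and every sample of a
#' group contributes equally to its group. The shared group quota is
#' `Q = min_g(m_g * min_{s in g} n_s)` (with `m_g` samples per group and
#' `n_s` eligible events per sample): the largest quota satisfying both
#' equality constraints without replacement. Each sample of group `g`
#' receives `floor(Q / m_g)` events, drawn uniformly without replacement.
#' No events are removed.
#'
#' @param dataset A `cp_dataset`.
#' @param base_tag Tag restricting eligibility (e.g. `"gate:Tregs"`), or
#'   `"root"` for all events.
#' @param seed Integer seed; per-sample substreams are derived from it so
#'   results do not depend on dataset order.
#' @return The tagged `cp_dataset`.
#' @export
downsample_balanced <- function(dataset, base_tag = "root", seed = 1L) {
  eligible <- lapply(dataset$samples, function(s) which(tag_mask(s, base_tag)))
  n_s <- vapply(eligible, length, integer(1))
  empty <- n_s == 0
  if (any(empty)) {
    cp_stop("cp_infeasibility_error",
            "no eligible events under '%s' in sample(s): %s", base_tag,
            paste(names(n_s)[empty], collapse = ", "))
  }
  groups <- dataset$groups
  quota <- vapply(unique(groups), function(g) {
    in_g <- names(groups)[groups == g]
    length(in_g) * min(n_s[in_g])
  }, numeric(1))
  Q <- min(quota)
  dataset <- map_samples(dataset, function(s) {
    m_g <- sum(groups == groups[[s$sample_id]])
    take <- floor(Q / m_g)
    rows <- eligible[[s$sample_id]]
    pick <- with_seed(string_seed(s$sample_id, seed),
                      sample(rows, size = take, replace = FALSE))
    tag <- rep(FALSE, n_events(s))
    tag[pick] <- TRUE
    s$tags[["downsampled"]] <- tag
    record_provenance(s, "downsample_balanced",
                      list(base_tag = base_tag, seed = seed, quota = Q,
                           taken = take))
  })
  dataset
}

#' Parameter-wise percentile rescaling
#'
#' Rescales each channel to `[0, 1]` using pooled percentiles computed over
#' all events of all samples (downsampled or not), preventing highly
#' expressed channels from dominating distance-based steps purely by
#' magnitude: `x -> clip((x - p_lo) / (p_hi - p_lo), 0, 1)`.
#'
#' @param dataset A `cp_dataset`.
#' @param channels Channels to rescale; default all panel channels.
#' @param lo_pct,hi_pct Percentiles in `[0, 100]` defining the linear
#'   range; defaults 0.1 and 99.9 (robust to outliers).
#' @return The rescaled `cp_dataset`; provenance records `p_lo`/`p_hi`.
#' @export
rescale <- function(dataset, channels = NULL, lo_pct = 0.1, hi_pct = 99.9) {
  if (lo_pct < 0 || hi_pct > 100 || lo_pct >= hi_pct) {
    cp_stop("cp_parameter_error", "need 0 <= lo_pct < hi_pct <= 100")
  }
  if (is.null(channels)) channels <- dataset$panel$label
  idx <- resolve_channels(dataset$panel, channels)
  pooled <- pooled_events(dataset, channels)
  p_lo <- apply(pooled, 2, stats::quantile, probs = lo_pct / 100, names = FALSE)
  p_hi <- apply(pooled, 2, stats::quantile, probs = hi_pct / 100, names = FALSE)
  degen <- p_hi <= p_lo
  if (any(degen)) {
    cp_stop("cp_degenerate_channel_error",
            "channel(s) with degenerate percentile range: %s",
            paste(channels[degen], collapse = ", "))
  }
  map_samples(dataset, function(s) {
    for (k in seq_along(idx)) {
      v <- (s$events[, idx[k]] - p_lo[k]) / (p_hi[k] - p_lo[k])
      s$events[, idx[k]] <- pmin(pmax(v, 0), 1)
    }
    record_provenance(s, "rescale",
                      list(channels = channels, p_lo = p_lo, p_hi = p_hi,
                           lo_pct = lo_pct, hi_pct = hi_pct))
  })
}

#' Cell-wise dataset splitting
#'
#' Splits the cells of each sample (but never the samples themselves) into
#' two halves tagged `split:A` (`floor(fraction * n)` events) and
#' `split:B` (the remainder), among `downsampled`-tagged events when that
#' tag exists, else all events. Every sample appears in both halves.
#'
#' @param dataset A `cp_dataset`.
#' @param fraction Fraction assigned to `split:A`, in (0, 1).
#' @param seed Integer seed (per-sample substreams).
#' @return The tagged `cp_dataset`.
#' @export
split_dataset <- function(dataset, fraction = 0.5, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) {
    cp_stop("cp_parameter_error", "fraction must be in (0, 1)")
  }
  map_samples(dataset, function(s) {
    base <- if ("downsampled" %in% names(s$tags)) "downsampled" else NULL
    rows <- which(tag_mask(s, base))
    n <- length(rows)
    n_a <- floor(fraction * n)
    if (n < 2 || n_a == 0 || n_a == n) {
      cp_stop("cp_infeasibility_error",
              "sample '%s': cannot place events in both halves (%d eligible, fraction %g)",
              s$sample_id, n, fraction)
    }
    pick <- with_seed(string_seed(s$sample_id, seed + 7L),
                      sample(rows, size = n_a, replace = FALSE))
    a <- rep(FALSE, n_events(s)); a[pick] <- TRUE
    b <- rep(FALSE, n_events(s)); b[setdiff(rows, pick)] <- TRUE
    s$tags[["split:A"]] <- a
    s$tags[["split:B"]] <- b
    record_provenance(s, "split_dataset",
                      list(fraction = fraction, seed = seed, n_a = n_a,
                           n_b = n - n_a))
  })
}
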