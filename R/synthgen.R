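# Synthetic multi-sample, multi-group cytometry datasets with known
# population structure, spillover and batch shifts, so every pipeline
# stage can be exercised without external data.
#
# Populations are Gaussian mixtures generated directly on the transformed
# scale (where clustering operates); a linear-scale mode with a known
# spillover matrix exists to exercise the compensation and transformation
# stages. Batch shifts are additive on the transformed scale -- the kind of
# displacement landmark normalization corrects. Ground-truth per-event
# population labels are returned alongside (never inside) the samples.

#' Describe one synthetic cell population
#'
#' @param name Population name.
#' @param weight Mixture weight in (0, 1]; weights of a sample sum to 1.
#' @param centers Named numeric vector of per-channel means.
#' @param sigma Named numeric vector of per-channel standard deviations
#'   (> 0), or one value recycled.
#' @param binary_truth Optional named 0/1 vector: the marker-positivity
#'   pattern the population is designed to show.
#' @return A `cp_population` object.
#' @export
population_spec <- function(name, weight, centers, sigma, binary_truth = NULL) {
  if (weight <= 0 || weight > 1) {
    cp_stop("cp_parameter_error", "population weight must be in (0, 1]")
  }
  sigma <- rep_len(sigma, length(centers))
  names(sigma) <- names(centers)
  if (any(sigma <= 0)) cp_stop("cp_parameter_error", "sigma must be > 0")
  structure(list(name = name, weight = weight, centers = centers,
                 sigma = sigma, binary_truth = binary_truth),
            class = "cp_population")
}

#' Describe a synthetic multi-group experiment
#'
#' @param groups Named integer vector `group -> number of samples`.
#' @param populations Named list `group -> list of` [population_spec()]
#'   (group effects are expressed as weight differences); weights per group
#'   must sum to 1.
#' @param n_events Events per sample.
#' @param channels Channel short names (taken from the populations when
#'   NULL).
#' @param batch_shifts Optional named list `sample_id -> named numeric`
#'   additive shifts per channel (transformed scale).
#' @param spillover Optional `cp_spillover` mixed into the events
#'   (linear-scale mode).
#' @param seed Integer seed; per-sample substreams derive from it.
#' @return A `cp_sim_design` object. Sample IDs are `<group>_<replicate>`.
#' @export
simulation_design <- function(groups, populations, n_events = 10000,
                              channels = NULL, batch_shifts = list(),
                              spillover = NULL, seed = 1L) {
  for (g in names(groups)) {
    w <- sum(vapply(populations[[g]], function(p) p$weight, numeric(1)))
    if (abs(w - 1) > 1e-8) {
      cp_stop("cp_parameter_error",
              "population weights of group '%s' sum to %g, not 1", g, w)
    }
  }
  if (is.null(channels)) channels <- names(populations[[1]][[1]]$centers)
  structure(list(groups = groups, populations = populations,
                 n_events = n_events, channels = channels,
                 batch_shifts = batch_shifts, spillover = spillover,
                 seed = seed),
            class = "cp_sim_design")
}

design_sample_ids <- function(design) {
  unlist(lapply(names(design$groups), function(g) {
    sprintf("%s_%d", g, seq_len(design$groups[[g]]))
  }))
}

#' Simulate one sample of a design
#'
#' Draws the sample's events from its group's Gaussian mixture, applies the
#' sample's batch shift, and mixes the events through the spillover matrix
#' when one is present. Ground-truth population labels are returned in a
#' side table, never stored in the sample.
#'
#' @param design A [simulation_design()].
#' @param sample_id One of the design's sample IDs
#'   (`<group>_<replicate>`).
#' @return List with `sample` (a `cp_sample`) and `truth` (integer
#'   population index per event).
#' @export
simulate_sample <- function(design, sample_id) {
  group <- sub("_[0-9]+$", "", sample_id)
  pops <- design$populations[[group]]
  if (is.null(pops)) {
    cp_stop("cp_lookup_error", "sample '%s' matches no design group", sample_id)
  }
  chans <- design$channels
  n <- design$n_events
  res <- with_seed(string_seed(sample_id, design$seed), {
    w <- vapply(pops, function(p) p$weight, numeric(1))
    truth <- sample.int(length(pops), n, replace = TRUE, prob = w)
    events <- matrix(0, n, length(chans))
    for (k in seq_along(pops)) {
      rows <- which(truth == k)
      if (!length(rows)) next
      for (j in seq_along(chans)) {
        events[rows, j] <- stats::rnorm(length(rows),
                                        pops[[k]]$centers[[chans[j]]],
                                        pops[[k]]$sigma[[chans[j]]])
      }
    }
    list(events = events, truth = truth)
  })
  events <- res$events
  shift <- design$batch_shifts[[sample_id]]
  if (!is.null(shift)) {
    for (ch in names(shift)) {
      j <- match(ch, chans)
      events[, j] <- events[, j] + shift[[ch]]
    }
  }
  keywords <- character(0)
  if (!is.null(design$spillover)) {
    S <- design$spillover
    j <- match(S$channels, chans)
    events[, j] <- events[, j, drop = FALSE] %*% S$matrix
    keywords["$SPILLOVER"] <- paste(
      c(length(S$channels), S$channels, t(S$matrix)), collapse = ",")
  }
  s <- new_sample(sample_id, events, channel_info(chans), group = group,
                  keywords = keywords)
  s <- record_provenance(s, "simulate_sample", list(seed = design$seed))
  list(sample = s, truth = res$truth)
}

#' Simulate a full dataset
#'
#' One sample per (group, replicate); optionally writes each sample as an
#' FCS file to exercise the reader end-to-end.
#'
#' @param design A [simulation_design()].
#' @param fcs_dir Optional directory; when given, every sample is written
#'   as `<sample_id>.fcs`.
#' @return List with `dataset` (a `cp_dataset`) and `truth` (named list of
#'   integer label vectors).
#' @export
simulate_dataset <- function(design, fcs_dir = NULL) {
  ids <- design_sample_ids(design)
  sims <- lapply(ids, simulate_sample, design = design)
  samples <- lapply(sims, `[[`, "sample")
  truth <- stats::setNames(lapply(sims, `[[`, "truth"), ids)
  if (!is.null(fcs_dir)) {
    dir.create(fcs_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in samples) write_fcs(s, file.path(fcs_dir, paste0(s$sample_id, ".fcs")))
  }
  list(dataset = new_dataset(samples), truth = truth)
}

#' The standard two-group benchmark design
#'
#' Eight populations with distinct 6-bit marker-positivity patterns over
#' six channels, two groups of four samples, 10^4 events per sample, and
#' an additive batch shift of 0.4 transformed units on two channels for
#' the second half of each group's samples (a two-batch layout). The first
#' population is group-differential: 30% of events in group A versus 5% in
#' group B. Negative and positive modes sit at 1.0 and 3.0 transformed
#' units with standard deviation 0.15.
#'
#' @param n_samples_per_group Samples per group (default 4).
#' @param n_events Events per sample (default 10000).
#' @param batch_shift Shift magnitude in transformed units (default 0.4).
#' @param seed Integer seed.
#' @return A `cp_sim_design`.
#' @export
benchmark_design <- function(n_samples_per_group = 4, n_events = 10000,
                             batch_shift = 0.4, seed = 1L) {
  channels <- c("CD3", "CD4", "CD25", "FoxP3", "CD127", "CTLA4")
  patterns <- rbind(
    c(1, 1, 1, 1, 0, 1),
    c(1, 1, 1, 1, 0, 0),
    c(1, 1, 0, 0, 1, 0),
    c(1, 0, 0, 0, 0, 0),
    c(1, 0, 1, 0, 0, 1),
    c(0, 0, 0, 0, 0, 0),
    c(0, 1, 0, 1, 1, 0),
    c(0, 0, 1, 0, 1, 1)
  )
  colnames(patterns) <- channels
  make_pops <- function(weights) {
    lapply(seq_len(nrow(patterns)), function(k) {
      population_spec(
        name = sprintf("pop%d", k), weight = weights[k],
        centers = stats::setNames(ifelse(patterns[k, ] == 1, 3.0, 1.0), channels),
        sigma = stats::setNames(rep(0.15, length(channels)), channels),
        binary_truth = patterns[k, ]
      )
    })
  }
  w_a <- c(0.30, rep(0.10, 7))
  w_b <- c(0.05, rep(0.95 / 7, 7))
  groups <- c(A = n_samples_per_group, B = n_samples_per_group)
  ids <- unlist(lapply(names(groups), function(g)
    sprintf("%s_%d", g, seq_len(groups[[g]]))))
  # second half of each group's replicates forms batch 2
  shifts <- list()
  for (g in names(groups)) {
    m <- groups[[g]]
    for (r in seq_len(m)) {
      if (r > m / 2) {
        shifts[[sprintf("%s_%d", g, r)]] <-
          c(CD3 = batch_shift, CD4 = batch_shift)
      }
    }
  }
  simulation_design(
    groups = groups,
    populations = list(A = make_pops(w_a), B = make_pops(w_b)),
    n_events = n_events, channels = channels,
    batch_shifts = shifts, seed = seed
  )
}

#' Truth abundance table of a simulated dataset
#'
#' Percent of each sample's events in each designed population, from the
#' ground-truth labels (for validating recovered abundances).
#'
#' @param design The `cp_sim_design` used.
#' @param truth The `truth` list from [simulate_dataset()].
#' @return Data.frame, rows = samples, columns = populations, plus `group`.
#' @export
truth_abundance <- function(design, truth) {
  n_pop <- length(design$populations[[1]])
  rows <- lapply(names(truth), function(id) {
    100 * tabulate(truth[[id]], nbins = n_pop) / length(truth[[id]])
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- as.character(seq_len(n_pop))
  rownames(out) <- names(truth)
  out$group <- sub("_[0-9]+$", "", names(truth))
  out
}
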