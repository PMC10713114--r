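#' Channel metadata table
#'
#' Builds the channel description shared by samples of a dataset. Channels
#' are identified across samples by their FCS short name (`$PnN`); the label
#' is the user-facing, renameable name shown in plots and used to address
#' channels in most operations.
#'
#' @param short_name Character vector of FCS `$PnN` short names (unique).
#' @param label User-facing labels; defaults to `short_name`.
#' @param role One of `"scatter"`, `"fluorescence"`, `"metal"`, `"time"`,
#'   `"derived"` per channel (recycled).
#' @return A `data.frame` with columns `short_name`, `label`, `role`,
#'   `index`.
#' @export
channel_info <- function(short_name, label = short_name, role = "fluorescence") {
  if (anyDuplicated(short_name)) {
    cp_stop("cp_invariant_error", "channel short names must be unique")
  }
  roles <- c("scatter", "fluorescence", "metal", "time", "derived")
  role <- rep_len(role, length(short_name))
  if (!all(role %in% roles)) {
    cp_stop("cp_invariant_error", "unknown channel role; must be one of %s",
            paste(roles, collapse = ", "))
  }
  data.frame(
    short_name = as.character(short_name),
    label = as.character(label),
    role = role,
    index = seq_along(short_name),
    stringsAsFactors = FALSE
  )
}

#' Construct a cytometry sample
#'
#' A `cp_sample` holds one FCS file in memory: the events matrix (rows =
#' cells, columns = channels), channel metadata, named per-event tag vectors
#' (gate membership, downsampling flag, split assignment, cluster labels),
#' the FCS TEXT keywords, and an append-only provenance log.
#'
#' @param sample_id Unique sample identifier.
#' @param events Numeric matrix, `n_events x n_channels`.
#' @param channels Channel table from [channel_info()].
#' @param group Optional group assignment.
#' @param keywords Named character vector (FCS TEXT keywords).
#' @param tags Named list of per-event vectors.
#' @param provenance List of provenance records.
#' @return An object of class `cp_sample`.
#' @export
new_sample <- function(sample_id, events, channels, group = NA_character_,
                       keywords = character(), tags = list(),
                       provenance = list()) {
  events <- as.matrix(events)
  storage.mode(events) <- "double"
  if (ncol(events) != nrow(channels)) {
    cp_stop("cp_invariant_error",
            "events has %d columns but %d channels are described",
            ncol(events), nrow(channels))
  }
  colnames(events) <- channels$short_name
  for (nm in names(tags)) {
    if (length(tags[[nm]]) != nrow(events)) {
      cp_stop("cp_invariant_error",
              "tag '%s' has length %d but the sample has %d events",
              nm, length(tags[[nm]]), nrow(events))
    }
  }
  structure(
    list(
      sample_id = as.character(sample_id),
      group = as.character(group),
      events = events,
      channels = channels,
      tags = tags,
      keywords = keywords,
      provenance = provenance
    ),
    class = "cp_sample"
  )
}

#' @export
print.cp_sample <- function(x, ...) {
  cat(sprintf("<cp_sample> %s: %d events x %d channels", x$sample_id,
              nrow(x$events), nrow(x$channels)))
  if (!is.na(x$group)) cat(sprintf(" [group %s]", x$group))
  cat("\n")
  if (length(x$tags)) cat("  tags:", paste(names(x$tags), collapse = ", "), "\n")
  invisible(x)
}

n_events <- function(sample) nrow(sample$events)

record_provenance <- function(sample, operation, params = list()) {
  sample$provenance <- c(
    sample$provenance,
    list(list(operation = operation, params = params,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  )
  sample
}

#' Construct a dataset of samples sharing one panel
#'
#' A `cp_dataset` is an ordered collection of [new_sample()] objects with a
#' group assignment per sample and a shared channel panel. All samples must
#' carry the same channels (same short names, labels and order).
#'
#' @param samples List of `cp_sample` objects.
#' @param groups Optional named character vector `sample_id -> group`;
#'   defaults to each sample's own `group` field.
#' @return An object of class `cp_dataset`.
#' @export
new_dataset <- function(samples, groups = NULL) {
  if (!length(samples)) cp_stop("cp_invariant_error", "dataset needs >= 1 sample")
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) {
    cp_stop("cp_invariant_error", "duplicate sample_id: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(samples) <- ids
  panel <- samples[[1]]$channels
  for (s in samples) {
    if (!identical(s$channels$short_name, panel$short_name) ||
        !identical(s$channels$label, panel$label)) {
      cp_stop("cp_invariant_error",
              "sample '%s' does not share the dataset panel", s$sample_id)
    }
  }
  if (is.null(groups)) {
    groups <- vapply(samples, function(s) s$group, character(1))
  }
  if (!all(ids %in% names(groups))) {
    cp_stop("cp_invariant_error", "every sample_id must appear in groups")
  }
  groups <- groups[ids]
  for (i in seq_along(samples)) samples[[i]]$group <- unname(groups[ids[i]])
  structure(
    list(samples = samples, groups = groups, panel = panel),
    class = "cp_dataset"
  )
}

#' @export
print.cp_dataset <- function(x, ...) {
  cat(sprintf("<cp_dataset> %d samples, %d channels, groups: %s\n",
              length(x$samples), nrow(x$panel),
              paste(sprintf("%s(%d)", names(table(x$groups)),
                            table(x$groups)), collapse = ", ")))
  invisible(x)
}

sample_ids <- function(dataset) names(dataset$samples)

# Map labels or short names to panel column indices.
resolve_channels <- function(panel, channels) {
  idx <- match(channels, panel$label)
  miss <- is.na(idx)
  idx[miss] <- match(channels[miss], panel$short_name)
  if (anyNA(idx)) {
    cp_stop("cp_lookup_error",
            "unknown channel(s): %s. Available: %s",
            paste(channels[is.na(idx)], collapse = ", "),
            paste(panel$label, collapse = ", "))
  }
  idx
}

# Apply a function sample-wise, preserving dataset structure.
map_samples <- function(dataset, f, ...) {
  dataset$samples <- lapply(dataset$samples, f, ...)
  dataset
}

# Pooled event matrix over selected channels, restricted to a tag.
pooled_events <- function(dataset, channels = NULL, tag = NULL) {
  idx <- if (is.null(channels)) seq_len(nrow(dataset$panel)) else
    resolve_channels(dataset$panel, channels)
  blocks <- lapply(dataset$samples, function(s) {
    keep <- tag_mask(s, tag)
    s$events[keep, idx, drop = FALSE]
  })
  do.call(rbind, blocks)
}

# Resolve a tag name to a logical mask; NULL or "root" selects all events.
tag_mask <- function(sample, tag) {
  if (is.null(tag) || identical(tag, "root")) return(rep(TRUE, n_events(sample)))
  if (!tag %in% names(sample$tags)) {
    cp_stop("cp_lookup_error", "sample '%s' has no tag '%s'",
            sample$sample_id, tag)
  }
  v <- sample$tags[[tag]]
  if (!is.logical(v)) cp_stop("cp_lookup_error", "tag '%s' is not boolean", tag)
  v
}

# index table (sample_id, row) of events selected by a tag, in dataset order
tag_index <- function(dataset, tag) {
  out <- lapply(dataset$samples, function(s) {
    rows <- which(tag_mask(s, tag))
    if (!length(rows)) return(NULL)
    data.frame(sample_id = s$sample_id, row = rows, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
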