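# FCS 3.0/3.1 reading and FCS 3.1 writing.
#
# The reader honours $DATATYPE (F = float32, D = float64, I = unsigned
# integer), $BYTEORD (1,2,3,4 little-endian / 4,3,2,1 big-endian), $PnB and
# $PnR, and cross-checks the decoded row count against $TOT. The writer
# emits one unambiguous dialect: FCS 3.1, $DATATYPE=F, little-endian, a
# single data segment. Delimiter characters inside keyword values are
# escaped by doubling, as the standard prescribes.

FCS_DELIM <- "/"

split_text_segment <- function(text, delim) {
  parts <- strsplit(text, delim, fixed = TRUE)[[1]]
  # doubled delimiters inside values arrive as empty strings: re-join them
  out <- character(0)
  i <- 1
  while (i <= length(parts)) {
    piece <- parts[i]
    while (i < length(parts) && parts[i + 1] == "" && i + 2 <= length(parts)) {
      piece <- paste0(piece, delim, parts[i + 2])
      i <- i + 2
    }
    out <- c(out, piece)
    i <- i + 1
  }
  out
}

parse_text_keywords <- function(raw, delim) {
  text <- rawToChar(raw)
  parts <- split_text_segment(text, delim)
  if (length(parts) && parts[1] == "") parts <- parts[-1]
  if (length(parts) %% 2 == 1) parts <- c(parts, "")
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  stats::setNames(trimws(vals), trimws(keys))
}

# safe keyword lookup: NULL when absent (works for named character vectors)
kw_get <- function(keywords, key) {
  if (!length(keywords) || !key %in% names(keywords)) return(NULL)
  unname(keywords[[key]])
}

kw_num <- function(keywords, key, default = NA_real_) {
  v <- kw_get(keywords, key)
  if (is.null(v) || is.na(v) || v == "") return(default)
  suppressWarnings(as.numeric(v))
}

#' Read an FCS 3.0/3.1 file
#'
#' Parses the HEADER, TEXT and DATA segments of an FCS file and returns a
#' [new_sample()] with the events matrix decoded according to `$DATATYPE`,
#' `$BYTEORD` and `$PnB`. The declared event count (`$TOT`) is verified
#' against the number of rows actually decodable from the data segment.
#'
#' @param path Path to an FCS 3.0 or 3.1 file.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @param group Optional group assignment.
#' @return A `cp_sample` with keywords populated from the TEXT segment.
#' @export
read_fcs <- function(path, sample_id = NULL, group = NA_character_) {
  if (!file.exists(path)) cp_stop("cp_io_error", "file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 58)
  version <- rawToChar(header[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    cp_stop("cp_unsupported_format_error",
            "unsupported FCS version '%s' (only 3.0 and 3.1 are handled)",
            version)
  }
  offs <- function(i) {
    s <- rawToChar(header[(11 + 8 * (i - 1)):(10 + 8 * i)])
    suppressWarnings(as.numeric(trimws(s)))
  }
  text_beg <- offs(1); text_end <- offs(2)
  data_beg <- offs(3); data_end <- offs(4)
  if (is.na(text_beg) || is.na(text_end) || text_end <= text_beg) {
    cp_stop("cp_integrity_error", "malformed FCS header text offsets")
  }
  seek(con, text_beg)
  text_raw <- readBin(con, "raw", text_end - text_beg + 1)
  delim <- rawToChar(text_raw[1])
  keywords <- parse_text_keywords(text_raw[-1], delim)

  if (is.na(data_beg) || data_beg == 0) data_beg <- kw_num(keywords, "$BEGINDATA")
  if (is.na(data_end) || data_end == 0) data_end <- kw_num(keywords, "$ENDDATA")
  n_par <- as.integer(kw_num(keywords, "$PAR"))
  n_tot <- as.integer(kw_num(keywords, "$TOT"))
  if (is.na(n_par) || is.na(n_tot)) {
    cp_stop("cp_integrity_error", "missing $PAR or $TOT keyword")
  }
  datatype <- kw_get(keywords, "$DATATYPE")
  byteord <- kw_get(keywords, "$BYTEORD")
  endian <- if (identical(byteord, "4,3,2,1")) "big" else "little"
  bits <- vapply(seq_len(n_par), function(i)
    as.integer(kw_num(keywords, sprintf("$P%dB", i))), integer(1))

  n_bytes <- data_end - data_beg + 1
  seek(con, data_beg)
  if (datatype == "F") {
    if (any(bits != 32)) cp_stop("cp_unsupported_format_error",
                                 "$DATATYPE=F requires $PnB=32")
    vals <- readBin(con, "numeric", n = n_bytes %/% 4, size = 4, endian = endian)
  } else if (datatype == "D") {
    if (any(bits != 64)) cp_stop("cp_unsupported_format_error",
                                 "$DATATYPE=D requires $PnB=64")
    vals <- readBin(con, "numeric", n = n_bytes %/% 8, size = 8, endian = endian)
  } else if (datatype == "I") {
    b <- unique(bits)
    if (length(b) != 1 || !b %in% c(16L, 32L)) {
      cp_stop("cp_unsupported_format_error",
              "integer data supported only for uniform $PnB of 16 or 32")
    }
    size <- b %/% 8L
    if (size == 2) {
      vals <- readBin(con, "integer", n = n_bytes %/% size, size = 2,
                      signed = FALSE, endian = endian)
    } else {
      vals <- readBin(con, "integer", n = n_bytes %/% size, size = 4,
                      endian = endian)
      vals <- ifelse(vals < 0, vals + 2^32, as.numeric(vals))
    }
    vals <- as.numeric(vals)
  } else {
    cp_stop("cp_unsupported_format_error", "unsupported $DATATYPE '%s'",
            datatype)
  }
  n_rows <- length(vals) %/% n_par
  if (n_rows != n_tot) {
    cp_stop("cp_integrity_error",
            "$TOT declares %d events but %d rows were decoded", n_tot, n_rows)
  }
  events <- matrix(vals[seq_len(n_rows * n_par)], nrow = n_rows, ncol = n_par,
                   byrow = TRUE)

  short <- vapply(seq_len(n_par), function(i) {
    v <- kw_get(keywords, sprintf("$P%dN", i))
    if (is.null(v) || !nzchar(v)) sprintf("P%d", i) else v
  }, character(1))
  label <- vapply(seq_len(n_par), function(i) {
    v <- kw_get(keywords, sprintf("$P%dS", i))
    if (is.null(v) || !nzchar(v)) short[i] else v
  }, character(1))
  role <- ifelse(grepl("^(FSC|SSC)", short), "scatter",
                 ifelse(grepl("^Time$", short, ignore.case = TRUE), "time",
                        "fluorescence"))
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  s <- new_sample(sample_id, events, channel_info(short, label, role),
                  group = group, keywords = keywords)
  record_provenance(s, "read_fcs", list(path = path, version = version))
}

escape_delim <- function(x, delim) gsub(delim, paste0(delim, delim), x, fixed = TRUE)

#' Write a sample as an FCS 3.1 file
#'
#' Writes an FCS 3.1 file with `$DATATYPE=F` (float32), little-endian byte
#' order and a single data segment. The user-facing channel label is
#' exported as `$PnS`; `$PnN` keeps the stable short name. Extra per-event
#' channels (e.g. UMAP coordinates or cluster IDs) can be appended after the
#' panel channels.
#'
#' @param sample A `cp_sample`.
#' @param path Output path.
#' @param extra_channels Optional named list of numeric vectors of length
#'   `n_events`, appended as additional channels.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(sample, path, extra_channels = NULL) {
  events <- sample$events
  short <- sample$channels$short_name
  label <- sample$channels$label
  if (!is.null(extra_channels)) {
    for (nm in names(extra_channels)) {
      v <- extra_channels[[nm]]
      if (length(v) != nrow(events)) {
        cp_stop("cp_dimension_error",
                "extra channel '%s' has length %d but the sample has %d events",
                nm, length(v), nrow(events))
      }
      events <- cbind(events, as.numeric(v))
      short <- c(short, nm)
      label <- c(label, nm)
    }
  }
  n_par <- ncol(events)
  n_tot <- nrow(events)

  rng <- vapply(seq_len(n_par), function(i) {
    kw <- kw_get(sample$keywords, sprintf("$P%dR", i))
    if (!is.null(kw) && !is.na(suppressWarnings(as.numeric(kw)))) {
      as.numeric(kw)
    } else {
      m <- if (n_tot) max(events[, i], na.rm = TRUE) else 0
      max(ceiling(m) + 1, 1)
    }
  }, numeric(1))

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot)
  )
  for (i in seq_len(n_par)) {
    kw[[sprintf("$P%dN", i)]] <- short[i]
    kw[[sprintf("$P%dS", i)]] <- label[i]
    kw[[sprintf("$P%dB", i)]] <- "32"
    kw[[sprintf("$P%dE", i)]] <- "0,0"
    kw[[sprintf("$P%dR", i)]] <- format(rng[i], scientific = FALSE, trim = TRUE)
  }
  kw[["$BEGINDATA"]] <- "0000000000"  # placeholder, fixed width
  kw[["$ENDDATA"]] <- "0000000000"

  build_text <- function(kw) {
    paste0(FCS_DELIM,
           paste0(vapply(names(kw), function(k)
             paste0(escape_delim(k, FCS_DELIM), FCS_DELIM,
                    escape_delim(kw[[k]], FCS_DELIM), FCS_DELIM),
             character(1)), collapse = ""))
  }
  text_beg <- 58
  text <- build_text(kw)
  text_end <- text_beg + nchar(text, type = "bytes") - 1
  data_beg <- text_end + 1
  data_end <- data_beg + 4 * n_par * n_tot - 1
  kw[["$BEGINDATA"]] <- sprintf("%010d", data_beg)
  kw[["$ENDDATA"]] <- sprintf("%010d", data_end)
  text <- build_text(kw)  # same width: offsets unchanged

  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_beg, text_end,
                    if (data_end <= 99999999) data_beg else 0,
                    if (data_end <= 99999999) data_end else 0,
                    0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.numeric(t(events)), con, size = 4, endian = "little")
  invisible(path)
}

#' Subset and rename the channels of a dataset
#'
#' Restricts every sample to the channels named in `keep` (matched by short
#' name, in the order given) and relabels them per `rename`. Event values
#' are untouched; scatter and time channels are typically dropped here.
#'
#' @param dataset A `cp_dataset`.
#' @param keep Character vector of channel short names to keep, in the
#'   desired order.
#' @param rename Named character map `short_name -> new label`; keys must be
#'   a subset of `keep`.
#' @return A `cp_dataset` with the reduced, relabelled panel.
#' @export
subset_rename <- function(dataset, keep, rename = character()) {
  panel <- dataset$panel
  idx <- match(keep, panel$short_name)
  if (anyNA(idx)) {
    cp_stop("cp_lookup_error", "unknown channel(s): %s. Available: %s",
            paste(keep[is.na(idx)], collapse = ", "),
            paste(panel$short_name, collapse = ", "))
  }
  if (length(rename) && !all(names(rename) %in% keep)) {
    cp_stop("cp_lookup_error", "rename keys must be a subset of keep")
  }
  new_panel <- panel[idx, , drop = FALSE]
  hit <- match(new_panel$short_name, names(rename))
  new_panel$label[!is.na(hit)] <- unname(rename[hit[!is.na(hit)]])
  new_panel$index <- seq_len(nrow(new_panel))
  rownames(new_panel) <- NULL
  dataset <- map_samples(dataset, function(s) {
    s$events <- s$events[, idx, drop = FALSE]
    s$channels <- new_panel
    record_provenance(s, "subset_rename",
                      list(keep = keep, rename = as.list(rename)))
  })
  dataset$panel <- new_panel
  dataset
}

CHECKPOINT_FORMAT <- "cytopipe-checkpoint"
CHECKPOINT_VERSION <- 1L

#' Save and restore pipeline checkpoints
#'
#' Checkpoints persist a whole dataset (events, tags, keywords, provenance)
#' between pipeline stages in a self-describing, versioned container so that
#' expensive stages need not be re-run. Round-trips are bit-exact.
#'
#' @param dataset A `cp_dataset`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `cp_dataset`.
#' @export
save_checkpoint <- function(dataset, path) {
  saveRDS(list(format = CHECKPOINT_FORMAT, version = CHECKPOINT_VERSION,
               dataset = dataset),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    cp_stop("cp_integrity_error", "cannot read checkpoint '%s': %s",
            path, conditionMessage(e))
  })
  if (!is.list(obj) || !identical(obj$format, CHECKPOINT_FORMAT)) {
    cp_stop("cp_integrity_error", "'%s' is not a cytopipe checkpoint", path)
  }
  if (obj$version > CHECKPOINT_VERSION) {
    cp_stop("cp_integrity_error", "checkpoint version %d is newer than supported %d",
            obj$version, CHECKPOINT_VERSION)
  }
  obj$dataset
}

#' Read a delimited sample sheet
#'
#' Reads a sample sheet (columns `sample_id`, `group`, `path`) and loads the
#' listed FCS files into a dataset.
#'
#' @param sheet_path Path to a TSV/CSV file with columns `sample_id`,
#'   `group`, `path`.
#' @param sep Field separator; default tab.
#' @return A `cp_dataset`.
#' @export
read_sample_sheet <- function(sheet_path, sep = "\t") {
  tab <- utils::read.table(sheet_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "path")
  if (!all(need %in% names(tab))) {
    cp_stop("cp_io_error", "sample sheet must have columns %s",
            paste(need, collapse = ", "))
  }
  samples <- lapply(seq_len(nrow(tab)), function(i) {
    read_fcs(tab$path[i], sample_id = tab$sample_id[i], group = tab$group[i])
  })
  new_dataset(samples)
}
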