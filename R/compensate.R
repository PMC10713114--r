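# Spillover compensation.
#
# Spillover is linear in signal, so compensation always operates on the
# linear scale: when the dataset has already been transformed, the covered
# channels are inverse-transformed, right-multiplied by the inverse
# spillover matrix, and re-transformed.

#' Construct a spillover matrix
#'
#' @param matrix Square numeric matrix; `S[i, j]` is the fraction of
#'   channel-i signal spilling into channel j. Diagonal must be 1.
#' @param channels Channel labels, one per row/column.
#' @return A `cp_spillover` object.
#' @export
spillover_matrix <- function(matrix, channels) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) {
    cp_stop("cp_invariant_error", "spillover matrix must be square")
  }
  if (length(channels) != nrow(matrix)) {
    cp_stop("cp_invariant_error",
            "spillover matrix needs one channel name per row")
  }
  if (any(abs(diag(matrix) - 1) > 1e-9)) {
    cp_stop("cp_invariant_error", "spillover diagonal entries must equal 1")
  }
  if (!all(is.finite(matrix)) || rcond(matrix) < .Machine$double.eps) {
    cp_stop("cp_numerical_error", "spillover matrix is singular or not finite")
  }
  dimnames(matrix) <- list(channels, channels)
  structure(list(channels = as.character(channels), matrix = matrix),
            class = "cp_spillover")
}

#' @export
print.cp_spillover <- function(x, ...) {
  cat(sprintf("<cp_spillover> %d channels: %s\n", length(x$channels),
              paste(x$channels, collapse = ", ")))
  print(x$matrix)
  invisible(x)
}

#' Extract the spillover matrix self-contained in a sample
#'
#' Parses the `$SPILLOVER` (FCS 3.1) or `SPILL` keyword, whose value is
#' `n, name1..namen, n*n row-major values`.
#'
#' @param sample A `cp_sample`.
#' @return A `cp_spillover`, or `NULL` when the sample carries no spillover
#'   keyword.
#' @export
extract_spillover <- function(sample) {
  kw <- sample$keywords
  v <- kw_get(kw, "$SPILLOVER")
  if (is.null(v)) v <- kw_get(kw, "SPILL")
  if (is.null(v)) v <- kw_get(kw, "$SPILL")
  if (is.null(v) || is.na(v) || !nzchar(v)) return(NULL)
  parts <- trimws(strsplit(v, ",")[[1]])
  n <- suppressWarnings(as.integer(parts[1]))
  if (is.na(n) || n < 1) {
    cp_stop("cp_parse_error", "malformed spillover keyword: bad channel count")
  }
  if (length(parts) != 1 + n + n * n) {
    cp_stop("cp_parse_error",
            "malformed spillover keyword: %d names declared but %d fields found (expected %d)",
            n, length(parts) - 1, n + n * n)
  }
  chans <- parts[2:(n + 1)]
  vals <- suppressWarnings(as.numeric(parts[(n + 2):length(parts)]))
  if (anyNA(vals)) cp_stop("cp_parse_error", "malformed spillover keyword: non-numeric value")
  spillover_matrix(matrix(vals, nrow = n, byrow = TRUE), chans)
}

#' Edit one spillover coefficient
#'
#' Returns an updated copy; the diagonal is immutable.
#'
#' @param matrix A `cp_spillover`.
#' @param source,target Channel labels (source signal spilling into target).
#' @param value New spillover fraction.
#' @return The updated `cp_spillover`.
#' @export
set_spillover <- function(matrix, source, target, value) {
  i <- match(source, matrix$channels)
  j <- match(target, matrix$channels)
  if (is.na(i) || is.na(j)) {
    cp_stop("cp_lookup_error", "unknown spillover channel: %s",
            paste(c(source, target)[is.na(c(i, j))], collapse = ", "))
  }
  if (i == j) {
    cp_stop("cp_constraint_error", "diagonal spillover entries are fixed at 1")
  }
  matrix$matrix[i, j] <- value
  matrix
}

#' Apply spillover compensation to a dataset
#'
#' For the channels covered by the matrix, observed events `O` (linear
#' scale) are mapped to `O %*% solve(S)`. With `transform_specs` given, the
#' covered channels are inverse-transformed first and re-transformed after,
#' since spillover algebra is valid only on the linear scale. A warning is
#' raised when provenance shows the dataset was already compensated.
#'
#' @param dataset A `cp_dataset`.
#' @param matrix A `cp_spillover`, or the string `"per-sample"` to use each
#'   sample's self-contained spillover keyword.
#' @param transform_specs Optional named list of [transform_spec()] covering
#'   (at least) the matrix channels, when the dataset is already
#'   transformed.
#' @return The compensated `cp_dataset`.
#' @export
apply_compensation <- function(dataset, matrix, transform_specs = NULL) {
  per_sample <- identical(matrix, "per-sample")
  if (!per_sample && !inherits(matrix, "cp_spillover")) {
    cp_stop("cp_parameter_error",
            "matrix must be a cp_spillover or \"per-sample\"")
  }
  already <- any(vapply(dataset$samples[[1]]$provenance,
                        function(p) identical(p$operation, "apply_compensation"),
                        logical(1)))
  if (already) {
    cp_warn("cp_double_compensation_warning",
            "dataset provenance already records a compensation step; compensation is not idempotent")
  }
  map_samples(dataset, function(s) {
    sp <- if (per_sample) {
      m <- extract_spillover(s)
      if (is.null(m)) {
        cp_stop("cp_availability_error",
                "sample '%s' carries no spillover keyword", s$sample_id)
      }
      m
    } else {
      matrix
    }
    idx <- resolve_channels(s$channels, sp$channels)
    block <- s$events[, idx, drop = FALSE]
    if (!is.null(transform_specs)) {
      specs <- transform_specs[sp$channels]
      if (any(vapply(specs, is.null, logical(1)))) {
        cp_stop("cp_parameter_error",
                "transform_specs must cover every compensated channel")
      }
      for (k in seq_along(idx)) {
        block[, k] <- transform_backward(block[, k], specs[[k]])
      }
    }
    inv <- tryCatch(solve(sp$matrix), error = function(e) {
      cp_stop("cp_numerical_error", "spillover matrix is singular")
    })
    block <- block %*% inv
    if (!is.null(transform_specs)) {
      for (k in seq_along(idx)) {
        block[, k] <- as.numeric(transform_forward(block[, k], specs[[k]]))
      }
    }
    s$events[, idx] <- block
    record_provenance(s, "apply_compensation",
                      list(channels = sp$channels, per_sample = per_sample))
  })
}

#' Read a spillover matrix from a delimited file
#'
#' First row and first column hold the channel labels.
#'
#' @param path Path to a delimited matrix file.
#' @param sep Field separator; default comma.
#' @return A `cp_spillover`.
#' @export
read_spillover <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE)
  spillover_matrix(as.matrix(tab), colnames(tab))
}
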