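# Display transformations for cytometry intensities.
#
# arcsinh:        y = asinh(a + b*x) + c           (closed form both ways)
# biexponential:  y solves x = a*exp(b*(y-w)) - c*exp(-d*(y-w)) + f,
#                 found by bracketed bisection (1e-8 absolute tolerance)
# logicle:        the Parks-Roederer-Moore biexponential family
#                 parameterized by (t, w, m, a); the inverse is closed form
#                 and the forward map is obtained by bisection on it.
#                 Output is scaled to [0, m] display decades so transformed
#                 values are directly comparable across channels.

#' Define a per-channel transformation
#'
#' @param kind `"logicle"`, `"biexponential"` or `"arcsinh"`.
#' @param ... Named parameters. Logicle: `t` (top of scale, > 0), `w`
#'   (linearization width in decades, `0 <= w <= m/2`), `m` (total display
#'   decades, > 0), `a` (additional negative decades, >= 0). Biexponential:
#'   `a`, `b`, `c`, `d`, `f`, `w` with `b > 0`, `d > 0`. Arcsinh: `a`
#'   (pre-offset), `b` (scale, non-zero), `c` (post-offset).
#' @return A `cp_transform` object.
#' @export
transform_spec <- function(kind = c("logicle", "biexponential", "arcsinh"), ...) {
  kind <- match.arg(kind)
  params <- list(...)
  defaults <- switch(kind,
    logicle = list(t = 262144, w = 0.5, m = 4.5, a = 0),
    biexponential = list(a = 0.5, b = 1, c = 0.5, d = 1, f = 0, w = 0),
    arcsinh = list(a = 0, b = 1, c = 0)
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    cp_stop("cp_parameter_error", "unknown %s parameter(s): %s", kind,
            paste(unknown, collapse = ", "))
  }
  p <- utils::modifyList(defaults, params)
  if (kind == "logicle") {
    if (p$t <= 0) cp_stop("cp_parameter_error", "logicle requires t > 0")
    if (p$m <= 0) cp_stop("cp_parameter_error", "logicle requires m > 0")
    if (p$w < 0 || p$w > p$m / 2) {
      cp_stop("cp_parameter_error", "logicle requires 0 <= w <= m/2")
    }
    if (p$a < 0) cp_stop("cp_parameter_error", "logicle requires a >= 0")
  } else if (kind == "biexponential") {
    if (p$b <= 0 || p$d <= 0) {
      cp_stop("cp_parameter_error", "biexponential requires b > 0 and d > 0")
    }
  } else {
    if (p$b == 0) cp_stop("cp_parameter_error", "arcsinh requires b != 0")
  }
  structure(list(kind = kind, params = p), class = "cp_transform")
}

#' @export
print.cp_transform <- function(x, ...) {
  cat(sprintf("<cp_transform> %s(%s)\n", x$kind,
              paste(sprintf("%s=%g", names(x$params), unlist(x$params)),
                    collapse = ", ")))
  invisible(x)
}

# ---- logicle internals (Parks, Roederer & Moore parameterization) ----

logicle_coef <- function(p) {
  Tt <- p$t; W <- p$w; M <- p$m; A <- p$a
  b <- (M + A) * log(10)
  w_rel <- W / (M + A)
  x2 <- A / (M + A)
  x1 <- x2 + w_rel
  x0 <- x2 + 2 * w_rel
  d <- if (W == 0) b else {
    stats::uniroot(function(d) 2 * (log(d) - log(b)) + w_rel * (b + d),
                   lower = .Machine$double.xmin^0.25, upper = b,
                   tol = 1e-14)$root
  }
  c_a <- exp(x0 * (b + d))
  mf_a <- exp(b * x1) - c_a / exp(d * x1)
  a_c <- Tt / ((exp(b) - mf_a) - c_a / exp(d))
  list(a = a_c, b = b, c = c_a * a_c, d = d, f = -mf_a * a_c, x1 = x1)
}

# signal value for normalized display position y in [0, 1]
logicle_inverse_scale <- function(y, cf) {
  neg <- y < cf$x1
  y2 <- ifelse(neg, 2 * cf$x1 - y, y)
  v <- cf$a * exp(cf$b * y2) - cf$c * exp(-cf$d * y2) + cf$f
  ifelse(neg, -v, v)
}

# vectorized bisection of a strictly increasing function g on [lo, hi]
bisect_increasing <- function(g, x, lo, hi, iter = 80L) {
  lo <- rep_len(lo, length(x))
  hi <- rep_len(hi, length(x))
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    below <- g(mid) < x
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

logicle_forward <- function(x, p) {
  if (!length(x)) return(structure(numeric(0), clamped = 0L))
  cf <- logicle_coef(p)
  floor_val <- logicle_inverse_scale(0, cf)
  clamped <- sum(x < floor_val)
  x <- pmax(x, floor_val)
  y <- bisect_increasing(function(y) logicle_inverse_scale(y, cf), x, 0, 1)
  structure(y * p$m, clamped = clamped)
}

logicle_backward <- function(y, p) {
  cf <- logicle_coef(p)
  logicle_inverse_scale(y / p$m, cf)
}

# ---- biexponential internals ----

biexp_value <- function(y, p) {
  p$a * exp(p$b * (y - p$w)) - p$c * exp(-p$d * (y - p$w)) + p$f
}

biexp_forward <- function(x, p, tol = 1e-8) {
  if (!length(x)) return(numeric(0))
  lo <- -1; hi <- 1
  for (i in 1:200) {
    if (biexp_value(lo + p$w, p) <= min(x)) break
    lo <- lo * 2
  }
  for (i in 1:200) {
    if (biexp_value(hi + p$w, p) >= max(x)) break
    hi <- hi * 2
  }
  iters <- ceiling(log2((hi - lo) / tol)) + 2L
  bisect_increasing(function(y) biexp_value(y, p), x,
                    lo + p$w, hi + p$w, iter = iters)
}

transform_forward <- function(x, spec) {
  p <- spec$params
  switch(spec$kind,
    arcsinh = asinh(p$a + p$b * x) + p$c,
    biexponential = biexp_forward(x, p),
    logicle = logicle_forward(x, p)
  )
}

transform_backward <- function(y, spec) {
  p <- spec$params
  switch(spec$kind,
    arcsinh = (sinh(y - p$c) - p$a) / p$b,
    biexponential = biexp_value(y, p),
    logicle = logicle_backward(y, p)
  )
}

#' Apply per-channel transformations to a dataset
#'
#' Transforms the named channels of every sample in place; channels without
#' a spec are untouched. Values below the logicle domain floor are clamped
#' to the transform of the floor and the clamped-event count is recorded in
#' provenance.
#'
#' @param dataset A `cp_dataset`.
#' @param specs Named list mapping channel labels (or short names) to
#'   [transform_spec()] objects.
#' @return The transformed `cp_dataset`.
#' @export
apply_transform <- function(dataset, specs) {
  idx <- resolve_channels(dataset$panel, names(specs))
  map_samples(dataset, function(s) {
    clamped <- integer(0)
    for (k in seq_along(specs)) {
      y <- transform_forward(s$events[, idx[k]], specs[[k]])
      cl <- attr(y, "clamped")
      if (!is.null(cl) && cl > 0) clamped[names(specs)[k]] <- cl
      s$events[, idx[k]] <- as.numeric(y)
    }
    record_provenance(s, "apply_transform", list(
      channels = names(specs),
      specs = lapply(specs, function(sp) c(kind = sp$kind, sp$params)),
      clamped = as.list(clamped)
    ))
  })
}

#' Invert a transformation
#'
#' Maps transformed display values back to the original signal scale, e.g.
#' for spillover compensation or FCS export on the linear scale.
#'
#' @param values Numeric vector of transformed values.
#' @param spec A [transform_spec()].
#' @return Numeric vector on the original scale.
#' @export
inverse_transform <- function(values, spec) {
  if (!inherits(spec, "cp_transform")) {
    cp_stop("cp_parameter_error", "spec must be a cp_transform")
  }
  transform_backward(values, spec)
}

#' Estimate logicle parameters from the data
#'
#' Uses the conventional automatic rule: `t` is the channel range (`$PnR` if
#' present, else the observed maximum), `m = 4.5` decades, `a = 0`, and the
#' linearization width `w = max(0.1, (m - log10(t/|r|)) / 2)` where `r` is
#' the 5th percentile of the channel's negative values; with no negative
#' events, `w = 1`.
#'
#' @param sample A `cp_sample` with at least 100 events.
#' @param channel Channel label or short name.
#' @return A logicle [transform_spec()].
#' @export
estimate_logicle <- function(sample, channel) {
  if (n_events(sample) < 100) {
    cp_stop("cp_estimation_error",
            "logicle estimation needs >= 100 events (got %d)", n_events(sample))
  }
  i <- resolve_channels(sample$channels, channel)
  x <- sample$events[, i]
  t_val <- kw_num(sample$keywords, sprintf("$P%dR", i))
  if (is.na(t_val) || t_val <= 0) t_val <- max(x)
  m <- 4.5
  neg <- x[x < 0]
  w <- if (!length(neg)) 1.0 else {
    r <- stats::quantile(neg, 0.05, names = FALSE)
    max(0.1, (m - log10(t_val / abs(r))) / 2)
  }
  transform_spec("logicle", t = t_val, w = min(w, m / 2), m = m, a = 0)
}
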