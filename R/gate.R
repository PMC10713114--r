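# Declarative gating.
#
# Gates are geometric regions on 1-2 channels arranged in a tree; applying
# a gate tags events (never deletes them), ANDed with the parent gate's
# tag, so iterative gating strategies compose. Boundary convention:
# rectangles, intervals and quadrants are closed on the lower/left bound
# and open on the upper/right bound, so the four quadrant sub-regions
# partition the plane exactly; polygon boundary points count as inside.

#' Define a gate
#'
#' Constructors for the four gate shapes. Geometries:
#' * `gate_rectangle`: `xmin`, `xmax`, `ymin`, `ymax` on two channels;
#' * `gate_polygon`: vertex matrix (`>= 3` rows, columns x and y),
#'   implicitly closed;
#' * `gate_quadrant`: centre `(cx, cy)`; tags four sub-regions
#'   `Q1` (x+, y+), `Q2` (x-, y+), `Q3` (x-, y-), `Q4` (x+, y-);
#' * `gate_interval`: `lo`, `hi` on a single channel.
#'
#' @param gate_id Unique gate identifier.
#' @param channels One (interval) or two channel labels.
#' @param parent Parent gate id, or `"root"` for the whole sample.
#' @param overrides Optional named list `sample_id -> geometry` replacing
#'   the global geometry wholesale for particular samples (same shape).
#' @param xmin,xmax,ymin,ymax Rectangle bounds (`xmin < xmax`,
#'   `ymin < ymax`).
#' @param vertices Polygon vertex matrix or data.frame.
#' @param cx,cy Quadrant centre.
#' @param lo,hi Interval bounds (`lo < hi`).
#' @return A `cp_gate` object.
#' @export
gate_rectangle <- function(gate_id, channels, xmin, xmax, ymin, ymax,
                           parent = "root", overrides = list()) {
  if (xmin >= xmax || ymin >= ymax) {
    cp_stop("cp_parameter_error", "rectangle bounds must be ordered")
  }
  new_gate(gate_id, "rectangle", channels, 2,
           list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
           parent, overrides)
}

#' @rdname gate_rectangle
#' @export
gate_polygon <- function(gate_id, channels, vertices, parent = "root",
                         overrides = list()) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3 || ncol(vertices) != 2) {
    cp_stop("cp_parameter_error", "polygon needs >= 3 vertices of (x, y)")
  }
  new_gate(gate_id, "polygon", channels, 2, list(vertices = vertices),
           parent, overrides)
}

#' @rdname gate_rectangle
#' @export
gate_quadrant <- function(gate_id, channels, cx, cy, parent = "root",
                          overrides = list()) {
  new_gate(gate_id, "quadrant", channels, 2, list(cx = cx, cy = cy),
           parent, overrides)
}

#' @rdname gate_rectangle
#' @export
gate_interval <- function(gate_id, channels, lo, hi, parent = "root",
                          overrides = list()) {
  if (lo >= hi) cp_stop("cp_parameter_error", "interval bounds must be ordered")
  new_gate(gate_id, "interval", channels, 1, list(lo = lo, hi = hi),
           parent, overrides)
}

new_gate <- function(gate_id, shape, channels, n_chan, geometry, parent,
                     overrides) {
  if (length(channels) != n_chan) {
    cp_stop("cp_parameter_error", "%s gate needs exactly %d channel(s)",
            shape, n_chan)
  }
  structure(list(gate_id = gate_id, shape = shape,
                 channels = as.character(channels), geometry = geometry,
                 parent = parent, overrides = overrides),
            class = "cp_gate")
}

#' @export
print.cp_gate <- function(x, ...) {
  cat(sprintf("<cp_gate> %s: %s on (%s), parent %s\n", x$gate_id, x$shape,
              paste(x$channels, collapse = ", "), x$parent))
  invisible(x)
}

# boundary-inclusive even-odd point-in-polygon, vectorized over points
points_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  vx <- vertices[, 1]; vy <- vertices[, 2]
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # collinear and within the segment's bounding box -> on boundary
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    on_seg <- abs(cross) <= 1e-12 * pmax(1, abs(xj - xi) + abs(yj - yi)) &
      px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
      py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | on_seg
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

gate_membership <- function(gate, geometry, x, y = NULL) {
  switch(gate$shape,
    rectangle = x >= geometry$xmin & x < geometry$xmax &
      y >= geometry$ymin & y < geometry$ymax,
    interval = x >= geometry$lo & x < geometry$hi,
    polygon = points_in_polygon(x, y, geometry$vertices),
    cp_stop("cp_parameter_error", "unhandled gate shape")
  )
}

#' Apply a gate across a dataset
#'
#' Tags every sample's events with membership of the gate's effective
#' geometry (a per-sample override if present, else the global geometry),
#' ANDed with the parent gate's tag. Quadrant gates produce four tags
#' `gate:<id>:Q1` .. `gate:<id>:Q4` that partition the parent population.
#' Events are never removed.
#'
#' @param dataset A `cp_dataset`.
#' @param gate A `cp_gate`.
#' @return The tagged `cp_dataset`.
#' @export
apply_gate <- function(dataset, gate) {
  idx <- resolve_channels(dataset$panel, gate$channels)
  parent_tag <- if (identical(gate$parent, "root")) NULL else
    paste0("gate:", gate$parent)
  map_samples(dataset, function(s) {
    if (!is.null(parent_tag) && !parent_tag %in% names(s$tags)) {
      cp_stop("cp_dependency_error",
              "sample '%s' lacks parent gate tag '%s'; apply the parent gate first",
              s$sample_id, parent_tag)
    }
    parent_mask <- if (is.null(parent_tag)) rep(TRUE, n_events(s)) else
      s$tags[[parent_tag]]
    geom <- gate$overrides[[s$sample_id]]
    if (is.null(geom)) geom <- gate$geometry
    x <- s$events[, idx[1]]
    y <- if (length(idx) > 1) s$events[, idx[2]] else NULL
    if (gate$shape == "quadrant") {
      xp <- x >= geom$cx; yp <- y >= geom$cy
      quads <- list(Q1 = xp & yp, Q2 = !xp & yp, Q3 = !xp & !yp, Q4 = xp & !yp)
      for (q in names(quads)) {
        s$tags[[sprintf("gate:%s:%s", gate$gate_id, q)]] <-
          quads[[q]] & parent_mask
      }
    } else {
      s$tags[[paste0("gate:", gate$gate_id)]] <-
        gate_membership(gate, geom, x, y) & parent_mask
    }
    record_provenance(s, "apply_gate",
                      list(gate_id = gate$gate_id, shape = gate$shape,
                           override = !is.null(gate$overrides[[s$sample_id]])))
  })
}

#' Per-sample gate frequencies
#'
#' @param dataset A gated `cp_dataset`.
#' @param gate_id Gate identifier (tag `gate:<gate_id>` must exist); for
#'   quadrant sub-regions pass e.g. `"myquad:Q1"`.
#' @param parent Parent gate id or `"root"`; the denominator population.
#' @return A data.frame with `sample_id`, `n_in`, `n_parent`, `percent` and
#'   a logical `empty_parent` flag (percent is reported as 0 with a warning
#'   when the parent population is empty).
#' @export
gate_frequencies <- function(dataset, gate_id, parent = "root") {
  tag <- paste0("gate:", gate_id)
  parent_tag <- if (identical(parent, "root")) NULL else paste0("gate:", parent)
  rows <- lapply(dataset$samples, function(s) {
    n_in <- sum(tag_mask(s, tag))
    n_parent <- if (is.null(parent_tag)) n_events(s) else
      sum(tag_mask(s, parent_tag))
    empty <- n_parent == 0
    data.frame(sample_id = s$sample_id, n_in = n_in, n_parent = n_parent,
               percent = if (empty) 0 else 100 * n_in / n_parent,
               empty_parent = empty, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (any(out$empty_parent)) {
    cp_warn("cp_empty_parent_warning",
            "empty parent population for sample(s): %s",
            paste(out$sample_id[out$empty_parent], collapse = ", "))
  }
  out
}

#' Read a gating tree from a YAML file
#'
#' Each entry needs `id`, `shape`, `channels`, `geometry` (shape-specific
#' fields; polygon vertices as a list of `[x, y]` pairs) and optionally
#' `parent` and `overrides`.
#'
#' @param path Path to the YAML gates file.
#' @return List of `cp_gate` objects in file order (parents before
#'   children as written).
#' @export
read_gates_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(g) {
    parent <- if (is.null(g$parent)) "root" else g$parent
    ov <- if (is.null(g$overrides)) list() else g$overrides
    geom <- g$geometry
    switch(g$shape,
      rectangle = gate_rectangle(g$id, unlist(g$channels), geom$xmin,
                                 geom$xmax, geom$ymin, geom$ymax, parent, ov),
      polygon = gate_polygon(g$id, unlist(g$channels),
                             do.call(rbind, geom$vertices), parent, ov),
      quadrant = gate_quadrant(g$id, unlist(g$channels), geom$cx, geom$cy,
                               parent, ov),
      interval = gate_interval(g$id, unlist(g$channels), geom$lo, geom$hi,
                               parent, ov),
      cp_stop("cp_parameter_error", "unknown gate shape '%s'", g$shape)
    )
  })
}
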