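# In-code fixtures shared across test files.

# tiny deterministic sample with given event matrix
make_sample <- function(events, id = "S1", group = "A",
                        labels = NULL, keywords = character()) {
  events <- as.matrix(events)
  short <- paste0("FL", seq_len(ncol(events)))
  ch <- channel_info(short, if (is.null(labels)) short else labels)
  new_sample(id, events, ch, group = group, keywords = keywords)
}

# dataset of gaussian-mixture samples on shared channels
make_mixture_dataset <- function(n_per_sample, centers_list, sigma = 0.15,
                                 groups = NULL, seed = 42) {
  set.seed(seed)
  ids <- names(centers_list)
  samples <- lapply(seq_along(centers_list), function(i) {
    centers <- centers_list[[i]]  # matrix pops x channels
    n_pop <- nrow(centers)
    truth <- sample.int(n_pop, n_per_sample, replace = TRUE)
    ev <- centers[truth, , drop = FALSE] +
      matrix(rnorm(n_per_sample * ncol(centers), 0, sigma),
             n_per_sample, ncol(centers))
    make_sample(ev, id = ids[i],
                group = if (is.null(groups)) "A" else groups[i])
  })
  new_dataset(samples)
}

# independent ray-casting point-in-polygon oracle (scalar loop, counts
# boundary points as inside via an explicit on-segment check)
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  crossings <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- poly[i, 1]; y1 <- poly[i, 2]
    x2 <- poly[j, 1]; y2 <- poly[j, 2]
    # on-segment check
    d <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    if (abs(d) < 1e-12 &&
        px >= min(x1, x2) - 1e-12 && px <= max(x1, x2) + 1e-12 &&
        py >= min(y1, y2) - 1e-12 && py <= max(y1, y2) + 1e-12) {
      return(TRUE)
    }
    if ((y1 > py) != (y2 > py)) {
      x_int <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      if (px < x_int) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}

# brute-force kNN majority-vote oracle over a full distance matrix,
# ties between majority labels resolved to the nearest neighbour's label
oracle_knn <- function(train, train_labels, query, k) {
  apply(query, 1, function(q) {
    d <- sqrt(colSums((t(train) - q)^2))
    nn <- order(d)[seq_len(k)]
    lab <- train_labels[nn]
    tab <- table(lab)
    winners <- as.integer(names(tab)[tab == max(tab)])
    if (length(winners) == 1) winners else lab[1]
  })
}

# independent greedy re-implementation on plain matrices: phase 1 merges
# identical bit vectors; phase 2 merges the best pair (Hamming, smallest
# member count, lowest pair IDs) while above K_max
oracle_collapse <- function(bits, sizes, der, K_max) {
  groups <- lapply(seq_len(nrow(bits)), function(i)
    list(ids = i, n = sizes[i], d = der[i, ]))
  state <- function() {
    B <- t(vapply(groups, function(g) as.integer(g$d > 0.5),
                  integer(ncol(bits))))
    if (is.null(dim(B))) B <- matrix(B, nrow = 1)
    B
  }
  pair_table <- function(B) {
    n_g <- length(groups)
    pairs <- expand.grid(i = seq_len(n_g), j = seq_len(n_g))
    pairs <- pairs[pairs$i < pairs$j, , drop = FALSE]
    pairs$h <- mapply(function(i, j) sum(B[i, ] != B[j, ]), pairs$i, pairs$j)
    pairs$msize <- mapply(function(i, j) min(groups[[i]]$n, groups[[j]]$n),
                          pairs$i, pairs$j)
    pairs$mid <- mapply(function(i, j) min(groups[[i]]$ids, groups[[j]]$ids),
                        pairs$i, pairs$j)
    pairs$mid2 <- mapply(function(i, j)
      max(min(groups[[i]]$ids), min(groups[[j]]$ids)), pairs$i, pairs$j)
    pairs
  }
  do_merge <- function(i, j) {
    gi <- groups[[i]]; gj <- groups[[j]]
    merged <- list(ids = c(gi$ids, gj$ids), n = gi$n + gj$n,
                   d = (gi$n * gi$d + gj$n * gj$d) / (gi$n + gj$n))
    groups[[i]] <<- merged
    groups[[j]] <<- NULL
  }
  repeat {  # phase 1
    if (length(groups) <= 1) break
    pairs <- pair_table(state())
    ident <- pairs[pairs$h == 0, , drop = FALSE]
    if (!nrow(ident)) break
    do_merge(ident$i[1], ident$j[1])
  }
  while (length(groups) > K_max) {  # phase 2
    pairs <- pair_table(state())
    best <- pairs[order(pairs$h, pairs$msize, pairs$mid, pairs$mid2), ][1, ]
    do_merge(best$i, best$j)
  }
  sort(vapply(groups, function(g) g$n, numeric(1)), decreasing = TRUE)
}
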