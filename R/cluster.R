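# Guided semi-supervised clustering and UMAP embedding.
#
# The clustering proceeds in four stages: (1) agglomerative (Ward)
# clustering of a seeded training subset of the downsampled cells, cut
# into K_init fine clusters; (2) propagation of the training labels to the
# remaining cells by k-nearest-neighbour majority vote; (3) binarization
# of each fine cluster into a marker-positivity bit vector against
# per-channel thresholds; (4) collapsing of fine clusters by binary
# proximity -- identical bit vectors merge first, then the closest pairs by
# Hamming distance until at most K_max clusters remain, recomputing the
# merged phenotype from the pooled member events at each step.

#' UMAP embedding of the downsampled events
#'
#' Embeds all `downsampled`-tagged events over the stated channels into 2D
#' with UMAP. Runs single-threaded under a fixed seed so coordinates are
#' reproducible.
#'
#' @param dataset A `cp_dataset` with a `downsampled` tag and rescaled
#'   channels.
#' @param channels Channels to embed on.
#' @param n_neighbors,min_dist,metric UMAP parameters (defaults 15, 0.1,
#'   `"euclidean"`).
#' @param seed Integer seed.
#' @return List with `coordinates` (matrix, one row per tagged event),
#'   `params` and `event_index` (data.frame `sample_id`, `row`).
#' @export
run_umap <- function(dataset, channels, n_neighbors = 15, min_dist = 0.1,
                     metric = "euclidean", seed = 1L) {
  X <- pooled_events(dataset, channels, tag = "downsampled")
  if (nrow(X) < n_neighbors + 1) {
    cp_stop("cp_infeasibility_error",
            "UMAP needs at least n_neighbors + 1 = %d tagged events (got %d)",
            n_neighbors + 1, nrow(X))
  }
  coords <- with_seed(seed, uwot::umap(
    X, n_neighbors = n_neighbors, min_dist = min_dist, metric = metric,
    n_threads = 1, n_sgd_threads = 0, verbose = FALSE
  ))
  colnames(coords) <- c("UMAP1", "UMAP2")
  list(
    coordinates = coords,
    params = list(n_neighbors = n_neighbors, min_dist = min_dist,
                  metric = metric, seed = seed),
    event_index = tag_index(dataset, "downsampled")
  )
}

#' Hierarchical clustering of a training subset
#'
#' Draws a seeded uniform training subset of the tagged events and cuts a
#' Ward-linkage (Euclidean) agglomerative tree into `K_init` fine clusters.
#'
#' @param dataset A `cp_dataset` with a `downsampled` tag.
#' @param channels Channels to cluster on (rescaled).
#' @param training_fraction Fraction of tagged events used for training
#'   (default 0.1).
#' @param K_init Number of fine clusters to cut (default 100).
#' @param linkage Agglomeration method for [stats::hclust()]; default
#'   `"ward.D2"`.
#' @param seed Integer seed.
#' @return A partial `cp_cluster_model` holding the training events,
#'   labels and parameters.
#' @export
train_hierarchical <- function(dataset, channels, training_fraction = 0.1,
                               K_init = 100, linkage = "ward.D2", seed = 1L) {
  X <- pooled_events(dataset, channels, tag = "downsampled")
  n <- nrow(X)
  n_train <- floor(training_fraction * n)
  if (n_train < K_init) {
    cp_stop("cp_infeasibility_error",
            "training set of %d events is smaller than K_init = %d",
            n_train, K_init)
  }
  train_rows <- sort(with_seed(seed, sample.int(n, n_train)))
  Xt <- X[train_rows, , drop = FALSE]
  hc <- stats::hclust(stats::dist(Xt), method = linkage)
  labels <- stats::cutree(hc, k = K_init)
  structure(
    list(channels = channels, training_index = train_rows,
         training_events = Xt, training_labels = labels,
         linkage = linkage, K_init = K_init, seed = seed),
    class = "cp_cluster_model"
  )
}

# majority vote over the k nearest training labels; ties broken by the
# label of the single nearest neighbour
knn_vote <- function(neighbor_labels) {
  apply(neighbor_labels, 1, function(lab) {
    tab <- table(lab)
    winners <- as.integer(names(tab)[tab == max(tab)])
    # tie between majority labels -> fall back to the nearest neighbour
    if (length(winners) == 1) winners else lab[1]
  })
}

#' Propagate training labels by k-nearest neighbours
#'
#' Assigns every tagged event a fine-cluster label: training events keep
#' their own label; every other event receives the majority label of its
#' `k_nn` nearest training events (Euclidean distance on the model's
#' channels), with ties broken by the label of the single nearest
#' neighbour.
#'
#' @param model A `cp_cluster_model` from [train_hierarchical()].
#' @param dataset The `cp_dataset` the model was trained on.
#' @param k_nn Number of neighbours (default 11); must not exceed the
#'   training size.
#' @return Integer labels, one per tagged event (in [run_umap()]
#'   `event_index` order).
#' @export
knn_assign <- function(model, dataset, k_nn = 11) {
  if (k_nn > length(model$training_labels)) {
    cp_stop("cp_parameter_error",
            "k_nn = %d exceeds the training size %d", k_nn,
            length(model$training_labels))
  }
  X <- pooled_events(dataset, model$channels, tag = "downsampled")
  labels <- integer(nrow(X))
  labels[model$training_index] <- model$training_labels
  query_rows <- setdiff(seq_len(nrow(X)), model$training_index)
  if (length(query_rows)) {
    nn <- FNN::get.knnx(model$training_events, X[query_rows, , drop = FALSE],
                        k = k_nn)
    neighbor_labels <- matrix(model$training_labels[nn$nn.index],
                              nrow = length(query_rows))
    labels[query_rows] <- knn_vote(neighbor_labels)
  }
  labels
}

#' Binarize cluster phenotypes against per-channel thresholds
#'
#' For every cluster and channel, computes the fraction of member events
#' whose value exceeds the channel threshold; the phenotype bit is 1 iff
#' that fraction is strictly greater than 0.5.
#'
#' @param data Numeric event matrix (tagged events x clustering channels).
#' @param labels Integer cluster labels, one per row of `data`.
#' @param thresholds Named numeric vector of positivity cutoffs covering
#'   every column of `data`.
#' @return A `cp_phenotypes` object: per-cluster bit matrix, fraction-
#'   positive (`derivation`) matrix and member counts.
#' @export
binarize_phenotypes <- function(data, labels, thresholds) {
  channels <- colnames(data)
  if (!all(channels %in% names(thresholds))) {
    cp_stop("cp_parameter_error",
            "thresholds missing for channel(s): %s",
            paste(setdiff(channels, names(thresholds)), collapse = ", "))
  }
  thr <- thresholds[channels]
  ids <- sort(unique(labels))
  sizes <- as.integer(table(factor(labels, levels = ids)))
  if (any(sizes == 0)) {
    cp_warn("cp_empty_cluster_warning", "empty cluster(s) excluded")
    keep <- sizes > 0
    ids <- ids[keep]; sizes <- sizes[keep]
  }
  pos <- sweep(data, 2, thr, FUN = ">")
  derivation <- do.call(rbind, lapply(ids, function(id) {
    colMeans(pos[labels == id, , drop = FALSE])
  }))
  rownames(derivation) <- ids
  bits <- (derivation > 0.5) * 1L
  structure(list(ids = ids, bits = bits, derivation = derivation,
                 sizes = stats::setNames(sizes, ids), thresholds = thr),
            class = "cp_phenotypes")
}

#' Collapse clusters by binary proximity
#'
#' Stage 1 merges clusters with identical phenotype bit vectors. Stage 2
#' repeatedly merges the pair of collapsed clusters with the smallest
#' Hamming distance between bit vectors until at most `K_max` remain (ties:
#' the pair containing the smallest cluster by member count, then lowest
#' cluster IDs), recomputing the merged phenotype from the pooled member
#' events after every merge. Final cluster IDs are renumbered 1..K_final by
#' decreasing size.
#'
#' @param phenotypes A `cp_phenotypes` from [binarize_phenotypes()].
#' @param K_max Maximum number of final clusters (>= 1).
#' @return List with `collapse_map` (named integer vector, initial ID ->
#'   final ID), `K_final`, and the final `phenotypes`.
#' @export
collapse_clusters <- function(phenotypes, K_max) {
  if (K_max < 1) cp_stop("cp_parameter_error", "K_max must be >= 1")
  # state: groups of initial cluster ids, with pooled derivations
  groups <- lapply(seq_along(phenotypes$ids), function(i) {
    list(members = phenotypes$ids[i],
         size = unname(phenotypes$sizes[i]),
         derivation = phenotypes$derivation[i, ],
         min_id = phenotypes$ids[i])
  })
  bits_of <- function(g) (g$derivation > 0.5) * 1L
  merge_groups <- function(g1, g2) {
    n1 <- g1$size; n2 <- g2$size
    list(members = c(g1$members, g2$members), size = n1 + n2,
         derivation = (n1 * g1$derivation + n2 * g2$derivation) / (n1 + n2),
         min_id = min(g1$min_id, g2$min_id))
  }
  # stage 1: merge identical bit vectors
  repeat {
    keys <- vapply(groups, function(g) paste(bits_of(g), collapse = ""),
                   character(1))
    dup <- which(duplicated(keys))
    if (!length(dup)) break
    j <- dup[1]
    i <- match(keys[j], keys)
    groups[[i]] <- merge_groups(groups[[i]], groups[[j]])
    groups[[j]] <- NULL
  }
  # stage 2: greedy Hamming merges until <= K_max
  while (length(groups) > K_max) {
    B <- do.call(rbind, lapply(groups, bits_of))
    best <- NULL
    for (i in seq_len(length(groups) - 1)) {
      for (j in (i + 1):length(groups)) {
        h <- sum(B[i, ] != B[j, ])
        cand <- list(
          i = i, j = j,
          key = c(h, min(groups[[i]]$size, groups[[j]]$size),
                  min(groups[[i]]$min_id, groups[[j]]$min_id),
                  max(groups[[i]]$min_id, groups[[j]]$min_id))
        )
        # lexicographic: Hamming distance, smallest member count,
        # then the pair's lowest (and second) original cluster IDs
        if (is.null(best)) {
          best <- cand
        } else {
          cmp <- cand$key - best$key
          first <- which(cmp != 0)[1]
          if (!is.na(first) && cmp[first] < 0) best <- cand
        }
      }
    }
    groups[[best$i]] <- merge_groups(groups[[best$i]], groups[[best$j]])
    groups[[best$j]] <- NULL
  }
  # renumber by decreasing size
  ord <- order(vapply(groups, function(g) g$size, numeric(1)),
               decreasing = TRUE)
  groups <- groups[ord]
  collapse_map <- integer(0)
  for (f in seq_along(groups)) {
    for (m in groups[[f]]$members) collapse_map[as.character(m)] <- f
  }
  final_bits <- do.call(rbind, lapply(groups, bits_of))
  final_der <- do.call(rbind, lapply(groups, function(g) g$derivation))
  rownames(final_bits) <- rownames(final_der) <- seq_along(groups)
  list(
    collapse_map = collapse_map,
    K_final = length(groups),
    phenotypes = structure(
      list(ids = seq_along(groups), bits = final_bits,
           derivation = final_der,
           sizes = stats::setNames(
             vapply(groups, function(g) g$size, numeric(1)),
             seq_along(groups)),
           thresholds = phenotypes$thresholds),
      class = "cp_phenotypes")
  )
}

#' Default positivity thresholds from pooled densities
#'
#' Per channel, when the pooled kernel density estimate is bimodal the
#' threshold is placed at the minimum-density valley between the two
#' highest peaks; otherwise the pooled median is used. Any user-supplied
#' override wins.
#'
#' @param dataset A `cp_dataset` with rescaled channels and a
#'   `downsampled` tag.
#' @param channels Channels needing thresholds.
#' @param overrides Optional named numeric vector of user thresholds.
#' @return Named numeric vector of thresholds.
#' @export
estimate_thresholds <- function(dataset, channels, overrides = NULL) {
  X <- pooled_events(dataset, channels, tag = "downsampled")
  thr <- vapply(seq_along(channels), function(k) {
    x <- X[, k]
    d <- stats::density(x, bw = "nrd0", n = 512, from = min(x), to = max(x))
    idx <- local_maxima(d$y)
    if (length(idx)) {
      prom <- peak_prominence(d$y, idx)
      idx <- idx[prom >= 0.05 * max(d$y)]
    }
    if (length(idx) >= 2) {
      top2 <- sort(idx[order(d$y[idx], decreasing = TRUE)[1:2]])
      valley <- top2[1] + which.min(d$y[top2[1]:top2[2]]) - 1L
      d$x[valley]
    } else {
      stats::median(x)
    }
  }, numeric(1))
  names(thr) <- channels
  if (!is.null(overrides)) thr[names(overrides)] <- overrides
  thr
}

#' Guided semi-supervised clustering
#'
#' Orchestrates the full clustering flow: hierarchical training,
#' k-nearest-neighbour label propagation, phenotype binarization and
#' binary-proximity collapsing. Final labels are attached to each sample as
#' the integer tag `cluster` (NA for events outside the downsampled set).
#'
#' @param dataset A `cp_dataset` with a `downsampled` tag and rescaled
#'   channels.
#' @param channels Channels to cluster on.
#' @param training_fraction,K_init,k_nn,K_max Method parameters; defaults
#'   0.1, 100, 11, 40.
#' @param thresholds Optional named positivity thresholds; estimated by
#'   [estimate_thresholds()] when absent.
#' @param linkage Linkage method, default `"ward.D2"`.
#' @param seed Integer seed.
#' @param embedding Optional [run_umap()] result; when given, an overlay
#'   table (embedding coordinates + final label) is returned for colouring
#'   the UMAP map.
#' @return List with `dataset` (labels attached), `labels`, `model` (a
#'   completed `cp_cluster_model`), `phenotypes` (final), `collapse_map`,
#'   `K_final`, and `overlay` (or NULL).
#' @export
guided_cluster <- function(dataset, channels, training_fraction = 0.1,
                           K_init = 100, k_nn = 11, K_max = 40,
                           thresholds = NULL, linkage = "ward.D2", seed = 1L,
                           embedding = NULL) {
  model <- train_hierarchical(dataset, channels, training_fraction, K_init,
                              linkage, seed)
  fine <- knn_assign(model, dataset, k_nn)
  X <- pooled_events(dataset, channels, tag = "downsampled")
  if (is.null(thresholds)) thresholds <- estimate_thresholds(dataset, channels)
  phen <- binarize_phenotypes(X, fine, thresholds)
  collapsed <- collapse_clusters(phen, K_max)
  final <- unname(collapsed$collapse_map[as.character(fine)])
  model$k_nn <- k_nn
  model$thresholds <- thresholds
  model$collapse_map <- collapsed$collapse_map
  model$K_final <- collapsed$K_final
  model$phenotypes <- collapsed$phenotypes

  index <- tag_index(dataset, "downsampled")
  dataset <- map_samples(dataset, function(s) {
    lab <- rep(NA_integer_, n_events(s))
    here <- index$sample_id == s$sample_id
    lab[index$row[here]] <- final[here]
    s$tags[["cluster"]] <- lab
    record_provenance(s, "guided_cluster",
                      list(channels = channels, K_init = K_init, k_nn = k_nn,
                           K_max = K_max, K_final = collapsed$K_final,
                           seed = seed))
  })
  overlay <- NULL
  if (!is.null(embedding)) {
    overlay <- cbind(embedding$event_index,
                     as.data.frame(embedding$coordinates),
                     cluster = final)
  }
  list(dataset = dataset, labels = final, model = model,
       phenotypes = collapsed$phenotypes,
       collapse_map = collapsed$collapse_map,
       K_final = collapsed$K_final, overlay = overlay)
}
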