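# Downstream reporting: phenotype and abundance tables, sample-level
# embedding with outlier flagging, nonparametric group comparisons and ROC
# analyses of per-sample features.

cluster_labels_tag <- function(sample) {
  if (!"cluster" %in% names(sample$tags)) {
    cp_stop("cp_lookup_error", "sample '%s' has no 'cluster' tag; run guided_cluster first",
            sample$sample_id)
  }
  sample$tags[["cluster"]]
}

#' Per-cluster median marker intensities
#'
#' @param dataset A clustered `cp_dataset` (integer tag `cluster`).
#' @param channels Channels to summarize.
#' @return Matrix (clusters x channels) of median intensities over member
#'   events, clusters ordered by ID.
#' @export
phenotype_table <- function(dataset, channels) {
  idx <- resolve_channels(dataset$panel, channels)
  blocks <- lapply(dataset$samples, function(s) {
    lab <- cluster_labels_tag(s)
    keep <- !is.na(lab)
    cbind(lab[keep], s$events[keep, idx, drop = FALSE])
  })
  all <- do.call(rbind, blocks)
  ids <- sort(unique(all[, 1]))
  out <- do.call(rbind, lapply(ids, function(id) {
    apply(all[all[, 1] == id, -1, drop = FALSE], 2, stats::median)
  }))
  dimnames(out) <- list(ids, channels)
  out
}

#' Per-sample cluster abundance table
#'
#' Percent of each sample's clustered events falling in each final
#' cluster; absent clusters are zero-filled, and rows sum to 100. Samples
#' with zero clustered events are excluded with a warning.
#'
#' @param dataset A clustered `cp_dataset`.
#' @return A data.frame with rownames `sample_id`, one column per cluster
#'   ID, and a trailing `group` column.
#' @export
abundance_table <- function(dataset) {
  ids <- sort(unique(unlist(lapply(dataset$samples, function(s) {
    lab <- cluster_labels_tag(s)
    lab[!is.na(lab)]
  }))))
  rows <- list()
  dropped <- character(0)
  for (s in dataset$samples) {
    lab <- cluster_labels_tag(s)
    lab <- lab[!is.na(lab)]
    if (!length(lab)) {
      dropped <- c(dropped, s$sample_id)
      next
    }
    counts <- table(factor(lab, levels = ids))
    rows[[s$sample_id]] <- 100 * as.numeric(counts) / length(lab)
  }
  if (length(dropped)) {
    cp_warn("cp_empty_sample_warning",
            "sample(s) with zero clustered events excluded: %s",
            paste(dropped, collapse = ", "))
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- as.character(ids)
  out$group <- unname(dataset$groups[rownames(out)])
  out
}

abundance_matrix <- function(abundance) {
  as.matrix(abundance[, setdiff(names(abundance), "group"), drop = FALSE])
}

#' Sample-level UMAP on cluster abundances
#'
#' Embeds samples (not cells) in cluster-abundance space, joins optional
#' metadata for colouring, and flags outliers: samples whose
#' nearest-neighbour distance in abundance space exceeds the median plus 3
#' MAD of all nearest-neighbour distances. Outliers are only flagged, never
#' removed.
#'
#' @param abundance An [abundance_table()] result.
#' @param metadata Optional data.frame keyed by column `sample_id`.
#' @param n_neighbors UMAP neighbourhood size (default 5; sample-level
#'   tables are small).
#' @param min_dist UMAP minimum distance (default 0.1).
#' @param seed Integer seed.
#' @return A data.frame with `sample_id`, `UMAP1`, `UMAP2`, `group`,
#'   `nn_dist`, `outlier`, plus any metadata columns.
#' @export
sample_umap <- function(abundance, metadata = NULL, n_neighbors = 5,
                        min_dist = 0.1, seed = 1L) {
  A <- abundance_matrix(abundance)
  if (nrow(A) < n_neighbors + 1) {
    cp_stop("cp_infeasibility_error",
            "sample UMAP needs at least n_neighbors + 1 = %d samples (got %d)",
            n_neighbors + 1, nrow(A))
  }
  coords <- with_seed(seed, uwot::umap(
    A, n_neighbors = n_neighbors, min_dist = min_dist,
    n_threads = 1, n_sgd_threads = 0, verbose = FALSE
  ))
  nn <- FNN::get.knn(A, k = 1)$nn.dist[, 1]
  cutoff <- stats::median(nn) + 3 * stats::mad(nn)
  out <- data.frame(sample_id = rownames(A), UMAP1 = coords[, 1],
                    UMAP2 = coords[, 2], group = abundance$group,
                    nn_dist = nn, outlier = nn > cutoff,
                    stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    if (!"sample_id" %in% names(metadata)) {
      cp_stop("cp_parameter_error", "metadata must have a sample_id column")
    }
    out <- merge(out, metadata, by = "sample_id", all.x = TRUE, sort = FALSE)
  }
  out
}

#' Nonparametric group comparison of cluster abundances
#'
#' Per cluster: two-sided Wilcoxon rank-sum test for two groups, Kruskal-
#' Wallis for more, with Benjamini-Hochberg adjustment across clusters.
#'
#' @param abundance An [abundance_table()] result with >= 2 groups of >= 2
#'   samples each.
#' @param exact Passed to [stats::wilcox.test()]; default FALSE (normal
#'   approximation, robust to ties).
#' @return A data.frame with one row per cluster: per-group medians, the
#'   test statistic, `p`, and BH-adjusted `p_adj`.
#' @export
group_compare <- function(abundance, exact = FALSE) {
  A <- abundance_matrix(abundance)
  g <- factor(abundance$group)
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    cp_stop("cp_parameter_error",
            "group comparison needs >= 2 groups with >= 2 samples each")
  }
  rows <- lapply(colnames(A), function(cl) {
    v <- A[, cl]
    med <- tapply(v, g, stats::median)
    if (nlevels(g) == 2) {
      tst <- suppressWarnings(stats::wilcox.test(
        v[g == levels(g)[1]], v[g == levels(g)[2]], exact = exact))
      stat <- unname(tst$statistic); test <- "wilcoxon"
    } else {
      tst <- stats::kruskal.test(v, g)
      stat <- unname(tst$statistic); test <- "kruskal-wallis"
    }
    out <- data.frame(cluster = cl, test = test, statistic = stat,
                      p = tst$p.value, stringsAsFactors = FALSE)
    for (lv in levels(g)) out[[paste0("median_", lv)]] <- unname(med[lv])
    out
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Empirical ROC analysis of a per-sample feature
#'
#' Computes the empirical ROC of a real-valued feature for separating one
#' group (the positives) from the rest, sweeping all distinct values as
#' thresholds (a sample is called positive when `value >= threshold`). The
#' AUC is the rank-based Mann-Whitney statistic (identical to the
#' trapezoidal area under the empirical curve, and tie-robust); the Youden
#' cutoff maximizes `sensitivity + specificity - 1`, ties resolved to the
#' lower cutoff.
#'
#' @param values Named numeric vector (one feature value per sample) or
#'   plain numeric vector aligned with `groups`.
#' @param groups Group label per sample.
#' @param positive_group Label treated as positive.
#' @return A `cp_roc` list: `thresholds`, `sensitivity`, `specificity`,
#'   `auc`, `youden_cutoff`, `positive_group`.
#' @export
roc_analysis <- function(values, groups, positive_group) {
  pos <- groups == positive_group
  if (!any(pos) || all(pos)) {
    cp_stop("cp_parameter_error",
            "ROC needs both a positive and a negative class")
  }
  v <- as.numeric(values)
  thr <- sort(unique(v))
  thresholds <- c(-Inf, thr, Inf)
  sens <- vapply(thresholds, function(t) mean(v[pos] >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(v[!pos] < t), numeric(1))
  # rank-based (Mann-Whitney) AUC; handles ties by midranks
  r <- rank(v)
  n1 <- sum(pos); n0 <- sum(!pos)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  youden <- sens + spec - 1
  best <- which(youden == max(youden))
  youden_cutoff <- min(thresholds[best])
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc,
                 youden_cutoff = youden_cutoff,
                 positive_group = positive_group),
            class = "cp_roc")
}

#' @export
print.cp_roc <- function(x, ...) {
  cat(sprintf("<cp_roc> positive = %s, AUC = %.4f, Youden cutoff = %g\n",
              x$positive_group, x$auc, x$youden_cutoff))
  invisible(x)
}

#' Export report tables
#'
#' Writes the phenotype table, abundance table, group-comparison table and
#' optional ROC coordinates as delimited files.
#'
#' @param dir Output directory.
#' @param phenotype,abundance,comparison,roc Report objects (any may be
#'   NULL to skip).
#' @return Paths written, invisibly.
#' @export
export_report <- function(dir, phenotype = NULL, abundance = NULL,
                          comparison = NULL, roc = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(obj, name, rn) {
    p <- file.path(dir, name)
    utils::write.table(obj, p, sep = "\t", quote = FALSE,
                       row.names = rn, col.names = NA)
    paths <<- c(paths, p)
  }
  if (!is.null(phenotype)) wr(phenotype, "phenotype_table.tsv", TRUE)
  if (!is.null(abundance)) wr(abundance, "abundance_table.tsv", TRUE)
  if (!is.null(comparison)) {
    p <- file.path(dir, "group_comparison.tsv")
    utils::write.table(comparison, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(roc)) {
    p <- file.path(dir, "roc_coordinates.tsv")
    utils::write.table(
      data.frame(threshold = roc$thresholds, sensitivity = roc$sensitivity,
                 specificity = roc$specificity),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
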