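# helper: small clustered dataset from designed abundances
clustered_dataset <- function(n_samples_per_group = 3, n_events = 200,
                              seed = 71) {
  design <- benchmark_design(n_samples_per_group, n_events, seed = seed)
  sim <- simulate_dataset(design)
  ds <- sim$dataset
  # attach the designed population labels as the cluster tag
  for (id in names(ds$samples)) {
    ds$samples[[id]]$tags$cluster <- sim$truth[[id]]
  }
  list(dataset = ds, truth = sim$truth)
}

test_that("phenotype table reports per-cluster medians", {
  s <- make_sample(rbind(c(0.9, 0.1), c(0.9, 0.5), c(0.9, 0.9),
                         c(0.2, 0.2), c(0.4, 0.4)))
  s$tags$cluster <- c(1L, 1L, 1L, 2L, 2L)
  tab <- phenotype_table(new_dataset(list(s)), c("FL1", "FL2"))
  expect_equal(dim(tab), c(2, 2))
  expect_equal(tab["1", "FL1"], 0.9)
  expect_equal(tab["1", "FL2"], 0.5)  # odd-sized median
  expect_equal(tab["2", "FL2"], 0.3)
})

test_that("abundance rows sum to 100 with zero-filled absent clusters", {
  sa <- make_sample(matrix(0, 100, 1), id = "a", group = "X")
  sa$tags$cluster <- rep(c(1L, 2L), c(25, 75))
  sb <- make_sample(matrix(0, 50, 1), id = "b", group = "Y")
  sb$tags$cluster <- rep(3L, 50)
  ab <- abundance_table(new_dataset(list(sa, sb)))
  expect_equal(ab["a", "1"], 25)
  expect_equal(ab["a", "3"], 0)
  expect_equal(ab["b", "3"], 100)
  expect_equal(unname(rowSums(ab[, c("1", "2", "3")])), c(100, 100),
               tolerance = 1e-6)
  expect_identical(ab$group, c("X", "Y"))

  sc <- make_sample(matrix(0, 10, 1), id = "c", group = "X")
  sc$tags$cluster <- rep(NA_integer_, 10)
  expect_warning(ab2 <- abundance_table(new_dataset(list(sa, sb, sc))),
                 class = "cp_empty_sample_warning")
  expect_false("c" %in% rownames(ab2))
})

test_that("sample-level UMAP separates disjoint abundance profiles and flags outliers", {
  set.seed(72)
  n <- 8
  profA <- matrix(rep(c(60, 30, 5, 5), each = n), n) +
    matrix(rnorm(4 * n, 0, 1), n)
  profB <- matrix(rep(c(5, 5, 30, 60), each = n), n) +
    matrix(rnorm(4 * n, 0, 1), n)
  ab <- as.data.frame(rbind(profA, profB))
  names(ab) <- as.character(1:4)
  rownames(ab) <- sprintf("s%d", 1:(2 * n))
  ab$group <- rep(c("A", "B"), each = n)
  emb <- sample_umap(ab, n_neighbors = 4, seed = 5)
  sil <- cluster::silhouette(as.integer(factor(emb$group)),
                             dist(emb[, c("UMAP1", "UMAP2")]))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  expect_true(all(c("nn_dist", "outlier") %in% names(emb)))

  # an aberrant sample is flagged, never dropped
  ab2 <- ab
  ab2[1, 1:4] <- c(0, 0, 0, 100) * 10
  emb2 <- sample_umap(ab2, n_neighbors = 4, seed = 5)
  expect_true(emb2$outlier[emb2$sample_id == "s1"])
  expect_equal(nrow(emb2), nrow(ab2))

  # metadata joins by sample_id
  md <- data.frame(sample_id = rownames(ab), age = seq_len(2 * n))
  emb3 <- sample_umap(ab, metadata = md, n_neighbors = 4, seed = 5)
  expect_true("age" %in% names(emb3))

  expect_error(sample_umap(ab[1:3, ], n_neighbors = 15),
               class = "cp_infeasibility_error")
})

test_that("group comparison detects designed differences and is null-calibrated", {
  set.seed(73)
  # designed 30% vs 5% difference in cluster 1, n = 10/10 samples
  mk_ab <- function(w1, n, g) {
    rest <- (100 - w1) / 3
    out <- as.data.frame(
      matrix(rep(c(w1, rest, rest, rest), each = n), n) +
        matrix(rnorm(4 * n, 0, 1.5), n))
    names(out) <- as.character(1:4)
    out <- out / rowSums(out) * 100
    out$group <- g
    out
  }
  ab <- rbind(mk_ab(30, 10, "case"), mk_ab(5, 10, "control"))
  rownames(ab) <- sprintf("s%d", 1:20)
  res <- group_compare(ab)
  expect_lt(res$p_adj[res$cluster == "1"], 0.01)
  expect_identical(unique(res$test), "wilcoxon")

  # identical groups: all adjusted p = 1
  same <- mk_ab(25, 10, "a")
  both <- rbind(same, same)
  both$group <- rep(c("a", "b"), each = 10)
  rownames(both) <- sprintf("t%d", 1:20)
  res2 <- group_compare(both)
  expect_true(all(res2$p_adj > 0.999))

  # three groups dispatch to Kruskal-Wallis
  ab3 <- rbind(mk_ab(30, 4, "a"), mk_ab(20, 4, "b"), mk_ab(10, 4, "c"))
  rownames(ab3) <- sprintf("u%d", 1:12)
  expect_identical(unique(group_compare(ab3)$test), "kruskal-wallis")

  expect_error(group_compare(mk_ab(10, 5, "only")),
               class = "cp_parameter_error")
})

test_that("p-values are uniform under permuted group labels", {
  # exact rank-sum null; group sizes large enough that its discrete
  # support is fine relative to a continuous Uniform(0,1) KS reference
  set.seed(74)
  n <- 50
  ab <- data.frame(`1` = rnorm(2 * n, 20, 4), check.names = FALSE)
  p <- replicate(1000, {
    ab$group <- sample(rep(c("a", "b"), n))
    group_compare(ab, exact = TRUE)$p
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ROC analysis matches its contracts and the pROC cross-check", {
  # perfectly separated classes
  r <- roc_analysis(c(1, 2, 3, 10, 11, 12), rep(c("n", "p"), each = 3), "p")
  expect_equal(r$auc, 1.0)
  expect_true(r$youden_cutoff > 3 && r$youden_cutoff <= 10)

  # random labels: AUC near 0.5
  set.seed(75)
  v <- rnorm(2000)
  g <- sample(rep(c("n", "p"), 1000))
  expect_lt(abs(roc_analysis(v, g, "p")$auc - 0.5), 0.03)

  # agreement with pROC on tied, noisy data
  set.seed(76)
  v2 <- round(c(rnorm(300, 1), rnorm(300)), 1)
  g2 <- rep(c("p", "n"), each = 300)
  ours <- roc_analysis(v2, g2, "p")
  ref <- pROC::roc(g2, v2, levels = c("n", "p"), direction = "<",
                   quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  # curves are monotone and bounded
  expect_true(all(diff(ours$sensitivity) <= 0))
  expect_true(all(diff(ours$specificity) >= 0))
  expect_true(all(ours$sensitivity >= 0 & ours$sensitivity <= 1))

  expect_error(roc_analysis(1:5, rep("p", 5), "p"),
               class = "cp_parameter_error")
})

test_that("trapezoidal empirical AUC equals the Mann-Whitney statistic on tie-free data", {
  set.seed(77)
  v <- sample(seq(0, 1, length.out = 400))  # tie-free
  g <- rep(c("p", "n"), 200)
  r <- roc_analysis(v, g, "p")
  fpr <- 1 - r$specificity
  ord <- order(fpr, r$sensitivity)
  x <- fpr[ord]; y <- r$sensitivity[ord]
  trap <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(trap, r$auc, tolerance = 1e-12)
  w <- wilcox.test(v[g == "p"], v[g == "n"], exact = FALSE)$statistic
  expect_equal(unname(w) / (200 * 200), r$auc, tolerance = 1e-12)
})

test_that("report tables export as delimited files", {
  cd <- clustered_dataset(2, 150)
  ab <- abundance_table(cd$dataset)
  ph <- phenotype_table(cd$dataset, cd$dataset$panel$label)
  cmp <- group_compare(ab)
  r <- roc_analysis(ab[["1"]], ab$group, "A")
  dir <- withr::local_tempdir()
  paths <- export_report(dir, phenotype = ph, abundance = ab,
                         comparison = cmp, roc = r)
  expect_length(paths, 4)
  expect_true(all(file.exists(paths)))
  back <- read.table(file.path(dir, "abundance_table.tsv"), sep = "\t",
                     header = TRUE, row.names = 1, check.names = FALSE)
  expect_equal(as.numeric(back["A_1", "1"]), ab["A_1", "1"])
})
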