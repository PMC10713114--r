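# helper: dataset of well-separated gaussian blobs, fully downsampled
blob_dataset <- function(n_per_blob, centers, sigma = 0.05, seed = 61) {
  set.seed(seed)
  truth <- rep(seq_len(nrow(centers)), each = n_per_blob)
  ev <- centers[truth, , drop = FALSE] +
    matrix(rnorm(length(truth) * ncol(centers), 0, sigma),
           ncol = ncol(centers))
  s <- make_sample(ev)
  s$tags$downsampled <- rep(TRUE, nrow(ev))
  list(dataset = new_dataset(list(s)), truth = truth)
}

test_that("UMAP embedding separates well-separated blobs and is seed-deterministic", {
  centers <- rbind(c(0.1, 0.1, 0.1, 0.1), c(0.9, 0.1, 0.9, 0.1),
                   c(0.5, 0.9, 0.1, 0.9))
  bd <- blob_dataset(150, centers, sigma = 0.02)
  emb <- run_umap(bd$dataset, paste0("FL", 1:4), seed = 3)
  expect_equal(nrow(emb$coordinates), 450)
  expect_true(all(is.finite(emb$coordinates)))
  sil <- cluster::silhouette(bd$truth, dist(emb$coordinates))
  expect_gt(mean(sil[, "sil_width"]), 0.6)

  emb2 <- run_umap(bd$dataset, paste0("FL", 1:4), seed = 3)
  expect_identical(emb$coordinates, emb2$coordinates)

  expect_error(run_umap(bd$dataset, paste0("FL", 1:4), n_neighbors = 451),
               class = "cp_infeasibility_error")
})

test_that("hierarchical training reproduces blob membership on separated data", {
  centers <- rbind(c(0.1, 0.1), c(0.9, 0.9))
  bd <- blob_dataset(300, centers, sigma = 0.05)
  model <- train_hierarchical(bd$dataset, c("FL1", "FL2"),
                              training_fraction = 0.5, K_init = 2, seed = 5)
  lab <- model$training_labels
  truth <- bd$truth[model$training_index]
  # labels identical up to permutation
  expect_equal(length(unique(paste(lab, truth))), 2)

  # training_fraction = 1 uses every tagged cell
  m2 <- train_hierarchical(bd$dataset, c("FL1", "FL2"),
                           training_fraction = 1, K_init = 2, seed = 5)
  expect_equal(length(m2$training_labels), 600)
  # degenerate cut: every training cell its own cluster
  m3 <- train_hierarchical(bd$dataset, c("FL1", "FL2"),
                           training_fraction = 0.05, K_init = 30, seed = 5)
  expect_equal(length(unique(m3$training_labels)), 30)
  expect_error(
    train_hierarchical(bd$dataset, c("FL1", "FL2"),
                       training_fraction = 0.001, K_init = 10),
    class = "cp_infeasibility_error"
  )
})

test_that("knn_assign equals the brute-force majority-vote oracle", {
  set.seed(62)
  centers <- rbind(c(0.2, 0.2, 0.2), c(0.8, 0.2, 0.8), c(0.5, 0.8, 0.3))
  bd <- blob_dataset(834, centers, sigma = 0.15)
  model <- train_hierarchical(bd$dataset, paste0("FL", 1:3),
                              training_fraction = 0.2, K_init = 12, seed = 6)
  got <- knn_assign(model, bd$dataset, k_nn = 11)
  X <- cytopipe:::pooled_events(bd$dataset, paste0("FL", 1:3),
                                tag = "downsampled")
  queries <- setdiff(seq_len(nrow(X)), model$training_index)
  want <- oracle_knn(model$training_events, model$training_labels,
                     X[queries, , drop = FALSE], 11)
  expect_identical(got[queries], as.integer(want))
  # training events keep their own labels
  expect_identical(got[model$training_index], unname(model$training_labels))
  # a query at an exact training point gets that point's label (k = 1)
  got1 <- knn_assign(model, bd$dataset, k_nn = 1)
  expect_identical(got1[model$training_index[5]],
                   unname(model$training_labels[5]))
  expect_error(knn_assign(model, bd$dataset, k_nn = 1e6),
               class = "cp_parameter_error")
})

test_that("phenotype binarization applies the strict majority rule", {
  data <- cbind(CD25 = c(rep(0.9, 9), 0.1), CD3 = c(rep(0.4, 5), rep(0.6, 5)))
  lab <- rep(1L, 10)
  ph <- binarize_phenotypes(data, lab, c(CD25 = 0.5, CD3 = 0.5))
  expect_equal(unname(ph$derivation[1, ]), c(0.9, 0.5))
  # 90% above -> bit 1; exactly 50% above -> bit 0 (strict inequality)
  expect_equal(unname(ph$bits[1, ]), c(1L, 0L))
  all_below <- binarize_phenotypes(cbind(CD25 = rep(0.1, 4)), rep(1L, 4),
                                   c(CD25 = 0.5))
  expect_equal(unname(all_below$bits[1, 1]), 0L)
  expect_error(binarize_phenotypes(data, lab, c(CD25 = 0.5)),
               class = "cp_parameter_error")
})

test_that("collapse merges identical phenotypes, then closest Hamming pairs", {
  mk_phen <- function(bits, sizes) {
    der <- bits * 0.9 + (1 - bits) * 0.1
    structure(list(ids = seq_len(nrow(bits)), bits = bits, derivation = der,
                   sizes = setNames(sizes, seq_len(nrow(bits))),
                   thresholds = setNames(rep(0.5, ncol(bits)),
                                         colnames(bits))),
              class = "cp_phenotypes")
  }
  b1 <- rbind(c(0, 1, 1, 0), c(0, 1, 1, 0), c(1, 0, 0, 1))
  colnames(b1) <- paste0("C", 1:4)
  r1 <- collapse_clusters(mk_phen(b1, c(10, 20, 30)), K_max = 10)
  expect_equal(r1$K_final, 2)
  expect_equal(unname(r1$collapse_map[c("1", "2")]),
               rep(unname(r1$collapse_map[["1"]]), 2))

  # 4 distinct phenotypes, K_max = 4: no stage-2 merges
  b2 <- rbind(c(0,0), c(0,1), c(1,0), c(1,1)); colnames(b2) <- c("C1", "C2")
  expect_equal(collapse_clusters(mk_phen(b2, rep(5, 4)), 4)$K_final, 4)

  # {0000, 0001, 1111}, K_max 2: the Hamming-1 pair merges first
  b3 <- rbind(c(0,0,0,0), c(0,0,0,1), c(1,1,1,1)); colnames(b3) <- paste0("C", 1:4)
  r3 <- collapse_clusters(mk_phen(b3, c(50, 5, 40)), 2)
  expect_equal(r3$K_final, 2)
  expect_equal(r3$collapse_map[["1"]], r3$collapse_map[["2"]])
  expect_false(r3$collapse_map[["1"]] == r3$collapse_map[["3"]])

  # final IDs ordered by decreasing size
  expect_equal(unname(r3$phenotypes$sizes), sort(unname(r3$phenotypes$sizes),
                                                 decreasing = TRUE))

  # collapsing never increases the count; re-collapsing is idempotent
  r3b <- collapse_clusters(r3$phenotypes, 2)
  expect_equal(r3b$K_final, r3$K_final)
  expect_equal(unname(r3b$collapse_map), seq_len(r3$K_final))
})

test_that("collapse agrees with an independent exhaustive-pair oracle", {
  set.seed(63)
  for (trial in 1:25) {
    K <- sample(3:10, 1)
    ncol_b <- sample(3:6, 1)
    der <- matrix(runif(K * ncol_b), K, ncol_b)
    colnames(der) <- paste0("C", seq_len(ncol_b))
    sizes <- sample(1:100, K)
    bits <- (der > 0.5) * 1L
    phen <- structure(list(ids = seq_len(K), bits = bits, derivation = der,
                           sizes = setNames(sizes, seq_len(K)),
                           thresholds = setNames(rep(0.5, ncol_b),
                                                 colnames(der))),
                      class = "cp_phenotypes")
    K_max <- sample(1:K, 1)
    got <- collapse_clusters(phen, K_max)
    want_sizes <- oracle_collapse(bits, sizes, der, K_max)
    expect_lte(got$K_final, K_max)
    expect_equal(unname(got$phenotypes$sizes), unname(want_sizes))
  }
})

test_that("threshold estimation finds bimodal valleys and falls back to medians", {
  set.seed(64)
  x_bim <- c(rnorm(3000, 0.2, 0.05), rnorm(3000, 0.8, 0.05))
  x_uni <- rnorm(6000, 0.4, 0.05)
  s <- make_sample(cbind(x_bim, x_uni))
  s$tags$downsampled <- rep(TRUE, 6000)
  ds <- new_dataset(list(s))
  thr <- estimate_thresholds(ds, c("FL1", "FL2"))
  expect_lt(abs(thr[["FL1"]] - 0.5), 0.1)
  expect_equal(thr[["FL2"]], median(x_uni), tolerance = 1e-9)
  thr2 <- estimate_thresholds(ds, c("FL1", "FL2"), overrides = c(FL1 = 0.42))
  expect_equal(thr2[["FL1"]], 0.42)
})

test_that("guided clustering recovers designed populations end to end", {
  design <- benchmark_design(n_samples_per_group = 2, n_events = 2500, seed = 13)
  sim <- simulate_dataset(design)
  ds <- downsample_balanced(sim$dataset, seed = 13)
  ds <- rescale(ds)
  res <- guided_cluster(ds, ds$panel$label, training_fraction = 0.1,
                        K_init = 60, k_nn = 11, K_max = 40, seed = 13)
  truth <- unlist(lapply(names(sim$truth), function(id)
    sim$truth[[id]][ds$samples[[id]]$tags$downsampled]))
  expect_equal(res$K_final, 8)
  expect_gte(mclust::adjustedRandIndex(res$labels, truth), 0.9)
  # every tagged event carries exactly one final label
  expect_false(anyNA(res$labels))
  expect_equal(length(res$labels),
               sum(sapply(ds$samples, function(s) sum(s$tags$downsampled))))
  lab_tag <- unlist(lapply(res$dataset$samples, function(s)
    s$tags$cluster[s$tags$downsampled]))
  expect_equal(unname(lab_tag), res$labels)
  # populations indistinguishable on every thresholded channel merge
  expect_lte(res$K_final, res$model$K_init)
})
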