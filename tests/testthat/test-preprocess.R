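# Preprocess module: QC boundaries, CLR contract, variable genes, PCA,
# SNN graph, clustering and annotation.

make_counts <- function(m) {
  g <- sprintf("g%02d", seq_len(nrow(m)))
  c <- sprintf("c%02d", seq_len(ncol(m)))
  dimnames(m) <- list(g, c)
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

test_that("qc_filter applies strict boundary rules and is idempotent", {
  n_genes <- 300L
  m <- matrix(0L, n_genes, 4)
  # genes 1:15 are mitochondrial; cells 1-2 express none of them
  m[16L + seq_len(199), 1] <- 1L          # 199 features -> removed (< 200)
  m[15L + seq_len(200), 2] <- 1L          # exactly 200 features -> kept
  m[seq_len(15), 3] <- 1L                 # 15 mito / 250 total = 0.06
  m[15L + seq_len(235), 3] <- 1L          #   -> removed (> 0.05)
  m[seq_len(12), 4] <- 1L                 # 12 mito / 240 total = 0.05
  m[15L + seq_len(228), 4] <- 1L          #   -> kept (not strict excess)
  counts <- make_counts(m)
  rownames(counts)[1:15] <- paste0("mt-", rownames(counts)[1:15])
  th <- qc_thresholds(min_features = 200, max_features = 2500,
                      max_mito_frac = 0.05)
  res <- qc_filter(counts, th)
  kept <- colnames(res$counts)
  expect_false("c01" %in% kept)
  expect_true("c02" %in% kept)
  expect_false("c03" %in% kept)
  expect_true("c04" %in% kept)
  expect_identical(res$report$low_features, 1L)
  expect_identical(res$report$high_mito, 1L)
  # idempotence
  res2 <- qc_filter(res$counts, th)
  expect_identical(res2$report$n_after, res2$report$n_before)
  # all removed -> error
  expect_error(qc_filter(counts, qc_thresholds(min_features = 280,
                                               max_features = 2500)),
               "all cells removed")
})

test_that("clr_normalize satisfies the per-cell mean-zero contract", {
  m <- matrix(rpois(200, 3), 20, 10)
  counts <- make_counts(m)
  norm <- clr_normalize(counts)
  expect_lt(max(abs(colMeans(norm))), 1e-9)
  # all-equal cell -> all-zero column
  m2 <- make_counts(matrix(5L, 4, 2))
  expect_true(all(abs(clr_normalize(m2)) < 1e-12))
  # counts (0, 8) -> (-ln(9)/2 bits): y = (0, log 9) centered
  m3 <- make_counts(matrix(c(0L, 8L), 2, 1))
  expect_equal(unname(clr_normalize(m3)[, 1]), c(-1.0986, 1.0986),
               tolerance = 1e-4)
})

test_that("select_variable_genes ranks planted variation first", {
  set.seed(42)
  n <- 200; ncells <- 120
  m <- matrix(rpois(n * ncells, 4), n, ncells)
  # gene 5: 4x difference between two halves of the cells, same overall mean
  m[5, ] <- c(rpois(ncells / 2, 1.6), rpois(ncells / 2, 6.4))
  counts <- make_counts(m)
  norm <- clr_normalize(counts)
  top <- select_variable_genes(norm, 20L)
  expect_true("g05" %in% top)
  expect_identical(select_variable_genes(norm, nrow(norm)) |> length(),
                   nrow(norm))
  expect_identical(select_variable_genes(norm, 50L),
                   select_variable_genes(norm, 50L))
  flat <- make_counts(matrix(3L, 10, 8))
  expect_error(select_variable_genes(clr_normalize(flat), 5L), "constant")
})

test_that("embed_cells: variance ordering, separation, reconstruction", {
  set.seed(7)
  n <- 50; per <- 40
  base <- matrix(rnorm(n * 2 * per, sd = 0.5), n)
  base[1:10, seq_len(per)] <- base[1:10, seq_len(per)] + 4  # two blobs
  colnames(base) <- sprintf("c%03d", seq_len(2 * per))
  rownames(base) <- sprintf("g%02d", seq_len(n))
  sc <- embed_cells(base, n_pcs = 10L)
  sdev <- attr(sc, "sdev")
  expect_true(all(diff(sdev) <= 1e-12))
  rot <- attr(sc, "rotation")
  expect_equal(crossprod(rot), diag(ncol(rot)), tolerance = 1e-8,
               ignore_attr = TRUE)
  grp <- rep(1:2, each = per)
  between <- sqrt(sum((colMeans(sc[grp == 1, ]) -
                         colMeans(sc[grp == 2, ]))^2))
  within <- mean(dist(sc[grp == 1, ]))
  expect_gt(between, within)
  # truncation error against the rank-10 reconstruction shrinks with k
  errs <- vapply(c(2L, 5L, 9L), function(k)
    sum(sc[, (k + 1L):10L]^2), numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_error(embed_cells(base, n_pcs = 1000L), "n_pcs")
})

test_that("build_snn_graph computes Jaccard weights over kNN sets", {
  # 1-D layout engineered so kNN sets are unambiguous with k = 2:
  # a and b flank the tight pair (c, d); e-h mirror them far away
  x <- matrix(c(-1, 1.1, 0, 0.2, 99, 101.1, 100, 100.2), ncol = 1)
  rownames(x) <- letters[1:8]
  g <- build_snn_graph(x, k = 2L, prune = 0)
  w <- function(i, j) {
    e <- igraph::get_edge_ids(g, c(i, j))
    if (e == 0) 0 else igraph::E(g)$weight[e]
  }
  # kNN(a) = {c, d} = kNN(b): identical sets -> weight 1
  expect_equal(w("a", "b"), 1)
  # kNN(c) = {d, a}: |shared| = 1 of union 3 -> 1/3
  expect_equal(w("a", "c"), 1 / 3)
  # disjoint neighborhoods across the gap -> no edge
  expect_equal(w("a", "e"), 0)
  expect_error(build_snn_graph(x, k = 8L), "k must be smaller")
})

test_that("cluster_cells separates disconnected cliques and is
           permutation-invariant", {
  full <- function(n, off) {
    eg <- t(combn(seq_len(n) + off, 2))
    data.frame(from = eg[, 1], to = eg[, 2], weight = 1)
  }
  g <- igraph::graph_from_data_frame(rbind(full(6, 0), full(6, 6)),
                                     directed = FALSE)
  for (cand in cluster_cells(g, resolutions = c(0.4, 1.0), seed = 1L))
    expect_identical(cand$n_clusters, 2L)
  # permuting vertex order relabels but preserves the partition
  perm <- igraph::permute(g, c(3:12, 1:2))
  c1 <- cluster_cells(g, resolutions = 1, seed = 1L)[[1]]$membership
  c2 <- cluster_cells(perm, resolutions = 1, seed = 1L)[[1]]$membership
  c2 <- c2[names(c1)]
  expect_equal(ari(c1, c2), 1)
  expect_error(cluster_cells(igraph::make_empty_graph(0), 1), "empty")
})

test_that("silhouette and model selection behave on planted blobs", {
  # point equidistant between its own and the nearest other cluster -> 0
  sc <- matrix(c(0, 2, 1, 0, 0, 0), ncol = 2)
  rownames(sc) <- c("p", "q", "r")
  sw <- silhouette_widths(setNames(c(0L, 1L, 0L), rownames(sc)), sc)
  expect_equal(unname(sw$widths["r"]), 0)
  expect_true(all(abs(sw$widths) <= 1))

  set.seed(33)
  centers <- rbind(c(0, 0), c(12, 0), c(0, 12))
  sc2 <- do.call(rbind, lapply(1:3, function(i)
    cbind(rnorm(60, centers[i, 1]), rnorm(60, centers[i, 2]))))
  rownames(sc2) <- sprintf("c%03d", 1:180)
  g <- build_snn_graph(sc2, k = 15L)
  cands <- cluster_cells(g, resolutions = c(0.2, 0.8, 1.4), seed = 2L)
  best <- choose_clustering(cands, sc2)
  expect_identical(best$n_clusters, 3L)
  expect_gt(best$mean_silhouette, 0.3)
  truth <- rep(1:3, each = 60)
  expect_gte(ari(best$membership[rownames(sc2)], truth), 0.9)

  # single high-dimensional blob: weak structure warning
  blob <- matrix(rnorm(1200), ncol = 10)
  rownames(blob) <- sprintf("b%03d", seq_len(nrow(blob)))
  gb <- build_snn_graph(blob, k = 15L)
  cb <- cluster_cells(gb, resolutions = c(0.8, 1.4), seed = 3L)
  if (any(vapply(cb, `[[`, integer(1), "n_clusters") >= 2))
    expect_warning(choose_clustering(cb, blob), "weak cluster structure")
})

test_that("annotate_clusters assigns marker labels with tie rules", {
  set.seed(5)
  n_genes <- 60L
  genes <- sprintf("g%02d", seq_len(n_genes))
  mk_a <- genes[1:6]; mk_b <- genes[7:12]
  m <- matrix(rpois(n_genes * 80, 2), n_genes, 80,
              dimnames = list(genes, sprintf("c%02d", 1:80)))
  m[1:6, 1:40] <- m[1:6, 1:40] + 12L     # cluster 0 overexpresses set A
  m[7:12, 41:80] <- m[7:12, 41:80] + 12L # cluster 1 overexpresses set B
  norm <- clr_normalize(make_counts(m))
  asg <- structure(list(membership = setNames(rep(0:1, each = 40),
                                              colnames(m)),
                        n_clusters = 2L), class = "cluster_assignment")
  ann <- annotate_clusters(asg, norm, list(typeA = mk_a, typeB = mk_b))
  expect_identical(ann$cell_type[ann$cluster == 0], "typeA")
  expect_identical(ann$cell_type[ann$cluster == 1], "typeB")
  # no overlap with any marker set -> unknown
  ann2 <- annotate_clusters(asg, norm,
                            list(typeC = genes[40:50]))
  expect_true(all(ann2$cell_type == "unknown"))
  # absent marker genes shrink the set with a warning
  expect_warning(
    annotate_clusters(asg, norm, list(typeA = c(mk_a, "nothere"))),
    "absent")
})
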