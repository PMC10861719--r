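# Preprocess module: QC filtering, CLR normalization, variable-gene
# selection, PCA embedding, shared-nearest-neighbor graph construction,
# modularity clustering with silhouette-based model selection and
# marker-based cell-type annotation.

#' Quality-control thresholds
#'
#' Cells are removed when their detected-feature count is strictly below
#' `min_features` or strictly above `max_features`, or when their
#' mitochondrial count fraction is strictly above `max_mito_frac`.
#'
#' @param min_features,max_features Detected-feature bounds (defaults 200
#'   and 2500).
#' @param max_mito_frac Mitochondrial fraction bound (default 0.05).
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_features = 200L, max_features = 2500L,
                          max_mito_frac = 0.05, mito_prefix = "mt-") {
  .assert(.is_count(min_features, 1L) && .is_count(max_features, 1L) &&
            min_features < max_features,
          "need 0 < min_features < max_features")
  .assert(.is_prop(max_mito_frac), "max_mito_frac must be in [0,1]")
  structure(list(min_features = as.integer(min_features),
                 max_features = as.integer(max_features),
                 max_mito_frac = max_mito_frac,
                 mito_prefix = mito_prefix),
            class = "qc_thresholds")
}

#' Filter cells by quality-control metrics
#'
#' @param counts Sparse genes x cells count matrix with dimnames.
#' @param thresholds A [qc_thresholds()].
#' @return A list (`counts` filtered, `report`): the report gives
#'   per-rule removal counts (`low_features`, `high_features`,
#'   `high_mito`; a cell may fail several rules) and totals.
#' @export
qc_filter <- function(counts, thresholds = qc_thresholds()) {
  .assert(inherits(thresholds, "qc_thresholds"),
          "thresholds must come from qc_thresholds()")
  .assert(min(counts) >= 0, "counts must be nonnegative")
  detected <- Matrix::colSums(counts > 0)
  mito <- startsWith(rownames(counts), thresholds$mito_prefix)
  total <- Matrix::colSums(counts)
  mito_frac <- if (any(mito))
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(total, 1)
  else rep(0, ncol(counts))
  low <- detected < thresholds$min_features
  high <- detected > thresholds$max_features
  hmito <- mito_frac > thresholds$max_mito_frac
  keep <- !(low | high | hmito)
  .assert(any(keep),
          "all cells removed by QC; review the thresholds for this dataset")
  report <- list(n_before = ncol(counts), n_after = sum(keep),
                 low_features = sum(low), high_features = sum(high),
                 high_mito = sum(hmito), thresholds = unclass(thresholds))
  list(counts = counts[, keep, drop = FALSE], report = report)
}

#' Centered log-ratio normalization
#'
#' Per cell c and gene g: `y = ln(1 + x_gc) - mean_g ln(1 + x_gc)`, so
#' every cell's mean over genes is zero. The +1 pseudocount handles zeros.
#' Note CLR is not invariant to a multiplicative library-size factor; only
#' the per-cell mean-zero contract is guaranteed.
#'
#' @param counts Nonnegative genes x cells matrix (sparse or dense).
#' @return A dense genes x cells matrix of class `clr_matrix` with
#'   attribute `method = "CLR"`.
#' @export
clr_normalize <- function(counts) {
  .assert(min(counts) >= 0, "counts must be nonnegative")
  y <- log1p(as.matrix(counts))
  y <- sweep(y, 2L, colMeans(y), `-`)
  structure(y, method = "CLR", class = c("clr_matrix", class(y)))
}

#' Select highly variable genes
#'
#' Ranks genes by standardized variance: the per-gene variance of the
#' normalized values divided by a loess mean-variance trend. Ties are
#' broken by gene label; the ordering is deterministic.
#'
#' @param norm Normalized genes x cells matrix.
#' @param n_top Number of genes to return (default 2500, capped at the
#'   number of genes).
#' @return Character vector of `n_top` gene names, most variable first.
#' @export
select_variable_genes <- function(norm, n_top = 2500L) {
  .assert(n_top <= nrow(norm), "n_top exceeds the number of genes")
  mu <- rowMeans(norm)
  v <- apply(norm, 1L, stats::var)
  .assert(any(v > 0), "constant matrix: no variable genes")
  std_var <- v
  if (sum(v > 0) >= 10) {
    # robust local-linear trend: degree 1 avoids boundary overshoot,
    # the symmetric family downweights genuinely variable outlier genes
    fit <- suppressWarnings(stats::loess(v ~ mu, span = 0.5, degree = 1,
                                         family = "symmetric"))
    trend <- pmax(stats::predict(fit, mu), 1e-8)
    std_var <- v / trend
  }
  ord <- order(-std_var, rownames(norm))
  rownames(norm)[ord][seq_len(n_top)]
}

#' Embed cells by principal components
#'
#' Per-gene z-scoring (constant genes dropped), clipping at +/-10, then a
#' truncated PCA. The returned loading basis is orthonormal and component
#' variances are non-increasing.
#'
#' @param norm Normalized genes x cells matrix.
#' @param genes Genes to use (e.g. from [select_variable_genes()]).
#' @param n_pcs Number of components (default 10).
#' @return Cells x components score matrix with attributes `sdev` and
#'   `rotation`.
#' @export
embed_cells <- function(norm, genes = rownames(norm), n_pcs = 10L) {
  .assert(all(genes %in% rownames(norm)), "unknown gene(s) in selection")
  x <- norm[genes, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  x <- x[sds > 0, , drop = FALSE]
  sds <- sds[sds > 0]
  .assert(n_pcs <= min(nrow(x), ncol(x)),
          "n_pcs exceeds min(n_genes_selected, n_cells)")
  z <- (x - rowMeans(x)) / sds
  z[z > 10] <- 10; z[z < -10] <- -10
  pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE, rank. = n_pcs)
  scores <- pc$x
  rownames(scores) <- colnames(norm)
  attr(scores, "sdev") <- pc$sdev[seq_len(n_pcs)]
  attr(scores, "rotation") <- pc$rotation
  scores
}

# k-nearest-neighbor index matrix (cells x k), self excluded, Euclidean.
.knn_index <- function(scores, k) {
  d <- as.matrix(stats::dist(scores))
  n <- nrow(d)
  .assert(k < n, "k must be smaller than the number of cells")
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    o <- order(d[i, ], decreasing = FALSE)
    idx[i, ] <- setdiff(o, i)[seq_len(k)]
  }
  idx
}

#' Build a shared-nearest-neighbor graph
#'
#' Nodes are cells; the weight of edge (i, j) is the Jaccard index of the
#' two cells' k-nearest-neighbor sets (Euclidean distance in PC space,
#' self excluded). Weights strictly below `prune` are dropped.
#'
#' @param scores Cells x components embedding.
#' @param k Neighborhood size (default 20).
#' @param prune Pruning threshold (default 1/15).
#' @return An undirected weighted `igraph` with vertex names.
#' @export
build_snn_graph <- function(scores, k = 20L, prune = 1 / 15) {
  n <- nrow(scores)
  .assert(k < n, "k must be smaller than the number of cells")
  idx <- .knn_index(scores, k)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(idx),
                            x = 1, dims = c(n, n))
  S <- Matrix::tcrossprod(A)  # shared-neighbor counts
  S <- methods::as(S, "TsparseMatrix")
  ii <- S@i + 1L; jj <- S@j + 1L; shared <- S@x
  keep <- ii < jj & shared > 0
  ii <- ii[keep]; jj <- jj[keep]; shared <- shared[keep]
  jac <- shared / (2 * k - shared)
  ok <- jac >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = ii[ok], to = jj[ok], weight = jac[ok]),
    directed = FALSE,
    vertices = data.frame(id = seq_len(n)))
  igraph::V(g)$name <- rownames(scores) %||% as.character(seq_len(n))
  g
}

#' Cluster cells on the SNN graph over a resolution grid
#'
#' Louvain modularity community detection per resolution; deterministic
#' given `seed`. Cluster indices are contiguous from 0.
#'
#' @param graph Weighted `igraph` from [build_snn_graph()].
#' @param resolutions Resolution grid (default `seq(0.2, 2, 0.2)`).
#' @param seed Integer seed.
#' @return A list of `cluster_assignment` objects (`membership`: named
#'   cell -> cluster, `n_clusters`, `resolution`).
#' @export
cluster_cells <- function(graph, resolutions = seq(0.2, 2, by = 0.2),
                          seed = 1L) {
  .assert(igraph::vcount(graph) > 0, "empty graph")
  lapply(resolutions, function(r) {
    cl <- .with_seed(seed, igraph::cluster_louvain(graph, resolution = r))
    mem <- igraph::membership(cl)
    mem <- setNames(match(mem, sort(unique(mem))) - 1L, names(mem))
    structure(list(membership = mem, n_clusters = length(unique(mem)),
                   resolution = r),
              class = "cluster_assignment")
  })
}

#' Mean silhouette width of a labeling
#'
#' `s(i) = (b - a) / max(a, b)` with `a` the mean distance of cell i to
#' its own cluster and `b` the smallest mean distance to another cluster;
#' singleton clusters score 0. Values lie in `[-1, 1]`.
#'
#' @param membership Named integer cluster labels.
#' @param scores Cells x components embedding (Euclidean distances).
#' @return A list (`mean`, `widths`).
#' @export
silhouette_widths <- function(membership, scores) {
  d <- as.matrix(stats::dist(scores[names(membership), , drop = FALSE]))
  labs <- unique(membership)
  .assert(length(labs) >= 2, "silhouette needs at least 2 clusters")
  n <- length(membership)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- membership == membership[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- sum(d[i, own]) / (sum(own) - 1)
    b <- min(vapply(labs[labs != membership[i]], function(l)
      mean(d[i, membership == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  list(mean = mean(s), widths = setNames(s, names(membership)))
}

#' Choose a clustering by silhouette width
#'
#' Returns the candidate maximizing the mean silhouette width in PC space;
#' ties go to fewer clusters. Single-cluster candidates are ignored; if
#' every retained candidate scores below 0.3 a warning about weak cluster
#' structure is emitted.
#'
#' @param candidates List of `cluster_assignment`s from [cluster_cells()].
#' @param scores The embedding the candidates were computed on.
#' @return The winning `cluster_assignment`, with `mean_silhouette` set.
#' @export
choose_clustering <- function(candidates, scores) {
  multi <- Filter(function(x) x$n_clusters >= 2, candidates)
  .assert(length(multi) > 0,
          "no candidate with >= 2 clusters; nothing to select")
  sil <- vapply(multi, function(x)
    silhouette_widths(x$membership, scores)$mean, numeric(1))
  if (max(sil) < 0.3)
    .warnf("weak cluster structure: best mean silhouette %.3f < 0.3",
           max(sil))
  nc <- vapply(multi, `[[`, integer(1), "n_clusters")
  ord <- order(-sil, nc)
  best <- multi[[ord[1]]]
  best$mean_silhouette <- sil[ord[1]]
  best
}

#' Annotate clusters with cell types from marker gene sets
#'
#' Per cluster, upregulated genes are found by a one-sided Wilcoxon
#' rank-sum test (cluster vs rest, Bonferroni q < `q_thresh`, mean
#' normalized difference > `logfc_thresh`); each marker set is then tested
#' for hypergeometric enrichment among those genes (universe = all genes
#' in the matrix, BH-adjusted across sets). The label with the smallest q
#' wins; q ties go to the larger overlap, then alphabetical order.
#' Clusters with no set at q < `q_thresh` are labeled `"unknown"`.
#'
#' @param assignment A `cluster_assignment`.
#' @param norm Normalized genes x cells matrix.
#' @param markers Named list of marker gene sets (cell type -> genes).
#' @param q_thresh Significance threshold (default 0.05).
#' @param logfc_thresh Upregulation threshold on the normalized scale.
#' @return A data.frame (`cluster`, `cell_type`, `q`, `n_upregulated`,
#'   `overlap`).
#' @export
annotate_clusters <- function(assignment, norm, markers, q_thresh = 0.05,
                              logfc_thresh = 0.25) {
  .assert(length(markers) > 0 && !is.null(names(markers)),
          "markers must be a nonempty named list")
  genes_all <- rownames(norm)
  markers <- lapply(markers, function(m) {
    mm <- intersect(m, genes_all)
    if (length(mm) < length(m))
      .warnf("%d marker gene(s) absent from the matrix; set shrunk",
             length(m) - length(mm))
    mm
  })
  markers <- Filter(length, markers)
  .assert(length(markers) > 0, "no marker set left after shrinking")

  mem <- assignment$membership
  norm <- norm[, names(mem), drop = FALSE]
  out <- lapply(sort(unique(mem)), function(cl) {
    inn <- mem == cl
    p <- apply(norm, 1L, function(y)
      suppressWarnings(stats::wilcox.test(y[inn], y[!inn],
                                          alternative = "greater")$p.value))
    lfc <- rowMeans(norm[, inn, drop = FALSE]) -
      rowMeans(norm[, !inn, drop = FALSE])
    q <- bonferroni_adjust(p)
    up <- genes_all[q < q_thresh & lfc > logfc_thresh]
    enr <- data.frame(
      cell_type = names(markers),
      overlap = vapply(markers, function(m)
        length(intersect(up, m)), integer(1)),
      p = vapply(markers, function(m)
        stats::phyper(length(intersect(up, m)) - 1, length(m),
                      length(genes_all) - length(m), length(up),
                      lower.tail = FALSE), numeric(1)),
      stringsAsFactors = FALSE)
    enr$q <- stats::p.adjust(enr$p, method = "BH")
    enr <- enr[order(enr$q, -enr$overlap, enr$cell_type), , drop = FALSE]
    hit <- enr[1, ]
    data.frame(cluster = cl,
               cell_type = if (hit$q < q_thresh) hit$cell_type else "unknown",
               q = hit$q, n_upregulated = length(up),
               overlap = hit$overlap, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
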