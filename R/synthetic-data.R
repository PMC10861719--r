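# Synthetic-data module: count matrices with planted genotype-by-sex
# effects, ground-truth signed regulatory networks, and on-disk bundles,
# so that every downstream stage is testable without external data.

MITO_PREFIX <- "mt-"

#' Simulation configuration for synthetic single-cell counts
#'
#' Describes a 2x2 genotype (TG/WT) by sex (M/F) Drop-seq-like design with
#' one or more cell types. Counts are Poisson (optionally gamma-mixed for
#' overdispersion) with per-cell lognormal size factors, a configurable
#' fraction of mitochondrial genes (prefix `"mt-"`) and a fraction of cells
#' forced above the mitochondrial QC threshold. Each cell type receives a
#' disjoint block of marker genes with an elevated baseline so that cell
#' types are separable in expression space.
#'
#' @param n_genes Number of genes (>= 10).
#' @param cells_per_arm Named integer vector: cells per (genotype, sex) arm
#'   for each cell type; all four arms are generated for every type.
#' @param baseline_log_mean_range Interval of natural-log baseline mean
#'   expression; baselines are drawn uniformly from it.
#' @param libsize_lognormal `c(mu, sigma)` of the lognormal per-cell size
#'   factors.
#' @param mito_gene_fraction Proportion of genes that are mitochondrial.
#' @param mito_high_cell_fraction Proportion of cells whose mitochondrial
#'   means are inflated (by `mito_high_log_shift` on the log scale) to
#'   exercise the QC filter.
#' @param mito_high_log_shift Natural-log shift applied to mitochondrial
#'   genes in mito-high cells.
#' @param marker_genes_per_type Number of marker genes per cell type.
#' @param marker_log_shift Natural-log baseline shift of a marker gene in
#'   its own cell type.
#' @param overdispersion Gamma overdispersion; 0 (default) gives pure
#'   Poisson counts matching the differential-expression model.
#' @param seed Integer seed; all randomness is derived from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L,
                       cells_per_arm = c(endothelial = 300L),
                       baseline_log_mean_range = c(-0.5, 1.5),
                       libsize_lognormal = c(mu = 0, sigma = 0.3),
                       mito_gene_fraction = 0.05,
                       mito_high_cell_fraction = 0.05,
                       mito_high_log_shift = 2.5,
                       marker_genes_per_type = 10L,
                       marker_log_shift = 2,
                       overdispersion = 0,
                       seed = 1L) {
  .assert(.is_count(n_genes, 10L), "n_genes must be a count >= 10")
  .assert(length(cells_per_arm) >= 1L && !is.null(names(cells_per_arm)) &&
            all(nzchar(names(cells_per_arm))),
          "cells_per_arm must be a named vector of per-arm cell counts")
  .assert(all(vapply(cells_per_arm, .is_count, logical(1))),
          "all per-arm cell counts must be >= 1")
  .assert(length(baseline_log_mean_range) == 2L &&
            diff(baseline_log_mean_range) >= 0,
          "baseline_log_mean_range must be a non-degenerate interval")
  .assert(length(libsize_lognormal) == 2L && libsize_lognormal[2] >= 0,
          "libsize_lognormal must be c(mu, sigma) with sigma >= 0")
  .assert(.is_prop(mito_gene_fraction), "mito_gene_fraction must be in [0,1]")
  .assert(.is_prop(mito_high_cell_fraction),
          "mito_high_cell_fraction must be in [0,1]")
  .assert(.is_count(marker_genes_per_type, 0L),
          "marker_genes_per_type must be a nonnegative count")
  n_marked <- length(cells_per_arm) * marker_genes_per_type
  n_mito <- round(mito_gene_fraction * n_genes)
  .assert(n_marked + n_mito <= n_genes,
          "n_genes too small for the requested marker and mito genes")
  structure(list(
    n_genes = as.integer(n_genes),
    cells_per_arm = cells_per_arm,
    baseline_log_mean_range = baseline_log_mean_range,
    libsize_lognormal = c(mu = unname(libsize_lognormal[1]),
                          sigma = unname(libsize_lognormal[2])),
    mito_gene_fraction = mito_gene_fraction,
    mito_high_cell_fraction = mito_high_cell_fraction,
    mito_high_log_shift = mito_high_log_shift,
    marker_genes_per_type = as.integer(marker_genes_per_type),
    marker_log_shift = marker_log_shift,
    overdispersion = overdispersion,
    seed = as.integer(seed)
  ), class = "sim_config")
}

EFFECT_CLASSES <- c("neutral", "male_specific", "female_specific",
                    "dimorphic", "null")

#' Planted genotype effects
#'
#' Builds a validated table of planted TG-vs-WT log fold changes (natural
#' log) per gene, sex and cell type. Class invariants: `neutral` requires
#' both logFCs nonzero with a shared sign; `male_specific` requires
#' `logFC_f == 0` (and symmetric for `female_specific`); `dimorphic`
#' requires nonzero logFCs of opposite sign; `null` requires both zero.
#'
#' @param gene Gene labels.
#' @param effect_class One of `neutral`, `male_specific`, `female_specific`,
#'   `dimorphic`, `null`; recycled.
#' @param logFC_m,logFC_f Natural-log fold changes per sex, recycled.
#' @param cell_type Cell type label or `"ALL"`, recycled.
#' @return A `data.frame` of class `planted_effects`.
#' @export
planted_effects <- function(gene, effect_class, logFC_m, logFC_f,
                            cell_type = "ALL") {
  df <- data.frame(gene = as.character(gene),
                   cell_type = as.character(cell_type),
                   effect_class = as.character(effect_class),
                   logFC_m = as.numeric(logFC_m),
                   logFC_f = as.numeric(logFC_f),
                   stringsAsFactors = FALSE)
  bad <- !df$effect_class %in% EFFECT_CLASSES
  .assert(!any(bad), "unknown effect class: %s",
          paste(unique(df$effect_class[bad]), collapse = ", "))
  for (i in seq_len(nrow(df))) {
    m <- df$logFC_m[i]; f <- df$logFC_f[i]; cl <- df$effect_class[i]
    ok <- switch(cl,
      neutral         = m != 0 && f != 0 && sign(m) == sign(f),
      male_specific   = m != 0 && f == 0,
      female_specific = m == 0 && f != 0,
      dimorphic       = m != 0 && f != 0 && sign(m) == -sign(f),
      null            = m == 0 && f == 0)
    .assert(ok, "effect for gene %s violates the %s class invariant",
            df$gene[i], cl)
  }
  class(df) <- c("planted_effects", "data.frame")
  df
}

#' Generate a synthetic count matrix with planted effects
#'
#' Draws counts for gene g in cell c as Poisson with mean
#' `size_factor(c) * exp(base_g + shifts + logFC_{g, arm(c)})`, where the
#' planted logFC applies to TG cells of the matching sex (and cell type,
#' unless `"ALL"`). Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param effects A [planted_effects()] table or `NULL` (all-null).
#' @return A list of class `sim_counts` with elements `counts` (sparse
#'   genes x cells `dgCMatrix`), `metadata` (`barcode`, `genotype`,
#'   `gender`, `cell_type`, `size_factor`, `mito_high`), `gene_info`
#'   (`gene`, `base_log_mean`, `is_mito`, `marker_type`) and `markers`
#'   (list of per-type marker gene sets).
#' @export
generate_counts <- function(config, effects = NULL) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  types <- names(config$cells_per_arm)
  n_genes <- config$n_genes

  if (!is.null(effects)) {
    .assert(inherits(effects, "planted_effects"),
            "effects must come from planted_effects()")
  }

  .with_seed(config$seed, {
    n_mito <- round(config$mito_gene_fraction * n_genes)
    genes <- sprintf("g%04d", seq_len(n_genes))
    if (n_mito > 0)
      genes[seq_len(n_mito)] <- paste0(MITO_PREFIX, genes[seq_len(n_mito)])
    base <- stats::runif(n_genes, config$baseline_log_mean_range[1],
                         config$baseline_log_mean_range[2])
    names(base) <- genes

    # Disjoint marker blocks drawn from the non-mito genes.
    marker_type <- rep(NA_character_, n_genes)
    names(marker_type) <- genes
    free <- setdiff(genes, genes[seq_len(n_mito)])
    markers <- list()
    for (ty in types) {
      if (config$marker_genes_per_type == 0) { markers[[ty]] <- character(); next }
      pick <- sample(free, config$marker_genes_per_type)
      markers[[ty]] <- sort(pick)
      marker_type[pick] <- ty
      free <- setdiff(free, pick)
    }

    if (!is.null(effects)) {
      bad_g <- setdiff(effects$gene, genes)
      .assert(length(bad_g) == 0, "effects reference unknown gene(s): %s",
              paste(bad_g, collapse = ", "))
      bad_t <- setdiff(setdiff(effects$cell_type, "ALL"), types)
      .assert(length(bad_t) == 0, "effects reference unknown cell type(s): %s",
              paste(bad_t, collapse = ", "))
    }

    arms <- expand.grid(genotype = c("TG", "WT"), gender = c("M", "F"),
                        stringsAsFactors = FALSE)
    meta_list <- list(); count_cols <- list()
    cell_i <- 0L
    for (ty in types) {
      n_arm <- config$cells_per_arm[[ty]]
      base_ty <- base
      mk <- markers[[ty]]
      if (length(mk)) base_ty[mk] <- base_ty[mk] + config$marker_log_shift
      for (a in seq_len(nrow(arms))) {
        gt <- arms$genotype[a]; gd <- arms$gender[a]
        lfc <- numeric(n_genes); names(lfc) <- genes
        if (gt == "TG" && !is.null(effects)) {
          sel <- effects$cell_type == "ALL" | effects$cell_type == ty
          ef <- effects[sel, , drop = FALSE]
          if (nrow(ef)) {
            v <- if (gd == "M") ef$logFC_m else ef$logFC_f
            lfc[ef$gene] <- lfc[ef$gene] + v
          }
        }
        sf <- stats::rlnorm(n_arm, config$libsize_lognormal["mu"],
                            config$libsize_lognormal["sigma"])
        mito_high <- stats::runif(n_arm) < config$mito_high_cell_fraction
        log_mu <- base_ty + lfc
        mu <- outer(exp(log_mu), sf)  # genes x cells
        if (n_mito > 0 && any(mito_high)) {
          mu[seq_len(n_mito), mito_high] <-
            mu[seq_len(n_mito), mito_high] * exp(config$mito_high_log_shift)
        }
        if (config$overdispersion > 0) {
          shape <- 1 / config$overdispersion
          mu <- mu * matrix(stats::rgamma(length(mu), shape, shape),
                            nrow = nrow(mu))
        }
        cnt <- matrix(stats::rpois(length(mu), mu), nrow = n_genes)
        count_cols[[length(count_cols) + 1L]] <- cnt
        meta_list[[length(meta_list) + 1L]] <- data.frame(
          barcode = sprintf("cell%05d", cell_i + seq_len(n_arm)),
          genotype = gt, gender = gd, cell_type = ty,
          size_factor = sf, mito_high = mito_high,
          stringsAsFactors = FALSE)
        cell_i <- cell_i + n_arm
      }
    }
    metadata <- do.call(rbind, meta_list)
    counts <- do.call(cbind, count_cols)
    dimnames(counts) <- list(genes, metadata$barcode)
    counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                      "CsparseMatrix"), "generalMatrix")
    gene_info <- data.frame(gene = genes, base_log_mean = unname(base),
                            is_mito = startsWith(genes, MITO_PREFIX),
                            marker_type = unname(marker_type),
                            stringsAsFactors = FALSE)
    structure(list(counts = counts, metadata = metadata,
                   gene_info = gene_info, markers = markers,
                   config = config, effects = effects),
              class = "sim_counts")
  })
}

NETWORK_CATEGORIES <- c("Influence on Expression", "Transcriptional Regulation",
                        "Regulation", "co Regulation of Transcription",
                        "Binding")

#' Specification of a synthetic prior-knowledge network
#'
#' @param n_nodes Number of nodes.
#' @param n_edges Number of directed edges; for connected topologies at
#'   least `n_nodes - n_roots` are required.
#' @param frac_inhibition Fraction of edges with a true inhibitory sign.
#' @param frac_unknown_sign Fraction of edges whose sign is masked as
#'   `"unknown"` in the emitted network (ground truth keeps the real sign).
#' @param acyclic Emit a DAG (`TRUE`) or allow cycles.
#' @param n_roots Number of root regulators whose Boolean flip defines the
#'   disease state.
#' @param topology `"random"` (parent sampling) or `"chain"` (a path).
#' @param node_names Optional node labels (length `n_nodes`).
#' @param seed Integer seed.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_nodes, n_edges, frac_inhibition = 0.3,
                         frac_unknown_sign = 0.2, acyclic = TRUE,
                         n_roots = 1L, topology = c("random", "chain"),
                         node_names = NULL, seed = 1L) {
  topology <- match.arg(topology)
  .assert(.is_count(n_nodes, 2L), "n_nodes must be a count >= 2")
  .assert(.is_count(n_edges, 1L), "n_edges must be a positive count")
  .assert(n_edges <= n_nodes * (n_nodes - 1),
          "infeasible edge count: %d edges on %d nodes", n_edges, n_nodes)
  if (acyclic)
    .assert(n_edges <= n_nodes * (n_nodes - 1) / 2,
            "infeasible edge count for an acyclic network")
  .assert(.is_prop(frac_inhibition) && .is_prop(frac_unknown_sign),
          "fractions must be in [0,1]")
  .assert(.is_count(n_roots, 1L) && n_roots < n_nodes,
          "n_roots must be in [1, n_nodes)")
  .assert(n_edges >= n_nodes - n_roots,
          "need at least n_nodes - n_roots edges to connect every node")
  if (topology == "chain")
    .assert(n_edges == n_nodes - 1L && n_roots == 1L,
            "chain topology requires n_edges == n_nodes - 1 and one root")
  if (!is.null(node_names))
    .assert(length(node_names) == n_nodes && !anyDuplicated(node_names),
            "node_names must be %d unique labels", n_nodes)
  structure(list(n_nodes = as.integer(n_nodes), n_edges = as.integer(n_edges),
                 frac_inhibition = frac_inhibition,
                 frac_unknown_sign = frac_unknown_sign, acyclic = acyclic,
                 n_roots = as.integer(n_roots), topology = topology,
                 node_names = node_names, seed = as.integer(seed)),
            class = "network_spec")
}

# Synchronous signed propagation used to derive disease states at
# generation time: roots clamped DOWN, everything else starts UNCHANGED.
.propagate_from_roots <- function(src, tgt, sgn, nodes, roots) {
  st <- setNames(integer(length(nodes)), nodes)
  st[roots] <- -1L
  for (round in seq_len(2L * length(nodes))) {
    prev <- st
    for (v in setdiff(nodes, roots)) {
      inc <- which(tgt == v)
      if (!length(inc)) next
      s <- sum(sgn[inc] * prev[src[inc]])
      st[v] <- if (s > 0) 1L else if (s < 0) -1L else 0L
    }
    if (identical(st, prev)) break
  }
  st
}

#' Generate a ground-truth signed regulatory network
#'
#' Builds a directed network whose disease (TG) Boolean states arise from
#' clamping the root regulators DOWN and propagating along the true signs
#' (activation copies the state, inhibition negates it; multiple parents
#' combine by sign-weighted majority). Control (WT) states are the mirror
#' of TG states for affected genes. A fraction of edge signs is masked as
#' `"unknown"` in the emitted network. Ground-truth perturbation scores are
#' computed under the perturbation module's propagation rule.
#'
#' @param spec A [network_spec()].
#' @return A list of class `sim_network`: `network` (emitted edges:
#'   `source`, `target`, `effect`, `category`), `truth` (edges with true
#'   signs), `states` (list `TG`, `WT` of named state vectors), `scores`
#'   (named ground-truth perturbation scores) and `roots`.
#' @export
generate_prior_network <- function(spec) {
  .assert(inherits(spec, "network_spec"), "spec must be a network_spec")
  n <- spec$n_nodes
  .with_seed(spec$seed, {
    names_out <- spec$node_names %||% sprintf("g%04d", seq_len(n))
    # Topological positions 1..n carry a random permutation of the labels
    # so the root's label carries no ordering information.
    lab <- sample(names_out)
    roots <- lab[seq_len(spec$n_roots)]

    if (spec$topology == "chain") {
      src_i <- seq_len(n - 1L); tgt_i <- seq_len(n - 1L) + 1L
    } else {
      src_i <- integer(0); tgt_i <- integer(0)
      # one parent per non-root node guarantees every node descends from a root
      for (i in (spec$n_roots + 1L):n) {
        src_i <- c(src_i, sample.int(i - 1L, 1L)); tgt_i <- c(tgt_i, i)
      }
      extra <- spec$n_edges - length(src_i)
      if (extra > 0) {
        have <- paste(src_i, tgt_i)
        cand <- expand.grid(s = seq_len(n), t = seq_len(n))
        cand <- cand[cand$s != cand$t, ]
        if (spec$acyclic) cand <- cand[cand$s < cand$t, ]
        key <- paste(cand$s, cand$t)
        cand <- cand[!key %in% have, , drop = FALSE]
        .assert(nrow(cand) >= extra, "infeasible edge count")
        pick <- cand[sample.int(nrow(cand), extra), , drop = FALSE]
        src_i <- c(src_i, pick$s); tgt_i <- c(tgt_i, pick$t)
      }
    }
    src <- lab[src_i]; tgt <- lab[tgt_i]
    e <- length(src)
    sgn <- ifelse(stats::runif(e) < spec$frac_inhibition, -1L, 1L)
    if (spec$topology == "chain") sgn[] <- 1L

    st_num <- .propagate_from_roots(src, tgt, sgn, lab, roots)
    tg <- setNames(.num_to_state(st_num), names(st_num))[names_out]
    wt <- ifelse(tg == "UP", "DOWN", ifelse(tg == "DOWN", "UP", "UNCHANGED"))
    names(wt) <- names_out

    truth <- data.frame(
      source = src, target = tgt,
      effect = ifelse(sgn > 0, "activation", "inhibition"),
      category = sample(NETWORK_CATEGORIES, e, replace = TRUE),
      stringsAsFactors = FALSE)
    emitted <- truth
    n_unknown <- round(spec$frac_unknown_sign * e)
    if (n_unknown > 0)
      emitted$effect[sample.int(e, n_unknown)] <- "unknown"

    scores <- setNames(integer(length(names_out)), names_out)
    rk <- rank_regulators(truth, tg, wt)
    scores[rk$regulator] <- rk$score

    structure(list(network = emitted, truth = truth,
                   states = list(TG = tg, WT = wt),
                   scores = scores, roots = roots, spec = spec),
              class = "sim_network")
  })
}

#' Assemble the default synthetic bundle
#'
#' The stated world for end-to-end testing: one endothelial-like cell type
#' with 300 cells per arm, 1000 genes, and a 40-node / 60-edge signed prior
#' network over a random subset of genes. The transcriptome is kept large
#' relative to the planted effects so that the differentially expressed
#' genes do not dominate per-cell library composition (with a much smaller
#' transcriptome the library-size offset would induce spurious
#' counter-regulation of every null gene). The network's disease state is a
#' single root-regulator flip; every affected network gene receives a
#' male-specific planted logFC of +/-1.0 aligned with its Boolean state.
#' A handful of neutral, female-specific and dimorphic genes are planted
#' outside the network; remaining genes are null. Pathway gene sets include
#' one "planted_disease" set collecting the network DEGs plus random sets.
#'
#' @param seed Integer seed driving every stochastic choice.
#' @param config A [sim_config()]; defaults to the stated world.
#' @param n_net_genes,n_net_edges Size of the prior network.
#' @param frac_inhibition,frac_unknown_sign Network sign composition.
#' @param lfc Magnitude of the planted male-specific logFC on network genes.
#' @param n_pathways Number of random pathway sets.
#' @return A list of class `sim_bundle` combining the pieces of
#'   [generate_counts()] and [generate_prior_network()] plus `pathways`.
#' @export
simulate_bundle <- function(seed = 1L,
                            config = sim_config(n_genes = 1000L, seed = seed),
                            n_net_genes = 40L, n_net_edges = 60L,
                            frac_inhibition = 0.25, frac_unknown_sign = 0.2,
                            lfc = 1.0, n_pathways = 20L) {
  sim_net <- .with_seed(seed + 1000L, {
    # network genes: non-mito genes, leaving marker blocks free
    n_mito <- round(config$mito_gene_fraction * config$n_genes)
    genes <- sprintf("g%04d", seq_len(config$n_genes))
    if (n_mito > 0)
      genes[seq_len(n_mito)] <- paste0(MITO_PREFIX, genes[seq_len(n_mito)])
    pool <- genes[!startsWith(genes, MITO_PREFIX)]
    net_genes <- sample(pool, n_net_genes)
    generate_prior_network(network_spec(
      n_nodes = n_net_genes, n_edges = n_net_edges,
      frac_inhibition = frac_inhibition,
      frac_unknown_sign = frac_unknown_sign,
      acyclic = TRUE, node_names = net_genes, seed = seed + 2000L))
  })

  tg <- sim_net$states$TG
  deg_net <- names(tg)[tg != "UNCHANGED"]
  eff_net <- if (length(deg_net)) {
    planted_effects(gene = deg_net, effect_class = "male_specific",
                    logFC_m = ifelse(tg[deg_net] == "UP", lfc, -lfc),
                    logFC_f = 0)
  } else NULL

  extra <- .with_seed(seed + 3000L, {
    n_mito <- round(config$mito_gene_fraction * config$n_genes)
    genes <- sprintf("g%04d", seq_len(config$n_genes))
    if (n_mito > 0)
      genes[seq_len(n_mito)] <- paste0(MITO_PREFIX, genes[seq_len(n_mito)])
    free <- setdiff(genes, c(names(tg), genes[seq_len(max(n_mito, 0))]))
    pick <- sample(free, 16L)
    s <- sample(c(-1, 1), 16L, replace = TRUE)
    rbind(
      planted_effects(pick[1:8], "neutral", 0.8 * s[1:8], 0.8 * s[1:8]),
      planted_effects(pick[9:12], "female_specific", 0, 0.8 * s[9:12]),
      planted_effects(pick[13:16], "dimorphic", 0.8 * s[13:16],
                      -0.8 * s[13:16]))
  })
  effects <- rbind(eff_net, extra)
  class(effects) <- c("planted_effects", "data.frame")

  sim <- generate_counts(config, effects)

  pathways <- .with_seed(seed + 4000L, {
    all_genes <- sim$gene_info$gene
    ps <- lapply(seq_len(n_pathways), function(i) {
      sort(sample(all_genes, sample(10:40, 1L)))
    })
    names(ps) <- sprintf("pathway%02d", seq_len(n_pathways))
    ps$planted_disease <- sort(deg_net)
    ps
  })

  structure(c(sim, list(network = sim_net$network, truth = sim_net$truth,
                        states = sim_net$states, scores = sim_net$scores,
                        roots = sim_net$roots, pathways = pathways,
                        seed = as.integer(seed))),
            class = "sim_bundle")
}

#' Write a synthetic bundle to disk
#'
#' Emits the standard plain-text exchange formats: Matrix Market counts
#' with `features.tsv`/`barcodes.tsv`, `metadata.tsv`, marker and pathway
#' GMT files, the prior network TSV and `ground_truth.json`, plus a
#' `manifest.json` listing each file with its MD5 checksum.
#'
#' @param bundle A `sim_bundle` (or `sim_counts`-compatible list).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest as a data.frame (`file`, `md5`).
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    .assert(ok, "cannot create directory %s", dir)
  }
  p <- function(f) file.path(dir, f)
  Matrix::writeMM(bundle$counts, p("matrix.mtx"))
  utils::write.table(
    data.frame(gene_id = rownames(bundle$counts),
               gene_symbol = rownames(bundle$counts)),
    p("features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  writeLines(colnames(bundle$counts), p("barcodes.tsv"))
  utils::write.table(
    bundle$metadata[, c("barcode", "genotype", "gender", "cell_type")],
    p("metadata.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(bundle$markers, p("markers.gmt"), description = "cell type markers")
  write_gmt(bundle$pathways, p("pathways.gmt"), description = "synthetic pathway")
  utils::write.table(bundle$network, p("network.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gt <- list(states = lapply(bundle$states, as.list),
             scores = as.list(bundle$scores),
             roots = bundle$roots,
             truth = bundle$truth,
             effects = if (is.null(bundle$effects)) list() else
               as.data.frame(bundle$effects))
  jsonlite::write_json(gt, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- c("matrix.mtx", "features.tsv", "barcodes.tsv", "metadata.tsv",
             "markers.gmt", "pathways.gmt", "network.tsv",
             "ground_truth.json")
  manifest <- data.frame(file = files,
                         md5 = vapply(files, function(f) .file_md5(p(f)),
                                      character(1)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param dir Bundle directory.
#' @return A list with `counts`, `metadata`, `markers`, `pathways`,
#'   `network` and `ground_truth` (the latter `NULL` when absent, e.g. for
#'   user-supplied real data laid out in the same format).
#' @export
read_bundle <- function(dir) {
  .assert(dir.exists(dir), "no such directory: %s", dir)
  p <- function(f) file.path(dir, f)
  for (f in c("matrix.mtx", "features.tsv", "barcodes.tsv", "metadata.tsv"))
    .assert(file.exists(p(f)), "bundle is missing %s", f)
  counts <- methods::as(methods::as(Matrix::readMM(p("matrix.mtx")),
                                    "CsparseMatrix"), "generalMatrix")
  feats <- utils::read.table(p("features.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)
  barcodes <- readLines(p("barcodes.tsv"))
  dimnames(counts) <- list(feats[[1]], barcodes)
  metadata <- utils::read.table(p("metadata.tsv"), sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  out <- list(counts = counts, metadata = metadata)
  if (file.exists(p("markers.gmt"))) out$markers <- read_gmt(p("markers.gmt"))
  if (file.exists(p("pathways.gmt"))) out$pathways <- read_gmt(p("pathways.gmt"))
  if (file.exists(p("network.tsv")))
    out$network <- utils::read.table(p("network.tsv"), sep = "\t",
                                     header = TRUE, stringsAsFactors = FALSE)
  if (file.exists(p("ground_truth.json"))) {
    gt <- jsonlite::read_json(p("ground_truth.json"), simplifyVector = TRUE)
    gt$states <- lapply(gt$states, unlist)
    gt$scores <- unlist(gt$scores)
    out$ground_truth <- gt
  }
  out
}
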