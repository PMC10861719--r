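# Workflow module: stage functions over an inspectable TSV/JSON contract,
# a full-pipeline driver with provenance manifest, and a summary report.

.PIPELINE_KEYS <- c("input_dir", "output_dir", "simulate", "qc",
                    "n_variable_genes", "n_pcs", "snn_k", "resolutions",
                    "use_true_cell_types", "de", "enrichment", "grn",
                    "seed")

#' Pipeline configuration
#'
#' Defaults reproduce the published thresholds: QC 200/2500 features and
#' 5% mitochondrial counts, DE significance q < 0.05 with a q > 0.5 null
#' buffer, pathway q < 0.05, set sizes 10-500. Unknown keys are a schema
#' error naming the key. Every stochastic stage derives its seed from
#' `seed`.
#'
#' @param input_dir Bundle directory (see [read_bundle()] for the layout);
#'   may be missing when `simulate` is set.
#' @param output_dir Where stage outputs are written.
#' @param ... Overrides for the keys listed above (nested lists for `qc`,
#'   `de`, `grn`, `enrichment`, `simulate`).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = tempfile("scdim_"),
                            ...) {
  cfg <- list(
    input_dir = input_dir, output_dir = output_dir,
    simulate = NULL,
    qc = list(min_features = 200L, max_features = 2500L,
              max_mito_frac = 0.05, mito_prefix = "mt-"),
    n_variable_genes = 2500L, n_pcs = 10L, snn_k = 20L,
    resolutions = seq(0.2, 2, by = 0.2),
    use_true_cell_types = FALSE,
    de = list(q_sig = 0.05, q_null = 0.5, min_cells = 3L,
              include_all = TRUE),
    enrichment = list(min_set = 10L, max_set = 500L, min_degs = 3L),
    grn = list(cell_type = NULL, gender = "M", q_thresh = 0.05,
               population = 200L, generations = 300L,
               allow_uncurated = TRUE),
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), .PIPELINE_KEYS)
  .assert(length(bad) == 0, "unknown config key(s): %s",
          paste(bad, collapse = ", "))
  for (k in names(over)) {
    if (is.list(cfg[[k]]) && is.list(over[[k]])) {
      badk <- setdiff(names(over[[k]]), names(cfg[[k]]))
      if (k != "simulate")
        .assert(length(badk) == 0, "unknown config key(s): %s",
                paste(paste0(k, ".", badk), collapse = ", "))
      cfg[[k]][names(over[[k]])] <- over[[k]]
    } else {
      cfg[[k]] <- over[[k]]
    }
  }
  .assert(!is.null(cfg$input_dir) || !is.null(cfg$simulate),
          "either input_dir or simulate must be given")
  if (is.null(cfg$input_dir))
    cfg$input_dir <- file.path(cfg$output_dir, "bundle")
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a JSON file
#'
#' @param path JSON config file.
#' @param ... Overrides applied on top of the file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, ...) {
  .assert(file.exists(path), "no such config file: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config,
          utils::modifyList(raw, list(...), keep.null = TRUE))
}

.out <- function(cfg, f) file.path(cfg$output_dir, f)

.ensure_outdir <- function(cfg) {
  if (!dir.exists(cfg$output_dir))
    dir.create(cfg$output_dir, recursive = TRUE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
  .assert(file.exists(path), "missing stage output: %s (run the earlier stage)",
          path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname run_pipeline
#' @export
stage_simulate <- function(config) {
  .ensure_outdir(config)
  sim <- config$simulate
  if (!is.list(sim)) sim <- list()
  seed <- sim$seed %||% config$seed %||% 1L
  cpa <- unlist(sim$cells_per_arm) %||% c(endothelial = 300L)
  scfg <- sim_config(n_genes = sim$n_genes %||% 1000L,
                     cells_per_arm = cpa, seed = seed)
  b <- simulate_bundle(seed = seed, config = scfg,
                       n_net_genes = sim$n_net_genes %||% 40L,
                       n_net_edges = sim$n_net_edges %||% 60L)
  write_bundle(b, config$input_dir)
  invisible(config$input_dir)
}

#' @rdname run_pipeline
#' @export
stage_preprocess <- function(config) {
  .ensure_outdir(config)
  bundle <- read_bundle(config$input_dir)
  qc <- qc_filter(bundle$counts, do.call(qc_thresholds, config$qc))
  jsonlite::write_json(qc$report, .out(config, "qc_report.json"),
                       auto_unbox = TRUE)
  norm <- clr_normalize(qc$counts)
  hvg <- select_variable_genes(norm, min(config$n_variable_genes, nrow(norm)))
  scores <- embed_cells(norm, hvg, config$n_pcs)
  md <- bundle$metadata[match(colnames(qc$counts), bundle$metadata$barcode), ]
  if (isTRUE(config$use_true_cell_types) || length(unique(md$cell_type)) < 2) {
    cl_df <- data.frame(barcode = md$barcode, cluster = NA_integer_,
                        cell_type = md$cell_type, stringsAsFactors = FALSE)
  } else {
    g <- build_snn_graph(scores, k = min(config$snn_k, nrow(scores) - 1L))
    cands <- cluster_cells(g, config$resolutions, seed = config$seed %||% 1L)
    best <- choose_clustering(cands, scores)
    ann <- annotate_clusters(best, norm, bundle$markers)
    lab <- setNames(ann$cell_type, ann$cluster)
    cl_df <- data.frame(barcode = names(best$membership),
                        cluster = unname(best$membership),
                        cell_type = unname(lab[as.character(best$membership)]),
                        stringsAsFactors = FALSE)
  }
  .write_tsv(cl_df, .out(config, "clusters.tsv"))
  invisible(cl_df)
}

#' @rdname run_pipeline
#' @export
stage_de <- function(config) {
  bundle <- read_bundle(config$input_dir)
  cl <- .read_tsv(.out(config, "clusters.tsv"))
  md <- bundle$metadata[bundle$metadata$barcode %in% cl$barcode, , drop = FALSE]
  de <- run_stratified_de(
    bundle$counts[, cl$barcode, drop = FALSE], md,
    cell_types = setNames(cl$cell_type, cl$barcode),
    include_all = isTRUE(config$de$include_all),
    min_cells = config$de$min_cells)
  classes <- classify_gender_patterns(de, config$de$q_sig, config$de$q_null)
  .write_tsv(de, .out(config, "de_results.tsv"))
  .write_tsv(classes, .out(config, "gender_classes.tsv"))
  invisible(list(de = de, classes = classes))
}

#' @rdname run_pipeline
#' @export
stage_enrich <- function(config) {
  bundle <- read_bundle(config$input_dir)
  .assert(!is.null(bundle$pathways), "bundle has no pathways.gmt")
  classes <- .read_tsv(.out(config, "gender_classes.tsv"))
  scope <- if ("ALL" %in% classes$cell_type) "ALL" else
    classes$cell_type[1]
  cc <- classes[classes$cell_type == scope, , drop = FALSE]
  res <- run_enrichment(cc, gene_set_collection(bundle$pathways),
                        min_set = config$enrichment$min_set,
                        max_set = config$enrichment$max_set,
                        min_degs = config$enrichment$min_degs)
  .write_tsv(res, .out(config, "enrichment_results.tsv"))
  invisible(res)
}

# Pick the GRN stratum: configured cell type, else the one with the most
# male-specific DEGs (mirroring the published analysis focus).
.grn_stratum <- function(config, classes) {
  ct <- config$grn$cell_type
  if (!is.null(ct)) return(ct)
  ms <- classes[classes$label == "male_specific", , drop = FALSE]
  if (nrow(ms) == 0) return(unique(classes$cell_type)[1])
  names(sort(table(ms$cell_type), decreasing = TRUE))[1]
}

#' @rdname run_pipeline
#' @export
stage_grn <- function(config) {
  netfile <- file.path(config$input_dir, "network.tsv")
  .assert(file.exists(netfile), "missing network file: %s", netfile)
  prior <- read_prior_network(netfile,
                              allow_uncurated =
                                isTRUE(config$grn$allow_uncurated))
  de <- .read_tsv(.out(config, "de_results.tsv"))
  classes <- .read_tsv(.out(config, "gender_classes.tsv"))
  ct <- .grn_stratum(config, classes)
  stratum <- de[de$cell_type == ct & de$gender == config$grn$gender, ,
                drop = FALSE]
  .assert(nrow(stratum) > 0, "no DE results for stratum (%s, %s)",
          ct, config$grn$gender)
  states <- booleanize(stratum, config$grn$q_thresh)
  ga <- ga_config(population = config$grn$population,
                  generations = config$grn$generations,
                  seed = config$seed %||% 1L)
  nets <- build_genotype_networks(prior, states, ga)
  for (ph in c("TG", "WT"))
    .write_tsv(nets[[ph]]$edges, .out(config, sprintf("grn_%s.tsv",
                                                      tolower(ph))))
  jsonlite::write_json(
    list(stratum = list(cell_type = ct, gender = config$grn$gender),
         TG = c(list(fitness = nets$TG$fitness), nets$TG$report),
         WT = c(list(fitness = nets$WT$fitness), nets$WT$report),
         n_shared_edges = nrow(nets$shared_edges)),
    .out(config, "grn_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(nets)
}

#' @rdname run_pipeline
#' @export
stage_perturb <- function(config) {
  de <- .read_tsv(.out(config, "de_results.tsv"))
  classes <- .read_tsv(.out(config, "gender_classes.tsv"))
  ct <- .grn_stratum(config, classes)
  stratum <- de[de$cell_type == ct & de$gender == config$grn$gender, ,
                drop = FALSE]
  states <- booleanize(stratum, config$grn$q_thresh)
  edges <- .read_tsv(.out(config, "grn_tg.tsv"))
  rk <- rank_regulators(edges, states$TG, states$WT)
  .write_tsv(rk, .out(config, "perturbation_ranking.tsv"))
  jsonlite::write_json(setNames(as.list(rk$score), rk$regulator),
                       .out(config, "perturbation.json"), auto_unbox = TRUE)
  invisible(rk)
}

#' @rdname run_pipeline
#' @export
stage_report <- function(config) {
  classes <- .read_tsv(.out(config, "gender_classes.tsv"))
  # per-cell-type Venn counts of significant DEGs by sex
  venn <- lapply(split(classes, classes$cell_type), function(cc) {
    m_sig <- cc$q_m < 0.05 & !is.na(cc$q_m)
    f_sig <- cc$q_f < 0.05 & !is.na(cc$q_f)
    list(male_only = sum(m_sig & !f_sig), female_only = sum(f_sig & !m_sig),
         shared = sum(m_sig & f_sig))
  })
  class_tables <- lapply(split(classes, classes$cell_type), function(cc)
    as.list(table(factor(cc$label, levels = GENDER_CLASSES))))
  report <- list(venn = venn, class_tables = class_tables)
  rkf <- .out(config, "perturbation_ranking.tsv")
  if (file.exists(rkf)) {
    rk <- .read_tsv(rkf)
    report$perturbation_ranking <- setNames(as.list(rk$score), rk$regulator)
  }
  jsonlite::write_json(report, .out(config, "report.json"),
                       auto_unbox = TRUE)
  invisible(report)
}

#' Run the full pipeline
#'
#' Executes simulate (when configured), preprocess, differential
#' expression and classification, enrichment, GRN inference, perturbation
#' ranking and the summary report; writes all stage outputs plus a
#' provenance manifest (`manifest.json` with per-file MD5 checksums, the
#' config and package version) under `config$output_dir`. A stage failure
#' halts the run with the stage name. Outputs are pure functions of
#' (inputs, config, seed); inputs are never mutated.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "pipeline_config"),
          "config must come from pipeline_config()")
  .ensure_outdir(config)
  stages <- list(
    simulate = function() if (!is.null(config$simulate))
      stage_simulate(config),
    preprocess = function() stage_preprocess(config),
    de = function() stage_de(config),
    enrich = function() stage_enrich(config),
    grn = function() stage_grn(config),
    perturb = function() stage_perturb(config),
    report = function() stage_report(config))
  if (is.null(config$simulate))
    .assert(dir.exists(config$input_dir), "input_dir does not exist: %s",
            config$input_dir)
  # validate the GRN input before any compute
  if (is.null(config$simulate)) {
    netfile <- file.path(config$input_dir, "network.tsv")
    .assert(file.exists(netfile),
            "missing network file before pipeline start: %s", netfile)
  }
  for (nm in names(stages)) {
    t0 <- Sys.time()
    tryCatch(stages[[nm]](),
             error = function(e) .stopf("stage '%s' failed: %s", nm,
                                        conditionMessage(e)))
    message(sprintf("[scDimorph] stage %-10s %.1fs", nm,
                    as.numeric(Sys.time() - t0, units = "secs")))
  }
  outs <- list.files(config$output_dir, recursive = TRUE)
  files <- file.path(config$output_dir, outs)
  manifest <- list(
    package_version = as.character(utils::packageVersion("scDimorph")),
    seed = config$seed,
    config = unclass(config),
    files = data.frame(file = outs,
                       md5 = vapply(files, .file_md5, character(1)),
                       stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, .out(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
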