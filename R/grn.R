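# GRN inference module: Booleanize differential-expression results into
# phenotype states and select, via a genetic algorithm over a signed
# prior-knowledge network, genotype-specific consistent subnetworks,
# inferring unknown edge signs from the expression states.

EDGE_EFFECTS <- c("activation", "inhibition", "unknown")

#' Read a prior-knowledge interaction network
#'
#' Tab-separated edge list with columns `source`, `target`, `effect`
#' (activation/inhibition/unknown; empty treated as unknown) and optional
#' `category`. Self-loops are dropped with a warning. Edges are restricted
#' to the curated regulatory categories unless `allow_uncurated = TRUE`.
#'
#' @param path File path.
#' @param allowed_categories Category whitelist.
#' @param allow_uncurated Keep edges with other/missing categories (tagged
#'   `"uncurated"`).
#' @return A data.frame of prior edges.
#' @export
read_prior_network <- function(path,
                               allowed_categories = NETWORK_CATEGORIES,
                               allow_uncurated = FALSE) {
  .assert(file.exists(path), "no such file: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  .assert(all(c("source", "target") %in% names(df)),
          "prior network needs source and target columns")
  if (is.null(df$effect)) df$effect <- "unknown"
  df$effect[is.na(df$effect) | df$effect == ""] <- "unknown"
  bad <- !df$effect %in% EDGE_EFFECTS
  .assert(!any(bad), "invalid effect value(s): %s",
          paste(unique(df$effect[bad]), collapse = ", "))
  if (is.null(df$category)) df$category <- "uncurated"
  df$category[is.na(df$category) | !df$category %in% allowed_categories] <-
    "uncurated"
  loops <- df$source == df$target
  if (any(loops)) {
    .warnf("dropping %d self-loop(s)", sum(loops))
    df <- df[!loops, , drop = FALSE]
  }
  if (!allow_uncurated) df <- df[df$category != "uncurated", , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Booleanize one stratum's differential-expression results
#'
#' The disease (TG) state of a gene is UP if `q < q_thresh` and
#' `logFC > 0`, DOWN if `q < q_thresh` and `logFC < 0`, and UNCHANGED
#' otherwise. The control (WT) state is the opposite for affected genes
#' and UNCHANGED otherwise.
#'
#' @param de A data.frame with columns `gene`, `logFC`, `q` (one stratum).
#' @param q_thresh Significance threshold (default 0.05).
#' @return A list of class `boolean_states` with named state vectors `TG`
#'   and `WT`.
#' @export
booleanize <- function(de, q_thresh = 0.05) {
  .assert(is.data.frame(de) && all(c("gene", "logFC", "q") %in% names(de)),
          "de must have columns gene, logFC, q")
  .assert(!anyDuplicated(de$gene),
          "booleanize expects one row per gene (a single stratum)")
  tg <- ifelse(de$q < q_thresh & de$logFC > 0, "UP",
               ifelse(de$q < q_thresh & de$logFC < 0, "DOWN", "UNCHANGED"))
  names(tg) <- de$gene
  wt <- ifelse(tg == "UP", "DOWN", ifelse(tg == "DOWN", "UP", "UNCHANGED"))
  names(wt) <- de$gene
  structure(list(TG = tg, WT = wt), class = "boolean_states")
}

#' Edge consistency under one phenotype's Boolean states
#'
#' An edge with a resolved sign is consistent iff both endpoints are
#' non-UNCHANGED and the target state equals the source state under
#' activation (or its opposite under inhibition). Edges touching an
#' UNCHANGED node are uninformative and return `NA`.
#'
#' @param states Named character state vector for one phenotype.
#' @param source,target Endpoint gene vectors (recycled together).
#' @param effect `"activation"` or `"inhibition"` per edge; an unresolved
#'   `"unknown"` is an error (resolve first).
#' @return Logical vector with `NA` for uninformative edges.
#' @export
edge_consistent <- function(states, source, target, effect) {
  .assert(all(effect %in% c("activation", "inhibition")),
          "edge_consistent requires resolved signs; got unknown effect")
  s <- .state_to_num(.states_for(states, source))
  t <- .state_to_num(.states_for(states, target))
  out <- ifelse(effect == "activation", s * t > 0, s * t < 0)
  out[s == 0L | t == 0L] <- NA
  out
}

#' Infer the sign of an unknown-effect edge from expression states
#'
#' Returns the sign that makes the edge consistent under the given
#' phenotype states: matching non-UNCHANGED endpoint states imply
#' activation, opposite states imply inhibition. If either endpoint is
#' UNCHANGED the edge is uninformative and `NA` is returned (the edge can
#' still be displayed with unknown effect).
#'
#' @inheritParams edge_consistent
#' @return Character vector (`"activation"`/`"inhibition"`/`NA`).
#' @export
resolve_unknown_sign <- function(states, source, target) {
  s <- .state_to_num(.states_for(states, source))
  t <- .state_to_num(.states_for(states, target))
  ifelse(s == 0L | t == 0L, NA_character_,
         ifelse(s == t, "activation", "inhibition"))
}

#' Fitness of a candidate edge subset
#'
#' `fitness = n_consistent + n_covered_degs - lambda * n_inconsistent`,
#' where `n_covered_degs` counts DEG nodes (non-UNCHANGED in the phenotype
#' states) incident to at least one consistent included edge. Uninformative
#' edges contribute nothing.
#'
#' @param edges Data.frame with `source`, `target` and resolved
#'   `effect_resolved` (or `effect`); `NA` effects are uninformative.
#' @param states Named character state vector for one phenotype.
#' @param lambda Penalty weight for inconsistent edges.
#' @return A list (`fitness`, `n_consistent`, `n_inconsistent`,
#'   `n_covered_degs`).
#' @export
network_fitness <- function(edges, states, lambda = 1) {
  if (nrow(edges) == 0)
    return(list(fitness = 0, n_consistent = 0L, n_inconsistent = 0L,
                n_covered_degs = 0L))
  eff_col <- if ("effect_resolved" %in% names(edges)) "effect_resolved" else "effect"
  eff <- edges[[eff_col]]
  known <- !is.na(eff) & eff %in% c("activation", "inhibition")
  cons <- rep(NA, nrow(edges))
  cons[known] <- edge_consistent(states, edges$source[known],
                                 edges$target[known], eff[known])
  deg <- names(states)[states != "UNCHANGED"]
  covered <- unique(c(edges$source[which(cons)], edges$target[which(cons)]))
  covered <- intersect(covered, deg)
  n_c <- sum(cons, na.rm = TRUE)
  n_i <- sum(!cons, na.rm = TRUE)
  list(fitness = n_c + length(covered) - lambda * n_i,
       n_consistent = as.integer(n_c), n_inconsistent = as.integer(n_i),
       n_covered_degs = length(covered))
}

#' Genetic-algorithm configuration
#'
#' @param population Population size (>= 2).
#' @param generations Number of generations.
#' @param crossover_rate Probability of uniform crossover per pair.
#' @param mutation_rate Per-bit flip probability.
#' @param elitism Number of elites copied unchanged each generation.
#' @param lambda Inconsistency penalty in the fitness.
#' @param seed Integer seed.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population = 200L, generations = 300L,
                      crossover_rate = 0.8, mutation_rate = 0.02,
                      elitism = 2L, lambda = 1, seed = 1L) {
  .assert(.is_count(population, 2L), "population must be >= 2")
  .assert(.is_count(generations, 1L), "generations must be >= 1")
  .assert(.is_prop(crossover_rate) && .is_prop(mutation_rate),
          "rates must be in [0,1]")
  .assert(.is_count(elitism, 0L) && elitism < population,
          "elitism must be in [0, population)")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism = as.integer(elitism), lambda = lambda,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Restrict a prior network to DEG nodes of a stratum
#'
#' Keeps edges whose two endpoints are both non-UNCHANGED in the given
#' phenotype states (the DEGs the subnetwork is built over).
#'
#' @param prior Prior edge data.frame.
#' @param states Named character state vector.
#' @return The restricted edge data.frame.
#' @export
restrict_prior_to_degs <- function(prior, states) {
  deg <- names(states)[states != "UNCHANGED"]
  out <- prior[prior$source %in% deg & prior$target %in% deg, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Resolve unknown signs against one phenotype's states and precompute each
# edge's contribution: +1 consistent, -lambda inconsistent, 0 uninformative.
.ga_prepare <- function(prior, st, lambda) {
  eff <- prior$effect
  unk <- eff == "unknown"
  resolved <- eff
  if (any(unk))
    resolved[unk] <- resolve_unknown_sign(st, prior$source[unk],
                                          prior$target[unk])
  known <- !is.na(resolved)
  cons <- rep(NA, nrow(prior))
  cons[known] <- edge_consistent(st, prior$source[known],
                                 prior$target[known], resolved[known])
  w <- ifelse(is.na(cons), 0, ifelse(cons, 1, -lambda))
  deg <- names(st)[st != "UNCHANGED"]
  # DEG-node x edge incidence over consistent edges, for the coverage term
  ce <- which(!is.na(cons) & cons)
  M <- Matrix::sparseMatrix(
    i = match(c(prior$source[ce], prior$target[ce]), deg),
    j = rep(ce, 2L), x = 1,
    dims = c(length(deg), nrow(prior)))
  list(resolved = resolved, cons = cons, w = w, deg = deg, M = M)
}

# Vectorized fitness of a population: X is an edges x pop 0/1 matrix.
.ga_fitness_pop <- function(X, prep) {
  base <- as.numeric(crossprod(X, prep$w))
  cover <- Matrix::colSums((prep$M %*% X) > 0)
  base + cover
}

#' Select a genotype-consistent subnetwork with a genetic algorithm
#'
#' Chromosomes carry one inclusion bit per prior edge. Unknown signs are
#' resolved against the phenotype's states before fitness evaluation.
#' Tournament selection (size 3), uniform crossover, per-bit mutation and
#' elitism; deterministic given `config$seed`. The best fitness is
#' non-decreasing across generations.
#'
#' @param prior Prior edge data.frame (ideally already restricted to DEG
#'   nodes, see [restrict_prior_to_degs()]).
#' @param states A `boolean_states` object (or list with `TG`/`WT` maps).
#' @param phenotype `"TG"` or `"WT"`.
#' @param config A [ga_config()].
#' @return An object of class `genotype_network`: `phenotype`, `edges`
#'   (included edges with `effect_prior` and `effect_resolved`), `fitness`,
#'   `report` (`n_consistent`, `n_inconsistent`, `n_covered_degs`) and
#'   `history` (best fitness per generation).
#' @export
ga_optimize <- function(prior, states, phenotype = c("TG", "WT"),
                        config = ga_config()) {
  phenotype <- match.arg(phenotype)
  st <- states[[phenotype]]
  .assert(!is.null(st), "states lack phenotype %s", phenotype)
  E <- nrow(prior)
  .assert(!is.null(E) && E > 0,
          "insufficient interactions: prior has no edges among the DEGs")
  prep <- .ga_prepare(prior, st, config$lambda)

  .with_seed(config$seed, {
    P <- config$population
    X <- matrix(as.numeric(stats::runif(E * P) < 0.5), nrow = E)
    fit <- .ga_fitness_pop(X, prep)
    best_i <- which.max(fit)
    best <- X[, best_i, drop = FALSE]; best_fit <- fit[best_i]
    history <- numeric(config$generations)
    for (g in seq_len(config$generations)) {
      ord <- order(fit, decreasing = TRUE)
      elite <- X[, ord[seq_len(config$elitism)], drop = FALSE]
      # tournament selection, size 3
      n_off <- P - config$elitism
      tour <- matrix(sample.int(P, 3L * n_off, replace = TRUE), nrow = 3L)
      ft <- matrix(fit[tour], nrow = 3L)
      winners <- tour[cbind(max.col(t(ft), ties.method = "first"),
                            seq_len(n_off))]
      off <- X[, winners, drop = FALSE]
      # uniform crossover on consecutive pairs
      n_pair <- n_off %/% 2L
      if (n_pair > 0) {
        do_cx <- stats::runif(n_pair) < config$crossover_rate
        for (p in which(do_cx)) {
          a <- 2L * p - 1L; b <- 2L * p
          mask <- stats::runif(E) < 0.5
          tmp <- off[mask, a]
          off[mask, a] <- off[mask, b]
          off[mask, b] <- tmp
        }
      }
      # per-bit mutation
      mut <- matrix(stats::runif(E * n_off) < config$mutation_rate, nrow = E)
      off[mut] <- 1 - off[mut]
      X <- cbind(elite, off)
      fit <- .ga_fitness_pop(X, prep)
      gi <- which.max(fit)
      if (fit[gi] > best_fit) { best_fit <- fit[gi]; best <- X[, gi, drop = FALSE] }
      history[g] <- best_fit
    }

    incl <- which(best[, 1] > 0.5)
    edges <- prior[incl, , drop = FALSE]
    edges$effect_prior <- edges$effect
    edges$effect_resolved <- prep$resolved[incl]
    edges$effect <- NULL
    rownames(edges) <- NULL
    rep_ <- network_fitness(
      data.frame(source = edges$source, target = edges$target,
                 effect_resolved = edges$effect_resolved,
                 stringsAsFactors = FALSE),
      st, lambda = config$lambda)
    structure(list(phenotype = phenotype, edges = edges,
                   fitness = best_fit, report = rep_[-1],
                   history = history),
              class = "genotype_network")
  })
}

#' Build TG and WT genotype-specific networks
#'
#' Restricts the prior to DEG nodes, runs [ga_optimize()] once per
#' phenotype, and reports the shared edges.
#'
#' @param prior Prior edge data.frame.
#' @param states A `boolean_states` object with `TG` and `WT` maps.
#' @param config A [ga_config()].
#' @return A list of class `genotype_networks` with elements `TG`, `WT`
#'   and `shared_edges` (edges included in both with identical resolved
#'   signs).
#' @export
build_genotype_networks <- function(prior, states, config = ga_config()) {
  .assert(!is.null(states$TG) && !is.null(states$WT),
          "states must contain both TG and WT phenotypes")
  net <- lapply(c(TG = "TG", WT = "WT"), function(ph) {
    pr <- restrict_prior_to_degs(prior, states[[ph]])
    ga_optimize(pr, states, ph, config)
  })
  key <- function(x) paste(x$edges$source, x$edges$target,
                           x$edges$effect_resolved)
  shared <- net$TG$edges[key(net$TG) %in% key(net$WT), , drop = FALSE]
  rownames(shared) <- NULL
  structure(list(TG = net$TG, WT = net$WT, shared_edges = shared),
            class = "genotype_networks")
}
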