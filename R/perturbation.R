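# Perturbation module: clamp a regulator to its control (WT) state on a
# signed genotype-specific network, propagate synchronously, and score the
# regulator by the number of downstream disease-state genes reverted.

# Extract a resolved-sign edge table from a genotype_network or data.frame.
.pert_edges <- function(network) {
  edges <- if (inherits(network, "genotype_network")) network$edges else network
  .assert(is.data.frame(edges) && all(c("source", "target") %in% names(edges)),
          "network must be a genotype_network or an edge data.frame")
  if ("sign" %in% names(edges) && !any(c("effect", "effect_resolved") %in%
                                         names(edges)))
    return(edges[, c("source", "target", "sign")])
  eff_col <- if ("effect_resolved" %in% names(edges)) "effect_resolved" else "effect"
  eff <- edges[[eff_col]]
  unresolved <- is.na(eff) | !eff %in% c("activation", "inhibition")
  if (any(unresolved)) {
    .warnf("%d edge(s) without a resolved sign excluded from propagation",
           sum(unresolved))
    edges <- edges[!unresolved, , drop = FALSE]
    eff <- eff[!unresolved]
  }
  data.frame(source = edges$source, target = edges$target,
             sign = ifelse(eff == "activation", 1L, -1L),
             stringsAsFactors = FALSE)
}

#' Propagate a clamped perturbation through a signed Boolean network
#'
#' Synchronous iteration from the disease (TG) states: in every round each
#' non-clamped node with at least one incoming resolved-sign edge takes the
#' sign-weighted majority of its regulators' previous states (activation
#' transmits the state, inhibition negates it, UNCHANGED regulators
#' contribute nothing). A tied nonzero majority is a conflict: the node
#' keeps its TG state and is reported as conflicted. Nodes unreachable from
#' the clamp keep their TG states. Iteration stops at a fixed point or
#' after `2 * n_nodes` rounds; nodes still changing at the cutoff are
#' flagged oscillating (and are never counted as reverted).
#'
#' @param network A `genotype_network` or edge data.frame with columns
#'   `source`, `target` and `effect`/`effect_resolved`; edges without a
#'   resolved sign are excluded with a warning.
#' @param tg_states Named character vector of disease states
#'   (`UP`/`DOWN`/`UNCHANGED`).
#' @param clamp Named character vector of forced states; the clamped genes
#'   must be nodes of the network.
#' @return A list with `states` (named post-perturbation states),
#'   `conflicted`, `oscillating` (character vectors) and `converged`.
#' @export
propagate <- function(network, tg_states, clamp) {
  edges <- .pert_edges(network)
  nodes <- sort(unique(c(edges$source, edges$target)))
  .assert(length(nodes) > 0, "empty network")
  .assert(length(clamp) >= 1 && !is.null(names(clamp)),
          "clamp must be a named state vector")
  bad <- setdiff(names(clamp), nodes)
  .assert(length(bad) == 0, "clamped gene(s) not in network: %s",
          paste(bad, collapse = ", "))

  tg <- setNames(.state_to_num(.states_for(tg_states, nodes)), nodes)
  st <- tg
  st[names(clamp)] <- .state_to_num(unname(clamp))
  clamped <- nodes %in% names(clamp)

  # incoming adjacency: per node, regulator indices and signs
  src_i <- match(edges$source, nodes)
  tgt_i <- match(edges$target, nodes)
  inc <- split(seq_len(nrow(edges)), tgt_i)
  upd <- setdiff(which(!clamped), setdiff(seq_along(nodes),
                                          unique(tgt_i)))  # indeg >= 1, free

  conflicted <- logical(length(nodes))
  converged <- FALSE
  max_rounds <- 2L * length(nodes)
  changed_last <- logical(length(nodes))
  for (round in seq_len(max_rounds)) {
    prev <- st
    conflicted[] <- FALSE
    for (v in upd) {
      ii <- inc[[as.character(v)]]
      sig <- edges$sign[ii] * prev[src_i[ii]]
      s <- sum(sig)
      if (s > 0) st[v] <- 1L
      else if (s < 0) st[v] <- -1L
      else if (any(sig != 0)) { st[v] <- tg[v]; conflicted[v] <- TRUE }
      else st[v] <- tg[v]
    }
    changed_last <- st != prev
    if (!any(changed_last)) { converged <- TRUE; break }
  }
  list(states = setNames(.num_to_state(st), nodes),
       conflicted = nodes[conflicted],
       oscillating = if (converged) character(0) else nodes[changed_last],
       converged = converged)
}

#' Perturb one regulator and count reverted downstream genes
#'
#' Clamps `regulator` to its WT state and counts the genes `g != regulator`
#' whose post-perturbation state equals their WT state while their TG state
#' differed from it (i.e. disease-state genes reverted toward control).
#' Oscillating nodes are never counted.
#'
#' @inheritParams propagate
#' @param wt_states Named character vector of control states.
#' @param regulator Gene to perturb; must be a node (a leaf query is
#'   allowed and scores 0).
#' @return A list of class `perturbation_result`: `regulator`, `score`,
#'   `reverted_genes`, `unresolved_conflicts`, `oscillating`.
#' @export
perturb_and_score <- function(network, tg_states, wt_states, regulator) {
  edges <- .pert_edges(network)
  nodes <- sort(unique(c(edges$source, edges$target)))
  .assert(regulator %in% nodes, "regulator not in network: %s", regulator)
  wt <- setNames(.states_for(wt_states, nodes), nodes)
  tg <- setNames(.states_for(tg_states, nodes), nodes)
  res <- propagate(edges, tg_states,
                   clamp = setNames(wt[[regulator]], regulator))
  others <- setdiff(nodes, regulator)
  reverted <- others[res$states[others] == wt[others] &
                       tg[others] != wt[others] &
                       !others %in% res$oscillating]
  structure(list(regulator = regulator, score = length(reverted),
                 reverted_genes = reverted,
                 unresolved_conflicts = res$conflicted,
                 oscillating = res$oscillating),
            class = "perturbation_result")
}

#' Rank all regulators by perturbation score
#'
#' Perturbs every node with out-degree >= 1 and sorts by score
#' (descending), breaking ties alphabetically.
#'
#' @inheritParams perturb_and_score
#' @return A data.frame (`regulator`, `score`, `reverted_genes`,
#'   `conflicts`) sorted as ranked, of class `perturbation_ranking`.
#' @export
rank_regulators <- function(network, tg_states, wt_states) {
  edges <- .pert_edges(network)
  .assert(nrow(edges) > 0, "network has no resolved edges")
  regs <- sort(unique(edges$source))
  rows <- lapply(regs, function(r)
    perturb_and_score(edges, tg_states, wt_states, r))
  df <- data.frame(
    regulator = regs,
    score = vapply(rows, `[[`, integer(1), "score"),
    reverted_genes = vapply(rows, function(x)
      paste(x$reverted_genes, collapse = ","), character(1)),
    conflicts = vapply(rows, function(x)
      paste(x$unresolved_conflicts, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$regulator), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("perturbation_ranking", "data.frame")
  df
}

#' Brute-force propagation oracle
#'
#' Reference implementation of [perturb_and_score()] for networks of at
#' most 20 nodes: explicit synchronous state-vector iteration over every
#' node with edge-list scans and no precomputed adjacency. Used to verify
#' the optimized path; must agree exactly.
#'
#' @inheritParams perturb_and_score
#' @return Integer score.
#' @export
brute_force_oracle <- function(network, tg_states, wt_states, regulator) {
  edges <- if (inherits(network, "genotype_network")) network$edges else network
  eff_col <- if ("effect_resolved" %in% names(edges)) "effect_resolved" else "effect"
  keep <- !is.na(edges[[eff_col]]) &
    edges[[eff_col]] %in% c("activation", "inhibition")
  edges <- edges[keep, , drop = FALSE]
  nodes <- sort(unique(c(edges$source, edges$target)))
  .assert(length(nodes) <= 20, "brute-force oracle limited to 20 nodes")
  .assert(regulator %in% nodes, "regulator not in network: %s", regulator)

  tg <- setNames(.states_for(tg_states, nodes), nodes)
  wt <- setNames(.states_for(wt_states, nodes), nodes)
  num <- function(s) if (s == "UP") 1L else if (s == "DOWN") -1L else 0L
  st <- vapply(tg, num, integer(1))
  tgn <- st
  st[regulator] <- num(wt[[regulator]])

  converged <- FALSE
  changed <- setNames(logical(length(nodes)), nodes)
  for (round in seq_len(2L * length(nodes))) {
    prev <- st
    for (v in nodes) {
      if (v == regulator) next
      total <- 0L; nonzero <- FALSE; has_in <- FALSE
      for (i in seq_len(nrow(edges))) {
        if (edges$target[i] != v) next
        has_in <- TRUE
        s <- if (edges[[eff_col]][i] == "activation") 1L else -1L
        sig <- s * prev[[edges$source[i]]]
        total <- total + sig
        if (sig != 0L) nonzero <- TRUE
      }
      if (!has_in) next
      if (total > 0L) st[v] <- 1L
      else if (total < 0L) st[v] <- -1L
      else st[v] <- tgn[[v]]  # tie or all-quiet: keep disease state
    }
    changed <- st != prev
    if (!any(changed)) { converged <- TRUE; break }
  }
  score <- 0L
  for (v in setdiff(nodes, regulator)) {
    if (!converged && changed[[v]]) next
    post <- if (st[[v]] > 0) "UP" else if (st[[v]] < 0) "DOWN" else "UNCHANGED"
    if (post == wt[[v]] && tg[[v]] != wt[[v]]) score <- score + 1L
  }
  score
}
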