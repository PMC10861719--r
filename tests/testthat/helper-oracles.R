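# Independent oracles and small fixture builders used across the suite.

# Closed-form two-group Poisson LRT: group totals are sufficient under the
# offset model, so the deviance is 2 * sum_g T_g log(rate_g / rate_pooled).
lrt_oracle <- function(yA, eA, yB, eB) {
  TA <- sum(yA); TB <- sum(yB); EA <- sum(eA); EB <- sum(eB)
  lam <- (TA + TB) / (EA + EB)
  term <- function(T, E) if (T == 0) 0 else T * log((T / E) / lam)
  2 * (term(TA, EA) + term(TB, EB))
}

# Exact hypergeometric upper tail by combinatorial enumeration.
hyper_enum_oracle <- function(pop, m, draws, k) {
  js <- k:min(m, draws)
  sum(choose(m, js) * choose(pop - m, draws - js)) / choose(pop, draws)
}

# Adjusted Rand Index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  exp_idx <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# Exhaustive optimum over all 2^E edge subsets (E <= 14): independent
# search, reusing only the package's consistency semantics.
ga_exhaustive_optimum <- function(prior, st, lambda = 1) {
  E <- nrow(prior)
  stopifnot(E <= 14)
  eff <- prior$effect
  unk <- eff == "unknown"
  eff[unk] <- resolve_unknown_sign(st, prior$source[unk], prior$target[unk])
  known <- !is.na(eff)
  cons <- rep(NA, E)
  cons[known] <- edge_consistent(st, prior$source[known],
                                 prior$target[known], eff[known])
  deg <- names(st)[st != "UNCHANGED"]
  best <- -Inf
  for (mask in 0:(2^E - 1)) {
    incl <- which(bitwAnd(mask, 2^(seq_len(E) - 1L)) > 0)
    ci <- incl[which(cons[incl])]
    ndeg <- length(intersect(unique(c(prior$source[ci], prior$target[ci])),
                             deg))
    f <- length(ci) + ndeg - lambda * sum(!cons[incl], na.rm = TRUE)
    if (f > best) best <- f
  }
  best
}

# Random signed network plus mirrored TG/WT states for perturbation tests.
random_signed_network <- function(n_nodes, n_edges, cyclic = FALSE,
                                  seed = 1L) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(n_nodes))
    cand <- expand.grid(s = seq_len(n_nodes), t = seq_len(n_nodes))
    cand <- cand[cand$s != cand$t, ]
    if (!cyclic) cand <- cand[cand$s < cand$t, ]
    pick <- cand[sample.int(nrow(cand), min(n_edges, nrow(cand))), ]
    edges <- data.frame(
      source = nodes[pick$s], target = nodes[pick$t],
      effect = sample(c("activation", "inhibition"), nrow(pick),
                      replace = TRUE, prob = c(0.7, 0.3)),
      stringsAsFactors = FALSE)
    tg <- setNames(sample(c("UP", "DOWN", "UNCHANGED"), n_nodes,
                          replace = TRUE, prob = c(0.4, 0.4, 0.2)), nodes)
    wt <- ifelse(tg == "UP", "DOWN", ifelse(tg == "DOWN", "UP", "UNCHANGED"))
    names(wt) <- nodes
    list(edges = edges, tg = tg, wt = wt)
  })
}

# Small two-sex count fixture for DE unit tests: two genes per planted
# class on a modest transcriptome.
small_de_world <- function(seed, n_cells_arm = 300L, lfc = 1.2,
                           classes = c("male_specific")) {
  cfg <- sim_config(n_genes = 400L, cells_per_arm = c(ct = n_cells_arm),
                    marker_genes_per_type = 0L, seed = seed)
  genes <- sprintf("g%04d", seq_len(400L))
  genes[seq_len(20L)] <- paste0("mt-", genes[seq_len(20L)])
  pick <- genes[101:(100 + 2 * length(classes))]
  eff <- do.call(rbind, lapply(seq_along(classes), function(i) {
    g <- pick[c(2 * i - 1, 2 * i)]
    switch(classes[i],
      male_specific = planted_effects(g, "male_specific", c(lfc, -lfc), 0),
      female_specific = planted_effects(g, "female_specific", 0, c(lfc, -lfc)),
      neutral = planted_effects(g, "neutral", c(lfc, -lfc), c(lfc, -lfc)),
      dimorphic = planted_effects(g, "dimorphic", c(lfc, -lfc), c(-lfc, lfc)))
  }))
  class(eff) <- c("planted_effects", "data.frame")
  list(sim = generate_counts(cfg, eff), effects = eff)
}
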