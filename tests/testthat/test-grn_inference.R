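# GRN inference: Booleanization, consistency semantics, sign resolution,
# fitness, GA optimality against exhaustive search.

test_that("booleanize maps DE statistics to phenotype states", {
  de <- data.frame(gene = c("B2m", "Egr1", "x"),
                   logFC = c(0.68, -0.26, 0.9),
                   q = c(4.4e-17, 0.0012, 0.2))
  st <- booleanize(de)
  expect_identical(unname(st$TG[c("B2m", "Egr1", "x")]),
                   c("UP", "DOWN", "UNCHANGED"))
  expect_identical(unname(st$WT[c("B2m", "Egr1", "x")]),
                   c("DOWN", "UP", "UNCHANGED"))
  expect_error(booleanize(rbind(de, de)), "one row per gene")
})

test_that("edge consistency and sign resolution follow the Boolean rules", {
  st <- c(a = "UP", b = "UP", c = "DOWN", u = "UNCHANGED")
  expect_true(edge_consistent(st, "a", "b", "activation"))
  expect_false(edge_consistent(st, "a", "b", "inhibition"))
  expect_true(edge_consistent(st, "a", "c", "inhibition"))
  expect_false(edge_consistent(st, "a", "c", "activation"))
  expect_true(is.na(edge_consistent(st, "a", "u", "activation")))
  expect_error(edge_consistent(st, "a", "b", "unknown"), "resolved")
  expect_identical(resolve_unknown_sign(st, "a", "b"), "activation")
  expect_identical(resolve_unknown_sign(st, "a", "c"), "inhibition")
  expect_true(is.na(resolve_unknown_sign(st, "a", "u")))
  # shared reduced expression of regulator and target implies activation
  st2 <- c(Klf4 = "DOWN", Klf2 = "DOWN")
  expect_identical(resolve_unknown_sign(st2, "Klf4", "Klf2"), "activation")
})

test_that("network_fitness implements consistency + coverage - penalty", {
  st <- c(a = "UP", b = "UP", c = "DOWN", d = "UP")
  edges <- data.frame(source = c("a", "b", "a"), target = c("b", "c", "d"),
                      effect = c("activation", "inhibition", "activation"))
  f <- network_fitness(edges, st)
  expect_equal(f$fitness, 3 + 4)  # E consistent edges + D covered DEGs
  expect_identical(f$n_inconsistent, 0L)
  bad <- rbind(edges, data.frame(source = "a", target = "c",
                                 effect = "activation"))
  f2 <- network_fitness(bad, st)
  expect_equal(f2$fitness, f$fitness - 1)
  expect_equal(network_fitness(edges[0, ], st)$fitness, 0)
})

test_that("GA finds the optimum on transparent instances", {
  st <- list(TG = c(a = "UP", b = "UP", c = "DOWN", d = "UP", e = "DOWN"))
  prior <- data.frame(
    source = c("a", "a", "b", "b", "d"),
    target = c("b", "c", "d", "e", "e"),
    effect = c("activation", "inhibition", "activation", "inhibition",
               "inhibition"))
  cfg <- ga_config(population = 40L, generations = 60L, seed = 1L)
  net <- ga_optimize(prior, st, "TG", cfg)
  # everything is consistent: full edge set is optimal
  expect_identical(nrow(net$edges), nrow(prior))
  expect_equal(net$fitness, 5 + 5)
  expect_identical(net$report$n_inconsistent, 0L)
  # fitness reproducible from the returned edges
  f <- network_fitness(net$edges, st$TG)
  expect_equal(f$fitness, net$fitness)
  # elitism: best fitness non-decreasing
  expect_true(all(diff(net$history) >= 0))

  # one planted inconsistent edge among 10 gets excluded
  prior2 <- rbind(prior,
                  data.frame(source = c("c", "c", "e", "a", "d"),
                             target = c("d", "e", "a", "e", "c"),
                             effect = c("inhibition", "activation",
                                        "inhibition", "inhibition",
                                        "activation")))
  # edge a -| e: a UP, e DOWN under inhibition is consistent; flip one:
  prior2$effect[8] <- "activation"  # e -> a activation: DOWN vs UP, bad
  net2 <- ga_optimize(prior2, st, "TG", cfg)
  key <- paste(net2$edges$source, net2$edges$target)
  expect_false("e a" %in% key)
  expect_equal(net2$fitness, ga_exhaustive_optimum(prior2, st$TG))
})

test_that("GA matches exhaustive search on random 12-edge priors", {
  match_n <- 0L
  for (s in 1:10) {
    rn <- random_signed_network(8L, 12L, cyclic = TRUE, seed = 400L + s)
    prior <- rn$edges
    prior$effect[1:3] <- "unknown"
    st <- list(TG = rn$tg)
    net <- ga_optimize(prior, st, "TG",
                       ga_config(population = 60L, generations = 80L,
                                 seed = s))
    opt <- ga_exhaustive_optimum(prior, rn$tg)
    expect_lte(net$fitness, opt)  # never exceeds the oracle
    match_n <- match_n + (net$fitness == opt)
  }
  expect_gte(match_n, 9L)
})

test_that("ga_optimize requires edges and resolves every included unknown
           over DEG nodes", {
  st <- list(TG = c(a = "UP", b = "DOWN"))
  expect_error(ga_optimize(data.frame(source = character(),
                                      target = character(),
                                      effect = character()), st, "TG"),
               "insufficient interactions")
  prior <- data.frame(source = "a", target = "b", effect = "unknown")
  net <- ga_optimize(prior, st, "TG",
                     ga_config(population = 10L, generations = 10L, seed = 2L))
  expect_identical(net$edges$effect_resolved, "inhibition")
})

test_that("build_genotype_networks is symmetric for mirrored states", {
  states <- structure(list(
    TG = c(a = "UP", b = "DOWN", c = "UP"),
    WT = c(a = "DOWN", b = "UP", c = "DOWN")), class = "boolean_states")
  prior <- data.frame(source = c("a", "b", "a"),
                      target = c("b", "c", "c"),
                      effect = c("inhibition", "inhibition", "activation"))
  nets <- build_genotype_networks(prior, states,
                                  ga_config(population = 30L,
                                            generations = 40L, seed = 3L))
  keys <- function(n) sort(paste(n$edges$source, n$edges$target,
                                 n$edges$effect_resolved))
  expect_identical(keys(nets$TG), keys(nets$WT))
  expect_identical(nrow(nets$shared_edges), nrow(nets$TG$edges))
})

test_that("read_prior_network validates, drops self-loops and filters
           categories", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(source = c("a", "b", "c", "d"),
                   target = c("b", "b", "d", "e"),
                   effect = c("activation", "inhibition", "unknown", ""),
                   category = c("Transcriptional Regulation", "self",
                                "Binding", "weird"))
  df$target[2] <- "b"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(out <- read_prior_network(path), "self-loop")
  expect_identical(nrow(out), 2L)  # uncurated rows dropped by default
  expect_identical(out$effect[out$source == "d"], character(0))
  out2 <- suppressWarnings(read_prior_network(path, allow_uncurated = TRUE))
  expect_identical(nrow(out2), 3L)
  expect_identical(out2$effect[out2$source == "d"], "unknown")
})
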