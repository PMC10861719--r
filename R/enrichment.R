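# Enrichment module: over-representation analysis of classified DEG lists
# against GMT gene-set collections (one-sided hypergeometric upper tail,
# Benjamini-Hochberg q values, gene-ratio statistic).

#' Read a GMT gene-set file
#'
#' @param path File path; lines are `set_name <TAB> description <TAB>
#'   gene1 <TAB> gene2 ...`.
#' @return Named list of character gene vectors with a `descriptions`
#'   attribute.
#' @export
read_gmt <- function(path) {
  .assert(file.exists(path), "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  .assert(all(lengths(parts) >= 3L), "malformed GMT line (need >= 3 fields)")
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "descriptions") <-
    setNames(vapply(parts, `[[`, character(1), 2L), names(sets))
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character gene vectors.
#' @param path Output path.
#' @param description Single description reused for every set, or a vector
#'   matching `sets`.
#' @export
write_gmt <- function(sets, path, description = "") {
  desc <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
}

#' Build a gene-set collection
#'
#' @param sets Named list of nonempty character gene vectors.
#' @param universe Background gene universe; defaults to the union of all
#'   sets (the convention of standard over-representation tools). Pass all
#'   measured genes to use the measured universe instead.
#' @return A list of class `gene_set_collection` (`sets`, `universe`,
#'   `descriptions`).
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  .assert(length(sets) > 0 && !is.null(names(sets)) &&
            all(nzchar(names(sets))), "sets must be a named list")
  .assert(all(lengths(sets) > 0), "empty gene sets are not allowed")
  u <- sort(unique(unlist(sets, use.names = FALSE)))
  if (!is.null(universe)) u <- sort(unique(as.character(universe)))
  structure(list(sets = lapply(sets, unique), universe = u,
                 descriptions = attr(sets, "descriptions") %||%
                   setNames(rep("", length(sets)), names(sets))),
            class = "gene_set_collection")
}

#' One-sided hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= k)` of the overlap `k` between the DEG
#' list and the gene set, drawing `N = |deg_list in universe|` genes from a
#' population of `|universe|` genes containing `m = |set in universe|`
#' successes. Genes outside the universe are dropped with a warning.
#'
#' @param deg_list Character DEG vector.
#' @param gene_set Character gene set.
#' @param universe Character background universe.
#' @return The p value.
#' @export
ora_test <- function(deg_list, gene_set, universe) {
  .assert(length(universe) > 0, "empty universe")
  universe <- unique(universe)
  deg <- unique(deg_list)
  unmapped <- setdiff(deg, universe)
  if (length(unmapped))
    .warnf("%d DEG(s) outside the universe dropped", length(unmapped))
  deg <- intersect(deg, universe)
  set <- intersect(unique(gene_set), universe)
  k <- length(intersect(deg, set))
  stats::phyper(k - 1, length(set), length(universe) - length(set),
                length(deg), lower.tail = FALSE)
}

#' Over-representation analysis of classified DEG lists
#'
#' Runs [ora_test()] for every retained gene set against each DEG class
#' list, with Benjamini-Hochberg adjustment per class and the gene-ratio
#' statistic `k / N` (overlap over DEGs mapped to the universe). Classes
#' with fewer than `min_degs` mapped genes are skipped with a warning
#' (small input lists do not support a robust enrichment).
#'
#' @param degs Either a `gender_classes` data.frame (class lists are the
#'   non-`unclassified` labels) or a named list of character gene vectors.
#' @param collection A [gene_set_collection()].
#' @param min_set,max_set Retained set-size bounds (within the universe).
#' @param min_degs Minimum mapped DEGs per class (default 3).
#' @return A data.frame of class `enrichment_results` (`class`, `set_id`,
#'   `description`, `k`, `m`, `N`, `gene_ratio`, `p`, `q`, `genes`),
#'   sorted by `q` then decreasing `gene_ratio` within class.
#' @export
run_enrichment <- function(degs, collection, min_set = 10L, max_set = 500L,
                           min_degs = 3L) {
  .assert(inherits(collection, "gene_set_collection"),
          "collection must be a gene_set_collection")
  if (is.data.frame(degs)) {
    keep <- degs$label != "unclassified"
    degs <- split(degs$gene[keep], degs$label[keep])
  }
  .assert(is.list(degs) && !is.null(names(degs)),
          "degs must be a named list or gender_classes data.frame")
  u <- collection$universe
  sets <- lapply(collection$sets, intersect, u)
  sizes <- lengths(sets)
  sets <- sets[sizes >= min_set & sizes <= max_set]
  .assert(length(sets) > 0, "no gene set within the size bounds")

  out <- list()
  for (cl in names(degs)) {
    deg <- intersect(unique(degs[[cl]]), u)
    if (length(deg) < min_degs) {
      .warnf("class %s has %d mapped DEG(s) (< %d); skipped",
             cl, length(deg), min_degs)
      next
    }
    N <- length(deg)
    rows <- lapply(names(sets), function(sid) {
      ov <- intersect(deg, sets[[sid]])
      data.frame(class = cl, set_id = sid,
                 description = unname(collection$descriptions[sid] %||% ""),
                 k = length(ov), m = length(sets[[sid]]), N = N,
                 gene_ratio = length(ov) / N,
                 p = stats::phyper(length(ov) - 1, length(sets[[sid]]),
                                   length(u) - length(sets[[sid]]), N,
                                   lower.tail = FALSE),
                 genes = paste(sort(ov), collapse = ","),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$q <- stats::p.adjust(df$p, method = "BH")
    df <- df[order(df$q, -df$gene_ratio, df$set_id), , drop = FALSE]
    out[[cl]] <- df
  }
  .assert(length(out) > 0, "no DEG class had enough mapped genes")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("enrichment_results", "data.frame")
  res
}
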