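# Differential-expression module: per-stratum Poisson-GLM tests of TG vs
# WT with a library-size offset, Bonferroni adjustment, classification of
# genes into sex-neutral / sex-specific / sex-dimorphic patterns,
# percent-expressing statistics and cross-dataset DEG comparison.

GENDER_CLASSES <- c("neutral", "male_specific", "female_specific",
                    "dimorphic", "unclassified")

#' Poisson GLM likelihood-ratio test for one gene
#'
#' Fits `log mu = b0 + b1 * 1[TG] + log(exposure)` by iteratively
#' reweighted least squares and tests `b1 = 0` with a likelihood-ratio test
#' against chi-square with 1 df. `logFC` is the coefficient `b1` (natural
#' log). Genes with zero total count in both groups return `logFC = 0`,
#' `p = 1`. Complete separation (one group all zero) yields a finite
#' deviance and p value.
#'
#' @param counts_g Nonnegative integer counts, one per cell.
#' @param group Character/factor with values `"TG"`/`"WT"`.
#' @param exposure Positive per-cell exposures (total counts).
#' @return A list (`logFC`, `p`, `stat`).
#' @export
poisson_glm_test <- function(counts_g, group, exposure) {
  .assert(all(counts_g >= 0), "negative counts are not allowed")
  group <- as.character(group)
  .assert(all(group %in% c("TG", "WT")), "group must be TG/WT")
  .assert(any(group == "TG") && any(group == "WT"),
          "both groups must be nonempty")
  .assert(length(counts_g) == length(group) &&
            length(exposure) == length(group),
          "counts, group and exposure lengths differ")
  .assert(all(exposure > 0), "exposures must be positive")
  if (sum(counts_g) == 0) return(list(logFC = 0, p = 1, stat = 0))
  x <- cbind(`(Intercept)` = 1, TG = as.numeric(group == "TG"))
  ctrl <- list(epsilon = 1e-12, maxit = 100)
  fit <- suppressWarnings(stats::glm.fit(
    x, counts_g, offset = log(exposure), family = stats::poisson(),
    control = ctrl))
  # null model must keep the offset (glm.fit's null.deviance drops it)
  fit0 <- suppressWarnings(stats::glm.fit(
    x[, 1L, drop = FALSE], counts_g, offset = log(exposure),
    family = stats::poisson(), control = ctrl))
  stat <- max(fit0$deviance - fit$deviance, 0)
  list(logFC = unname(fit$coefficients["TG"]),
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       stat = stat)
}

#' Bonferroni adjustment
#'
#' `q = min(1, p * n_tests)`; the family size is the number of genes
#' tested within the stratum.
#'
#' @param p_values Numeric p values in `[0, 1]`.
#' @param n_tests Family size; defaults to `length(p_values)`.
#' @return q values.
#' @export
bonferroni_adjust <- function(p_values, n_tests = length(p_values)) {
  .assert(all(p_values >= 0 & p_values <= 1, na.rm = TRUE),
          "p values must be in [0,1]")
  pmin(1, p_values * n_tests)
}

#' Percentage of cells expressing a gene per genotype
#'
#' @param counts_g Per-cell counts.
#' @param group `"TG"`/`"WT"` labels.
#' @return Named numeric `c(pct_tg, pct_wt)` (fractions of cells with
#'   count > 0).
#' @export
compute_pct_expressing <- function(counts_g, group) {
  group <- as.character(group)
  .assert(any(group == "TG") && any(group == "WT"),
          "both groups must be nonempty")
  c(pct_tg = mean(counts_g[group == "TG"] > 0),
    pct_wt = mean(counts_g[group == "WT"] > 0))
}

#' Sex-stratified differential expression
#'
#' Within every (cell type, sex) stratum -- and, when requested, the
#' cell-type-agnostic (`"ALL"`, sex) strata -- TG cells are compared
#' against WT cells of the same sex with [poisson_glm_test()], using
#' `log(total counts per cell)` as the offset. Genes detected in fewer
#' than `min_cells` cells of a stratum are skipped. q values are
#' Bonferroni-adjusted within the stratum. Strata missing a genotype are
#' skipped with a warning.
#'
#' @param counts Sparse genes x cells count matrix with dimnames.
#' @param metadata Data.frame with `barcode`, `genotype` (`TG`/`WT`) and
#'   `gender` (`M`/`F`).
#' @param cell_types Optional named vector barcode -> cell type (e.g. from
#'   clustering); defaults to `metadata$cell_type`.
#' @param include_all Add the (`"ALL"`, sex) strata.
#' @param min_cells Detection filter (default 3).
#' @return A data.frame of class `de_results` with columns `gene`,
#'   `cell_type`, `gender`, `logFC`, `p`, `q`, `pct_tg`, `pct_wt`.
#' @export
run_stratified_de <- function(counts, metadata, cell_types = NULL,
                              include_all = TRUE, min_cells = 3L) {
  .assert(!is.null(rownames(counts)) && !is.null(colnames(counts)),
          "counts must carry gene and cell names")
  .assert(all(metadata$barcode %in% colnames(counts)),
          "metadata barcodes absent from counts")
  if (is.null(cell_types)) {
    .assert(!is.null(metadata$cell_type),
            "cell_types not given and metadata has no cell_type column")
    cell_types <- setNames(metadata$cell_type, metadata$barcode)
  }
  types <- sort(unique(stats::na.omit(unname(cell_types[metadata$barcode]))))
  strata_types <- if (include_all) c(types, "ALL") else types

  exposure_all <- Matrix::colSums(counts)
  out <- list()
  for (ty in strata_types) {
    for (gd in c("M", "F")) {
      if (ty == "ALL") {
        bc <- metadata$barcode[metadata$gender == gd]
      } else {
        bc <- metadata$barcode[metadata$gender == gd &
                                 cell_types[metadata$barcode] == ty]
      }
      bc <- bc[!is.na(bc)]
      md <- metadata[match(bc, metadata$barcode), , drop = FALSE]
      if (!any(md$genotype == "TG") || !any(md$genotype == "WT")) {
        .warnf("stratum (%s, %s) lacks a genotype; skipped", ty, gd)
        next
      }
      sub <- counts[, bc, drop = FALSE]
      expo <- exposure_all[bc]
      detected <- Matrix::rowSums(sub > 0)
      genes <- rownames(sub)[detected >= min_cells]
      if (!length(genes)) next
      subT <- Matrix::t(sub)  # column access is fast on CsparseMatrix
      res <- lapply(genes, function(g) {
        y <- as.numeric(subT[, g])
        t0 <- poisson_glm_test(y, md$genotype, expo)
        pct <- compute_pct_expressing(y, md$genotype)
        c(logFC = t0$logFC, p = t0$p, pct)
      })
      m <- do.call(rbind, res)
      out[[length(out) + 1L]] <- data.frame(
        gene = genes, cell_type = ty, gender = gd,
        logFC = m[, "logFC"], p = m[, "p"],
        q = bonferroni_adjust(m[, "p"], length(genes)),
        pct_tg = m[, "pct_tg"], pct_wt = m[, "pct_wt"],
        stringsAsFactors = FALSE)
    }
  }
  .assert(length(out) > 0, "no stratum could be tested")
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  class(df) <- c("de_results", "data.frame")
  df
}

#' Classify one gene's sex pattern from its two per-sex results
#'
#' Rules (applied to Bonferroni q values): `neutral` when significant in
#' both sexes (q < `q_sig`) with a shared logFC sign; `dimorphic` when
#' significant in both with opposite signs; `male_specific` when
#' significant only in males with the female q above `q_null` (and
#' symmetrically `female_specific`); everything else `unclassified`. A
#' zero logFC with q < `q_sig` in both sexes has no sign and yields
#' `unclassified` with a warning.
#'
#' @param de_m,de_f Single-row data.frames (or lists) with `logFC` and `q`
#'   for the male and female stratum of the same gene and cell type.
#' @param q_sig Significance threshold (default 0.05).
#' @param q_null Null buffer threshold (default 0.5).
#' @return One of `neutral`, `male_specific`, `female_specific`,
#'   `dimorphic`, `unclassified`.
#' @export
classify_gender_pattern <- function(de_m, de_f, q_sig = 0.05, q_null = 0.5) {
  qm <- de_m$q; qf <- de_f$q; lm <- de_m$logFC; lf <- de_f$logFC
  if (qm < q_sig && qf < q_sig) {
    if (lm == 0 || lf == 0) {
      .warnf("zero logFC with q < %g in both sexes: sign undefined", q_sig)
      return("unclassified")
    }
    return(if (sign(lm) == sign(lf)) "neutral" else "dimorphic")
  }
  if (qm < q_sig && qf > q_null) return("male_specific")
  if (qf < q_sig && qm > q_null) return("female_specific")
  "unclassified"
}

#' Classify all genes from stratified DE results
#'
#' Joins the male and female rows per (gene, cell type) and applies
#' [classify_gender_pattern()]. Genes tested in only one sex are
#' `unclassified`.
#'
#' @param de A `de_results` data.frame from [run_stratified_de()].
#' @inheritParams classify_gender_pattern
#' @return A data.frame of class `gender_classes` with columns `gene`,
#'   `cell_type`, `label`, `logFC_m`, `logFC_f`, `q_m`, `q_f`.
#' @export
classify_gender_patterns <- function(de, q_sig = 0.05, q_null = 0.5) {
  m <- de[de$gender == "M", , drop = FALSE]
  f <- de[de$gender == "F", , drop = FALSE]
  merged <- merge(m, f, by = c("gene", "cell_type"),
                  suffixes = c("_m", "_f"), all = TRUE)
  label <- character(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    if (is.na(merged$q_m[i]) || is.na(merged$q_f[i])) {
      label[i] <- "unclassified"
    } else {
      label[i] <- classify_gender_pattern(
        list(q = merged$q_m[i], logFC = merged$logFC_m[i]),
        list(q = merged$q_f[i], logFC = merged$logFC_f[i]),
        q_sig, q_null)
    }
  }
  out <- data.frame(gene = merged$gene, cell_type = merged$cell_type,
                    label = label, logFC_m = merged$logFC_m,
                    logFC_f = merged$logFC_f, q_m = merged$q_m,
                    q_f = merged$q_f, stringsAsFactors = FALSE)
  out <- out[order(out$cell_type, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gender_classes", "data.frame")
  out
}

#' Compare two classified DEG sets across datasets
#'
#' For every (cell type, class label) the genes present in both sets are
#' flagged concordant (same logFC sign in the relevant sex) or discordant.
#' With `map_uppercase = TRUE` gene symbols are matched case-insensitively
#' via uppercase mapping (mouse-to-human convention).
#'
#' @param set_a,set_b `gender_classes` data.frames.
#' @param map_uppercase Map symbols to uppercase before joining.
#' @return A data.frame (`cell_type`, `label`, `gene`, `sign_a`, `sign_b`,
#'   `concordant`); empty when the sets are disjoint.
#' @export
compare_deg_sets <- function(set_a, set_b, map_uppercase = TRUE) {
  sig <- function(x) x[x$label != "unclassified", , drop = FALSE]
  a <- sig(set_a); b <- sig(set_b)
  keyify <- function(x) if (map_uppercase) toupper(x) else x
  a$key <- keyify(a$gene); b$key <- keyify(b$gene)
  mg <- merge(a, b, by = c("key", "cell_type", "label"),
              suffixes = c("_a", "_b"))
  main_sign <- function(label, lm, lf) {
    ifelse(label == "female_specific", sign(lf), sign(lm))
  }
  if (nrow(mg) == 0) {
    return(data.frame(cell_type = character(), label = character(),
                      gene = character(), sign_a = numeric(),
                      sign_b = numeric(), concordant = logical()))
  }
  sa <- main_sign(mg$label, mg$logFC_m_a, mg$logFC_f_a)
  sb <- main_sign(mg$label, mg$logFC_m_b, mg$logFC_f_b)
  out <- data.frame(cell_type = mg$cell_type, label = mg$label,
                    gene = mg$key, sign_a = sa, sign_b = sb,
                    concordant = sa == sb, stringsAsFactors = FALSE)
  out[order(out$cell_type, out$label, out$gene), , drop = FALSE]
}
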