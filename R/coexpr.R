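#' Pearson co-expression of circRNAs with their parental genes
#'
#' For each (circRNA, parent gene) pair, the Pearson correlation of the two
#' expression profiles across shared samples, with a two-sided p-value from
#' the t-distribution on `n - 2` degrees of freedom. A pair is `sig_pos`
#' when `r >= r_min` and `p < p_max`, `sig_neg` when `r <= -r_min` and
#' `p < p_max`, otherwise `ns`. Pairs where either profile has zero
#' variance get `r = NA` and are flagged.
#'
#' @param circ_expr Long tibble: `feature_id`, `sample`, `value` (e.g. RPM;
#'   an `rpm` column is accepted).
#' @param gene_expr Long tibble: `feature_id`, `sample`, `value` (e.g.
#'   FPKM; an `fpkm` column is accepted).
#' @param pairs Tibble: `circ_id`, `gene_id`.
#' @param r_min,p_max Significance thresholds.
#' @return Tibble: `circ_id`, `gene_id`, `n`, `r`, `p`, `class`,
#'   `zero_variance`.
#' @export
pair_correlation <- function(circ_expr, gene_expr, pairs,
                             r_min = 0.5, p_max = 0.05) {
  cm <- expr_matrix(circ_expr)
  gm <- expr_matrix(gene_expr)
  shared <- intersect(colnames(cm), colnames(gm))
  if (length(shared) < 3) {
    abort(sprintf("need >= 3 paired samples, have %d", length(shared)))
  }
  assert_columns(pairs, c("circ_id", "gene_id"), "pairs")
  bad <- !pairs$circ_id %in% rownames(cm) | !pairs$gene_id %in% rownames(gm)
  if (any(bad)) {
    abort(sprintf("pair references unknown feature(s): %s",
                  paste(pairs$circ_id[bad][1], pairs$gene_id[bad][1])))
  }
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    x <- cm[pairs$circ_id[i], shared]
    y <- gm[pairs$gene_id[i], shared]
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(circ_id = pairs$circ_id[i], gene_id = pairs$gene_id[i],
                    n = length(shared), r = NA_real_, p = NA_real_,
                    class = "ns", zero_variance = TRUE))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble(circ_id = pairs$circ_id[i], gene_id = pairs$gene_id[i],
           n = length(shared), r = unname(ct$estimate), p = ct$p.value,
           class = corr_class(unname(ct$estimate), ct$p.value, r_min, p_max),
           zero_variance = FALSE)
  })
}

corr_class <- function(r, p, r_min, p_max) {
  dplyr::case_when(
    !is.na(r) & r >= r_min & p < p_max ~ "sig_pos",
    !is.na(r) & r <= -r_min & p < p_max ~ "sig_neg",
    TRUE ~ "ns")
}

# long tibble (feature_id, sample, value-ish) -> features x samples matrix
expr_matrix <- function(x) {
  if (!"feature_id" %in% names(x)) {
    for (alt in c("circ_id", "gene_id")) {
      if (alt %in% names(x)) { x <- x %>% rename(feature_id = all_of(alt)); break }
    }
  }
  if (!"value" %in% names(x)) {
    for (alt in c("rpm", "fpkm", "count")) {
      if (alt %in% names(x)) { x <- x %>% rename(value = all_of(alt)); break }
    }
  }
  assert_columns(x, c("feature_id", "sample", "value"), "expression table")
  w <- x %>%
    select("feature_id", "sample", "value") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "value")
  m <- as.matrix(w[, -1])
  rownames(m) <- w$feature_id
  m
}

#' Correlate circRNAs with co-expression module eigengenes
#'
#' A module's eigengene is the first principal component of its gene-wise
#' standardized expression (first right singular vector over samples),
#' sign-oriented to correlate positively with the module's mean profile.
#' Each circRNA is then correlated with each eigengene; classification uses
#' the strict module thresholds (`r >= 0.9` by default). Module membership
#' is an input (from any module-detection tool); only the module-circRNA
#' correlation is computed here.
#'
#' @param circ_expr Long tibble: `feature_id`, `sample`, `value`.
#' @param gene_expr Long tibble: `feature_id`, `sample`, `value`.
#' @param modules Tibble: `gene_id`, `module`.
#' @param r_min,p_max Significance thresholds.
#' @return List with `eigengenes` (long tibble: `module`, `sample`,
#'   `value`), `correlations` (tibble like [pair_correlation()] with
#'   `module` instead of `gene_id`) and `var_explained` (tibble: `module`,
#'   `prop_var`).
#' @export
module_correlation <- function(circ_expr, gene_expr, modules,
                               r_min = 0.9, p_max = 0.05) {
  assert_columns(modules, c("gene_id", "module"), "modules")
  gm <- expr_matrix(gene_expr)
  cm <- expr_matrix(circ_expr)
  shared <- intersect(colnames(gm), colnames(cm))
  if (length(shared) < 3) {
    abort(sprintf("need >= 3 shared samples, have %d", length(shared)))
  }
  eig <- list(); varex <- list()
  for (mod in sort(unique(modules$module))) {
    gids <- intersect(modules$gene_id[modules$module == mod], rownames(gm))
    if (length(gids) < 2) {
      warn(sprintf("module %s has < 2 genes with expression; skipped", mod))
      next
    }
    x <- gm[gids, shared, drop = FALSE]
    sds <- apply(x, 1, sd)
    if (all(sds == 0)) {
      warn(sprintf("module %s has constant expression; skipped", mod))
      next
    }
    x <- x[sds > 0, , drop = FALSE]
    xs <- t(scale(t(x)))
    sv <- svd(xs)
    e <- sv$v[, 1]
    if (cor(e, colMeans(xs)) < 0) e <- -e
    eig[[mod]] <- tibble(module = mod, sample = shared, value = e)
    varex[[mod]] <- tibble(module = mod,
                           prop_var = sv$d[1]^2 / sum(sv$d^2))
  }
  if (length(eig) == 0) {
    return(list(eigengenes = tibble(), correlations = tibble(),
                var_explained = tibble()))
  }
  eigengenes <- bind_rows(eig)
  correlations <- purrr::map_dfr(names(eig), function(mod) {
    e <- eig[[mod]]$value
    purrr::map_dfr(rownames(cm), function(cid) {
      x <- cm[cid, shared]
      if (sd(x) == 0) {
        return(tibble(circ_id = cid, module = mod, n = length(shared),
                      r = NA_real_, p = NA_real_, class = "ns",
                      zero_variance = TRUE))
      }
      ct <- cor.test(x, e, method = "pearson")
      tibble(circ_id = cid, module = mod, n = length(shared),
             r = unname(ct$estimate), p = ct$p.value,
             class = corr_class(unname(ct$estimate), ct$p.value, r_min,
                                p_max),
             zero_variance = FALSE)
    })
  })
  list(eigengenes = eigengenes, correlations = correlations,
       var_explained = bind_rows(varex))
}

#' Hypergeometric term enrichment with a minimum gene-count gate
#'
#' For each term, the upper-tail hypergeometric probability
#' `P(X >= k)` of drawing `k` term genes in a query of size `n` from a
#' background of size `N` containing `K` term genes; q-values by
#' Benjamini-Hochberg across the tested terms. A term is significant iff
#' `q < q_max` *and* the query contains at least `min_count` of its genes.
#'
#' @param query_genes Character vector (must be a subset of the
#'   background).
#' @param background_genes Character vector, the enrichment universe.
#' @param term_map Tibble: `term`, `gene` (genes outside the background are
#'   ignored).
#' @param q_max,min_count Significance gates.
#' @return Tibble: `term`, `genes_in_query`, `genes_in_term`, `background`,
#'   `fold_enrichment`, `p`, `q`, `significant`.
#' @export
hypergeom_enrichment <- function(query_genes, background_genes, term_map,
                                 q_max = 0.05, min_count = 3) {
  background_genes <- unique(background_genes)
  if (length(background_genes) == 0) {
    abort("configuration error: empty background")
  }
  query_genes <- unique(query_genes)
  outside <- setdiff(query_genes, background_genes)
  if (length(outside) > 0) {
    abort(sprintf("query gene(s) not in background: %s",
                  paste(utils::head(outside, 3), collapse = ", ")))
  }
  assert_columns(term_map, c("term", "gene"), "term_map")
  N <- length(background_genes)
  nq <- length(query_genes)
  res <- term_map %>%
    filter(.data$gene %in% background_genes) %>%
    distinct(.data$term, .data$gene) %>%
    group_by(.data$term) %>%
    summarise(genes_in_term = n(),
              genes_in_query = sum(.data$gene %in% query_genes),
              .groups = "drop") %>%
    mutate(
      background = N,
      fold_enrichment = (.data$genes_in_query / nq) /
        (.data$genes_in_term / N),
      p = phyper(.data$genes_in_query - 1, .data$genes_in_term,
                 N - .data$genes_in_term, nq, lower.tail = FALSE),
      q = p.adjust(.data$p, method = "BH"),
      significant = .data$q < q_max & .data$genes_in_query >= min_count
    ) %>%
    arrange(.data$p) %>%
    select("term", "genes_in_query", "genes_in_term", "background",
           "fold_enrichment", "p", "q", "significant")
  res
}
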