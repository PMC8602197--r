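#' Junction reads per million (RPM)
#'
#' `RPM = junction_reads / total_reads * 1e6`, the expression unit for
#' circRNAs: junction reads are the only reads that unambiguously belong to
#' the circle.
#'
#' @param counts Long tibble: `feature_id` (or `circ_id`), `sample`,
#'   `count`.
#' @param library_sizes Tibble: `sample`, `total_reads` (> 0).
#' @return The input with an `rpm` column.
#' @export
compute_rpm <- function(counts, library_sizes) {
  counts <- normalize_counts(counts)
  assert_columns(library_sizes, c("sample", "total_reads"), "library_sizes")
  if (any(is.na(library_sizes$total_reads) | library_sizes$total_reads <= 0)) {
    abort("configuration error: library sizes must be > 0")
  }
  missing <- setdiff(unique(counts$sample), library_sizes$sample)
  if (length(missing) > 0) {
    abort(sprintf("no library size for sample(s): %s",
                  paste(missing, collapse = ", ")))
  }
  counts %>%
    left_join(library_sizes, by = "sample") %>%
    mutate(rpm = .data$count / .data$total_reads * 1e6) %>%
    select(-"total_reads")
}

normalize_counts <- function(counts) {
  if (!"feature_id" %in% names(counts) && "circ_id" %in% names(counts)) {
    counts <- counts %>% rename(feature_id = "circ_id")
  }
  if (!"count" %in% names(counts) && "n_reads" %in% names(counts)) {
    counts <- counts %>% rename(count = "n_reads")
  }
  if (!"count" %in% names(counts) && "n_junction_reads" %in% names(counts)) {
    counts <- counts %>% rename(count = "n_junction_reads")
  }
  assert_columns(counts, c("feature_id", "sample", "count"), "counts")
  counts
}

#' Fragments per kilobase of exon per million mapped fragments (FPKM)
#'
#' `FPKM = count / (exonic_kb * mapped_millions)`, with the exonic length of
#' a gene taken as the merged span of its annotated exons. The linear-gene
#' expression unit used alongside circRNA RPM.
#'
#' @param counts Long tibble: `gene_id` (or `feature_id`), `sample`,
#'   `count` of exonic fragments.
#' @param genome A `genome_model` supplying exon structures.
#' @param library_sizes Tibble: `sample`, `total_reads` = mapped fragments.
#' @return The input with an `fpkm` column.
#' @export
compute_fpkm <- function(counts, genome, library_sizes) {
  if (!"feature_id" %in% names(counts) && "gene_id" %in% names(counts)) {
    counts <- counts %>% rename(feature_id = "gene_id")
  }
  counts <- normalize_counts(counts)
  assert_columns(library_sizes, c("sample", "total_reads"), "library_sizes")
  exlen <- genome$exons %>%
    group_by(.data$gene_id) %>%
    summarise(exonic_len = sum(
      IRanges::width(IRanges::reduce(IRanges::IRanges(.data$start, .data$end)))),
      .groups = "drop")
  missing <- setdiff(unique(counts$feature_id), exlen$gene_id)
  if (length(missing) > 0) {
    abort(sprintf("lookup error: gene(s) absent from models: %s",
                  paste(missing, collapse = ", ")))
  }
  counts %>%
    left_join(exlen, by = c(feature_id = "gene_id")) %>%
    left_join(library_sizes, by = "sample") %>%
    mutate(fpkm = .data$count /
             ((.data$exonic_len / 1e3) * (.data$total_reads / 1e6))) %>%
    select(-"exonic_len", -"total_reads")
}

#' Tissue-pair differential expression of circRNAs
#'
#' Fold changes are computed from the replicate-mean RPM of each tissue
#' (`log2fc = log2((mean_A + pseudo) / (mean_B + pseudo))`). P-values come
#' from a two-sided conditional binomial test on the pooled junction reads:
#' conditional on the pooled total `n = x_A + x_B`, under the null
#' `x_A ~ Binomial(n, pi0)` with `pi0` the tissue-A share of the pooled
#' library size; the two-sided p-value is twice the smaller tail, capped at
#' 1. Q-values are Benjamini-Hochberg over all features of the pair. A
#' feature is `up`/`down` iff `|log2fc| >= lfc_min` *and* `q <= q_max`.
#'
#' @param counts Long tibble: `feature_id`, `sample`, `count`.
#' @param library_sizes Tibble: `sample`, `total_reads`.
#' @param design Tibble: `sample`, `tissue`.
#' @param pair Length-2 character `(A, B)`; fold change is A over B.
#' @param lfc_min Absolute log2 fold-change threshold.
#' @param q_max Q-value threshold.
#' @param pseudo Pseudocount in RPM units, guarding zero-count features.
#' @return A `circ_de` tibble: `feature_id`, `tissue_a`, `tissue_b`,
#'   `mean_rpm_a`, `mean_rpm_b`, `log2fc`, `p`, `q`, `status`.
#' @export
differential_expression <- function(counts, library_sizes, design, pair,
                                    lfc_min = 1, q_max = 0.05,
                                    pseudo = 0.01) {
  counts <- normalize_counts(counts)
  assert_columns(design, c("sample", "tissue"), "design")
  stopifnot(length(pair) == 2)
  if (!all(pair %in% design$tissue)) {
    abort(sprintf("pair tissues not in design: %s",
                  paste(setdiff(pair, design$tissue), collapse = ", ")))
  }
  smp_a <- design$sample[design$tissue == pair[1]]
  smp_b <- design$sample[design$tissue == pair[2]]
  if (length(smp_a) < 1 || length(smp_b) < 1) {
    abort("each tissue of the pair needs at least one sample")
  }
  lib <- setNames(library_sizes$total_reads, library_sizes$sample)
  features <- sort(unique(counts$feature_id))
  full <- tidyr::expand_grid(feature_id = features,
                             sample = c(smp_a, smp_b)) %>%
    left_join(counts %>% select("feature_id", "sample", "count"),
              by = c("feature_id", "sample")) %>%
    mutate(count = tidyr::replace_na(.data$count, 0),
           rpm = .data$count / lib[.data$sample] * 1e6,
           side = ifelse(.data$sample %in% smp_a, "a", "b"))
  stats_tbl <- full %>%
    group_by(.data$feature_id, .data$side) %>%
    summarise(mean_rpm = mean(.data$rpm), x = sum(.data$count),
              .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "side",
                       values_from = c("mean_rpm", "x"))
  pi0 <- sum(lib[smp_a]) / (sum(lib[smp_a]) + sum(lib[smp_b]))
  n_pool <- stats_tbl$x_a + stats_tbl$x_b
  p <- ifelse(
    n_pool == 0, 1,
    pmin(1, 2 * pmin(pbinom(stats_tbl$x_a, n_pool, pi0),
                     pbinom(stats_tbl$x_a - 1, n_pool, pi0,
                            lower.tail = FALSE))))
  res <- tibble(
    feature_id = stats_tbl$feature_id,
    tissue_a = pair[1], tissue_b = pair[2],
    mean_rpm_a = stats_tbl$mean_rpm_a,
    mean_rpm_b = stats_tbl$mean_rpm_b,
    log2fc = log2((stats_tbl$mean_rpm_a + pseudo) /
                    (stats_tbl$mean_rpm_b + pseudo)),
    p = p,
    q = p.adjust(p, method = "BH")
  ) %>%
    mutate(status = dplyr::case_when(
      abs(.data$log2fc) >= lfc_min & .data$q <= q_max & .data$log2fc > 0 ~ "up",
      abs(.data$log2fc) >= lfc_min & .data$q <= q_max & .data$log2fc < 0 ~ "down",
      TRUE ~ "ns"))
  class(res) <- c("circ_de", class(res))
  attr(res, "pair") <- pair
  attr(res, "thresholds") <- c(lfc_min = lfc_min, q_max = q_max,
                               pseudo = pseudo)
  res
}

#' Z-score profile clustering of circRNA expression
#'
#' Per-feature Z-scores of tissue-mean RPM are clustered hierarchically
#' (Euclidean distance, average linkage) in both directions; the feature
#' tree is cut into `k` clusters labelled with Roman numerals. Features
#' with zero variance across tissue means carry no profile shape and are
#' dropped with a warning.
#'
#' @param rpm Long tibble: `feature_id`, `sample`, `rpm` (or `value`).
#' @param design Tibble: `sample`, `tissue` (profiles are tissue means).
#' @param k Number of feature clusters.
#' @return A `circ_cluster` object: `z` (matrix features x tissues),
#'   `assignments` (tibble: `feature_id`, `cluster`), `feature_hclust`,
#'   `profile_hclust`, `k`, `dropped`.
#' @export
zscore_cluster <- function(rpm, design, k = 5) {
  if (!"rpm" %in% names(rpm) && "value" %in% names(rpm)) {
    rpm <- rpm %>% rename(rpm = "value")
  }
  if (!"feature_id" %in% names(rpm) && "circ_id" %in% names(rpm)) {
    rpm <- rpm %>% rename(feature_id = "circ_id")
  }
  assert_columns(rpm, c("feature_id", "sample", "rpm"), "rpm")
  assert_columns(design, c("sample", "tissue"), "design")
  prof <- rpm %>%
    left_join(design, by = "sample") %>%
    group_by(.data$feature_id, .data$tissue) %>%
    summarise(mean_rpm = mean(.data$rpm), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "tissue", values_from = "mean_rpm")
  m <- as.matrix(prof[, -1])
  rownames(m) <- prof$feature_id
  constant <- apply(m, 1, function(r) sd(r) == 0 || !all(is.finite(r)))
  dropped <- rownames(m)[constant]
  if (any(constant)) {
    warn(sprintf("dropping %d feature(s) with constant profiles",
                 sum(constant)))
  }
  m <- m[!constant, , drop = FALSE]
  if (k > nrow(m)) {
    abort(sprintf("configuration error: k = %d exceeds %d usable features",
                  k, nrow(m)))
  }
  z <- t(apply(m, 1, function(r) (r - mean(r)) / sd(r)))
  colnames(z) <- colnames(m)
  fh <- hclust(dist(z, method = "euclidean"), method = "average")
  ph <- if (ncol(z) >= 2) {
    hclust(dist(t(z), method = "euclidean"), method = "average")
  } else NULL
  cl <- cutree(fh, k = k)
  # stable labels: order clusters by first appearance in the dendrogram
  ord <- unique(cl[fh$order])
  lab <- setNames(as.character(utils::as.roman(seq_len(k))), ord)
  assignments <- tibble(feature_id = rownames(z),
                        cluster = unname(lab[as.character(cl)]))
  structure(list(z = z, assignments = assignments, feature_hclust = fh,
                 profile_hclust = ph, k = k, dropped = dropped),
            class = "circ_cluster")
}

#' @export
print.circ_cluster <- function(x, ...) {
  cat(sprintf("<circ_cluster> %d feature(s) in %d cluster(s) over %d profile column(s)\n",
              nrow(x$z), x$k, ncol(x$z)))
  invisible(x)
}
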