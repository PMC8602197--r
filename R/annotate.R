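#' Classify back-splice junctions as exonic, intronic or intergenic
#'
#' A junction is *exonic* when both of its ends overlap exons of a single
#' gene (the parent gene); circles whose span additionally covers introns
#' still count as exonic, so the catalog keeps three classes. A junction
#' that is not exonic but lies entirely within a single gene is *intronic*;
#' anything else is *intergenic*. For exonic circles the number of parent
#' exons overlapping the span and the position category of those exons in
#' transcript orientation (`first` = 5'-most exon only, `last`, `middle`,
#' `first_and_last`) are reported. When the two ends overlap exons of two
#' different genes and no single gene covers both, the junction falls back
#' to intergenic with a warning.
#'
#' @param junctions Tibble with `scaffold`, `start`, `end` (one row per
#'   junction; `start < end`).
#' @param genome A `genome_model`.
#' @param slop Boundary tolerance (nt): an end within `slop` of an exon
#'   still counts as overlapping it. Default 0 (exact).
#' @return The input joined with `circ_id`, `circ_class`, `parent_gene`,
#'   `spanned_exons`, `position_category` and `strand` (inherited from the
#'   parent gene, `"."` for intergenic circles).
#' @examples
#' g <- simulate_genome(1, 50000, 5, c(3, 5), seed = 2)
#' j <- tibble::tibble(scaffold = "scf1", start = 10L, end = 50L)
#' classify_junctions(j, g)$circ_class
#' @export
classify_junctions <- function(junctions, genome, slop = 0) {
  assert_columns(junctions, c("scaffold", "start", "end"), "junctions")
  if (any(junctions$start >= junctions$end)) {
    abort("malformed junction: start must be < end")
  }
  bad <- !junctions$scaffold %in% names(genome$seqs)
  if (any(bad)) {
    abort(sprintf("malformed junction: unknown scaffold %s",
                  junctions$scaffold[which(bad)[1]]))
  }
  n <- nrow(junctions)
  ex <- genome$exons
  gn <- genome$genes
  out <- tibble(circ_class = character(n), parent_gene = NA_character_,
                spanned_exons = NA_integer_,
                position_category = NA_character_, strand = ".")
  if (n > 0 && nrow(ex) > 0) {
    ex_gr <- GenomicRanges::GRanges(
      ex$scaffold, IRanges::IRanges(ex$start - slop, ex$end + slop))
    gn_gr <- GenomicRanges::GRanges(
      gn$scaffold, IRanges::IRanges(gn$start, gn$end))
    s_pts <- GenomicRanges::GRanges(
      junctions$scaffold, IRanges::IRanges(junctions$start, junctions$start))
    e_pts <- GenomicRanges::GRanges(
      junctions$scaffold, IRanges::IRanges(junctions$end, junctions$end))
    spans <- GenomicRanges::GRanges(
      junctions$scaffold, IRanges::IRanges(junctions$start, junctions$end))
    hit_genes <- function(pts) {
      fo <- GenomicRanges::findOverlaps(pts, ex_gr)
      split(ex$gene_id[S4Vectors::subjectHits(fo)],
            factor(S4Vectors::queryHits(fo), levels = seq_len(n)))
    }
    gs <- hit_genes(s_pts)
    ge <- hit_genes(e_pts)
    fo_w <- GenomicRanges::findOverlaps(spans, gn_gr, type = "within")
    gw <- split(gn$gene_id[S4Vectors::subjectHits(fo_w)],
                factor(S4Vectors::queryHits(fo_w), levels = seq_len(n)))
    for (i in seq_len(n)) {
      both <- sort(intersect(gs[[i]], ge[[i]]))
      if (length(both) >= 1) {
        if (length(both) > 1) {
          warn(sprintf("junction %s-%d-%d matches exons of %d genes; using %s",
                       junctions$scaffold[i], junctions$start[i],
                       junctions$end[i], length(both), both[1]))
        }
        gid <- both[1]
        gx <- ex[ex$gene_id == gid, , drop = FALSE]
        inc <- which(gx$end >= junctions$start[i] &
                       gx$start <= junctions$end[i])
        n_ex <- nrow(gx)
        plus <- gx$strand[1] == "+"
        first_ex <- if (plus) 1L else n_ex
        last_ex <- if (plus) n_ex else 1L
        hf <- first_ex %in% inc; hl <- last_ex %in% inc
        out$circ_class[i] <- "exonic"
        out$parent_gene[i] <- gid
        out$spanned_exons[i] <- length(inc)
        out$position_category[i] <-
          if (hf && hl) "first_and_last" else if (hf) "first" else
            if (hl) "last" else "middle"
        out$strand[i] <- gx$strand[1]
      } else {
        if (length(gs[[i]]) > 0 && length(ge[[i]]) > 0) {
          warn(sprintf(
            "junction %s-%d-%d ends overlap exons of different genes; intergenic",
            junctions$scaffold[i], junctions$start[i], junctions$end[i]))
        }
        within_g <- sort(gw[[i]])
        if (length(within_g) >= 1) {
          out$circ_class[i] <- "intronic"
          out$parent_gene[i] <- within_g[1]
          out$strand[i] <- gn$strand[match(within_g[1], gn$gene_id)]
        } else {
          out$circ_class[i] <- "intergenic"
        }
      }
    }
  } else if (n > 0) {
    out$circ_class <- "intergenic"
  }
  junctions %>%
    select(-dplyr::any_of(c("circ_id", "circ_class", "parent_gene",
                            "spanned_exons", "position_category",
                            "strand"))) %>%
    mutate(circ_id = circ_id(.data$scaffold, .data$start, .data$end),
           .before = 1) %>%
    bind_cols(out)
}

#' Alternative circularization: circRNAs per parent gene
#'
#' Groups exonic circRNAs by parent gene and tabulates how many genes
#' produce k = 1, 2, 3, ... distinct circles, the standard summary of
#' alternative back-splice usage.
#'
#' @param annotations Tibble from [classify_junctions()] (only exonic rows
#'   with a parent gene are used).
#' @return List with `groups` (tibble: `parent_gene`, `n_circ`, `circ_ids`
#'   list-column) and `histogram` (tibble: `n_circ`, `n_genes`).
#' @export
alternative_circularization <- function(annotations) {
  exonic <- annotations %>%
    filter(.data$circ_class == "exonic", !is.na(.data$parent_gene)) %>%
    distinct(.data$circ_id, .keep_all = TRUE)
  groups <- exonic %>%
    group_by(.data$parent_gene) %>%
    summarise(n_circ = n(), circ_ids = list(sort(.data$circ_id)),
              .groups = "drop") %>%
    arrange(dplyr::desc(.data$n_circ), .data$parent_gene)
  histogram <- groups %>%
    count(.data$n_circ, name = "n_genes") %>%
    arrange(.data$n_circ)
  list(groups = groups, histogram = histogram)
}

#' Circular sequences for an annotated junction table
#'
#' Vectorized wrapper around [circ_sequence()].
#'
#' @param genome A `genome_model`.
#' @param annotations Tibble with `scaffold`, `start`, `end`, `circ_class`,
#'   `parent_gene` (from [classify_junctions()]).
#' @return Named character vector of sequences, names = `circ_id`.
#' @export
circ_sequences <- function(genome, annotations) {
  setNames(
    vapply(seq_len(nrow(annotations)), function(i) {
      .circ_seq(genome, annotations$scaffold[i], annotations$start[i],
                annotations$end[i], annotations$circ_class[i],
                annotations$parent_gene[i])
    }, character(1)),
    circ_id(annotations$scaffold, annotations$start, annotations$end))
}
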