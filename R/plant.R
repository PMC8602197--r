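#' Plant exonic, intronic and intergenic circRNAs in a simulated genome
#'
#' Chooses back-splice junctions of the three classes seen in plant
#' circRNA-seq studies: exonic circles spanning 1--5 consecutive exons of one
#' gene (junction ends on exon boundaries), intronic circles lying strictly
#' within one intron, and intergenic circles overlapping no gene. Each circle
#' gets a base abundance (copies per library before tissue scaling) drawn
#' log-normally.
#'
#' Back-splice coordinates are only recoverable exactly from split reads when
#' the junction is not shifted by microhomology (the base after `end`
#' coinciding with the base at `start`, or the base before `start` with the
#' base at `end`). The generator therefore adjusts at most two bases
#' immediately *outside* each planted circle (never inside an exon) so every
#' planted junction has a unique genomic representation, and returns the
#' adjusted genome.
#'
#' @param genome A `genome_model`.
#' @param n_exonic,n_intronic,n_intergenic Requested counts per class.
#' @param seed Integer seed.
#' @param min_len Minimum circle (spliced) length in nt. Keep this at or
#'   above the simulated read length so junction reads never wrap the circle
#'   more than once.
#' @param max_exons Maximum exons spanned by an exonic circle.
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters for the
#'   per-circle base abundance.
#' @return List with `truth` (tibble: `circ_id`, `scaffold`, `start`, `end`,
#'   `strand`, `true_class`, `host_gene`, `spliced`, `base_abundance`) and
#'   `genome` (the input genome with junction-disambiguating base
#'   adjustments).
#' @examples
#' g <- simulate_genome(1, 50000, 10, c(3, 8), seed = 1)
#' p <- plant_circrnas(g, 5, 2, 2, seed = 3)
#' table(p$truth$true_class)
#' @export
plant_circrnas <- function(genome, n_exonic, n_intronic, n_intergenic,
                           seed = 1, min_len = 150, max_exons = 5,
                           abundance_meanlog = log(8),
                           abundance_sdlog = 0.4) {
  stopifnot(n_exonic >= 0, n_intronic >= 0, n_intergenic >= 0)
  withr::with_seed(seed, {
    pools <- list(
      exonic = exonic_pool(genome, min_len, max_exons),
      intronic = intronic_pool(genome, min_len),
      intergenic = intergenic_pool(genome, min_len)
    )
    wanted <- c(exonic = n_exonic, intronic = n_intronic,
                intergenic = n_intergenic)
    # greedy acceptance under the junction-disambiguation constraints:
    # each circle forbids one base value just before its start and one just
    # after its end; at most 3 distinct values may be forbidden per position
    forb <- list()
    seen <- character(0)
    accepted <- list()
    for (cls in names(wanted)) {
      if (wanted[[cls]] == 0) next
      pool <- pools[[cls]]
      if (nrow(pool) > 0) pool <- pool[sample.int(nrow(pool)), ]
      got <- 0L
      for (i in seq_len(nrow(pool))) {
        if (got == wanted[[cls]]) break
        cid <- circ_id(pool$scaffold[i], pool$start[i], pool$end[i])
        if (cid %in% seen) next
        upd <- constraint_update(forb, genome, pool$scaffold[i],
                                 pool$start[i], pool$end[i])
        if (is.null(upd)) next
        forb <- upd
        seen <- c(seen, cid)
        got <- got + 1L
        accepted[[length(accepted) + 1L]] <- pool[i, ]
      }
      if (got < wanted[[cls]]) {
        abort(sprintf(
          "capacity error: could place only %d of %d %s circRNAs (%d candidates)",
          got, wanted[[cls]], cls, nrow(pool)))
      }
    }
    truth <- bind_rows(accepted) %>%
      mutate(circ_id = circ_id(.data$scaffold, .data$start, .data$end),
             spliced = .data$true_class == "exonic",
             base_abundance = rlnorm(n(), abundance_meanlog,
                                     abundance_sdlog)) %>%
      select("circ_id", "scaffold", "start", "end", "strand", "true_class",
             "host_gene", "spliced", "base_abundance")
    genome <- disambiguate_junctions(genome, truth)
    list(truth = truth, genome = genome)
  })
}

# candidate pools, one row per legal placement -------------------------------

exonic_pool <- function(genome, min_len, max_exons) {
  cand <- list()
  for (gid in genome$genes$gene_id) {
    ex <- gene_exons(genome, gid)
    ne <- nrow(ex)
    for (i in seq_len(ne)) {
      for (j in i:min(ne, i + max_exons - 1)) {
        splen <- sum(ex$end[i:j] - ex$start[i:j] + 1)
        if (splen >= min_len) {
          cand[[length(cand) + 1]] <- tibble(
            scaffold = ex$scaffold[1], start = ex$start[i], end = ex$end[j],
            strand = ex$strand[1], true_class = "exonic", host_gene = gid)
        }
      }
    }
  }
  if (length(cand)) bind_rows(cand) else empty_pool()
}

intronic_pool <- function(genome, min_len, margin = 5L) {
  if (nrow(genome$exons) == 0) return(empty_pool())
  introns <- genome$exons %>%
    group_by(.data$gene_id, .data$scaffold) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(istart = list(.data$end[-n()] + 1L),
              iend = list(.data$start[-1] - 1L), .groups = "drop") %>%
    tidyr::unnest(c("istart", "iend")) %>%
    mutate(ilen = .data$iend - .data$istart + 1L) %>%
    filter(.data$ilen >= min_len + 2L * margin)
  if (nrow(introns) == 0) return(empty_pool())
  len <- vapply(introns$ilen, function(L) {
    sample_vec(seq(min_len, min(400L, L - 2L * margin)), 1)
  }, numeric(1))
  off <- vapply(introns$ilen - 2L * margin - len, function(r) {
    if (r > 0) sample.int(r + 1L, 1) - 1L else 0L
  }, numeric(1))
  tibble(scaffold = introns$scaffold,
         start = as.integer(introns$istart + margin + off),
         end = as.integer(introns$istart + margin + off + len - 1),
         strand = ".", true_class = "intronic",
         host_gene = introns$gene_id)
}

intergenic_pool <- function(genome, min_len, margin = 50L) {
  gaps <- lapply(names(genome$seqs), function(s) {
    gs <- genome$genes %>% filter(.data$scaffold == s) %>%
      arrange(.data$start)
    bounds <- c(0L, gs$end, nchar(genome$seqs[[s]]) + 1L)
    starts <- utils::head(bounds, -1) + 1L
    ends <- c(gs$start, nchar(genome$seqs[[s]]) + 1L) - 1L
    tibble(scaffold = s, gstart = starts, gend = ends)
  }) %>% bind_rows() %>%
    mutate(glen = .data$gend - .data$gstart + 1L) %>%
    filter(.data$glen >= min_len + 2L * margin)
  if (nrow(gaps) == 0) return(empty_pool())
  len <- vapply(gaps$glen, function(L) {
    sample_vec(seq(min_len, min(400L, L - 2L * margin)), 1)
  }, numeric(1))
  off <- vapply(gaps$glen - 2L * margin - len, function(r) {
    if (r > 0) sample.int(r + 1L, 1) - 1L else 0L
  }, numeric(1))
  tibble(scaffold = gaps$scaffold,
         start = as.integer(gaps$gstart + margin + off),
         end = as.integer(gaps$gstart + margin + off + len - 1),
         strand = ".", true_class = "intergenic",
         host_gene = NA_character_)
}

empty_pool <- function() {
  tibble(scaffold = character(), start = integer(), end = integer(),
         strand = character(), true_class = character(),
         host_gene = character())
}

#' @noRd
#' Try to add a circle's two disambiguation constraints to `forb`
#' (position key -> forbidden base values). Returns the updated list, or
#' NULL when a position would have all four bases forbidden.
constraint_update <- function(forb, genome, scaffold, start, end) {
  slen <- nchar(genome$seqs[[scaffold]])
  pairs <- list(c(start - 1L, end), c(end + 1L, start))
  for (pr in pairs) {
    if (pr[1] < 1L || pr[1] > slen) next
    key <- paste0(scaffold, ":", pr[1])
    fb <- substr(genome$seqs[[scaffold]], pr[2], pr[2])
    newset <- union(forb[[key]], fb)
    if (length(newset) > 3L) return(NULL)
    forb[[key]] <- newset
  }
  forb
}

#' @noRd
#' Ensure base(start-1) != base(end) and base(end+1) != base(start) for every
#' planted junction, editing only positions outside the circles. Constraints
#' at a shared position are satisfied jointly.
disambiguate_junctions <- function(genome, truth) {
  if (nrow(truth) == 0) return(genome)
  cons <- bind_rows(
    tibble(scaffold = truth$scaffold, pos = truth$start - 1L,
           forbid_pos = truth$end),
    tibble(scaffold = truth$scaffold, pos = truth$end + 1L,
           forbid_pos = truth$start)
  )
  cons <- cons %>%
    filter(.data$pos >= 1L,
           .data$pos <= nchar(genome$seqs[.data$scaffold]))
  for (s in unique(cons$scaffold)) {
    cs <- cons[cons$scaffold == s, ]
    for (p in unique(cs$pos)) {
      forbidden <- unique(substring(genome$seqs[[s]],
                                    cs$forbid_pos[cs$pos == p],
                                    cs$forbid_pos[cs$pos == p]))
      cur <- substr(genome$seqs[[s]], p, p)
      if (cur %in% forbidden) {
        repl <- setdiff(DNA_BASES, forbidden)
        if (length(repl) == 0) {
          abort("cannot disambiguate junction bases; forbidden set exhausted")
        }
        substr(genome$seqs[[s]], p, p) <- repl[1]
      }
    }
  }
  genome
}

#' Circular sequence of a back-splice junction
#'
#' Returns the circle linearized at the back-splice, starting at `start`.
#' Exonic circles are spliced: the parent gene's exon sub-intervals
#' overlapping `[start, end]` are clipped to the span and concatenated in
#' genomic order, then reverse-complemented for minus-strand genes. Intronic
#' and intergenic circles are the genomic substring `[start, end]`.
#'
#' @param genome A `genome_model`.
#' @param junction One-row tibble/list with `scaffold`, `start`, `end`.
#' @param annotation One-row tibble/list with `circ_class` (or `true_class`)
#'   and `parent_gene` (or `host_gene`); `NULL` classifies on the fly.
#' @return Character scalar sequence (plus-strand for unstranded circles,
#'   gene-strand for exonic ones).
#' @export
circ_sequence <- function(genome, junction, annotation = NULL) {
  if (is.null(annotation)) {
    annotation <- classify_junctions(
      tibble(scaffold = junction$scaffold, start = junction$start,
             end = junction$end), genome)
  }
  cls <- annotation$circ_class %||% annotation$true_class
  gene <- annotation$parent_gene %||% annotation$host_gene
  s <- .circ_seq(genome, junction$scaffold[1], junction$start[1],
                 junction$end[1], cls[1], gene[1])
  if (nchar(s) == 0) abort("zero-length circular sequence")
  s
}

.circ_seq <- function(genome, scaffold, start, end, cls, gene) {
  if (identical(cls, "exonic") && !is.na(gene)) {
    ex <- gene_exons(genome, gene)
    ov <- ex$end >= start & ex$start <= end
    ex <- ex[ov, , drop = FALSE]
    parts <- mapply(function(a, b) scf_seq(genome, scaffold,
                                           max(a, start), min(b, end)),
                    ex$start, ex$end)
    s <- paste(parts, collapse = "")
    if (ex$strand[1] == "-") revcomp(s) else s
  } else {
    scf_seq(genome, scaffold, start, end)
  }
}

# per-segment map of a circle's linearized sequence to genomic coordinates:
# tibble(cstart, cend, gstart, gend) in circle coordinates (1..n). For
# minus-strand exonic circles circle coordinates run antiparallel to the
# genome (gstart > gend segment-wise ordering handled by `minus`).
circ_segments <- function(genome, scaffold, start, end, cls, gene) {
  if (identical(cls, "exonic") && !is.na(gene)) {
    ex <- gene_exons(genome, gene)
    ov <- ex$end >= start & ex$start <= end
    ex <- ex[ov, , drop = FALSE]
    gs <- pmax(ex$start, start); ge <- pmin(ex$end, end)
    w <- ge - gs + 1L
    minus <- ex$strand[1] == "-"
    if (minus) { gs <- rev(gs); ge <- rev(ge); w <- rev(w) }
    ce <- cumsum(w); cs <- ce - w + 1L
    tibble(cstart = cs, cend = ce, gstart = gs, gend = ge, minus = minus)
  } else {
    tibble(cstart = 1L, cend = end - start + 1L, gstart = start, gend = end,
           minus = FALSE)
  }
}
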