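#' Quality-filter reads
#'
#' A read fails when the fraction of bases with quality below `q_threshold`
#' exceeds `max_lowq_frac`, or the fraction of `N` bases exceeds
#' `max_n_frac`. When either mate of a pair fails, both mates are removed.
#'
#' @param reads Tibble with `id`, `mate`, `sequence`, `quality` (phred+33),
#'   optionally `sample`.
#' @param q_threshold Phred threshold (default Q20).
#' @param max_lowq_frac Maximum tolerated fraction of low-quality bases.
#' @param max_n_frac Maximum tolerated fraction of `N` bases.
#' @return List with `reads` (kept rows) and `summary` (tibble per sample:
#'   `kept_reads`, `removed_reads`, `removed_pairs`).
#' @export
qc_filter_reads <- function(reads, q_threshold = 20, max_lowq_frac = 0.5,
                            max_n_frac = 0.05) {
  assert_columns(reads, c("id", "mate", "sequence", "quality"), "reads")
  if (!"sample" %in% names(reads)) reads$sample <- "S1"
  bad_len <- nchar(reads$sequence) != nchar(reads$quality)
  if (any(bad_len)) {
    abort(sprintf("format error: sequence/quality length mismatch for read %s",
                  reads$id[which(bad_len)[1]]))
  }
  lowq_frac <- vapply(reads$quality, function(q) {
    mean(utf8ToInt(q) - 33L < q_threshold)
  }, numeric(1), USE.NAMES = FALSE)
  n_frac <- stringr::str_count(reads$sequence, "N") / nchar(reads$sequence)
  fails <- lowq_frac > max_lowq_frac | n_frac > max_n_frac
  reads$.fails <- fails
  kept <- reads %>%
    group_by(.data$sample, .data$id) %>%
    filter(!any(.data$.fails)) %>%
    ungroup()
  summary <- reads %>%
    group_by(.data$sample) %>%
    summarise(
      kept_reads = sum(!tapply(.data$.fails, .data$id, any)[
        as.character(.data$id)]),
      removed_reads = n() - .data$kept_reads,
      removed_pairs = n_distinct(.data$id[tapply(.data$.fails, .data$id,
                                                 any)[as.character(.data$id)]]),
      .groups = "drop")
  kept$.fails <- NULL
  list(reads = kept, summary = summary)
}

# common suffix length of two strings, bytewise
common_suffix_len <- function(a, b) {
  ra <- rev(charToRaw(a)); rb <- rev(charToRaw(b))
  m <- min(length(ra), length(rb))
  if (m == 0L) return(0L)
  d <- which(ra[seq_len(m)] != rb[seq_len(m)])
  if (length(d) == 0L) m else d[1L] - 1L
}

#' Detect back-splice junctions from chimeric split reads
#'
#' The split-segment caller: a read supports a back-splice junction
#' `(start, end)` when a prefix segment of the read maps exactly to a
#' genomic interval ending at `end`, its complementary suffix segment maps
#' to an interval beginning at `start` on the same scaffold, the suffix
#' interval lies *upstream* of the prefix interval (reversed genomic order
#' -- the back-splice signature), and both segments are at least `anchor`
#' nt. Both orientations of every read are searched; reads mapping
#' colinearly are ignored, and reads whose anchor hits are consistent with
#' more than one junction are dropped as ambiguous. Mapping is exact k-mer
#' anchoring plus ungapped extension -- adequate for the package's read
#' simulator, not a general-purpose aligner. When the aligned segments
#' overlap (junction-flanking microhomology), the maximal-prefix
#' representation is reported.
#'
#' @param reads Tibble with `sequence` and optionally `sample` (junctions
#'   are called per sample).
#' @param genome A `genome_model`.
#' @param anchor Minimum segment length (nt).
#' @param max_span Maximum circle size `end - start + 1` (nt).
#' @param min_reads Minimum junction reads to report a junction.
#' @return Tibble: `circ_id`, `scaffold`, `start`, `end`, `strand` (`"."`),
#'   `sample`, `n_reads`, `caller = "split"`.
#' @export
detect_split <- function(reads, genome, anchor = 20, max_span = 100000,
                         min_reads = 2) {
  assert_columns(reads, "sequence", "reads")
  if (!"sample" %in% names(reads)) reads$sample <- "S1"
  subjects <- Biostrings::DNAStringSet(genome$seqs)
  out <- list()
  for (smp in unique(reads$sample)) {
    seqs <- reads$sequence[reads$sample == smp]
    seqs <- seqs[nchar(seqs) >= 2 * anchor]
    if (length(seqs) == 0) next
    ent <- c(seqs, revcomp(seqs))
    L <- nchar(ent)
    pre <- substr(ent, 1L, anchor)
    suf <- substr(ent, L - anchor + 1L, L)
    pre_hits <- anchor_hits(pre, subjects)
    suf_hits <- anchor_hits(suf, subjects)
    cand <- intersect(unique(pre_hits$entry), unique(suf_hits$entry))
    support <- list()
    for (e in cand) {
      ph <- pre_hits[pre_hits$entry == e, ]
      sh <- suf_hits[suf_hits$entry == e, ]
      rseq <- ent[e]; rl <- L[e]
      juncs <- character(0); colinear <- FALSE
      for (pi in seq_len(nrow(ph))) {
        sc <- ph$scaffold[pi]; p_pos <- ph$pos[pi]
        gseq <- genome$seqs[[sc]]
        gwin <- substr(gseq, p_pos, min(p_pos + rl - 1L, nchar(gseq)))
        p_max <- common_prefix_len(rseq, gwin)
        if (p_max == rl) { colinear <- TRUE; break }
        shs <- sh[sh$scaffold == sc, , drop = FALSE]
        for (si in seq_len(nrow(shs))) {
          ge <- shs$pos[si] + anchor - 1L
          gwin2 <- substr(gseq, max(1L, ge - rl + 1L), ge)
          s_max <- common_suffix_len(rseq, gwin2)
          if (s_max == rl) { colinear <- TRUE; break }
          ssize <- rl - p_max
          if (p_max >= anchor && ssize >= anchor && ssize <= s_max) {
            j_start <- ge - ssize + 1L
            j_end <- p_pos + p_max - 1L
            if (j_start >= 1L && j_start < p_pos && j_start < j_end &&
                j_end - j_start + 1L <= max_span) {
              juncs <- c(juncs, paste(sc, j_start, j_end, sep = "\r"))
            }
          }
        }
        if (colinear) break
      }
      if (colinear) next
      juncs <- unique(juncs)
      read_idx <- (e - 1L) %% length(seqs) + 1L
      if (length(juncs) == 1) {
        support[[length(support) + 1L]] <-
          tibble(read = read_idx, key = juncs)
      }
    }
    if (length(support) == 0) next
    sup <- bind_rows(support) %>%
      distinct(.data$read, .data$key) %>%
      count(.data$key, name = "n_reads") %>%
      filter(.data$n_reads >= min_reads)
    if (nrow(sup) == 0) next
    parts <- stringr::str_split_fixed(sup$key, "\r", 3)
    out[[smp]] <- tibble(
      scaffold = parts[, 1], start = as.integer(parts[, 2]),
      end = as.integer(parts[, 3]), strand = ".",
      sample = smp, n_reads = sup$n_reads, caller = "split")
  }
  finalize_junctions(out)
}

#' @noRd
#' Exact matches of fixed-width anchors against a set of scaffolds.
#' Returns tibble(entry, scaffold, pos).
anchor_hits <- function(anchors, subjects) {
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(anchors))
  hits <- list()
  for (sc in names(subjects)) {
    mi <- Biostrings::matchPDict(pd, subjects[[sc]])
    st <- Biostrings::startIndex(mi)
    nz <- which(lengths(st) > 0)
    if (length(nz) > 0) {
      hits[[sc]] <- tibble(
        entry = rep(nz, lengths(st[nz])),
        scaffold = sc,
        pos = unlist(st[nz], use.names = FALSE))
    }
  }
  if (length(hits)) bind_rows(hits) else
    tibble(entry = integer(), scaffold = character(), pos = integer())
}

finalize_junctions <- function(out) {
  if (length(out) == 0) {
    return(tibble(circ_id = character(), scaffold = character(),
                  start = integer(), end = integer(), strand = character(),
                  sample = character(), n_reads = integer(),
                  caller = character()))
  }
  bind_rows(out) %>%
    mutate(circ_id = circ_id(.data$scaffold, .data$start, .data$end),
           .before = 1) %>%
    arrange(.data$sample, .data$scaffold, .data$start, .data$end)
}

#' Detect back-splice junctions by realignment to candidate junction
#' pseudo-references
#'
#' The realignment caller: candidate junctions (typically the split caller's
#' output, pooled across samples) are augmented with every annotated
#' exon-boundary pair within `max_span`, a junction pseudo-sequence
#' (end-flank followed by start-flank, exon-spliced for exonic candidates)
#' is built for each, and reads aligning across the junction midpoint with
#' at least `anchor` nt on each side and at most `max_mismatch` mismatches
#' are counted. Reads are located on the pseudo-references by exact matching
#' of the junction-centered `2 * anchor`-mer (both orientations), then
#' verified by full ungapped comparison; junction-crossing reads whose
#' errors fall inside the seed can therefore be missed.
#'
#' @param reads Tibble with `sequence`, optionally `sample`.
#' @param genome A `genome_model`.
#' @param candidates Tibble with `scaffold`, `start`, `end` seeding the
#'   candidate set (e.g. [detect_split()] output); `NULL` for
#'   annotation-derived candidates only.
#' @param anchor Minimum junction overhang (nt).
#' @param max_mismatch Maximum mismatches in the read/pseudo-reference
#'   comparison.
#' @param min_reads Minimum junction reads to report a candidate.
#' @param max_span Maximum circle size (nt); larger candidates are rejected
#'   (see `attr(, "rejected")`).
#' @return Tibble like [detect_split()] with `caller = "realign"`; rejected
#'   candidates with reasons in `attr(, "rejected")`.
#' @export
detect_realign <- function(reads, genome, candidates = NULL, anchor = 20,
                           max_mismatch = 2, min_reads = 2,
                           max_span = 100000) {
  assert_columns(reads, "sequence", "reads")
  if (!"sample" %in% names(reads)) reads$sample <- "S1"
  cand <- candidate_junctions(genome, candidates, max_span)
  rejected <- cand %>% filter(!is.na(.data$reject_reason)) %>%
    select("scaffold", "start", "end", "reject_reason")
  cand <- cand %>% filter(is.na(.data$reject_reason))
  if (nrow(cand) == 0) {
    res <- finalize_junctions(list())
    attr(res, "rejected") <- rejected
    return(res)
  }
  ann <- classify_junctions(cand[, c("scaffold", "start", "end")], genome)
  cseq <- circ_sequences(genome, ann)
  clen <- nchar(cseq)
  short <- clen < anchor
  if (any(short)) {
    rejected <- bind_rows(rejected, tibble(
      scaffold = cand$scaffold[short], start = cand$start[short],
      end = cand$end[short],
      reject_reason = "circle shorter than anchor"))
    cand <- cand[!short, ]; cseq <- cseq[!short]; clen <- clen[!short]
  }
  read_len <- max(nchar(reads$sequence))
  flank <- read_len - anchor
  tail_len <- pmin(flank, clen)
  head_len <- pmin(flank, clen)
  pr <- paste0(substring(cseq, clen - tail_len + 1L, clen),
               substring(cseq, 1L, head_len))
  seed <- paste0(substring(cseq, clen - anchor + 1L, clen),
                 substring(cseq, 1L, anchor))
  seeds_all <- c(seed, revcomp(seed))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds_all))
  nc <- nrow(cand)
  out <- list()
  sep <- strrep("N", 2L * anchor + 10L)
  for (smp in unique(reads$sample)) {
    seqs <- reads$sequence[reads$sample == smp]
    widths <- nchar(seqs)
    starts0 <- cumsum(c(0L, utils::head(widths + nchar(sep), -1L)))
    subject <- Biostrings::DNAString(paste(seqs, collapse = sep))
    mi <- Biostrings::matchPDict(pd, subject)
    st <- Biostrings::startIndex(mi)
    nz <- which(lengths(st) > 0)
    if (length(nz) == 0) next
    hits <- tibble(pat = rep(nz, lengths(st[nz])),
                   pos = unlist(st[nz], use.names = FALSE)) %>%
      mutate(cand_i = (.data$pat - 1L) %% nc + 1L,
             rc = .data$pat > nc,
             read = findInterval(.data$pos, starts0 + 1L),
             q = .data$pos - starts0[.data$read])
    # verify full ungapped alignment against the pseudo-reference
    keep <- vapply(seq_len(nrow(hits)), function(h) {
      i <- hits$cand_i[h]; r <- hits$read[h]
      rseq <- seqs[r]
      rl <- widths[r]
      q <- hits$q[h]
      if (q < 1L || q + 2L * anchor - 1L > rl) return(FALSE)
      if (hits$rc[h]) {
        rseq <- revcomp(rseq)
        q <- rl - (q + 2L * anchor - 1L) + 1L
      }
      jpos <- tail_len[i]  # junction between jpos and jpos+1 in pr
      off <- (jpos - anchor + 1L) - q
      a1 <- max(1L, 1L + off); a2 <- min(nchar(pr[i]), rl + off)
      r1 <- a1 - off; r2 <- a2 - off
      mm <- sum(charToRaw(substr(pr[i], a1, a2)) !=
                  charToRaw(substr(rseq, r1, r2)))
      mm <= max_mismatch
    }, logical(1))
    sup <- hits[keep, ] %>%
      distinct(.data$cand_i, .data$read) %>%
      count(.data$cand_i, name = "n_reads") %>%
      filter(.data$n_reads >= min_reads)
    if (nrow(sup) == 0) next
    out[[smp]] <- tibble(
      scaffold = cand$scaffold[sup$cand_i],
      start = cand$start[sup$cand_i], end = cand$end[sup$cand_i],
      strand = ".", sample = smp, n_reads = sup$n_reads,
      caller = "realign")
  }
  res <- finalize_junctions(out)
  attr(res, "rejected") <- rejected
  res
}

#' @noRd
#' Candidate set: user/split seeds plus all annotated exon-boundary pairs
#' within max_span. Adds reject_reason (NA = kept).
candidate_junctions <- function(genome, candidates, max_span) {
  ex_pairs <- purrr::map_dfr(
    split(genome$exons, genome$exons$gene_id),
    function(gx) {
      idx <- expand.grid(i = seq_len(nrow(gx)), j = seq_len(nrow(gx)))
      idx <- idx[idx$i <= idx$j, , drop = FALSE]
      tibble(scaffold = gx$scaffold[1],
             start = gx$start[idx$i], end = gx$end[idx$j])
    })
  cand <- bind_rows(
    if (!is.null(candidates)) {
      assert_columns(candidates, c("scaffold", "start", "end"), "candidates")
      candidates[, c("scaffold", "start", "end")]
    },
    ex_pairs
  ) %>%
    distinct(.data$scaffold, .data$start, .data$end) %>%
    mutate(reject_reason = dplyr::if_else(
      .data$end - .data$start + 1L > max_span,
      sprintf("span %d exceeds max_span %d",
              .data$end - .data$start + 1L, as.integer(max_span)),
      NA_character_))
  cand
}
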