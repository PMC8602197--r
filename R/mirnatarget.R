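# miRNA sponge-site scanning with an additive complementarity penalty.
#
# Penalty table (per aligned miRNA position, counted from the miRNA 5' end):
# Watson-Crick match 0, G:U wobble 0.5, mismatch 1.0, gap 2.0 -- doubled
# when the position falls in the core region (positions 2-13). Lower totals
# mean better sites; sites at or below the expectation cutoff are reported.

MIRNA_CORE <- c(2L, 13L)

rna_norm <- function(x) {
  x <- toupper(x)
  gsub("T", "U", x)
}

wc_partner <- c(A = "U", U = "A", G = "C", C = "G")

#' Score one miRNA/target-site alignment
#'
#' `mirna_aln` is the miRNA 5'->3'; `site_aln` holds the target bases each
#' miRNA base pairs with (the target read 3'->5', i.e. antiparallel,
#' aligned column by column with the miRNA). Either string may contain
#' `"-"` for a gap. The expectation score is the sum of per-position
#' penalties: Watson-Crick match 0, G:U wobble 0.5, mismatch 1, gap 2, each
#' doubled when the miRNA position (5'-anchored) lies in the core region.
#'
#' @param mirna_aln,site_aln Aligned strings of equal length (RNA or DNA
#'   alphabet; T is normalized to U).
#' @param core Length-2 integer range of core miRNA positions.
#' @return Numeric expectation (penalty) score, >= 0.
#' @examples
#' score_alignment("ACGUACGUACGUACGUACGUA", "UGCAUGCAUGCAUGCAUGCAU")
#' @export
score_alignment <- function(mirna_aln, site_aln, core = MIRNA_CORE) {
  m <- strsplit(rna_norm(mirna_aln), "")[[1]]
  t <- strsplit(rna_norm(site_aln), "")[[1]]
  if (length(m) != length(t)) {
    abort("aligned strings must have equal length")
  }
  ok <- c("A", "C", "G", "U", "-")
  if (!all(m %in% ok) || !all(t %in% ok)) {
    abort("input error: non-RNA characters in alignment")
  }
  score <- 0
  pos <- 0L
  for (i in seq_along(m)) {
    if (m[i] == "-") {
      # insertion in the target, attributed to the next miRNA position
      at <- pos + 1L
      pen <- 2
    } else {
      pos <- pos + 1L
      at <- pos
      pen <- if (t[i] == "-") {
        2
      } else if (t[i] == wc_partner[[m[i]]]) {
        0
      } else if ((m[i] == "G" && t[i] == "U") ||
                 (m[i] == "U" && t[i] == "G")) {
        0.5
      } else {
        1
      }
    }
    if (at >= core[1] && at <= core[2]) pen <- pen * 2
    score <- score + pen
  }
  score
}

#' Scan circRNA sequences for miRNA binding sites
#'
#' Each circular sequence is linearized at the back-splice and padded with
#' its own first `max(miRNA length) - 1` nt so sites spanning the junction
#' are found; every window is scored gaplessly against the miRNA
#' (antiparallel pairing), and windows above the cutoff are retried with a
#' single gap on either strand. Overlapping candidate windows collapse to
#' the best-scoring site (ties to the leftmost start); wrap-around
#' coordinates are mapped back to the unpadded circle, so `site_end <
#' site_start` marks a junction-spanning site.
#'
#' @param mirnas Tibble (`mirna_id`, `sequence`) or named character vector;
#'   18-26 nt, T normalized to U.
#' @param circ_seqs Named character vector of circular sequences (names =
#'   circRNA ids).
#' @param cutoff Maximum expectation score of a reported site.
#' @param allow_gap Try single-gap alignments for windows failing the
#'   gapless pass.
#' @param core Core-region bounds passed to [score_alignment()].
#' @return Tibble: `mirna_id`, `circ_id`, `site_start`, `site_end`,
#'   `expectation`, `alignment` (three lines: miRNA 3'->5', match line,
#'   target 5'->3').
#' @export
scan_targets <- function(mirnas, circ_seqs, cutoff = 5, allow_gap = TRUE,
                         core = MIRNA_CORE) {
  if (is.character(mirnas) && !is.null(names(mirnas))) {
    mirnas <- tibble(mirna_id = names(mirnas), sequence = unname(mirnas))
  }
  if (nrow(mirnas) == 0 || length(circ_seqs) == 0) {
    return(tibble(mirna_id = character(), circ_id = character(),
                  site_start = integer(), site_end = integer(),
                  expectation = numeric(), alignment = character()))
  }
  assert_columns(mirnas, c("mirna_id", "sequence"), "mirnas")
  mirnas$sequence <- rna_norm(mirnas$sequence)
  if (any(nchar(mirnas$sequence) < 18 | nchar(mirnas$sequence) > 26)) {
    abort("miRNA sequences must be 18-26 nt")
  }
  hits <- list()
  for (mi in seq_len(nrow(mirnas))) {
    mseq <- mirnas$sequence[mi]
    Lm <- nchar(mseq)
    mvec <- strsplit(mseq, "")[[1]]
    for (ci in seq_along(circ_seqs)) {
      circ <- rna_norm(circ_seqs[[ci]])
      n <- nchar(circ)
      if (n < Lm) next
      padded <- paste0(circ, substr(circ, 1L, Lm - 1L))
      pvec <- strsplit(padded, "")[[1]]
      # gapless scores for all windows, vectorized over window starts:
      # miRNA position i pairs with window position Lm - i + 1
      starts <- seq_len(n)
      score <- numeric(n)
      for (i in seq_len(Lm)) {
        tchar <- pvec[starts + Lm - i]
        pen <- penalty_vec(mvec[i], tchar)
        if (i >= core[1] && i <= core[2]) pen <- pen * 2
        score <- score + pen
      }
      cand <- which(score <= cutoff)
      cand_scores <- score[cand]
      cand_len <- rep(Lm, length(cand))
      if (allow_gap) {
        retry <- which(score > cutoff)
        for (w in retry) {
          g <- best_single_gap(mvec, pvec, w, Lm, core)
          if (!is.null(g) && g$score <= cutoff) {
            cand <- c(cand, w)
            cand_scores <- c(cand_scores, g$score)
            cand_len <- c(cand_len, g$site_len)
          }
        }
      }
      if (length(cand) == 0) next
      picked <- collapse_windows(cand, cand_scores, cand_len, n)
      for (pi in seq_len(nrow(picked))) {
        w <- picked$start[pi]; sl <- picked$len[pi]
        site <- substr(padded, w, w + sl - 1L)
        hits[[length(hits) + 1L]] <- tibble(
          mirna_id = mirnas$mirna_id[mi],
          circ_id = names(circ_seqs)[ci],
          site_start = w,
          site_end = (w + sl - 2L) %% n + 1L,
          expectation = picked$score[pi],
          alignment = format_alignment(mseq, site, core))
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble(mirna_id = character(), circ_id = character(),
                  site_start = integer(), site_end = integer(),
                  expectation = numeric(), alignment = character()))
  }
  bind_rows(hits) %>%
    arrange(.data$mirna_id, .data$circ_id, .data$site_start)
}

# vectorized gapless penalty of one miRNA base vs many target bases
penalty_vec <- function(m, t) {
  ifelse(t == wc_partner[[m]], 0,
         ifelse((m == "G" & t == "U") | (m == "U" & t == "G"), 0.5, 1))
}

#' @noRd
#' Best single-gap alignment of the miRNA against the window starting at w
#' (gap in target: site_len = Lm - 1; gap in miRNA: site_len = Lm + 1).
best_single_gap <- function(mvec, pvec, w, Lm, core) {
  best <- NULL
  npad <- length(pvec)
  # gap in the target at miRNA position gp (miRNA base gp unpaired)
  if (w + Lm - 2L <= npad) {
    site_rev <- rev(pvec[w:(w + Lm - 2L)])  # 3'->5' of Lm-1 target bases
    for (gp in seq_len(Lm)) {
      t_aln <- append(site_rev, "-", after = gp - 1L)
      s <- score_cols(mvec, t_aln, core)
      if (is.null(best) || s < best$score) {
        best <- list(score = s, site_len = Lm - 1L)
      }
    }
  }
  # gap in the miRNA between positions gp and gp+1 (extra target base)
  if (w + Lm <= npad) {
    site_rev <- rev(pvec[w:(w + Lm)])  # Lm+1 target bases
    for (gp in seq_len(Lm - 1L)) {
      m_aln <- append(mvec, "-", after = gp)
      s <- score_cols(m_aln, site_rev, core)
      if (is.null(best) || s < best$score) {
        best <- list(score = s, site_len = Lm + 1L)
      }
    }
  }
  best
}

# column scorer on pre-split vectors (same rules as score_alignment)
score_cols <- function(m, t, core) {
  score <- 0
  pos <- 0L
  for (i in seq_along(m)) {
    if (m[i] == "-") {
      at <- pos + 1L; pen <- 2
    } else {
      pos <- pos + 1L; at <- pos
      pen <- if (t[i] == "-") 2
      else if (t[i] == wc_partner[[m[i]]]) 0
      else if ((m[i] == "G" && t[i] == "U") ||
               (m[i] == "U" && t[i] == "G")) 0.5
      else 1
    }
    if (at >= core[1] && at <= core[2]) pen <- pen * 2
    score <- score + pen
  }
  score
}

#' @noRd
#' Greedy best-score collapse of overlapping windows on a circle of size n.
#' Ties broken by leftmost start. Returns tibble(start, len, score).
collapse_windows <- function(starts, scores, lens, n) {
  ord <- order(scores, starts)
  occupied <- rep(FALSE, n)
  keep <- list()
  for (k in ord) {
    span <- ((starts[k] - 1L) + seq_len(lens[k]) - 1L) %% n + 1L
    if (!any(occupied[span])) {
      occupied[span] <- TRUE
      keep[[length(keep) + 1L]] <- tibble(start = starts[k],
                                          len = lens[k],
                                          score = scores[k])
    }
  }
  bind_rows(keep) %>% arrange(.data$start)
}

# three-line alignment text: miRNA 3'->5', match line, target 5'->3'
format_alignment <- function(mseq, site, core) {
  mvec <- rev(strsplit(mseq, "")[[1]])       # 3'->5'
  tvec <- strsplit(rna_norm(site), "")[[1]]  # 5'->3'
  L <- min(length(mvec), length(tvec))
  match_line <- vapply(seq_len(L), function(i) {
    m <- mvec[i]; t <- tvec[i]
    if (t == wc_partner[[m]]) "|"
    else if ((m == "G" && t == "U") || (m == "U" && t == "G")) "o"
    else " "
  }, character(1))
  paste(paste(rev(strsplit(mseq, "")[[1]])[seq_len(L)], collapse = ""),
        paste(match_line, collapse = ""),
        paste(tvec[seq_len(L)], collapse = ""),
        sep = "\n")
}

#' Sponge multiplicity summaries of a target-hit table
#'
#' Per miRNA: how many distinct circRNAs carry a binding site; per circRNA:
#' how many distinct miRNAs bind it. Duplicate hits of a (miRNA, circRNA)
#' pair count once. Tables are sorted by descending multiplicity, ties
#' lexicographically.
#'
#' @param hits Tibble from [scan_targets()].
#' @return List with `mirna` (tibble: `mirna_id`, `n_circ`) and `circ`
#'   (tibble: `circ_id`, `n_mirna`).
#' @export
sponge_summary <- function(hits) {
  if (nrow(hits) == 0) {
    return(list(mirna = tibble(mirna_id = character(), n_circ = integer()),
                circ = tibble(circ_id = character(), n_mirna = integer())))
  }
  u <- hits %>% distinct(.data$mirna_id, .data$circ_id)
  list(
    mirna = u %>% count(.data$mirna_id, name = "n_circ") %>%
      arrange(dplyr::desc(.data$n_circ), .data$mirna_id),
    circ = u %>% count(.data$circ_id, name = "n_mirna") %>%
      arrange(dplyr::desc(.data$n_mirna), .data$circ_id)
  )
}
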