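#' Per-sample two-caller consensus with intersection/union ratio
#'
#' Junctions called by both callers in the same sample (identical scaffold,
#' start and end; optionally within `slop` nt) form the consensus set. The
#' report gives, per sample, the two set sizes, the intersection and union
#' sizes and their ratio -- the per-sample agreement statistic between the
#' two callers.
#'
#' @param set_split,set_realign Junction tibbles from [detect_split()] /
#'   [detect_realign()]; may contain several samples (matched per sample).
#' @param count_from Which caller's junction-read count the consensus
#'   junction keeps: `"realign"` (default) or `"max"` of the two.
#' @param slop Coordinate tolerance (nt) for matching; default 0 (exact).
#' @return List with `consensus` (junction tibble, `caller = "consensus"`)
#'   and `report` (tibble: `sample`, `n_split`, `n_realign`, `n_intersect`,
#'   `n_union`, `ratio`).
#' @export
intersect_callers <- function(set_split, set_realign,
                              count_from = c("realign", "max"), slop = 0) {
  count_from <- match.arg(count_from)
  for (x in list(set_split, set_realign)) {
    assert_columns(x, c("scaffold", "start", "end", "n_reads"), "junction set")
    dup <- x %>%
      mutate(sample = if ("sample" %in% names(x)) .data$sample else "S1") %>%
      count(.data$sample, .data$scaffold, .data$start, .data$end) %>%
      filter(.data$n > 1)
    if (nrow(dup) > 0) {
      abort(sprintf("input error: duplicate junction id %s in sample %s",
                    circ_id(dup$scaffold[1], dup$start[1], dup$end[1]),
                    dup$sample[1]))
    }
  }
  a <- set_split; b <- set_realign
  if (!"sample" %in% names(a)) a$sample <- "S1"
  if (!"sample" %in% names(b)) b$sample <- "S1"
  samples <- union(unique(a$sample), unique(b$sample))
  cons <- list(); rep <- list()
  for (smp in samples) {
    as <- a %>% filter(.data$sample == smp)
    bs <- b %>% filter(.data$sample == smp)
    if (slop > 0) {
      m <- match_with_slop(as, bs, slop)
    } else {
      m <- inner_join(as %>% select("scaffold", "start", "end",
                                    split_reads = "n_reads"),
                      bs %>% select("scaffold", "start", "end",
                                    realign_reads = "n_reads"),
                      by = c("scaffold", "start", "end"))
    }
    n_int <- nrow(m)
    n_union <- nrow(as) + nrow(bs) - n_int
    rep[[smp]] <- tibble(
      sample = smp, n_split = nrow(as), n_realign = nrow(bs),
      n_intersect = n_int, n_union = n_union,
      ratio = if (n_union > 0) n_int / n_union else NA_real_)
    if (n_int > 0) {
      cons[[smp]] <- m %>%
        mutate(
          circ_id = circ_id(.data$scaffold, .data$start, .data$end),
          strand = ".", sample = smp,
          n_reads = if (count_from == "realign") .data$realign_reads else
            pmax(.data$split_reads, .data$realign_reads),
          caller = "consensus") %>%
        select("circ_id", "scaffold", "start", "end", "strand", "sample",
               "n_reads", "caller")
    }
  }
  list(consensus = finalize_junctions(cons), report = bind_rows(rep))
}

#' @noRd
match_with_slop <- function(as, bs, slop) {
  gr_a <- GenomicRanges::GRanges(as$scaffold, IRanges::IRanges(as$start, as$end))
  gr_b <- GenomicRanges::GRanges(bs$scaffold, IRanges::IRanges(bs$start, bs$end))
  fo <- GenomicRanges::findOverlaps(gr_a, gr_b)
  qh <- S4Vectors::queryHits(fo); sh <- S4Vectors::subjectHits(fo)
  ok <- abs(as$start[qh] - bs$start[sh]) <= slop &
    abs(as$end[qh] - bs$end[sh]) <= slop
  qh <- qh[ok]; sh <- sh[ok]
  keep <- !duplicated(qh) & !duplicated(sh)
  tibble(scaffold = as$scaffold[qh[keep]], start = as$start[qh[keep]],
         end = as$end[qh[keep]], split_reads = as$n_reads[qh[keep]],
         realign_reads = bs$n_reads[sh[keep]])
}

#' Merge per-sample junction sets into a cross-sample circRNA catalog
#'
#' Duplicate junctions (same scaffold/start/end) across samples are
#' collapsed into one catalog entry; per-sample junction-read counts are
#' preserved (0 where a sample did not call the junction), and provenance
#' records which samples contributed each junction.
#'
#' @param junctions Junction tibble with a `sample` column (e.g. the
#'   consensus sets of all samples bound together).
#' @param samples Optional character vector fixing the full sample set
#'   (defaults to the samples present).
#' @return A `circ_catalog`: list with `junctions` (tibble: `circ_id`,
#'   `scaffold`, `start`, `end`, `strand`, `n_samples`), `counts` (long
#'   tibble: `circ_id`, `sample`, `n_reads`, zero-filled) and `samples`.
#' @export
merge_samples <- function(junctions, samples = NULL) {
  assert_columns(junctions, c("scaffold", "start", "end", "sample",
                              "n_reads"), "junctions")
  samples <- samples %||% sort(unique(junctions$sample))
  jx <- junctions %>%
    mutate(circ_id = circ_id(.data$scaffold, .data$start, .data$end))
  cat_j <- jx %>%
    group_by(.data$circ_id, .data$scaffold, .data$start, .data$end) %>%
    summarise(strand = dplyr::first(.data$strand),
              n_samples = n_distinct(.data$sample), .groups = "drop") %>%
    arrange(.data$scaffold, .data$start, .data$end)
  counts <- tidyr::expand_grid(circ_id = cat_j$circ_id, sample = samples) %>%
    left_join(jx %>% select("circ_id", "sample", "n_reads"),
              by = c("circ_id", "sample")) %>%
    mutate(n_reads = tidyr::replace_na(.data$n_reads, 0L))
  structure(list(junctions = cat_j, counts = counts, samples = samples),
            class = "circ_catalog")
}

#' @export
print.circ_catalog <- function(x, ...) {
  cat(sprintf("<circ_catalog> %d junction(s) across %d sample(s)\n",
              nrow(x$junctions), length(x$samples)))
  invisible(x)
}

#' Junction-read count matrix of a catalog
#'
#' @param catalog A `circ_catalog`.
#' @return Wide tibble, one row per `circ_id`, one column per sample.
#' @export
catalog_counts <- function(catalog) {
  catalog$counts %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "n_reads",
                       values_fill = 0L)
}

#' Replicate- and group-sharing statistics of a circRNA catalog
#'
#' For every group (e.g. tissue) of samples: the union of junctions seen in
#' any member, and how many are shared by *all* members. For every pair and
#' triple of groups: the overlap counts needed to draw 2- and 3-set Venn
#' diagrams (a junction belongs to a group when any member sample called
#' it).
#'
#' @param catalog A `circ_catalog`.
#' @param grouping Named character vector or tibble (`sample`, `group`)
#'   assigning every catalog sample to one group.
#' @return List with `groups`, `pairs` and `triples` tibbles.
#' @export
sharing_stats <- function(catalog, grouping) {
  if (is.data.frame(grouping)) {
    grouping <- setNames(grouping$group, grouping$sample)
  }
  missing <- setdiff(catalog$samples, names(grouping))
  if (length(missing) > 0) {
    abort(sprintf("configuration error: sample(s) missing from grouping: %s",
                  paste(missing, collapse = ", ")))
  }
  present <- catalog$counts %>% filter(.data$n_reads > 0)
  groups <- sort(unique(unname(grouping[catalog$samples])))
  # per-group: set of junctions per member sample
  member_sets <- lapply(groups, function(g) {
    smps <- catalog$samples[grouping[catalog$samples] == g]
    lapply(setNames(smps, smps), function(s) {
      present$circ_id[present$sample == s]
    })
  })
  names(member_sets) <- groups
  group_sets <- lapply(member_sets, function(ms) unique(unlist(ms)))
  g_tbl <- tibble(
    group = groups,
    n_members = unname(lengths(member_sets)),
    union_size = unname(lengths(group_sets)),
    shared_all = vapply(member_sets, function(ms) {
      length(Reduce(intersect, ms))
    }, integer(1), USE.NAMES = FALSE),
  ) %>%
    mutate(shared_pct = ifelse(.data$union_size > 0,
                               100 * .data$shared_all / .data$union_size,
                               NA_real_))
  pairs <- if (length(groups) >= 2) {
    cmb <- utils::combn(groups, 2)
    purrr::map_dfr(seq_len(ncol(cmb)), function(i) {
      A <- group_sets[[cmb[1, i]]]; B <- group_sets[[cmb[2, i]]]
      tibble(group1 = cmb[1, i], group2 = cmb[2, i],
             n1 = length(A), n2 = length(B),
             n_intersect = length(intersect(A, B)),
             n_union = length(union(A, B)))
    })
  } else tibble()
  triples <- if (length(groups) >= 3) {
    cmb <- utils::combn(groups, 3)
    purrr::map_dfr(seq_len(ncol(cmb)), function(i) {
      A <- group_sets[[cmb[1, i]]]; B <- group_sets[[cmb[2, i]]]
      C <- group_sets[[cmb[3, i]]]
      u <- union(union(A, B), C)
      pat <- paste0(as.integer(u %in% A), as.integer(u %in% B),
                    as.integer(u %in% C))
      cnt <- table(factor(pat, levels = c("100", "010", "001", "110",
                                          "101", "011", "111")))
      tibble(group1 = cmb[1, i], group2 = cmb[2, i], group3 = cmb[3, i],
             only1 = as.integer(cnt[["100"]]),
             only2 = as.integer(cnt[["010"]]),
             only3 = as.integer(cnt[["001"]]),
             only12 = as.integer(cnt[["110"]]),
             only13 = as.integer(cnt[["101"]]),
             only23 = as.integer(cnt[["011"]]),
             all3 = as.integer(cnt[["111"]]),
             n_union = length(u))
    })
  } else tibble()
  list(groups = g_tbl, pairs = pairs, triples = triples)
}
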