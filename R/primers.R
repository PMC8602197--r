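# Convergent/divergent primer design for circRNA validation, and an exact
# in-silico PCR. Tm by the Wallace rule 2(A+T) + 4(G+C).

#' Wallace-rule melting temperature
#'
#' @param x Primer sequence(s).
#' @return `2 * (A + T) + 4 * (G + C)` in degrees C.
#' @export
primer_tm <- function(x) {
  at <- stringr::str_count(x, "[AT]")
  gc <- stringr::str_count(x, "[GC]")
  2 * at + 4 * gc
}

#' Design convergent and divergent primer pairs for a circRNA
#'
#' Primers are picked on the circle's linearized sequence (the cDNA of the
#' circle), each fully inside a single exon segment so that both primers
#' also bind the genome. The *convergent* pair faces inward within the
#' circle's genomic span (forward primer near the circle start, reverse
#' primer near the end): it amplifies linear cDNA and genomic DNA, and the
#' genomic product is longer whenever the span contains introns. The
#' *divergent* pair faces outward on the genome (forward primer near the
#' circle end, reverse near the start): its only inward-facing template is
#' the circular cDNA, where the product spans the back-splice junction; on
#' genomic DNA it yields nothing.
#'
#' @param genome A `genome_model`.
#' @param junction One-row tibble/list: `scaffold`, `start`, `end`.
#' @param annotation One-row tibble/list from [classify_junctions()];
#'   `NULL` classifies on the fly.
#' @param primer_len Allowed primer lengths (nt).
#' @param product Length-2 target product-size range (bp) on the circular
#'   cDNA.
#' @param max_dtm Maximum Tm difference within a pair (degrees C).
#' @return Tibble with one row per orientation (`convergent`,
#'   `divergent`): primer sequences, circle coordinates (`fwd_start`,
#'   `rev_start` of the 5' base on the linearized circle), genomic 5'
#'   coordinates, Tm's, and expected product sizes on circular cDNA,
#'   linear cDNA and genomic DNA (`NA` = no product).
#' @export
design_primers <- function(genome, junction, annotation = NULL,
                           primer_len = 18:24, product = c(100, 400),
                           max_dtm = 4) {
  if (is.null(annotation)) {
    annotation <- classify_junctions(
      tibble(scaffold = junction$scaffold[1], start = junction$start[1],
             end = junction$end[1]), genome)
  }
  cls <- (annotation$circ_class %||% annotation$true_class)[1]
  gene <- (annotation$parent_gene %||% annotation$host_gene)[1]
  cseq <- .circ_seq(genome, junction$scaffold[1], junction$start[1],
                    junction$end[1], cls, gene)
  n <- nchar(cseq)
  if (n < 80) {
    abort(sprintf("primer design refused: circular sequence is %d nt (< 80)",
                  n))
  }
  segs <- circ_segments(genome, junction$scaffold[1], junction$start[1],
                        junction$end[1], cls, gene)
  nseg <- nrow(segs)
  win <- 80L  # search window (nt) for primer 5' positions
  if (nseg > 1) {
    # convergent primers straddle the first intron: forward primer at the
    # 3' end of segment 1, reverse primer at the 5' start of segment 2,
    # so the genomic product includes the intron
    conv_f <- c(max(segs$cstart[1], segs$cend[1] - win + 1L), segs$cend[1])
    conv_r <- c(segs$cstart[2], min(segs$cend[2], segs$cstart[2] + win - 1L))
  } else {
    conv_f <- c(1L, min(n, win))
    conv_r <- c(max(1L, product[1] - max(primer_len) + 1L),
                min(n, product[1] + 2L * win))
  }
  # divergent primers flank the back-splice junction: forward primer near
  # the end of the linearized circle, reverse primer near its start
  div_f <- c(max(segs$cstart[nseg], n - win + 1L), n)
  div_r <- c(1L, min(segs$cend[1], win))

  conv <- pick_pair(cseq, n, fwd_region = conv_f, rev_region = conv_r,
                    orientation = "convergent", primer_len = primer_len,
                    product = product, max_dtm = max_dtm)
  div <- pick_pair(cseq, n, fwd_region = div_f, rev_region = div_r,
                   orientation = "divergent", primer_len = primer_len,
                   product = product, max_dtm = max_dtm)

  # genomic span of the convergent product (introns included)
  gspan <- function(cpos_f, cpos_r_end) {
    gf <- circ2genomic(segs, cpos_f)
    gr <- circ2genomic(segs, cpos_r_end)
    abs(gr - gf) + 1L
  }
  conv_gprod <- gspan(conv$fwd_start, conv$rev_start + conv$rev_len - 1L)
  rows <- bind_rows(
    conv %>% mutate(orientation = "convergent",
                    product_circular = .data$product_size,
                    product_linear_cdna = .data$product_size,
                    product_genomic = conv_gprod),
    div %>% mutate(orientation = "divergent",
                   product_circular = .data$product_size,
                   product_linear_cdna = NA_integer_,
                   product_genomic = NA_integer_)
  )
  rows %>%
    mutate(circ_id = circ_id(junction$scaffold[1], junction$start[1],
                             junction$end[1]),
           fwd_genomic = vapply(.data$fwd_start, circ2genomic,
                                integer(1), segs = segs),
           rev_genomic = vapply(.data$rev_start + .data$rev_len - 1L,
                                circ2genomic, integer(1), segs = segs)) %>%
    select("circ_id", "orientation", "fwd", "rev", "fwd_start", "rev_start",
           "fwd_genomic", "rev_genomic", "tm_fwd", "tm_rev",
           "product_circular", "product_linear_cdna", "product_genomic")
}

# genomic coordinate of a circle coordinate
circ2genomic <- function(segs, cpos) {
  k <- which(segs$cstart <= cpos & segs$cend >= cpos)[1]
  if (is.na(k)) return(NA_integer_)
  if (segs$minus[k]) {
    as.integer(segs$gend[k] - (cpos - segs$cstart[k]))
  } else {
    as.integer(segs$gstart[k] + (cpos - segs$cstart[k]))
  }
}

#' @noRd
#' Enumerate primer pairs in the two regions and pick the first satisfying
#' product-size and delta-Tm constraints; preference order: smallest |dTm|,
#' then product closest to mid-range.
pick_pair <- function(cseq, n, fwd_region, rev_region, orientation,
                      primer_len, product, max_dtm) {
  cand <- function(region) {
    purrr::map_dfr(primer_len, function(l) {
      starts <- seq(region[1], region[2] - l + 1L)
      if (length(starts) == 0 || starts[1] > region[2] - l + 1L) {
        return(tibble())
      }
      tibble(start = starts, len = l,
             seq = substring(cseq, starts, starts + l - 1L))
    }) %>%
      mutate(tm = primer_tm(.data$seq))
  }
  fc <- cand(fwd_region)
  rc_ <- cand(rev_region)
  if (nrow(fc) == 0 || nrow(rc_) == 0) {
    abort(sprintf("design failure (%s): no primer candidates in region",
                  orientation))
  }
  pairs <- tidyr::expand_grid(f = seq_len(nrow(fc)), r = seq_len(nrow(rc_)))
  fs <- fc$start[pairs$f]; fl <- fc$len[pairs$f]
  rs <- rc_$start[pairs$r]; rl <- rc_$len[pairs$r]
  psize <- if (orientation == "convergent") {
    (rs + rl - 1L) - fs + 1L
  } else {
    (n - fs + 1L) + (rs + rl - 1L)
  }
  no_overlap <- if (orientation == "convergent") {
    rs > fs + fl - 1L
  } else {
    fs > rs + rl - 1L
  }
  dtm <- abs(fc$tm[pairs$f] - rc_$tm[pairs$r])
  ok <- which(psize >= product[1] & psize <= product[2] & no_overlap &
                dtm <= max_dtm)
  if (length(ok) == 0) {
    abort(sprintf(
      paste0("design failure (%s): no pair with product in [%d, %d] and ",
             "dTm <= %g (fwd region %d-%d: %d candidates, rev region: %d)"),
      orientation, product[1], product[2], max_dtm,
      fwd_region[1], fwd_region[2], nrow(fc), nrow(rc_)))
  }
  best <- ok[order(dtm[ok], abs(psize[ok] - mean(product)), fs[ok])][1]
  tibble(
    fwd = fc$seq[pairs$f[best]],
    rev = revcomp(rc_$seq[pairs$r[best]]),
    fwd_start = fc$start[pairs$f[best]], fwd_len = fc$len[pairs$f[best]],
    rev_start = rc_$start[pairs$r[best]], rev_len = rc_$len[pairs$r[best]],
    tm_fwd = fc$tm[pairs$f[best]], tm_rev = rc_$tm[pairs$r[best]],
    product_size = as.integer(psize[best]))
}

#' Exact in-silico PCR
#'
#' Finds exact binding sites of both primers on both strands of the
#' template and reports an amplicon for every inward-facing combination up
#' to `max_product` bp. Circular templates are searched across the origin;
#' amplicons never exceed one full turn of the circle.
#'
#' @param fwd,rev Primer sequences (5'->3').
#' @param template Template sequence.
#' @param circular Treat the template as circular.
#' @param max_product Maximum amplicon size (bp).
#' @return Tibble: `fwd_pos`, `rev_pos` (5' binding positions on the
#'   template's plus strand), `size`, `sequence`, `crosses_origin`. Zero
#'   rows = no product.
#' @export
insilico_pcr <- function(fwd, rev, template, circular = FALSE,
                         max_product = 5000) {
  n <- nchar(template)
  search_space <- if (circular) paste0(template, template) else template
  find_sites <- function(p) {
    hits <- stringr::str_locate_all(search_space, stringr::fixed(p))[[1]]
    st <- hits[, 1]
    if (circular) st <- st[st <= n]
    st
  }
  amps <- list()
  add_amp <- function(f_start, plus_len, r_end) {
    # f_start: plus-strand 5' of the extending primer;
    # r_end: plus-strand position where the reverse primer's rc ends
    size <- r_end - f_start + 1L
    if (circular) {
      if (size <= 0L) size <- size + n
      if (size > n) return()
    } else if (size <= 0L) return()
    if (size > max_product) return()
    seq <- if (r_end <= nchar(search_space)) {
      substr(search_space, f_start, f_start + size - 1L)
    } else NA_character_
    amps[[length(amps) + 1L]] <<- tibble(
      fwd_pos = ((f_start - 1L) %% n) + 1L,
      rev_pos = ((r_end - 1L) %% n) + 1L,
      size = as.integer(size), sequence = seq,
      crosses_origin = circular && (f_start + size - 1L > n))
  }
  f_plus <- find_sites(fwd)
  r_rc <- find_sites(revcomp(rev))
  for (f in f_plus) {
    for (r in r_rc) {
      r_end <- r + nchar(rev) - 1L
      if (circular || r_end >= f) add_amp(f, nchar(fwd), r_end)
    }
  }
  # swapped roles: rev extends on the plus strand, fwd binds as rc
  r_plus <- find_sites(rev)
  f_rc <- find_sites(revcomp(fwd))
  for (f in r_plus) {
    for (r in f_rc) {
      r_end <- r + nchar(fwd) - 1L
      if (circular || r_end >= f) add_amp(f, nchar(rev), r_end)
    }
  }
  if (length(amps) == 0) {
    return(tibble(fwd_pos = integer(), rev_pos = integer(),
                  size = integer(), sequence = character(),
                  crosses_origin = logical()))
  }
  bind_rows(amps) %>%
    distinct(.data$fwd_pos, .data$rev_pos, .data$size, .keep_all = TRUE) %>%
    filter(.data$size > nchar(fwd), .data$size > nchar(rev)) %>%
    arrange(.data$size)
}
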