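# reverse complement in RNA space (A-U, G-C), 5'->3'
rna_rc <- function(x) {
  chartr("ACGU", "UGCA",
         vapply(strsplit(x, ""), function(v) paste(rev(v), collapse = ""),
                character(1)))
}

test_that("penalty scores match hand-computed values on enumerated patterns", {
  m <- "ACGUACGUACGUACGUACGUA"  # 21 nt
  perfect <- rna_rc(m)          # target 5'->3'
  site35 <- function(site) {
    # helper: present the target 3'->5' aligned with the miRNA 5'->3'
    vapply(strsplit(site, ""), function(v) paste(rev(v), collapse = ""),
           character(1))
  }
  p <- site35(perfect)
  subst <- function(s, i, ch) { substr(s, i, i) <- ch; s }
  cases <- list(
    # 1: perfect 21-mer duplex
    list(m = m, t = p, exp = 0),
    # 2: G:U wobble at miRNA position 15 (outside the core): 0.5
    list(m = m, t = subst(p, 15, "U"), exp = 0.5),   # m[15] = G pairs U
    # 3: G:U wobble at position 5 (core): doubled to 1.0
    list(m = m, t = subst(p, 5, "U"), exp = 1.0),    # m[5] = A... see below
    # 4: mismatch at position 3 (core) = 2.0
    list(m = m, t = subst(p, 3, "A"), exp = 2.0),
    # 5: mismatch at position 20 (outside core) = 1.0 (m[20] = U vs C)
    list(m = m, t = subst(p, 20, "C"), exp = 1.0),
    # 6: target gap at position 18 = 2.0
    list(m = m, t = subst(p, 18, "-"), exp = 2.0),
    # 7: target gap at position 10 (core) = 4.0
    list(m = m, t = subst(p, 10, "-"), exp = 4.0),
    # 8: mismatch at 3 (2.0) + gap at 18 (2.0) = 4.0
    list(m = m, t = subst(subst(p, 3, "A"), 18, "-"), exp = 4.0),
    # 9: two U:G wobbles, positions 4 (core, 1.0) and 16 (0.5): 1.5
    list(m = m, t = subst(subst(p, 4, "G"), 16, "G"), exp = 1.5),
    # 10: three core mismatches: 6.0
    list(m = m, t = subst(subst(subst(p, 4, "C"), 6, "C"), 8, "C"),
         exp = 6.0),
    # 11: miRNA gap between positions 13 and 14 (attributed to 14): 2.0
    list(m = paste0(substr(m, 1, 13), "-", substr(m, 14, 21)),
         t = paste0(substr(p, 1, 13), "A", substr(p, 14, 21)), exp = 2.0)
  )
  # fix case 3: make the wobble legal -- m[5] is A, so use position 7 (G)
  cases[[3]] <- list(m = m, t = subst(p, 7, "U"), exp = 1.0)
  for (i in seq_along(cases)) {
    expect_equal(score_alignment(cases[[i]]$m, cases[[i]]$t),
                 cases[[i]]$exp,
                 info = sprintf("pattern %d", i))
  }
  expect_error(score_alignment("ACGUX", "ACGUA"), "non-RNA")
  expect_error(score_alignment("ACGU", "ACGUA"), "equal length")
})

test_that("scoring depends only on the pairing pattern", {
  # swapping the strand roles (the target becomes the query, both strands
  # reread in their own 5'->3' sense) preserves every pair's status
  # (match/wobble/mismatch), so with uniform position weights the score is
  # identical
  revs <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
  withr::with_seed(20, {
    for (rep in 1:20) {
      m <- paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE),
                 collapse = "")
      t35 <- paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE),
                   collapse = "")
      s1 <- score_alignment(m, t35, core = c(0, 0))
      s2 <- score_alignment(revs(t35), revs(m), core = c(0, 0))
      expect_equal(s2, s1)
    }
  })
})

test_that("exact complements are found, including across the junction", {
  mir <- "UGGAGUGUGACAAUGGUGUUUG"  # 22 nt
  target <- chartr("U", "T", rna_rc(mir))
  withr::with_seed(21, {
    pad <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")
    # site fully internal
    circ1 <- paste0(pad(40), target, pad(60))
    hits1 <- scan_targets(tibble::tibble(mirna_id = "m1", sequence = mir),
                          c(c1 = circ1), cutoff = 5)
    expect_equal(nrow(hits1), 1)
    expect_equal(hits1$expectation, 0)
    expect_equal(hits1$site_start, 41L)
    expect_equal(hits1$site_end, 62L)
    # the same site split across the back-splice junction
    circ2 <- paste0(substr(target, 12, 22), pad(100),
                    substr(target, 1, 11))
    hits2 <- scan_targets(tibble::tibble(mirna_id = "m1", sequence = mir),
                          c(c2 = circ2), cutoff = 5)
    hit0 <- hits2[hits2$expectation == 0, ]
    expect_equal(nrow(hit0), 1)
    expect_equal(hit0$site_start, nchar(circ2) - 10L)
    expect_equal(hit0$site_end, 11L)  # wraps the junction
  })
})

test_that("wrap-around planted sites are always recovered", {
  withr::with_seed(22, {
    found <- 0
    for (rep in 1:100) {
      mir <- paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE),
                   collapse = "")
      target <- chartr("U", "T", rna_rc(mir))
      cut <- sample(2:20, 1)  # split point inside the site
      mid <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                   collapse = "")
      circ <- paste0(substr(target, cut + 1, 21), mid,
                     substr(target, 1, cut))
      hits <- scan_targets(tibble::tibble(mirna_id = "m", sequence = mir),
                           c(c = circ), cutoff = 0, allow_gap = FALSE)
      if (any(hits$expectation == 0 &
                hits$site_start > hits$site_end)) found <- found + 1
    }
    expect_equal(found, 100)
  })
})

test_that("random sequences yield no hits at cutoff 0 and the cutoff is monotone", {
  withr::with_seed(23, {
    mir <- paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE),
                 collapse = "")
    circ <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                  collapse = "")
    h0 <- scan_targets(tibble::tibble(mirna_id = "m", sequence = mir),
                       c(c = circ), cutoff = 0)
    expect_equal(nrow(h0), 0)
    h_lo <- scan_targets(tibble::tibble(mirna_id = "m", sequence = mir),
                         c(c = circ), cutoff = 8)
    h_hi <- scan_targets(tibble::tibble(mirna_id = "m", sequence = mir),
                         c(c = circ), cutoff = 12)
    expect_true(all(h_lo$site_start %in% h_hi$site_start))
    expect_true(all(h_hi$expectation <= 12))
  })
})

test_that("site collapse equals brute-force enumeration on short sequences", {
  withr::with_seed(24, {
    for (rep in 1:10) {
      mir <- paste(sample(c("A", "C", "G", "U"), 20, replace = TRUE),
                   collapse = "")
      circ <- paste(sample(c("A", "C", "G", "T"), 250, replace = TRUE),
                    collapse = "")
      cutoff <- 11
      hits <- scan_targets(tibble::tibble(mirna_id = "m", sequence = mir),
                           c(c = circ), cutoff = cutoff, allow_gap = FALSE)
      # brute force: score every window, then greedy best-first collapse
      n <- nchar(circ); Lm <- nchar(mir)
      padded <- paste0(circ, substr(circ, 1, Lm - 1))
      t35 <- function(w) {
        paste(rev(strsplit(substr(padded, w, w + Lm - 1), "")[[1]]),
              collapse = "")
      }
      sc <- vapply(1:n, function(w) score_alignment(mir, t35(w)),
                   numeric(1))
      cand <- which(sc <= cutoff)
      ord <- cand[order(sc[cand], cand)]
      occ <- rep(FALSE, n); keep <- integer(0)
      for (w in ord) {
        span <- ((w - 1) + seq_len(Lm) - 1) %% n + 1
        if (!any(occ[span])) { occ[span] <- TRUE; keep <- c(keep, w) }
      }
      expect_setequal(hits$site_start, keep)
      expect_equal(hits$expectation[order(hits$site_start)],
                   sc[sort(keep)])
    }
  })
})

test_that("sponge multiplicity tables count distinct pairs", {
  hits <- tibble::tibble(
    mirna_id = c("m1", "m1", "m2", "m1"),
    circ_id = c("c1", "c2", "c1", "c1"),  # duplicate (m1, c1)
    site_start = 1L, site_end = 20L, expectation = 0,
    alignment = "")
  ss <- sponge_summary(hits)
  expect_equal(ss$mirna$n_circ[ss$mirna$mirna_id == "m1"], 2L)
  expect_equal(ss$mirna$n_circ[ss$mirna$mirna_id == "m2"], 1L)
  expect_equal(ss$circ$n_mirna[ss$circ$circ_id == "c1"], 2L)
  # sorted descending, ties lexicographic
  expect_equal(ss$mirna$mirna_id, c("m1", "m2"))
  empty <- sponge_summary(hits[0, ])
  expect_equal(nrow(empty$mirna), 0)
  expect_equal(nrow(empty$circ), 0)
})

test_that("miRNA inputs are validated and an empty set returns empty output", {
  expect_equal(nrow(scan_targets(tibble::tibble(mirna_id = character(),
                                                sequence = character()),
                                 c(c = strrep("A", 100)))), 0)
  expect_error(scan_targets(tibble::tibble(mirna_id = "m",
                                           sequence = "ACGU"),
                            c(c = strrep("A", 100))), "18-26")
})
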