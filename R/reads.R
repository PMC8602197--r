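#' Describe the tissue/replicate sampling design of a simulated experiment
#'
#' Captures the study layout the read simulator emulates: a set of tissues
#' with biological replicates, per-tissue abundance multipliers applied to
#' each circle's base abundance, a negative-binomial dispersion for junction
#' read counts (variance `mu + phi * mu^2`), and the fraction of linear
#' transcript reads surviving RNase R depletion.
#'
#' @param tissues Character vector of tissue names.
#' @param replicates Replicates per tissue (>= 1).
#' @param multipliers Named numeric, one non-negative multiplier per tissue.
#' @param dispersion Negative-binomial dispersion phi (>= 0); 0 = Poisson.
#' @param linear_retention Fraction of linear reads surviving RNase R, in
#'   \[0, 1\].
#' @param min_junction_reads Guaranteed minimum junction reads per circle in
#'   every sample where its expected abundance is positive (coverage floor
#'   for validation designs; 0 disables).
#' @return A `sample_design` list.
#' @export
sample_design <- function(tissues = c("leaf", "root", "stem"),
                          replicates = 3,
                          multipliers = c(leaf = 1, root = 4, stem = 2),
                          dispersion = 0.2, linear_retention = 0.05,
                          min_junction_reads = 0) {
  stopifnot(replicates >= 1, all(multipliers >= 0), dispersion >= 0,
            linear_retention >= 0, linear_retention <= 1)
  if (!all(tissues %in% names(multipliers))) {
    abort("every tissue needs an abundance multiplier")
  }
  structure(list(tissues = tissues, replicates = as.integer(replicates),
                 multipliers = multipliers[tissues],
                 dispersion = dispersion,
                 linear_retention = linear_retention,
                 min_junction_reads = as.integer(min_junction_reads)),
            class = "sample_design")
}

design_samples <- function(design) {
  tidyr::expand_grid(tissue = design$tissues,
                     replicate = seq_len(design$replicates)) %>%
    mutate(sample = sprintf("%s_R%d", .data$tissue, .data$replicate)) %>%
    select("sample", "tissue", "replicate")
}

#' Simulate paired-end RNase R-depleted RNA-seq reads with back-splice
#' junction reads
#'
#' For each sample of the design, emits (a) linear-transcript read pairs per
#' gene, thinned by the RNase R retention fraction, and (b) back-splice
#' junction read pairs per planted circRNA, with counts drawn
#' negative-binomially around `base_abundance * multiplier[tissue]`. Mate 1
#' of a junction pair crosses the back-splice with at least `anchor` nt on
#' both sides; for exonic circles both genomic anchors stay inside the
#' junction-flanking exons so a two-segment split aligner can detect them.
#' Mate 2 is drawn from a non-crossing window of the circle. Base-call
#' errors are uniform substitutions; correct bases get Q37, error bases Q12.
#'
#' @param genome A `genome_model` (as adjusted by [plant_circrnas()]).
#' @param truth Truth tibble from [plant_circrnas()].
#' @param design A [sample_design()].
#' @param read_len Read length in nt (>= `2 * anchor`).
#' @param error_rate Per-base substitution probability in \[0, 0.05\].
#' @param seed Integer seed; output is deterministic per seed.
#' @param anchor Minimum junction overhang (nt) guaranteed on each side.
#' @param linear_mean Pre-depletion mean fragment count per gene.
#' @param fastq_dir If non-`NULL`, write per-sample `\{sample\}_R1.fastq` /
#'   `_R2.fastq` files there.
#' @return List with `reads` (tibble: `sample`, `id`, `mate`, `sequence`,
#'   `quality`, `is_junction`, `circ_id`), `truth_counts` (tibble: `circ_id`,
#'   `sample`, `n_junction_reads`), `library_sizes` (tibble: `sample`,
#'   `total_reads`) and `samples` (the design grid).
#' @export
simulate_reads <- function(genome, truth, design = sample_design(),
                           read_len = 150, error_rate = 0, seed = 1,
                           anchor = 20, linear_mean = 100,
                           fastq_dir = NULL) {
  if (read_len < 2 * anchor) {
    abort(sprintf("configuration error: read_len (%d) must be >= 2 * anchor (%d)",
                  read_len, 2 * anchor))
  }
  stopifnot(error_rate >= 0, error_rate <= 0.05)
  samples <- design_samples(design)
  withr::with_seed(seed, {
    gene_expr <- setNames(rlnorm(nrow(genome$genes), 0, 0.5),
                          genome$genes$gene_id)
    tx <- setNames(lapply(genome$genes$gene_id, transcript_seq,
                          genome = genome), genome$genes$gene_id)
    circ_seqs <- setNames(
      mapply(.circ_seq, truth$scaffold, truth$start, truth$end,
             truth$true_class, truth$host_gene,
             MoreArgs = list(genome = genome)),
      truth$circ_id)

    # per-circle junction offset window (exonic anchors confined to the
    # junction-flanking exons)
    u_window <- lapply(seq_len(nrow(truth)), function(i) {
      n <- nchar(circ_seqs[[truth$circ_id[i]]])
      if (truth$true_class[i] == "exonic") {
        segs <- circ_segments(genome, truth$scaffold[i], truth$start[i],
                              truth$end[i], "exonic", truth$host_gene[i])
        first_seg <- segs$cend[1] - segs$cstart[1] + 1L
        last_seg <- segs$cend[nrow(segs)] - segs$cstart[nrow(segs)] + 1L
      } else {
        first_seg <- n; last_seg <- n
      }
      lo <- max(anchor, read_len - first_seg)
      hi <- min(read_len - anchor, last_seg, n)
      lo <- max(lo, read_len - n)
      if (lo > hi) {
        abort(sprintf(
          "circle %s too short for read_len %d with anchor %d",
          truth$circ_id[i], read_len, anchor))
      }
      c(lo, hi)
    })

    all_reads <- list(); all_counts <- list()
    for (si in seq_len(nrow(samples))) {
      smp <- samples$sample[si]; tis <- samples$tissue[si]
      ids <- character(0); m1 <- character(0); m2 <- character(0)
      isj <- logical(0); src <- character(0)

      # junction read pairs
      mu <- truth$base_abundance * design$multipliers[[tis]]
      nj <- rnb_counts(nrow(truth), mu, design$dispersion)
      nj[mu > 0] <- pmax(nj[mu > 0], design$min_junction_reads)
      for (i in seq_len(nrow(truth))) {
        if (nj[i] == 0) next
        cs <- circ_seqs[[truth$circ_id[i]]]; n <- nchar(cs)
        uw <- u_window[[i]]
        u <- sample_vec(seq(uw[1], uw[2]), nj[i], replace = TRUE)
        r1 <- paste0(substring(cs, n - u + 1, n),
                     substring(cs, 1, read_len - u))
        v <- sample.int(n - read_len + 1L, nj[i], replace = TRUE)
        r2 <- revcomp(substring(cs, v, v + read_len - 1L))
        ids <- c(ids, sprintf("circ:%s:%s:%d|bsj", smp, truth$circ_id[i],
                              seq_len(nj[i])))
        m1 <- c(m1, r1); m2 <- c(m2, r2)
        isj <- c(isj, rep(TRUE, nj[i]))
        src <- c(src, rep(truth$circ_id[i], nj[i]))
      }
      all_counts[[smp]] <- tibble(circ_id = truth$circ_id, sample = smp,
                                  n_junction_reads = nj)

      # linear transcript read pairs (RNase R-thinned)
      for (gid in names(tx)) {
        t <- tx[[gid]]; L <- nchar(t)
        if (L < read_len) next
        nf <- rpois(1, linear_mean * gene_expr[[gid]] *
                      design$multipliers[[tis]] * design$linear_retention)
        if (nf == 0) next
        p1 <- sample.int(L - read_len + 1L, nf, replace = TRUE)
        p2 <- sample.int(L - read_len + 1L, nf, replace = TRUE)
        ids <- c(ids, sprintf("lin:%s:%s:%d", smp, gid, seq_len(nf)))
        m1 <- c(m1, substring(t, p1, p1 + read_len - 1L))
        m2 <- c(m2, revcomp(substring(t, p2, p2 + read_len - 1L)))
        isj <- c(isj, rep(FALSE, nf))
        src <- c(src, rep(NA_character_, nf))
      }

      reads <- tibble(
        sample = smp,
        id = rep(ids, 2L),
        mate = rep(c(1L, 2L), each = length(ids)),
        sequence = c(m1, m2),
        is_junction = c(isj, rep(FALSE, length(isj))),
        circ_id = c(src, rep(NA_character_, length(src)))
      )
      err <- apply_seq_errors(reads$sequence, error_rate)
      reads$sequence <- err$sequence
      reads$quality <- err$quality
      all_reads[[smp]] <- reads
    }
    reads <- bind_rows(all_reads) %>%
      select("sample", "id", "mate", "sequence", "quality",
             "is_junction", "circ_id")
    out <- list(
      reads = reads,
      truth_counts = bind_rows(all_counts),
      library_sizes = reads %>% count(.data$sample, name = "total_reads"),
      samples = samples
    )
    if (!is.null(fastq_dir)) write_fastq(reads, fastq_dir)
    out
  })
}

#' @noRd
#' Uniform substitution errors; Q37 for correct bases, Q12 for error bases.
apply_seq_errors <- function(seqs, error_rate) {
  qual <- strrep("F", nchar(seqs))  # phred+33, Q37
  if (error_rate > 0) {
    n_err <- rbinom(length(seqs), nchar(seqs), error_rate)
    hit <- which(n_err > 0)
    for (i in hit) {
      pos <- sample.int(nchar(seqs[i]), n_err[i])
      for (p in pos) {
        cur <- substr(seqs[i], p, p)
        substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, cur), 1)
        substr(qual[i], p, p) <- "-"  # Q12
      }
    }
  }
  list(sequence = seqs, quality = qual)
}

#' Write simulated reads as paired FASTQ (phred+33)
#'
#' @param reads Reads tibble as produced by [simulate_reads()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_fastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (smp in unique(reads$sample)) {
    for (m in c(1L, 2L)) {
      r <- reads %>% filter(.data$sample == smp, .data$mate == m) %>%
        arrange(.data$id)
      path <- file.path(dir, sprintf("%s_R%d.fastq", smp, m))
      x <- Biostrings::DNAStringSet(r$sequence)
      names(x) <- sprintf("%s/%d", r$id, m)
      Biostrings::writeXStringSet(
        x, path, format = "fastq",
        qualities = Biostrings::BStringSet(r$quality))
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}

#' Read a FASTQ file into a reads tibble
#'
#' @param path FASTQ path (optionally gzipped).
#' @param sample Sample label attached to the reads.
#' @param mate Mate number (1 or 2).
#' @return Tibble with `sample`, `id`, `mate`, `sequence`, `quality`.
#' @export
read_fastq <- function(path, sample = "S1", mate = 1L) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble(sample = sample,
         id = sub("/[12]$", "", names(x)),
         mate = as.integer(mate),
         sequence = as.character(x),
         quality = as.character(S4Vectors::mcols(x)$qualities))
}
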