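test_that("simulated genomes respect bounds, gaps and gene structure", {
  g <- simulate_genome(1, 50000, 10, c(3, 8), seed = 1)
  expect_equal(nrow(g$genes), 10)
  expect_true(all(g$exons$start >= 1 & g$exons$end <= 50000))
  expect_true(all(g$exons$start <= g$exons$end))
  # exons sorted, non-overlapping within genes
  for (gid in g$genes$gene_id) {
    ex <- g$exons[g$exons$gene_id == gid, ]
    expect_true(all(diff(ex$start) > 0))
    expect_true(all(ex$start[-1] > ex$end[-nrow(ex)]))
  }
  # genes non-overlapping with >= 500 nt intergenic gaps
  gs <- g$genes[order(g$genes$start), ]
  expect_true(all(gs$start[-1] - gs$end[-nrow(gs)] - 1 >= 500))
  expect_true(all(grepl("^[ACGT]+$", g$seqs)))
})

test_that("a gene-free genome is valid and writes a FASTA/GFF3 pair", {
  g <- simulate_genome(1, 5000, 0, c(3, 8), seed = 5)
  expect_equal(nrow(g$genes), 0)
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_genome(g, fa, gff)
  expect_true(file.exists(fa) && file.exists(gff))
  expect_identical(readLines(gff)[1], "##gff-version 3")
})

test_that("genome simulation is byte-identical for a fixed seed", {
  fa1 <- tempfile(); gff1 <- tempfile(); fa2 <- tempfile(); gff2 <- tempfile()
  write_genome(simulate_genome(2, 20000, 6, c(3, 6), seed = 7), fa1, gff1)
  write_genome(simulate_genome(2, 20000, 6, c(3, 6), seed = 7), fa2, gff2)
  expect_identical(readLines(fa1), readLines(fa2))
  expect_identical(readLines(gff1), readLines(gff2))
  g3 <- simulate_genome(2, 20000, 6, c(3, 6), seed = 8)
  expect_false(identical(as.character(g3$seqs[1]),
                         as.character(simulate_genome(2, 20000, 6, c(3, 6),
                                                      seed = 7)$seqs[1])))
})

test_that("genomes round-trip through FASTA/GFF3", {
  g <- simulate_genome(2, 20000, 6, c(3, 6), seed = 7)
  fa <- tempfile(); gff <- tempfile()
  write_genome(g, fa, gff)
  g2 <- read_genome(fa, gff)
  expect_identical(g2$seqs, g$seqs)
  expect_equal(as.data.frame(g2$exons[order(g2$exons$gene_id, g2$exons$start), ]),
               as.data.frame(g$exons[order(g$exons$gene_id, g$exons$start), ]))
})

test_that("oversized gene requests fail with a sizing error naming the scaffold", {
  expect_error(simulate_genome(1, 5000, 40, c(5, 8), seed = 1),
               "scf1")
})

test_that("planted circRNAs have the requested classes and legal placements", {
  g <- simulate_genome(2, 50000, 12, c(3, 8), seed = 2)
  p <- plant_circrnas(g, 20, 5, 5, seed = 3)
  expect_equal(as.integer(table(p$truth$true_class)[c("exonic", "intronic",
                                                      "intergenic")]),
               c(20L, 5L, 5L))
  expect_true(all(p$truth$circ_id ==
                    paste(p$truth$scaffold, p$truth$start, p$truth$end,
                          sep = "-")))
  # exonic circles start/end exactly on exon boundaries of the host gene
  ex <- p$truth[p$truth$true_class == "exonic", ]
  for (i in seq_len(nrow(ex))) {
    gx <- p$genome$exons[p$genome$exons$gene_id == ex$host_gene[i], ]
    expect_true(ex$start[i] %in% gx$start)
    expect_true(ex$end[i] %in% gx$end)
    expect_lte(sum(gx$end >= ex$start[i] & gx$start <= ex$end[i]), 5)
  }
  # intronic circles lie strictly inside one intron of the host gene
  intr <- p$truth[p$truth$true_class == "intronic", ]
  for (i in seq_len(nrow(intr))) {
    gx <- p$genome$exons[p$genome$exons$gene_id == intr$host_gene[i], ]
    expect_false(any(gx$end >= intr$start[i] & gx$start <= intr$end[i]))
  }
  # intergenic circles overlap no gene
  ig <- p$truth[p$truth$true_class == "intergenic", ]
  for (i in seq_len(nrow(ig))) {
    gn <- p$genome$genes[p$genome$genes$scaffold == ig$scaffold[i], ]
    expect_false(any(gn$end >= ig$start[i] & gn$start <= ig$end[i]))
  }
})

test_that("planted classes round-trip through junction classification", {
  # property: over several seeds, >= 200 plantings all reclassify to truth
  total <- 0
  for (s in 1:3) {
    g <- simulate_genome(3, 50000, 18, c(3, 8), seed = s)
    p <- plant_circrnas(g, 50, 10, 10, seed = s + 10)
    ann <- classify_junctions(p$truth[, c("scaffold", "start", "end")],
                              p$genome)
    expect_identical(ann$circ_class, p$truth$true_class)
    host <- ifelse(is.na(p$truth$host_gene), NA_character_,
                   p$truth$host_gene)
    expect_identical(ann$parent_gene, host)
    total <- total + nrow(p$truth)
  }
  expect_gte(total, 200)
})

test_that("degenerate planting cases work", {
  # one intergenic circle on a gene-free genome
  g0 <- simulate_genome(1, 5000, 0, c(1, 1), seed = 1)
  p0 <- plant_circrnas(g0, 0, 0, 1, seed = 2)
  expect_equal(p0$truth$true_class, "intergenic")
  # one exonic circle on a single-exon gene spans exactly that exon
  g1 <- simulate_genome(1, 5000, 1, c(1, 1), seed = 3,
                        exon_len = c(200, 200))
  p1 <- plant_circrnas(g1, 1, 0, 0, seed = 4)
  expect_equal(p1$truth$start, g1$exons$start[1])
  expect_equal(p1$truth$end, g1$exons$end[1])
  # capacity errors
  expect_error(plant_circrnas(g0, 1, 0, 0, seed = 1), "capacity")
  expect_error(plant_circrnas(g1, 0, 5, 0, seed = 1), "capacity")
})

test_that("junction reads are exact flank concatenations at error rate 0", {
  ex <- small_experiment(seed = 11)
  cs <- circ_sequences(ex$genome,
                       classify_junctions(ex$truth[, c("scaffold", "start",
                                                       "end")], ex$genome))
  jr <- ex$sim$reads[ex$sim$reads$is_junction, ]
  expect_gt(nrow(jr), 0)
  ok <- vapply(seq_len(nrow(jr)), function(i) {
    circ <- cs[[jr$circ_id[i]]]
    # read = tail(circ, u) + head(circ, L - u) for some legal u
    any(vapply(20:130, function(u) {
      jr$sequence[i] == paste0(substr(circ, nchar(circ) - u + 1, nchar(circ)),
                               substr(circ, 1, 150 - u))
    }, logical(1)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("zero abundance in a tissue yields zero junction reads there", {
  g <- simulate_genome(1, 50000, 6, c(3, 6), seed = 4)
  p <- plant_circrnas(g, 4, 0, 0, seed = 5)
  des <- sample_design(tissues = c("leaf", "root"), replicates = 2,
                       multipliers = c(leaf = 0, root = 2), dispersion = 0)
  sim <- simulate_reads(p$genome, p$truth, des, seed = 6)
  leaf <- sim$truth_counts[grepl("^leaf", sim$truth_counts$sample), ]
  expect_true(all(leaf$n_junction_reads == 0))
  root <- sim$truth_counts[grepl("^root", sim$truth_counts$sample), ]
  expect_gt(sum(root$n_junction_reads), 0)
})

test_that("emitted junction reads are conserved and deterministic", {
  ex <- small_experiment(seed = 21)
  flagged <- sum(ex$sim$reads$is_junction)
  expect_equal(flagged, sum(ex$sim$truth_counts$n_junction_reads))
  # determinism: identical seeds give byte-identical FASTQ
  d1 <- tempfile(); d2 <- tempfile()
  sim_a <- simulate_reads(ex$genome, ex$truth, ex$design, seed = 33,
                          fastq_dir = d1)
  sim_b <- simulate_reads(ex$genome, ex$truth, ex$design, seed = 33,
                          fastq_dir = d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }
  # FASTQ round-trips through the reader
  rt <- read_fastq(f1[1])
  expect_equal(nrow(rt), sum(sim_a$reads$sample == "leaf_R1" &
                               sim_a$reads$mate == 1))
  expect_true(all(nchar(rt$sequence) == 150))
})

test_that("expected junction reads scale with the tissue multiplier", {
  g <- simulate_genome(2, 50000, 10, c(3, 6), seed = 8)
  p <- plant_circrnas(g, 30, 10, 10, seed = 9)
  des <- sample_design(tissues = c("leaf", "root"), replicates = 1,
                       multipliers = c(leaf = 1, root = 8),
                       dispersion = 1e-9)
  sim <- simulate_reads(p$genome, p$truth, des, seed = 10)
  tc <- sim$truth_counts
  leaf <- sum(tc$n_junction_reads[tc$sample == "leaf_R1"])
  root <- sum(tc$n_junction_reads[tc$sample == "root_R1"])
  # Poisson totals: root ~ Pois(8 * lambda), leaf ~ Pois(lambda)
  lambda <- sum(p$truth$base_abundance)
  se <- sqrt(8 * lambda + 64 * lambda)  # SE of root - 8 * leaf
  expect_lt(abs(root - 8 * leaf), 3 * se)
})

test_that("read simulation rejects incompatible read geometry", {
  ex <- small_experiment(seed = 31)
  expect_error(simulate_reads(ex$genome, ex$truth, ex$design,
                              read_len = 30, anchor = 20),
               "read_len")
  expect_error(simulate_reads(ex$genome, ex$truth, ex$design,
                              error_rate = 0.2), "error_rate")
})
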