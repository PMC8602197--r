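# Fixtures and independent oracles shared across test files.

# A small handcrafted genome: one scaffold, a plus-strand and a
# minus-strand gene with known exon structure, built from seeded random
# sequence.
toy_genome <- function(seed = 42, len = 5000) {
  seq <- withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  })
  genes <- tibble::tibble(
    gene_id = c("G1", "G2"),
    scaffold = "chr",
    strand = c("+", "-"),
    start = c(101L, 1001L),
    end = c(600L, 1450L)
  )
  exons <- tibble::tibble(
    gene_id = c("G1", "G1", "G1", "G2", "G2"),
    scaffold = "chr",
    strand = c("+", "+", "+", "-", "-"),
    exon = c(1L, 2L, 3L, 1L, 2L),
    start = c(101L, 301L, 501L, 1001L, 1301L),
    end = c(200L, 400L, 600L, 1150L, 1450L)
  )
  structure(list(seqs = c(chr = seq), genes = genes, exons = exons),
            class = "genome_model")
}

# a fully simulated small experiment reused by several test files
small_experiment <- function(seed = 7, n_exonic = 8, n_intronic = 3,
                             n_intergenic = 3, replicates = 2,
                             min_junction_reads = 4) {
  g <- simulate_genome(2, 50000, 12, c(3, 8), seed = seed)
  p <- plant_circrnas(g, n_exonic, n_intronic, n_intergenic, seed = seed + 1)
  des <- sample_design(replicates = replicates, dispersion = 0,
                       min_junction_reads = min_junction_reads)
  sim <- simulate_reads(p$genome, p$truth, des, seed = seed + 2)
  list(genome = p$genome, truth = p$truth, design = des, sim = sim)
}

# brute-force junction classification by direct interval scan
classify_oracle <- function(scaffold, start, end, genome) {
  exonic_hit <- function(pos) {
    ex <- genome$exons
    unique(ex$gene_id[ex$scaffold == scaffold & ex$start <= pos &
                        ex$end >= pos])
  }
  both <- intersect(exonic_hit(start), exonic_hit(end))
  if (length(both) >= 1) return(list(class = "exonic", gene = sort(both)[1]))
  gn <- genome$genes
  inside <- gn$gene_id[gn$scaffold == scaffold & gn$start <= start &
                         gn$end >= end]
  if (length(inside) >= 1) {
    return(list(class = "intronic", gene = sort(inside)[1]))
  }
  list(class = "intergenic", gene = NA_character_)
}

# textbook two-pass Pearson correlation
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# sort / cummin Benjamini-Hochberg oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# exact hypergeometric upper tail by enumeration (small backgrounds)
hyper_oracle <- function(k, K, N, n) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

rc <- function(x) {
  chartr("ACGTU", "TGCAA",
         vapply(strsplit(x, ""), function(v) paste(rev(v), collapse = ""),
                character(1)))
}
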