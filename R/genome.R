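#' Simulate a multi-scaffold genome with multi-exon gene models
#'
#' Generates random scaffolds of A/C/G/T and places non-overlapping,
#' multi-exon gene models on them, leaving intergenic gaps. The result is the
#' coordinate frame for planting circRNAs, simulating reads and annotating
#' detected back-splice junctions. All coordinates are 1-based inclusive.
#'
#' Genes are distributed round-robin over scaffolds. Each gene gets a random
#' strand, `exons_per_gene` exons with lengths drawn uniformly from
#' `exon_len`, and introns drawn uniformly from `intron_len`. Placement fails
#' with an informative error if the requested genes do not fit on a scaffold
#' while keeping every intergenic gap at least `intergenic_gap` nt.
#'
#' @param n_scaffolds Number of scaffolds.
#' @param scaffold_len Length of each scaffold in nt (>= 5000).
#' @param n_genes Total number of genes across all scaffolds.
#' @param exons_per_gene Length-2 integer range, exons drawn uniformly.
#' @param seed Integer seed; identical calls are byte-identical.
#' @param exon_len,intron_len Length-2 ranges (nt) for exon/intron sizes.
#' @param intergenic_gap Minimum gap (nt) between genes and scaffold ends.
#' @return A `genome_model`: list with `seqs` (named character vector of
#'   scaffold sequences), `genes` (tibble: `gene_id`, `scaffold`, `strand`,
#'   `start`, `end`) and `exons` (tibble: `gene_id`, `scaffold`, `strand`,
#'   `exon` rank in genomic order, `start`, `end`).
#' @examples
#' g <- simulate_genome(1, 50000, 10, c(3, 8), seed = 1)
#' nrow(g$genes)
#' @export
simulate_genome <- function(n_scaffolds = 5, scaffold_len = 50000,
                            n_genes = 30, exons_per_gene = c(3, 8),
                            seed = 1, exon_len = c(80, 250),
                            intron_len = c(150, 500),
                            intergenic_gap = 500) {
  stopifnot(scaffold_len >= 5000, n_scaffolds >= 1, n_genes >= 0,
            length(exons_per_gene) == 2, exons_per_gene[1] >= 1)
  withr::with_seed(seed, {
    scf_names <- sprintf("scf%d", seq_len(n_scaffolds))
    seqs <- setNames(vapply(scf_names, function(.) random_dna(scaffold_len),
                            character(1)), scf_names)
    gene_scf <- if (n_genes > 0) scf_names[(seq_len(n_genes) - 1) %% n_scaffolds + 1] else character(0)
    genes <- list(); exons <- list()
    for (s in scf_names) {
      idx <- which(gene_scf == s)
      if (length(idx) == 0) next
      structs <- lapply(idx, function(i) {
        ne <- sample_vec(seq(exons_per_gene[1], exons_per_gene[2]), 1)
        el <- sample_vec(seq(exon_len[1], exon_len[2]), ne, replace = TRUE)
        il <- if (ne > 1) sample_vec(seq(intron_len[1], intron_len[2]), ne - 1,
                                 replace = TRUE) else integer(0)
        list(exon_len = el, intron_len = il, len = sum(el) + sum(il))
      })
      k <- length(idx)
      need <- sum(vapply(structs, `[[`, numeric(1), "len")) +
        (k + 1) * intergenic_gap
      if (need > scaffold_len) {
        abort(sprintf(
          "requested genes do not fit on scaffold %s: need %d nt, have %d",
          s, need, scaffold_len))
      }
      slack <- scaffold_len - need
      extra <- if (slack > 0) {
        as.integer(stats::rmultinom(1, slack, rep(1, k + 1)))
      } else rep(0L, k + 1)
      pos <- intergenic_gap + extra[1] + 1
      for (j in seq_len(k)) {
        st <- structs[[j]]
        gid <- sprintf("gene%03d", idx[j])
        strand <- sample(c("+", "-"), 1)
        e_start <- integer(0); e_end <- integer(0); p <- pos
        for (e in seq_along(st$exon_len)) {
          e_start[e] <- p
          e_end[e] <- p + st$exon_len[e] - 1
          p <- e_end[e] + 1 + if (e < length(st$exon_len)) st$intron_len[e] else 0
        }
        genes[[gid]] <- tibble(gene_id = gid, scaffold = s, strand = strand,
                               start = e_start[1], end = e_end[length(e_end)])
        exons[[gid]] <- tibble(gene_id = gid, scaffold = s, strand = strand,
                               exon = seq_along(e_start),
                               start = e_start, end = e_end)
        pos <- e_end[length(e_end)] + 1 + intergenic_gap + extra[j + 1]
      }
    }
    genes <- if (length(genes)) bind_rows(genes) else
      tibble(gene_id = character(), scaffold = character(),
             strand = character(), start = integer(), end = integer())
    exons <- if (length(exons)) bind_rows(exons) else
      tibble(gene_id = character(), scaffold = character(),
             strand = character(), exon = integer(),
             start = integer(), end = integer())
    structure(list(seqs = seqs, genes = genes, exons = exons),
              class = "genome_model")
  })
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d scaffold(s), %s nt total, %d gene(s)\n",
              length(x$seqs), format(sum(nchar(x$seqs)), big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

#' Write a genome model to FASTA and GFF3
#'
#' FASTA is wrapped at 60 columns; GFF3 carries `gene` and `exon` features
#' with `ID`/`Parent` attributes. Output is deterministic for a fixed genome.
#'
#' @param genome A `genome_model`.
#' @param fasta,gff3 Output paths (either may be `NULL` to skip).
#' @return Invisibly, the genome.
#' @export
write_genome <- function(genome, fasta = NULL, gff3 = NULL) {
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seqs),
                                fasta, width = 60L)
  }
  if (!is.null(gff3)) {
    g <- genome$genes
    e <- genome$exons
    gr <- GenomicRanges::GRanges(
      c(g$scaffold, e$scaffold),
      IRanges::IRanges(c(g$start, e$start), c(g$end, e$end)),
      strand = c(g$strand, e$strand),
      seqlengths = nchar(genome$seqs),
      type = c(rep("gene", nrow(g)), rep("exon", nrow(e))),
      ID = c(g$gene_id, sprintf("%s.exon%d", e$gene_id, e$exon)))
    gr$Parent <- c(rep(NA_character_, nrow(g)), e$gene_id)
    if (length(gr) == 0) {
      writeLines("##gff-version 3", gff3)
    } else {
      rtracklayer::export(sort(gr), gff3, format = "gff3")
    }
  }
  invisible(genome)
}

#' Read a genome model from FASTA and GFF3
#'
#' Inverse of [write_genome()]: expects `gene` and `exon` features with
#' `ID`/`Parent` attributes.
#'
#' @param fasta,gff3 Input paths.
#' @return A `genome_model`.
#' @export
read_genome <- function(fasta, gff3) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  seqs <- setNames(as.character(seqs), sub("\\s.*", "", names(seqs)))
  gr <- rtracklayer::import(gff3, format = "gff3")
  is_exon <- gr$type == "exon"
  parent <- as.character(unlist(gr$Parent[is_exon]))
  e <- tibble(
    gene_id = parent,
    scaffold = as.character(GenomicRanges::seqnames(gr)[is_exon]),
    strand = as.character(GenomicRanges::strand(gr)[is_exon]),
    start = GenomicRanges::start(gr)[is_exon],
    end = GenomicRanges::end(gr)[is_exon]
  ) %>%
    arrange(.data$gene_id, .data$start) %>%
    group_by(.data$gene_id) %>%
    mutate(exon = row_number()) %>%
    ungroup() %>%
    select("gene_id", "scaffold", "strand", "exon", "start", "end")
  g <- e %>%
    group_by(.data$gene_id, .data$scaffold, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") %>%
    select("gene_id", "scaffold", "strand", "start", "end") %>%
    arrange(.data$gene_id)
  structure(list(seqs = seqs, genes = g, exons = e), class = "genome_model")
}

# exons of one gene, genomic order
gene_exons <- function(genome, gene_id) {
  genome$exons[genome$exons$gene_id == gene_id, , drop = FALSE]
}

# spliced transcript sequence of a gene, 5'->3' in gene orientation
transcript_seq <- function(genome, gene_id) {
  ex <- gene_exons(genome, gene_id)
  s <- paste(mapply(function(a, b) scf_seq(genome, ex$scaffold[1], a, b),
                    ex$start, ex$end),
             collapse = "")
  if (ex$strand[1] == "-") revcomp(s) else s
}
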