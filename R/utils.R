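# shared internal helpers

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# sample from the elements of x (safe for length-1 x, unlike sample())
sample_vec <- function(x, n, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

#' @noRd
#' Draw counts from a negative binomial with variance mu + phi * mu^2.
#' phi -> 0 degenerates to Poisson.
rnb_counts <- function(n, mu, phi) {
  mu <- rep_len(mu, n)
  out <- integer(n)
  pos <- mu > 0
  if (!any(pos)) return(out)
  if (phi <= 1e-8) {
    out[pos] <- rpois(sum(pos), mu[pos])
  } else {
    out[pos] <- rnbinom(sum(pos), size = 1 / phi, mu = mu[pos])
  }
  out
}

# substring of a scaffold, 1-based inclusive
scf_seq <- function(genome, scaffold, start, end) {
  substr(genome$seqs[[scaffold]], start, end)
}

# length of the common prefix of two equal-semantics strings, compared
# bytewise; `b` may be shorter than `a`
common_prefix_len <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  m <- min(length(ra), length(rb))
  if (m == 0L) return(0L)
  d <- which(ra[seq_len(m)] != rb[seq_len(m)])
  if (length(d) == 0L) m else d[1L] - 1L
}

assert_columns <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(x)
}

circ_id <- function(scaffold, start, end) {
  paste(scaffold, start, end, sep = "-")
}
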