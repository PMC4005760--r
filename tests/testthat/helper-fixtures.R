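# Small fixture builders used across test files.

# peak frame from summit positions (one chromosome)
peaks_at <- function(summits, chrom = "chr1", halfwidth = 10, fe = 1, q = 5) {
  n <- length(summits)
  summits <- as.integer(summits)
  data.frame(chrom = rep_len(chrom, n), start = summits - as.integer(halfwidth),
             end = summits + as.integer(halfwidth),
             name = sprintf("p%d", seq_len(n)), score = rep_len(0, n),
             strand = rep_len(".", n),
             fold_enrichment = rep_len(fe, n), neg_log10_p = rep_len(-1, n),
             neg_log10_q = rep_len(q, n), summit = summits,
             stringsAsFactors = FALSE)
}

# peak frame from explicit intervals
peaks_iv <- function(start, end, chrom = "chr1", fe = 1, q = 5) {
  n <- length(start)
  data.frame(chrom = chrom, start = start, end = end,
             name = sprintf("p%d", seq_len(n)), score = 0, strand = ".",
             fold_enrichment = rep_len(fe, n), neg_log10_p = -1,
             neg_log10_q = rep_len(q, n),
             summit = (start + end) %/% 2, stringsAsFactors = FALSE)
}

one_peak <- function(start, end, chrom = "chr1") {
  list(chrom = chrom, start = start, end = end)
}

# a genome made of one chromosome with a given sequence
genome_of <- function(seq, chrom = "chr1") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- chrom
  g
}

# random A/C/G/T string
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# the 4 unambiguous expansions of the DR3 consensus with N bases fixed to A
dr3_expansions <- function(n_base = "A") {
  tmpl <- sprintf("%%sGGTCA%s%sG%%sGTTCA", n_base, n_base)
  c(sprintf(tmpl, "A", "A"), sprintf(tmpl, "A", "G"),
    sprintf(tmpl, "G", "A"), sprintf(tmpl, "G", "G"))
}

# plant sequences into a random background chromosome at given 0-based starts
plant_into <- function(len, plants) {
  seq <- random_dna(len)
  for (p in plants) {
    substr(seq, p$start + 1, p$start + nchar(p$seq)) <- p$seq
  }
  seq
}
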