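# Independent oracles used across the suite.  Each deliberately takes a
# different route than the implementation it checks.

# Whole-protein translation via the Biostrings genetic-code table
# (independent of the package's own code table): chunk a CDS by 3 and
# look codons up.
oracle_translate <- function(cds) {
  code <- Biostrings::getGeneticCode("2")  # vertebrate mitochondrial
  n <- nchar(cds) %/% 3L
  vapply(seq_len(n), function(k)
    unname(code[[substr(cds, 3L * k - 2L, 3L * k)]]), character(1))
}

# Brute-force global alignment score by exhaustive recursion (sequences
# of length <= 8).
oracle_align_score <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0L)
    best <- -Inf
    if (i > 0L && j > 0L) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1L, j - 1L) + s)
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  as.integer(rec(nchar(a), nchar(b)))
}

# Two-sided Fisher p by direct factorial-ratio enumeration over all
# admissible tables with the observed margins.
oracle_fisher <- function(a, b, c, d) {
  m <- a + c; n <- b + d; r <- a + b
  if (r == 0L || r == m + n) return(1)
  lp <- function(x)  # log point probability from factorials
    lfactorial(m) - lfactorial(x) - lfactorial(m - x) +
    lfactorial(n) - lfactorial(r - x) - lfactorial(n - r + x) -
    (lfactorial(m + n) - lfactorial(r) - lfactorial(m + n - r))
  support <- max(0L, r - n):min(r, m)
  p <- exp(vapply(support, lp, numeric(1)))
  sum(p[p <= exp(lp(a)) * (1 + 1e-7)])
}

# A small two-gene genome with one H-strand and one L-strand CDS built
# by hand (not via make_genome), for annotation tests.
hand_genome <- function(seed = 11L) {
  set.seed(seed)
  feats <- gene_features(
    gene = c("ND1", "CO1", "tRNA-Phe"),
    start = c(10L, 130L, 250L), end = c(99L, 219L, 290L),
    strand = c("H", "L", "H"), kind = c("CDS", "CDS", "tRNA"),
    genome_length = 300L)
  sense <- {
    code <- mito_genetic_code()
    setdiff(names(code)[code != "*"], c("ATG", "ATA"))
  }
  orf <- function(n_codons)
    paste0("ATG", paste(sample(sense, n_codons - 2L, TRUE), collapse = ""), "TAA")
  chars <- sample(c("A", "C", "G", "T"), 300L, TRUE)
  chars[10:99] <- strsplit(orf(30L), "")[[1]]
  chars[130:219] <- strsplit(revcomp(orf(30L)), "")[[1]]
  list(genome = circular_genome("hand", sequence = paste(chars, collapse = "")),
       features = feats)
}

# strip class/attributes for plain value comparison of variant tables
plain_variants <- function(v) {
  d <- data.frame(position = v$position, ref = v$ref, alt = v$alt,
                  kind = v$kind, stringsAsFactors = FALSE)
  d <- d[order(d$position, d$ref, d$alt), , drop = FALSE]
  rownames(d) <- NULL
  d
}
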