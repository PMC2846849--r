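# Circular mitogenome model: sequence container, strand-aware gene
# features, circular coordinate arithmetic, codon framing.
#
# All coordinates are 1-based inclusive, matching rCRS position numbering
# (m.10398 etc.).  A feature may wrap the origin (start > end); wrapped
# offsets are computed modulo the genome length.

#' Circular genome container
#'
#' A lightweight container for a circular DNA molecule.  The sequence is
#' optional: coordinate-only genomes (length known, bases unknown) support
#' every operation that does not need bases, e.g. codon-index arithmetic.
#'
#' @param name Text identifier.
#' @param length Positive integer, genome size in bases.  Derived from
#'   `sequence` when omitted.
#' @param sequence Optional DNA string over `{A,C,G,T,N}` of exactly
#'   `length` bases.
#' @return Object of class `circular_genome` with fields `name`, `length`,
#'   `sequence` (possibly `NA`).
#' @examples
#' g <- circular_genome("toy", sequence = "ACGTACGTAA")
#' g$length
#' @export
circular_genome <- function(name, length = NULL, sequence = NULL) {
  if (!is.null(sequence)) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    sequence <- toupper(sequence)
    if (grepl("[^ACGTN]", sequence))
      stop("sequence contains characters outside {A,C,G,T,N}")
    if (is.null(length)) length <- nchar(sequence)
    if (nchar(sequence) != length)
      stop("sequence length (", nchar(sequence),
           ") does not match declared length (", length, ")")
  }
  length <- as.integer(length)
  if (is.na(length) || length <= 0L) stop("genome length must be positive")
  structure(list(name = as.character(name), length = length,
                 sequence = if (is.null(sequence)) NA_character_ else sequence),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat("<circular_genome> ", x$name, ": ", x$length, " bp",
      if (is.na(x$sequence)) " (coordinates only)" else "", "\n", sep = "")
  invisible(x)
}

#' Read a single-record FASTA as a circular genome
#'
#' @param path Path to a FASTA file with exactly one record.
#' @return A [circular_genome()].
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L)
    stop("expected a single-record FASTA, found ", length(ss), " records")
  circular_genome(sub("\\s.*$", "", names(ss)[1]),
                  sequence = as.character(ss[[1]]))
}

#' Construct a gene feature table
#'
#' Validates and normalizes a table of strand-aware gene features
#' (CDS / tRNA / rRNA intervals with OXPHOS-complex assignment).
#'
#' @param gene Character, gene symbols (e.g. `"ND3"`, `"tRNA-Leu(CUN)"`).
#' @param start,end 1-based inclusive genomic positions.  `start > end` is
#'   permitted only for a feature wrapping the origin.
#' @param strand `"H"` (heavy, genomic sense) or `"L"` (light, reverse
#'   complement).
#' @param kind `"CDS"`, `"tRNA"` or `"rRNA"`.
#' @param complex OXPHOS complex: `"I"`, `"III"`, `"IV"`, `"V"`, or `"RNA"`
#'   for non-coding genes.  Inferred from the gene symbol when missing.
#' @param incomplete_stop Logical; `TRUE` for CDS whose stop codon is
#'   completed by polyadenylation (a trailing partial codon of 1-2 bases).
#' @param genome_length Optional genome length used to validate wrapped
#'   features and CDS framing.
#' @return A `data.frame` of class `gene_features`.
#' @export
gene_features <- function(gene, start, end, strand, kind,
                          complex = NULL, incomplete_stop = FALSE,
                          genome_length = NULL) {
  n <- length(gene)
  start <- as.integer(start); end <- as.integer(end)
  strand <- as.character(strand); kind <- as.character(kind)
  incomplete_stop <- rep_len(as.logical(incomplete_stop), n)
  stopifnot(length(start) == n, length(end) == n, length(strand) == n,
            length(kind) == n)
  if (!all(strand %in% c("H", "L"))) stop("strand must be 'H' or 'L'")
  if (!all(kind %in% c("CDS", "tRNA", "rRNA")))
    stop("kind must be CDS, tRNA or rRNA")
  if (is.null(complex)) complex <- complex_for_gene(gene, kind)
  complex <- as.character(complex)
  bad <- (kind != "CDS" & complex != "RNA") | (kind == "CDS" & complex == "RNA")
  if (any(bad)) stop("complex must be 'RNA' for exactly the non-CDS features: ",
                     paste(gene[bad], collapse = ", "))
  wrapped <- start > end
  if (sum(wrapped) > 1L)
    stop("at most one feature may wrap the origin")
  if (any(wrapped) && is.null(genome_length))
    stop("genome_length is required when a feature wraps the origin")
  len <- feature_span(start, end, genome_length)
  # CDS framing: full codons plus, when incomplete_stop, a 1-2 base tail
  is_cds <- kind == "CDS"
  tail_len <- len[is_cds] %% 3L
  ok <- ifelse(incomplete_stop[is_cds], tail_len %in% 1:2, tail_len == 0L)
  if (!all(ok))
    stop("CDS length incompatible with codon framing: ",
         paste(gene[is_cds][!ok], collapse = ", "))
  structure(data.frame(gene = as.character(gene), start = start, end = end,
                       strand = strand, kind = kind, complex = complex,
                       incomplete_stop = incomplete_stop,
                       stringsAsFactors = FALSE),
            class = c("gene_features", "data.frame"))
}

# span of a (possibly wrapped) 1-based inclusive interval
feature_span <- function(start, end, genome_length = NULL) {
  ifelse(start <= end, end - start + 1L,
         end + (if (is.null(genome_length)) NA_integer_ else genome_length) -
           start + 1L)
}

#' Infer OXPHOS complex from a gene symbol
#'
#' `ND*` genes belong to complex I, `CYB` to III, `CO*` to IV, `ATPase*`
#' (or `ATP*`) to V; tRNA/rRNA genes are classed `"RNA"`.
#'
#' @param gene Character vector of gene symbols.
#' @param kind Optional feature kinds; any non-CDS kind forces `"RNA"`.
#' @return Character vector of complex labels.
#' @export
complex_for_gene <- function(gene, kind = NULL) {
  out <- rep(NA_character_, length(gene))
  g <- toupper(gene)
  out[grepl("^ND", g)] <- "I"
  out[grepl("^CYB|^CYTB", g)] <- "III"
  out[grepl("^CO", g)] <- "IV"
  out[grepl("^ATP", g)] <- "V"
  out[grepl("RNA|^12S|^16S", g)] <- "RNA"
  if (!is.null(kind)) out[kind != "CDS"] <- "RNA"
  if (anyNA(out))
    stop("cannot infer complex for gene(s): ",
         paste(gene[is.na(out)], collapse = ", "))
  out
}

#' Read a gene feature table from TSV
#'
#' Expected columns: `gene`, `start`, `end`, `strand`, `kind`, `complex`,
#' `incomplete_stop`.
#'
#' @param path Path to a tab-separated file.
#' @param genome_length Optional genome length (see [gene_features()]).
#' @return A `gene_features` data frame.
#' @export
read_feature_table <- function(path, genome_length = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "start", "end", "strand", "kind")
  if (!all(need %in% names(df)))
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  gene_features(df$gene, df$start, df$end, df$strand, df$kind,
                complex = if ("complex" %in% names(df)) df$complex else NULL,
                incomplete_stop = if ("incomplete_stop" %in% names(df))
                  df$incomplete_stop else FALSE,
                genome_length = genome_length)
}

#' Embedded rCRS (NC_012920) gene layout
#'
#' The 37-gene annotation of the revised Cambridge Reference Sequence:
#' 13 protein-coding genes, 22 tRNAs and 2 rRNAs, with strand, OXPHOS
#' complex and incomplete-stop flags.  The D-loop / control region is not a
#' gene and is not included; no embedded feature wraps the origin.
#' Coordinates are 1-based inclusive on the 16,569-bp circle.
#'
#' @return A `gene_features` data frame with 37 rows.
#' @examples
#' f <- rcrs_features()
#' table(f$kind)
#' @export
rcrs_features <- function() {
  # gene, start, end, strand, kind, incomplete_stop
  tab <- list(
    list("tRNA-Phe",        577L,   647L, "H", "tRNA", FALSE),
    list("12S rRNA",        648L,  1601L, "H", "rRNA", FALSE),
    list("tRNA-Val",       1602L,  1670L, "H", "tRNA", FALSE),
    list("16S rRNA",       1671L,  3229L, "H", "rRNA", FALSE),
    list("tRNA-Leu(UUR)",  3230L,  3304L, "H", "tRNA", FALSE),
    list("ND1",            3307L,  4262L, "H", "CDS",  TRUE),
    list("tRNA-Ile",       4263L,  4331L, "H", "tRNA", FALSE),
    list("tRNA-Gln",       4329L,  4400L, "L", "tRNA", FALSE),
    list("tRNA-Met",       4402L,  4469L, "H", "tRNA", FALSE),
    list("ND2",            4470L,  5511L, "H", "CDS",  TRUE),
    list("tRNA-Trp",       5512L,  5579L, "H", "tRNA", FALSE),
    list("tRNA-Ala",       5587L,  5655L, "L", "tRNA", FALSE),
    list("tRNA-Asn",       5657L,  5729L, "L", "tRNA", FALSE),
    list("tRNA-Cys",       5761L,  5826L, "L", "tRNA", FALSE),
    list("tRNA-Tyr",       5826L,  5891L, "L", "tRNA", FALSE),
    list("CO1",            5904L,  7445L, "H", "CDS",  FALSE),
    list("tRNA-Ser(UCN)",  7446L,  7514L, "L", "tRNA", FALSE),
    list("tRNA-Asp",       7518L,  7585L, "H", "tRNA", FALSE),
    list("CO2",            7586L,  8269L, "H", "CDS",  FALSE),
    list("tRNA-Lys",       8295L,  8364L, "H", "tRNA", FALSE),
    list("ATPase8",        8366L,  8572L, "H", "CDS",  FALSE),
    list("ATPase6",        8527L,  9207L, "H", "CDS",  FALSE),
    list("CO3",            9207L,  9990L, "H", "CDS",  TRUE),
    list("tRNA-Gly",       9991L, 10058L, "H", "tRNA", FALSE),
    list("ND3",           10059L, 10404L, "H", "CDS",  TRUE),
    list("tRNA-Arg",      10405L, 10469L, "H", "tRNA", FALSE),
    list("ND4L",          10470L, 10766L, "H", "CDS",  FALSE),
    list("ND4",           10760L, 12137L, "H", "CDS",  TRUE),
    list("tRNA-His",      12138L, 12206L, "H", "tRNA", FALSE),
    list("tRNA-Ser(AGY)", 12207L, 12265L, "H", "tRNA", FALSE),
    list("tRNA-Leu(CUN)", 12266L, 12336L, "H", "tRNA", FALSE),
    list("ND5",           12337L, 14148L, "H", "CDS",  FALSE),
    list("ND6",           14149L, 14673L, "L", "CDS",  FALSE),
    list("tRNA-Glu",      14674L, 14742L, "L", "tRNA", FALSE),
    list("CYB",           14747L, 15887L, "H", "CDS",  TRUE),
    list("tRNA-Thr",      15888L, 15953L, "H", "tRNA", FALSE),
    list("tRNA-Pro",      15956L, 16023L, "L", "tRNA", FALSE))
  m <- do.call(rbind, lapply(tab, function(r)
    data.frame(gene = r[[1]], start = r[[2]], end = r[[3]], strand = r[[4]],
               kind = r[[5]], incomplete_stop = r[[6]],
               stringsAsFactors = FALSE)))
  gene_features(m$gene, m$start, m$end, m$strand, m$kind,
                incomplete_stop = m$incomplete_stop, genome_length = 16569L)
}

#' rCRS genome length
#' @return 16569L
#' @export
rcrs_length <- function() 16569L

# 0-based offset of `position` within a (possibly wrapped) feature,
# NA when outside.
.feature_offset <- function(start, end, position, genome_length) {
  if (start <= end) {
    ifelse(position >= start & position <= end, position - start, NA_integer_)
  } else {
    ifelse(position >= start, position - start,
           ifelse(position <= end, position + genome_length - start,
                  NA_integer_))
  }
}

#' Features overlapping a genomic position
#'
#' Returns every feature whose (circularly interpreted) interval contains
#' the query position.  In overlap regions (e.g. ATPase8/ATPase6) several
#' rows are returned; an empty result means the position is intergenic.
#'
#' @param features A `gene_features` data frame.
#' @param position 1-based genomic position.
#' @param genome_length Genome length for circular arithmetic (defaults to
#'   [rcrs_length()]).
#' @return Subset of `features` (possibly zero rows).
#' @examples
#' feature_at(rcrs_features(), 10398)$gene  # "ND3"
#' @export
feature_at <- function(features, position, genome_length = rcrs_length()) {
  position <- as.integer(position)
  stopifnot(length(position) == 1L)
  if (is.na(position) || position < 1L || position > genome_length)
    stop("position ", position, " outside genome [1, ", genome_length, "]")
  off <- mapply(.feature_offset, features$start, features$end,
                MoreArgs = list(position = position,
                                genome_length = genome_length))
  features[!is.na(off), , drop = FALSE]
}

#' Extract a feature's sequence on its coding strand
#'
#' @param feature One-row `gene_features` subset (or list with `start`,
#'   `end`, `strand`).
#' @param genome A [circular_genome()] with sequence.
#' @return Character scalar: the feature sequence, reverse-complemented for
#'   L-strand features.
#' @export
feature_sequence <- function(feature, genome) {
  if (is.na(genome$sequence)) stop("genome has no sequence")
  L <- genome$length
  idx <- if (feature$start <= feature$end) feature$start:feature$end
         else c(feature$start:L, 1:feature$end)
  s <- paste(strsplit(genome$sequence, "")[[1]][idx], collapse = "")
  if (feature$strand == "L") revcomp(s) else s
}

#' Codon context of a position inside a CDS
#'
#' Computes the codon index (1-based, on the coding strand), the within-
#' codon offset (0/1/2 on the coding strand) and, when the genome carries
#' sequence, the reference codon.  For H-strand genes the codon index is
#' `floor((position - start)/3) + 1`; for L-strand genes it is
#' `floor((end - position)/3) + 1` and the codon is the reverse complement
#' of the genomic triplet.  Positions falling in the trailing partial codon
#' of an incomplete-stop gene are rejected: those bases are completed by
#' polyadenylation and have no genomic codon.
#'
#' @param feature One-row CDS `gene_features` subset.
#' @param genome A [circular_genome()]; sequence optional (then `ref_codon`
#'   is `NA`).
#' @param position 1-based genomic position inside the feature.
#' @return List with `codon_index`, `offset_in_codon`, `ref_codon`.
#' @examples
#' nd3 <- rcrs_features()[rcrs_features()$gene == "ND3", ]
#' codon_context(nd3, circular_genome("rCRS", 16569), 10398)$codon_index  # 114
#' @export
codon_context <- function(feature, genome, position) {
  if (feature$kind != "CDS")
    stop("codon_context requires a CDS feature, got ", feature$kind)
  L <- genome$length
  position <- as.integer(position)
  off <- .feature_offset(feature$start, feature$end, position, L)
  if (is.na(off))
    stop("position ", position, " outside feature ", feature$gene)
  span <- feature_span(feature$start, feature$end, L)
  n_codons <- span %/% 3L
  # offset on the coding strand
  coff <- if (feature$strand == "H") off else span - 1L - off
  if (coff >= 3L * n_codons)
    stop("position ", position, " falls in the incomplete trailing codon of ",
         feature$gene)
  codon_index <- coff %/% 3L + 1L
  offset_in_codon <- coff %% 3L
  ref_codon <- NA_character_
  if (!is.na(genome$sequence)) {
    cds <- feature_sequence(feature, genome)
    ref_codon <- substr(cds, 3L * (codon_index - 1L) + 1L, 3L * codon_index)
  }
  list(codon_index = codon_index, offset_in_codon = offset_in_codon,
       ref_codon = ref_codon)
}
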