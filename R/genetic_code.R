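# Vertebrate mitochondrial genetic code (NCBI translation table 2) and
# amino-acid name handling.

# Amino acids for the 64 codons in TCAG order (first base slowest), i.e. the
# NCBI table layout.  Differs from the standard code at exactly four codons:
# TGA=W, ATA=M, AGA=*, AGG=*.
.MITO_AA <- "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSS**VVVVAAAADDEEGGGG"

#' Vertebrate mitochondrial genetic code
#'
#' Returns the vertebrate mitochondrial genetic code (NCBI translation
#' table 2) as a named character vector mapping each of the 64 codons to a
#' one-letter amino acid, with `"*"` for stop codons.  Relative to the
#' standard code, TGA encodes Trp, ATA encodes Met, and AGA/AGG are stop
#' codons, leaving 60 sense codons.
#'
#' @return Named character vector of length 64; names are codons over
#'   `{A,C,G,T}`, values are one-letter amino acids or `"*"`.
#' @examples
#' code <- mito_genetic_code()
#' code[["TGA"]]  # "W"
#' code[["AGA"]]  # "*"
#' @export
mito_genetic_code <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  stats::setNames(strsplit(.MITO_AA, "")[[1]], codons)
}

#' Translate a codon under the vertebrate mitochondrial code
#'
#' @param codon Character scalar, a 3-mer over `{A,C,G,T,N}`
#'   (case-insensitive).
#' @param code Genetic code as returned by [mito_genetic_code()].
#' @return One-letter amino acid, `"*"` for stop, or `"X"` (undetermined)
#'   when the codon contains an ambiguous base.
#' @examples
#' translate_codon("TGA")  # "W" (Trp, not stop, in mitochondria)
#' translate_codon("GCC")  # "A" (Ala)
#' @export
translate_codon <- function(codon, code = mito_genetic_code()) {
  stopifnot(is.character(codon), length(codon) == 1L)
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGTN]", codon))
    stop("not a valid codon: '", codon, "'")
  if (grepl("N", codon)) return("X")
  unname(code[[codon]])
}

# one-letter <-> three-letter amino-acid tables
.AA1 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", `*` = "Ter", X = "Xaa")

#' Convert between one- and three-letter amino-acid names
#'
#' `aa_one_letter()` accepts one-letter codes, canonical three-letter names
#' and the spelling variants that occur in printed mitochondrial variant
#' tables ("Iso", "IsoLeu" for isoleucine, doubled names like "SerSer",
#' stray trailing punctuation).
#'
#' @param aa Character vector of amino-acid names.
#' @return Character vector of one-letter codes (`"*"` for stop).
#' @export
aa_one_letter <- function(aa) {
  vapply(aa, function(x) {
    tok <- gsub("[^A-Za-z*]", "", x)
    if (tok %in% names(.AA1)) return(tok)
    low <- tolower(tok)
    # printed-table variants of isoleucine
    if (low %in% c("ile", "iso", "isoleu", "isoleucine")) return("I")
    if (low %in% c("ter", "stop")) return("*")
    hit <- names(.AA1)[match(low, tolower(.AA1))]
    if (!is.na(hit)) return(hit)
    # doubled three-letter name, e.g. "SerSer" -> "S"
    if (nchar(tok) == 6L && tolower(substr(tok, 1, 3)) == tolower(substr(tok, 4, 6)))
      return(aa_one_letter(substr(tok, 1, 3)))
    stop("unrecognized amino-acid name: '", x, "'")
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname aa_one_letter
#' @export
aa_three_letter <- function(aa) {
  one <- aa_one_letter(aa)
  unname(.AA1[one])
}

#' Reverse complement of a DNA string
#'
#' @param x Character scalar over `{A,C,G,T,N}`.
#' @return Reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(toupper(x), "")[[1]]), collapse = ""))
}
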