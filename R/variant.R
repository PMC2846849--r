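# Variant data model and parsing/formatting of the compact notations used
# in mitochondrial case reports: "G10398A", "10398 G>A", "Ins T at 2790".

#' Construct a variant
#'
#' A substitution or insertion on the mitochondrial circle.  Insertions are
#' anchored immediately AFTER `position` (HGVS-style between-position
#' insertion).
#'
#' @param position 1-based genomic position.
#' @param ref Reference base (single base for substitutions, `""` for
#'   insertions).
#' @param alt Alternate base (substitution) or inserted sequence
#'   (insertion).
#' @param kind `"substitution"` or `"insertion"`; inferred from `ref` when
#'   missing.
#' @return A one-row `data.frame` of class `mito_variant` with columns
#'   `position`, `ref`, `alt`, `kind`.
#' @export
variant <- function(position, ref, alt, kind = NULL) {
  position <- as.integer(position)
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (is.null(kind)) kind <- ifelse(nchar(ref) == 0L, "insertion", "substitution")
  stopifnot(length(position) == length(ref), length(ref) == length(alt))
  kind <- rep_len(as.character(kind), length(position))
  for (i in seq_along(position)) {
    if (is.na(position[i]) || position[i] < 1L)
      stop("invalid variant position: ", position[i])
    if (kind[i] == "substitution") {
      if (nchar(ref[i]) != 1L || nchar(alt[i]) != 1L ||
          grepl("[^ACGTN]", ref[i]) || grepl("[^ACGTN]", alt[i]))
        stop("substitution must have single-base ref and alt: ",
             ref[i], position[i], alt[i])
      if (ref[i] == alt[i])
        stop("substitution with ref equal to alt: ", ref[i], position[i], alt[i])
    } else if (kind[i] == "insertion") {
      if (nchar(ref[i]) != 0L)
        stop("insertion must have empty ref")
      if (nchar(alt[i]) < 1L || grepl("[^ACGTN]", alt[i]))
        stop("insertion must have a non-empty inserted sequence")
    } else stop("unknown variant kind: ", kind[i])
  }
  structure(data.frame(position = position, ref = ref, alt = alt, kind = kind,
                       stringsAsFactors = FALSE),
            class = c("mito_variant", "data.frame"))
}

#' Parse a variant token
#'
#' Accepts the three notations used in printed mitochondrial variant
#' tables (case-insensitive):
#' * `"G10398A"` — ref, position, alt;
#' * `"10398 G>A"` (also `"At 10398 G>A"`) — position then base change;
#' * `"Ins T at 2790"` / `"Ins. of T at 2790_91"` — insertion after the
#'   stated position.
#'
#' @param token Character scalar.
#' @return A [variant()].
#' @examples
#' parse_variant("G10398A")
#' parse_variant("Ins T at 2790")
#' @export
parse_variant <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  tok <- trimws(token)
  # insertion: "Ins T at 2790", "Ins. of T at 2790_91 (16sRNA)"
  m <- regmatches(tok, regexec(
    "^[Ii]ns\\.?(?:\\s+of)?\\s+([ACGTNacgtn]+)\\s+at\\s+([0-9]+)",
    tok))[[1]]
  if (length(m)) return(variant(as.integer(m[3]), "", m[2]))
  # "10398 G>A" (optional leading "At")
  m <- regmatches(tok, regexec(
    "^(?:[Aa]t\\s+)?([0-9]+)\\s*([ACGTNacgtn])\\s*>\\s*([ACGTNacgtn])$",
    tok))[[1]]
  if (length(m)) return(variant(as.integer(m[2]), m[3], m[4]))
  # "G10398A"
  m <- regmatches(tok, regexec(
    "^([ACGTNacgtn])\\s*([0-9]+)\\s*([ACGTNacgtn])$", tok))[[1]]
  if (length(m)) return(variant(as.integer(m[3]), m[2], m[4]))
  stop("cannot parse variant token: '", token, "'")
}

#' Format a variant in compact notation
#'
#' Substitutions render as `"G10398A"`, insertions as `"Ins T at 2790"`,
#' round-tripping through [parse_variant()].
#'
#' @param v A [variant()] (one or more rows).
#' @return Character vector of tokens.
#' @export
format_variant <- function(v) {
  ifelse(v$kind == "insertion",
         paste0("Ins ", v$alt, " at ", v$position),
         paste0(v$ref, v$position, v$alt))
}

#' Format an amino-acid change in protein notation
#'
#' Emits `"p.<ref><index><alt>"` with one-letter amino acids, e.g.
#' `"p.A114T"`; synonymous changes repeat the letter (`"p.K120K"`).  Stop
#' codons are written `"*"` and a warning is raised (a nonsense change in
#' mtDNA protein genes is unexpected in this context).
#'
#' @param ref_aa,alt_aa Amino acids, one- or three-letter.
#' @param codon_index 1-based codon (residue) index.
#' @return Character scalar.
#' @examples
#' format_protein_change("Ala", 114, "Thr")  # "p.A114T"
#' @export
format_protein_change <- function(ref_aa, codon_index, alt_aa) {
  r <- aa_one_letter(ref_aa); a <- aa_one_letter(alt_aa)
  if (r == "*" || a == "*")
    warning("stop codon in protein notation at residue ", codon_index)
  paste0("p.", r, as.integer(codon_index), a)
}

#' Deduplicate variants by (position, ref, alt)
#'
#' Variant identity is the triple (position, ref, alt); annotations such as
#' accession numbers are not part of identity.
#'
#' @param v A `mito_variant` data frame.
#' @return `v` with duplicate rows removed.
#' @export
dedup_variants <- function(v) {
  v[!duplicated(paste(v$position, v$ref, v$alt)), , drop = FALSE]
}

#' Read / write a per-sample variant list TSV
#'
#' Columns: `sample_id`, `position`, `ref`, `alt`, `kind`.
#'
#' @param path File path.
#' @param df For writing: data frame with the columns above.
#' @return `read_variant_tsv()` returns the data frame.
#' @export
read_variant_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(ref = "character",
                                         alt = "character"))
  need <- c("sample_id", "position", "ref", "alt", "kind")
  if (!all(need %in% names(df)))
    stop("variant TSV must have columns: ", paste(need, collapse = ", "))
  df$ref[is.na(df$ref)] <- ""
  df
}

#' @rdname read_variant_tsv
#' @export
write_variant_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimal single-sample VCF export
#'
#' Output-only interoperability shim: writes substitutions and insertions
#' as a minimal VCFv4.2 body.  Insertions need the reference base at the
#' anchor position, so a genome with sequence is required when any are
#' present.
#'
#' @param v A `mito_variant` data frame.
#' @param path Output path.
#' @param genome Optional [circular_genome()] with sequence.
#' @param contig Contig name to write (default `"chrM"`).
#' @param sample_id Sample column name.
#' @return `path`, invisibly.
#' @export
write_minimal_vcf <- function(v, path, genome = NULL, contig = "chrM",
                              sample_id = "SAMPLE") {
  lines <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", contig,
                    if (!is.null(genome)) paste0(",length=", genome$length),
                    ">"),
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_id, sep = "\t"))
  rows <- vapply(seq_len(nrow(v)), function(i) {
    if (v$kind[i] == "substitution") {
      ref <- v$ref[i]; alt <- v$alt[i]; pos <- v$position[i]
    } else {
      if (is.null(genome) || is.na(genome$sequence))
        stop("insertion VCF export requires a genome with sequence")
      anchor <- substr(genome$sequence, v$position[i], v$position[i])
      ref <- anchor; alt <- paste0(anchor, v$alt[i]); pos <- v$position[i]
    }
    paste(contig, pos, ".", ref, alt, ".", "PASS", ".", "GT", "1", sep = "\t")
  }, character(1))
  writeLines(c(lines, rows), path)
  invisible(path)
}
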