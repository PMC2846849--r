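# Variant annotation: gene/complex assignment, codon and amino-acid
# effect under the vertebrate mitochondrial code, novelty flagging,
# distribution tallies and reconciliation against printed tables.
#
# Two classification pathways exist and are never mixed silently:
#  * sequence-based  -- codon recomputation from a genome with sequence
#    (annotate()); used for real or synthetic sequence input;
#  * fixture-based   -- effect_from_aa_pair() on a printed amino-acid
#    column; used to reproduce published tallies, because printed tables
#    sometimes contain rows whose codon column and amino-acid column
#    disagree and the published headline counts follow the amino-acid
#    column.

#' Annotate a variant against a genome and feature table
#'
#' Returns one row per overlapping feature.  CDS substitutions get codon
#' index, ref/alt codons, amino acids, effect (synonymous /
#' non-synonymous) and protein notation via [codon_context()] and
#' [translate_codon()].  tRNA/rRNA variants get effect `rna_gene` and no
#' codon fields.  Insertions inside a CDS are annotated gene-level only
#' with effect `non_coding` and `frameshift = TRUE`.  A variant outside
#' every feature yields a single `non_coding` row with `gene = NA`.
#'
#' @param v A one-row [variant()].
#' @param genome A [circular_genome()]; sequence optional (codon change
#'   fields are `NA` without it).
#' @param features A `gene_features` data frame.
#' @param code Genetic code (default vertebrate mitochondrial).
#' @return Data frame of class `annotated_variant` with columns
#'   `position`, `ref`, `alt`, `kind`, `gene`, `complex`, `feature_kind`,
#'   `codon_index`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `effect`, `protein_notation`, `frameshift`.
#' @examples
#' feats <- rcrs_features()
#' g <- circular_genome("rCRS", 16569)
#' annotate(variant(10398, "G", "A"), g, feats)[, c("gene", "codon_index")]
#' @export
annotate <- function(v, genome, features, code = mito_genetic_code()) {
  stopifnot(nrow(v) == 1L)
  if (v$position > genome$length)
    stop("variant position ", v$position, " outside genome")
  hits <- feature_at(features, v$position, genome$length)
  empty_row <- function() data.frame(
    position = v$position, ref = v$ref, alt = v$alt, kind = v$kind,
    gene = NA_character_, complex = NA_character_,
    feature_kind = NA_character_, codon_index = NA_integer_,
    ref_codon = NA_character_, alt_codon = NA_character_,
    ref_aa = NA_character_, alt_aa = NA_character_,
    effect = "non_coding", protein_notation = NA_character_,
    frameshift = FALSE, stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) {
    out <- empty_row()
    class(out) <- c("annotated_variant", "data.frame")
    return(out)
  }
  rows <- lapply(seq_len(nrow(hits)), function(k) {
    f <- hits[k, , drop = FALSE]
    row <- empty_row()
    row$gene <- f$gene; row$complex <- f$complex; row$feature_kind <- f$kind
    if (f$kind != "CDS") {
      row$effect <- "rna_gene"
      return(row)
    }
    if (v$kind == "insertion") {
      row$effect <- "non_coding"; row$frameshift <- TRUE
      return(row)
    }
    ctx <- tryCatch(codon_context(f, genome, v$position),
                    error = function(e) NULL)
    if (is.null(ctx)) {  # trailing partial codon of an incomplete-stop CDS
      row$effect <- "non_coding"
      return(row)
    }
    row$codon_index <- ctx$codon_index
    if (!is.na(ctx$ref_codon)) {
      # base change on the coding strand
      ref_b <- v$ref; alt_b <- v$alt
      if (f$strand == "L") { ref_b <- revcomp(ref_b); alt_b <- revcomp(alt_b) }
      if (substr(ctx$ref_codon, ctx$offset_in_codon + 1L,
                 ctx$offset_in_codon + 1L) != ref_b)
        stop("variant ref base disagrees with genome at ", v$position)
      alt_codon <- ctx$ref_codon
      substr(alt_codon, ctx$offset_in_codon + 1L,
             ctx$offset_in_codon + 1L) <- alt_b
      row$ref_codon <- ctx$ref_codon; row$alt_codon <- alt_codon
      row$ref_aa <- translate_codon(ctx$ref_codon, code)
      row$alt_aa <- translate_codon(alt_codon, code)
      row$effect <- if (row$ref_aa == row$alt_aa) "synonymous" else "non-synonymous"
      row$protein_notation <- suppressWarnings(
        format_protein_change(row$ref_aa, row$codon_index, row$alt_aa))
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("annotated_variant", "data.frame")
  out
}

#' Annotate a set of variants
#'
#' @param v A `mito_variant` data frame.
#' @inheritParams annotate
#' @return Row-bound `annotated_variant` data frame (one or more rows per
#'   input variant in gene-overlap regions).
#' @export
annotate_all <- function(v, genome, features, code = mito_genetic_code()) {
  out <- do.call(rbind, lapply(seq_len(nrow(v)), function(i)
    annotate(v[i, , drop = FALSE], genome, features, code)))
  if (is.null(out)) {
    out <- annotate(variant(1, "A", "C"), circular_genome("x", 2),
                    gene_features(character(0), integer(0), integer(0),
                                  character(0), character(0)))[0, ]
  }
  class(out) <- c("annotated_variant", "data.frame")
  out
}

#' Classify effect from a printed amino-acid pair
#'
#' Fixture-based classification: synonymous iff the normalized amino-acid
#' names are equal.  Handles the spelling variants found in printed tables
#' ("IsoLeu", "Iso", doubled names, stray punctuation) via
#' [aa_one_letter()].
#'
#' @param ref_aa,alt_aa Amino-acid names.
#' @return `"synonymous"` or `"non-synonymous"`.
#' @export
effect_from_aa_pair <- function(ref_aa, alt_aa) {
  ifelse(aa_one_letter(ref_aa) == aa_one_letter(alt_aa),
         "synonymous", "non-synonymous")
}

#' Flag novel variants against a known-variant catalogue
#'
#' @param v A `mito_variant` data frame.
#' @param catalogue A data frame with columns `position`, `ref`, `alt`
#'   (see [default_catalogue()]); an empty catalogue makes everything
#'   novel.
#' @return Logical vector: `TRUE` iff the (position, ref, alt) triple is
#'   absent from the catalogue.
#' @export
flag_novelty <- function(v, catalogue) {
  key <- function(d) paste(d$position, toupper(d$ref), toupper(d$alt))
  !(key(v) %in% key(catalogue))
}

#' Tally an annotated variant set
#'
#' Counts by effect class (synonymous / non-synonymous / RNA gene) and by
#' OXPHOS complex, plus novelty counts when a `novel` column or vector is
#' supplied.
#'
#' @param annotated An `annotated_variant` data frame (or fixture-derived
#'   equivalent with columns `effect` and `complex`).
#' @param novel Optional logical vector aligned with `annotated` rows.
#' @return List of class `tally_report`: `total_variants`, `by_effect`,
#'   `by_complex`, `novel_count`, `novel_nonsyn_count`.
#' @export
tally <- function(annotated, novel = annotated$novel) {
  eff <- annotated$effect
  by_effect <- c(synonymous = sum(eff == "synonymous"),
                 `non-synonymous` = sum(eff == "non-synonymous"),
                 rna_gene = sum(eff == "rna_gene"))
  cx <- annotated$complex
  by_complex <- c(I = sum(cx == "I", na.rm = TRUE),
                  III = sum(cx == "III", na.rm = TRUE),
                  IV = sum(cx == "IV", na.rm = TRUE),
                  V = sum(cx == "V", na.rm = TRUE),
                  RNA = sum(cx == "RNA", na.rm = TRUE))
  novel_count <- if (is.null(novel)) NA_integer_ else sum(novel)
  novel_nonsyn <- if (is.null(novel)) NA_integer_
                  else sum(novel & eff == "non-synonymous")
  structure(list(total_variants = nrow(annotated), by_effect = by_effect,
                 by_complex = by_complex, novel_count = novel_count,
                 novel_nonsyn_count = novel_nonsyn),
            class = "tally_report")
}

#' @export
print.tally_report <- function(x, ...) {
  pct <- function(k) sprintf("%.2f%%", round(100 * k / x$total_variants, 2))
  cat("<tally_report> ", x$total_variants, " variants\n", sep = "")
  for (nm in names(x$by_effect))
    cat("  ", nm, ": ", x$by_effect[[nm]], " (", pct(x$by_effect[[nm]]), ")\n",
        sep = "")
  cat("  complex:", paste(names(x$by_complex), x$by_complex,
                          sep = "=", collapse = " "), "\n")
  if (!is.na(x$novel_count))
    cat("  novel: ", x$novel_count, " (non-syn ", x$novel_nonsyn_count, ")\n",
        sep = "")
  invisible(x)
}

#' Reconcile computed annotation against a printed fixture table
#'
#' Column-by-column comparison of the engine's annotation with a
#' transcribed published table.  Without a reference sequence only the
#' coordinate-derived columns (gene, codon index) are recomputed; the
#' printed codon change, amino-acid change and syn/non-syn label are in
#' addition checked for INTERNAL consistency (does the printed codon pair
#' translate to the printed amino-acid pair?).  Mismatches never raise;
#' they are reported.
#'
#' @param fixture_rows Data frame from [load_fixture()] (`table1` or
#'   `table2`).
#' @param genome A [circular_genome()]; sequence optional.
#' @param features A `gene_features` data frame.
#' @return Data frame of class `reconciliation_report`, one row per
#'   fixture row, with logical columns `gene_match`, `codon_index_match`,
#'   `codon_aa_consistent`, `label_consistent` (NA where not applicable)
#'   and an `n_mismatch` attribute.
#' @export
reconcile <- function(fixture_rows, genome = circular_genome("rCRS", rcrs_length()),
                      features = rcrs_features()) {
  code <- mito_genetic_code()
  res <- lapply(seq_len(nrow(fixture_rows)), function(i) {
    fr <- fixture_rows[i, ]
    v <- if (fr$kind == "insertion") variant(fr$position, "", fr$alt)
         else variant(fr$position, fr$ref, fr$alt)
    ann <- annotate(v, genome, features, code)
    # in overlap regions keep the row matching the printed gene if any
    j <- match(fr$gene, ann$gene); if (is.na(j)) j <- 1L
    ann <- ann[j, ]
    gene_match <- identical(ann$gene, fr$gene) ||
      (startsWith(paste0(ann$gene), sub("\\(.*", "", paste0(fr$gene))))
    codon_index_match <- if (is.na(fr$aa_position) || is.na(ann$codon_index))
      NA else ann$codon_index == fr$aa_position
    codon_aa <- NA
    label_ok <- NA
    if (!is.na(fr$ref_codon) && !is.na(fr$alt_codon)) {
      t_ref <- translate_codon(fr$ref_codon, code)
      t_alt <- translate_codon(fr$alt_codon, code)
      codon_aa <- identical(t_ref, aa_one_letter(fr$ref_aa)) &&
        identical(t_alt, aa_one_letter(fr$alt_aa))
      label_ok <- identical(
        unname(effect_from_aa_pair(fr$ref_aa, fr$alt_aa)),
        fr$effect)
    }
    data.frame(position = fr$position, gene = fr$gene,
               gene_match = gene_match, codon_index_match = codon_index_match,
               codon_aa_consistent = codon_aa, label_consistent = label_ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "n_mismatch") <- sum(!out$gene_match, na.rm = TRUE) +
    sum(!out$codon_index_match, na.rm = TRUE) +
    sum(!out$codon_aa_consistent, na.rm = TRUE) +
    sum(!out$label_consistent, na.rm = TRUE)
  class(out) <- c("reconciliation_report", "data.frame")
  out
}
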