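# Pairwise global alignment and variant calling.  Replaces the external
# multiple-alignment step of a Sanger re-sequencing workflow with an
# internal, testable Needleman-Wunsch aligner: case amplicons are
# near-identical to the reference, so isolated substitutions and short
# insertions are recovered under any sane scoring scheme.

#' Global pairwise alignment
#'
#' Optimal global (Needleman-Wunsch) alignment under linear gap penalties,
#' with deterministic tie-breaking: on equal score the diagonal
#' (match/mismatch) move is preferred over gaps, and a gap in the sample
#' over a gap in the reference.  `N` bases are scored 0 against anything.
#'
#' @param ref_window Reference sequence window (DNA string).
#' @param sample Sample sequence (DNA string).
#' @param match,mismatch,gap Scoring parameters (defaults +1/-1/-2).
#' @param ref_offset 1-based genomic position of the first reference
#'   column, used by [call_variants()] to place calls on the genome.
#' @return An `alignment_result`: list with `aligned_ref`,
#'   `aligned_sample` (equal-length gapped strings), `score`,
#'   `ref_offset`.
#' @export
align_global <- function(ref_window, sample, match = 1L, mismatch = -1L,
                         gap = -2L, ref_offset = 1L) {
  stopifnot(is.character(ref_window), length(ref_window) == 1L,
            is.character(sample), length(sample) == 1L)
  ref_window <- toupper(ref_window); sample <- toupper(sample)
  if (nchar(ref_window) == 0L || nchar(sample) == 0L)
    stop("sequences must be non-empty")
  if (grepl("[^ACGTN]", ref_window) || grepl("[^ACGTN]", sample))
    stop("sequences must be over {A,C,G,T,N}")
  res <- .nw_align_cpp(ref_window, sample, as.integer(match),
                       as.integer(mismatch), as.integer(gap))
  res$ref_offset <- as.integer(ref_offset)
  class(res) <- "alignment_result"
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result> score ", x$score, ", ", nchar(x$aligned_ref),
      " columns, ref offset ", x$ref_offset, "\n", sep = "")
  invisible(x)
}

#' Call variants from a global alignment
#'
#' Mismatch columns become substitutions at genomic positions (adjusted by
#' `ref_offset`); runs of gap-in-reference become insertions anchored
#' after the preceding reference position and are left-normalized (shifted
#' to their left-most equivalent placement).  Runs of gap-in-sample are
#' NOT called as deletions: they are reported in the `uncovered` attribute
#' (a Sanger workflow treats them as missing coverage).  Columns where
#' either base is `N` never produce calls; they are counted in the
#' `n_skipped` attribute.
#'
#' @param alignment An `alignment_result` from [align_global()].
#' @return A `mito_variant` data frame (possibly zero rows) with
#'   attributes `uncovered` (data frame of `start`,`end` reference runs)
#'   and `n_skipped`.
#' @export
call_variants <- function(alignment) {
  ar <- strsplit(alignment$aligned_ref, "")[[1]]
  as_ <- strsplit(alignment$aligned_sample, "")[[1]]
  stopifnot(length(ar) == length(as_))
  refseq <- ar[ar != "-"]
  off <- alignment$ref_offset - 1L

  pos <- integer(0); ref <- character(0); alt <- character(0); kind <- character(0)
  unc_s <- integer(0); unc_e <- integer(0)
  n_skipped <- 0L

  rp <- 0L  # reference bases consumed
  i <- 1L
  ncol <- length(ar)
  while (i <= ncol) {
    if (ar[i] != "-" && as_[i] != "-") {
      rp <- rp + 1L
      if (ar[i] != as_[i]) {
        if (ar[i] == "N" || as_[i] == "N") n_skipped <- n_skipped + 1L
        else {
          pos <- c(pos, rp + off); ref <- c(ref, ar[i]); alt <- c(alt, as_[i])
          kind <- c(kind, "substitution")
        }
      }
      i <- i + 1L
    } else if (ar[i] == "-") {
      ins <- character(0)
      while (i <= ncol && ar[i] == "-") { ins <- c(ins, as_[i]); i <- i + 1L }
      if (any(ins == "N")) { n_skipped <- n_skipped + 1L; next }
      # left-normalize: insertion after rp of S; while the reference base
      # at rp equals the last base of S, rotate S right and move left
      anchor <- rp; S <- ins
      while (anchor >= 1L && refseq[anchor] == S[length(S)]) {
        S <- c(S[length(S)], S[-length(S)])
        anchor <- anchor - 1L
      }
      if (anchor == 0L) { anchor <- rp; S <- ins }  # cannot anchor before window
      pos <- c(pos, anchor + off); ref <- c(ref, "")
      alt <- c(alt, paste(S, collapse = "")); kind <- c(kind, "insertion")
    } else {
      s <- rp + 1L
      while (i <= ncol && i <= length(ar) && ar[i] != "-" && as_[i] == "-") {
        rp <- rp + 1L; i <- i + 1L
      }
      unc_s <- c(unc_s, s + off); unc_e <- c(unc_e, rp + off)
    }
  }
  out <- if (length(pos)) variant(pos, ref, alt, kind)
         else variant(integer(0), character(0), character(0), character(0))
  attr(out, "uncovered") <- data.frame(start = unc_s, end = unc_e)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Apply variants to a reference sequence
#'
#' Substitutions replace the stated base (after checking it matches the
#' reference); insertions insert `alt` immediately after `position`.
#'
#' @param sequence Reference DNA string.
#' @param v A `mito_variant` data frame.
#' @return Mutated sequence (character scalar).
#' @export
apply_variants <- function(sequence, v) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (nrow(v) == 0L) return(paste(chars, collapse = ""))
  subs <- v[v$kind == "substitution", , drop = FALSE]
  for (i in seq_len(nrow(subs))) {
    p <- subs$position[i]
    if (chars[p] != subs$ref[i])
      stop("reference mismatch at ", p, ": expected ", subs$ref[i],
           ", found ", chars[p])
    chars[p] <- subs$alt[i]
  }
  ins <- v[v$kind == "insertion", , drop = FALSE]
  if (nrow(ins)) {
    ins <- ins[order(-ins$position), , drop = FALSE]  # right to left
    for (i in seq_len(nrow(ins))) {
      p <- ins$position[i]
      chars <- append(chars, strsplit(ins$alt[i], "")[[1]], after = p)
    }
  }
  paste(chars, collapse = "")
}

#' Align a sample against a genome and call variants
#'
#' Convenience wrapper: whole-sequence global alignment followed by
#' [call_variants()].
#'
#' @param genome A [circular_genome()] with sequence.
#' @param sample_seq Sample DNA string.
#' @param ... Scoring parameters passed to [align_global()].
#' @return A `mito_variant` data frame.
#' @export
call_sample <- function(genome, sample_seq, ...) {
  if (is.na(genome$sequence)) stop("genome has no sequence")
  call_variants(align_global(genome$sequence, sample_seq, ...))
}

#' Merge variant calls from overlapping amplicon windows
#'
#' Takes per-window call sets and returns their deduplicated union, sorted
#' by position.  With window overlaps exceeding twice the maximum indel
#' length, the merged set equals a whole-genome call set.
#'
#' @param calls List of `mito_variant` data frames.
#' @return A single `mito_variant` data frame.
#' @export
merge_variant_calls <- function(calls) {
  all <- do.call(rbind, lapply(calls, as.data.frame))
  if (is.null(all) || nrow(all) == 0L)
    return(variant(integer(0), character(0), character(0), character(0)))
  all <- all[order(all$position, all$ref, all$alt), , drop = FALSE]
  out <- variant(all$position, all$ref, all$alt, all$kind)
  dedup_variants(out)
}
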