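# Packaged fixture transcriptions of a published PCG case-control mtDNA
# variant study: the per-variant tables for cases (132 rows) and controls
# (58 rows), the per-patient variant/clinical matrix (35 patients) and
# the per-gene carrier-count table (13 rows).  The TSVs are shipped
# exactly as printed -- including typography quirks and internally
# inconsistent rows -- and normalization happens here, in code, where it
# is unit-tested.

.fixture_path <- function(file)
  system.file("extdata", file, package = "mitoburden", mustWork = TRUE)

# canonical gene symbol from a printed gene label
.normalize_gene <- function(g) {
  g <- gsub("\\*", "", g)
  g <- trimws(g)
  g <- gsub("t\\s*RNA\\s*", "tRNA-", g)       # "t RNA Lys", "tRNA Leu"
  g <- sub("^16s\\s*RNA$", "16S rRNA", g, ignore.case = TRUE)
  g <- sub("^12s\\s*RNA$", "12S rRNA", g, ignore.case = TRUE)
  g <- sub("^ATP(\\d)$", "ATPase\\1", g)
  g
}

# digits from a printed position / amino-acid index, tolerating the "At"
# prefix and a letter O standing in for zero
.normalize_int <- function(x) {
  x <- gsub("[Oo]", "0", gsub("^At\\s+", "", trimws(x)))
  x <- gsub("[^0-9]", "", x)
  ifelse(nchar(x) == 0, NA_integer_, suppressWarnings(as.integer(x)))
}

# split a printed codon change "GCC>ACC" (tolerating stray punctuation)
.split_codons <- function(x) {
  x <- gsub("[^ACGTacgt>]", "", x)
  parts <- strsplit(x, ">", fixed = TRUE)
  t(vapply(parts, function(p) {
    if (length(p) == 2 && all(nchar(p) == 3)) toupper(p)
    else c(NA_character_, NA_character_)
  }, character(2)))
}

# split a printed amino-acid change; "SerSer" (no ">") means Ser>Ser
.split_aa <- function(x) {
  x <- trimws(x)
  t(vapply(x, function(s) {
    if (s %in% c("-", "", "–")) return(c(NA_character_, NA_character_))
    p <- strsplit(s, ">", fixed = TRUE)[[1]]
    if (length(p) == 2) return(trimws(p))
    if (nchar(s) == 6) return(c(substr(s, 1, 3), substr(s, 4, 6)))
    c(NA_character_, NA_character_)
  }, character(2), USE.NAMES = FALSE))
}

.load_variant_table <- function(file, expected_rows, has_carriers) {
  raw <- utils::read.delim(.fixture_path(file), stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(raw) != expected_rows)
    stop("fixture corruption: ", file, " has ", nrow(raw),
         " rows, expected ", expected_rows)
  pos <- .normalize_int(raw$position)
  bc <- trimws(raw$base_change)
  ins <- grepl("^Ins", bc, ignore.case = TRUE)
  ref <- ifelse(ins, "", toupper(sub(">.*$", "", bc)))
  alt <- ifelse(ins, toupper(gsub("[^ACGTacgtn]", "", sub("^Ins\\.?", "", bc))),
                toupper(sub("^.*>", "", bc)))
  codons <- .split_codons(raw$codon_change)
  aas <- .split_aa(raw$aa_change)
  gene <- .normalize_gene(raw$gene)
  effect <- ifelse(grepl("RNA", gene), "rna_gene",
                   ifelse(trimws(raw$syn_nonsyn) == "non-syn",
                          "non-synonymous", "synonymous"))
  acc <- trimws(raw$accession)
  out <- data.frame(
    row = .normalize_int(raw$row), position = pos, ref = ref, alt = alt,
    kind = ifelse(ins, "insertion", "substitution"), gene = gene,
    complex = complex_for_gene(gene),
    aa_position = .normalize_int(raw$aa_position),
    ref_codon = codons[, 1], alt_codon = codons[, 2],
    ref_aa = aas[, 1], alt_aa = aas[, 2],
    protein_change = gsub("\\s+", "", sub("^p\\.", "", raw$protein_change)),
    effect = effect,
    accession = ifelse(grepl("^GU\\d+", acc), acc, NA_character_),
    novel = grepl("^GU\\d+", acc),
    at_prefix = grepl("^At\\s", trimws(raw$position)),
    stringsAsFactors = FALSE)
  if (has_carriers) out$carrier_count <- .normalize_int(raw$carrier_count)
  out
}

# parse one token from the per-patient "other changes" column, e.g.
# "A>G at 12308 tRNA Leu", "Ins. of T at 2790_91 (16sRNA)"
.parse_other_token <- function(tok) {
  tok <- trimws(tok)
  if (tok %in% c("-", "", "–")) return(NULL)
  m <- regmatches(tok, regexec(
    "^([ACGTacgtn])\\s*>\\s*([ACGTacgtn])\\s+at\\s+([0-9]+)", tok))[[1]]
  if (length(m)) return(variant(as.integer(m[4]), m[2], m[3]))
  tryCatch(parse_variant(tok), error = function(e) {
    warning("unparseable token in other-changes column: '", tok, "'")
    NULL
  })
}

.load_patient_table <- function(table1) {
  raw <- utils::read.delim(.fixture_path("table3_patient_matrix.tsv"),
                           stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(raw) != 35L)
    stop("fixture corruption: table3 has ", nrow(raw), " rows, expected 35")
  gene_cols <- c("ND1", "ND2", "CO1", "CO2", "ATPase8", "ATPase6", "CO3",
                 "ND3", "ND4L", "ND4", "ND5", "CYB")
  # lookup: gene + normalized protein token -> table1 variant
  t1key <- paste(table1$gene, table1$protein_change)
  lapply(seq_len(nrow(raw)), function(i) {
    tokens <- list(); unresolved <- character(0)
    vs <- list()
    for (g in gene_cols) {
      cell <- raw[[g]][i]
      if (is.na(cell)) next
      toks <- trimws(strsplit(cell, ";")[[1]])
      toks <- toks[!(toks %in% c("-", "", "–"))]
      toks <- gsub("\\s+", "", sub("^p\\.", "", toks))
      if (!length(toks)) next
      tokens[[g]] <- toks
      for (tk in toks) {
        j <- match(paste(g, tk), t1key)
        if (is.na(j)) unresolved <- c(unresolved, paste0(g, ":", tk))
        else vs[[length(vs) + 1L]] <-
            data.frame(position = table1$position[j], ref = table1$ref[j],
                       alt = table1$alt[j], kind = table1$kind[j],
                       gene = g, effect = table1$effect[j],
                       stringsAsFactors = FALSE)
      }
    }
    oc <- raw$other_changes[i]
    if (!is.na(oc)) for (tk in trimws(strsplit(oc, ";")[[1]])) {
      pv <- suppressWarnings(.parse_other_token(tk))
      if (is.null(pv)) { if (!tk %in% c("-", "", "–"))
        unresolved <- c(unresolved, paste0("other:", tk)); next }
      hit <- feature_at(rcrs_features(), pv$position)
      vs[[length(vs) + 1L]] <-
        data.frame(position = pv$position, ref = pv$ref, alt = pv$alt,
                   kind = pv$kind,
                   gene = if (nrow(hit)) hit$gene[1] else NA_character_,
                   effect = "rna_gene", stringsAsFactors = FALSE)
    }
    vdf <- if (length(vs)) do.call(rbind, vs)
           else data.frame(position = integer(0), ref = character(0),
                           alt = character(0), kind = character(0),
                           gene = character(0), effect = character(0))
    vdf <- vdf[!duplicated(paste(vdf$position, vdf$ref, vdf$alt)), ,
               drop = FALSE]
    list(patient_id = as.integer(raw$patient[i]),
         variants = vdf,
         protein_tokens = tokens,
         unresolved = unresolved,
         clinical = list(cup_disc_ratio = raw$cup_disc_ratio[i],
                         corneal_diameter = raw$corneal_diameter[i],
                         iop = raw$iop[i]))
  })
}

.load_carrier_counts <- function() {
  raw <- utils::read.delim(.fixture_path("table4_carrier_counts.tsv"),
                           stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(raw) != 13L)
    stop("fixture corruption: table4 has ", nrow(raw), " rows, expected 13")
  count_of <- function(x) .normalize_int(sub("\\s*\\(.*$", "", x))
  data.frame(gene = .normalize_gene(raw$gene),
             a = count_of(raw$cases), b = count_of(raw$controls),
             p_printed = trimws(raw$p_value),
             rr_printed = trimws(raw$relative_risk_ci),
             stringsAsFactors = FALSE)
}

#' Load a packaged study fixture
#'
#' * `"table1"`: 132 case variants with printed annotation columns;
#' * `"table2"`: 58 control variants;
#' * `"table3"`: 35 patient records (variants resolved against table1
#'   where the printed tokens allow, unresolved tokens kept verbatim,
#'   clinical fields carried as printed);
#' * `"table4_counts"`: 13 per-gene carrier-count rows (cases n=35,
#'   controls n=40) with the printed p-values and relative risks as text.
#'
#' Row counts are validated on load; a mismatch raises a
#' fixture-corruption error.  Printed inconsistencies are preserved, not
#' repaired (see [reconcile()]).
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`,
#'   `"table4_counts"`.
#' @return A data frame (`table1`, `table2`, `table4_counts`) or a list
#'   of patient records (`table3`).
#' @export
load_fixture <- function(name = c("table1", "table2", "table3",
                                  "table4_counts")) {
  name <- match.arg(name)
  switch(name,
    table1 = .load_variant_table("table1_pcg_variants.tsv", 132L, TRUE),
    table2 = .load_variant_table("table2_control_variants.tsv", 58L, FALSE),
    table3 = .load_patient_table(load_fixture("table1")),
    table4_counts = .load_carrier_counts())
}

#' Default known-variant catalogue
#'
#' The packaged catalogue is exactly the non-novel fixture variants (case
#' and control tables combined); no external database is bundled.  A
#' variant absent from this catalogue is flagged novel by
#' [flag_novelty()].
#'
#' @return Data frame with columns `position`, `ref`, `alt`.
#' @export
default_catalogue <- function() {
  t1 <- load_fixture("table1"); t2 <- load_fixture("table2")
  known <- rbind(t1[!t1$novel, c("position", "ref", "alt")],
                 t2[!t2$novel, c("position", "ref", "alt")])
  known[!duplicated(paste(known$position, known$ref, known$alt)), ,
        drop = FALSE]
}

#' Read a known-variant catalogue TSV
#'
#' @param path TSV with columns `position`, `ref`, `alt`.
#' @return Data frame.
#' @export
read_catalogue_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(ref = "character",
                                         alt = "character"))
  if (!all(c("position", "ref", "alt") %in% names(df)))
    stop("catalogue TSV must have columns position, ref, alt")
  df$ref[is.na(df$ref)] <- ""
  df
}
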