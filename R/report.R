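# End-to-end reproduction of the published analysis from packaged
# fixtures, plus the command-line entry points that tie the stages
# together.  All reproduce-mode computation is deterministic; percentages
# are display-rounded half-up to 2 decimals while internal math never
# rounds.

# round-half-up to `digits` (base round() is banker's rounding)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reproduce the published tallies and burden statistics from fixtures
#'
#' Runs the full desk-scale analysis: fixture-based tallies of the case
#' and control variant tables (effect, OXPHOS complex, novelty),
#' reconciliation of the printed annotation columns against the embedded
#' coordinate arithmetic, per-gene burden statistics recomputed from the
#' printed carrier counts (exact Fisher by default), and the ROS/LHON
#' risk screen over the patient records.
#'
#' @param outdir Optional directory; when given, writes
#'   `annotated_table1.tsv` (with reconciliation columns),
#'   `tally_summary.tsv`, `burden_table4.tsv` and `risk_screen.tsv`.
#' @param policy Test policy for the burden table (default `"fisher"`).
#' @param orientation RR orientation (default `"case-cohort"`).
#' @return List of class `reproduce_report` with fields `tally_case`,
#'   `tally_control`, `novel_union`, `reconciliation`, `burden`,
#'   `risk`, `checks` (named logicals) and `status` (0 when every check
#'   passes, 3 otherwise).
#' @export
run_reproduce <- function(outdir = NULL, policy = "fisher",
                          orientation = "case-cohort") {
  t1 <- load_fixture("table1")
  t2 <- load_fixture("table2")
  t4 <- load_fixture("table4_counts")
  patients <- load_fixture("table3")

  tally_case <- tally(t1)
  tally_control <- tally(t2)
  both <- rbind(t1[t1$novel, c("position", "ref", "alt")],
                t2[t2$novel, c("position", "ref", "alt")])
  novel_union <- sum(!duplicated(paste(both$position, both$ref, both$alt)))

  rec <- reconcile(t1)
  burden <- burden_from_counts(t4, n_cases = 35L, n_controls = 40L,
                               policy = policy, orientation = orientation)

  cohort <- lapply(patients, `[[`, "variants")
  risk <- patient_risk_summary(cohort)

  nd5 <- burden[burden$gene == "ND5", ]
  checks <- c(
    total_132      = tally_case$total_variants == 132L,
    nonsyn_42      = tally_case$by_effect[["non-synonymous"]] == 42L,
    complex_I_66   = tally_case$by_complex[["I"]] == 66L,
    complex_V_20   = tally_case$by_complex[["V"]] == 20L,
    control_ns_14  = tally_control$by_effect[["non-synonymous"]] == 14L,
    novel_union_44 = novel_union == 44L,
    novel_ns_13    = tally_case$novel_nonsyn_count == 13L,
    fisher_nd1     = round_half_up(burden$p_value[burden$gene == "ND1"], 3) == 0.136,
    fisher_co2     = round_half_up(burden$p_value[burden$gene == "CO2"], 3) == 0.019,
    fisher_cyb     = round_half_up(burden$p_value[burden$gene == "CYB"], 3) == 0.360,
    rr_nd5         = round_half_up(nd5$rr, 2) == 3.00 &&
                     round_half_up(nd5$ci_low, 2) == 1.86 &&
                     round_half_up(nd5$ci_high, 2) == 4.83,
    codon_10398    = {
      f <- rcrs_features()
      ctx <- codon_context(f[f$gene == "ND3", ],
                           circular_genome("rCRS", rcrs_length()), 10398)
      ctx$codon_index == 114L
    },
    lhon_none      = sum(risk$per_patient$any_lhon) == 0L)

  out <- structure(list(tally_case = tally_case,
                        tally_control = tally_control,
                        novel_union = novel_union,
                        reconciliation = rec, burden = burden, risk = risk,
                        checks = checks,
                        status = if (all(checks)) 0L else 3L),
                   class = "reproduce_report")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    ann <- merge(t1, as.data.frame(rec)[, c("position", "gene_match",
                                            "codon_index_match",
                                            "codon_aa_consistent",
                                            "label_consistent")],
                 by = "position", sort = FALSE)
    utils::write.table(ann, file.path(outdir, "annotated_table1.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ts <- data.frame(
      metric = c("total", "non-synonymous", "synonymous", "rna_gene",
                 "complex_I", "complex_III", "complex_IV", "complex_V",
                 "novel", "novel_non_syn", "novel_union_with_controls"),
      count = c(tally_case$total_variants, tally_case$by_effect,
                tally_case$by_complex[c("I", "III", "IV", "V")],
                tally_case$novel_count, tally_case$novel_nonsyn_count,
                novel_union))
    ts$percent <- sprintf("%.2f", round_half_up(
      100 * ts$count / tally_case$total_variants, 2))
    utils::write.table(ts, file.path(outdir, "tally_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(burden, file.path(outdir, "burden_table4.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(risk$per_patient,
                       file.path(outdir, "risk_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' @export
print.reproduce_report <- function(x, ...) {
  cat("<reproduce_report> status ", x$status, "\n", sep = "")
  print(x$tally_case)
  cat("checks: ", sum(x$checks), "/", length(x$checks), " passed\n", sep = "")
  if (!all(x$checks))
    cat("failed:", paste(names(x$checks)[!x$checks], collapse = ", "), "\n")
  invisible(x)
}

# ---- command line ---------------------------------------------------------

.cli_opts <- function(args) {
  opts <- list(); positional <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (grepl("=", key)) {
        opts[[sub("=.*", "", key)]] <- sub("^[^=]*=", "", key)
      } else if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]; i <- i + 1L
      } else opts[[key]] <- TRUE
    } else positional <- c(positional, a)
    i <- i + 1L
  }
  list(opts = opts, positional = positional)
}

#' Command-line entry point
#'
#' Subcommands: `call` (FASTA in, variant TSV out), `annotate` (variant
#' TSV in, annotated TSV out), `burden` (two annotated TSVs in, burden
#' TSV out), `screen` (variant TSV + scores TSV in), `simulate` (seeded
#' synthetic cohort out) and `reproduce` (fixture reproduction bundle).
#' Exit codes: 0 success, 1 usage error, 2 data validation error, 3
#' acceptance failure in reproduce mode.
#'
#' @param args Character vector of command-line arguments (defaults to
#'   the process arguments).
#' @return Integer exit code, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mitoburden <call|annotate|burden|screen|simulate|reproduce>",
    "[--in PATH] [--ref PATH] [--out PATH] [--outdir DIR] [--seed N]",
    "[--policy fisher|chi2|auto] [--orientation case-cohort|control-cohort|exposure]",
    sep = "\n  ")
  parsed <- .cli_opts(args)
  sub <- parsed$positional[1]
  o <- parsed$opts
  if (is.na(sub) || !sub %in% c("call", "annotate", "burden", "screen",
                                "simulate", "reproduce")) {
    message(usage); return(invisible(1L))
  }
  code <- tryCatch({
    switch(sub,
      call = {
        genome <- read_genome_fasta(o$ref)
        ss <- Biostrings::readDNAStringSet(o[["in"]])
        rows <- lapply(seq_along(ss), function(i) {
          v <- call_sample(genome, as.character(ss[[i]]))
          if (nrow(v)) cbind(sample_id = names(ss)[i], as.data.frame(v))
          else NULL
        })
        out <- do.call(rbind, rows)
        write_variant_tsv(out, o$out)
        0L
      },
      annotate = {
        df <- read_variant_tsv(o[["in"]])
        genome <- if (!is.null(o$ref)) read_genome_fasta(o$ref)
                  else circular_genome("rCRS", rcrs_length())
        feats <- if (!is.null(o$features))
          read_feature_table(o$features, genome$length) else rcrs_features()
        v <- variant(df$position, df$ref, df$alt, df$kind)
        ann <- annotate_all(v, genome, feats)
        cat_df <- if (!is.null(o$catalogue)) read_catalogue_tsv(o$catalogue)
                  else default_catalogue()
        ann$novel <- flag_novelty(ann, cat_df)
        utils::write.table(ann, o$out, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        0L
      },
      burden = {
        split_cohort <- function(path) {
          df <- utils::read.delim(path, stringsAsFactors = FALSE)
          lapply(split(df, df$sample_id), identity)
        }
        cases <- split_cohort(o$cases); controls <- split_cohort(o$controls)
        genes <- unique(stats::na.omit(unlist(lapply(cases, `[[`, "gene"))))
        bt <- burden_table(cases, controls, sort(genes),
                           policy = if (is.null(o$policy)) "fisher" else o$policy,
                           orientation = if (is.null(o$orientation))
                             "case-cohort" else o$orientation)
        utils::write.table(bt, o$out, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        0L
      },
      screen = {
        df <- read_variant_tsv(o[["in"]])
        v <- variant(df$position, df$ref, df$alt, df$kind)
        res <- screen_special_sets(v)
        if (!is.null(o$scores)) {
          sc <- read_scores_tsv(o$scores)
          m <- match(paste(v$position, v$ref, v$alt),
                     paste(sc$position, sc$ref, sc$alt))
          calls <- lapply(seq_along(m), function(i) {
            if (is.na(m[i])) return(list(combined = NA_character_))
            classify_scores(sc$sift_score[m[i]], sc$polyphen_score[m[i]])
          })
          res$pathogenicity <- vapply(calls, `[[`, character(1), "combined")
        }
        utils::write.table(res, o$out, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        0L
      },
      simulate = {
        cfg <- sim_config(seed = as.integer(o$seed))
        gen <- make_genome(cfg)
        coh <- make_cohorts(gen$genome, gen$features, cfg)
        dir.create(o$outdir, showWarnings = FALSE, recursive = TRUE)
        ref <- Biostrings::DNAStringSet(gen$genome$sequence)
        names(ref) <- gen$genome$name
        Biostrings::writeXStringSet(ref, file.path(o$outdir, "reference.fasta"))
        write_cohort_fasta(coh$samples, file.path(o$outdir, "samples.fasta"))
        utils::write.table(coh$truth, file.path(o$outdir, "truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(gen$features,
                           file.path(o$outdir, "features.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        0L
      },
      reproduce = {
        rep <- run_reproduce(outdir = o$outdir)
        print(rep)
        rep$status
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(code)
}
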