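# Seeded synthetic-data generation: small circular genomes with valid
# mitochondrial reading frames, case/control cohorts with planted
# variants at configured per-gene carrier probabilities, and score files
# with known truth.  Everything is deterministic under the master seed;
# each sample draws from its own stream derived from (seed, sample id),
# so cohorts are reproducible regardless of generation order.

.SENSE_CODONS <- function(code = mito_genetic_code()) names(code)[code != "*"]

#' Simulation configuration
#'
#' Defaults state the emulated study design: 35 cases vs 40 controls,
#' with modest per-gene carrier probabilities (cases enriched for
#' non-synonymous carriers the way a burden-positive gene is, controls at
#' background rates).
#'
#' @param features A `gene_features` layout or `"rcrs-like"` for the
#'   built-in miniature layout ([mini_features()]).
#' @param genome_length Genome length; required for custom layouts,
#'   derived for the preset.
#' @param n_cases,n_controls Cohort sizes (defaults 35 and 40).
#' @param p_nonsyn_case,p_nonsyn_control Per-gene probability that a
#'   subject carries a non-synonymous variant (scalar or named by gene).
#' @param p_syn Per-gene probability of a synonymous carrier (both
#'   cohorts).
#' @param p_rna_ins Probability of a single-base insertion in each RNA
#'   gene.
#' @param seed Mandatory integer master seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(features = "rcrs-like", genome_length = NULL,
                       n_cases = 35L, n_controls = 40L,
                       p_nonsyn_case = 0.3, p_nonsyn_control = 0.05,
                       p_syn = 0.15, p_rna_ins = 0.02, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (identical(features, "rcrs-like")) {
    features <- mini_features()
    genome_length <- attr(features, "genome_length")
  }
  if (is.null(genome_length))
    stop("genome_length is required for custom feature layouts")
  probs <- c(p_nonsyn_case, p_nonsyn_control, p_syn, p_rna_ins)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  structure(list(features = features,
                 genome_length = as.integer(genome_length),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 p_nonsyn_case = p_nonsyn_case,
                 p_nonsyn_control = p_nonsyn_control,
                 p_syn = p_syn, p_rna_ins = p_rna_ins,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Miniature mitogenome-like feature layout
#'
#' A 1,650-bp circular layout echoing the real gene organisation at
#' reduced scale: one tRNA and one rRNA on the H strand, three CDS
#' spanning complexes I/IV/V -- one of them on the L strand and one with
#' an incomplete stop codon -- an L-strand tRNA, and intergenic spacers.
#'
#' @return A `gene_features` data frame with attribute `genome_length`.
#' @export
mini_features <- function() {
  f <- gene_features(
    gene   = c("tRNA-Ala", "12S rRNA", "ND1", "tRNA-Ser", "CO1", "ATPase6"),
    start  = c(21L,  91L,  241L,  725L,  801L, 1291L),
    end    = c(90L,  240L, 720L,  790L, 1280L, 1591L),
    strand = c("H",  "H",  "H",   "L",  "L",   "H"),
    kind   = c("tRNA", "rRNA", "CDS", "tRNA", "CDS", "CDS"),
    incomplete_stop = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    genome_length = 1650L)
  attr(f, "genome_length") <- 1650L
  f
}

# derive a 32-bit stream seed from (master seed, index); keeps below 2^31
.stream_seed <- function(master, index)
  as.integer((as.numeric(master) * 100003 + 7919 * index) %% 2147483647)

# random ORF on the coding strand: ATG start, sense codons, stop (TAA) or
# a partial stop tail for incomplete_stop genes
.random_orf <- function(span, incomplete_stop, code) {
  sense <- setdiff(.SENSE_CODONS(code), c("ATG", "ATA"))
  if (incomplete_stop) {
    tail_len <- span %% 3L
    n_codons <- span %/% 3L
    body <- sample(sense, n_codons - 1L, replace = TRUE)
    paste0("ATG", paste(body, collapse = ""),
           substr("TA", 1L, tail_len))
  } else {
    n_codons <- span %/% 3L
    body <- sample(sense, n_codons - 2L, replace = TRUE)
    paste0("ATG", paste(body, collapse = ""), "TAA")
  }
}

#' Generate a synthetic circular genome
#'
#' Intergenic and RNA-gene bases are uniform random; every CDS gets a
#' valid reading frame on its coding strand (ATG start, no internal stop
#' under the vertebrate mitochondrial code, TAA stop or a partial stop
#' tail when `incomplete_stop`).  L-strand CDS are placed as the reverse
#' complement of their ORF.  Deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (a [circular_genome()]) and `features`.
#' @export
make_genome <- function(config) {
  code <- mito_genetic_code()
  set.seed(.stream_seed(config$seed, 0L))
  L <- config$genome_length
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  f <- config$features
  for (i in seq_len(nrow(f))) {
    if (f$kind[i] != "CDS") next
    span <- feature_span(f$start[i], f$end[i], L)
    if (span < 9L) stop("CDS feature too short for an ORF: ", f$gene[i])
    orf <- .random_orf(span, f$incomplete_stop[i], code)
    placed <- if (f$strand[i] == "L") revcomp(orf) else orf
    idx <- if (f$start[i] <= f$end[i]) f$start[i]:f$end[i]
           else c(f$start[i]:L, 1:f$end[i])
    chars[idx] <- strsplit(placed, "")[[1]]
  }
  list(genome = circular_genome(paste0("synthetic_", config$seed),
                                sequence = paste(chars, collapse = "")),
       features = f)
}

# pick a planted substitution in a CDS: returns genomic (position, ref,
# alt) whose coding-strand effect is `effect`
.plant_cds_substitution <- function(feature, genome, effect, code) {
  cds <- feature_sequence(feature, genome)
  span <- nchar(cds)
  n_codons <- span %/% 3L
  bases <- c("A", "C", "G", "T")
  for (try in 1:200) {
    ci <- sample(2:(n_codons - 1L), 1L)   # avoid start and stop codons
    off <- sample(0:2, 1L)
    codon <- substr(cds, 3L * (ci - 1L) + 1L, 3L * ci)
    ref_b <- substr(codon, off + 1L, off + 1L)
    alt_b <- sample(setdiff(bases, ref_b), 1L)
    alt_codon <- codon
    substr(alt_codon, off + 1L, off + 1L) <- alt_b
    if (code[[alt_codon]] == "*") next
    is_syn <- code[[codon]] == code[[alt_codon]]
    if ((effect == "synonymous") != is_syn) next
    coff <- 3L * (ci - 1L) + off          # coding-strand offset
    if (feature$strand == "H") {
      pos <- feature$start + coff
      g_ref <- ref_b; g_alt <- alt_b
    } else {
      pos <- feature$end - coff
      g_ref <- revcomp(ref_b); g_alt <- revcomp(alt_b)
    }
    if (pos > genome$length) pos <- pos - genome$length
    return(list(position = as.integer(pos), ref = g_ref, alt = g_alt,
                effect = effect))
  }
  stop("no single-base ", effect, " change found in gene ", feature$gene)
}

#' Generate case/control cohorts with planted variants
#'
#' Carrier draws are independent Bernoulli per gene per subject at the
#' configured probabilities.  Non-synonymous plants pick a codon position
#' where a single-base change alters the amino acid (verified at
#' generation time); synonymous plants preserve it.  RNA genes receive
#' single-base insertions with probability `p_rna_ins` (the inserted base
#' is chosen to differ from the anchor base, so the planted record is
#' already left-normalized).  Planted variants within a sample are kept
#' at least 2 bp apart; each sample's sequence is the reference with its
#' variants applied.
#'
#' @param genome,features From [make_genome()].
#' @param config The same [sim_config()].
#' @return List with `samples` (named list of sequences, names
#'   `case_i` / `control_i`), `truth` (data frame: `sample`, `cohort`,
#'   `position`, `ref`, `alt`, `kind`, `gene`, `effect`).
#' @export
make_cohorts <- function(genome, features, config) {
  code <- mito_genetic_code()
  cds <- features[features$kind == "CDS", , drop = FALSE]
  rna <- features[features$kind != "CDS", , drop = FALSE]
  p_gene <- function(p, gene, default) {
    if (length(p) == 1L && is.null(names(p))) return(p)
    if (gene %in% names(p)) p[[gene]] else default
  }
  gen_sample <- function(label, cohort, idx, p_nonsyn) {
    set.seed(.stream_seed(config$seed, idx))
    plants <- list()
    taken <- integer(0)
    ok_dist <- function(p) all(abs(taken - p) >= 2L)
    for (i in seq_len(nrow(cds))) {
      f <- cds[i, , drop = FALSE]
      for (eff in c("non-synonymous", "synonymous")) {
        p <- if (eff == "non-synonymous") p_gene(p_nonsyn, f$gene, 0)
             else p_gene(config$p_syn, f$gene, 0)
        if (stats::runif(1) >= p) next
        for (try in 1:50) {
          pl <- .plant_cds_substitution(f, genome, eff, code)
          if (ok_dist(pl$position)) break
          pl <- NULL
        }
        if (is.null(pl)) next
        taken <- c(taken, pl$position)
        plants[[length(plants) + 1L]] <- data.frame(
          sample = label, cohort = cohort, position = pl$position,
          ref = pl$ref, alt = pl$alt, kind = "substitution",
          gene = f$gene, effect = pl$effect, stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(nrow(rna))) {
      f <- rna[i, , drop = FALSE]
      if (stats::runif(1) >= config$p_rna_ins) next
      for (try in 1:50) {
        pos <- sample(f$start:(f$end - 1L), 1L)
        anchor <- substr(genome$sequence, pos, pos)
        b <- sample(setdiff(c("A", "C", "G", "T"), anchor), 1L)
        if (ok_dist(pos)) break
        pos <- NULL
      }
      if (is.null(pos)) next
      taken <- c(taken, pos)
      plants[[length(plants) + 1L]] <- data.frame(
        sample = label, cohort = cohort, position = pos, ref = "",
        alt = b, kind = "insertion", gene = f$gene, effect = "rna_gene",
        stringsAsFactors = FALSE)
    }
    truth <- if (length(plants)) do.call(rbind, plants)
             else data.frame(sample = character(0), cohort = character(0),
                             position = integer(0), ref = character(0),
                             alt = character(0), kind = character(0),
                             gene = character(0), effect = character(0))
    v <- if (nrow(truth)) variant(truth$position, truth$ref, truth$alt,
                                  truth$kind)
         else variant(integer(0), character(0), character(0), character(0))
    list(seq = apply_variants(genome$sequence, v), truth = truth)
  }
  samples <- list(); truth <- list()
  for (i in seq_len(config$n_cases)) {
    s <- gen_sample(sprintf("case_%02d", i), "case", i, config$p_nonsyn_case)
    samples[[sprintf("case_%02d", i)]] <- s$seq
    truth[[length(truth) + 1L]] <- s$truth
  }
  for (i in seq_len(config$n_controls)) {
    s <- gen_sample(sprintf("control_%02d", i), "control",
                    config$n_cases + i, config$p_nonsyn_control)
    samples[[sprintf("control_%02d", i)]] <- s$seq
    truth[[length(truth) + 1L]] <- s$truth
  }
  list(samples = samples, truth = do.call(rbind, truth))
}

#' Write cohort samples as a multi-record FASTA
#'
#' @param samples Named list of sequences from [make_cohorts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_fasta <- function(samples, path) {
  ss <- Biostrings::DNAStringSet(unlist(samples))
  names(ss) <- names(samples)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Generate a synthetic pathogenicity score file
#'
#' Assigns SIFT / PolyPhen scores to variants such that stated fractions
#' fall below/above the decision thresholds; truth columns record the
#' intended calls.
#'
#' @param v A `mito_variant` data frame.
#' @param frac_deleterious Fraction with SIFT below 0.05.
#' @param frac_damaging Fraction with PolyPhen at or above 1.5.
#' @param seed Integer seed.
#' @return Data frame with `position`, `ref`, `alt`, `sift_score`,
#'   `polyphen_score`, `truth_deleterious`, `truth_damaging`.
#' @export
make_score_file <- function(v, frac_deleterious = 0.3, frac_damaging = 0.3,
                            seed) {
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(.stream_seed(seed, 999L))
  n <- nrow(v)
  del <- stats::runif(n) < frac_deleterious
  dam <- stats::runif(n) < frac_damaging
  data.frame(position = v$position, ref = v$ref, alt = v$alt,
             sift_score = ifelse(del, stats::runif(n, 0, 0.049),
                                 stats::runif(n, 0.05, 1)),
             polyphen_score = ifelse(dam, stats::runif(n, 1.5, 3.5),
                                     stats::runif(n, 0, 1.49)),
             truth_deleterious = del, truth_damaging = dam,
             stringsAsFactors = FALSE)
}
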