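# Annotation: gene/codon/effect assignment, novelty, tallies,
# reconciliation against the printed tables.

rcrs_coord <- circular_genome("rCRS", rcrs_length())

test_that("annotate assigns gene, complex and codon index on coordinates", {
  f <- rcrs_features()
  ann <- annotate(variant(10398, "G", "A"), rcrs_coord, f)
  expect_identical(ann$gene, "ND3")
  expect_identical(ann$complex, "I")
  expect_identical(ann$codon_index, 114L)
  expect_true(is.na(ann$ref_codon))  # no sequence available

  ann <- annotate(variant(12308, "A", "G"), rcrs_coord, f)
  expect_match(ann$gene, "^tRNA-Leu")
  expect_identical(ann$effect, "rna_gene")
  expect_true(is.na(ann$protein_notation))

  # overlap region: one row per overlapping feature, frames differ
  ann <- annotate(variant(8550, "A", "G"), rcrs_coord, f)
  expect_setequal(ann$gene, c("ATPase8", "ATPase6"))
  expect_identical(nrow(ann), 2L)
  expect_false(ann$codon_index[1] == ann$codon_index[2])
})

test_that("sequence-based effects agree with the whole-protein oracle", {
  hg <- hand_genome()
  set.seed(81)
  bases <- c("A", "C", "G", "T")
  for (gname in c("ND1", "CO1")) {
    f <- hg$features[hg$features$gene == gname, ]
    prot_ref <- oracle_translate(feature_sequence(f, hg$genome))
    for (i in 1:60) {
      pos <- sample(f$start:f$end, 1)
      ref_b <- substr(hg$genome$sequence, pos, pos)
      alt_b <- sample(setdiff(bases, ref_b), 1)
      ann <- annotate(variant(pos, ref_b, alt_b), hg$genome, hg$features)
      ann <- ann[ann$gene == gname, ]
      mutated <- apply_variants(hg$genome$sequence, variant(pos, ref_b, alt_b))
      prot_alt <- oracle_translate(
        feature_sequence(f, circular_genome("m", sequence = mutated)))
      oracle_effect <- if (identical(prot_ref, prot_alt)) "synonymous"
                       else "non-synonymous"
      expect_identical(ann$effect, oracle_effect,
                       info = paste(gname, pos, alt_b))
    }
  }
})

test_that("insertions in RNA genes and CDS are annotated gene-level", {
  hg <- hand_genome()
  ann <- annotate(variant(260, "", "T"), hg$genome, hg$features)
  expect_identical(ann$gene, "tRNA-Phe")
  expect_identical(ann$effect, "rna_gene")
  ann <- annotate(variant(50, "", "T"), hg$genome, hg$features)
  expect_identical(ann$effect, "non_coding")
  expect_true(ann$frameshift)
})

test_that("intergenic variants report non_coding with no gene", {
  f <- rcrs_features()
  ann <- annotate(variant(15954, "C", "T"), rcrs_coord, f)
  expect_identical(ann$effect, "non_coding")
  expect_true(is.na(ann$gene))
})

test_that("effect_from_aa_pair normalizes printed amino-acid spellings", {
  expect_identical(unname(effect_from_aa_pair("Ala", "Thr")), "non-synonymous")
  expect_identical(unname(effect_from_aa_pair("Lys", "Lys")), "synonymous")
  expect_identical(unname(effect_from_aa_pair("Trp", "Trp")), "synonymous")
  expect_identical(unname(effect_from_aa_pair("IsoLeu", "Thr")), "non-synonymous")
  expect_identical(unname(effect_from_aa_pair("Iso", "Ile")), "synonymous")
  expect_error(effect_from_aa_pair("Qux", "Ala"), "unrecognized")
})

test_that("novelty is pure catalogue lookup", {
  cat_df <- data.frame(position = c(10398L, 12308L), ref = c("G", "A"),
                       alt = c("A", "G"))
  v <- variant(c(10398L, 10398L, 3311L), c("G", "G", "C"), c("A", "C", "T"))
  expect_identical(flag_novelty(v, cat_df), c(FALSE, TRUE, TRUE))
  expect_true(all(flag_novelty(v, cat_df[0, ])))  # empty catalogue
})

test_that("the default catalogue is exactly the non-novel fixture variants", {
  cat_df <- default_catalogue()
  t1 <- load_fixture("table1")
  expect_identical(flag_novelty(
    variant(t1$position, t1$ref, t1$alt, t1$kind), cat_df), t1$novel)
})

test_that("tally reproduces the printed distribution counts", {
  t1 <- load_fixture("table1")
  tl <- tally(t1)
  expect_identical(tl$total_variants, 132L)
  expect_identical(unname(tl$by_effect),
                   c(82L, 42L, 8L))  # syn, non-syn, rna
  expect_identical(unname(tl$by_complex), c(66L, 12L, 26L, 20L, 8L))
  expect_identical(tl$novel_count, 31L)
  expect_identical(tl$novel_nonsyn_count, 13L)
  t2 <- load_fixture("table2")
  tl2 <- tally(t2)
  expect_identical(tl2$total_variants, 58L)
  expect_identical(tl2$by_effect[["non-synonymous"]], 14L)
})

test_that("tally is permutation-invariant and additive over disjoint splits", {
  t1 <- load_fixture("table1")
  set.seed(82)
  perm <- t1[sample.int(nrow(t1)), ]
  expect_identical(tally(perm)$by_complex, tally(t1)$by_complex)
  split1 <- t1[1:60, ]; split2 <- t1[61:132, ]
  expect_identical(tally(split1)$by_effect + tally(split2)$by_effect,
                   tally(t1)$by_effect)
  empty <- tally(t1[0, ])
  expect_identical(empty$total_variants, 0L)
  expect_true(all(empty$by_complex == 0L))
})

test_that("reconcile matches clean rows and flags the inconsistent ones", {
  t1 <- load_fixture("table1")
  rec <- reconcile(t1)
  expect_identical(nrow(rec), 132L)  # every fixture row appears once
  r78 <- rec[rec$position == 10398, ]
  expect_true(r78$gene_match && r78$codon_index_match &&
                r78$codon_aa_consistent && r78$label_consistent)
  # printed codon change CCT>CCA (Pro>Pro) vs printed amino acids Leu>Pro
  expect_false(rec$codon_aa_consistent[rec$position == 14000])
  # printed TTT>CTT is Phe>Leu, not the printed Phe>Thr
  expect_false(rec$codon_aa_consistent[rec$position == 8875])
  # printed ATC>ACC is Ile>Thr, not the printed Ile>Ile
  expect_false(rec$codon_aa_consistent[rec$position == 8843])
  expect_gt(attr(rec, "n_mismatch"), 0L)
})

test_that("reconcile is clean on a fixture generated from the engine itself", {
  hg <- hand_genome()
  set.seed(83)
  f <- hg$features[hg$features$gene == "ND1", ]
  pos <- sample(f$start:(f$end - 3L), 10)
  rows <- lapply(pos, function(p) {
    ref_b <- substr(hg$genome$sequence, p, p)
    alt_b <- sample(setdiff(c("A", "C", "G", "T"), ref_b), 1)
    ann <- annotate(variant(p, ref_b, alt_b), hg$genome, hg$features)[1, ]
    data.frame(position = p, ref = ref_b, alt = alt_b, kind = "substitution",
               gene = ann$gene, aa_position = ann$codon_index,
               ref_codon = ann$ref_codon, alt_codon = ann$alt_codon,
               ref_aa = aa_three_letter(ann$ref_aa),
               alt_aa = aa_three_letter(ann$alt_aa),
               effect = ann$effect, stringsAsFactors = FALSE)
  })
  fixture <- do.call(rbind, rows)
  rec <- reconcile(fixture, hg$genome, hg$features)
  expect_identical(attr(rec, "n_mismatch"), 0L)
})
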