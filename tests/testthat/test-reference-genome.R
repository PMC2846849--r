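# Circular genome model, embedded gene layout, codon framing, genetic code.

test_that("vertebrate mitochondrial code has 64 entries and the four diffs", {
  code <- mito_genetic_code()
  expect_length(code, 64L)
  expect_identical(code[["TGA"]], "W")
  expect_identical(code[["ATA"]], "M")
  expect_identical(code[["AGA"]], "*")
  expect_identical(code[["AGG"]], "*")
  expect_equal(sum(code != "*"), 60L)
  # full agreement with the Biostrings table
  ref <- Biostrings::getGeneticCode("2")
  expect_identical(unname(code[names(ref)]), as.character(ref))
})

test_that("translate_codon handles examples, stops and ambiguity", {
  expect_identical(translate_codon("TGA"), "W")
  expect_identical(translate_codon("GCC"), "A")
  expect_identical(translate_codon("AGA"), "*")
  expect_identical(translate_codon("ANA"), "X")  # never silently an amino acid
  expect_error(translate_codon("AC"), "codon")
  expect_error(translate_codon("ACU"), "codon")
})

test_that("embedded rCRS layout has 13 CDS, 22 tRNA, 2 rRNA and sane framing", {
  f <- rcrs_features()
  expect_identical(as.integer(table(f$kind)[c("CDS", "tRNA", "rRNA")]),
                   c(13L, 22L, 2L))
  expect_true(all(f$complex[f$kind != "CDS"] == "RNA"))
  expect_true(all(f$complex[f$kind == "CDS"] %in% c("I", "III", "IV", "V")))
  expect_true(all(f$start <= f$end))  # no embedded feature wraps the origin
  spans <- f$end - f$start + 1L
  cds <- f$kind == "CDS"
  expect_true(all(ifelse(f$incomplete_stop[cds], spans[cds] %% 3L %in% 1:2,
                         spans[cds] %% 3L == 0L)))
})

test_that("feature_at finds genes, overlaps and intergenic gaps", {
  f <- rcrs_features()
  expect_identical(feature_at(f, 10398)$gene, "ND3")
  hit <- feature_at(f, 12308)
  expect_identical(hit$kind, "tRNA")
  expect_match(hit$gene, "^tRNA-Leu")
  # ATPase8/ATPase6 overlap region returns both
  expect_setequal(feature_at(f, 8550)$gene, c("ATPase8", "ATPase6"))
  # intergenic spacer between tRNA-Thr and tRNA-Pro
  expect_identical(nrow(feature_at(f, 15954)), 0L)
  expect_error(feature_at(f, 0), "outside genome")
  expect_error(feature_at(f, 20000), "outside genome")
})

test_that("feature_at is invariant under circular coordinate shift", {
  f <- rcrs_features()
  L <- rcrs_length()
  shift <- 4321L
  shifted <- gene_features(f$gene,
                           (f$start + shift - 1L) %% L + 1L,
                           (f$end + shift - 1L) %% L + 1L,
                           f$strand, f$kind, f$complex, f$incomplete_stop,
                           genome_length = L)
  for (pos in c(577L, 3307L, 10398L, 12308L, 15954L, 16569L)) {
    q <- (pos + shift - 1L) %% L + 1L
    expect_identical(feature_at(shifted, q, L)$gene, feature_at(f, pos, L)$gene,
                     info = paste("pos", pos))
  }
})

test_that("codon_context matches printed amino-acid indices on rCRS coordinates", {
  f <- rcrs_features()
  g <- circular_genome("rCRS", rcrs_length())
  cases <- list(list("ND3", 10398L, 114L, 0L), list("ND3", 10400L, 114L, 2L),
                list("ND1", 3311L, 2L, 1L), list("ND5", 14000L, 555L, 1L),
                list("CYB", 15670L, 308L, 2L), list("ATPase6", 8886L, 120L, 2L))
  for (cs in cases) {
    ctx <- codon_context(f[f$gene == cs[[1]], ], g, cs[[2]])
    expect_identical(ctx$codon_index, cs[[3]], info = cs[[1]])
    expect_identical(ctx$offset_in_codon, cs[[4]], info = cs[[1]])
  }
  # frame anchor: feature start is codon 1, offset 0
  nd1 <- f[f$gene == "ND1", ]
  ctx <- codon_context(nd1, g, nd1$start)
  expect_identical(ctx$codon_index, 1L)
  expect_identical(ctx$offset_in_codon, 0L)
})

test_that("codon_context rejects non-CDS, outside and partial-codon positions", {
  f <- rcrs_features()
  g <- circular_genome("rCRS", rcrs_length())
  expect_error(codon_context(f[f$gene == "tRNA-Phe", ], g, 600), "CDS")
  expect_error(codon_context(f[f$gene == "ND3", ], g, 5000), "outside feature")
  # ND3 ends at 10404 with a 1-base partial stop: 10404 is invalid,
  # 10403 is the last base of codon 115
  expect_error(codon_context(f[f$gene == "ND3", ], g, 10404), "incomplete")
  expect_identical(codon_context(f[f$gene == "ND3", ], g, 10403)$codon_index, 115L)
})

test_that("L-strand codon_context agrees with a reverse-complement oracle", {
  hg <- hand_genome()
  co1 <- hg$features[hg$features$gene == "CO1", ]
  cds <- feature_sequence(co1, hg$genome)
  # oracle: explicit revcomp + chunk-by-3
  oracle_codons <- substring(cds, seq(1, nchar(cds) - 2, 3),
                             seq(3, nchar(cds), 3))
  for (pos in co1$start:co1$end) {
    ctx <- codon_context(co1, hg$genome, pos)
    expect_identical(ctx$ref_codon, oracle_codons[ctx$codon_index],
                     info = paste("pos", pos))
    # position maps back: the codon covers this genomic position
    genomic_off <- co1$end - pos
    expect_identical(ctx$codon_index, genomic_off %/% 3L + 1L)
  }
})

test_that("codon_context + translate equals whole-protein oracle on every CDS", {
  hg <- hand_genome()
  for (gname in c("ND1", "CO1")) {
    f <- hg$features[hg$features$gene == gname, ]
    prot <- oracle_translate(feature_sequence(f, hg$genome))
    for (pos in f$start:f$end) {
      ctx <- codon_context(f, hg$genome, pos)
      expect_identical(translate_codon(ctx$ref_codon), prot[ctx$codon_index],
                       info = paste(gname, pos))
    }
  }
})

test_that("origin-wrapping features are supported in the data model", {
  f <- gene_features("WRAP", 290L, 10L, "H", "CDS", complex = "I",
                     genome_length = 300L)
  expect_identical(nrow(feature_at(f, 295L, 300L)), 1L)
  expect_identical(nrow(feature_at(f, 5L, 300L)), 1L)
  expect_identical(nrow(feature_at(f, 150L, 300L)), 0L)
  set.seed(1)
  chars <- sample(c("A", "C", "G", "T"), 300L, TRUE)
  orf <- paste0("ATG", strrep("GCC", 5L), "TAA")  # 21 bases = span
  chars[c(290:300, 1:10)] <- strsplit(orf, "")[[1]]
  g <- circular_genome("wrap", sequence = paste(chars, collapse = ""))
  expect_identical(codon_context(f[1, ], g, 290L)$ref_codon, "ATG")
  ctx <- codon_context(f[1, ], g, 2L)  # offset 12 -> codon 5
  expect_identical(ctx$codon_index, 5L)
  expect_identical(ctx$ref_codon, "GCC")
})

test_that("genome and feature validation rejects malformed input", {
  expect_error(circular_genome("x", 0), "positive")
  expect_error(circular_genome("x", sequence = "ACGU"), "outside")
  expect_error(circular_genome("x", length = 5, sequence = "ACGT"), "match")
  expect_error(gene_features("G", 10, 99, "H", "CDS", complex = "RNA"), "RNA")
  expect_error(gene_features("tRNA-X", 1, 50, "H", "tRNA", complex = "I"),
               "RNA")
  expect_error(gene_features("ND9", 1, 91, "H", "CDS"), "framing")
})
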