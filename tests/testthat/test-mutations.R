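write_toy_maf <- function(rows, path = tempfile(fileext = ".maf")) {
  header <- paste(c("Hugo_Symbol", "Chromosome", "Start_Position",
                    "Reference_Allele", "Tumor_Seq_Allele2",
                    "Variant_Classification", "Variant_Type",
                    "Tumor_Sample_Barcode"), collapse = "\t")
  writeLines(c(header, rows), path)
  path
}

test_that("MAF positions convert from 1-based to 0-based and indels drop", {
  maf <- write_toy_maf(c(
    "geneA\tchr1\t100\tC\tT\tSilent\tSNP\tS1",
    "geneA\tchr1\t200\tC\t-\tFrame_Shift_Del\tDEL\tS1",
    "geneB\tchr1\t300\tG\tA\tMissense_Mutation\tSNP\tS2"))
  expect_message(rec <- read_mutations(maf, "maf"), "dropped")
  expect_equal(nrow(rec), 2)
  expect_equal(rec$pos, c(99, 299))
  expect_equal(rec$consequence, c("synonymous", "non_synonymous"))
})

test_that("column_map dialect reproduces the MAF records", {
  maf <- write_toy_maf("geneA\tchr1\t100\tC\tT\tSilent\tSNP\tS1")
  icgc <- tempfile(fileext = ".tsv")
  writeLines(c("icgc_sample_id\tchromosome\tstart\tref\talt\tcons\tgene",
               "S1\tchr1\t100\tC\tT\tsynonymous_variant\tgeneA"), icgc)
  a <- read_mutations(maf, "maf")
  b <- read_mutations(icgc, "column_map",
                      column_map = c(sample_id = "icgc_sample_id",
                                     chrom = "chromosome", pos = "start",
                                     ref = "ref", alt = "alt",
                                     consequence = "cons", gene_id = "gene"))
  expect_equal(a, b)
})

test_that("missing columns and bad positions raise informative errors", {
  bad <- tempfile()
  writeLines(c("Hugo_Symbol\tChromosome", "x\ty"), bad)
  expect_error(read_mutations(bad, "maf"), "missing required column")
  maf <- write_toy_maf("geneA\tchr1\toops\tC\tT\tSilent\tSNP\tS1")
  expect_error(read_mutations(maf, "maf"), "unparseable position")
})

test_that("consequence annotation follows the codon table on both strands", {
  g <- toy_genome()
  tx <- toy_transcripts()
  # + strand: GGA codon at 13..15; third position A>G keeps Gly
  rec <- data.frame(sample_id = "S", chrom = "chrT", pos = 15, ref = "A",
                    alt = "G", consequence = "other", gene_id = "gP",
                    stringsAsFactors = FALSE)
  expect_equal(annotate_consequences(rec, tx, g), "synonymous")
  # first position G>A makes Arg
  rec$pos <- 13; rec$ref <- "G"; rec$alt <- "A"
  expect_equal(annotate_consequences(rec, tx, g), "non_synonymous")
  # - strand: coding CTG -> CTA (Leu, synonymous) is genomic C>T at 43
  rec$pos <- 43; rec$ref <- "C"; rec$alt <- "T"
  expect_equal(annotate_consequences(rec, tx, g), "synonymous")
  # outside any CDS
  rec$pos <- 2; rec$ref <- "T"; rec$alt <- "A"
  expect_equal(annotate_consequences(rec, tx, g), "other")
  # reference mismatch is an error
  rec$pos <- 15; rec$ref <- "C"; rec$alt <- "G"
  expect_error(annotate_consequences(rec, tx, g), "reference mismatch")
})

test_that("single-record wrapper agrees with the vectorized annotator", {
  g <- toy_genome()
  tx <- toy_transcripts()
  rec <- list(sample_id = "S", chrom = "chrT", pos = 15, ref = "A", alt = "G",
              consequence = "other", gene_id = "gP")
  expect_equal(annotate_consequence(rec, tx[tx$transcript_id == "txP", ], g),
               "synonymous")
})

test_that("annotation and recompute filtering agree on simulated cohorts", {
  sim <- small_sim(seed = 21, n_genes = 15, n_tumours = 10)
  a <- filter_synonymous(sim$mutations, "annotation")
  b <- filter_synonymous(sim$mutations, "recompute",
                         transcripts = sim$transcripts, genome = sim$genome)
  cols <- c("sample_id", "chrom", "pos", "ref", "alt")
  expect_equal(a[, cols], b[, cols])
  expect_gt(nrow(a), 0)
  expect_equal(nrow(filter_synonymous(a[0, ], "annotation")), 0)
  expect_error(filter_synonymous(sim$mutations, "recompute"), "requires")
})

test_that("all twelve substitutions collapse onto the six classes", {
  expected <- c("A>C" = "A>C", "A>G" = "A>G", "A>T" = "A>T",
                "C>A" = "G>T", "C>G" = "C>G", "C>T" = "C>T",
                "G>A" = "C>T", "G>C" = "C>G", "G>T" = "G>T",
                "T>A" = "A>T", "T>C" = "A>G", "T>G" = "A>C")
  ref <- substr(names(expected), 1, 1)
  alt <- substr(names(expected), 3, 3)
  expect_equal(canonical_substitution_class(ref, alt), unname(expected))
  # reverse-complement invariance
  expect_equal(canonical_substitution_class(comp_base(ref), comp_base(alt)),
               unname(expected))
  expect_length(unique(expected), 6)
  expect_error(canonical_substitution_class("A", "A"), "differ")
  expect_error(canonical_substitution_class("N", "A"), "single bases")
})

test_that("trinucleotide classes canonicalize by reverse complement", {
  g <- Biostrings::DNAStringSet(c(chrZ = "AACGTCGATT"))
  # 0-based pos 2 is the C of A-C-G
  expect_equal(trinucleotide_class(g, "chrZ", 2, "C", "T"), "A[C>T]G")
  # genomic C[G>A]T at pos 5 (C G A ... check): bases 5,6,7 = C,G,A
  g2 <- Biostrings::DNAStringSet(c(chrZ = "AAAACGTAAA"))
  expect_equal(trinucleotide_class(g2, "chrZ", 5, "G", "A"), "A[C>T]G")
  expect_error(trinucleotide_class(g2, "chrZ", 0, "A", "C"), "contig edge")
  g3 <- Biostrings::DNAStringSet(c(chrZ = "ANCGT"))
  expect_message(lab <- trinucleotide_class(g3, "chrZ", 2, "C", "T"),
                 "N context")
  expect_true(is.na(lab))
})

test_that("the trinucleotide label space has exactly 96 reachable classes", {
  expect_length(trinuc_classes(), 96)
  # enumerate all 12 substitutions x 16 contexts on constructed genomes
  seen <- character()
  for (l in c("A", "C", "G", "T")) for (r in c("A", "C", "G", "T"))
    for (ref in c("A", "C", "G", "T")) {
      g <- Biostrings::DNAStringSet(setNames(paste0("T", l, ref, r, "T"), "c"))
      for (alt in setdiff(c("A", "C", "G", "T"), ref))
        seen <- c(seen, trinucleotide_class(g, "c", 2, ref, alt))
    }
  expect_setequal(unique(seen), trinuc_classes())
})

test_that("MAF files written by the package read back identically", {
  sim <- small_sim(seed = 22, n_genes = 10, n_tumours = 5)
  path <- tempfile(fileext = ".maf")
  write_maf(sim$mutations, path)
  back <- read_mutations(path, "maf")
  cols <- c("sample_id", "chrom", "pos", "ref", "alt", "consequence")
  ord <- function(d) d[order(d$sample_id, d$pos), cols]
  expect_equal(ord(back), ord(sim$mutations[, cols]), ignore_attr = TRUE)
})
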