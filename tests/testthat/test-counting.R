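mk_regions <- function(chrom, starts, ends, roles, strand = "+") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts + 1, ends),
                               strand = strand)
  S4Vectors::mcols(gr)$role <- roles
  S4Vectors::mcols(gr)$side <- NA_character_
  S4Vectors::mcols(gr)$exon_id <- paste0("e", seq_along(gr))
  gr
}

mk_ssms <- function(pos, ref = "A", alt = "C", sample_id = "S1",
                    chrom = "chr1") {
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, consequence = "synonymous", gene_id = "g",
             stringsAsFactors = FALSE)
}

test_that("CpG masking marks C and G positions using outside context", {
  g <- Biostrings::DNAStringSet(c(chr1 = "AACGTTA"))
  reg <- mk_regions("chr1", 0, 6, "core")
  m <- mask_cpg_positions(g, reg)
  expect_equal(start(m) - 1, c(2, 3))

  g2 <- Biostrings::DNAStringSet(c(chr1 = "ACGCGTA"))
  expect_equal(start(mask_cpg_positions(g2, mk_regions("chr1", 0, 6, "core")))
               - 1, 1:4)

  # interval ends on a C whose G context lies outside: the C is masked
  g3 <- Biostrings::DNAStringSet(c(chr1 = "AACGAA"))
  expect_equal(start(mask_cpg_positions(g3, mk_regions("chr1", 0, 3, "core")))
               - 1, 2)
  # symmetric case: interval starting on the G
  expect_equal(start(mask_cpg_positions(g3, mk_regions("chr1", 3, 6, "core")))
               - 1, 3)
  # contig edge: message, no phantom mask
  expect_message(mask_cpg_positions(g3, mk_regions("chr1", 0, 6, "core")),
                 "contig edge")
})

test_that("mutations are counted per role with mask exclusion", {
  reg <- mk_regions("chr1", c(0, 100), c(50, 150), c("core", "flank"))
  ssms <- mk_ssms(c(5, 10, 20, 110, 400))
  out <- count_mutations_in_regions(ssms, reg)
  expect_equal(out$count[out$role == "core"], 3)
  expect_equal(out$count[out$role == "flank"], 1)

  mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 11))  # pos 10
  out2 <- count_mutations_in_regions(ssms, reg, mask)
  expect_equal(out2$count[out2$role == "core"], 2)
  expect_equal(out2$effective_bp[out2$role == "core"], 49)
  expect_equal(out2$total_bp[out2$role == "core"], 50)

  # overlapping regions are a contract violation
  bad <- mk_regions("chr1", c(0, 40), c(50, 90), c("core", "flank"))
  expect_error(count_mutations_in_regions(mk_ssms(45), bad),
               "more than one region")
})

test_that("density arithmetic and depletion sign convention hold", {
  expect_equal(ssm_density(10, 100, 5), 0.02)
  expect_equal(ssm_density(0, 1000, 50), 0)
  expect_error(ssm_density(1, 0, 5), "positive")
  # algebraic identity: pooled density equals the mean of per-tumour
  # per-bp rates when counts are attributed evenly
  k <- 12; b <- 40; n <- 4
  expect_equal(ssm_density(k, b, n), mean(rep((k / n) / b, n)))

  expect_equal(depletion_fraction(0.83, 1), 0.17)
  expect_equal(depletion_fraction(1, 1), 0)
  expect_equal(depletion_fraction(1.2, 1), -0.2)
  expect_error(depletion_fraction(1, 0), "non-zero")
})

test_that("per-tumour tables keep explicit zeros and conserve counts", {
  reg <- mk_regions("chr1", c(0, 100), c(50, 150), c("core", "flank"))
  ssms <- rbind(mk_ssms(c(5, 10), sample_id = "S1"),
                mk_ssms(110, sample_id = "S2"))
  pt <- per_tumour_density_table(ssms, reg, samples = c("S1", "S2", "S3"))
  expect_equal(nrow(pt), 6)                     # 3 tumours x 2 roles
  expect_equal(sum(pt$count == 0), 4)
  pooled <- count_mutations_in_regions(ssms, reg)
  agg <- tapply(pt$count, pt$role, sum)
  expect_equal(as.vector(agg[pooled$role]), pooled$count)
})

test_that("class-normalized rates match a brute-force tally on a toy region", {
  seqc <- paste0(strrep("A", 10), strrep("T", 10),
                 strrep("C", 20), strrep("G", 20))   # 60 bp
  g <- Biostrings::DNAStringSet(setNames(seqc, "chr1"))
  reg <- mk_regions("chr1", 0, 60, "core")
  ssms <- rbind(mk_ssms(c(2, 3), ref = "A", alt = "C"),       # A>C class
                mk_ssms(25, ref = "C", alt = "T"))            # C>T class
  out <- class_normalized_rates(ssms, reg, g, n_tumours = 1)
  expect_equal(out$rate[out$class == "A>C"], 2 / 20)   # 10 A + 10 T
  expect_equal(out$rate[out$class == "C>T"], 1 / 40)   # 20 C + 20 G
  expect_equal(sum(out$count), nrow(ssms))             # partition

  # brute-force denominators: per-base tally of X or comp(X)
  chars <- strsplit(seqc, "")[[1]]
  for (cl in substitution_classes()) {
    x <- substr(cl, 1, 1)
    expect_equal(out$denom_bp[out$class == cl],
                 sum(chars %in% c(x, comp_base(x))))
  }
})

test_that("trinucleotide rates use strand-collapsed sliding-window denominators", {
  seqc <- "TAACGTAC"
  g <- Biostrings::DNAStringSet(setNames(seqc, "chr1"))
  reg <- mk_regions("chr1", 1, 7, "core")       # covers AACGTA
  ssms <- mk_ssms(3, ref = "C", alt = "T")      # context A[C>T]G
  out <- trinuc_rates(ssms, reg, g, n_tumours = 1)
  expect_equal(out$count[out$class == "A[C>T]G"], 1)
  expect_equal(sum(out$count), 1)

  # brute-force: trinucleotides centred on each region base, both strands
  chars <- strsplit(seqc, "")[[1]]
  tri_at <- vapply(2:7, function(p) paste(chars[(p - 1):(p + 1)],
                                          collapse = ""), "")
  for (cl in c("A[C>T]G", "G[A>G]C", "T[A>C]A")) {
    ref_tri <- paste0(substr(cl, 1, 1), substr(cl, 3, 3), substr(cl, 7, 7))
    expect_equal(out$denom[out$class == cl],
                 sum(tri_at == ref_tri) + sum(tri_at == revcomp(ref_tri)),
                 info = cl)
  }
})

test_that("rates are invariant under renaming and coordinate translation", {
  sim <- small_sim(seed = 31, n_genes = 12, n_tumours = 8)
  ssms <- sim$mutations[sim$mutations$consequence == "synonymous", ]
  base <- count_mutations_in_regions(ssms, sim$regions)
  shift <- 1000
  ssms2 <- ssms; ssms2$pos <- ssms2$pos + shift; ssms2$chrom <- "chrX"
  reg2 <- GenomicRanges::shift(sim$regions, shift)
  reg2 <- GenomicRanges::GRanges("chrX", ranges(reg2), strand = strand(reg2),
                                 role = mcols(reg2)$role,
                                 side = mcols(reg2)$side,
                                 exon_id = mcols(reg2)$exon_id)
  out <- count_mutations_in_regions(ssms2, reg2)
  expect_equal(out, base)
})

test_that("per-role mean scores equal the weighted mean of interval means", {
  reg <- mk_regions("chr1", c(0, 10), c(4, 16), c("flank", "flank"))
  sc <- data.frame(chrom = "chr1", pos = c(0:3, 10:15),
                   score = c(rep(1, 4), rep(0, 6)))
  out <- region_mean_score(sc, reg)
  expect_equal(out$per_role$mean, 0.4)           # 4 ones over 10 bases
  expect_equal(out$per_interval$mean, c(1, 0))
  # constant scores give that constant everywhere
  sc$score <- 2.5
  expect_equal(region_mean_score(sc, reg)$per_role$mean, 2.5)
  # uncovered bases are excluded with a coverage message
  expect_message(region_mean_score(sc[1:3, ], reg), "coverage")
})

test_that("synonymous opportunity normalization is exact on the toy genome", {
  g <- toy_genome()
  tx <- toy_transcripts()
  st <- coding_site_table(tx, g)
  reg <- mk_regions("chrT", 10, 22, "core", strand = "+")
  # uniform conditionals: opportunity = (# synonymous alts) / 3 summed
  cond <- matrix(1 / 3, 4, 4, dimnames = list(DNA <- c("A", "C", "G", "T"),
                                              DNA))
  diag(cond) <- 0
  opp <- synonymous_opportunity(st, reg, cond)
  syn_m <- as.matrix(st[st$chrom == "chrT" & st$pos >= 10 & st$pos < 22,
                        c("cls_A", "cls_C", "cls_G", "cls_T")]) == "Silent"
  expect_equal(unname(opp["core"]), sum(syn_m, na.rm = TRUE) / 3)
})
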