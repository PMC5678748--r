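test_that("genePred and BED12 dialects parse to the same coding exons", {
  gp <- tempfile(fileext = ".genepred")
  writeLines(paste(c("tx1", "chr1", "+", 10, 260, 10, 260, 3,
                     "10,100,200,", "60,160,260,", "geneA"), collapse = "\t"),
             gp)
  bed <- tempfile(fileext = ".bed")
  writeLines(paste(c("chr1", 10, 260, "tx1", 0, "+", 10, 260, "0", 3,
                     "50,60,60", "0,90,190"), collapse = "\t"), bed)
  a <- parse_transcript_table(gp, "genepred")
  b <- parse_transcript_table(bed, "bed12")
  expect_equal(nrow(a), 3)
  expect_equal(a[, c("chrom", "strand", "start", "end", "exon_rank")],
               b[, c("chrom", "strand", "start", "end", "exon_rank")])
  expect_equal(a$gene_id[1], "geneA")
})

test_that("coding exons are clipped to the CDS and UTR-only exons dropped", {
  gp <- tempfile()
  # exon 1 is 5' UTR entirely, exon 2 partially coding
  writeLines(paste(c("tx1", "chr1", "+", 0, 500, 150, 460, 3,
                     "0,100,400,", "50,200,500,"), collapse = "\t"), gp)
  m <- parse_transcript_table(gp, "genepred")
  expect_equal(nrow(m), 2)
  expect_equal(m$start, c(150, 400))
  expect_equal(m$end, c(200, 460))
})

test_that("malformed rows raise errors naming the line", {
  gp <- tempfile()
  writeLines(c("# comment",
               paste(c("tx1", "chr1", "+", 10, 260, 10, 260, 1,
                       "100,", "60,"), collapse = "\t")), gp)
  expect_error(parse_transcript_table(gp, "genepred"), "line 2.*end < start")
  writeLines(paste(c("tx1", "chr1", "+", "ten", 260, 10, 260, 1,
                     "10,", "60,"), collapse = "\t"), gp)
  expect_error(parse_transcript_table(gp, "genepred"), "line 1")
})

test_that("transcripts without coding sequence are skipped with a warning", {
  gp <- tempfile()
  writeLines(paste(c("tx1", "chr1", "+", 10, 60, 30, 30, 1,
                     "10,", "60,"), collapse = "\t"), gp)
  expect_warning(m <- parse_transcript_table(gp, "genepred"),
                 "without coding exons")
  expect_equal(nrow(m), 0)
})

test_that("only internal exons at or above the length threshold are kept", {
  m <- data.frame(transcript_id = "t", gene_id = "g", chrom = "chr1",
                  strand = "+",
                  start = c(0, 300, 700), end = c(200, 600, 950),
                  exon_rank = 1:3, n_coding_exons = 3,
                  stringsAsFactors = FALSE)
  out <- select_internal_coding_exons(m)
  expect_equal(nrow(out), 1)
  expect_equal(out$L, 300)

  m$end[2] <- 300 + 159                        # internal exon of 159 bp
  expect_equal(nrow(select_internal_coding_exons(m)), 0)
  m$end[2] <- 300 + 160                        # boundary: 160 bp included
  expect_equal(select_internal_coding_exons(m)$L, 160)
})

test_that("flank/core construction matches the stated interval formulas", {
  ex <- data.frame(transcript_id = "t", gene_id = "g", chrom = "chr1",
                   strand = "+", start = 0, end = 160, exon_rank = 2L,
                   n_coding_exons = 3, ordinal = 2L, L = 160, M = 80,
                   exon_id = "chr1:0-160:+", stringsAsFactors = FALSE)
  rs <- make_flank_core_regions(ex)
  df <- data.frame(role = mcols(rs)$role, start = start(rs) - 1, end = end(rs))
  expect_setequal(paste(df$role, df$start, df$end),
                  c("flank 0 20", "flank 140 160", "core 60 100"))

  rs3 <- make_flank_core_regions(ex, end_exclusion = 3)
  df3 <- data.frame(role = mcols(rs3)$role, start = start(rs3) - 1,
                    end = end(rs3))
  expect_setequal(paste(df3$role, df3$start, df3$end),
                  c("flank 3 20", "flank 140 157", "core 60 100"))

  # odd length: M = floor(L/2), core = [M-20, M+20)
  ex161 <- ex; ex161$end <- 161; ex161$L <- 161; ex161$M <- 80
  rs161 <- make_flank_core_regions(ex161)
  core <- rs161[mcols(rs161)$role == "core"]
  expect_equal(c(start(core) - 1, end(core)), c(60, 100))
})

test_that("construction errors on invalid geometry", {
  ex <- data.frame(transcript_id = "t", gene_id = "g", chrom = "chr1",
                   strand = "+", start = 0, end = 70, exon_rank = 2L,
                   n_coding_exons = 3, ordinal = 2L, L = 70, M = 35,
                   exon_id = "chr1:0-70:+", stringsAsFactors = FALSE)
  expect_error(make_flank_core_regions(ex), "overlap")
  ex$end <- 200; ex$L <- 200; ex$M <- 100
  expect_error(make_flank_core_regions(ex, end_exclusion = 20),
               "end_exclusion")
})

test_that("flank and core footprints are equal at defaults", {
  sim <- small_sim()
  rs <- make_flank_core_regions(sim$exons)
  expect_equal(sum(width(rs[mcols(rs)$role == "flank"])),
               sum(width(rs[mcols(rs)$role == "core"])))
  expect_equal(sum(width(rs[mcols(rs)$role == "core"])), 40 * nrow(sim$exons))
})

test_that("flank orientation follows transcription direction and is idempotent", {
  mk <- function(strand) {
    ex <- data.frame(transcript_id = "t", gene_id = "g", chrom = "chr1",
                     strand = strand, start = 0, end = 160, exon_rank = 2L,
                     n_coding_exons = 3, ordinal = 2L, L = 160, M = 80,
                     exon_id = paste0("chr1:0-160:", strand),
                     stringsAsFactors = FALSE)
    orient_flanks(make_flank_core_regions(ex))
  }
  plus <- mk("+")
  expect_equal(mcols(plus)$role[start(plus) == 1], "flank5")
  minus <- mk("-")
  expect_equal(mcols(minus)$role[start(minus) == 141], "flank5")
  # mirrored exon swaps the labels exactly
  expect_equal(sort(paste(mcols(plus)$role, start(plus))),
               sort(paste(c("flank3", "flank5", "core")[
                 match(mcols(minus)$role, c("flank5", "flank3", "core"))],
                 start(minus))))
  expect_identical(mcols(orient_flanks(plus))$role, mcols(plus)$role)
})

test_that("region sets round-trip through BED6", {
  sim <- small_sim()
  rs <- orient_flanks(make_flank_core_regions(sim$exons[1:5, ]))
  path <- tempfile(fileext = ".bed")
  write_regions_bed(rs, path)
  back <- read_regions_bed(path)
  expect_equal(length(back), length(rs))
  key <- function(g) sort(paste(seqnames(g), start(g), end(g),
                                mcols(g)$role, mcols(g)$exon_id))
  expect_equal(key(back), key(rs))

  write_regions_bed(empty_region_set <- rs[0], path)
  expect_equal(length(read_regions_bed(path)), 0)
  expect_match(readLines(path)[1], "^#")
})
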