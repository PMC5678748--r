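# Hand-built toy genome with one coding transcript per strand, used by the
# consequence-annotation and counting tests.
#   txP (+): CDS ATG GGA CTG TAA at chrT:10-22
#   txM (-): coding ATG CTG TAA; genome holds its reverse complement at 40-49
toy_genome <- function() {
  pad1 <- strrep("T", 10)
  cds_p <- "ATGGGACTGTAA"                     # 12 bp, +
  pad2 <- strrep("A", 18)                      # 22..40
  cds_m <- "TTACAGCAT"                         # revcomp(ATGCTGTAA), 9 bp, -
  pad3 <- strrep("T", 11)
  g <- Biostrings::DNAStringSet(paste0(pad1, cds_p, pad2, cds_m, pad3))
  names(g) <- "chrT"
  g
}

toy_transcripts <- function() {
  data.frame(
    transcript_id = c("txP", "txM"), gene_id = c("gP", "gM"),
    chrom = "chrT", strand = c("+", "-"),
    start = c(10, 40), end = c(22, 49),
    exon_rank = 1L, n_coding_exons = 1L, stringsAsFactors = FALSE)
}

# A small synthetic cohort shared by several tests.
small_sim <- function(seed = 7, n_genes = 40, n_tumours = 30, mu = 0.004,
                      purge_flank = 0.2, purge_ese = 0, cpg_multiplier = 1,
                      ese_hexamers = NULL, exons_per_gene = 5, ...) {
  p <- sim_params(n_genes = n_genes, exons_per_gene = exons_per_gene,
                  n_tumours = n_tumours,
                  mu = mu, purge_flank = purge_flank, purge_ese = purge_ese,
                  cpg_multiplier = cpg_multiplier, seed = seed, ...)
  gen <- generate_genome_and_transcripts(p, ese_hexamers)
  exons <- select_internal_coding_exons(gen$transcripts)
  regions <- orient_flanks(make_flank_core_regions(exons))
  sim <- simulate_cohort(gen$genome, gen$transcripts, regions, p)
  list(params = p, genome = gen$genome, transcripts = gen$transcripts,
       planted = gen$planted, exons = exons, regions = regions,
       mutations = sim$mutations, truth = sim$truth,
       site_table = sim$site_table,
       samples = sprintf("T%04d", seq_len(n_tumours)))
}

# Exhaustive-enumeration oracle for the two-sided exact signed-rank p-value
# (distinct nonzero differences).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wall <- as.vector(signs %*% r)
  min(1, 2 * min(mean(wall <= w), mean(wall >= w)))
}

# Exhaustive-permutation oracle for the two-sided exact rank-sum p-value
# (no ties).
oracle_rank_sum_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(a)
  wobs <- sum(vapply(a, function(x) sum(x > b), 0))
  combs <- utils::combn(length(pool), n)
  wall <- apply(combs, 2, function(idx)
    sum(vapply(pool[idx], function(x) sum(x > pool[-idx]), 0)))
  min(1, 2 * min(mean(wall <= wobs), mean(wall >= wobs)))
}

# Brute-force position-by-position membership for flank/core construction.
oracle_flank_core_membership <- function(L, flank_len = 20, core_len = 40,
                                         end_exclusion = 0) {
  M <- L %/% 2
  p <- 0:(L - 1)
  flank <- (p >= end_exclusion & p < flank_len) |
    (p >= L - flank_len & p < L - end_exclusion)
  core <- p >= M - core_len / 2 & p < M + core_len / 2
  list(flank = p[flank], core = p[core])
}

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else with_seed_test(seed, draw())
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
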