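#' Default substitution-class signature
#'
#' A generic cancer-like spectrum with an excess of C>T transitions, on the
#' six strand-collapsed classes.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_signature <- function() {
  c(`A>C` = 0.09, `A>G` = 0.17, `A>T` = 0.09,
    `C>G` = 0.11, `C>T` = 0.40, `G>T` = 0.14)
}

#' Simulation parameters
#'
#' Generator knobs for the synthetic genome, transcripts and tumour cohort.
#' Selection is modelled as independent thinning: a mutation arising in a
#' flank region is removed with probability `purge_flank`, in an ESE region
#' with `purge_ese` (when a site is both, the larger probability applies; no
#' compounding). These purge probabilities are the selection coefficients the
#' pipeline is asked to recover as depletion fractions.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Coding exons per gene (>= 3 so internal exons exist).
#' @param exon_length Length range `c(min, max)` in bp; minimum 160.
#' @param intron_length,intergenic_length Spacer lengths in bp.
#' @param gc_content Genome GC fraction.
#' @param ese_plant_rate Expected planted ESE hexamers per 69-bp flank zone
#'   of each internal exon (Poisson).
#' @param mu Per-base per-tumour mutation probability at non-CpG sites.
#' @param cpg_multiplier Fold increase of `mu` at CpG sites.
#' @param signature Named weights over the six substitution classes.
#' @param purge_flank,purge_ese Purge probabilities in `[0, 1]`.
#' @param gene_class_overrides Named list replacing `purge_flank` for genes
#'   of a given class (requires `gene_classes`), e.g.
#'   `list(tumour_suppressor = 0)`.
#' @param gene_classes Optional `data.frame` (`gene_id`, `class`).
#' @param n_tumours Cohort size.
#' @param seed Master seed; every downstream stream is derived from it.
#' @return A validated parameter list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 750, exons_per_gene = 6,
                       exon_length = c(180, 240), intron_length = 120,
                       intergenic_length = 300, gc_content = 0.5,
                       ese_plant_rate = 1.5, mu = 0.006,
                       cpg_multiplier = 10, signature = default_signature(),
                       purge_flank = 0.17, purge_ese = 0.25,
                       gene_class_overrides = list(), gene_classes = NULL,
                       n_tumours = 200, seed = 1) {
  if (min(exon_length) < 160) stop("exon lengths must be >= 160 bp")
  if (exons_per_gene < 3) stop("need >= 3 exons per gene for internal exons")
  probs <- c(purge_flank, purge_ese, gc_content, mu)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(signature) - 1) > 1e-8) stop("signature weights must sum to 1")
  if (!all(names(signature) %in% substitution_classes()) ||
      length(signature) != 6)
    stop("signature must weight exactly the six substitution classes")
  structure(list(n_genes = n_genes, exons_per_gene = exons_per_gene,
                 exon_length = exon_length, intron_length = intron_length,
                 intergenic_length = intergenic_length,
                 gc_content = gc_content, ese_plant_rate = ese_plant_rate,
                 mu = mu, cpg_multiplier = cpg_multiplier,
                 signature = signature[substitution_classes()],
                 purge_flank = purge_flank, purge_ese = purge_ese,
                 gene_class_overrides = gene_class_overrides,
                 gene_classes = gene_classes,
                 n_tumours = n_tumours, seed = seed),
            class = "sim_params")
}

#' Generate a synthetic genome and transcript set
#'
#' Random sequence at the requested GC content, tandem multi-exon genes on
#' alternating strands, with ESE hexamers from a supplied list planted
#' uniformly within 69 bp of the ends of internal exons (in coding
#' orientation; hexamers are reverse-complemented into the genome for
#' minus-strand genes). Deterministic under the parameter seed.
#'
#' @param params A [sim_params()] object.
#' @param ese_hexamers Optional hexamer list to plant; no planting if NULL.
#' @param zone_width Planting zone width from each internal-exon end.
#' @return A list: `genome` (`DNAStringSet`, one chromosome), `transcripts`
#'   (coding-exon table), `planted` (`data.frame` of planted motif
#'   positions).
#' @export
generate_genome_and_transcripts <- function(params, ese_hexamers = NULL,
                                            zone_width = 69) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(derive_seed(params$seed, 0L), {
    E <- params$exons_per_gene
    lens <- matrix(sample(seq(params$exon_length[1], params$exon_length[2]),
                          params$n_genes * E, replace = TRUE),
                   nrow = params$n_genes)
    adj <- rowSums(lens) %% 3L
    lens[, E] <- lens[, E] - adj
    strands <- sample(c("+", "-"), params$n_genes, replace = TRUE)
    total <- sum(lens) + params$n_genes *
      ((E - 1) * params$intron_length + params$intergenic_length) +
      params$intergenic_length
    gc <- params$gc_content
    chars <- sample(DNA, total, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    cursor <- params$intergenic_length
    tx_rows <- vector("list", params$n_genes)
    planted <- list()
    for (g in seq_len(params$n_genes)) {
      starts <- integer(E); ends <- integer(E)
      for (k in seq_len(E)) {
        starts[k] <- cursor
        ends[k] <- cursor + lens[g, k]
        cursor <- ends[k] + if (k < E) params$intron_length else
          params$intergenic_length
      }
      tx_rows[[g]] <- data.frame(
        transcript_id = sprintf("tx%04d", g), gene_id = sprintf("g%04d", g),
        chrom = "chr1", strand = strands[g],
        start = starts, end = ends, exon_rank = seq_len(E),
        n_coding_exons = E, stringsAsFactors = FALSE)
      if (!is.null(ese_hexamers)) {
        for (k in 2:(E - 1)) {
          L <- lens[g, k]
          for (zone in 0:1) {
            n_plant <- stats::rpois(1, params$ese_plant_rate)
            if (n_plant == 0) next
            offs <- sample(0:(zone_width - 6L), n_plant, replace = TRUE)
            p <- if (zone == 0) offs else L - zone_width + offs
            hx <- sample(ese_hexamers, n_plant, replace = TRUE)
            for (m in seq_len(n_plant)) {
              if (strands[g] == "+") {
                gs <- starts[k] + p[m]
                chars[(gs + 1):(gs + 6)] <- strsplit(hx[m], "")[[1]]
              } else {
                gs <- ends[k] - p[m] - 6L
                chars[(gs + 1):(gs + 6)] <- strsplit(revcomp(hx[m]), "")[[1]]
              }
              planted[[length(planted) + 1L]] <- data.frame(
                chrom = "chr1", start = gs, end = gs + 6L,
                strand = strands[g], hexamer = hx[m],
                exon_id = sprintf("chr1:%d-%d:%s", starts[k], ends[k],
                                  strands[g]),
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
    genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
    names(genome) <- "chr1"
    list(genome = genome,
         transcripts = validate_transcripts(do.call(rbind, tx_rows)),
         planted = if (length(planted)) do.call(rbind, planted)
         else data.frame(chrom = character(), start = integer(),
                         end = integer(), strand = character(),
                         hexamer = character(), exon_id = character()))
  })
}

# Per-site purge probability, CpG status and mutation weight.
site_annotations <- function(st, genome, regions, params) {
  chars <- genome_chars(load_genome(genome))
  nxt <- prv <- rep("", nrow(st))
  for (chrom in unique(st$chrom)) {
    k <- st$chrom == chrom
    v <- chars[[chrom]]
    p <- st$pos[k]
    nxt[k] <- ifelse(p + 2L <= length(v), v[p + 2L], "")
    prv[k] <- ifelse(p >= 1L, v[p], "")
  }
  cpg <- (st$ref == "C" & nxt == "G") | (st$ref == "G" & prv == "C")
  gr <- GenomicRanges::GRanges(st$chrom, IRanges::IRanges(st$pos + 1L, width = 1L))
  role <- mcols(regions)$role
  flags <- list(
    flank = IRanges::overlapsAny(
      gr, regions[role %in% c("flank", "flank5", "flank3")],
      ignore.strand = TRUE),
    core = IRanges::overlapsAny(gr, regions[role == "core"],
                                      ignore.strand = TRUE),
    ese = IRanges::overlapsAny(gr, regions[role == "ese"],
                                     ignore.strand = TRUE),
    non_ese = IRanges::overlapsAny(gr, regions[role == "non_ese"],
                                         ignore.strand = TRUE))
  pf <- rep(params$purge_flank, nrow(st))
  if (length(params$gene_class_overrides) && !is.null(params$gene_classes)) {
    gc_tab <- params$gene_classes
    for (cl in names(params$gene_class_overrides)) {
      gset <- gc_tab$gene_id[gc_tab$class == cl]
      pf[st$gene_id %in% gset] <- params$gene_class_overrides[[cl]]
    }
  }
  purge <- pmax(ifelse(flags$flank, pf, 0),
                ifelse(flags$ese, params$purge_ese, 0))
  w <- params$mu * ifelse(cpg, params$cpg_multiplier, 1)
  list(cpg = cpg, flags = flags, purge = purge, w = w)
}

#' Simulate a tumour cohort with region-dependent purifying selection
#'
#' For each tumour, candidate mutations arise independently per coding site
#' with probability `mu` (times `cpg_multiplier` at CpG sites, at most one
#' mutation per site per tumour); alternate alleles are drawn from the
#' substitution-class signature conditioned on the reference base; each
#' candidate falling in a flank region is purged with probability
#' `purge_flank` (gene-class overrides applied), in an ESE region with
#' `purge_ese`, the larger probability applying when both. Retained
#' mutations carry a re-derived consequence annotation; the truth table
#' records every arisen and purged event per region class.
#'
#' @param genome,transcripts Synthetic genome and transcript table.
#' @param regions `GRanges` region set whose roles (`flank5`/`flank3`/`core`,
#'   `ese`/`non_ese`) define where purging acts; pass the same region set the
#'   pipeline will analyse.
#' @param params A [sim_params()] object.
#' @param site_table Optional precomputed [coding_site_table()].
#' @return A list: `mutations` (record table with `maf_class`), `truth`
#'   (per-region-class arisen/purged/retained counts and realized depletion),
#'   `site_table`.
#' @export
simulate_cohort <- function(genome, transcripts, regions, params,
                            site_table = NULL) {
  stopifnot(inherits(params, "sim_params"))
  genome <- load_genome(genome)
  st <- site_table %||% coding_site_table(transcripts, genome)
  ann <- site_annotations(st, genome, regions, params)
  if (sum(ann$w) * params$n_tumours < 1)
    warning("expected mutation count below 1; increase mu")
  # Alt-allele distribution conditioned on the reference base.
  sig <- params$signature
  alt_prob <- lapply(setNames(DNA, DNA), function(b) {
    alts <- setdiff(DNA, b)
    wts <- vapply(alts, function(a) sig[[canonical_substitution_class(b, a)]], 0)
    list(alts = alts, cum = cumsum(wts / sum(wts)))
  })
  ref <- st$ref
  ref_idx <- lapply(setNames(DNA, DNA), function(b) which(ref == b))
  cls_m <- cbind(st$cls_A, st$cls_C, st$cls_G, st$cls_T)
  classes <- c("flank", "core", "ese", "non_ese", "outside")
  arisen <- purged <- setNames(numeric(5), classes)
  out_site <- out_alt <- out_tum <- vector("list", params$n_tumours)
  with_seed(derive_seed(params$seed, 1L), {
    for (t in seq_len(params$n_tumours)) {
      idx <- which(stats::runif(nrow(st)) < ann$w)
      if (length(idx) == 0L) { out_site[[t]] <- integer(); next }
      alt <- character(length(idx))
      for (b in DNA) {
        k <- which(ref[idx] == b)
        if (!length(k)) next
        u <- stats::runif(length(k))
        pick <- findInterval(u, alt_prob[[b]]$cum) + 1L
        alt[k] <- alt_prob[[b]]$alts[pick]
      }
      keep <- stats::runif(length(idx)) >= ann$purge[idx]
      for (cl in c("flank", "core", "ese", "non_ese")) {
        f <- ann$flags[[cl]][idx]
        arisen[cl] <- arisen[cl] + sum(f)
        purged[cl] <- purged[cl] + sum(f & !keep)
      }
      outside <- !(ann$flags$flank[idx] | ann$flags$core[idx] |
                     ann$flags$ese[idx] | ann$flags$non_ese[idx])
      arisen["outside"] <- arisen["outside"] + sum(outside)
      purged["outside"] <- purged["outside"] + sum(outside & !keep)
      out_site[[t]] <- idx[keep]
      out_alt[[t]] <- alt[keep]
      out_tum[[t]] <- rep(t, sum(keep))
    }
  })
  sites <- unlist(out_site, use.names = FALSE)
  alts <- unlist(out_alt, use.names = FALSE)
  tums <- unlist(out_tum, use.names = FALSE)
  maf_class <- cls_m[cbind(sites, match(alts, DNA))]
  mutations <- data.frame(
    sample_id = sprintf("T%04d", tums),
    chrom = st$chrom[sites], pos = st$pos[sites],
    ref = ref[sites], alt = alts,
    consequence = ifelse(maf_class == "Silent", "synonymous",
                         "non_synonymous"),
    gene_id = st$gene_id[sites], maf_class = maf_class,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    region_class = classes,
    arisen = as.numeric(arisen), purged = as.numeric(purged),
    retained = as.numeric(arisen - purged),
    realized_depletion = ifelse(arisen > 0, purged / arisen, NA_real_),
    stringsAsFactors = FALSE)
  list(mutations = mutations, truth = truth, site_table = st)
}

#' Synthetic covariate and label fixtures
#'
#' Per-exon scores drawn uniformly and independently of flank/core identity
#' (null covariates), gene class labels and per-sample MSI labels at
#' configurable fractions; deterministic under the seed. Columns match the
#' stratification module's input contract.
#'
#' @param exons Exon-context table (provides exon and gene ids).
#' @param n_samples Number of cohort samples to label.
#' @param seed Integer seed.
#' @param onc_fraction,tsg_fraction Fractions of oncogenes / tumour
#'   suppressors.
#' @param essential_fraction Fraction of essential genes.
#' @param alt_fraction Fraction of alternatively spliced exons.
#' @param msi_fraction Fraction of MSI samples.
#' @return A list of `data.frame`s: `exon_scores`, `gene_table`,
#'   `sample_table`.
#' @export
make_covariate_fixtures <- function(exons, n_samples, seed = 1,
                                    onc_fraction = 0.05, tsg_fraction = 0.05,
                                    essential_fraction = 0.3,
                                    alt_fraction = 0.3, msi_fraction = 0.2) {
  with_seed(derive_seed(seed, 2L), {
    exon_scores <- data.frame(
      exon_id = exons$exon_id,
      nucleosome = stats::runif(nrow(exons)),
      replication_timing = stats::runif(nrow(exons)),
      mappability = stats::runif(nrow(exons), 0.95, 1),
      alt_const = sample(c("alternative", "constitutive"), nrow(exons),
                         replace = TRUE,
                         prob = c(alt_fraction, 1 - alt_fraction)),
      stringsAsFactors = FALSE)
    genes <- unique(exons$gene_id)
    n_onc <- round(onc_fraction * length(genes))
    n_tsg <- round(tsg_fraction * length(genes))
    shuffled <- sample(genes)
    cancer_class <- setNames(rep("non_cancer", length(genes)), shuffled)
    cancer_class[seq_len(n_onc)] <- "oncogene"
    cancer_class[n_onc + seq_len(n_tsg)] <- "tumour_suppressor"
    gene_table <- data.frame(
      gene_id = shuffled, cancer_class = unname(cancer_class),
      essentiality = sample(c("essential", "non_essential"), length(genes),
                            replace = TRUE,
                            prob = c(essential_fraction,
                                     1 - essential_fraction)),
      stringsAsFactors = FALSE)
    sample_table <- data.frame(
      sample_id = sprintf("T%04d", seq_len(n_samples)),
      msi_status = sample(c("MSI", "MSS"), n_samples, replace = TRUE,
                          prob = c(msi_fraction, 1 - msi_fraction)),
      cohort = "SIM", stringsAsFactors = FALSE)
    list(exon_scores = exon_scores, gene_table = gene_table,
         sample_table = sample_table)
  })
}
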