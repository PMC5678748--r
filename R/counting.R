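#' Positions participating in a CpG dinucleotide
#'
#' Returns every position inside the given regions whose base is the C or the
#' G of a CG dinucleotide on the plus genome strand. Context is read across
#' interval boundaries (a terminal C whose next genomic base lies outside the
#' interval is still masked) because CpG hypermutability is a property of the
#' sequence context, not of the interval. At a contig edge the missing
#' context contributes no mask, with a message.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param regions `GRanges` region set.
#' @return A `GRanges` of width-1 masked positions (unique, sorted).
#' @export
mask_cpg_positions <- function(genome, regions) {
  genome <- load_genome(genome)
  if (any(start(regions) == 1 |
          end(regions) == Biostrings::width(genome)[
            match(as.character(seqnames(regions)), names(genome))]))
    message("interval end(s) at a contig edge: context absent on that side")
  out <- list()
  for (chrom in intersect(names(genome), unique(as.character(seqnames(regions))))) {
    # scan the whole contig so context beyond interval edges is included
    hits <- gregexpr("CG", as.character(genome[[chrom]]), fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    pos1 <- sort(unique(c(hits, hits + 1L)))  # 1-based C and G positions
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos1, width = 1L))
    out[[chrom]] <- IRanges::subsetByOverlaps(gr, regions, ignore.strand = TRUE)
  }
  if (length(out) == 0L) return(GenomicRanges::GRanges())
  sort(unique(do.call(c, unname(out))))
}

mutations_granges <- function(ssms) {
  GenomicRanges::GRanges(ssms$chrom, IRanges::IRanges(ssms$pos + 1, width = 1L))
}

# Role of each mutation, NA outside all regions; errors if a mutation is
# claimed by two regions (region construction guarantees disjointness).
assign_roles <- function(ssms, regions) {
  gr <- mutations_granges(ssms)
  hits <- GenomicRanges::findOverlaps(gr, regions, ignore.strand = TRUE)
  if (anyDuplicated(queryHits(hits))) {
    dup <- queryHits(hits)[duplicated(queryHits(hits))][1]
    stop("mutation at ", ssms$chrom[dup], ":", ssms$pos[dup],
         " assignable to more than one region")
  }
  role <- rep(NA_character_, nrow(ssms))
  role[queryHits(hits)] <- mcols(regions)$role[subjectHits(hits)]
  role
}

region_effective_bp <- function(regions, mask = NULL) {
  roles <- unique(mcols(regions)$role)
  total <- vapply(roles, function(r)
    sum(width(regions[mcols(regions)$role == r])), 0)
  masked <- rep(0, length(roles))
  if (!is.null(mask) && length(mask) > 0L) {
    masked <- vapply(roles, function(r)
      sum(GenomicRanges::countOverlaps(mask,
                                       regions[mcols(regions)$role == r],
                                       ignore.strand = TRUE) > 0), 0)
  }
  data.frame(role = roles, total_bp = total, effective_bp = total - masked,
             stringsAsFactors = FALSE, row.names = NULL)
}

drop_masked_mutations <- function(ssms, mask) {
  if (is.null(mask) || length(mask) == 0L) return(ssms)
  gr <- mutations_granges(ssms)
  hit <- IRanges::overlapsAny(gr, mask, ignore.strand = TRUE)
  ssms[!hit, , drop = FALSE]
}

#' Count mutations per region role
#'
#' Assigns each mutation to at most one role by position, excludes mutations
#' at masked positions, and returns per-role counts together with total and
#' effective (unmasked) bp.
#'
#' @param ssms Mutation table.
#' @param regions `GRanges` region set.
#' @param mask Optional `GRanges` of masked width-1 positions.
#' @return A `data.frame` with `role`, `count`, `total_bp`, `effective_bp`.
#' @export
count_mutations_in_regions <- function(ssms, regions, mask = NULL) {
  bp <- region_effective_bp(regions, mask)
  ssms <- drop_masked_mutations(ssms, mask)
  role <- assign_roles(ssms, regions)
  cnt <- table(factor(role, levels = bp$role))
  bp$count <- as.integer(cnt[bp$role])
  bp[, c("role", "count", "total_bp", "effective_bp")]
}

#' SSM density per bp per tumour
#'
#' @param count Mutation count.
#' @param effective_bp Unmasked interval footprint in bp.
#' @param n_tumours Number of tumours in the cohort.
#' @return `count / (effective_bp * n_tumours)` (vectorized).
#' @export
ssm_density <- function(count, effective_bp, n_tumours) {
  if (any(effective_bp <= 0) || any(n_tumours <= 0))
    stop("effective_bp and n_tumours must be positive")
  count / (effective_bp * n_tumours)
}

#' Per-tumour, per-role density table
#'
#' One row per tumour per role, with explicit zero counts for tumours that
#' have no mutation in a role, so paired tests keep every tumour.
#'
#' @param ssms Mutation table.
#' @param regions `GRanges` region set.
#' @param mask Optional mask positions.
#' @param samples Sample universe; defaults to the samples present in `ssms`
#'   (supply the full cohort to retain tumours with zero mutations).
#' @return A `data.frame` with `sample_id`, `role`, `count`, `effective_bp`,
#'   `rate` (count per bp for that tumour).
#' @export
per_tumour_density_table <- function(ssms, regions, mask = NULL,
                                     samples = NULL) {
  bp <- region_effective_bp(regions, mask)
  ssms <- drop_masked_mutations(ssms, mask)
  role <- assign_roles(ssms, regions)
  samples <- samples %||% sort(unique(ssms$sample_id))
  grid <- expand.grid(sample_id = samples, role = bp$role,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  inreg <- !is.na(role)
  cnt <- table(factor(ssms$sample_id[inreg], levels = samples),
               factor(role[inreg], levels = bp$role))
  grid$count <- as.integer(cnt[cbind(grid$sample_id, grid$role)])
  grid$effective_bp <- bp$effective_bp[match(grid$role, bp$role)]
  grid$rate <- grid$count / grid$effective_bp
  grid
}

# DNAStringSet of the sequences under a set of intervals.
region_sequences <- function(genome, regions, flank = 0L) {
  genome <- load_genome(genome)
  out <- vector("list", length(unique(seqnames(regions))))
  seqs <- Biostrings::DNAStringSet()
  for (chrom in unique(as.character(seqnames(regions)))) {
    sub <- regions[seqnames(regions) == chrom]
    ir <- IRanges::IRanges(pmax(start(sub) - flank, 1L),
                           pmin(end(sub) + flank, length(genome[[chrom]])))
    seqs <- c(seqs, Biostrings::extractAt(genome[[chrom]], ir))
  }
  seqs
}

#' Substitution-class normalized rates per role
#'
#' For each role and class X>Y the rate is the count of SSMs of that class
#' divided by the number of eligible reference bases (occurrences of X plus
#' occurrences of complement(X) in the role's sequence, since X>Y and its
#' reverse complement are one class) times the tumour count. Roles with no
#' eligible bases for a class report `NA`.
#'
#' @param ssms Mutation table.
#' @param regions `GRanges` region set.
#' @param genome `DNAStringSet` or FASTA path.
#' @param n_tumours Number of tumours.
#' @return A `data.frame` with `role`, `class`, `count`, `denom_bp`, `rate`.
#' @export
class_normalized_rates <- function(ssms, regions, genome, n_tumours) {
  genome <- load_genome(genome)
  role <- assign_roles(ssms, regions)
  cls <- canonical_substitution_class(ssms$ref, ssms$alt)
  roles <- unique(mcols(regions)$role)
  classes <- substitution_classes()
  rows <- list()
  for (r in roles) {
    seqs <- region_sequences(genome, regions[mcols(regions)$role == r])
    basecnt <- colSums(Biostrings::letterFrequency(seqs, DNA))
    inrole <- !is.na(role) & role == r
    cnt <- table(factor(cls[inrole], levels = classes))
    for (cl in classes) {
      x <- substr(cl, 1, 1)
      denom <- unname(basecnt[x] + basecnt[comp_base(x)])
      rows[[length(rows) + 1L]] <- data.frame(
        role = r, class = cl, count = as.integer(cnt[cl]), denom_bp = denom,
        rate = if (denom > 0) as.integer(cnt[cl]) / (denom * n_tumours)
        else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (any(is.na(out$rate)))
    message(sum(is.na(out$rate)), " role/class rate(s) undefined (no eligible bases)")
  out
}

#' Trinucleotide-context normalized rates per role
#'
#' Numerators are SSM counts per canonical trinucleotide class in the role;
#' denominators are the occurrences of the class's reference trinucleotide in
#' the role's sequence, counted on both strands via the canonical collapse
#' (occurrences of the trinucleotide plus of its reverse complement), with
#' 1 bp of genome context beyond interval edges so terminal bases keep their
#' context, times the tumour count.
#'
#' @inheritParams class_normalized_rates
#' @return A `data.frame` with `role`, `class`, `count`, `denom`, `rate`.
#' @export
trinuc_rates <- function(ssms, regions, genome, n_tumours) {
  genome <- load_genome(genome)
  role <- assign_roles(ssms, regions)
  keep <- !is.na(role)
  tnc <- rep(NA_character_, nrow(ssms))
  if (any(keep))
    tnc[keep] <- trinucleotide_class(genome, ssms$chrom[keep],
                                     ssms$pos[keep], ssms$ref[keep],
                                     ssms$alt[keep])
  roles <- unique(mcols(regions)$role)
  classes <- trinuc_classes()
  # label layout: 5'base [ ref > alt ] 3'base, e.g. "A[C>T]G"
  ref_tri <- vapply(classes, function(cl) {
    paste0(substr(cl, 1, 1), substr(cl, 3, 3), substr(cl, 7, 7))
  }, "")
  rows <- list()
  for (r in roles) {
    seqs <- region_sequences(genome, regions[mcols(regions)$role == r],
                             flank = 1L)
    tri_cnt <- colSums(Biostrings::trinucleotideFrequency(seqs))
    inrole <- keep & role == r & !is.na(tnc)
    cnt <- table(factor(tnc[inrole], levels = classes))
    denom <- tri_cnt[ref_tri] + tri_cnt[revcomp(ref_tri)]
    rows[[length(rows) + 1L]] <- data.frame(
      role = r, class = classes, count = as.integer(cnt[classes]),
      denom = unname(denom),
      rate = ifelse(denom > 0, as.integer(cnt[classes]) / (denom * n_tumours),
                    NA_real_),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Estimated fraction of mutations removed by selection
#'
#' Treating the core rate as the local background mutation rate, the share of
#' flank mutational events rendered unobservable by purifying selection is
#' `1 - flank_rate / core_rate`. Negative values indicate a flank excess.
#'
#' @param flank_rate,core_rate Densities on the same scale.
#' @return The depletion fraction.
#' @export
depletion_fraction <- function(flank_rate, core_rate) {
  if (any(core_rate == 0)) stop("core_rate must be non-zero")
  1 - flank_rate / core_rate
}

#' Mean per-base score per role and per interval
#'
#' Scores arrive as a long table (`chrom`, `pos` 0-based, `score`), e.g.
#' mappability or nucleosome occupancy averaged per base. Uncovered bases are
#' excluded and the coverage fraction reported via a message.
#'
#' @param per_base_scores Score table.
#' @param regions `GRanges` region set.
#' @return A list with `per_role` (role, mean, n_bases) and `per_interval`
#'   (interval index, role, exon_id, mean, n_bases).
#' @export
region_mean_score <- function(per_base_scores, regions) {
  key <- paste(per_base_scores$chrom, per_base_scores$pos)
  per_int <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    pos <- seq.int(start(regions)[i] - 1L, end(regions)[i] - 1L)
    v <- per_base_scores$score[
      match(paste(as.character(seqnames(regions)[i]), pos), key)]
    per_int[[i]] <- data.frame(
      interval = i, role = mcols(regions)$role[i],
      exon_id = mcols(regions)$exon_id[i],
      mean = mean(v, na.rm = TRUE), n_bases = sum(!is.na(v)),
      stringsAsFactors = FALSE)
  }
  per_int <- do.call(rbind, per_int)
  covered <- sum(per_int$n_bases) / sum(width(regions))
  if (covered < 1) message(sprintf("score coverage: %.1f%% of region bases",
                                   100 * covered))
  agg <- lapply(split(per_int, per_int$role), function(d)
    data.frame(role = d$role[1],
               mean = sum(d$mean * d$n_bases, na.rm = TRUE) /
                 sum(d$n_bases[!is.na(d$mean)]),
               n_bases = sum(d$n_bases), stringsAsFactors = FALSE))
  list(per_role = do.call(rbind, c(agg, list(make.row.names = FALSE))),
       per_interval = per_int)
}

#' Alt-allele conditional probabilities from observed mutations
#'
#' Empirical probability of each alternate allele given the reference base,
#' estimated from all observed single-nucleotide records. Because purifying
#' selection removes mutations irrespective of the alternate allele, these
#' conditionals are not distorted by region-dependent purging.
#'
#' @param records Mutation table (all consequences, not just synonymous).
#' @return A 4x4 matrix `cond[ref, alt]` with rows summing to 1 over the
#'   three alternates (diagonal 0).
#' @export
estimate_alt_conditionals <- function(records) {
  cnt <- table(factor(records$ref, levels = DNA),
               factor(records$alt, levels = DNA))
  cond <- matrix(0, 4, 4, dimnames = list(DNA, DNA))
  for (b in DNA) {
    tot <- sum(cnt[b, ])
    cond[b, ] <- if (tot > 0) cnt[b, ] / tot else
      ifelse(DNA == b, 0, 1 / 3)
  }
  cond
}

#' Synonymous opportunity per region role
#'
#' For each (unmasked) coding site the opportunity is the probability that a
#' mutation arising there is synonymous, under the supplied alt-allele
#' conditionals; the per-role sum is the expected number of synonymous
#' mutations per unit of per-site mutation rate. Dividing SSM counts by this
#' opportunity (times the tumour count) gives a density that is comparable
#' across region classes with different base composition and codon structure.
#'
#' @param site_table A [coding_site_table()].
#' @param regions `GRanges` region set.
#' @param cond Alt conditionals from [estimate_alt_conditionals()].
#' @param mask Optional `GRanges` of masked positions.
#' @return Named numeric vector of opportunities, one per role.
#' @export
synonymous_opportunity <- function(site_table, regions, cond, mask = NULL) {
  st <- site_table
  gr <- GenomicRanges::GRanges(st$chrom, IRanges::IRanges(st$pos + 1L, width = 1L))
  if (!is.null(mask) && length(mask) > 0L) {
    keep <- !IRanges::overlapsAny(gr, mask, ignore.strand = TRUE)
    st <- st[keep, ]; gr <- gr[keep]
  }
  syn_m <- cbind(st$cls_A, st$cls_C, st$cls_G, st$cls_T) == "Silent"
  syn_m[is.na(syn_m)] <- FALSE
  cond_site <- cond[st$ref, , drop = FALSE]
  opp <- rowSums(syn_m * cond_site)
  roles <- unique(mcols(regions)$role)
  vapply(setNames(roles, roles), function(r) {
    sum(opp[IRanges::overlapsAny(gr, regions[mcols(regions)$role == r],
                                 ignore.strand = TRUE)])
  }, 0)
}
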