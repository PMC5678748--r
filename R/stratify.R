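#' Upper/lower quantile strata of scored exons
#'
#' High stratum: exons with score at or above the `1 - upper_q` quantile.
#' Low stratum: exons with score at or below the `lower_q` quantile. With the
#' defaults these are the top and bottom 25%.
#'
#' @param exon_scores Named numeric vector (names are exon ids).
#' @param upper_q,lower_q Tail fractions.
#' @return A list with character vectors `high` and `low` (disjoint).
#' @export
quartile_strata <- function(exon_scores, upper_q = 0.25, lower_q = 0.25) {
  if (length(exon_scores) < 4) stop("need at least 4 scored exons")
  if (length(unique(exon_scores)) == 1L)
    stop("all scores identical: quantile strata are degenerate")
  hi_cut <- stats::quantile(exon_scores, 1 - upper_q)
  lo_cut <- stats::quantile(exon_scores, lower_q)
  high <- names(exon_scores)[exon_scores >= hi_cut]
  low <- names(exon_scores)[exon_scores <= lo_cut]
  both <- intersect(high, low)
  if (length(both))
    stop("degenerate quantiles: ", length(both),
         " exon(s) fall in both strata")
  list(high = high, low = low)
}

#' Partition genes into cancer classes
#'
#' Every analysed gene is assigned to exactly one of `oncogene`,
#' `tumour_suppressor` or `non_cancer`; genes absent from the table default
#' to `non_cancer`, and genes annotated with conflicting classes are excluded
#' from all three sets with a message.
#'
#' @param gene_table `data.frame` with `gene_id` and `cancer_class`.
#' @param genes Character vector of all analysed gene ids.
#' @return A named list of gene-id vectors.
#' @export
partition_genes <- function(gene_table, genes) {
  classes <- c("oncogene", "tumour_suppressor", "non_cancer")
  assigned <- setNames(rep("non_cancer", length(genes)), genes)
  if (!is.null(gene_table) && nrow(gene_table) > 0) {
    dup <- tapply(gene_table$cancer_class, gene_table$gene_id,
                  function(x) length(unique(x)))
    conflicted <- names(dup)[dup > 1]
    if (length(conflicted))
      message(length(conflicted),
              " gene(s) with conflicting cancer classes excluded")
    tab <- gene_table[!gene_table$gene_id %in% conflicted, , drop = FALSE]
    hit <- tab$gene_id %in% genes
    assigned[tab$gene_id[hit]] <- tab$cancer_class[hit]
    assigned <- assigned[!names(assigned) %in% conflicted]
  }
  lapply(setNames(classes, classes), function(cl)
    names(assigned)[assigned == cl])
}

#' Split cohort samples by a categorical annotation
#'
#' @param sample_table `data.frame` with `sample_id` and the key column.
#' @param key Column to split on (default `msi_status`).
#' @param samples Optional sample universe; samples absent from the table go
#'   into the `unknown` set.
#' @return A named list of sample-id vectors.
#' @export
split_samples <- function(sample_table, key = "msi_status", samples = NULL) {
  if (!key %in% names(sample_table)) stop("key column not found: ", key)
  samples <- samples %||% unique(sample_table$sample_id)
  val <- sample_table[[key]][match(samples, sample_table$sample_id)]
  val[is.na(val)] <- "unknown"
  split(samples, val)
}

#' Run the flank/core comparison within covariate strata
#'
#' Executes the identical counting -> per-tumour table -> paired statistics
#' pipeline within each stratum. Strata can be sets of exon ids (the regions
#' are subset) or sets of sample ids (the mutations are subset). Empty strata
#' are skipped with a message.
#'
#' @param strata Named list of exon-id or sample-id vectors.
#' @param ssms Synonymous mutation table.
#' @param regions Oriented flank/core `GRanges` region set.
#' @param by `"exon"` or `"sample"`.
#' @param samples Full cohort sample ids (defines `n_tumours` for exon
#'   strata).
#' @param mask Optional CpG mask.
#' @param B,confidence,seed Bootstrap settings.
#' @return A `data.frame` with one row per non-empty stratum.
#' @export
run_stratified_comparison <- function(strata, ssms, regions,
                                      by = c("exon", "sample"),
                                      samples = NULL, mask = NULL,
                                      B = 500, confidence = 0.95, seed = 1) {
  by <- match.arg(by)
  samples <- samples %||% sort(unique(ssms$sample_id))
  rows <- list()
  for (nm in names(strata)) {
    set <- strata[[nm]]
    if (by == "exon") {
      reg_s <- regions[mcols(regions)$exon_id %in% set]
      ssm_s <- ssms
      samp_s <- samples
    } else {
      reg_s <- regions
      ssm_s <- ssms[ssms$sample_id %in% set, , drop = FALSE]
      samp_s <- intersect(samples, set)
    }
    if (length(reg_s) == 0L || length(samp_s) == 0L) {
      message("stratum '", nm, "' empty: skipped")
      next
    }
    mask_s <- if (!is.null(mask) && length(mask) > 0L)
      mask[IRanges::overlapsAny(mask, reg_s, ignore.strand = TRUE)]
    else mask
    pt <- per_tumour_density_table(ssm_s, reg_s, mask_s, samples = samp_s)
    cmp <- compare_flank_core(pt, B = B, confidence = confidence,
                              seed = derive_seed(seed, match(nm, names(strata))))
    cmp$stratum <- nm
    rows[[nm]] <- cmp
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
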