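#' Build a run configuration
#'
#' Collects input locations (or in-memory objects) and every analysis
#' parameter, with defaults matching the reference analysis: 20-bp flanks,
#' 40-bp core, internal exons >= 160 bp, a 69-bp hexamer scan window,
#' non-ESE hexamers at Hamming distance >= 2, bootstrap B = 500 at 95%
#' confidence.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param transcripts Coding-exon table, or path (dialect from extension:
#'   `.bed` is BED12, otherwise genePred).
#' @param mutations Mutation table, or MAF path.
#' @param cohorts Optional `data.frame` (`sample_id`, `cohort`); default puts
#'   every sample in one cohort. Samples listed here but absent from the
#'   mutation table still count toward `n_tumours`.
#' @param hexamers_ese ESE hexamer vector or list-file path.
#' @param hexamers_non_ese Optional explicit control hexamer set; default is
#'   derived with [build_non_ese_set()].
#' @param non_ese_sample Optional integer: use a seeded random sample of this
#'   size from the derived control set (a size-matched control; see the
#'   methods vignette).
#' @param covariates Optional list with `exon_scores`, `gene_table`,
#'   `sample_table` (objects or TSV paths).
#' @param flank_len,core_len,min_exon_length,end_exclusion Interval geometry.
#' @param ese_end_window Hexamer scan window from each exon end.
#' @param non_ese_min_distance Minimum Hamming distance for the control set.
#' @param watson_only Restrict hexamer scanning to plus-strand genes.
#' @param symmetric_overlap_discard Drop both sides of ESE/non-ESE overlaps.
#' @param cpg_mask Mask CpG dinucleotide positions before counting.
#' @param consequence_mode `"annotation"` or `"recompute"`.
#' @param B,confidence Bootstrap settings.
#' @param seed Master seed for all derived randomness.
#' @return A configuration list of class `ssm_run_config`.
#' @export
run_config <- function(genome, transcripts, mutations = NULL, cohorts = NULL,
                       hexamers_ese = NULL, hexamers_non_ese = NULL,
                       non_ese_sample = NULL, covariates = NULL,
                       flank_len = 20, core_len = 40, min_exon_length = 160,
                       end_exclusion = 0, ese_end_window = 69,
                       non_ese_min_distance = 2, watson_only = FALSE,
                       symmetric_overlap_discard = TRUE, cpg_mask = FALSE,
                       consequence_mode = c("annotation", "recompute"),
                       B = 500, confidence = 0.95, seed = 1) {
  structure(list(genome = genome, transcripts = transcripts,
                 mutations = mutations, cohorts = cohorts,
                 hexamers_ese = hexamers_ese,
                 hexamers_non_ese = hexamers_non_ese,
                 non_ese_sample = non_ese_sample, covariates = covariates,
                 flank_len = flank_len, core_len = core_len,
                 min_exon_length = min_exon_length,
                 end_exclusion = end_exclusion,
                 ese_end_window = ese_end_window,
                 non_ese_min_distance = non_ese_min_distance,
                 watson_only = watson_only,
                 symmetric_overlap_discard = symmetric_overlap_discard,
                 cpg_mask = cpg_mask,
                 consequence_mode = match.arg(consequence_mode),
                 B = B, confidence = confidence, seed = seed),
            class = "ssm_run_config")
}

#' Read a run configuration from YAML
#'
#' Field names mirror the arguments of [run_config()]; path-valued fields are
#' resolved relative to the YAML file's directory.
#'
#' @param path YAML file.
#' @return An `ssm_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("genome", "transcripts", "mutations", "hexamers_ese",
              "hexamers_non_ese")) {
    if (!is.null(y[[f]]) && is.character(y[[f]]) &&
        !file.exists(y[[f]]) && file.exists(file.path(base, y[[f]])))
      y[[f]] <- file.path(base, y[[f]])
  }
  do.call(run_config, y)
}

resolve_config_inputs <- function(config) {
  config$genome <- load_genome(config$genome)
  if (is.character(config$transcripts)) {
    dialect <- if (grepl("\\.bed$", config$transcripts, ignore.case = TRUE))
      "bed12" else "genepred"
    config$transcripts <- parse_transcript_table(config$transcripts, dialect)
  }
  is_path <- function(x) is.character(x) && length(x) == 1L && file.exists(x)
  if (is.character(config$mutations))
    config$mutations <- read_mutations(config$mutations, "maf")
  if (is_path(config$hexamers_ese))
    config$hexamers_ese <- read_hexamer_list(config$hexamers_ese)
  if (is_path(config$hexamers_non_ese))
    config$hexamers_non_ese <- read_hexamer_list(config$hexamers_non_ese)
  config
}

# Pool the two oriented flank roles into one "flank" role per tumour.
pool_flank_roles <- function(pt) {
  fl <- pt[pt$role %in% c("flank5", "flank3"), , drop = FALSE]
  agg <- stats::aggregate(cbind(count, effective_bp) ~ sample_id, fl, sum)
  agg$role <- "flank"
  agg$rate <- agg$count / agg$effective_bp
  rbind(agg[, names(pt)], pt[!pt$role %in% c("flank5", "flank3"), , drop = FALSE])
}

# Paired comparison of two roles on a per-tumour table: pooled and mean
# rates, Wilcoxon signed rank, bootstrap CIs, depletion fraction.
compare_pair <- function(pt, role_a, role_b, B = 500, confidence = 0.95,
                         seed = 1) {
  wide <- merge(pt[pt$role == role_a, ], pt[pt$role == role_b, ],
                by = "sample_id", suffixes = c("_a", "_b"))
  n <- nrow(wide)
  bp_a <- wide$effective_bp_a[1]; bp_b <- wide$effective_bp_b[1]
  pooled_a <- sum(wide$count_a) / (bp_a * n)
  pooled_b <- sum(wide$count_b) / (bp_b * n)
  ci_a <- bootstrap_mean_ci(wide$rate_a, B, confidence, derive_seed(seed, 11))
  ci_b <- bootstrap_mean_ci(wide$rate_b, B, confidence, derive_seed(seed, 12))
  data.frame(
    n_tumours = n,
    count_a = sum(wide$count_a), count_b = sum(wide$count_b),
    effective_bp_a = bp_a, effective_bp_b = bp_b,
    pooled_rate_a = pooled_a, pooled_rate_b = pooled_b,
    mean_rate_a = mean(wide$rate_a), mean_rate_b = mean(wide$rate_b),
    ci_low_a = ci_a[["low"]], ci_high_a = ci_a[["high"]],
    ci_low_b = ci_b[["low"]], ci_high_b = ci_b[["high"]],
    wilcoxon_p = wilcoxon_signed_rank(wide$rate_a, wide$rate_b),
    depletion = if (pooled_b > 0) depletion_fraction(pooled_a, pooled_b)
    else NA_real_,
    stringsAsFactors = FALSE)
}

# Flank (5'+3' pooled) vs core comparison on an oriented per-tumour table.
compare_flank_core <- function(pt, B = 500, confidence = 0.95, seed = 1) {
  compare_pair(pool_flank_roles(pt), "flank", "core", B, confidence, seed)
}

cohort_map <- function(config) {
  if (!is.null(config$cohorts)) return(config$cohorts)
  samples <- sort(unique(config$mutations$sample_id))
  data.frame(sample_id = samples, cohort = "cohort1",
             stringsAsFactors = FALSE)
}

filtered_ssms <- function(config, site_table = NULL) {
  ssms <- filter_synonymous(config$mutations, config$consequence_mode,
                            config$transcripts, config$genome,
                            site_table = site_table)
  if (nrow(ssms) == 0L)
    stop("no synonymous mutations after filtering (",
         nrow(config$mutations), " input records; consequences: ",
         paste(names(table(config$mutations$consequence)), collapse = ", "),
         ")")
  ssms
}

# Per-cohort battery plus cross-cohort combination for any region pair.
cohort_battery <- function(ssms, regions, mask, cohorts, config,
                           role_a, role_b, pooled_flank = FALSE) {
  per_cohort <- list()
  per_tumour <- list()
  sign_counts <- c(k = 0L, n = 0L)
  for (co in unique(cohorts$cohort)) {
    samples <- sort(cohorts$sample_id[cohorts$cohort == co])
    ssm_co <- ssms[ssms$sample_id %in% samples, , drop = FALSE]
    pt <- per_tumour_density_table(ssm_co, regions, mask, samples = samples)
    cmp <- if (pooled_flank)
      compare_flank_core(pt, config$B, config$confidence,
                         derive_seed(config$seed, length(per_cohort) + 1L))
    else
      compare_pair(pt, role_a, role_b, config$B, config$confidence,
                   derive_seed(config$seed, length(per_cohort) + 1L))
    cmp <- cbind(cohort = co, cmp, stringsAsFactors = FALSE)
    per_cohort[[co]] <- cmp
    pt$cohort <- co
    per_tumour[[co]] <- pt
    if (pooled_flank) {
      n <- cmp$n_tumours
      cnt <- stats::aggregate(count ~ role, pt, sum)
      eff <- pt[!duplicated(pt$role), c("role", "effective_bp")]
      r5 <- cnt$count[cnt$role == "flank5"] /
        (eff$effective_bp[eff$role == "flank5"] * n)
      r3 <- cnt$count[cnt$role == "flank3"] /
        (eff$effective_bp[eff$role == "flank3"] * n)
      if (length(r5) && length(r3) && r5 != r3) {
        sign_counts["n"] <- sign_counts["n"] + 1L
        if (r5 < r3) sign_counts["k"] <- sign_counts["k"] + 1L
      }
    }
  }
  per_cohort <- do.call(rbind, c(per_cohort, list(make.row.names = FALSE)))
  fisher <- fishers_combined(per_cohort$wilcoxon_p)
  d <- if (nrow(per_cohort) >= 2)
    cohens_d(per_cohort$mean_rate_a, per_cohort$mean_rate_b,
             config$confidence)
  else c(d = NA_real_, low = NA_real_, high = NA_real_)
  n_tot <- sum(per_cohort$n_tumours)
  pooled_a <- sum(per_cohort$count_a) / (per_cohort$effective_bp_a[1] * n_tot)
  pooled_b <- sum(per_cohort$count_b) / (per_cohort$effective_bp_b[1] * n_tot)
  sign_p <- NA_real_
  if (pooled_flank) {
    if (nrow(per_cohort) >= 2) {
      if (sign_counts["n"] > 0)
        sign_p <- binomial_sign_test(sign_counts[["k"]], sign_counts[["n"]],
                                     sided = "one")
    } else {
      # single cohort: per-tumour 5' vs 3' sign test
      pt <- per_tumour[[1]]
      w5 <- pt[pt$role == "flank5", ]; w3 <- pt[pt$role == "flank3", ]
      m <- merge(w5, w3, by = "sample_id", suffixes = c("5", "3"))
      informative <- m$rate5 != m$rate3
      sign_counts <- c(k = sum(m$rate5 < m$rate3),
                       n = sum(informative))
      if (sign_counts[["n"]] > 0)
        sign_p <- binomial_sign_test(sign_counts[["k"]], sign_counts[["n"]],
                                     sided = "one")
    }
  }
  list(per_cohort = per_cohort,
       per_tumour = do.call(rbind, c(per_tumour, list(make.row.names = FALSE))),
       combined = list(
         fisher_chi2 = fisher$chi2, fisher_df = fisher$df,
         fisher_p = fisher$p,
         cohens_d = d[["d"]], d_ci_low = d[["low"]], d_ci_high = d[["high"]],
         pooled_rate_a = pooled_a, pooled_rate_b = pooled_b,
         depletion = if (pooled_b > 0) depletion_fraction(pooled_a, pooled_b)
         else NA_real_,
         sign_k = sign_counts[["k"]], sign_n = sign_counts[["n"]],
         sign_test_p = sign_p))
}

#' Run the flank-vs-core analysis
#'
#' End to end: transcript parsing, internal-exon selection, flank/core
#' interval construction and orientation, optional CpG masking, synonymous
#' filtering, per-cohort per-tumour density tables, Wilcoxon signed-rank per
#' cohort, Fisher's combined p, Cohen's d over cohort mean rates, pooled
#' depletion fraction, and the 5'-vs-3' flank binomial sign test.
#' Deterministic given the config seed.
#'
#' @param config An `ssm_run_config`.
#' @return A list: `per_cohort`, `per_tumour`, `combined`, `regions`,
#'   `exons`, `mask`.
#' @export
run_flank_core <- function(config) {
  config <- resolve_config_inputs(config)
  exons <- select_internal_coding_exons(config$transcripts,
                                        config$min_exon_length)
  if (nrow(exons) == 0L) stop("no eligible internal exons")
  regions <- orient_flanks(make_flank_core_regions(
    exons, config$flank_len, config$core_len, config$end_exclusion))
  mask <- if (config$cpg_mask) mask_cpg_positions(config$genome, regions)
  else NULL
  ssms <- filtered_ssms(config)
  res <- cohort_battery(ssms, regions, mask, cohort_map(config), config,
                        role_a = "flank", role_b = "core",
                        pooled_flank = TRUE)
  st <- coding_site_table(config$transcripts, config$genome)
  res$combined <- c(res$combined, adjusted_depletion(
    st, regions, mask, config$mutations, res,
    a_roles = c("flank5", "flank3"), b_roles = "core"))
  c(res, list(regions = regions, exons = exons, mask = mask))
}

# Synonymous-opportunity-normalized pooled rates and depletion for a region
# pair; the alt-allele conditionals are estimated from all observed records.
adjusted_depletion <- function(site_table, regions, mask, all_records, res,
                               a_roles, b_roles) {
  cond <- estimate_alt_conditionals(all_records)
  opp <- synonymous_opportunity(site_table, regions, cond, mask)
  n_tot <- sum(res$per_cohort$n_tumours)
  opp_a <- sum(opp[intersect(a_roles, names(opp))])
  opp_b <- sum(opp[intersect(b_roles, names(opp))])
  adj_a <- sum(res$per_cohort$count_a) / (opp_a * n_tot)
  adj_b <- sum(res$per_cohort$count_b) / (opp_b * n_tot)
  list(opportunity_a = opp_a, opportunity_b = opp_b,
       adjusted_rate_a = adj_a, adjusted_rate_b = adj_b,
       depletion_adjusted = if (adj_b > 0) depletion_fraction(adj_a, adj_b)
       else NA_real_)
}

#' Run the ESE-vs-non-ESE analysis
#'
#' Scans internal exons for ESE and control hexamer regions within the end
#' window, resolves cross-set overlaps, and applies the same per-cohort
#' statistical battery to ESE vs non-ESE densities, plus substitution-class
#' and trinucleotide-context normalized rate tables.
#'
#' @param config An `ssm_run_config` with `hexamers_ese` set.
#' @return A list: `per_cohort`, `per_tumour`, `combined`, `class_rates`,
#'   `trinuc_rates`, `regions`, `exons`.
#' @export
run_ese <- function(config) {
  config <- resolve_config_inputs(config)
  if (is.null(config$hexamers_ese)) stop("hexamers_ese is required")
  ese <- validate_hexamers(config$hexamers_ese)
  non_ese <- config$hexamers_non_ese %||%
    build_non_ese_set(ese, config$non_ese_min_distance)
  if (length(non_ese) == 0L)
    stop("empty non-ESE set after distance filtering")
  if (!is.null(config$non_ese_sample))
    non_ese <- with_seed(derive_seed(config$seed, 7L),
                         sample(non_ese, config$non_ese_sample))
  exons <- select_internal_coding_exons(config$transcripts,
                                        config$min_exon_length)
  regions <- scan_exons_hexamers(exons, config$genome, ese, non_ese,
                                 config$ese_end_window,
                                 symmetric = config$symmetric_overlap_discard,
                                 watson_only = config$watson_only)
  roles <- mcols(regions)$role
  if (!any(roles == "ese") || !any(roles == "non_ese"))
    stop("hexamer scan produced no ", if (any(roles == "ese")) "non-ESE"
         else "ESE", " regions")
  mask <- if (config$cpg_mask) mask_cpg_positions(config$genome, regions)
  else NULL
  ssms <- filtered_ssms(config)
  cohorts <- cohort_map(config)
  res <- cohort_battery(ssms, regions, mask, cohorts, config,
                        role_a = "ese", role_b = "non_ese")
  st <- coding_site_table(config$transcripts, config$genome)
  res$combined <- c(res$combined, adjusted_depletion(
    st, regions, mask, config$mutations, res,
    a_roles = "ese", b_roles = "non_ese"))
  n_tot <- length(unique(cohorts$sample_id))
  ssms_all <- ssms[ssms$sample_id %in% cohorts$sample_id, , drop = FALSE]
  c(res, list(
    class_rates = class_normalized_rates(ssms_all, regions, config$genome,
                                         n_tot),
    trinuc_rates = trinuc_rates(ssms_all, regions, config$genome, n_tot),
    regions = regions, exons = exons))
}

#' Run covariate-stratified flank/core comparisons
#'
#' Builds the covariate strata (nucleosome and replication-timing quartiles,
#' cancer gene classes, essentiality, alternative/constitutive exons, MSI
#' status) and routes each through the flank/core comparison.
#'
#' @param config An `ssm_run_config` with `covariates` set.
#' @return A named list of stratified result tables.
#' @export
run_strata <- function(config) {
  config <- resolve_config_inputs(config)
  cov <- config$covariates
  if (is.null(cov)) stop("covariates are required for run_strata")
  for (f in names(cov)) if (is.character(cov[[f]]))
    cov[[f]] <- utils::read.delim(cov[[f]], stringsAsFactors = FALSE)
  exons <- select_internal_coding_exons(config$transcripts,
                                        config$min_exon_length)
  regions <- orient_flanks(make_flank_core_regions(
    exons, config$flank_len, config$core_len, config$end_exclusion))
  mask <- if (config$cpg_mask) mask_cpg_positions(config$genome, regions)
  else NULL
  ssms <- filtered_ssms(config)
  cohorts <- cohort_map(config)
  samples <- sort(unique(cohorts$sample_id))
  out <- list()
  es <- cov$exon_scores
  if (!is.null(es)) {
    for (score in intersect(c("nucleosome", "replication_timing"), names(es))) {
      sc <- setNames(es[[score]], es$exon_id)
      qs <- quartile_strata(sc)
      out[[score]] <- run_stratified_comparison(
        qs, ssms, regions, by = "exon", samples = samples, mask = mask,
        B = config$B, confidence = config$confidence, seed = config$seed)
    }
    if ("alt_const" %in% names(es)) {
      strata <- split(es$exon_id, es$alt_const)
      out$alt_const <- run_stratified_comparison(
        strata, ssms, regions, by = "exon", samples = samples, mask = mask,
        B = config$B, confidence = config$confidence, seed = config$seed)
    }
  }
  gt <- cov$gene_table
  if (!is.null(gt)) {
    parts <- partition_genes(gt, unique(exons$gene_id))
    exon_sets <- lapply(parts, function(g)
      exons$exon_id[exons$gene_id %in% g])
    out$cancer_class <- run_stratified_comparison(
      exon_sets, ssms, regions, by = "exon", samples = samples, mask = mask,
      B = config$B, confidence = config$confidence, seed = config$seed)
    if ("essentiality" %in% names(gt)) {
      ess <- split(gt$gene_id, gt$essentiality)
      ess_sets <- lapply(ess, function(g) exons$exon_id[exons$gene_id %in% g])
      out$essentiality <- run_stratified_comparison(
        ess_sets, ssms, regions, by = "exon", samples = samples, mask = mask,
        B = config$B, confidence = config$confidence, seed = config$seed)
    }
  }
  st <- cov$sample_table
  if (!is.null(st)) {
    strata <- split_samples(st, "msi_status", samples = samples)
    out$msi_status <- run_stratified_comparison(
      strata, ssms, regions, by = "sample", samples = samples, mask = mask,
      B = config$B, confidence = config$confidence, seed = config$seed)
  }
  out
}

#' Write result tables and a run log
#'
#' One TSV per table plus a log recording the package version, seed and
#' parameter values. Rerunning overwrites (idempotent).
#'
#' @param results Output of [run_flank_core()], [run_ese()] or a named list
#'   of tables.
#' @param dir Output directory (created if absent).
#' @param config The `ssm_run_config` used (for the log).
#' @return The directory, invisibly.
#' @export
report_results <- function(results, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x))
      utils::write.table(x, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    else if (is.list(x) && nm == "combined")
      utils::write.table(data.frame(statistic = names(x),
                                    value = unlist(lapply(x, format)),
                                    stringsAsFactors = FALSE),
                         file.path(dir, "combined.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  log <- c(paste0("ssmflank version: ",
                  as.character(utils::packageVersion("ssmflank"))),
           paste0("timestamp: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  if (!is.null(config)) {
    scalars <- Filter(function(x) is.atomic(x) && length(x) <= 6,
                      unclass(config))
    log <- c(log, vapply(names(scalars), function(n)
      paste0(n, ": ", paste(scalars[[n]], collapse = ",")), ""))
  }
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
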