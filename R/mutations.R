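maf_required_cols <- c("Hugo_Symbol", "Chromosome", "Start_Position",
                       "Reference_Allele", "Tumor_Seq_Allele2",
                       "Variant_Classification", "Variant_Type",
                       "Tumor_Sample_Barcode")

default_consequence_map <- c(
  Silent = "synonymous", synonymous_variant = "synonymous",
  Missense_Mutation = "non_synonymous", Nonsense_Mutation = "non_synonymous",
  Nonstop_Mutation = "non_synonymous", missense_variant = "non_synonymous",
  stop_gained = "non_synonymous")

#' Read somatic mutation calls
#'
#' Parses a MAF file or any tab-separated table via an explicit column map,
#' keeping only single-nucleotide substitutions. Input positions are 1-based
#' and converted to the package-internal 0-based convention. Indels,
#' multi-nucleotide and multi-allelic records are dropped with a message.
#'
#' @param path Path to the mutation table.
#' @param dialect `"maf"` or `"column_map"`.
#' @param column_map For the `column_map` dialect, a named character vector
#'   mapping internal fields to column names; required fields `sample_id`,
#'   `chrom`, `pos`, `ref`, `alt`; optional `consequence`, `gene_id`,
#'   `variant_type`.
#' @param consequence_map Named character vector translating raw consequence
#'   labels to `synonymous` / `non_synonymous`; unmapped labels become
#'   `other`.
#' @return A `data.frame` of mutation records: `sample_id`, `chrom`, `pos`
#'   (0-based), `ref`, `alt`, `consequence`, `gene_id`.
#' @export
read_mutations <- function(path, dialect = c("maf", "column_map"),
                           column_map = NULL,
                           consequence_map = default_consequence_map) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", data.table = FALSE)
  if (dialect == "maf") {
    missing <- setdiff(maf_required_cols, names(tab))
    if (length(missing))
      stop("missing required column: ", paste(missing, collapse = ", "))
    raw <- data.frame(sample_id = tab$Tumor_Sample_Barcode,
                      chrom = tab$Chromosome,
                      pos_in = tab$Start_Position,
                      ref = tab$Reference_Allele,
                      alt = tab$Tumor_Seq_Allele2,
                      consequence_raw = tab$Variant_Classification,
                      gene_id = tab$Hugo_Symbol,
                      variant_type = tab$Variant_Type,
                      stringsAsFactors = FALSE)
  } else {
    req <- c("sample_id", "chrom", "pos", "ref", "alt")
    if (is.null(column_map) || !all(req %in% names(column_map)))
      stop("column_map must name columns for: ", paste(req, collapse = ", "))
    missing <- setdiff(unname(column_map), names(tab))
    if (length(missing))
      stop("missing required column: ", paste(missing, collapse = ", "))
    get_col <- function(f, default = NA_character_) {
      if (f %in% names(column_map)) tab[[column_map[[f]]]]
      else rep(default, nrow(tab))
    }
    raw <- data.frame(sample_id = get_col("sample_id"),
                      chrom = get_col("chrom"),
                      pos_in = get_col("pos"),
                      ref = get_col("ref"),
                      alt = get_col("alt"),
                      consequence_raw = get_col("consequence"),
                      gene_id = get_col("gene_id"),
                      variant_type = get_col("variant_type"),
                      stringsAsFactors = FALSE)
  }
  pos <- suppressWarnings(as.numeric(raw$pos_in))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    stop("unparseable position at data line ", bad, ": '", raw$pos_in[bad], "'")
  }
  n0 <- nrow(raw)
  snv <- rep(TRUE, n0)
  if (!all(is.na(raw$variant_type)))
    snv <- toupper(raw$variant_type) %in% c("SNP", "SNV",
                                            "SINGLE BASE SUBSTITUTION", NA)
  single <- raw$ref %in% DNA & raw$alt %in% DNA & raw$ref != raw$alt
  keep <- snv & single
  if (sum(!keep) > 0)
    message(sum(!keep), " non-SNV/invalid record(s) dropped of ", n0)
  raw <- raw[keep, , drop = FALSE]
  cons <- unname(consequence_map[raw$consequence_raw])
  cons[is.na(cons) & !is.na(raw$consequence_raw)] <- "other"
  cons[is.na(cons)] <- "other"
  data.frame(sample_id = raw$sample_id, chrom = raw$chrom,
             pos = pos[keep] - 1, ref = raw$ref, alt = raw$alt,
             consequence = cons, gene_id = raw$gene_id,
             stringsAsFactors = FALSE)
}

#' Write mutation records as a minimal MAF
#'
#' @param records Mutation table with a `maf_class` column
#'   (`Silent`/`Missense_Mutation`/`Nonsense_Mutation`) or a standardized
#'   `consequence` column.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_maf <- function(records, path) {
  cls <- if ("maf_class" %in% names(records)) records$maf_class
  else c(synonymous = "Silent", non_synonymous = "Missense_Mutation",
         other = "IGR")[records$consequence]
  tab <- data.frame(Hugo_Symbol = records$gene_id,
                    Chromosome = records$chrom,
                    Start_Position = as.integer(records$pos + 1),
                    End_Position = as.integer(records$pos + 1),
                    Reference_Allele = records$ref,
                    Tumor_Seq_Allele2 = records$alt,
                    Variant_Classification = cls,
                    Variant_Type = "SNP",
                    Tumor_Sample_Barcode = records$sample_id,
                    stringsAsFactors = FALSE)
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' Per-site consequence lookup table for a transcript set
#'
#' Walks every coding position of every transcript, derives the reading
#' frame from the coding-exon structure, and classifies each of the three
#' possible substitutions at each site under the standard genetic code
#' (reverse-complementing on minus-strand transcripts). Coding lengths that
#' are not multiples of three are trimmed at the 3' end with a warning.
#'
#' @param transcripts Coding-exon table.
#' @param genome `DNAStringSet` or FASTA path.
#' @return A `data.table` keyed by `chrom, pos` with the genomic reference
#'   base, strand, gene and per-alt classifications `cls_A` .. `cls_T`
#'   (values `Silent`, `Missense_Mutation`, `Nonsense_Mutation`, NA for the
#'   reference base itself).
#' @export
coding_site_table <- function(transcripts, genome) {
  genome <- load_genome(genome)
  chars <- genome_chars(genome)
  gc_tab <- Biostrings::GENETIC_CODE
  txs <- split(transcripts, transcripts$transcript_id)
  out <- vector("list", length(txs))
  trimmed <- 0L
  for (j in seq_along(txs)) {
    tx <- txs[[j]][order(txs[[j]]$start), , drop = FALSE]
    chrom <- tx$chrom[1]; minus <- tx$strand[1] == "-"
    pos <- unlist(mapply(function(s, e) seq.int(s, e - 1L), tx$start, tx$end,
                         SIMPLIFY = FALSE), use.names = FALSE)
    if (minus) pos <- rev(pos)
    r <- length(pos) %% 3L
    if (r > 0L) { trimmed <- trimmed + 1L; pos <- pos[seq_len(length(pos) - r)] }
    if (length(pos) == 0L) next
    refg <- chars[[chrom]][pos + 1L]
    cod_base <- if (minus) comp_base(refg) else refg
    m <- matrix(cod_base, nrow = 3L)
    codons <- paste0(m[1, ], m[2, ], m[3, ])
    codon_site <- rep(codons, each = 3L)
    codon_pos <- rep(1:3, length(codons))
    aa_ref <- unname(gc_tab[codons])[rep(seq_along(codons), each = 3L)]
    cls <- matrix(NA_character_, nrow = length(pos), ncol = 4,
                  dimnames = list(NULL, DNA))
    for (a in DNA) {
      ca <- if (minus) comp_base(a) else a
      newcod <- paste0(substr(codon_site, 1, codon_pos - 1L), ca,
                       substr(codon_site, codon_pos + 1L, 3L))
      aa_alt <- unname(gc_tab[newcod])
      cls[, a] <- ifelse(aa_alt == aa_ref, "Silent",
                         ifelse(aa_alt == "*", "Nonsense_Mutation",
                                "Missense_Mutation"))
      cls[refg == a, a] <- NA_character_
    }
    out[[j]] <- data.table::data.table(
      chrom = chrom, pos = pos, ref = refg, strand = tx$strand[1],
      gene_id = tx$gene_id[1], transcript_id = tx$transcript_id[1],
      cls_A = cls[, "A"], cls_C = cls[, "C"],
      cls_G = cls[, "G"], cls_T = cls[, "T"])
  }
  if (trimmed > 0L)
    warning(trimmed, " transcript(s) with coding length not a multiple of 3; ",
            "trailing bases ignored")
  st <- data.table::rbindlist(out)
  data.table::setkeyv(st, c("chrom", "pos"))
  st
}

site_lookup_cls <- function(st, chrom, pos, alt) {
  idx <- match(paste(chrom, pos), paste(st$chrom, st$pos))
  found <- !is.na(idx)
  cls <- ref <- rep(NA_character_, length(pos))
  if (any(found)) {
    sub <- st[idx[found], ]
    m <- cbind(sub$cls_A, sub$cls_C, sub$cls_G, sub$cls_T)
    cls[found] <- m[cbind(seq_len(nrow(sub)), match(alt[found], DNA))]
    ref[found] <- sub$ref
  }
  list(cls = cls, found = found, ref = ref)
}

#' Annotate mutation consequences from transcript structure
#'
#' Vectorized re-annotation: each record falling in a coding exon of the
#' supplied transcripts is classified as `synonymous` or `non_synonymous` by
#' codon comparison; records outside any coding exon return `other`. A
#' reference-allele mismatch against the genome is an error.
#'
#' @param records Mutation table (see [read_mutations()]).
#' @param transcripts Coding-exon table.
#' @param genome `DNAStringSet` or FASTA path.
#' @param site_table Optional precomputed [coding_site_table()].
#' @return Character vector of consequences, one per record.
#' @export
annotate_consequences <- function(records, transcripts, genome,
                                  site_table = NULL) {
  st <- site_table %||% coding_site_table(transcripts, genome)
  lk <- site_lookup_cls(st, records$chrom, records$pos, records$alt)
  mism <- lk$found & lk$ref != records$ref
  if (any(mism)) {
    i <- which(mism)[1]
    stop("reference mismatch at ", records$chrom[i], ":", records$pos[i],
         " (genome ", lk$ref[i], ", record ", records$ref[i], ")")
  }
  out <- rep("other", nrow(records))
  syn <- lk$found & lk$cls == "Silent"
  non <- lk$found & lk$cls %in% c("Missense_Mutation", "Nonsense_Mutation")
  out[syn] <- "synonymous"
  out[non] <- "non_synonymous"
  out
}

#' @rdname annotate_consequences
#' @param record A single mutation record (one-row `data.frame` or list).
#' @param transcript A coding-exon table for one transcript.
#' @export
annotate_consequence <- function(record, transcript, genome) {
  rec <- as.data.frame(record, stringsAsFactors = FALSE)
  annotate_consequences(rec, transcript, genome)[1]
}

#' Keep synonymous single-nucleotide records
#'
#' `annotation` mode trusts the standardized `consequence` field (the MAF
#' Silent flag or equivalent); `recompute` mode re-annotates against the
#' supplied transcripts and genome and keeps records classified synonymous.
#'
#' @param records Mutation table.
#' @param mode `"annotation"` or `"recompute"`.
#' @param transcripts,genome Required for `recompute` mode.
#' @param site_table Optional precomputed [coding_site_table()].
#' @return The filtered mutation table.
#' @export
filter_synonymous <- function(records, mode = c("annotation", "recompute"),
                              transcripts = NULL, genome = NULL,
                              site_table = NULL) {
  mode <- match.arg(mode)
  if (mode == "annotation") {
    out <- records[records$consequence == "synonymous", , drop = FALSE]
  } else {
    if (is.null(genome) || (is.null(transcripts) && is.null(site_table)))
      stop("recompute mode requires transcripts and genome")
    cons <- annotate_consequences(records, transcripts, genome, site_table)
    out <- records[cons == "synonymous", , drop = FALSE]
    out$consequence <- "synonymous"
  }
  rownames(out) <- NULL
  out
}

#' The six strand-collapsed substitution classes
#'
#' @return `c("A>C", "A>G", "A>T", "C>G", "C>T", "G>T")`.
#' @export
substitution_classes <- function() c("A>C", "A>G", "A>T", "C>G", "C>T", "G>T")

subst_class_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      canon <- substitution_classes()
      m <- character()
      for (r in DNA) for (a in setdiff(DNA, r)) {
        lab <- paste0(r, ">", a)
        m[lab] <- if (lab %in% canon) lab
        else paste0(comp_base(r), ">", comp_base(a))
      }
      cache <<- m
    }
    cache
  }
})

#' Collapse a substitution to its canonical class
#'
#' Each of the 12 raw single-base substitutions maps to one of six classes by
#' identifying a substitution with its reverse complement (for example T>G is
#' the same class as A>C).
#'
#' @param ref,alt Single reference and alternate bases (vectorized).
#' @return Character vector of class labels.
#' @export
canonical_substitution_class <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!ref %in% DNA) || any(!alt %in% DNA))
    stop("ref and alt must be single bases in A, C, G, T")
  if (any(ref == alt)) stop("ref and alt must differ")
  unname(subst_class_map()[paste0(ref, ">", alt)])
}

#' The 96 canonical trinucleotide classes
#'
#' @return Character vector of labels `5'base[class]3'base`, 96 in all
#'   (6 substitution classes x 16 flanking contexts).
#' @export
trinuc_classes <- function() {
  out <- character()
  for (cl in substitution_classes())
    for (l in DNA) for (r in DNA)
      out <- c(out, sprintf("%s[%s]%s", l, cl, r))
  sort(out)
}

#' Trinucleotide context class of a substitution
#'
#' Reads the genome base before and after each mutation. If the substitution
#' is already one of the six canonical classes the context is used as-is;
#' otherwise the substitution and both context bases are reverse-complemented
#' (5'/3' swap) so the central substitution is canonical. Positions at contig
#' edges are an error; an `N` in the context yields `NA` with a message (the
#' record should be excluded by the caller).
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param chrom,pos,ref,alt Vectors describing the substitutions (`pos`
#'   0-based); the genome base at `pos` must equal `ref`.
#' @return Character vector of trinucleotide class labels.
#' @export
trinucleotide_class <- function(genome, chrom, pos, ref, alt) {
  genome <- load_genome(genome)
  chars <- genome_chars(genome)
  lens <- vapply(chars, length, 0L)
  if (any(pos < 1 | pos + 1 >= lens[chrom]))
    stop("position at contig edge: no trinucleotide context")
  left <- mapply(function(c, p) chars[[c]][p], chrom, pos, USE.NAMES = FALSE)
  cent <- mapply(function(c, p) chars[[c]][p + 1L], chrom, pos, USE.NAMES = FALSE)
  right <- mapply(function(c, p) chars[[c]][p + 2L], chrom, pos, USE.NAMES = FALSE)
  if (any(cent != toupper(ref)))
    stop("genome base does not match ref at position ",
         pos[which(cent != toupper(ref))[1]])
  lab <- rep(NA_character_, length(pos))
  hasN <- left == "N" | right == "N"
  if (any(hasN)) message(sum(hasN), " record(s) with N context excluded")
  canon <- paste0(ref, ">", alt) %in% substitution_classes()
  cl <- canonical_substitution_class(ref, alt)
  l2 <- ifelse(canon, left, comp_base(right))
  r2 <- ifelse(canon, right, comp_base(left))
  lab[!hasN] <- sprintf("%s[%s]%s", l2[!hasN], cl[!hasN], r2[!hasN])
  lab
}
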