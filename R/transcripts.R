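#' Parse transcript models from genePred or BED12
#'
#' Reads one transcript per row and returns a table of coding exons in
#' 0-based half-open genome coordinates (the package-internal convention;
#' both input dialects are already 0-based half-open). For genePred, exons
#' are clipped to `[cdsStart, cdsEnd)`; for BED12, blocks are clipped to the
#' thick range. Transcripts without coding sequence are skipped with a
#' warning.
#'
#' @param path Path to a tab-separated genePred file (columns `name, chrom,
#'   strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts,
#'   exonEnds[, gene]`, no header, `#` comments allowed) or a BED12 file.
#' @param dialect `"genepred"` or `"bed12"`.
#' @return A `data.frame` with one row per coding exon: `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `start`, `end` (0-based half-open),
#'   `exon_rank` (1-based, genomic order) and `n_coding_exons`.
#' @export
parse_transcript_table <- function(path, dialect = c("genepred", "bed12")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "genepred") parse_genepred(path) else parse_bed12(path)
}

parse_genepred <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_transcripts())
  out <- vector("list", length(lines))
  skipped <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 10L)
      stop("malformed genePred row at line ", lineno[i], ": expected >= 10 columns")
    num <- suppressWarnings(as.numeric(f[4:8]))
    if (anyNA(num))
      stop("malformed genePred row at line ", lineno[i], ": non-numeric coordinate")
    starts <- suppressWarnings(as.numeric(strsplit(f[9], ",", fixed = TRUE)[[1]]))
    ends <- suppressWarnings(as.numeric(strsplit(f[10], ",", fixed = TRUE)[[1]]))
    if (anyNA(starts) || anyNA(ends) || length(starts) != length(ends))
      stop("malformed genePred row at line ", lineno[i], ": bad exon lists")
    if (any(ends < starts))
      stop("malformed genePred row at line ", lineno[i], ": exon end < start")
    cds_s <- num[3]; cds_e <- num[4]
    s <- pmax(starts, cds_s); e <- pmin(ends, cds_e)
    ok <- e > s
    if (!any(ok)) { skipped <- skipped + 1L; next }
    s <- s[ok]; e <- e[ok]
    o <- order(s)
    out[[i]] <- data.frame(
      transcript_id = f[1],
      gene_id = if (length(f) >= 11L && nzchar(f[11])) f[11] else f[1],
      chrom = f[2], strand = f[3],
      start = s[o], end = e[o],
      exon_rank = seq_along(s), n_coding_exons = length(s),
      stringsAsFactors = FALSE)
  }
  if (skipped > 0L)
    warning(skipped, " transcript(s) without coding exons skipped")
  models <- do.call(rbind, out)
  if (is.null(models)) return(empty_transcripts())
  validate_transcripts(models)
}

parse_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) return(empty_transcripts())
  blocks <- rtracklayer::blocks(gr)
  thick <- gr$thick
  out <- vector("list", length(gr))
  skipped <- 0L
  for (i in seq_along(gr)) {
    ex <- ranges(blocks[[i]])
    cds <- IRanges::restrict(ex, start = start(thick)[i], end = end(thick)[i])
    cds <- cds[width(cds) > 0L]
    if (length(cds) == 0L) { skipped <- skipped + 1L; next }
    cds <- sort(cds)
    out[[i]] <- data.frame(
      transcript_id = gr$name[i] %||% paste0("tx", i),
      gene_id = gr$name[i] %||% paste0("tx", i),
      chrom = as.character(seqnames(gr)[i]),
      strand = as.character(strand(gr)[i]),
      start = start(cds) - 1L, end = end(cds),
      exon_rank = seq_along(cds), n_coding_exons = length(cds),
      stringsAsFactors = FALSE)
  }
  if (skipped > 0L)
    warning(skipped, " transcript(s) without coding exons skipped")
  models <- do.call(rbind, out)
  if (is.null(models)) return(empty_transcripts())
  validate_transcripts(models)
}

empty_transcripts <- function() {
  data.frame(transcript_id = character(), gene_id = character(),
             chrom = character(), strand = character(),
             start = numeric(), end = numeric(),
             exon_rank = integer(), n_coding_exons = integer(),
             stringsAsFactors = FALSE)
}

validate_transcripts <- function(models) {
  stopifnot(all(c("transcript_id", "gene_id", "chrom", "strand",
                  "start", "end") %in% names(models)))
  if (any(!models$strand %in% c("+", "-")))
    stop("transcript strand must be '+' or '-'")
  if (any(models$end <= models$start))
    stop("exon end must exceed exon start")
  for (tx in split(models, models$transcript_id)) {
    o <- order(tx$start)
    if (any(tx$start[o][-1] < tx$end[o][-length(o)]))
      stop("overlapping exons in transcript ", tx$transcript_id[1])
  }
  rownames(models) <- NULL
  models
}

#' Select internal coding exons above a length threshold
#'
#' Internal means neither the first nor the last coding exon of its
#' transcript. The default threshold keeps exons of at least 160 bp
#' (inclusive), the minimum length at which two 20-bp flanks and a central
#' 40-bp core are guaranteed disjoint with room to spare.
#'
#' @param models Coding-exon table from [parse_transcript_table()].
#' @param min_length Minimum exon length in bp (inclusive).
#' @return A `data.frame` of exon contexts: the input columns plus `ordinal`
#'   (= exon_rank), `L` (length), `M` (centre offset, `L %/% 2`) and
#'   `exon_id` (`chrom:start-end:strand`).
#' @export
select_internal_coding_exons <- function(models, min_length = 160) {
  if (nrow(models) == 0L) return(cbind(models, ordinal = integer(),
                                       L = numeric(), M = numeric(),
                                       exon_id = character()))
  internal <- models$exon_rank > 1L & models$exon_rank < models$n_coding_exons
  L <- models$end - models$start
  keep <- internal & L >= min_length
  out <- models[keep, , drop = FALSE]
  out$ordinal <- out$exon_rank
  out$L <- out$end - out$start
  out$M <- out$L %/% 2
  out$exon_id <- sprintf("%s:%d-%d:%s", out$chrom, as.integer(out$start),
                         as.integer(out$end), out$strand)
  rownames(out) <- NULL
  out
}

#' Write transcript models as genePred
#'
#' Inverse of the genePred dialect of [parse_transcript_table()] (the written
#' CDS spans all coding exons).
#'
#' @param models Coding-exon table.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genepred <- function(models, path) {
  rows <- lapply(split(models, models$transcript_id), function(tx) {
    tx <- tx[order(tx$start), , drop = FALSE]
    data.frame(
      name = tx$transcript_id[1], chrom = tx$chrom[1], strand = tx$strand[1],
      txStart = min(tx$start), txEnd = max(tx$end),
      cdsStart = min(tx$start), cdsEnd = max(tx$end),
      exonCount = nrow(tx),
      exonStarts = paste0(paste(as.integer(tx$start), collapse = ","), ","),
      exonEnds = paste0(paste(as.integer(tx$end), collapse = ","), ","),
      gene = tx$gene_id[1], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
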