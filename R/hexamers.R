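#' Enumerate all DNA hexamers
#'
#' @return Character vector of all 4096 distinct 6-mers over A, C, G, T,
#'   in lexicographic order.
#' @export
enumerate_hexamers <- function() {
  sort(Biostrings::mkAllStrings(DNA, 6))
}

validate_hexamers <- function(x) {
  x <- toupper(x)
  bad <- nchar(x) != 6L | !grepl("^[ACGT]{6}$", x)
  if (any(bad)) stop("invalid hexamer(s): ", paste(utils::head(x[bad], 5), collapse = ", "))
  unique(x)
}

#' Hamming distance between equal-length DNA words
#'
#' @param a,b Character vectors of equal-length words (recycled pairwise).
#' @return Integer vector of mismatch counts.
#' @export
hamming_distance <- function(a, b) {
  if (any(nchar(a) != nchar(b)))
    stop("hamming_distance requires equal-length words")
  mapply(function(x, y) {
    sum(strsplit(x, "", fixed = TRUE)[[1]] != strsplit(y, "", fixed = TRUE)[[1]])
  }, a, b, USE.NAMES = FALSE)
}

# 4096 x 6 character matrix of all hexamers, built once per session.
hexamer_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      hx <- enumerate_hexamers()
      cache <<- list(hex = hx,
                     mat = matrix(unlist(strsplit(hx, "", fixed = TRUE)),
                                  ncol = 6, byrow = TRUE))
    }
    cache
  }
})

#' Build the non-ESE control hexamer set
#'
#' Returns every hexamer whose minimum Hamming distance to the ESE set is at
#' least `min_distance` (default 2, i.e. hexamers with one or fewer
#' differences from any ESE are discarded). The result is always disjoint
#' from the ESE set.
#'
#' @param ese Character vector of ESE hexamers.
#' @param min_distance Minimum Hamming distance in `[1, 6]`.
#' @return Character vector of control hexamers, sorted.
#' @export
build_non_ese_set <- function(ese, min_distance = 2) {
  ese <- validate_hexamers(ese)
  if (length(ese) == 0L) stop("ESE set must be non-empty")
  if (min_distance < 1 || min_distance > 6)
    stop("min_distance must be in [1, 6]")
  hm <- hexamer_matrix()
  mind <- rep(6L, length(hm$hex))
  for (e in ese) {
    ev <- strsplit(e, "", fixed = TRUE)[[1]]
    d <- rowSums(hm$mat != matrix(ev, nrow = nrow(hm$mat), ncol = 6, byrow = TRUE))
    mind <- pmin(mind, d)
  }
  hm$hex[mind >= min_distance]
}

#' Read a hexamer list file
#'
#' Plain text, one 6-mer per line; blank lines and `#` comments ignored.
#'
#' @param path File path.
#' @return Character vector of hexamers (upper case, unique).
#' @export
read_hexamer_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  validate_hexamers(lines[nzchar(lines)])
}

#' Scan an exon sequence for hexamer-set matches near the exon ends
#'
#' Reports every 6-bp perfect match to a set member whose start offset lies
#' within `end_window` bp of either exon end (offset `< end_window` from the
#' left end, or `>= L - end_window` from the right end, 0-based). Overlapping
#' matches to the same set are merged into maximal regions. `N` bases never
#' match.
#'
#' @param exon_sequence A single exon sequence (character or `DNAString`),
#'   upper-case ACGT with N allowed.
#' @param hexamers Character vector of hexamers to match.
#' @param end_window Zone width in bp measured from each exon end.
#' @return A `data.frame` of exon-relative merged regions with 0-based
#'   half-open `start`, `end`.
#' @export
scan_hexamer_regions <- function(exon_sequence, hexamers, end_window = 69) {
  seqc <- toupper(as.character(exon_sequence))
  if (length(seqc) != 1L) stop("exon_sequence must be a single sequence")
  if (!grepl("^[ACGTN]*$", seqc))
    stop("exon sequence contains characters other than A, C, G, T, N")
  hexamers <- validate_hexamers(hexamers)
  L <- nchar(seqc)
  if (L < 6L) return(data.frame(start = integer(), end = integer()))
  starts0 <- 0:(L - 6L)
  starts0 <- starts0[starts0 < end_window | starts0 >= L - end_window]
  if (length(starts0) == 0L) return(data.frame(start = integer(), end = integer()))
  win <- substring(seqc, starts0 + 1L, starts0 + 6L)
  hit <- win %in% hexamers
  if (!any(hit)) return(data.frame(start = integer(), end = integer()))
  red <- IRanges::reduce(IRanges::IRanges(start = starts0[hit] + 1L, width = 6L))
  data.frame(start = start(red) - 1L, end = end(red))
}

#' Discard ESE regions that overlap non-ESE regions
#'
#' By default the discard is symmetric: both the ESE region and the non-ESE
#' region involved in an overlap are dropped, so no base is claimed by both
#' classes and neither class is contaminated by ambiguous sequence. Setting
#' `symmetric = FALSE` drops only the ESE side.
#'
#' @param ese_regions,non_ese_regions Exon-relative region `data.frame`s from
#'   [scan_hexamer_regions()].
#' @param symmetric Drop overlapping regions from both sets?
#' @return A list with elements `ese` and `non_ese`.
#' @export
resolve_overlaps <- function(ese_regions, non_ese_regions, symmetric = TRUE) {
  to_ir <- function(df) IRanges::IRanges(start = df$start + 1L, end = df$end)
  ov <- IRanges::findOverlaps(to_ir(ese_regions), to_ir(non_ese_regions))
  drop_e <- unique(queryHits(ov))
  drop_n <- if (symmetric) unique(subjectHits(ov)) else integer()
  ese <- if (length(drop_e)) ese_regions[-drop_e, , drop = FALSE] else ese_regions
  non <- if (length(drop_n)) non_ese_regions[-drop_n, , drop = FALSE] else non_ese_regions
  rownames(ese) <- rownames(non) <- NULL
  list(ese = ese, non_ese = non)
}

#' Annotate ESE and non-ESE regions on a set of exons
#'
#' Extracts each exon's coding-strand sequence, scans it for both hexamer
#' sets within `end_window` of each exon end, resolves cross-set overlaps and
#' maps the surviving regions back to genome coordinates.
#'
#' @param exons Exon-context table from [select_internal_coding_exons()].
#' @param genome `DNAStringSet` or FASTA path.
#' @param ese,non_ese Hexamer sets (character vectors).
#' @param end_window Zone width in bp from each exon end.
#' @param symmetric Symmetric overlap discard (see [resolve_overlaps()]).
#' @param watson_only Restrict to plus-strand genes (parity mode).
#' @return A `GRanges` region set with roles `"ese"` and `"non_ese"`.
#' @export
scan_exons_hexamers <- function(exons, genome, ese, non_ese, end_window = 69,
                                symmetric = TRUE, watson_only = FALSE) {
  genome <- load_genome(genome)
  if (watson_only) exons <- exons[exons$strand == "+", , drop = FALSE]
  pieces <- vector("list", nrow(exons))
  for (i in seq_len(nrow(exons))) {
    ex <- exons[i, ]
    seqc <- as.character(Biostrings::subseq(genome[[ex$chrom]],
                                            ex$start + 1L, ex$end))
    if (ex$strand == "-") seqc <- revcomp(seqc)
    res <- resolve_overlaps(
      scan_hexamer_regions(seqc, ese, end_window),
      scan_hexamer_regions(seqc, non_ese, end_window),
      symmetric = symmetric)
    n_e <- nrow(res$ese); n_n <- nrow(res$non_ese)
    if (n_e + n_n == 0L) next
    rel_s <- c(res$ese$start, res$non_ese$start)
    rel_e <- c(res$ese$end, res$non_ese$end)
    if (ex$strand == "+") {
      gs <- ex$start + rel_s; ge <- ex$start + rel_e
    } else {
      gs <- ex$end - rel_e; ge <- ex$end - rel_s
    }
    pieces[[i]] <- data.frame(
      chrom = ex$chrom, start = gs, end = ge, strand = ex$strand,
      role = rep(c("ese", "non_ese"), c(n_e, n_n)),
      exon_id = ex$exon_id, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, pieces)
  if (is.null(tab)) return(empty_region_set())
  gr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$start + 1L, tab$end),
                               strand = tab$strand)
  mcols(gr)$role <- tab$role
  mcols(gr)$side <- NA_character_
  mcols(gr)$exon_id <- tab$exon_id
  validate_region_set(sort(gr, ignore.strand = TRUE))
}
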