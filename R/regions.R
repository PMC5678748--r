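#' Build flank and core intervals for internal coding exons
#'
#' Each exon of length `L` (0-based half-open `[start, end)`) is partitioned
#' into a flank of `flank_len` bp at each end and a core of `core_len` bp
#' centred on `M = L %/% 2`:
#' left flank `[start + end_exclusion, start + flank_len)`, right flank
#' `[end - flank_len, end - end_exclusion)`, core
#' `[start + M - core_len/2, start + M + core_len/2)`. A non-zero
#' `end_exclusion` trims the terminal bases of each flank so canonical splice
#' site positions can be excluded from the analysis.
#'
#' @param exons Exon-context table from [select_internal_coding_exons()].
#' @param flank_len Flank width in bp.
#' @param core_len Core width in bp (must be even).
#' @param end_exclusion Terminal bases trimmed from each flank
#'   (`0 <= end_exclusion < flank_len`).
#' @return A `GRanges` with metadata columns `role` (`"flank"` before
#'   orientation, `"core"`), `side` (`"left"`/`"right"` for flanks) and
#'   `exon_id`.
#' @export
make_flank_core_regions <- function(exons, flank_len = 20, core_len = 40,
                                    end_exclusion = 0) {
  if (core_len %% 2 != 0) stop("core_len must be even")
  if (end_exclusion < 0 || end_exclusion >= flank_len)
    stop("end_exclusion must satisfy 0 <= end_exclusion < flank_len")
  if (nrow(exons) == 0L) return(empty_region_set())
  s <- exons$start; e <- exons$end
  L <- e - s; M <- L %/% 2
  core_s <- s + M - core_len / 2
  core_e <- s + M + core_len / 2
  bad <- (s + flank_len > core_s) | (core_e > e - flank_len)
  if (any(bad))
    stop("flanks and core overlap for exon(s): ",
         paste(utils::head(exons$exon_id[bad], 5), collapse = ", "),
         " (exon too short for the requested widths)")
  n <- nrow(exons)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(exons$chrom, 3),
    ranges = IRanges::IRanges(
      start = c(s + end_exclusion, e - flank_len, core_s) + 1L,
      end = c(s + flank_len, e - end_exclusion, core_e)),
    strand = rep(exons$strand, 3))
  mcols(gr)$role <- rep(c("flank", "flank", "core"), each = n)
  mcols(gr)$side <- rep(c("left", "right", NA_character_), each = n)
  mcols(gr)$exon_id <- rep(exons$exon_id, 3)
  validate_region_set(sort(gr, ignore.strand = TRUE))
}

empty_region_set <- function() {
  gr <- GenomicRanges::GRanges()
  mcols(gr)$role <- character()
  mcols(gr)$side <- character()
  mcols(gr)$exon_id <- character()
  gr
}

validate_region_set <- function(gr) {
  stopifnot(all(c("role", "exon_id") %in% names(mcols(gr))))
  for (r in unique(mcols(gr)$role)) {
    if (!isDisjoint(gr[mcols(gr)$role == r], ignore.strand = TRUE))
      stop("regions within role '", r, "' overlap")
  }
  gr
}

#' Label flanks as 5' or 3' by transcription direction
#'
#' For a plus-strand exon the genomically left flank is the 5' flank; for a
#' minus-strand exon it is the genomically right flank. The operation is
#' idempotent: labels are recomputed from coordinates and strand, so applying
#' it to an already-oriented region set leaves it unchanged.
#'
#' @param regions `GRanges` region set containing exactly two flank intervals
#'   per exon (roles `"flank"`, `"flank5"` or `"flank3"`).
#' @return The region set with flank roles replaced by `"flank5"`/`"flank3"`.
#' @export
orient_flanks <- function(regions) {
  role <- mcols(regions)$role
  is_fl <- which(role %in% c("flank", "flank5", "flank3"))
  if (!length(is_fl)) stop("region set contains no flank intervals")
  ids <- mcols(regions)$exon_id[is_fl]
  if (any(table(ids) != 2L))
    stop("exon(s) without exactly two flank intervals: ",
         paste(utils::head(names(which(table(ids) != 2L)), 3), collapse = ", "))
  o <- order(ids, start(regions)[is_fl])
  left <- o[!duplicated(ids[o])]              # genomically left flank per exon
  is_left <- logical(length(is_fl)); is_left[left] <- TRUE
  plus <- as.character(strand(regions))[is_fl] == "+"
  mcols(regions)$role[is_fl] <- ifelse(is_left == plus, "flank5", "flank3")
  regions
}

#' Write a region set to BED6
#'
#' The name field carries `role|exon_id` so the file round-trips losslessly
#' through [read_regions_bed()]. An empty region set yields a file holding
#' only a header comment.
#'
#' @param regions `GRanges` region set.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  if (length(regions) == 0L) {
    writeLines("# chrom\tstart\tend\tname\tscore\tstrand", path)
    return(invisible(path))
  }
  gr <- regions
  names(gr) <- NULL
  mcols(gr) <- NULL
  mcols(gr)$name <- paste(mcols(regions)$role, mcols(regions)$exon_id, sep = "|")
  mcols(gr)$score <- 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a region set written by [write_regions_bed()]
#'
#' @param path BED6 path.
#' @return A `GRanges` with `role`, `side` (NA) and `exon_id` columns.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  if (!any(!grepl("^\\s*(#|$)", lines))) return(empty_region_set())
  gr <- rtracklayer::import(path, format = "BED")
  parts <- strsplit(gr$name, "|", fixed = TRUE)
  out <- GenomicRanges::granges(gr)
  mcols(out)$role <- vapply(parts, `[`, "", 1)
  mcols(out)$side <- NA_character_
  mcols(out)$exon_id <- vapply(parts, function(p)
    if (length(p) > 1) paste(p[-1], collapse = "|") else NA_character_, "")
  out
}
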