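## Raw-read preprocessing: 3' adapter trimming, PCR-duplicate collapsing by
## exact sequence identity, then 4-nt barcode demultiplexing — in that
## order, matching the upstream chain the classification expects.

#' Trim 3' adapter sequence from reads
#'
#' Removes the longest read suffix that matches a prefix of the adapter with
#' at most `max_mismatch` mismatches and an overlap of at least
#' `min_overlap` bases. Reads without a qualifying adapter occurrence pass
#' through unchanged.
#'
#' @param reads character vector of read sequences (names preserved).
#' @param adapter 3' adapter sequence.
#' @param min_overlap minimum adapter overlap considered.
#' @param max_mismatch mismatches tolerated within the overlap.
#' @return character vector of trimmed reads.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L, max_mismatch = 1L) {
  stopifnot(nchar(adapter) >= 1L, min_overlap >= 1L)
  reads <- as_dna_character(reads)
  cut <- cpp_trim_positions(unname(reads), toupper(adapter),
                            as.integer(min_overlap),
                            as.integer(max_mismatch))
  out <- substr(reads, 1L, cut)
  names(out) <- names(reads)
  out
}

#' Collapse PCR duplicates by exact sequence identity
#'
#' One representative tag per distinct sequence; `multiplicity` records the
#' duplicate-family size. Identity is by sequence alone (no random
#' barcodes / UMIs are modelled), so the operation is idempotent.
#'
#' @param reads character vector of (trimmed) read sequences; names are used
#'   as read ids, the first read of each family naming the tag.
#' @return data.frame with `tag_id`, `sequence`, `multiplicity`.
#' @export
collapse_duplicates <- function(reads) {
  reads <- as_dna_character(reads)
  if (is.null(names(reads))) names(reads) <- sprintf("read_%06d",
                                                     seq_along(reads))
  rep_idx <- which(!duplicated(reads))
  mult <- tabulate(match(reads, reads[rep_idx]), nbins = length(rep_idx))
  data.frame(tag_id = names(reads)[rep_idx],
             sequence = unname(reads[rep_idx]),
             multiplicity = mult, stringsAsFactors = FALSE)
}

#' Demultiplex collapsed tags by 4-nt experimental barcode
#'
#' Assigns each tag by exact match of its first four bases against the
#' barcode table and strips the barcode from assigned tags. Tags with an
#' unlisted prefix are routed to library `"unassigned"` with their sequence
#' left intact.
#'
#' @param tags data.frame from [collapse_duplicates()] (columns `tag_id`,
#'   `sequence`, `multiplicity`).
#' @param barcodes named character vector mapping library name to its 4-nt
#'   barcode, e.g. `c(MRB8170 = "TCGA")`. Barcodes must be distinct.
#' @return the tag data.frame with a `library` column; assigned tags have
#'   the barcode removed from `sequence`.
#' @export
demultiplex <- function(tags, barcodes) {
  barcodes <- toupper(barcodes)
  if (any(nchar(barcodes) != 4L)) stop("barcodes must be 4 nt")
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in table")
  if (is.null(names(barcodes)) || any(names(barcodes) == "")) {
    stop("barcodes must be named by library")
  }
  prefix <- substr(tags$sequence, 1L, 4L)
  lib <- names(barcodes)[match(prefix, barcodes)]
  assigned <- !is.na(lib)
  tags$library <- ifelse(assigned, lib, "unassigned")
  tags$sequence[assigned] <- substring(tags$sequence[assigned], 5L)
  tags[c("tag_id", "library", "sequence", "multiplicity")]
}

#' Preprocess a raw read library into demultiplexed, deduplicated tags
#'
#' Runs the full chain trim -> collapse -> demultiplex and keeps the
#' per-stage accounting. Trimmed reads shorter than
#' `min_length + 4` (insert floor plus barcode) are discarded and counted.
#' Read conservation holds by construction:
#' `n_input = sum(assigned multiplicities) + n_short + sum(unassigned
#' multiplicities)`.
#'
#' @param reads named character vector of raw reads (or a FASTQ path).
#' @param adapter 3' adapter sequence.
#' @param barcodes named character vector of 4-nt barcodes per library.
#' @param min_length minimum insert length after barcode removal.
#' @param min_overlap,max_mismatch adapter-trimming tolerances.
#' @return list of class `preprocess_run` with `tags` (assigned tags:
#'   `tag_id`, `library`, `sequence`, `multiplicity`), `unassigned`, and a
#'   one-row `report` of stage counts.
#' @export
preprocess_library <- function(reads, adapter, barcodes, min_length = 20L,
                               min_overlap = 5L, max_mismatch = 1L) {
  if (length(reads) == 1L && file.exists(reads)) reads <- read_fastq(reads)
  reads <- as_dna_character(reads)
  n_input <- length(reads)
  trimmed <- trim_adapter(reads, adapter, min_overlap, max_mismatch)
  keep <- nchar(trimmed) >= min_length + 4L
  n_short <- sum(!keep)
  collapsed <- collapse_duplicates(trimmed[keep])
  demuxed <- demultiplex(collapsed, barcodes)
  tags <- demuxed[demuxed$library != "unassigned", , drop = FALSE]
  unassigned <- demuxed[demuxed$library == "unassigned", , drop = FALSE]
  rownames(tags) <- rownames(unassigned) <- NULL
  report <- data.frame(
    n_input = n_input,
    n_short_discarded = n_short,
    n_unique = nrow(collapsed),
    n_assigned_unique = nrow(tags),
    n_assigned_reads = sum(tags$multiplicity),
    n_unassigned_unique = nrow(unassigned),
    n_unassigned_reads = sum(unassigned$multiplicity))
  stopifnot(report$n_input == report$n_assigned_reads + report$n_short_discarded +
              report$n_unassigned_reads)
  structure(list(tags = tags, unassigned = unassigned, report = report),
            class = "preprocess_run")
}

#' @export
print.preprocess_run <- function(x, ...) {
  r <- x$report
  cat("preprocess_run\n")
  cat(sprintf("  input reads:        %d\n", r$n_input))
  cat(sprintf("  short, discarded:   %d\n", r$n_short_discarded))
  cat(sprintf("  unique tags:        %d\n", r$n_unique))
  cat(sprintf("  assigned:           %d unique (%d reads)\n",
              r$n_assigned_unique, r$n_assigned_reads))
  cat(sprintf("  unassigned barcode: %d unique (%d reads)\n",
              r$n_unassigned_unique, r$n_unassigned_reads))
  for (lib in unique(x$tags$library)) {
    n <- sum(x$tags$library == lib)
    cat(sprintf("    library %s: %d unique tags\n", lib, n))
  }
  invisible(x)
}

#' Write a preprocessing run report as TSV
#'
#' @param run a `preprocess_run`.
#' @param path output path.
#' @export
write_preprocess_report <- function(run, path) {
  utils::write.table(run$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
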