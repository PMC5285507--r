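## Maxicircle reference model: transcript annotations, uridine editing
## events, preedited/fully-edited sequence pairs and editing extents.
##
## Conventions: DNA alphabet throughout (U stored as T, as in cDNA reads and
## genomic references); coordinates 0-based half-open internally.

EDITING_CATEGORIES <- c("pan_edited", "minimally_edited", "never_edited")

#' Validate a transcript annotation table
#'
#' An annotation table has one row per maxicircle transcript with columns
#' `transcript_id`, `start`, `end` (0-based half-open genome coordinates),
#' `strand` (`+`/`-`) and `category` (one of `pan_edited`,
#' `minimally_edited`, `never_edited`).
#'
#' @param annotations data.frame as described above.
#' @param genome_length optional genome length for bounds checking.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_annotations <- function(annotations, genome_length = NULL) {
  req <- c("transcript_id", "start", "end", "strand", "category")
  missing <- setdiff(req, names(annotations))
  if (length(missing)) {
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(annotations$transcript_id)) {
    stop("duplicated transcript_id in annotations")
  }
  if (!all(annotations$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (!all(annotations$category %in% EDITING_CATEGORIES)) {
    stop("category must be one of: ", paste(EDITING_CATEGORIES, collapse = ", "))
  }
  bad <- annotations$start < 0 | annotations$start >= annotations$end
  if (any(bad)) {
    stop("invalid interval for transcript(s): ",
         paste(annotations$transcript_id[bad], collapse = ", "))
  }
  if (!is.null(genome_length) && any(annotations$end > genome_length)) {
    stop("annotation extends beyond the genome")
  }
  annotations
}

#' Read a transcript annotation table from TSV
#'
#' @param path tab-separated file with columns `transcript_id`, `start`,
#'   `end`, `strand`, `category`.
#' @return validated annotation data.frame.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_annotations(ann)
}

#' Read a uridine editing event table from TSV
#'
#' Each row is one editing event: `transcript_id`, `anchor` (0-based
#' position in the preedited transcript; the event applies immediately 3' of
#' this base), `kind` (`insertion`/`deletion`) and `n_u` (number of uridines).
#'
#' @param path tab-separated event file.
#' @return event data.frame.
#' @export
read_editing_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_events(ev)
}

validate_events <- function(events) {
  req <- c("transcript_id", "anchor", "kind", "n_u")
  missing <- setdiff(req, names(events))
  if (length(missing)) {
    stop("event table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(events$kind %in% c("insertion", "deletion"))) {
    stop("event kind must be 'insertion' or 'deletion'")
  }
  if (any(events$n_u < 1)) stop("n_u must be >= 1")
  dup <- stats::aggregate(anchor ~ transcript_id, events,
                          function(a) anyDuplicated(a) > 0)
  if (any(dup$anchor)) {
    stop("duplicated event anchors within transcript(s): ",
         paste(dup$transcript_id[dup$anchor], collapse = ", "))
  }
  events
}

#' Extract transcript-oriented preedited sequences from a genome
#'
#' Minus-strand transcripts are reverse-complemented so that every returned
#' sequence reads 5' to 3' in transcript orientation.
#'
#' @param genome genome sequence (single character string or
#'   one-element `DNAStringSet`).
#' @param annotations validated annotation table.
#' @return named character vector of preedited transcript sequences.
#' @export
transcript_sequences <- function(genome, annotations) {
  genome <- unname(as_dna_character(genome)[1])
  validate_annotations(annotations, nchar(genome))
  seqs <- substring(genome, annotations$start + 1L, annotations$end)
  minus <- annotations$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  stats::setNames(seqs, annotations$transcript_id)
}

#' Apply uridine editing events to a preedited transcript sequence
#'
#' Events are anchored on the preedited sequence (0-based; an event applies
#' immediately 3' of its anchor base) and applied from the highest anchor
#' down, so anchor coordinates never shift during application. An insertion
#' adds `n_u` T characters after the anchor base; a deletion removes `n_u`
#' T characters immediately after the anchor base and requires that the
#' preedited sequence carries at least `n_u` consecutive Ts there.
#'
#' @param preedited_seq preedited transcript sequence (character scalar,
#'   transcript orientation, U as T).
#' @param events data.frame with columns `anchor`, `kind`, `n_u` (a
#'   `transcript_id` column, if present, is ignored here).
#' @return edited sequence (character scalar). Removing all T characters
#'   from input and output yields identical strings.
#' @examples
#' build_edited_sequence("AGCGA", data.frame(anchor = 1, kind = "insertion", n_u = 2))
#' @export
build_edited_sequence <- function(preedited_seq, events) {
  preedited_seq <- as_dna_character(preedited_seq)[1]
  if (is.null(events) || nrow(events) == 0L) return(preedited_seq)
  events <- validate_events(cbind(transcript_id = "x",
                                  events[c("anchor", "kind", "n_u")]))
  n <- nchar(preedited_seq)
  if (any(events$anchor < 0 | events$anchor >= n)) {
    stop("event anchor outside the preedited sequence")
  }
  ## validate deletions against the *preedited* sequence up front
  del <- events[events$kind == "deletion", , drop = FALSE]
  if (nrow(del)) {
    run <- substring(preedited_seq, del$anchor + 2L, del$anchor + 1L + del$n_u)
    ok <- nchar(run) == del$n_u & run == strrep("T", del$n_u)
    if (!all(ok)) {
      bad <- del[!ok, , drop = FALSE][1L, ]
      stop(sprintf(
        "invalid deletion anchor %d (n_u=%d): fewer than %d consecutive Us follow",
        bad$anchor, bad$n_u, bad$n_u))
    }
  }
  s <- strsplit(preedited_seq, "", fixed = TRUE)[[1]]
  for (i in order(events$anchor, decreasing = TRUE)) {
    a <- events$anchor[i]
    k <- events$n_u[i]
    if (events$kind[i] == "insertion") {
      s <- append(s, rep("T", k), after = a + 1L)
    } else {
      s <- s[-seq.int(a + 2L, a + 1L + k)]
    }
  }
  paste(s, collapse = "")
}

#' Count the editing extent between a preedited and an edited sequence
#'
#' Computes the minimal uridine-only edit counts separating two sequences
#' whose non-T backbones are identical: aligning the two with all non-T
#' characters as forced matches, the optimal alignment compares, gap by gap,
#' the T-run lengths between consecutive backbone characters. Ts present
#' only in the edited sequence are insertions; Ts present only in the
#' preedited sequence are deletions.
#'
#' @param preedited_seq,edited_seq the two transcript sequences (U as T).
#' @return one-row data.frame with columns `insertions`, `deletions`,
#'   `total`.
#' @examples
#' count_editing_extent("AGTCA", "AGCTTA") # 2 insertions, 1 deletion
#' @export
count_editing_extent <- function(preedited_seq, edited_seq) {
  preedited_seq <- as_dna_character(preedited_seq)[1]
  edited_seq <- as_dna_character(edited_seq)[1]
  if (strip_t(preedited_seq) != strip_t(edited_seq)) {
    stop("not an editing pair: non-U backbones differ")
  }
  gp <- t_gap_lengths(preedited_seq)
  ge <- t_gap_lengths(edited_seq)
  ins <- sum(pmax(ge - gp, 0L))
  del <- sum(pmax(gp - ge, 0L))
  data.frame(insertions = ins, deletions = del, total = ins + del)
}

#' Build the preedited/fully-edited reference pair
#'
#' Constructs, from a maxicircle genome, transcript annotations and an
#' editing event table, the two mapping references used for tag
#' classification: the preedited genome itself, and the fully edited
#' sequences of all transcripts in an editing category (pan-edited and
#' minimally edited; never-edited transcripts are represented in the genome
#' only). The edited sequences are catenated into a single reference
#' separated by runs of `spacer` N characters so that no tag can align
#' across a junction, together with a coordinate map back to transcript
#' space.
#'
#' @param genome genome sequence (character or `DNAStringSet`, one sequence).
#' @param annotations validated annotation table.
#' @param events editing event table (may be empty / NULL).
#' @param spacer number of N characters between catenated edited sequences.
#' @return an object of class `reference_pair`: a list with elements
#'   `genome`, `annotations`, `events`, `preedited` (named per-transcript
#'   preedited sequences), `edited` (named fully edited sequences),
#'   `catenated` (the spacered edited reference), `catalog` (transcript
#'   offsets/lengths within `catenated`), `extents` (per-transcript editing
#'   extents) and `spacer`.
#' @export
build_reference_pair <- function(genome, annotations, events = NULL,
                                 spacer = 100L) {
  genome <- unname(as_dna_character(genome)[1])
  annotations <- validate_annotations(annotations, nchar(genome))
  if (is.null(events)) {
    events <- data.frame(transcript_id = character(), anchor = integer(),
                         kind = character(), n_u = integer())
  }
  if (nrow(events)) {
    events <- validate_events(events)
    unknown <- setdiff(events$transcript_id, annotations$transcript_id)
    if (length(unknown)) {
      stop("events reference unknown transcript(s): ",
           paste(unknown, collapse = ", "))
    }
    never <- annotations$transcript_id[annotations$category == "never_edited"]
    bad <- intersect(events$transcript_id, never)
    if (length(bad)) {
      stop("never-edited transcript(s) with editing events: ",
           paste(bad, collapse = ", "))
    }
  }
  pre <- transcript_sequences(genome, annotations)
  editing <- annotations$transcript_id[annotations$category != "never_edited"]
  edited <- vapply(editing, function(tx) {
    build_edited_sequence(pre[[tx]],
                          events[events$transcript_id == tx, , drop = FALSE])
  }, character(1))
  lens <- nchar(edited)
  offsets <- if (length(lens)) {
    cumsum(c(0L, head(lens + spacer, -1L)))
  } else integer(0)
  catalog <- data.frame(transcript_id = editing, offset = offsets,
                        length = unname(lens), stringsAsFactors = FALSE)
  catenated <- paste(edited, collapse = strrep("N", spacer))
  extents <- do.call(rbind, lapply(annotations$transcript_id, function(tx) {
    if (tx %in% editing) {
      cbind(transcript_id = tx, count_editing_extent(pre[[tx]], edited[[tx]]))
    } else {
      data.frame(transcript_id = tx, insertions = 0L, deletions = 0L,
                 total = 0L)
    }
  }))
  structure(list(genome = genome, annotations = annotations, events = events,
                 preedited = pre, edited = edited, catenated = catenated,
                 catalog = catalog, extents = extents, spacer = spacer),
            class = "reference_pair")
}

#' @export
print.reference_pair <- function(x, ...) {
  cat("reference_pair\n")
  cat(sprintf("  genome: %d nt, %d annotated transcripts (%d editing-category)\n",
              nchar(x$genome), nrow(x$annotations), nrow(x$catalog)))
  cat(sprintf("  catenated edited reference: %d nt (%d-N spacers)\n",
              nchar(x$catenated), x$spacer))
  cat(sprintf("  total editing extent: %d insertions, %d deletions\n",
              sum(x$extents$insertions), sum(x$extents$deletions)))
  invisible(x)
}

#' Per-transcript editing extents of a reference pair
#'
#' @param ref_pair a `reference_pair`.
#' @return data.frame with `transcript_id`, `insertions`, `deletions`,
#'   `total` (never-edited transcripts have total 0).
#' @export
editing_extents <- function(ref_pair) {
  stopifnot(inherits(ref_pair, "reference_pair"))
  ref_pair$extents
}

#' Map positions on the catenated edited reference back to transcript space
#'
#' @param ref_pair a `reference_pair`.
#' @param pos integer vector of 0-based positions on the catenated
#'   reference.
#' @return data.frame with `transcript_id` (NA within spacers) and
#'   `transcript_pos` (0-based position within the fully edited transcript).
#' @export
map_catenated_position <- function(ref_pair, pos) {
  cat <- ref_pair$catalog
  idx <- findInterval(pos, cat$offset)
  tx <- rep(NA_character_, length(pos))
  tpos <- rep(NA_integer_, length(pos))
  inside <- idx >= 1L
  if (any(inside)) {
    off <- cat$offset[idx[inside]]
    len <- cat$length[idx[inside]]
    rel <- pos[inside] - off
    ok <- rel < len
    tx[inside][ok] <- cat$transcript_id[idx[inside]][ok]
    tpos[inside][ok] <- rel[ok]
  }
  data.frame(transcript_id = tx, transcript_pos = tpos)
}

#' Write a reference pair to disk
#'
#' Writes the genome FASTA, the fully edited transcript FASTA (one entry per
#' transcript, un-spacered) and the extent table TSV.
#'
#' @param ref_pair a `reference_pair`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
write_reference_pair <- function(ref_pair, dir, prefix = "maxicircle") {
  stopifnot(inherits(ref_pair, "reference_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_genome.fa", "_edited.fa",
                                           "_extents.tsv")))
  write_fasta(stats::setNames(ref_pair$genome, "maxicircle"), paths[1])
  write_fasta(ref_pair$edited, paths[2])
  utils::write.table(ref_pair$extents, paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
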