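## Editing-aware sequential two-reference mapping: every tag is aligned
## first to the maxicircle genome, and only tags without a genome hit are
## then aligned to the catenated fully-edited reference. Uniquely mapped
## tags are classified preedited or fully_edited accordingly; best-score
## ties are multimapped and discarded from binding counts.

#' Alignment parameters
#'
#' @param seed_length minimum tag length considered alignable; shorter tags
#'   are unmapped by contract.
#' @param max_mismatches per-alignment mismatch cap.
#' @param mismatch_penalty score deducted per mismatch.
#' @param match_score score gained per matching base.
#' @param min_score_fraction minimum score / tag length to accept a hit.
#' @return list of class `alignment_params`.
#' @export
alignment_params <- function(seed_length = 12L, max_mismatches = 2L,
                             mismatch_penalty = 1, match_score = 1,
                             min_score_fraction = 0.9) {
  stopifnot(seed_length >= 1L, max_mismatches >= 0L)
  structure(list(seed_length = as.integer(seed_length),
                 max_mismatches = as.integer(max_mismatches),
                 mismatch_penalty = mismatch_penalty,
                 match_score = match_score,
                 min_score_fraction = min_score_fraction),
            class = "alignment_params")
}

#' Align tags ungapped against a reference set
#'
#' Exact ungapped seed-and-extend over both strands: a hit is any locus
#' where the full tag aligns with at most `max_mismatches` mismatches and a
#' score of at least `min_score_fraction * length`. All qualifying loci are
#' returned (no heuristic loss); `N` characters never match.
#'
#' @param tags character vector of tag sequences (names become `tag_id`).
#' @param refs named character vector of reference sequences.
#' @param params an [alignment_params()].
#' @return data.frame with `tag_id`, `ref`, `pos` (0-based start on the
#'   forward reference), `strand`, `mismatches`, `score`.
#' @export
align_tags <- function(tags, refs, params = alignment_params()) {
  tags <- as_dna_character(tags)
  refs <- as_dna_character(refs)
  if (is.null(names(tags))) names(tags) <- sprintf("tag_%06d",
                                                   seq_along(tags))
  if (is.null(names(refs))) names(refs) <- sprintf("ref_%d", seq_along(refs))
  h <- cpp_align_tags(unname(tags), unname(refs), params$seed_length,
                      params$max_mismatches, params$mismatch_penalty,
                      params$match_score, params$min_score_fraction)
  data.frame(tag_id = names(tags)[h$tag], ref = names(refs)[h$ref],
             pos = h$pos, strand = h$strand, mismatches = h$mismatches,
             score = h$score, stringsAsFactors = FALSE)
}

#' Align a single tag
#'
#' @inheritParams align_tags
#' @param tag one tag sequence.
#' @return hit data.frame as in [align_tags()].
#' @export
align_tag <- function(tag, refs, params = alignment_params()) {
  align_tags(stats::setNames(tag, "tag"), refs, params)
}

## per-tag summary of a hit table: best score, number of best-score hits,
## and the locus of the single best hit where unique
best_hit_summary <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(tag_id = character(), n_best = integer(),
                      pos = integer(), strand = character(),
                      mismatches = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  best <- stats::aggregate(score ~ tag_id, hits, max)
  m <- merge(hits, best, by = c("tag_id", "score"))
  m <- m[order(m$tag_id, m$ref, m$pos, m$strand), , drop = FALSE]
  n_best <- stats::aggregate(pos ~ tag_id, m, length)
  names(n_best)[2] <- "n_best"
  first <- m[!duplicated(m$tag_id), , drop = FALSE]
  out <- merge(first, n_best, by = "tag_id")
  out[c("tag_id", "n_best", "pos", "strand", "mismatches", "score")]
}

#' Classify tags by sequential mapping to the dual references
#'
#' Stage 1 aligns every tag to the maxicircle genome: a single best-score
#' locus gives status `preedited`; several tied best loci give
#' `multimapped` (final, never re-mapped). Stage 2 aligns the tags with no
#' genome hit to the catenated fully-edited reference under the same
#' uniqueness rule, giving `fully_edited` or `multimapped`; everything else
#' is `unmapped`. Edited-reference hits overlapping an N spacer are
#' impossible within the mismatch budget and are dropped defensively.
#'
#' @param tags data.frame with columns `tag_id`, `sequence`, `multiplicity`
#'   (and optionally `library`), as produced by [preprocess_library()], or a
#'   named character vector of sequences.
#' @param ref_pair a [build_reference_pair()].
#' @param params an [alignment_params()].
#' @return data.frame of tag assignments: `tag_id`, `library`,
#'   `multiplicity`, `length`, `status`
#'   (`preedited`/`fully_edited`/`multimapped`/`unmapped`), `ref`, `pos`,
#'   `strand`, `score`, `mismatches`. Mapped statuses carry exactly one
#'   locus; the others carry NA.
#' @export
map_library <- function(tags, ref_pair, params = alignment_params()) {
  stopifnot(inherits(ref_pair, "reference_pair"))
  if (is.character(tags)) {
    tags <- data.frame(tag_id = names(tags) %||%
                         sprintf("tag_%06d", seq_along(tags)),
                       sequence = unname(tags), multiplicity = 1L,
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(c("tag_id", "sequence", "multiplicity") %in% names(tags)))
  if (anyDuplicated(tags$tag_id)) stop("tag ids must be unique")
  if (is.null(tags$library)) tags$library <- NA_character_

  out <- data.frame(tag_id = tags$tag_id, library = tags$library,
                    multiplicity = tags$multiplicity,
                    length = nchar(tags$sequence),
                    status = "unmapped", ref = NA_character_,
                    pos = NA_integer_, strand = NA_character_,
                    score = NA_real_, mismatches = NA_integer_,
                    stringsAsFactors = FALSE)
  seqs <- stats::setNames(tags$sequence, tags$tag_id)

  ## stage 1: maxicircle genome
  h1 <- align_tags(seqs, c(genome = ref_pair$genome), params)
  s1 <- best_hit_summary(h1)
  if (nrow(s1)) {
    i <- match(s1$tag_id, out$tag_id)
    uniq <- s1$n_best == 1L
    out$status[i] <- ifelse(uniq, "preedited", "multimapped")
    out$ref[i[uniq]] <- "genome"
    out$pos[i[uniq]] <- s1$pos[uniq]
    out$strand[i[uniq]] <- s1$strand[uniq]
    out$score[i[uniq]] <- s1$score[uniq]
    out$mismatches[i[uniq]] <- s1$mismatches[uniq]
  }

  ## stage 2: catenated fully-edited reference, remaining tags only
  remaining <- out$status == "unmapped"
  if (any(remaining) && nchar(ref_pair$catenated) > 0L) {
    h2 <- align_tags(seqs[remaining], c(edited = ref_pair$catenated), params)
    if (nrow(h2)) {
      len2 <- out$length[match(h2$tag_id, out$tag_id)]
      seg <- map_catenated_position(ref_pair, h2$pos)
      seg_end <- map_catenated_position(ref_pair, h2$pos + len2 - 1L)
      within <- !is.na(seg$transcript_id) & !is.na(seg_end$transcript_id) &
        seg$transcript_id == seg_end$transcript_id
      h2 <- h2[within, , drop = FALSE]
    }
    s2 <- best_hit_summary(h2)
    if (nrow(s2)) {
      i <- match(s2$tag_id, out$tag_id)
      uniq <- s2$n_best == 1L
      out$status[i] <- ifelse(uniq, "fully_edited", "multimapped")
      out$ref[i[uniq]] <- "edited"
      out$pos[i[uniq]] <- s2$pos[uniq]
      out$strand[i[uniq]] <- s2$strand[uniq]
      out$score[i[uniq]] <- s2$score[uniq]
      out$mismatches[i[uniq]] <- s2$mismatches[uniq]
    }
  }
  out
}

#' Project tag assignments into transcript space
#'
#' Genome hits are intersected with the annotation intervals: a hit is
#' assigned to the transcript containing its start, translated into
#' transcript-oriented coordinates (position of the tag's 5' end); hits
#' outside any annotation are flagged `intergenic`, and hits discordant
#' with the annotated strand are flagged `antisense` (tags derive from
#' mRNA, so only sense hits enter binding counts). Edited-reference hits
#' are translated through the catenated coordinate map; by construction
#' they are always sense and always within one transcript segment.
#'
#' @param assignments result of [map_library()].
#' @param ref_pair the [build_reference_pair()] used for mapping.
#' @return the assignment data.frame with added columns `transcript_id`,
#'   `frame` (`preedited`/`fully_edited`), `tpos` (0-based 5'-end position
#'   in the transcript frame) and `flag`
#'   (`sense`/`antisense`/`intergenic`).
#' @export
project_to_transcripts <- function(assignments, ref_pair) {
  stopifnot(inherits(ref_pair, "reference_pair"))
  ann <- ref_pair$annotations
  out <- assignments
  out$transcript_id <- NA_character_
  out$frame <- NA_character_
  out$tpos <- NA_integer_
  out$flag <- NA_character_

  g <- which(out$status == "preedited")
  if (length(g)) {
    pos <- out$pos[g]
    len <- out$length[g]
    ## transcript containing the hit start (annotations may overlap; prefer
    ## one containing the full hit, then the first by genomic start)
    ord <- order(ann$start)
    idx <- vapply(seq_along(g), function(k) {
      cand <- ord[ann$start[ord] <= pos[k] & pos[k] < ann$end[ord]]
      if (!length(cand)) return(NA_integer_)
      full <- cand[pos[k] + len[k] <= ann$end[cand]]
      if (length(full)) full[1] else cand[1]
    }, integer(1))
    hit <- !is.na(idx)
    out$flag[g[!hit]] <- "intergenic"
    gi <- g[hit]; ai <- idx[hit]
    sense <- out$strand[gi] == ann$strand[ai]
    out$transcript_id[gi] <- ann$transcript_id[ai]
    out$frame[gi] <- "preedited"
    out$flag[gi] <- ifelse(sense, "sense", "antisense")
    plus <- ann$strand[ai] == "+"
    out$tpos[gi[plus]] <- out$pos[gi[plus]] - ann$start[ai[plus]]
    out$tpos[gi[!plus]] <- ann$end[ai[!plus]] -
      (out$pos[gi[!plus]] + out$length[gi[!plus]])
  }

  e <- which(out$status == "fully_edited")
  if (length(e)) {
    seg <- map_catenated_position(ref_pair, out$pos[e])
    if (anyNA(seg$transcript_id)) {
      stop("edited-reference hit crosses a spacer; this cannot happen")
    }
    out$transcript_id[e] <- seg$transcript_id
    out$frame[e] <- "fully_edited"
    sense <- out$strand[e] == "+"
    out$flag[e] <- ifelse(sense, "sense", "antisense")
    out$tpos[e[sense]] <- seg$transcript_pos[sense]
    if (any(!sense)) {
      seglen <- ref_pair$catalog$length[
        match(seg$transcript_id[!sense], ref_pair$catalog$transcript_id)]
      out$tpos[e[!sense]] <- seglen -
        (seg$transcript_pos[!sense] + out$length[e[!sense]])
    }
  }
  out
}

#' Write tag assignments as TSV
#'
#' @param assignments assignment data.frame (projected or not).
#' @param path output path.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Emit mapped assignments as a minimal SAM file
#'
#' One record per uniquely mapped tag, 1-based positions per the SAM
#' standard, full-length match CIGAR (the aligner is ungapped). Intended
#' for browser inspection of the dual-reference mapping.
#'
#' @param assignments result of [map_library()].
#' @param ref_pair the matching `reference_pair`.
#' @param path output path.
#' @export
write_sam <- function(assignments, ref_pair, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:genome\tLN:%d", nchar(ref_pair$genome)),
               sprintf("@SQ\tSN:edited\tLN:%d", nchar(ref_pair$catenated))),
             con)
  m <- assignments[assignments$status %in% c("preedited", "fully_edited"), ,
                   drop = FALSE]
  if (nrow(m)) {
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\tNM:i:%d",
                       m$tag_id, ifelse(m$strand == "-", 16L, 0L), m$ref,
                       m$pos + 1L, m$length, m$mismatches), con)
  }
  invisible(path)
}
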