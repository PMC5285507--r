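## Binding quantification: per-transcript tag counts and shares, category
## and region (preedited vs fully edited) shares, length-normalised
## densities, coverage tracks, 5'-end bias, and the correlation of binding
## share with editing extent.
##
## All quantities count unique tags (deduplicated cDNAs) with a sense,
## uniquely mapped assignment; multimapped, intergenic and antisense tags
## are excluded throughout.

sense_mapped <- function(proj) {
  stopifnot(all(c("status", "flag", "transcript_id") %in% names(proj)))
  proj[proj$status %in% c("preedited", "fully_edited") &
         !is.na(proj$flag) & proj$flag == "sense", , drop = FALSE]
}

#' Count uniquely mapped tags per transcript
#'
#' For transcripts undergoing editing, preedited and fully-edited tags are
#' combined into `n_total`; never-edited transcripts can only carry
#' preedited tags. `share_total` is each transcript's percentage of all
#' assigned (sense, unique) tags.
#'
#' @param proj projected assignments from [project_to_transcripts()].
#' @param ref_pair the matching `reference_pair` (supplies the annotation).
#' @return data.frame with one row per annotated transcript:
#'   `transcript_id`, `category`, `length` (preedited nt), `n_preedited`,
#'   `n_fully_edited`, `n_total`, `share_total` (percent).
#' @export
count_per_transcript <- function(proj, ref_pair) {
  stopifnot(inherits(ref_pair, "reference_pair"))
  ann <- ref_pair$annotations
  s <- sense_mapped(proj)
  tab <- function(frame) {
    x <- s[s$frame == frame, , drop = FALSE]
    cnt <- table(factor(x$transcript_id, levels = ann$transcript_id))
    as.integer(cnt)
  }
  out <- data.frame(transcript_id = ann$transcript_id,
                    category = ann$category,
                    length = ann$end - ann$start,
                    n_preedited = tab("preedited"),
                    n_fully_edited = tab("fully_edited"),
                    stringsAsFactors = FALSE)
  out$n_total <- out$n_preedited + out$n_fully_edited
  grand <- sum(out$n_total)
  out$share_total <- if (grand > 0) 100 * out$n_total / grand else NA_real_
  out
}

#' Percent of assigned tags per editing category
#'
#' @param counts result of [count_per_transcript()].
#' @return data.frame with `category`, `n_tags`, `share` (percent; shares
#'   sum to 100, NA when no tags are assigned).
#' @export
category_shares <- function(counts) {
  n <- vapply(EDITING_CATEGORIES, function(cat) {
    sum(counts$n_total[counts$category == cat])
  }, numeric(1))
  grand <- sum(n)
  data.frame(category = EDITING_CATEGORIES, n_tags = as.integer(n),
             share = if (grand > 0) 100 * n / grand else NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Percent preedited vs fully edited among editing-category tags
#'
#' Never-edited transcripts are excluded from the denominator: the
#' preedited/fully-edited split is only meaningful for transcripts that
#' undergo editing.
#'
#' @param counts result of [count_per_transcript()].
#' @return data.frame with `region` (`preedited`/`fully_edited`), `n_tags`,
#'   `share` (percent, NA when the denominator is zero).
#' @export
region_shares <- function(counts) {
  ed <- counts[counts$category != "never_edited", , drop = FALSE]
  n <- c(preedited = sum(ed$n_preedited),
         fully_edited = sum(ed$n_fully_edited))
  grand <- sum(n)
  data.frame(region = names(n), n_tags = as.integer(n),
             share = if (grand > 0) 100 * n / grand else NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Length-normalised binding density (tags per kilonucleotide)
#'
#' @param counts result of [count_per_transcript()].
#' @return `counts` with an added `density` column:
#'   `1000 * n_total / length` of the preedited transcript.
#' @export
length_normalized_density <- function(counts) {
  counts$density <- 1000 * counts$n_total / counts$length
  counts
}

#' Per-position unique-tag coverage tracks
#'
#' For each transcript and reference frame, counts at every position the
#' number of unique tags whose ungapped alignment covers it. Track length
#' equals the transcript length in its frame (preedited length from the
#' annotation, fully edited length from the catenated catalog); the summed
#' track equals the summed (in-frame) lengths of the contributing tags.
#'
#' @param proj projected assignments.
#' @param ref_pair the matching `reference_pair`.
#' @return object of class `coverage_track`: a named list of integer
#'   vectors keyed `"<transcript>:<frame>"`.
#' @export
coverage_track <- function(proj, ref_pair) {
  stopifnot(inherits(ref_pair, "reference_pair"))
  ann <- ref_pair$annotations
  s <- sense_mapped(proj)
  tracks <- list()
  for (i in seq_len(nrow(ann))) {
    tx <- ann$transcript_id[i]
    frames <- if (ann$category[i] == "never_edited") "preedited"
              else c("preedited", "fully_edited")
    for (fr in frames) {
      L <- if (fr == "preedited") ann$end[i] - ann$start[i]
           else ref_pair$catalog$length[ref_pair$catalog$transcript_id == tx]
      x <- s[s$transcript_id == tx & s$frame == fr, , drop = FALSE]
      d <- numeric(L + 1L)
      if (nrow(x)) {
        from <- pmax(x$tpos, 0L) + 1L
        to <- pmin(x$tpos + x$length, L) + 1L
        ok <- from <= L & to > from
        for (k in which(ok)) {
          d[from[k]] <- d[from[k]] + 1
          d[to[k]] <- d[to[k]] - 1
        }
      }
      tracks[[paste0(tx, ":", fr)]] <- as.integer(cumsum(d)[seq_len(L)])
    }
  }
  structure(tracks, class = "coverage_track")
}

#' Write coverage tracks as bedGraph
#'
#' 0-based half-open intervals per the bedGraph standard, one chrom per
#' transcript/frame track, zero runs omitted.
#'
#' @param tracks a [coverage_track()] result.
#' @param path output path.
#' @export
write_bedgraph <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph", con)
  for (nm in names(tracks)) {
    r <- rle(tracks[[nm]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%d", nm, starts[keep], ends[keep],
                         r$values[keep]), con)
    }
  }
  invisible(path)
}

#' Fraction of tag 5' ends in the 5' third of the transcript
#'
#' Measures 5'-end accumulation of binding: the proportion of uniquely
#' mapped sense tags whose 5' end falls within the first third of the
#' transcript in the chosen frame. Uniform tag starts give roughly 1/3.
#'
#' @param proj projected assignments.
#' @param ref_pair the matching `reference_pair`.
#' @param transcripts transcripts to pool (default: all annotated).
#' @param frame reference frame of the positions (default `"preedited"`).
#' @return fraction in `[0, 1]`, or NA when no tag qualifies.
#' @export
five_prime_bias <- function(proj, ref_pair, transcripts = NULL,
                            frame = "preedited") {
  stopifnot(inherits(ref_pair, "reference_pair"))
  ann <- ref_pair$annotations
  if (is.null(transcripts)) transcripts <- ann$transcript_id
  s <- sense_mapped(proj)
  s <- s[s$frame == frame & s$transcript_id %in% transcripts, , drop = FALSE]
  if (nrow(s) == 0L) return(NA_real_)
  L <- if (frame == "preedited") {
    stats::setNames(ann$end - ann$start, ann$transcript_id)
  } else {
    stats::setNames(ref_pair$catalog$length, ref_pair$catalog$transcript_id)
  }
  mean(s$tpos < L[s$transcript_id] / 3)
}

#' Correlate per-transcript binding share with editing extent
#'
#' Pearson product-moment correlation between the total binding share
#' (preedited + fully edited tags of a transcript as a percentage of all
#' assigned tags) and the transcript's editing extent (total uridines
#' inserted plus deleted), over the transcripts of one category.
#'
#' @param counts result of [count_per_transcript()].
#' @param extents result of [editing_extents()].
#' @param category transcript category to correlate over (default
#'   pan-edited, the category spanning a wide extent range).
#' @return list of class `correlation_result` with `r`, `n`,
#'   `transcripts`, `x` (extents), `y` (shares, percent).
#' @export
correlate_with_editing_extent <- function(counts, extents,
                                          category = "pan_edited") {
  sel <- counts[counts$category == category, , drop = FALSE]
  if (nrow(sel) < 3L) stop("need >= 3 transcripts to report a correlation")
  x <- extents$total[match(sel$transcript_id, extents$transcript_id)]
  y <- sel$share_total
  if (anyNA(x) || anyNA(y)) stop("missing extent or share values")
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in extents or shares; correlation undefined")
    NA_real_
  } else {
    stats::cor(x, y)
  }
  structure(list(r = r, n = nrow(sel), transcripts = sel$transcript_id,
                 x = x, y = y), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f over %d transcripts\n", x$r, x$n))
  invisible(x)
}

#' One-stop binding summary of a projected tag library
#'
#' @param proj projected assignments.
#' @param ref_pair the matching `reference_pair`.
#' @return list of class `binding_summary` with elements `counts`
#'   (per-transcript, with densities), `category_shares`, `region_shares`
#'   and `correlation` (pan-edited share vs extent; NULL when fewer than 3
#'   pan-edited transcripts are annotated).
#' @export
binding_summary <- function(proj, ref_pair) {
  counts <- length_normalized_density(count_per_transcript(proj, ref_pair))
  corr <- if (sum(counts$category == "pan_edited") >= 3L) {
    correlate_with_editing_extent(counts, editing_extents(ref_pair))
  }
  structure(list(counts = counts,
                 category_shares = category_shares(counts),
                 region_shares = region_shares(counts),
                 correlation = corr),
            class = "binding_summary")
}

#' @export
print.binding_summary <- function(x, ...) {
  cat("binding_summary\n")
  cs <- x$category_shares
  cat(sprintf("  %-17s %7d tags  %5.1f%%\n", cs$category, cs$n_tags,
              cs$share), sep = "")
  rs <- x$region_shares
  cat(sprintf("  editing-category tags: %.1f%% preedited / %.1f%% fully edited\n",
              rs$share[1], rs$share[2]))
  if (!is.null(x$correlation)) {
    cat(sprintf("  share vs editing extent (pan-edited): r = %.3f (n = %d)\n",
                x$correlation$r, x$correlation$n))
  }
  invisible(x)
}

#' Write a binding summary as TSV files
#'
#' @param summary a [binding_summary()].
#' @param dir output directory.
#' @param prefix file name prefix.
#' @export
write_binding_summary <- function(summary, dir, prefix = "binding") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, what) {
    p <- file.path(dir, sprintf("%s_%s.tsv", prefix, what))
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(w(summary$counts, "counts"),
             w(summary$category_shares, "category_shares"),
             w(summary$region_shares, "region_shares"))
  if (!is.null(summary$correlation)) {
    co <- summary$correlation
    paths <- c(paths, w(data.frame(transcript_id = co$transcripts,
                                   extent = co$x, share = co$y,
                                   r = co$r, n = co$n), "correlation"))
  }
  invisible(paths)
}
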