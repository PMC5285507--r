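## Synthetic maxicircle world: genome, annotations, a 3'-to-5' gRNA-block
## editing cascade, and iCLIP-style read libraries with ground truth.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator. Defaults emulate
#' the study system: an ~20 kb AT-rich circular genome carrying 18
#' protein-coding transcripts (9 pan-edited, 3 minimally edited, 6
#' never-edited); pan-edited extents spanning roughly 50-550 uridines and
#' minimally edited extents 4-40; editing consumed in fixed-length gRNA
#' blocks strictly 3' to 5'; tags of 30-50 nt carrying a 4-nt experimental
#' barcode and a 3' sequencing adapter; PCR duplication with a geometric
#' family-size distribution; and a near-empty control library of 483 tags.
#'
#' @param seed integer seed; all generator functions derive their RNG state
#'   from it, so identical configurations give byte-identical output.
#' @param genome_length genome size in nt.
#' @param n_pan,n_minimal,n_never transcript counts per editing category.
#' @param transcript_length length range (nt) of preedited transcripts.
#' @param pan_extent,minimal_extent ranges of total editing extent
#'   (insertions + deletions) for pan-edited and minimally edited
#'   transcripts. Pan extents are laid out as jittered evenly spaced values
#'   across the range so every simulated maxicircle spans it, as the real
#'   nine pan-edited mRNAs do.
#' @param deletion_fraction fraction of editing extent realised as U
#'   deletions where the preedited sequence allows it.
#' @param grna_block_length nt of preedited sequence covered per editing
#'   block; editing progress is measured in completed 3' blocks.
#' @param editing_progress distribution of per-molecule editing progress:
#'   `"uniform"` (uniform over 0..n_blocks), `"none"` (all preedited) or
#'   `"full"` (all fully edited).
#' @param binding_model `"extent_proportional"` (expected tags per
#'   transcript proportional to its editing extent),
#'   `"five_prime_restricted"` (uniform transcript weights, insert 5' ends
#'   confined to the 5' third of the molecule) or `"uniform"`.
#' @param n_reads number of raw reads emitted per library (after PCR
#'   duplication).
#' @param tag_length insert length range, must lie within [20, 60].
#' @param read_length sequencer read length; the emitted read is
#'   barcode + insert + adapter truncated to this many bases.
#' @param barcode 4-nt experimental barcode of the default library.
#' @param adapter 3' adapter sequence.
#' @param pcr_duplication_rate probability parameter of the geometric
#'   duplicate-family size (0 = no duplicates).
#' @param sequencing_error_rate per-base substitution rate, applied after
#'   duplication.
#' @param control_tag_count reads in the simulated control library.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 20000L,
                              n_pan = 9L, n_minimal = 3L, n_never = 6L,
                              transcript_length = c(400L, 900L),
                              pan_extent = c(50L, 550L),
                              minimal_extent = c(4L, 40L),
                              deletion_fraction = 0.1,
                              grna_block_length = 50L,
                              editing_progress = c("uniform", "none", "full"),
                              binding_model = c("extent_proportional",
                                                "five_prime_restricted",
                                                "uniform"),
                              n_reads = 50000L,
                              tag_length = c(30L, 50L),
                              read_length = 75L,
                              barcode = "TCGA",
                              adapter = "AGATCGGAAGAGC",
                              pcr_duplication_rate = 0.3,
                              sequencing_error_rate = 0.001,
                              control_tag_count = 483L) {
  editing_progress <- match.arg(editing_progress)
  binding_model <- match.arg(binding_model)
  stopifnot(length(tag_length) == 2L, tag_length[1] <= tag_length[2])
  if (tag_length[1] < 20L || tag_length[2] > 60L) {
    stop("tag_length must lie within [20, 60]")
  }
  for (r in c(pcr_duplication_rate, sequencing_error_rate)) {
    if (r < 0 || r > 1) stop("rates must be in [0, 1]")
  }
  if (nchar(barcode) != 4L) stop("barcode must be 4 nt")
  if (nchar(adapter) < 1L) stop("adapter must be nonempty")
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 n_pan = n_pan, n_minimal = n_minimal, n_never = n_never,
                 transcript_length = transcript_length,
                 pan_extent = pan_extent, minimal_extent = minimal_extent,
                 deletion_fraction = deletion_fraction,
                 grna_block_length = grna_block_length,
                 editing_progress = editing_progress,
                 binding_model = binding_model,
                 n_reads = n_reads, tag_length = tag_length,
                 read_length = read_length, barcode = toupper(barcode),
                 adapter = toupper(adapter),
                 pcr_duplication_rate = pcr_duplication_rate,
                 sequencing_error_rate = sequencing_error_rate,
                 control_tag_count = control_tag_count),
            class = "simulation_config")
}

## Canonical maxicircle gene names per category, used to label simulated
## transcripts (recycled/numbered if counts exceed the real gene sets).
PAN_EDITED_GENES <- c("RPS12", "ND3", "CR4", "ND8", "ND9", "CR3", "A6",
                      "ND7", "COX3")
MINIMALLY_EDITED_GENES <- c("COX2", "MURF2", "CYB")
NEVER_EDITED_GENES <- c("ND1", "COX1", "ND4", "ND5", "MURF5", "MURF1")

category_names <- function(pool, n, prefix) {
  if (n <= length(pool)) pool[seq_len(n)]
  else c(pool, sprintf("%s%d", prefix, seq_len(n - length(pool))))
}

#' Draw a random valid uridine editing event set for one transcript
#'
#' Events are anchored at distinct non-T bases of the preedited sequence (at
#' most one event per backbone gap, the natural anchoring for editing sites,
#' which sit between non-U bases); deletions are only placed where the
#' preedited sequence carries enough consecutive Ts. With this anchoring the
#' per-kind event sums are exactly recoverable by
#' [count_editing_extent()] after [build_edited_sequence()].
#'
#' Uses the current RNG state (call `set.seed()` upstream for
#' reproducibility).
#'
#' @param preedited_seq preedited transcript sequence.
#' @param total_extent target total number of inserted + deleted uridines.
#' @param deletion_fraction fraction of extent attempted as deletions.
#' @param max_event_size maximum uridines per single event.
#' @param transcript_id label written into the event table.
#' @return event data.frame (`transcript_id`, `anchor`, `kind`, `n_u`).
#' @export
random_editing_events <- function(preedited_seq, total_extent,
                                  deletion_fraction = 0.1,
                                  max_event_size = 4L,
                                  transcript_id = "tx") {
  chars <- strsplit(preedited_seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  nonT <- which(chars != "T") - 1L            # 0-based anchors
  ## T-run length immediately 3' of each non-T base
  run_after <- vapply(nonT, function(a) {
    j <- a + 2L; r <- 0L
    while (j <= n && chars[j] == "T") { r <- r + 1L; j <- j + 1L }
    r
  }, integer(1))
  avail <- rep(TRUE, length(nonT))
  out <- vector("list", 0L)
  remaining <- as.integer(total_extent)
  while (remaining > 0L && any(avail)) {
    want_del <- stats::runif(1) < deletion_fraction
    cand <- if (want_del) which(avail & run_after >= 1L) else which(avail)
    if (!length(cand)) { cand <- which(avail); want_del <- FALSE }
    i <- cand[sample.int(length(cand), 1L)]
    avail[i] <- FALSE
    cap <- min(max_event_size, remaining,
               if (want_del) run_after[i] else remaining)
    k <- sample.int(cap, 1L)
    out[[length(out) + 1L]] <- data.frame(
      transcript_id = transcript_id, anchor = nonT[i],
      kind = if (want_del) "deletion" else "insertion", n_u = k)
    remaining <- remaining - k
  }
  if (!length(out)) {
    return(data.frame(transcript_id = character(), anchor = integer(),
                      kind = character(), n_u = integer()))
  }
  ev <- do.call(rbind, out)
  ev[order(ev$anchor), , drop = FALSE]
}

## jittered evenly spaced extents spanning [lo, hi]
stratified_extents <- function(n, lo, hi) {
  base <- seq(lo, hi, length.out = n)
  jit <- base * stats::runif(n, 0.9, 1.1)
  ext <- as.integer(round(pmin(pmax(jit, lo), hi)))
  sample(ext)
}

#' Simulate a maxicircle-like genome, annotations and editing events
#'
#' Generates a random AT-rich genome, places non-overlapping transcripts of
#' the three editing categories on it (both strands), and draws a valid
#' editing event set per editing-category transcript with total extents in
#' the configured ranges. Deterministic for a fixed configuration.
#'
#' @param config a [simulation_config()].
#' @return list with elements `genome` (named character), `annotations`,
#'   `events`, of class `maxicircle_sim`.
#' @export
simulate_maxicircle <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_tx <- config$n_pan + config$n_minimal + config$n_never
  lens <- sample(config$transcript_length[1]:config$transcript_length[2],
                 n_tx, replace = TRUE)
  if (sum(lens) > 0.85 * config$genome_length) {
    stop("genome too short for the requested transcripts")
  }
  genome <- paste(sample(c("A", "C", "G", "T"), config$genome_length,
                         replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.3)),
                  collapse = "")
  ids <- c(category_names(PAN_EDITED_GENES, config$n_pan, "PAN"),
           category_names(MINIMALLY_EDITED_GENES, config$n_minimal, "MIN"),
           category_names(NEVER_EDITED_GENES, config$n_never, "NEV"))
  cats <- rep(EDITING_CATEGORIES, c(config$n_pan, config$n_minimal,
                                    config$n_never))
  ord <- sample(n_tx)                       # shuffle genomic order
  slack <- config$genome_length - sum(lens)
  ## random partition of the slack into n_tx + 1 intergenic gaps
  gaps <- floor(slack * diff(sort(c(0, stats::runif(n_tx), 1))))
  starts <- integer(n_tx); pos <- 0L
  for (i in seq_len(n_tx)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + lens[ord[i]]
  }
  ann <- data.frame(transcript_id = ids[ord], start = starts,
                    end = starts + lens[ord],
                    strand = sample(c("+", "-"), n_tx, replace = TRUE,
                                    prob = c(0.7, 0.3)),
                    category = cats[ord], stringsAsFactors = FALSE)
  ann <- ann[order(match(ann$transcript_id, ids)), , drop = FALSE]
  rownames(ann) <- NULL
  validate_annotations(ann, config$genome_length)
  pre <- transcript_sequences(genome, ann)
  ext_target <- stats::setNames(rep(0L, n_tx), ann$transcript_id)
  pan_ids <- ann$transcript_id[ann$category == "pan_edited"]
  min_ids <- ann$transcript_id[ann$category == "minimally_edited"]
  ext_target[pan_ids] <- stratified_extents(length(pan_ids),
                                            config$pan_extent[1],
                                            config$pan_extent[2])
  ext_target[min_ids] <- stratified_extents(length(min_ids),
                                            config$minimal_extent[1],
                                            config$minimal_extent[2])
  events <- do.call(rbind, lapply(c(pan_ids, min_ids), function(tx) {
    random_editing_events(pre[[tx]], ext_target[[tx]],
                          deletion_fraction = config$deletion_fraction,
                          transcript_id = tx)
  }))
  if (is.null(events)) {
    events <- data.frame(transcript_id = character(), anchor = integer(),
                         kind = character(), n_u = integer())
  }
  rownames(events) <- NULL
  structure(list(genome = c(maxicircle = genome), annotations = ann,
                 events = events),
            class = "maxicircle_sim")
}

#' Simulate the transcript pool of partially edited molecules
#'
#' Editing proceeds 3' to 5' in fixed-length gRNA blocks over the preedited
#' sequence: a molecule with progress p is preedited 5' of its boundary and
#' fully edited 3' of it, where the boundary sits p blocks from the 3' end.
#' Progress 0 yields the preedited transcript; full progress yields the
#' fully edited transcript. Because the molecule sequence depends only on
#' (transcript, progress), the pool is returned as one row per such class
#' with a sampling weight combining the binding-model transcript weight and
#' the progress probability.
#'
#' @param config a [simulation_config()].
#' @param ref_pair the [build_reference_pair()] of the simulated maxicircle.
#' @return data.frame of class `transcript_pool` with columns
#'   `transcript_id`, `category`, `n_blocks`, `progress`, `boundary`
#'   (molecule position where the preedited 5' part ends), `sequence`,
#'   `length`, `weight`.
#' @export
simulate_transcript_pool <- function(config, ref_pair) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(ref_pair, "reference_pair"))
  ann <- ref_pair$annotations
  ext <- stats::setNames(ref_pair$extents$total, ref_pair$extents$transcript_id)
  block <- config$grna_block_length
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    tx <- ann$transcript_id[i]
    pre <- ref_pair$preedited[[tx]]
    Lp <- nchar(pre)
    ev <- ref_pair$events[ref_pair$events$transcript_id == tx, , drop = FALSE]
    n_blocks <- if (ann$category[i] == "never_edited") 0L
                else as.integer(ceiling(Lp / block))
    progress <- switch(config$editing_progress,
                       uniform = 0:n_blocks,
                       none = 0L,
                       full = n_blocks)
    p_prob <- rep(1 / length(progress), length(progress))
    seqs <- vapply(progress, function(p) {
      boundary <- max(Lp - p * block, 0L)
      sub <- ev[ev$anchor >= boundary, , drop = FALSE]
      if (nrow(sub) == 0L && boundary == Lp) return(pre)
      sub$anchor <- sub$anchor - boundary
      paste0(substring(pre, 1L, boundary),
             build_edited_sequence(substring(pre, boundary + 1L, Lp), sub))
    }, character(1))
    w_tx <- switch(config$binding_model,
                   extent_proportional = ext[[tx]],
                   1)
    data.frame(transcript_id = tx, category = ann$category[i],
               n_blocks = n_blocks, progress = progress,
               boundary = pmax(Lp - progress * block, 0L),
               sequence = seqs, length = nchar(seqs),
               weight = w_tx * p_prob, stringsAsFactors = FALSE)
  })
  pool <- do.call(rbind, rows)
  rownames(pool) <- NULL
  if (sum(pool$weight) <= 0) {
    stop("all pool weights are zero under the chosen binding model")
  }
  class(pool) <- c("transcript_pool", class(pool))
  pool
}

## geometric duplicate-family sizes summing exactly to n_reads
draw_family_sizes <- function(n_reads, dup_rate) {
  if (n_reads == 0L) return(integer(0))
  sizes <- integer(0)
  while (sum(sizes) < n_reads) {
    k <- max(n_reads, 1000L)
    sizes <- c(sizes, 1L + stats::rgeom(k, prob = 1 - dup_rate))
  }
  cum <- cumsum(sizes)
  m <- which(cum >= n_reads)[1]
  sizes <- sizes[seq_len(m)]
  sizes[m] <- sizes[m] - (cum[m] - n_reads)
  sizes[sizes > 0L]
}

inject_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  lens <- nchar(reads)
  n_err <- stats::rbinom(length(reads), lens, rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    s <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) {
      s[p] <- sample(setdiff(bases, s[p]), 1L)
    }
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

#' Simulate an iCLIP-style cross-linking tag library with ground truth
#'
#' Samples inserts from the molecule pool under the configured binding
#' model, assembles reads as barcode + insert + 3' adapter (truncated to the
#' read length), amplifies each unique cDNA into a geometric duplicate
#' family, and finally applies per-base sequencing errors. Every emitted
#' read has exactly one ground-truth record.
#'
#' @param config a [simulation_config()].
#' @param pool a [simulate_transcript_pool()] result.
#' @param library_name label written into read ids and truth records.
#' @param seed RNG seed for this library (defaults to `config$seed + 10` so
#'   that several libraries can be drawn from one configuration).
#' @param barcode 4-nt barcode of this library (default `config$barcode`).
#' @return list of class `iclap_library` with `reads` (named character
#'   vector, FASTQ-ready) and `truth` (one row per read: `read_id`,
#'   `library`, `family`, `transcript_id`, `progress`, `mol_start`,
#'   `insert_length`, `source` = preedited/edited/junction relative to the
#'   molecule's editing boundary, `has_error`).
#' @export
simulate_iclap_library <- function(config, pool, library_name = "iCLAP",
                                   seed = config$seed + 10L,
                                   barcode = config$barcode) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(pool, "transcript_pool"), nrow(pool) > 0L)
  set.seed(seed)
  sizes <- draw_family_sizes(config$n_reads, config$pcr_duplication_rate)
  m <- length(sizes)
  row <- sample.int(nrow(pool), m, replace = TRUE, prob = pool$weight)
  L <- pool$length[row]
  len <- sample(config$tag_length[1]:config$tag_length[2], m, replace = TRUE)
  len <- pmin(len, L)
  start_max <- if (config$binding_model == "five_prime_restricted") {
    pmax(pmin(floor(L / 3) - 1L, L - len), 0L)
  } else {
    L - len
  }
  start <- floor(stats::runif(m) * (start_max + 1L))
  insert <- substring(pool$sequence[row], start + 1L, start + len)
  boundary <- pool$boundary[row]
  source <- ifelse(start + len <= boundary, "preedited",
                   ifelse(start >= boundary, "edited", "junction"))
  unique_reads <- substr(paste0(barcode, insert, config$adapter),
                         1L, config$read_length)
  fam <- rep.int(seq_len(m), sizes)
  reads <- unique_reads[fam]
  reads <- inject_errors(reads, config$sequencing_error_rate)
  has_error <- reads != unique_reads[fam]
  ids <- sprintf("%s_r%06d", library_name, seq_along(reads))
  truth <- data.frame(read_id = ids, library = library_name, family = fam,
                      transcript_id = pool$transcript_id[row][fam],
                      progress = pool$progress[row][fam],
                      mol_start = start[fam], insert_length = len[fam],
                      source = source[fam], has_error = has_error,
                      stringsAsFactors = FALSE)
  structure(list(reads = stats::setNames(reads, ids), truth = truth),
            class = "iclap_library")
}

#' Simulate the near-empty control library
#'
#' Emits `config$control_tag_count` reads of valid barcode + random insert +
#' adapter structure whose inserts are random sequence unrelated to the
#' simulated references, emulating the background of a mock purification.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed (defaults to `config$seed + 2`).
#' @param barcode 4-nt barcode (default `config$barcode`).
#' @return named character vector of reads (possibly empty).
#' @export
simulate_control_library <- function(config, seed = config$seed + 2L,
                                     barcode = config$barcode) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  n <- config$control_tag_count
  if (n == 0L) return(stats::setNames(character(0), character(0)))
  len <- sample(config$tag_length[1]:config$tag_length[2], n, replace = TRUE)
  insert <- vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
  reads <- substr(paste0(barcode, insert, config$adapter),
                  1L, config$read_length)
  stats::setNames(reads, sprintf("ctrl_r%06d", seq_len(n)))
}
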