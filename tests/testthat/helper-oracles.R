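# Independent oracles and small fixture builders shared across test files.
# The oracles deliberately avoid the package's own code paths: the aligner
# oracle is an exhaustive all-offsets/all-strands scan, and the editing
# extent oracle is a dynamic program over T-only indels.

random_seq <- function(n, prob = c(0.3, 0.2, 0.2, 0.3)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Exhaustive ungapped scan of every offset on both strands of every
# reference, applying the same acceptance rule as the aligner contract.
oracle_align <- function(tag, refs, params = alignment_params()) {
  n <- nchar(tag)
  empty <- data.frame(ref = character(), pos = integer(),
                      strand = character(), mismatches = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (n < params$seed_length) return(empty)
  out <- list(empty)
  for (rn in names(refs)) {
    refv <- strsplit(refs[[rn]], "")[[1]]
    L <- length(refv)
    if (L < n) next
    for (st in c("+", "-")) {
      tv <- strsplit(if (st == "+") tag else oracle_revcomp(tag), "")[[1]]
      offs <- 0:(L - n)
      idx <- outer(seq_len(n), offs, `+`)
      mm <- colSums(matrix(refv[idx], nrow = n) != tv)
      score <- params$match_score * (n - mm) - params$mismatch_penalty * mm
      keep <- mm <= params$max_mismatches &
        score >= params$min_score_fraction * n
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          ref = rn, pos = offs[keep], strand = st,
          mismatches = as.integer(mm[keep]), score = score[keep],
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$ref, res$pos, res$strand), , drop = FALSE]
}

# Minimal T-only edit distance by dynamic programming: matches only between
# equal characters, insertions/deletions only of T, substitutions
# forbidden. Returns the per-kind counts of the optimal alignment.
oracle_extent <- function(pre, ed) {
  a <- strsplit(pre, "")[[1]]
  b <- strsplit(ed, "")[[1]]
  n <- length(a); m <- length(b)
  INF <- .Machine$integer.max %/% 4L
  d <- matrix(INF, n + 1L, m + 1L)
  d[1, 1] <- 0L
  for (i in 0:n) {
    for (j in 0:m) {
      cur <- d[i + 1L, j + 1L]
      if (cur >= INF) next
      if (i < n && j < m && a[i + 1L] == b[j + 1L]) {
        d[i + 2L, j + 2L] <- min(d[i + 2L, j + 2L], cur)
      }
      if (i < n && a[i + 1L] == "T") {
        d[i + 2L, j + 1L] <- min(d[i + 2L, j + 1L], cur + 1L)
      }
      if (j < m && b[j + 1L] == "T") {
        d[i + 1L, j + 2L] <- min(d[i + 1L, j + 2L], cur + 1L)
      }
    }
  }
  D <- d[n + 1L, m + 1L]
  if (D >= INF) stop("oracle: sequences are not a T-indel pair")
  list(insertions = (D + (m - n)) %/% 2L, deletions = (D - (m - n)) %/% 2L)
}

# Brute-force adapter trimming: try every cut point, keep the leftmost one
# whose suffix matches an adapter prefix within tolerance.
oracle_trim <- function(read, adapter, min_overlap = 5L, max_mismatch = 1L) {
  L <- nchar(read)
  rv <- strsplit(read, "")[[1]]
  av <- strsplit(adapter, "")[[1]]
  for (p in 0:(L - min_overlap)) {
    ov <- min(L - p, length(av))
    if (ov < min_overlap) break
    mm <- sum(rv[p + seq_len(ov)] != av[seq_len(ov)])
    if (mm <= max_mismatch) return(substr(read, 1L, p))
  }
  read
}

# A tiny hand-laid maxicircle world: 3 transcripts (one per category) on a
# deterministic random genome, with a small explicit event set.
make_toy_world <- function(seed = 7L, genome_length = 3000L) {
  set.seed(seed)
  genome <- random_seq(genome_length)
  ann <- data.frame(
    transcript_id = c("PAN1", "MIN1", "NEV1"),
    start = c(100L, 900L, 1700L),
    end = c(500L, 1300L, 2100L),
    strand = c("+", "-", "+"),
    category = c("pan_edited", "minimally_edited", "never_edited"),
    stringsAsFactors = FALSE)
  pre <- transcript_sequences(genome, ann)
  events <- rbind(
    random_editing_events(pre[["PAN1"]], 60L, transcript_id = "PAN1"),
    random_editing_events(pre[["MIN1"]], 10L, transcript_id = "MIN1"))
  list(genome = genome, annotations = ann, events = events,
       ref_pair = build_reference_pair(genome, ann, events))
}

# Edited-frame location of a transcript's first insertion event: the
# 0-based position of the first inserted T in the fully edited sequence.
# The offset of an anchor a is shifted by the net length change of all
# events at smaller anchors (event anchors sit at non-T bases, so those
# events act entirely 5' of base a).
edited_insertion_site <- function(rp, tx) {
  ev <- rp$events[rp$events$transcript_id == tx, ]
  ins <- ev[ev$kind == "insertion", ]
  ins <- ins[order(ins$anchor), ]
  a <- ins$anchor[ceiling(nrow(ins) / 2)]   # a mid-transcript event
  before <- ev[ev$anchor < a, ]
  shift <- sum(before$n_u[before$kind == "insertion"]) -
    sum(before$n_u[before$kind == "deletion"])
  list(anchor = a, edited_pos = a + 1L + shift,
       n_u = ins$n_u[ins$anchor == a])
}

# Minimal projected-assignment rows for quantification unit tests.
make_proj <- function(transcript_id, frame, tpos, length = 40L,
                      status = ifelse(frame == "preedited", "preedited",
                                      "fully_edited"),
                      flag = "sense") {
  n <- max(lengths(list(transcript_id, frame, tpos)))
  data.frame(tag_id = sprintf("t%04d", seq_len(n)),
             library = rep_len("lib", n), multiplicity = rep_len(1L, n),
             length = rep_len(length, n), status = rep_len(status, n),
             ref = rep_len(NA_character_, n), pos = rep_len(NA_integer_, n),
             strand = rep_len("+", n), score = rep_len(NA_real_, n),
             mismatches = rep_len(NA_integer_, n),
             transcript_id = rep_len(transcript_id, n),
             frame = rep_len(frame, n), tpos = rep_len(tpos, n),
             flag = rep_len(flag, n), stringsAsFactors = FALSE)
}

# Full synthetic run shared by several acceptance checks (computed once).
full_run_cache <- new.env(parent = emptyenv())
default_full_run <- function() {
  if (!is.null(full_run_cache$run)) return(full_run_cache$run)
  cfg <- simulation_config(seed = 42L)
  sim <- simulate_maxicircle(cfg)
  rp <- build_reference_pair(sim$genome, sim$annotations, sim$events)
  pool <- simulate_transcript_pool(cfg, rp)
  lib <- simulate_iclap_library(cfg, pool, "MRB8170")
  run <- preprocess_library(lib$reads, cfg$adapter,
                            c(MRB8170 = cfg$barcode))
  asn <- map_library(run$tags, rp)
  proj <- project_to_transcripts(asn, rp)
  full_run_cache$run <- list(cfg = cfg, sim = sim, ref_pair = rp,
                             pool = pool, lib = lib, pre = run,
                             assignments = asn, proj = proj)
  full_run_cache$run
}
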