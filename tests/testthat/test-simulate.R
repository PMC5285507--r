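# Synthetic-data generator: determinism, the editing cascade, binding
# models and library structure.

test_that("simulation is deterministic under a fixed configuration", {
  cfg <- simulation_config(seed = 5L, n_reads = 2000L)
  a <- simulate_maxicircle(cfg)
  b <- simulate_maxicircle(cfg)
  expect_identical(a, b)
  rp <- build_reference_pair(a$genome, a$annotations, a$events)
  pool <- simulate_transcript_pool(cfg, rp)
  la <- simulate_iclap_library(cfg, pool)
  lb <- simulate_iclap_library(cfg, pool)
  expect_identical(la$reads, lb$reads)
  expect_identical(la$truth, lb$truth)
  expect_identical(simulate_control_library(cfg),
                   simulate_control_library(cfg))
})

test_that("the default maxicircle carries 18 transcripts in the 9/3/6 split", {
  cfg <- simulation_config(seed = 1L)
  sim <- simulate_maxicircle(cfg)
  expect_identical(nrow(sim$annotations), 18L)
  expect_equal(as.integer(table(sim$annotations$category)[
    c("pan_edited", "minimally_edited", "never_edited")]),
    c(9L, 3L, 6L))
  # transcripts lie within the genome and do not overlap
  ann <- sim$annotations[order(sim$annotations$start), ]
  expect_true(all(ann$end <= nchar(sim$genome)))
  expect_true(all(head(ann$end, -1) <= tail(ann$start, -1)))
})

test_that("generated editing events round-trip through the extent counter", {
  cfg <- simulation_config(seed = 3L)
  sim <- simulate_maxicircle(cfg)
  rp <- build_reference_pair(sim$genome, sim$annotations, sim$events)
  ext <- editing_extents(rp)
  for (tx in rp$catalog$transcript_id) {
    ev <- sim$events[sim$events$transcript_id == tx, ]
    e <- ext[ext$transcript_id == tx, ]
    expect_identical(e$insertions, sum(ev$n_u[ev$kind == "insertion"]))
    expect_identical(e$deletions, sum(ev$n_u[ev$kind == "deletion"]))
  }
  # extents sit in the configured category ranges
  pan <- ext$total[match(
    sim$annotations$transcript_id[sim$annotations$category == "pan_edited"],
    ext$transcript_id)]
  expect_true(all(pan >= cfg$pan_extent[1] & pan <= cfg$pan_extent[2]))
})

test_that("the editing cascade is 3'-to-5' in fixed blocks", {
  cfg <- simulation_config(seed = 2L)
  sim <- simulate_maxicircle(cfg)
  rp <- build_reference_pair(sim$genome, sim$annotations, sim$events)
  pool <- simulate_transcript_pool(cfg, rp)
  tx <- rp$catalog$transcript_id[1]
  sub <- pool[pool$transcript_id == tx, ]
  # progress 0 is the preedited molecule, full progress the edited one
  expect_identical(sub$sequence[sub$progress == 0], rp$preedited[[tx]])
  expect_identical(sub$sequence[sub$progress == max(sub$progress)],
                   rp$edited[[tx]])
  # never-edited molecules exist only in the preedited form
  nev <- pool[pool$category == "never_edited", ]
  expect_true(all(nev$progress == 0))
})

test_that("one completed block applies exactly the events in the 3'-most window", {
  # hand-built transcript: events inside and outside the 3'-most 10 nt
  pre <- "AGCAGGACCAGACCAGGAGCCAGACGAC"        # 28 nt, no Ts
  ev <- data.frame(transcript_id = "TX",
                   anchor = c(2L, 20L, 25L),
                   kind = "insertion", n_u = c(2L, 1L, 3L))
  genome <- paste0("ACGAC", pre, "GGACA")
  ann <- data.frame(transcript_id = "TX", start = 5L, end = 33L,
                    strand = "+", category = "pan_edited")
  rp <- build_reference_pair(genome, ann, ev)
  cfg <- simulation_config(seed = 1L, grna_block_length = 10L)
  pool <- simulate_transcript_pool(cfg, rp)
  one <- pool$sequence[pool$transcript_id == "TX" & pool$progress == 1]
  # boundary at 28 - 10 = 18: only anchors 20 and 25 apply
  expected <- build_edited_sequence(pre, ev[ev$anchor >= 18L, ])
  expect_identical(one, expected)
  expect_identical(nchar(one), nchar(pre) + 4L)
})

test_that("tag sampling follows the extent-proportional binding model", {
  cfg <- simulation_config(seed = 9L, n_reads = 4000L,
                           pcr_duplication_rate = 0,
                           sequencing_error_rate = 0)
  sim <- simulate_maxicircle(cfg)
  rp <- build_reference_pair(sim$genome, sim$annotations, sim$events)
  pool <- simulate_transcript_pool(cfg, rp)
  lib <- simulate_iclap_library(cfg, pool)
  ext <- stats::setNames(rp$extents$total, rp$extents$transcript_id)
  counts <- table(lib$truth$transcript_id)
  # compare two transcripts with extents near 1:3 at binomial tolerance
  e <- ext[ext > 0]
  pick <- names(sort(e))[c(2, length(e) - 1)]
  ratio_expected <- e[pick[2]] / e[pick[1]]
  ratio_observed <- counts[pick[2]] / counts[pick[1]]
  expect_lt(abs(log(ratio_observed / ratio_expected)), log(1.5))
  # never-edited transcripts draw no tags under this model
  nev <- sim$annotations$transcript_id[
    sim$annotations$category == "never_edited"]
  expect_false(any(lib$truth$transcript_id %in% nev))
})

test_that("reads are barcode + insert + adapter and inserts match molecules", {
  cfg <- simulation_config(seed = 4L, n_reads = 500L,
                           pcr_duplication_rate = 0,
                           sequencing_error_rate = 0)
  sim <- simulate_maxicircle(cfg)
  rp <- build_reference_pair(sim$genome, sim$annotations, sim$events)
  pool <- simulate_transcript_pool(cfg, rp)
  lib <- simulate_iclap_library(cfg, pool)
  expect_identical(length(lib$reads), 500L)
  expect_identical(nrow(lib$truth), 500L)
  expect_true(all(substr(lib$reads, 1, 4) == cfg$barcode))
  for (i in sample(length(lib$reads), 25)) {
    tr <- lib$truth[i, ]
    insert <- substr(lib$reads[[i]], 5L, 4L + tr$insert_length)
    mol <- pool$sequence[pool$transcript_id == tr$transcript_id &
                           pool$progress == tr$progress]
    expect_identical(insert,
                     substr(mol, tr$mol_start + 1L,
                            tr$mol_start + tr$insert_length))
    # read tail is the adapter (reads are short enough not to truncate it)
    expect_identical(substr(lib$reads[[i]], 5L + tr$insert_length,
                            nchar(lib$reads[[i]])),
                     cfg$adapter)
  }
})

test_that("five_prime_restricted confines truth 5' ends to the 5' third", {
  cfg <- simulation_config(seed = 6L, n_reads = 3000L,
                           binding_model = "five_prime_restricted",
                           editing_progress = "none",
                           pcr_duplication_rate = 0,
                           sequencing_error_rate = 0)
  sim <- simulate_maxicircle(cfg)
  rp <- build_reference_pair(sim$genome, sim$annotations, sim$events)
  pool <- simulate_transcript_pool(cfg, rp)
  lib <- simulate_iclap_library(cfg, pool)
  L <- stats::setNames(nchar(rp$preedited), names(rp$preedited))
  frac <- mean(lib$truth$mol_start < L[lib$truth$transcript_id] / 3)
  expect_gte(frac, 0.95)
})

test_that("PCR duplication and errors behave as configured", {
  cfg <- simulation_config(seed = 8L, n_reads = 2000L,
                           pcr_duplication_rate = 0,
                           sequencing_error_rate = 0)
  sim <- simulate_maxicircle(cfg)
  rp <- build_reference_pair(sim$genome, sim$annotations, sim$events)
  pool <- simulate_transcript_pool(cfg, rp)
  lib <- simulate_iclap_library(cfg, pool)
  # no duplication: every family has size one
  expect_identical(max(table(lib$truth$family)), 1L)
  expect_false(any(lib$truth$has_error))
  cfg2 <- simulation_config(seed = 8L, n_reads = 2000L,
                            pcr_duplication_rate = 0.5,
                            sequencing_error_rate = 0)
  lib2 <- simulate_iclap_library(cfg2, pool)
  expect_identical(length(lib2$reads), 2000L)
  expect_lt(length(unique(lib2$truth$family)), 2000L)
})

test_that("the control library has the configured size and structure", {
  cfg <- simulation_config(seed = 1L)
  ctrl <- simulate_control_library(cfg)
  expect_identical(length(ctrl), 483L)
  expect_true(all(substr(ctrl, 1, 4) == cfg$barcode))
  cfg0 <- simulation_config(seed = 1L, control_tag_count = 0L)
  expect_identical(length(simulate_control_library(cfg0)), 0L)
})

test_that("FASTQ output round-trips through Biostrings", {
  cfg <- simulation_config(seed = 2L, n_reads = 50L,
                           pcr_duplication_rate = 0)
  sim <- simulate_maxicircle(cfg)
  rp <- build_reference_pair(sim$genome, sim$annotations, sim$events)
  pool <- simulate_transcript_pool(cfg, rp)
  lib <- simulate_iclap_library(cfg, pool)
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(lib$reads, f)
  back <- read_fastq(f)
  expect_identical(unname(back), unname(lib$reads))
})
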