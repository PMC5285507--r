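# Binding quantification: counts, shares, densities, coverage, 5'-bias and
# the share-vs-extent correlation.

test_that("per-transcript counts combine frames and partition assigned tags", {
  w <- make_toy_world()
  rp <- w$ref_pair
  empty <- make_proj(character(), character(), integer())
  c0 <- count_per_transcript(empty, rp)
  expect_true(all(c0$n_total == 0L))
  expect_true(all(is.na(c0$share_total)))

  proj <- rbind(make_proj(rep("PAN1", 7), "preedited", 0:6),
                make_proj(rep("PAN1", 3), "fully_edited", 0:2))
  cnt <- count_per_transcript(proj, rp)
  p1 <- cnt[cnt$transcript_id == "PAN1", ]
  expect_identical(p1$n_preedited, 7L)
  expect_identical(p1$n_fully_edited, 3L)
  expect_identical(p1$n_total, 10L)
  expect_equal(p1$share_total, 100)
  # multimapped / antisense / intergenic rows never count
  noisy <- rbind(proj,
                 make_proj("PAN1", "preedited", 0L, status = "multimapped"),
                 make_proj("PAN1", "preedited", 0L, flag = "antisense"))
  expect_identical(count_per_transcript(noisy, rp)$n_total, cnt$n_total)
})

test_that("category shares are percentages that sum to 100", {
  w <- make_toy_world()
  rp <- w$ref_pair
  all_pan <- make_proj(rep("PAN1", 5), "preedited", 1:5)
  cs <- category_shares(count_per_transcript(all_pan, rp))
  expect_equal(cs$share[cs$category == "pan_edited"], 100)
  expect_equal(sum(cs$share), 100)

  mixed <- rbind(make_proj(rep("PAN1", 60), "preedited", 1:60),
                 make_proj(rep("MIN1", 30), "preedited", 1:30),
                 make_proj(rep("NEV1", 10), "preedited", 1:10))
  cs <- category_shares(count_per_transcript(mixed, rp))
  expect_equal(cs$share, c(60, 30, 10))
  expect_equal(sum(cs$share), 100)
})

test_that("region shares exclude never-edited tags from the denominator", {
  w <- make_toy_world()
  rp <- w$ref_pair
  all_pre <- make_proj(rep("PAN1", 4), "preedited", 1:4)
  rs <- region_shares(count_per_transcript(all_pre, rp))
  expect_equal(rs$share, c(100, 0))

  proj <- rbind(make_proj(rep("PAN1", 953), "preedited",
                          rep(1:100, length.out = 953)),
                make_proj(rep("PAN1", 46), "fully_edited",
                          rep(1:46)),
                make_proj("NEV1", "preedited", 1L))
  rs <- region_shares(count_per_transcript(proj, rp))
  expect_equal(rs$n_tags, c(953L, 46L))
  expect_equal(rs$share, 100 * c(953, 46) / 999)
  expect_equal(round(rs$share, 1), c(95.4, 4.6))
  expect_equal(sum(rs$share), 100)
})

test_that("density is tags per kilonucleotide and scales as expected", {
  counts <- data.frame(transcript_id = c("A", "B"),
                       category = "pan_edited",
                       length = c(1000L, 500L),
                       n_preedited = c(100L, 100L),
                       n_fully_edited = 0L)
  counts$n_total <- counts$n_preedited
  counts$share_total <- 50
  d <- length_normalized_density(counts)
  expect_equal(d$density, c(100, 200))   # equal counts, half length -> 2x
  counts2 <- counts
  counts2$n_total <- counts2$n_total * 2L
  expect_equal(length_normalized_density(counts2)$density, 2 * d$density)
})

test_that("coverage tracks pile up tag intervals and conserve mass", {
  w <- make_toy_world()
  rp <- w$ref_pair
  L <- nchar(rp$preedited[["PAN1"]])
  one <- make_proj("PAN1", "preedited", 0L, length = 40L)
  tr <- coverage_track(one, rp)[["PAN1:preedited"]]
  expect_identical(length(tr), L)
  expect_true(all(tr[1:40] == 1L))
  expect_true(all(tr[41:L] == 0L))

  two <- rbind(one, one)
  tr2 <- coverage_track(two, rp)[["PAN1:preedited"]]
  expect_true(all(tr2[1:40] == 2L))
  # mass conservation over a scattered set
  set.seed(61)
  n <- 30L
  starts <- sample(0:(L - 40L), n, replace = TRUE)
  many <- make_proj(rep("PAN1", n), "preedited", starts, length = 40L)
  trm <- coverage_track(many, rp)[["PAN1:preedited"]]
  expect_identical(sum(trm), n * 40L)
})

test_that("bedGraph output reproduces the track as 0-based intervals", {
  w <- make_toy_world()
  rp <- w$ref_pair
  proj <- make_proj("PAN1", "preedited", 10L, length = 25L)
  tracks <- coverage_track(proj, rp)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tracks, f)
  lines <- readLines(f)
  body <- strsplit(grep("PAN1:preedited", lines, value = TRUE), "\t")[[1]]
  expect_identical(as.integer(body[2:3]), c(10L, 35L))
  expect_identical(as.integer(body[4]), 1L)
})

test_that("five_prime_bias reflects where tag 5' ends fall", {
  w <- make_toy_world()
  rp <- w$ref_pair
  L <- nchar(rp$preedited[["PAN1"]])
  at_zero <- make_proj(rep("PAN1", 20), "preedited", rep(0L, 20))
  expect_equal(five_prime_bias(at_zero, rp), 1.0)
  tail3 <- make_proj(rep("PAN1", 20), "preedited",
                     round(seq(2 * L / 3, L - 40)))
  expect_equal(five_prime_bias(tail3, rp), 0.0)
  expect_true(is.na(five_prime_bias(make_proj(character(), character(),
                                              integer()), rp)))
})

test_that("the correlation matches the closed-form Pearson coefficient", {
  w <- make_toy_world()
  rp <- w$ref_pair
  # perfect proportionality gives r = 1
  counts <- data.frame(transcript_id = c("P1", "P2", "P3", "P4"),
                       category = "pan_edited", length = 500L,
                       n_preedited = c(10L, 20L, 30L, 40L),
                       n_fully_edited = 0L)
  counts$n_total <- counts$n_preedited
  counts$share_total <- 100 * counts$n_total / sum(counts$n_total)
  extents <- data.frame(transcript_id = counts$transcript_id,
                        insertions = c(50L, 100L, 150L, 200L),
                        deletions = 0L)
  extents$total <- extents$insertions
  res <- correlate_with_editing_extent(counts, extents)
  expect_equal(res$r, 1.0)
  expect_identical(res$n, 4L)

  # hand-computed product-moment coefficient for x=(1,2,3,4), y=(1,3,2,5)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 5)
  counts$share_total <- y
  extents$total <- x
  res <- correlate_with_editing_extent(counts, extents)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand)
  expect_equal(round(res$r, 2), 0.83)

  # zero variance is NA with a warning
  extents$total <- rep(7L, 4)
  expect_warning(res0 <- correlate_with_editing_extent(counts, extents),
                 "zero variance")
  expect_true(is.na(res0$r))
  expect_error(correlate_with_editing_extent(counts[1:2, ], extents),
               ">= 3 transcripts")
})

test_that("binding_summary assembles a coherent report", {
  run <- default_full_run()
  bs <- binding_summary(run$proj, run$ref_pair)
  expect_equal(sum(bs$category_shares$share), 100, tolerance = 1e-9)
  expect_equal(sum(bs$region_shares$share), 100, tolerance = 1e-9)
  expect_true(all(bs$counts$density >= 0))
  expect_identical(sum(bs$counts$n_total),
                   sum(run$proj$status %in% c("preedited", "fully_edited") &
                         run$proj$flag == "sense"))
  d <- withr::local_tempdir()
  paths <- write_binding_summary(bs, d)
  expect_true(all(file.exists(paths)))
})
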