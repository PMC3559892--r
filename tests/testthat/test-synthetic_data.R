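test_that("planted satellite arrays follow their consensus grammars", {
  cfg <- tiny_cfg(seed = 11L)
  gb <- build_genome(cfg)
  expect_gt(nrow(gb$repeats), 0)
  sat2 <- "^(ATTCCATTCGATTCCATTCG(ATG){1,2})+$"
  sat3 <- "^((ATTCC){7,13}ATTCGGGTTG)+$"
  for (i in seq_len(nrow(gb$repeats))) {
    arr <- extract_sequence(gb$genome, gb$repeats$chrom[i],
                            gb$repeats$start[i], gb$repeats$end[i])
    pattern <- if (gb$repeats$rep_name[i] == "HSATII") sat2 else sat3
    expect_match(arr, pattern)
    if (gb$repeats$rep_name[i] == "HSATII") {
      # two TCCATT occurrences per ~23 bp consensus unit
      n_units <- lengths(regmatches(arr, gregexpr("ATTCCATTCGATTCCATTCG",
                                                  arr, fixed = TRUE)))
      n_tccatt <- lengths(regmatches(arr, gregexpr("TCCATT", arr,
                                                   fixed = TRUE)))
      expect_gte(n_tccatt, 2 * n_units)
    }
  }
})

test_that("truth table places 147 bp positives in satellites, negatives outside", {
  gb <- build_genome(tiny_cfg(seed = 12L))
  expect_true(all(gb$truth$end - gb$truth$start == 147L))
  pos <- gb$truth[gb$truth$class == "positive", ]
  neg <- gb$truth[gb$truth$class == "negative", ]
  inside <- function(nuc) {
    any(gb$repeats$chrom == nuc["chrom"] &
          as.integer(nuc["start"]) >= gb$repeats$start &
          as.integer(nuc["end"]) <= gb$repeats$end)
  }
  expect_true(all(apply(pos[, c("chrom", "start", "end")], 1, inside)))
  expect_false(any(apply(neg[, c("chrom", "start", "end")], 1, inside)))
})

test_that("generator output is byte-identical under a fixed seed", {
  cfg <- tiny_cfg(seed = 3L)
  a <- build_genome(cfg); b <- build_genome(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)
  ra <- simulate_reads(cfg, a$truth, "positive")
  rb <- simulate_reads(cfg, b$truth, "positive")
  expect_identical(ra, rb)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_bed(ra, f1); write_bed(rb, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("signal reads flank nucleosome edges with near-equal strand counts", {
  cfg <- synth_config(genome_length = 10000L, sat2_arrays = 0L,
                      sat3_arrays = 0L, n_pos_nucs = 0L, n_neg_nucs = 0L,
                      background_rate = 0, dup_rate = 0,
                      reads_per_nuc = 200, start_jitter_sd = 4, seed = 5L)
  truth <- data.frame(chrom = "chr1", start = 4000L, end = 4147L,
                      class = "positive", family = NA_character_,
                      stringsAsFactors = FALSE)
  r <- simulate_reads(cfg, truth, "positive")
  plus <- r[r$strand == "+", ]
  minus <- r[r$strand == "-", ]
  expect_true(all(abs(plus$start - 3999L) <= 4 * 4))
  expect_true(all(abs((minus$end - 1L) - 4147L) <= 4 * 4))
  expect_lt(abs(nrow(plus) - nrow(minus)) / nrow(r), 0.2)
})

test_that("duplicate fraction matches the closed-form expectation", {
  # p/(1+p) of emitted lines are duplicates when input reads are unique;
  # background-only reads on a long genome are unique with high probability
  cfg <- synth_config(genome_length = 1000000L, sat2_arrays = 0L,
                      sat3_arrays = 0L, n_pos_nucs = 0L, n_neg_nucs = 0L,
                      background_rate = 3e-3, dup_rate = 0.2, seed = 8L)
  truth <- build_genome(cfg)$truth
  r <- simulate_reads(cfg, truth, "positive")
  frac <- dedup_reads(r)$stats$duplicate_fraction
  expected <- 0.2 / 1.2
  se <- sqrt(expected * (1 - expected) / nrow(r))
  expect_lt(abs(frac - expected), 4 * se + 0.005)
})

test_that("unmapped feature channels are uniform over the genome", {
  cfg <- synth_config(genome_length = 200000L, sat2_arrays = 2L,
                      sat3_arrays = 0L, sat2_units = c(30L, 40L),
                      n_pos_nucs = 2L, n_neg_nucs = 2L,
                      background_rate = 5e-3, dup_rate = 0, seed = 9L)
  gb <- build_genome(cfg)
  ch <- simulate_feature_channels(cfg, gb$truth, channels = c("X1", "X2"),
                                  coloc_map = list(
                                    X1 = list(class = "positive",
                                              intensity = 50)))
  unmapped <- ch$X2
  bins <- cut(unmapped$start, breaks = seq(0, cfg$genome_length, length.out = 21))
  gof <- suppressWarnings(stats::chisq.test(table(bins)))
  expect_gt(gof$p.value, 0.01)
  # mapped channel concentrates at positive nucleosomes
  pos <- gb$truth[gb$truth$class == "positive", ]
  near_pos <- vapply(seq_len(nrow(ch$X1)), function(i) {
    any(ch$X1$start[i] >= pos$start - 200 & ch$X1$start[i] <= pos$end + 200)
  }, logical(1))
  window_frac <- nrow(pos) * (147 + 425) / cfg$genome_length
  expect_gt(mean(near_pos), 5 * window_frac)
})

test_that("requesting 37 channels yields 37 read sets", {
  cfg <- tiny_cfg(seed = 2L, background_rate = 1e-4)
  gb <- build_genome(cfg)
  ch <- simulate_feature_channels(cfg, gb$truth)
  expect_length(ch, 37L)
  expect_named(ch, default_feature_channels())
  expect_error(
    simulate_feature_channels(cfg, gb$truth, channels = c("A", "B"),
                              coloc_map = list(A = list(class = "bogus",
                                                        intensity = 1))),
    "unknown class")
})
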