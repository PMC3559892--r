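test_that("motif occurrence histogram counts overlapping forward matches", {
  h <- motif_occurrence_histogram(c("TCCATT", "AAAAAA"), "TCCATT")
  expect_equal(h$histogram,
               data.frame(count = c(0L, 1L), n_sequences = c(1L, 1L)))
  expect_equal(h$fraction_present, 0.5)

  h2 <- motif_occurrence_histogram("TCCATTCCATT", "TCCATT")
  expect_equal(h2$counts, 2L)
  # overlapping occurrences each count
  h3 <- motif_occurrence_histogram("AAAA", "AA")
  expect_equal(h3$counts, 3L)
  expect_error(motif_occurrence_histogram("ACGT", ""), "empty motif")
})

test_that("satellite-derived nucleosome sequences are TCCATT-rich", {
  cfg <- tiny_cfg(seed = 61L)
  gb <- build_genome(cfg)
  sat2 <- gb$truth[gb$truth$class == "positive" &
                     gb$truth$family == "HSATII", ]
  seqs <- vapply(seq_len(nrow(sat2)), function(i) {
    extract_sequence(gb$genome, sat2$chrom[i], sat2$start[i], sat2$end[i])
  }, character(1))
  h <- motif_occurrence_histogram(seqs, "TCCATT")
  expect_equal(h$fraction_present, 1)
  expect_true(all(h$counts >= 10))  # two per ~23-26 bp unit over 147 bp
})

test_that("repeat composition matches a per-bp oracle and handles extremes", {
  peak <- function(start) data.frame(chrom = "chr1", start = start,
                                     end = start + 147L,
                                     stringsAsFactors = FALSE)
  annot <- data.frame(chrom = "chr1", start = 500L, end = 1000L,
                      rep_name = "HSATII", rep_class = "Satellite",
                      stringsAsFactors = FALSE)
  # fully inside
  comp <- repeat_composition(list(m = peak(600L)), annot,
                             families = list("satellite II" = "HSATII"))
  expect_equal(comp$`satellite II`, 1.0)
  expect_equal(comp$residual, 0)
  # no overlap
  comp0 <- repeat_composition(list(m = peak(2000L)), annot,
                              families = list("satellite II" = "HSATII"))
  expect_equal(comp0$`satellite II`, 0)
  expect_equal(comp0$residual, 1)
  # partial overlap, against brute-force bp counting
  p <- peak(930L)
  comp_h <- repeat_composition(list(m = p), annot,
                               families = list("satellite II" = "HSATII"))
  expect_equal(comp_h$`satellite II`, oracle_composition(p, annot, 3000L))
  expect_equal(comp_h$`satellite II`, 70 / 147)
  expect_error(
    repeat_composition(list(m = p), rbind(annot,
      data.frame(chrom = "chr1", start = 900L, end = 1100L,
                 rep_name = "(CATTC)n", rep_class = "Satellite")),
      families = list(a = "HSATII", b = "(CATTC)n")),
    "overlap")
})

test_that("composition agrees with the oracle on randomized layouts", {
  set.seed(19)
  for (rep in 1:8) {
    n_pk <- sample(1:6, 1)
    peaks <- data.frame(chrom = "chr1",
                        start = s <- sample.int(2500, n_pk),
                        end = s + 147L, stringsAsFactors = FALSE)
    n_an <- sample(1:4, 1)
    annot <- data.frame(chrom = "chr1",
                        start = a <- sample.int(2500, n_an),
                        end = a + sample(50:400, n_an, replace = TRUE),
                        rep_name = "HSATII", rep_class = "Satellite",
                        stringsAsFactors = FALSE)
    comp <- repeat_composition(list(m = peaks), annot,
                               families = list(f = "HSATII"))
    expect_equal(comp$f, oracle_composition(peaks, annot, 4000L))
  }
})

test_that("occupancy profiles match per-bp membership and shrink denominators", {
  inst <- data.frame(chrom = "chr1", start = c(100L, 1100L),
                     end = c(400L, 1300L), stringsAsFactors = FALSE)
  no_peaks <- data.frame(chrom = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
  prof0 <- occupancy_profile(no_peaks, inst)
  expect_true(all(prof0$occupancy == 0))
  expect_equal(prof0$summary, 0)

  cover_all <- data.frame(chrom = "chr1", start = c(50L, 1050L),
                          end = c(450L, 1350L), stringsAsFactors = FALSE)
  prof1 <- occupancy_profile(cover_all, inst)
  expect_true(all(prof1$occupancy == 1))
  expect_equal(prof1$summary, 1)

  one <- data.frame(chrom = "chr1", start = 100L, end = 247L,
                    stringsAsFactors = FALSE)
  prof2 <- occupancy_profile(one, inst)
  expect_equal(prof2$occupancy[11], 0.5)  # offset 10: covered in one of two
  expect_equal(prof2$occupancy, oracle_occupancy(one, inst, 2000L))
  # denominators shrink monotonically with offset
  expect_true(all(diff(prof2$n_at_position) <= 0))
  expect_true(all(prof2$occupancy >= 0 & prof2$occupancy <= 1))
  expect_error(occupancy_profile(one, inst[0, ]), "empty")
})

test_that("occupancy agrees with the oracle on randomized layouts", {
  set.seed(23)
  for (rep in 1:8) {
    n_in <- sample(2:6, 1)
    inst <- data.frame(chrom = "chr1",
                       start = s <- sort(sample(seq(0, 3000, 400), n_in)),
                       end = s + sample(100:350, n_in, replace = TRUE),
                       stringsAsFactors = FALSE)
    n_pk <- sample(1:5, 1)
    peaks <- data.frame(chrom = "chr1",
                        start = p <- sample.int(3200, n_pk),
                        end = p + 147L, stringsAsFactors = FALSE)
    prof <- occupancy_profile(peaks, inst)
    expect_equal(prof$occupancy, oracle_occupancy(peaks, inst, 4000L))
  }
})
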