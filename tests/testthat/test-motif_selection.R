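test_that("stratified partition allocates fraction f per class, seeded", {
  seqs <- list(positive = stats::setNames(random_dna(100, 50, seed = 1),
                                          paste0("p", 1:100)),
               negative = stats::setNames(random_dna(100, 50),
                                          paste0("n", 1:100)))
  part <- partition_sequences(seqs, f = 0.2, seed = 3L)
  expect_length(part$discovery$positive, 20L)
  expect_length(part$discovery$negative, 20L)
  expect_length(part$classification$positive, 80L)
  expect_length(part$classification$negative, 80L)
  expect_length(intersect(names(part$discovery$positive),
                          names(part$classification$positive)), 0L)
  part2 <- partition_sequences(seqs, f = 0.2, seed = 3L)
  expect_identical(part, part2)

  tiny <- list(positive = c(a = "ACGTAC", b = "GGCCTT"),
               negative = c(c = "TTAAGG", d = "CCGGAA"))
  p5 <- partition_sequences(tiny, f = 0.5, seed = 1L)
  expect_length(p5$discovery$positive, 1L)
  expect_length(p5$classification$positive, 1L)
  expect_error(partition_sequences(list(positive = c(a = "ACGT"),
                                        negative = tiny$negative), 0.2),
               "fewer than 2")
})

test_that("presence z-statistic equals the two-proportion formula", {
  # plant a 10-mer in 18/20 positive and 2/20 negative homopolymer contexts
  planted <- "GGATCCGGAA"
  mk <- function(with) {
    if (with) paste0(strrep("T", 20), planted, strrep("T", 20))
    else strrep("T", 50)
  }
  disc <- list(
    positive = stats::setNames(vapply(1:20, function(i) mk(i <= 18),
                                      character(1)), paste0("p", 1:20)),
    negative = stats::setNames(vapply(1:20, function(i) mk(i <= 2),
                                      character(1)), paste0("n", 1:20)))
  mot <- elicit_motifs(disc)
  p1 <- 18 / 20; p2 <- 2 / 20; pbar <- 0.5
  z_expected <- (p1 - p2) / sqrt(pbar * (1 - pbar) * (1 / 20 + 1 / 20))
  expect_equal(max(abs(mot$z)), z_expected, tolerance = 1e-12)
  top <- mot[which.max(abs(mot$z)), ]
  expect_equal(top$direction, "positive")
})

test_that("identical class multisets elicit nothing", {
  same <- stats::setNames(random_dna(6, 60, seed = 5), paste0("s", 1:6))
  disc <- list(positive = stats::setNames(same, paste0("p", 1:6)),
               negative = stats::setNames(same, paste0("n", 1:6)))
  expect_equal(nrow(elicit_motifs(disc)), 0L)
})

test_that("elicited motifs respect length and count bounds", {
  cfg <- tiny_cfg(seed = 51L)
  gb <- build_genome(cfg)
  pos_seq <- vapply(which(gb$truth$class == "positive"), function(i) {
    extract_sequence(gb$genome, gb$truth$chrom[i], gb$truth$start[i],
                     gb$truth$end[i])
  }, character(1))
  disc <- list(
    positive = stats::setNames(pos_seq, paste0("p", seq_along(pos_seq))),
    negative = stats::setNames(random_dna(8, 147), paste0("n", 1:8)))
  mot <- elicit_motifs(disc, max_motifs = 50)
  expect_lte(nrow(mot), 50L)
  expect_true(all(mot$length >= 5L & mot$length <= 10L))
  expect_true(all(grepl("^[ACGT]+$", mot$motif)))
  expect_true(all(abs(mot$z) > 0))
  # satellite-derived positives put a TCCATT-bearing motif on top
  expect_match(mot$motif[1], "TCCATT|AATGGA")
})

test_that("match_count handles exact, mismatched and reverse-complement windows", {
  expect_equal(match_count("TCCATT", "TCCATT", 0L), 1L)
  # rc window AATGGA is Hamming 5 from TCCATT, beyond M = 2
  expect_equal(match_count("TCCATT", "TCCATT", 2L), 1L)
  expect_equal(match_count("ACGT", "ACGTACGT", 2L), 0L)
  expect_error(match_count("ACGT", "", 0L), "empty motif")
})

test_that("match_count equals the exhaustive scan oracle on random triples", {
  set.seed(77)
  for (i in 1:60) {
    s <- random_dna(1, sample(20:60, 1))
    m <- random_dna(1, sample(5:8, 1))
    M <- sample(0:3, 1)
    expect_equal(match_count(s, m, M), oracle_match_count(s, m, M))
  }
})

test_that("match_count is reverse-complement symmetric in the sequence", {
  set.seed(78)
  for (i in 1:25) {
    s <- random_dna(1, 40)
    m <- random_dna(1, 6)
    expect_equal(match_count(s, m, 2L), match_count(rev_comp(s), m, 2L))
  }
})

test_that("motif matrix is built on the withheld partition only", {
  target <- strrep("TCCATTCGATG", 3)
  seqs <- list(
    positive = stats::setNames(
      paste0(random_dna(10, 30, seed = 9), target, random_dna(10, 30)),
      paste0("p", 1:10)),
    negative = stats::setNames(random_dna(10, 93), paste0("n", 1:10)))
  part <- partition_sequences(seqs, f = 0.5, seed = 2L)
  mot <- elicit_motifs(part$discovery, max_motifs = 20)
  disc_ids <- c(names(part$discovery$positive),
                names(part$discovery$negative))
  m <- build_motif_matrix(part$classification, mot, discovery_ids = disc_ids)
  expect_equal(nrow(m), 10L)
  expect_false(any(m$id %in% disc_ids))
  planted <- mot$motif[mot$direction == "positive" &
                         vapply(mot$motif, function(x)
                           grepl(x, target, fixed = TRUE) ||
                             grepl(rev_comp(x), target, fixed = TRUE),
                           logical(1))]
  expect_gt(length(planted), 0L)
  planted_col <- planted[1]
  expect_gt(mean(m[[planted_col]][m$label == "positive"]),
            mean(m[[planted_col]][m$label == "negative"]))
  expect_error(build_motif_matrix(part$discovery, mot,
                                  discovery_ids = disc_ids),
               "reusage")
  m0 <- build_motif_matrix(part$classification, mot[0, ],
                           discovery_ids = disc_ids)
  expect_equal(ncol(m0), 2L)
})
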