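# Independent reference implementations used to check the package against.
# These are deliberately naive (loops, series sums, per-bp membership) and
# share no code with the implementation paths they verify.

# upper-tail Poisson probability by direct series summation in log space
oracle_poisson_tail <- function(k, lambda, terms = 2000L) {
  i <- seq(k, k + terms)
  sum(exp(i * log(lambda) - lambda - lgamma(i + 1)))
}

# naive mismatch-tolerant window scan over both strands
oracle_match_count <- function(sequence, motif, max_mismatch) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- paste(rev(comp[strsplit(sequence, "")[[1]]]), collapse = "")
  k <- nchar(motif)
  scan <- function(s) {
    n <- nchar(s)
    if (k > n) return(0L)
    total <- 0L
    for (i in 1:(n - k + 1L)) {
      mism <- sum(strsplit(substr(s, i, i + k - 1L), "")[[1]] !=
                    strsplit(motif, "")[[1]])
      if (mism <= max_mismatch) total <- total + 1L
    }
    total
  }
  scan(sequence) + scan(rc)
}

# per-bp membership composition: fraction of peak-covered bp (union)
# that falls inside family annotation bp (union), one chromosome
oracle_composition <- function(peaks, annots, chrom_len) {
  in_peak <- logical(chrom_len)
  for (i in seq_len(nrow(peaks))) {
    in_peak[(peaks$start[i] + 1L):peaks$end[i]] <- TRUE
  }
  in_fam <- logical(chrom_len)
  if (nrow(annots) > 0) {
    for (i in seq_len(nrow(annots))) {
      in_fam[(annots$start[i] + 1L):annots$end[i]] <- TRUE
    }
  }
  sum(in_peak & in_fam) / sum(in_peak)
}

# per-bp occupancy at each offset of start-aligned instances
oracle_occupancy <- function(peaks, instances, chrom_len) {
  in_peak <- logical(chrom_len)
  for (i in seq_len(nrow(peaks))) {
    in_peak[(peaks$start[i] + 1L):peaks$end[i]] <- TRUE
  }
  lens <- instances$end - instances$start
  L <- max(lens)
  occ <- numeric(L)
  for (pos in seq_len(L)) {
    reach <- which(lens >= pos)
    hit <- vapply(reach, function(j) {
      in_peak[instances$start[j] + pos]
    }, logical(1))
    occ[pos] <- sum(hit) / length(reach)
  }
  occ
}

# compact generator settings for fast unit tests
tiny_cfg <- function(...) {
  synth_config(genome_length = 60000L, sat2_arrays = 4L,
               sat2_units = c(30L, 40L), sat3_arrays = 2L,
               sat3_units = c(8L, 12L), n_pos_nucs = 8L, n_neg_nucs = 8L,
               ...)
}

# balanced two-class matrix of pure-noise count features
null_matrix <- function(n_rows = 100L, features = default_feature_channels(),
                        seed = 1L) {
  set.seed(seed)
  m <- data.frame(
    id = paste0("s", seq_len(n_rows)),
    label = factor(rep(c("positive", "negative"), length.out = n_rows),
                   levels = c("positive", "negative")),
    stringsAsFactors = FALSE)
  for (f in features) m[[f]] <- stats::rpois(n_rows, 2)
  m
}

random_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
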