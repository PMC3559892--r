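# Synthetic ChIP-Seq generator. Emulates the statistical structure the
# analysis assumes: strand-structured 25 bp read pileups flanking planted
# 147 bp nucleosomes, uniform background, PCR duplicates at a configurable
# rate, per-sample depth variation, satellite II/III consensus arrays, and
# co-localization between an outcome mark and chosen feature channels.

NUC_WIDTH <- 147L

#' Configuration for the synthetic data generator
#'
#' Defaults describe the simulated study conditions used throughout the
#' package tests: a 300 kb single-chromosome genome carrying satellite II
#' (`HSATII`) and satellite III (`(CATTC)n`) arrays, 50 stable nucleosomes
#' per class, ~40 signal reads per nucleosome with 5 bp positional jitter,
#' a low uniform background, and a 6% per-read duplication probability
#' (matching a duplicate fraction in the mid single digits).
#'
#' @param genome_length Chromosome length in bp.
#' @param n_chroms Number of chromosomes.
#' @param sat2_arrays,sat3_arrays Number of planted satellite II / III arrays.
#' @param sat2_units,sat3_units Range (length-2 integer) of consensus units
#'   per array.
#' @param n_pos_nucs,n_neg_nucs Planted stable nucleosomes per class.
#'   Positives are placed inside satellite arrays, negatives in background.
#' @param reads_per_nuc Mean signal reads per planted nucleosome (split
#'   evenly between strands).
#' @param background_rate Background reads per bp.
#' @param dup_rate Probability that an emitted read is duplicated once.
#' @param start_jitter_sd SD (bp) of read 5'-end positions around the
#'   nucleosome edges.
#' @param read_length Read length in bp.
#' @param nuc_spacing Minimum distance between planted nucleosome starts.
#' @param depth_multipliers Length-2 numeric: relative background/total depth
#'   of the positive- and negative-mark samples (default spans 3-fold).
#' @param coloc_map Named list mapping feature channel names to
#'   `list(class =, intensity =)`; see [simulate_feature_channels()].
#' @param seed Integer seed fixing all generator output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(genome_length = 300000L, n_chroms = 1L,
                         sat2_arrays = 14L, sat2_units = c(50L, 70L),
                         sat3_arrays = 5L, sat3_units = c(14L, 22L),
                         n_pos_nucs = 50L, n_neg_nucs = 50L,
                         reads_per_nuc = 40, background_rate = 5e-4,
                         dup_rate = 0.06, start_jitter_sd = 5,
                         read_length = 25L, nuc_spacing = 300L,
                         depth_multipliers = c(1, 3),
                         coloc_map = NULL, seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_chroms = as.integer(n_chroms),
              sat2_arrays = as.integer(sat2_arrays),
              sat2_units = as.integer(sat2_units),
              sat3_arrays = as.integer(sat3_arrays),
              sat3_units = as.integer(sat3_units),
              n_pos_nucs = as.integer(n_pos_nucs),
              n_neg_nucs = as.integer(n_neg_nucs),
              reads_per_nuc = reads_per_nuc,
              background_rate = background_rate,
              dup_rate = dup_rate,
              start_jitter_sd = start_jitter_sd,
              read_length = as.integer(read_length),
              nuc_spacing = as.integer(nuc_spacing),
              depth_multipliers = depth_multipliers,
              coloc_map = coloc_map,
              seed = as.integer(seed))
  stopifnot(cfg$genome_length > 0, cfg$n_chroms >= 1,
            cfg$sat2_arrays >= 0, cfg$sat3_arrays >= 0,
            cfg$n_pos_nucs >= 0, cfg$n_neg_nucs >= 0,
            cfg$reads_per_nuc >= 0, cfg$background_rate >= 0,
            cfg$dup_rate >= 0, cfg$dup_rate <= 1,
            cfg$start_jitter_sd >= 0, cfg$read_length > 0)
  class(cfg) <- "synth_config"
  cfg
}

# derive a reproducible sub-seed for one generator stage
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% (2^31 - 1))
}

# one satellite II consensus unit: two copies of ATTCCATTCG then 1-2 ATG
sat2_unit <- function() {
  paste0(strrep("ATTCCATTCG", 2L), strrep("ATG", sample(1:2, 1L)))
}

# one satellite III consensus unit: 7-13 copies of ATTCC then one ATTCGGGTTG
sat3_unit <- function() {
  paste0(strrep("ATTCC", sample(7:13, 1L)), "ATTCGGGTTG")
}

sat_array <- function(n_units, unit_fun) {
  paste(vapply(seq_len(n_units), function(i) unit_fun(), character(1)),
        collapse = "")
}

#' Build a synthetic genome with satellite arrays and planted nucleosomes
#'
#' The background is i.i.d. uniform ACGT. Satellite II arrays concatenate
#' units of two `ATTCCATTCG` copies followed by 1-2 `ATG` copies; satellite
#' III arrays concatenate units of 7-13 `ATTCC` copies followed by one
#' `ATTCGGGTTG`. Annotations exactly cover the planted arrays
#' (`rep_name` `HSATII` or `(CATTC)n`). Positive-class nucleosomes are
#' placed inside satellite arrays, negative-class nucleosomes in background.
#'
#' @param cfg A [synth_config()].
#' @return List with `genome` (named character), `repeats`
#'   (annotation data frame), `truth` (planted nucleosome data frame with
#'   columns `chrom`, `start`, `end`, `class`, `family`) and `config`.
#' @export
build_genome <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(derive_seed(cfg$seed, 1L))
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  genome <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), cfg$genome_length, replace = TRUE),
          collapse = "")
  }, character(1))

  # array sequences, then sequential non-overlapping placement
  arrays <- list()
  if (cfg$sat2_arrays > 0) {
    for (i in seq_len(cfg$sat2_arrays)) {
      n_units <- sample(cfg$sat2_units[1]:cfg$sat2_units[2], 1L)
      arrays[[length(arrays) + 1L]] <-
        list(seq = sat_array(n_units, sat2_unit), rep_name = "HSATII")
    }
  }
  if (cfg$sat3_arrays > 0) {
    for (i in seq_len(cfg$sat3_arrays)) {
      n_units <- sample(cfg$sat3_units[1]:cfg$sat3_units[2], 1L)
      arrays[[length(arrays) + 1L]] <-
        list(seq = sat_array(n_units, sat3_unit), rep_name = "(CATTC)n")
    }
  }

  margin <- 400L
  occupied <- lapply(chroms, function(ch) {
    data.frame(start = integer(), end = integer())
  })
  names(occupied) <- chroms
  repeats <- list()
  for (a in arrays) {
    alen <- nchar(a$seq)
    placed <- FALSE
    for (try in seq_len(2000L)) {
      ch <- sample(chroms, 1L)
      if (cfg$genome_length - alen - 2L * margin <= 0) break
      s <- sample.int(cfg$genome_length - alen - 2L * margin, 1L) + margin
      occ <- occupied[[ch]]
      if (nrow(occ) == 0L ||
          all(s + alen + margin <= occ$start | s >= occ$end + margin)) {
        substr(genome[[ch]], s + 1L, s + alen) <- a$seq
        occupied[[ch]] <- rbind(occ, data.frame(start = s, end = s + alen))
        repeats[[length(repeats) + 1L]] <-
          data.frame(chrom = ch, start = s, end = s + alen,
                     rep_name = a$rep_name, rep_class = "Satellite",
                     stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place satellite arrays: genome too small")
  }
  repeats <- if (length(repeats)) do.call(rbind, repeats) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               rep_name = character(), rep_class = character(),
               stringsAsFactors = FALSE)

  # positive nucleosomes: evenly spaced slots inside arrays
  slots <- list()
  if (nrow(repeats) > 0L) {
    for (i in seq_len(nrow(repeats))) {
      alen <- repeats$end[i] - repeats$start[i]
      if (alen < NUC_WIDTH) next
      k <- (alen - NUC_WIDTH) %/% cfg$nuc_spacing + 1L
      pad <- (alen - (NUC_WIDTH + (k - 1L) * cfg$nuc_spacing)) %/% 2L
      for (j in seq_len(k)) {
        slots[[length(slots) + 1L]] <-
          data.frame(chrom = repeats$chrom[i],
                     start = repeats$start[i] + pad + (j - 1L) * cfg$nuc_spacing,
                     family = repeats$rep_name[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (cfg$n_pos_nucs > 0) {
    if (length(slots) < cfg$n_pos_nucs) {
      stop("not enough satellite array space for requested positive nucleosomes")
    }
    slots <- do.call(rbind, slots)
    pick <- sort(sample.int(nrow(slots), cfg$n_pos_nucs))
    pos <- slots[pick, , drop = FALSE]
    pos_truth <- data.frame(chrom = pos$chrom, start = pos$start,
                            end = pos$start + NUC_WIDTH, class = "positive",
                            family = pos$family, stringsAsFactors = FALSE)
  } else {
    pos_truth <- NULL
  }

  # negative nucleosomes: background placements away from arrays
  neg_truth <- NULL
  if (cfg$n_neg_nucs > 0) {
    placed <- data.frame(chrom = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
    for (i in seq_len(cfg$n_neg_nucs)) {
      ok <- FALSE
      for (try in seq_len(5000L)) {
        ch <- sample(chroms, 1L)
        s <- sample.int(cfg$genome_length - NUC_WIDTH - 2L * margin, 1L) + margin
        occ <- occupied[[ch]]
        clear_arrays <- nrow(occ) == 0L ||
          all(s + NUC_WIDTH + margin <= occ$start | s >= occ$end + margin)
        prev <- placed[placed$chrom == ch, , drop = FALSE]
        clear_nucs <- nrow(prev) == 0L ||
          all(abs(prev$start - s) >= cfg$nuc_spacing)
        if (clear_arrays && clear_nucs) {
          placed <- rbind(placed,
                          data.frame(chrom = ch, start = s,
                                     end = s + NUC_WIDTH,
                                     stringsAsFactors = FALSE))
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place negative nucleosomes: genome too crowded")
    }
    neg_truth <- data.frame(chrom = placed$chrom, start = placed$start,
                            end = placed$end, class = "negative",
                            family = NA_character_, stringsAsFactors = FALSE)
  }

  truth <- rbind(pos_truth, neg_truth)
  if (is.null(truth)) {
    truth <- data.frame(chrom = character(), start = integer(),
                        end = integer(), class = character(),
                        family = character(), stringsAsFactors = FALSE)
  }
  truth <- truth[order(truth$class, truth$chrom, truth$start), ,
                 drop = FALSE]
  rownames(truth) <- NULL
  list(genome = genome, repeats = repeats, truth = truth, config = cfg)
}

# Emit signal + background reads using the current RNG stream.
# Plus-strand 5' ends are drawn around (nucleosome start - 1), minus-strand
# 5' ends around the last nucleosome base + 1, so that 3' extension to
# 150 bp stacks reads over the nucleosome from both sides.
emit_reads <- function(cfg, nucs, reads_per_nuc, depth_multiplier) {
  rl <- cfg$read_length
  chrom <- character(0); start <- integer(0); strand <- character(0)
  if (nrow(nucs) > 0 && reads_per_nuc > 0) {
    for (i in seq_len(nrow(nucs))) {
      np <- stats::rpois(1L, reads_per_nuc / 2)
      if (np > 0) {
        s5 <- round(stats::rnorm(np, nucs$start[i] - 1L, cfg$start_jitter_sd))
        chrom <- c(chrom, rep(nucs$chrom[i], np))
        start <- c(start, as.integer(s5))
        strand <- c(strand, rep("+", np))
      }
      nm <- stats::rpois(1L, reads_per_nuc / 2)
      if (nm > 0) {
        e5 <- round(stats::rnorm(nm, nucs$end[i], cfg$start_jitter_sd))
        chrom <- c(chrom, rep(nucs$chrom[i], nm))
        start <- c(start, as.integer(e5) - rl + 1L)
        strand <- c(strand, rep("-", nm))
      }
    }
  }
  total_len <- cfg$genome_length * cfg$n_chroms
  nb <- stats::rpois(1L, cfg$background_rate * total_len * depth_multiplier)
  if (nb > 0) {
    bch <- paste0("chr", sample.int(cfg$n_chroms, nb, replace = TRUE))
    bst <- sample.int(cfg$genome_length - rl, nb, replace = TRUE) - 1L
    chrom <- c(chrom, bch)
    start <- c(start, bst)
    strand <- c(strand, sample(c("+", "-"), nb, replace = TRUE))
  }
  keep <- start >= 0L & start + rl <= cfg$genome_length
  reads <- data.frame(chrom = chrom[keep], start = start[keep],
                      end = start[keep] + rl, strand = strand[keep],
                      stringsAsFactors = FALSE)
  # PCR duplicates: each read re-emitted once with probability dup_rate
  if (cfg$dup_rate > 0 && nrow(reads) > 0) {
    dup <- stats::runif(nrow(reads)) < cfg$dup_rate
    reads <- rbind(reads, reads[dup, , drop = FALSE])
  }
  if (nrow(reads) > 0) {
    reads$name <- paste0("r", seq_len(nrow(reads)))
    reads$score <- 0
  } else {
    reads$name <- character(0)
    reads$score <- numeric(0)
  }
  rownames(reads) <- NULL
  reads[, c("chrom", "start", "end", "name", "score", "strand")]
}

#' Simulate ChIP-Seq reads for one outcome mark
#'
#' Emits ~`reads_per_nuc`/2 plus-strand reads whose 5' ends are jittered
#' around each planted nucleosome's 5' edge and a mirrored count of
#' minus-strand reads at the 3' edge, plus uniform background reads scaled
#' by the depth multiplier; each read is duplicated with probability
#' `dup_rate`.
#'
#' @param cfg A [synth_config()].
#' @param truth Truth table from [build_genome()].
#' @param class Which planted class the mark covers
#'   (`"positive"` or `"negative"`).
#' @param depth_multiplier Relative sequencing depth of this sample.
#' @param seed Seed for this sample (defaults derive from `cfg$seed`).
#' @return Read data frame in BED6 column layout.
#' @export
simulate_reads <- function(cfg, truth, class = "positive",
                           depth_multiplier = 1,
                           seed = derive_seed(cfg$seed,
                                              if (class == "positive") 2L else 3L)) {
  stopifnot(inherits(cfg, "synth_config"), class %in% c("positive", "negative"))
  set.seed(seed)
  nucs <- truth[truth$class == class, , drop = FALSE]
  emit_reads(cfg, nucs, cfg$reads_per_nuc, depth_multiplier)
}

#' Default histone-modification feature channel names
#'
#' 19 histone methylations plus 18 histone acetylations (37 channels), the
#' feature panel size used for the modification overlap matrix.
#'
#' @return Character vector of length 37.
#' @export
default_feature_channels <- function() {
  meth <- c("H3K4me1", "H3K4me2", "H3K4me3", "H3K9me1", "H3K9me2",
            "H3K9me3", "H3K27me1", "H3K27me2", "H3K27me3", "H3K36me1",
            "H3K36me3", "H3K79me1", "H3K79me2", "H3K79me3", "H3R2me1",
            "H3R2me2a", "H4K20me1", "H4K20me3", "H4R3me2")
  ac <- c("H2AK5ac", "H2AK9ac", "H2BK5ac", "H2BK12ac", "H2BK20ac",
          "H2BK120ac", "H3K4ac", "H3K9ac", "H3K14ac", "H3K18ac",
          "H3K23ac", "H3K27ac", "H3K36ac", "H4K5ac", "H4K8ac",
          "H4K12ac", "H4K16ac", "H4K91ac")
  c(meth, ac)
}

#' Simulate feature-modification read channels
#'
#' Channels named in `coloc_map` emit signal reads at planted nucleosomes of
#' their mapped class at their mapped intensity (mean reads per nucleosome),
#' plus uniform background; unmapped channels emit background only.
#'
#' @param cfg A [synth_config()].
#' @param truth Truth table from [build_genome()].
#' @param channels Character vector of channel names.
#' @param coloc_map Named list `channel -> list(class =, intensity =)`;
#'   defaults to `cfg$coloc_map`.
#' @param seed Base seed; each channel derives its own stream.
#' @return Named list of read data frames, one per channel.
#' @export
simulate_feature_channels <- function(cfg, truth,
                                      channels = default_feature_channels(),
                                      coloc_map = cfg$coloc_map,
                                      seed = derive_seed(cfg$seed, 4L)) {
  stopifnot(inherits(cfg, "synth_config"))
  if (anyDuplicated(channels)) stop("duplicate feature channel names")
  if (!is.null(coloc_map)) {
    bad <- setdiff(vapply(coloc_map, function(m) m$class, character(1)),
                   c("positive", "negative"))
    if (length(bad)) stop("coloc_map references unknown class: ", bad[1L])
    orphan <- setdiff(names(coloc_map), channels)
    if (length(orphan)) stop("coloc_map references unknown channel: ", orphan[1L])
  }
  out <- vector("list", length(channels))
  names(out) <- channels
  for (i in seq_along(channels)) {
    set.seed(derive_seed(seed, i))
    map <- coloc_map[[channels[i]]]
    if (is.null(map)) {
      out[[i]] <- emit_reads(cfg, truth[0L, , drop = FALSE], 0, 1)
    } else {
      nucs <- truth[truth$class == map$class, , drop = FALSE]
      out[[i]] <- emit_reads(cfg, nucs, map$intensity, 1)
    }
  }
  out
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: builds the genome, simulates reads for the two
#' outcome marks (positive mark at `depth_multipliers[1]`, negative at
#' `depth_multipliers[2]`) and for all feature channels.
#'
#' @param cfg A [synth_config()].
#' @param channels Feature channel names.
#' @param marks Length-2 named character vector giving the positive- and
#'   negative-class outcome mark names.
#' @return List with `genome`, `repeats`, `truth`, `outcome_reads`,
#'   `feature_reads`, `marks`, `config`.
#' @export
synth_dataset <- function(cfg = synth_config(),
                          channels = default_feature_channels(),
                          marks = c(positive = "H2A.H4R3me2s",
                                    negative = "H2A.Z")) {
  gb <- build_genome(cfg)
  outcome <- list(
    simulate_reads(cfg, gb$truth, "positive",
                   depth_multiplier = cfg$depth_multipliers[1]),
    simulate_reads(cfg, gb$truth, "negative",
                   depth_multiplier = cfg$depth_multipliers[2]))
  names(outcome) <- unname(marks[c("positive", "negative")])
  features <- simulate_feature_channels(cfg, gb$truth, channels)
  list(genome = gb$genome, repeats = gb$repeats, truth = gb$truth,
       outcome_reads = outcome, feature_reads = features,
       marks = marks, config = cfg)
}
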