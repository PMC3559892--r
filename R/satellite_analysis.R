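# Downstream interpretation of the elicited features: motif occurrence
# histograms over nucleosome-bound sequences, repeat-family composition of
# the DNA bound by stable nucleosomes of each mark, and occupancy profiles
# over start-aligned satellite repeat instances.

#' Motif occurrence histogram over nucleosome-bound sequences
#'
#' Counts exact (0-mismatch) overlapping occurrences of the motif on the
#' forward strand of each sequence and tabulates the per-sequence counts.
#'
#' @param sequences Character vector of uppercase DNA sequences.
#' @param motif Uppercase DNA motif (non-empty).
#' @return List: `histogram` (data frame `count`, `n_sequences`),
#'   `fraction_present` (sequences with >= 1 occurrence), `max_count`,
#'   `median_count` (median over sequences with >= 1 occurrence, NA if
#'   none), `counts` (per-sequence vector).
#' @export
motif_occurrence_histogram <- function(sequences, motif) {
  if (!nzchar(motif)) stop("empty motif")
  counts <- vapply(sequences, function(s) {
    hits <- gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1]]
    if (length(hits) == 1L && hits[1L] == -1L) 0L else length(hits)
  }, integer(1), USE.NAMES = FALSE)
  tab <- table(counts)
  hist <- data.frame(count = as.integer(names(tab)),
                     n_sequences = as.integer(tab))
  list(histogram = hist,
       fraction_present = if (length(counts)) mean(counts >= 1L) else NA_real_,
       max_count = if (length(counts)) max(counts) else NA_integer_,
       median_count = if (any(counts >= 1L))
         stats::median(counts[counts >= 1L]) else NA_real_,
       counts = counts)
}

to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L,
                                          end = df$end))
}

#' Repeat-family composition of stable-nucleosome-bound DNA
#'
#' For each mark, the fraction of the union of its canonical nucleosome
#' intervals (in bp) overlapping the union of each repeat family's
#' annotation intervals. Unions are taken before intersection so that
#' overlapping intervals never double-count bp. Families must be disjoint
#' in the annotation.
#'
#' @param peaks_by_mark Named list of called-nucleosome data frames.
#' @param annotations Repeat annotation data frame ([read_repeats()]
#'   layout).
#' @param families Named list mapping family labels to `rep_name` values,
#'   e.g. `list("satellite II" = "HSATII", "satellite III" = c("(CATTC)n",
#'   "(GAATG)n"))`.
#' @return Data frame: `mark`, one fraction column per family, `residual`.
#' @export
repeat_composition <- function(peaks_by_mark, annotations,
                               families = list(
                                 "satellite II" = "HSATII",
                                 "satellite III" = c("(CATTC)n", "(GAATG)n"))) {
  stopifnot(is.list(peaks_by_mark), !is.null(names(peaks_by_mark)))
  fam_ranges <- lapply(families, function(reps) {
    sel <- annotations[annotations$rep_name %in% reps, , drop = FALSE]
    GenomicRanges::reduce(to_granges(sel))
  })
  if (length(fam_ranges) > 1L) {
    all_fam <- do.call(c, unname(fam_ranges))
    if (sum(IRanges::width(GenomicRanges::reduce(all_fam))) <
        sum(IRanges::width(all_fam))) {
      stop("repeat families overlap in the annotation; fractions undefined")
    }
  }
  rows <- lapply(names(peaks_by_mark), function(mark) {
    peaks <- peaks_by_mark[[mark]]
    row <- list(mark = mark)
    if (nrow(peaks) == 0L) {
      for (f in names(families)) row[[f]] <- NA_real_
      row$residual <- NA_real_
      return(as.data.frame(row, check.names = FALSE))
    }
    bound <- GenomicRanges::reduce(to_granges(peaks))
    total <- sum(IRanges::width(bound))
    fr <- vapply(fam_ranges, function(fr) {
      sum(IRanges::width(GenomicRanges::intersect(bound, fr))) / total
    }, numeric(1))
    for (f in names(families)) row[[f]] <- unname(fr[f])
    row$residual <- 1 - sum(fr)
    as.data.frame(row, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Occupancy profile over start-aligned repeat instances
#'
#' At offset `pos` from the aligned instance starts, occupancy is the
#' fraction of instances whose base at that offset is covered by at least
#' one canonical nucleosome of the mark, among instances long enough to
#' reach the offset. The summary scalar is the mean occupancy over offsets
#' up to the median instance length.
#'
#' @param peaks Called-nucleosome data frame for one mark.
#' @param instances Repeat instance data frame (`chrom`, `start`, `end`).
#' @return List of class `occupancy_profile`: `position` (0-based offsets),
#'   `occupancy`, `n_at_position`, `n_instances`, `summary`.
#' @export
occupancy_profile <- function(peaks, instances) {
  if (nrow(instances) == 0L) stop("empty repeat instance set")
  lens <- instances$end - instances$start
  L <- max(lens)
  covered <- matrix(FALSE, nrow = nrow(instances), ncol = L)
  peak_ranges <- if (nrow(peaks) > 0L) {
    GenomicRanges::reduce(to_granges(peaks))
  } else NULL
  for (i in seq_len(nrow(instances))) {
    if (is.null(peak_ranges)) next
    inst <- GenomicRanges::GRanges(
      instances$chrom[i],
      IRanges::IRanges(instances$start[i] + 1L, instances$end[i]))
    hits <- GenomicRanges::intersect(peak_ranges, inst)
    if (length(hits) == 0L) next
    for (j in seq_along(hits)) {
      lo <- GenomicRanges::start(hits)[j] - 1L - instances$start[i]
      hi <- GenomicRanges::end(hits)[j] - 1L - instances$start[i]
      covered[i, (lo + 1L):(hi + 1L)] <- TRUE
    }
  }
  n_at <- vapply(seq_len(L), function(pos) sum(lens >= pos), integer(1))
  occ <- colSums(covered) / n_at
  med <- as.integer(stats::median(lens))
  res <- list(position = 0:(L - 1L), occupancy = occ, n_at_position = n_at,
              n_instances = nrow(instances),
              summary = mean(occ[seq_len(med)]))
  class(res) <- "occupancy_profile"
  res
}
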