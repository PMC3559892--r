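# Histone-modification features: for each stable outcome nucleosome, count
# deduplicated feature-channel reads whose 5' ends fall within +/- 50 bp of
# the relevant nucleosome boundary, strand-specifically: '+' reads score at
# the 5' boundary, '-' reads at the 3' boundary.

#' Strand-specific boundary overlap count for one nucleosome
#'
#' Counts `+` feature reads whose 5' end (start) lies in the closed window
#' `[start - flank, start + flank]` around the canonical 5' boundary, plus
#' `-` feature reads whose 5' end (`end - 1`) lies in
#' `[end - 1 - flank, end - 1 + flank]` around the 3' boundary.
#'
#' @param nuc_start,nuc_end Canonical nucleosome interval (0-based
#'   half-open).
#' @param reads Deduplicated feature read data frame (same chromosome).
#' @param flank Window half-width in bp.
#' @return Integer count.
#' @export
score_overlap <- function(nuc_start, nuc_end, reads, flank = 50L) {
  plus <- reads$strand == "+"
  p5 <- reads$start[plus]
  m5 <- reads$end[!plus] - 1L
  sum(p5 >= nuc_start - flank & p5 <= nuc_start + flank) +
    sum(m5 >= nuc_end - 1L - flank & m5 <= nuc_end - 1L + flank)
}

# sorted 5'-end tallies per chromosome for one feature sample
index_5prime <- function(reads) {
  plus <- reads$strand == "+"
  list(plus = split(reads$start[plus], reads$chrom[plus]),
       minus = split(reads$end[!plus] - 1L, reads$chrom[!plus]))
}

count_sorted <- function(sorted, lo, hi) {
  if (is.null(sorted) || length(sorted) == 0L) return(integer(length(lo)))
  sorted <- sort(sorted)
  findInterval(hi + 0.5, sorted) - findInterval(lo - 0.5, sorted)
}

#' Build the modification overlap feature matrix
#'
#' One row per stable outcome nucleosome (labeled by class), one column per
#' feature channel; entries are strand-specific boundary overlap counts of
#' deduplicated feature reads (see [score_overlap()]). Rows are ordered by
#' `(class, chrom, start)` with the positive class first.
#'
#' @param peaks_by_class Named list with elements `positive` and `negative`,
#'   each a called-nucleosome data frame from [call_nucleosomes()].
#' @param feature_samples Named list of deduplicated feature read data
#'   frames (one per channel).
#' @param flank Window half-width in bp.
#' @return Data frame with columns `id`, `label` (factor, positive level
#'   first) and one numeric column per feature channel.
#' @export
build_modification_matrix <- function(peaks_by_class, feature_samples,
                                      flank = 50L) {
  stopifnot(all(c("positive", "negative") %in% names(peaks_by_class)))
  if (is.null(names(feature_samples)) || anyDuplicated(names(feature_samples))) {
    stop("feature samples must have unique names")
  }
  part <- function(cls) {
    p <- peaks_by_class[[cls]][, c("chrom", "start", "end"), drop = FALSE]
    p$label <- rep(cls, nrow(p))
    p
  }
  nucs <- rbind(part("positive"), part("negative"))
  if (nrow(nucs) > 0) {
    nucs <- nucs[order(match(nucs$label, c("positive", "negative")),
                       nucs$chrom, nucs$start), , drop = FALSE]
  }
  rownames(nucs) <- NULL
  out <- data.frame(
    id = if (nrow(nucs)) paste0(nucs$label, "_", nucs$chrom, "_", nucs$start)
         else character(0),
    label = factor(nucs$label, levels = c("positive", "negative")),
    stringsAsFactors = FALSE)
  for (fname in names(feature_samples)) {
    idx <- index_5prime(feature_samples[[fname]])
    counts <- integer(nrow(nucs))
    if (nrow(nucs) > 0) {
      for (ch in unique(nucs$chrom)) {
        sel <- which(nucs$chrom == ch)
        s <- nucs$start[sel]; e <- nucs$end[sel]
        counts[sel] <-
          count_sorted(idx$plus[[ch]], s - flank, s + flank) +
          count_sorted(idx$minus[[ch]], e - 1L - flank, e - 1L + flank)
      }
    }
    out[[fname]] <- counts
  }
  out
}
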