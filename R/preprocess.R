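# Pre-processing: collapse PCR duplicates, then equalize unique-read depth
# across samples by seeded uniform down-sampling (in that order).

#' Collapse duplicate reads
#'
#' Retains exactly one read per distinct `(chrom, start, strand)` key — the
#' 5'-end criterion appropriate for fixed-length single-end reads, where PCR
#' duplicates share the mapped start position. Output is sorted by
#' `(chrom, start, strand)`.
#'
#' @param reads Read data frame (BED6 layout).
#' @return List with `reads` (deduplicated, sorted) and `stats`
#'   (`n_total`, `n_unique`, `duplicate_fraction`).
#' @export
dedup_reads <- function(reads) {
  stopifnot(is.data.frame(reads))
  n_total <- nrow(reads)
  key <- paste(reads$chrom, reads$start, reads$strand, sep = "\r")
  out <- reads[!duplicated(key), , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  n_unique <- nrow(out)
  list(reads = out,
       stats = list(n_total = n_total, n_unique = n_unique,
                    duplicate_fraction =
                      if (n_total > 0) 1 - n_unique / n_total else 0))
}

#' Normalize samples to equal unique-read depth by down-sampling
#'
#' Every sample is reduced to the minimum unique-read count across samples
#' by uniform sampling without replacement; samples already at the minimum
#' pass through unchanged. Selection is seeded and reproducible.
#'
#' @param samples Named list of deduplicated read data frames.
#' @param seed Integer seed.
#' @return Named list of read data frames, all with the same row count.
#' @export
normalize_depth <- function(samples, seed = 1L) {
  stopifnot(is.list(samples), length(samples) > 0)
  sizes <- vapply(samples, nrow, integer(1))
  if (any(sizes == 0L)) {
    stop("cannot normalize depth: sample '",
         names(samples)[which(sizes == 0L)[1L]], "' is empty")
  }
  n_min <- min(sizes)
  set.seed(seed)
  sub_seeds <- sample.int(2^31 - 1, length(samples))
  out <- vector("list", length(samples))
  names(out) <- names(samples)
  for (i in seq_along(samples)) {
    if (sizes[i] == n_min) {
      out[[i]] <- samples[[i]]
    } else {
      set.seed(sub_seeds[i])
      keep <- sort(sample.int(sizes[i], n_min))
      res <- samples[[i]][keep, , drop = FALSE]
      rownames(res) <- NULL
      out[[i]] <- res
    }
  }
  out
}

#' Per-sample pre-processing statistics table
#'
#' @param samples Named list of raw read data frames.
#' @param seed Seed passed to [normalize_depth()].
#' @return List with `samples` (deduplicated and depth-normalized reads) and
#'   `stats` (data frame: sample, n_total, n_unique, duplicate_fraction,
#'   n_retained).
#' @export
preprocess_samples <- function(samples, seed = 1L) {
  dd <- lapply(samples, dedup_reads)
  uniq <- lapply(dd, `[[`, "reads")
  norm <- normalize_depth(uniq, seed = seed)
  stats <- data.frame(
    sample = names(samples),
    n_total = vapply(dd, function(x) x$stats$n_total, integer(1)),
    n_unique = vapply(dd, function(x) x$stats$n_unique, integer(1)),
    duplicate_fraction =
      vapply(dd, function(x) x$stats$duplicate_fraction, numeric(1)),
    n_retained = vapply(norm, nrow, integer(1)),
    stringsAsFactors = FALSE)
  rownames(stats) <- NULL
  list(samples = norm, stats = stats)
}
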