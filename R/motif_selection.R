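# Discriminatory motif feature construction in two stages, on two disjoint
# partitions of the labeled nucleosome sequences: motifs of length 5-10 are
# elicited on a discovery set (both strands searched) by a two-sample
# proportion z-statistic on per-sequence presence, and mismatch-tolerant
# match-count features are then built on the withheld classification set.
# The partition guard makes discovery/classification leakage a hard error.

#' Stratified discovery/classification partition
#'
#' Allocates a fraction `f` of each class (rounded, at least 1 and at most
#' n - 1) to the discovery set and the remainder to the classification set.
#'
#' @param seqs_by_class Named list (`positive`, `negative`) of named
#'   character vectors of uppercase DNA sequences; names are sequence ids.
#' @param f Discovery fraction, strictly between 0 and 1.
#' @param seed Integer seed.
#' @return List with `discovery` and `classification`, each a list of named
#'   character vectors per class.
#' @export
partition_sequences <- function(seqs_by_class, f = 0.2, seed = 1L) {
  stopifnot(all(c("positive", "negative") %in% names(seqs_by_class)),
            f > 0, f < 1)
  for (cl in c("positive", "negative")) {
    if (length(seqs_by_class[[cl]]) < 2L) {
      stop("class '", cl, "' has fewer than 2 sequences")
    }
    if (is.null(names(seqs_by_class[[cl]]))) {
      names(seqs_by_class[[cl]]) <-
        paste0(cl, "_", seq_along(seqs_by_class[[cl]]))
    }
  }
  set.seed(seed)
  disc <- list(); clas <- list()
  for (cl in c("positive", "negative")) {
    seqs <- seqs_by_class[[cl]]
    n <- length(seqs)
    nd <- max(1L, min(n - 1L, round(f * n)))
    pick <- sort(sample.int(n, nd))
    disc[[cl]] <- seqs[pick]
    clas[[cl]] <- seqs[-pick]
  }
  list(discovery = disc, classification = clas)
}

# all k-mer windows of a sequence (forward strand)
seq_windows <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

#' Elicit discriminatory motifs on the discovery set
#'
#' For every motif length in `[l_min, l_max]`, every k-mer observed in the
#' discovery sequences is scored by the two-sample proportion z-statistic
#' between classes on per-sequence presence, where a motif is present in a
#' sequence if it or its reverse complement occurs (strand-collapsed
#' counting: each k-mer is pooled with its reverse complement). Candidates
#' are ranked by |z|, with ties broken by total occurrence count, then
#' length, then alphabetically; a candidate that is a substring of an
#' already retained motif (in either orientation) is dropped as redundant.
#'
#' @param discovery Discovery set: named list (`positive`, `negative`) of
#'   character vectors.
#' @param l_min,l_max Motif length bounds.
#' @param max_motifs Maximum number of motifs returned.
#' @param min_support Minimum presence fraction in at least one class.
#' @return Data frame: `motif`, `length`, `z`, `direction` (`"positive"` or
#'   `"negative"`), `p_pos`, `p_neg`, `occurrences`, ordered by rank.
#' @export
elicit_motifs <- function(discovery, l_min = 5L, l_max = 10L,
                          max_motifs = 300L, min_support = 0.05) {
  stopifnot(all(c("positive", "negative") %in% names(discovery)))
  n1 <- length(discovery$positive)
  n2 <- length(discovery$negative)
  if (n1 == 0L || n2 == 0L) stop("empty discovery class")

  pres_pos <- new.env(parent = emptyenv())
  pres_neg <- new.env(parent = emptyenv())
  occ <- new.env(parent = emptyenv())        # canonical -> total occurrences
  orient <- new.env(parent = emptyenv())     # observed-form occurrence counts

  tally <- function(seqs, pres_env) {
    for (s in seqs) {
      seen <- character(0)
      for (k in l_min:l_max) {
        win <- seq_windows(s, k)
        if (length(win) == 0L) next
        win <- win[!grepl("[^ACGT]", win)]
        if (length(win) == 0L) next
        rc <- rev_comp(win)
        canon <- ifelse(win <= rc, win, rc)
        tab <- table(win)
        for (nm in names(tab)) {
          cn <- canon[match(nm, win)]
          occ[[cn]] <- (if (is.null(occ[[cn]])) 0L else occ[[cn]]) + tab[[nm]]
          orient[[nm]] <- (if (is.null(orient[[nm]])) 0L else orient[[nm]]) +
            tab[[nm]]
        }
        seen <- c(seen, unique(canon))
      }
      for (cn in unique(seen)) {
        pres_env[[cn]] <- (if (is.null(pres_env[[cn]])) 0L else pres_env[[cn]]) + 1L
      }
    }
  }
  tally(discovery$positive, pres_pos)
  tally(discovery$negative, pres_neg)

  keys <- union(ls(pres_pos), ls(pres_neg))
  if (length(keys) == 0L) {
    return(data.frame(motif = character(), length = integer(),
                      z = numeric(), direction = character(),
                      p_pos = numeric(), p_neg = numeric(),
                      occurrences = integer(), stringsAsFactors = FALSE))
  }
  c1 <- vapply(keys, function(k) if (is.null(pres_pos[[k]])) 0L else pres_pos[[k]],
               integer(1))
  c2 <- vapply(keys, function(k) if (is.null(pres_neg[[k]])) 0L else pres_neg[[k]],
               integer(1))
  p1 <- c1 / n1; p2 <- c2 / n2
  pbar <- (c1 + c2) / (n1 + n2)
  z <- ifelse(pbar > 0 & pbar < 1,
              (p1 - p2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2)),
              0)
  occurrences <- vapply(keys, function(k) as.integer(occ[[k]]), integer(1))
  cand <- data.frame(canonical = keys, length = nchar(keys), z = z,
                     p_pos = p1, p_neg = p2, occurrences = occurrences,
                     stringsAsFactors = FALSE)
  cand <- cand[abs(cand$z) > 0 & pmax(cand$p_pos, cand$p_neg) >= min_support, ,
               drop = FALSE]
  if (nrow(cand) == 0L) {
    return(data.frame(motif = character(), length = integer(),
                      z = numeric(), direction = character(),
                      p_pos = numeric(), p_neg = numeric(),
                      occurrences = integer(), stringsAsFactors = FALSE))
  }
  cand <- cand[order(-abs(cand$z), -cand$occurrences, -cand$length,
                     cand$canonical), , drop = FALSE]

  # greedy redundancy collapse: drop candidates contained in a retained motif
  retained <- character(0)
  keep_idx <- integer(0)
  for (i in seq_len(nrow(cand))) {
    m <- cand$canonical[i]
    rc <- rev_comp(m)
    contained <- any(vapply(retained, function(r) {
      grepl(m, r, fixed = TRUE) || grepl(rc, r, fixed = TRUE)
    }, logical(1)))
    if (!contained) {
      retained <- c(retained, m)
      keep_idx <- c(keep_idx, i)
      if (length(retained) >= max_motifs) break
    }
  }
  out <- cand[keep_idx, , drop = FALSE]
  # report each motif in its majority observed orientation
  out$motif <- vapply(out$canonical, function(m) {
    rc <- rev_comp(m)
    fwd <- if (is.null(orient[[m]])) 0L else orient[[m]]
    rev <- if (is.null(orient[[rc]])) 0L else orient[[rc]]
    if (rev > fwd) rc else m
  }, character(1))
  out$direction <- ifelse(out$z > 0, "positive", "negative")
  rownames(out) <- NULL
  out[, c("motif", "length", "z", "direction", "p_pos", "p_neg",
          "occurrences")]
}

# character-matrix windows (k rows, one column per window) for fast
# mismatch counting; columns align with forward window start positions
window_matrix <- function(chars, k) {
  n <- length(chars)
  if (n < k) return(NULL)
  nw <- n - k + 1L
  m <- matrix("", nrow = k, ncol = nw)
  for (j in seq_len(k)) m[j, ] <- chars[j:(j + nw - 1L)]
  m
}

count_matches <- function(wm, motif_chars, max_mismatch) {
  if (is.null(wm)) return(0L)
  sum(colSums(wm != motif_chars) <= max_mismatch)
}

#' Mismatch-tolerant motif match count
#'
#' Number of windows of length `|motif|` in the sequence, plus windows in
#' its reverse complement, whose Hamming distance to the motif is at most
#' `max_mismatch`. Overlapping windows all count.
#'
#' @param sequence Uppercase DNA string.
#' @param motif Uppercase DNA motif.
#' @param max_mismatch Maximum Hamming distance.
#' @return Integer count (0 when the motif is longer than the sequence).
#' @export
match_count <- function(sequence, motif, max_mismatch = 2L) {
  k <- nchar(motif)
  if (k == 0L) stop("empty motif")
  if (k > nchar(sequence)) return(0L)
  mc <- strsplit(motif, "")[[1]]
  fwd <- strsplit(sequence, "")[[1]]
  rev <- strsplit(rev_comp(sequence), "")[[1]]
  count_matches(window_matrix(fwd, k), mc, max_mismatch) +
    count_matches(window_matrix(rev, k), mc, max_mismatch)
}

#' Build the motif feature matrix on the classification set
#'
#' Rows are classification-set sequences (labeled), columns are elicited
#' motifs, entries are [match_count()] values. Any overlap between the
#' classification sequence ids and the discovery ids is a leakage error.
#'
#' @param class_seqs Named list (`positive`, `negative`) of named character
#'   vectors: the classification partition.
#' @param motifs Motif data frame from [elicit_motifs()].
#' @param max_mismatch Maximum Hamming distance when matching.
#' @param discovery_ids Character vector of discovery sequence ids.
#' @return Data frame with `id`, `label` and one numeric column per motif.
#' @export
build_motif_matrix <- function(class_seqs, motifs, max_mismatch = 2L,
                               discovery_ids = character(0)) {
  stopifnot(all(c("positive", "negative") %in% names(class_seqs)))
  ids <- c(names(class_seqs$positive), names(class_seqs$negative))
  leak <- intersect(ids, discovery_ids)
  if (length(leak)) {
    stop("data reusage: classification rows overlap the discovery set (",
         leak[1L], ")")
  }
  labels <- c(rep("positive", length(class_seqs$positive)),
              rep("negative", length(class_seqs$negative)))
  seqs <- c(class_seqs$positive, class_seqs$negative)
  out <- data.frame(id = ids,
                    label = factor(labels, levels = c("positive", "negative")),
                    stringsAsFactors = FALSE)
  if (nrow(motifs) == 0L) return(out)
  ks <- sort(unique(motifs$length))
  fwd_chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  rev_chars <- lapply(seqs, function(s) strsplit(rev_comp(s), "")[[1]])
  wm_f <- lapply(ks, function(k) lapply(fwd_chars, window_matrix, k = k))
  wm_r <- lapply(ks, function(k) lapply(rev_chars, window_matrix, k = k))
  names(wm_f) <- names(wm_r) <- as.character(ks)
  for (i in seq_len(nrow(motifs))) {
    m <- motifs$motif[i]
    mc <- strsplit(m, "")[[1]]
    kk <- as.character(motifs$length[i])
    counts <- vapply(seq_along(seqs), function(j) {
      count_matches(wm_f[[kk]][[j]], mc, max_mismatch) +
        count_matches(wm_r[[kk]][[j]], mc, max_mismatch)
    }, integer(1))
    out[[m]] <- counts
  }
  out
}
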