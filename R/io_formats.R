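# Shared conventions: all coordinates are BED-style 0-based half-open
# ([start, end), end exclusive). Strand is "+" or "-"; "." is rejected for
# read files because every downstream scoring step is strand-specific.

#' Read aligned ChIP-Seq reads from a BED6 file
#'
#' Parses a BED file of mapped single-end reads. At least six
#' whitespace-separated columns are required; column 6 must be `+` or `-`.
#' Coordinates are kept 0-based half-open and input order is preserved.
#'
#' @param path Path to a BED file.
#' @return A data frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, one row per read.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file does not exist: ", path)
  raw <- readLines(path)
  keep <- which(nzchar(trimws(raw)) &
                  !startsWith(raw, "track") & !startsWith(raw, "#"))
  if (length(keep) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(raw[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    bad <- keep[which(nf < 6L)[1L]]
    stop(sprintf("BED parse error at line %d: expected >= 6 fields, got %d",
                 bad, nf[which(nf < 6L)[1L]]))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  chrom <- col(1L)
  start <- suppressWarnings(as.integer(col(2L)))
  end <- suppressWarnings(as.integer(col(3L)))
  strand <- col(6L)
  bad_coord <- which(is.na(start) | is.na(end))
  if (length(bad_coord) > 0L) {
    stop(sprintf("BED parse error at line %d: non-integer coordinates",
                 keep[bad_coord[1L]]))
  }
  bad_order <- which(end <= start)
  if (length(bad_order) > 0L) {
    stop(sprintf("BED parse error at line %d: end <= start",
                 keep[bad_order[1L]]))
  }
  bad_strand <- which(!strand %in% c("+", "-"))
  if (length(bad_strand) > 0L) {
    stop(sprintf("BED parse error at line %d: strand must be '+' or '-', got '%s'",
                 keep[bad_strand[1L]], strand[bad_strand[1L]]))
  }
  if (any(!nzchar(chrom))) stop("BED parse error: empty chromosome name")
  data.frame(chrom = chrom, start = start, end = end,
             name = col(4L),
             score = suppressWarnings(as.numeric(col(5L))),
             strand = strand, stringsAsFactors = FALSE)
}

#' Write reads to a BED6 file
#'
#' Inverse of [read_bed()]: `read_bed(write_bed(x, f))` recovers `x`.
#'
#' @param reads Data frame as returned by [read_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(reads, path) {
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  name <- if ("name" %in% names(reads)) reads$name else "."
  score <- if ("score" %in% names(reads)) reads$score else 0
  lines <- paste(reads$chrom, reads$start, reads$end, name, score,
                 reads$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read repeat annotations from a BED4+ file
#'
#' Column 4 is interpreted as the repeat family name (RepeatMasker
#' `repName`, e.g. `HSATII` or `(CATTC)n`); an optional column 5 is kept as
#' the repeat class.
#'
#' @param path Path to a BED file with >= 4 columns.
#' @return Data frame with columns `chrom`, `start`, `end`, `rep_name`,
#'   `rep_class`.
#' @export
read_repeats <- function(path) {
  if (!file.exists(path)) stop("repeat BED file does not exist: ", path)
  raw <- readLines(path)
  keep <- which(nzchar(trimws(raw)) &
                  !startsWith(raw, "track") & !startsWith(raw, "#"))
  if (length(keep) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), rep_name = character(),
                      rep_class = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(raw[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop(sprintf("repeat BED parse error at line %d: expected >= 4 fields",
                 keep[which(nf < 4L)[1L]]))
  }
  col <- function(i, default = NA_character_) {
    vapply(seq_along(fields), function(j) {
      if (length(fields[[j]]) >= i) fields[[j]][[i]] else default
    }, character(1))
  }
  start <- suppressWarnings(as.integer(col(2L)))
  end <- suppressWarnings(as.integer(col(3L)))
  rep_name <- col(4L)
  if (any(is.na(start) | is.na(end)) || any(end <= start)) {
    stop("repeat BED parse error: invalid coordinates")
  }
  if (any(!nzchar(rep_name))) stop("repeat BED parse error: empty rep_name")
  data.frame(chrom = col(1L), start = start, end = end,
             rep_name = rep_name, rep_class = col(5L, "Satellite"),
             stringsAsFactors = FALSE)
}

#' Read a genome FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences, one per record.
#'   Duplicate headers are an error.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA header: ", nm[duplicated(nm)][1L])
  }
  out <- toupper(as.character(seqs))
  names(out) <- nm
  out
}

#' Write a genome to a FASTA file
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (ACGTN).
#' @return Character vector of reverse complements.
#' @export
rev_comp <- function(x) {
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

#' Extract a genomic subsequence
#'
#' Returns the forward-strand substring of `genome[[chrom]]` over the
#' 0-based half-open interval `[start, end)`, reverse-complemented when
#' `strand` is `-`.
#'
#' @param genome Named character vector as from [read_fasta()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return A DNA string.
#' @export
extract_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  len <- nchar(genome[[chrom]])
  if (start < 0 || end > len || end <= start) {
    stop(sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                 start, end, chrom, len))
  }
  s <- substr(genome[[chrom]], start + 1L, end)
  if (strand == "-") rev_comp(s) else s
}
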