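# Internal helpers shared across modules. All genomic coordinates inside the
# package are 0-based half-open; conversions happen at file boundaries only.

#' @importFrom rlang .data %||% abort warn inform
#' @importFrom tibble tibble as_tibble
NULL

# reverse complement for plain character vectors (C-level, no S4 dispatch:
# this runs once per element in the simulator's inner loop)
revcomp <- function(x) {
  vapply(x, function(s) chartr("ACGTacgtN", "TGCAtgcaN", intToUtf8(rev(utf8ToInt(s)))),
         character(1), USE.NAMES = FALSE)
}

# fetch genome[chrom][start, end) as an uppercase string (0-based half-open)
genome_slice <- function(genome, chrom, start, end) {
  seqs <- genome_sequences(genome)
  if (!chrom %in% names(seqs)) {
    abort(paste0("unknown chromosome: ", chrom))
  }
  len <- nchar(seqs[[chrom]])
  if (start < 0 || end > len || start > end) {
    abort(sprintf("interval [%d,%d) off chromosome %s (length %d)",
                  start, end, chrom, len))
  }
  substr(seqs[[chrom]], start + 1L, end)
}

# accept a named character vector, a list, or a Biostrings::DNAStringSet
genome_sequences <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else if (is.list(genome) && !is.null(genome$sequences)) {
    genome$sequences
  } else if (is.character(genome)) {
    if (is.null(names(genome))) abort("genome sequences must be named by chromosome")
    genome
  } else {
    abort("unsupported genome representation")
  }
}

genome_lengths <- function(genome) {
  vapply(genome_sequences(genome), nchar, integer(1))
}

# "100-500,600-900" <-> two-column matrix of 0-based half-open blocks
parse_blocks <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), function(b) {
    m <- do.call(rbind, strsplit(b, "-", fixed = TRUE))
    storage.mode(m) <- "integer"
    colnames(m) <- c("start", "end")
    m[order(m[, 1L]), , drop = FALSE]
  })
}

format_blocks <- function(blocks) {
  vapply(blocks, function(m) paste(sprintf("%d-%d", m[, 1L], m[, 2L]), collapse = ","),
         character(1))
}

block_span <- function(blocks) {
  vapply(blocks, function(m) sum(m[, 2L] - m[, 1L]), integer(1))
}

# longest common suffix length of two character scalars
common_suffix_len <- function(a, b) {
  ca <- rev(strsplit(a, "")[[1]])
  cb <- rev(strsplit(b, "")[[1]])
  n <- min(length(ca), length(cb))
  if (n == 0L) return(0L)
  neq <- which(ca[seq_len(n)] != cb[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

# point overlap: positions (0-based) against segments tibble with chrom/start/end.
# Returns a tibble of (call_row, segment_row) index pairs.
point_in_segments <- function(chrom, pos, segments) {
  out <- vector("list", 0L)
  for (ch in unique(segments$chrom)) {
    seg_idx <- which(segments$chrom == ch)
    call_idx <- which(chrom == ch)
    if (length(seg_idx) == 0L || length(call_idx) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = pos[call_idx] + 1L, width = 1L),
      IRanges::IRanges(start = segments$start[seg_idx] + 1L,
                       end = segments$end[seg_idx]))
    out[[length(out) + 1L]] <- tibble(
      call_row = call_idx[S4Vectors::queryHits(hits)],
      segment_row = seg_idx[S4Vectors::subjectHits(hits)])
  }
  if (length(out) == 0L) {
    tibble(call_row = integer(), segment_row = integer())
  } else {
    dplyr::bind_rows(out)
  }
}

rand_dna <- function(n, prob = c(0.3, 0.2, 0.2, 0.3)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob), collapse = "")
}

# random DNA free of CpG dinucleotides (used where CpG content must be controlled)
rand_dna_nocg <- function(n) {
  s <- rand_dna(n)
  while (grepl("CG", s, fixed = TRUE)) {
    s <- gsub("CG", "CA", s, fixed = TRUE)
  }
  s
}
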