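#' Filter 5'RACE long reads by uniqueness and primer anchoring
#'
#' Retains a read only when (i) its alignment is primary, (ii) it aligned to
#' one genomic position only at its best alignment score
#' (`n_best == 1`), and (iii) the element-specific primer matches one read
#' terminus and the universal RACE primer the other, in either orientation,
#' each within the terminal `terminal_nt` bases and with at most
#' `max_mismatch` mismatches (no indels).
#'
#' @param reads Tibble with `read_id` and `sequence`.
#' @param alignments Block-table tibble with `read_id`, `chrom`, `strand`,
#'   `blocks` (e.g. `"100-500,600-900"`, 0-based half-open), `score`,
#'   `primary`, `n_best`.
#' @param l1_primer,universal_primer Primer sequences (18-30 nt).
#' @param max_mismatch Maximum mismatches per primer match (default 2).
#' @param terminal_nt Terminal window searched for primers (default 40).
#' @return The retained alignments joined with per-read primer annotations:
#'   columns of `alignments` plus `l1_primer_at_terminus` and
#'   `universal_primer_at_terminus` (both `TRUE` by construction).
#' @export
filter_race_reads <- function(reads, alignments, l1_primer, universal_primer,
                              max_mismatch = 2L, terminal_nt = 40L) {
  for (p in c(l1_primer, universal_primer)) {
    if (nchar(p) < 18 || nchar(p) > 30) abort("primer sequences must be 18-30 nt")
  }
  aligned <- reads$read_id %in% alignments$read_id
  if (any(!aligned)) {
    inform(sprintf("%d unaligned read(s) dropped", sum(!aligned)))
    reads <- reads[aligned, , drop = FALSE]
  }
  n <- nchar(reads$sequence)
  head_seq <- substr(reads$sequence, 1L, pmin(terminal_nt, n))
  tail_seq <- substr(reads$sequence, pmax(1L, n - terminal_nt + 1L), n)
  l1_head <- primer_hit(head_seq, l1_primer, max_mismatch)
  l1_tail <- primer_hit(tail_seq, l1_primer, max_mismatch)
  uni_head <- primer_hit(head_seq, universal_primer, max_mismatch)
  uni_tail <- primer_hit(tail_seq, universal_primer, max_mismatch)
  primer_ok <- (l1_head & uni_tail) | (l1_tail & uni_head)
  ann <- tibble(read_id = reads$read_id,
                l1_primer_at_terminus = l1_head | l1_tail,
                universal_primer_at_terminus = uni_head | uni_tail,
                primer_ok = primer_ok)
  out <- dplyr::inner_join(alignments, ann, by = "read_id")
  out <- out[out$primary & out$n_best == 1L & out$primer_ok, , drop = FALSE]
  out$primer_ok <- NULL
  out
}

# TRUE when `primer` (either orientation) occurs in `x` with <= max_mismatch
primer_hit <- function(x, primer, max_mismatch) {
  subj <- Biostrings::DNAStringSet(x)
  fwd <- Biostrings::vcountPattern(primer, subj, max.mismatch = max_mismatch,
                                   with.indels = FALSE) > 0
  rev <- Biostrings::vcountPattern(revcomp(primer), subj,
                                   max.mismatch = max_mismatch,
                                   with.indels = FALSE) > 0
  fwd | rev
}

#' Assign retained 5'RACE reads to elements and classify their TSS
#'
#' Each retained read is assigned to an overlapped full-length element whose
#' body contains the alignment's 3' terminus in element-strand sense; the
#' alignment's 5' terminus on the element strand is recorded as the TSS.
#' Categories: `upstream` when the TSS lies 5' of the element within
#' `upstream_window`, `utr5` when inside the element 5'UTR, `body` when
#' inside the element downstream of the 5'UTR. Reads overlapping two
#' qualifying elements go to the one containing the 3' terminus; exact ties
#' are left unassigned (logged). Transcript length is the summed aligned
#' block length; `full_length` means transcript length > 6000 bp.
#'
#' @param alignments Retained alignments from [filter_race_reads()].
#' @param elements Full-length L1 element tibble with 5'UTR intervals.
#' @param upstream_window Maximum upstream TSS distance in bp (default 1000).
#' @return A tibble of TSS calls: `read_id`, `element_id`, `tss_pos`,
#'   `category`, `transcript_len`, `full_length`. Unassigned reads are
#'   omitted.
#' @export
assign_tss <- function(alignments, elements, upstream_window = 1000L) {
  if (nrow(alignments) == 0L) {
    return(tibble(read_id = character(), element_id = character(),
                  tss_pos = integer(), category = character(),
                  transcript_len = integer(), full_length = logical()))
  }
  blocks <- parse_blocks(alignments$blocks)
  span <- block_span(blocks)
  aln_start <- vapply(blocks, function(m) m[1L, 1L], integer(1))
  aln_end <- vapply(blocks, function(m) m[nrow(m), 2L], integer(1))
  n_tie <- 0L
  calls <- purrr::map_dfr(seq_len(nrow(alignments)), function(i) {
    el <- elements[elements$chrom == alignments$chrom[[i]] &
                     elements$start < aln_end[[i]] &
                     elements$end > aln_start[[i]], , drop = FALSE]
    if (nrow(el) == 0L) return(NULL)
    # 5'/3' termini of the alignment in element-strand sense
    # (RACE reads are element-sense transcripts: alignment strand = element strand)
    tss <- ifelse(el$strand == "+", aln_start[[i]], aln_end[[i]] - 1L)
    ter3 <- ifelse(el$strand == "+", aln_end[[i]] - 1L, aln_start[[i]])
    qual <- ter3 >= el$start & ter3 < el$end
    if (sum(qual) == 0L) return(NULL)
    if (sum(qual) > 1L) {
      n_tie <<- n_tie + 1L
      return(NULL)
    }
    el <- el[qual, , drop = FALSE]
    tss <- tss[qual]
    has_utr <- !is.na(el$utr5_start) && !is.na(el$utr5_end)
    in_utr <- has_utr && tss >= el$utr5_start && tss < el$utr5_end
    in_el <- tss >= el$start && tss < el$end
    up_dist <- if (el$strand == "+") el$start - tss else tss - (el$end - 1L)
    category <- if (in_utr) "utr5"
      else if (in_el) "body"
      else if (up_dist > 0 && up_dist <= upstream_window) "upstream"
      else NA_character_
    if (is.na(category)) return(NULL)
    tibble(read_id = alignments$read_id[[i]], element_id = el$element_id,
           tss_pos = as.integer(tss), category = category,
           transcript_len = span[[i]],
           full_length = span[[i]] > study_presets()$full_length_bp)
  })
  if (n_tie > 0L) inform(sprintf("%d read(s) tied between elements left unassigned", n_tie))
  calls
}

#' Summarize TSS categories and the full-length mRNA fraction
#'
#' Category fractions over assigned reads (they sum to 1) and the share of
#' reads whose transcript exceeds 6 kbp.
#'
#' @param calls TSS call tibble from [assign_tss()].
#' @return A one-row tibble: `n_reads`, `frac_upstream`, `frac_utr5`,
#'   `frac_body`, `full_length_fraction`.
#' @export
summarize_tss <- function(calls) {
  if (nrow(calls) == 0L) abort("no TSS calls to summarize")
  tibble(
    n_reads = nrow(calls),
    frac_upstream = mean(calls$category == "upstream"),
    frac_utr5 = mean(calls$category == "utr5"),
    frac_body = mean(calls$category == "body"),
    full_length_fraction = mean(calls$full_length))
}
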