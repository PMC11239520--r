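#' Detect chimeric element-promoter transcripts spliced into gene exons
#'
#' A spliced transcript is called chimeric for an element/gene pair when
#' (i) its 5' terminus (on the transcript strand) lies inside the element's
#' 5'UTR, (ii) it carries at least one splice junction whose acceptor
#' coincides (within `acceptor_tol` bp) with an annotated exon start of the
#' gene, (iii) the transcript strand equals the gene strand, and (iv) its
#' first exon overlaps the element by at least `min_overlap` bp. Transcripts
#' antisense to the element (the antisense-promoter configuration) are
#' marked `antisense_to_element = TRUE`; sense-promoter events are emitted
#' too but flagged `FALSE`. Junction-less transcripts are never chimeric.
#'
#' @param transcripts Tibble of spliced transcript models/alignments:
#'   `transcript_id`, `chrom`, `strand`, `blocks` (0-based half-open,
#'   `"s1-e1,s2-e2,..."`).
#' @param elements Element tibble with `utr5_start`/`utr5_end`.
#' @param genes Gene-model tibble: `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `exon_rank`, `start`, `end`, `cds_tx_start`, `cds_tx_end`
#'   (CDS interval in transcript coordinates, 0-based half-open).
#' @param acceptor_tol Splice-acceptor matching tolerance in bp (default 2).
#' @param min_overlap Minimum first-exon overlap with the element (default 20).
#' @return A tibble of chimeric transcripts: `transcript_id`, `element_id`,
#'   `gene_id`, `tss_pos`, `antisense_to_element`, `sense_with_gene`,
#'   `junctions`, `first_gene_exon_joined`, plus `chrom`, `strand`,
#'   `blocks` carried through for [orf_frame_check()].
#' @export
find_chimeric_transcripts <- function(transcripts, elements, genes,
                                      acceptor_tol = 2L, min_overlap = 20L) {
  out <- purrr::map_dfr(seq_len(nrow(transcripts)), function(i) {
    tx <- transcripts[i, ]
    blocks <- parse_blocks(tx$blocks)[[1]]
    if (nrow(blocks) < 2L) return(NULL)   # no junction: not chimeric
    tss <- if (tx$strand == "+") blocks[1L, 1L] else blocks[nrow(blocks), 2L] - 1L
    first_exon <- if (tx$strand == "+") blocks[1L, , drop = FALSE] else
      blocks[nrow(blocks), , drop = FALSE]
    el <- elements[elements$chrom == tx$chrom &
                     !is.na(elements$utr5_start) &
                     elements$utr5_start <= tss & tss < elements$utr5_end, ,
                   drop = FALSE]
    if (nrow(el) == 0L) return(NULL)
    el <- el[1L, ]
    ov <- min(first_exon[1L, 2L], el$end) - max(first_exon[1L, 1L], el$start)
    if (ov < min_overlap) return(NULL)
    # junctions as (donor-side end, acceptor-side start) in genome coordinates
    left_end <- blocks[-nrow(blocks), 2L]
    right_start <- blocks[-1L, 1L]
    cand_genes <- genes[genes$chrom == tx$chrom & genes$strand == tx$strand, ,
                        drop = FALSE]
    if (nrow(cand_genes) == 0L) return(NULL)
    # acceptor = exon start in transcription sense
    acc_pos <- if (tx$strand == "+") right_start else left_end - 1L
    exon_tss_start <- if (tx$strand == "+") cand_genes$start else cand_genes$end - 1L
    hit <- outer(acc_pos, exon_tss_start, function(a, b) abs(a - b) <= acceptor_tol)
    if (!any(hit)) return(NULL)
    exon_hits <- which(apply(hit, 2L, any))
    g <- cand_genes[exon_hits, , drop = FALSE]
    gene_id <- g$gene_id[[which.min(g$exon_rank)]]
    first_rank <- min(g$exon_rank[g$gene_id == gene_id])
    tibble(
      transcript_id = tx$transcript_id, element_id = el$element_id,
      gene_id = gene_id, tss_pos = as.integer(tss),
      antisense_to_element = tx$strand != el$strand,
      sense_with_gene = TRUE,
      junctions = paste(sprintf("%d-%d", left_end, right_start), collapse = ","),
      first_gene_exon_joined = as.integer(first_rank),
      chrom = tx$chrom, strand = tx$strand, blocks = tx$blocks)
  })
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble(transcript_id = character(), element_id = character(),
                  gene_id = character(), tss_pos = integer(),
                  antisense_to_element = logical(), sense_with_gene = logical(),
                  junctions = character(), first_gene_exon_joined = integer(),
                  chrom = character(), strand = character(), blocks = character()))
  }
  out
}

# spliced transcript sequence from block coordinates, 5'->3' on its strand
transcript_sequence <- function(genome, chrom, strand, blocks) {
  pieces <- vapply(seq_len(nrow(blocks)), function(k)
    genome_slice(genome, chrom, blocks[k, 1L], blocks[k, 2L]), character(1))
  s <- paste(pieces, collapse = "")
  if (strand == "-") revcomp(s) else s
}

translate_dna <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(dna, 1L, n)),
                                     if.fuzzy.codon = "X"))
}

# longest AUG-initiated ORF: returns list(start (0-based nt), protein
# (stop-trimmed), has_stop) or NULL
longest_aug_orf <- function(tx_seq) {
  starts <- gregexpr("ATG", tx_seq, fixed = TRUE)[[1]]
  if (starts[[1]] == -1L) return(NULL)
  best <- NULL
  for (s in as.integer(starts)) {
    aa <- translate_dna(substr(tx_seq, s, nchar(tx_seq)))
    stop_at <- regexpr("*", aa, fixed = TRUE)
    prot <- if (stop_at > 0) substr(aa, 1L, stop_at - 1L) else aa
    if (is.null(best) || nchar(prot) > nchar(best$protein)) {
      best <- list(start = s - 1L, protein = prot, has_stop = stop_at > 0)
    }
  }
  best
}

#' Reading-frame check of a chimeric transcript against the canonical ORF
#'
#' Derives the chimeric transcript sequence from the genome, takes its
#' longest AUG-initiated ORF, and compares the translated protein with the
#' canonical protein of the gene: the chimera is in frame when its
#' C-terminal region is identical to the canonical protein from the first
#' shared exon onward (codons entirely downstream of the junction).
#' `novel_nterm_aa` is the chimeric protein length minus the shared suffix
#' length. A chimeric ORF shorter than `min_codons` codons yields
#' `in_frame = FALSE` with a reason code.
#'
#' @param chimeric One row of [find_chimeric_transcripts()] output.
#' @param genes Gene-model tibble (see [find_chimeric_transcripts()]).
#' @param genome Genome object.
#' @param min_codons Minimum chimeric ORF length (default 50 codons).
#' @return A list: `in_frame`, `novel_nterm_aa`, `reason` (`"ok"`,
#'   `"no_orf"`, `"frame_mismatch"`), `chimeric_protein`.
#' @export
orf_frame_check <- function(chimeric, genes, genome, min_codons = 50L) {
  g <- genes[genes$gene_id == chimeric$gene_id, , drop = FALSE]
  g <- g[order(g$exon_rank), , drop = FALSE]
  gene_blocks <- cbind(start = g$start, end = g$end)
  gene_blocks <- gene_blocks[order(gene_blocks[, 1L]), , drop = FALSE]
  canon_tx <- transcript_sequence(genome, g$chrom[[1]], g$strand[[1]], gene_blocks)
  cds <- substr(canon_tx, g$cds_tx_start[[1]] + 1L, g$cds_tx_end[[1]])
  canon_prot <- sub("\\*$", "", translate_dna(cds))
  chi_seq <- transcript_sequence(genome, chimeric$chrom, chimeric$strand,
                                 parse_blocks(chimeric$blocks)[[1]])
  orf <- longest_aug_orf(chi_seq)
  if (is.null(orf) || nchar(orf$protein) < min_codons) {
    return(list(in_frame = FALSE, novel_nterm_aa = NA_integer_,
                reason = "no_orf", chimeric_protein = orf$protein %||% ""))
  }
  # canonical residues encoded entirely at/after the first shared exon
  exon_lens <- g$end - g$start
  joined <- chimeric$first_gene_exon_joined
  t_off <- sum(exon_lens[g$exon_rank < joined])
  d <- t_off - g$cds_tx_start[[1]]
  r0 <- if (d <= 0) 0L else as.integer(ceiling(d / 3))
  expected_shared <- nchar(canon_prot) - r0
  lcs <- common_suffix_len(orf$protein, canon_prot)
  in_frame <- expected_shared > 0 && lcs >= expected_shared
  list(in_frame = in_frame,
       novel_nterm_aa = nchar(orf$protein) - lcs,
       reason = if (in_frame) "ok" else "frame_mismatch",
       chimeric_protein = orf$protein)
}

#' Genome-wide screen for element-promoter chimeric transcripts
#'
#' Restricts elements to young L1 subfamilies, detects chimeric transcripts
#' with [find_chimeric_transcripts()], and returns one row per element with
#' at least `min_support` supporting transcript reads.
#'
#' @param transcripts,elements,genes As in [find_chimeric_transcripts()].
#' @param young_subfamilies Subfamilies considered young (default
#'   TFI/TFII/TFIII/GF/A).
#' @param min_support Minimum supporting reads per element (default 1).
#' @param ... Passed to [find_chimeric_transcripts()].
#' @return A tibble: `element_id`, `support`, `gene_ids`.
#' @export
screen_genome <- function(transcripts, elements, genes,
                          young_subfamilies = c("TFI", "TFII", "TFIII", "GF", "A"),
                          min_support = 1L, ...) {
  el <- elements[!is.na(elements$subfamily) &
                   elements$subfamily %in% young_subfamilies, , drop = FALSE]
  if (nrow(transcripts) == 0L || nrow(el) == 0L) {
    return(tibble(element_id = character(), support = integer(),
                  gene_ids = character()))
  }
  hits <- find_chimeric_transcripts(transcripts, el, genes, ...)
  hits |>
    dplyr::group_by(.data$element_id) |>
    dplyr::summarise(support = dplyr::n(),
                     gene_ids = paste(sort(unique(.data$gene_id)), collapse = ","),
                     .groups = "drop") |>
    dplyr::filter(.data$support >= min_support)
}
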