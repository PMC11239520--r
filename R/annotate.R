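#' Parse repeat annotations into an element table
#'
#' Reads either a standard 15-column RepeatMasker `.out` file (1-based
#' inclusive coordinates, `C` for minus strand) or a BED6 file (already
#' 0-based half-open) and returns one row per retrotransposon locus with
#' coordinates converted to the package's 0-based half-open convention.
#' Repeat names are mapped to superfamily/subfamily via `subfamily_map`;
#' names that match no pattern are skipped with a warning (counted), and
#' rows whose chromosome is absent from `known_chroms` are rejected with a
#' warning. Structurally malformed rows (wrong column count or non-numeric
#' coordinates) raise an error naming the offending line.
#'
#' @param path Path to a RepeatMasker `.out` or BED6 file.
#' @param subfamily_map Mapping table, see [default_subfamily_map()].
#' @param known_chroms Optional character vector of valid chromosome names
#'   (e.g. `names(genome)`); rows on other chromosomes are dropped.
#' @param format `"auto"` (sniff from extension/content), `"rm"` or `"bed"`.
#' @return A tibble of elements: `element_id`, `chrom`, `start`, `end`,
#'   `strand`, `superfamily`, `subfamily`, `rm_name`, `length`,
#'   `full_length`, `monomer_count`, `utr5_start`, `utr5_end`.
#' @export
parse_repeatmasker <- function(path, subfamily_map = default_subfamily_map(),
                               known_chroms = NULL, format = c("auto", "rm", "bed")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE) ||
                  any(grepl("^track", lines[seq_len(min(3, length(lines)))])))
      "bed"
    else if (grepl("\\.out$", path) || any(grepl("^\\s*SW|perc|score", lines[1:min(2, length(lines))])))
      "rm"
    else if (length(lines) && length(strsplit(trimws(lines[[1]]), "\\s+")[[1]]) <= 6)
      "bed"
    else "rm"
  }
  if (format == "rm") {
    rows <- parse_rm_out(lines)
  } else {
    rows <- parse_bed6(lines)
  }
  if (nrow(rows) == 0L) {
    return(empty_elements())
  }
  mapped <- map_repeat_names(rows$rm_name, subfamily_map)
  n_skip <- sum(is.na(mapped$superfamily))
  if (n_skip > 0L) {
    warn(sprintf("%d element(s) with unrecognized repeat name skipped", n_skip))
  }
  rows <- dplyr::bind_cols(rows, mapped) |> dplyr::filter(!is.na(.data$superfamily))
  if (!is.null(known_chroms)) {
    bad <- !rows$chrom %in% known_chroms
    if (any(bad)) {
      warn(sprintf("%d element(s) on unknown chromosomes rejected", sum(bad)))
      rows <- rows[!bad, , drop = FALSE]
    }
  }
  tibble(
    element_id = sprintf("%s:%d-%d(%s)", rows$chrom, rows$start, rows$end, rows$strand),
    chrom = rows$chrom, start = rows$start, end = rows$end, strand = rows$strand,
    superfamily = rows$superfamily, subfamily = rows$subfamily,
    rm_name = rows$rm_name, length = rows$end - rows$start,
    full_length = NA, monomer_count = NA_integer_,
    utr5_start = NA_integer_, utr5_end = NA_integer_)
}

empty_elements <- function() {
  tibble(element_id = character(), chrom = character(), start = integer(),
         end = integer(), strand = character(), superfamily = character(),
         subfamily = character(), rm_name = character(), length = integer(),
         full_length = logical(), monomer_count = integer(),
         utr5_start = integer(), utr5_end = integer())
}

parse_rm_out <- function(lines) {
  is_header <- grepl("^\\s*$", lines) |
    grepl("^\\s*(SW|score)\\b", lines) |
    grepl("^\\s*(perc|div\\.)", lines)
  keep <- which(!is_header)
  recs <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(f) < 14L) {
      abort(sprintf("malformed RepeatMasker row at line %d: expected >= 14 fields, got %d",
                    i, length(f)))
    }
    qb <- suppressWarnings(as.integer(f[[6]]))
    qe <- suppressWarnings(as.integer(f[[7]]))
    if (is.na(qb) || is.na(qe)) {
      abort(sprintf("malformed RepeatMasker row at line %d: non-numeric coordinates", i))
    }
    tibble(chrom = f[[5]], start = qb - 1L, end = qe,
           strand = if (f[[9]] %in% c("C", "-")) "-" else "+", rm_name = f[[10]])
  })
  if (length(recs) == 0L) {
    tibble(chrom = character(), start = integer(), end = integer(),
           strand = character(), rm_name = character())
  } else {
    dplyr::bind_rows(recs)
  }
}

parse_bed6 <- function(lines) {
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(f) < 4L) {
      abort(sprintf("malformed BED row at line %d: expected >= 4 fields", i))
    }
    st <- suppressWarnings(as.integer(f[[2]]))
    en <- suppressWarnings(as.integer(f[[3]]))
    if (is.na(st) || is.na(en)) {
      abort(sprintf("malformed BED row at line %d: non-numeric coordinates", i))
    }
    tibble(chrom = f[[1]], start = st, end = en,
           strand = if (length(f) >= 6 && f[[6]] %in% c("+", "-")) f[[6]] else "+",
           rm_name = f[[4]])
  })
  dplyr::bind_rows(recs)
}

map_repeat_names <- function(names, subfamily_map) {
  superfamily <- rep(NA_character_, length(names))
  subfamily <- rep(NA_character_, length(names))
  for (k in seq_len(nrow(subfamily_map))) {
    hit <- is.na(superfamily) & grepl(subfamily_map$pattern[[k]], names)
    superfamily[hit] <- subfamily_map$superfamily[[k]]
    subfamily[hit] <- subfamily_map$subfamily[[k]]
  }
  tibble(superfamily = superfamily, subfamily = subfamily)
}

#' Retain full-length elements by family-specific length cutoffs
#'
#' Applies the strict length thresholds used for family-level summaries:
#' L1 > 6000 bp, B1 > 140 bp, B2 > 185 bp, MT2 > 470 bp, IAP > 320 bp.
#' Retained rows have `full_length` set to `TRUE`; order is preserved and
#' the operation is idempotent.
#'
#' @param elements Element tibble from [parse_repeatmasker()].
#' @param thresholds Named list of cutoffs (defaults from [study_presets()]).
#' @return The retained subset of `elements` with `full_length = TRUE`.
#' @export
select_full_length <- function(elements, thresholds = study_presets()) {
  cut <- c(L1 = thresholds$len_l1, SINE_B1 = thresholds$len_b1,
           SINE_B2 = thresholds$len_b2, ERVL_MT2 = thresholds$len_mt2,
           IAP = thresholds$len_iap)
  keep <- elements$length > unname(cut[elements$superfamily])
  keep[is.na(keep)] <- FALSE
  out <- elements[keep, , drop = FALSE]
  out$full_length <- TRUE
  out
}

#' Count tandem 5'UTR monomers and delimit the 5'UTR
#'
#' Counts tandem copies of a monomer consensus at the 5' end of an L1
#' element, on the element's own strand, by gap-free anchored stepping: the
#' consensus is compared against successive windows starting at the 5'
#' terminus, and each window with per-base identity at or above
#' `min_identity` counts as one monomer. The 5'UTR interval spans from the
#' element 5' terminus through the end of the last monomer, extended to
#' `orf1_start` (element-relative bp, e.g. from an ORF annotation) when
#' supplied, to cover the nonmonomeric linker.
#'
#' @param element One-row element tibble (L1).
#' @param genome Genome (named character vector or `DNAStringSet`).
#' @param monomer_consensus Monomer unit sequence (150-250 bp).
#' @param min_identity Minimum per-copy identity (default 0.75).
#' @param orf1_start Optional element-relative position of ORF1 start.
#' @return A list with `monomer_count` and `utr5` (a `c(start, end)` genome
#'   interval, or `NULL` when no monomer was found).
#' @export
detect_monomers <- function(element, genome, monomer_consensus = toy_monomer(),
                            min_identity = 0.75, orf1_start = NULL) {
  L <- nchar(monomer_consensus)
  if (L < 150 || L > 250) abort("monomer consensus length must be 150-250 bp")
  elen <- element$end - element$start
  if (elen < L) {
    return(list(monomer_count = 0L, utr5 = NULL))
  }
  seq <- genome_slice(genome, element$chrom, element$start, element$end)
  if (element$strand == "-") seq <- revcomp(seq)
  cons <- strsplit(monomer_consensus, "")[[1]]
  count <- 0L
  off <- 0L
  while (off + L <= elen) {
    win <- strsplit(substr(seq, off + 1L, off + L), "")[[1]]
    if (mean(win == cons) >= min_identity) {
      count <- count + 1L
      off <- off + L
    } else {
      break
    }
  }
  if (count == 0L) {
    return(list(monomer_count = 0L, utr5 = NULL))
  }
  utr_len <- off
  if (!is.null(orf1_start) && orf1_start > utr_len && orf1_start <= elen) {
    utr_len <- as.integer(orf1_start)
  }
  utr5 <- if (element$strand == "+") {
    c(element$start, element$start + utr_len)
  } else {
    c(element$end - utr_len, element$end)
  }
  list(monomer_count = count, utr5 = as.integer(utr5))
}

#' Annotate monomer counts and 5'UTR intervals for a table of L1 elements
#'
#' Vectorized convenience wrapper around [detect_monomers()] filling the
#' `monomer_count`, `utr5_start` and `utr5_end` columns for every L1 row.
#'
#' @inheritParams detect_monomers
#' @param elements Element tibble.
#' @return `elements` with monomer columns filled for L1 rows.
#' @export
annotate_monomers <- function(elements, genome, monomer_consensus = toy_monomer(),
                              min_identity = 0.75, orf1_start = NULL) {
  for (i in seq_len(nrow(elements))) {
    if (!identical(elements$superfamily[[i]], "L1")) next
    res <- detect_monomers(elements[i, ], genome, monomer_consensus,
                           min_identity, orf1_start)
    elements$monomer_count[[i]] <- res$monomer_count
    if (!is.null(res$utr5)) {
      elements$utr5_start[[i]] <- res$utr5[[1]]
      elements$utr5_end[[i]] <- res$utr5[[2]]
    }
  }
  elements
}

#' Catalog CpG sites in a genomic interval
#'
#' One site per forward-strand `CG` dinucleotide; a CpG on the reverse
#' strand collapses to the forward-strand position of its C. Position is the
#' 0-based coordinate of the C.
#'
#' @param genome Genome object.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval (defaults: whole chromosome).
#' @return A tibble with `chrom` and `pos`.
#' @export
extract_cpg_sites <- function(genome, chrom, start = 0L,
                              end = genome_lengths(genome)[[chrom]]) {
  seq <- genome_slice(genome, chrom, start, end)
  hits <- Biostrings::matchPattern("CG", Biostrings::DNAString(seq))
  tibble(chrom = chrom, pos = as.integer(BiocGenerics::start(hits)) - 1L + start)
}

#' Tile the genome into fixed-width bins
#'
#' Non-overlapping half-open windows tiling each chromosome; the final
#' partial window is included, so window lengths sum to the genome length.
#'
#' @param genome Genome object.
#' @param width Bin width in bp (default 10 kbp).
#' @return A tibble of segments: `segment_id`, `chrom`, `start`, `end`.
#' @export
genome_bins <- function(genome, width = study_presets()$bin_width) {
  if (width <= 0) abort("bin width must be positive")
  lens <- genome_lengths(genome)
  purrr::map_dfr(names(lens), function(ch) {
    starts <- seq.int(0L, lens[[ch]] - 1L, by = width)
    tibble(segment_id = sprintf("%s:%d", ch, starts), chrom = ch,
           start = as.integer(starts),
           end = as.integer(pmin(starts + width, lens[[ch]])))
  })
}

#' Write / read the element table as TSV
#'
#' Plain TSV with the package's element columns; coordinates stay 0-based
#' half-open on disk.
#'
#' @param elements Element tibble.
#' @param path Output path.
#' @return `path`, invisibly (writer); an element tibble (reader).
#' @export
write_elements <- function(elements, path) {
  readr::write_tsv(elements, path)
  invisible(path)
}

#' @rdname write_elements
#' @export
read_elements <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = readr::col_character(),
                    strand = readr::col_character(),
                    start = readr::col_integer(), end = readr::col_integer()))
}

#' Write elements as BED6
#'
#' The BED name field carries the RepeatMasker-style repeat name so that
#' re-parsing with [parse_repeatmasker()] reproduces coordinates, strand and
#' subfamily exactly.
#'
#' @param elements Element tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_elements_bed <- function(elements, path) {
  name <- elements$rm_name
  if (is.null(name)) name <- subfamily_to_name(elements$superfamily, elements$subfamily)
  name[is.na(name)] <- subfamily_to_name(elements$superfamily[is.na(name)],
                                         elements$subfamily[is.na(name)])
  df <- data.frame(elements$chrom, elements$start, elements$end, name,
                   0L, elements$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Imports `exon` and `CDS` features and returns the package's gene-model
#' tibble: one row per exon with transcript-coordinate CDS bounds
#' (0-based half-open), exons ranked 5' to 3' on the gene strand.
#'
#' @param path GTF path.
#' @return A gene tibble (see [find_chimeric_transcripts()]).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(gr$type),
    gene_id = gr$gene_id, transcript_id = gr$transcript_id)
  purrr::map_dfr(unique(df$transcript_id), function(tid) {
    ex <- df[df$transcript_id == tid & df$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), ]
    minus <- ex$strand[[1]] == "-"
    rank <- if (minus) rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
    ex <- ex[order(rank), ]
    exon_lens <- ex$end - ex$start
    tx_off <- cumsum(c(0L, exon_lens[-length(exon_lens)]))
    cds <- df[df$transcript_id == tid & df$type == "CDS", , drop = FALSE]
    if (nrow(cds) > 0L) {
      cds_lo <- min(cds$start); cds_hi <- max(cds$end)
      # genomic CDS bounds -> transcript coordinates via the containing exons
      g2t <- function(gpos) {
        k <- which(ex$start <= gpos & gpos <= ex$end)[1]
        if (minus) tx_off[[k]] + (ex$end[[k]] - gpos)
        else tx_off[[k]] + (gpos - ex$start[[k]])
      }
      bounds <- if (minus) c(g2t(cds_hi), g2t(cds_lo)) else c(g2t(cds_lo), g2t(cds_hi))
      cds_tx_start <- bounds[[1]]; cds_tx_end <- bounds[[2]]
    } else {
      cds_tx_start <- NA_integer_; cds_tx_end <- NA_integer_
    }
    tibble(gene_id = ex$gene_id[[1]], transcript_id = tid, chrom = ex$chrom[[1]],
           strand = ex$strand[[1]], exon_rank = seq_len(nrow(ex)),
           start = ex$start, end = ex$end,
           cds_tx_start = as.integer(cds_tx_start),
           cds_tx_end = as.integer(cds_tx_end))
  })
}
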