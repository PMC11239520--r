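#' Load per-CpG methylation calls
#'
#' Reads a nanopolish-style methylation call TSV (columns `chromosome`,
#' `strand`, `start`, `end`, `read_name`, `log_lik_ratio`, ...,
#' `num_motifs`, `sequence`) or the package's simplified 5-column dialect
#' (`read_id`, `chrom`, `pos`, `llr`, `primary`). Grouped calls
#' (`num_motifs = k > 1`) are expanded to k per-CpG calls sharing the
#' group's log-likelihood ratio, with positions taken from the CpG offsets
#' in the `sequence` field. States are assigned by the symmetric threshold
#' `tau`: methylated when `llr >= tau`, unmethylated when `llr <= -tau`,
#' ambiguous otherwise. Minus-strand positions collapse to the
#' forward-strand C.
#'
#' @param path Call TSV path.
#' @param population Population label attached to every call.
#' @param tau Log-likelihood-ratio call threshold (default 2.0).
#' @return A tibble of calls: `read_id`, `chrom`, `pos`, `llr`, `state`,
#'   `population`, `primary`.
#' @export
load_meth_calls <- function(path, population, tau = study_presets()$llr_tau) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("chromosome", "start", "read_name", "log_lik_ratio") %in% header)) {
    calls <- expand_nanopolish(raw)
  } else if (all(c("read_id", "chrom", "pos", "llr") %in% header)) {
    bad <- !is.finite(suppressWarnings(as.numeric(raw$llr)))
    if (any(bad)) {
      warn(sprintf("%d row(s) with non-numeric log-likelihood ratio rejected", sum(bad)))
      raw <- raw[!bad, , drop = FALSE]
    }
    calls <- tibble(read_id = as.character(raw$read_id), chrom = raw$chrom,
                    pos = as.integer(raw$pos), llr = as.numeric(raw$llr),
                    primary = if ("primary" %in% header) as.logical(raw$primary) else TRUE)
  } else {
    abort("unrecognized methylation call table: missing required columns")
  }
  calls$state <- call_state(calls$llr, tau)
  calls$population <- population
  calls[c("read_id", "chrom", "pos", "llr", "state", "population", "primary")]
}

call_state <- function(llr, tau) {
  dplyr::case_when(llr >= tau ~ "methylated",
                   llr <= -tau ~ "unmethylated",
                   TRUE ~ "ambiguous")
}

expand_nanopolish <- function(raw) {
  bad <- !is.finite(suppressWarnings(as.numeric(raw$log_lik_ratio)))
  if (any(bad)) {
    warn(sprintf("%d row(s) with non-numeric log-likelihood ratio rejected", sum(bad)))
    raw <- raw[!bad, , drop = FALSE]
  }
  # positions of every CpG in a grouped call, from the sequence context:
  # the first CG in `sequence` sits at `start`; the rest are offset by the
  # spacing of CG occurrences within the sequence field
  pos_list <- purrr::pmap(list(raw$start, raw$num_motifs, raw$sequence),
    function(start, k, seq) {
      if (k <= 1L) return(as.integer(start))
      occ <- gregexpr("CG", seq, fixed = TRUE)[[1]]
      if (occ[[1]] == -1L || length(occ) < k) return(as.integer(start))
      as.integer(start + (occ[seq_len(k)] - occ[[1]]))
    })
  n_each <- lengths(pos_list)
  out <- tibble(
    read_id = rep(as.character(raw$read_name), n_each),
    chrom = rep(raw$chromosome, n_each),
    pos = unlist(pos_list),
    llr = rep(as.numeric(raw$log_lik_ratio), n_each),
    primary = TRUE)
  strand <- rep(raw$strand %||% "+", n_each)
  out$pos <- ifelse(strand == "-", out$pos - 1L, out$pos)
  out
}

#' Aggregate methylation calls over segments
#'
#' Each non-ambiguous (when `excl_ambig`) primary (when `primary_only`)
#' call whose position falls inside a segment increments that segment's
#' counters. For element segments carrying a 5'UTR interval
#' (`utr5_start`/`utr5_end` non-missing and `full_length` true), only
#' calls at 5'UTR positions count, matching the convention that
#' full-length L1 methylation is measured on 5'UTR CpGs.
#'
#' @param calls Call tibble from [load_meth_calls()] (may combine
#'   populations).
#' @param segments Segment tibble with `segment_id`, `chrom`, `start`,
#'   `end`, optionally `utr5_start`, `utr5_end`, `full_length`. Element
#'   tables from the annotate stage are accepted directly (the
#'   `element_id` column is used as `segment_id`).
#' @param excl_ambig Drop ambiguous calls (default TRUE).
#' @param primary_only Keep only primary-alignment calls (default TRUE).
#' @return A tibble with one row per covered segment and population:
#'   `segment_id`, `population`, `n_reads`, `n_calls`, `n_meth`,
#'   `n_unmeth`, `fraction`.
#' @export
segment_methylation <- function(calls, segments, excl_ambig = TRUE,
                                primary_only = TRUE) {
  segments <- normalize_segments(segments)
  if (excl_ambig) calls <- calls[calls$state != "ambiguous", , drop = FALSE]
  if (primary_only) calls <- calls[calls$primary, , drop = FALSE]
  if (nrow(calls) == 0L || nrow(segments) == 0L) {
    return(tibble(segment_id = character(), population = character(),
                  n_reads = integer(), n_calls = integer(), n_meth = integer(),
                  n_unmeth = integer(), fraction = double()))
  }
  hits <- point_in_segments(calls$chrom, calls$pos, segments)
  if (nrow(hits) == 0L) {
    return(tibble(segment_id = character(), population = character(),
                  n_reads = integer(), n_calls = integer(), n_meth = integer(),
                  n_unmeth = integer(), fraction = double()))
  }
  tibble(segment_id = segments$segment_id[hits$segment_row],
         population = calls$population[hits$call_row],
         read_id = calls$read_id[hits$call_row],
         state = calls$state[hits$call_row]) |>
    dplyr::group_by(.data$segment_id, .data$population) |>
    dplyr::summarise(
      n_reads = dplyr::n_distinct(.data$read_id),
      n_meth = sum(.data$state == "methylated"),
      n_unmeth = sum(.data$state == "unmethylated"),
      .groups = "drop") |>
    dplyr::mutate(n_calls = .data$n_meth + .data$n_unmeth,
                  fraction = ifelse(.data$n_calls > 0,
                                    .data$n_meth / .data$n_calls, NA_real_)) |>
    dplyr::select("segment_id", "population", "n_reads", "n_calls",
                  "n_meth", "n_unmeth", "fraction")
}

# accept element tables (element_id -> segment_id) and restrict full-length
# elements with a 5'UTR to the 5'UTR counting interval
normalize_segments <- function(segments) {
  if (!"segment_id" %in% names(segments) && "element_id" %in% names(segments)) {
    segments$segment_id <- segments$element_id
  }
  if (all(c("utr5_start", "utr5_end") %in% names(segments))) {
    use_utr <- !is.na(segments$utr5_start) & !is.na(segments$utr5_end)
    if ("full_length" %in% names(segments)) {
      use_utr <- use_utr & !is.na(segments$full_length) & segments$full_length
    }
    segments$start <- ifelse(use_utr, segments$utr5_start, segments$start)
    segments$end <- ifelse(use_utr, segments$utr5_end, segments$end)
  }
  segments[c("segment_id", "chrom", "start", "end")]
}

#' Coverage filter for cross-population comparison
#'
#' Retains a segment only when it accrued at least `min_reads` reads and
#' `min_calls` non-ambiguous calls in every compared population.
#'
#' @param segmeth Output of [segment_methylation()] covering at least the
#'   populations in `populations`.
#' @param populations Populations that must each satisfy the thresholds
#'   (default: all present).
#' @param min_reads,min_calls Inclusive thresholds (defaults 4 and 20).
#' @return The rows of `segmeth` (restricted to `populations`) for
#'   retained segments.
#' @export
coverage_filter <- function(segmeth, populations = unique(segmeth$population),
                            min_reads = study_presets()$min_reads,
                            min_calls = study_presets()$min_calls) {
  sm <- segmeth[segmeth$population %in% populations, , drop = FALSE]
  ok <- sm |>
    dplyr::group_by(.data$segment_id) |>
    dplyr::summarise(
      retained = dplyr::n_distinct(.data$population) == length(populations) &&
        all(.data$n_reads >= min_reads) && all(.data$n_calls >= min_calls),
      .groups = "drop")
  sm[sm$segment_id %in% ok$segment_id[ok$retained], , drop = FALSE]
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `rbind(c(a, b), c(c, d))`, computed
#' by summing hypergeometric point probabilities of all tables with the
#' observed margins that are no more probable than the observed table
#' (point-probability extremity criterion, ties included).
#'
#' @param a,b,c,d Non-negative integer cell counts; at least one margin
#'   must be positive.
#' @return The two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(10, 10, 10, 10) # 1
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("cell counts must be non-negative")
  if (a + b + c + d == 0) abort("all-zero table")
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  # relative tolerance guards against ties lost to floating-point noise
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Per-locus differential methylation between two populations
#'
#' One Fisher's exact test per element on the 2x2 table of methylated and
#' unmethylated call counts across the two populations, Bonferroni-corrected
#' over the number of elements actually tested. `delta` is
#' `fraction(pop_b) - fraction(pop_a)`, so a positive delta means the locus
#' is hypomethylated in population A. Results are sorted by `|delta|`
#' descending to support top-k absolute-change rankings.
#'
#' @param segmeth Coverage-filtered output of [segment_methylation()] (see
#'   [coverage_filter()]) containing both populations.
#' @param pop_a,pop_b Population labels to compare.
#' @param alpha Significance level on the Bonferroni-corrected p-value
#'   (default 0.01).
#' @return An object of class `retro_dm`; use [generics::tidy()] for the
#'   per-locus table and [generics::glance()] for the one-row summary.
#' @export
differential_methylation <- function(segmeth, pop_a, pop_b,
                                     alpha = study_presets()$alpha) {
  wide <- segmeth |>
    dplyr::filter(.data$population %in% c(pop_a, pop_b)) |>
    dplyr::mutate(side = ifelse(.data$population == pop_a, "a", "b")) |>
    tidyr::pivot_wider(id_cols = "segment_id", names_from = "side",
                       values_from = c("n_meth", "n_unmeth", "fraction"))
  missing <- !stats::complete.cases(wide[c("n_meth_a", "n_meth_b")])
  if (any(missing)) {
    inform(sprintf("%d element(s) missing in one population skipped", sum(missing)))
    wide <- wide[!missing, , drop = FALSE]
  }
  m <- nrow(wide)
  p <- purrr::pmap_dbl(wide[c("n_meth_a", "n_unmeth_a", "n_meth_b", "n_unmeth_b")],
                       function(n_meth_a, n_unmeth_a, n_meth_b, n_unmeth_b) {
                         fisher_exact_2x2(n_meth_a, n_unmeth_a, n_meth_b, n_unmeth_b)
                       })
  res <- wide |>
    dplyr::rename(element_id = "segment_id") |>
    dplyr::mutate(
      p = p,
      p_adj = stats::p.adjust(p, method = "bonferroni"),
      significant = .data$p_adj < alpha,
      delta = .data$fraction_b - .data$fraction_a,
      direction = dplyr::case_when(
        .data$delta > 0 ~ "hypomethylated_in_a",
        .data$delta < 0 ~ "hypomethylated_in_b",
        TRUE ~ "none")) |>
    dplyr::arrange(dplyr::desc(abs(.data$delta)))
  structure(list(results = res, pop_a = pop_a, pop_b = pop_b,
                 alpha = alpha, n_tested = m),
            class = "retro_dm")
}

#' Top differentially methylated loci by absolute change
#'
#' @param x A `retro_dm` object.
#' @param n Number of loci (default 50).
#' @param significant_only Restrict to significant loci first (default TRUE).
#' @return A tibble of up to `n` rows.
#' @export
top_differential <- function(x, n = 50, significant_only = TRUE) {
  res <- x$results
  if (significant_only) res <- res[res$significant, , drop = FALSE]
  utils::head(res, n)
}

#' Composite methylation profile over six-monomer elements
#'
#' Mean methylation per strand-oriented element-relative position over the
#' first `max_bp` of qualifying elements (full-length, `monomer_count`
#' equal to `monomers`). Positions covered by fewer than `min_calls`
#' non-ambiguous calls are masked.
#'
#' @param calls Call tibble.
#' @param elements Element tibble (one subfamily, typically).
#' @param monomers Required monomer count (default 6).
#' @param max_bp Profile extent from the 5' terminus (default 2000).
#' @param min_calls Per-position masking threshold (default 5).
#' @return A `retro_composite` tibble: `rel_pos`, `mean_meth`, `n_calls`,
#'   with attribute `n_elements`.
#' @export
composite_profile <- function(calls, elements, monomers = 6L, max_bp = 2000L,
                              min_calls = 5L) {
  el <- elements[!is.na(elements$monomer_count) &
                   elements$monomer_count == monomers &
                   !is.na(elements$full_length) & elements$full_length, ,
                 drop = FALSE]
  if (nrow(el) == 0L) {
    warn("no qualifying element; empty composite profile")
    out <- tibble(rel_pos = integer(), mean_meth = double(), n_calls = integer())
    return(structure(out, n_elements = 0L, class = c("retro_composite", class(out))))
  }
  calls <- calls[calls$state != "ambiguous" & calls$primary, , drop = FALSE]
  hits <- point_in_segments(calls$chrom, calls$pos,
                            tibble(chrom = el$chrom, start = el$start, end = el$end))
  rel <- ifelse(el$strand[hits$segment_row] == "+",
                calls$pos[hits$call_row] - el$start[hits$segment_row],
                el$end[hits$segment_row] - 1L - calls$pos[hits$call_row])
  keep <- rel >= 0L & rel < max_bp
  df <- tibble(rel_pos = rel[keep],
               meth = calls$state[hits$call_row][keep] == "methylated") |>
    dplyr::group_by(.data$rel_pos) |>
    dplyr::summarise(mean_meth = mean(.data$meth), n_calls = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$n_calls >= min_calls) |>
    dplyr::arrange(.data$rel_pos)
  structure(df, n_elements = nrow(el), class = c("retro_composite", class(df)))
}

#' Locus methylation profile in genome space and CpG space
#'
#' Per-CpG methylation fractions over an element plus flank, with a
#' centered sliding-window smooth in genome space (window in bp) and the
#' per-CpG track indexed by CpG ordinal (CpG space). The CpG catalog comes
#' from the genome, so the CpG-space track length equals the number of CpG
#' sites in the region, with `NA` fractions at uncovered sites.
#'
#' @param calls Call tibble.
#' @param element One-row element tibble.
#' @param genome Genome object.
#' @param flank Flank in bp on each side (default 1000).
#' @param window Smoothing window in bp (default 28).
#' @return A `retro_locus_profile` tibble: `cpg_index`, `pos`,
#'   `fraction`, `smoothed`.
#' @export
locus_profile <- function(calls, element, genome, flank = 1000L,
                          window = study_presets()$locus_window) {
  lo <- max(0L, element$start - flank)
  hi <- min(genome_lengths(genome)[[element$chrom]], element$end + flank)
  sites <- extract_cpg_sites(genome, element$chrom, lo, hi)
  calls <- calls[calls$state != "ambiguous" & calls$primary &
                   calls$chrom == element$chrom &
                   calls$pos >= lo & calls$pos < hi, , drop = FALSE]
  per_site <- calls |>
    dplyr::group_by(.data$pos) |>
    dplyr::summarise(n = dplyr::n(),
                     frac = mean(.data$state == "methylated"), .groups = "drop")
  prof <- dplyr::left_join(sites, per_site, by = "pos")
  half <- window / 2
  smoothed <- vapply(prof$pos, function(p) {
    sel <- calls$pos >= p - half & calls$pos <= p + half
    if (!any(sel)) return(NA_real_)
    mean(calls$state[sel] == "methylated")
  }, double(1))
  out <- tibble(cpg_index = seq_len(nrow(prof)), pos = prof$pos,
                fraction = prof$frac, smoothed = smoothed)
  structure(out, element_id = element$element_id, window = window,
            class = c("retro_locus_profile", class(out)))
}
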