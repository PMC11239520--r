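#' Call per-CpG methylation states on a bisulfite amplicon read
#'
#' Bisulfite-aware comparison of a read against the reference amplicon:
#' at each reference CpG, a read `C` means methylated (conversion
#' protected), `T` unmethylated (converted), anything else missing.
#' Conversion efficiency is the fraction of non-CpG reference cytosines
#' read as `T`; reads below `min_conversion` are rejected (failed
#' conversion makes methylation calls unreliable). Reads are expected
#' pre-aligned to the amplicon (same length, forward orientation);
#' length-discordant reads are rejected as unalignable.
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param reference Reference amplicon sequence (untreated strand).
#' @param min_conversion Minimum conversion rate to keep a read
#'   (default 0.95).
#' @return A tibble with one row per retained read: `read_id`, `mcpg`
#'   (methylated CpG count), `n_scored` (non-missing CpGs),
#'   `conversion_rate`, `states` (compact string over reference CpGs:
#'   `M`/`U`/`.`).
#' @export
call_amplicon <- function(reads, reference, min_conversion = 0.95) {
  ref_chars <- strsplit(reference, "")[[1]]
  cpg_pos <- as.integer(gregexpr("CG", reference, fixed = TRUE)[[1]])
  if (cpg_pos[[1]] == -1L) cpg_pos <- integer()
  non_cpg_c <- setdiff(which(ref_chars == "C"), cpg_pos)
  bad_len <- nchar(reads$sequence) != nchar(reference)
  if (any(bad_len)) {
    warn(sprintf("%d unalignable read(s) rejected (length mismatch)", sum(bad_len)))
    reads <- reads[!bad_len, , drop = FALSE]
  }
  out <- purrr::map_dfr(seq_len(nrow(reads)), function(i) {
    rc <- strsplit(reads$sequence[[i]], "")[[1]]
    cpg_read <- rc[cpg_pos]
    states <- dplyr::case_when(cpg_read == "C" ~ "M", cpg_read == "T" ~ "U",
                               TRUE ~ ".")
    conv <- if (length(non_cpg_c)) mean(rc[non_cpg_c] == "T") else 1
    tibble(read_id = reads$read_id[[i]],
           sequence = reads$sequence[[i]],
           mcpg = sum(states == "M"),
           n_scored = sum(states != "."),
           conversion_rate = conv,
           states = paste(states, collapse = ""))
  })
  if (nrow(out) == 0L) return(out)
  low <- out$conversion_rate < min_conversion
  if (any(low)) {
    warn(sprintf("%d read(s) below conversion threshold rejected", sum(low)))
    out <- out[!low, , drop = FALSE]
  }
  out
}

#' Sample nonidentical amplicon reads
#'
#' Deduplicates reads by exact sequence identity and samples `n` uniformly
#' without replacement under a fixed seed; when fewer than `n` unique
#' sequences exist, all are returned with a warning.
#'
#' @param reads Called amplicon tibble from [call_amplicon()] (must carry
#'   `sequence`).
#' @param n Number of sequences to sample (default 100).
#' @param seed RNG seed for reproducible sampling.
#' @return The sampled subset, one row per unique sequence.
#' @export
sample_nonidentical <- function(reads, n = 100L, seed = 1L) {
  uniq <- reads[!duplicated(reads$sequence), , drop = FALSE]
  if (nrow(uniq) < n) {
    warn(sprintf("only %d unique sequence(s) available (requested %d)",
                 nrow(uniq), n))
    return(uniq)
  }
  idx <- withr::with_seed(seed, sample.int(nrow(uniq), n))
  uniq[idx, , drop = FALSE]
}

#' Classify amplicon reads by methylated-CpG count
#'
#' Per-read mCpG percentage uses scored (non-missing) CpGs as the
#' denominator. Classes: fully unmethylated (`mCpG = 0`), nearly
#' unmethylated (`0 < mCpG < 5`), and the combined `mCpG < 5` class
#' corresponding to the dashed-line convention on lollipop panels.
#'
#' @param reads Called amplicon tibble.
#' @return A one-row tibble: `n_reads`, `mean_mcpg_pct`, `n_fully_unmeth`,
#'   `n_nearly_unmeth`, `n_below5`.
#' @export
classify_amplicons <- function(reads) {
  pct <- 100 * reads$mcpg / reads$n_scored
  tibble(
    n_reads = nrow(reads),
    mean_mcpg_pct = mean(pct),
    n_fully_unmeth = sum(reads$mcpg == 0L),
    n_nearly_unmeth = sum(reads$mcpg > 0L & reads$mcpg < 5L),
    n_below5 = sum(reads$mcpg < 5L))
}

#' Lollipop-style text matrix of amplicon methylation states
#'
#' One row per read, one column per reference CpG; `M` methylated, `U`
#' unmethylated, `.` missing. Suitable for plain-text inspection or
#' plotting.
#'
#' @param reads Called amplicon tibble.
#' @return A character matrix with `read_id` rownames.
#' @export
amplicon_matrix <- function(reads) {
  m <- do.call(rbind, strsplit(reads$states, ""))
  rownames(m) <- reads$read_id
  m
}
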