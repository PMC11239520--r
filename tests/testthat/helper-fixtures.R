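# Shared fixture builders. Everything is generated in code; no data files.

# small, fast simulation config for tests
small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_l1 = 6L, n_b1 = 2L, n_b2 = 2L, n_mt2 = 2L,
             n_iap = 2L, ...)
}

# a toy genome from named sequences
toy_genome <- function(...) {
  c(...)
}

# a minimal element row
toy_element <- function(element_id = "e1", chrom = "chrT", start = 0L,
                        end = 1000L, strand = "+", superfamily = "L1",
                        subfamily = "TFI", full_length = TRUE,
                        monomer_count = NA_integer_,
                        utr5_start = NA_integer_, utr5_end = NA_integer_) {
  tibble::tibble(element_id = element_id, chrom = chrom, start = start,
                 end = end, strand = strand, superfamily = superfamily,
                 subfamily = subfamily, rm_name = NA_character_,
                 length = end - start, full_length = full_length,
                 monomer_count = monomer_count,
                 utr5_start = utr5_start, utr5_end = utr5_end)
}

# calls tibble builder
toy_calls <- function(pos, state, chrom = "chrT", population = "A",
                      read_id = paste0("r", seq_along(pos)), primary = TRUE) {
  tibble::tibble(read_id = read_id, chrom = chrom, pos = as.integer(pos),
                 llr = ifelse(state == "methylated", 5,
                              ifelse(state == "unmethylated", -5, 0)),
                 state = state, population = population, primary = primary)
}

# brute-force O(calls x segments) aggregation oracle
naive_segmeth <- function(calls, segments, excl_ambig = TRUE, primary_only = TRUE) {
  if (!"segment_id" %in% names(segments)) segments$segment_id <- segments$element_id
  rows <- list()
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    lo <- s$start; hi <- s$end
    if ("utr5_start" %in% names(s) && !is.na(s$utr5_start) &&
        isTRUE(s$full_length)) {
      lo <- s$utr5_start; hi <- s$utr5_end
    }
    for (pop in unique(calls$population)) {
      nm <- nu <- 0L; reads <- character()
      for (j in seq_len(nrow(calls))) {
        cl <- calls[j, ]
        if (cl$population != pop) next
        if (primary_only && !cl$primary) next
        if (excl_ambig && cl$state == "ambiguous") next
        if (cl$chrom != s$chrom || cl$pos < lo || cl$pos >= hi) next
        if (cl$state == "methylated") nm <- nm + 1L else nu <- nu + 1L
        reads <- union(reads, cl$read_id)
      }
      if (nm + nu > 0L) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          segment_id = s$segment_id, population = pop,
          n_reads = length(reads), n_calls = nm + nu,
          n_meth = nm, n_unmeth = nu, fraction = nm / (nm + nu))
      }
    }
  }
  dplyr::bind_rows(rows)
}

# exhaustive two-sided Fisher oracle via explicit factorial-ratio enumeration
naive_fisher2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0L, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  probs <- exp(logp)
  p_obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# random substitution noise at a given per-base rate
add_noise <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    repl <- vapply(ch[hit], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
                   character(1))
    ch[hit] <- repl
  }
  paste(ch, collapse = "")
}
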