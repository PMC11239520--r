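#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator with defaults
#' set to the study conditions the package emulates: a cohort of 500
#' full-length L1 TF elements with six-monomer 5'UTRs, two cell
#' populations whose 5'UTR methylation probabilities equal the printed
#' PV+ (83.9%) and PV- (91.8%) means, escapee loci at near-zero
#' methylation, SINE B1/B2 and MT2/IAP decoy elements above their
#' full-length cutoffs, a gene with an intronic antisense L1 driving a
#' chimeric spliced transcript, 5'RACE reads with a configurable
#' truncation distribution, and bisulfite monomer amplicons. Identical
#' seeds give byte-identical outputs.
#'
#' @param seed Master RNG seed.
#' @param ... Named overrides of any default listed below.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # element census
    n_l1 = 500L,
    l1_subfamilies = c(TFI = 0.4, TFII = 0.3, TFIII = 0.3),
    monomer = toy_monomer(),
    monomer_count = 6L,
    monomer_noise = 0.02,
    linker_len = 180L,
    body_len = 5800L,
    spacer = 300L,
    n_b1 = 20L, len_b1 = 150L,
    n_b2 = 20L, len_b2 = 190L,
    n_mt2 = 8L, len_mt2 = 500L,
    n_iap = 8L, len_iap = 400L,
    # chimera cassettes
    n_chimera_genes = 1L,
    chimera_in_frame = TRUE,
    # methylation calls
    depth = 10L,
    llr_mag = 5,
    ambig_rate = 0.05,
    tau = study_presets()$llr_tau,
    # 5'RACE
    n_race_reads = 1000L,
    tss_mix = c(upstream = 0.1, utr5 = 0.8, body = 0.1),
    full_length_share = study_presets()$race_fl_pv,
    n_contaminants = 0L,
    race_primer_offset = 7100L,
    l1_primer = TOY_L1_PRIMER,
    universal_primer = TOY_UNI_PRIMER,
    # bisulfite
    n_bs_reads = 200L,
    bs_amplicon_monomers = 3L,
    bs_mix = tibble::tibble(weight = c(0.9, 0.1), meth_prob = c(0.9, 0.0)),
    conversion_failure = 0.01
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) abort(paste("unknown sim_config field(s):",
                                   paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  structure(cfg, class = "sim_config")
}

# vectorized forward-strand CpG catalog over the 5'UTR intervals of many
# elements (plain string scan; the generator's inner loop)
utr_cpg_catalog <- function(genome, elements) {
  seqs <- genome_sequences(genome)
  utr_seq <- substring(unname(seqs[elements$chrom]),
                       elements$utr5_start + 1L, elements$utr5_end)
  occ <- gregexpr("CG", utr_seq, fixed = TRUE)
  n_each <- vapply(occ, function(o) if (o[[1L]] == -1L) 0L else length(o), integer(1))
  tibble(chrom = rep(elements$chrom, n_each),
         pos = unlist(lapply(seq_along(occ), function(i)
           if (n_each[[i]] == 0L) integer() else
             as.integer(occ[[i]]) - 1L + elements$utr5_start[[i]])),
         element_id = rep(elements$element_id, n_each))
}

mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    alt <- c(A = "T", C = "A", G = "T", T = "G")  # deterministic substitution map
    ch[hit] <- alt[ch[hit]]
  }
  paste(ch, collapse = "")
}

#' Build a synthetic genome with planted elements, genes and transcripts
#'
#' Lays out three chromosomes: `chr1` carries the L1 cohort (tandem
#' six-monomer 5'UTRs built from the toy monomer consensus with per-copy
#' substitution noise, a nonmonomeric linker, and a body with the RACE
#' primer site planted near the 3' end), `chr2` the SINE/LTR decoys, and
#' `chr3` one gene cassette per configured chimera: a plus-strand gene of
#' four exons whose first intron contains a full-length antisense L1, plus
#' a chimeric transcript initiating inside the L1 5'UTR and splicing into
#' gene exon 3. When `chimera_in_frame` is `FALSE` the unique region
#' carries a 4 bp deletion that shifts the frame at the junction. Every
#' planted property is recorded in the returned truth tables.
#'
#' @param config A [sim_config()] object.
#' @return A list: `genome` (named character), `elements`, `genes`,
#'   `transcripts`, `truth` (list with `utr_len`, `element_len`,
#'   `chimera`).
#' @export
build_genome <- function(config = sim_config()) {
  withr::with_seed(config$seed, build_genome_impl(config))
}

build_genome_impl <- function(cfg) {
  mono_len <- nchar(cfg$monomer)
  utr_len <- mono_len * cfg$monomer_count + cfg$linker_len
  elt_len <- utr_len + cfg$body_len
  if (elt_len <= study_presets()$full_length_bp) {
    abort("configured element length does not exceed the full-length cutoff")
  }
  prim_off <- cfg$race_primer_offset
  if (prim_off + 50L > elt_len) abort("race_primer_offset beyond element body")
  sub_names <- sample(names(cfg$l1_subfamilies), cfg$n_l1, replace = TRUE,
                      prob = cfg$l1_subfamilies)

  make_l1 <- function() {
    monomers <- paste(vapply(seq_len(cfg$monomer_count), function(k)
      mutate_seq(cfg$monomer, cfg$monomer_noise), character(1)), collapse = "")
    linker <- rand_dna_nocg(cfg$linker_len)
    body <- rand_dna(cfg$body_len)
    s <- paste0(monomers, linker, body)
    # plant the element-specific RACE primer site in the body
    substr(s, prim_off - nchar(cfg$l1_primer) + 1L, prim_off) <- cfg$l1_primer
    s
  }

  # chr1: L1 cohort
  pieces <- character(2L * cfg$n_l1)
  el_rows <- vector("list", cfg$n_l1)
  cursor <- 0L
  for (i in seq_len(cfg$n_l1)) {
    pieces[[2L * i - 1L]] <- rand_dna(cfg$spacer)
    cursor <- cursor + cfg$spacer
    strand <- if (i %% 2L == 1L) "+" else "-"
    s <- make_l1()
    pieces[[2L * i]] <- if (strand == "-") revcomp(s) else s
    el_rows[[i]] <- tibble(
      element_id = sprintf("L1_%03d", i), chrom = "chr1",
      start = cursor, end = cursor + elt_len, strand = strand,
      superfamily = "L1", subfamily = sub_names[[i]],
      rm_name = subfamily_to_name("L1", sub_names[[i]]),
      length = elt_len, full_length = TRUE,
      monomer_count = cfg$monomer_count,
      utr5_start = if (strand == "+") cursor else cursor + elt_len - utr_len,
      utr5_end = if (strand == "+") cursor + utr_len else cursor + elt_len)
    cursor <- cursor + elt_len
  }
  chr1 <- paste(c(pieces, rand_dna(cfg$spacer)), collapse = "")
  elements <- dplyr::bind_rows(el_rows)

  # chr2: decoys
  decoy_spec <- tibble(
    superfamily = rep(c("SINE_B1", "SINE_B2", "ERVL_MT2", "IAP"),
                      times = c(cfg$n_b1, cfg$n_b2, cfg$n_mt2, cfg$n_iap)),
    subfamily = rep(c("B1", "B2", "MT2", "IAP"),
                    times = c(cfg$n_b1, cfg$n_b2, cfg$n_mt2, cfg$n_iap)),
    len = rep(c(cfg$len_b1, cfg$len_b2, cfg$len_mt2, cfg$len_iap),
              times = c(cfg$n_b1, cfg$n_b2, cfg$n_mt2, cfg$n_iap)))
  pieces2 <- character(2L * nrow(decoy_spec))
  dec_rows <- vector("list", nrow(decoy_spec))
  cursor <- 0L
  for (i in seq_len(nrow(decoy_spec))) {
    pieces2[[2L * i - 1L]] <- rand_dna(cfg$spacer)
    cursor <- cursor + cfg$spacer
    strand <- if (i %% 2L == 1L) "+" else "-"
    pieces2[[2L * i]] <- rand_dna(decoy_spec$len[[i]])
    dec_rows[[i]] <- tibble(
      element_id = sprintf("%s_%03d", decoy_spec$subfamily[[i]], i), chrom = "chr2",
      start = cursor, end = cursor + decoy_spec$len[[i]], strand = strand,
      superfamily = decoy_spec$superfamily[[i]],
      subfamily = decoy_spec$subfamily[[i]],
      rm_name = subfamily_to_name(decoy_spec$superfamily[[i]],
                                  decoy_spec$subfamily[[i]]),
      length = decoy_spec$len[[i]],
      full_length = NA, monomer_count = NA_integer_,
      utr5_start = NA_integer_, utr5_end = NA_integer_)
    cursor <- cursor + decoy_spec$len[[i]]
  }
  chr2 <- paste(pieces2, collapse = "")
  elements <- dplyr::bind_rows(elements, dplyr::bind_rows(dec_rows))

  # chr3: gene cassettes with intronic antisense L1 and chimeric transcript
  chr3_parts <- character()
  gene_rows <- list()
  tx_rows <- list()
  chim_truth <- list()
  cursor <- 0L
  for (gidx in seq_len(cfg$n_chimera_genes)) {
    cas <- build_gene_cassette(cfg, gidx, cursor, utr_len, elt_len)
    chr3_parts <- c(chr3_parts, cas$seq)
    gene_rows[[gidx]] <- cas$genes
    tx_rows[[gidx]] <- cas$transcripts
    elements <- dplyr::bind_rows(elements, cas$element)
    chim_truth[[gidx]] <- cas$truth
    cursor <- cursor + nchar(cas$seq)
  }
  chr3 <- paste(chr3_parts, collapse = "")

  genome <- c(chr1 = chr1, chr2 = chr2, chr3 = chr3)
  genome <- genome[nchar(genome) > 0L]
  list(genome = genome,
       elements = elements,
       genes = if (length(gene_rows)) dplyr::bind_rows(gene_rows) else NULL,
       transcripts = if (length(tx_rows)) dplyr::bind_rows(tx_rows) else NULL,
       truth = list(utr_len = utr_len, element_len = elt_len,
                    primer_offset = prim_off, chimera = chim_truth))
}

# random coding sequence of n codons with no stop codon
rand_codons <- function(n) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste(sample(codons, n, replace = TRUE), collapse = "")
}

# one gene cassette: exon1 - intron(L1 antisense) - exon2 - exon3 - exon4,
# plus the chimeric transcript model joining the L1 5'UTR to exon 3
build_gene_cassette <- function(cfg, gidx, origin, utr_len, elt_len) {
  gene_id <- sprintf("geneA%d", gidx)
  exon1_utr <- 50L; exon1_cds <- 150L
  exon2_len <- 120L; exon3_len <- 240L
  exon4_cds <- 180L; exon4_utr <- 100L
  sp <- 500L; isp <- 300L
  unique_orf_nt <- 120L   # ATG + 39 designed codons before the junction

  l1_seq <- {
    monomers <- paste(vapply(seq_len(cfg$monomer_count), function(k)
      mutate_seq(cfg$monomer, cfg$monomer_noise), character(1)), collapse = "")
    s <- paste0(monomers, rand_dna_nocg(cfg$linker_len), rand_dna(cfg$body_len))
    substr(s, cfg$race_primer_offset - nchar(cfg$l1_primer) + 1L,
           cfg$race_primer_offset) <- cfg$l1_primer
    s
  }

  # keep the annotated ATG as the first ATG of the transcript
  exon1 <- paste0(gsub("ATG", "ATT", rand_dna_nocg(exon1_utr), fixed = TRUE),
                  "ATG", rand_codons(49L))
  exon2 <- rand_codons(exon2_len / 3L)
  # exon3 starts with a 12 nt block clean in frame 0 but carrying stop
  # codons in both shifted frames, so frameshifted chimeras truncate early
  exon3 <- paste0("TTAATTAATAGA", rand_codons((exon3_len - 12L) / 3L))
  exon4 <- paste0(rand_codons(exon4_cds / 3L - 1L), "TAA", rand_dna(exon4_utr))

  orf_codons <- rand_codons(39L)
  orf_in <- paste0("ATG", orf_codons)                       # 120 nt, frame-true
  orf_out <- paste0("CCCC", "ATG", substr(orf_codons, 1L, 113L))  # 4 bp deletion
  orf_seg <- if (cfg$chimera_in_frame) orf_in else orf_out

  # intron 1: spacer + antisense L1 + spacer carrying the designed unique ORF
  post_l1 <- rand_dna(isp)
  substr(post_l1, 150L - unique_orf_nt + 1L, 150L) <- orf_seg
  seq <- paste0(rand_dna(sp), exon1, rand_dna(isp), revcomp(l1_seq), post_l1,
                exon2, rand_dna(400L), exon3, rand_dna(400L), exon4,
                rand_dna(cfg$spacer))

  e1s <- origin + sp
  l1s <- e1s + nchar(exon1) + isp
  l1e <- l1s + elt_len
  e2s <- l1e + isp
  e3s <- e2s + exon2_len + 400L
  e4s <- e3s + exon3_len + 400L
  exon_starts <- c(e1s, e2s, e3s, e4s)
  exon_ends <- exon_starts + c(nchar(exon1), exon2_len, exon3_len,
                               exon4_cds + exon4_utr)

  genes <- tibble(
    gene_id = gene_id, transcript_id = paste0(gene_id, ".1"),
    chrom = "chr3", strand = "+", exon_rank = 1:4,
    start = as.integer(exon_starts), end = as.integer(exon_ends),
    cds_tx_start = exon1_utr,
    cds_tx_end = exon1_utr + exon1_cds + exon2_len + exon3_len + exon4_cds)

  element <- tibble(
    element_id = sprintf("L1_gene%d", gidx), chrom = "chr3",
    start = as.integer(l1s), end = as.integer(l1e), strand = "-",
    superfamily = "L1", subfamily = "TFIII",
    rm_name = subfamily_to_name("L1", "TFIII"),
    length = elt_len, full_length = TRUE, monomer_count = cfg$monomer_count,
    utr5_start = as.integer(l1e - utr_len), utr5_end = as.integer(l1e))

  tss <- l1e - 800L                       # inside the antisense L1 5'UTR
  donor_end <- l1e + 150L                 # junction donor at end of unique exon
  chim_blocks <- sprintf("%d-%d,%d-%d,%d-%d", tss, donor_end,
                         e3s, e3s + exon3_len, e4s, exon_ends[[4]])
  transcripts <- tibble(
    transcript_id = c(paste0(gene_id, ".1"), sprintf("tx_chimera%d", gidx)),
    chrom = "chr3", strand = "+",
    blocks = c(paste(sprintf("%d-%d", exon_starts, exon_ends), collapse = ","),
               chim_blocks))

  list(seq = seq, genes = genes, element = element, transcripts = transcripts,
       truth = list(gene_id = gene_id, element_id = element$element_id,
                    tss = tss, donor_end = donor_end,
                    in_frame = cfg$chimera_in_frame,
                    first_gene_exon_joined = 3L))
}

#' Simulate per-CpG methylation call tables for one population
#'
#' For each L1 element, `depth` reads are sampled; every CpG in the
#' element's 5'UTR yields one call per read, methylated with the locus's
#' population probability, ambiguous at the configured rate. Methylated
#' calls draw log-likelihood ratios uniformly in `[tau, 2*llr_mag - tau]`
#' (mean `llr_mag`), unmethylated calls the negative, ambiguous calls
#' inside the open interval `(-tau, tau)`.
#'
#' @param sim Output of [build_genome()].
#' @param population Population label.
#' @param probs Per-locus methylation probability: a scalar, or a named
#'   vector keyed by `element_id` (unnamed loci fall back to the scalar
#'   `default`).
#' @param config A [sim_config()] (for depth/llr/ambiguity defaults).
#' @param seed RNG seed for this call set.
#' @param default Fallback probability when `probs` is a partial named
#'   vector.
#' @return A list: `calls` (simplified-dialect tibble: `read_id`, `chrom`,
#'   `pos`, `llr`, `primary`) and `truth` (per-locus probabilities).
#' @export
simulate_meth_calls <- function(sim, population, probs, config = sim_config(),
                                seed = config$seed, default = NULL) {
  l1 <- sim$elements[sim$elements$superfamily == "L1" &
                       !is.na(sim$elements$utr5_start), , drop = FALSE]
  p_locus <- if (length(probs) == 1L && is.null(names(probs))) {
    stats::setNames(rep(probs, nrow(l1)), l1$element_id)
  } else {
    base <- stats::setNames(rep(default %||% NA_real_, nrow(l1)), l1$element_id)
    base[names(probs)] <- probs
    if (anyNA(base)) abort("probs must cover every locus (or supply `default`)")
    base
  }
  sites <- utr_cpg_catalog(sim$genome, l1)
  tau <- config$tau; mag <- config$llr_mag
  calls <- withr::with_seed(seed, {
    n_sites <- nrow(sites)
    idx <- rep(seq_len(n_sites), times = config$depth)
    read_no <- rep(seq_len(config$depth), each = n_sites)
    n <- length(idx)
    ambig <- stats::runif(n) < config$ambig_rate
    meth <- stats::runif(n) < p_locus[sites$element_id[idx]]
    llr <- ifelse(ambig, stats::runif(n, -tau + 0.01, tau - 0.01),
                  ifelse(meth, stats::runif(n, tau, 2 * mag - tau),
                         -stats::runif(n, tau, 2 * mag - tau)))
    tibble(read_id = sprintf("%s_%s_r%d", sites$element_id[idx], population, read_no),
           chrom = sites$chrom[idx], pos = sites$pos[idx],
           llr = llr, primary = TRUE)
  })
  list(calls = calls,
       truth = tibble(element_id = names(p_locus), prob = unname(p_locus),
                      population = population))
}

#' Write / read the simplified methylation call dialect
#'
#' @param calls Call tibble from [simulate_meth_calls()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_meth_calls <- function(calls, path) {
  readr::write_tsv(calls, path)
  invisible(path)
}

#' Simulate 5'RACE long reads over the planted L1 cohort
#'
#' Reads are element-sense transcripts running from a sampled TSS to the
#' planted primer site near the element 3' end, carrying the universal
#' primer at the 5' terminus and the element-specific primer at the 3'
#' terminus. TSS categories follow `tss_mix`; the full-length (>6 kbp)
#' share is controlled by allocating 5'UTR TSSs above or below the span
#' cutoff (upstream TSSs are always full-length, body TSSs never).
#' Optional primer-less contaminant reads exercise the primer filter.
#'
#' @param sim Output of [build_genome()].
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @return A list: `reads` (`read_id`, `sequence`), `alignments`
#'   (block-table tibble), `truth` (per-read category/full-length/TSS).
#' @export
simulate_race_reads <- function(sim, config = sim_config(), seed = config$seed) {
  el <- sim$elements[sim$elements$chrom == "chr1" &
                       sim$elements$superfamily == "L1", , drop = FALSE]
  utr_len <- sim$truth$utr_len
  prim_off <- sim$truth$primer_offset
  fl_max_off <- prim_off - study_presets()$full_length_bp - 1L  # span > 6 kbp
  mix <- config$tss_mix / sum(config$tss_mix)
  fl <- config$full_length_share
  q_utr <- min(1, max(0, (fl - mix[["upstream"]]) / mix[["utr5"]]))
  withr::with_seed(seed, {
    n <- config$n_race_reads
    ei <- sample.int(nrow(el), n, replace = TRUE)
    category <- sample(names(mix), n, replace = TRUE, prob = mix)
    is_fl <- category == "upstream" |
      (category == "utr5" & stats::runif(n) < q_utr)
    off <- integer(n)
    up <- category == "upstream"
    off[up] <- -sample.int(200L, sum(up), replace = TRUE)
    ufl <- category == "utr5" & is_fl
    off[ufl] <- sample.int(fl_max_off, sum(ufl), replace = TRUE) - 1L
    utr <- category == "utr5" & !is_fl
    off[utr] <- fl_max_off + sample.int(utr_len - fl_max_off - 1L, sum(utr),
                                        replace = TRUE)
    body <- category == "body"
    off[body] <- utr_len + sample.int(2000L, sum(body), replace = TRUE) - 1L
    st <- el$start[ei]; en <- el$end[ei]; strand <- el$strand[ei]
    b_start <- ifelse(strand == "+", st + off, en - prim_off)
    b_end <- ifelse(strand == "+", st + prim_off, en - off)
    span <- as.integer(b_end - b_start)
    read_id <- sprintf("race_%05d", seq_len(n))
    seqs <- vapply(seq_len(n), function(i) {
      g <- genome_slice(sim$genome, el$chrom[[ei[i]]], b_start[[i]], b_end[[i]])
      if (strand[[i]] == "-") g <- revcomp(g)
      paste0(config$universal_primer, g)
    }, character(1))
    reads <- tibble(read_id = read_id, sequence = seqs)
    aln <- tibble(read_id = read_id, chrom = el$chrom[ei], strand = strand,
                  blocks = sprintf("%d-%d", b_start, b_end),
                  score = span, primary = TRUE, n_best = 1L)
    truth <- tibble(read_id = read_id, element_id = el$element_id[ei],
                    category = category, full_length = span > 6000L,
                    tss_pos = as.integer(ifelse(strand == "+", b_start, b_end - 1L)))
    if (config$n_contaminants > 0L) {
      cid <- sprintf("contam_%04d", seq_len(config$n_contaminants))
      creads <- tibble(read_id = cid,
                       sequence = vapply(seq_len(config$n_contaminants),
                                         function(i) rand_dna(800L), character(1)))
      caln <- tibble(read_id = cid, chrom = "chr2", strand = "+",
                     blocks = "0-800", score = 800L, primary = TRUE, n_best = 1L)
      reads <- dplyr::bind_rows(reads, creads)
      aln <- dplyr::bind_rows(aln, caln)
    }
    list(reads = reads, alignments = aln, truth = truth)
  })
}

#' Simulate bisulfite-converted monomer amplicon reads
#'
#' The reference amplicon is a tandem array of the toy monomer. Each read
#' draws a mixture component (weight, per-CpG methylation probability),
#' then a CpG state vector; methylated CpGs keep their C, unmethylated
#' CpGs convert to T, and non-CpG cytosines convert with probability
#' `1 - conversion_failure`.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @return A list: `reference`, `reads` (`read_id`, `sequence`), `truth`
#'   (per-read component, state string, mCpG count).
#' @export
simulate_bisulfite_reads <- function(config = sim_config(), seed = config$seed) {
  reference <- paste(rep(config$monomer, config$bs_amplicon_monomers),
                     collapse = "")
  ref_chars <- strsplit(reference, "")[[1]]
  cpg_pos <- as.integer(gregexpr("CG", reference, fixed = TRUE)[[1]])
  non_cpg_c <- setdiff(which(ref_chars == "C"), cpg_pos)
  withr::with_seed(seed, {
    n <- config$n_bs_reads
    comp <- sample.int(nrow(config$bs_mix), n, replace = TRUE,
                       prob = config$bs_mix$weight)
    rows <- purrr::map_dfr(seq_len(n), function(i) {
      p <- config$bs_mix$meth_prob[[comp[[i]]]]
      meth <- stats::runif(length(cpg_pos)) < p
      ch <- ref_chars
      ch[cpg_pos[!meth]] <- "T"
      conv <- stats::runif(length(non_cpg_c)) >= config$conversion_failure
      ch[non_cpg_c[conv]] <- "T"
      tibble(read_id = sprintf("bs_%04d", i),
             sequence = paste(ch, collapse = ""),
             component = comp[[i]],
             true_states = paste(ifelse(meth, "M", "U"), collapse = ""),
             true_mcpg = sum(meth))
    })
    list(reference = reference,
         reads = rows[c("read_id", "sequence")],
         truth = rows[c("read_id", "component", "true_states", "true_mcpg")])
  })
}

#' Write reads as FASTA / FASTQ
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, path) {
  writeLines(paste0(">", reads$read_id, "\n", reads$sequence), path)
  invisible(path)
}

#' @rdname write_reads_fasta
#' @export
write_reads_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$sequence), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", qual), path)
  invisible(path)
}

#' Write the gene models as GTF
#'
#' Emits `exon` and `CDS` features (1-based inclusive, per GTF convention)
#' for each transcript in the gene table.
#'
#' @param genes Gene tibble (see [find_chimeric_transcripts()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_gtf <- function(genes, path) {
  lines <- character()
  for (tid in unique(genes$transcript_id)) {
    g <- genes[genes$transcript_id == tid, , drop = FALSE]
    g <- g[order(g$exon_rank), ]
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s";', g$gene_id[[1]], tid)
    lines <- c(lines, sprintf("%s\tretroepi\texon\t%d\t%d\t.\t%s\t.\t%s",
                              g$chrom, g$start + 1L, g$end, g$strand, attr_str))
    # CDS rows: map the transcript-coordinate CDS back to exon pieces
    exon_lens <- g$end - g$start
    tx_off <- cumsum(c(0L, exon_lens[-length(exon_lens)]))
    for (k in seq_len(nrow(g))) {
      cs <- max(g$cds_tx_start[[1]], tx_off[[k]])
      ce <- min(g$cds_tx_end[[1]], tx_off[[k]] + exon_lens[[k]])
      if (cs >= ce) next
      if (g$strand[[1]] == "+") {
        gs <- g$start[[k]] + (cs - tx_off[[k]])
        ge <- g$start[[k]] + (ce - tx_off[[k]])
      } else {
        ge <- g$end[[k]] - (cs - tx_off[[k]])
        gs <- g$end[[k]] - (ce - tx_off[[k]])
      }
      lines <- c(lines, sprintf("%s\tretroepi\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                                g$chrom[[1]], gs + 1L, ge, g$strand[[1]], attr_str))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
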