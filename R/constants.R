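#' Study-condition presets and analysis defaults
#'
#' Central table of the fixed analysis parameters and the population-level
#' quantities the synthetic-data generator emulates: mean L1 TF 5'UTR monomer
#' methylation of sorted PV+ neurons (83.9%) versus PV- cells (91.8%), and the
#' fraction of L1 TF mRNAs longer than 6 kbp recovered by 5'RACE from sorted
#' PV interneurons (76.0%) versus bulk hippocampus (63.8%). Analysis defaults
#' (bin width, coverage filters, significance level, call threshold, smoothing
#' window, full-length cutoffs) are the values used throughout the pipeline.
#'
#' @return A named list of numeric constants.
#' @export
#' @examples
#' study_presets()$meth_pv_pos
study_presets <- function() {
  list(
    # population 5'UTR methylation probabilities (bisulfite monomer means)
    meth_pv_pos = 0.839,
    meth_pv_neg = 0.918,
    # escapee loci: near-complete promoter demethylation
    escapee_prob = 0.02,
    n_escapee = 20L,
    # 5'RACE full-length (>6 kbp) mRNA shares
    race_fl_pv = 0.760,
    race_fl_bulk = 0.638,
    # analysis defaults
    bin_width = 10000L,
    min_reads = 4L,
    min_calls = 20L,
    alpha = 0.01,
    llr_tau = 2.0,
    locus_window = 28L,
    composite_bp = 2000L,
    composite_monomers = 6L,
    full_length_bp = 6000L,
    # family length cutoffs (strict '>')
    len_l1 = 6000L, len_b1 = 140L, len_b2 = 185L, len_mt2 = 470L, len_iap = 320L
  )
}

# Toy L1 monomer consensus (206 bp, 5 CpG sites, no other CG dinucleotide).
# A bundled stand-in for a real promoter monomer; used by the simulator and by
# monomer-detection defaults. Synthetic sequence, not a database extract.
TOY_MONOMER <- paste0(
  "AGAAAATAGGCTCTATCTAATGTATCTTTCTATCTCTACGAATATACCACTTATAATTAATCTAATAGATT",
  "GGATCTACACGTATCACAACTGAGTCCTAATGTCACAATATAGAAAGTACGTACAAGTATCTACCTTTCAG",
  "ATCACTCAAACTCTTAGTAACGAATCACTACAAGATTTAATTCCCAGGACTACAGGCGTTAAGG")

# Synthetic RACE primer sequences (CpG-free so they never perturb CpG catalogs)
TOY_L1_PRIMER <- "TAATTAGCTATGGATTCAGAAA"
TOY_UNI_PRIMER <- "GATTTTGTCCAATTTTAGAGATGTT"

#' Toy L1 monomer consensus sequence
#'
#' The bundled synthetic ~206 bp monomer unit used to build tandem-monomer
#' L1 5'UTRs in the simulator and as the default consensus for
#' [detect_monomers()]. It carries five CpG dinucleotides and no CpG outside
#' those sites, so per-monomer CpG content is exactly known.
#'
#' @return A single DNA string.
#' @export
toy_monomer <- function() TOY_MONOMER

#' Default RepeatMasker name to subfamily mapping
#'
#' Maps RepeatMasker repeat names to the superfamily/subfamily vocabulary used
#' throughout the package (young L1 subfamilies TFI/TFII/TFIII/GF/A/F, SINE
#' B1/B2, ERVL MT2 and IAP LTRs). Patterns are regular expressions matched
#' against the repeat name; the first hit wins, so more specific patterns come
#' first. Unmapped names with a recognizable class fall into superfamily-only
#' bins (subfamily `NA`). The table can be edited or replaced by the caller.
#'
#' @return A tibble with columns `pattern`, `superfamily`, `subfamily`.
#' @export
default_subfamily_map <- function() {
  tibble::tribble(
    ~pattern,        ~superfamily, ~subfamily,
    "^L1MdTf_I$",    "L1",         "TFI",
    "^L1MdTf_II$",   "L1",         "TFII",
    "^L1MdTf_III$",  "L1",         "TFIII",
    "^L1MdGf",       "L1",         "GF",
    "^L1MdA",        "L1",         "A",
    "^L1MdF",        "L1",         "F",
    "^L1",           "L1",         NA,
    "^B1",           "SINE_B1",    "B1",
    "^B2",           "SINE_B2",    "B2",
    "^MT2",          "ERVL_MT2",   "MT2",
    "^IAP",          "IAP",        "IAP"
  )
}

# reverse lookup used when elements are written back to BED: subfamily -> a
# representative RepeatMasker-style name that the forward map resolves
subfamily_to_name <- function(superfamily, subfamily) {
  key <- ifelse(is.na(subfamily), superfamily, subfamily)
  lut <- c(TFI = "L1MdTf_I", TFII = "L1MdTf_II", TFIII = "L1MdTf_III",
           GF = "L1MdGf_I", A = "L1MdA_I", F = "L1MdF_I",
           B1 = "B1_Mus1", B2 = "B2_Mm1a", MT2 = "MT2_Mm", IAP = "IAPLTR1_Mm",
           L1 = "L1_Mus", SINE_B1 = "B1_Mus1", SINE_B2 = "B2_Mm1a",
           ERVL_MT2 = "MT2_Mm")
  unname(lut[key])
}
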