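test_that("the planted antisense-promoter chimera is detected and in frame", {
  cfg <- small_config(seed = 3)
  sim <- build_genome(cfg)
  hits <- find_chimeric_transcripts(sim$transcripts, sim$elements, sim$genes)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$transcript_id, "tx_chimera1")
  expect_equal(hits$element_id, "L1_gene1")
  expect_equal(hits$gene_id, "geneA1")
  expect_true(hits$antisense_to_element)
  expect_true(hits$sense_with_gene)
  expect_equal(hits$first_gene_exon_joined, 3L)
  truth <- sim$truth$chimera[[1]]
  expect_equal(hits$tss_pos, truth$tss)

  fr <- orf_frame_check(hits[1, ], sim$genes, sim$genome)
  expect_true(fr$in_frame)
  expect_gt(fr$novel_nterm_aa, 0L)
  expect_equal(fr$reason, "ok")
})

test_that("a 4 bp deletion in the unique region breaks the reading frame", {
  cfg <- small_config(seed = 3, chimera_in_frame = FALSE)
  sim <- build_genome(cfg)
  hits <- find_chimeric_transcripts(sim$transcripts, sim$elements, sim$genes)
  expect_equal(nrow(hits), 1L)
  fr <- orf_frame_check(hits[1, ], sim$genes, sim$genome)
  expect_false(fr$in_frame)
})

test_that("non-chimeric configurations are rejected", {
  cfg <- small_config(seed = 3)
  sim <- build_genome(cfg)
  chim <- sim$transcripts[sim$transcripts$transcript_id == "tx_chimera1", ]

  # the canonical transcript starts outside any element 5'UTR
  canon <- sim$transcripts[sim$transcripts$transcript_id == "geneA1.1", ]
  expect_equal(nrow(find_chimeric_transcripts(canon, sim$elements, sim$genes)), 0L)

  # junction-less transcript starting in the 5'UTR
  single <- chim
  single$blocks <- strsplit(chim$blocks, ",")[[1]][1]
  expect_equal(nrow(find_chimeric_transcripts(single, sim$elements, sim$genes)), 0L)

  # transcript antisense to the gene
  anti <- chim
  anti$strand <- "-"
  expect_equal(nrow(find_chimeric_transcripts(anti, sim$elements, sim$genes)), 0L)

  # no junction acceptor coincides with an annotated exon start
  off <- chim
  b <- retroepi:::parse_blocks(chim$blocks)[[1]]
  b[2:3, 1] <- b[2:3, 1] + 10L
  off$blocks <- retroepi:::format_blocks(list(b))
  expect_equal(nrow(find_chimeric_transcripts(off, sim$elements, sim$genes)), 0L)

  # a shifted first acceptor falls back to the next annotated junction
  part <- chim
  b1 <- retroepi:::parse_blocks(chim$blocks)[[1]]
  b1[2, 1] <- b1[2, 1] + 10L
  part$blocks <- retroepi:::format_blocks(list(b1))
  got <- find_chimeric_transcripts(part, sim$elements, sim$genes)
  expect_equal(got$first_gene_exon_joined, 4L)

  # but 2 bp of splice wobble is tolerated
  wob <- chim
  b2 <- retroepi:::parse_blocks(chim$blocks)[[1]]
  b2[2, 1] <- b2[2, 1] + 2L
  wob$blocks <- retroepi:::format_blocks(list(b2))
  expect_equal(nrow(find_chimeric_transcripts(wob, sim$elements, sim$genes)), 1L)
})

test_that("a chimeric ORF identical to the canonical ORF is trivially in frame", {
  cfg <- small_config(seed = 3)
  sim <- build_genome(cfg)
  g <- sim$genes
  fake <- tibble::tibble(
    transcript_id = "selftx", element_id = "none", gene_id = "geneA1",
    tss_pos = g$start[[1]], antisense_to_element = FALSE, sense_with_gene = TRUE,
    junctions = "", first_gene_exon_joined = 1L, chrom = "chr3", strand = "+",
    blocks = paste(sprintf("%d-%d", g$start, g$end), collapse = ","))
  fr <- orf_frame_check(fake, g, sim$genome)
  expect_true(fr$in_frame)
  expect_equal(fr$novel_nterm_aa, 0L)
})

test_that("frame verdicts agree with a naive three-frame translation check", {
  cfg <- small_config(seed = 3)
  sim <- build_genome(cfg)
  hits <- find_chimeric_transcripts(sim$transcripts, sim$elements, sim$genes)
  chi_seq <- retroepi:::transcript_sequence(
    sim$genome, hits$chrom, hits$strand, retroepi:::parse_blocks(hits$blocks)[[1]])
  g <- sim$genes
  canon_tx <- retroepi:::transcript_sequence(
    sim$genome, g$chrom[[1]], g$strand[[1]], cbind(g$start, g$end))
  canon_prot <- sub("\\*.*$", "", retroepi:::translate_dna(
    substr(canon_tx, g$cds_tx_start[[1]] + 1L, g$cds_tx_end[[1]])))
  # naive check: some frame of the chimera contains the canonical C-terminus
  tail_aa <- substr(canon_prot, nchar(canon_prot) - 49L, nchar(canon_prot))
  frames <- vapply(1:3, function(f)
    retroepi:::translate_dna(substr(chi_seq, f, nchar(chi_seq))), character(1))
  expect_true(any(grepl(tail_aa, frames, fixed = TRUE)))
  expect_true(orf_frame_check(hits[1, ], sim$genes, sim$genome)$in_frame)
})

test_that("the genome screen reports one row per supported element", {
  cfg <- small_config(seed = 4, n_chimera_genes = 5L)
  sim <- build_genome(cfg)
  tab <- screen_genome(sim$transcripts, sim$elements, sim$genes)
  expect_equal(nrow(tab), 5L)
  expect_true(all(tab$support == 1L))

  # duplicate reads of one transcript collapse to support = 2
  dup <- dplyr::bind_rows(sim$transcripts,
                          dplyr::mutate(sim$transcripts,
                                        transcript_id = paste0(transcript_id, "_dup")))
  tab2 <- screen_genome(dup, sim$elements, sim$genes)
  expect_equal(nrow(tab2), 5L)
  expect_true(all(tab2$support == 2L))

  # restricting the young set excludes the planted TFIII cassettes
  expect_equal(nrow(screen_genome(sim$transcripts, sim$elements, sim$genes,
                                  young_subfamilies = c("GF", "A"))), 0L)
  expect_equal(nrow(screen_genome(sim$transcripts[0, ], sim$elements, sim$genes)), 0L)
})

test_that("detection is invariant under a whole-fixture mirror", {
  cfg <- small_config(seed = 5)
  sim <- build_genome(cfg)
  L <- nchar(sim$genome[["chr3"]])
  flip_iv <- function(s, e) list(start = L - e, end = L - s)
  g_m <- sim$genome
  g_m[["chr3"]] <- retroepi:::revcomp(sim$genome[["chr3"]])
  el <- sim$elements[sim$elements$chrom == "chr3", ]
  iv <- flip_iv(el$start, el$end)
  ivu <- flip_iv(el$utr5_start, el$utr5_end)
  el_m <- dplyr::mutate(el, start = iv$start, end = iv$end,
                        utr5_start = ivu$start, utr5_end = ivu$end,
                        strand = ifelse(strand == "+", "-", "+"))
  gn <- sim$genes
  ivg <- flip_iv(gn$start, gn$end)
  gn_m <- dplyr::mutate(gn, start = ivg$start, end = ivg$end,
                        strand = ifelse(strand == "+", "-", "+"))
  tx <- sim$transcripts
  tx_m <- tx
  tx_m$strand <- ifelse(tx$strand == "+", "-", "+")
  tx_m$blocks <- vapply(retroepi:::parse_blocks(tx$blocks), function(b) {
    m <- cbind(L - b[, 2L], L - b[, 1L])
    retroepi:::format_blocks(list(m[order(m[, 1L]), , drop = FALSE]))
  }, character(1))
  a <- find_chimeric_transcripts(tx, el, gn)
  b <- find_chimeric_transcripts(tx_m, el_m, gn_m)
  expect_equal(nrow(a), nrow(b))
  expect_equal(sort(a$transcript_id), sort(b$transcript_id))
  expect_equal(a$antisense_to_element, b$antisense_to_element)
  fr_m <- orf_frame_check(b[1, ], gn_m, g_m)
  expect_true(fr_m$in_frame)
})
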