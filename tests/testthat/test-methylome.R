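test_that("call loading assigns states by the llr threshold", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    read_id = c("r1", "r2", "r3"), chrom = "chrT", pos = c(10L, 20L, 30L),
    llr = c(5.1, -0.4, -3.2), primary = TRUE), path)
  calls <- load_meth_calls(path, "A", tau = 2.0)
  expect_equal(calls$state, c("methylated", "ambiguous", "unmethylated"))
  expect_equal(calls$population, rep("A", 3))
})

test_that("non-numeric llr rows are rejected with a warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("read_id\tchrom\tpos\tllr\tprimary",
               "r1\tchrT\t10\t4.0\tTRUE",
               "r2\tchrT\t20\tbroken\tTRUE"), path)
  expect_warning(calls <- load_meth_calls(path, "A"), "rejected")
  expect_equal(nrow(calls), 1L)
})

test_that("grouped nanopolish calls expand to per-CpG positions", {
  seq_field <- "ATTACGTTACGTTTTACGTTT"  # CGs at offsets 4, 9, 16 (0-based)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    chromosome = "chrT", strand = "+", start = 100L, end = 112L,
    read_name = "r1", log_lik_ratio = 4.0, log_lik_methylated = -2.0,
    log_lik_unmethylated = -6.0, num_calling_strands = 1L,
    num_motifs = 3L, sequence = seq_field), path)
  calls <- load_meth_calls(path, "A")
  occ <- as.integer(gregexpr("CG", seq_field, fixed = TRUE)[[1]])
  expect_equal(calls$pos, 100L + occ - occ[[1]])
  expect_equal(calls$state, rep("methylated", 3))
  expect_equal(calls$read_id, rep("r1", 3))
})

test_that("segment aggregation counts states and honors flags", {
  seg <- tibble::tibble(segment_id = "s1", chrom = "chrT", start = 0L, end = 100L)
  calls <- toy_calls(pos = rep(c(10, 20), c(9, 1)),
                     state = rep(c("methylated", "unmethylated"), c(9, 1)))
  out <- segment_methylation(calls, seg)
  expect_equal(out$fraction, 0.9)
  expect_equal(out$n_reads, 10L)

  mixed <- toy_calls(pos = 1:100,
                     state = rep(c("methylated", "unmethylated", "ambiguous"),
                                 c(5, 5, 90)))
  out2 <- segment_methylation(mixed, seg)
  expect_equal(out2$n_calls, 10L)
  expect_equal(out2$fraction, 0.5)

  sec <- toy_calls(pos = c(10, 11), state = rep("methylated", 2),
                   primary = c(TRUE, FALSE))
  expect_equal(segment_methylation(sec, seg)$n_calls, 1L)
})

test_that("segment aggregation matches the naive per-call oracle", {
  withr::with_seed(23, {
    for (k in 1:10) {
      n_seg <- sample(2:5, 1)
      starts <- sort(sample(0:400, n_seg))
      segs <- tibble::tibble(segment_id = paste0("s", seq_len(n_seg)),
                             chrom = sample(c("c1", "c2"), n_seg, TRUE),
                             start = starts, end = starts + sample(20:120, n_seg, TRUE))
      n <- 200
      calls <- tibble::tibble(
        read_id = paste0("r", sample(1:30, n, TRUE)),
        chrom = sample(c("c1", "c2"), n, TRUE),
        pos = sample(0:500, n, TRUE),
        llr = 0,
        state = sample(c("methylated", "unmethylated", "ambiguous"), n, TRUE),
        population = sample(c("A", "B"), n, TRUE),
        primary = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.9, 0.1)))
      got <- segment_methylation(calls, segs) |>
        dplyr::arrange(segment_id, population)
      want <- naive_segmeth(calls, segs) |>
        dplyr::arrange(segment_id, population)
      expect_equal(as.data.frame(got), as.data.frame(want))
    }
  })
})

test_that("full-length element segments count only 5'UTR CpG calls", {
  el <- toy_element(end = 7000L, utr5_start = 0L, utr5_end = 1400L)
  calls <- toy_calls(pos = c(100, 2000), state = rep("methylated", 2))
  out <- segment_methylation(calls, el)
  expect_equal(out$n_calls, 1L)
})

test_that("binned call totals conserve the non-ambiguous primary call count", {
  sim <- build_genome(small_config())
  cfg <- small_config()
  mc <- simulate_meth_calls(sim, "A", 0.8, cfg, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_meth_calls(mc$calls, path)
  calls <- load_meth_calls(path, "A")
  bins <- genome_bins(sim$genome, 10000L)
  seg <- segment_methylation(calls, bins)
  expect_equal(sum(seg$n_calls), sum(calls$state != "ambiguous" & calls$primary))
})

test_that("aggregation is invariant under mirror (reverse-complement) transform", {
  withr::with_seed(31, {
    L <- 600L
    s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    g <- toy_genome(chrT = s)
    sites <- extract_cpg_sites(g, "chrT")$pos
    st <- sample(c("methylated", "unmethylated"), length(sites), TRUE)
    calls <- toy_calls(pos = sites, state = st)
    seg <- tibble::tibble(segment_id = "s1", chrom = "chrT",
                          start = 100L, end = 400L)
    a <- segment_methylation(calls, seg)
    # mirrored fixture: CpG at p maps to L - 2 - p, segment [s,e) to [L-e, L-s)
    calls_m <- calls; calls_m$pos <- L - 2L - calls$pos
    seg_m <- tibble::tibble(segment_id = "s1", chrom = "chrT",
                            start = L - 400L, end = L - 100L)
    b <- segment_methylation(calls_m, seg_m)
    expect_equal(a$fraction, b$fraction)
    expect_equal(a$n_calls, b$n_calls)
  })
})

test_that("coverage filter applies inclusive thresholds in every population", {
  mk <- function(id, pop, reads, calls) tibble::tibble(
    segment_id = id, population = pop, n_reads = reads, n_calls = calls,
    n_meth = calls, n_unmeth = 0L, fraction = 1)
  sm <- dplyr::bind_rows(
    mk("ok", "A", 4L, 20L), mk("ok", "B", 4L, 20L),
    mk("lowcalls", "A", 10L, 19L), mk("lowcalls", "B", 10L, 30L),
    mk("onepop", "A", 10L, 30L))
  kept <- coverage_filter(sm, c("A", "B"))
  expect_equal(unique(kept$segment_id), "ok")
  expect_equal(nrow(coverage_filter(sm[0, ], c("A", "B"))), 0L)
})

test_that("fisher_exact_2x2 matches enumeration and base R on spot cases", {
  expect_equal(fisher_exact_2x2(10, 10, 10, 10), 1.0)
  expect_equal(fisher_exact_2x2(90, 10, 60, 40), naive_fisher2x2(90, 10, 60, 40),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(0, 20, 20, 0), naive_fisher2x2(0, 20, 20, 0),
               tolerance = 1e-12)
  # independent cross-check against the standard implementation
  for (tb in list(c(5, 1, 2, 7), c(12, 3, 4, 9), c(0, 8, 8, 0))) {
    expect_equal(fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4]),
                 stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("differential methylation corrects over tested elements only", {
  mk <- function(id, pop, meth, unmeth) tibble::tibble(
    segment_id = id, population = pop, n_reads = 10L,
    n_calls = meth + unmeth, n_meth = meth, n_unmeth = unmeth,
    fraction = meth / (meth + unmeth))
  # single element: adjusted p equals raw p
  one <- dplyr::bind_rows(mk("e1", "A", 5L, 95L), mk("e1", "B", 80L, 20L))
  dm1 <- differential_methylation(one, "A", "B")
  expect_equal(tidy(dm1)$p_adj, tidy(dm1)$p)
  expect_true(tidy(dm1)$significant)
  expect_equal(tidy(dm1)$direction, "hypomethylated_in_a")

  # identical fractions with large counts: not significant
  same <- dplyr::bind_rows(mk("e1", "A", 300L, 100L), mk("e1", "B", 300L, 100L))
  expect_false(tidy(differential_methylation(same, "A", "B"))$significant)

  # element present in only one population is skipped with a message
  part <- dplyr::bind_rows(one, mk("e2", "A", 10L, 10L))
  expect_message(dm2 <- differential_methylation(part, "A", "B"), "skipped")
  expect_equal(dm2$n_tested, 1L)

  # results ordered by |delta| descending
  multi <- dplyr::bind_rows(
    mk("big", "A", 5L, 95L), mk("big", "B", 95L, 5L),
    mk("small", "A", 45L, 55L), mk("small", "B", 55L, 45L))
  expect_equal(tidy(differential_methylation(multi, "A", "B"))$element_id[1], "big")
})

test_that("tidy, glance and autoplot work on the DM fit", {
  mk <- function(id, pop, meth, unmeth) tibble::tibble(
    segment_id = id, population = pop, n_reads = 10L,
    n_calls = meth + unmeth, n_meth = meth, n_unmeth = unmeth,
    fraction = meth / (meth + unmeth))
  dm <- differential_methylation(
    dplyr::bind_rows(mk("e1", "A", 5L, 95L), mk("e1", "B", 80L, 20L)), "A", "B")
  expect_s3_class(tidy(dm), "tbl_df")
  g <- glance(dm)
  expect_equal(g$n_tested, 1L)
  expect_equal(g$n_significant, 1L)
  expect_s3_class(autoplot(dm), "ggplot")
  expect_output(print(dm), "retro_dm")
})

test_that("composite profile restricts to six-monomer elements and averages", {
  mono_ok <- toy_element("m6", end = 7000L, monomer_count = 6L)
  mono_no <- toy_element("m5", chrom = "chrU", end = 7000L, monomer_count = 5L)
  calls <- dplyr::bind_rows(
    toy_calls(pos = c(10, 10, 50), state = rep("methylated", 3),
              read_id = paste0("r", 1:3)),
    toy_calls(pos = c(10), state = "unmethylated", chrom = "chrU",
              read_id = "q1"))
  prof <- composite_profile(calls, dplyr::bind_rows(mono_ok, mono_no),
                            min_calls = 1L)
  expect_equal(attr(prof, "n_elements"), 1L)
  expect_true(all(prof$mean_meth == 1))
  expect_s3_class(autoplot(prof), "ggplot")
  expect_warning(composite_profile(calls, mono_no), "no qualifying element")
})

test_that("composite profile matches a naive per-position average", {
  withr::with_seed(41, {
    els <- dplyr::bind_rows(
      toy_element("e1", start = 0L, end = 7000L, strand = "+", monomer_count = 6L),
      toy_element("e2", start = 8000L, end = 15000L, strand = "-", monomer_count = 6L),
      toy_element("e3", start = 16000L, end = 23000L, strand = "+", monomer_count = 6L))
    n <- 500
    ei <- sample(1:3, n, TRUE)
    rel <- sample(0:1999, n, TRUE)
    pos <- ifelse(els$strand[ei] == "+", els$start[ei] + rel,
                  els$end[ei] - 1L - rel)
    st <- sample(c("methylated", "unmethylated"), n, TRUE)
    calls <- toy_calls(pos = pos, state = st, read_id = paste0("r", 1:n))
    prof <- composite_profile(calls, els, min_calls = 1L)
    want <- tibble::tibble(rel_pos = rel, meth = st == "methylated") |>
      dplyr::group_by(rel_pos) |>
      dplyr::summarise(mean_meth = mean(meth), n_calls = dplyr::n(), .groups = "drop") |>
      dplyr::arrange(rel_pos)
    expect_equal(prof$rel_pos, want$rel_pos)
    expect_equal(prof$mean_meth, want$mean_meth)
    expect_equal(prof$n_calls, want$n_calls)
  })
})

test_that("locus profile smooths in genome space and indexes CpG space", {
  withr::with_seed(13, {
    unit <- "ACGTTT"                      # one CpG per 6 bp
    g <- toy_genome(chrT = strrep(unit, 200))  # 1200 bp, 200 CpGs
    el <- toy_element(end = 1200L)
    sites <- extract_cpg_sites(g, "chrT")$pos
    # uniform 50%: alternate states at every CpG across two reads
    calls <- dplyr::bind_rows(
      toy_calls(pos = sites, state = "methylated", read_id = rep("r1", length(sites))),
      toy_calls(pos = sites, state = "unmethylated", read_id = rep("r2", length(sites))))
    prof <- locus_profile(calls, el, g, flank = 0L)
    expect_equal(nrow(prof), length(sites))
    expect_true(all(abs(prof$smoothed - 0.5) < 1e-9))
    expect_s3_class(autoplot(prof), "ggplot")

    # planted step change: fully methylated left half, unmethylated right half
    st <- ifelse(sites < 600, "methylated", "unmethylated")
    calls2 <- toy_calls(pos = sites, state = st,
                        read_id = paste0("r", seq_along(sites)))
    prof2 <- locus_profile(calls2, el, g, flank = 0L, window = 28L)
    left <- prof2$smoothed[prof2$pos < 600 - 28]
    right <- prof2$smoothed[prof2$pos > 600 + 28]
    expect_true(all(left > 0.5))
    expect_true(all(right < 0.5))
    cross <- prof2$pos[abs(prof2$smoothed - 0.5) <= 0.5 &
                         prof2$smoothed != 1 & prof2$smoothed != 0]
    expect_true(all(abs(cross - 600) <= 28))
  })
})
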