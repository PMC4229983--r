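test_that("source models have ordered components and stated sizes", {
  set.seed(31)
  lib <- sva_source_library(seed = 31)
  expect_length(lib, 2L)
  s1 <- lib[[1]]; s2 <- lib[[2]]
  expect_equal(s1$total_len, 4039L)
  expect_equal(s2$total_len, 2691L)
  for (s in lib) {
    comp <- s$components
    expect_true(all(diff(comp$start) > 0))
    expect_equal(comp$start[1], 1L)
    expect_equal(comp$end[nrow(comp)], s$total_len)
    expect_true(all(comp$start <= comp$end))
    expect_equal(s$total_len, sum(comp$end - comp$start + 1L))
    vntr <- comp[comp$name == "VNTR", ]
    expect_gte(gc_content(substr(s$seq, vntr$start, vntr$end)), 0.7)
  }
  # hexamer content
  hx <- s2$components[s2$components$name == "hexamer", ]
  expect_equal(substr(s2$seq, hx$start, hx$end), strrep("CCCTCT", 4))
})

test_that("full-length and truncated copies annotate at planted boundaries", {
  set.seed(32)
  lib <- sva_source_library(seed = 32)
  src <- lib[[2]]
  ann <- annotate_sva(src$seq, lib)
  expect_equal(ann$source_id, src$source_id)
  expect_equal(ann$truncation_offset, 0L)
  expect_equal(classify_truncation(ann), "full_length")
  for (nm in src$components$name) {
    planted <- src$components[src$components$name == nm, ]
    got <- ann$components[ann$components$name == nm, ]
    expect_equal(nrow(got), 1L)
    expect_lte(abs(got$start - planted$start), 5L)
    expect_lte(abs(got$end - planted$end), 5L)
  }
  # 5'-truncated copy retaining VNTR tail + SINE-R + polyA
  off <- 1200L
  copy <- substr(src$seq, off + 1L, src$total_len)
  ann2 <- annotate_sva(copy, lib)
  expect_equal(ann2$source_id, src$source_id)
  expect_equal(ann2$truncation_offset, off)
  expect_equal(classify_truncation(ann2), "five_prime_truncated")
  expect_false("hexamer" %in% ann2$components$name)
  expect_false("Alu_like" %in% ann2$components$name)
  expect_true("SINE_R" %in% ann2$components$name)
  # a GC-matched random sequence is not called
  expect_null(annotate_sva(rdna(2000, 0.6), lib))
})

test_that("truncation threshold behaves at the boundary", {
  set.seed(33)
  lib <- sva_source_library(seed = 33)
  src <- lib[[2]]
  ann <- annotate_sva(substr(src$seq, 51L, src$total_len), lib)
  expect_equal(ann$truncation_offset, 50L)
  expect_equal(classify_truncation(ann), "full_length")
  # a replica of a 4,039 bp source annotated at ~1.7 kb is truncated
  big <- lib[[1]]
  copy <- substr(big$seq, big$total_len - 1700L + 1L, big$total_len)
  ann2 <- annotate_sva(copy, lib)
  expect_equal(ann2$source_id, big$source_id)
  expect_equal(classify_truncation(ann2), "five_prime_truncated")
})

test_that("source assignment resolves libraries differing by >= 5 points", {
  set.seed(34)
  lib <- sva_source_library(seed = 34)
  cfg <- sim_config(seed = 34, n_per_mechanism = 1L)
  ref <- make_reference(cfg, seed = 341)
  for (k in 1:4) {
    src <- lib[[1L + k %% 2L]]
    sim <- simulate_sva_tprt_deletion(ref, src, cfg,
                                      junction_id = sprintf("sv%d", k))
    ann <- annotate_sva(sim$junction$seq, lib)
    expect_equal(ann$source_id, src$source_id)
    # local alignment may rag a few bases into the polyT boundary
    expect_lte(abs(ann$truncation_offset - sim$truth$sva_truncation), 10L)
    expect_equal(ann$orientation, "+")
  }
})

test_that("TSD detection: planted duplication, thresholds, brute force", {
  set.seed(35)
  tsd <- rdna(15)
  lf <- paste0(rdna(40), tsd)
  rf <- paste0(tsd, rdna(40))
  got <- detect_tsd(lf, rf)
  expect_equal(got$tsd_seq, tsd)
  expect_equal(got$left_span, c(41L, 55L))
  # below min_len -> none
  w4 <- rdna(4)
  expect_null(detect_tsd(paste0(rdna(40), w4), paste0(w4, rdna(40)),
                         min_len = 5L))
  # brute-force longest boundary word on random flanks
  for (i in 1:50) {
    lf <- rdna(60); rf <- rdna(60)
    got <- detect_tsd(lf, rf)
    brute <- NULL
    for (len in 5:25) {
      if (substr(lf, 61 - len, 60) == substr(rf, 1, len)) {
        brute <- substr(rf, 1, len)
      }
    }
    expect_equal(got$tsd_seq, brute)
  }
})

test_that("TPRT deletion junctions carry all four hallmarks, no TSD", {
  set.seed(36)
  cfg <- sim_config(seed = 36, n_per_mechanism = 1L)
  lib <- sva_source_library(seed = 36)
  ref <- make_reference(cfg, seed = 361)
  sim <- simulate_sva_tprt_deletion(ref, lib[[2]], cfg)
  ann <- annotate_sva(sim$junction$seq, lib)
  expect_false(is.null(ann))
  h <- tprt_hallmarks(sim$junction$seq, ann,
                      prox_flank = sim$prox_flank$seq)
  expect_true(h$en_site_at_integration)
  expect_true(h$polyt_tract)
  expect_gte(h$polyt_len, cfg$polyT_len)
  expect_true(h$polya_tail)
  expect_true(h$vntr_gc_high)
  # deletion-type junction: no target site duplication across the element
  el <- ann$element_span
  lf <- substr(sim$junction$seq, 1, el[1] - 1)
  rf <- substr(sim$junction$seq, el[2] + 1, nchar(sim$junction$seq))
  expect_null(detect_tsd(lf, rf))
  # a bare copy pasted without polyT/EN context lacks those hallmarks
  bare <- paste0(rdna(300, 0.5), substr(lib[[2]]$seq, 1200, 2691),
                 rdna(300, 0.5))
  ann_b <- annotate_sva(bare, lib)
  h_b <- tprt_hallmarks(bare, ann_b)
  expect_false(h_b$en_site_at_integration)
  expect_false(h_b$polyt_tract)
})
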