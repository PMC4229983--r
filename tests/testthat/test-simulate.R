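test_that("reference contigs hit the target GC and are seed-stable", {
  cfg <- sim_config(seed = 41, contig_len = 100000L, gc_fraction = 0.5)
  r1 <- make_reference(cfg)
  r2 <- make_reference(cfg)
  expect_identical(r1$record$seq, r2$record$seq)
  expect_lt(abs(gc_content(r1$record$seq) - 0.5), 0.02)
  r3 <- make_reference(cfg, seed = 42)
  expect_false(identical(r1$record$seq, r3$record$seq))
  # extreme composition
  at <- make_reference(sim_config(seed = 1, gc_fraction = 0))
  expect_true(grepl("^[ATN]*$",
                    gsub("CTTTA", "", at$record$seq, fixed = TRUE)))
  # planted endonuclease sites are really there
  en <- r1$features[r1$features$kind == "l1_en", ]
  expect_gte(nrow(en), 3L)
  for (i in seq_len(nrow(en))) {
    expect_equal(substr(r1$record$seq, en$start[i], en$end[i]), "CTTTA")
  }
  expect_s3_class(make_reference(sim_config(seed = 1,
                                            contig_len = 10000L)),
                  "sim_reference")
  expect_error(sim_config(contig_len = 5000L))
})

test_that("planted Alu pairs realize the requested identity/orientation", {
  cfg <- sim_config(seed = 43)
  ref <- make_reference(cfg)
  set.seed(43)
  ref2 <- plant_alu_pair(ref, c(2000L, 9000L), identity = 100,
                         arm_len = 300L)
  s <- ref2$record$seq
  expect_identical(substr(s, 2000, 2299), substr(s, 9000, 9299))
  ref3 <- plant_alu_pair(ref, c(2000L, 9000L), identity = 84,
                         arm_len = 135L)
  a1 <- substr(ref3$record$seq, 2000, 2134)
  a2 <- substr(ref3$record$seq, 9000, 9134)
  mm <- sum(strsplit(a1, "")[[1]] != strsplit(a2, "")[[1]])
  realized <- 100 * (135 - mm) / 135
  expect_lt(abs(realized - 84), 3)
  feats <- ref3$features[ref3$features$kind == "alu", ]
  expect_equal(feats$identity, rep(realized, 2L))
  # inverted orientation plants a reverse-complement copy
  ref4 <- plant_alu_pair(ref, c(2000L, 9000L), identity = 100,
                         arm_len = 200L, orientation = "inverted")
  s4 <- ref4$record$seq
  expect_identical(substr(s4, 9000, 9199), revcomp(substr(s4, 2000, 2199)))
  expect_error(plant_alu_pair(ref, c(2000L, 2100L), arm_len = 300L),
               "overlap")
})

test_that("simulated junctions reproduce their planted features exactly", {
  set.seed(44)
  cfg <- sim_config(seed = 44, n_per_mechanism = 1L)
  # blunt join: junction is left flank + right flank exactly
  repeat {
    ref <- make_reference(cfg, seed = sample.int(1e6, 1))
    sim <- simulate_deletion(ref, cfg, "NHEJ")
    if (sim$truth$planted_mh_len == 0L) break
  }
  expect_identical(sim$junction$seq,
                   paste0(sim$prox_flank$seq, sim$dist_flank$seq))
  # insertion junction: truth records the template, junction contains it
  repeat {
    ref <- make_reference(cfg, seed = sample.int(1e6, 1))
    sim <- simulate_deletion(ref, cfg, "NHEJ_RBM")
    if (!is.na(sim$truth$planted_insertion)) break
  }
  ins <- sim$truth$planted_insertion
  expect_true(nchar(ins) %in% 9:11)
  expect_true(grepl(ins, sim$junction$seq, fixed = TRUE))
  expect_false(is.na(sim$truth$template_side))
  hits <- find_insertion_template(ins, sim$prox_flank$seq,
                                  sim$dist_flank$seq)
  expect_true(any(hits$source_side == sim$truth$template_side &
                    hits$offset == sim$truth$template_offset &
                    hits$strand == sim$truth$template_strand))
})

test_that("cohorts are complete, deterministic and self-consistent", {
  cfg <- sim_config(seed = 45, n_per_mechanism = 2L)
  co <- build_cohort(cfg)
  expect_length(co$junctions, 10L)
  expect_equal(nrow(co$truth), 10L)
  expect_equal(sort(unique(co$truth$mechanism)), sort(mechanism_levels))
  co2 <- build_cohort(cfg)
  expect_identical(vapply(co$junctions, `[[`, character(1), "seq"),
                   vapply(co2$junctions, `[[`, character(1), "seq"))
  co3 <- build_cohort(sim_config(seed = 46, n_per_mechanism = 2L))
  expect_false(identical(co$junctions[[1]]$seq, co3$junctions[[1]]$seq))
  # consistency: brute-force rederivation equals the planted values
  for (jid in names(co$junctions)) {
    tr <- co$truth[co$truth$junction_id == jid, ]
    o <- oracle_dissect(co$junctions[[jid]]$seq,
                        co$flanks[[paste0(jid, "__prox")]]$seq,
                        co$flanks[[paste0(jid, "__dist")]]$seq)
    # the exact-match oracle applies to junctions without planted SNCs
    if (tr$n_sncs > 0L) next
    if (is.na(tr$planted_insertion) && tr$mechanism != "SVA_INSERTION") {
      expect_equal(o$mh_len, tr$flank_mh)
      expect_null(o$insertion)
    } else if (!is.na(tr$planted_insertion)) {
      expect_equal(o$insertion, tr$planted_insertion)
    }
  }
})

test_that("TPRT junction construction follows the cleavage/polyT model", {
  cfg <- sim_config(seed = 47, n_per_mechanism = 1L)
  lib <- sva_source_library(seed = 47)
  set.seed(470)
  n_ok_cttt <- 0L
  for (k in 1:20) {
    ref <- make_reference(cfg, seed = 4700 + k)
    sim <- simulate_sva_tprt_deletion(ref, lib[[1 + k %% 2]], cfg)
    P <- sim$prox_flank$seq
    if (grepl("CTTT$", P)) n_ok_cttt <- n_ok_cttt + 1L
    # the deleted side of the reference starts with the consensus A
    e <- sim$truth$en_cleavage_pos
    expect_equal(substr(ref$record$seq, e - 3L, e + 1L), "CTTTA")
    # polyT tract of the configured length right after the flank
    expect_equal(substr(sim$junction$seq, 301L, 300L + cfg$polyT_len),
                 strrep("T", cfg$polyT_len))
    # no target site duplication by construction
    src <- lib[[1 + k %% 2]]
    expect_equal(
      nchar(sim$junction$seq),
      600L + cfg$polyT_len + src$total_len - sim$truth$sva_truncation)
  }
  expect_equal(n_ok_cttt, 20L)
  # zero truncation keeps the full source; hexamer occurs once
  ref <- make_reference(cfg, seed = 48)
  src <- lib[[2]]
  sim <- simulate_sva_tprt_deletion(ref, src, cfg, truncation = 0L)
  ins <- substr(sim$junction$seq, 301L + cfg$polyT_len,
                300L + cfg$polyT_len + src$total_len)
  expect_equal(nchar(ins), src$total_len)
  hex <- gregexpr("CCCTCTCCCTCTCCCTCTCCCTCT", ins, fixed = TRUE)[[1]]
  expect_equal(length(hex[hex > 0]), 1L)
  expect_error(simulate_sva_tprt_deletion(ref, src, cfg,
                                          truncation = src$total_len),
               "truncation")
})
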