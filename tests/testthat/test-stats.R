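test_that("deletion sizes and separations use the inclusive convention", {
  expect_equal(deletion_size(29102848, 30079302), 976455)
  expect_equal(deletion_size(28142439, 34112082), 5969644)
  expect_equal(deletion_size(5, 5), 1)
  expect_error(deletion_size(10, 5))
  expect_equal(breakpoint_separation(29100005, 29103071), 3067)
  expect_equal(breakpoint_separation(29082023, 29082032), 10)
  expect_equal(breakpoint_separation(7, 7), 1)
  expect_equal(breakpoint_separation(10, 5), breakpoint_separation(5, 10))
})

test_that("densest window matches exhaustive subset search", {
  set.seed(61)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    coords <- sample.int(1e6, n)
    k <- sample(2:n, 1)
    got <- min_span_window(coords, k)
    expect_equal(got$span, oracle_min_span(coords, k))
    expect_length(got$members, k)
  }
  expect_equal(min_span_window(c(10, 99, 3), 1L)$span, 1)
  expect_error(min_span_window(1:3, 4L), "exceeds")
  # leftmost tie-breaking
  got <- min_span_window(c(0, 10, 100, 110), 2L)
  expect_equal(got$members, c(0, 10))
})

test_that("control fragmentization tiles regions and places midpoints", {
  r300 <- data.frame(start = c(29118000, 30020000),
                     end = c(29148000, 30050000))
  f <- fragmentize_control(r300, 300L)
  expect_equal(nrow(f), 200L)
  expect_equal(unique(f$end - f$start + 1), 300)
  # hypothetical breakpoint between fragment nucleotides 150 and 151
  expect_equal(f$hypothetical_breakpoint[1] - f$start[1] + 1, 150)
  r4k <- data.frame(start = c(29118000, 30020000),
                    end = c(29210000, 30048000))
  f4 <- fragmentize_control(r4k, 4000L)
  expect_equal(nrow(f4), 30L)
  expect_equal(f4$hypothetical_breakpoint[1] - f4$start[1] + 1, 2000)
  # region shorter than the fragment yields nothing; remainders drop
  expect_equal(nrow(fragmentize_control(
    data.frame(start = 0, end = 200), 300L)), 0L)
  expect_equal(nrow(fragmentize_control(
    data.frame(start = 0, end = 1000), 300L)), 3L)
})

test_that("Fisher exact equals full enumeration and the stats oracle", {
  expect_equal(fisher_exact_two_tailed(matrix(c(1, 1, 1, 1), 2))$p_two_tailed,
               1)
  r <- fisher_exact_two_tailed(matrix(c(0, 5, 5, 0), 2, byrow = TRUE))
  expect_equal(r$p_two_tailed, 2 / 252)
  expect_equal(r$odds_ratio, 0)
  z <- fisher_exact_two_tailed(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_equal(z$p_two_tailed, 1)
  set.seed(62)
  for (i in 1:200) {
    tb <- matrix(sample(0:12, 4, replace = TRUE), 2)
    mine <- fisher_exact_two_tailed(tb)$p_two_tailed
    expect_equal(mine, oracle_fisher_p(tb[1, 1], tb[1, 2],
                                       tb[2, 1], tb[2, 2]),
                 tolerance = 1e-12)
    if (sum(tb) > 0 && all(rowSums(tb) > 0) && all(colSums(tb) > 0)) {
      expect_equal(mine, stats::fisher.test(tb)$p.value, tolerance = 1e-9)
    }
  }
})

test_that("feature overlap counting equals the naive scan", {
  set.seed(63)
  for (i in 1:20) {
    nq <- sample(5:40, 1); nf <- sample(0:30, 1)
    qs <- sample.int(5000, nq)
    queries <- data.frame(contig = sample(c("c1", "c2"), nq, TRUE),
                          start = qs, end = qs + sample(10:300, nq, TRUE))
    fs <- sample.int(5000, max(nf, 1))[seq_len(nf)]
    features <- data.frame(contig = sample(c("c1", "c2"), nf, TRUE),
                           start = fs,
                           end = fs + sample(5:500, max(nf, 1),
                                             TRUE)[seq_len(nf)])
    got <- count_feature_overlap(queries, features)
    expect_equal(got$present, oracle_overlap(queries, features))
    expect_equal(got$n_present + got$n_absent, nq)
  }
  # a constructed 22-of-30 presence set
  queries <- data.frame(contig = "c1", start = (1:30) * 1000,
                        end = (1:30) * 1000 + 299)
  features <- data.frame(contig = "c1", start = (1:22) * 1000 + 50,
                         end = (1:22) * 1000 + 120)
  got <- count_feature_overlap(queries, features)
  expect_equal(got$n_present, 22L)
  expect_equal(unname(round(100 * got$n_present / 30)), 73)
  empty <- count_feature_overlap(queries,
                                 features[0, , drop = FALSE])
  expect_equal(empty$n_present, 0L)
})

test_that("breakpoints are labeled by containing interval or gap", {
  ann <- nf1_region_annotation()
  expect_equal(locate_breakpoint_in_annotation(29102848, ann), "SUZ12P")
  expect_equal(locate_breakpoint_in_annotation(30079302, ann),
               "between RAB11FIP4 and COPRS")
  expect_equal(locate_breakpoint_in_annotation(30187273, ann),
               "between COPRS and UTP6")
  expect_error(locate_breakpoint_in_annotation(1, ann), "outside")
  recs <- nf1_deletion_fixture()
  prox_labels <- vapply(recs, function(r)
    locate_breakpoint_in_annotation(r$proximal_bp, ann), character(1))
  expect_equal(sum(prox_labels == "SUZ12P"), 11L)
  # labels match the fixture's printed locus columns row by row
  printed <- vapply(recs, `[[`, character(1), "proximal_locus_label")
  expect_equal(prox_labels, printed)
  dist_labels <- vapply(recs, function(r)
    locate_breakpoint_in_annotation(r$distal_bp, ann), character(1))
  expect_equal(dist_labels,
               vapply(recs, `[[`, character(1), "distal_locus_label"))
})
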