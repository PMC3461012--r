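lib1 <- library_preset("1kb")
lib10 <- library_preset("10kb")

test_that("resolution is the absolute predicted-truth distance", {
  expect_equal(resolution(126631843, 126631456), 387)
  expect_equal(resolution(100, 100), 0)
  expect_error(resolution(1, 2, chrom_predicted = "chr1",
                          chrom_truth = "chr2"), "chromosome")
  expect_equal(median_resolution(c(0, 115, 1205)), 115)
  expect_equal(median_resolution(tibble::tibble(resolution = c(0, 115, 1205))),
               115)
})

test_that("exact 2x2 probability reproduces the published breakpoint table", {
  # PCR-confirmed breakpoints: 38/104 large-insert-specific vs 12/138
  # shared breakpoints with resolution > 1.5 kb
  m <- matrix(c(38, 12, 66, 126), nrow = 2)
  expect_equal(fisher_exact_2x2(m), stats::fisher.test(m)$p.value,
               tolerance = 1e-10)
  expect_lt(fisher_exact_2x2(m), 1e-6)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 9, 9), 2)), 1)  # identical rows
  expect_error(fisher_exact_2x2(matrix(1:6, 2)), "2x2")
})

test_that("exact probability matches the reference implementation on random tables", {
  set.seed(20)
  for (k in 1:60) {
    m <- matrix(sample(0:12, 4, replace = TRUE), nrow = 2)
    if (sum(m) == 0 || any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact_2x2(m), stats::fisher.test(m)$p.value,
                 tolerance = 1e-10, label = sprintf("table %d", k))
  }
})

test_that("resolution contingency reports row percentages and exact p", {
  records <- dplyr::bind_rows(
    tibble::tibble(class = "10kb_specific",
                   resolution = c(rep(2000, 38), rep(100, 66))),
    tibble::tibble(class = "common",
                   resolution = c(rep(2000, 12), rep(100, 126))))
  ct <- resolution_contingency(records, threshold = 1500)
  expect_equal(round(ct$row_pct[["10kb_specific"]], 1), 36.5)
  expect_equal(round(ct$row_pct[["common"]], 1), 8.7)
  expect_lt(ct$p_value, 1e-6)
  expect_equal(unname(ct$table["10kb_specific", ]), c(38, 66))
  td <- tidy(ct)
  expect_equal(nrow(td), 2)
  expect_error(resolution_contingency(records[records$class == "common", ]),
               "two")
})

test_that("threshold boundary counts strictly above", {
  records <- tibble::tibble(class = rep(c("a", "b"), each = 2),
                            resolution = c(1500, 1501, 1500, 1499))
  ct <- resolution_contingency(records)
  expect_equal(unname(ct$table[, "above"]), c(1, 0))
})

# two-library comparison on a small simulated genome with one shared
# deletion, one small-insert-only deletion (3 kb, under the 10 kb span
# bound) and one large-insert-only deletion (masked 1.5 kb flanks that
# 1 kb fragments cannot span)
comparison_fixture <- function() {
  genome <- tibble::tibble(chrom = "chr1", length = 1e7)
  masked <- tibble::tibble(chrom = "chr1",
                           start = c(6e6 - 1500, 6.025e6),
                           end = c(6e6, 6.025e6 + 1500))
  plan <- genome_plan(genome, masked = masked)
  plan <- plant_svs(plan, list(
    sv_deletion("chr1", 2e6, 2.05e6),   # visible to both
    sv_deletion("chr1", 4e6, 4.003e6),  # 3 kb: 1 kb library only
    sv_deletion("chr1", 6e6, 6.025e6)   # masked flanks: 10 kb library only
  ))
  run_lib <- function(preset, coverage, seed) {
    lib <- library_preset(preset)
    pets <- simulate_pets(plan, sim_preset(preset, coverage = coverage),
                          seed = seed)
    pets <- deduplicate_pets(classify_pets(pets, lib))
    cl <- filter_clusters(cluster_dpets(pets, lib),
                          if (preset == "1kb") 2 else 3)
    calls <- call_svs(cl, lib)
    sc <- build_superclusters(cl, lib)
    list(calls = classify_complexity(calls, sc), clusters = cl, lib = lib)
  }
  list(ten = run_lib("10kb", 50, seed = 21), one = run_lib("1kb", 10, seed = 22))
}

test_that("cross-library matching splits common and specific SVs", {
  fx <- comparison_fixture()
  cmp <- match_across_libraries(fx$ten$calls, fx$ten$clusters,
                                fx$one$calls, fx$one$clusters,
                                fx$ten$lib, fx$one$lib)
  # the 50 kb deletion is common; the 25 kb one is 10 kb-specific (its
  # cluster count ~50 passes the raised cutoff of 6); the 3 kb one is
  # 1 kb-specific
  expect_equal(nrow(cmp$common), 1)
  common_ref <- fx$ten$calls[fx$ten$calls$sv_id == cmp$common$ref_sv_id, ]
  expect_equal(common_ref$sv_type, "deletion")
  expect_lt(abs(common_ref$bp5_1 - 2e6), 1e4)
  expect_equal(nrow(cmp$ref_specific), 1)
  expect_lt(abs(cmp$ref_specific$bp5_1 - 6e6), 1e4)
  expect_gte(min(cmp$ref_specific$count), fx$ten$lib$specific_cluster_count_min)
  expect_true(any(abs(cmp$other_specific$bp5_1 - 4e6) < 3e3))
  g <- glance(cmp)
  expect_equal(g$n_common, 1)
})

test_that("low-count unmatched reference SVs are set aside, not called specific", {
  fx <- comparison_fixture()
  ref_calls <- fx$ten$calls
  # force the 10 kb-specific candidate below the specific cutoff
  sel <- abs(ref_calls$bp5_1 - 6e6) < 1e4
  ref_calls$count[sel] <- 4L
  cmp <- match_across_libraries(ref_calls, fx$ten$clusters,
                                fx$one$calls, fx$one$clusters,
                                fx$ten$lib, fx$one$lib)
  expect_equal(nrow(cmp$ref_specific), 0)
  expect_equal(nrow(cmp$ref_low_confidence), 1)
})

test_that("an empty other library leaves all confident reference SVs specific", {
  fx <- comparison_fixture()
  empty <- fx$one$calls[0, ]
  cmp <- match_across_libraries(fx$ten$calls, fx$ten$clusters,
                                empty, fx$one$clusters[0, ],
                                fx$ten$lib, fx$one$lib)
  expect_equal(nrow(cmp$common), 0)
  expect_equal(nrow(cmp$ref_specific) + nrow(cmp$ref_low_confidence),
               nrow(fx$ten$calls))
})

test_that("disjoint chromosome sets are rejected", {
  fx <- comparison_fixture()
  other <- fx$one$calls
  other$chrom5_1 <- "chrX"; other$chrom3_1 <- "chrX"
  expect_error(match_across_libraries(fx$ten$calls, fx$ten$clusters,
                                      other, fx$one$clusters,
                                      fx$ten$lib, fx$one$lib), "disjoint")
})
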