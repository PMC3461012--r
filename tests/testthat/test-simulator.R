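lib10 <- library_preset("10kb")

test_that("planting edits the donor and records fusions at bp precision", {
  plan <- genome_plan(c(chr1 = 1e6, chr2 = 1e6))
  # no requests: donor is the reference, zero fusions
  p0 <- plant_svs(plan, list())
  expect_equal(nrow(p0$truth), 0)
  expect_equal(nrow(donor_fusions(p0)), 0)
  # one 50 kb deletion: donor shorter by 50 kb, one fusion point
  p1 <- plant_svs(plan, list(sv_deletion("chr1", 4e5, 4.5e5)))
  donor_len <- sum(vapply(p1$donor, function(d) sum(d$end - d$start),
                          numeric(1)))
  expect_equal(donor_len, 2e6 - 5e4)
  expect_equal(nrow(p1$truth), 1)
  expect_equal(p1$truth$pos5, 4e5)
  expect_equal(p1$truth$pos3, 4.5e5)
  # inter-chromosomal inverted insertion: two fusions, flipped strands
  p2 <- plant_svs(plan, list(
    sv_insertion("chr1", 4e5, 4.5e5, "chr2", 7e5, inverted = TRUE)))
  expect_equal(nrow(p2$truth), 2)
  expect_setequal(c(p2$truth$strand5, p2$truth$strand3),
                  c("+", "-", "-", "+"))
  inv_piece <- p2$donor$chr2[p2$donor$chr2$strand == "-", ]
  expect_equal(nrow(inv_piece), 1)
  expect_equal(inv_piece$chrom, "chr1")
})

test_that("overlapping or out-of-range requests are rejected", {
  plan <- genome_plan(c(chr1 = 1e6))
  expect_error(plant_svs(plan, list(sv_deletion("chr1", 1e5, 3e5),
                                    sv_inversion("chr1", 2e5, 4e5))),
               "overlapping")
  expect_error(plant_svs(plan, list(sv_deletion("chr2", 1e5, 2e5))),
               "unknown chromosome")
  expect_error(plant_svs(plan, list(sv_deletion("chr1", 1e5, 2e6))),
               "outside")
  # editing a copied region is refused
  expect_error(plant_svs(plan, list(
    sv_insertion("chr1", 1e5, 2e5, "chr1", 5e5),
    sv_deletion("chr1", 1.4e5, 1.6e5))), "copied")
})

test_that("the assembled donor agrees with the analytic truth table", {
  plan <- sim_study_plan()
  key <- function(d, p5 = "pos5", p3 = "pos3") {
    paste(d$chrom5, d[[p5]], d$strand5, d$chrom3, d[[p3]], d$strand3)
  }
  ft <- donor_fusions(plan)
  expect_setequal(key(plan$truth), key(ft))
})

test_that("an unrearranged genome yields only concordant PETs", {
  plan <- plant_svs(genome_plan(c(chr1 = 5e6)), list())
  pets <- simulate_pets(plan, sim_preset("10kb", coverage = 5,
                                         chimera_rate = 0,
                                         duplicate_rate = 0), seed = 4)
  pets <- classify_pets(pets, lib10)
  expect_gt(nrow(pets), 1000)
  expect_equal(unique(pets$status), "concordant")
})

test_that("emitted spans recover the configured fragment distribution", {
  plan <- plant_svs(genome_plan(c(chr1 = 2e7)), list())
  cfg <- sim_preset("10kb", coverage = 10, chimera_rate = 0,
                    duplicate_rate = 0)
  pets <- classify_pets(simulate_pets(plan, cfg, seed = 8), lib10)
  st <- span_stats(pets, lib10)
  se <- cfg$frag_sd / sqrt(st$n)
  expect_lt(abs(st$mean - cfg$frag_mean), 3 * se + 1)
  expect_lt(abs(st$sd - cfg$frag_sd), 0.05 * cfg$frag_sd)
  # and the physical-coverage contract holds within 5%
  expect_lt(abs(physical_coverage(pets, 2e7) - 10) / 10, 0.05)
})

test_that("chimeric ligation produces the configured discordant fraction", {
  plan <- plant_svs(genome_plan(c(chr1 = 1e7, chr2 = 1e7)), list())
  cfg <- sim_preset("10kb", coverage = 5, chimera_rate = 0.05,
                    duplicate_rate = 0)
  pets <- classify_pets(simulate_pets(plan, cfg, seed = 9), lib10)
  n <- nrow(pets)
  frac <- mean(pets$status == "discordant")
  # most chimeras are discordant; a few land concordant-like by chance
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n) + 0.005)
})

test_that("PCR duplicates are re-emitted and removed by deduplication", {
  plan <- plant_svs(genome_plan(c(chr1 = 5e6)), list())
  cfg <- sim_preset("10kb", coverage = 5, chimera_rate = 0,
                    duplicate_rate = 0.2)
  pets <- simulate_pets(plan, cfg, seed = 10)
  dd <- deduplicate_pets(pets)
  expect_lt(nrow(dd), nrow(pets))
  expect_gt(nrow(pets) / nrow(dd), 1.1)
})

test_that("simulation is reproducible under a fixed seed", {
  plan <- sim_study_plan()
  cfg <- sim_preset("10kb", coverage = 1)
  a <- simulate_pets(plan, cfg, seed = 123)
  b <- simulate_pets(plan, cfg, seed = 123)
  expect_identical(a, b)
  c <- simulate_pets(plan, cfg, seed = 124)
  expect_false(identical(a, c))
})

test_that("a planted deletion cluster count tracks physical coverage", {
  plan <- plant_svs(genome_plan(c(chr1 = 5e6)),
                    list(sv_deletion("chr1", 2e6, 2.1e6)))
  pets <- simulate_pets(plan, sim_preset("10kb", coverage = 60), seed = 11)
  pets <- deduplicate_pets(classify_pets(pets, lib10))
  cl <- filter_clusters(cluster_dpets(pets, lib10), 3)
  expect_equal(nrow(cl), 1)
  expect_lt(abs(cl$count - 60), 3 * sqrt(60))
  # predicted breakpoints within one nominal insert of the truth
  expect_lt(abs(cl$bp5 - 2e6), lib10$nominal_insert)
  expect_lt(abs(cl$bp3 - 2.1e6), lib10$nominal_insert)
})

test_that("masked tracts longer than the insert defeat short fragments only", {
  masked <- tibble::tibble(chrom = "chr1",
                           start = c(2e6 - 1500, 2.05e6),
                           end = c(2e6, 2.05e6 + 1500))
  plan <- plant_svs(genome_plan(tibble::tibble(chrom = "chr1", length = 5e6),
                                masked = masked),
                    list(sv_deletion("chr1", 2e6, 2.05e6)))
  lib1 <- library_preset("1kb")
  p1 <- deduplicate_pets(classify_pets(
    simulate_pets(plan, sim_preset("1kb", coverage = 8), seed = 12), lib1))
  cl1 <- filter_clusters(cluster_dpets(p1, lib1), 3)
  expect_equal(nrow(cl1), 0)  # 1 kb fragments cannot span the masks
  p10 <- deduplicate_pets(classify_pets(
    simulate_pets(plan, sim_preset("10kb", coverage = 30), seed = 12), lib10))
  cl10 <- filter_clusters(cluster_dpets(p10, lib10), 3)
  expect_equal(nrow(cl10), 1)  # 10 kb fragments reach across
})

test_that("truth_report matches calls to fusions and scores recall", {
  plan <- plant_svs(genome_plan(c(chr1 = 5e6)),
                    list(sv_deletion("chr1", 2e6, 2.1e6)))
  pets <- deduplicate_pets(classify_pets(
    simulate_pets(plan, sim_preset("10kb", coverage = 40), seed = 13), lib10))
  calls <- call_svs(filter_clusters(cluster_dpets(pets, lib10), 3), lib10)
  rep <- truth_report(plan$truth, calls, window = lib10$nominal_insert)
  expect_equal(rep$recall, 1)
  expect_equal(rep$precision, 1)
  expect_true(all(rep$resolution_records$resolution <= lib10$nominal_insert))
  # empty calls give zero recall
  rep0 <- truth_report(plan$truth, calls[0, ], window = lib10$nominal_insert)
  expect_equal(rep0$recall, 0)
})
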