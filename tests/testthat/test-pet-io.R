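lib1 <- library_preset("1kb")
lib10 <- library_preset("10kb")

test_that("library presets carry the documented span bounds", {
  expect_equal(library_preset("1kb")$span_max, 3000)
  expect_equal(library_preset("10kb")$span_max, 20000)
  expect_equal(library_preset("20kb")$span_max, 40000)
  expect_error(pet_library("x", 1000, span_max = 500, span_min = 600),
               "span_min")
  expect_error(pet_library("x", 1000, 3000, cluster_count_min = 3,
                           specific_cluster_count_min = 2), "specific")
})

test_that("PET tables parse, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# comment",
    "r1\tchr1\t100\t125\t+\tchr1\t900\t925\t+",
    "r2\tchr2\t500\t400\t+\tchr2\t900\t925\t+",   # end < start
    "r3\tchr1\t100\t125\t*\tchr1\t900\t925\t+",   # bad strand
    "r4\tchr1\t100\t125\t-\tchr2\t900\t925\t-"
  ), f)
  expect_warning(pets <- read_pet_table(f), "2 malformed")
  expect_equal(nrow(pets), 2)
  expect_equal(attr(pets, "rejected"), c(3L, 4L))
  expect_equal(pets$start5[1], 100)
  expect_equal(pets$strand3[2], "-")

  out <- withr::local_tempfile(fileext = ".tsv")
  write_pet_table(pets, out)
  again <- read_pet_table(out)
  expect_equal(as.data.frame(again), as.data.frame(pets),
               ignore_attr = TRUE)

  # BEDPE column order
  outb <- withr::local_tempfile(fileext = ".bedpe")
  write_pet_table(pets, outb, format = "bedpe")
  againb <- read_pet_table(outb, format = "bedpe")
  expect_equal(againb$read_id, pets$read_id)
  expect_equal(againb$start3, pets$start3)
})

test_that("empty and single-line files parse to the matching tables", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f)
  expect_equal(nrow(read_pet_table(f)), 0)
  writeLines("only\tchr1\t10\t35\t+\tchr1\t800\t825\t+", f)
  one <- read_pet_table(f)
  expect_equal(nrow(one), 1)
  expect_equal(one$end3, 825)
})

test_that("concordance needs same chromosome, orientation, order and span", {
  mk <- function(s5, e5, st5, s3, e3, st3, c5 = "chr1", c3 = "chr1") {
    classify_pets(pet_tbl("r", c5, s5, e5, st5, c3, s3, e3, st3), lib1)$status
  }
  # 1 kb library, same chrom/strand/order, span 800 -> concordant
  expect_equal(mk(1000, 1025, "+", 1775, 1800, "+"), "concordant")
  # different chromosomes -> discordant
  expect_equal(mk(1000, 1025, "+", 1775, 1800, "+", c3 = "chr2"), "discordant")
  # opposite strands -> discordant
  expect_equal(mk(1000, 1025, "+", 1775, 1800, "-"), "discordant")
  # wrong order (3' upstream on +) -> discordant
  expect_equal(mk(1775, 1800, "+", 1000, 1025, "+"), "discordant")
  # minus-strand correct order: 5' tag downstream
  expect_equal(mk(1775, 1800, "-", 1000, 1025, "-"), "concordant")
})

test_that("concordant span bound is inclusive at both ends", {
  span_status <- function(span) {
    classify_pets(pet_tbl("r", "chr1", 0, 25, "+", "chr1", span - 25, span,
                          "+"), lib1)$status
  }
  expect_equal(span_status(2999), "concordant")
  expect_equal(span_status(3000), "concordant")
  expect_equal(span_status(3001), "discordant")
  # classification is a total partition
  set.seed(42)
  n <- 200
  s5 <- floor(runif(n, 0, 1e5))
  s3 <- floor(runif(n, 0, 1e5))
  pets <- pet_tbl(sprintf("r%d", 1:n), "chr1", s5, s5 + 25,
                  sample(c("+", "-"), n, TRUE), "chr1", s3, s3 + 25,
                  sample(c("+", "-"), n, TRUE))
  st <- classify_pets(pets, lib1)$status
  expect_true(all(st %in% c("concordant", "discordant")))
})

test_that("deduplication keys on the exact coordinate tuple", {
  pets <- pet_tbl(c("a", "b", "c"), "chr1", c(100, 100, 101), c(125, 125, 126),
                  "+", "chr1", c(900, 900, 900), c(925, 925, 925), "+")
  dd <- deduplicate_pets(pets)
  expect_equal(dd$read_id, c("a", "c"))  # first occurrence kept
  expect_equal(deduplicate_pets(dd), dd)  # idempotent
  expect_equal(nrow(deduplicate_pets(pets[0, ])), 0)
})

test_that("downsampling is binomial, seeded and bounded", {
  n <- 20000
  s <- floor(runif(n, 0, 1e7))
  pets <- pet_tbl(sprintf("r%d", 1:n), "chr1", s, s + 25, "+",
                  "chr1", s + 900, s + 925, "+")
  expect_equal(nrow(downsample_pets(pets, n, seed = 1)), n)
  expect_equal(nrow(downsample_pets(pets, 0, seed = 1)), 0)
  expect_error(downsample_pets(pets, n + 1), "between")
  a <- downsample_pets(pets, n / 2, seed = 7)
  b <- downsample_pets(pets, n / 2, seed = 7)
  expect_identical(a, b)
  # retained count within 3 binomial SDs of the target
  expect_lt(abs(nrow(a) - n / 2), 3 * sqrt(n * 0.5 * 0.5))
})

test_that("span statistics summarise concordant spans only", {
  spans <- c(900, 1000, 1100)
  pets <- pet_tbl(sprintf("r%d", 1:3), "chr1", 0, 25, "+",
                  "chr1", spans - 25, spans, "+")
  pets <- classify_pets(pets, lib1)
  st <- span_stats(pets, lib1)
  expect_equal(st$median, 1000)
  expect_equal(st$mean, 1000)
  expect_equal(st$n, 3)
  one <- classify_pets(pet_tbl("r", "chr1", 0, 25, "+", "chr1", 975, 1000,
                               "+"), lib1)
  s1 <- span_stats(one, lib1)
  expect_equal(s1$median, 1000)
  expect_equal(s1$sd, 0)
  disc <- classify_pets(pet_tbl("r", "chr1", 0, 25, "+", "chr2", 975, 1000,
                                "+"), lib1)
  expect_error(span_stats(disc, lib1), "no concordant")
})

test_that("physical coverage is summed span over genome length", {
  s <- seq(0, 9e4, by = 1e4)
  pets <- classify_pets(
    pet_tbl(sprintf("r%d", 1:10), "chr1", s, s + 25, "+",
            "chr1", s + 9975, s + 10000, "+"), lib10)
  expect_equal(physical_coverage(pets, 1e5), 1.0)
  expect_equal(physical_coverage(pets[0, ], 1e5), 0)
  expect_error(physical_coverage(pets, 0), "genome_length")
})

test_that("SAM importer pairs primary mate-pair records", {
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:100000",
    # flags: 0x1|0x40 = 65 first-in-pair fwd; 0x1|0x80 = 129 second fwd
    paste("q1", 65, "chr1", 101, 60, "25M", "=", 1001, 0,
          strrep("A", 25), "*", sep = "\t"),
    paste("q1", 129, "chr1", 1001, 60, "25M", "=", 101, 0,
          strrep("A", 25), "*", sep = "\t")
  ), f)
  pets <- read_pets_sam(f)
  expect_equal(nrow(pets), 1)
  expect_equal(pets$start5, 100)  # converted to 0-based
  expect_equal(pets$start3, 1000)
  expect_equal(pets$strand5, "+")
})
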