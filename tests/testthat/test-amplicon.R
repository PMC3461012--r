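lib10 <- library_preset("10kb")

# deterministic concordant fragments tiling a genome: `per_pos` fragments
# of length `flen` starting every `step` bp
tiled_pets <- function(chrom, len, flen = 10000, step = 1000,
                       skip = NULL) {
  starts <- seq(0, len - flen, by = step)
  if (!is.null(skip)) {
    starts <- starts[!(starts + flen > skip[1] & starts < skip[2])]
  }
  pet_tbl(sprintf("%s_%d", chrom, seq_along(starts)),
          chrom, starts, starts + 25, "+",
          chrom, starts + flen - 25, starts + flen, "+")
}

test_that("copy number normalises depth to the genome-wide median", {
  genome <- tibble::tibble(chrom = "chr1", length = 1e6)
  pets <- classify_pets(tiled_pets("chr1", 1e6), lib10)
  tr <- coverage_track(pets, genome, bin_size = 10000)
  inner <- tr[tr$bin_start >= 2e4 & tr$bin_end <= 9.8e5, ]
  # uniform depth equal to the median: copy number 2 everywhere
  expect_true(all(abs(inner$copy_number - 2) < 0.11))
  # a region at 2.5x the median depth has copy number 5: baseline bins see
  # 20 overlapping fragments (20 kb catchment / 1 kb step); 3 extra copies
  # every 2 kb add 30 more
  s <- rep(seq(4.9e5, 6.0e5, by = 2000), times = 3)
  extra <- classify_pets(dplyr::bind_rows(
    tiled_pets("chr1", 1e6),
    pet_tbl(sprintf("e%d", seq_along(s)), "chr1", s, s + 25, "+",
            "chr1", s + 9975, s + 10000, "+")), lib10)
  tr2 <- coverage_track(extra, genome, bin_size = 10000)
  amp_bins <- tr2[tr2$bin_start >= 5.2e5 & tr2$bin_end <= 5.8e5, ]
  expect_true(all(abs(amp_bins$copy_number - 5) < 0.5))
  expect_error(coverage_track(extra[0, ], genome), "median")
})

test_that("contigs split at cluster breakpoints and zero-coverage runs", {
  genome <- tibble::tibble(chrom = "chr1", length = 1e6)
  # full coverage, no clusters: one contig per chromosome
  pets <- classify_pets(tiled_pets("chr1", 1e6), lib10)
  tr <- coverage_track(pets, genome, bin_size = 10000)
  c0 <- segment_contigs(tibble::tibble(chrom5 = character(0),
                                       bp5 = numeric(0),
                                       chrom3 = character(0),
                                       bp3 = numeric(0)), tr)
  expect_equal(nrow(c0), 1)
  expect_equal(c0$end - c0$start, 1e6)
  # one deletion cluster: three contigs (left, deleted, right)
  cl <- toy_cluster(1, "chr1", 4e5, "+", "chr1", 5e5, "+")
  c1 <- segment_contigs(cl, tr)
  expect_equal(nrow(c1), 3)
  expect_equal(c1$start, c(0, 4e5, 5e5))
  # an internal zero-coverage run adds boundaries at its ends
  gap_pets <- classify_pets(tiled_pets("chr1", 1e6, skip = c(6e5, 7e5)),
                            lib10)
  tr_gap <- coverage_track(gap_pets, genome, bin_size = 10000)
  c2 <- segment_contigs(tibble::tibble(chrom5 = character(0),
                                       bp5 = numeric(0),
                                       chrom3 = character(0),
                                       bp3 = numeric(0)), tr_gap)
  expect_equal(nrow(c2), 3)
  expect_true(any(c2$start == 6e5))
  expect_true(any(c2$end == 7e5))
})

test_that("reference edges require straddling concordant fragments", {
  genome <- tibble::tibble(chrom = "chr1", length = 1e6)
  gap_pets <- classify_pets(tiled_pets("chr1", 1e6, skip = c(6e5, 7e5)),
                            lib10)
  tr <- coverage_track(gap_pets, genome, bin_size = 10000)
  cl <- toy_cluster(1, "chr1", 2e5, "+", "chr1", 3e5, "+")
  contigs <- segment_contigs(cl, tr)
  g <- build_genome_graph(contigs, cl, gap_pets)
  # junction at the cluster breakpoints is straddled by concordant
  # fragments; the zero-coverage junctions are not
  junctions <- g$ref_edges$junction
  expect_true(2e5 %in% junctions)
  expect_true(3e5 %in% junctions)
  expect_false(6e5 %in% junctions)
  expect_false(7e5 %in% junctions)
  # one dPET edge per cluster, weighted by its count
  expect_equal(nrow(g$dpet_edges), 1)
  expect_equal(g$dpet_edges$weight, cl$count)
  # fused ends follow the anchor strands
  expect_equal(g$dpet_edges$end5, "high")
  expect_equal(g$dpet_edges$end3, "low")
  # and the 5' endpoint is the contig ending at the breakpoint
  expect_equal(contigs$end[contigs$contig_id == g$dpet_edges$contig5], 2e5)
})

# small synthetic genome graph built directly
toy_graph <- function(cn, ref_pairs, dpet, chrom = "chrT") {
  n <- length(cn)
  contigs <- tibble::tibble(
    contig_id = seq_len(n), chrom = chrom,
    start = (seq_len(n) - 1) * 1e5, end = seq_len(n) * 1e5,
    copy_number = cn, amplified = round(cn) > 2)
  ref_edges <- tibble::tibble(
    contig_a = vapply(ref_pairs, `[`, 0L, 1),
    contig_b = vapply(ref_pairs, `[`, 0L, 2),
    chrom = chrom, junction = 0, support = 1)
  dpet_edges <- tibble::tibble(
    edge_id = seq_along(dpet),
    cluster_id = seq_along(dpet),
    contig5 = vapply(dpet, function(d) as.integer(d[1]), 0L),
    end5 = "high",
    contig3 = vapply(dpet, function(d) as.integer(d[2]), 0L),
    end3 = "low",
    weight = vapply(dpet, function(d) as.numeric(d[3]), 0))
  structure(list(contigs = contigs, ref_edges = ref_edges,
                 dpet_edges = dpet_edges), class = "genome_graph")
}

test_that("amplicon growth collects amplified neighbours from the seed", {
  # contigs A,B,C all copy number 5; dPET edge A-C; reference edges A-B, B-C
  g <- toy_graph(cn = c(5, 5, 5), ref_pairs = list(c(1L, 2L), c(2L, 3L)),
                 dpet = list(c(1, 3, 10)))
  amps <- grow_amplicons(g)
  expect_length(amps, 1)
  expect_equal(amps[[1]]$contigs, c(1L, 2L, 3L))
  expect_equal(amps[[1]]$seed_edge, 1L)
})

test_that("neighbours at copy number exactly 2 are not added", {
  g <- toy_graph(cn = c(5, 2, 5, 5), ref_pairs = list(c(1L, 2L), c(2L, 3L)),
                 dpet = list(c(1, 4, 10), c(3, 4, 5)))
  amps <- grow_amplicons(g)
  expect_length(amps, 1)
  expect_false(2L %in% amps[[1]]$contigs)
  expect_equal(sort(amps[[1]]$contigs), c(1L, 3L, 4L))
})

test_that("grown graphs with two contigs or fewer are discarded", {
  g <- toy_graph(cn = c(5, 5, 2), ref_pairs = list(c(2L, 3L)),
                 dpet = list(c(1, 2, 10)))
  expect_length(grow_amplicons(g), 0)
})

test_that("growth matches the exhaustive fixpoint oracle on random graphs", {
  for (seed in 1:120) {
    set.seed(seed)
    n <- sample(3:10, 1)
    cn <- sample(c(1, 2, 3, 5, 8), n, replace = TRUE)
    n_ref <- sample(0:(n - 1), 1)
    ref_pairs <- if (n_ref > 0) {
      lapply(seq_len(n_ref), function(i) sort(sample.int(n, 2)))
    } else list()
    n_dpet <- sample(1:min(15, n * 2), 1)
    ws <- sample(1:100, n_dpet)  # unique weights: unambiguous seed order
    dpet <- lapply(seq_len(n_dpet), function(i) {
      c(sample.int(n, 2), ws[i])
    })
    g <- toy_graph(cn, ref_pairs, dpet)
    amps <- grow_amplicons(g)

    # every dPET edge belongs to at most one amplicon
    all_edges <- unlist(lapply(amps, `[[`, "dpet_edges"))
    expect_equal(anyDuplicated(all_edges), 0)

    # first amplicon's membership equals the oracle fixpoint from the
    # heaviest seed
    heaviest <- which.max(g$dpet_edges$weight)
    want <- oracle_grow_once(
      g$contigs$contig_id, setNames(cn, g$contigs$contig_id),
      ref_pairs,
      lapply(seq_len(n_dpet), function(i)
        c(g$dpet_edges$contig5[i], g$dpet_edges$contig3[i])),
      c(g$dpet_edges$contig5[heaviest], g$dpet_edges$contig3[heaviest]))
    if (length(want) > 2) {
      expect_true(length(amps) >= 1, label = sprintf("seed %d emits", seed))
      expect_equal(amps[[1]]$contigs, want,
                   label = sprintf("seed %d members", seed))
      expect_equal(amps[[1]]$seed_edge, g$dpet_edges$edge_id[heaviest],
                   label = sprintf("seed %d seed", seed))
    }
    # amplicons are connected and their dPET edges come from the input
    for (a in amps) {
      expect_true(all(a$dpet_edges %in% g$dpet_edges$edge_id))
      expect_gt(length(a$contigs), 2)
    }
  }
})

test_that("graph exports are well-formed text", {
  g <- toy_graph(cn = c(5, 5, 5), ref_pairs = list(c(1L, 2L)),
                 dpet = list(c(1, 3, 10)))
  f <- withr::local_tempfile(fileext = ".dot")
  write_dot(g, f)
  lines <- readLines(f)
  expect_match(lines[1], "digraph")
  expect_equal(sum(grepl("->", lines, fixed = TRUE)), 2)
  skip_if_not_installed("igraph")
  ig <- as_igraph(g)
  expect_equal(igraph::vcount(ig), 3)
  expect_equal(igraph::ecount(ig), 2)
})

test_that("bedGraph and BED exports round numbers per bin and contig", {
  genome <- tibble::tibble(chrom = "chr1", length = 1e5)
  pets <- classify_pets(tiled_pets("chr1", 1e5, flen = 10000, step = 2000),
                        lib10)
  tr <- coverage_track(pets, genome, bin_size = 10000)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  expect_equal(length(readLines(f)), nrow(tr) + 1)
  contigs <- segment_contigs(tibble::tibble(chrom5 = character(0),
                                            bp5 = numeric(0),
                                            chrom3 = character(0),
                                            bp3 = numeric(0)), tr)
  b <- withr::local_tempfile(fileext = ".bed")
  write_contigs_bed(contigs, b)
  expect_equal(length(readLines(b)), nrow(contigs))
})
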