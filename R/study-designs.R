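#' Built-in simulation study designs
#'
#' A fixed synthetic study used throughout the package's benchmarks: a
#' 50 Mb genome (five 9 Mb chromosomes plus a 5 Mb contrast chromosome)
#' carrying a 30-event panel that covers the six base SV types and all
#' eight insertion sub-types, plus a contrast set that reproduces the two
#' qualitative insert-size phenomena — small deletions visible only to
#' short-insert libraries, and a deletion flanked by 1.5 kb unmappable
#' tracts visible only to large-insert libraries.
#'
#' Event sizes are chosen so every panel SV is detectable by a 10 kb
#' library (deletion sizes above the 20 kb concordant-span bound; inserted
#' segments of 80 kb so the two junction clusters of an insertion are
#' unambiguous at the 20 kb pairing window) and events are spaced several
#' hundred kb apart so superclustering leaves them isolated.
#'
#' `sim_study_plan()` assembles the planted plan; the panel SV ids are
#' `1:30` (attribute `main_sv_ids`), the contrast deletions follow
#' (attribute `contrast_sv_ids`, with sub-attributes naming the small and
#' masked deletions).
#'
#' @return `sim_study_genome()`: a genome tibble. `sim_study_masked()`:
#'   masked-tract tibble. `sim_study_panel()`, `sim_contrast_panel()`:
#'   lists of [sv_requests]. `sim_study_plan()`: a planted
#'   [genome_plan()].
#' @name study_designs
NULL

M <- function(x) x * 1e6

#' @rdname study_designs
#' @export
sim_study_genome <- function() {
  tibble(chrom = paste0("chr", 1:6),
         length = c(rep(9e6, 5), 5e6))
}

#' @rdname study_designs
#' @export
sim_study_masked <- function() {
  # 1.5 kb unmappable tracts flanking both breakpoints of the masked
  # contrast deletion chr6:4.00-4.05 Mb
  tibble(chrom = "chr6",
         start = c(M(4.0) - 1500, M(4.05)),
         end = c(M(4.0), M(4.05) + 1500))
}

#' @rdname study_designs
#' @export
sim_study_panel <- function() {
  list(
    # deletions (7)
    sv_deletion("chr1", M(1.00), M(1.05)),
    sv_deletion("chr1", M(2.00), M(2.08)),
    sv_deletion("chr1", M(3.00), M(3.12)),
    sv_deletion("chr2", M(1.00), M(1.03)),
    sv_deletion("chr2", M(2.00), M(2.25)),
    sv_deletion("chr3", M(1.00), M(1.50)),
    sv_deletion("chr4", M(3.00), M(3.05)),
    # tandem duplications (4)
    sv_tandem_duplication("chr1", M(4.00), M(4.06)),
    sv_tandem_duplication("chr2", M(3.00), M(3.04)),
    sv_tandem_duplication("chr3", M(2.00), M(2.10)),
    sv_tandem_duplication("chr4", M(1.00), M(1.05)),
    # inversions (4)
    sv_inversion("chr1", M(5.00), M(5.20)),
    sv_inversion("chr2", M(4.00), M(4.08)),
    sv_inversion("chr3", M(3.00), M(3.50)),
    sv_inversion("chr4", M(2.00), M(2.06)),
    # the eight insertion sub-types
    sv_insertion("chr5", M(1.00), M(1.08), "chr5", M(1.30)),
    sv_insertion("chr5", M(2.00), M(2.08), "chr5", M(1.70)),
    sv_insertion("chr5", M(2.60), M(2.68), "chr5", M(2.90), inverted = TRUE),
    sv_insertion("chr5", M(3.60), M(3.68), "chr5", M(3.30), inverted = TRUE),
    sv_insertion("chr5", M(4.20), M(4.28), "chr5", M(4.50), cut = TRUE),
    sv_insertion("chr5", M(5.00), M(5.08), "chr5", M(5.30), inverted = TRUE,
                 cut = TRUE),
    sv_insertion("chr2", M(7.60), M(7.68), "chr3", M(4.50)),
    sv_insertion("chr4", M(8.00), M(8.08), "chr1", M(7.80), inverted = TRUE),
    # translocations (4); applied after intra edits
    sv_translocation("chr4", M(5.00), "chr5", M(5.80)),
    sv_translocation("chr3", M(8.00), "chr1", M(7.00)),
    sv_translocation("chr2", M(6.00), "chr3", M(6.00), balanced = TRUE),
    sv_translocation("chr4", M(7.00), "chr5", M(7.00), balanced = TRUE),
    # terminal fold-backs (unpaired inversions), applied last
    sv_unpaired_inversion("chr1", M(8.55), M(8.60)),
    sv_unpaired_inversion("chr2", M(8.70), M(8.74)),
    sv_unpaired_inversion("chr5", M(8.80), M(8.85))
  )
}

#' @rdname study_designs
#' @export
sim_contrast_panel <- function() {
  list(
    # small deletions (2.5 / 3 / 4 kb): below the 10 kb library's span
    # bound, visible only to the 1 kb library
    sv_deletion("chr6", M(1.00), M(1.00) + 2500),
    sv_deletion("chr6", M(2.00), M(2.00) + 3000),
    sv_deletion("chr6", M(3.00), M(3.00) + 4000),
    # 50 kb deletion whose breakpoints are flanked by 1.5 kb masked
    # tracts: 1 kb fragments cannot place a tag outside the masks
    sv_deletion("chr6", M(4.00), M(4.05))
  )
}

#' @rdname study_designs
#' @param include_contrast Plant the contrast deletions as well?
#' @export
sim_study_plan <- function(include_contrast = TRUE) {
  plan <- genome_plan(sim_study_genome(),
                      masked = if (include_contrast) sim_study_masked())
  panel <- sim_study_panel()
  contrast <- if (include_contrast) sim_contrast_panel() else list()
  plan <- plant_svs(plan, c(panel, contrast))
  attr(plan, "main_sv_ids") <- seq_along(panel)
  attr(plan, "contrast_sv_ids") <- length(panel) + seq_along(contrast)
  attr(plan, "small_deletion_sv_ids") <- length(panel) + seq_len(3)
  attr(plan, "masked_deletion_sv_id") <- length(panel) + 4L
  plan
}

#' Simulated multi-chromosome amplicon plan
#'
#' A focal amplification spanning three chromosomes, mimicking the
#' architecture of a fusion-gene amplicon in a leukemia-like genome: a
#' dominant fusion joining two segments (present in `dominant_copies`
#' copies, so its dPET cluster is about ten times heavier than the
#' satellites) plus a satellite derivative linking further amplified
#' segments on a third chromosome (`satellite_copies` copies). Used to
#' exercise fusion-point-guided concatenation: the first amplicon graph
#' must seed at the dominant fusion and collect all connected amplified
#' contigs.
#'
#' @param dominant_copies,satellite_copies Copy counts of the two
#'   derivative chromosomes (defaults 20 and 2).
#' @return A planted [genome_plan()] over three 5 Mb chromosomes with
#'   attribute `dominant_fusion` (tibble with the fusion coordinates).
#' @export
sim_amplicon_plan <- function(dominant_copies = 20L, satellite_copies = 2L) {
  genome <- tibble(chrom = paste0("chr", 1:3), length = rep(5e6, 3))
  plan <- genome_plan(genome)
  # dominant fusion: chr1 segment joined to chr2 segment
  dom <- tibble(chrom = c("chr1", "chr2"),
                start = c(M(1.0), M(2.0)), end = c(M(1.4), M(2.3)),
                strand = "+")
  # satellites: the amplified chr2 segment linked onward to two chr3
  # segments (junctions chr2-chr3 and chr3-chr3)
  sat <- tibble(chrom = c("chr2", "chr3", "chr3"),
                start = c(M(2.0), M(1.0), M(3.0)),
                end = c(M(2.3), M(1.2), M(4.0)),
                strand = "+")
  plan <- plant_svs(plan, list(
    sv_derivative(dom, copies = dominant_copies),
    sv_derivative(sat, copies = satellite_copies)
  ))
  attr(plan, "dominant_fusion") <- tibble(
    chrom5 = "chr1", pos5 = M(1.4), chrom3 = "chr2", pos3 = M(2.0))
  plan
}
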