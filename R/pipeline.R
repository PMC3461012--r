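#' Run the full SV detection pipeline
#'
#' Orchestrates classify, deduplicate, cluster, count-filter, (optionally)
#' coverage estimation, SV calling, superclustering and complexity
#' labelling, and (optionally) amplicon reconstruction, collecting
#' per-stage record counts in a run manifest. Total non-redundant PETs
#' always split exactly into concordant plus discordant.
#'
#' @param pets PET tibble (raw; will be classified and deduplicated).
#' @param config [pet_library()] configuration.
#' @param min_count Cluster-count cutoff (default: the library's
#'   `cluster_count_min`).
#' @param genome Optional genome tibble (`chrom`, `length`); enables the
#'   coverage track, coverage-aware insertion sub-typing, and amplicon
#'   reconstruction.
#' @param bin_size Coverage bin width in bp.
#' @param amplicons Grow amplicon graphs (needs `genome`)?
#' @return An object of class `pet_pipeline`: list with `pets` (classified,
#'   deduplicated), `clusters` (filtered), `calls`, `superclusters`,
#'   `coverage`, `contigs`, `graph`, `amplicons`, `manifest`.
#' @examples
#' plan <- sim_study_plan(include_contrast = FALSE)
#' lib <- library_preset("10kb")
#' pets <- simulate_pets(plan, sim_preset("10kb", coverage = 5), seed = 7)
#' \donttest{
#' run <- run_pet_pipeline(pets, lib)
#' glance(run)
#' }
#' @export
run_pet_pipeline <- function(pets, config, min_count = NULL, genome = NULL,
                             bin_size = 10000, amplicons = !is.null(genome)) {
  min_count <- min_count %||% config$cluster_count_min
  if (amplicons && is.null(genome)) {
    abort("amplicon reconstruction needs a genome table")
  }
  counts <- list(input = nrow(pets))

  pets <- classify_pets(pets, config)
  pets <- deduplicate_pets(pets)
  counts$nonredundant <- nrow(pets)
  counts$concordant <- sum(pets$status == "concordant")
  counts$discordant <- sum(pets$status == "discordant")

  coverage <- NULL
  if (!is.null(genome)) {
    coverage <- coverage_track(pets, genome, bin_size = bin_size)
  }

  clusters_all <- cluster_dpets(pets, config)
  counts$clusters <- nrow(clusters_all)
  clusters <- filter_clusters(clusters_all, min_count)
  counts$clusters_filtered <- nrow(clusters)
  counts$dpets_in_filtered_clusters <- sum(clusters$count)

  calls <- call_svs(clusters, config, coverage = coverage)
  superclusters <- build_superclusters(clusters, config)
  calls <- classify_complexity(calls, superclusters)
  counts$svs <- nrow(calls)

  contigs <- NULL; graph <- NULL; amp <- NULL
  if (amplicons) {
    contigs <- segment_contigs(clusters, coverage)
    graph <- build_genome_graph(contigs, clusters, pets)
    amp <- grow_amplicons(graph)
    counts$amplicon_graphs <- length(amp)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("petsv")),
    library = unclass(config),
    min_count = min_count,
    bin_size = bin_size,
    input_hash = rlang::hash(pets[, pet_cols]),
    counts = counts
  )
  structure(
    list(pets = pets, clusters = clusters, calls = calls,
         superclusters = superclusters, coverage = coverage,
         contigs = contigs, graph = graph, amplicons = amp,
         manifest = manifest),
    class = "pet_pipeline"
  )
}

#' @export
print.pet_pipeline <- function(x, ...) {
  cn <- x$manifest$counts
  cat(sprintf("<pet_pipeline '%s'>\n", x$manifest$library$name))
  cat(sprintf("  NR PETs %d = %d cPET (%.1f%%) + %d dPET (%.1f%%)\n",
              cn$nonredundant, cn$concordant,
              100 * cn$concordant / max(cn$nonredundant, 1),
              cn$discordant, 100 * cn$discordant / max(cn$nonredundant, 1)))
  cat(sprintf("  clusters %d (>= count %d: %d), SV calls %d\n",
              cn$clusters, x$manifest$min_count, cn$clusters_filtered,
              cn$svs))
  invisible(x)
}

#' @describeIn run_pet_pipeline The SV call table of a run.
#' @param x A `pet_pipeline` object.
#' @param ... Unused.
#' @export
tidy.pet_pipeline <- function(x, ...) x$calls

#' @describeIn run_pet_pipeline One-row stage-count summary
#'   (Table-1-style: NR PETs, cPET/dPET counts and percentages, clusters,
#'   calls).
#' @export
glance.pet_pipeline <- function(x, ...) {
  cn <- x$manifest$counts
  tibble(
    library = x$manifest$library$name,
    n_pets = cn$input, n_nonredundant = cn$nonredundant,
    n_concordant = cn$concordant, n_discordant = cn$discordant,
    pct_discordant = 100 * cn$discordant / max(cn$nonredundant, 1),
    n_clusters = cn$clusters, n_clusters_filtered = cn$clusters_filtered,
    n_svs = cn$svs
  )
}
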