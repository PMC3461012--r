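#' Cluster discordant PETs around fusion points
#'
#' Discordant PETs spanning the same fusion point are grouped into clusters.
#' Two dPETs are co-clustered when they share the (5' chromosome, 3'
#' chromosome) pair and the (5' strand, 3' strand) pair, and both their 5'
#' tags and their 3' tags lie within `window` of each other — concretely,
#' the coordinate hull of the two same-side tags must fit within `window`,
#' since two fragments spanning one fusion point can differ by at most one
#' fragment length on each side. Clustering is the transitive closure
#' (single linkage) of this pairwise relation, so the result is independent
#' of input order.
#'
#' For each cluster the 5' and 3' anchors (the genomic regions covered by
#' the member tags on each side) are reported together with the cluster
#' count (number of member dPETs) and the predicted breakpoints (the inner
#' tag edges nearest the fusion point; see [predict_breakpoints()]).
#'
#' @param dpets PET tibble of discordant PETs (rows with
#'   `status == "discordant"` are used; others are dropped with a warning).
#' @param config [pet_library()] configuration.
#' @param window Co-clustering distance in bp; defaults to the library's
#'   `span_max` (the same bound that defines discordance).
#' @return A cluster tibble with columns `cluster_id`, anchor coordinates
#'   (`chrom5, start5, end5, strand5`, same for 3'), predicted breakpoints
#'   `bp5`, `bp3`, `count`, and a `members` list-column of read ids.
#'   Cluster ids are assigned deterministically by sorting on
#'   (chrom5, start5, chrom3, start3).
#' @examples
#' lib <- library_preset("10kb")
#' p <- pet_tbl(c("a", "b"), "chr1", c(1000, 1100), c(1025, 1125), "+",
#'              "chr1", c(51000, 51100), c(51025, 51125), "+")
#' p <- classify_pets(p, lib)
#' cluster_dpets(p, lib)
#' @export
cluster_dpets <- function(dpets, config, window = NULL) {
  validate_pet_tbl(dpets)
  window <- window %||% config$span_max
  if ("status" %in% names(dpets)) {
    dpets <- dpets[dpets$status == "discordant", , drop = FALSE]
  }
  empty <- tibble(
    cluster_id = integer(0),
    chrom5 = character(0), start5 = numeric(0), end5 = numeric(0),
    strand5 = character(0), bp5 = numeric(0),
    chrom3 = character(0), start3 = numeric(0), end3 = numeric(0),
    strand3 = character(0), bp3 = numeric(0),
    count = integer(0), members = list()
  )
  if (nrow(dpets) == 0) return(empty)

  key <- paste(dpets$chrom5, dpets$chrom3, dpets$strand5, dpets$strand3,
               sep = "\r")
  groups <- split(seq_len(nrow(dpets)), key)

  comp_global <- integer(nrow(dpets))
  offset <- 0L
  for (idx in groups) {
    sub <- dpets[idx, , drop = FALSE]
    comp <- cluster_group(sub, window)
    comp_global[idx] <- comp + offset
    offset <- offset + max(comp)
  }

  cl <- dpets %>%
    mutate(.comp = comp_global) %>%
    group_by(.data$.comp) %>%
    summarise(
      chrom5 = .data$chrom5[1],
      start5 = min(.data$start5), end5 = max(.data$end5),
      strand5 = .data$strand5[1],
      chrom3 = .data$chrom3[1],
      start3 = min(.data$start3), end3 = max(.data$end3),
      strand3 = .data$strand3[1],
      count = dplyr::n(),
      members = list(.data$read_id),
      .groups = "drop"
    ) %>%
    mutate(
      bp5 = ifelse(.data$strand5 == "+", .data$end5, .data$start5),
      bp3 = ifelse(.data$strand3 == "+", .data$start3, .data$end3)
    ) %>%
    arrange(.data$chrom5, .data$start5, .data$chrom3, .data$start3) %>%
    mutate(cluster_id = row_number()) %>%
    select("cluster_id", "chrom5", "start5", "end5", "strand5", "bp5",
           "chrom3", "start3", "end3", "strand3", "bp3", "count", "members")
  cl
}

# Single-linkage components within one orientation/chromosome-pair group.
# Sorted sweep on 5' start keeps the candidate set small; the exact hull
# test on both sides decides linkage.
cluster_group <- function(sub, window) {
  n <- nrow(sub)
  if (n == 1) return(1L)
  ord <- order(sub$start5, sub$end5)
  s5 <- sub$start5[ord]; e5 <- sub$end5[ord]
  s3 <- sub$start3[ord]; e3 <- sub$end3[ord]
  parent <- uf_new(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (s5[j] - s5[i] > window) break
      hull5 <- max(e5[i], e5[j]) - min(s5[i], s5[j])
      if (hull5 > window) next
      hull3 <- max(e3[i], e3[j]) - min(s3[i], s3[j])
      if (hull3 <= window) parent <- uf_union(parent, i, j)
    }
  }
  comp_sorted <- uf_components(parent)
  comp <- integer(n)
  comp[ord] <- comp_sorted
  comp
}

#' Filter clusters by count
#'
#' Singleton and low-count clusters are dominated by chimeric-ligation noise;
#' only clusters with multiple overlapping dPETs (by default at least 3) are
#' treated as true rearrangement signals.
#'
#' @param clusters Cluster tibble from [cluster_dpets()].
#' @param min_count Minimum cluster count (>= 1).
#' @return Filtered cluster tibble.
#' @export
filter_clusters <- function(clusters, min_count = 3L) {
  if (min_count < 1) abort("min_count must be >= 1")
  clusters[clusters$count >= min_count, , drop = FALSE]
}

#' Predicted breakpoints of a cluster
#'
#' Per anchor, the member-tag coordinate nearest the fusion point. Reading
#' a fragment 5' to 3', the 5' anchor runs *into* the fusion and the 3'
#' anchor runs *out of* it, so the inner edges differ by side: for the 5'
#' anchor the fusion lies beyond the reading-direction end (`max end` on
#' `+`, `min start` on `-`); for the 3' anchor it lies at the
#' reading-direction start (`min start` on `+`, `max end` on `-`). A
#' single-member cluster therefore predicts the PET's inner tag edges.
#' [cluster_dpets()] already fills `bp5`/`bp3`; this recomputes them from
#' the anchors, e.g. after manual edits.
#'
#' @param clusters Cluster tibble.
#' @return The tibble with `bp5` and `bp3` recomputed.
#' @export
predict_breakpoints <- function(clusters) {
  clusters %>%
    mutate(
      bp5 = ifelse(.data$strand5 == "+", .data$end5, .data$start5),
      bp3 = ifelse(.data$strand3 == "+", .data$start3, .data$end3)
    )
}

#' Write clusters as a BEDPE-style table
#'
#' Two-interval export: the 5' and 3' anchors with strands, the cluster
#' count as score, member read ids as a comma-separated extra column.
#'
#' @param clusters Cluster tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters_bedpe <- function(clusters, path) {
  df <- tibble(
    chrom1 = clusters$chrom5, start1 = clusters$start5, end1 = clusters$end5,
    chrom2 = clusters$chrom3, start2 = clusters$start3, end2 = clusters$end3,
    name = paste0("cluster_", clusters$cluster_id), score = clusters$count,
    strand1 = clusters$strand5, strand2 = clusters$strand3,
    bp1 = clusters$bp5, bp2 = clusters$bp3,
    members = vapply(clusters$members, paste, "", collapse = ",")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# petsv dPET clusters (BEDPE + bp5 bp3 members); 0-based half-open", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
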