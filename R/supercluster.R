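#' Group dPET clusters into superclusters
#'
#' To separate breakpoints in complex regions from isolated events, a
#' breakpoint interconnection network is built: each cluster anchor is
#' extended on both sides by the maximum insert size of the library to form
#' a search window, and clusters whose windows overlap on the same
#' chromosome (either anchor; touching counts as overlap) are joined.
#' Superclusters are the connected components of this window-overlap graph,
#' so the grouping partitions the clusters and is independent of input
#' order.
#'
#' @param clusters Cluster tibble (already count-filtered).
#' @param config [pet_library()] configuration.
#' @param extension Window extension in bp on each side of each anchor;
#'   defaults to the library's `span_max`.
#' @return A tibble with one row per cluster: `cluster_id`,
#'   `supercluster_id`, `supercluster_count` (number of interconnected
#'   clusters in the component). Supercluster ids are ordered by their
#'   lowest member `cluster_id`.
#' @export
build_superclusters <- function(clusters, config, extension = NULL) {
  extension <- extension %||% config$span_max
  n <- nrow(clusters)
  if (n == 0) {
    return(tibble(cluster_id = integer(0), supercluster_id = integer(0),
                  supercluster_count = integer(0)))
  }
  windows <- bind_rows(
    tibble(cluster = seq_len(n), chrom = clusters$chrom5,
           start = clusters$start5 - extension, end = clusters$end5 + extension),
    tibble(cluster = seq_len(n), chrom = clusters$chrom3,
           start = clusters$start3 - extension, end = clusters$end3 + extension)
  )
  parent <- uf_new(n)
  for (w in split(windows, windows$chrom)) {
    comp <- interval_components(w$start, w$end)
    for (grp in split(w$cluster, comp)) {
      if (length(grp) > 1) {
        for (k in 2:length(grp)) parent <- uf_union(parent, grp[1], grp[k])
      }
    }
  }
  comp <- uf_components(parent)
  # stable ids: order components by their smallest member cluster_id
  first_member <- tapply(clusters$cluster_id, comp, min)
  relabel <- match(comp, as.integer(names(sort(first_member))))
  counts <- table(relabel)
  tibble(
    cluster_id = clusters$cluster_id,
    supercluster_id = relabel,
    supercluster_count = as.integer(counts[as.character(relabel)])
  ) %>% arrange(.data$cluster_id)
}

#' Label SV calls as isolated or complex
#'
#' An SV is *isolated* when every cluster supporting it sits in a
#' supercluster of at most `isolated_max` interconnected clusters (default
#' 3); otherwise it is *complex*, i.e. part of a densely rearranged region.
#'
#' @param calls SV call tibble.
#' @param superclusters Membership tibble from [build_superclusters()].
#' @param isolated_max Largest supercluster count still considered isolated.
#' @return The call tibble with `complexity` and `supercluster_id` filled
#'   in (`supercluster_id` of the first cluster).
#' @export
classify_complexity <- function(calls, superclusters, isolated_max = 3L) {
  if (nrow(calls) == 0) return(calls)
  look <- setNames(superclusters$supercluster_count, superclusters$cluster_id)
  ids <- setNames(superclusters$supercluster_id, superclusters$cluster_id)
  cnt1 <- look[as.character(calls$cluster_id1)]
  cnt2 <- look[as.character(calls$cluster_id2)]
  if (anyNA(cnt1) || anyNA(cnt2[!is.na(calls$cluster_id2)])) {
    abort("every call cluster must be assigned to a supercluster")
  }
  maxcnt <- pmax(cnt1, cnt2, na.rm = TRUE)
  calls$complexity <- ifelse(maxcnt <= isolated_max, "isolated", "complex")
  calls$supercluster_id <- as.integer(ids[as.character(calls$cluster_id1)])
  calls
}

#' Supercluster count distribution
#'
#' @param superclusters Membership tibble from [build_superclusters()].
#' @return Tibble `supercluster_count`, `n_superclusters`, `n_clusters`.
#' @export
supercluster_histogram <- function(superclusters) {
  superclusters %>%
    distinct(.data$supercluster_id, .data$supercluster_count) %>%
    dplyr::count(.data$supercluster_count, name = "n_superclusters") %>%
    mutate(n_clusters = .data$supercluster_count * .data$n_superclusters) %>%
    arrange(.data$supercluster_count)
}
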