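#' Match SV calls across libraries of different insert sizes
#'
#' Starting from the larger-insert (reference) library, each isolated
#' reference SV's anchors are extended one-sidedly toward their breakpoints
#' by the reference library's maximum span to form search windows. A
#' same-type SV from the other library whose breakpoints fall into all the
#' reference windows is grouped with it as a *common* SV; when one
#' reference SV matches several candidates the nearest by summed breakpoint
#' distance wins. Unmatched reference SVs with cluster count at least
#' `specific_cluster_count_min` are *library-specific*; unmatched ones
#' below that cutoff are set aside as low confidence (raising the cutoff
#' from 3 to 6 for large-insert-specific claims). The other library may
#' legitimately include low-count (size 2) clusters so that weak but
#' corroborated signals still match.
#'
#' Complex SVs are excluded from the comparison on both sides.
#'
#' @param ref_calls,ref_clusters Calls and clusters of the reference
#'   (larger-insert) library.
#' @param other_calls,other_clusters Calls and clusters of the other
#'   library (may be built with `min_count = 2`).
#' @param ref_config,other_config Library configurations.
#' @return An object of class `library_comparison`: list with `common`
#'   (tibble `ref_sv_id`, `other_sv_id`, `sv_type`, `dist`),
#'   `ref_specific`, `ref_low_confidence`, `other_specific` (call tibbles)
#'   and the two library names.
#' @export
match_across_libraries <- function(ref_calls, ref_clusters,
                                   other_calls, other_clusters,
                                   ref_config, other_config) {
  ref_chroms <- unique(c(ref_calls$chrom5_1, ref_calls$chrom3_1))
  other_chroms <- unique(c(other_calls$chrom5_1, other_calls$chrom3_1))
  if (nrow(ref_calls) > 0 && nrow(other_calls) > 0 &&
      length(intersect(ref_chroms, other_chroms)) == 0) {
    abort("chromosome name sets of the two libraries are disjoint; mismatched genomes?")
  }
  drop_complex <- function(calls) {
    calls[is.na(calls$complexity) | calls$complexity != "complex", , drop = FALSE]
  }
  ref <- drop_complex(ref_calls)
  other <- drop_complex(other_calls)

  other_bps <- sv_breakpoints(other)

  match_one <- function(k) {
    win <- call_windows(ref[k, ], ref_clusters, ref_config$span_max)
    cand_ids <- unique(other$sv_id[other$sv_type == ref$sv_type[k]])
    if (length(cand_ids) == 0) return(NULL)
    best <- NULL
    for (oid in cand_ids) {
      obp <- other_bps[other_bps$sv_id == oid, ]
      dist <- windows_cover(win, obp)
      if (is.finite(dist) && (is.null(best) || dist < best$dist)) {
        best <- list(other_sv_id = oid, dist = dist)
      }
    }
    best
  }

  common <- list()
  matched_ref <- logical(nrow(ref))
  matched_other <- integer(0)
  for (k in seq_len(nrow(ref))) {
    m <- match_one(k)
    if (!is.null(m)) {
      matched_ref[k] <- TRUE
      matched_other <- c(matched_other, m$other_sv_id)
      common[[length(common) + 1L]] <- tibble(
        ref_sv_id = ref$sv_id[k], other_sv_id = m$other_sv_id,
        sv_type = ref$sv_type[k], dist = m$dist
      )
    }
  }
  common <- if (length(common)) bind_rows(common) else
    tibble(ref_sv_id = integer(0), other_sv_id = integer(0),
           sv_type = character(0), dist = numeric(0))

  unmatched <- ref[!matched_ref, , drop = FALSE]
  confident <- unmatched$count >= ref_config$specific_cluster_count_min
  other_conf <- other[!(other$sv_id %in% matched_other) &
                        other$count >= other_config$cluster_count_min, , drop = FALSE]
  structure(
    list(
      ref_name = ref_config$name, other_name = other_config$name,
      common = common,
      ref_specific = unmatched[confident, , drop = FALSE],
      ref_low_confidence = unmatched[!confident, , drop = FALSE],
      other_specific = other_conf
    ),
    class = "library_comparison"
  )
}

# One-sided search windows of a call: each supporting anchor extended by
# `ext` toward (beyond) its predicted breakpoint only.
call_windows <- function(call, clusters, ext) {
  ids <- c(call$cluster_id1, call$cluster_id2)
  ids <- ids[!is.na(ids)]
  cl <- clusters[clusters$cluster_id %in% ids, , drop = FALSE]
  one <- function(chrom, start, end, bp) {
    at_start <- abs(bp - start) <= abs(end - bp)
    tibble(chrom = chrom,
           lo = if (at_start) start - ext else start,
           hi = if (at_start) end else end + ext)
  }
  bind_rows(lapply(seq_len(nrow(cl)), function(i) {
    bind_rows(
      one(cl$chrom5[i], cl$start5[i], cl$end5[i], cl$bp5[i]),
      one(cl$chrom3[i], cl$start3[i], cl$end3[i], cl$bp3[i])
    )
  }))
}

# Every window must contain at least one breakpoint of the candidate; the
# return value is the summed distance from each window centre's breakpoint
# (Inf when some window is empty).
windows_cover <- function(win, bps) {
  total <- 0
  for (i in seq_len(nrow(win))) {
    hit <- bps$chrom == win$chrom[i] & bps$bp >= win$lo[i] & bps$bp <= win$hi[i]
    if (!any(hit)) return(Inf)
    centre <- (win$lo[i] + win$hi[i]) / 2
    total <- total + min(abs(bps$bp[hit] - centre))
  }
  total
}

#' @export
print.library_comparison <- function(x, ...) {
  cat(sprintf("<library_comparison %s vs %s>\n", x$ref_name, x$other_name))
  cat(sprintf("  common: %d   %s-specific: %d (low conf. %d)   %s-specific: %d\n",
              nrow(x$common), x$ref_name, nrow(x$ref_specific),
              nrow(x$ref_low_confidence), x$other_name, nrow(x$other_specific)))
  invisible(x)
}

#' @describeIn match_across_libraries Per-type Venn-style summary of a
#'   comparison: one row per SV type and category with counts.
#' @param x A `library_comparison` object.
#' @param ... Unused.
#' @export
tidy.library_comparison <- function(x, ...) {
  bind_rows(
    x$common %>% dplyr::count(.data$sv_type) %>% mutate(category = "common"),
    x$ref_specific %>% dplyr::count(.data$sv_type) %>%
      mutate(category = paste0(x$ref_name, "_specific")),
    x$other_specific %>% dplyr::count(.data$sv_type) %>%
      mutate(category = paste0(x$other_name, "_specific"))
  ) %>% select("category", "sv_type", "n")
}

#' @describeIn match_across_libraries One-row comparison summary.
#' @export
glance.library_comparison <- function(x, ...) {
  tibble(ref = x$ref_name, other = x$other_name, n_common = nrow(x$common),
         n_ref_specific = nrow(x$ref_specific),
         n_ref_low_confidence = nrow(x$ref_low_confidence),
         n_other_specific = nrow(x$other_specific))
}

#' Breakpoint resolution
#'
#' Resolution is the genomic distance in bp between a cluster-predicted
#' breakpoint coordinate and the true breakpoint (validated or simulated).
#' The best attainable resolution is 0 bp.
#'
#' @param predicted,truth Breakpoint coordinates in bp (vectorised).
#' @param chrom_predicted,chrom_truth Optional chromosome names; if given,
#'   any pair on different chromosomes raises an error.
#' @return Absolute distances in bp.
#' @export
resolution <- function(predicted, truth, chrom_predicted = NULL,
                       chrom_truth = NULL) {
  if (!is.null(chrom_predicted) && !is.null(chrom_truth) &&
      any(chrom_predicted != chrom_truth)) {
    abort("resolution is undefined across chromosomes")
  }
  abs(predicted - truth)
}

#' @describeIn resolution Median resolution over a set of records (a
#'   numeric vector or a tibble with a `resolution` column).
#' @param records Resolution records.
#' @export
median_resolution <- function(records) {
  r <- if (is.data.frame(records)) records$resolution else records
  median(r)
}

#' Exact probability of a 2x2 contingency table
#'
#' Two-sided exact association probability computed by full enumeration of
#' all tables with the observed margins: hypergeometric probabilities are
#' summed over every table no more probable than the observed one (the
#' classical two-sided exact test convention).
#'
#' @param m A 2x2 integer matrix (rows = classes, columns = outcome).
#' @return The exact p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(38, 12, 66, 126), nrow = 2))
#' @export
fisher_exact_2x2 <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2, 2)) || any(m < 0)) abort("need a non-negative 2x2 table")
  a <- m[1, 1]
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  k <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(k, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Resolution contingency table against a threshold
#'
#' Cross-classifies resolution records by class (e.g. large-insert-specific
#' versus shared breakpoints) and whether their resolution exceeds a
#' threshold (default 1.5 kb, the scale above which repeat-obstructed
#' mapping dominates). Reports counts, row percentages, and the exact
#' association probability from [fisher_exact_2x2()].
#'
#' @param records Tibble with columns `class` and `resolution`.
#' @param threshold Resolution threshold in bp (default 1500).
#' @return An object of class `resolution_contingency`: list with `table`
#'   (2x2 matrix, columns `above`/`at_or_below`), `row_pct` (percent above
#'   threshold per class), `p_value`, `threshold`.
#' @export
resolution_contingency <- function(records, threshold = 1500) {
  stopifnot_cols(records, c("class", "resolution"), "resolution records")
  classes <- unique(records$class)
  if (length(classes) != 2) abort("need exactly two non-empty classes")
  tab <- vapply(classes, function(cl) {
    r <- records$resolution[records$class == cl]
    if (length(r) == 0) abort(sprintf("class '%s' is empty", cl))
    c(above = sum(r > threshold), at_or_below = sum(r <= threshold))
  }, numeric(2))
  tab <- t(tab)  # rows = classes
  colnames(tab) <- c("above", "at_or_below")
  row_pct <- 100 * tab[, "above"] / rowSums(tab)
  structure(
    list(table = tab, row_pct = row_pct,
         p_value = fisher_exact_2x2(tab), threshold = threshold),
    class = "resolution_contingency"
  )
}

#' @export
print.resolution_contingency <- function(x, ...) {
  cat(sprintf("<resolution_contingency> threshold %g bp, exact p = %.3g\n",
              x$threshold, x$p_value))
  print(cbind(x$table, pct_above = round(x$row_pct, 1)))
  invisible(x)
}

#' @describeIn resolution_contingency Tidy one row per class.
#' @param x A `resolution_contingency` object.
#' @param ... Unused.
#' @export
tidy.resolution_contingency <- function(x, ...) {
  tibble(class = rownames(x$table),
         above = x$table[, "above"],
         at_or_below = x$table[, "at_or_below"],
         pct_above = x$row_pct)
}

#' @describeIn resolution_contingency One-row summary with the exact p.
#' @export
glance.resolution_contingency <- function(x, ...) {
  tibble(threshold = x$threshold, p_value = x$p_value,
         n = sum(x$table))
}
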