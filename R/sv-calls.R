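#' The eight insertion sub-types
#'
#' Paired-cluster insertion signatures are the combination of intra- versus
#' inter-chromosomal placement, direct versus inverted segment orientation,
#' and (intra-chromosomal only) forward versus backward movement of the
#' segment relative to its source locus. Two further sub-types are
#' cut-and-paste variants in which the source copy is lost, recognisable by
#' a physical-coverage gap over the source segment. Inter-chromosomal
#' insertions have no shared coordinate axis, so forward/backward does not
#' apply and the inter-chromosomal signatures collapse into the direct and
#' inverted sub-types.
#'
#' @return A tibble with one row per sub-type: `subtype` (1-8), `label`,
#'   and the predicate flags `intra`, `inverted`, `backward` (NA where not
#'   applicable) and `deletion_plus`.
#' @examples
#' insertion_subtypes()
#' @export
insertion_subtypes <- function() {
  tibble(
    subtype = 1:8,
    label = c(
      "intra-chromosomal direct forward insertion",
      "intra-chromosomal direct backward insertion",
      "intra-chromosomal inverted forward insertion",
      "intra-chromosomal inverted backward insertion",
      "deletion plus intra-chromosomal direct forward insertion",
      "deletion plus intra-chromosomal inverted forward insertion",
      "inter-chromosomal direct insertion",
      "inter-chromosomal inverted insertion"
    ),
    intra = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    inverted = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
    backward = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, NA, NA),
    deletion_plus = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  )
}

# Map geometry flags to the sub-type number. Cut-and-paste events are typed
# 5/6 regardless of direction: the taxonomy names only the forward variants,
# and the source-loss signal dominates the direction label.
insertion_subtype_of <- function(intra, inverted, backward, deletion_plus) {
  if (!intra) return(if (inverted) 8L else 7L)
  if (deletion_plus) return(if (inverted) 6L else 5L)
  if (inverted) {
    if (backward) 4L else 3L
  } else {
    if (backward) 2L else 1L
  }
}

sv_call_cols <- function() {
  tibble(
    sv_id = integer(0), sv_type = character(0),
    insertion_subtype = integer(0), n_clusters = integer(0),
    cluster_id1 = integer(0), cluster_id2 = integer(0),
    count = integer(0),
    chrom5_1 = character(0), bp5_1 = numeric(0), strand5_1 = character(0),
    chrom3_1 = character(0), bp3_1 = numeric(0), strand3_1 = character(0),
    chrom5_2 = character(0), bp5_2 = numeric(0), strand5_2 = character(0),
    chrom3_2 = character(0), bp3_2 = numeric(0), strand3_2 = character(0),
    span = numeric(0), caveat = character(0),
    complexity = character(0), supercluster_id = integer(0)
  )
}

# Single-cluster mapping-pattern type, vectorised over a cluster tibble.
# Returns a character vector; NA for clusters with no discordant pattern
# (possible only when span_min > 0 produces short-span dPETs).
single_cluster_type <- function(clusters, config) {
  same_chrom <- clusters$chrom5 == clusters$chrom3
  same_strand_ok <- if (config$orientation == "same_strand") {
    clusters$strand5 == clusters$strand3
  } else {
    clusters$strand5 != clusters$strand3
  }
  order_ok <- ifelse(clusters$strand5 == "+",
                     clusters$bp5 <= clusters$bp3,
                     clusters$bp3 <= clusters$bp5)
  # discordance-by-distance is judged on the anchor hull (the outermost
  # member-tag coordinates): a deletion smaller than the span bound has a
  # breakpoint distance below span_max, but its member PETs exceed it
  span <- ifelse(clusters$chrom5 == clusters$chrom3,
                 pmax(clusters$end5, clusters$end3) -
                   pmin(clusters$start5, clusters$start3),
                 NA_real_)
  dplyr::case_when(
    !same_chrom ~ "isolated_translocation",
    !same_strand_ok ~ "unpaired_inversion",
    !order_ok ~ "tandem_duplication",
    span > config$span_max ~ "deletion",
    span < config$span_min ~ NA_character_,
    TRUE ~ "concordant_pattern"
  )
}

#' Type single dPET clusters as SV calls
#'
#' SVs with one rearrangement point are identified from a single cluster's
#' mapping pattern: a *deletion* when the 5' anchor is far (beyond the
#' concordant span bound) upstream of the 3' anchor in otherwise concordant
#' orientation; a *tandem duplication* when the mapping order is 3'-to-5'
#' instead of the normal 5'-to-3'; an *unpaired inversion* when the mapping
#' orientation is reversed (anchors on different strands); an *isolated
#' translocation* when the anchors map to different chromosomes. A
#' consequence of the deletion rule is that deletions smaller than the
#' library span bound are undetectable by that library.
#'
#' @param clusters Cluster tibble (already count-filtered).
#' @param config [pet_library()] configuration.
#' @return An SV call tibble, one row per cluster. A cluster whose pattern
#'   matches concordance is an internal inconsistency and raises an error.
#' @export
call_single_cluster <- function(clusters, config) {
  if (nrow(clusters) == 0) return(sv_call_cols())
  type <- single_cluster_type(clusters, config)
  if (any(type == "concordant_pattern", na.rm = TRUE)) {
    abort("cluster with concordant mapping pattern passed to call_single_cluster")
  }
  keep <- !is.na(type)
  if (any(!keep)) {
    warn(sprintf("%d short-span cluster(s) left untyped", sum(!keep)))
  }
  clusters <- clusters[keep, , drop = FALSE]
  type <- type[keep]
  calls <- tibble(
    sv_id = seq_len(nrow(clusters)),
    sv_type = type,
    insertion_subtype = NA_integer_,
    n_clusters = 1L,
    cluster_id1 = clusters$cluster_id,
    cluster_id2 = NA_integer_,
    count = as.integer(clusters$count),
    chrom5_1 = clusters$chrom5, bp5_1 = clusters$bp5, strand5_1 = clusters$strand5,
    chrom3_1 = clusters$chrom3, bp3_1 = clusters$bp3, strand3_1 = clusters$strand3,
    chrom5_2 = NA_character_, bp5_2 = NA_real_, strand5_2 = NA_character_,
    chrom3_2 = NA_character_, bp3_2 = NA_real_, strand3_2 = NA_character_,
    span = NA_real_, caveat = NA_character_,
    complexity = NA_character_, supercluster_id = NA_integer_
  )
  calls$span <- sv_span(calls)
  calls
}

# Gap between two anchor intervals (0 when they touch or overlap); Inf on
# different chromosomes.
anchor_gap <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  if (chrom_a != chrom_b) return(Inf)
  max(0, max(start_a, start_b) - min(end_a, end_b))
}

# Joint two-cluster signature. a and b are single rows of the cluster
# tibble. Returns NULL if the pair matches no paired signature, else a list
# with type, subtype, caveat and the pair's summed anchor distance.
pair_signature <- function(a, b, config, window, coverage = NULL,
                           cn_gap_max = 1, cn_copy_min = 2.5) {
  g55 <- anchor_gap(a$chrom5, a$start5, a$end5, b$chrom5, b$start5, b$end5)
  g33 <- anchor_gap(a$chrom3, a$start3, a$end3, b$chrom3, b$start3, b$end3)
  g53 <- anchor_gap(a$chrom5, a$start5, a$end5, b$chrom3, b$start3, b$end3)
  g35 <- anchor_gap(a$chrom3, a$start3, a$end3, b$chrom5, b$start5, b$end5)
  p55 <- g55 <= window; p33 <- g33 <= window
  p53 <- g53 <= window; p35 <- g35 <= window

  same_pat <- function(x) x$strand5 == x$strand3
  opp_patterns <- !same_pat(a) && !same_pat(b) && a$strand5 != b$strand5
  intra_a <- a$chrom5 == a$chrom3
  intra_b <- b$chrom5 == b$chrom3

  # Inversion: two opposite-orientation clusters delimiting one segment;
  # anchors coincide side-for-side at both breakpoints.
  if (intra_a && intra_b && a$chrom5 == b$chrom5 && opp_patterns &&
      p55 && p33) {
    return(list(type = "inversion", subtype = NA_integer_,
                caveat = NA_character_, dist = g55 + g33))
  }

  # Balanced translocation: reciprocal inter-chromosomal pair; anchors
  # coincide cross-side on both chromosomes.
  if (!intra_a && !intra_b &&
      setequal(c(a$chrom5, a$chrom3), c(b$chrom5, b$chrom3)) &&
      p53 && p35) {
    return(list(type = "balanced_translocation", subtype = NA_integer_,
                caveat = NA_character_, dist = g53 + g35))
  }

  # Insertion: the two clusters share a locus (the target point) cross-side;
  # the far anchors delimit the inserted segment on the source chromosome.
  # When both cross pairs are proximal (short inserted segment) the tighter
  # pair is taken as the target side.
  if ((p53 || p35) && !(p55 && p33)) {
    if (p35 && (!p53 || g35 < g53)) { tmp <- a; a <- b; b <- tmp; g53 <- g35 }
    # Now a's 5' anchor ~ b's 3' anchor = target locus.
    target_chrom <- a$chrom5
    t_pos <- (a$bp5 + b$bp3) / 2
    src_chrom_1 <- a$chrom3
    src_chrom_2 <- b$chrom5
    if (src_chrom_1 != src_chrom_2) return(NULL)
    s_lo <- min(a$bp3, b$bp5); s_hi <- max(a$bp3, b$bp5)
    intra <- src_chrom_1 == target_chrom
    direct <- same_pat(a) && same_pat(b)
    inverted <- !same_pat(a) && !same_pat(b)
    if (!direct && !inverted) return(NULL)
    backward <- NA
    if (intra) {
      if (t_pos > s_hi) backward <- FALSE
      else if (t_pos < s_lo) backward <- TRUE
      else return(NULL)  # target inside the segment: not an insertion pattern
    }
    deletion_plus <- FALSE
    caveat <- NA_character_
    if (is.null(coverage)) {
      if (intra) caveat <- "subtype_without_coverage"
    } else {
      # Copy-number consistency gate. An insertion leaves the target flanks
      # intact and either gains a source copy (copy-and-paste: segment CN
      # above baseline) or loses the deleted margins around the source
      # segment (deletion-plus-insertion: flank CN near zero). Candidates
      # with neither signature are spurious pairings of unrelated junction
      # clusters and are rejected. NaN (off-chromosome flank) passes.
      m <- window
      cn_at <- function(chrom, lo, hi) {
        mean_copy_number(coverage, chrom, lo, hi)
      }
      t_lo <- min(a$bp5, b$bp3); t_hi <- max(a$bp5, b$bp3)
      tl <- cn_at(target_chrom, t_lo - m, t_lo)
      tr <- cn_at(target_chrom, t_hi, t_hi + m)
      if ((is.finite(tl) && tl < cn_gap_max) ||
            (is.finite(tr) && tr < cn_gap_max)) return(NULL)
      src_cn <- cn_at(src_chrom_1, s_lo, s_hi)
      sl <- cn_at(src_chrom_1, s_lo - m, s_lo)
      sr <- cn_at(src_chrom_1, s_hi, s_hi + m)
      deletion_plus <- (!is.finite(sl) || sl < cn_gap_max) &&
        (!is.finite(sr) || sr < cn_gap_max) &&
        (is.finite(sl) || is.finite(sr))
      gained <- is.finite(src_cn) && src_cn > cn_copy_min
      if (!deletion_plus && !gained) return(NULL)
    }
    st <- insertion_subtype_of(intra, inverted, isTRUE(backward), deletion_plus)
    return(list(type = "insertion", subtype = st, caveat = caveat, dist = g53))
  }
  NULL
}

#' Call SVs from filtered dPET clusters
#'
#' Two-breakpoint SVs (inversions, balanced translocations, insertions) are
#' identified by two closely positioned clusters whose anchors fall within a
#' pairing window of each other and whose joint orientation pattern matches
#' a paired signature; the eight insertion sub-types are distinguished by
#' intra/inter-chromosomal placement, direct/inverted orientation,
#' forward/backward direction and source-coverage loss (see
#' [insertion_subtypes()]). Pairing is greedy by descending combined cluster
#' count (ties to the smaller summed anchor distance), so well-supported
#' events claim their partners first and the result is deterministic and
#' invariant to cluster order. Clusters left unpaired fall back to
#' single-cluster calls ([call_single_cluster()]).
#'
#' Cut-and-paste sub-types (5-6) need the physical-coverage gap at the
#' source locus; when `coverage` is `NULL` such events are reported as
#' sub-types 1/3 with `caveat = "subtype_without_coverage"`.
#'
#' @param clusters Cluster tibble, already filtered with
#'   [filter_clusters()].
#' @param config [pet_library()] configuration.
#' @param coverage Optional [coverage_track()] used to detect source-loss
#'   insertions.
#' @param pairing_window Window in bp within which two clusters are
#'   "closely positioned"; defaults to the library's `span_max` (each
#'   flanking fusion point of a two-cluster event is localised within one
#'   fragment length).
#' @param cn_gap_max Copy-number ceiling below which the source segment of
#'   an insertion counts as lost (default 1, i.e. under half the diploid
#'   baseline).
#' @param cn_copy_min Copy-number floor above which the source segment
#'   counts as gained (default 2.5). When a coverage track is supplied, an
#'   insertion candidate whose source segment shows neither loss nor gain
#'   is rejected as a spurious pairing.
#' @return An SV call tibble; see [call_single_cluster()] for columns.
#' @export
call_svs <- function(clusters, config, coverage = NULL,
                     pairing_window = NULL, cn_gap_max = 1,
                     cn_copy_min = 2.5) {
  window <- pairing_window %||% config$span_max
  n <- nrow(clusters)
  if (n == 0) return(sv_call_cols())

  # Candidate pairs: any two clusters with some pair of anchors on one
  # chromosome within the window and a valid joint signature.
  cand <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        sig <- pair_signature(clusters[i, ], clusters[j, ], config, window,
                              coverage, cn_gap_max, cn_copy_min)
        if (!is.null(sig)) {
          cand[[length(cand) + 1L]] <- tibble(
            i = i, j = j, type = sig$type, subtype = sig$subtype,
            caveat = sig$caveat %||% NA_character_,
            combined = clusters$count[i] + clusters$count[j],
            dist = sig$dist
          )
        }
      }
    }
  }
  used <- rep(FALSE, n)
  paired_calls <- list()
  if (length(cand) > 0) {
    cand <- bind_rows(cand) %>% arrange(dplyr::desc(.data$combined), .data$dist)
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (used[i] || used[j]) next
      used[i] <- used[j] <- TRUE
      a <- clusters[i, ]; b <- clusters[j, ]
      paired_calls[[length(paired_calls) + 1L]] <- tibble(
        sv_type = cand$type[k],
        insertion_subtype = cand$subtype[k],
        n_clusters = 2L,
        cluster_id1 = a$cluster_id, cluster_id2 = b$cluster_id,
        count = as.integer(a$count + b$count),
        chrom5_1 = a$chrom5, bp5_1 = a$bp5, strand5_1 = a$strand5,
        chrom3_1 = a$chrom3, bp3_1 = a$bp3, strand3_1 = a$strand3,
        chrom5_2 = b$chrom5, bp5_2 = b$bp5, strand5_2 = b$strand5,
        chrom3_2 = b$chrom3, bp3_2 = b$bp3, strand3_2 = b$strand3,
        span = NA_real_, caveat = cand$caveat[k],
        complexity = NA_character_, supercluster_id = NA_integer_
      )
    }
  }
  singles <- call_single_cluster(clusters[!used, , drop = FALSE], config)
  out <- bind_rows(bind_rows(paired_calls), singles %>% select(-"sv_id"))
  if (nrow(out) == 0) return(sv_call_cols())
  out <- out %>%
    arrange(.data$chrom5_1, .data$bp5_1, .data$chrom3_1, .data$bp3_1) %>%
    mutate(sv_id = row_number()) %>%
    select(dplyr::all_of(names(sv_call_cols())))
  out$span <- sv_span(out)
  out
}

#' Span of SV calls
#'
#' Distance between the outermost predicted breakpoints of a call when all
#' its breakpoints lie on one chromosome; `NA` (undefined) for
#' inter-chromosomal calls.
#'
#' @param calls SV call tibble.
#' @return Numeric vector of spans in bp.
#' @export
sv_span <- function(calls) {
  vapply(seq_len(nrow(calls)), function(k) {
    chroms <- c(calls$chrom5_1[k], calls$chrom3_1[k],
                calls$chrom5_2[k], calls$chrom3_2[k])
    bps <- c(calls$bp5_1[k], calls$bp3_1[k], calls$bp5_2[k], calls$bp3_2[k])
    ok <- !is.na(chroms)
    chroms <- chroms[ok]; bps <- bps[ok]
    if (length(unique(chroms)) != 1) return(NA_real_)
    max(bps) - min(bps)
  }, numeric(1))
}

#' Breakpoints of SV calls in long form
#'
#' @param calls SV call tibble.
#' @return Tibble with one row per breakpoint: `sv_id`, `cluster`,
#'   `side` (5 or 3), `chrom`, `bp`, `strand`.
#' @export
sv_breakpoints <- function(calls) {
  out <- bind_rows(
    tibble(sv_id = calls$sv_id, cluster = 1L, side = 5L,
           chrom = calls$chrom5_1, bp = calls$bp5_1, strand = calls$strand5_1),
    tibble(sv_id = calls$sv_id, cluster = 1L, side = 3L,
           chrom = calls$chrom3_1, bp = calls$bp3_1, strand = calls$strand3_1),
    tibble(sv_id = calls$sv_id, cluster = 2L, side = 5L,
           chrom = calls$chrom5_2, bp = calls$bp5_2, strand = calls$strand5_2),
    tibble(sv_id = calls$sv_id, cluster = 2L, side = 3L,
           chrom = calls$chrom3_2, bp = calls$bp3_2, strand = calls$strand3_2)
  )
  out %>% filter(!is.na(.data$chrom)) %>% arrange(.data$sv_id, .data$cluster, .data$side)
}

#' Write an SV call table
#'
#' Tab-delimited export of the call tibble (type, sub-type, breakpoints,
#' span, counts, complexity, supercluster).
#'
#' @param calls SV call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_table <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# petsv SV calls; 0-based half-open coordinates", con)
  suppressWarnings(utils::write.table(
    as.data.frame(calls), con, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Export SV calls as a minimal VCF with symbolic alleles
#'
#' Intra-chromosomal calls become symbolic `<DEL>`, `<DUP>`, `<INV>`,
#' `<INS>` records with `END`/`SVLEN`; translocations become breakend pairs
#' with `MATEID`. Coordinates are converted to 1-based. This is a
#' convenience export, not a full VCF writer.
#'
#' @param calls SV call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
    "##INFO=<ID=CLUSTERCOUNT,Number=1,Type=Integer,Description=\"dPET cluster count\">",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  symbolic <- c(deletion = "DEL", tandem_duplication = "DUP",
                inversion = "INV", unpaired_inversion = "INV",
                insertion = "INS")
  for (k in seq_len(nrow(calls))) {
    type <- calls$sv_type[k]
    id <- sprintf("sv%d", calls$sv_id[k])
    cc <- sprintf("CLUSTERCOUNT=%d", calls$count[k])
    if (type %in% names(symbolic) && !is.na(calls$span[k])) {
      bps <- sv_breakpoints(calls[k, , drop = FALSE])
      pos <- floor(min(bps$bp)) + 1
      end <- floor(max(bps$bp))
      writeLines(sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d;SVLEN=%d;%s",
                         bps$chrom[1], pos, id, symbolic[[type]],
                         symbolic[[type]], end, end - pos, cc), con)
    } else {
      # breakend pair for inter-chromosomal events
      p1 <- floor(calls$bp5_1[k]) + 1; p2 <- floor(calls$bp3_1[k]) + 1
      writeLines(sprintf("%s\t%d\t%s_1\tN\tN[%s:%d[\t.\tPASS\tSVTYPE=BND;MATEID=%s_2;%s",
                         calls$chrom5_1[k], p1, id, calls$chrom3_1[k], p2, id, cc), con)
      writeLines(sprintf("%s\t%d\t%s_2\tN\t]%s:%d]N\t.\tPASS\tSVTYPE=BND;MATEID=%s_1;%s",
                         calls$chrom3_1[k], p2, id, calls$chrom5_1[k], p1, id, cc), con)
    }
  }
  invisible(path)
}
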