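#' Physical coverage track and copy-number estimate
#'
#' Bins each chromosome and counts the concordant fragments (outer tag
#' hull) overlapping each bin — the physical (clone) coverage profile. Copy
#' number per bin is the depth divided by the genome-wide median depth,
#' scaled by the baseline ploidy; the median baseline is robust to focal
#' amplicons dominating the mean.
#'
#' @param pets Classified PET tibble (concordant rows are used).
#' @param genome Tibble with columns `chrom`, `length`.
#' @param bin_size Bin width in bp (> 0), default 10 kb.
#' @param baseline_ploidy Copy number assigned to the median bin (default 2).
#' @return A tibble of class `coverage_track`: `chrom`, `bin_start`,
#'   `bin_end`, `depth`, `copy_number`; bins tile each chromosome.
#' @export
coverage_track <- function(pets, genome, bin_size = 10000,
                           baseline_ploidy = 2) {
  if (bin_size <= 0) abort("bin_size must be > 0")
  stopifnot_cols(genome, c("chrom", "length"), "genome table")
  stopifnot_cols(pets, "status", "classified PET table")
  conc <- pets[pets$status == "concordant", , drop = FALSE]
  frag_lo <- pmin(conc$start5, conc$start3)
  frag_hi <- pmax(conc$end5, conc$end3)
  tracks <- lapply(seq_len(nrow(genome)), function(g) {
    chrom <- genome$chrom[g]
    len <- genome$length[g]
    nbin <- ceiling(len / bin_size)
    depth_diff <- numeric(nbin + 1)
    sel <- conc$chrom5 == chrom
    if (any(sel)) {
      b0 <- pmin(pmax(floor(frag_lo[sel] / bin_size), 0), nbin - 1) + 1
      b1 <- pmin(pmax(floor((frag_hi[sel] - 1) / bin_size), 0), nbin - 1) + 1
      for (k in seq_along(b0)) {
        depth_diff[b0[k]] <- depth_diff[b0[k]] + 1
        depth_diff[b1[k] + 1] <- depth_diff[b1[k] + 1] - 1
      }
    }
    depth <- cumsum(depth_diff[seq_len(nbin)])
    tibble(chrom = chrom,
           bin_start = (seq_len(nbin) - 1) * bin_size,
           bin_end = pmin(seq_len(nbin) * bin_size, len),
           depth = depth)
  })
  out <- bind_rows(tracks)
  med <- median(out$depth)
  if (med == 0) abort("genome-wide median depth is zero; cannot normalise copy number")
  out$copy_number <- out$depth / med * baseline_ploidy
  class(out) <- c("coverage_track", class(out))
  out
}

# Mean copy number of bins overlapping [start, end) on chrom; NaN if none.
mean_copy_number <- function(track, chrom, start, end) {
  sel <- track$chrom == chrom & track$bin_end > start & track$bin_start < end
  mean(track$copy_number[sel])
}

#' Segment the reference genome into contigs
#'
#' Cut positions are the predicted breakpoints of the dPET clusters plus
#' the boundaries of zero-physical-coverage runs (regions no concordant
#' fragment covers, e.g. deleted or unmappable segments); chromosome ends
#' close the set. Contigs are the intervals between consecutive cuts, each
#' annotated with its mean copy number and an `amplified` flag
#' (copy number > 2).
#'
#' @param clusters Filtered cluster tibble.
#' @param track [coverage_track()] of the concordant PETs.
#' @param amplified_min Copy number strictly above which a contig counts as
#'   amplified (default 2; tune for non-diploid genomes). The test is
#'   applied to the nearest-integer copy-number call.
#' @return Contig tibble: `contig_id`, `chrom`, `start`, `end`,
#'   `copy_number`, `amplified`. Contigs per chromosome are non-overlapping,
#'   ordered, and tile the chromosome.
#' @export
segment_contigs <- function(clusters, track, amplified_min = 2) {
  chroms <- unique(track$chrom)
  out <- lapply(chroms, function(ch) {
    bins <- track[track$chrom == ch, , drop = FALSE]
    len <- max(bins$bin_end)
    cuts <- c(0, len)
    cuts <- c(cuts, clusters$bp5[clusters$chrom5 == ch],
              clusters$bp3[clusters$chrom3 == ch])
    # boundaries of zero-coverage runs (each run spans >= 1 full bin)
    zero <- bins$depth == 0
    if (any(zero)) {
      r <- rle(zero)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      zi <- which(r$values)
      cuts <- c(cuts, bins$bin_start[starts[zi]], bins$bin_end[ends[zi]])
    }
    cuts <- sort(unique(pmin(pmax(cuts, 0), len)))
    cuts <- cuts[!duplicated(cuts)]
    if (length(cuts) < 2) return(NULL)
    tibble(chrom = ch, start = head(cuts, -1), end = tail(cuts, -1))
  })
  contigs <- bind_rows(out) %>%
    filter(.data$end > .data$start) %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(contig_id = row_number())
  contigs$copy_number <- vapply(seq_len(nrow(contigs)), function(i) {
    mean_copy_number(track, contigs$chrom[i], contigs$start[i], contigs$end[i])
  }, numeric(1))
  # amplification status uses the nearest-integer copy-number call: the
  # continuous estimate scatters around the true integer copy number, so a
  # strict > threshold on the raw value would flip on baseline noise
  contigs$amplified <- round(contigs$copy_number) > amplified_min
  contigs %>% select("contig_id", "chrom", "start", "end",
                     "copy_number", "amplified")
}

#' Build the contig genome graph
#'
#' Contigs consecutive on the reference genome are connected by a
#' *reference edge* when at least one concordant PET fragment straddles
#' their junction; contigs linked by dPET clusters are connected by *dPET
#' edges* weighted by cluster size, with the fused contig end recorded per
#' anchor strand (a `+` 5' anchor fuses at its contig's high-coordinate
#' end, a `-` 5' anchor at the low end; mirrored for the 3' side).
#'
#' @param contigs Contig tibble from [segment_contigs()].
#' @param clusters Filtered cluster tibble.
#' @param pets Classified PET tibble (concordant fragments support
#'   reference edges).
#' @return An object of class `genome_graph`: list with `contigs`,
#'   `ref_edges` (`contig_a`, `contig_b`, `chrom`, `junction`, `support`)
#'   and `dpet_edges` (`edge_id`, `cluster_id`, `contig5`, `end5`,
#'   `contig3`, `end3`, `weight`).
#' @export
build_genome_graph <- function(contigs, clusters, pets) {
  conc <- pets[pets$status == "concordant", , drop = FALSE]
  frag_lo <- pmin(conc$start5, conc$start3)
  frag_hi <- pmax(conc$end5, conc$end3)

  ref_edges <- contigs %>%
    group_by(.data$chrom) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(next_id = dplyr::lead(.data$contig_id),
           next_start = dplyr::lead(.data$start)) %>%
    ungroup() %>%
    filter(!is.na(.data$next_id) & .data$end == .data$next_start) %>%
    select(contig_a = "contig_id", contig_b = "next_id",
           chrom = "chrom", junction = "end")
  ref_edges$support <- vapply(seq_len(nrow(ref_edges)), function(i) {
    sum(conc$chrom5 == ref_edges$chrom[i] &
          frag_lo < ref_edges$junction[i] & frag_hi > ref_edges$junction[i])
  }, numeric(1))
  ref_edges <- ref_edges[ref_edges$support >= 1, , drop = FALSE]

  # A fused "high" end belongs to the contig *ending* at the breakpoint
  # (the segmentation cut runs through the fusion), a "low" end to the
  # contig starting there.
  locate <- function(chrom, bp, side) {
    hit <- if (side == "high") {
      which(contigs$chrom == chrom & contigs$start < bp & bp <= contigs$end)
    } else {
      which(contigs$chrom == chrom & contigs$start <= bp & bp < contigs$end)
    }
    if (length(hit) == 0) {
      hit <- which(contigs$chrom == chrom &
                     (contigs$start == bp | contigs$end == bp))[1]
      hit <- hit[!is.na(hit)]
    }
    if (length(hit) != 1) {
      abort(sprintf("breakpoint %s:%g is not inside any contig", chrom, bp))
    }
    contigs$contig_id[hit]
  }
  n <- nrow(clusters)
  end5 <- ifelse(clusters$strand5 == "+", "high", "low")
  end3 <- ifelse(clusters$strand3 == "+", "low", "high")
  dpet_edges <- tibble(
    edge_id = seq_len(n),
    cluster_id = clusters$cluster_id,
    contig5 = vapply(seq_len(n), function(i)
      locate(clusters$chrom5[i], clusters$bp5[i], end5[i]), integer(1)),
    end5 = end5,
    contig3 = vapply(seq_len(n), function(i)
      locate(clusters$chrom3[i], clusters$bp3[i], end3[i]), integer(1)),
    end3 = end3,
    weight = as.numeric(clusters$count)
  )
  structure(list(contigs = contigs, ref_edges = ref_edges,
                 dpet_edges = dpet_edges),
            class = "genome_graph")
}

#' @export
print.genome_graph <- function(x, ...) {
  cat(sprintf("<genome_graph> %d contigs, %d reference edges, %d dPET edges\n",
              nrow(x$contigs), nrow(x$ref_edges), nrow(x$dpet_edges)))
  invisible(x)
}

#' Grow amplicon graphs by fusion-point-guided concatenation
#'
#' Locally amplified regions are reconstructed iteratively: the unused dPET
#' edge with the highest weight is selected as seed and its two adjacent
#' contigs enter the amplicon graph (the seed contigs are exempt from the
#' amplification test). Then, for each contig in the graph, its neighbours
#' over both reference and dPET links are added as long as they are
#' amplified (nearest-integer copy number strictly greater than
#' `amplified_min`), until no more contigs can be added. Traversed dPET edges are marked used, so each
#' dPET edge belongs to at most one amplicon graph; the process repeats on
#' the remaining unused dPET edges until none remain. Only graphs with more
#' than two contigs are returned. Ties among equal-weight seeds go to the
#' edge with the lowest contig coordinates.
#'
#' @param graph A [build_genome_graph()] result.
#' @param amplified_min Copy-number threshold for growth (default 2,
#'   strict inequality).
#' @return A list of `amplicon_graph` objects, each a list with `id`,
#'   `seed_edge` (edge id), `contigs` (contig ids), `dpet_edges` (edge
#'   ids), `ref_edges` (row indices into `graph$ref_edges`).
#' @export
grow_amplicons <- function(graph, amplified_min = 2) {
  contigs <- graph$contigs
  dpet <- graph$dpet_edges
  refe <- graph$ref_edges
  ne <- nrow(dpet)
  if (ne == 0) return(list())
  cn <- setNames(contigs$copy_number, contigs$contig_id)
  coord_key <- setNames(paste(contigs$chrom, formatC(contigs$start, width = 15, flag = "0")),
                        contigs$contig_id)
  seed_order <- order(-dpet$weight,
                      pmin(coord_key[as.character(dpet$contig5)],
                           coord_key[as.character(dpet$contig3)]),
                      pmax(coord_key[as.character(dpet$contig5)],
                           coord_key[as.character(dpet$contig3)]))
  used <- rep(FALSE, ne)
  out <- list()
  amp_id <- 0L
  repeat {
    avail <- seed_order[!used[seed_order]]
    if (length(avail) == 0) break
    seed <- avail[1]
    members <- unique(c(dpet$contig5[seed], dpet$contig3[seed]))
    used[seed] <- TRUE
    edge_set <- seed
    repeat {
      grew <- FALSE
      # dPET neighbours: unused edges with one endpoint in the graph
      for (e in which(!used)) {
        a <- dpet$contig5[e]; b <- dpet$contig3[e]
        in_a <- a %in% members; in_b <- b %in% members
        if (in_a && in_b) {
          used[e] <- TRUE; edge_set <- c(edge_set, e); grew <- TRUE
        } else if (in_a || in_b) {
          nb <- if (in_a) b else a
          if (round(cn[as.character(nb)]) > amplified_min) {
            members <- c(members, nb)
            used[e] <- TRUE; edge_set <- c(edge_set, e); grew <- TRUE
          }
        }
      }
      # reference neighbours
      for (r in seq_len(nrow(refe))) {
        a <- refe$contig_a[r]; b <- refe$contig_b[r]
        in_a <- a %in% members; in_b <- b %in% members
        if (in_a && !in_b && round(cn[as.character(b)]) > amplified_min) {
          members <- c(members, b); grew <- TRUE
        } else if (in_b && !in_a && round(cn[as.character(a)]) > amplified_min) {
          members <- c(members, a); grew <- TRUE
        }
      }
      if (!grew) break
    }
    if (length(members) > 2) {
      amp_id <- amp_id + 1L
      ref_in <- which(refe$contig_a %in% members & refe$contig_b %in% members)
      out[[amp_id]] <- structure(
        list(id = amp_id, seed_edge = dpet$edge_id[seed],
             contigs = sort(members),
             dpet_edges = sort(dpet$edge_id[edge_set]),
             ref_edges = ref_in),
        class = "amplicon_graph")
    }
  }
  out
}

#' @export
print.amplicon_graph <- function(x, ...) {
  cat(sprintf("<amplicon_graph %d> seed edge %d, %d contigs, %d dPET edges\n",
              x$id, x$seed_edge, length(x$contigs), length(x$dpet_edges)))
  invisible(x)
}

#' Write a coverage track as bedGraph
#'
#' @param track [coverage_track()] tibble.
#' @param path Output path.
#' @param value `"depth"` or `"copy_number"`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value = c("depth", "copy_number")) {
  value <- match.arg(value)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=petsv_%s", value), con)
  utils::write.table(
    data.frame(track$chrom, track$bin_start, track$bin_end, track[[value]]),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write contigs as BED
#'
#' @param contigs Contig tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contigs_bed <- function(contigs, path) {
  df <- data.frame(contigs$chrom, contigs$start, contigs$end,
                   paste0("contig_", contigs$contig_id),
                   round(contigs$copy_number, 2))
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Render a genome graph in DOT notation
#'
#' Contigs become boxes whose width encodes contig length (on a log scale,
#' clamped to \[0.1, 6\]) and border width encodes copy number; reference
#' edges are bold, dPET edges dashed red with pen width scaled by cluster
#' size; arrowheads point toward the low-coordinate fused end of a contig
#' and away from the high-coordinate end.
#'
#' @param graph A `genome_graph`.
#' @param path Output path.
#' @param amplicon Optional `amplicon_graph` restricting the rendering to
#'   its members.
#' @return `path`, invisibly.
#' @export
write_dot <- function(graph, path, amplicon = NULL) {
  contigs <- graph$contigs
  dpet <- graph$dpet_edges
  refe <- graph$ref_edges
  if (!is.null(amplicon)) {
    contigs <- contigs[contigs$contig_id %in% amplicon$contigs, , drop = FALSE]
    dpet <- dpet[dpet$edge_id %in% amplicon$dpet_edges, , drop = FALSE]
    refe <- refe[seq_len(nrow(refe)) %in% amplicon$ref_edges, , drop = FALSE]
  }
  wclamp <- function(x) pmin(pmax(x, 0.1), 6)
  lines <- c("digraph amplicon {", "  rankdir=LR;",
             "  node [shape=box];")
  for (i in seq_len(nrow(contigs))) {
    lines <- c(lines, sprintf(
      "  c%d [label=\"%s:%.0fk-%.0fk\\nCN %.1f\", width=%.2f, penwidth=%.2f];",
      contigs$contig_id[i], contigs$chrom[i], contigs$start[i] / 1000,
      contigs$end[i] / 1000, contigs$copy_number[i],
      wclamp((contigs$end[i] - contigs$start[i]) / 1e5),
      wclamp(contigs$copy_number[i] / 2)))
  }
  for (i in seq_len(nrow(refe))) {
    lines <- c(lines, sprintf(
      "  c%d -> c%d [style=bold, color=black, arrowhead=none];",
      refe$contig_a[i], refe$contig_b[i]))
  }
  for (i in seq_len(nrow(dpet))) {
    head5 <- if (dpet$end5[i] == "low") "normal" else "inv"
    head3 <- if (dpet$end3[i] == "low") "normal" else "inv"
    lines <- c(lines, sprintf(
      "  c%d -> c%d [style=dashed, color=red, penwidth=%.2f, arrowtail=%s, arrowhead=%s, dir=both, label=\"%g\"];",
      dpet$contig5[i], dpet$contig3[i], wclamp(dpet$weight[i] / 50),
      head5, head3, dpet$weight[i]))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Convert a genome graph to an igraph object
#'
#' Vertices are contigs (attributes: chrom, start, end, copy number,
#' amplified); edges carry `kind` (`"reference"`/`"dpet"`) and `weight`.
#' Requires the igraph package.
#'
#' @param graph A `genome_graph`.
#' @return An igraph graph.
#' @export
as_igraph <- function(graph) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    abort("the igraph package is required for as_igraph()")
  }
  verts <- data.frame(name = as.character(graph$contigs$contig_id),
                      chrom = graph$contigs$chrom,
                      start = graph$contigs$start, end = graph$contigs$end,
                      copy_number = graph$contigs$copy_number,
                      amplified = graph$contigs$amplified)
  edges <- rbind(
    data.frame(from = as.character(graph$ref_edges$contig_a),
               to = as.character(graph$ref_edges$contig_b),
               kind = "reference", weight = graph$ref_edges$support),
    data.frame(from = as.character(graph$dpet_edges$contig5),
               to = as.character(graph$dpet_edges$contig3),
               kind = "dpet", weight = graph$dpet_edges$weight)
  )
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}
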