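# Independent brute-force oracles used by the property tests. These follow
# different routes than the package implementation (adjacency matrices and
# BFS instead of union-find / sweeps) on purpose.

# Connected components of a logical adjacency matrix by BFS.
oracle_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# All-pairs transitive-closure clustering of discordant PETs.
oracle_cluster_assignment <- function(dpets, window) {
  n <- nrow(dpets)
  if (n == 0) return(integer(0))
  same_group <- outer(seq_len(n), seq_len(n), function(i, j) {
    dpets$chrom5[i] == dpets$chrom5[j] & dpets$chrom3[i] == dpets$chrom3[j] &
      dpets$strand5[i] == dpets$strand5[j] & dpets$strand3[i] == dpets$strand3[j]
  })
  hull5 <- outer(seq_len(n), seq_len(n), function(i, j) {
    pmax(dpets$end5[i], dpets$end5[j]) - pmin(dpets$start5[i], dpets$start5[j])
  })
  hull3 <- outer(seq_len(n), seq_len(n), function(i, j) {
    pmax(dpets$end3[i], dpets$end3[j]) - pmin(dpets$start3[i], dpets$start3[j])
  })
  adj <- same_group & hull5 <= window & hull3 <= window
  diag(adj) <- TRUE
  oracle_components(adj)
}

# Same-partition check between two integer labellings.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# Exhaustive fixpoint oracle for amplicon growth on one seed edge: repeated
# whole-set expansion over amplified neighbours.
oracle_grow_once <- function(contig_ids, cn, ref_pairs, dpet_pairs, seed_pair,
                             amplified_min = 2) {
  members <- unique(seed_pair)
  amp <- setNames(round(cn) > amplified_min, contig_ids)
  repeat {
    nxt <- members
    for (p in c(ref_pairs, dpet_pairs)) {
      if (p[1] %in% nxt && !(p[2] %in% nxt) && amp[as.character(p[2])]) {
        nxt <- c(nxt, p[2])
      }
      if (p[2] %in% nxt && !(p[1] %in% nxt) && amp[as.character(p[1])]) {
        nxt <- c(nxt, p[1])
      }
    }
    if (length(nxt) == length(members)) break
    members <- nxt
  }
  sort(members)
}

# Random dPET table generator for clustering property tests.
random_dpets <- function(n, seed, n_chrom = 2, span = 2e5) {
  set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chrom))
  pet_tbl(
    read_id = sprintf("r%03d", seq_len(n)),
    chrom5 = sample(chroms, n, TRUE),
    start5 = s5 <- floor(runif(n, 0, span)),
    end5 = s5 + 25,
    strand5 = sample(c("+", "-"), n, TRUE),
    chrom3 = sample(chroms, n, TRUE),
    start3 = s3 <- floor(runif(n, 0, span)),
    end3 = s3 + 25,
    strand3 = sample(c("+", "-"), n, TRUE)
  )
}

# Minimal cluster-row constructor for signature tests: anchors of length
# `alen` ending (strand +) or starting (strand -) at the breakpoint.
toy_cluster <- function(id, chrom5, bp5, strand5, chrom3, bp3, strand3,
                        count = 10, alen = 5000) {
  a5 <- if (strand5 == "+") c(bp5 - alen, bp5) else c(bp5, bp5 + alen)
  a3 <- if (strand3 == "+") c(bp3, bp3 + alen) else c(bp3 - alen, bp3)
  tibble::tibble(
    cluster_id = id,
    chrom5 = chrom5, start5 = a5[1], end5 = a5[2], strand5 = strand5,
    bp5 = bp5,
    chrom3 = chrom3, start3 = a3[1], end3 = a3[2], strand3 = strand3,
    bp3 = bp3,
    count = count, members = list(sprintf("m%d", seq_len(count)))
  )
}

# Synthetic coverage track with given per-interval copy numbers.
toy_track <- function(chrom_len, bin_size = 10000, baseline = 2,
                      regions = NULL) {
  bins <- lapply(names(chrom_len), function(ch) {
    nb <- ceiling(chrom_len[[ch]] / bin_size)
    tibble::tibble(chrom = ch, bin_start = (seq_len(nb) - 1) * bin_size,
                   bin_end = pmin(seq_len(nb) * bin_size, chrom_len[[ch]]),
                   depth = 30, copy_number = baseline)
  })
  track <- dplyr::bind_rows(bins)
  if (!is.null(regions)) {
    for (i in seq_len(nrow(regions))) {
      sel <- track$chrom == regions$chrom[i] &
        track$bin_end > regions$start[i] & track$bin_start < regions$end[i]
      track$copy_number[sel] <- regions$cn[i]
      track$depth[sel] <- 15 * regions$cn[i]
    }
  }
  class(track) <- c("coverage_track", class(track))
  track
}

# Canonical two-cluster fixtures for each insertion sub-type. Geometry:
# source segment [s1, s2] (80 kb), target t; junction clusters as produced
# by spanning fragments.
insertion_fixture <- function(subtype) {
  s1 <- 2e6; s2 <- 2.08e6
  src <- "chr5"
  if (subtype %in% c(1, 3, 5, 6)) t <- 2.4e6          # forward
  if (subtype %in% c(2, 4)) t <- 1.6e6                # backward
  tgt <- if (subtype >= 7) "chr7" else src
  if (subtype >= 7) t <- 3e6
  inverted <- subtype %in% c(3, 4, 6, 8)
  if (!inverted) {
    a <- toy_cluster(1, tgt, t, "+", src, s1, "+")
    b <- toy_cluster(2, src, s2, "+", tgt, t, "+")
  } else {
    a <- toy_cluster(1, tgt, t, "+", src, s2, "-")
    b <- toy_cluster(2, src, s1, "-", tgt, t, "+")
  }
  dplyr::bind_rows(a, b)
}

insertion_track <- function(subtype) {
  cn <- if (subtype %in% 5:6) {
    # deletion-plus: source flanks lost, segment itself retained by the
    # moved copy
    tibble::tibble(chrom = "chr5",
                   start = c(1.975e6, 2.08e6), end = c(2.0e6, 2.105e6),
                   cn = 0)
  } else {
    # copy-and-paste: source segment gained
    tibble::tibble(chrom = "chr5", start = 2e6, end = 2.08e6, cn = 4)
  }
  toy_track(c(chr5 = 5e6, chr7 = 5e6), regions = cn)
}

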