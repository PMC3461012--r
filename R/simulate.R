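#' Create a genome plan for simulation
#'
#' A genome plan holds a reference genome (chromosome lengths), optional
#' masked intervals standing in for unmappable repeats (tags falling inside
#' them are lost, which is how mapping pipelines actually behave for
#' ambiguous placements), and — after [plant_svs()] — the donor genome as
#' an ordered list of reference segments per donor chromosome together
#' with the ground-truth fusion points. The simulation is coordinate-level
#' throughout: no nucleotide sequences are generated because the analysis
#' chain starts at mapped tags.
#'
#' @param genome Tibble with columns `chrom`, `length` (or a named numeric
#'   vector of chromosome lengths).
#' @param masked Optional tibble `chrom`, `start`, `end` of unmappable
#'   tracts.
#' @return An object of class `genome_plan`.
#' @export
genome_plan <- function(genome, masked = NULL) {
  if (is.numeric(genome) && !is.null(names(genome))) {
    genome <- tibble(chrom = names(genome), length = as.numeric(genome))
  }
  stopifnot_cols(genome, c("chrom", "length"), "genome")
  if (is.null(masked)) {
    masked <- tibble(chrom = character(0), start = numeric(0), end = numeric(0))
  }
  donor <- lapply(seq_len(nrow(genome)), function(i) {
    tibble(chrom = genome$chrom[i], start = 0, end = genome$length[i],
           strand = "+")
  })
  names(donor) <- genome$chrom
  structure(
    list(genome = genome, masked = as_tibble(masked), donor = donor,
         truth = empty_truth(), requests = list()),
    class = "genome_plan"
  )
}

empty_truth <- function() {
  tibble(sv_id = integer(0), sv_type = character(0),
         insertion_subtype = integer(0), fusion_id = integer(0),
         expected_type = character(0), expected_subtype = integer(0),
         chrom5 = character(0), pos5 = numeric(0), strand5 = character(0),
         chrom3 = character(0), pos3 = numeric(0), strand3 = character(0))
}

#' @export
print.genome_plan <- function(x, ...) {
  cat(sprintf(
    "<genome_plan> %d chromosome(s), %.1f Mb reference, %d donor chromosome(s), %d planted SV(s), %d fusion point(s)\n",
    nrow(x$genome), sum(x$genome$length) / 1e6, length(x$donor),
    length(x$requests), nrow(x$truth)))
  invisible(x)
}

#' Structural-variant requests for the simulator
#'
#' Constructors for the rearrangements [plant_svs()] can apply to a genome
#' plan. All coordinates are reference coordinates, 0-based half-open.
#' Requests must not overlap (copied source segments may be read but not
#' edited by another request).
#'
#' * `sv_deletion()`: remove `[start, end)`.
#' * `sv_tandem_duplication()`: repeat `[start, end)` in place `copies`
#'   times total.
#' * `sv_inversion()`: invert `[start, end)` in place.
#' * `sv_unpaired_inversion()`: terminal fold-back — the chromosome ends
#'   with an inverted copy of `[start, end)` appended after `end`; only one
#'   inversion-type fusion point exists, so a single cluster supports it.
#' * `sv_translocation()`: join `chrom_a[0, pos_a)` to
#'   `chrom_b[pos_b, end)`. With `balanced = TRUE` the reciprocal
#'   derivative is also formed; otherwise the leftover pieces survive as
#'   free fragments so coverage is preserved.
#' * `sv_insertion()`: insert a copy of `source_chrom[start, end)` at
#'   `target_pos` on `target_chrom`, optionally `inverted`. With
#'   `cut = TRUE` a deletion-plus-insertion is planted: a deletion of
#'   `[start - cut_margin, end + cut_margin)` whose central `[start, end)`
#'   re-appears at the target. The co-deleted margins leave a genuine
#'   physical-coverage gap flanking the source (an exact cut-and-paste
#'   would not: tags of the moved copy still map to the source
#'   coordinates), plus a deletion-type fusion across the gap.
#' * `sv_derivative()`: a new donor chromosome assembled from arbitrary
#'   `segments` (tibble `chrom`, `start`, `end`, `strand`), present in
#'   `copies` copies — the building block for focally amplified regions.
#'
#' @param chrom,chrom_a,chrom_b,source_chrom,target_chrom Chromosome names.
#' @param start,end,pos_a,pos_b,target_pos Coordinates in bp.
#' @param copies Total copy count (duplication: >= 2; derivative: >= 1).
#' @param balanced Reciprocal translocation?
#' @param inverted Insert the segment in inverted orientation?
#' @param cut Plant a deletion-plus-insertion (see above)?
#' @param cut_margin Co-deleted margin in bp on each side of a `cut`
#'   source segment (default 25 kb, comfortably above the pairing window
#'   so the deletion cluster stays separate from the insertion clusters).
#' @param segments Tibble of segments for `sv_derivative()`.
#' @return An `sv_request` object.
#' @name sv_requests
NULL

new_request <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "sv_request")
}

#' @rdname sv_requests
#' @export
sv_deletion <- function(chrom, start, end) {
  new_request("deletion", chrom = chrom, start = start, end = end)
}

#' @rdname sv_requests
#' @export
sv_tandem_duplication <- function(chrom, start, end, copies = 2L) {
  if (copies < 2) abort("copies must be >= 2")
  new_request("tandem_duplication", chrom = chrom, start = start, end = end,
              copies = as.integer(copies))
}

#' @rdname sv_requests
#' @export
sv_inversion <- function(chrom, start, end) {
  new_request("inversion", chrom = chrom, start = start, end = end)
}

#' @rdname sv_requests
#' @export
sv_unpaired_inversion <- function(chrom, start, end) {
  new_request("unpaired_inversion", chrom = chrom, start = start, end = end)
}

#' @rdname sv_requests
#' @export
sv_translocation <- function(chrom_a, pos_a, chrom_b, pos_b,
                             balanced = FALSE) {
  new_request(if (balanced) "balanced_translocation" else "isolated_translocation",
              chrom_a = chrom_a, pos_a = pos_a, chrom_b = chrom_b,
              pos_b = pos_b, balanced = balanced)
}

#' @rdname sv_requests
#' @export
sv_insertion <- function(source_chrom, start, end, target_chrom, target_pos,
                         inverted = FALSE, cut = FALSE, cut_margin = 25000) {
  new_request("insertion", source_chrom = source_chrom, start = start,
              end = end, target_chrom = target_chrom,
              target_pos = target_pos, inverted = inverted, cut = cut,
              cut_margin = cut_margin)
}

#' @rdname sv_requests
#' @export
sv_derivative <- function(segments, copies = 1L) {
  stopifnot_cols(segments, c("chrom", "start", "end", "strand"),
                 "derivative segments")
  new_request("derivative", segments = as_tibble(segments),
              copies = as.integer(copies))
}

# --- donor assembly -------------------------------------------------------

# Split the unique untouched (+) piece strictly containing pos; no-op when
# pos already falls on a piece boundary.
donor_split <- function(donor, chrom, pos) {
  hits <- list()
  for (dc in names(donor)) {
    p <- donor[[dc]]
    at_boundary <- any(p$chrom == chrom & (p$start == pos | p$end == pos))
    if (at_boundary) return(donor)
    idx <- which(p$chrom == chrom & p$strand == "+" & p$start < pos & pos < p$end)
    for (i in idx) hits[[length(hits) + 1L]] <- c(dc = dc, i = i)
  }
  if (length(hits) == 0) {
    abort(sprintf("position %s:%g not found in any donor segment", chrom, pos))
  }
  if (length(hits) > 1) {
    abort(sprintf("position %s:%g is ambiguous (duplicated region)", chrom, pos))
  }
  dc <- hits[[1]][["dc"]]; i <- as.integer(hits[[1]][["i"]])
  p <- donor[[dc]]
  left <- p[i, ]; right <- p[i, ]
  left$end <- pos; right$start <- pos
  donor[[dc]] <- bind_rows(p[seq_len(i - 1), ], left, right,
                           p[seq_len(nrow(p)) > i, ])
  donor
}

# Locate the piece exactly equal to [start, end) on chrom (after splits).
donor_piece <- function(donor, chrom, start, end) {
  for (dc in names(donor)) {
    p <- donor[[dc]]
    i <- which(p$chrom == chrom & p$strand == "+" &
                 p$start == start & p$end == end)
    if (length(i) == 1) return(list(dc = dc, i = i))
    if (length(i) > 1) abort("ambiguous donor segment")
  }
  abort(sprintf("segment %s:%g-%g not found in donor", chrom, start, end))
}

# Boundary at pos: index of the piece that *starts* at pos (suffix side) or
# ends at pos (prefix side) within one donor chromosome.
donor_boundary <- function(donor, chrom, pos) {
  for (dc in names(donor)) {
    p <- donor[[dc]]
    i_end <- which(p$chrom == chrom & p$strand == "+" & p$end == pos)
    i_start <- which(p$chrom == chrom & p$strand == "+" & p$start == pos)
    if (length(i_end) == 1 || length(i_start) == 1) {
      return(list(dc = dc,
                  prefix_last = if (length(i_end) == 1) i_end else
                    (if (length(i_start) == 1) i_start - 1L else NA_integer_)))
    }
  }
  abort(sprintf("boundary %s:%g not found in donor", chrom, pos))
}

#' Plant structural variants into a genome plan
#'
#' Applies the requested rearrangements to the donor genome and records the
#' ground-truth fusion points at base-pair precision. Requests are applied
#' in order; intra-chromosomal edits should precede translocations, which
#' should precede fold-backs, because later requests operate on the donor
#' as already rearranged. Requested intervals must be pairwise disjoint
#' (copy sources may not be edited by another request).
#'
#' The truth table records, for every fusion point, the exit (5') and entry
#' (3') coordinates and strands in reference space — exactly the
#' breakpoints a dPET cluster spanning that fusion predicts — plus the
#' SV-call type and insertion sub-type the detection chain is expected to
#' produce.
#'
#' @param plan A [genome_plan()].
#' @param requests List of [sv_requests] objects.
#' @return The plan with donor and `truth` updated.
#' @export
plant_svs <- function(plan, requests) {
  if (inherits(requests, "sv_request")) requests <- list(requests)
  validate_requests(plan, requests)
  donor <- plan$donor
  truth <- list()
  der_n <- 0L
  rem_n <- 0L
  for (k in seq_along(requests)) {
    rq <- requests[[k]]
    add_truth <- function(expected_type, c5, p5, s5, c3, p3, s3,
                          expected_subtype = NA_integer_) {
      truth[[length(truth) + 1L]] <<- tibble(
        sv_id = k, sv_type = rq$type,
        insertion_subtype = rq$subtype %||% NA_integer_,
        fusion_id = length(truth) + 1L,
        expected_type = expected_type, expected_subtype = expected_subtype,
        chrom5 = c5, pos5 = p5, strand5 = s5,
        chrom3 = c3, pos3 = p3, strand3 = s3)
    }
    if (rq$type == "deletion") {
      donor <- donor_split(donor, rq$chrom, rq$start)
      donor <- donor_split(donor, rq$chrom, rq$end)
      loc <- donor_piece(donor, rq$chrom, rq$start, rq$end)
      donor[[loc$dc]] <- donor[[loc$dc]][-loc$i, ]
      add_truth("deletion", rq$chrom, rq$start, "+", rq$chrom, rq$end, "+")
    } else if (rq$type == "tandem_duplication") {
      donor <- donor_split(donor, rq$chrom, rq$start)
      donor <- donor_split(donor, rq$chrom, rq$end)
      loc <- donor_piece(donor, rq$chrom, rq$start, rq$end)
      p <- donor[[loc$dc]]
      reps <- p[rep(loc$i, rq$copies - 1L), ]
      donor[[loc$dc]] <- bind_rows(p[seq_len(loc$i), ], reps,
                                   p[seq_len(nrow(p)) > loc$i, ])
      add_truth("tandem_duplication", rq$chrom, rq$end, "+",
                rq$chrom, rq$start, "+")
    } else if (rq$type == "inversion") {
      donor <- donor_split(donor, rq$chrom, rq$start)
      donor <- donor_split(donor, rq$chrom, rq$end)
      loc <- donor_piece(donor, rq$chrom, rq$start, rq$end)
      donor[[loc$dc]]$strand[loc$i] <- "-"
      add_truth("inversion", rq$chrom, rq$start, "+", rq$chrom, rq$end, "-")
      add_truth("inversion", rq$chrom, rq$start, "-", rq$chrom, rq$end, "+")
    } else if (rq$type == "unpaired_inversion") {
      donor <- donor_split(donor, rq$chrom, rq$start)
      donor <- donor_split(donor, rq$chrom, rq$end)
      loc <- donor_piece(donor, rq$chrom, rq$start, rq$end)
      p <- donor[[loc$dc]]
      inv <- p[loc$i, ]
      inv$strand <- "-"
      donor[[loc$dc]] <- bind_rows(p[seq_len(loc$i), ], inv)
      add_truth("unpaired_inversion", rq$chrom, rq$end, "+",
                rq$chrom, rq$end, "-")
    } else if (rq$type %in% c("isolated_translocation", "balanced_translocation")) {
      donor <- donor_split(donor, rq$chrom_a, rq$pos_a)
      donor <- donor_split(donor, rq$chrom_b, rq$pos_b)
      ba <- donor_boundary(donor, rq$chrom_a, rq$pos_a)
      bb <- donor_boundary(donor, rq$chrom_b, rq$pos_b)
      if (ba$dc == bb$dc) abort("translocation endpoints share a donor chromosome")
      pa <- donor[[ba$dc]]; pb <- donor[[bb$dc]]
      der_n <- der_n + 1L
      der_a <- bind_rows(pa[seq_len(ba$prefix_last), ],
                         pb[seq_len(nrow(pb)) > bb$prefix_last, ])
      new <- list(der_a)
      names(new) <- sprintf("der_%d", der_n)
      if (rq$balanced) {
        der_n <- der_n + 1L
        der_b <- bind_rows(pb[seq_len(bb$prefix_last), ],
                           pa[seq_len(nrow(pa)) > ba$prefix_last, ])
        new[[sprintf("der_%d", der_n)]] <- der_b
        add_truth("balanced_translocation", rq$chrom_a, rq$pos_a, "+",
                  rq$chrom_b, rq$pos_b, "+")
        add_truth("balanced_translocation", rq$chrom_b, rq$pos_b, "+",
                  rq$chrom_a, rq$pos_a, "+")
      } else {
        rem_n <- rem_n + 1L
        rem_a <- pa[seq_len(nrow(pa)) > ba$prefix_last, ]
        rem_b <- pb[seq_len(bb$prefix_last), ]
        if (nrow(rem_a) > 0) new[[sprintf("rem_%d_a", rem_n)]] <- rem_a
        if (nrow(rem_b) > 0) new[[sprintf("rem_%d_b", rem_n)]] <- rem_b
        add_truth("isolated_translocation", rq$chrom_a, rq$pos_a, "+",
                  rq$chrom_b, rq$pos_b, "+")
      }
      donor[[ba$dc]] <- NULL
      donor[[bb$dc]] <- NULL
      donor <- c(donor, new)
    } else if (rq$type == "insertion") {
      donor <- donor_split(donor, rq$source_chrom, rq$start)
      donor <- donor_split(donor, rq$source_chrom, rq$end)
      src <- donor_piece(donor, rq$source_chrom, rq$start, rq$end)
      seg <- donor[[src$dc]][src$i, ]
      if (rq$cut) {
        # deletion-plus-insertion: the deletion strictly contains the
        # re-inserted segment so the co-deleted margins leave a real
        # coverage gap flanking the source
        d1 <- rq$start - rq$cut_margin
        d2 <- rq$end + rq$cut_margin
        donor <- donor_split(donor, rq$source_chrom, d1)
        donor <- donor_split(donor, rq$source_chrom, d2)
        lm <- donor_piece(donor, rq$source_chrom, d1, rq$start)
        donor[[lm$dc]] <- donor[[lm$dc]][-lm$i, ]
        rm <- donor_piece(donor, rq$source_chrom, rq$end, d2)
        donor[[rm$dc]] <- donor[[rm$dc]][-rm$i, ]
        src <- donor_piece(donor, rq$source_chrom, rq$start, rq$end)
        donor[[src$dc]] <- donor[[src$dc]][-src$i, ]
      }
      if (rq$inverted) seg$strand <- "-"
      donor <- donor_split(donor, rq$target_chrom, rq$target_pos)
      tb <- donor_boundary(donor, rq$target_chrom, rq$target_pos)
      p <- donor[[tb$dc]]
      donor[[tb$dc]] <- bind_rows(p[seq_len(tb$prefix_last), ], seg,
                                  p[seq_len(nrow(p)) > tb$prefix_last, ])
      intra <- rq$source_chrom == rq$target_chrom
      backward <- intra && rq$target_pos < rq$start
      subtype <- insertion_subtype_of(intra, rq$inverted, backward, rq$cut)
      rq$subtype <- subtype
      # entry/exit coordinates of the inserted copy depend on orientation
      if (rq$inverted) {
        add_truth("insertion", rq$target_chrom, rq$target_pos, "+",
                  rq$source_chrom, rq$end, "-", subtype)
        add_truth("insertion", rq$source_chrom, rq$start, "-",
                  rq$target_chrom, rq$target_pos, "+", subtype)
      } else {
        add_truth("insertion", rq$target_chrom, rq$target_pos, "+",
                  rq$source_chrom, rq$start, "+", subtype)
        add_truth("insertion", rq$source_chrom, rq$end, "+",
                  rq$target_chrom, rq$target_pos, "+", subtype)
      }
      if (rq$cut) {
        # the containing deletion also leaves a deletion-type fusion
        add_truth("deletion", rq$source_chrom, rq$start - rq$cut_margin, "+",
                  rq$source_chrom, rq$end + rq$cut_margin, "+")
      }
    } else if (rq$type == "derivative") {
      segs <- rq$segments
      for (cp in seq_len(rq$copies)) {
        der_n <- der_n + 1L
        donor[[sprintf("der_%d", der_n)]] <- segs
      }
      if (nrow(segs) > 1) {
        for (i in seq_len(nrow(segs) - 1)) {
          a <- segs[i, ]; b <- segs[i + 1, ]
          exit5 <- if (a$strand == "+") a$end else a$start
          entry3 <- if (b$strand == "+") b$start else b$end
          add_truth(junction_call_type(a$chrom, exit5, a$strand,
                                       b$chrom, entry3, b$strand),
                    a$chrom, exit5, a$strand, b$chrom, entry3, b$strand)
        }
      }
    } else {
      abort(sprintf("unknown request type '%s'", rq$type))
    }
    requests[[k]] <- rq
  }
  truth <- if (length(truth)) bind_rows(truth) %>%
    distinct(.data$chrom5, .data$pos5, .data$strand5, .data$chrom3,
             .data$pos3, .data$strand3, .keep_all = TRUE) else empty_truth()
  truth$fusion_id <- seq_len(nrow(truth))
  plan$donor <- donor
  plan$truth <- truth
  plan$requests <- c(plan$requests, requests)
  plan
}

# Single-cluster call type a junction with this geometry will produce
# (span cutoffs aside).
junction_call_type <- function(c5, p5, s5, c3, p3, s3) {
  if (c5 != c3) return("isolated_translocation")
  if (s5 != s3) return("unpaired_inversion")
  order_ok <- if (s5 == "+") p5 <= p3 else p3 <= p5
  if (order_ok) "deletion" else "tandem_duplication"
}

validate_requests <- function(plan, requests) {
  mods <- list(); reads <- list()
  add <- function(lst, chrom, start, end) {
    lst[[length(lst) + 1L]] <- tibble(chrom = chrom, start = start, end = end)
    lst
  }
  chrom_len <- setNames(plan$genome$length, plan$genome$chrom)
  check_on <- function(chrom, ...) {
    pos <- c(...)
    if (!chrom %in% names(chrom_len)) {
      abort(sprintf("unknown chromosome '%s'", chrom))
    }
    if (any(pos < 0 | pos > chrom_len[[chrom]])) {
      abort(sprintf("request coordinates outside %s", chrom))
    }
  }
  for (rq in requests) {
    if (rq$type %in% c("deletion", "tandem_duplication", "inversion")) {
      check_on(rq$chrom, rq$start, rq$end)
      mods <- add(mods, rq$chrom, rq$start, rq$end)
    } else if (rq$type == "unpaired_inversion") {
      check_on(rq$chrom, rq$start, rq$end)
      mods <- add(mods, rq$chrom, rq$start, chrom_len[[rq$chrom]])
    } else if (rq$type %in% c("isolated_translocation", "balanced_translocation")) {
      check_on(rq$chrom_a, rq$pos_a); check_on(rq$chrom_b, rq$pos_b)
      mods <- add(mods, rq$chrom_a, rq$pos_a, rq$pos_a)
      mods <- add(mods, rq$chrom_b, rq$pos_b, rq$pos_b)
    } else if (rq$type == "insertion") {
      check_on(rq$source_chrom, rq$start, rq$end)
      check_on(rq$target_chrom, rq$target_pos)
      mods <- add(mods, rq$target_chrom, rq$target_pos, rq$target_pos)
      if (rq$cut) {
        mods <- add(mods, rq$source_chrom, rq$start - rq$cut_margin,
                    rq$end + rq$cut_margin)
      } else {
        reads <- add(reads, rq$source_chrom, rq$start, rq$end)
      }
    } else if (rq$type == "derivative") {
      for (i in seq_len(nrow(rq$segments))) {
        check_on(rq$segments$chrom[i], rq$segments$start[i], rq$segments$end[i])
        reads <- add(reads, rq$segments$chrom[i], rq$segments$start[i],
                     rq$segments$end[i])
      }
    }
  }
  mods <- bind_rows(mods); reads <- bind_rows(reads)
  overlap <- function(a, b) {
    a$chrom == b$chrom & pmax(a$start, b$start) < pmin(a$end, b$end)
  }
  if (nrow(mods) > 1) {
    for (i in seq_len(nrow(mods) - 1)) {
      for (j in (i + 1):nrow(mods)) {
        if (overlap(mods[i, ], mods[j, ])) {
          abort(sprintf("overlapping requests at %s:%g-%g",
                        mods$chrom[i], mods$start[i], mods$end[i]))
        }
      }
    }
  }
  if (nrow(mods) > 0 && nrow(reads) > 0) {
    for (i in seq_len(nrow(reads))) {
      for (j in seq_len(nrow(mods))) {
        if (overlap(reads[i, ], mods[j, ])) {
          abort(sprintf("request edits a copied region at %s:%g-%g",
                        reads$chrom[i], reads$start[i], reads$end[i]))
        }
      }
    }
  }
  invisible(TRUE)
}

#' Fusion points present in the assembled donor genome
#'
#' Walks every donor chromosome and reports each junction between
#' consecutive segments that are not reference-adjacent. Used to audit that
#' the donor assembly agrees with the analytic truth table.
#'
#' @param plan A planted [genome_plan()].
#' @return Tibble `chrom5, pos5, strand5, chrom3, pos3, strand3`, one row
#'   per distinct fusion.
#' @export
donor_fusions <- function(plan) {
  out <- list()
  for (p in plan$donor) {
    if (nrow(p) < 2) next
    for (i in seq_len(nrow(p) - 1)) {
      a <- p[i, ]; b <- p[i + 1, ]
      ref_adjacent <- a$chrom == b$chrom && a$strand == b$strand &&
        ((a$strand == "+" && a$end == b$start) ||
           (a$strand == "-" && a$start == b$end))
      if (ref_adjacent) next
      out[[length(out) + 1L]] <- tibble(
        chrom5 = a$chrom, pos5 = if (a$strand == "+") a$end else a$start,
        strand5 = a$strand,
        chrom3 = b$chrom, pos3 = if (b$strand == "+") b$start else b$end,
        strand3 = b$strand)
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom5 = character(0), pos5 = numeric(0),
                  strand5 = character(0), chrom3 = character(0),
                  pos3 = numeric(0), strand3 = character(0)))
  }
  bind_rows(out) %>% distinct()
}

#' Simulation configuration
#'
#' Fragment-length and noise parameters of a simulated size-selected PET
#' library. The built-in presets use truncated-normal fragment lengths with
#' (mean, SD) of (1000, 100), (10000, 1000) and (20000, 2000) bp for the
#' 1 kb / 10 kb / 20 kb regimes — tight unimodal size selections whose SD
#' scales with the insert. Truncation defaults to mean +/- 4 SD.
#'
#' @param frag_mean,frag_sd Fragment length mean and SD in bp.
#' @param coverage Target physical (fragment) coverage of the reference
#'   genome; the number of fragments is `coverage * genome / frag_mean`.
#' @param n_pets Alternative to `coverage`: exact number of PETs to draw.
#' @param chimera_rate Fraction of PETs formed by chimeric ligation of two
#'   independent fragments (spurious discordant singletons).
#' @param duplicate_rate Fraction of PETs re-emitted as PCR duplicates.
#' @param tag_length Mapped tag length in bp (default 25).
#' @param trunc_lo,trunc_hi Truncation bounds of the fragment-length
#'   distribution.
#' @return A `sim_config` object.
#' @export
sim_config <- function(frag_mean, frag_sd, coverage = NULL, n_pets = NULL,
                       chimera_rate = 0.01, duplicate_rate = 0.02,
                       tag_length = 25, trunc_lo = NULL, trunc_hi = NULL) {
  if (is.null(coverage) && is.null(n_pets)) {
    abort("give either coverage or n_pets")
  }
  if (chimera_rate < 0 || chimera_rate > 1 ||
      duplicate_rate < 0 || duplicate_rate > 1) {
    abort("rates must be in [0, 1]")
  }
  if (frag_mean <= 0) abort("frag_mean must be > 0")
  structure(
    list(frag_mean = frag_mean, frag_sd = frag_sd, coverage = coverage,
         n_pets = n_pets, chimera_rate = chimera_rate,
         duplicate_rate = duplicate_rate, tag_length = tag_length,
         trunc_lo = trunc_lo %||% max(2 * tag_length + 10,
                                      frag_mean - 4 * frag_sd),
         trunc_hi = trunc_hi %||% (frag_mean + 4 * frag_sd)),
    class = "sim_config"
  )
}

#' @describeIn sim_config Preset fragment regimes matching the library
#'   presets.
#' @param preset `"1kb"`, `"10kb"` or `"20kb"`.
#' @param ... Overrides passed to `sim_config()`.
#' @export
sim_preset <- function(preset = c("1kb", "10kb", "20kb"), ...) {
  preset <- match.arg(preset)
  par <- switch(preset,
                "1kb" = c(1000, 100), "10kb" = c(10000, 1000),
                "20kb" = c(20000, 2000))
  do.call(sim_config, utils::modifyList(
    list(frag_mean = par[1], frag_sd = par[2]), list(...)))
}

# Truncated-normal sampler via inverse-CDF (exact, vectorised).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate a PET library from a planted genome plan
#'
#' Fragments are sampled uniformly along the donor genome with
#' truncated-normal lengths; the two terminal tags of each fragment are
#' mapped back to reference coordinates through the donor segment map
#' (each fragment is reported in its donor-forward orientation). A tag that
#' crosses a segment junction or lands in a masked interval is unmappable
#' and the whole PET is dropped — exactly how junction-spanning and
#' repeat tags vanish in real pipelines. A `chimera_rate` fraction of PETs
#' joins the 5' tag of one fragment to the 3' tag of an independent one,
#' and a `duplicate_rate` fraction is re-emitted as PCR duplicates.
#'
#' @param plan A planted [genome_plan()].
#' @param config A [sim_config()].
#' @param seed Integer seed; the full draw is reproducible.
#' @return A PET tibble (status `"unclassified"`); classify with
#'   [classify_pets()].
#' @export
simulate_pets <- function(plan, config, seed = 1L) {
  set.seed(seed)
  pieces <- bind_rows(lapply(names(plan$donor), function(dc) {
    p <- plan$donor[[dc]]
    if (nrow(p) == 0) return(NULL)
    p$donor_chrom <- dc
    p$len <- p$end - p$start
    p$donor_start <- cumsum(c(0, head(p$len, -1)))
    p
  }))
  chrom_lens <- pieces %>%
    group_by(.data$donor_chrom) %>%
    summarise(clen = sum(.data$len), .groups = "drop")
  ref_len <- sum(plan$genome$length)
  tagl <- config$tag_length
  n_pets <- config$n_pets %||% round(config$coverage * ref_len / config$frag_mean)
  n_chim <- rbinom(1, n_pets, config$chimera_rate)
  n_norm <- n_pets - n_chim
  n_frag <- n_norm + 2 * n_chim
  if (n_frag == 0) return(classify_ready_empty())

  lens <- round(rtruncnorm(n_frag, config$frag_mean, config$frag_sd,
                           config$trunc_lo, config$trunc_hi))
  dc_idx <- sample.int(nrow(chrom_lens), n_frag, replace = TRUE,
                       prob = chrom_lens$clen)
  clen <- chrom_lens$clen[dc_idx]
  fit <- clen >= lens + 1
  starts <- floor(runif(n_frag) * pmax(clen - lens, 1))
  dc <- chrom_lens$donor_chrom[dc_idx]

  # map one tag [pos, pos+tagl) on donor chromosome dc to reference
  map_tags <- function(dc, pos) {
    out_chrom <- rep(NA_character_, length(pos))
    out_start <- rep(NA_real_, length(pos))
    out_strand <- rep(NA_character_, length(pos))
    for (one in unique(dc)) {
      sel <- which(dc == one)
      p <- pieces[pieces$donor_chrom == one, , drop = FALSE]
      i <- findInterval(pos[sel], p$donor_start)
      ok <- i >= 1 & (pos[sel] + tagl) <= (p$donor_start[i] + p$len[i])
      off <- pos[sel] - p$donor_start[i]
      plus <- p$strand[i] == "+"
      rs <- ifelse(plus, p$start[i] + off, p$end[i] - off - tagl)
      out_chrom[sel[ok]] <- p$chrom[i][ok]
      out_start[sel[ok]] <- rs[ok]
      out_strand[sel[ok]] <- p$strand[i][ok]
    }
    tibble(chrom = out_chrom, start = out_start, strand = out_strand)
  }

  t5 <- map_tags(dc, starts)
  t3 <- map_tags(dc, starts + lens - tagl)

  # chimeric PETs: 5' tag of fragment 2j-1 with 3' tag of fragment 2j
  if (n_chim > 0) {
    ia <- n_norm + 2 * seq_len(n_chim) - 1
    ib <- n_norm + 2 * seq_len(n_chim)
    idx5 <- c(seq_len(n_norm), ia)
    idx3 <- c(seq_len(n_norm), ib)
  } else {
    idx5 <- idx3 <- seq_len(n_norm)
  }
  keep <- fit[idx5] & fit[idx3] &
    !is.na(t5$chrom[idx5]) & !is.na(t3$chrom[idx3])

  pets <- tibble(
    read_id = sprintf("pet%08d", seq_len(length(idx5))),
    chrom5 = t5$chrom[idx5], start5 = t5$start[idx5],
    end5 = t5$start[idx5] + tagl, strand5 = t5$strand[idx5],
    chrom3 = t3$chrom[idx3], start3 = t3$start[idx3],
    end3 = t3$start[idx3] + tagl, strand3 = t3$strand[idx3],
    status = "unclassified"
  )[keep, , drop = FALSE]

  pets <- drop_masked(pets, plan$masked)
  if (nrow(pets) == 0) {
    abort("no mappable PETs emitted; masked fraction too high?")
  }

  n_dup <- rbinom(1, nrow(pets), config$duplicate_rate)
  if (n_dup > 0) {
    dup <- pets[sample.int(nrow(pets), n_dup, replace = TRUE), , drop = FALSE]
    dup$read_id <- sprintf("dup%08d", seq_len(n_dup))
    pets <- bind_rows(pets, dup)
  }
  pets
}

classify_ready_empty <- function() {
  pet_tbl(character(0), character(0), numeric(0), numeric(0), character(0),
          character(0), numeric(0), numeric(0), character(0))
}

# Remove PETs with a tag overlapping a masked interval.
drop_masked <- function(pets, masked) {
  if (nrow(masked) == 0 || nrow(pets) == 0) return(pets)
  hit <- function(chrom, start, end) {
    res <- rep(FALSE, length(chrom))
    for (one in unique(masked$chrom)) {
      m <- masked[masked$chrom == one, , drop = FALSE]
      m <- m[order(m$start), , drop = FALSE]
      sel <- which(chrom == one)
      if (length(sel) == 0) next
      i <- findInterval(start[sel], m$start)
      over <- (i >= 1 & m$end[pmax(i, 1)] > start[sel]) |
        (i < nrow(m) & m$start[pmin(i + 1, nrow(m))] < end[sel])
      res[sel] <- over
    }
    res
  }
  bad <- hit(pets$chrom5, pets$start5, pets$end5) |
    hit(pets$chrom3, pets$start3, pets$end3)
  pets[!bad, , drop = FALSE]
}

#' Score SV calls against simulation ground truth
#'
#' A call matches a truth fusion point when one of its clusters' predicted
#' breakpoint pair lies within `window` (one nominal insert size) of the
#' fusion's two coordinates, directly or side-swapped. A planted SV is
#' *recovered* when every one of its fusion points is matched by a call of
#' the expected type (and, for insertions, the expected sub-type when
#' `require_subtype` is on). Precision counts the fraction of calls that
#' match any truth fusion.
#'
#' @param truth Truth table from a planted [genome_plan()] (`plan$truth`).
#' @param calls SV call tibble.
#' @param window Matching window in bp (use the library's nominal insert).
#' @param sv_ids Optional subset of truth `sv_id`s over which recall is
#'   computed (precision always uses the full truth table).
#' @param require_subtype Require insertion sub-types to match exactly
#'   (default TRUE; disable when calls were typed without a coverage
#'   track).
#' @return An object of class `truth_report`: list with `per_sv`,
#'   `recall_by_type`, `recall`, `precision`, `confusion`,
#'   `resolution_records`.
#' @export
truth_report <- function(truth, calls, window, sv_ids = NULL,
                         require_subtype = TRUE) {
  # breakpoint pairs per call, one row per supporting cluster
  pair_rows <- function(calls) {
    bind_rows(
      tibble(sv_id = calls$sv_id, sv_type = calls$sv_type,
             subtype = calls$insertion_subtype,
             chromA = calls$chrom5_1, bpA = calls$bp5_1,
             chromB = calls$chrom3_1, bpB = calls$bp3_1),
      tibble(sv_id = calls$sv_id, sv_type = calls$sv_type,
             subtype = calls$insertion_subtype,
             chromA = calls$chrom5_2, bpA = calls$bp5_2,
             chromB = calls$chrom3_2, bpB = calls$bp3_2)
    ) %>% filter(!is.na(.data$chromA))
  }
  cp <- pair_rows(calls)

  match_fusion <- function(f) {
    direct <- cp$chromA == f$chrom5 & cp$chromB == f$chrom3 &
      abs(cp$bpA - f$pos5) <= window & abs(cp$bpB - f$pos3) <= window
    swapped <- cp$chromA == f$chrom3 & cp$chromB == f$chrom5 &
      abs(cp$bpA - f$pos3) <= window & abs(cp$bpB - f$pos5) <= window
    which(direct | swapped)
  }

  n_f <- nrow(truth)
  fusion_hit <- logical(n_f)
  fusion_type_ok <- logical(n_f)
  best_type <- rep(NA_character_, n_f)
  res_records <- list()
  matched_call_ids <- integer(0)
  for (i in seq_len(n_f)) {
    f <- truth[i, ]
    hits <- match_fusion(f)
    if (length(hits) == 0) next
    fusion_hit[i] <- TRUE
    matched_call_ids <- c(matched_call_ids, cp$sv_id[hits])
    # nearest match for confusion/resolution
    d <- vapply(hits, function(h) {
      min(abs(cp$bpA[h] - f$pos5) + abs(cp$bpB[h] - f$pos3),
          abs(cp$bpA[h] - f$pos3) + abs(cp$bpB[h] - f$pos5))
    }, numeric(1))
    type_hits <- hits[cp$sv_type[hits] == f$expected_type &
                        (!require_subtype | is.na(f$expected_subtype) |
                           (!is.na(cp$subtype[hits]) &
                              cp$subtype[hits] == f$expected_subtype))]
    fusion_type_ok[i] <- length(type_hits) > 0
    use <- if (length(type_hits) > 0) {
      type_hits[which.min(d[match(type_hits, hits)])]
    } else hits[which.min(d)]
    best_type[i] <- cp$sv_type[use]
    swap <- (abs(cp$bpA[use] - f$pos3) + abs(cp$bpB[use] - f$pos5)) <
      (abs(cp$bpA[use] - f$pos5) + abs(cp$bpB[use] - f$pos3))
    p5 <- if (swap) cp$bpB[use] else cp$bpA[use]
    p3 <- if (swap) cp$bpA[use] else cp$bpB[use]
    res_records[[length(res_records) + 1L]] <- tibble(
      fusion_id = f$fusion_id, sv_id = f$sv_id, sv_type = f$sv_type,
      side = c("5", "3"),
      predicted = c(p5, p3), truth = c(f$pos5, f$pos3),
      resolution = c(abs(p5 - f$pos5), abs(p3 - f$pos3)))
  }

  use_truth <- if (is.null(sv_ids)) truth else truth[truth$sv_id %in% sv_ids, ]
  sel <- truth$sv_id %in% use_truth$sv_id
  per_sv <- tibble(sv_id = truth$sv_id[sel], sv_type = truth$sv_type[sel],
                   ok = fusion_type_ok[sel]) %>%
    group_by(.data$sv_id, .data$sv_type) %>%
    summarise(n_fusions = dplyr::n(), recovered = all(.data$ok),
              .groups = "drop")
  recall_by_type <- per_sv %>%
    group_by(.data$sv_type) %>%
    summarise(n = dplyr::n(), n_recovered = sum(.data$recovered),
              recall = .data$n_recovered / .data$n, .groups = "drop")
  precision <- if (nrow(calls) == 0) NA_real_ else
    mean(calls$sv_id %in% matched_call_ids)
  confusion <- tibble(truth_type = truth$expected_type,
                      call_type = best_type) %>%
    filter(!is.na(.data$call_type)) %>%
    dplyr::count(.data$truth_type, .data$call_type)
  structure(
    list(per_sv = per_sv, recall_by_type = recall_by_type,
         recall = mean(per_sv$recovered), precision = precision,
         n_calls = nrow(calls),
         confusion = confusion,
         resolution_records = bind_rows(res_records)),
    class = "truth_report"
  )
}

#' @export
print.truth_report <- function(x, ...) {
  cat(sprintf("<truth_report> recall %.3f, precision %.3f over %d SV(s), %d call(s)\n",
              x$recall, x$precision, nrow(x$per_sv), x$n_calls))
  print(x$recall_by_type, n = 20)
  invisible(x)
}

#' @describeIn truth_report Per-type recall rows.
#' @param x A `truth_report`.
#' @param ... Unused.
#' @export
tidy.truth_report <- function(x, ...) x$recall_by_type

#' @describeIn truth_report One-row summary.
#' @export
glance.truth_report <- function(x, ...) {
  tibble(recall = x$recall, precision = x$precision,
         n_svs = nrow(x$per_sv), n_calls = x$n_calls,
         median_resolution = median_resolution(x$resolution_records))
}
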