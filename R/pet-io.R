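#' Build a PET table from vectors
#'
#' The central data structure of the package is the PET table: one row per
#' mapped di-tag, with the 5' and 3' tag alignments side by side. All
#' coordinates are 0-based half-open (`start` inclusive, `end` exclusive);
#' converters at the I/O boundary handle 1-based genome-browser coordinates.
#'
#' @param read_id Character vector of read identifiers.
#' @param chrom5,start5,end5,strand5 5' tag alignment (chromosome, 0-based
#'   start, exclusive end, strand `"+"`/`"-"`).
#' @param chrom3,start3,end3,strand3 3' tag alignment.
#' @return A tibble with one row per PET and a `status` column initialised to
#'   `"unclassified"`.
#' @seealso [classify_pets()], [read_pet_table()]
#' @export
pet_tbl <- function(read_id, chrom5, start5, end5, strand5,
                    chrom3, start3, end3, strand3) {
  out <- tibble(
    read_id = as.character(read_id),
    chrom5 = as.character(chrom5), start5 = as.numeric(start5),
    end5 = as.numeric(end5), strand5 = as.character(strand5),
    chrom3 = as.character(chrom3), start3 = as.numeric(start3),
    end3 = as.numeric(end3), strand3 = as.character(strand3),
    status = "unclassified"
  )
  validate_pet_tbl(out)
  out
}

pet_cols <- c("read_id", "chrom5", "start5", "end5", "strand5",
              "chrom3", "start3", "end3", "strand3")

validate_pet_tbl <- function(pets) {
  stopifnot_cols(pets, pet_cols, "PET table")
  bad <- which(pets$start5 >= pets$end5 | pets$start3 >= pets$end3)
  if (length(bad) > 0) {
    abort(sprintf("PET table rows with start >= end: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  bad_strand <- which(!(pets$strand5 %in% c("+", "-")) |
                        !(pets$strand3 %in% c("+", "-")))
  if (length(bad_strand) > 0) {
    abort(sprintf("PET table rows with unknown strand: %s",
                  paste(head(bad_strand, 5), collapse = ", ")))
  }
  invisible(pets)
}

#' Read a PET table from a tab-delimited file
#'
#' Expects one PET per line with columns `read_id, chrom5, start5, end5,
#' strand5, chrom3, start3, end3, strand3` (or BEDPE column order with
#' `format = "bedpe"`: chrom1 start1 end1 chrom2 start2 end2 name score
#' strand1 strand2). Lines starting with `#` are comments. Malformed lines
#' (start >= end, unknown strand, wrong field count, non-numeric coordinate)
#' are rejected individually and summarised in a warning; parsing continues.
#'
#' @param path Path to the file.
#' @param format `"pet"` (native column order) or `"bedpe"`.
#' @param one_based Set `TRUE` if starts are 1-based inclusive; they are
#'   converted to 0-based half-open on read.
#' @return A PET tibble; the number of rejected lines and their line numbers
#'   are attached as attribute `"rejected"`.
#' @export
read_pet_table <- function(path, format = c("pet", "bedpe"), one_based = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("cannot read '%s'", path))
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    out <- pet_tbl(character(0), character(0), numeric(0), numeric(0),
                   character(0), character(0), numeric(0), numeric(0),
                   character(0))
    attr(out, "rejected") <- integer(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_need <- if (format == "pet") 9L else 10L
  parse_one <- function(f) {
    if (length(f) < ncol_need) return(NULL)
    if (format == "pet") {
      rec <- list(read_id = f[1], chrom5 = f[2], start5 = f[3], end5 = f[4],
                  strand5 = f[5], chrom3 = f[6], start3 = f[7], end3 = f[8],
                  strand3 = f[9])
    } else {
      rec <- list(read_id = f[7], chrom5 = f[1], start5 = f[2], end5 = f[3],
                  strand5 = f[9], chrom3 = f[4], start3 = f[5], end3 = f[6],
                  strand3 = f[10])
    }
    s5 <- suppressWarnings(as.numeric(rec$start5)); e5 <- suppressWarnings(as.numeric(rec$end5))
    s3 <- suppressWarnings(as.numeric(rec$start3)); e3 <- suppressWarnings(as.numeric(rec$end3))
    if (anyNA(c(s5, e5, s3, e3))) return(NULL)
    if (one_based) { s5 <- s5 - 1; s3 <- s3 - 1 }
    if (s5 >= e5 || s3 >= e3) return(NULL)
    if (!(rec$strand5 %in% c("+", "-")) || !(rec$strand3 %in% c("+", "-"))) return(NULL)
    c(rec$read_id, rec$chrom5, s5, e5, rec$strand5, rec$chrom3, s3, e3, rec$strand3)
  }
  parsed <- lapply(fields, parse_one)
  ok <- !vapply(parsed, is.null, logical(1))
  rejected <- lineno[!ok]
  if (length(rejected) > 0) {
    warn(sprintf("rejected %d malformed line(s): %s", length(rejected),
                 paste(head(rejected, 10), collapse = ", ")))
  }
  m <- do.call(rbind, parsed[ok])
  if (is.null(m)) {
    out <- pet_tbl(character(0), character(0), numeric(0), numeric(0),
                   character(0), character(0), numeric(0), numeric(0),
                   character(0))
  } else {
    out <- pet_tbl(m[, 1], m[, 2], as.numeric(m[, 3]), as.numeric(m[, 4]),
                   m[, 5], m[, 6], as.numeric(m[, 7]), as.numeric(m[, 8]),
                   m[, 9])
  }
  attr(out, "rejected") <- rejected
  out
}

#' Write a PET table
#'
#' @param pets PET tibble.
#' @param path Output path.
#' @param format `"pet"` or `"bedpe"` column order.
#' @return `path`, invisibly.
#' @export
write_pet_table <- function(pets, path, format = c("pet", "bedpe")) {
  format <- match.arg(format)
  validate_pet_tbl(pets)
  header <- "# petsv PET table; 0-based half-open coordinates"
  if (format == "pet") {
    df <- pets[, pet_cols]
  } else {
    df <- tibble(chrom1 = pets$chrom5, start1 = pets$start5, end1 = pets$end5,
                 chrom2 = pets$chrom3, start2 = pets$start3, end2 = pets$end3,
                 name = pets$read_id, score = ".", strand1 = pets$strand5,
                 strand2 = pets$strand3)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Import PETs from a name-sorted SAM file
#'
#' Best-effort importer for mate-pair runs stored in SAM: primary alignments
#' are paired by query name; the first-in-pair read is taken as the 5' tag.
#' Reads with unmapped self or mate, secondary or supplementary alignments
#' are skipped. This is a convenience path; the native tab format is primary.
#'
#' @param path Path to a SAM file.
#' @return A PET tibble.
#' @export
read_pets_sam <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read '%s'", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(pet_tbl(character(0), character(0), numeric(0), numeric(0),
                   character(0), character(0), numeric(0), numeric(0),
                   character(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(f, `[`, "", 1)
  flag <- as.integer(vapply(f, `[`, "", 2))
  rname <- vapply(f, `[`, "", 3)
  pos <- as.numeric(vapply(f, `[`, "", 4))
  seqlen <- nchar(vapply(f, `[`, "", 10))
  cigar_ref_len <- function(cig) {
    m <- gregexpr("\\d+[MIDNSHP=X]", cig)[[1]]
    if (m[1] == -1) return(NA_real_)
    ops <- regmatches(cig, gregexpr("\\d+[MIDNSHP=X]", cig))[[1]]
    sum(vapply(ops, function(o) {
      n <- as.numeric(sub("[A-Z=]$", "", o))
      if (grepl("[MDN=X]$", o)) n else 0
    }, numeric(1)))
  }
  reflen <- vapply(vapply(f, `[`, "", 6), cigar_ref_len, numeric(1))
  reflen[is.na(reflen)] <- seqlen[is.na(reflen)]
  keep <- bitwAnd(flag, 0x4) == 0 & bitwAnd(flag, 0x8) == 0 &
    bitwAnd(flag, 0x100) == 0 & bitwAnd(flag, 0x800) == 0 &
    bitwAnd(flag, 0x1) == 1
  first <- bitwAnd(flag, 0x40) != 0
  strand <- ifelse(bitwAnd(flag, 0x10) != 0, "-", "+")
  start0 <- pos - 1
  end0 <- start0 + reflen
  d5 <- data.frame(qname, rname, start0, end0, strand,
                   stringsAsFactors = FALSE)[keep & first, ]
  d3 <- data.frame(qname, rname, start0, end0, strand,
                   stringsAsFactors = FALSE)[keep & !first, ]
  j <- merge(d5, d3, by = "qname", suffixes = c("5", "3"))
  pet_tbl(j$qname, j$rname5, j$start05, j$end05, j$strand5,
          j$rname3, j$start03, j$end03, j$strand3)
}

# Strand-aware 5'-to-3' order predicate, vectorised.
# same_strand convention: on "+" the 5' tag is upstream, on "-" downstream.
# fr convention: tags on opposite strands; the "+" tag (always the 5' one in
# a proper pair) is leftmost — the same coordinate test applies.
pet_order_ok <- function(pets, orientation) {
  ifelse(pets$strand5 == "+", pets$start5 <= pets$start3,
         pets$start3 <= pets$start5)
}

pet_orientation_ok <- function(pets, orientation) {
  if (orientation == "same_strand") {
    pets$strand5 == pets$strand3
  } else {
    pets$strand5 != pets$strand3
  }
}

#' Outermost-coordinate span of each PET
#'
#' Span is the distance between the outermost mapped coordinates of the two
#' tags: `max(end5, end3) - min(start5, start3)`. Defined for any pair on one
#' chromosome; `NA` across chromosomes.
#'
#' @param pets PET tibble.
#' @return Numeric vector of spans in bp.
#' @export
pet_span <- function(pets) {
  ifelse(pets$chrom5 == pets$chrom3,
         pmax(pets$end5, pets$end3) - pmin(pets$start5, pets$start3),
         NA_real_)
}

#' Classify PETs as concordant or discordant
#'
#' A PET is concordant when both tags map to the same chromosome, the
#' orientation matches the library convention, the tags are in correct
#' 5'-to-3' order, and the outer span lies within the library's concordant
#' range (inclusive bounds). Every other PET is discordant. The function is
#' total: every row receives exactly one of the two labels.
#'
#' @param pets PET tibble.
#' @param config A [pet_library()] configuration.
#' @return The PET tibble with `span` and `status` columns filled in.
#' @examples
#' lib <- library_preset("1kb")
#' p <- pet_tbl("r1", "chr1", 1000, 1025, "+", "chr1", 1775, 1800, "+")
#' classify_pets(p, lib)$status  # concordant (span 800)
#' @export
classify_pets <- function(pets, config) {
  validate_pet_tbl(pets)
  span <- pet_span(pets)
  conc <- pets$chrom5 == pets$chrom3 &
    pet_orientation_ok(pets, config$orientation) &
    pet_order_ok(pets, config$orientation) &
    !is.na(span) & span >= config$span_min & span <= config$span_max
  pets$span <- span
  pets$status <- ifelse(conc, "concordant", "discordant")
  pets
}

#' Remove redundant PETs
#'
#' Keeps at most one PET per exact coordinate tuple of both tags
#' (chromosome, start, end, strand of the 5' and the 3' tag). The first
#' occurrence is retained. This models the removal of PCR-duplicate
#' redundancy based on tag mapping locations, not read sequence.
#'
#' @param pets PET tibble.
#' @return PET tibble with duplicates removed; idempotent.
#' @export
deduplicate_pets <- function(pets) {
  validate_pet_tbl(pets)
  distinct(pets, .data$chrom5, .data$start5, .data$end5, .data$strand5,
           .data$chrom3, .data$start3, .data$end3, .data$strand3,
           .keep_all = TRUE)
}

#' Randomly down-sample a PET library
#'
#' Retains each PET independently with probability
#' `p = required / nrow(pets)`; the retained count is therefore
#' Binomial(n, p) rather than exactly `required`. This mirrors the
#' per-record random-number scheme used to equalise non-redundant PET
#' numbers across libraries.
#'
#' @param pets PET tibble.
#' @param required Target number of PETs (0 <= required <= nrow).
#' @param seed Integer seed; the draw is reproducible for a fixed seed.
#' @return Down-sampled PET tibble.
#' @export
downsample_pets <- function(pets, required, seed = 1L) {
  validate_pet_tbl(pets)
  n <- nrow(pets)
  if (required < 0 || required > n) {
    abort(sprintf("required (%s) must be between 0 and nrow(pets) (%s)",
                  required, n))
  }
  if (n == 0) return(pets)
  p <- required / n
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  u <- withr_seed(runif(n))
  pets[u < p, , drop = FALSE]
}

#' Span statistics of a library's concordant PETs
#'
#' Descriptive statistics (median, mean, SD) and a histogram of the
#' outer-coordinate spans of concordant PETs — the empirical insert-size
#' distribution of the library.
#'
#' @param pets Classified PET tibble (see [classify_pets()]).
#' @param config The library configuration (used for the histogram range).
#' @param binwidth Histogram bin width in bp; defaults to 1/50 of `span_max`.
#' @return An object of class `pet_spans`: list with `median`, `mean`, `sd`,
#'   `n`, and a `histogram` tibble (`bin_start`, `bin_end`, `count`).
#' @export
span_stats <- function(pets, config, binwidth = NULL) {
  stopifnot_cols(pets, c("status"), "classified PET table")
  spans <- pet_span(pets)[pets$status == "concordant"]
  spans <- spans[!is.na(spans)]
  if (length(spans) == 0) abort("no concordant PETs; cannot compute span statistics")
  binwidth <- binwidth %||% max(1, round(config$span_max / 50))
  breaks <- seq(0, max(config$span_max, max(spans)) + binwidth, by = binwidth)
  h <- hist(spans, breaks = breaks, plot = FALSE)
  structure(
    list(
      median = median(spans),
      mean = mean(spans),
      sd = if (length(spans) > 1) sd(spans) else 0,
      n = length(spans),
      library = config$name,
      histogram = tibble(bin_start = head(h$breaks, -1),
                         bin_end = tail(h$breaks, -1),
                         count = h$counts)
    ),
    class = "pet_spans"
  )
}

#' @export
print.pet_spans <- function(x, ...) {
  cat(sprintf("<pet_spans '%s'> n=%d median=%.0f mean=%.1f sd=%.1f\n",
              x$library, x$n, x$median, x$mean, x$sd))
  invisible(x)
}

#' Physical (fragment) coverage of a genome
#'
#' Physical coverage is the summed span of concordant fragments divided by
#' the genome length — clone coverage, as opposed to nucleotide sequencing
#' depth. Large-insert libraries reach much higher physical coverage at the
#' same tag count, which drives their sensitivity for rearrangements.
#'
#' @param pets Classified PET tibble.
#' @param genome_length Genome length in bp (> 0).
#' @return Fold physical coverage (numeric scalar).
#' @export
physical_coverage <- function(pets, genome_length) {
  if (genome_length <= 0) abort("genome_length must be > 0")
  stopifnot_cols(pets, "status", "classified PET table")
  spans <- pet_span(pets)[pets$status == "concordant"]
  sum(spans, na.rm = TRUE) / genome_length
}
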