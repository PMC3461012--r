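#' Describe a PET sequencing library
#'
#' A library configuration captures the insert-size model of one mate-pair
#' (paired-end-tag, PET) library: the nominal fragment size selected on the
#' gel, the span range within which a tag pair is still considered concordant,
#' the orientation convention of the platform, and the cluster-count cutoffs
#' used downstream.
#'
#' The span of a PET is the distance between the outermost mapped coordinates
#' of its two tags. A pair is concordant when both tags map to the same
#' chromosome, in the expected orientation and 5'-to-3' order, with a span
#' inside `[span_min, span_max]` (both bounds inclusive). Everything else is
#' discordant and a candidate rearrangement signal.
#'
#' @param name Library name (free text, used in reports).
#' @param nominal_insert Nominal fragment size in bp (the size selection
#'   target); also the window used when matching calls to ground truth.
#' @param span_max Maximum concordant span in bp. For the built-in presets
#'   this is 3 kb for 1 kb inserts, 20 kb for 10 kb and 40 kb for 20 kb.
#' @param span_min Minimum concordant span in bp; defaults to 0 (size
#'   selection implies a practical minimum, which tight protocols may set).
#' @param orientation Concordant orientation convention. `"same_strand"`
#'   (SOLiD mate-pair: both tags on one strand, 5' tag upstream on `+`,
#'   downstream on `-`) or `"fr"` (forward/reverse paired-end: tags on
#'   opposite strands, the `+` tag leftmost).
#' @param cluster_count_min Minimum number of discordant PETs per cluster for
#'   a call (default 3).
#' @param specific_cluster_count_min Stricter minimum applied to clusters
#'   claimed specific to a large-insert library in cross-library comparison
#'   (default 6).
#'
#' @return An object of class `pet_library` (a named list).
#' @examples
#' lib <- pet_library("10kb", nominal_insert = 10000, span_max = 20000)
#' lib$span_max
#' @export
pet_library <- function(name,
                        nominal_insert,
                        span_max,
                        span_min = 0,
                        orientation = c("same_strand", "fr"),
                        cluster_count_min = 3L,
                        specific_cluster_count_min = 6L) {
  orientation <- match.arg(orientation)
  if (!(span_min >= 0 && span_min < span_max)) {
    abort("need 0 <= span_min < span_max")
  }
  if (cluster_count_min < 1) abort("cluster_count_min must be >= 1")
  if (specific_cluster_count_min < cluster_count_min) {
    abort("specific_cluster_count_min must be >= cluster_count_min")
  }
  structure(
    list(
      name = as.character(name),
      nominal_insert = as.numeric(nominal_insert),
      span_max = as.numeric(span_max),
      span_min = as.numeric(span_min),
      orientation = orientation,
      cluster_count_min = as.integer(cluster_count_min),
      specific_cluster_count_min = as.integer(specific_cluster_count_min)
    ),
    class = "pet_library"
  )
}

#' Built-in library presets
#'
#' Presets for the three insert-size regimes commonly used with large-insert
#' DNA-PET sequencing: 1 kb (concordant span up to 3 kb), 10 kb (up to
#' 20 kb) and 20 kb (up to 40 kb).
#'
#' @param preset One of `"1kb"`, `"10kb"`, `"20kb"`.
#' @param ... Overrides passed on to [pet_library()].
#' @return A `pet_library` object.
#' @examples
#' library_preset("1kb")$span_max  # 3000
#' @export
library_preset <- function(preset = c("1kb", "10kb", "20kb"), ...) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    "1kb"  = list(name = "1kb",  nominal_insert = 1000,  span_max = 3000),
    "10kb" = list(name = "10kb", nominal_insert = 10000, span_max = 20000),
    "20kb" = list(name = "20kb", nominal_insert = 20000, span_max = 40000)
  )
  overrides <- list(...)
  do.call(pet_library, utils::modifyList(defaults, overrides))
}

#' @export
print.pet_library <- function(x, ...) {
  cat(sprintf(
    "<pet_library '%s'> insert %g bp, concordant span [%g, %g], %s, min count %d (specific %d)\n",
    x$name, x$nominal_insert, x$span_min, x$span_max, x$orientation,
    x$cluster_count_min, x$specific_cluster_count_min))
  invisible(x)
}
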