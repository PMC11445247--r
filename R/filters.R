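#' Site filter configuration
#'
#' Coverage and quality thresholds applied to per-site allelic depths before
#' the allele-fraction histogram is built. The defaults restrict total read
#' coverage to the range 20--200 and require each allele to be supported by
#' strictly more than 7 reads, so that only confidently heterozygous sites
#' contribute to the ploidy signal.
#'
#' @param min_total Minimum admissible total depth (ref + alt), inclusive.
#' @param max_total Maximum admissible total depth, inclusive.
#' @param min_alt A site is retained only if `alt_depth` strictly exceeds
#'   this count (default 7, i.e. at least 8 alt reads).
#' @param min_ref Symmetric threshold on `ref_depth` restricting the
#'   histogram to heterozygous sites; set to `NA` to disable.
#' @param min_mapq Mapping-quality floor used by the alignment reader; reads
#'   below it are excluded from the pileup (operationalises "uniquely
#'   mapped").
#' @param min_baseq Base-quality floor used by the alignment reader.
#' @param fraction_window Closed interval of admissible alternative-allele
#'   fractions; trims residual homozygote/error mass near 0 and 1.
#' @return An object of class `filter_config`.
#' @examples
#' f <- filter_config()
#' apply_site_filter(site_depths("chr1", 100, ref_depth = 12, alt_depth = 8), f)
#' @export
filter_config <- function(min_total = 20L, max_total = 200L, min_alt = 7L,
                          min_ref = 7L, min_mapq = 20L, min_baseq = 13L,
                          fraction_window = c(0.05, 0.95)) {
  min_total <- as.integer(min_total)
  max_total <- as.integer(max_total)
  min_alt <- as.integer(min_alt)
  min_ref <- if (is.null(min_ref) || is.na(min_ref)) NA_integer_ else as.integer(min_ref)
  stopifnot(min_total > 0L, min_total <= max_total, min_alt >= 0L)
  if (!is.numeric(fraction_window) || length(fraction_window) != 2L ||
      fraction_window[1] < 0 || fraction_window[2] > 1 ||
      fraction_window[1] >= fraction_window[2]) {
    stop("`fraction_window` must be an interval [lo, hi] within [0, 1] with lo < hi")
  }
  structure(
    list(min_total = min_total, max_total = max_total, min_alt = min_alt,
         min_ref = min_ref, min_mapq = as.integer(min_mapq),
         min_baseq = as.integer(min_baseq),
         fraction_window = as.numeric(fraction_window)),
    class = "filter_config"
  )
}

#' @export
print.filter_config <- function(x, ...) {
  cat("Site filter: total depth in [", x$min_total, ", ", x$max_total,
      "], alt depth > ", x$min_alt, sep = "")
  if (!is.na(x$min_ref)) cat(", ref depth >", x$min_ref)
  cat(", fraction in [", x$fraction_window[1], ", ", x$fraction_window[2], "]\n",
      sep = "")
  invisible(x)
}

#' Build a table of per-site allelic depths
#'
#' Constructs and validates the canonical site-depth table used throughout
#' the package: one row per biallelic site with reference and alternative
#' read counts.
#'
#' @param contig Sequence name(s).
#' @param pos 1-based position(s).
#' @param ref_depth,alt_depth Non-negative read counts supporting the
#'   reference and the (single) alternative allele.
#' @return A `data.frame` with columns `contig`, `pos`, `ref_depth`,
#'   `alt_depth`, `total_depth`.
#' @export
site_depths <- function(contig, pos, ref_depth, alt_depth) {
  pos <- as.integer(pos)
  ref_depth <- as.integer(ref_depth)
  alt_depth <- as.integer(alt_depth)
  n <- max(length(contig), length(pos), length(ref_depth), length(alt_depth))
  df <- data.frame(
    contig = rep_len(as.character(contig), n),
    pos = rep_len(pos, n),
    ref_depth = rep_len(ref_depth, n),
    alt_depth = rep_len(alt_depth, n),
    stringsAsFactors = FALSE
  )
  if (any(df$pos < 1L)) stop("positions must be >= 1 (1-based coordinates)")
  if (any(df$ref_depth < 0L) || any(df$alt_depth < 0L)) {
    stop("allelic depths must be non-negative")
  }
  df$total_depth <- df$ref_depth + df$alt_depth
  df
}

#' Filter rejection reasons
#'
#' The enumerated, machine-readable outcomes of [apply_site_filter()], in
#' the order the predicates are evaluated.
#' @export
filter_reasons <- function() {
  c("retained", "total_below_min", "total_above_max", "alt_below_min",
    "ref_below_min", "fraction_outside_window")
}

#' Classify sites against a filter
#'
#' Total classification of each site as retained or rejected with a single
#' enumerated cause. A site is retained iff
#' `min_total <= total_depth <= max_total`, `alt_depth > min_alt`,
#' `ref_depth > min_ref` (when enabled), and the alternative-allele fraction
#' lies within `fraction_window`.
#'
#' @param sites A site-depth table as from [site_depths()].
#' @param filter A [filter_config()].
#' @return A factor (one element per site) with levels [filter_reasons()].
#' @export
apply_site_filter <- function(sites, filter = filter_config()) {
  stopifnot(inherits(filter, "filter_config"))
  total <- sites$ref_depth + sites$alt_depth
  frac <- ifelse(total > 0, sites$alt_depth / total, NA_real_)
  reason <- rep("retained", nrow(sites))
  win <- filter$fraction_window
  bad_frac <- is.na(frac) | frac < win[1] | frac > win[2]
  reason[bad_frac] <- "fraction_outside_window"
  if (!is.na(filter$min_ref)) {
    reason[sites$ref_depth <= filter$min_ref] <- "ref_below_min"
  }
  reason[sites$alt_depth <= filter$min_alt] <- "alt_below_min"
  reason[total > filter$max_total] <- "total_above_max"
  reason[total < filter$min_total] <- "total_below_min"
  factor(reason, levels = filter_reasons())
}

#' Split a site table into retained and rejected parts
#'
#' @inheritParams apply_site_filter
#' @return A list with elements `retained` (site table), `rejected` (site
#'   table with an extra `reason` column), and `counts` (named tally over
#'   [filter_reasons()]).
#' @export
filter_sites <- function(sites, filter = filter_config()) {
  reason <- apply_site_filter(sites, filter)
  keep <- reason == "retained"
  rejected <- sites[!keep, , drop = FALSE]
  rejected$reason <- as.character(reason[!keep])
  list(
    retained = sites[keep, , drop = FALSE],
    rejected = rejected,
    counts = table(reason)
  )
}
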