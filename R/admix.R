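#' Round half away from zero
#'
#' Commercial rounding (7.45 -> 7.5, 7.08 -> 7.1 at one decimal), the
#' convention that reproduces the published expected-ploidy cells; base R's
#' `round()` rounds half to even and would not.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @export
round_half_away <- function(x, digits = 1L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Expected F1 ploidy of two parental lineages
#'
#' The arithmetic mean of the parental ploidies, i.e. the ploidy of a
#' balanced first-generation hybrid formed from reduced gametes.
#'
#' @param p1,p2 Parental ploidies (>= 2).
#' @return Numeric, reported to one decimal.
#' @export
expected_f1_ploidy <- function(p1, p2) {
  stopifnot(all(p1 >= 2), all(p2 >= 2))
  round_half_away((p1 + p2) / 2, 1L)
}

#' Expected ploidy of an admixed individual
#'
#' Weighted arithmetic mean of the source-lineage ploidies with the
#' admixture proportions as weights, rounded half-away-from-zero to one
#' decimal. Proportions are used as given (not renormalised): published
#' admixture tables round proportions so rows may sum to slightly less than
#' 1, and the printed expected values are the plain weighted sums.
#'
#' @param proportions Admixture proportions (each in (0, 1]); a warning is
#'   issued if they depart from summing to 1 by more than `tol`.
#' @param ploidies Integer ploidies of the source lineages, same length.
#' @param tol Allowed departure of `sum(proportions)` from 1 before warning.
#' @return Numeric expected ploidy, one decimal.
#' @export
expected_admixture_ploidy <- function(proportions, ploidies, tol = 0.05) {
  if (length(proportions) != length(ploidies)) {
    stop("`proportions` and `ploidies` must have the same length")
  }
  stopifnot(all(proportions > 0), all(proportions <= 1), all(ploidies >= 2))
  s <- sum(proportions)
  if (abs(s - 1) > tol) {
    warning(sprintf("admixture proportions sum to %.3f, not 1", s))
  }
  round_half_away(sum(proportions * ploidies), 1L)
}

#' Classify an individual as neoploid
#'
#' Compares the predicted ploidy with the expectation from the parental
#' lineages. The comparison is strict up to a tiny epsilon (not a +-0.5
#' band): an individual predicted 8x with expectation 7.5 counts as
#' increased.
#'
#' @param expected Expected ploidy (weighted mean of lineage ploidies).
#' @param predicted Predicted (or measured) integer ploidy.
#' @param epsilon Numerical slack around equality.
#' @return `"increased"`, `"decreased"` or `"consistent"` (vectorised).
#' @export
classify_neoploidy <- function(expected, predicted, epsilon = 0.05) {
  stopifnot(epsilon >= 0)
  ifelse(predicted > expected + epsilon, "increased",
         ifelse(predicted < expected - epsilon, "decreased", "consistent"))
}

#' Flow-cytometry classifier configuration
#'
#' Reference 2C genome sizes (pg) per cytotype. Defaults are the medians of
#' the measured 2C values per predicted-ploidy group in the validation
#' panel: 4x 1.99 pg, 6x 3.09 pg, 8x 3.99 pg.
#'
#' @param class_means Named numeric vector mapping ploidy (as name) to the
#'   reference 2C value; must be strictly increasing with ploidy.
#' @export
flow_classifier_config <- function(class_means = c(`4` = 1.99, `6` = 3.09,
                                                   `8` = 3.99)) {
  ploidy <- as.integer(names(class_means))
  if (any(is.na(ploidy))) stop("`class_means` names must be integer ploidies")
  ord <- order(ploidy)
  ploidy <- ploidy[ord]; class_means <- class_means[ord]
  if (any(diff(as.numeric(class_means)) <= 0)) {
    stop("class means must be strictly increasing with ploidy")
  }
  structure(list(ploidy = ploidy, means = as.numeric(class_means)),
            class = "flow_classifier_config")
}

#' Classify a genome size into a cytotype
#'
#' Nearest-class rule on the 2C value; ties break towards the lower ploidy.
#'
#' @param size_pg 2C genome size(s) in picograms (> 0).
#' @param config A [flow_classifier_config()].
#' @return Integer ploidy per input value.
#' @export
classify_flow_cytometry <- function(size_pg, config = flow_classifier_config()) {
  stopifnot(all(size_pg > 0))
  vapply(size_pg, function(s) {
    # round distances so exact midpoints tie despite floating-point noise
    d <- round(abs(s - config$means), 9)
    config$ploidy[which.min(d)]  # which.min takes the first = lower ploidy
  }, integer(1))
}

#' Concordance between two ploidy assignments
#'
#' Fraction of shared ids with identical ploidy, plus the per-id
#' discrepancies.
#'
#' @param predicted,reference Named integer vectors (names are sample ids).
#' @return List: `fraction`, `n_shared`, `n_match`, and `discrepancies` (a
#'   data.frame sorted by id).
#' @export
concordance <- function(predicted, reference) {
  shared <- sort(intersect(names(predicted), names(reference)))
  if (!length(shared)) stop("no shared sample ids between the two mappings")
  p <- predicted[shared]; r <- reference[shared]
  match <- p == r
  disc <- data.frame(id = shared[!match], predicted = unname(p[!match]),
                     reference = unname(r[!match]), stringsAsFactors = FALSE)
  disc <- disc[order(disc$id), , drop = FALSE]
  rownames(disc) <- NULL
  list(fraction = mean(match), n_shared = length(shared),
       n_match = sum(match), discrepancies = disc)
}

#' Polyploid inbreeding coefficient
#'
#' F = 1 - H * ploidy / (ploidy - 1), where H is the individual
#' heterozygosity estimated under the correct ploidy. F may be negative
#' (excess heterozygosity) and never exceeds 1.
#'
#' @param hindhe Individual heterozygosity in \[0, 1\].
#' @param ploidy Integer ploidy >= 2.
#' @return Numeric F (vectorised).
#' @export
inbreeding_coefficient <- function(hindhe, ploidy) {
  if (any(ploidy < 2)) stop("ploidy must be >= 2")
  stopifnot(all(hindhe >= 0), all(hindhe <= 1))
  1 - hindhe * ploidy / (ploidy - 1)
}

parse_ploidy <- function(x) {
  # "8x" -> 8, "4X" -> 4, "8-10x"/"?" -> NA
  out <- suppressWarnings(as.integer(sub("[xX]$", "", trimws(x))))
  out
}

#' Read an admixture table
#'
#' TSV with columns `individual_id`, `lineages`, `proportions`,
#' `lineage_ploidies` (the latter three comma-separated within each cell)
#' and `predicted_ploidy`; extra columns are carried through. A packaged
#' example transcribing the validation panel of 16 admixed individuals is at
#' `system.file("extdata", "admixed_panel.tsv", package = "radploidy")`.
#'
#' @param path TSV path.
#' @return A data.frame with list-columns `lineages`, `proportions`,
#'   `lineage_ploidies`.
#' @export
read_admixture_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("individual_id", "lineages", "proportions", "lineage_ploidies",
            "predicted_ploidy")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df$lineages <- strsplit(df$lineages, ",", fixed = TRUE)
  df$proportions <- lapply(strsplit(df$proportions, ",", fixed = TRUE),
                           as.numeric)
  df$lineage_ploidies <- lapply(strsplit(df$lineage_ploidies, ",", fixed = TRUE),
                                as.integer)
  bad <- which(lengths(df$lineages) != lengths(df$proportions) |
                 lengths(df$lineages) != lengths(df$lineage_ploidies))
  if (length(bad)) {
    stop("row(s) with mismatched lineage/proportion/ploidy lengths: ",
         paste(df$individual_id[bad], collapse = ", "))
  }
  df
}

#' Evaluate an admixture table
#'
#' Adds the expected F1 ploidy (mean of the two largest-proportion
#' lineages' ploidies), the weighted-mean expected ploidy, and the
#' neoploidy verdict for each individual.
#'
#' @param df As returned by [read_admixture_table()].
#' @param epsilon Passed to [classify_neoploidy()].
#' @return The table with numeric columns `expected_f1`, `expected_ploidy`
#'   and character `verdict` appended.
#' @export
evaluate_admixture_table <- function(df, epsilon = 0.05) {
  df$expected_f1 <- vapply(seq_len(nrow(df)), function(i) {
    w <- df$proportions[[i]]
    p <- df$lineage_ploidies[[i]]
    top2 <- order(w, decreasing = TRUE)[1:2]
    expected_f1_ploidy(p[top2[1]], p[top2[2]])
  }, numeric(1))
  df$expected_ploidy <- vapply(seq_len(nrow(df)), function(i) {
    expected_admixture_ploidy(df$proportions[[i]], df$lineage_ploidies[[i]])
  }, numeric(1))
  df$verdict <- classify_neoploidy(df$expected_ploidy, df$predicted_ploidy,
                                   epsilon)
  df
}

#' Read a flow-cytometry panel table
#'
#' TSV with columns `sample_id`, `predicted_ploidy` (integer) and
#' `genome_size_pg` (2C value in pg, `NA` where not measured). A packaged
#' panel of 87 individuals (56 with measured 2C values) is at
#' `system.file("extdata", "flow_panel.tsv", package = "radploidy")`.
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_flow_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("sample_id", "predicted_ploidy", "genome_size_pg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df
}
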