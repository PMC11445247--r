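#' Build an allele-fraction profile for one sample
#'
#' Applies a site filter to a site-depth table and collects the retained
#' alternative-allele fractions, the input to ploidy calling.
#'
#' @param sites Site-depth table, e.g. from [read_depths_from_variants()]
#'   or [simulate_sample()].
#' @param filter The [filter_config()] to apply. Filtering is idempotent:
#'   profiling an already-retained table changes nothing.
#' @param sample_id Label carried into reports.
#' @return An object of class `fraction_profile`: `sample_id`, `fractions`
#'   (sorted by genomic order of the retained sites), `n_sites`, `filter`.
#' @export
fraction_profile <- function(sites, filter = filter_config(),
                             sample_id = "sample") {
  fs <- filter_sites(sites, filter)
  kept <- fs$retained
  structure(
    list(sample_id = sample_id,
         fractions = kept$alt_depth / kept$total_depth,
         n_sites = nrow(kept),
         filter = filter),
    class = "fraction_profile"
  )
}

#' Construct a profile directly from fractions
#'
#' Mostly for tests and for transformed re-analysis (e.g. mirroring
#' f -> 1 - f). Fractions must lie inside the filter's window.
#' @param fractions Numeric vector in (0, 1).
#' @inheritParams fraction_profile
#' @export
new_fraction_profile <- function(fractions, sample_id = "sample",
                                 filter = filter_config()) {
  stopifnot(is.numeric(fractions), all(fractions > 0), all(fractions < 1))
  structure(
    list(sample_id = sample_id, fractions = as.numeric(fractions),
         n_sites = length(fractions), filter = filter),
    class = "fraction_profile"
  )
}

#' @export
print.fraction_profile <- function(x, ...) {
  cat("Allele-fraction profile for", x$sample_id, "-", x$n_sites,
      "retained sites\n")
  invisible(x)
}

#' Candidate dosage model for one effective copy number
#'
#' An effective copy number m implies heterozygous-site allele fractions at
#' the dosage fractions k/m, k = 1..m-1. For a diploidized allotetraploid,
#' RAD loci are specific to one of the two subgenomes, so the visible copy
#' number is half the cytotype ploidy: `cytotype_factor = 2` maps m back to
#' the reported ploidy (m = 2 -> "4x"); set it to 1 for true autopolyploids.
#'
#' @param m Effective copy number, integer >= 2.
#' @param cytotype_factor Multiplier from effective copies to reported
#'   cytotype ploidy.
#' @param error_rate Per-read miscall probability used to shrink the
#'   component means towards 0.5: k/m becomes (k/m)(1-e) + (1-k/m)e.
#' @return An object of class `ploidy_model_spec` with `expected_modes`
#'   (the raw k/m set) and `component_means` (error-adjusted).
#' @export
ploidy_model_spec <- function(m, cytotype_factor = 2, error_rate = 0.005) {
  m <- as.integer(m)
  stopifnot(m >= 2L, error_rate >= 0, error_rate < 0.5)
  k <- seq_len(m - 1L)
  modes <- k / m
  structure(
    list(m = m,
         expected_modes = modes,
         component_means = modes * (1 - error_rate) + (1 - modes) * error_rate,
         cytotype_factor = cytotype_factor,
         reported_ploidy = m * cytotype_factor),
    class = "ploidy_model_spec"
  )
}

#' Tuning parameters for ploidy calling
#'
#' @param bandwidth Kernel bandwidth on the fraction axis (default 0.02,
#'   which separates the 1/3 vs 1/4 expected modes, gap 0.083, at typical
#'   read depths).
#' @param n_grid Number of uniform grid points on \[0, 1\].
#' @param min_sites Minimum retained sites for a confident call; below it
#'   the call is still emitted but flagged `low_sites`.
#' @param prominence_frac A density local maximum counts as a mode only if
#'   its prominence exceeds this fraction of the global maximum.
#' @param min_separation Minimum distance between reported modes; lesser
#'   peaks within it are suppressed.
#' @param match_tol Maximum |detected - expected| distance for a mode to
#'   match a dosage fraction.
#' @param error_rate Sequencing error rate used for component means.
#' @param plateau_mass,plateau_interval,dominance_ratio The octoploid
#'   plateau rule: an m = 4 candidate also matches a broad interior mass
#'   pattern when at least `plateau_mass` of the density lies inside
#'   `plateau_interval` and no single dominant mode explains it (a lone mode
#'   at 0.5 whose height exceeds `dominance_ratio` times the density at the
#'   interval shoulders is "dominant", i.e. a tetraploid signature).
#' @param ambiguity_margin Calls are flagged `ambiguous` when the top two
#'   candidates tie on peak matching and their mixture criterion differs by
#'   less than this margin (BIC units).
#' @param em_tol,em_maxit Convergence tolerance and iteration cap for the
#'   mixture-weight EM at fixed concentration.
#' @param kappa_range Search interval for the shared beta concentration.
#' @export
ploidy_control <- function(bandwidth = 0.02, n_grid = 512L, min_sites = 200L,
                           prominence_frac = 0.10, min_separation = 0.08,
                           match_tol = 0.06, error_rate = 0.005,
                           plateau_mass = 0.70, plateau_interval = c(0.3, 0.7),
                           dominance_ratio = 2, ambiguity_margin = 10,
                           em_tol = 1e-6, em_maxit = 500L,
                           kappa_range = c(2, 1e4)) {
  structure(
    list(bandwidth = bandwidth, n_grid = as.integer(n_grid),
         min_sites = as.integer(min_sites),
         prominence_frac = prominence_frac, min_separation = min_separation,
         match_tol = match_tol, error_rate = error_rate,
         plateau_mass = plateau_mass, plateau_interval = plateau_interval,
         dominance_ratio = dominance_ratio,
         ambiguity_margin = ambiguity_margin,
         em_tol = em_tol, em_maxit = as.integer(em_maxit),
         kappa_range = kappa_range),
    class = "ploidy_control"
  )
}

#' Estimate the allele-fraction density
#'
#' Gaussian kernel density of the retained fractions on a uniform grid over
#' \[0, 1\], renormalised so the trapezoid integral is exactly 1.
#'
#' @param profile A [fraction_profile()].
#' @param bandwidth,n_grid See [ploidy_control()].
#' @param min_sites Error below this many sites (callers that tolerate thin
#'   profiles pass `min_sites = 0`).
#' @return Class `fraction_density`: `x` (grid), `y` (density), `bw`, `n`.
#' @export
estimate_density <- function(profile, bandwidth = 0.02, n_grid = 512L,
                             min_sites = 200L) {
  f <- profile$fractions
  if (length(f) < min_sites) {
    stop(structure(
      class = c("radploidy_too_few_sites", "error", "condition"),
      list(message = sprintf(
             "profile '%s' has %d retained sites; %d required",
             profile$sample_id, length(f), min_sites),
           call = sys.call(-1), n_sites = length(f), min_sites = min_sites)
    ))
  }
  d <- stats::density(f, bw = bandwidth, from = 0, to = 1, n = n_grid)
  y <- pmax(d$y, 0)
  area <- trapz(d$x, y)
  structure(list(x = d$x, y = y / area, bw = bandwidth, n = length(f)),
            class = "fraction_density")
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

interval_mass <- function(dens, interval) {
  sel <- dens$x >= interval[1] & dens$x <= interval[2]
  if (sum(sel) < 2L) return(0)
  trapz(dens$x[sel], dens$y[sel])
}

#' Detect density modes by topographic prominence
#'
#' Local maxima of the density curve whose prominence (height above the
#' highest saddle separating them from higher terrain) exceeds
#' `prominence_frac` times the global maximum. Peaks closer than
#' `min_separation` to a more prominent peak are suppressed.
#'
#' @param dens A `fraction_density` from [estimate_density()].
#' @inheritParams ploidy_control
#' @return Sorted numeric vector of mode positions (possibly empty).
#' @export
detect_modes <- function(dens, prominence_frac = 0.10, min_separation = 0.08) {
  y <- dens$y
  x <- dens$x
  n <- length(y)
  if (n < 3L) return(numeric())
  is_max <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(is_max)) return(numeric())

  prom <- vapply(is_max, function(i) {
    h <- y[i]
    # walk left to first strictly higher point (or boundary), track the min
    left_min <- h
    j <- i - 1L
    while (j >= 1L && y[j] <= h) {
      left_min <- min(left_min, y[j]); j <- j - 1L
    }
    right_min <- h
    j <- i + 1L
    while (j <= n && y[j] <= h) {
      right_min <- min(right_min, y[j]); j <- j + 1L
    }
    h - max(left_min, right_min)
  }, numeric(1))

  keep <- prom >= prominence_frac * max(y)
  cand <- is_max[keep]
  cand_prom <- prom[keep]
  if (!length(cand)) return(numeric())

  # enforce minimum separation, most prominent first
  ord <- order(cand_prom, y[cand], decreasing = TRUE)
  chosen <- integer()
  for (i in cand[ord]) {
    if (all(abs(x[i] - x[chosen]) >= min_separation)) chosen <- c(chosen, i)
  }
  sort(x[chosen])
}

# Greedy nearest matching of detected modes to expected dosage fractions.
match_modes <- function(detected, expected, tol) {
  if (!length(detected) || !length(expected)) return(0L)
  d <- abs(outer(detected, expected, "-"))
  n_matched <- 0L
  repeat {
    i <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[i[1], i[2]] > tol) break
    n_matched <- n_matched + 1L
    d[i[1], ] <- Inf
    d[, i[2]] <- Inf
    if (all(!is.finite(d))) break
  }
  n_matched
}

#' Fit a fixed-mean beta mixture to allele fractions
#'
#' Mixture of beta components with means pinned at the error-adjusted dosage
#' fractions of one candidate copy number and one shared concentration
#' parameter. Weights are estimated by EM from a deterministic uniform
#' initialisation; the concentration is profiled out by golden-section
#' search. Free parameters: (K - 1) weights + 1 concentration = K, for K
#' components.
#'
#' @param fractions Numeric vector in (0, 1).
#' @param means Component means (error-adjusted k/m).
#' @param kappa_range,em_tol,em_maxit See [ploidy_control()].
#' @return List: `loglik`, `weights`, `kappa`, `k_params`, `bic`.
#' @export
fit_dosage_mixture <- function(fractions, means, kappa_range = c(2, 1e4),
                               em_tol = 1e-6, em_maxit = 500L) {
  f <- as.numeric(fractions)
  stopifnot(all(f > 0), all(f < 1), length(means) >= 1L)
  K <- length(means)
  n <- length(f)

  em_at_kappa <- function(log_kappa) {
    kappa <- exp(log_kappa)
    logp <- vapply(means, function(mu) {
      stats::dbeta(f, mu * kappa, (1 - mu) * kappa, log = TRUE)
    }, numeric(n))
    if (K == 1L) {
      ll <- sum(logp)
      return(list(loglik = ll, weights = 1))
    }
    w <- rep(1 / K, K)
    ll_old <- -Inf
    for (it in seq_len(em_maxit)) {
      lw <- sweep(logp, 2L, log(w), "+")
      mx <- do.call(pmax, lapply(seq_len(K), function(j) lw[, j]))
      lse <- mx + log(rowSums(exp(lw - mx)))
      ll <- sum(lse)
      resp <- exp(lw - lse)
      w <- colMeans(resp)
      w <- pmax(w, 1e-12); w <- w / sum(w)
      if (is.finite(ll_old) && abs(ll - ll_old) < em_tol * (abs(ll) + 1)) break
      ll_old <- ll
    }
    list(loglik = ll, weights = w)
  }

  opt <- stats::optimize(function(lk) -em_at_kappa(lk)$loglik,
                         interval = log(kappa_range), tol = 1e-3)
  fit <- em_at_kappa(opt$minimum)
  k_params <- K  # (K - 1) free weights + shared concentration
  list(loglik = fit$loglik, weights = fit$weights,
       kappa = exp(opt$minimum), k_params = k_params,
       bic = -2 * fit$loglik + k_params * log(n))
}

#' Score candidate copy numbers against a profile
#'
#' For each candidate m, computes (i) a peak-match score: detected density
#' modes are greedily matched to the expected dosage fractions within
#' `match_tol`, and the score is
#' `n_matched - n_unmatched_expected - n_unmatched_observed`; and (ii) the
#' fixed-mean beta-mixture BIC. The m = 4 candidate additionally matches a
#' broad interior plateau (see [ploidy_control()]), the empirical octoploid
#' signature when individual dosage peaks are not resolved.
#'
#' @param profile A [fraction_profile()].
#' @param candidates List of [ploidy_model_spec()] (or an integer vector of
#'   m values, expanded with defaults).
#' @param control A [ploidy_control()].
#' @return A data.frame: one row per candidate with `m`, `reported_ploidy`,
#'   `n_matched`, `peak_score`, `plateau`, `loglik`, `kappa`, `bic`; the
#'   detected modes are attached as attribute `modes`.
#' @export
score_candidates <- function(profile, candidates = 2:4,
                             control = ploidy_control()) {
  if (!length(candidates)) stop("empty candidate list")
  if (is.numeric(candidates)) {
    candidates <- lapply(candidates, ploidy_model_spec,
                         error_rate = control$error_rate)
  }
  dens <- estimate_density(profile, control$bandwidth, control$n_grid,
                           min_sites = 0L)
  modes <- detect_modes(dens, control$prominence_frac, control$min_separation)

  int_mass <- interval_mass(dens, control$plateau_interval)
  # a lone sharp tetraploid-style peak at 0.5 is not a plateau
  shoulder <- stats::approx(dens$x, dens$y,
                            xout = control$plateau_interval + c(0.05, -0.05))$y
  dominant_single <- length(modes) == 1L &&
    abs(modes - 0.5) <= control$match_tol &&
    max(dens$y) > control$dominance_ratio * max(shoulder)
  plateau_seen <- int_mass >= control$plateau_mass && !dominant_single

  rows <- lapply(candidates, function(spec) {
    n_matched <- match_modes(modes, spec$component_means, control$match_tol)
    peak <- 3L * n_matched - length(spec$component_means) - length(modes)
    plateau <- FALSE
    if (spec$m == 4L && plateau_seen && peak < 2L) {
      peak <- 2L
      plateau <- TRUE
    }
    fit <- fit_dosage_mixture(profile$fractions, spec$component_means,
                              control$kappa_range, control$em_tol,
                              control$em_maxit)
    data.frame(m = spec$m, reported_ploidy = spec$reported_ploidy,
               n_matched = n_matched, peak_score = peak, plateau = plateau,
               loglik = fit$loglik, kappa = fit$kappa, bic = fit$bic)
  })
  out <- do.call(rbind, rows)
  attr(out, "modes") <- modes
  attr(out, "density") <- dens
  out
}

#' Call the ploidy of one sample
#'
#' Selects the candidate copy number with the best peak-match score,
#' breaking ties by the beta-mixture information criterion, and reports the
#' cytotype ploidy `cytotype_factor * m`. Deterministic given the profile
#' and configuration.
#'
#' @inheritParams score_candidates
#' @param cytotype_factor Used when `candidates` is an integer vector.
#' @return Class `ploidy_call`: `sample_id`, `effective_m`,
#'   `reported_ploidy` (e.g. `"4x"`), `detected_modes`, `model_scores`,
#'   `n_sites_used`, `confidence_flag` (`ok`, `low_sites` or `ambiguous`).
#' @export
call_ploidy <- function(profile, candidates = 2:4,
                        control = ploidy_control(), cytotype_factor = 2) {
  if (!length(candidates)) stop("empty candidate list")
  if (is.numeric(candidates)) {
    candidates <- lapply(candidates, ploidy_model_spec,
                         cytotype_factor = cytotype_factor,
                         error_rate = control$error_rate)
  }
  low_sites <- profile$n_sites < control$min_sites
  if (low_sites) {
    warning(sprintf("profile '%s': only %d retained sites (< %d); call is low-confidence",
                    profile$sample_id, profile$n_sites, control$min_sites))
  }
  scores <- score_candidates(profile, candidates, control)
  top <- scores$peak_score == max(scores$peak_score)
  tied <- scores[top, , drop = FALSE]
  tied <- tied[order(tied$bic, tied$m), , drop = FALSE]
  winner <- tied[1, ]
  ambiguous <- nrow(tied) > 1 &&
    (tied$bic[2] - tied$bic[1]) < control$ambiguity_margin
  flag <- if (low_sites) "low_sites" else if (ambiguous) "ambiguous" else "ok"
  structure(
    list(sample_id = profile$sample_id,
         effective_m = winner$m,
         reported_ploidy = paste0(winner$reported_ploidy, "x"),
         detected_modes = attr(scores, "modes"),
         model_scores = scores,
         n_sites_used = profile$n_sites,
         confidence_flag = flag),
    class = "ploidy_call"
  )
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat(sprintf("Sample %s: %s (effective copy number m = %d, %d sites, %s)\n",
              x$sample_id, x$reported_ploidy, x$effective_m, x$n_sites_used,
              x$confidence_flag))
  cat("  detected modes:",
      if (length(x$detected_modes)) paste(round(x$detected_modes, 3), collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Flatten a ploidy call to a one-row report
#'
#' @param call A `ploidy_call`.
#' @return One-row data.frame matching the TSV report schema.
#' @export
as_report_row <- function(call) {
  sc <- call$model_scores
  data.frame(
    sample_id = call$sample_id,
    n_sites = call$n_sites_used,
    detected_modes = paste(round(call$detected_modes, 4), collapse = ";"),
    effective_m = call$effective_m,
    reported_ploidy = call$reported_ploidy,
    peak_scores = paste(sprintf("m%d=%d", sc$m, sc$peak_score), collapse = ";"),
    bic = paste(sprintf("m%d=%.2f", sc$m, sc$bic), collapse = ";"),
    confidence_flag = call$confidence_flag,
    stringsAsFactors = FALSE
  )
}
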