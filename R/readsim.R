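#' Depth laws for the read-depth simulator
#'
#' @param min,max Bounds of the discrete uniform depth law (inclusive).
#' @return A depth-law object consumed by [sim_config()].
#' @export
depth_uniform <- function(min = 25L, max = 60L) {
  min <- as.integer(min); max <- as.integer(max)
  stopifnot(min >= 1L, min <= max)
  structure(list(kind = "uniform", min = min, max = max), class = "depth_law")
}

#' @param mean,dispersion Negative-binomial mean and size (dispersion)
#'   parameters; depths of 0 are redrawn as 1. The default mean of 30 is a
#'   typical per-sample RAD-seq coverage.
#' @rdname depth_uniform
#' @export
depth_nbinom <- function(mean = 30, dispersion = 5) {
  stopifnot(mean > 0, dispersion > 0)
  structure(list(kind = "nbinom", mean = mean, dispersion = dispersion),
            class = "depth_law")
}

draw_depth <- function(law) {
  switch(law$kind,
    uniform = law$min + sample.int(law$max - law$min + 1L, 1L) - 1L,
    nbinom = max(1L, stats::rnbinom(1L, size = law$dispersion, mu = law$mean)),
    stop("unknown depth law")
  )
}

#' Simulator configuration
#'
#' Generative parameters for synthetic per-site allelic depths with a known
#' effective copy number m. At each heterozygous site an allele dosage d is
#' drawn from `dosage_weights` over 1..m-1, a depth D from `depth_law`, and
#' the alternative-read count from Binomial(D, p) with
#' p = (d/m)(1 - e) + (1 - d/m) e for miscall rate e.
#'
#' @param m True effective copy number (>= 2).
#' @param n_sites Number of heterozygous sites to emit (pre-filter).
#' @param depth_law [depth_uniform()] or [depth_nbinom()]; the default
#'   uniform 25--60 keeps depths inside the standard filter window.
#' @param error_rate Per-read miscall probability towards the other allele.
#' @param dosage_weights Probability vector over dosages 1..m-1 (default
#'   uniform).
#' @param hom_fraction Fraction of homozygous-alternative contaminant sites
#'   (dosage m).
#' @param seed Integer seed. Per-site random substreams are derived from it
#'   by site index, so enlarging `n_sites` extends the site list without
#'   reshuffling earlier sites.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(m, n_sites = 3000L, depth_law = depth_uniform(25, 60),
                       error_rate = 0.005, dosage_weights = NULL,
                       hom_fraction = 0, seed = 1L) {
  m <- as.integer(m)
  if (m < 2L) stop("effective copy number m must be >= 2")
  if (is.null(dosage_weights)) dosage_weights <- rep(1 / (m - 1L), m - 1L)
  if (length(dosage_weights) != m - 1L || any(dosage_weights < 0) ||
      abs(sum(dosage_weights) - 1) > 1e-8) {
    stop("`dosage_weights` must be a probability vector over dosages 1..m-1")
  }
  stopifnot(error_rate >= 0, error_rate < 0.5,
            hom_fraction >= 0, hom_fraction < 1,
            inherits(depth_law, "depth_law"))
  structure(
    list(m = m, n_sites = as.integer(n_sites), depth_law = depth_law,
         error_rate = error_rate, dosage_weights = dosage_weights,
         hom_fraction = hom_fraction, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Deterministic per-site substream seed; all arithmetic stays below 2^53 so
# doubles are exact, and the result fits a 32-bit seed.
site_seed <- function(seed, i) {
  as.integer(((as.double(seed) %% 2147483647) * 69069 + i * 1013904223) %%
               2147483647)
}

#' Simulate per-site allelic depths for one sample
#'
#' Emits sites pre-filter; pass the result through [fraction_profile()] to
#' apply the standard coverage filters. Identical configuration (including
#' seed) produces identical output.
#'
#' @param config A [sim_config()].
#' @return A site-depth table with extra columns `dosage` (true allele
#'   dosage; `m` marks a homozygous contaminant site) and `p_alt` (the
#'   error-adjusted binomial success probability), and attribute `config`.
#' @export
simulate_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_sites
  m <- config$m
  e <- config$error_rate
  dosage <- integer(n); depth <- integer(n); alt <- integer(n)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  for (i in seq_len(n)) {
    set.seed(site_seed(config$seed, i))
    is_hom <- stats::runif(1L) < config$hom_fraction
    dosage[i] <- if (is_hom) m else
      sample.int(m - 1L, 1L, prob = config$dosage_weights)
    depth[i] <- draw_depth(config$depth_law)
    p <- (dosage[i] / m) * (1 - e) + (1 - dosage[i] / m) * e
    alt[i] <- stats::rbinom(1L, depth[i], p)
  }
  sites <- site_depths("sim", seq_len(n), ref_depth = depth - alt,
                       alt_depth = alt)
  sites$dosage <- dosage
  sites$p_alt <- (dosage / m) * (1 - e) + (1 - dosage / m) * e
  attr(sites, "config") <- config
  sites
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate an admixed sample
#'
#' Each site is drawn from one of several parent generative laws, chosen
#' with the given mixing proportions -- a crude stand-in for an individual
#' whose loci descend from lineages of different copy number, used to probe
#' caller behaviour at contact zones.
#'
#' @param parent_configs List of two or more [sim_config()] objects; the
#'   first parent's `n_sites` and `seed` govern the output unless
#'   overridden.
#' @param mixing Proportions over parents, summing to 1.
#' @param n_sites,seed Optional overrides.
#' @return As [simulate_sample()], with an extra `parent` column.
#' @export
simulate_admixed_sample <- function(parent_configs, mixing,
                                    n_sites = NULL, seed = NULL) {
  if (length(parent_configs) < 2L) stop("need at least two parent configs")
  stopifnot(all(vapply(parent_configs, inherits, TRUE, "sim_config")))
  if (length(mixing) != length(parent_configs)) {
    stop("`mixing` must have one proportion per parent")
  }
  if (any(mixing < 0) || abs(sum(mixing) - 1) > 1e-8) {
    stop("`mixing` proportions must be non-negative and sum to 1")
  }
  n <- if (is.null(n_sites)) parent_configs[[1]]$n_sites else as.integer(n_sites)
  seed <- if (is.null(seed)) parent_configs[[1]]$seed else as.integer(seed)

  parent <- integer(n); dosage <- integer(n)
  depth <- integer(n); alt <- integer(n); p_alt <- numeric(n)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  for (i in seq_len(n)) {
    set.seed(site_seed(seed, i))
    parent[i] <- sample.int(length(mixing), 1L, prob = mixing)
    cfg <- parent_configs[[parent[i]]]
    m <- cfg$m; e <- cfg$error_rate
    is_hom <- stats::runif(1L) < cfg$hom_fraction
    dosage[i] <- if (is_hom) m else
      sample.int(m - 1L, 1L, prob = cfg$dosage_weights)
    depth[i] <- draw_depth(cfg$depth_law)
    p_alt[i] <- (dosage[i] / m) * (1 - e) + (1 - dosage[i] / m) * e
    alt[i] <- stats::rbinom(1L, depth[i], p_alt[i])
  }
  sites <- site_depths("sim", seq_len(n), ref_depth = depth - alt,
                       alt_depth = alt)
  sites$dosage <- dosage
  sites$p_alt <- p_alt
  sites$parent <- parent
  attr(sites, "mixing") <- mixing
  sites
}

#' Export simulated sites as a minimal single-sample VCF
#'
#' Writes a VCFv4.2 file with GT/AD/DP FORMAT fields (genotype left
#' unknown), so simulated depths can round-trip through
#' [read_depths_from_variants()]. Every site becomes a biallelic A>C SNP on
#' one synthetic contig.
#'
#' @param sites Site-depth table from [simulate_sample()].
#' @param path Output file.
#' @param sample_id Sample column name.
#' @param contig Contig name used in the header and records.
#' @return `path`, invisibly.
#' @export
write_sim_vcf <- function(sites, path, sample_id = "SIM", contig = "sim") {
  n <- nrow(sites)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=radploidy_simulate",
    sprintf("##contig=<ID=%s,length=%d>", contig, max(sites$pos) + 1L),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  body <- paste(contig, sites$pos, ".", "A", "C", ".", "PASS", ".",
                "GT:AD:DP",
                sprintf("./.:%d,%d:%d", sites$ref_depth, sites$alt_depth,
                        sites$ref_depth + sites$alt_depth),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
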