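#' Extract filtered allelic depths from a coordinate-sorted alignment
#'
#' Walks the pileup of a coordinate-sorted, indexed BAM file and emits one
#' row per biallelic site that survives the coverage filters. At each
#' position the most frequent non-reference base is treated as the
#' alternative allele; positions where a third allele exceeds 10% of the
#' column depth are discarded as likely collapsed paralogs. Reads below the
#' mapping-quality floor (and bases below the base-quality floor) never
#' enter the pileup, so the depths reflect uniquely mapped reads only.
#'
#' The file is assumed to contain a single sample (the usual case for
#' demultiplexed RAD-seq libraries).
#'
#' @param alignment_path Path to a coordinate-sorted BAM file with an index
#'   (`.bai`) alongside.
#' @param reference_path Path to the reference FASTA the reads were aligned
#'   to; a `.fai` index is created if absent.
#' @param filter A [filter_config()]; also supplies `min_mapq`/`min_baseq`.
#' @param exclude_contigs Character vector of contig names to skip (e.g.
#'   organellar sequences, which violate the nuclear dosage model).
#' @param max_pileup_depth Cap on pileup depth per position; must exceed
#'   `filter$max_total` to leave the over-coverage rejection observable.
#' @return A retained site-depth table (`contig`, `pos`, `ref_depth`,
#'   `alt_depth`, `total_depth`, `fraction`) with an attribute `counts`
#'   tallying rejection reasons.
#' @seealso [read_depths_from_variants()] for the VCF route.
#' @export
read_depths_from_alignment <- function(alignment_path, reference_path,
                                       filter = filter_config(),
                                       exclude_contigs = character(),
                                       max_pileup_depth = 10000L) {
  if (!file.exists(alignment_path)) {
    stop("alignment file not found: ", alignment_path)
  }
  idx <- paste0(alignment_path, ".bai")
  idx2 <- sub("\\.bam$", ".bai", alignment_path)
  if (!file.exists(idx) && !file.exists(idx2)) {
    stop("missing BAM index for ", alignment_path,
         " (expected ", idx, "); index the file first")
  }
  if (!file.exists(reference_path)) {
    stop("reference FASTA not found: ", reference_path)
  }

  ref <- Biostrings::readDNAStringSet(reference_path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  hdr <- Rsamtools::scanBamHeader(alignment_path)[[1]]$targets
  unknown <- setdiff(names(hdr), names(ref))
  if (length(unknown)) {
    stop("alignment contig(s) absent from reference: ",
         paste(unknown, collapse = ", "))
  }

  pp <- Rsamtools::PileupParam(
    max_depth = as.integer(max_pileup_depth),
    min_base_quality = filter$min_baseq,
    min_mapq = filter$min_mapq,
    min_nucleotide_depth = 1L,
    distinguish_strands = FALSE,
    distinguish_nucleotides = TRUE,
    include_deletions = FALSE,
    include_insertions = FALSE
  )
  sbp <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE, isDuplicate = FALSE
    ),
    mapqFilter = filter$min_mapq
  )
  pu <- Rsamtools::pileup(alignment_path, scanBamParam = sbp, pileupParam = pp)
  pu$seqnames <- as.character(pu$seqnames)
  pu <- pu[!(pu$seqnames %in% exclude_contigs) &
             pu$nucleotide %in% c("A", "C", "G", "T"), , drop = FALSE]
  if (nrow(pu) == 0L) {
    out <- site_depths(character(), integer(), integer(), integer())
    out$fraction <- numeric()
    return(out)
  }

  # wide per-position base counts
  key <- paste(pu$seqnames, pu$pos, sep = "\r")
  counts <- matrix(0L, nrow = length(unique(key)), ncol = 4L,
                   dimnames = list(unique(key), c("A", "C", "G", "T")))
  counts[cbind(match(key, rownames(counts)), match(pu$nucleotide, colnames(counts)))] <-
    pu$count
  parts <- strsplit(rownames(counts), "\r", fixed = TRUE)
  contig <- vapply(parts, `[`, "", 1L)
  pos <- as.integer(vapply(parts, `[`, "", 2L))

  ref_base <- mapply(function(ctg, p) {
    as.character(Biostrings::subseq(ref[[ctg]], p, p))
  }, contig, pos, USE.NAMES = FALSE)

  ref_idx <- match(ref_base, colnames(counts))
  keep <- !is.na(ref_idx)
  counts <- counts[keep, , drop = FALSE]
  contig <- contig[keep]; pos <- pos[keep]; ref_idx <- ref_idx[keep]

  n <- nrow(counts)
  ref_depth <- counts[cbind(seq_len(n), ref_idx)]
  nonref <- counts
  nonref[cbind(seq_len(n), ref_idx)] <- -1L  # exclude ref column from max
  alt_idx <- max.col(nonref, ties.method = "first")
  alt_depth <- counts[cbind(seq_len(n), alt_idx)]
  col_depth <- rowSums(counts)
  third <- col_depth - ref_depth - alt_depth

  variant <- alt_depth > 0L
  clean <- third <= 0.10 * col_depth
  sel <- variant & clean
  sites <- site_depths(contig[sel], pos[sel], ref_depth[sel], alt_depth[sel])
  sites <- sites[order(sites$contig, sites$pos), , drop = FALSE]

  fs <- filter_sites(sites, filter)
  out <- fs$retained
  out$fraction <- out$alt_depth / out$total_depth
  rownames(out) <- NULL
  attr(out, "counts") <- fs$counts
  attr(out, "n_nonvariant") <- sum(!variant)
  attr(out, "n_multiallelic") <- sum(variant & !clean)
  out
}

#' Extract filtered allelic depths from a VCF with AD fields
#'
#' Reads per-sample allelic depths (the `AD` FORMAT field) from a VCF and
#' applies the same filtering contract as the alignment route. Only
#' biallelic SNP records are used; multiallelic records and indels are
#' skipped and counted.
#'
#' @param vcf_path Path to a VCF (optionally gzipped) with per-sample AD.
#' @param sample_id Sample to extract; defaults to the only sample if the
#'   file has exactly one.
#' @param filter A [filter_config()].
#' @return As [read_depths_from_alignment()]; attributes report the numbers
#'   of skipped multiallelic/indel records and missing genotypes.
#' @export
read_depths_from_variants <- function(vcf_path, sample_id = NULL,
                                      filter = filter_config()) {
  if (!file.exists(vcf_path)) stop("variant file not found: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fmt <- vcf@gt[, "FORMAT"]
  if (nrow(vcf@gt) == 0L || !any(grepl("(^|:)AD(:|$)", fmt))) {
    stop("no per-sample allelic depth (AD) field in ", vcf_path)
  }
  samples <- colnames(vcf@gt)[-1]
  if (is.null(sample_id)) {
    if (length(samples) != 1L) {
      stop("`sample_id` required; available samples: ",
           paste(samples, collapse = ", "))
    }
    sample_id <- samples
  }
  if (!sample_id %in% samples) {
    stop("unknown sample '", sample_id, "'; available samples: ",
         paste(samples, collapse = ", "))
  }

  fix <- vcf@fix
  is_snp <- fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0L) {
    message("skipped ", n_skipped, " multiallelic/indel record(s)")
  }

  ad <- vcfR::extract.gt(vcf, element = "AD")[, sample_id]
  ad <- ad[is_snp]
  contig <- fix[is_snp, "CHROM"]
  pos <- as.integer(fix[is_snp, "POS"])

  ok <- !is.na(ad) & grepl("^[0-9]+,[0-9]+$", ad)
  n_missing <- sum(!ok)
  parts <- strsplit(ad[ok], ",", fixed = TRUE)
  ref_depth <- as.integer(vapply(parts, `[`, "", 1L))
  alt_depth <- as.integer(vapply(parts, `[`, "", 2L))

  sites <- site_depths(contig[ok], pos[ok], ref_depth, alt_depth)
  fs <- filter_sites(sites, filter)
  out <- fs$retained
  out$fraction <- out$alt_depth / out$total_depth
  rownames(out) <- NULL
  attr(out, "counts") <- fs$counts
  attr(out, "n_multiallelic") <- n_skipped
  attr(out, "n_missing") <- n_missing
  attr(out, "sample_id") <- sample_id
  out
}

#' Write a retained-site table as TSV
#'
#' @param sites Site-depth table (with or without a `fraction` column).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  if (is.null(sites$fraction)) {
    sites$fraction <- sites$alt_depth / sites$total_depth
  }
  utils::write.table(
    sites[, c("contig", "pos", "ref_depth", "alt_depth", "fraction")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a site table written by [write_sites_tsv()] or the simulator
#'
#' @param path TSV with columns `contig`, `pos`, `ref_depth`, `alt_depth`.
#' @return A site-depth table.
#' @export
read_sites_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  site_depths(df$contig, df$pos, df$ref_depth, df$alt_depth)
}
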