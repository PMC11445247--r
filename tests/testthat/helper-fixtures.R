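# Synthetic alignment/variant fixtures built at test time.
#
# Reads are 1 bp perfect matches (CIGAR 1M), which makes the brute-force
# pileup oracle a straight tabulation of the read table while still
# exercising the full BAM -> pileup -> filter path.

write_fixture_fasta <- function(dir, contig = "chr_syn", len = 5000L,
                                seed = 42L) {
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
  fa <- file.path(dir, "ref.fa")
  ss <- Biostrings::DNAStringSet(seq)
  names(ss) <- contig
  Biostrings::writeXStringSet(ss, fa)
  Rsamtools::indexFa(fa)
  list(path = fa, seq = seq, contig = contig, len = len)
}

other_base <- function(b) {
  setdiff(c("A", "C", "G", "T"), b)[1]
}

# One row per read: pos, base, mapq
make_read_table <- function(ref, n_sites = 60L, seed = 43L,
                            with_lowq = TRUE) {
  set.seed(seed)
  pos <- sort(sample(seq(10L, ref$len - 10L), n_sites))
  rows <- lapply(pos, function(p) {
    rb <- substr(ref$seq, p, p)
    ab <- other_base(rb)
    # depths chosen to hit every filter branch: below/above window, low alt,
    # low ref, and clean heterozygous sites
    ref_n <- sample(c(0:15, 10:60, 90:120), 1L)
    alt_n <- sample(c(0:9, 10:60, 90:120), 1L)
    out <- data.frame(
      pos = p,
      base = c(rep(rb, ref_n), rep(ab, alt_n)),
      mapq = 60L,
      stringsAsFactors = FALSE
    )
    if (with_lowq && stats::runif(1) < 0.3) {
      out <- rbind(out, data.frame(pos = p, base = ab, mapq = 5L))
    }
    out
  })
  do.call(rbind, rows)
}

write_fixture_sam <- function(dir, ref, reads, name = "reads") {
  sam <- file.path(dir, paste0(name, ".sam"))
  reads <- reads[order(reads$pos), , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", ref$contig, ref$len))
  body <- sprintf("r%06d\t0\t%s\t%d\t%d\t1M\t*\t0\t0\t%s\tI",
                  seq_len(nrow(reads)), ref$contig, reads$pos, reads$mapq,
                  reads$base)
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, name), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

# Brute-force pileup: tabulate reads above the MAPQ floor, pick the top
# non-reference base; site emitted whenever any alternative read exists.
oracle_pileup <- function(ref, reads, min_mapq = 20L) {
  reads <- reads[reads$mapq >= min_mapq, , drop = FALSE]
  out <- lapply(sort(unique(reads$pos)), function(p) {
    rb <- substr(ref$seq, p, p)
    tab <- table(factor(reads$base[reads$pos == p],
                        levels = c("A", "C", "G", "T")))
    ref_n <- as.integer(tab[rb])
    tab[rb] <- -1L
    alt_b <- names(tab)[which.max(tab)]
    alt_n <- as.integer(max(tab))
    data.frame(pos = p, ref_base = rb, alt_base = alt_b,
               ref_depth = ref_n, alt_depth = alt_n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

write_fixture_vcf <- function(dir, ref, pileup, name = "calls",
                              sample_id = "S1") {
  vcf <- file.path(dir, paste0(name, ".vcf"))
  pu <- pileup[pileup$alt_depth > 0L, , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", ref$contig, ref$len),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  body <- paste(ref$contig, pu$pos, ".", pu$ref_base, pu$alt_base, ".",
                "PASS", ".", "GT:AD",
                sprintf("./.:%d,%d", pu$ref_depth, pu$alt_depth),
                sep = "\t")
  writeLines(c(header, body), vcf)
  vcf
}

# Full fixture: FASTA + sorted/indexed BAM + oracle pileup + derived VCF.
make_alignment_fixture <- function(seed = 42L, n_sites = 60L,
                                   with_lowq = TRUE) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  ref <- write_fixture_fasta(dir, seed = seed)
  reads <- make_read_table(ref, n_sites = n_sites, seed = seed + 1L,
                           with_lowq = with_lowq)
  bam <- write_fixture_sam(dir, ref, reads)
  pu <- oracle_pileup(ref, reads, min_mapq = 20L)
  vcf <- write_fixture_vcf(dir, ref, pu)
  list(dir = dir, ref = ref, reads = reads, bam = bam, vcf = vcf,
       pileup = pu)
}

# Random site tables for filter property tests.
random_sites <- function(n, seed) {
  set.seed(seed)
  site_depths("c", seq_len(n),
              ref_depth = sample(0:250, n, replace = TRUE),
              alt_depth = sample(0:250, n, replace = TRUE))
}

extdata <- function(name) {
  system.file("extdata", name, package = "radploidy", mustWork = TRUE)
}
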