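test_that("alignment and variant routes agree with the brute-force pileup oracle", {
  fx <- make_alignment_fixture(seed = 42L, n_sites = 80L)
  f <- filter_config()

  oracle <- fx$pileup
  oracle_sites <- site_depths(fx$ref$contig, oracle$pos,
                              oracle$ref_depth, oracle$alt_depth)
  expected <- filter_sites(oracle_sites, f)$retained

  from_bam <- read_depths_from_alignment(fx$bam, fx$ref$path, f)
  from_vcf <- read_depths_from_variants(fx$vcf, "S1", f)

  cols <- c("contig", "pos", "ref_depth", "alt_depth", "total_depth")
  norm <- function(df) {
    df <- df[order(df$pos), cols]
    rownames(df) <- NULL
    df
  }
  expect_gt(nrow(expected), 5)
  expect_equal(norm(from_bam), norm(expected))
  expect_equal(norm(from_vcf), norm(expected))
})

test_that("reads below the mapping-quality floor never reach the depths", {
  fx <- make_alignment_fixture(seed = 77L, n_sites = 40L, with_lowq = TRUE)
  expect_true(any(fx$reads$mapq < 20L))  # fixture actually has low-MAPQ reads
  lenient <- oracle_pileup(fx$ref, fx$reads, min_mapq = 0L)
  strict <- oracle_pileup(fx$ref, fx$reads, min_mapq = 20L)
  expect_gt(sum(lenient$alt_depth), sum(strict$alt_depth))

  f <- filter_config()
  from_bam <- read_depths_from_alignment(fx$bam, fx$ref$path, f)
  expected <- filter_sites(
    site_depths(fx$ref$contig, strict$pos, strict$ref_depth,
                strict$alt_depth), f)$retained
  expect_equal(from_bam$alt_depth[order(from_bam$pos)],
               expected$alt_depth[order(expected$pos)])
})

test_that("sites with a substantial third allele are discarded", {
  dir <- withr::local_tempdir()
  ref <- write_fixture_fasta(dir, len = 200L, seed = 9L)
  p1 <- 50L; p2 <- 100L
  rb1 <- substr(ref$seq, p1, p1); ab1 <- other_base(rb1)
  third1 <- setdiff(c("A", "C", "G", "T"), c(rb1, ab1))[1]
  rb2 <- substr(ref$seq, p2, p2); ab2 <- other_base(rb2)
  third2 <- setdiff(c("A", "C", "G", "T"), c(rb2, ab2))[1]
  reads <- rbind(
    # p1: third allele at 6/46 = 13% of the column -> paralog-like, dropped
    data.frame(pos = p1, base = c(rep(rb1, 20), rep(ab1, 20), rep(third1, 6)),
               mapq = 60L),
    # p2: third allele at 2/52 = 3.8% -> kept, alt is the top non-ref base
    data.frame(pos = p2, base = c(rep(rb2, 25), rep(ab2, 25), rep(third2, 2)),
               mapq = 60L)
  )
  bam <- write_fixture_sam(dir, ref, reads)
  got <- read_depths_from_alignment(bam, ref$path, filter_config())
  expect_equal(got$pos, p2)
  expect_equal(got$ref_depth, 25L)
  expect_equal(got$alt_depth, 25L)
})

test_that("organellar contigs can be excluded by name", {
  fx <- make_alignment_fixture(seed = 5L, n_sites = 30L)
  none <- read_depths_from_alignment(fx$bam, fx$ref$path, filter_config(),
                                     exclude_contigs = fx$ref$contig)
  expect_equal(nrow(none), 0L)
})

test_that("missing index and contig mismatches raise explicit errors", {
  fx <- make_alignment_fixture(seed = 11L, n_sites = 10L)
  unindexed <- file.path(fx$dir, "copy.bam")
  file.copy(fx$bam, unindexed)
  expect_error(read_depths_from_alignment(unindexed, fx$ref$path), "index")

  other <- withr::local_tempdir()
  alt_ref <- write_fixture_fasta(other, contig = "other_contig", len = 300L)
  expect_error(read_depths_from_alignment(fx$bam, alt_ref$path, filter_config()),
               "chr_syn")
})

test_that("VCF route validates AD presence and sample names", {
  fx <- make_alignment_fixture(seed = 13L, n_sites = 10L)
  expect_error(read_depths_from_variants(fx$vcf, "nobody"), "S1")

  no_ad <- file.path(fx$dir, "no_ad.vcf")
  lines <- readLines(fx$vcf)
  lines <- sub("GT:AD", "GT", lines)
  lines <- sub(":(\\d+,\\d+)$", "", lines)
  writeLines(lines[!grepl("^##FORMAT=<ID=AD", lines)], no_ad)
  expect_error(read_depths_from_variants(no_ad, "S1"), "AD")
})

test_that("multiallelic and indel records are skipped with a count", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "mix.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=c1,length=1000>",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    "c1\t10\t.\tA\tC\t.\tPASS\t.\tAD\t25,25",
    "c1\t20\t.\tA\tC,G\t.\tPASS\t.\tAD\t20,20,5",   # multiallelic
    "c1\t30\t.\tAT\tA\t.\tPASS\t.\tAD\t30,30",      # indel
    "c1\t40\t.\tG\tT\t.\tPASS\t.\tAD\t12,8"
  ), vcf)
  expect_message(got <- read_depths_from_variants(vcf, "S1"), "skipped 2")
  expect_equal(got$pos, c(10L, 40L))
  expect_equal(attr(got, "n_multiallelic"), 2L)
})

test_that("site tables round-trip through TSV export", {
  sites <- random_sites(50, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sites_tsv(sites, path)
  back <- read_sites_tsv(path)
  expect_equal(back[c("contig", "pos", "ref_depth", "alt_depth")],
               sites[c("contig", "pos", "ref_depth", "alt_depth")])
})
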