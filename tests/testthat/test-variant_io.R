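make_vcf <- function(path, records, samples = character()) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", if (length(samples)) "FORMAT", samples),
                 collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

test_that("region filtering keeps exactly the overlapping records", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  make_vcf(tmp, c(
    "chr1\t150\t.\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "chr1\t999\t.\tC\tT\t.\tPASS\t.\tGT\t1/1",
    "chr2\t150\t.\tG\tA\t.\tPASS\t.\tGT\t0/0",
    # REF span overlaps the region even though POS is upstream of it
    "chr1\t98\t.\tAAAAA\tA\t.\tPASS\t.\tGT\t0/1"),
    samples = "S1")
  regions <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  gm <- read_panel_vcf(tmp, regions)
  expect_setequal(gm$variants$pos, c(150L, 98L))
  expect_equal(gm$accessions, "S1")
  # brute-force overlap oracle on random small VCFs
  set.seed(5)
  for (rep in 1:5) {
    pos <- sample(1:300, 12)
    reflen <- sample(1:4, 12, replace = TRUE)
    recs <- sprintf("chrR\t%d\t.\t%s\tG\t.\tPASS\t.", pos,
                    vapply(reflen, function(k)
                      paste(rep("A", k), collapse = ""), character(1)))
    recs <- recs[!duplicated(pos)]
    p2 <- pos[!duplicated(pos)]
    l2 <- reflen[!duplicated(pos)]
    tmp2 <- withr::local_tempfile(fileext = ".vcf")
    make_vcf(tmp2, recs)
    reg <- data.frame(chrom = "chrR", start = 120L, end = 180L)
    got <- suppressWarnings(read_panel_vcf(tmp2, reg))
    brute <- p2[p2 <= 180L & (p2 + l2 - 1L) >= 120L]
    expect_setequal(got$variants$pos, brute)
  }
})

test_that("sites-only VCFs give a zero-accession matrix with a warning", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  make_vcf(tmp, sprintf("chr1\t%d\t.\tA\tC\t.\tPASS\t.", 101:105))
  expect_warning(gm <- read_panel_vcf(tmp, data.frame(chrom = "chr1",
                                                      start = 1L,
                                                      end = 1000L)),
                 "sites-only")
  expect_equal(nrow(gm$variants), 5L)
  expect_length(gm$accessions, 0L)
})

test_that("multiallelic splitting maps genotypes per split allele", {
  parts <- split_multiallelic("chr1", 100L, "A", "G,T",
                              gt = c("0/0", "0/1", "1/1", "1/2", "2/2",
                                     "./.", "0/."))
  expect_length(parts, 2L)
  expect_equal(parts[[1]]$variant$alt, "G")
  expect_equal(parts[[2]]$variant$alt, "T")
  expect_equal(parts[[1]]$calls,
               c("hom_ref", "het", "hom_alt", "het", "hom_ref", "missing",
                 "missing"))
  expect_equal(parts[[2]]$calls,
               c("hom_ref", "hom_ref", "hom_ref", "het", "hom_alt",
                 "missing", "missing"))
  # dosage conservation: non-ref allele count is preserved across splits
  gts <- c("0/0", "0/1", "1/1", "1/2", "2/2", "0/2")
  orig_dosage <- vapply(gts, function(g)
    sum(as.integer(strsplit(g, "/")[[1]]) > 0), integer(1))
  split_dosage <- Reduce(`+`, lapply(parts_all <- split_multiallelic(
    "chr1", 100L, "A", "G,T", gts), function(p)
      c(hom_ref = 0L, het = 1L, hom_alt = 2L)[p$calls]))
  expect_equal(unname(split_dosage), unname(orig_dosage))
  # biallelic input passes through unchanged (idempotence)
  bi <- split_multiallelic("chr1", 5L, "C", "T", c("0/1", "1|1"))
  expect_length(bi, 1L)
  expect_equal(bi[[1]]$calls, c("het", "hom_alt"))
  # phased and unphased genotypes are equivalent
  expect_equal(split_multiallelic("chr1", 5L, "C", "T", "0|1")[[1]]$calls,
               split_multiallelic("chr1", 5L, "C", "T", "0/1")[[1]]$calls)
  expect_error(split_multiallelic("chr1", 5L, "C", "T", "0/2"),
               "exceeds")
})

test_that("normalization trims, left-aligns and is idempotent", {
  genome <- c(chr1 = "GGCCAAAAACAGTTTT")
  #            123456789012345
  v <- normalize_variant(variant("chr1", 10, "CAG", "CTG"), genome)
  expect_equal(v$pos, 11L)
  expect_equal(v$ref, "A")
  expect_equal(v$alt, "T")
  # 1-base deletion inside the A-run: leftmost representation
  vdel <- normalize_variant(variant("chr1", 8, "AA", "A"), genome)
  # oracle: enumerate all equivalent placements, take the minimum position
  seqs <- genome[["chr1"]]
  apply_del <- function(pos) paste0(substr(seqs, 1, pos),
                                    substr(seqs, pos + 2, nchar(seqs)))
  target <- apply_del(8)
  equivalents <- Filter(function(p) apply_del(p) == target, 1:12)
  expect_equal(vdel$pos, min(equivalents))
  expect_equal(nchar(vdel$ref) - nchar(vdel$alt), 1L)
  # idempotence and sequence preservation
  expect_equal(normalize_variant(vdel, genome), vdel)
  apply_var <- function(v) paste0(substr(seqs, 1, v$pos - 1), v$alt,
                                  substr(seqs, v$pos + nchar(v$ref),
                                         nchar(seqs)))
  expect_equal(apply_var(vdel), target)
  # canonical SNP unchanged
  vsnp <- variant("chr1", 3, "C", "T")
  expect_equal(normalize_variant(vsnp, genome), vsnp)
  expect_error(normalize_variant(variant("chr1", 3, "A", "T"), genome),
               "REF mismatch")
})

test_that("normalization preserves the mutated sequence on random indels", {
  set.seed(17)
  seqs <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE,
                       prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
  genome <- c(chr1 = seqs)
  apply_var <- function(v) paste0(substr(seqs, 1, v$pos - 1), v$alt,
                                  substr(seqs, v$pos + nchar(v$ref),
                                         nchar(seqs)))
  for (rep in 1:200) {
    p <- sample(20:380, 1)
    if (runif(1) < 0.5) {
      w <- sample(1:5, 1)
      raw <- variant("chr1", p, substr(seqs, p, p + w),
                     substr(seqs, p, p))
    } else {
      ins <- paste(sample(c("A", "T"), sample(1:4, 1), replace = TRUE),
                   collapse = "")
      raw <- variant("chr1", p, substr(seqs, p, p),
                     paste0(substr(seqs, p, p), ins))
    }
    norm <- normalize_variant(raw, genome)
    expect_identical(apply_var(norm), apply_var(raw))
    expect_identical(normalize_variant(norm, genome), norm)
    expect_lte(norm$pos, raw$pos)
  }
})

test_that("panel merging unions accessions and reconciles discordance", {
  va <- rbind(variant("chr1", 10, "A", "G"), variant("chr1", 20, "C", "T"))
  vb <- rbind(variant("chr1", 10, "A", "G"), variant("chr1", 30, "G", "A"))
  a <- genotype_matrix(matrix(c("hom_alt", "het",
                                "hom_ref", "hom_ref"), nrow = 2,
                              dimnames = list(NULL, c("S1", "S2"))), va)
  b <- genotype_matrix(matrix(c("hom_ref", "hom_alt",
                                "het", "missing"), nrow = 2,
                              dimnames = list(NULL, c("S2", "S3"))), vb)
  m <- merge_panels(a, b)
  expect_setequal(m$accessions, c("S1", "S2", "S3"))
  expect_equal(nrow(m$variants), 3L)
  conflicts <- attr(m, "conflicts")
  # S2 at chr1:10 is hom_ref in a but hom_ref in b? b says hom_ref -> no;
  # a says hom_ref (col S2 row 1), b says hom_ref: concordant. The het/hom
  # mismatch is S2 at chr1:20? absent from b -> fill, no conflict.
  expect_equal(nrow(conflicts), 0L)
  # absent cells default to missing, not hom_ref
  expect_equal(unname(m$calls["chr1:30:G:A", "S1"]), "missing")
  # planted discordance
  b2 <- genotype_matrix(matrix(c("hom_alt", "hom_alt"), nrow = 2,
                               dimnames = list(NULL, "S1")), va)
  m2 <- merge_panels(a, b2)
  conf2 <- attr(m2, "conflicts")
  expect_equal(nrow(conf2), 1L)  # S1 chr1:20 het vs hom_alt
  expect_equal(unname(m2$calls["chr1:20:C:T", "S1"]), "missing")
  m3 <- merge_panels(a, b2, policy = "b_wins")
  expect_equal(unname(m3$calls["chr1:20:C:T", "S1"]), "hom_alt")
  # disjoint accession sets: union size |a| + |b|
  expect_length(merge_panels(a, b)$accessions, 3L)
})
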