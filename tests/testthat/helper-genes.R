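# Deterministic toy gene builders for unit tests (no RNG).

# Build a two-exon gene from an explicit codon vector (last codon must be a
# stop). The transcript (UTR5 + CDS + UTR3) is split in half by a single
# intron of `intron_len` bases (GT..AG). `strand = "-"` places the
# reverse-complement on the chromosome with mirrored coordinates.
make_coding_gene <- function(codons, strand = "+", intron_len = 30L,
                             utr5 = "GGATCCTTAG", utr3 = "CCTAGGCATG",
                             gene_id = "toy") {
  stopifnot(intron_len >= 12L)
  cds <- paste(codons, collapse = "")
  u3 <- paste0(utr3, "TTAATTAATTAA")  # stops in all three frames
  transcript <- paste0(utr5, cds, u3)
  tlen <- nchar(transcript)
  half <- tlen %/% 2L
  intron <- paste0("GT", paste(rep(c("C", "A"),
                                   length.out = intron_len - 4L),
                               collapse = ""), "AG")
  gene_plus <- paste0(substr(transcript, 1, half), intron,
                      substr(transcript, half + 1L, tlen))
  flank_len <- 40L
  flank <- strrep("ACGTT", 8L)
  glen <- nchar(gene_plus)
  ex_rel <- data.frame(start = c(1L, half + intron_len + 1L),
                       end = c(half, glen))
  t2g <- function(tp) ifelse(tp <= half, tp, tp + intron_len)
  cds_lo_rel <- t2g(nchar(utr5) + 1L)
  cds_hi_rel <- t2g(nchar(utr5) + nchar(cds))
  if (strand == "+") {
    chromseq <- paste0(flank, gene_plus, flank)
    exons <- ex_rel + flank_len
    cds_lo <- cds_lo_rel + flank_len
    cds_hi <- cds_hi_rel + flank_len
  } else {
    chromseq <- paste0(flank, sorgscreen:::revcomp(gene_plus), flank)
    mirror <- function(p) flank_len + (glen - p + 1L)
    exons <- data.frame(start = mirror(ex_rel$end), end = mirror(ex_rel$start))
    exons <- exons[order(exons$start), , drop = FALSE]
    cds_lo <- mirror(cds_hi_rel)
    cds_hi <- mirror(cds_lo_rel)
  }
  model <- gene_model(gene_id = gene_id, chrom = "chrT", strand = strand,
                      span_start = flank_len + 1L,
                      span_end = flank_len + glen, exons = exons,
                      cds_start = cds_lo, cds_end = cds_hi,
                      protein_length = length(codons) - 1L)
  list(model = model, genome = c(chrT = chromseq))
}

# Codon vector: Met + filler Ala, with named substitutions at given codons,
# then a stop.
toy_codons <- function(n_res, at = list()) {
  codons <- c("ATG", rep("GCT", n_res - 1L), "TAA")
  for (pos in names(at)) codons[as.integer(pos)] <- at[[pos]]
  codons
}
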