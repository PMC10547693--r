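test_that("HGVS formatting matches the published allele descriptions", {
  expect_equal(format_hgvs_p(protein_change("missense", 184, "Lys", "Asn")),
               "p.(Lys184Asn)")
  expect_equal(format_hgvs_p(protein_change("nonsense", 270, "Gln",
                                            "Ter")), "p.(Gln270Ter)")
  expect_equal(format_hgvs_p(protein_change("frameshift", 94, "Glu", "Asp",
                                            ter_offset = 6)),
               "p.(Glu94AspfsTer6)")
  expect_equal(format_hgvs_p(protein_change("inframe_dup", 31, "His")),
               "p.(His31dup)")
  expect_equal(format_hgvs_p(protein_change("inframe_del", 1174, "Gln",
                                            pos2 = 1175, ref_aa2 = "Arg")),
               "p.(Gln1174_Arg1175del)")
  expect_equal(format_hgvs_p(protein_change("start_loss", 1, "Met")),
               "p.(Met1?)")
})

test_that("HGVS parsing inverts formatting and flags bad tokens", {
  pc <- parse_hgvs_p("p.(Ser443Ter)")
  expect_equal(pc$kind, "nonsense")
  expect_equal(pc$pos, 443L)
  fs <- parse_hgvs_p("p.(Leu184IlefsTer8)")
  expect_equal(fs$kind, "frameshift")
  expect_equal(fs$pos, 184L)
  expect_equal(fs$ter_offset, 8L)
  # tolerant of missing parentheses
  expect_equal(format_hgvs_p(parse_hgvs_p("p.Lys184Asn")), "p.(Lys184Asn)")
  expect_error(parse_hgvs_p("p.(Gly23Ala"), "unbalanced")
  expect_error(parse_hgvs_p("p.(Arg388Typ)"), "Typ")
  expect_error(parse_hgvs_p("nonsense-string"), "cannot parse")
})

test_that("all characterized allele strings parse and re-format to themselves", {
  for (s in CHARACTERIZED_HGVS) {
    expect_equal(format_hgvs_p(parse_hgvs_p(s)), s, label = s)
  }
})

test_that("parse/format round-trips over random protein changes", {
  set.seed(99)
  for (i in 1:500) {
    pc <- random_protein_change()
    back <- parse_hgvs_p(format_hgvs_p(pc))
    expect_equal(format_hgvs_p(back), format_hgvs_p(pc))
    expect_equal(back$kind, pc$kind)
    expect_equal(back$pos, pc$pos)
  }
})

test_that("translation follows the standard code and flags missing stops", {
  expect_equal(translate_cds("ATGTAA"), list(protein = "M",
                                             stop_found = TRUE))
  expect_equal(translate_cds("ATGTGG"), list(protein = "MW",
                                             stop_found = FALSE))
  expect_equal(translate_cds("TGGTAA")$protein, "W")
  expect_warning(out <- translate_cds("ATGANTTAA"), "X")
  expect_equal(out$protein, "MX")
  expect_error(translate_cds("AT"), "codon")
})

test_that("CDS mutation validates the reference allele and adjusts length", {
  cds <- "ATGGCTCAATAA"
  expect_equal(apply_variant_to_cds(cds, 4, "G", "A"), "ATGACTCAATAA")
  expect_equal(nchar(apply_variant_to_cds(cds, 4, "GCT", "G")),
               nchar(cds) - 2L)
  expect_equal(nchar(apply_variant_to_cds(cds, 6, "T", "TGTCGA")),
               nchar(cds) + 5L)
  expect_error(apply_variant_to_cds(cds, 4, "T", "A"), "mismatch")
})

test_that("nonsense, splice and in-frame deletions match published patterns", {
  # Gln (CAA) at codon 270; C>T at its first base introduces a stop
  tg <- make_coding_gene(toy_codons(300, at = list(`270` = "CAA")))
  m <- tg$model
  g270 <- cds_to_genomic(m, 3L * 270L - 2L)
  cons <- predict_consequence(m, tg$genome,
                              variant("chrT", g270, "C", "T"))
  expect_equal(cons$protein_change$kind, "nonsense")
  expect_equal(cons$hgvs_p, "p.(Gln270Ter)")
  # intronic variant at donor offset +4: splice region, no protein change
  intr <- sorgscreen:::introns_of(m)
  p4 <- intr$start[1] + 3L
  ref <- substr(tg$genome[["chrT"]], p4, p4)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  spl <- predict_consequence(m, tg$genome, variant("chrT", p4, ref, alt))
  expect_equal(spl$region, "splice_region")
  expect_true(is.na(spl$hgvs_p))
  expect_null(spl$protein_change)
  # 6-base deletion removing Gln-Arg: range deletion nomenclature
  tg2 <- make_coding_gene(toy_codons(60, at = list(`40` = "CAA",
                                                   `41` = "CGT")))
  m2 <- tg2$model
  c1 <- 3L * 40L - 2L
  g1 <- cds_to_genomic(m2, c1 - 1L)
  seqs <- tg2$genome[["chrT"]]
  delv <- normalize_variant(
    variant("chrT", g1, substr(seqs, g1, g1 + 6L), substr(seqs, g1, g1)),
    tg2$genome)
  cons2 <- predict_consequence(m2, tg2$genome, delv)
  expect_equal(cons2$hgvs_p, "p.(Gln40_Arg41del)")
})

test_that("duplication detection applies the 3'-most placement rule", {
  # CAT inserted right after a CAT codon encoding His31: duplication
  tg <- make_coding_gene(toy_codons(60, at = list(`31` = "CAT")))
  ctx <- model_context(tg$model, tg$genome)
  dup <- detect_duplication(ctx$cds, "CAT", 3L * 31L)
  expect_equal(dup$kind, "inframe_dup")
  expect_equal(format_hgvs_p(dup), "p.(His31dup)")
  # CAT inserted after a GGA codon: plain insertion
  tg2 <- make_coding_gene(toy_codons(60, at = list(`31` = "GGA")))
  ctx2 <- model_context(tg2$model, tg2$genome)
  ins <- detect_duplication(ctx2$cds, "CAT", 3L * 31L)
  expect_equal(ins$kind, "inframe_ins")
  # insertion inside a tandem repeat is placed at the 3'-most equivalent
  # position: oracle enumerates equivalent placements and takes the maximum
  tg3 <- make_coding_gene(toy_codons(60, at = list(`30` = "CAT",
                                                   `31` = "CAT",
                                                   `32` = "CAT")))
  ctx3 <- model_context(tg3$model, tg3$genome)
  dup3 <- detect_duplication(ctx3$cds, "CAT", 3L * 30L)
  # oracle: enumerate placements of the inserted His over the His-run
  P <- strsplit(translate_cds(ctx3$cds)$protein, "")[[1]]
  Q <- append(P, "H", after = 30L)
  valid <- Filter(function(a) identical(append(P, "H", after = a), Q), 0:59)
  expect_equal(dup3$pos, max(valid))  # 3'-most equivalent placement (His32)
  expect_equal(dup3$pos, 32L)
})

test_that("frameshift numbering equals brute-force re-translation", {
  set.seed(41)
  cfg <- simulation_config(seed = 41, n_genes = 2)
  ref <- simulate_reference(cfg)
  for (g in names(ref$models)) {
    m <- ref$models[[g]]
    ctx <- model_context(m, ref$genome)
    for (rep in 1:20) {
      pl <- plant_variant(m, ref$genome, protein_change("frameshift"),
                          used = integer(), remap = TRUE)
      cons <- predict_consequence(m, ref$genome, pl$variant, ctx = ctx)
      pc <- cons$protein_change
      if (pc$kind != "frameshift") next  # fs hitting an immediate stop
      # brute force: translate the mutant CDS fully and align
      orc <- oracle_consequence(m, ref$genome, pl$variant)
      expect_equal(pc$ter_offset, orc$ter_offset)
      expect_equal(format_hgvs_p(pc), format_hgvs_p(orc))
    }
  }
})

test_that("synonymous changes leave the protein identical", {
  set.seed(43)
  cfg <- simulation_config(seed = 43, n_genes = 2)
  ref <- simulate_reference(cfg)
  m <- ref$models[[1]]
  ctx <- model_context(m, ref$genome)
  for (rep in 1:10) {
    pl <- plant_variant(m, ref$genome, protein_change("synonymous"))
    cons <- predict_consequence(m, ref$genome, pl$variant, ctx = ctx)
    expect_equal(cons$protein_change$kind, "synonymous")
    orc <- oracle_consequence(m, ref$genome, pl$variant)
    expect_equal(orc$kind, "synonymous")
  }
})

test_that("strand mirroring yields identical protein changes", {
  codons <- toy_codons(80, at = list(`20` = "CAA", `50` = "AAA"))
  plus <- make_coding_gene(codons, strand = "+")
  minus <- make_coding_gene(codons, strand = "-")
  for (cp in c(3L * 20L - 2L, 3L * 50L - 2L, 100L)) {
    gp <- cds_to_genomic(plus$model, cp)
    gm <- cds_to_genomic(minus$model, cp)
    refp <- substr(plus$genome[["chrT"]], gp, gp)
    altp <- setdiff(c("A", "C", "G", "T"), refp)[1]
    vp <- variant("chrT", gp, refp, altp)
    vm <- variant("chrT", gm, sorgscreen:::revcomp(refp),
                  sorgscreen:::revcomp(altp))
    cp_plus <- predict_consequence(plus$model, plus$genome, vp)
    cp_minus <- predict_consequence(minus$model, minus$genome, vm)
    expect_equal(cp_plus$hgvs_p, cp_minus$hgvs_p)
  }
})

test_that("variants at consensus splice sites get no protein prediction", {
  tg <- make_coding_gene(toy_codons(60))
  m <- tg$model
  intr <- sorgscreen:::introns_of(m)
  for (p in c(intr$start[1], intr$start[1] + 1L, intr$end[1] - 1L,
              intr$end[1])) {
    ref <- substr(tg$genome[["chrT"]], p, p)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    cons <- predict_consequence(m, tg$genome, variant("chrT", p, ref, alt))
    expect_equal(cons$region, "splice_disrupting")
    expect_null(cons$protein_change)
  }
  # deletion spanning the exon/intron junction
  j <- intr$start[1]
  seqs <- tg$genome[["chrT"]]
  v <- normalize_variant(variant("chrT", j - 3L,
                                 substr(seqs, j - 3L, j + 1L),
                                 substr(seqs, j - 3L, j - 3L)), tg$genome)
  cons <- predict_consequence(m, tg$genome, v)
  expect_equal(cons$region, "splice_disrupting")
})

test_that("start- and stop-codon disruption are reported as such", {
  tg <- make_coding_gene(toy_codons(40))
  m <- tg$model
  g1 <- cds_to_genomic(m, 1L)  # the A of ATG
  ref <- substr(tg$genome[["chrT"]], g1, g1)
  cons <- predict_consequence(m, tg$genome, variant("chrT", g1, ref, "C"))
  expect_equal(cons$protein_change$kind, "start_loss")
  expect_equal(cons$hgvs_p, "p.(Met1?)")
  # stop codon (residue protein_length + 1) changed to a sense codon
  n <- m$protein_length
  cstop <- 3L * (n + 1L) - 2L
  gstop <- cds_to_genomic(m, cstop)
  refs <- substr(tg$genome[["chrT"]], gstop, gstop)
  alts <- if (m$strand == "+") "C" else "G"
  cons2 <- predict_consequence(m, tg$genome,
                               variant("chrT", gstop, refs, alts))
  expect_equal(cons2$protein_change$kind, "stop_loss")
  expect_match(cons2$hgvs_p, "^p\\.\\(Ter[0-9]+[A-Za-z]{3}extTer\\?\\)$")
})
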