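test_that("builtin catalog carries the characterized allele set", {
  cat_ <- builtin_catalog()
  names_ <- vapply(cat_, `[[`, character(1), "name")
  loci <- vapply(cat_, `[[`, character(1), "locus")
  expect_equal(sum(loci == "Ma1"), 7L)   # seven characterized Ma1 alleles
  expect_equal(sum(loci == "Dw3"), 3L)   # dw3-ref, dw3-sd1, dw3-sd2
  prr3 <- cat_[[which(names_ == "Sbprr37-3")]]
  expect_length(prr3$components, 2L)     # nonsense + missense conjunction
  expect_true("dw3-ref" %in% names_)
  dwref <- cat_[[which(names_ == "dw3-ref")]]
  expect_true(dwref$components[[1]]$unmatchable)
  expect_false(anyDuplicated(names_) > 0)
  ghd2 <- cat_[[which(names_ == "Sbghd7-2")]]
  expect_equal(ghd2$components[[1]]$mode, "coordinate")
  expect_equal(ghd2$components[[1]]$min_indel_len, 10L)
})

test_that("catalog round-trips through JSON without loss", {
  cat_ <- builtin_catalog()
  tmp <- withr::local_tempfile(fileext = ".json")
  catalog_to_json(cat_, tmp)
  back <- catalog_from_json(tmp)
  expect_length(back, length(cat_))
  for (i in seq_along(cat_)) {
    expect_equal(back[[i]]$name, cat_[[i]]$name)
    expect_equal(back[[i]]$locus, cat_[[i]]$locus)
    expect_equal(back[[i]]$allele_class, cat_[[i]]$allele_class)
    expect_length(back[[i]]$components, length(cat_[[i]]$components))
    for (j in seq_along(cat_[[i]]$components)) {
      expect_equal(back[[i]]$components[[j]]$hgvs_p,
                   cat_[[i]]$components[[j]]$hgvs_p)
      expect_equal(back[[i]]$components[[j]]$mode,
                   cat_[[i]]$components[[j]]$mode)
    }
  }
})

test_that("consequence matchers compare parsed changes, not raw strings", {
  m1 <- variant_matcher("consequence", hgvs_p = "p.Lys184Asn")
  m2 <- variant_matcher("consequence", hgvs_p = "p.(Lys184Asn)")
  expect_equal(m1$hgvs_p, m2$hgvs_p)
})

test_that("allele matching applies the zygosity and missingness rules", {
  d <- allele_definition("Ma1", "test", components = list(
    variant_matcher("consequence", hgvs_p = "p.(Gln270Ter)"),
    variant_matcher("consequence", hgvs_p = "p.(Lys184Asn)")),
    allele_class = "amorphic")
  resolved <- list("v1", "v2")
  calls <- c(v1 = "hom_alt", v2 = "hom_alt")
  expect_equal(match_allele(calls, d, resolved), "present_hom")
  calls["v2"] <- "het"
  expect_equal(match_allele(calls, d, resolved), "present_het")
  calls["v2"] <- "hom_ref"
  expect_equal(match_allele(calls, d, resolved), "absent")
  calls["v2"] <- "missing"
  expect_equal(match_allele(calls, d, resolved), "unknown")
  # absent beats missing: any hom_ref component settles the call
  calls <- c(v1 = "missing", v2 = "hom_ref")
  expect_equal(match_allele(calls, d, resolved), "absent")
  # unmatchable component (dw3-ref) is always unknown
  dref <- allele_definition("Dw3", "dw3-ref", components = list(
    variant_matcher("coordinate", unmatchable = TRUE)),
    allele_class = "unknown")
  expect_equal(match_allele(calls, dref, list(NULL)), "unknown")
  # a component with no matching panel variant means the allele is absent
  expect_equal(match_allele(calls, d, list("v1", character())), "absent")
})

test_that("locus calling follows the documented precedence", {
  cfg <- simulation_config(seed = 77, panel_size = 40, het_rate = 0.3,
                           missingness = 0)
  panel <- simulate_panel(cfg)
  truth <- panel$manifest$truth_calls
  calls <- genotype_panel(panel$gmat, panel$catalog, panel$classified)
  expect_equal(nrow(calls), 40L * 8L)  # one call per accession x locus
  mg <- merge(calls, truth, by = c("accession", "locus"),
              suffixes = c("", ".truth"))
  expect_equal(mg$status, mg$status.truth)
  named <- mg[mg$status == "named", ]
  expect_true(all(mapply(function(a, b) a %in% strsplit(b, ",")[[1]],
                         named$allele, named$matched_alleles)))
  # permuting variant order never changes a status
  perm <- sample(nrow(panel$gmat$variants))
  gmat2 <- genotype_matrix(panel$gmat$calls[perm, , drop = FALSE],
                           panel$gmat$variants[perm, , drop = FALSE])
  calls2 <- genotype_panel(gmat2, panel$catalog, panel$classified)
  key <- function(df) df[order(df$accession, df$locus),
                         c("accession", "locus", "status")]
  expect_equal(key(calls), key(calls2))
})

test_that("call_locus flags uncharacterized accessions and errors on bad locus", {
  cfg <- simulation_config(seed = 78, panel_size = 10, novel_del_rate = 0)
  panel <- simulate_panel(cfg)
  gmat <- panel$gmat
  acc <- gmat$accessions[1]
  expect_error(call_locus(acc, "NotALocus", panel$catalog,
                          panel$classified, gmat), "absent from catalog")
  # masking all interrogated sites for one accession at one locus
  sig <- panel$classified$variant_id[panel$classified$gene_id == "Dw1"]
  gmat$calls[intersect(sig, rownames(gmat$calls)), acc] <- "missing"
  lc <- call_locus(acc, "Dw1", panel$catalog, panel$classified, gmat)
  expect_equal(lc$status, "uncharacterized")
})

test_that("empty panels genotype to an empty call table", {
  cfg <- simulation_config(seed = 79, panel_size = 2)
  panel <- simulate_panel(cfg)
  empty <- genotype_matrix(
    matrix(character(), nrow = 0, ncol = 0),
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), id = character()))
  out <- genotype_panel(empty, panel$catalog, panel$classified)
  expect_equal(nrow(out), 0L)
})

test_that("panel summaries conserve totals and report multi-locus stacking", {
  cfg <- simulation_config(seed = 80, panel_size = 60)
  panel <- simulate_panel(cfg)
  calls <- genotype_panel(panel$gmat, panel$catalog, panel$classified)
  s <- summarize_panel(calls, k = 3)
  for (l in unique(s$per_locus$locus)) {
    expect_equal(sum(s$per_locus$n[s$per_locus$locus == l]), s$panel_size)
  }
  # per-allele counts equal the manifest's planted homozygous carriers
  truth <- panel$manifest$truth_calls
  planted <- table(truth$allele[truth$status == "named"])
  for (a in names(planted)) {
    got <- s$per_allele$n[s$per_allele$allele == a]
    expect_equal(if (length(got)) got else 0L, unname(planted[a]),
                 label = a)
  }
  # an accession mutant at >= k maturity loci appears with its wildtype loci
  for (entry in s$multi_locus) {
    expect_gte(length(entry$mutant_loci), 3L)
    sub <- truth[truth$accession == entry$accession &
                   truth$locus %in% c("Ma1", "Ma2", "Ma3", "Ma5", "Ma6"), ]
    expect_setequal(entry$wildtype_loci,
                    sub$locus[sub$status == "wildtype"])
  }
})

test_that("an accession mutant at four of five maturity loci is reported", {
  # construct a call table mirroring the stacked-mutant pattern directly
  loci <- c("Ma1", "Ma2", "Ma3", "Ma5", "Ma6", "Dw1", "Dw2", "Dw3")
  status <- c("named", "wildtype", "named", "novel_deleterious", "named",
              "named", "named", "wildtype")
  calls <- data.frame(accession = "PI_X", locus = loci, status = status,
                      matched_alleles = ifelse(status == "named", "a", ""),
                      supporting_variants = "", missing_fraction = 0,
                      stringsAsFactors = FALSE)
  s <- summarize_panel(calls, k = 4)
  expect_length(s$multi_locus, 1L)
  expect_equal(s$multi_locus[[1]]$accession, "PI_X")
  expect_equal(s$multi_locus[[1]]$wildtype_loci, "Ma2")
})

test_that("lollipop export maps glyphs and stays within protein bounds", {
  cfg <- simulation_config(seed = 81, panel_size = 5)
  panel <- simulate_panel(cfg)
  for (g in names(panel$models)) {
    sub <- panel$consequences[vapply(panel$consequences, function(r)
      r$gene_id == g, logical(1))]
    tab <- export_lollipop_table(sub, panel$models[[g]])
    if (nrow(tab) == 0) next
    expect_true(all(tab$protein_position >= 1 &
                      tab$protein_position <= panel$models[[g]]$protein_length))
    expect_true(all(tab$glyph %in% c("circle", "triangle_down",
                                     "triangle_up", "diamond")))
    expect_true(all(tab$color_class %in% c("missense", "nonsense",
                                           "splice")))
  }
  # nonsense SNP -> circle in the nonsense color class
  nn <- panel$classified[panel$classified$kind == "nonsense", ][1, ]
  g <- nn$gene_id
  sub <- panel$consequences[vapply(panel$consequences, function(r)
    r$gene_id == g & r$variant_id == nn$variant_id, logical(1))]
  tab <- export_lollipop_table(sub, panel$models[[g]])
  expect_equal(tab$glyph, "circle")
  expect_equal(tab$color_class, "nonsense")
  # insertions point down, deletions point up
  ins <- panel$classified[grepl("dup|ins", panel$classified$kind), ]
  if (nrow(ins)) {
    sub <- panel$consequences[vapply(panel$consequences, function(r)
      r$variant_id == ins$variant_id[1] & r$gene_id == ins$gene_id[1],
      logical(1))]
    tab <- export_lollipop_table(sub, panel$models[[ins$gene_id[1]]])
    expect_equal(tab$glyph, "triangle_down")
  }
})
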