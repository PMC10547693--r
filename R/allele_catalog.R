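#' Construct a variant matcher
#'
#' A matcher identifies the panel variants that realize one component of a
#' characterized allele. Two modes exist. `coordinate` matches on the
#' normalized variant key, or — for imprecise signatures — on a position
#' window plus a minimum insertion length. `consequence` matches on the
#' predicted protein change (parsed and canonicalized, so `p.Lys184Asn`
#' and `p.(Lys184Asn)` are equivalent); when the exact change was never
#' published, a consequence matcher may instead carry a change `kind`
#' plus a residue `pos_range`.
#'
#' @param mode `"coordinate"` or `"consequence"`.
#' @param chrom,pos,ref,alt Coordinate mode: exact normalized key.
#' @param window_start,window_end,min_indel_len Coordinate mode: window
#'   matching for imprecise signatures (insertions of at least
#'   `min_indel_len` bases anywhere in the window).
#' @param hgvs_p Consequence mode: HGVS p. string.
#' @param kind,pos_range Consequence mode alternative: change kind and
#'   1-based residue range.
#' @param unmatchable TRUE for signatures that cannot be matched from
#'   short-read data at all (always `unknown`).
#' @return An object of class `variant_matcher`.
#' @export
variant_matcher <- function(mode = c("coordinate", "consequence"),
                            chrom = NA, pos = NA, ref = NA, alt = NA,
                            window_start = NA, window_end = NA,
                            min_indel_len = NA, hgvs_p = NA,
                            kind = NA, pos_range = NULL,
                            unmatchable = FALSE) {
  mode <- match.arg(mode)
  if (mode == "coordinate" && !unmatchable) {
    exact <- !is.na(pos) && !is.na(ref) && !is.na(alt)
    window <- !is.na(window_start) && !is.na(window_end)
    if (!exact && !window) {
      stop("coordinate matcher needs an exact key or explicit window bounds",
           call. = FALSE)
    }
  }
  if (mode == "consequence" && !unmatchable && is.na(hgvs_p) && is.na(kind)) {
    stop("consequence matcher needs hgvs_p or kind", call. = FALSE)
  }
  canonical <- if (!is.na(hgvs_p)) format_hgvs_p(parse_hgvs_p(hgvs_p)) else NA
  structure(list(mode = mode, chrom = chrom, pos = pos, ref = ref, alt = alt,
                 window_start = window_start, window_end = window_end,
                 min_indel_len = min_indel_len, hgvs_p = canonical,
                 kind = kind, pos_range = pos_range,
                 unmatchable = unmatchable),
            class = "variant_matcher")
}

#' Construct a characterized-allele definition
#'
#' All components are required jointly (compound alleles such as
#' *Sbprr37-3* carry both their nonsense and missense variants), at the
#' required zygosity (default homozygous alternate, since het-only carriers
#' are reported separately).
#'
#' @param locus Locus name (matches the gene model's `gene_id`).
#' @param name Canonical allele name (unique within a catalog).
#' @param components List of [variant_matcher()] objects (>= 1).
#' @param allele_class `"amorphic"`, `"hypomorphic"`, `"missense"`, or
#'   `"unknown"`.
#' @param synonyms Character vector of alternative names / carrier lines.
#' @param zygosity Required zygosity, default `"hom_alt"`.
#' @param provenance Free-text provenance note.
#' @return An object of class `allele_definition`.
#' @export
allele_definition <- function(locus, name, components,
                              allele_class = c("amorphic", "hypomorphic",
                                               "missense", "unknown"),
                              synonyms = character(), zygosity = "hom_alt",
                              provenance = "") {
  allele_class <- match.arg(allele_class)
  if (length(components) < 1) stop("allele needs >= 1 component", call. = FALSE)
  structure(list(locus = locus, name = name, synonyms = synonyms,
                 components = components, allele_class = allele_class,
                 zygosity = zygosity, provenance = provenance),
            class = "allele_definition")
}

#' The built-in catalog of characterized Maturity/Dwarf alleles
#'
#' Machine-readable signatures for the previously characterized mutant
#' alleles at the eight loci: seven at *Ma1* (*Sbprr37-1/-2/-3* and the
#' race-specific *prr37* alleles), two at *Ma2*, two at *Ma3*
#' (*Sbphyb-1/-2*), one at *Ma5* (*SbphyC-1*), three at *Ma6*
#' (*Sbghd7-1*, its 4-bp alternate, and the window-matched *Sbghd7-2*),
#' and *dw1*, *dw2*, and three at *Dw3* (*dw3-ref* is metadata-only: its
#' 882-bp tandem duplication is undetectable from short-read panels and
#' always yields `unknown`).
#'
#' @return A list of [allele_definition()] objects.
#' @export
builtin_catalog <- function() {
  cm <- function(hgvs) variant_matcher("consequence", hgvs_p = hgvs)
  list(
    allele_definition("Ma1", "Sbprr37-1", synonyms = c("prr37^Milo"),
      components = list(variant_matcher("consequence", kind = "frameshift",
                                        pos_range = c(1L, 98L))),
      allele_class = "amorphic",
      provenance = paste("1-bp deletion upstream of the pseudoreceiver motif",
                         "(residues 99-207); exact HGVS never published, so",
                         "the signature is any frameshift before residue 99")),
    allele_definition("Ma1", "Sbprr37-2", synonyms = c("prr37^Kafir-1"),
      components = list(cm("p.(Lys184Asn)")), allele_class = "missense"),
    allele_definition("Ma1", "Sbprr37-3", synonyms = c("prr37^Kafir-2"),
      components = list(cm("p.(Gln270Ter)"), cm("p.(Lys184Asn)")),
      allele_class = "amorphic",
      provenance = paste("nonsense + missense conjunction; an alternative",
                         "report places the nonsense change at Gln292Ter",
                         "(unresolved, not used as a matcher)")),
    allele_definition("Ma1", "prr37^Sudangrass",
      components = list(cm("p.(Ile126Lys)")), allele_class = "missense"),
    allele_definition("Ma1", "prr37^Feterita",
      components = list(cm("p.(Gly177ArgfsTer4)")), allele_class = "amorphic"),
    allele_definition("Ma1", "prr37^Durra",
      components = list(cm("p.(Ser443Ter)")), allele_class = "amorphic"),
    allele_definition("Ma1", "prr37^Broomcorn",
      components = list(cm("p.(Gln494Ter)")), allele_class = "amorphic"),
    allele_definition("Ma2", "ma2-Leu141Ter",
      synonyms = c("38M", "44M", "SM60", "60M", "SM80", "80M"),
      components = list(cm("p.(Leu141Ter)")), allele_class = "amorphic"),
    allele_definition("Ma2", "ma2-Met83Thr", synonyms = c("IS3614-2"),
      components = list(cm("p.(Met83Thr)")), allele_class = "missense",
      provenance = "predicted deleterious by PROVEAN"),
    allele_definition("Ma3", "Sbphyb-1",
      synonyms = c("Ma3R", "Ma3Ryer", "58M"),
      components = list(cm("p.(Asn1023MetfsTer11)")),
      allele_class = "amorphic"),
    allele_definition("Ma3", "Sbphyb-2", synonyms = c("IS3620C"),
      components = list(cm("p.(His31dup)"), cm("p.(Asp308Gly)"),
                        cm("p.(Leu1113Val)")),
      allele_class = "hypomorphic",
      provenance = paste("the 3-bp in-frame event is reported as either",
                         "His31dup or His31del; dup is used as the matcher")),
    allele_definition("Ma5", "SbphyC-1", synonyms = c("R.07007"),
      components = list(cm("p.(Gly124Val)"), cm("p.(Gly162Arg)"),
                        cm("p.(Val190Ala)"), cm("p.(Glu922Asp)")),
      allele_class = "hypomorphic"),
    allele_definition("Ma6", "Sbghd7-1",
      synonyms = c("Tx623", "100M", "SM100", "BTx406"),
      components = list(cm("p.(Glu94AspfsTer6)")), allele_class = "amorphic",
      provenance = "5-bp insertion (GTCGA) in exon 1"),
    allele_definition("Ma6", "Sbghd7-1-alt",
      components = list(cm("p.(Glu94SerfsTer77)")), allele_class = "amorphic",
      provenance = "4-bp deletion at the same position as Sbghd7-1"),
    allele_definition("Ma6", "Sbghd7-2",
      synonyms = c("Red Kafir", "Hegari", "Double Dwarf Feterita", "Rio"),
      components = list(variant_matcher("coordinate", chrom = "Chr06",
                                        window_start = 698150L,
                                        window_end = 698185L,
                                        min_indel_len = 10L)),
      allele_class = "hypomorphic",
      provenance = paste("large intron-2 insertion of undetermined size;",
                         "short-read hallmark: insertions >= 10 bp at",
                         "Chr06:698,150-698,185")),
    allele_definition("Dw1", "dw1",
      components = list(cm("p.(Lys199Ter)")), allele_class = "amorphic"),
    allele_definition("Dw2", "dw2",
      components = list(cm("p.(Leu184IlefsTer8)")), allele_class = "amorphic",
      provenance = "2-bp deletion in exon 1"),
    allele_definition("Dw3", "dw3-ref",
      components = list(variant_matcher("coordinate", unmatchable = TRUE)),
      allele_class = "unknown",
      provenance = paste("882-bp tandem duplication in exon 5, undetectable",
                         "from short-read panels; always yields unknown")),
    allele_definition("Dw3", "dw3-sd1",
      components = list(cm("p.(Leu1435GlyfsTer120)")),
      allele_class = "amorphic"),
    allele_definition("Dw3", "dw3-sd2",
      components = list(cm("p.(Gln1174_Arg1175del)")),
      allele_class = "hypomorphic",
      provenance = "6-bp deletion in the ABC transporter signature motif")
  )
}

#' Serialize a catalog to JSON
#'
#' @param catalog List of [allele_definition()] objects.
#' @param path Optional output file.
#' @return The JSON string (invisibly when `path` is given).
#' @export
catalog_to_json <- function(catalog, path = NULL) {
  payload <- lapply(catalog, function(d) {
    list(locus = d$locus, name = d$name, synonyms = d$synonyms,
         allele_class = d$allele_class, zygosity = d$zygosity,
         provenance = d$provenance,
         components = lapply(d$components, function(m) {
           m[!vapply(m, function(x) is.null(x) ||
                       (length(x) == 1 && is.na(x)), logical(1))]
         }))
  })
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Deserialize a catalog from JSON
#'
#' @param path JSON file or JSON string produced by [catalog_to_json()].
#' @return List of [allele_definition()] objects.
#' @export
catalog_from_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(d) {
    allele_definition(
      locus = d$locus, name = d$name,
      synonyms = unlist(d$synonyms) %||% character(),
      allele_class = d$allele_class, zygosity = d$zygosity,
      provenance = d$provenance %||% "",
      components = lapply(d$components, function(m) {
        variant_matcher(
          mode = m$mode,
          chrom = m$chrom %||% NA, pos = m$pos %||% NA,
          ref = m$ref %||% NA, alt = m$alt %||% NA,
          window_start = m$window_start %||% NA,
          window_end = m$window_end %||% NA,
          min_indel_len = m$min_indel_len %||% NA,
          hgvs_p = m$hgvs_p %||% NA, kind = m$kind %||% NA,
          pos_range = if (!is.null(m$pos_range)) unlist(m$pos_range),
          unmatchable = isTRUE(m$unmatchable))
      }))
  })
}

# Resolve a matcher to the panel variant keys it designates.
# classified: data.frame from classify_consequences() (variant_id, gene_id,
# kind, hgvs_p, protein_position, ...). variants: panel variant records.
resolve_matcher <- function(matcher, locus, classified, variants) {
  if (matcher$unmatchable) return(NULL)  # NULL = cannot be interrogated
  if (matcher$mode == "coordinate") {
    if (!is.na(matcher$pos)) {
      key <- variant_key(matcher$chrom, matcher$pos, matcher$ref, matcher$alt)
      return(intersect(key, variants$id))
    }
    ins_len <- nchar(variants$alt) - nchar(variants$ref)
    hit <- variants$chrom == matcher$chrom &
      variants$pos >= matcher$window_start &
      variants$pos <= matcher$window_end &
      ins_len >= matcher$min_indel_len
    return(variants$id[hit])
  }
  rows <- classified[classified$gene_id == locus, , drop = FALSE]
  if (!is.na(matcher$hgvs_p)) {
    hit <- !is.na(rows$hgvs_p) & rows$hgvs_p == matcher$hgvs_p
  } else {
    hit <- rows$kind == matcher$kind
    if (!is.null(matcher$pos_range)) {
      hit <- hit & !is.na(rows$protein_position) &
        rows$protein_position >= matcher$pos_range[1] &
        rows$protein_position <= matcher$pos_range[2]
    }
  }
  rows$variant_id[hit]
}

# Per-component genotype state for one accession: strongest alt call over
# the resolved keys. A component with no matching panel variant is hom_ref
# (merged panel VCFs assert all discovered sites, so absence means no
# carrier).
component_state <- function(acc_calls, keys) {
  if (is.null(keys)) return("unknown_site")
  if (length(keys) == 0) return("hom_ref")
  calls <- acc_calls[keys]
  calls[is.na(calls)] <- "missing"
  if (any(calls == "hom_alt")) "hom_alt"
  else if (any(calls == "het")) "het"
  else if (any(calls == "missing")) "missing"
  else "hom_ref"
}

#' Match one accession's genotypes against an allele definition
#'
#' @param acc_calls Named character vector of call states keyed by
#'   normalized variant key (one accession's column of a
#'   [genotype_matrix()]).
#' @param definition An [allele_definition()].
#' @param resolved List of resolved variant-key sets, one per component
#'   (see the internal resolver used by [genotype_panel()]); components
#'   flagged unmatchable resolve to `NULL`.
#' @return One of `"present_hom"`, `"present_het"`, `"absent"`, `"unknown"`.
#' @export
match_allele <- function(acc_calls, definition, resolved) {
  states <- vapply(resolved, function(k) component_state(acc_calls, k),
                   character(1))
  if (any(states == "unknown_site")) return("unknown")
  if (any(states == "hom_ref")) return("absent")
  if (any(states == "missing")) return("unknown")
  if (all(states == "hom_alt")) return("present_hom")
  "present_het"
}

#' Call one accession's status at one locus
#'
#' Precedence: (1) any homozygous catalog allele gives `named` (all matched
#' names listed); (2) else any homozygous deleterious variant gives
#' `novel_deleterious`; (3) else any heterozygous allele or heterozygous
#' deleterious variant gives `heterozygous_carrier`; (4) else a
#' missing-data fraction at the interrogated sites above
#' `missingness_threshold` gives `uncharacterized`; (5) else `wildtype`.
#' Interrogated sites are the union of resolved signature sites and
#' deleterious variant sites at the locus.
#'
#' @param accession Accession identifier (column of `gmat`).
#' @param locus Locus name.
#' @param catalog List of [allele_definition()] objects.
#' @param classified Classified consequence table from
#'   [classify_consequences()].
#' @param gmat A [genotype_matrix()].
#' @param missingness_threshold Fraction in `[0, 1]`, default 0.5.
#' @return A one-row data.frame (`accession`, `locus`, `status`,
#'   `matched_alleles`, `supporting_variants`, `missing_fraction`).
#' @export
call_locus <- function(accession, locus, catalog, classified, gmat,
                       missingness_threshold = 0.5) {
  defs <- Filter(function(d) d$locus == locus, catalog)
  if (length(defs) == 0) stop("locus ", locus, " absent from catalog",
                              call. = FALSE)
  acc_calls <- if (nrow(gmat$calls)) gmat$calls[, accession] else character()
  names(acc_calls) <- rownames(gmat$calls)
  resolved_per_def <- lapply(defs, function(d) {
    lapply(d$components, resolve_matcher, locus = locus,
           classified = classified, variants = gmat$variants)
  })
  statuses <- mapply(function(d, res) match_allele(acc_calls, d, res),
                     defs, resolved_per_def)
  del_ids <- classified$variant_id[classified$gene_id == locus &
                                     classified$deleterious]
  del_ids <- intersect(del_ids, names(acc_calls))
  sig_ids <- unique(unlist(resolved_per_def))
  interrogated <- union(sig_ids, del_ids)
  miss_frac <- if (length(interrogated) == 0) 0 else {
    mean(acc_calls[interrogated] == "missing")
  }
  named_hits <- vapply(defs, `[[`, character(1), "name")[statuses == "present_hom"]
  hom_del <- del_ids[acc_calls[del_ids] == "hom_alt"]
  het_del <- del_ids[acc_calls[del_ids] == "het"]
  status <-
    if (length(named_hits)) "named"
    else if (length(hom_del)) "novel_deleterious"
    else if (any(statuses == "present_het") || length(het_del))
      "heterozygous_carrier"
    else if (miss_frac > missingness_threshold) "uncharacterized"
    else "wildtype"
  support <- switch(status,
    named = unique(unlist(resolved_per_def[statuses == "present_hom"])),
    novel_deleterious = hom_del,
    heterozygous_carrier = unique(c(
      unlist(resolved_per_def[statuses == "present_het"]), het_del)),
    character())
  data.frame(accession = accession, locus = locus, status = status,
             matched_alleles = paste(named_hits, collapse = ","),
             supporting_variants = paste(support, collapse = ","),
             missing_fraction = miss_frac, stringsAsFactors = FALSE)
}

#' Genotype a whole panel against the allele catalog
#'
#' @inheritParams call_locus
#' @param loci Character vector of loci to call (default: all loci in the
#'   catalog).
#' @return data.frame with exactly one row per accession x locus.
#' @export
genotype_panel <- function(gmat, catalog, classified,
                           missingness_threshold = 0.5, loci = NULL) {
  if (is.null(loci)) {
    loci <- unique(vapply(catalog, `[[`, character(1), "locus"))
  }
  accs <- gmat$accessions
  if (length(accs) == 0 || length(loci) == 0) {
    return(data.frame(accession = character(), locus = character(),
                      status = character(), matched_alleles = character(),
                      supporting_variants = character(),
                      missing_fraction = numeric(), stringsAsFactors = FALSE))
  }
  out <- vector("list", length(accs) * length(loci))
  i <- 0L
  for (locus in loci) {
    # resolve once per locus, then reuse across accessions
    defs <- Filter(function(d) d$locus == locus, catalog)
    if (length(defs) == 0) stop("locus ", locus, " absent from catalog",
                                call. = FALSE)
    resolved_per_def <- lapply(defs, function(d) {
      lapply(d$components, resolve_matcher, locus = locus,
             classified = classified, variants = gmat$variants)
    })
    def_names <- vapply(defs, `[[`, character(1), "name")
    del_ids <- classified$variant_id[classified$gene_id == locus &
                                       classified$deleterious]
    del_ids <- intersect(del_ids, rownames(gmat$calls))
    sig_ids <- unique(unlist(resolved_per_def))
    interrogated <- union(sig_ids, del_ids)
    for (acc in accs) {
      acc_calls <- gmat$calls[, acc]
      names(acc_calls) <- rownames(gmat$calls)
      statuses <- vapply(seq_along(defs), function(j) {
        match_allele(acc_calls, defs[[j]], resolved_per_def[[j]])
      }, character(1))
      miss_frac <- if (length(interrogated) == 0) 0 else {
        mean(acc_calls[interrogated] == "missing")
      }
      named_hits <- def_names[statuses == "present_hom"]
      hom_del <- del_ids[acc_calls[del_ids] == "hom_alt"]
      het_del <- del_ids[acc_calls[del_ids] == "het"]
      status <-
        if (length(named_hits)) "named"
        else if (length(hom_del)) "novel_deleterious"
        else if (any(statuses == "present_het") || length(het_del))
          "heterozygous_carrier"
        else if (miss_frac > missingness_threshold) "uncharacterized"
        else "wildtype"
      support <- switch(status,
        named = unique(unlist(resolved_per_def[statuses == "present_hom"])),
        novel_deleterious = hom_del,
        heterozygous_carrier = unique(c(
          unlist(resolved_per_def[statuses == "present_het"]), het_del)),
        character())
      i <- i + 1L
      out[[i]] <- data.frame(accession = acc, locus = locus, status = status,
                             matched_alleles = paste(named_hits, collapse = ","),
                             supporting_variants = paste(support, collapse = ","),
                             missing_fraction = miss_frac,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Summarize locus calls over a panel
#'
#' @param calls data.frame from [genotype_panel()].
#' @param k Report accessions with mutant calls (named or
#'   novel_deleterious) at `k` or more of the `maturity_loci`.
#' @param maturity_loci Loci counted for the multi-locus report.
#' @return A list of class `panel_summary` with `per_locus` (status counts),
#'   `per_allele` (named-allele counts), `mutant_locus_count` (per
#'   accession) and `multi_locus` (accessions at >= k mutant maturity loci,
#'   with their wildtype loci).
#' @export
summarize_panel <- function(calls, k = 4,
                            maturity_loci = c("Ma1", "Ma2", "Ma3", "Ma5",
                                              "Ma6")) {
  statuses <- c("named", "novel_deleterious", "heterozygous_carrier",
                "wildtype", "uncharacterized")
  loci <- unique(calls$locus)
  per_locus <- do.call(rbind, lapply(loci, function(l) {
    sub <- calls[calls$locus == l, ]
    data.frame(locus = l,
               status = statuses,
               n = vapply(statuses, function(s) sum(sub$status == s),
                          integer(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  named <- calls[calls$status == "named", , drop = FALSE]
  allele_names <- unlist(strsplit(named$matched_alleles, ","))
  per_allele <- as.data.frame(table(allele = allele_names),
                              stringsAsFactors = FALSE)
  names(per_allele)[2] <- "n"
  mutant <- calls$status %in% c("named", "novel_deleterious")
  per_acc <- tapply(mutant, calls$accession, sum)
  mut_ma <- calls[mutant & calls$locus %in% maturity_loci, , drop = FALSE]
  counts_ma <- table(mut_ma$accession)
  flagged <- names(counts_ma)[counts_ma >= k]
  multi <- lapply(flagged, function(acc) {
    sub <- calls[calls$accession == acc & calls$locus %in% maturity_loci, ]
    list(accession = acc,
         mutant_loci = sub$locus[sub$status %in% c("named",
                                                   "novel_deleterious")],
         wildtype_loci = sub$locus[sub$status == "wildtype"])
  })
  structure(list(per_locus = per_locus, per_allele = per_allele,
                 mutant_locus_count = per_acc, multi_locus = multi,
                 k = k, panel_size = length(unique(calls$accession))),
            class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat("<panel_summary>", x$panel_size, "accessions\n")
  print(x$per_locus)
  invisible(x)
}

#' Export the per-variant lollipop plotting table
#'
#' One row per protein-positioned consequence: `protein_position`, a glyph
#' (`circle` for substitutions, `triangle_down` for insertions,
#' `triangle_up` for deletions, `diamond` for combined
#' insertion-deletions), a color class (`nonsense`, `splice`, or
#' `missense` for everything else protein-changing) and the HGVS p. string.
#'
#' @param consequences List of `consequence_record` objects for one gene.
#' @param model The [gene_model()] (for the protein-length bound).
#' @return data.frame with columns `protein_position`, `glyph`,
#'   `color_class`, `hgvs_p`.
#' @export
export_lollipop_table <- function(consequences, model) {
  rows <- lapply(consequences, function(r) {
    pc <- r$protein_change
    if (is.null(pc) || is.na(pc$pos)) return(NULL)
    parts <- strsplit(r$variant_id, ":", fixed = TRUE)[[1]]
    ref_len <- nchar(parts[3])
    alt_len <- nchar(parts[4])
    glyph <- if (ref_len == alt_len) "circle"
             else if (ref_len > 1 && alt_len > 1) "diamond"
             else if (alt_len > ref_len) "triangle_down" else "triangle_up"
    color <- if (pc$kind == "nonsense") "nonsense"
             else if (r$region %in% c("splice_region", "splice_disrupting"))
               "splice"
             else "missense"
    pos <- min(pc$pos, model$protein_length, na.rm = TRUE)
    data.frame(protein_position = pos, glyph = glyph, color_class = color,
               hgvs_p = r$hgvs_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(data.frame(
    protein_position = integer(), glyph = character(),
    color_class = character(), hgvs_p = character(),
    stringsAsFactors = FALSE)), rows))
  rownames(out) <- NULL
  out
}

#' Classify a set of consequences into a flat table
#'
#' Convenience joiner used by the genotyper and the pipeline: flattens
#' consequence records, attaches scores, and adds `category` and
#' `deleterious` columns.
#'
#' @param consequences List of `consequence_record` objects.
#' @param scores Named numeric score vector keyed by variant id.
#' @param threshold Deleteriousness threshold (see [classify_effect()]).
#' @param count_splice_region Passed to [is_deleterious()].
#' @return data.frame: consequence columns plus `score`, `category`,
#'   `deleterious`.
#' @export
classify_consequences <- function(consequences, scores = numeric(),
                                  threshold = 0.05,
                                  count_splice_region = FALSE) {
  tab <- consequence_table(consequences)
  tab$score <- ifelse(tab$variant_id %in% names(scores),
                      unname(scores[tab$variant_id]), NA_real_)
  tab$category <- vapply(seq_along(consequences), function(i) {
    classify_effect(consequences[[i]], tab$score[i], threshold)
  }, character(1))
  tab$deleterious <- is_deleterious(tab$category, count_splice_region)
  tab
}
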