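CALL_STATES <- c("hom_ref", "het", "hom_alt", "missing")

#' Stable variant key
#'
#' @param chrom,pos,ref,alt Variant fields.
#' @return `"chrom:pos:ref:alt"` character vector.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Construct a normalized biallelic variant record
#'
#' @param chrom Chromosome. @param pos 1-based position of the first REF base
#'   (VCF anchor convention for indels).
#' @param ref,alt REF/ALT allele strings (uppercase A/C/G/T/N).
#' @return A one-row data.frame with columns `chrom`, `pos`, `ref`, `alt`, `id`.
#' @export
variant <- function(chrom, pos, ref, alt) {
  pos <- as.integer(pos)
  ref <- toupper(ref)
  alt <- toupper(alt)
  if (is.na(pos) || pos < 1L) stop("variant pos must be >= 1", call. = FALSE)
  if (!nzchar(ref) || !nzchar(alt)) stop("empty allele", call. = FALSE)
  if (grepl("[^ACGTN]", ref) || grepl("[^ACGTN]", alt)) {
    stop("alleles must be A/C/G/T/N: ", ref, "/", alt, call. = FALSE)
  }
  if (ref == alt) stop("REF and ALT are identical: ", ref, call. = FALSE)
  data.frame(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
             id = variant_key(chrom, pos, ref, alt), stringsAsFactors = FALSE)
}

#' Construct a genotype matrix
#'
#' Per-accession diploid genotype calls over normalized biallelic variants.
#' Calls are one of `hom_ref`, `het`, `hom_alt`, `missing`; genotypes are
#' treated as unphased.
#'
#' @param calls Character matrix, rows = variants (rownames = variant keys),
#'   columns = accessions.
#' @param variants data.frame of variant records (see [variant()]), one row
#'   per matrix row, in the same order.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, variants) {
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = length(calls))
  if (nrow(calls) != nrow(variants)) {
    stop("calls and variants disagree in length", call. = FALSE)
  }
  if (anyDuplicated(colnames(calls))) {
    stop("duplicate accession identifiers", call. = FALSE)
  }
  if (anyDuplicated(variants$id)) {
    stop("duplicate variant keys", call. = FALSE)
  }
  if (ncol(calls) > 0 && !all(calls %in% CALL_STATES)) {
    stop("invalid call state(s): ",
         paste(unique(calls[!calls %in% CALL_STATES]), collapse = ", "),
         call. = FALSE)
  }
  rownames(calls) <- variants$id
  structure(list(calls = calls, variants = variants,
                 accessions = colnames(calls) %||% character()),
            class = "genotype_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d variants x %d accessions\n",
              nrow(x$calls), ncol(x$calls)))
  invisible(x)
}

# Map diploid GT strings ("0/1", "1|1", "./.", ...) for one split ALT allele
# (1-based index k among the record's ALT alleles) to the four call states.
gt_to_call <- function(gt, k) {
  vapply(gt, function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return("missing")
    alleles <- strsplit(g, "[/|]")[[1]]
    if (length(alleles) == 1) alleles <- c(alleles, alleles)  # haploid-style
    if (any(alleles == ".") || any(!nzchar(alleles))) return("missing")
    ai <- suppressWarnings(as.integer(alleles))
    if (any(is.na(ai))) return("missing")
    dosage <- sum(ai == k)
    if (dosage == 2) "hom_alt" else if (dosage == 1) "het" else "hom_ref"
  }, character(1), USE.NAMES = FALSE)
}

#' Split a (possibly multiallelic) VCF record into biallelic variants
#'
#' Each of the `k` ALT alleles becomes its own biallelic record. For a given
#' split allele, genotypes carrying only *other* ALT alleles map to `hom_ref`
#' (they do not carry this allele); half-missing genotypes map to `missing`.
#' Biallelic input passes through unchanged.
#'
#' @param chrom,pos,ref Record fields.
#' @param alt Comma-separated ALT allele string.
#' @param gt Character vector of GT subfields, one per accession (may be
#'   length zero for sites-only input).
#' @return A list with one element per ALT allele, each a list with `variant`
#'   (one-row data.frame) and `calls` (character vector of call states).
#' @export
split_multiallelic <- function(chrom, pos, ref, alt, gt = character()) {
  alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
  k <- length(alts)
  if (k < 1) stop("record without ALT allele", call. = FALSE)
  max_idx <- suppressWarnings(max(c(0L, unlist(lapply(gt, function(g) {
    a <- strsplit(g, "[/|]")[[1]]
    as.integer(a[a != "." & nzchar(a) & !is.na(suppressWarnings(as.integer(a)))])
  }))), na.rm = TRUE))
  if (is.finite(max_idx) && max_idx > k) {
    stop("GT allele index ", max_idx, " exceeds number of ALT alleles (", k,
         ") at ", chrom, ":", pos, call. = FALSE)
  }
  lapply(seq_len(k), function(i) {
    list(variant = variant(chrom, pos, ref, alts[i]),
         calls = gt_to_call(gt, i))
  })
}

regions_from_models <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    genomic_interval(m$chrom, m$span[["start"]], m$span[["end"]])
  }))
}

#' Read a panel VCF restricted to candidate-locus regions
#'
#' Replays the screen's interval-intersection stage: only records whose REF
#' span overlaps one of `regions` are retained. Multiallelic records are
#' split into biallelic variants and GT fields are mapped to the four call
#' states (`./.` and half-missing genotypes become `missing`).
#'
#' @param path VCF 4.x file (plain or gzipped); only the GT subfield is used.
#' @param regions data.frame with `chrom`, `start`, `end` columns (1-based
#'   inclusive), e.g. from [regions_from_models()] or [read_bed_regions()].
#' @return A [genotype_matrix()]. Sites-only VCFs yield a zero-accession
#'   matrix with a warning.
#' @export
read_panel_vcf <- function(path, regions) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  if (is.null(regions) || nrow(regions) == 0) {
    stop("regions must be non-empty", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  n <- nrow(fix)
  gt_mat <- NULL
  sites_only <- ncol(vcf@gt) < 2 || is.null(vcf@gt) || nrow(vcf@gt) == 0
  if (!sites_only) {
    gt_mat <- vcfR::extract.gt(vcf, element = "GT")
  } else if (n > 0) {
    warning("sites-only VCF: no accession genotypes in ", path, call. = FALSE)
  }
  out_variants <- list()
  out_calls <- list()
  accs <- if (!is.null(gt_mat)) colnames(gt_mat) else character()
  for (i in seq_len(n)) {
    chrom <- fix[i, "CHROM"]
    pos <- as.integer(fix[i, "POS"])
    ref <- fix[i, "REF"]
    alt <- fix[i, "ALT"]
    if (is.na(alt) || !nzchar(alt)) next
    span_end <- pos + nchar(ref) - 1L
    hit <- any(regions$chrom == chrom & regions$start <= span_end &
               regions$end >= pos)
    if (!hit) next
    gt <- if (!is.null(gt_mat)) gt_mat[i, ] else character()
    for (piece in split_multiallelic(chrom, pos, ref, alt, gt)) {
      out_variants[[length(out_variants) + 1L]] <- piece$variant
      out_calls[[length(out_calls) + 1L]] <- piece$calls
    }
  }
  if (length(out_variants) == 0) {
    return(genotype_matrix(
      matrix(character(), nrow = 0, ncol = length(accs),
             dimnames = list(NULL, accs)),
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), id = character())))
  }
  variants <- do.call(rbind, out_variants)
  calls <- do.call(rbind, out_calls)
  if (length(accs)) colnames(calls) <- accs
  # drop duplicate keys arising from records repeated in the file
  keep <- !duplicated(variants$id)
  genotype_matrix(calls[keep, , drop = FALSE], variants[keep, , drop = FALSE])
}

#' Read regions from a BED file
#'
#' BED's 0-based half-open coordinates are converted to the package's
#' 1-based inclusive convention.
#'
#' @param path BED file (first three columns used).
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_bed_regions <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = as.character(bed[[1]]),
             start = as.integer(bed[[2]]) + 1L,
             end = as.integer(bed[[3]]))
}

#' Normalize a variant (trim + left-align)
#'
#' Shared prefix/suffix bases are trimmed (keeping one anchor base for pure
#' indels) and indels are shifted to their leftmost equivalent position
#' against the reference (VCF-style normalization). Idempotent. The HGVS
#' 3'-rule is deliberately *not* applied here — it belongs to protein-level
#' naming, where the two standards disagree.
#'
#' @param v A one-row variant data.frame (see [variant()]).
#' @param genome Named list/vector of chromosome sequences (character), or a
#'   single unnamed sequence.
#' @return The normalized variant (one-row data.frame).
#' @export
normalize_variant <- function(v, genome) {
  seqs <- resolve_chrom_seq(genome, v$chrom)
  pos <- v$pos
  ref <- v$ref
  alt <- v$alt
  obs <- substr(seqs, pos, pos + nchar(ref) - 1L)
  if (!identical(obs, ref)) {
    stop("REF mismatch at ", v$chrom, ":", pos, ": VCF says '", ref,
         "', reference has '", obs, "'", call. = FALSE)
  }
  last1 <- function(s) substr(s, nchar(s), nchar(s))
  repeat {
    if (nchar(ref) >= 1 && nchar(alt) >= 1 && last1(ref) == last1(alt) &&
        !(nchar(ref) == 1 && nchar(alt) == 1)) {
      if (nchar(ref) == 1 || nchar(alt) == 1) {
        if (pos == 1L) break
        b <- substr(seqs, pos - 1L, pos - 1L)
        ref <- paste0(b, substr(ref, 1, nchar(ref) - 1L))
        alt <- paste0(b, substr(alt, 1, nchar(alt) - 1L))
        pos <- pos - 1L
      } else {
        ref <- substr(ref, 1, nchar(ref) - 1L)
        alt <- substr(alt, 1, nchar(alt) - 1L)
      }
    } else break
  }
  while (nchar(ref) >= 2 && nchar(alt) >= 2 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  variant(v$chrom, pos, ref, alt)
}

resolve_chrom_seq <- function(genome, chrom) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  if (is.list(genome)) genome <- unlist(genome)
  if (is.null(names(genome)) && length(genome) == 1) return(genome[[1]])
  if (!chrom %in% names(genome)) {
    stop("reference lacks chromosome ", chrom, call. = FALSE)
  }
  genome[[chrom]]
}

#' Merge two genotype panels
#'
#' Accessions are unioned; for accessions present in both panels, concordant
#' calls are kept and discordant calls are reconciled per `policy` (default:
#' set to `missing` and logged). Variant keys are unioned; cells absent from
#' a source panel default to `missing` (merged VCFs do not assert reference
#' calls at sites they lack), or `hom_ref` if `absent = "hom_ref"`.
#'
#' @param a,b [genotype_matrix()] objects on normalized variant keys.
#' @param policy One of `"missing"`, `"a_wins"`, `"b_wins"`.
#' @param absent Fill state for variant x accession cells absent from a
#'   source panel: `"missing"` (default) or `"hom_ref"`.
#' @return A merged [genotype_matrix()]; attribute `"conflicts"` holds a
#'   data.frame of discordant (accession, variant) pairs with both calls.
#' @export
merge_panels <- function(a, b, policy = c("missing", "a_wins", "b_wins"),
                         absent = c("missing", "hom_ref")) {
  policy <- match.arg(policy)
  absent <- match.arg(absent)
  variants <- rbind(a$variants, b$variants)
  variants <- variants[!duplicated(variants$id), , drop = FALSE]
  accs <- union(a$accessions, b$accessions)
  fill <- function(m) {
    out <- matrix(absent, nrow = nrow(variants), ncol = length(accs),
                  dimnames = list(variants$id, accs))
    if (nrow(m$calls) && ncol(m$calls)) {
      out[m$variants$id, m$accessions] <- m$calls
    }
    out
  }
  ma <- fill(a)
  mb <- fill(b)
  in_a <- matrix(FALSE, nrow(variants), length(accs),
                 dimnames = list(variants$id, accs))
  in_b <- in_a
  in_a[intersect(variants$id, a$variants$id), intersect(accs, a$accessions)] <- TRUE
  in_b[intersect(variants$id, b$variants$id), intersect(accs, b$accessions)] <- TRUE
  merged <- ma
  merged[!in_a & in_b] <- mb[!in_a & in_b]
  both <- in_a & in_b
  disagree <- both & ma != mb
  if (any(disagree)) {
    idx <- which(disagree, arr.ind = TRUE)
    conflicts <- data.frame(
      accession = accs[idx[, 2]],
      variant = variants$id[idx[, 1]],
      a_call = ma[disagree],
      b_call = mb[disagree],
      stringsAsFactors = FALSE)
    merged[disagree] <- switch(policy,
      missing = "missing",
      a_wins = ma[disagree],
      b_wins = mb[disagree])
  } else {
    conflicts <- data.frame(accession = character(), variant = character(),
                            a_call = character(), b_call = character())
  }
  out <- genotype_matrix(merged, variants)
  attr(out, "conflicts") <- conflicts
  out
}
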