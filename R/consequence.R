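# Amino-acid code tables. Translation uses the standard nuclear code from
# Biostrings; HGVS p. descriptions use 3-letter codes with Ter for stops.
AA_1TO3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
             Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
             L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
             S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
             `*` = "Ter", X = "Xaa")
AA_3TO1 <- structure(names(AA_1TO3), names = unname(AA_1TO3))

aa3 <- function(x) {
  out <- AA_1TO3[x]
  if (any(is.na(out))) stop("unknown amino acid code: ",
                            paste(x[is.na(out)], collapse = ","), call. = FALSE)
  unname(out)
}

revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", x), "",
                       fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

translate_residues <- function(seq) {
  n <- nchar(seq)
  n_codons <- n %/% 3L
  if (n_codons == 0L) {
    return(list(residues = character(), stop_found = FALSE))
  }
  starts <- seq.int(1L, by = 3L, length.out = n_codons)
  codons <- substring(seq, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa)) {
    warning("codon(s) with non-ACGT base translated as 'X'", call. = FALSE)
    aa[is.na(aa)] <- "X"
  }
  stop_at <- which(aa == "*")[1]
  if (!is.na(stop_at)) {
    list(residues = unname(aa[seq_len(stop_at - 1L)]), stop_found = TRUE)
  } else {
    list(residues = unname(aa), stop_found = FALSE)
  }
}

#' Translate a coding sequence
#'
#' Standard nuclear genetic code; translation stops at the first in-frame
#' stop codon. Codons containing non-ACGT bases translate to `X` with a
#' warning.
#'
#' @param seq Coding sequence (character scalar, length >= 3).
#' @return A list with `protein` (residue string, 1-letter codes, stop
#'   excluded) and `stop_found` (FALSE when no in-frame stop exists).
#' @export
translate_cds <- function(seq) {
  if (nchar(seq) < 3) stop("sequence shorter than one codon", call. = FALSE)
  tr <- translate_residues(toupper(seq))
  list(protein = paste(tr$residues, collapse = ""), stop_found = tr$stop_found)
}

#' Apply a CDS-space variant to a coding sequence
#'
#' @param cds Coding sequence (character scalar).
#' @param cds_pos 1-based CDS position of the first REF base.
#' @param ref,alt CDS-projected (strand-adjusted) alleles.
#' @return The mutated coding sequence; length changes by
#'   `nchar(alt) - nchar(ref)`.
#' @export
apply_variant_to_cds <- function(cds, cds_pos, ref, alt) {
  obs <- substr(cds, cds_pos, cds_pos + nchar(ref) - 1L)
  if (!identical(obs, ref)) {
    stop("CDS REF mismatch at position ", cds_pos, ": expected '", ref,
         "', found '", obs, "'", call. = FALSE)
  }
  paste0(substr(cds, 1L, cds_pos - 1L), alt,
         substr(cds, cds_pos + nchar(ref), nchar(cds)))
}

#' Construct a protein-level change description
#'
#' @param kind One of `synonymous`, `missense`, `nonsense`, `frameshift`,
#'   `inframe_del`, `inframe_ins`, `inframe_dup`, `inframe_delins`,
#'   `start_loss`, `stop_loss`.
#' @param pos First affected residue (1-based; the stop codon is residue
#'   `protein_length + 1`).
#' @param ref_aa 3-letter code of the reference residue at `pos`.
#' @param alt_aa Concatenated 3-letter codes of replacement residues
#'   (may be `""`, may end in `"Ter"`).
#' @param pos2,ref_aa2 End of the affected range for range-style changes.
#' @param ter_offset For frameshifts: codon number of the new stop in the
#'   shifted frame, counting the first changed residue as 1 (so `fsTer6`
#'   means the stop is the 6th codon).
#' @param no_stop TRUE when no downstream in-frame stop was found (the
#'   change is then flagged, never silently numbered).
#' @return An object of class `protein_change`.
#' @export
protein_change <- function(kind, pos = NA, ref_aa = NA, alt_aa = "",
                           pos2 = NA, ref_aa2 = NA, ter_offset = NA,
                           no_stop = FALSE) {
  kinds <- c("synonymous", "missense", "nonsense", "frameshift",
             "inframe_del", "inframe_ins", "inframe_dup", "inframe_delins",
             "start_loss", "stop_loss")
  if (!kind %in% kinds) stop("unknown protein change kind: ", kind,
                             call. = FALSE)
  if (!is.na(pos2) && pos2 == pos && kind %in% c("inframe_del", "inframe_dup")) {
    pos2 <- NA
    ref_aa2 <- NA
  }
  if (kind == "frameshift" && !is.na(ter_offset) && ter_offset < 1) {
    stop("frameshift ter_offset must be >= 1", call. = FALSE)
  }
  structure(list(kind = kind, pos = as.integer(pos), ref_aa = ref_aa,
                 alt_aa = alt_aa, pos2 = as.integer(pos2), ref_aa2 = ref_aa2,
                 ter_offset = as.integer(ter_offset), no_stop = no_stop),
            class = "protein_change")
}

#' @export
print.protein_change <- function(x, ...) {
  cat("<protein_change>", format_hgvs_p(x), "\n")
  invisible(x)
}

#' @export
format.protein_change <- function(x, ...) format_hgvs_p(x)

#' Format a protein change as an HGVS p. string
#'
#' Predicted consequences always carry prediction parentheses: `p.(...)`.
#'
#' @param pc A [protein_change()].
#' @return HGVS p. description, e.g. `p.(Lys184Asn)`, `p.(Glu94AspfsTer6)`,
#'   `p.(Gln1174_Arg1175del)`, `p.(His31dup)`.
#' @export
format_hgvs_p <- function(pc) {
  body <- switch(pc$kind,
    synonymous = "=",
    start_loss = "Met1?",
    missense = paste0(pc$ref_aa, pc$pos, pc$alt_aa),
    nonsense = paste0(pc$ref_aa, pc$pos, "Ter"),
    stop_loss = paste0("Ter", pc$pos,
                       if (nzchar(pc$alt_aa)) pc$alt_aa else "Xaa", "extTer?"),
    frameshift = paste0(pc$ref_aa, pc$pos, pc$alt_aa, "fsTer",
                        if (pc$no_stop) "?" else pc$ter_offset),
    inframe_del = paste0(range_part(pc), "del"),
    inframe_dup = paste0(range_part(pc), "dup"),
    inframe_ins = paste0(range_part(pc), "ins", pc$alt_aa),
    inframe_delins = paste0(range_part(pc), "delins", pc$alt_aa),
    stop("cannot format protein change of kind ", pc$kind, call. = FALSE)
  )
  paste0("p.(", body, ")")
}

range_part <- function(pc) {
  if (is.na(pc$pos2)) {
    paste0(pc$ref_aa, pc$pos)
  } else {
    paste0(pc$ref_aa, pc$pos, "_", pc$ref_aa2, pc$pos2)
  }
}

RE_AA <- "(Ter|[A-Z][a-z]{2})"

check_aa3_token <- function(tok, context) {
  bad <- setdiff(tok, unname(AA_1TO3))
  if (length(bad)) {
    stop("unknown amino-acid token '", bad[1], "' in '", context, "'",
         call. = FALSE)
  }
  tok
}

split_aa3 <- function(s, context) {
  if (!nzchar(s)) return(character())
  if (nchar(s) %% 3 != 0) {
    stop("residue run '", s, "' in '", context,
         "' is not a sequence of 3-letter codes", call. = FALSE)
  }
  starts <- seq.int(1L, nchar(s), by = 3L)
  check_aa3_token(substring(s, starts, starts + 2L), context)
}

#' Parse an HGVS p. string
#'
#' Inverse of [format_hgvs_p()] on its image; tolerant of the presence or
#' absence of prediction parentheses (`p.Lys184Asn` and `p.(Lys184Asn)`
#' parse identically).
#'
#' @param s HGVS p. description.
#' @return A [protein_change()].
#' @export
parse_hgvs_p <- function(s) {
  orig <- s
  if (!is.character(s) || length(s) != 1 || !nzchar(s)) {
    stop("HGVS p. input must be a single non-empty string", call. = FALSE)
  }
  s <- sub("^p\\.", "", trimws(s))
  if (startsWith(s, "(") || endsWith(s, ")")) {
    if (!(startsWith(s, "(") && endsWith(s, ")"))) {
      stop("unbalanced parentheses in '", orig, "'", call. = FALSE)
    }
    s <- substr(s, 2, nchar(s) - 1L)
  }
  if (s == "=") return(protein_change("synonymous"))
  if (s == "Met1?" || s == "Met1?") return(protein_change("start_loss", pos = 1L,
                                                          ref_aa = "Met"))
  m <- regmatches(s, regexec(paste0("^Ter([0-9]+)", RE_AA, "extTer([0-9?]*)$"), s))[[1]]
  if (length(m)) {
    return(protein_change("stop_loss", pos = as.integer(m[2]), ref_aa = "Ter",
                          alt_aa = check_aa3_token(m[3], orig)))
  }
  m <- regmatches(s, regexec(paste0("^", RE_AA, "([0-9]+)", RE_AA,
                                    "fsTer([0-9]+|\\?)$"), s))[[1]]
  if (length(m)) {
    no_stop <- m[5] == "?"
    return(protein_change("frameshift", pos = as.integer(m[3]),
                          ref_aa = check_aa3_token(m[2], orig),
                          alt_aa = check_aa3_token(m[4], orig),
                          ter_offset = if (no_stop) NA else as.integer(m[5]),
                          no_stop = no_stop))
  }
  m <- regmatches(s, regexec(paste0("^", RE_AA, "([0-9]+)(_", RE_AA,
                                    "([0-9]+))?(del|dup)(ins([A-Za-z]+))?$"), s))[[1]]
  if (length(m)) {
    has_range <- nzchar(m[4])
    op <- m[7]
    ins_seq <- m[9]
    if (op == "dup" && nzchar(ins_seq)) {
      stop("cannot combine dup with ins in '", orig, "'", call. = FALSE)
    }
    kind <- if (op == "dup") "inframe_dup"
            else if (nzchar(ins_seq)) "inframe_delins" else "inframe_del"
    return(protein_change(kind, pos = as.integer(m[3]),
                          ref_aa = check_aa3_token(m[2], orig),
                          alt_aa = if (nzchar(ins_seq))
                            paste(split_aa3(ins_seq, orig), collapse = "") else "",
                          pos2 = if (has_range) as.integer(m[6]) else NA,
                          ref_aa2 = if (has_range)
                            check_aa3_token(m[5], orig) else NA))
  }
  m <- regmatches(s, regexec(paste0("^", RE_AA, "([0-9]+)_", RE_AA,
                                    "([0-9]+)ins([A-Za-z]+)$"), s))[[1]]
  if (length(m)) {
    return(protein_change("inframe_ins", pos = as.integer(m[3]),
                          ref_aa = check_aa3_token(m[2], orig),
                          alt_aa = paste(split_aa3(m[6], orig), collapse = ""),
                          pos2 = as.integer(m[5]),
                          ref_aa2 = check_aa3_token(m[4], orig)))
  }
  m <- regmatches(s, regexec(paste0("^", RE_AA, "([0-9]+)Ter$"), s))[[1]]
  if (length(m)) {
    return(protein_change("nonsense", pos = as.integer(m[3]),
                          ref_aa = check_aa3_token(m[2], orig),
                          alt_aa = "Ter"))
  }
  m <- regmatches(s, regexec(paste0("^", RE_AA, "([0-9]+)", RE_AA, "$"), s))[[1]]
  if (length(m)) {
    if (m[2] == "Ter") {
      stop("substitution with Ter reference must use extTer form: '", orig,
           "'", call. = FALSE)
    }
    return(protein_change("missense", pos = as.integer(m[3]),
                          ref_aa = check_aa3_token(m[2], orig),
                          alt_aa = check_aa3_token(m[4], orig)))
  }
  stop("cannot parse HGVS p. description '", orig, "'", call. = FALSE)
}

longest_common_prefix <- function(a, b) {
  k <- min(length(a), length(b))
  if (k == 0) return(0L)
  neq <- which(a[seq_len(k)] != b[seq_len(k)])
  if (length(neq)) neq[1] - 1L else k
}

longest_common_suffix <- function(a, b) {
  k <- min(length(a), length(b))
  if (k == 0) return(0L)
  ra <- rev(a)[seq_len(k)]
  rb <- rev(b)[seq_len(k)]
  neq <- which(ra != rb)
  if (length(neq)) neq[1] - 1L else k
}

# Derive a ProteinChange by comparing reference and mutant protein residue
# vectors (1-letter codes, stops excluded). nt_diff is the nucleotide length
# change; stop_found says whether the mutant translation hit an in-frame stop.
# Conventions (documented in the methods vignette):
#   * a change whose mutant protein equals the reference is synonymous;
#   * any change leaving a non-Met first residue is start_loss (p.(Met1?));
#   * a (possibly frameshift) change whose first altered codon is a stop is
#     reported as nonsense p.(Xaa#Ter) -- fsTer1 is never emitted;
#   * a change translating past the reference stop is stop_loss with
#     unevaluated extension length;
#   * in-frame indels use the HGVS 3'-most placement; inserted residues equal
#     to the residues immediately 5' are a duplication.
compare_proteins <- function(P, Q, nt_diff, stop_found) {
  n <- length(P)
  m <- length(Q)
  fs <- (nt_diff %% 3L) != 0L
  if (n == m && (n == 0L || all(P == Q)) && stop_found) {
    return(protein_change("synonymous"))
  }
  k_min <- min(n, m)
  i <- k_min + 1L
  if (k_min > 0) {
    neq <- which(P[seq_len(k_min)] != Q[seq_len(k_min)])
    if (length(neq)) i <- neq[1]
  }
  if (i == 1L && (m == 0L || Q[1] != "M")) {
    return(protein_change("start_loss", pos = 1L, ref_aa = "Met"))
  }
  if (fs) {
    if (m < n && i > m) {
      # shifted frame reproduces the reference until an early stop
      return(protein_change("nonsense", pos = m + 1L,
                            ref_aa = aa3(P[m + 1L]), alt_aa = "Ter"))
    }
    if (m > n && i > n) {
      return(protein_change("stop_loss", pos = n + 1L, ref_aa = "Ter",
                            alt_aa = aa3(Q[n + 1L]), no_stop = !stop_found))
    }
    return(protein_change("frameshift", pos = i, ref_aa = aa3(P[i]),
                          alt_aa = aa3(Q[i]),
                          ter_offset = if (stop_found) m - i + 2L else NA,
                          no_stop = !stop_found))
  }
  if (!stop_found) {
    # in-frame change destroying the stop without creating one downstream
    return(protein_change("stop_loss", pos = n + 1L, ref_aa = "Ter",
                          alt_aa = if (m > n) aa3(Q[n + 1L]) else "",
                          no_stop = TRUE))
  }
  d <- nt_diff %/% 3L
  p_len <- longest_common_prefix(P, Q)
  s_len <- longest_common_suffix(P, Q)
  if (d == 0L && n == m) {
    j <- max(n - s_len, i)
    if (i == j) {
      return(protein_change("missense", pos = i, ref_aa = aa3(P[i]),
                            alt_aa = aa3(Q[i])))
    }
    return(protein_change("inframe_delins", pos = i, ref_aa = aa3(P[i]),
                          pos2 = j, ref_aa2 = aa3(P[j]),
                          alt_aa = paste(aa3(Q[i:j]), collapse = "")))
  }
  if (d < 0L && m == n + d && p_len + s_len >= m) {
    # pure deletion; a = p_len is the 3'-most placement
    k <- -d
    a <- p_len
    del <- (a + 1L):(a + k)
    return(protein_change("inframe_del", pos = del[1], ref_aa = aa3(P[del[1]]),
                          pos2 = del[k], ref_aa2 = aa3(P[del[k]])))
  }
  if (d > 0L && m == n + d && p_len + s_len >= n) {
    # pure insertion; a = p_len is the 3'-most placement
    k <- d
    a <- p_len
    ins <- Q[(a + 1L):(a + k)]
    if (a >= k && all(P[(a - k + 1L):a] == ins)) {
      return(protein_change("inframe_dup", pos = a - k + 1L,
                            ref_aa = aa3(P[a - k + 1L]),
                            pos2 = a, ref_aa2 = aa3(P[a])))
    }
    ref2 <- if (a < n) aa3(P[a + 1L]) else "Ter"
    return(protein_change("inframe_ins", pos = a, ref_aa = aa3(P[a]),
                          pos2 = a + 1L, ref_aa2 = ref2,
                          alt_aa = paste(aa3(ins), collapse = "")))
  }
  if (m < n && i > m) {
    # impure shortening that reproduces the reference until an early stop
    return(protein_change("nonsense", pos = m + 1L, ref_aa = aa3(P[m + 1L]),
                          alt_aa = "Ter"))
  }
  if (m > n && i > n) {
    return(protein_change("stop_loss", pos = n + 1L, ref_aa = "Ter",
                          alt_aa = aa3(Q[n + 1L]), no_stop = !stop_found))
  }
  # general in-frame delins (includes early-truncation cases)
  s_use <- min(s_len, n - i, m - i)
  j2 <- n - s_use
  alt_res <- Q[i:(m - s_use)]
  alt_str <- paste(aa3(alt_res), collapse = "")
  if (m < n + d) alt_str <- paste0(alt_str, "Ter")  # replacement ends in stop
  protein_change("inframe_delins", pos = i, ref_aa = aa3(P[i]),
                 pos2 = j2, ref_aa2 = aa3(P[j2]), alt_aa = alt_str)
}

#' Precompute the sequence context of a gene model
#'
#' Extracts and caches the reference CDS (stop codon included), the
#' transcript sequence downstream of the stop (for numbering frameshift
#' stops that fall past the reference stop codon), and the reference
#' protein. Validates the CDS invariants: length divisible by 3, ATG start,
#' single in-frame stop at the end.
#'
#' @param model A [gene_model()] with exon intervals and CDS boundaries.
#' @param genome Named list/vector of chromosome sequences.
#' @return A list with `cds`, `utr3`, `protein` (1-letter residue vector)
#'   and `n_res`.
#' @export
model_context <- function(model, genome) {
  stop_no_exons(model)
  chromseq <- resolve_chrom_seq(genome, model$chrom)
  ce <- coding_exons(model)
  cds_plus <- paste(substring(chromseq, ce$start, ce$end), collapse = "")
  cds <- if (model$strand == "+") cds_plus else revcomp(cds_plus)
  if (nchar(cds) %% 3L != 0L) {
    stop("gene ", model$gene_id, ": CDS length not divisible by 3",
         call. = FALSE)
  }
  ex <- model$exons
  if (model$strand == "+") {
    lo <- pmax(ex$start, model$cds_end + 1L)
    hi <- ex$end
    keep <- lo <= hi
    utr3 <- paste(substring(chromseq, lo[keep], hi[keep]), collapse = "")
  } else {
    lo <- ex$start
    hi <- pmin(ex$end, model$cds_start - 1L)
    keep <- lo <= hi
    utr3 <- revcomp(paste(substring(chromseq, lo[keep], hi[keep]),
                          collapse = ""))
  }
  tr <- translate_residues(cds)
  if (!tr$stop_found || length(tr$residues) != nchar(cds) / 3 - 1) {
    stop("gene ", model$gene_id,
         ": CDS does not end in a single in-frame stop codon", call. = FALSE)
  }
  list(cds = cds, utr3 = utr3, protein = tr$residues,
       n_res = length(tr$residues))
}

#' Predict the protein-level consequence of a normalized variant
#'
#' Coding variants are applied to the reference CDS, both proteins are
#' translated (the mutant past the reference stop into the 3' transcript
#' where needed), and the change is derived by protein-string comparison
#' with the HGVS 3'-most placement rule. Intronic variants receive splice
#' labels from [classify_position()]; variants touching a splice consensus
#' dinucleotide or spanning an exon/intron junction get a
#' `splice_disrupting` label and no protein prediction (the transcript
#' outcome is unknowable without a splicing model).
#'
#' @param model A [gene_model()] with exon intervals and CDS boundaries.
#' @param genome Named list/vector of chromosome sequences.
#' @param v A normalized one-row variant data.frame (see
#'   [normalize_variant()]).
#' @param ctx Optional precomputed [model_context()] (for repeated calls).
#' @return An object of class `consequence_record`: a list with
#'   `variant_id`, `gene_id`, `region`, `annotation`, `protein_change`
#'   (NULL for non-coding effects) and `hgvs_p` (NA for non-coding effects).
#' @export
predict_consequence <- function(model, genome, v, ctx = NULL) {
  stop_no_exons(model)
  if (v$chrom != model$chrom || v$pos + nchar(v$ref) - 1L < model$span[["start"]] ||
      v$pos > model$span[["end"]]) {
    stop("variant ", v$id, " does not overlap gene ", model$gene_id,
         call. = FALSE)
  }
  chromseq <- resolve_chrom_seq(genome, model$chrom)
  obs <- substr(chromseq, v$pos, v$pos + nchar(v$ref) - 1L)
  if (!identical(obs, v$ref)) {
    stop("REF mismatch at ", v$chrom, ":", v$pos, ": variant says '", v$ref,
         "', reference has '", obs, "'", call. = FALSE)
  }
  has_anchor <- (nchar(v$ref) > 1L || nchar(v$alt) > 1L) &&
    substr(v$ref, 1, 1) == substr(v$alt, 1, 1)
  if (has_anchor) {
    a <- v$pos + 1L
    b <- v$pos + nchar(v$ref) - 1L
    ins_seq <- substr(v$alt, 2, nchar(v$alt))
  } else {
    a <- v$pos
    b <- v$pos + nchar(v$ref) - 1L
    ins_seq <- v$alt
  }
  pure_insertion <- b < a
  points <- if (pure_insertion) c(v$pos, v$pos + 1L) else a:b
  anns <- lapply(points, function(p) classify_position(model, p))
  regions <- vapply(anns, `[[`, character(1), "region")
  if (any(regions == "intergenic")) {
    stop("variant ", v$id, " extends outside the span of gene ",
         model$gene_id, call. = FALSE)
  }
  first_ann <- anns[[1]]
  rec <- function(region, pc = NULL) {
    structure(list(variant_id = v$id, gene_id = model$gene_id,
                   region = region, annotation = first_ann,
                   protein_change = pc,
                   hgvs_p = if (is.null(pc)) NA_character_
                            else format_hgvs_p(pc)),
              class = "consequence_record")
  }
  intronic <- c("intron", "splice_region", "splice_donor", "splice_acceptor")
  if (any(regions %in% c("splice_donor", "splice_acceptor"))) {
    return(rec("splice_disrupting"))
  }
  exonic <- regions %in% c("cds", "utr5", "utr3")
  if (any(exonic) && any(regions %in% intronic)) {
    return(rec("splice_disrupting"))
  }
  if (all(regions %in% intronic)) {
    if (pure_insertion) {
      # an insertion between two intronic bases: report the more
      # splice-proximal of the two flanking labels
      sev <- c(splice_region = 2L, intron = 1L)
      region <- names(which.max(sev[regions]))
    } else {
      region <- if (any(regions == "splice_region")) "splice_region" else "intron"
    }
    return(rec(region))
  }
  if (all(regions == "utr5")) return(rec("utr5"))
  if (all(regions == "utr3")) return(rec("utr3"))
  if (pure_insertion && any(regions == "utr5")) return(rec("utr5"))
  if (pure_insertion && any(regions == "utr3")) return(rec("utr3"))
  if (is.null(ctx)) ctx <- model_context(model, genome)
  if (any(regions == "utr5")) {
    # deletion/delins crossing the CDS 5' boundary disrupts the start codon
    return(rec("cds", protein_change("start_loss", pos = 1L, ref_aa = "Met")))
  }
  if (any(regions == "utr3")) {
    # crossing the CDS 3' boundary removes the stop codon
    return(rec("cds", protein_change("stop_loss", pos = ctx$n_res + 1L,
                                     ref_aa = "Ter", alt_aa = "")))
  }
  # fully coding
  cds <- ctx$cds
  n_cds <- nchar(cds)
  s_cds <- if (model$strand == "+") ins_seq else revcomp(ins_seq)
  if (pure_insertion) {
    c1 <- genomic_to_cds(model, v$pos)
    c2 <- genomic_to_cds(model, v$pos + 1L)
    if (abs(c1 - c2) != 1L) {
      return(rec("splice_disrupting"))
    }
    insert_after <- min(c1, c2)
    mutant <- paste0(substr(cds, 1L, insert_after), s_cds,
                     substr(cds, insert_after + 1L, n_cds))
    first_cds_pos <- insert_after
  } else {
    c1 <- genomic_to_cds(model, a)
    c2 <- genomic_to_cds(model, b)
    clo <- min(c1, c2)
    chi <- max(c1, c2)
    if (chi - clo != b - a) {
      return(rec("splice_disrupting"))
    }
    mutant <- paste0(substr(cds, 1L, clo - 1L), s_cds,
                     substr(cds, chi + 1L, n_cds))
    first_cds_pos <- clo
  }
  nt_diff <- nchar(v$alt) - nchar(v$ref)
  mut_tr <- translate_residues(paste0(mutant, ctx$utr3))
  pc <- compare_proteins(ctx$protein, mut_tr$residues, nt_diff,
                         mut_tr$stop_found)
  ann <- first_ann
  ann$cds_position <- first_cds_pos
  out <- rec("cds", pc)
  out$annotation <- ann
  out
}

#' Decide whether an in-frame insertion is a duplication
#'
#' Applies the HGVS 3'-most placement rule, then reports `inframe_dup` when
#' the inserted residue(s) equal the residue(s) immediately 5' of the
#' (shifted) insertion point, else `inframe_ins`.
#'
#' @param cds Reference coding sequence.
#' @param inserted Inserted bases (length divisible by 3).
#' @param cds_pos_after CDS position after which the bases are inserted.
#' @return A [protein_change()] of kind `inframe_dup` or `inframe_ins`
#'   (or whatever the change reduces to, e.g. `inframe_delins` when the
#'   insertion interrupts a codon and changes flanking residues).
#' @export
detect_duplication <- function(cds, inserted, cds_pos_after) {
  if (nchar(inserted) %% 3 != 0) {
    stop("inserted length must be divisible by 3", call. = FALSE)
  }
  mutant <- paste0(substr(cds, 1L, cds_pos_after), inserted,
                   substr(cds, cds_pos_after + 1L, nchar(cds)))
  ref_tr <- translate_residues(cds)
  mut_tr <- translate_residues(mutant)
  compare_proteins(ref_tr$residues, mut_tr$residues, nchar(inserted),
                   mut_tr$stop_found)
}

#' Flatten consequence records into a table
#'
#' @param records List of `consequence_record` objects.
#' @return data.frame with columns `variant_id`, `gene_id`, `region`,
#'   `kind`, `hgvs_p`, `protein_position`, `ter_offset`.
#' @export
consequence_table <- function(records) {
  do.call(rbind, c(list(data.frame(
    variant_id = character(), gene_id = character(), region = character(),
    kind = character(), hgvs_p = character(), protein_position = integer(),
    ter_offset = integer(), stringsAsFactors = FALSE)),
    lapply(records, function(r) {
      pc <- r$protein_change
      data.frame(variant_id = r$variant_id, gene_id = r$gene_id,
                 region = r$region,
                 kind = if (is.null(pc)) r$region else pc$kind,
                 hgvs_p = r$hgvs_p,
                 protein_position = if (is.null(pc)) NA_integer_ else pc$pos,
                 ter_offset = if (is.null(pc)) NA_integer_ else pc$ter_offset,
                 stringsAsFactors = FALSE)
    })))
}
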