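# Independent brute-force oracle for protein-consequence prediction.
#
# Mechanics are deliberately different from the package implementation:
# the variant is applied to the *chromosome* sequence, exon and CDS
# coordinates are re-derived by shifting, the mutant CDS is re-extracted
# and translated codon-by-codon with a local loop, and in-frame indel
# placement is found by enumerating every equivalent placement (taking the
# 3'-most) rather than by prefix/suffix arithmetic. Only the translation
# table is shared.

oracle_translate <- function(seq) {
  tab <- Biostrings::GENETIC_CODE
  out <- character()
  i <- 1L
  stop_found <- FALSE
  while (i + 2L <= nchar(seq)) {
    codon <- substr(seq, i, i + 2L)
    aa <- if (codon %in% names(tab)) tab[[codon]] else "X"
    if (aa == "*") {
      stop_found <- TRUE
      break
    }
    out <- c(out, aa)
    i <- i + 3L
  }
  list(residues = out, stop_found = stop_found)
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Extract the coding-orientation CDS + downstream transcript sequence from
# a chromosome sequence given exon intervals and CDS bounds.
oracle_extract <- function(chromseq, exons, cds_start, cds_end, strand) {
  ce_lo <- pmax(exons$start, cds_start)
  ce_hi <- pmin(exons$end, cds_end)
  keep <- ce_lo <= ce_hi
  cds_plus <- paste(substring(chromseq, ce_lo[keep], ce_hi[keep]),
                    collapse = "")
  if (strand == "+") {
    u_lo <- pmax(exons$start, cds_end + 1L)
    u_hi <- exons$end
    keep <- u_lo <= u_hi
    down <- paste(substring(chromseq, u_lo[keep], u_hi[keep]), collapse = "")
    list(cds = cds_plus, down = down)
  } else {
    u_lo <- exons$start
    u_hi <- pmin(exons$end, cds_start - 1L)
    keep <- u_lo <= u_hi
    down <- oracle_revcomp(paste(substring(chromseq, u_lo[keep], u_hi[keep]),
                                 collapse = ""))
    list(cds = oracle_revcomp(cds_plus), down = down)
  }
}

# Canonical comparison by enumeration; must realize the same conventions
# the package documents (3'-most placement, fsTer1 -> nonsense, Met1?,
# extTer? for lost stops).
oracle_compare <- function(P, Q, nt_diff, stop_found) {
  n <- length(P)
  m <- length(Q)
  fs <- (nt_diff %% 3L) != 0L
  if (n == m && all(P == Q) && stop_found) {
    return(protein_change("synonymous"))
  }
  i <- 1L
  while (i <= min(n, m) && P[i] == Q[i]) i <- i + 1L
  if (i == 1L && (m == 0L || Q[1] != "M")) {
    return(protein_change("start_loss", pos = 1L, ref_aa = "Met"))
  }
  if (fs) {
    if (m < n && i > m) {
      return(protein_change("nonsense", pos = m + 1L,
                            ref_aa = unname(AA_1TO3[P[m + 1L]]),
                            alt_aa = "Ter"))
    }
    if (m > n && i > n) {
      return(protein_change("stop_loss", pos = n + 1L, ref_aa = "Ter",
                            alt_aa = unname(AA_1TO3[Q[n + 1L]]),
                            no_stop = !stop_found))
    }
    return(protein_change("frameshift", pos = i,
                          ref_aa = unname(AA_1TO3[P[i]]),
                          alt_aa = unname(AA_1TO3[Q[i]]),
                          ter_offset = if (stop_found) m - i + 2L else NA,
                          no_stop = !stop_found))
  }
  if (!stop_found) {
    return(protein_change("stop_loss", pos = n + 1L, ref_aa = "Ter",
                          alt_aa = if (m > n) unname(AA_1TO3[Q[n + 1L]])
                                   else "",
                          no_stop = TRUE))
  }
  d <- nt_diff %/% 3L
  aa3v <- function(x) paste(unname(AA_1TO3[x]), collapse = "")
  if (d == 0L && n == m) {
    j <- n
    while (j > i && P[j] == Q[j]) j <- j - 1L
    if (i == j) {
      return(protein_change("missense", pos = i,
                            ref_aa = unname(AA_1TO3[P[i]]),
                            alt_aa = unname(AA_1TO3[Q[i]])))
    }
    return(protein_change("inframe_delins", pos = i,
                          ref_aa = unname(AA_1TO3[P[i]]), pos2 = j,
                          ref_aa2 = unname(AA_1TO3[P[j]]),
                          alt_aa = aa3v(Q[i:j])))
  }
  if (d < 0L && m == n + d) {
    k <- -d
    # enumerate every deletion placement, keep the 3'-most
    best <- -1L
    for (a in 0:(n - k)) {
      if (identical(c(P[seq_len(a)], P[seq_len(n - a - k) + a + k]), Q)) {
        best <- a
      }
    }
    if (best >= 0L) {
      del <- (best + 1L):(best + k)
      return(protein_change("inframe_del", pos = del[1],
                            ref_aa = unname(AA_1TO3[P[del[1]]]),
                            pos2 = del[k],
                            ref_aa2 = unname(AA_1TO3[P[del[k]]])))
    }
  }
  if (d > 0L && m == n + d) {
    k <- d
    best <- -1L
    for (a in 0:n) {
      ins <- Q[a + seq_len(k)]
      if (identical(c(P[seq_len(a)], ins, P[seq_len(n - a) + a]), Q)) {
        best <- a
      }
    }
    if (best >= 0L) {
      a <- best
      ins <- Q[a + seq_len(k)]
      if (a >= k && identical(P[(a - k + 1L):a], ins)) {
        return(protein_change("inframe_dup", pos = a - k + 1L,
                              ref_aa = unname(AA_1TO3[P[a - k + 1L]]),
                              pos2 = a, ref_aa2 = unname(AA_1TO3[P[a]])))
      }
      return(protein_change("inframe_ins", pos = a,
                            ref_aa = unname(AA_1TO3[P[a]]), pos2 = a + 1L,
                            ref_aa2 = if (a < n) unname(AA_1TO3[P[a + 1L]])
                                      else "Ter",
                            alt_aa = aa3v(ins)))
    }
  }
  if (m < n && i > m) {
    return(protein_change("nonsense", pos = m + 1L,
                          ref_aa = unname(AA_1TO3[P[m + 1L]]),
                          alt_aa = "Ter"))
  }
  if (m > n && i > n) {
    return(protein_change("stop_loss", pos = n + 1L, ref_aa = "Ter",
                          alt_aa = unname(AA_1TO3[Q[n + 1L]]),
                          no_stop = !stop_found))
  }
  # general delins: widest-suffix alignment by scanning from the ends
  s_use <- 0L
  while (s_use < min(n - i, m - i) &&
         P[n - s_use] == Q[m - s_use]) s_use <- s_use + 1L
  j2 <- n - s_use
  alt_res <- if (m - s_use >= i) Q[i:(m - s_use)] else character()
  alt_str <- aa3v(alt_res)
  if (m < n + d) alt_str <- paste0(alt_str, "Ter")
  protein_change("inframe_delins", pos = i, ref_aa = unname(AA_1TO3[P[i]]),
                 pos2 = j2, ref_aa2 = unname(AA_1TO3[P[j2]]),
                 alt_aa = alt_str)
}

# Full oracle path: mutate the chromosome, shift coordinates, re-extract,
# translate, compare. Valid for normalized variants whose changed bases
# (and anchor) lie within a single coding exon.
oracle_consequence <- function(model, genome, v) {
  chromseq <- sorgscreen:::resolve_chrom_seq(genome, model$chrom)
  mutseq <- paste0(substr(chromseq, 1L, v$pos - 1L), v$alt,
                   substr(chromseq, v$pos + nchar(v$ref), nchar(chromseq)))
  d <- nchar(v$alt) - nchar(v$ref)
  vend <- v$pos + nchar(v$ref) - 1L
  shift <- function(p) ifelse(p > vend, p + d, p)
  ex2 <- data.frame(start = shift(model$exons$start),
                    end = shift(model$exons$end))
  ref_x <- oracle_extract(chromseq, model$exons, model$cds_start,
                          model$cds_end, model$strand)
  mut_x <- oracle_extract(mutseq, ex2, shift(model$cds_start),
                          shift(model$cds_end), model$strand)
  P <- oracle_translate(ref_x$cds)
  Q <- oracle_translate(paste0(mut_x$cds, mut_x$down))
  oracle_compare(P$residues, Q$residues, d, Q$stop_found)
}

# Random coding variant on a model, rejected until its normalized form sits
# entirely within one coding exon (the oracle's validity domain).
random_coding_variant <- function(model, genome, max_tries = 60L) {
  chromseq <- sorgscreen:::resolve_chrom_seq(genome, model$chrom)
  ce <- sorgscreen:::coding_exons(model)
  for (try in seq_len(max_tries)) {
    e <- sample.int(nrow(ce), 1L)
    lo <- ce$start[e]
    hi <- ce$end[e]
    type <- sample(c("snp", "mnp", "ins", "del"), 1L,
                   prob = c(0.5, 0.1, 0.2, 0.2))
    v <- tryCatch({
      if (type == "snp") {
        p <- sample(lo:hi, 1L)
        ref <- substr(chromseq, p, p)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        variant(model$chrom, p, ref, alt)
      } else if (type == "mnp") {
        w <- sample(2:3, 1L)
        if (hi - lo + 1L < w) next
        p <- sample(lo:(hi - w + 1L), 1L)
        ref <- substr(chromseq, p, p + w - 1L)
        alt <- paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                     collapse = "")
        if (alt == ref) next
        variant(model$chrom, p, ref, alt)
      } else if (type == "ins") {
        p <- sample((lo + 1L):(hi - 1L), 1L)
        anchor <- substr(chromseq, p, p)
        ins <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1L),
                            replace = TRUE), collapse = "")
        variant(model$chrom, p, anchor, paste0(anchor, ins))
      } else {
        w <- sample(1:6, 1L)
        if (hi - lo < w + 2L) next
        p <- sample((lo + 1L):(hi - w), 1L)
        anchor <- substr(chromseq, p - 1L, p - 1L)
        ref <- substr(chromseq, p - 1L, p + w - 1L)
        variant(model$chrom, p - 1L, ref, anchor)
      }
    }, error = function(err) NULL)
    if (is.null(v)) next
    v <- normalize_variant(v, genome)
    # validity: changed bases and anchor inside one coding exon
    has_anchor <- (nchar(v$ref) > 1L || nchar(v$alt) > 1L) &&
      substr(v$ref, 1, 1) == substr(v$alt, 1, 1)
    a <- if (has_anchor) v$pos + 1L else v$pos
    b <- v$pos + nchar(v$ref) - 1L
    pts <- unique(c(v$pos, if (b >= a) a:b else c(v$pos, v$pos + 1L)))
    e_hit <- which(ce$start <= min(pts) & max(pts) <= ce$end)
    if (length(e_hit) == 1L) return(v)
  }
  NULL
}

pc_equal <- function(a, b) {
  identical(format_hgvs_p(a), format_hgvs_p(b)) &&
    identical(a$kind, b$kind) &&
    identical(a$no_stop, b$no_stop) &&
    identical(is.na(a$ter_offset), is.na(b$ter_offset)) &&
    (is.na(a$ter_offset) || a$ter_offset == b$ter_offset)
}
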