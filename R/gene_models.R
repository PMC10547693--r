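#' Construct a genomic interval
#'
#' Intervals are 1-based and inclusive at both ends throughout the package
#' (GFF3/VCF convention); no half-open coordinates are used anywhere.
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @return A one-row data.frame with columns `chrom`, `start`, `end`.
#' @export
genomic_interval <- function(chrom, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end) {
    stop("invalid interval: ", chrom, ":", start, "-", end, call. = FALSE)
  }
  data.frame(chrom = as.character(chrom), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Construct a gene model
#'
#' A gene model holds a locus's genomic span, strand, exon structure and CDS
#' geometry. `cds_start`/`cds_end` are genomic positions of the coding-region
#' boundaries (stop codon included, so CDS length = 3 * (protein_length + 1)
#' when a sequence is attached). Exon intervals may be `NULL` for
#' metadata-only models (e.g. the packed locus table), in which case
#' sequence-level operations are unavailable.
#'
#' @param gene_id Primary identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param span_start,span_end Genomic span (1-based inclusive).
#' @param exons `NULL`, or a data.frame with `start`, `end` columns, sorted
#'   ascending, pairwise non-overlapping, all within the span.
#' @param cds_start,cds_end Genomic CDS boundaries (`NA` when unavailable).
#' @param synonyms Character vector of alternative identifiers.
#' @param transcript_length,protein_length,exon_count Annotation metadata.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, span_start, span_end,
                       exons = NULL, cds_start = NA, cds_end = NA,
                       synonyms = character(), transcript_length = NA,
                       protein_length = NA, exon_count = NA) {
  if (!strand %in% c("+", "-")) {
    stop("gene ", gene_id, ": strand must be '+' or '-', got '", strand, "'",
         call. = FALSE)
  }
  span_start <- as.integer(span_start)
  span_end <- as.integer(span_end)
  if (is.na(span_start) || is.na(span_end) || span_start < 1L ||
      span_start > span_end) {
    stop("gene ", gene_id, ": malformed span coordinates", call. = FALSE)
  }
  if (!is.null(exons)) {
    exons <- data.frame(start = as.integer(exons$start),
                        end = as.integer(exons$end))
    exons <- exons[order(exons$start), , drop = FALSE]
    rownames(exons) <- NULL
    if (any(exons$start > exons$end)) {
      stop("gene ", gene_id, ": exon with start > end", call. = FALSE)
    }
    if (nrow(exons) > 1 &&
        any(exons$start[-1] <= exons$end[-nrow(exons)])) {
      stop("gene ", gene_id, ": overlapping exons", call. = FALSE)
    }
    if (exons$start[1] < span_start || exons$end[nrow(exons)] > span_end) {
      stop("gene ", gene_id, ": exon outside gene span", call. = FALSE)
    }
    if (is.na(exon_count)) exon_count <- nrow(exons)
    if (exon_count != nrow(exons)) {
      stop("gene ", gene_id, ": exon_count disagrees with exon intervals",
           call. = FALSE)
    }
  }
  structure(list(
    gene_id = gene_id,
    synonyms = as.character(synonyms),
    chrom = as.character(chrom),
    strand = strand,
    span = c(start = span_start, end = span_end),
    exons = exons,
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_end),
    transcript_length = as.integer(transcript_length),
    protein_length = as.integer(protein_length),
    exon_count = as.integer(exon_count)
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%s-%s (%s)  exons: %s  protein: %s aa\n",
              x$gene_id, x$chrom,
              format(x$span[["start"]], big.mark = ","),
              format(x$span[["end"]], big.mark = ","),
              x$strand,
              ifelse(is.na(x$exon_count), "?", x$exon_count),
              ifelse(is.na(x$protein_length), "?", x$protein_length)))
  invisible(x)
}

has_exons <- function(model) !is.null(model$exons)

stop_no_exons <- function(model) {
  if (!has_exons(model)) {
    stop("gene ", model$gene_id, ": exon intervals unavailable ",
         "(metadata-only model); supply GFF3 + FASTA for sequence-level work",
         call. = FALSE)
  }
}

# Exonic sub-intervals restricted to [cds_start, cds_end], ascending genomic order.
coding_exons <- function(model) {
  stop_no_exons(model)
  if (is.na(model$cds_start) || is.na(model$cds_end)) {
    stop("gene ", model$gene_id, ": CDS boundaries unavailable", call. = FALSE)
  }
  ex <- model$exons
  lo <- pmax(ex$start, model$cds_start)
  hi <- pmin(ex$end, model$cds_end)
  keep <- lo <= hi
  data.frame(start = lo[keep], end = hi[keep])
}

# Intron intervals in ascending genomic order (empty for single-exon genes).
introns_of <- function(model) {
  stop_no_exons(model)
  ex <- model$exons
  if (nrow(ex) < 2) return(data.frame(start = integer(), end = integer()))
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
}

cds_length <- function(model) {
  ce <- coding_exons(model)
  sum(ce$end - ce$start + 1L)
}

#' Map a genomic position to a CDS coordinate
#'
#' On the `+` strand the CDS coordinate counts coding bases from `cds_start`
#' through `pos`; on the `-` strand it is counted from `cds_end` downward
#' (reverse-complement orientation). The stop codon is part of the CDS.
#'
#' @param model A [gene_model()] with exon intervals and CDS boundaries.
#' @param pos Genomic position.
#' @return 1-based CDS coordinate.
#' @seealso [cds_to_genomic()], [cds_to_protein()]
#' @export
genomic_to_cds <- function(model, pos) {
  ce <- coding_exons(model)
  pos <- as.integer(pos)
  inside <- which(ce$start <= pos & pos <= ce$end)
  if (length(inside) != 1) {
    stop("position ", pos, " is not a coding base of gene ", model$gene_id,
         call. = FALSE)
  }
  widths <- ce$end - ce$start + 1L
  before <- if (inside > 1) sum(widths[seq_len(inside - 1)]) else 0L
  plus_coord <- before + (pos - ce$start[inside] + 1L)
  if (model$strand == "+") plus_coord else sum(widths) - plus_coord + 1L
}

#' Map a CDS coordinate back to a genomic position
#'
#' Inverse of [genomic_to_cds()].
#'
#' @inheritParams genomic_to_cds
#' @param cds_pos 1-based CDS coordinate.
#' @return Genomic position.
#' @export
cds_to_genomic <- function(model, cds_pos) {
  ce <- coding_exons(model)
  cds_pos <- as.integer(cds_pos)
  total <- sum(ce$end - ce$start + 1L)
  if (is.na(cds_pos) || cds_pos < 1L || cds_pos > total) {
    stop("CDS position ", cds_pos, " outside [1, ", total, "]", call. = FALSE)
  }
  plus_coord <- if (model$strand == "+") cds_pos else total - cds_pos + 1L
  widths <- ce$end - ce$start + 1L
  cum <- cumsum(widths)
  i <- which(plus_coord <= cum)[1]
  offset_in_exon <- plus_coord - (if (i > 1) cum[i - 1] else 0L)
  ce$start[i] + offset_in_exon - 1L
}

#' Map a CDS coordinate to protein residue and within-codon offset
#'
#' @param cds_pos 1-based CDS coordinate.
#' @return A list with `residue` (= `ceiling(cds_pos / 3)`) and `offset`
#'   (1, 2 or 3 within the codon).
#' @export
cds_to_protein <- function(cds_pos) {
  cds_pos <- as.integer(cds_pos)
  if (any(is.na(cds_pos)) || any(cds_pos < 1L)) {
    stop("CDS position must be >= 1", call. = FALSE)
  }
  list(residue = as.integer(ceiling(cds_pos / 3)),
       offset = as.integer((cds_pos - 1L) %% 3L + 1L))
}

# Splice windows, in intron-offset coordinates on the coding strand.
# Donor side (+k = k bases from the intron 5' end): +1,+2 consensus GT;
# +3..+5 splice region. Acceptor side (-k = k bases from the intron 3' end):
# -1,-2 consensus AG; -3..-10 splice region. Donor-side classification takes
# precedence over acceptor-side on overlap in short introns.
SPLICE_DONOR_OFFSETS <- 1:2
SPLICE_ACCEPTOR_OFFSETS <- -(1:2)
SPLICE_REGION_DONOR_OFFSETS <- 3:5
SPLICE_REGION_ACCEPTOR_OFFSETS <- -(3:10)

#' Classify a genomic position relative to a gene model
#'
#' Partitions positions into `cds`, `utr5`, `utr3`, `intron`, `splice_donor`
#' (intron offsets +1, +2), `splice_acceptor` (-1, -2), `splice_region`
#' (+3..+5 from the intron 5' end and -3..-10 from the intron 3' end, the
#' windows in which non-consensus splice variants are flagged) and
#' `intergenic`. Intron offsets are defined on the coding strand: the donor
#' side is the intron 5' end of the mRNA, which is the highest genomic
#' coordinate for a `-` strand gene.
#'
#' @inheritParams genomic_to_cds
#' @param pos Genomic position.
#' @return A list with `region`, and when applicable `exon_index`,
#'   `intron_index` (1-based, in transcription order), `intron_offset`
#'   (signed) and `cds_position`.
#' @export
classify_position <- function(model, pos) {
  stop_no_exons(model)
  pos <- as.integer(pos)
  ann <- list(region = "intergenic", exon_index = NA_integer_,
              intron_index = NA_integer_, intron_offset = NA_integer_,
              cds_position = NA_integer_)
  if (pos < model$span[["start"]] || pos > model$span[["end"]]) {
    return(ann)
  }
  ex <- model$exons
  n_ex <- nrow(ex)
  exon_i <- which(ex$start <= pos & pos <= ex$end)
  if (length(exon_i) == 1) {
    # transcription-order exon index
    ann$exon_index <- if (model$strand == "+") exon_i else n_ex - exon_i + 1L
    if (!is.na(model$cds_start) && pos >= model$cds_start &&
        pos <= model$cds_end) {
      ann$region <- "cds"
      ann$cds_position <- genomic_to_cds(model, pos)
    } else if (is.na(model$cds_start)) {
      ann$region <- "cds"  # no UTR annotated: exonic implies coding
      ann$cds_position <- NA_integer_
    } else {
      before_cds <- pos < model$cds_start
      ann$region <- if ((before_cds && model$strand == "+") ||
                        (!before_cds && model$strand == "-")) "utr5" else "utr3"
    }
    return(ann)
  }
  intr <- introns_of(model)
  intron_i <- which(intr$start <= pos & pos <= intr$end)
  if (length(intron_i) != 1) {
    return(ann)  # in span but neither exon nor intron cannot happen; guard
  }
  istart <- intr$start[intron_i]
  iend <- intr$end[intron_i]
  if (model$strand == "+") {
    off_donor <- pos - istart + 1L
    off_acceptor <- -(iend - pos + 1L)
    ann$intron_index <- intron_i
  } else {
    off_donor <- iend - pos + 1L
    off_acceptor <- -(pos - istart + 1L)
    ann$intron_index <- nrow(intr) - intron_i + 1L
  }
  if (off_donor %in% SPLICE_DONOR_OFFSETS) {
    ann$region <- "splice_donor"
    ann$intron_offset <- off_donor
  } else if (off_donor %in% SPLICE_REGION_DONOR_OFFSETS) {
    ann$region <- "splice_region"
    ann$intron_offset <- off_donor
  } else if (off_acceptor %in% SPLICE_ACCEPTOR_OFFSETS) {
    ann$region <- "splice_acceptor"
    ann$intron_offset <- off_acceptor
  } else if (off_acceptor %in% SPLICE_REGION_ACCEPTOR_OFFSETS) {
    ann$region <- "splice_region"
    ann$intron_offset <- off_acceptor
  } else {
    ann$region <- "intron"
    # report the nearer end's offset
    ann$intron_offset <- if (abs(off_donor) <= abs(off_acceptor))
      off_donor else off_acceptor
  }
  ann
}

#' Load gene models from GFF3 or the packaged TSV dialect
#'
#' GFF3 input uses `gene`/`mRNA`/`exon`/`CDS` features with `ID`/`Parent`
#' attributes; only primary transcripts are modeled (the first mRNA of each
#' gene in file order). The TSV dialect carries locus metadata only
#' (columns `gene_id`, `synonyms`, `chrom`, `strand`, `span_start`,
#' `span_end`, `transcript_length`, `protein_length`, `exon_count`) and
#' yields metadata-only models without exon intervals.
#'
#' @param path Path to a `.gff3`/`.gff` or `.tsv` file.
#' @return A named list of [gene_model()] objects.
#' @export
load_gene_models <- function(path) {
  if (!file.exists(path)) stop("gene model file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("gff", "gff3")) {
    load_gene_models_gff3(path)
  } else {
    load_gene_models_tsv(path)
  }
}

load_gene_models_gff3 <- function(path) {
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines == 0) return(structure(list(), names = character()))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(structure(list(), names = character()))
  df$type <- as.character(df$type)
  df$strand <- as.character(df$strand)
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  models <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    gid <- g$ID
    if (!g$strand %in% c("+", "-")) {
      stop("record ", gid, ": strand '", g$strand,
           "' is not '+' or '-'", call. = FALSE)
    }
    tx <- mrnas[vapply(mrnas$Parent, function(p) gid %in% p, logical(1)), ,
                drop = FALSE]
    if (nrow(tx) == 0) next
    tx <- tx[1, ]  # primary transcript only
    kids <- df[vapply(df$Parent, function(p) tx$ID %in% p, logical(1)), ,
               drop = FALSE]
    ex <- kids[kids$type == "exon", c("start", "end"), drop = FALSE]
    cds <- kids[kids$type == "CDS", c("start", "end"), drop = FALSE]
    if (nrow(ex) == 0) {
      stop("record ", gid, ": mRNA without exon features", call. = FALSE)
    }
    models[[gid]] <- gene_model(
      gene_id = gid, chrom = as.character(g$seqnames), strand = g$strand,
      span_start = g$start, span_end = g$end, exons = ex,
      cds_start = if (nrow(cds)) min(cds$start) else NA,
      cds_end = if (nrow(cds)) max(cds$end) else NA,
      transcript_length = sum(ex$end - ex$start + 1L)
    )
  }
  models
}

load_gene_models_tsv <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) return(structure(list(), names = character()))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene_id", "chrom", "strand", "span_start", "span_end")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("gene model TSV lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  models <- list()
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (!r$strand %in% c("+", "-")) {
      stop("record ", r$gene_id, ": strand '", r$strand,
           "' is not '+' or '-'", call. = FALSE)
    }
    syn <- if ("synonyms" %in% names(tab) && nzchar(r$synonyms))
      strsplit(r$synonyms, ",")[[1]] else character()
    models[[r$gene_id]] <- gene_model(
      gene_id = r$gene_id, chrom = r$chrom, strand = r$strand,
      span_start = r$span_start, span_end = r$span_end, exons = NULL,
      synonyms = trimws(syn),
      transcript_length = if ("transcript_length" %in% names(tab))
        r$transcript_length else NA,
      protein_length = if ("protein_length" %in% names(tab))
        r$protein_length else NA,
      exon_count = if ("exon_count" %in% names(tab)) r$exon_count else NA
    )
  }
  models
}

#' The eight characterized sorghum Maturity/Dwarf locus models
#'
#' Locus metadata for *Ma1*, *Ma2*, *Ma3*, *Ma5*, *Ma6*, *Dw1*, *Dw2* and
#' *Dw3* (BTx623 v3 coordinates): genomic span, coding strand, transcript and
#' protein length, exon count, and common identifiers. Exon boundaries are
#' deliberately not included — these are metadata-only models, so
#' sequence-level operations on them require a user-supplied GFF3 + FASTA.
#'
#' @return A named list of eight metadata-only [gene_model()] objects,
#'   keyed by locus name (`Ma1` ... `Dw3`).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "maturity_dwarf_loci.tsv",
                      package = "sorgscreen")
  load_gene_models(path)
}
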