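EFFECT_CATEGORIES <- c("same_sense", "tolerated_missense",
                       "deleterious_missense", "nonsense", "frameshift",
                       "splice_disrupting", "splice_region",
                       "other_noncoding", "unscored_missense")

#' Assign a consequence its effect category
#'
#' Follows the screen's four-way separation with explicit handling of
#' unscored missense variants: synonymous changes are `same_sense`;
#' missense changes are `deleterious_missense` when their substitution
#' score is strictly below `threshold` (SIFT convention: lower = more
#' damaging), `tolerated_missense` at or above it, and `unscored_missense`
#' when no score is supplied (so missing annotations cannot masquerade as
#' benign). Nonsense, frameshift and splice labels pass through regardless
#' of score. A score exactly at the threshold is tolerated (strict
#' inequality).
#'
#' @param consequence A `consequence_record` from [predict_consequence()].
#' @param score Numeric substitution score in `[0, 1]`, or `NA`/`NULL` when
#'   unscored.
#' @param threshold Deleteriousness threshold, default 0.05.
#' @return One of the effect category strings.
#' @export
classify_effect <- function(consequence, score = NULL, threshold = 0.05) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  if (length(score) && !is.na(score)) {
    if (score < 0 || score > 1) {
      stop("substitution score ", score, " outside [0, 1]", call. = FALSE)
    }
  } else {
    score <- NA_real_
  }
  region <- consequence$region
  if (region %in% c("splice_disrupting", "splice_region")) return(region)
  if (region %in% c("intron", "utr5", "utr3")) return("other_noncoding")
  pc <- consequence$protein_change
  if (is.null(pc)) return("other_noncoding")
  switch(pc$kind,
    synonymous = "same_sense",
    nonsense = "nonsense",
    frameshift = "frameshift",
    missense = if (is.na(score)) "unscored_missense"
               else if (score < threshold) "deleterious_missense"
               else "tolerated_missense",
    start_loss = ,
    stop_loss = ,
    inframe_del = ,
    inframe_ins = ,
    inframe_dup = ,
    inframe_delins = {
      # in-frame protein events are scored like missense when a score
      # exists; unscored in-frame changes stay visible as unscored_missense
      if (is.na(score)) "unscored_missense"
      else if (score < threshold) "deleterious_missense"
      else "tolerated_missense"
    },
    "other_noncoding")
}

#' Is an effect category counted as deleterious?
#'
#' Deleterious = predicted loss of function: `deleterious_missense`,
#' `nonsense`, `frameshift` and `splice_disrupting`. Splice-region (the
#' non-consensus window) variants are reported but not counted deleterious
#' unless `count_splice_region = TRUE`.
#'
#' @param category Effect category string (vectorized).
#' @param count_splice_region Count `splice_region` as deleterious
#'   (default FALSE).
#' @return Logical vector.
#' @export
is_deleterious <- function(category, count_splice_region = FALSE) {
  base <- c("deleterious_missense", "nonsense", "frameshift",
            "splice_disrupting")
  if (count_splice_region) base <- c(base, "splice_region")
  category %in% base
}

#' Tabulate effect counts per locus, category, and variant class
#'
#' @param consequences List of `consequence_record` objects.
#' @param scores Named numeric vector of substitution scores keyed by
#'   variant id (may be missing entries).
#' @param variants data.frame of variant records (for the SNP/InDel split:
#'   SNP iff both alleles have length 1).
#' @param threshold Deleteriousness threshold passed to [classify_effect()].
#' @return data.frame with columns `gene_id`, `category`, `class`
#'   (`SNP`/`InDel`) and `n`; counts partition the (variant, gene) pairs.
#' @export
effect_counts <- function(consequences, scores = numeric(), variants = NULL,
                          threshold = 0.05) {
  grid <- expand.grid(gene_id = unique(vapply(consequences, `[[`, character(1),
                                              "gene_id")),
                      category = EFFECT_CATEGORIES,
                      class = c("SNP", "InDel"),
                      stringsAsFactors = FALSE)
  grid$n <- rep(0L, nrow(grid))
  if (length(consequences) == 0) {
    return(grid[order(grid$gene_id, grid$category, grid$class), ,
                drop = FALSE])
  }
  for (r in consequences) {
    sc <- if (r$variant_id %in% names(scores)) scores[[r$variant_id]] else NA
    cat_i <- classify_effect(r, sc, threshold)
    if (!is.null(variants)) {
      vrow <- variants[variants$id == r$variant_id, , drop = FALSE]
      cls <- if (nrow(vrow) == 1 && nchar(vrow$ref) == 1 &&
                 nchar(vrow$alt) == 1) "SNP" else "InDel"
    } else {
      parts <- strsplit(r$variant_id, ":", fixed = TRUE)[[1]]
      cls <- if (nchar(parts[3]) == 1 && nchar(parts[4]) == 1) "SNP" else "InDel"
    }
    hit <- grid$gene_id == r$gene_id & grid$category == cat_i &
      grid$class == cls
    grid$n[hit] <- grid$n[hit] + 1L
  }
  grid[order(grid$gene_id, grid$category, grid$class), , drop = FALSE]
}

#' Read a substitution-score table
#'
#' @param path TSV with columns `variant_id`, `score`, and optionally
#'   `source`.
#' @return Named numeric vector keyed by variant id, with a `source`
#'   attribute.
#' @export
read_scores <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("variant_id", "score") %in% names(tab))) {
    stop("scores TSV needs columns variant_id, score", call. = FALSE)
  }
  if (any(tab$score < 0 | tab$score > 1, na.rm = TRUE)) {
    stop("substitution scores outside [0, 1] in ", path, call. = FALSE)
  }
  out <- stats::setNames(tab$score, tab$variant_id)
  attr(out, "source") <- if ("source" %in% names(tab)) tab$source else NULL
  out
}
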