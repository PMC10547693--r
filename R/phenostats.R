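#' Fit a one-way allele group-means model
#'
#' A linear model of the trait on the allele factor with treatment coding
#' against the wildtype level (when present), giving per-allele effect
#' estimates and two-sided coefficient t-tests — the screen's
#' genotype-phenotype association. Residual normality is assessed with a
#' Shapiro-Wilk test and a Kruskal-Wallis rank-sum test is run as the
#' non-parametric fallback. Levels with no observations (or aliased columns
#' in a multi-factor design) are dropped and reported as singularities.
#'
#' @param values Numeric trait values (missing values dropped pairwise).
#' @param alleles Character/factor of allele levels, same length.
#' @param reference Reference level; defaults to `"wildtype"` when present,
#'   else the first level.
#' @param alpha Significance level recorded in the result (default 0.05).
#' @return A list of class `association_result`: `coefficients` (level, n,
#'   estimate, std_error, t, p, significant), `reference`, `dropped`
#'   (singularities), `shapiro` (W, p or NA when n outside [3, 5000]),
#'   `kruskal` (H, df, p), `alpha`, `n`.
#' @export
fit_allele_means <- function(values, alleles, reference = NULL,
                             alpha = 0.05) {
  keep <- !is.na(values) & !is.na(alleles) & nzchar(as.character(alleles))
  values <- values[keep]
  alleles <- as.character(alleles)[keep]
  present <- table(alleles)
  dropped <- names(present)[present == 0]
  usable <- names(present)[present > 0]
  if (length(usable) < 2) {
    stop("need >= 2 allele levels with observations; have ",
         length(usable), call. = FALSE)
  }
  if (is.null(reference)) {
    reference <- if ("wildtype" %in% usable) "wildtype" else usable[1]
  }
  f <- stats::relevel(factor(alleles, levels = usable), ref = reference)
  fit <- stats::lm(values ~ f)
  sm <- summary(fit)
  co <- sm$coefficients
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased)) {
    dropped <- c(dropped, sub("^f", "", aliased))
  }
  lvl <- rownames(co)
  is_int <- lvl == "(Intercept)"
  lvl[!is_int] <- sub("^f", "", lvl[!is_int])
  lvl[is_int] <- reference
  coef_tab <- data.frame(
    level = lvl,
    n = as.integer(table(f)[lvl]),
    estimate = unname(co[, "Estimate"]),
    std_error = unname(co[, "Std. Error"]),
    t = unname(co[, "t value"]),
    p = unname(co[, "Pr(>|t|)"]),
    stringsAsFactors = FALSE)
  coef_tab$significant <- coef_tab$p < alpha
  res <- stats::residuals(fit)
  shapiro <- if (length(res) >= 3 && length(res) <= 5000 &&
                 stats::sd(res) > 0) {
    sw <- shapiro_wilk(res)
    c(W = sw$W, p = sw$p)
  } else c(W = NA_real_, p = NA_real_)
  groups <- split(values, f)
  kruskal <- tryCatch({
    kw <- kruskal_wallis(groups)
    c(H = kw$H, df = kw$df, p = kw$p)
  }, error = function(e) c(H = NA_real_, df = NA_real_, p = NA_real_))
  structure(list(coefficients = coef_tab, reference = reference,
                 dropped = unique(dropped), shapiro = shapiro,
                 kruskal = kruskal, alpha = alpha, n = length(values)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("<association_result> n =", x$n, " reference =", x$reference, "\n")
  print(x$coefficients, digits = 4)
  cat(sprintf("Shapiro-Wilk W = %.5f (p = %.4g); Kruskal-Wallis H = %.4g (df = %d, p = %.4g)\n",
              x$shapiro[["W"]], x$shapiro[["p"]], x$kruskal[["H"]],
              as.integer(x$kruskal[["df"]]), x$kruskal[["p"]]))
  if (length(x$dropped)) {
    cat("dropped levels (singularities):", paste(x$dropped, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Royston's approximation (via the vetted base implementation). W and p
#' are invariant under affine transformation of the data.
#'
#' @param values Numeric sample, 3 <= n <= 5000.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) {
    stop("Shapiro-Wilk requires n >= 3, have ", length(values), call. = FALSE)
  }
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p = unname(ht$p.value))
}

#' Kruskal-Wallis rank-sum test
#'
#' H = 12 / (N (N + 1)) * sum n_i (rbar_i - (N + 1) / 2)^2 with mid-ranks
#' for ties and the standard tie-correction divisor; df = k - 1; p from
#' the chi-square upper tail.
#'
#' @param groups List of numeric vectors (>= 2 groups, total n >= 3).
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  if (length(groups) < 2) stop("need >= 2 non-empty groups", call. = FALSE)
  x <- unlist(groups)
  if (length(x) < 3) stop("need total n >= 3", call. = FALSE)
  if (length(unique(x)) == 1) {
    stop("all values identical: statistic undefined after tie correction",
         call. = FALSE)
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ht <- stats::kruskal.test(x, g)
  list(H = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Read a phenotype table
#'
#' @param path TSV with columns `accession`, `trait`, `value` and
#'   optionally `unit`.
#' @return data.frame with one value per accession x trait.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("accession", "trait", "value")
  if (!all(needed %in% names(tab))) {
    stop("phenotype TSV needs columns accession, trait, value", call. = FALSE)
  }
  if (anyDuplicated(tab[, c("accession", "trait")])) {
    stop("more than one value per accession x trait", call. = FALSE)
  }
  tab$value <- as.numeric(tab$value)
  tab
}

#' Associate locus calls with a phenotype
#'
#' Builds the per-accession allele level at a locus from its
#' [genotype_panel()] calls (named calls use the matched allele name,
#' novel deleterious calls pool as `"novel"`, wildtype stays
#' `"wildtype"`), excludes `uncharacterized` and `heterozygous_carrier`
#' accessions by default (their allele level is ambiguous), and fits
#' [fit_allele_means()].
#'
#' @param calls data.frame from [genotype_panel()] for one locus or more.
#' @param phenotypes data.frame from [read_phenotypes()].
#' @param locus Locus to test.
#' @param trait Trait name present in `phenotypes`.
#' @param include_ambiguous Keep uncharacterized / heterozygous carriers as
#'   their own levels (default FALSE).
#' @param alpha Significance level.
#' @return An `association_result`.
#' @export
associate_locus <- function(calls, phenotypes, locus, trait,
                            include_ambiguous = FALSE, alpha = 0.05) {
  sub <- calls[calls$locus == locus, , drop = FALSE]
  ph <- phenotypes[phenotypes$trait == trait, , drop = FALSE]
  merged <- merge(sub, ph, by = "accession")
  if (nrow(merged) == 0) {
    stop("no overlapping accessions between locus calls and phenotypes",
         call. = FALSE)
  }
  level <- ifelse(merged$status == "named",
                  vapply(strsplit(merged$matched_alleles, ","), `[`,
                         character(1), 1),
                  ifelse(merged$status == "novel_deleterious", "novel",
                         merged$status))
  if (!include_ambiguous) {
    keep <- !merged$status %in% c("uncharacterized", "heterozygous_carrier")
    merged <- merged[keep, , drop = FALSE]
    level <- level[keep]
  }
  fit_allele_means(merged$value, level, alpha = alpha)
}

#' Combined multi-locus association model
#'
#' Additive linear model of the trait on the allele factors of several loci
#' jointly (no interactions). Aliased (perfectly confounded) columns are
#' dropped by the fit and reported as singularities, mirroring what happens
#' when allele combinations do not segregate independently in a panel.
#'
#' @inheritParams associate_locus
#' @param loci Character vector of loci to include as additive factors.
#' @return A list with `coefficients` (term-level estimates and t-tests),
#'   `dropped` (aliased terms), `shapiro`, `alpha`, `n`.
#' @export
associate_combined <- function(calls, phenotypes, loci, trait,
                               alpha = 0.05) {
  ph <- phenotypes[phenotypes$trait == trait, , drop = FALSE]
  wide <- NULL
  for (locus in loci) {
    sub <- calls[calls$locus == locus &
                   !calls$status %in% c("uncharacterized",
                                        "heterozygous_carrier"), ,
                 drop = FALSE]
    lev <- ifelse(sub$status == "named",
                  vapply(strsplit(sub$matched_alleles, ","), `[`,
                         character(1), 1),
                  ifelse(sub$status == "novel_deleterious", "novel",
                         "wildtype"))
    col <- data.frame(accession = sub$accession, lev, stringsAsFactors = FALSE)
    names(col)[2] <- locus
    wide <- if (is.null(wide)) col else merge(wide, col, by = "accession")
  }
  merged <- merge(wide, ph, by = "accession")
  if (nrow(merged) == 0) {
    stop("no overlapping accessions between locus calls and phenotypes",
         call. = FALSE)
  }
  for (locus in loci) {
    lv <- unique(merged[[locus]])
    ref <- if ("wildtype" %in% lv) "wildtype" else lv[1]
    merged[[locus]] <- stats::relevel(factor(merged[[locus]]), ref = ref)
  }
  usable <- loci[vapply(loci, function(l) nlevels(droplevels(merged[[l]])) > 1,
                        logical(1))]
  if (length(usable) == 0) stop("no locus with >= 2 allele levels",
                                call. = FALSE)
  fml <- stats::as.formula(paste("value ~",
                                 paste(sprintf("`%s`", usable),
                                       collapse = " + ")))
  fit <- stats::lm(fml, data = merged)
  sm <- summary(fit)
  co <- sm$coefficients
  dropped <- names(which(is.na(stats::coef(fit))))
  res <- stats::residuals(fit)
  shapiro <- if (length(res) >= 3 && length(res) <= 5000 &&
                 stats::sd(res) > 0) {
    sw <- shapiro_wilk(res)
    c(W = sw$W, p = sw$p)
  } else c(W = NA_real_, p = NA_real_)
  list(coefficients = data.frame(term = rownames(co),
                                 estimate = unname(co[, "Estimate"]),
                                 std_error = unname(co[, "Std. Error"]),
                                 t = unname(co[, "t value"]),
                                 p = unname(co[, "Pr(>|t|)"]),
                                 stringsAsFactors = FALSE),
       dropped = dropped, shapiro = shapiro, alpha = alpha,
       n = nrow(merged))
}
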