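NON_STOP_CODONS <- NULL  # filled at load time (see .onLoad)
STOP_CODONS <- c("TAA", "TAG", "TGA")

.onLoad <- function(libname, pkgname) {
  gc_tab <- Biostrings::GENETIC_CODE
  assignInMyNamespace("NON_STOP_CODONS", names(gc_tab)[gc_tab != "*"])
}

#' Build a simulation configuration
#'
#' Defaults define the study conditions the generator emulates: an inbred
#' (mostly homozygous) diploid germplasm panel segregating for the
#' characterized Maturity/Dwarf alleles at frequencies mirroring their
#' observed panel proportions (clipped to \[0.05, 0.5\]), with novel
#' deleterious variants, neutral variants, optional genotype missingness
#' and heterozygosity, substitution scores concordant with the planted
#' categories, and additive phenotype effects plus Gaussian noise.
#'
#' @param seed Integer seed (mandatory); every source of randomness in the
#'   generator flows from it.
#' @param n_genes Number of synthetic loci (8 = the screen's locus set,
#'   named Ma1..Dw3).
#' @param exon_count_range,exon_len_range,intron_len_range,utr_len_range
#'   Gene-geometry ranges (bases; exon lengths are coding lengths).
#' @param panel_size Number of accessions.
#' @param allele_freq Named planting frequency per catalog allele
#'   (homozygous carrier frequency).
#' @param novel_del_rate Per-locus probability that a wildtype accession
#'   carries the locus's novel deleterious variant (homozygous).
#' @param neutral_rate Homozygous carrier frequency of each neutral variant.
#' @param missingness Per-cell genotype missingness rate.
#' @param het_rate Probability that a planted carrier is heterozygous
#'   rather than homozygous.
#' @param baseline,sigma Phenotype baseline and residual standard deviation.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_genes = 8L,
                              exon_count_range = c(2L, 6L),
                              exon_len_range = c(90L, 240L),
                              intron_len_range = c(60L, 180L),
                              utr_len_range = c(12L, 45L),
                              panel_size = 200L,
                              allele_freq = default_allele_frequencies(),
                              novel_del_rate = 0.05,
                              neutral_rate = 0.1,
                              missingness = 0,
                              het_rate = 0,
                              baseline = 250,
                              sigma = 10) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("seed is mandatory", call. = FALSE)
  }
  rates <- c(novel_del_rate, neutral_rate, missingness, het_rate, allele_freq)
  if (any(rates < 0 | rates > 1)) {
    stop("all rates and frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (panel_size < 1) stop("panel_size must be positive", call. = FALSE)
  if (any(c(exon_len_range, intron_len_range, utr_len_range) < 1)) {
    stop("length ranges must be positive", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 exon_count_range = exon_count_range,
                 exon_len_range = exon_len_range,
                 intron_len_range = intron_len_range,
                 utr_len_range = utr_len_range,
                 panel_size = as.integer(panel_size),
                 allele_freq = allele_freq,
                 novel_del_rate = novel_del_rate,
                 neutral_rate = neutral_rate,
                 missingness = missingness, het_rate = het_rate,
                 baseline = baseline, sigma = sigma),
            class = "simulation_config")
}

#' Default planting frequencies for the characterized alleles
#'
#' Homozygous carrier frequencies mirroring each allele's observed share of
#' the 860-accession panel, clipped to \[0.05, 0.5\] so every planted allele
#' is recoverable at desk-scale panel sizes. Alleles absent from the map
#' (rare race-specific alleles and the unmatchable dw3-ref) are not planted.
#'
#' @return Named numeric vector keyed by catalog allele name.
#' @export
default_allele_frequencies <- function() {
  c("Sbprr37-1" = 0.21, "Sbprr37-2" = 0.18, "Sbprr37-3" = 0.05,
    "prr37^Durra" = 0.05,
    "ma2-Leu141Ter" = 0.05, "ma2-Met83Thr" = 0.05,
    "Sbphyb-1" = 0.05, "Sbphyb-2" = 0.05,
    "SbphyC-1" = 0.07,
    "Sbghd7-1" = 0.45, "Sbghd7-2" = 0.05,
    "dw1" = 0.33, "dw2" = 0.30,
    "dw3-sd1" = 0.05, "dw3-sd2" = 0.05)
}

#' Default additive phenotype effects per allele
#'
#' Dwarfing alleles shorten the plant (cm); maturity alleles advance
#' anthesis (days). `novel-<locus>` keys cover the generator's novel
#' deleterious variants.
#'
#' @param trait `"plant_height"` or `"days_to_anthesis"`.
#' @return Named numeric vector of effects (same scale as the trait).
#' @export
default_phenotype_effects <- function(trait = c("plant_height",
                                                "days_to_anthesis")) {
  trait <- match.arg(trait)
  ma_loci <- c("Ma1", "Ma2", "Ma3", "Ma5", "Ma6")
  dw_effect <- c("dw1" = -50, "dw2" = -45, "dw3-sd1" = -40, "dw3-sd2" = -35,
                 "novel-Dw1" = -50, "novel-Dw2" = -45, "novel-Dw3" = -40)
  ma_names <- c("Sbprr37-1", "Sbprr37-2", "Sbprr37-3", "prr37^Durra",
                "prr37^Sudangrass", "prr37^Feterita", "prr37^Broomcorn",
                "ma2-Leu141Ter", "ma2-Met83Thr", "Sbphyb-1", "Sbphyb-2",
                "SbphyC-1", "Sbghd7-1", "Sbghd7-1-alt", "Sbghd7-2",
                paste0("novel-", ma_loci))
  if (trait == "plant_height") {
    c(dw_effect, stats::setNames(rep(0, length(ma_names)), ma_names))
  } else {
    ma_eff <- stats::setNames(rep(c(-18, -8, -10, -6, -15),
                                  length.out = length(ma_names)), ma_names)
    c(ma_eff, stats::setNames(rep(0, length(dw_effect)), names(dw_effect)))
  }
}

SYNTHETIC_LOCI <- c("Ma1", "Ma2", "Ma3", "Ma5", "Ma6", "Dw1", "Dw2", "Dw3")

#' Simulate a reference genome and gene models
#'
#' Each synthetic gene has an ATG start, a single in-frame stop at the CDS
#' end, GT..AG introns, a CDS length divisible by 3, and 5'/3' UTRs (the
#' 3' UTR ends in a stop-rich tail so shifted reading frames terminate
#' within the transcript). Both strands are represented. Each gene sits on
#' its own chromosome with 100-base flanks.
#'
#' @param config A [simulation_config()].
#' @return A list with `genome` (named character vector of chromosome
#'   sequences) and `models` (named list of [gene_model()] objects).
#' @export
simulate_reference <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  gene_names <- if (n == 8L) SYNTHETIC_LOCI else paste0("G", seq_len(n))
  genome <- character()
  models <- list()
  for (i in seq_len(n)) {
    strand <- if (i %% 2L == 1L) "+" else "-"
    g <- random_gene(config, gene_names[i], strand)
    chrom <- paste0("chr_", gene_names[i])
    genome[[chrom]] <- g$chromseq
    g$model$chrom <- chrom
    models[[gene_names[i]]] <- g$model
  }
  list(genome = genome, models = models)
}

rand_int <- function(rng) sample(rng[1]:rng[2], 1L)
rand_bases <- function(k) paste(sample(c("A", "C", "G", "T"), k,
                                       replace = TRUE), collapse = "")

# Build one gene in coding orientation, then place it on the chromosome
# (reverse-complemented for '-' strand genes).
random_gene <- function(config, gene_id, strand) {
  n_ex <- rand_int(config$exon_count_range)
  coding_lens <- vapply(seq_len(n_ex), function(i)
    rand_int(config$exon_len_range), integer(1))
  total <- sum(coding_lens)
  pad <- (3L - total %% 3L) %% 3L
  coding_lens[n_ex] <- coding_lens[n_ex] + pad
  total <- total + pad
  n_res <- total %/% 3L - 1L
  cds <- paste0("ATG",
                paste(sample(setdiff(NON_STOP_CODONS, "ATG"), n_res - 1L,
                             replace = TRUE), collapse = ""),
                sample(STOP_CODONS, 1L))
  u5 <- rand_bases(rand_int(config$utr_len_range))
  # TTAATTAATTAA carries a stop codon in all three reading frames
  u3 <- paste0(rand_bases(rand_int(config$utr_len_range)), "TTAATTAATTAA")
  tx_ex_lens <- coding_lens
  tx_ex_lens[1] <- tx_ex_lens[1] + nchar(u5)
  tx_ex_lens[n_ex] <- tx_ex_lens[n_ex] + nchar(u3)
  transcript <- paste0(u5, cds, u3)
  intron_seqs <- if (n_ex > 1) {
    vapply(seq_len(n_ex - 1L), function(i) {
      paste0("GT", rand_bases(rand_int(config$intron_len_range) - 4L), "AG")
    }, character(1))
  } else character()
  # assemble plus-orientation gene sequence and exon coordinates
  pieces <- character()
  exon_start <- integer(n_ex)
  exon_end <- integer(n_ex)
  cursor <- 0L
  tx_cursor <- 0L
  for (e in seq_len(n_ex)) {
    exon_seq <- substr(transcript, tx_cursor + 1L, tx_cursor + tx_ex_lens[e])
    tx_cursor <- tx_cursor + tx_ex_lens[e]
    exon_start[e] <- cursor + 1L
    exon_end[e] <- cursor + tx_ex_lens[e]
    pieces <- c(pieces, exon_seq)
    cursor <- exon_end[e]
    if (e < n_ex) {
      pieces <- c(pieces, intron_seqs[e])
      cursor <- cursor + nchar(intron_seqs[e])
    }
  }
  gene_seq <- paste(pieces, collapse = "")
  glen <- nchar(gene_seq)
  cds_start_rel <- nchar(u5) + 1L
  cds_end_rel <- nchar(u5) + nchar(cds)
  # map transcript-relative CDS bounds to plus-orientation gene coordinates
  tx_to_gene <- function(tp) {
    acc <- 0L
    for (e in seq_len(n_ex)) {
      if (tp <= acc + tx_ex_lens[e]) return(exon_start[e] + (tp - acc - 1L))
      acc <- acc + tx_ex_lens[e]
    }
    stop("transcript position out of range")
  }
  cds_lo_rel <- tx_to_gene(cds_start_rel)
  cds_hi_rel <- tx_to_gene(cds_end_rel)
  flank <- 100L
  if (strand == "+") {
    chromseq <- paste0(rand_bases(flank), gene_seq, rand_bases(flank))
    ex <- data.frame(start = exon_start + flank, end = exon_end + flank)
    cds_lo <- cds_lo_rel + flank
    cds_hi <- cds_hi_rel + flank
  } else {
    chromseq <- paste0(rand_bases(flank), revcomp(gene_seq),
                       rand_bases(flank))
    mirror <- function(p) flank + (glen - p + 1L)
    ex <- data.frame(start = mirror(exon_end), end = mirror(exon_start))
    ex <- ex[order(ex$start), , drop = FALSE]
    cds_lo <- mirror(cds_hi_rel)
    cds_hi <- mirror(cds_lo_rel)
  }
  model <- gene_model(gene_id = gene_id, chrom = "pending", strand = strand,
                      span_start = flank + 1L, span_end = flank + glen,
                      exons = ex, cds_start = cds_lo, cds_end = cds_hi,
                      transcript_length = sum(tx_ex_lens),
                      protein_length = n_res)
  list(chromseq = chromseq, model = model)
}

# Convert a CDS-space edit to a normalized genomic variant.
# Substitution/deletion/delins: replace CDS positions c1..c2 with s.
cds_edit_to_variant <- function(model, genome, c1, c2, s) {
  chromseq <- resolve_chrom_seq(genome, model$chrom)
  g1 <- cds_to_genomic(model, c1)
  g2 <- cds_to_genomic(model, c2)
  glo <- min(g1, g2)
  ghi <- max(g1, g2)
  ref_g <- substr(chromseq, glo, ghi)
  alt_g <- if (model$strand == "+") s else revcomp(s)
  if (!nzchar(alt_g)) {
    anchor <- substr(chromseq, glo - 1L, glo - 1L)
    v <- variant(model$chrom, glo - 1L, paste0(anchor, ref_g), anchor)
  } else {
    v <- variant(model$chrom, glo, ref_g, alt_g)
  }
  normalize_variant(v, genome)
}

# Insertion of s between CDS positions a and a+1 (1 <= a < CDS length).
cds_insertion_to_variant <- function(model, genome, a, s) {
  chromseq <- resolve_chrom_seq(genome, model$chrom)
  if (model$strand == "+") {
    g <- cds_to_genomic(model, a)
    anchor <- substr(chromseq, g, g)
    v <- variant(model$chrom, g, anchor, paste0(anchor, s))
  } else {
    g <- cds_to_genomic(model, a + 1L)
    anchor <- substr(chromseq, g, g)
    v <- variant(model$chrom, g, anchor, paste0(anchor, revcomp(s)))
  }
  normalize_variant(v, genome)
}

codon_at <- function(ctx, p) substr(ctx$cds, 3L * p - 2L, 3L * p)

codons_for <- function(aa1) NON_STOP_CODONS[
  Biostrings::GENETIC_CODE[NON_STOP_CODONS] == aa1]

#' Plant a variant realizing a target consequence on a synthetic gene
#'
#' Constructs a genomic variant whose predicted consequence reproduces the
#' target: either a [protein_change()] (kinds `missense`, `nonsense`,
#' `frameshift`, `inframe_dup`, `inframe_del`, `synonymous`) or a region
#' label (`"intron"`, `"splice_region"`, `"splice_donor"`,
#' `"splice_acceptor"`). When `remap = TRUE` (the default for catalog
#' planting), the residue position is re-chosen to the nearest feasible
#' codon, so real-locus signatures can be planted on synthetic models that
#' do not replicate real exon structures.
#'
#' @param model Synthetic [gene_model()].
#' @param genome Reference from [simulate_reference()].
#' @param target A [protein_change()] or region label string.
#' @param used Integer vector of residue (or intron-offset) positions
#'   already occupied, to keep planted variants disjoint.
#' @param remap Allow re-choosing the residue position.
#' @return A list with `variant` (normalized, one row) and `position`
#'   (the residue or genomic position used).
#' @export
plant_variant <- function(model, genome, target, used = integer(),
                          remap = TRUE) {
  ctx <- model_context(model, genome)
  n_res <- ctx$n_res
  if (is.character(target)) {
    return(plant_region_variant(model, genome, target))
  }
  # genomic position of every CDS base, in CDS order; codons that straddle
  # an exon junction cannot take single edits and are excluded
  ce <- coding_exons(model)
  gpos <- unlist(mapply(function(s, e) s:e, ce$start, ce$end,
                        SIMPLIFY = FALSE), use.names = FALSE)
  if (model$strand == "-") gpos <- rev(gpos)
  contig <- function(c1, c2) all(abs(diff(gpos[c1:c2])) == 1L)
  codon_ok <- vapply(seq_len(n_res), function(p)
    contig(3L * p - 2L, 3L * p), logical(1))
  free_codons <- setdiff(2:(n_res - 2L), unlist(lapply(used, function(u)
    (u - 2L):(u + 2L))))
  free_codons <- free_codons[codon_ok[free_codons]]
  pick_pos <- function(desired, ref_aa1 = NULL, also_ok = NULL) {
    cand <- free_codons
    if (!is.null(also_ok)) {
      cand <- cand[vapply(cand, also_ok, logical(1))]
    }
    base_cand <- cand
    if (!is.null(ref_aa1)) {
      cand <- cand[ctx$protein[cand] == ref_aa1]
    }
    if (remap && length(cand) == 0) {
      cand <- base_cand  # requested residue absent: any free codon will do
    }
    if (!remap) {
      if (is.na(desired) || desired > n_res) {
        stop("target residue ", desired, " beyond protein length ", n_res,
             call. = FALSE)
      }
      if (!desired %in% cand) {
        stop("requested reference residue not available at position ",
             desired, call. = FALSE)
      }
      return(desired)
    }
    if (length(cand) == 0) {
      stop("no feasible codon for target on gene ", model$gene_id,
           call. = FALSE)
    }
    if (!is.na(desired)) cand[which.min(abs(cand - desired))]
    else sample(cand, 1L)
  }
  kind <- target$kind
  ref_aa1 <- if (!is.na(target$ref_aa) && target$ref_aa %in% names(AA_3TO1))
    unname(AA_3TO1[target$ref_aa]) else NULL
  if (kind == "missense") {
    p <- pick_pos(target$pos, ref_aa1)
    alt1 <- if (nzchar(target$alt_aa) && target$alt_aa %in% names(AA_3TO1))
      unname(AA_3TO1[target$alt_aa]) else NA
    if (is.na(alt1) || alt1 == ctx$protein[p]) {
      alt1 <- sample(setdiff(unique(unname(
        Biostrings::GENETIC_CODE[NON_STOP_CODONS])), ctx$protein[p]), 1L)
    }
    new_codon <- sample(codons_for(alt1), 1L)
    v <- cds_edit_to_variant(model, genome, 3L * p - 2L, 3L * p, new_codon)
    return(list(variant = v, position = p))
  }
  if (kind == "nonsense") {
    p <- pick_pos(target$pos, ref_aa1)
    old <- codon_at(ctx, p)
    stopc <- STOP_CODONS[STOP_CODONS != old][1]
    v <- cds_edit_to_variant(model, genome, 3L * p - 2L, 3L * p, stopc)
    return(list(variant = v, position = p))
  }
  if (kind == "frameshift") {
    p <- pick_pos(target$pos)
    # delete the first base of the codon (or insert one, alternating on
    # position parity, so both indel directions occur)
    if (p %% 2L == 0L) {
      v <- cds_edit_to_variant(model, genome, 3L * p - 2L, 3L * p - 2L, "")
    } else {
      ins <- sample(c("A", "C", "G", "T"), 1L)
      v <- cds_insertion_to_variant(model, genome, 3L * p - 2L, ins)
    }
    return(list(variant = v, position = p))
  }
  if (kind == "inframe_dup") {
    p <- pick_pos(target$pos, ref_aa1,
                  also_ok = function(p) contig(3L * p, 3L * p + 1L))
    v <- cds_insertion_to_variant(model, genome, 3L * p, codon_at(ctx, p))
    return(list(variant = v, position = p))
  }
  if (kind == "inframe_del") {
    k <- if (!is.na(target$pos2)) target$pos2 - target$pos + 1L else 1L
    p <- pick_pos(min(target$pos, n_res - k - 2L, na.rm = TRUE),
                  also_ok = function(p) p <= n_res - k - 2L &&
                    contig(3L * p - 2L, 3L * (p + k - 1L)))
    v <- cds_edit_to_variant(model, genome, 3L * (p - 1L) + 1L,
                             3L * (p + k - 1L), "")
    return(list(variant = v, position = p))
  }
  if (kind == "synonymous") {
    for (p in sample(free_codons)) {
      old <- codon_at(ctx, p)
      syn <- setdiff(codons_for(ctx$protein[p]), old)
      if (length(syn)) {
        v <- cds_edit_to_variant(model, genome, 3L * p - 2L, 3L * p, syn[1])
        return(list(variant = v, position = p))
      }
    }
    stop("no codon with a synonymous alternative found", call. = FALSE)
  }
  stop("cannot plant target of kind ", kind, call. = FALSE)
}

plant_region_variant <- function(model, genome, label) {
  chromseq <- resolve_chrom_seq(genome, model$chrom)
  intr <- introns_of(model)
  if (nrow(intr) == 0) stop("gene ", model$gene_id, " has no introns",
                            call. = FALSE)
  widths <- intr$end - intr$start + 1L
  ok <- switch(label,
    intron = which(widths >= 26L),
    which(widths >= 14L))
  if (length(ok) == 0) stop("no intron long enough for label ", label,
                            call. = FALSE)
  i <- ok[sample.int(length(ok), 1L)]
  off <- switch(label,
    splice_donor = sample(1:2, 1L),
    splice_acceptor = -sample(1:2, 1L),
    splice_region = if (stats::runif(1) < 0.5) sample(3:5, 1L)
                    else -sample(3:10, 1L),
    intron = sample(6:(widths[i] - 12L), 1L),
    stop("unknown region label ", label, call. = FALSE))
  pos <- intron_offset_to_genomic(model, i, off)
  ref <- substr(chromseq, pos, pos)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  list(variant = normalize_variant(variant(model$chrom, pos, ref, alt),
                                   genome),
       position = pos)
}

# Genomic position at signed offset `off` within intron i (ascending
# genomic index), offsets defined on the coding strand.
intron_offset_to_genomic <- function(model, i, off) {
  intr <- introns_of(model)
  s <- intr$start[i]
  e <- intr$end[i]
  if (model$strand == "+") {
    if (off > 0) s + off - 1L else e + off + 1L
  } else {
    if (off > 0) e - off + 1L else s - off - 1L
  }
}

#' Simulate a genotyped variant panel with ground truth
#'
#' Plants the catalog alleles on the synthetic reference (remapped by
#' consequence, so the synthetic catalog returned carries matchers for the
#' realized changes), adds one novel deleterious variant and a set of
#' neutral variants (synonymous, intronic, tolerated missense) per locus,
#' draws inbred-line genotypes at the configured frequencies, fabricates
#' substitution scores concordant with the planted categories
#' (deleterious bands in \[0, 0.05), tolerated in \[0.05, 1\]), applies
#' missingness, and records everything in a truth manifest.
#'
#' @param config A [simulation_config()].
#' @param reference Output of [simulate_reference()].
#' @param catalog Allele catalog (default [builtin_catalog()]).
#' @return A list of class `synthetic_panel`: `gmat` ([genotype_matrix()]),
#'   `scores` (named vector), `consequences` (list of records),
#'   `classified` (table from [classify_consequences()]), `catalog`
#'   (remapped synthetic catalog), `manifest` (truth manifest), `models`,
#'   `genome`.
#' @export
simulate_panel <- function(config, reference = simulate_reference(config),
                           catalog = builtin_catalog()) {
  set.seed(config$seed + 1000L)
  genome <- reference$genome
  models <- reference$models
  loci <- names(models)
  unknown <- setdiff(names(config$allele_freq),
                     vapply(catalog, `[[`, character(1), "name"))
  if (length(unknown)) {
    stop("frequency map references unknown allele(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ctxs <- lapply(models, model_context, genome = genome)
  used <- stats::setNames(vector("list", length(loci)), loci)
  variants <- list()      # one-row data.frames
  var_meta <- list()      # role/allele/kind/score_band per variant
  syn_catalog <- list()
  planted_freq <- config$allele_freq
  add_variant <- function(v, locus, role, allele, kind, band) {
    id <- v$id
    if (!id %in% names(variants)) {
      variants[[id]] <<- v
      var_meta[[id]] <<- list(locus = locus, role = role, allele = allele,
                              kind = kind, band = band)
    }
    id
  }
  for (d in catalog) {
    freq <- planted_freq[d$name]
    if (d$locus %in% loci) model <- models[[d$locus]] else next
    if (is.na(freq) || freq == 0) {
      # keep the definition (unplanted alleles must stay absent), with
      # unmatched consequence matchers
      syn_catalog[[length(syn_catalog) + 1L]] <- d
      next
    }
    comp_matchers <- list()
    comp_ids <- character()
    feasible <- TRUE
    for (m in d$components) {
      if (m$unmatchable) {
        comp_matchers[[length(comp_matchers) + 1L]] <- m
        next
      }
      if (m$mode == "coordinate" && !is.na(m$window_start)) {
        # imprecise window signature: a long insertion deep in an intron
        intr <- introns_of(model)
        wide <- which(intr$end - intr$start + 1L >= 40L)
        if (length(wide) == 0) { feasible <- FALSE; break }
        wi <- wide[min(2L, length(wide))]
        pos <- intr$start[wi] + 15L
        chromseq <- resolve_chrom_seq(genome, model$chrom)
        anchor <- substr(chromseq, pos, pos)
        ins_len <- max(m$min_indel_len, 18L)
        v <- normalize_variant(
          variant(model$chrom, pos, anchor,
                  paste0(anchor, rand_bases(ins_len))), genome)
        id <- add_variant(v, d$locus, "catalog", d$name, "intron", NA)
        comp_ids <- c(comp_ids, id)
        comp_matchers[[length(comp_matchers) + 1L]] <- variant_matcher(
          "coordinate", chrom = model$chrom,
          window_start = v$pos - 10L, window_end = v$pos + 10L,
          min_indel_len = m$min_indel_len)
        next
      }
      target <- if (!is.na(m$hgvs_p)) parse_hgvs_p(m$hgvs_p)
                else protein_change(m$kind,
                                    pos = if (!is.null(m$pos_range))
                                      m$pos_range[2] else NA,
                                    no_stop = TRUE)
      pl <- plant_variant(model, genome, target, used = used[[d$locus]])
      used[[d$locus]] <- c(used[[d$locus]], pl$position)
      cons <- predict_consequence(model, genome, pl$variant,
                                  ctx = ctxs[[d$locus]])
      band <- if (cons$region == "cds" &&
                  cons$protein_change$kind %in%
                    c("missense", "inframe_dup", "inframe_del",
                      "inframe_ins", "inframe_delins")) "deleterious" else NA
      id <- add_variant(pl$variant, d$locus, "catalog", d$name,
                        if (is.null(cons$protein_change)) cons$region
                        else cons$protein_change$kind, band)
      comp_ids <- c(comp_ids, id)
      comp_matchers[[length(comp_matchers) + 1L]] <- variant_matcher(
        "consequence", hgvs_p = cons$hgvs_p)
    }
    if (!feasible) next
    syn_catalog[[length(syn_catalog) + 1L]] <- allele_definition(
      d$locus, d$name, components = comp_matchers,
      allele_class = d$allele_class, synonyms = d$synonyms,
      zygosity = d$zygosity, provenance = d$provenance)
  }
  # novel deleterious + neutral variants per locus
  novel_ids <- stats::setNames(rep(NA_character_, length(loci)), loci)
  for (locus in loci) {
    model <- models[[locus]]
    if (config$novel_del_rate > 0) {
      pl <- plant_variant(model, genome, protein_change("nonsense"),
                          used = used[[locus]])
      used[[locus]] <- c(used[[locus]], pl$position)
      novel_ids[locus] <- add_variant(pl$variant, locus, "novel",
                                      paste0("novel-", locus), "nonsense", NA)
    }
    if (config$neutral_rate > 0) {
      pl <- plant_variant(model, genome, protein_change("synonymous"),
                          used = used[[locus]])
      used[[locus]] <- c(used[[locus]], pl$position)
      add_variant(pl$variant, locus, "neutral", NA, "synonymous", NA)
      pl <- plant_variant(model, genome, "intron", used = used[[locus]])
      add_variant(pl$variant, locus, "neutral", NA, "intron", NA)
      pl <- plant_variant(model, genome, protein_change("missense"),
                          used = used[[locus]])
      used[[locus]] <- c(used[[locus]], pl$position)
      add_variant(pl$variant, locus, "neutral", NA, "missense", "tolerated")
    }
  }
  var_df <- do.call(rbind, unname(variants))
  ord <- order(var_df$chrom, var_df$pos)
  var_df <- var_df[ord, , drop = FALSE]
  var_meta <- var_meta[var_df$id]
  # accession genotypes
  accs <- sprintf("ACC%04d", seq_len(config$panel_size))
  calls <- matrix("hom_ref", nrow = nrow(var_df), ncol = length(accs),
                  dimnames = list(var_df$id, accs))
  truth <- list()
  allele_by_locus <- split(
    names(planted_freq)[planted_freq > 0],
    vapply(names(planted_freq)[planted_freq > 0], function(nm) {
      d <- Filter(function(x) x$name == nm, catalog)[[1]]
      d$locus
    }, character(1)))
  comp_ids_of <- function(allele) {
    names(var_meta)[vapply(var_meta, function(m)
      identical(m$allele, allele) && m$role == "catalog", logical(1))]
  }
  allele_comp_ids <- lapply(
    stats::setNames(nm = names(planted_freq)[planted_freq > 0]), comp_ids_of)
  for (locus in loci) {
    av <- allele_by_locus[[locus]] %||% character()
    pvec <- if (length(av)) planted_freq[av] else numeric()
    wt_p <- 1 - sum(pvec)
    draw <- sample(c(av, ".wildtype"), size = length(accs), replace = TRUE,
                   prob = c(pvec, wt_p))
    het <- stats::runif(length(accs)) < config$het_rate
    for (j in seq_along(accs)) {
      if (draw[j] == ".wildtype") {
        truth[[length(truth) + 1L]] <- data.frame(
          accession = accs[j], locus = locus, status = "wildtype",
          allele = NA_character_, stringsAsFactors = FALSE)
        next
      }
      ids <- allele_comp_ids[[draw[j]]]
      state <- if (het[j]) "het" else "hom_alt"
      calls[ids, j] <- state
      truth[[length(truth) + 1L]] <- data.frame(
        accession = accs[j], locus = locus,
        status = if (het[j]) "heterozygous_carrier" else "named",
        allele = draw[j], stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  # novel deleterious carriers among truth-wildtype accessions
  if (config$novel_del_rate > 0) {
    for (locus in loci) {
      id <- novel_ids[locus]
      if (is.na(id)) next
      wt <- truth$accession[truth$locus == locus & truth$status == "wildtype"]
      carriers <- wt[stats::runif(length(wt)) < config$novel_del_rate]
      if (length(carriers)) {
        calls[id, carriers] <- "hom_alt"
        sel <- truth$locus == locus & truth$accession %in% carriers
        truth$status[sel] <- "novel_deleterious"
        truth$allele[sel] <- paste0("novel-", locus)
      }
    }
  }
  # neutral carriers
  for (id in names(var_meta)) {
    if (var_meta[[id]]$role != "neutral") next
    hom <- stats::runif(length(accs)) < config$neutral_rate
    calls[id, hom] <- "hom_alt"
  }
  # scores concordant with planted bands
  bands <- vapply(var_meta, function(m)
    if (is.null(m$band) || is.na(m$band)) "" else m$band, character(1))
  scores <- numeric()
  del_ids <- names(bands)[bands == "deleterious"]
  tol_ids <- names(bands)[bands == "tolerated"]
  scores[del_ids] <- stats::runif(length(del_ids), 0, 0.0499)
  scores[tol_ids] <- stats::runif(length(tol_ids), 0.05, 1)
  # expected effect category per planted variant (truth definition)
  expected_cat <- vapply(names(var_meta), function(id) {
    m <- var_meta[[id]]
    switch(m$kind,
      synonymous = "same_sense",
      nonsense = "nonsense",
      frameshift = "frameshift",
      intron = "other_noncoding",
      splice_region = "splice_region",
      missense = if (identical(m$band, "deleterious")) "deleterious_missense"
                 else "tolerated_missense",
      if (identical(m$band, "deleterious")) "deleterious_missense"
      else "tolerated_missense")
  }, character(1))
  # apply missingness last; truth reflects the pre-missing state
  if (config$missingness > 0 && length(calls)) {
    mask <- stats::runif(length(calls)) < config$missingness
    calls[mask] <- "missing"
  }
  gmat <- genotype_matrix(calls, var_df)
  consequences <- lapply(seq_len(nrow(var_df)), function(i) {
    locus <- var_meta[[var_df$id[i]]]$locus
    predict_consequence(models[[locus]], genome, var_df[i, , drop = FALSE],
                        ctx = ctxs[[locus]])
  })
  classified <- classify_consequences(consequences, scores)
  manifest <- list(
    seed = config$seed,
    variants = data.frame(
      id = var_df$id,
      locus = vapply(var_meta, `[[`, character(1), "locus"),
      role = vapply(var_meta, `[[`, character(1), "role"),
      allele = vapply(var_meta, function(m)
        if (is.null(m$allele) || is.na(m$allele)) NA_character_
        else m$allele, character(1)),
      kind = vapply(var_meta, `[[`, character(1), "kind"),
      expected_category = unname(expected_cat),
      score = unname(ifelse(var_df$id %in% names(scores),
                            scores[var_df$id], NA_real_)),
      stringsAsFactors = FALSE, row.names = NULL),
    truth_calls = truth,
    allele_frequencies = as.list(planted_freq))
  structure(list(gmat = gmat, scores = scores, consequences = consequences,
                 classified = classified, catalog = syn_catalog,
                 manifest = manifest, models = models, genome = genome,
                 config = config),
            class = "synthetic_panel")
}

#' Simulate phenotypes from the truth manifest
#'
#' `value = baseline + sum(effects over the accession's true alleles) +
#' Normal(0, sigma)`; homozygous (named / novel) alleles contribute their
#' full effect, heterozygous carriers half. With `sigma = 0` the values
#' equal the expectations exactly.
#'
#' @param panel A `synthetic_panel` from [simulate_panel()] (or its
#'   manifest).
#' @param effects Named effect vector keyed by allele name (see
#'   [default_phenotype_effects()]); a planted allele without an effect key
#'   is an error.
#' @param sigma Residual standard deviation.
#' @param seed Integer seed.
#' @param trait,unit,baseline Trait annotation and baseline.
#' @return data.frame `accession`, `trait`, `value`, `unit`, `expectation`.
#' @export
simulate_phenotypes <- function(panel, effects = default_phenotype_effects(),
                                sigma = 10, seed = 1L,
                                trait = "plant_height", unit = "cm",
                                baseline = 250) {
  manifest <- if (inherits(panel, "synthetic_panel")) panel$manifest else panel
  truth <- manifest$truth_calls
  planted <- unique(truth$allele[!is.na(truth$allele)])
  missing_eff <- setdiff(planted, names(effects))
  if (length(missing_eff)) {
    stop("no effect supplied for planted allele(s): ",
         paste(missing_eff, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  accs <- unique(truth$accession)
  expectation <- vapply(accs, function(acc) {
    sub <- truth[truth$accession == acc & !is.na(truth$allele), , drop = FALSE]
    if (nrow(sub) == 0) return(baseline)
    w <- ifelse(sub$status == "heterozygous_carrier", 0.5, 1)
    baseline + sum(w * effects[sub$allele])
  }, numeric(1))
  noise <- if (sigma > 0) stats::rnorm(length(accs), 0, sigma) else 0
  data.frame(accession = accs, trait = trait,
             value = unname(expectation + noise), unit = unit,
             expectation = unname(expectation), stringsAsFactors = FALSE)
}

#' Write a genotype matrix as a VCF 4.2 file
#'
#' @param gmat A [genotype_matrix()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(gmat, path) {
  v <- gmat$variants
  gt_of <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  header <- c("##fileformat=VCFv4.2",
              "##source=sorgscreen-simulate",
              paste0("##contig=<ID=", unique(v$chrom), ">"),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", if (length(gmat$accessions)) "FORMAT",
                      gmat$accessions), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(i) {
    fields <- c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], ".",
                "PASS", ".",
                if (length(gmat$accessions))
                  c("GT", unname(gt_of[gmat$calls[i, ]])))
    paste(fields, collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the reference genome as FASTA and gene models as GFF3
#'
#' @param reference Output of [simulate_reference()].
#' @param fasta_path,gff3_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_reference <- function(reference, fasta_path, gff3_path) {
  seqs <- Biostrings::DNAStringSet(unlist(reference$genome))
  Biostrings::writeXStringSet(seqs, fasta_path)
  lines <- "##gff-version 3"
  for (m in reference$models) {
    attr_gene <- paste0("ID=", m$gene_id)
    tx_id <- paste0(m$gene_id, ".1")
    lines <- c(lines,
      paste(m$chrom, "sorgscreen", "gene", m$span[["start"]],
            m$span[["end"]], ".", m$strand, ".", attr_gene, sep = "\t"),
      paste(m$chrom, "sorgscreen", "mRNA", m$span[["start"]],
            m$span[["end"]], ".", m$strand, ".",
            paste0("ID=", tx_id, ";Parent=", m$gene_id), sep = "\t"))
    for (e in seq_len(nrow(m$exons))) {
      lines <- c(lines,
        paste(m$chrom, "sorgscreen", "exon", m$exons$start[e],
              m$exons$end[e], ".", m$strand, ".",
              paste0("ID=", tx_id, ".exon", e, ";Parent=", tx_id),
              sep = "\t"))
    }
    ce <- coding_exons(m)
    for (e in seq_len(nrow(ce))) {
      lines <- c(lines,
        paste(m$chrom, "sorgscreen", "CDS", ce$start[e], ce$end[e], ".",
              m$strand, "0",
              paste0("ID=", tx_id, ".cds", e, ";Parent=", tx_id),
              sep = "\t"))
    }
  }
  writeLines(lines, gff3_path)
  invisible(list(fasta = fasta_path, gff3 = gff3_path))
}
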