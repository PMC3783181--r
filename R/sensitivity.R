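#' Sensitivity of a profile to a shift in tRNA availability
#'
#' The length-normalised L1 distance between the smoothed time profiles
#' of one gene under a reference condition c1 and a comparison condition
#' c2: S = (1/l) * sum_j |t_j^c1 - t_j^c2|, where l is the number of
#' smoothed positions (the codon count after stop stripping). S is a
#' metric on profiles: nonnegative, symmetric, zero exactly for identical
#' profiles, and satisfying the triangle inequality.
#'
#' @param p_ref \code{speed_profile} under the reference condition.
#' @param p_alt \code{speed_profile} of the same gene, same length and
#'   window, under the comparison condition.
#' @return an object of class \code{sensitivity_result}: one-row data
#'   frame with columns gene, c1, c2, l, S.
#' @export
profile_sensitivity <- function(p_ref, p_alt) {
  if (!identical(p_ref$gene_id, p_alt$gene_id))
    stop("profiles belong to different genes")
  if (length(p_ref$smoothed_times) != length(p_alt$smoothed_times))
    stop("profile length mismatch for gene '", p_ref$gene_id, "'")
  if (p_ref$window != p_alt$window)
    stop("profiles smoothed with different windows")
  l <- length(p_ref$smoothed_times)
  out <- data.frame(gene = p_ref$gene_id,
                    c1 = p_ref$condition, c2 = p_alt$condition,
                    l = l,
                    S = sum(abs(p_ref$smoothed_times -
                                p_alt$smoothed_times)) / l,
                    stringsAsFactors = FALSE)
  class(out) <- c("sensitivity_result", class(out))
  out
}

#' Sensitivity of every gene for every condition against the reference
#'
#' @param profiles_by_condition named list (condition -> named list of
#'   \code{speed_profile}s) as produced by repeated
#'   \code{\link{profile_genes}} calls.
#' @param reference_condition label of the reference condition.
#' @return data frame with one row per gene x non-reference condition
#'   (columns of \code{\link{profile_sensitivity}}).
#' @export
sensitivity_table <- function(profiles_by_condition, reference_condition) {
  if (!reference_condition %in% names(profiles_by_condition))
    stop("reference condition '", reference_condition, "' not present")
  ref <- profiles_by_condition[[reference_condition]]
  alts <- profiles_by_condition[names(profiles_by_condition) !=
                                  reference_condition]
  out <- do.call(rbind, lapply(alts, function(plist) {
    shared <- intersect(names(ref), names(plist))
    do.call(rbind, lapply(shared, function(g)
      profile_sensitivity(ref[[g]], plist[[g]])))
  }))
  rownames(out) <- NULL
  out
}

#' Most- and least-sensitive gene slices
#'
#' Ranks genes by descending sensitivity and returns the top and bottom
#' fractions. Genes tagged untranslated or pseudo are excluded before
#' slicing. Ties at a cut are broken by lexicographic gene id, so slices
#' are deterministic across runs. Slice size is
#' \code{ceiling(fraction * n)}.
#'
#' @param results sensitivity data frame for one condition pair (columns
#'   gene, S).
#' @param fraction slice fraction in (0, 0.5]; default 0.10.
#' @param categories optional named character vector gene -> category used
#'   for the exclusion rule.
#' @return list with \code{most_sensitive} and \code{least_sensitive}
#'   character vectors and the full \code{ranked} data frame (with rank
#'   and percentile columns).
#' @export
rank_and_slice <- function(results, fraction = 0.10, categories = NULL) {
  if (!nrow(results)) stop("empty sensitivity table")
  if (fraction <= 0 || fraction > 0.5)
    stop("fraction must lie in (0, 0.5]")
  keep <- results
  if (!is.null(categories)) {
    excl <- names(categories)[categories %in% c("untranslated", "pseudo")]
    keep <- keep[!keep$gene %in% excl, , drop = FALSE]
  }
  ord <- order(-keep$S, keep$gene)
  ranked <- keep[ord, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  ranked$percentile <- 100 * (1 - (ranked$rank - 1) / nrow(ranked))
  rownames(ranked) <- NULL
  k <- ceiling(fraction * nrow(ranked))
  list(most_sensitive = ranked$gene[seq_len(k)],
       least_sensitive = rev(ranked$gene)[seq_len(k)],
       ranked = ranked)
}

#' One-sided rank test for higher sensitivity in one gene group
#'
#' Wilcoxon rank-sum test of the alternative that group A's sensitivities
#' are stochastically greater than group B's (e.g. non-essential vs
#' essential genes, or untranslated sequences vs coding genes).
#'
#' @param results sensitivity data frame (columns gene, S).
#' @param group_a,group_b disjoint nonempty character vectors of gene ids.
#' @return list with \code{n_a}, \code{n_b}, \code{statistic} (Wilcoxon
#'   W), \code{p_value}, \code{median_a}, \code{median_b}, \code{test}.
#' @export
group_compare <- function(results, group_a, group_b) {
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  sa <- results$S[results$gene %in% group_a]
  sb <- results$S[results$gene %in% group_b]
  if (!length(sa) || !length(sb))
    stop("both groups must contain genes present in the results")
  wt <- suppressWarnings(stats::wilcox.test(sa, sb,
                                            alternative = "greater"))
  list(n_a = length(sa), n_b = length(sb),
       statistic = unname(wt$statistic), p_value = wt$p.value,
       median_a = stats::median(sa), median_b = stats::median(sb),
       test = "one-sided Wilcoxon rank-sum (A > B)")
}

#' Bin the genome and average gene-level statistics per bin
#'
#' The genome is tiled into \code{n_bins} equal-width stretches (the last
#' bin absorbs the remainder); a gene belongs to the bin containing its
#' start coordinate. Per bin the mean sensitivity (one column per
#' condition), mean CAI and mean GC fraction over member genes are
#' reported; empty bins are flagged with NA means and n_genes = 0.
#'
#' @param genes list of \code{coding_sequence}s with
#'   \code{genome_start} set.
#' @param genome_length genome length in bp.
#' @param n_bins number of stretches; default 200.
#' @param sensitivities optional sensitivity data frame over several
#'   conditions (columns gene, c2, S).
#' @param cai_values optional named numeric vector gene -> CAI.
#' @return data frame with columns bin, start, end, n_genes, mean_GC,
#'   mean_CAI and one mean_S column per condition.
#' @export
bin_genome <- function(genes, genome_length, n_bins = 200L,
                       sensitivities = NULL, cai_values = NULL) {
  width <- genome_length %/% n_bins
  starts <- vapply(genes, function(g) {
    if (is.null(g$genome_start))
      stop("gene '", g$id, "' has no genome_start")
    as.numeric(g$genome_start)
  }, numeric(1))
  if (any(starts < 1 | starts > genome_length))
    stop("gene start coordinate outside the genome")
  ids <- vapply(genes, function(g) g$id, character(1))
  bin_of <- pmin((starts - 1) %/% width + 1, n_bins)
  bins <- data.frame(bin = seq_len(n_bins),
                     start = (seq_len(n_bins) - 1) * width + 1,
                     end = c(seq_len(n_bins - 1) * width, genome_length))
  bins$n_genes <- as.integer(table(factor(bin_of, levels = seq_len(n_bins))))
  gc <- vapply(genes, function(g) {
    nt <- strsplit(paste(g$codons, collapse = ""), "")[[1]]
    mean(nt %in% c("G", "C"))
  }, numeric(1))
  mean_by_bin <- function(values) {
    v <- tapply(values, factor(bin_of, levels = seq_len(n_bins)),
                mean, na.rm = TRUE)
    as.numeric(v)
  }
  bins$mean_GC <- mean_by_bin(gc)
  if (!is.null(cai_values))
    bins$mean_CAI <- mean_by_bin(unname(cai_values[ids]))
  if (!is.null(sensitivities)) {
    for (cc in unique(sensitivities$c2)) {
      sv <- sensitivities[sensitivities$c2 == cc, ]
      bins[[paste0("mean_S_", cc)]] <-
        mean_by_bin(sv$S[match(ids, sv$gene)])
    }
  }
  bins
}

#' Codon adaptation index of a coding sequence
#'
#' The geometric mean of relative adaptiveness weights over all
#' translated codons (Sharp-Li definition). Weights are reference-set
#' dependent and user-supplied: within each synonymous family the
#' preferred codon has weight 1. Codons whose weight is exactly zero are
#' floored at 0.01 before taking logs, so a single unused codon does not
#' annihilate the index; amino acids without synonyms carry weight 1 and
#' leave the index unchanged only through the codon count.
#'
#' @param cds a \code{coding_sequence}.
#' @param weights named numeric vector codon -> relative adaptiveness in
#'   [0, 1], covering every sense codon used.
#' @param zero_floor replacement for zero weights; default 0.01.
#' @return CAI value in (0, 1].
#' @export
cai <- function(cds, weights, zero_floor = 0.01) {
  names(weights) <- chartr("Tt", "Uu", toupper(names(weights)))
  w <- weights[cds$codons]
  if (anyNA(w))
    stop("gene '", cds$id, "': codon(s) missing from CAI weights: ",
         paste(unique(cds$codons[is.na(w)]), collapse = ", "))
  w[w <= 0] <- zero_floor
  exp(mean(log(w)))
}

#' Relative adaptiveness weights from a rate table
#'
#' A convenience reference set: within each synonymous codon family the
#' weight is W_i / max(family W), mirroring how a highly-expressed
#' reference set would be summarised. Bundled example weights are also
#' shipped under \code{extdata/example_cai_weights.tsv}.
#'
#' @param rates a \code{rate_table}.
#' @return named numeric vector codon -> weight in [0, 1].
#' @export
cai_weights_from_rates <- function(rates) {
  aa <- vapply(names(rates$W), codon_amino_acid, character(1))
  w <- rates$W
  for (a in unique(aa)) {
    fam <- aa == a
    m <- max(w[fam])
    w[fam] <- if (m > 0) w[fam] / m else 0
  }
  w
}

# standard genetic code, RNA alphabet
codon_amino_acid <- function(codon) {
  GENETIC_CODE <- Biostrings::GENETIC_CODE
  unname(GENETIC_CODE[chartr("U", "T", codon)])
}

#' Spearman correlation between a gene-level covariate and sensitivity
#'
#' Rank correlation with tie handling, its p-value, and the goodness of
#' fit of the rank-rank linear relation (the squared rank correlation).
#'
#' @param x per-gene covariate values (e.g. CAI or GC fraction).
#' @param y per-gene sensitivity values, paired with \code{x}.
#' @return list with \code{rho}, \code{p_value}, \code{r_squared},
#'   \code{n}. Constant input yields NA values with a warning.
#' @export
correlate_sensitivity <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_,
                r_squared = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  rho <- unname(ct$estimate)
  list(rho = rho, p_value = ct$p.value, r_squared = rho^2, n = length(x))
}
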