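# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' The bundled toy organism: eight isoacceptors spanning every pairing
#'
#' A minimal species set chosen so that each wobble pairing kind
#' (A34:U3, G34:C3, U34:A3, C34:G3, G34:U3, I34:C3, I34:A3, U34:G3,
#' L34:A3) and the CGA:ACG override are exercised at least once, with an
#' \emph{E. coli}-like five-member leucine family: Leu1-CAG (reads CUG),
#' Leu2-GAG (CUC, CUU), Leu3-UAG (CUA, CUG), Leu4-CAA (UUG), Leu5-UAA
#' (UUA, UUG), plus Ile2-CAU (lysidine, reads AUA), elongator Met-CAU
#' (AUG) and Arg-ACG (CGU, CGC and the overridden CGA). Together they
#' read 12 sense codons; toy coding sequences use those codons only, so
#' every profile is finite.
#'
#' @return named list of \code{\link{trna_species}}.
#' @export
toy_species <- function() {
  sp <- list(
    trna_species("Leu1", "L", "CAG"),
    trna_species("Leu2", "L", "GAG"),
    trna_species("Leu3", "L", "UAG"),
    trna_species("Leu4", "L", "CAA"),
    trna_species("Leu5", "L", "UAA"),
    trna_species("Ile2", "I", "CAU"),
    trna_species("Met",  "M", "CAU"),
    trna_species("Arg",  "R", "ACG"))
  stats::setNames(sp, vapply(sp, function(s) s$name, character(1)))
}

#' Codons readable by a species set
#'
#' @param species list of \code{\link{trna_species}}; defaults to the toy
#'   organism.
#' @return character vector of codons with at least one recognizer.
#' @export
covered_codons <- function(species = toy_species()) {
  map <- build_recognition_map(species)
  names(map)[vapply(map, nrow, integer(1)) > 0L]
}

#' Specification for deterministic synthetic fixtures
#'
#' One seed fully determines every pool, perturbation and coding
#' sequence generated from the spec.
#'
#' @param seed integer; mandatory source of all randomness.
#' @param n_species species count for generated pools (the toy organism's
#'   8 when its species are used directly).
#' @param n_genes number of background genes; default 12.
#' @param gene_length_range translated length range in codons.
#' @param codon_bias optional named nonnegative weight per codon; uniform
#'   over the covered codons when NULL.
#' @param perturbation list describing the condition shift:
#'   \code{list(mode = "uniform", factors = c(c2 = 0.5, ...))} scales all
#'   concentrations (growth-rate-like), or \code{list(mode = "targeted",
#'   species = c("Leu1", ...), factors = c(c2 = 0.05, ...), other_factors
#'   = c(c2 = 1, ...))} sets charged fractions and applies
#'   \code{\link{effective_availability}} (starvation-like).
#' @return an object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed, n_species = 8L, n_genes = 12L,
                         gene_length_range = c(60L, 120L),
                         codon_bias = NULL,
                         perturbation = list(mode = "uniform",
                                             factors = c(c2 = 0.5))) {
  if (!is.null(codon_bias) &&
      (any(codon_bias < 0) || all(codon_bias == 0)))
    stop("codon bias weights must be nonnegative and not all zero")
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 codon_bias = codon_bias, perturbation = perturbation),
            class = "fixture_spec")
}

#' Generate a reproducible reference tRNA pool
#'
#' Uses the toy organism's species when \code{n_species} is 8 (the
#' default); otherwise generates that many species with random valid
#' anticodons. Concentrations are log-normal-like positive values on the
#' scale of hundreds of molecules, mirroring the spread of measured
#' isoacceptor abundances.
#'
#' For the toy organism, the leucine family's concentrations are
#' calibrated so that the low-rate synonym trio CUU/CUC/CUA and the
#' robust trio CUG/UUG/UUA have equal summed expected times at the
#' reference condition. Under any uniform (growth-rate-like) pool
#' scaling, paired leucine-twin sequences then keep identical
#' sensitivities, whereas differential per-isoacceptor charging
#' (starvation-like) separates them — the contrast the twin constructs
#' of \code{\link{make_cds_set}} are built to expose.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param condition condition label; default \code{"c1"}.
#' @return a \code{\link{trna_pool}}.
#' @export
make_pool <- function(spec, condition = "c1") {
  with_seed(spec$seed, {
    sp <- if (spec$n_species == 8L) toy_species()
          else random_species(spec$n_species)
    conc <- round(stats::rlnorm(length(sp), meanlog = log(400),
                                sdlog = 0.6), 1)
    conc[conc <= 0] <- 1
    names(conc) <- names(sp)
    if (spec$n_species == 8L) {
      # balance the leucine trios: with W(CUC) = c, W(CUU) = (1-sGU) c,
      # W(CUA) = c, sum of 1/W over the sensitive trio is (2 + 1/(1-sGU))/c;
      # give each robust-trio codon adaptiveness w = 3c / that sum
      s <- wobble_rules()$s
      cc <- conc[["Leu2"]]
      conc[["Leu3"]] <- cc
      w <- 3 * cc / (2 + 1 / (1 - s[["G34:U3"]]))
      conc[["Leu5"]] <- w                                   # W(UUA)
      conc[["Leu4"]] <- w * (1 - (1 - s[["U34:G3"]]))       # W(UUG)
      conc[["Leu1"]] <- w - (1 - s[["U34:G3"]]) * cc        # W(CUG)
    }
    trna_pool(condition, sp, conc)
  })
}

# n random species with distinct names and valid non-stop anticodons
random_species <- function(n) {
  all_ac <- as.vector(outer(outer(c("A", "C", "G", "U"),
                                  c("A", "C", "G", "U"), paste0),
                            c("A", "C", "G", "U"), paste0))
  ok <- vapply(all_ac, function(ac) {
    wc_codon <- paste(rev(strsplit(chartr("ACGU", "UGCA", ac), "")[[1]]),
                      collapse = "")
    !wc_codon %in% STOP_CODONS
  }, logical(1))
  acs <- sample(all_ac[ok], n, replace = n > sum(ok))
  sp <- lapply(seq_len(n), function(i) {
    wc_codon <- paste(rev(strsplit(chartr("ACGU", "UGCA", acs[i]),
                                   "")[[1]]), collapse = "")
    trna_species(paste0("Sp", i), codon_amino_acid(wc_codon), acs[i],
                 lysidine = FALSE)
  })
  stats::setNames(sp, vapply(sp, function(s) s$name, character(1)))
}

#' Perturb a reference pool into a multi-condition set
#'
#' Uniform mode emulates growth-rate shifts: every concentration is
#' multiplied by the schedule factor of each condition. Targeted mode
#' emulates amino-acid starvation: the named species' charged fractions
#' are set to the schedule factor (near-depletion with e.g. 0.05) while
#' all other species take \code{other_factors} (default 1), and
#' charging-adjusted availability against the reference is computed.
#'
#' @param pool the reference \code{\link{trna_pool}}.
#' @param spec a \code{\link{fixture_spec}} carrying the perturbation.
#' @return a \code{\link{condition_set}} with the reference pool first.
#' @export
perturb_pool <- function(pool, spec) {
  pert <- spec$perturbation
  factors <- pert$factors
  if (any(factors < 0)) stop("perturbation factors must be >= 0")
  pools <- list(pool)
  if (identical(pert$mode, "uniform")) {
    for (cc in names(factors))
      pools[[cc]] <- trna_pool(cc, pool$species,
                               pool$concentration * factors[[cc]])
  } else if (identical(pert$mode, "targeted")) {
    missing_sp <- setdiff(pert$species, names(pool$species))
    if (length(missing_sp))
      stop("targeted species not in pool: ",
           paste(missing_sp, collapse = ", "))
    other <- pert$other_factors
    for (cc in names(factors)) {
      frac <- stats::setNames(rep(
        if (!is.null(other) && cc %in% names(other)) other[[cc]] else 1,
        length(pool$species)), names(pool$species))
      frac[pert$species] <- factors[[cc]]
      charging <- trna_pool(cc, pool$species, pool$concentration,
                            charged_fraction = pmin(frac, 1))
      pools[[cc]] <- effective_availability(charging, pool)
    }
  } else stop("unknown perturbation mode: ", pert$mode)
  names(pools) <- vapply(pools, function(p) p$condition, character(1))
  condition_set(pools, reference_condition = pool$condition)
}

#' Generate a deterministic coding-sequence set
#'
#' Background genes are random codon strings drawn from the covered
#' codons under the spec's bias, starting with AUG and free of internal
#' stops. Two paired constructs are appended: \code{twin_sensitive} and
#' \code{twin_robust} share one amino-acid sequence and differ only at
#' synonymous leucine positions — the sensitive twin uses the low-rate
#' codons CUU/CUC/CUA, the robust twin the faster, less variable
#' CUG/UUG/UUA.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param species species set defining the usable codons; defaults to the
#'   toy organism.
#' @return named list of \code{coding_sequence} objects.
#' @export
make_cds_set <- function(spec, species = toy_species()) {
  usable <- setdiff(covered_codons(species), "AUG")
  bias <- spec$codon_bias
  if (is.null(bias)) bias <- stats::setNames(rep(1, length(usable)), usable)
  bias <- bias[names(bias) %in% usable]
  if (!length(bias) || all(bias == 0))
    stop("codon bias covers no codon readable by the species set")
  with_seed(spec$seed + 1L, {
    lens <- sample(seq(spec$gene_length_range[1],
                       spec$gene_length_range[2]),
                   spec$n_genes, replace = TRUE)
    genes <- lapply(seq_len(spec$n_genes), function(i) {
      body <- sample(names(bias), lens[i] - 1L, replace = TRUE,
                     prob = bias)
      parse_cds(sprintf("g%02d", i),
                chartr("U", "T", paste(c("AUG", body), collapse = "")),
                strict = FALSE)
    })
    names(genes) <- vapply(genes, function(g) g$id, character(1))

    # leucine twins: identical amino acids, synonymous Leu swap; the
    # trios are cycled so each synonym appears equally often and the
    # twins' summed reference times match under the calibrated toy pool
    sens_leu <- c("CUU", "CUC", "CUA")
    rob_leu <- c("CUG", "UUG", "UUA")
    tlen <- round(mean(spec$gene_length_range))
    non_leu <- setdiff(names(bias), c(sens_leu, rob_leu))
    backbone <- sample(non_leu, tlen - 1L, replace = TRUE)
    n_leu <- 3L * max(1L, round(0.25 * tlen / 3))
    leu_pos <- sort(sample(seq_along(backbone), n_leu))
    sens <- rob <- backbone
    sens[leu_pos] <- rep_len(sens_leu, n_leu)
    rob[leu_pos] <- rep_len(rob_leu, n_leu)
    genes$twin_sensitive <- parse_cds(
      "twin_sensitive", chartr("U", "T", paste(c("AUG", sens),
                                               collapse = "")),
      strict = FALSE)
    genes$twin_robust <- parse_cds(
      "twin_robust", chartr("U", "T", paste(c("AUG", rob),
                                            collapse = "")),
      strict = FALSE)
    genes
  })
}

#' Write a full fixture (FASTA + pool TSVs) from a spec
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
write_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pool <- make_pool(spec)
  cs <- perturb_pool(pool, spec)
  genes <- make_cds_set(spec)
  fasta <- file.path(dir, "cds.fasta")
  pools <- file.path(dir, "pools.tsv")
  amap <- file.path(dir, "anticodons.tsv")
  write_cds_fasta(genes, fasta)
  write_pool_table(cs, pools)
  sp <- cs$pools[[1]]$species
  utils::write.table(
    data.frame(name = names(sp),
               amino_acid = vapply(sp, `[[`, character(1), "amino_acid"),
               anticodon = vapply(sp, `[[`, character(1), "anticodon"),
               inosine = vapply(sp, `[[`, logical(1), "inosine"),
               lysidine = vapply(sp, `[[`, logical(1), "lysidine")),
    amap, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fasta, pools = pools, anticodon_map = amap)
}
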