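#' Define a tRNA isoacceptor species
#'
#' A species is identified by its isoacceptor label (e.g. \code{"Leu1"}),
#' the one-letter amino acid it carries, and its anticodon written 5'->3'
#' over \{A,C,G,U\}. The first anticodon base is the wobble base (position
#' 34), which pairs with the third codon base and is where non-Watson-Crick
#' decoding occurs.
#'
#' Two post-transcriptional conventions matter for bacterial decoding and
#' are carried as flags: an A at position 34 is deaminated to inosine
#' (\code{inosine = TRUE} by default), and the C34 of the second isoleucine
#' isoacceptor is modified to lysidine, switching its reading from AUG to
#' AUA (\code{lysidine}, default \code{TRUE} for an Ile species with
#' anticodon CAU). Initiator methionine tRNA takes no part in elongation
#' and must not be included in pools.
#'
#' @param name isoacceptor label, unique within a pool.
#' @param amino_acid one-letter amino acid code.
#' @param anticodon 3-mer over A/C/G/U (T accepted and converted), 5'->3'.
#' @param inosine treat an A34 as inosine (reads U, C and weakly A)?
#' @param lysidine is C34 modified to lysidine (Ile2-type, reads AUA only)?
#' @return an object of class \code{trna_species}.
#' @examples
#' trna_species("Leu1", "L", "CAG")
#' @export
trna_species <- function(name, amino_acid, anticodon,
                         inosine = TRUE,
                         lysidine = identical(amino_acid, "I") &&
                           toupper(anticodon) %in% c("CAU", "CAT")) {
  anticodon <- chartr("Tt", "Uu", toupper(anticodon))
  if (nchar(anticodon) != 3L || grepl("[^ACGU]", anticodon))
    stop("anticodon must be a 3-mer over A/C/G/U: ", anticodon)
  aa <- toupper(amino_acid)
  if (!aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    stop("amino_acid must be a standard one-letter code, got: ", amino_acid)
  structure(list(name = as.character(name), amino_acid = aa,
                 anticodon = anticodon,
                 wobble_base = substr(anticodon, 1L, 1L),
                 inosine = isTRUE(inosine), lysidine = isTRUE(lysidine)),
            class = "trna_species")
}

#' Construct a condition-labelled tRNA availability pool
#'
#' Concentrations are in whatever units the source table uses; they are
#' carried through unchanged and all downstream rates, times and thresholds
#' inherit those units. Charged fractions, when present, are the
#' aminoacylated proportion of each species and must lie in [0, 1].
#'
#' @param condition condition label (e.g. \code{"mu2.5"}, \code{"t17"}).
#' @param species list of \code{\link{trna_species}}.
#' @param concentration named numeric vector, one nonnegative value per
#'   species name.
#' @param charged_fraction optional named numeric vector in [0, 1] over the
#'   same species names.
#' @return an object of class \code{trna_pool}.
#' @export
trna_pool <- function(condition, species, concentration,
                      charged_fraction = NULL) {
  if (inherits(species, "trna_species")) species <- list(species)
  nm <- vapply(species, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate species names in pool")
  if (is.null(names(concentration)))
    names(concentration) <- nm
  if (!setequal(names(concentration), nm))
    stop("concentration names do not match species names")
  concentration <- concentration[nm]
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("concentrations must be finite and >= 0")
  if (!is.null(charged_fraction)) {
    if (!setequal(names(charged_fraction), nm))
      stop("charged_fraction names do not match species names")
    charged_fraction <- charged_fraction[nm]
    if (any(charged_fraction < 0 | charged_fraction > 1))
      stop("charged fractions must lie in [0, 1]")
  }
  names(species) <- nm
  structure(list(condition = as.character(condition), species = species,
                 concentration = concentration,
                 charged_fraction = charged_fraction),
            class = "trna_pool")
}

#' @export
print.trna_pool <- function(x, ...) {
  cat("<trna_pool> condition:", x$condition,
      "|", length(x$species), "species | total",
      format(sum(x$concentration)), "\n")
  invisible(x)
}

#' Bundle per-condition pools with a designated reference
#'
#' @param pools list of \code{\link{trna_pool}}, all over the same species
#'   set.
#' @param reference_condition label of the reference pool; defaults to the
#'   first pool's condition.
#' @return an object of class \code{condition_set}.
#' @export
condition_set <- function(pools, reference_condition = NULL) {
  if (inherits(pools, "trna_pool")) pools <- list(pools)
  conds <- vapply(pools, function(p) p$condition, character(1))
  if (anyDuplicated(conds)) stop("duplicate condition labels")
  base_nm <- names(pools[[1]]$species)
  for (p in pools)
    if (!identical(names(p$species), base_nm))
      stop("all pools in a condition set must share one species set")
  if (is.null(reference_condition)) reference_condition <- conds[[1]]
  if (!reference_condition %in% conds)
    stop("reference condition '", reference_condition, "' not among pools")
  names(pools) <- conds
  structure(list(reference_condition = reference_condition, pools = pools),
            class = "condition_set")
}

#' @export
print.condition_set <- function(x, ...) {
  cat("<condition_set>", length(x$pools), "conditions:",
      paste(names(x$pools), collapse = ", "),
      "| reference:", x$reference_condition, "\n")
  invisible(x)
}

#' Read an isoacceptor -> anticodon mapping table
#'
#' Expects a TSV with columns \code{name}, \code{amino_acid},
#' \code{anticodon} and optionally \code{inosine}/\code{lysidine} logical
#' columns. A curated map for the \emph{E. coli} K-12 elongator tRNA set is
#' bundled at \code{system.file("extdata", "ecoli_anticodons.tsv",
#' package = "transens")}.
#'
#' @param path path to the TSV file.
#' @return named list of \code{\link{trna_species}}.
#' @export
read_anticodon_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("name", "amino_acid", "anticodon")
  if (!all(need %in% names(tab)))
    stop("anticodon map needs columns: ", paste(need, collapse = ", "))
  sp <- lapply(seq_len(nrow(tab)), function(i) {
    args <- list(name = tab$name[i], amino_acid = tab$amino_acid[i],
                 anticodon = tab$anticodon[i])
    if ("inosine" %in% names(tab)) args$inosine <- as.logical(tab$inosine[i])
    if ("lysidine" %in% names(tab)) args$lysidine <- as.logical(tab$lysidine[i])
    do.call(trna_species, args)
  })
  names(sp) <- tab$name
  sp
}

#' Read a multi-condition tRNA pool table
#'
#' The pool table is a TSV whose first column holds isoacceptor names and
#' whose remaining columns are one condition each (header row = condition
#' labels). An optional parallel table of charged fractions with identical
#' shape may be given. Every isoacceptor must be covered by the anticodon
#' map; unknown names are rejected.
#'
#' @param table path to the concentration TSV.
#' @param anticodon_map path to the anticodon map TSV, or a species list as
#'   returned by \code{\link{read_anticodon_map}}.
#' @param charged_table optional path to a charged-fraction TSV of the same
#'   shape as \code{table}.
#' @param reference_condition label passed to \code{\link{condition_set}};
#'   defaults to the first condition column.
#' @return a \code{\link{condition_set}}.
#' @export
read_pool_table <- function(table, anticodon_map, charged_table = NULL,
                            reference_condition = NULL) {
  species <- if (is.character(anticodon_map))
    read_anticodon_map(anticodon_map) else anticodon_map
  tab <- utils::read.delim(table, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#")
  iso <- as.character(tab[[1]])
  missing_map <- setdiff(iso, names(species))
  if (length(missing_map))
    stop("isoacceptor(s) absent from anticodon map: ",
         paste(missing_map, collapse = ", "))
  conds <- names(tab)[-1]
  conc <- as.matrix(tab[, -1, drop = FALSE])
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("pool table contains negative or non-numeric concentrations")
  rownames(conc) <- iso
  charged <- NULL
  if (!is.null(charged_table)) {
    ctab <- utils::read.delim(charged_table, stringsAsFactors = FALSE,
                              check.names = FALSE, comment.char = "#")
    charged <- as.matrix(ctab[, -1, drop = FALSE])
    rownames(charged) <- as.character(ctab[[1]])
    if (!identical(dim(charged), dim(conc)) ||
        !setequal(rownames(charged), iso) ||
        !identical(colnames(charged), conds))
      stop("charged-fraction table shape does not match pool table")
    charged <- charged[iso, , drop = FALSE]
  }
  sp <- species[iso]
  pools <- lapply(conds, function(cc)
    trna_pool(cc, sp, stats::setNames(conc[, cc], iso),
              charged_fraction = if (is.null(charged)) NULL else
                stats::setNames(charged[, cc], iso)))
  condition_set(pools, reference_condition)
}

#' Write a condition set back to pool-table TSV(s)
#'
#' Inverse of \code{\link{read_pool_table}}: reading a written set yields
#' identical values.
#'
#' @param cs a \code{\link{condition_set}}.
#' @param table output path for the concentration TSV.
#' @param charged_table optional output path for the charged fractions
#'   (written only if every pool carries them).
#' @return \code{table}, invisibly.
#' @export
write_pool_table <- function(cs, table, charged_table = NULL) {
  iso <- names(cs$pools[[1]]$species)
  conc <- vapply(cs$pools, function(p) p$concentration[iso],
                 numeric(length(iso)))
  df <- data.frame(isoacceptor = iso, conc, check.names = FALSE)
  utils::write.table(df, table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(charged_table)) {
    has <- vapply(cs$pools, function(p) !is.null(p$charged_fraction),
                  logical(1))
    if (all(has)) {
      ch <- vapply(cs$pools, function(p) p$charged_fraction[iso],
                   numeric(length(iso)))
      utils::write.table(
        data.frame(isoacceptor = iso, ch, check.names = FALSE),
        charged_table, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(table)
}

#' Split grouped isoacceptors by gene copy number ratios
#'
#' Some measurement sets report two isoacceptors collectively (in
#' \emph{E. coli}: Gly1+Gly2 and Ile1+Ile2). The grouped value is split
#' into member rows in proportion to the members' gene copy numbers
#' (Gly1:Gly2 = 1:1, Ile1:Ile2 = 3:1 for the bundled map); the pool total
#' is conserved exactly.
#'
#' @param pool a \code{\link{trna_pool}} containing the grouped rows.
#' @param ratios named list, one entry per grouped row; each entry is a
#'   list with \code{species} (list of \code{\link{trna_species}} for the
#'   members) and \code{proportions} (numeric, summing to 1).
#' @return a \code{\link{trna_pool}} with group rows replaced by members.
#' @examples
#' gly <- trna_species("Gly", "G", "GCC")
#' p <- trna_pool("c1", list(gly), c(Gly = 1000))
#' members <- list(trna_species("Gly1", "G", "CCC"),
#'                 trna_species("Gly2", "G", "UCC"))
#' split_grouped_isoacceptors(p,
#'   list(Gly = list(species = members, proportions = c(0.5, 0.5))))
#' @export
split_grouped_isoacceptors <- function(pool, ratios) {
  species <- pool$species
  conc <- pool$concentration
  charged <- pool$charged_fraction
  for (grp in names(ratios)) {
    if (!grp %in% names(species))
      stop("grouped isoacceptor '", grp, "' not present in pool")
    r <- ratios[[grp]]
    prop <- r$proportions
    if (abs(sum(prop) - 1) > 1e-9)
      stop("proportions for group '", grp, "' must sum to 1")
    members <- r$species
    mnm <- vapply(members, function(s) s$name, character(1))
    if (length(prop) != length(members))
      stop("proportions and member species differ in length for '", grp, "'")
    idx <- match(grp, names(species))
    species <- append(species[-idx], stats::setNames(members, mnm),
                      after = idx - 1L)
    add <- stats::setNames(conc[[grp]] * prop, mnm)
    conc <- conc[names(conc) != grp]
    conc <- c(conc, add)[names(species)]
    if (!is.null(charged)) {
      chadd <- stats::setNames(rep(charged[[grp]], length(mnm)), mnm)
      charged <- c(charged[names(charged) != grp], chadd)[names(species)]
    }
  }
  trna_pool(pool$condition, species, conc, charged)
}

#' Charging-adjusted effective availability
#'
#' For starvation-style data sets that report charged fractions over time
#' against a single reference concentration measurement, the availability
#' usable in elongation is the charged fraction times the reference
#' concentration, species by species. The result carries no charged
#' fractions of its own.
#'
#' @param charging_pool a \code{\link{trna_pool}} with
#'   \code{charged_fraction} set; its concentrations are ignored.
#' @param reference_pool a \code{\link{trna_pool}} over the same species
#'   providing the concentrations.
#' @return a \code{\link{trna_pool}} labelled with the charging pool's
#'   condition.
#' @export
effective_availability <- function(charging_pool, reference_pool) {
  if (!setequal(names(charging_pool$species), names(reference_pool$species)))
    stop("species sets differ between charging and reference pools")
  if (is.null(charging_pool$charged_fraction))
    stop("charging pool carries no charged fractions")
  nm <- names(reference_pool$species)
  conc <- charging_pool$charged_fraction[nm] *
    reference_pool$concentration[nm]
  trna_pool(charging_pool$condition, reference_pool$species,
            stats::setNames(conc, nm))
}

#' Charging-adjust every pool of a condition set
#'
#' Applies \code{\link{effective_availability}} to each pool carrying
#' charged fractions, against the set's reference pool concentrations.
#' Pools without charged fractions are kept as they are.
#'
#' @param cs a \code{\link{condition_set}} whose pools carry charged
#'   fractions (starvation-style layout: concentration columns hold the
#'   reference measurement).
#' @return a \code{\link{condition_set}} of concentration-only pools.
#' @export
charge_adjust_set <- function(cs) {
  ref <- cs$pools[[cs$reference_condition]]
  pools <- lapply(cs$pools, function(p)
    if (is.null(p$charged_fraction)) p
    else effective_availability(p, trna_pool(p$condition, ref$species,
                                             ref$concentration)))
  condition_set(pools, cs$reference_condition)
}
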