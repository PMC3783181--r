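RNA_BASES <- c("U", "C", "A", "G")
STOP_CODONS <- c("UAA", "UAG", "UGA")

#' All 61 sense codons, RNA alphabet, 5'->3'
#' @return character vector of codons.
#' @export
sense_codons <- function() {
  all64 <- as.vector(outer(outer(RNA_BASES, RNA_BASES, paste0),
                           RNA_BASES, paste0))
  sort(setdiff(all64, STOP_CODONS))
}

rna_complement <- function(x) chartr("ACGU", "UGCA", x)

#' Wobble pairing constraints (s-values)
#'
#' Selective constraints on codon-anticodon coupling efficiency, one per
#' wobble pairing kind, each in [0, 1] (0 = perfect Watson-Crick
#' coupling). Defaults follow the standard prokaryotic tRNA-adaptation-
#' index parameterisation: Watson-Crick pairings 0, G34:U3 = 0.41,
#' I34:C3 = 0.28, I34:A3 = 0.9999, U34:G3 = 0.68 and the lysidine
#' pairing L34:A3 = 0.89. One override is on by default: recognition of
#' CGA by the ACG anticodon uses s = 0.9172, because the generic
#' inosine:A constraint leaves that codon two orders of magnitude slower
#' than any other and dominates every downstream statistic.
#'
#' @param s named numeric vector replacing any of the default pairing
#'   constraints.
#' @param overrides named numeric vector of per-pairing overrides keyed
#'   \code{"CODON:ANTICODON"}; set to \code{NULL} to drop the CGA:ACG
#'   default.
#' @return an object of class \code{wobble_rules}.
#' @examples
#' wobble_rules()                          # defaults
#' wobble_rules(s = c("G34:U3" = 0.5))     # retuned G:U wobble
#' @export
wobble_rules <- function(s = NULL, overrides = c("CGA:ACG" = 0.9172)) {
  defaults <- c("A34:U3" = 0, "G34:C3" = 0, "U34:A3" = 0, "C34:G3" = 0,
                "G34:U3" = 0.41, "I34:C3" = 0.28, "I34:A3" = 0.9999,
                "U34:G3" = 0.68, "L34:A3" = 0.89)
  if (!is.null(s)) {
    bad <- setdiff(names(s), names(defaults))
    if (length(bad)) stop("unknown pairing kind(s): ",
                          paste(bad, collapse = ", "))
    defaults[names(s)] <- s
  }
  if (any(defaults < 0 | defaults > 1)) stop("s-values must lie in [0, 1]")
  if (!is.null(overrides) && any(overrides < 0 | overrides > 1))
    stop("override s-values must lie in [0, 1]")
  structure(list(s = defaults, overrides = overrides),
            class = "wobble_rules")
}

#' Read s-values and overrides from a key/value config file
#'
#' Lines of the form \code{G34:U3 = 0.41} set pairing constraints; lines
#' of the form \code{CGA:ACG = 0.9172} (codon first) set per-interaction
#' overrides. Blank lines and \code{#} comments are ignored.
#'
#' @param path config file path.
#' @return a \code{\link{wobble_rules}}.
#' @export
read_wobble_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- as.numeric(vapply(kv, `[`, character(1), 2L))
  is_pairing <- grepl("^[AGUCIL]34:[ACGU]3$", keys)
  s <- if (any(is_pairing)) stats::setNames(vals[is_pairing],
                                            keys[is_pairing]) else NULL
  ov <- if (any(!is_pairing)) stats::setNames(vals[!is_pairing],
                                              keys[!is_pairing]) else NULL
  wobble_rules(s = s, overrides = ov)
}

#' Build the codon -> recognizing-species map under Crick wobble rules
#'
#' For each sense-codon box x1x2N the third position is decoded as:
#' codon ending U by anticodon wobble A (A34:U3) and G (G34:U3); ending C
#' by G (G34:C3) and A-read-as-inosine (I34:C3); ending A by U (U34:A3)
#' and inosine (I34:A3); ending G by C (C34:G3) and U (U34:G3).
#' Anticodon positions 35 and 36 must pair Watson-Crick with codon
#' positions 2 and 1. Two bacterial exceptions are enforced: AUA is read
#' only by the lysidine-modified Ile species (pairing L34:A3), and AUG
#' only by elongator Met. Stop codons are absent from the map.
#'
#' @param species list of \code{\link{trna_species}}.
#' @return an object of class \code{recognition_map}: a named list over
#'   sense codons, each element a data frame with columns \code{species}
#'   and \code{pairing}.
#' @export
build_recognition_map <- function(species) {
  if (inherits(species, "trna_species")) species <- list(species)
  entries <- lapply(sense_codons(), function(...) {
    data.frame(species = character(0), pairing = character(0),
               stringsAsFactors = FALSE)
  })
  names(entries) <- sense_codons()
  add <- function(codon, sp_name, pairing) {
    entries[[codon]] <<- rbind(entries[[codon]],
                               data.frame(species = sp_name,
                                          pairing = pairing,
                                          stringsAsFactors = FALSE))
  }
  for (sp in species) {
    ac <- sp$anticodon
    # codon positions 1,2 from anticodon positions 36,35 (antiparallel)
    c12 <- paste0(rna_complement(substr(ac, 3L, 3L)),
                  rna_complement(substr(ac, 2L, 2L)))
    w <- sp$wobble_base
    if (sp$lysidine) {
      # lysidine switches C34 reading from G3 to A3; AUA only
      codon <- paste0(c12, "A")
      if (codon == "AUA") add(codon, sp$name, "L34:A3")
      next
    }
    reads <- switch(w,
      A = if (sp$inosine)
            list(c("U", "A34:U3"), c("C", "I34:C3"), c("A", "I34:A3"))
          else list(c("U", "A34:U3")),
      G = list(c("C", "G34:C3"), c("U", "G34:U3")),
      U = list(c("A", "U34:A3"), c("G", "U34:G3")),
      C = list(c("G", "C34:G3")))
    for (rd in reads) {
      codon <- paste0(c12, rd[[1]])
      if (codon %in% STOP_CODONS) next
      if (codon == "AUA") next                     # lysidine species only
      if (codon == "AUG" && sp$amino_acid != "M") next  # elongator Met only
      add(codon, sp$name, rd[[2]])
    }
  }
  structure(entries, class = "recognition_map")
}

#' Per-codon adaptiveness from a pool and recognition map
#'
#' The adaptiveness of codon i is the availability-weighted sum over the
#' tRNA species recognizing it, each discounted by its pairing
#' constraint: W_i = sum_j (1 - s_ij) * conc_j. Per-interaction overrides
#' (by default CGA:ACG -> 0.9172) replace the generic constraint for that
#' codon-anticodon pair. Codons with no recognizer at positive
#' availability get W = 0.
#'
#' @param pool a \code{\link{trna_pool}} covering every species in the map.
#' @param map a \code{\link{build_recognition_map}} result; built from the
#'   pool's species when omitted.
#' @param rules a \code{\link{wobble_rules}}.
#' @return an object of class \code{adaptiveness_table}: list with
#'   \code{W} (named numeric over sense codons) and \code{condition}.
#' @export
adaptiveness <- function(pool, map = NULL, rules = wobble_rules()) {
  if (is.null(map)) map <- build_recognition_map(pool$species)
  conc <- pool$concentration
  W <- vapply(names(map), function(codon) {
    ent <- map[[codon]]
    if (nrow(ent) == 0L) return(0)
    missing_sp <- setdiff(ent$species, names(conc))
    if (length(missing_sp))
      stop("species in recognition map missing from pool: ",
           paste(missing_sp, collapse = ", "))
    s <- rules$s[ent$pairing]
    if (!is.null(rules$overrides)) {
      key <- paste0(codon, ":",
                    vapply(ent$species,
                           function(n) pool$species[[n]]$anticodon,
                           character(1)))
      hit <- key %in% names(rules$overrides)
      s[hit] <- rules$overrides[key[hit]]
    }
    sum((1 - s) * conc[ent$species])
  }, numeric(1))
  structure(list(W = W, condition = pool$condition),
            class = "adaptiveness_table")
}

#' Normalised codon translation rates and expected times
#'
#' Adaptiveness values are normalised to coupling probabilities and scaled
#' by the total pool size: r_i = (W_i / sum_j W_j) * sum_k conc_k, so the
#' rates sum to the total tRNA concentration and carry its units. The
#' expected time on a codon is t_i = 1 / r_i (exponential waiting for a
#' matching charged tRNA). Codons with W = 0 get r = 0 and t = Inf; any
#' profile containing one is flagged unusable downstream.
#'
#' @param W an \code{adaptiveness_table} from \code{\link{adaptiveness}}.
#' @param pool the \code{\link{trna_pool}} the table was computed from.
#' @return an object of class \code{rate_table}: list with named numeric
#'   \code{r} and \code{t} over sense codons, \code{W}, \code{total_pool}
#'   and \code{condition}.
#' @export
translation_rates <- function(W, pool) {
  w <- W$W
  total <- sum(pool$concentration)
  sw <- sum(w)
  if (sw <= 0) stop("all adaptiveness values are zero; cannot normalise")
  r <- w / sw * total
  t <- ifelse(r > 0, 1 / r, Inf)
  structure(list(r = r, t = t, W = w, total_pool = total,
                 condition = W$condition),
            class = "rate_table")
}

#' One-call rate table from a pool
#'
#' Convenience composition of \code{\link{build_recognition_map}},
#' \code{\link{adaptiveness}} and \code{\link{translation_rates}}.
#'
#' @inheritParams adaptiveness
#' @return a \code{rate_table}.
#' @export
codon_rates <- function(pool, map = NULL, rules = wobble_rules()) {
  translation_rates(adaptiveness(pool, map, rules), pool)
}

#' @export
print.rate_table <- function(x, ...) {
  cat("<rate_table> condition:", x$condition,
      "| total pool", format(x$total_pool),
      "|", sum(x$r > 0), "of", length(x$r), "codons with positive rate\n")
  invisible(x)
}

#' Per-codon rate fold changes between two conditions
#'
#' Ratio r_alt / r_ref per codon. Codons with an undefined (zero) rate in
#' either table are excluded and returned in the \code{excluded}
#' attribute.
#'
#' @param rates_ref reference \code{rate_table}.
#' @param rates_alt comparison \code{rate_table} over the same codons.
#' @return named numeric vector of ratios, with attribute
#'   \code{excluded} naming dropped codons.
#' @export
fold_changes <- function(rates_ref, rates_alt) {
  if (!setequal(names(rates_ref$r), names(rates_alt$r)))
    stop("rate tables cover different codon sets")
  codons <- names(rates_ref$r)
  a <- rates_ref$r[codons]
  b <- rates_alt$r[codons]
  ok <- a > 0 & b > 0
  out <- b[ok] / a[ok]
  attr(out, "excluded") <- codons[!ok]
  out
}

#' Export a rate table as TSV
#'
#' Columns: codon, W, r, t, condition.
#'
#' @param rates a \code{rate_table}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_rate_table <- function(rates, path) {
  df <- data.frame(codon = names(rates$r), W = unname(rates$W),
                   r = unname(rates$r), t = unname(rates$t),
                   condition = rates$condition)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
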