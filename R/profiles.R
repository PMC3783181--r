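#' Build a coding sequence object from nucleotides
#'
#' Accepts DNA or RNA (T and U equivalent), splits 5'->3' into codons and
#' strips a trailing stop codon from the translated codon list. Strict
#' validation (the default for \code{category = "none"} or
#' \code{"essential"}) requires length divisible by 3, a start codon and
#' no internal stop codons. Sequences tagged \code{"untranslated"} skip
#' codon validation entirely: they are profiled as if coding, in frame
#' from their annotated start.
#'
#' @param id gene identifier.
#' @param nucleotides nucleotide string over A/C/G/T/U.
#' @param category one of \code{"none"}, \code{"essential"},
#'   \code{"untranslated"}, \code{"pseudo"}.
#' @param strict validate start codon and internal stops? Ignored (off)
#'   for untranslated sequences.
#' @param genome_start optional 1-based genomic start coordinate.
#' @param strand optional \code{"+"} or \code{"-"}. Minus-strand input is
#'   assumed to be given already in coding orientation by
#'   \code{\link{read_cds_fasta}}; use \code{reverse_complement = TRUE}
#'   here to flip a genome-orientation string first.
#' @param reverse_complement reverse-complement before codon splitting.
#' @return an object of class \code{coding_sequence} with fields
#'   \code{id}, \code{codons} (translated codons, stop stripped),
#'   \code{category}, \code{genome_start}, \code{strand}.
#' @examples
#' parse_cds("toy", "ATGAAATAA")$codons   # "AUG" "AAA"
#' @export
parse_cds <- function(id, nucleotides, category = c("none", "essential",
                                                    "untranslated",
                                                    "pseudo"),
                      strict = TRUE, genome_start = NULL, strand = NULL,
                      reverse_complement = FALSE) {
  category <- match.arg(category)
  nt <- chartr("Tt", "Uu", toupper(gsub("\\s", "", nucleotides)))
  if (grepl("[^ACGU]", nt)) {
    warning("gene '", id, "' contains ambiguous bases; flagged and skipped")
    return(NULL)
  }
  if (reverse_complement)
    nt <- paste(rev(strsplit(chartr("ACGU", "UGCA", nt), "")[[1]]),
                collapse = "")
  if (nchar(nt) %% 3L != 0L) {
    if (strict && category != "untranslated")
      stop("gene '", id, "': length ", nchar(nt), " not divisible by 3")
    nt <- substr(nt, 1L, nchar(nt) - nchar(nt) %% 3L)
  }
  codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
  if (length(codons) && codons[length(codons)] %in% STOP_CODONS)
    codons <- codons[-length(codons)]
  if (strict && category %in% c("none", "essential")) {
    if (!length(codons)) stop("gene '", id, "': empty after stop stripping")
    if (!codons[1] %in% c("AUG", "GUG", "UUG"))
      stop("gene '", id, "': first codon ", codons[1],
           " is not a bacterial start codon")
    if (any(codons %in% STOP_CODONS))
      stop("gene '", id, "': internal stop codon")
  }
  structure(list(id = as.character(id), codons = codons,
                 category = category,
                 genome_start = genome_start, strand = strand),
            class = "coding_sequence")
}

#' Read coding sequences from a multi-FASTA file
#'
#' Each record becomes one \code{\link{parse_cds}} call; records failing
#' validation are dropped with a warning when \code{strict = FALSE} would
#' not apply. Record ids are the first whitespace-separated token of the
#' FASTA header.
#'
#' @param path FASTA file of CDS nucleotide sequences (coding
#'   orientation).
#' @param categories optional named character vector id -> category.
#' @param strict passed to \code{\link{parse_cds}}.
#' @return named list of \code{coding_sequence} objects.
#' @export
read_cds_fasta <- function(path, categories = NULL, strict = TRUE) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  out <- stats::setNames(vector("list", length(seqs)), ids)
  for (i in seq_along(seqs)) {
    cat_i <- if (!is.null(categories) && ids[i] %in% names(categories))
      categories[[ids[i]]] else "none"
    out[[i]] <- parse_cds(ids[i], as.character(seqs[[i]]),
                          category = cat_i, strict = strict)
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Write coding sequences to FASTA
#'
#' @param cds_list list of \code{coding_sequence} objects.
#' @param path output path.
#' @param append_stop append a UAA stop codon to each record.
#' @return \code{path}, invisibly.
#' @export
write_cds_fasta <- function(cds_list, path, append_stop = TRUE) {
  nt <- vapply(cds_list, function(x)
    chartr("U", "T", paste0(paste(x$codons, collapse = ""),
                            if (append_stop) "UAA" else "")), character(1))
  ids <- vapply(cds_list, function(x) x$id, character(1))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(nt, ids)), path)
  invisible(path)
}

#' Raw per-codon time profile
#'
#' Looks up the expected translation time of every translated codon in
#' sequence order. A codon with infinite time (no recognizing tRNA at
#' positive availability) makes the whole profile unusable; it is
#' returned with attribute \code{usable = FALSE} and a warning.
#'
#' @param cds a \code{coding_sequence}.
#' @param rates a \code{rate_table}.
#' @return numeric vector of times, length = number of translated codons,
#'   with attribute \code{usable}.
#' @export
raw_profile <- function(cds, rates) {
  if (!length(cds$codons)) stop("gene '", cds$id, "': empty codon list")
  unknown <- setdiff(cds$codons, names(rates$t))
  if (length(unknown))
    stop("gene '", cds$id, "': codon(s) absent from rate table: ",
         paste(unique(unknown), collapse = ", "))
  tt <- unname(rates$t[cds$codons])
  usable <- all(is.finite(tt))
  if (!usable)
    warning("gene '", cds$id,
            "': infinite-time codon; profile flagged unusable")
  attr(tt, "usable") <- usable
  tt
}

#' Centered sliding-window mean with truncated edges
#'
#' Position j receives the arithmetic mean of the input over all indices
#' within half a window of j; near the termini the effective window
#' shrinks so that output length equals input length. Window 1 is the
#' identity.
#'
#' @param times numeric vector.
#' @param window odd positive integer; default 19 codons (ribosomal
#'   footprint scale).
#' @return numeric vector, same length as \code{times}.
#' @export
smooth_times <- function(times, window = 19L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive integer")
  n <- length(times)
  if (n == 0L) stop("empty profile")
  h <- window %/% 2L
  cs <- c(0, cumsum(times))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Translational speed profile of one gene under one condition
#'
#' Composition of \code{\link{raw_profile}} and \code{\link{smooth_times}};
#' speed is the elementwise reciprocal of the smoothed time.
#'
#' @param cds a \code{coding_sequence}.
#' @param rates a \code{rate_table}.
#' @param window odd smoothing window in codons.
#' @return an object of class \code{speed_profile}: list with
#'   \code{gene_id}, \code{condition}, \code{raw_times},
#'   \code{smoothed_times}, \code{speed}, \code{window}, \code{usable}.
#' @export
speed_profile <- function(cds, rates, window = 19L) {
  raw <- raw_profile(cds, rates)
  sm <- smooth_times(raw, window)
  structure(list(gene_id = cds$id, condition = rates$condition,
                 raw_times = as.numeric(raw), smoothed_times = sm,
                 speed = 1 / sm, window = as.integer(window),
                 usable = attr(raw, "usable")),
            class = "speed_profile")
}

#' @export
print.speed_profile <- function(x, ...) {
  cat("<speed_profile>", x$gene_id, "@", x$condition,
      "|", length(x$raw_times), "codons | window", x$window,
      if (!x$usable) "| UNUSABLE" else "", "\n")
  invisible(x)
}

#' Profile a set of genes under one condition
#'
#' @param cds_list list of \code{coding_sequence} objects.
#' @param rates a \code{rate_table}.
#' @param window odd smoothing window.
#' @param drop_unusable drop profiles containing infinite times (with one
#'   summary warning) instead of keeping them flagged.
#' @return named list of \code{speed_profile} objects.
#' @export
profile_genes <- function(cds_list, rates, window = 19L,
                          drop_unusable = TRUE) {
  profs <- lapply(cds_list, function(cds)
    suppressWarnings(speed_profile(cds, rates, window)))
  names(profs) <- vapply(cds_list, function(x) x$id, character(1))
  if (drop_unusable) {
    bad <- !vapply(profs, function(p) p$usable, logical(1))
    if (any(bad))
      warning(sum(bad), " profile(s) excluded (infinite-time codons): ",
              paste(names(profs)[bad], collapse = ", "))
    profs <- profs[!bad]
  }
  profs
}

#' Export per-gene profiles as a long TSV
#'
#' Columns: gene, position (1-based codon index), codon, raw_time,
#' smoothed_time, speed, condition.
#'
#' @param profiles named list of \code{speed_profile}s.
#' @param cds_list the matching coding sequences (for codon identities).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_profile_table <- function(profiles, cds_list, path) {
  cds_ids <- vapply(cds_list, function(x) x$id, character(1))
  rows <- lapply(profiles, function(p) {
    cds <- cds_list[[match(p$gene_id, cds_ids)]]
    data.frame(gene = p$gene_id,
               position = seq_along(p$raw_times),
               codon = cds$codons,
               raw_time = p$raw_times,
               smoothed_time = p$smoothed_times,
               speed = p$speed,
               condition = p$condition)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
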