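# Independent brute-force oracles. These re-derive the model quantities by
# literal enumeration, sharing no code path with the package internals.

# flat table of every admissible wobble pairing: anticodon base 34 (with
# inosine/lysidine reading), codon base 3, pairing label
oracle_pairing_table <- data.frame(
  w34 = c("A", "G", "G", "U", "C", "A", "A", "U", "L"),
  c3  = c("U", "C", "U", "A", "G", "C", "A", "G", "A"),
  kind = c("A34:U3", "G34:C3", "G34:U3", "U34:A3", "C34:G3",
           "I34:C3", "I34:A3", "U34:G3", "L34:A3"),
  stringsAsFactors = FALSE)

oracle_revcomp <- function(x)
  paste(rev(strsplit(chartr("ACGU", "UGCA", x), "")[[1]]), collapse = "")

# all sense codons a species decodes, with pairing labels, by scanning
# all 64 codons
oracle_decodes <- function(sp) {
  bases <- c("A", "C", "G", "U")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  stops <- c("UAA", "UAG", "UGA")
  out <- NULL
  for (codon in setdiff(all64, stops)) {
    # positions 35/36 must be the Watson-Crick reverse complement of
    # codon positions 2/1
    if (substr(oracle_revcomp(codon), 2, 3) != substr(sp$anticodon, 2, 3))
      next
    w <- substr(sp$anticodon, 1, 1)
    eff_w <- if (sp$lysidine) "L" else w
    c3 <- substr(codon, 3, 3)
    hits <- oracle_pairing_table[
      oracle_pairing_table$c3 == c3 &
        oracle_pairing_table$w34 == eff_w, , drop = FALSE]
    if (eff_w == "A" && !sp$inosine)
      hits <- hits[hits$kind == "A34:U3", , drop = FALSE]
    if (eff_w == "L")
      hits <- hits[hits$kind == "L34:A3", , drop = FALSE]
    if (codon == "AUA" && !sp$lysidine) next
    if (codon == "AUG" && sp$amino_acid != "M") next
    if (nrow(hits))
      out <- rbind(out, data.frame(codon = codon, kind = hits$kind,
                                   stringsAsFactors = FALSE))
  }
  out
}

# literal adaptiveness + rate computation over a pool
oracle_rates <- function(pool, rules = wobble_rules()) {
  codons <- sense_codons()
  W <- setNames(numeric(length(codons)), codons)
  for (sp in pool$species) {
    dec <- oracle_decodes(sp)
    if (is.null(dec)) next
    for (i in seq_len(nrow(dec))) {
      s <- rules$s[[dec$kind[i]]]
      key <- paste0(dec$codon[i], ":", sp$anticodon)
      if (!is.null(rules$overrides) && key %in% names(rules$overrides))
        s <- rules$overrides[[key]]
      W[dec$codon[i]] <- W[dec$codon[i]] +
        (1 - s) * pool$concentration[[sp$name]]
    }
  }
  C <- sum(pool$concentration)
  r <- W / sum(W) * C
  list(W = W, r = r, t = ifelse(r > 0, 1 / r, Inf))
}

# O(n*w) windowed mean with truncated edges
oracle_smooth <- function(x, window) {
  h <- window %/% 2
  n <- length(x)
  vapply(seq_len(n), function(j) {
    idx <- max(1, j - h):min(n, j + h)
    mean(x[idx])
  }, numeric(1))
}

# run-length drop statistics on a logical below-threshold vector
oracle_drops <- function(below) {
  runs <- 0L
  lens <- integer(0)
  cur <- 0L
  for (b in below) {
    if (b) cur <- cur + 1L
    else {
      if (cur > 0L) { runs <- runs + 1L; lens <- c(lens, cur) }
      cur <- 0L
    }
  }
  if (cur > 0L) { runs <- runs + 1L; lens <- c(lens, cur) }
  list(count = runs, max_len = if (length(lens)) max(lens) else 0L,
       all_below = all(below))
}

# random species set for property tests (anticodons whose Watson-Crick
# codon is not a stop; no lysidine so generic rules apply)
random_test_species <- function(n) {
  bases <- c("A", "C", "G", "U")
  all_ac <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  ok <- vapply(all_ac, function(ac)
    !oracle_revcomp(ac) %in% c("UAA", "UAG", "UGA"), logical(1))
  acs <- sample(all_ac[ok], n)
  aa_of <- function(codon)
    unname(Biostrings::GENETIC_CODE[chartr("U", "T", codon)])
  sp <- lapply(seq_len(n), function(i)
    trna_species(paste0("T", i), aa_of(oracle_revcomp(acs[i])), acs[i],
                 lysidine = FALSE))
  setNames(sp, paste0("T", seq_len(n)))
}

random_test_pool <- function(n, condition = "c1") {
  sp <- random_test_species(n)
  trna_pool(condition, sp,
            setNames(round(runif(n, 10, 1000), 2), names(sp)))
}
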