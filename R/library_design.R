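## SSM library design: variant-space enumeration and NNK primer layout for
## two-step overlap PCR.

#' Construct a coding sequence object
#'
#' Validates an open reading frame (ORF) and attaches its translation.
#' The ORF must start with ATG, have length divisible by 3, and contain
#' no internal stop codon (a single terminal stop is allowed and trimmed
#' from the protein).
#'
#' @param nt DNA string (A/C/G/T only).
#' @param id Identifier carried through to outputs.
#' @return An object of class `coding_sequence` with elements `id`, `nt`
#'   and `protein` (amino-acid string, no stop symbol).
#' @examples
#' cds <- coding_sequence("ATGGCTAAA")
#' cds$protein
#' @export
coding_sequence <- function(nt, id = "orf") {
  nt <- toupper(nt)
  assert_dna(nt, "ORF")
  if (nchar(nt) %% 3L != 0L) stop("ORF length not divisible by 3", call. = FALSE)
  if (substr(nt, 1L, 3L) != "ATG") stop("ORF must begin with ATG", call. = FALSE)
  prot <- translate_nt(nt)
  core <- sub("\\*$", "", prot)
  if (grepl("\\*", core)) stop("ORF contains an internal stop codon", call. = FALSE)
  structure(list(id = id, nt = nt, protein = core), class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("coding_sequence '%s': %d nt, %d aa\n", x$id, nchar(x$nt),
              nchar(x$protein)))
  invisible(x)
}

#' Read the first record of a FASTA file as a coding sequence
#'
#' @param path FASTA file with one (or more; only the first is used) ORF.
#' @return A [coding_sequence()].
#' @export
read_orf_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  coding_sequence(as.character(ss[[1L]]), id = names(ss)[1L])
}

#' Enumerate a site-saturation mutagenesis variant space
#'
#' For every protein position not excluded, pairs the position with each of
#' the 20 standard amino acids. The wild-type identity is included among the
#' 20 and tagged (`is_wt`), so a protein of length 185 with the start
#' methionine excluded yields exactly 184 x 20 = 3680 specs.
#'
#' @param protein Amino-acid string (standard 20-letter alphabet).
#' @param exclude Integer vector of 1-based positions to leave out
#'   (typically `1` for the start methionine).
#' @return A data.frame with columns `position`, `wt_aa`, `mut_aa`,
#'   `is_wt` (logical) and `codon` (an NNK-compatible codon encoding
#'   `mut_aa`).
#' @examples
#' nrow(enumerate_ssm(strrep("A", 185), exclude = 1))  # 3680
#' @export
enumerate_ssm <- function(protein, exclude = integer()) {
  if (!is.character(protein) || length(protein) != 1L || nchar(protein) == 0L)
    stop("protein must be a non-empty string", call. = FALSE)
  aa <- strsplit(protein, "")[[1L]]
  bad <- which(!aa %in% AA_ORDER[1:20])
  if (length(bad))
    stop("invalid amino-acid character at position(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  exclude <- as.integer(exclude)
  if (length(exclude) && (any(exclude < 1L) || any(exclude > length(aa))))
    stop("exclude contains positions outside 1..", length(aa), call. = FALSE)
  keep <- setdiff(seq_along(aa), exclude)
  if (!length(keep)) {
    return(data.frame(position = integer(), wt_aa = character(),
                      mut_aa = character(), is_wt = logical(),
                      codon = character(), stringsAsFactors = FALSE))
  }
  muts <- AA_ORDER[1:20]
  out <- data.frame(
    position = rep(keep, each = 20L),
    wt_aa    = rep(aa[keep], each = 20L),
    mut_aa   = rep(muts, times = length(keep)),
    stringsAsFactors = FALSE
  )
  out$is_wt <- out$wt_aa == out$mut_aa
  out$codon <- nnk_codon_for(out$mut_aa)
  out
}

#' Expand a degenerate IUPAC codon
#'
#' Expands an IUPAC triplet (e.g. `"NNK"`) into all concrete codons it
#' covers, each mapped to its standard-genetic-code translation
#' (stop = `"*"`).
#'
#' @param codon_template Three-letter IUPAC string.
#' @return Named character vector: names are concrete codons, values the
#'   encoded amino acids.
#' @examples
#' length(expand_degenerate("NNK"))  # 32
#' @export
expand_degenerate <- function(codon_template) {
  codon_template <- toupper(codon_template)
  if (!is.character(codon_template) || length(codon_template) != 1L ||
      nchar(codon_template) != 3L)
    stop("codon_template must be a single 3-letter string", call. = FALSE)
  letters3 <- strsplit(codon_template, "")[[1L]]
  if (!all(letters3 %in% names(IUPAC_NT)))
    stop("non-IUPAC character in codon template: ", codon_template,
         call. = FALSE)
  grid <- expand.grid(IUPAC_NT[[letters3[1L]]], IUPAC_NT[[letters3[2L]]],
                      IUPAC_NT[[letters3[3L]]], stringsAsFactors = FALSE)
  codons <- paste0(grid[[1L]], grid[[2L]], grid[[3L]])
  setNames(unname(GENETIC_CODE_1[codons]), codons)
}

## first NNK codon (lexicographic) encoding each amino acid / stop
nnk_codon_for <- function(aa) {
  tab <- expand_degenerate("NNK")
  first <- tapply(names(tab), tab, function(x) sort(x)[1L])
  unname(first[aa])
}

#' Design an NNK primer pair for one SSM position
#'
#' Lays out the two-step overlap-PCR primers for a single position: a
#' forward primer carrying the NNK codon flanked by `flank_len` template
#' nucleotides on each side, and a reverse primer that reverse-complements
#' a template window ending just 5' of the mutated codon (so it partially
#' overlaps the forward primer's upstream flank).
#'
#' @param cds A [coding_sequence()].
#' @param position 1-based protein position to saturate (the start
#'   methionine, position 1, is rejected).
#' @param flank_len Template nucleotides on each side of the NNK codon
#'   (default 18).
#' @return A list of class `primer_set` with `position`, `fwd_nnk`,
#'   `rev_overlap`, `flank_len`.
#' @export
design_nnk_primers <- function(cds, position, flank_len = 18L) {
  stopifnot(inherits(cds, "coding_sequence"))
  position <- as.integer(position)
  flank_len <- as.integer(flank_len)
  L <- nchar(cds$protein)
  if (position == 1L)
    stop("position 1 (start methionine) is excluded from SSM", call. = FALSE)
  if (position < 2L || position > L)
    stop("position out of range 2..", L, call. = FALSE)
  cstart <- 3L * (position - 1L) + 1L   # first nt of the codon
  if (cstart - flank_len < 1L || cstart + 2L + flank_len > nchar(cds$nt))
    stop("flank_len extends past the template", call. = FALSE)
  up <- substr(cds$nt, cstart - flank_len, cstart - 1L)
  down <- substr(cds$nt, cstart + 3L, cstart + 2L + flank_len)
  fwd <- paste0(up, "NNK", down)
  ## reverse primer: revcomp of the window ending just 5' of the codon,
  ## twice the flank so that it overlaps half of the forward primer's flank
  rev_start <- max(1L, cstart - 2L * flank_len)
  rev_window <- substr(cds$nt, rev_start, cstart - 1L)
  structure(list(position = position, fwd_nnk = fwd,
                 rev_overlap = revcomp(rev_window), flank_len = flank_len),
            class = "primer_set")
}

#' @export
print.primer_set <- function(x, ...) {
  cat(sprintf("primer_set @%d: fwd %s / rev %s\n", x$position, x$fwd_nnk,
              x$rev_overlap))
  invisible(x)
}

#' Reconstruct the template region implied by a primer set
#'
#' Splices the reverse-overlap window onto the forward primer with the NNK
#' codon replaced by a concrete codon; used to verify that a design touches
#' exactly one codon.
#'
#' @param ps A `primer_set`.
#' @param cds The template [coding_sequence()].
#' @param codon Concrete codon to substitute for NNK (default: the
#'   wild-type codon).
#' @return The implied mutant ORF (full-length DNA string).
#' @export
primer_implied_orf <- function(ps, cds, codon = NULL) {
  stopifnot(inherits(ps, "primer_set"), inherits(cds, "coding_sequence"))
  cstart <- 3L * (ps$position - 1L) + 1L
  codon <- codon %||% substr(cds$nt, cstart, cstart + 2L)
  paste0(substr(cds$nt, 1L, cstart - 1L), codon,
         substr(cds$nt, cstart + 3L, nchar(cds$nt)))
}

#' Design NNK primers for every SSM position of an ORF
#'
#' @param cds A [coding_sequence()].
#' @param flank_len Flank length in nt per side (default 18).
#' @param exclude Positions to skip (default 1, the start methionine).
#' @return A data.frame with columns `position`, `fwd_nnk`, `rev_overlap`.
#' @export
design_library_primers <- function(cds, flank_len = 18L, exclude = 1L) {
  L <- nchar(cds$protein)
  positions <- setdiff(seq_len(L), exclude)
  ## drop positions whose flanks would run off the template
  cstart <- 3L * (positions - 1L) + 1L
  ok <- cstart - flank_len >= 1L & cstart + 2L + flank_len <= nchar(cds$nt)
  positions <- positions[ok]
  sets <- lapply(positions, function(p) design_nnk_primers(cds, p, flank_len))
  data.frame(
    position = positions,
    fwd_nnk = vapply(sets, `[[`, "", "fwd_nnk"),
    rev_overlap = vapply(sets, `[[`, "", "rev_overlap"),
    stringsAsFactors = FALSE
  )
}

#' Write SSM variant specs to TSV and primers to FASTA
#'
#' @param specs Output of [enumerate_ssm()].
#' @param primers Output of [design_library_primers()] (optional).
#' @param specs_path,primers_path Output paths (`NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_library_design <- function(specs, primers = NULL, specs_path = NULL,
                                 primers_path = NULL) {
  written <- character()
  if (!is.null(specs_path)) {
    write.table(specs, specs_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <- c(written, specs_path)
  }
  if (!is.null(primers) && !is.null(primers_path)) {
    recs <- Biostrings::DNAStringSet(
      setNames(primers$fwd_nnk, sprintf("pos%03d_fwd_NNK", primers$position)))
    Biostrings::writeXStringSet(recs, primers_path)
    written <- c(written, primers_path)
  }
  invisible(written)
}
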