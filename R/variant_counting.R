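## Variant counting: translate merged reads, classify each against the
## wild-type protein, and accumulate the per-position x per-mutation-type
## count matrix f_ij.
##
## Reads are anchored to the ORF by an exact match of the non-coding
## (UTR/vector-derived) flank of their amplicon plus an exact length check;
## no gapped alignment is performed, so reads with indels or a damaged
## anchor fall into the INDEL_OR_LEN class.

#' Define the two-amplicon sequencing layout over an ORF
#'
#' The coding sequence (with optional non-coding flanks) is split into two
#' amplicons that overlap by `overlap_codons` codons (42 bp at the
#' default), mirroring a gene too long for a single MiSeq read pair.
#' Amplicon 1 carries the 5' flank as its anchor, amplicon 2 the 3' flank.
#'
#' @param cds A [coding_sequence()].
#' @param utr5,utr3 Non-coding flanking sequence (anchors; never
#'   mutagenized). May be empty strings, in which case reads are anchored
#'   by length alone.
#' @param overlap_codons Codons shared by the two amplicons (default 14,
#'   i.e. 42 nt).
#' @return A list of class `amplicon_layout`; element `amplicons` holds
#'   per-amplicon `seq`, `anchor`, `anchor_side`, `codon_start`,
#'   `codon_end`, `coding_from` (nt offset of the first codon inside the
#'   amplicon) and `length`.
#' @export
amplicon_layout <- function(cds, utr5 = "", utr3 = "", overlap_codons = 14L) {
  stopifnot(inherits(cds, "coding_sequence"))
  L <- nchar(cds$protein)
  overlap_codons <- as.integer(overlap_codons)
  stopifnot(overlap_codons >= 1L, overlap_codons < L)
  k1 <- as.integer(ceiling((L + overlap_codons) / 2))
  k2 <- k1 - overlap_codons + 1L
  amp1_seq <- paste0(utr5, substr(cds$nt, 1L, 3L * k1))
  amp2_seq <- paste0(substr(cds$nt, 3L * (k2 - 1L) + 1L, 3L * L), utr3)
  amps <- list(
    list(name = "amp1", seq = amp1_seq, anchor = utr5, anchor_side = "5p",
         codon_start = 1L, codon_end = k1, coding_from = nchar(utr5) + 1L,
         length = nchar(amp1_seq)),
    list(name = "amp2", seq = amp2_seq, anchor = utr3, anchor_side = "3p",
         codon_start = k2, codon_end = L, coding_from = 1L,
         length = nchar(amp2_seq))
  )
  if (amps[[1L]]$length == amps[[2L]]$length && nchar(utr5) == 0L &&
      nchar(utr3) == 0L)
    stop("amplicons have equal length and no anchors; reads cannot be assigned",
         call. = FALSE)
  structure(list(cds = cds, utr5 = utr5, utr3 = utr3,
                 overlap_codons = overlap_codons, amplicons = amps),
            class = "amplicon_layout")
}

#' Translate an ORF substring
#'
#' Translates `seq` starting at `frame_offset` nucleotides in codon steps
#' using the standard genetic code. Codons containing ambiguous bases
#' translate to `"X"` (callers classify such reads as UNTRANSLATABLE).
#'
#' @param seq DNA string.
#' @param frame_offset Nucleotides to skip before the first codon
#'   (default 0).
#' @return Amino-acid string, or `NA` with attribute `reason = "length"`
#'   if the trimmed length is not a codon multiple.
#' @examples
#' translate_orf("ATGGCT")  # "MA"
#' @export
translate_orf <- function(seq, frame_offset = 0L) {
  body <- substr(seq, frame_offset + 1L, nchar(seq))
  if (nchar(body) %% 3L != 0L)
    return(structure(NA_character_, reason = "length"))
  translate_nt(body)
}

#' Classify one translated read against the wild type
#'
#' @param protein Amino-acid string of the read (may contain `"*"` or
#'   `"X"`).
#' @param wt Wild-type amino-acid string of the same region.
#' @return A list with `cls` in `WT`, `SINGLE`, `MULTI`, `INDEL_OR_LEN`,
#'   `UNTRANSLATABLE`; for SINGLE also `position` (1-based, local to `wt`)
#'   and `mut_aa`.
#' @examples
#' classify_read("MALV", "MKLV")  # SINGLE at 2 -> A
#' @export
classify_read <- function(protein, wt) {
  if (is.na(protein)) return(list(cls = "UNTRANSLATABLE"))
  if (nchar(protein) != nchar(wt)) return(list(cls = "INDEL_OR_LEN"))
  if (grepl("X", protein, fixed = TRUE)) return(list(cls = "UNTRANSLATABLE"))
  a <- strsplit(protein, "")[[1L]]
  b <- strsplit(wt, "")[[1L]]
  d <- which(a != b)
  if (length(d) == 0L) return(list(cls = "WT"))
  if (length(d) == 1L)
    return(list(cls = "SINGLE", position = d, mut_aa = a[d]))
  list(cls = "MULTI")
}

#' Classify merged reads and accumulate variant calls
#'
#' Vectorised pipeline: assigns each merged read to an amplicon by exact
#' anchor/length match, translates the coding window, and classifies it
#' against the wild type. Positions are reported in global protein
#' coordinates.
#'
#' @param seqs Character vector of merged read sequences.
#' @param layout An [amplicon_layout()].
#' @param id Optional read identifiers.
#' @return A data.frame of variant calls: `read_id`, `cls`, `position`,
#'   `mut_aa` (`NA` except for SINGLE).
#' @export
call_variants <- function(seqs, layout, id = NULL) {
  stopifnot(inherits(layout, "amplicon_layout"))
  id <- id %||% sprintf("read%06d", seq_along(seqs))
  n <- length(seqs)
  cls <- rep("INDEL_OR_LEN", n)
  position <- rep(NA_integer_, n)
  mut_aa <- rep(NA_character_, n)
  wt_prot <- layout$cds$protein
  assigned <- rep(NA_integer_, n)
  len <- nchar(seqs)
  for (k in seq_along(layout$amplicons)) {
    a <- layout$amplicons[[k]]
    cand <- which(is.na(assigned) & len == a$length)
    if (!length(cand)) next
    if (nchar(a$anchor) > 0L) {
      anc <- if (a$anchor_side == "5p") {
        substr(seqs[cand], 1L, nchar(a$anchor)) == a$anchor
      } else {
        substr(seqs[cand], a$length - nchar(a$anchor) + 1L, a$length) == a$anchor
      }
      cand <- cand[anc]
    }
    if (!length(cand)) next
    assigned[cand] <- k
    n_codons <- a$codon_end - a$codon_start + 1L
    coding <- substr(seqs[cand], a$coding_from,
                     a$coding_from + 3L * n_codons - 1L)
    prot <- translate_nt(coding)
    wt_win <- substr(wt_prot, a$codon_start, a$codon_end)
    ## character-matrix comparison against the wild-type window
    pm <- as.matrix(Biostrings::AAStringSet(prot))
    wt_row <- strsplit(wt_win, "")[[1L]]
    diff <- pm != matrix(wt_row, nrow = nrow(pm), ncol = n_codons,
                         byrow = TRUE)
    has_x <- rowSums(pm == "X") > 0L
    ndiff <- rowSums(diff)
    cls_k <- ifelse(has_x, "UNTRANSLATABLE",
                    ifelse(ndiff == 0L, "WT",
                           ifelse(ndiff == 1L, "SINGLE", "MULTI")))
    cls[cand] <- cls_k
    singles <- which(cls_k == "SINGLE")
    if (length(singles)) {
      local_pos <- apply(diff[singles, , drop = FALSE], 1L, which)
      position[cand[singles]] <- a$codon_start - 1L + local_pos
      mut_aa[cand[singles]] <- pm[cbind(singles, local_pos)]
    }
  }
  data.frame(read_id = id, cls = cls, position = position, mut_aa = mut_aa,
             stringsAsFactors = FALSE)
}

#' Accumulate variant calls into a count matrix
#'
#' Builds the per-position x per-mutation-type count matrix `f_ij` from
#' SINGLE calls. The 21 mutation-type columns are the 20 amino acids plus
#' stop (see [mutation_types()]); per-position wild-type identity cells
#' are flagged and excluded from enrichment downstream. MULTI,
#' INDEL_OR_LEN and UNTRANSLATABLE reads are excluded from `f_ij` but
#' tallied for QC.
#'
#' @param calls Data.frame from [call_variants()] (or with the same
#'   columns).
#' @param wt Wild-type amino-acid string (defines the number of positions
#'   and the wild-type flags).
#' @param label Library label (e.g. `"naive"`, `"round1"`).
#' @return An object of class `count_matrix`: list with `counts`
#'   (positions x 21 integer matrix), `wt` (per-position amino acid),
#'   `label`, `tallies` (named integer vector by class) and
#'   `n_reads_classified`.
#' @export
count_mutations <- function(calls, wt, label = "library") {
  N <- nchar(wt)
  stopifnot(N > 0L)
  m <- matrix(0L, nrow = N, ncol = length(AA_ORDER),
              dimnames = list(position = seq_len(N), mut = AA_ORDER))
  singles <- calls[calls$cls == "SINGLE", , drop = FALSE]
  if (nrow(singles)) {
    if (any(singles$position < 1L | singles$position > N))
      stop("SINGLE call position outside 1..", N, call. = FALSE)
    idx <- cbind(singles$position, match(singles$mut_aa, AA_ORDER))
    if (anyNA(idx[, 2L])) stop("unknown mutation symbol in calls", call. = FALSE)
    tab <- table(idx[, 1L], idx[, 2L])
    m[cbind(as.integer(rownames(tab)[row(tab)]),
            as.integer(colnames(tab)[col(tab)]))] <- as.integer(tab)
  }
  tallies <- table(factor(calls$cls, levels = c("WT", "SINGLE", "MULTI",
                                                "INDEL_OR_LEN",
                                                "UNTRANSLATABLE")))
  structure(list(counts = m, wt = strsplit(wt, "")[[1L]], label = label,
                 tallies = c(tallies),
                 n_reads_classified = nrow(calls)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix '%s': %d positions x %d mutation types, %d single-mutant reads\n",
              x$label, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  print(x$tallies)
  invisible(x)
}

#' Logical matrix flagging wild-type identity cells
#'
#' @param cm A `count_matrix` (or any list with `counts` and `wt`).
#' @return Logical matrix, `TRUE` where the column amino acid equals the
#'   position's wild-type identity.
#' @export
wt_cells <- function(cm) {
  outer(cm$wt, AA_ORDER, `==`)
}

#' Write a count matrix to TSV (wide or long form)
#'
#' @param cm A `count_matrix`.
#' @param path Output path.
#' @param long If `TRUE`, write long form (`position`, `wt_aa`, `mut_aa`,
#'   `count`); otherwise the wide positions x 21 matrix.
#' @return The path, invisibly.
#' @export
write_count_matrix <- function(cm, path, long = FALSE) {
  if (long) {
    df <- data.frame(position = rep(seq_len(nrow(cm$counts)), ncol(cm$counts)),
                     wt_aa = rep(cm$wt, ncol(cm$counts)),
                     mut_aa = rep(AA_ORDER, each = nrow(cm$counts)),
                     count = as.vector(cm$counts))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(position = seq_len(nrow(cm$counts)), wt_aa = cm$wt,
                     cm$counts, check.names = FALSE)
    colnames(df) <- c("position", "wt_aa", AA_ORDER)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()] (wide form)
#'
#' @param path TSV path.
#' @param label Library label to attach.
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(path, label = "library") {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  counts <- as.matrix(df[, AA_ORDER, drop = FALSE])
  mode(counts) <- "integer"
  dimnames(counts) <- list(position = df$position, mut = AA_ORDER)
  structure(list(counts = counts, wt = df$wt_aa, label = label,
                 tallies = NULL, n_reads_classified = NA_integer_),
            class = "count_matrix")
}
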