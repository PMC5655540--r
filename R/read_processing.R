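## Paired-end read merging and Phred quality filtering.
##
## Merging model: the reverse read is reverse-complemented and overlapped
## against the 3' end of the forward read (suffix/prefix overlap, no gaps).
## Among all overlap lengths >= min_overlap whose mismatch fraction is
## <= max_mismatch_frac, the one maximizing matched bases is chosen;
## ties are rejected as "ambiguous" rather than broken arbitrarily.
## In the overlap, agreeing bases get the capped Phred sum (cap 41) and
## disagreeing bases take the higher-Phred call.

#' Quality-control parameters for merged reads
#'
#' @param min_avg_phred Minimum mean Phred score over the merged read
#'   (default 18).
#' @param min_pos_phred Minimum per-position Phred score (default 12).
#' @param min_overlap Minimum pair overlap in bases (default 11).
#' @param max_mismatch_frac Maximum mismatch fraction tolerated in the
#'   overlap (default 0.1).
#' @param qual_cap Phred cap for agreeing overlap bases (default 41).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_avg_phred = 18, min_pos_phred = 12L,
                      min_overlap = 11L, max_mismatch_frac = 0.1,
                      qual_cap = 41L) {
  stopifnot(min_avg_phred >= 0, min_pos_phred >= 0, min_overlap >= 1,
            max_mismatch_frac >= 0, qual_cap > 0)
  structure(list(min_avg_phred = min_avg_phred,
                 min_pos_phred = as.integer(min_pos_phred),
                 min_overlap = as.integer(min_overlap),
                 max_mismatch_frac = max_mismatch_frac,
                 qual_cap = as.integer(qual_cap)),
            class = "qc_params")
}

phred_to_string <- function(q) {
  vapply(q, function(x) intToUtf8(pmin(x, 93L) + 33L), "")
}

string_to_phred <- function(s) {
  lapply(s, function(x) utf8ToInt(x) - 33L)
}

#' Merge many read pairs (vectorised)
#'
#' @param fwd,rev Character vectors of forward/reverse read sequences
#'   (reverse reads in sequencer orientation; they are
#'   reverse-complemented internally).
#' @param fwd_qual,rev_qual Phred+33-encoded quality strings, or lists of
#'   integer Phred vectors.
#' @param params A [qc_params()] object.
#' @param id Optional read identifiers.
#' @return A data.frame with columns `id`, `status` (`merged`,
#'   `no_overlap`, `ambiguous`, `bad_input`), `seq`, `qual` (Phred+33),
#'   `overlap_len`, `mean_q`, `min_q`.
#' @export
merge_pairs <- function(fwd, rev, fwd_qual, rev_qual, params = qc_params(),
                        id = NULL) {
  stopifnot(inherits(params, "qc_params"))
  if (is.list(fwd_qual)) fwd_qual <- phred_to_string(fwd_qual)
  if (is.list(rev_qual)) rev_qual <- phred_to_string(rev_qual)
  stopifnot(length(fwd) == length(rev), length(fwd) == length(fwd_qual),
            length(fwd) == length(rev_qual))
  res <- .merge_pairs_cpp(fwd, rev, fwd_qual, rev_qual,
                          params$min_overlap, params$max_mismatch_frac,
                          params$qual_cap)
  data.frame(id = id %||% sprintf("read%06d", seq_along(fwd)),
             status = res$status, seq = res$seq, qual = res$qual,
             overlap_len = res$overlap_len, mean_q = res$mean_q,
             min_q = res$min_q, stringsAsFactors = FALSE)
}

#' Merge a single read pair
#'
#' @param pair A list with `fwd_seq`, `rev_seq`, `fwd_qual`, `rev_qual`
#'   (qualities as integer Phred vectors) and optionally `id`.
#' @param params A [qc_params()] object.
#' @return A list of class `merged_read` with `id`, `seq`, `qual`
#'   (integer Phred), `overlap_len` if merged; otherwise a list of class
#'   `merge_rejection` with a `reason` of `no_overlap`, `ambiguous` or
#'   `bad_input`.
#' @export
merge_pair <- function(pair, params = qc_params()) {
  if (length(pair$fwd_seq) != 1L || length(pair$rev_seq) != 1L ||
      nchar(pair$fwd_seq) != length(pair$fwd_qual) ||
      nchar(pair$rev_seq) != length(pair$rev_qual))
    return(structure(list(id = pair$id %||% "read", reason = "bad_input"),
                     class = "merge_rejection"))
  df <- merge_pairs(pair$fwd_seq, pair$rev_seq, list(pair$fwd_qual),
                    list(pair$rev_qual), params, id = pair$id %||% "read")
  if (df$status != "merged")
    return(structure(list(id = df$id, reason = df$status),
                     class = "merge_rejection"))
  structure(list(id = df$id, seq = df$seq,
                 qual = string_to_phred(df$qual)[[1L]],
                 overlap_len = df$overlap_len),
            class = "merged_read")
}

#' Apply average/minimum Phred filters to a merged read
#'
#' A read passes iff its mean Phred is at least `min_avg_phred` and its
#' minimum per-position Phred at least `min_pos_phred`.
#'
#' @param read A `merged_read` (from [merge_pair()]) or any list with a
#'   `qual` integer vector.
#' @param params A [qc_params()] object.
#' @return A list with `pass` (logical) and `reason` (`ok`, `avg`,
#'   `min_pos` or `empty`).
#' @export
quality_filter <- function(read, params = qc_params()) {
  q <- read$qual
  if (length(q) == 0L) return(list(pass = FALSE, reason = "empty"))
  if (mean(q) < params$min_avg_phred) return(list(pass = FALSE, reason = "avg"))
  if (min(q) < params$min_pos_phred) return(list(pass = FALSE, reason = "min_pos"))
  list(pass = TRUE, reason = "ok")
}

#' Merge and quality-filter paired FASTQ input
#'
#' End-to-end read processing: merge each pair, then apply the Phred
#' filters. Operates on in-memory vectors (see [read_fastq()] to load
#' files).
#'
#' @inheritParams merge_pairs
#' @return A list with `merged` (data.frame of passing reads),
#'   `rejections` (data.frame `id`, `reason`), and `tallies` (named
#'   integer vector).
#' @export
process_read_pairs <- function(fwd, rev, fwd_qual, rev_qual,
                               params = qc_params(), id = NULL) {
  df <- merge_pairs(fwd, rev, fwd_qual, rev_qual, params, id)
  ok <- df$status == "merged"
  merged <- df[ok, , drop = FALSE]
  pass_avg <- merged$mean_q >= params$min_avg_phred
  pass_min <- merged$min_q >= params$min_pos_phred
  reason <- rep("ok", nrow(merged))
  reason[!pass_min] <- "min_pos"
  reason[!pass_avg] <- "avg"        # avg failure reported first, like the scalar path
  keep <- pass_avg & pass_min
  rejections <- rbind(
    data.frame(id = df$id[!ok], reason = df$status[!ok],
               stringsAsFactors = FALSE),
    data.frame(id = merged$id[!keep], reason = reason[!keep],
               stringsAsFactors = FALSE)
  )
  tallies <- c(input = nrow(df), merged = sum(ok), passed = sum(keep),
               no_overlap = sum(df$status == "no_overlap"),
               ambiguous = sum(df$status == "ambiguous"),
               bad_input = sum(df$status == "bad_input"),
               qc_failed = sum(!keep))
  list(merged = merged[keep, , drop = FALSE], rejections = rejections,
       tallies = tallies)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (Phred+33).
#' @return A list with `id`, `seq` and `qual` (Phred+33 strings).
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  list(id = names(ss), seq = unname(as.character(ss)),
       qual = unname(as.character(S4Vectors::mcols(ss)$qualities)))
}

#' Write a FASTQ file
#'
#' @param id,seq,qual Identifiers, sequences, Phred+33 quality strings.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(id, seq, qual, path) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  ss <- Biostrings::DNAStringSet(setNames(seq, id))
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}
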