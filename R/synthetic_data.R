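## Synthetic SSM experiment generator: a random wild-type ORF, a
## single-mutant library with known per-variant fitness, deterministic
## multi-round selection, and MiSeq-like paired-end reads with a
## substitution error model and truncated-normal Phred scores.
##
## All randomness flows from explicit integer seeds; the same seed always
## reproduces the same bytes.

NON_STOP_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]

#' Generate a random wild-type coding sequence
#'
#' @param length_aa Protein length (>= 2); the ORF is `3 * length_aa` nt,
#'   starts with ATG and contains no internal stop codon.
#' @param seed Integer seed.
#' @return A [coding_sequence()].
#' @examples
#' nchar(make_wt(185, seed = 0)$nt)  # 555
#' @export
make_wt <- function(length_aa, seed = 0L) {
  stopifnot(length_aa >= 2L)
  set.seed(seed)
  codons <- c("ATG", sample(NON_STOP_CODONS, length_aa - 1L, replace = TRUE))
  coding_sequence(paste(codons, collapse = ""), id = sprintf("synthetic_wt_%daa", length_aa))
}

#' Define the ground truth of a synthetic SSM selection experiment
#'
#' The library is uniform over all protein-level single mutants (every
#' non-wild-type standard amino acid at every position except the start
#' methionine), with a wild-type fraction making up the remainder. Each
#' variant gets an NNK-compatible codon and a per-round fitness (true
#' log2 enrichment); wild-type fitness is 0.
#'
#' @param cds A [coding_sequence()] (see [make_wt()]).
#' @param seed Integer seed (codon choice, flank sequence, fitness draw).
#' @param wt_fraction Wild-type fraction of the library (default 0.1).
#' @param fitness Either `NULL` (draw uniform on `fitness_range`), a
#'   single number applied to all variants (e.g. 0 for a neutral control),
#'   or a numeric vector of length `nrow(variants)`.
#' @param fitness_range Range of the uniform fitness draw (default
#'   `c(-2, 2)`).
#' @param utr_len Length of the non-coding anchor flanks (default 20 nt).
#' @return A list of class `synthetic_truth`: `cds`, `utr5`, `utr3`,
#'   `variants` (data.frame `position`, `wt_aa`, `mut_aa`, `codon`,
#'   `freq`, `fitness`), `wt_fraction`, `seed`.
#' @export
synthetic_truth <- function(cds, seed = 0L, wt_fraction = 0.1,
                            fitness = NULL, fitness_range = c(-2, 2),
                            utr_len = 20L) {
  stopifnot(inherits(cds, "coding_sequence"), wt_fraction >= 0,
            wt_fraction < 1)
  set.seed(seed)
  specs <- enumerate_ssm(cds$protein, exclude = 1L)
  variants <- specs[!specs$is_wt, c("position", "wt_aa", "mut_aa", "codon")]
  rownames(variants) <- NULL
  n <- nrow(variants)
  variants$freq <- (1 - wt_fraction) / n
  if (is.null(fitness)) {
    variants$fitness <- runif(n, fitness_range[1L], fitness_range[2L])
  } else if (length(fitness) == 1L) {
    variants$fitness <- rep(as.numeric(fitness), n)
  } else {
    stopifnot(length(fitness) == n)
    variants$fitness <- as.numeric(fitness)
  }
  utr5 <- paste(sample(c("A", "C", "G", "T"), utr_len, replace = TRUE),
                collapse = "")
  utr3 <- paste(sample(c("A", "C", "G", "T"), utr_len, replace = TRUE),
                collapse = "")
  structure(list(cds = cds, utr5 = utr5, utr3 = utr3, variants = variants,
                 wt_fraction = wt_fraction, seed = seed),
            class = "synthetic_truth")
}

#' Deterministic multi-round selection on a variant pool
#'
#' Each round multiplies every variant's frequency by `2^fitness`
#' (wild-type fitness 0) and renormalises, so a variant's expected log2
#' enrichment after round r is `r * fitness`.
#'
#' @param truth A [synthetic_truth()].
#' @param rounds Number of rounds (>= 1).
#' @return A list of numeric vectors (one per round, plus the naive pool
#'   as element `"naive"`); each vector has one element per variant plus a
#'   final `"WT"` element and sums to 1.
#' @export
simulate_selection <- function(truth, rounds = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), rounds >= 1L)
  keys <- variant_keys(truth$variants)
  f0 <- c(setNames(truth$variants$freq, keys), WT = truth$wt_fraction)
  w <- c(2^truth$variants$fitness, 1)   # per-round multiplier; WT = 2^0
  out <- list(naive = f0)
  f <- f0
  for (r in seq_len(rounds)) {
    f <- f * w
    f <- f / sum(f)
    out[[sprintf("round%d", r)]] <- f
  }
  out
}

variant_keys <- function(variants) {
  sprintf("p%d%s", variants$position, variants$mut_aa)
}

#' Read-simulation parameters
#'
#' @param depth Total read pairs per library (split evenly across the two
#'   amplicons).
#' @param fwd_len,rev_len Read lengths in nt (defaults 305 and 295;
#'   truncated to the amplicon length).
#' @param error_rate Per-base substitution error probability
#'   (default 0.001).
#' @param phred_mean,phred_sd,phred_floor Truncated-normal Phred model
#'   (defaults 32, 4, 2).
#' @param indel_rate Per-read probability of a 1-nt deletion (default 0;
#'   exercises the INDEL_OR_LEN path when positive).
#' @return A list of class `read_sim_params`.
#' @export
read_sim_params <- function(depth = 2e5, fwd_len = 305L, rev_len = 295L,
                            error_rate = 0.001, phred_mean = 32,
                            phred_sd = 4, phred_floor = 2L,
                            indel_rate = 0) {
  stopifnot(depth >= 1, fwd_len >= 1, rev_len >= 1, error_rate >= 0,
            error_rate < 1, phred_sd >= 0, indel_rate >= 0, indel_rate < 1)
  structure(list(depth = as.integer(depth), fwd_len = as.integer(fwd_len),
                 rev_len = as.integer(rev_len), error_rate = error_rate,
                 phred_mean = phred_mean, phred_sd = phred_sd,
                 phred_floor = as.integer(phred_floor),
                 indel_rate = indel_rate),
            class = "read_sim_params")
}

inject_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0 || !length(seqs)) return(seqs)
  k <- rbinom(length(seqs), nchar(seqs), error_rate)
  hit <- which(k > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(nchar(seqs[i]), k[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, old), 1L)
    }
  }
  seqs
}

phred_strings <- function(n, len, params, chunk = 20000L) {
  ## chunked to bound peak memory at high depth
  out <- character(n)
  done <- 0L
  while (done < n) {
    m <- min(chunk, n - done)
    q <- matrix(as.integer(pmax(round(rnorm(m * len, params$phred_mean,
                                            params$phred_sd)),
                                params$phred_floor)),
                nrow = m)
    q[q > 41L] <- 41L
    out[done + seq_len(m)] <- apply(q + 33L, 1L, intToUtf8)
    done <- done + m
  }
  out
}

#' Simulate paired-end reads from a variant pool
#'
#' Samples variants multinomially by frequency, splits the template into
#' the two-amplicon layout, emits forward/reverse reads of the configured
#' lengths, injects substitution errors and draws Phred scores from the
#' truncated-normal model. Deterministic given `seed`.
#'
#' @param freqs Named frequency vector (variant keys plus `"WT"`), e.g.
#'   one element of [simulate_selection()].
#' @param truth The [synthetic_truth()] that defines variants and flanks.
#' @param params A [read_sim_params()].
#' @param seed Integer seed.
#' @param layout Amplicon layout (default: built from `truth`).
#' @param r1_path,r2_path Optional FASTQ output paths.
#' @return A list with `id`, `fwd`, `rev` (sequences), `fwd_qual`,
#'   `rev_qual` (Phred+33 strings), `source` (true variant key per read)
#'   and `amplicon`.
#' @export
simulate_reads <- function(freqs, truth, params = read_sim_params(),
                           seed = 0L, layout = NULL,
                           r1_path = NULL, r2_path = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(params, "read_sim_params"))
  set.seed(seed)
  layout <- layout %||% amplicon_layout(truth$cds, truth$utr5, truth$utr3)
  keys <- variant_keys(truth$variants)
  stopifnot(identical(sort(names(freqs)), sort(c(keys, "WT"))))
  freqs <- freqs[c(keys, "WT")]
  n_amp <- c(floor(params$depth / 2), ceiling(params$depth / 2))
  out <- list()
  for (k in seq_along(layout$amplicons)) {
    a <- layout$amplicons[[k]]
    counts <- as.vector(rmultinom(1L, n_amp[k], freqs))
    ## per-variant amplicon sequence: substitute the variant codon when the
    ## position falls inside this amplicon's codon window
    amp_seqs <- rep(a$seq, length(freqs))
    vin <- which(c(truth$variants$position, NA) >= a$codon_start &
                   c(truth$variants$position, NA) <= a$codon_end)
    for (v in vin) {
      off <- a$coding_from + 3L * (truth$variants$position[v] - a$codon_start)
      s <- amp_seqs[v]
      substr(s, off, off + 2L) <- truth$variants$codon[v]
      amp_seqs[v] <- s
    }
    src <- rep(names(freqs), counts)
    seqs <- rep(amp_seqs, counts)
    n <- length(seqs)
    if (n == 0L) next
    ord <- sample.int(n)           # shuffle reads
    seqs <- seqs[ord]; src <- src[ord]
    if (params$indel_rate > 0) {
      del <- which(runif(n) < params$indel_rate)
      for (i in del) {
        p <- sample.int(nchar(seqs[i]) - 1L, 1L)
        seqs[i] <- paste0(substr(seqs[i], 1L, p - 1L),
                          substr(seqs[i], p + 1L, nchar(seqs[i])))
      }
    }
    L <- nchar(seqs)
    fl <- pmin(params$fwd_len, L)
    rl <- pmin(params$rev_len, L)
    fwd <- substr(seqs, 1L, fl)
    rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(substr(seqs, L - rl + 1L, L))))
    fwd <- inject_substitutions(fwd, params$error_rate)
    rev <- inject_substitutions(rev, params$error_rate)
    ## qualities drawn at the maximum length, trimmed per read (lengths can
    ## differ by one when the indel path is exercised)
    fq <- substr(phred_strings(n, max(fl), params), 1L, nchar(fwd))
    rq <- substr(phred_strings(n, max(rl), params), 1L, nchar(rev))
    out[[k]] <- list(
      id = sprintf("%s_%s_%06d", a$name, src, seq_len(n)),
      fwd = fwd, rev = rev,
      fwd_qual = fq, rev_qual = rq,
      source = src, amplicon = rep(a$name, n)
    )
  }
  res <- list(
    id = unlist(lapply(out, `[[`, "id")),
    fwd = unlist(lapply(out, `[[`, "fwd")),
    rev = unlist(lapply(out, `[[`, "rev")),
    fwd_qual = unlist(lapply(out, `[[`, "fwd_qual")),
    rev_qual = unlist(lapply(out, `[[`, "rev_qual")),
    source = unlist(lapply(out, `[[`, "source")),
    amplicon = unlist(lapply(out, `[[`, "amplicon"))
  )
  if (!is.null(r1_path)) write_fastq(res$id, res$fwd, res$fwd_qual, r1_path)
  if (!is.null(r2_path)) write_fastq(res$id, res$rev, res$rev_qual, r2_path)
  res
}

#' Simulate and analyse a full SSM selection experiment
#'
#' Convenience wrapper: generates reads for the naive library and each
#' selection round, merges and quality-filters them, counts variants and
#' returns the count matrices alongside the ground truth.
#'
#' @param truth A [synthetic_truth()].
#' @param rounds Selection rounds (default 1).
#' @param params A [read_sim_params()].
#' @param qc A [qc_params()].
#' @param seed Integer seed; per-library read seeds are derived from it.
#' @return A list with `truth`, `layout`, `counts` (named list of
#'   `count_matrix`: `naive`, `round1`, ...), and `tallies` per library.
#' @export
simulate_ssm_experiment <- function(truth, rounds = 1L,
                                    params = read_sim_params(),
                                    qc = qc_params(), seed = 0L) {
  layout <- amplicon_layout(truth$cds, truth$utr5, truth$utr3)
  pools <- simulate_selection(truth, rounds)
  counts <- list()
  tallies <- list()
  for (i in seq_along(pools)) {
    lib <- names(pools)[i]
    reads <- simulate_reads(pools[[i]], truth, params,
                            seed = seed * 131L + i, layout = layout)
    proc <- process_read_pairs(reads$fwd, reads$rev, reads$fwd_qual,
                               reads$rev_qual, qc, id = reads$id)
    calls <- call_variants(proc$merged$seq, layout, id = proc$merged$id)
    counts[[lib]] <- count_mutations(calls, truth$cds$protein, label = lib)
    tallies[[lib]] <- proc$tallies
  }
  list(truth = truth, layout = layout, counts = counts, tallies = tallies)
}

#' Ground-truth fitness as a positions x mutation-types matrix
#'
#' @param truth A [synthetic_truth()].
#' @return Numeric matrix aligned with `count_matrix$counts` (NA where no
#'   variant exists: wild-type cells, position 1, stop column).
#' @export
truth_fitness_matrix <- function(truth) {
  N <- nchar(truth$cds$protein)
  m <- matrix(NA_real_, nrow = N, ncol = length(AA_ORDER),
              dimnames = list(position = seq_len(N), mut = AA_ORDER))
  idx <- cbind(truth$variants$position, match(truth$variants$mut_aa, AA_ORDER))
  m[idx] <- truth$variants$fitness
  m
}
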