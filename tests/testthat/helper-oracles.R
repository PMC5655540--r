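# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force scans, hand-rolled BFS, hard-coded
# lookup tables.

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- standard genetic code, hard-coded (independent of Biostrings) -------
.codon_table <- local({
  b <- c("T", "C", "A", "G")
  # first base varies slowest, third fastest (standard table layout)
  codons <- paste0(rep(b, each = 16), rep(b, each = 4, times = 4),
                   rep(b, times = 16))
  # TCAG-order amino-acid string, standard code (table 1)
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aas, codons)
})

oracle_translate <- function(nt) {
  n <- nchar(nt) %/% 3
  paste(vapply(seq_len(n), function(i)
    .codon_table[[substr(nt, 3 * i - 2, 3 * i)]], ""), collapse = "")
}

# --- exhaustive merge oracle ---------------------------------------------
# Mirrors the documented merge contract: suffix/prefix overlap of fwd vs
# revcomp(rev); feasible offsets have ov >= min_overlap and mismatches <=
# floor(0.1 * ov + 1e-9); among them the max matched bases wins; ties are
# ambiguous. Returns a list like merge_pair's result.
oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

oracle_merge <- function(fwd, rev, fq, rq, min_overlap = 11,
                         max_mm = 0.1, cap = 41) {
  rc <- oracle_revcomp(rev)
  rcq <- rev(rq)
  f <- strsplit(fwd, "")[[1]]; r <- strsplit(rc, "")[[1]]
  lf <- length(f); lr <- length(r)
  feas <- list()
  for (ov in seq_len(min(lf, lr))) {
    if (ov < min_overlap) next
    a <- f[(lf - ov + 1):lf]; b <- r[1:ov]
    mism <- sum(a != b)
    if (mism <= floor(max_mm * ov + 1e-9))
      feas[[length(feas) + 1]] <- list(ov = ov, matches = ov - mism)
  }
  if (!length(feas)) return(list(reason = "no_overlap"))
  matches <- vapply(feas, `[[`, 0, "matches")
  best <- max(matches)
  if (sum(matches == best) > 1) return(list(reason = "ambiguous"))
  ov <- feas[[which.max(matches)]]$ov
  seq <- c(f[seq_len(lf - ov)], character(ov), r[(ov + 1):lr][seq_len(lr - ov)])
  qual <- c(fq[seq_len(lf - ov)], integer(ov), rcq[(ov + 1):lr][seq_len(lr - ov)])
  for (i in seq_len(ov)) {
    fi <- lf - ov + i
    q1 <- fq[fi]; q2 <- rcq[i]
    if (f[fi] == r[i]) {
      seq[lf - ov + i] <- f[fi]
      qual[lf - ov + i] <- min(q1 + q2, cap)
    } else {
      seq[lf - ov + i] <- if (q2 > q1) r[i] else f[fi]
      qual[lf - ov + i] <- max(q1, q2)
    }
  }
  list(reason = "merged", seq = paste(seq, collapse = ""), qual = qual,
       overlap_len = ov)
}

random_read <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# --- hand BFS bridge oracle ----------------------------------------------
# a bond is in a cycle iff its endpoints stay connected after removing it
oracle_bond_in_ring <- function(bonds, n_atoms) {
  vapply(seq_len(nrow(bonds)), function(b) {
    adj <- vector("list", n_atoms)
    for (k in seq_len(nrow(bonds))) {
      if (k == b) next
      adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], bonds$j[k])
      adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], bonds$i[k])
    }
    seen <- rep(FALSE, n_atoms)
    queue <- bonds$i[b]; seen[queue] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    seen[bonds$j[b]]
  }, logical(1))
}

# rule-by-rule rotatable-bond oracle on a conformer
oracle_rotatable <- function(cf) {
  el <- cf$atoms$element
  n <- nrow(cf$atoms)
  deg <- integer(n)
  for (k in seq_len(nrow(cf$bonds))) {
    i <- cf$bonds$i[k]; j <- cf$bonds$j[k]
    if (el[j] != "H") deg[i] <- deg[i] + 1
    if (el[i] != "H") deg[j] <- deg[j] + 1
  }
  in_ring <- oracle_bond_in_ring(cf$bonds, n)
  co <- unique(unlist(lapply(seq_len(nrow(cf$bonds)), function(k) {
    if (cf$bonds$order[k] != 2) return(NULL)
    i <- cf$bonds$i[k]; j <- cf$bonds$j[k]
    c(if (el[i] == "C" && el[j] == "O") i,
      if (el[j] == "C" && el[i] == "O") j)
  })))
  cnt <- 0
  for (k in seq_len(nrow(cf$bonds))) {
    i <- cf$bonds$i[k]; j <- cf$bonds$j[k]
    if (cf$bonds$order[k] != 1 || in_ring[k]) next
    if (el[i] == "H" || el[j] == "H") next
    if (deg[i] < 2 || deg[j] < 2) next
    if ((el[i] == "N" && j %in% co) || (el[j] == "N" && i %in% co)) next
    cnt <- cnt + 1
  }
  cnt
}

# random connected molecular graph (tree plus optional extra ring edges)
random_toy_graph <- function(n_atoms, n_extra = 1,
                             elements = c("C", "C", "C", "N", "O")) {
  atoms <- data.frame(element = sample(elements, n_atoms, replace = TRUE),
                      x = NA_real_, y = NA_real_, z = NA_real_)
  atoms$element[1] <- "C"
  bonds <- data.frame(i = integer(), j = integer(), order = integer())
  for (v in 2:n_atoms)
    bonds[nrow(bonds) + 1, ] <- list(sample(v - 1, 1), v,
                                     sample(c(1L, 1L, 1L, 2L), 1))
  for (e in seq_len(n_extra)) {
    pair <- sample(n_atoms, 2)
    dup <- any(bonds$i == min(pair) & bonds$j == max(pair) |
                 bonds$i == max(pair) & bonds$j == min(pair))
    if (!dup) bonds[nrow(bonds) + 1, ] <- list(pair[1], pair[2], 1L)
  }
  # avoid O with double bonds to multiple atoms nonsense: irrelevant for rule
  conformer(atoms, bonds)
}

# --- geometry toys --------------------------------------------------------
toy_tetra_amine <- function(bond_len = 1.47) {
  t <- acos(-1 / 3)  # 109.4712 deg
  data_at <- data.frame(
    element = c("N", "C", "C", "C"),
    x = c(0, bond_len * sin(t) * cos(0), bond_len * sin(t) * cos(2 * pi / 3),
          bond_len * sin(t) * cos(4 * pi / 3)),
    y = c(0, bond_len * sin(t) * sin(0), bond_len * sin(t) * sin(2 * pi / 3),
          bond_len * sin(t) * sin(4 * pi / 3)),
    z = c(0, bond_len * cos(t), bond_len * cos(t), bond_len * cos(t)))
  conformer(data_at, data.frame(i = c(1, 1, 1), j = c(2, 3, 4), order = 1L))
}

toy_carbonyl <- function() {
  at <- data.frame(element = c("C", "O", "C", "C"),
                   x = c(0, 1.23, -0.77, -0.77),
                   y = c(0, 0, 1.25, -1.25),
                   z = c(0, 0, 0, 0))
  conformer(at, data.frame(i = c(1, 1, 1), j = c(2, 3, 4),
                           order = c(2L, 1L, 1L)))
}

# spherical grid-search oracle: direction minimizing sum((angle - target)^2)
# at fixed radius from the nitrogen
oracle_amine_water_grid <- function(cf, n_idx, radius = 3.0, target = 109,
                                    n_grid = 20000) {
  nb <- cf$bonds$j[cf$bonds$i == n_idx]
  nb <- c(nb, cf$bonds$i[cf$bonds$j == n_idx])
  n <- as.numeric(cf$atoms[n_idx, c("x", "y", "z")])
  i <- seq_len(n_grid) - 0.5
  phi <- acos(1 - 2 * i / n_grid)
  theta <- pi * (1 + sqrt(5)) * i
  dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  score <- rep(0, n_grid)
  for (c_idx in nb) {
    u <- as.numeric(cf$atoms[c_idx, c("x", "y", "z")]) - n
    u <- u / sqrt(sum(u^2))
    ang <- acos(pmin(pmax(dirs %*% u, -1), 1)) * 180 / pi
    score <- score + (ang - target)^2
  }
  n + radius * dirs[which.min(score), ]
}

# --- pose-filter fixtures and brute-force conjunction oracle --------------
random_records <- function(n, seed = 1, na_frac = 0) {
  set.seed(seed)
  rec <- data.frame(
    pose_id = sprintf("pose%03d", seq_len(n)),
    sc = round(runif(n, 0.3, 0.8), 3),
    ife = round(runif(n, -20, 0), 2),
    dsasa = round(runif(n, 0.5, 1.0), 3),
    restraint = round(runif(n, 0, 10), 2),
    pocket_rmsd = round(runif(n, 0, 2), 3),
    ddg = round(runif(n, -20, 0), 2),
    field_H_sign = sample(c("negative", "nonnegative"), n, replace = TRUE),
    field_O_sign = sample(c("negative", "nonnegative"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  if (na_frac > 0) {
    for (col in c("sc", "ddg", "field_O_sign"))
      rec[[col]][sample(n, ceiling(na_frac * n))] <- NA
  }
  rec
}

oracle_survivors <- function(rec, th = design_filter_thresholds()) {
  keep <- logical(nrow(rec))
  for (r in seq_len(nrow(rec))) {
    vals <- rec[r, c("sc", "ife", "dsasa", "restraint", "pocket_rmsd", "ddg",
                     "field_H_sign", "field_O_sign")]
    if (anyNA(vals) || vals$field_H_sign == "missing" ||
        vals$field_O_sign == "missing") { keep[r] <- FALSE; next }
    keep[r] <- (vals$sc > th$sc) && (vals$ife < th$ife) &&
      (vals$dsasa >= th$dsasa) && (vals$restraint <= th$restraint) &&
      (vals$pocket_rmsd < th$pocket_rmsd) && (vals$ddg < th$ddg) &&
      (vals$field_H_sign == "negative") && (vals$field_O_sign == "negative")
  }
  rec$pose_id[keep]
}

# manual Eq. 1-3 oracle on raw count matrices with wild-type flags
oracle_enrichment <- function(f_naive, f_sel, wt_flag, min_count = 15) {
  pn <- f_naive / sum(f_naive[!wt_flag])
  ps <- f_sel / sum(f_sel[!wt_flag])
  E <- matrix(NA_real_, nrow(f_naive), ncol(f_naive))
  ok <- !wt_flag & f_naive > min_count & f_sel > 0
  E[ok] <- log2(ps[ok] / pn[ok])
  E
}

# small count_matrix builder for enrichment tests
toy_count_matrix <- function(counts, wt, label = "lib") {
  structure(list(counts = counts, wt = wt, label = label,
                 tallies = NULL, n_reads_classified = sum(counts)),
            class = "count_matrix")
}
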