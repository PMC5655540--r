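## Enrichment statistics: mutation probabilities and masked log2 enrichment
## between a selected and a naive library.
##
##   p_ij = f_ij / sum_{i,j} f_ij        (per library; wild-type identity
##                                        cells excluded from numerator and
##                                        denominator)
##   E_ij = log2(p_ij^select / p_ij^naive)
##
## E_ij is reported only where the naive library has more than `min_count`
## reads for the mutation; other cells carry an explicit mask code.

#' Normalise a count matrix to mutation probabilities
#'
#' Divides every non-wild-type cell by the total single-mutant count over
#' all positions and the 21 mutation types (stop included). Wild-type
#' identity cells are `NA`.
#'
#' @param counts A `count_matrix` (see [count_mutations()]).
#' @return A list of class `frequency_matrix` with `p` (positions x 21
#'   numeric matrix), `wt`, `label` and `total` (the normalising count).
#' @export
compute_probabilities <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  f <- counts$counts
  wt <- wt_cells(counts)
  total <- sum(f[!wt])
  if (total == 0L) stop("empty_library: all counts are zero", call. = FALSE)
  p <- f / total
  p[wt] <- NA_real_
  structure(list(p = p, wt = counts$wt, label = counts$label, total = total),
            class = "frequency_matrix")
}

MASK_LEVELS <- c("OK", "LOW_COUNT", "WT_CELL", "NO_DATA")

#' Compute masked log2 enrichment between two libraries
#'
#' For every position x mutation-type cell, `E_ij =
#' log2(p_ij_select / p_ij_naive)` where the naive library has more than
#' `min_count` reads for the mutation (`f_naive > min_count`). Other cells
#' are masked: `LOW_COUNT` (naive count at or below the threshold),
#' `WT_CELL` (the position's wild-type identity), or `NO_DATA` (naive
#' count sufficient but no reads in the selected library; reported rather
#' than numerically faked). With `require_selected = TRUE` the count
#' threshold is additionally applied to the selected library.
#'
#' @param naive,selected `count_matrix` objects of identical shape and
#'   wild-type sequence.
#' @param min_count Count threshold (default 15; cells require
#'   strictly more than this many naive reads).
#' @param require_selected Also require `f_select > min_count`
#'   (default `FALSE`).
#' @param pseudocount Optional additive pseudocount applied to both
#'   libraries before normalisation (default 0; exploratory use only, the
#'   value is recorded in the result).
#' @return A list of class `enrichment_matrix` with `E` (numeric matrix,
#'   `NA` outside OK cells), `mask` (character matrix over
#'   `r toString(MASK_LEVELS)`), `min_count`, `pseudocount` and
#'   `rounds_compared`.
#' @export
compute_enrichment <- function(naive, selected, min_count = 15L,
                               require_selected = FALSE, pseudocount = 0) {
  stopifnot(inherits(naive, "count_matrix"), inherits(selected, "count_matrix"))
  if (!identical(dim(naive$counts), dim(selected$counts)))
    stop("count matrices differ in shape", call. = FALSE)
  if (!identical(naive$wt, selected$wt))
    stop("count matrices disagree on the wild-type sequence", call. = FALSE)
  wt <- wt_cells(naive)
  fn <- naive$counts + pseudocount
  fs <- selected$counts + pseudocount
  tn <- sum(fn[!wt]); ts <- sum(fs[!wt])
  if (tn == 0 || ts == 0) stop("empty_library: all counts are zero", call. = FALSE)
  pn <- fn / tn
  ps <- fs / ts
  mask <- matrix("OK", nrow = nrow(fn), ncol = ncol(fn),
                 dimnames = dimnames(naive$counts))
  mask[naive$counts <= min_count] <- "LOW_COUNT"
  if (require_selected) mask[selected$counts <= min_count & mask == "OK"] <- "LOW_COUNT"
  mask[mask == "OK" & fs == 0] <- "NO_DATA"
  mask[wt] <- "WT_CELL"
  E <- matrix(NA_real_, nrow = nrow(fn), ncol = ncol(fn),
              dimnames = dimnames(naive$counts))
  ok <- mask == "OK"
  E[ok] <- log2(ps[ok] / pn[ok])
  structure(list(E = E, mask = mask, min_count = as.integer(min_count),
                 pseudocount = pseudocount,
                 rounds_compared = c(naive = naive$label,
                                     selected = selected$label)),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("enrichment_matrix %s vs %s: %d OK cells (min_count %d)\n",
              x$rounds_compared["selected"], x$rounds_compared["naive"],
              sum(x$mask == "OK"), x$min_count))
  invisible(x)
}

#' Render an enrichment heat map and its matrix files
#'
#' Writes the enrichment values and mask as TSV, and draws a
#' positions x mutation-types heat map with a diverging palette
#' (green = depletion, red = enrichment), grey for cells with
#' insufficient data (`LOW_COUNT`/`NO_DATA`) and a dot marking each
#' position's wild-type identity.
#'
#' @param em An `enrichment_matrix`.
#' @param path Output prefix; writes `<path>_E.tsv`, `<path>_mask.tsv`
#'   and (unless `image = FALSE`) `<path>.png`.
#' @param image Draw the PNG image (default `TRUE`).
#' @param zmax Symmetric colour range (default: max |E| over OK cells,
#'   or 1 if none).
#' @return Invisibly, a list with the files written and `n_ok`,
#'   `n_masked` cell counts.
#' @export
render_heatmap <- function(em, path, image = TRUE, zmax = NULL) {
  stopifnot(inherits(em, "enrichment_matrix"))
  e_path <- paste0(path, "_E.tsv")
  m_path <- paste0(path, "_mask.tsv")
  write.table(em$E, e_path, sep = "\t", quote = FALSE, row.names = TRUE,
              col.names = NA)
  write.table(em$mask, m_path, sep = "\t", quote = FALSE, row.names = TRUE,
              col.names = NA)
  files <- c(e_path, m_path)
  ok <- em$mask == "OK"
  if (image) {
    png_path <- paste0(path, ".png")
    grDevices::png(png_path, width = 200 + 6 * nrow(em$E), height = 400)
    op <- graphics::par(mar = c(4, 4, 2, 1))
    on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
    zmax <- zmax %||% max(abs(em$E[ok]), 1e-9, na.rm = TRUE)
    if (!is.finite(zmax) || zmax <= 0) zmax <- 1
    pal <- grDevices::colorRampPalette(c("darkgreen", "white", "firebrick"))(101)
    z <- pmin(pmax(em$E, -zmax), zmax)
    graphics::image(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                    z = matrix(NA_real_, nrow(z), ncol(z)),
                    zlim = c(-zmax, zmax), col = pal,
                    xlab = "position", ylab = "mutation",
                    axes = FALSE)
    graphics::axis(1)
    graphics::axis(2, at = seq_len(ncol(z)), labels = colnames(z), las = 2,
                   cex.axis = 0.5)
    grey <- em$mask == "LOW_COUNT" | em$mask == "NO_DATA"
    grey_cells <- which(grey, arr.ind = TRUE)
    if (nrow(grey_cells))
      graphics::rect(grey_cells[, 1] - 0.5, grey_cells[, 2] - 0.5,
                     grey_cells[, 1] + 0.5, grey_cells[, 2] + 0.5,
                     col = "grey80", border = NA)
    ok_cells <- which(ok, arr.ind = TRUE)
    if (nrow(ok_cells)) {
      cols <- pal[1 + round(100 * (z[ok] + zmax) / (2 * zmax))]
      graphics::rect(ok_cells[, 1] - 0.5, ok_cells[, 2] - 0.5,
                     ok_cells[, 1] + 0.5, ok_cells[, 2] + 0.5,
                     col = cols, border = NA)
    }
    wt_idx <- which(em$mask == "WT_CELL", arr.ind = TRUE)
    if (nrow(wt_idx))
      graphics::points(wt_idx[, 1], wt_idx[, 2], pch = 16, cex = 0.3)
    graphics::box()
    files <- c(files, png_path)
  }
  invisible(list(files = files, n_ok = sum(ok),
                 n_masked = sum(em$mask != "OK")))
}

#' Read back an enrichment TSV written by [render_heatmap()]
#'
#' @param e_path Path to the `_E.tsv` file.
#' @return Numeric matrix of E values (`NA` where masked).
#' @export
read_enrichment_tsv <- function(e_path) {
  df <- read.delim(e_path, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}
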