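## Design-pose selection and filtering, plus buried solvent-accessible
## surface area (dSASA) from coordinates via Shrake-Rupley numeric SASA.
##
## Filter thresholds default to the design-selection cascade used for the
## binder library: SC > 0.5 (strict), IFE < -10 REU (strict),
## dSASA >= 0.8 (non-strict), restraint <= 5 (non-strict),
## pocket RMSD < 1 A (strict), ddG < -10 REU (strict), and both
## electrostatic-field signs (charged amine hydrogen; carbonyl oxygen)
## negative. Inequality strictness follows the printed thresholds exactly
## and is honoured at the boundaries.

#' Select the top-scoring poses per scaffold
#'
#' Dock scores are higher-is-better by default (PatchDock polarity); ties
#' are broken by `pose_id` lexicographic order, deterministically.
#'
#' @param dock_scores Data.frame with columns `scaffold_id`, `pose_id`,
#'   `score`.
#' @param k Poses kept per scaffold (default 20).
#' @param higher_is_better Score polarity (default `TRUE`).
#' @return Data.frame of the selected rows (all columns preserved).
#' @export
select_top_poses <- function(dock_scores, k = 20L, higher_is_better = TRUE) {
  stopifnot(k >= 1L,
            all(c("scaffold_id", "pose_id", "score") %in% names(dock_scores)))
  s <- if (higher_is_better) -dock_scores$score else dock_scores$score
  ord <- order(dock_scores$scaffold_id, s, dock_scores$pose_id)
  df <- dock_scores[ord, , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$scaffold_id),
                        function(ix) head(ix, k)), use.names = FALSE)
  out <- df[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default design-filter thresholds
#'
#' @return Named list of thresholds consumed by [apply_design_filters()].
#' @export
design_filter_thresholds <- function() {
  list(sc = 0.5, ife = -10, dsasa = 0.8, restraint = 5, pocket_rmsd = 1,
       ddg = -10)
}

FILTER_ORDER <- c("sc", "ife", "dsasa", "restraint", "pocket_rmsd", "ddg",
                  "field_H", "field_O", "missing_data")

#' Apply the design filter cascade to pose score records
#'
#' A record survives iff `sc > thresholds$sc`, `ife < thresholds$ife`,
#' `dsasa >= thresholds$dsasa`, `restraint <= thresholds$restraint`,
#' `pocket_rmsd < thresholds$pocket_rmsd`, `ddg < thresholds$ddg`, and
#' both `field_H_sign` and `field_O_sign` equal `"negative"`. Records
#' with any missing field fail with reason `missing_data` and never pass
#' silently. Attrition is logged per filter in declared order (a record
#' is charged to the first filter it fails).
#'
#' @param records Data.frame with columns `pose_id`, `sc`, `ife`,
#'   `dsasa`, `restraint`, `pocket_rmsd`, `ddg`, `field_H_sign`,
#'   `field_O_sign`.
#' @param thresholds See [design_filter_thresholds()].
#' @return A list of class `filter_report`: `survivors` (pose ids),
#'   `attrition` (named integer vector, filter order preserved),
#'   `thresholds`, `n_input`.
#' @export
apply_design_filters <- function(records,
                                 thresholds = design_filter_thresholds()) {
  need <- c("pose_id", "sc", "ife", "dsasa", "restraint", "pocket_rmsd",
            "ddg", "field_H_sign", "field_O_sign")
  miss_col <- setdiff(need, names(records))
  for (m in miss_col) records[[m]] <- NA
  num <- c("sc", "ife", "dsasa", "restraint", "pocket_rmsd", "ddg")
  missing <- Reduce(`|`, lapply(records[c(num, "field_H_sign",
                                          "field_O_sign")], is.na))
  missing <- missing | records$field_H_sign == "missing" |
    records$field_O_sign == "missing"
  missing[is.na(missing)] <- TRUE
  pass <- list(
    sc = records$sc > thresholds$sc,
    ife = records$ife < thresholds$ife,
    dsasa = records$dsasa >= thresholds$dsasa,
    restraint = records$restraint <= thresholds$restraint,
    pocket_rmsd = records$pocket_rmsd < thresholds$pocket_rmsd,
    ddg = records$ddg < thresholds$ddg,
    field_H = records$field_H_sign == "negative",
    field_O = records$field_O_sign == "negative"
  )
  attrition <- setNames(integer(length(FILTER_ORDER)), FILTER_ORDER)
  failed <- missing
  attrition["missing_data"] <- sum(missing)
  alive <- !missing
  for (f in setdiff(FILTER_ORDER, "missing_data")) {
    drop <- alive & !pass[[f]]
    attrition[f] <- sum(drop)
    alive <- alive & pass[[f]]
  }
  structure(list(survivors = records$pose_id[alive],
                 attrition = attrition, thresholds = thresholds,
                 n_input = nrow(records)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d / %d poses survive\n",
              length(x$survivors), x$n_input))
  print(x$attrition)
  invisible(x)
}

## Bondi van der Waals radii (Angstrom)
BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                 P = 1.80, F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98)

#' Build an atom set for SASA computation
#'
#' @param element Character vector of element symbols.
#' @param x,y,z Coordinates in Angstrom.
#' @param radius Optional explicit radii; defaults to Bondi values by
#'   element.
#' @return Data.frame of class `atom_set`.
#' @export
atom_set <- function(element, x, y, z, radius = NULL) {
  radius <- radius %||% unname(BONDI_RADII[element])
  if (anyNA(radius)) stop("no Bondi radius for element(s): ",
                          paste(unique(element[is.na(radius)]), collapse = ", "),
                          call. = FALSE)
  stopifnot(all(radius > 0), all(is.finite(c(x, y, z))))
  structure(data.frame(element = element, x = x, y = y, z = z,
                       radius = radius, stringsAsFactors = FALSE),
            class = c("atom_set", "data.frame"))
}

## quasi-uniform points on the unit sphere (golden-spiral lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' @param atoms An [atom_set()] whose surface is measured.
#' @param occluders Optional additional [atom_set()] that occludes but is
#'   not measured (e.g. the protein environment around a ligand).
#' @param probe Probe radius in Angstrom (default 1.4).
#' @param n_points Sphere points per atom (default 960).
#' @return Total SASA in Angstrom^2 over `atoms`.
#' @export
shrake_rupley_sasa <- function(atoms, occluders = NULL, probe = 1.4,
                               n_points = 960L) {
  stopifnot(nrow(atoms) > 0L)
  pts <- sphere_points(n_points)
  all_xyz <- rbind(as.matrix(atoms[, c("x", "y", "z")]),
                   if (!is.null(occluders))
                     as.matrix(occluders[, c("x", "y", "z")]))
  all_r <- c(atoms$radius, occluders$radius) + probe
  total <- 0
  for (i in seq_len(nrow(atoms))) {
    ri <- atoms$radius[i] + probe
    center <- as.numeric(atoms[i, c("x", "y", "z")])
    ## neighbours that can possibly occlude atom i's sphere
    d2 <- colSums((t(all_xyz) - center)^2)
    nb <- which(d2 < (ri + all_r)^2 & d2 > 0)
    nb <- nb[nb != i]
    p <- sweep(pts * ri, 2L, center, `+`)
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (k in nb) {
        if (!any(acc)) break
        dd <- (p[acc, 1L] - all_xyz[k, 1L])^2 +
          (p[acc, 2L] - all_xyz[k, 2L])^2 +
          (p[acc, 3L] - all_xyz[k, 3L])^2
        acc[acc] <- dd > all_r[k]^2
      }
      frac <- sum(acc) / n_points
    } else frac <- 1
    total <- total + frac * 4 * pi * ri^2
  }
  total
}

#' Fraction of ligand surface buried by an environment (dSASA)
#'
#' `dsasa = 1 - SASA(ligand in complex) / SASA(ligand alone)`, both sides
#' computed with the same Shrake-Rupley settings.
#'
#' @param ligand,environment [atom_set()] objects (`environment` may have
#'   zero rows).
#' @inheritParams shrake_rupley_sasa
#' @return dSASA in `[0, 1]`.
#' @export
compute_dsasa <- function(ligand, environment, probe = 1.4,
                          n_points = 960L) {
  alone <- shrake_rupley_sasa(ligand, NULL, probe, n_points)
  if (alone <= 0) stop("ligand SASA alone is zero", call. = FALSE)
  env <- if (!is.null(environment) && nrow(environment)) environment else NULL
  complexed <- shrake_rupley_sasa(ligand, env, probe, n_points)
  1 - complexed / alone
}

#' Read ATOM/HETATM coordinates from a PDB file
#'
#' Minimal fixed-column reader sufficient for [atom_set()] input (no
#' parser for PDB coordinate records is available among the package's
#' dependencies).
#'
#' @param path PDB file.
#' @return An [atom_set()] with Bondi radii.
#' @export
read_pdb_atoms <- function(path) {
  lines <- readLines(path)
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(rec)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  el <- trimws(substr(rec, 77L, 78L))
  fallback <- toupper(substr(trimws(substr(rec, 13L, 16L)), 1L, 1L))
  el[el == ""] <- fallback[el == ""]
  el <- paste0(substr(el, 1L, 1L), tolower(substr(el, 2L, 2L)))
  atom_set(el,
           as.numeric(substr(rec, 31L, 38L)),
           as.numeric(substr(rec, 39L, 46L)),
           as.numeric(substr(rec, 47L, 54L)))
}

#' Read / write pose score records as TSV
#'
#' @param path TSV with the [apply_design_filters()] columns.
#' @return Data.frame of records.
#' @export
read_pose_scores <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_pose_scores
#' @param records Data.frame of pose score records.
#' @export
write_pose_scores <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
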