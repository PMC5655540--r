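## Hydrated-ligand preparation: small-molecule graphs (from SMILES or SDF),
## explicit water-oxygen placement at idealized geometry (3.0 A, 109 deg at
## a tertiary amine; 3.0 A, 120 deg in-plane at a carbonyl), and a
## rotatable-bond counter. All geometry runs on heavy atoms; hydrogens, if
## present, are ignored.

#' Construct a small-molecule conformer
#'
#' @param atoms Data.frame with columns `element`, `x`, `y`, `z`
#'   (coordinates may be `NA` for pure graph work) and optionally
#'   `charge`, `aromatic`.
#' @param bonds Data.frame with columns `i`, `j` (1-based atom indices)
#'   and `order` (1, 2, 3).
#' @return An object of class `conformer`.
#' @export
conformer <- function(atoms, bonds) {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds),
            all(c("element", "x", "y", "z") %in% names(atoms)),
            all(c("i", "j", "order") %in% names(bonds)))
  if (nrow(bonds) &&
      (any(bonds$i < 1L) || any(bonds$j < 1L) ||
       any(bonds$i > nrow(atoms)) || any(bonds$j > nrow(atoms))))
    stop("bond indices out of range", call. = FALSE)
  if (any(is.finite(c(atoms$x, atoms$y, atoms$z)) &
          !is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite coordinates", call. = FALSE)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  structure(list(atoms = atoms, bonds = bonds), class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("conformer: %d atoms (%d heavy), %d bonds\n", nrow(x$atoms),
              sum(x$atoms$element != "H"), nrow(x$bonds)))
  invisible(x)
}

heavy_idx <- function(c) which(c$atoms$element != "H")

## heavy-atom adjacency: list of heavy neighbours per atom
heavy_neighbors <- function(c) {
  n <- nrow(c$atoms)
  adj <- vector("list", n)
  hv <- c$atoms$element != "H"
  for (b in seq_len(nrow(c$bonds))) {
    i <- c$bonds$i[b]; j <- c$bonds$j[b]
    if (hv[j]) adj[[i]] <- c(adj[[i]], j)
    if (hv[i]) adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

## ring perception on the heavy-atom graph: a bond is acyclic iff it is a
## bridge (removing it disconnects its endpoints)
acyclic_bonds <- function(c) {
  if (!nrow(c$bonds)) return(logical(0))
  g <- igraph::graph_from_edgelist(cbind(c$bonds$i, c$bonds$j),
                                   directed = FALSE)
  if (igraph::vcount(g) < nrow(c$atoms))
    g <- igraph::add_vertices(g, nrow(c$atoms) - igraph::vcount(g))
  br <- igraph::bridges(g)
  seq_len(nrow(c$bonds)) %in% as.integer(br)
}

## carbonyl carbons: carbons double-bonded to an oxygen
carbonyl_carbons <- function(c) {
  el <- c$atoms$element
  dbl <- c$bonds[c$bonds$order == 2L, , drop = FALSE]
  unique(c(dbl$i[el[dbl$i] == "C" & el[dbl$j] == "O"],
           dbl$j[el[dbl$j] == "C" & el[dbl$i] == "O"]))
}

#' Find tertiary-amine nitrogens
#'
#' Returns every nitrogen with exactly three heavy neighbours, all of them
#' carbon, none of which is a carbonyl carbon (i.e. amide nitrogens are
#' excluded), and that is not aromatic. For a fentanyl-like molecule this
#' singles out the protonatable piperidine nitrogen rather than the amide
#' nitrogen.
#'
#' @param c A [conformer()].
#' @return Integer vector of candidate atom indices (length >= 1); errors
#'   with `no_amine` if none qualify.
#' @export
find_tertiary_amine <- function(c) {
  el <- c$atoms$element
  adj <- heavy_neighbors(c)
  co <- carbonyl_carbons(c)
  cand <- which(vapply(seq_len(nrow(c$atoms)), function(i) {
    if (el[i] != "N" || isTRUE(c$atoms$aromatic[i])) return(FALSE)
    nb <- adj[[i]]
    length(nb) == 3L && all(el[nb] == "C") && !any(nb %in% co)
  }, logical(1)))
  if (!length(cand)) stop("no_amine: no tertiary amine found", call. = FALSE)
  cand
}

coords <- function(c, i) as.numeric(c$atoms[i, c("x", "y", "z")])

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) v / vnorm(v)

#' Angle (degrees) at vertex b formed by points a-b-c
#' @param a,b,c Numeric xyz vectors.
#' @return Angle in degrees.
#' @export
angle_deg <- function(a, b, c) {
  u <- unitv(a - b); w <- unitv(c - b)
  acos(pmin(pmax(sum(u * w), -1), 1)) * 180 / pi
}

#' Place a water oxygen at a tertiary amine
#'
#' The water oxygen is placed on the ray opposite the normalised sum of
#' the three N->C unit vectors -- the fourth tetrahedral vertex -- at
#' exactly `distance` from the nitrogen. For ideal tetrahedral geometry
#' each C-N-O(water) angle is 109.47 degrees, matching the idealized
#' 109-degree target.
#'
#' @param c A [conformer()] with coordinates.
#' @param n_idx Index of a tertiary-amine nitrogen (see
#'   [find_tertiary_amine()]).
#' @param distance Target N-O distance in Angstrom (default 3.0).
#' @return A list of class `hydration_site`: `anchor_atom`, `water_O`
#'   (xyz), `target_distance`, `target_angle` (109), `site_kind`
#'   (`"amine"`), `mean_angle` (the realised mean C-N-O angle).
#' @export
place_amine_water <- function(c, n_idx, distance = 3.0) {
  adj <- heavy_neighbors(c)
  nb <- adj[[n_idx]]
  if (length(nb) != 3L) stop("n_idx is not a tertiary amine", call. = FALSE)
  n <- coords(c, n_idx)
  units <- lapply(nb, function(i) unitv(coords(c, i) - n))
  s <- Reduce(`+`, units)
  if (vnorm(s) < 1e-8)
    stop("degenerate geometry: substituents are planar/collinear around N",
         call. = FALSE)
  w <- n - distance * unitv(s)
  angles <- vapply(nb, function(i) angle_deg(coords(c, i), n, w), numeric(1))
  structure(list(anchor_atom = n_idx, water_O = w,
                 target_distance = distance, target_angle = 109,
                 site_kind = "amine", mean_angle = mean(angles),
                 angles = angles),
            class = "hydration_site")
}

#' Place a water oxygen at a carbonyl
#'
#' The water oxygen lies in the sp2 plane of the carbonyl (defined by the
#' carbon, the oxygen and a heavy substituent of the carbon), at exactly
#' `distance` from the carbonyl oxygen with a C-O-O(water) angle of
#' `angle` degrees. Of the two in-plane solutions the one with the larger
#' minimum distance to all other ligand heavy atoms is returned
#' (deterministic; ties fall to the first azimuth).
#'
#' @param c A [conformer()] with coordinates.
#' @param c_idx,o_idx Indices of the carbonyl carbon and oxygen (must be
#'   joined by a double bond).
#' @param distance Target O-O distance in Angstrom (default 3.0).
#' @param angle Target C-O-O(water) angle in degrees (default 120).
#' @return A `hydration_site` with `site_kind = "carbonyl"`, the realised
#'   `angle`, and `flagged = TRUE` when no substituent defined the plane.
#' @export
place_carbonyl_water <- function(c, c_idx, o_idx, distance = 3.0,
                                 angle = 120) {
  is_co <- any((c$bonds$i == c_idx & c$bonds$j == o_idx |
                  c$bonds$i == o_idx & c$bonds$j == c_idx) &
                 c$bonds$order == 2L)
  if (!is_co) stop("(c_idx, o_idx) is not a C=O double bond", call. = FALSE)
  adj <- heavy_neighbors(c)
  subs <- setdiff(adj[[c_idx]], o_idx)
  pc <- coords(c, c_idx); po <- coords(c, o_idx)
  a <- unitv(pc - po)                     # from O toward C
  flagged <- FALSE
  if (length(subs) >= 1L) {
    r <- coords(c, subs[1L])
    nrm <- crossp(po - pc, r - pc)
    if (vnorm(nrm) < 1e-8) flagged <- TRUE
  } else flagged <- TRUE
  if (flagged) {
    ## no plane available: any vector at the target angle, flagged
    nrm <- crossp(a, if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
  }
  b <- unitv(crossp(unitv(nrm), a))       # in-plane, perpendicular to O->C
  th <- angle * pi / 180
  cands <- list(po + distance * (cos(th) * a + sin(th) * b),
                po + distance * (cos(th) * a - sin(th) * b))
  hv <- setdiff(heavy_idx(c), c(c_idx, o_idx))
  clearance <- vapply(cands, function(w) {
    if (!length(hv)) return(Inf)
    min(vapply(hv, function(i) vnorm(w - coords(c, i)), numeric(1)))
  }, numeric(1))
  pick <- if (clearance[2L] > clearance[1L]) 2L else 1L
  w <- cands[[pick]]
  structure(list(anchor_atom = o_idx, carbon = c_idx, water_O = w,
                 target_distance = distance, target_angle = angle,
                 site_kind = "carbonyl",
                 angle = angle_deg(pc, po, w), flagged = flagged,
                 candidate = pick),
            class = "hydration_site")
}

crossp <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Count rotatable bonds
#'
#' A bond is rotatable iff it is a single bond, acyclic (a bridge of the
#' heavy-atom graph), both atoms are non-terminal heavy atoms (heavy
#' degree >= 2), and it is not an amide C-N bond (carbon double-bonded to
#' oxygen joined to nitrogen). This rule reproduces the count of 6 for
#' fentanyl.
#'
#' @param c A [conformer()].
#' @return Integer count.
#' @examples
#' rotatable_bond_count(parse_smiles("CCCC"))  # n-butane: 1
#' @export
rotatable_bond_count <- function(c) {
  if (!nrow(c$bonds)) return(0L)
  el <- c$atoms$element
  adj <- heavy_neighbors(c)
  deg <- lengths(adj)
  acyc <- acyclic_bonds(c)
  co <- carbonyl_carbons(c)
  n_rot <- 0L
  for (b in seq_len(nrow(c$bonds))) {
    i <- c$bonds$i[b]; j <- c$bonds$j[b]
    if (c$bonds$order[b] != 1L) next
    if (!acyc[b]) next
    if (el[i] == "H" || el[j] == "H") next
    if (deg[i] < 2L || deg[j] < 2L) next
    amide <- (el[i] == "N" && j %in% co) || (el[j] == "N" && i %in% co)
    if (amide) next
    n_rot <- n_rot + 1L
  }
  n_rot
}

#' Hydrate a ligand conformer
#'
#' Places explicit water oxygens at every tertiary amine (fourth
#' tetrahedral vertex, 3.0 A) and every carbonyl oxygen (in-plane, 3.0 A,
#' 120 degrees). Waters are pseudo-atoms: they are never added to the
#' covalent graph.
#'
#' @param c A [conformer()] with coordinates.
#' @param amine,carbonyl Include amine / carbonyl sites (default both).
#' @return A list of class `hydrated_conformer` with `base` and `sites`.
#' @export
hydrate_ligand <- function(c, amine = TRUE, carbonyl = TRUE) {
  sites <- list()
  if (amine) {
    n_idx <- tryCatch(find_tertiary_amine(c), error = function(e) integer())
    for (i in n_idx) sites[[length(sites) + 1L]] <- place_amine_water(c, i)
  }
  if (carbonyl) {
    el <- c$atoms$element
    dbl <- c$bonds[c$bonds$order == 2L, , drop = FALSE]
    for (b in seq_len(nrow(dbl))) {
      ci <- if (el[dbl$i[b]] == "C" && el[dbl$j[b]] == "O") dbl$i[b]
            else if (el[dbl$j[b]] == "C" && el[dbl$i[b]] == "O") dbl$j[b]
            else next
      oi <- setdiff(c(dbl$i[b], dbl$j[b]), ci)
      sites[[length(sites) + 1L]] <- place_carbonyl_water(c, ci, oi)
    }
  }
  structure(list(base = c, sites = sites), class = "hydrated_conformer")
}

#' Parse a SMILES string into a conformer graph
#'
#' Supports the organic subset needed for ligand bookkeeping: atoms B, C,
#' N, O, P, S, F, Cl, Br, I (aromatic `c`, `n`, `o`, `s`, `p`), bracket
#' atoms with charges, bonds `-`, `=`, `#`, branches and numeric ring
#' closures. No coordinates are produced (`x`, `y`, `z` are `NA`);
#' stereochemistry is ignored.
#'
#' @param smiles SMILES string.
#' @return A [conformer()] with `NA` coordinates.
#' @examples
#' fent <- parse_smiles("CCC(=O)N(c1ccccc1)C1CCN(CCc2ccccc2)CC1")
#' rotatable_bond_count(fent)  # 6
#' @export
parse_smiles <- function(smiles) {
  chars <- strsplit(smiles, "")[[1L]]
  atoms <- data.frame(element = character(), aromatic = logical(),
                      charge = integer(), stringsAsFactors = FALSE)
  bonds <- data.frame(i = integer(), j = integer(), order = integer())
  stack <- integer()          # open-branch anchors
  prev <- NA_integer_
  pending <- NA_integer_      # explicit bond order for the next bond
  rings <- list()             # digit -> c(atom, order)
  k <- 1L
  add_atom <- function(el, aromatic, charge = 0L) {
    atoms[nrow(atoms) + 1L, ] <<- list(el, aromatic, charge)
    idx <- nrow(atoms)
    if (!is.na(prev)) {
      ord <- if (!is.na(pending)) pending else 1L
      bonds[nrow(bonds) + 1L, ] <<- list(prev, idx, ord)
    }
    prev <<- idx
    pending <<- NA_integer_
    idx
  }
  n <- length(chars)
  while (k <= n) {
    ch <- chars[k]
    two <- if (k < n) paste0(ch, chars[k + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      add_atom(two, FALSE); k <- k + 2L; next
    }
    if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch, FALSE); k <- k + 1L; next
    }
    if (ch %in% c("c", "n", "o", "s", "p")) {
      add_atom(toupper(ch), TRUE); k <- k + 1L; next
    }
    if (ch == "[") {
      close <- k + which(chars[(k + 1L):n] == "]")[1L]
      if (is.na(close)) stop("unterminated bracket atom", call. = FALSE)
      body <- paste(chars[(k + 1L):(close - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^[0-9]*(Cl|Br|[BCNOPSFI]|[cnops])@{0,2}H?[0-9]?([+-][0-9]?)?$", body))[[1L]]
      if (!length(m)) stop("unsupported bracket atom: [", body, "]", call. = FALSE)
      el <- m[2L]
      aromatic <- el %in% c("c", "n", "o", "p", "s")
      chg <- 0L
      if (nzchar(m[3L])) {
        sign <- if (substr(m[3L], 1L, 1L) == "+") 1L else -1L
        mag <- if (nchar(m[3L]) > 1L) as.integer(substr(m[3L], 2L, 2L)) else 1L
        chg <- sign * mag
      }
      add_atom(toupper(el), aromatic, chg)
      k <- close + 1L; next
    }
    if (ch == "(") { stack <- c(stack, prev); k <- k + 1L; next }
    if (ch == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      k <- k + 1L; next
    }
    if (ch == "-") { pending <- 1L; k <- k + 1L; next }
    if (ch == "=") { pending <- 2L; k <- k + 1L; next }
    if (ch == "#") { pending <- 3L; k <- k + 1L; next }
    if (ch == ":") { pending <- 1L; k <- k + 1L; next }
    if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") { lab <- paste(chars[(k + 1L):(k + 2L)], collapse = ""); k <- k + 3L }
      else { lab <- ch; k <- k + 1L }
      ord <- if (!is.na(pending)) pending else 1L
      pending <- NA_integer_
      if (!is.null(rings[[lab]])) {
        bonds[nrow(bonds) + 1L, ] <- list(rings[[lab]][1L], prev,
                                          max(ord, rings[[lab]][2L]))
        rings[[lab]] <- NULL
      } else {
        rings[[lab]] <- c(prev, ord)
      }
      next
    }
    stop("unsupported SMILES character: '", ch, "'", call. = FALSE)
  }
  if (length(rings)) stop("unclosed ring bond in SMILES", call. = FALSE)
  atoms$x <- NA_real_; atoms$y <- NA_real_; atoms$z <- NA_real_
  conformer(atoms[, c("element", "x", "y", "z", "charge", "aromatic")], bonds)
}

#' Read the first molecule of an SDF/MOL (V2000) file
#'
#' @param path SDF or MOL file.
#' @return A [conformer()].
#' @export
read_sdf <- function(path) {
  lines <- readLines(path)
  counts <- lines[4L]
  na <- as.integer(substr(counts, 1L, 3L))
  nb <- as.integer(substr(counts, 4L, 6L))
  if (is.na(na) || is.na(nb)) stop("malformed V2000 counts line", call. = FALSE)
  at <- lines[5:(4 + na)]
  atoms <- data.frame(
    element = trimws(substr(at, 32L, 34L)),
    x = as.numeric(substr(at, 1L, 10L)),
    y = as.numeric(substr(at, 11L, 20L)),
    z = as.numeric(substr(at, 21L, 30L)),
    stringsAsFactors = FALSE
  )
  if (nb > 0L) {
    bl <- lines[(5 + na):(4 + na + nb)]
    bonds <- data.frame(
      i = as.integer(substr(bl, 1L, 3L)),
      j = as.integer(substr(bl, 4L, 6L)),
      order = as.integer(substr(bl, 7L, 9L))
    )
  } else bonds <- data.frame(i = integer(), j = integer(), order = integer())
  ## bond order 4 encodes aromatic in some writers; store as order 1 + flag
  arom <- bonds$order == 4L
  bonds$order[arom] <- 1L
  atoms$aromatic <- FALSE
  if (any(arom)) atoms$aromatic[unique(c(bonds$i[arom], bonds$j[arom]))] <- TRUE
  conformer(atoms, bonds)
}

#' Write a hydrated conformer as SDF plus a JSON sidecar
#'
#' Water oxygens are appended as additional `O` atoms with no bond
#' records (pseudo-atoms outside the covalent graph). Site geometry and
#' provenance go to `<path>.json`.
#'
#' @param hc A `hydrated_conformer` (see [hydrate_ligand()]).
#' @param path Output SDF path.
#' @param title Molecule title line.
#' @return Invisibly, the paths written.
#' @export
write_hydrated_sdf <- function(hc, path, title = "hydrated_ligand") {
  stopifnot(inherits(hc, "hydrated_conformer"))
  a <- hc$base$atoms
  waters <- do.call(rbind, lapply(hc$sites, function(s)
    data.frame(element = "O", x = s$water_O[1], y = s$water_O[2],
               z = s$water_O[3])))
  na <- nrow(a) + NROW(waters)
  nb <- nrow(hc$base$bonds)
  lines <- c(title, "  ssmenrich", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  fmt_atom <- function(el, x, y, z)
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            x, y, z, el)
  lines <- c(lines, mapply(fmt_atom, a$element, a$x, a$y, a$z),
             if (!is.null(waters))
               mapply(fmt_atom, waters$element, waters$x, waters$y, waters$z),
             sprintf("%3d%3d%3d  0  0  0  0", hc$base$bonds$i,
                     hc$base$bonds$j, hc$base$bonds$order),
             "M  END", "$$$$")
  writeLines(lines, path)
  side <- lapply(hc$sites, function(s)
    list(site_kind = s$site_kind, anchor_atom = s$anchor_atom,
         water_O = as.numeric(s$water_O),
         target_distance = s$target_distance,
         target_angle = s$target_angle))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(path, paste0(path, ".json")))
}
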