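# Residue interaction network construction.
#
# Two residues on *different* chains are in contact when some atom pair
# (a, b) satisfies d(a, b) <= r(a) + r(b) + 2.75 A, where r is the van der
# Waals radius and 2.75 A is the diameter of a water molecule. Only
# residues with at least one contact become network vertices.

#' Bondi van der Waals radii (Angstrom)
#'
#' The default radii table. The contact criterion needs a van der Waals
#' radius per element but no single table is canonical; the Bondi (1964)
#' consensus values are used, and any named numeric vector can be passed
#' in its place to [build_rin] / [residues_in_contact].
#' @format named numeric vector, element symbol -> radius in Angstrom
#' @export
bondi_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90
)

#' Water-diameter contact margin (Angstrom)
#' @export
WATER_DIAMETER <- 2.75

# fallback for elements missing from the radii table
DEFAULT_RADIUS <- 1.80

#' Van der Waals radius of an element
#'
#' @param element character vector of element symbols (case-insensitive)
#' @param radii named radii table (defaults to [bondi_radii])
#' @param default fallback radius for unknown elements
#' @return numeric vector of radii in Angstrom
#' @examples
#' vdw_radius(c("C", "N", "X"))  # 1.70 1.55 1.80
#' @export
vdw_radius <- function(element, radii = bondi_radii, default = DEFAULT_RADIUS) {
  r <- radii[toupper(trimws(element))]
  unknown <- is.na(r)
  if (any(unknown)) {
    message("unknown element(s) ", paste(unique(toupper(element)[unknown]), collapse = ", "),
            ": using fallback radius ", default, " A")
    r[unknown] <- default
  }
  unname(r)
}

#' Are two residues in atomic contact?
#'
#' True when some atom pair from the two residues lies within the sum of
#' the atoms' van der Waals radii plus one water diameter (2.75 A).
#' Symmetric in its arguments.
#'
#' @param atoms_a,atoms_b data frames with columns `element`, `x`, `y`, `z`
#'   (coordinates in Angstrom), one row per atom; must be non-empty
#' @param radii named radii table
#' @param margin added distance margin (default the water diameter)
#' @return logical scalar
#' @export
residues_in_contact <- function(atoms_a, atoms_b, radii = bondi_radii,
                                margin = WATER_DIAMETER) {
  for (a in list(atoms_a, atoms_b)) {
    if (!is.data.frame(a) || nrow(a) == 0L ||
        !all(c("element", "x", "y", "z") %in% names(a))) {
      abort_input("each residue needs a non-empty atom table with element, x, y, z")
    }
  }
  ra <- vdw_radius(atoms_a$element, radii)
  rb <- vdw_radius(atoms_b$element, radii)
  d2 <- outer(atoms_a$x, atoms_b$x, "-")^2 +
        outer(atoms_a$y, atoms_b$y, "-")^2 +
        outer(atoms_a$z, atoms_b$z, "-")^2
  thr <- outer(ra, rb, "+") + margin
  any(d2 <= thr^2)
}

#' Parse a structure file into a per-residue atom table
#'
#' Reads PDB (`.pdb`/`.ent`, plain or gzipped) or mmCIF (`.cif`) files via
#' bio3d. Keeps the first model only; polymer amino-acid residues only
#' (HETATM records are dropped except selenomethionine MSE, which is
#' treated as MET); waters are excluded; alternate locations are resolved
#' to the highest-occupancy conformer (ties prefer label 'A').
#'
#' @param path structure file path
#' @param keep_hydrogens keep hydrogen atoms when present (default TRUE;
#'   no hydrogens are ever added)
#' @return a tibble of atoms with columns `chain`, `resno`, `icode`,
#'   `resname`, `atom_name`, `element`, `x`, `y`, `z`, `occupancy`, plus a
#'   `structure_id` attribute; class `structure_atoms`
#' @export
parse_structure <- function(path, keep_hydrogens = TRUE) {
  if (!file.exists(path)) abort_input("structure file not found: %s", path)
  read_path <- path
  if (grepl("\\.gz$", path)) {
    read_path <- tempfile(fileext = sub("^.*(\\.[A-Za-z]+)\\.gz$", "\\1", path))
    writeLines(readLines(gzfile(path)), read_path)
    on.exit(unlink(read_path))
  }
  is_cif <- grepl("\\.cif$", read_path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(read_path, verbose = FALSE)
    else bio3d::read.pdb(truncate_first_model(read_path), multi = FALSE,
                         rm.alt = FALSE, verbose = FALSE),
    error = function(e) abort_input("cannot parse structure %s: %s", path, conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) abort_input("structure %s contains no atoms", path)

  water <- c("HOH", "WAT", "DOD", "H2O")
  keep <- (at$type == "ATOM" | (at$type == "HETATM" & at$resid == "MSE")) &
    !(at$resid %in% water)
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) abort_input("structure %s has no polymer amino-acid atoms", path)
  at$resid[at$resid == "MSE"] <- "MET"

  elem <- toupper(trimws(at$elesy))
  noel <- is.na(elem) | elem == ""
  if (any(noel)) {
    # derive from the atom name: strip digits/primes, first letters
    nm <- gsub("[^A-Za-z]", "", at$elety[noel])
    two <- toupper(substr(nm, 1, 2)) %in% c("CL", "BR", "SE", "FE", "ZN", "MG")
    elem[noel] <- ifelse(two, toupper(substr(nm, 1, 2)), toupper(substr(nm, 1, 1)))
  }
  if (!keep_hydrogens) {
    at <- at[elem != "H", , drop = FALSE]
    elem <- elem[elem != "H"]
  }

  icode <- trimws(ifelse(is.na(at$insert), "", at$insert))
  alt <- trimws(ifelse(is.na(at$alt), "", at$alt))
  occ <- ifelse(is.na(at$o), 1, at$o)
  tb <- tibble::tibble(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    icode = icode,
    resname = as.character(at$resid),
    atom_name = trimws(as.character(at$elety)),
    alt = alt,
    element = elem,
    x = at$x, y = at$y, z = at$z,
    occupancy = occ
  )
  # altloc resolution: per (chain, resno, icode, atom name) keep the
  # highest-occupancy conformer; ties prefer '' then 'A' then 'B' ...
  key <- paste(tb$chain, tb$resno, tb$icode, tb$atom_name, sep = "\r")
  ord <- order(key, -tb$occupancy, tb$alt, method = "radix")
  tb <- tb[ord, , drop = FALSE]
  tb <- tb[!duplicated(key[ord]), , drop = FALSE]
  tb$alt <- NULL
  tb <- tb[order(tb$chain, tb$resno, tb$icode, method = "radix"), , drop = FALSE]
  structure_id <- sub("\\.(pdb|ent|cif)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  attr(tb, "structure_id") <- structure_id
  class(tb) <- c("structure_atoms", class(tb))
  tb
}

# keep only the first MODEL of a multi-model PDB file
truncate_first_model <- function(path) {
  lines <- readLines(path)
  endm <- grep("^ENDMDL", lines)
  if (length(endm) == 0L) return(path)
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(lines[seq_len(endm[1] - 1L)], "END"), tmp)
  tmp
}

# canonical vertex identifier: chain:resnum[:icode]:resname
residue_key <- function(chain, resno, icode, resname) {
  ifelse(nzchar(icode),
         paste(chain, resno, icode, resname, sep = ":"),
         paste(chain, resno, resname, sep = ":"))
}

#' Build a residue interaction network from a parsed structure
#'
#' Tests every inter-chain residue pair for atomic contact and keeps, as
#' vertices, only the residues with at least one contact. Edges never join
#' residues on the same chain. The default neighbour search bins atoms in
#' a spatial grid with cell size equal to the largest possible contact
#' threshold, which is exact: it returns identical edges to the all-pairs
#' scan (`method = "allpairs"`).
#'
#' @param atoms a `structure_atoms` table from [parse_structure]
#' @param radii named radii table (default [bondi_radii])
#' @param margin contact margin in Angstrom (default the water diameter)
#' @param method `"grid"` (default) or `"allpairs"` — must agree
#' @return an igraph graph whose vertices are residue identifiers
#'   `chain:resnum[:icode]:resname` with attributes `chain`, `resno`,
#'   `icode`, `resname`, and graph attributes `source_structure`,
#'   `margin`; class adds `contact_network`
#' @export
build_rin <- function(atoms, radii = bondi_radii, margin = WATER_DIAMETER,
                      method = c("grid", "allpairs")) {
  method <- match.arg(method)
  if (!inherits(atoms, "structure_atoms")) {
    abort_input("atoms must come from parse_structure()")
  }
  if (length(unique(atoms$chain)) < 2L) {
    abort_input("structure has a single chain: no inter-chain contacts possible")
  }
  r <- vdw_radius(atoms$element, radii)
  rk <- residue_key(atoms$chain, atoms$resno, atoms$icode, atoms$resname)
  cell <- 2 * max(r) + margin

  pairs <- if (method == "grid") {
    candidate_pairs_grid(atoms, cell)
  } else {
    which(upper.tri(matrix(TRUE, nrow(atoms), nrow(atoms))), arr.ind = TRUE)
  }
  if (nrow(pairs) > 0L) {
    i <- pairs[, 1]; j <- pairs[, 2]
    inter <- atoms$chain[i] != atoms$chain[j]
    i <- i[inter]; j <- j[inter]
    d2 <- (atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
          (atoms$z[i] - atoms$z[j])^2
    hit <- d2 <= (r[i] + r[j] + margin)^2
    em <- unique(cbind(pmin(rk[i][hit], rk[j][hit]), pmax(rk[i][hit], rk[j][hit])))
  } else {
    em <- matrix(character(0), ncol = 2)
  }
  g <- ds_graph(em)  # endpoints only: degree >= 1 by construction
  meta <- unique(tibble::tibble(key = rk, chain = atoms$chain, resno = atoms$resno,
                                icode = atoms$icode, resname = atoms$resname))
  idx <- match(igraph::V(g)$name, meta$key)
  g <- igraph::set_vertex_attr(g, "chain", value = meta$chain[idx])
  g <- igraph::set_vertex_attr(g, "resno", value = meta$resno[idx])
  g <- igraph::set_vertex_attr(g, "icode", value = meta$icode[idx])
  g <- igraph::set_vertex_attr(g, "resname", value = meta$resname[idx])
  g <- igraph::set_graph_attr(g, "source_structure", attr(atoms, "structure_id"))
  g <- igraph::set_graph_attr(g, "margin", margin)
  class(g) <- unique(c("contact_network", class(g)))
  g
}

# atom index pairs within one grid cell distance of each other
candidate_pairs_grid <- function(atoms, cell) {
  cx <- floor(atoms$x / cell); cy <- floor(atoms$y / cell); cz <- floor(atoms$z / cell)
  key <- paste(cx, cy, cz, sep = ",")
  cells <- split(seq_len(nrow(atoms)), key)
  coords <- unique(data.frame(cx = cx, cy = cy, cz = cz))
  coords$key <- paste(coords$cx, coords$cy, coords$cz, sep = ",")
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  out <- vector("list", nrow(coords) * 14L)
  k <- 0L
  for (ci in seq_len(nrow(coords))) {
    here <- cells[[coords$key[ci]]]
    for (oi in seq_len(nrow(offs))) {
      nk <- paste(coords$cx[ci] + offs$dx[oi], coords$cy[ci] + offs$dy[oi],
                  coords$cz[ci] + offs$dz[oi], sep = ",")
      there <- cells[[nk]]
      if (is.null(there)) next
      if (nk == coords$key[ci]) {
        if (length(here) > 1L) {
          p <- t(utils::combn(here, 2L))
          k <- k + 1L; out[[k]] <- p
        }
      } else if (nk > coords$key[ci]) {  # each cell pair once
        p <- as.matrix(expand.grid(here, there))
        k <- k + 1L; out[[k]] <- p
      }
    }
  }
  if (k == 0L) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out[seq_len(k)])
}

#' Write a contact network as an edge list with a JSON sidecar
#'
#' The sidecar records the structure id, the contact options and the radii
#' table, so a network file is self-describing.
#'
#' @param network a `contact_network` from [build_rin]
#' @param path output edge-list path; the sidecar is written to
#'   `paste0(path, ".json")`
#' @param radii the radii table used (recorded in the sidecar)
#' @return `path`, invisibly
#' @export
write_rin <- function(network, path, radii = bondi_radii) {
  write_edge_list(network, path)
  sidecar <- list(
    structure_id = igraph::graph_attr(network, "source_structure"),
    margin = igraph::graph_attr(network, "margin"),
    radii = as.list(radii),
    n_vertices = igraph::vcount(network),
    n_edges = igraph::ecount(network)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
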