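# Hot-spot labelling from alanine-scanning affinity data, and the
# precision/recall/F-beta evaluation of subgraph predictions.
#
# Binding free energy from a dissociation constant: dG = RT ln(Kd) with
# R = 8.314 J/(mol K) converted to kcal and T = 298.15 K, i.e.
# RT = (8.314/4184) * (273.15 + 25.0) ~ 0.59246 kcal/mol. A residue is a
# hot spot when alanine substitution raises the binding free energy by
# ddG = dG_mut - dG_wt >= 2.0 kcal/mol.

#' Gas-constant times temperature at 25 C, in kcal/mol
#' @export
RT_KCAL <- (8.314 / 4184) * (273.15 + 25.0)

#' Hot-spot threshold in kcal/mol
#' @export
HOTSPOT_DDG <- 2.0

#' Binding free energy from a dissociation constant
#'
#' @param kd dissociation constant(s) in molar; must be positive
#' @return dG = RT ln(Kd) in kcal/mol at 298.15 K
#' @examples
#' delta_g(1)      # 0
#' delta_g(1e-9)   # about -12.28
#' @export
delta_g <- function(kd) {
  if (!is.numeric(kd) || any(is.na(kd)) || any(kd <= 0)) {
    abort_input("Kd must be positive (molar)")
  }
  RT_KCAL * log(kd)
}

#' Change in binding free energy upon mutation
#'
#' @param kd_wt,kd_mut wild-type and mutant dissociation constants (molar)
#' @return ddG = dG_mut - dG_wt = RT ln(kd_mut / kd_wt), kcal/mol
#' @examples
#' ddg(1e-9, 1e-7)  # about +2.73: a hundred-fold affinity loss
#' @export
ddg <- function(kd_wt, kd_mut) {
  delta_g(kd_mut) - delta_g(kd_wt)
}

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M"
)

#' Read a SKEMPI-2.0-style mutation table
#'
#' Expects a delimited table with a complex identifier column (like
#' `#Pdb`, `1ABC_A_B`), a cleaned single-mutation column (like `TI17A`:
#' wild-type amino acid, chain, position with optional insertion code,
#' mutant amino acid) and parsed wild-type/mutant affinities in molar.
#' Multi-point mutation rows (comma-separated) are dropped.
#'
#' @param path file path
#' @param delim field delimiter (default `;`)
#' @param columns named list mapping the roles `pdb`, `mutation`,
#'   `affinity_wt`, `affinity_mut` to column names in the file
#' @return tibble with columns `structure_id`, `chain`, `wt_aa`, `resno`,
#'   `icode`, `mut_aa`, `affinity_wt`, `affinity_mut`
#' @export
read_skempi <- function(path, delim = ";",
                        columns = list(pdb = "#Pdb",
                                       mutation = "Mutation(s)_cleaned",
                                       affinity_wt = "Affinity_wt_parsed",
                                       affinity_mut = "Affinity_mut_parsed")) {
  if (!file.exists(path)) abort_input("mutation table not found: %s", path)
  tab <- utils::read.table(path, sep = delim, header = TRUE, check.names = FALSE,
                           comment.char = "", quote = "\"", stringsAsFactors = FALSE)
  need <- unlist(columns)
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    abort_input("mutation table lacks column(s): %s (found: %s)",
                paste(missing, collapse = ", "), paste(names(tab), collapse = ", "))
  }
  mut <- as.character(tab[[columns$mutation]])
  single <- !grepl(",", mut)
  tab <- tab[single, , drop = FALSE]
  mut <- mut[single]
  m <- regmatches(mut, regexec("^([A-Z])([A-Za-z0-9])([0-9]+)([A-Za-z]?)([A-Z])$", mut))
  ok <- lengths(m) == 6L
  if (any(!ok)) {
    warning(sum(!ok), " unparseable mutation string(s) dropped, e.g. '", mut[!ok][1], "'")
  }
  tab <- tab[ok, , drop = FALSE]
  m <- do.call(rbind, m[ok])
  tibble::tibble(
    structure_id = toupper(sub("_.*$", "", as.character(tab[[columns$pdb]]))),
    chain = m[, 3],
    wt_aa = m[, 2],
    resno = as.integer(m[, 4]),
    icode = toupper(m[, 5]),
    mut_aa = m[, 6],
    affinity_wt = as.numeric(tab[[columns$affinity_wt]]),
    affinity_mut = as.numeric(tab[[columns$affinity_mut]])
  )
}

#' Label network residues as hot spots from alanine-scanning records
#'
#' Uses only records whose mutant amino acid is alanine and whose
#' affinities are positive. Records are matched to network vertices by
#' chain, residue number and insertion code; a record whose wild-type
#' amino acid disagrees with the structure's residue name is skipped with
#' a warning. Replicate measurements on one residue are aggregated
#' (default: maximum ddG — a residue shown to lose >= 2 kcal/mol in any
#' experiment counts as a hot spot). Residues with no qualifying record
#' carry no label row.
#'
#' @param records mutation tibble as from [read_skempi]
#' @param network a `contact_network` (or any igraph whose vertices carry
#'   `chain`, `resno`, `icode`, `resname` attributes)
#' @param aggregate `"max"` (default) or `"mean"` over replicate records
#' @param threshold hot-spot ddG threshold in kcal/mol (default 2.0,
#'   inclusive)
#' @return tibble with columns `residue` (vertex id or NA if absent from
#'   the network), `chain`, `resno`, `icode`, `n_records`, `ddg`,
#'   `is_hotspot`, `in_network`
#' @export
label_hotspots <- function(records, network, aggregate = c("max", "mean"),
                           threshold = HOTSPOT_DDG) {
  aggregate <- match.arg(aggregate)
  assert_graph(network)
  rec <- records[records$mut_aa == "A" & records$affinity_wt > 0 &
                   records$affinity_mut > 0, , drop = FALSE]
  vmeta <- network_residues(network)
  idx <- match(paste(rec$chain, rec$resno, rec$icode),
               paste(vmeta$chain, vmeta$resno, vmeta$icode))
  in_net <- !is.na(idx)
  mismatch <- in_net & AA3TO1[vmeta$resname[idx]] != rec$wt_aa
  mismatch[is.na(mismatch)] <- FALSE
  if (any(mismatch)) {
    warning(sum(mismatch), " record(s) skipped: wild-type amino acid disagrees ",
            "with the structure residue")
    rec <- rec[!mismatch, , drop = FALSE]
    idx <- idx[!mismatch]; in_net <- in_net[!mismatch]
  }
  if (nrow(rec) == 0L) {
    return(tibble::tibble(residue = character(), chain = character(),
                          resno = integer(), icode = character(),
                          n_records = integer(), ddg = numeric(),
                          is_hotspot = logical(), in_network = logical()))
  }
  rec$ddg <- ddg(rec$affinity_wt, rec$affinity_mut)
  key <- paste(rec$chain, rec$resno, rec$icode)
  agg_fun <- if (aggregate == "max") max else mean
  agg <- tapply(rec$ddg, key, agg_fun)
  cnt <- tapply(rec$ddg, key, length)
  first <- !duplicated(key)
  out <- tibble::tibble(
    residue = ifelse(in_net[first], vmeta$residue[idx[first]], NA_character_),
    chain = rec$chain[first],
    resno = rec$resno[first],
    icode = rec$icode[first],
    n_records = as.integer(cnt[key[first]]),
    ddg = as.numeric(agg[key[first]]),
    in_network = in_net[first]
  )
  out$is_hotspot <- out$ddg >= threshold
  out[order(out$chain, out$resno, out$icode, method = "radix"),
      c("residue", "chain", "resno", "icode", "n_records", "ddg",
        "is_hotspot", "in_network")]
}

# residue metadata for network vertices; networks read back from an edge
# list carry no attributes, so fall back to parsing the canonical
# chain:resnum[:icode]:resname identifiers
network_residues <- function(network) {
  nm <- igraph::V(network)$name
  if (!is.null(igraph::vertex_attr(network, "chain"))) {
    return(tibble::tibble(
      residue = nm,
      chain = igraph::V(network)$chain,
      resno = igraph::V(network)$resno,
      icode = igraph::V(network)$icode,
      resname = igraph::V(network)$resname
    ))
  }
  parts <- strsplit(nm, ":", fixed = TRUE)
  bad <- !(lengths(parts) %in% c(3L, 4L))
  if (any(bad)) {
    abort_input("vertex id '%s' is not of the form chain:resnum[:icode]:resname",
                nm[bad][1])
  }
  tibble::tibble(
    residue = nm,
    chain = vapply(parts, `[`, "", 1L),
    resno = as.integer(vapply(parts, `[`, "", 2L)),
    icode = vapply(parts, function(p) if (length(p) == 4L) p[3L] else "", ""),
    resname = vapply(parts, function(p) p[length(p)], "")
  )
}

f_beta <- function(p, r, beta) {
  num <- (1 + beta^2) * p * r
  den <- beta^2 * p + r
  if (den == 0) 0 else num / den
}

#' Evaluate a predicted residue set against hot-spot labels
#'
#' TP are predicted hot spots, FP predicted residues that are not labelled
#' hot spots (unlabelled residues count as FP), FN hot spots that were not
#' predicted. By default the FN universe is restricted to hot spots
#' present in the network (`fn_universe = "network"`): residues absent
#' from the contact network cannot be predicted by any graph method.
#' `fn_universe = "all"` counts every labelled hot spot.
#'
#' @param predicted character vector of predicted vertex ids, or a
#'   `subgraph_result` / `subgraph_list`
#' @param labels tibble from [label_hotspots]
#' @param fn_universe `"network"` (default) or `"all"`
#' @return one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`, `f2`
#' @examples
#' labs <- tibble::tibble(residue = c("A:1:GLY", "B:2:GLY"),
#'                        is_hotspot = c(TRUE, FALSE), in_network = TRUE)
#' evaluate_prediction("A:1:GLY", labs)  # perfect: P = R = 1
#' @export
evaluate_prediction <- function(predicted, labels,
                                fn_universe = c("network", "all")) {
  fn_universe <- match.arg(fn_universe)
  if (inherits(predicted, c("subgraph_result", "subgraph_list"))) {
    predicted <- predicted_vertices(predicted)
  }
  predicted <- unique(as.character(predicted))
  hs <- labels[labels$is_hotspot, , drop = FALSE]
  if (fn_universe == "network") hs <- hs[hs$in_network, , drop = FALSE]
  hotspots <- unique(stats::na.omit(c(
    hs$residue[!is.na(hs$residue)],
    if (fn_universe == "all") paste(hs$chain, hs$resno, hs$icode, sep = ":")[is.na(hs$residue)]
  )))
  tp <- length(intersect(predicted, hotspots))
  fp <- length(setdiff(predicted, hotspots))
  fn <- length(setdiff(hotspots, predicted))
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  tibble::tibble(tp = tp, fp = fp, fn = fn, precision = p, recall = r,
                 f1 = f_beta(p, r, 1), f2 = f_beta(p, r, 2))
}

#' Average evaluation metrics across complexes
#'
#' Unweighted mean of each metric over per-complex rows.
#'
#' @param per_complex tibble with columns `precision`, `recall`, `f1`, `f2`
#'   (one row per complex)
#' @return one-row tibble of means, plus `n_complexes`
#' @export
aggregate_metrics <- function(per_complex) {
  if (!is.data.frame(per_complex) || nrow(per_complex) == 0L) {
    abort_input("need metrics for at least one complex")
  }
  cols <- c("precision", "recall", "f1", "f2")
  out <- as.list(colMeans(per_complex[, cols, drop = FALSE]))
  tibble::as_tibble(c(out, n_complexes = nrow(per_complex)))
}

#' Sweep the Min-SDS density tolerance
#'
#' Runs Min-SDS at each theta and evaluates the predicted residues against
#' the labels. A theta of 1 is run as Min-DS, the exact limit of Min-SDS
#' as theta approaches 1 from below.
#'
#' @param g contact network (igraph) with at least one edge
#' @param labels tibble from [label_hotspots]
#' @param thetas tolerance grid (default 0.5 to 0.95 by 0.05)
#' @param fn_universe passed to [evaluate_prediction]
#' @return tibble: one row per theta with `n_subgraphs`, `n_predicted`
#'   and the metrics
#' @export
sweep_theta <- function(g, labels, thetas = seq(0.5, 0.95, by = 0.05),
                        fn_universe = "network") {
  rows <- lapply(thetas, function(th) {
    res <- if (th >= 1) find_all_minimal_densest(g) else min_sds(g, theta = th)
    pred <- predicted_vertices(res)
    cbind(tibble::tibble(theta = th, n_subgraphs = length(res),
                         n_predicted = length(pred)),
          evaluate_prediction(pred, labels, fn_universe = fn_universe))
  })
  do.call(rbind, rows)
}
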