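#' Load an atomic model from a PDB-format file
#'
#' Thin wrapper around \code{bio3d::read.pdb} returning a flat atom table.
#' Insertion codes are preserved; HETATM records are dropped unless
#' requested (a warning is raised when that leaves no atoms).
#'
#' @param path PDB-format file.
#' @param include_het keep HETATM records (default FALSE).
#' @return Object of class \code{"atomic_model"}: list with \code{atoms}
#'   (data frame: chain, resno, insert, resid, elety, x, y, z, type) and
#'   \code{source} (the path).
#' @export
load_structure <- function(path, include_het = FALSE) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (!include_het) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L)
    warning("no atoms loaded (HETATM-only file with include_het = FALSE?)")
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      insert = at$insert, resid = at$resid,
                      elety = at$elety, x = at$x, y = at$y, z = at$z,
                      type = at$type, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, source = path), class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic model: %d atoms, %d residues, chains %s\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[c("chain", "resno", "insert")])),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

# charged side-chain atoms per residue type (positive: K/R; negative: D/E)
.charged_atoms <- list(
  LYS = c("NZ"), ARG = c("NE", "NH1", "NH2"),
  GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"))
.charge_sign <- c(LYS = 1, ARG = 1, GLU = -1, ASP = -1)
# polar side-chain N/O fallback for formally uncharged residues
.polar_atoms <- list(
  ASN = c("OD1", "ND2"), GLN = c("OE1", "NE2"), SER = "OG", THR = "OG1",
  TYR = "OH", HIS = c("ND1", "NE2"), TRP = "NE1", CYS = "SG", MET = "SD")

parse_residue <- function(res) {
  if (is.character(res) && length(res) == 1L) {
    parts <- strsplit(res, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("residue selector must look like 'A:146'")
    list(chain = parts[1], resno = as.integer(parts[2]))
  } else if (is.list(res)) {
    list(chain = res$chain, resno = as.integer(res$resno))
  } else stop("residue selector must be 'CHAIN:RESNO' or list(chain, resno)")
}

residue_atoms <- function(model, sel) {
  a <- model$atoms
  a[a$chain == sel$chain & a$resno == sel$resno, , drop = FALSE]
}

residue_pair_info <- function(model, res_a, res_b) {
  sa <- parse_residue(res_a); sb <- parse_residue(res_b)
  aa <- residue_atoms(model, sa); ab <- residue_atoms(model, sb)
  if (nrow(aa) == 0L) stop("residue ", sa$chain, ":", sa$resno, " not found")
  if (nrow(ab) == 0L) stop("residue ", sb$chain, ":", sb$resno, " not found")
  pick <- function(at) {
    rn <- at$resid[1]
    sel <- .charged_atoms[[rn]]
    if (!is.null(sel)) {
      got <- at[at$elety %in% sel, , drop = FALSE]
      if (nrow(got) > 0L)
        return(list(atoms = got, charged = TRUE,
                    sign = unname(.charge_sign[rn])))
    }
    sel <- .polar_atoms[[rn]]
    got <- if (!is.null(sel)) at[at$elety %in% sel, , drop = FALSE]
           else at[0, , drop = FALSE]
    if (nrow(got) == 0L) {
      # last resort: any side-chain N/O
      side <- !(at$elety %in% c("N", "CA", "C", "O", "OXT"))
      got <- at[side & grepl("^[NO]", at$elety), , drop = FALSE]
    }
    if (nrow(got) == 0L)
      stop("no charged or polar side-chain atoms in residue ", rn)
    list(atoms = got, charged = FALSE, sign = 0)
  }
  pa <- pick(aa); pb <- pick(ab)
  d <- outer(seq_len(nrow(pa$atoms)), seq_len(nrow(pb$atoms)),
             function(i, j) sqrt((pa$atoms$x[i] - pb$atoms$x[j])^2 +
                                 (pa$atoms$y[i] - pb$atoms$y[j])^2 +
                                 (pa$atoms$z[i] - pb$atoms$z[j])^2))
  list(distance = min(d),
       chain_a = sa$chain, resno_a = sa$resno, resname_a = aa$resid[1],
       chain_b = sb$chain, resno_b = sb$resno, resname_b = ab$resid[1],
       both_charged = pa$charged && pb$charged,
       opposite = pa$charged && pb$charged && pa$sign * pb$sign < 0)
}

#' Minimum charged-atom distance between two residues
#'
#' The minimum Euclidean distance (Angstrom) over the cross product of the
#' two residues' charged side-chain atoms (Lys: NZ; Arg: NE/NH1/NH2;
#' Glu: OE1/OE2; Asp: OD1/OD2).  For formally uncharged residues the
#' distance is computed over polar side-chain N/O atoms instead, and the
#' pair can never classify as a salt bridge.
#'
#' @param model an \code{"atomic_model"}.
#' @param res_a,res_b residue selectors, \code{"A:146"} style or
#'   \code{list(chain =, resno =)}.
#' @return Distance in Angstrom.
#' @export
min_charged_distance <- function(model, res_a, res_b) {
  residue_pair_info(model, res_a, res_b)$distance
}

#' Classify candidate salt bridges
#'
#' A pair is a salt bridge when both residues carry formal side-chain
#' charges of opposite sign (K/R versus D/E) and the minimum charged-atom
#' distance is at or below the cutoff.  The default 4.0 Angstrom cutoff
#' separates genuine close contacts (~3 Angstrom) from broken ones
#' (>= 4.5 Angstrom); lowering the cutoff can only demote bridges, never
#' create them.
#'
#' @param model an \code{"atomic_model"}.
#' @param pairs list of length-2 residue-selector vectors (or a 2-column
#'   character matrix / data frame), e.g.
#'   \code{list(c("A:146", "A:774"))}.
#' @param cutoff salt-bridge distance cutoff (Angstrom).
#' @return Data frame with one row per pair: residue identities,
#'   \code{min_charged_distance}, \code{opposite_charge},
#'   \code{is_salt_bridge}.
#' @export
classify_salt_bridges <- function(model, pairs, cutoff = 4.0) {
  if (is.matrix(pairs) || is.data.frame(pairs))
    pairs <- lapply(seq_len(nrow(pairs)), function(i) unlist(pairs[i, 1:2]))
  rows <- lapply(pairs, function(p) {
    info <- residue_pair_info(model, p[[1]], p[[2]])
    data.frame(chain_a = info$chain_a, resno_a = info$resno_a,
               resname_a = info$resname_a,
               chain_b = info$chain_b, resno_b = info$resno_b,
               resname_b = info$resname_b,
               min_charged_distance = info$distance,
               opposite_charge = info$opposite,
               is_salt_bridge = info$opposite && info$distance <= cutoff,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
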