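#' Residue-level bead model of a single conformation
#'
#' A conformation is represented at residue resolution: one bead per residue,
#' carrying its position (Angstrom), an effective radius (Angstrom) and its
#' electron count. This is the unit from which path nodes are built and from
#' which ideal particle projections are rendered.
#'
#' @param positions numeric `B x 3` matrix of bead centers, in Angstrom.
#' @param radii per-bead radii in Angstrom, all `> 0`.
#' @param electrons per-bead electron counts, all `> 0`.
#' @param label free-text label.
#' @return an object of class `"conformation"`.
#' @examples
#' conf <- conformation(matrix(rnorm(9), 3, 3), radii = rep(3, 3),
#'                      electrons = rep(50, 3))
#' conf
#' @export
conformation <- function(positions, radii, electrons, label = "") {
  positions <- unname(as.matrix(positions))
  if (ncol(positions) != 3) stopf("positions must be a B x 3 matrix")
  b <- nrow(positions)
  if (b < 1) stopf("a conformation needs at least one bead")
  radii <- as.numeric(radii); electrons <- as.numeric(electrons)
  if (length(radii) != b || length(electrons) != b)
    stopf("positions, radii and electrons must describe the same number of beads")
  if (!all(is.finite(positions)) || !all(is.finite(radii)) || !all(is.finite(electrons)))
    stopf("conformation fields must be finite")
  if (any(radii <= 0)) stopf("bead radii must be positive")
  if (any(electrons <= 0)) stopf("bead electron counts must be positive")
  structure(list(positions = positions, radii = radii, electrons = electrons,
                 label = as.character(label)),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation> %d beads%s\n", nrow(x$positions),
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  invisible(x)
}

n_beads <- function(conf) nrow(conf$positions)

#' Per-residue bead parameters
#'
#' Effective radius and electron count for each of the twenty standard amino
#' acids, used when coarse-graining an atomic structure to one bead per
#' residue. Electron counts are the summed atomic numbers of the residue as
#' incorporated in a peptide chain (free amino acid minus one water). Radii
#' are equivalent-sphere radii `(3V / 4 pi)^(1/3)` from standard residue
#' volumes (Zamyatnin, 1972).
#'
#' @return a data frame with columns `resid` (three-letter code, upper case),
#'   `radius` (Angstrom) and `electrons`.
#' @examples
#' head(residue_bead_table())
#' @export
residue_bead_table <- function() {
  .residue_table
}

# Residue volumes in A^3 (Zamyatnin 1972); electrons = summed atomic numbers
# of the chain residue (amino acid minus H2O).
.residue_table <- local({
  vol <- c(
    ALA = 88.6, ARG = 173.4, ASN = 114.1, ASP = 111.1, CYS = 108.5,
    GLN = 143.8, GLU = 138.4, GLY = 60.1, HIS = 153.2, ILE = 166.7,
    LEU = 166.7, LYS = 168.6, MET = 162.9, PHE = 189.9, PRO = 112.7,
    SER = 89.0, THR = 116.1, TRP = 227.8, TYR = 193.6, VAL = 140.0)
  electrons <- c(
    ALA = 38, ARG = 84, ASN = 60, ASP = 60, CYS = 54,
    GLN = 68, GLU = 68, GLY = 30, HIS = 72, ILE = 62,
    LEU = 62, LYS = 70, MET = 70, PHE = 78, PRO = 52,
    SER = 46, THR = 54, TRP = 98, TYR = 86, VAL = 54)
  data.frame(resid = names(vol),
             radius = (3 * vol / (4 * pi))^(1 / 3),
             electrons = as.numeric(electrons),
             row.names = NULL)
})

.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, SE = 78.971)

#' Coarse-grain an atomic structure to one bead per residue
#'
#' Collapses each residue to a single bead at the residue's center of mass,
#' with radius and electron count looked up per residue type in
#' [residue_bead_table()].
#'
#' @param atoms either a `pdb` object from [bio3d::read.pdb()] or a data frame
#'   with columns `x`, `y`, `z`, `resid` (three-letter residue code), `resno`
#'   (residue number) and optionally `elety`/`elesy` or `element` and `chain`.
#' @param table bead lookup table, by default [residue_bead_table()].
#' @return a [conformation()] with one bead per residue (chains concatenated
#'   in file order).
#' @details Residue types absent from the lookup table are an error (they are
#'   never silently dropped). Hydrogens, if present, contribute to the center
#'   of mass through their atomic masses.
#' @export
coarse_grain <- function(atoms, table = residue_bead_table()) {
  if (inherits(atoms, "pdb")) atoms <- atoms$atom
  atoms <- as.data.frame(atoms)
  need <- c("x", "y", "z", "resid", "resno")
  if (!all(need %in% names(atoms)))
    stopf("atom records need columns: %s", paste(need, collapse = ", "))
  atoms <- atoms[is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z), ]
  if (nrow(atoms) == 0) stopf("structure has no resolvable coordinates")

  chain <- if ("chain" %in% names(atoms)) as.character(atoms$chain) else ""
  chain[is.na(chain)] <- ""
  key <- paste(chain, atoms$resno, sep = "|")
  key <- factor(key, levels = unique(key))  # preserve file order

  elem <- if ("element" %in% names(atoms)) toupper(as.character(atoms$element))
          else toupper(substr(gsub("[^A-Za-z].*$", "", as.character(atoms$elety %||% "C")), 1, 1))
  mass <- .element_mass[elem]
  mass[is.na(mass)] <- 12.011

  pieces <- split(seq_len(nrow(atoms)), key)
  pos <- matrix(0, length(pieces), 3)
  rad <- numeric(length(pieces)); ele <- numeric(length(pieces))
  for (i in seq_along(pieces)) {
    idx <- pieces[[i]]
    rtype <- toupper(as.character(atoms$resid[idx[1]]))
    row <- match(rtype, table$resid)
    if (is.na(row))
      stopf("residue type '%s' is missing from the bead table", rtype)
    w <- mass[idx] / sum(mass[idx])
    pos[i, ] <- c(sum(w * atoms$x[idx]), sum(w * atoms$y[idx]), sum(w * atoms$z[idx]))
    rad[i] <- table$radius[row]
    ele[i] <- table$electrons[row]
  }
  conformation(pos, rad, ele, label = "coarse-grained")
}
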