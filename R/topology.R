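#' @keywords internal
"_PACKAGE"

# Bondi-style van der Waals radii (Angstrom) per element. Ions use the
# plain element radius (no ionic-radius distinction). Unknown elements fall
# back to .vdw_default.
.vdw_table <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  "NA" = 2.27, K = 2.75, MG = 1.73, CA = 2.31, ZN = 1.39, FE = 1.56
)
.vdw_default <- 1.70

# approximate atomic masses for center-of-mass calculations
.mass_table <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  "NA" = 22.990, K = 39.098, MG = 24.305, CA = 40.078, ZN = 65.38,
  FE = 55.845
)
.mass_default <- 12.011

.water_resnames <- c("HOH", "TIP3", "TIP", "WAT", "SOL", "SPC", "H2O", "TP3")
.ion_resnames <- c("NA", "SOD", "CL", "CLA", "K", "POT", "MG", "ZN", "CAL", "FE")

#' Look up a van der Waals radius by element symbol
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of radii in Angstrom; unknown elements receive the
#'   documented default of 1.70 Angstrom.
#' @export
vdw_radius <- function(element) {
  r <- .vdw_table[toupper(element)]
  r[is.na(r)] <- .vdw_default
  unname(r)
}

.atomic_mass <- function(element) {
  m <- .mass_table[toupper(element)]
  m[is.na(m)] <- .mass_default
  unname(m)
}

# map monoatomic-ion residue names to element symbols
.ion_elements <- c("NA" = "NA", SOD = "NA", CL = "CL", CLA = "CL", K = "K",
                   POT = "K", MG = "MG", ZN = "ZN", CAL = "CA", FE = "FE")

# derive element symbol from PDB fields: prefer the element column; for ion
# residues use the residue name; otherwise the first alphabetic character of
# the atom name (so atom name "CA" stays carbon, not calcium)
.guess_element <- function(elesy, name, res_name = NULL) {
  e <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  miss <- e == ""
  if (any(miss)) {
    nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", name[miss])))
    e[miss] <- substr(nm, 1, 1)
    if (!is.null(res_name)) {
      ion <- .ion_elements[toupper(res_name[miss])]
      e[miss] <- ifelse(is.na(ion), e[miss], ion)
    }
  }
  e
}

#' Read a PDB file into a Topology
#'
#' Parses ATOM/HETATM records and classifies each atom as protein, water,
#' ion or substrate.  Roles are assigned deterministically from the residue
#' name: conventional water residue names (HOH, TIP3, WAT, SOL, ...) become
#' \code{water}, monoatomic ion residue names (NA, SOD, CL, CLA, K, ...)
#' become \code{ion}, residues matching \code{substrate_name} become
#' \code{substrate}, and everything else is \code{protein}.
#'
#' @param path path to a PDB file (single- or multi-model; only the first
#'   model defines the topology).
#' @param substrate_name residue name to tag as substrate, or \code{NULL}.
#' @return a \code{topology} object: a data.frame with columns
#'   \code{serial}, \code{name}, \code{element}, \code{res_name},
#'   \code{res_id}, \code{chain}, \code{role}, \code{vdw_radius},
#'   \code{mass}.
#' @export
load_topology <- function(path, substrate_name = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("malformed PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  a <- pdb$atom
  if (nrow(a) == 0L) stop("empty input: no ATOM/HETATM records in ", path)
  res_name <- toupper(trimws(a$resid))
  element <- .guess_element(a$elesy, a$elety, res_name)
  role <- rep("protein", nrow(a))
  role[res_name %in% .water_resnames] <- "water"
  role[res_name %in% .ion_resnames] <- "ion"
  if (!is.null(substrate_name))
    role[res_name == toupper(substrate_name)] <- "substrate"
  chain <- ifelse(is.na(a$chain), "A", a$chain)
  top <- data.frame(
    serial = a$eleno, name = trimws(a$elety), element = element,
    res_name = res_name, res_id = a$resno, chain = chain, role = role,
    vdw_radius = vdw_radius(element), mass = .atomic_mass(element),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(top$serial)) top$serial <- seq_len(nrow(top))
  class(top) <- c("topology", "data.frame")
  attr(top, "source") <- path
  top
}

#' @export
print.topology <- function(x, ...) {
  cat("Topology:", nrow(x), "atoms,",
      length(unique(paste(x$chain, x$res_id))), "residues\n")
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$role)),
                                as.integer(table(x$role))), collapse = ", "),
      "\n")
  invisible(x)
}

n_atoms <- function(topology) nrow(topology)
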