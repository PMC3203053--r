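#' Resolve a selection expression to atom indices
#'
#' Selections name residues and optionally atom names and a chain, e.g.
#' \code{"res 493, atoms OE1 OE2"}, \code{"res 88-94"} or
#' \code{"chain A res 79 atoms NH1 NH2"}.  A selection can also be given
#' structurally as a list with elements \code{res_id} (integer vector),
#' \code{atom_names} (character or NULL), \code{chain} (single chain id or
#' NULL) and \code{role} (role filter or NULL).
#'
#' @param topology a \code{topology}.
#' @param spec selection string or list.
#' @return sorted unique integer vector of 1-based row indices into the
#'   topology.  An empty result is an error (fail-fast), never an empty
#'   vector.
#' @export
resolve_selection <- function(topology, spec) {
  sel <- if (is.character(spec)) parse_selection(spec) else spec
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(sel$chain)) keep <- keep & topology$chain == sel$chain
  if (!is.null(sel$res_id)) keep <- keep & topology$res_id %in% sel$res_id
  if (!is.null(sel$atom_names))
    keep <- keep & topology$name %in% sel$atom_names
  if (!is.null(sel$role)) keep <- keep & topology$role == sel$role
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("unknown selection: no atoms match ",
         if (is.character(spec)) spec else deparse(spec, nlines = 1))
  sort(unique(idx))
}

#' Parse a selection string
#'
#' Grammar: optional \code{chain <id>}, optional \code{res <ids>} where ids
#' are space/comma separated integers or \code{a-b} ranges, optional
#' \code{atoms <names>}, optional \code{role <role>}.
#'
#' @param spec selection string.
#' @return selection list (see \code{\link{resolve_selection}}).
#' @export
parse_selection <- function(spec) {
  toks <- strsplit(gsub(",", " ", spec), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  out <- list(res_id = NULL, atom_names = NULL, chain = NULL, role = NULL)
  mode <- ""
  for (tk in toks) {
    low <- tolower(tk)
    if (low %in% c("res", "resid", "residue", "residues")) { mode <- "res"; next }
    if (low %in% c("atom", "atoms", "name", "names")) { mode <- "atoms"; next }
    if (low == "chain") { mode <- "chain"; next }
    if (low == "role") { mode <- "role"; next }
    if (mode == "res") {
      if (grepl("^-?[0-9]+--?[0-9]+$", tk) && grepl("[0-9]-", tk)) {
        ab <- regmatches(tk, regexec("^(-?[0-9]+)-(-?[0-9]+)$", tk))[[1]][2:3]
        out$res_id <- c(out$res_id, seq(as.integer(ab[1]), as.integer(ab[2])))
      } else if (grepl("^-?[0-9]+$", tk)) {
        out$res_id <- c(out$res_id, as.integer(tk))
      } else stop("cannot parse residue token '", tk, "' in selection: ", spec)
    } else if (mode == "atoms") {
      out$atom_names <- c(out$atom_names, tk)
    } else if (mode == "chain") {
      out$chain <- tk
    } else if (mode == "role") {
      out$role <- low
    } else {
      stop("cannot parse selection token '", tk, "' in: ", spec)
    }
  }
  out
}

# indices of all atoms of the residues in a TM range (inclusive)
.tm_indices <- function(topology, range, chain = NULL) {
  sel <- list(res_id = seq(range[1], range[2]), chain = chain)
  resolve_selection(topology, sel)
}

# C-alpha subset of a set of atom indices, ordered by residue
.ca_indices <- function(topology, idx) {
  ca <- idx[topology$name[idx] == "CA"]
  ca[order(topology$res_id[ca])]
}

# indices of water oxygen atoms
.water_oxygens <- function(topology) {
  which(topology$role == "water" & topology$element == "O")
}
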