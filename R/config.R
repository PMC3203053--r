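#' Named residue/atom groups driving every analysis
#'
#' @param tm_ranges named list; each entry \code{c(start, end)} residue ids
#'   (inclusive).  Sub-helix entries such as \code{TM1a}/\code{TM1b} are
#'   ordinary entries.
#' @param gates list of \code{\link{gate_definition}} objects.
#' @param pathway_residues integer residue ids of the cytoplasmic pathway.
#' @param cavity_defs list of \code{\link{cavity_definition}} objects.
#' @param scaffold_tms,bundle_tms character TM names; must be disjoint.
#' @param ion_ids atom serials of tracked ions.
#' @param substrate_res substrate residue name.
#' @param tm_polarity named numeric (+1/-1) per TM: +1 when the helix runs
#'   IC-to-EC in the N-to-C direction.  Used to orient helix axes; TMs
#'   absent from the map default to +1.
#' @param frame_dt frame spacing in ns.
#' @return a \code{selection_config} object.
#' @export
selection_config <- function(tm_ranges = list(), gates = list(),
                             pathway_residues = integer(),
                             cavity_defs = list(),
                             scaffold_tms = character(),
                             bundle_tms = character(),
                             ion_ids = integer(),
                             substrate_res = NULL,
                             tm_polarity = numeric(),
                             frame_dt = 0.1) {
  if (length(intersect(scaffold_tms, bundle_tms)) > 0L)
    stop("scaffold and bundle TM sets must be disjoint")
  structure(list(tm_ranges = tm_ranges, gates = gates,
                 pathway_residues = as.integer(pathway_residues),
                 cavity_defs = cavity_defs,
                 scaffold_tms = scaffold_tms, bundle_tms = bundle_tms,
                 ion_ids = ion_ids, substrate_res = substrate_res,
                 tm_polarity = tm_polarity, frame_dt = frame_dt),
            class = "selection_config")
}

#' Check a selection config against a topology
#'
#' Verifies that every residue referenced by TM ranges, gates, pathway and
#' cavity definitions exists in the topology.
#'
#' @param cfg a \code{selection_config}.
#' @param topology a \code{topology}.
#' @return invisibly TRUE; errors otherwise.
#' @export
validate_config <- function(cfg, topology) {
  have <- unique(topology$res_id)
  for (nm in names(cfg$tm_ranges)) {
    r <- cfg$tm_ranges[[nm]]
    miss <- setdiff(seq(r[1], r[2]), have)
    if (length(miss))
      stop("TM range ", nm, " references absent residues: ",
           paste(utils::head(miss, 5), collapse = ", "))
  }
  miss <- setdiff(cfg$pathway_residues, have)
  if (length(miss))
    stop("pathway references absent residues: ",
         paste(utils::head(miss, 5), collapse = ", "))
  for (g in cfg$gates) {
    resolve_selection(topology, g$groupA)
    resolve_selection(topology, g$groupB)
  }
  for (cv in cfg$cavity_defs)
    if (!(cv$reference_residue %in% have))
      stop("cavity reference residue ", cv$reference_residue, " absent")
  invisible(TRUE)
}

#' Read a selection config from a YAML file
#'
#' @param path YAML file, as written by \code{\link{write_selection_config}}
#'   or the synthetic generator.
#' @return a \code{selection_config}.
#' @export
read_selection_config <- function(path) {
  y <- yaml::read_yaml(path)
  gates <- lapply(y$gates, function(g)
    gate_definition(g$name, g$groupA, g$groupB,
                    formed_cutoff = g$formed_cutoff %||% 4.0,
                    broken_cutoff = g$broken_cutoff %||% 6.0))
  cavs <- lapply(y$cavity_defs, function(cv)
    cavity_definition(cv$side, cv$reference_residue, unlist(cv$tm_list),
                      cutoff = cv$cutoff %||% 10,
                      z_min = cv$z_min %||% -Inf,
                      z_max = cv$z_max %||% Inf,
                      tm_logic = cv$tm_logic %||% "all"))
  pol <- unlist(y$tm_polarity %||% list())
  selection_config(
    tm_ranges = lapply(y$tm_ranges, function(r) as.integer(unlist(r))),
    gates = gates,
    pathway_residues = unlist(y$pathway_residues %||% integer()),
    cavity_defs = cavs,
    scaffold_tms = unlist(y$scaffold_tms %||% character()),
    bundle_tms = unlist(y$bundle_tms %||% character()),
    ion_ids = unlist(y$ion_ids %||% integer()),
    substrate_res = y$substrate_res,
    tm_polarity = pol,
    frame_dt = y$frame_dt %||% 0.1
  )
}

#' Write a selection config to YAML
#'
#' @param cfg a \code{selection_config}.
#' @param path output path.
#' @export
write_selection_config <- function(cfg, path) {
  y <- list(
    tm_ranges = lapply(cfg$tm_ranges, as.integer),
    gates = lapply(cfg$gates, function(g)
      list(name = g$name, groupA = g$groupA, groupB = g$groupB,
           formed_cutoff = g$formed_cutoff, broken_cutoff = g$broken_cutoff)),
    pathway_residues = as.integer(cfg$pathway_residues),
    cavity_defs = lapply(cfg$cavity_defs, function(cv)
      list(side = cv$side, reference_residue = cv$reference_residue,
           tm_list = cv$tm_list, cutoff = cv$cutoff,
           z_min = if (is.finite(cv$z_min)) cv$z_min else NULL,
           z_max = if (is.finite(cv$z_max)) cv$z_max else NULL,
           tm_logic = cv$tm_logic)),
    scaffold_tms = cfg$scaffold_tms, bundle_tms = cfg$bundle_tms,
    ion_ids = as.integer(cfg$ion_ids), substrate_res = cfg$substrate_res,
    tm_polarity = as.list(cfg$tm_polarity), frame_dt = cfg$frame_dt
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
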