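#' Define a small-molecule ligand
#'
#' A ligand is a metabolite (inducer or anti-inducer) that allosterically
#' regulates one or more repressors. Its `working_concentration` is the
#' concentration at which it is supplied whenever an input signal carrying it
#' is set to 1.
#'
#' @param name Ligand identifier (e.g. `"IPTG"`).
#' @param working_concentration Concentration in millimolar at which the
#'   ligand is added to a reaction; must be non-negative.
#' @return An object of class `rca_ligand`.
#' @examples
#' ligand("IPTG", 5)
#' @export
ligand <- function(name, working_concentration) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.numeric(working_concentration),
            length(working_concentration) == 1L,
            working_concentration >= 0)
  structure(list(name = name,
                 working_concentration = as.numeric(working_concentration)),
            class = "rca_ligand")
}

#' Define an allosterically regulated repressor
#'
#' Repressors bind their operator sequence on the circular template and block
#' the strand-displacing polymerase. Two regulation modes exist:
#' `"inducer"` repressors (e.g. LacI, GalR) bind DNA in the absence of their
#' cognate ligand and are released by it; `"anti_inducer"` repressors
#' (e.g. TrpR, MetJ) bind DNA only when their cognate ligand (a co-repressor)
#' is present.
#'
#' `affinity_thresholds` gives, per ligand, the minimal concentration (mM) at
#' which that ligand allosterically switches this repressor. The cognate
#' ligand must have an entry; additional entries encode cross-reactivity
#' (a non-cognate ligand that switches the repressor at high concentration).
#' Ligands with no entry never switch the repressor (threshold `Inf`).
#'
#' `leak` is the fraction of the full polymerase rate that escapes a bound
#' site; it affects only the kinetic layer, never the Boolean layer.
#'
#' @param name Repressor identifier.
#' @param mode `"inducer"` or `"anti_inducer"`.
#' @param cognate_ligand Name of the regulating metabolite.
#' @param operator_id Identifier of the recognition sequence in the operator
#'   database.
#' @param affinity_thresholds Named numeric vector, ligand name ->
#'   switching threshold in mM. Must contain `cognate_ligand`.
#' @param leak Residual rate fraction in `[0, 1]` through a bound site.
#' @return An object of class `rca_repressor`.
#' @examples
#' repressor_spec("LacI", "inducer", "IPTG", "lacO1_syn",
#'                c(IPTG = 0.1, `D-Gal` = 10))
#' @export
repressor_spec <- function(name, mode = c("inducer", "anti_inducer"),
                           cognate_ligand, operator_id,
                           affinity_thresholds, leak = 0) {
  mode <- match.arg(mode)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.numeric(affinity_thresholds),
            !is.null(names(affinity_thresholds)),
            all(nzchar(names(affinity_thresholds))))
  if (!cognate_ligand %in% names(affinity_thresholds)) {
    stop("affinity_thresholds must contain the cognate ligand '",
         cognate_ligand, "'")
  }
  stopifnot(all(affinity_thresholds > 0))
  stopifnot(is.numeric(leak), length(leak) == 1L, leak >= 0, leak <= 1)
  structure(list(name = name, mode = mode,
                 cognate_ligand = cognate_ligand,
                 operator_id = operator_id,
                 affinity_thresholds = affinity_thresholds,
                 leak = as.numeric(leak)),
            class = "rca_repressor")
}

#' Species registry: ligands and repressors available to a reaction
#'
#' @param ligands List of [ligand()] objects.
#' @param repressors List of [repressor_spec()] objects.
#' @return An object of class `rca_registry` with named member lists.
#' @seealso [default_registry()] for the shipped LacI/GalR/TrpR/MetJ library.
#' @export
species_registry <- function(ligands, repressors) {
  lig_names <- vapply(ligands, function(x) x$name, character(1))
  rep_names <- vapply(repressors, function(x) x$name, character(1))
  if (anyDuplicated(lig_names)) stop("duplicate ligand names in registry")
  if (anyDuplicated(rep_names)) stop("duplicate repressor names in registry")
  for (r in repressors) {
    if (!r$cognate_ligand %in% lig_names) {
      stop("repressor '", r$name, "' names unknown cognate ligand '",
           r$cognate_ligand, "'")
    }
  }
  structure(list(ligands = stats::setNames(ligands, lig_names),
                 repressors = stats::setNames(repressors, rep_names)),
            class = "rca_registry")
}

#' The default repressor/ligand library
#'
#' Two inducer-regulated repressors (LacI released by IPTG, GalR released by
#' D-galactose) and two anti-inducer-regulated repressors (TrpR bound upon
#' L-tryptophan, MetJ bound upon S-adenosylmethionine). Working
#' concentrations are 5 mM IPTG, 5 mM D-Gal, 1 mM SAM and 1 mM L-Trp;
#' D-Gal and SAM are deliberately held below the concentrations at which they
#' cross-react (D-Gal weakly induces LacI above 10 mM, SAM triggers TrpR
#' binding above 1.5 mM). MetJ represses imperfectly and carries a leak of
#' 0.15; the other repressors repress completely.
#'
#' @return An `rca_registry`.
#' @export
default_registry <- function() {
  species_registry(
    ligands = list(
      ligand("IPTG", 5),
      ligand("D-Gal", 5),
      ligand("SAM", 1),
      ligand("L-Trp", 1)
    ),
    repressors = list(
      repressor_spec("LacI", "inducer", "IPTG", "lacO1_syn",
                     c(IPTG = 0.1, `D-Gal` = 10), leak = 0),
      repressor_spec("GalR", "inducer", "D-Gal", "galO_syn",
                     c(`D-Gal` = 0.1), leak = 0),
      repressor_spec("TrpR", "anti_inducer", "L-Trp", "trpO_syn",
                     c(`L-Trp` = 0.1, SAM = 1.5), leak = 0),
      repressor_spec("MetJ", "anti_inducer", "SAM", "metbox_syn",
                     c(SAM = 0.1), leak = 0.15)
    )
  )
}

#' Construct a species state
#'
#' The condition of one truth-table row: which repressor proteins are in the
#' tube and at what concentration each ligand is present. Absent ligands are
#' concentration 0.
#'
#' @param repressors Character vector of repressor names present.
#' @param ligand_concentrations Named numeric vector, ligand name -> mM.
#' @return An object of class `rca_state`.
#' @export
species_state <- function(repressors = character(),
                          ligand_concentrations = numeric()) {
  stopifnot(is.character(repressors))
  if (length(ligand_concentrations)) {
    stopifnot(is.numeric(ligand_concentrations),
              !is.null(names(ligand_concentrations)),
              all(ligand_concentrations >= 0))
  }
  structure(list(repressors = unique(repressors),
                 ligand_concentrations = ligand_concentrations),
            class = "rca_state")
}

ligand_conc <- function(state, name) {
  lc <- state$ligand_concentrations
  if (name %in% names(lc)) unname(lc[[name]]) else 0
}

#' Operator site on a circular template
#'
#' @param operator_id Identifier of the recognition sequence.
#' @param repressor Name of the cognate repressor.
#' @return An object of class `rca_site`.
#' @export
operator_site <- function(operator_id, repressor) {
  stopifnot(is.character(operator_id), length(operator_id) == 1L,
            is.character(repressor), length(repressor) == 1L)
  structure(list(operator_id = operator_id, repressor = repressor),
            class = "rca_site")
}

#' Circular RCA template carrying operator sites in series
#'
#' Site order is circular: two templates whose sites are rotations of one
#' another are the same molecule. Because a repressor bound anywhere along
#' the circle stops the polymerase, the Boolean activity of a template never
#' depends on site order; order matters only for sequence assembly.
#'
#' @param name Template identifier.
#' @param sites List of [operator_site()] objects (may be empty).
#' @param primer_region Primer-binding sequence on the template strand
#'   (optional until sequence assembly).
#' @param total_length Target circle length in nt (optional).
#' @param spacers Integer vector of spacer lengths (nt) preceding each site;
#'   recycled if length 1.
#' @return An object of class `rca_template`.
#' @export
circular_template <- function(name, sites = list(), primer_region = NULL,
                              total_length = NULL, spacers = 6L) {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot(is.list(sites))
  for (s in sites) stopifnot(inherits(s, "rca_site"))
  reps <- vapply(sites, function(s) s$repressor, character(1))
  if (anyDuplicated(reps)) {
    stop("template '", name, "' carries the same repressor site twice")
  }
  spacers <- rep_len(as.integer(spacers), max(1L, length(sites)))
  structure(list(name = name, sites = sites, primer_region = primer_region,
                 total_length = total_length, spacers = spacers),
            class = "rca_template")
}

#' Assemble a reaction system
#'
#' A reaction system is the unit whose truth table is evaluated: one or more
#' circular templates, the species held constant across all conditions, and a
#' mapping from named input signals to the species each signal adds when set
#' to 1. An input may carry several ligands and/or repressor proteins
#' (composite inputs). A ligand may be constant or input-controlled, never
#' both.
#'
#' @param templates List of [circular_template()] objects (at least one).
#' @param constants An [species_state()] of species always present.
#' @param input_map Named list, input signal name -> list with elements
#'   `ligands` (character vector) and/or `repressors` (character vector).
#' @param label Free-text label (e.g. the gate name).
#' @param registry An `rca_registry`; defaults to [default_registry()].
#' @return An object of class `rca_system`.
#' @examples
#' and_gate <- reaction_system(
#'   templates = list(circular_template("t1", list(
#'     operator_site("lacO1_syn", "LacI"),
#'     operator_site("galO_syn", "GalR")))),
#'   constants = species_state(c("LacI", "GalR")),
#'   input_map = list(A = list(ligands = "IPTG"),
#'                    B = list(ligands = "D-Gal")),
#'   label = "AND")
#' @export
reaction_system <- function(templates, constants = species_state(),
                            input_map = list(), label = "",
                            registry = default_registry()) {
  stopifnot(is.list(templates), length(templates) >= 1L)
  for (tp in templates) stopifnot(inherits(tp, "rca_template"))
  stopifnot(inherits(constants, "rca_state"))
  if (length(input_map)) {
    stopifnot(!is.null(names(input_map)), all(nzchar(names(input_map))))
  }
  input_map <- lapply(input_map, function(entry) {
    list(ligands = as.character(entry$ligands %||% character()),
         repressors = as.character(entry$repressors %||% character()))
  })
  const_lig <- names(constants$ligand_concentrations)
  for (nm in names(input_map)) {
    clash <- intersect(input_map[[nm]]$ligands, const_lig)
    if (length(clash)) {
      stop("ligand(s) ", paste(clash, collapse = ", "),
           " are both constant and controlled by input '", nm, "'")
    }
  }
  # every referenced species must be registered
  all_sites <- unlist(lapply(templates, function(tp) {
    vapply(tp$sites, function(s) s$repressor, character(1))
  }))
  unknown <- setdiff(all_sites, names(registry$repressors))
  if (length(unknown)) {
    stop("unregistered repressor(s) on template sites: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(templates = templates, constants = constants,
                 input_map = input_map, label = label, registry = registry),
            class = "rca_system")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve a truth-table assignment to a species state
#'
#' Merges the system's constant species with the species carried by every
#' input signal assigned 1. Ligands enter at their registry working
#' concentration; inputs assigned 0 contribute nothing.
#'
#' @param system An `rca_system`.
#' @param assignment Named integer/logical vector over exactly the system's
#'   input names (0/1).
#' @return An [species_state()].
#' @export
resolve_state <- function(system, assignment) {
  inputs <- names(system$input_map)
  assignment <- check_assignment(assignment, inputs)
  reps <- system$constants$repressors
  lig <- system$constants$ligand_concentrations
  if (length(lig) == 0) lig <- stats::setNames(numeric(), character())
  for (nm in inputs[assignment == 1L]) {
    entry <- system$input_map[[nm]]
    reps <- union(reps, entry$repressors)
    for (lg in entry$ligands) {
      spec <- system$registry$ligands[[lg]]
      if (is.null(spec)) stop("input '", nm, "' carries unregistered ligand '",
                              lg, "'")
      lig[[lg]] <- max(ligand_conc_vec(lig, lg), spec$working_concentration)
    }
  }
  species_state(reps, lig)
}

ligand_conc_vec <- function(lig, name) {
  if (name %in% names(lig)) lig[[name]] else 0
}

check_assignment <- function(assignment, inputs) {
  if (is.logical(assignment)) assignment <- as.integer(assignment)
  stopifnot(is.numeric(assignment))
  if (is.null(names(assignment)) && length(assignment) == length(inputs)) {
    names(assignment) <- inputs
  }
  missing <- setdiff(inputs, names(assignment))
  extra <- setdiff(names(assignment), inputs)
  if (length(missing)) stop("assignment misses input(s): ",
                            paste(missing, collapse = ", "))
  if (length(extra)) stop("assignment names unknown input(s): ",
                          paste(extra, collapse = ", "))
  out <- as.integer(assignment[inputs])
  stopifnot(all(out %in% c(0L, 1L)))
  stats::setNames(out, inputs)
}

#' Is an operator site occupied by its repressor?
#'
#' The threshold binding rule. A site can only be occupied when its cognate
#' repressor protein is present. An inducer-regulated repressor then binds
#' unless some ligand reaches its switching threshold (the inducer releases
#' it from DNA); an anti-inducer-regulated repressor binds only when some
#' ligand reaches its threshold (the co-repressor licenses binding).
#' Non-cognate thresholds model cross-reactivity at high concentration.
#'
#' @param site An [operator_site()].
#' @param registry An `rca_registry`.
#' @param state An [species_state()].
#' @return 0/1 occupancy bit.
#' @export
site_occupied <- function(site, registry, state) {
  spec <- registry$repressors[[site$repressor]]
  if (is.null(spec)) stop("site names unregistered repressor '",
                          site$repressor, "'")
  if (!spec$name %in% state$repressors) return(0L)
  thr <- spec$affinity_thresholds
  switched <- any(vapply(names(thr), function(lg) {
    ligand_conc(state, lg) >= thr[[lg]]
  }, logical(1)))
  if (spec$mode == "inducer") {
    if (switched) 0L else 1L
  } else {
    if (switched) 1L else 0L
  }
}

#' Is a circular template free to amplify?
#'
#' The polymerase traverses the whole circle, so a repressor bound at any
#' site stops amplification: a template is active iff every one of its sites
#' is unoccupied. Site order and position never affect the bit.
#'
#' @inheritParams site_occupied
#' @param template An [circular_template()].
#' @return 0/1 activity bit.
#' @export
template_active <- function(template, registry, state) {
  for (s in template$sites) {
    if (site_occupied(s, registry, state) == 1L) return(0L)
  }
  1L
}

#' Count active templates under one assignment
#'
#' Templates act independently: a repressor bound on one circle does not
#' affect another. Returns both the number and fraction of active templates.
#'
#' @param system An `rca_system`.
#' @param assignment Named 0/1 vector over the system's inputs.
#' @return List with `active_count`, `fraction` and the resolved `state`.
#' @export
system_activity <- function(system, assignment) {
  state <- resolve_state(system, assignment)
  act <- vapply(system$templates, template_active,
                integer(1), registry = system$registry, state = state)
  list(active_count = sum(act), fraction = mean(act), state = state,
       active = act)
}

#' Ligand-by-repressor allosteric switching matrix
#'
#' For each (ligand, repressor) pair, whether the ligand at the given
#' concentration switches the repressor (releases it if inducer-regulated,
#' binds it if anti-inducer-regulated). At the default working
#' concentrations the matrix is diagonal — the four modules are orthogonal.
#' Raising D-Gal above 10 mM additionally switches LacI; raising SAM above
#' 1.5 mM additionally switches TrpR.
#'
#' @param registry An `rca_registry`.
#' @param concentrations Optional named numeric vector ligand -> mM;
#'   defaults to registry working concentrations.
#' @return Integer matrix, rows = ligands, columns = repressors.
#' @export
switch_matrix <- function(registry = default_registry(),
                          concentrations = NULL) {
  lig_names <- names(registry$ligands)
  rep_names <- names(registry$repressors)
  if (is.null(concentrations)) {
    concentrations <- vapply(registry$ligands,
                             function(l) l$working_concentration, numeric(1))
  }
  m <- matrix(0L, nrow = length(lig_names), ncol = length(rep_names),
              dimnames = list(lig_names, rep_names))
  for (lg in lig_names) {
    conc <- if (lg %in% names(concentrations)) concentrations[[lg]] else 0
    for (rp in rep_names) {
      thr <- registry$repressors[[rp]]$affinity_thresholds
      if (lg %in% names(thr) && conc >= thr[[lg]]) m[lg, rp] <- 1L
    }
  }
  m
}

#' @export
print.rca_system <- function(x, ...) {
  cat("Reaction system", if (nzchar(x$label)) paste0("'", x$label, "'"),
      "\n", sep = " ")
  for (tp in x$templates) {
    sites <- vapply(tp$sites, function(s) s$repressor, character(1))
    cat("  template ", tp$name, ": [",
        paste(sites, collapse = " - "), "]\n", sep = "")
  }
  cat("  constants: repressors {",
      paste(x$constants$repressors, collapse = ", "), "}",
      sep = "")
  lc <- x$constants$ligand_concentrations
  if (length(lc)) {
    cat(", ligands {", paste(sprintf("%s=%g mM", names(lc), lc),
                             collapse = ", "), "}", sep = "")
  }
  cat("\n")
  for (nm in names(x$input_map)) {
    entry <- x$input_map[[nm]]
    parts <- c(entry$ligands, entry$repressors)
    cat("  input ", nm, " -> {", paste(parts, collapse = ", "), "}\n",
        sep = "")
  }
  invisible(x)
}
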