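#' Serialize a reaction system to a design document
#'
#' The design document is a versioned YAML text format carrying the species
#' registry, templates, constant species and input mappings — everything
#' needed to rebuild the `rca_system` losslessly.
#'
#' @param system An `rca_system`.
#' @param path Optional file path; when given the text is written there.
#' @return The YAML text, invisibly when `path` is given.
#' @export
save_design <- function(system, path = NULL) {
  stopifnot(inherits(system, "rca_system"))
  doc <- list(
    schema = 1L,
    label = system$label,
    registry = list(
      ligands = lapply(unname(system$registry$ligands), function(l) {
        list(name = l$name,
             working_concentration = l$working_concentration)
      }),
      repressors = lapply(unname(system$registry$repressors), function(r) {
        list(name = r$name, mode = r$mode,
             cognate_ligand = r$cognate_ligand,
             operator_id = r$operator_id,
             affinity_thresholds = as.list(r$affinity_thresholds),
             leak = r$leak)
      })
    ),
    templates = lapply(system$templates, function(tp) {
      out <- list(name = tp$name,
                  sites = lapply(tp$sites, function(s) {
                    list(operator_id = s$operator_id,
                         repressor = s$repressor)
                  }))
      if (!is.null(tp$primer_region)) out$primer_region <- tp$primer_region
      if (!is.null(tp$total_length)) out$total_length <- tp$total_length
      out
    }),
    constants = list(
      repressors = as.list(system$constants$repressors),
      ligands = as.list(system$constants$ligand_concentrations)
    ),
    inputs = lapply(names(system$input_map), function(nm) {
      entry <- system$input_map[[nm]]
      list(name = nm, ligands = as.list(entry$ligands),
           repressors = as.list(entry$repressors))
    })
  )
  txt <- yaml::as.yaml(doc)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

doc_check_keys <- function(node, allowed, where) {
  extra <- setdiff(names(node), allowed)
  if (length(extra)) {
    stop("design document: unknown key(s) ", paste(extra, collapse = ", "),
         " at ", where, call. = FALSE)
  }
}

doc_require <- function(node, keys, where) {
  missing <- setdiff(keys, names(node))
  if (length(missing)) {
    stop("design document: missing field(s) ",
         paste(missing, collapse = ", "), " at ", where, call. = FALSE)
  }
}

#' Load a design document into a reaction system
#'
#' Validates the schema and reports violations with the path to the
#' offending field. Accepts a file path or YAML text.
#'
#' @param path_or_text A file path, or YAML text (detected by a newline).
#' @return An `rca_system`.
#' @export
load_design <- function(path_or_text) {
  txt <- if (length(path_or_text) == 1L && !grepl("\n", path_or_text) &&
             file.exists(path_or_text)) {
    paste(readLines(path_or_text, warn = FALSE), collapse = "\n")
  } else paste(path_or_text, collapse = "\n")
  doc <- yaml::yaml.load(txt)
  doc_check_keys(doc, c("schema", "label", "registry", "templates",
                        "constants", "inputs", "kinetics"), "top level")
  doc_require(doc, c("schema", "templates", "inputs"), "top level")
  if (!identical(as.integer(doc$schema), 1L)) {
    stop("design document: unsupported schema version '", doc$schema, "'")
  }

  registry <- if (is.null(doc$registry)) default_registry() else {
    doc_check_keys(doc$registry, c("ligands", "repressors"), "registry")
    doc_require(doc$registry, c("ligands", "repressors"), "registry")
    ligands <- lapply(seq_along(doc$registry$ligands), function(i) {
      node <- doc$registry$ligands[[i]]
      where <- paste0("registry/ligands[", i, "]")
      doc_check_keys(node, c("name", "working_concentration"), where)
      doc_require(node, c("name", "working_concentration"), where)
      ligand(node$name, node$working_concentration)
    })
    repressors <- lapply(seq_along(doc$registry$repressors), function(i) {
      node <- doc$registry$repressors[[i]]
      where <- paste0("registry/repressors[", i, "]")
      doc_check_keys(node, c("name", "mode", "cognate_ligand",
                             "operator_id", "affinity_thresholds", "leak"),
                     where)
      doc_require(node, c("name", "mode", "cognate_ligand", "operator_id",
                          "affinity_thresholds"), where)
      thr <- unlist(node$affinity_thresholds)
      repressor_spec(node$name, node$mode, node$cognate_ligand,
                     node$operator_id, thr, node$leak %||% 0)
    })
    species_registry(ligands, repressors)
  }

  templates <- lapply(seq_along(doc$templates), function(i) {
    node <- doc$templates[[i]]
    where <- paste0("templates[", i, "]")
    doc_check_keys(node, c("name", "sites", "primer_region", "total_length"),
                   where)
    doc_require(node, "name", where)
    sites <- lapply(seq_along(node$sites), function(j) {
      sn <- node$sites[[j]]
      sw <- paste0(where, "/sites[", j, "]")
      doc_check_keys(sn, c("operator_id", "repressor"), sw)
      doc_require(sn, c("operator_id", "repressor"), sw)
      operator_site(sn$operator_id, sn$repressor)
    })
    circular_template(node$name, sites,
                      primer_region = node$primer_region,
                      total_length = node$total_length)
  })

  constants <- species_state()
  if (!is.null(doc$constants)) {
    doc_check_keys(doc$constants, c("repressors", "ligands"), "constants")
    lig <- unlist(doc$constants$ligands)
    constants <- species_state(
      as.character(unlist(doc$constants$repressors)),
      if (is.null(lig)) numeric() else lig)
  }

  input_map <- list()
  for (i in seq_along(doc$inputs)) {
    node <- doc$inputs[[i]]
    where <- paste0("inputs[", i, "]")
    doc_check_keys(node, c("name", "ligands", "repressors"), where)
    doc_require(node, "name", where)
    input_map[[node$name]] <-
      list(ligands = as.character(unlist(node$ligands)),
           repressors = as.character(unlist(node$repressors)))
  }

  reaction_system(templates, constants, input_map,
                  label = doc$label %||% "", registry = registry)
}
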