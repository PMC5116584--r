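#' Names of the encoded gate designs
#'
#' The 12 two-input gates, the three-input gate, and the four basic modules
#' (one repressor/operator pair each, with the metabolite and the repressor
#' protein as the two inputs).
#'
#' @return Character vector of 17 design names.
#' @export
catalogue_names <- function() {
  c("AND", "OR", "NOR", "NAND", "ANDN", "ORN", "XNOR", "XOR",
    "YES", "NOT", "ALL", "NONE", "THREE_INPUT",
    "ORN1", "ORN2", "NAND1", "NAND2")
}

site_for <- function(registry, repressor) {
  operator_site(registry$repressors[[repressor]]$operator_id, repressor)
}

#' Retrieve an encoded gate design
#'
#' Returns the reaction system for one of the 17 published designs, encoded
#' as data: templates, constant species and input mappings exactly as
#' described for each gate. Inducer-regulated modules (LacI/IPTG, GalR/D-Gal)
#' behave as ORN gates over (metabolite, repressor); anti-inducer-regulated
#' modules (TrpR/L-Trp, MetJ/SAM) behave as NAND gates. Series connection
#' (sites on one template) composes modules by conjunction; parallel
#' connection (separate templates) composes by disjunction.
#'
#' @param gate_name One of [catalogue_names()].
#' @param registry Species registry; the default library is assumed to
#'   contain LacI, GalR, TrpR, MetJ and their ligands.
#' @return An `rca_system`.
#' @examples
#' evaluate_truth_table(paper_design("AND"))
#' @export
paper_design <- function(gate_name, registry = default_registry()) {
  gate_name <- toupper(gate_name)
  if (!gate_name %in% catalogue_names()) {
    stop("unknown gate design '", gate_name, "'; see catalogue_names()")
  }
  s <- function(rep) site_for(registry, rep)
  tpl <- function(name, ...) circular_template(name, list(...))
  sys <- function(templates, constants, input_map) {
    reaction_system(templates, constants, input_map, label = gate_name,
                    registry = registry)
  }
  switch(gate_name,
    # --- series / parallel combinations of two like modules -------------
    AND = sys(list(tpl("t1", s("LacI"), s("GalR"))),
              species_state(c("LacI", "GalR")),
              list(A = list(ligands = "IPTG"), B = list(ligands = "D-Gal"))),
    OR = sys(list(tpl("t1", s("LacI")), tpl("t2", s("GalR"))),
             species_state(c("LacI", "GalR")),
             list(A = list(ligands = "IPTG"), B = list(ligands = "D-Gal"))),
    NOR = sys(list(tpl("t1", s("MetJ"), s("TrpR"))),
              species_state(c("MetJ", "TrpR")),
              list(A = list(ligands = "SAM"), B = list(ligands = "L-Trp"))),
    NAND = sys(list(tpl("t1", s("MetJ")), tpl("t2", s("TrpR"))),
               species_state(c("MetJ", "TrpR")),
               list(A = list(ligands = "SAM"), B = list(ligands = "L-Trp"))),
    # --- mixed-mode combinations ----------------------------------------
    ANDN = sys(list(tpl("t1", s("GalR"), s("TrpR"))),
               species_state(c("GalR", "TrpR")),
               list(A = list(ligands = "D-Gal"), B = list(ligands = "L-Trp"))),
    ORN = sys(list(tpl("t1", s("GalR")), tpl("t2", s("TrpR"))),
              species_state(c("GalR", "TrpR")),
              list(A = list(ligands = "D-Gal"), B = list(ligands = "L-Trp"))),
    # --- composite-input gates ------------------------------------------
    XNOR = sys(list(tpl("t1", s("LacI"), s("GalR"))),
               species_state(),
               list(A = list(ligands = "IPTG", repressors = "GalR"),
                    B = list(ligands = "D-Gal", repressors = "LacI"))),
    XOR = sys(list(tpl("t1", s("LacI"), s("MetJ")),
                   tpl("t2", s("GalR"), s("TrpR"))),
              species_state(c("LacI", "GalR", "MetJ", "TrpR")),
              list(A = list(ligands = c("IPTG", "L-Trp")),
                   B = list(ligands = c("D-Gal", "SAM")))),
    # --- single-output-literal gates on the series LacI+GalR template ---
    YES = sys(list(tpl("t1", s("LacI"), s("GalR"))),
              species_state("GalR"),
              list(A = list(ligands = "IPTG"), B = list(ligands = "D-Gal"))),
    NOT = sys(list(tpl("t1", s("MetJ"), s("TrpR"))),
              species_state("TrpR"),
              list(A = list(ligands = "SAM"), B = list(ligands = "L-Trp"))),
    ALL = sys(list(tpl("t1", s("LacI"), s("GalR"))),
              species_state(),
              list(A = list(ligands = "IPTG"), B = list(ligands = "D-Gal"))),
    NONE = sys(list(tpl("t1", s("LacI"), s("GalR"))),
               species_state("GalR"),
               list(A = list(ligands = "IPTG"), B = list(repressors = "LacI"))),
    # --- three-input series gate ----------------------------------------
    THREE_INPUT = sys(list(tpl("t1", s("LacI"), s("GalR"), s("TrpR"))),
                      species_state(c("LacI", "GalR", "TrpR")),
                      list(A = list(ligands = "IPTG"),
                           B = list(ligands = "D-Gal"),
                           C = list(ligands = "L-Trp"))),
    # --- the four basic modules (metabolite, repressor) as inputs -------
    ORN1 = sys(list(tpl("t1", s("LacI"))), species_state(),
               list(m = list(ligands = "IPTG"),
                    r = list(repressors = "LacI"))),
    ORN2 = sys(list(tpl("t1", s("GalR"))), species_state(),
               list(m = list(ligands = "D-Gal"),
                    r = list(repressors = "GalR"))),
    NAND1 = sys(list(tpl("t1", s("TrpR"))), species_state(),
                list(m = list(ligands = "L-Trp"),
                     r = list(repressors = "TrpR"))),
    NAND2 = sys(list(tpl("t1", s("MetJ"))), species_state(),
                list(m = list(ligands = "SAM"),
                     r = list(repressors = "MetJ")))
  )
}

#' Expected truth table of a catalogue design
#'
#' The published output column for each design, in canonical row order over
#' the design's own input order. The YES and NOT designs read out their
#' second input (D-Gal resp. L-Trp), so their tables here are the mirrored
#' forms of the canonical `YES`/`NOT` masks; [classify_gate()] recovers the
#' canonical name via input permutation.
#'
#' @param gate_name One of [catalogue_names()].
#' @return An `rca_truth_table`.
#' @export
catalogue_truth_table <- function(gate_name) {
  gate_name <- toupper(gate_name)
  g2 <- two_input_gates()
  masks <- c(g2,
             list(THREE_INPUT = three_input_mask(),
                  # basic modules over (metabolite, repressor):
                  # ORN = m OR NOT r ; NAND = NOT(m AND r)
                  ORN1 = g2$ORN, ORN2 = g2$ORN,
                  NAND1 = g2$NAND, NAND2 = g2$NAND))
  # design orientation: YES reads its second input, NOT negates it
  masks$YES <- c(0L, 1L, 0L, 1L)
  masks$NOT <- c(1L, 0L, 1L, 0L)
  if (!gate_name %in% names(masks)) stop("unknown gate '", gate_name, "'")
  inputs <- if (gate_name == "THREE_INPUT") c("A", "B", "C")
            else if (gate_name %in% c("ORN1", "ORN2", "NAND1", "NAND2"))
              c("m", "r")
            else c("A", "B")
  truth_table(inputs, masks[[gate_name]])
}
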