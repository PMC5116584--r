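reg <- default_registry()

test_that("resolve_state merges constants with species of 1-assigned inputs", {
  and_sys <- paper_design("AND")
  st <- resolve_state(and_sys, c(A = 1, B = 0))
  expect_setequal(st$repressors, c("LacI", "GalR"))
  expect_equal(st$ligand_concentrations[["IPTG"]], 5)
  expect_false("D-Gal" %in% names(st$ligand_concentrations)[
    st$ligand_concentrations > 0])

  st0 <- resolve_state(and_sys, c(A = 0, B = 0))
  expect_equal(st0$repressors, and_sys$constants$repressors)
  expect_true(all(st0$ligand_concentrations == 0) ||
                length(st0$ligand_concentrations) == 0)

  xor_sys <- paper_design("XOR")
  stx <- resolve_state(xor_sys, c(A = 1, B = 0))
  lc <- stx$ligand_concentrations
  expect_true(lc[["IPTG"]] > 0 && lc[["L-Trp"]] > 0)
  expect_true(!"D-Gal" %in% names(lc) || lc[["D-Gal"]] == 0)
  expect_true(!"SAM" %in% names(lc) || lc[["SAM"]] == 0)
})

test_that("resolve_state rejects malformed assignments", {
  sys <- paper_design("AND")
  expect_error(resolve_state(sys, c(A = 1)), "misses")
  expect_error(resolve_state(sys, c(A = 1, B = 0, Z = 1)), "unknown")
})

test_that("site occupancy follows the inducer / anti-inducer threshold rules", {
  laci_site <- operator_site("lacO1_syn", "LacI")
  trpr_site <- operator_site("trpO_syn", "TrpR")

  # repressor present, no inducer -> bound
  expect_equal(site_occupied(laci_site, reg,
                             species_state("LacI")), 1L)
  # repressor absent -> free regardless of ligands
  expect_equal(site_occupied(laci_site, reg,
                             species_state(character(), c(IPTG = 5))), 0L)
  # inducer above threshold releases
  expect_equal(site_occupied(laci_site, reg,
                             species_state("LacI", c(IPTG = 5))), 0L)
  # anti-inducer repressor alone, or ligand alone, leaves RCA untouched
  expect_equal(site_occupied(trpr_site, reg, species_state("TrpR")), 0L)
  expect_equal(site_occupied(trpr_site, reg,
                             species_state(character(), c(`L-Trp` = 1))), 0L)
  # both present -> bound
  expect_equal(site_occupied(trpr_site, reg,
                             species_state("TrpR", c(`L-Trp` = 1))), 1L)
  # cross-reactivity: D-Gal at working concentration does not release LacI
  expect_equal(site_occupied(laci_site, reg,
                             species_state("LacI", c(`D-Gal` = 5))), 1L)
  # ... but above the cross threshold it does
  expect_equal(site_occupied(laci_site, reg,
                             species_state("LacI", c(`D-Gal` = 12))), 0L)
  # SAM above its cross threshold triggers TrpR binding
  expect_equal(site_occupied(trpr_site, reg,
                             species_state("TrpR", c(SAM = 2))), 1L)
  # SAM at working concentration does not
  expect_equal(site_occupied(trpr_site, reg,
                             species_state("TrpR", c(SAM = 1))), 0L)
})

test_that("occupancy is monotone in the cognate ligand concentration", {
  concs <- c(0, 0.05, 0.1, 1, 5, 20)
  laci_site <- operator_site("lacO1_syn", "LacI")
  occ_ind <- vapply(concs, function(cc) {
    site_occupied(laci_site, reg, species_state("LacI", c(IPTG = cc)))
  }, integer(1))
  expect_true(all(diff(occ_ind) <= 0))   # inducer: non-increasing

  trpr_site <- operator_site("trpO_syn", "TrpR")
  occ_anti <- vapply(concs, function(cc) {
    site_occupied(trpr_site, reg, species_state("TrpR", c(`L-Trp` = cc)))
  }, integer(1))
  expect_true(all(diff(occ_anti) >= 0))  # anti-inducer: non-decreasing
})

test_that("template activity is the conjunction of free sites, order-free", {
  reps <- c("LacI", "GalR", "TrpR")
  sites <- lapply(reps, function(r) {
    operator_site(reg$repressors[[r]]$operator_id, r)
  })
  lig_on <- c(IPTG = 5, `D-Gal` = 5, `L-Trp` = 1)
  set.seed(42)
  # exhaustive: all repressor subsets x all ligand subsets
  for (rmask in 0:7) {
    present <- reps[which(int_to_bits(rmask, 3) == 1L)]
    for (lmask in 0:7) {
      lg <- lig_on[which(int_to_bits(lmask, 3) == 1L)]
      st <- species_state(present, lg)
      occ <- vapply(sites, site_occupied, integer(1), registry = reg,
                    state = st)
      tpl <- circular_template("t", sites)
      expect_equal(template_active(tpl, reg, st),
                   as.integer(all(occ == 0L)))
      # rotation / permutation invariance
      perm <- sample(3)
      tpl_p <- circular_template("tp", sites[perm])
      expect_equal(template_active(tpl_p, reg, st),
                   template_active(tpl, reg, st))
    }
  }
})

test_that("series templates with replacement dynamics stay inhibited", {
  # GalR+TrpR series template: incoming TrpR replaces the released GalR
  tpl <- circular_template("t", list(operator_site("galO_syn", "GalR"),
                                     operator_site("trpO_syn", "TrpR")))
  st <- species_state(c("GalR", "TrpR"), c(`D-Gal` = 5, `L-Trp` = 1))
  expect_equal(template_active(tpl, reg, st), 0L)
  # zero repressors present: nothing can bind
  expect_equal(template_active(tpl, reg, species_state()), 1L)
})

test_that("system_activity counts independent templates", {
  or_sys <- paper_design("OR")
  act <- system_activity(or_sys, c(A = 1, B = 0))
  expect_equal(act$active_count, 1L)
  expect_equal(act$fraction, 0.5)

  nand_sys <- paper_design("NAND")
  act2 <- system_activity(nand_sys, c(A = 1, B = 1))
  expect_equal(act2$active_count, 0L)
  expect_equal(act2$fraction, 0)

  solo <- reaction_system(list(circular_template("t", list())),
                          input_map = list(A = list(ligands = "IPTG")))
  act3 <- system_activity(solo, c(A = 0))
  expect_equal(act3$active_count, 1L)
  expect_equal(act3$fraction, 1)
})

test_that("the ligand x repressor switching matrix is diagonal at working concentrations", {
  m <- switch_matrix(reg)
  expect_equal(dim(m), c(4L, 4L))
  expect_equal(unname(diag(m[c("IPTG", "D-Gal", "L-Trp", "SAM"),
                             c("LacI", "GalR", "TrpR", "MetJ")])),
               rep(1L, 4))
  expect_equal(sum(m), 4L)   # nothing off-diagonal switches
})

test_that("constructors enforce their invariants", {
  expect_error(ligand("IPTG", -1))
  expect_error(repressor_spec("X", "inducer", "IPTG", "op",
                              c(Other = 1)), "cognate")
  expect_error(repressor_spec("X", "inducer", "IPTG", "op",
                              c(IPTG = 1), leak = 1.5))
  expect_error(circular_template("t", list(operator_site("a", "LacI"),
                                           operator_site("b", "LacI"))),
               "twice")
  expect_error(reaction_system(
    list(circular_template("t", list())),
    constants = species_state(character(), c(IPTG = 5)),
    input_map = list(A = list(ligands = "IPTG"))), "constant")
})
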