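test_that("formula evaluation follows Boolean semantics", {
  P <- f_atom("P"); Q <- f_atom("Q")
  orn <- f_or(P, f_not(Q))
  expect_equal(eval_formula(orn, c(P = 0, Q = 1)), 0L)
  expect_equal(eval_formula(orn, c(P = 0, Q = 0)), 1L)
  expect_equal(eval_formula(f_const(TRUE), c(P = 0)), 1L)
  expect_equal(eval_formula(f_not(f_and(P, Q)), c(P = 1, Q = 1)), 0L)
  expect_error(eval_formula(P, c(Q = 1)), "unbound")
})

test_that("formula evaluation matches an R logical-expression oracle", {
  P <- f_atom("P"); Q <- f_atom("Q"); R <- f_atom("R")
  cases <- list(
    list(f = f_or(f_and(P, f_not(Q)), f_and(Q, f_not(P))),
         oracle = function(p, q, r) xor(p, q)),
    list(f = f_and(f_or(P, Q), f_not(R)),
         oracle = function(p, q, r) (p | q) & !r),
    list(f = f_not(f_or(P, f_and(Q, R))),
         oracle = function(p, q, r) !(p | (q & r))))
  for (cs in cases) {
    for (m in 0:7) {
      bits <- int_to_bits(m, 3)
      expect_equal(eval_formula(cs$f, c(P = bits[1], Q = bits[2],
                                        R = bits[3])),
                   as.integer(cs$oracle(bits[1] == 1, bits[2] == 1,
                                        bits[3] == 1)))
    }
  }
})

test_that("equivalence is exhaustive truth-table equality", {
  P <- f_atom("P"); Q <- f_atom("Q")
  xor_dnf <- f_or(f_and(P, f_not(Q)), f_and(Q, f_not(P)))
  xor_cnf <- f_and(f_or(P, Q), f_not(f_and(P, Q)))
  expect_true(equivalent(xor_dnf, xor_cnf))
  expect_false(equivalent(f_or(P, Q), f_and(P, Q)))
  # ORN(P, T) collapses to P (verified over both assignments by hand:
  # P|~T = P|F = P)
  orn_pt <- f_or(P, f_not(f_const(TRUE)))
  expect_true(equivalent(orn_pt, P))
})

test_that("derive finds the published module structures", {
  g2 <- canonical_two_input_tables()
  and_tr <- derive(truth_table(c("A", "B"), g2$AND))
  expect_true(and_tr$found)
  expect_equal(and_tr$depth, 1L)        # one series step of two ORN modules
  expect_equal(and_tr$n_templates, 1L)
  expect_true(equivalent(and_tr$formula, f_and(f_atom("A"), f_atom("B"))))

  nor_tr <- derive(truth_table(c("A", "B"), g2$NOR))
  expect_true(nor_tr$found)
  expect_true(equivalent(nor_tr$formula,
                         f_and(f_not(f_atom("A")), f_not(f_atom("B")))))
  # NOR comes from the two anti-inducer modules in series
  mods <- unique(vapply(unlist(nor_tr$dnf, recursive = FALSE),
                        function(i) i$type, character(1)))
  expect_equal(mods, "NAND")

  xor_tr <- derive(truth_table(c("A", "B"), g2$XOR))
  expect_true(xor_tr$found)
  expect_equal(xor_tr$n_templates, 2L)  # the two-template parallel design
  ops <- vapply(xor_tr$steps, function(s) s$op, character(1))
  expect_equal(sum(ops == "PARALLEL_OR"), 1L)
  expect_equal(sum(ops == "SERIES_AND"), 2L)
})

test_that("all thirteen constructed gates derive from the four basic modules", {
  v <- verify_all_thirteen()
  expect_equal(v$count, 13L)
  expect_true(all(v$verified))
  # soundness: every trace's final formula is equivalent to its target
  for (nm in names(v$traces)) {
    tr <- v$traces[[nm]]
    expect_true(tr$found, label = nm)
    expect_equal(formula_mask(tr$formula, tr$inputs), as.integer(tr$goal),
                 label = paste(nm, "equivalence"))
    expect_lte(tr$depth, 3L)
  }
})

test_that("the inducer-only basis cannot reach anti-monotone gates", {
  b2 <- basic_modules()[c("ORN1", "ORN2")]
  nor <- derive(truth_table(c("A", "B"), c(1L, 0L, 0L, 0L)), basis = b2,
                max_depth = 4L)
  expect_false(nor$found)
  # ... while monotone gates still derive
  and_tr <- derive(truth_table(c("A", "B"), c(0L, 0L, 0L, 1L)), basis = b2)
  expect_true(and_tr$found)
  # empty-behaviour guard
  expect_error(derive(truth_table(c("A", "B"), c(1L, 0L, 0L, 0L)),
                      basis = list()))
})

test_that("widening repressor substitution to inputs unlocks protein-carrying designs", {
  b2 <- basic_modules()[c("ORN1", "ORN2")]
  nor <- derive(truth_table(c("A", "B"), c(1L, 0L, 0L, 0L)), basis = b2,
                repressor_substitution = "full")
  expect_true(nor$found)   # ORN(F, A) & ORN(F, B) = ~A & ~B
})

test_that("increasing the depth bound never loses a derivation", {
  g2 <- canonical_two_input_tables()
  for (nm in c("AND", "XOR", "XNOR", "NOT")) {
    shallow <- derive(truth_table(c("A", "B"), g2[[nm]]), max_depth = 4L)
    deep <- derive(truth_table(c("A", "B"), g2[[nm]]), max_depth = 6L)
    expect_true(shallow$found && deep$found)
    expect_equal(deep$depth, shallow$depth, label = nm)
  }
})

test_that("derivations map onto reaction systems with matching truth tables", {
  v <- verify_all_thirteen()
  for (nm in names(v$traces)) {
    sys <- trace_to_system(v$traces[[nm]])
    tt <- evaluate_truth_table(sys)
    expect_equal(tt$outputs, as.integer(v$traces[[nm]]$goal),
                 label = paste(nm, "round-trip"))
  }
  # the XOR mapping reproduces the published two-template structure:
  # two parallel templates, each pairing one inducer-type with one
  # anti-inducer-type module, all four repressors in play
  xor_sys <- trace_to_system(v$traces$XOR)
  expect_length(xor_sys$templates, 2L)
  reg <- xor_sys$registry
  modes <- lapply(xor_sys$templates, function(tp) {
    sort(vapply(tp$sites, function(s) reg$repressors[[s$repressor]]$mode,
                character(1)))
  })
  expect_equal(modes[[1]], c("anti_inducer", "inducer"))
  expect_equal(modes[[2]], c("anti_inducer", "inducer"))
  all_reps <- unlist(lapply(xor_sys$templates, function(tp) {
    vapply(tp$sites, function(s) s$repressor, character(1))
  }))
  expect_setequal(all_reps, c("LacI", "GalR", "TrpR", "MetJ"))
})
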