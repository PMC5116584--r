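test_that("channel assignment covers both polarities with the default library", {
  ch <- assign_channels(c("A", "B"))
  expect_false(inherits(ch, "rca_infeasible"))
  for (nm in c("A", "B")) {
    expect_equal(ch[[nm]]$pos$mode, "inducer")
    expect_equal(ch[[nm]]$neg$mode, "anti_inducer")
  }
  used <- c(vapply(ch, function(x) x$pos$name, character(1)),
            vapply(ch, function(x) x$neg$name, character(1)))
  expect_false(anyDuplicated(used) > 0)
})

test_that("channel assignment reports the missing polarity (pigeonhole)", {
  need <- stats::setNames(rep(list("neg"), 3), c("A", "B", "C"))
  ch <- assign_channels(c("A", "B", "C"), need = need)
  expect_s3_class(ch, "rca_infeasible")
  expect_true("negative" %in% ch$missing_polarity)
  # a single input always gets a positive channel
  ch1 <- assign_channels("A", need = list(A = "pos"))
  expect_false(inherits(ch1, "rca_infeasible"))
  expect_equal(ch1$A$pos$mode, "inducer")
})

test_that("synthesis realizes the published AND and XOR structures", {
  g2 <- canonical_two_input_tables()
  res <- synthesize(truth_table(c("A", "B"), g2$AND))
  expect_true(res$feasible)
  expect_length(res$system$templates, 1L)
  reps <- vapply(res$system$templates[[1]]$sites, function(s) s$repressor,
                 character(1))
  expect_setequal(reps, c("LacI", "GalR"))
  expect_setequal(res$system$constants$repressors, c("LacI", "GalR"))

  resx <- synthesize(truth_table(c("A", "B"), g2$XOR))
  expect_true(resx$feasible)
  expect_length(resx$system$templates, 2L)
  sets <- vapply(resx$system$templates, function(tp) {
    paste(sort(vapply(tp$sites, function(s) s$repressor, character(1))),
          collapse = "+")
  }, character(1))
  expect_setequal(sets, c("LacI+MetJ", "GalR+TrpR"))
})

test_that("all 16 two-input functions synthesize and verify", {
  for (m in 0:15) {
    target <- truth_table(c("A", "B"), int_to_bits(m, 4))
    res <- synthesize(target)
    expect_true(res$feasible, label = paste("function", m))
    expect_true(verify_design(res$system, target),
                label = paste("function", m, "verifies"))
  }
})

test_that("template count equals the brute-force minimal cover size", {
  # all two-input functions
  for (m in 1:14) {
    target <- truth_table(c("A", "B"), int_to_bits(m, 4))
    res <- synthesize(target)
    expect_equal(length(res$system$templates),
                 brute_min_cover_size(target$outputs, 2L),
                 label = paste("n=2 function", m))
  }
  # a deterministic sample of three-input functions that fit the default
  # library (at most 2 positive and 2 negative literal channels)
  set.seed(11)
  tried <- 0L
  while (tried < 8L) {
    m <- sample(1:254, 1)
    target <- truth_table(c("A", "B", "C"), int_to_bits(m, 8))
    res <- synthesize(target)
    if (!res$feasible) next
    tried <- tried + 1L
    expect_equal(length(res$system$templates),
                 brute_min_cover_size(target$outputs, 3L),
                 label = paste("n=3 function", m))
  }
})

test_that("feasible three-input syntheses verify; infeasible ones name a polarity", {
  set.seed(7)
  masks <- sample(0:255, 30)
  n_feasible <- 0L
  for (m in masks) {
    target <- truth_table(c("A", "B", "C"), int_to_bits(m, 8))
    res <- synthesize(target)
    if (res$feasible) {
      n_feasible <- n_feasible + 1L
      expect_true(verify_design(res$system, target),
                  label = paste("3-input function", m))
    } else {
      expect_true(any(c("positive", "negative") %in% res$missing_polarity))
    }
  }
  expect_gt(n_feasible, 0L)
})

test_that("an enlarged library makes every three-input function feasible", {
  lig <- lapply(1:6, function(i) ligand(paste0("lig", i), 1))
  reps <- c(
    lapply(1:3, function(i) {
      repressor_spec(paste0("IndR", i), "inducer", paste0("lig", i),
                     paste0("op", i),
                     stats::setNames(0.1, paste0("lig", i)))
    }),
    lapply(4:6, function(i) {
      repressor_spec(paste0("AntiR", i), "anti_inducer", paste0("lig", i),
                     paste0("op", i),
                     stats::setNames(0.1, paste0("lig", i)))
    }))
  big <- species_registry(lig, reps)
  set.seed(3)
  for (m in sample(0:255, 12)) {
    target <- truth_table(c("A", "B", "C"), int_to_bits(m, 8))
    res <- synthesize(target, big)
    expect_true(res$feasible, label = paste("function", m))
    expect_true(verify_design(res$system, target))
  }
})

test_that("constant targets use the free-template and locked-repressor encodings", {
  none <- synthesize(truth_table(c("A", "B"), rep(0L, 4)))
  expect_true(none$feasible)
  tpl <- none$system$templates[[1]]
  expect_length(tpl$sites, 1L)
  lock <- tpl$sites[[1]]$repressor
  expect_equal(none$system$registry$repressors[[lock]]$mode, "inducer")
  expect_true(lock %in% none$system$constants$repressors)
  # its inducer never appears in any input set
  carried <- unlist(lapply(none$system$input_map, function(e) e$ligands))
  expect_false(none$system$registry$repressors[[lock]]$cognate_ligand %in%
                 carried)

  all_t <- synthesize(truth_table(c("A", "B"), rep(1L, 4)))
  expect_true(all_t$feasible)
  expect_length(all_t$system$templates[[1]]$sites, 0L)
})

test_that("synthesis is idempotent on truth tables", {
  set.seed(5)
  for (m in c(1, 6, 9, 11, sample(0:255, 4))) {
    n <- if (m > 15) 3L else 2L
    target <- truth_table(LETTERS[1:n], int_to_bits(m, 2^n))
    res <- synthesize(target)
    if (!res$feasible) next
    tt <- evaluate_truth_table(res$system)
    res2 <- synthesize(tt)
    expect_true(res2$feasible)
    expect_equal(evaluate_truth_table(res2$system)$outputs, tt$outputs)
  }
})

test_that("verify_design distinguishes matching from mismatching targets", {
  g2 <- canonical_two_input_tables()
  and_sys <- paper_design("AND")
  expect_true(verify_design(and_sys, truth_table(c("A", "B"), g2$AND)))
  expect_false(verify_design(and_sys, truth_table(c("A", "B"), g2$OR)))
  expect_error(verify_design(and_sys, truth_table("A", c(0L, 1L))),
               "arity")
})
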