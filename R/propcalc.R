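#' Propositional formulas over NOT, AND, OR
#'
#' Minimal AST used to mirror, in the propositional calculus, how gates are
#' assembled from basic repressor modules: series connection is conjunction,
#' parallel connection is disjunction, and allosteric inversion supplies
#' negation.
#'
#' @param name Atom name.
#' @return An object of class `rca_formula`.
#' @name formula-constructors
NULL

#' @rdname formula-constructors
#' @export
f_atom <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(kind = "atom", name = name), class = "rca_formula")
}

#' @rdname formula-constructors
#' @param value Logical constant.
#' @export
f_const <- function(value) {
  structure(list(kind = "const", value = isTRUE(value)),
            class = "rca_formula")
}

#' @rdname formula-constructors
#' @param x,y Operand formulas.
#' @export
f_not <- function(x) {
  stopifnot(inherits(x, "rca_formula"))
  structure(list(kind = "not", x = x), class = "rca_formula")
}

#' @rdname formula-constructors
#' @export
f_and <- function(x, y) {
  stopifnot(inherits(x, "rca_formula"), inherits(y, "rca_formula"))
  structure(list(kind = "and", x = x, y = y), class = "rca_formula")
}

#' @rdname formula-constructors
#' @export
f_or <- function(x, y) {
  stopifnot(inherits(x, "rca_formula"), inherits(y, "rca_formula"))
  structure(list(kind = "or", x = x, y = y), class = "rca_formula")
}

#' Evaluate a formula under an assignment
#'
#' @param f An `rca_formula`.
#' @param assignment Named logical/0-1 vector covering all of `f`'s atoms.
#' @return 0/1 bit.
#' @export
eval_formula <- function(f, assignment) {
  v <- eval_formula_rec(f, assignment)
  as.integer(v)
}

eval_formula_rec <- function(f, assignment) {
  switch(f$kind,
    atom = {
      if (!f$name %in% names(assignment)) {
        stop("unbound atom '", f$name, "'")
      }
      as.logical(assignment[[f$name]])
    },
    const = f$value,
    not = !eval_formula_rec(f$x, assignment),
    and = eval_formula_rec(f$x, assignment) && eval_formula_rec(f$y, assignment),
    or = eval_formula_rec(f$x, assignment) || eval_formula_rec(f$y, assignment)
  )
}

#' Atoms occurring in a formula
#' @param f An `rca_formula`.
#' @return Character vector.
#' @export
formula_atoms <- function(f) {
  switch(f$kind,
    atom = f$name,
    const = character(),
    not = formula_atoms(f$x),
    unique(c(formula_atoms(f$x), formula_atoms(f$y)))
  )
}

#' Output column of a formula over a declared variable set
#'
#' @param f An `rca_formula`.
#' @param vars Character vector of variables (canonical row order, first
#'   variable most significant). Must cover `f`'s atoms.
#' @return Integer vector of 2^n bits.
#' @export
formula_mask <- function(f, vars) {
  extra <- setdiff(formula_atoms(f), vars)
  if (length(extra)) stop("formula uses undeclared atom(s): ",
                          paste(extra, collapse = ", "))
  rows <- assignment_rows(vars)
  apply(rows, 1L, function(r) eval_formula(f, stats::setNames(r, vars)))
}

#' Exhaustive equivalence of two formulas
#'
#' @param f,g Formulas.
#' @param vars Variable set to compare over; defaults to the union of both
#'   atom sets. At most 10 variables.
#' @return TRUE/FALSE.
#' @export
equivalent <- function(f, g, vars = NULL) {
  if (is.null(vars)) vars <- union(formula_atoms(f), formula_atoms(g))
  if (length(vars) == 0L) vars <- "P"
  if (length(vars) > 10L) stop("equivalence check limited to 10 variables")
  identical(formula_mask(f, vars), formula_mask(g, vars))
}

#' @export
format.rca_formula <- function(x, ...) {
  switch(x$kind,
    atom = x$name,
    const = if (x$value) "T" else "F",
    not = paste0("~", format_operand(x$x)),
    and = paste0("(", format(x$x), " & ", format(x$y), ")"),
    or = paste0("(", format(x$x), " | ", format(x$y), ")")
  )
}

format_operand <- function(x) {
  if (x$kind %in% c("atom", "const", "not")) format(x) else format(x)
}

#' @export
print.rca_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' The four basic repressor logic modules
#'
#' Each module is one repressor/operator pair with its regulating metabolite.
#' Over the two atoms (metabolite `m`, repressor `r`), an inducer-regulated
#' module computes `m | ~r` (the site is free unless the repressor is
#' present without its inducer) and an anti-inducer-regulated module computes
#' `~(m & r)` (the site is blocked only when repressor and co-repressor
#' are both present).
#'
#' @return Named list of module descriptors with elements `name`, `type`
#'   (`"ORN"` or `"NAND"`), `repressor`, `metabolite` and `make(m, r)`
#'   returning the instantiated formula.
#' @export
basic_modules <- function() {
  mk <- function(name, type, repressor, metabolite) {
    make <- if (type == "ORN") {
      function(m, r) f_or(m, f_not(r))
    } else {
      function(m, r) f_not(f_and(m, r))
    }
    list(name = name, type = type, repressor = repressor,
         metabolite = metabolite, make = make)
  }
  list(ORN1 = mk("ORN1", "ORN", "LacI", "IPTG"),
       ORN2 = mk("ORN2", "ORN", "GalR", "D-Gal"),
       NAND1 = mk("NAND1", "NAND", "TrpR", "L-Trp"),
       NAND2 = mk("NAND2", "NAND", "MetJ", "SAM"))
}

sub_formula <- function(token) {
  if (token == ".T") f_const(TRUE)
  else if (token == ".F") f_const(FALSE)
  else f_atom(token)
}

sub_label <- function(token) {
  if (token == ".T") "T" else if (token == ".F") "F" else token
}

#' Derive a target truth table from basic modules
#'
#' Bounded-cost search for a composition of basic modules equivalent to a
#' target Boolean function, using only the three physically available
#' operations: SUBSTITUTE (instantiate a module's metabolite atom with an
#' input variable or a constant, and its repressor atom with a constant:
#' `T` = held present throughout, `F` = never supplied), SERIES_AND
#' (co-locating sites on one circular template) and PARALLEL_OR (separate
#' templates in one reaction). Cost counts composition steps; among
#' equal-cost derivations the one implying fewer templates, then the one
#' found first in the deterministic enumeration order (basis order, then
#' substitution order), is returned.
#'
#' By default the repressor atom only takes the constants `T`/`F`, matching
#' designs whose input signals are metabolite additions. Set
#' `repressor_substitution = "full"` to also allow input variables in the
#' repressor slot (protein-carrying input signals, as in the XNOR and NONE
#' designs).
#'
#' @param target An `rca_truth_table`, or an `rca_formula` (then `inputs`
#'   must be given).
#' @param basis List of basic modules (subset of [basic_modules()]).
#' @param max_depth Maximum number of composition steps (default 4).
#' @param inputs Input variable names when `target` is a formula.
#' @param repressor_substitution `"constants"` (default) or `"full"`.
#' @return An object of class `rca_derivation`: `found`, `steps`, `formula`,
#'   `depth`, `n_templates`, `dnf` (templates as lists of module instances).
#' @export
derive <- function(target, basis = basic_modules(), max_depth = 4L,
                   inputs = NULL,
                   repressor_substitution = c("constants", "full")) {
  repressor_substitution <- match.arg(repressor_substitution)
  stopifnot(length(basis) >= 1L, max_depth >= 1L)
  if (inherits(target, "rca_truth_table")) {
    inputs <- target$inputs
    goal <- as.integer(target$outputs)
    label <- "target"
  } else if (inherits(target, "rca_formula")) {
    if (is.null(inputs)) inputs <- formula_atoms(target)
    goal <- formula_mask(target, inputs)
    label <- format(target)
  } else stop("target must be a truth table or a formula")

  m_opts <- c(inputs, ".T", ".F")
  r_opts <- if (repressor_substitution == "full") c(inputs, ".T", ".F")
            else c(".T", ".F")

  key <- function(mask) paste(mask, collapse = "")
  seen <- new.env(parent = emptyenv())
  by_cost <- vector("list", max_depth + 1L)

  register <- function(cands, cost) {
    # stable order: fewer implied templates first, then enumeration order
    ord <- order(vapply(cands, function(e) e$n_templates, numeric(1)),
                 seq_along(cands))
    kept <- list()
    for (e in cands[ord]) {
      k <- key(e$mask)
      if (!is.null(seen[[k]])) next
      seen[[k]] <- e
      kept[[length(kept) + 1L]] <- e
    }
    by_cost[[cost + 1L]] <<- kept
    invisible(NULL)
  }

  # cost 0: all substituted basis modules
  base_cands <- list()
  for (mod in basis) {
    for (m in m_opts) {
      for (r in r_opts) {
        fl <- mod$make(sub_formula(m), sub_formula(r))
        inst <- list(module = mod$name, type = mod$type,
                     m_sub = m, r_sub = r)
        step <- list(op = "SUBSTITUTE",
                     detail = sprintf("%s(m=%s, r=%s)", mod$name,
                                      sub_label(m), sub_label(r)),
                     formula = fl)
        base_cands[[length(base_cands) + 1L]] <-
          list(mask = formula_mask(fl, inputs), formula = fl, cost = 0L,
               n_templates = 1L, steps = list(step),
               dnf = list(list(inst)))
      }
    }
  }
  register(base_cands, 0L)

  result_entry <- seen[[key(goal)]]
  cost <- 0L
  while (is.null(result_entry) && cost < max_depth) {
    cost <- cost + 1L
    cands <- list()
    for (a in 0:(cost - 1L)) {
      b <- cost - 1L - a
      for (e1 in by_cost[[a + 1L]]) {
        for (e2 in by_cost[[b + 1L]]) {
          for (op in c("SERIES_AND", "PARALLEL_OR")) {
            if (op == "SERIES_AND") {
              mask <- e1$mask & e2$mask
              fl <- f_and(e1$formula, e2$formula)
              dnf <- merge_series(e1$dnf, e2$dnf)
            } else {
              mask <- e1$mask | e2$mask
              fl <- f_or(e1$formula, e2$formula)
              dnf <- c(e1$dnf, e2$dnf)
            }
            step <- list(op = op,
                         detail = sprintf("%s %s %s", format(e1$formula),
                                          if (op == "SERIES_AND") "&" else "|",
                                          format(e2$formula)),
                         formula = fl)
            cands[[length(cands) + 1L]] <-
              list(mask = as.integer(mask), formula = fl, cost = cost,
                   n_templates = length(dnf),
                   steps = c(e1$steps, e2$steps, list(step)),
                   dnf = dnf)
          }
        }
      }
    }
    register(cands, cost)
    result_entry <- seen[[key(goal)]]
  }

  if (is.null(result_entry)) {
    return(structure(list(found = FALSE, target = label, inputs = inputs,
                          goal = goal, max_depth = max_depth),
                     class = "rca_derivation"))
  }
  structure(list(found = TRUE, target = label, inputs = inputs, goal = goal,
                 steps = result_entry$steps, formula = result_entry$formula,
                 depth = result_entry$cost,
                 n_templates = result_entry$n_templates,
                 dnf = result_entry$dnf),
            class = "rca_derivation")
}

# series composition distributes over parallel branches: each template of
# the left operand gains the sites of each template of the right operand
merge_series <- function(dnf1, dnf2) {
  out <- list()
  for (t1 in dnf1) {
    for (t2 in dnf2) {
      combined <- c(t1, t2)
      keys <- vapply(combined, function(i) {
        paste(i$module, i$m_sub, i$r_sub, sep = "/")
      }, character(1))
      out[[length(out) + 1L]] <- combined[!duplicated(keys)]
    }
  }
  out
}

#' @export
print.rca_derivation <- function(x, ...) {
  if (!x$found) {
    cat("No derivation of", x$target, "found within depth", x$max_depth, "\n")
    return(invisible(x))
  }
  cat("Derivation of ", x$target, " (", x$depth, " composition step",
      if (x$depth != 1) "s", ", ", x$n_templates, " template",
      if (x$n_templates != 1) "s", "):\n", sep = "")
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    cat(sprintf("  %2d. %-12s %s  =>  %s\n", i, s$op, s$detail,
                format(s$formula)))
  }
  cat("  final:", format(x$formula), "\n")
  invisible(x)
}

#' Map a derivation onto a physical reaction system
#'
#' Each distinct substituted module instance in the derivation is realized
#' by a distinct repressor of the matching regulation mode from the
#' registry; SERIES_AND co-locates sites on one template and PARALLEL_OR
#' separates templates. Metabolite substitutions become input-signal species
#' sets (`T` = ligand held constant, `F` = ligand withheld); repressor
#' substitutions `T`/`F` become constant/absent proteins, and input-variable
#' repressor substitutions become protein-carrying inputs.
#'
#' @param derivation A found `rca_derivation`.
#' @param registry Species registry supplying the repressor pool.
#' @return An `rca_system` whose truth table equals the derived formula.
#' @export
trace_to_system <- function(derivation, registry = default_registry()) {
  stopifnot(inherits(derivation, "rca_derivation"))
  if (!derivation$found) stop("derivation was not found; nothing to realize")
  inputs <- derivation$inputs

  inst_key <- function(i) paste(i$module, i$m_sub, i$r_sub, sep = "/")
  all_inst <- list()
  for (tpl in derivation$dnf) for (i in tpl) {
    k <- inst_key(i)
    if (is.null(all_inst[[k]])) all_inst[[k]] <- i
  }

  pool <- list(
    ORN = Filter(function(r) r$mode == "inducer", registry$repressors),
    NAND = Filter(function(r) r$mode == "anti_inducer", registry$repressors)
  )
  used <- character()
  assigned <- list()
  for (k in names(all_inst)) {
    i <- all_inst[[k]]
    avail <- Filter(function(r) !r$name %in% used, pool[[i$type]])
    if (length(avail) == 0L) {
      stop("registry has too few ",
           if (i$type == "ORN") "inducer" else "anti-inducer",
           "-regulated repressors to realize this derivation")
    }
    assigned[[k]] <- avail[[1L]]
    used <- c(used, avail[[1L]]$name)
  }

  const_reps <- character()
  const_lig <- numeric()
  input_map <- stats::setNames(
    lapply(inputs, function(nm) list(ligands = character(),
                                     repressors = character())),
    inputs)
  for (k in names(all_inst)) {
    i <- all_inst[[k]]
    spec <- assigned[[k]]
    lig <- spec$cognate_ligand
    if (i$m_sub == ".T") {
      const_lig[[lig]] <- registry$ligands[[lig]]$working_concentration
    } else if (i$m_sub != ".F") {
      input_map[[i$m_sub]]$ligands <-
        union(input_map[[i$m_sub]]$ligands, lig)
    }
    if (i$r_sub == ".T") {
      const_reps <- union(const_reps, spec$name)
    } else if (i$r_sub != ".F") {
      input_map[[i$r_sub]]$repressors <-
        union(input_map[[i$r_sub]]$repressors, spec$name)
    }
  }

  templates <- lapply(seq_along(derivation$dnf), function(ti) {
    insts <- derivation$dnf[[ti]]
    reps <- unique(vapply(insts, function(i) assigned[[inst_key(i)]]$name,
                          character(1)))
    circular_template(paste0("t", ti),
                      lapply(reps, function(r) site_for(registry, r)))
  })
  reaction_system(templates, species_state(const_reps, const_lig),
                  input_map, label = derivation$target,
                  registry = registry)
}

#' Derive all thirteen constructed gates from a basis
#'
#' Runs [derive()] for the 12 two-input gates and the three-input gate and
#' machine-checks every returned formula against its target by exhaustive
#' equivalence.
#'
#' @inheritParams derive
#' @return List with `count` (number derivable), `traces` (named list of
#'   `rca_derivation`), and `verified` (logical vector: trace found and
#'   equivalent to target).
#' @export
verify_all_thirteen <- function(basis = basic_modules(), max_depth = 4L,
                                repressor_substitution = "constants") {
  g2 <- two_input_gates()
  targets <- c(lapply(names(g2), function(nm) truth_table(c("A", "B"), g2[[nm]])),
               list(truth_table(c("A", "B", "C"), three_input_mask())))
  names(targets) <- c(names(g2), "THREE_INPUT")
  # the 13 constructed gates (all 12 two-input names + the 3-input gate)
  traces <- lapply(targets, derive, basis = basis, max_depth = max_depth,
                   repressor_substitution = repressor_substitution)
  verified <- vapply(names(targets), function(nm) {
    tr <- traces[[nm]]
    tr$found &&
      identical(formula_mask(tr$formula, targets[[nm]]$inputs),
                as.integer(targets[[nm]]$outputs))
  }, logical(1))
  list(count = sum(verified), traces = traces, verified = verified)
}
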