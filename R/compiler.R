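#' Prime implicants of a Boolean function (Quine-McCluskey)
#'
#' @param outputs Integer vector of 2^n output bits in canonical row order.
#' @param n Number of inputs.
#' @return List of implicants; each is an integer vector of length n with
#'   entries 0, 1 or NA (don't care).
#' @keywords internal
prime_implicants <- function(outputs, n) {
  minterms <- which(outputs == 1L) - 1L
  if (length(minterms) == 0L) return(list())
  to_vec <- function(m) (m %/% 2^((n - 1):0)) %% 2
  current <- lapply(minterms, to_vec)
  primes <- list()
  imp_key <- function(v) paste(ifelse(is.na(v), "-", v), collapse = "")
  while (length(current)) {
    combined_flag <- rep(FALSE, length(current))
    nxt <- list()
    nxt_keys <- character()
    for (i in seq_along(current)) {
      for (j in seq_along(current)) {
        if (i >= j) next
        a <- current[[i]]; b <- current[[j]]
        same_na <- identical(is.na(a), is.na(b))
        if (!same_na) next
        diff <- which(!is.na(a) & a != b)
        if (length(diff) == 1L) {
          m <- a; m[diff] <- NA
          combined_flag[i] <- combined_flag[j] <- TRUE
          k <- imp_key(m)
          if (!k %in% nxt_keys) {
            nxt[[length(nxt) + 1L]] <- m
            nxt_keys <- c(nxt_keys, k)
          }
        }
      }
    }
    for (i in which(!combined_flag)) {
      k <- imp_key(current[[i]])
      if (!k %in% vapply(primes, imp_key, character(1))) {
        primes[[length(primes) + 1L]] <- current[[i]]
      }
    }
    current <- nxt
  }
  primes
}

implicant_minterm_mask <- function(imp, n) {
  rows <- assignment_rows(paste0("x", seq_len(n)))
  fixed <- which(!is.na(imp))
  if (length(fixed) == 0L) return(rep(1L, 2^n))
  apply(rows, 1L, function(r) as.integer(all(r[fixed] == imp[fixed])))
}

#' Exact minimal cover of a target by prime implicants
#'
#' Brute-force smallest subset of primes covering all minterms; among
#' equal-size covers, the lexicographically first by the implicants'
#' minterm bitmasks. Exact and fast for n <= 4.
#'
#' @keywords internal
minimal_cover <- function(outputs, n) {
  primes <- prime_implicants(outputs, n)
  if (length(primes) == 0L) return(list())
  masks <- lapply(primes, implicant_minterm_mask, n = n)
  # sort primes by bitmask value (lexicographic tie-break)
  mask_val <- vapply(masks, function(m) sum(m * 2^(rev(seq_along(m)) - 1)),
                     numeric(1))
  ord <- order(-mask_val, seq_along(primes))
  primes <- primes[ord]; masks <- masks[ord]
  target <- as.integer(outputs)
  for (size in seq_along(primes)) {
    combos <- utils::combn(length(primes), size, simplify = FALSE)
    for (cmb in combos) {
      covered <- Reduce(`|`, masks[cmb])
      if (identical(as.integer(covered), target)) return(primes[cmb])
    }
  }
  stop("internal error: primes do not cover their own function")
}

#' Assign literal channels to inputs
#'
#' A positive channel realizes the literal "input present" with an
#' inducer-regulated repressor held constant (its site is free iff the
#' input's metabolite is added); a negative channel realizes "input absent"
#' with an anti-inducer-regulated repressor held constant (its site is free
#' iff the metabolite is withheld). Channels consume distinct repressors.
#'
#' @param inputs Character vector of input names.
#' @param registry Species registry (the repressor library).
#' @param need Optional named list, input -> character subset of
#'   `c("pos", "neg")`; defaults to both polarities for every input.
#' @return Named list per input with elements `pos`/`neg` (repressor specs
#'   or NULL), or an infeasibility report of class `rca_infeasible` naming
#'   the missing polarity.
#' @export
assign_channels <- function(inputs, registry = default_registry(),
                            need = NULL) {
  if (is.null(need)) {
    need <- stats::setNames(rep(list(c("pos", "neg")), length(inputs)),
                            inputs)
  }
  inducers <- Filter(function(r) r$mode == "inducer", registry$repressors)
  antis <- Filter(function(r) r$mode == "anti_inducer", registry$repressors)
  n_pos <- sum(vapply(inputs, function(i) "pos" %in% need[[i]], logical(1)))
  n_neg <- sum(vapply(inputs, function(i) "neg" %in% need[[i]], logical(1)))
  if (n_pos > length(inducers) || n_neg > length(antis)) {
    missing <- c(if (n_pos > length(inducers)) "positive",
                 if (n_neg > length(antis)) "negative")
    return(structure(
      list(feasible = FALSE, missing_polarity = missing,
           detail = sprintf(
             "need %d positive / %d negative channels but library has %d inducer / %d anti-inducer repressors",
             n_pos, n_neg, length(inducers), length(antis))),
      class = "rca_infeasible"))
  }
  ip <- 0L; ia <- 0L
  out <- stats::setNames(vector("list", length(inputs)), inputs)
  for (nm in inputs) {
    ch <- list(pos = NULL, neg = NULL)
    if ("pos" %in% need[[nm]]) { ip <- ip + 1L; ch$pos <- inducers[[ip]] }
    if ("neg" %in% need[[nm]]) { ia <- ia + 1L; ch$neg <- antis[[ia]] }
    out[[nm]] <- ch
  }
  out
}

#' Synthesize a reaction system realizing a target truth table
#'
#' Computes an exact minimal prime-implicant cover of the target; each
#' implicant becomes one circular template whose operator sites realize the
#' implicant's literals through per-input channels (series = conjunction of
#' literals), and the templates run in parallel (disjunction of implicants).
#' A constant-true target yields one site-free template; a constant-false
#' target yields one template with an inducer-regulated repressor held
#' constant whose inducer is never supplied. The result is verified against
#' the target by exhaustive truth-table evaluation before return.
#'
#' @param target_tt An `rca_truth_table` with at most 4 inputs.
#' @param registry Species registry (the repressor library).
#' @return An object of class `rca_synthesis`: `feasible`, `system`,
#'   `cover`, `channels`; or the infeasibility report from
#'   [assign_channels()] wrapped with `feasible = FALSE`.
#' @export
synthesize <- function(target_tt, registry = default_registry()) {
  stopifnot(inherits(target_tt, "rca_truth_table"))
  inputs <- target_tt$inputs
  n <- length(inputs)
  if (n > 4L) stop("synthesis supports at most 4 inputs")
  outputs <- target_tt$outputs
  empty_inputs <- stats::setNames(
    rep(list(list(ligands = character(), repressors = character())), n),
    inputs)

  if (all(outputs == 0L)) {
    # constant false: repressor locked on its template, inducer withheld
    inducers <- Filter(function(r) r$mode == "inducer", registry$repressors)
    if (length(inducers) == 0L) {
      return(structure(list(feasible = FALSE, missing_polarity = "positive",
                            detail = "constant-false needs one inducer-regulated repressor"),
                       class = "rca_synthesis"))
    }
    lock <- inducers[[1L]]
    system <- reaction_system(
      list(circular_template("t1", list(site_for(registry, lock$name)))),
      species_state(lock$name), empty_inputs,
      label = "synthesized", registry = registry)
    return(finish_synthesis(system, list(), list(), target_tt))
  }
  if (all(outputs == 1L)) {
    system <- reaction_system(list(circular_template("t1", list())),
                              species_state(), empty_inputs,
                              label = "synthesized", registry = registry)
    return(finish_synthesis(system, list(), list(), target_tt))
  }

  cover <- minimal_cover(outputs, n)
  need <- stats::setNames(rep(list(character()), n), inputs)
  for (imp in cover) {
    for (j in seq_len(n)) {
      if (is.na(imp[j])) next
      pol <- if (imp[j] == 1L) "pos" else "neg"
      need[[inputs[j]]] <- union(need[[inputs[j]]], pol)
    }
  }
  channels <- assign_channels(inputs, registry, need)
  if (inherits(channels, "rca_infeasible")) {
    return(structure(c(list(feasible = FALSE), unclass(channels)),
                     class = "rca_synthesis"))
  }

  const_reps <- character()
  input_map <- empty_inputs
  for (nm in inputs) {
    for (pol in c("pos", "neg")) {
      ch <- channels[[nm]][[pol]]
      if (is.null(ch)) next
      const_reps <- union(const_reps, ch$name)
      input_map[[nm]]$ligands <- union(input_map[[nm]]$ligands,
                                       ch$cognate_ligand)
    }
  }
  templates <- lapply(seq_along(cover), function(ti) {
    imp <- cover[[ti]]
    sites <- list()
    for (j in seq_len(n)) {
      if (is.na(imp[j])) next
      ch <- channels[[inputs[j]]][[if (imp[j] == 1L) "pos" else "neg"]]
      sites[[length(sites) + 1L]] <- site_for(registry, ch$name)
    }
    circular_template(paste0("t", ti), sites)
  })
  system <- reaction_system(templates, species_state(const_reps), input_map,
                            label = "synthesized", registry = registry)
  finish_synthesis(system, cover, channels, target_tt)
}

finish_synthesis <- function(system, cover, channels, target_tt) {
  if (!verify_design(system, target_tt)) {
    stop("internal error: synthesized system does not verify against target")
  }
  structure(list(feasible = TRUE, system = system, cover = cover,
                 channels = channels),
            class = "rca_synthesis")
}

#' Verify a reaction system against a target truth table
#'
#' @param system An `rca_system`.
#' @param target_tt An `rca_truth_table` over the same number of inputs.
#' @return TRUE iff the exhaustive truth tables are equal.
#' @export
verify_design <- function(system, target_tt) {
  if (length(system$input_map) != length(target_tt$inputs)) {
    stop("input arity mismatch: system has ", length(system$input_map),
         " inputs, target has ", length(target_tt$inputs))
  }
  tt <- evaluate_truth_table(system)
  identical(tt$outputs, as.integer(target_tt$outputs))
}

#' @export
print.rca_synthesis <- function(x, ...) {
  if (!x$feasible) {
    cat("Synthesis infeasible:", x$detail, "\n")
    return(invisible(x))
  }
  cat("Feasible synthesis with", length(x$system$templates), "template(s)\n")
  print(x$system)
  invisible(x)
}
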