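#' Construct a truth table
#'
#' Rows are in canonical binary order over the inputs with the first input as
#' the most significant bit: row `r` (0-based) assigns input `j` the bit
#' `floor(r / 2^(n-j)) %% 2`.
#'
#' @param inputs Character vector of input names (length n).
#' @param outputs Integer vector of 2^n output bits in canonical row order.
#' @return An object of class `rca_truth_table`.
#' @export
truth_table <- function(inputs, outputs) {
  n <- length(inputs)
  stopifnot(n >= 1L, length(outputs) == 2^n, all(outputs %in% c(0L, 1L)))
  structure(list(inputs = inputs, outputs = as.integer(outputs)),
            class = "rca_truth_table")
}

#' All assignments of a truth table in canonical row order
#'
#' @param inputs Character vector of input names.
#' @return Integer matrix with 2^n rows; column j is input j's bit, input 1
#'   most significant.
#' @export
assignment_rows <- function(inputs) {
  n <- length(inputs)
  rows <- 0:(2^n - 1)
  m <- sapply(seq_len(n), function(j) (rows %/% 2^(n - j)) %% 2)
  m <- matrix(as.integer(m), ncol = n,
              dimnames = list(NULL, inputs))
  m
}

#' Evaluate the truth table of a reaction system
#'
#' Runs every input assignment through the binding rules; a row outputs 1 iff
#' at least one circular template is free to amplify (any active template
#' produces RCA signal).
#'
#' @param system An `rca_system` with 1..8 inputs.
#' @return An `rca_truth_table`.
#' @export
evaluate_truth_table <- function(system) {
  inputs <- names(system$input_map)
  n <- length(inputs)
  if (n < 1L || n > 8L) stop("system must have between 1 and 8 inputs")
  rows <- assignment_rows(inputs)
  outputs <- apply(rows, 1L, function(r) {
    as.integer(system_activity(system, stats::setNames(r, inputs))$active_count > 0)
  })
  truth_table(inputs, outputs)
}

# canonical output masks for the 12 named two-input gates, identity input
# order (A = MSB). Asymmetric names (ANDN, ORN, YES, NOT) are stored in the
# A-oriented form; the mirror form matches via input permutation.
two_input_gates <- function() {
  list(NONE = c(0L, 0L, 0L, 0L),
       AND  = c(0L, 0L, 0L, 1L),
       ANDN = c(0L, 0L, 1L, 0L),   # A AND NOT B
       YES  = c(0L, 0L, 1L, 1L),   # A
       XOR  = c(0L, 1L, 1L, 0L),
       OR   = c(0L, 1L, 1L, 1L),
       NOR  = c(1L, 0L, 0L, 0L),
       XNOR = c(1L, 0L, 0L, 1L),
       NOT  = c(1L, 1L, 0L, 0L),   # NOT A
       ORN  = c(1L, 0L, 1L, 1L),   # A OR NOT B
       NAND = c(1L, 1L, 1L, 0L),
       ALL  = c(1L, 1L, 1L, 1L))
}

# the constructed three-input function: 1 exactly at (1, 1, 0)
three_input_mask <- function() {
  out <- integer(8)
  out[6 + 1] <- 1L   # row 110 in canonical order
  out
}

permute_table_outputs <- function(outputs, perm) {
  n <- log2(length(outputs))
  rows <- assignment_rows(paste0("x", seq_len(n)))
  # output of permuted table at assignment a equals original at a[perm]
  idx <- apply(rows, 1L, function(a) {
    b <- a[perm]
    sum(b * 2^((n - 1):0)) + 1
  })
  outputs[idx]
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Classify a two- or three-input truth table against the gate catalogue
#'
#' A table is matched against the named gates under every permutation of its
#' inputs, so mirror-image gates (e.g. `A AND NOT B` vs `B AND NOT A`)
#' collapse onto one name; the matching permutation is reported. All 16
#' two-input Boolean functions map to one of the 12 constructed gate names
#' under this symmetry. Three-input tables are matched against the
#' constructed three-input gate (active at exactly one assignment,
#' `1,1,0` up to permutation); anything else is `OTHER`.
#'
#' @param tt An `rca_truth_table` with 2 or 3 inputs.
#' @return List with `name` and `input_permutation` (indices into the
#'   table's inputs), class `rca_gate_label`.
#' @export
classify_gate <- function(tt) {
  stopifnot(inherits(tt, "rca_truth_table"))
  n <- length(tt$inputs)
  if (!n %in% c(2L, 3L)) stop("classification is defined for 2 or 3 inputs")
  catalogue <- if (n == 2L) two_input_gates() else
    list(THREE_INPUT_CUSTOM = three_input_mask())
  for (perm in all_permutations(n)) {
    permuted <- permute_table_outputs(tt$outputs, perm)
    for (nm in names(catalogue)) {
      if (identical(as.integer(permuted), catalogue[[nm]])) {
        return(structure(list(name = nm, input_permutation = perm),
                         class = "rca_gate_label"))
      }
    }
  }
  structure(list(name = "OTHER", input_permutation = seq_len(n)),
            class = "rca_gate_label")
}

#' @export
print.rca_gate_label <- function(x, ...) {
  cat(x$name)
  if (!identical(x$input_permutation, seq_along(x$input_permutation))) {
    cat(" (inputs permuted:", paste(x$input_permutation, collapse = ","),
        ")")
  }
  cat("\n")
  invisible(x)
}

#' @export
print.rca_truth_table <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.rca_truth_table <- function(x, ...) {
  rows <- assignment_rows(x$inputs)
  header <- paste(c(format(x$inputs, width = 5), "  out"), collapse = " ")
  body <- apply(cbind(rows, x$outputs), 1L, function(r) {
    paste(c(format(r[-length(r)], width = 5),
            sprintf("  %d", r[length(r)])), collapse = " ")
  })
  c(header, body)
}

#' Convert a truth table to a data frame
#'
#' @param x An `rca_truth_table`.
#' @param ... Unused.
#' @return Data frame with one column per input plus `output`.
#' @export
as.data.frame.rca_truth_table <- function(x, ...) {
  df <- as.data.frame(assignment_rows(x$inputs))
  df$output <- x$outputs
  df
}
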