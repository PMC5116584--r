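# Independent brute-force oracles used to freeze expected values.

# All product terms over n inputs (entries 0/1/NA, at least one fixed).
all_product_terms <- function(n) {
  grids <- do.call(expand.grid, rep(list(c(0L, 1L, NA)), n))
  terms <- lapply(seq_len(nrow(grids)), function(i) unlist(grids[i, ],
                                                           use.names = FALSE))
  Filter(function(tm) any(!is.na(tm)), terms)
}

term_minterms <- function(tm, n) {
  rows <- assignment_rows(paste0("x", seq_len(n)))
  fixed <- which(!is.na(tm))
  which(apply(rows, 1L, function(r) all(r[fixed] == tm[fixed])))
}

# smallest number of product terms whose union of minterms equals the target
# (exhaustive subset search; only usable for n <= 3)
brute_min_cover_size <- function(outputs, n) {
  target <- which(outputs == 1L)
  if (length(target) == 0L || length(target) == 2^n) return(0L)
  terms <- all_product_terms(n)
  covers <- Filter(function(m) all(m %in% target),
                   lapply(terms, term_minterms, n = n))
  covers <- covers[lengths(covers) > 0L]
  for (size in 1:length(covers)) {
    for (cmb in utils::combn(length(covers), size, simplify = FALSE)) {
      if (setequal(unlist(covers[cmb]), target)) return(size)
    }
  }
  stop("no cover found")
}

# least-squares slope oracle on an explicit index window
lm_slope <- function(curve, idx) {
  unname(stats::coef(stats::lm(curve$values[idx] ~ curve$times[idx]))[2])
}

# string reverse complement without Biostrings
rc_chartr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1L]]), collapse = "")
}

canonical_two_input_tables <- function() {
  list(NONE = c(0L, 0L, 0L, 0L), AND = c(0L, 0L, 0L, 1L),
       ANDN = c(0L, 0L, 1L, 0L), YES = c(0L, 0L, 1L, 1L),
       XOR = c(0L, 1L, 1L, 0L), OR = c(0L, 1L, 1L, 1L),
       NOR = c(1L, 0L, 0L, 0L), XNOR = c(1L, 0L, 0L, 1L),
       NOT = c(1L, 1L, 0L, 0L), ORN = c(1L, 0L, 1L, 1L),
       NAND = c(1L, 1L, 1L, 0L), ALL = c(1L, 1L, 1L, 1L))
}

int_to_bits <- function(m, n) as.integer(intToBits(m))[n:1]
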