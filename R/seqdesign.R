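#' Default operator sequence database
#'
#' Ships one recognition sequence per repressor, modelled on the canonical
#' literature motifs (lac O1-type palindrome, gal operator half-sites, trp
#' operator palindrome, tandem met-box repeat). These are synthetic
#' placeholders: real designs should replace them with the experimentally
#' used operator sequences via [operator_db()].
#'
#' @return A data frame of class `rca_operator_db` with columns
#'   `operator_id`, `sequence`, `repressor`, `note`.
#' @export
default_operator_db <- function() {
  operator_db(data.frame(
    operator_id = c("lacO1_syn", "galO_syn", "trpO_syn", "metbox_syn"),
    sequence = c("AATTGTGAGCGGATAACAATT",
                 "GTGTAAACGATTCCACTGTG",
                 "GTACTAGTTAACTAGTAC",
                 "AGACGTCTAGACGTCT"),
    repressor = c("LacI", "GalR", "TrpR", "MetJ"),
    note = rep("synthetic placeholder motif", 4L),
    stringsAsFactors = FALSE))
}

#' Construct/validate an operator database
#'
#' @param df Data frame with columns `operator_id`, `sequence`, `repressor`
#'   and optionally `note`. Sequences must be unique uppercase ACGT(N).
#' @return The validated data frame, class `rca_operator_db`.
#' @export
operator_db <- function(df) {
  need <- c("operator_id", "sequence", "repressor")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("operator db misses column(s): ",
                            paste(missing, collapse = ", "))
  if (!"note" %in% names(df)) df$note <- ""
  if (anyDuplicated(df$operator_id)) stop("duplicate operator ids")
  if (anyDuplicated(df$sequence)) stop("duplicate operator sequences")
  bad <- grepl("[^ACGTN]", df$sequence)
  if (any(bad)) stop("operator sequence(s) not uppercase ACGTN: ",
                     paste(df$operator_id[bad], collapse = ", "))
  structure(df, class = c("rca_operator_db", "data.frame"))
}

db_sequence <- function(db, operator_id) {
  i <- match(operator_id, db$operator_id)
  if (is.na(i)) stop("operator '", operator_id, "' not in database")
  db$sequence[i]
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# deterministic 50% GC filler, phase-continuous from `from` (0-based)
filler <- function(len, from = 0L) {
  if (len <= 0L) return("")
  unit <- c("T", "G", "C", "A")
  paste(unit[((from + seq_len(len) - 1L) %% 4L) + 1L], collapse = "")
}

#' Assemble the concrete oligonucleotides of a circular template
#'
#' Lays out, on the circularizable (5'-phosphorylated) strand linearized at
#' the ligation junction: the primer-binding region, then each operator
#' preceded by its spacer in the template's circular site order, then
#' padding up to the target length. The splint oligo is the reverse
#' complement of the head-to-tail junction (the last and first
#' `junction_arm` nt of the linearized strand, read across the circle); the
#' primer is the reverse complement of the primer-binding region.
#'
#' @param template An [circular_template()].
#' @param db Operator database.
#' @param target_length Circle length in nt; defaults to
#'   `template$total_length` or content plus 12 nt of padding.
#' @param primer_region Primer-binding sequence on the template strand;
#'   default is an 18-nt generic region.
#' @param spacer Spacer sequence inserted before each operator (default
#'   6 nt, AT-rich).
#' @param junction_arm Splint arm length on each side of the junction (nt).
#' @return An object of class `rca_template_build` with the linearized
#'   `circular_sequence`, `splint`, `primer` and 0-based half-open
#'   `site_coordinates`.
#' @export
assemble_template <- function(template, db = default_operator_db(),
                              target_length = NULL,
                              primer_region = "CAGTCAGTGACTTGACAT",
                              spacer = "ATGCAT", junction_arm = 9L) {
  stopifnot(inherits(template, "rca_template"))
  if (is.null(primer_region)) primer_region <- template$primer_region
  if (is.null(primer_region)) stop("a primer region is required")
  parts <- primer_region
  coords <- data.frame(operator_id = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  pos <- nchar(primer_region)
  for (s in template$sites) {
    op_seq <- db_sequence(db, s$operator_id)
    parts <- c(parts, spacer, op_seq)
    start <- pos + nchar(spacer)
    coords <- rbind(coords, data.frame(operator_id = s$operator_id,
                                       start = start,
                                       end = start + nchar(op_seq),
                                       stringsAsFactors = FALSE))
    pos <- start + nchar(op_seq)
  }
  content <- paste(parts, collapse = "")
  if (is.null(target_length)) {
    target_length <- template$total_length %||% (nchar(content) + 12L)
  }
  if (target_length < nchar(content)) {
    stop("target length ", target_length, " nt is smaller than content (",
         nchar(content), " nt)")
  }
  seq <- paste0(content, filler(target_length - nchar(content),
                                from = nchar(content)))
  L <- nchar(seq)
  stopifnot(junction_arm * 2 <= L)
  junction <- paste0(substr(seq, L - junction_arm + 1L, L),
                     substr(seq, 1L, junction_arm))
  build <- structure(list(name = template$name,
                          circular_sequence = seq,
                          splint = revcomp(junction),
                          primer = revcomp(primer_region),
                          primer_region = primer_region,
                          site_coordinates = coords,
                          circular = TRUE, phos5 = TRUE,
                          junction_arm = as.integer(junction_arm)),
                     class = "rca_template_build")
  build
}

count_circular <- function(seq, pattern) {
  L <- nchar(seq)
  if (nchar(pattern) > L) return(0L)
  doubled <- paste0(seq, seq)
  hits <- gregexpr(pattern, doubled, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(0L)
  sum(hits <= L)
}

#' Scan assembled templates for operator occurrences
#'
#' Exact-match scan of every operator (and its reverse complement, since
#' repressors read the double-stranded motif) over each circular sequence,
#' including matches spanning the ligation junction. The intended placed
#' sites are subtracted; any nonzero residual marks an unintended
#' cross-design occurrence.
#'
#' @param builds An `rca_template_build` or list thereof.
#' @param db Operator database.
#' @return Integer matrix (template x operator) of residual counts.
#' @export
scan_operators <- function(builds, db = default_operator_db()) {
  if (inherits(builds, "rca_template_build")) builds <- list(builds)
  m <- matrix(0L, nrow = length(builds), ncol = nrow(db),
              dimnames = list(vapply(builds, function(b) b$name, character(1)),
                              db$operator_id))
  for (i in seq_along(builds)) {
    b <- builds[[i]]
    for (j in seq_len(nrow(db))) {
      pat <- db$sequence[j]
      rc <- revcomp(pat)
      cnt <- count_circular(b$circular_sequence, pat)
      if (!identical(rc, pat)) {
        cnt <- cnt + count_circular(b$circular_sequence, rc)
      }
      intended <- sum(b$site_coordinates$operator_id == db$operator_id[j])
      m[i, j] <- cnt - intended
    }
  }
  m
}

#' Rotate the linearization point of a build
#'
#' The circle has no origin; rotating the stored linearization must not
#' change any scan result. Coordinates are shifted modulo the length (a
#' rotated site may wrap around the new junction).
#'
#' @param build An `rca_template_build`.
#' @param offset Rotation in nt (0-based).
#' @return A rotated `rca_template_build`.
#' @export
rotate_build <- function(build, offset) {
  L <- nchar(build$circular_sequence)
  offset <- ((offset %% L) + L) %% L
  if (offset == 0L) return(build)
  seq <- paste0(substr(build$circular_sequence, offset + 1L, L),
                substr(build$circular_sequence, 1L, offset))
  coords <- build$site_coordinates
  coords$start <- (coords$start - offset) %% L
  coords$end <- ((coords$end - 1L - offset) %% L) + 1L
  out <- build
  out$circular_sequence <- seq
  out$site_coordinates <- coords
  out
}

build_header <- function(build, role) {
  coords <- build$site_coordinates
  sites <- if (nrow(coords)) {
    paste(sprintf("%s:%d-%d", coords$operator_id, coords$start, coords$end),
          collapse = ";")
  } else "none"
  switch(role,
    template = sprintf(
      "%s_template role=template circular=true phos5=true synthetic=true sites=%s",
      build$name, sites),
    splint = sprintf("%s_splint role=splint synthetic=true", build$name),
    primer = sprintf("%s_primer role=primer synthetic=true", build$name))
}

#' Write assembled builds to FASTA
#'
#' One record per oligonucleotide (template, splint, primer), 60-column
#' wrapped, headers carrying role, circularity/phosphorylation flags and
#' site coordinates as key=value pairs. All shipped sequences are flagged
#' `synthetic=true`.
#'
#' @param builds List of `rca_template_build` objects (non-empty).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(builds, path) {
  if (inherits(builds, "rca_template_build")) builds <- list(builds)
  if (length(builds) == 0L) stop("no builds to write")
  seqs <- character(); headers <- character()
  for (b in builds) {
    seqs <- c(seqs, b$circular_sequence, b$splint, b$primer)
    headers <- c(headers, build_header(b, "template"),
                 build_header(b, "splint"), build_header(b, "primer"))
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read builds back from FASTA written by [write_fasta()]
#'
#' @param path FASTA path.
#' @return Named list of `rca_template_build` objects (splint/primer
#'   re-attached to their template by name).
#' @export
read_fasta_builds <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  headers <- names(x)
  seqs <- as.character(x)
  recs <- lapply(seq_along(headers), function(i) {
    toks <- strsplit(headers[i], " ", fixed = TRUE)[[1L]]
    kv <- strsplit(toks[-1L], "=", fixed = TRUE)
    vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                            vapply(kv, `[`, character(1), 1L))
    list(id = toks[1L], fields = vals, seq = unname(seqs[i]))
  })
  builds <- list()
  for (r in recs) {
    if (r$fields[["role"]] != "template") next
    name <- sub("_template$", "", r$id)
    sites <- r$fields[["sites"]]
    coords <- if (identical(sites, "none")) {
      data.frame(operator_id = character(), start = integer(),
                 end = integer(), stringsAsFactors = FALSE)
    } else {
      parts <- strsplit(strsplit(sites, ";", fixed = TRUE)[[1L]], "[:-]")
      data.frame(operator_id = vapply(parts, `[`, character(1), 1L),
                 start = as.integer(vapply(parts, `[`, character(1), 2L)),
                 end = as.integer(vapply(parts, `[`, character(1), 3L)),
                 stringsAsFactors = FALSE)
    }
    builds[[name]] <- structure(
      list(name = name, circular_sequence = r$seq, splint = NA_character_,
           primer = NA_character_, primer_region = NA_character_,
           site_coordinates = coords,
           circular = identical(r$fields[["circular"]], "true"),
           phos5 = identical(r$fields[["phos5"]], "true"),
           junction_arm = NA_integer_),
      class = "rca_template_build")
  }
  for (r in recs) {
    role <- r$fields[["role"]]
    if (role == "template") next
    name <- sub(paste0("_", role, "$"), "", r$id)
    if (!is.null(builds[[name]])) builds[[name]][[role]] <- r$seq
  }
  builds
}

#' Assemble every template of a reaction system
#'
#' @param system An `rca_system`.
#' @param db Operator database.
#' @param ... Passed to [assemble_template()].
#' @return Named list of `rca_template_build` objects.
#' @export
assemble_system <- function(system, db = default_operator_db(), ...) {
  builds <- lapply(system$templates, assemble_template, db = db, ...)
  stats::setNames(builds, vapply(system$templates, function(t) t$name,
                                 character(1)))
}

#' @export
print.rca_template_build <- function(x, ...) {
  cat("Template build '", x$name, "': ", nchar(x$circular_sequence),
      " nt circle, ", nrow(x$site_coordinates), " operator site(s)\n",
      sep = "")
  invisible(x)
}
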