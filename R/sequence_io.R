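#' Read proteins from a FASTA file into a record table
#'
#' Headers are interpreted as `id<delim>species<delim>family`; fields that are
#' absent default to `"unknown"`. Sequences are uppercased and validated
#' against the 20 canonical amino-acid letters plus `X` (unknown residue).
#'
#' @param path Path to a protein FASTA file.
#' @param delim Field delimiter inside the FASTA header (default `"|"`).
#' @return A tibble with columns `id`, `species`, `family`, `sequence`, one
#'   row per input record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1|MO1|MamP", "MKAV"), fa)
#' read_protein_fasta(fa)
#' @export
read_protein_fasta <- function(path, delim = "|") {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^\\s*$", lines))
  if (length(body) > 0 && !startsWith(lines[body[1]], ">")) {
    abort(paste0("malformed FASTA: sequence before first header at line ", body[1]))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA in ", path, ": ", conditionMessage(e)))
  )
  headers <- names(set)
  seqs <- toupper(as.character(set))
  fields <- stringr::str_split(headers, stringr::fixed(delim))
  take <- function(i) map_chr(fields, function(f) {
    v <- if (length(f) >= i) stringr::str_trim(f[[i]]) else ""
    if (identical(v, "")) "unknown" else v
  })
  records <- tibble(
    id = take(1), species = take(2), family = take(3),
    sequence = unname(seqs)
  )
  validate_protein_records(records)
  records
}

#' Write a protein record table to FASTA
#'
#' The inverse of [read_protein_fasta()]: headers are written as
#' `id<delim>species<delim>family` and sequences wrapped at `width` columns,
#' so that reading the file back reproduces the records field for field.
#'
#' @param records Tibble with columns `id`, `species`, `family`, `sequence`.
#' @param path Output file path.
#' @param delim Header field delimiter.
#' @param width Sequence line width (default 60).
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path, delim = "|", width = 60) {
  records <- validate_protein_records(records)
  if (nrow(records) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- paste(records$id, records$species, records$family, sep = delim)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Validate a protein record table
#'
#' Checks the record invariants: non-empty sequences over the alphabet
#' `ACDEFGHIKLMNPQRSTVWYX` (uppercased in place) and unique ids.
#'
#' @param records Tibble with columns `id`, `species`, `family`, `sequence`.
#' @return The validated (uppercased) tibble, invisibly usable in pipes.
#' @export
validate_protein_records <- function(records) {
  needed <- c("id", "species", "family", "sequence")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort(paste0("record table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  records$sequence <- toupper(records$sequence)
  if (anyDuplicated(records$id)) {
    dup <- records$id[duplicated(records$id)][1]
    abort(paste0("duplicate record id: ", dup))
  }
  for (i in seq_len(nrow(records))) {
    check_sequence(records$sequence[i], records$id[i])
  }
  records
}

check_sequence <- function(sequence, id) {
  if (is.na(sequence) || nchar(sequence) == 0) {
    abort(paste0("record ", id, ": empty sequence"))
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_INPUT_ALPHABET)
  if (length(bad) > 0) {
    abort(paste0("record ", id, ": illegal residue '", chars[bad[1]],
                 "' at position ", bad[1]))
  }
  invisible(TRUE)
}
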