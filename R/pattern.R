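#' Compile a PROSITE-dialect protein pattern
#'
#' Supports the dialect subset used for the magnetochrome harvest pattern:
#' fixed residues (`C`), bracketed residue classes (`[IVMLQA]`), the wildcard
#' `x`/`X` (any of the 20 canonical residues; the unknown-residue symbol `X`
#' in a *sequence* never matches), repeat counts `(n)` and ranges `(n,m)`,
#' and `-` element separators. Unicode minus signs are normalised to `-`.
#'
#' @param text Pattern string, e.g. `"[PTH]-[H]-x(5,9)-C-x-x-C-H"`.
#' @param name Optional name carried on the compiled object.
#' @return An object of class `mcr_pattern`: a list with an `elements`
#'   tibble (`class`, `min`, `max`, `wildcard`) plus `min_total`/`max_total`
#'   match-length bounds.
#' @examples
#' p <- compile_pattern("C-x-x-C-H", name = "heme anchor")
#' p$min_total
#' @export
compile_pattern <- function(text, name = "pattern") {
  if (is.null(text) || is.na(text) || !nzchar(text)) abort("empty pattern text")
  txt <- gsub("−|–", "-", text)   # unicode minus/en-dash
  txt <- gsub("\\s+", "", txt)
  n <- nchar(txt)
  pos <- 1L
  elements <- list()
  fail <- function(msg, at) {
    abort(paste0("pattern compile error at character ", at, ": ", msg,
                 " (in \"", text, "\")"))
  }
  while (pos <= n) {
    ch <- substr(txt, pos, pos)
    if (ch == "-") { pos <- pos + 1L; next }
    start_at <- pos
    if (ch == "[") {
      close <- regexpr("]", substr(txt, pos, n), fixed = TRUE)
      if (close < 0) fail("unbalanced '['", start_at)
      inner <- substr(txt, pos + 1L, pos + close - 2L)
      if (!nzchar(inner)) fail("empty residue class", start_at)
      letters <- unique(strsplit(toupper(inner), "", fixed = TRUE)[[1]])
      bad <- setdiff(letters, AA_MODEL_ORDER)
      if (length(bad) > 0) fail(paste0("unknown residue '", bad[1], "' in class"), start_at)
      cls <- paste(letters, collapse = "")
      wildcard <- FALSE
      pos <- pos + close
    } else if (grepl("^[A-Za-z]$", ch)) {
      if (toupper(ch) == "X") {
        cls <- paste(AA_MODEL_ORDER, collapse = "")
        wildcard <- TRUE
      } else {
        if (!toupper(ch) %in% AA_MODEL_ORDER) fail(paste0("unknown residue '", ch, "'"), start_at)
        cls <- toupper(ch)
        wildcard <- FALSE
      }
      pos <- pos + 1L
    } else {
      fail(paste0("unexpected character '", ch, "'"), start_at)
    }
    min_rep <- 1L; max_rep <- 1L
    if (pos <= n && substr(txt, pos, pos) == "(") {
      close <- regexpr(")", substr(txt, pos, n), fixed = TRUE)
      if (close < 0) fail("unbalanced '('", pos)
      inner <- substr(txt, pos + 1L, pos + close - 2L)
      parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
      if (length(parts) < 1 || length(parts) > 2 || any(!grepl("^\\d+$", parts))) {
        fail(paste0("non-numeric repeat count '", inner, "'"), pos)
      }
      min_rep <- as.integer(parts[1])
      max_rep <- if (length(parts) == 2) as.integer(parts[2]) else min_rep
      if (max_rep < min_rep) fail(paste0("repeat range ", min_rep, " > ", max_rep), pos)
      pos <- pos + close
    }
    elements[[length(elements) + 1L]] <- tibble(
      class = cls, min = min_rep, max = max_rep, wildcard = wildcard
    )
  }
  if (length(elements) == 0) abort("pattern contains no elements")
  elements <- bind_rows(elements)
  structure(
    list(
      name = name, text = text, elements = elements,
      min_total = sum(elements$min), max_total = sum(elements$max)
    ),
    class = "mcr_pattern"
  )
}

#' @export
print.mcr_pattern <- function(x, ...) {
  cat("<mcr_pattern> ", x$name, "\n  ", x$text, "\n  ",
      nrow(x$elements), " elements, match length in [",
      x$min_total, ", ", x$max_total, "]\n", sep = "")
  invisible(x)
}

#' The magnetochrome harvest pattern
#'
#' The PROSITE-dialect pattern devised from a structure-based alignment of
#' magnetochrome domains; it anchors on the `CXXCH` c-type heme attachment
#' motif with the upstream `PH` distal-ligand context. Its match length is
#' bounded in \[20, 34\] residues.
#'
#' @return A compiled `mcr_pattern`.
#' @export
mcr_harvest_pattern <- function() {
  compile_pattern(
    "[P]-x(0,6)-[IVMLQA]-x(6)-[PTH]-X(0,2)-[H]-x(1,3)-[GN]-x(1,5)-C-x-x-C-H-x-[IVMLFY]",
    name = "magnetochrome harvest"
  )
}

#' The minimal magnetochrome unit pattern
#'
#' The minimal unit defining an MCR domain, `[P/T/H]HX(5-9)CX(2)CH`: the PH
#' dipeptide providing the sixth heme ligand, a 5-9 residue spacer, and the
#' `CXXCH` heme-binding motif. Match length is bounded in \[12, 16\].
#'
#' @return A compiled `mcr_pattern`.
#' @export
mcr_minimal_pattern <- function() {
  compile_pattern("[PTH]-[H]-x(5,9)-C-x-x-C-H", name = "magnetochrome minimal unit")
}

#' Read patterns from a pattern file
#'
#' One PROSITE-dialect pattern per line; `#` starts a comment; blank lines
#' are ignored. An optional `name:` prefix (text before a tab) names the
#' pattern.
#'
#' @param path Path to the pattern file.
#' @return A list of compiled `mcr_pattern` objects.
#' @export
read_pattern_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- stringr::str_trim(lines)
  lines <- lines[nzchar(lines)]
  map(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 2) {
      compile_pattern(parts[2], name = parts[1])
    } else {
      compile_pattern(parts[1], name = paste0("pattern_", i))
    }
  })
}

# Logical membership matrix: element x sequence position.  The unknown
# residue X matches nothing, including the wildcard.
pattern_membership <- function(chars, pattern) {
  el <- pattern$elements
  out <- matrix(FALSE, nrow(el), length(chars))
  for (e in seq_len(nrow(el))) {
    cls <- strsplit(el$class[e], "", fixed = TRUE)[[1]]
    out[e, ] <- chars %in% cls
  }
  out
}

#' Scan a sequence with a compiled pattern
#'
#' Finds all non-overlapping matches left to right. At each feasible start
#' the *shortest* feasible match is taken (so a match cannot swallow the
#' boundary of a neighbouring tandem domain), and scanning resumes after the
#' reported match.
#'
#' Feasibility is decided by a small dynamic programme over (element,
#' consumed-length) states, so variable-repeat elements are handled exactly,
#' without backtracking.
#'
#' @param sequence A single amino-acid string.
#' @param pattern A compiled `mcr_pattern`.
#' @return Tibble with columns `start`, `end` (1-based inclusive) and
#'   `length`; zero rows when there is no match.
#' @export
scan_pattern <- function(sequence, pattern) {
  stopifnot(inherits(pattern, "mcr_pattern"), length(sequence) == 1)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < pattern$min_total) {
    return(tibble(start = integer(0), end = integer(0), length = integer(0)))
  }
  memb <- pattern_membership(chars, pattern)
  # run[e, p] = number of consecutive residues matching element e starting
  # at p (vectorised: distance to the next non-matching position)
  el <- pattern$elements
  n_el <- nrow(el)
  runlen <- matrix(0L, n_el, n + 1L)
  pos <- seq_len(n)
  for (e in seq_len(n_el)) {
    fail <- ifelse(memb[e, ], Inf, pos)
    next_fail <- pmin(rev(cummin(rev(fail))), n + 1)
    runlen[e, seq_len(n)] <- as.integer(next_fail - pos)
  }
  spans <- scan_spans_cpp(runlen, el$min, el$max, pattern$min_total)
  tibble(start = spans[, 1], end = spans[, 2],
         length = spans[, 2] - spans[, 1] + 1L)
}

#' Delineate a magnetochrome domain around a CXXCH anchor
#'
#' Implements the structural delineation `psi1 X(5-9) P H X(5-9) C X X C H
#' psi2`: starting from the `CXXCH` heme anchor, the `PH` distal-ligand
#' dipeptide is located 5-9 residues upstream (nearest first), the
#' N-terminal boundary `psi1` is the nearest hydrophobic residue
#' (`IVMLFYWA`) 5-9 residues upstream of the P, and the C-terminal boundary
#' `psi2` the nearest hydrophobic residue 1-2 residues downstream of the
#' final H. A complete delineation therefore spans 19-28 residues. When the
#' `PH` or either boundary cannot be found the hit falls back to the minimal
#' unit actually present and is flagged `partial`.
#'
#' @param sequence Amino-acid string.
#' @param core_start 1-based position of the first C of the `CXXCH` anchor.
#' @return One-row tibble: `start`, `end`, `core_start`, `core_end`,
#'   `partial`, `sequence`.
#' @export
delineate_domain <- function(sequence, core_start) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  core_end <- core_start + 4L
  if (core_start < 1L || core_end > n) {
    abort(paste0("CXXCH anchor [", core_start, ", ", core_end,
                 "] outside sequence of length ", n))
  }
  core <- chars[core_start:core_end]
  if (!(core[1] == "C" && core[4] == "C" && core[5] == "H" &&
        !any(core[2:3] == "X"))) {
    abort(paste0("no CXXCH motif at position ", core_start))
  }

  # PH with 5-9 residues between its H and the anchor C; nearest first.
  p_pos <- NA_integer_
  for (spacer in 5:9) {
    p <- core_start - spacer - 2L
    if (p >= 1L && chars[p] == "P" && chars[p + 1L] == "H") { p_pos <- p; break }
  }

  psi1 <- NA_integer_
  if (!is.na(p_pos)) {
    for (spacer in 5:9) {
      q <- p_pos - spacer - 1L
      if (q >= 1L && chars[q] %in% AA_HYDROPHOBIC) { psi1 <- q; break }
    }
  }

  psi2 <- NA_integer_
  for (off in 1:2) {
    q <- core_end + off
    if (q <= n && chars[q] %in% AA_HYDROPHOBIC) { psi2 <- q; break }
  }

  partial <- is.na(p_pos) || is.na(psi1) || is.na(psi2)
  start <- if (!is.na(psi1)) psi1 else if (!is.na(p_pos)) p_pos else core_start
  end <- if (!partial || !is.na(psi2)) psi2 else core_end
  if (is.na(end)) end <- core_end
  tibble(
    start = start, end = end, core_start = core_start, core_end = core_end,
    partial = partial, sequence = substr(sequence, start, end)
  )
}

# Residues after the CXXCH block of a pattern, when that length is fixed
# (all trailing elements have min == max).  NA when it cannot be deduced.
pattern_anchor_trailing <- function(pattern) {
  el <- pattern$elements
  n_el <- nrow(el)
  for (j in seq_len(n_el)) {
    if (j + 4L > n_el) break
    block <- el[j:(j + 4L), ]
    if (identical(block$class[c(1, 4, 5)], c("C", "C", "H")) &&
        block$wildcard[2] && block$wildcard[3] &&
        all(block$min == 1L) && all(block$max == 1L)) {
      if (j + 5L > n_el) return(0L)
      trail <- el[(j + 5L):n_el, ]
      if (all(trail$min == trail$max)) return(sum(trail$min))
      return(NA_integer_)
    }
  }
  NA_integer_
}

locate_anchor <- function(chars, m_start, m_end, trailing) {
  if (!is.na(trailing)) {
    cs <- m_end - trailing - 4L
    if (cs >= m_start && chars[cs] == "C") return(cs)
  }
  # fallback: rightmost CXXCH wholly inside the match span
  for (cs in (m_end - 4L):m_start) {
    if (chars[cs] == "C" && chars[cs + 3L] == "C" && chars[cs + 4L] == "H" &&
        !any(chars[(cs + 1L):(cs + 2L)] == "X")) {
      return(cs)
    }
  }
  NA_integer_
}

#' Harvest magnetochrome domains from a set of proteins
#'
#' Scans every record with the pattern, delineates each match around its
#' `CXXCH` anchor, and numbers tandem occurrences `1..k` from the N-terminus
#' (`position_index`, the MCR1/MCR2 labels).
#'
#' @param records Protein record tibble (see [read_protein_fasta()]).
#' @param pattern A compiled `mcr_pattern`; default the harvest pattern.
#' @return Tibble of domain hits: `protein_id`, `species`, `family`,
#'   `position_index`, `start`, `end`, `core_start`, `core_end`, `partial`,
#'   `sequence` (coordinates 1-based inclusive). Records without any hit are
#'   listed in the `"no_hit"` attribute.
#' @export
harvest_domains <- function(records, pattern = mcr_harvest_pattern()) {
  records <- validate_protein_records(records)
  trailing <- pattern_anchor_trailing(pattern)
  out <- vector("list", nrow(records))
  no_hit <- character(0)
  for (i in seq_len(nrow(records))) {
    seqi <- records$sequence[i]
    chars <- strsplit(seqi, "", fixed = TRUE)[[1]]
    spans <- scan_pattern(seqi, pattern)
    if (nrow(spans) == 0) {
      no_hit <- c(no_hit, records$id[i])
      next
    }
    hits <- map(seq_len(nrow(spans)), function(k) {
      cs <- locate_anchor(chars, spans$start[k], spans$end[k], trailing)
      if (is.na(cs)) return(NULL)
      delineate_domain(seqi, cs)
    })
    hits <- bind_rows(hits[!vapply(hits, is.null, logical(1))])
    if (nrow(hits) == 0) {
      no_hit <- c(no_hit, records$id[i])
      next
    }
    hits <- hits %>%
      distinct(.data$core_start, .keep_all = TRUE) %>%
      arrange(.data$start) %>%
      mutate(
        protein_id = records$id[i], species = records$species[i],
        family = records$family[i], position_index = row_number()
      )
    out[[i]] <- hits
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(
      protein_id = character(0), species = character(0), family = character(0),
      position_index = integer(0), start = integer(0), end = integer(0),
      core_start = integer(0), core_end = integer(0), partial = logical(0),
      sequence = character(0)
    )
  } else {
    res <- select(res, "protein_id", "species", "family", "position_index",
                  "start", "end", "core_start", "core_end", "partial", "sequence")
  }
  attr(res, "no_hit") <- no_hit
  res
}

#' Write a domain-hit table to TSV
#'
#' Columns `protein_id`, `species`, `family`, `position_index`,
#' `start_1based`, `end_1based`, `partial_flag`, `sequence`.
#'
#' @param hits A hit tibble from [harvest_domains()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  out <- tibble(
    protein_id = hits$protein_id, species = hits$species, family = hits$family,
    position_index = hits$position_index,
    start_1based = hits$start, end_1based = hits$end,
    partial_flag = hits$partial, sequence = hits$sequence
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
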