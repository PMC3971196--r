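#' Scoring parameters for the progressive aligner
#'
#' @param matrix Substitution matrix name (only `"BLOSUM62"` is packaged,
#'   taken from Biostrings) or a symmetric numeric matrix with residue
#'   dimnames.
#' @param gap_open Gap opening penalty (< 0). A gap of length k costs
#'   `gap_open + k * gap_extend`.
#' @param gap_extend Gap extension penalty (< 0).
#' @return A list of class `scoring_params`.
#' @export
scoring_params <- function(matrix = "BLOSUM62", gap_open = -10, gap_extend = -1) {
  if (is.character(matrix)) {
    if (!identical(matrix, "BLOSUM62")) abort("only BLOSUM62 is packaged")
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    matrix <- env$BLOSUM62
  }
  keep <- intersect(AA_INPUT_ALPHABET, rownames(matrix))
  matrix <- matrix[keep, keep, drop = FALSE]
  if (!isTRUE(all.equal(matrix, t(matrix)))) abort("substitution matrix must be symmetric")
  if (gap_open >= 0 || gap_extend >= 0) abort("gap penalties must be negative")
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_params")
}

seq_to_indices <- function(sequence, alphabet) {
  idx <- match(strsplit(sequence, "", fixed = TRUE)[[1]], alphabet)
  if (anyNA(idx)) abort("sequence contains residues outside the scoring alphabet")
  idx
}

# profile: integer matrix rows x columns, 0 = gap, otherwise index into the
# scoring alphabet.  Column frequency matrix (alphabet x columns), counts
# divided by the number of rows so that gap-rich columns weigh less.
profile_freqs <- function(profile, n_letters) {
  n_col <- ncol(profile)
  f <- matrix(0, n_letters, n_col)
  for (j in seq_len(n_col)) {
    idx <- profile[, j]
    idx <- idx[idx > 0L]
    if (length(idx) > 0) {
      tb <- tabulate(idx, nbins = n_letters)
      f[, j] <- tb / nrow(profile)
    }
  }
  f
}

align_profiles <- function(pa, pb, params) {
  alpha_n <- nrow(params$matrix)
  S <- crossprod(profile_freqs(pa, alpha_n), params$matrix %*% profile_freqs(pb, alpha_n))
  res <- affine_align_dp(S, params$gap_open, params$gap_extend)
  moves <- res$moves
  out <- matrix(0L, nrow(pa) + nrow(pb), length(moves))
  ia <- 0L; ib <- 0L
  ra <- seq_len(nrow(pa)); rb <- nrow(pa) + seq_len(nrow(pb))
  for (k in seq_along(moves)) {
    mv <- moves[k]
    if (mv == 1L) {
      ia <- ia + 1L; ib <- ib + 1L
      out[ra, k] <- pa[, ia]; out[rb, k] <- pb[, ib]
    } else if (mv == 2L) {
      ia <- ia + 1L
      out[ra, k] <- pa[, ia]
    } else {
      ib <- ib + 1L
      out[rb, k] <- pb[, ib]
    }
  }
  list(profile = out, score = res$score)
}

#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment of two residue strings under
#' [scoring_params()]. Traceback ties are broken deterministically
#' (diagonal, then gap in the second sequence, then gap in the first).
#'
#' @param a,b Amino-acid strings (non-empty).
#' @param params A `scoring_params` object.
#' @return List with `score` and `aligned`, a length-2 character vector of
#'   gapped sequences.
#' @examples
#' align_pairwise("CAACH", "CAACH")$score
#' @export
align_pairwise <- function(a, b, params = scoring_params()) {
  if (!nzchar(a) || !nzchar(b)) abort("cannot align an empty sequence")
  alphabet <- rownames(params$matrix)
  pa <- matrix(seq_to_indices(toupper(a), alphabet), nrow = 1)
  pb <- matrix(seq_to_indices(toupper(b), alphabet), nrow = 1)
  res <- align_profiles(pa, pb, params)
  gapped <- apply(res$profile, 1, function(idx) {
    paste(ifelse(idx == 0L, "-", alphabet[pmax(idx, 1L)]), collapse = "")
  })
  list(score = res$score, aligned = gapped)
}

pairwise_identity_dist <- function(seqs, params) {
  alphabet <- rownames(params$matrix)
  idx <- lapply(seqs, function(s) seq_to_indices(toupper(s), alphabet))
  d <- pairwise_identity_matrix_cpp(idx, params$matrix,
                                    params$gap_open, params$gap_extend)
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

#' UPGMA guide tree from pairwise alignment identities
#'
#' Distances are one minus the fractional identity of the optimal pairwise
#' alignment (matching columns over alignment length); clustering is
#' average-linkage (UPGMA) via [stats::hclust()].
#'
#' @param seqs Named character vector of at least two sequences.
#' @param params A `scoring_params` object.
#' @return An `hclust` object.
#' @export
build_guide_tree <- function(seqs, params = scoring_params()) {
  if (length(seqs) < 2) abort("need at least two sequences for a guide tree")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  d <- pairwise_identity_dist(seqs, params)
  hclust(as.dist(d), method = "average")
}

#' Progressive multiple alignment of magnetochrome domains
#'
#' Profiles are merged in UPGMA guide-tree order with affine profile-profile
#' alignment; the score of aligning two profile columns is the mean of all
#' residue-pair substitution scores. Row order in the result equals the
#' input order, and removing gaps from any row reproduces its input
#' sequence exactly.
#'
#' @param x Either a domain-hit tibble from [harvest_domains()] (rows are
#'   labelled `protein_id|species|family|position_index`) or a named
#'   character vector of sequences.
#' @param params A `scoring_params` object.
#' @return An `mcr_alignment` object (see [new_mcr_alignment()]).
#' @export
align_progressive <- function(x, params = scoring_params()) {
  if (is.data.frame(x)) {
    seqs <- x$sequence
    names(seqs) <- hit_labels(x)
    meta <- x
  } else {
    seqs <- x
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    meta <- NULL
  }
  if (length(seqs) < 2) abort("need at least two sequences to align")
  if (anyDuplicated(names(seqs))) abort("duplicate sequence labels")
  alphabet <- rownames(params$matrix)
  tree <- build_guide_tree(seqs, params)
  profiles <- list()   # by merge step
  rows_of <- list()
  leaf_profile <- function(i) {
    list(profile = matrix(seq_to_indices(toupper(seqs[[i]]), alphabet), nrow = 1),
         rows = i)
  }
  n_merge <- nrow(tree$merge)
  for (k in seq_len(n_merge)) {
    get_node <- function(id) {
      if (id < 0) leaf_profile(-id) else list(profile = profiles[[id]], rows = rows_of[[id]])
    }
    a <- get_node(tree$merge[k, 1])
    b <- get_node(tree$merge[k, 2])
    merged <- align_profiles(a$profile, b$profile, params)
    profiles[[k]] <- merged$profile
    rows_of[[k]] <- c(a$rows, b$rows)
  }
  final <- profiles[[n_merge]]
  ord <- order(rows_of[[n_merge]])
  final <- final[ord, , drop = FALSE]
  gapped <- apply(final, 1, function(idx) {
    paste(ifelse(idx == 0L, "-", alphabet[pmax(idx, 1L)]), collapse = "")
  })
  names(gapped) <- names(seqs)
  new_mcr_alignment(gapped, meta = meta)
}

hit_labels <- function(hits) {
  paste(hits$protein_id, hits$species, hits$family, hits$position_index, sep = "|")
}

#' Construct an alignment object
#'
#' @param seqs Named character vector of equal-length gapped sequences
#'   (`-` for gaps).
#' @param meta Optional per-row metadata tibble (carried through stripping).
#' @return An object of class `mcr_alignment` with elements `seqs`, `meta`
#'   and `n_columns`.
#' @export
new_mcr_alignment <- function(seqs, meta = NULL) {
  if (length(seqs) == 0) abort("alignment must contain at least one row")
  if (is.null(names(seqs))) abort("alignment rows must be named")
  widths <- unique(nchar(seqs))
  if (length(widths) > 1) abort("alignment rows differ in length")
  structure(list(seqs = seqs, meta = meta, n_columns = widths),
            class = "mcr_alignment")
}

#' @export
print.mcr_alignment <- function(x, ...) {
  cat("<mcr_alignment> ", length(x$seqs), " rows x ", x$n_columns, " columns\n", sep = "")
  show <- head(x$seqs, 6)
  for (i in seq_along(show)) {
    cat(format(names(show)[i], width = 28), " ",
        substr(show[[i]], 1, 50), "\n", sep = "")
  }
  if (length(x$seqs) > 6) cat("  ... ", length(x$seqs) - 6, " more rows\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.mcr_alignment <- function(x, ...) {
  tb <- tibble(label = names(x$seqs), aligned = unname(x$seqs))
  if (!is.null(x$meta)) tb <- dplyr::bind_cols(tb, tibble::as_tibble(x$meta))
  tb
}

#' Remove gap and missing-data columns (complete deletion)
#'
#' Keeps exactly the columns that contain no gap (`-`) and no unknown
#' residue (`X`) in any row, the complete-deletion rule applied before
#' distance estimation and tree building.
#'
#' @param aln An `mcr_alignment`.
#' @return An `mcr_alignment` with the same rows, possibly fewer columns.
#' @export
strip_gap_columns <- function(aln) {
  stopifnot(inherits(aln, "mcr_alignment"))
  mat <- alignment_matrix(aln)
  keep <- !apply(mat == "-" | mat == "X", 2, any)
  kept <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  if (length(aln$seqs) == 1) kept <- setNames(kept, names(aln$seqs))
  out <- aln
  out$seqs <- setNames(kept, names(aln$seqs))
  out$n_columns <- sum(keep)
  out
}

alignment_matrix <- function(aln) {
  mat <- do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
  if (aln$n_columns == 0) mat <- matrix(character(0), nrow = length(aln$seqs), ncol = 0)
  rownames(mat) <- names(aln$seqs)
  mat
}

#' Write an alignment as gapped FASTA
#' @param aln An `mcr_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  set <- Biostrings::BStringSet(aln$seqs)
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Read a gapped FASTA alignment
#'
#' Allows importing an externally produced multiple alignment (for example
#' from MUSCLE) so the rest of the pipeline can run on it unchanged.
#'
#' @param path Path to an aligned FASTA file.
#' @return An `mcr_alignment`.
#' @export
read_alignment_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- names(set)
  new_mcr_alignment(seqs)
}
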