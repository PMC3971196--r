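#' Maximum-likelihood pairwise distances under an amino-acid model
#'
#' For each pair of rows the distance is the branch length t maximising the
#' likelihood `prod_sites pi_a P(t)_ab` with `P(t) = exp(Qt)`, found by
#' bounded one-dimensional optimisation on `[0, d_max]`. Saturated pairs are
#' capped at `d_max`. By reversibility the estimate is symmetric in the two
#' sequences.
#'
#' @param aln A gap-free `mcr_alignment` (apply [strip_gap_columns()] first).
#' @param model An `aa_model`, default [jtt_model()].
#' @param d_max Saturation cap in substitutions per site (default 5).
#' @return A symmetric numeric matrix with the alignment row labels.
#' @export
jtt_distance <- function(aln, model = jtt_model(), d_max = 5) {
  stopifnot(inherits(aln, "mcr_alignment"))
  if (aln$n_columns < 1) abort("alignment has zero columns")
  mat <- alignment_matrix(aln)
  if (any(mat == "-" | mat == "X")) {
    abort("alignment contains gaps or missing data; strip columns first")
  }
  idx <- matrix(match(mat, model$alphabet), nrow = nrow(mat))
  if (anyNA(idx)) abort("alignment contains residues outside the model alphabet")
  d <- ml_pair_distances_cpp(idx, model$eig_values, model$eig_left,
                             t(model$eig_right), log(model$pi), d_max)
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

#' Write a distance matrix as TSV
#' @param d Symmetric labelled distance matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(d, path) {
  df <- data.frame(label = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining (via [ape::nj()]), returning an
#' unrooted tree. Negative branch-length estimates are clamped to zero with
#' the deficit transferred to the sibling branch, preserving path lengths
#' between the joined pair and the rest of the tree.
#'
#' @param d Symmetric distance matrix (labelled) or `dist` object, n >= 3.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("distance matrix must be square")
  if (nrow(d) < 3) abort("neighbor joining needs at least 3 leaves")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  tr <- ape::nj(as.dist(d))
  clamp_negative_branches(tr)
}

clamp_negative_branches <- function(tr) {
  # single sweep, most negative first: each edge donates its deficit to a
  # sibling once; anything still negative afterwards is truncated to zero
  for (i in order(tr$edge.length)) {
    if (tr$edge.length[i] >= 0) next
    parent <- tr$edge[i, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), i)
    if (length(sibs) > 0) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + tr$edge.length[i]
    }
    tr$edge.length[i] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Fixed-topology log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning over alignment columns with `P(t) = exp(Qt)` on each
#' branch and the model's equilibrium frequencies at the (arbitrary) root;
#' under reversibility the value does not depend on root placement.
#'
#' @param tree A `phylo` tree whose tip labels are alignment row labels.
#' @param aln A gap-free `mcr_alignment` containing every tip.
#' @param model An `aa_model`.
#' @return List of class `tree_score` with `log_likelihood` (natural log)
#'   and `n_sites`.
#' @export
tree_log_likelihood <- function(tree, aln, model = jtt_model()) {
  stopifnot(inherits(tree, "phylo"), inherits(aln, "mcr_alignment"))
  mat <- alignment_matrix(aln)
  if (any(mat == "-" | mat == "X")) abort("alignment contains gaps or missing data")
  missing <- setdiff(tree$tip.label, rownames(mat))
  if (length(missing) > 0) {
    abort(paste0("tree tip without alignment row: ", missing[1]))
  }
  mat <- mat[tree$tip.label, , drop = FALSE]
  idx <- matrix(match(mat, model$alphabet), nrow = nrow(mat))
  if (anyNA(idx)) abort("alignment contains residues outside the model alphabet")
  n_sites <- ncol(idx)
  n_tip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  n_node <- n_tip + tree$Nnode
  partial <- vector("list", n_node)
  scaler <- rep(0, n_sites)
  for (tip in seq_len(n_tip)) {
    m <- matrix(0, 20, n_sites)
    m[cbind(idx[tip, ], seq_len(n_sites))] <- 1
    partial[[tip]] <- m
  }
  edge <- tree$edge
  len <- tree$edge.length
  if (is.null(len)) len <- rep(0, nrow(edge))
  for (k in seq_len(nrow(edge))) {
    parent <- edge[k, 1]; child <- edge[k, 2]
    P <- probability_matrix(model, len[k])
    contrib <- P %*% partial[[child]]
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- contrib
    } else {
      partial[[parent]] <- partial[[parent]] * contrib
      mx <- apply(partial[[parent]], 2, max)
      mx[mx <= 0] <- 1
      partial[[parent]] <- sweep(partial[[parent]], 2, mx, "/")
      scaler <- scaler + log(mx)
    }
  }
  root <- edge[nrow(edge), 1]
  site_ll <- log(as.vector(model$pi %*% partial[[root]])) + scaler
  structure(list(log_likelihood = sum(site_ll), n_sites = n_sites),
            class = "tree_score")
}

#' @export
print.tree_score <- function(x, ...) {
  cat("<tree_score> log-likelihood ", format(x$log_likelihood, digits = 10),
      " over ", x$n_sites, " sites\n", sep = "")
  invisible(x)
}

#' Read a Newick tree
#'
#' @param x A file path or a Newick string.
#' @return A `phylo` tree; missing branch lengths default to 0.
#' @export
read_newick <- function(x) {
  tr <- tryCatch(
    if (length(x) == 1 && file.exists(x) && !grepl("\\(", x)) {
      ape::read.tree(file = x)
    } else {
      ape::read.tree(text = x)
    },
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e)))
  )
  if (is.null(tr)) abort("Newick parse error: no tree found")
  if (anyDuplicated(tr$tip.label)) {
    abort(paste0("duplicate leaf label: ", tr$tip.label[duplicated(tr$tip.label)][1]))
  }
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  tr$edge.length[is.na(tr$edge.length)] <- 0
  tr
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` tree.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @param digits Significant digits for branch lengths (default 10).
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
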