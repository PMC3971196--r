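#' Configuration for the magnetochrome evolution simulator
#'
#' The generator realises the two duplication-order scenarios as depth
#' orderings of the same three events on a domain tree: family divergence
#' (depth `t_family`), tandem duplication (`t_dup`) and species divergence
#' (`t_species`), all in substitutions per site before the present. Under
#' model 1 the duplication predates family divergence (`t_dup > t_family`);
#' under model 2 each family duplicates its domain independently after the
#' families have diverged (`t_dup < t_family`).
#'
#' @param n_species Number of species (default 10).
#' @param families Protein family names (default MamE, MamP, MamT, MamX).
#' @param model Duplication-order model, 1 or 2.
#' @param t_family Family-divergence depth (default 1.5).
#' @param t_dup Duplication depth; defaults to 0.3 under model 2 and 1.8
#'   under model 1.
#' @param t_species Species-tree depth (default 0.2).
#' @param domain_spacers Lengths of the psi1-PH and PH-CXXCH spacers, both
#'   in \[5, 9\] (default `c(5, 5)`, the spacing observed in MamP).
#' @param linker_length Residues between the two tandem domains (default
#'   40, the middle of the 30-60 range seen between MamE domains).
#' @param seed RNG seed; the whole simulation is deterministic given it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 10,
                              families = c("MamE", "MamP", "MamT", "MamX"),
                              model = 2,
                              t_family = 1.5,
                              t_dup = NULL,
                              t_species = 0.2,
                              domain_spacers = c(5, 5),
                              linker_length = 40,
                              seed = 1) {
  if (!model %in% c(1, 2)) abort("model must be 1 or 2")
  if (is.null(t_dup)) t_dup <- if (model == 2) 0.3 else 1.8
  if (any(c(t_family, t_dup, t_species) <= 0)) abort("all depths must be > 0")
  if (model == 1 && t_dup <= t_family) {
    abort("model 1 requires t_dup > t_family (duplication precedes family divergence)")
  }
  if (model == 2 && t_dup >= t_family) {
    abort("model 2 requires t_dup < t_family (families diverge before duplicating)")
  }
  if (t_species >= min(t_dup, t_family)) {
    abort("t_species must be smaller than both t_dup and t_family")
  }
  if (length(domain_spacers) != 2 || any(domain_spacers < 5 | domain_spacers > 9)) {
    abort("domain_spacers must be two integers in [5, 9]")
  }
  if (n_species < 1 || length(families) < 1) abort("need >= 1 species and family")
  structure(
    list(
      n_species = as.integer(n_species), families = families,
      model = as.integer(model), t_family = t_family, t_dup = t_dup,
      t_species = t_species, domain_spacers = as.integer(domain_spacers),
      linker_length = as.integer(linker_length), seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

species_names <- function(n) sprintf("sp%02d", seq_len(n))

# Ultrametric Yule species tree of given height; single-species case is a
# bare tip.  Returns a Newick fragment (no trailing semicolon) via a
# label-template function.
species_subtree_newick <- function(n_species, height, label_fun) {
  sp <- species_names(n_species)
  if (n_species == 1) {
    return(function(fam, pos) paste0(label_fun(sp[1], fam, pos)))
  }
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth * height
  function(fam, pos) {
    cp <- tr
    cp$tip.label <- vapply(sp[as.integer(sub("^t", "", tr$tip.label))],
                           label_fun, character(1), fam = fam, pos = pos)
    sub(";$", "", ape::write.tree(cp, digits = 12))
  }
}

#' Build the generating domain tree for a simulation
#'
#' Model 1: the root splits into the two tandem-position lineages at depth
#' `t_dup`, each lineage splits into the families at `t_family`, and each
#' family into a shared Yule species tree of height `t_species`. Model 2:
#' the root splits into families at `t_family`, each family duplicates at
#' `t_dup`, then follows the species tree. Leaf labels are
#' `protein|species|family|position`; the leaf count is
#' `n_species * n_families * 2`.
#'
#' @param config A `simulation_config`.
#' @return A `phylo` tree.
#' @export
build_domain_tree <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(config$seed, build_domain_tree_impl(config))
}

build_domain_tree_impl <- function(config) {
  label_fun <- function(species, fam, pos) {
    paste(paste0(species, "_", fam), species, fam, pos, sep = "|")
  }
  sub_nwk <- species_subtree_newick(config$n_species, config$t_species, label_fun)
  dup_stem <- config$t_dup - config$t_species
  fam_stem_m2 <- config$t_family - config$t_dup
  if (config$model == 2) {
    fams <- vapply(config$families, function(f) {
      pair <- paste0("(", sub_nwk(f, 1), ":", dup_stem, ",",
                     sub_nwk(f, 2), ":", dup_stem, ")")
      paste0(pair, ":", fam_stem_m2)
    }, character(1))
    nwk <- paste0("(", paste(fams, collapse = ","), ");")
  } else {
    pos_stem <- config$t_dup - config$t_family
    fam_stem <- config$t_family - config$t_species
    lineage <- function(pos) {
      fams <- vapply(config$families, function(f) {
        paste0(sub_nwk(f, pos), ":", fam_stem)
      }, character(1))
      paste0("(", paste(fams, collapse = ","), "):", pos_stem)
    }
    nwk <- paste0("(", lineage(1), ",", lineage(2), ");")
  }
  read_newick(nwk)
}

#' Evolve a sequence along a branch
#'
#' Each unconstrained site is resampled from the row of `P(t) = exp(Qt)`
#' corresponding to its current residue; constrained sites (the conserved
#' motif positions) are copied verbatim. No indels: length is preserved.
#' Uses the current RNG state.
#'
#' @param sequence Parent amino-acid string.
#' @param t Branch length in substitutions per site (>= 0).
#' @param model An `aa_model`.
#' @param constrained Integer positions held invariant.
#' @return The child sequence.
#' @export
evolve_sequence <- function(sequence, t, model = jtt_model(), constrained = integer(0)) {
  stopifnot(t >= 0)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (length(constrained) > 0 && (min(constrained) < 1 || max(constrained) > n)) {
    abort("constrained position out of range")
  }
  if (t == 0) return(sequence)
  free <- setdiff(seq_len(n), constrained)
  if (length(free) == 0) return(sequence)
  idx <- match(chars, model$alphabet)
  if (anyNA(idx[free])) {
    free <- free[!is.na(idx[free])]    # unknown residues (X) are copied
  }
  P <- probability_matrix(model, t)
  new_idx <- idx
  for (a in unique(idx[free])) {
    sites <- free[idx[free] == a]
    new_idx[sites] <- sample.int(20L, length(sites), replace = TRUE, prob = P[a, ])
  }
  chars[free] <- model$alphabet[new_idx[free]]
  paste(chars, collapse = "")
}

# Root magnetochrome domain satisfying the delineation rule:
# psi1 - spacer1 - P H - spacer2 - C x x C H - psi2.  When spacer1 is wider
# than the minimal 5 residues, the spacer positions that sit 5-8 residues
# upstream of the P are held non-hydrophobic (and invariant) so that the
# nearest-candidate boundary search keeps identifying the implanted psi1 in
# every descendant.
root_domain <- function(spacers) {
  s1 <- spacers[1]; s2 <- spacers[2]
  filler <- setdiff(AA_MODEL_ORDER, c("C", "P", "H"))
  nonhydro <- setdiff(filler, AA_HYDROPHOBIC)
  draw <- function(k) sample(filler, k, replace = TRUE)
  spacer1 <- draw(s1)
  guard <- integer(0)
  if (s1 > 5) {
    guard <- 2:(s1 - 4) # residue indices with 5..(s1-1) residues before P
    spacer1[guard - 1L] <- sample(nonhydro, length(guard), replace = TRUE)
  }
  chars <- c(
    sample(AA_HYDROPHOBIC, 1), spacer1, "P", "H", draw(s2),
    "C", draw(2), "C", "H", sample(AA_HYDROPHOBIC, 1)
  )
  constrained <- c(1L, guard, s1 + 2L, s1 + 3L, s1 + s2 + 4L, s1 + s2 + 7L,
                   s1 + s2 + 8L, s1 + s2 + 9L)
  list(sequence = paste(chars, collapse = ""), constrained = constrained)
}

has_cxxch <- function(x) grepl("C[^X]{2}CH", x)

random_linker <- function(k) {
  if (k == 0) return("")
  repeat {
    link <- paste(sample(AA_MODEL_ORDER, k, replace = TRUE), collapse = "")
    if (!has_cxxch(link)) return(link)
  }
}

#' Simulate a ground-truth magnetochrome dataset
#'
#' Constructs a root domain satisfying the delineation rule, evolves it
#' down the generating domain tree under the JTT model with the motif
#' positions (psi1, P, H, C, C, H, psi2) held invariant, and assembles the
#' two domain copies of every species-family pair into one protein record
#' with random linkers (rejection-sampled so no spurious `CXXCH` or
#' minimal-unit match arises). Deterministic given `config$seed`.
#'
#' @param config A `simulation_config`.
#' @return Object of class `mcr_simulation`: list with `records` (protein
#'   tibble), `truth` (tibble `protein_id`, `position_index`, `start`,
#'   `end`, 1-based inclusive), `tree` (the generating domain tree),
#'   `model` and `config`.
#' @export
simulate_mcr_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  model <- jtt_model()
  with_local_seed(config$seed, simulate_impl(config, model))
}

simulate_impl <- function(config, model) {
  tree <- build_domain_tree_impl(config)
  root <- root_domain(config$domain_spacers)
  dom_len <- nchar(root$sequence)

  # evolve down the tree (preorder over edges)
  tree_po <- ape::reorder.phylo(tree, "postorder")
  edge <- tree_po$edge[rev(seq_len(nrow(tree_po$edge))), , drop = FALSE]
  elen <- tree_po$edge.length[rev(seq_len(nrow(tree_po$edge)))]
  n_tip <- length(tree$tip.label)
  seqs <- character(n_tip + tree$Nnode)
  seqs[edge[1, 1]] <- root$sequence
  for (k in seq_len(nrow(edge))) {
    seqs[edge[k, 2]] <- evolve_sequence(seqs[edge[k, 1]], elen[k], model,
                                        constrained = root$constrained)
  }
  leaf_parent <- edge[match(seq_len(n_tip), edge[, 2]), 1]
  leaf_len <- elen[match(seq_len(n_tip), edge[, 2])]

  meta <- parse_leaf_labels(tree)
  meta$tip <- seq_len(n_tip)
  flank <- 10L
  minimal <- mcr_minimal_pattern()
  records <- list(); truths <- list()
  proteins <- distinct(meta, .data$protein_id, .data$species, .data$family)
  for (r in seq_len(nrow(proteins))) {
    pid <- proteins$protein_id[r]
    tips <- meta[meta$protein_id == pid, ]
    tips <- tips[order(as.integer(tips$position)), ]
    starts <- flank + 1L + (seq_len(nrow(tips)) - 1L) * (dom_len + config$linker_length)
    truth <- tibble(
      protein_id = pid, position_index = seq_len(nrow(tips)),
      start = starts, end = starts + dom_len - 1L
    )
    ok <- FALSE
    for (attempt in 1:60) {
      doms <- seqs[tips$tip]
      pieces <- c(random_linker(flank))
      for (d in seq_along(doms)) {
        pieces <- c(pieces, doms[d],
                    if (d < length(doms)) random_linker(config$linker_length))
      }
      pieces <- c(pieces, random_linker(flank))
      protein <- paste(pieces, collapse = "")
      hits <- harvest_domains(
        tibble(id = pid, species = tips$species[1], family = tips$family[1],
               sequence = protein),
        pattern = minimal
      )
      if (nrow(hits) == nrow(truth) && !any(hits$partial) &&
          all(hits$start == truth$start) && all(hits$end == truth$end)) {
        ok <- TRUE
        break
      }
      if (attempt %% 10 == 0) {
        # rare domain-internal accident (e.g. a second CXXCH arose in a
        # spacer): redraw the affected leaves along their terminal branch
        for (d in seq_len(nrow(tips))) {
          tip <- tips$tip[d]
          seqs[tip] <- evolve_sequence(seqs[leaf_parent[tip]], leaf_len[tip],
                                       model, constrained = root$constrained)
        }
      }
    }
    if (!ok) abort(paste0("could not assemble a clean protein for ", pid))
    records[[r]] <- tibble(id = pid, species = tips$species[1],
                           family = tips$family[1], sequence = protein)
    truths[[r]] <- truth
  }
  structure(
    list(records = bind_rows(records), truth = bind_rows(truths),
         tree = tree, model = config$model, config = config),
    class = "mcr_simulation"
  )
}

#' @export
print.mcr_simulation <- function(x, ...) {
  cat("<mcr_simulation> model ", x$model, ": ", nrow(x$records),
      " proteins, ", nrow(x$truth), " implanted domains\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the protein FASTA, a truth TSV (`protein_id`, `position_index`,
#' `start_1based`, `end_1based`) and the generating domain tree in Newick.
#'
#' @param sim An `mcr_simulation`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_protein_fasta(sim$records, file.path(dir, "proteins.fasta"))
  truth <- sim$truth
  names(truth)[names(truth) == "start"] <- "start_1based"
  names(truth)[names(truth) == "end"] <- "end_1based"
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_newick(sim$tree, file.path(dir, "lineage_tree.nwk"))
  invisible(dir)
}
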