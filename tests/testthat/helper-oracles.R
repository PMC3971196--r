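# Independent oracles used across the suite.  These deliberately do not
# share code with the package implementations they check.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# ---- brute-force global affine alignment score ---------------------------
# Enumerates every monotone alignment path, charging gap_open + gap_extend
# when a gap run starts (or restarts after a different move) and gap_extend
# for continuations.  Exponential; fine for lengths <= 7.
brute_force_align_score <- function(a, b, sub, go, ge) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  rec <- function(i, j, prev) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, sub[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(av)) {
      cost <- if (prev == "X") ge else go + ge
      best <- max(best, cost + rec(i + 1, j, "X"))
    }
    if (j <= length(bv)) {
      cost <- if (prev == "Y") ge else go + ge
      best <- max(best, cost + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "M")
}

# ---- regex feasibility oracle for the pattern scanner --------------------
# Translates a compiled pattern to an anchored regular expression and
# re-derives the scanner's contract (shortest feasible match at each start,
# non-overlapping, left to right) from substring feasibility tests alone.
pattern_to_regex <- function(pattern) {
  parts <- vapply(seq_len(nrow(pattern$elements)), function(e) {
    el <- pattern$elements[e, ]
    cls <- paste0("[", el$class, "]")
    if (el$min == 1 && el$max == 1) cls
    else paste0(cls, "{", el$min, ",", el$max, "}")
  }, character(1))
  paste0(parts, collapse = "")
}

oracle_scan <- function(sequence, pattern) {
  rx <- paste0("^", pattern_to_regex(pattern), "$")
  n <- nchar(sequence)
  out <- NULL
  s <- 1
  while (s + pattern$min_total - 1 <= n) {
    hit_len <- NA
    for (len in pattern$min_total:min(pattern$max_total, n - s + 1)) {
      if (grepl(rx, substr(sequence, s, s + len - 1), perl = TRUE)) { hit_len <- len; break }
    }
    if (is.na(hit_len)) {
      s <- s + 1
    } else {
      out <- rbind(out, c(s, s + hit_len - 1))
      s <- s + hit_len
    }
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# draw one concrete string matching the pattern (used to implant motifs)
sample_pattern_instance <- function(pattern) {
  paste(vapply(seq_len(nrow(pattern$elements)), function(e) {
    el <- pattern$elements[e, ]
    k <- sample(el$min:el$max, 1)
    if (k == 0) return("")
    paste(sample(strsplit(el$class, "")[[1]], k, replace = TRUE), collapse = "")
  }, character(1)), collapse = "")
}

# ---- exhaustive parsimony oracle -----------------------------------------
# Minimum number of changes over all assignments of states to internal
# nodes; exact for any tree small enough to enumerate.
exhaustive_parsimony <- function(tree, states) {
  states <- states[tree$tip.label]
  lv <- unique(unname(states))
  n_tip <- length(tree$tip.label)
  internal <- sort(unique(tree$edge[, 1]))
  combos <- expand.grid(rep(list(lv), length(internal)), stringsAsFactors = FALSE)
  node_state <- function(combo, node) {
    if (node <= n_tip) states[[node]] else combo[[match(node, internal)]]
  }
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    combo <- combos[r, , drop = FALSE]
    changes <- sum(vapply(seq_len(nrow(tree$edge)), function(e) {
      node_state(combo, tree$edge[e, 1]) != node_state(combo, tree$edge[e, 2])
    }, logical(1)))
    if (changes < best) best <- changes
  }
  best
}

# ---- random additive distance matrix from a random tree ------------------
random_additive_case <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# simulate one pair of sequences at divergence t under the packaged model,
# sampling sites independently (test-side code, no reuse of evolve_sequence)
simulate_model_pair <- function(model, t, n_sites) {
  P <- probability_matrix(model, t)
  root <- sample.int(20, n_sites, replace = TRUE, prob = model$pi)
  child <- vapply(root, function(a) sample.int(20, 1, prob = P[a, ]), integer(1))
  matrix(c(root, child), nrow = 2, byrow = TRUE)
}
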