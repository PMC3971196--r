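test_that("parsimony lengths match hand cases and phangorn", {
  tr <- read_newick("((A,B),(C,D));")
  expect_equal(fitch_length(tr, c(A = "1", B = "1", C = "2", D = "2")), 1)
  expect_equal(fitch_length(tr, c(A = "1", B = "2", C = "1", D = "2")), 2)
  expect_equal(fitch_length(tr, c(A = "1", B = "1", C = "1", D = "1")), 0)
  expect_error(fitch_length(tr, c(A = "1", B = "1", C = "2")), "leaf without a state")

  set.seed(71)
  for (r in 1:10) {
    n <- sample(4:10, 1)
    phy <- ape::rtree(n)
    states <- setNames(sample(c("x", "y", "z"), n, replace = TRUE), phy$tip.label)
    pd <- phangorn::phyDat(matrix(states[phy$tip.label], ncol = 1,
                                  dimnames = list(phy$tip.label, NULL)),
                           type = "USER", levels = c("x", "y", "z"))
    expect_equal(fitch_length(phy, states),
                 as.integer(phangorn::parsimony(phy, pd)))
  }
})

test_that("parsimony length equals exhaustive enumeration on random trees", {
  set.seed(72)
  for (r in 1:40) {
    n <- sample(4:8, 1)
    phy <- ape::rtree(n)
    states <- setNames(sample(c("a", "b", "c")[seq_len(sample(2:3, 1))],
                              n, replace = TRUE), phy$tip.label)
    expect_equal(fitch_length(phy, states), exhaustive_parsimony(phy, states),
                 info = paste("case", r))
  }
})

test_that("parsimony statistics ignore rooting and leaf order", {
  set.seed(73)
  phy <- ape::rtree(8)
  states <- setNames(rep(c("p", "q"), 4), phy$tip.label)
  base_l <- fitch_length(phy, states)
  base_ri <- retention_index(phy, states)
  for (tip in phy$tip.label[1:4]) {
    rr <- ape::root(phy, outgroup = tip, resolve.root = TRUE)
    expect_equal(fitch_length(rr, states), base_l)
    expect_equal(as.numeric(retention_index(rr, states)), as.numeric(base_ri))
  }
  expect_equal(fitch_length(phy, states[sample(names(states))]), base_l)
})

test_that("retention index evaluates its defining formula", {
  clustered <- read_newick("((A,B),(C,D));")
  s <- c(A = "1", B = "1", C = "2", D = "2")
  expect_equal(as.numeric(retention_index(clustered, s)), 1)  # L=1,Lmin=1,Lmax=2
  inter <- read_newick("((A,C),(B,D));")
  expect_equal(as.numeric(retention_index(inter, s)), 0)      # L=2
  expect_warning(ri <- retention_index(clustered, c(A = "1", B = "1", C = "1", D = "1")),
                 "uninformative")
  expect_equal(as.numeric(ri), 1)
  expect_true(attr(ri, "uninformative"))
})

test_that("permutation p-values honour the add-one formula and the seed", {
  set.seed(74)
  phy <- read_newick(paste0(
    "((((a1,a2),(a3,a4)),(a5,a6)),(((b1,b2),(b3,b4)),(b5,b6)));"))
  # perfectly clustered character: one change on the central split
  clust <- setNames(c(rep("1", 6), rep("2", 6)), phy$tip.label)
  expect_equal(fitch_length(phy, clust), 1)
  p <- permutation_pvalue(phy, clust, n_perm = 999, seed = 5)
  expect_lte(p, 0.01)
  expect_equal(p, permutation_pvalue(phy, clust, n_perm = 999, seed = 5))

  const <- setNames(rep("1", 12), phy$tip.label)
  expect_equal(permutation_pvalue(phy, const, n_perm = 99, seed = 1), 1)

  # lower bound 1/(n_perm + 1): identical permutation cannot push p below it
  expect_gte(permutation_pvalue(phy, clust, n_perm = 1, seed = 1), 0.5)
})

make_labelled_tree <- function(newick) {
  read_newick(newick)
}

test_that("family-clustered trees yield model 2 and position-clustered model 1", {
  fams <- c("MamE", "MamP", "MamT", "MamX")
  # per-family clades, each containing both positions (two species)
  clades <- vapply(fams, function(f) {
    tips <- vapply(c(1, 2), function(p) {
      paste0("(", paste0("s1_", f, "|s1|", f, "|", p), ":0.1,",
             paste0("s2_", f, "|s2|", f, "|", p), ":0.1):0.2")
    }, character(1))
    paste0("(", tips[1], ",", tips[2], "):0.5")
  }, character(1))
  tr2 <- make_labelled_tree(paste0("(", paste(clades, collapse = ","), ");"))
  v2 <- classify_duplication_order(tr2, n_perm = 199, seed = 3)
  expect_equal(v2$verdict, "model2")
  expect_equal(v2$RI_family, 1)
  expect_lt(v2$p_family, 0.05)

  # mirror: two position clades, families interleaved inside each
  lineage <- function(p) {
    tips <- unlist(lapply(c("s1", "s2"), function(sp) {
      paste0(sp, "_", fams, "|", sp, "|", fams, "|", p)
    }))
    tips <- tips[order(rep(seq_along(fams), 2))]  # E,E,P,P,T,T,X,X
    tips <- tips[c(1, 3, 5, 7, 2, 4, 6, 8)]       # interleave families
    paste0("(", paste0(tips, ":0.1", collapse = ","), "):0.5")
  }
  tr1 <- make_labelled_tree(paste0("(", lineage(1), ",", lineage(2), ");"))
  v1 <- classify_duplication_order(tr1, n_perm = 199, seed = 3)
  expect_equal(v1$verdict, "model1")
  expect_equal(v1$RI_position, 1)
})

test_that("shuffled star-like trees come out ambiguous", {
  set.seed(75)
  fams <- c("MamE", "MamP", "MamT", "MamX")
  labels <- as.vector(outer(c("s1", "s2", "s3"), fams, function(sp, f) {
    paste0(sp, "_", f, "|", sp, "|", f, "|")
  }))
  labels <- paste0(rep(labels, 2), rep(c(1, 2), each = length(labels)))
  labels <- sample(labels)
  star <- make_labelled_tree(paste0("(", paste0(labels, ":1", collapse = ","), ");"))
  v <- classify_duplication_order(star, n_perm = 99, seed = 7)
  expect_equal(v$verdict, "ambiguous")
})

test_that("out-groups are excluded and degenerate characters rejected", {
  tr <- make_labelled_tree(paste0(
    "((a_MamE|a|MamE|1:1,a_MamE2|a|MamE|2:1):1,",
    "(a_MamP|a|MamP|1:1,a_MamP2|a|MamP|2:1):1,",
    "(nifB|a|MamTENifB|1:1,odd|a|unknown|2:1):1);"))
  v <- classify_duplication_order(tr, n_perm = 49, seed = 1)
  expect_equal(v$n_outgroup, 2)
  expect_equal(v$n_leaves, 4)

  one_fam <- make_labelled_tree(
    "((a|a|MamE|1:1,b|b|MamE|1:1):1,(c|c|MamE|2:1,d|d|MamE|2:1):1);")
  expect_error(classify_duplication_order(one_fam), "uninformative")
  only_pos1 <- make_labelled_tree(
    "((a|a|MamE|1:1,b|b|MamP|1:1):1,(c|c|MamT|1:1,d|d|MamX|1:1):1);")
  expect_error(classify_duplication_order(only_pos1), "uninformative")
})

test_that("positions beyond the tandem collapse to one extra state", {
  tr <- make_labelled_tree(paste0(
    "((a|a|MamE|1:1,b|a|MamE|2:1):1,(c|a|MamP|3:1,d|a|MamP|4:1):1,",
    "(e|a|MamT|1:1,f|a|MamT|2:1):1);"))
  v <- classify_duplication_order(tr, n_perm = 49, seed = 1)
  # states 1, 2 and "extra": positions 3 and 4 merge
  expect_equal(v$L_position, fitch_length(tr, setNames(
    c("1", "2", "extra", "extra", "1", "2"), tr$tip.label)))
})

test_that("verdicts tidy and glance into the documented shapes", {
  tr <- make_labelled_tree(paste0(
    "((a|a|MamE|1:1,b|a|MamE|2:1):1,(c|a|MamP|1:1,d|a|MamP|2:1):1);"))
  v <- classify_duplication_order(tr, n_perm = 49, seed = 2)
  td <- tidy(v)
  expect_equal(td$character, c("family", "position"))
  expect_true(all(c("fitch_length", "retention_index", "p_value") %in% names(td)))
  gl <- glance(v)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$ri_difference, v$RI_family - v$RI_position)

  js <- withr::local_tempfile(fileext = ".json")
  write_verdict_json(v, js, tree_file = "tree.nwk")
  back <- jsonlite::read_json(js)
  expect_equal(back$verdict, v$verdict)
  expect_equal(back$tree_file, "tree.nwk")
})
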