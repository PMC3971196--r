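model <- jtt_model()

test_that("the substitution model is a unit-rate reversible generator", {
  expect_equal(rowSums(model$Q), rep(0, 20), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(model$pi), 1)
  expect_equal(-sum(model$pi * diag(model$Q)), 1)
  flux <- model$pi * model$Q
  expect_equal(flux, t(flux), tolerance = 1e-12)  # detailed balance
})

test_that("transition matrices match an independent matrix-exponential oracle", {
  # values computed with scipy.linalg.expm on the same published rates
  P <- probability_matrix(model, 0.1)
  expect_equal(P["A", "A"], 0.885228971332, tolerance = 1e-9)
  expect_equal(P["A", "R"], 0.003223116189, tolerance = 1e-9)
  P <- probability_matrix(model, 0.7)
  expect_equal(P["C", "H"], 0.012648279227, tolerance = 1e-9)
  expect_equal(P["W", "W"], 0.358074871138, tolerance = 1e-9)
  P <- probability_matrix(model, 2.0)
  expect_equal(P["A", "A"], 0.179074828310, tolerance = 1e-9)
  expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(probability_matrix(model, 0), diag(20), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("identical rows get distance zero and saturated pairs the cap", {
  aln <- new_mcr_alignment(c(a = "ARNDC", b = "ARNDC", c = "VWYFM"))
  d <- jtt_distance(aln, model)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 5)  # every column different at 5 sites
  expect_equal(d, t(d))
  expect_error(jtt_distance(new_mcr_alignment(c(a = "A-C", b = "AGC")), model),
               "gaps")
})

test_that("the distance estimator is consistent at moderate divergence", {
  set.seed(61)
  ok <- 0
  for (r in 1:100) {
    pair <- simulate_model_pair(model, 0.1, 10000)
    seqs <- apply(pair, 1, function(i) paste(model$alphabet[i], collapse = ""))
    aln <- new_mcr_alignment(c(a = seqs[1], b = seqs[2]))
    est <- jtt_distance(aln, model)["a", "b"]
    if (abs(est - 0.1) <= 0.02) ok <- ok + 1
  }
  expect_gte(ok, 95)
})

test_that("estimator bias shrinks as sites grow", {
  set.seed(62)
  bias <- vapply(c(100, 1000, 10000), function(n_sites) {
    ests <- vapply(1:20, function(r) {
      pair <- simulate_model_pair(model, 0.3, n_sites)
      seqs <- apply(pair, 1, function(i) paste(model$alphabet[i], collapse = ""))
      jtt_distance(new_mcr_alignment(c(a = seqs[1], b = seqs[2])), model)["a", "b"]
    }, numeric(1))
    abs(mean(ests) - 0.3)
  }, numeric(1))
  expect_lt(bias[3], bias[1])
  expect_lt(bias[3], 0.01)
})

test_that("neighbor joining reproduces a known additive tree exactly", {
  d <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  expect_equal(ape::Ntip(tr), 4)
  # AB|CD split with the generating branch lengths
  expect_equal(unname(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]),
               unname(d))
  bt <- ape::bitsplits(tr)
  expect_equal(phangorn::RF.dist(tr, read_newick("((A:1,B:2):1,(C:3,D:1):0);")), 0)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("three leaves solve the closed three-point formula", {
  d <- matrix(c(0, 2, 3,
                2, 0, 5,
                3, 5, 0), 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  pl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(pl[["a"]], (2 + 3 - 5) / 2)
  expect_equal(pl[["b"]], (2 + 5 - 3) / 2)
  expect_equal(pl[["c"]], (3 + 5 - 2) / 2)
})

test_that("neighbor joining recovers random additive topologies", {
  set.seed(63)
  for (r in 1:30) {
    case <- random_additive_case(sample(4:8, 1))
    tr <- neighbor_joining(case$d)
    expect_equal(phangorn::RF.dist(tr, ape::unroot(case$tree)), 0)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("clamped trees preserve total path lengths where possible", {
  # a slightly non-additive matrix that yields a negative NJ branch
  set.seed(64)
  case <- random_additive_case(6)
  d <- case$d + matrix(stats::runif(36, 0, 0.02), 6, 6)
  d <- (d + t(d)) / 2; diag(d) <- 0
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("zero-branch and two-leaf likelihoods match closed forms", {
  aln <- new_mcr_alignment(c(a = "AAAA", b = "AAAA", c = "AAAA"))
  tr <- read_newick("(a:0,b:0,c:0);")
  sc <- tree_log_likelihood(tr, aln, model)
  expect_equal(sc$log_likelihood, 4 * log(model$pi[["A"]]))
  expect_equal(sc$n_sites, 4)
  expect_s3_class(sc, "tree_score")
  expect_lte(sc$log_likelihood, 0)

  # frozen scipy value for a fixed pair at t1 + t2 = 0.55
  pa <- "MKAVCLIPHGWCAACHRDEY"
  pb <- "MKSVCLVPHGYCSACHKDEF"
  two <- tree_log_likelihood(read_newick("(a:0.25,b:0.3);"),
                             new_mcr_alignment(c(a = pa, b = pb)), model)
  expect_equal(two$log_likelihood, -95.06274644349627, tolerance = 1e-9)
})

test_that("two-leaf likelihood reduces to the pairwise formula", {
  set.seed(65)
  for (r in 1:5) {
    t1 <- runif(1, 0, 1); t2 <- runif(1, 0, 1)
    pair <- simulate_model_pair(model, 0.4, 50)
    seqs <- apply(pair, 1, function(i) paste(model$alphabet[i], collapse = ""))
    ll <- tree_log_likelihood(
      read_newick(sprintf("(a:%f,b:%f);", t1, t2)),
      new_mcr_alignment(c(a = seqs[1], b = seqs[2])), model)$log_likelihood
    P <- probability_matrix(model, t1 + t2)
    want <- sum(log(model$pi[pair[1, ]] * P[cbind(pair[1, ], pair[2, ])]))
    expect_equal(ll, want, tolerance = 1e-6)
  }
})

test_that("the likelihood is invariant to rooting and leaf order", {
  set.seed(66)
  labs <- paste0("t", 1:6)
  seqs <- setNames(vapply(1:6, function(i) random_protein(40), character(1)), labs)
  aln <- new_mcr_alignment(seqs)
  tr <- ape::rtree(6, tip.label = labs)
  base <- tree_log_likelihood(tr, aln, model)$log_likelihood
  for (tip in labs[1:4]) {
    rerooted <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(tree_log_likelihood(rerooted, aln, model)$log_likelihood, base)
  }
  shuffled <- new_mcr_alignment(seqs[c(3, 1, 6, 2, 5, 4)])
  expect_equal(tree_log_likelihood(tr, shuffled, model)$log_likelihood, base)
  expect_error(tree_log_likelihood(tr, new_mcr_alignment(seqs[1:5]), model),
               "without alignment row")
})

test_that("newick io round trips topology, labels and branch lengths", {
  tr <- read_newick("(A:1,B:2):0;")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(sort(tr$edge.length), c(1, 2))

  nolen <- read_newick("((A,B),(C,D));")
  expect_equal(nolen$edge.length, rep(0, nrow(nolen$edge)))

  set.seed(67)
  for (n in c(4, 10, 20)) {
    tr <- ape::rtree(n)
    tr$edge.length <- round(stats::runif(nrow(tr$edge), 0.001, 2), 6)
    txt <- write_newick(tr)
    back <- read_newick(txt)
    expect_equal(write_newick(back), txt)   # canonical round trip
    expect_equal(phangorn::RF.dist(back, tr), 0)
    expect_equal(sort(back$edge.length), sort(tr$edge.length))
  }
  expect_error(read_newick("((A,B);"), "parse error")
  expect_error(read_newick("(A:1,A:2);"), "duplicate leaf label")
})

test_that("distance matrices export as labelled TSV", {
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_distance_tsv(d, tsv)
  back <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(back$label, c("x", "y"))
  expect_equal(back$x, c(0, 1))
})
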