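test_that("nucleotide distances match the JC formula and flag saturation", {
  a <- msa(c(x = "ACGTACGTACGTACGTACGT", y = "ACGTACGTACGTACGTACGT"))
  expect_equal(nucleotide_distance(a, "JC")["x", "y"], 0)

  # 2 of 20 sites differ: d = -3/4 log(1 - 4p/3), p = 0.1
  b <- msa(c(x = "ACGTACGTACGTACGTACGT", y = "TCGTACGTACGTACGTACGA"))
  expect_equal(nucleotide_distance(b, "JC")["x", "y"],
               -0.75 * log(1 - 4 * 0.1 / 3), tolerance = 1e-9)

  # p >= 3/4 saturates
  sat <- msa(c(x = "AAAAAAAAAAAAAAAAAAAA", y = "CCCCCCCCCCCCCCCCGGGG"))
  dm <- nucleotide_distance(sat, "JC")
  expect_true(is.infinite(dm["x", "y"]))
  expect_error(nj_tree(rbind(cbind(dm, z = 1), z = 1)), "non-finite")
})

test_that("NJ recovers additive matrices and ignores taxon order", {
  for (s in 1:10) {
    ref <- random_additive_matrix(sample(5:12, 1), seed = 100 + s)
    tr <- nj_tree(ref$dist)
    expect_equal(phangorn::RF.dist(ape::unroot(ref$tree), tr), 0)
    perm <- sample(rownames(ref$dist))
    tr2 <- nj_tree(ref$dist[perm, perm])
    expect_identical(splits_of(tr), splits_of(tr2))
  }
  # 3 taxa resolve as the unique star
  d3 <- matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(length(nj_tree(d3)$tip.label), 3)
})

test_that("pruning likelihood equals state enumeration on small trees", {
  set.seed(77)
  for (rep in 1:5) {
    ntax <- sample(3:4, 1)
    tr <- ape::rtree(ntax)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.6)
    exch <- c(stats::runif(5, 0.5, 3), 1)
    x <- stats::rgamma(4, 5)
    bf <- x / sum(x)
    shape <- stats::runif(1, 0.3, 2)
    params <- gtr_gamma_params(exch = exch, bf = bf, shape = shape)
    aln <- evolve_sequences(tr, params, 12, seed = 500 + rep)
    got <- log_likelihood(tr, aln, params)
    want <- oracle_loglik(tr, unclass(aln), exch, bf, shape)
    expect_equal(got$total, want$total, tolerance = 1e-8)
    expect_equal(got$site, want$site, tolerance = 1e-8)
  }
})

test_that("site vector sums to the total and survives re-rooting", {
  set.seed(42)
  tr <- ape::rtree(6)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
  params <- gtr_gamma_params(exch = c(1, 2, 1, 1, 2, 1),
                             bf = c(0.3, 0.2, 0.2, 0.3), shape = 0.7)
  aln <- evolve_sequences(tr, params, 300, seed = 8)
  ll <- log_likelihood(tr, aln, params)
  expect_equal(sum(ll$site), ll$total, tolerance = 1e-6)
  # pulley principle: unrooted likelihood is invariant to root placement
  rr <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[3],
                  resolve.root = TRUE)
  ll2 <- log_likelihood(rr, aln, params)
  expect_equal(ll2$total, ll$total, tolerance = 1e-4)
  expect_error(log_likelihood(ape::rtree(4), aln, params), "mismatch")
})

test_that("optimization is a fixed point and increases the likelihood", {
  set.seed(13)
  tr <- ape::rtree(6)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 0.4)
  params <- gtr_gamma_params(shape = 0.8)
  aln <- evolve_sequences(tr, params, 500, seed = 14)
  start <- tr
  start$edge.length <- rep(0.25, nrow(tr$edge))
  fit1 <- optimize_ml(start, aln, params)
  expect_gte(fit1$logLik, log_likelihood(start, aln, params)$total)
  fit2 <- optimize_ml(fit1$tree, aln, fit1$params)
  expect_lt(abs(fit2$logLik - fit1$logLik), 1e-4)
})

test_that("branch lengths and shape are recovered from simulated data", {
  tr <- simulate_species_tree(10, seed = 6)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * 0.6
  params <- gtr_gamma_params(exch = c(1, 2, 1, 1, 2, 1),
                             bf = c(0.3, 0.2, 0.2, 0.3), shape = 0.5)
  aln <- evolve_sequences(tr, params, 5000, seed = 16)
  fit <- optimize_ml(tr, aln, params, opt_shape = TRUE)
  # the optimizer may re-root, so compare patristic (path) distances
  want <- ape::cophenetic.phylo(tr)
  got <- ape::cophenetic.phylo(fit$tree)[rownames(want), colnames(want)]
  rel_err <- abs(got - want)[upper.tri(want)] /
    pmax(want[upper.tri(want)], 0.02)
  expect_lt(stats::median(rel_err), 0.15)
  expect_lt(abs(fit$params$shape - 0.5) / 0.5, 0.25)
})

test_that("monophyly is read off the unrooted tree", {
  tr <- parse_newick("((POPB_Le,(POPB_Ga,POPB_Am)),(POPA_Am,POP_Ga));")
  expect_true(is_monophyletic(tr, c("POPB_Le", "POPB_Ga", "POPB_Am")))
  expect_false(is_monophyletic(tr, c("POPB_Le", "POPA_Am")))
  expect_true(is_monophyletic(tr, "POPB_Le"))
  expect_true(is_monophyletic(tr, tr$tip.label))
  expect_error(is_monophyletic(tr, "nope"), "unknown")
})

test_that("bipartition conflicts are detected against the species tree", {
  # gene subtree (Le,(Ga,Am)) conflicts with species (Am,(Ga,Le))
  gt <- parse_newick("((Le_1,(Ga_1,Am_1)),(O1,O2));")
  st <- parse_newick("((Am,(Ga,Le)),(O1,O2));")
  map <- c(Le_1 = "Le", Ga_1 = "Ga", Am_1 = "Am", O1 = "O1", O2 = "O2")
  conf <- conflicting_bipartitions(gt, st, map)
  expect_gte(length(conf), 1)
  expect_true(any(vapply(conf, function(x) setequal(x, c("Ga", "Am")),
                         logical(1))))
  # identical trees: no conflicts
  gt2 <- parse_newick("((Am_1,(Ga_1,Le_1)),(O1,O2));")
  expect_equal(length(conflicting_bipartitions(gt2, st, map)), 0)
  expect_error(conflicting_bipartitions(gt, st, map[-1]), "unmapped")
})

test_that("constrained NNI search respects constraints and finds the truth", {
  tr <- simulate_species_tree(8, seed = 23)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * 0.5
  params <- gtr_gamma_params(shape = 1)
  aln <- evolve_sequences(tr, params, 2000, seed = 24)
  start <- nj_tree(nucleotide_distance(aln, "JC"))
  found <- nni_search(aln, start, params)
  expect_identical(splits_of(found$tree), splits_of(tr))

  # a true clade constraint is a no-op
  clade <- ape::extract.clade(tr, ape::getMRCA(tr, tr$tip.label[1:2]))
  if (length(clade$tip.label) >= 2 && length(clade$tip.label) < 7) {
    con <- nni_search(aln, start, params,
                      constraints = list(clade$tip.label))
    expect_true(is_monophyletic(con$tree, clade$tip.label))
    expect_equal(con$logLik, found$logLik, tolerance = 1e-3)
  }

  # a false clade caps the likelihood below the unconstrained optimum
  dm <- nucleotide_distance(aln, "JC")
  false_clade <- names(sort(dm[1, ]))[c(1, length(dm[1, ]))]
  # build a start satisfying the (false) constraint directly
  others <- setdiff(tr$tip.label, false_clade)
  set.seed(5)
  cstart <- ape::multi2di(parse_newick(paste0(
    "((", paste(false_clade, collapse = ","), "),(",
    paste(others, collapse = ","), "));")))
  cstart$edge.length <- rep(0.1, nrow(cstart$edge))
  cfit <- nni_search(aln, cstart, params,
                     constraints = list(false_clade))
  expect_true(is_monophyletic(cfit$tree, false_clade))
  expect_lte(cfit$logLik, found$logLik + 1e-6)
  expect_error(nni_search(aln, start, params,
                          constraints = list(false_clade)),
               "violates")
})
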