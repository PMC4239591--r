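test_that("two-species gene-tree root height has the coalescent mean tau + 1", {
  tau <- 0.8
  sp3 <- parse_newick(sprintf("((X:%f,Y:%f):1,Z:%f);", tau, tau, tau + 1))
  # use only the XY pair statistics: their coalescence must be >= tau, with
  # excess time Exp(1) once both lineages share a branch
  gts <- simulate_gene_trees(msc_model(sp3), 20000, seed = 21)
  xy_height <- vapply(gts, function(tr) {
    d <- ape::node.depth.edgelength(tr)
    h <- max(d) - d
    h[ape::mrca(tr)["X", "Y"]]
  }, numeric(1))
  expect_true(all(xy_height >= tau - 1e-9))
  # P(XY coalesce in [tau, tau+1]) = 1 - e^-1; conditional on that, height
  # mean is tau + E[Exp(1) | < 1]; easier robust check: mean of the root
  # height of the final stage. Use the 2-species reduction instead:
  sp2 <- parse_newick(sprintf("(X:%f,Y:%f);", tau, tau))
  gts2 <- simulate_gene_trees(
    structure(list(tree = sp2), class = "msc_model"), 20000, seed = 22)
  heights <- vapply(gts2, function(tr)
    max(ape::node.depth.edgelength(tr)), numeric(1))
  se <- stats::sd(heights) / sqrt(length(heights))
  expect_lt(abs(mean(heights) - (tau + 1)), 3 * se)
})

test_that("three-species triplet frequency follows 1 - (2/3) exp(-t)", {
  for (t in c(0, 0.5)) {
    sp <- parse_newick(sprintf("((A:1,B:1):%f,C:%f);", t, 1 + t))
    gts <- simulate_gene_trees(msc_model(sp), 10000, seed = 31 + round(10 * t))
    tab <- tabulate_triplets(gts)
    p_hat <- tab$counts[1, "ab|c"] / sum(tab$counts[1, ])
    p_exp <- 1 - (2 / 3) * exp(-t)
    se <- sqrt(p_exp * (1 - p_exp) / 10000)
    expect_lt(abs(p_hat - p_exp), 3 * se)
    if (t == 0) {
      # star symmetry: all three resolutions near 1/3
      for (k in 1:3)
        expect_lt(abs(tab$counts[1, k] / 10000 - 1 / 3),
                  3 * sqrt((1 / 3) * (2 / 3) / 10000))
    }
  }
})

test_that("gene trees are ultrametric and contained in the species tree", {
  sp <- random_rooted_tree(5, seed = 41)
  m <- msc_model(sp)
  gts <- simulate_gene_trees(m, 50, seed = 42)
  sp_ages <- local({
    d <- ape::node.depth.edgelength(sp)
    max(d) - d
  })
  Msp <- ape::mrca(sp)
  for (tr in gts) {
    expect_true(ape::is.rooted(tr))
    expect_true(ape::is.binary(tr))
    d <- ape::node.depth.edgelength(tr)
    expect_lt(diff(range(d[seq_along(tr$tip.label)])), 1e-9)
    # each gene coalescence is no older than allowed: the MRCA (in the
    # species tree) of the species under the gene node bounds it from below
    h <- max(d) - d
    desc <- bbca:::.descendant_tips(tr)
    ntip <- length(tr$tip.label)
    for (v in (ntip + 1L):(ntip + tr$Nnode)) {
      spp <- match(desc[[v]], sp$tip.label)
      sp_mrca <- if (length(spp) == 2L) Msp[spp[1], spp[2]]
      else ape::getMRCA(sp, spp)
      expect_gte(h[v], sp_ages[sp_mrca] - 1e-9)
    }
  }
})

test_that("simulator triplet frequencies match the closed form on all triples of a 5-taxon tree", {
  sp <- parse_newick(
    "((((a:1,b:1):0.4,c:1.4):0.3,d:1.7):0.6,e:2.3);")
  n <- 10000
  gts <- simulate_gene_trees(msc_model(sp), n, seed = 55)
  tab <- tabulate_triplets(gts)
  for (i in seq_len(nrow(tab$triples))) {
    p <- triplet_probabilities(sp, tab$triples[i, ])
    for (k in 1:3) {
      se <- sqrt(max(p[k] * (1 - p[k]), 1e-6) / n)
      expect_lt(abs(tab$counts[i, k] / n - p[k]), 3.5 * se)
    }
  }
})

test_that("rescaling to substitution units multiplies lengths by the rate", {
  tr <- random_rooted_tree(5, seed = 61)
  expect_equal(scale_to_substitutions(tr, 1)$edge.length, tr$edge.length)
  s <- scale_to_substitutions(tr, 0.05)
  expect_equal(s$edge.length, tr$edge.length * 0.05)
  expect_identical(attr(s, "units"), "substitutions")
  expect_equal(sum(scale_to_substitutions(tr, 3)$edge.length),
               3 * sum(tr$edge.length))
  expect_error(scale_to_substitutions(tr, 0), "positive")
  expect_error(scale_to_substitutions(tr, -1), "positive")
})

test_that("gtr_params validates input and scales Q to mean rate 1", {
  p <- gtr_params(rates = c(1, 2, 1, 1, 2, 1), base_freq = c(.1, .2, .3, .4))
  expect_equal(unname(rowSums(p$Q)), rep(0, 4), tolerance = 1e-12)
  expect_equal(-sum(p$base_freq * diag(p$Q)), 1, tolerance = 1e-12)
  expect_error(gtr_params(rates = rep(-1, 6)), "positive")
  expect_error(gtr_params(base_freq = c(.5, .5, .2, .2)), "summing to 1")
  expect_error(gtr_params(gamma_shape = 0), "positive")
})

test_that("zero branch lengths copy the root sequence to every leaf", {
  tr <- parse_newick("((A:0,B:0):0,C:0);")
  aln <- simulate_alignment(tr, gtr_params(), 200, seed = 71)
  expect_identical(aln["A", ], aln["B", ])
  expect_identical(aln["A", ], aln["C", ])
})

test_that("JC-limit mismatch fraction matches the closed form", {
  t <- 0.25
  tr <- parse_newick(sprintf("(X:%f,Y:0);", t))
  n <- 20000
  aln <- simulate_alignment(tr, gtr_params(), n, seed = 72)
  p_hat <- mean(aln["X", ] != aln["Y", ])
  p_exp <- 0.75 * (1 - exp(-4 * t / 3))
  expect_lt(abs(p_hat - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
})

test_that("long simulated sequences approach the stationary composition", {
  bf <- c(.1, .2, .3, .4)
  tr <- parse_newick("(X:4,Y:4);")
  aln <- simulate_alignment(tr, gtr_params(base_freq = bf), 100000,
                            seed = 73)
  comp <- table(factor(aln["X", ], levels = c("A", "C", "G", "T"))) / 1e5
  for (k in 1:4)
    expect_lt(abs(comp[k] - bf[k]), 3 * sqrt(bf[k] * (1 - bf[k]) / 1e5))
})

test_that("sequence simulator agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  p <- gtr_params(rates = c(1, 3, 1, 1, 3, 1), base_freq = c(.3, .2, .2, .3))
  t <- 0.3
  tr <- parse_newick(sprintf("(X:%f,Y:0);", t))
  n <- 50000
  mine <- simulate_alignment(tr, p, n, seed = 74)
  p_mine <- mean(mine["X", ] != mine["Y", ])
  set.seed(75)
  # phangorn uses the same exchangeability order (AC, AG, AT, CG, CT, GT)
  sq <- phangorn::simSeq(ape::read.tree(text = sprintf("(X:%f,Y:0);", t)),
                         l = n, Q = p$rates, bf = p$base_freq)
  ch <- toupper(as.character(sq))
  p_ref <- mean(ch["X", ] != ch["Y", ])
  pooled_se <- sqrt(2 * p_ref * (1 - p_ref) / n)
  expect_lt(abs(p_mine - p_ref), 4 * pooled_se)
})

test_that("alignments are deterministic given the seed", {
  tr <- random_rooted_tree(5, seed = 81)
  p <- gtr_params(gamma_shape = 0.5)
  a1 <- simulate_alignment(tr, p, 300, seed = 82)
  a2 <- simulate_alignment(tr, p, 300, seed = 82)
  expect_identical(a1, a2)
})

test_that("model conditions match their stated shapes and are seeded", {
  c1 <- make_model_condition("strongILS-like", seed = 5)
  expect_length(c1$model$tree$tip.label, 11L)
  expect_length(bipartition_set(c1$model$tree), 8L)   # n - 3 internal edges
  expect_identical(c1$sequence_length, 500L)
  expect_identical(c1$n_genes, 100L)

  c2 <- make_model_condition("laurasiatheria-like", 1500, seed = 5)
  expect_length(c2$model$tree$tip.label, 12L)
  expect_identical(c2$sequence_length, 1500L)
  expect_true(c2$outgroup %in% c2$model$tree$tip.label)
  # the outgroup hangs off the root
  root_kids <- c2$model$tree$edge[
    c2$model$tree$edge[, 1] == 13L, 2]
  expect_true(match("OUT", c2$model$tree$tip.label) %in% root_kids)

  expect_error(make_model_condition("laurasiatheria-like", 700), "500")
  expect_error(make_model_condition("nope"), "strongILS-like")

  c3 <- make_model_condition("laurasiatheria-like", 1000, seed = 9)
  c4 <- make_model_condition("laurasiatheria-like", 1000, seed = 9)
  expect_identical(write_newick(c3$model$tree), write_newick(c4$model$tree))
  expect_identical(c3$gene_params[[7]]$rates, c4$gene_params[[7]]$rates)
})

test_that("write_replicate emits a complete, reproducible dataset", {
  cond <- make_model_condition("laurasiatheria-like", 500, seed = 2,
                               n_genes = 5)
  d1 <- file.path(tempdir(), "rep1a")
  d2 <- file.path(tempdir(), "rep1b")
  write_replicate(cond, 1, d1)
  write_replicate(cond, 1, d2)
  fa <- list.files(d1, pattern = "\\.fasta$")
  expect_length(fa, 5L)
  expect_true(file.exists(file.path(d1, "true_gene_trees.tre")))
  expect_true(file.exists(file.path(d1, "true_species_tree.tre")))
  expect_true(file.exists(file.path(d1, "manifest.txt")))
  expect_length(read_tree_sample(file.path(d1, "true_gene_trees.tre")), 5L)
  # byte-identical re-run
  expect_identical(readLines(file.path(d1, fa[1])),
                   readLines(file.path(d2, fa[1])))
  aln <- read_fasta(file.path(d1, fa[1]))
  expect_identical(nrow(aln), 12L)
  expect_identical(ncol(aln), 500L)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("FASTA and relaxed PHYLIP readers round-trip alignments", {
  tr <- random_rooted_tree(4, seed = 91)
  aln <- simulate_alignment(tr, gtr_params(), 60, seed = 92)
  fa <- tempfile(fileext = ".fasta")
  write_fasta(aln, fa)
  expect_identical(unclass(read_fasta(fa)), unclass(aln))
  phy <- tempfile(fileext = ".phy")
  writeLines(c(paste(nrow(aln), ncol(aln)),
               paste(rownames(aln), apply(aln, 1, paste, collapse = ""))),
             phy)
  expect_identical(unclass(read_phylip(phy)), unclass(aln))
})

test_that("simulators reject invalid inputs", {
  expect_error(msc_model(random_unrooted_tree(5, seed = 1)), "rooted")
  sp <- random_rooted_tree(4, seed = 2)
  expect_error(simulate_gene_trees(msc_model(sp), 0), "positive")
  expect_error(simulate_alignment(sp, list(), 100), "gtr_params")
})
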