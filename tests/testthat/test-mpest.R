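test_that("triplet tabulation counts rooted resolutions", {
  tr <- parse_newick("((a:1,b:1):1,c:2);")
  tab <- tabulate_triplets(replicate(10, tr, simplify = FALSE))
  expect_equal(unname(tab$counts[1, ]), c(10, 0, 0))
  expect_identical(tab$triples[1, ], c("a", "b", "c"))

  four <- lapply(1:6, function(i) random_rooted_tree(4, seed = i))
  tab4 <- tabulate_triplets(four)
  expect_identical(nrow(tab4$triples), 4L)           # C(4,3)
  expect_true(all(rowSums(tab4$counts) == 6))

  expect_error(tabulate_triplets(list(random_unrooted_tree(5, seed = 9))),
               "rooted")
})

test_that("triplet counts are additive over any partition of the gene trees", {
  set.seed(23)
  gts <- lapply(1:30, function(i) random_rooted_tree(6))
  pooled <- tabulate_triplets(gts)
  for (sizes in list(c(10, 20), c(15, 15), c(5, 10, 15))) {
    parts <- split(gts, rep(seq_along(sizes), sizes))
    summed <- Reduce(`+`, lapply(parts,
                                 function(p) tabulate_triplets(p)$counts))
    expect_equal(summed, pooled$counts)
  }
})

test_that("polytomies leave their triples untabulated", {
  poly <- parse_newick("((a,b,c),d);")
  tab <- tabulate_triplets(list(poly))
  abc <- which(apply(tab$triples, 1, paste, collapse = "") == "abc")
  expect_equal(sum(tab$counts[abc, ]), 0)       # unresolved, skipped
  abd <- which(apply(tab$triples, 1, paste, collapse = "") == "abd")
  expect_equal(unname(tab$counts[abd, "ab|c"]), 1)
})

test_that("triplet probabilities follow the coalescent closed form", {
  mk <- function(t) parse_newick(sprintf("((a:1,b:1):%.17g,c:%.17g);",
                                         t, 1 + t))
  p0 <- triplet_probabilities(mk(0), c("a", "b", "c"))
  expect_equal(unname(as.vector(p0)), rep(1 / 3, 3))
  pl <- triplet_probabilities(mk(50), c("a", "b", "c"))
  expect_lt(abs(pl[["ab|c"]] - 1), 1e-12)
  p2 <- triplet_probabilities(mk(log(2)), c("a", "b", "c"))
  expect_equal(p2[["ab|c"]], 2 / 3)
  expect_equal(sum(p2), 1)
  expect_identical(attr(p2, "match"), "ab|c")
  expect_error(triplet_probabilities(mk(1), c("a", "b", "z")),
               "not fully present")
})

test_that("pseudo-log-likelihood matches direct per-triple arithmetic", {
  tab1 <- manual_triplet_table(matrix(c("a", "b", "c"), 1), c(10, 0, 0))
  big_t <- parse_newick("((a:1,b:1):19,c:20);")
  ll <- pseudo_log_likelihood(big_t, tab1)
  expect_lt(ll, 0)
  expect_gt(ll, -1e-6)

  tab2 <- manual_triplet_table(matrix(c("a", "b", "c"), 1), c(4, 3, 3))
  zero_t <- parse_newick("((a:1,b:1):0,c:1);")
  expect_equal(pseudo_log_likelihood(zero_t, tab2), 10 * log(1 / 3))
})

test_that("pseudo-log-likelihood equals a brute-force per-gene product", {
  # independent oracle: multiply per-gene triplet probabilities directly
  oracle <- function(sp, gts) {
    total <- 0
    triples <- t(utils::combn(sort(sp$tip.label), 3))
    for (tr in gts) {
      for (i in seq_len(nrow(triples))) {
        obs <- tabulate_triplets(list(tr))$counts
        key <- which(apply(tabulate_triplets(list(tr))$triples, 1,
                           paste, collapse = "\r") ==
                       paste(triples[i, ], collapse = "\r"))
        k <- which(obs[key, ] == 1)
        p <- triplet_probabilities(sp, triples[i, ])
        total <- total + log(p[[k]])
      }
    }
    total
  }
  for (seed in 1:3) {
    sp <- random_rooted_tree(5, seed = 200 + seed)
    gts <- simulate_gene_trees(msc_model(sp), 4, seed = 300 + seed)
    tab <- tabulate_triplets(gts)
    expect_equal(pseudo_log_likelihood(sp, tab), oracle(sp, gts),
                 tolerance = 1e-10)
  }
})

test_that("branch-length optimization recovers the closed-form MLE", {
  topo <- parse_newick("((a,b),c);")
  # f = n1/n > 1/3  =>  t-hat = -log(1.5 * (1 - f))
  est <- optimize_branch_lengths(
    topo, manual_triplet_table(matrix(c("a", "b", "c"), 1), c(80, 10, 10)))
  expect_equal(est$internal_lengths, -log(0.3), tolerance = 1e-4)

  est2 <- optimize_branch_lengths(
    topo, manual_triplet_table(matrix(c("a", "b", "c"), 1), c(34, 33, 33)))
  expect_equal(est2$internal_lengths, -log(1.5 * 0.66), tolerance = 1e-3)

  # match fraction at or below 1/3: boundary at zero
  est3 <- optimize_branch_lengths(
    topo, manual_triplet_table(matrix(c("a", "b", "c"), 1), c(20, 40, 40)))
  expect_equal(est3$internal_lengths, 0, tolerance = 1e-6)

  # terminal branches are reported as absent
  expect_true(all(is.na(est$tree$edge.length[
    est$tree$edge[, 2] <= 3])))
  expect_error(optimize_branch_lengths(parse_newick("((a,b,c),d);"),
                                       manual_triplet_table(
                                         matrix(c("a", "b", "c"), 1),
                                         c(1, 1, 1))),
               "binary")
})

test_that("perfect gene-tree concordance drives branches to the upper bound", {
  gt <- parse_newick("((((a,b),c),d),e);")
  fit <- mpest(replicate(20, gt, simplify = FALSE), n_runs = 3, seed = 5)
  expect_equal(rf_distance(fit$tree, gt)$raw, 0L)
  internal <- fit$tree$edge.length[!is.na(fit$tree$edge.length)]
  expect_true(all(internal > 19))
})

test_that("the searched species tree matches the truth on clean input", {
  sp <- parse_newick("((((a:1,b:1):0.5,c:1.5):0.5,d:2):0.5,e:2.5);")
  gts <- simulate_gene_trees(msc_model(sp), 1000, seed = 7)
  tab <- tabulate_triplets(gts)
  ex <- search_species_tree(tab, mode = "exhaustive")
  nn <- search_species_tree(tab, n_runs = 10, seed = 3, mode = "nni")
  expect_equal(rf_distance(ex$tree, sp)$raw, 0L)
  expect_equal(nn$log_pseudo_likelihood, ex$log_pseudo_likelihood,
               tolerance = 1e-8)
  expect_error(search_species_tree(tabulate_triplets(
    lapply(1:2, function(i) random_rooted_tree(9, seed = i))),
    mode = "exhaustive"), "8 species")
})

test_that("more runs can only improve the best score, deterministically", {
  set.seed(29)
  gts <- lapply(1:40, function(i) random_rooted_tree(6))
  tab <- tabulate_triplets(gts)
  one <- search_species_tree(tab, n_runs = 1, seed = 11)
  ten <- search_species_tree(tab, n_runs = 10, seed = 11)
  expect_identical(ten$run_scores[1], one$run_scores[1])
  expect_gte(ten$log_pseudo_likelihood, one$log_pseudo_likelihood)
  again <- search_species_tree(tab, n_runs = 10, seed = 11)
  expect_identical(write_newick(again$tree), write_newick(ten$tree))
})

test_that("scaling all counts preserves the optimum", {
  sp <- random_rooted_tree(5, seed = 400)
  gts <- simulate_gene_trees(msc_model(sp), 100, seed = 401)
  tab <- tabulate_triplets(gts)
  tab3 <- tab
  tab3$counts <- tab$counts * 3
  e1 <- search_species_tree(tab, mode = "exhaustive")
  e3 <- search_species_tree(tab3, mode = "exhaustive")
  expect_equal(rf_distance(e1$tree, e3$tree)$raw, 0L)
  expect_equal(e1$internal_lengths, e3$internal_lengths, tolerance = 1e-4)
  expect_equal(e3$log_pseudo_likelihood, 3 * e1$log_pseudo_likelihood,
               tolerance = 1e-6)
})

test_that("point and distribution summaries agree on degenerate distributions", {
  sp <- random_rooted_tree(5, seed = 500)
  gts <- simulate_gene_trees(msc_model(sp), 50, seed = 501)
  point <- summarize_gene_trees(gts, mode = "point", n_runs = 3, seed = 77)
  expect_true(all(rowSums(point$table$counts) == 50))
  dists <- lapply(gts, function(g) replicate(20, g, simplify = FALSE))
  dist_fit <- summarize_gene_trees(dists, mode = "distribution",
                                   n_runs = 3, seed = 77)
  expect_true(all(rowSums(dist_fit$table$counts) == 1000))
  expect_equal(rf_distance(point$tree, dist_fit$tree)$raw, 0L)
})

test_that("mpest_fit methods expose the fit", {
  gts <- simulate_gene_trees(msc_model(random_rooted_tree(5, seed = 600)),
                             100, seed = 601)
  fit <- mpest(gts, n_runs = 2, seed = 602)
  expect_s3_class(fit, "mpest_fit")
  out <- capture.output(print(fit))
  expect_true(any(grepl("pseudo-likelihood", out)))
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(as.numeric(ll), fit$log_pseudo_likelihood)
  expect_identical(attr(ll, "df"), 3L)     # 5-taxon rooted: 3 internal edges
  sum_out <- capture.output(summary(fit))
  expect_true(any(grepl("per-run scores", sum_out)))
})

test_that("gene trees with missing taxa still contribute their triples", {
  full <- parse_newick("(((a:1,b:1):1,c:2):1,d:3);")
  partial <- parse_newick("((a:1,b:1):1,c:2);")
  tab <- tabulate_triplets(list(full, partial))
  abc <- which(apply(tab$triples, 1, paste, collapse = "") == "abc")
  abd <- which(apply(tab$triples, 1, paste, collapse = "") == "abd")
  expect_equal(sum(tab$counts[abc, ]), 2)
  expect_equal(sum(tab$counts[abd, ]), 1)
})
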