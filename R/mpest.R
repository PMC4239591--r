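## Step 3 of the pipeline: pseudo-maximum-likelihood species-tree estimation
## from rooted gene trees via rooted-triplet distributions. Under the
## multispecies coalescent, for a species triple whose two most closely
## related species are separated from the third by an internal path of t
## coalescent units, the gene-tree triplet matching the species tree has
## probability 1 - (2/3) exp(-t) and each mismatching triplet has
## probability (1/3) exp(-t). The pseudo-likelihood treats the per-triple
## multinomials as independent and is maximized over rooted topologies and
## internal branch lengths.

.PROB_FLOOR <- 1e-12
.BRANCH_UPPER <- 20

## topological node depths (edges from the root), indexed by node id
.topo_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  dep <- integer(ntip + tree$Nnode)
  for (e in seq_len(nrow(edge)))
    dep[edge[e, 2L]] <- dep[edge[e, 1L]] + 1L
  dep
}

## all unordered triples over sorted taxa, as a character matrix (a < b < c)
.all_triples <- function(taxa) {
  t(utils::combn(sort(taxa), 3L))
}

#' Tabulate rooted-triplet frequencies across gene trees
#'
#' For every unordered species triple `{a, b, c}` (with `a < b < c`) and
#' every rooted gene tree containing the three taxa, increments the count of
#' the observed rooted resolution (`ab|c`, `ac|b` or `bc|a`). Triples left
#' unresolved by a polytomy are skipped; taxa missing from a gene tree
#' contribute no counts for their triples.
#'
#' @param gene_trees List of rooted `phylo` objects.
#' @return An object of class `triplet_table`: `taxa`, `triples` (character
#'   matrix, one row per triple) and `counts` (matrix with columns `ab|c`,
#'   `ac|b`, `bc|a`).
#' @export
tabulate_triplets <- function(gene_trees) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  stopifnot(length(gene_trees) >= 1L)
  for (tr in gene_trees)
    if (!ape::is.rooted(tr))
      stop("triplet tabulation requires rooted gene trees")
  taxa <- sort(unique(unlist(lapply(gene_trees, `[[`, "tip.label"))))
  if (length(taxa) < 3L) stop("need at least 3 taxa")
  triples <- .all_triples(taxa)
  counts <- matrix(0, nrow(triples), 3L,
                   dimnames = list(NULL, c("ab|c", "ac|b", "bc|a")))
  for (tr in gene_trees) {
    M <- ape::mrca(tr)
    dep <- .topo_depths(tr)
    ia <- match(triples[, 1L], tr$tip.label)
    ib <- match(triples[, 2L], tr$tip.label)
    ic <- match(triples[, 3L], tr$tip.label)
    ok <- !(is.na(ia) | is.na(ib) | is.na(ic))
    if (!any(ok)) next
    dab <- dac <- dbc <- rep(NA_integer_, nrow(triples))
    dab[ok] <- dep[M[cbind(ia[ok], ib[ok])]]
    dac[ok] <- dep[M[cbind(ia[ok], ic[ok])]]
    dbc[ok] <- dep[M[cbind(ib[ok], ic[ok])]]
    r <- integer(nrow(triples))
    r[ok & dab > dac & dab > dbc] <- 1L
    r[ok & dac > dab & dac > dbc] <- 2L
    r[ok & dbc > dab & dbc > dac] <- 3L
    hit <- which(r > 0L)
    if (length(hit))
      counts[cbind(hit, r[hit])] <- counts[cbind(hit, r[hit])] + 1
  }
  out <- list(taxa = taxa, triples = triples, counts = counts)
  class(out) <- "triplet_table"
  out
}

## per-triple geometry of a rooted species tree: the matching resolution
## index (1 = ab|c, 2 = ac|b, 3 = bc|a), the internal path length t between
## the triple's MRCA and its cherry's MRCA, and (optionally) which internal
## edges lie on that path
.species_triplet_info <- function(sp, triples, with_edges = FALSE) {
  ntip <- length(sp$tip.label)
  M <- ape::mrca(sp)
  dep <- .topo_depths(sp)
  dlen <- if (is.null(sp$edge.length)) dep else {
    el <- sp$edge.length
    el[is.na(el)] <- 0
    tmp <- sp; tmp$edge.length <- el
    ape::node.depth.edgelength(tmp)
  }
  ia <- match(triples[, 1L], sp$tip.label)
  ib <- match(triples[, 2L], sp$tip.label)
  ic <- match(triples[, 3L], sp$tip.label)
  if (anyNA(c(ia, ib, ic))) {
    bad <- which(is.na(ia) | is.na(ib) | is.na(ic))[1L]
    stop("triple {", paste(triples[bad, ], collapse = ", "),
         "} is not fully present in the species tree")
  }
  nab <- M[cbind(ia, ib)]; nac <- M[cbind(ia, ic)]; nbc <- M[cbind(ib, ic)]
  dab <- dep[nab]; dac <- dep[nac]; dbc <- dep[nbc]
  n_tr <- nrow(triples)
  match_idx <- integer(n_tr)
  cherry_node <- top_node <- integer(n_tr)
  for (i in seq_len(n_tr)) {
    ds <- c(dab[i], dac[i], dbc[i])
    nodes <- c(nab[i], nac[i], nbc[i])
    top_node[i] <- nodes[which.min(ds)]
    deepest <- which(ds == max(ds))
    if (length(deepest) != 1L || max(ds) == min(ds)) {
      match_idx[i] <- 0L       # unresolved triple (species-tree polytomy)
      cherry_node[i] <- top_node[i]
    } else {
      match_idx[i] <- deepest
      cherry_node[i] <- nodes[deepest]
    }
  }
  t_len <- dlen[cherry_node] - dlen[top_node]
  out <- list(match_idx = match_idx, t = t_len,
              cherry_node = cherry_node, top_node = top_node)
  if (with_edges) {
    parent <- integer(ntip + sp$Nnode)
    edge_of_child <- integer(ntip + sp$Nnode)
    for (e in seq_len(nrow(sp$edge))) {
      parent[sp$edge[e, 2L]] <- sp$edge[e, 1L]
      edge_of_child[sp$edge[e, 2L]] <- e
    }
    int_edges <- which(sp$edge[, 2L] > ntip)
    A <- matrix(FALSE, n_tr, length(int_edges))
    edge_col <- integer(nrow(sp$edge))
    edge_col[int_edges] <- seq_along(int_edges)
    for (i in seq_len(n_tr)) {
      v <- cherry_node[i]
      while (v != top_node[i]) {
        e <- edge_of_child[v]
        if (edge_col[e] > 0L) A[i, edge_col[e]] <- TRUE
        v <- parent[v]
      }
    }
    out$A <- A
    out$internal_edges <- int_edges
  }
  out
}

#' Rooted-triplet probabilities for a species triple
#'
#' For a rooted species tree in coalescent units and a triple `{a, b, c}`,
#' the matching gene-tree triplet has probability `1 - (2/3) exp(-t)` and
#' each mismatching triplet `(1/3) exp(-t)`, where `t` is the coalescent
#' path length between the triple's most recent common ancestor and the
#' MRCA of its species-tree cherry.
#'
#' @param species_tree Rooted `phylo` with nonnegative branch lengths in
#'   coalescent units.
#' @param triple Character vector of three leaf labels.
#' @return Named numeric vector of probabilities over the three resolutions
#'   (`ab|c`, `ac|b`, `bc|a` with `a < b < c`), summing to 1, with
#'   attributes `t` and `match` (the matching resolution, `NA` at `t = 0`
#'   for an unresolved triple).
#' @export
triplet_probabilities <- function(species_tree, triple) {
  stopifnot(inherits(species_tree, "phylo"), length(triple) == 3L)
  if (!ape::is.rooted(species_tree)) stop("the species tree must be rooted")
  trip <- matrix(sort(triple), 1L, 3L)
  info <- .species_triplet_info(species_tree, trip)
  t <- max(0, info$t[1L])
  mis <- exp(-t) / 3
  p <- rep(mis, 3L)
  if (info$match_idx[1L] > 0L) p[info$match_idx[1L]] <- 1 - 2 * mis
  else p <- rep(1 / 3, 3L)
  names(p) <- c("ab|c", "ac|b", "bc|a")
  attr(p, "t") <- t
  attr(p, "match") <- if (info$match_idx[1L] > 0L)
    names(p)[info$match_idx[1L]] else NA_character_
  p
}

## core objective given per-triple t, match index and counts
.pll_from_t <- function(t, match_idx, n_match, n_total) {
  mis <- exp(-t) / 3
  p_match <- ifelse(match_idx > 0L, 1 - 2 * mis, 1 / 3)
  p_mis <- ifelse(match_idx > 0L, mis, 1 / 3)
  sum(n_match * log(pmax(p_match, .PROB_FLOOR)) +
        (n_total - n_match) * log(pmax(p_mis, .PROB_FLOOR)))
}

#' Pseudo-log-likelihood of a species tree given a triplet table
#'
#' Sum over triples of `count * log(probability)` across the three rooted
#' resolutions, with probabilities floored at `1e-12` inside the logarithm.
#'
#' @param species_tree Rooted `phylo` with branch lengths in coalescent
#'   units (internal lengths used; terminal lengths may be `NA`).
#' @param table A `triplet_table`.
#' @return The pseudo-log-likelihood (a finite real).
#' @export
pseudo_log_likelihood <- function(species_tree, table) {
  stopifnot(inherits(table, "triplet_table"))
  info <- .species_triplet_info(species_tree, table$triples)
  n_match <- ifelse(info$match_idx > 0L,
                    table$counts[cbind(seq_len(nrow(table$counts)),
                                       pmax(info$match_idx, 1L))], 0)
  .pll_from_t(pmax(info$t, 0), info$match_idx, n_match,
              rowSums(table$counts))
}

#' Maximize the pseudo-likelihood over internal branch lengths
#'
#' Coordinate-wise bounded scalar maximization (branch bounds
#' `[0, 20]` coalescent units) iterated until the objective improves by
#' less than `1e-6`. Only internal branch lengths are estimated; terminal
#' branches are reported as absent (`NA`).
#'
#' @param topology Rooted binary `phylo` (branch lengths ignored).
#' @param table A `triplet_table` whose taxa all appear in the topology.
#' @param tol Convergence tolerance on the objective (default 1e-6).
#' @return A list of class `species_tree_estimate`: `tree` (with internal
#'   branch lengths, terminal lengths `NA`), `log_pseudo_likelihood`,
#'   `internal_lengths`.
#' @export
optimize_branch_lengths <- function(topology, table, tol = 1e-6) {
  stopifnot(inherits(table, "triplet_table"))
  if (!ape::is.rooted(topology)) stop("the topology must be rooted")
  if (!ape::is.binary(topology)) stop("the topology must be binary")
  info <- .species_triplet_info(topology, table$triples, with_edges = TRUE)
  A <- info$A
  n_edge <- ncol(A)
  n_total <- rowSums(table$counts)
  n_match <- ifelse(info$match_idx > 0L,
                    table$counts[cbind(seq_len(nrow(table$counts)),
                                       pmax(info$match_idx, 1L))], 0)
  obj_t <- function(t) .pll_from_t(t, info$match_idx, n_match, n_total)
  x <- rep(0.5, n_edge)
  t_cur <- as.vector(A %*% x)
  cur <- obj_t(t_cur)
  for (sweep in seq_len(200L)) {
    prev <- cur
    for (j in seq_len(n_edge)) {
      aj <- A[, j]
      if (!any(aj)) { x[j] <- 0; next }
      base <- t_cur - aj * x[j]
      f <- function(xj) obj_t(base + aj * xj)
      opt <- stats::optimize(f, interval = c(0, .BRANCH_UPPER),
                             maximum = TRUE, tol = 1e-8)
      cand_x <- c(opt$maximum, 0, .BRANCH_UPPER)
      cand_v <- c(opt$objective, f(0), f(.BRANCH_UPPER))
      k <- which.max(cand_v)
      x[j] <- cand_x[k]
      t_cur <- base + aj * x[j]
      cur <- cand_v[k]
    }
    if (cur - prev < tol) break
  }
  tree <- topology
  el <- rep(NA_real_, nrow(tree$edge))
  el[info$internal_edges] <- x
  tree$edge.length <- el
  attr(tree, "units") <- "coalescent"
  out <- list(tree = tree, log_pseudo_likelihood = cur,
              internal_lengths = x)
  class(out) <- "species_tree_estimate"
  out
}

## ---- rooted topology generation and NNI, on nested-list trees ----

.tl_canonical <- function(tl) {
  if (is.character(tl)) return(tl)
  k1 <- .tl_canonical(tl[[1L]]); k2 <- .tl_canonical(tl[[2L]])
  if (k1 > k2) { tmp <- k1; k1 <- k2; k2 <- tmp }
  paste0("(", k1, ",", k2, ")")
}

.tl_newick <- function(tl) {
  rec <- function(x) {
    if (is.character(x)) return(.nwk_label(x))
    paste0("(", rec(x[[1L]]), ",", rec(x[[2L]]), ")")
  }
  paste0(rec(tl), ";")
}

.tl_to_phylo <- function(tl) parse_newick(.tl_newick(tl))

## uniform-ish random rooted topology by sequential random attachment
.tl_random <- function(labels) {
  labels <- sample(labels)
  tl <- list(labels[1L], labels[2L])
  for (k in seq_along(labels)[-(1:2)]) {
    n_pos <- 2L * (k - 1L) - 1L      # edges + above-root position
    pos <- sample.int(n_pos, 1L)
    tl <- .tl_insert_at(tl, labels[k], pos)$tree
  }
  tl
}

## insert tip above the `pos`-th node in preorder (root = position 1)
.tl_insert_at <- function(tl, tip, pos) {
  counter <- 0L
  rec <- function(node) {
    counter <<- counter + 1L
    if (counter == pos) return(list(tip, node))
    if (is.character(node)) return(node)
    list(rec(node[[1L]]), rec(node[[2L]]))
  }
  out <- rec(tl)
  stopifnot(counter >= pos)
  list(tree = out)
}

## all rooted binary topologies on the given labels ((2n-3)!! of them)
.tl_all_topologies <- function(labels) {
  labels <- sort(labels)
  trees <- list(list(labels[1L], labels[2L]))
  for (k in seq_along(labels)[-(1:2)]) {
    nxt <- list()
    for (tr in trees)
      nxt <- c(nxt, .tl_insertions(tr, labels[k]))
    trees <- nxt
  }
  trees
}

## all trees obtained by attaching `tip` above every node (incl. the root)
.tl_insertions <- function(tl, tip) {
  out <- list(list(tip, tl))
  if (is.character(tl)) return(out)
  for (sub in .tl_insertions(tl[[1L]], tip))
    out <- c(out, list(list(sub, tl[[2L]])))
  for (sub in .tl_insertions(tl[[2L]], tip))
    out <- c(out, list(list(tl[[1L]], sub)))
  out
}

## rooted NNI neighborhood: for each internal edge (to child v with sibling
## w), swap w with either child of v
.tl_nni <- function(tl) {
  out <- list()
  rec <- function(node, wrap) {
    if (is.character(node)) return(invisible())
    a <- node[[1L]]; b <- node[[2L]]
    if (!is.character(b)) {
      out[[length(out) + 1L]] <<- wrap(list(b[[1L]], list(a, b[[2L]])))
      out[[length(out) + 1L]] <<- wrap(list(b[[2L]], list(b[[1L]], a)))
    }
    if (!is.character(a)) {
      out[[length(out) + 1L]] <<- wrap(list(list(a[[1L]], b), a[[2L]]))
      out[[length(out) + 1L]] <<- wrap(list(a[[1L]], list(a[[2L]], b)))
    }
    rec(a, function(x) wrap(list(x, b)))
    rec(b, function(x) wrap(list(a, x)))
  }
  rec(tl, identity)
  out
}

.phylo_to_tl <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  rec <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    ch <- kids[[as.character(v)]]
    stopifnot(length(ch) == 2L)
    list(rec(ch[1L]), rec(ch[2L]))
  }
  rec(ntip + 1L)
}

#' Search for the pseudo-maximum-likelihood species tree
#'
#' `"nni"` mode runs `n_runs` independent hill-climbs: each starts from a
#' random rooted topology (sequential random attachment), repeatedly moves
#' to the best-scoring rooted-NNI neighbor (re-optimizing internal branch
#' lengths at every candidate) and stops at a local optimum; the
#' best-scoring result across runs is returned. `"exhaustive"` mode
#' (allowed for up to 8 species) scores every rooted binary topology and
#' returns the global optimum.
#'
#' @param table A `triplet_table` over at least 3 species.
#' @param n_runs Independent hill-climbs in `"nni"` mode (default 10).
#' @param seed Optional integer seed (search deterministic given it).
#' @param mode `"nni"` or `"exhaustive"`.
#' @return A `species_tree_estimate` with an extra `run_scores` element
#'   (per-run best scores in `"nni"` mode).
#' @export
search_species_tree <- function(table, n_runs = 10, seed = NULL,
                                mode = c("nni", "exhaustive")) {
  stopifnot(inherits(table, "triplet_table"))
  mode <- match.arg(mode)
  taxa <- table$taxa
  if (length(taxa) < 3L) stop("need at least 3 species")
  if (mode == "exhaustive") {
    if (length(taxa) > 8L)
      stop("exhaustive search is limited to 8 species")
    best <- NULL
    for (tl in .tl_all_topologies(taxa)) {
      est <- optimize_branch_lengths(.tl_to_phylo(tl), table)
      if (is.null(best) ||
          est$log_pseudo_likelihood > best$log_pseudo_likelihood)
        best <- est
    }
    best$run_scores <- best$log_pseudo_likelihood
    best$mode <- "exhaustive"
    return(best)
  }
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  run_scores <- numeric(n_runs)
  cache <- new.env(parent = emptyenv())   # topology -> estimate, per table
  score_topology <- function(tl) {
    key <- .tl_canonical(tl)
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    est <- optimize_branch_lengths(.tl_to_phylo(tl), table)
    assign(key, est, envir = cache)
    est
  }
  for (r in seq_len(n_runs)) {
    tl <- .tl_random(taxa)
    est <- score_topology(tl)
    repeat {
      improved <- FALSE
      for (nb in .tl_nni(tl)) {
        cand <- score_topology(nb)
        if (cand$log_pseudo_likelihood >
            est$log_pseudo_likelihood + 1e-9) {
          est <- cand; tl <- nb; improved <- TRUE
        }
      }
      if (!improved) break
    }
    run_scores[r] <- est$log_pseudo_likelihood
    if (is.null(best) ||
        est$log_pseudo_likelihood > best$log_pseudo_likelihood)
      best <- est
  }
  best$run_scores <- run_scores
  best$mode <- "nni"
  best
}

#' Fit a species tree to rooted gene trees by pseudo-maximum likelihood
#'
#' The user-facing fitting interface: tabulates rooted-triplet frequencies
#' across the input gene trees and searches for the rooted species tree
#' (topology and internal branch lengths in coalescent units) maximizing
#' the triplet pseudo-likelihood. Following common practice the search is
#' repeated `n_runs` times from random starting topologies and the best
#' pseudo-likelihood score is kept.
#'
#' @param gene_trees List of rooted `phylo` gene trees (or a
#'   `triplet_table`).
#' @param n_runs Independent search runs (default 10).
#' @param seed Optional integer seed.
#' @param mode `"nni"` (heuristic) or `"exhaustive"` (<= 8 species).
#' @return An object of class `mpest_fit`.
#' @export
mpest <- function(gene_trees, n_runs = 10, seed = NULL,
                  mode = c("nni", "exhaustive")) {
  mode <- match.arg(mode)
  table <- if (inherits(gene_trees, "triplet_table")) gene_trees
  else tabulate_triplets(gene_trees)
  est <- search_species_tree(table, n_runs = n_runs, seed = seed,
                             mode = mode)
  out <- list(tree = est$tree,
              log_pseudo_likelihood = est$log_pseudo_likelihood,
              run_scores = est$run_scores, mode = est$mode,
              n_runs = if (est$mode == "nni") n_runs else 1L,
              table = table, seed = seed)
  class(out) <- "mpest_fit"
  out
}

#' Summarize gene trees (or gene-tree distributions) into a species tree
#'
#' Point mode consumes one point-estimate tree per locus; distribution mode
#' consumes the concatenation of all per-locus subsampled trees as one
#' gene-tree list. Both tabulate triplets over the pooled list and search.
#' A `coestimation_result` supplies its MCC trees (point mode) or its
#' subsampled distributions (distribution mode) directly.
#'
#' @param input A `coestimation_result`, a list of rooted trees (point
#'   mode), or a list of lists of rooted trees (distribution mode).
#' @param mode `"point"` or `"distribution"`.
#' @param n_runs Search runs (default 10).
#' @param seed Optional integer seed.
#' @param search `"nni"` or `"exhaustive"`.
#' @return An `mpest_fit`.
#' @export
summarize_gene_trees <- function(input, mode = c("point", "distribution"),
                                 n_runs = 10, seed = NULL,
                                 search = c("nni", "exhaustive")) {
  mode <- match.arg(mode)
  search <- match.arg(search)
  pooled <- if (inherits(input, "coestimation_result")) {
    if (mode == "point") input$mcc_trees
    else unlist(input$tree_samples, recursive = FALSE)
  } else if (mode == "distribution" && is.list(input) &&
             !inherits(input[[1L]], "phylo")) {
    unlist(input, recursive = FALSE)
  } else {
    input
  }
  labsets <- lapply(pooled, function(tr) sort(tr$tip.label))
  core <- Reduce(intersect, labsets)
  if (length(core) < 3L)
    stop("gene trees share fewer than 3 taxa; no common core to summarize")
  mpest(pooled, n_runs = n_runs, seed = seed, mode = search)
}

## ---- S3 methods for mpest_fit ----

#' @export
print.mpest_fit <- function(x, ...) {
  cat("Pseudo-maximum-likelihood species tree (rooted triplets)\n")
  cat("  taxa:", length(x$table$taxa),
      " triples:", nrow(x$table$triples),
      " gene-tree count (max per triple):", max(rowSums(x$table$counts)),
      "\n")
  cat("  search:", x$mode, "with", length(x$run_scores), "run(s)\n")
  cat("  best log pseudo-likelihood:",
      format(x$log_pseudo_likelihood, digits = 8), "\n")
  cat("  topology:", write_newick(x$tree, precision = 4), "\n")
  invisible(x)
}

#' @export
summary.mpest_fit <- function(object, ...) {
  print(object)
  cat("  per-run scores:",
      paste(format(object$run_scores, digits = 8), collapse = ", "), "\n")
  cat("  internal branch lengths (coalescent units):",
      paste(format(stats::na.omit(object$tree$edge.length), digits = 4),
            collapse = ", "), "\n")
  invisible(object)
}

#' @export
logLik.mpest_fit <- function(object, ...) {
  val <- object$log_pseudo_likelihood
  attr(val, "df") <- sum(!is.na(object$tree$edge.length))
  class(val) <- "logLik"
  val
}

#' @export
plot.mpest_fit <- function(x, ...) {
  tr <- x$tree
  tr$edge.length[is.na(tr$edge.length)] <- 0
  ape::plot.phylo(tr, ...)
}
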