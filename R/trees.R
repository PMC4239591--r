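## Core tree utilities: newick/NEXUS I/O, bipartitions, Robinson-Foulds
## distance, maximum clade credibility summaries and outgroup rooting.
## Trees are ape "phylo" objects throughout; branch-length units are carried
## in the "units" attribute ("coalescent", "substitutions", or "none").

#' Parse a newick string into a phylo object
#'
#' Thin validating wrapper around [ape::read.tree()]. Accepts quoted labels
#' and scientific-notation branch lengths; rejects unbalanced parentheses,
#' missing semicolons and duplicate leaf labels.
#'
#' @param text A single newick string, terminated by `;`.
#' @return A `phylo` object.
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single newick string")
  if (!grepl(";", text, fixed = TRUE))
    stop("newick parse error at position ", nchar(text),
         ": missing terminating ';'")
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error at position ", i, ": unmatched ')'")
    }
  }
  if (depth != 0L)
    stop("newick parse error at position ", nchar(text), ": unmatched '('")
  if (!grepl("(", text, fixed = TRUE)) {
    # degenerate single-leaf tree, e.g. "A;" or "A:1.0;"
    body <- sub(";.*$", "", trimws(text))
    lab <- sub(":.*$", "", body)
    lab <- gsub("^'|'$", "", lab)
    if (!nzchar(lab)) stop("newick parse error: empty leaf label")
    return(.single_tip_tree(lab))
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error: unreadable string")
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup))
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "))
  tr
}

.single_tip_tree <- function(label) {
  tr <- list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = label,
             Nnode = 1L)
  class(tr) <- "phylo"
  tr
}

#' Write a phylo object as a newick string
#'
#' Child order follows the tree as stored, so output is deterministic for a
#' given tree. Branch lengths are omitted where absent or `NA` (the
#' pseudo-likelihood species-tree estimator reports only internal branch
#' lengths, so terminal lengths may legitimately be `NA`).
#'
#' @param tree A `phylo` object.
#' @param precision Significant digits for branch lengths.
#' @return A single newick string ending in `;`.
#' @export
write_newick <- function(tree, precision = 10) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip == 1L) return(paste0(.nwk_label(tree$tip.label), ";"))
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  el <- tree$edge.length
  rec <- function(node) {
    ki <- kids[[as.character(node)]]
    if (is.null(ki)) {
      lab <- .nwk_label(tree$tip.label[node])
      return(lab)
    }
    parts <- vapply(ki, function(e) {
      s <- rec(tree$edge[e, 2L])
      if (!is.null(el) && !is.na(el[e]))
        s <- paste0(s, ":", format(el[e], digits = precision,
                                   scientific = FALSE))
      s
    }, character(1L))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- ntip + 1L
  paste0(rec(root), ";")
}

.nwk_label <- function(lab) {
  if (grepl("[^A-Za-z0-9_.|-]", lab)) paste0("'", lab, "'") else lab
}

#' Read a sample of trees from a newick or NEXUS file
#'
#' Newick files hold one tree per line; NEXUS files (detected by a leading
#' `#NEXUS`) may carry a TREES block with a translate table, handled by
#' [ape::read.nexus()].
#'
#' @param path Path to the tree file.
#' @return A list of `phylo` objects.
#' @export
read_tree_sample <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  trs <- if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE))
    ape::read.nexus(path)
  else
    ape::read.tree(path)
  if (inherits(trs, "phylo")) trs <- list(trs)
  lapply(unname(trs), identity)
}

#' Write a sample of trees, one newick string per line
#' @param trees List of `phylo` objects.
#' @param path Output file.
#' @param precision Significant digits for branch lengths.
#' @export
write_tree_sample <- function(trees, path, precision = 10) {
  writeLines(vapply(trees, write_newick, character(1L),
                    precision = precision), path)
  invisible(path)
}

## descendant tip-label sets, one per node (list indexed by node id)
.descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Canonical bipartition set of a tree
#'
#' One canonical key per internal edge of the unrooted version of the tree;
#' trivial splits (single leaf vs rest) are excluded. The canonical
#' orientation stores the block that does not contain the lexicographically
#' smallest leaf label, so keys hash deterministically.
#'
#' @param tree A `phylo` object.
#' @return Character vector of canonical bipartition keys (sorted labels
#'   joined by tab). Empty for trees with fewer than 4 leaves or a star
#'   topology.
#' @export
bipartition_set <- function(tree) {
  labs <- sort(tree$tip.label)
  n <- length(labs)
  if (n < 4L) return(character(0L))
  ut <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ntip <- length(ut$tip.label)
  desc <- .descendant_tips(ut)
  root <- ntip + 1L
  internal_children <- ut$edge[ut$edge[, 2L] > ntip, 2L]
  keys <- character(0L)
  for (v in internal_children) {
    block <- desc[[v]]
    if (length(block) < 2L || length(block) > n - 2L) next
    if (labs[1L] %in% block) block <- setdiff(labs, block)
    keys <- c(keys, paste(sort(block), collapse = "\t"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' Raw distance is the size of the symmetric difference of the two trees'
#' non-trivial bipartition sets (unrooted convention); the normalized
#' distance divides by `2 * (n - 3)`, the maximum for two binary trees on
#' `n` leaves. Polytomies contribute only their resolved bipartitions; the
#' denominator is unchanged.
#'
#' @param t1,t2 `phylo` objects over the same leaf set.
#' @return A list with elements `raw` (integer) and `normalized` (in
#'   `[0, 1]`).
#' @export
rf_distance <- function(t1, t2) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    only1 <- setdiff(l1, l2); only2 <- setdiff(l2, l1)
    stop("leaf sets differ; only in first: [",
         paste(only1, collapse = ", "), "]; only in second: [",
         paste(only2, collapse = ", "), "]")
  }
  b1 <- bipartition_set(t1); b2 <- bipartition_set(t2)
  raw <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  n <- length(l1)
  norm <- if (n > 3L) raw / (2 * (n - 3L)) else 0
  list(raw = as.integer(raw), normalized = norm)
}

## clade keys (descendant tip sets of internal nodes) of a rooted tree
.clade_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- .descendant_tips(tree)
  vapply(desc[(ntip + 1L):(ntip + tree$Nnode)],
         function(b) paste(sort(b), collapse = "\t"), character(1L))
}

## node heights above the deepest tip (ultrametric trees: above the tips)
.node_heights <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  max(d) - d
}

#' Maximum clade credibility tree of a rooted tree sample
#'
#' Returns the tree *from the sample* that maximizes the sum over its clades
#' of the log of the clade's frequency in the sample (the product-form MCC
#' criterion); ties are broken by the earliest sample index. When every
#' sampled tree carries branch lengths, node heights of the winner are
#' re-annotated as the mean height of the matching clade across the sampled
#' trees that contain it ("mean heights" annotation).
#'
#' @param sample A list of rooted `phylo` objects over one leaf set.
#' @return The winning `phylo`, with attributes `log_clade_credibility`
#'   (its score) and `clade_credibility` (named clade frequencies).
#' @export
mcc_tree <- function(sample) {
  if (!length(sample)) stop("empty tree sample")
  labs <- sort(sample[[1L]]$tip.label)
  for (tr in sample) {
    if (!identical(sort(tr$tip.label), labs))
      stop("trees in the sample do not share one leaf set")
    if (!ape::is.rooted(tr)) stop("maximum clade credibility requires rooted trees")
  }
  keysets <- lapply(sample, .clade_keys)
  tab <- table(unlist(lapply(keysets, unique), use.names = FALSE))
  freq <- as.numeric(tab) / length(sample)
  names(freq) <- names(tab)
  scores <- vapply(keysets, function(k) sum(log(freq[unique(k)])),
                   numeric(1L))
  best <- which.max(scores)          # first index on ties
  tr <- sample[[best]]
  has_lengths <- all(vapply(sample, function(x) !is.null(x$edge.length),
                            logical(1L)))
  if (has_lengths) {
    hsum <- new.env(parent = emptyenv())
    for (i in seq_along(sample)) {
      h <- .node_heights(sample[[i]])
      ntip_i <- length(sample[[i]]$tip.label)
      ks <- keysets[[i]]
      for (j in seq_along(ks)) {
        prev <- get0(ks[j], envir = hsum, ifnotfound = c(0, 0))
        assign(ks[j], prev + c(h[ntip_i + j], 1), envir = hsum)
      }
    }
    ntip <- length(tr$tip.label)
    h <- .node_heights(tr)
    ks <- keysets[[best]]
    for (j in seq_along(ks)) {
      s <- get(ks[j], envir = hsum)
      h[ntip + j] <- s[1L] / s[2L]
    }
    el <- tr$edge.length
    for (e in seq_len(nrow(tr$edge)))
      el[e] <- max(0, h[tr$edge[e, 1L]] - h[tr$edge[e, 2L]])
    tr$edge.length <- el
  }
  attr(tr, "log_clade_credibility") <- scores[best]
  cred <- freq[keysets[[best]]]
  names(cred) <- keysets[[best]]
  attr(tr, "clade_credibility") <- cred
  tr
}

#' Root a tree with a single outgroup leaf
#'
#' The returned tree is rooted on the pendant edge of the outgroup, so the
#' root has the outgroup leaf as one child; the ingroup topology is
#' unchanged. Re-rooting an already-correctly-rooted tree is a topological
#' no-op.
#'
#' @param tree A `phylo` object.
#' @param outgroup A leaf label present in the tree.
#' @return A rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"), is.character(outgroup),
            length(outgroup) == 1L)
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a leaf of the tree")
  rt <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  og <- match(outgroup, rt$tip.label)
  root <- length(rt$tip.label) + 1L
  if (!og %in% rt$edge[rt$edge[, 1L] == root, 2L])
    rt <- ape::root(ape::unroot(rt), outgroup = outgroup,
                    resolve.root = TRUE)
  rt
}
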