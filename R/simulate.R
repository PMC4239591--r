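## Data-generating process: gene trees under the multispecies coalescent
## within a species tree in coalescent units, then sequences under GTR(+Gamma)
## down each gene tree.

#' Multispecies coalescent model
#'
#' Wraps a rooted species tree whose branch lengths are in coalescent units
#' (time divided by population size, so k lineages coalesce at rate
#' `k*(k-1)/2` per unit). One haploid sample per species.
#'
#' @param species_tree Rooted `phylo` with nonnegative branch lengths in
#'   coalescent units and at least 3 leaves.
#' @return An object of class `msc_model`.
#' @export
msc_model <- function(species_tree) {
  stopifnot(inherits(species_tree, "phylo"))
  if (!ape::is.rooted(species_tree))
    stop("the species tree must be rooted")
  if (length(species_tree$tip.label) < 3L)
    stop("the species tree must have at least 3 leaves")
  if (is.null(species_tree$edge.length))
    stop("the species tree must carry branch lengths (coalescent units)")
  if (any(species_tree$edge.length < 0))
    stop("species-tree branch lengths must be nonnegative")
  out <- list(tree = species_tree)
  class(out) <- "msc_model"
  out
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Contained (censored) coalescent: within a species-tree branch of duration
#' `T` holding `k` lineages, successive coalescence waiting times are
#' exponential with rate `k*(k-1)/2`, truncated at `T`; surviving lineages
#' enter the parent branch, and coalescence continues above the root until a
#' single lineage remains. Gene trees are rooted, binary and ultrametric in
#' coalescent time (for an ultrametric species tree), with one tip per
#' species.
#'
#' @param model An `msc_model` (or a rooted `phylo`, coerced).
#' @param n_genes Number of gene trees to simulate.
#' @param seed Optional integer seed.
#' @return List of rooted `phylo` gene trees with branch lengths in
#'   coalescent units.
#' @export
simulate_gene_trees <- function(model, n_genes, seed = NULL) {
  if (inherits(model, "phylo")) model <- msc_model(model)
  stopifnot(inherits(model, "msc_model"))
  if (!is.numeric(n_genes) || n_genes < 1)
    stop("'n_genes' must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  sp <- model$tree
  ntip <- length(sp$tip.label)
  depths <- ape::node.depth.edgelength(sp)
  ages <- max(depths) - depths
  kids <- split(sp$edge[, 2L], sp$edge[, 1L])
  root <- ntip + 1L
  lapply(seq_len(n_genes), function(g)
    .sim_one_gene_tree(sp, ntip, ages, kids, root))
}

.sim_one_gene_tree <- function(sp, ntip, ages, kids, root) {
  # growing record of gene-tree coalescences
  max_nodes <- 2L * ntip - 1L
  ch1 <- integer(ntip - 1L); ch2 <- integer(ntip - 1L)
  tm <- numeric(max_nodes)
  tm[seq_len(ntip)] <- ages[seq_len(ntip)]
  n_int <- 0L

  coalesce <- function(lin, t0, t1) {
    k <- length(lin)
    while (k >= 2L) {
      dt <- stats::rexp(1L, rate = k * (k - 1L) / 2)
      if (t0 + dt > t1) break
      t0 <- t0 + dt
      pair <- sample.int(k, 2L)
      n_int <<- n_int + 1L
      id <- ntip + n_int
      ch1[n_int] <<- lin[pair[1L]]
      ch2[n_int] <<- lin[pair[2L]]
      tm[id] <<- t0
      lin <- c(lin[-pair], id)
      k <- k - 1L
    }
    lin
  }
  walk <- function(v) {
    if (v <= ntip) return(v)
    unlist(lapply(kids[[as.character(v)]], function(ch) {
      coalesce(walk(ch), ages[ch], ages[v])
    }))
  }
  lin <- coalesce(walk(root), ages[root], Inf)
  stopifnot(length(lin) == 1L)

  # assemble a phylo: tips keep ids 1..ntip; internal node created last
  # (the gene-tree root) must become ntip+1
  remap <- c(seq_len(ntip), ntip + rev(seq_len(n_int)))
  edge <- matrix(0L, 2L * (ntip - 1L), 2L)
  elen <- numeric(2L * (ntip - 1L))
  for (j in seq_len(n_int)) {
    p <- remap[ntip + j]
    for (k in 1:2) {
      ch <- if (k == 1L) ch1[j] else ch2[j]
      e <- 2L * (j - 1L) + k
      edge[e, ] <- c(p, remap[ch])
      elen[e] <- tm[ntip + j] - tm[ch]
    }
  }
  tr <- list(edge = edge, edge.length = elen,
             tip.label = sp$tip.label, Nnode = ntip - 1L)
  class(tr) <- "phylo"
  attr(tr, "units") <- "coalescent"
  tr
}

#' Rescale a gene tree from coalescent units to expected substitutions/site
#'
#' @param gene_tree A `phylo` in coalescent units.
#' @param rate Per-gene rate scalar (expected substitutions per site per
#'   coalescent unit), strictly positive.
#' @return The tree with all branch lengths multiplied by `rate`.
#' @export
scale_to_substitutions <- function(gene_tree, rate) {
  stopifnot(inherits(gene_tree, "phylo"))
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("'rate' must be a single positive number")
  gene_tree$edge.length <- gene_tree$edge.length * rate
  attr(gene_tree, "units") <- "substitutions"
  gene_tree
}

#' GTR substitution-model parameters
#'
#' Builds the reversible rate matrix `Q[i,j] = s_ij * pi_j` from six
#' exchangeabilities and four stationary base frequencies, scaled so the
#' mean substitution rate at stationarity is 1 (branch lengths are then in
#' expected substitutions per site). Optional discrete-gamma rate variation
#' across sites.
#'
#' @param rates Six positive exchangeabilities in the order AC, AG, AT, CG,
#'   CT, GT.
#' @param base_freq Four stationary frequencies (A, C, G, T) summing to 1.
#' @param gamma_shape Optional gamma shape `alpha > 0`; when set, site rates
#'   follow a 4-category discretized gamma with mean 1.
#' @param rate_scalar Per-gene scalar converting coalescent units to
#'   expected substitutions per site (used by the simulation conditions).
#' @return An object of class `gtr_params` with the scaled `Q`.
#' @export
gtr_params <- function(rates = rep(1, 6), base_freq = rep(0.25, 4),
                       gamma_shape = NULL, rate_scalar = 1) {
  if (length(rates) != 6L || any(!is.finite(rates)) || any(rates <= 0))
    stop("'rates' must be 6 positive exchangeabilities")
  if (length(base_freq) != 4L || any(base_freq <= 0) ||
      abs(sum(base_freq) - 1) > 1e-8)
    stop("'base_freq' must be 4 positive frequencies summing to 1")
  if (!is.null(gamma_shape) && (!is.finite(gamma_shape) || gamma_shape <= 0))
    stop("'gamma_shape' must be positive")
  if (!is.finite(rate_scalar) || rate_scalar <= 0)
    stop("'rate_scalar' must be positive")
  Q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    Q[i, j] <- rates[k] * base_freq[j]
    Q[j, i] <- rates[k] * base_freq[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(base_freq * diag(Q))
  Q <- Q / mu
  out <- list(rates = rates, base_freq = base_freq, Q = Q,
              gamma_shape = gamma_shape, rate_scalar = rate_scalar)
  class(out) <- "gtr_params"
  out
}

## discretized gamma rate categories (mean 1), median-of-quantile scheme
.gamma_categories <- function(shape, n_cat = 4L) {
  q <- stats::qgamma((seq_len(n_cat) - 0.5) / n_cat, shape = shape,
                     rate = shape)
  q / mean(q)
}

## transition probability matrices exp(Q*t) via symmetric eigendecomposition
.gtr_pmat_factory <- function(params) {
  pi_sqrt <- sqrt(params$base_freq)
  S <- diag(pi_sqrt) %*% params$Q %*% diag(1 / pi_sqrt)
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  V <- diag(1 / pi_sqrt) %*% eg$vectors
  Vi <- t(eg$vectors) %*% diag(pi_sqrt)
  function(t) {
    P <- V %*% (exp(eg$values * t) * Vi)
    P[P < 0] <- 0
    P / rowSums(P)
  }
}

#' Simulate a multiple sequence alignment down a gene tree under GTR(+Gamma)
#'
#' The root sequence is drawn from the stationary frequencies; each child
#' sequence is obtained site by site from the transition matrix
#' `exp(Q * t * g)`, where `t` is the branch length in expected
#' substitutions per site and `g` the site's gamma rate multiplier (1 when
#' `gamma_shape` is unset).
#'
#' @param gene_tree `phylo` with finite branch lengths in substitutions/site.
#' @param params A `gtr_params` object.
#' @param length Alignment length in sites.
#' @param seed Optional integer seed (result deterministic given the seed).
#' @return A character matrix (rows = taxa, columns = sites) of bases
#'   `A/C/G/T`, of class `locus_alignment`.
#' @export
simulate_alignment <- function(gene_tree, params, length, seed = NULL) {
  stopifnot(inherits(gene_tree, "phylo"))
  if (!inherits(params, "gtr_params")) stop("'params' must be gtr_params")
  if (!is.numeric(length) || length < 1) stop("'length' must be >= 1")
  if (!all(is.finite(gene_tree$edge.length)))
    stop("gene-tree branch lengths must be finite")
  if (!is.null(seed)) set.seed(seed)
  length <- as.integer(length)
  bases <- c("A", "C", "G", "T")
  ntip <- base::length(gene_tree$tip.label)
  nnode <- ntip + gene_tree$Nnode
  pmat <- .gtr_pmat_factory(params)
  if (is.null(params$gamma_shape)) {
    gcat <- 1
    site_cat <- rep(1L, length)
  } else {
    gcat <- .gamma_categories(params$gamma_shape)
    site_cat <- sample.int(base::length(gcat), length, replace = TRUE)
  }
  state <- matrix(0L, nnode, length)
  root <- ntip + 1L
  state[root, ] <- sample.int(4L, length, replace = TRUE,
                              prob = params$base_freq)
  edge <- ape::reorder.phylo(gene_tree, "cladewise")
  el <- edge$edge.length
  edge <- edge$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    for (cc in seq_along(gcat)) {
      P <- pmat(el[e] * gcat[cc])
      cum <- t(apply(P, 1L, cumsum))
      in_cat <- site_cat == cc
      ps <- state[p, ]
      u <- stats::runif(length)
      newstate <- state[ch, ]
      for (s in 1:4) {
        idx <- which(in_cat & ps == s)
        if (base::length(idx))
          newstate[idx] <- findInterval(u[idx], cum[s, ]) + 1L
      }
      state[ch, in_cat] <- newstate[in_cat]
    }
  }
  aln <- matrix(bases[state[seq_len(ntip), , drop = FALSE]], ntip, length)
  rownames(aln) <- gene_tree$tip.label
  class(aln) <- c("locus_alignment", class(aln))
  aln
}

#' Build one of the two simulation model conditions
#'
#' `"strongILS-like"`: an 11-taxon rooted species tree (10 ingroup taxa from
#' a seeded coalescent topology with short internal branches, so ILS is
#' severe, plus the outgroup `OUT`), 100 genes of 500 bp under strongly
#' heterogeneous per-gene GTR models. `"laurasiatheria-like"`: a 12-taxon
#' tree (11 ingroup taxa with moderate ILS plus `OUT` attached by a long
#' branch), 100 genes at 500, 1000 or 1500 bp.
#'
#' @param name One of `"strongILS-like"`, `"laurasiatheria-like"`.
#' @param sequence_length Alignment length; fixed at 500 for
#'   `"strongILS-like"`, one of 500/1000/1500 for `"laurasiatheria-like"`.
#' @param seed Integer seed; the species tree and all per-gene samplers are
#'   deterministic functions of it.
#' @param n_genes Number of loci (default 100).
#' @param n_replicates Replicate datasets per condition (default 10).
#' @param ils_scale Positive multiplier on ingroup branch lengths; smaller
#'   values mean more incomplete lineage sorting.
#' @return An object of class `model_condition`.
#' @export
make_model_condition <- function(name, sequence_length = 500, seed = 1,
                                 n_genes = 100, n_replicates = 10,
                                 ils_scale = 1) {
  valid <- c("strongILS-like", "laurasiatheria-like")
  if (!name %in% valid)
    stop("unrecognized condition '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  if (ils_scale <= 0) stop("'ils_scale' must be positive")
  set.seed(seed)
  if (name == "strongILS-like") {
    sequence_length <- 500L
    n_ingroup <- 10L
    scale <- 0.4 * ils_scale      # short internal branches: severe ILS
    stem <- 1.5
    het <- "strong"
  } else {
    if (!sequence_length %in% c(500L, 1000L, 1500L))
      stop("'sequence_length' must be 500, 1000 or 1500 for ",
           "laurasiatheria-like")
    n_ingroup <- 11L
    scale <- 1.2 * ils_scale      # moderate ILS
    stem <- 3
    het <- "mild"
  }
  ing <- ape::rcoal(n_ingroup, tip.label = paste0("T", seq_len(n_ingroup)))
  ing$edge.length <- ing$edge.length * scale
  sp <- .attach_outgroup(ing, "OUT", stem)
  model <- msc_model(sp)
  gene_params <- lapply(seq_len(n_genes), function(i) {
    r <- exp(stats::runif(1, log(0.02), log(0.2)))
    if (het == "strong") {
      ex <- exp(stats::runif(6, log(0.3), log(3)))
      bf <- stats::rgamma(4, shape = 8)
      bf <- bf / sum(bf)
      a <- exp(stats::runif(1, log(0.3), log(2)))
    } else {
      ex <- exp(stats::runif(6, log(0.7), log(1.5)))
      bf <- stats::rgamma(4, shape = 40)
      bf <- bf / sum(bf)
      a <- 1
    }
    gtr_params(rates = ex, base_freq = bf, gamma_shape = a, rate_scalar = r)
  })
  out <- list(name = name, model = model, n_genes = as.integer(n_genes),
              sequence_length = as.integer(sequence_length),
              gene_params = gene_params,
              n_replicates = as.integer(n_replicates),
              outgroup = "OUT", seed = seed)
  class(out) <- "model_condition"
  out
}

## attach an outgroup tip below a new root, `stem` coalescent units above
## the ingroup root
.attach_outgroup <- function(ingroup, label, stem) {
  h <- max(ape::node.depth.edgelength(ingroup))
  nwk_in <- sub(";$", "", write_newick(ingroup))
  parse_newick(sprintf("(%s:%.10f,%s:%.10f);", nwk_in, stem, label,
                       h + stem))
}

#' Write one simulated replicate dataset to disk
#'
#' Emits one FASTA per locus, the true gene trees and true species tree as
#' newick, and a plain-text manifest (`key = value` lines) recording every
#' seed and parameter needed to reproduce the dataset byte for byte.
#'
#' @param condition A `model_condition`.
#' @param replicate Replicate index (1-based).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of the paths written.
#' @export
write_replicate <- function(condition, replicate, dir) {
  stopifnot(inherits(condition, "model_condition"))
  rep_data <- simulate_replicate(condition, replicate)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dir, 2L) != 0L) stop("directory not writable: ", dir)
  fasta <- character(condition$n_genes)
  for (i in seq_len(condition$n_genes)) {
    fasta[i] <- file.path(dir, sprintf("locus_%03d.fasta", i))
    write_fasta(rep_data$alignments[[i]], fasta[i])
  }
  gt_path <- file.path(dir, "true_gene_trees.tre")
  write_tree_sample(rep_data$gene_trees, gt_path)
  sp_path <- file.path(dir, "true_species_tree.tre")
  writeLines(write_newick(condition$model$tree), sp_path)
  manifest <- file.path(dir, "manifest.txt")
  writeLines(c(
    paste("condition =", condition$name),
    paste("condition_seed =", condition$seed),
    paste("replicate =", replicate),
    paste("replicate_seed =", rep_data$seed),
    paste("n_genes =", condition$n_genes),
    paste("sequence_length =", condition$sequence_length),
    paste("outgroup =", condition$outgroup)
  ), manifest)
  invisible(list(fasta = fasta, gene_trees = gt_path,
                 species_tree = sp_path, manifest = manifest))
}

#' Simulate one replicate in memory (gene trees and alignments)
#'
#' @inheritParams write_replicate
#' @return List with `gene_trees` (coalescent units), `scaled_trees`
#'   (substitutions/site), `alignments` and the derived `seed`.
#' @export
simulate_replicate <- function(condition, replicate) {
  stopifnot(inherits(condition, "model_condition"))
  seed <- derive_seed(condition$seed, 1000L + as.integer(replicate))
  gts <- simulate_gene_trees(condition$model, condition$n_genes, seed = seed)
  scaled <- vector("list", condition$n_genes)
  alns <- vector("list", condition$n_genes)
  for (i in seq_len(condition$n_genes)) {
    p <- condition$gene_params[[i]]
    scaled[[i]] <- scale_to_substitutions(gts[[i]], p$rate_scalar)
    alns[[i]] <- simulate_alignment(scaled[[i]], p,
                                    condition$sequence_length,
                                    seed = derive_seed(seed, i))
  }
  list(gene_trees = gts, scaled_trees = scaled, alignments = alns,
       seed = seed)
}

#' Write an alignment as FASTA
#' @param aln Character matrix with taxon rownames.
#' @param path Output file.
#' @export
write_fasta <- function(aln, path) {
  lines <- character(2L * nrow(aln))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln))
  lines[c(FALSE, TRUE)] <- apply(aln, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA alignment into a character matrix
#' @param path FASTA file with equal-length aligned sequences.
#' @return A `locus_alignment` character matrix (upper case).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  names_ <- sub("^>\\s*", "", lines[hdr])
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    paste(lines[starts[i]:ends[i]], collapse = "")
  }, character(1L))
  .alignment_from_strings(names_, toupper(seqs), path)
}

#' Read a relaxed PHYLIP alignment
#'
#' Sequential relaxed PHYLIP: a `ntax nchar` header line, then one
#' `name  sequence` record per taxon (whitespace separated, possibly
#' wrapped).
#'
#' @param path PHYLIP file.
#' @return A `locus_alignment` character matrix.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(hdr) < 2L) stop("malformed PHYLIP header in ", path)
  ntax <- as.integer(hdr[1L]); nchr <- as.integer(hdr[2L])
  body <- paste(lines[-1L], collapse = " ")
  toks <- strsplit(trimws(body), "\\s+")[[1L]]
  names_ <- character(ntax); seqs <- character(ntax)
  i <- 1L
  for (t in seq_len(ntax)) {
    names_[t] <- toks[i]; i <- i + 1L
    s <- ""
    while (nchar(s) < nchr) {
      s <- paste0(s, toks[i]); i <- i + 1L
    }
    seqs[t] <- s
  }
  .alignment_from_strings(names_, toupper(seqs), path)
}

.alignment_from_strings <- function(names_, seqs, path) {
  if (anyDuplicated(names_))
    stop("duplicate taxon names in ", path)
  w <- unique(nchar(seqs))
  if (length(w) != 1L)
    stop("unequal sequence lengths in ", path)
  aln <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(aln) <- names_
  class(aln) <- c("locus_alignment", class(aln))
  aln
}

#' Derive a stage seed from a master seed
#'
#' Per-stage seeds are deterministic functions of the master seed
#' (`(master mod 1e6) * 2039 + stage`), so any pipeline stage can be re-run
#' in isolation. Values stay below `2^31`.
#'
#' @param master Master integer seed.
#' @param stage Small nonnegative stage counter.
#' @return An integer seed.
#' @export
derive_seed <- function(master, stage) {
  as.integer((abs(as.numeric(master)) %% 1e6) * 2039 + (stage %% 2039))
}
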