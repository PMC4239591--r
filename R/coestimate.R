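## Step 2 of the pipeline: per-locus rooted gene-tree point estimates and
## tree distributions for each bin. A built-in desk-scale surrogate
## (neighbor joining on JC-corrected distances with a nonparametric site
## bootstrap, rooted by the outgroup) stands behind the same contract as an
## external Bayesian co-estimation run, whose results can be read back in.

## JC-corrected pairwise distances; saturated pairs clamped to a large
## finite distance so NJ never sees infinities
.SATURATION_DISTANCE <- 10

.jc_distance <- function(dna) {
  if (!inherits(dna, "DNAbin")) dna <- ape::as.DNAbin(tolower(unclass(dna)))
  d <- ape::dist.dna(dna, model = "JC69", pairwise.deletion = TRUE)
  d[!is.finite(d)] <- .SATURATION_DISTANCE
  d[d > .SATURATION_DISTANCE] <- .SATURATION_DISTANCE
  d
}

.nj_rooted <- function(dna, outgroup) {
  tr <- ape::nj(.jc_distance(dna))
  tr$edge.length[tr$edge.length < 0] <- 0
  root_with_outgroup(tr, outgroup)
}

.check_locus_alignment <- function(aln, id = "?") {
  if (!is.matrix(aln) || nrow(aln) < 3L)
    stop("locus ", id, ": an alignment needs >= 3 taxa")
  if (is.null(rownames(aln)))
    stop("locus ", id, ": alignment rows must be named by taxon")
  invisible(aln)
}

#' Estimate rooted gene trees for one bin of loci (surrogate estimator)
#'
#' For each locus: JC-corrected pairwise distances, a neighbor-joining tree
#' rooted at the outgroup, and a tree distribution formed by the rooted NJ
#' trees of `n_bootstrap` nonparametric site-resampled replicates; the
#' per-locus point estimate is the maximum clade credibility tree of that
#' distribution. This is the built-in desk-scale estimator behind the same
#' contract as an external Bayesian co-estimation run
#' ([read_external_results()]).
#'
#' @param bin List of `locus_alignment` matrices (rows = taxa).
#' @param outgroup Leaf label present in every locus.
#' @param n_bootstrap Bootstrap replicates per locus (default 200).
#' @param seed Optional integer master seed; per-locus seeds are derived
#'   from it, so results are deterministic.
#' @return An object of class `coestimation_result` with `mcc_trees`,
#'   `tree_samples` (one list of rooted trees per locus), `traces` (`NULL`
#'   for the surrogate), `provenance` and `seed`.
#' @export
surrogate_estimate_bin <- function(bin, outgroup, n_bootstrap = 200,
                                   seed = NULL) {
  stopifnot(is.list(bin), length(bin) >= 1L, n_bootstrap >= 1)
  ids <- names(bin)
  if (is.null(ids)) ids <- as.character(seq_along(bin))
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  samples <- vector("list", length(bin))
  mccs <- vector("list", length(bin))
  for (i in seq_along(bin)) {
    aln <- .check_locus_alignment(bin[[i]], ids[i])
    if (!outgroup %in% rownames(aln))
      stop("locus ", ids[i], " is missing the outgroup '", outgroup, "'")
    if (!is.null(base_seed)) set.seed(derive_seed(base_seed, i))
    nsite <- ncol(aln)
    dna <- ape::as.DNAbin(tolower(unclass(aln)))
    boot <- vector("list", n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      cols <- sample.int(nsite, nsite, replace = TRUE)
      boot[[b]] <- .nj_rooted(dna[, cols], outgroup)
    }
    samples[[i]] <- boot
    mccs[[i]] <- mcc_tree(boot)
  }
  names(samples) <- ids
  names(mccs) <- ids
  out <- list(mcc_trees = mccs, tree_samples = samples, traces = NULL,
              provenance = "surrogate", seed = seed)
  class(out) <- "coestimation_result"
  out
}

#' Combine two MCMC chains after burn-in removal
#'
#' Drops the first `floor(burnin_fraction * N)` trees of each chain and
#' concatenates the remainders (chain a first, then chain b).
#'
#' @param chain_a,chain_b Lists of trees over one leaf set.
#' @param burnin_fraction Fraction of each chain discarded (default 0.5).
#' @return The combined list of trees.
#' @export
combine_chains <- function(chain_a, chain_b, burnin_fraction = 0.5) {
  if (burnin_fraction < 0 || burnin_fraction >= 1)
    stop("'burnin_fraction' must be in [0, 1)")
  la <- sort(chain_a[[1L]]$tip.label)
  for (tr in c(chain_a, chain_b))
    if (!identical(sort(tr$tip.label), la))
      stop("chains do not share one leaf set")
  drop_a <- floor(burnin_fraction * length(chain_a))
  drop_b <- floor(burnin_fraction * length(chain_b))
  keep_a <- chain_a[seq_len(length(chain_a) - drop_a) + drop_a]
  keep_b <- chain_b[seq_len(length(chain_b) - drop_b) + drop_b]
  out <- c(keep_a, keep_b)
  if (!length(out)) stop("no trees remain after burn-in removal")
  out
}

#' Randomly subsample trees from a distribution
#'
#' Draws uniformly without replacement when the sample holds at least `n`
#' trees, otherwise with replacement (so small distributions still yield
#' `n` trees per locus).
#'
#' @param sample List of trees.
#' @param n Trees to draw (default 100).
#' @param seed Optional integer seed.
#' @return A list of `n` trees.
#' @export
subsample_trees <- function(sample, n = 100, seed = NULL) {
  if (!length(sample)) stop("empty tree sample")
  if (n < 1) stop("'n' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(length(sample), n, replace = length(sample) < n)
  sample[idx]
}

#' Write a self-contained configuration bundle for an external co-estimation
#' run
#'
#' Emits, for one bin of loci, a plain-text bundle: a `config.txt` of
#' `key = value` pairs (chain length, sampling interval, expected samples
#' per chain, two distinct chain seeds), one FASTA per locus, and a
#' `run.sh` command script with one line per chain. The format is
#' documented and round-trip readable via [read_external_config()]; it is
#' not a byte-compatible clone of any particular Bayesian tool's input
#' dialect.
#'
#' @param bin Named list of `locus_alignment` matrices.
#' @param dir Output directory for the bundle.
#' @param mcmc_length Number of MCMC iterations (default 1e9).
#' @param sample_every Sampling interval in iterations (default 40000).
#' @param seed Integer seed from which the two chain seeds are derived.
#' @return Invisibly, the bundle directory.
#' @export
write_external_config <- function(bin, dir, mcmc_length = 1e9,
                                  sample_every = 40000, seed = 1) {
  stopifnot(is.list(bin), length(bin) >= 1L)
  ids <- names(bin)
  if (is.null(ids)) ids <- sprintf("locus_%03d", seq_along(bin))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(bin))
    write_fasta(bin[[i]], file.path(dir, paste0(ids[i], ".fasta")))
  seed1 <- derive_seed(seed, 1L)
  seed2 <- derive_seed(seed, 2L)
  stopifnot(seed1 != seed2)
  cfg <- c(
    paste("n_loci =", length(bin)),
    paste("loci =", paste(ids, collapse = " ")),
    paste("mcmc_length =", format(mcmc_length, scientific = FALSE)),
    paste("sample_every =", format(sample_every, scientific = FALSE)),
    paste("expected_samples_per_chain =",
          format(floor(mcmc_length / sample_every), scientific = FALSE)),
    paste("seed_chain1 =", seed1),
    paste("seed_chain2 =", seed2)
  )
  writeLines(cfg, file.path(dir, "config.txt"))
  writeLines(c(
    "#!/bin/sh",
    "# two independent chains of the external co-estimation tool",
    sprintf("coestimate --config config.txt --seed %d --out chain1", seed1),
    sprintf("coestimate --config config.txt --seed %d --out chain2", seed2)
  ), file.path(dir, "run.sh"))
  invisible(dir)
}

#' Read back a configuration bundle written by [write_external_config()]
#' @param dir Bundle directory.
#' @return List with `config` (named character) and `alignments`.
#' @export
read_external_config <- function(dir) {
  lines <- readLines(file.path(dir, "config.txt"), warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  cfg <- vapply(kv, `[`, character(1L), 2L)
  names(cfg) <- vapply(kv, `[`, character(1L), 1L)
  ids <- strsplit(cfg[["loci"]], "\\s+")[[1L]]
  alns <- lapply(ids, function(id)
    read_fasta(file.path(dir, paste0(id, ".fasta"))))
  names(alns) <- ids
  list(config = cfg, alignments = alns)
}

#' Read external co-estimation results (tree samples and trace logs)
#'
#' For each locus, reads the two chains' tree samples (newick lists or NEXUS
#' TREES blocks), removes burn-in from each chain, combines them
#' ([combine_chains()]), computes the maximum clade credibility point
#' estimate and subsamples `n_subsample` trees. Trace logs (tab-delimited,
#' leading state column) are burn-in-trimmed per chain and concatenated;
#' chains whose headers disagree are rejected.
#'
#' @param tree_files List (one element per locus) of length-2 character
#'   vectors: the two chain tree files.
#' @param trace_files Optional list of length-2 character vectors of chain
#'   trace logs, one per locus bin or run.
#' @param burnin_fraction Burn-in fraction per chain (default 0.5).
#' @param n_subsample Trees subsampled per locus (default 100).
#' @param seed Optional integer seed for subsampling.
#' @return A `coestimation_result` with provenance `"external"`.
#' @export
read_external_results <- function(tree_files, trace_files = NULL,
                                  burnin_fraction = 0.5, n_subsample = 100,
                                  seed = NULL) {
  stopifnot(is.list(tree_files), length(tree_files) >= 1L)
  ids <- names(tree_files)
  if (is.null(ids)) ids <- as.character(seq_along(tree_files))
  mccs <- vector("list", length(tree_files))
  samples <- vector("list", length(tree_files))
  for (i in seq_along(tree_files)) {
    tf <- tree_files[[i]]
    stopifnot(length(tf) == 2L)
    combined <- combine_chains(read_tree_sample(tf[1L]),
                               read_tree_sample(tf[2L]),
                               burnin_fraction = burnin_fraction)
    mccs[[i]] <- mcc_tree(combined)
    samples[[i]] <- subsample_trees(
      combined, n_subsample,
      seed = if (is.null(seed)) NULL else derive_seed(seed, i))
  }
  names(mccs) <- ids
  names(samples) <- ids
  traces <- NULL
  if (!is.null(trace_files)) {
    traces <- lapply(trace_files, function(tf) {
      if (length(tf) == 1L)
        return(read_trace_log(tf, burnin_fraction = burnin_fraction))
      a <- read_trace_log(tf[1L], burnin_fraction = burnin_fraction)
      b <- read_trace_log(tf[2L], burnin_fraction = burnin_fraction)
      if (!identical(names(a), names(b)))
        stop("trace headers differ between chains '", tf[1L], "' and '",
             tf[2L], "'")
      stats::setNames(lapply(seq_along(a), function(k)
        c(a[[k]], b[[k]])), names(a))
    })
  }
  out <- list(mcc_trees = mccs, tree_samples = samples, traces = traces,
              provenance = "external", seed = seed)
  class(out) <- "coestimation_result"
  out
}
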