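# shared fixtures: all data built in code at test time

# random rooted binary tree with branch lengths (ultrametric coalescent)
random_rooted_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ape::rcoal(n, tip.label = paste0("t", seq_len(n)))
}

# random (possibly unrooted) binary tree with branch lengths
random_unrooted_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ape::unroot(ape::rtree(n, tip.label = paste0("t", seq_len(n))))
}

# a triplet_table built by hand for one or more triples
manual_triplet_table <- function(triples, counts) {
  tab <- list(taxa = sort(unique(as.vector(triples))),
              triples = triples,
              counts = matrix(counts, nrow = nrow(triples), ncol = 3L,
                              byrow = TRUE,
                              dimnames = list(NULL,
                                              c("ab|c", "ac|b", "bc|a"))))
  class(tab) <- "triplet_table"
  tab
}

# 6-taxon species tree with all internal branches >= `internal` coalescent
# units (low ILS when internal >= 2)
low_ils_species_tree <- function(internal = 2) {
  s <- internal
  parse_newick(sprintf(
    "(((((a:1,b:1):%f,c:%f):%f,d:%f):%f,e:%f):%f,f:%f);",
    s, 1 + s, s, 1 + 2 * s, s, 1 + 3 * s, s, 1 + 4 * s))
}

# deterministic AR(1) series
ar1_series <- function(n, rho, seed) {
  set.seed(seed)
  x <- numeric(n)
  x[1] <- rnorm(1)
  innov <- rnorm(n - 1, sd = sqrt(1 - rho^2))
  for (i in 2:n) x[i] <- rho * x[i - 1] + innov[i - 1]
  x
}

# write a tab-delimited trace log
write_trace_fixture <- function(path, n = 100, stats = c("posterior",
                                                         "prior",
                                                         "likelihood"),
                                seed = 1, interval = 1000) {
  set.seed(seed)
  m <- cbind(state = seq(0, by = interval, length.out = n),
             matrix(rnorm(n * length(stats)), n,
                    dimnames = list(NULL, stats)))
  writeLines(c(paste(colnames(m), collapse = "\t"),
               apply(m, 1, paste, collapse = "\t")), path)
  path
}
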