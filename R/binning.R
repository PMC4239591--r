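## Step 1 of the pipeline: randomly partition loci into near-equal bins.

#' Randomly partition loci into near-equal bins
#'
#' Locus indices are shuffled by the seeded generator and dealt round-robin
#' into `ceiling(n_loci / bin_size)` bins, so any two bin sizes differ by at
#' most 1.
#'
#' @param n_loci Number of loci (>= 1).
#' @param bin_size Target loci per bin (default 25).
#' @param seed Optional integer seed; the partition is deterministic given
#'   it.
#' @return An object of class `locus_partition`: a list with `bins` (list of
#'   integer vectors), `bin_size` and `seed`.
#' @export
random_partition <- function(n_loci, bin_size = 25, seed = NULL) {
  if (!is.numeric(n_loci) || length(n_loci) != 1L || n_loci < 1)
    stop("'n_loci' must be a positive integer")
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size < 1)
    stop("'bin_size' must be a positive integer")
  n_loci <- as.integer(n_loci); bin_size <- as.integer(bin_size)
  if (!is.null(seed)) set.seed(seed)
  n_bins <- as.integer(ceiling(n_loci / bin_size))
  ord <- sample.int(n_loci)
  bins <- split(ord, rep_len(seq_len(n_bins), n_loci))
  bins <- lapply(unname(bins), sort)
  out <- list(bins = bins, bin_size = bin_size, seed = seed)
  class(out) <- "locus_partition"
  out
}

.validate_partition <- function(partition) {
  stopifnot(inherits(partition, "locus_partition"))
  all_idx <- unlist(partition$bins)
  if (anyDuplicated(all_idx))
    stop("invalid partition: duplicated locus indices")
  if (!setequal(all_idx, seq_along(all_idx)))
    stop("invalid partition: locus indices must cover 1..n exactly once")
  sizes <- lengths(partition$bins)
  if (length(sizes) > 1L && diff(range(sizes)) > 1L)
    stop("invalid partition: bin sizes differ by more than 1")
  invisible(partition)
}

#' Write a locus partition to a plain-text file
#'
#' One bin per line; locus identifiers are whitespace-separated. Locus
#' names, when given, replace the integer indices.
#'
#' @param partition A `locus_partition`.
#' @param path Output file.
#' @param locus_names Optional character vector of locus names, indexed by
#'   locus.
#' @export
write_partition <- function(partition, path, locus_names = NULL) {
  .validate_partition(partition)
  lines <- vapply(partition$bins, function(b) {
    ids <- if (is.null(locus_names)) as.character(b) else locus_names[b]
    paste(ids, collapse = " ")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a locus partition from a plain-text file
#'
#' @param path File written by [write_partition()] (integer locus indices).
#' @return A `locus_partition`.
#' @export
read_partition <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines))
    if (!nzchar(trimws(lines[i])))
      stop("partition file ", path, ": blank line at line ", i)
  bins <- lapply(seq_along(lines), function(i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    idx <- suppressWarnings(as.integer(toks))
    if (anyNA(idx))
      stop("partition file ", path, ": non-integer locus id at line ", i)
    sort(idx)
  })
  all_idx <- unlist(bins)
  dups <- unique(all_idx[duplicated(all_idx)])
  if (length(dups))
    stop("partition file ", path, ": duplicate locus ids: ",
         paste(dups, collapse = ", "))
  out <- list(bins = bins, bin_size = max(lengths(bins)), seed = NULL)
  class(out) <- "locus_partition"
  .validate_partition(out)
}
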