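# Independent brute-force oracles, deliberately naive and separate from the
# package's Rcpp counting path.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(s)), "", fixed = TRUE)[[1]]),
        collapse = "")
}

oracle_canonical <- function(s) {
  rc <- oracle_revcomp(s)
  if (s <= rc) s else rc
}

# window-by-window canonical k-mer counts of a sequence set
oracle_count <- function(seqs, k) {
  out <- new.env(parent = emptyenv())
  for (s in toupper(seqs)) {
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (grepl("[^ACGT]", w)) next
      w <- oracle_canonical(w)
      out[[w]] <- (if (is.null(out[[w]])) 0L else out[[w]]) + 1L
    }
  }
  keys <- sort(ls(out))
  stats::setNames(vapply(keys, function(k2) out[[k2]], integer(1)), keys)
}

# closed-form NB pmf via the gamma-function representation, r = 1/alpha,
# p = r / (r + mu)
oracle_nb_pmf <- function(x, mu, alpha) {
  r <- 1 / alpha
  p <- r / (r + mu)
  exp(lgamma(x + r) - lgamma(r) - lgamma(x + 1) + r * log(p) + x * log(1 - p))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_spectrum <- function(abundance, count, k = 21L) {
  kspectra:::new_kmer_spectrum(abundance, count, k)
}

withr_local_file <- function(name) file.path(tempdir(), name)

# enumerate all DNA strings of length k
all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE))
}
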