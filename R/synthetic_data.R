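random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Declarative description of a synthetic genome's repeat architecture
#'
#' Each block (n, L) embeds one random L-bp sequence n times in the genome.
#' The implied genome length is sum(n * L) plus the unique spacers that
#' separate embedded copies.
#'
#' @param blocks data frame (or list coercible to one) with columns
#'   `copy_number` and `length` (bp).
#' @param seed integer RNG seed; the emitted genome is byte-identical for a
#'   given spec.
#' @param gc GC fraction of the random sequence (default 0.5).
#' @param spacer_length length of the unique random spacer placed after each
#'   embedded segment (default 200 bp; must be >= k for spectra so that
#'   windows spanning copy boundaries stay unique).
#' @return a `genome_spec` object.
#' @export
genome_spec <- function(blocks, seed = 1L, gc = 0.5, spacer_length = 200L) {
  blocks <- as.data.frame(blocks)
  stopifnot(all(c("copy_number", "length") %in% names(blocks)),
            all(blocks$copy_number >= 1), all(blocks$length >= 1),
            gc > 0, gc < 1, spacer_length >= 1)
  structure(list(blocks = blocks, seed = as.integer(seed), gc = gc,
                 spacer_length = as.integer(spacer_length)),
            class = "genome_spec")
}

#' Generate a synthetic genome with prescribed repeat architecture
#'
#' For each block (n, L) a random L-bp sequence is embedded n times,
#' separated (and flanked) by unique random spacers; segment order is
#' shuffled so repeat copies are dispersed. The returned "true" repeat
#' profile is computed by [genome_copy_table()] on the emitted sequence, so
#' boundary windows and any rare random k-mer collisions are reflected
#' honestly rather than assumed away.
#'
#' @param spec a [genome_spec()].
#' @param k k-mer length used for the true profile (default 21).
#' @return list with `sequence` (single character string), `length`,
#'   `profile` (exact `repeat_profile`), and the `spec`.
#' @export
generate_genome <- function(spec, k = 21L) {
  stopifnot(inherits(spec, "genome_spec"))
  if (sum(spec$blocks$copy_number * spec$blocks$length) < k)
    stop("spec implies a genome shorter than k", call. = FALSE)
  seq <- local_seed(spec$seed, {
    segments <- character(0)
    for (b in seq_len(nrow(spec$blocks))) {
      n <- spec$blocks$copy_number[b]
      unit <- random_dna(spec$blocks$length[b], spec$gc)
      segments <- c(segments, rep(unit, n))
    }
    segments <- segments[sample.int(length(segments))]
    spacers <- vapply(seq_along(segments),
                      function(i) random_dna(spec$spacer_length, spec$gc),
                      character(1))
    paste(as.vector(rbind(segments, spacers)), collapse = "")
  })
  list(sequence = seq, length = nchar(seq),
       profile = genome_copy_table(seq, k = k), spec = spec)
}

#' Shotgun read simulation parameters
#'
#' @param read_length read length in bp (default 76, a typical short-read
#'   Illumina length).
#' @param depth mean fold-coverage (> 0).
#' @param error_rate independent per-base substitution probability in
#'   \[0, 1).
#' @param seed integer RNG seed.
#' @return a `sim_params` object.
#' @export
sim_params <- function(read_length = 76L, depth, error_rate = 0, seed = 1L) {
  stopifnot(read_length >= 1, depth > 0, error_rate >= 0, error_rate < 1)
  structure(list(read_length = as.integer(read_length), depth = depth,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sim_params")
}

BASES <- c("A", "C", "G", "T")

# substitute bases at global positions of the read pool, uniformly over the
# three alternatives; vectorised in rounds so that multiple errors landing in
# the same read are applied one per round
inject_errors <- function(reads, error_rate) {
  if (error_rate == 0) return(reads)
  L <- nchar(reads[1L])
  total <- length(reads) * L
  n_err <- rbinom(1L, total, error_rate)
  if (n_err == 0) return(reads)
  pos <- sample.int(total, n_err)
  read_idx <- (pos - 1L) %/% L + 1L
  base_pos <- (pos - 1L) %% L + 1L
  shift <- sample.int(3L, n_err, replace = TRUE)   # 1..3 places away, mod 4
  ord <- order(read_idx)
  round <- sequence(rle(read_idx[ord])$lengths)    # 1, 2, ... within each read
  for (r in seq_len(max(round))) {
    j <- ord[round == r]                           # distinct reads this round
    i <- read_idx[j]; p <- base_pos[j]
    old <- match(substr(reads[i], p, p), BASES)
    repl <- BASES[(old - 1L + shift[j]) %% 4L + 1L]
    x <- reads[i]
    substr(x, p, p) <- repl
    reads[i] <- x
  }
  reads
}

#' Simulate uniform-coverage shotgun reads
#'
#' Draws uniform random start positions on both strands until the total
#' emitted bases reach `depth * genome length` (within one read), then
#' substitutes each base independently with probability `error_rate`
#' (uniform over the three alternatives). Coverage is therefore even —
#' the regime in which per-k-mer abundances are Poisson-mixed. Reads are
#' single-end; deterministic given the seed.
#'
#' @param genome genome sequence: single character string or the list
#'   returned by [generate_genome()].
#' @param params a [sim_params()].
#' @return character vector of reads.
#' @export
simulate_reads <- function(genome, params) {
  stopifnot(inherits(params, "sim_params"))
  if (is.list(genome)) genome <- genome$sequence
  stopifnot(is.character(genome), length(genome) == 1L)
  G <- nchar(genome)
  L <- params$read_length
  if (G < L) stop("genome shorter than read length", call. = FALSE)
  n_reads <- ceiling(params$depth * G / L)
  local_seed(params$seed, {
    starts <- sample.int(G - L + 1L, n_reads, replace = TRUE)
    reads <- substring(genome, starts, starts + L - 1L)
    rev <- runif(n_reads) < 0.5
    if (any(rev))
      reads[rev] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads[rev])))
    inject_errors(reads, params$error_rate)
  })
}

#' Write reads as FASTQ
#'
#' Constant placeholder quality ("I" = Q40).
#'
#' @param reads character vector of reads.
#' @param path output path (".gz" suffix gzips).
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  qual <- strrep("I", nchar(reads))
  writeLines(paste0("@read", seq_along(reads), "\n", reads, "\n+\n", qual), con)
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param sequences named or unnamed character vector.
#' @param path output path (".gz" suffix gzips).
#' @export
write_fasta <- function(sequences, path) {
  nm <- names(sequences) %||% paste0("seq", seq_along(sequences))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste0(">", nm, "\n", sequences), con)
  invisible(path)
}

#' End-to-end parameter-recovery experiment
#'
#' Generates a genome from `spec`, simulates reads with `params`, counts
#' k-mers, fits the mixture model, and compares the estimates against the
#' exact truth of the emitted genome. If the spectrum has no resolvable
#' principal peak (coverage too low), the report flags the failure instead
#' of returning estimates.
#'
#' @param spec a [genome_spec()].
#' @param params a [sim_params()].
#' @param config a [fit_config()].
#' @param k k-mer length (default 21).
#' @return list with `status` ("ok"; "unreliable" when the fitted coverage
#'   peak is below ~10x; "low_coverage" when no peak resolves), the emitted genome
#'   `true_length` and `true_profile`, and on success the `fit`,
#'   `genome_size_estimate`, `size_relative_error`, and `estimated_profile`.
#' @export
recovery_experiment <- function(spec, params, config = fit_config(), k = 21L) {
  genome <- generate_genome(spec, k = k)
  reads <- simulate_reads(genome, params)
  spectrum <- kmer_spectrum(reads, k = k)
  fit <- tryCatch(fit_spectrum(spectrum, config),
                  kspectra_low_coverage = function(e) e)
  if (inherits(fit, "condition")) {
    return(list(status = "low_coverage", message = conditionMessage(fit),
                true_length = genome$length, true_profile = genome$profile,
                spectrum = spectrum))
  }
  est <- genome_size_estimate(fit)
  list(status = if (fit$reliable) "ok" else "unreliable",
       true_length = genome$length,
       true_profile = genome$profile,
       spectrum = spectrum,
       fit = fit,
       genome_size_estimate = est,
       size_relative_error = (est - genome$length) / genome$length,
       estimated_profile = repeat_profile_from_model(fit))
}
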