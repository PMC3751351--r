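#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the A/C/G/T alphabet.
#'
#' @param x character vector of DNA strings (A, C, G, T; case-insensitive).
#' @return character vector of reverse complements, uppercase.
#' @examples
#' reverse_complement(c("ACGT", "AAACC"))
#' @export
reverse_complement <- function(x) {
  x <- toupper(x)
  rev_one <- function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  vapply(x, function(s) chartr("ACGT", "TGCA", rev_one(s)), character(1),
         USE.NAMES = FALSE)
}

#' Canonical form of a k-mer
#'
#' The canonical representative of a k-mer is the lexicographic minimum of
#' the k-mer and its reverse complement; counting canonical forms collapses
#' the strand ambiguity of shotgun reads. The operation is idempotent.
#'
#' @param kmer character vector of DNA strings over A, C, G, T
#'   (case-insensitive).
#' @return character vector of canonical k-mers, uppercase.
#' @examples
#' canonicalize("TTTTT")   # "AAAAA"
#' canonicalize("AAACC")   # unchanged
#' @export
canonicalize <- function(kmer) {
  kmer <- toupper(kmer)
  if (any(grepl("[^ACGT]", kmer)))
    stop("k-mer contains non-ACGT characters", call. = FALSE)
  rc <- reverse_complement(kmer)
  ifelse(kmer <= rc, kmer, rc)
}

#' Number of distinct canonical k-mers
#'
#' Size of the canonical k-mer space over \{A,C,G,T\}: reverse-complement
#' degeneracy halves the 4^k strings, except that for even k the
#' 4^(k/2) palindromic k-mers are their own reverse complement (no
#' odd-length DNA string can be). Hence 4^k / 2 for odd k and
#' (4^k + 4^(k/2)) / 2 for even k — approximately 4^k / 2 throughout.
#'
#' @param k k-mer length (positive integer).
#' @return number of distinct canonical k-mers (numeric; exact for k <= 31).
#' @examples
#' n_canonical_kmers(15)  # 536870912, > 5e8
#' @export
n_canonical_kmers <- function(k) {
  stopifnot(length(k) == 1L, k >= 1, k == as.integer(k))
  if (k %% 2 == 1) 4^k / 2 else (4^k + 4^(k / 2)) / 2
}

as_char_seqs <- function(sequences) {
  if (inherits(sequences, "XStringSet") || inherits(sequences, "XString"))
    sequences <- as.character(sequences)
  if (!is.character(sequences))
    stop("sequences must be a character vector or a Biostrings XStringSet",
         call. = FALSE)
  toupper(sequences)
}

#' Count canonical k-mers in a sequence collection
#'
#' Slides a window of length `k` over every sequence and counts each
#' all-ACGT window under its canonical form. Windows containing any other
#' symbol (N, IUPAC ambiguity codes) are skipped; sequences shorter than
#' `k` contribute nothing. A repeat-free sequence of length l contributes
#' l - k + 1 distinct k-mers.
#'
#' @param sequences character vector or `Biostrings::DNAStringSet` of reads
#'   or contigs.
#' @param k k-mer length, 1--31 (default 21).
#' @return a `kmer_count_table`: named integer vector (canonical k-mer ->
#'   count) with attribute `k`.
#' @examples
#' count_kmers(c("ACGTACGT"), k = 3)
#' @export
count_kmers <- function(sequences, k = 21L) {
  stopifnot(length(k) == 1L, k == as.integer(k))
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k > 31) stop("k must be <= 31", call. = FALSE)
  counts <- .cpp_kmer_counts(as_char_seqs(sequences), as.integer(k))
  structure(counts, k = as.integer(k), class = "kmer_count_table")
}

#' @export
print.kmer_count_table <- function(x, ...) {
  cat("kmer_count_table: ", length(x), " distinct canonical ",
      attr(x, "k"), "-mers, ", format(sum(as.numeric(x)), big.mark = ","),
      " instances\n", sep = "")
  invisible(x)
}

new_kmer_spectrum <- function(abundance, count, k) {
  keep <- count > 0
  df <- data.frame(abundance = as.integer(abundance[keep]),
                   count = as.numeric(count[keep]))
  if (anyDuplicated(df$abundance)) {
    agg <- tapply(df$count, df$abundance, sum)
    df <- data.frame(abundance = as.integer(names(agg)),
                     count = as.numeric(agg))
  }
  df <- df[order(df$abundance), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, k = as.integer(k), class = c("kmer_spectrum", "data.frame"))
}

#' Build an abundance spectrum from a k-mer count table
#'
#' The spectrum (abundance histogram) records, for each abundance x, the
#' number z_x of distinct canonical k-mers observed exactly x times.
#' Conservation: sum(x * z_x) equals the total number of k-mer instances and
#' sum(z_x) the number of distinct k-mers.
#'
#' @param table a `kmer_count_table` from [count_kmers()].
#' @return a `kmer_spectrum`: data frame with columns `abundance`, `count`.
#' @export
build_spectrum <- function(table) {
  stopifnot(inherits(table, "kmer_count_table"))
  if (length(table) == 0L)
    return(new_kmer_spectrum(integer(0), numeric(0), attr(table, "k")))
  tab <- table(as.integer(table))
  new_kmer_spectrum(as.integer(names(tab)), as.numeric(tab), attr(table, "k"))
}

#' k-mer abundance spectrum of reads or contigs
#'
#' One-step spectrum construction. For large read sets this avoids
#' materialising the per-k-mer table: counting and histogramming happen in
#' one pass in C++.
#'
#' @inheritParams count_kmers
#' @return a `kmer_spectrum` data frame (`abundance`, `count`).
#' @export
kmer_spectrum <- function(sequences, k = 21L) {
  if (inherits(sequences, "kmer_count_table")) return(build_spectrum(sequences))
  stopifnot(length(k) == 1L, k == as.integer(k))
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k > 31) stop("k must be <= 31", call. = FALSE)
  df <- .cpp_kmer_spectrum(as_char_seqs(sequences), as.integer(k))
  new_kmer_spectrum(df$abundance, df$count, k)
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("kmer_spectrum (k = ", attr(x, "k"), "): ", nrow(x), " abundance bins, ",
      format(sum(x$count), big.mark = ","), " distinct k-mers, ",
      format(sum(x$abundance * x$count), big.mark = ","), " instances\n",
      sep = "")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10L))
  invisible(x)
}

new_repeat_profile <- function(copy_number, unique_amount, k = NA_integer_) {
  keep <- unique_amount > 0
  df <- data.frame(copy_number = as.integer(copy_number[keep]),
                   unique_bp = as.numeric(unique_amount[keep]))
  df <- df[order(df$copy_number), , drop = FALSE]
  df$total_bp <- df$copy_number * df$unique_bp
  rownames(df) <- NULL
  structure(df, k = as.integer(k),
            class = c("repeat_profile", "data.frame"))
}

#' Exact per-copy-number repeat table of an assembled genome
#'
#' Counts canonical k-mers across the assembled sequence(s) and tabulates,
#' for each copy number n, the number of distinct k-mers occurring exactly
#' n times (`unique_bp`, a bp-equivalent since each distinct k-mer stands
#' for ~1 bp of unique sequence) and the total n * unique_bp. The cumulative
#' total over rows is the k-mer-space genome size.
#'
#' @param genome character vector / `DNAStringSet` of contigs, or a file
#'   path readable by [read_sequences()].
#' @param k k-mer length (default 21).
#' @return a `repeat_profile` data frame with columns `copy_number`,
#'   `unique_bp`, `total_bp`.
#' @export
genome_copy_table <- function(genome, k = 21L) {
  if (is.character(genome) && length(genome) >= 1L &&
      all(file.exists(genome)) && !any(grepl("^[ACGTNacgtn]+$", genome)))
    genome <- read_sequences(genome)
  spec <- kmer_spectrum(genome, k = k)
  new_repeat_profile(spec$abundance, spec$count, k = attr(spec, "k"))
}

#' @export
print.repeat_profile <- function(x, ...) {
  cat("repeat_profile: genome size ",
      format(genome_size_estimate(x), big.mark = ","), " bp, ",
      format(unique_kmer_estimate(x), big.mark = ","), " unique k-mers\n",
      sep = "")
  print.data.frame(as.data.frame(x))
  invisible(x)
}

# ---- file I/O ---------------------------------------------------------------

detect_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!length(first)) stop("empty sequence file: ", path, call. = FALSE)
  if (startsWith(first, ">")) "fasta"
  else if (startsWith(first, "@")) "fastq"
  else stop("unrecognised sequence format: ", path, call. = FALSE)
}

#' Read sequences from FASTA/FASTQ files
#'
#' Reads one or more FASTA or FASTQ files (plain or gzipped; format
#' auto-detected per file) and concatenates them into one `DNAStringSet`.
#'
#' @param files character vector of file paths.
#' @return a `Biostrings::DNAStringSet`.
#' @export
read_sequences <- function(files) {
  stopifnot(is.character(files), length(files) >= 1L, all(file.exists(files)))
  sets <- lapply(files, function(f)
    Biostrings::readDNAStringSet(f, format = detect_format(f)))
  do.call(c, sets)
}

#' Read and write abundance histograms
#'
#' Plain-text histogram format: one bin per line, `abundance count`
#' separated by whitespace, ascending abundance — interoperable with the
#' histogram output of common k-mer counters, so externally produced
#' histograms can be fitted directly.
#'
#' @param path file path.
#' @param k k-mer length to record on the returned spectrum (the format
#'   itself does not carry k).
#' @return `read_histogram()` returns a `kmer_spectrum`.
#' @export
read_histogram <- function(path, k = 21L) {
  df <- read.table(path, header = FALSE, col.names = c("abundance", "count"))
  if (any(df$abundance <= 0) || any(df$count < 0))
    stop("invalid histogram: abundances must be positive, counts non-negative",
         call. = FALSE)
  if (anyDuplicated(df$abundance))
    stop("invalid histogram: duplicated abundance values", call. = FALSE)
  new_kmer_spectrum(df$abundance, df$count, k)
}

#' @param spectrum a `kmer_spectrum`.
#' @rdname read_histogram
#' @export
write_histogram <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  writeLines(sprintf("%d %s", spectrum$abundance,
                     format(spectrum$count, scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}

#' Write a repeat profile as TSV
#'
#' Columns `copy_number`, `unique_bp`, `total_bp`, with a final cumulative
#' row summing the unique and total columns.
#'
#' @param profile a `repeat_profile`.
#' @param path output file path.
#' @export
write_repeat_profile <- function(profile, path) {
  stopifnot(inherits(profile, "repeat_profile"))
  df <- as.data.frame(profile)
  cum <- data.frame(copy_number = NA_integer_,
                    unique_bp = sum(df$unique_bp),
                    total_bp = sum(df$total_bp))
  out <- rbind(df, cum)
  out$copy_number <- ifelse(is.na(out$copy_number), "cumulative",
                            as.character(out$copy_number))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
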