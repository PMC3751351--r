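test_that("canonicalize returns the lexicographic minimum of strand pair", {
  expect_identical(canonicalize("AAACC"), "AAACC")  # revcomp GGTTT sorts later
  expect_identical(canonicalize("TTTTT"), "AAAAA")
  expect_identical(canonicalize(canonicalize("GATTACA")),
                   canonicalize("GATTACA"))          # idempotent
  expect_identical(canonicalize("acgt"), "ACGT")     # case folded
  expect_error(canonicalize("ACGNT"), "non-ACGT")
})

test_that("canonical k-mer space has the expected size", {
  k5 <- unique(vapply(all_kmers(5), oracle_canonical, character(1)))
  expect_length(k5, 512)                     # 4^5 / 2, no odd palindromes
  expect_identical(n_canonical_kmers(5), 512)
  k3 <- unique(vapply(all_kmers(3), oracle_canonical, character(1)))
  expect_identical(n_canonical_kmers(3), as.numeric(length(k3)))
  k4 <- unique(vapply(all_kmers(4), oracle_canonical, character(1)))
  # even k: 4^(k/2) palindromic k-mers are their own reverse complement
  expect_identical(n_canonical_kmers(4), as.numeric(length(k4)))
})

test_that("count_kmers matches window arithmetic and the brute-force oracle", {
  set.seed(41)
  s <- random_dna_str(100)
  tab <- count_kmers(s, k = 21)
  expect_s3_class(tab, "kmer_count_table")
  expect_length(tab, 80)                     # l - k + 1 windows, repeat-free
  expect_true(all(tab == 1L))
  expect_identical(as.integer(tab), unname(oracle_count(s, 21)[names(tab)]))

  expect_length(count_kmers(random_dna_str(20), k = 21), 0L)  # no full window
  expect_error(count_kmers(s, k = 0), "positive")
  expect_error(count_kmers(s, k = 35), "31")

  reads <- replicate(5, random_dna_str(60))
  got <- count_kmers(reads, k = 11)
  want <- oracle_count(reads, 11)
  expect_identical(names(got), names(want))
  expect_identical(as.integer(got), unname(want))
})

test_that("counting is strand-invariant and handles ambiguity codes", {
  set.seed(42)
  s <- random_dna_str(50)
  one <- count_kmers(s, k = 9)
  both <- count_kmers(c(s, oracle_revcomp(s)), k = 9)
  expect_identical(names(both), names(one))           # same canonical key set
  expect_identical(as.integer(both), 2L * as.integer(one))

  # full strand invariance on a set
  seqs <- replicate(4, random_dna_str(40))
  expect_identical(
    unclass(count_kmers(seqs, k = 13)),
    unclass(count_kmers(vapply(seqs, oracle_revcomp, character(1)), k = 13)))

  # windows containing N (or other codes) are skipped entirely
  with_n <- paste0(substr(s, 1, 20), "N", substr(s, 21, 50))
  expect_identical(unname(oracle_count(with_n, 9)),
                   as.integer(count_kmers(with_n, k = 9)))
})

test_that("build_spectrum bins counts and conserves totals", {
  tab <- structure(c(K1 = 1L, K2 = 1L, K3 = 3L), k = 2L,
                   class = "kmer_count_table")
  sp <- build_spectrum(tab)
  expect_equal(sp$abundance, c(1L, 3L))
  expect_equal(sp$count, c(2, 1))

  empty <- count_kmers(character(0), k = 5)
  expect_identical(nrow(build_spectrum(empty)), 0L)

  set.seed(43)
  reads <- replicate(20, random_dna_str(45))
  tab2 <- count_kmers(reads, k = 7)
  sp2 <- build_spectrum(tab2)
  expect_equal(sum(sp2$abundance * sp2$count), sum(as.numeric(tab2)))
  expect_equal(sum(sp2$count), length(tab2))
  # one-pass spectrum agrees with table-then-bin
  expect_equal(as.data.frame(kmer_spectrum(reads, k = 7)), as.data.frame(sp2))
})

test_that("genome_copy_table tabulates exact repeat copy numbers", {
  set.seed(44)
  contig <- random_dna_str(100)
  prof <- genome_copy_table(contig, k = 21)
  expect_equal(as.data.frame(prof),
               data.frame(copy_number = 1L, unique_bp = 80, total_bp = 80),
               ignore_attr = TRUE)
  expect_equal(genome_size_estimate(prof), 80)

  # unique-flank + B + unique-spacer + B: copy-2 row equals the brute-force
  # window count
  B <- random_dna_str(50)
  contig2 <- paste0(random_dna_str(80), B, random_dna_str(60), B,
                    random_dna_str(70))
  prof2 <- genome_copy_table(contig2, k = 21)
  oc <- oracle_count(contig2, 21)
  expect_equal(prof2$unique_bp[prof2$copy_number == 2], sum(oc == 2))
  expect_equal(prof2$unique_bp[prof2$copy_number == 1], sum(oc == 1))
  expect_equal(genome_size_estimate(prof2), sum(oc))

  # spectrum of a genome counted as a read set agrees with the copy table
  sp <- kmer_spectrum(contig2, k = 21)
  expect_equal(sp$abundance, prof2$copy_number)
  expect_equal(sp$count, prof2$unique_bp)
})

test_that("histogram text format round-trips and rejects bad input", {
  sp <- make_spectrum(c(1L, 3L, 57L), c(120, 4, 1e6))
  path <- withr_local_file("hist.txt")
  write_histogram(sp, path)
  back <- read_histogram(path)
  expect_equal(as.data.frame(back), as.data.frame(sp))

  writeLines(c("5 10", "5 3"), path)
  expect_error(read_histogram(path), "duplicated")
  writeLines(c("0 10"), path)
  expect_error(read_histogram(path), "positive")
})

test_that("sequence files round-trip through FASTA and FASTQ, plain and gzip", {
  set.seed(45)
  seqs <- replicate(3, random_dna_str(70))
  fa <- withr_local_file("x.fasta")
  fq <- withr_local_file("x.fastq.gz")
  write_fasta(seqs, fa)
  write_fastq(seqs, fq)
  expect_equal(unname(as.character(read_sequences(fa))), seqs)
  expect_equal(unname(as.character(read_sequences(fq))), seqs)
  # multiple files concatenate
  expect_length(read_sequences(c(fa, fq)), 6L)
})

test_that("repeat profile TSV carries a cumulative row", {
  prof <- kspectra:::new_repeat_profile(c(1L, 7L), c(100, 10))
  path <- withr_local_file("prof.tsv")
  write_repeat_profile(prof, path)
  lines <- readLines(path)
  expect_equal(lines[1], "copy_number\tunique_bp\ttotal_bp")
  expect_match(lines[length(lines)], "^cumulative\t110\t170$")
})
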