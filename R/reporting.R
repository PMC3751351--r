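#' Transformed spectrum for visualisation
#'
#' Multiplies the number of distinct k-mers at each abundance by that
#' abundance, so that the area near high-copy peaks is visible on a plot.
#' Purely presentational: never used in fitting, and the sum of the
#' transformed values equals the total number of k-mer instances.
#'
#' @param spectrum a `kmer_spectrum`.
#' @return data frame with columns `abundance`, `transformed`
#'   (= abundance * count).
#' @export
transformed_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  data.frame(abundance = spectrum$abundance,
             transformed = as.numeric(spectrum$abundance) * spectrum$count)
}

#' Rank-order statistics of k-mer abundances
#'
#' Two sampling-depth-stable spectrum summaries: the rank-order
#' distribution of k-mer abundances (abundances sorted descending) and the
#' cumulative fraction of all k-mer instances consumed by the top-r
#' k-mers. For a spectrum the ranks are grouped by abundance bin (each bin
#' covers `count` consecutive ranks), which is exact and avoids expanding
#' millions of k-mers.
#'
#' @param x a `kmer_count_table`, a `kmer_spectrum`, or a plain vector of
#'   per-k-mer counts.
#' @return data frame with columns `rank` (last rank of the group),
#'   `abundance`, `cumulative_fraction` (non-decreasing, ending at 1).
#' @export
rank_order_stats <- function(x) UseMethod("rank_order_stats")

#' @export
rank_order_stats.default <- function(x) {
  x <- as.numeric(x)
  if (!length(x)) stop("empty input", call. = FALSE)
  x <- sort(x, decreasing = TRUE)
  data.frame(rank = seq_along(x), abundance = x,
             cumulative_fraction = cumsum(x) / sum(x))
}

#' @export
rank_order_stats.kmer_count_table <- function(x) {
  rank_order_stats(as.integer(unclass(x)))
}

#' @export
rank_order_stats.kmer_spectrum <- function(x) {
  if (!nrow(x)) stop("empty input", call. = FALSE)
  ord <- order(x$abundance, decreasing = TRUE)
  ab <- x$abundance[ord]; z <- x$count[ord]
  data.frame(rank = cumsum(z), abundance = ab,
             cumulative_fraction = cumsum(ab * z) / sum(ab * z))
}

default_copy_bins <- function() {
  data.frame(lo = c(1:10, 11, 21), hi = c(1:10, 20, 79),
             label = c(paste0(1:10, "x"), "11x-20x", "21x-79x"))
}

bin_profile <- function(profile, bins) {
  unique_bp <- numeric(nrow(bins))
  total_bp <- numeric(nrow(bins))
  for (i in seq_len(nrow(bins))) {
    sel <- profile$copy_number >= bins$lo[i] & profile$copy_number <= bins$hi[i]
    unique_bp[i] <- sum(profile$unique_bp[sel])
    total_bp[i] <- sum(profile$total_bp[sel])
  }
  above <- profile$copy_number > max(bins$hi)
  list(rows = data.frame(copy_number = bins$label, unique_bp = unique_bp,
                         total_bp = total_bp),
       above = data.frame(unique_bp = sum(profile$unique_bp[above]),
                          total_bp = sum(profile$total_bp[above])))
}

#' Side-by-side repeat-structure table
#'
#' Formats one or more repeat profiles into a binned copy-number table:
#' one row per bin (single rows 1x..10x and ranges 11x-20x, 21x-79x by
#' default; configurable), an overflow row when any profile has copy
#' numbers above the last bin, and a final row of cumulative totals (the
#' genome-size estimates).
#'
#' @param profiles a `repeat_profile` or named list of them.
#' @param bins data frame with columns `lo`, `hi`, `label`; default
#'   `1x..10x`, `11x-20x`, `21x-79x`.
#' @return data frame (one `unique`/`total` column pair per profile);
#'   attribute `tsv` carries the tab-separated text rendering.
#' @export
report_table <- function(profiles, bins = default_copy_bins()) {
  if (inherits(profiles, "repeat_profile")) profiles <- list(profile = profiles)
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "repeat_profile")))
  nm <- names(profiles) %||% paste0("profile", seq_along(profiles))
  out <- data.frame(copy_number = c(bins$label, ">", "cumulative"))
  for (i in seq_along(profiles)) {
    b <- bin_profile(profiles[[i]], bins)
    out[[paste0(nm[i], ".unique")]] <- c(b$rows$unique_bp, b$above$unique_bp,
                                         unique_kmer_estimate(profiles[[i]]))
    out[[paste0(nm[i], ".total")]] <- c(b$rows$total_bp, b$above$total_bp,
                                        genome_size_estimate(profiles[[i]]))
  }
  if (all(out[out$copy_number == ">", -1L] == 0))
    out <- out[out$copy_number != ">", , drop = FALSE]
  rownames(out) <- NULL
  tsv <- paste(capture_tsv(out), collapse = "\n")
  structure(out, tsv = tsv)
}

capture_tsv <- function(df) {
  c(paste(names(df), collapse = "\t"),
    apply(df, 1L, function(r) paste(r, collapse = "\t")))
}
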