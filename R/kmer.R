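#' k-mer spectrum configuration
#'
#' @param k k-mer length (default 23, the classic genome-profiling choice;
#'   odd k avoids palindromic self-complementary k-mers).
#' @param smoothing_window odd window (bins) of the centred moving average
#'   applied before peak detection (default 5).
#' @param multiplicity_cap histogram cap; k-mers seen more often are binned
#'   at the cap (default 10000).
#' @param peak_tolerance relative tolerance for matching secondary peaks to
#'   their expected positions 0.5x / 2x / 3x the main peak (default 0.12 —
#'   wide enough for the drift real duplication peaks show).
#' @return a `spectrum_config` list.
#' @export
spectrum_config <- function(k = 23L, smoothing_window = 5L,
                            multiplicity_cap = 10000L,
                            peak_tolerance = 0.12) {
  stopifnot(k >= 3L, smoothing_window >= 1L, smoothing_window %% 2L == 1L,
            multiplicity_cap >= 1L, peak_tolerance > 0)
  structure(list(k = as.integer(k),
                 smoothing_window = as.integer(smoothing_window),
                 multiplicity_cap = as.integer(multiplicity_cap),
                 peak_tolerance = peak_tolerance),
            class = "spectrum_config")
}

#' Count canonical k-mers into a multiplicity histogram
#'
#' Counts every k-long window of every read in canonical form (the
#' lexicographic minimum of the k-mer and its reverse complement, so the
#' histogram is invariant to read strand) and tabulates how many distinct
#' k-mers occur with each multiplicity. Windows containing `N` are skipped.
#'
#' @param reads a [read_set()] or plain character vector of sequences.
#' @param config a [spectrum_config()] (or just `k` via that constructor).
#' @return a `kmer_histogram`: data.frame with columns `multiplicity` and
#'   `count`, with attributes `total_kmers` (number of k-mer instances
#'   counted), `distinct_kmers`, and `k`.
#' @export
count_kmers <- function(reads, config = spectrum_config()) {
  seqs <- if (inherits(reads, "read_set")) reads$seq else as.character(reads)
  res <- kmer_hist_cpp(seqs, config$k, config$multiplicity_cap)
  if (res$total_kmers == 0) {
    stop("no countable k-mer: all reads shorter than k = ", config$k,
         " or all windows contain N")
  }
  out <- data.frame(multiplicity = res$multiplicity, count = res$count)
  attr(out, "total_kmers") <- res$total_kmers
  attr(out, "distinct_kmers") <- res$distinct_kmers
  attr(out, "k") <- config$k
  class(out) <- c("kmer_histogram", "data.frame")
  out
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat("kmer_histogram (k =", attr(x, "k"), "):",
      format(attr(x, "distinct_kmers"), big.mark = ","), "distinct k-mers,",
      format(attr(x, "total_kmers"), big.mark = ","), "instances\n")
  invisible(x)
}

#' Write / read a k-mer histogram as 2-column TSV
#'
#' The multiplicity/count layout k-mer counters conventionally emit.
#'
#' @param hist a `kmer_histogram`.
#' @param path file path.
#' @param k k-mer length to attach on read (stored nowhere in the TSV).
#' @return `write_kmer_hist`: `path` invisibly; `read_kmer_hist`: a
#'   `kmer_histogram`.
#' @export
write_kmer_hist <- function(hist, path) {
  utils::write.table(as.data.frame(hist)[, c("multiplicity", "count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_kmer_hist
#' @export
read_kmer_hist <- function(path, k = NA_integer_) {
  df <- utils::read.table(path, sep = "\t", col.names = c("multiplicity",
                                                          "count"))
  df <- df[order(df$multiplicity), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "total_kmers") <- sum(df$multiplicity * df$count)
  attr(df, "distinct_kmers") <- sum(df$count)
  attr(df, "k") <- k
  class(df) <- c("kmer_histogram", "data.frame")
  df
}

# Dense count vector f(1..max) from a sparse histogram.
dense_counts <- function(hist) {
  f <- numeric(max(hist$multiplicity))
  f[hist$multiplicity] <- hist$count
  f
}

# Centred moving average with window w (odd); edges use the available span.
smooth_counts <- function(f, w) {
  if (w <= 1L) return(f)
  h <- (w - 1L) %/% 2L
  n <- length(f)
  cs <- cumsum(c(0, f))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Fit a descriptive model to a k-mer spectrum
#'
#' Characterises the multiplicity spectrum by smoothed local extrema: the
#' error cutoff is the first local minimum after multiplicity 1 (separating
#' the error tail from genomic k-mers), the main peak is the smoothed-count
#' argmax beyond the cutoff (the k-mer coverage depth of the diploid
#' single-copy genome), and secondary local maxima near 0.5x, 2x and 3x the
#' main peak are classified as heterozygosity (HET), duplication (DUP) and
#' triplication (TRIP) peaks. The genome size is estimated by
#' [estimate_genome_size()].
#'
#' @param hist a `kmer_histogram`.
#' @param config a [spectrum_config()].
#' @return a `spectrum_model` with fields `error_cutoff`, `main_peak`,
#'   `secondary_peaks` (data.frame multiplicity/class),
#'   `heterozygous_peak_detected`, `genome_size`, plus the inputs.
#' @export
fit_spectrum <- function(hist, config = spectrum_config()) {
  stopifnot(inherits(hist, "kmer_histogram"))
  if (nrow(hist) < 2L) stop("degenerate histogram: fewer than 2 occupied multiplicities")
  f <- dense_counts(hist)
  s <- smooth_counts(f, config$smoothing_window)
  n <- length(s)
  # first local minimum after m = 1
  cutoff <- NA_integer_
  for (m in 2:(n - 1L)) {
    if (s[m] <= s[m - 1L] && s[m] <= s[m + 1L] && s[m + 1L] > s[m]) {
      cutoff <- m
      break
    }
  }
  if (is.na(cutoff)) {
    if (which.max(s) <= 1L) {
      stop("no local minimum in the spectrum (monotone histogram); ",
           "coverage too shallow to separate errors from genomic k-mers")
    }
    cutoff <- 0L # spectrum rises from the start: no error component to cut
  }
  if (cutoff + 1L > n) stop("error cutoff at the end of the spectrum")
  above <- (cutoff + 1L):n
  main_peak <- above[which.max(s[above])]
  # k-mer coverage depth: count-weighted centroid of the unsmoothed counts
  # over [0.5, 1.5] x peak — finer than the integer bin position, wide
  # enough to avoid skew bias, and clear of the 0.5x/2x secondary peaks
  win <- max(cutoff + 1L, ceiling(0.5 * main_peak)):min(n, floor(1.5 * main_peak))
  lambda <- sum(win * f[win]) / sum(f[win])

  # local maxima beyond the cutoff, excluding the main peak
  is_max <- c(FALSE, diff(sign(diff(s))) < 0, FALSE)
  cand <- which(is_max)
  cand <- setdiff(cand[cand > cutoff], main_peak)
  classes <- c(HET = 0.5, DUP = 2, TRIP = 3)
  sec <- data.frame(multiplicity = integer(0), class = character(0),
                    stringsAsFactors = FALSE)
  for (cl in names(classes)) {
    expected <- classes[[cl]] * main_peak
    ok <- cand[abs(cand - expected) <= config$peak_tolerance * expected]
    if (length(ok)) {
      best <- ok[which.max(s[ok])]
      sec <- rbind(sec, data.frame(multiplicity = best, class = cl,
                                   stringsAsFactors = FALSE))
    }
  }
  model <- structure(list(
    error_cutoff = cutoff,
    main_peak = main_peak,
    lambda = lambda,
    secondary_peaks = sec,
    heterozygous_peak_detected = "HET" %in% sec$class,
    genome_size = NA_real_,
    smoothed = s,
    config = config,
    hist = hist
  ), class = "spectrum_model")
  model$genome_size <- estimate_genome_size(hist, model)
  model
}

#' Estimate genome size from a k-mer spectrum
#'
#' Classic spectrum arithmetic: the number of k-mer instances above the
#' error cutoff divided by the k-mer coverage depth. The depth is the
#' model's `lambda` (the count-weighted centroid around the main peak) when
#' available, else the integer main-peak position. For reads of length L at
#' base coverage C the k-mer coverage is approximately C (L - k + 1) / L.
#'
#' @param hist a `kmer_histogram`.
#' @param model a `spectrum_model` (or a list with `error_cutoff` and
#'   `main_peak`, optionally `lambda`).
#' @return genome size estimate in bp (rounded to the nearest integer).
#' @export
estimate_genome_size <- function(hist, model) {
  lambda <- if (!is.null(model$lambda)) model$lambda else model$main_peak
  if (is.null(lambda) || is.na(lambda) || lambda == 0) {
    stop("no main peak: k-mer coverage depth is zero")
  }
  use <- hist$multiplicity > model$error_cutoff
  round(sum(hist$multiplicity[use] * hist$count[use]) / lambda)
}

#' @export
print.spectrum_model <- function(x, ...) {
  cat("k-mer spectrum model (k =", attr(x$hist, "k"), ")\n")
  cat("  error cutoff : multiplicity", x$error_cutoff, "\n")
  cat(sprintf("  main peak    : %dx (depth centroid %.2f)\n",
              x$main_peak, x$lambda))
  if (nrow(x$secondary_peaks)) {
    cat("  secondary    :",
        paste(sprintf("%s@%dx", x$secondary_peaks$class,
                      x$secondary_peaks$multiplicity), collapse = ", "), "\n")
  } else {
    cat("  secondary    : none\n")
  }
  cat("  het peak     :",
      if (x$heterozygous_peak_detected) "detected" else "not detected", "\n")
  cat("  genome size  :", format(x$genome_size, big.mark = ","), "bp\n")
  invisible(x)
}

#' @export
summary.spectrum_model <- function(object, ...) {
  out <- list(
    k = attr(object$hist, "k"),
    error_cutoff = object$error_cutoff,
    main_peak = object$main_peak,
    secondary_peaks = object$secondary_peaks,
    heterozygous_peak_detected = object$heterozygous_peak_detected,
    genome_size = object$genome_size,
    total_kmers = attr(object$hist, "total_kmers"),
    distinct_kmers = attr(object$hist, "distinct_kmers")
  )
  class(out) <- "summary.spectrum_model"
  out
}

#' @export
print.summary.spectrum_model <- function(x, ...) {
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' @export
plot.spectrum_model <- function(x, log = "y", ...) {
  h <- x$hist
  graphics::plot(h$multiplicity, pmax(h$count, 0.5), type = "h", log = log,
                 xlab = "k-mer multiplicity", ylab = "distinct k-mers", ...)
  graphics::abline(v = x$error_cutoff, lty = 3)
  graphics::abline(v = x$main_peak, lty = 2)
  if (nrow(x$secondary_peaks)) {
    graphics::abline(v = x$secondary_peaks$multiplicity, lty = 2,
                     col = "grey50")
  }
  invisible(x)
}
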