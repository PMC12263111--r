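# Protein-length diagnostics: medians, two-sample Kolmogorov-Smirnov
# distances between length distributions, ortholog/singleton splits and
# Pearson correlations.

#' A labeled sample of protein lengths
#'
#' @param label species or group name.
#' @param lengths positive integer lengths (amino acids).
#' @return list of class `LengthSample`.
#' @export
length_sample <- function(label, lengths) {
  lengths <- as.numeric(lengths)
  if (any(lengths < 1)) stop_data("protein lengths must be >= 1")
  structure(list(label = label, lengths = lengths),
            class = "LengthSample")
}

as_lengths <- function(x) {
  if (inherits(x, "LengthSample")) x$lengths else as.numeric(x)
}

#' Median protein length
#'
#' Even-sized samples use the midpoint of the two central order
#' statistics, so the median of an integer sample may be half-integral.
#'
#' @param sample a `LengthSample` or numeric vector (non-empty).
#' @return the median length.
#' @export
median_length <- function(sample) {
  v <- as_lengths(sample)
  if (length(v) == 0L) stop_data("empty length sample")
  median(v)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum distance between the two empirical CDFs,
#' `D = sup_x |F_a(x) - F_b(x)|`; 0 means identical distributions, 1
#' maximal dissimilarity. Only the statistic is computed (it is used as a
#' distance, not a test).
#'
#' @param a,b `LengthSample`s or numeric vectors (non-empty).
#' @return `D` in `[0, 1]`.
#' @export
ks_statistic <- function(a, b) {
  va <- as_lengths(a); vb <- as_lengths(b)
  if (length(va) == 0L || length(vb) == 0L)
    stop_data("empty sample in ks_statistic")
  unname(suppressWarnings(ks.test(va, vb, exact = FALSE))$statistic)
}

#' Pairwise KS distance matrix across length samples
#'
#' @param samples list of `LengthSample`s (>= 2) or named list of numeric
#'   vectors.
#' @return list of class `KSMatrix`: `labels`, `D` (symmetric matrix with
#'   zero diagonal) and `average` (mean over unordered pairs).
#' @export
ks_matrix <- function(samples) {
  if (length(samples) < 2L) stop_data("need >= 2 samples")
  labels <- vapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    if (inherits(s, "LengthSample")) s$label
    else names(samples)[i] %||% as.character(i)
  }, "")
  n <- length(samples)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- ks_statistic(samples[[i]], samples[[j]])
  }
  structure(list(labels = labels, D = D,
                 average = mean(D[upper.tri(D)])),
            class = "KSMatrix")
}

#' Split canonical protein lengths by orthology status
#'
#' Partitions the canonical proteins of a proteome into those with at
#' least one ortholog and the singletons, as length samples.
#'
#' @param proteome the canonicalized `Proteome` the proportion was
#'   computed from.
#' @param proportion the matching `OrthologProportion`.
#' @return list with `with_orthologs` and `singletons` (`LengthSample`s;
#'   the singleton sample may be empty).
#' @export
split_by_orthology <- function(proteome, proportion) {
  can <- proteome[proteome$canonical, , drop = FALSE]
  if (!all(proportion$singletons %in% can$id))
    stop_data("singleton ids do not match the proteome")
  if (proportion$n_canonical != nrow(can))
    stop_data("proportion was computed from a different proteome")
  len <- protein_lengths(can)
  is_single <- can$id %in% proportion$singletons
  sp <- proteome$species[1L]
  list(with_orthologs = structure(
         list(label = paste0(sp, ":with_orthologs"),
              lengths = as.numeric(len[!is_single])),
         class = "LengthSample"),
       singletons = structure(
         list(label = paste0(sp, ":singletons"),
              lengths = as.numeric(len[is_single])),
         class = "LengthSample"))
}

#' Pearson product-moment correlation
#'
#' @param x,y paired numeric vectors (n >= 3, both non-constant).
#' @return `r` in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_data("x and y must be paired")
  if (length(x) < 3L) stop_data("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_data("correlation undefined for a constant series")
  cor(x, y, method = "pearson")
}
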