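#' Absolute Pearson correlation between two expression profiles
#'
#' The absolute value of the Pearson correlation coefficient (APCC) over the
#' pairwise-complete positions of the two profiles. Values lie in `[0, 1]`:
#' 0 means no linear dependence, 1 total (positive or negative) linear
#' dependence.
#'
#' @param x,y numeric expression profiles of equal length; `NA` allowed.
#' @param min_obs minimum number of pairwise-complete observations (default
#'   3); below it the similarity is 0 with a warning.
#' @return similarity in `[0, 1]`.
#' @examples
#' apcc(1:4, c(1, 3, 2, 4)) # 0.8
#' @export
apcc <- function(x, y, min_obs = 3L) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < min_obs) {
    warning("fewer than ", min_obs, " pairwise-complete observations; APCC = 0")
    return(0)
  }
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant profile; APCC = 0")
    return(0)
  }
  min(abs(cor(x, y)), 1)
}

#' Non-linear correlation coefficient based on mutual information (NCMI)
#'
#' Estimates the mutual information I between the two profiles on a
#' `bins` x `bins` equal-width two-dimensional histogram of the
#' pairwise-complete values (in nats), with the Miller-Madow occupancy
#' correction `(m_x + m_y - m_xy - 1) / (2 n)` applied to the plug-in
#' estimate (m = number of occupied bins); without it the plug-in bias,
#' about `(bins - 1)^2 / (2 n)` for independent profiles, would push the
#' similarity of unrelated genes far from 0. The corrected estimate is
#' clamped at 0 and mapped to `[0, 1]` via the global correlation transform
#' `lambda = sqrt(1 - exp(-2 I))`. Unlike APCC, NCMI detects any statistical
#' dependence, including non-monotone (e.g. quadratic) relationships, and is
#' invariant under strictly monotone transforms of either profile up to
#' binning error.
#'
#' @param x,y numeric expression profiles of equal length; `NA` allowed.
#' @param bins number of histogram bins per axis, or `"auto"` for
#'   `ceiling(sqrt(n_obs / 5))`, which keeps the two-dimensional histogram
#'   populated (about 5 observations per occupied cell on the diagonal);
#'   one-dimensional rules such as Sturges' leave most of the `bins^2` cells
#'   nearly empty and blow up the variance of the estimate.
#' @param min_obs minimum pairwise-complete observations (default 8); below
#'   it the similarity is 0 with a warning.
#' @return similarity in `[0, 1]`.
#' @export
ncmi <- function(x, y, bins = "auto", min_obs = 8L) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < min_obs) {
    warning("fewer than ", min_obs, " pairwise-complete observations; NCMI = 0")
    return(0)
  }
  x <- x[ok]; y <- y[ok]
  if (identical(bins, "auto") || identical(bins, "AUTO")) {
    bins <- max(2L, ceiling(sqrt(n / 5)))
  }
  bins <- as.integer(bins)
  stopifnot(bins >= 2L)
  if (n < 2L * bins) {
    warning("fewer observations than 2 * bins; reducing bins")
    bins <- max(2L, n %/% 2L)
  }
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    warning("constant profile; NCMI = 0")
    return(0)
  }
  mi <- .hist2d_mi(x, y, bins)
  lambda <- sqrt(1 - exp(-2 * max(mi, 0)))
  min(max(lambda, 0), 1)
}

# Miller-Madow corrected MI (nats) from an equal-width 2-D histogram
.hist2d_mi <- function(x, y, bins) {
  bx <- .equal_width_bin(x, bins)
  by <- .equal_width_bin(y, bins)
  joint <- tabulate((bx - 1L) * bins + by, nbins = bins * bins)
  n <- length(x)
  p <- joint / n
  px <- tabulate(bx, nbins = bins) / n
  py <- tabulate(by, nbins = bins) / n
  idx <- which(p > 0)
  ix <- (idx - 1L) %/% bins + 1L
  iy <- (idx - 1L) %% bins + 1L
  plug_in <- sum(p[idx] * log(p[idx] / (px[ix] * py[iy])))
  plug_in + (sum(px > 0) + sum(py > 0) - length(idx) - 1) / (2 * n)
}

.equal_width_bin <- function(v, bins) {
  r <- range(v)
  b <- floor((v - r[1L]) / (r[2L] - r[1L]) * bins) + 1L
  pmin(b, bins)
}

#' Normalized mean residue similarity (NMRS)
#'
#' Both profiles are range-normalized to `[0, 1]`
#' (`(v - min(v)) / (max(v) - min(v))`); the similarity is one minus the mean
#' absolute residue between the normalized profiles. By construction NMRS is
#' invariant to additive shifts and positive rescaling of either profile, so
#' it detects shifted expression patterns that sit at different absolute
#' levels.
#'
#' @param x,y numeric expression profiles of equal length; `NA` allowed.
#' @param min_obs minimum pairwise-complete observations (default 3); below
#'   it the similarity is 0 with a warning.
#' @return similarity in `[0, 1]`.
#' @export
nmrs <- function(x, y, min_obs = 3L) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < min_obs) {
    warning("fewer than ", min_obs, " pairwise-complete observations; NMRS = 0")
    return(0)
  }
  x <- x[ok]; y <- y[ok]
  rx <- diff(range(x)); ry <- diff(range(y))
  if (rx == 0 || ry == 0) {
    warning("zero-range profile; NMRS = 0")
    return(0)
  }
  xh <- (x - min(x)) / rx
  yh <- (y - min(y)) / ry
  1 - mean(abs(xh - yh))
}

#' Pairwise similarity matrix over all genes
#'
#' Applies one similarity measure to every unordered gene pair of an
#' expression matrix, handling missing values pairwise-complete. The result
#' is symmetric with unit diagonal; pairs with fewer than `min_obs` complete
#' observations (or degenerate profiles) get similarity 0, counted in a
#' message.
#'
#' @param E numeric matrix, genes in rows, samples in columns, `NA` missing.
#' @param measure one of `"apcc"`, `"ncmi"`, `"nmrs"`.
#' @param bins histogram bins for NCMI (number or `"auto"`).
#' @param min_obs minimum pairwise overlap; defaults to the measure's own
#'   minimum (8 for NCMI, 3 otherwise).
#' @return symmetric numeric matrix in `[0, 1]` with `measure` attribute.
#' @export
similarity_matrix <- function(E, measure = c("apcc", "ncmi", "nmrs"),
                              bins = "auto", min_obs = NULL) {
  measure <- match.arg(measure)
  stopifnot(is.matrix(E), nrow(E) >= 2L)
  if (is.null(min_obs)) min_obs <- if (measure == "ncmi") 8L else 3L
  n <- nrow(E)
  S <- diag(1, n)
  dimnames(S) <- list(rownames(E), rownames(E))
  n_zeroed <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- withCallingHandlers(
        switch(measure,
               apcc = apcc(E[i, ], E[j, ], min_obs = min_obs),
               ncmi = ncmi(E[i, ], E[j, ], bins = bins, min_obs = min_obs),
               nmrs = nmrs(E[i, ], E[j, ], min_obs = min_obs)),
        warning = function(w) {
          n_zeroed <<- n_zeroed + 1L
          invokeRestart("muffleWarning")
        })
      S[i, j] <- S[j, i] <- s
    }
  }
  if (n_zeroed > 0L) {
    .log_msg(n_zeroed, " gene pair(s) with degenerate or insufficient ",
             "overlap set to similarity 0")
  }
  attr(S, "measure") <- toupper(measure)
  S
}

#' Compare two similarity matrices at a common threshold
#'
#' Counts, over unordered off-diagonal gene pairs, how many clear the
#' threshold under both measures, only the first, only the second, or
#' neither. This quantifies how many candidate network edges one measure
#' finds that the other misses (e.g. non-linear co-expression seen by NCMI
#' but not APCC).
#'
#' @param S_a,S_b symmetric similarity matrices over the same genes.
#' @param tau threshold in `(0, 1]`.
#' @return named list `both`, `only_a`, `only_b`, `neither`, `tau`; the four
#'   counts sum to `n(n-1)/2`.
#' @export
compare_measures <- function(S_a, S_b, tau) {
  stopifnot(is.matrix(S_a), is.matrix(S_b), tau > 0, tau <= 1)
  if (!identical(dim(S_a), dim(S_b)) ||
      !identical(rownames(S_a), rownames(S_b))) {
    stop("mismatched gene sets")
  }
  ut <- upper.tri(S_a)
  a <- S_a[ut] >= tau
  b <- S_b[ut] >= tau
  list(both = sum(a & b), only_a = sum(a & !b),
       only_b = sum(!a & b), neither = sum(!a & !b), tau = tau)
}
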