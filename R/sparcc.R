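#' Dirichlet resampling of compositional fractions
#'
#' Sequencing counts are a multinomial draw from unknown fractions; zeros
#' are sampling zeros, not structural ones. Each sample's fraction vector
#' is drawn from the Dirichlet posterior under a unit pseudocount per genus
#' (concentration = count + 1), so zero counts become small positive
#' fractions and downstream log-ratios are defined.
#'
#' @param counts an [abundance_table] or a count matrix (genus x sample).
#' @param seed optional integer seed for reproducibility.
#' @return matrix of fractions (genus x sample); columns sum to 1.
#' @export
dirichlet_resample_fractions <- function(counts, seed = NULL) {
  m <- if (inherits(counts, "abundance_table")) counts$counts else as.matrix(counts)
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(stats::rgamma(length(m), shape = m + 1, rate = 1),
              nrow(m), ncol(m), dimnames = dimnames(m))
  sweep(g, 2, colSums(g), "/")
}

#' Variance matrix of pairwise log-ratios
#'
#' The basic statistic of sparse compositional correlation inference:
#' `t[i,j] = var over samples of log(f_i) - log(f_j)`. Computed via the
#' covariance matrix of log fractions, `t[i,j] = C[i,i] + C[j,j] - 2 C[i,j]`.
#'
#' @param fractions strictly positive matrix (genus x sample).
#' @return symmetric non-negative matrix with zero diagonal.
#' @export
logratio_variances <- function(fractions) {
  f <- as.matrix(fractions)
  if (any(f <= 0))
    stop("fractions must be strictly positive; resample zeros first ",
         "(see dirichlet_resample_fractions)")
  if (ncol(f) < 2) stop("need at least 2 samples to compute a variance")
  L <- log(f)
  C <- stats::cov(t(L))            # samples as observations, n-1 denominator
  v <- diag(C)
  t <- outer(v, v, "+") - 2 * C
  t[t < 0] <- 0                    # numeric guard
  diag(t) <- 0
  dimnames(t) <- list(rownames(f), rownames(f))
  t
}

#' Estimate basis correlations from log-ratio variances
#'
#' Under the sparsity assumption (most pairs uncorrelated) the basis
#' variances `omega` solve the linear system obtained from the row sums of
#' the log-ratio variance matrix; the basis correlation follows as
#' `rho[i,j] = (omega_i + omega_j - t[i,j]) / (2 sqrt(omega_i omega_j))`.
#' Strongly correlated pairs violate the assumption, so the pair with the
#' largest `|rho|` above `exclusion_threshold` is iteratively removed from
#' the system and the variances re-solved, up to `max_exclusion_rounds`
#' times.
#'
#' @param t log-ratio variance matrix from [logratio_variances()].
#' @param exclusion_threshold correlation magnitude above which the
#'   strongest pair is excluded each round (default 0.1).
#' @param max_exclusion_rounds maximum number of excluded pairs (default 10).
#' @return list with `rho` (correlations, clipped to \[-1, 1\], unit
#'   diagonal), `omega` (basis variances, floored at 1e-10) and
#'   `n_excluded`.
#' @export
estimate_basis <- function(t, exclusion_threshold = 0.1,
                           max_exclusion_rounds = 10) {
  t <- as.matrix(t)
  D <- nrow(t)
  if (D < 4) stop("basis estimation needs at least 4 genera")
  keep <- matrix(TRUE, D, D); diag(keep) <- FALSE
  n_excluded <- 0L
  floored <- FALSE
  repeat {
    A <- keep + diag(rowSums(keep))          # A[i,i] = d_i, A[i,j] = 1 if kept
    b <- rowSums(t * keep)
    omega <- tryCatch(solve(A, b), error = function(e)
      stop("singular basis-variance system: ", conditionMessage(e)))
    if (any(omega <= 0)) {
      omega[omega <= 0] <- 1e-10
      floored <- TRUE
    }
    s <- sqrt(omega)
    rho <- (outer(omega, omega, "+") - t) / (2 * outer(s, s))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    if (n_excluded >= max_exclusion_rounds) break
    cand <- abs(rho) * keep
    # never let a genus drop below 2 partners: the system would go singular
    deg <- rowSums(keep)
    cand[deg <= 2, ] <- 0
    cand[, deg <= 2] <- 0
    m <- max(cand)
    if (m <= exclusion_threshold) break
    ij <- which(cand == m, arr.ind = TRUE)[1, ]
    keep[ij[1], ij[2]] <- keep[ij[2], ij[1]] <- FALSE
    n_excluded <- n_excluded + 1L
  }
  if (floored)
    warning("negative basis variance estimate(s) floored at 1e-10")
  dimnames(rho) <- dimnames(t)
  list(rho = rho, omega = stats::setNames(omega, rownames(t)),
       n_excluded = n_excluded)
}

#' Sparse compositional correlation (SparCC) between genera
#'
#' Infers pairwise basis correlations between genus abundance profiles
#' from compositional count data. Zeros are handled by Dirichlet
#' resampling; the basis estimate is aggregated over resamples
#' (element-wise median by default, robust to occasional degenerate
#' re-solves).
#'
#' @param counts an [abundance_table] or count matrix (genus x sample).
#' @param n_resamples number of Dirichlet resamples to aggregate (default 20).
#' @param exclusion_threshold,max_exclusion_rounds see [estimate_basis()].
#' @param seed integer seed; recorded in the result.
#' @param aggregate `"median"` (default) or `"mean"` across resamples.
#' @return object of class `sparcc_fit`: list with `rho` (symmetric,
#'   unit-diagonal correlation matrix), `omega` (aggregated basis
#'   variances), and the settings used.
#' @export
sparcc <- function(counts, n_resamples = 20, exclusion_threshold = 0.1,
                   max_exclusion_rounds = 10, seed = NULL,
                   aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  m <- if (inherits(counts, "abundance_table")) counts$counts else as.matrix(counts)
  stopifnot(n_resamples >= 1)
  if (!is.null(seed)) set.seed(seed)
  D <- nrow(m)
  rhos <- array(NA_real_, c(D, D, n_resamples))
  omegas <- matrix(NA_real_, D, n_resamples)
  for (r in seq_len(n_resamples)) {
    f <- dirichlet_resample_fractions(m)
    est <- suppressWarnings(
      estimate_basis(logratio_variances(f),
                     exclusion_threshold = exclusion_threshold,
                     max_exclusion_rounds = max_exclusion_rounds))
    rhos[, , r] <- est$rho
    omegas[, r] <- est$omega
  }
  agg <- if (aggregate == "median") function(x) apply(x, c(1, 2), stats::median)
         else function(x) apply(x, c(1, 2), mean)
  rho <- agg(rhos)
  rho <- (rho + t(rho)) / 2
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  dimnames(rho) <- list(rownames(m), rownames(m))
  omega <- apply(omegas, 1, if (aggregate == "median") stats::median else mean)
  structure(list(rho = rho, omega = stats::setNames(omega, rownames(m)),
                 n_resamples = n_resamples, seed = seed,
                 exclusion_threshold = exclusion_threshold,
                 max_exclusion_rounds = max_exclusion_rounds,
                 aggregate = aggregate),
            class = "sparcc_fit")
}

#' @export
print.sparcc_fit <- function(x, ...) {
  off <- x$rho[upper.tri(x$rho)]
  cat(sprintf(paste0("SparCC correlation fit: %d genera, %d resample(s)\n",
                     "  off-diagonal rho range: [%.3f, %.3f]\n"),
              nrow(x$rho), x$n_resamples, min(off), max(off)))
  invisible(x)
}
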