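# per-module preservation statistics.
# ref/test: lists with elements rho (correlation), adj (adjacency),
# profiles (transformed genus x sample matrix). idx: integer indices of
# the module members within the shared genus universe.
# Density statistics are computed in the test dataset; connectivity
# statistics compare the two datasets over the module members.
.preservation_stats <- function(ref, test, idx) {
  off <- function(m) m[upper.tri(m)]
  eig1 <- function(dat) {
    X <- .standardize_rows(dat$profiles[idx, , drop = FALSE])
    X <- X[rowSums(is.na(X)) == 0, , drop = FALSE]
    sv <- svd(X, nu = 0, nv = 1)
    v <- sv$v[, 1]
    s <- sign(sum(v * colMeans(X)))
    if (is.na(s) || s == 0) s <- 1
    list(score = v * s, ve = sv$d[1]^2 / sum(sv$d^2),
         kme = suppressWarnings(stats::cor(t(dat$profiles[idx, , drop = FALSE]),
                                           v * s))[, 1])
  }
  et <- eig1(test); er <- eig1(ref)
  # intramodular connectivity within the module (adjacency row sums)
  kim <- function(dat) rowSums(dat$adj[idx, idx, drop = FALSE]) - 1
  suppressWarnings(c(
    mean_adj      = mean(off(test$adj[idx, idx])),
    mean_cor      = mean(off(test$rho[idx, idx])),
    mean_abs_kme  = mean(abs(et$kme), na.rm = TRUE),
    prop_var      = et$ve,
    cor_kim       = stats::cor(kim(ref), kim(test)),
    cor_kme       = stats::cor(er$kme, et$kme, use = "complete.obs"),
    cor_cor       = stats::cor(off(ref$rho[idx, idx]), off(test$rho[idx, idx]))
  ))
}

.density_stat_names <- c("mean_adj", "mean_cor", "mean_abs_kme", "prop_var")
.connectivity_stat_names <- c("cor_kim", "cor_kme", "cor_cor")

#' Permutation Z-summary module preservation
#'
#' Quantifies whether co-occurrence modules defined in a reference dataset
#' reappear in an independent test dataset. Correlation and adjacency are
#' estimated separately in both datasets; for each module, four density
#' statistics (mean intramodular adjacency, mean intramodular correlation,
#' mean |kME|, proportion of variance explained by the eigengenus — all in
#' the test dataset) and three connectivity statistics (cross-dataset
#' correlations of intramodular connectivity, of kME, and of the
#' intramodular correlation entries) are compared against a null obtained
#' by re-computing them on random genus sets of the same size. Each
#' statistic yields `Z = (observed - null mean) / null sd`;
#' `Z_density` and `Z_connectivity` are the medians of their groups and
#' `Z_summary` their average.
#'
#' @param ref,test [abundance_table]s over the same genus set (use
#'   [align_shared_genera()] first).
#' @param assignment `module_assignment` (or named genus -> module vector)
#'   defined on the reference genera.
#' @param n_permutations size of the permutation null (default 100,
#'   minimum 20).
#' @param seed integer seed for the permutation draws and the correlation
#'   resampling.
#' @param beta soft-threshold power for the adjacency (default 4).
#' @param correlation `"sparcc"` (default) or `"pearson"` (log-fraction
#'   Pearson correlation, for speed on large universes).
#' @param transform abundance transform for eigengenus/kME profiles
#'   (see [transform_abundance()]).
#' @param sparcc_args list of extra arguments to [sparcc()].
#' @return object of class `preservation_report`: data.frame `summary`
#'   (per module: size, Z_density, Z_connectivity, Z_summary), per-module
#'   `details` (observed statistics, null means/sds, per-statistic Zs),
#'   and the settings used.
#' @export
module_preservation <- function(ref, test, assignment, n_permutations = 100,
                                seed = NULL, beta = 4,
                                correlation = c("sparcc", "pearson"),
                                transform = "log", sparcc_args = list()) {
  correlation <- match.arg(correlation)
  stopifnot(inherits(ref, "abundance_table"), inherits(test, "abundance_table"))
  if (n_permutations < 20) stop("n_permutations must be at least 20")
  lab <- if (inherits(assignment, "module_assignment")) assignment$labels else assignment
  genera <- rownames(ref$counts)
  if (!setequal(genera, rownames(test$counts)))
    stop("ref and test must share the same genus set (align_shared_genera)")
  test$counts <- test$counts[genera, , drop = FALSE]
  lab <- lab[genera]
  if (anyNA(lab)) stop("assignment does not cover every reference genus")
  if (!is.null(seed)) set.seed(seed)

  prep <- function(tab) {
    rho <- if (correlation == "sparcc")
      do.call(sparcc, c(list(tab), sparcc_args))$rho
    else {
      f <- dirichlet_resample_fractions(tab$counts)
      stats::cor(t(log(f)))
    }
    list(rho = rho,
         adj = adjacency_from_correlation(rho, beta),
         profiles = transform_abundance(to_relative(tab), method = transform))
  }
  refd <- prep(ref); testd <- prep(test)

  mods <- setdiff(unique(lab), "grey")
  mods <- mods[order(-vapply(mods, function(m) sum(lab == m), numeric(1)))]
  if (!length(mods)) stop("no non-grey modules to test")
  D <- length(genera)

  details <- list()
  summary_rows <- list()
  for (m in mods) {
    idx <- which(lab == m)
    if (length(idx) > D) stop("module larger than the genus universe")
    if (length(idx) < 3) {
      warning("module '", m, "' has fewer than 3 genera; skipped")
      next
    }
    obs <- .preservation_stats(refd, testd, idx)
    null <- matrix(NA_real_, n_permutations, length(obs),
                   dimnames = list(NULL, names(obs)))
    for (p in seq_len(n_permutations)) {
      ridx <- sample.int(D, length(idx))
      null[p, ] <- .preservation_stats(refd, testd, ridx)
    }
    mu <- colMeans(null, na.rm = TRUE)
    sd <- apply(null, 2, stats::sd, na.rm = TRUE)
    z <- (obs - mu) / sd
    degenerate <- !is.finite(z)
    if (any(degenerate))
      warning("module '", m, "': degenerate null sd for ",
              paste(names(z)[degenerate], collapse = ", "),
              "; dropped from the median")
    zd <- stats::median(z[.density_stat_names][!degenerate[.density_stat_names]])
    zc <- stats::median(z[.connectivity_stat_names][!degenerate[.connectivity_stat_names]])
    zs <- (zd + zc) / 2
    details[[m]] <- list(observed = obs, null_mean = mu, null_sd = sd, z = z)
    summary_rows[[m]] <- data.frame(module = m, size = length(idx),
                                    Z_density = zd, Z_connectivity = zc,
                                    Z_summary = zs, stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, c(summary_rows, make.row.names = FALSE)),
                 details = details, n_permutations = n_permutations,
                 seed = seed, beta = beta, correlation = correlation),
            class = "preservation_report")
}

#' @export
print.preservation_report <- function(x, ...) {
  cat(sprintf("Module preservation (%d permutations, %s correlation):\n",
              x$n_permutations, x$correlation))
  s <- x$summary
  s$verdict <- classify_preservation(x)$verdict
  print(s, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Categorise preservation evidence from Z-summary
#'
#' Standard thresholds: `Z < 2` no evidence of preservation;
#' `2 <= Z <= 5` weak; `5 < Z <= 10` moderate; `Z > 10` strong.
#'
#' @param report a `preservation_report` (or a numeric vector of Z-summary
#'   values).
#' @return data.frame with `module`, `Z_summary` and `verdict`.
#' @export
classify_preservation <- function(report) {
  if (inherits(report, "preservation_report")) {
    z <- report$summary$Z_summary
    mod <- report$summary$module
  } else {
    z <- as.numeric(report)
    mod <- names(report)
    if (is.null(mod)) mod <- paste0("module", seq_along(z))
  }
  if (anyNA(z)) stop("missing Z-summary value(s)")
  verdict <- ifelse(z < 2, "none",
             ifelse(z <= 5, "weak",
             ifelse(z <= 10, "moderate", "strong")))
  data.frame(module = mod, Z_summary = z, verdict = verdict,
             stringsAsFactors = FALSE)
}
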