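#' Signed weighted adjacency from a correlation matrix
#'
#' The signed soft-thresholding transform `a[i,j] = (0.5 + 0.5 rho[i,j])^beta`
#' maps co-occurrence (rho -> 1) to adjacency 1 and co-exclusion
#' (rho -> -1) to adjacency 0 while preserving the continuous nature of
#' the association measure.
#'
#' @param rho correlation matrix (a [sparcc()] fit or a plain symmetric
#'   matrix with entries in \[-1, 1\]).
#' @param beta soft-threshold power, > 0; default 4, suited to networks
#'   with a few hundred nodes.
#' @return symmetric adjacency matrix in \[0, 1\] with unit diagonal and
#'   attribute `beta`.
#' @export
adjacency_from_correlation <- function(rho, beta = 4) {
  if (inherits(rho, "sparcc_fit")) rho <- rho$rho
  rho <- as.matrix(rho)
  if (beta <= 0) stop("beta must be positive")
  if (max(abs(rho)) > 1 + 1e-8) stop("correlations must lie in [-1, 1]")
  a <- (0.5 + 0.5 * pmin(pmax(rho, -1), 1))^beta
  diag(a) <- 1
  attr(a, "beta") <- beta
  a
}

#' Choose the soft-threshold power by the scale-free topology criterion
#'
#' For each candidate power the weighted connectivity `k_i = sum_j a[i,j]`
#' is binned into ~10 equal-width bins and `log10 p(k)` regressed on
#' `log10 k` (bin mean); the signed fit index is `-sign(slope) * R^2`, positive when
#' the degree distribution decays as a power law. The smallest power whose
#' signed R^2 reaches `r2_cut` is chosen; if none does, the power with the
#' maximum signed R^2.
#'
#' @param rho correlation matrix or [sparcc()] fit.
#' @param powers increasing candidate powers (default 1:10).
#' @param r2_cut signed R^2 target (default 0.8).
#' @param n_bins number of connectivity bins (default 10).
#' @return object of class `scale_free_report`: data.frame `fits` with per
#'   power signed R^2, slope, mean and median connectivity; `power`, the
#'   chosen value.
#' @export
pick_soft_threshold <- function(rho, powers = 1:10, r2_cut = 0.8, n_bins = 10) {
  if (inherits(rho, "sparcc_fit")) rho <- rho$rho
  if (length(powers) < 2 || is.unsorted(powers, strictly = TRUE))
    stop("powers must be at least 2 strictly increasing values")
  fits <- data.frame(power = powers, r_squared = NA_real_, slope = NA_real_,
                     mean_k = NA_real_, median_k = NA_real_)
  for (i in seq_along(powers)) {
    a <- adjacency_from_correlation(rho, powers[i])
    diag(a) <- 0
    k <- rowSums(a)
    fits$mean_k[i] <- mean(k); fits$median_k[i] <- stats::median(k)
    if (stats::sd(k) < .Machine$double.eps^0.5 * max(mean(k), 1)) next  # degenerate
    brk <- unique(seq(min(k), max(k), length.out = n_bins + 1))
    if (length(brk) < 3) next
    bin <- cut(k, breaks = brk, include.lowest = TRUE)
    pk <- tabulate(bin, nbins = nlevels(bin)) / length(k)
    kc <- tapply(k, bin, mean)
    ok <- pk > 0 & kc > 0
    if (sum(ok) < 3) next
    fit <- stats::lm(log10(pk[ok]) ~ log10(kc[ok]))
    fits$slope[i] <- stats::coef(fit)[2]
    fits$r_squared[i] <- -sign(stats::coef(fit)[2]) * summary(fit)$r.squared
  }
  if (all(is.na(fits$r_squared)))
    stop("scale-free fit degenerate at every candidate power")
  hit <- which(!is.na(fits$r_squared) & fits$r_squared >= r2_cut)
  power <- if (length(hit)) powers[hit[1]] else
    powers[which.max(fits$r_squared)]
  structure(list(fits = fits, power = power, r2_cut = r2_cut),
            class = "scale_free_report")
}

#' @export
print.scale_free_report <- function(x, ...) {
  cat("Scale-free topology fit (signed R^2):\n")
  print(x$fits, row.names = FALSE, digits = 3)
  cat("chosen power:", x$power, "\n")
  invisible(x)
}

#' Topological overlap matrix
#'
#' The topological overlap of two nodes counts their shared weighted
#' neighbours relative to the less-connected node:
#' `TOM[i,j] = (sum_u a[i,u] a[u,j] + a[i,j]) / (min(k_i, k_j) + 1 - a[i,j])`
#' with `k_i = sum_{u != i} a[i,u]` and the sum over `u != i, j`. It is a
#' robust interconnectedness measure used as the clustering similarity.
#'
#' @param adj adjacency matrix from [adjacency_from_correlation()].
#' @return list with `tom` (unit diagonal, values in \[0, 1\]) and
#'   `dissimilarity` (`1 - tom`).
#' @export
topological_overlap <- function(adj) {
  a <- as.matrix(adj)
  diag(a) <- 0
  if (all(a == 0)) stop("adjacency has no edges")
  k <- rowSums(a)
  num <- a %*% a + a                       # [A^2]_ij sums over all u != i,j
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom <- pmin(pmax((tom + t(tom)) / 2, 0), 1)
  dimnames(tom) <- dimnames(adj)
  list(tom = tom, dissimilarity = 1 - tom)
}

# canonical module colour order; largest module gets the first colour
module_color_order <- function() c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white")

#' Detect co-occurrence modules by dynamic tree cut
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, decomposed into
#' branches by a tree-variant dynamic cut. Every dendrogram branch of at
#' least `min_module_size` genera below the height ceiling is scored by
#' its separation — the mean dissimilarity from its members to the rest of
#' the network minus the mean dissimilarity within the branch. Separation
#' peaks exactly at coherent, distinct branches: sub-branches of a module
#' are less separated (their complement contains the rest of the module)
#' and supersets dilute cohesion. Branches whose separation reaches a
#' `deep_split`-controlled fraction of the dissimilarity spread are
#' candidate modules; candidates are accepted greedily by size-weighted
#' separation (skipping branches nested with an accepted one), accepted
#' modules that are not mutually separated are merged, and remaining
#' genera whose affinity to their closest module matches that module's
#' internal cohesion are attached to it.
#' Genera outside accepted branches stay unassigned ("grey"). Modules are
#' labelled by decreasing size with the canonical colour order, so
#' "turquoise" is always the largest module. A structureless (pure-noise)
#' network yields one all-encompassing module or only grey genera, never
#' a crowd of small spurious modules.
#'
#' @param tom a TOM matrix or the list returned by [topological_overlap()].
#' @param min_module_size smallest branch kept as a module (default 5).
#' @param deep_split split sensitivity 0-3 (default 2); the separation
#'   threshold is `c(0.20, 0.10, 0.05, 0.025)[deep_split + 1]` times the
#'   spread of the off-diagonal dissimilarities, so higher values split
#'   more finely.
#' @param cut_height height ceiling above which merges are always split;
#'   default `0.995 * max merge height`.
#' @return object of class `module_assignment`: `labels` (named character,
#'   genus -> colour), `sizes`, `dendrogram` (the hclust tree),
#'   `cut_height` and parameters.
#' @export
detect_modules <- function(tom, min_module_size = 5, deep_split = 2,
                           cut_height = NULL) {
  if (is.list(tom) && !is.null(tom$tom)) tom <- tom$tom
  if (min_module_size < 2) stop("min_module_size must be at least 2")
  if (!deep_split %in% 0:3) stop("deep_split must be 0, 1, 2 or 3")
  n <- nrow(tom)
  if (n < min_module_size)
    stop("fewer genera than min_module_size")
  d <- 1 - tom
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  h <- tree$height
  if (is.null(cut_height)) cut_height <- 0.995 * max(h)
  offd <- d[upper.tri(d)]
  spread <- diff(range(offd))
  sep_min <- c(0.20, 0.10, 0.05, 0.025)[deep_split + 1] * spread

  # subtree bookkeeping over the hclust merge matrix (children precede
  # parents, so one forward pass suffices)
  members <- vector("list", n - 1)
  size <- integer(n - 1)
  wmean <- numeric(n - 1)           # mean within-subtree dissimilarity
  pairsum <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    ch <- tree$merge[i, ]
    mem <- lapply(ch, function(j) if (j < 0) -j else members[[j]])
    ps <- sum(vapply(ch, function(j) if (j < 0) 0 else pairsum[j], 0)) +
      sum(d[mem[[1]], mem[[2]]])
    members[[i]] <- c(mem[[1]], mem[[2]])
    size[i] <- length(members[[i]])
    pairsum[i] <- ps
    wmean[i] <- ps / choose(size[i], 2)
  }

  mod_members <- list()
  if (spread == 0) {
    mod_members <- list(seq_len(n))        # saturated TOM: one block
  } else {
    eligible <- which(size >= min_module_size & size < n & h <= cut_height)
    sep <- vapply(eligible, function(i) {
      mem <- members[[i]]
      mean(d[mem, -mem]) - wmean[i]
    }, numeric(1))
    cand <- eligible[sep >= sep_min]
    sep <- sep[match(cand, eligible)]
    # greedy acceptance: size-weighted separation (exponent 0.75) prefers
    # whole branches over tight sub-cliques without rewarding loose
    # supersets; deterministic tie-breaks
    ord <- order(-sep * size[cand]^0.75, -size[cand],
                 vapply(cand, function(i) min(members[[i]]), numeric(1)))
    taken <- rep(FALSE, n)
    for (i in cand[ord]) {
      mem <- members[[i]]
      if (!any(taken[mem])) {
        mod_members <- c(mod_members, list(mem))
        taken[mem] <- TRUE
      }
    }
    within_mean <- function(mem)
      if (length(mem) < 2) 0 else mean(d[mem, mem][upper.tri(d[mem, mem])])
    # merge module pairs that are not mutually separated
    while (length(mod_members) > 1) {
      K <- length(mod_members)
      wm <- vapply(mod_members, within_mean, numeric(1))
      best <- NULL; best_sep <- Inf
      for (i in seq_len(K - 1)) for (j in (i + 1):K) {
        s <- mean(d[mod_members[[i]], mod_members[[j]]]) - max(wm[i], wm[j])
        if (s < best_sep) { best_sep <- s; best <- c(i, j) }
      }
      if (best_sep >= sep_min) break
      mod_members[[best[1]]] <- c(mod_members[[best[1]]],
                                  mod_members[[best[2]]])
      mod_members[[best[2]]] <- NULL
    }
    # attach unassigned genera whose affinity to their closest module is
    # on par with that module's internal cohesion
    if (length(mod_members)) {
      repeat {
        assigned <- unlist(mod_members)
        loose <- setdiff(seq_len(n), assigned)
        if (!length(loose)) break
        wm <- vapply(mod_members, within_mean, numeric(1))
        aff <- vapply(mod_members, function(mem)
          rowMeans(d[loose, mem, drop = FALSE]), numeric(length(loose)))
        aff <- matrix(aff, nrow = length(loose))
        pick <- apply(aff, 1, which.min)
        take <- aff[cbind(seq_along(loose), pick)] <= wm[pick] + 3 * sep_min
        if (!any(take)) break
        for (m in unique(pick[take]))
          mod_members[[m]] <- c(mod_members[[m]], loose[take & pick == m])
      }
    }
    mod_members <- Filter(function(mem) length(mem) >= min_module_size,
                          mod_members)
  }

  # order modules by decreasing size, ties by lowest genus index
  msize <- lengths(mod_members)
  first_idx <- vapply(mod_members, min, numeric(1))
  mod_members <- mod_members[order(-msize, first_idx)]
  colors <- module_color_order()
  lab <- rep("grey", n)
  for (i in seq_along(mod_members)) {
    col <- if (i <= length(colors)) colors[i] else paste0("module", i)
    lab[mod_members[[i]]] <- col
  }
  names(lab) <- rownames(tom)
  tb <- table(lab[lab != "grey"])
  msize <- stats::setNames(as.integer(tb), names(tb))
  structure(list(labels = lab,
                 sizes = sort(msize, decreasing = TRUE),
                 dendrogram = tree, cut_height = cut_height,
                 min_module_size = min_module_size, deep_split = deep_split),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  n_grey <- sum(x$labels == "grey")
  cat(sprintf("Module assignment: %d module(s) over %d genera (%d unassigned)\n",
              length(x$sizes), length(x$labels), n_grey))
  if (length(x$sizes)) print(x$sizes)
  invisible(x)
}

#' Module names of an assignment (non-grey, largest first)
#' @param x a `module_assignment`.
#' @export
module_names <- function(x) names(x$sizes)

#' Genus members of one module
#' @param x a `module_assignment`.
#' @param module module colour name.
#' @export
module_members <- function(x, module) names(x$labels)[x$labels == module]
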