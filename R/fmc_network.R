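#' Fit a functional microbial community network
#'
#' The package's main fitting function: estimates pairwise genus
#' associations with the sparse compositional correlation estimator
#' ([sparcc()]), soft-thresholds them into a signed weighted network,
#' clusters the topological overlap dissimilarity into modules (functional
#' microbial communities), and summarises each module by its eigengenus,
#' member kME values and — when metadata is supplied — module-trait
#' correlations and per-genus differential abundance.
#'
#' @param counts an [abundance_table] (or count matrix, genus x sample).
#' @param metadata optional sample metadata (see [read_sample_metadata()]).
#' @param beta soft-threshold power (default 4).
#' @param min_module_size,deep_split see [detect_modules()].
#' @param transform abundance transform for eigengenus/kME profiles.
#' @param n_resamples,exclusion_threshold,max_exclusion_rounds passed to
#'   [sparcc()].
#' @param min_reads_per_sample,drop_singletons quality filter settings;
#'   set `min_reads_per_sample = 0, drop_singletons = FALSE` to skip.
#' @param seed integer seed for the correlation resampling.
#' @return object of class `fmc_network` holding the filtered table, the
#'   correlation fit, adjacency, TOM, module assignment, eigengenus
#'   matrix, kME matrix and (with metadata) trait and differential
#'   reports.
#' @seealso [module_preservation()], [nsc()], [simulate_fmc()]
#' @export
fmc_network <- function(counts, metadata = NULL, beta = 4,
                        min_module_size = 5, deep_split = 2,
                        transform = "log",
                        n_resamples = 20, exclusion_threshold = 0.1,
                        max_exclusion_rounds = 10,
                        min_reads_per_sample = 3000, drop_singletons = TRUE,
                        seed = NULL) {
  tab <- if (inherits(counts, "abundance_table")) counts else abundance_table(counts)
  tab <- quality_filter(tab, min_reads_per_sample, drop_singletons)
  if (nrow(tab$counts) < 4 || ncol(tab$counts) < 3)
    stop("need at least 4 genera and 3 samples after filtering")
  cor_fit <- sparcc(tab, n_resamples = n_resamples,
                    exclusion_threshold = exclusion_threshold,
                    max_exclusion_rounds = max_exclusion_rounds, seed = seed)
  adj <- adjacency_from_correlation(cor_fit, beta)
  tom <- topological_overlap(adj)
  modules <- detect_modules(tom$tom, min_module_size = min_module_size,
                            deep_split = deep_split)
  rel <- to_relative(tab)
  profiles <- transform_abundance(rel, method = transform)
  eig <- if (length(modules$sizes))
    module_eigengenus(profiles, modules) else NULL
  kme_mat <- if (!is.null(eig)) kme(profiles, eig) else NULL
  traits <- differential <- NULL
  if (!is.null(metadata)) {
    metadata <- validate_metadata(metadata)
    miss <- setdiff(colnames(tab$counts), metadata$sample_id)
    if (length(miss)) stop("metadata missing sample(s): ",
                           paste(miss[seq_len(min(3, length(miss)))], collapse = ", "))
    if (!is.null(eig))
      traits <- module_trait_correlation(eig, metadata)
    grp <- metadata$diagnosis[match(colnames(tab$counts), metadata$sample_id)]
    if (nlevels(droplevels(grp)) >= 2 && all(table(droplevels(grp)) >= 2))
      differential <- differential_abundance(rel, droplevels(grp))
  }
  structure(list(table = tab, relative = rel, correlation = cor_fit,
                 adjacency = adj, tom = tom$tom, modules = modules,
                 eigengenus = eig, kme = kme_mat,
                 traits = traits, differential = differential,
                 metadata = metadata,
                 settings = list(beta = beta, min_module_size = min_module_size,
                                 deep_split = deep_split, transform = transform,
                                 n_resamples = n_resamples,
                                 exclusion_threshold = exclusion_threshold,
                                 max_exclusion_rounds = max_exclusion_rounds,
                                 min_reads_per_sample = min_reads_per_sample,
                                 drop_singletons = drop_singletons,
                                 seed = seed)),
            class = "fmc_network")
}

#' @export
print.fmc_network <- function(x, ...) {
  cat(sprintf("Co-occurrence network fit: %d genera x %d samples, beta = %s\n",
              nrow(x$table$counts), ncol(x$table$counts), x$settings$beta))
  off <- x$correlation$rho[upper.tri(x$correlation$rho)]
  cat(sprintf("  SparCC rho range: [%.3f, %.3f]\n", min(off), max(off)))
  print(x$modules)
  invisible(x)
}

#' @export
summary.fmc_network <- function(object, ...) {
  out <- list(n_genera = nrow(object$table$counts),
              n_samples = ncol(object$table$counts),
              modules = object$modules$sizes,
              n_grey = sum(object$modules$labels == "grey"),
              var_explained = if (!is.null(object$eigengenus))
                object$eigengenus$var_explained else NULL,
              traits = object$traits)
  class(out) <- "summary.fmc_network"
  out
}

#' @export
print.summary.fmc_network <- function(x, ...) {
  cat(sprintf("Network of %d genera over %d samples\n", x$n_genera, x$n_samples))
  cat(sprintf("Modules (%d unassigned genera):\n", x$n_grey))
  print(x$modules)
  if (!is.null(x$var_explained)) {
    cat("Eigengenus variance explained:\n")
    print(round(x$var_explained, 3))
  }
  if (!is.null(x$traits)) print(x$traits)
  invisible(x)
}

#' Plot the module dendrogram of a network fit
#'
#' Draws the average-linkage tree of the topological-overlap
#' dissimilarity with leaves annotated by module colour and the adaptive
#' cut height marked.
#'
#' @param x an `fmc_network` fit.
#' @param ... passed to [plot.hclust()].
#' @export
plot.fmc_network <- function(x, ...) {
  tree <- x$modules$dendrogram
  plot(tree, labels = FALSE, hang = -1,
       main = "Genus clustering on topological overlap",
       xlab = "", sub = "", ...)
  graphics::abline(h = x$modules$cut_height, lty = 2, col = "red")
  lab <- x$modules$labels[tree$order]
  col <- ifelse(lab == "grey", "grey70", lab)
  n <- length(lab)
  graphics::points(seq_len(n), rep(-0.02, n), pch = 15, col = col,
                   xpd = NA, cex = 0.6)
  invisible(x)
}
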