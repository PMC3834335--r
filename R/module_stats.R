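#' Transform relative abundances for module summarisation
#'
#' Compositional abundance distributions are strongly right-skewed; the
#' default `log10(fraction + 1e-6)` transform symmetrises them before
#' genus profiles enter principal-component summaries. Alternatives: the
#' raw fractions, or within-genus ranks.
#'
#' @param x a `relative_abundance_table` or a fractions matrix
#'   (genus x sample).
#' @param method `"log"` (default), `"raw"` or `"rank"`.
#' @param pseudo pseudo-fraction added before the log (default 1e-6).
#' @return numeric matrix (genus x sample).
#' @export
transform_abundance <- function(x, method = c("log", "raw", "rank"),
                                pseudo = 1e-6) {
  method <- match.arg(method)
  f <- if (inherits(x, "relative_abundance_table")) x$fractions else as.matrix(x)
  switch(method,
         log = log10(f + pseudo),
         raw = f,
         rank = t(apply(f, 1, rank)))
}

# standardize genus rows to zero mean, unit variance across samples;
# zero-variance rows come back as NA rows
.standardize_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  out <- (m - mu) / sd
  out[sd == 0, ] <- NA_real_
  out
}

#' Module eigengenus: first principal component of each module
#'
#' Each module's member profiles are standardized across samples and the
#' first right singular vector of the member x sample submatrix taken as
#' the module's per-sample summary score (the eigengenus). The score is
#' unit-norm and oriented so that it correlates non-negatively with the
#' module's mean standardized profile.
#'
#' @param profiles transformed abundance matrix (genus x sample), e.g.
#'   from [transform_abundance()].
#' @param assignment a `module_assignment` (or a named genus -> module
#'   vector); "grey" genera are ignored.
#' @return object of class `eigengenus_matrix`: `scores` (sample x module
#'   matrix, unit-norm columns), `var_explained` (named vector in
#'   \[0, 1\]) and `sample_ids`.
#' @export
module_eigengenus <- function(profiles, assignment) {
  lab <- if (inherits(assignment, "module_assignment")) assignment$labels else assignment
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 2) stop("need at least 2 samples")
  mods <- if (inherits(assignment, "module_assignment")) module_names(assignment)
          else setdiff(unique(lab), "grey")
  if (!length(mods)) stop("no non-grey modules in assignment")
  scores <- matrix(NA_real_, ncol(profiles), length(mods),
                   dimnames = list(colnames(profiles), mods))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    members <- intersect(names(lab)[lab == m], rownames(profiles))
    if (!length(members)) stop("module '", m, "' has no members in the profile matrix")
    X <- .standardize_rows(profiles[members, , drop = FALSE])
    dropped <- rowSums(is.na(X)) > 0
    if (any(dropped)) {
      warning("module '", m, "': dropped zero-variance genus/genera: ",
              paste(members[dropped], collapse = ", "))
      X <- X[!dropped, , drop = FALSE]
    }
    if (nrow(X) == 0) stop("module '", m, "' has only zero-variance members")
    sv <- svd(X, nu = 0, nv = 1)
    v <- sv$v[, 1]
    ref <- colMeans(X)
    s <- sign(sum(v * ref))
    if (s == 0) s <- sign(v[which(v != 0)[1]])
    v <- v * s
    scores[, m] <- v
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(scores = scores, var_explained = ve,
                 sample_ids = colnames(profiles)),
            class = "eigengenus_matrix")
}

#' @export
print.eigengenus_matrix <- function(x, ...) {
  cat(sprintf("Eigengenus matrix: %d sample(s) x %d module(s)\n",
              nrow(x$scores), ncol(x$scores)))
  cat("variance explained:\n")
  print(round(x$var_explained, 3))
  invisible(x)
}

#' Intramodular connectivity (kME)
#'
#' Pearson correlation of each genus profile with each module eigengenus.
#' High-kME members are the hubs of their module.
#'
#' @param profiles transformed abundance matrix (genus x sample).
#' @param eigengenus an `eigengenus_matrix` with matching samples.
#' @return genus x module matrix of correlations; zero-variance genera get
#'   `NA`.
#' @export
kme <- function(profiles, eigengenus) {
  stopifnot(inherits(eigengenus, "eigengenus_matrix"))
  profiles <- as.matrix(profiles)
  if (!identical(colnames(profiles), eigengenus$sample_ids))
    stop("sample ids of profiles and eigengenus matrix do not match")
  sd <- apply(profiles, 1, stats::sd)
  k <- suppressWarnings(stats::cor(t(profiles), eigengenus$scores))
  k[sd == 0, ] <- NA_real_
  k
}

#' Encode clinical traits as a numeric matrix
#'
#' Diagnosis becomes three one-vs-rest indicators (control, UC, CD) plus a
#' combined IBD indicator; colon region is coded ordinally 0-4 from cecum
#' to rectum; collection site becomes one indicator per level (one column
#' if two levels).
#'
#' @param metadata validated metadata (see [validate_metadata()]).
#' @param sample_ids optional ordering/subset of samples.
#' @return numeric sample x trait matrix.
#' @export
encode_traits <- function(metadata, sample_ids = metadata$sample_id) {
  metadata <- validate_metadata(metadata)
  i <- match(sample_ids, metadata$sample_id)
  if (anyNA(i)) stop("metadata missing sample(s): ",
                     paste(sample_ids[is.na(i)], collapse = ", "))
  md <- metadata[i, ]
  tr <- cbind(control = as.numeric(md$diagnosis == "control"),
              UC = as.numeric(md$diagnosis == "UC"),
              CD = as.numeric(md$diagnosis == "CD"),
              IBD = as.numeric(md$diagnosis %in% c("UC", "CD")),
              region = as.numeric(md$region) - 1)
  sites <- sort(unique(as.character(md$site)))
  if (length(sites) == 2) {
    tr <- cbind(tr, site = as.numeric(md$site == sites[2]))
  } else if (length(sites) > 2) {
    for (s in sites) tr <- cbind(tr, as.numeric(md$site == s))
    colnames(tr)[(ncol(tr) - length(sites) + 1):ncol(tr)] <- paste0("site_", sites)
  }
  rownames(tr) <- md$sample_id
  tr
}

#' Correlate module eigengenera with clinical traits
#'
#' Pearson correlation of each eigengenus with each encoded trait;
#' two-sided p-values from the t distribution with n - 2 degrees of
#' freedom. Constant traits are flagged and reported as `NA`.
#'
#' @param eigengenus an `eigengenus_matrix`.
#' @param traits numeric sample x trait matrix (see [encode_traits()]) or
#'   a metadata data.frame, which is encoded automatically.
#' @return object of class `trait_association`: matrices `correlation`
#'   and `p_value` (module x trait), plus `n` and `flagged_constant`.
#' @export
module_trait_correlation <- function(eigengenus, traits) {
  stopifnot(inherits(eigengenus, "eigengenus_matrix"))
  if (is.data.frame(traits)) traits <- encode_traits(traits, eigengenus$sample_ids)
  traits <- as.matrix(traits)
  if (!is.null(rownames(traits)))
    traits <- traits[eigengenus$sample_ids, , drop = FALSE]
  n <- nrow(traits)
  const <- apply(traits, 2, function(v) stats::sd(v) == 0)
  r <- matrix(NA_real_, ncol(eigengenus$scores), ncol(traits),
              dimnames = list(colnames(eigengenus$scores), colnames(traits)))
  p <- r
  for (j in which(!const)) {
    for (m in seq_len(nrow(r))) {
      ct <- stats::cor.test(eigengenus$scores[, m], traits[, j])
      r[m, j] <- unname(ct$estimate)
      p[m, j] <- ct$p.value
    }
  }
  if (any(const))
    warning("constant trait(s) flagged: ",
            paste(colnames(traits)[const], collapse = ", "))
  structure(list(correlation = r, p_value = p, n = n,
                 flagged_constant = colnames(traits)[const]),
            class = "trait_association")
}

#' @export
print.trait_association <- function(x, digits = 3, ...) {
  cat(sprintf("Module-trait correlations (n = %d samples):\n", x$n))
  print(round(x$correlation, digits))
  cat("p-values:\n")
  print(signif(x$p_value, digits))
  invisible(x)
}

#' Differential abundance across diagnosis groups
#'
#' One-way equal-variance ANOVA of each taxon's relative abundance across
#' the diagnosis groups, with Benjamini-Hochberg correction across taxa.
#' Taxa with zero total variance get F = 0 and p = 1 by convention.
#'
#' @param x a `relative_abundance_table` or a fractions matrix
#'   (taxon x sample).
#' @param groups factor or character of diagnosis labels, one per sample.
#' @param alpha FDR threshold used only to set the enriched-group flag
#'   (default 0.05).
#' @return data.frame, one row per taxon: per-group means, `F`, `p_value`,
#'   `p_adjusted` (BH) and `enriched_in` (group with the largest mean,
#'   reported for taxa significant at `alpha`).
#' @export
differential_abundance <- function(x, groups, alpha = 0.05) {
  f <- if (inherits(x, "relative_abundance_table")) x$fractions else as.matrix(x)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 diagnosis groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  if (length(groups) != ncol(f)) stop("one group label per sample required")
  res <- data.frame(taxon = rownames(f), stringsAsFactors = FALSE)
  gm <- t(apply(f, 1, function(v) tapply(v, groups, mean)))
  colnames(gm) <- paste0("mean_", levels(groups))
  res <- cbind(res, gm)
  Fv <- numeric(nrow(f)); pv <- numeric(nrow(f))
  for (i in seq_len(nrow(f))) {
    v <- f[i, ]
    if (stats::sd(v) == 0) { Fv[i] <- 0; pv[i] <- 1; next }
    ow <- tryCatch(stats::oneway.test(v ~ groups, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(ow) || is.na(ow$p.value)) { Fv[i] <- 0; pv[i] <- 1 } else {
      Fv[i] <- unname(ow$statistic); pv[i] <- ow$p.value
    }
  }
  res$F <- Fv
  res$p_value <- pv
  res$p_adjusted <- stats::p.adjust(pv, method = "BH")
  top <- levels(groups)[apply(gm, 1, which.max)]
  res$enriched_in <- ifelse(res$p_adjusted < alpha, top, NA_character_)
  res
}

#' Hub enrichment test within a module
#'
#' Welch two-sample t-test comparing the intramodular connectivities (kME)
#' of flagged members (e.g. disease-enriched genera) against the remaining
#' members of the same module. A positive statistic means the flagged
#' group has the higher mean kME.
#'
#' @param kme_values numeric kME values of the module members.
#' @param flags logical, same length; `TRUE` marks the flagged subgroup.
#' @return `htest` object from [stats::t.test()].
#' @export
hub_enrichment_test <- function(kme_values, flags) {
  flags <- as.logical(flags)
  stopifnot(length(kme_values) == length(flags))
  if (sum(flags) < 2 || sum(!flags) < 2)
    stop("both groups need at least 2 members")
  stats::t.test(kme_values[flags], kme_values[!flags])
}
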