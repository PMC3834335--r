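#' Assemble subject-level features across colon regions
#'
#' Builds one row per subject, crossing taxa (relative abundances) or
#' modules (eigengenus scores) with the requested colon regions; feature
#' names follow the `"<unit>@<region>"` convention. Subjects lacking a
#' sample from any requested region are excluded (matched-sample design).
#'
#' @param x a `relative_abundance_table` (genus unit) — ignored for the
#'   module unit.
#' @param metadata validated sample metadata.
#' @param regions character subset of [region_levels()].
#' @param unit `"genus"` or `"module"`.
#' @param eigengenus an `eigengenus_matrix` over the metadata samples
#'   (required for the module unit).
#' @return object of class `feature_table`: `x` (subject x feature
#'   matrix), `diagnosis` (factor per subject) and `excluded_subjects`.
#' @export
build_features <- function(x, metadata, regions, unit = c("genus", "module"),
                           eigengenus = NULL) {
  unit <- match.arg(unit)
  metadata <- validate_metadata(metadata)
  regions <- match.arg(regions, region_levels(), several.ok = TRUE)
  if (unit == "genus") {
    vals <- if (inherits(x, "relative_abundance_table")) x$fractions else as.matrix(x)
  } else {
    if (is.null(eigengenus)) stop("module unit requires an eigengenus matrix")
    vals <- t(eigengenus$scores)   # module x sample
  }
  metadata <- metadata[metadata$sample_id %in% colnames(vals), , drop = FALSE]
  subjects <- unique(metadata$subject_id)
  # one sample per requested region per subject
  pick <- function(subj, reg) {
    s <- metadata$sample_id[metadata$subject_id == subj & metadata$region == reg]
    if (length(s) >= 1) s[1] else NA_character_
  }
  grid <- vapply(subjects, function(su)
    vapply(regions, function(rg) pick(su, rg), character(1)),
    character(length(regions)))
  grid <- matrix(grid, nrow = length(regions),
                 dimnames = list(regions, subjects))
  complete <- colSums(is.na(grid)) == 0
  excluded <- subjects[!complete]
  if (length(excluded))
    message("build_features: excluded subject(s) lacking a requested region: ",
            paste(excluded, collapse = ", "))
  subjects <- subjects[complete]
  if (!length(subjects)) stop("no subject has samples in every requested region")
  feat <- do.call(cbind, lapply(regions, function(rg) {
    m <- t(vals[, grid[rg, subjects], drop = FALSE])
    colnames(m) <- paste0(rownames(vals), "@", rg)
    m
  }))
  rownames(feat) <- subjects
  diag_per_subject <- factor(
    vapply(subjects, function(su)
      as.character(metadata$diagnosis[metadata$subject_id == su][1]), character(1)),
    levels = diagnosis_levels())
  structure(list(x = feat, diagnosis = droplevels(diag_per_subject),
                 regions = regions, unit = unit,
                 excluded_subjects = excluded),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d subject(s) x %d %s-region feature(s)\n",
              nrow(x$x), ncol(x$x), x$unit))
  print(table(x$diagnosis))
  invisible(x)
}

#' Fit a nearest shrunken centroids classifier
#'
#' Class centroids are shrunk toward the overall centroid by soft
#' thresholding of the standardized differences
#' `d[i,k] = (xbar[i,k] - xbar[i]) / (m_k (s_i + s0))`, with
#' `m_k = sqrt(1/n_k - 1/n)` and `s_i` the pooled within-class standard
#' deviation. Features whose shrunken difference vanishes in every class
#' carry no discriminative weight and are dropped, giving embedded feature
#' selection controlled by the shrinkage `delta`.
#'
#' @param x subject x feature numeric matrix, or a `feature_table`.
#' @param y class labels (factor); taken from the feature table if omitted.
#' @param delta non-negative shrinkage threshold.
#' @param s0 fudge constant added to `s_i`; default the median of the
#'   `s_i`.
#' @param priors `"empirical"` class frequencies (default) or `"uniform"`.
#' @return object of class `nsc` with centroids, shrunken centroids,
#'   pooled sds, priors and the surviving feature set.
#' @export
nsc <- function(x, y = NULL, delta = 0, s0 = NULL,
                priors = c("empirical", "uniform")) {
  priors <- match.arg(priors)
  if (inherits(x, "feature_table")) { if (is.null(y)) y <- x$diagnosis; x <- x$x }
  x <- as.matrix(x)
  y <- droplevels(factor(y))
  if (delta < 0) stop("delta must be non-negative")
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("every class needs at least 2 subjects")
  if (length(y) != nrow(x)) stop("one label per subject required")
  n <- nrow(x); K <- nlevels(y); nk <- table(y)
  overall <- colMeans(x)
  cent <- t(rowsum(x, y) / as.vector(nk))           # feature x class
  ws <- vapply(levels(y), function(k) {
    xi <- x[y == k, , drop = FALSE]
    colSums((xi - matrix(cent[, k], nrow(xi), ncol(xi), byrow = TRUE))^2)
  }, numeric(ncol(x)))
  within_ss <- rowSums(matrix(ws, nrow = ncol(x)))
  s <- sqrt(within_ss / (n - K))
  if (is.null(s0)) s0 <- stats::median(s)
  mk <- sqrt(1 / as.vector(nk) - 1 / n)
  d <- (cent - overall) / (outer(s + s0, mk))
  dshr <- sign(d) * pmax(abs(d) - delta, 0)
  surviving <- rowSums(dshr != 0) > 0
  shrunk_cent <- overall + (outer(s + s0, mk)) * dshr
  pi_k <- if (priors == "empirical") as.vector(nk) / n else rep(1 / K, K)
  structure(list(classes = levels(y), overall = overall, centroids = cent,
                 shrunken_centroids = shrunk_cent, s = s, s0 = s0,
                 mk = stats::setNames(mk, levels(y)),
                 priors = stats::setNames(pi_k, levels(y)),
                 delta = delta, d = d, d_shrunken = dshr,
                 surviving = surviving, n = n),
            class = "nsc")
}

#' @export
print.nsc <- function(x, ...) {
  cat(sprintf(paste0("Nearest shrunken centroids fit: %d class(es), ",
                     "%d/%d feature(s) surviving at delta = %.4g\n"),
              length(x$classes), sum(x$surviving), length(x$surviving), x$delta))
  invisible(x)
}

#' @export
coef.nsc <- function(object, ...) object$d_shrunken[object$surviving, , drop = FALSE]

#' Predict disease state with a fitted NSC model
#'
#' Uses the discriminant
#' `delta_k(x) = sum_i (x_i - xbar'[i,k])^2 / (s_i + s0)^2 - 2 log pi_k`
#' over the surviving features; the predicted class minimises it, and
#' class probabilities follow from the softmin `exp(-delta_k / 2)`.
#'
#' @param object an `nsc` fit.
#' @param newx subject x feature matrix (or `feature_table`) with the
#'   training features present.
#' @param type `"class"` (default) or `"posterior"`.
#' @param ... unused.
#' @export
predict.nsc <- function(object, newx, type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  if (inherits(newx, "feature_table")) newx <- newx$x
  newx <- as.matrix(newx)
  miss <- setdiff(names(object$overall), colnames(newx))
  if (length(miss)) stop("missing feature(s): ", paste(miss[1:min(3, length(miss))],
                                                       collapse = ", "))
  newx <- newx[, names(object$overall), drop = FALSE]
  surv <- object$surviving
  disc <- vapply(seq_along(object$classes), function(k) {
    if (any(surv)) {
      dev <- sweep(newx[, surv, drop = FALSE], 2,
                   object$shrunken_centroids[surv, k], "-")
      rowSums(sweep(dev^2, 2, (object$s[surv] + object$s0)^2, "/"))
    } else rep(0, nrow(newx))
  }, numeric(nrow(newx)))
  disc <- matrix(disc, nrow = nrow(newx),
                 dimnames = list(rownames(newx), object$classes))
  disc <- sweep(disc, 2, 2 * log(object$priors), "-")
  if (type == "class") {
    lab <- object$classes[apply(disc, 1, which.min)]
    return(factor(lab, levels = object$classes))
  }
  w <- exp(-(disc - apply(disc, 1, min)) / 2)
  w / rowSums(w)
}

#' Leave-one-out cross-validation of NSC over a shrinkage grid
#'
#' One fold per subject: the model is refit without the held-out subject
#' and its class probabilities predicted. A subject is counted correctly
#' classified when the cross-validated probability of its true class
#' exceeds 50%. The reported `delta` is the largest grid value achieving
#' the minimum error count (the most parsimonious optimum).
#'
#' @param x subject x feature matrix or `feature_table`.
#' @param y class labels; taken from the feature table if omitted.
#' @param delta_grid non-negative shrinkage values to evaluate.
#' @param priors passed to [nsc()].
#' @return object of class `nsc_cv`: data.frame `errors` (per delta:
#'   surviving features on the full data, error count, error rate),
#'   `probabilities` (subject x delta matrix of cross-validated true-class
#'   probabilities), `delta` (chosen) and `n`.
#' @export
nsc_loocv <- function(x, y = NULL, delta_grid = seq(0, 3, by = 0.25),
                      priors = "empirical") {
  if (inherits(x, "feature_table")) { if (is.null(y)) y <- x$diagnosis; x <- x$x }
  x <- as.matrix(x)
  y <- droplevels(factor(y))
  n <- nrow(x)
  if (n < 3) stop("need at least 3 subjects for leave-one-out")
  prob <- matrix(NA_real_, n, length(delta_grid),
                 dimnames = list(rownames(x), paste0("delta_", delta_grid)))
  flagged <- rep(FALSE, n)
  for (i in seq_len(n)) {
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < nlevels(y) || any(table(ytr) < 2)) {
      flagged[i] <- TRUE
      next
    }
    for (j in seq_along(delta_grid)) {
      fit <- nsc(x[-i, , drop = FALSE], ytr, delta = delta_grid[j],
                 priors = priors)
      post <- predict(fit, x[i, , drop = FALSE], type = "posterior")
      prob[i, j] <- post[1, as.character(y[i])]
    }
  }
  if (any(flagged))
    warning(sum(flagged), " fold(s) lost a class in training; excluded from the error rate")
  denom <- sum(!flagged)
  err <- colSums(prob[!flagged, , drop = FALSE] <= 0.5)
  surv <- vapply(delta_grid, function(d) sum(nsc(x, y, delta = d,
                                                 priors = priors)$surviving),
                 numeric(1))
  errors <- data.frame(delta = delta_grid, surviving = surv,
                       errors = as.integer(err), n = denom,
                       error_rate = err / denom)
  best <- max(delta_grid[err == min(err)])
  structure(list(errors = errors, probabilities = prob, delta = best,
                 n = denom, flagged_folds = which(flagged)),
            class = "nsc_cv")
}

#' @export
print.nsc_cv <- function(x, ...) {
  cat(sprintf("NSC leave-one-out cross-validation (%d folds):\n", x$n))
  print(x$errors, row.names = FALSE, digits = 3)
  cat(sprintf("chosen delta = %.4g (error %d/%d = %.1f%%)\n", x$delta,
              x$errors$errors[x$errors$delta == x$delta], x$n,
              100 * x$errors$error_rate[x$errors$delta == x$delta]))
  invisible(x)
}
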