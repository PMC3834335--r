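#' Describe a synthetic cohort scenario
#'
#' Bundles every knob of the compositional count generator. The defaults
#' emulate the cohort the package targets: 64 subjects (32 control, 16 UC,
#' 16 CD) sampled at 3 colon regions each, 263 genera organised into 5
#' co-occurring communities of heterogeneous sizes, sequencing depth with
#' mean 6909 reads per sample and a 3000-read floor, one community
#' elevated in CD and one depressed in IBD.
#'
#' @param n_genera total number of genera.
#' @param module_sizes sizes of the planted modules (sum <= n_genera);
#'   remaining genera are unstructured background.
#' @param r_in nominal within-module basis correlation (|r_in| < 1);
#'   either a single value or one value per module.
#' @param r_out correlation between genera of different modules
#'   (0 <= r_out <= min(r_in)).
#' @param hub_spread half-width of the per-genus module loading
#'   heterogeneity: each member's squared loading is drawn uniformly from
#'   `r_in +/- hub_spread` (clipped to \[0.05, 0.95\]), giving every module
#'   an intramodular hub gradient as observed in real co-occurrence
#'   networks. The gradient is part of the generative law (fixed by the
#'   scenario seed), so paired datasets share it. Set 0 for exactly
#'   exchangeable members; modules with `r_in = 0` get loading 0.
#' @param effects module x diagnosis matrix of log-unit mean shifts
#'   (columns control/UC/CD); default shifts module 1 by +1 in CD and
#'   module 2 by -1 in UC and CD.
#' @param n_subjects named vector of subjects per diagnosis.
#' @param regions_per_subject number of distinct colon regions sampled per
#'   subject (1-5).
#' @param depth_mean,depth_dispersion negative-binomial read-depth law
#'   (mean, size); draws are floored at `depth_min`.
#' @param depth_min sequencing-depth floor (QC floor).
#' @param base_mean_sd standard deviation of the per-genus baseline
#'   log-abundance (controls abundance skew).
#' @param seed default seed used by [simulate_fmc()].
#' @return list of class `fmc_scenario`.
#' @export
fmc_scenario <- function(n_genera = 263,
                         module_sizes = c(5, 20, 40, 80, 118),
                         r_in = 0.6, r_out = 0,
                         effects = NULL,
                         n_subjects = c(control = 32, UC = 16, CD = 16),
                         regions_per_subject = 3,
                         depth_mean = 6909, depth_dispersion = 10,
                         depth_min = 3000,
                         base_mean_sd = 1.5,
                         hub_spread = 0.2,
                         seed = 1L) {
  n_mod <- length(module_sizes)
  if (sum(module_sizes) > n_genera)
    stop("module sizes exceed the number of genera")
  r_in <- rep_len(r_in, n_mod)
  if (any(abs(r_in) >= 1) || r_out < 0 ||
      (n_mod > 0 && r_out > min(pmax(r_in, 0))))
    stop("need |r_in| < 1 and 0 <= r_out <= min(r_in)")
  if (depth_min < 1) stop("depth floor must be at least 1 read")
  if (!regions_per_subject %in% 1:5)
    stop("regions_per_subject must be between 1 and 5")
  if (is.null(names(n_subjects)) ||
      !all(names(n_subjects) %in% diagnosis_levels()))
    stop("n_subjects must be named with diagnosis levels")
  if (is.null(effects)) {
    effects <- matrix(0, n_mod, 3,
                      dimnames = list(NULL, diagnosis_levels()))
    if (n_mod >= 1) effects[1, "CD"] <- 1
    if (n_mod >= 2) effects[2, c("UC", "CD")] <- -1
  }
  effects <- as.matrix(effects)
  if (nrow(effects) != n_mod || !all(diagnosis_levels() %in% colnames(effects)))
    stop("effects must be a module x diagnosis matrix with columns control/UC/CD")
  if (hub_spread < 0 || hub_spread >= 1) stop("hub_spread must be in [0, 1)")
  structure(list(n_genera = n_genera, module_sizes = module_sizes,
                 r_in = r_in, r_out = r_out, effects = effects,
                 n_subjects = n_subjects,
                 regions_per_subject = regions_per_subject,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 depth_min = depth_min, base_mean_sd = base_mean_sd,
                 hub_spread = hub_spread,
                 seed = as.integer(seed)),
            class = "fmc_scenario")
}

#' @export
print.fmc_scenario <- function(x, ...) {
  cat(sprintf(paste0("Synthetic scenario: %d genera, %d module(s) of sizes ",
                     "{%s}, r_in = %s, %d subjects x %d regions\n"),
              x$n_genera, length(x$module_sizes),
              paste(x$module_sizes, collapse = ", "),
              paste(unique(x$r_in), collapse = "/"),
              sum(x$n_subjects), x$regions_per_subject))
  invisible(x)
}

#' Simulate a compositional count dataset with planted modules
#'
#' Latent per-sample log-basis abundances follow a factor model: member
#' `i` of module `m` loads with `sqrt(r_i - r_out)` on a shared module
#' factor and `sqrt(r_out)` on a global factor, plus independent noise,
#' where the squared loading `r_i` varies around the nominal `r_in[m]` by
#' `hub_spread` — so each module carries a reproducible hub gradient. The
#' pair (i, j) of one module then has basis correlation
#' `sqrt((r_i - r_out) (r_j - r_out)) + r_out`, averaging close to
#' `r_in[m]`. Diagnosis shifts module-member means by the configured
#' log-unit effects. Fractions are the softmax of the latent logs;
#' observed counts are a multinomial draw at a per-sample depth from a
#' floored negative-binomial law, so column sums equal the sampled depths
#' exactly.
#'
#' Law parameters — per-genus baseline log-abundance and the module
#' loadings — are drawn from the scenario's own seed, so two datasets
#' simulated from the same scenario with different call seeds are
#' replicates of one generative law (the situation module preservation
#' probes); the call seed drives the cohort, factors, noise and counts.
#'
#' @param scenario an [fmc_scenario()].
#' @param seed integer seed (defaults to the scenario's).
#' @param sample_prefix prefix for generated sample ids.
#' @return object of class `fmc_simulation`: `table` (an
#'   [abundance_table]), `metadata` (validated data.frame) and `truth`
#'   (module assignment with colour labels, basis correlation matrix,
#'   expected fractions, latent log-basis matrix, diagnosis per sample).
#' @export
simulate_fmc <- function(scenario = fmc_scenario(), seed = scenario$seed,
                         sample_prefix = "S") {
  stopifnot(inherits(scenario, "fmc_scenario"))
  sizes <- scenario$module_sizes
  n_mod <- length(sizes)
  G <- scenario$n_genera
  r_in <- scenario$r_in; r_out <- scenario$r_out

  # module membership; colours assigned by size rank (largest = turquoise)
  colors <- module_color_order()
  size_rank <- order(order(-sizes, seq_along(sizes)))
  mod_color <- colors[size_rank]
  mod_index <- integer(G)
  if (n_mod > 0)
    mod_index[seq_len(sum(sizes))] <- rep(seq_len(n_mod), sizes)
  truth_lab <- ifelse(mod_index > 0, mod_color[pmax(mod_index, 1)], "grey")
  genus_ids <- sprintf("g%03d", seq_len(G))
  names(truth_lab) <- genus_ids

  # law parameters: fixed by the scenario seed, shared by paired datasets
  set.seed(scenario$seed)
  base_mu <- stats::rnorm(G, 0, scenario$base_mean_sd)
  r_i <- numeric(G)
  if (n_mod > 0) {
    in_mod <- mod_index > 0
    nominal <- r_in[mod_index[in_mod]]
    lo <- pmax(nominal - scenario$hub_spread, 0.05)
    hi <- pmin(nominal + scenario$hub_spread, 0.95)
    r_i[in_mod] <- stats::runif(sum(in_mod), lo, hi)
    r_i[in_mod][nominal == 0] <- 0       # ablated or uncorrelated modules
  }

  # cohort draw
  set.seed(seed)
  diag_per_subject <- rep(names(scenario$n_subjects), scenario$n_subjects)
  n_subj <- length(diag_per_subject)
  subject_ids <- sprintf("subj%03d", seq_len(n_subj))
  regions <- lapply(seq_len(n_subj), function(i)
    sort(sample.int(5, scenario$regions_per_subject)))
  metadata <- data.frame(
    sample_id = unlist(lapply(seq_len(n_subj), function(i)
      paste0(sample_prefix, subject_ids[i], "_", region_levels()[regions[[i]]]))),
    subject_id = rep(subject_ids, lengths(regions)),
    diagnosis = rep(diag_per_subject, lengths(regions)),
    region = region_levels()[unlist(regions)],
    site = "siteA",
    stringsAsFactors = FALSE)
  n_samp <- nrow(metadata)

  # latent factor model: z_i = sqrt(1 - r_i) e + sqrt(r_i - r_out) f_mod
  #                            + sqrt(r_out) f_global (module members only)
  Z <- matrix(stats::rnorm(G * n_samp), G, n_samp)
  if (n_mod > 0) {
    in_mod <- mod_index > 0
    Z[in_mod, ] <- Z[in_mod, , drop = FALSE] * sqrt(1 - r_i[in_mod])
    Fm <- matrix(stats::rnorm(n_mod * n_samp), n_mod, n_samp)
    load_mod <- sqrt(pmax(r_i[in_mod] - r_out, 0))
    Z[in_mod, ] <- Z[in_mod, ] + load_mod * Fm[mod_index[in_mod], , drop = FALSE]
    if (r_out > 0) {
      fg <- stats::rnorm(n_samp)
      Z[in_mod, ] <- Z[in_mod, ] +
        sqrt(r_out) * matrix(fg, sum(in_mod), n_samp, byrow = TRUE)
    }
  }

  # diagnosis effects on module members
  eff <- matrix(0, G, n_samp)
  diag_per_sample <- metadata$diagnosis
  for (m in seq_len(n_mod)) {
    rows <- which(mod_index == m)
    eff[rows, ] <- matrix(scenario$effects[m, diag_per_sample],
                          length(rows), n_samp, byrow = TRUE)
  }
  logbasis <- base_mu + Z + eff
  dimnames(logbasis) <- list(genus_ids, metadata$sample_id)
  expf <- apply(logbasis, 2, function(v) { e <- exp(v - max(v)); e / sum(e) })

  # true basis correlation matrix implied by the loadings
  true_cor <- diag(1, G)
  if (n_mod > 0) {
    in_mod <- mod_index > 0
    if (r_out > 0) true_cor[in_mod, in_mod] <- r_out
    lm_ <- sqrt(pmax(r_i - r_out, 0))
    for (m in seq_len(n_mod)) {
      rows <- which(mod_index == m)
      true_cor[rows, rows] <- outer(lm_[rows], lm_[rows]) + r_out
    }
    diag(true_cor) <- 1
  }
  dimnames(true_cor) <- list(genus_ids, genus_ids)

  depth <- pmax(stats::rnbinom(n_samp, mu = scenario$depth_mean,
                               size = scenario$depth_dispersion),
                scenario$depth_min)
  counts <- vapply(seq_len(n_samp), function(j)
    stats::rmultinom(1, depth[j], expf[, j])[, 1], integer(G))
  dimnames(counts) <- list(genus_ids, metadata$sample_id)
  dimnames(expf) <- dimnames(counts)

  structure(list(table = abundance_table(counts),
                 metadata = validate_metadata(metadata),
                 truth = list(assignment = truth_lab,
                              basis_correlation = true_cor,
                              module_loading = stats::setNames(r_i, genus_ids),
                              expected_fractions = expf,
                              log_basis = logbasis,
                              diagnosis = stats::setNames(diag_per_sample,
                                                          metadata$sample_id)),
                 scenario = scenario, seed = seed),
            class = "fmc_simulation")
}

#' @export
print.fmc_simulation <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort: %d genera x %d samples ",
                     "(%d subjects), %d planted module(s)\n"),
              nrow(x$table$counts), ncol(x$table$counts),
              length(unique(x$metadata$subject_id)),
              length(x$scenario$module_sizes)))
  invisible(x)
}

#' Simulate a reference/test dataset pair for preservation analysis
#'
#' The reference is always a draw from the scenario. The test dataset is
#' either an independent replicate of the same generative law
#' (`"replicate"`), a replicate whose genus labels are randomly shuffled
#' (`"permute_labels"`, destroying any correspondence between reference
#' modules and test co-occurrence structure), or a draw in which module
#' `k`'s within-module correlation is zeroed (`"drop_module"`, selective
#' structure loss).
#'
#' @param scenario an [fmc_scenario()].
#' @param perturbation one of `"replicate"`, `"permute_labels"`,
#'   `"drop_module"`.
#' @param k module index to ablate for `"drop_module"`.
#' @param seed integer seed; the test draw uses a deterministically
#'   derived seed.
#' @return list with `reference` and `test`, both `fmc_simulation`s.
#' @export
simulate_fmc_pair <- function(scenario = fmc_scenario(),
                              perturbation = c("replicate", "permute_labels",
                                               "drop_module"),
                              k = NULL, seed = scenario$seed) {
  perturbation <- match.arg(perturbation)
  reference <- simulate_fmc(scenario, seed = seed, sample_prefix = "R")
  test_seed <- (seed + 1000003L) %% .Machine$integer.max
  test_scenario <- scenario
  if (perturbation == "drop_module") {
    if (is.null(k) || k < 1 || k > length(scenario$module_sizes))
      stop("k must index a planted module")
    test_scenario$r_in[k] <- 0
  }
  test <- simulate_fmc(test_scenario, seed = test_seed, sample_prefix = "T")
  if (perturbation == "permute_labels") {
    set.seed((seed + 2000003L) %% .Machine$integer.max)
    perm <- sample.int(nrow(test$table$counts))
    m <- test$table$counts
    rownames(m) <- rownames(m)[perm]
    test$table$counts <- m[order(rownames(m)), , drop = FALSE]
    test$permuted <- TRUE
  }
  list(reference = reference, test = test)
}
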