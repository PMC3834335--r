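# small programmatic fixtures shared across test files

# deterministic toy count table
toy_counts <- function(n_genera = 3, n_samples = 3, seed = 42,
                       lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_genera * n_samples, lambda), n_genera, n_samples,
              dimnames = list(paste0("genus", seq_len(n_genera)),
                              paste0("sample", seq_len(n_samples))))
  abundance_table(m)
}

write_tsv_table <- function(tab, path = tempfile(fileext = ".tsv")) {
  write_abundance_table(tab, path)
  path
}

# minimal valid metadata for a set of sample ids
toy_metadata <- function(sample_ids,
                         diagnosis = rep_len(c("control", "UC", "CD"),
                                             length(sample_ids)),
                         region = rep_len(region_levels(), length(sample_ids)),
                         subject = paste0("subj", seq_along(sample_ids))) {
  data.frame(sample_id = sample_ids, subject_id = subject,
             diagnosis = diagnosis, region = region, site = "siteA",
             stringsAsFactors = FALSE)
}

# strictly positive random fraction matrix (genus x sample)
random_fractions <- function(n_genera, n_samples, seed = 1) {
  set.seed(seed)
  g <- matrix(rgamma(n_genera * n_samples, shape = 2), n_genera, n_samples,
              dimnames = list(paste0("g", seq_len(n_genera)),
                              paste0("s", seq_len(n_samples))))
  sweep(g, 2, colSums(g), "/")
}

# block TOM matrix with perfect within-block overlap
block_tom <- function(sizes, between = 0) {
  n <- sum(sizes)
  tom <- matrix(between, n, n)
  at <- 0
  for (s in sizes) {
    tom[(at + 1):(at + s), (at + 1):(at + s)] <- 1
    at <- at + s
  }
  diag(tom) <- 1
  dimnames(tom) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  tom
}

# compact planted-module cohort used by several statistics tests
small_cohort <- function(seed = 7) {
  scenario <- fmc_scenario(
    n_genera = 60, module_sizes = c(12, 20), r_in = 0.7,
    n_subjects = c(control = 16, UC = 8, CD = 8),
    regions_per_subject = 3, seed = seed)
  simulate_fmc(scenario)
}
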