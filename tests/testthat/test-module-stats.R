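test_that("eigengenus equals the SVD first component and explains rank-1 modules fully", {
  # module of identical profiles: variance explained 1, scores track the profile
  prof <- matrix(rep(c(1, 3, 2, 5, 4), each = 4), 4, 5, byrow = FALSE,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  lab <- setNames(rep("turquoise", 4), rownames(prof))
  eig <- module_eigengenus(prof, lab)
  expect_equal(unname(eig$var_explained["turquoise"]), 1)
  z <- scale(c(1, 3, 2, 5, 4))[, 1]; z <- z / sqrt(sum(z^2))
  expect_equal(unname(eig$scores[, "turquoise"]), z, tolerance = 1e-12)

  # antisymmetric rank-1 module (x and -x) still explains all variance
  prof2 <- rbind(g1 = c(1, 3, 2, 5, 4), g2 = -c(1, 3, 2, 5, 4))
  colnames(prof2) <- paste0("s", 1:5)
  eig2 <- module_eigengenus(prof2, setNames(rep("blue", 2), rownames(prof2)))
  expect_equal(unname(eig2$var_explained["blue"]), 1)
  expect_equal(sum(eig2$scores[, "blue"]^2), 1)

  # random 20-genus module against a brute-force SVD oracle
  set.seed(12)
  prof3 <- matrix(rnorm(20 * 15), 20, 15,
                  dimnames = list(paste0("g", 1:20), paste0("s", 1:15)))
  eig3 <- module_eigengenus(prof3, setNames(rep("brown", 20), rownames(prof3)))
  X <- t(scale(t(prof3)))
  sv <- svd(X)
  v <- sv$v[, 1]
  expect_lt(min(max(abs(eig3$scores[, "brown"] - v)),
                max(abs(eig3$scores[, "brown"] + v))), 1e-10)
  expect_equal(unname(eig3$var_explained["brown"]),
               sv$d[1]^2 / sum(sv$d^2))

  # zero-variance members are dropped with a warning
  prof4 <- rbind(prof3, flat = rep(1, 15))
  expect_warning(
    module_eigengenus(prof4, setNames(rep("brown", 21), rownames(prof4))),
    "zero-variance")
})

test_that("eigengenus is invariant to genus and sample order", {
  set.seed(13)
  prof <- matrix(rnorm(10 * 12), 10, 12,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  lab <- setNames(rep("turquoise", 10), rownames(prof))
  eig <- module_eigengenus(prof, lab)
  eig_g <- module_eigengenus(prof[sample(10), ], lab)
  expect_equal(eig_g$scores, eig$scores, tolerance = 1e-10)
  sp <- sample(12)
  eig_s <- module_eigengenus(prof[, sp], lab)
  expect_equal(eig_s$scores[colnames(prof), , drop = FALSE], eig$scores,
               tolerance = 1e-10)
})

test_that("kME is the correlation with the eigengenus", {
  set.seed(14)
  prof <- matrix(rnorm(6 * 10), 6, 10,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  lab <- setNames(rep("turquoise", 6), rownames(prof))
  eig <- module_eigengenus(prof, lab)
  # a genus identical to the eigengenus has kME 1
  prof2 <- rbind(prof, clone = eig$scores[, "turquoise"])
  k <- kme(prof2, eig)
  expect_equal(unname(k["clone", "turquoise"]), 1)
  # a constructed orthogonal genus has kME 0
  e <- eig$scores[, "turquoise"]
  y <- resid(lm(rnorm(10) ~ e))   # orthogonal to e by construction
  prof3 <- rbind(prof, ortho = y)
  k3 <- kme(prof3, eig)
  expect_lt(abs(k3["ortho", "turquoise"]), 1e-12)
  # zero-variance genus is missing
  prof4 <- rbind(prof, flat = rep(2, 10))
  expect_true(is.na(kme(prof4, eig)["flat", "turquoise"]))
})

test_that("planted-module members point to their own module's eigengenus", {
  sim <- small_cohort(seed = 17)
  profiles <- transform_abundance(to_relative(sim$table))
  eig <- module_eigengenus(profiles, sim$truth$assignment)
  k <- kme(profiles, eig)
  lab <- sim$truth$assignment
  members <- names(lab)[lab != "grey"]
  own <- k[cbind(members, lab[members])]
  other <- apply(k[members, , drop = FALSE], 1, max) == own
  expect_gte(mean(other), 0.95)
})

test_that("module-trait correlations recover a planted disease association", {
  sim <- small_cohort(seed = 19)   # module 1 (blue) is elevated in CD
  profiles <- transform_abundance(to_relative(sim$table))
  eig <- module_eigengenus(profiles, sim$truth$assignment)
  tr <- module_trait_correlation(eig, sim$metadata)
  expect_true(all(abs(tr$correlation) <= 1, na.rm = TRUE))
  expect_gt(tr$correlation["blue", "CD"], 0)
  expect_lt(tr$p_value["blue", "CD"], 0.01)

  # an eigengenus equal to the CD indicator correlates perfectly
  traits <- encode_traits(sim$metadata, eig$sample_ids)
  fake <- eig
  v <- traits[, "CD"]
  fake$scores <- cbind(turquoise = v / sqrt(sum(v^2)))
  tr2 <- module_trait_correlation(fake, sim$metadata)
  expect_equal(unname(tr2$correlation["turquoise", "CD"]), 1)
  expect_lt(tr2$p_value["turquoise", "CD"], 1e-12)

  # constant traits are flagged, not crashed on
  md <- sim$metadata
  md$site <- "siteA"              # single site: no site column emitted
  expect_s3_class(module_trait_correlation(eig, md), "trait_association")
})

test_that("differential abundance ANOVA behaves like t^2 and obeys BH monotonicity", {
  set.seed(23)
  f <- random_fractions(15, 20)
  groups <- rep(c("control", "CD"), each = 10)
  res <- differential_abundance(f, groups)
  # two groups: F equals the squared pooled t statistic
  for (i in c(1, 7, 15)) {
    tt <- t.test(f[i, 1:10], f[i, 11:20], var.equal = TRUE)
    expect_equal(res$F[i], unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-9)
  }
  expect_true(all(res$p_adjusted >= res$p_value))
  o <- order(res$p_value)
  expect_true(all(diff(res$p_adjusted[o]) >= -1e-12))

  # constant taxon: F = 0, p = 1 by convention
  f2 <- rbind(f, flat = 0.01)
  res2 <- differential_abundance(f2, groups)
  expect_equal(res2$F[res2$taxon == "flat"], 0)
  expect_equal(res2$p_value[res2$taxon == "flat"], 1)

  expect_error(differential_abundance(f, rep("control", 20)), "2 diagnosis groups")
})

test_that("a two-fold depletion is reliably detected at FDR 0.05", {
  hits <- 0L
  for (rep in 1:20) {
    set.seed(300 + rep)
    n <- 30; taxa <- 40
    logf <- matrix(rnorm(taxa * 2 * n, mean = -4, sd = 0.5), taxa, 2 * n)
    logf[1, (n + 1):(2 * n)] <- logf[1, (n + 1):(2 * n)] - log(2)  # CD depletion
    f <- sweep(exp(logf), 2, colSums(exp(logf)), "/")
    rownames(f) <- paste0("g", 1:taxa); colnames(f) <- paste0("s", 1:(2 * n))
    res <- differential_abundance(f, rep(c("control", "CD"), each = n))
    if (res$p_adjusted[1] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 18L)   # >= 90% power
})

test_that("hub enrichment is a Welch t-test on kME values", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  ht <- hub_enrichment_test(c(x, x), c(rep(TRUE, 4), rep(FALSE, 4)))
  expect_equal(unname(ht$statistic), 0)
  expect_equal(ht$p.value, 1)

  set.seed(29)
  flagged <- rnorm(10, 0.8, 0.1); others <- rnorm(40, 0.5, 0.1)
  ht2 <- hub_enrichment_test(c(flagged, others),
                             c(rep(TRUE, 10), rep(FALSE, 40)))
  expect_lt(ht2$p.value, 0.001)
  expect_gt(ht2$statistic, 0)
  # flagged group lower: negative statistic
  ht3 <- hub_enrichment_test(c(others, flagged),
                             c(rep(TRUE, 40), rep(FALSE, 10)))
  expect_lt(ht3$statistic, 0)

  expect_error(hub_enrichment_test(1:5, c(TRUE, rep(FALSE, 4))),
               "at least 2")
})
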