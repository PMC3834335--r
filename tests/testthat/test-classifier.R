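# cohort with matched samples across requested regions
feature_fixture <- function(n_subj = 12, genera = 3, seed = 61,
                            regions = c("descending", "rectum")) {
  set.seed(seed)
  subjects <- sprintf("subj%02d", seq_len(n_subj))
  md <- expand.grid(subject_id = subjects, region = regions,
                    stringsAsFactors = FALSE)
  md$sample_id <- paste0(md$subject_id, "_", md$region)
  md$diagnosis <- rep(rep_len(c("control", "UC", "CD"), n_subj), length(regions))
  md$site <- "siteA"
  f <- random_fractions(genera, nrow(md), seed = seed)
  colnames(f) <- md$sample_id
  list(f = f, md = md)
}

test_that("feature assembly crosses units with regions and enforces matching", {
  fx <- feature_fixture(n_subj = 4)
  ft <- build_features(fx$f, fx$md, regions = c("descending", "rectum"))
  expect_equal(dim(ft$x), c(4L, 6L))     # 3 genera x 2 regions
  expect_setequal(colnames(ft$x),
                  as.vector(outer(rownames(fx$f), c("descending", "rectum"),
                                  paste, sep = "@")))

  # a subject missing the rectum sample is excluded
  fx2 <- feature_fixture(n_subj = 4)
  keep <- !(fx2$md$subject_id == "subj01" & fx2$md$region == "rectum")
  expect_message(
    ft2 <- build_features(fx2$f[, fx2$md$sample_id[keep]], fx2$md[keep, ],
                          regions = c("descending", "rectum")),
    "subj01")
  expect_equal(nrow(ft2$x), 3L)

  # module unit: 2 modules x 2 regions = 4 module-region variables
  eig <- structure(list(
    scores = matrix(rnorm(2 * ncol(fx$f)), ncol(fx$f), 2,
                    dimnames = list(colnames(fx$f), c("turquoise", "blue"))),
    var_explained = c(turquoise = 0.5, blue = 0.4),
    sample_ids = colnames(fx$f)), class = "eigengenus_matrix")
  ftm <- build_features(NULL, fx$md, regions = c("descending", "rectum"),
                        unit = "module", eigengenus = eig)
  expect_equal(ncol(ftm$x), 4L)
})

test_that("unshrunken NSC is the plain standardized nearest-centroid rule", {
  set.seed(63)
  n <- 20; p <- 6
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- factor(rep(c("control", "IBD"), each = n / 2))
  x[y == "IBD", 1:2] <- x[y == "IBD", 1:2] + 1.5
  fit <- nsc(x, y, delta = 0, priors = "uniform")
  pred <- predict(fit, x)

  # oracle: standardized distance to the raw class centroids
  cent <- t(rowsum(x, y) / as.vector(table(y)))
  s <- fit$s; s0 <- fit$s0
  d2 <- sapply(levels(y), function(k)
    colSums((t(x) - cent[, k])^2 / (s + s0)^2))
  oracle <- factor(levels(y)[apply(d2, 1, which.min)], levels = levels(y))
  expect_identical(pred, oracle)
})

test_that("extreme shrinkage removes all features and predicts by prior", {
  set.seed(64)
  x <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- factor(c(rep("control", 20), rep("IBD", 10)))
  fit <- nsc(x, y, delta = 50)
  expect_equal(sum(fit$surviving), 0L)
  expect_true(all(predict(fit, x) == "control"))   # larger empirical prior
})

test_that("shrunken differences match a hand-worked toy example", {
  # 2 classes x 2 subjects, 3 features with known means
  x <- rbind(c(0, 0, 0), c(2, 2, 2), c(4, 0, 1), c(6, 2, 1))
  colnames(x) <- c("fa", "fb", "fc")
  y <- factor(c("A", "A", "B", "B"))
  fit <- nsc(x, y, delta = 0)
  n <- 4; K <- 2; nk <- c(2, 2)
  overall <- colMeans(x)
  centA <- colMeans(x[1:2, ]); centB <- colMeans(x[3:4, ])
  s <- sqrt((colSums((x[1:2, ] - rep(centA, each = 2))^2) +
             colSums((x[3:4, ] - rep(centB, each = 2))^2)) / (n - K))
  s0 <- median(s)
  mk <- sqrt(1 / 2 - 1 / 4)
  dA <- (centA - overall) / (mk * (s + s0))
  expect_equal(unname(fit$d[, "A"]), unname(dA), tolerance = 1e-12)

  # at a delta between the two |d| magnitudes only the stronger survives
  dmag <- sort(unique(round(abs(fit$d[, "A"]), 10)))
  mid <- mean(range(dmag))
  fit2 <- nsc(x, y, delta = mid)
  expect_identical(unname(fit2$surviving), unname(abs(fit$d[, "A"]) > mid))
})

test_that("feature survival is non-increasing in delta and training error minimal at 0", {
  set.seed(65)
  x <- matrix(rnorm(40 * 20), 40, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- factor(rep(c("control", "IBD"), each = 20))
  x[y == "IBD", 1:5] <- x[y == "IBD", 1:5] + 2
  grid <- seq(0, 4, by = 0.5)
  surv <- vapply(grid, function(d) sum(nsc(x, y, delta = d)$surviving),
                 numeric(1))
  expect_true(all(diff(surv) <= 0))
  err <- vapply(grid, function(d)
    sum(predict(nsc(x, y, delta = d), x) != y), numeric(1))
  expect_true(all(err >= err[1]))
})

test_that("prediction respects centroids and priors", {
  x <- rbind(c(0, 0), c(0.2, -0.2), c(4, 4), c(3.8, 4.2), c(0.1, 0.1),
             c(4.1, 3.9))
  colnames(x) <- c("fa", "fb")
  y <- factor(c("A", "A", "B", "B", "A", "B"))
  fit <- nsc(x, y, delta = 0, priors = "uniform")
  # a point sitting on a class centroid belongs to that class
  at_b <- rbind(fit$centroids[, "B"])
  expect_equal(as.character(predict(fit, at_b)), "B")
  # an equidistant point goes to the larger prior
  y2 <- factor(c("A", "A", "B", "B", "A", "A"))
  fit2 <- nsc(x[, 1, drop = FALSE], y2, delta = 50)  # no surviving features
  eq <- matrix(2, 1, 1, dimnames = list(NULL, "fa"))
  expect_equal(as.character(predict(fit2, eq)), "A")
  expect_error(predict(fit, matrix(1, 1, 1, dimnames = list(NULL, "zz"))),
               "missing feature")
})

test_that("leave-one-out cross-validation separates signal from noise", {
  set.seed(66)
  n <- 18
  x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- factor(rep(c("control", "IBD"), each = n / 2))
  x[y == "IBD", 1:3] <- x[y == "IBD", 1:3] + 4
  cv <- nsc_loocv(x, y, delta_grid = c(0, 0.5))
  expect_equal(cv$errors$errors[cv$errors$delta == 0], 0L)

  # determinism
  cv2 <- nsc_loocv(x, y, delta_grid = c(0, 0.5))
  expect_identical(cv$probabilities, cv2$probabilities)
  expect_error(nsc_loocv(x[1:2, ], y[1:2]), "at least 3")
})
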