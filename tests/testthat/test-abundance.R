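test_that("TSV round-trip preserves the table and respects orientation", {
  tab <- toy_counts(4, 3)
  path <- write_tsv_table(tab)
  back <- read_abundance_table(path)
  expect_identical(back$counts, tab$counts)

  # a samples-in-rows file read with the other orientation transposes back
  tpath <- tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = colnames(tab$counts), t(tab$counts),
                   check.names = FALSE)
  write.table(df, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  back_t <- read_abundance_table(tpath, orientation = "samples_rows")
  expect_identical(back_t$counts[rownames(tab$counts), colnames(tab$counts)],
                   tab$counts)
})

test_that("sparse triplet files load into the dense matrix", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("genus_id\tsample_id\tcount",
               "gA\ts1\t5", "gA\ts2\t0", "gB\ts1\t2", "gC\ts2\t7"), path)
  tab <- read_abundance_table(path)
  expect_equal(dim(tab$counts), c(3L, 2L))
  expect_equal(tab$counts["gC", "s2"], 7L)
  expect_equal(tab$counts["gB", "s2"], 0L)  # absent triplet = zero
})

test_that("validation rejects duplicates and bad counts, naming the culprit", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("gA", "gA"), c("s1", "s2")))
  expect_error(abundance_table(m), "gA")
  m2 <- matrix(c(1, -2, 3, 4), 2, 2,
               dimnames = list(c("gA", "gB"), c("s1", "s2")))
  expect_error(abundance_table(m2), "gB.*s1")
  m3 <- matrix(c(1, 2.5, 3, 4), 2, 2,
               dimnames = list(c("gA", "gB"), c("s1", "s2")))
  expect_error(abundance_table(m3), "non-integer")

  path <- tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), path)
  expect_error(read_abundance_table(path), "gA")
})

test_that("quality filter applies the read floor and singleton rule", {
  m <- matrix(0L, 3, 3, dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  m[, 1] <- c(1000L, 1000L, 999L)   # 2999 reads: below the floor
  m[, 2] <- c(2000L, 1500L, 0L)
  m[, 3] <- c(1500L, 1501L, 1L)     # g3 appears once in total: singleton
  tab <- abundance_table(m)
  filt <- quality_filter(tab, min_reads_per_sample = 3000)
  expect_false("s1" %in% colnames(filt$counts))
  expect_false("g3" %in% rownames(filt$counts))
  expect_setequal(colnames(filt$counts), c("s2", "s3"))

  # threshold 0 without singleton dropping is the identity
  expect_identical(quality_filter(tab, 0, drop_singletons = FALSE)$counts,
                   tab$counts)
  expect_error(quality_filter(tab, 1e9), "all samples")
})

test_that("quality filter is idempotent", {
  set.seed(5)
  m <- matrix(rpois(30 * 12, 300), 30, 12,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:12)))
  m[1:5, ] <- 0L; m[1, 3] <- 1L
  tab <- abundance_table(m)
  once <- quality_filter(tab, min_reads_per_sample = 3000)
  twice <- quality_filter(once, min_reads_per_sample = 3000)
  expect_identical(once$counts, twice$counts)
})

test_that("relative abundances normalise each sample to one", {
  m <- matrix(c(2L, 2L, 4L), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  rel <- to_relative(abundance_table(m))
  expect_equal(rel$fractions[, 1], c(g1 = 0.25, g2 = 0.25, g3 = 0.5))

  single <- abundance_table(matrix(c(5L, 7L), 1, 2,
                                   dimnames = list("g1", c("s1", "s2"))))
  expect_true(all(to_relative(single)$fractions == 1))

  for (seed in 1:5) {
    tab <- toy_counts(10, 6, seed = seed, lambda = 20)
    expect_true(all(abs(colSums(to_relative(tab)$fractions) - 1) < 1e-9))
  }

  zero <- abundance_table(matrix(c(1L, 0L), 1, 2,
                                 dimnames = list("g1", c("s1", "s2"))))
  expect_error(to_relative(zero), "zero-total")
})

test_that("shared-genus alignment reports read retention", {
  a <- abundance_table(matrix(c(500L, 400L, 68L, 30L, 2L),
                              5, 1, dimnames = list(
                                c("gA", "gB", "gC", "gD", "gE"), "s1")))
  b <- abundance_table(matrix(c(10L, 20L, 30L), 3, 1,
                              dimnames = list(c("gB ", "GA", "gC"), "s1")))
  al <- align_shared_genera(a, b)
  # matching is trimmed + case-folded; a keeps 500+400+68 = 968 of 1000
  expect_equal(al$report$reads_kept[1], 968)
  expect_equal(al$report$reads_total[1], 1000)
  expect_equal(al$report$percent_kept[1], 96.8)
  expect_identical(tolower(trimws(rownames(al$a$counts))),
                   tolower(trimws(rownames(al$b$counts))))

  ident <- align_shared_genera(a, a)
  expect_equal(ident$report$percent_kept, c(100, 100))
  expect_identical(ident$a$counts, a$counts)

  disj <- abundance_table(matrix(1L, 1, 1, dimnames = list("gZ", "s1")))
  expect_error(align_shared_genera(a, disj), "no shared genera")

  # retention denominator equals the input column-sum total
  expect_equal(al$report$reads_total[2], sum(b$counts))
})

test_that("metadata validation enforces the closed vocabularies", {
  md <- toy_metadata(paste0("s", 1:5))
  expect_s3_class(validate_metadata(md)$region, "ordered")
  md_bad <- md; md_bad$diagnosis[1] <- "healthy"
  expect_error(validate_metadata(md_bad), "diagnosis")
  md_miss <- md[, -3]
  expect_error(validate_metadata(md_miss), "diagnosis")
  expect_error(validate_metadata(rbind(md, md[1, ])), "duplicated sample_id")
})

test_that("phylum roll-up sums genus counts by taxonomy", {
  tab <- toy_counts(4, 2)
  tab$taxonomy <- c(genus1 = "Firmicutes", genus2 = "Firmicutes",
                    genus3 = "Bacteroidetes")
  ph <- rollup_phylum(tab)
  expect_equal(ph$counts["Firmicutes", ],
               colSums(tab$counts[c("genus1", "genus2"), ]))
  expect_equal(ph$counts["unclassified", ], tab$counts["genus4", ])
})
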