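test_that("expression matrix TSV round-trips and rejects malformed input", {
  em <- make_em(matrix(c(1, 2, 3, 4), 2, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(em, path)
  back <- read_expression_matrix(path, species = "AA")
  expect_equal(back$values, em$values)
  expect_equal(dim(back), c(2L, 2L))

  lines <- readLines(path)
  writeLines(c(lines, lines[2]), path) # duplicate first gene row
  expect_error(read_expression_matrix(path, species = "AA"), "duplicate")

  writeLines(c("gene_id\tsubgenome\tlength_bp", "g1\tAr\t100"), path)
  expect_error(read_expression_matrix(path, species = "AA"),
               "no sample columns")
  writeLines(c("gene_id\tlength_bp\ts1", "g1\t100\t1"), path)
  expect_error(read_expression_matrix(path, species = "AA"), "subgenome")
})

test_that("constructor enforces matrix invariants", {
  expect_error(make_em(matrix(-1, 1, 1)), "non-negative")
  expect_error(expression_matrix(matrix(1, 2, 1), c("a", "a"),
                                 c("Ar", "Ar"), c(100, 100), "AA", "fpkm"),
               "duplicate")
  expect_error(make_em(matrix(1, 1, 1), length_bp = 0), "positive")
})

test_that("FPKM conversion matches the defining formula", {
  # column sum 1e6: count 10 over 1 kb -> FPKM 10
  counts <- matrix(c(10, 1e6 - 10), 2, 1)
  em <- make_em(counts, unit = "counts", length_bp = c(1000, 2000))
  f <- compute_fpkm(em)
  expect_equal(f$values[1, 1], 10)
  expect_identical(f$unit, "fpkm")
  # count 5, 500 bp, column total 2e6 -> FPKM 5
  counts <- matrix(c(5, 2e6 - 5), 2, 1)
  em <- make_em(counts, unit = "counts", length_bp = c(500, 1000))
  expect_equal(compute_fpkm(em)$values[1, 1], 5)
  # zero count stays zero; zero column warns and yields zeros
  em <- make_em(matrix(c(0, 7), 2, 2) * c(1, 1), unit = "counts")
  expect_equal(compute_fpkm(em)$values[1, ], c(rep1 = 0, rep2 = 0))
  em0 <- make_em(matrix(0, 2, 1), unit = "counts")
  expect_warning(f0 <- compute_fpkm(em0), "zero library size")
  expect_true(all(f0$values == 0))
  expect_error(compute_fpkm(f), "counts-mode")
})

test_that("FPKM is invariant to scaling a sample's counts", {
  set.seed(1)
  counts <- matrix(rpois(40, 50), 10, 4)
  em <- make_em(counts, unit = "counts",
                length_bp = sample(500:2000, 10))
  scaled <- em
  scaled$values[, 2] <- scaled$values[, 2] * 7
  expect_equal(compute_fpkm(em)$values, compute_fpkm(scaled)$values)
})

test_that("expression bins are half-open and partition all genes", {
  x <- c(0, 0.5, 1, 9.99, 10, 99.9, 100, 5000)
  b <- bin_by_expression(x)
  expect_equal(as.character(b),
               c("[0,1)", "[0,1)", "[1,10)", "[1,10)", "[10,100)",
                 "[10,100)", "[100,Inf)", "[100,Inf)"))
  expect_false(anyNA(b))
  expect_equal(sum(table(b)), length(x))
  expect_error(bin_by_expression(c(1, -0.1)), "non-negative")
})

test_that("Venn region counts match brute-force membership enumeration", {
  ov <- overlap_counts(list(P1 = "a", H = "b", P2 = "c"))
  expect_true(all(ov$regions[grepl("&", names(ov$regions))] == 0))
  ov <- overlap_counts(list(P1 = letters[1:5], H = letters[1:5],
                            P2 = letters[1:5]))
  expect_equal(unname(ov$regions[["P1&H&P2"]]), 5)
  expect_equal(sum(ov$regions), 5)

  set.seed(42)
  for (i in 1:10) {
    sets <- lapply(1:3, function(.) sample(letters, sample(0:20, 1)))
    names(sets) <- c("A", "B", "C")
    ov <- overlap_counts(sets)
    ids <- unique(unlist(sets))
    brute <- sapply(ids, function(g)
      paste(names(sets)[sapply(sets, function(s) g %in% s)],
            collapse = "&"))
    expect_equal(sum(ov$regions), length(ids))
    for (key in names(ov$regions))
      expect_equal(unname(ov$regions[[key]]), sum(brute == key))
  }
})

test_that("sample correlation is Spearman with unit diagonal", {
  set.seed(3)
  m <- matrix(rexp(20, 0.1), 5, 4)
  m[, 2] <- m[, 1]                 # duplicated sample
  em <- make_em(m)
  cc <- sample_correlation(em)
  expect_equal(cc[1, 2], 1)
  expect_equal(unname(diag(cc)), rep(1, 4))
  # monotone transform preserves rank correlation
  m2 <- cbind(m[, 3], log1p(m[, 3]))
  expect_equal(sample_correlation(make_em(m2))[1, 2], 1)
  # naive rank-then-Pearson oracle
  naive <- cor(apply(m, 2, rank))
  expect_equal(unname(cc), unname(naive), tolerance = 1e-12)
  # constant column reported as missing
  m[, 4] <- 1
  expect_true(anyNA(sample_correlation(make_em(m))))
})

test_that("PCA embedding returns k components of the log10 matrix", {
  set.seed(4)
  em <- make_em(matrix(rexp(60, 0.05), 15, 4))
  coords <- pca_embedding(em, k = 2)
  expect_equal(dim(coords), c(4L, 2L))
  expect_length(attr(coords, "var_explained"), 2L)
  ref <- prcomp(t(log10(em$values + 1)))$x[, 1:2]
  expect_equal(abs(unname(coords)), abs(unname(ref)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(pca_embedding(make_em(matrix(1:3, 3, 1))), "2 samples")
})
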