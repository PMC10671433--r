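blast_line <- function(q, s, e, bits)
  sprintf("%s\t%s\t98.5\t350\t5\t0\t1\t350\t1\t350\t%s\t%s", q, s, e, bits)

test_that("BLAST tabular parsing accepts outfmt 6 and rejects junk", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(blast_line("q1", "s1", "1e-50", "200"), path)
  hits <- read_blast_tab(path)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$e_value, 1e-50)
  expect_equal(hits$bit_score, 200)

  writeLines("q1\ts1\t98.5\t350\t5\t0\t1\t350\t1\t350\t1e-50", path)
  expect_error(read_blast_tab(path), "11 columns")

  writeLines(c(blast_line("q1", "s1", "1e-50", "200"),
               blast_line("q1", "s2", "xx", "100")), path)
  expect_error(read_blast_tab(path), "line 2")

  writeLines(c(blast_line("a", "x", "1e-30", "150"),
               blast_line("b", "y", "1e-40", "180"),
               blast_line("c", "z", "1e-25", "120")), path)
  hits <- read_blast_tab(path)
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$query_id, c("a", "b", "c"))
})

test_that("best hits keep the top bit score with deterministic tie-breaks", {
  hits <- data.frame(query_id = "q", subject_id = "s",
                     e_value = 1e-30, bit_score = 100)
  expect_equal(best_hits(hits)$subject_id, "s")

  hits <- data.frame(query_id = c("q", "q"), subject_id = c("s1", "s2"),
                     e_value = c(1e-30, 1e-30), bit_score = c(200, 150))
  expect_equal(best_hits(hits)$subject_id, "s1")

  # tie on bit score and e-value -> lexicographically smallest subject,
  # whatever the input order
  for (ord in list(1:2, 2:1)) {
    hits <- data.frame(query_id = "q", subject_id = c("gB", "gA")[ord],
                       e_value = 1e-30, bit_score = 100)
    expect_equal(best_hits(hits)$subject_id, "gA")
  }

  # e-value filter and self-hit exclusion
  hits <- data.frame(query_id = c("q", "q"), subject_id = c("s1", "q"),
                     e_value = c(1e-5, 1e-60), bit_score = c(50, 500))
  expect_equal(nrow(best_hits(hits)), 0L)
  expect_equal(best_hits(hits, e_cutoff = 1)$subject_id, "s1")
})

test_that("reciprocal filtering keeps mutual best hits only", {
  fwd <- data.frame(query_id = "a", subject_id = "x",
                    e_value = 1e-40, bit_score = 120)
  rev_ok <- data.frame(query_id = "x", subject_id = "a",
                       e_value = 1e-42, bit_score = 118)
  pairs <- reciprocal_best_hits(fwd, rev_ok, "An")
  expect_equal(pairs$ar_gene, "a")
  expect_equal(pairs$partner_gene, "x")
  expect_equal(pairs$rev_bit_score, 118)

  rev_bad <- data.frame(query_id = "x", subject_id = "b",
                        e_value = 1e-42, bit_score = 118)
  expect_equal(nrow(reciprocal_best_hits(fwd, rev_bad, "An")), 0L)
})

test_that("pair output is a partial matching and monotone in the cutoff", {
  set.seed(11)
  score <- matrix(runif(400, 30, 300), 20, 20,
                  dimnames = list(sprintf("a%02d", 1:20),
                                  sprintf("x%02d", 1:20)))
  h <- hits_from_scores(score)
  pairs <- reciprocal_best_hits(best_hits(h$fwd), best_hits(h$rev), "An")
  expect_false(anyDuplicated(pairs$ar_gene) > 0)
  expect_false(anyDuplicated(pairs$partner_gene) > 0)

  # stricter cutoff never adds pairs
  strict <- reciprocal_best_hits(best_hits(h$fwd, e_cutoff = 1e-150),
                                 best_hits(h$rev, e_cutoff = 1e-150), "An")
  key <- function(p) paste(p$ar_gene, p$partner_gene)
  expect_true(all(key(strict) %in% key(pairs)))
})

test_that("file-based pairing wrapper reproduces the in-memory path", {
  set.seed(12)
  score <- matrix(runif(100, 30, 200), 10, 10,
                  dimnames = list(sprintf("a%02d", 1:10),
                                  sprintf("x%02d", 1:10)))
  h <- hits_from_scores(score)
  fwd_path <- withr::local_tempfile(fileext = ".tsv")
  rev_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(with(h$fwd, blast_line(query_id, subject_id,
                                    format(e_value), bit_score)), fwd_path)
  writeLines(with(h$rev, blast_line(query_id, subject_id,
                                    format(e_value), bit_score)), rev_path)
  from_file <- homoeolog_pairs(fwd_path, rev_path, "Cn")
  in_mem <- reciprocal_best_hits(best_hits(h$fwd), best_hits(h$rev), "Cn")
  expect_equal(from_file[c("ar_gene", "partner_gene")],
               in_mem[c("ar_gene", "partner_gene")])
  expect_true(all(from_file$partner_subgenome == "Cn"))
})
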