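outcomes <- c("greater", "less", "ns")

test_that("pair test triple reflects the constructed geometry", {
  x <- c(32, 33, 31)
  tt <- pair_tests(x, x, x / 2, x / 2)
  expect_equal(unname(tt$outcome), rep("ns", 3))

  # parent1 far above parent2, hybrid total at parent1's level
  set.seed(51)
  ar_p <- 2^(8 + rnorm(4, 0, 0.1))
  o_p <- 2^(5 + rnorm(4, 0, 0.1))
  ar_h <- 2^(7 + rnorm(4, 0, 0.1))
  o_h <- 2^(7 + rnorm(4, 0, 0.1))
  tt <- pair_tests(ar_p, o_p, ar_h, o_h)
  expect_equal(unname(tt$outcome[c("t_parents", "t_h1", "t_h2")]),
               c("greater", "ns", "greater"))
  expect_equal(classify_eld(tt), "ELD_P1_high")

  # hybrid total far above both parents
  tt <- pair_tests(o_p, o_p, ar_h, ar_h)
  expect_equal(unname(tt$outcome[c("t_h1", "t_h2")]),
               c("greater", "greater"))
  expect_equal(classify_eld(tt), "transgressive_up")
  expect_error(pair_tests(1, c(1, 2), c(1, 2), c(1, 2)), "2 replicates")
})

test_that("decision table handles the canonical triples", {
  expect_equal(classify_eld("ns", "ns", "ns"), "no_change")
  expect_equal(classify_eld("greater", "ns", "greater"), "ELD_P1_high")
  expect_equal(classify_eld("less", "ns", "less"), "ELD_P1_low")
  expect_equal(classify_eld("less", "greater", "ns"), "ELD_P2_high")
  expect_equal(classify_eld("greater", "less", "ns"), "ELD_P2_low")
  expect_equal(classify_eld("greater", "less", "greater"), "additivity")
  expect_equal(classify_eld("less", "greater", "less"), "additivity")
  for (tp in outcomes) {
    expect_equal(classify_eld(tp, "greater", "greater"),
                 "transgressive_up")
    expect_equal(classify_eld(tp, "less", "less"), "transgressive_down")
  }
  # underdetermined or conflicting patterns
  expect_equal(classify_eld("greater", "ns", "ns"), "ambiguous")
  expect_equal(classify_eld("ns", "ns", "greater"), "ambiguous")
  expect_equal(classify_eld("greater", "ns", "less"), "ambiguous")
  expect_equal(classify_eld("ns", "greater", "less"), "ambiguous")
})

test_that("swapping the parents mirrors the dominance labels", {
  mirror <- c(no_change = "no_change", additivity = "additivity",
              ELD_P1_high = "ELD_P2_high", ELD_P1_low = "ELD_P2_low",
              ELD_P2_high = "ELD_P1_high", ELD_P2_low = "ELD_P1_low",
              transgressive_up = "transgressive_up",
              transgressive_down = "transgressive_down",
              ambiguous = "ambiguous")
  flip <- c(greater = "less", less = "greater", ns = "ns")
  for (tp in outcomes) for (t1 in outcomes) for (t2 in outcomes) {
    direct <- classify_eld(tp, t1, t2)
    swapped <- classify_eld(flip[[tp]], t2, t1)
    expect_identical(swapped, unname(mirror[direct]))
  }
})

test_that("linkage cases come from per-homoeolog tests", {
  set.seed(52)
  base <- 2^(5 + rnorm(4, 0, 0.1))
  up <- 2^(8 + rnorm(4, 0, 0.1))
  # A^r unchanged, partner up
  pe <- make_pe(matrix(base, 1), matrix(base, 1),
                matrix(base, 1), matrix(up, 1))
  lk <- linkage_calls(pe)
  expect_equal(lk$case_id, "unchanged:up")
  # A^r unchanged, partner down
  pe <- make_pe(matrix(base, 1), matrix(up, 1),
                matrix(base, 1), matrix(base, 1))
  expect_equal(linkage_calls(pe)$case_id, "unchanged:down")
  # everything identical
  pe <- make_pe(matrix(base, 1), matrix(base, 1),
                matrix(base, 1), matrix(base, 1))
  lk <- linkage_calls(pe)
  expect_equal(lk$ar_change, "unchanged")
  expect_equal(lk$partner_change, "unchanged")
})

test_that("ELD summary partitions pairs and tallies linkage tables", {
  set.seed(53)
  pe <- make_pe(reps_around(5, 8, 3), reps_around(5, 8, 3),
                reps_around(5, 8, 3), reps_around(5, 8, 3))
  calls <- eld_calls(pe)
  lk <- linkage_calls(pe)
  s <- eld_summary(calls, lk)
  expect_equal(sum(s$category$n), 8L)
  for (sub in unique(s$category$partner_subgenome))
    expect_equal(sum(s$category$prop[s$category$partner_subgenome == sub]),
                 1)
  expect_equal(sum(vapply(s$linkage, sum, 0)), 8)
  # hand tally on a toy mix
  toy <- data.frame(pair_id = paste0("p", 1:8),
                    partner_subgenome = rep(c("An", "Cn"), each = 4),
                    category = c("no_change", "no_change", "ELD_P1_high",
                                 "additivity", "no_change",
                                 "transgressive_up", "transgressive_up",
                                 "ambiguous"))
  st <- eld_summary(toy)$category
  expect_equal(st$n[st$partner_subgenome == "An" &
                      st$category == "no_change"], 2L)
  expect_equal(st$n[st$partner_subgenome == "Cn" &
                      st$category == "transgressive_up"], 2L)
  # permutation invariance
  st2 <- eld_summary(toy[sample(8), ])$category
  expect_equal(st[order(st$partner_subgenome, st$category), ],
               st2[order(st2$partner_subgenome, st2$category), ],
               ignore_attr = TRUE)
  expect_error(eld_summary(toy[0, ]), "empty")
})

test_that("eld_calls category always matches its own recorded triple", {
  set.seed(54)
  sim <- simulate_experiment(sim_config(300, seed = 54))
  pe <- pair_expression(sim$pairs, sim$parent1, sim$parent2, sim$hybrid)
  calls <- eld_calls(pe)
  expect_equal(calls$category,
               classify_eld(calls$t_parents, calls$t_h1, calls$t_h2))
  expect_true(all(calls$category %in% eld_categories()))
})
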