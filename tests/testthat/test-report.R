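# helper: NOVA assignment table with given group counts
fake_nova <- function(counts, prefix = "f") {
  groups <- rep(names(counts), counts)
  tibble::tibble(id = paste0(prefix, seq_along(groups)), group = groups,
                 rule_fired = "fixture", matched_terms = "",
                 hits = replicate(length(groups), tibble::tibble(), simplify = FALSE))
}
fake_tiers <- function(ids, tier = "Dairy", pyramid = "tMDP") {
  tibble::tibble(id = ids, pyramid = pyramid, status = "assigned", tier = tier)
}

test_that("the scope distribution reproduces published count arithmetic", {
  nova <- fake_nova(c(NOVA1 = 604, NOVA2 = 34, NOVA3 = 164, NOVA4 = 565,
                      UNCLASSIFIABLE = 18))
  eligible <- nova$id[nova$group != "UNCLASSIFIABLE"]
  out <- nova_distribution_table(nova, list(tMDP = fake_tiers(eligible)))
  row <- out[out$scope == "tMDP", ]
  expect_identical(unique(row$scope_n), 1367L)
  expect_equal(round(row$pct, 1), c(44.2, 2.5, 12.0, 41.3))
  # unclassifiable foods never enter a denominator
  expect_identical(unique(out$scope_n[out$scope == "All foods"]), 1367L)
  empty <- nova_distribution_table(nova[0, ], list())
  expect_identical(unique(empty$scope_n), 0L)
  expect_true(all(empty$pct == 0))
})

test_that("the tier-by-NOVA crosstab has conserved, percentage-complete rows", {
  foods <- make_food_table(
    make_food(id = paste0("c", 1:4), subcategory = "Cheese",
              ingredient_text = "milk, salt, rennet")
  )
  nova <- tibble::tibble(id = paste0("c", 1:4),
                         group = c("NOVA3", "NOVA3", "NOVA3", "NOVA4"))
  tiers <- fake_tiers(paste0("c", 1:4))
  out <- tier_nova_crosstab(foods, nova, tiers, by_subcategory = TRUE)
  expect_identical(out$n, c(3L, 1L))
  expect_equal(out$pct, c(75, 25))
  expect_identical(unique(out$row_n), 4L)
  # tiers with no foods are simply absent
  expect_false("Fish" %in% out$tier)
  # row sums and percentages conserve across a generated database
  cfg <- default_synth_config()
  cfg$blocks <- Filter(function(b) b$subcategory %in%
                         c("Pulses", "Cheese", "Vegetable", "Seafood Product",
                           "Chocolate", "Extruded Snack"), cfg$blocks)
  db <- generate_food_db(cfg, seed = 5)
  ct <- tier_nova_crosstab(db$foods, classify_all(db$foods),
                           assign_tiers(db$foods, default_pyramid_mapping("smdp")))
  sums <- tapply(ct$pct, ct$tier, sum)
  expect_true(all(abs(sums - 100) < 0.1))
  expect_identical(tapply(ct$n, ct$tier, sum)[names(sums)],
                   tapply(ct$row_n, ct$tier, function(x) sum(unique(x)))[names(sums)])
})

test_that("nutrient comparisons report medians, tests, and n.a. guards", {
  set.seed(1)
  n <- 40
  foods <- make_food_table(
    make_food(id = paste0("a", 1:n), salt_g = round(runif(n, 0, 0.2), 3)),
    make_food(id = paste0("b", 1:n), salt_g = round(runif(n, 2, 3), 3)),
    make_food(id = "solo", salt_g = 9)
  )
  nova <- tibble::tibble(
    id = foods$id,
    group = c(rep("NOVA1", n), rep("NOVA4", n), "NOVA3")
  )
  tiers <- fake_tiers(foods$id, tier = "Olives, Pulses, Nuts")
  out <- nutrient_comparison_table(foods, nova, tiers, alpha = 0.01)
  salt <- out$summary[out$summary$nutrient == "salt_g", ]
  expect_equal(salt$n, c(n, 1, n))
  expect_equal(salt$median[salt$group == "NOVA3"], 9)
  tests <- out$tests[out$tests$nutrient == "salt_g", ]
  # NOVA3 has n < 2: its pairwise comparison is n.a., the other is testable
  expect_identical(tests$label[tests$comparison == "NOVA3 vs NOVA4"], "n.a.")
  expect_true(tests$significant[tests$comparison == "NOVA1 vs NOVA4"])
  # Bonferroni never lowers a p-value and is capped at 1
  pairwise <- out$tests[!is.na(out$tests$p_adj), ]
  expect_true(all(pairwise$p_adj >= pairwise$p))
  expect_true(all(pairwise$p_adj <= 1))

  # a tier with a single NOVA group is descriptive only
  solo_nova <- tibble::tibble(id = paste0("a", 1:n), group = "NOVA4")
  out2 <- nutrient_comparison_table(foods[1:n, ], solo_nova,
                                    fake_tiers(paste0("a", 1:n), "Red Meat"))
  expect_true(all(out2$tests$label == "n.a."))
})

test_that("the score table reports mean-sd cells and complete grade rows", {
  scores <- tibble::tibble(
    id = c("e1", "x1", "x2"), status = "scored",
    score = c(-4, 0, 2), grade = c("A", "B", "B")
  )
  nova <- tibble::tibble(id = c("e1", "x1", "x2"),
                         group = c("NOVA4", "NOVA1", "NOVA1"))
  tiers <- dplyr::bind_rows(fake_tiers("e1", tier = "Eggs"),
                            fake_tiers(c("x1", "x2"), tier = "Dairy"))
  out <- nutriscore_distribution_table(scores, nova, tiers)
  egg <- out$summary[out$summary$tier == "Eggs", ]
  expect_identical(egg$n, 1L)
  expect_equal(egg$mean_score, -4)
  expect_identical(egg$A_n, 1L)
  expect_equal(egg$A_pct, 100)
  dairy <- out$summary[out$summary$tier == "Dairy", ]
  expect_equal(dairy$mean_score, 1)
  expect_equal(dairy$sd_score, sqrt(2), tolerance = 1e-12)
  expect_identical(dairy$B_n, 2L)
  pct_cols <- paste0(c("A", "B", "C", "D", "E"), "_pct")
  expect_true(all(abs(rowSums(out$summary[, pct_cols]) - 100) < 0.1))
  # all-singleton tiers are untestable
  expect_true(all(out$tests$label[out$tests$tier == "Eggs"] == "n.a."))
})

test_that("a one-gram salt shift is detected virtually always at n = 100", {
  set.seed(202)
  hits <- 0
  for (i in 1:100) {
    a <- rlnorm(100, log(0.1), 0.5)
    b <- rlnorm(100, log(0.1), 0.5) + 1
    if (mann_whitney_u(a, b)$p < 0.01) hits <- hits + 1
  }
  expect_gte(hits / 100, 0.95)
})
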