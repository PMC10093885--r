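tables <- default_score_tables()

test_that("component points count thresholds strictly below the value", {
  solid_energy <- tables$solid$energy_kj$thresholds
  expect_identical(component_points(0, solid_energy), 0)
  expect_identical(component_points(4000, solid_energy), 10)
  expect_identical(component_points(192.464, solid_energy), 0)
  # boundary values take the lower band
  expect_identical(component_points(335, solid_energy), 0)
  expect_identical(component_points(335.01, solid_energy), 1)
  # monotone non-decreasing in the value
  v <- seq(0, 4000, by = 50)
  expect_true(all(diff(component_points(v, solid_energy)) >= 0))
  # explicit band -> points map (FV component)
  fv <- tables$solid$fv_percent
  expect_identical(component_points(c(10, 41, 61, 81), fv$thresholds, fv$points),
                   c(0, 1, 2, 5))
  expect_error(component_points(1, c(3, 2, 1)), "strictly increasing")
})

test_that("negative and positive totals sum component points", {
  zero <- list(energy_kcal = 0, sugars_g = 0, sfa_g = 0, salt_g = 0)
  expect_identical(negative_points(zero, "solid", tables)$total, 0)
  saturated <- list(energy_kcal = 1000, sugars_g = 50, sfa_g = 11, salt_g = 2.5)
  expect_identical(negative_points(saturated, "solid", tables)$total, 40)
  egg <- list(energy_kcal = 46, sugars_g = 0.3, sfa_g = 0, salt_g = 0.44)
  np <- negative_points(egg, "solid", tables)
  expect_identical(np$total, 1)
  expect_identical(unname(np$breakdown), c(0, 0, 0, 1)) # the point is sodium
  expect_error(negative_points(list(energy_kcal = 100, sugars_g = NA,
                                    sfa_g = 0, salt_g = 0), "solid", tables),
               "sugars_g")

  expect_identical(positive_points(list(protein_g = 0, fiber_g = 0,
                                        fv_percent = 0), "solid", tables)$total, 0)
  expect_identical(positive_points(list(protein_g = 10, fiber_g = 5,
                                        fv_percent = 100), "solid", tables)$total, 15)
  expect_identical(positive_points(list(protein_g = 11, fiber_g = 0,
                                        fv_percent = 0), "solid", tables)$total, 5)
})

test_that("scoring applies the exclusion and zero-imputation rules", {
  egg <- make_food(id = "egg", subcategory = "Fresh or Processed Egg",
                   energy_kcal = 46, protein_g = 11, total_fat_g = 0.3,
                   sfa_g = 0, sugars_g = 0.3, salt_g = 0.44,
                   fiber_g = NA_real_, fv_percent = NA_real_)
  res <- fsam_nps(egg, tables)
  expect_identical(res$status, "scored")
  expect_identical(res$score, -4)
  expect_identical(res$grade, "A")
  expect_identical(res$imputed_fields, "fiber_g,fv_percent")

  zero <- make_food(id = "z", energy_kcal = 0, protein_g = 0, total_fat_g = 0,
                    sfa_g = 0, sugars_g = 0, salt_g = 0)
  res0 <- fsam_nps(zero, tables)
  expect_identical(res0$score, 0)
  expect_identical(res0$grade, "B")

  missing_sugars <- make_food(id = "m", sugars_g = NA_real_)
  resm <- fsam_nps(missing_sugars, tables)
  expect_identical(resm$status, "excluded_missing_negative")
  expect_true(is.na(resm$score) && is.na(resm$grade))
})

test_that("grading reproduces the published interval map per basis", {
  expect_identical(nutriscore_grade(-5, "solid"), "A")
  expect_identical(nutriscore_grade(1, "beverage"), "B")
  expect_identical(nutriscore_grade(37, "beverage", is_water = TRUE), "A")
  expect_identical(nutriscore_grade(10, "beverage"), "E")
  expect_error(nutriscore_grade(41, "solid"), "attainable range")
  expect_error(nutriscore_grade(-16, "solid"), "attainable range")
  scores <- -15:40
  expect_identical(
    nutriscore_grade(scores, "solid"),
    ifelse(scores <= -1, "A", ifelse(scores <= 2, "B",
      ifelse(scores <= 10, "C", ifelse(scores <= 18, "D", "E")))))
  expect_identical(
    nutriscore_grade(scores, "beverage"),
    ifelse(scores <= 1, "B", ifelse(scores <= 5, "C",
      ifelse(scores <= 9, "D", "E"))))
  # monotone non-decreasing within each basis class
  rank <- function(g) match(g, c("A", "B", "C", "D", "E"))
  expect_true(all(diff(rank(nutriscore_grade(scores, "solid"))) >= 0))
  expect_true(all(diff(rank(nutriscore_grade(scores, "beverage"))) >= 0))
})

test_that("scores stay integer, bounded, and monotone in each nutrient", {
  set.seed(7)
  for (i in 1:50) {
    basis <- sample(c("solid", "beverage"), 1)
    food <- list(id = "r", basis = basis,
                 energy_kcal = runif(1, 0, 900), sugars_g = runif(1, 0, 80),
                 sfa_g = runif(1, 0, 30), salt_g = runif(1, 0, 5),
                 protein_g = runif(1, 0, 30), fiber_g = runif(1, 0, 10),
                 fv_percent = runif(1, 0, 100))
    res <- fsam_nps(food, tables)
    expect_true(res$n_points >= 0 && res$n_points <= 40)
    expect_true(res$p_points >= 0 && res$p_points <= 15)
    expect_true(res$score >= -15 && res$score <= 40)
    expect_identical(res$score, round(res$score))
    expect_identical(res$score, res$n_points - res$p_points)
    # raising a negative nutrient never lowers the score
    up <- food; up$sugars_g <- up$sugars_g + 20
    expect_gte(fsam_nps(up, tables)$score, res$score)
    # raising a positive nutrient never raises the score
    up2 <- food; up2$protein_g <- up2$protein_g + 10
    expect_lte(fsam_nps(up2, tables)$score, res$score)
  }
})

test_that("full-rule mode applies the protein-counting restriction", {
  full <- default_score_tables(mode = "full_rule")
  rich <- make_food(id = "r", subcategory = "Preserved Meat",
                    energy_kcal = 500, protein_g = 11, total_fat_g = 30,
                    sfa_g = 11, sugars_g = 50, salt_g = 2.5,
                    fiber_g = 0, fv_percent = 0)
  # N = 40 >= 11, FV not maximal, not cheese: protein is not counted
  expect_identical(fsam_nps(rich, full)$protein_pts, 0)
  expect_identical(fsam_nps(rich, tables)$protein_pts, 5)
  # cheese keeps its protein points
  cheese <- rich; cheese$subcategory <- "Cheese"
  expect_identical(fsam_nps(cheese, full)$protein_pts, 5)
  # maximal FV points also restore protein counting
  fv_max <- rich; fv_max$fv_percent <- 100
  expect_identical(fsam_nps(fv_max, full)$protein_pts, 5)
  # below the N threshold the modes agree
  mild <- make_food(id = "m2", energy_kcal = 100, protein_g = 11,
                    total_fat_g = 1, sfa_g = 0.5, sugars_g = 2, salt_g = 0.1,
                    fiber_g = 0, fv_percent = 0)
  expect_identical(fsam_nps(mild, full)$score, fsam_nps(mild, tables)$score)
})

test_that("score_foods matches per-food scoring and counts exclusions", {
  foods <- make_food_table(
    make_food(id = "s1"),
    make_food(id = "s2", salt_g = NA_real_),
    make_food(id = "s3", energy_kcal = NA_real_, sugars_g = NA_real_)
  )
  out <- score_foods(foods, tables)
  expect_identical(out$id, foods$id)
  expect_identical(sum(out$status == "excluded_missing_negative"), 2L)
  expect_identical(out$score[1], fsam_nps(foods[1, ], tables)$score)
  expect_identical(nrow(score_foods(foods[0, ], tables)), 0L)
})
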