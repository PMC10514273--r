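survey_row <- function(grid = "G1", plot = "P1", session, taxon = "Erodium",
                       cover = 1, new_growth = 0, budding = 0, flowering = 0,
                       set_seed = 0, seeded = 0, dead = 0) {
  data.frame(grid = grid, plot = plot, session = as.Date(session),
             taxon = taxon, cover = cover, new_growth = new_growth,
             budding = budding, flowering = flowering, set_seed = set_seed,
             seeded = seeded, dead = dead, stringsAsFactors = FALSE)
}

test_that("seed availability sums seed-bearing states weighted by cover", {
  s <- rbind(
    survey_row(session = "2016-04-01", flowering = 0.5),   # alive earlier
    survey_row(session = "2016-05-15", flowering = 0.2, seeded = 0.3,
               dead = 0.1))
  out <- seed_availability(s)
  v <- out$score[out$session == as.Date("2016-05-15")]
  expect_equal(v, 0.6)     # 0.2 + 0.3 + newly-dead 0.1, cover weight 1
  # all states zero
  z <- seed_availability(survey_row(session = "2016-04-01"))
  expect_equal(z$score, 0)
  # cover weighting scales the plot contribution
  s2 <- rbind(survey_row(session = "2016-04-01", flowering = 0.4, cover = 25),
              survey_row(session = "2016-04-01", plot = "P2",
                         flowering = 0.2, cover = 50))
  out2 <- seed_availability(s2)
  expect_equal(out2$score, 25 * 0.4 + 50 * 0.2)
})

test_that("the newly-dead rule credits a taxon only in its first dead
           session", {
  s <- rbind(
    survey_row(session = "2016-04-01", flowering = 0.5),
    survey_row(session = "2016-05-15", dead = 0.6),
    survey_row(session = "2016-07-01", dead = 0.6))
  out <- seed_availability(s)
  by_sess <- stats::setNames(out$score, format(out$session))
  expect_equal(unname(by_sess["2016-05-15"]), 0.6)  # newly dead counts
  expect_equal(unname(by_sess["2016-07-01"]), 0)    # still dead: no credit
  # first session of a year has no previous session: dead contributes 0
  s2 <- survey_row(session = "2016-04-01", dead = 0.9)
  expect_equal(seed_availability(s2)$score, 0)
  # a new year restarts the rule even if the taxon died the previous fall
  s3 <- rbind(survey_row(session = "2016-09-15", flowering = 0.3),
              survey_row(session = "2017-04-01", dead = 0.5))
  expect_equal(seed_availability(s3)$score[2], 0)
})

test_that("grid standardization sums reads, restricts to surveyed taxa and
           renormalizes", {
  meta <- data.frame(sample_id = c("F1", "F2", "F3"),
                     grid = "G1", session = as.Date("2016-04-01"),
                     stringsAsFactors = FALSE)
  counts <- rbind(F1 = c(Erodium = 60, Acmispon = 40, Ghost = 100),
                  F2 = c(Erodium = 20, Acmispon = 80, Ghost = 0),
                  F3 = c(Erodium = 0, Acmispon = 0, Ghost = 0))
  av <- seed_availability(rbind(
    survey_row(session = "2016-04-01", taxon = "Erodium", flowering = 0.6),
    survey_row(session = "2016-04-01", taxon = "Acmispon", flowering = 0.2)))
  std <- standardize_grid(counts, meta, av)
  # Ghost is in diet but never surveyed: excluded from the universe
  expect_setequal(colnames(std$diet), c("Erodium", "Acmispon"))
  # summed counts: Erodium 80, Acmispon 120 -> 0.4 / 0.6
  expect_equal(unname(std$diet[1, c("Erodium", "Acmispon")]), c(0.4, 0.6))
  expect_equal(unname(std$availability[1, c("Erodium", "Acmispon")]),
               c(0.75, 0.25))
  # a single sample passes through as its own renormalized RRA
  std1 <- standardize_grid(counts[1, , drop = FALSE], meta[1, ], av)
  expect_equal(unname(std1$diet[1, c("Erodium", "Acmispon")]), c(0.6, 0.4))
  # two samples with equal totals average their proportions
  eq <- rbind(F1 = c(Erodium = 80, Acmispon = 20, Ghost = 0),
              F2 = c(Erodium = 40, Acmispon = 60, Ghost = 0))
  stde <- standardize_grid(eq, meta[1:2, ], av)
  expect_equal(unname(stde$diet[1, "Erodium"]), 0.6)
  expect_error(standardize_grid(counts, meta[1:2, ], av), "metadata")
})

test_that("matching intersects keys, drops fall and counts the design", {
  ref <- generate_reference(4, 1, seed = 6)
  dates <- as.Date(c("2016-04-15", "2016-07-15", "2017-04-15", "2017-07-15"))
  phen <- generate_phenology(ref, paste0("G", 1:5), dates, seed = 3)
  counts <- generate_diet_counts(phen, 500, seed = 4)
  av <- seed_availability(phen$survey)
  std <- standardize_grid(counts, phen$metadata, av)
  ms <- match_samples(std)
  # 5 grids x 2 seasons x 2 years fully crossed
  expect_length(ms$keys, 20)
  expect_false(any(ms$season == "fall"))
  # a fall-only availability key vanishes; a diet-only key is dropped
  std2 <- std
  fall_key <- "G9|2016-09-15"
  std2$availability <- rbind(std2$availability,
                             stats::setNames(std2$availability[1, ],
                                             colnames(std2$availability)))
  rownames(std2$availability)[nrow(std2$availability)] <- fall_key
  ms2 <- match_samples(std2)
  expect_false(fall_key %in% ms2$keys)
  expect_true(fall_key %in% attr(ms2, "dropped_keys"))
  empty <- list(diet = std$diet[0, , drop = FALSE],
                availability = std$availability)
  expect_error(match_samples(empty), "no matched")
})

test_that("selection differences carry the diet-minus-availability sign and
           balance to zero", {
  ms <- list(keys = c("G1|2016-04-01", "G1|2016-07-01"),
             diet = rbind(c(0.3, 0.7), c(0.6, 0.4)),
             availability = rbind(c(0.1, 0.9), c(0.6, 0.4)),
             taxa = c("t1", "t2"),
             season = c("spring", "summer"), year = c(2016L, 2016L))
  dimnames(ms$diet) <- dimnames(ms$availability) <-
    list(ms$keys, ms$taxa)
  sel <- selection_difference(ms)
  expect_equal(sel$difference[sel$taxon == "t1" & sel$season == "spring"],
               0.2)
  expect_equal(sel$difference[sel$taxon == "t1" & sel$season == "summer"], 0)
  sums <- tapply(sel$difference, sel$key, sum)
  expect_equal(as.vector(sums), c(0, 0))
  flipped <- selection_difference(ms, flip_sign = TRUE)
  expect_equal(flipped$difference, -sel$difference)
  means <- attr(sel, "taxon_means")
  expect_equal(unname(means$overall["t1"]), 0.1)
})

test_that("fold flags follow the 10x rule with sane zero handling", {
  ms <- list(keys = "G1|2016-04-01",
             diet = rbind(c(0.22, 0.02, 0.0, 0.05, 0.0)),
             availability = rbind(c(0.02, 0.22, 0.0, 0.004, 0.71)),
             taxa = paste0("t", 1:5),
             season = "spring", year = 2016L)
  dimnames(ms$diet) <- dimnames(ms$availability) <-
    list(ms$keys, ms$taxa)
  f <- fold_representation(ms, fold = 10)
  flag <- stats::setNames(f$flag, f$taxon)
  expect_equal(unname(flag["t1"]), "overrepresented")       # 11x
  expect_equal(unname(flag["t2"]), "underrepresented")      # 11x the other way
  expect_equal(unname(flag["t3"]), "proportional")          # 0 vs 0
  expect_equal(unname(flag["t4"]), "overrepresented")       # 12.5x
  expect_equal(unname(flag["t5"]), "underrepresented")
  ms$availability[1, 4] <- 0
  f2 <- fold_representation(ms, fold = 10)
  expect_equal(f2$flag[f2$taxon == "t4"], "overrepresented (unavailable)")
  expect_error(fold_representation(ms, fold = 1), "fold")
})

test_that("diversity comparison pairs H' and J' per matched key", {
  even <- rbind(c(0.25, 0.25, 0.25, 0.25), c(0.3, 0.3, 0.2, 0.2),
                c(0.25, 0.3, 0.25, 0.2))
  skew <- rbind(c(0.9, 0.05, 0.03, 0.02), c(0.85, 0.1, 0.03, 0.02),
                c(0.8, 0.1, 0.05, 0.05))
  keys <- paste0("G1|2016-0", 4:6, "-01")
  ms <- list(keys = keys, diet = even, availability = skew,
             taxa = paste0("t", 1:4),
             season = rep("spring", 3), year = rep(2016L, 3))
  dimnames(ms$diet) <- dimnames(ms$availability) <- list(keys, ms$taxa)
  out <- diversity_compare(ms)
  expect_gt(out$J$mean_diff, 0)      # diet strictly more even
  expect_gt(out$H$t, 0)
  expect_equal(out$H$df, 2)          # matched keys - 1
  same <- ms; same$availability <- same$diet
  out0 <- diversity_compare(same)
  expect_equal(out0$H$t, 0)
  expect_equal(out0$J$p, 1)
})

test_that("planted selection coefficients are recovered in sign", {
  ref <- generate_reference(6, 1, seed = 9)
  sel <- c(Genus01 = -log(10), Genus02 = 0, Genus03 = log(2),
           Genus04 = log(10))
  dates <- as.Date(c("2016-04-15", "2016-07-15", "2017-04-15", "2017-07-15"))
  signs_ok <- vapply(1:10, function(rep) {
    phen <- generate_phenology(ref, c("GA", "GB"), dates, selection = sel,
                               seed = 100 + rep)
    counts <- generate_diet_counts(phen, 4000, seed = 200 + rep)
    std <- standardize_grid(counts, phen$metadata,
                            seed_availability(phen$survey))
    ms <- match_samples(std)
    mean_diff <- attr(selection_difference(ms), "taxon_means")$overall
    sign(mean_diff[["Genus01"]]) == -1 &&
      sign(mean_diff[["Genus03"]]) == 1 &&
      sign(mean_diff[["Genus04"]]) == 1
  }, logical(1))
  expect_true(all(signs_ok))
})
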