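test_that("Bray-Curtis matches hand values and the zero-adjustment works", {
  m <- rbind(s1 = c(1, 0), s2 = c(0, 1), s3 = c(1, 0))
  d <- bray_curtis(m, zero_adjust = FALSE)
  expect_equal(unname(d["s1", "s2"]), 100)
  expect_equal(unname(d["s1", "s3"]), 0)
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  dz <- bray_curtis(m, zero_adjust = TRUE, dummy_value = 1)
  expect_equal(unname(dz["s1", "s2"]), 50)   # 2/4 * 100
  z <- rbind(a = c(0, 0), b = c(0, 0))
  expect_equal(unname(bray_curtis(z, TRUE)["a", "b"]), 0)
  expect_error(bray_curtis(rbind(c(-1, 2))), "negative")
  # cross-check against an independent implementation
  set.seed(20)
  x <- matrix(runif(48), 6, 8)
  expect_equal(bray_curtis(x, zero_adjust = FALSE),
               100 * as.matrix(vegan::vegdist(x, "bray")),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("ANOSIM attains its closed-form extremes and matches vegan", {
  # two internally identical, mutually distinct groups: R = 1
  m <- rbind(a1 = c(10, 0), a2 = c(10, 0), b1 = c(0, 10), b2 = c(0, 10))
  d <- bray_curtis(m, zero_adjust = FALSE)
  r <- anosim_test(d, c("A", "A", "B", "B"), n_perm = 99, seed = 1)
  expect_equal(r$R, 1)
  # all samples identical: every rank tied, R = 0
  same <- matrix(5, 4, 3, dimnames = list(paste0("s", 1:4), NULL))
  d0 <- bray_curtis(same, zero_adjust = FALSE)
  expect_equal(anosim_test(d0, c("A", "A", "B", "B"), 99, seed = 1)$R, 0)
  # agreement with vegan on arbitrary data
  set.seed(21)
  x <- matrix(runif(70), 10, 7)
  dx <- bray_curtis(x, zero_adjust = FALSE)
  grp <- rep(c("g1", "g2"), each = 5)
  mine <- anosim_test(dx, grp, n_perm = 199, seed = 3)
  ref <- vegan::anosim(stats::as.dist(dx), grp, permutations = 199)
  expect_equal(mine$R, unname(ref$statistic), tolerance = 1e-12)
  expect_error(anosim_test(dx, c(rep("g1", 9), "solo"), 99, 1), "solo")
  expect_error(anosim_test(dx, rep("g1", 10), 99, 1), "two groups")
})

test_that("permutation p-values are reproducible and bounded away from 0", {
  set.seed(22)
  x <- matrix(runif(48), 8, 6)
  d <- bray_curtis(x, zero_adjust = FALSE)
  grp <- rep(c("a", "b"), each = 4)
  r1 <- anosim_test(d, grp, n_perm = 499, seed = 11)
  r2 <- anosim_test(d, grp, n_perm = 499, seed = 11)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 500)
  rr1 <- relate_test(d, d + 1, n_perm = 199, seed = 4)
  rr2 <- relate_test(d, d + 1, n_perm = 199, seed = 4)
  expect_identical(rr1$p, rr2$p)
})

test_that("SIMPER decomposes the between-group dissimilarity exactly", {
  # single taxon: it contributes everything
  m1 <- rbind(a = 5, b = 1, c = 4, d = 2)
  colnames(m1) <- "only"
  s1 <- simper_pairwise(m1, c("g1", "g1", "g2", "g2"))
  expect_equal(s1$contrib_pct, 100)
  # 2x2 toy: per-taxon Av.Diss equals the hand-computed pair mean
  m <- rbind(a1 = c(4, 0), a2 = c(2, 2), b1 = c(0, 4), b2 = c(1, 3))
  colnames(m) <- c("t1", "t2")
  s <- simper_pairwise(m, c("A", "A", "B", "B"))
  # pairs (a1,b1) (a1,b2) (a2,b1) (a2,b2); denominators all 8
  t1_hand <- mean(100 * c(4, 3, 2, 1) / 8)
  t2_hand <- mean(100 * c(4, 3, 2, 1) / 8)
  expect_equal(s$av_diss[s$taxon == "t1"], t1_hand)
  expect_equal(s$av_diss[s$taxon == "t2"], t2_hand)
  # conservation: contributions sum to 100, Av.Diss to the total average
  # between-group Bray-Curtis (no dummy)
  set.seed(23)
  x <- matrix(runif(36), 6, 6,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:6)))
  grp <- rep(c("A", "B"), each = 3)
  sx <- simper_pairwise(x, grp)
  expect_equal(sum(sx$contrib_pct), 100, tolerance = 1e-9)
  d <- bray_curtis(x, zero_adjust = FALSE)
  between <- as.vector(d[1:3, 4:6])
  expect_equal(attr(sx, "total_dissimilarity"), mean(between),
               tolerance = 1e-9)
  expect_false(is.unsorted(sx$cum_pct))
  # per-taxon agreement with vegan::simper
  vg <- summary(vegan::simper(x, grp))[[1]]
  expect_equal(sx$av_diss[match(rownames(vg), sx$taxon)],
               100 * vg$average, tolerance = 1e-9)
  expect_error(simper_pairwise(x, rep("A", 6)), "two groups")
})

test_that("Chao2 follows its closed form and the bootstrap CI brackets the
           estimate", {
  # no uniques: estimator equals the observed richness
  inc0 <- incidence_with_Q(10, 20, 0, 0)
  c0 <- chao2_estimate(inc0, n_rand = 50, seed = 1)
  expect_equal(c0$S_est, c0$S_obs)
  # m=10, S_obs=20, Q1=4, Q2=2 -> 20 + 0.9 * 16/4 = 23.6
  inc <- incidence_with_Q(10, 20, 4, 2)
  cc <- chao2_estimate(inc, n_rand = 200, seed = 2)
  expect_equal(cc$Q1, 4L); expect_equal(cc$Q2, 2L)
  expect_equal(cc$S_est, 23.6)
  expect_lte(cc$ci95[1], cc$S_est)
  expect_gte(cc$ci95[2], cc$S_est)
  expect_gte(cc$S_est, cc$S_obs)
  # bias-corrected branch when Q2 = 0
  incq <- incidence_with_Q(10, 20, 4, 0)
  cq <- chao2_estimate(incq, n_rand = 50, seed = 3)
  expect_equal(cq$S_est, 20 + 0.9 * 4 * 3 / 2)
  ln <- chao2_estimate(inc, ci = "lognormal")
  expect_lte(ln$ci95[1], ln$S_est)
  expect_error(chao2_estimate(inc[1, , drop = FALSE]), "2 samples")
})

test_that("accumulation curves are monotone and exact at the endpoints", {
  set.seed(24)
  inc <- matrix(rbinom(120, 1, 0.3), 8, 15)
  acc <- accumulation_curve(inc, n_rand = 100, seed = 5)
  S_obs <- sum(colSums(inc) > 0)
  expect_equal(acc$mean_richness[8], S_obs)
  expect_equal(acc$sd_richness[8], 0)
  expect_false(is.unsorted(acc$mean_richness))
  one <- accumulation_curve(inc[3, , drop = FALSE], n_rand = 10, seed = 1)
  expect_equal(one$mean_richness, sum(inc[3, ] > 0))
})

test_that("Shannon and Pielou hit their closed forms", {
  u <- shannon_pielou(rep(0.25, 4))
  expect_equal(u$H, log(4))
  expect_equal(u$J, 1)
  expect_equal(shannon_pielou(c(1, 0, 0))$H, 0)
  expect_equal(shannon_pielou(c(0.5, 0.25, 0.25))$H, 1.5 * log(2))
  # counts and proportions give the same answer; zeros are skipped
  expect_equal(shannon_pielou(c(8, 4, 4, 0))$H,
               shannon_pielou(c(0.5, 0.25, 0.25))$H)
  expect_error(shannon_pielou(c(0, 0)), "all-zero")
  set.seed(25)
  p <- runif(10)
  expect_equal(shannon_pielou(p)$H,
               vegan::diversity(p / sum(p), "shannon"), ignore_attr = TRUE)
})

test_that("RELATE is rank-invariant and approaches 1 as matrices converge", {
  set.seed(26)
  x <- matrix(runif(50), 10, 5)
  d1 <- bray_curtis(x, zero_adjust = FALSE)
  expect_equal(relate_test(d1, d1, 99, 1)$rho, 1)
  expect_equal(relate_test(d1, sqrt(d1) * 3 + 1 - diag(1, 10), 99, 1)$rho, 1,
               tolerance = 1e-12)
  rhos <- vapply(c(40, 10, 1), function(noise) {
    set.seed(27)
    d2 <- d1 + matrix(runif(100, 0, noise), 10, 10)
    d2 <- (d2 + t(d2)) / 2; diag(d2) <- 0
    relate_test(d1, d2, 99, 1)$rho
  }, numeric(1))
  expect_false(is.unsorted(rhos))
  # cross-check rho against the Mantel statistic with Spearman ranks
  d3 <- as.matrix(stats::dist(matrix(rnorm(20), 10, 2)))
  mine <- relate_test(d1, d3, 199, 2)
  vg <- vegan::mantel(stats::as.dist(d1), stats::as.dist(d3),
                      method = "spearman", permutations = 199)
  expect_equal(mine$rho, unname(vg$statistic), tolerance = 1e-12)
  expect_error(relate_test(d1, d1[1:5, 1:5]), "size")
})

test_that("nMDS embeds representable configurations at near-zero stress and
           majorization never increases stress", {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4))
  d <- as.matrix(stats::dist(pts)) * 10
  fit <- nmds_ordination(d, ndim = 2, restarts = 10, seed = 2)
  expect_lt(fit$stress, 0.01)
  set.seed(28)
  x <- matrix(runif(56), 8, 7)
  dx <- bray_curtis(x, zero_adjust = FALSE)
  fx <- nmds_ordination(dx, restarts = 10, seed = 3)
  expect_true(all(diff(fx$trace) <= 1e-8))
  # planted two-cluster structure separates in the embedding
  cl <- rbind(matrix(rnorm(8, 0, 0.05), 4, 2),
              matrix(rnorm(8, 5, 0.05), 4, 2))
  dcl <- as.matrix(stats::dist(cl))
  fcl <- nmds_ordination(dcl, restarts = 20, seed = 4)
  emb <- fcl$points
  between <- sqrt(sum((colMeans(emb[1:4, ]) - colMeans(emb[5:8, ]))^2))
  within <- mean(c(stats::dist(emb[1:4, ]), stats::dist(emb[5:8, ])))
  expect_gt(between, within)
  deg <- nmds_ordination(matrix(1, 4, 4) - diag(4), seed = 1)
  expect_true(deg$degenerate)
  expect_equal(deg$stress, 0)
})

test_that("the paired t-test matches its closed form and stats::t.test", {
  x <- c(1.2, 2.3, 3.1, 4.8, 5.0)
  y <- c(1.0, 2.9, 2.2, 4.1, 5.6)
  mine <- paired_t_test(x, y)
  ref <- stats::t.test(x, y, paired = TRUE)
  expect_equal(mine$t, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value)
  expect_equal(mine$df, unname(ref$parameter))
  same <- paired_t_test(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(paired_t_test(c(2, 3, 4, 5), c(1, 2, 3, 4)), "zero-variance")
  expect_error(paired_t_test(1:3, 1:2), "paired")
})
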