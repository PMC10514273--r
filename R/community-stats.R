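#' PRIMER-style community statistics
#'
#' From-scratch implementations of the multivariate and diversity machinery
#' used in the diet analysis: zero-adjusted Bray-Curtis resemblance,
#' one-way ANOSIM with seeded permutations, SIMPER decomposition, the Chao2
#' incidence-based richness estimator with randomized confidence intervals,
#' species-accumulation curves, Shannon/Pielou diversity, the RELATE rank
#' correlation between resemblance matrices, non-metric multidimensional
#' scaling by iterative majorization, and paired t-tests. Tie handling uses
#' midranks throughout; permutation p-values use the (b+1)/(m+1) estimator.
#'
#' @name community_stats
NULL

lower_tri <- function(m) m[lower.tri(m)]

#' Bray-Curtis resemblance matrix (optionally zero-adjusted)
#'
#' Dissimilarity on the 0-100 scale:
#' `100 * sum(|y_ij - y_ik|) / sum(y_ij + y_ik)`. With `zero_adjust` a dummy
#' taxon with constant value `dummy_value` (on the same scale as the matrix
#' entries) is appended to every sample first, so near-empty samples remain
#' comparable.
#'
#' @param m samples x taxa abundance matrix (non-negative).
#' @param zero_adjust append the dummy taxon?
#' @param dummy_value dummy taxon abundance.
#' @return symmetric n x n dissimilarity matrix, zero diagonal.
#' @export
bray_curtis <- function(m, zero_adjust = TRUE, dummy_value = 1) {
  m <- as.matrix(m)
  if (any(m < 0)) stopf("negative abundances are not allowed")
  if (zero_adjust) m <- cbind(m, `_dummy_` = dummy_value)
  man <- as.matrix(stats::dist(m, method = "manhattan"))
  tot <- outer(rowSums(m), rowSums(m), "+")
  d <- ifelse(tot == 0, 0, 100 * man / tot)
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

# midranked lower-triangle ranks of a dissimilarity matrix
rank_lower <- function(d) rank(lower_tri(d))

anosim_R <- function(r, same, M) {
  rw <- mean(r[same]); rb <- mean(r[!same])
  (rb - rw) / (M / 2)
}

#' One-way analysis of similarities (ANOSIM)
#'
#' Rank-based comparison of between- versus within-group dissimilarities:
#' `R = (mean between rank - mean within rank) / (M/2)`, `M = n(n-1)/2`,
#' with midranks for ties. Significance by seeded label permutations,
#' `p = (1 + #(R_perm >= R_obs)) / (n_perm + 1)`.
#'
#' @param d square dissimilarity matrix.
#' @param groups group labels, one per sample (>= 2 groups, each >= 2
#'   members).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list(R, p, n_perm, group_sizes, perm_R).
#' @export
anosim_test <- function(d, groups, n_perm = 9999L, seed = 1L) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  n <- nrow(d)
  stopifnot(length(groups) == n)
  sizes <- table(groups)
  if (length(sizes) < 2) stopf("need at least two groups")
  if (any(sizes < 2))
    stopf("group(s) of size 1: %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  M <- n * (n - 1) / 2
  r <- rank_lower(d)
  pair_i <- row(d)[lower.tri(d)]
  pair_j <- col(d)[lower.tri(d)]
  same <- groups[pair_i] == groups[pair_j]
  R_obs <- anosim_R(r, same, M)
  perm_R <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      g <- sample(groups)
      anosim_R(r, g[pair_i] == g[pair_j], M)
    }, numeric(1))
  })
  list(R = R_obs,
       p = (1 + sum(perm_R >= R_obs)) / (n_perm + 1),
       n_perm = n_perm,
       group_sizes = as.vector(sizes),
       perm_R = perm_R)
}

#' SIMPER: per-taxon contributions to between-group dissimilarity
#'
#' For every between-group sample pair (j, k), taxon i contributes
#' `100 * |y_ij - y_ik| / sum_t(y_tj + y_tk)`; Av.Diss is the mean over
#' pairs, Diss.SD the ratio of Av.Diss to the SD of the per-pair
#' contributions, and Contrib% the share of the total average
#' between-group dissimilarity. No dummy taxon is used inside SIMPER, so
#' the per-taxon Av.Diss sum exactly to the reported total.
#'
#' @param m samples x taxa abundance matrix.
#' @param groups two-level group labels.
#' @return data.frame (taxon, av_abund_1, av_abund_2, av_diss, diss_sd,
#'   contrib_pct, cum_pct) sorted by contribution, with attributes
#'   "total_dissimilarity" and "group_levels".
#' @export
simper_pairwise <- function(m, groups) {
  m <- as.matrix(m)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stopf("simper_pairwise needs exactly two groups")
  i1 <- which(groups == lev[1]); i2 <- which(groups == lev[2])
  if (length(i1) == 0 || length(i2) == 0)
    stopf("empty group: %s", lev[c(length(i1) == 0, length(i2) == 0)][1])
  denom <- outer(rowSums(m)[i1], rowSums(m)[i2], "+")
  ntaxa <- ncol(m)
  av <- sdv <- numeric(ntaxa)
  for (t in seq_len(ntaxa)) {
    contrib <- 100 * abs(outer(m[i1, t], m[i2, t], "-")) / denom
    av[t] <- mean(contrib)
    sdv[t] <- stats::sd(as.vector(contrib))
  }
  total <- sum(av)
  out <- data.frame(taxon = colnames(m),
                    av_abund_1 = colMeans(m[i1, , drop = FALSE]),
                    av_abund_2 = colMeans(m[i2, , drop = FALSE]),
                    av_diss = av,
                    diss_sd = ifelse(sdv > 0, av / sdv, NA_real_),
                    contrib_pct = 100 * av / total,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$contrib_pct), ]
  out$cum_pct <- cumsum(out$contrib_pct)
  rownames(out) <- NULL
  attr(out, "total_dissimilarity") <- total
  attr(out, "group_levels") <- lev
  out
}

#' Chao2 incidence-based richness with randomized confidence interval
#'
#' `S_est = S_obs + ((m-1)/m) * Q1^2 / (2 Q2)` when duplicates exist, and
#' the bias-corrected `S_obs + ((m-1)/m) * Q1 (Q1-1) / (2 (Q2+1))`
#' otherwise, where Q1/Q2 count taxa found in exactly one/two samples. The
#' default 95% CI takes percentiles of the estimator over seeded bootstrap
#' resamples of samples; an analytic log-normal CI is available.
#'
#' @param incidence samples x taxa presence/absence matrix (m >= 2 rows).
#' @param n_rand bootstrap randomizations.
#' @param seed RNG seed.
#' @param ci "bootstrap" or "lognormal".
#' @return list(S_obs, Q1, Q2, m, S_est, ci95, n_rand).
#' @export
chao2_estimate <- function(incidence, n_rand = 1000L, seed = 1L,
                           ci = c("bootstrap", "lognormal")) {
  ci <- match.arg(ci)
  x <- as.matrix(incidence) > 0
  m <- nrow(x)
  if (m < 2) stopf("Chao2 needs at least 2 samples")
  core <- function(x) {
    inc <- colSums(x)
    S_obs <- sum(inc > 0)
    Q1 <- sum(inc == 1); Q2 <- sum(inc == 2)
    A <- (nrow(x) - 1) / nrow(x)
    S_est <- if (Q2 > 0) S_obs + A * Q1^2 / (2 * Q2)
             else S_obs + A * Q1 * (Q1 - 1) / (2 * (Q2 + 1))
    c(S_obs = S_obs, Q1 = Q1, Q2 = Q2, S_est = S_est)
  }
  obs <- core(x)
  ci95 <- if (ci == "bootstrap") {
    boot <- with_seed(seed, {
      vapply(seq_len(n_rand), function(b) {
        core(x[sample.int(m, m, replace = TRUE), , drop = FALSE])[["S_est"]]
      }, numeric(1))
    })
    unname(stats::quantile(boot, c(0.025, 0.975)))
  } else {
    Q1 <- obs[["Q1"]]; Q2 <- obs[["Q2"]]; A <- (m - 1) / m
    T_ <- obs[["S_est"]] - obs[["S_obs"]]
    if (T_ <= 0 || Q1 == 0) c(obs[["S_obs"]], obs[["S_obs"]])
    else {
      h <- if (Q2 > 0) Q1 / Q2 else Q1
      v <- if (Q2 > 0) Q2 * (A * h^2 / 2 + A^2 * h^3 + A^2 * h^4 / 4)
           else A * Q1 * (Q1 - 1) / 2 + A^2 * Q1 * (2 * Q1 - 1)^2 / 4 -
                A^2 * Q1^4 / (4 * obs[["S_est"]])
      K <- exp(1.96 * sqrt(log(1 + v / T_^2)))
      c(obs[["S_obs"]] + T_ / K, obs[["S_obs"]] + T_ * K)
    }
  }
  list(S_obs = as.integer(obs[["S_obs"]]), Q1 = as.integer(obs[["Q1"]]),
       Q2 = as.integer(obs[["Q2"]]), m = m, S_est = obs[["S_est"]],
       ci95 = ci95, n_rand = if (ci == "bootstrap") n_rand else 0L)
}

#' Species-accumulation curve over random sample orderings
#'
#' @param incidence samples x taxa presence/absence matrix.
#' @param n_rand random orderings.
#' @param seed RNG seed.
#' @return data.frame(k, mean_richness, sd_richness).
#' @export
accumulation_curve <- function(incidence, n_rand = 1000L, seed = 1L) {
  x <- as.matrix(incidence) > 0
  m <- nrow(x)
  acc <- with_seed(seed, {
    vapply(seq_len(n_rand), function(b) {
      xp <- x[sample.int(m), , drop = FALSE]
      detected <- matrix(apply(xp, 2L, cumsum), nrow = m) > 0
      rowSums(detected)
    }, numeric(m))
  })
  acc <- matrix(acc, nrow = m)
  data.frame(k = seq_len(m),
             mean_richness = rowMeans(acc),
             sd_richness = apply(acc, 1L, stats::sd))
}

#' Shannon diversity and Pielou evenness
#'
#' `H' = -sum(p_i ln p_i)` over taxa with positive abundance (renormalized
#' internally); `J' = H'/ln(S)` for S > 1 taxa.
#'
#' @param p non-negative abundance or proportion vector.
#' @return list(H, J, S).
#' @export
shannon_pielou <- function(p) {
  if (all(p == 0)) stopf("all-zero abundance vector")
  if (any(p < 0)) stopf("negative abundances")
  p <- p[p > 0]
  p <- p / sum(p)
  H <- -sum(p * log(p))
  S <- length(p)
  list(H = H, J = if (S > 1) H / log(S) else NA_real_, S = S)
}

#' RELATE: rank correlation between two resemblance matrices
#'
#' Spearman correlation (midranks) of the unraveled lower triangles;
#' significance by permuting one matrix's sample ordering (rows and columns
#' together).
#'
#' @param d1,d2 square dissimilarity matrices over the same samples in the
#'   same order.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return list(rho, p, n_perm, perm_rho).
#' @export
relate_test <- function(d1, d2, n_perm = 999L, seed = 1L) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2)))
    stopf("resemblance matrices differ in size (%d vs %d)",
          nrow(d1), nrow(d2))
  n <- nrow(d1)
  v1 <- lower_tri(d1)
  rho_obs <- stats::cor(v1, lower_tri(d2), method = "spearman")
  perm_rho <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      idx <- sample.int(n)
      stats::cor(v1, lower_tri(d2[idx, idx]), method = "spearman")
    }, numeric(1))
  })
  list(rho = rho_obs,
       p = (1 + sum(perm_rho >= rho_obs)) / (n_perm + 1),
       n_perm = n_perm, perm_rho = perm_rho)
}

# Kruskal stress-1 for configuration distances vs monotone targets
stress1 <- function(dd, dhat) {
  denom <- sum(dd^2)
  if (denom == 0) return(0)
  sqrt(sum((dd - dhat)^2) / denom)
}

# monotone (isotonic) regression of configuration distances on the
# dissimilarity order, averaging within tie blocks of equal dissimilarity
monotone_fit <- function(diss, dd) {
  ord <- order(diss)
  fit <- stats::isoreg(seq_along(ord), dd[ord])$yf
  blocks <- split(seq_along(ord), diss[ord])
  for (b in blocks) if (length(b) > 1) fit[b] <- mean(fit[b])
  dhat <- numeric(length(dd))
  dhat[ord] <- fit
  dhat
}

#' Non-metric multidimensional scaling by iterative majorization
#'
#' Embeds samples in `ndim` dimensions so that embedded distances are
#' rank-concordant with the dissimilarities. Each seeded random restart is
#' refined by alternating monotone regression on the dissimilarity ranks
#' with a Guttman-transform update; iteration stops when the Kruskal
#' stress-1 change falls below `tol` or stress drops under `min_stress`.
#' The lowest-stress restart wins.
#'
#' @param d square dissimilarity matrix.
#' @param ndim embedding dimension (n >= ndim + 1).
#' @param restarts random restarts.
#' @param seed RNG seed.
#' @param max_iter iteration cap per restart.
#' @param tol stress-change convergence tolerance.
#' @param min_stress early-stop stress.
#' @return list(points, stress, trace, degenerate).
#' @export
nmds_ordination <- function(d, ndim = 2L, restarts = 50L, seed = 1L,
                            max_iter = 200L, tol = 1e-6, min_stress = 0.01) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < ndim + 1) stopf("need at least ndim + 1 samples")
  diss <- lower_tri(d)
  if (max(diss) - min(diss) < 1e-12) {
    ang <- 2 * pi * seq_len(n) / n
    pts <- cbind(cos(ang), sin(ang))[, seq_len(ndim), drop = FALSE]
    rownames(pts) <- rownames(d)
    return(list(points = pts, stress = 0, trace = 0, degenerate = TRUE))
  }
  li <- lower.tri(d)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      X <- matrix(runif(n * ndim, -1, 1), n, ndim)
      trace <- numeric(0)
      last <- Inf
      for (it in seq_len(max_iter)) {
        dm <- as.matrix(stats::dist(X))
        dd <- dm[li]
        dhat <- monotone_fit(diss, dd)
        s <- stress1(dd, dhat)
        trace <- c(trace, s)
        if (s < min_stress || abs(last - s) < tol) break
        last <- s
        # Guttman transform
        ratio <- matrix(0, n, n)
        dh <- matrix(0, n, n)
        dh[li] <- dhat; dh <- dh + t(dh)
        nz <- dm > 0
        ratio[nz] <- dh[nz] / dm[nz]
        B <- -ratio
        diag(B) <- -rowSums(B)
        X <- B %*% X / n
      }
      if (is.null(best) || s < best$stress)
        best <- list(points = X, stress = s, trace = trace)
    }
  })
  rownames(best$points) <- rownames(d)
  best$degenerate <- FALSE
  best
}

#' Paired t-test (closed form)
#'
#' `t = mean(x - y) / (sd(x - y)/sqrt(n))` with n-1 degrees of freedom and a
#' two-sided p-value. All-zero differences give t = 0, p = 1 (no evidence of
#' a difference); otherwise zero-variance differences are an error.
#'
#' @param x,y paired vectors of equal length >= 2.
#' @return list(t, df, p, mean_diff).
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 2) stopf("need at least 2 pairs")
  d <- x - y
  if (all(d == 0)) return(list(t = 0, df = n - 1L, p = 1, mean_diff = 0))
  s <- stats::sd(d)
  if (s == 0) stopf("zero-variance differences: paired t-test undefined")
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, df = n - 1L,
       p = 2 * stats::pt(-abs(t_stat), n - 1),
       mean_diff = mean(d))
}
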