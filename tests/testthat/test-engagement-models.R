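roster4 <- c("MA", "MK", "ML", "MC")

test_that("SEI is the weighted sum of score row-sums and sums to zero over the group", {
  # all-zero matrices: SEI 0 for any weights
  zero <- rand_score_matrices(roster4, 1)
  for (d in SOC_DIMENSIONS) zero[[d]][] <- 0L
  expect_equal(unname(compute_sei(zero, c(0.3, 0.7, 0.1))), rep(0, 4))

  # equal weights with per-dimension row-sums (-1, 2, -1): index 0
  m <- rand_score_matrices(c("A", "B", "C"), 2)
  m$aggression[] <- 0L; m$aggression["A", "B"] <- -1L; m$aggression["B", "A"] <- 1L
  m$grooming[] <- 0L; m$grooming["A", "B"] <- 1L; m$grooming["B", "A"] <- -1L
  m$grooming["A", "C"] <- 1L; m$grooming["C", "A"] <- -1L
  m$proximity[] <- 0L; m$proximity["A", "C"] <- -1L; m$proximity["C", "A"] <- 1L
  expect_equal(compute_sei(m, c(1, 1, 1), "A"), 0)

  # brute-force double-loop oracle over partners and dimensions, random matrices
  for (seed in 1:100) {
    M <- rand_score_matrices(roster4, seed)
    set.seed(seed + 1000)
    w <- runif(3)
    sei <- compute_sei(M, w)
    for (s in roster4) {
      acc <- 0
      for (p in setdiff(roster4, s)) {
        acc <- acc + w[1] * M$aggression[s, p] + w[2] * M$grooming[s, p] +
          w[3] * M$proximity[s, p]
      }
      expect_equal(sei[[s]], acc)
    }
    # zero-sum across the group for arbitrary weights
    expect_equal(sum(sei), 0, tolerance = 1e-12)
  }
})

test_that("IEI is the weighted dyadic score and antisymmetric under equal weights", {
  M <- rand_score_matrices(roster4, 3)
  M$aggression["MA", "MK"] <- 1L; M$aggression["MK", "MA"] <- -1L
  M$grooming["MA", "MK"] <- -1L; M$grooming["MK", "MA"] <- 1L
  M$proximity["MA", "MK"] <- 1L; M$proximity["MK", "MA"] <- -1L
  expect_equal(compute_iei(M, c(0.5, 0.5, 0.5), "MA", "MK"), 0.5)
  expect_equal(compute_iei(M, c(0, 0, 0), "MA", "MK"), 0)
  expect_error(compute_iei(M, c(1, 1, 1), "MA", "MA"), "differ")

  for (seed in 1:50) {
    M <- rand_score_matrices(roster4, seed)
    w <- rep(runif(1), 3)
    for (i in roster4) for (j in setdiff(roster4, i)) {
      expect_equal(compute_iei(M, w, i, j), -compute_iei(M, w, j, i))
    }
  }
  # the IEI table enumerates all ordered dyads
  tab <- engagement_index_table(M, c(1, 1, 1), "iei")
  expect_equal(nrow(tab), 4 * 3)
})

test_that("the weight grid enumerates multiples of the step and drops the zero vector", {
  expect_equal(nrow(weight_grid(0.5)), 3^3 - 1)
  W <- weight_grid(0.02)
  expect_equal(nrow(W), 51^3 - 1)
  # contains the reported in-group triple
  hit <- which(abs(W[, 1] - 0.34) < 1e-9 & abs(W[, 2] - 0.54) < 1e-9 &
                 abs(W[, 3] - 0.58) < 1e-9)
  expect_length(hit, 1)
  expect_false(any(rowSums(W) == 0))
  expect_error(weight_grid(0.03), "divide")
  expect_error(weight_grid(0), "in \\(0, 1\\]")
})

test_that("canonical tie-breaking prefers the largest component sum, then lexicographic", {
  expect_equal(unname(canonical_weights(rbind(c(0.17, 0.27, 0.29),
                                              c(0.34, 0.54, 0.58)))),
               c(0.34, 0.54, 0.58))
  expect_equal(unname(canonical_weights(rbind(c(0.2, 0.4, 0.1)))), c(0.2, 0.4, 0.1))
  expect_equal(unname(canonical_weights(rbind(c(1, 0, 0), c(0, 1, 0)))), c(1, 0, 0))
  expect_error(canonical_weights(matrix(numeric(0), 0, 3)), "empty")
})

test_that("fit_line matches exact lines and a permutation oracle for p", {
  x <- c(1, 2, 3, 4, 5)
  f <- fit_line(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r, 1)
  f2 <- fit_line(x, -x)
  expect_equal(f2$r, -1)
  expect_error(fit_line(rep(1, 5), x), "variance")
  expect_error(fit_line(x[1:2], x[1:2]), "at least 3")

  # p from the t distribution vs a permutation estimate (moderate effect so the
  # permutation p is resolvable at 4000 draws)
  set.seed(42)
  n <- 48
  xx <- rnorm(n)
  yy <- -0.3 * xx + rnorm(n, 0, 1)
  f3 <- fit_line(xx, yy)
  perm <- replicate(4000, abs(cor(xx, sample(yy))))
  p_perm <- mean(perm >= abs(f3$r))
  se <- sqrt(p_perm * (1 - p_perm) / 4000)
  expect_lt(abs(f3$p - p_perm), 4 * se + 0.005)
  # and agrees with cor.test
  ct <- cor.test(xx, yy)
  expect_equal(f3$p, ct$p.value)
  expect_equal(f3$r, unname(ct$estimate))
})

test_that("grid search finds the exact tie ray on noiseless linearly-coupled biases", {
  set.seed(7)
  repeat {
    M <- rand_score_matrices(roster4, sample.int(1e6, 1))
    X <- sapply(M, function(S) rowSums(unclass(S)))
    if (qr(X)$rank == 3) break
  }
  sei <- compute_sei(M, c(0.5, 0.5, 0.5))
  bias <- data.frame(subject = rep(roster4, 3), day = rep(1:3, each = 4),
                     bias_ms = rep(-10 * unname(sei), 3))
  gs <- grid_search_weights(bias, M, "sei", step = 0.1)
  expect_equal(gs$best_r, -1)
  # the tie set contains omega* and all its grid-representable scalings
  has <- function(w) any(apply(gs$tie_set, 1, function(tw) all(abs(tw - w) < 1e-9)))
  expect_true(has(c(0.5, 0.5, 0.5)))
  expect_true(has(c(1, 1, 1)))
  expect_true(has(c(0.1, 0.1, 0.1)))
  expect_equal(unname(gs$canonical), c(1, 1, 1))
  expect_equal(gs$fit$r, -1)

  # pure-noise biases: no strong correlation anywhere on the grid
  set.seed(8)
  noise <- data.frame(subject = rep(roster4, 12), day = rep(1:12, each = 4),
                      bias_ms = rnorm(48))
  gn <- grid_search_weights(noise, M, "sei", step = 0.1)
  expect_lt(abs(gn$best_r), 0.75)

  # degenerate pairing: all biases join to identical indices
  M0 <- M
  for (d in SOC_DIMENSIONS) M0[[d]][] <- 0L
  expect_error(grid_search_weights(bias, M0, "sei", step = 0.5), "degenerate")
  expect_error(grid_search_weights(bias[1:2, ], M, "sei", step = 0.5), "at least 3")
})

test_that("vectorized grid search equals the naive triple-loop oracle", {
  for (seed in 1:5) {
    repeat {
      M <- rand_score_matrices(roster4, seed * 13 + sample.int(100, 1))
      if (qr(sapply(M, function(S) rowSums(unclass(S))))$rank == 3) break
    }
    set.seed(seed)
    bias <- data.frame(subject = rep(roster4, 6), day = rep(1:6, each = 4),
                       bias_ms = rnorm(24, 50, 20))
    gs <- grid_search_weights(bias, M, "sei", step = 0.1)
    oracle <- naive_grid_search(bias, M, step = 0.1)
    key <- function(m) paste(round(m[, 1], 6), round(m[, 2], 6), round(m[, 3], 6))
    o <- oracle$surface[match(key(as.matrix(gs$r_surface)), key(oracle$surface)), ]
    expect_equal(nrow(gs$r_surface), nrow(oracle$surface))
    expect_lt(max(abs(gs$r_surface$r - o[, "r"])), 1e-12)
    expect_equal(gs$best_r, oracle$best_r, tolerance = 1e-12)
  }
})

test_that("Pearson r on the grid is invariant to positive weight rescaling", {
  repeat {
    M <- rand_score_matrices(roster4, 101)
    if (qr(sapply(M, function(S) rowSums(unclass(S))))$rank == 3) break
  }
  X <- sapply(M, function(S) rowSums(unclass(S)))
  set.seed(9)
  bias <- rnorm(48, 40, 15)
  subj <- rep(roster4, 12)
  for (k in 1:100) {
    w <- sample(seq(0.02, 0.5, by = 0.02), 3, replace = TRUE)
    x1 <- drop(X %*% w)[subj]
    x2 <- drop(X %*% (2 * w))[subj]
    x3 <- drop(X %*% (w / 2))[subj]
    expect_lt(abs(cor(x1, bias) - cor(x2, bias)), 1e-12)
    expect_lt(abs(cor(x1, bias) - cor(x3, bias)), 1e-12)
  }
})

test_that("recovery quality degrades monotonically as bias noise grows", {
  noise_levels <- c(0, 0.5, 1, 2)   # multiples of the signal SD
  mean_cos <- vapply(noise_levels, function(nf) {
    cs <- vapply(1:8, function(k) {
      cfg <- study_config(rt_noise_sd = 0, bias_noise_frac = nf,
                          group_effect = c("in" = 1, "out" = 1),
                          fixation_break_rate = 0, n_days = 8,
                          sessions_per_day = 6, obs_sessions = 8)
      st <- gen_full_study(cfg, seed = 7000 + k + round(1e4 * nf),
                           conditions = FALSE)
      b <- distractor_bias_table(drifting_time_table(st$trials), "all")
      gs <- grid_search_weights(b, st$matrices, "sei", step = 0.04)
      cosine(gs$canonical, cfg$omega_star)
    }, numeric(1))
    mean(cs)
  }, numeric(1))
  expect_equal(mean_cos[1], 1, tolerance = 1e-3)       # noiseless: exact direction
  # non-increasing within simulation error
  expect_true(all(diff(mean_cos) < 0.05))
  expect_lt(mean_cos[4], mean_cos[1])
})

test_that("pairwise SEI differences enumerate all unordered pairs", {
  z <- setNames(rep(0, 4), roster4)
  pz <- pairwise_index_differences(z)
  expect_equal(pz$differences$diff, rep(0, 6))
  expect_equal(pz$mean, 0)

  p <- pairwise_index_differences(setNames(c(1, 2, 3, 4), roster4))
  expect_equal(sort(p$differences$diff), c(1, 1, 1, 2, 2, 3))
  expect_equal(p$mean, 5 / 3)
  expect_equal(p$n_pairs, 6)
  expect_error(pairwise_index_differences(1), "at least 2")
})
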