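make_pwm <- function(consensus, strength = 0.85) {
  bases <- c("A", "C", "G", "T")
  L <- nchar(consensus)
  m <- matrix((1 - strength) / 3, 4, L, dimnames = list(bases, NULL))
  cc <- strsplit(consensus, "")[[1]]
  for (j in seq_len(L)) m[cc[j], j] <- strength
  list(id = consensus, name = consensus, matrix = m)
}

unif_bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

test_that("length-1 motif threshold admits exactly the qualifying bases", {
  pwm <- list(id = "m", name = "m",
              matrix = matrix(c(0.7, 0.1, 0.1, 0.1), 4,
                              dimnames = list(c("A", "C", "G", "T"), NULL)))
  th <- pwm_threshold(pwm, p_cutoff = 0.25, background = unif_bg)
  # exactly one of four bases scores at or above the threshold
  expect_equal(sum(th$scores >= th$threshold), 1)
  expect_equal(th$p_attained, 0.25)

  th1 <- pwm_threshold(pwm, p_cutoff = 1, background = unif_bg)
  expect_equal(th1$threshold, min(th1$scores))
  expect_error(pwm_threshold(pwm, p_cutoff = 0), "p_cutoff")
})

test_that("DP threshold equals exhaustive enumeration for short motifs", {
  set.seed(61)
  motifs <- list(make_pwm("ACGT"), make_pwm("GATTAC"), make_pwm("TTAAGG", 0.6))
  bgs <- list(unif_bg, c(A = 0.3, C = 0.2, G = 0.2, T = 0.3))
  for (pwm in motifs) for (bg in bgs) for (pc in c(5e-4, 1e-2, 0.2)) {
    th <- pwm_threshold(pwm, pc, bg)
    U <- th$scores; L <- ncol(U)
    ks <- 0:(4^L - 1)
    sc <- numeric(length(ks)); pr <- rep(1, length(ks))
    for (j in seq_len(L)) {
      dig <- (ks %/% 4^(j - 1)) %% 4 + 1
      sc <- sc + U[cbind(dig, j)]
      pr <- pr * bg[dig]
    }
    uniq <- sort(unique(sc))
    tails <- vapply(uniq, function(s) sum(pr[sc >= s]), 0)
    feasible <- uniq[tails <= pc]
    want <- if (length(feasible)) min(feasible) else max(sc) + 1
    expect_equal(th$threshold, want)
    expect_equal(th$p_attained, sum(pr[sc >= th$threshold]), tolerance = 1e-12)
  }
})

test_that("threshold is monotone in the p-value cutoff", {
  pwm <- make_pwm("ACGTAC")
  cuts <- c(0.5, 0.1, 1e-2, 1e-3, 5e-4)
  ths <- vapply(cuts, function(pc) pwm_threshold(pwm, pc, unif_bg)$threshold, 0L)
  expect_true(all(diff(ths) >= 0))
})

test_that("scanning finds planted hits and ignores unscannable sequence", {
  pwm <- make_pwm("CGCGAT", 0.94)
  win <- paste0(strrep("A", 40), "CGCGAT", strrep("T", 40))
  expect_equal(unname(count_motif_hits(c(w = win), list(m = pwm),
                                       background = unif_bg)[1, 1]), 1L)
  expect_equal(unname(count_motif_hits(c(w = strrep("N", 80)), list(m = pwm),
                                       background = unif_bg)[1, 1]), 0L)
  expect_warning(count_motif_hits(c(w = "ACG"), list(m = pwm),
                                  background = unif_bg), "shorter")
})

test_that("scanning counts match the naive rescanning oracle", {
  set.seed(67)
  pwms <- list(m1 = make_pwm("ACGTCA", 0.8), m2 = make_pwm("TTGACA", 0.7))
  wins <- vapply(1:60, function(i)
    paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = ""), "")
  names(wins) <- sprintf("w%02d", seq_along(wins))
  counts <- count_motif_hits(wins, pwms, background = unif_bg, p_cutoff = 5e-3)
  for (k in seq_along(pwms)) {
    th <- pwm_threshold(pwms[[k]], 5e-3, unif_bg)
    want <- vapply(wins, oracle_scan_count, 0L, U = th$scores,
                   threshold = th$threshold)
    expect_equal(unname(counts[, k]), unname(want))
  }
})

test_that("counts are invariant to reverse-complementing every window", {
  set.seed(71)
  pwm <- list(m = make_pwm("ACGGTA", 0.8))
  wins <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = ""), "")
  rc <- vapply(strsplit(wins, ""), function(ch)
    paste(rev(c(A = "T", C = "G", G = "C", T = "A")[ch]), collapse = ""), "")
  c1 <- count_motif_hits(wins, pwm, background = unif_bg, p_cutoff = 5e-3)
  c2 <- count_motif_hits(rc, pwm, background = unif_bg, p_cutoff = 5e-3)
  expect_equal(unname(c1), unname(c2))
})

test_that("motif effect model recovers planted effects and rejects nulls", {
  set.seed(73)
  X <- matrix(rpois(1000 * 20, 0.5), 1000, 20,
              dimnames = list(NULL, sprintf("M%02d", 1:20)))
  y1 <- 0.5 * X[, 1] - 0.5 * X[, 2] + rnorm(1000, 0, 0.5)
  y2 <- 0.5 * X[, 1] - 0.5 * X[, 2] + rnorm(1000, 0, 0.5)
  fit <- fit_motif_effect_model(X, y1, y2, seed = 1)
  m1 <- fit[fit$motif == "M01", ]; m2 <- fit[fit$motif == "M02", ]
  expect_true(m1$selected && m2$selected)
  expect_gt(m1$t_constant, 0); expect_lt(m2$t_constant, 0)
  expect_gt(m1$t_transient, 0); expect_lt(m2$t_transient, 0)
  expect_lt(m1$p_constant, 1e-5); expect_lt(m2$p_constant, 1e-5)

  # permuted response: nothing should pass the OLS significance bar
  fitp <- fit_motif_effect_model(X, sample(y1), sample(y2), seed = 1)
  expect_lte(sum(fitp$selected), 1)

  # all-zero counts: no motif ranked or selected
  fit0 <- fit_motif_effect_model(matrix(0L, 100, 5,
                                        dimnames = list(NULL, paste0("Z", 1:5))),
                                 rnorm(100), rnorm(100), seed = 1)
  expect_false(any(fit0$in_top))
  expect_false(any(fit0$selected))
  expect_error(fit_motif_effect_model(X[1:20, ], y1[1:20], y2[1:20], seed = 1),
               "fewer than 50")
})

test_that("selection is invariant to rescaling a count column", {
  set.seed(79)
  X <- matrix(rpois(600 * 10, 0.6), 600, 10,
              dimnames = list(NULL, sprintf("M%02d", 1:10)))
  y1 <- 0.6 * X[, 3] + rnorm(600, 0, 0.5)
  y2 <- 0.6 * X[, 3] + rnorm(600, 0, 0.5)
  f1 <- fit_motif_effect_model(X, y1, y2, seed = 2)
  Xs <- X; Xs[, 3] <- Xs[, 3] * 10
  f2 <- fit_motif_effect_model(Xs, y1, y2, seed = 2)
  expect_equal(f1$selected, f2$selected)
})

test_that("the largest grid lambda shrinks every coefficient to zero", {
  set.seed(83)
  X <- matrix(rpois(300 * 6, 0.5), 300, 6)
  y <- 0.5 * X[, 1] + rnorm(300, 0, 0.5)
  fit <- glmnet::glmnet(X, y, lambda = 100, standardize = TRUE)
  expect_true(all(abs(as.numeric(fit$beta)) == 0))
})

test_that("dose-response medians rise with a positive planted effect", {
  set.seed(89)
  cnt <- rpois(2000, 1)
  lfc <- 0.8 * cnt + rnorm(2000, 0, 0.3)
  dr <- motif_dose_response(lfc, cnt)
  expect_true(all(diff(dr$median) > 0))
  expect_true(all(dr$p_vs_zero[-1] < 1e-5))
  expect_true(is.na(dr$p_vs_zero[1]))

  # motif absent everywhere: a single bin and no test
  expect_warning(dr0 <- motif_dose_response(lfc, rep(0L, 2000)), "empty")
  expect_equal(nrow(dr0), 1)
  expect_true(is.na(dr0$p_vs_zero))

  # constant response: tests are uninformative (p = 1)
  set.seed(97)
  drc <- motif_dose_response(rep(1.5, 100), rpois(100, 3))
  expect_true(all(drc$p_vs_zero[-1] == 1 | is.na(drc$p_vs_zero[-1])))
})
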