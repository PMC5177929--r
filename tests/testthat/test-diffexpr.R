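test_that("TMM factors: identical libraries give exactly 1", {
  set.seed(41)
  x <- rpois(200, 60) + 1L
  f <- tmm_factors(cbind(A = x, B = x, C = x))
  expect_equal(unname(f$tmm_factor), rep(1, 3))
})

test_that("TMM factors: a tagwise-doubled library gives sqrt(2) factors", {
  set.seed(42)
  x <- rpois(300, 50) + 1L
  f <- tmm_factors(cbind(A = x, B = 2L * x))
  expect_equal(sort(unname(f$tmm_factor)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-6)
})

test_that("TMM factors equal an independent step-by-step reimplementation", {
  set.seed(43)
  for (r in 1:5) {
    cnt <- matrix(rnbinom(200 * 6, mu = exp(runif(200 * 6, 2, 6)), size = 5),
                  200, 6, dimnames = list(NULL, paste0("L", 1:6)))
    cnt[cnt == 0 & matrix(runif(length(cnt)) < 0.5, 200, 6)] <- 1L
    f <- tmm_factors(cnt)
    expect_equal(unname(f$tmm_factor), naive_tmm(cnt), tolerance = 1e-8)
  }
})

test_that("TMM factors respond reciprocally to scaling one library", {
  set.seed(44)
  cnt <- matrix(rnbinom(200 * 4, mu = 80, size = 5) + 1L, 200, 4,
                dimnames = list(NULL, paste0("L", 1:4)))
  f1 <- tmm_factors(cnt)$tmm_factor
  cnt2 <- cnt
  cnt2[, 3] <- cnt2[, 3] * 4L
  f2 <- tmm_factors(cnt2)$tmm_factor
  ## the scaled library's factor moves by ~4 (up to geometric rescaling
  ## spread over the other libraries)
  expect_equal(unname((f2[3] / f1[3]) / (f2[1] / f1[1])), 4, tolerance = 0.05)
})

test_that("common dispersion hits the Poisson boundary on Poisson data", {
  des <- full_design(treatments = c("control", "heat"), replicates = 1:3,
                     time_dat = c(0L, 1L, 2L))
  set.seed(45)
  cnt <- matrix(rpois(150 * nrow(des), lambda = rep(exp(runif(150, 3, 6)),
                                                    nrow(des))),
                150, nrow(des), dimnames = list(NULL, des$library_id))
  disp <- estimate_dispersion(cnt, des)
  expect_lte(disp$common, 1e-3)
})

test_that("infinite prior degrees of freedom collapse tagwise onto common", {
  des <- full_design(treatments = c("control", "heat"), replicates = 1:3,
                     time_dat = c(0L, 1L))
  set.seed(46)
  base <- exp(runif(100, 3, 6))
  cnt <- matrix(rnbinom(100 * nrow(des), mu = rep(base, nrow(des)), size = 10),
                100, nrow(des), dimnames = list(paste0("t", 1:100),
                                                des$library_id))
  d_inf <- estimate_dispersion(cnt, des, prior_df = Inf)
  expect_equal(unname(d_inf$tagwise), rep(d_inf$common, 100))
  d_fin <- estimate_dispersion(cnt, des, prior_df = 10)
  expect_equal(d_fin$common, d_inf$common, tolerance = 1e-6)
  expect_gt(stats::sd(d_fin$tagwise), 0)
})

test_that("NB dispersion is recovered from simulated counts", {
  des <- full_design()
  set.seed(47)
  base <- stats::setNames(pmax(20, round(exp(runif(600, 3.5, 7)))),
                          paste0("t", 1:600))
  cnt <- simulate_counts(des, base, dispersion = 0.1, seed = 48)
  disp <- estimate_dispersion(cnt, des)
  expect_lt(abs(disp$common - 0.1), 0.03)
})

test_that("constant counts across a balanced design give zero effect estimates", {
  des <- full_design(replicates = 1:2, time_dat = c(0L, 1L))
  X <- design_matrix(des)
  y <- rep(100L, nrow(des))
  fit <- fit_nb_glm(y, X, offset = rep(0, nrow(des)), phi = 0.1)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients[-1]), rep(0, ncol(X) - 1),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients[1]), log(100), tolerance = 1e-6)
})

test_that("the Poisson special case matches closed-form group log-mean ratios", {
  des <- data.frame(library_id = paste0("L", 1:8),
                    treatment = rep(c("control", "heat"), each = 4),
                    replicate = rep(1:4, 2), time_dat = 0L)
  X <- design_matrix(des)
  set.seed(49)
  y <- c(rpois(4, 100), rpois(4, 400))
  fit <- fit_nb_glm(y, X, offset = rep(0, 8), phi = 1e-10)
  expect_equal(unname(fit$coefficients["trtheat"]),
               log(mean(y[5:8]) / mean(y[1:4])), tolerance = 1e-6)
})

test_that("planted log2 fold changes are recovered by the GLM contrasts", {
  des <- full_design()
  set.seed(50)
  ## planted tags against an unaffected background, so the library-size
  ## offsets are not confounded with the planted effect
  base <- stats::setNames(c(rep(1000, 40), exp(runif(160, 3, 6))),
                          paste0(rep(c("p", "n"), c(40, 160)),
                                 c(1:40, 1:160)))
  eff <- do.call(rbind, lapply(c(0L, 1L), function(t)
    data.frame(sequence = paste0("p", 1:40), treatment = "heat",
               time_dat = t, log2fc = -2)))
  cnt <- simulate_counts(des, base, eff, dispersion = 0.1, seed = 51)
  ## libraries were simulated at equal depth: constant offsets isolate
  ## coefficient recovery from normalization
  res <- test_contrasts(cnt, des, dispersion = 0.1, offsets = rep(0, nrow(des)))
  res <- res[res$tag_id %in% paste0("p", 1:40), ]
  at0 <- res[res$treatment == "heat" & res$scope == "0", ]
  expect_equal(mean(at0$log2fc), -2, tolerance = 0.15)
  ## estimation bias is small at this depth
  expect_lt(abs(mean(at0$log2fc) + 2), 0.1)
  at7 <- res[res$treatment == "heat" & res$scope == "7", ]
  expect_equal(mean(at7$log2fc), 0, tolerance = 0.15)
})

test_that("DE results control FDR bookkeeping within contrast families", {
  des <- full_design(replicates = 1:3, time_dat = c(0L, 1L))
  set.seed(52)
  base <- stats::setNames(exp(runif(80, 3, 6)), paste0("t", 1:80))
  cnt <- simulate_counts(des, base, dispersion = 0.1, seed = 53)
  res <- test_contrasts(cnt, des, dispersion = 0.1)
  ov <- res[res$scope == "overall" & res$treatment == "heat", ]
  ## BH q-values dominate p-values and are a monotone transform of ranks
  expect_true(all(ov$fdr >= ov$p - 1e-12))
  o <- order(ov$p)
  expect_true(all(diff(ov$fdr[o]) >= -1e-12))
  ## direction is ns exactly when fdr >= alpha
  expect_true(all((res$direction == "ns") == (is.na(res$fdr) | res$fdr >= 0.05)))
})

test_that("Venn regions partition the three DE sets", {
  v <- venn_counts(list(heat = paste0("h", 1:79), light = paste0("l", 1:2),
                        uv = "u1"))
  expect_equal(unname(v[c("heat", "light", "uv")]), c(79, 2, 1))
  expect_equal(sum(v[4:7]), 0)
  s <- paste0("x", 1:10)
  v2 <- venn_counts(list(heat = s, light = s, uv = s))
  expect_equal(unname(v2["heat_light_uv"]), 10)
  expect_equal(sum(v2[1:6]), 0)
  ## random sets equal brute-force region counting
  set.seed(54)
  u <- paste0("t", 1:40)
  sets <- list(heat = sample(u, 20), light = sample(u, 15), uv = sample(u, 10))
  v3 <- venn_counts(sets)
  inh <- u %in% sets$heat
  inl <- u %in% sets$light
  inu <- u %in% sets$uv
  expect_equal(unname(v3["heat"]), sum(inh & !inl & !inu))
  expect_equal(unname(v3["heat_light"]), sum(inh & inl & !inu))
  expect_equal(unname(v3["heat_light_uv"]), sum(inh & inl & inu))
  expect_equal(sum(v3), length(unique(unlist(sets))))
})

test_that("heat-map entries follow the log2 CPM-with-pseudocount transform", {
  cnt <- matrix(c(0L, 10L, 5L, 20L), 2, 2,
                dimnames = list(c("t1", "t2"), c("A", "B")))
  hm <- heatmap_matrix(cnt, effective_size = c(1, 1), pseudocount = 1)
  expect_equal(hm$matrix["t1", "A"], 0)   # log2(0/1 * 1e6 + 1)
  expect_equal(hm$matrix["t2", "A"], log2(10 * 1e6 + 1))
  ## duplicated libraries sit adjacent in the column dendrogram order
  cnt2 <- matrix(rpois(40, 50), 10, 4,
                 dimnames = list(paste0("t", 1:10), c("A", "B", "C", "D")))
  cnt2[, 3] <- cnt2[, 1]
  hm2 <- heatmap_matrix(cnt2, effective_size = rep(1, 4))
  pos <- match(c(1, 3), hm2$col_order)
  expect_equal(abs(diff(pos)), 1)
  ## linkage heights equal a naive average-linkage recomputation
  hts <- naive_average_linkage_heights(stats::dist(hm2$matrix))
  expect_equal(sort(hm2$row_hclust$height), sort(hts), tolerance = 1e-9)
})
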