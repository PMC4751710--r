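## Statistical core: log transform, Welch t, Bonferroni, fold difference,
## full enrichment ranking, single-region z-score.

test_that("log_transform evaluates log_base(value + pseudocount)", {
  cfg1 <- enrichment_config(pseudocount = 1, log_base = 2)
  expect_equal(log_transform(0, cfg1), 0)
  expect_equal(log_transform(3, cfg1), 2)
  v <- c(0, 1, 3)
  expect_equal(log_transform(v, enrichment_config(pseudocount = 0.01)),
               log2(v + 0.01))
  expect_error(log_transform(c(1, -0.1)), "negative")
})

test_that("welch_t_test matches stats::t.test and the textbook formulas", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  r <- welch_t_test(x, y)
  # explicit Welch formulas
  se2 <- var(x) / 4 + var(y) / 4
  t_exp <- (mean(x) - mean(y)) / sqrt(se2)
  df_exp <- se2^2 / ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3)
  expect_equal(r$t, t_exp, tolerance = 1e-14)
  expect_equal(r$df, df_exp, tolerance = 1e-14)
  expect_equal(r$p, 2 * pt(-abs(t_exp), df_exp), tolerance = 1e-14)

  set.seed(31)
  for (i in 1:25) {
    a <- rnorm(sample(3:40, 1)); b <- rnorm(sample(3:40, 1), sd = runif(1, 0.5, 3))
    got <- welch_t_test(a, b)
    ref <- t.test(a, b)                       # independent oracle
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    one <- welch_t_test(a, b, sides = 1)
    expect_equal(one$p, t.test(a, b, alternative = "greater")$p.value,
                 tolerance = 1e-12)
  }
})

test_that("welch_t_test handles identical and degenerate samples", {
  x <- c(1, 2, 3)
  r <- welch_t_test(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  z <- welch_t_test(c(2, 2, 2), c(2, 2))      # both variances zero, equal means
  expect_equal(z$p, 1)
  expect_true(z$degenerate)
  z2 <- welch_t_test(c(2, 2), c(3, 3, 3))     # zero variance, different means
  expect_equal(z2$p, 0)
  expect_true(z2$degenerate)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("swapping the samples negates t and preserves the two-sided p", {
  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(30, 0.4)
    f <- welch_t_test(a, b); r <- welch_t_test(b, a)
    expect_equal(f$t, -r$t, tolerance = 1e-13)
    expect_equal(f$p, r$p, tolerance = 1e-13)
  }
})

test_that("bonferroni is min(1, p*m), monotone and identity at m = 1", {
  expect_equal(bonferroni(0.5, 1), 0.5)
  expect_equal(bonferroni(0.01, 200), 1)
  expect_equal(bonferroni(1e-5, 100), 1e-3)
  p <- seq(0, 0.01, length.out = 11)
  expect_true(all(diff(bonferroni(p, 50)) >= 0))            # monotone in p
  expect_true(all(diff(bonferroni(0.002, c(1, 10, 100, 1000))) >= 0))  # and in m
  expect_true(all(bonferroni(p, 1e6) <= 1))
})

test_that("fold_difference works on raw means with pseudocount guard", {
  # ratio of the canonical printed coverage pair 1.3 / 0.59 ~ 2.2
  expect_equal(fold_difference(1.3, 0.59, epsilon = 1e-12), 1.3 / 0.59)
  expect_equal(round(fold_difference(1.3, 0.59, epsilon = 1e-12), 1), 2.2)
  expect_equal(fold_difference(0.7, 0.7, epsilon = 0.3), 1)
  expect_equal(fold_difference(0, 0, epsilon = 0.01), 1)
})

test_that("log-base invariance and scale-cancellation hold for the t statistic", {
  set.seed(44)
  q <- abs(rnorm(20)); b <- abs(rnorm(50))
  c2 <- enrichment_config(log_base = 2); ce <- enrichment_config(log_base = exp(1))
  r2 <- welch_t_test(log_transform(q, c2), log_transform(b, c2))
  re <- welch_t_test(log_transform(q, ce), log_transform(b, ce))
  expect_equal(r2$t, re$t, tolerance = 1e-10)
  expect_equal(r2$p, re$p, tolerance = 1e-10)

  # multiplying coverage by k with co-scaled pseudocount leaves t unchanged
  k <- 37.5
  ck <- enrichment_config(pseudocount = 0.01 * k)
  rk <- welch_t_test(log_transform(q * k, ck), log_transform(b * k, ck))
  expect_equal(rk$t, r2$t, tolerance = 1e-10)
  expect_equal(rk$p, r2$p, tolerance = 1e-10)
})

test_that("enrich_all ranks the planted track first and respects symmetry", {
  env <- shared_fixture(); fx <- env$fx
  q <- promoters_for(fx$truth$enriched_gene_symbols, fx$annotation)
  bg <- sample_background(fx$annotation, n = 30, seed = 2)
  tab <- enrich_all(fx$collection, q, bg)
  expect_s3_class(tab, "enrichment_table")
  expect_equal(tab$track_id[1], fx$truth$enriched_track_ids)
  expect_lt(tab$bonferroni_p[1], 0.05)
  expect_equal(attr(tab, "m"), 4)
  expect_true(all(tab$bonferroni_p >= tab$p_value))
  expect_true(all(tab$fold_difference > 0))
  expect_equal(tab$n_query[1], length(q$ranges))

  # query == background -> every track p = 1
  same <- enrich_all(fx$collection, q, query_set("bg", q$ranges))
  expect_true(all(same$p_value == 1))

  # swapping query and background preserves p and negates t, per track
  swapped <- enrich_all(fx$collection, bg, q)
  i <- match(tab$track_id, swapped$track_id)
  expect_equal(swapped$t_statistic[i], -tab$t_statistic, tolerance = 1e-12)
  expect_equal(swapped$p_value[i], tab$p_value, tolerance = 1e-12)
})

test_that("enrich_all ranking is invariant to the log base", {
  env <- shared_fixture(); fx <- env$fx
  q <- promoters_for(fx$truth$enriched_gene_symbols, fx$annotation)
  bg <- sample_background(fx$annotation, n = 25, seed = 9)
  t2 <- enrich_all(fx$collection, q, bg, enrichment_config(log_base = 2))
  te <- enrich_all(fx$collection, q, bg, enrichment_config(log_base = exp(1)))
  expect_identical(t2$track_id, te$track_id)
  expect_equal(t2$t_statistic, te$t_statistic, tolerance = 1e-10)
  expect_equal(t2$p_value, te$p_value, tolerance = 1e-10)
})

test_that("all-zero tracks are reported degenerate with p = 1, not dropped", {
  dir <- withr::local_tempdir()
  fx <- shared_fixture()$fx
  zero <- constant_bw(0, 200000, file.path(dir, "zero.bw"))
  md <- rbind(as.data.frame(fx$collection)[, c("track_id", "path", "assembly",
                                               "category", "total_tags", "description")],
              data.frame(track_id = "ZERO", path = zero, assembly = "syn1",
                         category = "other", total_tags = 1, description = "flat zero"))
  f <- file.path(dir, "md.tsv")
  write.table(md, f, sep = "\t", quote = FALSE, row.names = FALSE)
  col <- load_collection(f)
  q <- promoters_for(fx$truth$enriched_gene_symbols[1:5], fx$annotation)
  bg <- sample_background(fx$annotation, n = 10, seed = 4)
  tab <- enrich_all(col, q, bg)
  zr <- tab[tab$track_id == "ZERO", ]
  expect_equal(nrow(tab), 5)                  # m includes the degenerate track
  expect_equal(attr(tab, "m"), 5)
  expect_true(zr$degenerate)
  expect_equal(zr$p_value, 1)
})

test_that("single_region_zscore standardizes against background log moments", {
  fx <- shared_fixture()$fx
  q <- promoters_for(fx$truth$enriched_gene_symbols[1], fx$annotation)
  bg <- sample_background(fx$annotation, n = 20, seed = 6)
  res <- single_region_zscore(fx$collection, q$ranges, bg)
  expect_equal(res$track_id[order(res$p_value, res$track_id)], res$track_id)

  # oracle re-computation from raw coverages for one track
  cfg <- enrichment_config()
  for (tid in res$track_id) {
    trk <- fx$collection[fx$collection$track_id == tid, ]
    x <- log_transform(mean_coverage(trk, q$ranges), cfg)
    b <- log_transform(mean_coverage(trk, bg$ranges), cfg)
    z_exp <- (x - mean(b)) / sd(b)
    row <- res[res$track_id == tid, ]
    expect_equal(row$z, z_exp, tolerance = 1e-12)
    expect_equal(row$p_value, 2 * pnorm(-abs(z_exp)), tolerance = 1e-12)
  }
  # the planted track should stand out at its own enriched promoter
  expect_equal(res$track_id[1], fx$truth$enriched_track_ids)

  # constant track -> zero background spread -> degenerate, p = 1
  dir <- withr::local_tempdir()
  cpath <- constant_bw(2, 200000, file.path(dir, "c.bw"))
  md <- data.frame(track_id = "CONST", path = cpath, assembly = "syn1",
                   category = "other", total_tags = 1, description = "flat")
  f <- file.path(dir, "md.tsv")
  write.table(md, f, sep = "\t", quote = FALSE, row.names = FALSE)
  rc <- single_region_zscore(load_collection(f), q$ranges, bg)
  expect_true(rc$degenerate)
  expect_equal(rc$p_value, 1)
  expect_error(single_region_zscore(fx$collection, q$ranges[c(1, 1)], bg), "one region")
})
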