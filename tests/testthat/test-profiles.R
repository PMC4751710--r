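## Center-anchored strand-aware profiles and stack data.

test_that("a constant track yields a flat profile for any set and strand", {
  dir <- withr::local_tempdir()
  p <- constant_bw(4, 20000, file.path(dir, "c.bw"))
  gr <- genomic_interval("chr1", c(3000, 8000, 12000), c(5000, 10000, 14000),
                         strand = c("+", "-", "."))
  pm <- coverage_profile(p, query_set("s", gr), halfwidth = 500, bin_size = 10)
  expect_equal(dim(pm$values), c(1, 100))
  expect_true(all(pm$values == 4))
  expect_equal(pm$offsets, seq(-500, 490, by = 10))
})

test_that("minus-strand windows equal the explicit per-base reversal oracle", {
  dir <- withr::local_tempdir()
  # asymmetric step: 1 below position 5000 (0-based), 9 from 5000 on
  vals <- c(rep(1, 5000), rep(9, 5000))
  p <- write_bw(vals, file.path(dir, "step.bw"))
  hw <- 200
  minus <- genomic_interval("chr1", 4800, 5200, strand = "-")
  pm <- coverage_profile(p, query_set("m", minus), halfwidth = hw, bin_size = 1)

  center <- 5000
  window <- vals[(center - hw + 1):(center + hw)]   # 1-based slice of [c-hw, c+hw)
  expect_equal(unname(pm$values[1, ]), rev(window))

  # plus strand on the same window is the unreversed oracle, and differs
  plus <- genomic_interval("chr1", 4800, 5200, strand = "+")
  pp <- coverage_profile(p, query_set("p", plus), halfwidth = hw, bin_size = 1)
  expect_equal(unname(pp$values[1, ]), window)
  expect_false(identical(pm$values, pp$values))

  # unstranded intervals are treated as plus
  dot <- genomic_interval("chr1", 4800, 5200, strand = ".")
  pd <- coverage_profile(p, query_set("d", dot), halfwidth = hw, bin_size = 1)
  expect_equal(pd$values, unname(pp$values), ignore_attr = TRUE)
})

test_that("opposite-strand promoters of one TSS profile identically on a symmetric signal", {
  # The promoter convention shifts minus-strand windows by +1 bp, which
  # exactly compensates the reversal anchor of half-open windows: a TSS-
  # symmetric signal therefore profiles identically from either strand.
  dir <- withr::local_tempdir()
  cfg0 <- synthetic_config(n_genes = 50, chrom_length = 2e5, n_tracks = 1,
                           n_enriched_tracks = 1, enriched_genes = 10,
                           peak_amplitude = 3, peak_halfwidth = 100,
                           noise_sd = 0, baseline = 0.5, seed = 101L)
  ann0 <- make_annotation(cfg0, dir)
  p0 <- make_track(cfg0, ann0$layout, TRUE, 1, file.path(dir, "sym.bw"))
  # SYNG0012 is one of the 10 evenly spread peak-bearing genes
  tss <- ann0$layout$tss[match("SYNG0012", ann0$layout$gene_symbol)]
  hw <- 400
  plus <- genomic_interval("chr1", tss - hw, tss + hw, strand = "+")
  minus <- genomic_interval("chr1", tss - hw + 1, tss + hw + 1, strand = "-")
  a <- coverage_profile(as.character(p0), query_set("p", plus),
                        halfwidth = hw, bin_size = 1)
  b <- coverage_profile(as.character(p0), query_set("m", minus),
                        halfwidth = hw, bin_size = 1)
  expect_equal(a$values, b$values, tolerance = 1e-12, ignore_attr = TRUE)
  v <- a$values[1, ]
  expect_equal(v[2:length(v)], rev(v[2:length(v)]), tolerance = 1e-6)
})

test_that("bin_size = 1 profiles re-binned externally equal binned profiles", {
  fx <- shared_fixture()$fx
  q <- promoters_for(fx$truth$enriched_gene_symbols[1:6], fx$annotation)
  trk <- fx$collection[1, ]
  fine <- coverage_profile(trk, query_set("q", q$ranges), halfwidth = 300, bin_size = 1)
  coarse <- coverage_profile(trk, query_set("q", q$ranges), halfwidth = 300, bin_size = 20)
  rebinned <- colMeans(matrix(fine$values[1, ], nrow = 20))
  expect_equal(unname(coarse$values[1, ]), rebinned, tolerance = 1e-12)
  expect_error(coverage_profile(trk, query_set("q", q$ranges),
                                halfwidth = 300, bin_size = 7), "divide")
})

test_that("a union of disjoint sets profiles as the count-weighted average", {
  fx <- shared_fixture()$fx
  syms <- fx$annotation$genes$gene_symbol
  qa <- promoters_for(syms[1:4], fx$annotation)
  qb <- promoters_for(syms[11:16], fx$annotation)
  qu <- query_set("union", c(qa$ranges, qb$ranges))
  trk <- fx$collection[2, ]
  pa <- coverage_profile(trk, qa, halfwidth = 200, bin_size = 10)$values[1, ]
  pb <- coverage_profile(trk, qb, halfwidth = 200, bin_size = 10)$values[1, ]
  pu <- coverage_profile(trk, qu, halfwidth = 200, bin_size = 10)$values[1, ]
  expect_equal(pu, (4 * pa + 6 * pb) / 10, tolerance = 1e-12)
})

test_that("per-million scaling divides the profile by total tags", {
  fx <- shared_fixture()$fx
  trk <- fx$collection[1, ]
  q <- promoters_for(fx$annotation$genes$gene_symbol[1:3], fx$annotation)
  raw <- coverage_profile(trk, q, halfwidth = 100, bin_size = 10)
  tpm <- coverage_profile(trk, q, halfwidth = 100, bin_size = 10,
                          scale_per_million = TRUE)
  expect_equal(tpm$values, raw$values * 1e6 / trk$total_tags, tolerance = 1e-12)
})

test_that("stack_data sorts per-interval coverages descending per set", {
  dir <- withr::local_tempdir()
  # three constant plateaus: coverages 2, 5, 1 by construction
  vals <- c(rep(2, 100), rep(5, 100), rep(1, 100))
  p <- write_bw(vals, file.path(dir, "plateau.bw"))
  gr <- genomic_interval("chr1", c(0, 100, 200), c(100, 200, 300),
                         label = c("a", "b", "c"))
  sd1 <- stack_data(p, query_set("s", gr))
  expect_equal(unname(sd1$sets$s), c(5, 2, 1))
  expect_equal(names(sd1$sets$s), c("b", "a", "c"))

  # identical sets give identical vectors; values match mean_coverage
  fx <- shared_fixture()$fx
  q <- promoters_for(fx$annotation$genes$gene_symbol[1:5], fx$annotation)
  s2 <- stack_data(fx$collection[1, ], list(q, q))
  expect_equal(unname(s2$sets[[1]]), unname(s2$sets[[2]]))
  expect_equal(sort(unname(s2$sets[[1]]), decreasing = TRUE),
               unname(sort(mean_coverage(fx$collection$path[1], q$ranges),
                           decreasing = TRUE)),
               tolerance = 1e-12)
})

test_that("windows beyond chromosome bounds contribute zeros with a warning", {
  dir <- withr::local_tempdir()
  p <- constant_bw(3, 1000, file.path(dir, "short.bw"))
  gr <- genomic_interval("chr1", 0, 100)     # center 50, window [-150, 250)
  expect_silent(pm <- coverage_profile(p, query_set("edge", gr),
                                       halfwidth = 200, bin_size = 1))
  v <- unname(pm$values[1, ])
  expect_equal(v[1:150], rep(0, 150))        # off-chromosome left flank
  expect_equal(v[151:400], rep(3, 250))
})
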