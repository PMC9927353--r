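test_that("expected replicate-shared stochastic count is N * p0^k", {
  expect_equal(expected_shared_stochastic(6.3e6, 1e-4, 3), 6.3e-6)
  expect_equal(expected_shared_stochastic(1e6, 0, 3), 0)
  expect_equal(expected_shared_stochastic(1e6, 2e-4, 1), 1e6 * 2e-4)
})

test_that("distance_to_box follows the nearest-base sign convention", {
  box <- data.frame(contig = "c1", start = 100L, end = 120L)
  expect_equal(as.numeric(distance_to_box(144L, box)), 25)   # 25 bp right of end
  expect_equal(as.numeric(distance_to_box(120L, box)), 1)    # adjacent base
  expect_equal(as.numeric(distance_to_box(99L, box)), 1)
  expect_equal(as.numeric(distance_to_box(100L, box)), -1)   # first box base
  expect_equal(as.numeric(distance_to_box(119L, box)), -1)   # last box base
  expect_equal(as.numeric(distance_to_box(109L, box)), -10)  # deepest
  expect_error(distance_to_box(5L, box, contig = "c2"), "no box on contig")
})

test_that("distance_to_box matches an exhaustive per-base scan", {
  oracle <- function(pos, start, end) {
    bases <- start:(end - 1)
    if (pos %in% bases) -(1 + min(abs(pos - start), abs(pos - (end - 1))))
    else min(abs(pos - bases)) # gap so that the adjacent base is 1
  }
  withr::with_seed(8, {
    for (i in 1:50) {
      start <- sample(50:200, 1)
      width <- sample(14:20, 1)
      pos <- sample(0:400, 1)
      box <- data.frame(contig = "c1", start = start, end = start + width)
      expect_equal(as.numeric(distance_to_box(pos, box)),
                   oracle(pos, start, start + width))
    }
  })
})

test_that("distance_to_box picks the nearest box and survives coordinate reflection", {
  boxes <- data.frame(contig = "c1", start = c(100L, 300L), end = c(120L, 320L))
  d <- distance_to_box(c(130L, 290L, 305L), boxes)
  expect_equal(as.numeric(d), c(11, 10, -6))
  expect_equal(attr(d, "box"), c(1L, 2L, 2L))
  # reflect genome of length L=400 about its centre: pos -> L-1-pos,
  # box [s,e) -> [L-e, L-s)
  L <- 400L
  refl <- data.frame(contig = "c1", start = L - boxes$end, end = L - boxes$start)
  d2 <- distance_to_box(L - 1L - c(130L, 290L, 305L), refl)
  expect_equal(as.numeric(d2), as.numeric(d))
})

test_that("strand class assigns the strand carrying the deaminated cytosine", {
  plus <- data.frame(strand = "+")
  minus <- data.frame(strand = "-")
  ct <- ss("c1:5:C>T"); ga <- ss("c1:6:G>A")
  expect_equal(strand_class(ct, plus), "CS")
  expect_equal(strand_class(ga, plus), "TS")
  expect_equal(strand_class(ct, minus), "TS")
  expect_equal(strand_class(ga, minus), "CS")
  expect_error(strand_class(ss("c1:7:A>G"), plus), "deamination signature")
})

test_that("strand classes are balanced under symmetric editing", {
  sim <- default_sim()
  res <- default_profile()
  a <- res$attributed
  a <- a[paste0(a$ref, ">", a$alt) %in% c("C>T", "G>A"), ]
  # classify each SNP against its nearest box's downstream gene strand
  d <- distance_to_box(a$pos, sim$boxes, contig = a$contig)
  gene_id <- vapply(strsplit(sim$boxes$promoter_gene[attr(d, "box")], ","),
                    `[`, "", 1)
  strands <- sim$genome$genes$strand[match(gene_id, sim$genome$genes$gene_id)]
  cls <- vapply(seq_len(nrow(a)), function(i) {
    strand_class(a[i, ], data.frame(strand = strands[i]))
  }, "")
  bt <- stats::binom.test(sum(cls == "TS"), length(cls))
  expect_gt(bt$p.value, 0.001)
})

test_that("promoter peak frequency is the per-promoter maximum", {
  a <- data.frame(region_class = "promoter_like",
                  upstream_of = c("p1", "p2", "p2", "p2", "p3"),
                  frequency = c(0.5, 0.1, 0.4, 0.2, NA))
  pk <- promoter_peak_frequency(a)
  expect_equal(pk[["p1"]], 0.5)
  expect_equal(pk[["p2"]], 0.4)
  expect_false("p3" %in% names(pk))  # unknown frequency ignored
  withr::with_seed(9, {
    big <- data.frame(region_class = "promoter_like",
                      upstream_of = sample(letters[1:6], 100, replace = TRUE),
                      frequency = runif(100))
  })
  pk2 <- promoter_peak_frequency(big)
  oracle <- c(tapply(big$frequency, big$upstream_of, max))
  expect_equal(pk2[names(oracle)], oracle)
})

test_that("replicate R^2 is 1 for exact linear agreement and matches the formula", {
  x <- c(0.1, 0.3, 0.5, 0.7)
  perfect <- data.frame(freq_rep1 = x, freq_rep2 = x, freq_rep3 = 2 * x)
  r2 <- suppressMessages(replicate_r2(perfect))
  expect_equal(r2$r_squared, c(1, 1, 1))
  withr::with_seed(12, {
    noisy <- data.frame(freq_rep1 = runif(40), freq_rep2 = runif(40),
                        freq_rep3 = runif(40))
  })
  out <- replicate_r2(noisy)
  # independent textbook computation: R^2 = 1 - SS_res / SS_tot
  formula_r2 <- function(x, y) {
    b <- stats::cov(x, y) / stats::var(x)
    a <- mean(y) - b * mean(x)
    1 - sum((y - a - b * x)^2) / sum((y - mean(y))^2)
  }
  expect_equal(out$r_squared[1], formula_r2(noisy$freq_rep1, noisy$freq_rep2),
               tolerance = 1e-12)
  expect_equal(out$r_squared[3], formula_r2(noisy$freq_rep2, noisy$freq_rep3),
               tolerance = 1e-12)
})

test_that("replicate R^2 is undefined (NA), not 0, for constant frequencies", {
  const <- data.frame(freq_rep1 = rep(0.4, 5), freq_rep2 = runif(5))
  expect_message(out <- replicate_r2(const), "undefined")
  expect_true(is.na(out$r_squared[1]))
})

test_that("venn_compare counts satisfy the benchmark identities", {
  same <- venn_compare(letters[1:5], letters[1:5])
  expect_equal(c(same$overlap, same$new_targets, same$not_detected), c(5, 0, 0))
  disj <- venn_compare(letters[1:3], letters[10:15])
  expect_equal(c(disj$overlap, disj$new_targets, disj$not_detected), c(0, 3, 6))
  # composite divergent-promoter ids match on either component
  comp <- venn_compare(c("g1,g2", "g5"), c("g2", "g9"))
  expect_equal(comp$overlap, 1)
  expect_equal(comp$new_targets, 1)
  expect_equal(comp$not_detected, 1)
  withr::with_seed(14, {
    for (i in 1:20) {
      det <- sample(letters, sample(0:15, 1))
      ref <- sample(letters, sample(0:15, 1))
      v <- venn_compare(det, ref)
      expect_equal(v$overlap + v$new_targets, length(det))
      expect_equal(v$overlap + v$not_detected, length(ref))
    }
  })
})

test_that("snps_per_box agrees with the distance oracle and handles empty input", {
  boxes <- data.frame(contig = "c1", start = c(100L, 400L), end = c(120L, 420L))
  none <- snps_per_box(snp_set(), boxes)
  expect_equal(none$per_box, c(0L, 0L))
  withr::with_seed(15, {
    s <- random_set(200, N = 600)
  })
  spb <- snps_per_box(s, boxes, window = 50)
  oracle <- vapply(seq_len(nrow(boxes)), function(j) {
    sum(vapply(s$pos, function(p) {
      d <- distance_to_box(p, boxes[j, , drop = FALSE])
      as.numeric(d) <= 50
    }, logical(1)))
  }, integer(1))
  expect_equal(spb$per_box, oracle)
})

test_that("simulated experiments yield few SNPs per box, all boxes hit", {
  sim <- default_sim()
  res <- default_profile()
  spb <- snps_per_box(res$attributed, sim$boxes, window = 100)
  expect_true(all(spb$per_box >= 1))
  expect_lte(stats::median(spb$per_box), 12)
})
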