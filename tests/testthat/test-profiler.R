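test_that("intersect_replicates keeps exactly the common identity keys", {
  a <- ss(c("c1:1:A>T", "c1:2:C>T", "c1:3:G>A", "c1:4:C>G", "c1:5:A>C"))
  expect_setequal(snp_key(intersect_replicates(list(a, a, a))), snp_key(a))
  x <- intersect_replicates(list(ss(c("c1:1:A>T", "c1:2:C>T")),
                                 ss(c("c1:2:C>T", "c1:3:G>A")),
                                 ss("c1:2:C>T")))
  expect_identical(snp_key(x), "c1:2:C>T")
  expect_error(intersect_replicates(list(a)), "at least 2")
})

test_that("intersect_replicates carries per-replicate frequencies", {
  r1 <- ss(c("c1:1:C>T", "c1:2:G>A"), freq = 0.2)
  r2 <- ss(c("c1:1:C>T", "c1:2:G>A"), freq = 0.4)
  r3 <- ss(c("c1:1:C>T", "c1:3:G>A"), freq = 0.6)
  x <- intersect_replicates(list(r1, r2, r3))
  expect_identical(snp_key(x), "c1:1:C>T")
  expect_equal(x$freq_rep1, 0.2)
  expect_equal(x$freq_rep2, 0.4)
  expect_equal(x$freq_rep3, 0.6)
  expect_equal(x$frequency, 0.4)
})

test_that("random replicate intersections match the hypergeometric expectation of ~0", {
  # 3 sets of 200 positions drawn without replacement from 1e6: the chance
  # of any 3-way shared position is ~ 200 * (200/1e6)^2 = 8e-6 per draw set
  withr::with_seed(5, {
    n_shared <- vapply(1:100, function(i) {
      sets <- lapply(1:3, function(j) sample.int(1e6, 200))
      length(Reduce(intersect, sets))
    }, integer(1))
  })
  expect_lte(mean(n_shared), 0.02)
})

test_that("build_background is the identity-key union of its three inputs", {
  a <- ss(c("c1:1:A>T", "c1:2:C>T", "c1:3:G>A"))
  b <- ss(c("c1:10:A>T", "c1:11:C>T", "c1:12:G>A", "c1:13:C>G"))
  expect_equal(nrow(build_background(a, b, snp_set())), 7)
  expect_setequal(snp_key(build_background(a, a, a)), snp_key(a))
  withr::with_seed(21, {
    x <- random_set(80); y <- random_set(80); z <- random_set(40)
  })
  u <- build_background(x, y, z)
  oracle <- unique(c(snp_key(x), snp_key(y), snp_key(z)))
  expect_setequal(snp_key(u), oracle)
  expect_equal(nrow(u), length(oracle))
})

test_that("subtract_background removes exactly the background keys", {
  a <- ss(c("c1:1:A>T", "c1:2:C>T"))
  expect_equal(nrow(subtract_background(a, build_background(a, a, a))), 0)
  expect_setequal(snp_key(subtract_background(a, snp_set())), snp_key(a))
  withr::with_seed(22, {
    ori <- random_set(120); neg <- random_set(120)
  })
  res <- subtract_background(ori, neg)
  oracle <- setdiff(snp_key(ori), snp_key(neg))
  expect_setequal(snp_key(res), oracle)
})

test_that("excluded-region filtering matches a per-position interval scan", {
  cfg <- profiler_config(exclusion_regions = data.frame(
    contig = c("c1", "c1"), start = c(100L, 500L), end = c(200L, 510L)))
  inside <- ss("c1:150:C>T")
  expect_equal(nrow(suppressMessages(filter_excluded_regions(inside, cfg))), 0)
  s <- ss(c("c1:99:C>T", "c1:100:G>A", "c1:199:C>G", "c1:200:A>T"))
  kept <- suppressMessages(filter_excluded_regions(s, cfg))
  expect_setequal(snp_key(kept), c("c1:99:C>T", "c1:200:A>T"))
  # empty exclusion list is the identity
  expect_identical(snp_key(filter_excluded_regions(s, profiler_config())),
                   snp_key(s))
  withr::with_seed(23, {
    big <- random_set(1000, N = 1000)
  })
  survivors <- suppressMessages(filter_excluded_regions(big, cfg))
  oracle <- !vapply(big$pos, function(p) {
    any(p >= cfg$exclusion_regions$start & p < cfg$exclusion_regions$end)
  }, logical(1))
  expect_setequal(snp_key(survivors), snp_key(big)[oracle])
})

test_that("cross-TF recurrence filter drops keys seen in more than the allowed number of experiments", {
  shared3 <- "c1:10:C>T"; shared2 <- "c1:20:G>A"; own <- "c1:30:C>T"
  focal <- ss(c(shared3, shared2, own), label = "tfA")
  all_sets <- list(tfA = focal,
                   tfB = ss(c(shared3, shared2)),
                   tfC = ss(shared3))
  kept <- suppressMessages(
    filter_recurrent_cross_tf(focal, all_sets, profiler_config()))
  expect_setequal(snp_key(kept), c(shared2, own))  # >2 removed, ==2 kept
  # excluding the focal TF from the tally keeps the 3-way key (now count 2)
  cfg2 <- profiler_config(recurrence_includes_focal = FALSE)
  kept2 <- filter_recurrent_cross_tf(focal, all_sets, cfg2, focal = "tfA")
  expect_setequal(snp_key(kept2), c(shared3, shared2, own))
})

test_that("recurrence filter agrees with a brute-force occurrence counter", {
  withr::with_seed(31, {
    sets <- lapply(1:5, function(i) random_set(60, N = 300, label = paste0("tf", i)))
  })
  names(sets) <- paste0("tf", 1:5)
  focal <- sets[["tf1"]]
  kept <- suppressMessages(
    filter_recurrent_cross_tf(focal, sets, profiler_config()))
  counts <- vapply(snp_key(focal), function(k) {
    sum(vapply(sets, function(s) k %in% snp_key(s), logical(1)))
  }, integer(1))
  expect_setequal(snp_key(kept), snp_key(focal)[counts <= 2])
})

test_that("region classification follows gene geometry", {
  gm <- tiny_genome()
  at <- function(p) {
    r <- substr(gm$contigs[["c1"]], p + 1, p + 1)
    snp_set("c1", p, r, if (r == "T") "A" else "T")
  }
  divergent <- classify_region(at(170L), gm)    # between g1(-) and g2(+)
  expect_equal(divergent$region_class, "promoter_like")
  expect_setequal(strsplit(divergent$upstream_of, ",")[[1]], c("g1", "g2"))
  in_cds <- classify_region(at(250L), gm)       # inside g2
  expect_equal(in_cds$region_class, "nonpromoter")
  expect_equal(in_cds$within_gene, "g2")
  convergent <- classify_region(at(320L), gm)   # between g2(+) and g3(-) 3' ends
  expect_equal(convergent$region_class, "nonpromoter")
  expect_true(is.na(convergent$within_gene))
  divergent2 <- classify_region(at(450L), gm)   # 5' of g3(-) and g4(+)
  expect_equal(divergent2$region_class, "promoter_like")
  expect_setequal(strsplit(divergent2$upstream_of, ",")[[1]], c("g3", "g4"))
  left_edge <- classify_region(at(10L), gm)     # right gene g1 is '-': not 5'
  expect_equal(left_edge$region_class, "nonpromoter")
})

test_that("every SNP receives exactly one region class", {
  gm <- tiny_genome()
  pos <- 0:599
  ref <- substring(gm$contigs[["c1"]], pos + 1, pos + 1)
  s <- snp_set("c1", pos, ref, ifelse(ref == "T", "A", "T"))
  cl <- classify_region(s, gm)
  expect_true(all(cl$region_class %in% c("promoter_like", "nonpromoter")))
  # promoter-like implies intergenic and upstream of at least one gene
  pl <- cl[cl$region_class == "promoter_like", ]
  expect_true(all(is.na(pl$within_gene)))
  expect_true(all(!is.na(pl$upstream_of)))
})

test_that("a contig without genes warns and classes everything nonpromoter", {
  gm <- genome_model(c(bare = strrep("ACGT", 50)))
  s <- snp_set("bare", 10L, "G", "A")
  expect_warning(cl <- classify_region(s, gm), "without genes")
  expect_equal(cl$region_class, "nonpromoter")
})

test_that("background subtraction and region exclusion commute", {
  cfg <- profiler_config(exclusion_regions = data.frame(
    contig = "c1", start = 200L, end = 400L))
  withr::with_seed(41, {
    ori <- random_set(200, N = 1000)
    neg <- random_set(200, N = 1000)
  })
  a <- suppressMessages(filter_excluded_regions(subtract_background(ori, neg), cfg))
  b <- subtract_background(suppressMessages(filter_excluded_regions(ori, cfg)), neg)
  expect_setequal(snp_key(a), snp_key(b))
})

test_that("run_profile is contractive and recovers planted boxes", {
  res <- default_profile()
  counts <- res$stage_counts[-1]  # after the replicate stage
  expect_true(all(diff(counts) <= 0))
  expect_true(all(snp_key(res$snp_tf) %in% snp_key(res$snp_ori)))
  # attributed output carries flanks and classes for every record
  a <- res$attributed
  expect_true(all(c("region_class", "flank_seq") %in% names(a)))
  expect_true(all(nchar(a$flank_seq) >= 101))
})

test_that("degenerate profiling inputs give empty, not broken, output", {
  gm <- tiny_genome()
  empty <- snp_set(label = "e")
  bg <- list(pjn_common = empty, aid_common = empty, wt = empty)
  res <- suppressMessages(run_profile(list(empty, empty, empty), bg, gm))
  expect_equal(nrow(res$attributed), 0)
  # replicates identical to the background annihilate
  s <- ss(c("c1:100:C>T", "c1:300:G>A"))
  bg2 <- list(pjn_common = s, aid_common = empty, wt = empty)
  res2 <- suppressMessages(run_profile(list(s, s, s), bg2, gm))
  expect_equal(nrow(res2$attributed), 0)
})
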