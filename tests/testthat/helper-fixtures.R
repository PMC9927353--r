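# Shared fixtures, built in code at test time.

# snp_set from compact key strings "contig:pos:REF>ALT"
ss <- function(keys, label = "s", freq = 0.3, depth = 100L) {
  if (length(keys) == 0) return(snp_set(label = label))
  parts <- strsplit(keys, "[:>]")
  alt_d <- as.integer(round(rep_len(freq, length(keys)) * depth))
  snp_set(contig = vapply(parts, `[`, "", 1),
          pos = as.integer(vapply(parts, `[`, "", 2)),
          ref = vapply(parts, `[`, "", 3),
          alt = vapply(parts, `[`, "", 4),
          ref_depth = depth - alt_d, alt_depth = alt_d, label = label)
}

# random snp_set of n distinct positions on [0, N)
random_set <- function(n, N = 1e4, label = "r", contig = "c1") {
  pos <- sample.int(N, n) - 1L
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                "", USE.NAMES = FALSE)
  snp_set(contig, pos, ref, alt, ref_depth = 70L, alt_depth = 30L, label = label)
}

# hand-laid genome: 600 bp, four genes covering the canonical promoter
# geometries --
#   g1(-) [50,150)   g2(+) [200,300) : divergent pair across [150,200)
#   g2(+) ends 300,  g3(-) [350,430) : convergent pair across [300,350)
#   g3(-) starts 350, g4(+) [480,560): gap [430,480) upstream of g4
# edge intergenic [0,50) is 5' of nothing on the left, g1(-) on right is
# not upstream-facing; [560,600) right edge is downstream of g4(+).
tiny_genome <- function() {
  withr::with_seed(42, {
    seq <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                 collapse = "")
  })
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    contig = "c1",
    start = c(50L, 200L, 350L, 480L),
    end = c(150L, 300L, 430L, 560L),
    strand = c("-", "+", "-", "+"),
    stringsAsFactors = FALSE)
  genome_model(c(c1 = seq), genes)
}

# one default simulated experiment, shared across test files
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_experiment(params = sim_params(seed = 7L))
    cache
  }
})

default_profile <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- default_sim()
      bg <- list(
        pjn_common = intersect_replicates(sim$pjn_replicates, label = "pjn"),
        aid_common = intersect_replicates(sim$aid_replicates, label = "aid"),
        wt = sim$wt_snps)
      cache <<- suppressMessages(run_profile(sim$tf_replicates, bg, sim$genome))
    }
    cache
  }
})
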