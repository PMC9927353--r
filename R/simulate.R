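#' Simulation parameters
#'
#' Parameters of the synthetic deaminase-mutagenesis experiment. Defaults
#' describe a serial-passage protocol of two 12-h rounds with 5x dilution
#' (about 24 generations), 100x sequencing depth, and a stochastic
#' background calibrated so that the per-experiment per-bp mutation
#' probability is about 1e-4.
#'
#' @param mu0 per-generation deamination probability of a fully occupied,
#'   fully accessible site at distance 0 from the box (default 0.03).
#' @param window_scale exponential decay length (bp) of editability with
#'   distance from the box (default 10).
#' @param window_max hard distance cutoff in bp beyond which no directed
#'   editing occurs (default 100).
#' @param p_bg per-generation per-bp stochastic mutation probability
#'   (default 4.2e-6; compounded over `generations` this gives ~1e-4 per
#'   experiment).
#' @param generations number of generations under induction (default 24).
#' @param s selection coefficient against mutant cells (default 0,
#'   neutral).
#' @param depth mean sequencing depth per site (default 100).
#' @param detect_min_frac,detect_min_alt variant-caller emulation: a site
#'   is reported only when the alternate fraction and alternate read count
#'   reach these thresholds (defaults 0.1 and 3).
#' @param wrc_hotspot if TRUE (default), sites in the deaminase's
#'   preferred WRC sequence context (GYW on the minus strand) are edited at
#'   the full rate and all other C/G sites at `cold_factor` times it.
#' @param cold_factor editability multiplier for non-hotspot sites
#'   (default 0.05).
#' @param seed base RNG seed of the experiment (replicates derive their own
#'   streams from it).
#' @return object of class `sim_params`.
#' @export
sim_params <- function(mu0 = 0.03, window_scale = 10, window_max = 100L,
                       p_bg = 4.2e-6, generations = 24L, s = 0,
                       depth = 100L, detect_min_frac = 0.1,
                       detect_min_alt = 3L, wrc_hotspot = TRUE,
                       cold_factor = 0.05, seed = 1L) {
  stopifnot(mu0 >= 0, mu0 <= 1, window_scale > 0, window_max >= 0,
            p_bg >= 0, p_bg <= 1, generations >= 1, s >= 0, s < 1,
            depth >= 1, detect_min_frac >= 0, detect_min_frac <= 1,
            detect_min_alt >= 0, cold_factor >= 0, cold_factor <= 1)
  structure(list(mu0 = mu0, window_scale = window_scale,
                 window_max = as.integer(window_max), p_bg = p_bg,
                 generations = as.integer(generations), s = s,
                 depth = as.integer(depth), detect_min_frac = detect_min_frac,
                 detect_min_alt = as.integer(detect_min_alt),
                 wrc_hotspot = isTRUE(wrc_hotspot), cold_factor = cold_factor,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Generate a random annotated genome
#'
#' Draws a uniform-composition A/C/G/T contig and packs `n_genes`
#' non-overlapping gene bodies onto it with random strands, separated by
#' random intergenic gaps of at least `min_intergenic` bp. Deterministic
#' under `seed`.
#'
#' @param length contig length in bp.
#' @param n_genes number of genes (0 gives one all-intergenic contig).
#' @param seed RNG seed.
#' @param gene_length_mean,gene_length_sd normal parameters of gene body
#'   lengths (bp), truncated below at 90.
#' @param min_intergenic minimum gap between gene bodies and at contig ends
#'   (bp).
#' @param contig contig id.
#' @return A [genome_model].
#' @export
generate_genome <- function(length, n_genes, seed = 1L,
                            gene_length_mean = 600, gene_length_sd = 120,
                            min_intergenic = 80L, contig = "chr1") {
  length <- as.integer(length); n_genes <- as.integer(n_genes)
  stopifnot(length > 0, n_genes >= 0)
  withr::with_seed(seed, {
    seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                 collapse = "")
    if (n_genes == 0) {
      return(genome_model(stats::setNames(seq, contig)))
    }
    glen <- pmax(90L, as.integer(round(stats::rnorm(n_genes, gene_length_mean,
                                                    gene_length_sd))))
    slack <- length - sum(glen) - (n_genes + 1L) * min_intergenic
    if (slack < 0)
      stop("infeasible packing: ", n_genes, " genes of total ", sum(glen),
           " bp (+ gaps) do not fit in ", length, " bp")
    gaps <- min_intergenic + as.vector(stats::rmultinom(1, slack,
                                                        rep(1, n_genes + 1L)))
    starts <- cumsum(gaps[seq_len(n_genes)] +
                       c(0L, glen[seq_len(n_genes - 1L)]))
    genes <- data.frame(
      gene_id = sprintf("gene_%03d", seq_len(n_genes)),
      contig = contig, start = starts, end = starts + glen,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      stringsAsFactors = FALSE)
    genome_model(stats::setNames(seq, contig), genes)
  })
}

#' Plant TF-binding boxes into promoter-like intergenic regions
#'
#' Writes the consensus box sequence (reverse-complemented on `-`) into
#' randomly chosen promoter-like intergenic regions and records the
#' ground-truth box table with per-box occupancies (the probability that
#' the box is TF-bound, `[TF]/([TF]+Kd)` under first-order binding).
#'
#' @param genome a [genome_model].
#' @param n_boxes number of boxes to plant (at most one per intergenic
#'   region).
#' @param consensus box consensus sequence (default a 20-bp dyad).
#' @param occupancy scalar, vector, or `function(n)` drawing occupancies in
#'   `[0, 1]`; default `function(n) runif(n, 0.5, 1)`.
#' @param seed RNG seed.
#' @param margin minimum distance (bp) between a box and the ends of its
#'   intergenic region.
#' @return list with `genome` (sequence updated in place) and `boxes`
#'   (data frame: contig, start, end, strand, occupancy, promoter_gene).
#' @export
plant_boxes <- function(genome, n_boxes, consensus = "ACCTGCCAGATCTGGCAGGT",
                        occupancy = function(n) stats::runif(n, 0.5, 1),
                        seed = 1L, margin = 10L) {
  stopifnot(inherits(genome, "genome_model"), n_boxes >= 1)
  consensus <- toupper(consensus)
  len <- nchar(consensus)
  ig <- genome$intergenic
  promoter_like <- (!is.na(ig$right_strand) & ig$right_strand == "+") |
    (!is.na(ig$left_strand) & ig$left_strand == "-")
  wide <- (ig$end - ig$start) >= len + 2L * margin
  cand <- which(promoter_like & wide)
  if (length(cand) < n_boxes)
    stop("insufficient promoter-like intergenic space: ", length(cand),
         " candidate region(s) for ", n_boxes, " boxes")
  withr::with_seed(seed, {
    pick <- sample(cand, n_boxes)
    occ <- if (is.function(occupancy)) occupancy(n_boxes)
           else rep_len(occupancy, n_boxes)
    stopifnot(all(occ >= 0 & occ <= 1))
    strand <- sample(c("+", "-"), n_boxes, replace = TRUE)
    start <- integer(n_boxes)
    contigs <- genome$contigs
    promoter_gene <- character(n_boxes)
    for (b in seq_len(n_boxes)) {
      r <- pick[b]
      lo <- ig$start[r] + margin
      hi <- ig$end[r] - margin - len
      start[b] <- if (hi > lo) lo + sample.int(hi - lo + 1L, 1L) - 1L else lo
      ins <- if (strand[b] == "+") consensus else revcomp(consensus)
      ct <- ig$contig[r]
      substr(contigs[[ct]], start[b] + 1L, start[b] + len) <- ins
      ups <- c(if (!is.na(ig$right_strand[r]) && ig$right_strand[r] == "+")
                 ig$right_gene[r],
               if (!is.na(ig$left_strand[r]) && ig$left_strand[r] == "-")
                 ig$left_gene[r])
      promoter_gene[b] <- paste(ups, collapse = ",")
    }
    boxes <- data.frame(contig = ig$contig[pick], start = start,
                        end = start + len, strand = strand, occupancy = occ,
                        promoter_gene = promoter_gene,
                        stringsAsFactors = FALSE)
    boxes <- boxes[order(boxes$contig, boxes$start), , drop = FALSE]
    rownames(boxes) <- NULL
    list(genome = genome_model(contigs, genome$genes), boxes = boxes)
  })
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Per-generation directed editing probability at a site
#'
#' `mu0 * occupancy * exp(-d / window_scale)` where `d` is the distance to
#' the box, clipped at 0 inside the box; 0 beyond `window_max` and for
#' bases that are not C or G (only cytosines -- on either strand -- can be
#' deaminated).
#'
#' @param box one-row box table (needs `start`, `end`, `occupancy`).
#' @param pos 0-based position(s) on the box's contig.
#' @param params a [sim_params].
#' @param base reference base at each `pos` ("C"/"G" editable).
#' @return numeric vector of per-generation editing probabilities.
#' @export
site_edit_prob <- function(box, pos, params, base) {
  d <- vapply(pos, signed_box_distance, numeric(1),
              start = box$start[1], end = box$end[1])
  d_eff <- pmax(d, 0)
  p <- params$mu0 * box$occupancy[1] * exp(-d_eff / params$window_scale)
  p[d > params$window_max] <- 0
  p[!(base %in% c("C", "G"))] <- 0
  p
}

#' Population allele frequency after serial-passage generations
#'
#' Deterministic recursion over `G` generations: each generation converts
#' unmutated cells with probability `mu` (`f <- f + (1 - f) * mu`), then
#' selection reweights mutants by `1 - s`
#' (`f <- f * (1 - s) / (1 - f * s)`). With `s = 0` the closed form is
#' `1 - (1 - mu)^G`.
#'
#' @param mu per-generation per-site conversion probability (vectorised).
#' @param G number of generations.
#' @param s selection coefficient against the mutant (0 = neutral).
#' @return population frequency in `[0, 1]`.
#' @examples
#' freq_after_generations(0.1, 24)      # 1 - 0.9^24
#' @export
freq_after_generations <- function(mu, G, s = 0) {
  stopifnot(all(mu >= 0 & mu <= 1), G >= 1, s >= 0, s < 1)
  f <- numeric(length(mu))
  for (g in seq_len(G)) {
    f <- f + (1 - f) * mu
    f <- f * (1 - s) / (1 - f * s)
  }
  f
}

# WRC/GYW hotspot context factor for directed deamination.
# For a reference-strand C the deaminase prefers W-R-C (W = A/T, R = A/G)
# ending at the site; for a reference G (C on the minus strand) the
# mirror-image G-Y-W starting at the site. Non-hotspot sites edit at
# cold_factor times the full rate.
context_factor <- function(seq, pos, base, params) {
  if (!params$wrc_hotspot) return(rep(1, length(pos)))
  up2 <- substring(seq, pos - 1L, pos - 1L)  # pos is 0-based; char i = pos+1
  up1 <- substring(seq, pos, pos)
  dn1 <- substring(seq, pos + 2L, pos + 2L)
  dn2 <- substring(seq, pos + 3L, pos + 3L)
  hot_c <- base == "C" & up2 %in% c("A", "T") & up1 %in% c("A", "G")
  hot_g <- base == "G" & dn1 %in% c("C", "T") & dn2 %in% c("A", "T")
  ifelse(hot_c | hot_g, 1, params$cold_factor)
}

#' Simulate one sequenced replicate of a deamination experiment
#'
#' Directed mutations: every C/G within `window_max` of a box converts in
#' the population at the frequency implied by its per-generation editing
#' probability ([site_edit_prob], times the WRC-context factor when
#' enabled) compounded over the generations; a reference-strand C yields a
#' C>T record and a G (edited C on the minus strand) a G>A record. Sites
#' covered by several box windows combine their per-generation
#' probabilities independently. Background mutations strike each position
#' with the per-experiment probability `1 - (1 - p_bg)^G`, change the base
#' to a random different one, and reach the neutral-drift frequency
#' `2^-g` of a lesion arising in one cell at a uniformly drawn generation
#' `g`. Sequencing draws `alt_depth ~ Binomial(depth, f)`; a record is
#' emitted only if the alternate fraction and count pass the caller
#' thresholds. Deterministic given `(params$seed, replicate_seed)`.
#'
#' @param genome a [genome_model] (typically after [plant_boxes]).
#' @param boxes ground-truth box table (may have zero rows).
#' @param params a [sim_params].
#' @param replicate_seed small integer distinguishing replicates.
#' @param label label of the returned set.
#' @return A [snp_set] with extra columns `true_frequency` and `directed`.
#' @export
simulate_replicate <- function(genome, boxes, params,
                               replicate_seed = 1L,
                               label = paste0("replicate_", replicate_seed)) {
  stopifnot(inherits(genome, "genome_model"), inherits(params, "sim_params"))
  seed <- as.integer((as.numeric(params$seed) * 1009 + replicate_seed) %%
                       2147483647)
  withr::with_seed(seed, {
    dir_df <- directed_site_table(genome, boxes, params)
    rows <- list(dir_df)
    # background: compounded per-experiment probability, positions sampled
    # by count (equivalent to independent Bernoulli per bp, fast)
    p_exp <- 1 - (1 - params$p_bg)^params$generations
    for (ct in names(genome$contigs)) {
      clen <- nchar(genome$contigs[[ct]])
      n_bg <- stats::rbinom(1L, clen, p_exp)
      if (n_bg == 0L) next
      pos <- sample.int(clen, n_bg) - 1L
      ref <- substring(genome$contigs[[ct]], pos + 1L, pos + 1L)
      alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                    character(1), USE.NAMES = FALSE)
      g_arise <- sample.int(params$generations, n_bg, replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        contig = ct, pos = pos, ref = ref, alt = alt,
        true_frequency = 2^(-g_arise), directed = FALSE,
        stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, rows)
    if (nrow(sites) > 0) {
      # a directed lesion at a position trumps a coinciding background one
      sites <- sites[order(!sites$directed), , drop = FALSE]
      sites <- sites[!duplicated(paste(sites$contig, sites$pos)), , drop = FALSE]
      ad <- stats::rbinom(nrow(sites), params$depth, sites$true_frequency)
      keep <- ad >= params$detect_min_alt &
        (ad / params$depth) >= params$detect_min_frac
      sites <- sites[keep, , drop = FALSE]
      ad <- ad[keep]
    } else {
      ad <- integer()
    }
    out <- data.frame(contig = sites$contig, pos = sites$pos,
                      ref = sites$ref, alt = sites$alt,
                      ref_depth = params$depth - ad, alt_depth = ad,
                      stringsAsFactors = FALSE)
    out$frequency <- snp_frequency(out$ref_depth, out$alt_depth)
    out$true_frequency <- sites$true_frequency
    out$directed <- sites$directed
    out <- out[order(out$contig, out$pos), , drop = FALSE]
    as_snp_set(out, label = label)
  })
}

# Deterministic table of directed sites and their population frequencies.
# Per-site per-generation probabilities from overlapping box windows
# combine as 1 - prod(1 - mu_b).
directed_site_table <- function(genome, boxes, params) {
  empty <- data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), true_frequency = numeric(),
                      directed = logical(), stringsAsFactors = FALSE)
  if (is.null(boxes) || nrow(boxes) == 0) return(empty)
  per_box <- lapply(seq_len(nrow(boxes)), function(b) {
    ct <- boxes$contig[b]
    clen <- nchar(genome$contigs[[ct]])
    w <- max(0L, boxes$start[b] - params$window_max):
      min(clen - 1L, boxes$end[b] - 1L + params$window_max)
    base <- substring(genome$contigs[[ct]], w + 1L, w + 1L)
    mu <- site_edit_prob(boxes[b, , drop = FALSE], w, params, base) *
      context_factor(genome$contigs[[ct]], w, base, params)
    keep <- mu > 0
    data.frame(contig = rep(ct, sum(keep)), pos = w[keep], ref = base[keep],
               mu = mu[keep], stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, per_box)
  if (nrow(sites) == 0) return(empty)
  key <- paste(sites$contig, sites$pos)
  mu_tot <- 1 - vapply(split(sites$mu, key), function(m) prod(1 - m), numeric(1))
  first <- !duplicated(key)
  sites <- sites[first, , drop = FALSE]
  sites$mu <- as.numeric(mu_tot[paste(sites$contig, sites$pos)])
  data.frame(contig = sites$contig, pos = sites$pos, ref = sites$ref,
             alt = ifelse(sites$ref == "C", "T", "A"),
             true_frequency = freq_after_generations(sites$mu,
                                                     params$generations,
                                                     params$s),
             directed = TRUE, stringsAsFactors = FALSE)
}

#' Simulate a complete profiling experiment
#'
#' Generates a genome, plants boxes, and simulates sequenced replicate sets
#' for the TF-fusion strain, the deaminase-only control (same boxes with
#' occupancy forced to 0, so only stochastic background remains) and the
#' void-vector control (stochastic background only). The returned pieces
#' plug directly into [run_profile].
#'
#' @param genome_length,n_genes,n_boxes scenario dimensions (defaults
#'   1e5 bp, 40 genes, 10 boxes).
#' @param n_replicates parallel experiments per strain (default 3).
#' @param params a [sim_params]; `params$seed` drives every stage.
#' @param consensus,occupancy passed to [plant_boxes].
#' @return list with `genome`, `boxes`, `params`, `tf_replicates`,
#'   `aid_replicates`, `pjn_replicates` (each a list of [snp_set]s) and
#'   `wt_snps` (empty stock set).
#' @export
simulate_experiment <- function(genome_length = 1e5, n_genes = 40,
                                n_boxes = 10, n_replicates = 3,
                                params = sim_params(),
                                consensus = "ACCTGCCAGATCTGGCAGGT",
                                occupancy = function(n) stats::runif(n, 0.5, 1)) {
  genome0 <- generate_genome(genome_length, n_genes, seed = params$seed)
  planted <- if (n_boxes == 0) {
    list(genome = genome0,
         boxes = data.frame(contig = character(), start = integer(),
                            end = integer(), strand = character(),
                            occupancy = numeric(), promoter_gene = character(),
                            stringsAsFactors = FALSE))
  } else {
    plant_boxes(genome0, n_boxes, consensus = consensus,
                occupancy = occupancy, seed = params$seed + 1L)
  }
  boxes0 <- planted$boxes
  boxes0$occupancy <- numeric(nrow(boxes0))
  sim_set <- function(boxes, offset, prefix) {
    lapply(seq_len(n_replicates), function(r) {
      simulate_replicate(planted$genome, boxes, params,
                         replicate_seed = offset + r,
                         label = paste0(prefix, "_rep", r))
    })
  }
  list(genome = planted$genome, boxes = planted$boxes, params = params,
       tf_replicates = sim_set(planted$boxes, 0L, "tf"),
       aid_replicates = sim_set(boxes0, 100L, "aid_only"),
       pjn_replicates = sim_set(boxes0[0, , drop = FALSE], 200L, "void_vector"),
       wt_snps = snp_set(label = "wt_stock"))
}
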