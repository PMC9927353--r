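#' Profiling configuration
#'
#' Collects the tunable screening rules of the SNP-profiling pipeline.
#'
#' @param n_replicates number of parallel experiments whose consensus
#'   defines a sample's SNP set (default 3).
#' @param exclusion_regions data frame (`contig`, `start`, `end`, 0-based
#'   half-open) of regions whose SNPs are discarded, e.g. a hypermutable
#'   prophage span; default empty.
#' @param cross_tf_max_occurrences a SNP seen in more than this many
#'   distinct TF experiments is discarded as weak-nonspecific binding
#'   (default 2, i.e. "more than twice" removes it).
#' @param recurrence_includes_focal whether the focal TF's own set counts
#'   toward the occurrence tally (default TRUE).
#' @param min_frequency optional frequency gate applied to replicate sets
#'   before intersection; default 0 (trust the variant caller).
#' @return object of class `profiler_config`.
#' @export
profiler_config <- function(n_replicates = 3L,
                            exclusion_regions = NULL,
                            cross_tf_max_occurrences = 2L,
                            recurrence_includes_focal = TRUE,
                            min_frequency = 0) {
  if (is.null(exclusion_regions)) {
    exclusion_regions <- data.frame(contig = character(), start = integer(),
                                    end = integer(), stringsAsFactors = FALSE)
  }
  stopifnot(n_replicates >= 2L, cross_tf_max_occurrences >= 1L,
            min_frequency >= 0, min_frequency <= 1,
            all(c("contig", "start", "end") %in% names(exclusion_regions)))
  structure(list(n_replicates = as.integer(n_replicates),
                 exclusion_regions = exclusion_regions,
                 cross_tf_max_occurrences = as.integer(cross_tf_max_occurrences),
                 recurrence_includes_focal = isTRUE(recurrence_includes_focal),
                 min_frequency = min_frequency),
            class = "profiler_config")
}

#' Replicate-consensus SNPs
#'
#' Keeps the records whose identity key appears in every input replicate,
#' the first screen against stochastic background mutation: a background
#' SNP recurs in all k replicates with probability ~p0^k. Retained records
#' carry each replicate's frequency in columns `freq_rep1..k` (NA where
#' unknown), with `frequency` set to their mean, for downstream
#' reproducibility statistics.
#'
#' @param sets list of >= 2 [snp_set]s (the parallel experiments).
#' @param label label for the consensus set.
#' @return A [snp_set] with per-replicate frequency columns.
#' @export
intersect_replicates <- function(sets, label = "consensus") {
  if (!is.list(sets) || length(sets) < 2)
    stop("need at least 2 replicate snp_sets")
  keys <- lapply(sets, snp_key)
  common <- Reduce(intersect, keys)
  base <- snp_subset(sets[[1]], match(common, keys[[1]]), label = label)
  fq <- matrix(NA_real_, nrow = length(common), ncol = length(sets),
               dimnames = list(NULL, paste0("freq_rep", seq_along(sets))))
  for (j in seq_along(sets)) {
    fq[, j] <- sets[[j]]$frequency[match(common, keys[[j]])]
  }
  out <- cbind(as.data.frame(base), as.data.frame(fq))
  out$frequency <- rowMeans(fq, na.rm = TRUE)
  out$frequency[is.nan(out$frequency)] <- NA_real_
  as_snp_set(out, label = label)
}

#' Union of background SNP sets
#'
#' The background set pools every SNP that arises without TF guidance:
#' the replicate-consensus of the void-vector strain, the consensus of the
#' deaminase-only strain, and SNPs already present in the wild-type stock.
#'
#' @param pjn_common,aid_common replicate-consensus [snp_set]s of the
#'   void-vector and deaminase-only controls.
#' @param wt_snps [snp_set] of pre-existing wild-type stock SNPs (may be
#'   empty).
#' @return A [snp_set] labelled `"SNP^negative"`; depths are taken from the
#'   first set contributing each key.
#' @export
build_background <- function(pjn_common, aid_common, wt_snps = snp_set()) {
  sets <- list(pjn_common, aid_common, wt_snps)
  df <- do.call(rbind, lapply(sets, function(s) {
    as.data.frame(s)[, c("contig", "pos", "ref", "alt",
                         "ref_depth", "alt_depth", "frequency")]
  }))
  df <- df[!duplicated(snp_key(df)), , drop = FALSE]
  as_snp_set(df, label = "SNP^negative")
}

#' Background subtraction
#'
#' Removes from the TF sample's consensus set every record whose identity
#' key occurs in the background set, leaving the TF-guided SNPs.
#'
#' @param snp_ori replicate-consensus [snp_set] of the TF sample.
#' @param snp_negative background [snp_set] (see [build_background]).
#' @param label label of the result (default `"SNP^TF"`).
#' @return A [snp_set].
#' @export
subtract_background <- function(snp_ori, snp_negative, label = "SNP^TF") {
  keep <- !(snp_key(snp_ori) %in% snp_key(snp_negative))
  snp_subset(snp_ori, keep, label = label)
}

#' Drop SNPs inside excluded regions
#'
#' Discards records falling in configured exclusion intervals -- used for
#' hypermutable loci such as a prophage region that mutates at high
#' frequency regardless of TF binding.
#'
#' @param snps a [snp_set].
#' @param cfg a [profiler_config] (its `exclusion_regions` are used), or a
#'   data frame of intervals directly.
#' @return The filtered [snp_set]; the number of dropped records is
#'   reported via `message()`.
#' @export
filter_excluded_regions <- function(snps, cfg) {
  regions <- if (inherits(cfg, "profiler_config")) cfg$exclusion_regions else cfg
  if (nrow(regions) == 0 || nrow(snps) == 0) return(snps)
  q <- GenomicRanges::GRanges(snps$contig, IRanges::IRanges(snps$pos + 1L, width = 1L))
  s <- GenomicRanges::GRanges(regions$contig,
                              IRanges::IRanges(regions$start + 1L, regions$end))
  hit <- IRanges::overlapsAny(q, s)
  if (any(hit)) message(sum(hit), " SNP(s) dropped in excluded region(s)")
  snp_subset(snps, !hit)
}

#' Drop SNPs recurring across many TF experiments
#'
#' A SNP whose identity key shows up in more than
#' `cross_tf_max_occurrences` distinct TF experiments is treated as
#' weak-nonspecific binding (the odds of one promoter being a true target
#' of three different TFs are low) and removed.
#'
#' @param snps the focal TF's [snp_set].
#' @param all_tf_sets named list of per-TF [snp_set]s from the whole
#'   experiment series. Whether the focal TF's own set counts is controlled
#'   by `cfg$recurrence_includes_focal`; when it is excluded, supply
#'   `focal` so its set can be identified.
#' @param cfg a [profiler_config].
#' @param focal name of the focal TF within `all_tf_sets` (only needed when
#'   `recurrence_includes_focal` is FALSE).
#' @return The filtered [snp_set]; removed keys are reported via `message()`.
#' @export
filter_recurrent_cross_tf <- function(snps, all_tf_sets, cfg = profiler_config(),
                                      focal = NULL) {
  if (length(all_tf_sets) == 0 || nrow(snps) == 0) return(snps)
  sets <- all_tf_sets
  if (!cfg$recurrence_includes_focal && !is.null(focal)) {
    sets <- sets[setdiff(names(sets), focal)]
  }
  occ_keys <- unlist(lapply(sets, function(s) unique(snp_key(s))), use.names = FALSE)
  counts <- table(occ_keys)
  keys <- snp_key(snps)
  n_occ <- as.integer(counts[keys])
  n_occ[is.na(n_occ)] <- 0L
  drop <- n_occ > cfg$cross_tf_max_occurrences
  if (any(drop)) {
    message(sum(drop), " SNP(s) removed as recurrent across >",
            cfg$cross_tf_max_occurrences, " TF experiments: ",
            paste(utils::head(keys[drop], 5), collapse = ", "),
            if (sum(drop) > 5) " ..." else "")
  }
  snp_subset(snps, !drop)
}

#' Classify SNPs into promoter-like and non-promoter regions
#'
#' A SNP inside any gene body is `nonpromoter` (with `within_gene` set).
#' An intergenic SNP is `promoter_like` when its intergenic region lies 5'
#' of at least one flanking gene: the right flanking gene on strand `+`
#' and/or the left flanking gene on strand `-` (both, for a divergent gene
#' pair). An intergenic region between two convergent 3' ends is
#' `nonpromoter`. The promoter-like class has no maximum upstream distance:
#' the definition is purely positional.
#'
#' @param snps a [snp_set] (or data frame with contig/pos).
#' @param genome a [genome_model].
#' @return `snps` with added columns `region_class`
#'   (`promoter_like`/`nonpromoter`), `within_gene` (gene id or NA) and
#'   `upstream_of` (comma-separated gene ids, NA when none).
#' @export
classify_region <- function(snps, genome) {
  stopifnot(inherits(genome, "genome_model"))
  n <- nrow(snps)
  region_class <- rep("nonpromoter", n)
  within_gene <- rep(NA_character_, n)
  upstream_of <- rep(NA_character_, n)
  if (n > 0) {
    g <- genome$genes
    no_genes <- setdiff(unique(snps$contig), unique(g$contig))
    if (length(no_genes) > 0)
      warning("contig(s) without genes, all SNPs there classed nonpromoter: ",
              paste(no_genes, collapse = ", "))
    q <- GenomicRanges::GRanges(snps$contig, IRanges::IRanges(snps$pos + 1L, width = 1L))
    if (nrow(g) > 0) {
      gr <- GenomicRanges::GRanges(g$contig, IRanges::IRanges(g$start + 1L, g$end))
      hits <- GenomicRanges::findOverlaps(q, gr, select = "first")
      inside <- !is.na(hits)
      within_gene[inside] <- g$gene_id[hits[inside]]
    } else {
      inside <- rep(FALSE, n)
    }
    ig <- genome$intergenic
    if (nrow(ig) > 0 && any(!inside)) {
      igr <- GenomicRanges::GRanges(ig$contig, IRanges::IRanges(ig$start + 1L, ig$end))
      ih <- GenomicRanges::findOverlaps(q[!inside], igr, select = "first")
      idx <- which(!inside)
      for (k in seq_along(idx)) {
        r <- ih[k]
        if (is.na(r)) next
        ups <- character()
        if (!is.na(ig$right_gene[r]) && ig$right_strand[r] == "+")
          ups <- c(ups, ig$right_gene[r])
        if (!is.na(ig$left_gene[r]) && ig$left_strand[r] == "-")
          ups <- c(ups, ig$left_gene[r])
        if (length(ups) > 0) {
          region_class[idx[k]] <- "promoter_like"
          upstream_of[idx[k]] <- paste(unique(ups), collapse = ",")
        }
      }
    }
  }
  out <- as.data.frame(snps)
  out$region_class <- region_class
  out$within_gene <- within_gene
  out$upstream_of <- upstream_of
  if (inherits(snps, "snp_set")) out <- as_snp_set(out, label = snp_label(snps))
  out
}

#' Run the full SNP-profiling pipeline
#'
#' Applies, in order: wild-type stock pre-exclusion from every replicate,
#' optional frequency gate, replicate intersection (SNP^ori), background
#' subtraction (SNP^TF), excluded-region filtering, cross-TF recurrence
#' filtering, region classification, and flank extraction. Every stage is
#' contractive on identity keys. An empty final set is a valid result.
#'
#' @param tf_replicates list of replicate [snp_set]s for the focal TF.
#' @param background_sets list with elements `pjn_common`, `aid_common`
#'   (replicate-consensus control sets) and optionally `wt` (wild-type
#'   stock SNPs).
#' @param genome a [genome_model].
#' @param cfg a [profiler_config].
#' @param all_tf_sets optional named list of per-TF SNP^TF sets for the
#'   recurrence filter (skipped when NULL).
#' @param focal focal TF name within `all_tf_sets`.
#' @param flank flank width in bp for sequence retrieval (default 100).
#' @return list with `attributed` (classified [snp_set] with flanks),
#'   `snp_ori`, `snp_negative`, `snp_tf`, and `stage_counts` (named integer
#'   vector of surviving records after each stage).
#' @export
run_profile <- function(tf_replicates, background_sets, genome,
                        cfg = profiler_config(), all_tf_sets = NULL,
                        focal = NULL, flank = 100L) {
  stopifnot(is.list(tf_replicates), inherits(genome, "genome_model"))
  if (length(tf_replicates) < 2) stop("need at least 2 TF replicates")
  wt <- background_sets$wt %||% snp_set(label = "wt")
  reps <- lapply(tf_replicates, function(s) {
    s <- snp_subset(s, !(snp_key(s) %in% snp_key(wt)))
    if (cfg$min_frequency > 0) {
      s <- snp_subset(s, !is.na(s$frequency) & s$frequency >= cfg$min_frequency)
    }
    s
  })
  ori <- intersect_replicates(reps, label = "SNP^ori")
  neg <- build_background(background_sets$pjn_common, background_sets$aid_common, wt)
  tf <- subtract_background(ori, neg)
  tf_rg <- filter_excluded_regions(tf, cfg)
  tf_rec <- if (is.null(all_tf_sets)) tf_rg else
    filter_recurrent_cross_tf(tf_rg, all_tf_sets, cfg, focal = focal)
  attributed <- classify_region(tf_rec, genome)
  attributed <- extract_flanks(attributed, genome, flank = flank)
  counts <- c(replicate_min = if (length(reps)) min(vapply(reps, nrow, integer(1))) else 0L,
              snp_ori = nrow(ori),
              after_background_subtraction = nrow(tf),
              after_region_exclusion = nrow(tf_rg),
              after_cross_tf_filter = nrow(tf_rec),
              attributed = nrow(attributed))
  if (nrow(attributed) == 0)
    message("profiling produced an EMPTY final SNP set")
  list(attributed = attributed, snp_ori = ori, snp_negative = neg,
       snp_tf = tf_rec, stage_counts = counts)
}
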