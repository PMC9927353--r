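#' Expected replicate-shared stochastic mutation count
#'
#' If stochastic (non-TF-directed) mutation strikes any base pair with
#' probability `p0` per experiment, a given position is mutated in all `k`
#' independent replicates with probability `p0^k`, so the expected number
#' of replicate-shared stochastic SNPs on an `N`-bp genome is `N * p0^k`.
#' For a bacterial genome (`N ~ 1e6..1e7`) at `p0 <= 1e-4` and `k = 3`
#' this is far below one, which is why replicate intersection removes the
#' stochastic background.
#'
#' @param N genome size in bp.
#' @param p0 per-bp stochastic mutation probability per experiment.
#' @param k number of replicates.
#' @return expected count (numeric).
#' @examples
#' expected_shared_stochastic(6.3e6, 1e-4, 3)  # 6.3e-6
#' @export
expected_shared_stochastic <- function(N, p0, k) {
  stopifnot(N >= 1, p0 >= 0, p0 <= 1, k >= 1)
  N * p0^k
}

#' Signed distance from a SNP position to a TF-binding box
#'
#' Measured to the nearest base of the box: positions outside the box get
#' the gap to the nearest box base (an adjacent base is 1); positions
#' inside the box get a negative value, `-(1 + bases to the nearest box
#' edge)`, so the first/last box base is -1. Only in-box SNPs have negative
#' distances. When `boxes` has several rows the nearest box is used (an
#' enclosing box wins; ties broken toward the lower-coordinate box).
#'
#' @param pos 0-based position(s).
#' @param boxes data frame of boxes (`contig`, `start`, `end`, 0-based
#'   half-open), e.g. from [plant_boxes].
#' @param contig contig of `pos`; all rows of `boxes` on other contigs are
#'   ignored, and it is an error if none remain.
#' @return numeric vector of signed distances (bp); attribute `"box"`
#'   carries the row index of the chosen box for each position.
#' @export
distance_to_box <- function(pos, boxes, contig = boxes$contig[1]) {
  stopifnot(nrow(boxes) >= 1)
  contig <- rep_len(as.character(contig), length(pos))
  res <- numeric(length(pos))
  chosen <- integer(length(pos))
  for (i in seq_along(pos)) {
    cand <- which(boxes$contig == contig[i])
    if (length(cand) == 0)
      stop("no box on contig '", contig[i], "'")
    d <- vapply(cand, function(j) {
      signed_box_distance(pos[i], boxes$start[j], boxes$end[j])
    }, numeric(1))
    # nearest box: an in-box (negative) distance always wins; otherwise the
    # smallest gap; ties toward the lower start coordinate (cand is in row
    # order; order() is stable so the first minimum wins)
    key <- ifelse(d < 0, -Inf, d)
    ord <- order(key, boxes$start[cand])
    best <- ord[1]
    res[i] <- d[best]
    chosen[i] <- cand[best]
  }
  attr(res, "box") <- chosen
  res
}

signed_box_distance <- function(pos, start, end) {
  if (pos < start) return(start - pos)
  if (pos >= end) return(pos - end + 1)
  -(1 + min(pos - start, end - 1 - pos))
}

#' Template/coding strand class of a deamination SNP
#'
#' Deaminase fusions edit a cytosine on one strand; after replication this
#' reads out as C>T when the edited C was on the reference strand and G>A
#' when it was on the minus strand. Relative to a gene, the edited C sits
#' on the coding strand (CS) or the template strand (TS): a reference C>T
#' is CS for a `+`-strand gene and TS for a `-`-strand gene, and a
#' reference G>A is the reverse. Other substitutions are not deamination
#' signatures and raise an error.
#'
#' @param snps a [snp_set] (or data frame with ref/alt columns).
#' @param gene a single gene feature (one-row data frame or list with a
#'   `strand` element).
#' @return character vector of `"TS"`/`"CS"`.
#' @export
strand_class <- function(snps, gene) {
  strand <- gene$strand[1]
  stopifnot(strand %in% c("+", "-"))
  sig <- paste0(snps$ref, ">", snps$alt)
  bad <- !sig %in% c("C>T", "G>A")
  if (any(bad))
    stop("not a deamination signature (need C>T or G>A): ",
         paste(unique(sig[bad]), collapse = ", "))
  edited_plus <- sig == "C>T"  # edited C lies on the reference (+) strand
  ifelse(edited_plus == (strand == "+"), "CS", "TS")
}

#' Per-promoter peak mutation frequency
#'
#' When a promoter carries several SNPs, the site with the highest mutation
#' frequency represents the promoter's degree of mutation.
#'
#' @param attributed classified SNPs (from [classify_region]) with known
#'   frequencies; records whose `region_class` is not `promoter_like`, or
#'   whose frequency is unknown, are ignored.
#' @return named numeric vector: promoter id (`upstream_of` label) to
#'   maximum frequency. Empty groups are simply absent.
#' @export
promoter_peak_frequency <- function(attributed) {
  a <- as.data.frame(attributed)
  a <- a[a$region_class == "promoter_like" & !is.na(a$frequency) &
           !is.na(a$upstream_of), , drop = FALSE]
  if (nrow(a) == 0) return(stats::setNames(numeric(0), character(0)))
  vapply(split(a$frequency, a$upstream_of), max, numeric(1))
}

#' Pairwise replicate reproducibility of mutation frequencies
#'
#' For each replicate pair (i, j), i < j, computes the ordinary
#' least-squares coefficient of determination R^2 of replicate j's
#' frequencies regressed on replicate i's, over the shared SNPs of the
#' consensus set. One R^2 per pair -- three values for three replicates.
#'
#' @param consensus output of [intersect_replicates] (needs `freq_rep*`
#'   columns).
#' @return data frame with columns `rep_i`, `rep_j`, `n`, `r_squared`.
#'   Pairs with fewer than 2 complete observations, or with a constant
#'   frequency vector, get `NA` (undefined, not 0) with a message.
#' @export
replicate_r2 <- function(consensus) {
  fc <- grep("^freq_rep[0-9]+$", names(consensus), value = TRUE)
  if (length(fc) < 2) stop("need >= 2 freq_rep columns (see intersect_replicates)")
  fc <- fc[order(as.integer(sub("freq_rep", "", fc)))]
  pairs <- utils::combn(seq_along(fc), 2)
  out <- data.frame(rep_i = pairs[1, ], rep_j = pairs[2, ],
                    n = NA_integer_, r_squared = NA_real_)
  for (p in seq_len(ncol(pairs))) {
    x <- consensus[[fc[pairs[1, p]]]]
    y <- consensus[[fc[pairs[2, p]]]]
    ok <- !is.na(x) & !is.na(y)
    out$n[p] <- sum(ok)
    if (sum(ok) < 2 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      message("R^2 undefined for replicate pair (", pairs[1, p], ",",
              pairs[2, p], "): constant or insufficient frequencies")
      next
    }
    # R^2 of the OLS fit with intercept equals the squared correlation
    out$r_squared[p] <- stats::cor(x[ok], y[ok])^2
  }
  out
}

#' Compare detected targets with a reference target list
#'
#' @param detected character vector of detected promoter/target ids. Ids
#'   on either side may be comma-separated composites (a divergent promoter
#'   region upstream of two genes); any shared component counts as overlap.
#' @param reference character vector of previously reported target ids.
#' @return object of class `benchmark_result`: list with `overlap`,
#'   `new_targets`, `not_detected` counts and a per-target `table`.
#'   Identities: overlap + new_targets = #detected;
#'   overlap + not_detected = #reference.
#' @export
venn_compare <- function(detected, reference) {
  detected <- unique(as.character(detected))
  reference <- unique(as.character(reference))
  det_parts <- strsplit(detected, ",", fixed = TRUE)
  ref_parts <- strsplit(reference, ",", fixed = TRUE)
  det_hit <- vapply(det_parts, function(p) any(p %in% unlist(ref_parts)),
                    logical(1))
  ref_hit <- vapply(ref_parts, function(p) any(p %in% unlist(det_parts)),
                    logical(1))
  tab <- rbind(
    data.frame(id = detected,
               status = ifelse(det_hit, "overlap", "new_target"),
               stringsAsFactors = FALSE),
    data.frame(id = reference[!ref_hit],
               status = rep("not_detected", sum(!ref_hit)),
               stringsAsFactors = FALSE))
  structure(list(overlap = sum(det_hit),
                 new_targets = sum(!det_hit),
                 not_detected = sum(!ref_hit),
                 table = tab),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("overlap: %d | new targets: %d | not detected: %d\n",
              x$overlap, x$new_targets, x$not_detected))
  invisible(x)
}

#' SNPs-per-box histogram
#'
#' Counts, for every TF-binding box, the SNPs lying within `window` bp of
#' the box (in-box SNPs count), and tabulates how many boxes carry 0, 1,
#' 2, ... SNPs. In a well-behaved directed-mutagenesis experiment the mode
#' is 1.
#'
#' @param snps a [snp_set] (or data frame with contig/pos).
#' @param boxes box table (`contig`, `start`, `end`).
#' @param window max distance in bp (default 100).
#' @return list with `per_box` (integer count per box row) and `histogram`
#'   (table over counts).
#' @export
snps_per_box <- function(snps, boxes, window = 100L) {
  per_box <- integer(nrow(boxes))
  for (j in seq_len(nrow(boxes))) {
    on_ct <- which(snps$contig == boxes$contig[j])
    if (length(on_ct) == 0) next
    d <- vapply(snps$pos[on_ct], signed_box_distance,
                numeric(1), start = boxes$start[j], end = boxes$end[j])
    per_box[j] <- sum(d <= window)
  }
  list(per_box = per_box, histogram = table(per_box))
}
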