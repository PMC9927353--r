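#' Genome model: sequences, genes, derived intergenic regions
#'
#' Bundles contig sequences with gene features and derives the intergenic
#' intervals between consecutive gene bodies on each contig. All coordinates
#' are internal 0-based half-open; conversion from 1-based formats (VCF,
#' GFF3) happens only at the I/O boundary.
#'
#' The derived `intergenic` table is the complement of the union of gene
#' bodies: disjoint intervals covering exactly the non-genic positions. Each
#' interval records its flanking genes (`left_gene` ends at the interval
#' start, `right_gene` starts at the interval end; NA at contig ends) and
#' their strands, which drive promoter-like classification: an intergenic
#' position is 5' of the right flanking gene when that gene is on `+`, and
#' 5' of the left flanking gene when that gene is on `-`.
#'
#' @param contigs named character vector of upper-case DNA sequences
#'   (A/C/G/T/N only), or a [Biostrings::DNAStringSet].
#' @param genes data frame with columns `gene_id`, `contig`, `start`, `end`
#'   (0-based half-open) and `strand` (`+`/`-`); may have zero rows.
#' @return An object of class `genome_model`: a list with elements
#'   `contigs`, `genes`, `intergenic`.
#' @examples
#' gm <- genome_model(
#'   c(c1 = paste(rep("ACGT", 25), collapse = "")),
#'   data.frame(gene_id = "g1", contig = "c1", start = 20, end = 60,
#'              strand = "+")
#' )
#' gm$intergenic
#' @export
genome_model <- function(contigs, genes = NULL) {
  if (inherits(contigs, "DNAStringSet")) {
    contigs <- stats::setNames(as.character(contigs), names(contigs))
  }
  stopifnot(is.character(contigs), !is.null(names(contigs)),
            !anyDuplicated(names(contigs)))
  contigs <- toupper(contigs)
  if (any(grepl("[^ACGTN]", contigs)))
    stop("contig sequences may contain only A/C/G/T/N")
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(), contig = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_id", "contig", "start", "end", "strand") %in% names(genes)))
  genes <- data.frame(gene_id = as.character(genes$gene_id),
                      contig = as.character(genes$contig),
                      start = as.integer(genes$start),
                      end = as.integer(genes$end),
                      strand = as.character(genes$strand),
                      stringsAsFactors = FALSE)
  if (nrow(genes) > 0) {
    if (any(genes$start >= genes$end))
      stop("gene intervals must satisfy start < end (0-based half-open)")
    if (!all(genes$strand %in% c("+", "-")))
      stop("gene strand must be '+' or '-'")
    if (!all(genes$contig %in% names(contigs)))
      stop("gene on unknown contig: ",
           paste(unique(setdiff(genes$contig, names(contigs))), collapse = ", "))
    clen <- nchar(contigs)[genes$contig]
    if (any(genes$end > clen))
      stop("gene interval extends beyond its contig")
    if (anyDuplicated(genes$gene_id))
      stop("duplicate gene_id in annotation")
  }
  genes <- genes[order(genes$contig, genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(contigs = contigs, genes = genes,
                 intergenic = derive_intergenic(contigs, genes)),
            class = "genome_model")
}

# Complement of the union of gene bodies per contig, with flanking genes.
derive_intergenic <- function(contigs, genes) {
  out <- lapply(names(contigs), function(ct) {
    clen <- nchar(contigs[[ct]])
    g <- genes[genes$contig == ct, , drop = FALSE]
    if (nrow(g) == 0) {
      return(data.frame(contig = ct, start = 0L, end = clen,
                        left_gene = NA_character_, left_strand = NA_character_,
                        right_gene = NA_character_, right_strand = NA_character_,
                        stringsAsFactors = FALSE))
    }
    ir <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    gaps <- IRanges::gaps(ir, start = 1L, end = clen)
    if (length(gaps) == 0) {
      return(data.frame(contig = character(), start = integer(), end = integer(),
                        left_gene = character(), left_strand = character(),
                        right_gene = character(), right_strand = character(),
                        stringsAsFactors = FALSE))
    }
    gs <- IRanges::start(gaps) - 1L   # back to 0-based half-open
    ge <- IRanges::end(gaps)
    # flanking gene of each gap: the gene whose body abuts the gap boundary.
    # With overlapping genes merged, pick the abutting gene nearest the gap
    # (max end on the left, min start on the right); ties by annotation order.
    left_idx <- vapply(gs, function(s) {
      cand <- which(g$end == s)
      if (length(cand) == 0) NA_integer_ else cand[which.max(g$end[cand])][1]
    }, integer(1))
    right_idx <- vapply(ge, function(e) {
      cand <- which(g$start == e)
      if (length(cand) == 0) NA_integer_ else cand[which.min(g$start[cand])][1]
    }, integer(1))
    data.frame(contig = ct, start = gs, end = ge,
               left_gene = g$gene_id[left_idx],
               left_strand = g$strand[left_idx],
               right_gene = g$gene_id[right_idx],
               right_strand = g$strand[right_idx],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model: %d contig(s), %s bp, %d gene(s), %d intergenic region(s)>\n",
              length(x$contigs), format(sum(nchar(x$contigs)), big.mark = ","),
              nrow(x$genes), nrow(x$intergenic)))
  invisible(x)
}

contig_length <- function(genome, contig) {
  if (!contig %in% names(genome$contigs))
    stop("unknown contig: ", contig)
  nchar(genome$contigs[[contig]])
}
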