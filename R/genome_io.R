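#' Read SNP calls from a VCF file
#'
#' Retains only biallelic single-nucleotide substitutions. Positions are
#' converted from 1-based VCF to the internal 0-based convention. The
#' per-sample allele frequency is computed from the AD (allelic depth)
#' FORMAT field; records without usable depths keep `frequency = NA`
#' ("unknown"), never 0. Indels and multi-nucleotide variants are dropped;
#' multiallelic records are split into per-alt records or skipped,
#' depending on `multiallelic`.
#'
#' @param path VCF file (plain or gzip-compressed). The first sample column
#'   is used when several are present.
#' @param label label for the returned set; defaults to the file name.
#' @param multiallelic `"split"` (default) expands `ALT=A,T` into one record
#'   per alternate allele; `"skip"` drops such rows.
#' @return A [snp_set].
#' @export
read_vcf <- function(path, label = basename(path),
                     multiallelic = c("split", "skip")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (is.null(fix) || nrow(fix) == 0) {
    return(snp_set(label = label))
  }
  contig <- fix[, "CHROM"]
  pos1 <- as.integer(fix[, "POS"])
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  ad <- rep(NA_character_, nrow(fix))
  if (ncol(v@gt) >= 2) {
    adm <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                    error = function(e) NULL)
    if (!is.null(adm)) ad <- unname(adm[, 1])
  }
  is_multi <- grepl(",", alt, fixed = TRUE)
  if (any(is_multi) && multiallelic == "skip") {
    message(sum(is_multi), " multiallelic record(s) skipped")
  }
  # expand multiallelic rows into one candidate row per alternate allele
  alt_list <- strsplit(alt, ",", fixed = TRUE)
  if (multiallelic == "skip") alt_list[is_multi] <- list(character())
  alt_n <- lengths(alt_list)
  alt_rank <- sequence(alt_n)            # which ALT within its source row
  i <- rep.int(seq_along(pos1), alt_n)
  a <- unlist(alt_list, use.names = FALSE)
  if (length(i) == 0) return(snp_set(label = label))
  # per-row AD depths: AD[1] = ref, AD[1 + j] = j-th alt
  depths <- lapply(strsplit(ifelse(is.na(ad), "", ad), ",", fixed = TRUE),
                   function(x) suppressWarnings(as.integer(x)))
  pick <- function(row, k) {
    d <- depths[[row]]
    if (length(d) >= k) d[k] else NA_integer_
  }
  rd <- mapply(pick, i, 1L)
  adp <- mapply(pick, i, alt_rank + 1L)
  keep <- nchar(ref[i]) == 1L & nchar(a) == 1L &
    ref[i] %in% c("A", "C", "G", "T") & a %in% c("A", "C", "G", "T")
  if (!any(keep)) return(snp_set(label = label))
  df <- data.frame(contig = contig[i][keep], pos = pos1[i][keep] - 1L,
                   ref = ref[i][keep], alt = a[keep],
                   ref_depth = as.integer(rd)[keep],
                   alt_depth = as.integer(adp)[keep],
                   stringsAsFactors = FALSE)
  df$frequency <- snp_frequency(df$ref_depth, df$alt_depth)
  df <- df[!duplicated(snp_key(df)), , drop = FALSE]
  as_snp_set(df, label = label)
}

#' Write a snp_set as a single-sample VCF
#'
#' Records are sorted by contig then position and written with 1-based
#' coordinates and an `AD` FORMAT field carrying the read depths. The file
#' is gzip-compressed (use a `.vcf.gz` path); [read_vcf] reproduces the set
#' exactly.
#'
#' @param snps a [snp_set].
#' @param path output path, conventionally ending in `.vcf.gz`.
#' @param sample sample column name; defaults to the set's label.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snps, path, sample = snp_label(snps)) {
  stopifnot(inherits(snps, "snp_set"))
  validate_snp_set(snps)
  meta <- c("##fileformat=VCFv4.2",
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
            '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">',
            paste0("##source=tfdeam_", as.character(utils::packageVersion("tfdeam"))))
  ord <- order(snps$contig, snps$pos)
  s <- as.data.frame(snps)[ord, , drop = FALSE]
  fmt_ad <- function(r, a) {
    ifelse(is.na(r) | is.na(a), ".", paste(r, a, sep = ","))
  }
  n <- nrow(s)
  fix <- matrix(c(s$contig, as.character(s$pos + 1L), rep(".", n),
                  s$ref, s$alt, rep(".", n), rep("PASS", n), rep(".", n)),
                nrow = n, ncol = 8,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER", "INFO")))
  ad_col <- if (n > 0) paste0("0/1:", fmt_ad(s$ref_depth, s$alt_depth)) else character(0)
  gt <- matrix(c(rep("GT:AD", n), ad_col),
               nrow = n, ncol = 2, dimnames = list(NULL, c("FORMAT", sample)))
  requireNamespace("vcfR", quietly = TRUE)
  obj <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                      meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(obj, file = path)
  invisible(path)
}

#' Read gene features from GFF3 or BED
#'
#' GFF3 1-based closed intervals and BED 0-based half-open intervals are
#' both normalised to the internal 0-based half-open convention, so the same
#' locus encoded in either format yields the identical feature. For GFF3,
#' rows with `type == "gene"` are used (all rows if no gene-typed rows
#' exist); the gene id is taken from the `ID`, `locus_tag` or `Name`
#' attribute, in that order. Features without a defined strand are rejected.
#'
#' @param path annotation file.
#' @param format `"gff3"` or `"bed"`; guessed from the file extension when
#'   missing.
#' @return data frame of gene features (`gene_id`, `contig`, `start`, `end`,
#'   `strand`), ready for [genome_model()].
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    type <- as.character(gr$type)
    if (any(type == "gene")) gr <- gr[type == "gene"]
    id <- as.character(gr$ID)
    if (all(is.na(id)) && !is.null(gr$locus_tag)) id <- as.character(gr$locus_tag)
    if (all(is.na(id)) && !is.null(gr$Name)) id <- as.character(gr$Name)
  } else {
    id <- as.character(gr$name)
  }
  if (length(gr) == 0) stop("no gene-level features found in ", path)
  if (anyNA(id)) id[is.na(id)] <- paste0("feature_", which(is.na(id)))
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("feature(s) without a defined strand in ", path,
         " (strand is required for promoter classification)")
  data.frame(gene_id = id,
             contig = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,   # to 0-based half-open
             end = BiocGenerics::end(gr),
             strand = strand,
             stringsAsFactors = FALSE)
}

#' Read a genome FASTA into a genome_model
#'
#' @param fasta_path genome FASTA.
#' @param annotation_path optional GFF3/BED gene annotation.
#' @param format annotation format, see [read_annotation].
#' @return A [genome_model].
#' @export
read_genome <- function(fasta_path, annotation_path = NULL, format = "auto") {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))  # FASTA description -> id
  genes <- if (!is.null(annotation_path)) read_annotation(annotation_path, format)
  genome_model(seqs, genes)
}

#' Extract reference-strand flanking sequence around SNPs
#'
#' For motif discovery the pipeline retrieves the window of `flank` bp on
#' each side of every SNP site (`2 * flank + 1` bp in all, 201 bp at the
#' default). Near contig ends the window is truncated, never padded, and the
#' truncation is flagged.
#'
#' @param snps a [snp_set] (or data frame with contig/pos/ref columns).
#' @param genome a [genome_model].
#' @param flank bp on each side of the SNP (default 100).
#' @return `snps` with added columns `flank_seq`, `flank_center` (0-based
#'   index of the SNP base within `flank_seq`) and `flank_truncated`.
#'   For untruncated windows `flank_center == flank` and the centre base
#'   equals the record's `ref`.
#' @export
extract_flanks <- function(snps, genome, flank = 100L) {
  stopifnot(inherits(genome, "genome_model"), flank >= 0)
  flank <- as.integer(flank)
  n <- nrow(snps)
  seqs <- character(n); center <- integer(n); trunc <- logical(n)
  for (ct in unique(snps$contig)) {
    idx <- which(snps$contig == ct)
    clen <- contig_length(genome, ct)
    pos <- snps$pos[idx]
    if (any(pos < 0L | pos >= clen))
      stop("SNP position outside contig ", ct)
    lo <- pmax(pos - flank, 0L)
    hi <- pmin(pos + flank, clen - 1L)
    seqs[idx] <- substring(genome$contigs[[ct]], lo + 1L, hi + 1L)
    center[idx] <- pos - lo
    trunc[idx] <- (lo > pos - flank) | (hi < pos + flank)
  }
  mism <- substring(seqs, center + 1L, center + 1L) != snps$ref
  if (any(mism))
    warning(sum(mism), " SNP(s) whose ref base does not match the genome sequence")
  out <- as.data.frame(snps)
  out$flank_seq <- seqs
  out$flank_center <- center
  out$flank_truncated <- trunc
  if (inherits(snps, "snp_set")) out <- as_snp_set(out, label = snp_label(snps))
  out
}

#' Write flank sequences as a motif-discovery-ready FASTA
#'
#' Headers follow `<contig>:<pos1based>:<ref>><alt>`, e.g. `c1:101:C>T`.
#'
#' @param snps output of [extract_flanks] (needs a `flank_seq` column).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_flank_fasta <- function(snps, path) {
  if (is.null(snps$flank_seq)) stop("no flank_seq column; run extract_flanks() first")
  ids <- sprintf("%s:%d:%s>%s", snps$contig, snps$pos + 1L, snps$ref, snps$alt)
  dss <- Biostrings::DNAStringSet(stats::setNames(as.character(snps$flank_seq), ids))
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Write genome sequences and annotation produced by the simulator
#'
#' @param genome a [genome_model].
#' @param fasta_path,gff3_path output paths (skipped when NULL).
#' @return invisibly, the paths written.
#' @export
write_genome <- function(genome, fasta_path = NULL, gff3_path = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  if (!is.null(fasta_path)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$contigs), fasta_path)
  }
  if (!is.null(gff3_path)) {
    g <- genome$genes
    gr <- GenomicRanges::GRanges(g$contig,
                                 IRanges::IRanges(g$start + 1L, g$end),
                                 strand = g$strand)
    gr$type <- "gene"
    gr$ID <- g$gene_id
    gr$Name <- g$gene_id
    rtracklayer::export(gr, gff3_path, format = "gff3")
  }
  invisible(c(fasta = fasta_path, gff3 = gff3_path))
}
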