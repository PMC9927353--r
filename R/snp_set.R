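#' SNP call sets
#'
#' A `snp_set` is a data frame of biallelic single-nucleotide substitution
#' calls for one sample (or one derived profiling stage), keyed by the
#' identity of the substitution: contig, 0-based position, reference base and
#' alternate base. Read-depth evidence travels with each record, but set
#' membership -- and every set operation in the profiling pipeline -- uses
#' the identity key only.
#'
#' Columns:
#' \describe{
#'   \item{contig}{character, contig/chromosome id}
#'   \item{pos}{integer, 0-based position on the contig}
#'   \item{ref, alt}{single upper-case bases, `ref != alt`}
#'   \item{ref_depth, alt_depth}{non-negative read counts (NA if unknown)}
#'   \item{frequency}{`alt_depth / (ref_depth + alt_depth)`; NA when total
#'     depth is zero or unknown ("frequency unknown" is distinct from 0)}
#' }
#' Extra columns (per-replicate frequencies, annotations) are carried along
#' untouched by the set algebra.
#'
#' @param contig,pos,ref,alt identity of each substitution.
#' @param ref_depth,alt_depth read-depth evidence; may be NA.
#' @param label sample or stage name, stored as the `"label"` attribute.
#' @return A data frame of class `snp_set`.
#' @examples
#' s <- snp_set("chr1", 100, "C", "T", ref_depth = 70, alt_depth = 30)
#' s$frequency  # 0.3
#' @export
snp_set <- function(contig = character(), pos = integer(),
                    ref = character(), alt = character(),
                    ref_depth = NA_integer_, alt_depth = NA_integer_,
                    label = "snp_set") {
  n <- length(pos)
  df <- data.frame(
    contig = as.character(contig),
    pos = as.integer(pos),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    ref_depth = as.integer(rep_len(ref_depth, n)),
    alt_depth = as.integer(rep_len(alt_depth, n)),
    stringsAsFactors = FALSE
  )
  df$frequency <- snp_frequency(df$ref_depth, df$alt_depth)
  as_snp_set(df, label = label)
}

#' Coerce a data frame to a snp_set
#'
#' @param x data frame with at least contig, pos, ref, alt columns.
#' @param label sample/stage name.
#' @return `x` with class `snp_set` and validated identity keys.
#' @export
as_snp_set <- function(x, label = attr(x, "label", exact = TRUE) %||% "snp_set") {
  stopifnot(is.data.frame(x),
            all(c("contig", "pos", "ref", "alt") %in% names(x)))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.null(x$ref_depth)) x$ref_depth <- NA_integer_
  if (is.null(x$alt_depth)) x$alt_depth <- NA_integer_
  if (is.null(x$frequency)) x$frequency <- snp_frequency(x$ref_depth, x$alt_depth)
  validate_snp_set(x)
  rownames(x) <- NULL
  structure(x, label = label, class = c("snp_set", "data.frame"))
}

validate_snp_set <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  bad <- nchar(x$ref) != 1L | nchar(x$alt) != 1L
  if (any(bad))
    stop("snp_set records must be single-nucleotide substitutions; ",
         sum(bad), " record(s) have multi-base ref/alt")
  if (any(x$ref == x$alt))
    stop("snp_set records must have ref != alt")
  if (any(x$pos < 0L))
    stop("snp_set positions are 0-based and must be >= 0")
  if (anyDuplicated(snp_key(x)))
    stop("duplicate identity keys (contig, pos, ref, alt) in snp_set")
  fr <- x$frequency[!is.na(x$frequency)]
  if (length(fr) > 0 && (min(fr) < 0 || max(fr) > 1))
    stop("snp frequencies must lie in [0, 1]")
  invisible(x)
}

snp_frequency <- function(ref_depth, alt_depth) {
  tot <- ref_depth + alt_depth
  ifelse(!is.na(tot) & tot > 0L, alt_depth / tot, NA_real_)
}

#' Identity key of each SNP record
#'
#' The key `(contig, pos, ref, alt)` defines SNP identity across samples;
#' depths and frequencies never enter membership tests. The rendering
#' `contig:pos:ref>alt` matches the flank-FASTA headers (with 0-based
#' positions here).
#'
#' @param x a `snp_set` (or any data frame with the four key columns).
#' @return character vector of keys, one per record.
#' @export
snp_key <- function(x) {
  if (nrow(x) == 0) return(character())
  sprintf("%s:%d:%s>%s", x$contig, x$pos, x$ref, x$alt)
}

#' @export
print.snp_set <- function(x, ...) {
  cat(sprintf("<snp_set '%s': %d record(s)>\n",
              attr(x, "label", exact = TRUE) %||% "?", nrow(x)))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10L, "more\n")
  invisible(x)
}

#' Label of a snp_set
#' @param x a `snp_set`.
#' @return character scalar.
#' @export
snp_label <- function(x) attr(x, "label", exact = TRUE) %||% "snp_set"

`%||%` <- function(a, b) if (is.null(a)) b else a

# subset rows, preserving class + label
snp_subset <- function(x, keep, label = snp_label(x)) {
  out <- as.data.frame(x)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, label = label, class = c("snp_set", "data.frame"))
}
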