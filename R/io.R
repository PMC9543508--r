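#' Read a pooled SNP count table
#'
#' Supports two plain-text formats:
#' \describe{
#'   \item{sync}{tab-delimited `chrom  pos  ref:alt  ref:alt ...`, one
#'     column of `ref:alt` counts per population. A comment line
#'     `#chrom pos A1 A2 ...` names the populations.}
#'   \item{vcf}{VCF 4.x with a per-sample `AD` field; the two allele
#'     depths of each biallelic record are used as pooled counts.
#'     Non-biallelic records are skipped with a message. Requires the
#'     VariantAnnotation package.}
#' }
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"sync"` or `"vcf"`.
#' @param pool_size diploid individuals per pool (default 100).
#' @return a [snp_table].
#' @export
read_counts <- function(path, format = c("auto", "sync", "vcf"),
                        pool_size = 100) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "sync"
  switch(format,
         sync = read_sync(path, pool_size),
         vcf  = read_vcf_counts(path, pool_size))
}

read_sync <- function(path, pool_size = 100) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  body_idx <- grep("^#", lines, invert = TRUE)
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  if (!length(body_idx)) stop("no data lines in ", path)
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1]))
    stop(sprintf("parse error at line %d of %s: expected %d fields, found %d",
                 body_idx[which(nf != nf[1])[1]], path, nf[1],
                 nf[which(nf != nf[1])[1]]))
  if (nf[1] < 3L) stop("sync file must have at least 3 columns")
  P <- nf[1] - 2L
  mat <- matrix(unlist(fields), ncol = nf[1], byrow = TRUE)
  pos <- suppressWarnings(as.integer(mat[, 2]))
  if (anyNA(pos))
    stop(sprintf("parse error at line %d of %s: non-integer position '%s'",
                 body_idx[which(is.na(pos))[1]], path,
                 mat[which(is.na(pos))[1], 2]))
  counts <- mat[, -(1:2), drop = FALSE]
  ok <- grepl("^[0-9]+:[0-9]+$", counts)
  if (!all(ok)) {
    bad <- (which(!ok)[1] - 1L) %% nrow(counts) + 1L
    stop(sprintf("parse error at line %d of %s: malformed count field",
                 body_idx[bad], path))
  }
  split2 <- function(j) {
    cc <- strsplit(counts[, j], ":", fixed = TRUE)
    vapply(cc, function(v) as.integer(v), integer(2))
  }
  refalt <- lapply(seq_len(P), split2)
  ref <- vapply(refalt, function(m) m[1, ], integer(length(pos)))
  alt <- vapply(refalt, function(m) m[2, ], integer(length(pos)))
  if (length(pos) == 1L) { ref <- rbind(ref); alt <- rbind(alt) }
  pop_ids <- NULL
  if (length(header)) {
    hf <- strsplit(sub("^#+\\s*", "", header[length(header)]), "[\t ]+")[[1]]
    if (length(hf) == P + 2L) pop_ids <- hf[-(1:2)]
  }
  snp_table(mat[, 1], pos, ref, alt, pop_ids, pool_size)
}

read_vcf_counts <- function(path, pool_size = 100) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  nalt <- lengths(VariantAnnotation::alt(vcf))
  if (any(nalt != 1L)) {
    message(sum(nalt != 1L), " non-biallelic record(s) skipped")
    vcf <- vcf[nalt == 1L]
  }
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop("VCF has no per-sample AD field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  S <- length(rr)
  P <- ncol(ad)
  ref <- matrix(0L, S, P)
  alt <- matrix(0L, S, P)
  for (j in seq_len(P)) {
    col <- ad[, j]
    ref[, j] <- vapply(col, function(v) as.integer(v[1]), integer(1))
    alt[, j] <- vapply(col, function(v) as.integer(v[2]), integer(1))
  }
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  o <- order(chrom, pos)
  snp_table(chrom[o], pos[o], ref[o, , drop = FALSE], alt[o, , drop = FALSE],
            colnames(ad), pool_size)
}

#' Write a `snp_table` as a sync-style TSV
#'
#' The inverse of [read_counts()] for the sync format; a commented header
#' records the population labels.
#' @param x a [snp_table].
#' @param path output path.
#' @export
write_counts <- function(x, path) {
  cols <- vapply(seq_along(x$pop_ids),
                 function(j) paste0(x$ref[, j], ":", x$alt[, j]),
                 character(n_snps(x)))
  if (n_snps(x) == 1L) cols <- rbind(cols)
  lines <- c(paste(c("#chrom", "pos", x$pop_ids), collapse = "\t"),
             apply(cbind(x$chrom, x$pos, cols), 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}
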