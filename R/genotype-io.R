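#' Construct a genotype matrix object
#'
#' A \code{genotype_matrix} holds reference-allele counts for \code{N}
#' individuals at \code{M} biallelic loci, together with per-locus metadata.
#' Calls are coded 0, 1, 2 (copies of the reference allele) with \code{NA}
#' for missing genotypes.
#'
#' @param calls integer N x M matrix with entries in \{0, 1, 2, NA\}.
#' @param samples data.frame with columns \code{fid} and \code{iid}; defaults
#'   to synthetic ids \code{F1..FN}/\code{I1..IN}.
#' @param loci data.frame with columns \code{id}, \code{chrom}, \code{pos},
#'   \code{ref_allele}, \code{alt_allele}; synthesized when absent.
#' @return An object of class \code{genotype_matrix} with elements
#'   \code{calls}, \code{samples}, \code{loci}.
#' @export
genotype_matrix <- function(calls, samples = NULL, loci = NULL) {
  calls <- as.matrix(calls)
  if (!is.numeric(calls)) stop("genotype calls must be numeric")
  bad <- which(!is.na(calls) & !(calls %in% c(0, 1, 2)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(calls))
    stop(sprintf("invalid genotype call %s at row %d, column %d (must be 0/1/2/NA)",
                 format(calls[bad[1]]), rc[1], rc[2]))
  }
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(samples)) {
    samples <- data.frame(fid = paste0("F", seq_len(n)),
                          iid = paste0("I", seq_len(n)),
                          stringsAsFactors = FALSE)
  }
  if (is.null(loci)) {
    loci <- data.frame(id = paste0("snp", seq_len(m)), chrom = "1",
                       pos = seq_len(m), ref_allele = "A", alt_allele = "C",
                       stringsAsFactors = FALSE)
  }
  if (nrow(samples) != n) stop("sample table does not match genotype rows")
  if (nrow(loci) != m) stop("locus table does not match genotype columns")
  storage.mode(calls) <- "integer"
  structure(list(calls = calls, samples = samples, loci = loci),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%d missing calls)\n",
              nrow(x$calls), ncol(x$calls), sum(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

## ---- PLINK binary filesets --------------------------------------------

#' Read a PLINK binary fileset
#'
#' Decodes a PLINK 1 binary fileset (\code{.bed}/\code{.bim}/\code{.fam},
#' SNP-major mode).  The 2-bit codes are 00 = homozygous allele 1,
#' 01 = missing, 10 = heterozygous, 11 = homozygous allele 2.
#'
#' @param prefix path prefix of the fileset (without extension).
#' @param count_allele1 logical; when \code{TRUE} (default) .bim allele 1 is
#'   the counted (reference) allele, so a homozygous-allele-1 genotype is
#'   coded 2.  Relatedness and heritability estimates are invariant to this
#'   orientation; only reported allele frequencies change.
#' @return A \code{genotype_matrix}.
#' @export
read_plink <- function(prefix, count_allele1 = TRUE) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing PLINK file: ", f)
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam_df); m <- nrow(bim_df)
  samples <- data.frame(fid = as.character(fam_df[[1]]),
                        iid = as.character(fam_df[[2]]),
                        stringsAsFactors = FALSE)
  loci <- data.frame(id = as.character(bim_df[[2]]),
                     chrom = as.character(bim_df[[1]]),
                     pos = as.integer(bim_df[[4]]),
                     ref_allele = as.character(bim_df[[5]]),
                     alt_allele = as.character(bim_df[[6]]),
                     stringsAsFactors = FALSE)
  raw <- readBin(bed, what = "raw", n = file.info(bed)$size)
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes): ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major PLINK .bed files (mode byte 0x01) are supported")
  bpl <- ceiling(n / 4)               # bytes per locus
  if (length(raw) - 3L != bpl * m)
    stop(sprintf(".bed file is corrupt: expected %d data bytes for %d x %d, found %d",
                 bpl * m, n, m, length(raw) - 3L))
  body <- raw[-(1:3)]
  # Split every byte into its four 2-bit fields, low bits first.
  ints <- as.integer(body)
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, ints %/% 64L)
  dim(codes) <- c(4L * bpl, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  # code -> allele-1 dosage: 00->2, 01->NA, 10->1, 11->0
  lut <- c(2L, NA_integer_, 1L, 0L)
  calls <- matrix(lut[codes + 1L], n, m)
  if (!count_allele1) {
    calls <- 2L - calls
    loci[, c("ref_allele", "alt_allele")] <- loci[, c("alt_allele", "ref_allele")]
  }
  genotype_matrix(calls, samples, loci)
}

#' Write a PLINK binary fileset
#'
#' Inverse of \code{\link{read_plink}}; writes SNP-major \code{.bed} plus
#' \code{.bim}/\code{.fam} text files so that read-back round-trips exactly.
#'
#' @param g a \code{genotype_matrix}.
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$calls); m <- ncol(g$calls)
  fam <- data.frame(g$samples$fid, g$samples$iid, 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(g$loci$chrom, g$loci$id, 0L, g$loci$pos,
                    g$loci$ref_allele, g$loci$alt_allele)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  # dosage -> 2-bit code (indexing by dosage + 1): 0->3 (hom a2), 1->2 (het), 2->0
  code_of <- c(3L, 2L, 0L)
  bpl <- ceiling(n / 4)
  pad <- 4L * bpl - n
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  out <- vapply(seq_len(m), function(k) {
    x <- g$calls[, k]
    cd <- ifelse(is.na(x), 1L, code_of[x + 1L])
    cd <- c(cd, rep(0L, pad))
    dim(cd) <- c(4L, bpl)
    as.raw(cd[1, ] + 4L * cd[2, ] + 16L * cd[3, ] + 64L * cd[4, ])
  }, raw(bpl))
  writeBin(as.vector(out), con)
  invisible(prefix)
}

## ---- text formats ------------------------------------------------------

#' Read a plain-text dosage matrix
#'
#' Whitespace-delimited table, one row per individual, entries in
#' \{0, 1, 2, NA\}.  Locus metadata is synthesized.
#'
#' @param path file path.
#' @return A \code{genotype_matrix}.
#' @export
read_text_genotypes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty genotype file: ", path)
  rows <- lapply(lines, function(l) strsplit(trimws(l), "[ \t]+")[[1]])
  m <- length(rows[[1]])
  calls <- matrix(NA_integer_, length(rows), m)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != m)
      stop(sprintf("row %d has %d entries, expected %d", i, length(r), m))
    for (j in seq_len(m)) {
      v <- r[j]
      if (v == "NA" || v == "-9") next
      if (!v %in% c("0", "1", "2"))
        stop(sprintf("invalid genotype '%s' at row %d, column %d", v, i, j))
      calls[i, j] <- as.integer(v)
    }
  }
  genotype_matrix(calls)
}

#' Read a phenotype file
#'
#' Whitespace-delimited "FID IID value" file with NA (or -9) for missing,
#' aligned to the samples of a genotype matrix or GRM by (FID, IID).
#'
#' @param path file path.
#' @param samples optional data.frame with \code{fid}/\code{iid} giving the
#'   target order; unmatched ids are an error.
#' @return Named numeric vector of phenotypes (names \code{fid:iid}).
#' @export
read_phenotype <- function(path, samples = NULL) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", "-9"))
  if (ncol(df) < 3) stop("phenotype file needs at least 3 columns: FID IID value")
  y <- as.numeric(df[[3]])
  names(y) <- paste(df[[1]], df[[2]], sep = ":")
  if (!is.null(samples)) {
    key <- paste(samples$fid, samples$iid, sep = ":")
    idx <- match(key, names(y))
    if (anyNA(idx))
      stop("phenotype file is missing ", sum(is.na(idx)), " sample id(s)")
    y <- y[idx]
  }
  y
}

## ---- frequencies and standardization ----------------------------------

#' Estimate reference-allele frequencies
#'
#' Per-locus frequency of the counted allele, computed from non-missing
#' calls only: \eqn{p_k = \sum x_{ik} / (2 n_k)} over the \eqn{n_k}
#' individuals with observed genotypes at locus \eqn{k}.
#'
#' @param g a \code{genotype_matrix} (or plain 0/1/2 matrix).
#' @return Numeric vector of frequencies in \[0, 1\].
#' @export
estimate_allele_frequencies <- function(g) {
  calls <- if (inherits(g, "genotype_matrix")) g$calls else as.matrix(g)
  nonmiss <- colSums(!is.na(calls))
  if (any(nonmiss == 0))
    stop("all genotypes missing at locus/loci: ",
         paste(which(nonmiss == 0), collapse = ", "))
  colSums(calls, na.rm = TRUE) / (2 * nonmiss)
}

#' Standardize genotypes
#'
#' Centers and scales each locus to \eqn{s_{ik} = (x_{ik} - 2p_k)/\sqrt{2 p_k q_k}},
#' the usual unit-variance coding under Hardy-Weinberg equilibrium.  Loci with
#' minor-allele frequency below \code{maf} are dropped (the scale factor
#' degenerates as \eqn{2 p q \to 0}).
#'
#' @param g a \code{genotype_matrix} or 0/1/2 matrix.
#' @param freqs frequencies of the counted allele; estimated from the sample
#'   when \code{NULL}.
#' @param missing enum: \code{"mean"} fills missing standardized entries with
#'   0 (mean imputation, keeps pairwise products unbiased);
#'   \code{"fail"} raises an error on any missing call.
#' @param maf minor-allele-frequency floor; loci below it are excluded.
#' @return Object of class \code{standardized_genotypes}: list with
#'   \code{scores} (N x M' numeric matrix), \code{freqs}, \code{kept}
#'   (indices of retained loci), \code{missing} policy, and \code{n_missing}
#'   count of imputed calls.
#' @export
standardize_genotypes <- function(g, freqs = NULL, missing = c("mean", "fail"),
                                  maf = 0.01) {
  missing <- match.arg(missing)
  calls <- if (inherits(g, "genotype_matrix")) g$calls else as.matrix(g)
  if (is.null(freqs)) freqs <- estimate_allele_frequencies(calls)
  if (length(freqs) != ncol(calls)) stop("frequency vector length mismatch")
  keep <- which(pmin(freqs, 1 - freqs) >= maf)
  if (!length(keep))
    stop("no polymorphic loci left after MAF filter (floor ", maf, ")")
  p <- freqs[keep]
  x <- calls[, keep, drop = FALSE]
  nmiss <- sum(is.na(x))
  if (missing == "fail" && nmiss > 0)
    stop(nmiss, " missing genotype call(s) with missing = \"fail\"")
  s <- sweep(x, 2, 2 * p, "-")
  s <- sweep(s, 2, sqrt(2 * p * (1 - p)), "/")
  if (nmiss > 0) s[is.na(s)] <- 0
  structure(list(scores = s, freqs = p, kept = keep, missing = missing,
                 n_missing = nmiss),
            class = "standardized_genotypes")
}

#' @export
print.standardized_genotypes <- function(x, ...) {
  cat(sprintf("standardized_genotypes: %d x %d (policy: %s, %d imputed)\n",
              nrow(x$scores), ncol(x$scores), x$missing, x$n_missing))
  invisible(x)
}
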