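#' Phased haplotype panel for a gene region
#'
#' A `haplotype_panel` stores phased binary haplotypes for a set of diploid
#' individuals: a `2N x M` matrix of 0/1 allele codes (1 = the coded, usually
#' minor, allele) together with per-variant metadata.  Haplotype rows `2i - 1`
#' and `2i` belong to individual `i`.
#'
#' @param haplotypes integer/numeric matrix of 0/1 values, one row per
#'   haplotype, one column per variant; an even number of rows is required.
#' @param variants optional `data.frame` with one row per variant and at least
#'   a column `id`; columns `pos`, `ref`, `alt` are carried along when present.
#' @param allow_monomorphic keep columns where only one allele is observed.
#'   The reference panel of a region must be polymorphic at every retained
#'   variant, but finite case/control samples drawn from it need not be.
#' @return an object of class `haplotype_panel` with elements `hap`
#'   (the haplotype matrix) and `variants` (metadata including the observed
#'   coded-allele frequency `freq` and folded `maf`).
#' @examples
#' h <- matrix(c(0, 1, 1, 0, 0, 0, 1, 1), nrow = 4)
#' p <- haplotype_panel(h, data.frame(id = c("v1", "v2")))
#' n_individuals(p)
#' genotypes(p)
#' @export
haplotype_panel <- function(haplotypes, variants = NULL,
                            allow_monomorphic = FALSE) {
  haplotypes <- as.matrix(haplotypes)
  if (nrow(haplotypes) %% 2L != 0L) {
    stop("haplotype matrix must have an even number of rows (two per individual)")
  }
  if (nrow(haplotypes) < 4L) {
    stop("a panel needs at least 2 individuals")
  }
  if (!all(haplotypes %in% c(0, 1))) {
    stop("haplotype entries must all be 0 or 1")
  }
  storage.mode(haplotypes) <- "integer"
  if (is.null(variants)) {
    ids <- colnames(haplotypes) %||% paste0("v", seq_len(ncol(haplotypes)))
    variants <- data.frame(id = ids, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(variants), nrow(variants) == ncol(haplotypes),
            "id" %in% names(variants))
  freq <- colMeans(haplotypes)
  mono <- freq == 0 | freq == 1
  if (any(mono) && !allow_monomorphic) {
    stop("monomorphic column(s): ", paste(variants$id[mono], collapse = ", "))
  }
  variants$freq <- freq
  variants$maf <- pmin(freq, 1 - freq)
  colnames(haplotypes) <- variants$id
  structure(list(hap = haplotypes, variants = variants),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d individuals x %d variants (MAF %.4g-%.4g)\n",
              n_individuals(x), n_variants(x),
              min(x$variants$maf), max(x$variants$maf)))
  invisible(x)
}

#' @rdname haplotype_panel
#' @param panel a `haplotype_panel`.
#' @export
n_individuals <- function(panel) nrow(panel$hap) %/% 2L

#' @rdname haplotype_panel
#' @export
n_variants <- function(panel) ncol(panel$hap)

#' Derive diploid genotypes from a phased panel
#'
#' Genotype of individual `i` at a variant is the sum of its two haplotype
#' entries (0, 1 or 2 copies of the coded allele).
#'
#' @param panel a `haplotype_panel`.
#' @return integer matrix, `N x M`, values in 0/1/2.
#' @export
genotypes <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  h <- panel$hap
  g <- h[seq(1L, nrow(h), by = 2L), , drop = FALSE] +
    h[seq(2L, nrow(h), by = 2L), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Observed genotype frequencies of one variant
#'
#' @param panel a `haplotype_panel`.
#' @param variant variant index or id.
#' @return length-3 numeric vector: frequencies of genotypes 0, 1 and 2.
#' @export
genotype_freqs <- function(panel, variant) {
  v <- .resolve_variant(panel, variant)
  g <- genotypes(panel)[, v]
  .geno_counts(g) / length(g)
}

.resolve_variant <- function(panel, variant) {
  if (is.character(variant)) {
    v <- match(variant, panel$variants$id)
    if (anyNA(v)) stop("unknown variant id: ", variant[is.na(v)][1L])
    return(v)
  }
  stopifnot(all(variant >= 1), all(variant <= n_variants(panel)))
  as.integer(variant)
}

#' Subset a panel to whole individuals
#'
#' @param panel a `haplotype_panel`.
#' @param individuals integer vector of individual indices (repeats allowed,
#'   e.g. for bootstrap resampling).
#' @return a new `haplotype_panel`; monomorphic columns are retained because a
#'   finite sample of a polymorphic panel can lose an allele.
#' @export
subset_individuals <- function(panel, individuals) {
  stopifnot(inherits(panel, "haplotype_panel"))
  rows <- as.vector(rbind(2L * individuals - 1L, 2L * individuals))
  haplotype_panel(panel$hap[rows, , drop = FALSE],
                  panel$variants[, c("id", intersect(c("pos", "ref", "alt"),
                                                     names(panel$variants))),
                                 drop = FALSE],
                  allow_monomorphic = TRUE)
}

# ---------------------------------------------------------------------------
# haplotype-matrix text format: a header row of variant ids, then one row per
# haplotype of comma-separated 0/1 codes; individuals are consecutive row pairs

#' Read/write the plain haplotype-matrix format
#'
#' The text format is a CSV with a header row of variant ids and one row of
#' 0/1 codes per haplotype; haplotype rows `2i - 1` and `2i` form individual
#' `i`.
#'
#' @param path file path.
#' @param allow_monomorphic passed to [haplotype_panel()].
#' @return `read_hapmatrix()` returns a `haplotype_panel`;
#'   `write_hapmatrix()` returns `path` invisibly.
#' @export
read_hapmatrix <- function(path, allow_monomorphic = FALSE) {
  m <- utils::read.csv(path, check.names = FALSE)
  haplotype_panel(as.matrix(m), data.frame(id = colnames(m),
                                           stringsAsFactors = FALSE),
                  allow_monomorphic = allow_monomorphic)
}

#' @rdname read_hapmatrix
#' @param panel a `haplotype_panel`.
#' @export
write_hapmatrix <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  utils::write.csv(as.data.frame(panel$hap), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# VCF input/output

#' Read a phased VCF into a haplotype panel
#'
#' Only biallelic SNVs with fully phased diploid genotypes are retained.
#' Unphased or missing genotype calls are hard errors: the frequency algebra
#' of the downstream tests assumes complete phased genotypes, so nothing is
#' imputed.  Variants whose minor allele frequency is at or below `maf_min`
#' are excluded (the count of exclusions is reported via `message()`), and
#' columns are ordered by position.  The coded allele (matrix value 1) is the
#' minor allele in the file; when the ALT frequency exceeds 0.5 the coding is
#' flipped and recorded in the metadata column `coded`.
#'
#' @param path path to a VCF 4.x file (uncompressed or bgzipped).
#' @param maf_min exclusion threshold: variants with MAF <= `maf_min` are
#'   dropped (default 0.001).
#' @return a `haplotype_panel`.
#' @export
read_vcf <- function(path, maf_min = 0.001) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fm <- vcfR::getFIX(v)
  if (is.null(dim(fm))) fm <- t(fm)  # single-record files come back as a vector
  fix <- as.data.frame(fm, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (!is.matrix(gt)) gt <- matrix(gt, nrow = nrow(fix))
  if (is.null(gt) || nrow(fix) == 0L) stop("no genotype records in ", path)

  snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_multi <- sum(!snv)
  if (n_multi > 0L) {
    message(n_multi, " non-biallelic-SNV record(s) excluded")
    fix <- fix[snv, , drop = FALSE]
    gt <- gt[snv, , drop = FALSE]
  }
  if (nrow(fix) == 0L) stop("no biallelic SNVs left after filtering")

  rec_name <- function(i) {
    sprintf("%s:%s (%s)", fix$CHROM[i], fix$POS[i],
            ifelse(is.na(fix$ID[i]) | fix$ID[i] == ".",
                   paste0(fix$REF[i], ">", fix$ALT[i]), fix$ID[i]))
  }
  as_mat <- function(x) matrix(x, nrow = nrow(gt))
  miss <- which(as_mat(is.na(gt) | gt %in% c(".", "./.", ".|.")),
                arr.ind = TRUE)
  if (nrow(miss) > 0L) {
    stop("missing genotype at record ", rec_name(miss[1L, 1L]),
         "; complete genotypes are required (no imputation)")
  }
  unphased <- which(as_mat(grepl("/", gt, fixed = TRUE)), arr.ind = TRUE)
  if (nrow(unphased) > 0L) {
    stop("unphased genotype '", gt[unphased[1L, , drop = FALSE]],
         "' at record ", rec_name(unphased[1L, 1L]),
         "; phased GT ('|') is required")
  }
  bad <- which(as_mat(!grepl("^[01]\\|[01]$", gt)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("unsupported GT '", gt[bad[1L, , drop = FALSE]], "' at record ",
         rec_name(bad[1L, 1L]))
  }

  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
  # haplotype rows: sample 1 hap A, sample 1 hap B, sample 2 hap A, ...
  hap <- matrix(0L, nrow = 2L * ncol(gt), ncol = nrow(gt))
  hap[seq(1L, nrow(hap), 2L), ] <- t(a1)
  hap[seq(2L, nrow(hap), 2L), ] <- t(a2)

  alt_freq <- colMeans(hap)
  flip <- alt_freq > 0.5  # ties at 0.5 keep ALT as the coded allele
  hap[, flip] <- 1L - hap[, flip]
  maf <- colMeans(hap)

  keep <- maf > maf_min
  if (any(!keep)) {
    message(sum(!keep), " variant(s) excluded at MAF <= ", maf_min)
  }
  if (sum(keep) == 0L) stop("no variants left after the MAF filter")

  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  meta <- data.frame(id = ids,
                     chrom = fix$CHROM,
                     pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     coded = ifelse(flip, fix$REF, fix$ALT),
                     stringsAsFactors = FALSE)
  meta <- meta[keep, , drop = FALSE]
  hap <- hap[, keep, drop = FALSE]
  ord <- order(meta$pos)
  haplotype_panel(hap[, ord, drop = FALSE], meta[ord, , drop = FALSE])
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits a minimal VCF 4.2 with phased GT fields; the coded allele of the
#' panel is written as ALT.
#'
#' @param panel a `haplotype_panel`.
#' @param path output file path.
#' @param chrom chromosome label used when the panel has no `chrom` metadata.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path, chrom = "19") {
  stopifnot(inherits(panel, "haplotype_panel"))
  m <- panel$variants
  pos <- m$pos %||% (seq_len(nrow(m)) * 100L)
  ref <- m$ref %||% rep("A", nrow(m))
  alt <- m$alt %||% rep("T", nrow(m))
  chr <- if ("chrom" %in% names(m)) m$chrom else rep(chrom, nrow(m))
  n <- n_individuals(panel)
  samples <- paste0("I", seq_len(n))
  h1 <- panel$hap[seq(1L, 2L * n, 2L), , drop = FALSE]
  h2 <- panel$hap[seq(2L, 2L * n, 2L), , drop = FALSE]
  gt <- matrix(paste0(h1, "|", h2), nrow = n)  # N x M
  lines <- c("##fileformat=VCFv4.2",
             "##source=varident",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(chr[i], pos[i], m$id[i], ref[i], alt[i], ".", "PASS", ".", "GT",
            gt[, i]), collapse = "\t")
  }, character(1L))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Per-variant frequency summary
#'
#' @param panel a `haplotype_panel`.
#' @param path optional TSV output path.
#' @return a `data.frame` with id, coded-allele frequency, MAF and genotype
#'   frequencies; written to `path` when given.
#' @export
freq_summary <- function(panel, path = NULL) {
  g <- genotypes(panel)
  gf <- t(apply(g, 2L, function(x) .geno_counts(x) / length(x)))
  out <- data.frame(id = panel$variants$id,
                    freq = panel$variants$freq,
                    maf = panel$variants$maf,
                    f_g0 = gf[, 1L], f_g1 = gf[, 2L], f_g2 = gf[, 3L],
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
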