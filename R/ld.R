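#' Pairwise linkage disequilibrium from phased haplotypes
#'
#' Computes `D = p_ij - p_i p_j` from haplotype (not genotype) counts,
#' together with the normalized coefficient D' and the squared allelic
#' correlation r-squared.  Frequencies refer to the coded (value 1) allele of
#' each column.
#'
#' @param panel a `haplotype_panel`.
#' @param i,j variant indices or ids; both columns must be polymorphic.
#' @return an object of class `ld_stats`: list with `D`, `D_prime`, `r2`,
#'   `maf_i`, `maf_j`, `p_i`, `p_j`.
#' @examples
#' h <- matrix(c(0, 1, 1, 0, 0, 1, 1, 0), nrow = 4)
#' ld_stats(haplotype_panel(h), 1, 2)$r2
#' @export
ld_stats <- function(panel, i, j) {
  stopifnot(inherits(panel, "haplotype_panel"))
  i <- .resolve_variant(panel, i)
  j <- .resolve_variant(panel, j)
  if (i == j) stop("i and j must name different variants")
  x <- panel$hap[, i]
  y <- panel$hap[, j]
  p_i <- mean(x)
  p_j <- mean(y)
  if (p_i %in% c(0, 1) || p_j %in% c(0, 1)) {
    stop("monomorphic column: r2 is undefined")
  }
  p_ij <- mean(x == 1L & y == 1L)
  D <- p_ij - p_i * p_j
  d_max <- if (D >= 0) {
    min(p_i * (1 - p_j), (1 - p_i) * p_j)
  } else {
    min(p_i * p_j, (1 - p_i) * (1 - p_j))
  }
  # D' carries the sign of D
  D_prime <- if (D == 0) 0 else abs(D) / d_max * sign(D)
  r2 <- D^2 / (p_i * (1 - p_i) * p_j * (1 - p_j))
  structure(list(D = D, D_prime = D_prime, r2 = r2,
                 p_i = p_i, p_j = p_j,
                 maf_i = min(p_i, 1 - p_i), maf_j = min(p_j, 1 - p_j)),
            class = "ld_stats")
}

#' @export
print.ld_stats <- function(x, ...) {
  cat(sprintf("<ld_stats> D = %.5g, D' = %.4g, r2 = %.4g\n",
              x$D, x$D_prime, x$r2))
  invisible(x)
}

#' Pairwise LD summary table
#'
#' @param panel a `haplotype_panel`.
#' @param pairs optional 2-column matrix/data.frame of variant ids or indices;
#'   defaults to all pairs.
#' @param path optional TSV output path.
#' @return data.frame with one row per pair (id_i, id_j, D, D_prime, r2).
#' @export
ld_summary <- function(panel, pairs = NULL, path = NULL) {
  if (is.null(pairs)) {
    pairs <- t(utils::combn(n_variants(panel), 2L))
  }
  pairs <- as.matrix(pairs)
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    s <- ld_stats(panel, pairs[r, 1L], pairs[r, 2L])
    data.frame(id_i = panel$variants$id[.resolve_variant(panel, pairs[r, 1L])],
               id_j = panel$variants$id[.resolve_variant(panel, pairs[r, 2L])],
               D = s$D, D_prime = s$D_prime, r2 = s$r2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Joint genotype-frequency table of two variants
#'
#' Empirical 3 x 3 table `P(G_i = a, D_j = b)` of the genotype of a candidate
#' variant against the genotype of a (possibly virtual) disease variant,
#' computed over the same individuals.  This genotype-level table carries the
#' allelic LD *and* any deviation from Hardy-Weinberg equilibrium present in
#' the sample, which is exactly what the case-expectation formula consumes.
#'
#' @param g_i,d_j integer genotype vectors (values 0/1/2) of equal length.
#' @return an object of class `joint_genotype_freq`: list with `table` (3 x 3
#'   matrix, rows = candidate genotype 0/1/2, columns = disease genotype
#'   0/1/2), `margin_g`, `margin_d` and `n`.
#' @export
joint_genotype_freq <- function(g_i, d_j) {
  if (length(g_i) == 0L) stop("empty genotype vectors")
  if (length(g_i) != length(d_j)) stop("genotype vectors differ in length")
  stopifnot(all(g_i %in% 0:2), all(d_j %in% 0:2))
  tab <- table(factor(g_i, levels = 0:2), factor(d_j, levels = 0:2))
  tab <- matrix(as.numeric(tab) / length(g_i), 3L, 3L,
                dimnames = list(G = .GENO_LEVELS, D = .GENO_LEVELS))
  structure(list(table = tab,
                 margin_g = rowSums(tab),
                 margin_d = colSums(tab),
                 n = length(g_i)),
            class = "joint_genotype_freq")
}
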