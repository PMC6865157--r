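#' @keywords internal
"_PACKAGE"

# genotype category labels used throughout: index 1,2,3 <-> 0,1,2 copies of
# the coded (minor/disease) allele
.GENO_LEVELS <- c("0", "1", "2")

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample from a set of indices; safe for length-1 sets (base sample() would
# expand a single integer x to 1:x)
.sample_idx <- function(x, n, replace = TRUE) {
  x[sample.int(length(x), n, replace = replace)]
}

.set_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

#' Tabulate a genotype vector into counts of the three genotype classes
#'
#' @param g integer vector with values in 0/1/2 (copies of the coded allele).
#' @return integer vector of length 3, counts of genotypes 0, 1 and 2.
#' @keywords internal
.geno_counts <- function(g) {
  stopifnot(all(g %in% 0:2))
  counts <- tabulate(g + 1L, nbins = 3L)
  names(counts) <- .GENO_LEVELS
  counts
}

# convert an (DD, Dd, dd) triple used by the SCC calculus into genotype-order
# probabilities (0, 1, 2 copies of the disease allele), and back
.triple_to_geno <- function(triple) {
  stopifnot(length(triple) == 3L)
  p <- rev(as.numeric(triple))
  names(p) <- .GENO_LEVELS
  p
}

.geno_to_triple <- function(p) {
  stopifnot(length(p) == 3L)
  out <- rev(as.numeric(p))
  names(out) <- c("DD", "Dd", "dd")
  out
}

.check_simplex <- function(p, what = "frequencies", tol = 1e-8) {
  if (any(p < -tol) || abs(sum(p) - 1) > tol) {
    stop(sprintf("%s must be non-negative and sum to 1 (sum = %.12g)",
                 what, sum(p)), call. = FALSE)
  }
  invisible(TRUE)
}
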