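#' Collapse putative disease variants into one virtual disease variant
#'
#' When all disease variants in a gene have the same defective effect, a
#' haplotype is a disease haplotype as soon as it carries a minor allele at
#' any member variant; carrying two or more still counts once.  The region
#' therefore behaves as if it contained a single composite ("virtual")
#' disease variant, defined on haplotypes first; individual genotypes (0, 1
#' or 2 disease haplotypes) follow from the phased pairs.  Defining the
#' collapse at the haplotype level, not on genotypes, makes compound
#' heterozygotes (two different member alleles on opposite haplotypes) count
#' as two disease haplotypes, which is what the same-effect assumption
#' implies.
#'
#' @param panel a `haplotype_panel`.
#' @param members variant indices or ids; order is irrelevant.
#' @return an object of class `virtual_variant`: list with `members`
#'   (resolved indices), `hap` (0/1 disease-haplotype indicator over panel
#'   haplotype rows), `genotypes` (0/1/2 per individual) and `freq` (disease
#'   haplotype frequency).
#' @examples
#' h <- matrix(c(0, 1, 0, 0, 0, 0, 1, 0), nrow = 4)
#' v <- collapse_variants(haplotype_panel(h), c(1, 2))
#' v$freq  # disjoint carriers: frequencies add
#' @export
collapse_variants <- function(panel, members) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (length(members) == 0L) stop("member set must be non-empty")
  members <- sort(unique(.resolve_variant(panel, members)))
  sub <- panel$hap[, members, drop = FALSE]
  hap <- as.integer(rowSums(sub) > 0L)
  geno <- hap[seq(1L, length(hap), 2L)] + hap[seq(2L, length(hap), 2L)]
  structure(list(members = members,
                 hap = hap,
                 genotypes = geno,
                 freq = mean(hap)),
            class = "virtual_variant")
}

#' @export
print.virtual_variant <- function(x, ...) {
  cat(sprintf("<virtual_variant> members {%s}, disease-haplotype freq %.4g\n",
              paste(x$members, collapse = ", "), x$freq))
  invisible(x)
}
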