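#' Sufficient-causal-component (SCC) disease models
#'
#' Under the SCC view, a complex disease occurs whenever any one sufficient
#' cause (a gene-gene or gene-environment combination) is completed.  A gene
#' region contributes one causal component: individuals carrying a disease
#' genotype at the (virtual) disease variant can develop the disease through
#' the focal cause, accounting for a proportion `y` of the population
#' lifetime incidence (PLI); everyone remains exposed to the other causes.
#' The functions here map between the causal proportion `y`, the allelic odds
#' ratio, case genotype frequencies, and penetrance, for dominant (DD and Dd
#' are disease genotypes) and recessive (DD only) variants.
#'
#' Genotype triples are always in the order `(P_DD, P_Dd, P_dd)` where `D`
#' is the disease allele.
#'
#' @param variants integer indices (or character ids) of the putative disease
#'   variants in a region.
#' @param mode `"dominant"` or `"recessive"`.
#' @param or allelic odds ratio (case vs control odds of the disease allele);
#'   supply exactly one of `or` and `y`.
#' @param y proportion of the focal sufficient cause in the PLI, in `[0, 1]`.
#' @param pli population lifetime incidence (default 0.01).
#' @return `disease_model()` returns an object of class `disease_model`.
#' @export
disease_model <- function(variants, mode = c("dominant", "recessive"),
                          or = NULL, y = NULL, pli = 0.01) {
  mode <- match.arg(mode)
  if (length(variants) == 0L) stop("a disease model needs at least one variant")
  if (is.null(or) == is.null(y)) {
    stop("supply exactly one of `or` and `y`")
  }
  if (!is.null(y) && (y < 0 || y > 1)) stop("y must lie in [0, 1]")
  if (!is.null(or) && or < 1) stop("or must be >= 1")
  stopifnot(pli > 0, pli < 1)
  structure(list(variants = variants, mode = mode, or = or, y = y, pli = pli),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  eff <- if (!is.null(x$or)) sprintf("OR = %g", x$or) else sprintf("y = %g", x$y)
  cat(sprintf("<disease_model> {%s}, %s, %s, PLI = %g\n",
              paste(x$variants, collapse = ", "), x$mode, eff, x$pli))
  invisible(x)
}

.disease_mass <- function(control_freqs, mode) {
  if (mode == "dominant") control_freqs[1L] + control_freqs[2L]
  else control_freqs[1L]
}

.check_triple <- function(control_freqs) {
  stopifnot(length(control_freqs) == 3L)
  .check_simplex(control_freqs, "a genotype triple")
}

#' Case genotype frequencies implied by a causal proportion
#'
#' In the case population the disease genotypes gain the causal mass `y`,
#' apportioned by their shares among disease genotypes in the control
#' population, while normal genotypes are scaled by `1 - y`:
#' for a disease genotype `g`, `P'_g = (1 - y) P_g + y P_g / S` with
#' `S` the total control mass of disease genotypes; for a normal genotype,
#' `P'_g = (1 - y) P_g`.  For a recessive variant the single disease genotype
#' DD receives the whole mass `y` even when `P_DD = 0` in controls (the case
#' homozygotes then arise from pairing two disease haplotypes).
#'
#' @param control_freqs genotype triple `(P_DD, P_Dd, P_dd)` in controls
#'   (taken as the population frequencies; the PLI is assumed small).
#' @param y causal proportion in `[0, 1]`.
#' @param mode `"dominant"` or `"recessive"`.
#' @return the case genotype triple `(P'_DD, P'_Dd, P'_dd)`.
#' @examples
#' case_genotype_freqs(c(0.09, 0.42, 0.49), y = 0.2, mode = "dominant")
#' @export
case_genotype_freqs <- function(control_freqs, y,
                                mode = c("dominant", "recessive")) {
  mode <- match.arg(mode)
  .check_triple(control_freqs)
  stopifnot(y >= 0, y <= 1)
  p <- as.numeric(control_freqs)
  if (y == 0) {
    out <- p
  } else if (mode == "dominant") {
    s <- p[1L] + p[2L]
    if (s == 0) stop("no disease genotypes in controls: model unsatisfiable")
    out <- c((1 - y) * p[1L] + y * p[1L] / s,
             (1 - y) * p[2L] + y * p[2L] / s,
             (1 - y) * p[3L])
  } else {
    if (p[1L] + p[2L] / 2 == 0) {
      stop("disease allele absent from controls: model unsatisfiable")
    }
    out <- c((1 - y) * p[1L] + y, (1 - y) * p[2L], (1 - y) * p[3L])
  }
  names(out) <- c("DD", "Dd", "dd")
  out
}

.allele_freq_of_triple <- function(triple) triple[1L] + triple[2L] / 2

#' Allelic odds ratio implied by a causal proportion
#'
#' `OR = [p'/(1 - p')] / [p/(1 - p)]` where `p` and `p'` are the disease
#' allele frequencies in controls and cases implied by the genotype triples.
#'
#' @inheritParams case_genotype_freqs
#' @return the allelic odds ratio (>= 1 for `y > 0`).
#' @examples
#' # HWE at allele frequency 0.3, causal proportion 0.2: OR is 1.3
#' or_from_y(c(0.09, 0.42, 0.49), y = 0.2, mode = "dominant")
#' @export
or_from_y <- function(control_freqs, y, mode = c("dominant", "recessive")) {
  mode <- match.arg(mode)
  .check_triple(control_freqs)
  p <- .allele_freq_of_triple(as.numeric(control_freqs))
  if (p <= 0 || p >= 1) stop("control disease-allele frequency must lie in (0, 1)")
  pp <- .allele_freq_of_triple(case_genotype_freqs(control_freqs, y, mode))
  unname((pp / (1 - pp)) / (p / (1 - p)))
}

#' Largest feasible dominant odds ratio
#'
#' For a dominant variant the causal proportion reaches `y = 1` at
#' `OR = 2 (1 - P_DD) / P_Dd - 1`; larger odds ratios would require `y > 1`
#' and are infeasible for those genotype frequencies.
#'
#' @param control_freqs genotype triple `(P_DD, P_Dd, P_dd)`; `P_Dd` must be
#'   positive.
#' @return the bound `2 (1 - P_DD) / P_Dd - 1`.
#' @export
max_dominant_or <- function(control_freqs) {
  .check_triple(control_freqs)
  if (control_freqs[2L] == 0) stop("P_Dd = 0: dominant OR bound is undefined")
  unname(2 * (1 - control_freqs[1L]) / control_freqs[2L] - 1)
}

#' Causal proportion implied by an allelic odds ratio
#'
#' Inverse of [or_from_y()].  Closed forms: with control disease-allele
#' frequency `p` and case frequency `p'` recovered from the odds ratio,
#' a dominant variant satisfies `p' = p (1 + y (1 - S)/S)` with
#' `S = P_DD + P_Dd`, and a recessive variant `p' = (1 - y) p + y`.
#'
#' @inheritParams max_dominant_or
#' @param or allelic odds ratio, `>= 1`.
#' @param mode `"dominant"` or `"recessive"`.
#' @return the causal proportion `y` in `[0, 1]`; dominant odds ratios beyond
#'   [max_dominant_or()] raise an error naming the bound.
#' @export
y_from_or <- function(control_freqs, or, mode = c("dominant", "recessive")) {
  mode <- match.arg(mode)
  .check_triple(control_freqs)
  if (or < 1) stop("or must be >= 1")
  p <- .allele_freq_of_triple(as.numeric(control_freqs))
  if (p <= 0 || p >= 1) stop("control disease-allele frequency must lie in (0, 1)")
  odds <- p / (1 - p)
  pp <- or * odds / (1 + or * odds)
  if (mode == "dominant") {
    s <- .disease_mass(control_freqs, mode)
    if (s >= 1) {
      if (or > 1) stop("all controls carry disease genotypes: OR > 1 infeasible")
      return(0)
    }
    y <- (pp / p - 1) * s / (1 - s)
    if (y > 1 + 1e-12) {
      stop(sprintf(paste0("OR = %g infeasible for a dominant variant with ",
                          "these genotype frequencies (bound 2(1-P_DD)/P_Dd - 1 ",
                          "= %.6g)"), or, max_dominant_or(control_freqs)))
    }
  } else {
    y <- (pp - p) / (1 - p)
  }
  unname(min(max(y, 0), 1))
}

#' Penetrance of a disease genotype under the SCC model
#'
#' Probability of disease given a disease genotype: the focal sufficient
#' cause contributes risk `y * pli / S`, where `S` is the control mass of
#' disease genotypes (the causal mass `y * pli` concentrated on carriers of a
#' disease genotype), and the aggregate of all other causes contributes the
#' background risk `(1 - y) * pli` independently of genotype.  The two cause
#' groups act as independent mechanisms, so the risks combine as a union of
#' independent events.
#'
#' @inheritParams case_genotype_freqs
#' @param pli population lifetime incidence, in `(0, 1)`.
#' @return probability of disease for a carrier of a disease genotype;
#'   decreasing in the disease-genotype frequency at fixed `y * pli`.
#' @export
penetrance <- function(control_freqs, y, pli,
                       mode = c("dominant", "recessive")) {
  mode <- match.arg(mode)
  .check_triple(control_freqs)
  stopifnot(y >= 0, y <= 1, pli > 0, pli < 1)
  s <- .disease_mass(control_freqs, mode)
  if (s == 0) stop("zero disease-genotype mass: penetrance is undefined")
  focal <- y * pli / s
  if (focal > 1) {
    stop("y * pli exceeds the disease-genotype frequency: model unsatisfiable")
  }
  background <- (1 - y) * pli
  unname(focal + background - focal * background)
}

#' Odds-ratio-versus-frequency curves
#'
#' Evaluates the allelic odds ratio over a grid of disease-allele frequencies
#' (genotypes at Hardy-Weinberg proportions) and causal proportions, for
#' dominant and/or recessive variants.
#'
#' @param freqs disease-allele frequencies in `(0, 1)`.
#' @param y_values causal proportions in `[0, 1]`.
#' @param modes character vector among `"dominant"`, `"recessive"`.
#' @param path optional TSV output path.
#' @return data.frame with columns mode, freq, y, or (NA where infeasible,
#'   which cannot occur on the forward map but is kept for symmetry).
#' @export
or_curve <- function(freqs = seq(0.01, 0.99, by = 0.01),
                     y_values = c(0.05, 0.1, 0.2, 0.5),
                     modes = c("dominant", "recessive"), path = NULL) {
  grid <- expand.grid(mode = modes, freq = freqs, y = y_values,
                      stringsAsFactors = FALSE)
  grid$or <- mapply(function(m, q, y) {
    or_from_y(c(q^2, 2 * q * (1 - q), (1 - q)^2), y, m)
  }, grid$mode, grid$freq, grid$y)
  if (!is.null(path)) {
    utils::write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  grid
}
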