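#' Configuration for synthetic haplotype panels
#'
#' A panel configuration is an explicit haplotype pool: a set of distinct
#' haplotypes with population frequencies.  Encoding LD through an explicit
#' pool (rather than a coalescent simulation) makes every target allele
#' frequency and pairwise r-squared an analytic function of the pool, so the
#' generator can be verified exactly.
#'
#' @param haplotypes 0/1 matrix, one row per pool haplotype, one column per
#'   variant.
#' @param freqs population frequency of each pool haplotype; must sum to 1.
#' @param variants optional variant metadata (`data.frame` with `id`, and
#'   optionally `pos`, `ref`, `alt`).
#' @param seed default RNG seed carried by the configuration.
#' @return an object of class `panel_config`.
#' @export
panel_config <- function(haplotypes, freqs, variants = NULL, seed = NULL) {
  haplotypes <- as.matrix(haplotypes)
  stopifnot(all(haplotypes %in% c(0, 1)), length(freqs) == nrow(haplotypes),
            all(freqs >= 0))
  if (abs(sum(freqs) - 1) > 1e-8) stop("pool frequencies must sum to 1")
  keep <- freqs > 0
  haplotypes <- haplotypes[keep, , drop = FALSE]
  freqs <- freqs[keep]
  if (nrow(unique(haplotypes)) < 2L) {
    stop("pool must contain at least 2 distinct haplotypes")
  }
  if (is.null(variants)) {
    ids <- colnames(haplotypes) %||% paste0("v", seq_len(ncol(haplotypes)))
    variants <- data.frame(id = ids, stringsAsFactors = FALSE)
  }
  colnames(haplotypes) <- variants$id
  structure(list(haplotypes = haplotypes, freqs = freqs,
                 variants = variants, seed = seed),
            class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat(sprintf("<panel_config> %d pool haplotypes x %d variants\n",
              nrow(x$haplotypes), ncol(x$haplotypes)))
  invisible(x)
}

#' Pool-implied allele frequencies and LD
#'
#' Exact population values implied by a haplotype pool, against which
#' sampled panels converge as the panel grows.
#'
#' @param config a [panel_config()].
#' @param i,j variant ids or indices.
#' @return `pool_freqs()`: named vector of coded-allele frequencies;
#'   `pool_ld_stats()`: list with `D`, `D_prime`, `r2` as in [ld_stats()].
#' @export
pool_freqs <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  f <- colSums(config$haplotypes * config$freqs)
  names(f) <- config$variants$id
  f
}

#' @rdname pool_freqs
#' @export
pool_ld_stats <- function(config, i, j) {
  stopifnot(inherits(config, "panel_config"))
  ids <- config$variants$id
  i <- if (is.character(i)) match(i, ids) else i
  j <- if (is.character(j)) match(j, ids) else j
  stopifnot(!is.na(i), !is.na(j), i != j)
  h <- config$haplotypes
  p_i <- sum(h[, i] * config$freqs)
  p_j <- sum(h[, j] * config$freqs)
  p_ij <- sum(h[, i] * h[, j] * config$freqs)
  D <- p_ij - p_i * p_j
  d_max <- if (D >= 0) min(p_i * (1 - p_j), (1 - p_i) * p_j)
  else min(p_i * p_j, (1 - p_i) * (1 - p_j))
  list(D = D,
       D_prime = if (D == 0) 0 else abs(D) / d_max * sign(D),
       r2 = D^2 / (p_i * (1 - p_i) * p_j * (1 - p_j)),
       p_i = p_i, p_j = p_j)
}

#' Draw a synthetic haplotype panel from a pool
#'
#' Haplotypes are drawn multinomially from the pool and paired at random
#' into individuals, so observed genotype frequencies deviate naturally from
#' Hardy-Weinberg proportions exactly as random union of gametes implies.
#' If a drawn panel is monomorphic at any variant (possible for very rare
#' alleles in small panels) the whole panel is redrawn, keeping the variant
#' set stable; the redraw count is reported via `message()`.
#'
#' @param config a [panel_config()].
#' @param n_individuals number of diploid individuals (>= 2).
#' @param seed RNG seed; defaults to the seed stored in the configuration.
#'   Identical seeds give identical panels.
#' @param max_redraws redraw attempts before giving up.
#' @return a `haplotype_panel`.
#' @export
synth_panel <- function(config, n_individuals, seed = NULL,
                        max_redraws = 100L) {
  stopifnot(inherits(config, "panel_config"))
  if (n_individuals < 2L) stop("n_individuals must be at least 2")
  pf <- pool_freqs(config)
  if (any(pf == 0) || any(pf == 1)) {
    stop("pool-monomorphic variant(s): ",
         paste(config$variants$id[pf == 0 | pf == 1], collapse = ", "))
  }
  .set_seed(seed %||% config$seed)
  n_hap <- 2L * n_individuals
  for (attempt in seq_len(max_redraws)) {
    rows <- sample.int(nrow(config$haplotypes), n_hap, replace = TRUE,
                       prob = config$freqs)
    hap <- config$haplotypes[rows, , drop = FALSE]
    f <- colMeans(hap)
    if (all(f > 0 & f < 1)) {
      if (attempt > 1L) message(attempt - 1L, " monomorphic redraw(s)")
      return(haplotype_panel(hap, config$variants))
    }
  }
  stop("could not draw a polymorphic panel in ", max_redraws, " attempts")
}

#' Built-in APOE-like panel configuration
#'
#' A 13-variant haplotype pool emulating the statistical structure of the
#' APOE gene region in phase 1 of the 1000 Genomes Project (1092
#' individuals): a minor-allele-frequency spectrum from 0.004 to 0.51
#' including the frequencies 0.00412, 0.00592, 0.00870, 0.082, 0.149, 0.325
#' and 0.510; designated pairs in strong LD with r-squared targets 0.446
#' (no18-no7), 0.502 (no15-no23), 0.410 (no15-no33), 0.768 (no22-no2) and
#' 0.77 (no28-no29); and rare alleles riding on common haplotype backgrounds
#' (D' = 1 with their background variant, r-squared near 0).  All targets
#' hold exactly at the pool level (see [pool_freqs()], [pool_ld_stats()]);
#' sampled panels match them to within sampling noise.
#'
#' @param seed default seed stored in the configuration.
#' @return a [panel_config()] with attribute `ld_targets` (data.frame of the
#'   designated pairs and their r-squared targets).
#' @export
apoe_like_config <- function(seed = NULL) {
  p7 <- 0.510; p18 <- 0.325
  p15 <- 0.082; p23 <- 0.149
  p16 <- 0.00412; p22 <- 0.00592; p10 <- 0.0087
  p28 <- 0.005; p26 <- 0.0304; p31 <- 0.051

  # overlap giving a target r2 between variants with fixed frequencies
  ov <- function(pa, pb, r2) {
    pa * pb + sqrt(r2 * pa * (1 - pa) * pb * (1 - pb))
  }
  ov_18_7 <- ov(p18, p7, 0.446)
  ov_15_23 <- ov(p15, p23, 0.502)
  # frequency of a fully nesting partner giving a target r2
  nest <- function(pa, r2) pa / (r2 * (1 - pa) + pa)
  p33 <- nest(p15, 0.410)   # no15 fully nested in no33
  p2 <- nest(p22, 0.768)    # no22 fully nested in no2
  p29 <- nest(p28, 0.770)   # no28 fully nested in no29

  ids <- c("no2", "no7", "no10", "no15", "no16", "no18", "no22", "no23",
           "no26", "no28", "no29", "no31", "no33")
  classes <- list(                       # carrier sets and frequencies
    list(c("no7", "no16", "no18"), p16),
    list(c("no7", "no18"),         ov_18_7 - p16),
    list(c("no18"),                p18 - ov_18_7),
    list(c("no7", "no10"),         p10),
    list(c("no7", "no31"),         p31),
    list(c("no7"),                 p7 - ov_18_7 - p10 - p31),
    list(c("no15", "no23", "no33"), ov_15_23),
    list(c("no15", "no33"),        p15 - ov_15_23),
    list(c("no2", "no22", "no23"), p22),
    list(c("no2", "no23"),         p2 - p22),
    list(c("no23"),                p23 - ov_15_23 - p2),
    list(c("no28", "no29", "no33"), p28),
    list(c("no29", "no33"),        p29 - p28),
    list(c("no33"),                p33 - p15 - p29),
    list(c("no26"),                p26)
  )
  freqs <- vapply(classes, function(x) x[[2L]], numeric(1L))
  stopifnot(all(freqs > 0), sum(freqs) < 1)
  hap <- t(vapply(classes, function(x) as.integer(ids %in% x[[1L]]),
                  integer(length(ids))))
  hap <- rbind(hap, rep(0L, length(ids)))           # all-major background
  freqs <- c(freqs, 1 - sum(freqs))

  num <- as.integer(sub("^no", "", ids))
  variants <- data.frame(id = ids,
                         pos = 45409000L + 50L * num,
                         ref = "A", alt = "T",
                         stringsAsFactors = FALSE)
  cfg <- panel_config(hap, freqs, variants, seed = seed)
  attr(cfg, "ld_targets") <- data.frame(
    id_i = c("no18", "no15", "no15", "no22", "no28"),
    id_j = c("no7", "no23", "no33", "no2", "no29"),
    r2 = c(0.446, 0.502, 0.410, 0.768, 0.770),
    stringsAsFactors = FALSE)
  cfg
}
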