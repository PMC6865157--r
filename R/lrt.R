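#' Convert an SCC genotype triple to genotype-order probabilities
#'
#' SCC functions use triples `(P_DD, P_Dd, P_dd)`; panel-level genotype
#' vectors count copies of the coded/disease allele (0, 1, 2).  This helper
#' maps between the two orders.
#'
#' @param triple length-3 vector `(P_DD, P_Dd, P_dd)`.
#' @return length-3 vector of probabilities for genotypes 0, 1, 2.
#' @export
geno_probs <- function(triple) .triple_to_geno(triple)

#' Expected case genotype frequencies of a candidate variant
#'
#' The genotype frequencies of a candidate variant shift in cases through the
#' genotype-level LD with the disease variant:
#' `pi_i = sum_j P(G_i D_j) / P(D_j) * P(D'_j)`,
#' i.e. each control conditional `P(G_i | D_j)` is reweighted by the case
#' frequency of the disease genotype `D_j`.  Because the joint table is
#' taken at the genotype level, sample deviations from Hardy-Weinberg
#' equilibrium propagate into the expectation instead of being idealised
#' away.
#'
#' @param joint a [joint_genotype_freq()] of the candidate against the
#'   (virtual) disease variant, computed on controls.
#' @param disease_case_freqs length-3 vector `P(D'_j)` of disease-variant
#'   genotype frequencies in cases, in genotype order (0, 1, 2 disease
#'   alleles); see [geno_probs()] to convert an SCC triple.
#' @return an object of class `case_expectation`: list with `pi` (length-3
#'   expected case genotype frequencies of the candidate), and the inputs.
#' @export
expected_case_freqs <- function(joint, disease_case_freqs) {
  if (inherits(joint, "joint_genotype_freq")) {
    tab <- joint$table
  } else {
    tab <- as.matrix(joint)
    stopifnot(all(dim(tab) == c(3L, 3L)))
  }
  pd <- as.numeric(disease_case_freqs)
  .check_simplex(pd, "disease_case_freqs")
  margin_d <- colSums(tab)
  bad <- margin_d == 0 & pd > 0
  if (any(bad)) {
    stop("disease genotype ", paste(which(bad) - 1L, collapse = ", "),
         " has case frequency > 0 but control frequency 0: ",
         "case genotype unreachable")
  }
  pi <- numeric(3L)
  for (j in which(pd > 0)) {
    pi <- pi + tab[, j] / margin_d[j] * pd[j]
  }
  names(pi) <- .GENO_LEVELS
  structure(list(pi = pi, disease_case_freqs = pd, joint = tab),
            class = "case_expectation")
}

#' Model-based multinomial covariance of genotype counts
#'
#' Covariance of the genotype counts of one variant among `n` cases under
#' the expected frequencies `pi`, restricted to the first `k - 1` genotype
#' categories (the last is determined by the others).  Categories with zero
#' expected frequency are dropped, reducing `k` and the degrees of freedom
#' accordingly.
#'
#' @param pi expected genotype frequencies (a simplex, length 3 or `k`).
#' @param n number of cases (>= 1).
#' @return covariance matrix of dimension `(k - 1) x (k - 1)` with
#'   attributes `categories` (indices of retained categories of `pi`) and
#'   `df` (`k - 1`).
#' @export
multinomial_covariance <- function(pi, n) {
  .check_simplex(pi, "pi")
  stopifnot(n >= 1)
  cats <- which(pi > 0)
  k <- length(cats)
  if (k < 2L) {
    sigma <- matrix(numeric(0), 0L, 0L)
    attr(sigma, "categories") <- cats
    attr(sigma, "df") <- 0L
    return(sigma)
  }
  p <- pi[cats][seq_len(k - 1L)]
  sigma <- n * (diag(p, nrow = k - 1L) - outer(p, p))
  attr(sigma, "categories") <- cats
  attr(sigma, "df") <- k - 1L
  sigma
}

# ---------------------------------------------------------------------------
# conditional genotype tables and the resampling engine

# Per-candidate conditional P(G = g | D = j) of candidate genotype given the
# virtual disease genotype, from control individuals.  The per-stratum
# empirical table is the estimate: it carries the sample's joint genotype
# composition, including its deviation from Hardy-Weinberg proportions,
# which is what keeps the test calibrated when cases and controls are drawn
# from the same finite population.  A disease-genotype class with no control
# carriers at all (typically the rare homozygote) is reconstructed by random
# union of gametes from the control haplotype pool: genotype class j pairs j
# disease haplotypes with 2 - j normal ones -- the same construction the
# simulation design uses for rare homozygotes missing from the panel.
#
# Returns an array [3 genotype categories, 3 disease genotypes, V candidates].
.cond_given_disease <- function(ctl, virt, candidates, need = rep(TRUE, 3L)) {
  G <- genotypes(ctl)[, candidates, drop = FALSE]
  V <- ncol(G)
  vg <- virt$genotypes
  cond <- array(NA_real_, dim = c(3L, 3L, V))
  dh <- virt$hap == 1L
  if (!any(dh) || all(dh)) stop("virtual variant monomorphic in controls")
  f1 <- colMeans(ctl$hap[dh, candidates, drop = FALSE])   # allele freq on disease haps
  f0 <- colMeans(ctl$hap[!dh, candidates, drop = FALSE])  # allele freq on normal haps
  pair_cond <- function(fa, fb) {
    rbind((1 - fa) * (1 - fb), fa * (1 - fb) + fb * (1 - fa), fa * fb)
  }
  for (j in 0:2) {
    if (!need[j + 1L]) next
    idx <- which(vg == j)
    if (length(idx) > 0L) {
      sub <- G[idx, , drop = FALSE]
      cond[, j + 1L, ] <- rbind(colMeans(sub == 0L),
                                colMeans(sub == 1L),
                                colMeans(sub == 2L))
    } else {
      cond[, j + 1L, ] <- switch(as.character(j),
                                 "0" = pair_cond(f0, f0),
                                 "1" = pair_cond(f1, f0),
                                 "2" = pair_cond(f1, f1))
    }
  }
  cond
}

# Group genotype categories so that every group has positive expected
# frequency: a category with pi = 0 is merged into its nearest category with
# pi > 0 (the heterozygote class for an empty homozygote class and vice
# versa).  A finite control sample often assigns expectation 0 to a rare
# homozygote class that real cases can still reach; merging counts such an
# observation as carrier-class evidence instead of declaring the model
# impossible, and gives rare variants their natural two-category test
# (k = 2, df = 1).
.merge_zero_categories <- function(pi) {
  nz <- which(pi > 0)
  if (length(nz) == 0L) return(list())
  groups <- vector("list", length(nz))
  for (g in seq_along(pi)) {
    host <- which.min(abs(nz - g))  # ties resolve to the lower category
    groups[[host]] <- c(groups[[host]], g)
  }
  groups
}

.group_sums <- function(x, groups) {
  vapply(groups, function(g) sum(x[g]), numeric(1L))
}

# Per-replicate grouped G-sums over the informative candidates, evaluated on
# the engine's pseudo-case counts against its per-replicate expectations.
# This is the resampling null of the region total.  A replicate expectation
# that collapses to 0 on a group (the redrawn pseudo-controls lost every
# carrier) is floored at the full-sample group probability.
.pseudo_totals <- function(eng, groups_list, pg_list, informative, n) {
  counts <- eng$counts
  pihat <- (eng$counts - eng$dev) / n
  V <- eng$V
  tot <- numeric(nrow(counts))
  for (vi in which(informative)) {
    groups <- groups_list[[vi]]
    og <- vapply(groups, function(g) {
      rowSums(counts[, (g - 1L) * V + vi, drop = FALSE])
    }, numeric(nrow(counts)))
    pg <- vapply(groups, function(g) {
      rowSums(pihat[, (g - 1L) * V + vi, drop = FALSE])
    }, numeric(nrow(counts)))
    pfix <- matrix(pg_list[[vi]], nrow(pg), length(groups), byrow = TRUE)
    bad <- pg <= 0
    pg[bad] <- pfix[bad]
    term <- og * log(og / (n * pg))
    term[og == 0] <- 0
    tot <- tot + 2 * rowSums(term)
  }
  tot
}

# Tabulate sampled individual indices into a reps x m count matrix.
.draw_matrix <- function(idx, repid, reps, m) {
  matrix(tabulate(repid + reps * (idx - 1L), nbins = reps * m), reps, m)
}

# Resampling engine behind the simulated variance.
#
# Each replicate reconstructs a pseudo-case sample of size n from the control
# panel: the observed disease-genotype classes are refilled by random union
# of gametes from the control haplotype pool (genotype class j pairs j
# disease haplotypes with 2 - j normal ones, the same construction that
# rebuilds rare homozygotes absent from the controls), so the candidate
# genotype counts of class j are multinomial draws from the pairing
# conditional.  Each replicate also redraws a pseudo-control sample of the
# same size (whole individuals, with replacement) and recomputes the
# expected case frequencies from its haplotype pool, so the spread of
# (counts - n * pi_hat_r) carries the sampling error of the finite control
# panel on top of the multinomial case noise.  The disease-genotype counts
# are held at their observed values: the test statistic conditions on them
# through P(D').
#
# Returns a list with `dev` (reps x 3V matrix of count deviations; column
# (g, v) at g * V + v) and bookkeeping fields.
.resample_case_dev <- function(ctl, virt, nD, candidates, reps,
                               resample_strata = FALSE,
                               resample_controls = TRUE) {
  m <- n_individuals(ctl)
  V <- length(candidates)
  n <- sum(nD)
  pD <- nD / n
  vg <- virt$genotypes
  fallback <- vapply(0:2, function(j) nD[j + 1L] > 0L && !any(vg == j),
                     logical(1L))

  cond_fix <- .cond_given_disease(ctl, virt, candidates, need = pD > 0)

  # disease-genotype counts per replicate (held at the observed counts unless
  # the strata are explicitly redrawn)
  nDr <- if (resample_strata) {
    t(stats::rmultinom(reps, n, pD))
  } else {
    matrix(rep(nD, each = reps), reps, 3L)
  }

  # pseudo-case counts: genotype-matched control individuals fill each
  # disease-genotype class (so cross-variant correlation within individuals
  # is preserved); classes with no control carrier are reconstructed by
  # pairing haplotypes from the control pool
  G <- genotypes(ctl)[, candidates, drop = FALSE]
  I3 <- cbind(G == 0L, G == 1L, G == 2L) * 1  # m x 3V
  hap <- ctl$hap[, candidates, drop = FALSE]
  dh_rows <- which(virt$hap == 1L)
  nh_rows <- which(virt$hap == 0L)
  counts <- matrix(0, reps, 3L * V)
  S_case <- matrix(0, reps, m)
  for (j in 0:2) {
    tot_j <- nDr[, j + 1L]
    if (sum(tot_j) == 0L) next
    repid <- rep(seq_len(reps), times = tot_j)
    sj <- which(vg == j)
    if (length(sj) > 0L) {
      idx <- .sample_idx(sj, sum(tot_j))
      S_case <- S_case + .draw_matrix(idx, repid, reps, m)
    } else {
      ndraw <- sum(tot_j)
      h1 <- hap[.sample_idx(dh_rows, ndraw), , drop = FALSE]
      pool2 <- if (j == 2L) dh_rows else nh_rows
      h2 <- hap[.sample_idx(pool2, ndraw), , drop = FALSE]
      gp <- h1 + h2
      for (g in 0:2) {
        add <- rowsum((gp == g) * 1, group = repid)
        rows <- as.integer(rownames(add))
        counts[rows, g * V + seq_len(V)] <-
          counts[rows, g * V + seq_len(V)] + add
      }
    }
  }
  counts <- counts + S_case %*% I3

  # expectation per replicate: the same hybrid construction as
  # .cond_given_disease, recomputed from each redrawn pseudo-control sample
  if (resample_controls) {
    cidx <- sample.int(m, reps * m, replace = TRUE)
    S_ctl <- .draw_matrix(cidx, rep(seq_len(reps), times = m), reps, m)
    # per-individual allele sums on disease / normal haplotypes
    two <- seq(2L, 2L * m, by = 2L)
    one <- two - 1L
    vh <- virt$hap
    Dv <- ctl$hap[one, candidates, drop = FALSE] * vh[one] +
      ctl$hap[two, candidates, drop = FALSE] * vh[two]
    Nv <- ctl$hap[one, candidates, drop = FALSE] * (1 - vh[one]) +
      ctl$hap[two, candidates, drop = FALSE] * (1 - vh[two])
    ndh <- vh[one] + vh[two]
    dtot <- as.numeric(S_ctl %*% ndh)
    ntot <- as.numeric(S_ctl %*% (2L - ndh))
    f1r <- (S_ctl %*% Dv) / pmax(dtot, 1)
    f0r <- (S_ctl %*% Nv) / pmax(ntot, 1)
    # replicates whose redraw lost all disease (or normal) haplotypes fall
    # back to the full-control frequencies
    dh <- vh == 1L
    if (any(dtot == 0)) {
      f1r[dtot == 0, ] <- matrix(colMeans(ctl$hap[dh, candidates,
                                                  drop = FALSE]),
                                 sum(dtot == 0), V, byrow = TRUE)
    }
    if (any(ntot == 0)) {
      f0r[ntot == 0, ] <- matrix(colMeans(ctl$hap[!dh, candidates,
                                                  drop = FALSE]),
                                 sum(ntot == 0), V, byrow = TRUE)
    }
    vcols <- seq_len(V)
    pihat <- matrix(0, reps, 3L * V)
    for (j in which(pD > 0) - 1L) {
      fa <- if (j >= 1L) f1r else f0r
      fb <- if (j == 2L) f1r else f0r
      pair_j <- cbind((1 - fa) * (1 - fb),
                      fa * (1 - fb) + fb * (1 - fa),
                      fa * fb)
      sj <- which(vg == j)
      if (length(sj) > 0L) {
        Sj <- S_ctl[, sj, drop = FALSE]
        sz <- rowSums(Sj)
        cj <- (Sj %*% I3[sj, , drop = FALSE]) / pmax(sz, 1)
        fill <- cj == 0 & pair_j > 0
        cj[fill] <- pair_j[fill]
        tot <- cj[, vcols] + cj[, V + vcols] + cj[, 2L * V + vcols]
        cj <- cj / cbind(tot, tot, tot)
        if (any(sz == 0)) cj[sz == 0, ] <- pair_j[sz == 0, ]
      } else {
        cj <- pair_j
      }
      pihat <- pihat + pD[j + 1L] * cj
    }
  } else {
    pv <- numeric(3L * V)
    for (j in which(pD > 0)) {
      pv <- pv + pD[j] * c(cond_fix[1L, j, ], cond_fix[2L, j, ],
                           cond_fix[3L, j, ])
    }
    pihat <- matrix(pv, reps, 3L * V, byrow = TRUE)
  }

  list(dev = counts - n * pihat, counts = counts, V = V,
       fallback = fallback, n = n)
}

# covariance determinant of one candidate's deviations over the first
# k - 1 category groups (columns of a group are summed before taking the
# covariance, mirroring the grouping of the observed counts)
.sigma_det <- function(dev, V, v, groups) {
  k <- length(groups)
  if (k < 2L) return(0)
  cols <- vapply(groups[seq_len(k - 1L)], function(g) {
    rowSums(dev[, (g - 1L) * V + v, drop = FALSE])
  }, numeric(nrow(dev)))
  s <- stats::cov(cols)
  det(s)
}

#' Resampling-based covariance determinant of case genotype counts
#'
#' Estimates the covariance determinant `|sigma|` of a candidate variant's
#' case genotype counts by rebuilding pseudo-case samples from the control
#' panel: disease-variant genotype classes are filled with genotype-matched
#' control individuals (pairing two disease haplotypes when a rare genotype
#' class is absent from the controls), and every replicate also redraws a
#' pseudo-control sample from which the expected frequencies are recomputed,
#' so the determinant reflects the sampling error of a finite control panel
#' on top of the multinomial case noise.  All pseudo-cases are
#' genotype-matched to their disease-variant genotype, so any same-genotype
#' quota `enrich` in [0, 1] is satisfied by construction.
#'
#' @param panel_controls a `haplotype_panel` of control individuals.
#' @param model a [disease_model()].
#' @param candidate candidate variant index or id.
#' @param n_cases number of pseudo-cases per replicate.
#' @param reps number of resampling replicates (>= 2; the paper-scale default
#'   is 1000).  Below 100 the result carries attribute `low_precision`.
#' @param enrich fraction of pseudo-cases guaranteed to be drawn from the
#'   same-genotype stratum; recorded for the audit trail (the construction
#'   is fully genotype-matched, satisfying any value).
#' @param seed optional RNG seed; identical seeds give identical results.
#' @return the determinant `|sigma|`, with attributes `df`, `categories`,
#'   `fallback` (which genotype classes used haplotype pairing) and possibly
#'   `low_precision`.
#' @export
simulated_variance <- function(panel_controls, model, candidate, n_cases,
                               reps = 1000L, enrich = 0.2, seed = NULL) {
  stopifnot(inherits(model, "disease_model"), reps >= 2L,
            enrich >= 0, enrich <= 1, n_cases >= 1L)
  .set_seed(seed)
  v <- .resolve_variant(panel_controls, candidate)
  virt <- collapse_variants(panel_controls, model$variants)
  if (virt$freq == 0 || virt$freq == 1) stop("virtual variant monomorphic")
  ctl_triple <- .geno_to_triple(.geno_counts(virt$genotypes) /
                                  length(virt$genotypes))
  y <- model$y %||% y_from_or(ctl_triple, model$or, model$mode)
  pD <- .triple_to_geno(case_genotype_freqs(ctl_triple, y, model$mode))
  nD <- .round_counts(pD, n_cases)
  eng <- .resample_case_dev(panel_controls, virt, nD, candidates = v,
                            reps = reps)
  cond <- .cond_given_disease(panel_controls, virt, v, need = pD > 0)
  pi <- numeric(3L)
  for (j in which(pD > 0)) pi <- pi + pD[j] * cond[, j, 1L]
  groups <- .merge_zero_categories(pi)
  out <- .sigma_det(eng$dev, eng$V, 1L, groups)
  attr(out, "df") <- length(groups) - 1L
  attr(out, "categories") <- groups
  attr(out, "fallback") <- eng$fallback
  attr(out, "enrich") <- enrich
  if (reps < 100L) attr(out, "low_precision") <- TRUE
  out
}

# round expected counts to integers summing to n (largest remainders win)
.round_counts <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Variance-corrected multinomial likelihood-ratio statistic
#'
#' The multinomial log-likelihood ratio of the observed case genotype counts
#' against the model expectation `pi`,
#' `G = 2 sum_i o_i log(o_i / (n pi_i))` (zero observed counts contribute 0),
#' deflated or inflated by the per-dimension variance ratio
#' `(|Sigma| / |sigma|)^(1/(k-1))` of the model-based multinomial covariance
#' `|Sigma|` against the resampling-based `|sigma|`.  When `|sigma| =
#' |Sigma|` the correction is 1 and the plain G-statistic is returned.  A
#' category with zero expected frequency but a positive observed count
#' rejects the model outright (infinite statistic, lower-tail probability 1);
#' zero expected categories otherwise drop out, reducing `k`.
#'
#' @param observed_case_counts length-3 (or length-k) vector of observed case
#'   genotype counts of the candidate variant.
#' @param pi expected case genotype frequencies (same length).
#' @param det_model model-based covariance determinant `|Sigma|` (see
#'   [multinomial_covariance()]).
#' @param det_sim resampling-based determinant `|sigma|`; non-positive values
#'   disable the correction (flagged in the result).
#' @return an object of class `lrt_result`: list with `statistic`, `df`,
#'   `det_sigma_model`, `det_sigma_sim`, `p_lower` (lower-tail chi-square
#'   probability), `g_raw` and `correction`.
#' @export
lrt_statistic <- function(observed_case_counts, pi, det_model = 1,
                          det_sim = 1) {
  o <- as.numeric(observed_case_counts)
  pi <- as.numeric(pi)
  stopifnot(length(o) == length(pi), all(o >= 0))
  .check_simplex(pi, "pi")
  n <- sum(o)
  cats <- which(pi > 0)
  k <- length(cats)
  df <- max(k - 1L, 0L)
  if (any(o > 0 & pi == 0)) {
    return(structure(list(statistic = Inf, df = df,
                          det_sigma_model = det_model, det_sigma_sim = det_sim,
                          p_lower = 1, g_raw = Inf, correction = 1,
                          rejected_support = TRUE),
                     class = "lrt_result"))
  }
  if (df == 0L) {
    return(structure(list(statistic = 0, df = 0L,
                          det_sigma_model = det_model, det_sigma_sim = det_sim,
                          p_lower = 0, g_raw = 0, correction = 1,
                          rejected_support = FALSE),
                     class = "lrt_result"))
  }
  oo <- o[cats]
  pp <- pi[cats]
  nz <- oo > 0
  g <- 2 * sum(oo[nz] * log(oo[nz] / (n * pp[nz])))
  g <- max(g, 0)
  correction <- 1
  no_corr <- FALSE
  if (is.finite(det_model) && is.finite(det_sim) &&
      det_model > 0 && det_sim > 0) {
    correction <- (det_model / det_sim)^(1 / df)
  } else {
    no_corr <- TRUE
  }
  stat <- g * correction
  structure(list(statistic = stat, df = df,
                 det_sigma_model = det_model, det_sigma_sim = det_sim,
                 p_lower = stats::pchisq(stat, df = df),
                 g_raw = g, correction = correction,
                 rejected_support = FALSE,
                 correction_disabled = no_corr),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("<lrt_result> statistic = %.4g (df = %d), p_lower = %.4g\n",
              x$statistic, x$df, x$p_lower))
  invisible(x)
}
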