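#' Test one disease-variant model against a case/control region
#'
#' Collapses the model's member variants into a virtual disease variant,
#' takes the case genotype frequencies of that virtual variant as `P(D')`
#' (the test conditions on them; no effect size is assumed), derives the
#' expected case genotype frequencies of every candidate variant in the
#' region through genotype-level LD with the virtual variant, and sums the
#' variance-corrected likelihood-ratio statistics and their degrees of
#' freedom.  Under the true model the total statistic follows a chi-square
#' distribution with the total degrees of freedom; under wrong models it
#' does not, which is the discriminating direction of the method.
#'
#' Variants monomorphic in the control sample cannot be evaluated (they have
#' no control genotype frequencies to condition on) and are excluded from
#' the candidate set for this test; their ids are reported in `excluded`.
#'
#' @param cases,controls `haplotype_panel` objects over the same variants
#'   (cases and controls must both be phased: the virtual-variant genotype
#'   of a compound heterozygote depends on phase).
#' @param model variant indices or ids forming the candidate disease-variant
#'   model, or a [disease_model()] (only its variant set is used: the test
#'   itself is independent of dominance mode and effect size).
#' @param reps resampling replicates for the simulated variance (default
#'   1000).
#' @param enrich same-genotype quota passed through to the resampler audit
#'   trail; see [simulated_variance()].
#' @param seed optional RNG seed.
#' @param candidates optional variant indices/ids to evaluate; defaults to
#'   every variant polymorphic in the controls.
#' @return an object of class `model_test_result`: list with `model`
#'   (member indices), `model_ids`, `total_statistic`, `total_df`,
#'   `p_lower` (lower-tail chi-square probability of the total), `accepted`
#'   (filled in by [identify_variants()]), `per_variant` (data.frame of
#'   per-candidate statistics), `excluded`, and `disease_case_freqs`.
#' @export
test_model <- function(cases, controls, model, reps = 1000L, enrich = 0.2,
                       seed = NULL, candidates = NULL) {
  stopifnot(inherits(cases, "haplotype_panel"),
            inherits(controls, "haplotype_panel"),
            reps >= 2L, enrich >= 0, enrich <= 1)
  if (!identical(cases$variants$id, controls$variants$id)) {
    stop("cases and controls must cover the same variants in the same order")
  }
  .set_seed(seed)
  members <- if (inherits(model, "disease_model")) model$variants else model
  members <- sort(unique(.resolve_variant(controls, members)))

  virt_ctl <- collapse_variants(controls, members)
  if (virt_ctl$freq == 0 || virt_ctl$freq == 1) {
    stop("virtual disease variant is monomorphic in the controls")
  }
  virt_case <- collapse_variants(cases, members)

  ctl_freq <- controls$variants$freq
  poly <- which(ctl_freq > 0 & ctl_freq < 1)
  if (is.null(candidates)) {
    candidates <- poly
  } else {
    candidates <- sort(unique(.resolve_variant(controls, candidates)))
    candidates <- intersect(candidates, poly)
  }
  excluded_ids <- controls$variants$id[setdiff(seq_len(n_variants(controls)),
                                               poly)]

  n <- n_individuals(cases)
  nD <- .geno_counts(virt_case$genotypes)
  pD <- nD / n

  cond <- .cond_given_disease(controls, virt_ctl, candidates, need = pD > 0)
  Gcase <- genotypes(cases)[, candidates, drop = FALSE]
  V <- length(candidates)

  eng <- .resample_case_dev(controls, virt_ctl, nD, candidates, reps = reps)

  per <- vector("list", V)
  groups_list <- vector("list", V)
  pg_list <- vector("list", V)
  informative <- logical(V)
  total_g <- 0
  total_df <- 0L
  for (vi in seq_len(V)) {
    pi <- numeric(3L)
    for (j in which(pD > 0)) pi <- pi + pD[j] * cond[, j, vi]
    # guard tiny negative rounding
    pi[pi < 0] <- 0
    pi <- pi / sum(pi)
    obs <- .geno_counts(Gcase[, vi])
    groups <- .merge_zero_categories(pi)
    obs_g <- .group_sums(obs, groups)
    pi_g <- .group_sums(pi, groups)
    groups_list[[vi]] <- groups
    pg_list[[vi]] <- pi_g
    sig <- multinomial_covariance(pi_g, n)
    det_model <- if (attr(sig, "df") >= 1L) det(sig) else 1
    det_sim <- .sigma_det(eng$dev, V, vi, groups)
    res <- lrt_statistic(obs_g, pi_g, det_model, det_sim)
    is_member <- candidates[vi] %in% members
    # the model's own variants are excluded from the total: their expected
    # case frequencies are conditioned on the observed case frequencies of
    # the virtual variant, so they fit perfectly by construction and carry
    # no information against the model
    informative[vi] <- !is_member && res$df >= 1L
    if (informative[vi]) {
      total_g <- total_g + res$g_raw
      total_df <- total_df + res$df
    }
    per[[vi]] <- data.frame(id = controls$variants$id[candidates[vi]],
                            index = candidates[vi],
                            member = is_member,
                            statistic = res$statistic, df = res$df,
                            g_raw = res$g_raw, correction = res$correction,
                            det_sigma_model = res$det_sigma_model,
                            det_sigma_sim = res$det_sigma_sim,
                            p_lower = res$p_lower,
                            stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, per)

  # reference null of the total: the resampler's own pseudo-case samples
  # evaluated with the same grouped G-sum, i.e. the variance-correction
  # machinery used for its full distribution; the calibrated total is then
  # mapped onto the chi-square scale of the total degrees of freedom
  if (total_df >= 1L && is.finite(total_g)) {
    t_null <- .pseudo_totals(eng, groups_list, pg_list, informative, n)
    p_lower <- (sum(t_null < total_g) + 0.5 * sum(t_null == total_g) + 0.5) /
      (length(t_null) + 1)
    total_stat <- stats::qchisq(p_lower, df = total_df)
  } else {
    p_lower <- if (is.finite(total_g)) 0 else 1
    total_stat <- if (is.finite(total_g)) 0 else Inf
  }

  structure(list(model = members,
                 model_ids = controls$variants$id[members],
                 total_statistic = total_stat,
                 total_df = total_df,
                 total_g_raw = total_g,
                 p_lower = p_lower,
                 accepted = NA,
                 per_variant = per,
                 candidates = candidates,
                 excluded = excluded_ids,
                 disease_case_freqs = pD,
                 fallback = eng$fallback,
                 enrich = enrich,
                 reps = reps),
            class = "model_test_result")
}

#' @export
print.model_test_result <- function(x, ...) {
  cat(sprintf("<model_test_result> {%s}: total = %.4g (df = %d), p_lower = %.4g\n",
              paste(x$model_ids, collapse = ", "),
              x$total_statistic, x$total_df, x$p_lower))
  invisible(x)
}

#' Exhaustive search for the disease-variant model of a region
#'
#' Tests every model of one disease variant, then every model of two, and so
#' on up to `max_model_size`, accepting models whose total statistic is not
#' in the upper `alpha` tail of its chi-square reference (lower-tail
#' probability `p_lower < 1 - alpha`).  The search stops at the first model
#' size with any acceptance and returns the accepted model with the smallest
#' `p_lower`; ties are broken by enumeration (lexicographic) order.  With
#' `M` candidates the size-1 pass performs `M` tests and the size-2 pass
#' `choose(M, 2)`.
#'
#' @inheritParams test_model
#' @param max_model_size largest model size to try (>= 1).
#' @param alpha acceptance level: a model is accepted when
#'   `p_lower < 1 - alpha` (default 0.05, i.e. the 0.95 rule).
#' @return an object of class `search_result`: list with `accepted_model`
#'   (indices or `NULL`), `accepted_ids`, `all_results` (data.frame audit
#'   trail of every tested model), `models_tested`, `alpha`, and `details`
#'   (the full `model_test_result` of the accepted model, if any).
#' @export
identify_variants <- function(cases, controls, max_model_size = 1L,
                              alpha = 0.05, reps = 1000L, enrich = 0.2,
                              seed = NULL) {
  stopifnot(max_model_size >= 1L, alpha > 0, alpha < 1)
  .set_seed(seed)
  ctl_freq <- controls$variants$freq
  poly <- which(ctl_freq > 0 & ctl_freq < 1)
  audit <- list()
  models_tested <- 0L
  accepted_model <- NULL
  details <- NULL
  for (s in seq_len(max_model_size)) {
    if (s > length(poly)) break
    sets <- utils::combn(poly, s)
    size_p <- rep(NA_real_, ncol(sets))
    size_res <- vector("list", ncol(sets))
    for (ci in seq_len(ncol(sets))) {
      r <- test_model(cases, controls, sets[, ci], reps = reps,
                      enrich = enrich, seed = NULL, candidates = poly)
      r$accepted <- r$p_lower < 1 - alpha
      size_p[ci] <- r$p_lower
      size_res[[ci]] <- r
      models_tested <- models_tested + 1L
      audit[[length(audit) + 1L]] <-
        data.frame(size = s,
                   model = paste(r$model_ids, collapse = "+"),
                   total_statistic = r$total_statistic,
                   total_df = r$total_df,
                   p_lower = r$p_lower,
                   accepted = r$accepted,
                   stringsAsFactors = FALSE)
    }
    acc <- which(size_p < 1 - alpha)
    if (length(acc) > 0L) {
      best <- acc[which.min(size_p[acc])]
      details <- size_res[[best]]
      accepted_model <- details$model
      break
    }
  }
  all_results <- do.call(rbind, audit)
  structure(list(accepted_model = accepted_model,
                 accepted_ids = if (!is.null(accepted_model))
                   controls$variants$id[accepted_model] else NULL,
                 all_results = all_results,
                 models_tested = models_tested,
                 alpha = alpha,
                 details = details),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  if (is.null(x$accepted_model)) {
    cat("<search_result> no model accepted")
  } else {
    cat(sprintf("<search_result> accepted {%s}, p_lower = %.4g",
                paste(x$accepted_ids, collapse = ", "),
                x$details$p_lower))
  }
  cat(sprintf(" (%d models tested, alpha = %g)\n", x$models_tested, x$alpha))
  invisible(x)
}
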