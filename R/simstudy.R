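#' Simulation-study configuration
#'
#' Bundles the reference panel, the true disease model and the sampling
#' dimensions of a simulation study.  Paper-scale defaults: 500 cases, 500
#' controls, 1000 simulations.
#'
#' @param panel reference `haplotype_panel` (the population).
#' @param model the true [disease_model()].
#' @param n_cases,n_controls sample sizes per replicate.
#' @param n_sims number of simulation replicates.
#' @param alpha acceptance level of the search.
#' @param reps resampling replicates inside each likelihood-ratio test.
#' @param seed RNG seed for the whole study.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(panel, model, n_cases = 500L, n_controls = 500L,
                       n_sims = 1000L, alpha = 0.05, reps = 1000L,
                       seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(model, "disease_model"),
            n_cases >= 1L, n_controls >= 1L, n_sims >= 1L,
            alpha > 0, alpha < 1)
  structure(list(panel = panel, model = model, n_cases = n_cases,
                 n_controls = n_controls, n_sims = n_sims, alpha = alpha,
                 reps = reps, seed = seed),
            class = "sim_config")
}

#' Draw one case/control sample under a disease model
#'
#' Controls are sampled from the panel individuals (with replacement by
#' default, so the control sample size is not limited by the panel).  For
#' the cases, the genotype counts of the virtual disease variant are drawn
#' from a multinomial with the case genotype frequencies implied by the
#' model, and each case is then sampled from the panel individuals carrying
#' that virtual genotype.  When a required genotype class (typically the
#' rare homozygote) is absent from the panel, the case is constructed by
#' pairing two independently sampled disease haplotypes (or a disease and a
#' normal haplotype); the number of such constructions is reported in the
#' result.
#'
#' @param panel reference `haplotype_panel`.
#' @param model a [disease_model()]; an effect given as an odds ratio is
#'   converted to the causal proportion `y` via [y_from_or()] using the
#'   panel's virtual-variant genotype frequencies.
#' @param n_cases,n_controls sample sizes.
#' @param seed optional RNG seed; identical seeds give identical samples.
#' @param replace_controls sample controls with replacement (default) or
#'   without.
#' @return list with `cases` and `controls` (phased `haplotype_panel`s that
#'   may contain monomorphic columns), `y`, `case_freqs` (the genotype
#'   triple used), `nD` (case virtual-genotype counts) and `n_constructed`
#'   (cases built by haplotype pairing).
#' @export
generate_case_control <- function(panel, model, n_cases = 500L,
                                  n_controls = 500L, seed = NULL,
                                  replace_controls = TRUE) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(model, "disease_model"))
  .set_seed(seed)
  virt <- collapse_variants(panel, model$variants)
  if (virt$freq == 0 || virt$freq == 1) {
    stop("virtual disease variant is monomorphic in the panel")
  }
  N <- n_individuals(panel)
  triple <- .geno_to_triple(.geno_counts(virt$genotypes) / N)
  y <- model$y %||% y_from_or(triple, model$or, model$mode)
  case_triple <- case_genotype_freqs(triple, y, model$mode)
  pD <- .triple_to_geno(case_triple)
  nD <- as.integer(stats::rmultinom(1L, n_cases, pD))

  strata <- lapply(0:2, function(j) which(virt$genotypes == j))
  dh_rows <- which(virt$hap == 1L)
  nh_rows <- which(virt$hap == 0L)
  hap_rows <- list()
  n_constructed <- 0L
  for (j in 0:2) {
    nj <- nD[j + 1L]
    if (nj == 0L) next
    sj <- strata[[j + 1L]]
    if (length(sj) > 0L) {
      idx <- .sample_idx(sj, nj)
      rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
      hap_rows[[length(hap_rows) + 1L]] <- panel$hap[rows, , drop = FALSE]
    } else {
      # genotype class absent from the panel: pair sampled haplotypes
      n_constructed <- n_constructed + nj
      h1 <- panel$hap[.sample_idx(dh_rows, nj), , drop = FALSE]
      pool2 <- if (j == 2L) dh_rows else nh_rows
      h2 <- panel$hap[.sample_idx(pool2, nj), , drop = FALSE]
      inter <- matrix(0L, 2L * nj, n_variants(panel))
      inter[seq(1L, 2L * nj, 2L), ] <- h1
      inter[seq(2L, 2L * nj, 2L), ] <- h2
      hap_rows[[length(hap_rows) + 1L]] <- inter
    }
  }
  case_hap <- do.call(rbind, hap_rows)
  colnames(case_hap) <- panel$variants$id
  meta_cols <- c("id", intersect(c("pos", "ref", "alt"),
                                 names(panel$variants)))
  meta <- panel$variants[, meta_cols, drop = FALSE]
  cases <- haplotype_panel(case_hap, meta, allow_monomorphic = TRUE)

  cidx <- sample.int(N, n_controls, replace = replace_controls)
  controls <- subset_individuals(panel, cidx)

  list(cases = cases, controls = controls, y = y,
       case_freqs = case_triple, nD = nD, n_constructed = n_constructed)
}

.rate_with_ci <- function(k, n) {
  ci <- stats::binom.test(k, n)$conf.int  # Clopper-Pearson
  c(rate = k / n, lo = ci[1L], hi = ci[2L])
}

#' Type I error of the model test
#'
#' Over `n_sims` simulated case/control samples drawn under the true model,
#' the fraction of replicates in which [test_model()] on the true model is
#' rejected (`p_lower >= 1 - alpha`).  A calibrated test rejects the true
#' model with probability close to `alpha`.
#'
#' @param config a [sim_config()].
#' @return an object of class `error_rates`: list with `type1`, its exact
#'   binomial (Clopper-Pearson) 95% CI, `alpha`, `n_sims` and the vector of
#'   per-replicate `p_lower` values (so other levels can be evaluated
#'   without re-simulating).
#' @export
type1_error <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .set_seed(config$seed)
  members <- config$model$variants
  p <- numeric(config$n_sims)
  for (i in seq_len(config$n_sims)) {
    gen <- generate_case_control(config$panel, config$model,
                                 config$n_cases, config$n_controls)
    r <- test_model(gen$cases, gen$controls, members, reps = config$reps)
    p[i] <- r$p_lower
  }
  k <- sum(p >= 1 - config$alpha)
  ci <- .rate_with_ci(k, config$n_sims)
  structure(list(type1 = unname(ci["rate"]),
                 ci = unname(ci[c("lo", "hi")]),
                 alpha = config$alpha, n_sims = config$n_sims,
                 p_lower = p),
            class = "error_rates")
}

#' Type II error of the exhaustive search
#'
#' Over `n_sims` simulated case/control samples drawn under the true model,
#' runs the full [identify_variants()] search and tallies how often the
#' accepted model differs from the true variant set (`type2`), splitting
#' out two failure modes: `partial_id` (a non-empty proper subset of the
#' true set was accepted, e.g. only the more frequent of two true variants)
#' and `wrong_id` (the accepted model contains a non-member, e.g. a variant
#' in strong LD with a true one).
#'
#' @param config a [sim_config()].
#' @param max_model_size largest model size the search may try; defaults to
#'   the true model size.
#' @return an object of class `error_rates`: list with `type2`,
#'   `partial_id`, `wrong_id`, `none_id` (no model accepted), Clopper-Pearson
#'   95% CIs, and the accepted variant sets per replicate.
#' @export
type2_error <- function(config, max_model_size = NULL) {
  stopifnot(inherits(config, "sim_config"))
  .set_seed(config$seed)
  members <- sort(unique(.resolve_variant(config$panel,
                                          config$model$variants)))
  max_model_size <- max_model_size %||% length(members)
  accepted <- vector("list", config$n_sims)
  for (i in seq_len(config$n_sims)) {
    gen <- generate_case_control(config$panel, config$model,
                                 config$n_cases, config$n_controls)
    r <- identify_variants(gen$cases, gen$controls,
                           max_model_size = max_model_size,
                           alpha = config$alpha, reps = config$reps)
    accepted[[i]] <- r$accepted_model %||% integer(0L)
  }
  is_exact <- vapply(accepted, function(a) setequal(a, members), logical(1L))
  is_partial <- vapply(accepted, function(a) {
    length(a) > 0L && all(a %in% members) && !setequal(a, members)
  }, logical(1L))
  is_wrong <- vapply(accepted, function(a) any(!a %in% members), logical(1L))
  is_none <- vapply(accepted, function(a) length(a) == 0L, logical(1L))
  n <- config$n_sims
  t2 <- .rate_with_ci(sum(!is_exact), n)
  structure(list(type2 = unname(t2["rate"]),
                 ci = unname(t2[c("lo", "hi")]),
                 partial_id = mean(is_partial),
                 partial_ci = unname(.rate_with_ci(sum(is_partial), n)[2:3]),
                 wrong_id = mean(is_wrong),
                 wrong_ci = unname(.rate_with_ci(sum(is_wrong), n)[2:3]),
                 none_id = mean(is_none),
                 alpha = config$alpha, n_sims = n,
                 accepted = accepted),
            class = "error_rates")
}

#' @export
print.error_rates <- function(x, ...) {
  if (!is.null(x$type1)) {
    cat(sprintf("<error_rates> Type I = %.4g [%.4g, %.4g] at alpha = %g (%d sims)\n",
                x$type1, x$ci[1L], x$ci[2L], x$alpha, x$n_sims))
  } else {
    cat(sprintf("<error_rates> Type II = %.4g [%.4g, %.4g] (partial %.3g, wrong %.3g, none %.3g; %d sims)\n",
                x$type2, x$ci[1L], x$ci[2L], x$partial_id, x$wrong_id,
                x$none_id, x$n_sims))
  }
  invisible(x)
}
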