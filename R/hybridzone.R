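# Per-individual maximum-likelihood hybrid index (HINDEX), interspecific
# heterozygosity, and recent-hybrid flagging for contact-zone samples.
#
# The likelihood treats the two gene copies of an individual as
# independent draws from a mixture of the two parental allele pools: a
# copy comes from parent B with probability h (the hybrid index), so it
# carries the alternate allele with probability q(h) = (1-h) pA + h pB
# and the genotype is Binomial(2, q(h)) per locus.

align_freqs <- function(geno, freqs_a, freqs_b) {
  # geno: named integer vector (names = locus ids) or plain vector
  # freqs: numeric vector aligned with geno, or tibble from allele_freqs()
  pick <- function(f) {
    if (is.data.frame(f)) {
      if (is.null(names(geno))) abort("genotype vector needs locus names to join on")
      f$freq[match(names(geno), f$locus_id)]
    } else as.numeric(f)
  }
  pa <- pick(freqs_a); pb <- pick(freqs_b)
  if (length(pa) != length(geno) || length(pb) != length(geno))
    abort("parental frequency tables must cover the genotype vector")
  usable <- !is.na(geno) & !is.na(pa) & !is.na(pb)
  list(g = as.integer(geno[usable]), pa = pa[usable], pb = pb[usable],
       n = sum(usable))
}

hindex_loglik <- function(h, g, pa, pb) {
  # vectorized over h
  vapply(h, function(hh) {
    q <- (1 - hh) * pa + hh * pb
    sum(dbinom(g, 2, q, log = TRUE))
  }, numeric(1))
}

#' Maximum-likelihood hybrid index of one individual
#'
#' Estimates the proportion `h` of the individual's gene copies inherited
#' from reference species B, given per-locus parental allele frequencies.
#' The likelihood is scanned on a coarse grid, the maximum is refined to
#' `1e-4` by local search ([stats::optimize()] golden-section within the
#' bracketing grid interval), and the support interval collects all `h`
#' whose log-likelihood is within 2 units of the maximum.
#'
#' @param geno Integer genotype vector (0/1/2 alternate-allele copies,
#'   `NA` missing), named by locus when frequency tables are joined by
#'   locus id.
#' @param freqs_a,freqs_b Parental alternate-allele frequencies: numeric
#'   vectors aligned with `geno`, or [allele_freqs()] tibbles (joined on
#'   locus id).
#' @param grid Coarse grid spacing for the initial scan (default 0.001).
#' @return A one-row tibble: `h`, `lower`, `upper` (2-log-likelihood-unit
#'   support), `n_loci_used`, `flat` (`TRUE` when the two parents are
#'   indistinguishable at every usable locus, in which case `h` is `NA`).
#' @export
hindex_mle <- function(geno, freqs_a, freqs_b, grid = 1e-3) {
  d <- align_freqs(geno, freqs_a, freqs_b)
  if (d$n == 0) abort("no usable loci: all genotypes or parental frequencies missing")
  if (all(abs(d$pa - d$pb) < 1e-12)) {
    warn("parental frequencies identical at every usable locus; hybrid index undefined")
    return(tibble(h = NA_real_, lower = 0, upper = 1,
                  n_loci_used = d$n, flat = TRUE))
  }
  hs <- seq(0, 1, by = grid)
  ll <- hindex_loglik(hs, d$g, d$pa, d$pb)
  i <- which.max(ll)
  lo <- hs[max(i - 1L, 1L)]; hi <- hs[min(i + 1L, length(hs))]
  h_hat <- if (lo < hi) {
    opt <- optimize(function(h) hindex_loglik(h, d$g, d$pa, d$pb),
                    c(lo, hi), maximum = TRUE, tol = 1e-6)
    if (opt$objective >= ll[i]) opt$maximum else hs[i]
  } else hs[i]
  ll_max <- max(ll[i], hindex_loglik(h_hat, d$g, d$pa, d$pb))
  inside <- ll >= ll_max - 2
  lower <- min(hs[inside], h_hat)
  upper <- max(hs[inside], h_hat)
  # refine the support edges between grid points where finite
  refine_edge <- function(a, b) {
    fa <- hindex_loglik(a, d$g, d$pa, d$pb) - (ll_max - 2)
    fb <- hindex_loglik(b, d$g, d$pa, d$pb) - (ll_max - 2)
    if (!is.finite(fa) || !is.finite(fb) || fa * fb > 0) return(NA_real_)
    uniroot(function(h) hindex_loglik(h, d$g, d$pa, d$pb) - (ll_max - 2),
            c(a, b))$root
  }
  if (lower > 0) {
    r <- refine_edge(max(lower - grid, 0), lower)
    if (!is.na(r)) lower <- r
  }
  if (upper < 1) {
    r <- refine_edge(upper, min(upper + grid, 1))
    if (!is.na(r)) upper <- r
  }
  tibble(h = h_hat, lower = min(lower, h_hat), upper = max(upper, h_hat),
         n_loci_used = d$n, flat = FALSE)
}

#' Interspecific heterozygosity of one individual
#'
#' The proportion of loci whose two gene copies descend one from each
#' parental species.  Per locus the three ancestry configurations of the
#' two copies (both from A; one from each; both from B) have prior
#' `((1-h)^2, 2h(1-h), h^2)`; the genotype likelihood under each
#' configuration follows from the parental allele frequencies, and the
#' reported value is the mean posterior probability of the mixed
#' configuration over usable loci.
#'
#' @inheritParams hindex_mle
#' @param h Hybrid index, typically the MLE from [hindex_mle()].
#' @return A value in \[0, 1\].
#' @export
intersp_het <- function(geno, freqs_a, freqs_b, h) {
  if (is.na(h) || h < 0 || h > 1) abort("h must lie in [0, 1]")
  d <- align_freqs(geno, freqs_a, freqs_b)
  if (d$n == 0) abort("no usable loci")
  g <- d$g; pa <- d$pa; pb <- d$pb
  lik_aa <- dbinom(g, 2, pa)
  lik_bb <- dbinom(g, 2, pb)
  lik_ab <- ifelse(g == 0L, (1 - pa) * (1 - pb),
            ifelse(g == 2L, pa * pb,
                   pa * (1 - pb) + (1 - pa) * pb))
  num <- 2 * h * (1 - h) * lik_ab
  den <- (1 - h)^2 * lik_aa + num + h^2 * lik_bb
  post <- ifelse(den > 0, num / den, 0)
  mean(post)
}

#' Hybrid-index table for every individual of a contact zone
#'
#' Runs [hindex_mle()] and [intersp_het()] over all individuals in a
#' genotype matrix against two parental reference frequency tables.
#'
#' @param gm A [geno_matrix()] of the contact-zone sample.
#' @param freqs_a,freqs_b Parental reference frequencies
#'   ([allele_freqs()] tibbles or numeric vectors aligned with the loci
#'   of `gm`).
#' @return A tibble with one row per individual: `id`, `species`, `h`,
#'   `lower`, `upper`, `intersp_het`, `n_loci_used`, `flat`.
#' @export
hindex_table <- function(gm, freqs_a, freqs_b) {
  purrr::map_dfr(seq_len(nrow(gm$genotypes)), function(i) {
    geno <- gm$genotypes[i, ]
    names(geno) <- gm$loci$locus_id
    est <- hindex_mle(geno, freqs_a, freqs_b)
    est$intersp_het <- if (is.na(est$h)) NA_real_ else
      intersp_het(geno, freqs_a, freqs_b, est$h)
    dplyr::bind_cols(tibble(id = gm$individuals$id[i],
                            species = gm$individuals$species[i]), est)
  })
}

#' Flag recent hybrids in a contact zone
#'
#' An individual is flagged when its hybrid index is inside the
#' intermediate window and its interspecific heterozygosity exceeds the
#' zone's background, measured as a quantile of the heterozygosity of
#' the individuals outside the window.  A zone whose individuals are all
#' intermediate (a long-standing admixed zone) provides no background
#' and yields no flags.
#'
#' @param estimates A tibble from [hindex_table()] (needs `h` and
#'   `intersp_het`); at least 5 individuals.
#' @param h_window Hybrid-index window for candidate hybrids (default
#'   `c(0.2, 0.8)`).
#' @param het_quantile Background quantile that candidates must exceed
#'   (default 0.9).
#' @return `estimates` with a logical `recent_hybrid` column.
#' @export
classify_recent_hybrids <- function(estimates, h_window = c(0.2, 0.8),
                                    het_quantile = 0.9) {
  if (nrow(estimates) < 5)
    abort("need at least 5 individuals to establish a background")
  inside <- !is.na(estimates$h) &
    estimates$h >= h_window[1] & estimates$h <= h_window[2]
  bg <- estimates$intersp_het[!inside & !is.na(estimates$intersp_het)]
  threshold <- if (length(bg)) quantile(bg, het_quantile, names = FALSE) else Inf
  dplyr::mutate(estimates,
                recent_hybrid = inside & .data$intersp_het > threshold)
}

#' Summarize the hybrid-index distribution of a contact zone
#'
#' The bimodality fraction is the share of individuals with `h < 0.1` or
#' `h > 0.9`; a strongly bimodal zone (pure parentals plus the odd
#' hybrid) scores near 1, a long-standing admixed zone near 0.
#'
#' @param estimates A tibble with columns `h` and `intersp_het` (at
#'   least 2 individuals).
#' @return A one-row tibble: `n`, `bimodality`, `h_mean`, `h_median`,
#'   `het_mean`, `het_median`, `het_q90`.
#' @export
zone_summary <- function(estimates) {
  h <- estimates$h[!is.na(estimates$h)]
  if (length(h) < 2) abort("need at least 2 individuals with a defined hybrid index")
  het <- estimates$intersp_het
  tibble(
    n = length(h),
    bimodality = mean(h < 0.1 | h > 0.9),
    h_mean = mean(h), h_median = stats::median(h),
    het_mean = mean(het, na.rm = TRUE),
    het_median = stats::median(het, na.rm = TRUE),
    het_q90 = quantile(het, 0.9, na.rm = TRUE, names = FALSE)
  )
}

#' Triangle plot of a contact zone
#'
#' Hybrid index against interspecific heterozygosity, the standard
#' diagnostic for separating recent hybrid classes (F1 at the apex,
#' backcrosses on the shoulders) from long-standing admixture.
#'
#' @param object A tibble from [hindex_table()], optionally after
#'   [classify_recent_hybrids()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_triangle <- function(object, ...) {
  p <- ggplot(object, aes(.data$h, .data$intersp_het)) +
    coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "hybrid index (ancestry from species B)",
         y = "interspecific heterozygosity") +
    theme_minimal()
  if ("recent_hybrid" %in% names(object))
    p + geom_point(aes(colour = .data$recent_hybrid))
  else p + geom_point()
}
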