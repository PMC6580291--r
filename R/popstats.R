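# Multilocus pairwise Fst between species, after Nei: within- and
# total-group expected heterozygosities combined as a ratio of sums.

#' Nei's multilocus Fst between two groups
#'
#' Per locus, the within-group expected heterozygosity is the unweighted
#' mean of `2 p (1 - p)` over the two groups and the total heterozygosity
#' is `2 pbar (1 - pbar)` with `pbar` the unweighted mean of the two
#' group frequencies; the multilocus estimate is `1 - sum(Hs) / sum(Ht)`
#' over loci with `Ht > 0` (ratio of sums, no sample-size correction).
#'
#' @param gm A [geno_matrix()].
#' @param pop_a,pop_b Species labels of the two groups.
#' @param clamp Clamp the (rarely negative) multilocus estimate to
#'   \[0, 1\] (default `TRUE`).
#' @return A single Fst value.
#' @export
nei_fst <- function(gm, pop_a, pop_b, clamp = TRUE) {
  freq_of <- function(pop) {
    rows <- which(gm$individuals$species == pop)
    if (!length(rows)) abort(sprintf("group `%s` is empty", pop))
    g <- gm$genotypes[rows, , drop = FALSE]
    n <- colSums(!is.na(g))
    ifelse(n > 0, colSums(g, na.rm = TRUE) / (2 * n), NA_real_)
  }
  pa <- freq_of(pop_a); pb <- freq_of(pop_b)
  ok <- !is.na(pa) & !is.na(pb)
  hs <- (2 * pa[ok] * (1 - pa[ok]) + 2 * pb[ok] * (1 - pb[ok])) / 2
  pbar <- (pa[ok] + pb[ok]) / 2
  ht <- 2 * pbar * (1 - pbar)
  use <- ht > 0
  if (!any(use)) return(NA_real_)
  fst <- 1 - sum(hs[use]) / sum(ht[use])
  if (clamp) min(max(fst, 0), 1) else fst
}

#' Pairwise Nei Fst over all species
#'
#' @param gm A [geno_matrix()].
#' @param groups Optional character vector of species labels (default:
#'   all species present, at least two).
#' @param clamp Passed to [nei_fst()].
#' @return A tibble with one row per unordered pair: `pop_a`, `pop_b`,
#'   `fst`, `n_loci` (loci with data in both groups).
#' @export
pairwise_fst <- function(gm, groups = NULL, clamp = TRUE) {
  groups <- groups %||% unique(gm$individuals$species)
  if (length(groups) < 2) abort("need at least two groups")
  pairs <- utils::combn(groups, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    rows_a <- gm$individuals$species == a
    rows_b <- gm$individuals$species == b
    n_loci <- sum(
      colSums(!is.na(gm$genotypes[rows_a, , drop = FALSE])) > 0 &
      colSums(!is.na(gm$genotypes[rows_b, , drop = FALSE])) > 0
    )
    tibble(pop_a = a, pop_b = b,
           fst = nei_fst(gm, a, b, clamp = clamp),
           n_loci = as.integer(n_loci))
  })
}

#' Square matrix view of a pairwise Fst table
#'
#' @param tbl A tibble from [pairwise_fst()].
#' @return A symmetric numeric matrix with a zero diagonal.
#' @export
fst_matrix <- function(tbl) {
  labs <- unique(c(tbl$pop_a, tbl$pop_b))
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_len(nrow(tbl))) {
    m[tbl$pop_a[i], tbl$pop_b[i]] <- tbl$fst[i]
    m[tbl$pop_b[i], tbl$pop_a[i]] <- tbl$fst[i]
  }
  m
}
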