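# Small builders shared across the suite.

# genotype matrix from a plain integer matrix, with optional tags/species
toy_gm <- function(geno, species = NULL, tag_id = NULL, pos = NULL) {
  geno <- as.matrix(geno)
  n_ind <- nrow(geno); n_loci <- ncol(geno)
  species <- species %||% rep("sp1", n_ind)
  loci <- tibble::tibble(locus_id = sprintf("L%03d", seq_len(n_loci)))
  if (!is.null(tag_id)) loci$tag_id <- tag_id
  if (!is.null(pos)) loci$pos <- pos
  geno_matrix(geno,
              tibble::tibble(id = sprintf("ind%02d", seq_len(n_ind)),
                             species = species),
              loci)
}

`%||%` <- rlang::`%||%`

# fully diagnostic parental frequencies
diag_freqs <- function(n_loci) {
  list(a = rep(0, n_loci), b = rep(1, n_loci))
}

# Nei-style Fst computed from an expected joint spectrum, using unbiased
# within/between diversity estimators (independent of nei_fst(), which
# works on genotypes)
fst_from_jafs <- function(s) {
  n1 <- s$sample_sizes[1]; n2 <- s$sample_sizes[2]
  p1 <- outer((0:n1) / n1, rep(1, n2 + 1))
  p2 <- outer(rep(1, n1 + 1), (0:n2) / n2)
  pi_w <- (2 * p1 * (1 - p1) * n1 / (n1 - 1) + 2 * p2 * (1 - p2) * n2 / (n2 - 1)) / 2
  pi_b <- p1 * (1 - p2) + p2 * (1 - p1)
  w <- s$entries
  w[s$mask] <- 0
  sum(w * (pi_b - pi_w)) / sum(w * (pi_b + pi_w))
}
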