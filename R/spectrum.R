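# Joint allele-frequency spectra (JAFS).
#
# A `jafs` is an (n1+1) x (n2+1) [x (n3+1)] non-negative array indexed by
# the number of derived/alternate alleles per population, with a logical
# mask (at minimum the all-ancestral and all-derived corners) excluded
# from every likelihood sum.

new_jafs <- function(entries, sample_sizes, folded = FALSE, mask = NULL) {
  entries <- as.array(entries)
  sample_sizes <- as.integer(sample_sizes)
  stopifnot(all(dim(entries) == sample_sizes + 1L))
  if (is.null(mask)) mask <- corner_mask(sample_sizes)
  structure(
    list(entries = entries, sample_sizes = sample_sizes,
         folded = folded, mask = mask),
    class = "jafs"
  )
}

corner_mask <- function(n) {
  m <- array(FALSE, n + 1L)
  m[matrix(1L, 1, length(n))] <- TRUE           # all-ancestral corner
  m[matrix(n + 1L, 1, length(n))] <- TRUE       # all-derived corner
  m
}

fold_mask <- function(n) {
  # cells with total derived count above half the total sample are
  # folded away; the existing corner mask is kept
  tot <- Reduce(`+`, lapply(seq_along(n), function(a) {
    idx <- slice.index(array(0, n + 1L), a) - 1L
    idx
  }))
  tot > sum(n) / 2
}

#' @export
#' @method print jafs
print.jafs <- function(x, ...) {
  cat(sprintf("<jafs> sample sizes (%s), %s, %.1f unmasked SNP mass\n",
              paste(x$sample_sizes, collapse = ", "),
              if (x$folded) "folded" else "unfolded",
              jafs_mass(x)))
  invisible(x)
}

#' Total unmasked mass of a spectrum
#'
#' @param s A `jafs`.
#' @return Sum of entries outside the mask.
#' @export
jafs_mass <- function(s) sum(s$entries[!s$mask])

#' Tidy a joint spectrum into a tibble
#'
#' @param x A `jafs`.
#' @param ... Unused.
#' @return A tibble with one row per cell: derived-allele counts `d1`,
#'   `d2` (and `d3` for triplets), `count` and `masked`.
#' @export
tidy.jafs <- function(x, ...) {
  dims <- dim(x$entries)
  idx <- arrayInd(seq_along(x$entries), dims) - 1L
  colnames(idx) <- paste0("d", seq_len(ncol(idx)))
  dplyr::bind_cols(as_tibble(idx),
                   tibble(count = as.vector(x$entries),
                          masked = as.vector(x$mask)))
}

#' Heatmap of a two-population joint spectrum
#'
#' @param object A two-dimensional `jafs`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.jafs <- function(object, ...) {
  if (length(object$sample_sizes) != 2)
    abort("autoplot.jafs draws two-population spectra only")
  df <- tidy(object)
  df$count[df$masked] <- NA
  ggplot(df, aes(.data$d1, .data$d2, fill = log10(.data$count + 1e-3))) +
    geom_tile() +
    scale_fill_viridis_c(name = "log10 SNPs") +
    labs(x = "derived allele count, population 1",
         y = "derived allele count, population 2") +
    theme_minimal()
}

# ---------------------------------------------------------------------------

#' Build a joint allele-frequency spectrum from genotypes
#'
#' Counts one SNP per retained locus into the cell given by the number of
#' alternate alleles observed in each group.  With `project_to`, sites
#' with missing genotypes are absorbed by per-site hypergeometric
#' downsampling: every site genotyped in at least the target number of
#' chromosomes in every group contributes its expected projected counts
#' (fractional entries), and sites below the target in any group are
#' dropped.  Without projection only fully genotyped sites are used.
#'
#' @param gm A [geno_matrix()].
#' @param groups Character vector of 2 or 3 species labels, in axis
#'   order.  Groups must be disjoint (species labels are, by
#'   construction).
#' @param project_to Optional integer vector of target haploid sample
#'   sizes, one per group.
#' @param polarization `"unfolded"` (alternate allele treated as derived)
#'   or `"folded"` (spectrum folded onto minor-allele counts).
#'
#' @return A `jafs` with the all-ancestral and all-derived corners
#'   masked.
#' @export
build_jafs <- function(gm, groups, project_to = NULL,
                       polarization = c("unfolded", "folded")) {
  polarization <- match.arg(polarization)
  if (anyDuplicated(groups)) abort("groups must be disjoint")
  rows <- lapply(groups, function(grp) {
    r <- which(gm$individuals$species == grp)
    if (!length(r)) abort(sprintf("group `%s` is empty", grp))
    r
  })
  full_n <- vapply(rows, function(r) 2L * length(r), 1L)
  n_target <- if (is.null(project_to)) full_n else as.integer(project_to)
  if (any(n_target > full_n))
    abort("projection target exceeds the available chromosomes")
  dims <- n_target + 1L
  entries <- array(0, dims)
  for (l in seq_len(ncol(gm$genotypes))) {
    weights <- vector("list", length(groups))
    ok <- TRUE
    for (a in seq_along(groups)) {
      g <- gm$genotypes[rows[[a]], l]
      called <- !is.na(g)
      m <- 2L * sum(called)
      d <- sum(g[called])
      if (m < n_target[a]) { ok <- FALSE; break }
      if (is.null(project_to)) {
        w <- rep(0, dims[a]); w[d + 1L] <- 1
      } else {
        w <- dhyper(0:n_target[a], d, m - d, n_target[a])
      }
      weights[[a]] <- w
    }
    if (!ok) next
    contrib <- Reduce(function(x, y) outer(x, y), weights)
    entries <- entries + contrib
  }
  s <- new_jafs(entries, n_target, folded = FALSE)
  if (polarization == "folded") s <- fold_jafs(s) else s
}

#' Project a spectrum to smaller sample sizes
#'
#' Applies expectation under hypergeometric subsampling independently per
#' axis: mass at derived count `i` out of `n` chromosomes is spread over
#' counts `j` out of `m` with weight `choose(i,j) choose(n-i,m-j) /
#' choose(n,m)`.  Unmasked mass is conserved up to the part moved into
#' the masked monomorphic corners.
#'
#' @param s An unfolded `jafs`.
#' @param target_sizes Integer haploid sample sizes, one per axis, each
#'   no larger than the current size.
#' @return A `jafs` at the target sizes.
#' @export
project_jafs <- function(s, target_sizes) {
  if (s$folded) abort("project before folding, not after")
  target_sizes <- as.integer(target_sizes)
  n <- s$sample_sizes
  if (length(target_sizes) != length(n))
    abort("one target size per axis is required")
  if (any(target_sizes > n)) abort("projection target exceeds current sample size")
  entries <- s$entries
  for (a in seq_along(n)) {
    if (target_sizes[a] == n[a]) next
    W <- outer(0:target_sizes[a], 0:n[a],
               function(j, i) dhyper(j, i, n[a] - i, target_sizes[a]))
    entries <- apply_axis(entries, a, W)
  }
  new_jafs(entries, target_sizes, folded = FALSE)
}

# multiply axis `a` of array `x` by matrix W (rows index the new axis)
apply_axis <- function(x, a, W) {
  d <- dim(x)
  perm <- c(a, seq_along(d)[-a])
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = d[a])
  out <- W %*% m
  d2 <- d; d2[a] <- nrow(W)
  out <- array(out, d2[perm])
  aperm(out, order(perm))
}

#' Fold a spectrum onto minor-allele counts
#'
#' Merges each cell with its orientation-reversed image (derived counts
#' `i` with `n - i` on every axis); cells exactly on the symmetry
#' boundary are halved after merging, per the usual convention, and the
#' majority half of the array is masked.
#'
#' @param s An unfolded `jafs`.
#' @return A folded `jafs`.
#' @export
fold_jafs <- function(s) {
  if (s$folded) abort("spectrum is already folded")
  n <- s$sample_sizes
  e <- s$entries + reverse_jafs_entries(s$entries)
  tot <- total_count_array(n)
  e[tot == sum(n) / 2] <- e[tot == sum(n) / 2] / 2
  mask <- corner_mask(n) | tot > sum(n) / 2
  e[tot > sum(n) / 2] <- 0
  new_jafs(e, n, folded = TRUE, mask = mask)
}

total_count_array <- function(n) {
  x <- array(0, n + 1L)
  Reduce(`+`, lapply(seq_along(n), function(a) slice.index(x, a) - 1L))
}

reverse_jafs_entries <- function(e) {
  idx <- lapply(dim(e), function(d) d:1)
  do.call(`[`, c(list(e), idx))
}

#' Mix a spectrum with its orientation-reversed image
#'
#' Models ancestral-state misorientation: with probability `O` a SNP is
#' correctly polarized, otherwise its derived and ancestral states are
#' swapped, giving `O * S + (1 - O) * reverse(S)`.
#'
#' @param s An unfolded `jafs`.
#' @param O Probability of correct orientation, in \[0, 1\].
#' @return A `jafs` of the same shape.
#' @export
misorient_jafs <- function(s, O) {
  if (s$folded) abort("misorientation applies to unfolded spectra")
  if (O < 0 || O > 1) abort("O must lie in [0, 1]")
  new_jafs(O * s$entries + (1 - O) * reverse_jafs_entries(s$entries),
           s$sample_sizes, folded = FALSE, mask = s$mask)
}

# ---------------------------------------------------------------------------
# dadi-style flat text i/o

#' Read or write a spectrum in dadi-style flat text
#'
#' The format is three lines: the array dimensions (`n+1` per axis)
#' followed by a `folded`/`unfolded` token; the entries in
#' column-of-last-axis-fastest (C) order; and the mask as 0/1 integers in
#' the same order.
#'
#' @param s A `jafs` (for writing).
#' @param path File path.
#' @return `read_sfs` returns a `jafs`; `write_sfs` returns `path`
#'   invisibly.
#' @export
write_sfs <- function(s, path) {
  dims <- dim(s$entries)
  header <- paste(c(dims, if (s$folded) "folded" else "unfolded"), collapse = " ")
  # C order: last axis fastest
  perm <- rev(seq_along(dims))
  ent <- as.vector(aperm(s$entries, perm))
  msk <- as.integer(as.vector(aperm(s$mask, perm)))
  writeLines(c(header,
               paste(format(ent, digits = 17, trim = TRUE), collapse = " "),
               paste(msk, collapse = " ")), path)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  head_tok <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  folded <- identical(head_tok[length(head_tok)], "folded")
  dims <- as.integer(head_tok[seq_len(length(head_tok) - 1)])
  ent <- as.numeric(strsplit(trimws(lines[2]), "[ \t]+")[[1]])
  msk <- as.integer(strsplit(trimws(lines[3]), "[ \t]+")[[1]])
  perm <- rev(seq_along(dims))
  e <- aperm(array(ent, rev(dims)), perm)
  m <- aperm(array(as.logical(msk), rev(dims)), perm)
  new_jafs(e, dims - 1L, folded = folded, mask = m)
}
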