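# Synthetic-data generators with known truth: a multi-taxon genotype
# matrix simulated under any compiled divergence scenario, a contact-zone
# sample assembled from Mendelian ancestry classes, and Gaussian niche
# occurrences.  Every generator is deterministic given (config, seed).

# Four-taxon fixture demography: parental split with (optionally
# heterogeneous) migration, a hybrid lineage founded by an admixture
# pulse, and a recent split of the hybrid lineage into two daughter taxa.
# Demes: 1, 2 parental; 3, 4 hybrid daughters.  Not part of the fitted
# model space; used by the generator to emulate the full species complex.
compile_complex4 <- function(p) {
  required <- c("nu1", "nu2", "nu3", "nu4", "M12", "M21", "me12", "me21",
                "P", "Ts", "Th", "T34", "f")
  p <- check_params("complex4", p, required)
  if (!(p$T34 < p$Th && p$Th < p$Ts))
    abort("complex4 needs T34 < Th < Ts")
  build <- function(M12, M21) {
    seg_end <- c(p$T34, p$Th, p$Ts, Inf)
    nu <- rbind(c(p$nu1, p$nu2, p$nu3, p$nu4),
                c(p$nu1, p$nu2, p$nu3, 1),
                c(p$nu1, p$nu2, 1, 1),
                c(1, 1, 1, 1))
    mig <- array(0, c(4, 4, 4))
    mig[1:3, 1, 2] <- M12 / 2     # parental gene flow until the split
    mig[1:3, 2, 1] <- M21 / 2
    events <- list(
      list(time = p$T34, type = 1L, a = 4L, b = 3L),
      list(time = p$Th, type = 2L, a = 3L, b = 1L, c = 2L, f = p$f),
      list(time = p$Ts, type = 1L, a = 2L, b = 1L)
    )
    new_schedule(4L, seg_end, nu, mig, events)
  }
  classes <- if (p$P > 0) {
    list(list(schedule = build(p$M12, p$M21), weight = 1 - p$P),
         list(schedule = build(p$me12, p$me21), weight = p$P))
  } else {
    list(list(schedule = build(p$M12, p$M21), weight = 1))
  }
  structure(list(model = "complex4", params = p, classes = classes, O = 1),
            class = "scenario")
}

#' Default parameters of the four-taxon study complex
#'
#' A reduced-scale emulation of the study system: a widespread lowland
#' parent (large `nu1`) and an alpine parent exchanging genes
#' heterogeneously along the genome (`M12`, `M21` for the neutral class;
#' `me12`, `me21` for a restricted fraction `P`), a hybrid lineage
#' founded midway through the divergence with admixture fraction `f`,
#' and a recent split of that lineage into two daughter taxa.
#'
#' @return A named list accepted by [gen_species_complex()] with
#'   `model = "complex4"`.
#' @export
complex4_params <- function() {
  list(nu1 = 2, nu2 = 1, nu3 = 2, nu4 = 2,
       M12 = 2, M21 = 0.5, me12 = 0.2, me21 = 0.1, P = 0.3,
       Ts = 2, Th = 0.5, T34 = 0.2, f = 0.5)
}

#' Simulate a species complex under a demographic scenario
#'
#' Simulates one coalescent genealogy per RAD tag under the scenario's
#' demography and drops mutations on it at rate `theta_tag/2` per unit
#' branch length (infinite sites; SNPs on a tag share their tree, so
#' multi-SNP tags are linked, and a tag with no mutation is monomorphic
#' and carries no SNP).  For two-class (`2m`) scenarios each tag is
#' assigned to the restricted class with probability `P`; with
#' orientation `O < 1` each SNP's ref/alt labels are swapped with
#' probability `1 - O`.  Haploid genomes are paired into diploid
#' individuals and missing calls are injected uniformly at random.
#'
#' @param model Scenario name (see [compile_two_pop()] /
#'   [compile_three_pop()]), or `"complex4"` for the four-taxon fixture
#'   demography of [complex4_params()].
#' @param p Scenario parameters for `model`.
#' @param n_ind Diploid individuals per taxon (recycled across demes).
#' @param n_tags Number of RAD tags to simulate.
#' @param theta_tag Scaled mutation rate per tag (`4 Nref mu L_tag`);
#'   0 places exactly one SNP per tag.
#' @param missing_rate Fraction of genotype calls set to missing.
#' @param species Taxon labels, one per deme.
#' @param seed Integer seed.
#' @return A list with `gm` (a [geno_matrix()]) and `truth` (generating
#'   model and parameters, per-tag locus class, per-individual ancestry,
#'   and the seed).
#' @export
gen_species_complex <- function(model, p, n_ind = 15, n_tags = 1000,
                                theta_tag = 0.5, missing_rate = 0.05,
                                species = NULL, seed = 1) {
  scenario <- if (identical(model, "complex4")) compile_complex4(p)
              else compile_scenario(model, p)
  n_demes <- scenario$classes[[1]]$schedule$n_demes
  n_ind <- rep_len(n_ind, n_demes)
  species <- species %||% paste0("taxon", seq_len(n_demes))
  stopifnot(length(species) == n_demes)
  n_hap <- 2L * n_ind
  set.seed(seed)
  # assign tags to locus classes (restricted class with probability P)
  weights <- vapply(scenario$classes, `[[`, 0, "weight")
  class_of <- sample.int(length(weights), n_tags, replace = TRUE, prob = weights)
  derived <- NULL; tag_of <- integer(0)
  for (ci in seq_along(scenario$classes)) {
    tags_ci <- which(class_of == ci)
    if (!length(tags_ci)) next
    sim <- cpp_sim_tags(pack_schedule(scenario$classes[[ci]]$schedule),
                        n_hap, length(tags_ci), theta_tag)
    if (nrow(sim$derived)) {
      derived <- rbind(derived, sim$derived)
      tag_of <- c(tag_of, tags_ci[sim$tag])
    }
  }
  if (is.null(derived) || nrow(derived) == 0)
    abort("no segregating site was produced; raise theta_tag or n_tags")
  ord <- order(tag_of)
  derived <- derived[ord, , drop = FALSE]
  tag_of <- tag_of[ord]
  # orientation: swap ref/alt with probability 1 - O
  if (scenario$O < 1) {
    flip <- runif(nrow(derived)) > scenario$O
    derived[flip, ] <- 1L - derived[flip, ]
  }
  # diploids: haploid 2i-1 and 2i form individual i, demes in order
  n_snp <- nrow(derived)
  geno <- derived[, seq(1, ncol(derived), by = 2), drop = FALSE] +
          derived[, seq(2, ncol(derived), by = 2), drop = FALSE]
  geno <- t(geno)
  if (missing_rate > 0) {
    drop <- runif(length(geno)) < missing_rate
    geno[drop] <- NA_integer_
  }
  pos_in_tag <- stats::ave(seq_len(n_snp), tag_of, FUN = seq_along)
  loci <- tibble(
    locus_id = sprintf("tag%04d_s%d", tag_of, pos_in_tag),
    tag_id = sprintf("tag%04d", tag_of),
    pos = pos_in_tag
  )
  deme_of_ind <- rep(seq_len(n_demes), n_ind)
  individuals <- tibble(
    id = sprintf("%s_%02d", species[deme_of_ind],
                 unlist(lapply(n_ind, seq_len))),
    species = species[deme_of_ind],
    locality = paste0("allopatric_", species[deme_of_ind])
  )
  gm <- geno_matrix(geno, individuals, loci)
  truth <- list(
    model = model, params = p, seed = seed, theta_tag = theta_tag,
    locus_class = tibble(tag_id = sprintf("tag%04d", seq_len(n_tags)),
                         class = ifelse(class_of == 2L, "restricted", "neutral")),
    ancestry = tibble(id = individuals$id, species = individuals$species)
  )
  list(gm = gm, truth = truth)
}

TRUE_H <- c(pureA = 0, pureB = 1, F1 = 0.5, F2 = 0.5, BC1 = 0.25, BC2 = 0.75)

#' Simulate a contact zone of known ancestry classes
#'
#' Assembles diploid genotypes from two parental allele-frequency sets
#' under free recombination: pure individuals draw both gametes from one
#' parental pool (Hardy-Weinberg), F1s one from each, F2s two gametes
#' from the F1 gamete pool (each locus from either parent with equal
#' probability), and backcrosses one parental plus one F1 gamete.  True
#' hybrid indices per class are 0, 1, 0.5, 0.5, 0.25 and 0.75 for pureA,
#' pureB, F1, F2, BC1 and BC2.
#'
#' @param freqs_a,freqs_b Parental alternate-allele frequencies (numeric
#'   vectors of equal length, or [allele_freqs()] tibbles for a shared
#'   locus set).
#' @param class_counts Named vector of individuals per ancestry class
#'   (names among pureA, pureB, F1, F2, BC1, BC2).
#' @param missing_rate Fraction of calls set to missing.
#' @param seed Integer seed.
#' @return A list with `gm` (species label `"zone"`) and `truth` (tibble
#'   of id, class, true `h`).
#' @export
gen_contact_zone <- function(freqs_a, freqs_b,
                             class_counts = c(pureA = 15, pureB = 15),
                             missing_rate = 0, seed = 1) {
  pa <- if (is.data.frame(freqs_a)) freqs_a$freq else as.numeric(freqs_a)
  pb <- if (is.data.frame(freqs_b)) freqs_b$freq else as.numeric(freqs_b)
  if (length(pa) != length(pb))
    abort("parental frequency tables must have the same length")
  bad <- names(class_counts)[!names(class_counts) %in% names(TRUE_H)]
  if (length(bad)) abort(sprintf("unknown ancestry class: %s", paste(bad, collapse = ", ")))
  if (sum(class_counts) < 1) abort("at least one individual is required")
  n_loci <- length(pa)
  set.seed(seed)
  gamete <- function(pool) {
    # pool: "A", "B" or "F1" (per-locus coin flip between parents)
    switch(pool,
      A = rbinom(n_loci, 1, pa),
      B = rbinom(n_loci, 1, pb),
      F1 = ifelse(runif(n_loci) < 0.5, rbinom(n_loci, 1, pa), rbinom(n_loci, 1, pb))
    )
  }
  pools <- list(pureA = c("A", "A"), pureB = c("B", "B"), F1 = c("A", "B"),
                F2 = c("F1", "F1"), BC1 = c("A", "F1"), BC2 = c("B", "F1"))
  rows <- list(); cls <- character(0)
  for (cl in names(class_counts)) {
    for (i in seq_len(class_counts[[cl]])) {
      rows[[length(rows) + 1L]] <- gamete(pools[[cl]][1]) + gamete(pools[[cl]][2])
      cls <- c(cls, cl)
    }
  }
  geno <- do.call(rbind, rows)
  if (missing_rate > 0) geno[runif(length(geno)) < missing_rate] <- NA_integer_
  ids <- sprintf("%s_%02d", cls, stats::ave(seq_along(cls), cls, FUN = seq_along))
  locus_ids <- if (is.data.frame(freqs_a)) freqs_a$locus_id else
    sprintf("L%04d", seq_len(n_loci))
  gm <- geno_matrix(geno,
                    tibble(id = ids, species = "zone", locality = "zone"),
                    tibble(locus_id = locus_ids))
  list(gm = gm,
       truth = tibble(id = ids, class = cls, true_h = TRUE_H[cls]))
}

#' Simulate Gaussian niche occurrences
#'
#' Draws each species' occurrences from an independent Gaussian in the
#' climate-variable space.
#'
#' @param n Occurrences per species (recycled).
#' @param centers Matrix (species x variables) of niche centers; row
#'   names become species labels.
#' @param spreads Positive standard deviations, recycled to the shape of
#'   `centers`.
#' @param seed Integer seed.
#' @return A tibble with `species` and one column per climate variable.
#' @export
gen_occurrences <- function(n, centers, spreads = 1, seed = 1) {
  centers <- as.matrix(centers)
  if (is.null(rownames(centers)))
    rownames(centers) <- paste0("species", seq_len(nrow(centers)))
  if (is.null(colnames(centers)))
    colnames(centers) <- paste0("bio", seq_len(ncol(centers)))
  spreads <- matrix(rep_len(spreads, length(centers)),
                    nrow(centers), ncol(centers))
  if (any(spreads <= 0)) abort("spreads must be positive")
  n <- rep_len(n, nrow(centers))
  set.seed(seed)
  purrr::map_dfr(seq_len(nrow(centers)), function(s) {
    vals <- vapply(seq_len(ncol(centers)), function(v)
      rnorm(n[s], centers[s, v], spreads[s, v]), numeric(n[s]))
    dplyr::bind_cols(tibble(species = rownames(centers)[s]),
                     as_tibble(matrix(vals, ncol = ncol(centers),
                                      dimnames = list(NULL, colnames(centers)))))
  })
}
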