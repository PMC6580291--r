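# Diploid biallelic genotype matrices with species/locality labels.
#
# Genotypes are stored as an individuals x loci integer matrix holding the
# number of copies of the alternate allele (0, 1, 2) with NA for missing
# calls.  Individual metadata (id, species, locality) and locus metadata
# (locus_id, tag_id, pos) live in tibbles alongside the matrix.

#' Construct a genotype matrix object
#'
#' Bundles a diploid genotype matrix (counts of the alternate allele; `NA`
#' marks missing calls) with per-individual and per-locus metadata and
#' validates the result.  Most users will obtain one from
#' [read_genotypes()] or [gen_species_complex()] rather than call this
#' directly.
#'
#' @param genotypes Integer matrix, individuals in rows and loci in
#'   columns; entries in `{0, 1, 2, NA}`.
#' @param individuals Data frame with columns `id`, `species` and
#'   optionally `locality`, one row per row of `genotypes`.
#' @param loci Data frame with column `locus_id` and optionally `tag_id`
#'   (RAD-tag the SNP sits on) and `pos` (position within the tag), one
#'   row per column of `genotypes`.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(genotypes, individuals, loci) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  individuals <- as_tibble(individuals)
  loci <- as_tibble(loci)
  if (!"locality" %in% names(individuals)) individuals$locality <- NA_character_
  if (!"tag_id" %in% names(loci)) loci$tag_id <- NA_character_
  if (!"pos" %in% names(loci)) loci$pos <- seq_len(nrow(loci))
  gm <- structure(
    list(genotypes = genotypes, individuals = individuals, loci = loci),
    class = "geno_matrix"
  )
  validate_geno_matrix(gm)
}

validate_geno_matrix <- function(gm) {
  g <- gm$genotypes
  if (nrow(g) != nrow(gm$individuals))
    abort("genotype matrix rows must match the individual table")
  if (ncol(g) != nrow(gm$loci))
    abort("genotype matrix columns must match the locus table")
  bad <- !(g %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad))
    abort("genotype values must be 0, 1, 2 or NA")
  if (anyDuplicated(gm$loci$locus_id))
    abort("locus ids must be unique")
  if (anyDuplicated(gm$individuals$id))
    abort("individual ids must be unique")
  if (!all(c("id", "species") %in% names(gm$individuals)))
    abort("individual table needs `id` and `species` columns")
  rownames(gm$genotypes) <- gm$individuals$id
  colnames(gm$genotypes) <- gm$loci$locus_id
  gm
}

#' @export
#' @method print geno_matrix
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d individuals x %d loci (%.1f%% missing)\n",
    nrow(x$genotypes), ncol(x$genotypes),
    100 * mean(is.na(x$genotypes))
  ))
  sp <- table(x$individuals$species)
  cat("  species:", paste(sprintf("%s (%d)", names(sp), sp), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$genotypes)

#' Tidy a genotype matrix into long format
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per individual x locus call: `id`,
#'   `species`, `locality`, `locus_id`, `genotype`.
#' @export
tidy.geno_matrix <- function(x, ...) {
  out <- as_tibble(x$genotypes, .name_repair = "minimal")
  names(out) <- x$loci$locus_id
  out <- dplyr::bind_cols(x$individuals[, c("id", "species", "locality")], out)
  tidyr::pivot_longer(out, -c("id", "species", "locality"),
                      names_to = "locus_id", values_to = "genotype")
}

subset_geno <- function(gm, ind = NULL, loci = NULL) {
  if (is.null(ind)) ind <- seq_len(nrow(gm$genotypes))
  if (is.null(loci)) loci <- seq_len(ncol(gm$genotypes))
  geno_matrix(gm$genotypes[ind, loci, drop = FALSE],
              gm$individuals[ind, , drop = FALSE],
              gm$loci[loci, , drop = FALSE])
}

# ---------------------------------------------------------------------------
# readers / writers

#' Read a genotype matrix from VCF or two-row STRUCTURE text
#'
#' Two dialects are supported: standard VCF (parsed with \pkg{vcfR}; the
#' `GT` field is read, `./.` is missing, and multi-allelic records are
#' rejected) and header-free two-row-per-individual STRUCTURE text whose
#' columns are individual id, integer population code, then one allele
#' code per locus, with `-9` for missing alleles.
#'
#' @param path Path to the input file.
#' @param format `"vcf"` or `"structure2row"`.
#' @param pop_map Optional data frame mapping individuals to labels.  For
#'   VCF: columns `id`, `species` and optionally `locality`.  For
#'   STRUCTURE: columns `pop` (the integer code), `species`, optionally
#'   `locality`.  Without a map, species labels default to the sample
#'   name prefix (`"pop<code>"` for STRUCTURE, `"unknown"` for VCF).
#'
#' @return A [geno_matrix()].
#' @examples
#' str_file <- system.file("extdata", "example_zone.str", package = "hybridscape")
#' pop_map <- utils::read.csv(system.file("extdata", "example_popmap.csv",
#'                                        package = "hybridscape"))
#' read_genotypes(str_file, "structure2row", pop_map = pop_map)
#' @export
read_genotypes <- function(path, format = c("vcf", "structure2row"),
                           pop_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  switch(format,
    structure2row = read_structure2row(path, pop_map),
    vcf = read_vcf_genotypes(path, pop_map)
  )
}

read_structure2row <- function(path, pop_map = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 2 != 0)
    abort("STRUCTURE two-row file must have an even number of data rows")
  toks <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(toks)
  if (length(unique(len)) != 1)
    abort(sprintf("malformed row length at line %d (expected %d fields, found %d)",
                  which(len != len[1])[1], len[1], len[which(len != len[1])[1]]))
  n_loci <- len[1] - 2L
  if (n_loci < 1) abort("STRUCTURE file has no locus columns")
  ids <- vapply(toks, `[`, "", 1)
  pops <- vapply(toks, `[`, "", 2)
  odd <- seq(1, length(toks), by = 2)
  if (!all(ids[odd] == ids[odd + 1]))
    abort("the two rows of each individual must carry the same id")
  alle <- matrix(NA_integer_, length(toks), n_loci)
  for (r in seq_along(toks)) {
    v <- suppressWarnings(as.integer(toks[[r]][-(1:2)]))
    if (anyNA(v))
      abort(sprintf("non-numeric allele code at line %d", r))
    alle[r, ] <- v
  }
  alle[alle == -9L] <- NA_integer_
  geno <- matrix(NA_integer_, length(odd), n_loci)
  locus_ids <- sprintf("L%04d", seq_len(n_loci))
  for (l in seq_len(n_loci)) {
    obs <- sort(unique(alle[!is.na(alle[, l]), l]))
    if (length(obs) > 2)
      abort(sprintf("locus %s is not biallelic (alleles: %s)",
                    locus_ids[l], paste(obs, collapse = ",")))
    alt <- if (length(obs) == 2) obs[2] else NA_integer_
    a1 <- alle[odd, l]; a2 <- alle[odd + 1, l]
    gl <- (a1 == alt) + (a2 == alt)
    gl[is.na(a1) | is.na(a2)] <- NA_integer_
    if (is.na(alt)) gl[!is.na(a1) & !is.na(a2)] <- 0L
    geno[, l] <- as.integer(gl)
  }
  species <- paste0("pop", pops[odd])
  locality <- rep(NA_character_, length(odd))
  if (!is.null(pop_map)) {
    m <- match(pops[odd], as.character(pop_map$pop))
    species <- ifelse(is.na(m), species, pop_map$species[m])
    if ("locality" %in% names(pop_map))
      locality <- pop_map$locality[m]
  }
  geno_matrix(geno,
              tibble(id = ids[odd], species = species, locality = locality),
              tibble(locus_id = locus_ids))
}

read_vcf_genotypes <- function(path, pop_map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    abort(sprintf("non-biallelic locus in VCF: %s",
                  paste(fix[multi, "ID"], collapse = ", ")))
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    out
  }
  geno <- t(apply(gt, 2, code))
  ids <- colnames(gt)
  locus_ids <- fix[, "ID"]
  if (any(is.na(locus_ids) | locus_ids == "."))
    locus_ids <- paste(fix[, "CHROM"], fix[, "POS"], sep = "_")
  species <- rep("unknown", length(ids))
  locality <- rep(NA_character_, length(ids))
  if (!is.null(pop_map)) {
    m <- match(ids, pop_map$id)
    species <- ifelse(is.na(m), species, pop_map$species[m])
    if ("locality" %in% names(pop_map)) locality <- pop_map$locality[m]
  }
  tag <- fix[, "CHROM"]
  pos <- suppressWarnings(as.numeric(fix[, "POS"]))
  geno_matrix(geno,
              tibble(id = ids, species = species, locality = locality),
              tibble(locus_id = locus_ids, tag_id = tag, pos = pos))
}

#' Write a genotype matrix to VCF or two-row STRUCTURE text
#'
#' The VCF writer emits a minimal VCFv4.2 file (gzip-compressed, via
#' \pkg{vcfR}) with the RAD tag as `CHROM`, the within-tag position as
#' `POS` and placeholder `REF`/`ALT` nucleotides; the STRUCTURE writer
#' emits the header-free two-row dialect read by [read_genotypes()], with
#' allele codes 1 (reference) and 2 (alternate) and `-9` for missing.
#'
#' @param gm A [geno_matrix()].
#' @param path Output path (use a `.vcf.gz` extension for VCF).
#' @param format `"vcf"` or `"structure2row"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("vcf", "structure2row")) {
  format <- match.arg(format)
  if (format == "structure2row") {
    g <- gm$genotypes
    pops <- as.integer(factor(gm$individuals$species))
    rows <- character(2L * nrow(g))
    for (i in seq_len(nrow(g))) {
      a1 <- ifelse(is.na(g[i, ]), -9L, ifelse(g[i, ] >= 1L, 2L, 1L))
      a2 <- ifelse(is.na(g[i, ]), -9L, ifelse(g[i, ] == 2L, 2L, 1L))
      rows[2 * i - 1] <- paste(c(gm$individuals$id[i], pops[i], a1), collapse = "\t")
      rows[2 * i] <- paste(c(gm$individuals$id[i], pops[i], a2), collapse = "\t")
    }
    writeLines(rows, path)
  } else {
    n_loci <- ncol(gm$genotypes)
    tag <- gm$loci$tag_id
    tag[is.na(tag)] <- "chr1"
    fix <- cbind(
      CHROM = tag,
      POS = as.character(ifelse(is.na(gm$loci$pos), seq_len(n_loci), gm$loci$pos)),
      ID = gm$loci$locus_id,
      REF = "A", ALT = "T", QUAL = ".", FILTER = "PASS", INFO = "."
    )
    gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- apply(gm$genotypes, c(1, 2), function(x)
      if (is.na(x)) "./." else gt_code[[as.character(x)]])
    gt <- t(gt)
    colnames(gt) <- gm$individuals$id
    gt <- cbind(FORMAT = "GT", gt)
    v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                      meta = c("##fileformat=VCFv4.2",
                               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
                      fix = fix, gt = gt)
    vcfR::write.vcf(v, file = path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# filtering

#' Filter SNP loci by tag presence, completeness, and allele frequency
#'
#' Applies, in order, the four retention rules used for ddRAD SNP panels:
#' the SNP's RAD tag must have data in at least `min_species_with_tag`
#' species; the SNP must be genotyped in more than `min_sample_fraction`
#' of all individuals; its minor-allele frequency across all genotyped
#' individuals must be at least `maf_min` (boundary inclusive); and at
#' most one SNP is kept per tag.  The one-per-tag tie-break keeps the SNP
#' with the fewest missing calls, then the smallest within-tag position,
#' then the lexicographically smallest locus id, so filtering is
#' deterministic.
#'
#' @param gm A [geno_matrix()].
#' @param maf_min Minimum minor-allele frequency (default 0.01).
#' @param min_species_with_tag Minimum number of species in which the
#'   SNP's tag must be genotyped (default 3).  Without tag ids the rule
#'   is evaluated per locus.
#' @param min_sample_fraction Fraction of all individuals that must be
#'   genotyped at the SNP; the rule is strict (`>`, default 0.40).
#' @param one_snp_per_tag Keep a single SNP per RAD tag (default `TRUE`;
#'   requires `tag_id` in the locus table).
#'
#' @return A filtered [geno_matrix()] whose `"filter_report"` attribute
#'   is a tibble counting loci dropped by each rule.
#' @export
filter_loci <- function(gm, maf_min = 0.01, min_species_with_tag = 3,
                        min_sample_fraction = 0.40, one_snp_per_tag = TRUE) {
  g <- gm$genotypes
  loci <- gm$loci
  n_in <- ncol(g)
  keep <- rep(TRUE, n_in)
  dropped <- c(tag_presence = 0L, sample_fraction = 0L, maf = 0L, one_per_tag = 0L)

  has_tags <- !all(is.na(loci$tag_id))
  if (one_snp_per_tag && !has_tags)
    abort("one_snp_per_tag = TRUE requires tag ids in the locus table")

  # 1. tag present (any non-missing call at any SNP of the tag) in enough species
  if (min_species_with_tag > 1) {
    species <- gm$individuals$species
    sp_levels <- unique(species)
    called <- !is.na(g)
    # species x locus: any call
    sp_called <- rowsum(called + 0, species) > 0
    if (has_tags) {
      tag_fac <- factor(loci$tag_id)
      # species x tag: any call at any SNP of the tag
      sp_tag <- sapply(split(seq_len(n_in), tag_fac), function(idx)
        rowSums(sp_called[, idx, drop = FALSE]) > 0)
      if (is.null(dim(sp_tag))) sp_tag <- matrix(sp_tag, nrow = 1)
      n_sp_tag <- colSums(sp_tag)
      ok <- n_sp_tag[as.character(loci$tag_id)] >= min_species_with_tag
    } else {
      ok <- colSums(sp_called) >= min_species_with_tag
    }
    dropped["tag_presence"] <- sum(keep & !ok)
    keep <- keep & ok
  }

  # 2. genotyped in more than min_sample_fraction of all individuals
  frac <- colMeans(!is.na(g))
  ok <- frac > min_sample_fraction
  dropped["sample_fraction"] <- sum(keep & !ok)
  keep <- keep & ok

  # 3. minor-allele frequency over genotyped individuals
  n_called <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  maf <- pmin(p, 1 - p)
  ok <- n_called > 0 & maf >= maf_min
  dropped["maf"] <- sum(keep & !ok)
  keep <- keep & ok

  # 4. one SNP per tag: fewest missing, then smallest pos, then locus id
  if (one_snp_per_tag) {
    idx <- which(keep)
    if (length(idx)) {
      miss <- colSums(is.na(g))[idx]
      ord <- idx[order(loci$tag_id[idx], miss,
                       loci$pos[idx], loci$locus_id[idx])]
      first <- ord[!duplicated(loci$tag_id[ord])]
      ok <- seq_len(n_in) %in% first
      dropped["one_per_tag"] <- sum(keep & !ok)
      keep <- keep & ok
    }
  }

  out <- subset_geno(gm, loci = which(keep))
  attr(out, "filter_report") <- tibble(
    rule = names(dropped),
    dropped = as.integer(dropped)
  )
  out
}

#' Per-group alternate-allele frequencies
#'
#' Computes, for each locus and each group, the alternate-allele
#' frequency over non-missing genotypes.  These are the reference
#' parental frequencies used by the hybrid-index machinery when the
#' groups are allopatric parental samples.
#'
#' @param gm A [geno_matrix()].
#' @param group_by Grouping column, `"species"` (default) or
#'   `"locality"`.
#' @param groups Optional character vector restricting which group
#'   labels are tabulated.
#'
#' @return A tibble with columns `group`, `locus_id`, `freq` (NA where no
#'   individual is genotyped), `n_genotyped` and `flagged` (no data).
#' @export
allele_freqs <- function(gm, group_by = "species", groups = NULL) {
  labels <- gm$individuals[[group_by]]
  if (is.null(labels)) abort(sprintf("no `%s` column in individual table", group_by))
  if (is.null(groups)) groups <- unique(labels)
  out <- purrr::map_dfr(groups, function(grp) {
    rows <- which(labels == grp)
    if (!length(rows)) abort(sprintf("group `%s` is empty", grp))
    g <- gm$genotypes[rows, , drop = FALSE]
    n_gen <- unname(colSums(!is.na(g)))
    freq <- ifelse(n_gen > 0, unname(colSums(g, na.rm = TRUE)) / (2 * n_gen), NA_real_)
    tibble(group = grp, locus_id = gm$loci$locus_id,
           freq = freq, n_genotyped = as.integer(n_gen),
           flagged = n_gen == 0L)
  })
  out
}
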