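# Reading, validating and filtering SNP genotype matrices.

test_that("two-row STRUCTURE files are transcribed, with -9 as missing", {
  path <- withr::local_tempfile()
  writeLines(c(
    "ind1 1 1 3 1",
    "ind1 1 2 3 1",
    "ind2 2 1 3 -9",
    "ind2 2 2 4 1"
  ), path)
  gm <- read_genotypes(path, "structure2row")
  expect_equal(dim(gm), c(2L, 3L))
  # locus 1: alleles {1,2}, alt = 2; both individuals heterozygous
  expect_equal(unname(gm$genotypes[, 1]), c(1L, 1L))
  # locus 2: ind2 carries the alternate allele 4 once
  expect_equal(unname(gm$genotypes[, 2]), c(0L, 1L))
  # locus 3: one -9 makes the call missing
  expect_equal(unname(gm$genotypes[, 3]), c(0L, NA_integer_))
  expect_equal(sum(is.na(gm$genotypes)), 1L)
  expect_equal(gm$individuals$species, c("pop1", "pop2"))
})

test_that("malformed STRUCTURE rows and triallelic loci are rejected", {
  path <- withr::local_tempfile()
  writeLines(c("ind1 1 1 2", "ind1 1 1"), path)
  expect_error(read_genotypes(path, "structure2row"), "line 2")
  writeLines(c("ind1 1 1", "ind1 1 2", "ind2 1 3", "ind2 1 3"), path)
  expect_error(read_genotypes(path, "structure2row"), "not biallelic")
})

test_that("a triallelic VCF record is a validation error naming the locus", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t10\tsnpA\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t20\tsnpB\tA\tT,C\t.\tPASS\t.\tGT\t0/1\t1/2"
  ), path)
  expect_error(read_genotypes(path, "vcf"), "snpB")
})

test_that("write/read round-trips preserve a synthetic 20 x 50 matrix", {
  sim <- gen_species_complex("IM", list(nu1 = 1, nu2 = 0.5, M12 = 1, M21 = 0.5, Ts = 1),
                             n_ind = 10, n_tags = 50, theta_tag = 0,
                             missing_rate = 0.05, species = c("A", "B"), seed = 8)
  gm <- sim$gm
  expect_equal(dim(gm), c(20L, 50L))
  vcf <- withr::local_tempfile(fileext = ".vcf.gz")
  write_genotypes(gm, vcf, "vcf")
  back <- read_genotypes(vcf, "vcf", pop_map = gm$individuals)
  expect_identical(unname(back$genotypes), unname(gm$genotypes))
  expect_identical(back$loci$locus_id, gm$loci$locus_id)
  expect_identical(back$individuals$species, gm$individuals$species)
  # STRUCTURE dialect loses nothing either (no alt-fixed locus exists:
  # every simulated mutation segregates in the full sample)
  str_path <- withr::local_tempfile()
  write_genotypes(gm, str_path, "structure2row")
  back2 <- read_genotypes(str_path, "structure2row")
  expect_identical(unname(back2$genotypes), unname(gm$genotypes))
})

test_that("invalid genotype containers are rejected", {
  expect_error(toy_gm(matrix(c(0L, 3L), 1, 2)), "0, 1, 2 or NA")
  expect_error(
    geno_matrix(matrix(0L, 1, 2),
                tibble::tibble(id = "a", species = "x"),
                tibble::tibble(locus_id = c("L1", "L1"))),
    "unique")
})

test_that("the four filter rules drop loci as a hand enumeration says", {
  # 4 species x 2 individuals; 10 loci on 8 tags (t1 carries 3 SNPs)
  species <- rep(c("a", "b", "c", "d"), each = 2)
  M <- NA  # built below, locus by locus
  g <- matrix(0L, 8, 10)
  tags <- c("t1", "t1", "t1", "t2", "t3", "t4", "t5", "t6", "t7", "t8")
  # L1 (t1): common variant, present everywhere; 1 missing call
  g[, 1] <- c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L); g[1, 1] <- NA
  # L2 (t1): sibling SNP, no missing calls (wins the one-per-tag rule)
  g[, 2] <- c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L)
  # L3 (t1): second sibling with a missing call
  g[, 3] <- c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L); g[2, 3] <- NA
  # L4 (t2): genotyped in 2 of 4 species only
  g[, 4] <- c(1L, 0L, 1L, 0L, NA, NA, NA, NA)
  # L5 (t3): genotyped in 3 of 8 individuals (37.5% <= 40%)
  g[, 5] <- c(1L, 0L, NA, NA, 1L, NA, NA, NA)
  # L6 (t4): monomorphic (MAF 0)
  g[, 6] <- 0L
  # L7 (t5): fine on all counts
  g[, 7] <- c(0L, 1L, 1L, 0L, 0L, 1L, 1L, 0L)
  # L8 (t6): singleton heterozygote, MAF 1/16 >= 1%
  g[, 8] <- c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)
  # L9 (t7): fixed difference pattern, fine
  g[, 9] <- c(2L, 2L, 0L, 0L, 2L, 2L, 0L, 0L)
  # L10 (t8): all missing
  g[, 10] <- NA_integer_
  gm <- toy_gm(g, species = species, tag_id = tags)
  out <- filter_loci(gm)
  report <- attr(out, "filter_report")

  # independent brute-force enumeration of the rules
  brute_keep <- function() {
    keep <- rep(TRUE, 10)
    sp_called <- function(l) length(unique(species[!is.na(g[, l])]))
    tag_sp <- function(l) {
      sib <- which(tags == tags[l])
      length(unique(unlist(lapply(sib, function(s) species[!is.na(g[, s])]))))
    }
    drop1 <- vapply(1:10, function(l) tag_sp(l) < 3, TRUE)
    keep <- keep & !drop1
    drop2 <- vapply(1:10, function(l) mean(!is.na(g[, l])) <= 0.40, TRUE)
    n2 <- sum(keep & drop2); keep <- keep & !drop2
    maf <- vapply(1:10, function(l) {
      gl <- g[!is.na(g[, l]), l]
      if (!length(gl)) return(0)
      p <- sum(gl) / (2 * length(gl)); min(p, 1 - p)
    }, 1)
    drop3 <- maf < 0.01
    n3 <- sum(keep & drop3); keep <- keep & !drop3
    # one per tag: fewest missing, then position, then id
    for (tg in unique(tags)) {
      idx <- which(keep & tags == tg)
      if (length(idx) > 1) {
        miss <- colSums(is.na(g))[idx]
        best <- idx[order(miss, idx)][1]
        keep[setdiff(idx, best)] <- FALSE
      }
    }
    list(keep = keep, n1 = sum(drop1), n2 = n2, n3 = n3)
  }
  ref <- brute_keep()
  expect_identical(out$loci$locus_id, gm$loci$locus_id[ref$keep])
  # t1 contributes exactly one survivor, the SNP without missing calls
  expect_identical(intersect(out$loci$locus_id, c("L001", "L002", "L003")), "L002")
  expect_equal(sum(report$dropped), ncol(gm$genotypes) - ncol(out$genotypes))
  expect_equal(report$dropped[report$rule == "tag_presence"], ref$n1)
  expect_equal(report$dropped[report$rule == "sample_fraction"], ref$n2)
  expect_equal(report$dropped[report$rule == "maf"], ref$n3)
})

test_that("the MAF rule is inclusive at 1% and drops 0.5%", {
  # 100 diploids, one species label: 1 alt copy = 0.5%, 2 copies = 1%
  g <- matrix(0L, 100, 2)
  g[1, 1] <- 1L
  g[1:2, 2] <- 1L
  gm <- toy_gm(g, species = rep(c("a", "b", "c", "d"), 25),
               tag_id = c("t1", "t2"))
  out <- filter_loci(gm)
  expect_identical(out$loci$locus_id, "L002")
})

test_that("filtering is idempotent and reports consistently", {
  sim <- gen_species_complex("complex4", complex4_params(), n_ind = 8,
                             n_tags = 150, theta_tag = 0.5,
                             missing_rate = 0.1, seed = 3)
  f1 <- filter_loci(sim$gm)
  f2 <- filter_loci(f1)
  expect_identical(f1$genotypes, f2$genotypes)
  expect_equal(sum(attr(f1, "filter_report")$dropped),
               ncol(sim$gm$genotypes) - ncol(f1$genotypes))
  expect_error(filter_loci(toy_gm(matrix(0L, 2, 2))), "tag ids")
})

test_that("allele frequencies are computed over non-missing calls only", {
  g <- rbind(c(0L, NA), c(1L, NA), c(2L, NA))
  gm <- toy_gm(g, species = rep("x", 3))
  af <- allele_freqs(gm)
  expect_equal(af$freq[1], 0.5)
  expect_equal(af$n_genotyped, c(3L, 0L))
  expect_true(is.na(af$freq[2]) && af$flagged[2])
  expect_error(allele_freqs(gm, groups = "missing_species"), "empty")
})

test_that("frequency estimates sit inside binomial bounds and ignore row order", {
  set.seed(42)
  n <- 200; p <- 0.3
  g <- matrix(rbinom(n, 2, p), ncol = 1)
  gm <- toy_gm(g, species = rep("x", n))
  est <- allele_freqs(gm)$freq
  bounds <- qbinom(c(0.005, 0.995), 2 * n, p) / (2 * n)
  expect_gte(est, bounds[1]); expect_lte(est, bounds[2])
  perm <- sample(n)
  gm2 <- geno_matrix(g[perm, , drop = FALSE],
                     gm$individuals[perm, ], gm$loci)
  expect_equal(allele_freqs(gm2)$freq, est)
})
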