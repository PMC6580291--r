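# Building, projecting, folding and misorienting joint spectra.

test_that("hand-counted toy spectra land in the right cells", {
  # one diploid per group: haploid sizes (2, 2)
  g <- rbind(c(1L, 2L, 0L),   # individual of species A
             c(0L, 1L, 1L))   # individual of species B
  gm <- toy_gm(g, species = c("A", "B"))
  s <- build_jafs(gm, c("A", "B"))
  expect_equal(s$sample_sizes, c(2L, 2L))
  expected <- array(0, c(3, 3))
  expected[2, 1] <- 1   # d = (1, 0)
  expected[3, 2] <- 1   # d = (2, 1)
  expected[1, 2] <- 1   # d = (0, 1)
  expect_equal(s$entries, expected)
  expect_true(s$mask[1, 1] && s$mask[3, 3])
  expect_equal(jafs_mass(s), 3)
})

test_that("monomorphic data leave no usable sites", {
  gm <- toy_gm(matrix(0L, 4, 5), species = rep(c("A", "B"), 2))
  s <- build_jafs(gm, c("A", "B"))
  expect_equal(jafs_mass(s), 0)
  expect_equal(s$entries[1, 1], 5)
  expect_error(build_jafs(gm, c("A", "A")), "disjoint")
})

test_that("unfolded marginals reproduce each population's 1-D SFS", {
  sim <- gen_species_complex("IM", list(nu1 = 1, nu2 = 0.5, M12 = 1, M21 = 0.5, Ts = 1),
                             n_ind = 8, n_tags = 400, theta_tag = 0,
                             missing_rate = 0, species = c("A", "B"), seed = 12)
  s <- build_jafs(sim$gm, c("A", "B"))
  raw <- s$entries
  for (pop in 1:2) {
    rows <- sim$gm$individuals$species == c("A", "B")[pop]
    d <- colSums(sim$gm$genotypes[rows, , drop = FALSE])
    sfs1 <- tabulate(d + 1L, nbins = 17L)
    expect_equal(unname(apply(raw, pop, sum)), sfs1)
  }
})

test_that("projection follows the closed-form hypergeometric weights", {
  # 1-D spectrum, n = 3, five singletons: project to n = 2
  s <- hybridscape:::new_jafs(array(c(0, 5, 0, 0), 4), 3L)
  p <- project_jafs(s, 2L)
  expect_equal(as.vector(p$entries), c(5 / 3, 10 / 3, 0))
  # identity projection
  s2 <- hybridscape:::new_jafs(array(runif(16), c(4, 4)), c(3L, 3L))
  expect_equal(project_jafs(s2, c(3L, 3L))$entries, s2$entries)
  expect_error(project_jafs(s2, c(4L, 3L)), "target exceeds")
})

test_that("projection commutes with axis order and conserves total mass", {
  set.seed(7)
  e <- array(rpois(11 * 9, 4), c(11, 9))
  s <- hybridscape:::new_jafs(e, c(10L, 8L))
  ab <- project_jafs(project_jafs(s, c(6L, 8L)), c(6L, 4L))
  ba <- project_jafs(project_jafs(s, c(10L, 4L)), c(6L, 4L))
  both <- project_jafs(s, c(6L, 4L))
  expect_equal(ab$entries, ba$entries, tolerance = 1e-12)
  expect_equal(ab$entries, both$entries, tolerance = 1e-12)
  # mass is conserved including what lands in the masked corners
  expect_equal(sum(both$entries), sum(e))
})

test_that("folding merges mirror cells, halves the ridge, and conserves mass", {
  set.seed(8)
  e <- array(runif(5 * 5), c(5, 5))
  s <- hybridscape:::new_jafs(e, c(4L, 4L))
  f <- fold_jafs(s)
  expect_true(f$folded)
  expect_error(fold_jafs(f), "already folded")
  expect_equal(sum(f$entries), sum(e))
  # cell (1,2): derived counts (0,1), conjugate (4,3)
  expect_equal(f$entries[1, 2], e[1, 2] + e[5, 4])
  # ridge cell (2,4): counts (1,3), total 4 = (n1+n2)/2, halved after merge
  expect_equal(f$entries[2, 4], (e[2, 4] + e[4, 2]) / 2)
  # majority half masked
  expect_true(f$mask[5, 5] && f$mask[4, 5])
})

test_that("building folded equals folding the unfolded build", {
  sim <- gen_species_complex("SI", list(nu1 = 1, nu2 = 1, Ts = 1),
                             n_ind = 6, n_tags = 200, theta_tag = 0.4,
                             missing_rate = 0.05, species = c("A", "B"), seed = 9)
  gm <- filter_loci(sim$gm, min_species_with_tag = 2)
  a <- fold_jafs(build_jafs(gm, c("A", "B"), project_to = c(8, 8)))
  b <- build_jafs(gm, c("A", "B"), project_to = c(8, 8), polarization = "folded")
  expect_equal(a$entries, b$entries)
  expect_equal(a$mask, b$mask)
})

test_that("misorientation mixes a spectrum with its reverse", {
  set.seed(10)
  e <- array(runif(4 * 6), c(4, 6))
  s <- hybridscape:::new_jafs(e, c(3L, 5L))
  expect_equal(misorient_jafs(s, 1)$entries, e)
  half <- misorient_jafs(s, 0.5)$entries
  expect_equal(half, half[4:1, 6:1])
  for (O in c(0, 0.3, 0.8)) {
    expect_equal(sum(misorient_jafs(s, O)$entries), sum(e))
  }
  expect_error(misorient_jafs(s, 1.2), "\\[0, 1\\]")
  expect_error(misorient_jafs(fold_jafs(s), 0.5), "unfolded")
})

test_that("dadi-style flat text round-trips spectra exactly", {
  set.seed(11)
  s <- hybridscape:::new_jafs(array(runif(7 * 5), c(7, 5)), c(6L, 4L))
  path <- withr::local_tempfile(fileext = ".fs")
  write_sfs(s, path)
  back <- read_sfs(path)
  expect_equal(back$entries, s$entries)
  expect_equal(back$mask, s$mask)
  expect_equal(back$sample_sizes, s$sample_sizes)
  expect_identical(back$folded, FALSE)
  f <- fold_jafs(s)
  write_sfs(f, path)
  expect_equal(read_sfs(path)$folded, TRUE)
})
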