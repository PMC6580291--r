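# Scenario compilation and the Monte-Carlo expected-spectrum engine.

test_that("parameter sets are checked exactly per model", {
  expect_error(compile_two_pop("SI", list(nu1 = 1, nu2 = 1, Ts = 1, M12 = 2)),
               "unexpected \\{M12\\}")
  expect_error(compile_two_pop("IM", list(nu1 = 1, nu2 = 1, Ts = 1)),
               "missing \\{M12, M21\\}")
  expect_error(compile_two_pop("AM", list(nu1 = 1, nu2 = 1, M12 = 1, M21 = 1,
                                          Ts = 1, Tam = 1.5)), "Tam < Ts")
  expect_error(compile_three_pop("HS", list(nu1 = 1, nu2 = 1, nu3 = 1,
                                            Ts = 1, Th = 1.2, f = 0.5)),
               "Th < Ts")
  expect_error(compile_two_pop("SI", list(nu1 = -1, nu2 = 1, Ts = 1)),
               "positive")
  expect_equal(length(model_params("IM2m")), 9L)   # the k used in AIC
  expect_equal(length(model_params("AM2m")), 10L)
})

test_that("ancient-migration schedules restrict gene flow to the epoch at the split", {
  sc <- compile_two_pop("AM", list(nu1 = 1, nu2 = 0.5, M12 = 2, M21 = 1,
                                   Ts = 1, Tam = 0.3))
  sched <- sc$classes[[1]]$schedule
  # recent segment [0, 0.7): no migration; [0.7, 1): active; ancestral: none
  expect_equal(sched$seg_end, c(0.7, 1, Inf))
  expect_equal(sched$mig[1, , ], matrix(0, 2, 2))
  expect_equal(sched$mig[2, 1, 2], 2 / 2)   # backward deme1 -> deme2 at M12/2
  expect_equal(sched$mig[2, 2, 1], 1 / 2)
  expect_equal(sched$mig[3, , ], matrix(0, 2, 2))
})

test_that("secondary-contact schedules restrict gene flow to the recent epoch", {
  sc <- compile_two_pop("SC", list(nu1 = 1, nu2 = 1, M12 = 4, M21 = 4,
                                   Ts = 2, Tsc = 0.25))
  sched <- sc$classes[[1]]$schedule
  expect_equal(sched$seg_end, c(0.25, 2, Inf))
  expect_equal(sched$mig[1, 1, 2], 2)
  expect_equal(sched$mig[2, , ], matrix(0, 2, 2))
})

test_that("two-class models collapse to their homogeneous limit at P = 0", {
  p2m <- list(nu1 = 1, nu2 = 0.5, M12 = 1, M21 = 0.5, me12 = 0.1, me21 = 0.1,
              Ts = 1, P = 0, O = 1)
  pim <- list(nu1 = 1, nu2 = 0.5, M12 = 1, M21 = 0.5, Ts = 1)
  e2m <- expected_jafs("IM2m", c(8, 8), n_reps = 2000, seed = 5, p = p2m)
  eim <- expected_jafs("IM", c(8, 8), n_reps = 2000, seed = 5, p = pim)
  expect_identical(e2m$entries, eim$entries)
})

test_that("hybrid-speciation nesting limits hold exactly under a shared seed", {
  p_hs <- list(nu1 = 1, nu2 = 1, nu3 = 0.5, Ts = 1, Th = 0.3, f = 0.6)
  e_hs <- expected_jafs("HS", c(6, 6, 6), n_reps = 2000, seed = 9, p = p_hs)
  e_hs2p <- expected_jafs("HS2p", c(6, 6, 6), n_reps = 2000, seed = 9,
                          p = c(p_hs, list(m13 = 0, m31 = 0, m23 = 0, m32 = 0)))
  expect_identical(e_hs$entries, e_hs2p$entries)
  # f = 1: the hybrid deme's history is a split from parent 1, i.e. SGF1
  # with no post-divergence migration
  e_f1 <- expected_jafs("HS", c(6, 6, 6), n_reps = 2000, seed = 9,
                        p = modifyList(p_hs, list(f = 1)))
  e_sgf <- expected_jafs("SGF1", c(6, 6, 6), n_reps = 2000, seed = 9,
                         p = list(nu1 = 1, nu2 = 1, nu3 = 0.5, Ts = 1, Th = 0.3,
                                  m13 = 0, m31 = 0, m23 = 0, m32 = 0))
  expect_identical(e_f1$entries, e_sgf$entries)
})

test_that("SGF1 and SGF2 with symmetric parameters mirror each other", {
  # deterministic check on the compiled demography: swapping the parental
  # demes maps one schedule onto the other
  p1 <- list(nu1 = 1, nu2 = 1, nu3 = 0.5, Ts = 1, Th = 0.4,
             m13 = 1, m31 = 1, m23 = 1, m32 = 1)
  s1 <- compile_three_pop("SGF1", p1)$classes[[1]]$schedule
  s2 <- compile_three_pop("SGF2", p1)$classes[[1]]$schedule
  swap <- c(2L, 1L, 3L)
  expect_equal(s1$nu[, swap], s2$nu)
  expect_equal(s1$mig[, swap, swap], s2$mig)
  # and the expected spectra agree statistically after swapping axes
  e1 <- expected_jafs("SGF1", c(10, 10, 6), n_reps = 30000, seed = 2, p = p1)
  e2 <- expected_jafs("SGF2", c(10, 10, 6), n_reps = 30000, seed = 3, p = p1)
  m1 <- apply(e1$entries, 3, sum)
  m2 <- apply(aperm(e2$entries, c(2, 1, 3)), 3, sum)
  expect_equal(m1, m2, tolerance = 0.05)
})

test_that("an isolated pair of demes never finds a common ancestor", {
  sched <- hybridscape:::new_schedule(
    2L, Inf, matrix(1, 1, 2), array(0, c(1, 2, 2)))
  sc <- structure(list(model = "broken", params = list(),
                       classes = list(list(schedule = sched, weight = 1)), O = 1),
                  class = "scenario")
  expect_error(expected_jafs(sc, c(2, 2), n_reps = 10, seed = 1),
               "no common root")
})

test_that("expected spectra are reproducible and non-negative", {
  p <- list(nu1 = 1, nu2 = 0.5, M12 = 1, M21 = 0.5, Ts = 1)
  a <- expected_jafs("IM", c(10, 10), n_reps = 3000, seed = 7, p = p)
  b <- expected_jafs("IM", c(10, 10), n_reps = 3000, seed = 7, p = p)
  expect_identical(a$entries, b$entries)
  expect_true(all(a$entries >= 0))
  c2 <- expected_jafs("IM", c(10, 10), n_reps = 3000, seed = 8, p = p)
  expect_false(identical(a$entries, c2$entries))
})

test_that("growth variants shrink daughter demes back to the ancestral size", {
  sc <- compile_two_pop("SIG", list(nu1 = 4, nu2 = 0.25, Ts = 1))
  sched <- sc$classes[[1]]$schedule
  n_seg <- length(sched$seg_end)
  # sizes move monotonically from the present-day value towards 1
  expect_true(all(diff(sched$nu[-n_seg, 1]) < 0))
  expect_true(all(diff(sched$nu[-n_seg, 2]) > 0))
  expect_lt(abs(sched$nu[1, 1] - 4), 0.5)
  expect_lt(abs(sched$nu[n_seg - 1, 1] - 1), 0.2)
})
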