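test_that("dRMSD matches hand arithmetic and the double-loop oracle", {
  A <- cbind(c(0, 1, 2), 0, 0)
  B <- cbind(c(0, 1, 3), 0, 0)
  expect_equal(drmsd(A, B), sqrt(2 / 3), tolerance = 1e-12)

  set.seed(11)
  for (i in 1:100) {
    p <- random_pair(sample(3:40, 1), noise = runif(1, 0.1, 3))
    expect_equal(drmsd(p$A, p$B), oracle_drmsd(p$A, p$B), tolerance = 1e-10)
  }
})

test_that("identical structures give dRMSD 0; mirrors are dRMSD-blind but not cRMSD-blind", {
  A <- make_base_structure(20, "helix")$coords
  expect_equal(drmsd(A, A), 0)
  M <- mirror_structure(structure_model(A))$coords
  expect_equal(drmsd(A, M), 0, tolerance = 1e-12)
  expect_gt(crmsd(A, M), 0.1)
})

test_that("contact maps use a strict cutoff and respect sequence separation", {
  two <- rbind(c(0, 0, 0), c(5, 0, 0))
  expect_equal(nrow(contact_map(two, cutoff = 8)$contacts), 1L)
  expect_equal(nrow(contact_map(two, cutoff = 5)$contacts), 0L) # exactly at cutoff

  A <- make_base_structure(10, "helix")$coords
  cm <- contact_map(A, cutoff = 8, min_separation = 3)
  expect_equal(cm$contacts, oracle_contacts(A, 8, 3), ignore_attr = TRUE)
  expect_true(all(cm$contacts[, 1] < cm$contacts[, 2]))
  expect_true(all(abs(cm$contacts[, 2] - cm$contacts[, 1]) >= 3))
})

test_that("Sorensen contact-map overlap reproduces direct set arithmetic", {
  A <- make_base_structure(15, "helix")
  cm <- contact_map(A, cutoff = 8)
  expect_equal(cmo_sorensen(cm, cm), 100)

  maps <- constructed_cmo_maps()
  expect_equal(cmo_sorensen(maps$A, maps$B), 100 * 16 / 24, tolerance = 1e-12)

  # disjoint non-empty maps
  m1 <- maps$A; m2 <- maps$A
  m1$contacts <- cbind(1:5, 11:15)
  m2$contacts <- cbind(1:5, 16:20)
  expect_equal(cmo_sorensen(m1, m2), 0)

  # empty-map conventions
  empty <- contact_map(rbind(c(0, 0, 0), c(50, 0, 0), c(100, 0, 0)), cutoff = 1)
  expect_equal(cmo_sorensen(empty, empty), 100)
  nonempty <- contact_map(rbind(c(0, 0, 0), c(0.5, 0, 0), c(100, 0, 0)), cutoff = 1)
  expect_equal(cmo_sorensen(empty, nonempty), 0)

  # parameter mismatches are input errors
  other <- contact_map(matrix(rnorm(30), ncol = 3), cutoff = 8)
  expect_error(cmo_sorensen(maps$A, other), "residue counts")
})

test_that("d0 follows the cubic-root formula with a floor, and MaxSub pins 3.5", {
  expect_equal(d0_tm(36), 1.24 * 21^(1 / 3) - 1.8, tolerance = 1e-12)
  expect_equal(d0_tm(15), 0.5) # formula gives -1.8, clamped
  expect_equal(d0_tm(8), 0.5)
  expect_equal(decoyclust:::D0_MAXSUB, 3.5)
})

test_that("search scores are exact on self-comparison", {
  set.seed(21)
  for (n in c(8, 36)) {
    A <- make_base_structure(n, "random_walk", seed = n)
    expect_equal(gdt_ts(A, A), 100)
    expect_equal(tm_score(A, A), 1)
    expect_equal(maxsub(A, A), 1)
  }
})

test_that("half-matched chain scores GDT_TS 50, confirmed by exhaustive subset search", {
  p <- half_matched_pair()
  expect_equal(gdt_ts(p$A, p$B), 50)

  subs <- utils::combn(8, 4)
  maxc <- c(0, 0, 0, 0)
  for (s in seq_len(ncol(subs))) {
    moved <- oracle_superpose(p$A, p$B, subs[, s])
    d <- sqrt(rowSums((moved - p$A)^2))
    maxc <- pmax(maxc, vapply(c(1, 2, 4, 8), function(cc) sum(d < cc), numeric(1)))
  }
  expect_equal(maxc, c(4, 4, 4, 4))
})

test_that("search scores are rigid-motion invariant and deterministic", {
  set.seed(31)
  A <- make_base_structure(20, "random_walk", seed = 5)$coords
  B <- A + matrix(rnorm(60, sd = 1.2), ncol = 3)
  base_g <- gdt_ts(A, B)
  base_t <- tm_score(A, B)
  for (i in 1:5) {
    R <- random_rotation()
    Bm <- sweep(B %*% t(R), 2, rnorm(3, sd = 20), "+")
    expect_lt(abs(gdt_ts(A, Bm) - base_g), 1e-6)
    expect_lt(abs(tm_score(A, Bm) - base_t), 1e-6)
  }
  expect_identical(gdt_ts(A, B), base_g) # bit-identical rerun
})

test_that("per-cutoff GDT counts are monotone and scores sit in their ranges", {
  set.seed(41)
  for (i in 1:10) {
    p <- random_pair(sample(8:40, 1), noise = runif(1, 0.5, 4))
    s <- gdt_search(p$A, p$B, measure = "gdt_ts")
    expect_true(all(diff(s$max_counts) >= 0))
    expect_gte(s$value, 0); expect_lte(s$value, 100)
    tm <- tm_score(p$A, p$B)
    expect_gt(tm, 0); expect_lte(tm, 1)
    expect_gte(drmsd(p$A, p$B), 0)
  }
})

test_that("the searched maximum dominates the single whole-chain superposition", {
  set.seed(51)
  for (i in 1:10) {
    p <- random_pair(20, noise = 2)
    moved <- oracle_superpose(p$A, p$B, 1:20)
    d <- sqrt(rowSums((moved - p$A)^2))
    whole <- 100 * mean(vapply(c(1, 2, 4, 8), function(cc) sum(d < cc), numeric(1)) / 20)
    expect_gte(gdt_ts(p$A, p$B) + 1e-9, whole)
  }
})

test_that("extended fragment seeding never lowers GDT_TS", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(12:40, 1)
    A <- make_base_structure(n, "random_walk", seed = i)$coords
    B <- A + matrix(rnorm(3 * n, sd = runif(1, 0.5, 3)), ncol = 3)
    expect_gte(
      gdt_ts(A, B, gdt_params(extended = TRUE)) + 1e-9,
      gdt_ts(A, B)
    )
  }
})

test_that("fragment seeding enumerates stride-1 windows of the stated lengths", {
  expect_equal(decoyclust:::gdt_fragment_lengths(36), c(4L, 9L, 18L, 36L))
  expect_equal(decoyclust:::gdt_fragment_lengths(36, extended = TRUE),
    c(4L, 8L, 9L, 16L, 18L, 32L, 36L))
  expect_equal(decoyclust:::gdt_fragment_lengths(8), c(4L, 8L)) # N/4 = 2 dropped
  s <- gdt_search(make_base_structure(8, "helix"), make_base_structure(8, "helix"),
    measure = "gdt_ts")
  expect_equal(s$seeds_tried, (8 - 4 + 1) + 1) # five 4-windows + whole chain
})
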