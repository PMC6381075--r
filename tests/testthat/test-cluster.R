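chn6 <- c("O1", "Oz", "O2", "P3", "P4", "Pz")
freqs16 <- seq(2, 32, 2)
times11 <- seq(0, 0.5, 0.05)

test_that("the montage adjacency contains the required neighbour pairs and is symmetric", {
  adj <- channel_adjacency(default_channels())
  expect_true(adj["O1", "Oz"] && adj["Oz", "O2"] && adj["P4", "P8"])
  expect_true(adj["P4", "O2"])              # right parieto-occipital chain
  expect_false(adj["O1", "Fp2"])
  expect_identical(unclass(adj), t(unclass(adj)))
  expect_false(any(diag(adj)))
  # ocular channels have no scalp position, hence no neighbours
  expect_false(any(adj["VEOG", ]))
})

test_that("the paired t-map matches the closed-form computation and its edge cases", {
  set.seed(1)
  a <- noise_means(3, c("O1", "Oz"), c(4, 6), c(0.1, 0.2))
  b <- noise_means(3, c("O1", "Oz"), c(4, 6), c(0.1, 0.2))
  tm <- triplet_t_map(a, b)
  expect_equal(tm$df, 2L)
  # hand-computed paired t at an arbitrary triplet
  d <- sapply(1:3, function(s) a[[s]][2, 1, 2] - b[[s]][2, 1, 2])
  t_ref <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(tm$t["Oz", "4", "0.2"], t_ref, tolerance = 1e-12)

  # identical conditions: all-zero t (with a zero-variance warning)
  expect_warning(tm0 <- triplet_t_map(a, a), "zero difference variance")
  expect_true(all(tm0$t == 0))

  # a constant positive shift with jitter gives uniformly positive t
  a2 <- lapply(a, function(x) x + 5 + rnorm(length(x), sd = 1e-3))
  tm2 <- triplet_t_map(a2, a)
  expect_true(all(tm2$t > 0))

  # NA in any subject excludes the triplet
  a3 <- a; a3[[2]][1, 1, 1] <- NA
  tm3 <- triplet_t_map(a3, b)
  expect_true(is.na(tm3$t[1, 1, 1]))
  expect_false(anyNA(tm3$t[-1]))

  expect_error(triplet_t_map(a[1], b[1]), ">= 2 subjects")
})

test_that("cluster formation needs two contiguous triplets of a common sign", {
  dims <- c(length(chn6), 16, 3)
  mk_tmap <- function(fill) {
    arr <- array(0, dims, dimnames = list(chn6, as.character(freqs16),
                                          as.character(c(0, 0.05, 0.1))))
    fill(arr)
  }
  df <- 9
  tcrit <- qt(0.975, df)

  # one isolated supra-threshold triplet: no cluster
  t1 <- mk_tmap(function(a) { a["Oz", "6", "0.05"] <- tcrit + 1; a })
  expect_length(form_clusters(structure(list(t = t1, df = df),
                                        class = "wm_tmap")), 0)

  # two time-adjacent triplets on Oz: one cluster of size 2
  t2 <- mk_tmap(function(a) {
    a["Oz", "6", "0.05"] <- 3; a["Oz", "6", "0.1"] <- 3.5; a
  })
  cl2 <- form_clusters(structure(list(t = t2, df = df), class = "wm_tmap"))
  expect_length(cl2, 1)
  expect_equal(nrow(cl2[[1]]$triplets), 2)
  expect_equal(cl2[[1]]$mass, 6.5)
  expect_equal(cl2[[1]]$sign, 1)

  # opposite signs sharing a boundary never merge
  t3 <- mk_tmap(function(a) {
    a["Oz", "6", "0.05"] <- 3; a["Oz", "8", "0.05"] <- 3
    a["Oz", "10", "0.05"] <- -3; a["Oz", "12", "0.05"] <- -3; a
  })
  cl3 <- form_clusters(structure(list(t = t3, df = df), class = "wm_tmap"))
  expect_length(cl3, 2)
  expect_setequal(vapply(cl3, `[[`, 0, "sign"), c(1, -1))

  # channel adjacency links O1-Oz-O2 but not O1-P4 directly
  t4 <- mk_tmap(function(a) {
    a["O1", "6", "0.05"] <- 3; a["Oz", "6", "0.05"] <- 3
    a["O2", "6", "0.05"] <- 3; a
  })
  cl4 <- form_clusters(structure(list(t = t4, df = df), class = "wm_tmap"))
  expect_length(cl4, 1)
  expect_equal(nrow(cl4[[1]]$triplets), 3)

  # diagonal moves (frequency and time both stepping) are not contiguous
  t5 <- mk_tmap(function(a) {
    a["Oz", "6", "0.05"] <- 3; a["Oz", "8", "0.1"] <- 3; a
  })
  expect_length(form_clusters(structure(list(t = t5, df = df),
                                        class = "wm_tmap")), 0)
})

test_that("permutation p-values are valid, relabelling-symmetric, and the null is balanced", {
  set.seed(11)
  a <- noise_means(10, chn6, freqs16, times11)
  b <- noise_means(10, chn6, freqs16, times11)
  r <- permutation_test(a, b, n_perm = 2000, seed = 5)
  for (cl in r$clusters) {
    expect_gte(cl$p, 1 / (r$n_perm + 1))
    expect_lte(cl$p, 1)
    expect_gte(nrow(cl$triplets), 2)
    expect_true(all(sign(cl$triplets$t) == cl$sign))
  }
  # swapping the condition labels mirrors masses and keeps each p
  r2 <- permutation_test(b, a, n_perm = 2000, seed = 5)
  m1 <- vapply(r$clusters, `[[`, 0, "mass")
  m2 <- vapply(r2$clusters, `[[`, 0, "mass")
  expect_equal(sort(m1), sort(-m2), tolerance = 1e-12)
  expect_equal(sort(vapply(r$clusters, `[[`, 0, "p")),
               sort(vapply(r2$clusters, `[[`, 0, "p")), tolerance = 1e-12)
  # sign-flip null: the extreme-mass distribution is symmetric in expectation
  expect_lt(abs(mean(r$null_max) + mean(r$null_min)),
            2 * sd(r$null_max + r$null_min) / sqrt(r$n_perm) * 3 + 0.5)
})

test_that("a planted box effect is recovered as a significant positive cluster", {
  set.seed(21)
  box <- list(ch = 1:3, f = 3:4, t = 5:7)     # O1/Oz/O2, 6-8 Hz, 0.2-0.3 s
  a <- noise_means(10, chn6, freqs16, times11, effect = 1.5, box = box)
  b <- noise_means(10, chn6, freqs16, times11)
  r <- permutation_test(a, b, n_perm = 1000, seed = 9)
  sig <- significant_clusters(r)
  expect_gte(length(sig), 1)
  expect_equal(sig[[1]]$sign, 1)
  hit <- sig[[1]]$triplets
  expect_true(any(hit$channel %in% chn6[1:3] &
                    hit$freq %in% freqs16[3:4] &
                    hit$time %in% times11[5:7]))
  # Bonferroni correction scales p and can only weaken decisions
  rb <- permutation_test(a, b, n_perm = 1000, seed = 9, bonferroni = 2)
  expect_equal(rb$clusters[[1]]$p_corrected,
               min(1, rb$clusters[[1]]$p * 2), tolerance = 1e-12)
})

test_that("Monte Carlo p agrees with exact sign-flip enumeration within 2 SE", {
  set.seed(31)
  box <- list(ch = 1:3, f = 3:4, t = 5:7)
  a <- noise_means(8, chn6, freqs16, times11, effect = 1.2, box = box)
  b <- noise_means(8, chn6, freqs16, times11)
  rex <- permutation_test(a, b, exact = TRUE)
  rmc <- permutation_test(a, b, n_perm = 4000, seed = 17)
  expect_equal(rex$n_perm, 2^8)
  expect_gte(length(rex$clusters), 1)
  for (i in seq_along(rex$clusters)) {
    pe <- rex$clusters[[i]]$p
    pm <- rmc$clusters[[i]]$p
    se <- sqrt(pe * (1 - pe) / 4000)
    expect_lt(abs(pe - pm), 2 * se + 1 / 4000 + 1e-9)
  }
})

test_that("triplets missing after ICF alignment are excluded, not zero-filled", {
  set.seed(41)
  a <- noise_means(6, chn6, freqs16, times11)
  b <- noise_means(6, chn6, freqs16, times11)
  for (s in 1:3) a[[s]][, 15:16, ] <- NA      # bins lost by an upward shift
  r <- permutation_test(a, b, n_perm = 200, seed = 3)
  expect_true(all(is.na(r$tmap$t[, 15:16, ])))
  for (cl in r$clusters)
    expect_false(any(cl$triplets$freq %in% freqs16[15:16]))
})

test_that("invalid permutation parameters are rejected", {
  a <- noise_means(4, chn6[1:3], c(4, 6), c(0, 0.05))
  b <- noise_means(4, chn6[1:3], c(4, 6), c(0, 0.05))
  expect_error(permutation_test(a, b, n_perm = 0), "n_perm")
  expect_error(permutation_test(a[1:3], b), "paired")
  big <- noise_means(17, chn6[1:3], c(4, 6), c(0, 0.05))
  expect_error(permutation_test(big, noise_means(17, chn6[1:3], c(4, 6),
                                                 c(0, 0.05)), exact = TRUE),
               "16")
})
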