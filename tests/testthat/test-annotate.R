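test_that("adjacent basic pairs use backbone 3-D distance and carry |dz|", {
  st <- data.frame(residue_id = 1:3, name = c("ARG", "LYS", "SER"),
                   chain = "A", resno = 1:3,
                   x = c(0, 0.5, 2), y = c(0, 0, 2), z = c(0, 0.2, 2))
  pairs <- find_adjacent_basics(1:3, st)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$distance_nm, sqrt(0.5^2 + 0.2^2), tolerance = 1e-12)
  expect_equal(pairs$z_separation_nm, 0.2, tolerance = 1e-12)
  expect_lte(pairs$z_separation_nm, pairs$distance_nm)
  # two Lys exactly 1.0 nm apart: not adjacent
  st2 <- data.frame(residue_id = 1:2, name = c("LYS", "LYS"),
                    chain = "A", resno = 1:2,
                    x = c(0, 1), y = 0, z = 0)
  expect_equal(nrow(find_adjacent_basics(1:2, st2)), 0)
  expect_error(find_adjacent_basics(9L, st), "no coordinates")
})

test_that("adjacency matches an all-pairs brute force on random sites", {
  set.seed(41)
  for (rep in 1:20) {
    n <- 10
    st <- data.frame(residue_id = 1:n,
                     name = sample(c("ARG", "LYS", "LEU", "SER"), n,
                                   replace = TRUE),
                     chain = "A", resno = 1:n,
                     x = runif(n, 0, 3), y = runif(n, 0, 3),
                     z = runif(n, -2, 2))
    pairs <- find_adjacent_basics(1:n, st)
    want <- 0
    bas <- st[st$name %in% c("ARG", "LYS"), ]
    if (nrow(bas) >= 2) {
      for (i in 1:(nrow(bas) - 1)) for (j in (i + 1):nrow(bas)) {
        d <- sqrt(sum((unlist(bas[i, c("x", "y", "z")]) -
                         unlist(bas[j, c("x", "y", "z")]))^2))
        if (d < 0.8) want <- want + 1
      }
    }
    expect_equal(nrow(pairs), want)
  }
})

test_that("annotation is invariant to residue ordering and flags composition", {
  st <- data.frame(residue_id = 1:5,
                   name = c("ARG", "LYS", "GLY", "THR", "PHE"),
                   chain = "A", resno = 1:5,
                   x = c(0, 0.5, 1, 1.2, 0.3), y = 0,
                   z = c(-1.8, -1.9, -1.7, -1.8, -1.5))
  site_fwd <- list(list(site_id = 1, residue_ids = c(1L, 2L, 3L, 4L, 5L),
                        occupancy = 0.5, residence_ns = 20))
  site_rev <- list(list(site_id = 1, residue_ids = c(5L, 3L, 1L, 4L, 2L),
                        occupancy = 0.5, residence_ns = 20))
  a1 <- annotate_sites(site_fwd, st)
  a2 <- annotate_sites(site_rev, st)
  attr(a1, "adjacent_pairs") <- attr(a2, "adjacent_pairs") <- NULL
  expect_equal(a1, a2)
  expect_equal(a1$n_basic, 2)
  expect_true(a1$has_adjacent_basics)
  expect_equal(a1$max_adjacent_cluster, 2)
  expect_true(a1$has_gly); expect_true(a1$has_thr)
  expect_false(a1$has_his); expect_false(a1$has_pro); expect_false(a1$has_ser)
  expect_identical(a1$leaflet, "inner")
})

test_that("t statistics match the closed-form pooled and Welch formulas", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  # pooled: t = (mx - my) / sqrt(sp2 * (1/n1 + 1/n2))
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_pooled <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  got <- occupancy_t_test(x, y, var_equal = TRUE)
  expect_equal(got$t, t_pooled, tolerance = 1e-9)
  expect_equal(got$t, -sqrt(3 / 2), tolerance = 1e-9)  # -1.2247...
  # Welch: t = (mx - my) / sqrt(vx/n1 + vy/n2), Welch-Satterthwaite df
  set.seed(43)
  x2 <- rnorm(10); y2 <- rnorm(14, 0.5, 2)
  t_welch <- (mean(x2) - mean(y2)) / sqrt(var(x2) / 10 + var(y2) / 14)
  df_welch <- (var(x2) / 10 + var(y2) / 14)^2 /
    ((var(x2) / 10)^2 / 9 + (var(y2) / 14)^2 / 13)
  gw <- occupancy_t_test(x2, y2)
  expect_equal(gw$t, t_welch, tolerance = 1e-9)
  expect_equal(gw$df, df_welch, tolerance = 1e-9)
  expect_equal(gw$p, 2 * pt(-abs(t_welch), df_welch), tolerance = 1e-9)
  # identical groups: p = 1
  expect_equal(occupancy_t_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # degenerate group sizes flagged as undefined
  expect_true(is.na(occupancy_t_test(1, c(1, 2))$p))
})

test_that("stratification reports the expected groups and medians", {
  set.seed(47)
  n <- 40
  ann <- data.frame(
    site_id = 1:n, n_residues = 5,
    occupancy = runif(n), residence_ns = 20,
    n_basic = rep(c(0L, 1L, 2L, 3L), each = 10),
    n_adjacent_pairs = rep(c(0L, 0L, 1L, 3L), each = 10),
    has_adjacent_basics = rep(c(FALSE, FALSE, TRUE, TRUE), each = 10),
    max_adjacent_cluster = rep(c(0L, 1L, 2L, 3L), each = 10),
    has_gly = rep(c(TRUE, FALSE), 20), has_his = FALSE, has_pro = FALSE,
    has_ser = rep(c(TRUE, FALSE), each = 20), has_thr = FALSE,
    leaflet = "inner")
  out <- stratify_occupancies(ann)
  expect_identical(out$strata$stratum,
                   c("all", "KR", "no KR", "1 KR", ">=2 KR", ">=2 KR adj",
                     ">=3 KR adj"))
  expect_equal(out$strata$n, c(40, 30, 10, 10, 20, 20, 10))
  expect_equal(out$strata$median[1], median(ann$occupancy))
  expect_equal(out$strata$median[7],
               median(ann$occupancy[ann$max_adjacent_cluster >= 3]))
  expect_equal(median(c(0.1, 0.5, 0.9)), 0.5)  # definition check on strata fn
  expect_identical(out$contrasts$flag, c("gly", "his", "pro", "ser", "thr"))
  # all-FALSE flags have an undefined contrast
  expect_true(is.na(out$contrasts$p[out$contrasts$flag == "his"]))
  expect_false(is.na(out$contrasts$p[out$contrasts$flag == "gly"]))
  expect_equal(out$basic_count$mean, mean(c(rep(1, 10), rep(2, 10), rep(3, 10))))
  expect_equal(out$basic_count$sem, out$basic_count$sd / sqrt(30))
})

test_that("a +0.2 occupancy shift is detected at alpha = 0.01 with median gap ~0.2", {
  set.seed(53)
  n <- 200
  base <- runif(n, 0.1, 0.5)
  shifted <- runif(n, 0.1, 0.5) + 0.2
  tt <- occupancy_t_test(shifted, base)
  expect_lt(tt$p, 0.01)
  expect_lt(abs((median(shifted) - median(base)) - 0.2), 0.05)
})
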