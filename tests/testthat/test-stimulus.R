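test_that("color wheel reproduces the published CIELAB coordinates", {
  # the published tables truncate toward zero at four decimals
  w4 <- color_wheel(4, 149.2975, L = 70, phase = 0)
  expect_equal(format_lab(w4$a[1]), 105.5692)
  expect_equal(format_lab(w4$b[1]), 0)
  expect_equal(format_lab(w4$a[2]), 0)
  expect_equal(format_lab(w4$b[2]), 105.5692)
  expect_equal(format_lab(w4$a[3]), -105.5692)
  # full precision stays available underneath
  expect_equal(w4$a[1], 149.2975 / (2 * sin(pi / 4)), tolerance = 1e-12)

  w5 <- color_wheel(5, 149.2975, L = 70, phase = 0)
  r5 <- sqrt(w5$a^2 + w5$b^2)
  expect_true(all(abs(r5 - 127) < 1e-3))
  expect_equal(format_lab(w5$a[1]), 127)
  expect_equal(format_lab(w5$b[1]), 0)
  # remaining five-color points as printed (these round rather than truncate)
  expect_equal(round(w5$a[2], 4), 39.2452)
  expect_equal(round(w5$b[2], 4), 120.7842)
  expect_equal(round(w5$a[3], 4), -102.7452)
})

test_that("wheel geometry holds for arbitrary parameters", {
  set.seed(401)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    d <- runif(1, 1, 300)
    ph <- runif(1, 0, 2 * pi)
    L <- runif(1, 20, 90)
    w <- color_wheel(k, d, L = L, phase = ph)
    pts <- cbind(w$a, w$b)
    chords <- sqrt(rowSums((pts - pts[c(2:k, 1), , drop = FALSE])^2))
    expect_true(max(abs(chords - d)) < 1e-9)
    radii <- sqrt(rowSums(pts^2))
    expect_true(max(abs(radii - radii[1])) < 1e-9)
    expect_true(all(w$L == L))
  }
  # square inscribed in circle: radius = chord / sqrt(2)
  w <- color_wheel(4, 10)
  expect_equal(sqrt(w$a[1]^2 + w$b[1]^2), 10 / sqrt(2), tolerance = 1e-12)
  expect_error(color_wheel(1, 10), "n_colors")
  expect_error(color_wheel(4, -1), "adjacent_distance")
})

test_that("array positions are equispaced at the given radius", {
  lay <- array_positions(4, 8.81, rotation = 0)
  gaps <- diff(c(lay$angle_rad, lay$angle_rad[1] + 2 * pi))
  expect_equal(gaps, rep(pi / 2, 4))
  expect_equal(sqrt(lay$x_deg^2 + lay$y_deg^2), rep(8.81, 4))
  expect_equal(sum(gaps), 2 * pi)

  one <- array_positions(1, 5, rotation = 1.2)
  expect_equal(one$angle_rad, 1.2)
  expect_equal(sqrt(one$x_deg^2 + one$y_deg^2), 5)

  # rotating a 13-item array by one gap reproduces the same point set
  a <- array_positions(13, 8.81, rotation = 0.4)
  b <- array_positions(13, 8.81, rotation = 0.4 + 2 * pi / 13)
  pa <- cbind(a$x_deg, a$y_deg)
  pb <- cbind(b$x_deg, b$y_deg)
  match_dist <- apply(pb, 1, function(p) {
    min(sqrt(colSums((t(pa) - p)^2)))
  })
  expect_true(max(match_dist) < 1e-9)
  expect_error(array_positions(0), "n_items")
})

test_that("cyclic color assignment keeps neighbours distinct", {
  idx9 <- assign_colors(array_positions(9), color_wheel(5, 149.2975))
  expect_false(any(idx9 == c(idx9[-1], idx9[1])))

  idx8 <- assign_colors(8, 4)
  expect_equal(idx8, rep(1:4, 2))

  idx4 <- assign_colors(4, 4)
  expect_equal(sort(idx4), 1:4)

  # the 4-color cyclic rule breaks when n = 1 mod 4 (wrap-around clash)
  expect_error(assign_colors(5, 4), class = "memmeta_constraint_violation")
  expect_error(assign_colors(13, 4), class = "memmeta_constraint_violation")

  # the design rule (5 colors for 5, 9, 13 items, else 4) always works
  for (n in 1:16) {
    k <- n_wheel_colors(n)
    expect_true(k == if (n > 1 && n %% 4 == 1) 5 else 4)
    expect_silent(assign_colors(n, k))
  }
})
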