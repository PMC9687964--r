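# Independent trig oracle: normalized dot product + acos.
acos_angle <- function(u, w) {
  acos(min(1, max(-1, sum(u * w) / sqrt(sum(u^2) * sum(w^2))))) * 180 / pi
}

random_landmarks <- function(size = 200) {
  landmark_set(unclass(ceph_template(size)) + matrix(stats::rnorm(52, 0, 4), 26, 2))
}

test_that("vertex angles match the normalized-dot-product oracle", {
  expect_equal(angle_at_vertex(c(1, 0), c(0, 0), c(0, 1)), 90)
  expect_equal(angle_at_vertex(c(5, 5), c(0, 0), c(10, 10)), 0)
  expect_equal(angle_at_vertex(c(3, 1), c(1, 1), c(1, 4)),
               acos_angle(c(2, 0), c(0, 3)), tolerance = 1e-12)
  set.seed(4)
  for (i in 1:30) {
    a <- runif(2, -10, 10); v <- runif(2, -10, 10); b <- runif(2, -10, 10)
    expect_equal(angle_at_vertex(a, v, b), acos_angle(a - v, b - v),
                 tolerance = 1e-9)
  }
})

test_that("degenerate angle inputs raise errors rather than returning 0", {
  expect_error(angle_at_vertex(c(1, 1), c(1, 1), c(0, 0)), "degenerate")
  expect_error(angle_at_vertex(c(0, 0), c(1, 1), c(1, 1)), "degenerate")
  expect_error(line_angle(c(1, 1), c(1, 1), c(0, 0), c(1, 0)), "zero-length")
})

test_that("directed line angles match the oracle and handle parallels", {
  expect_equal(line_angle(c(0, 0), c(1, 0), c(0, 0), c(0, 1)), 90)
  expect_equal(line_angle(c(0, 0), c(2, 2), c(5, 5), c(9, 9)), 0)
  set.seed(5)
  for (i in 1:30) {
    p <- runif(4, -10, 10); q <- runif(4, -10, 10)
    expect_equal(line_angle(p[1:2], p[3:4], q[1:2], q[3:4]),
                 acos_angle(p[3:4] - p[1:2], q[3:4] - q[1:2]),
                 tolerance = 1e-9)
  }
})

test_that("features are invariant under similarity transforms of the shape", {
  set.seed(6)
  for (i in 1:5) {
    ls <- random_landmarks()
    f0 <- ceph_features(ls)
    th <- runif(1, 0, 2 * pi); s <- runif(1, 0.5, 2)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    moved <- landmark_set(t(s * R %*% t(unclass(ls))) +
                            rep(runif(2, -30, 30), each = 26))
    expect_equal(ceph_features(moved), f0, tolerance = 1e-9)
  }
})

test_that("ANB is exactly SNA minus SNB, zero when A and B coincide", {
  set.seed(7)
  for (i in 1:10) {
    f <- ceph_features(random_landmarks())
    expect_equal(f[["anb"]], f[["sna"]] - f[["snb"]], tolerance = 1e-9)
  }
  ls <- ceph_template(256)
  m <- unclass(ls); m["B", ] <- m["A", ]
  expect_equal(ceph_features(landmark_set(m))[["anb"]], 0, tolerance = 1e-12)
})

test_that("template features match a per-angle oracle recomputation", {
  ls <- ceph_template(256)
  f <- ceph_features(ls)
  g <- function(n) unclass(ls)[n, ]
  expect_equal(f[["sna"]], acos_angle(g("S") - g("N"), g("A") - g("N")),
               tolerance = 1e-9)
  expect_equal(f[["snb"]], acos_angle(g("S") - g("N"), g("B") - g("N")),
               tolerance = 1e-9)
  expect_equal(f[["uc_ur_sn"]], acos_angle(g("Uc") - g("Ur"), g("N") - g("S")),
               tolerance = 1e-9)
  expect_equal(f[["lc_lr_gome"]], acos_angle(g("Lc") - g("Lr"), g("Me") - g("Go")),
               tolerance = 1e-9)
  expect_equal(f[["sn_gome"]], acos_angle(g("N") - g("S"), g("Me") - g("Go")),
               tolerance = 1e-9)
  expect_equal(f[["g_sn_pgs"]], acos_angle(g("G") - g("Sn"), g("PgS") - g("Sn")),
               tolerance = 1e-9)
  expect_true(all(is.finite(f)))
  expect_true(all(f[setdiff(names(f), "anb")] > 0 &
                    f[setdiff(names(f), "anb")] < 180))
})

test_that("landmark errors follow the hypot/atan2 oracle", {
  ls <- ceph_template(256)
  same <- landmark_errors(ls, ls)
  expect_true(all(same$magnitude == 0))
  expect_true(all(is.na(same$direction)))
  shifted <- landmark_set(unclass(ls) + rep(c(3, 4), each = 26))
  le <- landmark_errors(shifted, ls)
  expect_equal(le$magnitude, rep(5, 26))
  expect_equal(le$direction, rep(atan2(4, 3) * 180 / pi, 26), tolerance = 1e-9)
  set.seed(8)
  a <- random_landmarks(); b <- random_landmarks()
  fwd <- landmark_errors(a, b); rev <- landmark_errors(b, a)
  expect_equal(fwd$magnitude, rev$magnitude)
  expect_equal(fwd$direction, (rev$direction + 180) %% 360, tolerance = 1e-9)
  d <- unclass(a) - unclass(b)
  expect_equal(fwd$magnitude, unname(sqrt(d[, 1]^2 + d[, 2]^2)))
  expect_equal(fwd$direction, unname((atan2(d[, 2], d[, 1]) * 180 / pi) %% 360))
})

test_that("feature errors propagate the ANB = SNA - SNB identity", {
  ls <- ceph_template(256)
  expect_equal(unname(feature_errors(ls, ls)), rep(0, 7))
  m <- unclass(ls); m["B", ] <- m["B", ] + c(4, -3)
  fe <- feature_errors(landmark_set(m), ls)
  expect_equal(fe[["sna"]], 0)
  expect_true(abs(fe[["snb"]]) > 0)
  expect_equal(fe[["anb"]], -fe[["snb"]], tolerance = 1e-12)
})

test_that("ANB errors cancel when A and B slide along a common ray from N", {
  # exact construction: with N, A, B collinear, displacing A and B by the
  # same vector along that line leaves both rays (hence SNA, SNB and ANB)
  # unchanged; more generally anb error = sna error - snb error bounds
  # |anb error| by the triangle inequality
  m <- unclass(ceph_template(256))
  dir_ab <- c(0.2, 1); dir_ab <- dir_ab / sqrt(sum(dir_ab^2))
  m["A", ] <- m["N", ] + 120 * dir_ab
  m["B", ] <- m["N", ] + 180 * dir_ab
  ls <- landmark_set(m)
  m2 <- m
  m2["A", ] <- m2["A", ] + 15 * dir_ab
  m2["B", ] <- m2["B", ] + 15 * dir_ab
  fe <- feature_errors(landmark_set(m2), ls)
  expect_equal(fe[["anb"]], 0, tolerance = 1e-9)
  expect_equal(fe[["sna"]], 0, tolerance = 1e-9)
  set.seed(9)
  for (i in 1:10) {
    a <- random_landmarks(); b <- random_landmarks()
    fe <- feature_errors(a, b)
    expect_true(abs(fe[["anb"]]) <= abs(fe[["sna"]]) + abs(fe[["snb"]]) + 1e-12)
  }
})

test_that("points files round-trip and report malformed rows by name", {
  ls <- ceph_template(128)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_points(ls, path)
  expect_equal(unclass(read_points(path)), unclass(ls))
  df <- utils::read.csv(path)
  utils::write.csv(df[-8, ], path, row.names = FALSE, quote = FALSE)
  expect_error(read_points(path), "Me")
})
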