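# The 26-parameter periodic stroke model.

test_that("flat encoding has 26 free values, 18 of them pure sinusoid", {
  preset <- fix_preset()
  v <- encode_stroke(fix_stroke())
  expect_length(v, 26)
  sin_values <- grepl("\\.(min|max|phase)$", names(v))
  expect_equal(sum(sin_values), 18)
  expect_equal(sum(grepl("asym$", names(v))), 6)
  expect_equal(sum(grepl("hold$", names(v))), 2)
})

test_that("decode and encode round-trip exactly for valid parameters", {
  preset <- fix_preset()
  v <- encode_stroke(fix_stroke())
  expect_equal(unname(encode_stroke(decode_stroke(v, preset))), unname(v))
})

test_that("decode clamps into preset bounds, idempotently, swapping crossed pairs", {
  preset <- fix_preset()
  v <- encode_stroke(fix_stroke())
  v["fore.dv.min"] <- -200
  v["fore.dv.max"] <- 200
  s1 <- decode_stroke(v, preset, warn = FALSE)
  expect_equal(s1$fore$dv$min, preset$fore$dv[1])
  expect_equal(s1$fore$dv$max, preset$fore$dv[2])
  # idempotent
  expect_equal(decode_stroke(encode_stroke(s1), preset, warn = FALSE), s1)
  # min > max after clamping is swapped with a warning
  v["fore.dv.min"] <- 300
  v["fore.dv.max"] <- -300
  expect_warning(s2 <- decode_stroke(v, preset), "swap")
  expect_lte(s2$fore$dv$min, s2$fore$dv$max)
  expect_error(decode_stroke(numeric(25)), "length 26")
})

test_that("time warp is an identity at 0.5 and a monotone bijection otherwise", {
  t <- seq(0, 2, by = 0.001)
  expect_equal(warp_time(0.5, t, 2), (t / 2) %% 1, tolerance = 1e-12)
  for (a in c(0.2, 0.65, 0.9)) {
    w <- warp_time(a, t, 2)
    expect_true(all(diff(w[t < 2 - 1e-9]) > 0))
    expect_equal(w[1], 0)
    expect_equal(max(w), 1, tolerance = 2e-3)
  }
  # a = 0.65: power half-cycle (descending sweep) lasts (1 - a) * period
  sp <- sinusoid_spec(-30, 30, phase = 0, asym = 0.65)
  th <- eval_dof(sp, 0, t, 2)
  dmax <- t[which.max(th)]
  dmin <- t[which.min(th)]
  expect_equal((dmin - dmax) %% 2, 0.7, tolerance = 0.01)
  expect_error(warp_time(0, 1, 2), "inside")
  expect_error(warp_time(1.2, 1, 2), "inside")
})

test_that("eval_dof matches the closed-form sinusoid when unmodified", {
  sp <- sinusoid_spec(-25, 35, phase = 0.15, asym = 0.5)
  t <- seq(0, 4, by = 0.002)
  ref <- 5 + 30 * sin(2 * pi * (t / 2 + 0.15))
  expect_equal(eval_dof(sp, 0, t, 2), ref, tolerance = 1e-12)
  # midpoint at t = 0 with zero phase
  sp0 <- sinusoid_spec(-25, 35, phase = 0, asym = 0.5)
  expect_equal(eval_dof(sp0, 0, 0, 2), 5, tolerance = 1e-12)
  # time average equals the midpoint
  expect_equal(mean(eval_dof(sp, 0, seq(0, 2, length.out = 2001)[-1], 2)), 5,
               tolerance = 1e-3)
})

test_that("eval_dof attains its extremes, stays continuous and periodic", {
  t <- seq(0, 2, by = 5e-4)
  cases <- expand.grid(asym = c(0.2, 0.5, 0.8), hold = c(0, 0.6, 1.39),
                       phase = c(0, 0.3))
  for (i in seq_len(nrow(cases))) {
    sp <- sinusoid_spec(-40, 20, phase = cases$phase[i], asym = cases$asym[i])
    th <- eval_dof(sp, cases$hold[i], t, 2)
    expect_equal(range(th), c(-40, 20), tolerance = 1e-6)
    # continuity: no jump above the densest possible slope
    expect_lt(max(abs(diff(th))), 0.5)
    # exact periodicity
    expect_equal(eval_dof(sp, cases$hold[i], t + 2, 2), th,
                 tolerance = 1e-12)
  }
  expect_error(eval_dof(sinusoid_spec(0, 1), 2.5, 0, 2), "period")
})

test_that("a 1.39 s hold keeps the rotation stationary for 69.5% of a 2 s cycle", {
  sp <- sinusoid_spec(-45, 30, phase = 0, asym = 0.5)
  t <- seq(0, 2, length.out = 4001)[-1]
  th <- eval_dof(sp, 1.39, t, 2)
  stationary <- mean(abs(diff(th)) < 1e-9)
  expect_gte(stationary, 0.695 - 2e-3)
})

test_that("joint targets mirror left/right, lock inactive limbs, and respect bounds", {
  preset <- fix_preset()
  stroke <- fix_stroke()
  ts <- seq(0, 4, by = 0.05)
  for (t in ts[c(1, 11, 25, 50)]) {
    tg <- joint_targets(stroke, t, "all", preset)
    expect_equal(tg[1:3], tg[4:6], ignore_attr = TRUE)
    expect_equal(tg[7:9], tg[10:12], ignore_attr = TRUE)
  }
  # fore-only: hind locked at neutral (-30, -27, 0)
  tgf <- t(vapply(ts, function(t) joint_targets(stroke, t, "fore", preset),
                  numeric(12)))
  expect_true(all(tgf[, 7] == -30 & tgf[, 8] == -27 & tgf[, 9] == 0))
  # bounds
  tga <- t(vapply(ts, function(t) joint_targets(stroke, t, "all", preset),
                  numeric(12)))
  expect_true(all(tga[, 1] >= preset$fore$dv[1] - 1e-9 &
                  tga[, 1] <= preset$fore$dv[2] + 1e-9))
  expect_true(all(tga[, 9] >= preset$hind$rot[1] - 1e-9 &
                  tga[, 9] <= preset$hind$rot[2] + 1e-9))
})

test_that("presets share rotation bounds and neutral poses across ranges", {
  for (nm in c("narrow", "medium", "wide")) {
    p <- joint_presets(nm)
    expect_equal(p$fore$rot, c(-45, 30))
    expect_equal(p$hind$rot, c(-45, 30))
    expect_equal(unname(p$neutral$fore), c(-15, -16, 0))
    expect_equal(unname(p$neutral$hind), c(-30, -27, 0))
    expect_equal(unname(p$abducted$fore[["dv"]]), p$fore$dv[2])
  }
  # ranges widen monotonically
  expect_lt(joint_presets("medium")$fore$dv[1],
            joint_presets("narrow")$fore$dv[1])
  expect_lt(joint_presets("wide")$fore$dv[1],
            joint_presets("medium")$fore$dv[1])
})

test_that("stroke vectors survive a JSON round-trip", {
  v <- encode_stroke(fix_stroke())
  f <- tempfile(fileext = ".json")
  write_stroke(v, f)
  expect_equal(read_stroke(f), v)
})
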