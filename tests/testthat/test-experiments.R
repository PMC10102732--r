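# the spontaneous scan is reused by several runs; compute once at a coarser
# step than the interactive default to keep the suite fast
sp <- run_spontaneous(t_max = 500, dt = 0.02)

test_that("spontaneous run recovers the resting centre and stays bounded", {
  expect_equal(unname(sp$centre_projection), c(-10, 10, -20))
  expect_equal(sp$intensity, 1150)
  # pure-imaginary spectrum: orbit bounded, circling the centre
  dev <- sqrt(rowSums(Mod(sweep(sp$trajectory$states, 2,
                                unclass(sp$centre)))^2))
  expect_lt(max(dev), 2 * dev[1] + 1e-6)
  expect_true(sp$spectrum$centre_like)

  # with all intercepts zero the origin is the (trivial) orbit
  p0 <- linear_params(theta_g1 = 2i, theta_f1 = -1, theta_g2 = 1i,
                      theta_pi2 = 1i)
  sp0 <- run_spontaneous(p0, t_max = 10, dt = 0.1)
  expect_lt(max(Mod(sp0$trajectory$states)), 1e-10)
})

test_that("a printed real triple is completed from the spontaneous orbit", {
  near <- spontaneous_state_near(c(-16.9, 21.1, -13.3), t_max = 500,
                                 dt = 0.02)
  expect_lt(near$distance, 0.1)
  expect_equal(unname(Re(unclass(near$state)[1:3])),
               c(-16.9, 21.1, -13.3), tolerance = 0.01)
})

test_that("static input shifts the centre and precision damps intensity", {
  r <- run_static(s = 100, psi0 = attractor_centre(ref_params, 100),
                  t_max = 20, dt = 0.1)
  # starting on the shifted centre: constant trajectory
  expect_lt(max(Mod(sweep(r$trajectory$states, 2, unclass(r$centre)))), 1e-8)

  sw <- intensity_sweep(s_values = c(0, 50, 100))
  expect_equal(nrow(sw), 6L)
  # zero-stimulus sweep point reproduces the spontaneous intensity
  expect_equal(sw$intensity[sw$s == 0 & sw$m_z == 1][1], 1150)
  # heavier (more precise) masses need less excursion at the same stimulus
  i_unit <- sw$intensity[sw$s == 100 & sw$m_z == 1]
  i_heavy <- sw$intensity[sw$s == 100 & sw$m_z == 10]
  expect_lt(i_heavy, i_unit)
})

test_that("sigmoid drive carries the column to the saturated attractor", {
  r <- run_sigmoid(t_max = 500, dt = 0.05)
  tr <- r$trajectory
  # stimulus midpoint sits at t_m
  expect_equal(Re(tr$stimulus_values[which.min(abs(tr$times - 250))]), 50,
               tolerance = 1e-6)
  c100 <- attractor_centre(ref_params, 100)
  c0 <- attractor_centre(ref_params, 0)
  shift <- state_dist(c100, c0)
  # late-time average orbits the saturated centre
  late <- colMeans(tr$states[tr$times > 400, ])
  expect_lt(sqrt(sum(Mod(late - unclass(c100))^2)), 0.05 * shift)
  # early-time average still orbits the spontaneous centre (stimulus < 1e-4)
  expect_lt(Mod(tr$stimulus_values[tr$times == 100]), 1e-4)
  early <- colMeans(tr$states[tr$times <= 100, ])
  expect_lt(sqrt(sum(Mod(early - unclass(c0))^2)), 0.05 * shift)
  # the motor readout transitions between the two epochs
  expect_equal(names(r$motor_trace), c("t", "im_p_a"))
  m_early <- mean(r$motor_trace$im_p_a[tr$times <= 100])
  m_late <- mean(r$motor_trace$im_p_a[tr$times > 400])
  expect_equal(m_early, Im(unclass(c0)[["p_a"]]), tolerance = 1)
  expect_equal(m_late, Im(unclass(c100)[["p_a"]]), tolerance = 1)
  # the mean transition lives in the real part of the motor momentum here
  re_early <- mean(Re(tr$states[tr$times <= 100, 4]))
  re_late <- mean(Re(tr$states[tr$times > 400, 4]))
  expect_equal(re_early, Re(unclass(c0)[["p_a"]]), tolerance = 1)
  expect_equal(re_late, Re(unclass(c100)[["p_a"]]), tolerance = 1)
  expect_gt(abs(re_late - re_early), 10)
})

test_that("bifurcation run migrates between the two attractors", {
  r <- run_bifurcation(dt = 0.05)
  expect_equal(r$snapshots$t_end, c(5, 100, 260, 500))
  expect_lt(r$initial_state_distance, 0.1)
  shift <- r$centre_shift
  # pre-transition windows hug the spontaneous centre...
  expect_true(all(r$snapshots$dist_to_c0[1:2] < 0.1 * shift))
  # ...the final window hugs the saturated centre
  expect_lt(r$snapshots$dist_to_cinf[4], 0.05 * shift)
  expect_gt(r$snapshots$dist_to_cinf[1], 0.9 * shift)
  # empirical relaxation happens after the stimulus midpoint
  expect_gt(r$relaxation_time, 250)
  expect_lt(r$relaxation_time, 500)
})

test_that("a null-saturation sigmoid degenerates to the spontaneous run", {
  psi0 <- sp$trajectory$states[101, ]
  r <- run_bifurcation(s_inf = 0, psi0 = psi0, snapshot_times = c(5, 20),
                       dt = 0.05)
  # a zero-saturation sigmoid evaluates to exactly zero, so the integrated
  # path must coincide with the null-stimulus integration step for step
  ref <- integrate_bm(ref_model, psi0, stimulus_null(), 0, 0.05, 400)
  expect_lt(max(Mod(r$trajectory$states - ref$states)), 1e-12)
  # and track the exact propagator at the integrator's accuracy
  ex <- propagate(ref_params, psi0, stimulus_null(), 0, 0.05, 400)
  expect_lt(max(Mod(r$trajectory$states - ex$states)), 1e-2)
})
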