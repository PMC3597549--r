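test_that("compiled and pure-R integrators agree step for step", {
  dp <- dynamics_params()
  set.seed(7)
  dyn <- dyn_state(3)
  dyn$state[, "E"] <- runif(3); dyn$state[, "I"] <- runif(3)
  dyn$state[, "S"] <- c(3.75, 2.5, 1.25); dyn$state[, "R"] <- 3.75
  dyn$state[, "X"] <- 0.1
  dyn$cmat <- matrix(c(0, 2.5, 1.25, 2.5, 0, 0, 1.25, 0, 0), 3, 3)
  set.seed(11)
  cpp <- streamchains:::dyn_integrate_cpp(dyn$state, dyn$cmat,
                                          streamchains:::dyn_par_vector(dp),
                                          500, 1, TRUE, TRUE, 10, 0)
  set.seed(11)
  ref <- streamchains:::dyn_integrate_r(dyn, dp, 500)
  expect_equal(unname(cpp$state), unname(ref$state), tolerance = 1e-12)
  expect_equal(cpp$cmat, ref$cmat, tolerance = 1e-12)
})

test_that("state variables respect their ranges throughout a full run", {
  r <- chains_run(16, 200, duration_s = 120, seed = 4)
  tr <- r$traces
  for (v in c("E", "I")) {
    x <- tr[[v]][!is.na(tr[[v]])]
    expect_true(all(x >= 0 & x <= 1))
  }
  for (v in c("S", "R", "X", "A")) {
    x <- tr[[v]][!is.na(tr[[v]])]
    expect_true(all(x >= 0))
  }
  ## noise is the only signed variable, and it does go negative
  u <- tr$U[!is.na(tr$U)]
  expect_true(any(u < 0) && any(u > 0))
  ## suppressed chains keep a nonzero degree of excitation
  e <- tr$E[!is.na(tr$E)]
  expect_gt(min(e[e > 0]), 0)
  tail_e <- tr$E[nrow(tr$E), ]
  expect_true(all(tail_e[!is.na(tail_e)] > 0.005))
})

test_that("the noise process is mean-reverting with the printed time constant", {
  dp <- dynamics_params()
  ## zero diffusion: pure exponential decay at tau_noise
  dpz <- dynamics_params(sigma_noise = 0)
  u <- 1
  for (i in 1:500) u <- ou_step(u, 1, dpz)
  expect_equal(u, exp(-500 / dp$tau_noise), tolerance = 3e-3)
  ## autocorrelation time of a long sample path ~ tau_noise = 500 ms
  set.seed(42)
  n <- 2e5
  path <- numeric(n); x <- 0
  for (i in 1:n) { x <- ou_step(x, 1, dp); path[i] <- x }
  ac <- acf(path, lag.max = 500, plot = FALSE)$acf
  tau_hat <- -1 / coef(lm(log(ac[ac > 0.05]) ~ seq_along(ac[ac > 0.05])))[2]
  expect_gt(tau_hat, 400); expect_lt(tau_hat, 600)
  ## stationary spread matches sigma_noise
  expect_equal(sd(path[1000:n]), dp$sigma_noise, tolerance = 0.1)
})

test_that("noise paths of different chains are uncorrelated", {
  r <- chains_run(16, 200, duration_s = 120, seed = 9,
                  preinstall = c("ABA", "A", "B"), discover = FALSE)
  u <- r$traces$U
  cc <- cor(u)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.15)
})

test_that("leaky integrators average impulses to the true event rate", {
  ## impulses every 250 ms with the 1/tau increment -> time average 4/s,
  ## independent of the integrator's time constant
  for (tau_s in c(1, 5)) {
    dp <- dynamics_params(tau_success = tau_s * 1000)
    inc <- 1000 / dp$tau_success
    s <- 0; acc <- 0; n <- 0
    for (t in 1:40000) {                 # 40 s at 1 ms
      if (t %% 250 == 0) s <- s + inc
      s <- s * exp(-1 / dp$tau_success)
      if (t > 20000) { acc <- acc + s; n <- n + 1 }
    }
    expect_equal(acc / n, 4, tolerance = 0.02)
  }
})

test_that("adaptation tracks excitation towards w_adapt * E", {
  dp <- dynamics_params()
  a <- 0
  for (i in 1:20000) a <- adaptation_step(a, 0.9, 1, dp)
  expect_equal(a, dp$w_adapt * 0.9 * (1 - exp(-20000 / dp$tau_adapt)),
               tolerance = 1e-4)
  ## and decays when excitation is low
  for (i in 1:30000) a <- adaptation_step(a, 0, 1, dp)
  expect_lt(a, 0.001)
})

test_that("excitation inherits per-event fine structure from the rate drives", {
  r <- chains_run(16, 200, duration_s = 60, seed = 5,
                  preinstall = c("ABA", "A", "B"), discover = FALSE,
                  noise = FALSE)
  e <- r$traces$E[3000:6000, 1]
  s <- r$traces$S[3000:6000, 1]
  ## S oscillates around its steady rate; E shows a (smaller) ripple
  expect_gt(max(s) - min(s), 0.5)
  expect_gt(max(e) - min(e), 1e-4)
  expect_lt(max(e) - min(e), 0.2)
})

test_that("collision structure: the two segregated chains never collide", {
  ev <- aba_train(16, 200, duration_s = 8)
  ast <- streamchains:::asm_new_state(assembly_params(), 1600)
  for (w in c("ABA", "A", "B")) {
    ch <- streamchains:::canonical_chain(w, 16, 200)
    ch$id <- ast$next_id; ast$next_id <- ast$next_id + 1L
    ast$closed[[length(ast$closed) + 1L]] <- ch
  }
  pairs <- matrix(0, 3, 3)
  for (i in seq_len(nrow(ev))) {
    res <- streamchains:::asm_process_event(ast, ev$onset_ms[i],
                                            ev$frequency_hz[i],
                                            discover = FALSE)
    pr <- sort(res$predictors)
    if (length(pr) > 1)
      for (a in pr) for (b in pr) if (a < b)
        pairs[a, b] <- pairs[a, b] + 1
  }
  ## ids: 1 = ABA, 2 = A, 3 = B.  ABA collides with both; A and B never.
  expect_gt(pairs[1, 2], 0)
  expect_gt(pairs[1, 3], 0)
  expect_equal(pairs[2, 3], 0)
  ## ABA x A collide twice per cycle (both A positions), ABA x B once
  cycles <- floor(8000 / 800)
  expect_equal(pairs[1, 2] / cycles, 2, tolerance = 0.2)
  expect_equal(pairs[1, 3] / cycles, 1, tolerance = 0.2)
})

test_that("dominance is invariant to presentation rate for installed chains", {
  dom <- sapply(c(100, 200), function(dt) {
    mean(sapply(1:6, function(s)
      dominance_segregated(chains_run(16, dt, 120, seed = s + 50,
                                      preinstall = c("ABA", "A", "B"),
                                      discover = FALSE,
                                      keep_traces = FALSE))))
  })
  expect_lt(abs(dom[1] - dom[2]), 0.12)
})

test_that("without noise the installed system settles into one of two attractors", {
  finals <- matrix(NA_real_, 12, 3)
  for (i in 1:12) {
    set.seed(i)
    st0 <- charged_init(200, e = runif(3), i = runif(3))
    r <- chains_run(16, 200, 30, seed = 1, preinstall = c("ABA", "A", "B"),
                    discover = FALSE, noise = FALSE, init_state = st0,
                    init_collisions = charged_collisions(200))
    finals[i, ] <- r$traces$E[nrow(r$traces$E), ]
  }
  ## every endpoint lies on one of exactly two configurations
  centers <- unique(round(finals, 2))
  expect_equal(nrow(centers), 2)
  ## one has the integrated chain on top, the other the segregated pair
  on_top <- apply(finals, 1, which.max)
  expect_setequal(unique(on_top), c(1, 2))
})
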