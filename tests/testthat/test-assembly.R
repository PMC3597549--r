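ap <- assembly_params()
apInf <- assembly_params(tau_link = Inf)

test_that("matching uses a strict ellipse in time-feature space", {
  e <- c(1000, 400)
  expect_true(events_match(e, e))
  ## feature width alone: 0.6 ST at zero time difference is outside
  expect_false(events_match(e, c(1000, 400 * 2^(0.6 / 12))))
  expect_true(events_match(e, c(1000, 400 * 2^(0.4 / 12))))
  ## boundary is exclusive: exactly the temporal width does not match
  expect_false(events_match(e, c(1030, 400)))
  expect_true(events_match(e, c(1029, 400)))
  ## joint criterion: each coordinate inside its width but outside the ellipse
  expect_false(events_match(e, c(1025, 400 * 2^(0.42 / 12))))
  ## one-dimensional variants
  expect_true(match_time(c(0, 400), c(20, 999)))
  expect_false(match_time(c(0, 400), c(30, 400)))
  expect_true(match_feature(c(0, 400), c(5000, 400)))
  expect_false(match_feature(c(0, 400), c(0, 500)))
})

test_that("inclusion probability falls with feature jump, crowd and gap", {
  a <- c(0, 400)
  ## no feature change, no predictors, no temporal discounting -> certain
  expect_equal(p_include(a, c(200, 400), 0, apInf), 1.0)
  ## single predictor at beta = 1: hand evaluation of the exponential
  expect_equal(p_include(a, c(200, 400), 1, apInf), exp(-1))
  ## temporal-proximity factor at the default scale
  expect_equal(p_include(a, c(200, 400), 0, ap), exp(-200 / ap$tau_link))
  ## strictly decreasing in the feature jump (16 vs 4 ST over one interval)
  p16 <- p_include(a, c(100, 400 * 2^(16 / 12)), 0, ap)
  p4 <- p_include(a, c(100, 400 * 2^(4 / 12)), 0, ap)
  expect_lt(p16, p4)
  ## strictly decreasing in the number of predictors
  expect_lt(p_include(a, c(100, 500), 2, ap), p_include(a, c(100, 500), 1, ap))
  expect_error(p_include(c(100, 400), c(100, 500)), "later")
})

test_that("skipping is driven by rate of change and prediction imbalance", {
  a <- c(0, 400)
  b16 <- c(100, 400 * 2^(16 / 12))
  ## zero feature change, no imbalance: hand evaluation gives exactly 0
  expect_equal(p_skip(a, c(200, 400), 0), 0)
  ## rate-of-change cost: d^2/dt in ST^2 per second
  d <- semitone_distance(400, b16[2])
  expect_equal(p_skip(a, b16, 0), 1 - exp(-0.0055 * d^2 / 0.1))
  ## faster change (same jump, shorter gap) -> easier to skip
  expect_gt(p_skip(a, b16, 0), p_skip(a, c(300, b16[2]), 0))
  ## a positive prediction excess facilitates, a negative one does not
  expect_gt(p_skip(a, b16, 1), p_skip(a, b16, 0))
  expect_equal(p_skip(a, b16, -1), p_skip(a, b16, 0))
  ## an event matching an already-included frequency can never be skipped
  expect_equal(p_skip(a, b16, 1, included_freqs = c(400, b16[2])), 0)
})

test_that("forced draws on ABAC reproduce the canonical discovery trace", {
  ev <- abac_events()
  ast <- run_assembly(ev, force = TRUE)
  ## after the 2nd A both loops exist: AB<- (2 events) and A-<- (1 event)
  alive <- vapply(ast$closed, function(ch) ch$id, 0L)
  periods <- vapply(ast$closed, function(ch) ch$period, 0)
  sizes <- vapply(ast$closed, function(ch) length(ch$offsets), 0L)
  expect_setequal(paste(periods, sizes), c("200 2", "200 1"))
  ## and the open population still contains the A-A and ABA open chains
  keys <- paste(vapply(ast$open$nf, length, 0L),
                vapply(ast$open$nf, function(v) sum(abs(v - 400) < 1), 0L))
  expect_true("2 2" %in% keys)   # A-A
  expect_true("3 2" %in% keys)   # A B A
  ## C kills AB<- (its predicted B never arrives); A-<- persists
  tab <- chain_table(ast, t_end = 400)
  ab <- tab[tab$n_events == 2, ]
  a <- tab[tab$n_events == 1, ]
  expect_equal(ab$died_ms, 400)
  expect_true(is.na(a$died_ms))
  expect_equal(a$period, 200)
})

test_that("closure requires at least two events and retains the open copy", {
  ## a single A followed by nothing never closes
  ev <- event_sequence(0, 400, total_duration_ms = 1000)
  ast <- run_assembly(ev, force = TRUE)
  expect_length(ast$closed, 0)
  ## A at 0 and 400 ms close a 400-ms loop; the grown open chain remains
  ev2 <- event_sequence(c(0, 400), c(400, 400))
  ast2 <- run_assembly(ev2, force = TRUE)
  expect_equal(vapply(ast2$closed, function(ch) ch$period, 0), 400)
  expect_true(2 %in% vapply(ast2$open$nf, length, 0L))
})

test_that("closed chains are removed when a prediction goes unmatched", {
  ## install the canonical integrated chain, then stop the B tones
  ev <- aba_train(16, 200, duration_s = 4)
  broken <- ev[abs(ev$frequency_hz - 400) < 1 | ev$onset_ms < 2000, ]
  broken <- event_sequence(broken$onset_ms, broken$frequency_hz,
                           total_duration_ms = 4000)
  r <- chains_run(16, 200, events = broken, seed = 1,
                  preinstall = c("ABA", "A"), discover = FALSE,
                  keep_traces = FALSE)
  ch <- r$chains
  ## the integrated chain dies at the first missing B; the A chain survives
  expect_equal(ch$died_ms[ch$both_class], 2800)
  expect_true(is.na(ch$died_ms[!ch$both_class]))
})

test_that("probation and admission follow the p_compete gate", {
  ev <- aba_train(0.001, 200, duration_s = 10)  # effectively A-only train
  ## p_compete = 0: chains verify but never enter the competition
  ast0 <- run_assembly(ev, assembly_params(p_compete = 0), seed = 2)
  expect_length(Filter(function(ch) ch$status == "competitive", ast0$closed), 0)
  ## p_compete = 1: the first clean candidate always enters
  ast1 <- run_assembly(ev, assembly_params(p_compete = 1), seed = 2)
  expect_gt(length(Filter(function(ch) ch$status == "competitive",
                          ast1$closed)), 0)
})

test_that("admission frequency matches the probation gate on average", {
  ## on a plain periodic A train every clean candidate faces the same
  ## Bernoulli(p_compete) draw; the first-admission time is then
  ## geometric in the candidate stream.  Compare admission counts at two
  ## gate settings across seeds.
  n_admitted <- function(p, seeds) {
    sum(vapply(seeds, function(s) {
      ast <- run_assembly(aba_train(0.001, 250, duration_s = 5),
                          assembly_params(p_compete = p), seed = s)
      as.integer(any(vapply(ast$closed, function(ch)
        ch$status == "competitive", TRUE)))
    }, 0L))
  }
  expect_gt(n_admitted(0.9, 1:12), n_admitted(0.05, 1:12))
})

test_that("chain equivalence compares predictions over two cycles", {
  mk <- function(offsets, freqs, period, t0)
    streamchains:::new_closed_chain(1L, offsets, freqs, period, t0,
                                    close_t = t0 + period, close_n = 0L, ap)
  a1 <- mk(0, 400, 400, 0)
  expect_true(chains_equivalent(a1, a1))
  ## the same pattern rediscovered one cycle later
  a2 <- mk(0, 400, 400, 400)
  expect_true(chains_equivalent(a1, a2, now = 1000))
  ## a two-node representation of the same A stream (period doubled)
  a3 <- mk(c(0, 400), c(400, 400), 800, 0)
  expect_true(chains_equivalent(a1, a3, now = 1000))
  ## different frequency class: never equivalent
  b <- mk(0, 400 * 2^(16 / 12), 800, 200)
  expect_false(chains_equivalent(a1, b, now = 1000))
  ## same class, different period: not equivalent
  a4 <- mk(0, 400, 800, 0)
  expect_false(chains_equivalent(a1, a4, now = 1000))
})

test_that("open population stays bounded on long dense inputs", {
  ev <- aba_train(4, 100, duration_s = 60)
  ast <- run_assembly(ev, seed = 3)
  expect_lt(length(ast$open$first_t), 500)
  expect_true(all(vapply(ast$open$nf, length, 0L) <=
                    assembly_params()$max_open_length))
})

test_that("all three canonical chains are discoverable at the neutral condition", {
  roles <- c()
  for (s in 1:8) {
    r <- chains_run(16, 200, duration_s = 120, seed = s, keep_traces = FALSE)
    adm <- r$chains[!is.na(r$chains$admitted_ms), ]
    roles <- union(roles, chain_role(adm))
  }
  expect_setequal(roles, c("integrated", "A", "B"))
})
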