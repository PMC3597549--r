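## shared fixtures for the test suite -- all built in code

## an ABAC sequence at 100-ms spacing: A 400 Hz, B 5 ST up, C 12 ST up
abac_events <- function() {
  event_sequence(c(0, 100, 200, 300),
                 c(400, 400 * 2^(5 / 12), 400, 800))
}

## run the assembly engine alone over an event sequence, with optional
## forced branch draws; returns the engine state
run_assembly <- function(events, params = assembly_params(), seed = 1,
                         force = FALSE, span_fallback = 2000) {
  ast <- streamchains:::asm_new_state(params, span_fallback)
  set.seed(seed)
  for (i in seq_len(nrow(events)))
    streamchains:::asm_process_event(ast, events$onset_ms[i],
                                     events$frequency_hz[i],
                                     force_include = force,
                                     force_skip = force,
                                     force_admit = force)
  ast
}

chain_table <- function(ast, t_end = NULL) {
  if (!is.null(t_end)) streamchains:::asm_finalize(ast, t_end)
  streamchains:::chain_log_df(ast)
}

## classify chain-log rows into the canonical roles
chain_role <- function(ch, base = 400) {
  ifelse(ch$both_class, "integrated",
         ifelse(abs(12 * log2(ch$freq_lo / base)) < 0.5, "A", "B"))
}

## admission time (s) of the first single-frequency chain on the base tone
a_chain_delay <- function(run) {
  ch <- run$chains
  a <- ch[!ch$both_class & abs(ch$freq_lo - 400) < 1 &
            !is.na(ch$admitted_ms), ]
  if (nrow(a)) min(a$admitted_ms) / 1000 else NA_real_
}

b_chain_delay <- function(run) {
  ch <- run$chains
  b <- ch[!ch$both_class & ch$freq_lo > 450 & !is.na(ch$admitted_ms), ]
  if (nrow(b)) min(b$admitted_ms) / 1000 else NA_real_
}

first_label <- function(run) {
  if (nrow(run$phases)) run$phases$label[1] else NA_character_
}

## steady-state init for pre-installed canonical chains (rates charged)
charged_init <- function(delta_t, e = c(0, 0, 0), i = c(0, 0, 0)) {
  rate <- 1000 / delta_t / 4          # cycles per second
  st0 <- matrix(0, 3, 7)
  st0[, 1] <- e; st0[, 2] <- i
  st0[, 5] <- c(3, 2, 1) * rate       # S: ABA, A, B successes per second
  st0[, 6] <- 3 * rate                # R: events per second
  st0
}

charged_collisions <- function(delta_t) {
  rate <- 1000 / delta_t / 4
  matrix(c(0, 2, 1, 2, 0, 0, 1, 0, 0), 3, 3, byrow = TRUE) * rate
}
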