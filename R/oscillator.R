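#' Run a thresholded oscillator and collect gate events
#'
#' A discrete-time ideal sinusoid \eqn{a(t) = A \sin(2\pi f t + \phi_0)}
#' sampled at integer steps. A *trigger* event fires at every upward
#' threshold crossing — the first step `t` with `a(t-1) <= threshold < a(t)`
#' — and stands for the moment a discrete binding operation is released.
#' With `emit_gain = TRUE` the rising and falling crossings are additionally
#' reported as `gain_on` / `gain_off` events, the boolean reduction of
#' gain synchronization between populations.
#'
#' Time is unitless; mapping steps to milliseconds (theta/gamma bands) is a
#' matter of interpretation only.
#'
#' @param freq cycles per time step, in (0, 0.5) (below Nyquist).
#' @param threshold trigger level (same units as amplitude).
#' @param steps horizon; steps 1..steps are examined (>= 1).
#' @param phase0 initial phase in radians.
#' @param amplitude oscillation amplitude (>= 0).
#' @param source label recorded on each event.
#' @param emit_gain also emit gain_on/gain_off events at the crossings.
#' @return a data frame of events: `time_step`, `source`, `kind`,
#'   `decoded_order` (NA here; filled by [gated_encode()]).
#' @examples
#' run_oscillator(freq = 0.1, threshold = 0, steps = 40)
#' @export
run_oscillator <- function(freq, threshold = 0, steps, phase0 = 0,
                           amplitude = 1, source = "P1", emit_gain = FALSE) {
  if (freq <= 0 || freq >= 0.5) {
    vs_error("vsbind_param_error", "freq must be in (0, 0.5)")
  }
  if (steps < 1) vs_error("vsbind_param_error", "steps must be >= 1")
  t <- 0:steps
  a <- amplitude * sin(2 * pi * freq * t + phase0)
  up <- which(a[-length(a)] <= threshold & a[-1] > threshold)      # event at t = up
  down <- which(a[-length(a)] > threshold & a[-1] <= threshold)
  ev <- data.frame(time_step = up, source = rep(source, length(up)),
                   kind = rep("trigger", length(up)),
                   decoded_order = rep(NA_integer_, length(up)),
                   stringsAsFactors = FALSE)
  if (emit_gain) {
    gev <- data.frame(time_step = c(up, down), source = source,
                      kind = rep(c("gain_on", "gain_off"),
                                 c(length(up), length(down))),
                      decoded_order = NA_integer_, stringsAsFactors = FALSE)
    ev <- rbind(ev, gev)
  }
  ev[order(ev$time_step, ev$kind), , drop = FALSE]
}

#' Two antisynchronous gate streams
#'
#' Two oscillators of the same frequency held in antiphase (offset pi)
#' segregate two streams of operations: their trigger events interleave and
#' never share a time step, so operations driven by one stream cannot
#' interfere with the other's.
#'
#' @inheritParams run_oscillator
#' @return a list of two event data frames, sources `"P1"` and `"P2"`.
#' @export
antisynchronous_pair <- function(freq, steps, threshold = 0) {
  list(P1 = run_oscillator(freq, threshold, steps, phase0 = 0, source = "P1"),
       P2 = run_oscillator(freq, threshold, steps, phase0 = pi, source = "P2"))
}

#' Map oscillator phase to an ordinal position
#'
#' Divides the cycle into K equal phase bins and returns the 1-based bin:
#' `1 + floor(K * phase / 2pi)`, with phase wrapped into \[0, 2pi). The bin —
#' not absolute time — determines the positional tag, which is what makes
#' position codes boundary-relative: item onsets evenly spaced within one
#' cycle decode to orders 1..K in onset order wherever the cycle sits in
#' absolute time.
#'
#' @param phase phase in radians (any real; wrapped).
#' @param K number of positions per cycle (>= 1).
#' @return an integer order in 1..K.
#' @examples
#' phase_to_position(0, 4)            # 1
#' phase_to_position(2 * pi - 1e-9, 4)  # 4
#' @export
phase_to_position <- function(phase, K) {
  if (K < 1) vs_error("vsbind_param_error", "K must be >= 1")
  ph <- phase %% (2 * pi)
  pmin(1L + as.integer(floor(K * ph / (2 * pi))), as.integer(K))
}

#' Oscillator-gated sequence encoding
#'
#' Schedules the serial-order encoder with an oscillator: each token's
#' position (x) item binding is committed at the first trigger event at or
#' after its onset, and its order index is decoded from the phase of a
#' positional oscillator running at `freq / K` (K = the tag set's capacity),
#' referenced to the first committed token. Consecutive gate triggers
#' therefore advance the phase by exactly one position bin, so for stimuli
#' entrained to the gate the final trace is bit-identical to
#' [encode_sequence()] on the same ordered tokens — the scheduler changes
#' *when* operations happen, never *what* is computed.
#'
#' Two tokens claiming one trigger, or two tokens decoding to the same
#' position bin, raise a collision error advising a higher gate frequency.
#'
#' @param tokens vocabulary names, in presentation order.
#' @param onsets strictly increasing integer onset steps, one per token.
#' @param vocab,tags,gamma,rho as in [encode_sequence()].
#' @param freq gate frequency in cycles per step, in (0, 0.5).
#' @param threshold trigger threshold.
#' @param steps simulation horizon; defaults to the last onset plus two gate
#'   periods.
#' @return a `sequence_trace`, with the gate event log (including decoded
#'   orders) attached as attribute `"events"`.
#' @examples
#' voc <- hrr_vocabulary(c("A", "B", "C"), 256, seed = 2)
#' tg  <- make_tagset("item", 256, 3, seed = 2)
#' g <- gated_encode(c("A", "B", "C"), c(3, 13, 23), voc, tg, freq = 0.1,
#'                   gamma = 1, rho = 0)
#' identical(g$vector, encode_sequence(c("A", "B", "C"), voc, tg, 1, 0)$vector)
#' @export
gated_encode <- function(tokens, onsets, vocab, tags, freq, threshold = 0,
                         gamma = 0.82, rho = 0.35, steps = NULL) {
  tokens <- as.character(tokens)
  onsets <- as.integer(onsets)
  if (length(tokens) != length(onsets)) {
    vs_error("vsbind_param_error", "one onset per token required")
  }
  if (length(onsets) > 1 && any(diff(onsets) <= 0)) {
    vs_error("vsbind_param_error", "onsets must be strictly increasing")
  }
  check_buffer_params(gamma, rho)
  if (is.null(steps)) steps <- max(onsets) + ceiling(2 / freq)
  ev <- run_oscillator(freq, threshold, steps)
  trig <- ev$time_step
  commits <- vapply(onsets, function(on) {
    hit <- trig[trig >= on]
    if (length(hit) == 0) {
      vs_error("vsbind_param_error", "horizon too short: onset never gated")
    }
    hit[1]
  }, numeric(1))
  if (anyDuplicated(commits)) {
    vs_error("vsbind_collision_error",
             "two tokens claim one gate trigger; increase the gate frequency")
  }
  K <- tags$max_order
  pos_freq <- freq / K
  orders <- phase_to_position(2 * pi * pos_freq * (commits - commits[1]), K)
  if (anyDuplicated(orders)) {
    vs_error("vsbind_collision_error",
             "two tokens decode to one position bin; increase the gate frequency")
  }
  L <- length(tokens)
  if (L > 0 && max(orders) > K) {
    vs_error("vsbind_capacity_error", "decoded order exceeds tag capacity")
  }
  vec <- encode_weighted(tokens, orders, decay_weights(L, gamma, rho),
                         vocab, tags)
  ev$decoded_order[match(commits, ev$time_step)] <- orders
  out <- structure(list(vector = vec, length = L, dim = tags$dim,
                        level = tags$level, gamma = gamma, rho = rho,
                        log = tokens),
                   class = "sequence_trace")
  attr(out, "events") <- ev
  out
}

#' Phase concentration of gate events (phase-amplitude coupling readout)
#'
#' Computes the circular resultant length of the driving oscillator's phase
#' at each event time. Trigger events fire at a fixed phase of their
#' oscillator, so the concentration is near 1 — fast discrete operations
#' clustering at a preferred phase of a driving rhythm is the functional
#' signature of phase-amplitude coupling.
#'
#' @param events an event data frame from [run_oscillator()] (or the
#'   `"events"` attribute of [gated_encode()]).
#' @param freq,phase0 parameters of the driving oscillator.
#' @return resultant length in \[0, 1\]; 1 = perfectly phase-locked.
#' @export
phase_concentration <- function(events, freq, phase0 = 0) {
  ph <- (2 * pi * freq * events$time_step + phase0) %% (2 * pi)
  if (length(ph) == 0) return(NA_real_)
  Mod(mean(complex(modulus = 1, argument = ph)))
}
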