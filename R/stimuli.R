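#' Translating-block stimuli
#'
#' Builds the stimulus set: the input layer is divided into as many equal
#' contiguous partitions as there are stimuli, and each stimulus is an ordered
#' list of "transforms" — blocks of `width` contiguous input neurons shifted
#' by `shift` neurons per successive transform within that stimulus's
#' partition. `keep_every` subsamples the transform sequence (keeping
#' transforms 1, 1+keep_every, ...), which lowers the spatial overlap between
#' consecutive *kept* transforms to `max(0, width - shift * keep_every)`
#' without changing the span covered.
#'
#' @param n_input number of excitatory input-layer neurons.
#' @param n_stimuli number of stimuli (equal partitions of the input layer).
#' @param n_transforms number of transforms per stimulus before subsampling.
#' @param width neurons per transform.
#' @param shift neurons displaced per successive transform.
#' @param keep_every subsampling factor (1 keeps all transforms).
#' @return A `stimulus_set`: list with `transforms` (per stimulus, a list of
#'   integer index vectors into the input layer), the geometry fields, and
#'   `n_kept` transforms per stimulus after subsampling.
#' @examples
#' s <- make_stimuli(400, 2, 13, 56, 12)
#' transform_overlap(s)  # 44 shared neurons between consecutive transforms
#' @export
make_stimuli <- function(n_input, n_stimuli, n_transforms, width, shift,
                         keep_every = 1) {
  stopifnot(n_input >= 1, n_stimuli >= 1, n_transforms >= 1,
            width >= 1, shift >= 0, keep_every >= 1)
  partition <- n_input %/% n_stimuli
  span <- (n_transforms - 1) * shift + width
  if (span > partition) {
    stop(sprintf(
      "stimulus geometry exceeds its partition: %d transforms of width %d shifted by %d span %d neurons but the partition holds %d",
      n_transforms, width, shift, span, partition
    ))
  }
  kept <- seq(1, n_transforms, by = keep_every)
  transforms <- lapply(seq_len(n_stimuli), function(s) {
    base <- (s - 1L) * partition
    lapply(kept, function(k) {
      start <- base + (k - 1L) * shift + 1L
      as.integer(seq.int(start, start + width - 1L))
    })
  })
  structure(
    list(transforms = transforms, n_stimuli = as.integer(n_stimuli),
         n_transforms = as.integer(n_transforms),
         n_kept = length(kept), width = as.integer(width),
         shift = as.integer(shift), keep_every = as.integer(keep_every),
         n_input = as.integer(n_input)),
    class = "stimulus_set"
  )
}

#' Overlap between consecutive transforms
#'
#' @param stimset a `stimulus_set`.
#' @return The number of input neurons shared by consecutive kept transforms,
#'   `max(0, width - shift * keep_every)`.
#' @export
transform_overlap <- function(stimset) {
  max(0L, stimset$width - stimset$shift * stimset$keep_every)
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf(
    "<stimulus_set: %d stimuli x %d transforms (%d neurons each, shift %d%s) on %d inputs; consecutive overlap %d>\n",
    x$n_stimuli, x$n_kept, x$width, x$shift,
    if (x$keep_every > 1) sprintf(", every %dth kept", x$keep_every) else "",
    x$n_input, transform_overlap(x)
  ))
  invisible(x)
}

#' Presentation schedule
#'
#' Orders the `(stimulus, transform)` presentations of a training epoch or a
#' test sweep. Training regimes:
#' \describe{
#'   \item{`sequential`}{per epoch, stimuli in a freshly drawn random order,
#'     each stimulus's transforms presented in order before the next stimulus.}
#'   \item{`interleaved`}{stimuli alternate transform by transform:
#'     S1-t1, S2-t1, S1-t2, S2-t2, ...}
#'   \item{`randomized`}{like sequential, but each stimulus's transform order
#'     is shuffled independently per epoch.}
#'   \item{`randomized_interleaved`}{stimuli alternate while each stimulus
#'     follows its own shuffled transform order.}
#' }
#' The test phase presents all transforms of all stimuli in order, with
#' `reset_before = TRUE` for every event so that activity evoked by one
#' transform cannot contaminate the next. During training, `reset_before` is
#' set at stimulus boundaries when `settle_between_stimuli` is on (used in the
#' trace regime to avoid an artificial temporal association between stimuli)
#' and is `FALSE` otherwise — presentations abut with no gaps.
#'
#' Stimulus/transform order randomization draws from the R RNG; call
#' `set.seed()` beforehand for a reproducible schedule.
#'
#' @param stimset a `stimulus_set`.
#' @param regime one of `"sequential"`, `"interleaved"`, `"randomized"`,
#'   `"randomized_interleaved"`; ignored for the test phase.
#' @param phase `"train"` or `"test"`.
#' @param epochs number of training epochs (each presents every
#'   `(stimulus, transform)` pair exactly once).
#' @param duration_ms cue period per presentation; defaults to 100 ms for
#'   training and 250 ms for testing.
#' @param i_ext_nA injected cue current (nA) delivered to every neuron of the
#'   active transform for the whole cue period.
#' @param settle_between_stimuli logical; reset the network state whenever the
#'   stimulus identity changes (training only).
#' @return A `schedule`: data.frame with columns `event`, `stimulus`,
#'   `transform`, `t_start_ms`, `duration_ms`, `i_ext_nA`, `reset_before`.
#' @export
make_schedule <- function(stimset,
                          regime = c("sequential", "interleaved",
                                     "randomized", "randomized_interleaved"),
                          phase = c("train", "test"), epochs = 5,
                          duration_ms = NULL, i_ext_nA = 1.0,
                          settle_between_stimuli = FALSE) {
  phase <- match.arg(phase)
  regime <- match.arg(regime)
  stopifnot(epochs >= 1, i_ext_nA >= 0)
  n_s <- stimset$n_stimuli
  n_t <- stimset$n_kept
  duration_ms <- duration_ms %||% if (phase == "train") 100 else 250
  stopifnot(duration_ms > 0)

  if (phase == "test") {
    ev <- data.frame(
      stimulus = rep(seq_len(n_s), each = n_t),
      transform = rep(seq_len(n_t), times = n_s),
      reset_before = TRUE
    )
  } else {
    one_epoch <- function() {
      shuffle <- regime %in% c("randomized", "randomized_interleaved")
      orders <- lapply(seq_len(n_s), function(s) {
        if (shuffle) sample.int(n_t) else seq_len(n_t)
      })
      if (regime %in% c("interleaved", "randomized_interleaved")) {
        stim <- rep(seq_len(n_s), times = n_t)
        trans <- unlist(lapply(seq_len(n_t), function(k) {
          vapply(seq_len(n_s), function(s) orders[[s]][k], integer(1))
        }))
      } else {
        stim_order <- sample.int(n_s)
        stim <- rep(stim_order, each = n_t)
        trans <- unlist(orders[stim_order])
      }
      data.frame(stimulus = stim, transform = trans)
    }
    ev <- do.call(rbind, lapply(seq_len(epochs), function(e) one_epoch()))
    ev$reset_before <- if (settle_between_stimuli) {
      c(TRUE, ev$stimulus[-1] != ev$stimulus[-nrow(ev)])
    } else FALSE
  }

  ev$event <- seq_len(nrow(ev))
  ev$duration_ms <- duration_ms
  ev$i_ext_nA <- i_ext_nA
  ev$t_start_ms <- (ev$event - 1) * duration_ms
  sched <- ev[, c("event", "stimulus", "transform", "t_start_ms",
                  "duration_ms", "i_ext_nA", "reset_before")]
  attr(sched, "phase") <- phase
  attr(sched, "regime") <- if (phase == "test") "test" else regime
  class(sched) <- c("schedule", "data.frame")
  sched
}
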