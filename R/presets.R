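#' Preset experiment configurations
#'
#' Returns the fully specified network, stimuli and schedules for each of the
#' standard experiments. The two baseline regimes are:
#' \describe{
#'   \item{continuous-transformation (`ct_*`)}{fast feed-forward conductances
#'     (`tau_EE = 2` ms, cap 4 nS) and strongly overlapping transforms
#'     (13 per stimulus, 56 neurons wide, shifted by 12, overlap 44): learning
#'     rides on the spatial overlap between successive transforms.}
#'   \item{trace (`trace_*`)}{slow feed-forward conductances (`tau_EE = 150`
#'     ms, cap 1.25 nS) and orthogonal transforms (10 per stimulus, 20 neurons
#'     wide, shifted by 20, zero overlap) with the network settled between
#'     stimuli: learning rides on the conductance trace linking temporally
#'     adjacent transforms.}
#' }
#' Variants change one factor: `*_stdp_fast` / `*_stdp_slow` set the STDP
#' time constants to 3/5 or 75/125 ms (baseline 15/25); `*_inhibition_sweep`
#' lowers the inhibitory-to-excitatory conductance (default 0.5 nS, baseline
#' 2.5 nS); `ct_overlap_2nd` / `ct_overlap_3rd` keep every 2nd/3rd transform
#' (overlap 32/20 neurons); `*_interleaved` alternates the stimuli transform
#' by transform (with no settling, so a trace can bridge stimuli);
#' `ct_randomized_interleaved` additionally shuffles each stimulus's transform
#' order; `trace_randomized` shuffles the transform order within each
#' stimulus block.
#'
#' Schedule randomization and nothing else draws from the R RNG here; seed
#' before calling (or use [run_experiment()], which seeds everything).
#'
#' @param name preset name, see Details.
#' @param scale proportional network scale in `(0, 1]`; cell counts and
#'   stimulus geometry shrink with `scale`, synaptic increments grow by
#'   `1/scale` so that the summed drive per neuron is preserved. Use values
#'   for which the scaled geometry is integral (1, 0.5, 0.25).
#' @param epochs training epochs (0 = untrained).
#' @param g_IE_nS override for the inhibitory-to-excitatory conductance (nS).
#' @return A list: `name`, `config` ([network_config()]), `stimset`
#'   ([make_stimuli()]), `train_schedule`, `test_schedule`.
#' @export
preset <- function(name, scale = 1, epochs = 5, g_IE_nS = NULL) {
  names_all <- c(
    "ct_baseline", "ct_stdp_fast", "ct_stdp_slow", "ct_inhibition_sweep",
    "ct_overlap_2nd", "ct_overlap_3rd", "ct_interleaved",
    "ct_randomized_interleaved", "trace_baseline", "trace_stdp_fast",
    "trace_stdp_slow", "trace_inhibition_sweep", "trace_interleaved",
    "trace_randomized"
  )
  name <- match.arg(name, names_all)
  trace <- startsWith(name, "trace")

  tau_CD <- switch(sub("^(ct|trace)_", "", name),
    stdp_fast = c(3, 5), stdp_slow = c(75, 125), c(15, 25)
  )
  g_IE <- g_IE_nS %||%
    if (grepl("inhibition_sweep", name)) 0.5 else 2.5
  keep_every <- switch(name, ct_overlap_2nd = 2, ct_overlap_3rd = 3, 1)
  regime <- switch(sub("^(ct|trace)_", "", name),
    interleaved = "interleaved",
    randomized_interleaved = "randomized_interleaved",
    randomized = "randomized",
    "sequential"
  )
  settle <- trace && name != "trace_interleaved"

  config <- network_config(
    tau_EE_ms = if (trace) 150 else 2,
    lambda_EE_nS = if (trace) 1.25 else 4,
    g_IE_nS = g_IE,
    plasticity = plasticity_params(tau_C_ms = tau_CD[1], tau_D_ms = tau_CD[2]),
    scale = scale
  )
  geom <- if (trace) c(n_transforms = 10, width = 20, shift = 20)
          else c(n_transforms = 13, width = 56, shift = 12)
  w <- geom[["width"]] * scale
  sh <- geom[["shift"]] * scale
  if (w != round(w) || sh != round(sh)) {
    stop("scale must keep the stimulus geometry integral (use 1, 0.5 or 0.25)")
  }
  stimset <- make_stimuli(config$n_exc, 2, geom[["n_transforms"]],
                          round(w), round(sh), keep_every)
  train_schedule <- if (epochs >= 1) {
    make_schedule(stimset, regime = regime, phase = "train", epochs = epochs,
                  settle_between_stimuli = settle)
  } else NULL
  test_schedule <- make_schedule(stimset, phase = "test")
  list(name = name, config = config, stimset = stimset,
       train_schedule = train_schedule, test_schedule = test_schedule)
}

#' Train, test and analyze one preset in a single call
#'
#' Seeds the RNG, builds the network (uniform random initial efficacies),
#' runs the training schedule with learning on, then the test schedule with
#' learning off (every test presentation starts from a settled network),
#' converts the test spikes to a rate table and computes both information
#' measures.
#'
#' @param name preset name, see [preset()].
#' @param seed integer seed covering weight initialization, schedule
#'   randomization, membrane noise and decoding.
#' @param scale,epochs,g_IE_nS passed to [preset()].
#' @param n_iterations decoding iterations for [multi_cell_info()].
#' @param record_training logical; keep input-layer spikes from the training
#'   phase (for volley/raster analysis).
#' @return A list: `name`, `seed`, `preset`, trained `state`, `test` run,
#'   optionally `train` run, `rate` table, `info` ([multi_cell_info()]
#'   result) and a `summary` list with `max_single_bits`, `top_decile_bits`
#'   (mean single-cell information of the best 10% of cells),
#'   `multi_bits` (largest-ensemble multiple-cell information) and
#'   `responsive_rate_hz`.
#' @export
run_experiment <- function(name, seed = 1, scale = 1, epochs = 5,
                           g_IE_nS = NULL, n_iterations = 100,
                           record_training = FALSE) {
  set.seed(seed)
  p <- preset(name, scale = scale, epochs = epochs, g_IE_nS = g_IE_nS)
  state <- build_network(p$config)
  train <- NULL
  if (!is.null(p$train_schedule)) {
    train <- run_network(state, p$stimset, p$train_schedule,
                         learning_on = TRUE,
                         record = if (record_training) "input" else "none")
    state <- train$state
    if (!record_training) train$spikes <- NULL
  }
  test <- run_network(state, p$stimset, p$test_schedule,
                      learning_on = FALSE, record = "output")
  rate <- rates_from_spikes(test$spikes, p$test_schedule, p$config$n_exc)
  info <- multi_cell_info(rate, n_iterations = n_iterations)
  sci <- info$single_cell$max_bits
  top_k <- max(1L, round(0.1 * length(sci)))
  summary <- list(
    max_single_bits = max(sci),
    top_decile_bits = mean(sort(sci, decreasing = TRUE)[seq_len(top_k)]),
    multi_bits = info$bits[length(info$bits)],
    responsive_rate_hz = responsive_rate(rate)
  )
  list(name = name, seed = seed, preset = p, state = state,
       train = train, test = test, rate = rate, info = info,
       summary = summary)
}
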