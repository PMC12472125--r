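# Denoising diffusion over atom coordinates: linear beta schedule, forward
# Gaussian corruption, the epsilon-prediction training objective with Adam,
# and ancestral sampling. Only coordinates are ever noised; node and edge
# attributes other than geometry stay fixed throughout.

#' Diffusion configuration
#'
#' The beta endpoints default to the classic (1e-4, 0.02) pair rescaled by
#' `1000 / T`, which preserves the total corruption of the schedule for any
#' step count: the full-scale `T = 5000` gives (2e-5, 4e-3) and the
#' desk-scale `T = 200` gives (5e-4, 0.1); in both cases the final
#' `alpha_bar` falls below 1e-3, i.e. the terminal state is
#' indistinguishable from white noise.
#'
#' @param T Number of diffusion steps (full scale 5000; desk scale 200).
#' @param beta_start,beta_end Linear schedule endpoints.
#' @param seed Default RNG seed for sampling helpers.
#' @param coordinate_scale Divisor applied to coordinates before diffusion.
#' @export
diffusion_config <- function(T = 200L, beta_start = 1e-4 * 1000 / T,
                             beta_end = 0.02 * 1000 / T, seed = 1L,
                             coordinate_scale = 10) {
  stopifnot(T >= 2, beta_start < beta_end, beta_start > 0, beta_end < 1)
  structure(list(T = as.integer(T), beta_start = beta_start,
                 beta_end = beta_end, seed = as.integer(seed),
                 predict = "epsilon", coordinate_scale = coordinate_scale),
            class = "diffusion_config")
}

#' Build the noise schedule tables
#'
#' @param cfg A [diffusion_config()].
#' @return List of class `noise_schedule` with `T`, `betas`, `alphas`
#'   (1 - beta) and `alpha_bars` (cumulative products, strictly decreasing).
#' @export
make_schedule <- function(cfg = diffusion_config()) {
  if (cfg$T < 2) stop("T must be at least 2")
  betas <- seq(cfg$beta_start, cfg$beta_end, length.out = cfg$T)
  alphas <- 1 - betas
  structure(list(T = cfg$T, betas = betas, alphas = alphas,
                 alpha_bars = cumprod(alphas)),
            class = "noise_schedule")
}

#' Sinusoidal time embedding
#'
#' Half sines and half cosines at geometrically spaced frequencies; at
#' `t = 0` the sine half is all zeros and the cosine half all ones.
#'
#' @param t Step index (0-based position; the training loop passes `t - 1`
#'   for 1-based steps).
#' @param dim Embedding width (even).
#' @export
time_embedding <- function(t, dim = 16L) {
  if (t < 0) stop("t out of range")
  half <- dim %/% 2L
  freqs <- 10000^(-(0:(half - 1L)) / half)
  c(sin(t * freqs), cos(t * freqs))
}

#' Forward diffusion sample
#'
#' `x_t = sqrt(alpha_bar_t) x0 + sqrt(1 - alpha_bar_t) noise`; topology and
#' all non-coordinate features are untouched.
#'
#' @param x0 Clean coordinates (n x 3, scaled).
#' @param t Step in 1..T.
#' @param sched A `noise_schedule`.
#' @param noise Optional n x 3 standard-normal draw (drawn internally when
#'   NULL).
#' @return List with `x_t` and the `noise` used.
#' @export
forward_sample <- function(x0, t, sched, noise = NULL) {
  stopifnot(t >= 1, t <= sched$T)
  if (is.null(noise)) noise <- matrix(stats::rnorm(length(x0)), nrow(x0), 3)
  ab <- sched$alpha_bars[t]
  list(x_t = sqrt(ab) * x0 + sqrt(1 - ab) * noise, noise = noise)
}

#' Optimiser / schedule state for training
#'
#' Full-scale defaults: initial learning rate 0.003 decayed by 0.9 every
#' 30 epochs, gradient clipping at global norm 2. [desk_training_state()]
#' is the constant-rate variant used for the small overfit runs.
#'
#' @param lr Initial learning rate.
#' @param lr_decay Multiplicative decay factor.
#' @param decay_every Epochs between decays.
#' @param clip Global gradient-norm clip threshold.
#' @param batch_size Corruptions drawn per optimisation step.
#' @export
training_state <- function(lr = 0.003, lr_decay = 0.9, decay_every = 30L,
                           clip = 2, batch_size = 4L) {
  stopifnot(lr > 0, clip > 0)
  structure(list(lr = lr, lr_decay = lr_decay, decay_every = decay_every,
                 clip = clip, batch_size = as.integer(batch_size),
                 epoch = 0L, adam_m = NULL, adam_v = NULL, adam_t = 0L),
            class = "training_state")
}

#' @rdname training_state
#' @export
desk_training_state <- function(lr = 2e-3, batch_size = 2L) {
  training_state(lr = lr, decay_every = .Machine$integer.max,
                 batch_size = batch_size)
}

current_lr <- function(state) {
  state$lr * state$lr_decay^(state$epoch %/% state$decay_every)
}

# One Adam update from a flat gradient vector ordered like the
# column-major concatenation of the parameter list.
adam_update <- function(model, g, state) {
  if (is.null(state$adam_m)) {
    state$adam_m <- numeric(length(g))
    state$adam_v <- numeric(length(g))
  }
  gnorm <- sqrt(sum(g^2))
  if (gnorm > state$clip) g <- g * state$clip / gnorm
  state$adam_t <- state$adam_t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- current_lr(state)
  state$adam_m <- b1 * state$adam_m + (1 - b1) * g
  state$adam_v <- b2 * state$adam_v + (1 - b2) * g^2
  step <- lr * (state$adam_m / (1 - b1^state$adam_t)) /
    (sqrt(state$adam_v / (1 - b2^state$adam_t)) + eps)
  off <- 0L
  for (k in seq_along(model$params)) {
    len <- length(model$params[[k]])
    model$params[[k]] <- model$params[[k]] -
      matrix(step[(off + 1L):(off + len)], nrow(model$params[[k]]))
    off <- off + len
  }
  list(model = model, state = state)
}

#' One optimisation step of the denoiser
#'
#' Draws a uniform step t and a Gaussian noise field per batch item,
#' corrupts the clean coordinates, rebuilds the dynamic edges on the noisy
#' coordinates, and minimises the mean squared error between the drawn and
#' the predicted noise. Gradients are clipped at the configured global norm
#' and applied with Adam under the step learning-rate schedule.
#'
#' @param model A `denoiser_model`.
#' @param instances List of `diffusion_instance` objects (the batch draws
#'   uniformly among them).
#' @param sched A `noise_schedule`.
#' @param state A [training_state()].
#' @return List with updated `model`, `state` and the batch `loss`.
#' @export
training_step <- function(model, instances, sched, state) {
  stopifnot(length(instances) > 0)
  grads <- NULL
  loss <- 0
  for (b in seq_len(state$batch_size)) {
    inst <- instances[[sample.int(length(instances), 1L)]]
    t <- sample.int(sched$T, 1L)
    fs <- forward_sample(inst$x0, t, sched)
    inputs <- graph_inputs(inst, fs$x_t, t, sched)
    out <- denoiser_pass(model, inputs, target = fs$noise, with_grad = TRUE,
                         flat_grads = TRUE)
    loss <- loss + out$loss
    grads <- if (is.null(grads)) out$grads$flat else grads + out$grads$flat
  }
  loss <- loss / state$batch_size
  if (!is.finite(loss)) stop("non-finite training loss")
  up <- adam_update(model, grads / state$batch_size, state)
  up$state$epoch <- up$state$epoch + 1L
  list(model = up$model, state = up$state, loss = loss)
}

#' Train a denoiser
#'
#' @param model A `denoiser_model`.
#' @param instances List of `diffusion_instance` objects.
#' @param sched A `noise_schedule`.
#' @param steps Number of optimisation steps.
#' @param state A [training_state()].
#' @param seed RNG seed for the whole run.
#' @param log_every Record the running loss every this many steps.
#' @param ema Exponential-moving-average decay for a smoothed copy of the
#'   weights (standard practice for sampling from diffusion models);
#'   `NULL` disables it.
#' @return List with `model`, `state`, `ema_model` (NULL when disabled) and
#'   a `log` data frame (step, loss, lr).
#' @export
train_denoiser <- function(model, instances, sched, steps = 500L,
                           state = desk_training_state(), seed = 1L,
                           log_every = 25L, ema = 0.999) {
  shapes <- lapply(model$params, dim)
  ema_flat <- if (is.null(ema)) NULL else
    unlist(model$params, use.names = FALSE)
  with_seed(seed, {
    log <- NULL
    recent <- numeric(0)
    for (s in seq_len(steps)) {
      st <- training_step(model, instances, sched, state)
      model <- st$model; state <- st$state
      if (!is.null(ema_flat))
        ema_flat <- ema * ema_flat +
          (1 - ema) * unlist(model$params, use.names = FALSE)
      recent <- c(recent, st$loss)
      if (s %% log_every == 0L || s == steps) {
        log <- rbind(log, data.frame(step = s, loss = mean(recent),
                                     lr = current_lr(state)))
        recent <- numeric(0)
      }
    }
    ema_model <- NULL
    if (!is.null(ema_flat)) {
      ema_model <- model
      off <- 0L
      for (k in seq_along(ema_model$params)) {
        len <- length(ema_model$params[[k]])
        ema_model$params[[k]] <- matrix(ema_flat[(off + 1L):(off + len)],
                                        shapes[[k]][1], shapes[[k]][2])
        off <- off + len
      }
    }
    list(model = model, state = state, ema_model = ema_model, log = log)
  })
}

#' One reverse (denoising) step
#'
#' Standard posterior-mean update from the predicted noise with variance
#' `beta_tilde_t`; no noise is added at t = 1. Dynamic edges are rebuilt
#' from the current coordinates before the model call.
#'
#' @param model A `denoiser_model`.
#' @param instance A `diffusion_instance`.
#' @param x_t Current coordinates (n x 3, scaled).
#' @param t Step in 1..T.
#' @param sched A `noise_schedule`.
#' @param z Optional standard-normal draw for the stochastic part.
#' @param eps_hat Optional externally supplied noise prediction (used by
#'   oracle tests); the model is consulted when NULL.
#' @return `x_{t-1}` matrix.
#' @export
reverse_step <- function(model, instance, x_t, t, sched, z = NULL,
                         eps_hat = NULL) {
  stopifnot(t >= 1, t <= sched$T)
  if (is.null(eps_hat))
    eps_hat <- predict_noise(model, instance, x_t, t, sched)$eps_hat
  b <- sched$betas[t]
  a <- sched$alphas[t]
  ab <- sched$alpha_bars[t]
  mean <- (x_t - b / sqrt(1 - ab) * eps_hat) / sqrt(a)
  if (t == 1L) return(mean)
  ab_prev <- sched$alpha_bars[t - 1L]
  beta_tilde <- (1 - ab_prev) / (1 - ab) * b
  if (is.null(z)) z <- matrix(stats::rnorm(length(x_t)), nrow(x_t), 3)
  mean + sqrt(beta_tilde) * z
}

#' Generate a structure from sequence + secondary structure
#'
#' Builds the graph template from the Vienna-style input, initialises the
#' coordinates as white noise and runs the full reverse diffusion;
#' deterministic for a fixed seed. The returned structure is un-scaled back
#' to Angstrom (centered at the origin, as trained).
#'
#' @param model A trained `denoiser_model`.
#' @param sequences Per-strand base strings.
#' @param ss An `rna_ss` over the concatenated strands.
#' @param sched A `noise_schedule`.
#' @param seed RNG seed.
#' @param provider,embed_seed Embedding provider settings (must match
#'   training).
#' @param instance Optional ready-made `diffusion_instance` template
#'   (overrides sequences/ss).
#' @return A coarse-grained `rna_structure` in Angstrom.
#' @export
sample_structure <- function(model, sequences, ss, sched, seed = 1L,
                             provider = "fallback", embed_seed = 1L,
                             instance = NULL) {
  if (is.null(instance)) {
    tmpl <- template_structure(sequences)
    instance <- prepare_instance(tmpl, ss, provider = provider,
                                 seed = embed_seed)
  }
  with_seed(seed, {
    x <- matrix(stats::rnorm(3L * instance$n), instance$n, 3)
    for (t in seq(sched$T, 1L)) {
      x <- reverse_step(model, instance, x, t, sched)
    }
    out <- set_coords(instance$structure, x)
    out$scale_applied <- instance$scale
    out$centroid_offset <- c(0, 0, 0)
    out <- invert_center_and_scale(out)
    out
  })
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles the parameters, the architecture config and the
#' diffusion config so a run can be resumed or sampled reproducibly.
#'
#' @param model A `denoiser_model`.
#' @param diffusion_cfg The [diffusion_config()] used in training.
#' @param path File path.
#' @export
save_checkpoint <- function(model, diffusion_cfg, path) {
  saveRDS(list(params = model$params, cfg = model$cfg,
               diffusion_cfg = diffusion_cfg), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  list(model = structure(list(cfg = ck$cfg, params = ck$params),
                         class = "denoiser_model"),
       diffusion_cfg = ck$diffusion_cfg)
}
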