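#' Configure a synthetic latent-factor world
#'
#' The generator emulates the statistical structure a multi-network,
#' multi-subject representational study assumes: several networks whose
#' layer activations are noisy mixtures of (i) latent dimensions shared by
#' all networks and (ii) network-specific latent dimensions, plus brain
#' "subjects" whose voxel responses mix a configurable subset of the shared
#' latents. Stimuli are generated jointly for the fit and evaluation sets
#' and split deterministically by index (fit first, then evaluation).
#'
#' @param n_stim_fit number of fit-set stimuli (used to fit PC bases).
#' @param n_stim_eval number of evaluation-set stimuli (>= 20; metrics are
#'   computed on this split).
#' @param n_networks,n_layers,n_channels,n_spatial network geometry. The
#'   default `n_spatial = 1` keeps layer activations linear in the latents so
#'   that ground-truth variance decompositions are exact; larger values add a
#'   spatial axis that global max pooling later collapses (a nonlinearity).
#' @param n_universal,n_idio counts of shared and per-network latents.
#' @param universal_scale,idio_scale standard deviations of the mixing
#'   loadings for shared and idiosyncratic latents (dimensionless).
#' @param noise_sd additive Gaussian observation noise SD on activations.
#' @param nonneg if TRUE, layer activations are rectified (max(0, .)).
#' @param n_subjects,n_voxels brain geometry.
#' @param brain_latents which shared latents the brain mixes: `"all"`,
#'   `"subset:k"` (first k shared latents), or `"disjoint"` (brain latents
#'   sampled independently of all network latents — the null regime).
#' @param brain_noise_sd additive voxel noise SD (before standardization).
#' @param seed integer seed; identical (config, seed) reproduces every
#'   generated matrix bit-identically.
#' @return an object of class `world_config`.
#' @export
world_config <- function(n_stim_fit = 600, n_stim_eval = 200,
                         n_networks = 6, n_layers = 3, n_channels = 60,
                         n_spatial = 1,
                         n_universal = 3, n_idio = 6,
                         universal_scale = 1, idio_scale = 0.3,
                         noise_sd = 0.1, nonneg = FALSE,
                         n_subjects = 4, n_voxels = 120,
                         brain_latents = "all", brain_noise_sd = 0.1,
                         seed = 1L) {
  cfg <- list(n_stim_fit = as.integer(n_stim_fit),
              n_stim_eval = as.integer(n_stim_eval),
              n_networks = as.integer(n_networks),
              n_layers = as.integer(n_layers),
              n_channels = as.integer(n_channels),
              n_spatial = as.integer(n_spatial),
              n_universal = as.integer(n_universal),
              n_idio = as.integer(n_idio),
              universal_scale = as.numeric(universal_scale),
              idio_scale = as.numeric(idio_scale),
              noise_sd = as.numeric(noise_sd),
              nonneg = isTRUE(nonneg),
              n_subjects = as.integer(n_subjects),
              n_voxels = as.integer(n_voxels),
              brain_latents = as.character(brain_latents),
              brain_noise_sd = as.numeric(brain_noise_sd),
              seed = as.integer(seed))
  counts <- c("n_stim_fit", "n_stim_eval", "n_networks", "n_layers",
              "n_channels", "n_spatial", "n_universal", "n_subjects",
              "n_voxels")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop("configuration error: ", f, " must be >= 1", call. = FALSE)
    }
  }
  if (cfg$n_idio < 0L) stop("configuration error: n_idio must be >= 0", call. = FALSE)
  if (cfg$n_stim_eval < 20L) {
    stop("configuration error: n_stim_eval must be >= 20", call. = FALSE)
  }
  scales <- c("universal_scale", "idio_scale", "noise_sd", "brain_noise_sd")
  for (f in scales) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0) {
      stop("configuration error: ", f, " must be >= 0", call. = FALSE)
    }
  }
  if (!grepl("^(all|disjoint|subset:[0-9]+)$", cfg$brain_latents)) {
    stop("configuration error: brain_latents must be 'all', 'disjoint' or 'subset:k'",
         call. = FALSE)
  }
  class(cfg) <- "world_config"
  cfg
}

# number of brain latents implied by the brain_latents policy
n_brain_latents <- function(config) {
  if (config$brain_latents == "all") return(config$n_universal)
  if (config$brain_latents == "disjoint") return(config$n_universal)
  k <- as.integer(sub("^subset:", "", config$brain_latents))
  if (k < 1L || k > config$n_universal) {
    stop("configuration error: subset:k must have 1 <= k <= n_universal",
         call. = FALSE)
  }
  k
}

#' Generate the latent state of a synthetic world
#'
#' Draws standard-normal latent matrices for the union of fit and evaluation
#' stimuli: one shared latent matrix seen by every network, one idiosyncratic
#' latent matrix per network, and the brain latent matrix selected by the
#' `brain_latents` policy (columns of the shared latents, or an independent
#' draw when `"disjoint"`). Mixing weights for network layers and subjects
#' are drawn here too, so downstream generation is deterministic.
#'
#' @param config a [world_config()].
#' @return an object of class `latent_world` with elements `Z_shared`
#'   (stimuli x n_universal), `Z_idio` (list per network), `Z_brain`,
#'   `W_shared`/`W_idio` (per network, per layer loading matrices),
#'   `B_subject` (per subject voxel loadings), and the config.
#' @export
make_latents <- function(config) {
  stopifnot(inherits(config, "world_config"))
  n_stim <- config$n_stim_fit + config$n_stim_eval
  world <- with_component_seed(config$seed, "latents", {
    Z_shared <- matrix(stats::rnorm(n_stim * config$n_universal),
                       n_stim, config$n_universal)
    Z_idio <- lapply(seq_len(config$n_networks), function(i) {
      matrix(stats::rnorm(n_stim * config$n_idio), n_stim,
             max(config$n_idio, 0L))
    })
    L <- n_brain_latents(config)
    Z_brain <- if (config$brain_latents == "disjoint") {
      matrix(stats::rnorm(n_stim * L), n_stim, L)
    } else {
      Z_shared[, seq_len(L), drop = FALSE]
    }
    W_shared <- vector("list", config$n_networks)
    W_idio <- vector("list", config$n_networks)
    p <- config$n_channels * config$n_spatial
    for (i in seq_len(config$n_networks)) {
      W_shared[[i]] <- lapply(seq_len(config$n_layers), function(l) {
        matrix(stats::rnorm(config$n_universal * p, sd = config$universal_scale),
               config$n_universal, p)
      })
      W_idio[[i]] <- lapply(seq_len(config$n_layers), function(l) {
        matrix(stats::rnorm(config$n_idio * p, sd = config$idio_scale),
               max(config$n_idio, 0L), p)
      })
    }
    B_subject <- lapply(seq_len(config$n_subjects), function(s) {
      matrix(stats::rnorm(L * config$n_voxels), L, config$n_voxels)
    })
    list(Z_shared = Z_shared, Z_idio = Z_idio, Z_brain = Z_brain,
         W_shared = W_shared, W_idio = W_idio, B_subject = B_subject,
         config = config)
  })
  class(world) <- "latent_world"
  world
}

#' Generate the latent state of a null world
#'
#' Networks share latents exactly as in [make_latents()], but the brain
#' latents are sampled independently of all network latents, so brain
#' responses carry no signal about any network dimension. This is the
#' control regime in which universality still spans its full range while
#' the universality/brain-similarity association is absent.
#'
#' @param config a [world_config()]; its `brain_latents` field is forced to
#'   `"disjoint"`.
#' @return a `latent_world`.
#' @export
make_null_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  config$brain_latents <- "disjoint"
  make_latents(config)
}

# indices of the fit and evaluation splits (fit first, deterministic)
split_indices <- function(config) {
  list(fit = seq_len(config$n_stim_fit),
       eval = config$n_stim_fit + seq_len(config$n_stim_eval))
}

#' Generate one network's layerwise activations
#'
#' Each layer's raw activation tensor is
#' `[Z_shared | Z_idio] %*% W_layer + noise`, optionally rectified, with an
#' independent loading matrix per layer. With `universal_scale >= idio_scale`
#' the shared structure dominates the top of every layer's variance spectrum.
#'
#' @param world a `latent_world`.
#' @param network_id 1-based network index.
#' @param split `"fit"`, `"eval"`, or `"all"` — which stimulus rows to emit.
#' @return an `activation_set`: list with `network_id`, `split`, and `layers`,
#'   an ordered list of stimuli x channels matrices (when `n_spatial == 1`)
#'   or stimuli x channels x spatial arrays.
#' @export
make_network <- function(world, network_id, split = c("all", "fit", "eval")) {
  stopifnot(inherits(world, "latent_world"))
  split <- match.arg(split)
  config <- world$config
  if (network_id < 1L || network_id > config$n_networks) {
    stop("network_id out of range", call. = FALSE)
  }
  idx <- switch(split,
                all = seq_len(config$n_stim_fit + config$n_stim_eval),
                fit = split_indices(config)$fit,
                eval = split_indices(config)$eval)
  p <- config$n_channels * config$n_spatial
  Z <- cbind(world$Z_shared, world$Z_idio[[network_id]])
  layers <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    W <- rbind(world$W_shared[[network_id]][[l]],
               world$W_idio[[network_id]][[l]])
    A <- Z %*% W
    if (config$noise_sd > 0) {
      E <- with_component_seed(config$seed,
                               paste0("noise:net", network_id, ":layer", l), {
        matrix(stats::rnorm(nrow(Z) * p, sd = config$noise_sd), nrow(Z), p)
      })
      A <- A + E
    }
    if (config$nonneg) A <- pmax(A, 0)
    A <- A[idx, , drop = FALSE]
    if (config$n_spatial > 1L) {
      dim(A) <- c(length(idx), config$n_channels, config$n_spatial)
    }
    layers[[l]] <- A
  }
  names(layers) <- paste0("layer", seq_len(config$n_layers))
  structure(list(network_id = network_id, split = split, layers = layers),
            class = "activation_set")
}

#' Generate one subject's voxel responses on the evaluation set
#'
#' Voxel responses are `Z_brain %*% B_subject + noise`, then
#' column-standardized (mean 0, SD 1 per voxel), emulating session z-scored
#' trial-averaged responses. Subjects share the brain latents and differ in
#' their voxel loadings and noise.
#'
#' @param world a `latent_world`.
#' @param subject_id 1-based subject index.
#' @return a stimuli x voxels matrix over the evaluation split.
#' @export
make_brain <- function(world, subject_id) {
  stopifnot(inherits(world, "latent_world"))
  config <- world$config
  if (subject_id < 1L || subject_id > config$n_subjects) {
    stop("subject_id out of range", call. = FALSE)
  }
  idx <- split_indices(config)$eval
  V <- world$Z_brain[idx, , drop = FALSE] %*% world$B_subject[[subject_id]]
  if (config$brain_noise_sd > 0) {
    E <- with_component_seed(config$seed, paste0("brainnoise:sub", subject_id), {
      matrix(stats::rnorm(length(idx) * config$n_voxels,
                          sd = config$brain_noise_sd),
             length(idx), config$n_voxels)
    })
    V <- V + E
  }
  # column standardization; constant voxels are left at zero
  mu <- colMeans(V)
  V <- sweep(V, 2L, mu)
  s <- apply(V, 2L, stats::sd)
  s[s == 0] <- 1
  sweep(V, 2L, s, "/")
}

#' Ground-truth shared-variance fraction of principal components
#'
#' For each column of a PC basis fitted to one layer of a generated network,
#' returns the fraction of that component's population variance attributable
#' to the shared latents. With linear activations (`n_spatial = 1`,
#' `nonneg = FALSE`) the decomposition is exact: a PC loading v of layer l has
#' variance `v' (Ws'Ws + Wi'Wi + noise_sd^2 I) v`, of which `v' Ws'Ws v` is
#' shared. This is the generator-side oracle used to validate planted
#' dimension recovery.
#'
#' @param world a `latent_world`.
#' @param network_id,layer_id 1-based indices.
#' @param basis a `pc_basis` fitted to that layer (see [fit_pc_basis()]).
#' @return numeric vector, one fraction in [0, 1] per retained component.
#' @export
shared_variance_fraction <- function(world, network_id, layer_id, basis) {
  stopifnot(inherits(world, "latent_world"), inherits(basis, "pc_basis"))
  config <- world$config
  if (config$n_spatial != 1L || config$nonneg) {
    warning("shared_variance_fraction is exact only for linear activations")
  }
  Ws <- world$W_shared[[network_id]][[layer_id]]
  Wi <- world$W_idio[[network_id]][[layer_id]]
  V <- basis$loadings
  sh <- colSums((Ws %*% V)^2)
  id <- if (nrow(Wi) > 0) colSums((Wi %*% V)^2) else 0
  tot <- sh + id + config$noise_sd^2 * colSums(V^2)
  out <- ifelse(tot > 0, sh / tot, 0)
  as.numeric(out)
}
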