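# Shared fixtures, memoized so the aligned-world pipeline (the costly part)
# is computed once per test run and reused across test files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Aligned world at the study's default conditions: 6 networks x 3 layers x
# 60 channels, 3 universal + 6 idiosyncratic latents, scales 1 / 0.3,
# noise 0.1, 600 fit + 200 eval stimuli, 4 subjects sharing the universal
# latents. Includes ridge score table and ground-truth shared fractions.
aligned_fixture <- function() {
  memo("aligned", {
    cfg <- world_config(seed = 11)
    world <- make_latents(cfg)
    study <- build_study(world)
    plan <- fold_plan(cfg$n_stim_eval, 5, seed = 2)
    engines <- study_engines(study, plan)
    tbl <- score_dimensions(study, plan, engines = engines)
    fr <- unlist(lapply(seq_len(cfg$n_networks), function(i) {
      lapply(seq_len(cfg$n_layers), function(l) {
        shared_variance_fraction(world, i, l, study$bases[[i]][[l]])
      })
    }))
    list(cfg = cfg, world = world, study = study, plan = plan,
         engines = engines, tbl = tbl, shared_fraction = fr)
  })
}

aligned_ols_table <- function() {
  memo("aligned_ols", {
    fx <- aligned_fixture()
    score_dimensions(fx$study, fx$plan, engines = fx$engines, method = "ols")
  })
}

aligned_one_to_one_table <- function() {
  memo("aligned_oto", {
    fx <- aligned_fixture()
    score_dimensions(fx$study, fx$plan, engines = fx$engines,
                     method = "one_to_one")
  })
}

# small world for fast unit tests; any world_config field can be overridden
tiny_config <- function(...) {
  args <- list(n_stim_fit = 120, n_stim_eval = 40, n_networks = 3,
               n_layers = 2, n_channels = 8, n_universal = 2, n_idio = 2,
               n_subjects = 2, n_voxels = 12, seed = 5)
  over <- list(...)
  args[names(over)] <- over
  do.call(world_config, args)
}

# independent ridge oracle: explicit normal equations with centering
oracle_ridge_predict <- function(X_train, y_train, X_test, lambda) {
  mu <- colMeans(X_train)
  ybar <- mean(y_train)
  Xc <- sweep(X_train, 2, mu)
  beta <- solve(crossprod(Xc) + lambda * diag(ncol(Xc)),
                crossprod(Xc, y_train - ybar))
  drop(sweep(X_test, 2, mu) %*% beta) + ybar
}

# brute-force LOO predictions via n refits of the oracle
oracle_loo_predictions <- function(X, y, lambda) {
  vapply(seq_len(nrow(X)), function(i) {
    oracle_ridge_predict(X[-i, , drop = FALSE], y[-i],
                         X[i, , drop = FALSE], lambda)
  }, numeric(1))
}
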