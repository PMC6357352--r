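# Shared fixtures, built once per test session. Heavy objects (the desk
# synthetic pair and its pre-trained encoders) are cached so several test
# files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# a small labelled matrix with reproducible random content
rand_matrix <- function(nr, nc, seed, rfun = stats::rnorm,
                        rprefix = "g", cprefix = "s") {
  set.seed(seed)
  matrix(rfun(nr * nc), nr, nc,
         dimnames = list(paste0(rprefix, seq_len(nr)),
                         paste0(cprefix, seq_len(nc))))
}

# the default-config synthetic corpus/cohort pair used by model-level tests
desk_sim <- function() fixture("desk_sim", function() {
  generate_cohort(synthetic_config(seed = 101))
})

desk_imputed <- function() fixture("desk_imputed", function() {
  knn_impute_responses(desk_sim()$cohort$response)
})

# desk-scale pre-trained encoders: single-candidate grid (64, 32, 16)
desk_encoders <- function() fixture("desk_encoders", function() {
  sim <- desk_sim()
  g <- search_grid(layer1 = 64, layer2 = 32, bottleneck = 16, batch_size = 64,
                   screen_epochs = 5, refit_epochs = 60)
  list(
    menc = grid_search_autoencoder(sim$corpus$mutation, g, seed = 301)$encoder,
    eenc = grid_search_autoencoder(sim$corpus$expression, g, seed = 302)$encoder
  )
})

# small fast training config for model tests
fast_cfg <- function(seed = 1L, max_epochs = 60) {
  train_config(patience = 3, max_epochs = max_epochs, batch_size = 32,
               seed = seed)
}
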