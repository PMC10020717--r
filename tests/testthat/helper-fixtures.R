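# Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fx_case <- function() {
  fixture("case", function() build_case(sample_geometry_params(seed = 42L)))
}

fx_severe_case <- function() {
  fixture("severe_case", function() {
    cfg <- cohort_config(ava = list(dist = "uniform", range = c(0.45, 0.45)))
    build_case(sample_geometry_params(cfg, seed = 7L))
  })
}

fx_profile <- function() {
  fixture("profile", function() solve_profile(fx_case(), flow_rate = 300))
}

fx_samples <- function() {
  fixture("samples", function() {
    sample_fields(fx_case(), fx_profile(), oracle_params(), seed = 5L)
  })
}

# small circle/ellipse/orifice corpus for autoencoder tests
fx_shape_corpus <- function(n = 150, seed = 99) {
  fixture(paste0("shapes", n, "_", seed), function() {
    withr::with_seed(seed, {
      lapply(seq_len(n), function(i) {
        if (i %% 20 == 0) {
          matrix(0, 68, 68)   # empty section: no lumen
        } else if (i %% 3 == 0) {
          rasterize_section(tristar_boundary(runif(1, 40, 220)), 68, 50)
        } else {
          rasterize_section(ellipse_boundary(pi * runif(1, 4, 18)^2,
                                             ellipticity = runif(1, 0, 0.12),
                                             phase = runif(1, 0, pi)), 68, 50)
        }
      })
    })
  })
}

fx_ae <- function() {
  fixture("ae", function() {
    train_autoencoder(fx_shape_corpus(), m = 4, seed = 1, epochs = 1200)
  })
}

# compact trained pipeline shared by surrogate/evaluation tests (small but
# real: 18 geometries x 3 flows, tiny training budget)
fx_mini_run <- function() {
  fixture("mini_run", function() {
    suppressMessages(run_pipeline(
      run_config(n_geometries = 18L, seed = 5L, n_subsets = 6L,
                 ae_epochs = 500L, ae_corpus_max = 400L,
                 surrogate = surrogate_config(epochs = 15L, seed = 2L)),
      verbose = FALSE))
  })
}
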