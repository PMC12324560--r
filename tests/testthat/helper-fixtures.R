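# Shared fixtures: everything is generated in code at test time.

tiny_spec <- function(n = 30, r = 12, sessions = 1, frames = 80, seed = 1)
  cohort_spec(n, n_regions = r, n_sessions = sessions,
              frames_per_session = frames, seed = seed)

# reduced elastic-net grid used in the heavier statistical tests
enet_small <- function()
  model_spec("elastic_net",
             hyper_grid = list(alpha = 0.5,
                               lambda = 10^seq(-3, 3, length.out = 5)))

# dense random symmetric weight matrix (zero diagonal)
random_sc <- function(r, seed = 1) {
  set.seed(seed)
  A <- matrix(stats::runif(r * r), r, r)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

random_spectrum <- function(r, seed = 1, cutoff = NULL)
  graph_spectrum(normalized_laplacian(random_sc(r, seed)), cutoff = cutoff)
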