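# Shared fixtures. Heavy objects (full desk-scale studies and ADMM runs)
# are computed once per session and memoized, so several test files can
# reuse them without repeating minutes of computation.

fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# desk-scale study configuration (the package's standard synthetic study)
desk_config <- function(seed = 1L, ...) run_config(seed = seed, ...)

get_study <- function(seed = 1L) {
  memo(paste0("study", seed), simulate_study(desk_config(seed)))
}

get_phase_full <- function(seed = 1L) {
  memo(paste0("phase_full", seed), phase_estimate(get_study(seed)))
}

# a small, fast geometry for operator-level tests
tiny_sim <- function(seed = 1L, Nx = 32L, Ny = 32L, Nkz = 6L, Nc = 3L,
                     Nshot = 6L, Ry = 2L, amplitude = 1.5) {
  cfg <- sampling_config(Ny, Nkz, Nshot, Ry = Ry, dmax = 4)
  pats <- greedy_optimize(cfg)
  ph <- make_phantom(Nx, Ny, Nkz, seed = seed)
  sens <- make_sensitivities(Nc, Nx, Ny, s = 5L, seed = seed + 1L)
  psi <- make_shot_phases(Nshot, Nx, Ny, amplitude = amplitude,
                          seed = seed + 2L)
  list(cfg = cfg, pats = pats, phantom = ph, sens = sens, psi = psi)
}

rand_cplx <- function(n, sd = 1) {
  complex(real = rnorm(n, sd = sd), imaginary = rnorm(n, sd = sd))
}

rand_carr <- function(dims, sd = 1) array(rand_cplx(prod(dims), sd), dims)

rel_diff <- function(a, b) {
  sqrt(sum(Mod(a - b)^2)) / sqrt(sum(Mod(b)^2))
}

# relative adjoint-identity error |<Ax, y> - <x, A^H y>| / (|Ax||y|)
adjoint_gap <- function(forward, adjoint, x, y) {
  ax <- forward(x)
  aty <- adjoint(y)
  lhs <- sum(Conj(y) * ax)
  rhs <- sum(Conj(aty) * x)
  Mod(lhs - rhs) / (sqrt(sum(Mod(ax)^2)) * sqrt(sum(Mod(y)^2)))
}
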