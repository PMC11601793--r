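# Shared fixtures, built once per test run. The full 80x160 grid carries
# precomputed distance fields and is moderately expensive, so it is cached.

.fixtures <- new.env(parent = emptyenv())

default_cell <- function() build_unit_cell(1)

full_grid <- function() {
  if (is.null(.fixtures$grid)) .fixtures$grid <- lobule_grid(default_cell())
  .fixtures$grid
}

small_mesh <- function(nx = 8, ny = 16) {
  key <- paste0("mesh", nx, "x", ny)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- build_mesh(nx, ny, default_cell())
  }
  .fixtures[[key]]
}

# healthy-tissue constants used throughout
kv_matrix <- function() material_kelvin_voigt(2000, 0.8)

G_HEALTHY_100 <- complex(real = 2000, imaginary = 2 * pi * 100 * 0.8)

# independent dilute-limit oracle for incompressible spherical inclusions
dilute_fat_modulus <- function(phi, Gm, Gi) {
  Gm * (1 + 5 * phi * (Gi - Gm) / (3 * Gm + 2 * Gi))
}
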