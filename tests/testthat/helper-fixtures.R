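# Shared synthetic fixtures, built once per test run and cached.
.fix <- new.env()

fix_axis <- function(n = 512L) default_field_axis(n = n)

# rigid-limit single-label powder spectrum (the no-interaction reference)
fix_single <- function(n = 512L, orientations = 2000L) {
  key <- paste0("single_", n, "_", orientations)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- simulate_powder(nitroxide_system(), fix_axis(n),
                                   orientations = orientations)
  .fix[[key]]
}

# mobile / rigid pair on a 100 G sweep, spin-matched, for mobility tests
fix_mobility_pair <- function(n = 1024L, S = 0.3) {
  key <- paste0("mob_", n, "_", S)
  if (is.null(.fix[[key]])) {
    ax <- default_field_axis(sweep = 100, n = n)
    sys <- nitroxide_system()
    rigid <- simulate_powder(sys, ax)
    mobile <- normalize_to_spins(simulate_mobile(sys, S = S, axis = ax), rigid)
    .fix[[key]] <- list(mobile = mobile, rigid = rigid, axis = ax)
  }
  .fix[[key]]
}

# narrow Gaussian-line reference whose broadened support stays well inside
# the sweep window (for exact area-conservation checks)
fix_line <- function(n = 512L, sigma = 3) {
  ax <- fix_axis(n)
  field_spectrum(ax, deriv_gaussian(ax, 3430, sigma))
}

rel_err <- function(a, b) abs(a - b) / abs(b)
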