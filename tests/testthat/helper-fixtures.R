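# Shared fixtures, memoized across test files (built once per run).

.fx <- new.env(parent = emptyenv())
fixture <- function(name, build) {
  if (is.null(.fx[[name]])) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

# small PB phantom with 3 planted 18-um foci
fx_spec <- function(seed = 7)
  phantom_spec("PB", grid = c(112, 112, 18), focus_plan = list(c(18, 3)),
               seed = seed)

fx_gt <- function() fixture("gt", function() build_phantom(fx_spec()))

# noiseless, perfectly mounted rendering of fx_gt
fx_stack0 <- function() fixture("stack0", function()
  render_stack(fx_gt(), misalignment = c(0, 0), noise_sd = 0))

# full analysis of the noiseless stack (registration skipped: already aligned)
fx_res0 <- function() fixture("res0", function()
  analyze_stack(fx_stack0(), core_diameter_um = fx_gt()$core_diameter_um,
                register = FALSE))

# a luminance slice with real structure, for registration tests
fx_slice <- function() luminance(fx_stack0()$images[[6]])

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# digital ball of radius r voxels on an isotropic grid
digital_ball <- function(r, pad = 3) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  x <- seq_len(n)
  d2 <- outer(outer((x - c0)^2, (x - c0)^2, "+"), (x - c0)^2, "+")
  array(d2 <= r^2, c(n, n, n))
}
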