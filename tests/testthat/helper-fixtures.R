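# Small in-code fixtures shared across test files.

# smooth imposed anisotropy field with lateral + vertical structure
make_r_field <- function(nr, nc, base = 0.18, amp = 0.04) {
  X <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  Y <- matrix(rep(0:(nr - 1), nc), nr, nc)
  base + amp * X / nc + amp / 2 * sin(Y / 20)
}

# imposed vignetted G-factor field: g = 1 + 0.1 x / W
make_g_field <- function(nr, nc) {
  1 + 0.1 * matrix(rep(0:(nc - 1), each = nr), nr, nc) / nc
}

# run the full scene -> split -> (register) -> anisotropy chain
recover_r <- function(scene, g_field, transform = NULL,
                      tlow = 1000, thigh = 65535) {
  pair <- split_dual_view(scene$frame)
  if (!is.null(transform)) pair <- apply_transform(pair, transform)
  else pair$registered <- TRUE
  gm <- structure(list(g = g_field, source = "imposed"), class = "GFactorMap")
  compute_anisotropy_map(pair, gm, tlow, thigh)
}

interior_mask <- function(nr, nc, margin = 8) {
  m <- matrix(FALSE, nr, nc)
  m[(margin + 1):(nr - margin), (margin + 1):(nc - margin)] <- TRUE
  m
}
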