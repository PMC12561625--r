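# Shared builders for the test suite. Everything is generated in code;
# no stored fixtures.

make_mosaic <- function(h = 8, w = 8, kind = "blobs", seed = 1,
                        params = list(n_blobs = 1, radius = 1.5),
                        noise = noise_model("none"), phase = "even") {
  x <- generate_scene(scene_spec(kind, h, w, params, seed = seed))
  m <- build_checkerboard_mask(h, w, phase = phase)
  list(x = x, mask = m, y = apply_forward_model(x, m, noise))
}

random_stack <- function(h = 6, w = 6, c = 6, seed = 1) {
  set.seed(seed)
  spectral_stack(array(runif(h * w * c), c(h, w, c)),
                 channels = if (c == 6) NULL else paste0("ch", seq_len(c)))
}

# scalar-loop L1 mean, the brute-force oracle used across loss tests
loop_l1 <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
  s / length(a)
}
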