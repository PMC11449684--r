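# Shared small fixtures, built once per test run.

# Smallest input size for which all three conv blocks stay valid is ~89px;
# 96 keeps the arithmetic round.
tiny_input <- c(96L, 96L, 3L)

tiny_net <- function(num_classes = 4L) {
  network_spec(input_shape = tiny_input, num_classes = num_classes)
}

# cache: one small phantom set reused across files
.fixture_env <- new.env(parent = emptyenv())

tiny_phantoms <- function() {
  if (is.null(.fixture_env$ph)) {
    .fixture_env$ph <- generate_phantoms(
      n_per_class = 10L, image_size = tiny_input[1:2],
      noise_sd = 0.05, seed = 101L)
  }
  .fixture_env$ph
}

# grid of evaluation points away from the piecewise kinks at 0
kink_free_grid <- c(-3.7, -2.1, -1.3, -0.41, -0.09, 0.07, 0.37, 0.9,
                    1.7, 2.6, 4.2)
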