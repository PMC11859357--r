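# Shared fixtures: a coarse toy chromophore set with hand-pickable values and
# a two-layer toy model, both cheap enough for property loops.

toy_grid <- seq(1000, 1700, by = 100)

toy_chromophores <- function(water = NULL, blood = NULL, other = NULL) {
  n <- length(toy_grid)
  chromophore_set(toy_grid,
                  water %||% seq(0.5, 5, length.out = n),
                  blood %||% seq(2, 4, length.out = n),
                  other %||% rep(1, n))
}

toy_model <- function(g = 0.9, glass = TRUE) {
  skin_model(
    list(skin_layer("epi", "living_epidermis", 0.01, 0, 0.2, g = g),
         skin_layer("derm", "dermal", 0.5, 0.1, 0.6, g = g)),
    superstrate_thickness_cm = if (glass) 0.02 else 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual / expected - 1) <= tol),
              label = sprintf("max rel dev %.3g vs tol %.3g",
                              max(abs(actual / expected - 1)), tol))
}
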