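# Shared fixtures, built in code at test time.

# Downscaled phantom for fast unit tests; same statistical structure as the
# default study-regime configuration.
small_phantom_config <- function(seed = 1L, ...) {
  phantom_config(
    grid = image_grid(c(48, 48, 6), c(1, 1, 2.5)),
    outer_radius_mm = 19,
    wm_radius_mm = 10,
    infarct_radius_mm = 5.5,
    seed = seed,
    ...
  )
}

# A random pixel class table in the shape build_class_table() emits: unit
# weights, ties possible (CBF rounded to a coarse lattice).
random_class_table <- function(n1 = 40, n0 = 120, round_to = 0.5) {
  tibble::tibble(
    cbf = round(c(rnorm(n1, 15, 6), rnorm(n0, 30, 8)) / round_to) * round_to,
    label = rep(c(1L, 0L), c(n1, n0)),
    weight = 1
  )
}

# Tiny single-slice study assembled by hand for rule-level tests.
flat_grid <- function(n = 5) image_grid(c(n, n, 1), c(1, 1, 1))

# Exhaustive Mann-Whitney concordance (ties count one half), the
# independent AUC oracle. Weighted by pair mass.
mw_concordance <- function(table) {
  pos <- table[table$label == 1L, ]
  neg <- table[table$label == 0L, ]
  num <- 0
  den <- 0
  for (i in seq_len(nrow(pos))) {
    for (j in seq_len(nrow(neg))) {
      w <- pos$weight[i] * neg$weight[j]
      s <- if (pos$cbf[i] < neg$cbf[j]) 1 else if (pos$cbf[i] == neg$cbf[j]) 0.5 else 0
      num <- num + w * s
      den <- den + w
    }
  }
  num / den
}
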