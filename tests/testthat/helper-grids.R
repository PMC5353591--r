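# small in-code fixtures shared across test files

make_grid <- function(vals, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  image_grid(vals, spacing, origin)
}

const_grid <- function(value, shape = c(4, 4, 4), spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  image_grid(array(value, dim = shape), spacing, origin)
}

full_mask <- function(shape = c(4, 4, 4), spacing = c(1, 1, 1),
                      origin = c(0, 0, 0)) {
  binary_mask(array(TRUE, dim = shape), spacing, origin)
}

random_mask <- function(shape, p = 0.5, spacing = c(1, 1, 1)) {
  binary_mask(array(runif(prod(shape)) < p, dim = shape), spacing)
}

random_dose_on_mask <- function(n_mask = 500, max_dose = 60) {
  # a flat mask of exactly n_mask voxels inside a slightly larger grid,
  # with uniform random dose and a spike of exact-tie values
  shape <- c(n_mask, 1L, 1L) + c(4L, 1L, 1L)
  mvals <- array(FALSE, dim = shape)
  mvals[3:(n_mask + 2), 1, 1] <- TRUE
  d <- array(0, dim = shape)
  doses <- runif(n_mask, 0, max_dose)
  tie_idx <- sample(n_mask, n_mask %/% 10)
  doses[tie_idx] <- round(doses[tie_idx])
  d[mvals] <- doses
  list(dose = image_grid(d, c(1, 1, 1)), mask = binary_mask(mvals, c(1, 1, 1)))
}

# strip an equivalence-labelled dominance string into ordered groups,
# e.g. "Q \u2248 V > CT" -> list(c("Q","V"), "CT") with groups sorted
dominance_groups <- function(label) {
  lapply(strsplit(label, " > ", fixed = TRUE)[[1]],
         function(g) sort(strsplit(g, "\u0020\u2248\u0020", fixed = TRUE)[[1]]))
}
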