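# shared fixture builders; everything is generated in code at test time

small_cohort_config <- function(seed = 1, ...) {
  sim_cohort_config(mice_per_group = 2, cells_per_mouse = 120,
                    n_genes = 300, n_mito_genes = 6, program_size = 15,
                    seed = seed, ...)
}

# dense random count matrix with dimnames
random_counts <- function(n_genes, n_cells, lambda = 1, seed = 1,
                          sparse = FALSE) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("c%04d", seq_len(n_cells))))
    if (sparse) methods::as(Matrix::Matrix(m, sparse = TRUE),
                            "CsparseMatrix") else m
  })
}

# noise-free single-plaque image centered on a pixel, for geometry tests
centered_plaque_image <- function(size = 181, pixel_size_um = 1,
                                  lambda = 20, radius = 8,
                                  baseline = 0.2, amplitude = 1) {
  ctr <- (size + 1) / 2
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  d <- sqrt((rows - ctr)^2 + (cols - ctr)^2) * pixel_size_um
  list(channels = list(plaque = (d <= radius) * 1,
                       up = baseline + amplitude * exp(-d / lambda),
                       down = baseline + amplitude * (1 - exp(-d / lambda))),
       pixel_size_um = pixel_size_um,
       center = c(ctr, ctr))
}
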