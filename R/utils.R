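# Small shared helpers.

# Boltzmann constant in kJ/(mol K); k_B * 300 K = 2.494 kJ/mol.
.KB_KJMOL <- 0.008314462618

.assert_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(what, " must be a single positive number", call. = FALSE)
  }
  invisible(x)
}

# Euclidean norm per row.
.row_norms <- function(m) sqrt(rowSums(m^2))

# Minimum-image displacement components for a cubic box of edge `box`.
.min_image <- function(d, box) d - box * round(d / box)
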